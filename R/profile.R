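## Methylome summaries: PCA of samples over windows, variable-region
## hierarchical clustering, group mean bar plots, chromosome-scale tracks
## and metagene profiles. Every figure has a TSV twin; figures never alter
## the computed numbers.

#' Principal component analysis of samples over windows
#'
#' Samples are the observations and windows the variables; columns are
#' mean-centered but not variance-scaled (all windows already share the
#' `[0, 1]` level scale, and scaling would inflate near-constant windows).
#'
#' @param wm A `window_matrix`.
#' @param out_prefix Optional path prefix; when given, writes
#'   `<prefix>_pca.tsv` and `<prefix>_pca.png` (300 dpi).
#' @param dpi Figure resolution.
#' @return List with `coords` (`data.table`: `sample_name`, `group`, `PC1`,
#'   `PC2`), `var_explained` (fractions per component) — or `NULL` with a
#'   warning when fewer than 3 samples are available (2 points always
#'   separate trivially).
#' @export
run_pca <- function(wm, out_prefix = NULL, dpi = 300) {
  stopifnot(is(wm, "window_matrix"))
  if (length(wm$samples) < 3L) {
    warning("PCA skipped: fewer than 3 samples")
    return(NULL)
  }
  if (nrow(wm$windows) < 2L) {
    warning("PCA skipped: fewer than 2 windows")
    return(NULL)
  }
  x <- t(wm$levels)
  total_var <- sum(apply(x, 2L, var))
  if (total_var == 0) {
    warning("PCA skipped: matrix has zero variance")
    return(NULL)
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- data.table(sample_name = rownames(pc$x),
                       group = unname(wm$groups[rownames(pc$x)]),
                       PC1 = pc$x[, 1L],
                       PC2 = if (ncol(pc$x) >= 2L) pc$x[, 2L] else 0)
  res <- list(coords = coords, var_explained = ve, context = wm$context)
  if (!is.null(out_prefix)) {
    fwrite(coords, paste0(out_prefix, "_pca.tsv"), sep = "\t")
    p <- ggplot2::ggplot(coords, ggplot2::aes(PC1, PC2, colour = group)) +
      ggplot2::geom_point(size = 3) +
      ggplot2::labs(
        title = paste0("PCA of ", wm$context, " methylation windows"),
        x = sprintf("PC1 (%.1f%%)", 100 * ve[1L]),
        y = sprintf("PC2 (%.1f%%)", 100 * ve[min(2L, length(ve))])) +
      ggplot2::theme_bw()
    ggplot2::ggsave(paste0(out_prefix, "_pca.png"), p, width = 5, height = 4,
                    dpi = dpi)
  }
  res
}

#' Select variable methylation regions
#'
#' Retains windows whose across-sample spread (max minus min cell value)
#' is at least `threshold`, preserving the original order.
#'
#' @param wm A `window_matrix`.
#' @param threshold Minimum max-minus-min methylation difference, in
#'   `(0, 1]` (default 0.20).
#' @return A `window_matrix` restricted to the variable rows, with
#'   attribute `threshold`; `NULL` with a warning when no row qualifies.
#' @export
select_variable_regions <- function(wm, threshold = 0.20) {
  stopifnot(is(wm, "window_matrix"))
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  spread <- apply(wm$levels, 1L, max) - apply(wm$levels, 1L, min)
  keep <- spread >= threshold
  if (!any(keep)) {
    warning("no variable regions at threshold ", threshold)
    return(NULL)
  }
  out <- wm
  out$windows <- wm$windows[keep]
  out$levels <- wm$levels[keep, , drop = FALSE]
  out$n_sites <- wm$n_sites[keep, , drop = FALSE]
  keep_idx <- which(keep)
  out$sites <- wm$sites[window %in% keep_idx]
  out$sites[, window := match(window, keep_idx)]
  attr(out, "threshold") <- threshold
  out
}

#' Hierarchical clustering heatmap of variable regions
#'
#' Rows (regions) and columns (samples) are ordered by agglomerative
#' clustering with Euclidean distance and average linkage. The computed
#' orders are returned (and written as TSV) so the clustering is testable
#' independently of the rendered figure.
#'
#' @param vr A `window_matrix`, typically from [select_variable_regions()].
#' @param out_prefix Optional path prefix; writes `<prefix>_heatmap.png`
#'   and `<prefix>_heatmap_order.tsv`.
#' @param dpi Figure resolution.
#' @return List with `row_order`, `col_order` (labels in dendrogram order)
#'   and the `hclust` objects `row_hclust`, `col_hclust`.
#' @export
cluster_heatmap <- function(vr, out_prefix = NULL, dpi = 300) {
  stopifnot(is(vr, "window_matrix"))
  m <- vr$levels
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("heatmap needs at least 2 regions and 2 samples", call. = FALSE)
  }
  hc_row <- hclust(dist(m, method = "euclidean"), method = "average")
  hc_col <- hclust(dist(t(m), method = "euclidean"), method = "average")
  res <- list(row_order = rownames(m)[hc_row$order],
              col_order = colnames(m)[hc_col$order],
              row_hclust = hc_row, col_hclust = hc_col)
  if (!is.null(out_prefix)) {
    fwrite(data.table(rank = seq_along(res$col_order),
                      sample_name = res$col_order),
           paste0(out_prefix, "_heatmap_order.tsv"), sep = "\t")
    grDevices::png(paste0(out_prefix, "_heatmap.png"), width = 5, height = 6,
                   units = "in", res = dpi)
    pheatmap::pheatmap(m, cluster_rows = hc_row, cluster_cols = hc_col,
                       show_rownames = nrow(m) <= 50,
                       main = paste0("Variable ", vr$context, " regions"))
    grDevices::dev.off()
  }
  res
}

#' Group mean bar data across contexts
#'
#' Convenience wrapper turning [group_means()] results for several contexts
#' into one tidy table (and optionally a bar figure).
#'
#' @param gm_list List of [group_means()] results (one per context).
#' @param out_prefix Optional path prefix; writes `<prefix>_group_means.tsv`
#'   and `.png`.
#' @param dpi Figure resolution.
#' @return A `data.table` with `context`, `group`, `mean_level`.
#' @export
group_mean_barplot <- function(gm_list, out_prefix = NULL, dpi = 300) {
  dt <- rbindlist(lapply(gm_list, function(gm) {
    data.table(context = gm$context, group = names(gm$group_means),
               mean_level = unname(gm$group_means))
  }))
  if (!is.null(out_prefix)) {
    fwrite(dt, paste0(out_prefix, "_group_means.tsv"), sep = "\t")
    p <- ggplot2::ggplot(dt, ggplot2::aes(context, mean_level, fill = group)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(y = "Mean methylation level", x = "Context") +
      ggplot2::theme_bw()
    ggplot2::ggsave(paste0(out_prefix, "_group_means.png"), p,
                    width = 5, height = 4, dpi = dpi)
  }
  dt[]
}

#' Chromosome-scale methylation track
#'
#' Tiles the genome into large windows (default 1 Mb) and reports each
#' sample's mean level of the requested context per window; windows with
#' fewer than `min_cytosines` context cytosines in a sample are masked
#' (`NA`) for that sample. The delta track is the experimental-group mean
#' minus the control-group mean per window.
#'
#' @param sheet A `sample_sheet`.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param window_bp Track window width (default 1e6).
#' @param chrom_sizes Optional named chromosome lengths.
#' @param min_cytosines Minimum context cytosines per window per sample
#'   (default 4). No depth filter is applied at this scale.
#' @param out_prefix Optional path prefix; writes `<prefix>_track.tsv` and
#'   `.png` (per-chromosome facets: one line per sample plus a delta
#'   panel).
#' @param dpi Figure resolution.
#' @return An object of class `genome_track`: list with `windows`
#'   (`data.table` of all tiled windows), `levels` (windows x samples, `NA`
#'   where masked), `delta`, `context`, `window_bp`.
#' @export
genome_track <- function(sheet, context = "CG", window_bp = 1000000L,
                         chrom_sizes = NULL, min_cytosines = 4L,
                         out_prefix = NULL, dpi = 300) {
  stopifnot(is(sheet, "sample_sheet"))
  ctx <- context
  pieces <- list()
  max_pos <- list()
  for (i in seq_len(nrow(sheet))) {
    calls <- read_cgmap(sheet$path[i], min_depth = 1L)
    for (ch in unique(calls$chrom)) {
      m <- max(calls$position[calls$chrom == ch])
      max_pos[[ch]] <- max(max_pos[[ch]] %||% 0L, m)
    }
    sel <- calls[context == ctx, .(chrom, position, level)]
    sel[, sample_name := sheet$sample_name[i]]
    pieces[[i]] <- sel
  }
  if (is.null(chrom_sizes)) chrom_sizes <- unlist(max_pos)
  chrom_sizes <- .as_chrom_sizes(chrom_sizes)
  windows <- tile_genome(chrom_sizes, window_bp)
  windows[, window := .I]
  sites <- rbindlist(pieces)
  sites[, win_start := ((position - 1L) %/% as.integer(window_bp)) *
          as.integer(window_bp) + 1L]
  cell <- sites[, .(n = .N, mean_level = mean(level)),
                by = .(chrom, win_start, sample_name)]
  cell <- cell[n >= min_cytosines]

  lv <- matrix(NA_real_, nrow(windows), nrow(sheet),
               dimnames = list(paste0(windows$chrom, ":", windows$start),
                               sheet$sample_name))
  ridx <- match(paste(cell$chrom, cell$win_start),
                paste(windows$chrom, windows$start))
  lv[cbind(ridx, match(cell$sample_name, sheet$sample_name))] <-
    cell$mean_level

  groups <- setNames(sheet$group, sheet$sample_name)
  control <- attr(sheet, "control")
  ctrl_cols <- names(groups)[groups == control]
  exp_cols <- names(groups)[groups != control]
  mean_of <- function(cols) rowMeans(lv[, cols, drop = FALSE], na.rm = TRUE)
  delta_v <- mean_of(exp_cols) - mean_of(ctrl_cols)
  delta_v[!is.finite(delta_v)] <- NA_real_

  res <- structure(list(windows = windows[, .(chrom, start, end)],
                        levels = lv, delta = unname(delta_v),
                        context = context, window_bp = as.integer(window_bp)),
                   class = "genome_track")
  if (!is.null(out_prefix)) {
    dt <- cbind(res$windows, as.data.table(lv), delta = res$delta)
    fwrite(dt, paste0(out_prefix, "_track.tsv"), sep = "\t")
    long <- melt(dt, id.vars = c("chrom", "start", "end", "delta"),
                 variable.name = "sample_name", value.name = "level")
    p1 <- ggplot2::ggplot(long, ggplot2::aes(start / 1e6, level,
                                             colour = sample_name)) +
      ggplot2::geom_line(na.rm = TRUE) +
      ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
      ggplot2::labs(x = "Position (Mb)",
                    y = paste0(context, " level")) +
      ggplot2::theme_bw()
    p2 <- ggplot2::ggplot(unique(long[, .(chrom, start, delta)]),
                          ggplot2::aes(start / 1e6, delta)) +
      ggplot2::geom_line(na.rm = TRUE, colour = "grey30") +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
      ggplot2::labs(x = "Position (Mb)", y = "Δ level") +
      ggplot2::theme_bw()
    grDevices::png(paste0(out_prefix, "_track.png"), width = 8, height = 6,
                   units = "in", res = dpi)
    print(p1 + ggplot2::theme(legend.position = "bottom"))
    grDevices::dev.off()
    grDevices::png(paste0(out_prefix, "_track_delta.png"), width = 8,
                   height = 3, units = "in", res = dpi)
    print(p2)
    grDevices::dev.off()
  }
  res
}

## bin index for one call relative to one gene; returns NA outside the
## gene +/- flank. Bins run 1..n_flank (upstream, far -> near TSS), then
## n_flank+1..n_flank+n_body (body TSS -> TES), then downstream near -> far.
.metagene_bin <- function(pos, g_start, g_end, g_strand, flank_bp,
                          n_body_bins, n_flank_bins) {
  binw <- flank_bp / n_flank_bins
  len <- g_end - g_start + 1L
  if (g_strand == "+") {
    if (pos < g_start) {
      d <- g_start - pos
      if (d > flank_bp) return(NA_integer_)
      return(n_flank_bins - as.integer(ceiling(d / binw)) + 1L)
    }
    if (pos > g_end) {
      d <- pos - g_end
      if (d > flank_bp) return(NA_integer_)
      return(n_flank_bins + n_body_bins + as.integer(ceiling(d / binw)))
    }
    frac <- (pos - g_start) / len
    return(n_flank_bins + min(n_body_bins, as.integer(floor(frac * n_body_bins)) + 1L))
  }
  ## minus strand: mirror so upstream is always left
  if (pos > g_end) {
    d <- pos - g_end
    if (d > flank_bp) return(NA_integer_)
    return(n_flank_bins - as.integer(ceiling(d / binw)) + 1L)
  }
  if (pos < g_start) {
    d <- g_start - pos
    if (d > flank_bp) return(NA_integer_)
    return(n_flank_bins + n_body_bins + as.integer(ceiling(d / binw)))
  }
  frac <- (g_end - pos) / len
  n_flank_bins + min(n_body_bins, as.integer(floor(frac * n_body_bins)) + 1L)
}

#' Metagene methylation profile
#'
#' Averages methylation over length-normalized gene bodies plus fixed
#' flanks: each gene body is rescaled to `n_body_bins` equal-fraction bins
#' and each `flank_bp` flank is cut into `n_flank_bins` fixed-width bins.
#' Minus-strand genes are flipped so upstream is always on the left. The
#' per-bin value is first averaged within gene (over eligible cytosines),
#' then across genes (genes with no data in a bin skip that bin), then
#' across a group's samples; the delta profile is experimental minus
#' control.
#'
#' @param sheet A `sample_sheet`.
#' @param models A `gene_models` object.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param flank_bp Flank width (default 2000).
#' @param n_body_bins,n_flank_bins Bin counts (default 20 each, i.e. 100-bp
#'   flank bins).
#' @param min_depth Minimum reads per contributing cytosine (default 4,
#'   matching the window eligibility filter).
#' @param out_prefix Optional path prefix; writes `<prefix>_metagene.tsv`
#'   and `.png` with TSS/TES marks.
#' @param dpi Figure resolution.
#' @return An object of class `metagene_profile`: list with `bins`
#'   (`data.table`: `bin`, `region` in upstream/body/downstream, per-group
#'   mean columns, `delta`), `sample_profiles` (bins x samples matrix),
#'   `n_genes_used`, `n_genes_skipped`.
#' @export
metagene <- function(sheet, models, context = "CG", flank_bp = 2000L,
                     n_body_bins = 20L, n_flank_bins = 20L, min_depth = 4L,
                     out_prefix = NULL, dpi = 300) {
  stopifnot(is(sheet, "sample_sheet"), is(models, "gene_models"))
  genes <- models$genes
  if (nrow(genes) == 0L) stop("no genes provided", call. = FALSE)
  too_short <- (genes$end - genes$start + 1L) < n_body_bins
  if (any(too_short)) {
    message(sum(too_short), " gene(s) shorter than n_body_bins bp skipped")
    genes <- genes[!too_short]
    if (nrow(genes) == 0L) stop("all genes too short", call. = FALSE)
  }
  ctx <- context
  n_bins <- 2L * n_flank_bins + n_body_bins

  sample_profiles <- matrix(NA_real_, n_bins, nrow(sheet),
                            dimnames = list(NULL, sheet$sample_name))
  for (i in seq_len(nrow(sheet))) {
    calls <- read_cgmap(sheet$path[i], min_depth = min_depth)
    calls <- calls[context == ctx & !low_depth]
    ## per gene x bin means, then average over genes per bin
    acc_sum <- matrix(0, n_bins, 1L)
    acc_n <- matrix(0L, n_bins, 1L)
    for (g in seq_len(nrow(genes))) {
      lo <- genes$start[g] - flank_bp
      hi <- genes$end[g] + flank_bp
      sub <- calls[chrom == genes$chrom[g] & position >= lo & position <= hi]
      if (nrow(sub) == 0L) next
      bins <- vapply(sub$position, .metagene_bin, integer(1),
                     g_start = genes$start[g], g_end = genes$end[g],
                     g_strand = genes$strand[g], flank_bp = flank_bp,
                     n_body_bins = n_body_bins, n_flank_bins = n_flank_bins)
      ok <- !is.na(bins)
      if (!any(ok)) next
      gm <- tapply(sub$level[ok], bins[ok], mean)
      idx <- as.integer(names(gm))
      acc_sum[idx] <- acc_sum[idx] + gm
      acc_n[idx] <- acc_n[idx] + 1L
    }
    prof <- acc_sum / acc_n
    prof[acc_n == 0L] <- NA_real_
    sample_profiles[, i] <- prof
  }

  groups <- setNames(sheet$group, sheet$sample_name)
  control <- attr(sheet, "control")
  glabels <- unique(c(control, unname(groups)))
  gmeans <- vapply(glabels, function(g) {
    rowMeans(sample_profiles[, names(groups)[groups == g], drop = FALSE],
             na.rm = TRUE)
  }, numeric(n_bins))
  region <- c(rep("upstream", n_flank_bins), rep("body", n_body_bins),
              rep("downstream", n_flank_bins))
  bins_dt <- data.table(bin = seq_len(n_bins), region = region)
  for (g in glabels) set(bins_dt, j = g, value = gmeans[, g])
  set(bins_dt, j = "delta", value = gmeans[, 2L] - gmeans[, 1L])

  res <- structure(list(bins = bins_dt, sample_profiles = sample_profiles,
                        context = context, flank_bp = as.integer(flank_bp),
                        n_body_bins = as.integer(n_body_bins),
                        n_flank_bins = as.integer(n_flank_bins),
                        n_genes_used = nrow(genes),
                        n_genes_skipped = sum(too_short)),
                   class = "metagene_profile")
  if (!is.null(out_prefix)) {
    fwrite(bins_dt, paste0(out_prefix, "_metagene.tsv"), sep = "\t")
    long <- melt(bins_dt, id.vars = c("bin", "region", "delta"),
                 variable.name = "group", value.name = "level")
    tss <- n_flank_bins + 0.5
    tes <- n_flank_bins + n_body_bins + 0.5
    p <- ggplot2::ggplot(long, ggplot2::aes(bin, level, colour = group)) +
      ggplot2::geom_line(na.rm = TRUE) +
      ggplot2::geom_vline(xintercept = c(tss, tes), linetype = 2) +
      ggplot2::annotate("text", x = c(tss, tes), y = Inf,
                        label = c("TSS", "TES"), vjust = 1.5) +
      ggplot2::labs(x = "Metagene bin (upstream | body | downstream)",
                    y = paste0(context, " level")) +
      ggplot2::theme_bw()
    ggplot2::ggsave(paste0(out_prefix, "_metagene.png"), p, width = 6,
                    height = 4, dpi = dpi)
  }
  res
}
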