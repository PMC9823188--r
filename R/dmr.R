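## Differentially methylated region (DMR) and gene (DMG) calling.
##
## A window is a DMR when |delta| >= min_delta AND p < alpha, where delta is
## the experimental-group mean minus the control-group mean of the window's
## cell values, and p comes from a two-sample test on the window's
## observations. By default the observations are the per-cytosine levels
## pooled across a group's replicates, which keeps the tests meaningful even
## in 1-vs-1 designs; a replicate-means mode tests the per-replicate window
## means instead. Raw p-values are thresholded (no multiplicity correction
## by default); an optional Benjamini-Hochberg flag adds q-values.

#' DMR calling parameters
#'
#' @param test Two-sample test: `"ttest"` (Welch by default), `"ks"`
#'   (Kolmogorov–Smirnov) or `"mannwhitney"` (Mann–Whitney U / Wilcoxon
#'   rank-sum).
#' @param min_delta Minimum absolute group mean difference (default 0.10).
#' @param alpha Raw p-value cutoff (default 0.05).
#' @param var_equal For `"ttest"` only: pooled-variance Student's t instead
#'   of Welch.
#' @param adjust Also compute Benjamini–Hochberg q-values (reported, not
#'   used for thresholding).
#' @return A list of class `dmr_params`.
#' @export
dmr_params <- function(test = c("ttest", "ks", "mannwhitney"),
                       min_delta = 0.10, alpha = 0.05,
                       var_equal = FALSE, adjust = FALSE) {
  test <- match.arg(test)
  if (!(min_delta > 0 && min_delta <= 1)) {
    stop("min_delta must be in (0, 1]", call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(test = test, min_delta = min_delta, alpha = alpha,
                 var_equal = var_equal, adjust = adjust),
            class = "dmr_params")
}

#' Two-sample test on one window's observations
#'
#' Returns the two-sided p-value of the chosen test comparing the two
#' observation vectors (per-cytosine methylation levels, or per-replicate
#' window means). Conventions: when both groups have zero variance and
#' equal means the p-value is 1; when a test cannot be computed (too few
#' observations) the result is `NA` and the caller skips the window.
#'
#' @param control_obs,experimental_obs Numeric vectors of levels in
#'   `[0, 1]`.
#' @param test `"ttest"`, `"ks"` or `"mannwhitney"`.
#' @param var_equal Pooled-variance t test instead of Welch.
#' @return A p-value in `[0, 1]`, or `NA_real_`.
#' @export
test_window <- function(control_obs, experimental_obs,
                        test = c("ttest", "ks", "mannwhitney"),
                        var_equal = FALSE) {
  test <- match.arg(test)
  x <- control_obs[!is.na(control_obs)]
  y <- experimental_obs[!is.na(experimental_obs)]
  min_n <- if (test == "ttest") 2L else 1L
  if (length(x) < min_n || length(y) < min_n) return(NA_real_)
  ## degenerate case: no variation anywhere
  if (sd(c(x, y)) == 0) return(1)
  p <- switch(test,
    ttest = tryCatch(
      t.test(x, y, var.equal = var_equal)$p.value,
      error = function(e) NA_real_),
    ks = suppressWarnings(ks.test(x, y)$p.value),
    mannwhitney = suppressWarnings(wilcox.test(x, y)$p.value))
  ## a t test on two constant groups with different means has zero
  ## denominator; treat as perfectly separated
  if (test == "ttest" && is.na(p) && sd(x) == 0 && sd(y) == 0) {
    p <- if (mean(x) == mean(y)) 1 else 0
  }
  as.numeric(p)
}

#' Call DMRs between the two groups of a window matrix
#'
#' Per retained window: delta = experimental group mean minus control group
#' mean of the cell values; the window is emitted as a DMR when
#' `|delta| >= min_delta` and the test p-value is below `alpha`. Windows
#' whose test cannot be computed are skipped and counted, never treated as
#' significant.
#'
#' @param wm A `window_matrix` from [build_matrix()].
#' @param params A [dmr_params()].
#' @param mode `"pooled"` (default): test the per-cytosine levels pooled
#'   across each group's replicates; `"replicate_means"`: test the
#'   per-replicate window means (needs >= 2 replicates per group for the t
#'   test).
#' @return A `data.table` of class `dmr_set` with columns `chrom`, `start`,
#'   `end`, `context`, `mean_control`, `mean_experimental`, `delta`,
#'   `p_value`, (optionally `q_value`,) `direction`; attributes record the
#'   parameters and the tested / skipped / hyper / hypo counts.
#' @export
call_dmrs <- function(wm, params = dmr_params(),
                      mode = c("pooled", "replicate_means")) {
  stopifnot(is(wm, "window_matrix"), is(params, "dmr_params"))
  mode <- match.arg(mode)
  groups <- wm$groups
  control <- wm$control
  ctrl_samples <- names(groups)[groups == control]
  exp_samples <- names(groups)[groups != control]

  nwin <- nrow(wm$windows)
  mean_ctrl <- rowMeans(wm$levels[, ctrl_samples, drop = FALSE])
  mean_exp <- rowMeans(wm$levels[, exp_samples, drop = FALSE])

  pvals <- rep(NA_real_, nwin)
  if (mode == "pooled") {
    sites <- wm$sites
    ## split once instead of filtering per window
    lev_split <- split(sites$level, sites$window)
    grp_split <- split(sites$sample_name %in% ctrl_samples, sites$window)
    for (k in seq_along(lev_split)) {
      w <- as.integer(names(lev_split)[k])
      is_ctrl <- grp_split[[k]]
      pvals[w] <- test_window(lev_split[[k]][is_ctrl],
                              lev_split[[k]][!is_ctrl],
                              test = params$test,
                              var_equal = params$var_equal)
    }
  } else {
    for (w in seq_len(nwin)) {
      pvals[w] <- test_window(wm$levels[w, ctrl_samples],
                              wm$levels[w, exp_samples],
                              test = params$test,
                              var_equal = params$var_equal)
    }
  }

  delta_w <- mean_exp - mean_ctrl
  skipped <- is.na(pvals)
  hit <- !skipped & abs(delta_w) >= params$min_delta & pvals < params$alpha

  out <- data.table(chrom = wm$windows$chrom[hit],
                    start = wm$windows$start[hit],
                    end = wm$windows$end[hit],
                    context = wm$context,
                    mean_control = mean_ctrl[hit],
                    mean_experimental = mean_exp[hit],
                    delta = delta_w[hit],
                    p_value = pvals[hit])
  if (params$adjust) {
    q <- stats::p.adjust(pvals, method = "BH")
    out[, q_value := q[hit]]
  }
  out[, direction := fifelse(delta > 0, "hyper", "hypo")]
  setorder(out, chrom, start)
  structure(out, class = c("dmr_set", class(out)),
            context = wm$context, params = params, mode = mode,
            n_tested = sum(!skipped), n_skipped = sum(skipped),
            n_hyper = sum(out$direction == "hyper"),
            n_hypo = sum(out$direction == "hypo"))
}

#' Assign differentially methylated genes
#'
#' A gene is a DMG when at least one DMR overlaps (by >= 1 bp) its gene
#' body or its strand-aware promoter; the record notes which (possibly
#' both).
#'
#' @param dmrs A `dmr_set` (or compatible data frame with `chrom`, `start`,
#'   `end`).
#' @param catalog A `feature_catalog` (supplies per-gene promoters and gene
#'   spans).
#' @return A `data.table` with `gene_id`, logical `in_gene_body` /
#'   `in_promoter`, `overlap_class` (comma-joined), and `dmr_ids`
#'   (comma-joined `chrom:start-end` of supporting DMRs).
#' @export
assign_dmgs <- function(dmrs, catalog) {
  stopifnot(is(catalog, "feature_catalog"))
  genes <- catalog$genes
  dmr_gr <- GenomicRanges::GRanges(dmrs$chrom,
                                   IRanges::IRanges(dmrs$start, dmrs$end))
  dmr_id <- paste0(dmrs$chrom, ":", dmrs$start, "-", dmrs$end)

  body_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  hits_b <- GenomicRanges::findOverlaps(body_gr, dmr_gr, ignore.strand = TRUE)
  prom_gr <- catalog$promoters_by_gene
  hits_p <- GenomicRanges::findOverlaps(prom_gr, dmr_gr, ignore.strand = TRUE)

  recs <- rbind(
    data.table(gene_id = genes$gene_id[S4Vectors::queryHits(hits_b)],
               class = "gene_body",
               dmr = dmr_id[S4Vectors::subjectHits(hits_b)]),
    data.table(gene_id = prom_gr$gene_id[S4Vectors::queryHits(hits_p)],
               class = "promoter",
               dmr = dmr_id[S4Vectors::subjectHits(hits_p)]))
  if (nrow(recs) == 0L) {
    return(data.table(gene_id = character(), in_gene_body = logical(),
                      in_promoter = logical(), overlap_class = character(),
                      dmr_ids = character()))
  }
  out <- recs[, .(
    in_gene_body = any(class == "gene_body"),
    in_promoter = any(class == "promoter"),
    overlap_class = paste(sort(unique(class)), collapse = ","),
    dmr_ids = paste(sort(unique(dmr)), collapse = ",")), by = gene_id]
  setorder(out, gene_id)
  out[]
}

#' Export DMRs as TSV and BED
#'
#' Writes `<prefix>_<context>_DMR.tsv` with all record fields and
#' `<prefix>_<context>_DMR.bed`, a BED6 track loadable in genome browsers:
#' name `context:direction`, score `round(1000 * |delta|)` clipped to
#' `[0, 1000]`, strand `.`, coordinates shifted to 0-based half-open.
#'
#' @param dmrs A `dmr_set`.
#' @param out_prefix Path prefix for the two files.
#' @return Character vector `c(tsv=, bed=)`, invisibly.
#' @export
export_dmrs <- function(dmrs, out_prefix) {
  ctx <- attr(dmrs, "context") %||% unique(dmrs$context) %||% "NA"
  if (length(ctx) != 1L) ctx <- ctx[1L]
  tsv <- paste0(out_prefix, "_", ctx, "_DMR.tsv")
  bed <- paste0(out_prefix, "_", ctx, "_DMR.bed")
  fwrite(as.data.table(dmrs), tsv, sep = "\t")
  if (nrow(dmrs) == 0L) {
    writeLines(character(), bed)
  } else {
    bed_dt <- data.table(
      chrom = dmrs$chrom,
      start = dmrs$start - 1L,
      end = dmrs$end,
      name = paste0(dmrs$context, ":", dmrs$direction),
      score = pmin(1000L, pmax(0L, as.integer(round(1000 * abs(dmrs$delta))))),
      strand = ".")
    fwrite(bed_dt, bed, sep = "\t", col.names = FALSE)
  }
  invisible(c(tsv = tsv, bed = bed))
}

#' @export
print.dmr_set <- function(x, ...) {
  cat("DMR set (", attr(x, "context"), "): ", nrow(x), " DMRs (",
      attr(x, "n_hyper"), " hyper, ", attr(x, "n_hypo"), " hypo) from ",
      attr(x, "n_tested"), " tested windows (", attr(x, "n_skipped"),
      " skipped)\n", sep = "")
  if (nrow(x)) print(as.data.table(x), ...)
  invisible(x)
}
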