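## Fixed non-overlapping window tiling and window x sample methylation
## matrices.
##
## A window is eligible when, in EVERY sample, it contains at least
## min_cytosines cytosines of the requested context each covered by at least
## min_depth reads. Eligibility in all samples makes the retained window set
## identical across samples, which downstream PCA / clustering / DMR calling
## relies on. Cytosines on both strands count as separate sites; symmetric
## CpG strand pairs are not merged.

#' Window eligibility parameters
#'
#' @param window_bp Window width in bp (default 500).
#' @param min_cytosines Minimum context cytosines per window per sample
#'   (default 4).
#' @param min_depth Minimum reads covering each contributing cytosine
#'   (default 4).
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(window_bp = 500L, min_cytosines = 4L, min_depth = 4L) {
  window_bp <- as.integer(window_bp)
  min_cytosines <- as.integer(min_cytosines)
  min_depth <- as.integer(min_depth)
  if (any(c(window_bp, min_cytosines, min_depth) < 1L)) {
    stop("window_bp, min_cytosines and min_depth must be positive integers",
         call. = FALSE)
  }
  structure(list(window_bp = window_bp, min_cytosines = min_cytosines,
                 min_depth = min_depth), class = "window_spec")
}

#' Tile chromosomes into fixed non-overlapping windows
#'
#' Windows are anchored at position 1 per chromosome: `[1, w]`,
#' `[w+1, 2w]`, ...; the final partial window is retained, so the windows
#' partition each chromosome exactly.
#'
#' @param chrom_sizes Named vector of chromosome lengths (or a two-column
#'   data frame).
#' @param window_bp Window width in bp.
#' @return A `data.table` with `chrom`, `start`, `end` (1-based inclusive),
#'   ordered by chromosome then start.
#' @export
tile_genome <- function(chrom_sizes, window_bp = 500L) {
  chrom_sizes <- .as_chrom_sizes(chrom_sizes)
  window_bp <- as.integer(window_bp)
  if (window_bp < 1L) stop("window_bp must be positive", call. = FALSE)
  out <- rbindlist(lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq.int(1L, len, by = window_bp)
    data.table(chrom = ch, start = starts,
               end = pmin(starts + window_bp - 1L, len))
  }))
  out[]
}

## per (window, sample) site table for one context: window key columns,
## sample name, per-site level; only sites passing the depth filter
.window_sites <- function(sheet, spec, context_sel, chrom_sizes = NULL) {
  ctx <- context_sel
  pieces <- vector("list", nrow(sheet))
  max_pos <- list()
  for (i in seq_len(nrow(sheet))) {
    calls <- read_cgmap(sheet$path[i], min_depth = spec$min_depth)
    for (ch in unique(calls$chrom)) {
      m <- max(calls$position[calls$chrom == ch])
      max_pos[[ch]] <- max(max_pos[[ch]] %||% 0L, m)
    }
    sel <- calls[context == ctx & !low_depth,
                 .(chrom, position, level)]
    sel[, sample_name := sheet$sample_name[i]]
    pieces[[i]] <- sel
  }
  if (is.null(chrom_sizes)) {
    chrom_sizes <- unlist(max_pos)
    if (is.null(chrom_sizes) || length(chrom_sizes) == 0L) {
      stop("no methylation calls found in any sample", call. = FALSE)
    }
  } else {
    chrom_sizes <- .as_chrom_sizes(chrom_sizes)
  }
  sites <- rbindlist(pieces)
  w <- spec$window_bp
  sites[, win_start := ((position - 1L) %/% w) * w + 1L]
  list(sites = sites, chrom_sizes = chrom_sizes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a per-context window-by-sample methylation matrix
#'
#' For each tiled window and sample, collects the sample's calls of the
#' requested context with depth at least `min_depth`; the window passes for
#' that sample when it holds at least `min_cytosines` such calls, and is
#' retained only when it passes in every sample. Each retained cell is the
#' unweighted mean of the contributing per-cytosine levels.
#'
#' @param sheet A `sample_sheet`.
#' @param spec A [window_spec()].
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @param chrom_sizes Optional named chromosome lengths; when absent, each
#'   chromosome's length is approximated by the maximum position observed
#'   across samples (a message notes the approximation).
#' @return An object of class `window_matrix`: list with `context`, `spec`,
#'   `windows` (`data.table` of retained `chrom`, `start`, `end`), `levels`
#'   (windows x samples matrix of mean levels), `n_sites` (matching matrix
#'   of contributing-cytosine counts), `sites` (long `data.table` of the
#'   per-site levels backing each retained cell, used for pooled DMR
#'   testing), `samples` and `chrom_sizes`.
#' @export
build_matrix <- function(sheet, spec = window_spec(), context = "CG",
                         chrom_sizes = NULL) {
  stopifnot(is(sheet, "sample_sheet"), is(spec, "window_spec"))
  if (!context %in% .CONTEXTS) {
    stop("context must be one of ", paste(.CONTEXTS, collapse = ", "),
         call. = FALSE)
  }
  approx_sizes <- is.null(chrom_sizes)
  ws <- .window_sites(sheet, spec, context, chrom_sizes)
  if (approx_sizes) {
    message("chromosome lengths approximated by the maximum observed ",
            "call position per chromosome")
  }
  sites <- ws$sites

  cell <- sites[, .(n = .N, mean_level = mean(level)),
                by = .(chrom, win_start, sample_name)]
  nsamp <- nrow(sheet)
  elig <- cell[n >= spec$min_cytosines,
               .(n_pass = .N), by = .(chrom, win_start)][n_pass == nsamp]
  if (nrow(elig) == 0L) {
    stop("no eligible windows for context ", context,
         "; consider relaxing window_spec (wider windows, lower ",
         "min_cytosines or min_depth)", call. = FALSE)
  }
  setorder(elig, chrom, win_start)
  windows <- elig[, .(chrom, start = win_start)]
  windows[, end := pmin(start + spec$window_bp - 1L,
                        ws$chrom_sizes[chrom])]
  win_key <- paste0(windows$chrom, ":", windows$start, "-", windows$end)

  keep <- cell[elig, on = .(chrom, win_start)]
  keep[, row := match(paste(chrom, win_start), paste(windows$chrom,
                                                     windows$start))]
  levels_m <- matrix(NA_real_, nrow(windows), nsamp,
                     dimnames = list(win_key, sheet$sample_name))
  nsite_m <- matrix(0L, nrow(windows), nsamp,
                    dimnames = list(win_key, sheet$sample_name))
  idx <- cbind(keep$row, match(keep$sample_name, sheet$sample_name))
  levels_m[idx] <- keep$mean_level
  nsite_m[idx] <- keep$n

  retained_sites <- sites[elig, on = .(chrom, win_start)]
  retained_sites[, window := match(paste(chrom, win_start),
                                   paste(windows$chrom, windows$start))]

  structure(list(context = context, spec = spec, windows = windows,
                 levels = levels_m, n_sites = nsite_m,
                 sites = retained_sites[, .(window, chrom, win_start,
                                            position, sample_name, level)],
                 samples = sheet$sample_name,
                 groups = setNames(sheet$group, sheet$sample_name),
                 control = attr(sheet, "control"),
                 chrom_sizes = ws$chrom_sizes),
            class = "window_matrix")
}

#' @export
print.window_matrix <- function(x, ...) {
  cat("Window matrix (", x$context, "): ", nrow(x$windows),
      " eligible windows x ", length(x$samples), " samples; window ",
      x$spec$window_bp, " bp, >= ", x$spec$min_cytosines,
      " cytosines at depth >= ", x$spec$min_depth, "\n", sep = "")
  invisible(x)
}

#' Write a window matrix as TSV
#'
#' Columns: `chrom`, `start`, `end`, then one mean-level column per sample.
#'
#' @param wm A `window_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(wm, path) {
  stopifnot(is(wm, "window_matrix"))
  dt <- cbind(wm$windows, as.data.table(wm$levels))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Per-group and per-sample mean methylation of a window matrix
#'
#' The group mean is the mean of all retained cell values over that group's
#' sample columns — one scalar per group for the matrix's context.
#'
#' @param wm A `window_matrix`.
#' @param sheet The `sample_sheet` the matrix was built from (defaults to
#'   the grouping stored in the matrix).
#' @return List with `group_means` (named, control group first),
#'   `sample_means`, `delta` (experimental minus control) and `context`.
#' @export
group_means <- function(wm, sheet = NULL) {
  stopifnot(is(wm, "window_matrix"))
  groups <- if (is.null(sheet)) wm$groups else setNames(sheet$group,
                                                        sheet$sample_name)
  control <- if (is.null(sheet)) wm$control else attr(sheet, "control")
  if (!all(colnames(wm$levels) %in% names(groups))) {
    stop("matrix columns do not match the sample sheet", call. = FALSE)
  }
  glabels <- unique(c(control, unname(groups)))
  sample_means <- colMeans(wm$levels)
  gm <- vapply(glabels, function(g) {
    mean(wm$levels[, names(groups)[groups == g], drop = FALSE])
  }, numeric(1))
  list(group_means = gm,
       sample_means = sample_means,
       delta = unname(gm[2L] - gm[1L]),
       context = wm$context)
}
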