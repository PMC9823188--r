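## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths (base-R loops, closed-form statistics,
## exhaustive enumeration) so agreement is evidence, not tautology.

## ---- two-sample test oracles -------------------------------------------

## Welch (or pooled-variance Student) t-test p-value from the textbook
## formulas
oracle_t_p <- function(x, y, var_equal = FALSE) {
  n1 <- length(x); n2 <- length(y)
  m1 <- sum(x) / n1; m2 <- sum(y) / n2
  v1 <- sum((x - m1)^2) / (n1 - 1); v2 <- sum((y - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  2 * stats::pt(-abs(tstat), df)
}

ks_D <- function(x, y) {
  all_v <- sort(unique(c(x, y)))
  Fx <- vapply(all_v, function(v) mean(x <= v), numeric(1))
  Fy <- vapply(all_v, function(v) mean(y <= v), numeric(1))
  max(abs(Fx - Fy))
}

## exact two-sample KS p-value by exhaustive enumeration of all
## choose(n1+n2, n1) group assignments of the pooled values (no ties)
oracle_ks_exact_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  d_obs <- ks_D(x, y)
  combs <- utils::combn(length(pool), n1)
  hits <- 0L
  for (j in seq_len(ncol(combs))) {
    xi <- pool[combs[, j]]
    yi <- pool[-combs[, j]]
    if (ks_D(xi, yi) >= d_obs - 1e-12) hits <- hits + 1L
  }
  hits / ncol(combs)
}

## exact Mann-Whitney two-sided p-value by exhaustive rank enumeration,
## replicating the convention p = min(1, 2 * min(P(W <= w), P(W >= w)))
oracle_mwu_exact_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x); n2 <- length(y)
  r <- rank(pool)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  w_all <- apply(combs, 2L, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  lo <- mean(w_all <= w_obs + 1e-12)
  hi <- mean(w_all >= w_obs - 1e-12)
  mid <- n1 * n2 / 2
  if (abs(w_obs - mid) < 1e-12) return(1)
  min(1, 2 * min(lo, hi))
}

## ---- windowing oracle ---------------------------------------------------

## brute-force reimplementation of the eligibility filter and cell means:
## base-R loops over windows, sites re-read with read.delim, levels
## recomputed from counts
brute_window_matrix <- function(paths, sample_names, chrom_sizes,
                                window_bp, min_cytosines, min_depth, ctx) {
  calls <- lapply(paths, function(p) {
    df <- utils::read.delim(p, header = FALSE,
                            col.names = c("chrom", "sb", "pos", "context",
                                          "dinuc", "level", "meth", "total"))
    df[df$context == ctx & df$total >= min_depth, ]
  })
  win_rows <- list()
  lev_rows <- list()
  n_rows <- list()
  for (ch in names(chrom_sizes)) {
    len <- chrom_sizes[[ch]]
    starts <- seq.int(1L, as.integer(len), by = as.integer(window_bp))
    for (s in starts) {
      e <- min(s + as.integer(window_bp) - 1L, as.integer(len))
      ns <- numeric(length(paths))
      mns <- numeric(length(paths))
      for (k in seq_along(paths)) {
        sub <- calls[[k]]
        sub <- sub[sub$chrom == ch & sub$pos >= s & sub$pos <= e, ]
        ns[k] <- nrow(sub)
        mns[k] <- if (nrow(sub)) mean(sub$meth / sub$total) else NA_real_
      }
      if (all(ns >= min_cytosines)) {
        key <- paste0(ch, ":", s, "-", e)
        win_rows[[key]] <- data.frame(chrom = ch, start = s, end = e)
        lev_rows[[key]] <- mns
        n_rows[[key]] <- ns
      }
    }
  }
  if (length(win_rows) == 0L) {
    return(list(windows = data.frame(), levels = NULL))
  }
  levels_m <- do.call(rbind, lev_rows)
  colnames(levels_m) <- sample_names
  nm <- do.call(rbind, n_rows)
  colnames(nm) <- sample_names
  list(windows = do.call(rbind, win_rows), levels = levels_m, n_sites = nm)
}

## ---- interval oracles ---------------------------------------------------

## per-base membership vector over one chromosome for a set of intervals
## given as a data.frame(start, end)
membership <- function(ivs, len) {
  v <- logical(len)
  if (!is.null(ivs) && nrow(ivs)) {
    for (i in seq_len(nrow(ivs))) {
      v[ivs$start[i]:ivs$end[i]] <- TRUE
    }
  }
  v
}

## membership vector from a GRanges restricted to one chromosome
gr_membership <- function(gr, ch, len) {
  sel <- gr[as.character(GenomeInfoDb::seqnames(gr)) == ch]
  v <- logical(len)
  if (length(sel)) {
    for (i in seq_along(sel)) {
      v[GenomicRanges::start(sel)[i]:GenomicRanges::end(sel)[i]] <- TRUE
    }
  }
  v
}

## brute-force overlap length via per-base membership
brute_overlap_bp <- function(gr_a, gr_b, chrom_sizes) {
  total <- 0
  for (ch in names(chrom_sizes)) {
    total <- total + sum(gr_membership(gr_a, ch, chrom_sizes[[ch]]) &
                           gr_membership(gr_b, ch, chrom_sizes[[ch]]))
  }
  total
}
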