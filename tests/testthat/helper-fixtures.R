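## Fixture builders shared across test files. Everything is generated in
## code at test time; nothing is read from stored data.

## write a CGmap file from a plain data.frame of the 8 fields
write_cgmap_lines <- function(df, path = tempfile(fileext = ".cgmap")) {
  lines <- apply(df, 1L, paste, collapse = "\t")
  writeLines(lines, path)
  path
}

## a random valid call table (levels always meth/total)
random_calls <- function(n, chroms = c("Chr1", "Chr2"), max_pos = 100000L) {
  pos <- sort(sample.int(max_pos, n))
  ctx <- sample(c("CG", "CHG", "CHH"), n, replace = TRUE)
  total <- sample(1:30, n, replace = TRUE)
  meth <- vapply(total, function(t) sample(0:t, 1L), integer(1))
  data.table::data.table(
    chrom = sample(chroms, n, replace = TRUE),
    strand_base = sample(c("C", "G"), n, replace = TRUE),
    position = pos,
    context = ctx,
    dinucleotide = ifelse(ctx == "CG", "CG",
                          sample(c("CA", "CC", "CT"), n, replace = TRUE)),
    level = meth / total,
    meth_reads = meth,
    total_reads = total)[order(chrom, position)]
}

## build a window_matrix object directly in memory: window-level simulation
## used for test calibration (type-I error, power) where file I/O adds
## nothing. `level_fun(n)` draws n per-site observed levels for one
## (window, sample) cell; `shift` is added to the experimental group's
## levels before clipping to [0, 1].
make_wm <- function(n_windows, sites_per_cell, level_fun,
                    n_control = 3L, n_experimental = 3L, shift = 0,
                    shifted_windows = integer(), window_bp = 500L) {
  samples <- c(paste0("ctl_", seq_len(n_control)),
               paste0("trt_", seq_len(n_experimental)))
  nsamp <- length(samples)
  groups <- stats::setNames(rep(c("control", "treated"),
                                c(n_control, n_experimental)), samples)
  windows <- data.table::data.table(
    chrom = "Chr1",
    start = (seq_len(n_windows) - 1L) * window_bp + 1L)
  windows[, end := start + window_bp - 1L]

  sites <- data.table::data.table(
    window = rep(seq_len(n_windows), each = nsamp * sites_per_cell),
    sample_i = rep(rep(seq_len(nsamp), each = sites_per_cell), n_windows))
  sites[, level := level_fun(nrow(sites))]
  if (shift != 0 && length(shifted_windows)) {
    sites[window %in% shifted_windows & sample_i > n_control,
          level := pmin(1, pmax(0, level + shift))]
  }
  sites[, chrom := "Chr1"]
  sites[, win_start := windows$start[window]]
  sites[, position := win_start + data.table::rowid(window, sample_i) - 1L]
  sites[, sample_name := samples[sample_i]]

  cells <- sites[, .(m = mean(level)), by = .(window, sample_i)]
  lev <- matrix(NA_real_, n_windows, nsamp,
                dimnames = list(paste0("Chr1:", windows$start, "-",
                                       windows$end), samples))
  lev[cbind(cells$window, cells$sample_i)] <- cells$m
  ns <- matrix(sites_per_cell, n_windows, nsamp, dimnames = dimnames(lev))

  structure(list(context = "CG",
                 spec = methylDMR::window_spec(window_bp, 1L, 1L),
                 windows = windows, levels = lev, n_sites = ns,
                 sites = sites[, .(window, chrom, win_start, position,
                                   sample_name, level)],
                 samples = samples, groups = groups, control = "control",
                 chrom_sizes = c(Chr1 = n_windows * window_bp)),
            class = "window_matrix")
}

## a small simulated study kept on disk for the whole test run
sim_cache <- new.env()
default_sim <- function() {
  if (is.null(sim_cache$sim)) {
    dir <- file.path(tempdir(), "methylDMR_default_sim")
    sim_cache$sim <- suppressMessages(simulate_dataset(
      sim_config(seed = 424242, chrom_len = 30000L, n_genes = 4L,
                 n_dmr = 12L, baseline = c(CG = 0.6, CHG = 0.1, CHH = 0.05)),
      dir))
  }
  sim_cache$sim
}
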