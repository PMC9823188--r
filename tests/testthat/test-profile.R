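test_that("PCA places identical samples at the same point", {
  withr::local_seed(41)
  wm <- make_wm(30L, 4L, function(n) runif(n), n_control = 2L,
                n_experimental = 1L)
  wm$levels[, 2L] <- wm$levels[, 1L]  # duplicate sample
  pca <- run_pca(wm)
  expect_equal(pca$coords[1L, .(PC1, PC2)], pca$coords[2L, .(PC1, PC2)],
               tolerance = 1e-10)
  ## variance fractions sum to <= 1 and are non-increasing
  expect_lte(sum(pca$var_explained), 1 + 1e-12)
  expect_true(all(diff(pca$var_explained) <= 1e-12))
})

test_that("a two-cluster design loads almost entirely on PC1", {
  withr::local_seed(42)
  n_win <- 100L
  wm <- make_wm(n_win, 4L, function(n) pmin(1, pmax(0, rnorm(n, 0.3, 0.02))),
                shift = 0.5, shifted_windows = seq_len(90L))
  pca <- run_pca(wm)
  expect_gt(pca$var_explained[1L], 0.9)
  ## groups linearly separable on PC1
  pc1 <- split(pca$coords$PC1, pca$coords$group)
  expect_true(max(pc1$control) < min(pc1$treated) ||
                max(pc1$treated) < min(pc1$control))
})

test_that("PCA refuses designs it cannot support", {
  wm <- make_wm(10L, 4L, function(n) runif(n), n_control = 1L,
                n_experimental = 1L)
  expect_warning(expect_null(run_pca(wm)), "fewer than 3")
})

test_that("variable-region selection applies the spread threshold", {
  wm <- make_wm(2L, 1L, function(n) 0)
  wm$levels[1L, ] <- c(0.10, 0.35, 0.2, 0.2, 0.2, 0.2)  # spread 0.25
  wm$levels[2L, ] <- c(0.10, 0.25, 0.2, 0.2, 0.2, 0.2)  # spread 0.15
  vr <- select_variable_regions(wm, 0.20)
  expect_equal(nrow(vr$windows), 1L)
  expect_equal(vr$windows$start, wm$windows$start[1L])

  expect_warning(expect_null(select_variable_regions(wm, 0.9)),
                 "no variable regions")

  ## brute-force count agreement on a random matrix
  withr::local_seed(43)
  wm2 <- make_wm(50L, 3L, function(n) runif(n))
  thr <- 0.5
  vr2 <- select_variable_regions(wm2, thr)
  manual <- sum(apply(wm2$levels, 1L, function(r) max(r) - min(r) >= thr))
  expect_equal(nrow(vr2$windows), manual)
})

test_that("column clustering recovers the group partition", {
  withr::local_seed(44)
  wm <- make_wm(40L, 4L, function(n) pmin(1, pmax(0, rnorm(n, 0.3, 0.03))),
                shift = 0.4, shifted_windows = 1:40)
  hm <- cluster_heatmap(wm)
  ## the top split of the column dendrogram separates the groups
  top <- stats::cutree(hm$col_hclust, k = 2L)
  expect_equal(length(unique(top[wm$groups[names(top)] == "control"])), 1L)
  expect_equal(length(unique(top[wm$groups[names(top)] == "treated"])), 1L)
  expect_false(top[["ctl_1"]] == top[["trt_1"]])

  ## identical samples are nearest neighbours
  wm$levels[, 2L] <- wm$levels[, 1L]
  hm2 <- cluster_heatmap(wm)
  o <- match(c("ctl_1", "ctl_2"), hm2$col_order)
  expect_equal(abs(diff(o)), 1L)

  ## permutation invariance: same merge heights after column shuffle
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  wmp <- wm
  wmp$levels <- wm$levels[, perm]
  wmp$samples <- wm$samples[perm]
  hm3 <- cluster_heatmap(wmp)
  expect_equal(sort(hm3$col_hclust$height), sort(hm2$col_hclust$height))

  ## constant rows do not break the distance computation
  wmc <- make_wm(3L, 2L, function(n) rep(0.5, n))
  expect_silent(cluster_heatmap(wmc))
})

test_that("genome tracks are flat for uniform methylation and mirror a
          genome-wide loss", {
  dir <- withr::local_tempdir()
  sim_flat <- suppressMessages(simulate_dataset(
    sim_config(seed = 451, chrom_len = 10000L, n_genes = 0L, n_dmr = 0L,
               depth_mean = 60, depth_dispersion = 20,
               baseline = c(CG = 0.3, CHG = 0.3, CHH = 0.3),
               n_control = 2L, n_experimental = 2L),
    file.path(dir, "flat")))
  tr <- genome_track(sim_flat$sheet, "CG", window_bp = 2000L,
                     chrom_sizes = sim_flat$chrom_sizes)
  expect_equal(nrow(tr$windows), 10L)
  expect_true(all(abs(tr$levels - 0.3) < 0.05, na.rm = TRUE))
  expect_true(all(abs(tr$delta) < 0.05, na.rm = TRUE))

  ## experimental group scaled to zero: delta tracks -control everywhere
  sim_loss <- suppressMessages(simulate_dataset(
    sim_config(seed = 452, chrom_len = 10000L, n_genes = 0L, n_dmr = 0L,
               depth_mean = 60, depth_dispersion = 20,
               baseline = c(CG = 0.3, CHG = 0.1, CHH = 0.05),
               group_effect = c(CG = -0.3),
               n_control = 2L, n_experimental = 2L),
    file.path(dir, "loss")))
  tr2 <- genome_track(sim_loss$sheet, "CG", window_bp = 2000L,
                      chrom_sizes = sim_loss$chrom_sizes)
  ctrl_mean <- rowMeans(tr2$levels[, 1:2])
  expect_true(all(abs(tr2$delta + ctrl_mean) < 0.05, na.rm = TRUE))
  ## independent recomputation of the group delta
  expect_equal(tr2$delta,
               unname(rowMeans(tr2$levels[, 3:4]) - ctrl_mean))

  ## windows short on cytosines are masked
  expect_true(anyNA(genome_track(sim_flat$sheet, "CG", window_bp = 50L,
                                 chrom_sizes = sim_flat$chrom_sizes)$levels))

  ## large-window arithmetic: a 2.5-Mb chromosome in 1-Mb windows
  expect_equal(nrow(tile_genome(c(Chr1 = 2500000L), 1000000L)), 3L)
})

test_that("metagene profiles are flat on uniform data and show the
          implanted body/flank step", {
  dir <- withr::local_tempdir()
  sim_u <- suppressMessages(simulate_dataset(
    sim_config(seed = 461, chrom_len = 40000L, n_genes = 4L, n_dmr = 0L,
               depth_mean = 60, depth_dispersion = 20,
               baseline = c(CG = 0.4, CHG = 0.4, CHH = 0.4),
               n_control = 2L, n_experimental = 2L),
    file.path(dir, "uniform")))
  models <- parse_gtf(sim_u$gtf_path)
  mg <- suppressMessages(metagene(sim_u$sheet, models, "CG"))
  expect_equal(nrow(mg$bins), 60L)
  expect_true(all(abs(mg$bins$control - 0.4) < 0.05, na.rm = TRUE))
  expect_true(all(abs(mg$bins$delta) < 0.05, na.rm = TRUE))

  ## body 0.6 vs flank 0.1: step up at TSS, down at TES
  sim_s <- suppressMessages(simulate_dataset(
    sim_config(seed = 462, chrom_len = 40000L, n_genes = 4L, n_dmr = 0L,
               depth_mean = 60, depth_dispersion = 20,
               spatial_profile = list(body = 0.6, flank = 0.1),
               n_control = 2L, n_experimental = 2L),
    file.path(dir, "step")))
  models_s <- parse_gtf(sim_s$gtf_path)
  mg_s <- suppressMessages(metagene(sim_s$sheet, models_s, "CG"))
  body <- mg_s$bins[region == "body", control]
  flank <- mg_s$bins[region != "body", control]
  expect_true(all(body > 0.5, na.rm = TRUE))
  ## flank bins right next to the gene may catch body bp; the outer flank
  ## is clearly low
  expect_lt(mean(flank[c(1:15, 26:40)], na.rm = TRUE), 0.2)
})

test_that("minus-strand metagene equals the mirrored plus-strand profile", {
  withr::local_seed(47)
  dir <- withr::local_tempdir()
  len <- 20000L
  ## one gene on the minus strand with spatially asymmetric methylation
  calls <- random_calls(2500L, chroms = "Chr1", max_pos = len)
  calls <- calls[!duplicated(position)]
  calls[, level := pmin(1, pmax(0, 0.1 + 0.8 * (position / len)))]
  calls[, total_reads := 50L]
  calls[, meth_reads := as.integer(round(level * 50))]
  calls[, level := meth_reads / total_reads]

  mirror <- data.table::copy(calls)
  mirror[, position := len + 1L - position]
  data.table::setorder(mirror, position)

  write_pair <- function(dt, d) {
    p1 <- file.path(d, "s1.cgmap"); p2 <- file.path(d, "s2.cgmap")
    write_cgmap(dt, p1); write_cgmap(dt, p2)
    sheet_f <- file.path(d, "sheet.tsv")
    writeLines(c("s1 s1.cgmap A", "s2 s2.cgmap B"), sheet_f)
    read_sample_sheet(sheet_f)
  }
  d1 <- file.path(dir, "minus"); dir.create(d1)
  d2 <- file.path(dir, "plus"); dir.create(d2)
  sheet_m <- write_pair(calls, d1)
  sheet_p <- write_pair(mirror, d2)

  gene_m <- structure(list(
    genes = data.table::data.table(gene_id = "g1", chrom = "Chr1",
                                   strand = "-", start = 8001L,
                                   end = 12000L),
    exons = GenomicRanges::GRanges(), cds = GenomicRanges::GRanges(),
    utr5 = GenomicRanges::GRanges(), utr3 = GenomicRanges::GRanges()),
    class = "gene_models")
  gene_p <- gene_m
  gene_p$genes <- data.table::data.table(gene_id = "g1", chrom = "Chr1",
                                         strand = "+",
                                         start = len + 1L - 12000L,
                                         end = len + 1L - 8001L)
  mg_m <- metagene(sheet_m, gene_m, "CG", min_depth = 1L)
  mg_p <- metagene(sheet_p, gene_p, "CG", min_depth = 1L)
  expect_equal(mg_m$bins$A, mg_p$bins$A, tolerance = 1e-12)
  expect_equal(mg_m$bins$delta, mg_p$bins$delta, tolerance = 1e-12)
})

test_that("short genes are skipped with a count", {
  dir <- withr::local_tempdir()
  writeLines("Chr1\tC\t100\tCG\tCG\t1.00\t5\t5", file.path(dir, "s1"))
  writeLines("Chr1\tC\t100\tCG\tCG\t1.00\t5\t5", file.path(dir, "s2"))
  sheet_f <- file.path(dir, "sheet.tsv")
  writeLines(c("s1 s1 A", "s2 s2 B"), sheet_f)
  sheet <- read_sample_sheet(sheet_f)
  gm <- structure(list(
    genes = data.table::data.table(gene_id = c("tiny", "ok"),
                                   chrom = "Chr1", strand = "+",
                                   start = c(50L, 200L),
                                   end = c(55L, 900L)),
    exons = GenomicRanges::GRanges(), cds = GenomicRanges::GRanges(),
    utr5 = GenomicRanges::GRanges(), utr3 = GenomicRanges::GRanges()),
    class = "gene_models")
  expect_message(mg <- metagene(sheet, gm, "CG", min_depth = 1L),
                 "1 gene")
  expect_equal(mg$n_genes_used, 1L)
  expect_equal(mg$n_genes_skipped, 1L)
})
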