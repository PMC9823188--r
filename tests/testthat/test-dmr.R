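test_that("window test p-values match closed-form and exhaustive oracles", {
  x <- c(0.8, 0.9, 0.85, 0.95)
  y <- c(0.1, 0.2, 0.15, 0.05)
  expect_equal(test_window(x, y, "ttest"), oracle_t_p(x, y),
               tolerance = 1e-10)
  expect_equal(test_window(x, y, "ttest", var_equal = TRUE),
               oracle_t_p(x, y, var_equal = TRUE), tolerance = 1e-10)

  ## fully separated 4-vs-4: exact MWU two-sided p = 2 / choose(8, 4)
  expect_equal(test_window(x, y, "mannwhitney"), 2 / choose(8, 4),
               tolerance = 1e-10)
  expect_equal(test_window(x, y, "mannwhitney"), oracle_mwu_exact_p(x, y),
               tolerance = 1e-10)
  expect_equal(test_window(x, y, "ks"), oracle_ks_exact_p(x, y),
               tolerance = 1e-10)

  ## interleaved vectors, all three tests against the oracles
  a <- c(0.10, 0.40, 0.35, 0.60, 0.22)
  b <- c(0.25, 0.50, 0.70, 0.90)
  expect_equal(test_window(a, b, "ttest"), oracle_t_p(a, b),
               tolerance = 1e-10)
  expect_equal(test_window(a, b, "ks"), oracle_ks_exact_p(a, b),
               tolerance = 1e-10)
  expect_equal(test_window(a, b, "mannwhitney"), oracle_mwu_exact_p(a, b),
               tolerance = 1e-10)
})

test_that("degenerate observation sets follow the stated conventions", {
  ## identical constant lists: p = 1 by convention, never a DMR
  expect_equal(test_window(rep(0.5, 4), rep(0.5, 4), "ttest"), 1)
  expect_equal(test_window(rep(0.5, 4), rep(0.5, 4), "ks"), 1)
  expect_equal(test_window(rep(0.5, 4), rep(0.5, 4), "mannwhitney"), 1)
  ## two constant groups at different levels: perfectly separated
  expect_equal(test_window(rep(1, 4), rep(0, 4), "ttest"), 0)
  ## insufficient observations: NA, not significance
  expect_true(is.na(test_window(0.5, c(0.1, 0.2), "ttest")))
  expect_false(is.na(test_window(0.5, c(0.1, 0.2), "ks")))
})

test_that("DMR emission is the conjunction of effect size and significance", {
  withr::local_seed(31)
  wm <- make_wm(60L, 6L, function(n) pmin(1, pmax(0, rnorm(n, 0.5, 0.05))),
                shift = -0.3, shifted_windows = 1:20)
  params <- dmr_params(min_delta = 0.10, alpha = 0.05)
  dmrs <- call_dmrs(wm, params)

  ## every emitted record satisfies both thresholds
  expect_true(all(abs(dmrs$delta) >= params$min_delta))
  expect_true(all(dmrs$p_value < params$alpha))
  expect_true(all(dmrs$direction == ifelse(dmrs$delta > 0, "hyper", "hypo")))

  ## and no eligible window satisfying both was missed (brute force)
  groups <- wm$groups
  for (w in seq_len(nrow(wm$windows))) {
    obs <- wm$sites[window == w]
    p <- test_window(obs[groups[sample_name] == "control", level],
                     obs[groups[sample_name] != "control", level], "ttest")
    d <- mean(wm$levels[w, 4:6]) - mean(wm$levels[w, 1:3])
    in_set <- wm$windows$start[w] %in% dmrs$start
    expect_equal(in_set, !is.na(p) && abs(d) >= 0.10 && p < 0.05)
  }
})

test_that("an effect below min_delta is not a DMR regardless of p", {
  ## delta = -0.09 with tiny noise: p is minute but the effect filter holds
  wm <- make_wm(10L, 8L,
                function(n) 0.5 + seq_len(n) * 1e-4,
                shift = -0.09, shifted_windows = 1:10)
  dmrs <- call_dmrs(wm, dmr_params(min_delta = 0.10, alpha = 0.05))
  expect_equal(nrow(dmrs), 0L)
  dmrs2 <- call_dmrs(wm, dmr_params(min_delta = 0.05, alpha = 0.05))
  expect_equal(nrow(dmrs2), 10L)
})

test_that("swapping group labels mirrors direction with identical p-values", {
  withr::local_seed(32)
  wm <- make_wm(30L, 5L, function(n) pmin(1, pmax(0, rnorm(n, 0.4, 0.08))),
                shift = 0.25, shifted_windows = 1:10)
  swapped <- wm
  swapped$groups <- setNames(
    ifelse(wm$groups == "control", "treated", "control"), names(wm$groups))
  d1 <- call_dmrs(wm, dmr_params())
  d2 <- call_dmrs(swapped, dmr_params())
  expect_equal(nrow(d1), nrow(d2))
  expect_equal(d1$p_value, d2$p_value)
  expect_equal(d1$delta, -d2$delta)
  expect_equal(d1$direction, ifelse(d2$direction == "hyper", "hypo",
                                    "hyper"))
})

test_that("detection rate rises with implanted effect size", {
  withr::local_seed(33)
  rate <- vapply(c(0.1, 0.2, 0.4), function(d) {
    wm <- make_wm(40L, 5L,
                  function(n) pmin(1, pmax(0, rnorm(n, 0.5, 0.1))),
                  shift = -d, shifted_windows = 1:40)
    nrow(call_dmrs(wm, dmr_params())) / 40
  }, numeric(1))
  expect_true(all(diff(rate) >= 0))
  expect_gt(rate[3L], 0.9)
})

test_that("replicate-means mode tests per-replicate window means", {
  withr::local_seed(34)
  wm <- make_wm(20L, 5L, function(n) pmin(1, pmax(0, rnorm(n, 0.5, 0.05))),
                shift = -0.4, shifted_windows = 1:10)
  d <- call_dmrs(wm, dmr_params(), mode = "replicate_means")
  expect_gt(nrow(d), 0L)
  expect_true(all(d$direction == "hypo"))
  ## spot-check one window's p against a direct test on the matrix row
  w <- match(d$start[1L], wm$windows$start)
  expect_equal(d$p_value[1L],
               test_window(wm$levels[w, 1:3], wm$levels[w, 4:6], "ttest"))
})

test_that("DMG assignment equals a brute-force overlap scan", {
  sim <- default_sim()
  models <- parse_gtf(sim$gtf_path)
  cat <- build_catalog(models, sim$chrom_sizes)
  withr::local_seed(35)
  ## random DMR-like windows across the genome
  dmr_dt <- data.table::rbindlist(lapply(names(sim$chrom_sizes), function(ch) {
    s <- sort(sample(seq(1L, sim$chrom_sizes[[ch]] - 499L, by = 500L), 12L))
    data.table::data.table(chrom = ch, start = s, end = s + 499L)
  }))
  dmgs <- assign_dmgs(dmr_dt, cat)

  ## brute force: all gene x DMR pairs, 1-bp overlap rule on body/promoter
  genes <- cat$genes
  expected <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    prom <- if (g$strand == "+") c(max(1L, g$start - 2000L), g$start - 1L)
            else c(g$end + 1L, min(sim$chrom_sizes[[g$chrom]],
                                   g$end + 2000L))
    in_body <- any(dmr_dt$chrom == g$chrom & dmr_dt$start <= g$end &
                     dmr_dt$end >= g$start)
    in_prom <- prom[1L] <= prom[2L] &&
      any(dmr_dt$chrom == g$chrom & dmr_dt$start <= prom[2L] &
            dmr_dt$end >= prom[1L])
    if (in_body || in_prom) {
      expected[[g$gene_id]] <- c(body = in_body, prom = in_prom)
    }
  }
  expect_setequal(dmgs$gene_id, names(expected))
  for (gid in dmgs$gene_id) {
    expect_equal(dmgs[gene_id == gid, in_gene_body],
                 unname(expected[[gid]]["body"]), info = gid)
    expect_equal(dmgs[gene_id == gid, in_promoter],
                 unname(expected[[gid]]["prom"]), info = gid)
  }
  expect_true(all(nzchar(dmgs$overlap_class)))

  ## a DMR far from any gene assigns nothing
  none <- assign_dmgs(data.table::data.table(chrom = "Chr1",
                                             start = 1L, end = 10L), cat)
  gene1 <- genes[chrom == "Chr1"][1L]
  skip_if(gene1$start - 2000L <= 10L)
  expect_equal(nrow(none), 0L)
})

test_that("DMR export writes consistent TSV and BED6", {
  withr::local_seed(36)
  wm <- make_wm(20L, 5L, function(n) pmin(1, pmax(0, rnorm(n, 0.6, 0.05))),
                shift = -0.4, shifted_windows = 1:8)
  dmrs <- call_dmrs(wm, dmr_params())
  expect_gt(nrow(dmrs), 0L)
  dir <- withr::local_tempdir()
  paths <- export_dmrs(dmrs, file.path(dir, "out"))
  tsv <- data.table::fread(paths[["tsv"]])
  expect_equal(tsv$start, dmrs$start)
  bed <- data.table::fread(paths[["bed"]], header = FALSE)
  ## BED is 0-based half-open: re-shifted coordinates match the TSV
  expect_equal(bed$V2 + 1L, tsv$start)
  expect_equal(bed$V3, tsv$end)
  expect_equal(bed$V4, paste0(dmrs$context, ":", dmrs$direction))
  expect_equal(bed$V5, as.integer(round(1000 * abs(dmrs$delta))))
  expect_true(all(bed$V5 >= 0L & bed$V5 <= 1000L))
  expect_equal(unique(bed$V6), ".")

  ## empty set: header-only TSV, empty BED
  p0 <- export_dmrs(dmrs[0L], file.path(dir, "empty"))
  expect_equal(nrow(data.table::fread(p0[["tsv"]])), 0L)
  expect_identical(readLines(p0[["bed"]]), character())
})
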