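test_that("CGmap lines map to validated call records", {
  f <- write_cgmap_lines(data.frame(
    c("Chr1", "Chr1"), c("C", "G"), c(100L, 101L), c("CG", "CG"),
    c("CG", "CG"), c("0.75", "0.0"), c(3L, 0L), c(4L, 5L)))
  calls <- read_cgmap(f)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$chrom, c("Chr1", "Chr1"))
  expect_equal(calls$position, c(100L, 101L))
  expect_equal(calls$strand_base, c("C", "G"))
  expect_equal(calls$level, c(0.75, 0))
  expect_equal(calls$meth_reads, c(3L, 0L))
  expect_equal(calls$total_reads, c(4L, 5L))
  expect_equal(calls$low_depth, c(FALSE, FALSE))
  expect_true(read_cgmap(f, min_depth = 5L)$low_depth[1L])
})

test_that("malformed CGmap input is rejected with a line number", {
  f <- tempfile()
  writeLines(c("Chr1\tC\t100\tCG\tCG\t0.75\t3\t4",
               "Chr1\tC\t200\tCG\tCG\t0.5\t1"), f)
  expect_error(read_cgmap(f), "line 2")

  writeLines("Chr1\tC\t100\tCXG\tCG\t0.75\t3\t4", f)
  expect_error(read_cgmap(f), "context")

  writeLines("Chr1\tC\t100\tCG\tCG\t0.9\t3\t4", f)
  expect_error(read_cgmap(f), "level")

  writeLines("Chr1\tC\t100\tCG\tCG\t0\t0\t0", f)
  expect_error(read_cgmap(f), "counts")

  ## rounded levels are reconciled, not rejected
  writeLines("Chr1\tC\t100\tCG\tCG\t0.33\t1\t3", f)
  expect_equal(read_cgmap(f)$level, 1 / 3)
})

test_that("write/read round-trip is the identity on all fields", {
  withr::local_seed(11)
  x <- random_calls(1000L)
  f <- tempfile(fileext = ".cgmap")
  write_cgmap(x, f)
  y <- read_cgmap(f)
  expect_equal(as.data.frame(y[, names(x), with = FALSE]),
               as.data.frame(x), tolerance = 1e-12)

  ## gzip round-trip
  fz <- tempfile(fileext = ".cgmap.gz")
  write_cgmap(x, fz, compress = TRUE)
  expect_equal(as.data.frame(read_cgmap(fz)[, names(x), with = FALSE]),
               as.data.frame(x), tolerance = 1e-12)

  ## fully methylated records keep minimal two-decimal formatting
  f1 <- tempfile()
  write_cgmap(data.table::data.table(
    chrom = "Chr1", strand_base = "C", position = 10L, context = "CG",
    dinucleotide = "CG", level = 1, meth_reads = 7L, total_reads = 7L), f1)
  expect_match(readLines(f1), "1.00\t7\t7", fixed = TRUE)

  ## empty stream -> empty headerless file
  f0 <- tempfile()
  write_cgmap(x[0L], f0)
  expect_identical(readLines(f0), character())
  expect_equal(nrow(read_cgmap(f0)), 0L)
})

test_that("chunked reading reproduces whole-file parsing", {
  withr::local_seed(12)
  x <- random_calls(500L)
  f <- tempfile()
  write_cgmap(x, f)
  chunks <- list()
  n <- read_cgmap_chunked(f, function(dt) {
    chunks[[length(chunks) + 1L]] <<- dt
  }, chunk_size = 64L)
  expect_equal(n, 500L)
  expect_gt(length(chunks), 1L)
  expect_equal(as.data.frame(data.table::rbindlist(chunks)),
               as.data.frame(read_cgmap(f)))
})

test_that("the three dialects convert to equivalent CGmap records", {
  withr::local_seed(13)
  truth <- random_calls(500L)
  fb <- tempfile(); fm <- tempfile(); fi <- tempfile()
  write_dialect(truth, fb, "bismark_cx")
  write_dialect(truth, fm, "bsmap_methratio")
  write_dialect(truth, fi, "methimpute_tsv")
  cb <- convert_to_cgmap(fb, "bismark_cx")
  cm <- convert_to_cgmap(fm, "bsmap_methratio")
  ci <- convert_to_cgmap(fi, "methimpute_tsv")
  cols <- c("chrom", "strand_base", "position", "context", "level",
            "meth_reads", "total_reads")
  expect_equal(as.data.frame(cb), as.data.frame(cm), tolerance = 1e-12)
  ## METHimpute carries no dinucleotide; equivalence holds on the rest
  expect_equal(as.data.frame(cb[, cols, with = FALSE]),
               as.data.frame(ci[, cols, with = FALSE]), tolerance = 1e-12)
  expect_equal(as.data.frame(cb[, names(truth), with = FALSE]),
               as.data.frame(truth), tolerance = 1e-12)
})

test_that("dialect conversion handles counts and zero coverage per spec", {
  f <- tempfile()
  writeLines(c("Chr1\t100\t+\t3\t1\tCG\tCGT",
               "Chr1\t200\t-\t0\t0\tCHH\tCAT"), f)
  out <- convert_to_cgmap(f, "bismark_cx")
  expect_equal(nrow(out), 1L)  # zero-coverage site dropped
  expect_equal(out$level, 0.75)
  expect_equal(out$strand_base, "C")
  expect_equal(out$dinucleotide, "CG")

  expect_error(convert_to_cgmap(f, "unknown"))
})

test_that("sample sheets enforce the two-group contract", {
  dir <- withr::local_tempdir()
  for (s in c("wt1", "wt2", "wt3", "wt4", "m1", "m2", "m3")) {
    writeLines("Chr1\tC\t100\tCG\tCG\t1.00\t4\t4", file.path(dir, s))
  }
  sheet_f <- file.path(dir, "sheet.tsv")
  writeLines(c("# comment line",
               paste(c("wt1", "wt2", "wt3", "wt4"), c("wt1", "wt2", "wt3",
                                                      "wt4"), "WT"),
               paste(c("m1", "m2", "m3"), c("m1", "m2", "m3"), "mutant")),
             sheet_f)
  sheet <- read_sample_sheet(sheet_f)
  expect_equal(nrow(sheet), 7L)
  expect_equal(attr(sheet, "groups"), c("WT", "mutant"))
  expect_equal(attr(sheet, "control"), "WT")

  ## one sample per group is a legal design
  writeLines(c("wt1 wt1 WT", "m1 m1 mutant"), sheet_f)
  expect_equal(nrow(read_sample_sheet(sheet_f)), 2L)

  ## single group rejected
  writeLines(c("wt1 wt1 WT", "wt2 wt2 WT"), sheet_f)
  expect_error(read_sample_sheet(sheet_f), "two groups")

  ## duplicate sample name rejected
  writeLines(c("wt1 wt1 WT", "wt1 m1 mutant"), sheet_f)
  expect_error(read_sample_sheet(sheet_f), "duplicate")

  ## missing call file rejected
  writeLines(c("wt1 wt1 WT", "mx nope.cgmap mutant"), sheet_f)
  expect_error(read_sample_sheet(sheet_f), "not found")
})

test_that("chromosome-name harmonization is strict by default", {
  expect_error(harmonize_chroms(c("chr1", "chr2"), c("1", "2")),
               "chr1")
  expect_equal(harmonize_chroms(c("chr1", "chr2"), c("1", "2"),
                                mode = "strip"), c("1", "2"))
  expect_equal(harmonize_chroms(c("1", "chr2"), c("chr1", "chr2"),
                                mode = "add"), c("chr1", "chr2"))
})
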