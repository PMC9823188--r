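## Deterministic synthetic methylome generator.
##
## Emulates a two-group bisulfite study at read-count resolution: cytosine
## sites are scattered per context at plant-like densities, each site gets a
## true methylation level (context baseline, optional genome-wide group
## effect, implanted DMR windows, optional gene-body vs flank spatial
## pattern), read depth is drawn from an overdispersed negative-binomial
## distribution (so the >= 4-read filter actually removes sites) and
## methylated counts are binomial in the true level. Identical seeds give
## byte-identical files. What it does not emulate: sequence-driven site
## spacing, bisulfite conversion error, strand-symmetric CpG correlation,
## batch effects.

#' Configuration for the synthetic methylome generator
#'
#' Defaults describe the package's reference simulation: a 2 x 100-kb
#' genome, 3 control vs 3 experimental samples at mean depth 10, CG/CHG/CHH
#' baselines 0.19 / 0.10 / 0.05, and 50 implanted hypomethylated CG windows
#' of effect -0.4 on the 500-bp grid.
#'
#' @param seed Mandatory RNG seed; every draw is derived from it.
#' @param n_chroms,chrom_len Chromosome count and common length (bp).
#' @param n_genes Genes laid out evenly across the genome.
#' @param site_density Named per-bp site probabilities per context.
#' @param depth_mean,depth_dispersion Negative-binomial read-depth mean and
#'   size; depths are floored at 1.
#' @param baseline Named true methylation levels per context for the
#'   control group.
#' @param group_effect Named genome-wide level shift added to the
#'   experimental group per context (e.g. `c(CG = -0.185)` for a
#'   maintenance-methyltransferase-loss scenario).
#' @param n_dmr,dmr_delta,dmr_context Number, effect size and context of
#'   implanted DMR windows on the `dmr_window_bp` grid.
#' @param dmr_window_bp Grid width for implanted windows (default 500).
#' @param spatial_profile `NULL`, or `list(body=, flank=)` true levels that
#'   override the baseline inside/outside gene bodies (for metagene tests).
#' @param n_control,n_experimental Samples per group.
#' @param group_labels Two labels, control first.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_chroms = 2L, chrom_len = 100000L, n_genes = 10L,
                       site_density = c(CG = 0.04, CHG = 0.03, CHH = 0.08),
                       depth_mean = 10, depth_dispersion = 5,
                       baseline = c(CG = 0.19, CHG = 0.10, CHH = 0.05),
                       group_effect = c(CG = 0, CHG = 0, CHH = 0),
                       n_dmr = 50L, dmr_delta = -0.4, dmr_context = "CG",
                       dmr_window_bp = 500L,
                       spatial_profile = NULL,
                       n_control = 3L, n_experimental = 3L,
                       group_labels = c("control", "treated")) {
  if (missing(seed) || is.null(seed)) {
    stop("sim_config requires an explicit seed", call. = FALSE)
  }
  ge <- c(CG = 0, CHG = 0, CHH = 0)
  ge[names(group_effect)] <- group_effect
  stopifnot(all(names(site_density) %in% .CONTEXTS),
            all(baseline >= 0 & baseline <= 1),
            sum(site_density) <= 1,
            length(group_labels) == 2L,
            n_control >= 1L, n_experimental >= 1L)
  if (!is.null(spatial_profile)) {
    stopifnot(is.list(spatial_profile),
              all(c("body", "flank") %in% names(spatial_profile)))
  }
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_len = as.integer(chrom_len),
                 n_genes = as.integer(n_genes),
                 site_density = site_density, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion, baseline = baseline,
                 group_effect = ge, n_dmr = as.integer(n_dmr),
                 dmr_delta = dmr_delta, dmr_context = dmr_context,
                 dmr_window_bp = as.integer(dmr_window_bp),
                 spatial_profile = spatial_profile,
                 n_control = as.integer(n_control),
                 n_experimental = as.integer(n_experimental),
                 group_labels = group_labels),
            class = "sim_config")
}

.sim_dinucleotide <- function(context, n) {
  switch(context,
         CG = rep("CG", n),
         sample(c("CA", "CC", "CT"), n, replace = TRUE))
}

## evenly spaced non-overlapping genes, two exons with one intron,
## CDS strictly inside the exon span
.sim_genes <- function(config) {
  if (config$n_genes == 0L) {
    return(data.table(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer()))
  }
  per_chrom <- ceiling(config$n_genes / config$n_chroms)
  rows <- list()
  gid <- 0L
  for (ci in seq_len(config$n_chroms)) {
    slot <- config$chrom_len %/% (per_chrom + 1L)
    for (gi in seq_len(per_chrom)) {
      if (gid >= config$n_genes) break
      gid <- gid + 1L
      glen <- max(1000L, min(3000L, slot %/% 2L))
      start <- (gi - 1L) * slot + slot %/% 4L + 1L
      end <- start + glen - 1L
      rows[[gid]] <- data.table(gene_id = sprintf("g%04d", gid),
                                chrom = paste0("Chr", ci),
                                strand = if (gid %% 2L == 0L) "-" else "+",
                                start = start, end = end)
    }
  }
  rbindlist(rows)
}

.write_sim_gtf <- function(genes, path) {
  lines <- character()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    len <- g$end - g$start + 1L
    ## two exons separated by a central intron; CDS trimmed inside exons
    e1 <- c(g$start, g$start + as.integer(len * 0.4) - 1L)
    e2 <- c(g$start + as.integer(len * 0.6), g$end)
    cds <- c(g$start + as.integer(len * 0.1),
             g$end - as.integer(len * 0.1))
    attr_s <- sprintf('gene_id "%s"; transcript_id "%s.1";',
                      g$gene_id, g$gene_id)
    fmt <- function(type, lo, hi) {
      sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, type, lo, hi, g$strand, attr_s)
    }
    lines <- c(lines,
               fmt("gene", g$start, g$end),
               fmt("transcript", g$start, g$end),
               fmt("exon", e1[1L], e1[2L]),
               fmt("exon", e2[1L], e2[2L]),
               fmt("CDS", max(cds[1L], e1[1L]), e1[2L]),
               fmt("CDS", e2[1L], min(cds[2L], e2[2L])))
  }
  writeLines(lines, path)
  path
}

#' Generate a complete synthetic two-group methylome study
#'
#' Writes per-sample CGmap files, a sample sheet (control group first), a
#' GTF, a chromosome-sizes table and a ground-truth table of implanted DMR
#' windows into `out_dir`. All randomness derives from `config$seed`;
#' identical configurations give byte-identical files.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param compress Gzip the CGmap files.
#' @return A list with `sheet` (a `sample_sheet`), `sheet_path`,
#'   `cgmap_paths`, `gtf_path`, `chrom_sizes_path`, `chrom_sizes`, `genes`,
#'   `truth` (`data.table` of implanted windows: `chrom`, `start`, `end`,
#'   `context`, `delta`, `true_control`, `true_experimental`) and `config`.
#' @export
simulate_dataset <- function(config, out_dir, compress = FALSE) {
  stopifnot(is(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  chroms <- paste0("Chr", seq_len(config$n_chroms))
  chrom_sizes <- setNames(rep(config$chrom_len, config$n_chroms), chroms)
  genes <- .sim_genes(config)

  ## site layout: per-bp multinomial over contexts
  site_list <- list()
  dens <- config$site_density[.CONTEXTS]
  dens[is.na(dens)] <- 0
  cum <- cumsum(dens)
  for (ch in chroms) {
    u <- runif(config$chrom_len)
    ctx <- rep(NA_character_, config$chrom_len)
    ctx[u < cum[1L]] <- "CG"
    ctx[u >= cum[1L] & u < cum[2L]] <- "CHG"
    ctx[u >= cum[2L] & u < cum[3L]] <- "CHH"
    pos <- which(!is.na(ctx))
    n <- length(pos)
    dt <- data.table(chrom = ch, position = pos, context = ctx[pos],
                     strand_base = sample(c("C", "G"), n, replace = TRUE))
    dt[, dinucleotide := .sim_dinucleotide("CHH", .N)]
    dt[context == "CG", dinucleotide := "CG"]
    site_list[[ch]] <- dt
  }
  sites <- rbindlist(site_list)

  ## true control level per site
  if (is.null(config$spatial_profile)) {
    sites[, true_control := config$baseline[context]]
  } else {
    in_body <- rep(FALSE, nrow(sites))
    if (nrow(genes)) {
      for (i in seq_len(nrow(genes))) {
        in_body <- in_body | (sites$chrom == genes$chrom[i] &
                                sites$position >= genes$start[i] &
                                sites$position <= genes$end[i])
      }
    }
    sites[, true_control := fifelse(in_body, config$spatial_profile$body,
                                    config$spatial_profile$flank)]
  }

  ## implanted DMR windows on the dmr_window_bp grid, sampled among windows
  ## that actually contain sites of the DMR context
  truth <- data.table(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      delta = numeric(), true_control = numeric(),
                      true_experimental = numeric(),
                      realized_delta = numeric())
  sites[, dmr_shift := 0]
  if (config$n_dmr > 0L) {
    w <- config$dmr_window_bp
    cand <- unique(sites[context == config$dmr_context,
                         .(chrom, win_start = ((position - 1L) %/% w) * w + 1L)])
    setorder(cand, chrom, win_start)
    pick <- cand[sample(.N, min(config$n_dmr, .N))]
    setorder(pick, chrom, win_start)
    key_all <- paste(sites$chrom, ((sites$position - 1L) %/% w) * w + 1L)
    key_pick <- paste(pick$chrom, pick$win_start)
    in_dmr <- key_all %in% key_pick & sites$context == config$dmr_context
    sites[in_dmr, dmr_shift := config$dmr_delta]
    tc <- sites[in_dmr,
                .(true_control = mean(true_control)),
                by = .(chrom,
                       start = ((position - 1L) %/% w) * w + 1L)]
    truth <- tc[, .(chrom, start, end = pmin(start + w - 1L,
                                             chrom_sizes[chrom]),
                    context = config$dmr_context, delta = config$dmr_delta,
                    true_control,
                    true_experimental = pmin(1, pmax(0,
                      true_control + config$dmr_delta +
                        config$group_effect[config$dmr_context])))]
    ## effect actually realizable after clipping to [0, 1]
    truth[, realized_delta := true_experimental - true_control]
    setorder(truth, chrom, start)
  }

  ## per-group true levels, clipped to [0, 1]
  sites[, true_experimental := pmin(1, pmax(0, true_control +
                                              config$group_effect[context] +
                                              dmr_shift))]
  sites[, true_control := pmin(1, pmax(0, true_control))]
  n_clip <- sites[, sum(true_control + config$group_effect[context] +
                          dmr_shift < 0 |
                        true_control + config$group_effect[context] +
                          dmr_shift > 1)]
  if (n_clip > 0) {
    message(n_clip, " site-level effects clipped to [0, 1]")
  }

  group <- c(rep(config$group_labels[1L], config$n_control),
             rep(config$group_labels[2L], config$n_experimental))
  sample_names <- c(sprintf("%s_%d", config$group_labels[1L],
                            seq_len(config$n_control)),
                    sprintf("%s_%d", config$group_labels[2L],
                            seq_len(config$n_experimental)))
  ext <- if (compress) ".cgmap.gz" else ".cgmap"
  paths <- file.path(out_dir, paste0(sample_names, ext))

  for (i in seq_along(sample_names)) {
    p_true <- if (group[i] == config$group_labels[1L]) {
      sites$true_control
    } else sites$true_experimental
    depth <- pmax(1L, rnbinom(nrow(sites), mu = config$depth_mean,
                              size = config$depth_dispersion))
    meth <- rbinom(nrow(sites), depth, p_true)
    calls <- data.table(chrom = sites$chrom,
                        strand_base = sites$strand_base,
                        position = sites$position,
                        context = sites$context,
                        dinucleotide = sites$dinucleotide,
                        level = meth / depth,
                        meth_reads = meth,
                        total_reads = depth)
    setorder(calls, chrom, position)
    write_cgmap(calls, paths[i], compress = compress)
  }

  sheet_path <- file.path(out_dir, "samples.tsv")
  writeLines(paste(sample_names, basename(paths), group, sep = "\t"),
             sheet_path)
  sheet <- read_sample_sheet(sheet_path)

  gtf_path <- .write_sim_gtf(genes, file.path(out_dir, "annotation.gtf"))
  cs_path <- file.path(out_dir, "chrom.sizes")
  writeLines(paste(names(chrom_sizes), chrom_sizes, sep = "\t"), cs_path)
  truth_path <- file.path(out_dir, "truth.tsv")
  fwrite(truth, truth_path, sep = "\t")

  list(sheet = sheet, sheet_path = sheet_path, cgmap_paths = paths,
       gtf_path = gtf_path, chrom_sizes_path = cs_path,
       chrom_sizes = chrom_sizes, genes = genes, truth = truth,
       config = config)
}

#' Write calls in a third-party dialect
#'
#' Emits a call table in one of the formats [convert_to_cgmap()] reads;
#' used to exercise the converters against a common ground truth.
#' `bismark_cx` receives the methylated/unmethylated split and a
#' trinucleotide padded with `N`; `bsmap_methratio` sets the effective CT
#' count equal to the CT count; `methimpute_tsv` carries no dinucleotide.
#'
#' @param calls A call table shaped like [read_cgmap()] output.
#' @param path Output path.
#' @param dialect `"bismark_cx"`, `"bsmap_methratio"` or
#'   `"methimpute_tsv"`.
#' @return `path`, invisibly.
#' @export
write_dialect <- function(calls, path,
                          dialect = c("bismark_cx", "bsmap_methratio",
                                      "methimpute_tsv")) {
  dialect <- match.arg(dialect)
  calls <- as.data.table(calls)
  strand <- ifelse(calls$strand_base == "C", "+", "-")
  lines <- switch(dialect,
    bismark_cx = paste(calls$chrom, calls$position, strand,
                       calls$meth_reads,
                       calls$total_reads - calls$meth_reads,
                       calls$context, paste0(calls$dinucleotide, "N"),
                       sep = "\t"),
    bsmap_methratio = c(
      paste("chr", "pos", "strand", "context", "ratio", "eff_CT_count",
            "C_count", "CT_count", sep = "\t"),
      paste(calls$chrom, calls$position, strand,
            paste0(calls$dinucleotide,
                   fifelse(calls$context == "CHG", "G", "N")),
            sprintf("%.6f", calls$level),
            calls$total_reads, calls$meth_reads, calls$total_reads,
            sep = "\t")),
    methimpute_tsv = c(
      paste("seqnames", "position", "strand", "context",
            "counts.methylated", "counts.total", sep = "\t"),
      paste(calls$chrom, calls$position, strand, calls$context,
            calls$meth_reads, calls$total_reads, sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}
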