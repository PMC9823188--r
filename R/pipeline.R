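## End-to-end driver: preprocessing -> summaries -> differential analysis
## -> enrichment, with every figure backed by a TSV twin and a run log that
## records all effective parameters and input checksums.

#' Pipeline configuration
#'
#' @param sheet_path Sample sheet path (see [read_sample_sheet()]).
#' @param gtf_path Gene annotation GTF path.
#' @param contexts Subset of `c("CG", "CHG", "CHH")` to analyze.
#' @param out_dir Output directory.
#' @param chrom_sizes_path Optional two-column chromosome-sizes table; when
#'   absent, lengths are approximated from the data.
#' @param spec A [window_spec()].
#' @param params A [dmr_params()].
#' @param heatmap_threshold Variable-region spread threshold (default
#'   0.20).
#' @param track_window_bp Chromosome-track window width (default 1e6).
#' @param flank_bp,n_body_bins,n_flank_bins Metagene geometry.
#' @param promoter_bp Promoter width upstream of the TSS (default 2000).
#' @param dmr_mode Observation unit for the window tests; see
#'   [call_dmrs()].
#' @param figures Render PNG figures alongside the TSV outputs.
#' @param dpi Figure resolution (default 300).
#' @return A list of class `run_config`.
#' @export
run_config <- function(sheet_path, gtf_path,
                       contexts = c("CG", "CHG", "CHH"),
                       out_dir = "methylDMR_out",
                       chrom_sizes_path = NULL,
                       spec = window_spec(),
                       params = dmr_params(),
                       heatmap_threshold = 0.20,
                       track_window_bp = 1000000L,
                       flank_bp = 2000L, n_body_bins = 20L,
                       n_flank_bins = 20L,
                       promoter_bp = 2000L,
                       dmr_mode = "pooled",
                       figures = TRUE, dpi = 300) {
  stopifnot(all(contexts %in% .CONTEXTS), length(contexts) >= 1L)
  structure(list(sheet_path = sheet_path, gtf_path = gtf_path,
                 contexts = contexts, out_dir = out_dir,
                 chrom_sizes_path = chrom_sizes_path, spec = spec,
                 params = params, heatmap_threshold = heatmap_threshold,
                 track_window_bp = as.integer(track_window_bp),
                 flank_bp = as.integer(flank_bp),
                 n_body_bins = as.integer(n_body_bins),
                 n_flank_bins = as.integer(n_flank_bins),
                 promoter_bp = as.integer(promoter_bp),
                 dmr_mode = dmr_mode, figures = figures, dpi = dpi),
            class = "run_config")
}

.log_line <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), "  ", ...)
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' For each requested context: builds the window matrix (TSV), PCA,
#' variable-region heatmap, group means, chromosome-scale track, metagene
#' profile, DMR/DMG tables (TSV + BED) and feature enrichment. A run log
#' in the output directory records parameters, input MD5 checksums, window
#' and DMR counts and skipped entities, so a run can be reproduced from the
#' log alone. Stage errors are raised with the stage name; outputs written
#' before the failure are retained.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list per context with the computed objects
#'   (`matrix`, `pca`, `dmrs`, `dmgs`, `enrichment`, `track`, `metagene`)
#'   plus `catalog` and `group_means`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  .log_line(log_path, "pipeline start")
  sheet <- stage("sample_sheet", read_sample_sheet(config$sheet_path))
  for (i in seq_len(nrow(sheet))) {
    .log_line(log_path, "input ", sheet$sample_name[i], " (",
              sheet$group[i], ") md5=", tools::md5sum(sheet$path[i]))
  }
  .log_line(log_path, "input gtf md5=", tools::md5sum(config$gtf_path))
  .log_line(log_path, "parameters: contexts=",
            paste(config$contexts, collapse = ","),
            " window_bp=", config$spec$window_bp,
            " min_cytosines=", config$spec$min_cytosines,
            " min_depth=", config$spec$min_depth,
            " test=", config$params$test,
            " min_delta=", config$params$min_delta,
            " alpha=", config$params$alpha,
            " heatmap_threshold=", config$heatmap_threshold,
            " track_window_bp=", config$track_window_bp,
            " promoter_bp=", config$promoter_bp,
            " dmr_mode=", config$dmr_mode)

  chrom_sizes <- if (!is.null(config$chrom_sizes_path)) {
    read_chrom_sizes(config$chrom_sizes_path)
  } else NULL

  models <- stage("annotation", parse_gtf(config$gtf_path))
  results <- list()
  gm_list <- list()

  for (ctx in config$contexts) {
    pref <- file.path(config$out_dir, ctx)
    figpref <- if (config$figures) pref else NULL

    wm <- stage(paste0("windows[", ctx, "]"),
                suppressMessages(build_matrix(sheet, config$spec, ctx,
                                              chrom_sizes = chrom_sizes)))
    .log_line(log_path, ctx, ": ", nrow(wm$windows), " eligible windows")
    write_matrix_tsv(wm, paste0(pref, "_matrix.tsv"))

    if (is.null(chrom_sizes)) chrom_sizes_ctx <- wm$chrom_sizes
    else chrom_sizes_ctx <- chrom_sizes
    catalog <- stage("catalog",
                     build_catalog(models, chrom_sizes_ctx,
                                   promoter_bp = config$promoter_bp))

    gm <- group_means(wm)
    gm_list[[ctx]] <- gm
    .log_line(log_path, ctx, ": group means ",
              paste(sprintf("%s=%.4f", names(gm$group_means),
                            gm$group_means), collapse = " "))

    pca <- stage(paste0("pca[", ctx, "]"),
                 run_pca(wm, out_prefix = figpref, dpi = config$dpi))
    if (is.null(figpref) && !is.null(pca)) {
      fwrite(pca$coords, paste0(pref, "_pca.tsv"), sep = "\t")
    }

    vr <- select_variable_regions(wm, config$heatmap_threshold)
    hm <- NULL
    if (!is.null(vr) && nrow(vr$windows) >= 2L && length(wm$samples) >= 2L) {
      hm <- stage(paste0("heatmap[", ctx, "]"),
                  cluster_heatmap(vr, out_prefix = figpref,
                                  dpi = config$dpi))
      .log_line(log_path, ctx, ": ", nrow(vr$windows), " variable regions")
    } else {
      .log_line(log_path, ctx, ": heatmap skipped (too few variable regions)")
    }

    track <- stage(paste0("track[", ctx, "]"),
                   suppressMessages(genome_track(
                     sheet, ctx, window_bp = config$track_window_bp,
                     chrom_sizes = chrom_sizes_ctx,
                     out_prefix = figpref, dpi = config$dpi)))
    if (is.null(figpref)) {
      dt <- cbind(track$windows, as.data.table(track$levels),
                  delta = track$delta)
      fwrite(dt, paste0(pref, "_track.tsv"), sep = "\t")
    }

    mg <- stage(paste0("metagene[", ctx, "]"),
                suppressMessages(metagene(
                  sheet, models, ctx, flank_bp = config$flank_bp,
                  n_body_bins = config$n_body_bins,
                  n_flank_bins = config$n_flank_bins,
                  min_depth = config$spec$min_depth,
                  out_prefix = figpref, dpi = config$dpi)))
    if (is.null(figpref)) {
      fwrite(mg$bins, paste0(pref, "_metagene.tsv"), sep = "\t")
    }

    dmrs <- stage(paste0("dmr[", ctx, "]"),
                  call_dmrs(wm, config$params, mode = config$dmr_mode))
    .log_line(log_path, ctx, ": ", nrow(dmrs), " DMRs (",
              attr(dmrs, "n_hyper"), " hyper, ", attr(dmrs, "n_hypo"),
              " hypo); ", attr(dmrs, "n_skipped"), " windows skipped")
    export_dmrs(dmrs, file.path(config$out_dir, "result"))

    dmgs <- stage(paste0("dmg[", ctx, "]"), assign_dmgs(dmrs, catalog))
    .log_line(log_path, ctx, ": ", nrow(dmgs), " DMGs (",
              sum(dmgs$in_gene_body), " gene body, ",
              sum(dmgs$in_promoter), " promoter)")
    fwrite(dmgs, file.path(config$out_dir,
                           paste0("result_", ctx, "_DMG.tsv")), sep = "\t")

    enr <- NULL
    if (nrow(dmrs) > 0L) {
      enr <- stage(paste0("enrichment[", ctx, "]"),
                   enrich(dmrs, catalog, out_prefix = figpref,
                          dpi = config$dpi))
      if (is.null(figpref)) {
        fwrite(enr, paste0(pref, "_enrichment.tsv"), sep = "\t")
      }
    } else {
      .log_line(log_path, ctx, ": enrichment skipped (no DMRs)")
    }

    results[[ctx]] <- list(matrix = wm, catalog = catalog, pca = pca,
                           heatmap = hm, track = track, metagene = mg,
                           dmrs = dmrs, dmgs = dmgs, enrichment = enr,
                           group_means = gm)
  }

  bar_pref <- if (config$figures) file.path(config$out_dir, "all") else NULL
  gm_dt <- group_mean_barplot(gm_list, out_prefix = bar_pref,
                              dpi = config$dpi)
  if (is.null(bar_pref)) {
    fwrite(gm_dt, file.path(config$out_dir, "all_group_means.tsv"),
           sep = "\t")
  }
  ## feature catalog BED export (first context's catalog; identical across
  ## contexts when chromosome sizes are supplied)
  export_bed(results[[1L]]$catalog, file.path(config$out_dir, "features"))
  .log_line(log_path, "pipeline done")
  invisible(c(results, list(group_means = gm_dt)))
}

#' Convert a third-party call file to CGmap
#'
#' Thin wrapper over [convert_to_cgmap()] + [write_cgmap()], mirroring a
#' standalone converter subcommand.
#'
#' @param input Input call file.
#' @param dialect See [convert_to_cgmap()].
#' @param output Output CGmap path; compressed when it ends in `.gz`.
#' @return `output`, invisibly.
#' @export
convert_calls <- function(input, dialect, output) {
  calls <- convert_to_cgmap(input, dialect)
  write_cgmap(calls, output, compress = grepl("\\.gz$", output))
  invisible(output)
}
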