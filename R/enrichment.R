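## DMR enrichment over genomic features against the genome background.
##
## For each feature the score is
##   log2(RG / LR) - log2(LF / LG)
## where RG is the bp of overlap between the merged DMR set and the merged
## feature set, LR the total bp of all DMRs, LF the feature's total bp and
## LG the genome length. All four symbols are lengths, so the score compares
## the feature's share of the DMR footprint to its share of the genome; 0
## means the DMR composition matches the genome composition.

#' Total overlap length of two merged interval sets
#'
#' @param a,b `GRanges` (merged or not; they are reduced internally).
#' @return Total intersection length in bp.
#' @export
overlap_length <- function(a, b) {
  a <- GenomicRanges::reduce(GenomicRanges::granges(a), ignore.strand = TRUE)
  b <- GenomicRanges::reduce(GenomicRanges::granges(b), ignore.strand = TRUE)
  ## disjoint chromosome sets are a legal zero-overlap case, not a
  ## user-facing warning
  sum(as.numeric(GenomicRanges::width(suppressWarnings(
    GenomicRanges::intersect(a, b, ignore.strand = TRUE)))))
}

#' DMR enrichment across the eight-feature catalog
#'
#' Computes, per feature, `score = log2(RG/LR) - log2(LF/LG)` with RG the
#' overlap length between merged DMRs and the feature, LR the merged DMR
#' footprint, LF the feature length and LG the genome length. Positive
#' scores mean the DMR footprint is over-represented in the feature.
#' Features with `RG = 0` (or `LF = 0`) get `-Inf`, rendered as a capped
#' bar in the figure.
#'
#' @param dmrs A `dmr_set` (or any data frame with `chrom`, `start`, `end`,
#'   1-based inclusive), or a `GRanges`.
#' @param catalog A `feature_catalog`.
#' @param mask Optional `GRanges` coverage mask (e.g. RRBS fragments): when
#'   given, LF and LG — and RG/LR — are recomputed within the mask before
#'   scoring.
#' @param out_prefix Optional path prefix; writes `<prefix>_enrichment.tsv`
#'   and `.png` (300 dpi bar chart).
#' @param dpi Figure resolution.
#' @return A `data.table` with `feature`, `RG`, `LR`, `LF`, `LG`, `score`.
#' @export
enrich <- function(dmrs, catalog, mask = NULL, out_prefix = NULL, dpi = 300) {
  stopifnot(is(catalog, "feature_catalog"))
  dmr_gr <- if (is(dmrs, "GRanges")) GenomicRanges::granges(dmrs) else {
    GenomicRanges::GRanges(dmrs$chrom,
                           IRanges::IRanges(dmrs$start, dmrs$end))
  }
  dmr_gr <- GenomicRanges::reduce(dmr_gr, ignore.strand = TRUE)
  genome_gr <- GenomicRanges::GRanges(
    names(catalog$chrom_sizes),
    IRanges::IRanges(1L, unname(catalog$chrom_sizes)))

  if (!is.null(mask)) {
    mask <- GenomicRanges::reduce(GenomicRanges::granges(mask),
                                  ignore.strand = TRUE)
    dmr_gr <- GenomicRanges::intersect(dmr_gr, mask, ignore.strand = TRUE)
    genome_gr <- GenomicRanges::intersect(genome_gr, mask,
                                          ignore.strand = TRUE)
  }
  LR <- sum(as.numeric(GenomicRanges::width(dmr_gr)))
  if (LR == 0) stop("no DMRs: enrichment undefined (LR = 0)", call. = FALSE)
  LG <- sum(as.numeric(GenomicRanges::width(genome_gr)))

  rows <- lapply(names(catalog$features), function(f) {
    fgr <- catalog$features[[f]]
    if (!is.null(mask)) {
      fgr <- GenomicRanges::intersect(fgr, mask, ignore.strand = TRUE)
    }
    LF <- sum(as.numeric(GenomicRanges::width(fgr)))
    RG <- overlap_length(dmr_gr, fgr)
    score <- if (RG > 0 && LF > 0) {
      log2(RG / LR) - log2(LF / LG)
    } else -Inf
    data.table(feature = f, RG = RG, LR = LR, LF = LF, LG = LG,
               score = score)
  })
  out <- rbindlist(rows)
  if (!is.null(out_prefix)) {
    fwrite(out, paste0(out_prefix, "_enrichment.tsv"), sep = "\t")
    plot_dt <- copy(out)
    finite <- plot_dt$score[is.finite(plot_dt$score)]
    cap <- if (length(finite)) min(c(finite, 0)) - 1 else -1
    plot_dt[, capped := !is.finite(score)]
    plot_dt[capped == TRUE, score := cap]
    plot_dt[, feature := factor(feature, levels = names(catalog$features))]
    p <- ggplot2::ggplot(plot_dt,
                         ggplot2::aes(feature, score, fill = score > 0)) +
      ggplot2::geom_col(show.legend = FALSE) +
      ggplot2::geom_hline(yintercept = 0) +
      ggplot2::labs(x = NULL,
                    y = "log2(RG/LR) - log2(LF/LG)",
                    caption = if (any(plot_dt$capped))
                      "bars at the lower edge: no DMR overlap (-Inf)" else
                      NULL) +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
    ggplot2::ggsave(paste0(out_prefix, "_enrichment.png"), p, width = 5,
                    height = 4, dpi = dpi)
  }
  out[]
}
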