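## GTF parsing and the eight-feature genomic catalog:
## promoter, gene_body, exon, intron, utr5, cds, utr3, igr.
##
## Features are independent merged interval sets, not a partition: a base in
## one gene's intron and an overlapping gene's exon counts for both. Only
## gene_body and igr partition the genome exactly.

.FEATURES <- c("promoter", "gene_body", "exon", "intron",
               "utr5", "cds", "utr3", "igr")

#' Parse a GTF into per-gene models
#'
#' Reads a GFF2/GTF annotation and collapses it to one model per `gene_id`:
#' the gene body is the min-start/max-end span over all of the gene's rows,
#' and exon/CDS/UTR sets are unions over transcripts. When the file carries
#' no explicit `five_prime_utr`/`three_prime_utr` rows, UTRs are derived as
#' exon-minus-CDS, split by which side of the CDS span they fall on relative
#' to the strand.
#'
#' @param path Path to a GTF file.
#' @return An object of class `gene_models`: a list with `genes` (a
#'   `data.table` of `gene_id`, `chrom`, `strand`, `start`, `end`) and
#'   per-gene `GRanges` of `exons`, `cds`, `utr5`, `utr3` (each carrying a
#'   `gene_id` metadata column).
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0L) stop("no records in GTF: ", path, call. = FALSE)
  if (is.null(gr$gene_id) || all(is.na(gr$gene_id))) {
    stop("GTF attributes lack gene_id: ", path, call. = FALSE)
  }
  if (any(GenomicRanges::end(gr) < GenomicRanges::start(gr))) {
    stop("GTF record with end < start in ", path, call. = FALSE)
  }
  gr <- gr[!is.na(gr$gene_id)]
  type <- tolower(as.character(gr$type))

  spans <- unlist(range(S4Vectors::split(gr, gr$gene_id)))
  genes <- data.table(
    gene_id = names(spans),
    chrom = as.character(GenomeInfoDb::seqnames(spans)),
    strand = as.character(GenomicRanges::strand(spans)),
    start = GenomicRanges::start(spans),
    end = GenomicRanges::end(spans))
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("gene without a determinate strand in ", path, call. = FALSE)
  }
  setorder(genes, chrom, start, end, gene_id)

  take <- function(what) {
    sel <- gr[type %in% what]
    merged <- GenomicRanges::reduce(S4Vectors::split(sel, sel$gene_id))
    out <- unlist(merged)
    if (length(out)) {
      S4Vectors::mcols(out)$gene_id <- names(out)
      names(out) <- NULL
    } else {
      S4Vectors::mcols(out)$gene_id <- character()
    }
    out
  }
  exons <- take("exon")
  cds <- take("cds")
  utr5 <- take(c("five_prime_utr", "5utr", "utr5"))
  utr3 <- take(c("three_prime_utr", "3utr", "utr3"))

  if (length(utr5) == 0L && length(utr3) == 0L && length(cds) > 0L) {
    derived <- .derive_utrs(genes, exons, cds)
    utr5 <- derived$utr5
    utr3 <- derived$utr3
  }
  structure(list(genes = genes, exons = exons, cds = cds,
                 utr5 = utr5, utr3 = utr3),
            class = "gene_models")
}

## UTR = exon minus CDS, assigned 5'/3' by side of the CDS span, per gene
.derive_utrs <- function(genes, exons, cds) {
  empty <- GenomicRanges::GRanges()
  S4Vectors::mcols(empty)$gene_id <- character()
  utr5 <- utr3 <- empty
  cds_ids <- unique(cds$gene_id)
  for (gid in cds_ids) {
    ge <- exons[exons$gene_id == gid]
    gc <- cds[cds$gene_id == gid]
    if (length(ge) == 0L) next
    utr <- GenomicRanges::setdiff(ge, gc, ignore.strand = TRUE)
    if (length(utr) == 0L) next
    cds_lo <- min(GenomicRanges::start(gc))
    cds_hi <- max(GenomicRanges::end(gc))
    left <- utr[GenomicRanges::end(utr) < cds_lo]
    right <- utr[GenomicRanges::start(utr) > cds_hi]
    strand_g <- genes$strand[match(gid, genes$gene_id)]
    five <- if (strand_g == "+") left else right
    three <- if (strand_g == "+") right else left
    if (length(five)) {
      S4Vectors::mcols(five)$gene_id <- gid
      utr5 <- c(utr5, five)
    }
    if (length(three)) {
      S4Vectors::mcols(three)$gene_id <- gid
      utr3 <- c(utr3, three)
    }
  }
  list(utr5 = utr5, utr3 = utr3)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("Gene models: ", nrow(x$genes), " genes on ",
      length(unique(x$genes$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

## strand-aware promoter windows: the promoter_bp bases immediately upstream
## of the TSS, clipped to the chromosome
.promoters_gr <- function(genes, chrom_sizes, promoter_bp) {
  p_start <- ifelse(genes$strand == "+", genes$start - promoter_bp,
                    genes$end + 1L)
  p_end <- ifelse(genes$strand == "+", genes$start - 1L,
                  genes$end + promoter_bp)
  lens <- chrom_sizes[genes$chrom]
  p_start <- pmax(p_start, 1L)
  p_end <- pmin(p_end, lens)
  keep <- p_start <= p_end
  gr <- GenomicRanges::GRanges(genes$chrom[keep],
                               IRanges::IRanges(p_start[keep], p_end[keep]))
  S4Vectors::mcols(gr)$gene_id <- genes$gene_id[keep]
  gr
}

#' Build the eight-feature genomic catalog
#'
#' Derives merged interval sets for promoter (the `promoter_bp` bases
#' immediately upstream of each TSS, strand-aware, clipped to the
#' chromosome), gene body (TSS--TES span), exon, intron (gene body minus
#' exons, per gene), 5'UTR, CDS, 3'UTR, and IGR (the genome complement of
#' merged gene bodies; promoters are intentionally not carved out of it).
#'
#' @param models A `gene_models` object from [parse_gtf()].
#' @param chrom_sizes Named integer vector of chromosome lengths; every
#'   gene's chromosome must be present.
#' @param promoter_bp Promoter width upstream of the TSS (default 2000).
#' @return An object of class `feature_catalog`: list with `features`
#'   (named list of merged `GRanges`), `feature_lengths` (total bp per
#'   feature, `LF`), `genome_length` (`LG`), `chrom_sizes`, `promoter_bp`,
#'   and `promoters_by_gene` / `genes` kept for DMG assignment.
#' @export
build_catalog <- function(models, chrom_sizes, promoter_bp = 2000L) {
  stopifnot(is(models, "gene_models"))
  chrom_sizes <- .as_chrom_sizes(chrom_sizes)
  genes <- models$genes
  missing_chr <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(missing_chr)) {
    stop("chromosome size missing for: ", paste(missing_chr, collapse = ", "),
         call. = FALSE)
  }
  genome_gr <- GenomicRanges::GRanges(
    names(chrom_sizes), IRanges::IRanges(1L, unname(chrom_sizes)))

  gene_body <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end))
  gene_body_m <- GenomicRanges::reduce(gene_body)

  ## intron = per-gene span minus that gene's exons, then merged across genes
  intron_list <- lapply(seq_len(nrow(genes)), function(i) {
    span <- GenomicRanges::GRanges(genes$chrom[i],
                                   IRanges::IRanges(genes$start[i],
                                                    genes$end[i]))
    ex <- models$exons[models$exons$gene_id == genes$gene_id[i]]
    GenomicRanges::setdiff(span, GenomicRanges::granges(ex),
                           ignore.strand = TRUE)
  })
  intron <- GenomicRanges::reduce(do.call(c, c(list(GenomicRanges::GRanges()),
                                               intron_list)))

  promoters_by_gene <- .promoters_gr(genes, chrom_sizes, promoter_bp)

  strip <- function(gr) GenomicRanges::reduce(
    GenomicRanges::granges(gr), ignore.strand = TRUE)
  features <- list(
    promoter = strip(promoters_by_gene),
    gene_body = gene_body_m,
    exon = strip(models$exons),
    intron = intron,
    utr5 = strip(models$utr5),
    cds = strip(models$cds),
    utr3 = strip(models$utr3),
    igr = GenomicRanges::setdiff(genome_gr, gene_body_m,
                                 ignore.strand = TRUE))
  features <- lapply(features, function(gr) {
    GenomicRanges::strand(gr) <- "*"
    sort(gr)
  })
  feature_lengths <- vapply(features,
                            function(gr) sum(as.numeric(
                              GenomicRanges::width(gr))), numeric(1))
  structure(list(features = features,
                 feature_lengths = feature_lengths,
                 genome_length = sum(as.numeric(chrom_sizes)),
                 chrom_sizes = chrom_sizes,
                 promoter_bp = as.integer(promoter_bp),
                 promoters_by_gene = promoters_by_gene,
                 genes = genes),
            class = "feature_catalog")
}

.as_chrom_sizes <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    cs <- setNames(as.integer(chrom_sizes[[2L]]),
                   as.character(chrom_sizes[[1L]]))
  } else {
    cs <- chrom_sizes
  }
  if (is.null(names(cs)) || any(!nzchar(names(cs)))) {
    stop("chrom_sizes must be named by chromosome", call. = FALSE)
  }
  if (any(cs < 1L)) stop("non-positive chromosome size", call. = FALSE)
  cs
}

#' Read a two-column chromosome-sizes table
#'
#' @param path Tab- or whitespace-separated file: chromosome name, length.
#' @return Named integer vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- fread(path, header = FALSE)
  if (ncol(dt) < 2L) stop("chrom sizes file needs 2 columns", call. = FALSE)
  setNames(as.integer(dt[[2L]]), as.character(dt[[1L]]))
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat("Feature catalog over ", length(x$chrom_sizes), " chromosome(s), LG = ",
      x$genome_length, " bp\n", sep = "")
  for (f in names(x$features)) {
    cat(sprintf("  %-9s %6d intervals  LF = %.0f bp\n", f,
                length(x$features[[f]]), x$feature_lengths[[f]]))
  }
  invisible(x)
}

#' Export the feature catalog as BED files
#'
#' Writes one BED3 file per feature (`promoter.bed`, `gene_body.bed`,
#' `exon.bed`, `intron.bed`, `utr5.bed`, `cds.bed`, `utr3.bed`, `igr.bed`)
#' in 0-based half-open coordinates, sorted by chromosome then start.
#' Empty feature sets produce empty files.
#'
#' @param catalog A `feature_catalog`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the eight file paths, invisibly.
#' @export
export_bed <- function(catalog, out_dir) {
  stopifnot(is(catalog, "feature_catalog"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (f in .FEATURES) {
    gr <- catalog$features[[f]]
    path <- file.path(out_dir, paste0(f, ".bed"))
    dt <- data.table(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr))
    setorder(dt, chrom, start)
    fwrite(dt, path, sep = "\t", col.names = FALSE)
    paths[f] <- path
  }
  invisible(paths)
}

#' Read a BED file as 1-based inclusive intervals
#'
#' Convenience reader for the BED3+ files written by [export_bed()] and
#' [export_dmrs()]; converts 0-based half-open BED coordinates back to the
#' package's 1-based inclusive convention.
#'
#' @param path BED file path.
#' @return A `GRanges` (unstranded).
#' @export
read_bed <- function(path) {
  lines <- .read_lines_maybe_gz(path)
  if (length(lines) == 0L) return(GenomicRanges::GRanges())
  dt <- fread(text = lines, header = FALSE, sep = "\t")
  GenomicRanges::GRanges(as.character(dt[[1L]]),
                         IRanges::IRanges(dt[[2L]] + 1L, dt[[3L]]))
}
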