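## CGmap and related per-cytosine call format I/O.
##
## CGmap is the 8-column tab-separated convention of BS-Seeker-style callers:
##   chrom, nucleotide (C on forward / G on reverse strand), 1-based position,
##   context (CG/CHG/CHH), local dinucleotide (CG/CA/CT/CC), methylation
##   level, methylated read count, total read count.
## All call-level coordinates in this package are 1-based inclusive; the shift
## to 0-based half-open happens only when BED files are written.

.CONTEXTS <- c("CG", "CHG", "CHH")

.cgmap_cols <- c("chrom", "strand_base", "position", "context",
                 "dinucleotide", "level", "meth_reads", "total_reads")

## read a possibly gzip-compressed text file into a character vector;
## gzfile() transparently handles plain files too
.read_lines_maybe_gz <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  readLines(con)
}

.parse_cgmap_lines <- function(lines, path = "<text>") {
  if (length(lines) == 0L) {
    dt <- data.table(chrom = character(), strand_base = character(),
                     position = integer(), context = character(),
                     dinucleotide = character(), level = numeric(),
                     meth_reads = integer(), total_reads = integer())
    return(dt)
  }
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nfield != 8L)) {
    bad <- which(nfield != 8L)[1L]
    stop("malformed CGmap line ", bad, " in '", path, "': expected 8 ",
         "tab-separated fields, found ", nfield[bad], call. = FALSE)
  }
  dt <- fread(text = lines, header = FALSE, sep = "\t",
              colClasses = list(character = c(1L, 2L, 4L, 5L),
                                integer = c(3L, 7L, 8L), numeric = 6L))
  setnames(dt, .cgmap_cols)

  bad_ctx <- which(!dt$context %in% .CONTEXTS)
  if (length(bad_ctx)) {
    stop("unknown context token '", dt$context[bad_ctx[1L]], "' at line ",
         bad_ctx[1L], " in '", path, "' (expected CG, CHG or CHH)",
         call. = FALSE)
  }
  bad_sb <- which(!dt$strand_base %in% c("C", "G"))
  if (length(bad_sb)) {
    stop("invalid nucleotide column '", dt$strand_base[bad_sb[1L]],
         "' at line ", bad_sb[1L], " in '", path, "'", call. = FALSE)
  }
  bad_pos <- which(is.na(dt$position) | dt$position < 1L)
  if (length(bad_pos)) {
    stop("invalid position at line ", bad_pos[1L], " in '", path, "'",
         call. = FALSE)
  }
  bad_cnt <- which(is.na(dt$total_reads) | is.na(dt$meth_reads) |
                     dt$total_reads < 1L | dt$meth_reads < 0L |
                     dt$meth_reads > dt$total_reads)
  if (length(bad_cnt)) {
    stop("invalid read counts at line ", bad_cnt[1L], " in '", path,
         "': need 0 <= methylated <= total and total >= 1", call. = FALSE)
  }
  ## CGmap levels are often printed rounded (>= 2 decimals); reconcile the
  ## stored level with the exact count ratio, but reject anything further
  ## from it than printing could explain.
  exact <- dt$meth_reads / dt$total_reads
  bad_lvl <- which(is.na(dt$level) | abs(dt$level - exact) > 0.005 + 1e-9)
  if (length(bad_lvl)) {
    stop("methylation level disagrees with read counts at line ",
         bad_lvl[1L], " in '", path, "' (level ", dt$level[bad_lvl[1L]],
         ", counts give ", signif(exact[bad_lvl[1L]], 6), ")", call. = FALSE)
  }
  dt[, level := exact]
  dt[]
}

#' Read per-cytosine methylation calls from a CGmap file
#'
#' Parses an 8-column (optionally gzip-compressed) CGmap file into a
#' `data.table` of validated calls. Low-coverage records are retained but
#' flagged: depth filtering is a windowing decision, not an I/O one.
#'
#' @param path Path to a CGmap file, plain or `.gz`.
#' @param min_depth Read-depth threshold used only to set the `low_depth`
#'   flag (`total_reads < min_depth`). Default 4, matching the window
#'   eligibility filter.
#' @return A `data.table` with columns `chrom`, `strand_base`, `position`,
#'   `context`, `dinucleotide`, `level`, `meth_reads`, `total_reads` and the
#'   logical `low_depth`. `level` always equals `meth_reads / total_reads`
#'   exactly after parsing.
#' @seealso [write_cgmap()], [convert_to_cgmap()], [read_cgmap_chunked()]
#' @examples
#' f <- tempfile(fileext = ".cgmap")
#' writeLines("Chr1\tC\t100\tCG\tCG\t0.75\t3\t4", f)
#' read_cgmap(f)
#' @export
read_cgmap <- function(path, min_depth = 4L) {
  if (!file.exists(path)) stop("CGmap file not found: ", path, call. = FALSE)
  dt <- .parse_cgmap_lines(.read_lines_maybe_gz(path), path)
  dt[, low_depth := total_reads < as.integer(min_depth)]
  dt[]
}

#' Read a CGmap file in fixed-size chunks
#'
#' Streaming variant of [read_cgmap()] for files too large to hold in
#' memory: `callback` is invoked on each successive chunk of validated
#' calls, so peak memory is bounded by the chunk size.
#'
#' @inheritParams read_cgmap
#' @param callback Function of one argument, called with each chunk (a
#'   `data.table` shaped like the [read_cgmap()] result).
#' @param chunk_size Number of lines per chunk.
#' @return Invisibly, the total number of records processed.
#' @export
read_cgmap_chunked <- function(path, callback, chunk_size = 100000L,
                               min_depth = 4L) {
  stopifnot(is.function(callback), chunk_size >= 1L)
  if (!file.exists(path)) stop("CGmap file not found: ", path, call. = FALSE)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  total <- 0L
  offset <- 0L
  repeat {
    lines <- readLines(con, n = chunk_size)
    if (length(lines) == 0L) break
    dt <- tryCatch(.parse_cgmap_lines(lines, path), error = function(e) {
      stop(gsub("line (\\d+)", paste0("line \\1 (+", offset, ")"),
                conditionMessage(e)), call. = FALSE)
    })
    dt[, low_depth := total_reads < as.integer(min_depth)]
    callback(dt)
    total <- total + nrow(dt)
    offset <- offset + length(lines)
  }
  invisible(total)
}

## print a methylation level with at least two decimals, up to six
## significant decimals, no trailing zero noise
.format_level <- function(x) {
  s <- sprintf("%.6f", x)
  sub("(\\.\\d\\d\\d*?)0+$", "\\1", s)
}

#' Write methylation calls as a CGmap file
#'
#' Emits the canonical 8-column tab-separated CGmap layout, one record per
#' line, headerless. Levels are printed with at least two decimals.
#'
#' @param calls A `data.table`/`data.frame` of calls as returned by
#'   [read_cgmap()] or [convert_to_cgmap()] (extra columns are ignored).
#' @param path Output path.
#' @param compress Write gzip-compressed output.
#' @return `path`, invisibly.
#' @export
write_cgmap <- function(calls, path, compress = FALSE) {
  calls <- as.data.table(calls)
  missing_cols <- setdiff(.cgmap_cols, names(calls))
  if (length(missing_cols)) {
    stop("calls lack required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  lines <- if (nrow(calls) == 0L) character() else {
    paste(calls$chrom, calls$strand_base, format(calls$position,
                                                 scientific = FALSE,
                                                 trim = TRUE),
          calls$context, calls$dinucleotide, .format_level(calls$level),
          calls$meth_reads, calls$total_reads, sep = "\t")
  }
  con <- if (compress) gzfile(path, open = "wb") else file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Convert third-party methylation call formats to CGmap records
#'
#' Supported dialects:
#' * `bismark_cx`: Bismark cytosine (CX) report — chrom, position, strand,
#'   methylated count, unmethylated count, context, trinucleotide.
#' * `bsmap_methratio`: BSMAP `methratio.py` output — header line then chrom,
#'   position, strand, 3-nt context, ratio, effective CT count, C count,
#'   CT count (extra columns ignored). The effective CT count is rounded to
#'   the nearest integer for `total_reads`.
#' * `methimpute_tsv`: tab-separated table with a header naming `seqnames`,
#'   `position`, `strand`, `context`, `counts.methylated`, `counts.total`.
#'   This dialect does not record the local dinucleotide; it is emitted as
#'   `"CG"` for CG sites and `"CN"` otherwise.
#'
#' Levels are recomputed from counts; zero-coverage records are dropped
#' (their level is undefined). Strand `+` maps to nucleotide `C`, `-` to `G`.
#' No dialect auto-detection is attempted.
#'
#' @param path Input file, plain or gzip-compressed.
#' @param dialect One of `"bismark_cx"`, `"bsmap_methratio"`,
#'   `"methimpute_tsv"`.
#' @return A `data.table` of calls shaped like [read_cgmap()] output
#'   (without the `low_depth` flag).
#' @export
convert_to_cgmap <- function(path,
                             dialect = c("bismark_cx", "bsmap_methratio",
                                         "methimpute_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  lines <- .read_lines_maybe_gz(path)
  out <- switch(dialect,
    bismark_cx = .convert_bismark_cx(lines, path),
    bsmap_methratio = .convert_methratio(lines, path),
    methimpute_tsv = .convert_methimpute(lines, path))
  setcolorder(out, .cgmap_cols)
  setorder(out, chrom, position)
  out[]
}

.strand_to_base <- function(strand, path) {
  if (any(!strand %in% c("+", "-"))) {
    stop("invalid strand symbol in '", path, "'", call. = FALSE)
  }
  ifelse(strand == "+", "C", "G")
}

.classify_context <- function(triplet) {
  second <- substr(triplet, 2L, 2L)
  third <- substr(triplet, 3L, 3L)
  fifelse(second == "G", "CG", fifelse(third == "G", "CHG", "CHH"))
}

.convert_bismark_cx <- function(lines, path) {
  dt <- fread(text = lines, header = FALSE, sep = "\t",
              col.names = c("chrom", "position", "strand", "n_meth",
                            "n_unmeth", "context", "trinucleotide"),
              colClasses = list(character = c(1L, 3L, 6L, 7L),
                                integer = c(2L, 4L, 5L)))
  if (any(!dt$context %in% .CONTEXTS)) {
    stop("unknown context token in Bismark CX report '", path, "'",
         call. = FALSE)
  }
  dt <- dt[n_meth + n_unmeth > 0L]
  data.table(chrom = dt$chrom,
             strand_base = .strand_to_base(dt$strand, path),
             position = dt$position,
             context = dt$context,
             dinucleotide = substr(dt$trinucleotide, 1L, 2L),
             level = dt$n_meth / (dt$n_meth + dt$n_unmeth),
             meth_reads = dt$n_meth,
             total_reads = dt$n_meth + dt$n_unmeth)
}

.convert_methratio <- function(lines, path) {
  if (length(lines) < 1L) stop("empty methratio file: ", path, call. = FALSE)
  dt <- fread(text = lines[-1L], header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(dt) < 8L) {
    stop("methratio file '", path, "' has fewer than 8 columns", call. = FALSE)
  }
  setnames(dt, 1:8, c("chrom", "position", "strand", "context3", "ratio",
                      "eff_ct", "n_c", "n_ct"))
  dt <- dt[n_ct > 0L]
  total <- pmax(1L, as.integer(round(dt$eff_ct)))
  meth <- pmin(as.integer(dt$n_c), total)
  data.table(chrom = as.character(dt$chrom),
             strand_base = .strand_to_base(as.character(dt$strand), path),
             position = as.integer(dt$position),
             context = .classify_context(as.character(dt$context3)),
             dinucleotide = substr(as.character(dt$context3), 1L, 2L),
             level = meth / total,
             meth_reads = meth,
             total_reads = total)
}

.convert_methimpute <- function(lines, path) {
  dt <- fread(text = lines, header = TRUE, sep = "\t")
  need <- c("seqnames", "position", "strand", "context",
            "counts.methylated", "counts.total")
  ## some exports call the position column "start"
  if (!"position" %in% names(dt) && "start" %in% names(dt)) {
    setnames(dt, "start", "position")
  }
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop("METHimpute table '", path, "' lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!dt$context %in% .CONTEXTS)) {
    stop("unknown context token in METHimpute table '", path, "'",
         call. = FALSE)
  }
  dt <- dt[dt$counts.total > 0L, ]
  data.table(chrom = as.character(dt$seqnames),
             strand_base = .strand_to_base(as.character(dt$strand), path),
             position = as.integer(dt$position),
             context = as.character(dt$context),
             dinucleotide = fifelse(dt$context == "CG", "CG", "CN"),
             level = dt$counts.methylated / dt$counts.total,
             meth_reads = as.integer(dt$counts.methylated),
             total_reads = as.integer(dt$counts.total))
}

#' Read a two-group sample sheet
#'
#' The sheet is whitespace- or tab-separated plain text with one line per
#' sample: `sample_name path group_label`. Lines starting with `#` are
#' ignored. Exactly two distinct group labels are required; the
#' first-listed group is taken as the control/reference group, so the
#' pipeline's delta convention is experimental minus control.
#'
#' @param path Path to the sample sheet. Relative call-file paths are
#'   resolved against the sheet's own directory when they do not resolve
#'   against the working directory.
#' @return A `data.frame` of class `sample_sheet` with columns
#'   `sample_name`, `path`, `group` and attributes `groups` (control
#'   first) and `control`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path, call. = FALSE)
  lines <- .read_lines_maybe_gz(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("sample sheet is empty: ", path, call. = FALSE)
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) != 3L)) {
    bad <- which(lengths(fields) != 3L)[1L]
    stop("sample sheet entry ", bad, " does not have 3 fields ",
         "(sample_name path group_label)", call. = FALSE)
  }
  m <- do.call(rbind, fields)
  sheet <- data.frame(sample_name = m[, 1L], path = m[, 2L], group = m[, 3L],
                      stringsAsFactors = FALSE)
  if (anyDuplicated(sheet$sample_name)) {
    stop("duplicate sample name in sheet: ",
         sheet$sample_name[duplicated(sheet$sample_name)][1L], call. = FALSE)
  }
  ## resolve relative paths against the sheet location
  base <- dirname(normalizePath(path))
  resolved <- ifelse(file.exists(sheet$path), sheet$path,
                     file.path(base, sheet$path))
  missing_f <- !file.exists(resolved)
  if (any(missing_f)) {
    stop("call file not found for sample '",
         sheet$sample_name[missing_f][1L], "': ", sheet$path[missing_f][1L],
         call. = FALSE)
  }
  sheet$path <- resolved
  groups <- unique(sheet$group)
  if (length(groups) != 2L) {
    stop("exactly two groups required, found ", length(groups), ": ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  structure(sheet, groups = groups, control = groups[1L],
            class = c("sample_sheet", "data.frame"))
}

#' Construct a sample sheet from in-memory vectors
#'
#' Programmatic equivalent of [read_sample_sheet()], used by the simulator
#' and convenient in scripts.
#'
#' @param sample_name,path,group Equal-length character vectors.
#' @return A `sample_sheet` object; see [read_sample_sheet()].
#' @export
sample_sheet <- function(sample_name, path, group) {
  sheet <- data.frame(sample_name = as.character(sample_name),
                      path = as.character(path),
                      group = as.character(group), stringsAsFactors = FALSE)
  if (anyDuplicated(sheet$sample_name)) stop("duplicate sample name")
  groups <- unique(sheet$group)
  if (length(groups) != 2L) {
    stop("exactly two groups required, found ", length(groups), call. = FALSE)
  }
  structure(sheet, groups = groups, control = groups[1L],
            class = c("sample_sheet", "data.frame"))
}

#' @export
print.sample_sheet <- function(x, ...) {
  cat("Sample sheet: ", nrow(x), " samples, control group '",
      attr(x, "control"), "' vs '", setdiff(attr(x, "groups"),
                                            attr(x, "control")), "'\n",
      sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Harmonize chromosome naming between two name sets
#'
#' CGmap files and GTF annotations sometimes disagree on the `"chr"`
#' prefix. With `mode = "strict"` (the default) any mismatch is a hard
#' error listing the offending names; `"strip"` removes a leading `chr`
#' prefix, `"add"` prepends one where absent.
#'
#' @param chroms Character vector of chromosome names to adjust.
#' @param reference Character vector of names they must match.
#' @param mode `"strict"`, `"strip"` or `"add"`.
#' @return The adjusted `chroms` vector.
#' @export
harmonize_chroms <- function(chroms, reference,
                             mode = c("strict", "strip", "add")) {
  mode <- match.arg(mode)
  out <- switch(mode,
    strict = chroms,
    strip = sub("^chr", "", chroms),
    add = ifelse(grepl("^chr", chroms), chroms, paste0("chr", chroms)))
  bad <- setdiff(unique(out), reference)
  if (length(bad)) {
    stop("chromosome names not present in reference set: ",
         paste(bad, collapse = ", "),
         if (mode == "strict") " (consider mode = 'strip' or 'add')",
         call. = FALSE)
  }
  out
}
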