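# Readers/writers for the RepeatMasker .out dialect, FASTA, and BED6.
# All internal coordinates are 1-based inclusive (the .out convention);
# conversion to 0-based half-open happens only at the BED boundary.

.ANN_COLS <- c("sw_score", "pct_div", "pct_del", "pct_ins", "query_name",
               "query_begin", "query_end", "query_left", "strand",
               "repeat_name", "repeat_class", "cons_begin", "cons_end",
               "cons_left", "run_id")

.emptyAnnotations <- function() {
  data.frame(sw_score = integer(), pct_div = numeric(), pct_del = numeric(),
             pct_ins = numeric(), query_name = character(),
             query_begin = integer(), query_end = integer(),
             query_left = integer(), strand = character(),
             repeat_name = character(), repeat_class = character(),
             cons_begin = integer(), cons_end = integer(),
             cons_left = integer(), run_id = integer(),
             stringsAsFactors = FALSE)
}

.stripParen <- function(x) as.integer(gsub("[()]", "", x))

#' Read a RepeatMasker .out annotation table
#'
#' Parses the whitespace-delimited .out dialect: an optional 3-line header,
#' then one row per repeat hit. Parenthesized "(left)" fields are accepted
#' in the query and consensus columns. For C-strand (reverse) hits the
#' consensus columns appear as \code{(left) end begin} and are normalized so
#' that \code{cons_begin <= cons_end} always refers to consensus
#' coordinates. A trailing asterisk overlap-flag column, if present, is
#' ignored. The strand symbol "C" is preserved verbatim (not remapped to
#' "-") so that round-trips are exact.
#'
#' @param file path to a .out file, or a character vector of lines.
#' @return data.frame of annotations, one row per hit, with columns
#'   \code{sw_score}, \code{pct_div}, \code{pct_del}, \code{pct_ins},
#'   \code{query_name}, \code{query_begin}, \code{query_end},
#'   \code{query_left} (bases remaining on the contig, \code{NA} if the
#'   file omitted it), \code{strand} ("+" or "C"), \code{repeat_name},
#'   \code{repeat_class}, \code{cons_begin}, \code{cons_end},
#'   \code{cons_left}, \code{run_id}. Coordinates are 1-based inclusive as
#'   stored in the file.
#' @seealso \code{\link{writeRepeatMaskerOut}}, \code{\link{annotationsToBed}}
#' @export
readRepeatMaskerOut <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file))
    readLines(file) else unlist(strsplit(file, "\n"))
  # drop a 3-line banner header (first token not numeric) and blank lines
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  isHeader <- grepl("^\\s*(SW|score|bases)", lines)
  lineno <- lineno[!isHeader]
  lines <- lines[!isHeader]
  if (!length(lines)) return(.emptyAnnotations())
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) > 15L && f[length(f)] == "*") f <- f[-length(f)]
    if (length(f) < 15L)
      .stopf("malformed .out row at line %d: expected 15 fields, got %d",
             lineno[i], length(f))
    qb <- suppressWarnings(as.integer(f[6]))
    qe <- suppressWarnings(as.integer(f[7]))
    sw <- suppressWarnings(as.integer(f[1]))
    if (is.na(sw) || is.na(qb) || is.na(qe))
      .stopf("malformed .out row at line %d", lineno[i])
    if (qb < 0 || qe < 0 || qb > qe)
      .stopf("negative or inverted query interval at line %d", lineno[i])
    strand <- f[9]
    if (!strand %in% c("+", "C"))
      .stopf("bad strand '%s' at line %d", strand, lineno[i])
    if (strand == "+") {
      cb <- .stripParen(f[12]); ce <- .stripParen(f[13])
      cl <- .stripParen(f[14])
    } else {
      # C strand: (left) end begin
      cl <- .stripParen(f[12]); ce <- .stripParen(f[13])
      cb <- .stripParen(f[14])
    }
    if (any(is.na(c(cb, ce, cl))) || cb < 1L)
      .stopf("malformed consensus coordinates at line %d", lineno[i])
    data.frame(sw_score = sw, pct_div = as.numeric(f[2]),
               pct_del = as.numeric(f[3]), pct_ins = as.numeric(f[4]),
               query_name = f[5], query_begin = qb, query_end = qe,
               query_left = .stripParen(f[8]), strand = strand,
               repeat_name = f[10], repeat_class = f[11],
               cons_begin = cb, cons_end = ce, cons_left = cl,
               run_id = as.integer(f[15]), stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, rows)
  rownames(ann) <- NULL
  ann
}

#' Write annotations in RepeatMasker .out form
#'
#' Inverse of \code{\link{readRepeatMaskerOut}}: C-strand rows have their
#' consensus columns emitted as \code{(left) end begin}.
#'
#' @param ann annotation data.frame.
#' @param file output path, or \code{NULL} to return the lines.
#' @return invisibly, the text lines.
#' @export
writeRepeatMaskerOut <- function(ann, file = NULL) {
  lines <- vapply(seq_len(nrow(ann)), function(i) {
    a <- ann[i, ]
    qleft <- if (is.na(a$query_left)) "(0)" else sprintf("(%d)", a$query_left)
    cons <- if (a$strand == "+")
      sprintf("%d %d (%d)", a$cons_begin, a$cons_end, a$cons_left)
    else
      sprintf("(%d) %d %d", a$cons_left, a$cons_end, a$cons_begin)
    sprintf("%d %.1f %.1f %.1f %s %d %d %s %s %s %s %s %d",
            a$sw_score, a$pct_div, a$pct_del, a$pct_ins, a$query_name,
            a$query_begin, a$query_end, qleft, a$strand, a$repeat_name,
            a$repeat_class, cons, a$run_id)
  }, character(1))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Read a genome assembly or consensus library from FASTA
#'
#' Standard multi-record FASTA; sequences are uppercased and the header
#' token before the first whitespace becomes the id. Duplicate ids and
#' empty records are errors.
#'
#' @param file FASTA path.
#' @return a named \code{DNAStringSet}.
#' @importFrom Biostrings readDNAStringSet width
#' @export
readGenomeFasta <- function(file) {
  x <- readDNAStringSet(file)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    .stopf("duplicate sequence id: %s",
           names(x)[duplicated(names(x))][1])
  if (any(width(x) == 0L)) .stopf("empty FASTA record")
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Convert annotations to BED6 text
#'
#' BED uses 0-based half-open intervals: \code{query_begin - 1} becomes the
#' start and \code{query_end} the end. The score is the Smith-Waterman
#' score clamped to [0, 1000]; strand "C" maps to "-".
#'
#' @param ann annotation data.frame.
#' @return character vector of BED6 lines.
#' @export
annotationsToBed <- function(ann) {
  if (!nrow(ann)) return(character())
  sprintf("%s\t%d\t%d\t%s\t%d\t%s",
          ann$query_name, ann$query_begin - 1L, ann$query_end,
          ann$repeat_name, pmin(pmax(ann$sw_score, 0L), 1000L),
          ifelse(ann$strand == "C", "-", "+"))
}

#' Recover 1-based inclusive intervals from BED6 lines
#'
#' Inverse of the coordinate conversion in \code{\link{annotationsToBed}}.
#'
#' @param lines BED6 text lines.
#' @return data.frame with \code{query_name}, \code{query_begin},
#'   \code{query_end}, \code{repeat_name}, \code{sw_score}, \code{strand}.
#' @export
bedToIntervals <- function(lines) {
  if (!length(lines)) {
    return(data.frame(query_name = character(), query_begin = integer(),
                      query_end = integer(), repeat_name = character(),
                      sw_score = integer(), strand = character()))
  }
  f <- do.call(rbind, strsplit(lines, "\t"))
  data.frame(query_name = f[, 1], query_begin = as.integer(f[, 2]) + 1L,
             query_end = as.integer(f[, 3]), repeat_name = f[, 4],
             sw_score = as.integer(f[, 5]), strand = f[, 6],
             stringsAsFactors = FALSE)
}
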