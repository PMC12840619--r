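# Full-length filtering and flanked locus construction.

#' Filter annotations to full-length elements
#'
#' A copy is full length when its alignment starts within
#' \code{maxStartOffset} bp of the consensus 5' end (0-based offsets 0-4,
#' i.e. \code{cons_begin <= maxStartOffset + 1}) and reaches consensus
#' position \code{minEnd} or beyond. \code{minEnd} may be a single value or
#' a named vector per subfamily.
#'
#' @param ann annotation data.frame (caller restricts to the focal family,
#'   e.g. \code{repeat_class == "SINE/Platy"}).
#' @param consensusLengths named integer vector of consensus lengths; every
#'   \code{repeat_name} in \code{ann} must be present.
#' @param maxStartOffset maximum 0-based consensus start offset (default 4).
#' @param minEnd minimum consensus end position (default 103), optionally
#'   named per subfamily.
#' @return the retained rows, order preserved.
#' @export
filterFullLength <- function(ann, consensusLengths, maxStartOffset = 4,
                             minEnd = 103) {
  missing <- setdiff(unique(ann$repeat_name), names(consensusLengths))
  if (length(missing))
    .stopf("consensus length missing for: %s", paste(missing, collapse = ", "))
  if (!nrow(ann)) return(ann)
  minEndVec <- if (is.null(names(minEnd))) rep(minEnd, nrow(ann))
  else {
    v <- minEnd[ann$repeat_name]
    if (anyNA(v)) .stopf("minEnd missing for some subfamilies")
    v
  }
  keep <- (ann$cons_begin - 1L) <= maxStartOffset & ann$cons_end >= minEndVec
  ann[keep, , drop = FALSE]
}

#' Extract one flanked locus
#'
#' Slices the element plus up to \code{flank} bp on each side from its
#' contig; flanks are truncated at contig ends and the realized lengths
#' recorded. Loci with less than 50 bp of flank on either side are flagged
#' \code{short_flank} (they tend to genotype "?" downstream rather than
#' being dropped here).
#'
#' @param genome \code{DNAStringSet} containing the contig.
#' @param annotation one annotation row.
#' @param species species label recorded in the locus.
#' @param flank flank length in bp (default 500).
#' @param locusId id for the locus; default
#'   \code{<species>_<contig>_<begin>}.
#' @return a single-locus \linkS4class{LocusSet}.
#' @importFrom Biostrings subseq
#' @export
extractLocus <- function(genome, annotation, species = "genome",
                         flank = 500, locusId = NULL) {
  a <- annotation[1, ]
  if (!a$query_name %in% names(genome))
    .stopf("contig %s not in genome", a$query_name)
  contigLen <- length(genome[[a$query_name]])
  if (a$query_begin < 1L || a$query_end > contigLen)
    .stopf("interval [%d,%d] off contig %s (length %d)",
           a$query_begin, a$query_end, a$query_name, contigLen)
  fl <- min(flank, a$query_begin - 1L)
  fr <- min(flank, contigLen - a$query_end)
  seq <- as.character(subseq(genome[[a$query_name]],
                             a$query_begin - fl, a$query_end + fr))
  if (is.null(locusId))
    locusId <- sprintf("%s_%s_%d", species, a$query_name, a$query_begin)
  info <- data.frame(
    locus_id = locusId, species = species, contig = a$query_name,
    start = a$query_begin, end = a$query_end, strand = a$strand,
    subfamily = a$repeat_name, flank_left = fl, flank_right = fr,
    element_offset = fl, short_flank = fl < 50L || fr < 50L,
    stringsAsFactors = FALSE)
  new("LocusSet", info = info,
      seqs = Biostrings::DNAStringSet(stats::setNames(seq, locusId)))
}

#' Extract flanked loci for a set of annotations
#'
#' @param genome \code{DNAStringSet}.
#' @param ann annotation data.frame (typically the output of
#'   \code{\link{filterFullLength}}).
#' @inheritParams extractLocus
#' @return a \linkS4class{LocusSet}.
#' @export
extractLoci <- function(genome, ann, species = "genome", flank = 500) {
  if (!nrow(ann)) {
    info <- data.frame(locus_id = character(), species = character(),
                       contig = character(), start = integer(),
                       end = integer(), strand = character(),
                       subfamily = character(), flank_left = integer(),
                       flank_right = integer(), element_offset = integer(),
                       short_flank = logical(), stringsAsFactors = FALSE)
    return(new("LocusSet", info = info, seqs = Biostrings::DNAStringSet()))
  }
  parts <- lapply(seq_len(nrow(ann)), function(i)
    extractLocus(genome, ann[i, ], species, flank))
  info <- do.call(rbind, lapply(parts, locusInfo))
  rownames(info) <- NULL
  seqs <- do.call(c, lapply(parts, locusSeqs))
  new("LocusSet", info = info, seqs = seqs)
}

#' Combine LocusSets from several species
#'
#' @param ... \code{LocusSet} objects, or a single list of them.
#' @return one \linkS4class{LocusSet}; locus ids must be globally unique.
#' @export
combineLoci <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !is(parts[[1]], "LocusSet")) parts <- parts[[1]]
  info <- do.call(rbind, lapply(parts, locusInfo))
  rownames(info) <- NULL
  seqs <- do.call(c, unname(lapply(parts, locusSeqs)))
  new("LocusSet", info = info, seqs = seqs)
}

#' Write a LocusSet as FASTA plus a locus table
#'
#' @param loci a \code{LocusSet}.
#' @param fastaFile path for the flanked-sequence FASTA (id = locus id).
#' @param tableFile path for the locus-table TSV, or NULL to skip.
#' @return invisibly, the locus info table.
#' @export
writeLoci <- function(loci, fastaFile, tableFile = NULL) {
  Biostrings::writeXStringSet(locusSeqs(loci), fastaFile)
  if (!is.null(tableFile))
    utils::write.table(locusInfo(loci), tableFile, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(locusInfo(loci))
}
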