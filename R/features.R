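# TPRT hallmark detection on extracted loci: poly-A tail, target-site
# duplication (TSD), endonuclease cleavage motif, downstream TTTT
# termination signal. Loci are analyzed in element-sense orientation;
# reverse-strand loci are flipped first.

.locusParts <- function(locus, which = 1) {
  info <- locusInfo(locus)[which, ]
  seqChar <- as.character(locusSeqs(locus)[[which]])
  if (info$strand == "C") {
    seqChar <- .revcompChar(seqChar)
    fl <- info$flank_right; fr <- info$flank_left
  } else {
    fl <- info$flank_left; fr <- info$flank_right
  }
  Lel <- info$end - info$start + 1L
  list(seq = seqChar, flank_left = fl, flank_right = fr,
       elem_start = fl + 1L, elem_end = fl + Lel)
}

#' Measure the poly-A tail of a locus
#'
#' Starting at the element 3' end, extends rightward while the trailing
#' 10-base window stays at least 90 percent A and no run of more than
#' \code{maxNonA} consecutive non-A bases occurs; trailing non-A bases are
#' trimmed. Returns the extension length in bp.
#'
#' @param locus single-locus \code{LocusSet}.
#' @param which locus index (default 1).
#' @param window window size for the A-fraction rule.
#' @param minFrac minimum A fraction in the window.
#' @param maxNonA maximum tolerated run of consecutive non-A bases.
#' @return integer tail length (0 when no A follows the element).
#' @export
detectATail <- function(locus, which = 1, window = 10, minFrac = 0.9,
                        maxNonA = 2) {
  p <- .locusParts(locus, which)
  chars <- strsplit(substr(p$seq, p$elem_end + 1L, nchar(p$seq)), "")[[1]]
  if (!length(chars)) return(0L)
  isA <- chars == "A"
  run <- 0L
  ext <- 0L
  for (i in seq_along(chars)) {
    run <- if (isA[i]) 0L else run + 1L
    if (run > maxNonA) break
    lo <- max(1L, i - window + 1L)
    if (mean(isA[lo:i]) < minFrac) break
    ext <- i
  }
  while (ext > 0L && !isA[ext]) ext <- ext - 1L
  ext
}

#' Detect the target-site duplication of a locus
#'
#' Compares the 5' flank suffix (the left TSD copy) with the sequence
#' immediately after the poly-A tail (the right copy), reporting the
#' longest match of length in [\code{minLen}, \code{maxLen}] with at most
#' \code{maxMismatch} mismatches. Because a TSD beginning with adenines is
#' absorbed into the measured A-tail, the right-copy anchor is also tried
#' backed off by up to \code{tailBackoff} bases into the tail; the highest
#' scoring (length minus four per mismatch, ties to smaller backoff)
#' candidate wins. \code{precise} means zero mismatches.
#'
#' @param locus single-locus \code{LocusSet}.
#' @param aTailLength measured tail length (default: detect).
#' @param minLen,maxLen TSD length search range.
#' @param maxMismatch maximum mismatches tolerated.
#' @param tailBackoff how far the right-copy anchor may back into the tail.
#' @param which locus index.
#' @return list: \code{tsd} (character, "" when none), \code{length},
#'   \code{precise} (logical), \code{backoff} (bases of tail reclaimed).
#' @export
detectTSD <- function(locus, aTailLength = NULL, minLen = 6, maxLen = 25,
                      maxMismatch = 1, tailBackoff = 10, which = 1) {
  p <- .locusParts(locus, which)
  if (is.null(aTailLength)) aTailLength <- detectATail(locus, which)
  flank <- substr(p$seq, 1L, p$flank_left)
  if (nchar(flank) < maxLen) maxLen <- min(maxLen, nchar(flank))
  best <- NULL
  for (s in 0:min(tailBackoff, aTailLength)) {
    postStart <- p$elem_end + aTailLength - s + 1L
    post <- substr(p$seq, postStart, min(nchar(p$seq), postStart + maxLen - 1L))
    for (len in seq(min(maxLen, nchar(post)), minLen)) {
      a <- substr(flank, nchar(flank) - len + 1L, nchar(flank))
      b <- substr(post, 1L, len)
      if (nchar(a) < len) next
      mm <- .pMismatch(a, b)
      if (mm <= maxMismatch) {
        # mismatches are penalized heavily so that a marginally longer
        # imprecise candidate cannot displace an exact duplication
        score <- len - 4L * mm
        if (is.null(best) || score > best$score)
          best <- list(tsd = b, length = len, precise = mm == 0L,
                       backoff = s, score = score)
        break   # longest match at this backoff found
      }
    }
  }
  if (is.null(best)) return(list(tsd = "", length = 0L, precise = FALSE,
                                 backoff = 0L))
  best$score <- NULL
  best
}

#' Grade the endonuclease cleavage site of a locus
#'
#' Examines the 6 bp motif straddling the 5' TSD start -- four bases
#' upstream plus the first two TSD bases -- against the canonical
#' L1-endonuclease site TTTT|AA: \code{canonical} for an exact match,
#' \code{near} for at most one mismatch, \code{none} otherwise (or when no
#' TSD was found).
#'
#' @param locus single-locus \code{LocusSet}.
#' @param tsd result of \code{\link{detectTSD}} (default: detect).
#' @param which locus index.
#' @return "canonical", "near" or "none".
#' @export
detectCleavage <- function(locus, tsd = NULL, which = 1) {
  if (is.null(tsd)) tsd <- detectTSD(locus, which = which)
  if (tsd$length == 0L) return("none")
  p <- .locusParts(locus, which)
  tsdStart <- p$flank_left - tsd$length + 1L
  if (tsdStart <= 4L) return("none")
  motif <- paste0(substr(p$seq, tsdStart - 4L, tsdStart - 1L),
                  substr(p$seq, tsdStart, tsdStart + 1L))
  mm <- .pMismatch(motif, "TTTTAA")
  if (mm == 0L) "canonical" else if (mm <= 1L) "near" else "none"
}

#' Distance to the downstream TTTT termination signal
#'
#' Scans downstream of the 3' TSD for the nearest exact TTTT; the distance
#' is from the first base after the TSD to the first T of the motif
#' (0 when immediately adjacent).
#'
#' @param locus single-locus \code{LocusSet}.
#' @param tsd result of \code{\link{detectTSD}} (default: detect).
#' @param aTailLength measured tail length (default: detect).
#' @param scanLimit how far downstream to scan (default 200 bp).
#' @param which locus index.
#' @return integer distance, or \code{NA} if absent within the scan limit.
#' @export
findTermination <- function(locus, tsd = NULL, aTailLength = NULL,
                            scanLimit = 200, which = 1) {
  p <- .locusParts(locus, which)
  if (is.null(aTailLength)) aTailLength <- detectATail(locus, which)
  if (is.null(tsd)) tsd <- detectTSD(locus, aTailLength, which = which)
  if (tsd$length == 0L) return(NA_integer_)
  tsdEnd <- p$elem_end + aTailLength - tsd$backoff + tsd$length
  region <- substr(p$seq, tsdEnd + 1L,
                   min(nchar(p$seq), tsdEnd + scanLimit + 3L))
  hit <- regexpr("TTTT", region, fixed = TRUE)
  if (hit == -1L || hit > scanLimit + 1L) return(NA_integer_)
  as.integer(hit - 1L)
}

#' TPRT hallmark report for a locus set
#'
#' @param loci a \code{LocusSet}.
#' @param ... passed to the individual detectors.
#' @return data.frame: \code{locus_id}, \code{a_tail_length},
#'   \code{tsd}, \code{tsd_length}, \code{tsd_precise},
#'   \code{cleavage_match}, \code{termination_distance}.
#' @export
locusFeatures <- function(loci, ...) {
  info <- locusInfo(loci)
  rows <- lapply(seq_len(nrow(info)), function(i) {
    at <- detectATail(loci, which = i)
    ts <- detectTSD(loci, at, which = i, ...)
    data.frame(locus_id = info$locus_id[i], a_tail_length = at,
               tsd = ts$tsd, tsd_length = ts$length,
               tsd_precise = ts$precise,
               cleavage_match = detectCleavage(loci, ts, which = i),
               termination_distance = findTermination(loci, ts, at,
                                                      which = i),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(locus_id = character(), a_tail_length = integer(),
                      tsd = character(), tsd_length = integer(),
                      tsd_precise = logical(), cleavage_match = character(),
                      termination_distance = integer(),
                      stringsAsFactors = FALSE)
  out
}
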