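# Cross-genome presence/absence genotyping: seeded local alignment of each
# flanked locus against every target genome, then gap detection over the
# element span. The observable signature of an absent ~100 bp element is a
# locus-only gap of roughly element + A-tail + one TSD copy; the accepted
# gap window scales with element length rather than being a hard constant.

#' Genotyping thresholds
#'
#' @param minIdentity minimum flank identity per side.
#' @param minCoverage minimum flank coverage per side, measured over the
#'   proximal \code{anchorWindow} bp of each flank.
#' @param anchorWindow junction-adjacent flank window (bp) over which
#'   coverage is measured; distal flank rearrangements beyond it do not
#'   void the anchor.
#' @param minElementMatch fraction of the element span that must be aligned
#'   to target bases for a presence ("1") call.
#' @param gapMinFactor,gapMaxFactor accepted absence-gap window relative to
#'   element length L: [gapMinFactor * L, gapMaxFactor * (L + allowance)],
#'   where allowance is the larger of \code{maxATail} and the locus's own
#'   measured A-tail + 25 bp (the deletion at an absent site includes the
#'   element's tail and one TSD copy).
#' @param maxATail floor of the A-tail allowance in the gap window upper
#'   bound.
#' @param uniqueMargin best candidate window must score at least this
#'   factor above the runner-up, else the call is ambiguous.
#' @param match,mismatch,gapOpen,gapExtend affine local alignment scoring.
#' @return a list of thresholds for \code{\link{callGenotype}}.
#' @export
genotypeThresholds <- function(minIdentity = 0.85, minCoverage = 0.80,
                               anchorWindow = 150, minElementMatch = 0.80,
                               gapMinFactor = 0.6, gapMaxFactor = 1.3,
                               maxATail = 100, uniqueMargin = 1.1,
                               match = 1, mismatch = -1, gapOpen = 4,
                               gapExtend = 0.5) {
  list(minIdentity = minIdentity, minCoverage = minCoverage,
       anchorWindow = anchorWindow, minElementMatch = minElementMatch,
       gapMinFactor = gapMinFactor, gapMaxFactor = gapMaxFactor,
       maxATail = maxATail, uniqueMargin = uniqueMargin, match = match,
       mismatch = mismatch, gapOpen = gapOpen, gapExtend = gapExtend)
}

#' Find candidate target windows by two-flank k-mer seeding
#'
#' Exact k-mers sampled from both flanks are matched against the target
#' genome, projected back to an implied locus start, and clustered by
#' position; clusters with at least \code{minSeeds} seeds become windows
#' padded by \code{windowPad}. If no forward-strand cluster is found the
#' reverse complement of the locus is tried, mirroring the requirement
#' that both flanks anchor the orthologous site.
#'
#' @param locus single-locus \code{LocusSet} (or a row index into a larger
#'   set via \code{which}).
#' @param genome target \code{DNAStringSet}.
#' @param k seed length (default 14).
#' @param minSeeds minimum seeds per cluster (default 2).
#' @param windowPad padding added around the clustered span (default 600).
#' @param step spacing between sampled k-mer starts (default 7).
#' @param which locus index within \code{locus} (default 1).
#' @return data.frame of windows: \code{contig}, \code{start}, \code{end},
#'   \code{n_seeds}, \code{strand}, sorted by seed count descending.
#' @importFrom Biostrings PDict matchPDict startIndex
#' @export
findCandidateWindows <- function(locus, genome, k = 14, minSeeds = 2,
                                 windowPad = 600, step = 7, which = 1) {
  .findWindowsBatch(locus, genome, k = k, minSeeds = minSeeds,
                    windowPad = windowPad, step = step,
                    subset = which)[[1]]
}

# flank k-mer seeds of one locus sequence (filters ambiguous and
# low-complexity seeds: poly-A tails and simple repeats would otherwise
# seed spurious clusters genome-wide)
.locusSeeds <- function(seqChar, elemStart, elemEnd, k, step) {
  L <- nchar(seqChar)
  offs <- c(if (elemStart > k) seq(1L, elemStart - k, by = step),
            if (L - elemEnd >= k) seq(elemEnd + 1L, L - k + 1L, by = step))
  if (!length(offs)) return(NULL)
  kmers <- substring(seqChar, offs, offs + k - 1L)
  sp <- strsplit(kmers, "")
  nDistinct <- vapply(sp, function(x) length(unique(x)), integer(1))
  maxRun <- vapply(sp, function(x) max(rle(x)$lengths), integer(1))
  ok <- !grepl("[^ACGT]", kmers) & nDistinct >= 3L & maxRun < 8L
  if (!any(ok)) return(NULL)
  list(offs = offs[ok], kmers = kmers[ok])
}

# candidate windows for many loci against one genome in a single scan per
# contig (one combined PDict); per-locus reverse-complement fallback when a
# locus finds no forward cluster. Returns a list of window data.frames.
.findWindowsBatch <- function(loci, genome, k = 14, minSeeds = 2,
                              windowPad = 600, step = 7, subset = NULL) {
  info <- locusInfo(loci)
  idx <- if (is.null(subset)) seq_len(nrow(info)) else subset
  emptyWin <- data.frame(contig = character(), start = integer(),
                         end = integer(), n_seeds = integer(),
                         strand = character(), stringsAsFactors = FALSE)
  out <- rep(list(emptyWin), length(idx))
  names(out) <- info$locus_id[idx]
  seeds <- vector("list", length(idx))
  lens <- integer(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    seqChar <- as.character(locusSeqs(loci)[[i]])
    if (nchar(seqChar) < k) .stopf("locus shorter than k")
    lens[j] <- nchar(seqChar)
    elemStart <- info$flank_left[i] + 1L
    elemEnd <- info$flank_left[i] + (info$end[i] - info$start[i] + 1L)
    seeds[[j]] <- .locusSeeds(seqChar, elemStart, elemEnd, k, step)
  }
  nSeeds <- vapply(seeds, function(s) if (is.null(s)) 0L
                   else length(s$offs), integer(1))
  if (sum(nSeeds) > 0L) {
    allKmers <- unlist(lapply(seeds, `[[`, "kmers"))
    allOffs <- unlist(lapply(seeds, `[[`, "offs"))
    ofLocus <- rep(seq_along(idx), nSeeds)
    pd <- PDict(Biostrings::DNAStringSet(allKmers))
    for (ct in names(genome)) {
      m <- matchPDict(pd, genome[[ct]])
      st <- startIndex(m)
      nh <- vapply(st, function(x) if (is.null(x)) 0L else length(x),
                   integer(1))
      use <- nh > 0L & nh <= 25L   # overused seeds masked
      if (!any(use)) next
      proj <- unlist(st[use]) -
        rep(allOffs[use], nh[use]) + 1L
      locOf <- rep(ofLocus[use], nh[use])
      for (j in unique(locOf)) {
        hits <- proj[locOf == j]
        for (cl in .clusterPositions(hits, 500L)) {
          if (length(cl$positions) < minSeeds) next
          ws <- max(1L, min(cl$positions) - windowPad)
          we <- min(length(genome[[ct]]),
                    max(cl$positions) + lens[j] + windowPad)
          out[[j]] <- rbind(out[[j]], data.frame(
            contig = ct, start = ws, end = we,
            n_seeds = length(cl$positions), strand = "+",
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  ## reverse-complement fallback, locus by locus
  for (j in seq_along(idx)) {
    if (nrow(out[[j]])) {
      out[[j]] <- out[[j]][order(-out[[j]]$n_seeds), , drop = FALSE]
      rownames(out[[j]]) <- NULL
      next
    }
    i <- idx[j]
    seqChar <- .revcompChar(as.character(locusSeqs(loci)[[i]]))
    L <- nchar(seqChar)
    elemStart <- L - (info$flank_left[i] +
                        (info$end[i] - info$start[i] + 1L)) + 1L
    elemEnd <- L - info$flank_left[i]
    sd <- .locusSeeds(seqChar, elemStart, elemEnd, k, step)
    if (is.null(sd)) next
    pd <- PDict(Biostrings::DNAStringSet(sd$kmers))
    for (ct in names(genome)) {
      m <- matchPDict(pd, genome[[ct]])
      st <- startIndex(m)
      hits <- unlist(lapply(seq_along(st), function(q) {
        if (is.null(st[[q]]) || length(st[[q]]) > 25L) return(integer())
        st[[q]] - sd$offs[q] + 1L
      }))
      if (!length(hits)) next
      for (cl in .clusterPositions(hits, 500L)) {
        if (length(cl$positions) < minSeeds) next
        ws <- max(1L, min(cl$positions) - windowPad)
        we <- min(length(genome[[ct]]), max(cl$positions) + L + windowPad)
        out[[j]] <- rbind(out[[j]], data.frame(
          contig = ct, start = ws, end = we,
          n_seeds = length(cl$positions), strand = "-",
          stringsAsFactors = FALSE))
      }
    }
    if (nrow(out[[j]])) {
      out[[j]] <- out[[j]][order(-out[[j]]$n_seeds), , drop = FALSE]
      rownames(out[[j]]) <- NULL
    }
  }
  out
}

#' Align a locus against one candidate window
#'
#' Best local alignment under affine scoring; reports per-flank identity
#' and coverage, the aligned fraction of the element span, and the largest
#' locus-only gap (locus bases unmatched in the target) overlapping the
#' element span -- the absence signature.
#'
#' @param locus single-locus \code{LocusSet}.
#' @param windowSeq window sequence (character or \code{DNAString}).
#' @param thresholds scoring from \code{\link{genotypeThresholds}}.
#' @param strand "+" to align as is, "-" to align the reverse complement
#'   of the locus.
#' @param which locus index (default 1).
#' @return list: \code{score}, \code{ident_left}, \code{ident_right},
#'   \code{cov_left}, \code{cov_right}, \code{elem_aligned},
#'   \code{gap_len}, \code{gap_cover} (fraction of the element span inside
#'   the reported gap), \code{hit_start}, \code{hit_end} (window
#'   coordinates of the aligned subject range).
#' @importFrom Biostrings pairwiseAlignment alignedPattern alignedSubject
#' @export
alignLocus <- function(locus, windowSeq, thresholds = genotypeThresholds(),
                       strand = "+", which = 1) {
  info <- locusInfo(locus)[which, ]
  seqChar <- as.character(locusSeqs(locus)[[which]])
  L <- nchar(seqChar)
  elemStart <- info$flank_left + 1L
  elemEnd <- info$flank_left + (info$end - info$start + 1L)
  if (strand == "-") {
    seqChar <- .revcompChar(seqChar)
    es <- L - elemEnd + 1L; ee <- L - elemStart + 1L
    elemStart <- es; elemEnd <- ee
  }
  windowSeq <- as.character(windowSeq)
  if (nchar(windowSeq) < 2L * 14L) .stopf("window too short")
  localAlign <- function(p, s) pairwiseAlignment(
    Biostrings::DNAString(p), Biostrings::DNAString(s), type = "local",
    substitutionMatrix = .scoreMatrix(thresholds$match, thresholds$mismatch),
    gapOpening = thresholds$gapOpen, gapExtension = thresholds$gapExtend)
  colsOf <- function(al, patOff = 0L, subOff = 0L) {
    # as.character(pattern(al)) equals alignedPattern(al) here and avoids
    # its S4 construction overhead (hot path)
    pat <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
    list(pat = pat, sub = sub,
         # pattern/subject position at/before each column
         patPos = patOff + Biostrings::start(Biostrings::pattern(al)) - 1L +
           cumsum(pat != "-"),
         subPos = subOff + Biostrings::start(Biostrings::subject(al)) - 1L +
           cumsum(sub != "-"),
         patStart = patOff + Biostrings::start(Biostrings::pattern(al)),
         patEnd = patOff + Biostrings::end(Biostrings::pattern(al)),
         subStart = subOff + Biostrings::start(Biostrings::subject(al)),
         subEnd = subOff + Biostrings::end(Biostrings::subject(al)),
         score = Biostrings::score(al))
  }
  c1 <- colsOf(localAlign(seqChar, windowSeq))
  ## block stitching: a deletion larger than the affine penalty can bear
  ## truncates the local alignment on one side of the site; chain a second
  ## block over the remainder and record the implied locus-only net gap
  junction <- NULL
  blocks <- list(c1)
  if (c1$patEnd < elemEnd && c1$subEnd + 30L < nchar(windowSeq) &&
      c1$patEnd < L - 30L) {
    c2 <- colsOf(localAlign(substring(seqChar, c1$patEnd + 1L),
                            substring(windowSeq, c1$subEnd + 1L)),
                 patOff = c1$patEnd, subOff = c1$subEnd)
    if (c2$score >= 30) {
      blocks <- list(c1, c2)
      junction <- c(c1$patEnd, c2$patStart, c1$subEnd, c2$subStart)
    }
  } else if (c1$patStart > elemStart && c1$subStart > 30L &&
             c1$patStart > 30L) {
    c2 <- colsOf(localAlign(substr(seqChar, 1L, c1$patStart - 1L),
                            substr(windowSeq, 1L, c1$subStart - 1L)))
    if (c2$score >= 30) {
      blocks <- list(c2, c1)
      junction <- c(c2$patEnd, c1$patStart, c2$subEnd, c1$subStart)
    }
  }
  pat <- unlist(lapply(blocks, `[[`, "pat"))
  sub <- unlist(lapply(blocks, `[[`, "sub"))
  patPos <- unlist(lapply(blocks, `[[`, "patPos"))
  subPos <- unlist(lapply(blocks, `[[`, "subPos"))
  isBase <- pat != "-" & sub != "-"
  isMatch <- isBase & pat == sub
  inLeft <- patPos < elemStart & pat != "-"
  inRight <- patPos > elemEnd & pat != "-"
  inElem <- patPos >= elemStart & patPos <= elemEnd & pat != "-"
  flankLeftLen <- elemStart - 1L
  flankRightLen <- L - elemEnd
  identity <- function(sel) {
    n <- sum(sel & isBase)
    if (n == 0) 0 else sum(sel & isMatch) / n
  }
  elemAligned <- if (elemEnd < elemStart) 0 else
    sum(inElem & isBase) / (elemEnd - elemStart + 1L)
  ## locus-only gap runs (subject '-') overlapping the element span;
  ## runs split by short spuriously aligned islands are coalesced, so the
  ## reported gap is the total locus-only extent over the element region
  gapLen <- 0L
  gapCover <- 0
  elemLen <- elemEnd - elemStart + 1L
  covered <- 0L
  inStructGap <- logical(L)  # pattern positions in structural (>=30 bp)
                             # locus-only gaps
  r <- rle(sub == "-")
  if (any(r$values)) {
    endIdx <- cumsum(r$lengths)
    startIdx <- endIdx - r$lengths + 1L
    for (j in which(r$values)) {
      cols <- startIdx[j]:endIdx[j]
      p1 <- min(patPos[cols]); p2 <- max(patPos[cols])
      ov <- min(p2, elemEnd) - max(p1, elemStart) + 1L
      if (ov > 0) {
        gapLen <- gapLen + r$lengths[j]
        covered <- covered + ov
      }
      if (r$lengths[j] >= 30L) inStructGap[p1:p2] <- TRUE
    }
  }
  if (!is.null(junction)) {
    # locus bases and target bases skipped between the stitched blocks
    jp <- junction[2] - junction[1] - 1L
    js <- junction[4] - junction[3] - 1L
    net <- jp - js
    ov <- min(junction[2] - 1L, elemEnd) - max(junction[1] + 1L, elemStart) + 1L
    if (net > 0L && ov > 0L) {
      gapLen <- gapLen + net
      covered <- covered + ov
    }
    if (net >= 30L && junction[1] + 1L <= junction[2] - 1L)
      inStructGap[(junction[1] + 1L):(junction[2] - 1L)] <- TRUE
  }
  gapCover <- min(1, covered / elemLen)
  ## coverage is judged on the proximal (junction-adjacent) flank window
  ## or the whole flank, whichever is higher: a distal structural change
  ## (e.g. a neighboring polymorphic element) must not void the anchor.
  ## Flank positions inside structural locus-only gaps are excluded from
  ## the denominator -- at an absent site the element's own A-tail and TSD
  ## at the start of the right flank (or an absent neighboring insertion
  ## anywhere in the flank) are legitimately missing from the target.
  ## The denominator floor keeps a few high-identity islands from passing
  ## as an anchored flank.
  aw <- thresholds$anchorWindow
  awL <- min(aw, flankLeftLen); awR <- min(aw, flankRightLen)
  proxL <- patPos >= elemStart - awL & patPos < elemStart & pat != "-"
  proxR <- patPos > elemEnd & patPos <= elemEnd + awR & pat != "-"
  coverage <- function(selNum, lo, hi) {
    denom <- max(40L, (hi - lo + 1L) - sum(inStructGap[lo:hi]))
    min(1, sum(selNum & isBase) / denom)
  }
  covLeft <- if (awL == 0) 0 else
    max(coverage(proxL, elemStart - awL, elemStart - 1L),
        coverage(inLeft, 1L, elemStart - 1L))
  covRight <- if (awR == 0) 0 else
    max(coverage(proxR, elemEnd + 1L, elemEnd + awR),
        coverage(inRight, elemEnd + 1L, L))
  ## projected element interval in subject coordinates (for duplicate
  ## merging across ascertainment species)
  elemCols <- inElem & isBase
  list(score = sum(vapply(blocks, `[[`, numeric(1), "score")),
       ident_left = identity(inLeft), ident_right = identity(inRight),
       cov_left = covLeft, cov_right = covRight,
       elem_aligned = elemAligned, gap_len = gapLen, gap_cover = gapCover,
       hit_start = blocks[[1]]$subStart,
       hit_end = blocks[[length(blocks)]]$subEnd,
       elem_hit_start = if (any(elemCols)) min(subPos[elemCols])
                        else NA_integer_,
       elem_hit_end = if (any(elemCols)) max(subPos[elemCols])
                      else NA_integer_)
}

#' Call one genotype from window alignments
#'
#' Code "1" when both flanks align (coverage and identity met) and most of
#' the element span is matched; "0" when both flanks align and the element
#' span is covered by a locus-only gap inside the accepted window; "?"
#' otherwise, with a machine-readable reason (no hit, one-flank-only,
#' ambiguous multi-hit, short-flank locus, gap outside window, low
#' identity). Ambiguities are flagged, never silently resolved.
#'
#' @param locus single-locus \code{LocusSet}.
#' @param alignments list of results from \code{\link{alignLocus}}, one per
#'   candidate window (may be empty).
#' @param thresholds from \code{\link{genotypeThresholds}}.
#' @param which locus index (default 1).
#' @return one-row data.frame: \code{code}, \code{reason}, evidence fields.
#' @export
callGenotype <- function(locus, alignments,
                         thresholds = genotypeThresholds(), which = 1) {
  info <- locusInfo(locus)[which, ]
  Lel <- info$end - info$start + 1L
  res <- function(code, reason = NA_character_, al = NULL) {
    g <- function(f, miss) if (is.null(al) || is.null(al[[f]])) miss
    else al[[f]]
    data.frame(locus_id = info$locus_id, code = code, reason = reason,
               score = g("score", NA_real_),
               ident_left = g("ident_left", NA_real_),
               ident_right = g("ident_right", NA_real_),
               gap_len = g("gap_len", NA_integer_),
               hit_start = g("hit_start", NA_integer_),
               hit_end = g("hit_end", NA_integer_),
               elem_hit_start = g("elem_hit_start", NA_integer_),
               elem_hit_end = g("elem_hit_end", NA_integer_),
               stringsAsFactors = FALSE)
  }
  if (!length(alignments)) return(res("?", "no hit"))
  ## the deletion at an absent site is element + its own A-tail + one TSD
  ## copy; the locus carries its tail, so the window upper bound scales
  ## with the measured tail (maxATail acts as a floor allowance)
  tailAllow <- max(thresholds$maxATail,
                   detectATail(locus, which = which) + 25L)
  gapMax <- thresholds$gapMaxFactor * (Lel + tailAllow)
  scores <- vapply(alignments, `[[`, numeric(1), "score")
  o <- order(-scores)
  best <- alignments[[o[1]]]
  if (length(alignments) >= 2L &&
      scores[o[1]] < thresholds$uniqueMargin * scores[o[2]])
    return(res("?", "ambiguous multi-hit", best))
  if (info$short_flank) return(res("?", "short flank", best))
  okL <- best$ident_left >= thresholds$minIdentity &&
    best$cov_left >= thresholds$minCoverage
  okR <- best$ident_right >= thresholds$minIdentity &&
    best$cov_right >= thresholds$minCoverage
  if (okL && okR) {
    if (best$elem_aligned >= thresholds$minElementMatch)
      return(res("1", NA_character_, best))
    gapMin <- thresholds$gapMinFactor * Lel
    if (best$gap_cover >= 0.8 &&
        best$gap_len >= gapMin && best$gap_len <= gapMax)
      return(res("0", NA_character_, best))
    if (best$gap_cover >= 0.8)
      return(res("?", "gap outside window", best))
    return(res("?", "element partially aligned", best))
  }
  ## a target-side deletion engulfing the site: flank identity holds on
  ## the surviving aligned parts, the element span sits in one oversized
  ## locus-only gap, but proximal flank coverage is gone
  if (best$ident_left >= thresholds$minIdentity &&
      best$ident_right >= thresholds$minIdentity &&
      best$gap_cover >= 0.8 &&
      best$gap_len > gapMax)
    return(res("?", "gap outside window", best))
  if (xor(okL, okR)) return(res("?", "one-flank-only hit", best))
  res("?", "low identity", best)
}

# genotype one locus against one target genome given candidate windows
.genotypeOne <- function(locus, genome, thresholds, k = 14, minSeeds = 2,
                         windowPad = 600, which = 1, win = NULL) {
  if (is.null(win))
    win <- findCandidateWindows(locus, genome, k = k, minSeeds = minSeeds,
                                windowPad = windowPad, which = which)
  win <- utils::head(win, 6L)   # at most a few windows examined
  als <- lapply(seq_len(nrow(win)), function(i) {
    ws <- Biostrings::subseq(genome[[win$contig[i]]], win$start[i],
                             win$end[i])
    al <- alignLocus(locus, ws, thresholds, strand = win$strand[i],
                     which = which)
    al$hit_start <- al$hit_start + win$start[i] - 1L
    al$hit_end <- al$hit_end + win$start[i] - 1L
    if (!is.na(al$elem_hit_start)) {
      al$elem_hit_start <- al$elem_hit_start + win$start[i] - 1L
      al$elem_hit_end <- al$elem_hit_end + win$start[i] - 1L
    }
    al$contig <- win$contig[i]
    al
  })
  call <- callGenotype(locus, als, thresholds, which = which)
  call$contig <- if (length(als)) {
    scores <- vapply(als, `[[`, numeric(1), "score")
    als[[which.max(scores)]]$contig
  } else NA_character_
  call
}

#' Build a genotype matrix across species
#'
#' Genotypes every locus against every target genome (the source species is
#' recorded as "1" with its own coordinates as evidence), then merges
#' reciprocal duplicates: records of the same insertion ascertained from
#' two species are collapsed when each record's presence-call interval in
#' the other source genome overlaps the other record's element interval.
#' Code precedence within a merged row is 1 > 0 > ?.
#'
#' @param loci \code{LocusSet} combining loci from all source species.
#' @param genomes named list of \code{DNAStringSet}, one per species; the
#'   names define the matrix columns.
#' @param thresholds from \code{\link{genotypeThresholds}}.
#' @param k,minSeeds,windowPad seeding parameters, see
#'   \code{\link{findCandidateWindows}}.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
buildGenotypeMatrix <- function(loci, genomes,
                                thresholds = genotypeThresholds(),
                                k = 14, minSeeds = 2, windowPad = 600) {
  species <- names(genomes)
  info <- locusInfo(loci)
  n <- nrow(info)
  if (anyDuplicated(info$locus_id)) .stopf("locus ids must be unique")
  if (!n) {
    return(new("GenotypeMatrix",
               codes = matrix(character(), 0, length(species),
                              dimnames = list(NULL, species)),
               evidence = data.frame(), source = character(),
               members = list()))
  }
  evid <- vector("list", n * length(species))
  codes <- matrix("?", n, length(species),
                  dimnames = list(info$locus_id, species))
  idx <- 0L
  for (sp in species) {
    foreign <- which(info$species != sp)
    wins <- if (length(foreign))
      .findWindowsBatch(loci, genomes[[sp]], k = k, minSeeds = minSeeds,
                        windowPad = windowPad, subset = foreign)
    else list()
    for (i in seq_len(n)) {
      idx <- idx + 1L
      if (sp == info$species[i]) {
        row <- data.frame(locus_id = info$locus_id[i], code = "1",
                          reason = NA_character_, score = NA_real_,
                          ident_left = 1, ident_right = 1,
                          gap_len = NA_integer_, hit_start = info$start[i],
                          hit_end = info$end[i],
                          elem_hit_start = info$start[i],
                          elem_hit_end = info$end[i],
                          contig = info$contig[i],
                          stringsAsFactors = FALSE)
      } else {
        row <- .genotypeOne(loci, genomes[[sp]], thresholds, k, minSeeds,
                            windowPad, which = i,
                            win = wins[[match(i, foreign)]])
      }
      row$species <- sp
      codes[i, sp] <- row$code
      evid[[idx]] <- row
    }
  }
  evidence <- do.call(rbind, evid)
  ## merge reciprocal duplicates across source species
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  ev1 <- evidence[evidence$code == "1", ]
  evKey <- paste(ev1$locus_id, ev1$species)
  evIdx <- match(unique(evKey), evKey)
  lookup <- stats::setNames(evIdx, unique(evKey))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i || info$species[i] == info$species[j]) next
      ki <- lookup[paste(info$locus_id[i], info$species[j])]
      kj <- lookup[paste(info$locus_id[j], info$species[i])]
      if (is.na(ki) || is.na(kj)) next
      eij <- ev1[ki, ]; eji <- ev1[kj, ]
      # the projected element interval (not the whole aligned footprint)
      # must cross-map onto the other record's element interval
      ovij <- !is.na(eij$elem_hit_start) && !is.na(eij$contig) &&
        eij$contig == info$contig[j] &&
        eij$elem_hit_start <= info$end[j] &&
        eij$elem_hit_end >= info$start[j]
      ovji <- !is.na(eji$elem_hit_start) && !is.na(eji$contig) &&
        eji$contig == info$contig[i] &&
        eji$elem_hit_start <= info$end[i] &&
        eji$elem_hit_end >= info$start[i]
      if (ovij && ovji) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  keep <- sort(unique(roots))
  mcodes <- matrix("?", length(keep), length(species),
                   dimnames = list(info$locus_id[keep], species))
  members <- list()
  prec <- c("1" = 3L, "0" = 2L, "?" = 1L)
  for (r in seq_along(keep)) {
    grp <- which(roots == keep[r])
    members[[info$locus_id[keep[r]]]] <- info$locus_id[grp]
    for (sp in species) {
      cds <- codes[grp, sp]
      # the member ascertained from sp (if any) is authoritative
      own <- grp[info$species[grp] == sp]
      mcodes[r, sp] <- if (length(own)) "1"
      else cds[which.max(prec[cds])]
    }
  }
  new("GenotypeMatrix", codes = mcodes, evidence = evidence,
      source = stats::setNames(info$species[keep], info$locus_id[keep]),
      members = members)
}

#' Write a genotype matrix as TSV and NEXUS
#'
#' @param gm a \code{GenotypeMatrix}.
#' @param tsvFile TSV path (loci rows, species columns) or NULL.
#' @param nexusFile NEXUS binary-matrix path ("?" = missing) or NULL.
#' @return invisibly, the code matrix.
#' @export
writeGenotypeMatrix <- function(gm, tsvFile = NULL, nexusFile = NULL) {
  codes <- genotypeCodes(gm)
  if (!is.null(tsvFile)) {
    df <- data.frame(locus_id = rownames(codes), codes, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, tsvFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(nexusFile)) {
    sp <- colnames(codes)
    lines <- c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(sp),
                       nrow(codes)),
               "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
               "  MATRIX")
    for (s in sp)
      lines <- c(lines, sprintf("    %s %s", s,
                                paste(codes[, s], collapse = "")))
    lines <- c(lines, "  ;", "END;")
    writeLines(lines, nexusFile)
  }
  invisible(codes)
}
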