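# Subfamily assignment against a consensus library, discovery of new
# subfamilies from lineage-specific copies via co-segregating diagnostic
# substitutions, and library-augmentation score deltas.
#
# Alignment scores use a simple affine scheme (match +1, mismatch -1, gap
# open -4, gap extend -0.5) scaled x10 for integer reporting: only score
# differences and rankings are meaningful, never cross-tool score identity.

#' Assign an element to its best-matching subfamily
#'
#' Local affine alignment against every library consensus; the best score
#' wins, with ties broken by lower percent divergence and then library
#' order. Percent divergence is the p-distance (x100) over aligned,
#' non-gap columns of the winning alignment.
#'
#' @param element element sequence (character or \code{DNAString}).
#' @param library named \code{DNAStringSet} of consensi.
#' @param match,mismatch,gapOpen,gapExtend scoring parameters.
#' @return one-row data.frame: \code{subfamily}, \code{sw_score} (x10
#'   integer), \code{pct_div}, \code{align_length}.
#' @export
assignSubfamily <- function(element, library, match = 1, mismatch = -1,
                            gapOpen = 4, gapExtend = 0.5) {
  if (!length(library)) .stopf("empty consensus library")
  element <- as.character(element)
  if (!nchar(element)) .stopf("empty element sequence")
  stats <- lapply(seq_along(library), function(i) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(element),
      Biostrings::DNAString(as.character(library[[i]])),
      type = "local", substitutionMatrix = .scoreMatrix(match, mismatch),
      gapOpening = gapOpen, gapExtension = gapExtend)
    pat <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
    isBase <- pat != "-" & sub != "-"
    n <- sum(isBase)
    mm <- sum(isBase & pat != sub)
    list(score = as.integer(round(Biostrings::score(al) * 10)),
         pct_div = if (n) 100 * mm / n else 100, n = n)
  })
  sc <- vapply(stats, `[[`, numeric(1), "score")
  pd <- vapply(stats, `[[`, numeric(1), "pct_div")
  ord <- order(-sc, pd, seq_along(library))
  i <- ord[1]
  data.frame(subfamily = names(library)[i], sw_score = as.integer(sc[i]),
             pct_div = pd[i], align_length = stats[[i]]$n,
             stringsAsFactors = FALSE)
}

#' Assign many elements
#'
#' @param elements named \code{DNAStringSet}.
#' @inheritParams assignSubfamily
#' @return data.frame with one row per element (\code{element_id} first).
#' @export
assignSubfamilies <- function(elements, library, ...) {
  rows <- lapply(seq_along(elements), function(i)
    cbind(data.frame(element_id = names(elements)[i],
                     stringsAsFactors = FALSE),
          assignSubfamily(elements[[i]], library, ...)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score deltas after library augmentation
#'
#' Per-element change in alignment score and percent divergence between an
#' old and a new (augmented) library: \code{delta_sw = new - old} and
#' \code{delta_pct_div = old - new}, so positive values mean improvement
#' under the new library.
#'
#' @param elements named \code{DNAStringSet}.
#' @param oldLibrary,newLibrary consensus \code{DNAStringSet}s.
#' @param ... scoring parameters passed through.
#' @return list: \code{per_element} data.frame and \code{summary} with
#'   mean and sample sd of each delta.
#' @export
reassignmentDelta <- function(elements, oldLibrary, newLibrary, ...) {
  old <- assignSubfamilies(elements, oldLibrary, ...)
  new <- assignSubfamilies(elements, newLibrary, ...)
  per <- data.frame(element_id = old$element_id,
                    old_subfamily = old$subfamily,
                    new_subfamily = new$subfamily,
                    delta_sw = new$sw_score - old$sw_score,
                    delta_pct_div = old$pct_div - new$pct_div,
                    stringsAsFactors = FALSE)
  list(per_element = per,
       summary = data.frame(
         mean_delta_sw = mean(per$delta_sw),
         sd_delta_sw = stats::sd(per$delta_sw),
         mean_delta_pct_div = mean(per$delta_pct_div),
         sd_delta_pct_div = stats::sd(per$delta_pct_div)))
}

# project each element onto consensus columns via pairwise global
# alignment; returns a character matrix (elements x consensus positions,
# "-" where the element has no base)
.projectOnConsensus <- function(elements, consensus) {
  consensus <- as.character(consensus)
  L <- nchar(consensus)
  M <- matrix("-", length(elements), L,
              dimnames = list(names(elements), NULL))
  for (i in seq_along(elements)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(as.character(elements[[i]])),
      Biostrings::DNAString(consensus), type = "global",
      substitutionMatrix = .scoreMatrix(), gapOpening = 4,
      gapExtension = 0.5)
    pat <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
    sub <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
    cpos <- 0L
    for (j in seq_along(sub)) {
      if (sub[j] != "-") {
        cpos <- cpos + 1L
        if (pat[j] != "-") M[i, cpos] <- pat[j]
      }
    }
  }
  M
}

#' Discover subfamilies from lineage-specific copies
#'
#' A greedy co-segregating-diagnostic search in the spirit of COSEG: each
#' element is anchor-aligned to the parent consensus, exact consensus
#' matches are eliminated, candidate diagnostics are (position, derived
#' base) pairs carried by at least \code{minCount} elements, and the pair
#' of diagnostics with the largest joint carrier set (exceeding the
#' independence expectation) founds a subfamily. The diagnostic set is
#' greedily extended while the joint carrier set stays at or above
#' \code{minCount}; members are the carriers of all selected diagnostics,
#' the subfamily consensus is the column majority over members, members are
#' removed, and the search repeats. Models are named sf0, sf1, ... by
#' descending member count.
#'
#' @param elements named \code{DNAStringSet} of lineage-specific copies.
#' @param parentConsensus parent subfamily consensus.
#' @param minCount minimum members per subfamily (default 10).
#' @param minDiag minimum diagnostics per subfamily (default 2).
#' @return list of subfamily models, each a list with \code{name},
#'   \code{consensus}, \code{diagnostics} (data.frame \code{pos},
#'   \code{ancestral}, \code{derived}), \code{members}, \code{parent}.
#'   Empty list when fewer than \code{minCount} elements qualify.
#' @export
discoverSubfamilies <- function(elements, parentConsensus, minCount = 10,
                                minDiag = 2) {
  parentConsensus <- as.character(parentConsensus)
  if (length(elements) < minCount) return(list())
  M <- .projectOnConsensus(elements, parentConsensus)
  consChars <- strsplit(parentConsensus, "")[[1]]
  ## eliminate exact consensus matches
  exact <- vapply(seq_len(nrow(M)), function(i)
    all(M[i, ] == consChars), logical(1))
  M <- M[!exact, , drop = FALSE]
  models <- list()
  while (nrow(M) >= minCount) {
    ## candidate diagnostics: derived states carried by >= minCount rows
    cand <- list()
    for (p in seq_len(ncol(M))) {
      col <- M[, p]
      tab <- table(col[col %in% c("A", "C", "G", "T") &
                         col != consChars[p]])
      for (b in names(tab)[tab >= minCount])
        cand[[length(cand) + 1L]] <- list(pos = p, base = b,
                                          carriers = which(col == b))
    }
    if (length(cand) < minDiag) break
    nc <- length(cand)
    sizes <- vapply(cand, function(x) length(x$carriers), integer(1))
    ## best pair by joint carrier count, requiring co-occurrence above the
    ## independence expectation
    bestPair <- NULL; bestJoint <- -1L
    ord <- order(-sizes)
    for (ii in seq_len(nc - 1L)) {
      a <- ord[ii]
      if (sizes[a] <= bestJoint) break
      for (jj in (ii + 1L):nc) {
        b <- ord[jj]
        if (cand[[a]]$pos == cand[[b]]$pos) next
        joint <- length(intersect(cand[[a]]$carriers, cand[[b]]$carriers))
        expect <- sizes[a] * sizes[b] / nrow(M)
        if (joint >= minCount && joint > expect && joint > bestJoint) {
          bestJoint <- joint
          bestPair <- c(a, b)
        }
      }
    }
    if (is.null(bestPair)) break
    sel <- bestPair
    members <- intersect(cand[[sel[1]]]$carriers, cand[[sel[2]]]$carriers)
    ## greedy extension: keep adding the diagnostic that best preserves
    ## the member set
    repeat {
      bestAdd <- NULL; bestKeep <- -1L
      for (a in seq_len(nc)) {
        if (a %in% sel) next
        if (any(vapply(sel, function(s) cand[[s]]$pos == cand[[a]]$pos,
                       logical(1)))) next
        keep <- length(intersect(members, cand[[a]]$carriers))
        if (keep >= minCount && keep >= 0.9 * length(members) &&
            keep > bestKeep) {
          bestKeep <- keep; bestAdd <- a
        }
      }
      if (is.null(bestAdd)) break
      sel <- c(sel, bestAdd)
      members <- intersect(members, cand[[bestAdd]]$carriers)
    }
    ## consensus = column majority over members
    newCons <- consChars
    for (p in seq_len(ncol(M))) {
      col <- M[members, p]
      col <- col[col %in% c("A", "C", "G", "T")]
      if (length(col)) {
        tab <- sort(table(col), decreasing = TRUE)
        newCons[p] <- names(tab)[1]
      }
    }
    diag <- do.call(rbind, lapply(sel, function(s) data.frame(
      pos = cand[[s]]$pos, ancestral = consChars[cand[[s]]$pos],
      derived = cand[[s]]$base, stringsAsFactors = FALSE)))
    diag <- diag[order(diag$pos), , drop = FALSE]
    ## keep only diagnostics realized in the majority consensus
    diag <- diag[newCons[diag$pos] == diag$derived, , drop = FALSE]
    if (nrow(diag) < minDiag) break
    ## final membership tolerates one back-mutated diagnostic when three
    ## or more were selected (background divergence hits diagnostic sites
    ## too; requiring all of them would silently shed true members)
    need <- max(2L, nrow(diag) - 1L)
    carried <- vapply(seq_len(nrow(M)), function(i)
      sum(M[i, diag$pos] == diag$derived), integer(1))
    members <- which(carried >= need)
    if (length(members) < minCount) break
    models[[length(models) + 1L]] <- list(
      consensus = paste(newCons, collapse = ""),
      diagnostics = diag, members = rownames(M)[members],
      parent = "parent")
    M <- M[-members, , drop = FALSE]
  }
  if (!length(models)) return(list())
  ## name sf0, sf1, ... by descending member count
  ord <- order(-vapply(models, function(m) length(m$members), integer(1)))
  models <- models[ord]
  for (i in seq_along(models)) models[[i]]$name <- sprintf("sf%d", i - 1L)
  models
}
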