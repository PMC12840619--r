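# Repeat-landscape statistics: nearest-neighbor proximity, per-class genome
# content, divergence histograms, nested intra-repeat detection.

#' Proximity of focal elements to other repeat classes
#'
#' For each repeat class, the count and percentage of focal elements whose
#' nearest same-contig annotation of that class lies within \code{D} bp.
#' The distance between intervals is the number of bases strictly between
#' them (overlap = 0); \code{D} is inclusive, so a 50 bp gap counts at the
#' default. Raw rows are used with self-exclusion (an element is never its
#' own neighbor).
#'
#' @param focal focal annotation data.frame (e.g. the SINE family rows).
#' @param ann all annotations (may include the focal rows).
#' @param D distance cutoff in bp (default 50).
#' @return data.frame per class: \code{class}, \code{count}, \code{pct}
#'   (over the focal total), plus attribute \code{n_focal}.
#' @importFrom IRanges IRanges countOverlaps
#' @export
proximityWithin <- function(focal, ann, D = 50) {
  classes <- sort(unique(ann$repeat_class))
  nf <- nrow(focal)
  fkey <- paste(focal$query_name, focal$query_begin, focal$query_end,
                focal$repeat_name)
  akey <- paste(ann$query_name, ann$query_begin, ann$query_end,
                ann$repeat_name)
  out <- lapply(classes, function(cl) {
    hit <- logical(nf)
    sub <- ann[ann$repeat_class == cl, ]
    skey <- akey[ann$repeat_class == cl]
    for (ct in unique(focal$query_name)) {
      fi <- which(focal$query_name == ct)
      si <- which(sub$query_name == ct)
      if (!length(fi) || !length(si)) next
      fr <- IRanges(focal$query_begin[fi], focal$query_end[fi])
      sr <- IRanges(sub$query_begin[si], sub$query_end[si])
      cnt <- countOverlaps(fr, sr, maxgap = D)
      # self-exclusion: subtract the focal row itself when it is in `sub`
      self <- fkey[fi] %in% skey[si]
      hit[fi] <- (cnt - as.integer(self)) > 0L
    }
    data.frame(class = cl, count = sum(hit),
               pct = if (nf) 100 * sum(hit) / nf else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "n_focal") <- nf
  attr(out, "D") <- D
  out
}

#' Per-class repeat content as percent of genome
#'
#' Same-class overlapping intervals are merged before counting; classes
#' are measured independently, so cross-class overlaps count for each.
#'
#' @param ann annotation data.frame.
#' @param genomeSizes named integer vector contig -> length, or a single
#'   total genome size.
#' @return data.frame: \code{class}, \code{bp}, \code{pct}.
#' @importFrom IRanges reduce width
#' @export
genomeRepeatContent <- function(ann, genomeSizes) {
  total <- sum(genomeSizes)
  classes <- sort(unique(ann$repeat_class))
  out <- lapply(classes, function(cl) {
    sub <- ann[ann$repeat_class == cl, ]
    bp <- 0L
    for (ct in unique(sub$query_name)) {
      si <- sub$query_name == ct
      bp <- bp + sum(width(reduce(IRanges(sub$query_begin[si],
                                          sub$query_end[si]))))
    }
    data.frame(class = cl, bp = bp,
               pct = if (total > 0) 100 * bp / total else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(class = character(), bp = integer(),
                                      pct = numeric())
  out
}

#' Divergence histogram per repeat class
#'
#' Bins the \code{pct_div} column; each element contributes its interval
#' length in bp (or 1 when count-weighted) to bin
#' \code{floor(pct_div / bin)}. Bins are labeled by their left edge.
#'
#' @param ann annotation data.frame.
#' @param bin bin width in percent (default 1).
#' @param weight "bp" or "count".
#' @return data.frame: \code{class}, \code{bin} (left edge), \code{value}.
#' @export
divergenceHistogram <- function(ann, bin = 1.0, weight = c("bp", "count")) {
  weight <- match.arg(weight)
  if (bin <= 0) .stopf("bin width must be > 0")
  if (!nrow(ann))
    return(data.frame(class = character(), bin = numeric(),
                      value = numeric()))
  w <- if (weight == "bp") ann$query_end - ann$query_begin + 1L
  else rep(1L, nrow(ann))
  edge <- floor(ann$pct_div / bin) * bin
  agg <- stats::aggregate(w, by = list(class = ann$repeat_class, bin = edge),
                          FUN = sum)
  names(agg)[3] <- "value"
  agg[order(agg$class, agg$bin), , drop = FALSE]
}

#' Detect nested intra-repeat insertions
#'
#' Primary rule (fragment-run evidence): a focal element is nested when the
#' annotations immediately flanking it on the contig share one run id and
#' repeat name, and the downstream fragment's consensus start continues
#' from the upstream fragment's consensus end within \code{tol} bp.
#' Fallback rule: the focal interval lies strictly inside a single host
#' annotation. The host class is reported as Alu, L1 or other, and the
#' focal element's position on the host consensus is the upstream
#' fragment's consensus end.
#'
#' @param ann all annotations, including the focal rows.
#' @param focalClass repeat class of the focal elements (default
#'   "SINE/Platy").
#' @param tol consensus-continuity tolerance in bp (default 20).
#' @return data.frame: one row per nested focal element with columns
#'   \code{locus_key} (contig:begin-end), \code{query_name},
#'   \code{query_begin}, \code{query_end}, \code{repeat_name},
#'   \code{host_class} (Alu/L1/other), \code{host_name}, \code{mode}
#'   ("run_id-adjacency" or "containment"), \code{host_cons_pos}.
#' @export
detectNested <- function(ann, focalClass = "SINE/Platy", tol = 20) {
  empty <- data.frame(locus_key = character(), query_name = character(),
                      query_begin = integer(), query_end = integer(),
                      repeat_name = character(), host_class = character(),
                      host_name = character(), mode = character(),
                      host_cons_pos = integer(), stringsAsFactors = FALSE)
  if (!nrow(ann)) return(empty)
  hostClassOf <- function(cls) {
    if (grepl("Alu", cls)) "Alu" else if (grepl("L1", cls)) "L1" else "other"
  }
  out <- list()
  for (ct in unique(ann$query_name)) {
    sub <- ann[ann$query_name == ct, , drop = FALSE]
    sub <- sub[order(sub$query_begin), , drop = FALSE]
    focalIdx <- which(sub$repeat_class == focalClass)
    for (i in focalIdx) {
      rec <- NULL
      if (i > 1L && i < nrow(sub)) {
        up <- sub[i - 1L, ]; dn <- sub[i + 1L, ]
        if (up$run_id == dn$run_id && up$repeat_name == dn$repeat_name &&
            abs(dn$cons_begin - (up$cons_end + 1L)) <= tol) {
          rec <- data.frame(host_class = hostClassOf(up$repeat_class),
                            host_name = up$repeat_name,
                            mode = "run_id-adjacency",
                            host_cons_pos = up$cons_end,
                            stringsAsFactors = FALSE)
        }
      }
      if (is.null(rec)) {
        inside <- sub$query_begin < sub$query_begin[i] &
          sub$query_end > sub$query_end[i] &
          seq_len(nrow(sub)) != i
        if (sum(inside) == 1L) {
          host <- sub[inside, ]
          rec <- data.frame(host_class = hostClassOf(host$repeat_class),
                            host_name = host$repeat_name,
                            mode = "containment",
                            host_cons_pos = host$cons_begin +
                              (sub$query_begin[i] - host$query_begin),
                            stringsAsFactors = FALSE)
        }
      }
      if (!is.null(rec)) {
        out[[length(out) + 1L]] <- cbind(
          data.frame(locus_key = sprintf("%s:%d-%d", ct, sub$query_begin[i],
                                         sub$query_end[i]),
                     query_name = ct, query_begin = sub$query_begin[i],
                     query_end = sub$query_end[i],
                     repeat_name = sub$repeat_name[i],
                     stringsAsFactors = FALSE),
          rec)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Crosstab of nesting host class by specificity category
#'
#' @param nested output of \code{\link{detectNested}} with an added
#'   \code{locus_id} column, or any data.frame with \code{locus_id} and
#'   \code{host_class}.
#' @param calls \code{\link{classifySpecificity}} output covering the same
#'   loci (its \code{locus_id} universe defines the denominators).
#' @return list: \code{counts} (host class x category), \code{pct}
#'   (percent of each category's loci nested in each host),
#'   \code{overall_nested_fraction}.
#' @export
nestedByAge <- function(nested, calls) {
  cats <- c("FP", "LS", "MV", "Poly")
  hosts <- c("Alu", "L1", "other")
  counts <- matrix(0L, length(hosts), length(cats),
                   dimnames = list(hosts, cats))
  catOf <- stats::setNames(calls$category, calls$locus_id)
  if (nrow(nested)) {
    for (i in seq_len(nrow(nested))) {
      ct <- catOf[nested$locus_id[i]]
      if (is.na(ct)) next
      counts[nested$host_class[i], ct] <-
        counts[nested$host_class[i], ct] + 1L
    }
  }
  denom <- table(factor(calls$category, levels = cats))
  pct <- sweep(counts, 2, pmax(as.integer(denom), 1L), "/") * 100
  pct[, denom == 0] <- 0
  list(counts = counts, pct = pct,
       overall_nested_fraction =
         if (nrow(calls)) sum(counts) / nrow(calls) else 0)
}
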