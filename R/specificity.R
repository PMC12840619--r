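# Specificity taxonomy: FP (fixed present among non-missing taxa), LS
# (unique to one genome), MV (missing values in a majority of taxa), Poly
# (variable presence/absence) with named-clade sub-categories, plus flags
# for tree-incompatible presence sets (incomplete lineage sorting) and
# deletion-involved calls.

#' Classify one genotype row
#'
#' Precedence: (1) MV when the "?" count reaches the missing-value
#' threshold; (2) FP when every non-missing code is 1; (3) LS when exactly
#' one species is 1 and all other non-missing codes are 0; (4) otherwise
#' Poly, with the sub-category being the named clade whose species set
#' equals the presence set once "?" species are excluded from the
#' comparison. Unmatched presence sets are "Other", flagged ILS when the
#' set is not a clade of the master tree, and flagged deletion-involved
#' when any contributing call carried a "gap outside window" reason.
#'
#' @param row named character vector of codes in \{1, 0, ?\} covering every
#'   species of the clade map.
#' @param cladeMap a \code{\link{CladeMap}}.
#' @param reasons optional named character vector (species -> ambiguity
#'   reason) feeding the deletion flag.
#' @return one-row data.frame: \code{category}, \code{subcategory},
#'   \code{ils}, \code{deletion}.
#' @export
classifyLocus <- function(row, cladeMap, reasons = NULL) {
  species <- cladeMap@species
  if (!all(species %in% names(row)))
    .stopf("row does not cover all species of the clade map")
  row <- row[species]
  nQ <- sum(row == "?")
  present <- species[row == "1"]
  absent <- species[row == "0"]
  missing <- species[row == "?"]
  out <- data.frame(category = NA_character_, subcategory = NA_character_,
                    ils = FALSE, deletion = FALSE, stringsAsFactors = FALSE)
  if (nQ >= cladeMap@mvThreshold) {
    out$category <- "MV"
  } else if (length(absent) == 0L && length(present) > 0L) {
    out$category <- "FP"
  } else if (length(present) == 1L && length(absent) == length(species) - 1L - nQ) {
    out$category <- "LS"
  } else {
    out$category <- "Poly"
    sub <- NA_character_
    for (nm in names(cladeMap@clades)) {
      if (setequal(setdiff(cladeMap@clades[[nm]], missing), present)) {
        sub <- nm
        break
      }
    }
    if (is.na(sub)) {
      sub <- "Other"
      if (length(present) >= 2L &&
          !ape::is.monophyletic(cladeMap@tree, present))
        out$ils <- TRUE
      if (!is.null(reasons) &&
          any(reasons == "gap outside window", na.rm = TRUE))
        out$deletion <- TRUE
    }
    out$subcategory <- sub
  }
  out
}

#' Classify every row of a genotype matrix
#'
#' @param gm a \code{GenotypeMatrix} or a character code matrix.
#' @param cladeMap a \code{\link{CladeMap}}.
#' @return data.frame with one row per locus: \code{locus_id},
#'   \code{category}, \code{subcategory}, \code{ils}, \code{deletion}.
#' @export
classifySpecificity <- function(gm, cladeMap) {
  codes <- if (is(gm, "GenotypeMatrix")) genotypeCodes(gm) else gm
  evidence <- if (is(gm, "GenotypeMatrix")) genotypeEvidence(gm) else NULL
  rows <- lapply(seq_len(nrow(codes)), function(i) {
    reasons <- NULL
    if (!is.null(evidence) && nrow(evidence)) {
      ev <- evidence[evidence$locus_id == rownames(codes)[i], ]
      if (nrow(ev)) reasons <- stats::setNames(ev$reason, ev$species)
    }
    cbind(data.frame(locus_id = rownames(codes)[i],
                     stringsAsFactors = FALSE),
          classifyLocus(codes[i, ], cladeMap, reasons))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(locus_id = character(), category = character(),
                      subcategory = character(), ils = logical(),
                      deletion = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-species specificity summary
#'
#' Counts loci by category (and Poly sub-category) per ascertainment
#' species: for each species the tally covers the loci ascertained from
#' that species, so FP + LS + MV + Poly equals the species' locus total,
#' and the sub-category counts sum to its Poly total.
#'
#' @param gm a \code{GenotypeMatrix}.
#' @param cladeMap a \code{\link{CladeMap}}.
#' @param calls optional precomputed \code{\link{classifySpecificity}}
#'   output.
#' @return data.frame, one row per species: \code{species}, \code{FP},
#'   \code{LS}, \code{MV}, \code{Poly}, \code{total}, then one column per
#'   named clade plus \code{Other}.
#' @export
summarizeSpecificity <- function(gm, cladeMap, calls = NULL) {
  if (is.null(calls)) calls <- classifySpecificity(gm, cladeMap)
  src <- genotypeSource(gm)
  subs <- c(names(cladeMap@clades), "Other")
  out <- lapply(cladeMap@species, function(sp) {
    ids <- names(src)[src == sp]
    cc <- calls[calls$locus_id %in% ids, ]
    row <- data.frame(species = sp,
                      FP = sum(cc$category == "FP"),
                      LS = sum(cc$category == "LS"),
                      MV = sum(cc$category == "MV"),
                      Poly = sum(cc$category == "Poly"),
                      total = nrow(cc), stringsAsFactors = FALSE)
    for (s in subs)
      row[[s]] <- sum(cc$category == "Poly" & cc$subcategory == s,
                      na.rm = TRUE)
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
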