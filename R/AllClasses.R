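#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

setOldClass("phylo")

#' LocusSet: full-length elements with flanking sequence
#'
#' Container for ascertained loci: a per-locus table (coordinates,
#' provenance, flank bookkeeping) and the flanked sequences themselves.
#' Rows of \code{locusInfo(x)} and elements of \code{locusSeqs(x)} are
#' parallel and named by \code{locus_id}.
#'
#' @slot info data.frame with columns \code{locus_id}, \code{species},
#'   \code{contig}, \code{start}, \code{end} (1-based inclusive element
#'   interval on the contig), \code{strand}, \code{subfamily},
#'   \code{flank_left}, \code{flank_right} (realized flank lengths),
#'   \code{element_offset} (equal to \code{flank_left}) and
#'   \code{short_flank} (logical; either flank < 50 bp).
#' @slot seqs \linkS4class{DNAStringSet} of left flank + element + right
#'   flank, one per locus.
#'
#' @seealso \code{\link{extractLoci}}
#' @export
setClass("LocusSet", representation(info = "data.frame", seqs = "DNAStringSet"))

setValidity("LocusSet", function(object) {
  info <- object@info
  need <- c("locus_id", "species", "contig", "start", "end", "strand",
            "subfamily", "flank_left", "flank_right", "element_offset",
            "short_flank")
  if (!all(need %in% names(info)))
    return(paste("missing locus columns:",
                 paste(setdiff(need, names(info)), collapse = ", ")))
  if (nrow(info) != length(object@seqs))
    return("info rows and sequences differ in length")
  if (nrow(info)) {
    if (anyDuplicated(info$locus_id)) return("duplicate locus_id")
    if (!all(info$element_offset == info$flank_left))
      return("element_offset must equal flank_left")
    w <- info$flank_left + (info$end - info$start + 1L) + info$flank_right
    if (!all(Biostrings::width(object@seqs) == w))
      return("sequence widths inconsistent with flank/element lengths")
  }
  TRUE
})

#' @describeIn LocusSet per-locus table
#' @param x a \code{LocusSet}
#' @export
locusInfo <- function(x) x@info

#' @describeIn LocusSet flanked sequences
#' @export
locusSeqs <- function(x) x@seqs

setMethod("show", "LocusSet", function(object) {
  cat("LocusSet with", nrow(object@info), "loci from",
      length(unique(object@info$species)), "species\n")
  if (nrow(object@info))
    cat("  subfamilies:",
        paste(utils::head(sort(unique(object@info$subfamily)), 6),
              collapse = ", "), "\n")
})

#' GenotypeMatrix: presence/absence codes across species
#'
#' Loci-by-species grid of codes in \{"1", "0", "?"\} with per-call
#' evidence. The ascertainment (source) species of each locus always codes
#' "1" for that locus.
#'
#' @slot codes character matrix, rows = loci, columns = species.
#' @slot evidence data.frame of per-cell calls: \code{locus_id},
#'   \code{species}, \code{code}, best-hit \code{contig}, \code{hit_start},
#'   \code{hit_end}, flank identities, observed \code{gap_len} and the
#'   machine-readable ambiguity \code{reason} for "?" calls.
#' @slot source named character: locus id -> source species (after merging,
#'   the species the kept record was ascertained from).
#' @slot members named list: locus id -> ids of merged duplicate records.
#' @export
setClass("GenotypeMatrix",
         representation(codes = "matrix", evidence = "data.frame",
                        source = "character", members = "list"))

setValidity("GenotypeMatrix", function(object) {
  if (nrow(object@codes) && !all(object@codes %in% c("1", "0", "?")))
    return("codes must be in {1, 0, ?}")
  if (nrow(object@codes) != length(object@source))
    return("source length must match rows")
  src <- object@source
  for (i in seq_along(src)) {
    if (!src[i] %in% colnames(object@codes)) next
    if (object@codes[i, src[i]] != "1")
      return("source species must code 1 for its own locus")
  }
  TRUE
})

#' @describeIn GenotypeMatrix code grid (character matrix)
#' @param x a \code{GenotypeMatrix}
#' @export
genotypeCodes <- function(x) x@codes

#' @describeIn GenotypeMatrix per-call evidence table
#' @export
genotypeEvidence <- function(x) x@evidence

#' @describeIn GenotypeMatrix source species per locus
#' @export
genotypeSource <- function(x) x@source

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@codes), "loci x",
      ncol(object@codes), "species\n")
  if (nrow(object@codes)) {
    tab <- table(factor(object@codes, levels = c("1", "0", "?")))
    cat("  codes: 1 =", tab[["1"]], ", 0 =", tab[["0"]],
        ", ? =", tab[["?"]], "\n")
  }
})

#' CladeMap: species, families, named clades and the master tree
#'
#' Defines the taxon universe for specificity classification: each species'
#' family label, the named presence-set clades used as polymorphic
#' sub-categories, the master species tree used to flag tree-incompatible
#' (incomplete lineage sorting) presence sets, and the missing-value
#' threshold.
#'
#' @slot species character vector of species labels (column universe).
#' @slot family named character: species -> family label.
#' @slot clades named list of character vectors; order is the match
#'   precedence for sub-category naming.
#' @slot tree ape \code{phylo} master tree over \code{species}.
#' @slot mvThreshold integer; a locus with at least this many "?" codes is
#'   classified MV. Default \code{ceiling((N + 1) / 2)}, the simple
#'   majority (7 of 13 taxa).
#' @export
setClass("CladeMap",
         representation(species = "character", family = "character",
                        clades = "list", tree = "phylo",
                        mvThreshold = "integer"))

setValidity("CladeMap", function(object) {
  if (anyDuplicated(object@species)) return("duplicate species")
  if (!all(names(object@family) %in% object@species))
    return("family names must be species")
  if (length(object@clades)) {
    if (is.null(names(object@clades)) || anyDuplicated(names(object@clades)))
      return("clades must be uniquely named")
    ok <- vapply(object@clades, function(s) all(s %in% object@species),
                 logical(1))
    if (!all(ok)) return("clade species sets must be subsets of species")
  }
  if (!setequal(object@tree$tip.label, object@species))
    return("tree tips must equal the species set")
  TRUE
})

#' Construct a CladeMap
#'
#' @param species character vector of species labels.
#' @param family named character vector mapping species to family labels.
#' @param clades named list of species sets (polymorphic sub-categories),
#'   in match-precedence order.
#' @param tree master species tree: an ape \code{phylo} or a Newick string.
#' @param mvThreshold missing-value threshold; default simple majority
#'   \code{ceiling((N + 1) / 2)}.
#' @return a \linkS4class{CladeMap}
#' @export
CladeMap <- function(species, family, clades = list(), tree,
                     mvThreshold = ceiling((length(species) + 1) / 2)) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  new("CladeMap", species = species, family = family, clades = clades,
      tree = tree, mvThreshold = as.integer(mvThreshold))
}

setMethod("show", "CladeMap", function(object) {
  cat("CladeMap:", length(object@species), "species,",
      length(object@clades), "named clades, MV threshold",
      object@mvThreshold, "\n")
})

#' SimulationConfig: parameters of the clade simulator
#'
#' See \code{\link{simulationConfig}} for construction and parameter
#' meanings.
#'
#' @export
setClass("SimulationConfig",
         representation(tree = "character", rootLength = "numeric",
                        genomeLength = "numeric", insertionRate = "numeric",
                        mu = "numeric", library = "DNAStringSet",
                        libraryClass = "character",
                        subfamilySchedule = "list",
                        tsdRange = "numeric", aTailMean = "numeric",
                        aTailHeavyProb = "numeric", aTailHeavyMean = "numeric",
                        nestedFraction = "numeric",
                        backgroundDensity = "numeric",
                        truncatedFraction = "numeric", biasTT = "numeric",
                        parallelInsertions = "integer", sizeCap = "numeric",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object$insertionRate < 0 || object$mu < 0)
    return("rates must be >= 0")
  if (object$tsdRange[1] < 0 || object$tsdRange[2] < object$tsdRange[1])
    return("invalid tsdRange")
  if (object$nestedFraction < 0 || object$nestedFraction > 1)
    return("nestedFraction must be in [0, 1]")
  if (object$backgroundDensity < 0 || object$backgroundDensity >= 1)
    return("backgroundDensity must be in [0, 1)")
  TRUE
})

#' @export
setMethod("$", "SimulationConfig", function(x, name) slot(x, name))

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@genomeLength, "bp ancestor, lambda =",
      object@insertionRate, ", mu =", object@mu, ", seed =",
      object@seed, "\n")
})

#' SineSimulation: result of a clade simulation
#'
#' @slot genomes named list (species -> \code{DNAStringSet}) of simulated
#'   assemblies.
#' @slot annotations named list of per-species truth annotation tables in
#'   RepeatMasker-row form (see \code{\link{readRepeatMaskerOut}}).
#' @slot truth per-insertion ground truth: locus id, branch of origin,
#'   subfamily, TSD, A-tail length, full-length flag, nesting host.
#' @slot positions per-carrier element coordinates (locus_id, species,
#'   contig, start, end, a_tail_len, tsd_len).
#' @slot truthMatrix character matrix of planted presence ("1") / absence
#'   ("0"), full-length loci x species.
#' @slot config the \linkS4class{SimulationConfig} used.
#' @export
setClass("SineSimulation",
         representation(genomes = "list", annotations = "list",
                        truth = "data.frame", positions = "data.frame",
                        truthMatrix = "matrix", config = "SimulationConfig"))

setMethod("show", "SineSimulation", function(object) {
  cat("SineSimulation:", length(object@genomes), "genomes,",
      nrow(object@truth), "planted insertions (",
      sum(object@truth$full_length), "full-length )\n")
})

#' @describeIn SineSimulation simulated genomes (named list of DNAStringSet)
#' @param x a \code{SineSimulation}
#' @export
simGenomes <- function(x) x@genomes

#' @describeIn SineSimulation per-species truth annotations
#' @export
simAnnotations <- function(x) x@annotations

#' @describeIn SineSimulation per-insertion ground truth
#' @export
simTruth <- function(x) x@truth

#' @describeIn SineSimulation per-carrier insertion coordinates
#' @export
simPositions <- function(x) x@positions

#' @describeIn SineSimulation truth presence/absence matrix
#' @export
simTruthMatrix <- function(x) x@truthMatrix
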