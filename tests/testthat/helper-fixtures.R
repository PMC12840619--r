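# Shared fixtures: all built in code, no files.

# a canonical .out row (plus strand)
outLinePlus <- "463 10.5 3.2 0.0 chr1 1001 1105 (8895) + Platy-1-4a SINE/Platy 1 103 (0) 7"

# small deterministic random DNA
randomSeq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# build a single-locus LocusSet from explicit parts
makeLocus <- function(flankL, elem, flankR, species = "A", contig = "chr1",
                      start = 1000L, strand = "+", id = "L1",
                      subfamily = "Platy-1-4a") {
  seq <- paste0(flankL, elem, flankR)
  info <- data.frame(
    locus_id = id, species = species, contig = contig,
    start = start, end = start + nchar(elem) - 1L, strand = strand,
    subfamily = subfamily, flank_left = nchar(flankL),
    flank_right = nchar(flankR), element_offset = nchar(flankL),
    short_flank = nchar(flankL) < 50L || nchar(flankR) < 50L,
    stringsAsFactors = FALSE)
  new("LocusSet", info = info,
      seqs = Biostrings::DNAStringSet(stats::setNames(seq, id)))
}

# tiny fast simulation shared by several tests
tinySim <- function(seed = 3L, mu = 0.05, genomeLength = 2e5,
                    insertionRate = 8, ...) {
  simulateClade(simulationConfig(genomeLength = genomeLength,
                                 insertionRate = insertionRate,
                                 mu = mu, seed = seed, ...))
}

# clade map mirroring a 13-taxon platyrrhine-style panel
thirteenTaxa <- function() {
  species <- c("saki", "titi", "howler", "spider1", "spider2",
               "cap1", "cap2", "cap3", "squirrel", "owl",
               "marmoset", "tam1", "tam2")
  family <- stats::setNames(
    c("Pitheciidae", "Pitheciidae", "Atelidae", "Atelidae", "Atelidae",
      "Cebidae", "Cebidae", "Cebidae", "Cebidae", "Aotidae",
      "Callithrichidae", "Callithrichidae", "Callithrichidae"), species)
  clades <- list(
    "Pith" = c("saki", "titi"),
    "Pith and Atelidae" = c("saki", "titi", "howler", "spider1", "spider2"),
    "Atelidae-Ceb-Aot-Call" = setdiff(species, c("saki", "titi")),
    "Atelidae" = c("howler", "spider1", "spider2"),
    "Ateles" = c("spider1", "spider2"),
    "Ceb" = c("cap1", "cap2", "cap3", "squirrel", "owl", "marmoset",
              "tam1", "tam2"),
    "Cap" = c("cap1", "cap2", "cap3"),
    "Saimiri and Cap" = c("cap1", "cap2", "cap3", "squirrel"),
    "Call" = c("marmoset", "tam1", "tam2"),
    "Sag" = c("tam1", "tam2"))
  tree <- paste0("((saki,titi),((howler,(spider1,spider2)),",
                 "(((cap1,cap2,cap3),squirrel),(owl,",
                 "(marmoset,(tam1,tam2))))));")
  CladeMap(species = species, family = family, clades = clades,
           tree = tree)
}

# code row helper over the 13 taxa
codeRow <- function(present = character(), missing = character(),
                    cladeMap = thirteenTaxa()) {
  row <- stats::setNames(rep("0", length(cladeMap@species)),
                         cladeMap@species)
  row[present] <- "1"
  row[missing] <- "?"
  row
}
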