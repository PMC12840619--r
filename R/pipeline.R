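# End-to-end orchestration with a resolved config, per-stage counts and a
# manifest. Reruns with the same config and inputs are byte-identical
# (every stochastic stage is seeded from the config seed).

#' Configure a pipeline run
#'
#' @param outDir output directory (created; one run per directory).
#' @param simulation a \code{\link{simulationConfig}} (the pipeline's input
#'   generator), or \code{NULL} when genomes/annotations are supplied.
#' @param genomes named list of \code{DNAStringSet}; overrides simulation.
#' @param annotations named list of annotation data.frames (same names).
#' @param library consensus \code{DNAStringSet}.
#' @param libraryClass named character of per-entry repeat classes.
#' @param cladeMap a \code{\link{CladeMap}}, or NULL to derive one from the
#'   simulation tree (every species its own family, every internal-branch
#'   leaf set a named clade).
#' @param flank flank length for locus extraction.
#' @param thresholds \code{\link{genotypeThresholds}}.
#' @param stages character vector of stages to run, a subset of
#'   \code{c("simulate", "ascertain", "genotype", "classify", "landscape",
#'   "features", "subfamily", "tree")}.
#' @param minCount,minDiag subfamily-discovery parameters.
#' @param bootstrap NJ bootstrap replicates.
#' @param seed master seed; stage seeds derive from it.
#' @return config list for \code{\link{runPipeline}}.
#' @export
pipelineConfig <- function(outDir, simulation = simulationConfig(),
                           genomes = NULL, annotations = NULL,
                           library = NULL, libraryClass = NULL,
                           cladeMap = NULL, flank = 500,
                           thresholds = genotypeThresholds(),
                           stages = c("simulate", "ascertain", "genotype",
                                      "classify", "landscape", "features",
                                      "subfamily", "tree"),
                           minCount = 10, minDiag = 2, bootstrap = 100,
                           seed = 1L) {
  if (is.null(library) && !is.null(simulation)) {
    library <- simulation$library
    libraryClass <- simulation$libraryClass
  }
  list(outDir = outDir, simulation = simulation, genomes = genomes,
       annotations = annotations, library = library,
       libraryClass = libraryClass, cladeMap = cladeMap, flank = flank,
       thresholds = thresholds, stages = stages, minCount = minCount,
       minDiag = minDiag, bootstrap = bootstrap, seed = as.integer(seed))
}

# derive a CladeMap from a Newick tree: families = leaves, clades = leaf
# sets of internal branches (named by their species, joined with "+")
.cladeMapFromTree <- function(treeText) {
  tree <- ape::read.tree(text = treeText)
  species <- tree$tip.label
  sets <- .branchLeafSets(tree)
  clades <- list()
  for (nm in names(sets)) {
    s <- sets[[nm]]
    if (length(s) > 1L && length(s) < length(species))
      clades[[paste(sort(s), collapse = "+")]] <- s
  }
  CladeMap(species = species,
           family = stats::setNames(species, species),
           clades = clades, tree = tree)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order (simulate, ascertain, genotype,
#' classify, landscape, features, subfamily, tree), writing each stage's
#' outputs and a manifest (seed, per-stage counts, file checksums) under
#' \code{outDir}. A stage whose inputs were not produced (toggled-off
#' upstream stage and no user-supplied replacement) aborts with an error
#' naming the missing stage.
#'
#' @param config from \code{\link{pipelineConfig}}.
#' @return invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  res <- list()
  stageOn <- function(s) s %in% config$stages
  need <- function(x, stage, from) {
    if (is.null(x))
      .stopf("stage '%s' requires output of stage '%s', which did not run",
             stage, from)
    x
  }
  genomes <- config$genomes
  annotations <- config$annotations
  sim <- NULL

  if (stageOn("simulate")) {
    if (is.null(config$simulation)) .stopf("stage 'simulate': no simulation config")
    sim <- simulateClade(config$simulation)
    genomes <- simGenomes(sim)
    annotations <- simAnnotations(sim)
    emitTruthOut(sim, file.path(config$outDir, "truth"))
    utils::write.table(simTruth(sim),
                       file.path(config$outDir, "truth", "planted_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(locus_id = rownames(simTruthMatrix(sim)),
                 simTruthMatrix(sim), check.names = FALSE),
      file.path(config$outDir, "truth", "truth_matrix.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$simulate <- list(
      species = length(genomes),
      insertions = nrow(simTruth(sim)),
      full_length = sum(simTruth(sim)$full_length))
    res$sim <- sim
  }

  cladeMap <- config$cladeMap
  if (is.null(cladeMap) && !is.null(config$simulation))
    cladeMap <- .cladeMapFromTree(config$simulation$tree)

  loci <- NULL
  if (stageOn("ascertain")) {
    genomes <- need(genomes, "ascertain", "simulate")
    annotations <- need(annotations, "ascertain", "simulate")
    consLen <- stats::setNames(Biostrings::width(config$library),
                               names(config$library))
    parts <- list()
    for (sp in names(genomes)) {
      ann <- annotations[[sp]]
      focal <- ann[config$libraryClass[ann$repeat_name] == "SINE/Platy", ,
                   drop = FALSE]
      fl <- filterFullLength(focal, consLen)
      parts[[sp]] <- extractLoci(genomes[[sp]], fl, species = sp,
                                 flank = config$flank)
      writeLoci(parts[[sp]],
                file.path(config$outDir, paste0("loci_", sp, ".fasta")),
                file.path(config$outDir, paste0("loci_", sp, ".tsv")))
    }
    loci <- combineLoci(parts)
    manifest$stages$ascertain <- list(loci = nrow(locusInfo(loci)))
    res$loci <- loci
  }

  gm <- NULL
  if (stageOn("genotype")) {
    loci <- need(loci, "genotype", "ascertain")
    genomes <- need(genomes, "genotype", "simulate")
    gm <- buildGenotypeMatrix(loci, genomes, config$thresholds)
    writeGenotypeMatrix(gm,
                        file.path(config$outDir, "genotype_matrix.tsv"),
                        file.path(config$outDir, "genotype_matrix.nex"))
    utils::write.table(genotypeEvidence(gm),
                       file.path(config$outDir, "genotype_evidence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cd <- table(factor(genotypeCodes(gm), levels = c("1", "0", "?")))
    manifest$stages$genotype <- list(loci = nrow(genotypeCodes(gm)),
                                     code1 = cd[["1"]], code0 = cd[["0"]],
                                     codeQ = cd[["?"]])
    res$genotypes <- gm
  }

  calls <- NULL
  if (stageOn("classify")) {
    gm <- need(gm, "classify", "genotype")
    if (is.null(cladeMap)) .stopf("stage 'classify': no clade map")
    calls <- classifySpecificity(gm, cladeMap)
    summary <- summarizeSpecificity(gm, cladeMap, calls)
    utils::write.table(calls,
                       file.path(config$outDir, "specificity_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summary,
                       file.path(config$outDir, "specificity_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$classify <- as.list(table(calls$category))
    res$specificity <- calls
    res$summary <- summary
  }

  if (stageOn("landscape")) {
    annotations <- need(annotations, "landscape", "simulate")
    genomes <- need(genomes, "landscape", "simulate")
    for (sp in names(annotations)) {
      ann <- annotations[[sp]]
      focal <- ann[ann$repeat_class == "SINE/Platy", , drop = FALSE]
      sizes <- stats::setNames(Biostrings::width(genomes[[sp]]),
                               names(genomes[[sp]]))
      prox <- proximityWithin(focal, ann)
      cont <- genomeRepeatContent(ann, sizes)
      hist <- divergenceHistogram(ann)
      nest <- detectNested(ann)
      utils::write.table(prox, file.path(config$outDir,
                                         paste0("proximity_", sp, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cont, file.path(config$outDir,
                                         paste0("content_", sp, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(hist, file.path(config$outDir,
                                         paste0("divergence_", sp, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(nest, file.path(config$outDir,
                                         paste0("nested_", sp, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$stages$landscape <- list(species = length(annotations))
  }

  if (stageOn("features")) {
    loci <- need(loci, "features", "ascertain")
    feats <- locusFeatures(loci)
    utils::write.table(feats, file.path(config$outDir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$features <- list(
      loci = nrow(feats), tsd_precise = sum(feats$tsd_precise))
    res$features <- feats
  }

  models <- NULL
  if (stageOn("subfamily")) {
    gm <- need(gm, "subfamily", "genotype")
    loci <- need(loci, "subfamily", "ascertain")
    calls <- need(calls, "subfamily", "classify")
    ## lineage-specific loci, element portion only
    lsIds <- calls$locus_id[calls$category == "LS"]
    info <- locusInfo(loci)
    keep <- info$locus_id %in% lsIds
    elems <- Biostrings::DNAStringSet(vapply(which(keep), function(i) {
      s <- as.character(locusSeqs(loci)[[i]])
      substr(s, info$element_offset[i] + 1L,
             info$element_offset[i] + info$end[i] - info$start[i] + 1L)
    }, character(1)))
    names(elems) <- info$locus_id[keep]
    parent <- if ("Platy-1-4a" %in% names(config$library))
      config$library[["Platy-1-4a"]] else config$library[[1]]
    models <- discoverSubfamilies(elems, parent,
                                  minCount = config$minCount,
                                  minDiag = config$minDiag)
    if (length(models)) {
      cons <- Biostrings::DNAStringSet(
        stats::setNames(vapply(models, `[[`, character(1), "consensus"),
                        vapply(models, `[[`, character(1), "name")))
      Biostrings::writeXStringSet(
        cons, file.path(config$outDir, "discovered_subfamilies.fasta"))
    }
    manifest$stages$subfamily <- list(ls_elements = length(elems),
                                      models = length(models))
    res$subfamilies <- models
  }

  if (stageOn("tree")) {
    platy <- config$library[
      config$libraryClass[names(config$library)] == "SINE/Platy"]
    extra <- if (!is.null(models) && length(models)) {
      Biostrings::DNAStringSet(
        stats::setNames(vapply(models, `[[`, character(1), "consensus"),
                        vapply(models, `[[`, character(1), "name")))
    } else NULL
    seqs <- if (is.null(extra)) platy else c(platy, extra)
    if (length(seqs) >= 3L) {
      tr <- buildNJTree(seqs, bootstrap = config$bootstrap,
                        seed = config$seed + 7L)
      writeNewick(tr, file.path(config$outDir, "subfamily_tree.nwk"))
      manifest$stages$tree <- list(tips = length(seqs))
      res$tree <- tr
    }
  }

  files <- sort(setdiff(list.files(config$outDir, recursive = TRUE),
                        "manifest.json"))
  manifest$checksums <- as.list(tools::md5sum(
    file.path(config$outDir, files)))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest,
                       file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
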