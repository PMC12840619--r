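# Clade simulator: genomes descend along a species tree; SINE insertions
# are planted on branches via a target-primed reverse transcription (TPRT)
# event model (target-site duplication, poly-A tail, endonuclease-site
# bias), so presence/absence follows descent and every downstream stage can
# be validated against known truth.

.BACKGROUND_AGE <- 0.15  # JC dose applied to pre-seeded Alu/L1 copies

.withRNG <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.breakARuns <- function(s) {
  while (grepl("AAAA", s)) s <- sub("AAAA", "AAGA", s)
  s
}

#' Synthetic repeat consensus library
#'
#' A deterministic, randomly generated stand-in library: four ~105 bp SINE
#' subfamily consensi (class SINE/Platy, related to each other by a handful
#' of substitutions), one 300 bp Alu-like consensus (SINE/Alu) and one 6 kb
#' L1-like consensus (LINE/L1). These sequences are synthetic -- generated
#' by code under a fixed internal seed, not taken from any published
#' consensus -- and exist so that simulations and tests carry no external
#' data. Consensus 3' ends are kept free of A-runs so that a planted poly-A
#' tail is unambiguous.
#'
#' @return a named \code{DNAStringSet}; the repeat class of each entry is
#'   in \code{metadata(x)$class}.
#' @export
syntheticConsensusLibrary <- function() {
  .withRNG(190531L, {
    base <- rawToChar(.randomDNA(105L))
    base <- .breakARuns(base)
    substr(base, 103, 105) <- "GCG"   # non-A 3' terminus
    mutateAt <- function(s, pos, bases) {
      for (i in seq_along(pos)) substr(s, pos[i], pos[i]) <- bases[i]
      s
    }
    p4a <- base
    p4  <- mutateAt(base, c(12, 37, 58, 90), c("T", "A", "C", "T"))
    p2a <- mutateAt(base, c(5, 21, 33, 49, 61, 77, 84, 96),
                    c("C", "T", "A", "G", "T", "C", "A", "T"))
    p5  <- mutateAt(base, c(9, 28, 44, 70, 99), c("G", "C", "T", "A", "C"))
    alu <- .breakARuns(rawToChar(.randomDNA(300L)))
    l1  <- .breakARuns(rawToChar(.randomDNA(6000L)))
    lib <- Biostrings::DNAStringSet(c(
      "Platy-1-4a" = p4a, "Platy-1-4" = p4, "Platy-1-2a" = p2a,
      "Platy-1-5" = p5, "AluSyn" = alu, "L1Syn" = l1))
    S4Vectors::metadata(lib)$class <- c(
      "Platy-1-4a" = "SINE/Platy", "Platy-1-4" = "SINE/Platy",
      "Platy-1-2a" = "SINE/Platy", "Platy-1-5" = "SINE/Platy",
      "AluSyn" = "SINE/Alu", "L1Syn" = "LINE/L1")
    lib
  })
}

#' Configure a clade simulation
#'
#' Defaults describe the study conditions the package is validated under: a
#' five-species clade with root-to-tip depth 1 time unit, 5 Mb genomes, 25
#' expected insertions per unit branch length, and a flank substitution
#' dose of about 0.05 from root to tip.
#'
#' @param tree Newick string with branch lengths (arbitrary time units).
#' @param rootLength length of the stem branch above the root; insertions
#'   on it are ancestral (fixed present).
#' @param genomeLength ancestral genome size in bp.
#' @param insertionRate expected insertions per unit branch length (Poisson).
#' @param mu substitutions per site per unit time (Jukes-Cantor).
#' @param library consensus \code{DNAStringSet}; defaults to
#'   \code{\link{syntheticConsensusLibrary}()}.
#' @param libraryClass named character of repeat classes per library entry;
#'   default taken from the library metadata.
#' @param subfamilySchedule named list mapping a branch label (child node
#'   label; leaves by tip name, stem by "root") to the subfamily names
#'   eligible on that branch. Empty list = all SINE/Platy entries eligible
#'   everywhere.
#' @param tsdRange target-site duplication length range in bp.
#' @param aTailMean mean of the geometric A-tail length distribution.
#' @param aTailHeavyProb probability an A-tail receives a heavy-tail
#'   extension (emulating rare very long tails).
#' @param aTailHeavyMean mean of the geometric heavy-tail extension.
#' @param nestedFraction probability an insertion targets the interior of a
#'   pre-existing Alu/L1 copy.
#' @param backgroundDensity fraction of the ancestral genome pre-seeded
#'   with Alu/L1 copies.
#' @param truncatedFraction fraction of insertions planted 5'-truncated
#'   (consensus start offset 5-59); these are decoys for the full-length
#'   filter and are excluded from the truth genotype matrix.
#' @param biasTT probability an insertion site is chosen adjacent to a TT
#'   motif (endonuclease preference for AT-rich targets).
#' @param parallelInsertions number of identical-position insertions
#'   planted in a non-clade species pair (off by default; exercises
#'   incomplete-lineage-sorting-style "Other" presence sets).
#' @param sizeCap abort if the expected total sequence exceeds this many bp.
#' @param seed RNG seed; the full simulation is deterministic given it.
#' @return a \linkS4class{SimulationConfig}
#' @export
simulationConfig <- function(tree = "((A:0.4,B:0.4):0.6,((C:0.3,D:0.3):0.3,E:0.6):0.4);",
                             rootLength = 0.6,
                             genomeLength = 5e6,
                             insertionRate = 25,
                             mu = 0.05,
                             library = syntheticConsensusLibrary(),
                             libraryClass = NULL,
                             subfamilySchedule = list(),
                             tsdRange = c(6, 20),
                             aTailMean = 15,
                             aTailHeavyProb = 0.03,
                             aTailHeavyMean = 50,
                             nestedFraction = 0.12,
                             backgroundDensity = 0.15,
                             truncatedFraction = 0.1,
                             biasTT = 0.8,
                             parallelInsertions = 0L,
                             sizeCap = 5e7,
                             seed = 1L) {
  if (is.null(libraryClass)) {
    libraryClass <- S4Vectors::metadata(library)$class
    if (is.null(libraryClass))
      libraryClass <- stats::setNames(rep("SINE/Platy", length(library)),
                                      names(library))
  }
  new("SimulationConfig", tree = tree, rootLength = rootLength,
      genomeLength = genomeLength, insertionRate = insertionRate, mu = mu,
      library = library, libraryClass = libraryClass,
      subfamilySchedule = subfamilySchedule, tsdRange = tsdRange,
      aTailMean = aTailMean, aTailHeavyProb = aTailHeavyProb,
      aTailHeavyMean = aTailHeavyMean, nestedFraction = nestedFraction,
      backgroundDensity = backgroundDensity,
      truncatedFraction = truncatedFraction, biasTT = biasTT,
      parallelInsertions = as.integer(parallelInsertions),
      sizeCap = sizeCap, seed = as.integer(seed))
}

# registry row shift/split on insertion of M bases after position q.
# Background rows containing q are split into co-identified fragments
# (shared run_id, continuing consensus coordinates); guarded rows never
# contain q by site-selection construction.
.registryInsert <- function(reg, q, M) {
  if (!nrow(reg)) return(reg)
  inside <- reg$begin <= q & reg$end > q
  after <- reg$begin > q
  reg$begin[after] <- reg$begin[after] + M
  reg$end[after] <- reg$end[after] + M
  reg$guard_end[after] <- reg$guard_end[after] + M
  if (any(inside)) {
    for (i in which(inside)) {
      row <- reg[i, ]
      upLen <- q - row$begin + 1L
      up <- row; dn <- row
      up$end <- q
      up$guard_end <- q
      up$cons_end <- row$cons_begin + upLen - 1L
      dn$begin <- q + M + 1L
      dn$end <- row$end + M
      dn$guard_end <- row$guard_end + M
      dn$cons_begin <- row$cons_begin + upLen
      reg[i, ] <- up
      reg <- rbind(reg, dn)
    }
  }
  reg
}

.newRegistry <- function() {
  data.frame(kind = character(), class = character(), name = character(),
             begin = integer(), end = integer(), guard_end = integer(),
             cons_begin = integer(), cons_end = integer(),
             run_id = integer(), locus_id = character(),
             stringsAsFactors = FALSE)
}

# one TPRT insertion event; returns list(genome, registry)
.plantInsertion <- function(g, reg, subfamily, consBegin, age, cfg, branch,
                            state, forceQ = NA, forceTsd = NA,
                            locusId = NA) {
  cons <- state$cons[[subfamily]]
  elem <- substr(cons, consBegin, nchar(cons))
  elemRaw <- .jcMutate(charToRaw(elem), cfg$mu * age)
  la <- rgeom(1L, 1 / (cfg$aTailMean + 1))
  if (runif(1) < cfg$aTailHeavyProb)
    la <- la + rgeom(1L, 1 / (cfg$aTailHeavyMean + 1))
  d <- if (!is.na(forceTsd)) forceTsd
       else sample(cfg$tsdRange[1]:cfg$tsdRange[2], 1L)
  L <- length(g)
  nested <- FALSE
  hostClass <- NA_character_
  TT <- charToRaw("T")
  if (!is.na(forceQ)) {
    q <- forceQ
  } else if (runif(1) < cfg$nestedFraction) {
    bg <- which(reg$kind == "background" & (reg$end - reg$begin) >= d + 60L)
    q <- NA
    if (length(bg)) {
      i <- if (length(bg) == 1L) bg else sample(bg, 1L)
      # the base 5' of the target duplication is the nick T (it also keeps
      # the duplication boundary unambiguous for hallmark detection)
      for (try in 1:60) {
        cand <- sample((reg$begin[i] + 20L):(reg$end[i] - 20L), 1L)
        if (g[cand - d] != TT && try < 60L) next
        q <- cand
        break
      }
      nested <- TRUE
      hostClass <- reg$class[i]
    }
  } else q <- NA
  if (is.na(q)) {
    nested <- FALSE
    hostClass <- NA_character_
    guarded <- reg$kind != "background"
    gb <- reg$begin[guarded]; ge <- reg$guard_end[guarded]
    bias <- runif(1) < cfg$biasTT
    margin <- min(600L, max(20L, L %/% 10L))  # avoid contig-edge truncation
    for (try in 1:200) {
      cand <- sample.int(L - d - 2L * margin, 1L) + d + margin
      if (any(gb <= cand & ge >= cand)) next
      inBg <- any(reg$kind == "background" & reg$begin <= cand &
                    reg$end > cand)
      if (inBg) next  # chance nesting excluded: nested draws are explicit
      if (g[cand - d] != TT && try < 190) next  # nick T 5' of the TSD
      if (bias && g[cand - d - 1L] != TT && try < 150) next
      q <- cand
      break
    }
    if (is.na(q)) return(list(genome = g, registry = reg))  # no site found
  }
  tsdRaw <- g[(q - d + 1L):q]
  insBlock <- c(elemRaw, rep(charToRaw("A"), la), tsdRaw)
  M <- length(insBlock)
  g2 <- c(g[1:q], insBlock, if (q < L) g[(q + 1L):L] else raw(0))
  reg <- .registryInsert(reg, q, M)
  state$runId <- state$runId + 1L
  if (is.na(locusId)) {
    state$locusNum <- state$locusNum + 1L
    id <- sprintf("ins%04d", state$locusNum)
  } else id <- locusId
  Lel <- length(elemRaw)
  reg <- rbind(reg, data.frame(
    kind = "element", class = "SINE/Platy", name = subfamily,
    begin = q + 1L, end = q + Lel, guard_end = q + M,
    cons_begin = consBegin, cons_end = nchar(cons),
    run_id = state$runId, locus_id = id, stringsAsFactors = FALSE))
  state$truth[[id]] <- data.frame(
    locus_id = id, branch = branch, subfamily = subfamily,
    cons_begin = consBegin, cons_end = nchar(cons),
    full_length = consBegin == 1L, tsd = rawToChar(tsdRaw), tsd_len = d,
    a_tail_len = la, nested = nested,
    nested_host = if (nested) switch(hostClass, "SINE/Alu" = "Alu",
                                     "LINE/L1" = "L1", "other")
                  else NA_character_,
    stringsAsFactors = FALSE)
  list(genome = g2, registry = reg)
}

#' Simulate a clade of genomes with planted SINE insertions
#'
#' Draws a random ancestral genome, pre-seeds it with background Alu/L1
#' copies, then walks the species tree: along each branch the genome
#' accumulates Jukes-Cantor substitutions at rate \code{mu} and
#' Poisson(\code{insertionRate} x branch length) TPRT insertions, each with
#' a fresh target-site duplication, poly-A tail and an element copied from
#' its subfamily consensus and aged for the remainder of the branch.
#' Coordinates of all pre-existing repeats are lifted over consistently;
#' an insertion landing inside a background copy splits it into two
#' fragments sharing one run id (a nested integration). Deterministic
#' given \code{config@seed}.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return a \linkS4class{SineSimulation}.
#' @export
simulateClade <- function(config) {
  set.seed(config$seed)
  tree <- tryCatch(suppressWarnings(ape::read.tree(text = config$tree)),
                   error = function(e) NULL)
  if (is.null(tree) || is.null(tree$edge.length) ||
      anyNA(tree$edge.length))
    .stopf("cannot parse Newick tree (branch lengths required)")
  nTips <- length(tree$tip.label)
  if (nTips < 2L) .stopf("tree must have at least 2 leaves")
  lib <- config$library
  cons <- as.character(lib)
  libClass <- config$libraryClass
  platy <- names(lib)[libClass[names(lib)] == "SINE/Platy"]
  if (!length(platy)) .stopf("library has no SINE/Platy entries")
  totalLen <- sum(tree$edge.length) + config$rootLength
  expIns <- config$insertionRate * totalLen
  maxBlock <- max(nchar(cons[platy])) + 300 + config$tsdRange[2]
  if (config$genomeLength * (1 + config$backgroundDensity) +
      4 * expIns * maxBlock > config$sizeCap)
    .stopf("expected simulated size exceeds sizeCap")

  state <- new.env(parent = emptyenv())
  state$cons <- as.list(cons)
  state$locusNum <- 0L
  state$runId <- 0L
  state$truth <- list()

  ## ancestral genome + background repeats
  g <- .randomDNA(config$genomeLength)
  reg <- .newRegistry()
  targetBp <- config$backgroundDensity * config$genomeLength
  placedBp <- 0
  starts <- integer(); ends <- integer()
  hasAlu <- "AluSyn" %in% names(lib); hasL1 <- "L1Syn" %in% names(lib)
  while (placedBp < targetBp && (hasAlu || hasL1)) {
    useAlu <- hasAlu && (!hasL1 || runif(1) < 0.6)
    if (useAlu) {
      nm <- "AluSyn"; ce <- nchar(cons[["AluSyn"]]); cb <- 1L
    } else {
      nm <- "L1Syn"
      len <- sample(500:3000, 1L)
      ce <- nchar(cons[["L1Syn"]]); cb <- ce - len + 1L
    }
    len <- ce - cb + 1L
    p <- sample.int(config$genomeLength - len - 10L, 1L) + 5L
    if (length(starts) && any(p <= ends + 10L & p + len - 1L >= starts - 10L))
      next
    frag <- .jcMutate(charToRaw(substr(cons[[nm]], cb, ce)), .BACKGROUND_AGE)
    g[p:(p + len - 1L)] <- frag
    starts <- c(starts, p); ends <- c(ends, p + len - 1L)
    state$runId <- state$runId + 1L
    reg <- rbind(reg, data.frame(
      kind = "background", class = libClass[[nm]], name = nm,
      begin = p, end = p + len - 1L, guard_end = p + len - 1L,
      cons_begin = cb, cons_end = ce, run_id = state$runId,
      locus_id = NA_character_, stringsAsFactors = FALSE))
    placedBp <- placedBp + len
  }

  ## parallel-insertion markers (identical-position, non-clade species pair)
  parMeta <- NULL
  if (config$parallelInsertions > 0L && nTips >= 4L) {
    pair <- NULL
    combs <- utils::combn(tree$tip.label, 2L)
    for (i in seq_len(ncol(combs))) {
      if (!ape::is.monophyletic(tree, combs[, i])) { pair <- combs[, i]; break }
    }
    if (!is.null(pair)) {
      parMeta <- data.frame(locus_id = character(), subfamily = character(),
                            tsd_len = integer(), stringsAsFactors = FALSE)
      for (k in seq_len(config$parallelInsertions)) {
        repeat {
          q0 <- sample.int(config$genomeLength - 100L, 1L) + 50L
          if (!any(reg$begin <= q0 & reg$guard_end >= q0)) break
        }
        id <- sprintf("par%03d", k)
        state$runId <- state$runId + 1L
        reg <- rbind(reg, data.frame(
          kind = "marker", class = "marker", name = id,
          begin = q0, end = q0, guard_end = q0,
          cons_begin = 1L, cons_end = 1L, run_id = state$runId,
          locus_id = id, stringsAsFactors = FALSE))
        parMeta <- rbind(parMeta, data.frame(
          locus_id = id,
          subfamily = if (length(platy) == 1L) platy else sample(platy, 1L),
          tsd_len = sample(config$tsdRange[1]:config$tsdRange[2], 1L),
          stringsAsFactors = FALSE))
        attr(parMeta, "pair") <- pair
      }
    }
  }

  drawSubfamily <- function(branch) {
    elig <- config$subfamilySchedule[[branch]]
    if (is.null(elig)) elig <- platy
    if (length(elig) == 1L) elig else sample(elig, 1L)
  }

  plantBranch <- function(g, reg, t, branch, isLeafTip = NA) {
    n <- rpois(1L, config$insertionRate * t)
    if (n > 0L) {
      ages <- sort(runif(n) * t, decreasing = TRUE)
      for (a in ages) {
        trunc <- runif(1) < config$truncatedFraction
        sf <- drawSubfamily(branch)
        cb <- if (trunc) sample(6:60, 1L) else 1L
        res <- .plantInsertion(g, reg, sf, cb, a, config, branch, state)
        g <- res$genome; reg <- res$registry
      }
    }
    # forced parallel insertions at marker positions on leaf branches
    if (!is.null(parMeta) && !is.na(isLeafTip) &&
        isLeafTip %in% attr(parMeta, "pair")) {
      for (k in seq_len(nrow(parMeta))) {
        mrow <- which(reg$kind == "marker" &
                        reg$locus_id == parMeta$locus_id[k])
        if (!length(mrow)) next
        res <- .plantInsertion(g, reg, parMeta$subfamily[k], 1L,
                               runif(1) * t, config,
                               paste0("parallel:", parMeta$locus_id[k]),
                               state, forceQ = reg$begin[mrow[1]],
                               forceTsd = parMeta$tsd_len[k],
                               locusId = parMeta$locus_id[k])
        g <- res$genome; reg <- res$registry
      }
    }
    list(genome = g, registry = reg)
  }

  ## stem branch above the root
  g <- .jcMutate(g, config$mu * config$rootLength)
  res <- plantBranch(g, reg, config$rootLength, "root")
  g <- res$genome; reg <- res$registry

  leaves <- list()
  descend <- function(node, g, reg) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    for (child in kids) {
      t <- tree$edge.length[which(tree$edge[, 1] == node &
                                    tree$edge[, 2] == child)[1]]
      isLeaf <- child <= nTips
      label <- if (isLeaf) tree$tip.label[child] else paste0("node", child)
      gc <- .jcMutate(g, config$mu * t)
      res <- plantBranch(gc, reg, t, label,
                         isLeafTip = if (isLeaf) label else NA)
      if (isLeaf) leaves[[label]] <<- res
      else descend(child, res$genome, res$registry)
    }
  }
  descend(nTips + 1L, g, reg)

  ## per-leaf outputs
  truth <- if (length(state$truth)) do.call(rbind, state$truth)
  else data.frame(locus_id = character(), branch = character(),
                  subfamily = character(), cons_begin = integer(),
                  cons_end = integer(), full_length = logical(),
                  tsd = character(), tsd_len = integer(),
                  a_tail_len = integer(), nested = logical(),
                  nested_host = character(), stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  genomes <- list(); annotations <- list(); posrows <- list()
  for (sp in tree$tip.label) {
    gl <- leaves[[sp]]$genome
    rl <- leaves[[sp]]$registry
    rl <- rl[rl$kind != "marker", , drop = FALSE]
    rl <- rl[order(rl$begin), , drop = FALSE]
    genomes[[sp]] <- Biostrings::DNAStringSet(
      stats::setNames(rawToChar(gl), "chr1"))
    seqs <- substring(rawToChar(gl), rl$begin, rl$end)
    pd <- sw <- numeric(nrow(rl))
    for (i in seq_len(nrow(rl))) {
      cfrag <- substr(state$cons[[rl$name[i]]], rl$cons_begin[i],
                      rl$cons_end[i])
      mm <- .pMismatch(seqs[i], cfrag)
      len <- nchar(cfrag)
      pd[i] <- round(100 * mm / len, 1)
      sw[i] <- (len - 2L * mm) * 10L
    }
    annotations[[sp]] <- data.frame(
      sw_score = as.integer(sw), pct_div = pd, pct_del = 0, pct_ins = 0,
      query_name = "chr1", query_begin = rl$begin, query_end = rl$end,
      query_left = length(gl) - rl$end, strand = "+",
      repeat_name = rl$name, repeat_class = rl$class,
      cons_begin = rl$cons_begin, cons_end = rl$cons_end,
      cons_left = nchar(vapply(state$cons[rl$name], identity, character(1))) -
        rl$cons_end,
      run_id = rl$run_id, stringsAsFactors = FALSE)
    el <- rl[rl$kind == "element", , drop = FALSE]
    if (nrow(el))
      posrows[[sp]] <- data.frame(
        locus_id = el$locus_id, species = sp, contig = "chr1",
        start = el$begin, end = el$end, stringsAsFactors = FALSE)
  }
  positions <- if (length(posrows)) do.call(rbind, posrows)
  else data.frame(locus_id = character(), species = character(),
                  contig = character(), start = integer(), end = integer())
  rownames(positions) <- NULL

  ## truth genotype matrix over full-length loci
  clades <- .branchLeafSets(tree)
  flIds <- truth$locus_id[truth$full_length]
  tm <- matrix("0", nrow = length(flIds), ncol = nTips,
               dimnames = list(flIds, tree$tip.label))
  for (i in seq_along(flIds)) {
    b <- truth$branch[truth$locus_id == flIds[i]]
    present <- if (b == "root") tree$tip.label
    else if (startsWith(b, "parallel:")) attr(parMeta, "pair")
    else clades[[b]]
    tm[i, present] <- "1"
  }
  new("SineSimulation", genomes = genomes, annotations = annotations,
      truth = truth, positions = positions, truthMatrix = tm,
      config = config)
}

# map branch label (child node label) -> descendant leaf set
.branchLeafSets <- function(tree) {
  nTips <- length(tree$tip.label)
  out <- list()
  for (child in unique(tree$edge[, 2])) {
    label <- if (child <= nTips) tree$tip.label[child]
    else paste0("node", child)
    out[[label]] <- if (child <= nTips) tree$tip.label[child]
    else ape::extract.clade(tree, child)$tip.label
  }
  out
}

#' Write truth annotations as RepeatMasker .out text
#'
#' Each planted element becomes one annotation row with \code{pct_div}
#' equal to its realized divergence from the consensus; a nested insertion
#' appears as host fragment / element / host fragment with the fragments
#' sharing one run id.
#'
#' @param sim a \code{SineSimulation}.
#' @param dir output directory, or \code{NULL} to return text lines.
#' @return invisibly, a named list of per-species character vectors (the
#'   .out lines); files \code{<species>.out} are written when \code{dir} is
#'   given.
#' @export
emitTruthOut <- function(sim, dir = NULL) {
  out <- lapply(sim@annotations, writeRepeatMaskerOut)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (sp in names(out))
      writeLines(out[[sp]], file.path(dir, paste0(sp, ".out")))
  }
  invisible(out)
}

#' Expected specificity tally from simulator truth
#'
#' Derives each planted full-length locus's specificity category directly
#' from its branch of origin (descent logic, independent of the genotype
#' classifier): stem-branch insertions are fixed present, tip-branch
#' insertions lineage specific, internal branches polymorphic with the
#' matching named clade as sub-category (or Other for tree-incompatible
#' presence sets such as planted parallel insertions).
#'
#' @param sim a \code{SineSimulation}.
#' @param cladeMap a \code{\link{CladeMap}} over the simulated species.
#' @return data.frame: \code{locus_id}, \code{category}, \code{subcategory}.
#' @export
truthCategories <- function(sim, cladeMap) {
  tm <- sim@truthMatrix
  species <- cladeMap@species
  out <- data.frame(locus_id = rownames(tm),
                    category = NA_character_,
                    subcategory = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tm))) {
    present <- species[tm[i, species] == "1"]
    if (length(present) == length(species)) {
      out$category[i] <- "FP"
    } else if (length(present) == 1L) {
      out$category[i] <- "LS"
    } else {
      out$category[i] <- "Poly"
      sub <- "Other"
      for (nm in names(cladeMap@clades)) {
        if (setequal(cladeMap@clades[[nm]], present)) { sub <- nm; break }
      }
      out$subcategory[i] <- sub
    }
  }
  out
}

#' Compare a called genotype matrix with simulator truth
#'
#' Maps each (possibly merged) called row back to its planted locus via the
#' per-carrier coordinates, then scores cell-by-cell agreement with the
#' truth presence/absence matrix ("?" counts as disagreement).
#'
#' @param gm a \code{GenotypeMatrix} built from loci ascertained on
#'   \code{sim}'s genomes.
#' @param loci the \code{LocusSet} the matrix was built from.
#' @param sim the \code{SineSimulation} that produced the genomes.
#' @return list: \code{concordance} (fraction of agreeing cells),
#'   \code{n_cells}, \code{n_rows}, \code{n_truth} (full-length planted
#'   loci), \code{mapped} (called rows mapped to a planted locus),
#'   \code{mismatches} (data.frame of disagreeing cells).
#' @export
compareToTruth <- function(gm, loci, sim) {
  pos <- simPositions(sim)
  info <- locusInfo(loci)
  key <- paste(pos$species, pos$contig, pos$start, pos$end)
  ikey <- paste(info$species, info$contig, info$start, info$end)
  info$truth_id <- pos$locus_id[match(ikey, key)]
  codes <- genotypeCodes(gm)
  tm <- simTruthMatrix(sim)
  rowTruth <- info$truth_id[match(rownames(codes), info$locus_id)]
  ok <- 0L; tot <- 0L
  mism <- list()
  mapped <- 0L
  for (i in seq_len(nrow(codes))) {
    if (is.na(rowTruth[i]) || !rowTruth[i] %in% rownames(tm)) next
    mapped <- mapped + 1L
    tr <- tm[rowTruth[i], colnames(codes)]
    tot <- tot + length(tr)
    ok <- ok + sum(codes[i, ] == tr)
    bad <- which(codes[i, ] != tr)
    for (b in bad)
      mism[[length(mism) + 1L]] <- data.frame(
        locus_id = rownames(codes)[i], truth_id = rowTruth[i],
        species = colnames(codes)[b], called = codes[i, b],
        truth = tr[b], stringsAsFactors = FALSE)
  }
  mismatches <- if (length(mism)) do.call(rbind, mism)
  else data.frame(locus_id = character(), truth_id = character(),
                  species = character(), called = character(),
                  truth = character(), stringsAsFactors = FALSE)
  rownames(mismatches) <- NULL
  list(concordance = if (tot) ok / tot else NA_real_, n_cells = tot,
       n_rows = nrow(codes), n_truth = nrow(tm), mapped = mapped,
       mismatches = mismatches)
}

#' Ascertain full-length loci from every simulated genome
#'
#' Convenience wrapper: per species, restricts the truth annotations to the
#' SINE family, applies the full-length filter and extracts flanked loci.
#'
#' @param sim a \code{SineSimulation}.
#' @param flank flank length in bp.
#' @return a combined \code{LocusSet}.
#' @export
ascertainFromSimulation <- function(sim, flank = 500) {
  lib <- sim@config$library
  consLen <- stats::setNames(Biostrings::width(lib), names(lib))
  parts <- list()
  for (sp in names(simGenomes(sim))) {
    ann <- simAnnotations(sim)[[sp]]
    focal <- ann[ann$repeat_class == "SINE/Platy", , drop = FALSE]
    fl <- filterFullLength(focal, consLen)
    parts[[sp]] <- extractLoci(simGenomes(sim)[[sp]], fl, species = sp,
                               flank = flank)
  }
  combineLoci(parts)
}

#' Simulate a subfamily cohort with planted diagnostic substitutions
#'
#' Generates element copies of a parent consensus: \code{nParent} plain
#' copies plus one daughter cohort per entry of \code{sizes}, each daughter
#' defined by \code{nDiagnostics} fixed substitutions shared by all its
#' members. Every copy then receives independent background divergence.
#' Used to validate subfamily discovery with known membership.
#'
#' @param consensus parent consensus (character or \code{DNAString}).
#' @param sizes integer vector of daughter subfamily sizes (descending or
#'   not; discovery renames by size).
#' @param nParent number of plain parent-derived copies.
#' @param nDiagnostics diagnostics per daughter.
#' @param backgroundDivergence JC dose applied independently to every copy.
#' @param seed RNG seed.
#' @return list: \code{elements} (named \code{DNAStringSet}),
#'   \code{membership} (character: "parent" or "daughter1", ...),
#'   \code{diagnostics} (list of data.frames with \code{pos}, \code{base}).
#' @export
simulateSubfamilyCohort <- function(consensus, sizes = c(30, 15),
                                    nParent = 20, nDiagnostics = 3,
                                    backgroundDivergence = 0.03,
                                    seed = 1L) {
  set.seed(seed)
  consensus <- as.character(consensus)
  L <- nchar(consensus)
  usable <- seq_len(L)
  diagnostics <- list()
  for (k in seq_along(sizes)) {
    pos <- sort(sample(usable, nDiagnostics))
    usable <- setdiff(usable, pos)
    base <- vapply(pos, function(p) {
      cur <- substr(consensus, p, p)
      sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }, character(1))
    diagnostics[[paste0("daughter", k)]] <- data.frame(pos = pos, base = base,
                                                       stringsAsFactors = FALSE)
  }
  seqs <- character(); membership <- character()
  make <- function(tpl) rawToChar(.jcMutate(charToRaw(tpl),
                                            backgroundDivergence))
  for (i in seq_len(nParent)) {
    seqs <- c(seqs, make(consensus)); membership <- c(membership, "parent")
  }
  for (k in seq_along(sizes)) {
    tpl <- consensus
    dg <- diagnostics[[k]]
    for (j in seq_len(nrow(dg))) substr(tpl, dg$pos[j], dg$pos[j]) <- dg$base[j]
    for (i in seq_len(sizes[k])) {
      seqs <- c(seqs, make(tpl))
      membership <- c(membership, paste0("daughter", k))
    }
  }
  names(seqs) <- sprintf("el%03d", seq_along(seqs))
  list(elements = Biostrings::DNAStringSet(seqs),
       membership = stats::setNames(membership, names(seqs)),
       diagnostics = diagnostics)
}
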