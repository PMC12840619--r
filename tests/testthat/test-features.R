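# TPRT hallmark detectors on constructed loci and on simulator truth

featLocus <- function(tailSeq, afterTail, flankL = NULL, elem = NULL,
                      seed = 51) {
  set.seed(seed)
  if (is.null(flankL)) flankL <- randomSeq(200)
  if (is.null(elem)) elem <- paste0(randomSeq(100), "GTCGG")  # non-A end
  makeLocus(flankL, elem, paste0(tailSeq, afterTail), id = "F1")
}

test_that("A-tail measurement follows the windowed-A rule", {
  set.seed(61)
  after <- paste0("G", gsub("A", "C", randomSeq(100)))
  expect_equal(detectATail(featLocus(strrep("A", 30), after)), 30L)
  # one short interruption is tolerated
  tail23 <- paste0(strrep("A", 12), "C", strrep("A", 10))
  expect_equal(detectATail(featLocus(tail23, after)), 23L)
  # no A after the element
  expect_equal(detectATail(featLocus("", after)), 0L)
  # a run of 3 non-A ends the tail
  tailRun <- paste0(strrep("A", 15), "CCC", strrep("A", 20))
  expect_equal(detectATail(featLocus(tailRun, after)), 15L)
})

test_that("TSD detection recovers planted duplications", {
  set.seed(71)
  tsd <- "AGGTCCATC"
  flankL <- paste0(randomSeq(191), tsd)
  after <- paste0(tsd, gsub("A", "T", randomSeq(80)))
  loc <- featLocus(strrep("A", 20), after, flankL = flankL)
  got <- detectTSD(loc)
  expect_equal(got$tsd, tsd)
  expect_true(got$precise)
  # one substitution in the right copy: recovered but imprecise
  after2 <- paste0("AGGTCGATC", gsub("A", "T", randomSeq(80)))
  got2 <- detectTSD(featLocus(strrep("A", 20), after2, flankL = flankL))
  expect_equal(got2$length, 9L)
  expect_false(got2$precise)
  # an A-leading TSD absorbed by the tail is recovered via backoff
  # (a nick T precedes the duplication, as TPRT leaves it)
  tsdA <- "AATGCCGTC"
  flankA <- paste0(randomSeq(190), "T", tsdA)
  afterA <- paste0(tsdA, gsub("A", "T", randomSeq(80)))
  gotA <- detectTSD(featLocus(strrep("A", 20), afterA, flankL = flankA))
  expect_equal(gotA$tsd, tsdA)
  expect_true(gotA$precise)
  expect_equal(gotA$backoff, 2L)
})

test_that("random flanks almost never produce a TSD", {
  set.seed(81)
  hits <- 0L
  n <- 400L
  for (i in seq_len(n)) {
    loc <- makeLocus(randomSeq(120), paste0(randomSeq(100), "GTCGG"),
                     randomSeq(120), id = "N1")
    got <- detectTSD(loc, aTailLength = detectATail(loc))
    if (got$length > 0L) hits <- hits + 1L
  }
  expect_lt(hits / n, 0.02)
})

test_that("cleavage-site grading compares the 6 bp motif to TTTT|AA", {
  mkC <- function(motif4, tsdStart2) {
    tsd <- paste0(tsdStart2, "GTCCATC")
    flankL <- paste0(randomSeq(180, seed = 91), motif4, tsd)
    after <- paste0(tsd, gsub("A", "T", randomSeq(60)))
    featLocus(strrep("A", 15), after, flankL = flankL)
  }
  expect_equal(detectCleavage(mkC("TTTT", "AA")), "canonical")
  expect_equal(detectCleavage(mkC("TTTC", "AA")), "near")
  expect_equal(detectCleavage(mkC("GGGG", "CC")), "none")
  # no TSD -> none
  loc <- makeLocus(gsub("A", "C", randomSeq(120, seed = 92)),
                   paste0(randomSeq(100, seed = 93), "GTCGG"),
                   gsub("A", "G", randomSeq(120, seed = 94)), id = "C1")
  expect_equal(detectCleavage(loc), "none")
})

test_that("termination scan finds the nearest downstream TTTT", {
  tsd <- "AGGTCCATC"
  flankL <- paste0(randomSeq(191, seed = 95), tsd)
  noT <- function(n, seed) gsub("T", "C", randomSeq(n, seed = seed))
  # planted 22 bp downstream of the 3' TSD
  after <- paste0(tsd, noT(22, 96), "TTTT", noT(60, 97))
  expect_equal(findTermination(featLocus(strrep("A", 18), after,
                                         flankL = flankL)), 22L)
  # immediately adjacent
  after0 <- paste0(tsd, "TTTT", noT(60, 98))
  expect_equal(findTermination(featLocus(strrep("A", 18), after0,
                                         flankL = flankL)), 0L)
  # absent within the scan limit
  afterNone <- paste0(tsd, noT(240, 99))
  expect_true(is.na(findTermination(featLocus(strrep("A", 18), afterNone,
                                              flankL = flankL))))
})

test_that("with mu = 0 every planted TSD is recovered exactly and precise", {
  sim <- tinySim(seed = 14, mu = 0)
  lib <- sim@config$library
  consLen <- stats::setNames(Biostrings::width(lib), names(lib))
  truth <- simTruth(sim)
  checked <- 0L
  for (sp in names(simGenomes(sim))) {
    ann <- simAnnotations(sim)[[sp]]
    focal <- ann[ann$repeat_class == "SINE/Platy", ]
    fl <- filterFullLength(focal, consLen)
    loci <- extractLoci(simGenomes(sim)[[sp]], fl, species = sp)
    info <- locusInfo(loci)
    pos <- simPositions(sim)
    posSp <- pos[pos$species == sp, ]
    ids <- posSp$locus_id[match(info$start, posSp$start)]
    feats <- locusFeatures(loci)
    for (i in seq_len(nrow(feats))) {
      tr <- truth[truth$locus_id == ids[i], ]
      expect_identical(feats$tsd[i], tr$tsd)
      expect_true(feats$tsd_precise[i])
      # a TSD beginning with adenines is absorbed into the measured tail,
      # so the planted length is recovered within the interruption band
      expect_gte(feats$a_tail_length[i], tr$a_tail_len)
      expect_lte(feats$a_tail_length[i] - tr$a_tail_len, 10L)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 20L)
})
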