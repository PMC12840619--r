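# constructed locus/target pairs exercise seeding, alignment and calling;
# simulator truth exercises the full matrix path (see also test-acceptance)

makePresencePair <- function(seed = 31) {
  set.seed(seed)
  flankL <- randomSeq(500)
  flankR <- randomSeq(500)
  elem <- randomSeq(110)
  tsd <- "AGGTCCATC"
  tail <- strrep("A", 15)
  locus <- makeLocus(paste0(flankL, tsd), paste0(elem, tail),
                     paste0(tsd, flankR), id = "P1")
  list(locus = locus, flankL = flankL, flankR = flankR, elem = elem,
       tsd = tsd, tail = tail,
       present = paste0(randomSeq(800), flankL, tsd, elem, tail, tsd,
                        flankR, randomSeq(800)),
       absent = paste0(randomSeq(800), flankL, tsd, flankR,
                       randomSeq(800)))
}

test_that("two-flank seeding finds the orthologous site once", {
  p <- makePresencePair()
  g <- Biostrings::DNAStringSet(c(chr1 = p$present))
  win <- findCandidateWindows(p$locus, g)
  expect_equal(nrow(win), 1L)
  expect_lte(win$start, 801)
  expect_gte(win$end, 800 + nchar(p$present) - 1600)
  expect_equal(win$strand, "+")
  # a tandem duplication of the site yields two windows
  g2 <- Biostrings::DNAStringSet(c(chr1 = paste0(
    p$present, randomSeq(3000), substr(p$present, 801, nchar(p$present) - 800))))
  win2 <- findCandidateWindows(p$locus, g2)
  expect_gte(nrow(win2), 2L)
  # all-N target yields no windows
  gN <- Biostrings::DNAStringSet(c(chr1 = strrep("N", 5000)))
  expect_equal(nrow(findCandidateWindows(p$locus, gN)), 0L)
  # reverse-complement targets are found on the minus strand
  gR <- Biostrings::DNAStringSet(c(chr1 = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(p$present)))))
  winR <- findCandidateWindows(p$locus, gR)
  expect_gte(nrow(winR), 1L)
  expect_equal(winR$strand[1], "-")
})

test_that("alignment reports identity, coverage and the absence gap", {
  p <- makePresencePair()
  # identical target: full identity, no gap over the element
  alP <- alignLocus(p$locus, p$present)
  expect_gte(alP$ident_left, 0.999)
  expect_gte(alP$ident_right, 0.999)
  expect_gte(alP$elem_aligned, 0.999)
  expect_equal(alP$gap_cover, 0)
  # pre-integration site: single gap of element + A-tail + one TSD copy
  alA <- alignLocus(p$locus, p$absent)
  expect_gte(alA$gap_cover, 0.99)
  expect_equal(alA$gap_len,
               nchar(p$elem) + nchar(p$tail) + nchar(p$tsd))
  expect_lt(alA$elem_aligned, 0.1)
  # ~10% diverged flanks give ~0.9 flank identity
  set.seed(40)
  mutate <- function(s, p) {
    v <- strsplit(s, "")[[1]]
    i <- which(stats::runif(length(v)) < p)
    v[i] <- vapply(v[i], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(v, collapse = "")
  }
  div <- paste0(mutate(p$flankL, 0.1), p$tsd, p$elem, p$tail, p$tsd,
                mutate(p$flankR, 0.1))
  alD <- alignLocus(p$locus, div)
  expect_lt(abs(alD$ident_left - 0.9), 0.05)
  expect_lt(abs(alD$ident_right - 0.9), 0.05)
  expect_error(alignLocus(p$locus, "ACGTACGT"), "window")
})

test_that("genotype calls follow the decision rules", {
  p <- makePresencePair()
  th <- genotypeThresholds()
  g1 <- callGenotype(p$locus, list(alignLocus(p$locus, p$present)))
  expect_equal(g1$code, "1")
  g0 <- callGenotype(p$locus, list(alignLocus(p$locus, p$absent)))
  expect_equal(g0$code, "0")
  expect_equal(g0$gap_len, nchar(p$elem) + nchar(p$tail) + nchar(p$tsd))
  # no windows -> missing with reason
  gq <- callGenotype(p$locus, list())
  expect_equal(gq$code, "?")
  expect_equal(gq$reason, "no hit")
  # a 600 bp target-side deletion spanning the site -> gap outside window
  set.seed(33)
  bigdel <- paste0(substr(p$absent, 1, 800 + 250),
                   substr(p$absent, 800 + 250 + 600, nchar(p$absent)))
  gdel <- callGenotype(p$locus, list(alignLocus(p$locus, bigdel)))
  expect_equal(gdel$code, "?")
  expect_equal(gdel$reason, "gap outside window")
  # ambiguous multi-hit when two windows score within the margin
  amb <- callGenotype(p$locus, list(alignLocus(p$locus, p$present),
                                    alignLocus(p$locus, p$present)))
  expect_equal(amb$code, "?")
  expect_equal(amb$reason, "ambiguous multi-hit")
  # short-flank loci report missing
  shortLocus <- makeLocus(substr(p$flankL, 470, 500),
                          paste0(p$elem, p$tail), p$flankR, id = "S1")
  gs <- callGenotype(shortLocus, list(alignLocus(shortLocus, p$present)))
  expect_equal(gs$code, "?")
  expect_equal(gs$reason, "short flank")
})

test_that("matrix building merges reciprocal duplicates and forces the
          source to 1", {
  p <- makePresencePair()
  gA <- Biostrings::DNAStringSet(c(chr1 = p$present))
  gB <- Biostrings::DNAStringSet(c(chr1 = paste0(randomSeq(300),
                                                 p$present)))
  gC <- Biostrings::DNAStringSet(c(chr1 = p$absent))
  # ascertain the same insertion independently from A and B
  # element (elem + tail) starts at 800 + 500 + 9 + 1 in genome A and
  # 300 later in genome B
  lA <- makeLocus(paste0(substr(p$flankL, 192, 500), p$tsd),
                  paste0(p$elem, p$tail),
                  substr(paste0(p$tsd, p$flankR), 1, 300),
                  species = "A", start = 1310L, id = "A_chr1")
  lB <- makeLocus(paste0(substr(p$flankL, 192, 500), p$tsd),
                  paste0(p$elem, p$tail),
                  substr(paste0(p$tsd, p$flankR), 1, 300),
                  species = "B", start = 1610L, id = "B_chr1")
  loci <- combineLoci(lA, lB)
  gm <- buildGenotypeMatrix(loci, list(A = gA, B = gB, C = gC))
  codes <- genotypeCodes(gm)
  expect_equal(nrow(codes), 1L)
  expect_equal(unname(codes[1, ]), c("1", "1", "0"))
  expect_setequal(gm@members[[1]], c("A_chr1", "B_chr1"))
  expect_equal(unname(genotypeSource(gm)[1]) %in% c("A", "B"), TRUE)
  # empty locus set gives an empty matrix
  empty <- buildGenotypeMatrix(
    extractLoci(gA, data.frame()[0, ],  species = "A"),
    list(A = gA, B = gB))
  expect_equal(nrow(genotypeCodes(empty)), 0L)
})
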