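test_that("simulation is deterministic given the seed", {
  cfg <- simulationConfig(genomeLength = 5e4, insertionRate = 6, seed = 9)
  s1 <- simulateClade(cfg)
  s2 <- simulateClade(cfg)
  expect_identical(lapply(simGenomes(s1), as.character),
                   lapply(simGenomes(s2), as.character))
  expect_identical(simTruth(s1), simTruth(s2))
  expect_identical(simTruthMatrix(s1), simTruthMatrix(s2))
  s3 <- simulateClade(simulationConfig(genomeLength = 5e4,
                                       insertionRate = 6, seed = 10))
  expect_false(identical(simTruth(s1), simTruth(s3)))
})

test_that("presence sets follow descent along the tree", {
  sim <- tinySim(seed = 21)
  tree <- ape::read.tree(text = sim@config$tree)
  tm <- simTruthMatrix(sim)
  truth <- simTruth(sim)
  for (i in seq_len(nrow(tm))) {
    b <- truth$branch[truth$locus_id == rownames(tm)[i]]
    present <- colnames(tm)[tm[i, ] == "1"]
    if (b == "root") {
      expect_setequal(present, tree$tip.label)
    } else if (b %in% tree$tip.label) {
      expect_identical(present, b)
    } else {
      node <- as.integer(sub("node", "", b))
      expect_setequal(present, ape::extract.clade(tree, node)$tip.label)
    }
  }
})

test_that("with mu = 0 planted elements equal consensus + A-tail exactly", {
  sim <- tinySim(seed = 4, mu = 0)
  lib <- as.character(sim@config$library)
  pos <- simPositions(sim)
  truth <- simTruth(sim)
  for (i in seq_len(nrow(pos))) {
    tr <- truth[truth$locus_id == pos$locus_id[i], ]
    g <- simGenomes(sim)[[pos$species[i]]][[pos$contig[i]]]
    got <- as.character(Biostrings::subseq(
      g, pos$start[i], pos$end[i] + tr$a_tail_len))
    cons <- substr(lib[[tr$subfamily]], tr$cons_begin, tr$cons_end)
    expect_identical(got, paste0(cons, strrep("A", tr$a_tail_len)))
    # TSD flanks element + A-tail identically on both sides
    left <- as.character(Biostrings::subseq(
      g, pos$start[i] - tr$tsd_len, pos$start[i] - 1L))
    right <- as.character(Biostrings::subseq(
      g, pos$end[i] + tr$a_tail_len + 1L,
      pos$end[i] + tr$a_tail_len + tr$tsd_len))
    expect_identical(left, right)
    expect_identical(left, tr$tsd)
  }
})

test_that("realized element divergence matches the Jukes-Cantor expectation", {
  # one long tip branch, many insertions of age ~ U(0, t): the mean
  # realized divergence over ages integrates the JC curve
  mu <- 0.08; t <- 1
  cfg <- simulationConfig(tree = "(A:1,B:0.01);", rootLength = 0,
                          genomeLength = 6e5, insertionRate = 260,
                          mu = mu, truncatedFraction = 0,
                          nestedFraction = 0, seed = 12)
  sim <- simulateClade(cfg)
  ann <- simAnnotations(sim)$A
  el <- ann[ann$repeat_class == "SINE/Platy", ]
  expect_gt(nrow(el), 200)
  p <- el$pct_div / 100
  # E[p] = (1/t) integral_0^t 3/4 (1 - e^{-4/3 mu a}) da
  expectP <- 0.75 * (1 - (1 - exp(-4 / 3 * mu * t)) / (4 / 3 * mu * t))
  se <- stats::sd(p) / sqrt(length(p))
  expect_lt(abs(mean(p) - expectP), 3 * se + 1e-3)
})

test_that("nested fraction approaches its configured value", {
  sim <- simulateClade(simulationConfig(
    tree = "(A:1,B:0.01);", rootLength = 0, genomeLength = 6e5,
    insertionRate = 200, nestedFraction = 0.25, seed = 8))
  truth <- simTruth(sim)
  n <- nrow(truth)
  phat <- mean(truth$nested)
  tol <- 3 * sqrt(0.25 * 0.75 / n)
  expect_lt(abs(phat - 0.25), tol + 0.02)
  expect_true(all(truth$nested_host[truth$nested] %in% c("Alu", "L1")))
})

test_that("truth .out encodes nesting as co-identified fragments", {
  sim <- tinySim(seed = 5, mu = 0)
  truth <- simTruth(sim)
  nested <- truth[truth$nested, ]
  expect_gt(nrow(nested), 0)
  pos <- simPositions(sim)
  found <- 0L
  for (i in seq_len(nrow(nested))) {
    pp <- pos[pos$locus_id == nested$locus_id[i], ]
    for (j in seq_len(nrow(pp))) {
      ann <- simAnnotations(sim)[[pp$species[j]]]
      k <- which(ann$query_begin == pp$start[j] &
                   ann$query_end == pp$end[j])
      expect_length(k, 1L)
      up <- ann[k - 1L, ]; dn <- ann[k + 1L, ]
      expect_identical(up$run_id, dn$run_id)
      expect_identical(up$repeat_name, dn$repeat_name)
      expect_equal(dn$cons_begin, up$cons_end + 1L)
      found <- found + 1L
    }
  }
  expect_gt(found, 0L)
  # non-nested insertions are single rows with fresh run ids
  plain <- truth[!truth$nested, ][1, ]
  pp <- pos[pos$locus_id == plain$locus_id, ][1, ]
  ann <- simAnnotations(sim)[[pp$species]]
  k <- which(ann$query_begin == pp$start)
  expect_length(k, 1L)
  # zero divergence at mu = 0
  expect_equal(ann$pct_div[k], 0)
  # .out text emission round-trips the annotation table
  lines <- emitTruthOut(sim)[[pp$species]]
  expect_equal(readRepeatMaskerOut(lines), ann)
})

test_that("invalid trees and oversized configs are rejected", {
  expect_error(simulateClade(simulationConfig(tree = "not a tree ((")),
               "tree|parse")
  expect_error(simulateClade(simulationConfig(genomeLength = 1e6,
                                              insertionRate = 1e6,
                                              sizeCap = 2e6)),
               "sizeCap")
})
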