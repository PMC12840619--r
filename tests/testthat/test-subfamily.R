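lib4 <- local({
  l <- syntheticConsensusLibrary()
  l[S4Vectors::metadata(l)$class[names(l)] == "SINE/Platy"]
})

test_that("assignment is exact on consensus identity and counts mismatches", {
  res <- assignSubfamily(as.character(lib4[["Platy-1-4a"]]), lib4)
  expect_equal(res$subfamily, "Platy-1-4a")
  expect_equal(res$pct_div, 0)
  # 5 substitutions over 100 aligned columns -> 5% divergence
  cons <- paste(rep(c("ACGTG"), 20), collapse = "")
  el <- cons
  for (p in c(3, 23, 48, 71, 94))
    substr(el, p, p) <- setdiff(c("A", "C", "G", "T"),
                                substr(el, p, p))[1]
  one <- Biostrings::DNAStringSet(c(X = cons))
  res2 <- assignSubfamily(el, one)
  expect_equal(res2$pct_div, 5.0)
  expect_equal(res2$align_length, 100L)
  expect_error(assignSubfamily("ACGT", lib4[0]), "empty")
})

test_that("assignment is deterministic and ties break by library order", {
  dup <- Biostrings::DNAStringSet(c(B = as.character(lib4[[1]]),
                                    A = as.character(lib4[[1]])))
  res <- assignSubfamily(as.character(lib4[[1]]), dup)
  expect_equal(res$subfamily, "B")   # first in library order wins the tie
  # permuting distinct consensi does not change the winner
  res1 <- assignSubfamily(as.character(lib4[["Platy-1-5"]]), lib4)
  res2 <- assignSubfamily(as.character(lib4[["Platy-1-5"]]), rev(lib4))
  expect_equal(res1$subfamily, res2$subfamily)
})

test_that("simulated cohorts assign to their true subfamily", {
  set.seed(101)
  n <- 40
  els <- character(n); want <- character(n)
  for (i in seq_len(n)) {
    sf <- sample(names(lib4), 1)
    want[i] <- sf
    els[i] <- rawToChar(sineScout:::.jcMutate(
      charToRaw(as.character(lib4[[sf]])), 0.03))
  }
  got <- assignSubfamilies(
    Biostrings::DNAStringSet(stats::setNames(els, sprintf("e%02d", 1:n))),
    lib4)
  expect_gte(mean(got$subfamily == want), 0.95)
})

test_that("reassignment deltas are arithmetic on scores", {
  els <- Biostrings::DNAStringSet(c(a = as.character(lib4[[1]]),
                                    b = as.character(lib4[[2]])))
  same <- reassignmentDelta(els, lib4, lib4)
  expect_true(all(same$per_element$delta_sw == 0))
  expect_true(all(same$per_element$delta_pct_div == 0))
  expect_equal(same$summary$mean_delta_sw, 0)
})

test_that("discovery recovers planted daughter subfamilies and names by
          size", {
  parent <- as.character(lib4[["Platy-1-4a"]])
  coh <- simulateSubfamilyCohort(parent, sizes = c(30, 15), nParent = 20,
                                 nDiagnostics = 3,
                                 backgroundDivergence = 0.03, seed = 7)
  models <- discoverSubfamilies(coh$elements, parent)
  expect_length(models, 2L)
  expect_equal(vapply(models, `[[`, character(1), "name"), c("sf0", "sf1"))
  sizes <- vapply(models, function(m) length(m$members), integer(1))
  expect_true(sizes[1] >= sizes[2])
  for (k in 1:2) {
    truthMembers <- names(coh$membership)[
      coh$membership == paste0("daughter", k)]
    got <- models[[k]]$members
    precision <- mean(got %in% truthMembers)
    recall <- mean(truthMembers %in% got)
    expect_gte(precision, 0.9)
    expect_gte(recall, 0.9)
    # planted diagnostics are recovered in the model
    dg <- coh$diagnostics[[k]]
    key <- paste(models[[k]]$diagnostics$pos, models[[k]]$diagnostics$derived)
    expect_true(all(paste(dg$pos, dg$base) %in% key))
  }
  # exact consensus copies alone yield no subfamilies
  exact <- Biostrings::DNAStringSet(
    stats::setNames(rep(parent, 15), sprintf("x%02d", 1:15)))
  expect_length(discoverSubfamilies(exact, parent), 0L)
  # fewer elements than minCount is an empty result, not an error
  expect_length(discoverSubfamilies(exact[1:3], parent), 0L)
})

test_that("library augmentation improves divergence for daughter cohorts", {
  parent <- as.character(lib4[["Platy-1-4a"]])
  coh <- simulateSubfamilyCohort(parent, sizes = c(25), nParent = 5,
                                 nDiagnostics = 3, seed = 11)
  models <- discoverSubfamilies(coh$elements, parent)
  expect_gte(length(models), 1L)
  newLib <- c(lib4, Biostrings::DNAStringSet(
    stats::setNames(models[[1]]$consensus, "sf0")))
  daughters <- coh$elements[coh$membership == "daughter1"]
  delta <- reassignmentDelta(daughters, lib4, newLib)
  expect_gt(delta$summary$mean_delta_pct_div, 0)
  expect_gt(delta$summary$mean_delta_sw, 0)
})
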