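cm <- thirteenTaxa()

test_that("category precedence follows the taxonomy definitions", {
  all13 <- cm@species
  # fixed present across all genomes
  expect_equal(classifyLocus(codeRow(present = all13), cm)$category, "FP")
  # FP tolerates missing codes below the MV threshold
  r <- codeRow(present = setdiff(all13, c("titi", "owl")),
               missing = c("titi", "owl"))
  expect_equal(classifyLocus(r, cm)$category, "FP")
  # unique to one genome
  expect_equal(classifyLocus(codeRow(present = "saki"), cm)$category, "LS")
  # a second 1 demotes LS to Poly
  expect_equal(classifyLocus(codeRow(present = c("saki", "owl")), cm)$category,
               "Poly")
  # seven or more missing of thirteen -> MV, regardless of the rest
  expect_equal(cm@mvThreshold, 7L)
  r <- codeRow(present = all13[1:6], missing = all13[7:13])
  expect_equal(classifyLocus(r, cm)$category, "MV")
  r6 <- codeRow(present = all13[1:7], missing = all13[8:13])
  expect_false(classifyLocus(r6, cm)$category == "MV")
  # species mismatch errors
  expect_error(classifyLocus(c(saki = "1"), cm), "species")
})

test_that("polymorphic sub-categories match named clades with ?
          excluded from the comparison", {
  out <- classifyLocus(codeRow(present = c("howler", "spider1", "spider2")),
                       cm)
  expect_equal(out$category, "Poly")
  expect_equal(out$subcategory, "Atelidae")
  expect_false(out$ils)
  out <- classifyLocus(codeRow(present = c("spider1", "spider2")), cm)
  expect_equal(out$subcategory, "Ateles")
  out <- classifyLocus(codeRow(present = c("cap1", "cap2", "cap3"),
                               missing = "titi"), cm)
  expect_equal(out$subcategory, "Cap")
  # a missing clade member still matches once excluded
  out <- classifyLocus(codeRow(present = c("howler", "spider1"),
                               missing = "spider2"), cm)
  expect_equal(out$subcategory, "Atelidae")
  # presence set that is no named clade and not a tree clade: Other + ILS
  out <- classifyLocus(codeRow(present = c("saki", "squirrel")), cm)
  expect_equal(out$subcategory, "Other")
  expect_true(out$ils)
  # deletion flag from call evidence
  out <- classifyLocus(codeRow(present = c("saki", "squirrel")), cm,
                       reasons = c(titi = "gap outside window"))
  expect_true(out$deletion)
})

test_that("classification is invariant to species column order", {
  r <- codeRow(present = c("cap1", "cap2", "cap3", "squirrel"))
  shuffled <- r[rev(cm@species)]
  expect_equal(classifyLocus(r, cm), classifyLocus(shuffled, cm))
  expect_equal(classifyLocus(r, cm)$subcategory, "Saimiri and Cap")
})

test_that("summary partitions loci per ascertainment species", {
  set.seed(17)
  species <- cm@species
  n <- 40
  codes <- matrix("0", n, length(species),
                  dimnames = list(sprintf("L%02d", 1:n), species))
  src <- character(n)
  for (i in 1:n) {
    kind <- sample(c("FP", "LS", "Poly", "MV"), 1)
    row <- switch(kind,
      FP = codeRow(present = species),
      LS = codeRow(present = "howler"),
      Poly = codeRow(present = c("spider1", "spider2")),
      MV = codeRow(present = "saki", missing = species[5:12]))
    codes[i, ] <- row[species]
    src[i] <- species[which(row == "1")[1]]
  }
  gm <- new("GenotypeMatrix", codes = codes,
            evidence = data.frame(), members = list(),
            source = stats::setNames(src, rownames(codes)))
  calls <- classifySpecificity(gm, cm)
  expect_equal(nrow(calls), n)
  # categories partition loci
  expect_true(all(table(calls$locus_id) == 1))
  summ <- summarizeSpecificity(gm, cm, calls)
  expect_equal(summ$FP + summ$LS + summ$MV + summ$Poly, summ$total)
  subCols <- c(names(cm@clades), "Other")
  expect_equal(rowSums(summ[, subCols]), summ$Poly,
               ignore_attr = TRUE)
  expect_equal(sum(summ$total), n)
  # a species with no ascertained loci has an all-zero row
  none <- summ[summ$species %in% setdiff(species, src), ]
  if (nrow(none)) expect_true(all(none$total == 0))
})

test_that("homoplasy-free simulated truth classifies without Other", {
  sim <- tinySim(seed = 13)
  cmSim <- sineScout:::.cladeMapFromTree(sim@config$tree)
  tc <- truthCategories(sim, cmSim)
  calls <- classifySpecificity(simTruthMatrix(sim), cmSim)
  expect_equal(calls$category, tc$category)
  poly <- calls[calls$category == "Poly", ]
  expect_false(any(poly$subcategory == "Other"))
  expect_equal(poly$subcategory,
               tc$subcategory[tc$category == "Poly"])
})
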