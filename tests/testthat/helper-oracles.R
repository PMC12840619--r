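# Brute-force oracles for the landscape statistics: implemented
# independently of the package paths they check, and shared by the unit
# and acceptance suites.

oracleProximity <- function(focal, ann, D = 50) {
  classes <- sort(unique(ann$repeat_class))
  gapDist <- function(a1, a2, b1, b2) {
    if (a2 < b1) b1 - a2 - 1L else if (b2 < a1) a1 - b2 - 1L else 0L
  }
  sapply(classes, function(cl) {
    hits <- 0L
    for (i in seq_len(nrow(focal))) {
      found <- FALSE
      for (j in seq_len(nrow(ann))) {
        if (ann$repeat_class[j] != cl) next
        if (ann$query_name[j] != focal$query_name[i]) next
        same <- ann$query_begin[j] == focal$query_begin[i] &&
          ann$query_end[j] == focal$query_end[i] &&
          ann$repeat_name[j] == focal$repeat_name[i]
        if (same) next
        if (gapDist(focal$query_begin[i], focal$query_end[i],
                    ann$query_begin[j], ann$query_end[j]) <= D)
          found <- TRUE
      }
      hits <- hits + found
    }
    hits
  })
}

oracleContent <- function(ann, genomeSizes) {
  classes <- sort(unique(ann$repeat_class))
  sapply(classes, function(cl) {
    bp <- 0L
    for (ct in names(genomeSizes)) {
      mask <- logical(genomeSizes[[ct]])
      sub <- ann[ann$repeat_class == cl & ann$query_name == ct, ]
      for (j in seq_len(nrow(sub)))
        mask[sub$query_begin[j]:sub$query_end[j]] <- TRUE
      bp <- bp + sum(mask)
    }
    bp
  })
}

oracleNestedContainment <- function(ann, focalClass = "SINE/Platy") {
  keys <- character()
  for (i in seq_len(nrow(ann))) {
    if (ann$repeat_class[i] != focalClass) next
    hosts <- 0L
    for (j in seq_len(nrow(ann))) {
      if (j == i) next
      if (ann$query_name[j] != ann$query_name[i]) next
      if (ann$query_begin[j] < ann$query_begin[i] &&
          ann$query_end[j] > ann$query_end[i])
        hosts <- hosts + 1L
    }
    if (hosts >= 1L)
      keys <- c(keys, sprintf("%s:%d-%d", ann$query_name[i],
                              ann$query_begin[i], ann$query_end[i]))
  }
  keys
}

randomAnnotations <- function(n, size = 5e4, classes =
                                c("SINE/Platy", "SINE/Alu", "LINE/L1")) {
  qb <- sample.int(size - 400L, n, replace = TRUE)
  len <- sample(80:350, n, replace = TRUE)
  data.frame(sw_score = 100L, pct_div = round(stats::runif(n, 0, 30), 1),
             pct_del = 0, pct_ins = 0, query_name = "chr1",
             query_begin = qb, query_end = qb + len,
             query_left = size - qb - len, strand = "+",
             repeat_name = sample(classes, n, replace = TRUE),
             repeat_class = sample(classes, n, replace = TRUE),
             cons_begin = 1L, cons_end = len + 1L, cons_left = 0L,
             run_id = seq_len(n), stringsAsFactors = FALSE)
}

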