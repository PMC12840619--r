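# Internal sequence helpers. Genomes are manipulated as raw byte vectors
# during simulation (fast in-place-ish edits), and as Biostrings objects at
# every module boundary.

.BASES <- charToRaw("ACGT")

## raw <-> character
.rawToSeq <- function(r) rawToChar(r)
.seqToRaw <- function(s) charToRaw(s)

#' @importFrom stats runif rbinom rpois rgeom
.randomDNA <- function(n) {
  .BASES[sample.int(4L, n, replace = TRUE)]
}

# Apply a Jukes-Cantor substitution process for total dose mu*t to a raw
# genome. Each site is hit with probability p = 3/4 (1 - exp(-4/3 mu t)) and
# replaced by one of the three other bases uniformly; composing branches
# reproduces the JC transition matrix for the summed dose.
.jcMutate <- function(r, dose) {
  if (dose <= 0 || length(r) == 0L) return(r)
  p <- 0.75 * (1 - exp(-4 / 3 * dose))
  n <- rbinom(1L, length(r), p)
  if (n == 0L) return(r)
  pos <- sample.int(length(r), n)
  cur <- match(r[pos], .BASES)          # NA for N etc: leave untouched
  ok <- !is.na(cur)
  pos <- pos[ok]; cur <- cur[ok]
  if (!length(pos)) return(r)
  shift <- sample.int(3L, length(pos), replace = TRUE)
  r[pos] <- .BASES[((cur - 1L + shift) %% 4L) + 1L]
  r
}

# JC expected proportion of differing sites after dose mu*t
.jcExpectedP <- function(dose) 0.75 * (1 - exp(-4 / 3 * dose))

# Hamming p-distance between two equal-length raw/char sequences
.pMismatch <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  av <- charToRaw(a); bv <- charToRaw(b)
  sum(av != bv)
}

# nucleotide substitution matrix where N never matches anything
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
.scoreMatrix <- function(match = 1, mismatch = -1) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

.revcompChar <- function(s) {
  as.character(reverseComplement(DNAString(s)))
}

# split a vector of positions into clusters separated by more than `gap`
.clusterPositions <- function(pos, gap) {
  o <- order(pos)
  pos <- pos[o]
  brk <- c(0L, which(diff(pos) > gap), length(pos))
  lapply(seq_len(length(brk) - 1L), function(i) {
    idx <- (brk[i] + 1L):brk[i + 1L]
    list(positions = pos[idx], order = o[idx])
  })
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
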