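# Independent oracles and fixture builders used across the suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(len) paste(sample(AA20, len, replace = TRUE),
                                 collapse = "")

## random stop-free CDS of `len` codons
random_cds <- function(len) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste(sample(sense, len, replace = TRUE), collapse = "")
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

## Brute-force optimal global alignment score with affine gaps (a gap of
## length L costs open + L * extend) by explicit enumeration of all
## monotone alignments -- independent of any dynamic programming.
bf_global_score <- function(a, b, sm, gap_open = 11, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av)
  lb <- length(bv)
  rec <- function(i, j, last) {
    if (i > la && j > lb) return(0)
    best <- -Inf
    if (i <= la && j <= lb)
      best <- max(best, sm[av[i], bv[j]] + rec(i + 1L, j + 1L, "M"))
    if (i <= la)
      best <- max(best,
                  -(if (last == "D") gap_extend else gap_open + gap_extend) +
                    rec(i + 1L, j, "D"))
    if (j <= lb)
      best <- max(best,
                  -(if (last == "I") gap_extend else gap_open + gap_extend) +
                    rec(i, j + 1L, "I"))
    best
  }
  rec(1L, 1L, "M")
}

## Brute-force local score: best global score over all substring pairs,
## floored at 0 (the empty alignment).
bf_local_score <- function(a, b, sm, gap_open = 11, gap_extend = 1) {
  best <- 0
  la <- nchar(a)
  lb <- nchar(b)
  for (i1 in seq_len(la)) for (i2 in i1:la)
    for (j1 in seq_len(lb)) for (j2 in j1:lb)
      best <- max(best, bf_global_score(substr(a, i1, i2), substr(b, j1, j2),
                                        sm, gap_open, gap_extend))
  best
}

## Exact two-sided signed-rank p by full enumeration of all 2^n sign
## assignments (n <= ~14).
enum_wilcoxon_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  Ws <- vapply(0:(2^n - 1), function(m) {
    bits <- bitwAnd(m, 2^(0:(n - 1))) > 0
    sum(r[bits])
  }, numeric(1))
  min(1, 2 * min(mean(Ws <= W), mean(Ws >= W)))
}

## The published diploid 7-component mixture (printed means on the Ks
## scale, log-scale variances, mixing proportions); used as a simulation
## input for recovery checks.
diploid_mixture <- function() {
  props <- c(0.091, 0.074, 0.079, 0.278, 0.265, 0.176, 0.036)
  list(means_ks = c(0.128, 0.238, 0.499, 1.148, 1.526, 2.989, 4.561),
       vars_log = c(0.0004, 0.0048, 0.0248, 0.0461, 0.1619, 0.6015, 0.0790),
       props = props / sum(props))
}

sim_diploid_mixture <- function(seed, n = 8364L) {
  p <- diploid_mixture()
  withr::with_seed(seed, {
    z <- sample.int(7L, n, replace = TRUE, prob = p$props)
    stats::rnorm(n, log(p$means_ks)[z], sqrt(p$vars_log)[z])
  })
}
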