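test_that("NG86 reproduces hand-derived counts", {
  ## 10 Gly codons, one synonymous third-position difference:
  ## S = 10, N = 20, pS = 0.1, Ks = -0.75 log(1 - 0.4/3)
  aln <- codon_alignment("a", "b", rep("GGT", 10),
                         c(rep("GGT", 9), "GGC"))
  e <- ng86(aln)
  expect_equal(e$S, 10)
  expect_equal(e$N, 20)
  expect_equal(e$Sd, 1)
  expect_equal(e$Nd, 0)
  expect_equal(e$ks, -0.75 * log(1 - 0.4 / 3))
  expect_equal(e$ka, 0)
  expect_false(e$saturated)

  ## single TTT/TTC codon: one synonymous difference over 1/3 synonymous
  ## site -> pS = 3 > 3/4, saturated
  e2 <- suppressWarnings(ng86(codon_alignment("a", "b", "TTT", "TTC")))
  expect_equal(e2$S, 1 / 3)
  expect_true(e2$saturated)
  expect_true(is.na(e2$ks))

  ## identical sequences
  e3 <- suppressWarnings(ng86(codon_alignment("a", "b",
                                              c("ATG", "GAA", "TGC"),
                                              c("ATG", "GAA", "TGC"))))
  expect_equal(e3$ks, 0)
  expect_equal(e3$ka, 0)
})

test_that("NG86 is symmetric in its two sequences", {
  withr::with_seed(5, {
    for (i in 1:8) {
      p <- simulate_codon_pair(runif(1, 0.1, 1.5), length = 80)
      a <- align_codon_pair(p$nt[1], p$nt[2])
      b <- align_codon_pair(p$nt[2], p$nt[1])
      ea <- suppressWarnings(ng86(a))
      eb <- suppressWarnings(ng86(b))
      expect_equal(ea$ks, eb$ks)
      expect_equal(ea$ka, eb$ka)
    }
  })
})

test_that("GY94 generator and transition matrices are proper", {
  withr::with_seed(3, {
    for (i in 1:4) {
      kappa <- runif(1, 0.5, 8)
      omega <- runif(1, 0.05, 2)
      pi <- as.numeric(wgdks:::f3x4_frequencies(
        substring(random_cds(200), seq(1, 600, 3), seq(3, 600, 3))))
      Q <- wgdks:::gy94_rates(kappa, omega, pi)$Q
      expect_lt(max(abs(rowSums(Q))), 1e-10)
      eg <- wgdks:::gy94_eigen(kappa, omega, pi)
      for (t in c(0.01, 0.1, 1, 10)) {
        P <- wgdks:::gy94_tpm(eg, t)
        expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
        expect_true(all(P >= 0))
      }
    }
  })
})

test_that("ML estimate is ~0 for identical sequences and improves on its start", {
  p0 <- simulate_codon_pair(0, length = 120, seed = 9)
  aln <- align_codon_pair(p0$nt[1], p0$nt[2])
  m <- suppressWarnings(ml_ks(aln))
  expect_lt(m$ks, 1e-4)
  expect_lt(m$t, 1e-4)

  ## optimized log-likelihood is at least the value at the NG86 start
  p1 <- simulate_codon_pair(0.6, length = 200, seed = 10)
  aln1 <- align_codon_pair(p1$nt[1], p1$nt[2])
  m1 <- ml_ks(aln1)
  ng <- ng86(aln1)
  sc <- wgdks:::ks_scaling(2, max(ng$omega, 1e-3),
                           wgdks:::f3x4_frequencies(c(aln1$codons_a,
                                                      aln1$codons_b)))
  t0 <- 3 * (sc$f_s * ng$ks + (1 - sc$f_s) * ng$ka)
  ll_start <- codon_pair_loglik(aln1, t0, 2, max(ng$omega, 1e-3))
  expect_gte(m1$loglik, ll_start - 1e-6)
})

test_that("mean estimated Ks is monotone in the simulated truth", {
  withr::with_seed(17, {
    ks_levels <- c(0.1, 0.5, 1.0, 2.0)
    means <- vapply(ks_levels, function(ks) {
      est <- vapply(1:6, function(i) {
        p <- simulate_codon_pair(ks, length = 200)
        suppressWarnings(ml_ks(align_codon_pair(p$nt[1], p$nt[2])))$ks
      }, numeric(1))
      mean(est)
    }, numeric(1))
  })
  expect_true(all(diff(means) > 0))
})

test_that("ML and NG86 agree at low divergence without transition bias", {
  ## NG86's equal-rate site counting is exact when kappa = 1; at Ks <= 0.3
  ## the two estimators should agree closely on most replicates
  withr::with_seed(23, {
    model <- codon_model(kappa = 1, omega = 0.2)
    rel <- vapply(1:30, function(i) {
      ks <- runif(1, 0.1, 0.3)
      p <- simulate_codon_pair(ks, model = model, length = 400)
      aln <- align_codon_pair(p$nt[1], p$nt[2])
      m <- suppressWarnings(ml_ks(aln))
      n <- suppressWarnings(ng86(aln))
      abs(m$ks - n$ks) / n$ks
    }, numeric(1))
  })
  expect_gte(mean(rel <= 0.15), 0.9)
})

test_that("saturated alignments are flagged", {
  p <- simulate_codon_pair(15, length = 150, seed = 4)
  aln <- align_codon_pair(p$nt[1], p$nt[2])
  n <- suppressWarnings(ng86(aln))
  expect_true(n$saturated || n$ks > 2)
})

test_that("short alignments trigger a warning", {
  p <- simulate_codon_pair(0.3, length = 20, seed = 6)
  expect_warning(ml_ks(align_codon_pair(p$nt[1], p$nt[2])), "codons")
})
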