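test_that("zero divergence yields identical sequences; seeds fix the bytes", {
  p <- simulate_codon_pair(0, length = 100, seed = 3)
  expect_identical(p$nt[1], p$nt[2])

  p1 <- simulate_codon_pair(0.7, length = 120, seed = 42)
  p2 <- simulate_codon_pair(0.7, length = 120, seed = 42)
  expect_identical(p1$nt, p2$nt)
  p3 <- simulate_codon_pair(0.7, length = 120, seed = 43)
  expect_false(identical(p1$nt, p3$nt))
})

test_that("generator and estimators agree without transition bias", {
  ## kappa = 1 meets NG86's equal-rate site-counting assumption; the
  ## remaining few-percent NG86 offset at Ks 0.3 is the counting method's
  ## own aggregation/correction bias (it grows towards saturation), so the
  ## counting oracle is checked at ~8% and the production ML estimator,
  ## which shares the generator's model, at 5%
  model <- codon_model(kappa = 1, omega = 0.2)
  withr::with_seed(51, {
    est <- vapply(1:60, function(i) {
      p <- simulate_codon_pair(0.3, model = model, length = 1000)
      suppressWarnings(ng86(align_codon_pair(p$nt[1], p$nt[2])))$ks
    }, numeric(1))
    ml <- vapply(1:30, function(i) {
      p <- simulate_codon_pair(0.3, model = model, length = 1000)
      ml_ks(align_codon_pair(p$nt[1], p$nt[2]))$ks
    }, numeric(1))
  })
  expect_lt(abs(mean(est) - 0.3) / 0.3, 0.08)
  expect_lt(abs(mean(ml) - 0.3) / 0.3, 0.05)
})

test_that("realized Ks regresses on truth with slope near one", {
  model <- codon_model(kappa = 1, omega = 0.2)
  withr::with_seed(52, {
    true_ks <- runif(80, 0.1, 1.5)
    est <- vapply(true_ks, function(ks) {
      p <- simulate_codon_pair(ks, model = model, length = 500)
      suppressWarnings(ml_ks(align_codon_pair(p$nt[1], p$nt[2])))$ks
    }, numeric(1))
  })
  slope <- unname(coef(lm(est ~ true_ks))[2])
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)

  ## the NG86 oracle stays near-linear below Ks ~0.5 before its
  ## saturation bias sets in
  withr::with_seed(53, {
    lo_ks <- runif(30, 0.1, 0.5)
    lo <- vapply(lo_ks, function(ks) {
      p <- simulate_codon_pair(ks, model = model, length = 500)
      suppressWarnings(ng86(align_codon_pair(p$nt[1], p$nt[2])))$ks
    }, numeric(1))
  })
  lo_slope <- unname(coef(lm(lo ~ lo_ks))[2])
  expect_gt(lo_slope, 0.9)
  expect_lt(lo_slope, 1.15)
})

test_that("population truth tables are complete, deterministic and labelled", {
  cfg <- simulation_config(n_families = 30, seed = 9)
  pop <- simulate_population(cfg)
  ## row count = sum over families of m(m-1)/2
  fam_sizes <- table(sub("_g\\d+$", "", pop$sequences$id))
  expect_equal(nrow(pop$truth),
               sum(fam_sizes * (fam_sizes - 1) / 2))
  expect_true(all(pop$truth$origin %in% c("SSD", "WGD_1")))
  ## full determinism: identical FASTA and truth bytes
  pop2 <- simulate_population(cfg)
  expect_identical(pop$truth, pop2$truth)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_cds_fasta(pop$sequences, f1)
  write_cds_fasta(pop2$sequences, f2)
  expect_identical(readLines(f1), readLines(f2))
  ## histories drawn standalone match the population's truth
  expect_identical(simulate_history(cfg), pop$truth)
})

test_that("the WGD pair fraction matches the configured event fraction", {
  ## the configured fraction is per duplication event; in two-member
  ## families pairs and events coincide, so the pair fraction is binomial
  ## around it (in larger families old WGD roots own more pairs)
  cfg <- simulation_config(n_families = 1500, seed = 10,
                           family_size_probs = c(`2` = 1))
  tr <- simulate_history(cfg)
  frac <- mean(tr$origin != "SSD")
  expect_lt(abs(frac - 0.4), 3 * sqrt(0.4 * 0.6 / nrow(tr)))
})

test_that("tip-pair divergence reflects the event ages in larger families", {
  cfg <- simulation_config(n_families = 60, seed = 13,
                           family_size_probs = c(`4` = 1),
                           model = codon_model(kappa = 1, omega = 0.2),
                           gene_length = 500L)
  pop <- simulate_population(cfg)
  idx <- stats::setNames(seq_along(pop$sequences$id), pop$sequences$id)
  withr::with_seed(14, rows <- sample(nrow(pop$truth), 40))
  est <- vapply(rows, function(r) {
    a <- pop$sequences$nt[idx[pop$truth$id_a[r]]]
    b <- pop$sequences$nt[idx[pop$truth$id_b[r]]]
    suppressWarnings(ng86(align_codon_pair(a, b)))$ks
  }, numeric(1))
  truth <- pop$truth$true_ks[rows]
  keep <- is.finite(est) & truth <= 2
  expect_gt(cor(est[keep], truth[keep]), 0.9)
})
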