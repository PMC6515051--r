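test_that("a single Gaussian is recovered with monotone EM", {
  withr::with_seed(101, x <- rnorm(2000, 0, 0.3))
  f <- em_fit(x, k = 1, seed = 1)
  expect_lt(abs(f$means_log), 3 * 0.3 / sqrt(2000))
  expect_true(f$monotone)
  expect_true(f$converged)
  expect_equal(sum(f$proportions), 1, tolerance = 1e-9)

  ## BIC sign convention against the closed form for k = 1:
  ## max loglik of a Gaussian is -n/2 (log(2 pi sigma2_hat) + 1)
  n <- length(x)
  s2 <- mean((x - mean(x))^2)
  ll <- -n / 2 * (log(2 * pi * s2) + 1)
  expect_equal(f$loglik, ll, tolerance = 1e-4)
  expect_equal(f$bic, 2 * ll - 2 * log(n), tolerance = 1e-3)
})

test_that("well-separated components are recovered", {
  withr::with_seed(102, {
    x <- c(rnorm(2500, -2, 0.1), rnorm(2500, 0, 0.1))
  })
  f <- em_fit(x, k = 2, seed = 2)
  expect_lt(abs(f$means_log[1] - (-2)), 0.05)
  expect_lt(abs(f$means_log[2] - 0), 0.05)
  expect_true(f$monotone)
  expect_equal(f$proportions, c(0.5, 0.5), tolerance = 0.05)
})

test_that("EM fits are bit-reproducible under a fixed seed", {
  withr::with_seed(103, x <- c(rnorm(300, 0, 0.4), rnorm(200, 1, 0.2)))
  f1 <- em_fit(x, k = 3, seed = 42, n_init = 4)
  f2 <- em_fit(x, k = 3, seed = 42, n_init = 4)
  expect_identical(f1$means_log, f2$means_log)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("observation weights behave as fractional replication", {
  withr::with_seed(104, x <- c(rnorm(200, 0, 0.5), rnorm(100, 2, 0.3)))
  ## each point twice at weight 1 == each point once at weight 2
  f_rep <- em_fit(c(x, x), k = 2, seed = 5)
  f_w <- em_fit(x, weights = rep(2, length(x)), k = 2, seed = 5)
  expect_equal(f_w$means_log, f_rep$means_log, tolerance = 1e-5)
  expect_equal(f_w$loglik, f_rep$loglik, tolerance = 1e-5)
  expect_equal(f_w$n, 2 * length(x))
})

test_that("degenerate data collapses to one floored component", {
  expect_warning(f <- em_fit(rep(0.5, 50), k = 3, seed = 1), "degenerate")
  expect_equal(f$k, 1L)
  expect_equal(f$variances_log, 1e-6)
})

test_that("BIC selects parsimonious k and honors a forced range", {
  withr::with_seed(105, x <- rnorm(2000, 0, 0.3))
  best <- select_k(x, k_range = 1:5, seed = 9)
  expect_equal(best$k, 1L)
  rep <- attr(best, "report")
  expect_equal(nrow(rep), 5L)
  expect_true(all(diff(rep$bic) <= 0) || which.max(rep$bic) == 1L)

  forced <- select_k(x, k_range = c(3, 3), seed = 9)
  expect_equal(forced$k, 3L)
})

test_that("the BIC-selected model matches an independent mixture fitter", {
  ## cross-check against mclust (equal data, unweighted, unequal variances)
  withr::with_seed(106, {
    x <- c(rnorm(1500, -1.5, 0.2), rnorm(1500, 0.5, 0.4))
  })
  f <- em_fit(x, k = 2, seed = 3)
  mc <- mclust::densityMclust(x, G = 2, modelNames = "V", plot = FALSE)
  expect_equal(f$loglik, mc$loglik, tolerance = 1e-4)
  expect_equal(sort(f$means_log), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
})

test_that("component summaries back-transform, label and bootstrap", {
  withr::with_seed(107, {
    x <- c(rnorm(1200, log(1.2), 0.2), rnorm(2400, log(0.25), 0.5))
  })
  f <- em_fit(x, k = 2, seed = 11)
  s <- summarize_components(f, x, B = 60, seed = 12)
  expect_equal(s$mean_ks, exp(f$means_log))
  wgd <- s[which.max(s$mean_ks), ]
  expect_equal(wgd$label, "candidate-WGD")
  expect_true(wgd$ci_lo < wgd$mean_ks && wgd$mean_ks < wgd$ci_hi)

  ## components outside the window stay background
  withr::with_seed(108, y <- c(rnorm(600, log(4.5), 0.1),
                               rnorm(600, log(0.2), 0.3)))
  fy <- em_fit(y, k = 2, seed = 13)
  sy <- summarize_components(fy, y, B = 0, seed = 1)
  expect_true(all(sy$label == "background"))

  ## CI width shrinks with sample size
  gen <- function(n, seed) {
    withr::with_seed(seed, c(rnorm(n, log(1.2), 0.2),
                             rnorm(n, log(0.3), 0.4)))
  }
  ci_width <- function(x, seed) {
    f <- em_fit(x, k = 2, seed = seed)
    s <- summarize_components(f, x, B = 60, seed = seed + 1)
    i <- which.max(s$mean_ks)
    s$ci_hi[i] - s$ci_lo[i]
  }
  w_small <- ci_width(gen(250, 21), 22)
  w_big <- ci_width(gen(2500, 23), 24)
  expect_lt(w_big, w_small)
})

test_that("the WGD-window component is located sensibly", {
  f <- structure(list(k = 3, means_log = log(c(0.3, 1.15, 1.48)),
                      variances_log = c(0.1, 0.05, 0.17),
                      proportions = c(0.5, 0.27, 0.23)),
                 class = "ks_mixture_fit")
  expect_equal(wgd_component(f), 2L)
  f2 <- structure(list(k = 2, means_log = log(c(0.3, 4)),
                       variances_log = c(0.1, 0.1),
                       proportions = c(0.5, 0.5)),
                  class = "ks_mixture_fit")
  expect_true(is.na(wgd_component(f2)))
})
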