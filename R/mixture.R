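# Gaussian mixture modelling of log-transformed Ks values by (weighted) EM
# with BIC model selection.  Observation weights are the node weights of the
# Ks distribution, entering the likelihood as fractional observation counts;
# unweighted fits reproduce the behaviour of a plain mixture fit.  Components
# have unequal variances; BIC = 2 logL - p log(n) with p = 3k - 1 free
# parameters, larger is better.

## One EM run from a given starting point.  The E-step density matrix is a
## single matrix product: log N(x; mu, v) + log p is quadratic in x, so
## logd = [x, x^2, 1] %*% B with component-wise coefficient columns.
em_run <- function(x, w, k, mu, v, p, tol, max_iter, var_floor) {
  n <- length(x)
  v <- pmax(v, var_floor)
  A <- cbind(x, x * x, rep(1, n))
  ll_old <- -Inf
  converged <- FALSE
  monotone <- TRUE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    B <- rbind(mu / v, -1 / (2 * v),
               log(p) - 0.5 * log(2 * pi * v) - mu^2 / (2 * v))
    logd <- A %*% B
    mx <- logd[, 1]
    if (k > 1L) for (c in 2:k) mx <- pmax(mx, logd[, c])
    ls <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(w * ls)
    if (ll < ll_old - 1e-6) monotone <- FALSE
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
    r <- exp(logd - ls)
    Wk <- pmax(as.vector(crossprod(w, r)), 1e-12)
    p <- Wk / sum(Wk)
    mu <- as.vector(crossprod(w * x, r)) / Wk
    ex2 <- as.vector(crossprod(w * x * x, r)) / Wk
    v <- pmax(ex2 - mu^2, var_floor)
  }
  list(mu = mu, v = v, p = p, loglik = ll, iter = iter,
       converged = converged, monotone = monotone)
}

## k-means partition init: isolates tight clusters (very low-variance
## components) that equal-mass quantile groups smear over.
kmeans_init <- function(x, w, k, var_floor) {
  km <- tryCatch(stats::kmeans(x, centers = k, nstart = 5L, iter.max = 50L),
                 error = function(e) NULL)
  if (is.null(km)) return(NULL)
  mu <- numeric(k)
  v <- numeric(k)
  p <- numeric(k)
  for (c in seq_len(k)) {
    sel <- km$cluster == c
    ws <- w[sel]
    mu[c] <- sum(ws * x[sel]) / sum(ws)
    v[c] <- max(sum(ws * (x[sel] - mu[c])^2) / sum(ws), var_floor)
    p[c] <- sum(ws) / sum(w)
  }
  list(mu = mu, v = v, p = pmax(p, 1e-6) / sum(pmax(p, 1e-6)))
}

quantile_init <- function(x, w, k, var_floor) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  grp <- pmin(floor(cw * k) + 1L, k)
  mu <- numeric(k)
  v <- numeric(k)
  p <- numeric(k)
  for (c in seq_len(k)) {
    sel <- o[grp == c]
    if (!length(sel)) sel <- o[which.min(abs(cw - (c - 0.5) / k))]
    ws <- w[sel]
    mu[c] <- sum(ws * x[sel]) / sum(ws)
    v[c] <- max(sum(ws * (x[sel] - mu[c])^2) / sum(ws), var_floor)
    p[c] <- sum(ws) / sum(w)
  }
  list(mu = mu, v = v, p = pmax(p, 1e-6) / sum(pmax(p, 1e-6)))
}

random_init <- function(x, w, k, var_floor) {
  mu <- sample(x, k, replace = FALSE, prob = w / sum(w))
  v0 <- max(sum(w * (x - sum(w * x) / sum(w))^2) / sum(w), var_floor)
  list(mu = mu, v = rep(v0, k), p = rep(1 / k, k))
}

finish_fit <- function(run, k, n_eff, weighted) {
  o <- order(run$mu)
  structure(list(k = k, means_log = run$mu[o],
                 variances_log = run$v[o], proportions = run$p[o],
                 loglik = run$loglik,
                 bic = 2 * run$loglik - (3 * k - 1) * log(n_eff),
                 n = n_eff, iter = run$iter, converged = run$converged,
                 monotone = run$monotone, weighted = weighted),
            class = "ks_mixture_fit")
}

#' Fit a k-component Gaussian mixture to log-Ks values by weighted EM
#'
#' Initialization runs from a k-means partition, a weighted quantile
#' partition, and seeded random restarts up to `n_init` starts in total;
#' the best start by log-likelihood is returned.
#' Convergence is declared when the relative log-likelihood change drops
#' below `tol`; variances are floored at `var_floor`.
#'
#' @param log_ks numeric vector of `ln(Ks)` values.
#' @param weights optional observation weights (node weights); `NULL` for
#'   an unweighted fit.
#' @param k number of components (`>= 1`).
#' @param seed integer seed making the fit bit-reproducible; `NULL` uses the
#'   current RNG state.
#' @param n_init number of EM starts (k-means, quantile, then random).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @param var_floor lower bound on component variances (log scale).
#' @return object of class `ks_mixture_fit`: `k`, `means_log`,
#'   `variances_log`, `proportions` (components sorted by mean), `loglik`,
#'   `bic`, `n` (effective sample size, the summed weights), `iter`,
#'   `converged`, `monotone`.
#' @export
em_fit <- function(log_ks, weights = NULL, k, seed = NULL, n_init = 3L,
                   tol = 1e-8, max_iter = 2000L, var_floor = 1e-6) {
  x <- as.numeric(log_ks)
  w <- if (is.null(weights)) rep(1, length(x)) else as.numeric(weights)
  stopifnot(length(w) == length(x), k >= 1L)
  ok <- is.finite(x) & is.finite(w) & w > 0
  x <- x[ok]
  w <- w[ok]
  if (!length(x)) stop("no finite observations")
  if (length(x) < 10 * k)
    warning(sprintf("only %d observations for k = %d components",
                    length(x), k))
  n_eff <- sum(w)
  weighted <- !is.null(weights)
  if (diff(range(x)) < 1e-12) {
    if (k > 1L) warning("degenerate data (all values equal): k forced to 1")
    run <- list(mu = x[1], v = var_floor, p = 1,
                loglik = sum(w * stats::dnorm(x, x[1], sqrt(var_floor),
                                              log = TRUE)),
                iter = 0L, converged = TRUE, monotone = TRUE)
    return(finish_fit(run, 1L, n_eff, weighted))
  }
  if (length(x) < k) stop("fewer observations than components")
  with_seed_if(seed, {
    inits <- list(kmeans_init(x, w, k, var_floor),
                  quantile_init(x, w, k, var_floor))
    inits <- Filter(Negate(is.null), inits)
    inits <- c(inits,
               lapply(seq_len(max(0L, n_init - length(inits))),
                      function(i) random_init(x, w, k, var_floor)))
    runs <- lapply(inits, function(ini)
      em_run(x, w, k, ini$mu, ini$v, ini$p, tol, max_iter, var_floor))
    best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]
    finish_fit(best, k, n_eff, weighted)
  })
}

#' @export
print.ks_mixture_fit <- function(x, ...) {
  cat(sprintf(
    "Gaussian mixture on ln(Ks): k = %d, loglik = %.3f, BIC = %.3f, n = %.1f\n",
    x$k, x$loglik, x$bic, x$n))
  df <- data.frame(mean_ks = exp(x$means_log),
                   mean_log = x$means_log,
                   variance_log = x$variances_log,
                   proportion = x$proportions)
  print(df, digits = 4)
  invisible(x)
}

#' Select the number of mixture components by BIC
#'
#' Fits every `k` in `k_range` and returns the fit maximizing BIC
#' (`2 logL - p log n`); all fits are retained in the `"report"` attribute.
#'
#' @inheritParams em_fit
#' @param k_range candidate component counts (default `1:10`).
#' @return the best `ks_mixture_fit`; `attr(, "report")` is a data frame of
#'   (`k`, `loglik`, `bic`) and `attr(, "fits")` the full list.
#' @export
select_k <- function(log_ks, weights = NULL, k_range = 1:10, seed = NULL,
                     n_init = 3L, ...) {
  fits <- lapply(seq_along(k_range), function(i)
    em_fit(log_ks, weights, k = k_range[i],
           seed = if (is.null(seed)) NULL else seed + i, n_init = n_init,
           ...))
  report <- data.frame(k = k_range,
                       loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                       bic = vapply(fits, `[[`, numeric(1), "bic"))
  best <- fits[[which.max(report$bic)]]
  attr(best, "report") <- report
  attr(best, "fits") <- fits
  best
}

#' Locate the WGD-window component of a mixture fit
#'
#' Returns the index of the component representing the WGD peak: among
#' components whose Ks-scale mean lies in `window`, those reaching
#' `min_proportion` are preferred, and of these the one whose mean is
#' closest to the window midpoint is chosen (a fit occasionally places a
#' second, peripheral component just inside the window).
#'
#' @param fit a `ks_mixture_fit`.
#' @param window Ks window of the expected WGD peak.
#' @param min_proportion preferred minimum mixing proportion.
#' @return component index, or `NA` if no component mean falls in the
#'   window.
#' @export
wgd_component <- function(fit, window = c(0.9, 1.5), min_proportion = 0.1) {
  mk <- exp(fit$means_log)
  inw <- which(mk >= window[1] & mk <= window[2])
  if (!length(inw)) return(NA_integer_)
  big <- inw[fit$proportions[inw] >= min_proportion]
  if (length(big)) inw <- big
  inw[which.min(abs(mk[inw] - mean(window)))]
}

#' Summarize mixture components as candidate WGD peaks
#'
#' Back-transforms component means to the Ks scale, attaches bootstrap 95%
#' confidence intervals (resample, refit with `k` fixed starting from the
#' original solution, match components by nearest mean) and labels
#' components as `candidate-WGD` when the Ks-scale mean falls in
#' `wgd_window` with proportion at least `min_proportion`.  Peaks beyond
#' Ks = 2 are reported but never labelled WGD: saturation and stochastic
#' effects make them unreliable.
#'
#' @param fit a `ks_mixture_fit`.
#' @param log_ks,weights the data (and weights) the fit was computed from.
#' @param B bootstrap replicates (default 100).
#' @param seed seed for the bootstrap resampling.
#' @param wgd_window Ks window for the candidate label (default
#'   `c(0.5, 2)`).
#' @param min_proportion minimum mixing proportion for the candidate label.
#' @return data frame with one row per component: `component`, `mean_ks`,
#'   `ci_lo`, `ci_hi`, `mean_log`, `variance_log`, `variance_ks` (log-normal
#'   variance on the Ks scale), `proportion`, `label`.  The attribute
#'   `"ci_unstable"` is `TRUE` when more than 20% of bootstrap refits failed
#'   to converge.
#' @export
summarize_components <- function(fit, log_ks, weights = NULL, B = 100L,
                                 seed = NULL, wgd_window = c(0.5, 2),
                                 min_proportion = 0.1) {
  stopifnot(inherits(fit, "ks_mixture_fit"))
  x <- as.numeric(log_ks)
  w <- if (is.null(weights)) rep(1, length(x)) else as.numeric(weights)
  ok <- is.finite(x) & is.finite(w) & w > 0
  x <- x[ok]
  w <- w[ok]
  k <- fit$k
  boot_mu <- matrix(NA_real_, B, k)
  nonconv <- 0L
  if (B > 0L && length(x) >= k) {
    with_seed_if(seed, {
      prob <- w / sum(w)
      for (b in seq_len(B)) {
        idx <- sample.int(length(x), length(x), replace = TRUE, prob = prob)
        run <- em_run(x[idx], rep(1, length(idx)), k, fit$means_log,
                      fit$variances_log, fit$proportions,
                      tol = 1e-6, max_iter = 500L, var_floor = 1e-6)
        if (!run$converged) nonconv <- nonconv + 1L
        ## match bootstrap components to the original by nearest log-mean
        boot_mu[b, ] <- vapply(fit$means_log, function(m)
          run$mu[which.min(abs(run$mu - m))], numeric(1))
      }
    })
  }
  ci <- t(apply(exp(boot_mu), 2, function(col)
    if (all(is.na(col))) c(NA_real_, NA_real_)
    else stats::quantile(col, c(0.025, 0.975), na.rm = TRUE)))
  mean_ks <- exp(fit$means_log)
  label <- ifelse(mean_ks >= wgd_window[1] & mean_ks <= wgd_window[2] &
                    mean_ks <= 2 & fit$proportions >= min_proportion,
                  "candidate-WGD", "background")
  out <- data.frame(component = seq_len(k), mean_ks = mean_ks,
                    ci_lo = ci[, 1], ci_hi = ci[, 2],
                    mean_log = fit$means_log,
                    variance_log = fit$variances_log,
                    variance_ks = (exp(fit$variances_log) - 1) *
                      exp(2 * fit$means_log + fit$variances_log),
                    proportion = fit$proportions, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "ci_unstable") <- B > 0L && nonconv / B > 0.2
  out
}
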