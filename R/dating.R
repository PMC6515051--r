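# Molecular-clock conversion between Ks peaks, synonymous substitution
# rates and absolute ages, T = Ks / (2 r) (the factor two because both
# descendants of a duplication accumulate substitutions), plus the Wilcoxon
# matched-pairs comparison of two binned Ks frequency distributions.

#' Average plant synonymous substitution rate
#'
#' 6.1e-9 synonymous substitutions per synonymous site per year, the
#' plant-average clock commonly used to convert paranome Ks peaks to ages.
#'
#' @export
PLANT_KS_RATE <- 6.1e-9

#' Convert a Ks peak to an absolute age
#'
#' `T = Ks / (2 r)`.  Ages are additionally reported rounded to the nearest
#' million years (`age_mya`), the conventional reporting precision.
#'
#' @param ks Ks peak value(s) (`>= 0`); a vector propagates e.g. CI
#'   endpoints.
#' @param rate synonymous substitution rate per site per year (`> 0`);
#'   default [PLANT_KS_RATE].
#' @return object of class `wgd_date` with `ks_peak`, `rate`, `age_years`,
#'   `age_mya`, `mode = "age-from-rate"`.
#' @examples
#' age_from_ks(1.2)$age_mya   # ~98 My under the plant-average rate
#' @export
age_from_ks <- function(ks, rate = PLANT_KS_RATE) {
  if (any(rate <= 0)) stop("rate must be positive")
  if (any(ks < 0)) stop("ks must be non-negative")
  age <- ks / (2 * rate)
  structure(list(ks_peak = ks, rate = rate, age_years = age,
                 age_mya = round(age / 1e6), mode = "age-from-rate"),
            class = "wgd_date")
}

#' Derive a synonymous substitution rate from a Ks peak and a known age
#'
#' `r = Ks / (2 T)`; the inverse of [age_from_ks()].  The rate is also
#' reported rounded to two decimals in units of 1e-9 per site per year
#' (`rate_e9`), the conventional precision.
#'
#' @param ks Ks peak value.
#' @param age_years absolute age of the event in years (`> 0`).
#' @return object of class `wgd_date` with `ks_peak`, `rate`, `rate_e9`,
#'   `age_years`, `age_mya`, `mode = "rate-from-age"`.
#' @examples
#' rate_from_age(1.148, 52e6)$rate_e9   # 11.04
#' @export
rate_from_age <- function(ks, age_years) {
  if (any(age_years <= 0)) stop("age must be positive")
  if (any(ks < 0)) stop("ks must be non-negative")
  rate <- ks / (2 * age_years)
  structure(list(ks_peak = ks, rate = rate, rate_e9 = round(rate * 1e9, 2),
                 age_years = age_years, age_mya = round(age_years / 1e6),
                 mode = "rate-from-age"),
            class = "wgd_date")
}

#' @export
print.wgd_date <- function(x, ...) {
  if (x$mode == "age-from-rate")
    cat(sprintf("Ks peak %s at rate %.4g /site/yr -> %s mya\n",
                paste(format(x$ks_peak, digits = 4), collapse = ", "),
                x$rate[1],
                paste(x$age_mya, collapse = ", ")))
  else
    cat(sprintf("Ks peak %s at %s mya -> r = %s x 1e-9 /site/yr\n",
                paste(format(x$ks_peak, digits = 4), collapse = ", "),
                paste(x$age_mya, collapse = ", "),
                paste(format(x$rate_e9), collapse = ", ")))
  invisible(x)
}

#' Wilcoxon matched-pairs (signed-rank) test
#'
#' Compares two equal-length paired vectors (by convention, per-bin relative
#' frequencies of two Ks distributions over a shared bin grid).  Zero
#' differences are dropped; ties in the absolute differences receive average
#' ranks.  The null distribution is computed exactly (by dynamic-programming
#' enumeration over all sign assignments) for up to `exact_limit` non-zero
#' pairs and by normal approximation with continuity and tie correction
#' above.  The reported p-value is two-sided.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param exact_limit maximum number of non-zero pairs for the exact null
#'   (default 25).
#' @return list with `statistic` (W, the sum of positive ranks), `p_value`,
#'   `n` (non-zero pairs used) and `method`.
#' @export
wilcoxon_matched <- function(a, b, exact_limit = 25L) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; p reported as 1")
    return(list(statistic = NA_real_, p_value = 1, n = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r))     # doubled ranks are integers with ties
    tot <- sum(r2)
    v <- numeric(tot + 1L)
    v[1L] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), v[seq_len(tot + 1L - ri)])
      v <- v + shifted
    }
    v <- v / 2^n
    w2 <- as.integer(round(2 * W))
    p_le <- sum(v[seq_len(w2 + 1L)])
    p_ge <- sum(v[(w2 + 1L):(tot + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (abs(W - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "normal-approximation"
  }
  list(statistic = W, p_value = p, n = n, method = method)
}
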