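# Pairwise Ks/Ka estimation for a codon alignment.  Two estimators share the
# KsEstimate contract: NG86, a closed-form counting method that serves as an
# independently hand-checkable oracle, and a Goldman-Yang (GY94 + F3x4)
# maximum-likelihood estimator, the production method.  Both express Ks in
# synonymous substitutions per synonymous site.

new_ks_estimate <- function(ks, ka, t = NA_real_, kappa = NA_real_,
                            loglik = NA_real_, method, saturated = FALSE,
                            converged = NA, n_codons = NA_integer_,
                            extra = list()) {
  omega <- if (is.finite(ks) && ks > 0 && is.finite(ka)) ka / ks else NA_real_
  structure(c(list(ks = ks, ka = ka, omega = omega, t = t, kappa = kappa,
                   loglik = loglik, method = method, saturated = saturated,
                   converged = converged, n_codons = n_codons), extra),
            class = "ks_estimate")
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf("Ks estimate (%s, %d codons): ks=%s ka=%s omega=%s%s\n",
              x$method, x$n_codons,
              format(x$ks, digits = 4), format(x$ka, digits = 4),
              format(x$omega, digits = 4),
              if (isTRUE(x$saturated)) " [saturated]" else ""))
  invisible(x)
}

#' Nei-Gojobori (1986) Ks/Ka estimate
#'
#' Synonymous and nonsynonymous site counts are averaged over the two
#' sequences (mutations to stop codons are excluded from both site classes);
#' differences in multi-hit codons are averaged over all minimal mutational
#' pathways, excluding pathways through stop codons.  The proportions are
#' corrected for multiple hits with the Jukes-Cantor formula
#' `d = -3/4 log(1 - 4 p / 3)`; `p >= 3/4` is reported as saturated.
#'
#' @param aln a [codon_alignment()].
#' @return a `ks_estimate` (method `"NG86"`); also carries the raw counts
#'   `S`, `N`, `Sd`, `Nd`.
#' @export
ng86 <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  tab <- codon_tables()
  ia <- tab$codon_to_idx[aln$codons_a]
  ib <- tab$codon_to_idx[aln$codons_b]
  S <- (sum(tab$s_sites[ia]) + sum(tab$s_sites[ib])) / 2
  N <- (sum(tab$n_sites[ia]) + sum(tab$n_sites[ib])) / 2
  Sd <- sum(tab$sd_mat[cbind(ia, ib)])
  Nd <- sum(tab$nd_mat[cbind(ia, ib)])
  if (S <= 0) {
    warning("no synonymous sites; Ks undefined")
    return(new_ks_estimate(NA_real_, NA_real_, method = "NG86",
                           n_codons = aln$n_codons,
                           extra = list(S = S, N = N, Sd = Sd, Nd = Nd)))
  }
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  sat <- pS >= 0.75
  new_ks_estimate(ks = jc(pS), ka = jc(pN), method = "NG86",
                  saturated = sat, n_codons = aln$n_codons,
                  extra = list(S = S, N = N, Sd = Sd, Nd = Nd,
                               pS = pS, pN = pN))
}

## Log-likelihood machinery shared by ml_ks and the test suite.
pair_counts <- function(aln, tab = codon_tables()) {
  ia <- tab$codon_to_idx[aln$codons_a]
  ib <- tab$codon_to_idx[aln$codons_b]
  key <- (ia - 1L) * 61L + ib
  tt <- tabulate(key, nbins = 61L * 61L)
  k <- which(tt > 0L)
  list(i = (k - 1L) %/% 61L + 1L, j = (k - 1L) %% 61L + 1L,
       n = as.numeric(tt[k]))
}

#' Log-likelihood of a codon alignment under GY94 + F3x4
#'
#' Pairwise likelihood of the two sequences separated by total divergence
#' `t` (expected substitutions per codon) under the Goldman-Yang codon model
#' with F3x4 frequencies estimated jointly from the pair.
#'
#' @param aln a [codon_alignment()].
#' @param t total branch length between the two sequences
#'   (substitutions/codon).
#' @param kappa transition/transversion rate ratio.
#' @param omega nonsynonymous/synonymous rate ratio.
#' @return log-likelihood (a scalar).
#' @export
codon_pair_loglik <- function(aln, t, kappa, omega) {
  tab <- codon_tables()
  pc <- pair_counts(aln, tab)
  pi <- f3x4_frequencies(c(aln$codons_a, aln$codons_b), tab = tab)
  eg <- gy94_eigen(kappa, omega, pi, tab)
  P <- gy94_tpm(eg, t)
  p <- P[cbind(pc$i, pc$j)]
  p[p < 1e-300] <- 1e-300
  sum(pc$n * (log(pi[pc$i]) + log(p)))
}

#' Maximum-likelihood Ks/Ka estimate under a GY94 codon model
#'
#' Maximizes the pairwise likelihood over total divergence `t`,
#' transition/transversion ratio `kappa` and selection parameter `omega`
#' with F3x4 equilibrium frequencies computed jointly from the two aligned
#' sequences.  `t` is decomposed into per-site synonymous and nonsynonymous
#' components by Yang's convention (synonymous flux over synonymous sites),
#' so `ks = t * rho_s / (3 f_s)`.  Optimization profiles `t` (Brent search)
#' inside a bounded quasi-Newton search over `(log kappa, log omega)`,
#' started from the NG86 estimate.
#'
#' @param aln a [codon_alignment()]; fewer than `warn_codons` columns
#'   triggers a warning.
#' @param kappa_init,omega_init optional starting values.
#' @param t_bounds,kappa_bounds,omega_bounds box constraints; `t` reaching
#'   its upper bound is reported as saturated.
#' @param warn_codons alignment length below which a warning is emitted.
#' @return a `ks_estimate` (method `"ML"`).  If the optimizer fails to
#'   converge the NG86 estimate is returned instead, flagged with
#'   `converged = FALSE`.
#' @export
ml_ks <- function(aln, kappa_init = 2, omega_init = NULL,
                  t_bounds = c(1e-6, 50), kappa_bounds = c(0.1, 20),
                  omega_bounds = c(1e-4, 10), warn_codons = 30L) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (aln$n_codons < warn_codons)
    warning(sprintf("only %d codons; ML Ks may be unstable", aln$n_codons))
  tab <- codon_tables()
  pc <- pair_counts(aln, tab)
  pi <- f3x4_frequencies(c(aln$codons_a, aln$codons_b), tab = tab)

  ng <- suppressWarnings(ng86(aln))
  w0 <- omega_init %||%
    (if (is.finite(ng$omega) && ng$omega > 0) ng$omega else 0.2)
  w0 <- min(max(w0, omega_bounds[1] * 2), omega_bounds[2] / 2)
  k0 <- min(max(kappa_init, kappa_bounds[1] * 2), kappa_bounds[2] / 2)

  profile_t <- function(kappa, omega) {
    .gy94_profile_nll(kappa, omega, pi,
                      tab$single_i0, tab$single_j0,
                      as.integer(tab$single_ts), as.integer(tab$single_syn),
                      pc$i - 1L, pc$j - 1L, pc$n,
                      t_bounds[1], t_bounds[2])
  }
  outer_nll <- function(par) profile_t(exp(par[1]), exp(par[2]))$nll
  opt <- tryCatch(
    stats::optim(c(log(k0), log(w0)), outer_nll, method = "L-BFGS-B",
                 lower = log(c(kappa_bounds[1], omega_bounds[1])),
                 upper = log(c(kappa_bounds[2], omega_bounds[2])),
                 control = list(factr = 1e7)),
    error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0) {
    out <- ng
    out$converged <- FALSE
    return(out)
  }
  kappa_hat <- exp(opt$par[1])
  omega_hat <- exp(opt$par[2])
  prof <- profile_t(kappa_hat, omega_hat)
  sc <- ks_scaling(kappa_hat, omega_hat, pi, tab)
  t_hat <- prof$t
  saturated <- t_hat >= t_bounds[2] * 0.99
  new_ks_estimate(ks = t_hat * sc$ks_per_t, ka = t_hat * sc$ka_per_t,
                  t = t_hat, kappa = kappa_hat, loglik = -prof$nll,
                  method = "ML", saturated = saturated, converged = TRUE,
                  n_codons = aln$n_codons)
}

#' Estimate Ks for every retained pair of a family set
#'
#' Aligns each retained pair (global protein alignment back-translated to
#' codons) and runs the chosen estimator.
#'
#' @param seqs the [sequence_set()] the families were built from.
#' @param families a [build_families()] result, or any data frame with
#'   columns `family_id`, `id_a`, `id_b`.
#' @param method `"ML"` (default) or `"NG86"`.
#' @param quiet suppress per-pair warnings (short alignments etc.).
#' @return data frame: `family_id`, `id_a`, `id_b`, `n_codons`, `ks`, `ka`,
#'   `omega`, `t`, `kappa`, `method`, `saturated`.
#' @export
estimate_ks_pairs <- function(seqs, families, method = c("ML", "NG86"),
                              quiet = TRUE) {
  method <- match.arg(method)
  pairs <- if (inherits(families, "gene_families")) families$pairs
           else families
  need <- c("family_id", "id_a", "id_b")
  stopifnot(all(need %in% names(pairs)))
  idx <- stats::setNames(seq_along(seqs$id), seqs$id)
  nr <- nrow(pairs)
  ia <- idx[pairs$id_a]
  ib <- idx[pairs$id_b]
  sm <- substitution_matrix("BLOSUM62")
  need_int <- sort(unique(c(ia, ib)))
  aa_int <- vector("list", length(seqs$id))
  for (k in need_int)
    aa_int[[k]] <- match(strsplit(seqs$aa[k], "")[[1]], rownames(sm))
  cod <- function(nt, k) substring(nt, 3L * (k - 1L) + 1L, 3L * k)
  out <- vector("list", nr)
  for (r in seq_len(nr)) {
    est <- tryCatch({
      al <- .nw_align(aa_int[[ia[r]]], aa_int[[ib[r]]], sm, 11, 1)
      keep <- al$a_pos > 0L & al$b_pos > 0L
      aln <- codon_alignment(pairs$id_a[r], pairs$id_b[r],
                             cod(seqs$nt[ia[r]], al$a_pos[keep]),
                             cod(seqs$nt[ib[r]], al$b_pos[keep]))
      f <- function() if (method == "ML") ml_ks(aln) else ng86(aln)
      if (quiet) suppressWarnings(f()) else f()
    }, error = function(e) NULL)
    if (is.null(est)) next
    out[[r]] <- data.frame(
      family_id = pairs$family_id[r], id_a = pairs$id_a[r],
      id_b = pairs$id_b[r], n_codons = est$n_codons,
      ks = est$ks, ka = est$ka, omega = est$omega, t = est$t,
      kappa = est$kappa, method = est$method,
      saturated = isTRUE(est$saturated), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(family_id = character(0), id_a = character(0),
                      id_b = character(0), n_codons = integer(0),
                      ks = numeric(0), ka = numeric(0), omega = numeric(0),
                      t = numeric(0), kappa = numeric(0),
                      method = character(0), saturated = logical(0))
  rownames(res) <- NULL
  res
}
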