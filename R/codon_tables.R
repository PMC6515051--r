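# Codon-level machinery shared by the NG86 counter, the GY94 maximum
# likelihood estimator and the sequence simulator.  Everything here is a
# pure function of the standard genetic code, built once per session and
# cached.

.codon_cache <- new.env(parent = emptyenv())

## Lookup tables over the 61 sense codons of the standard code:
##  - ndiff:      61x61 count of differing codon positions
##  - single_*:   classification of the single-difference codon pairs
##  - s_sites/n_sites: NG86 synonymous / nonsynonymous site counts per codon
##                (mutations to stop codons excluded from both classes)
##  - sd_mat/nd_mat: NG86 synonymous / nonsynonymous differences per codon
##                pair, averaged over minimal mutational pathways, pathways
##                through stop codons excluded
codon_tables <- function() {
  tab <- .codon_cache$tab
  if (!is.null(tab)) return(tab)

  bases <- c("T", "C", "A", "G")
  grid <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  codons64 <- paste0(grid$b1, grid$b2, grid$b3)
  code <- Biostrings::GENETIC_CODE
  aa64 <- unname(code[codons64])

  sense <- codons64[aa64 != "*"]
  sense_aa <- aa64[aa64 != "*"]
  n <- length(sense)                    # 61
  chm <- matrix(unlist(strsplit(sense, "")), ncol = 3, byrow = TRUE)
  chm_idx <- matrix(match(chm, bases), ncol = 3)

  purine <- chm == "A" | chm == "G"
  ndiff <- matrix(0L, n, n)
  ts_any <- matrix(FALSE, n, n)
  for (p in 1:3) {
    ne <- outer(chm[, p], chm[, p], "!=")
    ndiff <- ndiff + ne
    same_class <- outer(purine[, p], purine[, p], "==")
    ts_any <- ts_any | (ne & same_class)
  }
  single <- which(ndiff == 1L)
  syn_mat <- outer(sense_aa, sense_aa, "==")
  single_ts <- ts_any[single]
  single_syn <- syn_mat[single]
  syn_off <- syn_mat
  diag(syn_off) <- FALSE

  ## NG86 site counts
  s_sites <- numeric(n)
  n_sites <- numeric(n)
  for (i in seq_len(n)) {
    syn <- 0L
    stp <- 0L
    for (p in 1:3) {
      for (b in bases) {
        if (b == chm[i, p]) next
        mut <- chm[i, ]
        mut[p] <- b
        maa <- code[[paste0(mut, collapse = "")]]
        if (maa == "*") stp <- stp + 1L
        else if (maa == sense_aa[i]) syn <- syn + 1L
      }
    }
    s_sites[i] <- syn / 3
    n_sites[i] <- (9L - syn - stp) / 3
  }

  ## NG86 pathway-averaged difference counts
  perm2 <- list(c(1L, 2L), c(2L, 1L))
  perm3 <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  sd_mat <- matrix(0, n, n)
  nd_mat <- matrix(0, n, n)
  path_counts <- function(from, to, ord, allow_stop) {
    cur <- from
    cur_aa <- code[[paste0(cur, collapse = "")]]
    s <- 0
    nn <- 0
    for (p in ord) {
      nxt <- cur
      nxt[p] <- to[p]
      nxt_aa <- code[[paste0(nxt, collapse = "")]]
      if (nxt_aa == "*" && !allow_stop) return(NULL)
      if (nxt_aa == cur_aa) s <- s + 1 else nn <- nn + 1
      cur <- nxt
      cur_aa <- nxt_aa
    }
    c(s, nn)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      dpos <- which(chm[i, ] != chm[j, ])
      k <- length(dpos)
      if (k == 0L) next
      orders <- switch(k,
                       list(dpos),
                       lapply(perm2, function(o) dpos[o]),
                       lapply(perm3, function(o) dpos[o]))
      res <- Filter(Negate(is.null),
                    lapply(orders, function(o)
                      path_counts(chm[i, ], chm[j, ], o, allow_stop = FALSE)))
      if (!length(res))   # all minimal pathways pass through a stop codon
        res <- lapply(orders, function(o)
          path_counts(chm[i, ], chm[j, ], o, allow_stop = TRUE))
      m <- colMeans(do.call(rbind, res))
      sd_mat[i, j] <- sd_mat[j, i] <- m[1]
      nd_mat[i, j] <- nd_mat[j, i] <- m[2]
    }
  }

  codon_to_idx <- stats::setNames(rep(NA_integer_, 64L), codons64)
  codon_to_idx[sense] <- seq_len(n)

  ## 0-based (row, col) coordinates of the single-difference entries, for
  ## the compiled likelihood core
  single_i0 <- as.integer((single - 1L) %% n)
  single_j0 <- as.integer((single - 1L) %/% n)

  tab <- list(bases = bases, codons64 = codons64, aa64 = aa64,
              sense = sense, sense_aa = sense_aa, chm = chm,
              chm_idx = chm_idx, ndiff = ndiff,
              single = single, single_ts = single_ts,
              single_syn = single_syn, single_i0 = single_i0,
              single_j0 = single_j0, syn_off = syn_off,
              s_sites = s_sites, n_sites = n_sites,
              sd_mat = sd_mat, nd_mat = nd_mat,
              codon_to_idx = codon_to_idx)
  .codon_cache$tab <- tab
  tab
}

## GY94 rate matrix over the 61 sense codons, scaled so that one unit of
## branch length is one expected substitution per codon at equilibrium.
## Returns the generator together with the synonymous flux fraction rho_s.
gy94_rates <- function(kappa, omega, pi, tab = codon_tables()) {
  stopifnot(kappa > 0, omega > 0, length(pi) == 61L, all(pi > 0))
  R <- matrix(0, 61L, 61L)
  R[tab$single] <- ifelse(tab$single_ts, kappa, 1) *
    ifelse(tab$single_syn, 1, omega)
  Q <- R * rep(pi, each = 61L)          # q_ij = r_ij * pi_j
  total <- sum(pi * rowSums(Q))
  syn_flux <- sum(pi * rowSums(Q * tab$syn_off))
  Q <- Q / total
  diag(Q) <- -rowSums(Q)
  list(Q = Q, rho_s = syn_flux / total)
}

## Spectral decomposition of the (reversible) GY94 generator.  P(t) is then
## A diag(exp(lambda t)) Ainv; the decomposition is reused across branch
## lengths, which is what makes both the likelihood optimisation and the
## simulator cheap.
gy94_eigen <- function(kappa, omega, pi, tab = codon_tables()) {
  r <- gy94_rates(kappa, omega, pi, tab)
  sp <- sqrt(pi)
  B <- r$Q * outer(sp, 1 / sp)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       A = e$vectors / sp,              # row i divided by sqrt(pi_i)
       Ainv = t(e$vectors * sp),
       pi = pi, rho_s = r$rho_s, kappa = kappa, omega = omega)
}

## Transition probability matrix at branch length t (substitutions/codon).
gy94_tpm <- function(eg, t) {
  P <- eg$A %*% (exp(eg$values * t) * eg$Ainv)
  P[P < 0] <- 0
  P / rowSums(P)
}

## Yang-convention decomposition factors: synonymous flux fraction under the
## full model (rho_s) and synonymous site fraction under omega = 1 (f_s),
## so that Ks = t * rho_s / (3 f_s) and Ka = t * (1 - rho_s) / (3 (1 - f_s)).
ks_scaling <- function(kappa, omega, pi, tab = codon_tables()) {
  rho <- gy94_rates(kappa, omega, pi, tab)$rho_s
  f_s <- gy94_rates(kappa, 1, pi, tab)$rho_s
  list(rho_s = rho, f_s = f_s,
       ks_per_t = rho / (3 * f_s),
       ka_per_t = (1 - rho) / (3 * (1 - f_s)))
}

## F3x4 codon frequencies from the pooled codons of an aligned pair.  A small
## pseudocount keeps every positional nucleotide frequency strictly positive
## so the generator stays irreducible on short alignments.
f3x4_frequencies <- function(codons, pseudocount = 0.5, tab = codon_tables()) {
  idx <- tab$codon_to_idx[codons]
  if (anyNA(idx)) {           # non-sense codons: fall back to raw characters
    m <- matrix(match(unlist(strsplit(codons, "")), tab$bases), ncol = 3,
                byrow = TRUE)
  } else {
    m <- tab$chm_idx[idx, , drop = FALSE]
  }
  pos <- vapply(1:3, function(p) {
    cnt <- tabulate(m[, p], nbins = 4L) + pseudocount
    cnt / sum(cnt)
  }, numeric(4))
  pi <- pos[tab$chm_idx[, 1], 1] * pos[tab$chm_idx[, 2], 2] *
    pos[tab$chm_idx[, 3], 3]
  pi / sum(pi)
}
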