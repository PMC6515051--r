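# Synthetic paranomes with known ground truth.  Families are generated with
# explicit duplication histories -- small-scale duplication (SSD) events
# whose ages (in Ks units) follow an exponential background, plus
# whole-genome duplication (WGD) bursts that are log-normal on Ks -- and the
# histories are realized as actual codon sequences evolved under the same
# GY94 model the ML estimator assumes, via matrix-exponential transition
# probabilities.  Branch lengths are scaled through the model's synonymous
# flux (Yang's convention) so the generator and the estimator share one
# definition of Ks: the expected model Ks between two tips equals the age of
# their most recent common duplication event.

#' Codon substitution model specification
#'
#' @param kappa transition/transversion rate ratio.
#' @param omega nonsynonymous/synonymous rate ratio.
#' @param pi equilibrium frequencies over the 61 sense codons (default
#'   uniform).
#' @return object of class `codon_model`.
#' @export
codon_model <- function(kappa = 2, omega = 0.2, pi = NULL) {
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  stopifnot(length(pi) == 61L, all(pi > 0), kappa > 0, omega > 0)
  structure(list(kappa = kappa, omega = omega, pi = pi / sum(pi)),
            class = "codon_model")
}

model_machinery <- function(model) {
  tab <- codon_tables()
  eg <- gy94_eigen(model$kappa, model$omega, model$pi, tab)
  sc <- ks_scaling(model$kappa, model$omega, model$pi, tab)
  list(tab = tab, eg = eg, sc = sc, t_per_ks = 1 / sc$ks_per_t)
}

evolve_states <- function(states, eg, t) {
  if (t <= 0) return(states)
  P <- gy94_tpm(eg, t)
  out <- integer(length(states))
  for (s in unique(states)) {
    idx <- which(states == s)
    out[idx] <- sample.int(61L, length(idx), replace = TRUE, prob = P[s, ])
  }
  out
}

states_to_nt <- function(states, tab) paste(tab$sense[states], collapse = "")

#' Simulate one codon-sequence pair at a target Ks
#'
#' Draws an ancestral sequence from the model's equilibrium and evolves two
#' descendants independently, each for the branch length whose expected
#' synonymous divergence is `true_ks / 2`, so the expected Ks between the
#' tips is `true_ks`.  The state space holds sense codons only, so no stop
#' codons are ever introduced.
#'
#' @param true_ks target synonymous divergence between the two sequences
#'   (`>= 0`).
#' @param model a [codon_model()].
#' @param length gene length in codons.
#' @param seed optional seed (byte-identical output for equal seeds).
#' @param ids the two sequence ids.
#' @return a `SequenceSet` of the two sequences.
#' @export
simulate_codon_pair <- function(true_ks, model = codon_model(),
                                length = 300L, seed = NULL,
                                ids = c("a", "b")) {
  stopifnot(true_ks >= 0, length >= 1L)
  mm <- model_machinery(model)
  with_seed_if(seed, {
    t_half <- true_ks * mm$t_per_ks / 2
    anc <- sample.int(61L, length, replace = TRUE, prob = model$pi)
    sa <- evolve_states(anc, mm$eg, t_half)
    sb <- evolve_states(anc, mm$eg, t_half)
    sequence_set(c(states_to_nt(sa, mm$tab), states_to_nt(sb, mm$tab)),
                 ids = ids, source_label = "synthetic")
  })
}

#' Configuration for a synthetic paranome
#'
#' The defaults define the reference simulation conditions: 2000 gene
#' families with sizes 2-4, an exponential SSD background with rate 3 per
#' Ks unit (most small-scale duplicates are young, reflecting their rapid
#' loss), and one WGD burst at Ks 1.2 (log-scale s.d. 0.15) contributing a
#' fraction 0.4 of duplication events.
#'
#' @param n_families number of gene families.
#' @param family_size_probs named numeric vector: probability of each family
#'   size (names are the sizes).
#' @param ssd_rate exponential decay rate of the background SSD age
#'   distribution (per Ks unit).
#' @param wgd_components list of WGD bursts, each a list/vector with
#'   `mean_ks`, `sd_log` and `fraction` (of duplication events); `NULL` or
#'   an empty list for an SSD-only population.
#' @param model a [codon_model()].
#' @param gene_length gene length in codons.
#' @param seed integer seed fixing every downstream draw.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(n_families = 2000L,
                              family_size_probs = c(`2` = 0.7, `3` = 0.2,
                                                    `4` = 0.1),
                              ssd_rate = 3,
                              wgd_components = list(list(mean_ks = 1.2,
                                                         sd_log = 0.15,
                                                         fraction = 0.4)),
                              model = codon_model(), gene_length = 300L,
                              seed = 1L) {
  if (is.null(wgd_components)) wgd_components <- list()
  wgd_components <- lapply(wgd_components, as.list)
  fr <- vapply(wgd_components, function(w) w$fraction, numeric(1))
  stopifnot(ssd_rate > 0, all(fr >= 0), sum(fr) <= 1,
            abs(sum(family_size_probs) - 1) < 1e-8)
  structure(list(n_families = as.integer(n_families),
                 family_size_probs = family_size_probs,
                 ssd_rate = ssd_rate, wgd_components = wgd_components,
                 model = model, gene_length = as.integer(gene_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

## Draw one family's duplication history: sizes, event origins/ages, a
## random sequential-splitting topology, and the per-pair truth (pair Ks =
## age of the most recent common duplication event).
sample_family_history <- function(fam_idx, config) {
  sizes <- as.integer(names(config$family_size_probs))
  m <- if (length(sizes) == 1L) sizes
       else sample(sizes, 1L, prob = config$family_size_probs)
  ne <- m - 1L
  fr <- vapply(config$wgd_components, function(w) w$fraction, numeric(1))
  origin <- character(ne)
  age <- numeric(ne)
  for (e in seq_len(ne)) {
    u <- stats::runif(1)
    comp <- which(u < cumsum(fr))[1]
    if (!is.na(comp)) {
      w <- config$wgd_components[[comp]]
      origin[e] <- paste0("WGD_", comp)
      age[e] <- stats::rlnorm(1, log(w$mean_ks), w$sd_log)
    } else {
      origin[e] <- "SSD"
      age[e] <- stats::rexp(1, config$ssd_rate)
    }
  }
  o <- order(age, decreasing = TRUE)
  age <- age[o]
  origin <- origin[o]
  ## sequential splitting: event e (ages descending) splits a random live
  ## lineage, so every event is younger than the event it hangs below
  parent_of_event <- integer(ne)
  lin <- 0L                            # parent event of each live lineage
  for (e in seq_len(ne)) {
    q <- if (length(lin) == 1L) 1L else sample.int(length(lin), 1L)
    parent_of_event[e] <- lin[q]
    lin <- c(lin[-q], e, e)
  }
  tip_parent <- lin                    # length m
  ancestors <- function(tip) {
    path <- integer(0)
    p <- tip_parent[tip]
    while (p != 0L) {
      path <- c(path, p)
      p <- parent_of_event[p]
    }
    path
  }
  anc <- lapply(seq_len(m), ancestors)
  pairs <- utils::combn(m, 2L)
  mrca <- apply(pairs, 2L, function(xy)
    max(intersect(anc[[xy[1]]], anc[[xy[2]]])))
  ids <- sprintf("f%05d_g%d", fam_idx, seq_len(m))
  list(m = m, age = age, origin = origin,
       parent_of_event = parent_of_event, tip_parent = tip_parent,
       ids = ids,
       truth = data.frame(family_id = sprintf("f%05d", fam_idx),
                          id_a = ids[pairs[1, ]], id_b = ids[pairs[2, ]],
                          true_ks = age[mrca], origin = origin[mrca],
                          stringsAsFactors = FALSE))
}

## Realize one history as codon sequences.  Node heights are age/2 in
## per-lineage Ks units; branch Ks lengths convert to substitutions/codon
## through the model's synonymous flux.
realize_family <- function(h, config, mm) {
  ne <- length(h$age)
  root_states <- sample.int(61L, config$gene_length, replace = TRUE,
                            prob = config$model$pi)
  states <- vector("list", ne)
  states[[1L]] <- root_states
  if (ne > 1L) for (e in 2L:ne) {
    p <- h$parent_of_event[e]
    dks <- (h$age[p] - h$age[e]) / 2
    states[[e]] <- evolve_states(states[[p]], mm$eg, dks * mm$t_per_ks)
  }
  tips <- lapply(seq_len(h$m), function(tp) {
    p <- h$tip_parent[tp]
    evolve_states(states[[p]], mm$eg, (h$age[p] / 2) * mm$t_per_ks)
  })
  vapply(tips, states_to_nt, character(1), tab = mm$tab)
}

#' Simulate duplication histories only (no sequences)
#'
#' Draws the same family histories as [simulate_population()] under the same
#' seed, returning just the truth table.  Useful for testing the
#' distributional machinery at scale without the cost of sequence
#' evolution.
#'
#' @param config a [simulation_config()].
#' @return data frame: `family_id`, `id_a`, `id_b`, `true_ks`, `origin`.
#' @export
simulate_history <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_if(config$seed, {
    hs <- lapply(seq_len(config$n_families), sample_family_history, config)
    do.call(rbind, lapply(hs, `[[`, "truth"))
  })
}

#' Simulate a transcriptome-like paralog population
#'
#' Samples every family's duplication history (SSD ages exponential, WGD
#' ages log-normal), then realizes the histories as codon sequences evolved
#' under the configured GY94 model.  Fully deterministic under the config
#' seed.
#'
#' @param config a [simulation_config()].
#' @return list with `sequences` (a `SequenceSet`), `truth` (data frame
#'   `family_id`, `id_a`, `id_b`, `true_ks`, `origin`: one row per generated
#'   pair) and `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mm <- model_machinery(config$model)
  with_seed_if(config$seed, {
    hs <- lapply(seq_len(config$n_families), sample_family_history, config)
    truth <- do.call(rbind, lapply(hs, `[[`, "truth"))
    nts <- lapply(hs, realize_family, config = config, mm = mm)
    ids <- unlist(lapply(hs, `[[`, "ids"))
    seqs <- sequence_set(unlist(nts), ids = ids,
                         source_label = "synthetic")
    list(sequences = seqs, truth = truth, config = config)
  })
}
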