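---
title: "Detecting and dating whole-genome duplications from Ks age distributions"
author: "wgdks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating whole-genome duplications from Ks age distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model behind the pipeline

A whole-genome duplication (WGD) duplicates every gene at once. Most copies
are lost, but the survivors form a cohort of paralog pairs of equal age. The
synonymous distance Ks between two coding sequences counts substitutions at
(approximately neutral) synonymous sites per synonymous site, so it grows
roughly linearly in time and is the standard proxy for duplication age when
only transcriptome data are available.

Under continuous small-scale duplication (SSD) and loss, the distribution
of Ks across a paranome is L-shaped: many young pairs, exponentially fewer
old ones. A WGD adds a hump on top of that background. The pipeline in this
package makes that statement operational:

1. **Paranome construction** (`all_vs_all()`, `build_families()`). All
   protein pairs are scored by exact Smith-Waterman local alignment
   (BLOSUM62, affine gaps 11/1) and converted to Karlin-Altschul E-values
   computed database-style, `E = K m n exp(-lambda S)` with the published
   gapped constants `lambda = 0.267`, `K = 0.041`. Families are the
   connected components of the graph of hits with `E <= 1e-5`; the stricter
   tier (aligned length strictly over 100 residues, `E < 1e-15`) selects
   the pairs whose Ks enters the age distribution. The two tiers are kept
   separate deliberately: the permissive one decides who is related at all,
   the strict one guards the quantitative distribution against marginal
   alignments.
2. **Pairwise Ks** (`ng86()`, `ml_ks()`). Two estimators share one
   contract. NG86 counts synonymous/nonsynonymous sites and differences
   (pathway-averaged, stop-codon pathways excluded) with the Jukes-Cantor
   correction; it is simple enough to verify by hand and serves as the
   oracle in the test suite. The production estimator maximizes the
   pairwise likelihood under a Goldman-Yang codon model with F3x4
   frequencies estimated jointly from the pair, free divergence `t`,
   transition/transversion ratio `kappa` and selection parameter `omega`,
   and decomposes `t` into Ks and Ka through the model's synonymous flux
   and synonymous site fractions (Yang's convention). The likelihood is
   profiled over `t` (golden-section on log t, compiled) inside a bounded
   quasi-Newton search over `(log kappa, log omega)` started from the NG86
   estimate; `t` is bounded in `[1e-6, 50]` and hitting the upper bound is
   reported as saturation.
3. **Redundancy correction** (`node_weight()`). An n-member family carries
   `n(n-1)/2` pairwise values but only `n-1` duplication events. Members
   are clustered by average linkage on pairwise Ks; each internal node of
   that tree is one duplication event; each pair is assigned to the node
   joining its members and weighted `1 / (pairs at that node)`, so every
   event contributes total weight exactly one. Weight conservation is
   asserted, not assumed, in the tests.
4. **Age distribution and mixture** (`filter_ks()`, `ks_histogram()`,
   `em_fit()`, `select_k()`). Ks values in `[0.1, 5]` (inclusive; the
   lower cut removes allelic/assembly redundancy, the upper cut saturated
   estimates) are binned at 0.1 and modelled on the log scale by a
   Gaussian mixture with unequal variances, fitted by weighted EM
   (observation weights = node weights). The number of components is
   chosen by `BIC = 2 logL - p log n`, `p = 3k - 1`. Components with
   back-transformed mean in `[0.5, 2]` and proportion at least 0.1 are
   labelled candidate WGDs; peaks beyond Ks = 2 are reported but never
   labelled, because saturation makes them unreliable.
5. **Dating** (`age_from_ks()`, `rate_from_age()`). A Ks peak converts to
   an absolute age by `T = Ks / (2 r)` — both descendants accumulate
   substitutions, hence the factor two. With the plant-average rate
   `r = 6.1e-9` per site per year a peak at Ks 1.2 dates to roughly 98
   million years; conversely a peak of known absolute age yields a
   lineage-specific rate `r = Ks / (2 T)`. Ages are reported to the
   nearest million years and rates to two decimals in units of `1e-9`,
   the conventional precision. Two distributions are compared by a
   Wilcoxon matched-pairs test on their per-bin relative frequencies over
   the shared grid — the only pairing structure two paranome histograms
   share; the pairing rule is configurable.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `family_evalue` | 1e-5 | E-value defining family membership |
| `pair_evalue`, `pair_min_length` | 1e-15, 100 aa | strict tier gating Ks pairs |
| `min_ks`, `max_ks` | 0.1, 5 | retained Ks range (inclusive) |
| `bin_width` | 0.1 | histogram bin width |
| `peak_window` | 0.9–1.5 | window for representative peak duplicates |
| `rate` | 6.1e-9 /site/yr | plant-average synonymous rate |
| `t_bounds` | 1e-6–50 | ML divergence bounds (saturation at the top) |
| `kappa_bounds`, `omega_bounds` | 0.1–20, 1e-4–10 | codon-model boxes |

EM convergence is declared at a relative log-likelihood change below 1e-8
(at most 2000 iterations), with a variance floor of 1e-6 on the log scale.
Initialization uses a k-means partition, a weighted quantile partition and
seeded random restarts; the k-means start matters in practice because
published Ks mixtures contain near-degenerate components (log-scale
variances of order 1e-4) that smooth initializations never isolate. The
bootstrap CIs of `summarize_components()` resample observations (weighted),
refit with k fixed from the original solution, and match components by
nearest mean.

## What the synthetic data emulate — and what they do not

`simulate_population()` draws, per family, a duplication history: event
ages are exponential with rate `ssd_rate` (SSD background) or log-normal
around a configured mean (WGD bursts, log-scale s.d. `sd_log`), assembled
into an ultrametric topology by sequential random splitting so every pair's
true Ks is the age of its most recent common duplication. Histories are
realized as codon sequences evolved by matrix-exponential transition
probabilities under the same GY94 model the estimator assumes, with branch
lengths scaled through the model's synonymous flux so that the generator
and the estimator share one definition of Ks. The state space contains
sense codons only, so simulated CDS never contain stops.

Defaults define the reference conditions: 2000 families with sizes
2/3/4 in proportions 0.7/0.2/0.1, `ssd_rate = 3` per Ks unit, one WGD
burst at Ks 1.2 (`sd_log = 0.15`) contributing 40% of duplication events,
300-codon genes, `kappa = 2`, `omega = 0.2`, uniform codon frequencies.
The SSD rate reflects how quickly small-scale duplicates are lost: most
surviving tandem/segmental duplicates in real paranomes are young, and a
decay scale of ~0.33 Ks units reproduces the steep L-shape that the
detection problem assumes. These are idealizations: real transcriptomes
add assembly artifacts, allelic redundancy, alternative transcripts,
among-site rate variation and codon-usage bias, none of which are
simulated. Passing the end-to-end tests therefore demonstrates that the
statistical machinery is correct and internally consistent, not that every
real dataset will yield so clean a peak.

A note on estimator bias that the tests make visible: NG86 assumes equal
rates for transitions and transversions when counting sites, so under the
default `kappa = 2` it overestimates Ks by roughly 15–20%. Even at
`kappa = 1`, where its site counting is exact, NG86 retains a small
aggregation bias from applying one Jukes–Cantor correction across sites of
mixed degeneracy — about +5% at Ks 0.3, growing to roughly +17% by Ks 1.5
as the correction steepens towards saturation. The generator-consistency
checks therefore probe NG86 at `kappa = 1` and low divergence, where it is
a trustworthy oracle, while calibration across the full usable range
(slope of estimate on truth within [0.9, 1.1] up to Ks 1.5) is asserted
for the ML estimator, which shares the generator's model and tracks truth
throughout.

## Numerical choices

* The GY94 generator is diagonalized through its symmetrized similarity
  transform (the chain is reversible), so transition matrices at any
  branch length cost one matrix product; tiny negative entries from
  round-off are clamped and rows renormalized.
* F3x4 frequencies use a pseudocount of 0.5 per nucleotide per position,
  keeping the generator irreducible on short alignments.
* NG86 multi-hit codons average over all minimal mutational pathways,
  excluding pathways through stop codons (falling back to all pathways in
  the rare case every route is blocked); mutations to stop codons are
  excluded from both site classes.
* Ties in `select_peak_duplicates()` go to the smaller Ks; the
  representative is the pair closest to the fitted peak mean, with the
  literal "closest to a window boundary" rule selectable.
* The signed-rank null is exact (dynamic programming over doubled ranks,
  which are integers under average tie ranks) up to 25 informative pairs,
  and a continuity- and tie-corrected normal approximation beyond.
* Degenerate inputs are handled explicitly: empty filtered sets flow
  through histogramming, all-equal data force `k = 1` with a floored
  variance, all-zero paired differences report p = 1 with a warning, and
  families whose pairs are all saturated are dropped with a message.

## Design choices where the protocol was open

* **How the two significance tiers combine.** The permissive E-value
  clusters; the strict pair criteria gate the distribution. Both are
  exposed in the configuration.
* **Node weighting mechanics.** Average-linkage clustering on pairwise Ks
  defines the duplication nodes; alternative linkages would change little
  for well-separated events but average linkage matches the established
  node-weighting construction for paranome distributions.
* **Log-scale reporting.** Mixtures are fitted in ln(Ks); Ks-scale
  component means are `exp(mu)` and both log-scale and back-transformed
  variances are emitted, since published tables rarely state which scale
  their variance column uses.
* **Weighted EM.** Node weights enter the mixture likelihood as fractional
  observation counts by default; an unweighted mode reproduces the
  behaviour of fitting the raw values.
* **Candidate prefilter.** Exhaustive all-vs-all alignment is quadratic in
  the paranome; `all_vs_all()` therefore aligns only pairs sharing at
  least one informative protein 6-mer by default. Homologous pairs
  anywhere in the retained Ks range share many 6-mers, and the hit lists
  with and without the prefilter are asserted equal on synthetic data;
  `prefilter = "none"` remains available.

## Problem sizes used by the shipped checks

The test suite and the acceptance script are sized for a desk machine: the
mixture-recovery check simulates 8364 values from the published
7-component diploid mixture and refits with k = 7 (5 starts, 100 bootstrap
replicates); estimator consistency uses 50 replicates of 500-codon pairs
at Ks 0.2/0.5/1.0; the negative control runs 20 seeded SSD-only
populations of 2000 families on true Ks values; and the positive control
runs the full pipeline once on a 2000-family simulated paranome
(~4800 genes) from FASTA to dated peak.

## Known limitations

* Pairwise ML assumes one `omega` per pair and no among-site rate
  variation; gamma-distributed rates are out of scope.
* The local-alignment stage scores candidate pairs exactly but does not
  implement composition-based statistics; E-values use fixed published
  Karlin-Altschul constants rather than sequence-specific ones.
* Node weighting needs a Ks value per member pair; pairs whose estimates
  are saturated are imputed beyond the oldest observed event for the
  clustering and excluded from the output.
* Dating inherits the strict molecular clock: rate misspecification
  propagates linearly into ages, which is exactly why the rate-from-age
  inverse is provided.
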