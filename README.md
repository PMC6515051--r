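# wgdks

Detection and dating of whole-genome duplications (WGDs) from Ks age
distributions of coding sequences.

## The problem

An ancient polyploidy event duplicates every gene at once and leaves, among
the surviving paralog pairs of a genome or transcriptome, a cohort of equal
age. Because synonymous substitutions are approximately neutral, the
synonymous distance Ks between two paralogs grows roughly linearly with
time since their duplication; the distribution of Ks over the paranome is
therefore an age distribution. Continuous small-scale duplication and loss
produce an L-shaped background, and a WGD appears as a peak superimposed on
it. Locating that peak and converting it to an absolute age is a standard
analysis in plant comparative genomics — this package implements it end to
end, for anyone with a FASTA of coding sequences, together with a
codon-level simulator that makes every stage testable against known truth.

## What it computes

* **Paranome**: all-against-all exact Smith–Waterman protein alignment
  (BLOSUM62, affine gaps 11/1) with Karlin–Altschul E-values,
  `E = K m n e^{-λS}` (λ = 0.267, K = 0.041); gene families are connected
  components of hits with `E ≤ 1e-5`; pairs entering the distribution
  additionally need aligned length > 100 aa and `E < 1e-15`.
* **Ks per pair**: Nei–Gojobori (1986) counting with Jukes–Cantor
  correction (`ng86()`), and maximum likelihood under a Goldman–Yang codon
  model with F3×4 frequencies and free (t, κ, ω) (`ml_ks()`), with
  `Ks = t·ρ_S/(3 f_S)` by Yang's convention.
* **Redundancy correction**: average-linkage clustering of each family on
  pairwise Ks defines duplication nodes; each node's pairs share total
  weight exactly 1 (`node_weight()`).
* **Age distribution**: weighted histogram of Ks in [0.1, 5], bins of 0.1.
* **Peaks**: Gaussian mixtures on ln(Ks) fitted by weighted EM, number of
  components chosen by `BIC = 2·logL − p·log n` (`em_fit()`, `select_k()`);
  components with mean Ks in [0.5, 2] and proportion ≥ 0.1 are candidate
  WGDs.
* **Dating**: `T = Ks/(2r)` (`age_from_ks()`), or the inverse
  `r = Ks/(2T)` (`rate_from_age()`); distributions are compared with a
  Wilcoxon matched-pairs test on binned relative frequencies
  (`wilcoxon_matched()`).

## Worked example

Simulate a transcriptome-like paranome with a known WGD burst at Ks 1.2
(40% of duplication events) on an exponential small-scale-duplication
background, then run the full pipeline on the FASTA:

```r
library(wgdks)

cfg <- simulation_config(n_families = 150, seed = 42)
pop <- simulate_population(cfg)
write_cds_fasta(pop$sequences, "demo.fasta")

res <- run_pipeline(pipeline_config("demo.fasta", out_dir = "demo_out",
                                    seed = 1))
res$result$components[, c("mean_ks", "ci_lo", "ci_hi", "proportion", "label")]
res$result$dating
```

The run log prints each stage:

```
sequences: 352 valid, 0 excluded (demo.fasta)
all-vs-all: 267 significant hits (E <= 1e-05)
families: 149 families, 267 retained pairs
Ks estimates: 267 pairs (ML), 0 saturated
node weighting: 267 weighted pairs, 236 in [0.1, 5]
mixture: best k = 3 (BIC -349.323)
candidate WGD component: mean Ks 1.261 (proportion 0.470)
dating: 103 mya at rate 6.1e-09
```

and the component table reads:

```
  component mean_ks ci_lo ci_hi proportion         label
1         1   0.133 0.122 0.151     0.0958    background
2         2   0.475 0.373 0.577     0.4338    background
3         3   1.261 1.202 1.312     0.4704 candidate-WGD
```

Two background components describe the L-shaped SSD decay; the third —
mean Ks 1.26 with a bootstrap 95% CI of [1.20, 1.31], carrying 47% of the
weighted pairs — is the recovered burst (truth: 1.2). Under the
plant-average synonymous rate of 6.1×10⁻⁹ substitutions/site/year it dates
to 103 (98–108) million years; at this sample size the peak mean is a few
percent high, and the larger reference simulation (2000 families) recovers
1.21. All intermediates (hits, families, Ks table, weighted distribution,
histogram, mixture, dating) are persisted as TSV/JSON under `demo_out/`
along with a Ks-distribution plot.

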