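make_set <- function(nts, ids) sequence_set(nts, ids = ids,
                                            source_label = "test")

test_that("all-vs-all scores each unordered pair once and respects the E cutoff", {
  withr::with_seed(21, {
    base <- random_cds(200)
    mut <- function(nt, n) {
      cod <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
      pos <- sample(length(cod), n)
      sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
      cod[pos] <- sample(sense, n, replace = TRUE)
      paste(cod, collapse = "")
    }
    s <- make_set(c(base, mut(base, 10), mut(base, 20)), c("a", "b", "c"))
  })
  hits <- all_vs_all(s, prefilter = "none")
  expect_equal(nrow(hits), 3L)          # 3 mutually similar genes -> 3 hits
  expect_equal(anyDuplicated(paste(hits$query_id, hits$subject_id)), 0L)
  expect_true(all(hits$evalue <= 1e-5))
})

test_that("unrelated random sequences produce no significant hits", {
  ## 40 random 100-residue proteins: 780 chance comparisons, none should
  ## reach E <= 1e-5
  withr::with_seed(31, {
    nts <- vapply(1:40, function(i) random_cds(100), "")
  })
  s <- make_set(nts, sprintf("r%02d", 1:40))
  hits <- all_vs_all(s, prefilter = "none")
  expect_equal(nrow(hits), 0L)
})

test_that("hit lists and families are invariant to input order", {
  withr::with_seed(22, {
    cfg <- simulation_config(n_families = 8, seed = 101)
    pop <- simulate_population(cfg)
    s <- pop$sequences
    perm <- sample(length(s$id))
  })
  h1 <- all_vs_all(s)
  h2 <- all_vs_all(s[perm])
  expect_equal(h1, h2, ignore_attr = TRUE)
  f1 <- build_families(h1)
  f2 <- build_families(h2)
  expect_equal(f1$members, f2$members)
  expect_equal(f1$pairs, f2$pairs)
})

test_that("families are connected components with two-tier pair retention", {
  ## chain a-b, b-c (a-c insignificant) -> one family of three
  hits <- data.frame(
    query_id = c("a", "b"), subject_id = c("b", "c"),
    score = c(500, 500), aligned_length = c(150L, 150L),
    identity = c(0.9, 0.9), evalue = c(1e-40, 1e-40))
  fam <- build_families(hits)
  expect_equal(nrow(fam$members), 3L)
  expect_equal(length(unique(fam$members$family_id)), 1L)
  expect_equal(nrow(fam$pairs), 2L)

  ## aligned length exactly 100 is NOT retained (strict >), nor E = 1e-15
  hits2 <- data.frame(
    query_id = c("a", "a", "a"), subject_id = c("b", "c", "d"),
    score = 500, aligned_length = c(100L, 101L, 101L),
    identity = 0.9, evalue = c(1e-40, 1e-15, 1e-16))
  fam2 <- build_families(hits2)
  expect_equal(nrow(fam2$members), 4L)
  expect_equal(nrow(fam2$pairs), 1L)
  expect_equal(fam2$pairs$id_b, "d")

  ## 4-member clique: 6 candidate pairs, all retained here
  cl <- t(combn(c("w", "x", "y", "z"), 2))
  hits3 <- data.frame(query_id = cl[, 1], subject_id = cl[, 2],
                      score = 500, aligned_length = 150L, identity = 0.9,
                      evalue = 1e-40)
  fam3 <- build_families(hits3)
  expect_equal(nrow(fam3$pairs), 6L)           # n(n-1)/2
  expect_equal(as.integer(fam3$sizes), 4L)     # n-1 = 3 duplication events
})

test_that("synthetic families are each recovered as one component (Ks <= 2)", {
  cfg <- simulation_config(
    n_families = 25, ssd_rate = 1.2,
    wgd_components = list(list(mean_ks = 1.5, sd_log = 0.1, fraction = 0.3)),
    seed = 77)
  pop <- simulate_population(cfg)
  keep_fams <- unique(pop$truth$family_id[
    tapply(pop$truth$true_ks, pop$truth$family_id, max)[pop$truth$family_id] <= 2])
  fam <- build_families(all_vs_all(pop$sequences))
  gene_fam <- stats::setNames(fam$members$family_id, fam$members$member_id)
  for (tf in keep_fams) {
    genes <- unique(c(pop$truth$id_a[pop$truth$family_id == tf],
                      pop$truth$id_b[pop$truth$family_id == tf]))
    got <- unique(gene_fam[genes])
    expect_equal(length(got), 1L, info = tf)
    expect_false(any(is.na(got)), info = tf)
  }
  ## retention only removes: retained pairs never exceed possible pairs
  sizes <- as.integer(fam$sizes)
  expect_lte(nrow(fam$pairs), sum(sizes * (sizes - 1) / 2))
})

test_that("kmer prefilter finds the same significant hits as exhaustive scoring", {
  cfg <- simulation_config(n_families = 12, seed = 55)
  pop <- simulate_population(cfg)
  h_all <- all_vs_all(pop$sequences, prefilter = "none")
  h_kmer <- all_vs_all(pop$sequences, prefilter = "kmer")
  expect_equal(h_kmer, h_all, ignore_attr = TRUE)
})
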