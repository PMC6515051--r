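test_that("node weighting reproduces the enumerated merge order", {
  ## 2-member family: single pair, weight 1
  p2 <- data.frame(family_id = "f", id_a = "A", id_b = "B", ks = 0.4)
  w2 <- node_weight(p2)
  expect_equal(w2$weight, 1)

  ## 3-member family with Ks (A,B)=0.2, (A,C)=1.0, (B,C)=1.1:
  ## average linkage merges {A,B} first, then {AB,C};
  ## (A,B) gets weight 1, (A,C) and (B,C) each 0.5, total 2 = n - 1
  p3 <- data.frame(family_id = "f",
                   id_a = c("A", "A", "B"), id_b = c("B", "C", "C"),
                   ks = c(0.2, 1.0, 1.1))
  w3 <- node_weight(p3)
  expect_equal(w3$weight[w3$id_a == "A" & w3$id_b == "B"], 1)
  expect_equal(w3$weight[w3$id_a == "A" & w3$id_b == "C"], 0.5)
  expect_equal(w3$weight[w3$id_a == "B" & w3$id_b == "C"], 0.5)
  expect_equal(sum(w3$weight), 2)
  expect_equal(length(unique(w3$node_id)), 2L)
})

test_that("node weights are conserved and invariant to relabeling", {
  cfg <- simulation_config(n_families = 120, seed = 12,
                           family_size_probs = c(`2` = 0.3, `3` = 0.3,
                                                 `4` = 0.25, `5` = 0.15))
  tr <- simulate_history(cfg)
  pairs <- data.frame(family_id = tr$family_id, id_a = tr$id_a,
                      id_b = tr$id_b, ks = tr$true_ks)
  w <- node_weight(pairs)
  ## per node: weights sum to exactly 1
  node_sums <- tapply(w$weight, w$node_id, sum)
  expect_true(all(abs(node_sums - 1) < 1e-12))
  ## per family: total weight = node count <= n - 1
  fam_w <- tapply(w$weight, w$family_id, sum)
  fam_nodes <- tapply(w$node_id, w$family_id, function(x) length(unique(x)))
  expect_equal(as.numeric(fam_w), as.numeric(fam_nodes))
  fam_n <- tapply(c(w$id_a, w$id_b), c(w$family_id, w$family_id),
                  function(x) length(unique(x)))
  expect_true(all(as.numeric(fam_nodes) <= as.numeric(fam_n) - 1 + 1e-12))

  ## invariance under pair reordering and member relabeling
  withr::with_seed(3, perm <- sample(nrow(pairs)))
  w_perm <- node_weight(pairs[perm, ])
  key <- function(d) paste(d$id_a, d$id_b)
  expect_equal(w_perm$weight[order(key(w_perm))], w$weight[order(key(w))])
})

test_that("node assignment recovers well-separated duplication events", {
  ## 4-member family: old event at Ks 2 splitting {A,B} from {C,D}, then
  ## young events at 0.2 and 0.3 -> 3 nodes with pair partition
  ## {AB}, {CD}, {AC, AD, BC, BD}
  p <- data.frame(family_id = "f",
                  id_a = c("A", "C", "A", "A", "B", "B"),
                  id_b = c("B", "D", "C", "D", "C", "D"),
                  ks = c(0.2, 0.3, 2.0, 2.1, 1.9, 2.05))
  w <- node_weight(p)
  nid <- stats::setNames(w$node_id, paste(w$id_a, w$id_b))
  expect_equal(length(unique(nid)), 3L)
  expect_false(nid[["A B"]] == nid[["C D"]])
  old <- nid[c("A C", "A D", "B C", "B D")]
  expect_equal(length(unique(old)), 1L)
  expect_equal(unname(w$weight[paste(w$id_a, w$id_b) == "A C"]), 0.25)
})

test_that("saturated pairs are excluded; all-saturated families dropped", {
  p <- data.frame(family_id = c("f1", "f1", "f1", "f2"),
                  id_a = c("A", "A", "B", "X"), id_b = c("B", "C", "C", "Y"),
                  ks = c(0.5, NA, 1.2, NA))
  expect_message(w <- node_weight(p), "saturated")
  expect_false("f2" %in% w$family_id)
  expect_equal(nrow(w), 2L)
  node_sums <- tapply(w$weight, w$node_id, sum)
  expect_true(all(abs(node_sums - 1) < 1e-12))
})

test_that("the Ks filter is inclusive at both ends", {
  w <- data.frame(family_id = "f", id_a = "a", id_b = "b",
                  ks = c(0.05, 0.1, 2, 5, 5.01), node_id = "n",
                  weight = 0.2)
  f <- filter_ks(w)
  expect_equal(f$ks, c(0.1, 2, 5))
  expect_equal(f$weight, rep(0.2, 3))   # weights unaltered
  expect_equal(nrow(filter_ks(w[w$ks > 9, ])), 0L)
})

test_that("histogram bins are half-open with conserved mass", {
  w <- data.frame(family_id = "f", id_a = "a", id_b = "b",
                  ks = c(0.15, 0.17, 0.2, 5.0), node_id = "n",
                  weight = c(1, 0.5, 0.25, 0.25))
  h <- ks_histogram(w)
  expect_equal(h$bins$weight[h$bins$bin_lo == 0.1], 1.5)   # [0.1, 0.2)
  expect_equal(h$bins$weight[h$bins$bin_lo == 0.2], 0.25)
  expect_equal(h$bins$weight[h$bins$bin_lo == 4.9], 0.25)  # last bin closed
  expect_equal(h$total_weight, sum(w$weight))
  h0 <- ks_histogram(w[0, ])
  expect_equal(h0$total_weight, 0)
  expect_true(all(h0$bins$weight == 0))
})

test_that("one representative peak duplicate per family", {
  w <- data.frame(family_id = c("f1", "f1", "f1", "f2", "f3"),
                  id_a = letters[1:5], id_b = LETTERS[1:5],
                  ks = c(0.5, 1.0, 1.45, 1.2, 0.3),
                  node_id = paste0("n", 1:5), weight = 1)
  sel <- select_peak_duplicates(w, peak_mean = 1.15)
  expect_equal(nrow(sel), 2L)                       # f3 has no in-window pair
  expect_equal(sel$ks[sel$family_id == "f1"], 1.0)  # |1.0-1.15| < |1.45-1.15|
  expect_equal(sel$ks[sel$family_id == "f2"], 1.2)
  ## tie goes to the smaller Ks
  wt <- data.frame(family_id = "f", id_a = c("a", "b"), id_b = c("A", "B"),
                   ks = c(1.0, 1.3), node_id = c("n1", "n2"), weight = 1)
  expect_equal(select_peak_duplicates(wt, peak_mean = 1.15)$ks, 1.0)
  ## boundary rule is selectable
  sel_b <- select_peak_duplicates(w, peak_mean = 1.15, rule = "boundary")
  expect_equal(sel_b$ks[sel_b$family_id == "f1"], 1.45)
})
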