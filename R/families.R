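# Paralog gene families from all-vs-all protein similarity.  Two-tier
# significance: a permissive E-value (1e-5) defines family membership
# (single-linkage components of the hit graph), while a stricter criterion
# (aligned length > 100 aa and E < 1e-15) gates which pairs enter the Ks
# distribution.

## Candidate pair generation by shared protein k-mers.  This is a pure
## prefilter in front of the exact Smith-Waterman scoring: it only decides
## which pairs get aligned, never how they score.  Homologous pairs retained
## anywhere in the usable Ks range share tens of 6-mers, so a threshold of a
## single shared 6-mer keeps them while discarding the vast majority of the
## n(n-1)/2 unrelated pairs.  `prefilter = "none"` scores every pair.
kmer_candidates <- function(aa, k = 6L, min_share = 1L, max_occ = 50L) {
  n <- length(aa)
  lst <- lapply(seq_len(n), function(i) {
    L <- nchar(aa[i])
    if (L < k) return(character(0))
    unique(substring(aa[i], 1:(L - k + 1L), k:L))
  })
  dt <- data.table::data.table(kmer = unlist(lst),
                               i = rep(seq_len(n), lengths(lst)))
  occ <- dt[, .N, by = kmer]
  dt <- dt[kmer %in% occ$kmer[occ$N <= max_occ]]
  if (!nrow(dt)) return(matrix(integer(0), ncol = 2))
  mg <- merge(dt, dt, by = "kmer", allow.cartesian = TRUE)
  mg <- mg[i.x < i.y]
  if (!nrow(mg)) return(matrix(integer(0), ncol = 2))
  pc <- mg[, .N, by = .(i.x, i.y)]
  pc <- pc[N >= min_share]
  cbind(pc$i.x, pc$i.y)
}

#' All-against-all protein similarity search
#'
#' Scores sequence pairs by exact Smith-Waterman local alignment and keeps
#' hits whose Karlin-Altschul E-value (computed database-style, with n =
#' total residue count of the set) passes `family_evalue`.  Self hits are
#' excluded and each unordered pair is scored once.
#'
#' @param seqs a [sequence_set()].
#' @param family_evalue E-value cutoff defining a significant hit
#'   (default 1e-5).
#' @param prefilter `"kmer"` aligns only pairs sharing at least
#'   `kmer_min_share` protein k-mers (see Details in the package vignette);
#'   `"none"` aligns every pair.
#' @param kmer_k,kmer_min_share,kmer_max_occ prefilter tuning: k-mer size,
#'   minimum shared k-mers, and the occupancy above which a (low-complexity)
#'   k-mer is ignored.
#' @inheritParams smith_waterman
#' @param lambda,K Karlin-Altschul constants (gapped BLOSUM62 11/1 defaults).
#' @return data frame of hits with columns `query_id`, `subject_id`
#'   (lexicographically ordered within each row), `score`, `aligned_length`,
#'   `identity`, `evalue`; attribute `db_residues` holds the search-space
#'   size.
#' @export
all_vs_all <- function(seqs, family_evalue = 1e-5,
                       prefilter = c("kmer", "none"),
                       kmer_k = 6L, kmer_min_share = 1L, kmer_max_occ = 50L,
                       matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                       lambda = 0.267, K = 0.041) {
  stopifnot(inherits(seqs, "SequenceSet"))
  prefilter <- match.arg(prefilter)
  n <- length(seqs$id)
  if (n < 2L) stop("need at least two sequences")
  cand <- if (prefilter == "kmer")
    kmer_candidates(seqs$aa, kmer_k, kmer_min_share, kmer_max_occ)
  else
    t(utils::combn(n, 2L))
  empty <- data.frame(query_id = character(0), subject_id = character(0),
                      score = numeric(0), aligned_length = integer(0),
                      identity = numeric(0), evalue = numeric(0),
                      stringsAsFactors = FALSE)
  db_residues <- sum(nchar(seqs$aa))
  attr(empty, "db_residues") <- db_residues
  if (!nrow(cand)) return(empty)

  sm <- substitution_matrix(matrix)
  ord <- order(cand[, 2], cand[, 1])
  ci <- cand[ord, 1]
  cj <- cand[ord, 2]
  score <- numeric(length(ci))
  alen <- integer(length(ci))
  ident <- numeric(length(ci))
  pos <- 1L
  for (j in unique(cj)) {
    sel <- which(cj == j)
    pat <- Biostrings::AAStringSet(seqs$aa[ci[sel]])
    aln <- Biostrings::pairwiseAlignment(
      pat, Biostrings::AAString(seqs$aa[j]), type = "local",
      substitutionMatrix = sm, gapOpening = gap_open,
      gapExtension = gap_extend)
    st <- aln_stats(aln)
    score[sel] <- Biostrings::score(aln)
    alen[sel] <- st$aligned_length
    ident[sel] <- st$identity
    pos <- pos + length(sel)
  }
  ev <- evalue(score, m = nchar(seqs$aa[ci]), n = db_residues, lambda, K)
  keep <- score > 0 & ev <= family_evalue
  if (!any(keep)) return(empty)
  ia <- seqs$id[ci[keep]]
  ib <- seqs$id[cj[keep]]
  hits <- data.frame(query_id = pmin(ia, ib), subject_id = pmax(ia, ib),
                     score = score[keep], aligned_length = alen[keep],
                     identity = ident[keep], evalue = ev[keep],
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$query_id, hits$subject_id), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "db_residues") <- db_residues
  hits
}

#' Build gene families from significant hits
#'
#' Families are the connected components (single linkage) of the hit graph;
#' within each family, the pairs that enter the Ks age distribution are
#' those whose alignment length strictly exceeds `pair_min_length` residues
#' and whose E-value is below `pair_evalue`.  Singletons never appear since
#' every vertex of the hit graph has at least one edge.
#'
#' @param hits hit table from [all_vs_all()].
#' @param pair_min_length minimum aligned length (strict `>`, default 100
#'   aa) for a retained pair.
#' @param pair_evalue E-value bound (strict `<`, default 1e-15) for a
#'   retained pair.
#' @return object of class `gene_families`: list with `members` (data frame
#'   `family_id`, `member_id`), `pairs` (retained pairs with their hit
#'   statistics) and `sizes`.
#' @export
build_families <- function(hits, pair_min_length = 100, pair_evalue = 1e-15) {
  if (!nrow(hits))
    return(structure(list(members = data.frame(family_id = character(0),
                                               member_id = character(0)),
                          pairs = data.frame(), sizes = integer(0)),
                     class = "gene_families"))
  g <- igraph::graph_from_data_frame(hits[, c("query_id", "subject_id")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership
  by_comp <- split(names(memb), memb)
  first_member <- vapply(by_comp, min, character(1))
  ord <- order(first_member)
  fam_id_of_comp <- character(length(by_comp))
  fam_id_of_comp[ord] <- sprintf("F%05d", seq_along(ord))
  names(fam_id_of_comp) <- names(by_comp)

  members <- data.frame(
    family_id = fam_id_of_comp[as.character(memb)],
    member_id = names(memb), stringsAsFactors = FALSE)
  members <- members[order(members$family_id, members$member_id), ,
                     drop = FALSE]
  rownames(members) <- NULL

  fam_of_gene <- stats::setNames(members$family_id, members$member_id)
  retained <- hits$aligned_length > pair_min_length & hits$evalue < pair_evalue
  pairs <- hits[retained, , drop = FALSE]
  pairs <- data.frame(family_id = unname(fam_of_gene[pairs$query_id]),
                      id_a = pairs$query_id, id_b = pairs$subject_id,
                      score = pairs$score,
                      aligned_length = pairs$aligned_length,
                      identity = pairs$identity, evalue = pairs$evalue,
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$family_id, pairs$id_a, pairs$id_b), ,
                 drop = FALSE]
  rownames(pairs) <- NULL

  structure(list(members = members, pairs = pairs,
                 sizes = table(members$family_id)),
            class = "gene_families")
}

#' @export
print.gene_families <- function(x, ...) {
  cat(sprintf("gene_families: %d families, %d genes, %d retained pairs\n",
              length(unique(x$members$family_id)), nrow(x$members),
              nrow(x$pairs)))
  if (length(x$sizes))
    cat("  family sizes:",
        paste(sprintf("%s:%d", names(table(as.integer(x$sizes))),
                      as.integer(table(as.integer(x$sizes)))),
              collapse = " "), "\n")
  invisible(x)
}
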