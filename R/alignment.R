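# Pairwise protein alignment (exact local alignment for homolog detection,
# global alignment for Ks input) plus Karlin-Altschul E-value statistics and
# codon back-translation.  The dynamic programming itself is delegated to
# Biostrings::pairwiseAlignment, which computes optimal affine-gap
# alignments; this module fixes the scoring conventions (BLOSUM62, gap
# open 11 / extend 1, i.e. a gap of length L costs 11 + L) so that hit
# significance reproduces the decision behaviour of a default BLASTP run.

.align_cache <- new.env(parent = emptyenv())

substitution_matrix <- function(name = "BLOSUM62") {
  if (is.matrix(name)) return(name)
  if (is.null(.align_cache[[name]])) {
    e <- new.env(parent = emptyenv())
    utils::data(list = name, package = "Biostrings", envir = e)
    .align_cache[[name]] <- e[[name]]
  }
  .align_cache[[name]]
}

aln_stats <- function(aln) {
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  list(aligned_length = nm + nmm,
       identity = ifelse(nm + nmm > 0, nm / (nm + nmm), NA_real_))
}

#' Optimal local (Smith-Waterman) protein alignment
#'
#' Exact affine-gap local alignment; the score floor is 0 (the empty
#' alignment), in which case the result is reported as no hit.
#'
#' @param a,b amino-acid strings (non-empty).
#' @param matrix substitution matrix name (from Biostrings) or a numeric
#'   matrix; default BLOSUM62.
#' @param gap_open,gap_extend affine gap penalties (positive); a gap of
#'   length L costs `gap_open + L * gap_extend`.
#' @return list with `score`, `aligned_length` (gap columns excluded),
#'   `identity` (fraction of identical aligned residue pairs), and the two
#'   gapped alignment strings `a_aligned` / `b_aligned` (empty when no
#'   positive-scoring local alignment exists).
#' @export
smith_waterman <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1) {
  stopifnot(nzchar(a), nzchar(b))
  sm <- substitution_matrix(matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = sm, gapOpening = gap_open, gapExtension = gap_extend)
  sc <- Biostrings::score(aln)
  if (sc <= 0)
    return(list(score = 0, aligned_length = 0L, identity = NA_real_,
                a_aligned = "", b_aligned = ""))
  st <- aln_stats(aln)
  list(score = sc, aligned_length = st$aligned_length,
       identity = st$identity,
       a_aligned = as.character(Biostrings::alignedPattern(aln)),
       b_aligned = as.character(Biostrings::alignedSubject(aln)))
}

#' Optimal global (Needleman-Wunsch) protein alignment
#'
#' Affine-gap global alignment with deterministic traceback (ties broken
#' diagonal > up > left).
#'
#' @inheritParams smith_waterman
#' @return list with `score`, the gapped strings `a_aligned` / `b_aligned`
#'   (equal lengths), `aligned_length` (gap-free columns) and `identity`.
#' @export
needleman_wunsch <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                             gap_extend = 1) {
  stopifnot(nzchar(a), nzchar(b))
  sm <- substitution_matrix(matrix)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  ai <- match(av, rownames(sm))
  bi <- match(bv, colnames(sm))
  if (anyNA(ai) || anyNA(bi))
    stop("residue not present in the substitution matrix")
  r <- .nw_align(ai, bi, sm, gap_open, gap_extend)
  ga <- ifelse(r$a_pos == 0L, "-", av[pmax(r$a_pos, 1L)])
  gb <- ifelse(r$b_pos == 0L, "-", bv[pmax(r$b_pos, 1L)])
  keep <- r$a_pos > 0L & r$b_pos > 0L
  nm <- sum(av[r$a_pos[keep]] == bv[r$b_pos[keep]])
  list(score = r$score,
       a_aligned = paste(ga, collapse = ""),
       b_aligned = paste(gb, collapse = ""),
       aligned_length = sum(keep),
       identity = if (sum(keep)) nm / sum(keep) else NA_real_)
}

#' Karlin-Altschul E-value of an alignment score
#'
#' E = K m n exp(-lambda S): the expected number of chance local alignments
#' scoring at least S between a query of length m and a search space of n
#' residues.  The default constants are the published gapped BLOSUM62
#' (11/1) values lambda = 0.267, K = 0.041.
#'
#' @param score alignment score(s).
#' @param m query length in residues.
#' @param n subject length, or total residue count of the searched set for
#'   database-style searches.
#' @param lambda,K Karlin-Altschul parameters (both positive).
#' @return E-value(s), same length as `score`.
#' @export
evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  stopifnot(lambda > 0, K > 0)
  if (any(m <= 0) || any(n <= 0)) stop("sequence lengths must be positive")
  K * m * n * exp(-lambda * score)
}

#' Codon alignment container
#'
#' @param gene_a,gene_b gene identifiers.
#' @param codons_a,codons_b equal-length character vectors of aligned sense
#'   codons (gap-containing columns already removed).
#' @return object of class `codon_alignment` with `n_codons` columns.
#' @export
codon_alignment <- function(gene_a, gene_b, codons_a, codons_b) {
  stopifnot(length(codons_a) == length(codons_b), length(codons_a) >= 1L)
  tab <- codon_tables()
  bad <- is.na(tab$codon_to_idx[codons_a]) | is.na(tab$codon_to_idx[codons_b])
  if (any(bad))
    stop("non-sense codon in alignment column ", which(bad)[1])
  structure(list(gene_a = gene_a, gene_b = gene_b,
                 codons_a = codons_a, codons_b = codons_b,
                 n_codons = length(codons_a)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon alignment %s / %s: %d gap-free codon columns\n",
              x$gene_a, x$gene_b, x$n_codons))
  invisible(x)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each aligned (gap-free) protein column becomes the corresponding codon
#' pair; columns where either row is a gap are removed.
#'
#' @param alignment list with gapped strings `a_aligned` and `b_aligned`
#'   (e.g. the result of [needleman_wunsch()]).
#' @param nt_a,nt_b the coding sequences whose translations were aligned
#'   (terminal stop already stripped).
#' @param id_a,id_b gene identifiers carried into the result.
#' @return a [codon_alignment()].
#' @export
backtranslate <- function(alignment, nt_a, nt_b, id_a = "a", id_b = "b") {
  ca <- strsplit(alignment$a_aligned, "")[[1]]
  cb <- strsplit(alignment$b_aligned, "")[[1]]
  stopifnot(length(ca) == length(cb))
  check_row <- function(chars, nt, label) {
    aa <- translate(nt)
    ung <- paste(chars[chars != "-"], collapse = "")
    if (ung != aa) {
      n <- min(nchar(ung), nchar(aa))
      pos <- which(strsplit(ung, "")[[1]][seq_len(n)] !=
                     strsplit(aa, "")[[1]][seq_len(n)])
      pos <- if (length(pos)) pos[1] else n + 1L
      stop(sprintf("translation mismatch for %s at residue %d", label, pos))
    }
  }
  check_row(ca, nt_a, id_a)
  check_row(cb, nt_b, id_b)
  ia <- cumsum(ca != "-")
  ib <- cumsum(cb != "-")
  keep <- ca != "-" & cb != "-"
  if (!any(keep)) stop("no gap-free alignment columns")
  cod <- function(nt, k)
    substring(nt, 3L * (k - 1L) + 1L, 3L * k)
  codon_alignment(id_a, id_b, cod(nt_a, ia[keep]), cod(nt_b, ib[keep]))
}

#' Align a pair of coding sequences at the codon level
#'
#' Convenience wrapper: global protein alignment of the translations,
#' back-translated to codons.
#'
#' @inheritParams backtranslate
#' @inheritParams smith_waterman
#' @return a [codon_alignment()].
#' @export
align_codon_pair <- function(nt_a, nt_b, id_a = "a", id_b = "b",
                             matrix = "BLOSUM62", gap_open = 11,
                             gap_extend = 1) {
  pa <- needleman_wunsch(translate(nt_a), translate(nt_b), matrix,
                         gap_open, gap_extend)
  backtranslate(pa, nt_a, nt_b, id_a, id_b)
}
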