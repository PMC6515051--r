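# Reading, validating and translating coding sequences.  A SequenceSet is
# the unit every downstream stage consumes: an ordered set of validated CDS
# with their conceptual translations and a report of the records that were
# rejected (and why).

#' Translate a coding sequence under the standard genetic code
#'
#' @param nt nucleotide string; length must be a positive multiple of 3 and
#'   contain only `A`, `C`, `G`, `T` (case-insensitive).
#' @return amino-acid string; stop codons are rendered as `"*"`.
#' @examples
#' translate("ATGGCTTGA")  # "MA*"
#' @export
translate <- function(nt) {
  stopifnot(is.character(nt), length(nt) == 1L)
  nt <- toupper(nt)
  L <- nchar(nt)
  if (L == 0L || L %% 3L != 0L)
    stop("sequence length must be a positive multiple of 3")
  bad <- regexpr("[^ACGT]", nt)
  if (bad > 0L)
    stop(sprintf("invalid character '%s' at position %d",
                 substr(nt, bad, bad), bad))
  codons <- substring(nt, seq(1L, L, 3L), seq(3L, L, 3L))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

## Validate one CDS.  Returns list(nt, aa) on success, or a character reason
## on rejection.  A single terminal stop codon is stripped from both the
## nucleotide and protein sequence so codon alignments only ever hold sense
## codons.
validate_cds <- function(nt, on_ambiguous = c("drop", "mask")) {
  on_ambiguous <- match.arg(on_ambiguous)
  nt <- toupper(nt)
  if (nchar(nt) == 0L) return("empty sequence")
  if (nchar(nt) %% 3L != 0L) return("length not multiple of 3")
  if (grepl("[^ACGT]", nt)) {
    if (on_ambiguous == "drop") return("ambiguous bases")
    codons <- substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
    codons <- codons[!grepl("[^ACGT]", codons)]
    if (!length(codons)) return("no unambiguous codons")
    nt <- paste(codons, collapse = "")
  }
  aa <- translate(nt)
  if (substring(aa, nchar(aa)) == "*") {      # strip one terminal stop
    aa <- substr(aa, 1L, nchar(aa) - 1L)
    nt <- substr(nt, 1L, nchar(nt) - 3L)
  }
  if (nchar(aa) == 0L) return("only a stop codon")
  if (grepl("*", aa, fixed = TRUE)) return("internal stop")
  list(nt = nt, aa = aa)
}

#' Construct a validated set of coding sequences
#'
#' Each record is checked against the coding-sequence invariants (length a
#' positive multiple of 3, unambiguous bases, no internal stop codons; a
#' single terminal stop is stripped before storage).  Failing records are
#' excluded, not fatal, and reported with a reason.
#'
#' @param nt named character vector of nucleotide sequences (or unnamed with
#'   `ids` supplied).
#' @param ids sequence identifiers, unique within the set.
#' @param source_label free-text label for the dataset (e.g. `"diploid"`).
#' @param on_ambiguous `"drop"` excludes records containing ambiguity codes
#'   (the default; transcriptome CDS sets contain few), `"mask"` removes the
#'   offending codons instead.
#' @return an object of class `SequenceSet`: parallel vectors `id`, `nt`,
#'   `aa` plus the `excluded` data frame (`id`, `reason`).
#' @export
sequence_set <- function(nt, ids = names(nt), source_label = "unnamed",
                         on_ambiguous = c("drop", "mask")) {
  on_ambiguous <- match.arg(on_ambiguous)
  if (is.null(ids)) stop("sequence ids are required")
  ids <- as.character(ids)
  stopifnot(length(ids) == length(nt))

  keep_id <- character(0)
  keep_nt <- character(0)
  keep_aa <- character(0)
  exc_id <- character(0)
  exc_reason <- character(0)
  seen <- new.env(parent = emptyenv())
  for (k in seq_along(nt)) {
    id <- ids[k]
    if (!is.null(seen[[id]])) {
      exc_id <- c(exc_id, id)
      exc_reason <- c(exc_reason, "duplicate id")
      next
    }
    seen[[id]] <- TRUE
    v <- validate_cds(nt[[k]], on_ambiguous)
    if (is.character(v)) {
      exc_id <- c(exc_id, id)
      exc_reason <- c(exc_reason, v)
    } else {
      keep_id <- c(keep_id, id)
      keep_nt <- c(keep_nt, v$nt)
      keep_aa <- c(keep_aa, v$aa)
    }
  }
  if (!length(keep_id)) stop("no valid coding sequences")
  structure(list(id = keep_id, nt = keep_nt, aa = keep_aa,
                 source_label = source_label,
                 excluded = data.frame(id = exc_id, reason = exc_reason,
                                       stringsAsFactors = FALSE)),
            class = "SequenceSet")
}

#' Read coding sequences from a nucleotide FASTA file
#'
#' Ids are taken up to the first whitespace of the description line; wrapped
#' and unwrapped FASTA are both accepted.  Records failing the
#' coding-sequence invariants are excluded and reported (see
#' [sequence_set()]).
#'
#' @param path FASTA file of frame-0 coding sequences.
#' @inheritParams sequence_set
#' @return a `SequenceSet`.
#' @export
read_cds_fasta <- function(path, source_label = basename(path),
                           on_ambiguous = c("drop", "mask")) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  x <- Biostrings::readDNAStringSet(path)
  if (!length(x)) stop("no FASTA records in '", path, "'")
  ids <- sub("\\s.*$", "", names(x))
  sequence_set(as.character(x), ids = ids, source_label = source_label,
               on_ambiguous = on_ambiguous)
}

#' Write a SequenceSet to FASTA
#'
#' @param x a `SequenceSet`.
#' @param path output path.
#' @param what `"nt"` for the coding sequences, `"aa"` for the translations.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(x, path, what = c("nt", "aa")) {
  what <- match.arg(what)
  stopifnot(inherits(x, "SequenceSet"))
  set <- if (what == "nt")
    Biostrings::DNAStringSet(stats::setNames(x$nt, x$id))
  else
    Biostrings::AAStringSet(stats::setNames(x$aa, x$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Validation report of a SequenceSet
#'
#' @param x a `SequenceSet`.
#' @param path optional path; when given, the report is also written as TSV.
#' @return data frame with columns `id` and `reason`.
#' @export
validation_report <- function(x, path = NULL) {
  stopifnot(inherits(x, "SequenceSet"))
  rep <- x$excluded
  if (!is.null(path)) write_tsv(rep, path)
  rep
}

#' @export
length.SequenceSet <- function(x) length(x$id)

#' @export
`[.SequenceSet` <- function(x, i) {
  structure(list(id = x$id[i], nt = x$nt[i], aa = x$aa[i],
                 source_label = x$source_label,
                 excluded = x$excluded),
            class = "SequenceSet")
}

#' @export
print.SequenceSet <- function(x, ...) {
  cat(sprintf("SequenceSet '%s': %d coding sequences (%d excluded)\n",
              x$source_label, length(x$id), nrow(x$excluded)))
  if (length(x$id)) {
    show <- utils::head(seq_along(x$id), 3L)
    for (k in show)
      cat(sprintf("  %s  %d nt / %d aa\n", x$id[k], nchar(x$nt[k]),
                  nchar(x$aa[k])))
    if (length(x$id) > 3L) cat("  ...\n")
  }
  invisible(x)
}
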