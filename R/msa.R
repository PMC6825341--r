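#' Aligned sequence sets and effective-sequence statistics
#'
#' An `AlignedSequenceSet` is a multiple sequence alignment (MSA) with a
#' designated query row. All rows share the same number of columns; gaps are
#' `-`. The alignment width is taken as the query length `L` used by the
#' effective-sequence-count statistic.
#'
#' @param ids character vector of row identifiers.
#' @param seqs character vector of aligned sequences (equal lengths, `-` gaps).
#' @param query_id identifier of the query row; defaults to the first row.
#' @return An object of class `AlignedSequenceSet` with elements `query_id`,
#'   `ids`, `seqs`, `L` (alignment width) and `n_seq`.
#' @export
aligned_set <- function(ids, seqs, query_id = ids[[1]]) {
  if (length(ids) != length(seqs)) {
    cf_abort("cf_parse_error", "ids and seqs lengths differ")
  }
  if (length(seqs) == 0L) {
    cf_abort("cf_empty_alignment_error", "alignment has no rows")
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    cf_abort("cf_ragged_alignment_error",
             "ragged alignment: row widths %s", paste(unique(widths), collapse = ", "))
  }
  if (widths[[1]] < 1L) {
    cf_abort("cf_empty_alignment_error", "alignment has zero columns")
  }
  if (!query_id %in% ids) {
    cf_abort("cf_parse_error", "query '%s' not present in alignment", query_id)
  }
  structure(
    list(query_id = query_id, ids = unname(as.character(ids)),
         seqs = unname(toupper(as.character(seqs))),
         L = as.integer(widths[[1]]), n_seq = length(seqs)),
    class = "AlignedSequenceSet"
  )
}

#' @export
print.AlignedSequenceSet <- function(x, ...) {
  cat(sprintf("AlignedSequenceSet: %d rows x %d columns (query: %s)\n",
              x$n_seq, x$L, x$query_id))
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Parses FASTA, Stockholm, or A3M alignments into an [aligned_set()]. A3M
#' lowercase letters mark insertion states relative to the query and are
#' removed, as are `.` columns, so every row is reduced to match columns.
#'
#' @param path file path.
#' @param format one of `"fasta"`, `"stockholm"`, `"a3m"`.
#' @param query_id optional query identifier; defaults to the first row.
#' @return An `AlignedSequenceSet`.
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm", "a3m"),
                           query_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    cf_abort("cf_unreadable_error", "cannot read alignment file '%s'", path)
  }
  if (format == "stockholm") {
    aln <- tryCatch(
      Biostrings::readAAMultipleAlignment(path, format = "stockholm"),
      error = function(e) cf_abort("cf_unreadable_error",
                                   "failed to parse Stockholm file '%s': %s",
                                   path, conditionMessage(e)))
    seqs <- as.character(Biostrings::unmasked(aln))
    ids <- names(seqs)
  } else {
    set <- tryCatch(
      Biostrings::readBStringSet(path, format = "fasta"),
      error = function(e) cf_abort("cf_unreadable_error",
                                   "failed to parse FASTA file '%s': %s",
                                   path, conditionMessage(e)))
    seqs <- as.character(set)
    ids <- sub("\\s.*$", "", names(set))
    if (format == "a3m") {
      # lowercase = insertion state, '.' = insertion gap: both dropped
      seqs <- gsub("[a-z.]", "", seqs)
    }
  }
  if (length(seqs) == 0L) {
    cf_abort("cf_empty_alignment_error", "alignment '%s' has no rows", path)
  }
  seqs <- chartr(".", "-", seqs)
  aligned_set(ids, seqs, query_id = query_id %||% ids[[1]])
}

#' Write an alignment as aligned FASTA
#'
#' @param msa an `AlignedSequenceSet`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path) {
  stopifnot(inherits(msa, "AlignedSequenceSet"))
  writeLines(paste0(">", msa$ids, "\n", msa$seqs), path)
  invisible(path)
}

# Character matrix view of the alignment (rows x columns).
msa_matrix <- function(msa) {
  m <- matrix(unlist(strsplit(msa$seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = msa$n_seq, ncol = msa$L, byrow = TRUE)
  rownames(m) <- msa$ids
  m
}

#' Pairwise sequence identity between two aligned rows
#'
#' Identity is the fraction of identical residues over the columns where both
#' rows are non-gap (local-alignment convention). With no co-aligned column
#' the identity is 0.
#'
#' @param a,b aligned strings of equal length.
#' @return identity in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    cf_abort("cf_length_mismatch_error", "aligned strings differ in length")
  }
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  both <- av != "-" & bv != "-"
  n <- sum(both)
  if (n == 0L) return(0)
  sum(av[both] == bv[both]) / n
}

#' Pairwise identity matrix of an alignment
#'
#' Computes the full symmetric matrix of [pairwise_identity()] values.
#' Internally one-hot encodes the alignment so the O(n^2 L) count reduces to
#' a handful of BLAS cross-products.
#'
#' @param msa an `AlignedSequenceSet`.
#' @return an `n_seq` x `n_seq` matrix with unit diagonal.
#' @export
identity_matrix <- function(msa) {
  m <- msa_matrix(msa)
  nongap <- m != "-"
  letters_used <- setdiff(unique(as.vector(m)), "-")
  matches <- matrix(0, nrow(m), nrow(m))
  for (a in letters_used) {
    xa <- (m == a) * 1
    matches <- matches + tcrossprod(xa)
  }
  coal <- tcrossprod(nongap * 1)
  s <- ifelse(coal > 0, matches / pmax(coal, 1), 0)
  diag(s) <- 1
  s
}

#' Effective number of sequences (Nf)
#'
#' Length-normalized count of sequence clusters at an identity threshold:
#' \deqn{Nf = \frac{1}{\sqrt{L}} \sum_{i=1}^{n_{seq}}
#'       \frac{1}{1 + \sum_{j \ne i} I(S_{ij} \ge t)}}
#' with \eqn{t = 0.8} by default, \eqn{S_{ij}} the pairwise identity and
#' \eqn{I} the Iverson bracket. Nf is the standard proxy for the coevolution
#' signal depth of an MSA feeding contact prediction.
#'
#' @param msa an `AlignedSequenceSet`.
#' @param threshold identity threshold in `(0, 1]` (default 0.8).
#' @return An `EffectiveCount` object: list with `nf`, `identity_threshold`,
#'   `n_seq`, `L`.
#' @export
effective_count <- function(msa, threshold = 0.8) {
  stopifnot(inherits(msa, "AlignedSequenceSet"))
  if (!(threshold > 0 && threshold <= 1)) {
    cf_abort("cf_domain_error", "identity threshold must be in (0, 1]")
  }
  s <- identity_matrix(msa)
  similar <- (s >= threshold)
  diag(similar) <- FALSE
  weights <- 1 / (1 + rowSums(similar))
  nf <- sum(weights) / sqrt(msa$L)
  structure(
    list(nf = nf, identity_threshold = threshold,
         n_seq = msa$n_seq, L = msa$L),
    class = "EffectiveCount"
  )
}

#' @export
print.EffectiveCount <- function(x, ...) {
  cat(sprintf("Nf = %.3f  (n_seq = %d, L = %d, identity >= %.2f)\n",
              x$nf, x$n_seq, x$L, x$identity_threshold))
  invisible(x)
}

#' Fraction of Nf contributed by an augmenting sequence set
#'
#' For a family searched against a base database alone (`nf_base`) and
#' against base plus a metagenomic augmentation (`nf_combined`),
#' `Nff = (nf_combined - nf_base) / nf_combined` measures how much of the
#' effective alignment depth the augmentation contributes.
#'
#' @param nf_combined Nf of the combined search (> 0).
#' @param nf_base Nf of the base-only search (>= 0).
#' @return An `NfFraction` object: list with `nf_combined`, `nf_base`, `nff`.
#' @export
nff <- function(nf_combined, nf_base) {
  if (!is.finite(nf_combined) || nf_combined <= 0) {
    cf_abort("cf_domain_error", "nf_combined must be > 0")
  }
  if (!is.finite(nf_base) || nf_base < 0) {
    cf_abort("cf_domain_error", "nf_base must be >= 0")
  }
  structure(
    list(nf_combined = nf_combined, nf_base = nf_base,
         nff = (nf_combined - nf_base) / nf_combined),
    class = "NfFraction"
  )
}

#' Remove gap-heavy alignment rows
#'
#' Rows whose gap fraction is at or above `max_gap_fraction` are dropped.
#' The query row is always retained.
#'
#' @param msa an `AlignedSequenceSet`.
#' @param max_gap_fraction removal cutoff (default 0.75).
#' @return the filtered `AlignedSequenceSet`.
#' @export
filter_gap_rows <- function(msa, max_gap_fraction = 0.75) {
  stopifnot(inherits(msa, "AlignedSequenceSet"))
  m <- msa_matrix(msa)
  gap_frac <- rowMeans(m == "-")
  keep <- gap_frac < max_gap_fraction | msa$ids == msa$query_id
  aligned_set(msa$ids[keep], msa$seqs[keep], query_id = msa$query_id)
}

#' Coverage- and identity-based redundancy filter
#'
#' Mirrors the usual alignment filter (`-id 90 -cov 75` style): first drops
#' rows that cover less than `min_coverage` of the query's match columns,
#' then greedily scans rows in input order (query first), rejecting any row
#' with identity at or above `max_identity` to an already-kept row.
#'
#' @param msa an `AlignedSequenceSet`.
#' @param max_identity redundancy cutoff (default 0.90).
#' @param min_coverage query-coverage cutoff (default 0.75).
#' @return the filtered `AlignedSequenceSet`.
#' @export
filter_redundancy <- function(msa, max_identity = 0.90, min_coverage = 0.75) {
  stopifnot(inherits(msa, "AlignedSequenceSet"))
  m <- msa_matrix(msa)
  qi <- match(msa$query_id, msa$ids)
  qcols <- which(m[qi, ] != "-")
  cov <- if (length(qcols)) rowMeans(m[, qcols, drop = FALSE] != "-") else
    rep(1, msa$n_seq)
  cand <- which(cov >= min_coverage | seq_len(msa$n_seq) == qi)
  # query first, then remaining candidates in input order
  cand <- c(qi, setdiff(cand, qi))
  sub <- aligned_set(msa$ids[cand], msa$seqs[cand], query_id = msa$query_id)
  s <- identity_matrix(sub)
  kept <- integer(0)
  for (k in seq_along(cand)) {
    if (length(kept) == 0L || all(s[k, kept] < max_identity)) {
      kept <- c(kept, k)
    }
  }
  aligned_set(sub$ids[kept], sub$seqs[kept], query_id = msa$query_id)
}

#' Triage a family by alignment depth and metagenome contribution
#'
#' Families with combined effective depth at or below `nf_cutoff` are deemed
#' not modelable by contact-guided folding. Modelable families are labelled
#' metagenome-driven when the augmentation contributes more than
#' `nff_cutoff` of the effective sequences, base-driven otherwise.
#'
#' @param nf_combined Nf with the metagenomic augmentation.
#' @param nf_base Nf of the base database alone.
#' @param nf_cutoff depth cutoff (default 64).
#' @param nff_cutoff contribution cutoff (default 0.5).
#' @return one of `"modelable_metagenome_driven"`, `"modelable_base_driven"`,
#'   `"not_modelable"`.
#' @export
triage_family <- function(nf_combined, nf_base,
                          nf_cutoff = 64, nff_cutoff = 0.5) {
  if (nf_combined < 0 || nf_base < 0) {
    cf_abort("cf_domain_error", "Nf values must be non-negative")
  }
  if (nf_combined <= nf_cutoff) return("not_modelable")
  f <- nff(nf_combined, nf_base)$nff
  if (f > nff_cutoff) "modelable_metagenome_driven" else "modelable_base_driven"
}
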