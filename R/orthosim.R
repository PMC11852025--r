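# Pairwise global alignment percent identity between a query protein and its
# orthologs, whole-sequence and per extracellular segment.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

check_aa_sequence <- function(seq, name) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    abort_input(paste0("`", name, "` must be a non-empty amino-acid string"))
  }
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0) {
    abort_input(paste0("invalid amino-acid character '", chars[bad[1]],
                       "' at position ", bad[1], " of `", name, "`"))
  }
  chars
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment under an affine gap model (a gap of
#' length L costs `gap_open + L * gap_extend`) with a substitution matrix
#' (BLOSUM62 by default). The optimal score is unique; among co-optimal
#' alignments the traceback deterministically prefers a match/mismatch column
#' over a gap in the first sequence over a gap in the second. Percent
#' identity is the headline similarity number: identical aligned columns
#' divided by the alignment length, times 100.
#'
#' @param seq_a,seq_b Amino-acid strings (20 standard residues plus `X`).
#' @param matrix Substitution matrix: `"BLOSUM62"` or a numeric matrix with
#'   residue dimnames.
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @param query_id,subject_id Optional identifiers carried into the result.
#' @return A one-row tibble of class `alignment_result` with columns
#'   `query_id`, `subject_id`, `alignment_length`, `n_identical`,
#'   `percent_identity`, `score`, `aligned_query`, `aligned_subject`.
#' @export
#' @examples
#' global_align("ACDE", "ACDF")$percent_identity  # 75
global_align <- function(seq_a, seq_b, matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5, query_id = "query",
                         subject_id = "subject") {
  chars_a <- check_aa_sequence(seq_a, "seq_a")
  chars_b <- check_aa_sequence(seq_b, "seq_b")
  sub <- if (is.character(matrix)) {
    if (!identical(matrix, "BLOSUM62")) {
      abort_config("only the bundled BLOSUM62 matrix is available by name")
    }
    blosum62_matrix()
  } else {
    matrix
  }
  letters_sub <- rownames(sub)
  ia <- match(chars_a, letters_sub) - 1L
  ib <- match(chars_b, letters_sub) - 1L
  if (anyNA(ia) || anyNA(ib)) {
    abort_input("sequence contains a residue absent from the substitution matrix")
  }
  res <- nw_affine_cpp(ia, ib, sub, gap_open, gap_extend)
  gap <- is.na(res$a_idx) | is.na(res$b_idx)
  aligned_a <- ifelse(is.na(res$a_idx), "-", letters_sub[res$a_idx + 1L])
  aligned_b <- ifelse(is.na(res$b_idx), "-", letters_sub[res$b_idx + 1L])
  identical_col <- !gap & aligned_a == aligned_b
  out <- tibble::tibble(
    query_id = query_id,
    subject_id = subject_id,
    alignment_length = length(aligned_a),
    n_identical = sum(identical_col),
    percent_identity = 100 * sum(identical_col) / length(aligned_a),
    score = res$score,
    aligned_query = paste(aligned_a, collapse = ""),
    aligned_subject = paste(aligned_b, collapse = "")
  )
  class(out) <- c("alignment_result", class(out))
  out
}

#' Per-segment similarity of extracellular regions
#'
#' Aligns the whole sequences once, projects the query's outside
#' (extracellular) segments onto the alignment columns, and reports percent
#' identity per segment. Columns that are gaps in the query but fall inside a
#' segment's span count as non-identical, as do substitutions and gaps in the
#' subject.
#'
#' @param seq_a Query amino-acid string (segments refer to it).
#' @param seq_b Subject amino-acid string.
#' @param segments A segments tibble (`start`, `end`, `label`, 1-based
#'   inclusive) as produced by the topology parsers; only `outside` segments
#'   are used.
#' @param ... Passed to [global_align()].
#' @return A tibble with one row per outside segment: `start`, `end`,
#'   `alignment_length`, `n_identical`, `percent_identity`.
#' @export
segment_similarity <- function(seq_a, seq_b, segments, ...) {
  chars_a <- check_aa_sequence(seq_a, "seq_a")
  outside <- segments[segments$label == "outside", , drop = FALSE]
  if (nrow(outside) == 0L) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          alignment_length = integer(0),
                          n_identical = integer(0),
                          percent_identity = numeric(0)))
  }
  if (any(outside$start < 1L) || any(outside$end > length(chars_a)) ||
      any(outside$start > outside$end)) {
    abort_validation("segment coordinates out of bounds for `seq_a`")
  }
  aln <- global_align(seq_a, seq_b, ...)
  qa <- strsplit(aln$aligned_query, "")[[1]]
  qb <- strsplit(aln$aligned_subject, "")[[1]]
  q_pos <- cumsum(qa != "-")
  q_pos[qa == "-"] <- NA_integer_
  purrr::pmap_dfr(list(outside$start, outside$end), function(s, e) {
    cols <- which(!is.na(q_pos) & q_pos >= s & q_pos <= e)
    span <- seq(min(cols), max(cols))
    ident <- sum(qa[span] != "-" & qb[span] != "-" & qa[span] == qb[span])
    tibble::tibble(
      start = as.integer(s), end = as.integer(e),
      alignment_length = length(span),
      n_identical = as.integer(ident),
      percent_identity = 100 * ident / length(span)
    )
  })
}

#' Read protein sequences from FASTA
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return A tibble with columns `id` (first word of the header) and
#'   `sequence`.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  tibble::tibble(
    id = sub("\\s.*$", "", names(seqs)),
    sequence = unname(as.character(seqs))
  )
}
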