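#' Pairwise alignment scoring model
#'
#' A simple linear-gap scoring model: by default +1 for a match and -1 for a
#' mismatch and for both gap opening and gap extension. With opening equal to
#' extension the gap cost is linear, so local alignment uses a single
#' per-column gap penalty.
#'
#' @param match Match score (> `mismatch`). Default +1.
#' @param mismatch Mismatch score. Default -1.
#' @param gap_open,gap_extend Gap penalties, both non-positive. Default -1.
#'   The local aligner supports the linear case `gap_open == gap_extend` only.
#' @return An object of class `scoring_model`.
#' @export
scoring_model <- function(match = 1L, mismatch = -1L,
                          gap_open = -1L, gap_extend = -1L) {
  if (!(match > mismatch))
    stop("match score must exceed mismatch score", call. = FALSE)
  if (gap_open > 0 || gap_extend > 0)
    stop("gap penalties must be <= 0", call. = FALSE)
  if (gap_open != gap_extend)
    stop("only the linear gap model (gap_open == gap_extend) is supported",
         call. = FALSE)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_model")
}

#' Local (Smith-Waterman) alignment of two nucleotide sequences
#'
#' Computes a maximal-scoring local alignment under a linear-gap scoring
#' model. Deterministic for fixed inputs: among co-optimal alignments the one
#' with the most matched residue pairs is returned (this makes the match
#' count — and hence [similarity()] — symmetric in the inputs, since swapping
#' them permutes the same optimal set), then the lowest end coordinate in
#' `a`, then in `b`; the traceback prefers substitution over gap moves. `N`
#' scores as a mismatch against every residue and never counts as a match.
#'
#' @param a,b [nt_seq()] records (or residue strings).
#' @param model A [scoring_model()].
#' @return A `local_alignment`: list with `score`, `matches`, `mismatches`,
#'   `gaps`, half-open spans `a_span`/`b_span` (0-based), and the aligned
#'   strings `a_aln`/`b_aln`. A score of 0 is the empty alignment.
#' @examples
#' align_local(nt_seq("a", "ACGT"), nt_seq("b", "ACGT"))$score
#' @export
align_local <- function(a, b, model = scoring_model()) {
  a <- as_nt_seq(a, "a"); b <- as_nt_seq(b, "b")
  res <- .sw_align_cpp(a$residues, b$residues,
                       model$match, model$mismatch, model$gap_extend)
  structure(
    list(score = res$score, matches = res$matches,
         mismatches = res$mismatches, gaps = res$gaps,
         a_span = c(res$a_start, res$a_end),
         b_span = c(res$b_start, res$b_end),
         a_aln = res$a_aln, b_aln = res$b_aln),
    class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf(
    "<local_alignment> score %d, %d matches / %d mismatches / %d gap cols\n",
    x$score, x$matches, x$mismatches, x$gaps))
  cat(sprintf("  a[%d,%d) x b[%d,%d)\n",
              x$a_span[1], x$a_span[2], x$b_span[1], x$b_span[2]))
  invisible(x)
}

#' Re-score an alignment traceback under a scoring model
#'
#' Used to check internal consistency: the score implied by the returned
#' aligned strings must equal the DP score.
#'
#' @param aln A `local_alignment`.
#' @param model A [scoring_model()].
#' @return Integer score.
#' @export
rescore_alignment <- function(aln, model = scoring_model()) {
  if (!nzchar(aln$a_aln)) return(0L)
  ac <- strsplit(aln$a_aln, "")[[1]]
  bc <- strsplit(aln$b_aln, "")[[1]]
  s <- 0L
  for (k in seq_along(ac)) {
    if (ac[k] == "-" || bc[k] == "-") s <- s + model$gap_extend
    else if (ac[k] == bc[k] && ac[k] != "N") s <- s + model$match
    else s <- s + model$mismatch
  }
  s
}

#' Pairwise similarity: matches over the shorter sequence
#'
#' The number of identically paired residues in the local alignment divided by
#' the length of the shorter input sequence.
#'
#' @inheritParams align_local
#' @return Similarity in `[0, 1]`.
#' @export
similarity <- function(a, b, model = scoring_model()) {
  a <- as_nt_seq(a, "a"); b <- as_nt_seq(b, "b")
  aln <- align_local(a, b, model)
  aln$matches / min(seq_len_nt(a), seq_len_nt(b))
}

#' Pairwise percent distance, 100 * (1 - similarity)
#'
#' Symmetric in its arguments; 0 for identical sequences, 100 when the local
#' alignment contains no matching residue pair.
#'
#' @inheritParams align_local
#' @return Distance in percent, in `[0, 100]`.
#' @export
distance_percent <- function(a, b, model = scoring_model()) {
  100 * (1 - similarity(a, b, model))
}
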