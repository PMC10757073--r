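#' Multiple-alignment block for one window
#'
#' Rows are gapped aligned strings of equal length; the reference (query) row
#' is first and its ungapped residues equal the window residues. At least two
#' homolog rows are required for the scorer to be informative.
#'
#' @param rows Named character vector of aligned rows, reference first.
#' @param window The `sub_query` the block covers.
#' @return An object of class `msa_block`.
#' @export
msa_block <- function(rows, window) {
  if (length(rows) < 3L)
    stopf("codonscout_scoring_error",
          "MSA block needs >= 3 rows (query + >= 2 homologs), got %d",
          length(rows))
  if (length(unique(nchar(rows))) != 1L)
    stopf("codonscout_scoring_error", "MSA rows have unequal lengths")
  ref <- gsub("-", "", rows[[1L]], fixed = TRUE)
  if (!identical(ref, window$residues))
    stopf("codonscout_scoring_error",
          "ungapped reference row does not equal the window residues")
  structure(list(rows = rows, ref_id = names(rows)[1L], window = window),
            class = "msa_block")
}

#' @export
print.msa_block <- function(x, ...) {
  cat(sprintf("<msa_block> %d rows x %d cols, window #%d [%d,%d)\n",
              length(x$rows), nchar(x$rows[[1]]), x$window$index,
              x$window$q_start, x$window$q_end))
  invisible(x)
}

#' Stub aligner adapter
#'
#' Deterministic in-process stand-in for an external multiple aligner, used
#' in tests and reproducible runs: equal-length inputs are returned unchanged
#' (gap-free block); unequal-length inputs are padded with trailing gaps.
#' Suitable for the substitution-only synthetic families, where the true
#' alignment is the identity.
#'
#' @return An aligner adapter: `function(seqs)` mapping a named character
#'   vector of unaligned sequences to a named vector of aligned rows.
#' @export
stub_aligner <- function() {
  function(seqs) {
    w <- max(nchar(seqs))
    vapply(seqs, function(s)
      paste0(s, strrep("-", w - nchar(s))), character(1))
  }
}

#' External command-line aligner adapter
#'
#' Subprocess wrapper around a multiple aligner that reads multi-FASTA and
#' writes aligned FASTA (Clustal Omega or mafft style invocations are
#' built in). Temporary input/output files live in `tempdir()` and are
#' removed when the call returns.
#'
#' @param tool `"clustalo"` or `"mafft"`.
#' @param command Binary name/path (defaults to `tool`).
#' @return An aligner adapter (see [stub_aligner()]).
#' @export
cmd_aligner <- function(tool = c("clustalo", "mafft"), command = NULL) {
  tool <- match.arg(tool)
  command <- command %||% tool
  if (Sys.which(command) == "")
    stop("aligner binary '", command, "' not found on PATH", call. = FALSE)
  function(seqs) {
    inf <- tempfile(fileext = ".fa"); outf <- tempfile(fileext = ".fa")
    on.exit(unlink(c(inf, outf)), add = TRUE)
    write_fasta(seqs, inf)
    if (tool == "clustalo") {
      rc <- system2(command, c("-i", shQuote(inf), "-o", shQuote(outf),
                               "--outfmt", "fasta", "--force"),
                    stdout = FALSE, stderr = FALSE)
    } else {
      rc <- system2(command, c("--auto", "--quiet", shQuote(inf)),
                    stdout = outf, stderr = FALSE)
    }
    if (rc != 0)
      stopf("codonscout_scoring_error", "aligner '%s' failed (exit %d)",
            command, rc)
    ss <- Biostrings::readBStringSet(outf)
    out <- toupper(as.character(ss))
    names(out) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
    out
  }
}

#' Align a window against its selected homologs
#'
#' Invokes the aligner adapter on plain multi-FASTA input (query/window row
#' plus homologs), reorders the output so the query row is first, and
#' validates the [msa_block()] invariants. Adapter failures surface as
#' scoring errors carrying the adapter's diagnostics.
#'
#' @param window A `sub_query` (the reference row).
#' @param homologs List of [candidate()]s or [nt_seq()]s (>= 2).
#' @param aligner An aligner adapter.
#' @param ref_id Identifier for the reference row.
#' @return An [msa_block()].
#' @export
build_msa <- function(window, homologs, aligner = stub_aligner(),
                      ref_id = "query") {
  if (length(homologs) < 2L)
    stopf("codonscout_scoring_error",
          "build_msa needs >= 2 homologs, got %d", length(homologs))
  hseqs <- lapply(homologs, function(h)
    if (inherits(h, "candidate")) h$sequence else as_nt_seq(h))
  seqs <- c(setNames(window$residues, ref_id),
            setNames(vapply(hseqs, function(s) s$residues, character(1)),
                     vapply(hseqs, function(s) s$id, character(1))))
  rows <- tryCatch(aligner(seqs), error = function(e)
    stopf("codonscout_scoring_error", "aligner failed: %s",
          conditionMessage(e)))
  if (length(rows) != length(seqs))
    stopf("codonscout_scoring_error",
          "aligner returned %d rows for %d sequences",
          length(rows), length(seqs))
  i <- match(ref_id, names(rows))
  if (is.na(i))
    stopf("codonscout_scoring_error", "aligner output lost the query row")
  rows <- c(rows[i], rows[-i])
  msa_block(rows, window)
}

# ---- scorer tabular dialect ------------------------------------------------

# 11 tab-separated fields per HSS (coding-potential scorer version-0.3 style):
# HSS id, strand, frame (1..3), length in amino acids, alignment-from,
# alignment-to, reference name, reference start, reference end (1-based,
# inclusive, start <= end on both strands), score, p-value.

#' Parse the coding-potential scorer's tabular output
#'
#' Accepts the 11-column tabular dialect (see Details), possibly empty, and
#' returns window-local high-scoring segments with 0-based half-open
#' coordinates and frames normalised to `{0,1,2}`.
#'
#' @details Fields per line: HSS id, strand (`+`/`-`), frame (1..3), length
#'   in amino acids, alignment-from, alignment-to, reference name, reference
#'   start, reference end (1-based inclusive, `start <= end`), score,
#'   p-value in `(0, 1]`. Lines starting with `#` are ignored.
#' @param text The scorer output as a single string or character vector of
#'   lines.
#' @return Data frame with columns `hss_id`, `strand`, `frame` (0..2,
#'   window-local), `length_aa`, `aln_start`, `aln_end`, `start`, `end`
#'   (0-based half-open), `ref_name`, `score`, `p_value`.
#' @section Errors: malformed lines raise `codonscout_parse_error` naming the
#'   line number.
#' @export
parse_scorer_tabular <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  out <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line)) || startsWith(trimws(line), "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 11L)
      stopf("codonscout_parse_error",
            "scorer tabular line %d: expected 11 fields, got %d",
            ln, length(f))
    num <- suppressWarnings(as.numeric(f[c(1, 3, 4, 5, 6, 8, 9, 10, 11)]))
    if (anyNA(num))
      stopf("codonscout_parse_error",
            "scorer tabular line %d: non-numeric field", ln)
    strand <- f[2]
    if (!strand %in% c("+", "-"))
      stopf("codonscout_parse_error",
            "scorer tabular line %d: strand must be + or -", ln)
    frame <- as.integer(f[3])
    if (!frame %in% 1:3)
      stopf("codonscout_parse_error",
            "scorer tabular line %d: frame must be 1..3", ln)
    p <- as.numeric(f[11])
    if (!(p > 0 && p <= 1))
      stopf("codonscout_parse_error",
            "scorer tabular line %d: p-value %g outside (0, 1]", ln, p)
    start1 <- as.integer(f[8]); end1 <- as.integer(f[9])
    if (start1 < 1L || end1 < start1)
      stopf("codonscout_parse_error",
            "scorer tabular line %d: bad reference coordinates %d..%d",
            ln, start1, end1)
    out[[length(out) + 1L]] <- data.frame(
      hss_id = as.integer(f[1]), strand = strand, frame = frame - 1L,
      length_aa = as.integer(f[4]),
      aln_start = as.integer(f[5]) - 1L, aln_end = as.integer(f[6]),
      start = start1 - 1L, end = end1, ref_name = f[7],
      score = as.numeric(f[10]), p_value = p,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(hss_id = integer(), strand = character(),
                      frame = integer(), length_aa = integer(),
                      aln_start = integer(), aln_end = integer(),
                      start = integer(), end = integer(),
                      ref_name = character(), score = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Serialize window-local HSS back to the scorer tabular dialect
#'
#' Inverse of [parse_scorer_tabular()]: `parse(serialize(x))` reproduces `x`.
#'
#' @param hss Data frame as returned by [parse_scorer_tabular()].
#' @return A single string (possibly empty) of tab-separated lines.
#' @export
serialize_scorer_tabular <- function(hss) {
  if (nrow(hss) == 0L) return("")
  lines <- vapply(seq_len(nrow(hss)), function(i) {
    h <- hss[i, ]
    paste(h$hss_id, h$strand, h$frame + 1L, h$length_aa,
          h$aln_start + 1L, h$aln_end, h$ref_name,
          h$start + 1L, h$end,
          sprintf("%g", h$score), sprintf("%g", h$p_value),
          sep = "\t")
  }, character(1))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Stub scorer adapter
#'
#' Deterministic in-process stand-in for the external coding-potential
#' scorer: returns canned tabular output, either one text for every window or
#' per-window texts keyed by window index. An empty string models a negative
#' result (no HSS), which is not an error.
#'
#' @param text Tabular text returned for every window (default: empty).
#' @param by_window Optional named list mapping window index (as character)
#'   to tabular text; windows without an entry get `text`.
#' @return A scorer adapter: `function(msa_block)` returning tabular text.
#' @export
stub_scorer <- function(text = "", by_window = NULL) {
  function(msa) {
    key <- as.character(msa$window$index)
    if (!is.null(by_window) && !is.null(by_window[[key]]))
      by_window[[key]]
    else text
  }
}

#' External coding-potential scorer adapter
#'
#' Subprocess wrapper invoking the scorer binary on a Clustal-format
#' alignment with tabular output and default scoring parameters (per-HSS
#' figure generation stays disabled). Temporary files live in `tempdir()`.
#'
#' @param command Binary name/path (default `"RNAcode"`).
#' @return A scorer adapter (see [stub_scorer()]).
#' @export
rnacode_scorer <- function(command = "RNAcode") {
  if (Sys.which(command) == "")
    stop("scorer binary '", command, "' not found on PATH", call. = FALSE)
  function(msa) {
    aln <- tempfile(fileext = ".aln"); on.exit(unlink(aln), add = TRUE)
    write_clustal(msa$rows, aln)
    res <- suppressWarnings(system2(command, c("--tabular", shQuote(aln)),
                                    stdout = TRUE, stderr = FALSE))
    status <- attr(res, "status")
    if (!is.null(status) && status != 0)
      stopf("codonscout_scoring_error", "scorer '%s' failed (exit %d)",
            command, status)
    paste(res, collapse = "\n")
  }
}

# minimal Clustal W-style writer (what the external scorer consumes)
write_clustal <- function(rows, path, block = 60L) {
  ids <- names(rows)
  wid <- max(nchar(ids)) + 3L
  con <- file(path, "w"); on.exit(close(con), add = TRUE)
  writeLines("CLUSTAL W (codonscout) multiple sequence alignment\n", con)
  len <- nchar(rows[[1]])
  for (off in seq(1L, len, by = block)) {
    for (i in seq_along(rows)) {
      writeLines(sprintf("%-*s%s", wid, ids[i],
                         substr(rows[[i]], off, min(len, off + block - 1L))),
                 con)
    }
    writeLines("", con)
  }
  invisible(path)
}

empty_hss_table <- function() {
  data.frame(window_index = character(), strand = character(),
             frame = integer(), q_start = integer(), q_end = integer(),
             length_aa = integer(), score = numeric(), p_value = numeric(),
             stringsAsFactors = FALSE)
}

#' Score one aligned window and map its HSS to query coordinates
#'
#' Runs the scorer adapter on an MSA block, parses its tabular output,
#' validates that every segment lies within the window, and maps window-local
#' coordinates to query space. Frames are re-expressed in query space so they
#' are comparable across windows: `q_start %% 3` on the plus strand and
#' `(query_len - q_end) %% 3` on the minus strand.
#'
#' @param msa An [msa_block()].
#' @param scorer A scorer adapter.
#' @param query_len Full query length in bp (for minus-strand frame
#'   normalisation).
#' @return HSS table in query coordinates: columns `window_index`, `strand`,
#'   `frame`, `q_start`, `q_end`, `length_aa`, `score`, `p_value`. A scorer
#'   reporting nothing yields zero rows (not an error).
#' @export
score_window <- function(msa, scorer, query_len) {
  text <- tryCatch(scorer(msa), error = function(e) {
    if (inherits(e, "codonscout_scoring_error")) stop(e)
    stopf("codonscout_scoring_error", "scorer failed: %s",
          conditionMessage(e))
  })
  local <- parse_scorer_tabular(text)
  if (nrow(local) == 0L) return(empty_hss_table())
  w <- msa$window
  wlen <- w$q_end - w$q_start
  if (any(local$end > wlen))
    stopf("codonscout_scoring_error",
          "scorer reported an HSS outside window #%d", w$index)
  q_start <- map_to_query(w, local$start)
  q_end <- map_to_query(w, local$end)
  frame <- ifelse(local$strand == "+", q_start %% 3L,
                  (query_len - q_end) %% 3L)
  data.frame(window_index = as.character(w$index), strand = local$strand,
             frame = as.integer(frame), q_start = q_start, q_end = q_end,
             length_aa = local$length_aa, score = local$score,
             p_value = local$p_value, stringsAsFactors = FALSE)
}
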