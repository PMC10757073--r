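#' Windowing configuration for long queries
#'
#' Long queries are subdivided into overlapping fixed-length chunks that are
#' searched and scored independently. The overlap default (300 bp) is a
#' multiple of 3 so that the codon phase of a region falling in the shared
#' zone is identical in both windows.
#'
#' @param chunk_len Window length in bp (default 1000).
#' @param overlap Minimum overlap between consecutive windows, `0 < overlap <
#'   chunk_len` (default 300).
#' @param long_query_threshold Queries strictly longer than this take the
#'   long-query path; must be `>= chunk_len` (default 1000).
#' @return An object of class `windowing_config`.
#' @export
windowing_config <- function(chunk_len = 1000L, overlap = 300L,
                             long_query_threshold = 1000L) {
  chunk_len <- as.integer(chunk_len); overlap <- as.integer(overlap)
  long_query_threshold <- as.integer(long_query_threshold)
  if (!(overlap > 0L && overlap < chunk_len))
    stop("windowing requires 0 < overlap < chunk_len", call. = FALSE)
  if (long_query_threshold < chunk_len)
    stop("long_query_threshold must be >= chunk_len", call. = FALSE)
  structure(list(chunk_len = chunk_len, overlap = overlap,
                 long_query_threshold = long_query_threshold),
            class = "windowing_config")
}

#' Does a query take the long-query path?
#'
#' @param query An [nt_seq()] (or residue string).
#' @param cfg A [windowing_config()].
#' @return `TRUE` iff the query is strictly longer than the threshold.
#' @export
is_long_query <- function(query, cfg = windowing_config()) {
  seq_len_nt(as_nt_seq(query)) > cfg$long_query_threshold
}

new_sub_query <- function(index, q_start, q_end, residues) {
  structure(list(index = as.integer(index), q_start = as.integer(q_start),
                 q_end = as.integer(q_end), residues = residues),
            class = "sub_query")
}

#' @export
print.sub_query <- function(x, ...) {
  cat(sprintf("<sub_query> #%d [%d,%d) (%d nt)\n", x$index, x$q_start,
              x$q_end, x$q_end - x$q_start))
  invisible(x)
}

#' Split a query into overlapping sub-queries
#'
#' Windows of exactly `chunk_len` are placed every `chunk_len - overlap`
#' positions from 0; the final window is anchored at the query end (start
#' `L - chunk_len`) rather than left as a short tail, because the downstream
#' scorer loses power on short blocks. Every query position is covered and
#' consecutive windows overlap by at least `overlap`. Queries no longer than
#' `chunk_len` yield a single window spanning the query.
#'
#' @param query An [nt_seq()] (or residue string).
#' @param cfg A [windowing_config()].
#' @return List of `sub_query` windows sorted by `q_start`, 0-based half-open
#'   coordinates.
#' @export
split_query <- function(query, cfg = windowing_config()) {
  query <- as_nt_seq(query, "query")
  L <- seq_len_nt(query)
  k <- cfg$chunk_len
  if (L <= k)
    return(list(new_sub_query(0L, 0L, L, query$residues)))
  step <- k - cfg$overlap
  starts <- seq.int(0L, L - k, by = step)
  if (starts[length(starts)] != L - k) starts <- c(starts, L - k)
  lapply(seq_along(starts), function(i) {
    s <- starts[i]
    new_sub_query(i - 1L, s, s + k, subseq_residues(query, s, s + k))
  })
}

#' Map window-local coordinates onto the query
#'
#' An additive shift by the window start; intervals keep their length and
#' strand is unchanged.
#'
#' @param w A `sub_query`.
#' @param local A scalar coordinate or `c(start, end)` half-open interval in
#'   `[0, length(w)]`.
#' @return The shifted coordinate/interval in query space.
#' @export
map_to_query <- function(w, local) {
  wlen <- w$q_end - w$q_start
  if (any(local < 0) || any(local > wlen))
    stop("local coordinate outside window [0,", wlen, "]", call. = FALSE)
  local + w$q_start
}

#' Map query coordinates into a window (inverse of [map_to_query()])
#'
#' @param w A `sub_query`.
#' @param query_coord Scalar or half-open interval in query space, inside the
#'   window.
#' @return Window-local coordinate/interval.
#' @export
map_from_query <- function(w, query_coord) {
  if (any(query_coord < w$q_start) || any(query_coord > w$q_end))
    stop("query coordinate outside window [", w$q_start, ",", w$q_end, "]",
         call. = FALSE)
  query_coord - w$q_start
}

windows_table <- function(windows) {
  data.frame(index = vapply(windows, `[[`, integer(1), "index"),
             start = vapply(windows, `[[`, integer(1), "q_start"),
             end = vapply(windows, `[[`, integer(1), "q_end"))
}
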