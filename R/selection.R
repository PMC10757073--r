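#' Candidate homolog
#'
#' An extended, full-query-length homolog together with the search E-value of
#' the hit that produced it and (once annotated) its percent distance to the
#' query.
#'
#' @param sequence An [nt_seq()].
#' @param evalue Non-negative E-value of the originating hit.
#' @param dist_to_query Percent distance to the query in `[0, 100]`, or `NA`
#'   before annotation.
#' @param species Species label (defaults to the sequence's).
#' @return An object of class `candidate`.
#' @export
candidate <- function(sequence, evalue, dist_to_query = NA_real_,
                      species = sequence$species) {
  stopifnot(is_nt_seq(sequence))
  evalue <- as.numeric(evalue)
  if (is.na(evalue) || evalue < 0)
    stop("evalue must be >= 0", call. = FALSE)
  if (!is.na(dist_to_query) && (dist_to_query < 0 || dist_to_query > 100))
    stop("dist_to_query must be in [0, 100]", call. = FALSE)
  structure(list(sequence = sequence, evalue = evalue,
                 dist_to_query = as.numeric(dist_to_query),
                 species = as.character(species)[1L]),
            class = "candidate")
}

cand_id <- function(x) x$sequence$id
cand_ids <- function(pool) vapply(pool, cand_id, character(1))

#' Acceptable query-candidate divergence band
#'
#' The closed interval of percent distances within which homologs are both
#' alignable and informative. Defaults 10--60 percent.
#'
#' @param min_dist,max_dist Band bounds in percent, `0 <= min < max <= 100`.
#' @return An object of class `distance_band`.
#' @export
distance_band <- function(min_dist = 10, max_dist = 60) {
  if (!(min_dist >= 0 && min_dist < max_dist && max_dist <= 100))
    stop("distance band requires 0 <= min_dist < max_dist <= 100",
         call. = FALSE)
  structure(list(min_dist = as.numeric(min_dist),
                 max_dist = as.numeric(max_dist)),
            class = "distance_band")
}

#' Bounds on the number of sequences passed to alignment
#'
#' At least 2 homologs are needed for an informative alignment; at most 16 are
#' used.
#'
#' @param min_n,max_n Integers with `2 <= min_n <= max_n`.
#' @return An object of class `selection_limits`.
#' @export
selection_limits <- function(min_n = 2L, max_n = 16L) {
  min_n <- as.integer(min_n); max_n <- as.integer(max_n)
  if (!(min_n >= 2L && min_n <= max_n))
    stop("selection limits require 2 <= min_n <= max_n", call. = FALSE)
  structure(list(min_n = min_n, max_n = max_n), class = "selection_limits")
}

#' Keep candidates inside the divergence band
#'
#' Retains exactly the candidates whose annotated distance to the query lies
#' in the closed interval `[min_dist, max_dist]`; input order is preserved.
#'
#' @param cands List of [candidate()]s with `dist_to_query` populated.
#' @param band A [distance_band()].
#' @return The retained sublist (possibly empty).
#' @export
band_filter <- function(cands, band = distance_band()) {
  if (length(cands) == 0L) return(cands)
  d <- vapply(cands, function(x) x$dist_to_query, numeric(1))
  if (anyNA(d))
    stop("band_filter: all candidates must have dist_to_query annotated",
         call. = FALSE)
  cands[d >= band$min_dist & d <= band$max_dist]
}

#' Pairwise distance matrix over a candidate pool
#'
#' @param pool List of [candidate()]s.
#' @param model A [scoring_model()].
#' @return Symmetric numeric matrix of percent distances, zero diagonal,
#'   dimnames = candidate ids.
#' @export
candidate_dist_matrix <- function(pool, model = scoring_model()) {
  n <- length(pool)
  D <- matrix(0, n, n, dimnames = list(cand_ids(pool), cand_ids(pool)))
  if (n < 2L) return(D)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- distance_percent(pool[[i]]$sequence, pool[[j]]$sequence, model)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

check_dist_matrix <- function(dist, n) {
  if (!is.matrix(dist) || nrow(dist) != n || ncol(dist) != n)
    stop("dist must be an n x n matrix matching the pool", call. = FALSE)
  invisible(dist)
}

# index-based neighbourhood: i plus every unclustered j with D[i, j] < t
.neighbourhood_idx <- function(i, D, clustered, t) {
  js <- which(!clustered & D[i, ] < t)
  sort(unique(c(i, js[js != i])))
}

#' Neighbourhood of a candidate under the clustering threshold
#'
#' The candidate itself plus every not-yet-clustered pool member at distance
#' strictly below `min_pair_dist`.
#'
#' @param s A [candidate()] that is an element of `pool`.
#' @param pool List of [candidate()]s.
#' @param clustered Character vector of already-clustered candidate ids.
#' @param min_pair_dist Percent threshold.
#' @param dist Optional precomputed distance matrix over `pool` (in pool
#'   order); computed from the sequences when `NULL`.
#' @param model A [scoring_model()] (used only when `dist` is `NULL`).
#' @return The sublist of `pool` forming the neighbourhood (always includes
#'   `s`), in pool order.
#' @export
neighbourhood <- function(s, pool, clustered = character(),
                          min_pair_dist = 10, dist = NULL,
                          model = scoring_model()) {
  ids <- cand_ids(pool)
  i <- match(cand_id(s), ids)
  if (is.na(i)) stop("candidate '", cand_id(s), "' is not in the pool",
                     call. = FALSE)
  if (is.null(dist)) dist <- candidate_dist_matrix(pool, model)
  check_dist_matrix(dist, length(pool))
  idx <- .neighbourhood_idx(i, dist, ids %in% clustered, min_pair_dist)
  pool[idx]
}

#' Density-based reduction to a minimum-pairwise-distance set
#'
#' DBSCAN-like clustering that thins a candidate pool until every surviving
#' pair is at least `min_pair_dist` percent apart. Repeatedly, a candidate
#' whose neighbourhood is only itself becomes its own representative;
#' otherwise the neighbourhood member with the largest own neighbourhood
#' becomes the centroid (ties keep the incumbent, i.e. the earliest in pool
#' order) and the rest of its neighbourhood is deleted. Pool order is the
#' iteration order, so pools sorted by increasing E-value are reduced
#' reproducibly in favour of closer homologs.
#'
#' @param pool List of [candidate()]s (iteration order matters; sort by
#'   E-value upstream).
#' @param min_pair_dist Percent threshold (default 10).
#' @param dist Optional precomputed distance matrix over `pool`.
#' @param model A [scoring_model()] (used only when `dist` is `NULL`).
#' @return The surviving sublist of `pool`, in pool order; all pairwise
#'   distances among survivors are `>= min_pair_dist`.
#' @export
reduce_cand_min_dist <- function(pool, min_pair_dist = 10, dist = NULL,
                                 model = scoring_model()) {
  n <- length(pool)
  if (n <= 1L) return(pool)
  if (is.null(dist)) dist <- candidate_dist_matrix(pool, model)
  check_dist_matrix(dist, n)

  clustered <- rep(FALSE, n)
  deleted <- rep(FALSE, n)
  while (sum(clustered) < n) {
    for (i in seq_len(n)) {
      if (clustered[i]) next
      N <- .neighbourhood_idx(i, dist, clustered, min_pair_dist)
      if (length(N) == 1L) {
        clustered[i] <- TRUE
      } else {
        centroid <- i
        for (j in setdiff(N, i)) {
          M <- .neighbourhood_idx(j, dist, clustered, min_pair_dist)
          if (length(M) > length(N)) { centroid <- j; N <- M }
        }
        clustered[N] <- TRUE
        deleted[setdiff(N, centroid)] <- TRUE
      }
    }
  }
  pool[!deleted]
}

#' Final selection of alignment inputs by increasing E-value
#'
#' From an already-clustered representative set, takes the `max_n` candidates
#' with the smallest E-values, i.e. the set most similar to the query given
#' the minimum-pairwise-distance constraint.
#'
#' @param reps List of clustered representative [candidate()]s.
#' @param limits A [selection_limits()].
#' @return List of candidates sorted by ascending E-value (ties: smaller
#'   distance to query, then id), of length `min(length(reps), max_n)`.
#' @section Errors: fewer than `min_n` representatives raises an
#'   `codonscout_insufficient_homologs` error naming the count found.
#' @export
select_final <- function(reps, limits = selection_limits()) {
  if (length(reps) < limits$min_n)
    stopf("codonscout_insufficient_homologs",
          "insufficient homologs: %d found, %d required",
          length(reps), limits$min_n)
  ev <- vapply(reps, function(x) x$evalue, numeric(1))
  d <- vapply(reps, function(x) x$dist_to_query, numeric(1))
  d[is.na(d)] <- Inf
  ord <- order(ev, d, cand_ids(reps))
  head(reps[ord], limits$max_n)
}

#' Write a candidate set as FASTA plus a TSV sidecar
#'
#' The sidecar columns are `id`, `species`, `taxon`, `evalue`,
#' `dist_to_query`, so a selection can be re-ingested and the selection step
#' run standalone.
#'
#' @param cands List of [candidate()]s.
#' @param fasta,tsv Output paths.
#' @return Invisibly, the two paths.
#' @export
write_candidates <- function(cands, fasta, tsv) {
  write_fasta(lapply(cands, `[[`, "sequence"), fasta)
  df <- data.frame(
    id = cand_ids(cands),
    species = vapply(cands, function(x) x$species, character(1)),
    taxon = vapply(cands, function(x) x$sequence$taxon, character(1)),
    evalue = vapply(cands, function(x) x$evalue, numeric(1)),
    dist_to_query = vapply(cands, function(x) x$dist_to_query, numeric(1)),
    stringsAsFactors = FALSE)
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, tsv = tsv))
}

#' Read a candidate set from FASTA plus its TSV sidecar
#'
#' @param fasta,tsv Paths written by [write_candidates()].
#' @return List of [candidate()]s in sidecar order.
#' @export
read_candidates <- function(fasta, tsv) {
  seqs <- read_fasta(fasta)
  df <- read.table(tsv, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c(id = "character", species = "character",
                                  taxon = "character"))
  missing <- setdiff(df$id, names(seqs))
  if (length(missing))
    stop("sidecar ids missing from FASTA: ", paste(missing, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    s <- seqs[[df$id[i]]]
    s$taxon <- df$taxon[i]; s$species <- df$species[i]
    candidate(s, df$evalue[i], df$dist_to_query[i], df$species[i])
  })
}
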