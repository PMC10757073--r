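#' The iterative blastn word-size / taxonomic-widening schedule
#'
#' Five iterations trade specificity for sensitivity: word sizes shrink while
#' the taxonomic scope widens from unrestricted through order, class, phylum
#' and kingdom (the restriction is anchored on the lineage of the best hit of
#' iteration 1). Word sizes differ between the full-pipeline search and the
#' sensitivity-oriented search used to build the temporary custom database.
#'
#' @return Data frame with columns `iteration`, `word_size_build_db`,
#'   `word_size_full`, `tax_rank` (`NA` = unrestricted).
#' @export
search_schedule <- function() {
  data.frame(
    iteration = 1:5,
    word_size_build_db = c(14L, 11L, 9L, 8L, 7L),
    word_size_full = c(18L, 14L, 10L, 8L, 7L),
    tax_rank = c(NA, "order", "class", "phylum", "kingdom"),
    stringsAsFactors = FALSE)
}

#' Word size and taxonomic rank for one search iteration
#'
#' @param iteration Integer in 1..5.
#' @param mode `"full"` (full-pipeline search) or `"build_db"` (custom
#'   database construction).
#' @return List with `word_size` and `tax_rank` (`NA` for iteration 1).
#' @export
schedule_for <- function(iteration, mode = c("full", "build_db")) {
  mode <- match.arg(mode)
  if (!is.numeric(iteration) || length(iteration) != 1L ||
      is.na(iteration) || iteration < 1 || iteration > 5 ||
      iteration != as.integer(iteration))
    stop("iteration must be an integer in 1..5", call. = FALSE)
  sched <- search_schedule()
  row <- sched[sched$iteration == iteration, ]
  ws <- if (mode == "full") row$word_size_full else row$word_size_build_db
  list(word_size = ws, tax_rank = row$tax_rank)
}

#' Drop hits on non-genomic records
#'
#' Nucleotide databases mix genomic and transcript records; only subjects
#' whose record annotation (`biomol`) is `"genomic"` (case-insensitive) are
#' kept, so that homologs are unspliced genomic DNA. Hits on subjects missing
#' from the metadata are dropped with a warning.
#'
#' @param hits Internal hit table.
#' @param metadata A [record_metadata()] table.
#' @return The retained subset of `hits`.
#' @export
genomic_filter <- function(hits, metadata) {
  if (nrow(hits) == 0L) return(hits)
  i <- match(hits$subject_id, metadata$id)
  if (anyNA(i)) {
    warnf("genomic_filter: dropping %d hit(s) on records without metadata",
          sum(is.na(i)))
  }
  biomol <- tolower(metadata$biomol[i])
  keep <- !is.na(i) & !is.na(biomol) & biomol == "genomic"
  out <- hits[keep, , drop = FALSE]
  if (nrow(out) == 0L && nrow(hits) > 0L)
    warnf("genomic_filter: no genomic hits remain")
  rownames(out) <- NULL
  out
}

#' Extend a hit to the full length of the query
#'
#' The unaligned query flanks are projected linearly beyond the hit on the
#' subject (a gap-free coordinate estimate, not a re-alignment): the left
#' query flank (`q_start` bases) grows the subject interval upstream and the
#' right flank (`query_len - q_end` bases) downstream — swapped on the minus
#' strand — and the result is clipped to the subject bounds. Minus-strand
#' candidates are reverse-complemented so every candidate is query-sense.
#'
#' @param hit One hit (a 1-row internal hit table, or a list with the same
#'   fields).
#' @param query_len Query length in bp.
#' @param backend A [search_backend()] able to serve subject slices.
#' @return A [candidate()] (with `dist_to_query` unset).
#' @export
extend_hit <- function(hit, query_len, backend) {
  hit <- as.list(hit)
  left <- hit$q_start
  right <- query_len - hit$q_end
  if (hit$strand == "-") { tmp <- left; left <- right; right <- tmp }
  slen <- backend$subject_length(hit$subject_id)
  s_from <- max(0L, hit$s_start - left)
  s_to <- min(slen, hit$s_end + right)
  res <- backend$get_subject(hit$subject_id, s_from, s_to)
  if (hit$strand == "-") res <- revcomp(res)
  meta <- meta_row(backend$metadata, hit$subject_id)
  s <- nt_seq(hit$subject_id, res,
              taxon = if (is.null(meta)) hit$taxon else meta$taxon,
              species = if (is.null(meta)) NA else meta$species)
  candidate(s, hit$evalue, species = s$species)
}

#' Keep the best hit per species
#'
#' For building the temporary custom database only the best-matching hit of
#' each species is retained: lowest E-value, ties broken by highest bitscore,
#' then lexicographic subject id. Hits on records without metadata keep their
#' subject id as a species key.
#'
#' @param hits Internal hit table.
#' @param metadata A [record_metadata()] table.
#' @return Hit table with pairwise-distinct species, in E-value order.
#' @export
dedupe_best_per_species <- function(hits, metadata) {
  if (nrow(hits) == 0L) return(hits)
  i <- match(hits$subject_id, metadata$id)
  species <- ifelse(is.na(i), hits$subject_id, metadata$species[i])
  species[is.na(species)] <- hits$subject_id[is.na(species)]
  ord <- order(hits$evalue, -hits$bitscore, hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  out <- hits[!duplicated(species[ord]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# lineage restriction for an iteration, anchored on the iteration-1 best hit
.restriction_for <- function(rank, anchor_lineage) {
  if (is.na(rank) || is.null(anchor_lineage)) return(NULL)
  v <- anchor_lineage[[rank]]
  if (is.null(v) || is.na(v)) return(NULL)
  list(rank = rank, value = v)
}

# pairwise-distance memo over candidate sequences, keyed by id pair
.dist_memo <- function(model) {
  env <- new.env(parent = emptyenv())
  function(a, b) {
    key <- paste(sort(c(a$sequence$id, b$sequence$id)), collapse = "\r")
    if (!is.null(env[[key]])) return(env[[key]])
    d <- distance_percent(a$sequence, b$sequence, model)
    env[[key]] <- d
    d
  }
}

.pool_dist_matrix <- function(pool, dfun) {
  n <- length(pool)
  D <- matrix(0, n, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- dfun(pool[[i]], pool[[j]])
  }
  D
}

#' Iterative homology search with word-size schedule and taxonomic widening
#'
#' Runs up to five search iterations against a backend. Iteration 1 is
#' taxonomically unrestricted; its best hit anchors the lineage used to
#' restrict iterations 2--5 to the corresponding order/class/phylum/kingdom
#' (if iteration 1 returned nothing, later iterations stay unrestricted).
#' After each iteration, hits are genomic-filtered (nt-kind backends only),
#' extended to full query length, annotated with their percent distance to
#' the query, band-filtered, pooled with previous iterations (one candidate
#' per subject, keeping the lowest E-value) and reduced by
#' [reduce_cand_min_dist()]. Iteration stops early once the representative
#' pool reaches `limits$max_n`.
#'
#' @param query An [nt_seq()].
#' @param backend A [search_backend()].
#' @param config A [run_config()] (or any list with `band`, `limits`,
#'   `evalue_cutoff`, `max_hits`, `model`).
#' @return List of representative [candidate()]s (E-value order), with
#'   attributes `search_log` (per-iteration count table with columns
#'   `iteration`, `word_size`, `tax_rank`, `hits`, `genomic`, `in_band`,
#'   `representatives`) and `iterations_run`.
#' @section Errors: if no backend hit is seen across all five iterations, a
#'   `codonscout_no_homologs` error is raised.
#' @export
iterative_search <- function(query, backend, config = run_config()) {
  query <- as_nt_seq(query, "query")
  band <- config$band; limits <- config$limits
  model <- config$model %||% scoring_model()
  dfun <- .dist_memo(model)

  pool <- list()          # in-band candidates keyed by subject id
  anchor <- NULL
  any_hits <- FALSE
  reps <- list()
  log <- list()
  iterations_run <- 0L

  for (it in 1:5) {
    iterations_run <- it
    sch <- schedule_for(it, "full")
    restriction <- if (it == 1L) NULL else .restriction_for(sch$tax_rank, anchor)
    hits <- backend$search(query, sch$word_size,
                           evalue_cutoff = config$evalue_cutoff,
                           max_hits = config$max_hits,
                           taxon_restriction = restriction)
    n_hits <- nrow(hits)
    any_hits <- any_hits || n_hits > 0L
    if (it == 1L && n_hits > 0L)
      anchor <- lineage_of(backend$metadata, hits$subject_id[1L])
    if (backend$kind == "nt") hits <- genomic_filter(hits, backend$metadata)
    n_genomic <- nrow(hits)

    n_in_band <- 0L
    if (n_genomic > 0L) {
      for (k in seq_len(n_genomic)) {
        id <- hits$subject_id[k]
        if (!is.null(pool[[id]])) {
          pool[[id]]$evalue <- min(pool[[id]]$evalue, hits$evalue[k])
          next
        }
        cand <- extend_hit(hits[k, ], seq_len_nt(query), backend)
        cand$dist_to_query <- distance_percent(query, cand$sequence, model)
        if (cand$dist_to_query >= band$min_dist &&
            cand$dist_to_query <= band$max_dist)
          pool[[id]] <- cand
      }
    }
    n_in_band <- length(pool)

    if (n_in_band > 0L) {
      ord <- order(vapply(pool, function(x) x$evalue, numeric(1)),
                   cand_ids(pool))
      sorted <- pool[ord]
      D <- .pool_dist_matrix(sorted, dfun)
      reps <- reduce_cand_min_dist(sorted, band$min_dist, dist = D)
    }
    log[[it]] <- data.frame(iteration = it, word_size = sch$word_size,
                            tax_rank = ifelse(is.na(sch$tax_rank), "none",
                                              sch$tax_rank),
                            hits = n_hits, genomic = n_genomic,
                            in_band = n_in_band,
                            representatives = length(reps))
    if (length(reps) >= limits$max_n) break
  }

  if (!any_hits)
    stopf("codonscout_no_homologs",
          "no homologs found for query '%s' after %d search iterations",
          query$id, iterations_run)
  structure(reps,
            search_log = do.call(rbind, log),
            iterations_run = iterations_run)
}

#' Build the temporary custom database for a long query
#'
#' Searches the backend with the sensitivity-oriented build-db word-size
#' schedule (all five iterations, taxonomically anchored on the iteration-1
#' best hit), keeps the best hit per species, caps the collection at
#' `customdb_max_seqs` sequences (E-value order), and stores each retained
#' subject interval centred on the hit midpoint and expanded to
#' `customdb_expansion` times the query length (clipped to the subject
#' bounds) — slack for possibly large intron-length differences. No
#' similarity-based selection happens at this stage.
#'
#' @param query An [nt_seq()].
#' @param backend A [search_backend()].
#' @param config A [run_config()].
#' @return A [word_seed_backend()] of kind `"custom"` over the extracted
#'   target sequences.
#' @section Errors: `codonscout_customdb_empty` if nothing is retrievable.
#' @export
build_custom_db <- function(query, backend, config = run_config()) {
  query <- as_nt_seq(query, "query")
  qlen <- seq_len_nt(query)
  all_hits <- empty_hits()
  anchor <- NULL
  for (it in 1:5) {
    sch <- schedule_for(it, "build_db")
    restriction <- if (it == 1L) NULL else .restriction_for(sch$tax_rank, anchor)
    hits <- backend$search(query, sch$word_size,
                           evalue_cutoff = config$evalue_cutoff,
                           max_hits = config$max_hits,
                           taxon_restriction = restriction)
    if (it == 1L && nrow(hits) > 0L)
      anchor <- lineage_of(backend$metadata, hits$subject_id[1L])
    if (backend$kind == "nt") hits <- genomic_filter(hits, backend$metadata)
    all_hits <- rbind(all_hits, hits)
    best <- dedupe_best_per_species(all_hits, backend$metadata)
    if (nrow(best) >= config$customdb_max_seqs) break
  }
  best <- dedupe_best_per_species(all_hits, backend$metadata)
  best <- head(best, config$customdb_max_seqs)
  if (nrow(best) == 0L)
    stopf("codonscout_customdb_empty",
          "custom database empty: no sequences retrievable for query '%s'",
          query$id)

  target_len <- config$customdb_expansion * qlen
  records <- lapply(seq_len(nrow(best)), function(k) {
    h <- best[k, ]
    slen <- backend$subject_length(h$subject_id)
    mid <- (h$s_start + h$s_end) / 2
    from <- max(0L, as.integer(floor(mid - target_len / 2)))
    to <- min(slen, from + target_len)
    from <- max(0L, to - target_len)  # re-anchor if clipped on the right
    meta <- meta_row(backend$metadata, h$subject_id)
    nt_seq(h$subject_id, backend$get_subject(h$subject_id, from, to),
           taxon = if (is.null(meta)) h$taxon else meta$taxon,
           species = if (is.null(meta)) NA else meta$species)
  })
  ids <- vapply(records, function(s) s$id, character(1))
  meta <- backend$metadata[backend$metadata$id %in% ids, , drop = FALSE]
  if (nrow(meta) < length(ids)) {
    extra <- setdiff(ids, meta$id)
    meta <- rbind(meta, record_metadata(data.frame(id = extra)))
  }
  meta$biomol <- "genomic"   # custom targets are genomic slices by construction
  word_seed_backend(records, meta, kind = "custom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
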