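#' Run the full pipeline on a single query
#'
#' Orchestrates the three processing steps — homolog retrieval/selection, MSA
#' construction, scoring — and the HSS post-processing, choosing between two
#' paths:
#' \describe{
#'   \item{short query (length <= windowing threshold)}{[iterative_search()]
#'     with the five-step word-size/taxonomy schedule, [select_final()],
#'     [build_msa()], [score_window()].}
#'   \item{long query}{[build_custom_db()] once, then [split_query()]; each
#'     window is searched independently against the custom database (single
#'     search at the iteration-1 full-pipeline word size), its hits extended
#'     to window length, band-filtered, clustered and selected, aligned and
#'     scored; window failures degrade gracefully (warning, window skipped)
#'     unless every window fails.}
#' }
#' Post-processing is merge (cross-window fragments are judged once), then
#' shadow resolution, then the p-value filter. A run with zero HSS is a
#' successful negative result.
#'
#' @param query Path to a single-record FASTA, or an [nt_seq()].
#' @param backend A [search_backend()].
#' @param config A [run_config()].
#' @param aligner Aligner adapter (default [stub_aligner()]).
#' @param scorer Scorer adapter (default [stub_scorer()], which reports no
#'   HSS).
#' @return An [hss_report()]; if `config$out_dir` is set the report is also
#'   exported there and the paths attached as attribute `"files"`.
#' @export
run_pipeline <- function(query, backend, config = run_config(),
                         aligner = stub_aligner(), scorer = stub_scorer()) {
  if (is.character(query)) {
    seqs <- read_fasta(query)
    if (length(seqs) != 1L)
      stopf("codonscout_input_error",
            "query FASTA must contain exactly one record, found %d",
            length(seqs))
    query <- seqs[[1L]]
  }
  stopifnot(is_nt_seq(query), inherits(backend, "search_backend"))
  qlen <- seq_len_nt(query)

  if (is_long_query(query, config$windowing)) {
    res <- .run_long_path(query, backend, config, aligner, scorer)
  } else {
    res <- .run_short_path(query, backend, config, aligner, scorer)
  }

  hss <- res$hss
  n_raw <- nrow(hss)
  hss <- merge_in_frame(hss, qlen)
  n_merged <- nrow(hss)
  hss <- resolve_shadows(hss)
  n_shadowed <- nrow(hss)
  hss <- filter_p(hss, config$p_display_cutoff)

  report <- hss_report(
    hss, query, res$windows,
    filters_applied = c(config_as_list(config),
                        list(hss_raw = n_raw, hss_merged = n_merged,
                             hss_after_shadows = n_shadowed,
                             hss_reported = nrow(hss))),
    search_log = res$log)
  if (!is.null(config$out_dir)) {
    files <- export_report(report, config$out_dir)
    attr(report, "files") <- files
  }
  report
}

.run_short_path <- function(query, backend, config, aligner, scorer) {
  reps <- iterative_search(query, backend, config)
  sel <- select_final(reps, config$limits)
  windows <- split_query(query, config$windowing)  # single window
  msa <- build_msa(windows[[1L]], sel, aligner, ref_id = query$id)
  hss <- score_window(msa, scorer, seq_len_nt(query))
  log <- attr(reps, "search_log")
  log$selected <- NA_integer_
  log$selected[nrow(log)] <- length(sel)
  list(hss = hss, windows = windows, log = log)
}

.run_long_path <- function(query, backend, config, aligner, scorer) {
  custom <- build_custom_db(query, backend, config)
  windows <- split_query(query, config$windowing)
  ws <- schedule_for(1L, "full")$word_size
  model <- config$model
  band <- config$band

  all_hss <- list()
  log <- list()
  n_ok <- 0L
  for (w in windows) {
    wq <- nt_seq(sprintf("%s|w%d", query$id, w$index), w$residues)
    wlen <- w$q_end - w$q_start
    counts <- data.frame(window = w$index, hits = 0L, in_band = 0L,
                         clustered = 0L, selected = 0L, hss = 0L)
    whss <- tryCatch({
      hits <- custom$search(wq, ws, evalue_cutoff = config$evalue_cutoff,
                            max_hits = config$max_hits,
                            taxon_restriction = NULL)
      counts$hits <- nrow(hits)
      if (nrow(hits) == 0L)
        stopf("codonscout_insufficient_homologs",
              "window %d: no hits against the custom database", w$index)
      hits <- hits[!duplicated(hits$subject_id), , drop = FALSE]
      cands <- lapply(seq_len(nrow(hits)), function(k)
        extend_hit(hits[k, ], wlen, custom))
      for (k in seq_along(cands))
        cands[[k]]$dist_to_query <- distance_percent(wq, cands[[k]]$sequence,
                                                     model)
      cands <- band_filter(cands, band)
      counts$in_band <- length(cands)
      cands <- cands[order(vapply(cands, function(x) x$evalue, numeric(1)),
                           cand_ids(cands))]
      reps <- reduce_cand_min_dist(cands, band$min_dist, model = model)
      counts$clustered <- length(reps)
      sel <- select_final(reps, config$limits)
      counts$selected <- length(sel)
      msa <- build_msa(w, sel, aligner, ref_id = query$id)
      hss <- score_window(msa, scorer, seq_len_nt(query))
      counts$hss <- nrow(hss)
      hss
    }, codonscout_insufficient_homologs = function(e) {
      warnf("window %d skipped: %s", w$index, conditionMessage(e))
      NULL
    }, codonscout_scoring_error = function(e) {
      warnf("window %d skipped: %s", w$index, conditionMessage(e))
      NULL
    }, codonscout_parse_error = function(e) {
      warnf("window %d skipped: %s", w$index, conditionMessage(e))
      NULL
    })
    if (!is.null(whss)) {
      n_ok <- n_ok + 1L
      all_hss[[length(all_hss) + 1L]] <- whss
    }
    log[[length(log) + 1L]] <- counts
  }
  if (n_ok == 0L)
    stopf("codonscout_no_homologs",
          "all %d windows failed: no scorable window for query '%s'",
          length(windows), query$id)
  hss <- if (length(all_hss)) do.call(rbind, all_hss) else empty_hss_table()
  list(hss = hss, windows = windows, log = do.call(rbind, log))
}
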