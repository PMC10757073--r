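#' Pipeline run configuration
#'
#' Aggregates every operating constant of the pipeline with its default:
#' divergence band 10--60 %, 2--16 selected sequences, 1000-bp windows with
#' 300-bp overlap, blastn-style E-value cutoff 0.01 with up to 10,000 hits
#' per search, p-value display cutoff 0.05, and a custom database of at most
#' 300 sequences expanded to 5 times the query length. Every override is
#' validated against its type's invariants.
#'
#' @param band A [distance_band()].
#' @param limits A [selection_limits()].
#' @param windowing A [windowing_config()].
#' @param evalue_cutoff Maximum E-value of retained hits (default 0.01).
#' @param max_hits Hits requested per search round (default 10,000).
#' @param p_display_cutoff HSS p-value cutoff (default 0.05).
#' @param customdb_max_seqs Cap on custom-database sequences (default 300).
#' @param customdb_expansion Target length of stored custom-database entries,
#'   as a multiple of the query length (default 5).
#' @param model A [scoring_model()].
#' @param seed Integer seed recorded in the run summary.
#' @param out_dir Output directory for [run_pipeline()] exports (`NULL`: no
#'   files).
#' @return An object of class `run_config`.
#' @export
run_config <- function(band = distance_band(),
                       limits = selection_limits(),
                       windowing = windowing_config(),
                       evalue_cutoff = 0.01,
                       max_hits = 10000L,
                       p_display_cutoff = 0.05,
                       customdb_max_seqs = 300L,
                       customdb_expansion = 5L,
                       model = scoring_model(),
                       seed = 1L,
                       out_dir = NULL) {
  stopifnot(inherits(band, "distance_band"),
            inherits(limits, "selection_limits"),
            inherits(windowing, "windowing_config"),
            inherits(model, "scoring_model"))
  if (evalue_cutoff <= 0)
    stop("config error: evalue_cutoff must be > 0", call. = FALSE)
  if (max_hits < 1)
    stop("config error: max_hits must be >= 1", call. = FALSE)
  if (p_display_cutoff <= 0 || p_display_cutoff > 1)
    stop("config error: p_display_cutoff must be in (0, 1]", call. = FALSE)
  if (customdb_max_seqs < 1)
    stop("config error: customdb_max_seqs must be >= 1", call. = FALSE)
  if (customdb_expansion < 1)
    stop("config error: customdb_expansion must be >= 1", call. = FALSE)
  structure(list(band = band, limits = limits, windowing = windowing,
                 evalue_cutoff = evalue_cutoff,
                 max_hits = as.integer(max_hits),
                 p_display_cutoff = p_display_cutoff,
                 customdb_max_seqs = as.integer(customdb_max_seqs),
                 customdb_expansion = as.integer(customdb_expansion),
                 model = model, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  band:        %g-%g %%\n", x$band$min_dist, x$band$max_dist))
  cat(sprintf("  limits:      %d-%d sequences\n",
              x$limits$min_n, x$limits$max_n))
  cat(sprintf("  windows:     %d bp, overlap %d, long-query threshold %d\n",
              x$windowing$chunk_len, x$windowing$overlap,
              x$windowing$long_query_threshold))
  cat(sprintf("  search:      E <= %g, max %d hits/round\n",
              x$evalue_cutoff, x$max_hits))
  cat(sprintf("  custom db:   <= %d seqs, %dx query length\n",
              x$customdb_max_seqs, x$customdb_expansion))
  cat(sprintf("  p cutoff:    %g\n", x$p_display_cutoff))
  invisible(x)
}

# flat key -> constructor argument mapping used by load_config
.flat_keys <- c("min_dist", "max_dist", "min_n", "max_n", "chunk_len",
                "overlap", "long_query_threshold", "evalue_cutoff",
                "max_hits", "p_display_cutoff", "customdb_max_seqs",
                "customdb_expansion", "seed", "out_dir",
                "match", "mismatch", "gap_open", "gap_extend")

#' Load a run configuration from a YAML file and/or overrides
#'
#' Precedence: package defaults, then the file, then `overrides` (e.g. CLI
#' flags). The file uses flat keys: `min_dist`, `max_dist`, `min_n`, `max_n`,
#' `chunk_len`, `overlap`, `long_query_threshold`, `evalue_cutoff`,
#' `max_hits`, `p_display_cutoff`, `customdb_max_seqs`,
#' `customdb_expansion`, `match`, `mismatch`, `gap_open`, `gap_extend`,
#' `seed`, `out_dir`. Invalid values raise a config error naming the key.
#'
#' @param path Optional YAML file.
#' @param overrides Named list of flat keys taking precedence over the file.
#' @return A validated [run_config()].
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop("config error: file '", path, "' not found", call. = FALSE)
    fv <- yaml::read_yaml(path)
    if (!is.list(fv)) fv <- list()
    vals <- modifyList(vals, fv)
  }
  vals <- modifyList(vals, overrides)
  bad <- setdiff(names(vals), .flat_keys)
  if (length(bad))
    stop("config error: unknown key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  g <- function(key, default) vals[[key]] %||% default
  wrap <- function(key_hint, expr) {
    tryCatch(expr, error = function(e)
      stop("config error (", key_hint, "): ", conditionMessage(e),
           call. = FALSE))
  }
  band <- wrap("min_dist/max_dist",
               distance_band(g("min_dist", 10), g("max_dist", 60)))
  limits <- wrap("min_n/max_n",
                 selection_limits(g("min_n", 2L), g("max_n", 16L)))
  windowing <- wrap("chunk_len/overlap/long_query_threshold",
                    windowing_config(g("chunk_len", 1000L),
                                     g("overlap", 300L),
                                     g("long_query_threshold", 1000L)))
  model <- wrap("match/mismatch/gap_open/gap_extend",
                scoring_model(g("match", 1L), g("mismatch", -1L),
                              g("gap_open", -1L), g("gap_extend", -1L)))
  wrap("evalue_cutoff/max_hits/p_display_cutoff/customdb",
       run_config(band = band, limits = limits, windowing = windowing,
                  evalue_cutoff = g("evalue_cutoff", 0.01),
                  max_hits = g("max_hits", 10000L),
                  p_display_cutoff = g("p_display_cutoff", 0.05),
                  customdb_max_seqs = g("customdb_max_seqs", 300L),
                  customdb_expansion = g("customdb_expansion", 5L),
                  model = model, seed = g("seed", 1L),
                  out_dir = g("out_dir", NULL)))
}

config_as_list <- function(cfg) {
  list(min_dist = cfg$band$min_dist, max_dist = cfg$band$max_dist,
       min_n = cfg$limits$min_n, max_n = cfg$limits$max_n,
       chunk_len = cfg$windowing$chunk_len,
       overlap = cfg$windowing$overlap,
       long_query_threshold = cfg$windowing$long_query_threshold,
       evalue_cutoff = cfg$evalue_cutoff, max_hits = cfg$max_hits,
       p_display_cutoff = cfg$p_display_cutoff,
       customdb_max_seqs = cfg$customdb_max_seqs,
       customdb_expansion = cfg$customdb_expansion,
       match = cfg$model$match, mismatch = cfg$model$mismatch,
       gap_open = cfg$model$gap_open, gap_extend = cfg$model$gap_extend,
       seed = cfg$seed)
}
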