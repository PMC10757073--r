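#' @title Synthetic sequence families and the mock search backend
#' @description Generators that emulate what the pipeline sees in the wild —
#'   a family of homologs derived from a common ancestor at controlled
#'   percent divergences, lineage labels at four ranks, and
#'   word-size-dependent discoverability — so every stage is testable offline
#'   and deterministically.
#' @name synth
NULL

# run code under a seeded, self-contained RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random DNA sequence
#'
#' @param n Length in bp.
#' @param seed Integer seed (deterministic output).
#' @param id Sequence id.
#' @return An [nt_seq()].
#' @export
random_dna <- function(n, seed = 1L, id = "seq") {
  with_seed(seed, nt_seq(id, paste(
    sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")))
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Random open reading frame
#'
#' `ATG` followed by `n_codons - 1` random non-stop codons: translating the
#' result gives an `n_codons`-residue peptide starting with `M` and free of
#' internal stops.
#'
#' @param n_codons Number of codons (= peptide length in amino acids).
#' @param seed Integer seed.
#' @return Residue string of length `3 * n_codons`.
#' @export
random_orf <- function(n_codons, seed = 1L) {
  stopifnot(n_codons >= 1L)
  with_seed(seed, {
    codons <- character(n_codons - 1L)
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(n_codons - 1L)) {
      repeat {
        cd <- paste(sample(bases, 3L, replace = TRUE), collapse = "")
        if (!cd %in% .STOP_CODONS) break
      }
      codons[i] <- cd
    }
    paste0("ATG", paste(codons, collapse = ""))
  })
}

#' Mutate a sequence to a target percent distance
#'
#' Introduces uniform random substitutions at distinct positions, measuring
#' the pairwise percent distance after each one, and stops the first time the
#' measured distance reaches the target. Substitution-only (no indels), so
#' the measured distance tracks the substitution load closely. When a coding
#' interval is given, substitutions are biased towards third codon positions
#' (synonymous-leaning divergence) and substitutions creating an in-frame
#' stop inside the interval are skipped.
#'
#' Note that the matches-over-shorter-length metric saturates: under the
#' default scoring model two unrelated sequences still measure only about
#' 40 % (1 kb) to 47 % (500 bp) distance, because cheap linear gaps let
#' random pairs align many spurious matches. Targets above that background
#' are unreachable by substitution at these lengths; the generator then
#' returns the most divergent state it reached.
#'
#' @param seq The ancestor [nt_seq()].
#' @param target_pct Target distance in percent, `[0, 100]`.
#' @param seed Integer seed (deterministic output).
#' @param model A [scoring_model()] for the distance measurements.
#' @param coding Optional `c(orf_start, orf_len_codons)` (0-based start).
#' @param id Id for the mutated sequence.
#' @return An [nt_seq()] whose measured [distance_percent()] to `seq` is
#'   `>= target_pct` (or the maximum reachable if positions are exhausted).
#' @export
mutate_to_distance <- function(seq, target_pct, seed = 1L,
                               model = scoring_model(), coding = NULL,
                               id = paste0(seq$id, "_mut")) {
  stopifnot(target_pct >= 0, target_pct <= 100)
  if (target_pct == 0)
    return(nt_seq(id, seq$residues, seq$taxon, seq$species))
  with_seed(seed, {
    chars <- strsplit(seq$residues, "")[[1]]
    n <- length(chars)
    weights <- rep(1, n)
    orf <- NULL
    if (!is.null(coding)) {
      orf <- c(coding[1L], coding[1L] + 3L * coding[2L])  # half-open
      inside <- seq_len(n) > orf[1L] & seq_len(n) <= orf[2L]
      third <- inside & ((seq_len(n) - 1L - orf[1L]) %% 3L == 2L)
      weights[inside] <- 0.15
      weights[third] <- 1
      weights[seq_len(n) <= orf[1L] + 3L & inside] <- 0  # keep the start codon
    }
    eligible <- which(weights > 0)
    ord <- sample(eligible, length(eligible), prob = weights[eligible])
    cur <- chars
    # a single substitution near the edge of the local alignment can truncate
    # its tail and jump the measured distance; when a step overshoots by more
    # than `slack`, revert it and look for a gentler position, falling back to
    # the smallest overshoot seen
    slack <- 2.5
    best_d <- -Inf; best_state <- NULL
    k <- 0L  # substitutions consumed from ord
    apply_sub <- function(state, pos) {
      old <- state[pos]
      if (old == "N") return(NULL)
      alt <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      state[pos] <- alt
      if (!is.null(orf) && pos > orf[1L] && pos <= orf[2L]) {
        ci <- (pos - 1L - orf[1L]) %/% 3L
        codon <- paste(state[(orf[1L] + 3L * ci + 1L):(orf[1L] + 3L * ci + 3L)],
                       collapse = "")
        if (codon %in% .STOP_CODONS) return(NULL)  # would create a stop
      }
      state
    }
    # coarse phase: each substitution shifts the distance by <= 100/min-length
    # points, so a deficit of `gap` points needs >= gap*n/100 substitutions;
    # apply 80% of that estimate between measurements to avoid a full-matrix
    # alignment per substitution on long roots
    repeat {
      d <- distance_percent(seq$residues, paste(cur, collapse = ""), model)
      gap <- target_pct - d
      if (gap <= 3 || k >= length(ord)) break
      batch <- max(1L, floor(0.8 * gap * n / 100))
      while (batch > 0L && k < length(ord)) {
        k <- k + 1L
        nxt <- apply_sub(cur, ord[k])
        if (!is.null(nxt)) { cur <- nxt; batch <- batch - 1L }
      }
    }
    # fine phase: measure after every substitution; revert steps that
    # overshoot by more than `slack` and try a gentler position, falling back
    # to the smallest overshoot seen
    d <- distance_percent(seq$residues, paste(cur, collapse = ""), model)
    if (d >= target_pct) { best_state <- cur; best_d <- d }
    if (!(d >= target_pct && d <= target_pct + slack)) {
      while (k < length(ord)) {
        k <- k + 1L
        nxt <- apply_sub(cur, ord[k])
        if (is.null(nxt)) next
        d <- distance_percent(seq$residues, paste(nxt, collapse = ""), model)
        if (d >= target_pct) {
          if (d <= target_pct + slack) { best_state <- nxt; break }
          if (is.null(best_state) || d < best_d) { best_d <- d; best_state <- nxt }
          # overshoot: keep cur, try the next position
        } else {
          cur <- nxt
        }
      }
    }
    if (!is.null(best_state)) cur <- best_state
    nt_seq(id, paste(cur, collapse = ""), seq$taxon, seq$species)
  })
}

# invented 4-rank lineages within one kingdom, cycled so that
# taxonomy-restricted searches are actually exercised
.lineage_pool <- function(n) {
  phyla <- c("Firmicutes", "Bacteroidota")
  classes <- list(Firmicutes = c("Clostridia", "Bacilli"),
                  Bacteroidota = c("Bacteroidia", "Chitinophagia"))
  orders <- list(Clostridia = c("Eubacteriales", "Thermoanaerobacterales"),
                 Bacilli = c("Bacillales", "Lactobacillales"),
                 Bacteroidia = c("Bacteroidales", "Marinilabiliales"),
                 Chitinophagia = c("Chitinophagales", "Saprospirales"))
  lapply(seq_len(n), function(i) {
    ph <- phyla[((i - 1L) %/% 4L) %% 2L + 1L]
    cl <- classes[[ph]][((i - 1L) %/% 2L) %% 2L + 1L]
    od <- orders[[cl]][(i - 1L) %% 2L + 1L]
    list(kingdom = "Bacteria", phylum = ph, class = cl, order = od)
  })
}

#' Generate a synthetic homolog family with metadata
#'
#' Builds a root sequence (optionally embedding an ORF with
#' synonymous-biased divergence) and one homolog per requested target
#' distance, each with a species name, taxon id and a 4-rank lineage spread
#' across orders/classes/phyla of one kingdom so that taxonomy-restricted
#' search is exercised. All records are labelled `biomol = "genomic"` unless
#' overridden.
#'
#' @param root_length Root length in bp (ignored if `root` is given).
#' @param target_distances Numeric vector of percent distances, one homolog
#'   each.
#' @param seed Integer seed; homolog `i` uses `seed + i`.
#' @param coding Optional `c(orf_start, orf_len_codons)` embedded in the root.
#' @param root Optional explicit root [nt_seq()].
#' @param biomol Biomolecule label(s) for the homolog records, recycled.
#' @return List with `root` ([nt_seq()]), `records` (list of homolog
#'   [nt_seq()]s), `metadata` (a [record_metadata()] table covering the
#'   homologs) and `coding`.
#' @export
make_family <- function(root_length = 600L, target_distances = numeric(),
                        seed = 1L, coding = NULL, root = NULL,
                        biomol = "genomic") {
  if (is.null(root)) {
    root <- random_dna(root_length, seed = seed, id = "QUERY")
    if (!is.null(coding)) {
      orf <- random_orf(coding[2L], seed = seed + 1000L)
      res <- root$residues
      substr(res, coding[1L] + 1L, coding[1L] + nchar(orf)) <- orf
      root <- nt_seq(root$id, res)
    }
  }
  n <- length(target_distances)
  lineages <- .lineage_pool(max(n, 1L))
  biomol <- rep_len(biomol, max(n, 1L))
  records <- list()
  meta <- list()
  for (i in seq_len(n)) {
    id <- sprintf("H%03d", i)
    h <- mutate_to_distance(root, target_distances[i], seed = seed + i,
                            coding = coding, id = id)
    h$taxon <- as.character(1000L + i)
    h$species <- sprintf("Synthetica homologa_%03d", i)
    records[[id]] <- h
    meta[[id]] <- data.frame(
      id = id, species = h$species, taxon = h$taxon, biomol = biomol[i],
      kingdom = lineages[[i]]$kingdom, phylum = lineages[[i]]$phylum,
      class = lineages[[i]]$class, order = lineages[[i]]$order,
      stringsAsFactors = FALSE)
  }
  metadata <- if (n > 0L) record_metadata(do.call(rbind, meta)) else
    record_metadata(data.frame(id = character()))
  list(root = root, records = records, metadata = metadata, coding = coding)
}

#' Mock search backend over synthetic records
#'
#' A [word_seed_backend()] (exact shared-word discoverability, monotone in
#' word size) over a record collection, defaulting to `"nt"` kind so the
#' genomic filter is exercised.
#'
#' @param records List of [nt_seq()]s.
#' @param metadata A [record_metadata()] table.
#' @param kind Backend kind.
#' @return A [search_backend()].
#' @export
make_mock_backend <- function(records, metadata, kind = "nt") {
  word_seed_backend(records, metadata, kind = kind)
}

#' Build scorer tabular fixture text
#'
#' Constructs well-formed 11-column scorer output from a table of segments;
#' `parse_scorer_tabular(make_scorer_fixture(x))` reproduces `x`'s fields.
#'
#' @param hss Data frame with columns `strand`, `frame` (0..2), `start`,
#'   `end` (0-based half-open window-local), `score`, `p_value`; optional
#'   `hss_id`, `length_aa`, `aln_start`, `aln_end`, `ref_name`.
#' @param window_len Window length, for coordinate validation.
#' @param ref_name Default reference name.
#' @return Tabular text accepted by [parse_scorer_tabular()].
#' @export
make_scorer_fixture <- function(hss, window_len = NULL, ref_name = "query") {
  if (nrow(hss) == 0L) return("")
  if (!all(c("strand", "frame", "start", "end", "score", "p_value") %in%
           names(hss)))
    stop("fixture spec must have strand, frame, start, end, score, p_value",
         call. = FALSE)
  if (any(hss$start < 0) || any(hss$end <= hss$start))
    stop("fixture spec: bad coordinates", call. = FALSE)
  if (!is.null(window_len) && any(hss$end > window_len))
    stop("fixture spec: coordinates outside window", call. = FALSE)
  if (any(hss$p_value <= 0 | hss$p_value > 1))
    stop("fixture spec: p-values must be in (0, 1]", call. = FALSE)
  if (is.null(hss$hss_id)) hss$hss_id <- seq_len(nrow(hss))
  if (is.null(hss$length_aa)) hss$length_aa <- (hss$end - hss$start) %/% 3L
  if (is.null(hss$aln_start)) hss$aln_start <- hss$start
  if (is.null(hss$aln_end)) hss$aln_end <- hss$end
  if (is.null(hss$ref_name)) hss$ref_name <- ref_name
  serialize_scorer_tabular(hss)
}

#' Write a family's FASTA and metadata TSV fixtures
#'
#' @param family A [make_family()] result.
#' @param dir Target directory (created if needed).
#' @return Named paths (`query`, `records`, `metadata`), invisibly.
#' @export
write_family_fixtures <- function(family, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  qp <- file.path(dir, "query.fa")
  rp <- file.path(dir, "records.fa")
  mp <- file.path(dir, "metadata.tsv")
  write_fasta(list(family$root), qp)
  write_fasta(family$records, rp)
  write_metadata_tsv(family$metadata, mp)
  invisible(c(query = qp, records = rp, metadata = mp))
}
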