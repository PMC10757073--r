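#' Filter HSS by p-value
#'
#' Keeps segments with `p_value` strictly below the cutoff; order preserved.
#' Idempotent. No multiple-testing correction is applied: p-values are
#' reported as produced by the scorer and 0.05 is a display cutoff.
#'
#' @param hss HSS table (see [score_window()]).
#' @param cutoff Default 0.05.
#' @return The retained subset.
#' @export
filter_p <- function(hss, cutoff = 0.05) {
  out <- hss[hss$p_value < cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

#' Resolve opposite-frame "shadow" segments
#'
#' True coding regions tend to cast a weaker but still significant segment on
#' the opposite strand or in another frame — a statistical artifact of the
#' genetic code's structure. Among overlapping segments that differ in strand
#' or frame, only the best (lowest p-value; ties by higher score, then
#' leftmost start) is retained; each kept segment suppresses every
#' lower-ranked segment it overlaps in a different strand/frame.
#' Non-overlapping segments are untouched.
#'
#' @param hss HSS table with query-space frames.
#' @return The retained subset, in the input's order.
#' @export
resolve_shadows <- function(hss) {
  n <- nrow(hss)
  if (n <= 1L) return(hss)
  ord <- order(hss$p_value, -hss$score, hss$q_start)
  keep <- rep(NA, n)  # NA undecided, TRUE kept, FALSE suppressed
  for (i in ord) {
    if (!is.na(keep[i])) next
    keep[i] <- TRUE
    conflict <- which(is.na(keep) &
                        (hss$strand != hss$strand[i] |
                           hss$frame != hss$frame[i]) &
                        .overlaps(hss$q_start, hss$q_end,
                                  hss$q_start[i], hss$q_end[i]))
    keep[conflict] <- FALSE
  }
  out <- hss[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge overlapping or abutting in-frame segments
#'
#' Segments with equal strand and equal query frame whose intervals overlap
#' or abut are unioned into a single prediction — typically fragments of one
#' coding region re-detected in the shared zone of adjacent windows. The
#' merged p-value is the minimum of the members (the scorer is not re-run on
#' merged spans; an approximation), the score is the maximum, and
#' `window_index` lists all contributors. The merged interval is trimmed to
#' the codon boundaries of the frame, anchored at the lowest-p member.
#'
#' @param hss HSS table with query-space frames.
#' @param query_len Query length (needed to anchor minus-strand codon
#'   boundaries).
#' @return Merged HSS table, sorted by `q_start`.
#' @export
merge_in_frame <- function(hss, query_len) {
  if (nrow(hss) <= 1L) return(hss)
  out <- list()
  for (key in unique(paste(hss$strand, hss$frame))) {
    g <- hss[paste(hss$strand, hss$frame) == key, , drop = FALSE]
    g <- g[order(g$q_start, g$q_end), , drop = FALSE]
    i <- 1L
    while (i <= nrow(g)) {
      members <- g[i, , drop = FALSE]
      cur_end <- g$q_end[i]
      j <- i + 1L
      while (j <= nrow(g) && g$q_start[j] <= cur_end) {  # overlap or abut
        members <- rbind(members, g[j, , drop = FALSE])
        cur_end <- max(cur_end, g$q_end[j])
        j <- j + 1L
      }
      out[[length(out) + 1L]] <- .merge_members(members, query_len)
      i <- j
    }
  }
  merged <- do.call(rbind, out)
  merged <- merged[order(merged$q_start, merged$q_end, merged$strand), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  merged
}

.merge_members <- function(members, query_len) {
  s <- min(members$q_start); e <- max(members$q_end)
  best <- which.min(members$p_value)
  strand <- members$strand[1L]
  if (strand == "+") {
    anchor <- members$q_start[best]
    s <- s + (anchor - s) %% 3L
    e <- s + 3L * ((e - s) %/% 3L)
  } else {
    anchor <- members$q_end[best]
    e <- e - (e - anchor) %% 3L
    s <- e - 3L * ((e - s) %/% 3L)
  }
  data.frame(
    window_index = paste(unique(unlist(
      strsplit(members$window_index, ",", fixed = TRUE))), collapse = ","),
    strand = strand, frame = members$frame[1L],
    q_start = as.integer(s), q_end = as.integer(e),
    length_aa = as.integer((e - s) / 3L),
    score = max(members$score), p_value = min(members$p_value),
    stringsAsFactors = FALSE)
}

#' Translate an HSS to protein
#'
#' Standard genetic code; minus-strand segments are reverse-complemented
#' first. Internal stop codons are rendered `*` and reported with a warning.
#'
#' @param query The query [nt_seq()].
#' @param h One HSS (1-row table or list) with `(q_end - q_start)` divisible
#'   by 3.
#' @return The peptide as a character string.
#' @export
translate_hss <- function(query, h) {
  h <- as.list(h)
  len <- h$q_end - h$q_start
  if (len %% 3L != 0L)
    stopf("codonscout_contract_error",
          "HSS [%d,%d) has length %d not divisible by 3",
          h$q_start, h$q_end, len)
  nt <- subseq_residues(query, h$q_start, h$q_end)
  if (h$strand == "-") nt <- revcomp(nt)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(nt), if.fuzzy.codon = "solve"))
  if (grepl("*", substr(aa, 1, nchar(aa) - 1L), fixed = TRUE))
    warnf("HSS [%d,%d)%s translation contains internal stop codon(s)",
          h$q_start, h$q_end, h$strand)
  aa
}

#' Assemble an HSS report
#'
#' @param hss Final HSS table in query coordinates.
#' @param query The query [nt_seq()].
#' @param windows List of `sub_query` windows used.
#' @param filters_applied Named list of thresholds applied (echoed into the
#'   run summary).
#' @param search_log Optional per-stage count table.
#' @return An object of class `hss_report`.
#' @export
hss_report <- function(hss, query, windows, filters_applied = list(),
                       search_log = NULL) {
  qlen <- seq_len_nt(query)
  if (nrow(hss) > 0L && (any(hss$q_start < 0L) || any(hss$q_end > qlen)))
    stop("HSS outside [0, query_length)", call. = FALSE)
  structure(list(hss = hss, query_id = query$id, query_length = qlen,
                 query = query, windows = windows,
                 filters_applied = filters_applied, search_log = search_log),
            class = "hss_report")
}

#' @export
print.hss_report <- function(x, ...) {
  cat(sprintf("<hss_report> query %s (%d nt), %d window(s), %d HSS\n",
              x$query_id, x$query_length, length(x$windows), nrow(x$hss)))
  if (nrow(x$hss) > 0L) print(x$hss)
  invisible(x)
}

hss_names <- function(hss) {
  sprintf("HSS_%d_%s_f%d_p%g", seq_len(nrow(hss)),
          ifelse(hss$strand == "+", "fwd", "rev"), hss$frame, hss$p_value)
}

hss_granges <- function(report) {
  hss <- report$hss
  GenomicRanges::GRanges(
    seqnames = rep(report$query_id, nrow(hss)),
    ranges = IRanges::IRanges(start = hss$q_start + 1L, end = hss$q_end),
    strand = hss$strand,
    seqlengths = setNames(report$query_length, report$query_id))
}

#' Export an HSS report to files
#'
#' Writes, per requested format: `hss.tsv` (the scorer's fields echoed in
#' query coordinates, 0-based half-open; re-ingestable with
#' [read_hss_tsv()]), `hss.bed` (BED6, 0-based half-open, score column
#' `min(1000, round(-10 log10 p))`), `hss.gff3` (1-based inclusive, source
#' `codonscout`, type `CDS_region`), `proteins.fa` (translations of all HSS)
#' and `summary.yaml` plus `windows.tsv` (applied thresholds, stage counts,
#' window table). Output is byte-deterministic for fixed input.
#'
#' @param report An [hss_report()].
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("tsv", "bed", "gff3", "fasta", "summary")`.
#' @return Named character vector of written paths, invisibly.
#' @export
export_report <- function(report,
                          dir,
                          formats = c("tsv", "bed", "gff3", "fasta",
                                      "summary")) {
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stopf("codonscout_io_error", "cannot create output directory '%s'", dir)
  hss <- report$hss
  paths <- character()

  if ("tsv" %in% formats) {
    p <- file.path(dir, "hss.tsv")
    df <- cbind(query_id = rep(report$query_id, nrow(hss)), hss)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["tsv"] <- p
  }
  if (("bed" %in% formats || "gff3" %in% formats)) {
    gr <- hss_granges(report)
    if ("bed" %in% formats) {
      p <- file.path(dir, "hss.bed")
      bed <- gr
      if (nrow(hss) > 0L) {
        S4Vectors::mcols(bed)$name <- hss_names(hss)
        S4Vectors::mcols(bed)$score <-
          pmin(1000L, as.integer(round(-10 * log10(hss$p_value))))
      }
      rtracklayer::export(bed, p, format = "BED")
      paths["bed"] <- p
    }
    if ("gff3" %in% formats) {
      p <- file.path(dir, "hss.gff3")
      gff <- gr
      if (nrow(hss) > 0L) {
        S4Vectors::mcols(gff)$source <- "codonscout"
        S4Vectors::mcols(gff)$type <- "CDS_region"
        S4Vectors::mcols(gff)$ID <- hss_names(hss)
        S4Vectors::mcols(gff)$frame <- hss$frame
        S4Vectors::mcols(gff)$p_value <- hss$p_value
        S4Vectors::mcols(gff)$score <- hss$score
      }
      rtracklayer::export(gff, p, format = "GFF3")
      paths["gff3"] <- p
    }
  }
  if ("fasta" %in% formats) {
    p <- file.path(dir, "proteins.fa")
    if (nrow(hss) > 0L) {
      aa <- vapply(seq_len(nrow(hss)), function(i)
        translate_hss(report$query, hss[i, ]), character(1))
      ss <- Biostrings::AAStringSet(setNames(aa, hss_names(hss)))
      Biostrings::writeXStringSet(ss, p, width = 60L)
    } else {
      writeLines(character(), p)
    }
    paths["fasta"] <- p
  }
  if ("summary" %in% formats) {
    p <- file.path(dir, "summary.yaml")
    yaml::write_yaml(list(
      query_id = report$query_id,
      query_length = report$query_length,
      n_windows = length(report$windows),
      n_hss = nrow(hss),
      filters_applied = report$filters_applied,
      search_log = if (is.null(report$search_log)) NULL else
        lapply(seq_len(nrow(report$search_log)), function(i)
          as.list(report$search_log[i, ]))), p)
    pw <- file.path(dir, "windows.tsv")
    write.table(windows_table(report$windows), pw, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths["summary"] <- p
    paths["windows"] <- pw
  }
  invisible(paths)
}

#' Re-ingest an exported HSS TSV
#'
#' @param path File written by [export_report()].
#' @return HSS table (without the `query_id` column).
#' @export
read_hss_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c(window_index = "character",
                                  strand = "character"))
  df$query_id <- NULL
  df
}
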