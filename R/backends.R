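#' Search backend contract
#'
#' A backend abstracts a blastn-style homology search plus retrieval of full
#' subject sequences. It is a list with:
#' \describe{
#'   \item{`search(query, word_size, evalue_cutoff, max_hits,
#'     taxon_restriction)`}{returns a hit table (see [empty_hits()]) whose
#'     rows respect the E-value cutoff and the taxon restriction. The
#'     restriction is `NULL` or `list(rank =, value =)` with rank one of
#'     `"order"`, `"class"`, `"phylum"`, `"kingdom"`.}
#'   \item{`get_subject(id, start, end)`}{returns the forward-strand residues
#'     of a subject, optionally the 0-based half-open slice `[start, end)`.}
#'   \item{`subject_length(id)`}{length of a subject record.}
#'   \item{`metadata`}{per-record metadata table (see
#'     [record_metadata()]).}
#'   \item{`kind`}{`"nt"` (heterogeneous biomolecules; genomic filtering
#'     applies), `"refseq"` (assumed genomic) or `"custom"` (temporary
#'     query-specific database).}
#' }
#'
#' @param search,get_subject,subject_length Functions as described.
#' @param metadata A [record_metadata()] table.
#' @param kind Backend kind.
#' @return An object of class `search_backend`.
#' @export
search_backend <- function(search, get_subject, subject_length, metadata,
                           kind = c("nt", "refseq", "custom")) {
  stopifnot(is.function(search), is.function(get_subject),
            is.function(subject_length))
  kind <- match.arg(kind)
  metadata <- record_metadata(metadata)
  structure(list(search = search, get_subject = get_subject,
                 subject_length = subject_length, metadata = metadata,
                 kind = kind),
            class = "search_backend")
}

#' Per-record metadata table
#'
#' Validates and normalises a metadata table with columns `id`, `species`,
#' `taxon`, `biomol` and the four lineage ranks `kingdom`, `phylum`, `class`,
#' `order` (any rank may be `NA`).
#'
#' @param df A data frame with at least an `id` column; missing columns are
#'   added as `NA`.
#' @return The normalised data frame, one row per record id.
#' @export
record_metadata <- function(df) {
  stopifnot(is.data.frame(df), "id" %in% names(df))
  cols <- c("id", "species", "taxon", "biomol",
            "kingdom", "phylum", "class", "order")
  for (cl in setdiff(cols, names(df))) df[[cl]] <- rep(NA_character_, nrow(df))
  df <- df[, cols]
  for (cl in cols) df[[cl]] <- as.character(df[[cl]])
  if (anyDuplicated(df$id))
    stop("record metadata: duplicate ids", call. = FALSE)
  rownames(df) <- df$id
  df
}

meta_row <- function(metadata, id) {
  i <- match(id, metadata$id)
  if (is.na(i)) NULL else metadata[i, ]
}

#' Lineage of a record
#'
#' @param metadata A [record_metadata()] table.
#' @param id Record id.
#' @return Named list with `kingdom`, `phylum`, `class`, `order` (possibly
#'   `NA`), or `NULL` if the id is unknown.
#' @export
lineage_of <- function(metadata, id) {
  r <- meta_row(metadata, id)
  if (is.null(r)) return(NULL)
  list(kingdom = r$kingdom, phylum = r$phylum,
       class = r$class, order = r$order)
}

passes_restriction <- function(metadata, id, restriction) {
  if (is.null(restriction)) return(TRUE)
  lin <- lineage_of(metadata, id)
  if (is.null(lin)) return(FALSE)
  v <- lin[[restriction$rank]]
  !is.na(v) && identical(v, restriction$value)
}

#' An empty hit table with the pipeline's internal hit schema
#'
#' Internal hit tables use 0-based half-open coordinates on the forward
#' strand of both query and subject; `strand` is `"+"` or `"-"` (a `-` hit
#' means the query matches the reverse complement of the subject slice).
#'
#' @return A zero-row data frame with the hit columns.
#' @export
empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             strand = character(), evalue = numeric(),
             identity = numeric(), bitscore = numeric(),
             taxon = character(), stringsAsFactors = FALSE)
}

#' In-process word-seed search backend over a set of records
#'
#' A FASTA-backed index that models blastn word seeding exactly: a subject is
#' discoverable at word size `w` iff it shares at least one exact common
#' substring of length `>= w` with the query (on either strand; `N` never
#' matches). The reported hit is the maximal shared block, with E-value
#' `L_query * 4^(-block_length)` (the random-expectation rate for a
#' quarter-alphabet), clipped below at 1e-180, so E-values decrease
#' monotonically with block length.
#'
#' This is both the mock backend used in tests and the searchable index
#' behind the temporary custom database for long queries.
#'
#' @param records List of [nt_seq()]s (the subject collection).
#' @param metadata A [record_metadata()] table covering the record ids.
#' @param kind Backend kind (see [search_backend()]).
#' @return A [search_backend()].
#' @export
word_seed_backend <- function(records, metadata, kind = "nt") {
  if (length(records) == 0L)
    stop("word_seed_backend: records must be non-empty", call. = FALSE)
  names(records) <- vapply(records, function(s) s$id, character(1))
  metadata <- record_metadata(metadata)

  get_subject <- function(id, start = NULL, end = NULL) {
    s <- records[[id]]
    if (is.null(s)) stop("unknown subject id '", id, "'", call. = FALSE)
    if (is.null(start)) s$residues else subseq_residues(s, start, end)
  }
  subject_length <- function(id) {
    s <- records[[id]]
    if (is.null(s)) stop("unknown subject id '", id, "'", call. = FALSE)
    seq_len_nt(s)
  }

  search <- function(query, word_size, evalue_cutoff = 0.01,
                     max_hits = 10000L, taxon_restriction = NULL) {
    query <- as_nt_seq(query, "query")
    qlen <- seq_len_nt(query)
    rows <- list()
    for (s in records) {
      if (!passes_restriction(metadata, s$id, taxon_restriction)) next
      fwd <- .lcs_cpp(query$residues, s$residues)
      rev <- .lcs_cpp(query$residues, revcomp(s$residues))
      use_rev <- rev$length > fwd$length
      blk <- if (use_rev) rev else fwd
      if (blk$length < word_size) next
      ev <- max(qlen * 4^(-blk$length), 1e-180)
      if (ev > evalue_cutoff) next
      slen <- seq_len_nt(s)
      if (use_rev) {
        s_start <- slen - (blk$b_start + blk$length); s_end <- slen - blk$b_start
      } else {
        s_start <- blk$b_start; s_end <- blk$b_start + blk$length
      }
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = query$id, subject_id = s$id,
        q_start = blk$a_start, q_end = blk$a_start + blk$length,
        s_start = s_start, s_end = s_end,
        strand = if (use_rev) "-" else "+",
        evalue = ev, identity = 100,
        bitscore = 2 * blk$length,
        taxon = metadata[s$id, "taxon"],
        stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L) return(empty_hits())
    hits <- do.call(rbind, rows)
    hits <- hits[order(hits$evalue, -hits$bitscore, hits$subject_id), ]
    rownames(hits) <- NULL
    head(hits, max_hits)
  }

  search_backend(search, get_subject, subject_length, metadata, kind)
}

#' Local blastn search backend
#'
#' Wraps the `makeblastdb`/`blastn` binaries over a local FASTA file. The
#' database is built once in a temporary directory; searches request tabular
#' output (`-outfmt 6` plus `sstrand`) and are converted to the internal
#' 0-based half-open hit schema. Taxon restrictions are applied after the
#' search via the metadata table (no taxdb is required).
#'
#' @param fasta Path to the subject FASTA.
#' @param metadata A [record_metadata()] table covering the FASTA ids.
#' @param kind Backend kind (see [search_backend()]).
#' @param blastn,makeblastdb Binary names/paths.
#' @return A [search_backend()].
#' @export
blast_backend <- function(fasta, metadata, kind = "nt",
                          blastn = "blastn", makeblastdb = "makeblastdb") {
  if (Sys.which(makeblastdb) == "" || Sys.which(blastn) == "")
    stop("blastn/makeblastdb not found on PATH", call. = FALSE)
  records <- read_fasta(fasta)
  metadata <- record_metadata(metadata)
  dbdir <- tempfile("blastdb_")
  dir.create(dbdir)
  db <- file.path(dbdir, "subjects")
  rc <- system2(makeblastdb,
                c("-in", shQuote(fasta), "-dbtype", "nucl",
                  "-out", shQuote(db)),
                stdout = FALSE, stderr = FALSE)
  if (rc != 0) stop("makeblastdb failed (exit ", rc, ")", call. = FALSE)

  get_subject <- function(id, start = NULL, end = NULL) {
    s <- records[[id]]
    if (is.null(s)) stop("unknown subject id '", id, "'", call. = FALSE)
    if (is.null(start)) s$residues else subseq_residues(s, start, end)
  }
  subject_length <- function(id) seq_len_nt(records[[id]])

  search <- function(query, word_size, evalue_cutoff = 0.01,
                     max_hits = 10000L, taxon_restriction = NULL) {
    query <- as_nt_seq(query, "query")
    qf <- tempfile(fileext = ".fa"); on.exit(unlink(qf), add = TRUE)
    write_fasta(list(query), qf)
    out <- tempfile(fileext = ".tsv"); on.exit(unlink(out), add = TRUE)
    rc <- system2(blastn,
                  c("-query", shQuote(qf), "-db", shQuote(db),
                    "-word_size", word_size, "-evalue", evalue_cutoff,
                    "-max_target_seqs", max_hits, "-dust", "no",
                    "-outfmt", shQuote(paste("6 qseqid sseqid pident length",
                                             "evalue bitscore qstart qend",
                                             "sstart send sstrand")),
                    "-out", shQuote(out)),
                  stdout = FALSE, stderr = FALSE)
    if (rc != 0) stop("blastn failed (exit ", rc, ")", call. = FALSE)
    if (file.size(out) == 0) return(empty_hits())
    raw <- read.table(out, sep = "\t", stringsAsFactors = FALSE,
                      col.names = c("qseqid", "sseqid", "pident", "length",
                                    "evalue", "bitscore", "qstart", "qend",
                                    "sstart", "send", "sstrand"))
    raw$staxids <- vapply(raw$sseqid, function(id) {
      r <- meta_row(metadata, id); if (is.null(r)) NA_character_ else r$taxon
    }, character(1))
    hits <- hits_from_blast_dialect(raw)
    keep <- vapply(hits$subject_id, passes_restriction,
                   logical(1), metadata = metadata,
                   restriction = taxon_restriction)
    hits <- hits[keep, , drop = FALSE]
    rownames(hits) <- NULL
    hits
  }

  search_backend(search, get_subject, subject_length, metadata, kind)
}

#' Convert blastn `-outfmt 6` style rows to the internal hit schema
#'
#' Expects columns `qseqid sseqid pident length evalue bitscore qstart qend
#' sstart send sstrand staxids` with 1-based inclusive coordinates and the
#' blast minus-strand convention (`sstart > send`); `sstrand` is
#' `plus`/`minus` (or `+`/`-`).
#'
#' @param raw Data frame in the dialect.
#' @return Internal hit table (see [empty_hits()]).
#' @export
hits_from_blast_dialect <- function(raw) {
  if (nrow(raw) == 0L) return(empty_hits())
  minus <- raw$sstrand %in% c("minus", "-") | raw$sstart > raw$send
  data.frame(query_id = as.character(raw$qseqid),
             subject_id = as.character(raw$sseqid),
             q_start = as.integer(raw$qstart - 1L),
             q_end = as.integer(raw$qend),
             s_start = as.integer(ifelse(minus, raw$send, raw$sstart) - 1L),
             s_end = as.integer(ifelse(minus, raw$sstart, raw$send)),
             strand = ifelse(minus, "-", "+"),
             evalue = as.numeric(raw$evalue),
             identity = as.numeric(raw$pident),
             bitscore = as.numeric(raw$bitscore),
             taxon = as.character(raw$staxids),
             stringsAsFactors = FALSE)
}

#' Write / read the tabular hit dialect
#'
#' Tab-separated, headerless columns `qseqid sseqid pident length evalue
#' bitscore qstart qend sstart send sstrand staxids` — blastn `-outfmt 6`
#' plus strand and taxon columns. 1-based inclusive coordinates; on the minus
#' strand `sstart > send`.
#'
#' @param hits Internal hit table.
#' @param path File path.
#' @return `write_hits_tsv`: the path, invisibly. `read_hits_tsv`: an
#'   internal hit table.
#' @export
write_hits_tsv <- function(hits, path) {
  minus <- hits$strand == "-"
  out <- data.frame(qseqid = hits$query_id, sseqid = hits$subject_id,
                    pident = hits$identity,
                    length = hits$q_end - hits$q_start,
                    evalue = hits$evalue, bitscore = hits$bitscore,
                    qstart = hits$q_start + 1L, qend = hits$q_end,
                    sstart = ifelse(minus, hits$s_end, hits$s_start + 1L),
                    send = ifelse(minus, hits$s_start + 1L, hits$s_end),
                    sstrand = ifelse(minus, "minus", "plus"),
                    staxids = hits$taxon)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  if (file.size(path) == 0) return(empty_hits())
  raw <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("qseqid", "sseqid", "pident", "length",
                                  "evalue", "bitscore", "qstart", "qend",
                                  "sstart", "send", "sstrand", "staxids"),
                    colClasses = c(qseqid = "character",
                                   sseqid = "character",
                                   staxids = "character"))
  hits_from_blast_dialect(raw)
}

#' Read a metadata TSV (id, species, taxon, biomol, kingdom, phylum, class,
#' order)
#'
#' @param path File with a header row.
#' @return A [record_metadata()] table.
#' @export
read_metadata_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  record_metadata(df)
}

#' @rdname read_metadata_tsv
#' @param metadata A [record_metadata()] table to write.
#' @export
write_metadata_tsv <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
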