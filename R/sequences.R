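#' Nucleotide sequence record
#'
#' The universal currency of the pipeline: a named DNA sequence with optional
#' taxon/species metadata. Residues are uppercased on ingest (soft-masking is
#' ignored) and must be drawn from `A`, `C`, `G`, `T`, `N`; other IUPAC
#' ambiguity codes are converted to `N`.
#'
#' @param id Non-empty identifier, unique within any collection.
#' @param residues Non-empty residue string.
#' @param taxon Optional taxon identifier (coerced to character).
#' @param species Optional species name.
#' @return An object of class `nt_seq`.
#' @examples
#' s <- nt_seq("q1", "acgtACGT")
#' nchar(s$residues)
#' @export
nt_seq <- function(id, residues, taxon = NA_character_, species = NA_character_) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    stop("sequence id must be a non-empty string", call. = FALSE)
  if (!is.character(residues) || length(residues) != 1L || is.na(residues) ||
      !nzchar(residues))
    stop("sequence '", id, "': residues must be non-empty", call. = FALSE)
  r <- toupper(residues)
  # collapse non-ACGT IUPAC codes (and anything else alphabetic) to N
  r <- gsub("[^ACGT]", "N", r)
  structure(
    list(id = id, residues = r,
         taxon = as.character(taxon)[1L], species = as.character(species)[1L]),
    class = "nt_seq")
}

#' @export
print.nt_seq <- function(x, ...) {
  n <- nchar(x$residues)
  preview <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("<nt_seq> %s (%d nt)%s\n  %s\n", x$id, n,
              if (!is.na(x$species)) paste0(" [", x$species, "]") else "",
              preview))
  invisible(x)
}

#' @export
length.nt_seq <- function(x) nchar(x$residues)

seq_len_nt <- function(x) nchar(x$residues)

is_nt_seq <- function(x) inherits(x, "nt_seq")

as_nt_seq <- function(x, id = "seq") {
  if (is_nt_seq(x)) x else nt_seq(id, as.character(x))
}

#' Reverse complement of a sequence
#'
#' @param x An `nt_seq` or residue string.
#' @return Same type as the input, reverse-complemented (`N` maps to `N`).
#' @export
revcomp <- function(x) {
  if (is_nt_seq(x)) {
    x$residues <- revcomp(x$residues)
    return(x)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

subseq_residues <- function(x, start, end) {
  # 0-based half-open slice of an nt_seq or string
  r <- if (is_nt_seq(x)) x$residues else x
  substr(r, start + 1L, end)
}

#' Read a (multi-)FASTA file into a list of sequence records
#'
#' The id is the first whitespace-delimited token of each header.
#'
#' @param path FASTA file.
#' @return Named list of [nt_seq()] records.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, call. = FALSE)
  out <- lapply(seq_along(ss), function(i) nt_seq(ids[i], as.character(ss[[i]])))
  names(out) <- ids
  out
}

#' Write sequence records to FASTA (wrapped at 60 columns)
#'
#' @param seqs A list of [nt_seq()] records (or a named character vector).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    v <- seqs
  } else {
    v <- vapply(seqs, function(s) s$residues, character(1))
    names(v) <- vapply(seqs, function(s) s$id, character(1))
  }
  ss <- Biostrings::DNAStringSet(v)
  Biostrings::writeXStringSet(ss, filepath = path, width = 60L)
  invisible(path)
}

stopf <- function(class, fmt, ...) {
  stop(structure(class = c(class, "codonscout_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
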