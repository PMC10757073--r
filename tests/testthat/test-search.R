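test_that("the five-iteration word-size schedule is exact", {
  expected <- data.frame(
    iteration = 1:5,
    build = c(14L, 11L, 9L, 8L, 7L),
    full = c(18L, 14L, 10L, 8L, 7L),
    rank = c(NA, "order", "class", "phylum", "kingdom"))
  for (i in 1:5) {
    expect_equal(schedule_for(i, "full")$word_size, expected$full[i])
    expect_equal(schedule_for(i, "build_db")$word_size, expected$build[i])
    expect_equal(schedule_for(i, "full")$tax_rank, expected$rank[i])
  }
  sched <- search_schedule()
  # word sizes non-increasing, scope widening
  expect_true(all(diff(sched$word_size_full) <= 0))
  expect_true(all(diff(sched$word_size_build_db) <= 0))
  expect_error(schedule_for(0), "1..5")
  expect_error(schedule_for(6), "1..5")
})

test_that("genomic filtering keeps only biomol == genomic", {
  meta <- record_metadata(data.frame(
    id = c("g1", "m1", "g2"), biomol = c("genomic", "mRNA", "GENOMIC")))
  hits <- rbind(mk_hit("g1", 0, 50, 10, 60), mk_hit("m1", 0, 50, 10, 60),
                mk_hit("g2", 0, 50, 10, 60))
  out <- genomic_filter(hits, meta)
  expect_equal(out$subject_id, c("g1", "g2"))   # case-insensitive

  expect_equal(nrow(genomic_filter(empty_hits(), meta)), 0L)

  mrna <- rbind(mk_hit("m1", 0, 50, 10, 60))
  expect_warning(out2 <- genomic_filter(mrna, meta), "no genomic hits")
  expect_equal(nrow(out2), 0L)

  stray <- rbind(mk_hit("unknown", 0, 50, 10, 60))
  expect_warning(expect_warning(genomic_filter(stray, meta),
                                "without metadata"),
                 "no genomic hits")
})

test_that("hit extension projects unaligned flanks and clips at bounds", {
  subject <- random_dna(1000, seed = 21, id = "S")
  meta <- record_metadata(data.frame(id = "S", species = "sp",
                                     taxon = "7", biomol = "genomic"))
  be <- word_seed_backend(list(subject), meta)

  # + strand: hit covers query [100,300) of a 400-length query at
  # subject [400,600); 100 grown left and right -> subject [300,700)
  h <- mk_hit("S", 100, 300, 400, 600)
  cand <- extend_hit(h, 400L, be)
  expect_equal(cand$sequence$residues, subseq_residues(subject, 300, 700))
  expect_equal(nchar(cand$sequence$residues), 400L)

  # hit covering the full query: candidate equals the subject slice
  h2 <- mk_hit("S", 0, 400, 200, 600)
  expect_equal(extend_hit(h2, 400L, be)$sequence$residues,
               subseq_residues(subject, 200, 600))

  # left extension clipped at subject position 0
  h3 <- mk_hit("S", 50, 400, 0, 350)
  expect_equal(extend_hit(h3, 400L, be)$sequence$residues,
               subseq_residues(subject, 0, 350))

  # minus strand: flanks swap and the candidate is query-sense
  h4 <- mk_hit("S", 100, 300, 400, 600, strand = "-")
  cand4 <- extend_hit(h4, 400L, be)
  expect_equal(cand4$sequence$residues,
               revcomp(subseq_residues(subject, 300, 700)))
})

test_that("per-species dedupe keeps the single best hit", {
  meta <- record_metadata(data.frame(
    id = c("a1", "a2", "a3", "b1"),
    species = c("X", "X", "X", "Y"), biomol = "genomic"))
  hits <- rbind(mk_hit("a1", 0, 50, 0, 50, evalue = 1e-30, bitscore = 80),
                mk_hit("a2", 0, 50, 0, 50, evalue = 1e-10),
                mk_hit("a3", 0, 50, 0, 50, evalue = 1e-5),
                mk_hit("b1", 0, 50, 0, 50, evalue = 1e-3))
  out <- dedupe_best_per_species(hits, meta)
  expect_equal(out$subject_id, c("a1", "b1"))

  # distinct species: unchanged (up to E-value ordering)
  only <- hits[c(1, 4), ]
  expect_equal(nrow(dedupe_best_per_species(only, meta)), 2L)

  # E-value tie: higher bitscore wins
  tied <- rbind(mk_hit("a1", 0, 50, 0, 50, evalue = 1e-8, bitscore = 50),
                mk_hit("a2", 0, 50, 0, 50, evalue = 1e-8, bitscore = 90))
  expect_equal(dedupe_best_per_species(tied, meta)$subject_id, "a2")
})

test_that("iterative search stops after one round when 16+ are in band", {
  fam <- wide_family()
  be <- make_mock_backend(fam$records, fam$metadata)
  reps <- iterative_search(fam$root, be, run_config())
  log <- attr(reps, "search_log")
  expect_equal(attr(reps, "iterations_run"), 1L)
  expect_equal(nrow(log), 1L)
  expect_equal(log$word_size, 18L)
  expect_gte(log$representatives, 16L)
  # retained candidates respect the E-value cutoff
  expect_true(all(vapply(reps, function(x) x$evalue, numeric(1)) <= 0.01))
})

test_that("near-identical-only backends run all five iterations then fail", {
  fam <- cached("family_near", make_family(
    root_length = 600L, target_distances = c(1, 2, 3), seed = 13L))
  be <- make_mock_backend(fam$records, fam$metadata)
  reps <- iterative_search(fam$root, be, run_config())
  expect_equal(attr(reps, "iterations_run"), 5L)
  expect_length(reps, 0L)   # everything below the 10% band floor
  expect_error(select_final(reps),
               class = "codonscout_insufficient_homologs")
})

test_that("a homolog sharing only a 9-mer surfaces at word size <= 9", {
  query <- random_dna(200, seed = 31, id = "Q")
  # plant a 9-mer of the query into an otherwise alien (G/C-free vs A/T-rich
  # mix chosen to avoid longer chance blocks) background
  set.seed(32)
  bg <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
              collapse = "")
  subject <- nt_seq("S9", paste0(substr(bg, 1, 80),
                                 subseq_residues(query, 50, 59),
                                 substr(bg, 90, 200)))
  stopifnot(codonscout:::.lcs_cpp(query$residues, subject$residues)$length == 9,
            codonscout:::.lcs_cpp(query$residues,
                                  revcomp(subject$residues))$length < 9)
  meta <- record_metadata(data.frame(id = "S9", species = "sp", taxon = "5",
                                     biomol = "genomic"))
  be <- word_seed_backend(list(subject), meta)
  for (w in c(18L, 14L, 10L)) {
    expect_equal(nrow(be$search(query, w)), 0L)
  }
  expect_equal(nrow(be$search(query, 9L)), 1L)
  expect_equal(nrow(be$search(query, 8L)), 1L)
  # through the full iterative schedule: first appears in iteration 4
  reps <- iterative_search(query, be, run_config())
  log <- attr(reps, "search_log")
  expect_equal(log$hits, c(0L, 0L, 0L, 1L, 1L))
})

test_that("no discoverable homolog raises the no-homologs error", {
  query <- nt_seq("Q", strrep("A", 300))
  be <- word_seed_backend(
    list(nt_seq("S", strrep("C", 300))),
    record_metadata(data.frame(id = "S", biomol = "genomic")))
  expect_error(iterative_search(query, be, run_config()),
               class = "codonscout_no_homologs")
})

test_that("taxonomic restriction anchors on the iteration-1 best hit", {
  fam <- test_family()
  be <- make_mock_backend(fam$records, fam$metadata)
  # restricted search: only records of the anchoring order are returned
  best <- be$search(fam$root, 18L)$subject_id[1]
  anchor <- lineage_of(fam$metadata, best)
  hits_r <- be$search(fam$root, 7L,
                      taxon_restriction = list(rank = "order",
                                               value = anchor$order))
  orders <- fam$metadata[hits_r$subject_id, "order"]
  expect_true(all(orders == anchor$order))
  # a different kingdom is never returned under any restriction
  hits_k <- be$search(fam$root, 7L,
                      taxon_restriction = list(rank = "kingdom",
                                               value = "Archaea"))
  expect_equal(nrow(hits_k), 0L)
})

test_that("custom database caps sequences and expands targets 5x", {
  # many species, each sharing a clean 40-mer block with the query
  query <- random_dna(400, seed = 41, id = "Q")
  n <- 350L
  recs <- lapply(seq_len(n), function(i) {
    bg <- random_dna(900, seed = 500 + i, id = sprintf("T%03d", i))
    res <- bg$residues
    substr(res, 301, 340) <- subseq_residues(query, 180, 220)
    nt_seq(bg$id, res)
  })
  meta <- record_metadata(data.frame(
    id = vapply(recs, function(s) s$id, character(1)),
    species = sprintf("species_%03d", seq_len(n)),
    taxon = as.character(seq_len(n)), biomol = "genomic",
    kingdom = "Bacteria"))
  be <- word_seed_backend(recs, meta)
  db <- build_custom_db(query, be, run_config())
  expect_s3_class(db, "search_backend")
  expect_equal(db$kind, "custom")
  # up to 300 sequences retained
  expect_equal(nrow(db$metadata), 300L)
  # stored target length = 5 x query length, clipped to the 900 bp record
  expect_equal(db$subject_length(db$metadata$id[1]), 900L)

  # amply long subject: stored target is exactly 5 x query length
  long_rec <- random_dna(6000, seed = 999, id = "LONG")
  res <- long_rec$residues
  substr(res, 3001, 3040) <- subseq_residues(query, 180, 220)
  long_rec <- nt_seq("LONG", res)
  meta2 <- record_metadata(data.frame(id = "LONG", species = "solo",
                                      taxon = "1", biomol = "genomic"))
  db2 <- build_custom_db(query, word_seed_backend(list(long_rec), meta2),
                         run_config())
  expect_equal(db2$subject_length("LONG"), 2000L)

  # nothing retrievable
  empty_be <- word_seed_backend(
    list(nt_seq("S", strrep("C", 300))),
    record_metadata(data.frame(id = "S", biomol = "genomic")))
  expect_error(build_custom_db(nt_seq("Q", strrep("A", 300)), empty_be,
                               run_config()),
               class = "codonscout_customdb_empty")
})

test_that("the blast outfmt-6 dialect round-trips including minus strand", {
  hits <- rbind(mk_hit("s1", 10, 110, 200, 300, evalue = 1e-20),
                mk_hit("s2", 0, 90, 500, 590, strand = "-", evalue = 1e-8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(hits, path)
  raw <- read.table(path, sep = "\t")
  # minus-strand rows use the blast convention sstart > send (1-based)
  expect_equal(raw$V9[2], 590)
  expect_equal(raw$V10[2], 501)
  back <- read_hits_tsv(path)
  expect_equal(back$s_start, hits$s_start)
  expect_equal(back$s_end, hits$s_end)
  expect_equal(back$strand, hits$strand)
  expect_equal(back$q_start, hits$q_start)
})

test_that("the blastn adapter finds a planted homolog with sane coordinates", {
  query <- random_dna(300, seed = 51, id = "Q")
  bg <- random_dna(800, seed = 52, id = "S1")
  res <- bg$residues
  substr(res, 201, 500) <- query$residues
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(list(nt_seq("S1", res)), fa)
  meta <- record_metadata(data.frame(id = "S1", species = "sp", taxon = "9",
                                     biomol = "genomic"))
  be <- blast_backend(fa, meta)
  hits <- be$search(query, 18L)
  expect_gte(nrow(hits), 1L)
  h <- hits[1, ]
  expect_equal(h$subject_id, "S1")
  expect_equal(h$strand, "+")
  expect_equal(h$s_start, 200L)
  expect_equal(h$s_end, 500L)
  expect_equal(h$taxon, "9")
  # extension recovers the planted region verbatim
  cand <- extend_hit(h, 300L, be)
  expect_equal(cand$sequence$residues, query$residues)
})
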