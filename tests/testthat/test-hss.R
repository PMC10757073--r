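test_that("p-value filtering is strict, order-preserving and idempotent", {
  hss <- rbind(mk_hss(0, 30, p_value = 0.001),
               mk_hss(60, 90, p_value = 0.04),
               mk_hss(120, 150, p_value = 0.2))
  out <- filter_p(hss)
  expect_equal(out$p_value, c(0.001, 0.04))
  expect_identical(filter_p(out), out)
  expect_true(all(out$p_value < 0.05))
  expect_equal(nrow(filter_p(hss, cutoff = 1.0)), 3L)
  expect_equal(nrow(filter_p(empty_hss_table <- hss[0, ])), 0L)
})

test_that("shadow resolution keeps the best of overlapping conflicts", {
  # strong + strand HSS vs weaker overlapping - strand shadow
  pair <- rbind(mk_hss(100, 400, strand = "+", frame = 1, p_value = 1e-8),
                mk_hss(200, 350, strand = "-", frame = 0, p_value = 0.03))
  out <- resolve_shadows(pair)
  expect_equal(nrow(out), 1L)
  expect_equal(out$strand, "+")

  # disjoint opposite-strand HSS both survive
  disjoint <- rbind(mk_hss(0, 90, strand = "+", p_value = 1e-4),
                    mk_hss(300, 390, strand = "-", p_value = 1e-3))
  expect_equal(nrow(resolve_shadows(disjoint)), 2L)

  # three mutually overlapping frames: exactly one survives
  trio <- rbind(mk_hss(100, 200, frame = 0, p_value = 1e-6),
                mk_hss(110, 210, frame = 1, p_value = 1e-3),
                mk_hss(120, 220, frame = 2, p_value = 1e-2))
  out3 <- resolve_shadows(trio)
  expect_equal(nrow(out3), 1L)
  expect_equal(out3$frame, 0L)

  # same strand and frame is not a conflict
  same <- rbind(mk_hss(100, 200, frame = 1), mk_hss(150, 250, frame = 1))
  expect_equal(nrow(resolve_shadows(same)), 2L)
})

test_that("in-frame merging unions overlapping or abutting segments", {
  a <- rbind(mk_hss(100, 400, frame = 1, p_value = 1e-5, score = 30),
             mk_hss(250, 700, frame = 1, p_value = 1e-3, score = 45))
  m <- merge_in_frame(a, 1000L)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$q_start, m$q_end), c(100L, 700L))
  expect_equal(m$p_value, 1e-5)      # min of members
  expect_equal(m$score, 45)          # max of members
  expect_equal(m$length_aa, 200L)

  # same interval in different frames stays separate
  diff_frames <- rbind(mk_hss(99, 399, frame = 0), mk_hss(100, 400, frame = 1))
  expect_equal(nrow(merge_in_frame(diff_frames, 1000L)), 2L)

  # abutting in-frame segments merge; window contributors accumulate
  ab <- rbind(mk_hss(0, 300, frame = 0, window_index = "0"),
              mk_hss(300, 600, frame = 0, window_index = "1"))
  mab <- merge_in_frame(ab, 1000L)
  expect_equal(nrow(mab), 1L)
  expect_equal(mab$window_index, "0,1")

  # disjoint same-frame segments stay apart
  far <- rbind(mk_hss(0, 90, frame = 0), mk_hss(300, 390, frame = 0))
  expect_equal(nrow(merge_in_frame(far, 1000L)), 2L)
})

test_that("post-processing properties hold on fuzzed HSS sets", {
  qlen <- 3000L
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(1:12, 1)
    starts <- sample(0:(qlen - 200L), n, replace = TRUE)
    hss <- do.call(rbind, lapply(seq_len(n), function(i)
      mk_hss(starts[i], starts[i] + 3L * sample(10:60, 1),
             strand = sample(c("+", "-"), 1), frame = sample(0:2, 1),
             p_value = 10^runif(1, -8, 0), score = runif(1, 0, 80),
             window_index = as.character(sample(0:3, 1)))))

    m <- merge_in_frame(hss, qlen)
    # no two merged segments of equal strand/frame overlap
    if (nrow(m) > 1) {
      for (key in unique(paste(m$strand, m$frame))) {
        g <- m[paste(m$strand, m$frame) == key, ]
        if (nrow(g) > 1) {
          g <- g[order(g$q_start), ]
          expect_true(all(g$q_start[-1] > g$q_end[-nrow(g)]))
        }
      }
    }
    # merging never loses covered bases beyond codon-boundary trimming
    union_len <- function(df) {
      if (nrow(df) == 0) return(0L)
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(df$q_start + 1L, df$q_end))))
    }
    for (key in unique(paste(hss$strand, hss$frame))) {
      raw_g <- hss[paste(hss$strand, hss$frame) == key, ]
      m_g <- m[paste(m$strand, m$frame) == key, ]
      expect_gte(union_len(m_g), union_len(raw_g) - 4L * nrow(m_g))
    }
    # merged intervals are codon-sized
    expect_true(all((m$q_end - m$q_start) %% 3L == 0L))
    # merging is idempotent
    expect_equal(merge_in_frame(m, qlen)[c("q_start", "q_end")],
                 m[c("q_start", "q_end")])

    r <- resolve_shadows(m)
    # exclusivity: no overlapping pair differing in strand or frame remains
    if (nrow(r) > 1) {
      for (i in 1:(nrow(r) - 1)) for (j in (i + 1):nrow(r)) {
        over <- r$q_start[i] < r$q_end[j] && r$q_start[j] < r$q_end[i]
        differ <- r$strand[i] != r$strand[j] || r$frame[i] != r$frame[j]
        expect_false(over && differ)
      }
    }
    expect_identical(resolve_shadows(r), r)

    f <- filter_p(r)
    expect_identical(filter_p(f), f)
    expect_true(all(f$p_value < 0.05))
  }
})

test_that("translation follows the standard code on both strands", {
  q <- nt_seq("q", "ATGAAA")
  expect_equal(translate_hss(q, mk_hss(0, 6, strand = "+")), "MK")
  qm <- nt_seq("q", "TTTCAT")   # reverse complement is ATGAAA
  expect_equal(translate_hss(qm, mk_hss(0, 6, strand = "-")), "MK")

  # a 54-codon synthetic ORF translates to a 54-residue stop-free peptide
  orf <- random_orf(54, seed = 23)
  qo <- nt_seq("q", orf)
  aa <- translate_hss(qo, mk_hss(0, nchar(orf), strand = "+"))
  expect_equal(nchar(aa), 54L)
  expect_equal(substr(aa, 1, 1), "M")
  expect_false(grepl("*", aa, fixed = TRUE))

  # length must be an exact codon multiple
  expect_error(translate_hss(q, mk_hss(0, 5, strand = "+")),
               class = "codonscout_contract_error")

  # internal stops are rendered '*' with a warning
  qs <- nt_seq("q", "ATGTAAAAA")
  expect_warning(aa2 <- translate_hss(qs, mk_hss(0, 9, strand = "+")),
                 "stop")
  expect_equal(aa2, "M*K")
})

test_that("reports export to TSV/BED/GFF3/FASTA with exact conventions", {
  q <- random_dna(1000, seed = 61, id = "QX")
  res <- q$residues
  substr(res, 731, 820) <- random_orf(30, seed = 62)  # stop-free interval
  q <- nt_seq("QX", res)
  hss <- mk_hss(730, 820, strand = "+", frame = 730 %% 3L, p_value = 1e-4,
                score = 33.3)
  rep <- hss_report(hss, q, split_query(q, windowing_config()),
                    filters_applied = list(p_display_cutoff = 0.05))
  dir <- withr::local_tempdir()
  paths <- export_report(rep, dir)
  expect_true(all(file.exists(paths)))

  bed <- read.table(paths[["bed"]], sep = "\t")
  expect_equal(bed$V2, 730)          # BED is 0-based half-open
  expect_equal(bed$V3, 820)
  expect_equal(bed$V6, "+")
  expect_equal(bed$V5, 40)           # -10 log10(1e-4)

  gff <- read.table(paths[["gff3"]], sep = "\t")
  expect_equal(gff$V4, 731)          # GFF3 is 1-based inclusive
  expect_equal(gff$V5, 820)
  expect_equal(gff$V2, "codonscout")
  expect_equal(gff$V3, "CDS_region")
  # converting between the two conventions is lossless
  expect_equal(gff$V4 - 1L, bed$V2)
  expect_equal(gff$V5, bed$V3)

  prot_lines <- readLines(paths[["fasta"]])
  expect_length(prot_lines, 2L)        # one header + one 30-residue line
  expect_equal(nchar(prot_lines[2]), 30L)
  expect_equal(substr(prot_lines[2], 1, 1), "M")

  back <- read_hss_tsv(paths[["tsv"]])
  expect_equal(back$q_start, hss$q_start)
  expect_equal(back$q_end, hss$q_end)
  expect_equal(back$p_value, hss$p_value)

  # zero-HSS reports still produce valid, empty-bodied files
  rep0 <- hss_report(hss[0, ], q, split_query(q, windowing_config()),
                     filters_applied = list())
  dir0 <- withr::local_tempdir()
  p0 <- export_report(rep0, dir0)
  expect_true(all(file.exists(p0)))
  expect_equal(nrow(read_hss_tsv(p0[["tsv"]])), 0L)
  expect_equal(length(readLines(p0[["bed"]])), 0L)
})
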