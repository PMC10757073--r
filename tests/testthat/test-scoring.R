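make_window <- function(residues, index = 0L, q_start = 0L) {
  codonscout:::new_sub_query(index, q_start, q_start + nchar(residues),
                             residues)
}

test_that("MSA construction validates the block invariants", {
  w <- make_window(strrep("ACGT", 25))
  homs <- list(nt_seq("h1", w$residues), nt_seq("h2", w$residues))
  msa <- build_msa(w, homs)
  expect_s3_class(msa, "msa_block")
  expect_length(msa$rows, 3L)
  expect_equal(names(msa$rows)[1], "query")
  expect_false(any(grepl("-", msa$rows, fixed = TRUE)))

  # fewer than 2 homologs
  expect_error(build_msa(w, homs[1]), class = "codonscout_scoring_error")

  # an aligner returning unequal row lengths violates the invariants
  broken <- function(seqs) { seqs[2] <- paste0(seqs[2], "ACGT"); seqs }
  expect_error(build_msa(w, homs, aligner = broken),
               class = "codonscout_scoring_error")

  # an aligner dropping the query row is an adapter failure
  lossy <- function(seqs) setNames(seqs, c("x", "h1", "h2"))
  expect_error(build_msa(w, homs, aligner = lossy),
               class = "codonscout_scoring_error")
})

test_that("a real external aligner satisfies the block contract", {
  # equal-length substitution-only homologs align gap-free; the ungapped
  # reference row must equal the window residues
  fam <- test_family()
  w <- make_window(fam$root$residues)
  homs <- lapply(fam$records[1:3], identity)
  msa <- build_msa(w, homs, aligner = cmd_aligner("mafft"))
  expect_equal(gsub("-", "", msa$rows[[1]], fixed = TRUE), w$residues)
  expect_length(msa$rows, 4L)
})

test_that("the tabular parser reads the 11-column dialect exactly", {
  expect_equal(nrow(parse_scorer_tabular("")), 0L)

  line <- "1\t+\t2\t48\t12\t155\tquery\t12\t155\t61.47\t0.0004"
  hss <- parse_scorer_tabular(line)
  expect_equal(nrow(hss), 1L)
  expect_equal(hss$strand, "+")
  expect_equal(hss$frame, 1L)          # file frame 2 -> 0-based 1
  expect_equal(hss$length_aa, 48L)
  expect_equal(hss$start, 11L)         # 1-based 12 -> 0-based 11
  expect_equal(hss$end, 155L)
  expect_equal(hss$p_value, 4e-4)
  expect_equal(hss$score, 61.47)

  two <- paste0(line, "\n2\t-\t1\t30\t200\t290\tquery\t200\t290\t20.1\t0.01")
  both <- parse_scorer_tabular(two)
  expect_equal(both$strand, c("+", "-"))

  # malformed lines name the line number
  expect_error(parse_scorer_tabular("1\t+\t2\tnope"),
               class = "codonscout_parse_error")
  err <- expect_error(
    parse_scorer_tabular(paste0(line, "\nbad\tline")),
    class = "codonscout_parse_error")
  expect_match(conditionMessage(err), "line 2")

  # out-of-range p-value is a validation error
  bad_p <- "1\t+\t1\t10\t1\t30\tq\t1\t30\t5.0\t1.5"
  expect_error(parse_scorer_tabular(bad_p), class = "codonscout_parse_error")
})

test_that("parse and serialize are mutually inverse", {
  set.seed(17)
  for (k in 1:100) {
    n <- sample(0:5, 1)
    if (n == 0) {
      expect_equal(nrow(parse_scorer_tabular(make_scorer_fixture(
        data.frame()[0, ]))), 0L)
      next
    }
    starts <- sort(sample(0:800, n))
    spec <- data.frame(
      strand = sample(c("+", "-"), n, replace = TRUE),
      frame = sample(0:2, n, replace = TRUE),
      start = starts,
      end = starts + 3L * sample(5:60, n, replace = TRUE),
      score = round(runif(n, -5, 80), 2),
      p_value = signif(10^runif(n, -8, 0), 3))
    text <- make_scorer_fixture(spec)
    parsed <- parse_scorer_tabular(text)
    expect_equal(parsed$strand, spec$strand)
    expect_equal(parsed$frame, spec$frame)
    expect_equal(parsed$start, spec$start)
    expect_equal(parsed$end, spec$end)
    expect_equal(parsed$score, spec$score)
    expect_equal(parsed$p_value, spec$p_value)
    # full round trip through the serializer is the identity
    expect_identical(parse_scorer_tabular(serialize_scorer_tabular(parsed)),
                     parsed)
  }
})

test_that("window scoring maps coordinates and normalises frames", {
  q <- random_dna(2500, 19)
  w <- split_query(q, windowing_config())[[2]]    # [700,1700)
  msa <- build_msa(w, list(nt_seq("h1", w$residues),
                           nt_seq("h2", w$residues)))

  # stub emitting nothing: empty result, not an error
  expect_equal(nrow(score_window(msa, stub_scorer(), 2500L)), 0L)

  fx <- make_scorer_fixture(data.frame(strand = "+", frame = 0L, start = 30L,
                                       end = 120L, score = 12, p_value = 0.02))
  hss <- score_window(msa, stub_scorer(fx), 2500L)
  expect_equal(hss$q_start, 730L)
  expect_equal(hss$q_end, 820L)
  expect_equal(hss$frame, 730L %% 3L)
  expect_equal(hss$window_index, "1")

  # minus strand frame anchors at the query 3' end
  fxm <- make_scorer_fixture(data.frame(strand = "-", frame = 0L, start = 30L,
                                        end = 120L, score = 12,
                                        p_value = 0.02))
  hssm <- score_window(msa, stub_scorer(fxm), 2500L)
  expect_equal(hssm$frame, (2500L - 820L) %% 3L)

  # an HSS beyond the window end is a contract violation
  fx_out <- make_scorer_fixture(data.frame(strand = "+", frame = 0L,
                                           start = 900L, end = 1200L,
                                           score = 5, p_value = 0.01))
  expect_error(score_window(msa, stub_scorer(fx_out), 2500L),
               class = "codonscout_scoring_error")
})

test_that("scoring is a pure function of its inputs", {
  fam <- test_family()
  w <- make_window(fam$root$residues)
  homs <- lapply(fam$records[1:4], identity)
  fx <- make_scorer_fixture(data.frame(strand = "+", frame = 0L, start = 120L,
                                       end = 282L, score = 55, p_value = 1e-4))
  r1 <- score_window(build_msa(w, homs), stub_scorer(fx), 600L)
  r2 <- score_window(build_msa(w, homs), stub_scorer(fx), 600L)
  expect_identical(r1, r2)
})
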