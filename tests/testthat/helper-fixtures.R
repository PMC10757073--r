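# Shared synthetic fixtures, built once per test run and cached (family
# generation measures distances repeatedly, so reuse keeps the suite fast).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# mid-size family: 600 bp root with an embedded 54-codon ORF at 120,
# 12 in-band homologs plus one near-identical (distance 2, out of band)
test_family <- function() {
  cached("family600", make_family(
    root_length = 600L,
    target_distances = c(12, 18, 25, 32, 15, 22, 28, 35, 38, 40, 20, 30, 2),
    seed = 5L, coding = c(120L, 54L)))
}

test_backend <- function() {
  cached("backend600", {
    fam <- test_family()
    make_mock_backend(fam$records, fam$metadata)
  })
}

# large family for the early-stop behaviour: 18 in-band homologs, all at
# modest divergence so every one is discoverable already at word size 18
wide_family <- function() {
  cached("family_wide", make_family(
    root_length = 600L, target_distances = seq(10.5, 19, by = 0.5), seed = 9L))
}

# long-query family: 2500 bp root with a 99-codon ORF spanning the
# window-0/window-1 overlap zone, 8 in-band homologs
long_family <- function() {
  cached("family2500", make_family(
    root_length = 2500L,
    target_distances = c(12, 15, 18, 20, 22, 25, 28, 30), seed = 11L,
    coding = c(801L, 99L)))
}

# candidates with injected ids/evalues/distances; sequences are distinct
# placeholders (clustering tests inject a distance matrix instead)
dummy_cands <- function(n, evalues = seq_len(n), dists = rep(30, n),
                        ids = sprintf("C%02d", seq_len(n))) {
  lapply(seq_len(n), function(i)
    candidate(nt_seq(ids[i], strrep(substr("ACGTACGTAC", i %% 10 + 1,
                                           i %% 10 + 1), 12L)),
              evalue = evalues[i], dist_to_query = dists[i],
              species = paste("sp", i)))
}

# random symmetric percent-distance matrix for clustering property tests
random_dist_matrix <- function(n, seed) {
  set.seed(seed)
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0, 40)
  D + t(D)
}

# one hit row in the internal schema
mk_hit <- function(subject_id, q_start, q_end, s_start, s_end, strand = "+",
                   evalue = 1e-10, bitscore = 100, taxon = "1",
                   query_id = "Q", identity = 95) {
  data.frame(query_id = query_id, subject_id = subject_id,
             q_start = as.integer(q_start), q_end = as.integer(q_end),
             s_start = as.integer(s_start), s_end = as.integer(s_end),
             strand = strand, evalue = evalue, identity = identity,
             bitscore = bitscore, taxon = taxon, stringsAsFactors = FALSE)
}

# HSS table row(s) in query coordinates
mk_hss <- function(q_start, q_end, strand = "+", frame = q_start %% 3L,
                   p_value = 0.01, score = 10, window_index = "0",
                   length_aa = (q_end - q_start) %/% 3L) {
  data.frame(window_index = as.character(window_index), strand = strand,
             frame = as.integer(frame), q_start = as.integer(q_start),
             q_end = as.integer(q_end), length_aa = as.integer(length_aa),
             score = score, p_value = p_value, stringsAsFactors = FALSE)
}
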