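# codonscout

Comparative detection of protein-coding regions from a **single nucleotide
query**, offline and reproducible.

Alignment-based coding-sequence detectors are far more accurate than
single-sequence methods on short coding regions — small peptides (sORFs),
overlooked exons — but they need a multiple sequence alignment of suitably
divergent homologs as input, and building that alignment by hand (BLAST
searches, hit curation, re-retrieval, alignment, post-processing) is tedious.
`codonscout` automates the whole pre- and post-processing pipeline around an
external coding-potential scorer:

1. **Retrieval** — iterative blastn-style homology search over a pluggable
   backend. Five iterations trade specificity for sensitivity, shrinking the
   seed word size (18, 14, 10, 8, 7) while widening the taxonomic scope
   (unrestricted, then the order/class/phylum/kingdom of the best first-round
   hit). Hits on non-genomic records are discarded, and every hit is extended
   to the full query length by linear projection of the unaligned flanks.
2. **Selection** — pairwise similarity is measured with a Smith–Waterman
   local alignment (match +1, mismatch −1, gap open = extend −1) as
   *s* = matches / length of the shorter sequence, and the percent distance
   is 100(1 − *s*). Candidates outside the configurable divergence band
   (default 10–60 %) are dropped; a DBSCAN-like density clustering
   (`reduce_cand_min_dist()`) thins near-duplicates until all survivors are
   ≥ 10 % apart; the final 2–16 sequences are taken in order of increasing
   E-value.
3. **Scoring** — the selected set is aligned (Clustal Omega/mafft adapter, or
   a deterministic stub) and scored by a coding-potential scorer adapter
   (RNAcode-style tabular output; stub and fixture support for offline
   runs). Reported **high-scoring segments (HSS)** carry strand, reading
   frame, score and p-value.
4. **Post-processing** — overlapping in-frame HSS are merged (fragments of
   one coding region seen from adjacent windows), opposite-strand/frame
   "shadow" artifacts are resolved in favour of the most significant
   segment, segments with p ≥ 0.05 are filtered, and predictions are
   exported as TSV, BED6, GFF3 and translated protein FASTA.

Queries longer than 1000 bp take a **long-query path**: a temporary custom
database is built (best hit per species, ≤ 300 sequences, each expanded to
5× the query length around the hit), the query is split into overlapping
1000-bp windows (300-bp overlap, final window end-anchored), and each window
is searched, aligned and scored independently before results are mapped back
to query coordinates and combined.

A synthetic-data module (`make_family()`, `make_mock_backend()`) generates
homolog families at controlled percent divergences with 4-rank lineages and
a mock backend whose discoverability follows exact shared-word length, so the
entire pipeline runs and is tested without network access or external
binaries.

## Worked example

A 600-bp synthetic query with a 54-codon ORF embedded at position 120, a
mock backend of 13 homologs (12 inside the 10–60 % band), and a canned
scorer reporting the ORF, an opposite-strand shadow (p = 0.03) and a weak
segment (p = 0.2):

```r
library(codonscout)

fam <- make_family(root_length = 600,
                   target_distances = c(12, 18, 25, 32, 15, 22, 28,
                                        35, 38, 40, 20, 30, 2),
                   seed = 5, coding = c(120, 54))
backend <- make_mock_backend(fam$records, fam$metadata)
scorer <- stub_scorer(make_scorer_fixture(
  data.frame(strand = "+", frame = 0, start = 120, end = 282,
             score = 61.2, p_value = 2e-4)))

report <- run_pipeline(fam$root, backend, run_config(), scorer = scorer)
report
#> <hss_report> query QUERY (600 nt), 1 window(s), 1 HSS
#>   window_index strand frame q_start q_end length_aa score p_value
#> 1            0      +     0     120   282        54  61.2   2e-04

translate_hss(report$query, report$hss[1, ])
#> [1] "MHLQLSDGDLLLYRRLIRLSASTYVPYSRRLHTLHGFQGELTIPRAVVHLPVGW"
```

The single retained prediction is the embedded ORF: the shadow and the weak
segment are removed by the post-processing, and the 162-bp interval
translates to the expected 54-residue peptide. `run_config(out_dir = ...)`
additionally writes `hss.tsv`, `hss.bed`, `hss.gff3`, `proteins.fa`,
`summary.yaml` and `windows.tsv`.

A shell entry point wrapping the same functions ships in
`inst/cli/codonscout.R`:

```sh
Rscript inst/cli/codonscout.R run --query q.fa --db records.fa \
    --meta meta.tsv --backend mock --out outdir
Rscript inst/cli/codonscout.R fixtures --out fixtures --seed 1
```

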