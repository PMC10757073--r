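---
title: "codonscout: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{codonscout: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the procedure

Evolutionarily conserved coding sequence leaves a characteristic substitution
signature — synonymous third-position changes, conservative amino-acid
replacements, absence of in-frame stops — that alignment-based detectors
exploit far more effectively than single-sequence models, especially for
short open reading frames. The bottleneck is the input: a multiple sequence
alignment of homologs that are divergent enough to be informative yet similar
enough to align reliably.

`codonscout` automates the construction of that input and the interpretation
of the scorer's output for a single nucleotide query. The pipeline has three
stages — homolog retrieval/selection, alignment, scoring — followed by
post-processing of the reported high-scoring segments (HSS). The
coding-potential statistic itself is deliberately external: the scorer is an
adapter (RNAcode-style tabular output), because re-deriving a
phylogeny-aware coding statistic is a different project. What this package
contributes is everything around it: the iterative retrieval schedule, the
diversity-constrained selection, windowing of long queries, and the HSS
algebra (merge, shadow resolution, filtering, export).

## The pairwise metric

Similarity between two sequences is computed from a Smith–Waterman local
alignment under a linear gap model (match +1, mismatch −1, gap open = gap
extend −1) as

$$ s = \frac{\text{matches}}{\min(|a|, |b|)}, \qquad d = 100\,(1 - s)\,\%. $$

Two numerical choices make this metric well-behaved:

* **Match-count tie-break.** Co-optimal local alignments can differ in their
  number of matched pairs, and the match count of an arbitrary optimum is not
  symmetric in the inputs. The aligner therefore selects, among
  score-optimal alignments, one with the *maximum* match count (a quantity
  that is invariant under swapping the inputs), then the lowest end
  coordinate in the first and second sequence. This makes $d$ symmetric and
  runs fully deterministic.
* **`N` handling.** `N` scores as a mismatch against everything, including
  `N`; masked or ambiguous positions can therefore only lower similarity,
  never inflate it.

**Saturation.** Because gaps are cheap (−1 per column), two *unrelated*
sequences still align many spurious matches: empirically $d$ saturates near
40 % for 1-kb pairs and ~47 % for 500-bp pairs. Distances beyond that
background are unreachable for substitution-only divergence at these
lengths. Practical consequences: the upper band bound (60 %) rarely excludes
anything at ≥ 500 bp, and the synthetic generator can hit targets within
±3 points only below saturation (its accuracy tests use targets ≤ 40 %).
This is a property of the published matches-over-shorter-length metric, not
of the implementation.

## Retrieval

The search backend is a narrow contract (word size, E-value cutoff, maximum
hits, taxonomic restriction in; tabular hits and subject slices out) with
three implementations: a local blastn wrapper, an in-process exact
shared-word index, and the same index over synthetic records as the mock
backend used in tests.

Retrieval iterates up to five times with word sizes 18, 14, 10, 8, 7
(14, 11, 9, 8, 7 when building the custom database, where sensitivity
matters more). Iteration 1 is unrestricted; its best hit anchors the lineage
used to restrict iterations 2–5 to the matching order, class, phylum and
kingdom. If iteration 1 returns nothing, later iterations stay unrestricted
— the anchoring assumes a best hit exists, and an unrestricted search is the
conservative fallback. After each iteration hits are genomic-filtered (for
`nt`-kind backends, which mix transcript and genomic records), extended,
distance-annotated, band-filtered and clustered; iteration stops early once
the representative pool reaches the selection maximum (16). Running further
iterations could only add more-distant material that selection would
discard.

Hit extension is a gap-free linear projection of the unaligned query flanks
beyond the hit on the subject, clipped at the subject bounds — a cheap
coordinate estimate, not a re-alignment, which is sufficient because the
subsequent aligner sees the full extended sequences.

## Selection

The divergence band (default 10–60 %, both ends inclusive — "minimal and
maximal distance" reads naturally as a closed interval) is applied before
clustering, matching the order of the retrieval description. Clustering then
enforces the *minimum pairwise* distance among the survivors: repeatedly,
a candidate whose neighbourhood (itself plus all unclustered candidates
closer than the threshold) is a singleton becomes its own representative;
otherwise the neighbourhood member with the largest own neighbourhood
becomes the centroid and the rest of its neighbourhood is deleted. Ties on
neighbourhood size keep the incumbent, i.e. the earliest candidate in
E-value order, favouring homologs closer to the query. The loop marks both
centroids and deleted members as clustered, which guarantees termination.
Survivors are pairwise ≥ threshold apart; the reduction is idempotent and a
subset of its input.

The final input set takes the 2–16 representatives with the smallest
E-values (ties: smaller distance to the query, then id). Fewer than 2
representatives is an error: a pairwise "alignment" carries no comparative
signal.

## Windowing

Queries strictly longer than 1000 bp are split into 1000-bp windows placed
every 700 bp, with the final window anchored at the query end. The defaults
embody three choices:

* **Overlap 300 bp, a multiple of 3.** The overlap must be long enough for
  the scorer to re-detect an HSS that crosses a window boundary, and
  divisibility by 3 keeps the codon phase of the shared zone identical in
  both windows, so the two detections merge as one in-frame prediction.
* **Long-query threshold = chunk length.** Splitting happens exactly when
  more than one chunk would exist.
* **End-anchored final window** rather than a short tail: coding-potential
  scorers lose statistical power on short blocks, so the last window keeps
  the full length at the cost of extra overlap.

Frames are normalised to query space — `q_start mod 3` on the plus strand,
`(query_length − q_end) mod 3` on the minus strand — so that segments from
different windows are comparable.

## Scoring adapters and the tabular dialect

Aligner and scorer are subprocess adapters behind one-function contracts;
deterministic stubs ship with the package and are the defaults in tests (the
stub aligner returns substitution-only families unchanged, which is their
true alignment). The scorer dialect is 11 tab-separated fields per HSS
(id, strand, frame 1–3, amino-acid length, alignment coordinates, reference
name, 1-based inclusive reference coordinates, score, p-value), frozen in
fixtures with a parser/serializer pair that round-trips exactly. A p-value
outside (0, 1], coordinates outside the window, or a malformed line are hard
errors naming the line.

## HSS post-processing

The order is **merge → shadow resolution → p-filter**, fixed so that
fragments of one coding region split across windows are judged once, as a
single prediction:

* **Merge:** overlapping-or-abutting segments with equal strand and equal
  query frame are unioned; the merged p-value is the minimum of the members
  and the score the maximum. The scorer cannot be re-run on merged spans
  without re-alignment, so the minimum is an explicit approximation. The
  merged interval is trimmed to the codon grid anchored at the lowest-p
  member.
* **Shadows:** genuine coding regions induce weaker but still significant
  segments on the opposite strand or frame (a consequence of the genetic
  code's structure). Among overlapping segments differing in strand or
  frame, the lowest-p (ties: higher score, then leftmost) survives and
  suppresses the rest.
* **Filter:** segments with p ≥ 0.05 are dropped. No multiple-testing
  correction is applied; p-values are reported as produced and 0.05 is a
  display cutoff.

Exports are byte-deterministic: TSV (0-based half-open, re-ingestable),
BED6 (score `min(1000, round(−10 log10 p))`), GFF3 (1-based, source
`codonscout`, type `CDS_region`), translated protein FASTA, and a YAML run
summary echoing the full effective configuration and per-stage counts.

## Long-query path

A temporary custom database is built once per query: the build-db word-size
schedule collects hits, only the best hit per species is kept (no
similarity-based selection at this stage), at most 300 sequences are
retained in E-value order, and each stored target is centred on the hit
midpoint and expanded to 5× the query length — slack for large intron-length
differences, distributed symmetrically because nothing favours either side.
Each window is then searched once against this database at the iteration-1
word size (the database is small, so no iterative widening is needed), and
windows proceed independently: a window that fails (no hits, too few
homologs, scorer failure, malformed scorer output) is skipped with a
warning, because the remaining windows are still informative. Only if every
window fails does the run abort.

## The synthetic-data module

`make_family()` emulates exactly what the pipeline consumes: a root sequence
(optionally with an embedded ORF), homologs produced by uniform random
substitution until the *measured* pairwise distance first reaches a target,
species labels and 4-rank lineages spread across the orders/classes/phyla of
one kingdom, and per-record biomolecule labels. Substitutions inside a
declared ORF are biased towards third codon positions and never create
in-frame stops, giving the synonymous-leaning signature of real coding
divergence. The generator measures distance after every substitution near
the target (batching estimates further out) and reverts steps that overshoot
by more than 2.5 points, since a single substitution at the local-alignment
boundary can truncate the alignment tail and jump the measured distance.

The mock backend returns a hit for a subject exactly when query and subject
share a substring at least as long as the word size (either strand,
computed exactly), mirroring blastn seed sensitivity; its E-value is
$L_\mathrm{query} \cdot 4^{-\ell}$ for shared-block length $\ell$ (the
random-expectation rate for a quarter alphabet, clipped below at 1e-180) —
monotone in $\ell$, so hit ordering is meaningful, and compatible with the
0.01 cutoff for the block lengths the schedule can discover.

What the generator does *not* model: insertions/deletions (indel robustness
is exercised by hand-built fixtures instead; substitution-only divergence
keeps the measured distance analytically predictable), rate heterogeneity,
codon-model evolution, and database-scale redundancy. Passing tests
therefore demonstrate the pipeline's mechanics — retrieval schedules,
selection guarantees, coordinate algebra, determinism — not the biological
accuracy of the external scorer on real alignments.

## Problem sizes and runtime choices

The test suite and the acceptance script run on desk-scale problems chosen
to exercise every code path while keeping a full run in minutes on one CPU:
600-bp queries with 13–18 homologs for the short path, a 2500-bp query
(4 windows) for the long path, 350 mock species for the custom-database cap,
exhaustive alignment-oracle checks over all {A,C} pairs of length ≤ 5 plus
300 seeded random pairs up to length 12, 200 random pools for the clustering
guarantees, 500 random lengths for the windowing invariants, and ~100 fuzzed
HSS sets for the post-processing algebra.

## Known limitations

* The percent-distance metric saturates near the random background
  (see above); very distant homologs are indistinguishable from noise under
  it, and the 60 % band ceiling is mostly nominal at ≥ 500 bp.
* Merged-HSS p-values are approximations (minimum of members).
* The scorer tabular dialect is frozen from fixtures; a pinned scorer binary
  should be used to re-verify the column layout when one is available.
* Hit extension is a linear projection; subjects with large indels relative
  to the query may receive shifted flanks (the aligner absorbs moderate
  shifts).
* Taxonomic restriction relies on the completeness of the metadata table;
  records with unknown lineage are excluded from restricted iterations.
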