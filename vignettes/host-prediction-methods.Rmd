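---
title: "CRISPR spacer-based phage host prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CRISPR spacer-based phage host prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological signal

CRISPR–Cas systems store fragments of past invaders as *spacers* between
the repeats of a CRISPR array. A spacer is a near-exact copy of a region
of a phage genome (the *protospacer*), so finding a stored spacer that
aligns to an unknown phage genome links that phage to the bacterium
carrying the array. Two features of array biology carry extra
information beyond mere homology:

* **Mismatch count as a clock.** Mutations accumulate in the phage after
  the spacer was acquired, so fewer spacer–protospacer mismatches
  suggest a more recent (and more credible) phage–host interaction.
* **Leader proximity as a clock.** New spacers are inserted at the 5'
  (leader) end of the array; a match involving a leader-proximal spacer
  likewise reflects a more recent interaction.

The practical obstacle is database bias: heavily sequenced genera
contribute enormous numbers of near-identical spacers, so picking "the
organism with the most hits" mostly rewards sequencing effort. `spacerhost`
implements a decision cascade designed around these observations.

## The decision cascade

For one phage, all spacer hits are collected and four filters run in
sequence; the cascade stops as soon as a single candidate genus remains.

1. **Alignment quality.** Hits with more than `cutoff` *corrected*
   mismatches are dropped, and only hits at the minimum surviving
   mismatch count are kept. The corrected count penalizes unaligned
   spacer tails as if they were mismatches:
   `spacer_length - aligned_length + reported_mismatches`. Hits with gap
   openings are discarded outright, because an ungapped mismatch count
   is not meaningful for them. The built-in scanner only emits
   full-length ungapped placements, for which the corrected count *is*
   the Hamming distance; partial alignments only arise when ingesting
   external 12-column alignment tables.
2. **Distinct targeted regions.** Genera whose spacers target the most
   distinct `(start, end)` intervals on the phage genome survive. A
   genus hitting five different regions is a better host candidate than
   one hitting a single region many times — the redundancy-bias failure
   mode. Intervals are compared exactly, without merging overlaps, and
   strand is ignored; identical intervals hit on both strands count
   once.
3. **5' (leader) proximity.** Each genus is scored by the minimum
   *relative position* of its matching spacers,
   `(position - 1) / (locus_length - 1)` (0 for a single-spacer locus,
   whose lone spacer is trivially the newest). Genera attaining the
   global minimum survive.
4. **Lowest common ancestor.** If several genera still tie, the
   prediction is their LCA, reported at the LCA's own rank. This is a
   safety net: a family- or order-level answer is still useful, and the
   evaluator penalizes the lost specificity. If the LCA is the root the
   prediction is flagged low-confidence rather than suppressed.

An E-value criterion can replace the mismatch criterion in filter 1
(for hits ingested from an external aligner which computes E-values),
but the mismatch count is the default: it does not depend on database
or query size and has a direct biological reading.

The filter order is fixed at 1 → 2 → 3 → 4. The quality filter must run
first — the region and recency signals are meaningless on uncurated
hits — and the LCA is by construction a fallback. The engine accepts
either ordering of filters 2 and 3 (`filter_order`), which is what
`filter_order_search()` sweeps.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `cutoff` | 2 mismatches | Filter-1 tolerance. 0 is the most precise but least sensitive; 2 tolerates sequencing error and recent mutation without giving up much precision. |
| `criterion` | `"mismatch"` | `"evalue"` switches filter 1 to an E-value cutoff (external hits only). |
| spacer export window | 23–48 nt | Lengths admitted to the prediction FASTA/scan. The store keeps all lengths. |
| plausibility band | 28–43 nt | The band containing ~99% of real spacer lengths; available as the `plausible` preset. Lengths outside it are usually boundary-calling artifacts of the upstream array detector. |
| `filter_order` | `c(2, 3)` | Order of the two tie-breaking filters. |
| rank vocabulary | superkingdom … species | Used for rank-depth comparisons; "no rank" nodes are transparent (they report the nearest ranked ancestor, flagged). |

## Evaluation semantics

*Recall* is the fraction of phages that receive any prediction.
*Precision at rank r* is computed over predicted phages only: a
prediction is accurate at rank *r* when the LCA of the predicted taxon
and the true host genus has rank *r* or deeper. Under this nesting,
precision at family can never be below precision at genus, and a
filter-4 family-level prediction counts as correct at family and order
but wrong at genus.

The *null model* asks what a naive predictor achieves: per phage, one
hit is drawn uniformly at random and its genus taken as the host;
success means matching the true genus. The draw can be conditioned on
the raw hit set or on the survivors of filter 1 or 2, which isolates
the marginal value of each later filter. Success rates over `n_sims`
simulations (default 1000) give an empirical distribution; the cascade
is compared to it with a +1-smoothed empirical p-value,
`(1 + #{rate >= precision}) / (n_sims + 1)`, so a p-value is never
exactly zero.

Phages with no hits at the conditioning stage are excluded from the
null model's denominator and reported; whether to count them is
genuinely ambiguous, and excluding them is the conservative choice
(it can only flatter the null, never the cascade).

## Numerical and representational choices

* **Coordinates** are 1-based inclusive throughout, matching GFF.
* **Leader re-indexing.** Spacer indices in the GFF `ID` attribute run
  in genome-coordinate order; for arrays annotated on the `-` strand
  the leader sits at the genome-distal end, so positions are re-indexed
  (`count - index + 1`) to make position 1 always leader-proximal.
  Filter 3 depends on this invariant.
* **Exact tie comparison in filter 3.** Relative positions are
  rationals `(p-1)/(L-1)`; comparing them as doubles could split a
  genuine tie such as 3/9 vs 2/6. Comparisons use integer cross
  products, which are exact.
* **N handling.** An `N` on either side of an alignment column is
  always a mismatch — conservative, since `N` asserts no base identity.
* **Palindromic spacers** (equal to their reverse complement) would
  report every placement twice, once per strand; the scanner reports
  such placements once, on the plus strand.
* **Seed-accelerated scanning.** The scanner enumerates candidates
  either directly (`Biostrings::matchPattern`) or, when spacers are
  long enough relative to `k`, via `k + 1` disjoint exact seeds
  (pigeonhole: a placement with ≤ k mismatches must match one seed
  exactly) matched in one `matchPDict` pass per genome. Every candidate
  is then verified by a full Hamming recount, so the accelerator cannot
  change the reported hit set; the test suite checks equality against a
  brute-force sliding-window oracle over both strands.
* **Store backend.** The spacer store is a set of in-memory relational
  tables (spacers, loci, organisms) with a documented CSV dump/load
  format. Queries the cascade needs (by genus, by length window) are
  data-frame subsets.
* **Atomic outputs.** CLI artifacts are written to a temporary path and
  renamed, so interrupted runs never leave half-written files.

## The synthetic benchmark

Real-scale evaluation of this method needs the full public spacer
corpus and thousands of reference phages; a package must be testable
without downloads. The generator (`sim_config()`, `simulate_dataset()`)
builds a complete miniature study: a balanced taxonomy (default 5
orders × 2 families × 5 genera = 50 genera), one organism per genus
with 2 CRISPR loci of 8 spacers, spacer lengths uniform on 28–43 nt,
and 20 phages of 20–60 kb of i.i.d. uniform background sequence. For
each phage, 3 protospacers (4 in the redundancy scenario) are copied
into its true host's arrays — optionally mutated, on either strand —
and every planted copy is recorded in a ledger that doubles as a
complete oracle for the expected hit set. At these lengths the chance
of a spurious ≤ 2-mismatch background match is negligible
(≪ 10⁻⁶ per window), which is what makes exact oracle tests possible.

Three decoy presets mirror failure modes observed on real data:

* `redundancy` — a dedicated decoy genus holds 12 identical copies of
  one of the phage's protospacers (the heavily-resequenced-genus
  effect). Filter 1 ties; filter 2 must decide. The decoy dominates
  the hit pool, so the random-host null collapses (~25% mean success)
  while the cascade stays at 100%.
* `recency` — a sibling genus (same family) matches the same number of
  regions but only via leader-distal spacers. Filters 1–2 tie; filter 3
  must decide.
* `sibling` — a sibling genus with an identical match profile.
  Filters 1–3 tie; filter 4 names the shared family.

The generator is a pure function of its config (seed included): the
same config yields byte-identical files.

**What the generator does not emulate:** real phage genome architecture
and composition biases, array turnover over time, partial or gapped
protospacer matches, mis-annotated arrays, and taxonomies with merged
or synonymous ids. Passing the synthetic benchmark therefore
demonstrates that the machinery is correct under the model's
assumptions — not that real-data precision will match the synthetic
numbers, which depend on corpus coverage and redundancy structure.

## Problem sizes in the test and acceptance runs

The default study conditions above (50 genera / 20 phages / 20–60 kb)
are used for the end-to-end scenario checks and the acceptance script.
The cutoff-sweep checks use a smaller instance (3 orders, 6 phages of
8–12 kb, 1 mutation per planted spacer) because the 0..10 mismatch grid
forces the scanner onto its direct path; the sweep's properties
(monotone recall, nested precision) do not depend on scale. Oracle
comparisons run on ~100–200 random instances with genomes of a few
hundred bases, where the brute-force reference is exact and fast.

## Known limitations

* Prediction is genus-level by design; species resolution is out of
  scope (spacer sharing within genera is too common for it to be
  reliable).
* Organisms whose taxon cannot be resolved to a genus are stored but
  cannot contribute candidates; they are logged and counted.
* The built-in scanner carries no E-value, so E-value mode requires an
  external alignment table.
* The narrative report and provenance JSON record candidate sets per
  stage, but no calibrated confidence score beyond the deciding-filter
  label is produced.
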