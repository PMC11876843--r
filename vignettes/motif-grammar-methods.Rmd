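---
title: "Methods: discovering transcription-factor motif grammar in tissue-specific enhancers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering transcription-factor motif grammar in tissue-specific enhancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifgrammar)
```

## The problem and the model

Tissue-specific enhancers recruit combinations of transcription factors
(TFs), and the *arrangement* of their binding motifs — which TFs co-occur,
in what order, and at what spacing — carries regulatory information beyond
mere motif presence. `motifgrammar` implements a pipeline for discovering
such combinatorial syntax from an enhancer catalog and projecting it
genome-wide:

1. **Motif scanning.** Each TF is modelled as a position count matrix turned
   into a position weight matrix (PWM). A window of motif width $w$ at
   offset $p$ on sequence $S$ scores
   $\mathrm{score} = \sum_{i=1}^{w} \log_2 \frac{f_i(S_{p+i})}{b(S_{p+i})}$,
   where $f_i$ is the pseudocount-regularised base frequency at motif
   position $i$ and $b$ the background composition. Hits are windows whose
   *relative* score $(\mathrm{score} - \min)/(\max - \min)$ reaches a
   threshold; both strands are scanned and reported in forward coordinates.
2. **Association mining.** Sequences are transactions, TF presences are
   items. The Apriori algorithm enumerates frequent itemsets; rules
   $A \to B$ report support $P(A \cup B)$, confidence
   $P(A \cup B)/P(A)$ and lift $\mathrm{conf}/P(B)$. The *minimal
   regulatory code* is the rule spanning at least three distinct TFs with
   the highest support, ties broken by confidence.
3. **Syntax analysis.** On each sequence the hits of all analysed TFs are
   ordered by position; an *adjacent ordered triad* is any three consecutive
   sites carrying exactly the three triad TFs. Per sequence one arrangement
   (the leftmost occurrence) is counted; arrangement proportions are
   compared by two-sided Fisher's exact tests on
   $[[a, n-a], [b, n-b]]$ tables, and inter-site spacings are summarised
   edge-to-edge.
4. **Genome-wide projection.** A CRM (cis-regulatory module) catalog is
   scanned for the *ordered* triad — a center-TF site strictly between the
   two flank TFs — without requiring adjacency.
5. **Conservation depth.** Mean per-CRM phastCons-style scores are binned
   into primate (< 0.2), mammalian ([0.2, 0.5]), birds ((0.5, 0.6]) and
   amphibian/teleost (> 0.6) categories.
6. **Epigenomic shortlisting.** CRMs are intersected with interval tracks
   (histone marks, DNase hypersensitivity, TF ChIP, SNPs) under half-open,
   ≥ 1 bp overlap arithmetic; a core set is shortlisted by a
   features-per-CRM rule.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_rel_score` | 0.80 | PWM relative-score hit threshold (fraction of the attainable score range). Genome-wide match counts are sensitive to it. |
| `pseudocount` | 0.8 | Added to each position's counts, split by background — a common PWM regularisation. |
| `background` | uniform | Per-base composition; configurable per dataset. |
| `min_support` | 0.1 | Apriori frequent-itemset threshold (fraction of sequences). |
| `min_confidence` | 0.6 | Rule confidence threshold. |
| `min_items` | 3 | Minimum distinct TFs in the minimal-code rule. |
| `require_adjacency` | TRUE (enhancer syntax) / FALSE (genome scan) | The enhancer-level grammar is defined on directly adjacent sites; the genome-wide pattern demands order only. |
| `allow_mirror` | TRUE | A segment read from the other strand reverses apparent order, so the mirrored order is accepted as the same pattern by default. |
| `core_k` | 3 | Features (classes) a CRM must carry to enter the core set. |

## Design choices where the design was open

* **Match threshold.** The scanning threshold is a relative-score cutoff,
  not a p-value calibration. 0.80 is a conventional PWM operating point;
  every function exposes it, and downstream counts should be read as
  conditional on it.
* **Fisher table construction.** Arrangement proportions are compared as
  two independent binomials over the same $n$, i.e.
  $[[a, n-a], [b, n-b]]$, with the two-sided p-value defined by the
  minimum-likelihood rule. This is the construction under which the
  arrangement-test values behave correctly for small $n$ and is verified
  against direct hypergeometric enumeration in the tests.
* **Spacing definition.** Gaps are edge-to-edge (next site start minus
  previous site end); center-to-center distances can be derived by adding
  site widths. Sample (n−1) standard deviations are the default, with a
  population option.
* **Multi-occurrence resolution.** A sequence with several adjacent triads
  contributes one arrangement — its leftmost occurrence — because the
  analysis counts *sequences* exhibiting a pattern, not occurrences.
  Same-TF hits tying at one position are collapsed to the best-scoring one.
* **Coordinates.** 0-based half-open everywhere internally (BED
  interchange); 1-based only where an external format demands it.
* **Uncovered conservation bases** are excluded from the mean rather than
  zero-filled: zero-filling would bias sparsely scored regions downward.
  An interval with no covered base yields an explicit no-coverage result,
  never a 0.0.
* **Support denominators.** Rule tables carry raw transaction counts next
  to the fractional metrics, so any ambiguity about the denominator behind
  a printed support value is auditable rather than hidden.
* **Core-set rule.** The default shortlisting rule is "at least three
  distinct feature classes" (histone marks unioned into one class, DNase,
  TF ChIP); a stricter `all_of` mode is equally supported because the
  narrative description of such core sets is often ambiguous.

## The synthetic-data generator

All pipeline inputs can be generated with known ground truth
(`sim_config()`, `generate_enhancers()`, `generate_negative_controls()`,
`generate_crm_catalog()`, `generate_tracks_and_scores()`). The defaults
define the study conditions the test-suite measures against:

* 160 positive enhancers of 2,000 bp i.i.d. background; the
  HES5–FOXP2–GATA3 triad planted adjacently in 28% of sequences, with
  center split 62.5 / 25 / 12.5 (FOXP2 / HES5 / GATA3) and uniform(35, 504)
  bp gaps — the arrangement statistics the enhancer-level analysis reports;
* independent marginal presence probability 0.35 per TF — a mid-range
  motif-presence rate chosen so that competing (non-planted) three-TF
  itemsets stay below the support threshold while pairwise structure is
  realistic;
* 100 pure-background negative controls;
* a 500-CRM catalog (1,200 bp CRMs, 500 bp spacers) with 120 planted
  ordered triads;
* track coverage fractions and a conservation category mixture matching the
  genome-wide catalog proportions (2051 / 414 / 21 / 128 of 2614).

Planted sites use motif consensus strings, which score at the maximum and
are therefore recoverable at any threshold; the bundled motif set
(`example_motifs()`) is synthetic, high-information (widths 13–14), so
chance background hits are rare (~0.03 per motif per 2 kb at the default
threshold). One RNG stream per generator stage is derived from the master
seed, so enlarging one stage never perturbs another; identical
configurations reproduce byte-identical outputs.

**What the generator does not emulate:** real genomic composition
(repeats, GC isochores, Markov structure beyond i.i.d.), degenerate
(non-consensus) binding sites unless explicitly planted, overlapping CRMs,
and correlated epigenomic tracks. Passing recovery tests therefore
demonstrates correctness of the machinery under the stated statistical
conditions, not performance on real chromatin.

## Numerical notes

* Reverse-strand window scores are accumulated in motif-position order, so
  the score of a site and of its reverse complement are bit-identical.
* Apriori support counting is exact (no sampling); results are checked
  against exhaustive subset enumeration for small item sets.
* Degenerate inputs: motifs wider than the sequence yield empty hit sets
  (not errors); all-N windows are skipped; an empty motif file yields an
  empty collection with a warning; empty binding matrices are an error.
* Problem sizes used by the test-suite and the acceptance script — 20–160
  sequences, 500–2,614 CRMs, 20-seed repetitions — were chosen as the
  smallest sizes at which the recovered statistics are stable against
  their binomial/multinomial sampling noise.

## Known limitations

* The scanner thresholds on relative score only; no p-value calibrated
  cutoffs (no dynamic-programming score distributions).
* No motif orientation (strand) grammar: order and spacing only.
* No FP-growth or weighted/multiplicity-aware mining; presence is binary.
* Published binding-site tables for real enhancer sets are consumed via
  `read_binding_matrix()` / `read_spacing_table()` (drop-in location
  `inst/extdata/supplementary/`), but are not redistributed with the
  package; the corresponding checks report their absence rather than
  silently passing.
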