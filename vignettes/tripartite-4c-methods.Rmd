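---
title: "Methods: fragment-level 4C quantification and tripartite contact detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragment-level 4C quantification and tripartite contact detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, conventions and numerical choices behind
`tricontact`, in the spirit of a methods supplement: what is computed, under
which assumptions, and where the design was genuinely open.

## Fragment maps and coordinates

All coordinates are 0-based half-open, internally and on disk (BED).
`digest()` cuts immediately **before** every occurrence of the first-cutter
motif, so each non-initial fragment begins with CATG. This convention is
forced by the chemistry of the multi-way protocol: the viewpoint primer is
trimmed back to its CATG, and every subsequent segment of a read begins at a
ligation seam whose CATG belongs to the captured fragment. Read prefixes
therefore align to fragment starts, which is also what makes exact
dictionary mapping possible (below). CATG and GATC are palindromic, so a
forward scan covers both strands; for non-palindromic user motifs the
reverse-complement occurrences are added. The second cutter is recorded as
a per-fragment boolean only — the analysis counts per fragment, and a
sub-fragment model of DpnII ends would add state the downstream statistics
never use. N bases never match a motif. Zero-length fragments cannot arise
(a cut at position 0 merges with the chromosome start).

## Exact-match read mapping

Reads and read segments are mapped by **unique exact occurrence** over both
strands, mirroring strict unique-alignment (`-m 1`) semantics on error-free
sequence: exactly one occurrence is a hit, zero or two or more is a discard
(tallied separately as unmatched vs ambiguous where the distinction
matters). Because every query starts with CATG, every genomic occurrence —
forward or reverse-complement — must anchor a CATG at a cut site, so
candidates can be enumerated from a key table at cut sites rather than by
scanning; candidates are verified by full substring comparison. The
semantics are identical to a genome-wide scan (the test suite cross-checks
against `Biostrings::matchPattern`), only the complexity differs. Segments
shorter than `min_len` (default 20 bp, exposed as an argument) are treated
as unmappable — a proxy for the reliability floor of a short-read aligner.

## Standard 4C quantification

The processing chain is:

1. `assign_reads()` — counts per fragment; `total_mapped` is the number of
   assigned reads.
2. `exclude_viewpoint()` — every fragment overlapping the bait interval
   extended by `exclusion_radius` (default 2,000 bp) on both sides is
   zeroed and masked, by any overlap, even 1 bp. `total_mapped` is then
   recomputed over the surviving fragments, so the subsequent per-million
   normalization is relative to informative signal; whether the original
   normalizer counted bait-proximal reads is ambiguous, and this is the
   reading adopted here (one scale factor of difference at most).
3. `normalize_total()` — reads per million: `score = count / total × 1e6`.
4. `smooth_profile()` — centred running mean over 11 fragments. Edges use
   **shrinking windows** rather than padding or NA-truncation: every
   fragment keeps a defined value and constant profiles are exact fixed
   points. Excluded fragments contribute 0 but stay masked.
5. `bait_normalize()` — divide by the mean score of non-excluded fragments
   whose midpoint lies within bait ± 1 Mb. The window mean is exactly 1
   afterwards (checked to 1e-12); this is a between-library display scale,
   not a statistical normalization.
6. `profile_correction()` — an optional branch, applied to smoothed
   scores, that divides by a fitted power law `E(d) = exp(c)·d^(−α)` with
   the slope **fixed** at −α (default α = 1) and only the intercept
   estimated: `c = mean(log s + α log d)` over fragments with positive
   score and bait distance within `fit_range` (default 5 kb – 2 Mb).
   Fixing the slope makes the fit a one-parameter mean, robust without
   pseudocounts; zero scores are excluded from the fit and stay zero.
   Distance is always fragment midpoint to bait midpoint.

Stage order is enforced (`normalized → smoothed → {bait_normalized,
corrected} → averaged`): the correction is a special-purpose branch for
long-range emphasis, not a mandatory chain link, and the bait-window
scaling accepts either smoothed or corrected input since the original
description does not pin down which feeds which. Replicates are combined
by the element-wise arithmetic mean with the union of exclusion masks.

Degenerate inputs error early and explicitly: zero mapped reads, an empty
bait window, a zero window mean, or fewer than two fit-eligible fragments.

## Tripartite detection

The multiway chain classifies **every** input read into exactly one of
eight classes (unassigned, no-primer, too-short, mid-unmapped,
third-missing, third-unmapped, undigested, duplicate) or yields a unique
contact; the class counts always sum to the input count, which the tests
assert. Choices worth recording:

* **Barcodes** match exactly (0 mismatches) as a prefix — the strict mode
  of the usual splitter, and the only reproducible dialect.
* **Trimming** is 3′ quality trimming (threshold Q10) followed by
  truncation at the first GATC. The quality rule removes the maximal
  suffix over which the running sum of `(threshold − q)`, accumulated from
  the 3′ end, stays positive. Reads shorter than 24 bp afterwards are
  discarded.
* **Splitting** takes the first internal CATG (position > 0): mid is
  everything before it, third begins with it. Ties cannot arise — the
  first occurrence is the split point by definition. A third that fails to
  map is split once more at its first internal CATG and only the 5′ part
  retried (`rescue_third()`); mids are never rescued. Reads with a third
  junction beyond the first two are thereby handled inside the third;
  four-way and higher contacts are out of scope.
* **Undigested filtering** is strand-aware: a pair is dropped iff mid and
  third are *collinear genomic continuations* — same chromosome, same
  strand, and fragment index +1 (plus strand) or −1 (minus strand).
  Only genomic contiguity produces undigested molecules, and contiguity
  read on the minus strand runs toward lower indices; a strand-agnostic
  |Δindex| = 1 variant is available behind `strand_aware_undigested =
  FALSE` for comparison.
* **Deduplication** keys on the exact 6-tuple (X chrom, pos, strand; Y
  chrom, pos, strand) — mapping positions, not fragment indices — keeping
  first occurrences in order.
* **The matrix** keeps contacts with **both** partners inside the analysis
  region, bins by `floor((pos − start)/binsize)` with 20-kb bins, and
  increments symmetrically (diagonal once). `zone_fraction()` reports the
  percentage of zone-overlapping bins whose row contains any nonzero
  entry.

## The synthetic generator

The generator is first-class code: it defines the conditions under which
the pipeline is validated, so its conventions matter as much as the
pipeline's.

* **Genome.** A random background is scrubbed of accidental CATG/GATC and
  the motifs are injected at Poisson-spaced positions at the configured
  densities (default 4/kb each, the genomic spacing of 4-bp cutters, mean
  fragment ≈ 250 bp on the default 2-Mb chromosome). Stray motifs created
  at injection boundaries are repaired by mutating a base outside any
  injected span. Zero densities therefore give a genuinely motif-free
  sequence.
* **Contact model.** `P_f ∝ w_f · max(d_f, 1 kb)^(−α)` with `w_f` the
  island weight (1 outside islands) attenuated by `β` per TAD boundary
  crossed between fragment and viewpoint midpoints. The 1-kb distance
  floor avoids the singularity at the bait and sits below the 2-kb
  exclusion radius, which zeroes bait-proximal fragments anyway.
  Fragments that cannot host a plantable read segment — the two terminal
  fragments, and fragments whose GATC-free CATG-anchored window is
  shorter than 24 bp on either strand — also get probability zero: reads
  from them could not survive the pipeline's own trimming rules, so
  planting them would conflate generator artifacts with pipeline errors.
* **Read geometry.** A planted segment is a genomic window anchored at a
  CATG: forward windows start at the fragment's own CATG; minus-strand
  windows end at the *next* fragment's CATG read on the minus strand (the
  palindrome makes it a CATG prefix after reverse complementing). Windows
  stop before any GATC, and a segment may not end in `GAT` (the following
  segment's leading C would complete a spurious GATC across the ligation
  seam and truncate the read). Segment lengths are drawn uniformly in
  [24, 96] bp, so a barcode (6 bp) + primer tag (20 bp) + two segments
  always fit in 250 bp.
* **Planted classes.** PCR duplicates are byte-exact copies of an earlier
  read (the worst case for deduplication); undigested products are
  collinear continuations (next fragment on plus, previous on minus,
  same strand); hub reads draw both partners uniformly from hub-zone
  fragments. Outside the undigested branch the generator never plants a
  coincidental collinear-adjacent pair — the filter could not distinguish
  it from a genuine undigested product, so such draws are rejected and
  redrawn. This makes the undigested class exactly identifiable and the
  truth comparison sharp.
* **Default landscape.** The default configuration mimics a regulatory
  locus: a 2-Mb chromosome, the viewpoint at 1 Mb, five 20-kb islands
  (weights 3–6) clustered in a hub zone at 300–520 kb, sub-TAD boundaries
  at 250/550/980 kb (and a separate TAD across the viewpoint at
  1.02–1.75 Mb), and strong insulation β = 0.1. The strong insulation is
  what gives the 20-kb occupancy statistic dynamic range at desk scale:
  with 5,000 reads, half of them hub-correlated, background coverage of
  the 900-kb analysis region must stay sparse outside the hub for hub vs
  non-hub occupancy to be a contrast rather than two saturated values. In
  the real experiment the same sparsity comes from the genome being three
  orders of magnitude larger than the analysis region.
* **Composition defaults** are the validated conditions: 5,000 multiway
  reads, 20% duplicate rate, 10% undigested rate, 50% hub probability,
  α = 1, 250-bp reads (100-bp for the standard library), constant-high
  qualities (Sanger encoding). The fraction of reads carrying a second
  junction at all is exposed as `p_third` (default 1).
* **Determinism.** Every simulation runs under a seed derived from
  `config$seed` in an isolated RNG scope; identical configurations give
  byte-identical FASTQ and truth tables.

What the generator does **not** emulate: sequencing errors and indels
(reads are error-free, hence exact-match mapping is lossless), trans
contacts, chimeric PCR artifacts other than exact duplicates, mappability
variation, or partial digestion beyond adjacent-fragment products.
Passing the recovery tests therefore demonstrates the correctness of the
pipeline's logic — splitting, filtering, deduplication, binning — not
robustness to noisy real-world reads, which would enter through the
(out-of-scope) external aligner.

## Differential statistics

Region score vectors are the smoothed (optionally corrected) scores of
non-excluded fragments whose midpoints fall in a region. Wilcoxon
rank-sum tests are exact only when both groups have at most `exact_max`
(default 8) tie-free observations; otherwise the tie-corrected normal
approximation with continuity correction is used — fragment vectors are
large, so the approximation is the operative path, and fully tied inputs
return p = 1 by convention. The BH family is the set of regions tested in
one invocation. Dunn's pairwise z statistics use mean ranks of the pooled
sample with the standard tie correction `Σ(t³−t)/(12(N−1))` and BH
adjustment across pairs; Kruskal–Wallis itself is delegated to
`stats::kruskal.test`. log2 ratios against the wild-type replicate mean
mask zeros (and excluded fragments) as NA rather than pseudocounting —
fold changes are only interpreted where both conditions have signal.
Significance thresholds are reported in the output table, never used to
filter rows.

## Rearrangements

Alleles are exact half-open edits: deletion removes `[start, end)`,
inversion substitutes the reverse complement in place. loxP scars are not
modeled — they are orders of magnitude below fragment resolution. The
coordinate map is a bijection between the mutant genome and the undeleted
wild-type positions; inside inversions the orientation flag flips, and
the involution property (applying an inversion twice restores the genome
byte-for-byte) is asserted in tests. Profile liftover splits mutant
fragments at breakpoints, reflects inverted pieces, and emits the deleted
wild-type interval as a no-data row; scores are carried unchanged.
Overlapping or nested multi-edit specifications are rejected rather than
composed — every allele of interest is a single edit, and disjoint edits
can be applied sequentially (order-independent, also asserted).

## Problem sizes and tolerances

The validation suite runs at deliberately chosen desk scales: 100 random
100-kb genomes for the digestion oracle; 500-fragment profiles for the
numerical identities of the quantification chain (smoothing to 1e-13,
bait-window mean to 1e-12, power-law flattening to 1e-9 on the log
scale); one 50,000-read structure-free library for decay-slope recovery
(|slope + 1| < 0.15, the tolerance reflecting multinomial noise after
smoothing); one 5,000-read multiway library at the composition defaults
for exact truth recovery; 1,000 null simulations (n = 20 per group) for
type-I calibration at 0.05 ± 0.02; 10,000 random positions per allele for
liftover round trips. These sizes make the whole suite run in a few
minutes while leaving each statistical check enough resolution to fail
loudly if the underlying computation drifts.

## Known limitations

* Exact-match mapping is intentional for synthetic data but means real
  FASTQ files should be aligned externally and imported as counts.
* Only cis (single-chromosome) quantification is implemented.
* The tripartite caller stops at two junctions per read; higher-order
  contacts are folded into the third segment's rescue.
* The bait-window scaling and decay correction assume a single viewpoint
  per profile; multi-viewpoint designs need one profile per bait.
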