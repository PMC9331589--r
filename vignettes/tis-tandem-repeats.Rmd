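---
title: "Tandem repeats upstream of translation initiation sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tandem repeats upstream of translation initiation sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tistr)
```

## The question

Tandem repeats (TRs) are unstable cis elements: their copy number mutates
orders of magnitude faster than point substitutions, which makes them
candidate drivers of regulatory innovation.  `tistr` asks a specific
comparative question: within groups of orthologous/paralogous genes
(pooled across species by shared gene name), do TRs found in the 120 bp
immediately 5' of a start codon in *one* species — reference-specific
TRs — co-occur with translation initiation sites (TISs) that have
*diverged* in that species, while TRs shared across species co-occur with
conserved TISs?

The package implements the full analysis as reusable, tested components:
TR mining, per-group specificity classification, weighted TIS-prefix
homology scoring, a gene-subsampled Fisher co-occurrence test, a
complementary full-protein alignment check, and a synthetic data
generator with planted ground truth.

## TR mining

A candidate is a run of adjacent exact copies of a DNA core.  Four rules
qualify a run as a TR:

1. mononucleotide cores need at least 6 copies;
2. 2–9 bp cores need at least 3 copies;
3. longer cores need at least 2 copies;
4. reported TRs of the same core never overlap within one upstream
   window.

Core lengths are banded into category 1 (1–6 bp), 2 (7–9 bp), 3
(10–15 bp) and 4 (16 bp and up), and every analysis can be restricted to
one band.  Three conventions are deliberate and are mirrored by the
brute-force oracle used in the tests:

* **Primitive cores only.** A run of `(CTCT)3` is reported as `(CT)6`;
  accepting both would double-count.
* **Maximal runs, integer copy counts.** A run is reported once, at its
  leftmost start, with the number of whole copies; trailing partial
  copies are ignored.  Under maximality, rule 4 holds automatically, but
  the test suite asserts it independently.
* **Phases are distinct types.** `CTCTCTC` carries both `(CT)3` and
  `(TC)3`.  A TR *type* is the exact pair (core string, copy count), with
  no rotational canonicalisation — so `(CT)3` and `(TC)3` are different
  types, as are `(T)6` and `(T)7`.
* **N matches nothing**, so runs can neither contain nor span `N`.  This
  is the conservative choice for assembly gaps.

Upstream windows shorter than 120 bp (genes near contig edges) are
scanned as-is rather than discarded, which would silently bias counts.
Coordinates are 0-based half-open on the given window, whose last base
abuts the start codon.

## Specificity within gene groups

Transcripts are grouped by gene name, uppercased and trimmed, because
annotation sources differ in case.  Within each group, each observed TR
type is assigned the set of species carrying it; a type seen in exactly
one species is SPECIFIC to that species, otherwise SHARED.  Specificity
is deliberately *per group*: the same `(CT)3` can be reference-specific
in one gene's context and shared in another's.  A separate global
summary (`specificity_summary()`) counts a type reference-specific only
if no non-reference species carries it in any group; it is reporting
only — the co-occurrence analysis consumes the per-group labels.

Each reference transcript is then flagged: group A transcripts carry at
least one reference-specific TR; group B transcripts carry TRs but none
reference-specific.  Both groups are defined over TR-flanked transcripts,
so the contrast isolates *specificity*, not TR presence.

## TIS homology

The TIS is represented operationally by the protein's first six residues.
Two weight vectors, summing to 100 with the initiator methionine fixed at
0, score positions 2–6 by exact identity:

* `W1 = (0, 25, 25, 25, 12.5, 12.5)` — front-loaded;
* `W2 = (0, 20, 20, 20, 20, 20)` — uniform.

The score of a transcript pair is the weighted sum of position matches; a
pair scoring **at least 50** (boundary inclusive) is called homologous.
Identity is exact (a 0/1 character comparison), not substitution-matrix
similarity; consequently under `W1` homology needs two matches among
positions 2–4 or one such match plus both of 5–6, and under `W2` any
three matches.  Proteins shorter than six residues are excluded from
events and counted in the output.

Events are *pairs*: every group-A (or group-B) reference transcript
against every TR-carrying non-reference transcript of the same gene
group.  A per-TIS roll-up (a TIS is homologous if any partner is) is also
available (`tis_rollup()`) for reporting, but the statistics consume pair
events.

## The co-occurrence test

Each fold builds a 2×2 table — homologous/non-homologous events × group
A/group B — after subsampling the group-B gene set down to the size of
the group-A gene set (uniformly, without replacement; if fewer group-B
genes exist they are all used, with a warning).  `fisher_exact()`
computes the two-sided exact p-value by hypergeometric enumeration,
summing all tables (margins fixed) whose point probability does not
exceed the observed one, with a relative tolerance of 1e-7 on the
comparison.  The reported odds ratio is the sample odds ratio
`a·d/(b·c)` (infinite when `b·c = 0` with `a·d > 0`; defined as 1 when
both products vanish).

Sidedness is a declared choice: the test is two-sided, with the
enrichment *direction* read off the odds ratio separately.  Fold seeds
are explicit (`base_seed + fold`), recorded in every result, and the
fold's RNG is private — the caller's random stream is untouched.  Fold
tables are aggregated by cell-wise arithmetic mean; per-fold p-values are
reported individually and never pooled, and no multiple-testing
correction is applied across the 8 (vector × category) analyses — each is
reported raw.

**A caveat the user should know**: the unit of the exact test is the pair
event, but events cluster by gene (a conserved gene's pairs are almost
all homologous).  When genes are heterogeneous, event counts are
overdispersed relative to the hypergeometric null and the test is
anti-conservative.  This is a property of the event-level design itself;
the package reports gene counts alongside so readers can judge the
effective sample size.

## Protein-level check

As a complementary measure, `global_align()` implements Needleman–Wunsch
global alignment with affine gaps (Gotoh's three-state recursion),
BLOSUM62, gap open 10 and gap extend 0.5.  A gap of length L costs
`open + L·extend`; this convention matches the independent implementation
used as a test oracle, so the dual-route check is exact.  Percent
similarity is the fraction of alignment columns with a positive
substitution score — the EMBOSS-needle notion — and percent identity the
fraction of identical columns.  Group similarity distributions are
compared with a two-sided Mann–Whitney U test (exact for groups of at
most 20 without ties, normal approximation with tie correction
otherwise); the test choice is declared here because no canonical choice
exists for this comparison.

## The synthetic generator

`simulate_bundle()` produces bundles in which every downstream claim has
a known truth value:

* **Divergence**: each gene is conserved (non-reference prefixes are
  copies of the reference prefix with per-position substitution
  probability `prefix_sub_rate`, default 0.05) or diverged (independent
  random prefixes) with probability `p_diverged`.
* **The plant**: a reference-specific TR is planted on one reference
  transcript with probability `p_d` (diverged genes) or `p_c` (conserved
  genes).  The implied gene-level odds ratio is
  `p_d(1−p_c)/(p_c(1−p_d))` (`expected_odds_ratio()`); the defaults
  0.5/0.25 plant an odds ratio of 3.
* **Shared TRs**: types planted with identical core and count into at
  least two species of a group (each species joins with probability 0.5,
  conditioned on two joiners).  The per-gene rate is solved so the
  overall mean TR count per transcript matches `tr_rate`, default 1.19
  per transcript.  The planted category mix defaults to the observed
  per-category abundance ratio 660:101:339:404 of reference-specific
  types.
* **Exact ground truth**: backgrounds are i.i.d. ACGT with rejection —
  a draw is discarded unless the detector finds *exactly* the planted
  repeats and nothing else.  Candidate cores are likewise rejected if
  their own repeated block contains a qualifying sub-repeat.  About
  half to two-thirds of draws are rejected at the defaults; the rate is
  reported in `$stats`.

The generator emulates none of the following, which bounds what passing
tests show about real genomes: base composition and codon structure,
per-species phylogenetic correlation, approximate/degenerate repeats,
and annotation noise in gene-name orthology.  Feasibility redraws of
overcrowded gene plans truncate the TR rate slightly (a few percent,
within the tolerance the tests assert).

## Null calibration design

Calibrating the per-fold p-value distribution requires a null in which
pair events are *exchangeable*; as noted above, a mixture of conserved
and diverged genes clusters outcomes by gene and the event-level test is
then anti-conservative by construction, which is a finding about the
method, not a calibration target.  The calibration condition therefore
uses a homogeneous divergence process — every gene conserved with
per-position substitution 0.5 (per-pair homology probability near 0.6),
one transcript per gene and species — with specific-TR planting
independent of everything (`p_d = p_c`), and one fold per independently
simulated bundle so the 500 p-values are independent draws.

One subtlety deserves spelling out.  An exact test's p-value is
discrete: within a fold it lives on the lattice of achievable
hypergeometric tail sums, so it can only be *sub*-uniform
(`P(p ≤ t) ≤ t`).  If every fold had the same margins, the lattices
would align and a Kolmogorov–Smirnov check against the continuous
uniform would reject even though the test is perfectly calibrated —
the rejection rate at any nominal level stays at or below that level.
Genuine replication folds never share margins, and neither do the
calibration folds here: bundle sizes sweep 140–320 genes, so the fold
tables range over a few hundred events and their p-value lattices
interleave.  The mixture is smooth enough for the KS check while the
per-level rejection rates verify calibration directly.

## Problem sizes used by the tests

The acceptance-style checks run at what a desk-scale study of this
design needs: the headline enrichment recovery uses 10 species × 1000
genes (≈16,000 transcripts, planted odds ratio 3, category 1, both
weight vectors, 10 folds); detector–oracle equivalence uses 1000 random
120-bp windows; the Fisher implementation is enumerated against an
independent oracle on all 20,475 tables with totals up to 24; null
calibration uses 500 independent bundles of 10 species × 220 genes; the
aligner is checked against an independent implementation on 200 random
pairs.  The genome-wide numbers of the motivating study (tens of
thousands of genes across 84 species) require the full public annotation
download and are out of scope here.

## Known limitations

* Gene-name pooling treats orthologs and paralogs alike; mis-annotated
  names leak transcripts across groups.
* Exact-identity prefix scoring ignores biochemical similarity by
  design; a conservative substitution at position 2 scores 0.
* The event-level Fisher test inherits the clustering caveat above.
* TR mining is exact: no mismatches within runs and no
  Tandem-Repeats-Finder-style scoring of degenerate repeats.
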