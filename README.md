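# tistr

Do tandem repeats (TRs) immediately upstream of a start codon co-occur
with evolutionary divergence of the translation initiation site (TIS)?
`tistr` implements this comparative-genomics analysis end to end for
anyone with per-species transcript tables, 120-bp TIS-upstream DNA and
protein sequences: it mines exact TRs, classifies each TR type as
reference-species-specific or shared within cross-species gene groups,
scores TIS conservation from the protein's first residues, and tests
the co-occurrence with a resampled Fisher's exact test.  A synthetic
multi-species generator with planted ground truth makes every stage
testable without downloads.

## The method in brief

* **TR mining.** A run of adjacent exact copies of a primitive core
  qualifies as a TR when mononucleotide cores repeat ≥ 6 times, 2–9 bp
  cores ≥ 3 times, and longer cores ≥ 2 times; same-core TRs never
  overlap.  Core lengths are banded into categories 1 (1–6 bp),
  2 (7–9 bp), 3 (10–15 bp), 4 (≥ 16 bp).  A TR *type* is the pair
  (core, copy count), e.g. `(CT)3`.
* **Specificity.** Transcripts are pooled across species by gene name.
  Within a group, a type observed in exactly one species is SPECIFIC to
  it; in two or more, SHARED.  Reference transcripts split into group A
  (carry a reference-specific TR) and group B (carry TRs, none
  reference-specific).
* **TIS homology.** For a reference transcript *t_a* and a TR-carrying
  transcript *t_b* of another species in the same group,

  S_k(t_a, t_b) = Σ_{i=2..6} w_{k,i} · Φ(P_i(t_a), P_i(t_b)),

  where P_i is the i-th residue, Φ is exact identity, and the weights
  are W1 = (0, 25, 25, 25, 12.5, 12.5) or W2 = (0, 20, 20, 20, 20, 20)
  (initiator methionine weighted 0).  A pair with S ≥ 50 is homologous.
* **Co-occurrence.** Each fold subsamples group-B genes down to the
  group-A gene count, tabulates homologous/non-homologous events by
  group, and applies a two-sided Fisher's exact test; 10 folds by
  default, per-fold p-values reported, direction read from the sample
  odds ratio a·d/(b·c).
* **Protein check.** Needleman–Wunsch global alignment (affine gaps,
  BLOSUM62, open 10 / extend 0.5) compares full proteins between the
  two groups with a Mann–Whitney U test.

See `vignettes/tis-tandem-repeats.Rmd` for conventions, parameter
defaults and design rationale.

## Worked example

```r
library(tistr)

cfg <- sim_config(n_species = 6, n_genes = 300,
                  p_specific_tr_given_diverged = 0.4,
                  p_specific_tr_given_conserved = 0.15, seed = 7)
expected_odds_ratio(cfg)
#> [1] 3.777778
sim <- simulate_bundle(cfg)
sim
#> Synthetic TIS-upstream bundle
#> TIS-upstream dataset bundle
#>   transcripts: 2858
#>   species:     6 (reference: species01)
#>   gene names:  300
#>   planted repeats: 3267 (103 specific, 3164 shared)
#>   background rejection rate: 68.0%

res <- tr_cooccurrence(sim$bundle, w = "W1", category = "all", k = 10, seed = 1)
res
#> TR / TIS-divergence co-occurrence analysis
#>   reference transcripts with a TR: 344 (of 478)
#>   genes with a reference-specific TR: 103
#> 10-fold co-occurrence analysis (W1, category all)
#> Mean 2x2 table (events):
#>             homologous non_homologous
#> specific         149.0            360
#> nonspecific      597.4            444
#> Odds ratios: median 0.31 (range 0.277-0.333)
#> Fisher p-values: max 3.52e-22 across folds
#>  direction: specific-TR TISs are LESS often homologous
```

The generator planted reference-specific TRs preferentially on genes
whose TIS prefixes were drawn independently per species (gene-level odds
ratio ≈ 3.8).  The pipeline recovers the association: TISs flanked by
reference-specific TRs are homologous in 149 of 509 pair events, versus
597 of 1041 for non-specific TRs, odds ratio ≈ 0.31 (below 1 = specific
TRs co-occur with diverged TISs), with every fold's Fisher p-value below
1e-21.

Real data enter through `read_bundle(metadata.tsv, upstream.fa,
protein.fa, reference_species)`; `write_bundle()` emits the same
formats.  A thin command-line front end with `simulate`, `ingest`,
`detect`, `classify`, `homology`, `analyze` and `align-check`
subcommands lives at `inst/cli/tistr.R`.

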