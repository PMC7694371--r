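---
title: "Rank-based integration of transcriptomic and proteomic differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based integration of transcriptomic and proteomic differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concordia)
```

## The problem

Transcript abundance predicts protein abundance only partially: in tumour
tissue, reported mRNA-protein fold-change correlations sit in the
0.3-0.6 range, and the two measurement platforms (microarray intensities,
label-free MS quantification) produce log2 fold-change (LFC) distributions
with very different spreads and offsets. Directly averaging or thresholding
the two LFC scales is therefore biased toward whichever platform has the
wider distribution. `concordia` implements a rank-based integration of two
differential-expression experiments over the same two-group contrast — the
motivating application is aggressive (grade III) versus benign (grade I)
meningioma — that is invariant to any strictly monotone rescaling of either
LFC column.

## The statistic

Let $t_g$ and $p_g$ be the transcript and protein log2 fold changes of gene
$g$ in a table of $N$ genes quantified at both levels (positive = higher in
the aggressive group; ranks use midranks for ties).

* **Concordance.** Rank both columns in *descending* order (largest LFC =
  rank 1) and average:
  $\bar r^{\mathrm{conc}}_g = \tfrac12\big(r^{t\downarrow}_g + r^{p\downarrow}_g\big)$.
  A low average rank marks concordant upregulation, a high one concordant
  downregulation.
* **Discordance.** Rank the protein column in *ascending* order (lowest
  LFC = rank 1), keep the transcript column descending:
  $\bar r^{\mathrm{disc}}_g = \tfrac12\big(r^{t\downarrow}_g + r^{p\uparrow}_g\big)$.
  A high average rank marks genes with upregulated protein but
  downregulated transcript — the pattern expected when a protein reaches
  the tissue from blood plasma rather than from local transcription — and a
  low average rank the reverse pattern.

On a tie-free table the two protein rankings are complementary
($r^{p\uparrow}_g = N + 1 - r^{p\downarrow}_g$), which the test suite
verifies together with the bijection of each rank column onto $1..N$ and
the invariance of both statistics under monotone transforms of either LFC
column.

Top-$k$ selections key on the relevant average rank with gene-identifier
tie-breaks so selections are deterministic. For the discordant directions a
literal sign filter (`lfc_protein > 0` and `lfc_transcript < 0`, or the
mirror image) is applied before taking the top $k$; whether such a filter
should precede or follow the cut-off is genuinely ambiguous, so the filter
sits behind the `sign_filter` switch (default on for discordant modes, off
for concordant modes, where the rank ordering alone encodes the
direction). The global association between the two levels is summarised by
the Pearson correlation of the paired LFCs with a two-sided t-distribution
p-value ($n - 2$ degrees of freedom); a permutation p-value is not offered
because at $n \approx 3600$ the analytic value is far below any attainable
permutation resolution.

## Identifier harmonisation

Platform-native identifiers are mapped to a common gene identifier space by
a two-stage route: a primary mapping table, then an optional fallback table
for features the primary mapping misses (emulating a direct
database conversion followed by a nomenclature-registry hop). Unmapped
features are dropped and *counted* — counts surface in the run log, never
silently. Multiple features per gene are collapsed before intersection;
the default rule keeps the record with the largest absolute LFC (ties to
the larger signed value) because a rank statistic keys on the strongest
signal, and an arithmetic-mean rule is available by configuration. LFCs
computed from expression matrices use the plain group-mean difference on
log2-scale values with listwise deletion of genes with missing values;
variance-moderated alternatives are deliberately out of scope since the
rank statistic consumes only the point estimates.

## Pre-ranked gene-set enrichment

Enrichment is computed from first principles (no wrapper around an
existing tool) so the permutation scheme and FDR estimator are fully
specified:

* **Enrichment score.** Walking the list ranked by descending score, an
  in-set gene advances the running sum by $|s|^w$ normalised over in-set
  scores, an out-of-set gene retreats by $1/(N - N_{hit})$; the ES is the
  signed extremum of the running sum, which closes to zero at the end of
  the list (checked to 1e-9). The weight default is $w = 1$; $w = 0$
  collapses to the classical Kolmogorov–Smirnov statistic between hit and
  miss positions, which the tests verify against an independent ECDF
  oracle, and weight-1 scores are cross-checked against an established
  implementation. An exact positive/negative tie of the two extrema
  resolves to the positive one — a convention, reachable only on contrived
  inputs.
* **Null model.** Gene-set resampling: uniform random subsets of matching
  size drawn from the ranked universe, 1000 permutations by default. In
  pre-ranked mode this is the only null available (there are no sample
  labels to permute). Sets of equal size share one null, drawn under a
  sub-seed `seed + size` so results are independent of collection order.
* **NES and p.** The normalised enrichment score divides the observed ES
  by the mean magnitude of same-sign null scores; permutation p-values use
  the add-one estimator $p = (1 + k)/(1 + m)$ over the $m$ same-sign null
  values, so $p \ge 1/(m+1)$ and is never zero. If no same-sign null value
  exists the NES is reported `NA` and $p = 1$.
* **FDR.** For each observed NES, q is the ratio of the pooled same-sign
  null tail fraction to the observed same-sign tail fraction, capped at 1
  and monotonised so q never increases with $|NES|$. The tests pin this to
  a hand tail-counting oracle.
* **Dual-level rule.** A set is reported as robustly enriched when its q
  is below the threshold (default 0.2) at *both* omic levels with
  same-sign NES. Because the two enrichment analyses run on independent
  datasets, the two FDR events multiply: threshold $t$ per level implies a
  combined threshold of $t^2$ (0.04 at the default), recorded on the
  result. Sets smaller than `min_size` (default 5) in the universe are
  skipped and logged; a name blocklist allows excluding e.g.
  disease-specific pathway entries, which no published enumeration pins
  down, so the list is user-supplied configuration.

## Reference overlaps

The plasma overlap intersects the top-100 discordant (protein-up,
transcript-down) genes with a plasma-proteome membership list, ordering
hits by discordance strength — candidates for proteins acquired from
circulation through tumour vasculature rather than synthesised in situ.
The drug-target filter is two-staged: genes with at least one approved
drug interaction, then the subset with a concordant increase. "Concordant
increase" is operationalised as strictly positive LFC at both levels; an
average-rank-quantile criterion is available by configuration but off by
default, since sign positivity is the only reading that needs no extra
tuning parameter. Reference lists are plain TSV memberships; no live
database is queried, so headline counts obtained from live snapshots of
plasma atlases or drug databases are reproducible only with those
snapshots and are out of scope.

## The synthetic study

Because the original cohort data require external repositories, every
stage is validated on a generator with planted ground truth:

* Background LFC pairs are bivariate normal with correlation
  $\rho = 0.35$, transcript margin $\mathcal N(0, 0.5^2)$ and protein
  margin $\mathcal N(0.41, 1.2^2)$ — matching the documented moments of
  the motivating datasets (correlation 0.35, transcript mean 0.0, protein
  mean 0.41, protein spread visibly wider). The two marginal standard
  deviations are declared constants: the source material describes the
  spread difference only qualitatively, so 0.5 and 1.2 were fixed once as
  a realistic 2.4-fold ratio and are not revisited.
* Planted effects are additive shifts of three marginal standard
  deviations: 30 concordant-up genes ($+3\sigma_t, +3\sigma_p$), 30
  concordant-down, 60 discordant ($-3\sigma_t, +3\sigma_p$), in a
  3598-gene universe (≥ 10× the planted count, keeping the background
  dominant). Additive shifts rather than mixture components keep analytic
  recovery bounds tractable.
* 21 of the planted discordant genes are flagged as plasma members; the
  remaining reference members up to the nominal size of 1929 are
  out-of-universe decoys, as in a real plasma catalogue where most
  members are absent from the analysed gene table. Consequently the
  top-100 overlap recovers exactly the planted 21 — this mirrors the
  motivating study's headline plasma signature size by construction, and
  shows list plumbing correctness, not statistical power.
* A planted gene set sits inside the concordant-up genes, so it must
  attain positive NES at both levels; 25 random sets (sizes 10–60) form
  the background collection.
* Expression matrices realise each gene's target LFC as a group-mean
  difference plus i.i.d. Gaussian noise, with default group sizes 6 vs 8
  emulating a small proteomic cohort, so `compute_lfc()` recovers targets
  with standard error $\sigma\sqrt{1/n_a + 1/n_b}$.

What passing recovery tests shows — and what it does not: the generator has
no probe-level microarray structure, no peptide-to-protein inference, no
missing-not-at-random proteomic dropout, no inter-cohort batch structure,
and its planted effects are cleanly additive. Recovery (discordant recall
≥ 0.8 at $k$ = planted count; dual-FDR detection of the planted set in
≥ 90% of 20 seeded replicates) therefore demonstrates correctness of the
statistics under the stated model, not performance on real tumour cohorts.

## Determinism and numerical choices

All randomness flows from one top-level seed, fanned out by fixed offsets
to per-stage sub-seeds (LFC draw, expression noise, set sampling,
reference sampling, one per enrichment level), so any stage can be rerun
in isolation bit-identically. Output TSVs render floats with 6 significant
digits, making whole-pipeline reruns byte-identical — the end-to-end
determinism test compares files byte for byte. Degenerate inputs fail
loudly: empty intersection, constant LFC vector in the correlation, gene
sets covering none or all of the universe, resampled set sizes outside
$[1, N-1]$. Boundary ties anywhere in a selection break on the gene
identifier.

Problem sizes used by the validation suite are the study-scale defaults
(3598 genes, 1000 permutations, ~26 sets per level, 20 replicates for the
detection-rate check); smaller universes appear only in unit fixtures
where exhaustive oracles (all $\binom{6}{2}$ subsets, hand running sums)
are feasible.

## Known limitations

* The duplicate-collapse rule of the motivating analysis is undocumented;
  `max_abs` is a declared default, and reproducing an exact published
  intersection count from raw repositories would additionally require the
  original identifier snapshots.
* The discordant sign filter's order of operations (filter-then-cut vs
  cut-then-filter) is ambiguous in the motivating description; both are
  available (`sign_filter`), the literal reading is the default.
* FDR q-values pool the resampling null across sets; with very few sets
  the observed-tail denominator is coarse, so q is conservative for small
  collections.
* The Pearson p-value uses the t-approximation and is only reported, never
  used for filtering.
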