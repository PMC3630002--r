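---
title: "Estimating the similarity of alternative probe sets from covariation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the similarity of alternative probe sets from covariation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probesim)
```

## The problem

3'-IVT Affymetrix chips quantify transcripts with probe sets of 11–16
probes placed near the 3' end.  When probe sets are re-mapped onto current
gene models, many genes end up with several probe sets targeting different
regions — *alternative* probe sets.  Whether such probe sets report the
same signal cannot be settled from annotation alone: alternative
polyadenylation and isoform switching make two probe sets on one gene
genuinely disagree in some biological conditions.  `probesim` estimates
similarity behaviourally, from the covariation of ternary
increased/decreased/not-changed (I/D/N) calls across many comparisons of
biological conditions.

## The model and its steps

**Call strings and correlations.**  The unit datum is a call string: one
I/D/N symbol per comparison.  For two strings, positions where *both* read
N are non-informative and dropped; `corr` is the percentage of `II`/`DD`
positions and `anti` of `ID`/`DI` positions among the informative ones.  A
position where exactly one string reads N stays in the denominator: it is
evidence that the two probe sets did *not* respond together, and counting
it dilutes both percentages for noisy probe sets.  A pair with no
informative position is degenerate and excluded everywhere.

**Significance filtering.**  Raw percentages are kept only when they beat
an empirical null built from random probe-set pairs of the same call
matrix: `p = (#{null ≥ value} + 1)/(n + 1)` (upper tail, add-one so p is
never 0), kept iff p ≤ α.  The default α = 0.05 is a conventional choice
exposed as a parameter.  One null is built per network, since each network
has its own comparison set; nulls are sampled without replacement over
unordered pairs and fall back to full enumeration when the requested
sample exceeds the number of distinct pairs.

**Neighbourhood overlap.**  The neighbourhood of a probe set is the set of
its significant *positive* partners (negative partners can be included via
an option, but overlap is used here as evidence of sameness, for which
anti-correlation is counter-evidence).  The overlap of two neighbourhoods
is scored by the hypergeometric upper tail with the population M equal to
the network size — neighbourhoods are network-relative objects, so the
draw is from the network, not from the whole chip.  Values are carried as
log10 p, computed in log space (`phyper(log.p = TRUE)`), stable for
populations far beyond 1e5.

**Calibration.**  Pairs positively correlated in *all* networks form the
calibration set; their per-network `corr`, `anti` and log10 p values are
pooled (each pair contributes one value per network) and the limits are
the nearest-rank 5th percentile of `corr` and 95th percentiles of `anti`
and log10 p.  Two refinements are deliberate:

* calibration pairs are restricted to pairs whose members each target a
  single gene, eliminating cross-hybridisation ambiguity from the
  calibration distribution (option `calibration_single_gene`);
* pooling per-network values (rather than per-pair means) keeps the limits
  sensitive to per-network variability, which is what the test is applied
  to.

**The test and the classes.**  A pair is similar in a network iff
`corr ≥ corr_5th` and `anti ≤ anti_95th` and `overlap ≤ overlap_95th`.
Absent (filtered) values enter as 0 for `corr`/`anti` and log10(1) = 0 for
the overlap, so non-significance can never help a pair pass.  The count of
passing networks maps to the class 0/1/25/50/75/100: 0 = no network,
100 = all, otherwise the largest threshold in {1, 25, 50, 75} whose
percentage of networks is met (1 meaning at least one network).

**Biclusters and gene assignment.**  The probe-set × gene adjacency at a
probe-number limit (cell set when ≥ limit probes hit the gene; default 7,
balancing specificity against sensitivity; limit 1 is equally supported)
partitions into connected components.  A component extracted from a seed
probe set records the recursion depth of the alternating closure, and the
component's class uses the *minimum* depth over its probe-set seeds —
depth is seed-dependent, membership is not, and the minimum makes the
label seed-order invariant.  Classes: SS/SM/MS by single/multiple
cardinalities, and MM/CX/HX for multiple×multiple at depth 1/2/≥3.
Density is reported but never used for classification.  Gene assignment
applies six criteria in order (most targeting probes; best target
category with exon > intron > upstream > downstream, compared by the probe
count in the best category; maximal probe-sets-to-transcript-groups ratio,
where probe sets targeting a gene are grouped by identical
targeted-transcript sets; fewest targeting probe sets; source
Ensembl > AceView > GOP; alphabetic).

**Grouping.**  Within one similarity class, triangles of similar pairs are
aggregated: triangles sharing an edge merge into a group, whose members
are the union of vertices.  Aggregation can introduce member pairs that
are not similar (*bad links*), which are recorded per group.  A similar
pair covered by no group forms a two-member group — the alternative would
silently drop similar pairs from the output.  A probe set belonging to
two or more groups is a *pivot*, reported separately; groups are never
merged through a single shared probe set, as one probe set is not
evidence that two transcript groups coincide.

**Merging and Markov clustering.**  A group collapses to one node whose
correlations to outsiders are the arithmetic means of the members' values
(absent values counted as 0); intra-group edges vanish.  Markov clustering
runs on the positive matrix only (negative correlations are not valid
random-walk weights), with a self-loop per node at its maximum incident
weight, column normalisation, and the usual expansion–inflation–pruning
loop (inflation 2, prune threshold 1e-4, convergence at 1e-8 elementwise).
The pruning score is the floor of 100 × mean retained column mass across
pruning steps — oriented like the customary 0 (worst) – 100 (best) scale,
with 100 exactly when nothing is pruned.  Clustering reproducibility
matches each of the k = 10 largest clusters of one result to its best
overlap in the other and averages `100·|common|/√(size_a·size_b)` with
weights `1/√(size_a·size_b)`.

**Downstream distributions.**  Signals are rank-normalised per condition
(average ties, mapped to 0–100); per pair, the empirical CDF of absolute
rank differences is evaluated on the 0..100 grid and averaged per class,
with a seeded random-pair baseline.  Per-comparison statistics report, for
each class of fixed membership, the percentage of pairs concordant
(`pcorr`) or discordant (`panti`) in each comparison, and
`rel = 100·panti/(pcorr + panti)` where defined; summaries use the mean
and the nearest-rank 95th percentile over comparisons.  The nearest-rank
(ceiling) percentile is used throughout the package: it always returns an
observed value and reproduces integer-valued summaries exactly.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | network edge significance against the random-pair null |
| `null_samples` | 1000 | random pairs per network null |
| probe-number `limit` | 7 | min probes on a gene to count as targeting |
| `gap` | 2000 bases | max neighbour distance inside a GOP |
| `min_probes` (localisation) | 11 | per-probe-set filter for score summaries |
| `inflation` | 2 | MCL inflation exponent |
| `prune_threshold` | 1e-4 | MCL pruning floor |
| `k` | 10 | clusters entering the reproducibility mean |

## The synthetic generator

`synthetic_spec()` / `generate_dataset()` emulate the pipeline inputs with
a known truth.  Latent transcript modules draw one I/D/N symbol per
comparison (I and D each with probability `p_change`); probe sets copy
their module's string, substituting N at rate `epsilon` and flipping I/D
at rate `delta`.  Genes receive 1–3 probe sets; multi-probe-set genes are
planted *same* (one shared module), *anti* (sign-flipped module — the
mutually-exclusive-isoform scenario) or *independent* (separate modules)
with probabilities 0.5 / 0.1 / 0.4.  The defaults — 200 genes, 5 networks
of two 10-condition groups (100 comparisons each), `p_change` 0.25,
`epsilon` 0.2, `delta` 0.02 — describe a noisy but realistic desk-scale
compendium: half of a probe set's calls carry signal, a fifth of copied
symbols are lost to N, flips are rare.  The same/anti/independent split
was chosen once so that each planted category is populated well enough to
estimate recovery rates at a few hundred alternative pairs; the condition
pool (`n_networks × 2 × group_size`) lets every network draw fresh
disjoint groups.  Signals give each module a normal level per condition
(mean 10, sd 2), inherited with a per-probe-set scale factor and unit
noise, mirrored around the mean for anti members.  The annotation places
11 exon probes per probe set; same-module pairs share transcripts and
exons (including the last exon), anti/independent pairs target disjoint
transcripts and exons.  One master seed derives per-network sub-seeds, so
individual networks regenerate independently.

What the generator does *not* emulate: chip-specific hybridisation
behaviour, cross-hybridisation between genes, correlated modules spanning
several genes, partially shared comparison groups between networks, and —
importantly — *graded* similarity: planted truth is binary per pair, so
intermediate classes (1–75) arise from sampling noise rather than from
biology.  Consequently, passing the recovery tests shows that the
calibration-and-test machinery separates planted signal from planted
noise at realistic noise rates; it does not by itself validate behaviour
on real chips, where the intermediate classes carry meaning.

## Numerical choices and degenerate inputs

* Network filtering uses an exact threshold derived from the sorted null
  (`value` passes iff `#{null ≥ value} + 1 ≤ α(n+1)`), making edge sets
  monotone in α by construction.
* Degenerate pairs (no informative position) never enter networks;
  explicit zeros in the sparse matrices are treated as absent by all
  consumers and writers.
* Exon-probe localisation percentages split each probe set's exon probes
  evenly over its targeted exons before attributing them to shared or
  exclusive exons (the table records counts per category, not per exon);
  the last-exon percentage summarises a pair by the larger of the two
  members' fractions.
* MCL ties (a node attracted equally by two attractors) resolve to the
  lexicographically smallest attractor; reproducibility matching breaks
  overlap ties toward the larger partner cluster, then lexicographically.
  Isolated nodes keep a unit self-loop and come out as singleton clusters.
* `rel` is undefined in comparisons where no pair is correlated either
  way; such comparisons are skipped when averaging `rel` (not zero-filled).

## Validation strategy and problem sizes

The test suite checks each stage against an independent oracle: a
position-by-position counter for `corr`/`anti` (1000 random string pairs),
exhaustive hypergeometric enumeration for every population up to 12, BFS
connected components for bicluster extraction (500 random bipartite
tables), an explicit triangle-graph-component oracle for grouping (500
random pair sets), and planted truth for the end-to-end run.  The
end-to-end checks use the default generator (about 400 probe sets, 5
networks of 100 comparisons), which keeps the whole suite within a couple
of minutes while leaving every rate estimated from hundreds of pairs; the
module-recovery check for Markov clustering uses two 6-probe-set modules
over 120 comparisons with a 40-probe-set independent reference for the
null, replicated 20 times.

## Known limitations

* The similarity classes are relative to the chosen networks: with few
  networks the class grid is coarse (5 networks make 25% steps visible
  only as 0/1/25/50/75/100 through the largest-threshold rule).
* Calibration needs a non-empty set of pairs positive in all networks;
  very noisy data or very many networks can empty it, which raises an
  error rather than silently degrading.
* The per-comparison statistics use raw concordance/discordance — no
  per-comparison significance exists in a single column of calls.
* The MCL pruning score measures retained mass of this implementation's
  pruning step; it is comparable across runs of this package, not across
  other MCL implementations.
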