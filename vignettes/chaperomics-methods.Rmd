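---
title: "Methods: differential connectivity and local-interactome enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential connectivity and local-interactome enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaperomics)
```

This vignette is the package's account of its statistical machinery: the
models, the parameters that matter, what the synthetic-data generator does
and does not emulate, and the numerical conventions adopted where the
procedure leaves genuine freedom.

## The analysis model

An AP-MS chaperomics experiment yields, per protein and replicate, a raw
MS1 intensity and an MS/MS spectral count, in two conditions (disease vs
control) with replicate structure at two levels: *sample groups* (technical
replicates of one biological sample) and *sample types* (all replicates of
a condition).

Preprocessing follows the printed order of the original protocol:

1. **Quantile normalization within sample groups.** Each column's
   non-missing values are replaced by the mean of the order statistics
   across the group's columns at the corresponding rank. Missing cells are
   masked out and stay missing.
2. **Minimal-intensity imputation within sample types.** A missing cell is
   filled with the minimum observed intensity of that protein across the
   replicates of its sample type — the conventional "the peptide was below
   the detection limit" surrogate.
3. **log10 transform** of intensities. Spectral counts are never
   transformed.

DC testing is a per-protein two-sided pooled-variance Student t-test,
disease vs control, on the log10 intensities (`Raw.p`) and on the raw
counts (`SC.p`). The default fold change is geometric,
$\mathrm{FC} = 10^{\overline{\log_{10} d} - \overline{\log_{10} c}}$,
consistent with testing on the log scale; the arithmetic ratio of linear
means is available (`fc_scale = "arithmetic"`) because the source protocol
is ambiguous on this point. Spectral-count fold changes are arithmetic, and
undefined (flagged) when the control mean count is zero; the
spectral-count branch of classification treats an undefined `SC.FC` as a
change (nothing → something). Classification applies the dataset-specific
threshold profiles (`threshold_profile()`); thresholds act on raw
p-values — no multiple-testing correction is applied at this stage, by
design of the original analysis. BH-FDR lives in the enrichment layer
only.

### Assumptions

- Replicate noise approximately normal on the log10 scale (the t-test's
  assumption). Quantile normalization makes within-group marginals
  identical, which strengthens exchangeability but induces mild
  cross-column dependence.
- The pooled-variance (not Welch) form is the default deliberately; Welch
  is available in `student_t_two_sided(var_equal = FALSE)`.
- Degenerate rows (both conditions constant) get p = 1 when means agree
  and the smallest representable positive p otherwise, so downstream
  thresholding never sees `NaN`.

## Enrichment statistics

**ORA.** For query $q$ (a DC pool) against universe $U$, a term with $K$
members in $U$ and overlap $k$ has
$p = P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N{=}|U|, K, n{=}|q|)$,
computed with `stats::phyper`. BH adjustment is applied across the tested
terms of one analysis; the reported `qvalue` equals the BH-adjusted value
(no separate q-value estimator is fitted). `GeneRatio` is $k$ over the
number of query proteins annotated anywhere in the tested collection;
`BgRatio` is $K/N$.

**Preranked GSEA.** Proteins are ranked by decreasing fold change, ties
broken by ascending accession so results are reproducible. The running sum
gains $|s_i|^p / N_R$ at members and loses $1/(N - N_h)$ elsewhere; the
enrichment score is the extremum of largest magnitude. The null is
gene-label permutation — `n_perm` random member sets of the observed size —
which is the only permutation scheme available for a preranked list;
phenotype permutation is out of scope. Normalization is sign-stratified:
$\mathrm{NES} = ES / \mathrm{mean}(|ES_{null}|\,;\,\text{same sign})$, and
$p = (1 + \#\{\text{same-sign null at least as extreme}\}) / (1 +
\#\{\text{same-sign null}\})$, so p is never zero. P-values are reported
unadjusted, matching the reference configuration (`nPerm = 10000`,
adjustment "none"); the test suite and acceptance script use
`n_perm = 1000`, which bounds the smallest attainable p at ~0.001 and keeps
runtimes in seconds.

Numerical conventions: the default weight exponent is 1 (magnitude-weighted
hits, the common choice; 0 gives the unweighted Kolmogorov–Smirnov form
used in the analytic tests). When the maximum peak and the magnitude of the
minimum trough tie exactly — which happens on small lists where both are
small rationals — the positive extremum wins, decided with a 1e-12
tolerance so floating-point accumulation order cannot flip it. An all-zero
score vector falls back to equal hit weights. The permutation path uses a
closed-form evaluation of the walk's extrema from hit positions only; the
suite asserts its exact equality with the full running sum, and
cross-checks the statistic against fgsea.

## iGSEA: enrichment in local interactomes

For each chaperome member $m$ and each DC pool, the query is
`local_interactome(m, pool)` — the first-degree neighbors of $m$ in the
annotated PPI network, intersected with the pool — and enrichment of that
query is computed against a background universe. Associations with
adjusted p below `alpha` (default 0.1) are retained and tagged with the
member and pool, yielding the bipartite chaperome-member ↔ term map.

Three decisions here were genuinely open:

- **Engine.** The reported fields (GeneRatio, BgRatio, qvalue, adjusted p)
  are over-representation outputs, so the default engine is hypergeometric
  ORA, even though the procedure is named after GSEA; a preranked-GSEA
  engine over the member's full neighborhood (scored by fold change) is
  available via `engine = "gsea"`.
- **Universe.** The background materially changes p-values. Default:
  all DC-tested proteins that appear in the annotation collection
  (`universe_policy = "dc_annotated"`); all network nodes or all annotated
  proteins are selectable.
- **BH family.** Adjustment is per member × pool analysis (the convention
  of standard enrichment tooling, where each query is one analysis);
  `bh_family = "global"` pools all members into one family instead.

Vague, uninformative terms ("protein binding", "plasma membrane",
"integral component of plasma membrane") are excluded up front by
case-insensitive exact name match, and the exclusion list is an argument.

## PPI network construction

Interaction records from both supported dialects are canonicalized
(uppercase accessions, isoform/version suffixes stripped), filtered by the
quality-control blacklist — genetic interactions (type "genetic" or MI code
MI:0208, matched exactly) and the experimental systems Co-localization,
Genetic interference, Synthetic Rescue, Synthetic Growth Defect, Synthetic
Lethality (matched case-insensitively) — and collapsed into an undirected
simple graph (self-loops dropped, duplicate pairs merged with the union of
source databases). Non-human interactors are dropped only when the dialect
carries taxon fields. Annotation attaches `dc_class`, `raw_p`, `raw_fc` to
every node and adds DC proteins absent from the reference network as
isolated nodes, so the map covers all identified proteins.

The alteration summary needs an edge rule the source only implies: an edge
is *altered* when it touches a DC node; *gained* when at least one endpoint
is disease-specific and none control-specific; *lost* in the mirror case;
an edge with one disease- and one control-specific endpoint is assigned to
gained by default (`mixed_edge = "lost"` flips it). Gained + lost = altered
holds exactly by construction. Because this rule is a declared convention
and the result depends on pinned database releases, headline alteration
percentages are reported but not treated as reference values.

## Orthology

The stepwise mouse→human conversion first rewrites the `_MOUSE` entry-name
suffix to `_HUMAN` and accepts the mapping when the converted name exists
in the human reference with an accession (`Direct`); failures are looked
up in the HCOP-style pair table (`HCOP`); the rest are `Unmapped` with a
missing accession. A step-1 success is never overridden. Inputs that
already look like human UniProt accessions pass through as `Direct` —
mixed-identifier MS tables are common and the behavior must be defined.
HCOP tables are cleaned at load time: rows without an accession dropped,
duplicate mouse ids resolved by keeping the first occurrence after sorting
(a deterministic stand-in for an unstated tie rule).

## The synthetic-data generator

The generator emulates, with known ground truth: per-protein baseline
log10 intensities drawn once (`baseline_log10_mean = 7`, SD 1 — typical
MS1 magnitudes), i.i.d. normal replicate noise on the log10 scale
(`noise_log10_sd = 0.1`), a planted fraction of DC proteins
(`frac_dc = 0.1`, split evenly) shifted by `effect_fold = 2` in the
disease replicates, negative-binomial spectral counts with mean
proportional to linear intensity (scaled so a baseline protein yields ~20
spectra; `count_dispersion = 0.5`), and missing-not-at-random dropout
following a logistic in log10 intensity (midpoint 5.5, slope 2, i.e. 50%
dropout ~1.5 decades below the typical protein; roughly a tenth of cells
end up missing). Missingness is an explicit mask (`NA`), never zero. PPI
networks are preferential-attachment graphs whose earliest — and therefore
highest-degree — vertices carry the designated chaperome hub accessions;
when given the planted truth, each hub is additionally wired to a fraction
(default 0.5) of each planted DC pool, emulating the chaperome's physical
engagement of the differentially connected proteome, which is what places
a recoverable enrichment signal in hub neighborhoods. Planted gene sets
draw ~80% of their members from one hub's pool-restricted neighborhood;
background terms are uniform draws.

What it does **not** emulate: peptide-level identification, shared
peptides and protein inference, intensity-dependent variance, batch
effects, correlated contaminant structure, bait-specific binding
chemistry, or the true degree distribution of curated interactome
databases. Passing recovery tests on these simulations therefore
demonstrates that the implementation recovers what it is supposed to
recover under its own model — not that the model captures every property
of real AP-MS data; the noise model is a stand-in, as no distributional
description of the original intensities is published.

## Known limitations

- **Minimal-value imputation is anticonservative under MNAR dropout.**
  When a protein loses two or more replicates in one condition, imputation
  duplicates that condition's minimum, deflating its variance and
  inflating the pooled t statistic. On null simulations with the default
  dropout the fraction of `Raw.p ≤ 0.05` sits well above the nominal 5%,
  while with complete data it is on target — the acceptance script
  computes both rates. This is a property of the published preprocessing
  recipe itself, reproduced faithfully; treat DC thresholds as ranking
  devices, not calibrated error rates, whenever missingness is
  substantial.
- BH retention at `alpha = 0.1` in iGSEA admits occasional false
  associations by design of FDR control; on null collections the retained
  count stays near the BH budget (asserted loosely in the suite).
- The preranked GSEA null permutes gene labels, not phenotypes, so its p
  answers "is this set unusually top-loaded given the scores", not "is
  the phenotype association real".
- `sample_group` defaults to one group per condition in the generator;
  real designs with several biological samples per condition should carry
  their actual group labels, as normalization runs within groups.

## Problem sizes used in the shipped checks

Simulated studies use 2000 proteins × 6 + 6 replicates (the scale of the
DC analyses reproduced here), a 2-hub chaperome panel, 30 gene sets of
size 5–25 with 2 planted terms at 0.8 overlap, 20 repetitions for recovery
rates, 10 seeds for null calibration and 1000 permutations for GSEA —
sizes at which every quantity the package reports is recomputed from
scratch in seconds.
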