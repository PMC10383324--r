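---
title: "Ego-module and signed-pathway permutation inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ego-module and signed-pathway permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egoperm)
```

## The problem

Label-free proteomics of a three-group rodent design — a sham-operated
control, a chronic cerebral hypoperfusion lesion (unilateral common
carotid artery occlusion, UCCAO) and a lesion-plus-treatment group — asks
two questions of a quantified protein table: which proteins change
relative to control, and which pathways shift as a whole. With ~10
replicates per group and thousands of proteins, per-protein tests are
noisy; this package instead borrows strength from a protein-interaction
network and from pathway membership, and calibrates both statistics with
permutation nulls. A behavioural module scores the companion Y-maze and
novel-object/novel-location assays so that the full study design can be
exercised end to end on synthetic data.

## Contrasts

All downstream statistics consume the per-protein contrast
$\mathrm{logFC}_i = \log_2(\bar{x}^{case}_i / \bar{x}^{ctrl}_i)$, where
$\bar{x}$ is the arithmetic mean of linear-scale abundances over
non-missing replicates. Log base 2 is the proteomics convention, and the
1.5-fold differential filter becomes $|\mathrm{logFC}| > \log_2 1.5
\approx 0.585$ (strict inequality; a ratio of exactly 1.5 is not
selected, enforced with a $10^{-9}$ relative tolerance against one-ulp
rounding of down-regulated ratios). Averaging linear intensities before
taking the ratio is the default because label-free quantification sums
ion intensities on the linear scale; `summary = "log-mean"` switches to a
geometric-mean ratio for users who prefer means of logs. A protein is
flagged missing when either group has fewer than two usable replicates;
missing proteins are excluded from filters and from permutation
backgrounds rather than imputed.

## Ego-modules and their permutation null

The module of a protein is the protein itself plus every protein that
directly interacts with it, intersected with the *measured background* —
the set of proteins with a valid contrast. For each module the mean and
sample standard deviation (SD, $n-1$ denominator; 0 for singletons) of
member logFC values are compared against **1000 randomly selected
modules of the same size**. "Random modules of the same size" is read as
random protein *sets* drawn uniformly without replacement from the
background: equal-size *ego*-modules need not exist for every size, which
would make the procedure ill-defined. The alternative reading is still
available (`null = "ego"` draws uniformly from ego-modules of matching
size whenever at least 50 exist, falling back to sets otherwise).

Empirical p-values use

* two-sided counting for the module mean: $p = (\#\{|m^\* - \bar{m}^\*|
  \ge |m - \bar{m}^\*|\} + 1)/(B + 1)$ with $\bar{m}^\*$ the null mean —
  the add-one rule never returns 0 and makes the test valid at finite
  $B$;
* upper-tailed counting for the SD (a module more *heterogeneous* than
  random is the interesting direction);
* exact counts without the add-one correction when the null is
  enumerated exhaustively.

Null draws that differ from the observed value only by floating-point
summation order are counted as ties (relative tolerance $10^{-9}$);
without this, exhaustive p-values would be wrong by $1/\binom{n}{k}$
whenever the observed set reappears among the draws. The two-sided p is
invariant under adding a constant to every logFC, since both the
observed and the null statistics shift together.

Between-contrast agreement of a module is measured by the Pearson
correlation of its members' logFC vectors in the two contrasts, with the
same random-set null and two-sided empirical p. Correlations are
undefined (flagged, no p) for modules smaller than 3 or with
zero-variance vectors.

A protein is *selected* when its module-mean p falls below
$\alpha = 0.05$; the SD p-value is reported but does not drive selection,
and no multiple-testing correction is applied across seeds — both
deliberate, documented choices for this screening statistic. Sidedness,
$\alpha$ and the null mode are configuration, since the procedure's
source leaves them open. Proteins measured but absent from the
interaction network are reported as untestable rather than dropped
silently.

## Signed pathway activity

A pathway is a named member set in which each protein carries a role
sign: $+1$ for a component/activator, $-1$ for a repressor of the
pathway's signal transduction (supplied in a signed GMT dialect,
`id|-1`). The activity of a pathway under a contrast is the signed sum
$A = \sum_i s_i \,\mathrm{logFC}_i$ over members with a valid contrast.
The null redraws member-sized protein sets from the background 1000
times; each draw is scored with the pathway's own sign multiset assigned
uniformly at random to the drawn proteins, so the repressor fraction is
preserved under the null (`null_signs = "all-positive"` gives the
simpler unsigned null). Significance is two-sided on the distance from
the null mean with the add-one rule; activation vs suppression is read
from the sign of $A$. In exhaustive mode every subset — and for mixed
signs every distinct placement of the sign multiset — is enumerated and
counted exactly.

## Behavioural scoring

* **Spontaneous alternation (%)** = 100 × (number of windows of 3
  consecutive arm entries visiting 3 distinct arms) / (total entries −
  2). Overlapping windows count, consecutive same-arm re-entries remain
  in the denominator, and sequences shorter than 3 entries are undefined.
* **Recognition index** = time exploring the novel object (or location)
  / total exploration time; 0.5 is chance. Records with less than 5 s of
  total exploration in the scored window are excluded (exactly 5 s is
  kept).
* Group comparisons use one-way ANOVA with Fisher's LSD pairwise tests
  on the pooled within-group variance, variance homogeneity by the
  median-centred (Brown–Forsythe) form of Levene's test, and Pearson
  correlation between a marker and the recognition index. When all
  groups are internally constant the ANOVA is degenerate: F is 0 (p = 1)
  if the means also agree and infinite (minimal representable p)
  otherwise.

## What the synthetic generator emulates

The generator's defaults are the study conditions the pipeline targets:
three groups (`SHAM`, `UCCAO`, `UCCAO_MF`, control first) × 10
replicates, 200 proteins (a desk-scale stand-in for a full proteome that
keeps every permutation run exact and fast), an Erdős–Rényi $G(n, p)$
interaction network with mean degree 6 ($p = \bar{d}/(n-1)$ — the module
statistic uses only first-neighbour adjacency, so no heavier topology
model is warranted), log-normal abundances (baseline $\log_2$ mean 20,
SD 2 across proteins) and i.i.d. Gaussian replicate noise of 0.3 on the
$\log_2$ scale (a ~20–25% CV, typical of label-free replicates). Planted
effects shift an ego-module (seed plus direct neighbours) by $\delta$
$\log_2$ units, or a pathway's members by their role sign times a
per-member shift, in one treated group only; the control group never
carries shifts. Pathway definitions draw members uniformly (sizes 8–25,
20% repressors, count = size × fraction rounded half up).

Behavioural sessions draw arm entries from a two-state chain in which
the next arm differs from both previous arms with probability $p_{alt}$
(defaults 0.75/0.55/0.70 — an impaired lesion group with partial
rescue); `expected_alternation_rate()` gives the exact finite-sequence
expectation of the resulting alternation score and serves as the
generator's own oracle. Exploration times are exponential in total
(mean 30 s, so short, excludable sessions occur) and split by a Beta
draw whose mean is the group's novelty preference (0.70/0.52/0.65). A
synthetic plasticity marker is drawn with correlation $r = 0.58$
($R^2 \approx 0.34$, the magnitude reported for hippocampal
plasticity markers against the recognition index) to the novel-object
recognition index.

The generator does **not** emulate missing-value mechanisms,
intensity-dependent variance, real interaction-network topology
(hubs/communities), or correlated replicate structure. Passing tests
therefore demonstrate the statistics' calibration and power under clean
assumptions, not robustness to those real-data features.

Determinism: one run seed; every stochastic operation derives a
sub-stream seed from the run seed plus an operation tag (a 31-bit hash),
so results do not depend on call order and whole-pipeline runs are
bit-reproducible.

## Reference problem sizes

Calibration and recovery runs use: 5 independent no-effect datasets
(200 proteins × 3 groups × 10 replicates, 999 permutations, both
treated contrasts — 2000 pooled module cells) for the module null; 1000
pathways × 2 contrasts for the pathway null; and 100 simulation
replicates for planted-effect recovery (ego-module shift $3\sigma_{noise}
= 0.9$ $\log_2$ units; pathway shift +1 per member among 20 equal-size
pathways). At these sizes the rejection-fraction estimate has a standard
error of ~0.5% and the whole battery runs in a few minutes on one core.
Top-rank recovery ties (several seeds at the minimal attainable p) are
broken by the standardized deviation of the module mean from its null.

## Known limitations

* The random-set null ignores network autocorrelation: overlapping
  modules of nearby seeds give correlated p-values, which affects
  neither per-seed calibration nor ranking, but means the set of
  selected seeds is not an independent discovery list (and no FDR is
  applied).
* With ~10 animals per group, exclusions included, the behavioural ANOVA
  has limited power at the default effect sizes; group differences in
  the recognition index will not always reach significance in a single
  synthetic cohort, mirroring the variability of the real assay.
* Identifiers must already be harmonised between the abundance table,
  the edge list and the GMT; no namespace mapping is attempted, and
  mismatches surface as untestable or skipped entries.
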