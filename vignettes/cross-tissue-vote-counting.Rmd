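---
title: "Cross-tissue candidate-gene discovery by vote counting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tissue candidate-gene discovery by vote counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuevote)
library(dplyr)
```

## The problem and the model

Complex metabolic diseases such as type 2 diabetes (T2DM) and obesity
perturb gene expression in many tissues at once, and no single case-control
microarray experiment is powered or positioned to see the whole picture.
`tissuevote` implements a vote-counting meta-analysis over many such
experiments ("groups": one case-control comparison on one platform, in one
tissue). Rather than pooling effect sizes — impossible across heterogeneous
platforms and tissues — each group casts a binary vote per gene, and genes
are ranked by the fraction of votes they win.

The per-group evidence is a classical two-sample comparison on normalized
log2 expression values, probe by probe:

1. **Variance-ratio pretest.** For each probe, an F test of variance
   equality with the larger sample variance on top
   ($F = s^2_{\max}/s^2_{\min} \ge 1$) and a two-sided p-value
   $p_F = 2\min\{P(F \le f),\, P(F \ge f)\}$, capped at 1.
2. **Gated t-test.** If $p_F \ge \alpha_F$ (default 0.05, the boundary
   counting as "equal"), the pooled-variance t-test with
   $df = n_1 + n_2 - 2$; otherwise the Welch test with
   Welch–Satterthwaite degrees of freedom. Both are two-sided, sign
   convention case minus control.
3. **Probe resolution.** Probes annotated to zero genes or to more than one
   gene are excluded before testing; only unambiguous single-gene probes
   vote.
4. **Gene aggregation.** A gene's p-value in a group is the *minimum* over
   its retained probes, and its direction (up = higher in cases) is taken
   from the probe attaining that minimum. The min-P reading subsumes
   "any probe significant" at every threshold; the probe count is carried
   so either convention can be reconstructed.

Across groups, the **differential-expression percentage** of gene $g$ is

$$\mathrm{pct}(g) = 100 \cdot \frac{\#\{\text{groups measuring } g
  \text{ with } p_g \le 0.05\}}{\#\{\text{groups measuring } g\}},$$

with the boundary $p = 0.05$ counting as significant. The denominator is
the number of groups *measuring* the gene, not the total number of groups:
platforms differ in gene content, and only per-gene denominators produce
percentages like 61.1% or 42.9% that are not multiples of one over the
group count. Candidates are the top of this ranking: at least 50% for the
T2DM arm and at least 60% for the obesity arm, with the obesity arm
additionally requiring at least 10 measuring groups because fewer groups
are available there. A second, stricter screen intersects the ranking with
susceptibility SNPs: genes whose interval lies within ±1 Mb of a
genome-wide-significant SNP ($P \le 5\times10^{-8}$) are re-ranked and kept
when their percentage is *strictly greater* than 40% (T2DM) or 50%
(obesity). The two threshold conventions (at-least genome-wide, strictly
greater for the screen) are deliberate and configurable
(`threshold_mode`).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `p_threshold` | 0.05 | per-group gene significance, boundary inclusive |
| `f_alpha` | 0.05 | level of the variance-ratio pretest; below it the Welch branch runs |
| `candidate_threshold_pct` | 50 / 60 (per arm) | genome-wide selection threshold, at-least |
| `min_groups` | 0 / 10 (per arm) | minimum measuring groups (vote denominators) |
| `screen_threshold_pct` | 40 / 50 (per arm) | SNP-screen threshold, strictly greater |
| `window_radius` | 1,000,000 bp | SNP window half-width, boundaries closed |
| `snp_assoc_p_max` | 5e-8 | genome-wide significance filter on SNP association P |

Coordinates are 1-based and inclusive throughout (the NCBI/CCDS
convention); BED input is converted on read (`start + 1`). Chromosome
labels are compared after normalization, so `chr7` and `7` match. The
window rule is *interval overlap*: a gene qualifies when its closed
interval intersects the closed window around the SNP, distance 0 when the
SNP falls inside the gene. This is the weakest assumption consistent with
all published gene–SNP pairings we reproduce in the tests; midpoint and
TSS anchors are available via the `anchor` argument but are not the
default, since the original choice of gene extent is not documented.

## Design choices on genuinely open points

* **"ANOVA with the F test"** is read as the two-sample variance-ratio
  pretest, not a one-way ANOVA of means, because its only role is to pick
  between the equal- and unequal-variance t-tests. Both t-tests are
  two-sided; sidedness of the original analysis is not documented, so it
  is configurable in the low-level functions and fixed two-sided in the
  pipeline.
* **Boundary at the gate.** $p_F$ exactly equal to `f_alpha` selects the
  pooled branch. Degenerate probes (zero variance on both sides) get
  p = 1 when the means agree and p = 0 when they differ, with a warning —
  never silently.
* **Direction from the min-P probe** rather than an average over probes,
  keeping the significance call and the direction attached to the same
  piece of evidence.
* **Tie-breaking in the ranking**: descending percentage, then larger
  `n_measured` (more evidence first), then lexicographic gene id; ranks
  are dense. Reports render percentages half-away-from-zero to one
  decimal, the convention of the published candidate tables; raw counts
  `k/n` are always carried alongside so no information is lost.
* **Multiplicity comparison is a side-channel.** `compare_adjustment()`
  reports per-group raw / BH-FDR / Bonferroni significant counts (the
  observation motivating the use of raw t-test p-values: FDR ≤ 0.05
  retains nothing in most null-like groups), but candidate selection
  always uses raw per-group p ≤ 0.05.
* **Per-tissue direction calls** are a majority vote over all measuring
  groups of the tissue, `mixed` on a non-zero tie; a switch
  (`significant_only`) restricts the vote to significant groups, since
  the original reconciliation rule is not documented.

## What the generator emulates — and what it does not

`simulate_studies()` is the stand-in for a compendium of GEO case-control
datasets. Its defaults are the study conditions used throughout the tests:
21 groups over 6 tissues, 2000 genes, 5 case and 5 control samples per
group, Gaussian noise (sd 1) on the log2 scale around a baseline of 7 —
RMA-normalized intensities are approximately Gaussian — with a per-gene
offset (sd 0.5), 1–3 probes per gene, 5% multi-gene probes (which the
pipeline must discard), 10% per-group gene dropout (platform content
differs by group, which is what makes per-gene denominators necessary),
and 20 planted genes shifted by ±2 noise-sd in the case samples of 70% of
the groups measuring them, with the sign fixed per (gene, tissue) so
direction summaries have recoverable truth. `variance_inflation`
multiplies the case-subgroup noise *variance* in a designated share of
groups to exercise the Welch branch.

What it does not emulate: probe-level chemistry (background, GC content),
batch effects, correlated probes within a gene (probe noise is
independent), heavy-tailed or outlier-contaminated intensities (an option
exists for none of these), and realistic linkage structure around SNPs.
Passing the recovery tests therefore demonstrates that the statistics and
plumbing are correct under the model's own assumptions, not that the
thresholds are optimal for any particular real compendium.

## Numerical and calibration notes

* **Problem sizes.** The null-calibration scenario uses 21 groups × 2000
  genes; the recovery property uses 50 seeded replicates of the default
  scenario; oracle-equivalence checks run 100 random small samples against
  `stats::t.test`/`stats::var.test` (agreement to 1e-10) and 200 random
  interval instances against a brute-force double loop.
* **Null calibration uses one probe per gene.** Min-P aggregation over
  $m$ probes has null gene-level rate $1-(1-0.05)^m > 0.05$, so the size
  of the *test* is only interpretable at $m = 1$; multi-probe worlds are
  anti-conservative by design, which is also what drives the planted
  gene's dominance in the smallest-p property (a three-probe planted gene
  against single-probe nulls).
* **Welch-branch power.** With 5 + 5 samples, the F pretest rejects a
  true variance ratio of 4 only ~21% of the time; the Welch-exercise
  scenario therefore uses 15 samples per subgroup, where
  $P(4 \cdot F_{14,14} \text{ outside the two-sided 5% bounds}) \approx 0.70$.
* **Determinism.** All randomness flows from a single integer seed; the
  pipeline stages themselves are deterministic, and rerunning with the
  same inputs and config produces byte-identical reports.

## Known limitations

Vote counting discards effect sizes and treats all groups as exchangeable
votes regardless of sample size; a group of 3 + 3 counts as much as one of
50 + 50. The percentage statistic has granularity $1/n$ per gene, so genes
measured in few groups take coarse values (the `min_groups` filter exists
for exactly this reason). The reproduced genome-wide counts of the
original compendium (gene universe, SNP-proximal gene counts, average
percentages) depend on that compendium and its annotation releases and are
out of scope here; the package reproduces the method and its printed
worked examples, and characterizes the statistic on synthetic data with
known truth.
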