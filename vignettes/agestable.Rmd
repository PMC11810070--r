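---
title: "Methods: screening for age-invariant reference genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening for age-invariant reference genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agestable)
```

# The problem

Reference ("housekeeping") genes anchor the normalization of qPCR and many
expression assays, yet a gene that is stable between conditions in young
animals may drift across the lifespan. `agestable` implements a screen for
**age-invariant** reference genes in multi-tissue bulk RNA-seq cohorts, the
classical panel of RT-qPCR stability scores for candidate verification, and
a synthetic cohort generator that makes the whole chain testable end to end.

# Dual normalization

Counts are normalized two ways and every filtering decision must hold under
both:

* **TPM** divides each gene's count by its exon-union length and rescales
  the column to sum to $10^6$; it approximates relative molar RNA
  concentration and is the closer analogue of what qPCR measures. Columns
  sum to $10^6$ by construction (checked to $10^{-6}$ relative tolerance in
  the tests).
* **TMM-scaled CPM** corrects counts per million by a between-sample factor
  assuming most genes are not differentially expressed. `tmm_factors()`
  implements the published trimmed-mean-of-M-values estimator: the
  reference sample is the one whose 75th-percentile relative abundance is
  closest to the cross-sample mean; per sample, gene-wise log2 abundance
  ratios (M) and mean log2 abundances (A) are formed over genes nonzero in
  both, 30% of each M tail and 5% of each A tail are discarded by rank, and
  the factor is $2$ to the precision-weighted mean of the surviving M
  values, with weights from the binomial delta method; factors are rescaled
  to geometric mean 1. All four tuning constants are exposed as arguments.
  The test suite checks the implementation against an independent published
  implementation (edgeR) to $10^{-8}$ on random matrices.

A nuance worth recording: because the delta-method weights depend on library
depth, the *weighted* TMM factors are only approximately invariant to a
uniform scaling of one sample (within ~1–2%); with `do_weighting = FALSE`
the invariance is exact. This mirrors the reference implementation.

Intersecting decisions across the two normalizations trades sensitivity for
robustness to method-specific artifacts: a gene must look invariant both on
the within-sample molar scale and after between-sample correction.

# Sample QC

`qc_samples()` flags samples below a library-size threshold (default
$5\times10^6$ counts, *inclusive*: a sample at exactly the threshold
passes — the threshold is phrased as a requirement for inclusion and we
resolve the boundary in the sample's favor) and, with two or more tissues,
flags potential tissue mislabels by average-linkage hierarchical clustering
on $1 -$ Spearman correlation of log2 CPM (top 2000 most-variable genes),
cutting at $k =$ number of tissues and comparing each sample's label to its
cluster's majority tissue. The flags are **advisory**: tissue mislabels in
real data were confirmed by marker inspection before removal, and an
automatic filter would overstep, so nothing is dropped without an explicit
user decision.

# The seven filters

Filters run per tissue, sequentially, on the log2 of normalized expression.
Zeros have no log2 value; they become `NA` without a pseudocount, and all
per-gene statistics are `NA` whenever a gene has a zero-count sample — such
genes fail the first filter and their statistics are written as empty fields
in reports.

1. **Continuous expression** — nonzero in every sample.
2. **Low variance** — sample standard deviation (denominator $n-1$) of the
   log2 values strictly below `sd_max = 1`.
3. **No outliers** — every log2 value within `outlier_delta = 2` units of
   the gene's mean, inclusive (a point exactly 4-fold from the mean stays).
4. **Medium-to-high expression** — the gene's mean log2 at or above the
   tissue **background**, defined as the pooled mean of all log2 values over
   genes passing filter 1. "All genes expressed" is ambiguous; the
   filter-1-passing set is the only one with fully defined log2 values, so
   it is the default background (`background = "any_nonzero"` is available).
5. **Low %CV** — $\mathrm{sd}/\mathrm{mean}\times100 \le$ `cv_max_pct = 20`,
   computed **on the log2 scale**. This is unconventional (CV of a
   logarithm) but is the screen's definition; a linear-scale CV sits behind
   `cv_scale = "linear"`. A gene whose mean log2 is not positive cannot
   satisfy a percentage bound and fails.
6. **No age correlation** — a gene is *removed* when its age-correlation
   p-value is $\le \alpha/n$, where $n$ counts the tissues in which that
   gene passed filters 1–4. The rationale: at a fixed per-tissue $\alpha$,
   a truly invariant gene tested in $n$ tissues is discarded somewhere with
   probability $1-(1-\alpha)^n$ — about 58% at $\alpha=0.05$, $n=17$ —
   so the per-tissue level is divided by $n$
   (`familywise_discard_probability()` computes the motivating quantity).
   Pearson correlation is the default; Spearman is available because the
   source material is internally inconsistent about which was used, and we
   surface rather than silently resolve that. P-values use the Student-t
   approximation for both methods, matching the tooling convention the
   screen was built with. A zero-variance gene has an undefined
   correlation; absence of evidence of age change keeps the gene, with the
   p-value recorded `NA`. A tissue whose samples share a single age is
   rejected outright — the screen is undefined there by design.
7. **Validation** — on an independent cohort, TPM only: `%CV ≤ 20` and
   Spearman p-value strictly above $\alpha/n$, where $n$ now counts tissues
   in which the gene survived step 6 in discovery. The two $n$ definitions
   (steps 1–4 for filter 6, step 6 for filter 7) are intentionally
   distinct. Candidates missing from the validation matrix fail with reason
   `"not measured"`; tissues without validation data keep their step-6
   lists.

Survivor sets are nested by construction; `pan_tissue_intersection()` is a
plain set intersection of the per-tissue final lists.
`stage_subset_analysis()` reruns steps 1–4 on a life-stage subset (or a
seeded size-matched cross-stage control) and returns the %CV distributions,
which is how stage-restricted variance structure (e.g. extra variability in
young adults) is examined.

# Ct stability scoring

All methods are implemented from their published descriptions and score
*instability* — lower is more stable.

* **geNorm**: relative quantities $Q = E^{\min Ct - Ct}$ with amplification
  efficiency $E$ (default 2, perfect doubling; per-gene efficiencies
  accepted); $M_j$ is the mean over partners $k$ of
  $\mathrm{sd}(\log_2 Q_j/Q_k)$.
* **delta-Ct**: mean over partners of $\mathrm{sd}(Ct_j - Ct_k)$. With
  $E = 2$ the two definitions coincide algebraically on two-gene panels;
  the tests assert that identity to $10^{-12}$.
* **BestKeeper**: per-gene Ct SD and CV, plus Pearson correlation with the
  BestKeeper index (per-sample geometric mean of Ct). Its contribution to
  the composite is ranked by **SD**, the tool's primary statistic, not by
  $r$ (the original's ranking statistic is not stated where we needed it;
  the choice is explicit and the $r$ column is reported).
* **NormFinder**: on log-scale relative quantities, sample effects are
  removed by centering each sample across genes; per gene and group the
  intra-group variance is estimated with the $k$-gene bias correction
  $\hat\sigma^2_{ig} = \frac{k}{k-2}\left(s^2_{ig} - \bar s^2_g/(k-1)\right)$
  (floored at zero; the raw variance is used at $k=2$), and the
  gene-by-group interaction $d_{ig}$ is shrunk by
  $\gamma^2/(\gamma^2 + \hat\sigma^2_{ig}/n_g)$, where $\gamma^2$ is the
  method-of-moments estimate of the interaction variance. The stability
  value averages $|\tilde d_{ig}| + \sqrt{\widetilde{var}_{ig}}$ over
  groups; with one group it degrades to the intra-group SD. The default
  grouping column is the age-by-sex cell.
* **RefFinder**: genes are ranked ascending within each available method
  (average ranks on ties — deterministic and order-invariant), and the
  composite is the geometric mean of the ranks over the methods available
  for that gene, hence always in $[1, n_{genes}]$.

All scores are invariant to adding a constant to every Ct (the BestKeeper
*index correlation* is only approximately so, since a geometric mean does
not commute with shifts; the SD used for ranking is exactly invariant).

# Characterization statistics

Fisher's exact test (two-sided, minimum-likelihood convention — the sum of
all table probabilities not exceeding the observed one) underlies both the
CpG-island-by-filter analysis and generic gene-set enrichment against a
user-supplied background, with Bonferroni adjustment
$\min(1, m\,p)$ over the tested collection. The odds ratio is the sample
$ad/bc$, reported `NA` when any cell is zero (never an infinity), with a
Haldane-corrected (+0.5 to every cell) value alongside. Feature shifts
(transcript lengths, GC) default to Mann–Whitney — length distributions are
heavily skewed — with Welch's t available to match the group-comparison
convention used elsewhere (`group_compare()`).

# The synthetic cohort generator

`simulate_cohort()` emulates a multi-tissue, mixed-sex cohort spanning the
four lifespan stages (adolescent 1 mo; young 3–6; middle 9–15; old 18–27 —
18 mo is assigned to old, consistent with "old" qPCR animals of about 19
months). Defaults describe the study conditions used throughout the tests:
3 tissues, 600 genes across seven planted classes
(100 stable-high, 100 stable-low, 100 age-trending, 100 high-variance,
80 dropout, 60 outlier-spiked, 60 young-variable), ages
$\{1,3,6,9,12,15,18,21,24,27\}$ months, both sexes, 4 samples per age per
sex, negative-binomial counts with dispersion 0.05 and lognormal library
sizes around $10^7$.

Design choices worth explaining:

* **Baselines live on the normalized scale.** A gene cannot sit at the same
  level under both TPM (which divides by length) and TMM-CPM (which does
  not) unless lengths are equal, so expected counts are
  $\mu \propto 2^{baseline}\sqrt{L_g/L_{geo}}$: the length factor is split
  evenly and each class lands within half the length spread of its intended
  level under *both* normalizations, with lengths log-uniform on
  [500, 100000] bp.
* **Planted over-dispersion is bounded.** The high-variance and
  young-variable classes add Gaussian log2 noise (SD set from
  `extra_cv_pct` and `young_extra_sd = 1`), truncated at $\pm2.5$ SD.
  Unbounded tails let a single draw swallow most of a library, which
  compresses every other gene's TPM in that sample by several log2 units —
  a sequencing-failure regime, not the biological variability the class
  represents.
* **Outlier spikes** multiply one random sample per tissue by
  $2^{4}$ (configurable, must exceed the 2-log2 outlier cutoff); at
  counting noise of ~0.3 log2 a 4-log2 spike trips filter 3 essentially
  always, which is what the class is for.
* **Age trends** use slopes of 0.05–0.1 log2/month with random sign,
  centered at mid-age so the class mean stays at its baseline.
* The class-to-filter mapping (dropout → step 1, outlier-spiked → step ≤ 3,
  stable-low → step 4, age-trending → step 6) is part of the generator's
  contract and is asserted in the tests.

What the generator does **not** emulate: batch effects, sex-specific
expression (available but off by default — the screen analyzes both sexes
together), read-level artifacts, annotation error, and the long-tailed
gene-abundance distribution of real transcriptomes (classes occupy a few
log2 bands). Passing tests therefore demonstrate the pipeline's statistical
behavior under a clean generative model, not performance on any real
cohort; in particular, per-tissue survivor counts on synthetic data carry no
information about how many genes a real tissue would yield.

`simulate_ct_table()` plants stable genes (no group effect, small Ct noise)
and unstable genes (group-dependent shifts spanning `group_shift` cycles —
a per-gene random permutation of centered offsets — plus larger noise)
on a configurable group design, defaulting to the age-by-sex 2x2 with
3 replicates.

# Numerical conventions and problem sizes

* Sample SD everywhere ($n-1$); average ranks on ties; genes sorted
  lexicographically in outputs so ordering is deterministic.
* Boundary semantics: filter 2 strict (<), filters 3, 4, 5 inclusive,
  filter 6 removal at $p \le \alpha/n$ (survival requires strictly larger
  p).
* Degenerate inputs fail loudly: empty class maps, non-positive ages or
  SDs, all-zero samples (TPM errors by default, `zero_sample = "na"`
  opts into NA columns), tissues with a single age, fewer than 3 samples,
  queries outside the enrichment background.
* Writers emit a `# agestable schema_version=1` comment line, `NA` as empty
  strings, and full float precision; readers skip comments and validate
  schemas with coordinates in the error message.
* The test suite exercises the default 600-gene cohort for pipeline
  properties (discovery seeds 1–10 with independently seeded validation
  cohorts), a compact 120-gene cohort for structural and IO behavior, 50
  random 200x5 matrices for the TMM cross-check, every 2x2 table with total
  at most 40 for the Fisher oracle, and 20 seeds for the Ct-panel
  discrimination checks. These sizes were chosen to make the statistical
  assertions sharp while keeping a full run around a minute.

# Limitations

* The screen's %CV is a CV of log-scale values; comparisons with CVs from
  other pipelines need care.
* The fractional threshold assumes approximately independent tests across
  tissues; shared samples or strong cross-tissue correlation would make it
  conservative in an uncontrolled way.
* NormFinder's shrinkage is noisy at 2–3 replicates per group; with such
  designs an unstable gene can occasionally outrank a stable one (visible
  in the discrimination tests as the occasional non-separating seed).
* No GO/KEGG/Reactome databases ship with the package; enrichment is
  against user-supplied sets and background. Gene identifiers are opaque
  strings — no symbol mapping is attempted.
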