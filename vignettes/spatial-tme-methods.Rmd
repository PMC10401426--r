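---
title: "Methods: radius-based spatial analysis of NK and T cells in the sarcoma microenvironment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radius-based spatial analysis of NK and T cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcspat)
```

# The problem

Soft-tissue sarcomas are immunologically "cold" tumors: immune infiltrates
are sparse, and checkpoint blockade has performed poorly. Natural killer
(NK) cells are of particular interest because their activation logic is
the mirror image of the CD8⁺ T cell's — MHC class I is the ligand CD8⁺
T cells require for antigen recognition and, at the same time, an
inhibitory "self" signal for NK cells. Whether NK and T cells occupy the
same neighborhoods of the tumor microenvironment, and how those
neighborhoods relate to local MHC-I expression, is therefore both a
biological and a prognostic question.

This package implements the full quantitative pipeline for that question:
multiplex-immunofluorescence cell tables in, survival curves out. It is
organised around one central primitive and three supporting layers.

# The central primitive: in-range neighbor counts

For a chosen *center* phenotype and *target* phenotype, and every center
cell $c$ in a tissue-microarray (TMA) core, the in-range count is

$$ N_r(c, T) \;=\; \bigl|\{\, x : x \neq c,\; \text{phenotype}(x) = T,\;
   \lVert x - c \rVert \le r \,\}\bigr| $$

with Euclidean distance on segmented-cell centroids and $r = 30\,\mu m$
by default (roughly two to three cell diameters — the scale of direct
cell–cell contact and short-range paracrine interaction). Conventions,
each deliberate and configurable:

* **Closed disc** ($\le r$): "within a radius" is read inclusively.
* **Self-exclusion by identity, not coordinates**: two distinct cells
  segmented at the same centroid count each other.
* **No edge correction by default.** Centers near the core boundary see
  truncated discs, biasing counts slightly downward; the source analyses
  apply no correction, so neither do we. An optional *guard margin*
  (drop centers within $r$ of a circular core's boundary) is available
  and is what the CSR calibration below uses.

Counts are computed with a uniform-grid spatial index (bucket width $r$,
3×3-bucket candidate search, exact distance filter). The test suite
verifies the index against an $O(n^2)$ exhaustive oracle on fixtures up
to 2,000 cells — any structure passing that invariant would be
acceptable; the grid is simply fast and dependency-free.

Counts aggregate at three levels: per core; per patient (unweighted mean
over that patient's replicate cores, matching how TMA replicate scores
are averaged); and pooled (all centers across cores), which is the level
at which per-center distributions are compared between groups. A
phenotype with no centers yields `NA`, never 0 — absence of centers is
not evidence of zero clustering.

On complete spatial randomness (homogeneous Poisson with intensity
$\lambda$), the expected in-range count is $\lambda \pi r^2$ exactly
(Slivnyak's theorem), which anchors the generator calibration test. Two
numerical notes there: the closed form holds for interior centers only,
so the check runs with the guard margin on; and it is asserted on the
*pooled* mean (total counts over total centers) because the average of
per-core means carries a small-sample ratio bias (~1% at these core
sizes — per-core counts and center numbers are positively correlated).

# Scoring layer

* **H-score** $= 100\,(f_1 + 2 f_2 + 3 f_3) \in [0, 300]$, from the
  fractions of cells staining weak/moderate/strong.
* **TIL score**: 0 (<1 lymphocyte per high-power field), 1 (1–10),
  2 (11–20), 3 (>20). Pathologist counts are integers; averaged inputs
  falling in the uncovered gap (10, 11) are rounded half-up to the
  nearest boundary first. This gap rule is a package convention — it is
  not inferable from the scoring definition.
* **Replicate aggregation**: arithmetic mean over a patient's cores.
* **Median stratification**: "high" means *strictly greater than* the
  cohort median. With sparse markers whose median is 0 (typical for NK
  markers in sarcoma) this is the only convention that yields a usable
  split: all zero-score patients are "low". The split uses per-patient
  averaged scores, consistent with replicate averaging upstream.

# Comparison statistics

Pooled-variance Student's t (the named test — not Welch), paired t,
one-way fixed-effects ANOVA with Tukey (studentized range) or Dunnett
(many-to-one multivariate t) post-tests, and Pearson correlation with
the $t$-transform p-value. All p-values are two-sided. Degenerate
zero-variance inputs — routine with flat synthetic data — are flagged
and reported as "no difference" (statistic 0, $p = 1$) rather than
crashing the pipeline. Dunnett p-values are computed with the
quasi-Monte-Carlo multivariate-t integrator under a locally pinned RNG
state, so results are deterministic to well below reporting precision
and the caller's random stream is untouched. No multiplicity correction
is applied across analyses beyond the post-hoc procedure inside an
ANOVA.

# Survival layer

Two endpoints: overall survival (diagnosis → death) and metastasis-free
survival (surgery → metastasis). Death without metastasis *censors* MFS
by default; competing-risk modelling is out of scope, and the toggle
(`mfs_death_as_event`) makes the convention explicit. The Kaplan-Meier
estimator is the standard product-limit with events-before-censorings
ties; the log-rank (Mantel-Cox) statistic uses the hypergeometric
covariance and a pseudo-inverse with rank-based degrees of freedom —
four-group median splits of small cohorts routinely produce singular
covariances, which the pseudo-inverse handles exactly the way the
reference survival implementations do. Two-marker stratification forms
the four high/low groups; empty subgroups are reported absent (small
cohorts legitimately leave a subgroup too thin to analyse), and a
one-group degenerate split skips the test with a warning.

# The synthetic world

No patient-level data are deposited with the source study, so every
stage is exercised against a generator whose *structure* mirrors what
the real analyses assume:

* **Geometry**: circular cores (TMA punches are circular), radius
  500 μm — the source never states core size; 0.5 mm is a standard
  punch. Coordinates are continuous μm, image convention (y down).
* **Point processes**: homogeneous Poisson background per phenotype
  plus Neyman–Scott (Thomas) clusters — Poisson parents, Poisson($\mu$)
  offspring, isotropic Gaussian($\sigma$) displacement, offspring
  outside the disc rejected (not reflected; edge effects are a
  documented limitation either way, and rejection keeps the density
  interpretation simple).
* **MHC-I field**: disc-shaped MHC-I⁺ regions; tumor cells inside them
  are MHC-I⁺. Immune cells carry an *undefined* MHC-I flag — the
  partition analysis treats MHC-I status as a property of the
  (tumor) tissue being infiltrated.
* **Coupling knobs**: `mhc1_affinity` places a fraction of a
  phenotype's cluster parents inside the MHC-I discs (this is how
  "T-cell aggregates co-localized with MHC-I⁺ regions" is emulated);
  `cross_attraction["A|B"]` makes phenotype B share a fraction of its
  cluster parents with A, dialing co-aggregation from full segregation
  (0) to full sharing (1).
* **Defaults** (the stated world): dense CD8 aggregates
  ($\mu = 60$, $\sigma = 12\,\mu m$, 95% of parents in MHC-I discs),
  moderate CD3 aggregates over a diffuse CD3 background, NK
  micro-aggregates ($\mu = 15$, $\sigma = 8\,\mu m$) placed independently
  of both the discs and the T cells, with CD8⁺ ⇒ CD3⁺ containment.
  Absolute densities were calibrated **once**, to reproduce only the
  *ordering* of the reference in-range means (CD8→CD8 > CD3→CD3 >
  NK→NK > CD3-around-NK > CD8-around-NK) — the printed values themselves
  depend on undeposited data and are not targets.
* **Survival**: exponential proportional hazards on cohort-standardized
  marker densities, $\text{rate}_i = \lambda_0 \exp(\sum_m \beta_m z_{im})$,
  independent exponential censoring truncated at the follow-up horizon,
  metastasis as a faster independent exponential on the same linear
  predictor. Exponential rather than Weibull: one fewer parameter, and
  recovery tests only need a controlled effect direction. Defaults
  $\lambda_0 = 0.02$/month (median ≈ 35 months, matching a
  locally-advanced sarcoma cohort), censoring 0.015/month, horizon
  60 months, 3 cores per patient, protective NK effect
  $\beta_{NK} = -0.5$ per SD.

What a green structure-recovery test establishes: the pipeline detects
NK self-preference, T/MHC-I⁺ co-localization, and NK enrichment around
MHC-I⁻ cells *when the generator puts them there*. What it does not
establish: anything about staining quality, segmentation error,
phenotype misclassification, tissue-compartment effects, or the actual
effect sizes in patients — the generator simulates none of these.

```{r example}
core <- simulate_core(point_process_config(), seed = 42)
clustering_matrix(core, c("CD3", "CD8", "NKp46"), radius = 30)
```

# Scaling choices in the test suite

Replicate-based checks reduce the simulated *unit*, never the effect
sizes or acceptance bands: structure recovery runs 100 replicates of a
3-patient × 2-core cohort under the default spatial world; survival
replicate tests use a quarter-radius core with identical cluster
geometry. Acceptance thresholds (e.g. "ordering holds in ≥95% of
replicates", "null rejection in [0.03, 0.07]") are as stated in the
build contract and were fixed before measurement.

# Known limitations

* No edge correction: near-boundary centers are biased low. The guard
  margin exists but is off by default to match the uncorrected source
  analysis.
* Clustering matrices compare distributions of per-center counts across
  groups without modelling within-core correlation; they are
  descriptive summaries, not fitted interaction models (Ripley's K,
  pair-correlation and permutation interaction tests are deliberate
  non-goals).
* The IHC bin generator draws Dirichlet fractions per core; it does not
  model pathologist reading error or section-to-section drift.
* MFS treats death-without-metastasis as censoring, which overestimates
  metastasis-free probability when mortality is informative; the toggle
  exists, a competing-risk estimator does not.
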