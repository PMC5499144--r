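---
title: "Methods: growth-curve fitness and genetic-interaction scoring in qfascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth-curve fitness and genetic-interaction scoring in qfascreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qfascreen)
```

# The measurement and the model

A quantitative fitness analysis (QFA) screen spots thousands of arrayed
yeast cultures onto agar and images each colony repeatedly over several
days. The raw datum is one intensity reading per culture per timepoint. We
model each culture's growth with the logistic law

$$G(t) = \frac{K G_0 e^{rt}}{K + G_0\,(e^{rt}-1)},$$

with carrying capacity $K$ and inoculum $G_0$ in (arbitrary) intensity
units and rate $r$ in 1/day. The logistic form is the standard generative
model for colony growth curves of this kind: it captures the exponential
phase, the approach to saturation, and is identifiable from a dozen or so
timepoints. Internally it is evaluated as
$K / (1 + ((K-G_0)/G_0)\,e^{-rt})$, which never overflows even for large
$rt$.

Two summaries convert a fit into fitness:

* **MDP** (Maximum Doubling Potential) — the number of doublings from
  inoculum to capacity, $\log_2(K/G_0)$, in doublings.
* **MDR** (Maximum Doubling Rate) — the reciprocal of the time the culture
  needs to double from its inoculum. Solving $G(t_d) = 2G_0$ gives the
  closed form $t_d = \ln[2(K-G_0)/(K-2G_0)]/r$, so
  $\mathrm{MDR} = r/\ln[2(K-G_0)/(K-2G_0)]$ in doublings/day. When
  $K \le 2G_0$ the culture can never double within its ceiling; MDR then
  falls back to the exponential-phase rate $r/\ln 2$ and the culture is
  flagged (`mdr_fallback`), which preserves the fitness ordering without an
  undefined logarithm. As $K/G_0 \to \infty$, MDR converges to $r/\ln 2$
  from below.

**Fitness** is $F = \mathrm{MDR} \times \mathrm{MDP}$ in doublings²/day. It
rewards both growing fast and growing far, and it is exactly linear in $r$
at fixed $(K, G_0)$ — a property the synthetic generator exploits (below).
Dead and unfittable cultures are assigned $F = 0$, the convention for
non-growing cultures in this kind of screen.

# Curve fitting

Imaging noise on colony intensities is multiplicative (it scales with
signal), so fitting minimizes squared residuals on **log** intensities.
Observed intensities are floored at $10^{-6}$ intensity units before the
log. Minimization is Levenberg–Marquardt (`minpack.lm::nls.lm`) with an
analytic Jacobian of $\log G$ with respect to $(K, r, G_0)$, which makes a
single fit take a fraction of a millisecond and converge essentially to
machine precision on clean data.

Choices that matter:

* **Initialization.** $K_0 = \max(y)$, $G_{0,0} = \min(y)$, and $r_0$ from
  the slope of log intensity regressed on time over the observations
  between 10% and 90% of the maximum (the near-exponential window). If the
  first attempt fails, one retry starts from $(2K_0, r_0/2, G_{0,0}/2)$;
  only then is the culture declared `failed`.
* **Bounds.** $K \in [0.5, 10]\times\max(y)$, $r \in [10^{-3}, 50]$/day,
  $G_0 \in [0.1\times\min(y),\; 0.25\times\max(y)]$. The $G_0$ ceiling is
  a fixed box chosen as half of the lowest admissible $K$, because a
  box-constrained Levenberg–Marquardt cannot express a bound that moves
  with another parameter ($G_0 < K/2$); fits that still end with
  $K \le G_0$ are rejected as failed. For flat-ish curves whose true
  inoculum exceeds a quarter of the maximum this box can bind, but such
  cultures sit near the dead-culture threshold anyway.
* **Dead-culture rule.** A culture whose maximum intensity is below
  `dead_threshold` (default 1.75) times its minimum is classed `dead`
  without fitting. The threshold is exposed because the appropriate fold
  change depends on imaging dynamic range; 1.75 is conservative for
  colony images whose healthy cultures span a 50–100× range. Requiring at
  least 4 observations is a hard error (`insufficient data`), distinct
  from dead/failed, because it indicates a malformed input rather than a
  biological outcome.

# Interaction scoring

Let $F_c(g)$ and $F_q(g)$ be a gene's mean fitness in the control and query
backgrounds. Under **multiplicative independence** the query mutation
rescales every non-interacting gene's fitness by a common factor $m$, so
the points $(F_c, F_q)$ of non-interacting genes lie on a line through the
origin — the solid independence line of a fitness plot, distinct from the
dashed equal-fitness diagonal. Deviations are genetic interactions:

$$\mathrm{GIS}(g) = F_q(g) - m\,F_c(g),$$

positive for suppressors, negative for enhancers.

* **Slope estimation.** The default is iteratively reweighted least squares
  through the origin with Tukey bisquare weights (tuning constant 4.685
  times the MAD of residuals, at most 20 iterations, tolerance $10^{-8}$ on
  $m$), started from the ordinary $\sum xy/\sum x^2$ estimate. The robust
  weighting reflects the core assumption that **most genes do not
  interact**: a minority of true suppressors/enhancers should not drag the
  line toward themselves. The plain least-squares variant is kept as
  `method = "lsq_origin"`.
* **Significance.** For each gene, a two-sided Welch $t$-test compares the
  query replicate fitnesses against the $m$-scaled control replicate
  fitnesses, so the null is centered exactly on the independence
  prediction. Welch was chosen over a pooled or model-based test because it
  is assumption-light (no equal-variance requirement, which scaled
  replicates would violate) and behaves conservatively at the replicate
  counts screens actually use (4–8). Genes with fewer than 2 replicates on
  either side are flagged and excluded from testing rather than silently
  given $p = 1$; genes absent from either screen are dropped and listed in
  a coverage attribute, never imputed as zeros.
* **Multiple testing.** Benjamini–Hochberg across all shared ORFs
  (`bh_fdr`, delegating to `stats::p.adjust`), calls at
  $q \le$ `q_threshold` (default 0.05) with direction by the sign of GIS.

GIS is equivariant under a common rescaling of both screens' fitness (GIS
scales, $m$, $p$, $q$ and calls are unchanged), and two identical screens
give $m = 1$ with all-zero GIS — both properties are tested.

# Profile analysis

A **fitness profile** is one gene's vector of fitness (or GIS) values
across several screen conditions; similar profiles suggest shared function.
`build_profile_matrix` takes the union of genes across screens (missing
gene/screen pairs stay missing, never zero-filled), `normalize_profiles`
z-scores each screen column over its non-missing entries, and
`rank_similar_profiles` ranks all other genes by similarity to a query
gene, over the screens where both are observed (pairwise-complete, so a
gene missing from one screen remains rankable; `min_overlap`, default 4,
guards against similarities estimated from too few shared conditions).

Pearson correlation is the default metric because it is invariant to
per-gene affine changes; negative root-mean-square difference is available
where absolute agreement matters. One subtlety deserves a note: Pearson
similarity between two gene profiles is **not** invariant to per-screen
rescaling of the raw matrix (changing each column's scale and offset
changes cross-gene correlations). Screen-scale invariance is achieved by
the intended workflow — normalize, then rank: column z-scoring removes
per-screen affine changes exactly, so the normalized ranking is invariant
to them. The test suite asserts exactly that form of the property.
Ties in similarity are broken lexicographically by ORF and positions are
1-based, so rankings are byte-deterministic.

# The synthetic screen generator

`simulate_screen_pair` generates the data the analysis assumes, with known
truth:

* Gene-level baselines $K, r, G_0$ are log-normal; defaults
  ($K \sim \mathrm{LN}(\log 0.2, 0.15)$,
  $r \sim \mathrm{LN}(\log 3, 0.2)$/day,
  $G_0 \sim \mathrm{LN}(\log 0.003, 0.1)$) emulate colony-image intensities
  with dilute spotting: healthy fitness lands around 20–40 doublings²/day
  and curves saturate within the 5-day imaging window.
* The query background's per-gene target fitness is
  $m_\mathrm{true} \times F_c$, times the planted effect size (default 1.8
  for suppressors, 0.5 for enhancers), times a per-gene viability factor
  under the acute temperature-cycling ("up-down") treatment. Because $F$ is
  linear in $r$, the target is hit **exactly** by scaling $r$ with $K, G_0$
  fixed — so for non-interacting genes under the chronic treatment,
  $F_q = m_\mathrm{true} F_c$ holds to machine precision before noise, and
  planted effects map monotonically to fitness (MDP untouched).
* Planted counts are $\lfloor \mathrm{fraction} \times n \rfloor$,
  suppressors assigned before enhancers from a seed-shuffled gene order.
* Measurement noise multiplies intensities by $e^{\varepsilon}$,
  $\varepsilon \sim N(0, \sigma^2)$ i.i.d. per timepoint
  ($\sigma = 0.02$ by default); dead cultures (default 1% of cultures) sit
  at $G_0$ times noise.
* The UD treatment draws each gene's viability as $e^{-E}$ with
  $E \sim \mathrm{Exponential}(1/\texttt{ud\_viability\_scale})$: most
  genes lose little, a tail loses a lot, mimicking acute killing during
  high-temperature pulses. It is a fitness-level multiplier, not explicit
  temperature-switched kinetics, because downstream analysis consumes only
  fitness. Note the multiplicative-model invariant
  $F_q = m_\mathrm{true}F_c$ intentionally does not hold gene-by-gene
  under UD — gene-specific acute killing *is* the scenario.
* Defaults are 1000 genes × 8 replicate cultures per background on 16×24
  plates, 15 timepoints over 5 days: the scale of one genome-wide screen
  plate set, and the size used by the heaviest tests and the acceptance
  script.

What the generator deliberately does **not** emulate: spatial plate
effects (edge colonies growing faster, neighbor competition), the
mating/selection steps that produce the double-mutant library and their
occasional failures, batch/temperature drift between plates, and
non-logistic growth (diauxic shifts, filamentous colonies). Passing tests
therefore demonstrate that the estimators are correct and well-calibrated
under the declared generative model — not that real screens are free of
the artifacts above, which in practice require plate-layout normalization
upstream of this package.

# Numerical and design notes

* All times are days internally; raw files declaring `time_hours` are
  divided by 24 on read.
* Tables are tab-delimited with `NA` for missing values; raw intensities
  are written at 15 significant digits, derived tables at 6. Writing, then
  reading, then writing again is byte-identical, and identical config +
  seed reproduces every table byte for byte (plots and the run log are
  outside that contract).
* Missing-library genes are represented as absent rows, not zeros, at
  every stage (scoring, profiles, rankings).
* The spotting density of real screens (dilute vs concentrated) changes
  the inoculum; it is exposed as `G0_dist` rather than fixed, since no
  canonical inoculum intensity exists across imaging setups.
* Fit failures are rare (none observed across the simulated conditions in
  the test suite) because the logistic model is well-conditioned with the
  chosen initialization; the retry path exists for pathological inputs.

# Known limitations

* The Welch construction treats the estimated slope $m$ as fixed when
  testing each gene; with hundreds of genes informing $m$ its sampling
  error is negligible relative to replicate noise, but at very small gene
  counts the q-values would be slightly anticonservative.
* Replicate fitness values inherit no uncertainty from the curve fit
  itself; a culture is one number. Genes with a dead replicate get a large
  within-gene variance and correspondingly reduced power — visible in the
  planted-suppressor recovery, where the few misses are genes carrying a
  dead culture.
* Only two-background (control vs query) designs are scored; joint
  modeling of temperature courses or more than two backgrounds is out of
  scope, though profiles across any number of screens are supported.
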