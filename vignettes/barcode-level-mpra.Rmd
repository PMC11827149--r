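---
title: "Barcode-level linear modelling of MPRA data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcode-level linear modelling of MPRA data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

A massively parallel reporter assay (MPRA) couples thousands of candidate
regulatory sequences to a reporter gene, each tagged by several short
barcodes carried in the transcript. Sequencing the barcodes in the input
plasmid pool (DNA) and in the transcribed output (RNA) yields, per barcode
and technical replicate, a pair of counts whose ratio measures the
regulatory activity of the tagged sequence. Two designs are supported here:

* **variant design** — each variant pairs a reference and an alternative
  allele oligo; the quantity of interest is the allelic log2 fold change
  (logFC) of activity;
* **element design** — each oligo is scored on its own; the quantity of
  interest is its log2 activity, optionally tested against a
  negative-control percentile.

Counts are overdispersed relative to Poisson, replicate effects shift whole
libraries, and individual barcodes misbehave (extreme GC content, RNA-binding
protein sites, integration-site effects), producing outliers. The classical
analysis aggregates barcode counts per sequence and replicate before
fitting, which is robust to nothing in particular: a single outlier barcode
contaminates its replicate's aggregate, and the per-sequence sample size
collapses to the number of replicates. This package instead treats **every
barcode measurement as a sample**, which raises the effective sample size
per sequence from the number of replicates to (number of barcodes) x
(number of replicates) and lets single outlier barcodes be down-weighted by
sheer majority. The aggregated analysis remains available
(`mode = "aggregate"`) and is used as the comparison baseline throughout.

# The model

For one row (a variant or an element), let $y$ collect the normalized
log-ratios of its barcode cells across replicates,

$$ y = \beta_0 + \beta_1 x + \varepsilon,\qquad
   \varepsilon \sim N\!\left(0,\ \sigma^2\, W^{-1/2} \Sigma W^{-1/2}\right), $$

where $x$ is the 0/1 allele indicator (absent in the element design, where
the model is $y = \beta_0 + \varepsilon$), $W$ is a diagonal matrix of
precision weights, and $\Sigma$ is block-diagonal compound symmetric: every
pair of cells observed in the same technical replicate shares a common
correlation $\rho$, cells in different replicates are independent. $\beta_1$
is the allelic logFC; $\beta_0$ the reference (or element) log2 activity.

The chain has five stages, each an exported function so every stage can be
inspected and tested in isolation.

**1. Normalization and log-ratios** (`normalize_and_logratio`). Library
sizes are totals per replicate block over all rows and both assays'
columns; counts get a pseudocount of 1 and are scaled
counts-per-million-style to a target library of $10^6$. The observation is
$\log_2(\mathrm{rna\ cpm}) - \log_2(\mathrm{dna\ cpm})$; the DNA abundance
$\log_2(\mathrm{dna\ cpm})$ is kept as the variance covariate. Because DNA
and RNA are normalized within the same replicate, uniform depth differences
between replicates cancel exactly (up to the pseudocount, whose effect
vanishes for counts in the hundreds).

**2. Mean-variance precision weights** (`voom_weights`). Low-DNA barcodes
have noisy ratios. Row-wise ordinary least squares gives residual standard
deviations $s_g$; a LOWESS curve (span 0.5) of $s_g^{1/2}$ against the
row-mean DNA log-abundance is interpolated (clamped at the fitted range)
and raised to the power $-4$, i.e. weights are reciprocal predicted
variances. The curve is evaluated, per cell, at the cell's **design-fitted**
DNA abundance — the mean abundance of its row and allele group. Evaluating
at each cell's *observed* abundance is offered (`interp = "cell"`) but not
the default: the observed DNA count is part of the cell's own log-ratio, so
weights become correlated with errors, and on null data the moderated tests
turn measurably conservative (the standardized coefficients shrink to a
standard deviation of about 0.93 and the null p-values fail a uniformity
check). With fitted-value interpolation the null is calibrated (standard
deviation within 1% of 1). The "cell" option remains appropriate when
per-barcode abundance differences are persistent properties of the library
rather than sampling noise.

**3. Consensus within-replicate correlation**
(`estimate_consensus_correlation`). Barcodes of one sequence within one
replicate share that replicate's effects, so residuals are correlated
within blocks. For every row the compound-symmetry correlation is estimated
by restricted maximum likelihood, profiled on a grid of 25 values of
$\rho$ over $(\max(-1/(k_{max}-1)+0.01, -0.3),\, 0.95)$ with parabolic
refinement around the per-row maximum; the per-row estimates are combined
by a 15% trimmed mean on the atanh scale and transformed back. The grid
profile is vectorized over all rows via the closed-form inverse square root
of a compound-symmetric block ($\Sigma^{-1/2} = aI + gJ$ per block), making
the estimator $O(\text{cells} \times \text{grid})$. If every block holds a
single observation per row the correlation is unidentifiable and an error
directs the user to the aggregated/element workflow (where it is skipped
because replicates are then genuinely independent).

**4. Weighted GLS** (`cs_gls_fit`). With $\rho$ fixed at the consensus,
each row is whitened ($W^{1/2}$ then the per-block closed form) and solved
by ordinary least squares in closed form (the design has at most two
columns). Rows whose surviving cells leave the design rank deficient —
e.g. all alternative-allele barcodes filtered out — are flagged and
excluded from testing, never imputed. Missing slots (barcode-multiplicity
padding) carry zero weight and identically zero whitened rows, so they
contribute nothing.

**5. Moderation and testing** (`squeeze_variances`, `moderated_test`).
Residual variances are shrunk toward a common prior by empirical Bayes:
the prior $(d_0, s_0^2)$ is estimated by moment matching on
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$, with the inverse trigamma
solved by Newton iteration; when the observed spread of $e_g$ does not
exceed the chi-square contribution, $d_0 = \infty$ and the common variance
is the plain mean. The moderated $t$ uses $d_g + d_0$ degrees of freedom
(normal when infinite) and two-sided p-values are Benjamini-Hochberg
adjusted. The convexity property
$\min(s_g^2, s_0^2) \le s^2_{post} \le \max(s_g^2, s_0^2)$ is asserted in
the tests.

## Threshold testing against negative controls

`treat_test` reimplements a TREAT-style threshold test for the element
design. The upper threshold is the configured percentile (default 0.975,
linear-interpolation quantile) of the negative-control activities, the
lower threshold the mirrored quantile, and all activities are first shifted
by the control mean so the test remains correct when the thresholds are
negative (e.g. when controls sit below the library average). With shifted
coefficient $b$, effective threshold $\tau$ and moderated standard error
$se$: activating $p = P(T \ge (b-\tau)/se)$; repressing
$p = P(T \ge (-b-\tau)/se)$; two-sided
$p = P(T \ge (|b|-\tau)/se) + P(T \ge (|b|+\tau)/se)$. At $\tau = 0$ the
two-sided form reduces exactly to the ordinary moderated test. Reported
activities are never shifted. One-sided activating is the default
direction, matching the common screen for enhancers against a roughly
neutral control set; conclusions are always relative to the control group,
not absolute. A configurable floor of 20 controls guards against
meaningless percentile estimates.

# Preprocessing

In order: (1) keep barcodes with DNA and RNA counts of at least 1 in
*every* replicate; (2) keep oligos with at least 10 surviving barcodes;
(3) optionally remove outlier barcodes — within each (oligo, replicate)
group, a barcode whose RNA count lies more than 3 sample standard
deviations from the group mean is removed from *all* replicates
(zero-variance groups remove nothing); (4) re-check the barcode floor;
(5) optionally cap barcode multiplicity at the 95th percentile
(linear interpolation, floored to an integer) of the per-oligo multiplicity
distribution, keeping a seeded uniform subset for oligos above the cap.

Two conventions had to be fixed where the procedure admits readings: the
3-SD rule is applied per replicate on raw RNA counts (pooling replicates
would let a depth difference masquerade as outliers), and the sample
($n-1$) standard deviation is used because groups can be small.

# The simulator

`simulate_dataset` generates barcode-level counts with known truth.
Variants divide equally into five effect groups with logFCs
$-2, -0.5, 0, 0.5, 2$; the alternative allele's RNA mean is the reference
mean times $0.25, 1/\sqrt2, 1, \sqrt2, 4$ respectively. Counts are drawn
from a negative binomial parameterized by method of moments,
$n = \mu^2/(\sigma^2-\mu)$, $p = n/(n+\mu)$, which reproduces the template
mean exactly and requires overdispersion ($\sigma^2 > \mu$). DNA
distributions are identical for the two alleles; the alternative RNA
variance preserves the template's dispersion factor $\phi = \sigma^2/\mu$
at the scaled mean, a choice the underlying protocol leaves open. Three
base replicate templates are each sampled twice, giving six replicates
whose template pairs share parameters but whose draws are independent.

Templates (`make_templates`) emulate reading empirical moments off a
library sequence: variant-level DNA and RNA means log-uniform on
(20, 500), per-replicate lognormal scaling with sdlog 0.25 (typical
replicate shifts within ~1.3-fold — large enough to make ignoring the
within-replicate correlation visibly anticonservative, small enough to be
realistic), dispersion factors log-uniform on (1.5, 10) shared across a
variant's replicates, and 10-60 barcodes per variant shared between its
alleles.

The outlier injector multiplies the RNA count of a seeded random fraction
of barcodes by 25 (rounded) in $k$ replicates, $k$ drawn with
probabilities $(0.85, 0.05, 0.04, 0.03, 0.02, 0.01)$ — most real outliers
hit a single replicate.

What the generator does **not** emulate: sequence-driven barcode biases
(GC, RBP sites) that make barcode effects persistent rather than i.i.d.,
integration-site variation, correlated DNA/RNA sampling within a cell
population, and contact between variants. Consequently, passing tests show
the estimator is correct and calibrated under negative-binomial noise with
replicate structure and multiplicative outliers; they do not certify
behavior under systematic barcode artifacts, which is precisely the data
regime where the `interp = "cell"` weighting and manual outlier inspection
deserve consideration.

# Numerical choices and degenerate inputs

* Quantiles everywhere use the linear-interpolation definition (R type 7);
  caps are floored to integers.
* The REML grid is 25 points with parabolic refinement; per-row estimates
  are clamped to $(-0.999, 0.999)$ before the atanh trimmed mean.
* Rows with zero residual degrees of freedom are excluded from the
  variance trend and from moderation but still receive weights and (where
  testable) coefficients; rows with zero residual variance cannot inform
  the correlation, and if no row can, the consensus falls back to 0 with a
  warning.
* The trend value is floored at $10^{-4}$ before the $-4$ power; a
  single-point trend (one usable row) degenerates to a constant.
* Aggregate variant mode sums raw counts per (replicate, allele) before
  normalization, so the collapsed analysis sees genuine count totals; the
  ref/alt pair within a replicate forms the correlation block.
* `fit_variants`/`fit_elements` report, per row, the number of
  contributing barcode slots alongside the statistics.

# Scale and reproducibility

All simulation-based checks run at the study scale of 5000 variants x six
replicates (about 2 million count records), which one fit processes in
under a minute; the bundled test suite and the acceptance script complete
in a few minutes on a single core. Every stochastic step takes an explicit
seed, and identical seeds reproduce byte-identical tables.

# Known limitations

* The design matrix is restricted to intercept-plus-allele or intercept
  only; multi-condition contrasts (e.g. cell-type interactions) would
  require generalizing `cs_gls_fit` beyond its two-column closed form.
* A single consensus correlation is shared by all rows; rows whose true
  within-replicate correlation deviates far from the consensus are mildly
  mis-scaled (the residual variance largely self-corrects, as the null
  calibration shows, but extreme heterogeneity is not modelled).
* The threshold test inherits the percentile's sampling noise; with few
  negative controls the threshold itself is uncertain, which the test does
  not propagate.
* Activities and logFCs are relative to the replicate libraries; absolute
  transcription rates are out of scope.
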