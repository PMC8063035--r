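---
title: "Two-phase non-linear normalization: model, estimation, and design choices"
author: "twoPhaseNorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase non-linear normalization: model, estimation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twoPhaseNorm)
```

## The problem

In single-cell RNA-seq without unique molecular identifiers, the observed
count for a gene reflects both its expression and a chain of technical
efficiencies: cell lysis, mRNA capture, reverse transcription, amplification,
sequencing depth. Dividing every count in a cell by a single size factor
(CPM and relatives) assumes this distortion is the same for every gene in the
cell and linear in library size. In real data neither holds: the slope of log
counts on log library size differs across genes, and genes that are not
actively transcribed in a cell show only a background level of counts that
does not respond to depth at all. A cell-wise factor therefore
*over-corrects* weakly depth-dependent genes, inflating their variance and
biasing group comparisons when sequencing depth is unbalanced between
populations.

This package estimates a **cell- and gene-specific** factor $S_{gi}$ and
removes it, using only the observations that actually carry information about
technical efficiency.

## The model

Each gene $g$ in each cell $i$ is in one of two latent phases $Z_{gi}$:

* **Background (inactive), $Z_{gi}=0$:** the count follows a cell-specific
  zero-inflated Poisson, $Y_{gi} \sim \mathrm{ZIP}(p_{0i}, \lambda_i)$, with
  $P(Y=0) = p_0 + (1-p_0)e^{-\lambda}$. These counts are low regardless of
  depth.
* **Active, $Z_{gi}=1$:** the expression concentration is lognormal,
  $\theta_{gi} \sim \mathrm{LN}(\mu_g, \sigma_g^2)$, and the count is
  $Y_{gi} \mid \theta \sim \mathrm{Poisson}(\theta_{gi} S_{gi})$, where
  $S_{gi}$ is the technical distortion we wish to remove.

$\theta$ and $S$ are only jointly identified; the constraint adopted here is
that the **average of $S_{gi}$ over unmasked genes equals 1 in the cell with
the median library size** (for an even number of cells, the lower middle
value, so the reference is always an actual cell). All internal logarithms
are natural; diagnostics that are conventionally displayed in base 2 convert
at the output boundary.

## Estimation

**1. Background, per cell** (`estimateZIP`, `estimateBackground`). If a cell
holds $N$ background genes whose non-suppressed counts are
$\mathrm{Poisson}(\lambda)$, the count-value frequencies satisfy
$\log n_y + \log y! = c + y \log\lambda$. Only the bins $y = 1..y_{\max}$
(default 10) enter this regression: higher bins are increasingly contaminated
by active-phase counts. Because contamination that falls *inside* the window
forms its own coherent line at high leverage, an ordinary least-squares fit
can be pulled arbitrarily far; the fit is therefore initialized from the two
lowest bins (the least contaminated and by far the most populated) and
polished by Tukey-bisquare IRLS (tuning constant 4.685, 20 rounds) with base
weights $n_y$ (since $\mathrm{Var}(\log n_y) \approx 1/n_y$) and a robust
scale taken as the $n_y$-weighted median of $\sqrt{n_y}$-standardized
residuals. $\hat\lambda = e^{\text{slope}}$;
$\hat N = e^{c + \hat\lambda}$; $\hat p_0$ comes from the excess of observed
zeros over the Poisson prediction, with one fixed-point pass to express it
relative to the full background population $\hat N/(1-\hat p_0)$. Cells with
fewer than two populated bins get the cohort-median parameters and are
flagged.

**2. Phase posterior, per gene** (`emFit`). The active-phase pmf is a
Poisson-lognormal integral with no closed form; it is evaluated by
Gauss-Hermite quadrature (25 nodes by default) *re-centred at the mode of the
integrand* (found by a few Newton steps). Mode-centring matters because for
large counts the Poisson kernel is much narrower than the lognormal prior;
naive quadrature centred on the prior misses the mass, while the re-centred
rule is uniformly accurate (tested to 1e-6 against brute-force integration,
typically ~1e-9). Initial phases come from each cell's ZIP upper tail (an
observation is initially active when it exceeds the 0.999 background
quantile); EM then alternates the phase posterior with an exact M-step that
updates $\mu_g, \sigma_g^2$ from the posterior moments of the latent log
concentration, conditioned on $Y \ge 1$, and floors $\sigma^2$ at 0.01.
The exactness of the M-step is what guarantees a non-decreasing
log-likelihood trace; a simpler update using moments of $\log Y$ directly is
*not* an EM step for this likelihood and was observed to drift downhill.
Since the likelihood factorizes over genes, each gene's EM is frozen
individually once its parameters move less than `tol` (1e-4), which makes the
fit cheap even when a few weakly expressed genes converge slowly. Genes whose
active weight mass falls below 3 effective cells are reported unestimable
(`NA` parameters, background-tail posterior) rather than dropped.

**3. Bias curves, per cell** (`computeResiduals`, `fitCellCurve`). For
observations called active ($\hat Z_{gi} > 0.99$) with $Y \ge 1$, the
residual $\hat\epsilon_{gi} = \log Y_{gi} - \hat\mu_g$ has expectation
$\log S_{gi}$. Plotted against $\hat\mu_g$ these residuals form the
phase-split MA picture; their smooth trend is the cell's bias curve
$\hat f_i$, fit as a natural cubic regression spline with 5 degrees of
freedom (knots at abscissa quantiles) by three rounds of bisquare IRLS, so
that outliers - including genuinely differentially expressed genes - do not
bend the technical estimate. Outside the fitted abscissa range the curve
extrapolates as a constant, preventing wild spline tails for extreme genes.
Cells with fewer than 50 usable residuals fall back to a constant (their
median residual); cells with fewer than 10 fall back to the cohort-median
curve. Thousands of genes jointly determine each curve, so individual phase
miscalls are immaterial.

**4. Factors and their use** (`evalLogS`, `rescaleToReference`,
`applyNormFactors`). $\log S_{gi}$ is read off $\hat f_i$ for each active
pair, shifted so the reference-cell constraint holds exactly (idempotent),
and applied either as a **log offset** for count models or by direct
division ($Y/S$) with background entries left untouched and a recommended
filter of genes active in at least 3 cells.

### Where the curve is evaluated

The curves are *fit* against mean log expression $\hat\mu_g$. Two evaluation
abscissae are supported: `mode = "at_mu"` (default) evaluates
$\hat f_i(\hat\mu_g)$, giving one factor per gene-cell pair; `mode =
"at_count"` evaluates $\hat f_i(\log Y_{gi})$ at the realized count. The
default is `at_mu`: at low expression the count's Poisson noise is large, and
feeding it through the bias curve injects that noise back into the factor -
precisely the over-adjustment of weakly expressed genes that this method
exists to avoid. On simulated data with expression-dependent bias, `at_mu`
reduces the conditional standard deviation in every expression stratum,
while `at_count` can inflate it in the weakest stratum (the package's
acceptance checks compute both the stratified SD ratios and the behaviour of
the cell-wise baseline on the same data).

## The simulator

`simulateTwoPhase()` draws directly from the generative model above, with a
single Mersenne-Twister stream and a frozen draw order (gene parameters,
cell parameters, then counts gene by gene), so every fixture is
bit-reproducible from its configuration and seed. Three bias models are
provided: none ($S=1$), `cellwise` ($S_{gi}=s_i$, the situation a size
factor could fix), and `smooth`
($\log S_{gi} = \log(d_i)\,(a + bt_g + ct_g^2)$ with $t_g$ the standardized
mean expression and $d_i$ a per-cell depth factor; defaults $a=0.4, b=0.8,
c=-0.2$), which produces the hallmark of real non-UMI data: count-depth
slopes that grow with expression level, with weakly expressed genes nearly
depth-independent. Optional design fields add background-only genes
($\pi_g = 0$), a two-group depth multiplier (null design with unbalanced
depth), and spiked true fold changes.

The canonical fixtures in `fixtureSuite()` (sizes and seeds documented
there) were chosen as the smallest designs that make each property sharply
testable: e.g. `cellwise_bias` uses 5000 genes x 40 cells with tight
dispersion ($\sigma = 0.2$, $\mu \in [\log 50, \log 500]$) because the
fitted-curve flatness check (range $\le 0.05$) requires the spline's
noise-induced wiggle, which scales with residual noise over the square root
of points per cell, to sit well below that band; and `unbalanced_depth` uses
a 4x depth ratio between two groups of 50 cells with no true difference.

What the simulator does **not** emulate: gene length and GC biases,
doublets, ambient RNA, cell-to-cell correlation, or non-Poisson counting
overdispersion within the active phase. Passing tests on these fixtures
demonstrates correct recovery *under the model's own assumptions*, not
performance on any real data set.

## Numerical choices and edge cases

* Quadrature: 25 mode-centred Gauss-Hermite nodes; Newton steps are clamped
  to $\pm 2$ per iteration for global stability.
* Robust scale floors (1e-8) and a zero-residual early exit keep the IRLS
  loops defined for degenerate (noise-free or constant) inputs.
* `df` is capped at one less than the number of points, with a warning.
* An all-zero cell cannot support background estimation: it is flagged and
  imputed, never fatal; an all-zero matrix and an all-background matrix are
  errors.
* Ties for the median library size resolve to the first cell in column
  order; rescaling is exactly idempotent; masked entries serialize as the
  literal string `NA`.
* EM determinism: the fit has no stochastic component; `seed` is accepted
  for interface uniformity only.

## Known limitations

* Residuals can only be observed for *called* active entries. Near the
  detection boundary (counts comparable to the background's upper tail) the
  calls select upward, so curves in shallow cells acquire a small positive
  bias at the lowest expression levels; in unbalanced designs this leaves a
  residual group difference of order 0.1 natural-log units in the weakest
  stratum. The same selection also means the method cannot normalize genes
  it never observes in the active phase.
* Comparing groups of very different depth on the log scale retains a small
  Jensen-type bias from unequal Poisson noise even under oracle
  normalization.
* The active phase assumes Poisson counting noise around the lognormal
  concentration; strongly overdispersed counting (e.g. amplification
  jackpots beyond lognormal variation) is absorbed into $\sigma_g^2$.
* One pass is performed (background, EM with $\log S = 0$, curves). The
  fitted factors could in principle be fed back into a second EM pass; this
  is exposed by passing `logS` to `emFit()` but is off by default.

## Problem sizes used in the checks

The test-suite and acceptance fixtures run at 500-5000 genes and 40-120
cells (20000 genes for the pure-background estimator checks), sizes at which
every property above is measurable with comfortable Monte-Carlo margins
while the whole suite completes in well under a minute of compute.
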