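---
title: "Covariate transformations for count-based gene signatures: models, choices, limits"
author: "countsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate transformations for count-based gene signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(countsig)
```

## The problem

RNA-Seq expression values are counts: their distributions are skewed, their
variance grows with their mean, and occasional entries are extreme enough to
dominate correlation estimates. Penalized regression methods used for
building prognostic gene signatures — componentwise likelihood-based
boosting, the lasso, ridge regression — are not invariant to covariate
scale. With a shared penalty $\lambda$, the penalized score statistic that
boosting uses to pick its next covariate,

$$ S_j \;=\; \frac{U_j^2}{I_j + \lambda}, $$

penalizes a high-variance covariate relatively less (its Fisher information
$I_j$ is large, so $\lambda$ matters less), so such covariates are selected
more often and shrunk less. On count covariates, variance is a proxy for
mean expression, not for prognostic relevance; the selection process is
therefore biased toward highly expressed genes. Transforming the covariates
before model fitting changes what gets selected and how well the resulting
signature predicts. `countsig` implements the ten candidate transformations,
the boosting and lasso fitters, and the evaluation machinery needed to
quantify these effects, plus a synthetic count generator so the whole
pipeline can be studied without any external data.

## Models and procedures

### Count generator

`generate_counts()` draws gene $g$, sample $i$ counts from a negative
binomial with mean $\mu_g s_i$ and variance $\mu_g s_i + \alpha_g (\mu_g
s_i)^2$:

* base means $\mu_g$ are log-normal (meanlog 3, sdlog 1.5), giving the
  heavy-tailed spread of expression levels seen in real data;
* dispersions $\alpha_g$ are log-normal around 0.2 (sdlog 0.7), so the
  log-variance vs. log-mean trend has slope above 1;
* library-size factors $s_i$ are log-normal (sdlog 0.25, geometric mean 1),
  so normalization is non-trivial;
* gene-gene correlation comes from a Gaussian copula with a shared latent
  factor per block of 50 genes (latent correlation 0.5);
* a fraction `extreme_value_rate` (default 0.001) of entries is multiplied
  by a uniform factor in [10, 50], reproducing the correlation-inflation
  artifact that motivates truncation.

What the generator does **not** emulate: isoform structure, gene-length
dependent counting (lengths are drawn independently of means and are used
only for binning informative genes), batch effects, and the long-range
correlation structure of real co-expression networks. Tests that pass on
this generator demonstrate correctness of the pipeline and reproduce
direction-of-effect findings; they do not certify performance numbers on
real cohorts.

### Preprocessing

`preprocess_counts()` applies, in order: removal of genes whose maximum
count is at most 10; median-of-ratios size factors (per sample, the median
over all-positive genes of the count divided by the gene's geometric mean);
and per-gene truncation at median + 3 IQR. Quartiles use linear
interpolation between order statistics (`stats::quantile` type 7 — the
convention matters because the truncation bound depends on it, and it is
recorded in every run manifest). Truncation is idempotent and only ever
reduces values, so it can be audited by re-application.

### The transformation registry

Ten tags: `naive`, `log`, `vst`, `boxcox`, their four standardized
compositions, `ranks`, and `blom`.

* **log**: $\log(x+1)$; the unit shift keeps zeros finite.
* **vst**: the dispersion $\alpha$ of the variance law $v(\mu) = \mu +
  \alpha\mu^2$ is estimated by regressing $s_g^2 - m_g$ on $m_g^2$ through
  the origin across genes (clamped at 0), and the transform is the closed
  form $w(x) = (2/\sqrt{\alpha})\,\mathrm{asinh}(\sqrt{\alpha x})$ — the
  integral of $1/\sqrt{v(\mu)}$ — falling back to $2\sqrt{x}$ as $\alpha
  \to 0$. This is deliberately a transparent moment-based estimator rather
  than a dispersion GLM: it is auditable in one line and accurate to well
  within the tolerance the studies need (a known $\alpha = 0.3$ is
  recovered within 20% from 2000 genes).
* **boxcox**: per gene, $((x+1)^\lambda - 1)/\lambda$ over the grid
  $\lambda \in \{-2, -1.75, \ldots, 2\}$, choosing the $\lambda$ with the
  highest Pearson correlation in a normal QQ-plot (Blom plotting
  positions). Candidates within $10^{-3}$ of the best correlation are
  treated as tied, and ties resolve toward $\lambda = 1$, then toward 0.
  The tolerance is a parsimony device: when the coefficient of variation is
  small every power transform is affine to within sampling noise of the
  QQ correlation (observed gaps $\sim 10^{-7}$–$10^{-4}$), while genuinely
  skewed genes separate by $\sim 10^{-2}$; without the tolerance the
  selector would pick an arbitrary neighbour of the identity on
  well-behaved genes.
* **standardize** (and compositions): per-gene mean 0, variance 1, SD with
  denominator $n-1$.
* **ranks**: within-gene ranks; genes containing ties first receive seeded
  Gaussian noise with SD $10^{-4}(\mathrm{IQR}_g + 1)$, so the transformed
  multiset is exactly $\{1, \ldots, n\}$ for every gene.
* **blom**: $\Phi^{-1}\!\big((r - c)/(n - 2c + 1)\big)$ with $c = 3/8$,
  mapping ranks to an identical normal-shaped multiset for every gene.

**Train/test discipline.** All data-dependent parameters (means, SDs,
$\lambda_g$, $\alpha$, the rank reference sample) are estimated on training
samples only (`transform_fit()`) and reused on held-out samples
(`transform_apply()`). Without this, prediction-error estimates leak
information. For the rank-based tags, a held-out value is placed at its
midrank against the *training* values — $\#\{x^{tr} < v\} + \tfrac12
\#\{x^{tr} = v\} + \tfrac12$ — keeping test covariates on the $1..n_{train}$
scale that the fitted coefficients expect; this choice is ours (rank
transforms have no canonical out-of-sample extension) and is the natural
monotone one.

### Boosting, penalty, and mandatory covariates

`boost_fit()` starts from zero penalized coefficients, and per step scores
every penalized covariate by $U_j^2/(I_j+\lambda)$ at the current fit,
updates the best one by the penalized Newton step $U_j/(I_j+\lambda)$
(score ties break toward the lowest column index, making paths
deterministic), and then refreshes the intercept and any mandatory
covariates with one unpenalized Newton step. At initialization the
intercept/mandatory block is fitted to convergence — the penalized path
then starts from the correct "clinical-only" model. The penalty derives
from a shrinkage factor $\nu$ (default 0.1) as $\lambda = (1/\nu - 1)
\times \sum_i w_i$ with $w_i$ the working weights of the null fit
($p(1-p)$ for logistic, 1 for the continuous special case, and the number
of events for the Cox model), so a unit-variance covariate's first update
is shrunk by about $\nu$. The continuous-response family is included
because it is the analytically transparent case: there boosting is
stagewise regression, and with orthonormal covariates and a small $\nu$
its coefficient path coincides with the lasso's soft-thresholding path —
both facts are kept as tests.

The Cox fitter never estimates the baseline hazard during fitting; the
Breslow estimator is computed afterwards only where survival probabilities
are needed for Brier scores.

### Lasso and tuning

The L1-penalized Cox path is solved by glmnet (`penalty.factor` 0 on the
mandatory block, `standardize = FALSE` — covariate scaling is the object of
study, so the solver must not re-scale behind our back). Solutions are
audited by an explicit KKT check on the partial-likelihood gradient
(`lasso_kkt_violation()`, accounting for glmnet's internal rescaling of
penalty factors to sum to the number of variables).

`cv_tune()` draws seeded folds stratified by outcome (logistic) or event
indicator (Cox). The Cox out-of-fold criterion is the full-minus-reduced
partial likelihood (the grouped criterion of cv.glmnet, reimplemented for
the boosting path); ties in the criterion resolve toward the smaller
model. Cox folds whose training part carries no events are redrawn, at
most ten times, with a warning.

### Evaluation

* **Selection curves**: walking a boosting path in step order, the partial
  area `pauc` is the mean over $f = 0..10$ of the best true-positive count
  achieved while at most $f$ false positives were in the model — the mean
  number of informative genes found within ten or fewer false positives.
  The path order is the only ordering available from a boosting fit, so
  curves are traced along it.
* **Prediction error**: censoring-weighted Brier curves with
  Kaplan-Meier censoring weights estimated on training data (floored at
  $10^{-3}$), survival predictions from the training-data Breslow
  baseline, a no-information curve that pairs every prediction with every
  outcome, and the 0.632+ combination
  $(1-w)\,\mathrm{app} + w\,\min(\mathrm{oob}, \mathrm{noinf})$ with $w =
  0.632/(1 - 0.368 R)$ and $R$ the clipped relative overfitting rate.
  IPEC integrates the 0.632+ curve by the trapezoid rule over training
  event times up to the 0.95 quantile of observed times (the upper limit
  is a convention, recorded in the manifest; Brier curves beyond the
  quantile rest on few subjects and IPEC would become unstable).
* **Added value**: $\Delta_k = 1 - \mathrm{IPEC}^{comb}_k /
  \mathrm{IPEC}^{clin}_k$ per split — zero when genes add nothing,
  negative when they hurt, the proportion of clinical prediction error
  eliminated when they help. This reconstruction is the unique form
  consistent with all three properties at once.

## The two studies

`run_simulation_study()` (identification): one generated matrix,
preprocessed once, all ten transformations fitted once; per replicate the
informative set is redrawn (one gene per gene-length bin so informative
genes span the length range), a common effect size is calibrated to the
target SNR, a binary outcome is simulated, and a fixed 500-step boosting
path per transformation is scored by `pauc`. Fixed-step paths (not
CV-stopped) are used here because identification is about the order in
which genes enter, not about a prediction-optimal stopping point.

**SNR definition.** The effect size solves $\mathrm{SNR}(b) = 2.5$ by
bisection (monotonicity checked on the bracket). The default SNR is the
latent-scale one, $\mathrm{Var}(\eta)/(\pi^2/3)$ — linear-predictor
variance over the variance of the standard logistic error — which is the
standard definition when a binary outcome is simulated from a logistic
model. The alternative `snr_def = "bernoulli"`,
$\mathrm{Var}(\eta)/\overline{\pi(1-\pi)}$, is retained and recorded in
run metadata. The latent definition is the default because, at the scale
this package runs its studies (200 samples, 2000 genes), the alternative
yields $\mathrm{Var}(\eta) \approx 0.55$, which puts every per-gene
association below the multiple-testing detection floor: all
transformations then score alike and the study degenerates into noise.
Under the latent definition ($\mathrm{Var}(\eta) \approx 8.2$) the
qualitative structure the study is designed to exhibit emerges clearly:
under linear effects every standardized and rank-based tag beats the
non-standardized ones; under logarithmic effects overall identification
improves, plain standardization of the raw scale falls behind the
correctly-specified transformations, and the rank-based and
standardized-log tags lead.

The linear predictor is centered across patients before applying the
logistic function: with all-positive covariates and positive effects an
uncentered $\eta$ would make nearly every patient a case, collapsing the
two-group design. Centering is an intercept; it changes no variance and
no ordering.

`run_resampling_study()` (prediction): per split (training fraction
0.632, matching the subsampling rationale of the 0.632+ estimator), the
transformation is fitted on training samples, a clinical-only Cox model
and combined clinical+gene models (CV-stopped boosting, CV-tuned lasso;
clinical block mandatory and unpenalized) are fitted on the training set,
and 0.632+/IPEC/added value are computed on that split. An optional
fixed-step run (200 steps in the shipped configuration) collects selected
sets for Table-style overlap accounting and selected-gene variance
summaries; the deliberately overfitted fixed-step models give stabler
selection characterization than CV-stopped ones.

### Problem sizes used

The shipped study configurations run at 2,000 genes x 200 samples with 10
replicates (identification) and 500 genes x 200 samples with 20 splits
(prediction), roughly a tenth of the real cohorts that motivate the
package; these sizes keep a full two-scenario study within a few minutes
on one core while leaving the qualitative contrasts testable. All scale
parameters are configuration fields.

## Numerical choices and degenerate inputs

* Quantile convention type 7 everywhere (truncation, IPEC upper limit).
* SD denominator $n-1$ (standardization, ridge scaling identity).
* Constant genes: standardization refuses them by name; Box-Cox returns
  $\lambda = 1$ with a warning; ranks break ties by seeded noise.
* Bisection tolerances: effect calibration to relative $10^{-6}$;
  censoring-level calibration solves the empirical censoring fraction
  exactly at a quantile of per-sample censoring thresholds and insists on
  hitting the target within 0.05.
* Boosting guards: working logistic weights floored at $10^{-10}$; a
  non-finite likelihood aborts with the step number; score ties break to
  the lowest index.
* IPCW weights floored at $10^{-3}$; the no-information curve uses
  training outcomes and training predictions.
* The KKT audit of glmnet solutions uses the objective scaling
  $-(1/n)\,\mathrm{pll} + \lambda P$ and passes at $10^{-6}$ with
  `thresh = 1e-12`.
* The data-derived lasso path stops at 5% of the critical penalty
  (`lambda.min.ratio = 0.05`): for $p \gg$ events the far tail of the
  path is badly conditioned (coordinate descent hits its iteration cap)
  and cross-validation never selects it. Explicit `lambda` grids are
  honored unchanged.

## Known limitations

* The VST uses a single pooled dispersion; per-gene dispersion trends
  (common in real data) are stabilized only on average.
* The rank/Blom out-of-sample midrank mapping is a convention; any
  monotone alternative (e.g. interpolated ECDF) would differ at the
  extremes.
* Added value compares IPECs split by split; it does not test
  calibration of the combined model.
* The generator's block-copula correlation is exchangeable within blocks;
  real co-expression is not.
* At 200 samples the identification study operates near the detection
  floor by design; individual replicate curves are coarse (multiples of
  1/11), which is why study-level claims are asserted on paired
  differences over replicates.
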