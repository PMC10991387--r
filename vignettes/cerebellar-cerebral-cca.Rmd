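---
title: "Methods: brain-behaviour CCA of cerebellar-cerebral connectivity"
author: "ccanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-behaviour CCA of cerebellar-cerebral connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Neurodevelopmental diagnoses (autism spectrum disorder, ADHD,
obsessive-compulsive disorder) overlap heavily in their behavioural
presentation, and a transdiagnostic view asks whether dimensional behaviour
measures — an attention-problems score, a social-communication score, an
obsessive-compulsive score — map onto shared patterns of brain functional
connectivity (FC) irrespective of categorical diagnosis. `ccanet` implements
that analysis for cerebellar-cerebral connectivity: it relates a matrix of
subject-level FC features to a small set of behaviour scores through
canonical correlation analysis (CCA), asks which canonical variates are
statistically significant and which coefficients are stable, clusters
subjects in variate space to look for latent subgroups, and scores whether
variates found in one cohort replicate in an independent cohort.

# Data model

## Connectivity features

Each scan provides a time series per region of interest (ROI) under a fixed
48-label parcellation: 17 cortical networks and 7 cerebellar networks, each
split into left and right hemisphere labels. Volumes are censored when
framewise displacement exceeds 0.5 mm or DVARS exceeds 0.5%, and a scan
fails quality control when more than a third of its volumes are censored.
Over the retained frames, the Pearson correlation matrix $\Sigma$ between
ROI time series is inverted to the precision matrix
$\Upsilon = \Sigma^{-1}$, and the partial correlation between ROIs $i$ and
$j$ is

$$\Pi_{ij} = -\frac{\Upsilon_{ij}}{\sqrt{\Upsilon_{ii}\,\Upsilon_{jj}}},
\qquad \Pi_{ii} = 1 .$$

Partial correlation measures the dependence between two regional signals
with the linear influence of every other region removed, which localizes
network edges better than full correlation. The matrix is Fisher
z-transformed elementwise ($z = \operatorname{atanh} r$; the diagonal is set
to 0 and never emitted) and its upper triangle — row-major in parcellation
order, $48 \cdot 47/2 = 1128$ entries — becomes the subject's feature
vector.

Inversion requires $\Sigma$ to be well-conditioned, which holds when the
number of retained frames comfortably exceeds the 48 ROIs. For shorter
series `partial_from_pearson()` refuses by default and offers an explicit
ridge (`ridge > 0` adds `ridge * I` before inversion); a silent fallback
would change the estimand, so the choice is always recorded in the call.

## Harmonization and nuisance control

Multi-site data carry additive and multiplicative site effects per feature.
`combat_adjust()` implements the standard parametric empirical-Bayes
location/scale model: per-feature standardization given protected
covariates, per-site mean ($\gamma$) and variance ($\delta^2$) estimates
shrunk toward a normal / inverse-gamma prior by iterative conditional
updates, then back-transformation. The implementation exposes the model
internals (pre- and post-shrinkage site effects, prior hyperparameters);
the test suite verifies numerical agreement with the `sva` reference
implementation to $10^{-4}$.

Two properties of the EB model are worth knowing. First, shrinkage pulls
per-feature site effects toward the cross-feature prior, so when a batch
effect is constant across features the residual site gap after adjustment is
of order $0.5\sqrt{2/n}$ rather than zero — a property shared by the
reference implementation. Second, by default nothing beyond an intercept is
protected during standardization; protecting the behaviour scores (the
safer modern practice when group composition differs by site) is available
via the `protect` argument of the pipeline configuration.

After harmonization, sex and viewing condition are removed by per-feature
ordinary least squares; residuals are mean-centred. Age is deliberately
**not** residualized, so that age differences between subject clusters
remain testable downstream.

## Canonical correlation with screening

FC features are screened before CCA: Spearman's $\rho$ is computed between
each feature and each behaviour score, with the two-tailed p-value from
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom, and a feature
is kept when it passes $p < 0.05$ against **any** score (a stricter
$p < 0.01$ variant is a configuration switch). The union rule keeps
features relevant to each variate, not only the first.

CCA then finds paired linear combinations (canonical variates) of the
screened FC block and the standardized behaviour block with maximal
correlation. The solver uses the QR/SVD formulation of the generalized
eigenproblem; the test suite checks it against a brute-force
eigendecomposition of
$\Sigma_{xx}^{-1}\Sigma_{xy}\Sigma_{yy}^{-1}\Sigma_{yx}$ and against
`stats::cancor` to $10^{-8}$. Coefficients are reported on standardized
inputs; variates have unit sample variance; each variate is oriented so its
largest-magnitude behaviour coefficient is positive (bootstrap redraws
inherit orientation through Procrustes alignment). When subjects do not
comfortably exceed columns the fit refuses, with a ridge-regularized
fallback (`ridge` on both block covariances) available explicitly.

## Inference

**Significance.** Rows of the behaviour block are permuted (10,000 times by
default) and CCA is refit on the *fixed* selected feature set. The statistic
for variate $k$ is the sequential Wilks' lambda
$\Lambda_k = \prod_{j \ge k} (1 - r_j^2)$ — the convention of standard CCA
significance packages — with $p_k = (1 + \#\{\Lambda_k^{perm} \le
\Lambda_k^{obs}\})/(n_{perm}+1)$. A max-correlation statistic is available
by configuration.

Holding the screen fixed inside the permutation loop follows the
screen-then-fit convention of biomarker-discovery CCA studies, and inherits
its known bias: because features were selected for correlation with the *observed*
scores, permuted refits are systematically disadvantaged and higher-order
variates can reach nominal significance under a global null. The type-I
calibration property therefore holds for a fixed (not data-selected)
feature set — which the test suite verifies — while end-to-end runs with
data-driven screening should treat small p-values on trailing variates with
caution. A nested re-screening per permutation is the unbiased (and much
more expensive) alternative and can be composed from the exported
functions.

**Stability.** Subjects are resampled with replacement (10,000 draws by
default), CCA refit on the fixed feature set, and each redraw's stacked
coefficient matrix $[A; B]$ is aligned to the original solution by
orthogonal Procrustes ($R = UV^\top$ from the SVD of the cross-product),
resolving rotation and sign indeterminacy. The per-coefficient bootstrap SD
divides the original coefficient to give $z$; $|z| > 1.96$ flags a stable
coefficient.

Coefficient-level inference has an identifiability limit worth stating
plainly: when the screened feature count is an appreciable fraction of the
sample size, individual CCA coefficients are noisy even though the variate
itself recovers the latent dimension almost perfectly. In simulations with
a planted component at $n = 400$ the fitted variate correlates with the
planted latent above 0.9 and the behaviour-weight direction is recovered
with cosine above 0.9, while the FC coefficient vector's cosine with the
planted loadings degrades as the selected-feature count grows. This is
exactly why the pipeline gates interpretation on bootstrap stability rather
than raw coefficients.

## Clustering

Subjects are clustered on their loading values for the variates that pass
permutation significance (the variate list is an explicit argument). The
affinity between subjects $i$ and $j$ is the scaled-exponential kernel

$$A_{ij} = \exp\!\left(-\frac{d_{ij}^2}{2(\mu\,\varepsilon_{ij})^2}\right),
\qquad
\varepsilon_{ij} = \tfrac{1}{3}\big(\bar d_i^{(k)} + \bar d_j^{(k)} +
d_{ij}\big),$$

with Euclidean $d_{ij}$, $\bar d_i^{(k)}$ the mean distance of $i$ to its
$k$ nearest neighbours (self excluded; $k = 10$, $\mu = 0.3$ by default),
symmetrized by averaging, self-affinity set to the row maximum. Clustering
uses the unnormalized Laplacian $L = D - A$, $D_{ii} = \sum_j A_{ij}$ — the
explicit formula this design states, chosen over the symmetric-normalized
variant common elsewhere — taking the eigenvectors of the $k$ smallest
eigenvalues and k-means with 50 restarts (best within-cluster sum of
squares; deterministic given the seed). Global rescaling of $A$ leaves the
Laplacian eigenvectors unchanged, so the kernel's overall constant is
irrelevant to the assignments.

Cluster counts $k = 2..10$ are scored by the Calinski-Harabasz index
$[\mathrm{tr}(B)/(k-1)] / [\mathrm{tr}(W)/(n-k)]$ (reported as `Inf` when
within-cluster scatter is exactly zero). Stability is the distribution of
the Rand and adjusted Rand indices between the original assignment and
re-clusterings of random subsets drawn without replacement (fraction 0.8 by
default, 10,000 resamples; the fraction is a configuration value since the
design leaves it open). Post-hoc, each cluster's diagnostic-category counts
are tested against whole-cohort proportions by a chi-squared
goodness-of-fit with $df = 3$ for four categories, and age, IQ and
in-scanner motion are compared across clusters by one-way ANOVAs.

## Replication scoring

Two cohorts analysed with the same score roles (the obsessive-compulsive
score may come from different instruments) are compared through their
coefficient vectors. Behaviour vectors are correlated directly for every
variate pair. FC vectors are first collapsed to the bilateral macro-network
parcellation: every ROI-pair feature maps to the unordered pair of its
endpoints' macro networks, the collapsed coefficient is the mean of its
constituents, and a collapsed entry is stable when at least one constituent
is stable (a majority rule is available). The 17 cortical networks collapse
to 7 bilateral macro networks — the temporoparietal subdivision folds into
the default mode network, following the usual 17-to-7 correspondence — and
the 7 cerebellar networks collapse to their bilateral selves, giving 14
macro networks; the mapping lives in the parcellation table and is fully
overridable. Collapsing by aggregation of the fitted coefficients (rather
than refitting CCA at collapsed resolution) is the default because the
stable-feature intersection step operates on the fitted vectors; the refit
interpretation can be composed from the exported functions.

For each variate pair the FC correlation runs over the collapsed features
stable in *both* cohorts (skipped with a recorded reason below 3 common
features). Correlations are Pearson's $r$ with
$t = r\sqrt{(n-2)/(1-r^2)}$, $df = n - 2$, and two-tailed $p$ from the $t$
distribution — note that with three-score behaviour vectors $df = 1$ and
the $t$ distribution is extremely heavy-tailed, so even $|r| \approx 0.99$
yields $p \approx 0.09$; reported p-values follow the $t(df)$ computation
exactly. A pair is declared replicated when both $|r|$ values exceed their
thresholds (0.9 behaviour, 0.5 FC by default). Sign flips between cohorts
are rotation artifacts of CCA and carry no meaning; magnitudes decide.

# The synthetic-cohort generator

Real cohorts of this kind are controlled-access, so the package ships a
generator that plants known structure for every stage to recover. For each
component $k$, a standard-normal latent $u_k$ per subject drives both
blocks:

* behaviour scores: $s = \sum_k \rho_k w_k u_k + \epsilon$, then
  diagnosis-linked mean shifts (ASD on the social score, ADHD on attention,
  OCD on the obsessive-compulsive score; 0.5 by default);
* FC features: $x = \sum_k a_k u_k + e$, then sex and viewing effects on
  fixed feature subsets, then per-site scale and offset.

Weights $w_k$ and loadings $a_k$ are unit norm; with behaviour noise SD
$\sqrt{1 - \rho_1^2}$ the optimal behaviour combination correlates with the
latent at exactly $\rho_1$, so the leading population canonical correlation
is $\rho_1$ times the FC block's latent-recovery correlation
$1/\sqrt{1 + \sigma_x^2}$ (0.97 at the default $\sigma_x = 0.25$). The
default component concentrates behaviour weight on the first score, which
keeps pairwise score correlations below 0.3 — matching the low collinearity
regime this analysis assumes — and concentrates FC support in four
macro-network pairs with a common sign within each pair, the way real
connectivity effects are organised by network. Diagnosis mixture defaults
to 0.19/0.36/0.34/0.11 (TD/ASD/ADHD/OCD).

Generation can emit features directly or ROI time series whose per-subject
covariance is the network-block base matrix plus a latent-modulated
symmetric perturbation along the component's support (coupling 0.12,
chosen once so both levels express the same downstream canonical
correlation; perturbations are halved until positive definite, with a
warning). Twin cohorts share component directions, with a `divergence`
fraction mixing in random directions for cohort B and the third score
re-expressed through a second instrument correlating at 0.51 with the
first.

What the generator does **not** emulate: temporal autocorrelation and
physiological noise in the time series, heavy-tailed score distributions,
site-by-diagnosis confounding, and missingness mechanisms. Passing tests
demonstrate the statistical machinery recovers planted structure under
Gaussian assumptions; they do not certify behaviour on real fMRI data.

# Numerical choices and degenerate inputs

* Singular $\Sigma$: hard error naming the remedy (ridge or longer
  series); ridge default 0.
* Constant features: passed through harmonization unchanged with a
  warning; dropped from the Spearman screen with a warning; hard error in
  standardization.
* Duplicate subjects in the affinity kernel: the local scale is floored at
  machine epsilon scale with a warning.
* Rank-deficient bootstrap draws: redrawn, with the count reported.
* k-means ties: broken by best inertia across 50 seeded restarts.
* Permutation p-values use the $+1$ correction, so zero exceedances report
  $1/(n_{perm}+1)$, never 0.
* All resampling is seeded per stage; identical configurations reproduce
  every number bit-for-bit.

# Problem sizes used by the test suite

The shipped tests exercise the pipeline at sizes a laptop handles in
minutes, chosen as the smallest scales at which each property is
statistically decisive: oracle identities on 100-1,000 random 3-6 variable
instances; permutation calibration on 500 null datasets of 100 subjects by
20 features at 500 permutations; stability recovery over 50 planted cohorts
of 300 subjects at 500 bootstraps; cluster recovery over 50 planted
three-cluster datasets of 120 points (centre separation six radial SDs);
twin replication at 400 subjects per cohort with the full 1128-feature
scheme for the behaviour panel and the 91-feature cerebellar scheme for the
FC panel, where coefficients are identifiable at that sample size.

# Known limitations

* In-sample canonical correlations are optimistic when the selected
  feature count approaches the sample size; the permutation test calibrates
  the leading variate under a fixed feature set, but out-of-sample
  correlation estimation (cross-validated CCA) is out of scope.
* The screen-then-fit procedure biases higher-order variate p-values
  anti-conservatively (see above).
* Parametric EB harmonization only; nonparametric priors and longitudinal
  designs are out of scope.
* FC coefficient vectors are only interpretable jointly with their
  stability flags at realistic feature counts.
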