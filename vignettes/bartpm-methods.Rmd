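---
title: "Sum-of-trees exposure modelling with calibrated prediction intervals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sum-of-trees exposure modelling with calibrated prediction intervals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`bartpm` estimates daily concentrations of a PM2.5 component (elemental
carbon, organic carbon, sulfate or nitrate, in µg/m³) at monitor-days from a
table of predictors, using Bayesian additive regression trees (BART). The
response is modelled as a sum of $K$ regression trees,

$$y_i = \sum_{k=1}^{K} T_k(M_k;\, x_i) + \varepsilon_i,\qquad
  \varepsilon_i \sim \mathcal N(0, \sigma^2),$$

where each tree $T_k$ routes the predictor vector $x_i$ through binary rules
of the form $x_{ij} \le c$ (ties go left) until a terminal node is reached,
and contributes that node's scalar value $\mu_{lk}$ to the prediction.
Regularization comes entirely from the priors:

* **Tree depth.** A node at depth $d$ is internal with probability
  $\alpha (1+d)^{-\beta}$, $\alpha \in (0,1)$, $\beta \ge 0$; larger values of
  either favour smaller trees. At each internal node the split variable is
  drawn from a probability vector over the $P$ predictors (uniform $1/P$, or
  a Dirichlet-distributed vector when sparsity-inducing variable selection is
  enabled), and the threshold is uniform over the observed unique values of
  the chosen predictor.
* **Leaf values.** Terminal values are
  $\mathcal N(m_0, \sigma_\mu^2)$ with $m_0 = (\max y - \min y)/(2K)$, a
  ridge-like shrinkage of each tree's contribution. A single $\sigma_\mu^2$
  is shared across all trees and sampled; its posterior tracks the overall
  variability of the response, so components with more variable
  concentrations show larger $\sigma_\mu^2$.
* **Variances.** $\sigma^2$ and $\sigma_\mu^2$ carry noninformative
  inverse-Gamma priors (defaults: shape/scale $0.001/0.001$ for $\sigma^2$;
  $3/1$ for $\sigma_\mu^2$, both on the standardized response scale).

Fitting is by Metropolis-within-Gibbs backfitting: each tree in turn is
updated against the partial residuals of the other $K-1$ trees with a
GROW / PRUNE / CHANGE proposal (probabilities 0.28 / 0.28 / 0.44; moves that
are structurally impossible, such as PRUNE on a single-leaf tree, are
resampled), accepted by a Metropolis–Hastings ratio in which the leaf values
are integrated out analytically. Leaf values, $\sigma^2$, $\sigma_\mu^2$ and
the split probabilities are then redrawn from conjugate full conditionals.
Proposals that would route no training row into some leaf are rejected
outright, which keeps every conjugate update proper.

Point predictions are posterior means over the retained draws; 95%
*prediction* intervals are the empirical 2.5th–97.5th percentiles of the
posterior predictive samples, i.e. each retained draw's forest prediction
plus a $\mathcal N(0, \sigma^2_{(s)})$ noise draw. We use predictive rather
than credible intervals because interval quality is judged by the coverage of
*held-out observations*, which include their own measurement-day noise.

## Numerical choices

The response is internally centred at its midrange and scaled by its range,
so that it occupies $[-0.5, 0.5]$; the leaf prior mean and all variance
hyperpriors act on that scale and every output is transformed back. A useful
consequence, which the test suite asserts exactly, is scale equivariance:
refitting on $c\,y$ with the same seed reproduces the same chain with
$\sigma^2$ and $\sigma_\mu^2$ multiplied by $c^2$.

The production sampler is compiled (C++ via Rcpp) and consumes its own
64-bit RNG stream seeded from `sampler_control(seed=)`, so runs are
bit-reproducible regardless of the R session's RNG state. The identical
kernel is also implemented in pure R (`backfit_iteration()` and the
`update_*` functions) as a readable reference; the tests check the two
routes against each other and check the conjugate updates against dense-grid
numerical posteriors.

Default settings are $K = 50$, $\alpha = 0.95$, $\beta = 2$ — a deliberately
smaller and shallower forest than the 200-tree default common in BART
software, because large default forests tend to underestimate $\sigma^2$
and produce prediction intervals that undercover. `tune_for_coverage()`
reproduces this calibration: it fits a candidate grid of
$(K, \alpha, \beta)$, computes in-sample 95%-interval coverage for each, and
selects the candidate closest to the 0.95 target, breaking ties toward fewer
trees and then larger $\beta$.

# The evaluation designs

Three 10-fold cross-validation designs probe increasingly hard prediction
tasks. Ordinary CV holds out 10% of monitor-days at random (interpolation at
monitored locations). Spatial CV holds out 10% of monitors (prediction where
no monitor exists). Spatial-cluster CV first groups the monitors into 10
k-means clusters on (longitude, latitude) — computed once for the dataset,
with 10 random restarts — and holds out one cluster per fold (prediction in
regions without nearby monitors). In the spatial designs all rows of a site
share the site's fold.

Metrics are the squared Pearson correlation $R^2$, the RMSE, and the
empirical coverage of the nominal 95% prediction intervals (Cvg95), pooled
over all held-out predictions jointly; per-fold values are also reported.
Pooling is the common convention for CV $R^2$ and makes Cvg95 a simple
proportion over all held-out rows. When observations or predictions are
degenerate (zero variance), $R^2$ is reported as undefined rather than 0, so
constant predictors are not silently rewarded.

# What the synthetic generator emulates

The real inputs behind this kind of exposure model — speciation-network
monitors, satellite aerosol optical depth (AOD), chemical-transport-model
(CMAQ) simulations, assimilated meteorology, land-use layers — are large and
proprietary-scale. The generator replaces them with parametric surrogates
that keep the *statistical design*: a network of ~40–55 monitors placed as a
few regional blobs plus background over a California-sized window, a
1-in-6-day sampling schedule (`sampling_rate = 1/6`, treated as missing
completely at random), and four predictor families.

The latent mean of the measured component is

$$m_1 = 2 + \underbrace{2\sin(\pi \tilde m_1 \tilde m_2)
        + 3(\tilde m_3 - 0.5)^2}_{\text{meteorology (Friedman-type)}}
      + \underbrace{0.4\,lu_1 + 0.2\,lu_2}_{\text{land use}}
      + g(\text{lon}, \text{lat})
      + \underbrace{0.4 \sin(2\pi t / 360 + 1)}_{\text{seasonality}}
      + \xi_{st} + u_s + v(\text{lon}, \text{lat}),$$

where $\tilde m_j$ are logistic transforms of the meteorology-like columns,
$g$ is a smooth surface with a planted high-concentration bump (a
central-valley analogue) plus a latitude gradient, $\xi_{st}$ is unmeasured
day-to-day variation (sd 0.5), $u_s$ is an iid site effect (sd 0.2), and $v$
is a random regional field built from 25 Gaussian bumps with a 0.8°
length-scale (a low-rank stand-in for a Gaussian process, chosen for
desk-scale cost). Additional latent components $m_2, \dots, m_C$ stand in
for the other species. The observables are then

* `cmaq_j` $= m_j^{\text{coarse}} + \mathcal N(0, 0.5^2)$, where the coarse
  version of $m_1$ *excludes* $u_s + v$ — a coarse-grid simulation does not
  resolve sub-grid structure;
* `aod_*`: the first half of the family loads on $m_1$ minus the site-local
  effect (satellite products resolve regional but not site-scale variation),
  the rest only on the other components;
* `noise_*`: iid standard normals, independent of the response;
* `pm25_total` $= \sum_c m_c + \mathcal N(0, 0.5^2)$ — a collocated
  total-mass measurement;
* $y = m_1 + \mathcal N(0, \sigma_{\text{true}}^2)$ with
  $\sigma_{\text{true}} = 0.5$ µg/m³ by default, and $m_1$ stored as
  `true_mean`.

These choices were fixed once so that the generator reproduces, jointly, the
qualitative structure the method is known for: cross-validated $R^2$ around
0.70–0.77 (moderate signal-to-noise, comparable to published speciation
models), ordinary-CV interval coverage near 0.95, spatial-CV coverage above
0.90 but below ordinary CV, an $R^2$ ordering
ordinary $\ge$ spatial $\ge$ cluster, and higher accuracy and lower
posterior $\sigma^2$ when the total-mass column is included. The mechanism
behind the last three is the $\xi, u, v$ terms: they are invisible to the
baseline covariates, partially visible to the proxies, and the site/regional
parts are only learnable from a monitor's own history or its neighbours.

What the generator does **not** emulate: informative missingness of
satellite retrievals, heteroscedastic or skewed measurement error,
small-scale spatial autocorrelation beyond the low-rank field, sampler
artefacts from network harmonization, or real geography. Passing tests
therefore demonstrate that the machinery is correct and calibrated under a
known, well-specified data-generating process — not that any particular real
dataset would achieve these numbers.

# Interpretation outputs

Variable importance is the *split-use proportion*: the number of times each
predictor is used in a splitting rule, summed over every internal node of
every retained draw, normalized to sum to one. Partial dependence
(marginal effect) of predictor $j$ at value $v$ is the average prediction
over background rows with $x_{ij}$ set to $v$, averaged over draws, with
pointwise 2.5%/97.5% bands over draws; the background population is the
training set, capped at 1000 evenly-spaced rows for tractability. Gridded
prediction averages daily posterior-mean predictions into a period mean per
cell and reports uncertainty as the average of the daily posterior
prediction standard errors (the literal reading of "average prediction
standard error"); the standard error of the period mean itself is available
via `se = "period_mean"`. Grid maps are intended for synthetic domains of at
most ~50×50 cells — statewide kilometre-scale gridding is out of scope.

# Problem sizes and open choices

The packaged analyses run at desk scale: the acceptance study uses ~4,800
monitor-days (40 monitors, 720 days, 1/6 sampling, 19 predictors) with
burn-in 1000 and 500 retained draws, scaled down from the 8000/2000 used in
full-scale analyses; property tests use ~1,000–2,000 rows with shorter
chains. Where the methodology leaves genuine choices, this package resolves
them as follows, for the reasons given: a single pooled $\sigma_\mu^2$
across trees (a single reported posterior for it implies it is sampled and
shared); posterior-predictive rather than credible intervals (coverage is
evaluated on observations); pooled rather than fold-averaged CV metrics;
k-means clustering computed once per dataset rather than per fold;
in-sample (not cross-validated) coverage as the tuning criterion; and
GROW/PRUNE/CHANGE with leaf-marginalized acceptance ratios as the sampling
kernel, the simplest correct choice in the BART literature.

Known limitations: no heteroscedastic, probit or multinomial variants; no
random effects; no spatial autocorrelation in the residual (longitude and
latitude enter only as split candidates); the Dirichlet concentration for
variable selection is fixed (default 1.0) rather than given a hyperprior;
and k-means cluster folds can be unbalanced by design when monitors are
strongly clustered, which is precisely the regime the design is meant to
probe.
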