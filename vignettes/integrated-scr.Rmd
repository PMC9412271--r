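---
title: "Integrated spatial capture-recapture with occupancy and telemetry data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated spatial capture-recapture with occupancy and telemetry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrim)
```

## The estimation problem

Spatial capture-recapture (SCR) estimates animal density from detections of
*identified* individuals at detectors with known coordinates. For species
with few or no usable natural marks, identified detections are expensive:
they require live trapping and physical tagging, and a trapping grid large
enough to span individual movement is often infeasible. Camera traps, by
contrast, produce abundant detections cheaply — but without identity.

`scrim` implements an integrated model that combines three data types that
share one latent spatial process:

1. **SCR capture histories** — individual-by-trap encounter counts from a
   live-trapping grid;
2. **occupancy (detection/nondetection) records** — per-camera counts of
   occasions with at least one detection of the species, identity unknown,
   typically over a larger area;
3. **telemetry fixes** — locations of a small subset of tagged individuals.

The pay-off is precision: detection/nondetection data sharpen the density
estimate, and telemetry sharpens the movement scale, without additional
invasive sampling.

## Model

Activity centers $s_i$ of the $N$ individuals are uniform on a rectangular
state space $S$ (a homogeneous point process), and density is $D = N/|S|$.
The expected encounter rate of individual $i$ at detector $j$ is half-normal
in the distance $d_{ij} = \lVert s_i - x_j \rVert$:

$$\lambda_{ij} = \lambda_0 \exp\!\left(-\frac{d_{ij}^2}{2\sigma^2}\right),$$

with a separate baseline $\lambda_0$ per detector class (live trap vs
camera) and a single shared scale $\sigma$ (km). Rates become per-occasion
detection probabilities through the complementary log-log link
$p = 1 - e^{-\lambda}$, and occasions are collapsed per detector (no
temporal variation in detection), so:

* SCR: $y^{scr}_{ij} \sim \mathrm{Binomial}(K_j,\, p^{scr}_{ij})$;
* occupancy: $y^{occ}_j \sim \mathrm{Binomial}\!\left(K_j,\,
  1 - \prod_i (1 - p^{occ}_{ij})^{z_i}\right)$ — a camera detects on an
  occasion when *at least one* member of the population does, which under
  the cloglog link is $1 - \exp(-\sum_i z_i \lambda^{occ}_{ij})$;
* telemetry: fixes of tagged individual $i$ are
  $\mathrm{BVN}(s_i, \sigma^2 I)$, reading $\sigma$ as the scale of a
  stationary bivariate-normal utilization distribution. Fixes are thinned
  to one per survey day to blunt temporal autocorrelation.

Unknown $N$ is handled by data augmentation: a super-population of $M$
slots with inclusion indicators $z_i \sim \mathrm{Bernoulli}(\psi)$,
observed individuals pinned at $z = 1$. Realized abundance is
$N = \sum_i z_i$. Tagged individuals come from the capture cohort, so their
activity centers are informed jointly by captures, camera data and fixes.

A trap-level binary bait covariate can enter the live-trap baseline,
$\log \lambda_{0j} = \beta_0 + \beta_1 b_j$, with its inclusion sampled by
reversible jump. The source design wrote this covariate with a logit link
on $\lambda_0$; since $\lambda_0$ is a rate (unbounded above), we default
to the log link and expose `cov_link = "logit"` for comparability — the
choice only matters for the covariate model itself.

## Inference

`run_fit()` runs independent Metropolis-within-Gibbs chains (compiled with
Rcpp) with a systematic scan:

* $z_i$ — exact Gibbs draws from the full conditional
  $\psi L_i / (\psi L_i + 1 - \psi)$, where $L_i$ multiplies the all-zero
  SCR mass and the occupancy likelihood ratio of flipping $z_i$;
* $s_i$ — per-individual random walks (proposals outside $S$ rejected);
  slots with $z_i = 0$ are refreshed from the uniform prior;
* $\sigma$, $\lambda_{0}$'s, $\beta$'s — random-walk Metropolis on the log
  (or natural) scale; $\psi$ — conjugate Beta draw;
* optional reversible-jump toggle of the bait effect, proposing $\beta_1$
  from a fixed normal proposal with the exact trans-dimensional ratio.

Proposal scales adapt toward 0.35 acceptance by Robbins-Monro **during
burn-in only**, so the retained kernel is fixed and valid. Default priors
are the vague choices standard in BUGS-style SCR: $\psi \sim \beta(1,1)$,
$\sigma \sim U(0, 5\,\mathrm{km})$, $\lambda_0 \sim U(0,1)$ per class,
$\beta \sim N(0, 10^2)$, prior inclusion probability $0.5$. All are
configurable; none are claimed to match the original analysis, whose priors
live only in its deposited code.

Summaries (`posterior_summary()`) report mean, SD, central 95% credible
interval, CV = SD/mean, split-chain $\hat R$ and an autocorrelation-based
effective sample size. The point estimate is the **half-sample mode** of
the pooled draws — robust for the right-skewed posteriors of $D$ — with a
KDE mode as an alternative. Non-convergence is reported, never raised.

### Numerical choices

* $\log(1 - e^{-\Lambda})$ is evaluated with `expm1`/`log1p` branches to
  stay accurate for small and large rates.
* The occupancy union term is maintained as per-camera sums
  $\Lambda_j = \lambda_{0c} \sum_{z_i=1} e^{-d_{ij}^2/2\sigma^2}$, which are
  linear in the baselines — so $z$ flips, baseline updates and per-individual
  moves cost no full-likelihood recomputation.
* Detectors with $K_j = 0$ are dropped with a warning; individuals captured
  once still contribute (no minimum-recapture filter).
* Binomial normalising constants are dropped inside the sampler (they
  cancel in every ratio); the pure-R likelihoods keep them and serve as the
  oracle the compiled code is tested against (exhaustive enumeration on
  toys, total-variation check of the $z$ marginal).
* The augmentation default is $M = 300$: the default generator world has
  $E[N] \approx 84$ on $\approx 240\ \mathrm{km}^2$, and the weakly
  informed SCR-only posterior has a long upper tail. `run_fit()` warns if
  posterior mass of $N$ touches $M$; mode-based point estimates are
  insensitive to residual tail clipping.

## The synthetic world

`scenario_config()` + `simulate_scenario()` generate a full dataset that
emulates a Mediterranean mesocarnivore survey:

* 60 live traps in 12 clusters (about 177 m between neighbouring traps,
  envelope about 9 x 6 km), 17 occasions each, alternating bait covariate;
* 40 cameras on a jittered 10 x 4 grid (mean nearest-neighbour spacing
  about 1.27 km), active 52-98 days, in a larger envelope that only
  partially overlaps the trap clusters. The printed envelope (12,174 ha)
  and the printed spacing cannot both hold exactly for a homogeneous
  40-point grid; the generator reproduces the spacing statistic, which is
  what drives detection overlap, and lands within about 20% of the
  envelope;
* state space = detector bounding box buffered by 2 km (about
  3.3$\sigma$), area about 240 km²;
* truth: $D = 0.35$ individuals/km², $\sigma = 0.6$ km; baselines are
  *solved* (by fixed-seed Monte-Carlo integration and `uniroot`) so that
  the expected totals match the emulated study: about 21 live captures and
  about 97 camera detections — mirroring how the original design chose
  rate and effort jointly. Four captured individuals carry 20 fixes each.

Data-preparation transforms are first-class operations: `quantize()`
(daily counts to binary), `thin_telemetry()` (one fix per individual-day),
and `dilute_occ()` (hypergeometric removal of detection events to a fixed
retained total, used by the precision-vs-sample-size experiment).

What the generator does **not** emulate: behavioural responses to traps,
movement-correlated (non-iid) telemetry, photo-event bookkeeping within 30
minutes, and inhomogeneous density. A green simulation test therefore
establishes correctness of the inference machinery under the model's own
assumptions — not robustness to their violation.

## Goodness of fit

`posterior_predictive_check()` simulates replicate capture histories from
posterior draws (conditioning on the drawn latent state), and compares
observed and replicated **Freeman-Tukey** discrepancies
$\sum (\sqrt{y} - \sqrt{E[y]})^2$ at three aggregation levels: individual x
trap cells, individual totals, and trap totals. The Bayesian p-value is the
proportion of draws whose replicate discrepancy exceeds the observed one
(ties counted one half). The discrepancy functional itself is a declared
convention (the source text names only the aggregation levels; Freeman-
Tukey is the worked choice in the standard SCR reference), so published
p-values are not treated as exact targets; a chi-square flavour is
available via `fun = "chisq"`.

One conditioning choice matters for calibration: individuals enter the
capture data only if they were encountered at least once, so replicate
histories are likewise conditioned on one or more encounters per observed
individual. Without this, replicated individual totals include zeros the
observed data cannot contain, and the individual-level p-values drift to
the boundaries even under a perfectly specified model.

## Experiments

* `run_sim_study()` — repeated datasets from one world, all four variants
  (SCR, SCR-Tel, SCR-Occ, SCR-Occ-Tel) fitted to the same data, aggregated
  to relative bias and RMSE of mode estimates. Geometry is fixed across
  datasets, as it is in a real deployment. Expected qualitative outcome,
  which the acceptance tests assert: occupancy integration reduces the
  (negative) bias of $\hat D$, telemetry slashes RMSE of $\hat\sigma$, and
  the full model does best overall.
* `run_dilution_study()` — thins the occupancy detections to fixed totals
  (e.g. 77/58/38/19 of 96) and tracks the CV of $\hat D$: precision decays
  monotonically as detections are removed. By default the removals are
  nested within a replicate (one random event permutation, each level
  keeping its first $L$ events): each level is still marginally a uniform
  subsample, but the positive correlation across levels sharpens the
  between-level comparison at a fixed replicate budget.
* `compare_variants()` — the case-study-style table: mean/mode/SD/CRI/CV
  per parameter and variant plus percent CV reductions relative to plain
  SCR.

## Known limitations

* Closed population, homogeneous density, no covariates on $\sigma$; the
  marginalized (non-augmented) likelihood and HMC backends are out of
  scope.
* The real case-study dataset is an external archive; without it the
  package demonstrates the pipeline on a clearly-labelled synthetic
  stand-in with the same detection totals.
* Split-$\hat R$/ESS are textbook implementations, adequate for the chain
  lengths used here; rank-normalized variants are not provided.
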