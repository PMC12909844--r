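---
title: "Inferring hidden niche axes from presence/absence community data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring hidden niche axes from presence/absence community data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgllvm)
```

## The problem

Regional biodiversity surveys — in particular eDNA metabarcoding surveys of
coastal waters — produce a species-by-site detection matrix together with a
small set of measured environmental covariates. Species distributions are
shaped not only by those covariates but by processes that are hard or
impossible to measure: unrecorded environmental gradients, dispersal
limitation, biogeographic history. In a joint species distribution model
these unmeasured drivers leave a signature in the *residual co-occurrence*
of species, which can be captured by a small number of latent variables.
When the latent variables are also given spatial structure, they can be
read as *hidden niche axes*: smooth spatially referenced gradients to which
many species respond.

`sgllvm` implements the full inference chain around that idea:

1. preprocessing of detection tables (rarefaction, occupancy and
   species-complex filters, missing-covariate site removal);
2. descriptive structure (district richness summaries, Jaccard distances,
   t-SNE ordination);
3. the core model — a Bernoulli generalised linear latent variable model
   (GLLVM) with spatially autocorrelated latent variables, site random
   effects and environmental covariates;
4. cross-validated selection among candidate models;
5. variance partitioning of the linear predictor;
6. the latent niche space: kernel-density species niche centres, zero-level
   biogeographic boundaries on interpolated latent surfaces;
7. the expected response diversity of local communities, with spectral
   clustering and log-log richness regressions.

A synthetic-community generator with full ground truth drives all recovery
tests.

## The model

For species $j$ at site $i$,

$$y_{ij} \sim \mathrm{Bernoulli}(p_{ij}), \qquad
\mathrm{logit}(p_{ij}) = \beta_{j0} + x_i^\top \beta_j +
u_i^\top \gamma_j + \alpha_i ,$$

where $x_i$ are standardized environmental covariates, $u_i$ the values of
$L$ latent variables at site $i$, $\gamma_j$ the species' loadings on those
axes, and $\alpha_i$ a site random effect absorbing differences in total
eDNA concentration or detectability. Each latent field follows a zero-mean
Gaussian process with Matérn correlation
$r(d) = \frac{2^{1-\nu}}{\Gamma(\nu)} (\kappa d)^\nu K_\nu(\kappa d)$,
$\kappa = \sqrt{8\nu}/\rho$, so the range $\rho$ is the distance at which
correlation falls to about 0.14. In estimation the field prior is carried by
a sparse precision built by nearest-neighbour conditioning (a Vecchia-type
Gaussian Markov random field); with full conditioning this reproduces the
dense Matérn covariance exactly, which is the oracle used in the tests.

### Identifiability conventions

* Loadings: $\gamma_{lj} = 0$ for species index $j < l$ and
  $\gamma_{ll} > 0$ — the standard GLLVM triangular constraint. Latent
  axes are therefore only determined up to this convention; recovery tests
  align estimate and truth by orthogonal Procrustes before comparing.
* Scale: each latent field is constrained to unit root-mean-square inside
  the objective and the loadings carry the scale. Without this, a
  penalized joint objective is degenerate along $u \to cu$,
  $\gamma \to \gamma/c$ (the penalty prefers $c \to 0$ while the
  likelihood is indifferent), which we observed as collapsing fields and
  exploding loadings. The convention also matches how the latent axes are
  reported downstream: `site_niche_positions()` returns fields scaled to
  unit standard deviation, with loadings rescaled accordingly — a
  model-invariant representation of $u^\top\gamma$.

## Estimation

The fit maximizes a penalized Bernoulli log-likelihood over intercepts,
covariate coefficients, loadings, latent fields and site effects jointly
(L-BFGS-B with analytic gradients): the latent fields carry the GMRF
penalty $\tfrac12 u_l^\top Q_l u_l$, site effects a Gaussian penalty
$\tfrac12 \alpha_i^2/\sigma_\alpha^2$. This is the
maximum-a-posteriori member of the Laplace/variational family; the
hyperparameters are updated between outer iterations:

* **Ranges $\rho_l$** — profile Gaussian-process likelihood of each fitted
  field (numerically zero nugget: the MAP field is a posterior mean,
  already smoothed by the prior, and a free nugget trades off against the
  range and pushes the estimate to its cap). Estimates are capped at the
  site-set diameter, beyond which the range is not identifiable on a
  bounded domain; because MAP fields partly track site-level signal, the
  estimates tend to read short of the generative range — they order the
  axes by spatial scale rather than recover it exactly.
* **$\sigma_\alpha$** — Laplace EM update
  $\sigma_\alpha^2 \leftarrow \mathrm{mean}(\hat\alpha_i^2 + v_i)$ with
  $v_i$ the per-site Laplace variance.
* **Covariate shrinkage** — coefficients carry Gaussian shrinkage whose
  per-covariate precision is re-estimated by an empirical-Bayes EM fixed
  point. A covariate with no real effect collapses to a near-zero prior
  variance, so chance correlations do not leak into the variance
  partition; covariates with real effects keep a mild ($\approx$
  standard-normal) prior.
* Loadings and intercept deviations from the prevalence logit keep a fixed
  standard-normal shrinkage (`ridge = 1`), which guards against
  quasi-separation for rare species.

Initial values matter: random initialisation reliably finds one-axis local
optima. The fit therefore initialises the latent structure from a singular
value decomposition of working logit-scale residuals, rotated to the
triangular constraint.

The recorded objective trace contains the accepted (improving) values
only, and is non-increasing by construction; `convergence` reports the
optimizer's exit status.

### Prediction at new sites

Latent fields at unvisited sites are kriged: the Gaussian-process
conditional mean of the fitted field under the fitted Matérn correlation.
Predictive uncertainty adds the GP conditional variance plus the
propagated Laplace estimation variance of the training-site field values,
and the returned probability marginalizes the Gaussian uncertainty of the
linear predictor with the standard logistic-normal approximation
$p \approx \mathrm{logit}^{-1}\!\big(\eta/\sqrt{1 + c^2\sigma^2}\big)$,
$c^2 = (16\sqrt3/(15\pi))^2$. Prediction at a training site returns the
fitted probabilities exactly (sites are matched by id). Far from all
training sites the latent contribution decays to zero and the prediction
reduces to the covariate-only value.

### Cross-validated model selection

`cross_validate_select()` partitions sites into $k$ random folds (shared
across all candidates), fits each candidate on $k-1$ folds, and scores the
held-out sites by mean per-cell negative log-likelihood under the
marginalized predictive probabilities. The canonical candidate grid
(`candidate_model_grid()`) crosses covariate sets with latent dimensions
0–5; three sets give 18 candidates.

A caveat established on synthetic data: with two true latent fields, a
*single* fitted axis blends both fields into one best-predicting
combination, so the held-out gain of the second axis is small, and at
moderate problem sizes (around 100 sites and 40 species) the selection
between one and two axes sits within ~0.002 NLL and can go either way.
Selection against zero or clearly-too-many axes is sharp. Larger surveys
separate the true dimension much more reliably.

## Synthetic communities

`generate_communities()` draws every quantity of the model equation and
records it. Defaults emulate a regional coastal survey: 500 sites along a
coastline (a half-elliptic arc rescaled to unit length, with small
coordinate jitter), 519 species, three latent Matérn fields with ranges
0.6/0.3/0.15 of the coastline length and unit variance, two standardized
covariates (a latitudinal gradient and an along-coast oscillation),
species intercepts $\mathcal N(-2, 1)$ (about 7–15% occupancy, matching
the sparse detection tables of real eDNA surveys), loadings
$\mathcal N(0,1)$, site effects $\mathcal N(0, 0.5^2)$, and covariate
coefficients $\mathcal N(0, 0.5^2)$. An optional read-count layer draws
zero-truncated Poisson counts on occupied cells, so the count matrix
binarizes back to the presence matrix exactly — the minimal structure
needed to exercise rarefaction.

What the generator does *not* emulate: sequence-level artefacts (ASV
denoising, taxonomic misassignment), spatially structured detectability,
abundance-dependent detection, tides or currents. Passing recovery tests
therefore show that the inference chain is correct under its own model
assumptions, not that those assumptions hold for any particular survey.

## Niche space, centres, boundaries

The niche space takes the first two scaled latent axes as coordinates.
A species' niche centre is the arg-max grid point of a Gaussian-kernel
density of its occupied sites' positions (default bandwidth: Silverman's
rule per axis; grid 200x200 over the positions' bounding box with a 10%
margin; ties broken at the lowest grid index). Niche regions are the sign
quadrants of the zero-value lines; because latent signs are arbitrary up
to reflection, the quadrant-to-region-name mapping is a declared
convention (`classify_niche_regions()`), and a centre exactly on a zero
line counts as positive.

Latent surfaces are interpolated onto a geographic grid by the same GP
conditional mean (noise-free, so the surface reproduces fitted values at
the sites), and `extract_zero_boundaries()` pulls the zero-level contours
via marching squares (`grDevices::contourLines`). Two degenerate cases are
flagged rather than contoured: fields without sign change, and fields with
broad near-zero areas (at least 20% of cells within 0.1 field standard
deviations of zero) — the latter mirrors the situation where a latent
axis separates scattered habitats rather than forming a line-like
boundary.

## Response diversity

The expected response diversity of a site to one latent axis is the
average, over communities sampled from the estimated occurrence
probabilities, of the interquartile range of the loadings of the present
species (100 samples by default; linear-interpolation quantiles;
communities with fewer than two species contribute 0 so the average stays
defined; signed loadings, as the scaled fit reports them). An exact
enumeration oracle (`exact_response_diversity()`, up to 20 species)
backstops the Monte-Carlo estimator in the tests.

Sites are clustered into high/low response diversity by spectral
clustering (RBF affinity with median-heuristic bandwidth, normalized
Laplacian, two clusters) on the same two log-scaled variables used in the
regressions, i.e. (log richness, log response diversity). The k-means step
is restarted 100 times and restarts are scored by the summed Gaussian
log-likelihood of the residuals of per-cluster
$\log(\mathrm{rd}) \sim \log(\mathrm{richness})$ regressions — the
restart-selection rule is a declared convention, as is the feature space.
Per-axis clustering is used (one clustering per latent variable). Sites
with zero response diversity are excluded from the regressions and
counted.

## Numerical choices

* Optimizer: L-BFGS-B, `factr = 1e10`, `maxit = 2000`, three outer
  iterations. A looser inner tolerance proved not only faster but slightly
  better for latent recovery than grinding the tail of the objective.
* GMRF: 10 conditioning neighbours by default, sites ordered along the
  first coordinate; dense-inverse agreement is tested at full
  conditioning.
* Matérn smoothness fixed at $\nu = 1.5$ (smooth fields) unless specified;
  $\nu \in \{0.5, 1, 1.5\}$ supported.
* Cholesky jitter $10^{-8}$–$10^{-10}$ on correlation matrices.
* Problem sizes in the test-suite: recovery at 200 sites x 60 species,
  model selection at 100 sites x 40 species with latent dimensions 0–3 and
  10 replicates, oracles at 5–20 sites. These sizes keep the full suite in
  the minutes range on a single core while leaving the conclusions
  representative.

## Known limitations

* Estimation is penalized/MAP rather than a fully marginal Laplace
  likelihood; loadings and fields are point estimates, and downstream
  quantities (variance partition, response diversity) ignore their
  estimation uncertainty.
* The L1-vs-L2 selection caveat above: at small problem sizes,
  cross-validation can prefer one blended axis over the true two.
* Smooth covariates that are collinear with smooth latent fields are
  intrinsically confounded with them; the variance partition reflects the
  fitted split, which is not unique in that case.
* Latent axes are interpretable only up to rotation and sign; all
  cross-run comparisons must align first.
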