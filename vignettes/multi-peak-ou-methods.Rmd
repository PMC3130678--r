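---
title: "Methods: multi-peak Ornstein-Uhlenbeck models of ecomorphological diversification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-peak Ornstein-Uhlenbeck models of ecomorphological diversification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakshift)
```

This vignette documents the models, the numerical choices, and the
design decisions behind `peakshift`, in the spirit of a methods
appendix: what each stage assumes, which knobs matter, and what the
test suite does and does not establish.

## The scientific question

Adaptive radiations leave two kinds of quantitative fingerprints on a
clade. First, an association between ecology and morphology across
living species: in a bat-like radiation spanning insectivory,
carnivory, frugivory, nectarivory and blood feeding, mandible shape
tracks diet. Second, a temporal signature: under an early burst of
ecological divergence followed by stabilizing selection, trait
disparity concentrates *between* the early-diverging lineages, and
within-lineage disparity in later epochs falls below what neutral
drift would produce. `peakshift` implements the comparative machinery
to quantify both fingerprints and then to test them formally by
fitting explicit evolutionary models: neutral Brownian motion against
Ornstein-Uhlenbeck processes with two to five adaptive peaks.

## Shape: Procrustes superimposition and its conventions

Landmark configurations (ordered 2-D points, each flagged landmark or
semilandmark) are superimposed by generalized Procrustes analysis:
centre, scale to unit centroid size, rotate to the evolving consensus,
iterate until the consensus moves less than `1e-10` (maximum 200
iterations). Centroid size is recorded *before* scaling, so shape and
size are analysed separately. When several specimens represent a
species, a within-species superimposition produces species mean shapes
first and the grand superimposition runs on those means — a two-stage
averaging that stops large-sample species from dominating the
consensus.

Semilandmarks carry no point-for-point anatomical correspondence:
after superimposition each one is allowed to slide along its local
tangent (the chord between its two neighbours in point order) to the
position minimizing its squared distance to the consensus, and sliding
alternates with re-superimposition. We slide against the Procrustes
least-squares criterion, not bending energy; the convergence rule is a
change below `1e-8` in the total Procrustes sum of squares, capped at
50 cycles. A semilandmark at the first or last position of the point
order has no two neighbours and is rejected — curves must be anchored
by landmarks. Full Procrustes distance (optimal rotation *and*
residual scale on unit-size preshapes) is the shape metric; it is
symmetric and verified against a brute-force rotation-grid search.

Shape principal components are extracted from the covariance matrix of
the species mean aligned coordinates — the variables share units, so
no rescaling. For component retention we use Horn's parallel analysis
with 95th-percentile thresholds. One deliberate choice: the comparison
between observed and random eigenvalues is made on the **correlation
scale** (both the observed data and the standard-normal random
datasets are standardized). Procrustes coordinates have variances of
order `1e-3`, so comparing their covariance eigenvalues against
unit-variance random data would retain zero components always;
standardizing both sides makes the rule scale-free, matches the
canonical implementations of the method, and leaves its calibration
intact (on null data the false-retention rate stays at the nominal
5%, and planted factors are recovered — both are asserted in the test
suite).

## Diet, and the ecomorphological regression

Diet is a species-by-five table of usage ranks (0 absent, 1
complementary, 2 predominant, 3 strict). Because insectivory and
carnivory co-occur and both trade off against frugivory, the raw ranks
are strongly collinear; the regression therefore uses the principal
components of their correlation matrix. The multivariate regression of
shape PCs on diet PCs 1-3 plus skull length (condylobasal length, CL,
in mm, untransformed) is a phylogenetic GLS with the Martins-Hansen
working covariance

$$V_{ij} = \gamma\, e^{-\alpha t_{ij}},$$

where $t_{ij}$ is the patristic distance. $\alpha$ (units 1/My) is the
strength of the restraining force: $\alpha \to 0$ recovers a
common-ancestry covariance, large $\alpha$ erases phylogeny.
$\gamma$ is concentrated out analytically as the GLS residual variance
per response, and a single shared $\alpha$ is profiled by a bounded
search of the summed profile log-likelihood over
$\log\alpha \in [\log 10^{-6}, \log 10^{3}]$. Per-predictor p-values
are two-sided t tests on the GLS coefficients with $n - m - 1$ degrees
of freedom; partial correlations are $t/\sqrt{t^2 + \mathrm{df}}$;
the per-response $R^2$ is $1 - \mathrm{RSS}/\mathrm{TSS}$ on
$V$-whitened data; the multivariate statistic is Wilks' lambda on the
whitened fit (the choice of multivariate statistic was open; Wilks is
the conventional likelihood-ratio choice). Variance inflation factors
are computed under the same covariance. With an identity covariance
the whole machinery collapses to OLS, which the tests assert to
`1e-8`.

## Disparity through time

Disparity of a species set is the mean over unordered pairs of the
squared Euclidean distance (shape; a flag switches to unsquared, since
the two conventions coexist in the literature) or the Manhattan
distance (diet ranks). For the curve, every internal node is a
divergence event ordered by time from the root; at an event, each
lineage crossing that time contributes the disparity of the clade it
subtends divided by the whole-tree disparity (singletons contribute
zero), and the event value is the mean. The relative-time axis is node
time over tree depth, so events live on `[0, 1)`.

The null envelope simulates Brownian data on the same tree with the
rate matrix estimated from phylogenetic independent contrasts
(cross-products of standardized contrasts over $n-1$; a rank-deficient
rate matrix gets a small ridge with a warning), and takes pointwise
per-event medians and central 95% intervals over 1000 simulations by
default. Calibration — BM data falling inside the envelope at ≥90% of
events on average — is checked in the acceptance suite at a reduced
size (50 replicates of 32 tips, 3 traits, 100 simulations each),
chosen so the whole suite stays a desk-scale run. Note the directional
logic: data whose variance lies wholly *between* the basal clades
collapse the curve toward zero (below the envelope), while
phylogeny-free data hold it near one (above it); an early burst
followed by stasis shows the first pattern in late epochs and elevated
within-lineage disparity early.

## Ancestral diets and regime paintings

Discrete ancestral states for the predominant diet use an equal-rates
Mk model — the minimal maximum-likelihood choice when no model is
specified — with the rate fitted by the pruning algorithm and marginal
node probabilities computed by the standard re-rooting recursion under
a flat root prior; the marginals are verified against exhaustive
enumeration on small trees. Each internal node takes its
maximum-probability state; each branch is painted with its *child*
node's state, so a branch's evolution is attributed to the regime it
evolves toward and a terminal branch carries the tip's own diet. Ties
resolve toward the parent (root ties toward the first label in
canonical order). Within-branch switches are not modelled: a
mid-branch regime change is unidentifiable from node-state estimates
alone, and users who want one can subdivide the branch in the input
tree. Continuous ancestral estimates (used for descriptive mapping)
solve the Brownian ML linear system in which every internal node is
the inverse-branch-length weighted mean of its neighbours; the root
estimate equals the GLS grand mean.

## The multi-peak OU (Hansen) model

Trait evolution on a painted tree follows the stochastic differential
equation

$$dX(t) = A\,(\theta_{r(t)} - X(t))\,dt + S\,dB(t),$$

with $X$ a $p$-vector, $A$ a $p \times p$ symmetric positive-definite
selection matrix (1/My), $S$ a $p \times p$ diffusion factor
($\Sigma = SS^\top$), $B$ a standard Wiener process, and
$\theta_{r}$ the optimum of the regime painted on the current branch.
One $A$ and one $S$ are shared by all regimes — selection differs
between peaks only in where they sit, not in how hard they pull — so a
model with $n_\theta$ optima estimates
$2\,p(p+1)/2 + p\,n_\theta$ parameters
(Brownian motion: $p(p+1)/2 + p$).

Working in the eigenbasis of $A$ ($A = U\Lambda U^\top$,
$D = U^\top \Sigma U$) makes everything closed-form. The expected tip
value is a weighted sum of optima: for tip $i$ with root-to-tip
segments $(t_a, t_b]$ painted regime $r$, the weight block is
$\sum_{\text{segments}} e^{-A(T_i - t_b)} - e^{-A(T_i - t_a)}$, plus a
root block $e^{-A T_i}$; the blocks sum to the identity. The root
state is tied to the root regime's optimum (its weight is folded into
that regime's design column): the published parameter counts leave no
room for a separate root-state parameter, and an explicit root state
is weakly identified at realistic tree depths anyway. Conditional on a
fixed root, the covariance between tips $i, j$ with shared time
$s_{ij}$ is, in eigen coordinates,

$$\mathrm{Cov}(z_{ik}, z_{jl}) = D_{kl}\,
e^{-\lambda_k (T_i - s_{ij})} e^{-\lambda_l (T_j - s_{ij})}\,
\frac{1 - e^{-(\lambda_k + \lambda_l) s_{ij}}}{\lambda_k + \lambda_l},$$

with the bracket replaced by $s_{ij}$ in the
$\lambda_k + \lambda_l \to 0$ limit — which is exactly multivariate
Brownian motion, and the simulator and likelihood both honour that
limit. The trait simulator samples branch-by-branch from this exact
transition distribution (no time discretization); it is validated
against an Euler-Maruyama integrator on small trees in the acceptance
suite.

**Estimation.** Given $(A, S)$, the optima are the GLS solution
$\hat\theta = (W^\top V^{-1} W)^{-1} W^\top V^{-1} y$ with $W$ the
stacked weight design — in the eigenbasis the design is block-diagonal
with scalar weights, which is what makes ~3 ms likelihood evaluations
possible. The profile likelihood is then maximized over $A$
(log-Cholesky, guaranteeing symmetric positive definiteness) and $S$
(lower triangular, log diagonal) from identity starts. The outer
optimizer is `nlminb` (quasi-Newton with finite-difference gradients);
on all test problems it reaches the same optimum as a Nelder-Mead
simplex at roughly a fifth of the evaluations, and `fit_hansen()`
falls back to the simplex automatically if the quasi-Newton run fails
to improve on its start (a simplex-only mode remains available). The
hot likelihood path is compiled (RcppArmadillo) and mirrors a pure-R
reference evaluator; the two are asserted equal to `1e-9` in the
tests. Degenerate inputs fail loudly: a painting with a regime on no
branch makes that optimum unidentifiable and is rejected before
optimization.

**Model sets and selection.** The nested model set merges the five
dietary regimes into two (mastication vs low-mastication), three
(splitting sanguivory from nectarivory), four (lumping insectivory and
carnivory as animalivory) and five regimes, each fitted with the same
machinery, plus Brownian motion. Models are ranked by
$\mathrm{AICc} = -2\ln L + 2k + 2k(k+1)/(n-k-1)$ and
$\mathrm{SIC} = -2\ln L + k \ln n$, with
$\Delta_i = \text{value}_i - \min$ and weights
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$. The effective sample
size is $n_{\text{species}} \times p$ (total observations): with 49
species and up to 55 parameters, a per-species convention would make
the AICc denominator negative, so total observations is the only
workable reading; it is exposed through the fitted objects. When even
$n_{\text{species}} \times p \le k + 1$ the AICc is reported `NA`
with a warning rather than a misleading number.

**Bootstrap.** `bootstrap_optima()` defaults to the full parametric
bootstrap (the published procedure used 5000 resamples): simulate from
the fitted model, re-estimate $(A, S, \theta)$, collect
$\hat\theta$ replicates; replicates that fail to refit are dropped and
more than 10% drops is an error. Whether the original analysis
re-estimated $(A, S)$ per replicate is not stated; we re-estimate by
default and expose `refit = "theta"` to hold them fixed. In that
conditional mode the refitted optima are *exactly* Gaussian around the
point estimate, so replicates are drawn from that distribution
directly — identical in law to simulate-then-refit, at negligible
cost. Regions are percentile intervals for univariate fits and
mean-plus-sample-covariance ellipsoids at the $\chi^2_{p,0.95}$
quantile for multivariate fits.

## The synthetic study design

`phyllostomid_like_fixture()` fixes the generative conditions used
throughout the tests: a 49-tip pure-birth tree rescaled to 30 My (any
ultrametric shape suffices once the real topology is unavailable; the
pure-birth prior is the simplest null); five dietary regimes painted
by a symmetric Markov jump process at 0.04 switches/My from an
insectivorous root (symmetric to match the equal-rates Mk model used
for estimation; the rate gives roughly one expected switch per
root-to-tip path, enough to exercise multi-regime lineages without
shredding the painting); five traits under a five-peak OU with
$A = 0.3 I$ plus weak off-diagonals (phylogenetic half-life
$\approx 2.3$ My against a 30 My tree — strong selection), $S = 0.15I$
scale diffusion, and optima separated by roughly five stationary
standard deviations; a univariate skull-length trait with per-regime
optima of 16-27 mm; diet ranks drawn with the focal item predominant
or strict (sanguivores strictly so) and regime-dependent secondary
items that plant the insectivory-carnivory association; and 20-point
landmark outlines (5 landmarks, 15 semilandmarks) around per-regime
mean shapes with isotropic noise and random similarity transforms.
The published record gives no numerical optima — they appear only in
figures — so the fixture's optima are free choices recorded in its
truth record. Recovery tests read the truth record rather than
re-deriving parameters.

What passing tests show, and what they do not: the generator produces
exactly the model the estimators assume (correct painting, no
measurement error, no missing data, single regime per branch). Tests
therefore establish internal correctness and statistical calibration
under the assumed model, not robustness to model violation on real
specimens (mis-estimated ancestral diets, within-branch switches,
digitization error).

## Problem sizes and determinism

Stochastic acceptance checks run at desk scale, chosen as the smallest
sizes at which the contracts are sharp: model and optimum recovery at
128 tips and two traits over 50 replicates with 200-replicate
conditional bootstraps; DTT calibration at 32 tips, three traits, 100
null simulations, 50 replicates; the Euler-Maruyama oracle at
$2\times 10^5$ paths with step $10^{-3}$ on a three-tip tree. Every
simulator takes an explicit `seed`, restores the caller's RNG state,
and is bit-reproducible given it; `run_full_analysis()` writes the
seeds and per-file checksums into its manifest, and rerunning a
configuration reproduces the outputs byte for byte.

## Known limitations

2-D landmarks only; no thin-plate-spline visualization layer; binary
trees only (collapse zero-length internal branches before use);
regimes are constant within a branch; a single $A$ and $S$ across
regimes (regime-specific selection strengths are a different model
family); no measurement-error term in the tip means; the PGLS shares
one $\alpha$ across responses. The published likelihoods, $R^2$ and
variance-inflation values of the original specimen data cannot be
recomputed here because the specimen data are not redistributable;
the acceptance layer therefore targets the arithmetic that *is*
reproducible from published values plus property-based recovery under
the synthetic design.
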