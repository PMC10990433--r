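---
title: "Multiparental multi-environment QTL mapping with EC sensitivities: models and design choices"
author: "mppqtlx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparental multi-environment QTL mapping with EC sensitivities: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mppqtlx)
```

## The problem

Backcross nested association mapping (BCNAM) populations introgress the
alleles of many donor parents into one or a few elite recurrent parents:
each cross is one backcross to the recurrent parent followed by several
selfing generations (BC1F4 here). Evaluated in several environments, such a
population lets us ask three nested questions about any genomic position:

1. Does the position carry a QTL, i.e. do the donor-parent alleles shift
   the trait relative to the recurrent parent in at least one environment?
2. For each parental allele, is the effect stable across environments or
   does it interact with the environment (QEI)?
3. When it interacts, can the interaction be explained as a linear response
   to an environmental covariate (EC) such as the photoperiod or the vapour
   pressure deficit over a developmental time window — and if so, what
   effect do we predict in a new environment with a known EC value?

`mppqtlx` implements this sequence on within-environment adjusted genotype
means (BLUEs), together with a simulator that generates BCNAM experiments
with known ground truth so that every stage has a recovery test.

## Models

### Plot model and heritability

Plot observations are modelled per cross with fixed environment (and block
within replicate and environment) effects and random genotype,
genotype-by-environment, and plot error terms, giving cross-specific
variance components $\sigma^2_G$, $\sigma^2_{GE}$, $\sigma^2_e$. Broad-sense
heritability on an entry-mean basis is

$$h^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{GE}/N_{env} +
\sigma^2_e/(N_{env} N_{rep})}.$$

These fits are ordinary mixed models and are delegated to `lme4`. With an
unreplicated layout the GxE and plot-error variances are confounded at the
plot level; `estimate_variance_components()` then drops the GxE term and
reports the compound in $\sigma^2_e$ with a warning, rather than reporting
an arbitrary split.

Within-environment BLUEs are ordinary least-squares genotype means adjusted
for fixed block effects under sum-to-zero contrasts
(`fit_env_blues()`). In an unreplicated augmented layout the replicated
checks carry the block information; a genotype confined to blocks whose
effect is not estimable gets a missing BLUE instead of a silently
unadjusted one. The package replaces 2D spline spatial adjustment with
this block model on purpose: the downstream QTL machinery consumes BLUEs
whatever the spatial model was, and a transparent fixed-effects adjustment
keeps the artifact self-contained and exactly testable (its OLS collapse
on balanced data is asserted in the tests).

### Detection model: environment-specific parental effects

On the stacked BLUEs $y_{icj}$ (genotype $i$, cross $c$, environment $j$)
the detection model at a position with donor-allele counts $x_{iqp}$ is

$$y_{icj} = E_j + C_{cj} + x_{iqp}\,\beta_{pj} + \varepsilon_{icj},$$

with one allelic effect per donor parent $p$ and environment $j$; the
recurrent parent is the reference. The combined GxE-plus-error residual
$\varepsilon$ is modelled with an **unstructured** environment covariance
$\Sigma$ ($N_{env}(N_{env}+1)/2$ parameters): genotypes are independent
blocks, and an incomplete genotype contributes the submatrix of $\Sigma$
for its observed environments.

$\Sigma$ is estimated by REML with a log-Cholesky parameterization — every
iterate is positive definite by construction — optimized by BFGS from a
moment start (the sample covariance of per-environment OLS residuals).
On balanced data with environment means as the only fixed effects this
start is already the REML optimum, which the tests exploit as a
closed-form oracle. Convergence uses a relative tolerance of `1e-10` with
at most 200 iterations; aliased fixed-effect columns are dropped in
deterministic first-come order.

The overall QTL test is a Wald test on the $\beta_{pj}$ block. The
parameter count (retained parental columns times environments) is used as
the primary degrees of freedom; an allele-count convention (columns only)
is also computed and reported in the scan profile as `p_alleles`, since
both conventions are defensible for an environment-specific effect block
and the choice matters for thresholding. Thresholds use the parameter-count
p-value.

### Approximate scan, cofactors, thresholds

Re-estimating $\Sigma$ at every marker would make genome scans needlessly
expensive. The scan therefore fixes $\Sigma$ at its null-model (cofactor-
only) REML estimate and estimates each position's QTL block by generalized
least squares (`gls_scan_stat()`): the response and null design are
whitened once, and each position only requires residualizing its incidence
columns. When $\Sigma$ equals the joint-fit estimate this reproduces the
exact Wald statistic to numerical precision — re-use of the null $\Sigma$
is the approximation's only error source, which the acceptance checks
quantify on random instances.

Detection runs simple interval mapping, greedy cofactor selection (at most
one per chromosome), composite interval mapping with cofactors removed
within 20 cM of the tested position, and a final greedy selection.
The exclusion window is 20 cM **per side** of a selected position; the
greedy rule is: take the most significant free position, exclude its
window, repeat while something clears the threshold (ties break toward the
lower position). Genome-wide thresholds use the Li–Ji effective number of
tests: per chromosome, $M_{eff} = \sum_i f(\lambda_i)$ over the eigenvalues
of the marker correlation matrix with
$f(x) = \mathbf{1}\{x \ge 1\} + (x - \lfloor x \rfloor)$, summed across
chromosomes (linkage does not extend across chromosomes), and the per-test
threshold $1 - (1-\alpha)^{1/M_{eff}}$. Eigenvalues are snapped to integers
at `1e-8` before applying $f$, because $f$ is discontinuous at integers and
exactly singular correlation matrices otherwise land at $3 - \epsilon$.
Chromosomes are thinned to at most 2000 evenly spaced markers before the
eigendecomposition.

QTL R² values come from an ordinary linear model with environment and
cross intercepts plus all QTL incidence terms: the global R² is the share
of residual-after-design variance explained by the QTL set, and a QTL's
partial R² is the global value minus the fit without it. Defining R²
against the environment+cross baseline (not the grand mean) makes "a QTL
explaining 10% of the variance" refer to the within-environment variance
the QTL model actually competes for.

### Main/QEI decomposition and EC regression

For the selected QTL, the characterization model splits each parental
effect into a main component and environment deviations,

$$y_{icj} = E_j + C_{cj} + \sum_q x_{iqp}(\alpha_p + \beta_{pj}) +
\varepsilon_{icj},$$

fitted by exact REML. $\beta_{pj}$ is constrained to sum to zero over
environments within each parent (sum-to-zero contrasts), so $\alpha_p$ is
the across-environment mean allelic effect and the two Wald tests —
$\alpha_p$ on 1 df, the $\beta_{p\cdot}$ block on $N_{env}-1$ df — are
separately well defined. The parameterization question (sum-to-zero versus
a reference environment) is genuinely open; sum-to-zero was chosen because
it makes the main/QEI split orthogonal and the classification rule
(`nonsignificant`, `main-only`, `QEI` at 0.05) unambiguous.

For alleles classified QEI, the factorial-regression model replaces
$\beta_{pj}$ by $EC_j S_p$: a linear sensitivity to one EC at a time. With
at most four or five environments a joint multi-EC fit is not estimable,
hence the one-at-a-time constraint; likewise the lack-of-fit term of the
EC regression is not given its own variance component (inestimable at
these sizes) but is absorbed by the unstructured residual, against which
$S_p$ is tested. The EC is centered at its across-environment mean before
fitting so that $\alpha_p$ keeps its mean-environment meaning; projection
un-centers consistently:

$$Q_{eff}(\text{point}) = \hat\alpha_p + (EC_{\text{point}} -
\overline{EC})\,\hat S_p,$$

a deviation from the recurrent-parent background, affine in the EC. The
whole analysis is invariant to affine rescaling of an EC: $\hat S_p$
rescales inversely and all p-values and $Q_{eff}$ values are unchanged,
which is asserted end-to-end at `1e-8`.

### EC window selection

Daily EC series are aggregated over candidate windows of 20, 40, 60, 80 or
100 days starting every 5 days from sowing (mean for intensive ECs,
sum for cumulative ones such as rain). For each cell the Pearson
correlation between the windowed EC and the per-environment mean of the
genotype BLUEs is computed — the only reading of a "trait mean per
environment" that yields one value per environment. ECs are ranked by the
mean |r| over the whole (start, size) grid (the averaging set is not
uniquely determined by the method's description; the full grid is the
declared choice), and each selected EC passes its single best window's
values downstream. With only four environments these correlations are
noisy; the module warns rather than attaching p-values to them.

### Unique-QTL grouping

QTL of the same trait detected in different subpopulations are grouped by
iterative agglomeration: repeatedly merge the two closest same-chromosome
clusters whenever the merged span stays within 10 cM, leftmost pair first
on ties. Spans therefore never exceed 10 cM and the result is invariant to
input order.

## The simulator

`simulate_bcnam()` generates: a genetic map (evenly spaced markers by
default); fully homozygous parent scores, informative for each cross
except at a configurable fraction of markers; BC1F4 progeny by explicit
meiosis under the Haldane map function (no interference, closed-form
testable), one backcross and three selfing generations by default — donor
allele frequency 1/4 and heterozygosity $0.5 \times (1/2)^3 = 1/16$;
daily EC series with per-environment level offsets and a seasonal phase
shift between environments (emulating staggered sowing dates, which is
what makes window selection identifiable); and phenotypes

$$y_{icj} = E_j + C_{cj} + \sum_q x_{iq}(\alpha_p + S_p EC_j + \beta_{pj})
+ GE_{icj}$$

with $GE$ rows drawn from the configured unstructured covariance, expanded
to plot records with block effects, iid plot error, and the recurrent
parents replicated in every block as checks. Setting all variance sources
to zero reproduces the deterministic part bit for bit. No selection is
applied during population development (real programs often select at
BC1F2; the simulator omits it so recovery tests are unbiased), and the
selfing-generation count is a parameter because genotyping and phenotyping
generations can differ in practice.

What the simulator does **not** emulate: genotyping error and missing-data
structure beyond a uniform uninformative-marker rate, segregation
distortion, spatial field trend (block effects only), multi-trait
correlation, and marker-dense maps. Passing recovery tests on this
generator therefore demonstrates the statistical machinery, not robustness
to those real-data features.

## Study sizes used in the checks

The calibration and recovery checks run at deliberately desk-scale sizes,
chosen once: null calibration on 500 simulated no-QTL datasets of 300
genotypes in 3 environments (42 markers on 2 chromosomes); parameter
recovery on 100 datasets of 600 genotypes in 4 environments with one QTL
at 50 cM explaining about 10% of the within-environment variance
($\alpha_{D1} = -0.8$, $S_{D1} = 3$ on photoperiod, GxE variance 4 with
0.5 correlation); oracle equivalence on 50 random instances of 120
genotypes. The genome-wide donor-share check uses a five-chromosome
genome so the Monte-Carlo standard error of the genome-wide mean
(~0.003) sits well inside the ±0.01 tolerance; the recombination check
uses adjacent 10-cM intervals against the Haldane closed form.

## Numerical choices and degenerate inputs

* $\Sigma$ parameterization: log-Cholesky; never emits a non-PSD matrix.
* Aliased design columns: dropped first-come, deterministically; a Wald
  block with singular covariance falls back to a generalized inverse with
  rank degrees of freedom and a warning.
* A position where every parental column has fewer than `min_seg = 10`
  carriers is **unscannable** — flagged distinctly from "not significant".
  `min_seg` guards against near-singular Wald tests from tiny carrier
  counts.
* Missing dosages: a marker uninformative for a cross (parents share a
  score) is imputed from the nearest informative flanking markers when
  they agree; otherwise the genotype is excluded from tests at that
  position (the observation subset is refitted, not zeroed). This
  flanking-consensus rule is a declared, transparent substitute for
  probabilistic IBD reconstruction, which is out of scope.
* Scan positions are the marker positions themselves; with dense maps,
  pseudo-markers between markers add cost without localization benefit.
* Ties in greedy selection break toward the lower position; ties in EC
  ranking break lexicographically; both make reruns reproducible.

## Known limitations

* The Wald/χ² reference is slightly liberal at small n (no small-sample
  correction such as Kenward–Roger); the null-calibration check bounds the
  practical impact at the sizes above.
* Subpopulations are analyzed independently; there is no joint
  cross-background model, so comparisons of the same donor in different
  backgrounds are post-hoc juxtapositions.
* With ≤ 4 environments, EC window correlations and EC sensitivities rest
  on very few effective observations; the package warns but cannot repair
  that design limitation.
* Kinship/polygenic background beyond the unstructured environment term is
  not modelled.
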