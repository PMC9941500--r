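---
title: "Modeling the multivariate genomic architecture of brain structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the multivariate genomic architecture of brain structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsemCortex)
```

# The problem

GWAS of regional brain phenotypes (cortical thickness and surface area of
the 34 Desikan–Killiany regions, say) produce dozens of summary-statistic
files whose underlying traits are strongly genetically correlated. This
package models that multivariate system in four stages:

1. **LD-score regression (LDSC)** turns the per-SNP z-statistics of k
   traits into a genetic covariance matrix `S` (heritabilities on the
   diagonal, co-heritabilities off it) and a jackknife sampling covariance
   `V` of its unique elements.
2. **Factor analysis** of the genetic correlation matrix decides how many
   genomic factors describe the data (non-graphical scree rules), finds an
   exploratory structure (ML extraction, promax rotation), and turns it
   into confirmatory common / correlated-factors / bifactor models fit by
   diagonally weighted least squares on `(S, V)`.
3. **Stratified enrichment** asks which functional annotations carry a
   disproportionate share of each factor's genetic variance.
4. **Topographical annotation** compares the factor parcellation of the
   cortex with categorical and continuous brain maps using spherical spin
   permutations.

A fully seeded synthetic-data generator emulates every input with known
ground truth, so the whole pipeline is testable end to end.

# LD-score regression

For SNP j and traits 1, 2 the cross-product of z-statistics has
expectation

$$E[z_{1j} z_{2j}] = \sqrt{N_1 N_2}\,\sum_c \tau_c \frac{\ell(j,c)}{M_c}
  + \frac{\rho N_s}{\sqrt{N_1 N_2}} + a,$$

where $\ell(j,c)$ is SNP j's LD score restricted to annotation $c$, $M_c$
the annotation's SNP count, $\tau_c$ the co-heritability it carries,
$\rho$ the phenotypic correlation among the $N_s$ overlapping
participants and $a$ a constant confounding term. With a single
whole-genome annotation this is ordinary bivariate LDSC; the diagonal
case ($z_{1j}^2 = \chi^2_j$) is univariate LDSC, and the intercept of the
cross-trait regression, $\rho N_s / \sqrt{N_1 N_2}$, is a quantitative
index of sample overlap.

Implementation choices that matter:

* **Weights.** Standard heteroskedasticity-and-overcounting weights,
  $1/[(c_1 c_2 + c_{12}^2)\max(\ell_j, 1)]$ with $c_i$ the model-implied
  per-SNP variance terms. The weight terms are seeded by a preliminary
  univariate pass for every trait and updated once; the same seeding is
  used for diagonal and off-diagonal trait pairs so that self-covariance
  identities hold exactly.
* **Two-step estimation.** The intercept is estimated on SNPs with
  $\chi^2 < 30$; the slope on the full set with the intercept fixed.
* **Jackknife.** 200 contiguous equal-count SNP blocks in input order.
  All k(k+1)/2 pair regressions are jackknifed with the *same* blocks, so
  the sampling covariance `V` of vech(S) (column-major lower triangle —
  the package-wide convention) captures dependence of estimation errors
  across elements, as produced by sample overlap. Weights are held fixed
  at their full-sample values within jackknife replicates.
* Negative heritability estimates are retained in `S` (flagged), but
  standardization to a correlation matrix refuses them.
* Liability-scale conversion uses the standard observed-to-liability
  multiplier; with a sum of effective sample sizes the sample prevalence
  is 0.5 by construction, because the effective N already encodes the
  case/control ascertainment.

# Factor structure

`factorCount()` applies the Kaiser rule (eigenvalues strictly > 1), the
acceleration factor (the scree position preceding the maximum second
difference) and optimal coordinates (eigenvalues exceeding the value
extrapolated from the line through the next and the last eigenvalue,
counted while consecutive) to the genetic correlation matrix.
`runEFA()` uses ML extraction (`factanal`) with varimax-then-promax
rotation; the promax power defaults to 4, the conventional choice.
Because LDSC can produce correlations slightly outside [-1, 1], entries
are clipped (with a warning) for eigen/EFA work only; confirmatory models
always use the unclipped `(S, V)`. Non-positive-definite inputs are
smoothed by eigenvalue clipping at 1e-8. The sign convention (largest
loading per factor positive) makes results deterministic.

`assignFactors()` implements the two-step assignment rule: an indicator
joins the factor with its largest absolute loading; indicators with
loadings above 0.5 on two or more factors are flagged as cross-loading,
and the cross-loading itself is *not* carried into confirmatory models.

# Confirmatory models on (S, V)

`buildFactorModel()` constructs common, correlated-factors and bifactor
specifications with the identification rules applied automatically:
unit-variance identification for every factor, equality-constrained
loadings for two-indicator factors, a fixed-to-zero residual variance for
single-indicator factors, and fully orthogonal factors in the bifactor
structure.

`fitGenomicSEM()` minimizes the diagonally weighted least-squares
discrepancy $(s - \sigma(\theta))' \mathrm{diag}(V)^{-1} (s -
\sigma(\theta))$ by damped Gauss–Newton with the analytic Jacobian, from
a fixed deterministic start (loadings 0.5, residual variances half the
observed, covariances 0); iteration caps at 5000 with a 1e-8 gradient
tolerance. Standard errors use the full sandwich
$(\Delta'W\Delta)^{-1}\Delta'W V W \Delta(\Delta'W\Delta)^{-1}$; the
model statistic is the residual-based quadratic form
$e'[V^{-1} - V^{-1}\Delta(\Delta'V^{-1}\Delta)^{-1}\Delta'V^{-1}]e$,
asymptotically $\chi^2_{p^*-q}$ when `V` is the true sampling covariance
(a pseudo-inverse handles jackknife-rank-deficient `V`; with fewer
jackknife blocks than unique elements of a large `S`, the statistic's
reference distribution becomes approximate). Non-convergence is always a
reportable outcome — the `converged` flag — never an exception, because
constrained models legitimately fail to converge and that is itself a
finding.

Fit is summarized by CFI (against an all-covariances-zero independence
model, clamped to [0,1] with a guard for a degenerate independence fit),
SRMR (RMS of correlation-metric residuals over unique elements) and
AIC = chi-square + 2 (free parameters). CFI > 0.9 and SRMR < 0.10 are the
conventional acceptability thresholds.

## Residual-covariance search

`residualSearch()` iteratively frees the residual covariance of the
indicator pair with the largest absolute standardized residual, keeps it
while its Wald p is below 0.01, and stops otherwise; non-converging
refits blacklist the candidate and the search continues. One property of
this procedure deserves emphasis: because the *largest* residual is
selected and then tested at a raw per-parameter threshold, the
family-wise probability of adding at least one covariance under a
correctly specified model is roughly $1 - (1-\alpha)^d$ for $d$ effective
residual dimensions — noticeably above $\alpha$ (about 8–10% for a
6-indicator model at $\alpha = 0.01$). We deliberately keep the raw-Wald
retention rule because it matches how the procedure is used in practice;
a selection-corrected variant would change its semantics. Users should read
the number of added covariances accordingly.

## External correlates

`jointExternalModel()` concatenates a brain measurement model with an
external one (e.g. a cognitive g-factor), frees all cross-block factor
correlations, extends the residual search to indicator–trait pairs, and
flags correlations against a configurable Bonferroni family (default:
product of the two indicator counts; e.g. 34 regions x 11 disorders gives
0.05/374). `omnibusEqualityTest()` compares the free model against one
with the cross-block correlations constrained to equality via the
chi-square difference; a non-converging constrained model is reported as
such. Where a study reports its family size inconsistently (a cognitive
family given as 204 alongside a threshold matching 34 x 7 = 238 tests),
the family size is left to the caller rather than guessed.

# Stratified enrichment

`stratifiedLDSC()` fits the multi-annotation regression above jointly per
trait pair (free intercept, genome-wide-seeded weights, single step) and
assembles per-annotation $\tau_c$ matrices with a shared multivariate
jackknife. `zeroOrderCovariance()` converts them to zero-order stratified
covariances

$$\zeta_t = \sum_c \frac{|M_c \cap M_t|}{|M_c|}\, \tau_c,$$

propagating sampling covariance through the same jackknife replicates
(not a post-hoc delta method). Zero-order values are used for enrichment
because conditional $\tau$ estimates are unstable at moderate GWAS sample
sizes; the cost is that enrichment can partly reflect signal shared with
overlapping annotations.

`screenCovariances()` eigen-clips each $\zeta_t$ to the nearest positive
semidefinite matrix and excludes annotations whose smoothing moved any
element by more than 1.96 standard errors. The screen operates on the
point estimates with V-derived SEs; clipping at zero (rather than a
Frobenius-optimal projection) is sufficient for a screen.

`factorEnrichment()` refits the genome-wide factor model on each
annotation's $\zeta_t$ with loadings fixed and factor/residual variances
free; enrichment is the annotation's factor variance over the genome-wide
factor variance, divided by the proportional annotation size $M_t/M$, so
the whole-genome annotation is exactly 1 by construction. The default
one-tailed p tests enrichment > 1 via $(est - 1)/SE$ — the natural null
for a ratio whose null value is 1 — and the $est/SE$ variant is reported
alongside. Continuous, flanking and control annotations belong in the
regression but not in enrichment reporting (`exclude=`).

# Spin tests

`spinPermutations()` draws uniform random rotations (QR of a Gaussian
matrix, sign-corrected to a proper rotation), applies each to
left-hemisphere region centroids and its x-mirrored counterpart to
right-hemisphere centroids, and relabels every region by the nearest
original centroid within its hemisphere (ties break toward lower region
order). Bilateral (hemisphere-averaged) maps are represented on
left-hemisphere centroids only. Relabelings are surjections — repeated
labels are expected.

`categoricalSpinTest()` uses the Fisher exact dependence p of the A-vs-B
contingency table as the statistic, recomputed with A spun; the reported
$P_{spin}$ is plus-one corrected, so its floor is $1/(n_{spins}+1)$.
Fisher p-values are computed by seeded Monte-Carlo sampling of tables
with fixed margins under the hypergeometric probability ordering, with
the mid-p convention (ties count half): spun maps coarsen the class
margins, and mid-p keeps p-values comparable across tables of different
granularity. The observed statistic defaults to 100000 draws and the
null statistics to 2000; for calibration studies both should be set
equal so observed and null statistics are exchangeable.
`continuousSpinTest()` uses a one-way omnibus F per continuous map with
Benjamini–Hochberg adjustment across maps; constant maps and single-class
labelings degrade to $P_{spin} = 1$ with a flag.

Calibration. Under independent random categorical maps the test is
close to, but not exactly at, nominal level: all spun relabelings share
the observed map, so the null statistics are mutually correlated and the
observed rank is slightly over-dispersed (we measure a rejection rate of
roughly 0.05–0.07 at $\alpha = 0.05$ for 34 regions and 5 classes). This
mild anti-conservatism is a known property of parcel-level spin tests
and should be kept in mind near significance boundaries.

# The synthetic-data generator

`simulateSumstats()` draws, for each SNP independently, the k-vector of
z-statistics from a zero-mean multivariate normal whose covariance is the
stratified-LDSC expectation itself, with $\tau_c = q_c S_{true}$ for
user-chosen per-annotation variance shares $q_c$ and
$S_{true}$ implied by the specified loadings, factor correlations and
heritabilities. Generation at the z level is deliberate: the expectation
above fully specifies the second moments LDSC consumes, so generator and
estimator are exact inverses in expectation, and individual-level
simulation would add cost without adding testable surface.

What it emulates — and does not. Per-SNP independence is the standard
LDSC design approximation: LD enters only through the scores. Real data
add correlated residuals across SNPs, allele-frequency-dependent
architectures, population stratification beyond a constant intercept
term, and imperfect imputation; passing tests here validate the
estimators under the model's own assumptions, not robustness to those
violations. LD-score defaults (mean score 2 over M = 20000 SNPs, gamma
block structure with 100-SNP blocks) are chosen so the per-SNP signal
$N h^2 \bar\ell / M$ matches the mean chi-square of a well-powered real
GWAS (about 1.5–2.5); heritability 0.3, N = 20000 and a 2-factor
structure with loadings 0.7 and factor correlation 0.4 are the default
study conditions used throughout the tests, and M = N = 20000 keeps a
full pipeline replicate under a few seconds on one CPU.
`simulateParcellation()` places region centroids uniformly on the left
hemisphere of the unit sphere and couples a second categorical map to the
first with a per-region copy probability.

Every generator function requires a seed; a `truthRecord` (serializable
to JSON) accompanies each study with the true S, per-annotation taus,
enrichments and intercepts.

# Worked example

```{r example, eval = FALSE}
L <- cbind(c(.7, .7, .7, 0, 0, 0), c(0, 0, 0, .7, .7, .7))
spec <- generativeSpec(L, matrix(c(1, .4, .4, 1), 2), h2 = 0.3,
                       N = 20000, M = 20000, seed = 1)
sim <- simulateSumstats(spec)
gcov <- multivariableLDSC(sim$sumstats, sim$ld)

fc <- factorCount(geneticCorrelation(gcov))
efa <- runEFA(geneticCorrelation(gcov), fc$kaiser)
asg <- assignFactors(efa$loadings)$assignment
fit <- fitGenomicSEM(gcov, model = buildFactorModel(asg, "correlated"))
fitIndices(fit)
```

# Known limitations

* The chi-square statistic's reference distribution degrades when `V` is
  rank-deficient (more unique S elements than jackknife blocks).
* The residual search's family-wise add rate exceeds its per-step alpha
  by construction (see above).
* The spin test is mildly anti-conservative for categorical maps at
  parcel granularity.
* Stratified regressions use a single weighted step (free intercept)
  rather than the genome-wide two-step scheme; on whole-genome-only
  designs the two agree well within one standard error.
* No liftover, allele-frequency harmonization against a panel, indel
  handling, cross-ancestry LDSC, or SNP-level multivariate GWAS.
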