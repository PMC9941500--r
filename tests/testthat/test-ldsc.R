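# The generative model draws z-scores with the exact second-moment
# structure the regression assumes, so parameter recovery against the
# truth record is the oracle for every estimator here.

simTwoFactor <- function(seed, h2 = 0.3, N = 20000, M = 20000) {
  L <- cbind(c(.7, .7, .7, 0, 0, 0), c(0, 0, 0, .7, .7, .7))
  spec <- generativeSpec(L, matrix(c(1, .4, .4, 1), 2), h2 = h2, N = N,
                         M = M, seed = seed)
  simulateSumstats(spec)
}

test_that("univariate LDSC is unbiased under the null and recovers h2", {
  # null: z ~ N(0,1) independent of LD scores
  ld <- simulateLDScores(20000, seed = 91)
  set.seed(92)
  z <- rnorm(20000)
  ss <- new("CleanedSumstats",
            records = data.frame(snp = ldScores(ld)$snp, a1 = "A", a2 = "G",
                                 z = z, n = 20000, maf = 0.3),
            trait = traitMeta("null"), log = numeric())
  fit <- univariateLDSC(ss, ld)
  expect_lt(abs(fit$h2), 2 * fit$h2SE)
  expect_lt(abs(fit$intercept - 1), 2 * fit$interceptSE)

  # signal: one trait with h2 = 0.20
  spec <- generativeSpec(matrix(sqrt(0.5), 1, 1), h2 = 0.2, N = 20000,
                         M = 20000, seed = 93)
  sim <- simulateSumstats(spec)
  fit2 <- univariateLDSC(sim$sumstats[[1]], sim$ld)
  # single replicate: 3-SE band (aggregate 2-SE coverage is checked in the
  # acceptance suite over 20 replicates)
  expect_lt(abs(fit2$h2 - 0.2), 3 * fit2$h2SE)
})

test_that("degenerate all-zero z gives non-positive h2 and near-zero intercept", {
  ld <- simulateLDScores(2000, seed = 94)
  ss <- new("CleanedSumstats",
            records = data.frame(snp = ldScores(ld)$snp, a1 = "A", a2 = "G",
                                 z = 0, n = 1000, maf = 0.3),
            trait = traitMeta("zero"), log = numeric())
  fit <- univariateLDSC(ss, ld, nBlocks = 50L)
  expect_lte(fit$h2, 0)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
})

test_that("bivariate LDSC: self-covariance equals h2; rg recovered; no-overlap intercept near 0", {
  sim <- simTwoFactor(95)
  s1 <- sim$sumstats[[1]]
  self <- bivariateLDSC(s1, s1, sim$ld)
  uni <- univariateLDSC(s1, sim$ld)
  expect_equal(self$covg, uni$h2, tolerance = 1e-10)
  expect_equal(self$intercept, uni$intercept, tolerance = 1e-10)

  # traits 1 and 4 load on different factors with r_between = 0.4 * .7 * .7
  s4 <- sim$sumstats[[4]]
  biv <- bivariateLDSC(s1, s4, sim$ld)
  truth <- sim$truth$Strue[1, 4]
  expect_lt(abs(biv$covg - truth), 2 * biv$covgSE)
  expect_lt(abs(biv$intercept), 2 * biv$interceptSE)
})

test_that("sample overlap shows up in the cross-trait intercept as rho*Ns/sqrt(N1N2)", {
  # rho = 0.5, Ns = 10000, N1 = N2 = 20000 -> expected intercept 0.25
  rho <- matrix(c(0, .5, .5, 0), 2); ns <- matrix(c(0, 1e4, 1e4, 0), 2)
  spec <- generativeSpec(matrix(c(sqrt(.5), sqrt(.5)), 2, 1), h2 = 0.2,
                         N = 20000, M = 20000, overlapRho = rho,
                         overlapN = ns, seed = 96)
  expect_equal(spec$overlapRho[1, 2] * ns[1, 2] / 2e4, 0.25)
  sim <- simulateSumstats(spec)
  biv <- bivariateLDSC(sim$sumstats[[1]], sim$sumstats[[2]], sim$ld)
  expect_lt(abs(biv$intercept - 0.25), 3 * biv$interceptSE)
})

test_that("multivariable LDSC assembles S/V with duplicate-trait limit", {
  sim <- simTwoFactor(97)
  s1 <- sim$sumstats[[1]]
  g <- multivariableLDSC(list(s1, s1), sim$ld)
  V <- samplingCov(g)
  # vech order for k=2: (1,1), (2,1), (2,2); duplicated input makes the
  # estimation errors of the two h2 elements perfectly dependent
  expect_equal(V[1, 3], V[1, 1], tolerance = 1e-12)
  expect_equal(covMatrix(g)[1, 2], covMatrix(g)[1, 1], tolerance = 1e-12)
})

test_that("trait order permutation permutes S and V consistently", {
  sim <- simTwoFactor(98)
  tr <- sim$sumstats[c(1, 2, 4)]
  g1 <- multivariableLDSC(tr, sim$ld)
  g2 <- multivariableLDSC(tr[c(3, 1, 2)], sim$ld)
  ord <- c(3, 1, 2)
  expect_equal(unname(covMatrix(g2)), unname(covMatrix(g1)[ord, ord]),
               tolerance = 1e-10)
  # V re-indexed by the half-vectorization convention
  perm <- gsemCortex:::.vechPermutation(3, ord)
  expect_equal(unname(samplingCov(g2)),
               unname(samplingCov(g1)[perm, perm]), tolerance = 1e-10)
})

test_that("jackknife estimates are block-count stable", {
  sim <- simTwoFactor(99)
  s1 <- sim$sumstats[[1]]
  f200 <- univariateLDSC(s1, sim$ld, nBlocks = 200L)
  f100 <- univariateLDSC(s1, sim$ld, nBlocks = 100L)
  expect_equal(f200$h2, f100$h2, tolerance = 1e-12)  # estimates identical
  expect_lt(abs(f200$h2SE - f100$h2SE) / f200$h2SE, 0.25)
})

test_that("non-positive h2 is flagged and standardization refuses it", {
  ld <- simulateLDScores(5000, seed = 100)
  set.seed(101)
  mk <- function(z) new("CleanedSumstats",
    records = data.frame(snp = ldScores(ld)$snp, a1 = "A", a2 = "G",
                         z = z, n = 5000, maf = 0.3),
    trait = traitMeta("t"), log = numeric())
  # chi-square decreasing in the LD score forces a negative slope
  l2 <- ldScores(ld)$L2
  zNeg <- rnorm(5000, sd = sqrt(pmax(0.2, 1 - 0.2 * l2)))
  g <- quietly(multivariableLDSC(list(mk(zNeg), mk(rnorm(5000))), ld,
                                 nBlocks = 50L))
  expect_true(length(g@flagged) >= 1)
  expect_error(geneticCorrelation(g), "refused")
})

test_that("liability conversion matches the closed form and its oracle value", {
  expect_equal(liabilityTransform(1, 0.5, 0.5), pi / 2, tolerance = 1e-12)
  expect_equal(liabilityTransform(0, 0.3, 0.1), 0)
  # frozen from an independent numeric evaluation of the formula
  expect_equal(liabilityTransform(0.1, 0.5, 0.01), 0.0551907298,
               tolerance = 1e-8)
  expect_error(liabilityTransform(0.1, 0, 0.5), "prevalence")
  expect_error(liabilityTransform(0.1, 0.5, 1), "prevalence")
})

test_that("fewer SNPs than blocks is an error", {
  ld <- simulateLDScores(1000, seed = 102)
  ss <- new("CleanedSumstats",
            records = data.frame(snp = ldScores(ld)$snp[1:100], a1 = "A",
                                 a2 = "G", z = 0.1, n = 1000, maf = 0.3),
            trait = traitMeta("t"), log = numeric())
  expect_error(univariateLDSC(ss, ld, nBlocks = 200L), "blocks")
})
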