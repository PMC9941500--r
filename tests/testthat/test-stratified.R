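# Stratified regression, the zero-order conversion and its brute-force
# oracle, the smoothing screen, and factor-variance enrichment.

test_that("zero-order conversion matches a brute-force oracle elementwise", {
  set.seed(31)
  k <- 3; nm <- paste0("t", 1:k)
  for (rep in 1:5) {
    anns <- paste0("a", 1:4)
    sizes <- setNames(sample(100:1000, 4), anns)
    # random symmetric overlap structure respecting overlap(c,c) = M_c
    ov <- matrix(0, 4, 4, dimnames = list(anns, anns))
    for (i in 1:4) for (j in 1:i) {
      ov[i, j] <- ov[j, i] <- if (i == j) sizes[i] else
        sample(0:min(sizes[i], sizes[j]), 1)
    }
    tau <- lapply(anns, function(a) {
      m <- matrix(rnorm(k * k), k); m <- (m + t(m)) / 2
      dimnames(m) <- list(nm, nm); m
    })
    names(tau) <- anns
    ts <- makeTauSet(tau, sizes, ov, M = 2000)
    zo <- zeroOrderCovariance(ts)
    for (t in anns) {
      # independent brute force: explicit double loop over annotations
      brute <- matrix(0, k, k)
      for (c in anns)
        brute <- brute + (ov[c, t] / sizes[c]) * tau[[c]]
      expect_equal(unname(zeroOrderCov(zo, t)), unname(brute),
                   tolerance = 1e-14)
    }
  }
})

test_that("zero-order limits: disjoint annotations and the whole genome", {
  k <- 2; nm <- c("t1", "t2")
  anns <- c("a1", "a2")
  tau <- lapply(c(2, 5), function(s) {
    m <- matrix(c(.1, .02, .02, .08), 2) * s
    dimnames(m) <- list(nm, nm); m
  })
  names(tau) <- anns
  sizes <- c(a1 = 400, a2 = 600)
  # disjoint: off-diagonal overlaps 0 -> zeta_t = tau_t
  ovD <- diag(sizes); dimnames(ovD) <- list(anns, anns)
  zoD <- zeroOrderCovariance(makeTauSet(tau, sizes, ovD, 1000))
  expect_equal(zeroOrderCov(zoD, "a1"), tau$a1, tolerance = 1e-14)
  expect_equal(zeroOrderCov(zoD, "a2"), tau$a2, tolerance = 1e-14)

  # nested: t inside c with |M_t|/|M_c| = 0.25 -> zeta_t = tau_t + 0.25 tau_c
  sizesN <- c(a1 = 150, a2 = 600)
  ovN <- matrix(c(150, 150, 150, 600), 2, dimnames = list(anns, anns))
  zoN <- zeroOrderCovariance(makeTauSet(tau, sizesN, ovN, 1000))
  expect_equal(zeroOrderCov(zoN, "a1"), tau$a1 + 0.25 * tau$a2,
               tolerance = 1e-13)

  # whole genome: every annotation fully inside -> zeta = sum of taus
  sizesG <- c(a1 = 400, base = 1000)
  ovG <- matrix(c(400, 400, 400, 1000), 2,
                dimnames = list(c("a1", "base"), c("a1", "base")))
  tauG <- tau; names(tauG) <- c("a1", "base")
  zoG <- zeroOrderCovariance(makeTauSet(tauG, sizesG, ovG, 1000))
  expect_equal(zeroOrderCov(zoG, "base"), tauG$a1 + tauG$base,
               tolerance = 1e-13)

  # missing overlap entry is an error
  ts <- makeTauSet(tau, sizes, ovD, 1000)
  expect_error(zeroOrderCovariance(ts, targets = "nope"), "overlap")
})

test_that("stratified regression recovers per-annotation signal shares", {
  # annotations A/B on 50%/50% of SNPs carrying 80%/20% of the variance:
  # per-SNP tau ratio 4:1
  ld <- simulateLDScores(20000, c(A = 0.5, B = 0.5), seed = 32)
  spec <- generativeSpec(matrix(sqrt(0.5), 1), h2 = 0.4, N = 20000,
                         M = 20000, ld = ld,
                         annotShares = c(A = 0.8, B = 0.2), seed = 33)
  sim <- simulateSumstats(spec)
  ts <- stratifiedLDSC(sim$sumstats, ld, annotations = c("A", "B"))
  tA <- ts@tau$A[1, 1]; tB <- ts@tau$B[1, 1]
  seA <- sqrt(ts@Vtau$A[1, 1]); seB <- sqrt(ts@Vtau$B[1, 1])
  expect_lt(abs(tA - 0.32), 2 * seA)
  expect_lt(abs(tB - 0.08), 2 * seB)

  # zero-signal annotation
  ld0 <- simulateLDScores(20000, c(A = 0.3, B = 0.7), seed = 34)
  spec0 <- generativeSpec(matrix(sqrt(0.5), 1), h2 = 0.4, N = 20000,
                          M = 20000, ld = ld0,
                          annotShares = c(B = 1), seed = 35)
  sim0 <- simulateSumstats(spec0)
  ts0 <- stratifiedLDSC(sim0$sumstats, ld0, annotations = c("A", "B"))
  expect_lt(abs(ts0@tau$A[1, 1]), 2 * sqrt(ts0@Vtau$A[1, 1]))

  # collinear annotations are rejected by the rank screen
  ld2 <- simulateLDScores(5000, c(A = 0.4), seed = 36)
  sc <- ldScores(ld2); sc$Acopy <- sc$A
  ld2@scores <- sc
  ld2@sizes <- c(ld2@sizes, Acopy = unname(ld2@sizes["A"]))
  ld2@overlaps <- rbind(cbind(ld2@overlaps,
                              Acopy = ld2@overlaps[, "A"]),
                        Acopy = c(ld2@overlaps["A", ], unname(ld2@sizes["A"])))
  spec2 <- generativeSpec(matrix(sqrt(0.5), 1), h2 = 0.3, N = 10000,
                          M = 5000, ld = ld2, seed = 37)
  sim2 <- simulateSumstats(spec2)
  expect_error(stratifiedLDSC(sim2$sumstats, ld2,
                              annotations = c("A", "Acopy")),
               "collinear")
})

test_that("whole-genome-only stratified regression matches genome-wide LDSC", {
  sim <- simulateSumstats(generativeSpec(
    cbind(c(.7, .7, 0), c(0, 0, .7)), h2 = 0.3, N = 20000, M = 20000,
    seed = 38))
  ts <- stratifiedLDSC(sim$sumstats, sim$ld, annotations = "base")
  g <- multivariableLDSC(sim$sumstats, sim$ld)
  se <- sqrt(diag(samplingCov(g)))
  # the regression collapses to genome-wide LDSC (two-step vs single-step
  # intercept handling leaves sub-SE numerical differences)
  expect_lt(max(abs(vech(ts@tau$base) - vech(covMatrix(g))) / se), 1)
})

test_that("smoothing screen retains benign matrices and excludes unstable ones", {
  nm <- c("t1", "t2")
  mkSet <- function(zeta, se2) {
    p <- 3L
    new("StratifiedCovarianceSet",
        zeta = list(a = zeta), Vzeta = list(a = diag(se2, p)),
        traits = nm, sizes = c(a = 100), M = 1000,
        screen = data.frame(annotation = character(),
                            maxZDiscrepancy = numeric(),
                            retained = logical()))
  }
  pd <- matrix(c(.2, .05, .05, .2), 2, dimnames = list(nm, nm))
  sPD <- screenCovariances(mkSet(pd, 1e-4))
  expect_true(screenTable(sPD)$retained)
  expect_equal(screenTable(sPD)$maxZDiscrepancy, 0)
  expect_equal(zeroOrderCov(sPD, "a"), pd)

  # tiny negative eigenvalue, large SEs: smoothed but retained
  npdSmall <- matrix(c(.2, .201, .201, .2), 2, dimnames = list(nm, nm))
  sOK <- screenCovariances(mkSet(npdSmall, 0.01))  # SE = 0.1
  expect_true(screenTable(sOK)$retained)
  expect_gt(screenTable(sOK)$maxZDiscrepancy, 0)
  ev <- eigen(zeroOrderCov(sOK, "a"))$values
  expect_gte(min(ev), -1e-12)

  # large negative eigenvalue, small SEs: discrepancy crosses 1.96
  npdBig <- matrix(c(.2, .5, .5, .2), 2, dimnames = list(nm, nm))
  sBad <- screenCovariances(mkSet(npdBig, 1e-4))   # SE = 0.01
  expect_false(screenTable(sBad)$retained)
})

test_that("factor enrichment recovers a planted annotation and is 1 genome-wide", {
  ld <- simulateLDScores(20000, c(annA = 0.10, rest = 0.90), seed = 39)
  L <- cbind(c(.7, .7, .7, 0, 0, 0), c(0, 0, 0, .7, .7, .7))
  spec <- generativeSpec(L, matrix(c(1, .4, .4, 1), 2), h2 = 0.3, N = 20000,
                         M = 20000, ld = ld,
                         annotShares = c(annA = 0.2, rest = 0.8), seed = 40)
  sim <- simulateSumstats(spec)
  ts <- stratifiedLDSC(sim$sumstats, ld, annotations = c("base", "annA"))
  zo <- screenCovariances(zeroOrderCovariance(ts))
  g <- multivariableLDSC(sim$sumstats, ld)
  assign <- setNames(c("F1", "F1", "F1", "F2", "F2", "F2"),
                     paste0("trait", 1:6))
  gw <- fitGenomicSEM(covMatrix(g), samplingCov(g),
                      buildFactorModel(assign, "correlated"))
  enr <- factorEnrichment(gw, zo)
  base <- enr[enr$annotation == "base", ]
  expect_equal(base$enrichment, c(1, 1))   # definitional
  annA <- enr[enr$annotation == "annA", ]
  expect_true(all(abs(annA$enrichment - 2) <= 2 * annA$se))
  expect_equal(attr(enr, "bonferroni"), 0.05 / 4)
})

test_that("summing zero-order matrices over a disjoint partition returns S", {
  ld <- simulateLDScores(20000, c(A = 0.4, B = 0.6), seed = 41)
  spec <- generativeSpec(cbind(c(.7, .7), c(0, 0)), h2 = 0.25, N = 20000,
                         M = 20000, ld = ld,
                         annotShares = c(A = 0.5, B = 0.5), seed = 42)
  sim <- simulateSumstats(spec)
  ts <- stratifiedLDSC(sim$sumstats, ld, annotations = c("A", "B"))
  zo <- zeroOrderCovariance(ts)
  g <- multivariableLDSC(sim$sumstats, ld)
  tot <- zeroOrderCov(zo, "A") + zeroOrderCov(zo, "B")
  se <- sqrt(diag(samplingCov(g)))
  expect_lt(max(abs(vech(tot) - vech(covMatrix(g))) / se), 1)
})
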