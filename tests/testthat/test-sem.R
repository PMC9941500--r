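# Confirmatory modeling on (S, V): identification rules, the DWLS fitter,
# fit indices, the residual search and joint/omnibus machinery.

test_that("model builders enforce the identification rules and df arithmetic", {
  # common factor on 6 indicators: 21 - (6 loadings + 6 residuals) = 9
  expect_equal(modelDf(buildFactorModel(toyAssign, "common")), 9L)

  # two-indicator factor gets an equality group on its loadings
  a <- setNames(c("F1", "F1", "F1", "F2", "F2"), paste0("x", 1:5))
  mod <- buildFactorModel(a, "correlated")
  pt <- mod@ptable
  eqLabs <- pt$label[pt$mat == "lambda" & pt$row %in% 4:5]
  expect_equal(length(unique(eqLabs)), 1L)

  # single-indicator factor: residual variance fixed to 0; bifactor keeps
  # all factor covariances absent (fixed 0)
  b <- setNames(c("F1", "F1", "F1", "F2", "F2", "F5"), paste0("x", 1:6))
  mb <- buildFactorModel(b, "bifactor")
  ptb <- mb@ptable
  r6 <- ptb[ptb$mat == "theta" & ptb$row == 6 & ptb$col == 6, ]
  expect_false(r6$free); expect_equal(r6$value, 0)
  expect_equal(nrow(ptb[ptb$mat == "psi" & ptb$row != ptb$col, ]), 0L)
  # psi diagonal all fixed to 1 (unit-variance identification)
  psiD <- ptb[ptb$mat == "psi" & ptb$row == ptb$col, ]
  expect_true(all(!psiD$free) && all(psiD$value == 1))

  expect_error(buildFactorModel(setNames(character(0), character(0)),
                                "correlated"))
})

test_that("exact model-implied S is recovered with chi2 ~ 0, CFI 1, SRMR ~ 0", {
  mod <- buildFactorModel(toyAssign, "correlated")
  fit <- fitGenomicSEM(toyS, toyV, mod)
  expect_true(isConverged(fit))
  expect_lt(fit@chi2, 1e-6)
  est <- semEstimates(fit)
  truth <- c(`F1=~x1` = .8, `F1=~x2` = .7, `F1=~x3` = .6,
             `F2=~x4` = .7, `F2=~x5` = .6, `F2=~x6` = .5, `F1~~F2` = .4)
  expect_lt(max(abs(est[names(truth)] - truth)), 1e-4)
  fi <- fitIndices(fit)
  expect_equal(fi$CFI, 1)
  expect_lt(fi$SRMR, 1e-6)
})

test_that("misfit produces positive chi2 and SRMR; bifactor fits no worse", {
  wrong <- setNames(c("F1", "F1", "F1", "F1", "F2", "F2"), paste0("x", 1:6))
  fitW <- fitGenomicSEM(toyS, toyV, buildFactorModel(wrong, "correlated"))
  expect_gt(fitW@chi2, 0)
  expect_gt(fitIndices(fitW)$SRMR, 0)

  # on a perturbed S the bifactor (more free parameters) cannot fit worse
  set.seed(21)
  Sn <- drawS(bifS, diag(2e-4, 45))
  corFit <- fitGenomicSEM(Sn, diag(2e-4, 45),
                          buildFactorModel(bifAssign, "correlated"))
  bifFit <- fitGenomicSEM(Sn, diag(2e-4, 45),
                          buildFactorModel(bifAssign, "bifactor"))
  expect_lte(bifFit@chi2, corFit@chi2 + 1e-6)
})

test_that("CFI arithmetic, clamping and the nested-AIC identity hold", {
  expect_equal(gsemCortex:::.cfi(50, 10, 500, 15), 1 - 40 / 485,
               tolerance = 1e-12)
  expect_equal(gsemCortex:::.cfi(5, 10, 500, 15), 1)   # chi2 < df guard
  expect_equal(gsemCortex:::.cfi(600, 10, 500, 15), 0) # clamp at 0

  mod1 <- buildFactorModel(toyAssign, "correlated")
  mod2 <- constrainEqual(mod1, c("F1=~x1", "F1=~x2"))
  set.seed(22)
  Sn <- drawS(toyS, toyV)
  f1 <- fitGenomicSEM(Sn, toyV, mod1); f2 <- fitGenomicSEM(Sn, toyV, mod2)
  a1 <- fitIndices(f1)$AIC; a2 <- fitIndices(f2)$AIC
  expect_equal(a2 - a1, (f2@chi2 - f1@chi2) - 2 * (f2@df - f1@df),
               tolerance = 1e-8)
})

test_that("estimates are invariant to consistent relabeling of S, V and spec", {
  ord <- c(4, 1, 6, 2, 5, 3)
  perm <- gsemCortex:::.vechPermutation(6, ord)
  S2 <- toyS[ord, ord]; V2 <- toyV[perm, perm]
  mod <- buildFactorModel(toyAssign, "correlated")
  f1 <- fitGenomicSEM(toyS, toyV, mod)
  f2 <- fitGenomicSEM(S2, V2, mod)   # S reordered; fitter matches by name
  expect_equal(semEstimates(f2), semEstimates(f1), tolerance = 1e-8)
})

test_that("WLS recovers generating parameters from noisy (S, V) at 2-SE coverage", {
  mod <- buildFactorModel(toyAssign, "correlated")
  truth <- c(`F1=~x1` = .8, `F1=~x2` = .7, `F1=~x3` = .6,
             `F2=~x4` = .7, `F2=~x5` = .6, `F2=~x6` = .5, `F1~~F2` = .4)
  set.seed(23)
  hits <- 0L; tot <- 0L
  for (r in 1:20) {
    Sn <- drawS(toyS, toyV)
    f <- fitGenomicSEM(Sn, toyV, mod)
    ok <- abs(semEstimates(f)[names(truth)] - truth) <=
      2 * semSE(f)[names(truth)]
    hits <- hits + sum(ok); tot <- tot + length(ok)
  }
  expect_gte(hits / tot, 0.9)
})

test_that("non-convergence is reportable, not a crash", {
  mod <- buildFactorModel(toyAssign, "correlated")
  set.seed(24)
  Sn <- drawS(toyS, toyV)
  fit <- fitGenomicSEM(Sn, toyV, mod, maxIter = 0L)
  expect_false(isConverged(fit))
  expect_s4_class(fit, "SEMFit")
})

test_that("residual search finds exactly a planted covariance and stops", {
  mod <- buildFactorModel(toyAssign, "correlated")
  Sp <- toyS
  Sp["x2", "x5"] <- Sp["x5", "x2"] <- Sp["x2", "x5"] + 0.15
  rs <- residualSearch(Sp, toyV, mod, alpha = 0.01)
  kept <- rs$trace[rs$trace$kept, ]
  expect_equal(nrow(kept), 1L)
  expect_setequal(c(kept$ind1, kept$ind2), c("x2", "x5"))
  expect_equal(kept$estimate, 0.15, tolerance = 1e-3)
  # the final candidate (not added) failed the threshold
  last <- rs$trace[nrow(rs$trace), ]
  expect_false(last$kept); expect_gte(last$p, 0.01)

  # exactly model-implied S: nothing significant to add
  rs0 <- residualSearch(toyS, toyV, mod, alpha = 0.01)
  expect_equal(sum(rs0$trace$kept), 0L)
})

test_that("general-factor share is the squared standardized general loading", {
  Lg <- cbind(c(.5, .6, .7, .6, .6, .6, .6, .6, .6), bifLoadings[, 2:4])
  S <- popCov(Lg); dimnames(S) <- dimnames(bifS)
  fit <- fitGenomicSEM(S, diag(1e-4, 45),
                       buildFactorModel(bifAssign, "bifactor"))
  gs <- generalFactorShare(fit)
  expect_equal(unname(gs$share[1:3]), c(.25, .36, .49), tolerance = 1e-3)
  expect_equal(gs$average, mean(Lg[, 1]^2), tolerance = 1e-3)
  expect_error(generalFactorShare(
    fitGenomicSEM(toyS, toyV, buildFactorModel(toyAssign, "correlated"))),
    "bifactor")
})

# joint brain-external machinery -------------------------------------------

extModel <- function() {
  e <- buildFactorModel(setNames(rep("gext", 4), paste0("cog", 1:4)),
                        "common")
  e@factors <- "gext"
  e@ptable$label <- sub("F1", "gext", e@ptable$label)
  e
}

jointPop <- function(rg = c(.3, 0, 0, 0)) {
  Le <- c(.7, .6, .65, .75)
  Se <- Le %o% Le; diag(Se) <- 1
  cross <- bifLoadings %*% matrix(rg, 4) %*% t(Le)
  S <- rbind(cbind(bifS, cross), cbind(t(cross), Se))
  nms <- c(rownames(bifS), paste0("cog", 1:4))
  dimnames(S) <- list(nms, nms)
  S
}

test_that("joint external model recovers factor correlations with Bonferroni flags", {
  S <- jointPop(c(.3, 0, 0, 0))
  V <- diag(2e-4, 13 * 14 / 2)
  bMod <- buildFactorModel(bifAssign, "bifactor")
  jm <- jointExternalModel(bMod, extModel(), S, V, searchResiduals = FALSE)
  co <- jm$correlations
  expect_equal(co$estimate[co$brainFactor == "g"], 0.3, tolerance = 2e-3)
  resid <- co$estimate[co$brainFactor != "g"]
  expect_lt(max(abs(resid)), 2 * max(co$se))
  expect_equal(jm$threshold, 0.05 / (9 * 4))
  expect_true(co$significant[co$brainFactor == "g"])

  # null construction: every correlation within 2 SE of zero
  jm0 <- jointExternalModel(bMod, extModel(), jointPop(c(0, 0, 0, 0)), V,
                            searchResiduals = FALSE)
  expect_true(all(abs(jm0$correlations$estimate) <=
                  2 * pmax(jm0$correlations$se, 1e-6)))
})

test_that("omnibus equality test: trivial identity, type-I rate and power", {
  S <- jointPop(c(.2, .2, .2, .2))   # truly equal correlations
  V <- diag(2e-4, 91)
  bMod <- buildFactorModel(bifAssign, "bifactor")
  joint <- combineModels(bMod, extModel())
  conMod <- constrainFactorCorrelations(joint, "gext")
  fitF <- fitGenomicSEM(S, V, joint)
  expect_equal(omnibusEqualityTest(fitF, fitF)$dChi2, 0)
  expect_equal(omnibusEqualityTest(fitF, fitF)$dDf, 0L)

  set.seed(25)
  alpha <- 0.05
  rejNull <- rejAlt <- logical(60)
  Salt <- jointPop(c(.4, 0, 0, 0))
  for (r in 1:60) {
    SnN <- drawS(S, V)
    fF <- fitGenomicSEM(SnN, V, joint)
    fC <- fitGenomicSEM(SnN, V, conMod)
    rejNull[r] <- isTRUE(omnibusEqualityTest(fF, fC)$p < alpha)
    SnA <- drawS(Salt, V)
    fF2 <- fitGenomicSEM(SnA, V, joint)
    fC2 <- fitGenomicSEM(SnA, V, conMod)
    rejAlt[r] <- isTRUE(omnibusEqualityTest(fF2, fC2)$p < alpha)
  }
  # type-I within binomial noise of alpha (60 draws: upper bound ~ 0.15)
  expect_lte(mean(rejNull), 0.15)
  expect_gte(mean(rejAlt), 0.8)
})

test_that("model syntax round-trips through the parser", {
  txt <- "
    F1 =~ x1 + x2 + x3
    F2 =~ x4 + x5 + x6
    F1 ~~ F2
  "
  mod <- parseModelSyntax(txt, paste0("x", 1:6))
  fit <- fitGenomicSEM(toyS, toyV, mod)
  expect_lt(fit@chi2, 1e-6)
  expect_equal(unname(semEstimates(fit)["F1~~F2"]), 0.4, tolerance = 1e-4)
})
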