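## Multivariable LD-score regression with a multivariate block jackknife.
##
## All pairwise regressions share one SNP universe (the intersection of the
## traits' munged SNPs with the LD-score panel, in panel order) and one set
## of contiguous equal-count jackknife blocks, so that the sampling
## covariance V of vech(S) captures dependence of estimation errors across
## elements (e.g. from participant sample overlap).

## weighted least squares of y on (1, x) restricted to `step1`, then the
## slope on the full set with the intercept fixed (the standard two-step
## LDSC estimator); `w` are fixed regression weights.
.twoStep <- function(y, x, w, step1) {
  X1 <- cbind(1, x[step1]); w1 <- w[step1]
  cf <- solve(crossprod(X1 * w1, X1), crossprod(X1 * w1, y[step1]))
  int <- cf[1L]
  slope <- sum(w * x * (y - int)) / sum(w * x * x)
  c(slope, int)
}

## delete-one-block jackknife replicates of the two-step estimator with
## weights held fixed at their full-sample values (LDSC convention)
.twoStepJack <- function(y, x, w, step1, blocks, nBlocks) {
  f <- factor(blocks, levels = seq_len(nBlocks))
  ## step-1 sufficient statistics per block (2x2 normal equations)
  w1 <- w * step1
  s11 <- rowsum(w1, f); s1x <- rowsum(w1 * x, f); s1xx <- rowsum(w1 * x * x, f)
  s1y <- rowsum(w1 * y, f); s1xy <- rowsum(w1 * x * y, f)
  T11 <- sum(s11); T1x <- sum(s1x); T1xx <- sum(s1xx)
  T1y <- sum(s1y); T1xy <- sum(s1xy)
  ## step-2 sufficient statistics per block
  sxx <- rowsum(w * x * x, f); sxy <- rowsum(w * x * y, f); sx <- rowsum(w * x, f)
  Txx <- sum(sxx); Txy <- sum(sxy); Tx <- sum(sx)
  reps <- matrix(NA_real_, nBlocks, 2L,
                 dimnames = list(NULL, c("slope", "int")))
  for (b in seq_len(nBlocks)) {
    a11 <- T11 - s11[b]; a1x <- T1x - s1x[b]; a1xx <- T1xx - s1xx[b]
    det <- a11 * a1xx - a1x * a1x
    intB <- ((T1y - s1y[b]) * a1xx - (T1xy - s1xy[b]) * a1x) / det
    reps[b, 2L] <- intB
    reps[b, 1L] <- ((Txy - sxy[b]) - intB * (Tx - sx[b])) / (Txx - sxx[b])
  }
  reps
}

## align k traits on the LD panel's SNPs (panel order); returns Z and N
## matrices plus the matched score table
.alignTraits <- function(traits, ld, nBlocks) {
  stopifnot(is(ld, "LDScorePanel"))
  sc <- ld@scores
  common <- sc$snp
  for (t in traits) common <- intersect(common, t@records$snp)
  if (length(common) == 0L) stop("no SNPs shared between sumstats and LD scores")
  if (length(common) < nBlocks)
    stop("fewer shared SNPs (", length(common), ") than jackknife blocks (",
         nBlocks, ")")
  sc <- sc[match(common, sc$snp), , drop = FALSE]
  Z <- N <- matrix(NA_real_, length(common), length(traits))
  for (i in seq_along(traits)) {
    r <- traits[[i]]@records
    m <- match(common, r$snp)
    Z[, i] <- r$z[m]; N[, i] <- r$n[m]
  }
  if (any(!is.finite(Z)))
    stop("non-finite z-statistics; filter upstream with mungeSumstats")
  nm <- vapply(traits, function(t) t@trait$name %||% "", "")
  nm[nm == ""] <- paste0("trait", seq_along(traits))[nm == ""]
  colnames(Z) <- colnames(N) <- nm
  list(Z = Z, N = N, scores = sc)
}

## LDSC heteroskedasticity + overcounting weights for a trait pair.
## ci = model-implied per-SNP variance terms N_i h2_i l/M + intercept_i,
## c12 = model-implied cross term.  For i = j this reduces to the standard
## univariate 1 / (2 c^2 max(l,1)) weight.
.pairWeights <- function(l2, c1, c2, c12) {
  1 / (pmax(c1 * c2 + c12 * c12, 1e-8) * pmax(l2, 1))
}

## one trait-pair regression (univariate when i == j): two weight updates,
## two-step estimation, jackknife replicates
.pairLDSC <- function(z1, z2, n1, n2, l2, M, blocks, nBlocks,
                      h1, int1, h2, int2) {
  y <- z1 * z2
  x <- sqrt(n1 * n2) * l2 / M
  step1 <- (z1 * z1 < 30) & (z2 * z2 < 30)
  if (sum(step1) < max(50L, 2L * nBlocks)) step1 <- rep(TRUE, length(y))
  c1 <- n1 * max(h1, 0) * l2 / M + int1
  c2 <- n2 * max(h2, 0) * l2 / M + int2
  rg <- 0; ic <- 0
  for (iter in 1:2) {
    w <- .pairWeights(l2, c1, c2, sqrt(n1 * n2) * rg * l2 / M + ic)
    est <- .twoStep(y, x, w, step1)
    rg <- max(min(est[1L], 1), -1); ic <- est[2L]
  }
  reps <- .twoStepJack(y, x, w, step1, blocks, nBlocks)
  list(est = est[1L], int = est[2L], reps = reps)
}

## crude closed-form starting value for h2 used only to seed the weights
.h2Guess <- function(z, n, l2, M) {
  g <- M * (mean(z * z) - 1) / mean(n * l2)
  max(min(g, 1), 0)
}

## preliminary univariate fit used to seed the weights of every trait-pair
## regression; using the same seed for diagonal and off-diagonal pairs
## makes self-covariance identities exact
.uniSeed <- function(z, n, l2, M, blocks, nBlocks) {
  g <- .h2Guess(z, n, l2, M)
  .pairLDSC(z, z, n, n, l2, M, blocks, nBlocks, g, 1, g, 1)
}

#' Univariate LD-score regression
#'
#' Regresses per-SNP chi-square statistics on \eqn{N l_j / M} with a free
#' intercept, using the standard two-step scheme (intercept estimated on
#' SNPs with chi-square < 30, slope on the full set) and LDSC
#' heteroskedasticity/overcounting weights. Standard errors come from a
#' delete-one-block jackknife over contiguous equal-count SNP blocks.
#'
#' @param ss a \code{\link{CleanedSumstats-class}}.
#' @param ld an \code{\link{LDScorePanel-class}}.
#' @param nBlocks jackknife block count (default 200).
#' @return List with \code{h2} (observed scale), \code{intercept}, their
#'   jackknife SEs, and \code{nSNPs}.
#' @export
univariateLDSC <- function(ss, ld, nBlocks = 200L) {
  al <- .alignTraits(list(ss), ld, nBlocks)
  z <- al$Z[, 1L]; n <- al$N[, 1L]; l2 <- al$scores$L2
  M <- ld@M
  blocks <- .blockIds(length(z), nBlocks)
  u0 <- .uniSeed(z, n, l2, M, blocks, nBlocks)
  fit <- .pairLDSC(z, z, n, n, l2, M, blocks, nBlocks,
                   u0$est, u0$int, u0$est, u0$int)
  V <- .jackknifeCov(fit$reps)
  list(h2 = fit$est, intercept = fit$int,
       h2SE = sqrt(V[1L, 1L]), interceptSE = sqrt(V[2L, 2L]),
       nSNPs = length(z), nBlocks = as.integer(nBlocks))
}

#' Bivariate LD-score regression
#'
#' Regresses \eqn{z_{1j} z_{2j}} on \eqn{\sqrt{N_1 N_2}\, l_j / M} with a
#' free intercept. The intercept estimates the sample-overlap index
#' \eqn{\rho N_s / \sqrt{N_1 N_2}} (phenotypic correlation weighted by
#' proportional sample overlap); the slope is the genetic covariance.
#'
#' @param ss1,ss2 \code{\link{CleanedSumstats-class}} objects.
#' @inheritParams univariateLDSC
#' @return List with \code{covg}, \code{intercept}, jackknife SEs, and
#'   \code{nSNPs}.
#' @export
bivariateLDSC <- function(ss1, ss2, ld, nBlocks = 200L) {
  al <- .alignTraits(list(ss1, ss2), ld, nBlocks)
  l2 <- al$scores$L2; M <- ld@M
  blocks <- .blockIds(nrow(al$Z), nBlocks)
  u1 <- .uniSeed(al$Z[, 1L], al$N[, 1L], l2, M, blocks, nBlocks)
  u2 <- .uniSeed(al$Z[, 2L], al$N[, 2L], l2, M, blocks, nBlocks)
  fit <- .pairLDSC(al$Z[, 1L], al$Z[, 2L], al$N[, 1L], al$N[, 2L], l2, M,
                   blocks, nBlocks, u1$est, u1$int, u2$est, u2$int)
  V <- .jackknifeCov(fit$reps)
  list(covg = fit$est, intercept = fit$int,
       covgSE = sqrt(V[1L, 1L]), interceptSE = sqrt(V[2L, 2L]),
       nSNPs = nrow(al$Z), nBlocks = as.integer(nBlocks))
}

#' Multivariable LD-score regression
#'
#' Runs all univariate and bivariate LDSC regressions for k traits on their
#' shared SNP set and assembles the genetic covariance matrix S together
#' with the sampling covariance V of its unique elements from a single
#' multivariate delete-one-block jackknife, so that off-diagonal V entries
#' capture dependence between estimation errors (e.g. sample overlap).
#'
#' @param traits list of \code{\link{CleanedSumstats-class}} objects
#'   (k >= 2).
#' @inheritParams univariateLDSC
#' @return A \code{\link{GeneticCovariance-class}} object. Traits with
#'   non-positive estimated heritability are flagged (standardization via
#'   \code{\link{geneticCorrelation}} refuses them) with a warning.
#' @export
multivariableLDSC <- function(traits, ld, nBlocks = 200L) {
  k <- length(traits)
  if (k < 2L) stop("need at least two traits")
  al <- .alignTraits(traits, ld, nBlocks)
  Z <- al$Z; N <- al$N; l2 <- al$scores$L2; M <- ld@M
  nm <- colnames(Z)
  blocks <- .blockIds(nrow(Z), nBlocks)

  uni <- vector("list", k)
  for (i in seq_len(k))
    uni[[i]] <- .uniSeed(Z[, i], N[, i], l2, M, blocks, nBlocks)

  S <- matrix(0, k, k)
  I <- matrix(0, k, k)
  ISE <- matrix(0, k, k)
  p <- k * (k + 1L) / 2L
  idx <- vechIndices(k)
  reps <- matrix(NA_real_, nBlocks, p)
  intReps <- matrix(NA_real_, nBlocks, p)
  for (r in seq_len(p)) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    f <- .pairLDSC(Z[, i], Z[, j], N[, i], N[, j], l2, M, blocks, nBlocks,
                   uni[[i]]$est, uni[[i]]$int, uni[[j]]$est, uni[[j]]$int)
    S[i, j] <- S[j, i] <- f$est
    I[i, j] <- I[j, i] <- f$int
    reps[, r] <- f$reps[, 1L]
    intReps[, r] <- f$reps[, 2L]
  }
  V <- .jackknifeCov(reps)
  iv <- diag(.jackknifeCov(intReps))
  for (r in seq_len(p)) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    ISE[i, j] <- ISE[j, i] <- sqrt(iv[r])
  }
  dimnames(S) <- dimnames(I) <- dimnames(ISE) <- list(nm, nm)

  flagged <- nm[diag(S) <= 0]
  if (length(flagged))
    warning("non-positive estimated heritability for: ",
            paste(flagged, collapse = ", "),
            " (standardization will refuse these traits)")
  new("GeneticCovariance", S = S, V = V, intercepts = I, interceptSE = ISE,
      nSNPs = nrow(Z), nBlocks = as.integer(nBlocks), flagged = flagged)
}

#' Observed-to-liability scale conversion of SNP heritability
#'
#' \deqn{h^2_{liab} = h^2_{obs} \frac{K^2 (1-K)^2}{P(1-P)\,\phi(\tau_K)^2}}
#' with \eqn{K} the population prevalence, \eqn{P} the sample prevalence
#' and \eqn{\tau_K} the standard-normal quantile at \eqn{1-K}. When the
#' sum of effective sample sizes is used for a binary trait, supply
#' \eqn{P = 0.5}: the effective N already accounts for ascertainment.
#'
#' @param h2Obs observed-scale heritability (or covariance element).
#' @param samplePrev sample prevalence P in (0,1).
#' @param popPrev population prevalence K in (0,1).
#' @return Liability-scale heritability.
#' @examples
#' liabilityTransform(1, 0.5, 0.5)  # multiplier pi/2
#' @export
liabilityTransform <- function(h2Obs, samplePrev, popPrev) {
  if (samplePrev <= 0 || samplePrev >= 1)
    stop("sample prevalence must lie in (0,1)")
  if (popPrev <= 0 || popPrev >= 1)
    stop("population prevalence must lie in (0,1)")
  K <- popPrev; P <- samplePrev
  z <- stats::dnorm(stats::qnorm(1 - K))
  h2Obs * K^2 * (1 - K)^2 / (P * (1 - P) * z^2)
}
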