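# Shared fixtures built in code: population covariance matrices with known
# factor structure, small reference/sumstats tables, and convenience
# constructors used across the unit tests.

# population covariance of a factor model with unit indicator variances
popCov <- function(loadings, factorCor = diag(ncol(loadings))) {
  L <- as.matrix(loadings)
  S <- L %*% factorCor %*% t(L)
  diag(S) <- 1
  S
}

# two-correlated-factor toy: 6 indicators, heterogeneous loadings
toyAssign <- setNames(rep(c("F1", "F2"), each = 3), paste0("x", 1:6))
toyLoadings <- cbind(c(.8, .7, .6, 0, 0, 0), c(0, 0, 0, .7, .6, .5))
toyPhi <- matrix(c(1, .4, .4, 1), 2)
toyS <- local({
  S <- popCov(toyLoadings, toyPhi)
  dimnames(S) <- list(names(toyAssign), names(toyAssign))
  S
})
toyV <- diag(1e-4, 21)

# 9-indicator bifactor (3 group factors; heterogeneous loadings so that
# general-vs-group correlations with external factors are identified)
bifAssign <- setNames(rep(c("F1", "F2", "F3"), each = 3), paste0("roi", 1:9))
bifLoadings <- local({
  L <- matrix(0, 9, 4)
  L[, 1] <- seq(.45, .7, length.out = 9)
  L[1:3, 2] <- c(.55, .42, .5)
  L[4:6, 3] <- c(.5, .6, .4)
  L[7:9, 4] <- c(.45, .55, .6)
  L
})
bifS <- local({
  S <- popCov(bifLoadings)
  dimnames(S) <- list(names(bifAssign), names(bifAssign))
  S
})

# small reference list and raw sumstats table for munge tests
refTable <- data.frame(
  SNP = paste0("rs", 1:5),
  A1 = c("A", "C", "G", "T", "A"),
  A2 = c("G", "T", "A", "C", "C"),
  stringsAsFactors = FALSE)

rawTable <- data.frame(
  SNP = paste0("rs", 1:5),
  A1 = c("A", "T", "G", "T", "A"),
  A2 = c("G", "C", "A", "C", "C"),
  Z = c(1, 2, -1, 0.5, 2),
  N = 1000,
  MAF = c(.3, .2, .005, .4, .25),
  stringsAsFactors = FALSE)

# draw a vech-scale covariance observation s ~ N(sigma, V) and return S
drawS <- function(Sigma, V) {
  s <- vech(Sigma) + drop(stats::rnorm(nrow(V)) %*% chol(V))
  k <- nrow(Sigma)
  out <- matrix(0, k, k)
  out[lower.tri(out, diag = TRUE)] <- s
  out <- out + t(out); diag(out) <- diag(out) / 2
  dimnames(out) <- dimnames(Sigma)
  out
}

quietly <- function(expr) suppressWarnings(suppressMessages(expr))

# build a StratifiedTauSet by hand (k traits, annotations with given
# overlap structure) from arbitrary tau matrices; replicates are the taus
# plus small deterministic jitter so jackknife covariances exist
makeTauSet <- function(tau, sizes, overlaps, M, nBlocks = 40L) {
  k <- nrow(tau[[1]])
  p <- k * (k + 1) / 2
  reps <- lapply(seq_along(tau), function(a) {
    base <- matrix(rep(vech(tau[[a]]), each = nBlocks), nBlocks, p)
    base + matrix(sin(seq_len(nBlocks * p) + a), nBlocks, p) * 1e-3
  })
  names(reps) <- names(tau)
  new("StratifiedTauSet", tau = tau,
      Vtau = lapply(reps, gsemCortex:::.jackknifeCov), reps = reps,
      traits = rownames(tau[[1]]), sizes = sizes, overlaps = overlaps,
      M = M, intercepts = diag(k))
}
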