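## Stratified multivariable LD-score regression, zero-order conversion,
## positive-definiteness screening and factor-variance enrichment.

#' StratifiedTauSet: conditional per-annotation coheritability matrices
#'
#' Holds, for every annotation in the regression model, the k x k matrix
#' of tau coefficients (co-heritability within the annotation controlling
#' for overlap with the other annotations) together with the jackknife
#' replicates needed to propagate sampling covariance through the
#' zero-order conversion.
#'
#' @slot tau named list of k x k tau matrices.
#' @slot Vtau named list of sampling covariances of \code{vech(tau_c)}.
#' @slot reps named list of B x p jackknife replicate matrices.
#' @slot traits trait labels.
#' @slot sizes,overlaps,M annotation bookkeeping from the LD panel.
#' @slot intercepts k x k intercept matrix from the stratified regression.
#' @export
setClass("StratifiedTauSet",
  slots = c(tau = "list", Vtau = "list", reps = "list", traits = "character",
            sizes = "numeric", overlaps = "matrix", M = "numeric",
            intercepts = "matrix"))

setMethod("show", "StratifiedTauSet", function(object) {
  cat("StratifiedTauSet:", length(object@tau), "annotations x",
      length(object@traits), "traits\n")
})

#' StratifiedCovarianceSet: zero-order stratified genetic covariances
#'
#' Per target annotation t, the zero-order genetic covariance matrix
#' (the overlap-weighted sum of tau matrices) with its jackknife sampling
#' covariance, plus the smoothing screen bookkeeping.
#'
#' @slot zeta named list of k x k zero-order covariance matrices.
#' @slot Vzeta named list of sampling covariances of \code{vech(zeta_t)}.
#' @slot traits trait labels.
#' @slot sizes,M annotation sizes and universe size.
#' @slot screen data.frame (annotation, maxZDiscrepancy, retained) filled
#'   by \code{\link{screenCovariances}}.
#' @export
setClass("StratifiedCovarianceSet",
  slots = c(zeta = "list", Vzeta = "list", traits = "character",
            sizes = "numeric", M = "numeric", screen = "data.frame"))

setMethod("show", "StratifiedCovarianceSet", function(object) {
  cat("StratifiedCovarianceSet:", length(object@zeta), "annotations x",
      length(object@traits), "traits\n")
  if (nrow(object@screen))
    cat("  screened:", sum(!object@screen$retained), "removed\n")
})

#' Accessors for stratified covariance sets
#' @param x a \code{\link{StratifiedCovarianceSet-class}}.
#' @param annotation annotation name.
#' @return \code{zeroOrderCov} one zeta matrix; \code{zeroOrderSamplingCov}
#'   its sampling covariance; \code{screenTable} the screen bookkeeping.
#' @export
zeroOrderCov <- function(x, annotation) x@zeta[[annotation]]

#' @rdname zeroOrderCov
#' @export
zeroOrderSamplingCov <- function(x, annotation) x@Vzeta[[annotation]]

#' @rdname zeroOrderCov
#' @export
screenTable <- function(x) x@screen

#' Stratified multivariable LD-score regression
#'
#' For every trait pair, jointly regresses \eqn{z_{1j} z_{2j}} on the
#' per-annotation design \eqn{\sqrt{N_1 N_2}\, l(j,c) / M_c} with a free
#' intercept. The coefficient on annotation c is the conditional
#' coheritability \eqn{\tau_c} (controlling for overlap with the other
#' annotations). Per-annotation sampling covariances come from a single
#' multivariate delete-one-block jackknife shared across pairs.
#'
#' With the whole-genome annotation as the only column, the regression
#' collapses to genome-wide LDSC.
#'
#' @param traits list of \code{\link{CleanedSumstats-class}} (k >= 1).
#' @param ld an \code{\link{LDScorePanel-class}} with stratified score
#'   columns for every annotation.
#' @param annotations annotation names to include (default: all in the
#'   panel).
#' @param nBlocks jackknife blocks (default 200).
#' @return A \code{\link{StratifiedTauSet-class}}.
#' @export
stratifiedLDSC <- function(traits, ld, annotations = names(ld@sizes),
                           nBlocks = 200L) {
  k <- length(traits)
  al <- .alignTraits(traits, ld, nBlocks)
  Z <- al$Z; N <- al$N; sc <- al$scores
  l2 <- sc$L2; M <- ld@M
  nm <- colnames(Z)
  C <- length(annotations)
  if (!all(annotations %in% names(sc)))
    stop("missing stratified score columns for: ",
         paste(setdiff(annotations, names(sc)), collapse = ", "))
  Lmat <- as.matrix(sc[, annotations, drop = FALSE])
  Mc <- ld@sizes[annotations]
  blocks <- .blockIds(nrow(Z), nBlocks)
  f <- factor(blocks, levels = seq_len(nBlocks))

  ## rank screen on the design (shared up to the sqrt(N1 N2) scale)
  X0 <- cbind(1, sweep(Lmat, 2L, Mc, "/"))
  qrX <- qr(X0)
  if (qrX$rank < ncol(X0)) {
    drop <- colnames(X0)[qrX$pivot[(qrX$rank + 1L):ncol(X0)]]
    stop("rank-deficient annotation design; collinear annotations: ",
         paste(drop, collapse = ", "))
  }

  ## genome-wide univariate fits to seed the weights
  uni <- lapply(seq_len(k), function(i)
    .uniSeed(Z[, i], N[, i], l2, M, blocks, nBlocks))

  p <- k * (k + 1L) / 2L
  idx <- vechIndices(k)
  est <- matrix(NA_real_, C + 1L, p)      # intercept + taus, per pair
  reps <- array(NA_real_, c(nBlocks, C + 1L, p))
  for (r in seq_len(p)) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    y <- Z[, i] * Z[, j]
    sn <- sqrt(N[, i] * N[, j])
    X <- cbind(1, sn * sweep(Lmat, 2L, Mc, "/"))
    c1 <- N[, i] * max(uni[[i]]$est, 0) * l2 / M + uni[[i]]$int
    c2 <- N[, j] * max(uni[[j]]$est, 0) * l2 / M + uni[[j]]$int
    c12 <- if (i == j) c1 else
      sn * 0 * l2 / M + 0    # cross term seeded at 0 for distinct traits
    w <- .pairWeights(l2, c1, c2, c12)
    Xw <- X * w
    A <- crossprod(Xw, X); b <- crossprod(Xw, y)
    est[, r] <- solve(A, b)
    ## per-block sufficient statistics for the jackknife
    AbList <- array(0, c(nBlocks, C + 1L, C + 1L))
    for (u in seq_len(C + 1L)) {
      Xu <- Xw[, u] * X
      AbList[, u, ] <- as.matrix(rowsum(Xu, f))
    }
    bb <- as.matrix(rowsum(Xw * y, f))
    for (bk in seq_len(nBlocks)) {
      Abk <- A - AbList[bk, , ]
      reps[bk, , r] <- solve(Abk, b - bb[bk, ])
    }
  }

  tau <- Vtau <- repsOut <- vector("list", C)
  names(tau) <- names(Vtau) <- names(repsOut) <- annotations
  for (a in seq_len(C)) {
    Ta <- matrix(0, k, k, dimnames = list(nm, nm))
    Ta[cbind(idx[, 1L], idx[, 2L])] <- est[a + 1L, ]
    Ta[cbind(idx[, 2L], idx[, 1L])] <- est[a + 1L, ]
    tau[[a]] <- Ta
    R <- reps[, a + 1L, , drop = FALSE]
    dim(R) <- c(nBlocks, p)
    repsOut[[a]] <- R
    Vtau[[a]] <- .jackknifeCov(R)
  }
  I <- matrix(0, k, k, dimnames = list(nm, nm))
  I[cbind(idx[, 1L], idx[, 2L])] <- est[1L, ]
  I[cbind(idx[, 2L], idx[, 1L])] <- est[1L, ]
  new("StratifiedTauSet", tau = tau, Vtau = Vtau, reps = repsOut,
      traits = nm, sizes = ld@sizes[annotations],
      overlaps = ld@overlaps[annotations, annotations, drop = FALSE],
      M = ld@M, intercepts = I)
}

#' Zero-order conversion of conditional tau matrices
#'
#' Converts the conditional per-annotation coheritabilities to zero-order
#' stratified genetic covariances that do not control for annotation
#' overlap:
#' \deqn{\zeta_t = \sum_c \frac{|M_c \cap M_t|}{|M_c|} \tau_c}
#' applied elementwise to the k x k matrices. Sampling covariance is
#' propagated through the same linear combination of the jackknife
#' replicates used for the tau regression (not a post-hoc delta method).
#'
#' @param taus a \code{\link{StratifiedTauSet-class}}.
#' @param targets target annotation names (default: all in the set).
#' @return A \code{\link{StratifiedCovarianceSet-class}}.
#' @export
zeroOrderCovariance <- function(taus, targets = names(taus@tau)) {
  anns <- names(taus@tau)
  k <- length(taus@traits)
  zeta <- Vzeta <- vector("list", length(targets))
  names(zeta) <- names(Vzeta) <- targets
  for (t in targets) {
    if (!t %in% colnames(taus@overlaps))
      stop("no overlap entries for target annotation ", t)
    wts <- taus@overlaps[anns, t] / taus@sizes[anns]
    if (any(is.na(wts))) stop("missing overlap entry for annotation ", t)
    Zt <- matrix(0, k, k, dimnames = list(taus@traits, taus@traits))
    Rt <- 0
    for (c in anns) {
      Zt <- Zt + wts[c] * taus@tau[[c]]
      Rt <- Rt + wts[c] * taus@reps[[c]]
    }
    zeta[[t]] <- Zt
    Vzeta[[t]] <- .jackknifeCov(Rt)
  }
  new("StratifiedCovarianceSet", zeta = zeta, Vzeta = Vzeta,
      traits = taus@traits, sizes = taus@sizes, M = taus@M,
      screen = data.frame(annotation = character(),
                          maxZDiscrepancy = numeric(),
                          retained = logical()))
}

#' Screen and smooth zero-order covariance matrices
#'
#' Eigen-clips each zero-order matrix to the nearest positive semidefinite
#' matrix and computes the per-element Z discrepancy
#' \eqn{|pre - post| / SE}. An annotation is excluded when any element's
#' discrepancy exceeds \code{zCrit} (default 1.96), indicating that the
#' estimates were unstable enough for smoothing to move them materially.
#'
#' @param set a \code{\link{StratifiedCovarianceSet-class}}.
#' @param zCrit discrepancy threshold (default 1.96).
#' @return The set with smoothed matrices and the screen table filled.
#' @export
screenCovariances <- function(set, zCrit = 1.96) {
  rows <- list()
  for (a in names(set@zeta)) {
    pre <- set@zeta[[a]]
    cl <- eigenClip(pre, floor = 0)
    se <- sqrt(pmax(diag(set@Vzeta[[a]]), 1e-300))
    k <- nrow(pre)
    seMat <- unvech(se, k)
    disc <- abs(cl$mat - pre) / seMat
    mx <- max(disc)
    rows[[length(rows) + 1L]] <- data.frame(
      annotation = a, maxZDiscrepancy = mx, retained = mx <= zCrit,
      stringsAsFactors = FALSE)
    set@zeta[[a]] <- cl$mat
  }
  set@screen <- do.call(rbind, rows)
  rownames(set@screen) <- NULL
  set
}

#' Enrichment of genomic-factor variances across annotations
#'
#' For each retained annotation, refits the genome-wide factor model on
#' the annotation's zero-order covariance matrix with the factor loadings
#' fixed at their genome-wide estimates and the factor and residual
#' variances free. The annotation's factor variance, divided by the
#' corresponding genome-wide factor variance and by the proportional
#' annotation size \eqn{M_t / M}, is the enrichment estimate (null value
#' 1); its SE is scaled identically. The default one-tailed p-value tests
#' enrichment > 1 via \eqn{Z = (est - 1)/SE}; the ratio est/SE variant is
#' also reported.
#'
#' @param gwFit converged genome-wide \code{\link{SEMFit-class}} (bifactor
#'   or correlated-factors).
#' @param set a screened \code{\link{StratifiedCovarianceSet-class}}.
#' @param baseAnnotation name of the whole-genome annotation (default
#'   "base"); its enrichment is exactly 1 by construction.
#' @param exclude annotations to keep out of enrichment reporting (e.g.
#'   continuous/flanking/control annotations).
#' @return data.frame (factor, annotation, enrichment, se, p,
#'   pRatio, retained) plus attribute \code{bonferroni} =
#'   0.05 / (#annotations x #factors).
#' @export
factorEnrichment <- function(gwFit, set, baseAnnotation = "base",
                             exclude = character()) {
  if (!gwFit@converged) stop("genome-wide fit did not converge")
  if (!baseAnnotation %in% names(set@zeta))
    stop("whole-genome annotation '", baseAnnotation, "' absent from the set")
  fixedModel <- fixedLoadingModel(gwFit@model, gwFit@estimates)
  facs <- gwFit@model@factors
  screen <- set@screen
  retained <- if (nrow(screen)) screen$annotation[screen$retained] else
    names(set@zeta)
  report <- setdiff(retained, exclude)
  ## genome-wide factor variances under the same fixed-loading refit
  gw <- fitGenomicSEM(set@zeta[[baseAnnotation]],
                      set@Vzeta[[baseAnnotation]], fixedModel)
  vgw <- gw@estimates[sprintf("var(%s)", facs)]
  rows <- list()
  for (a in report) {
    prop <- set@sizes[[a]] / set@M
    if (identical(a, baseAnnotation)) {
      fitA <- gw
    } else {
      fitA <- fitGenomicSEM(set@zeta[[a]], set@Vzeta[[a]], fixedModel)
    }
    for (fc in facs) {
      lab <- sprintf("var(%s)", fc)
      if (!fitA@converged) {
        rows[[length(rows) + 1L]] <- data.frame(
          factor = fc, annotation = a, enrichment = NA_real_, se = NA_real_,
          p = NA_real_, pRatio = NA_real_, retained = TRUE,
          stringsAsFactors = FALSE)
        next
      }
      enr <- (fitA@estimates[lab] / vgw[lab]) / prop
      se <- fitA@se[lab] / (vgw[lab] * prop)
      rows[[length(rows) + 1L]] <- data.frame(
        factor = fc, annotation = a, enrichment = unname(enr),
        se = unname(se),
        p = unname(stats::pnorm((enr - 1) / se, lower.tail = FALSE)),
        pRatio = unname(stats::pnorm(enr / se, lower.tail = FALSE)),
        retained = TRUE, stringsAsFactors = FALSE)
    }
  }
  if (nrow(screen)) {
    for (a in setdiff(screen$annotation[!screen$retained], exclude)) {
      for (fc in facs) {
        rows[[length(rows) + 1L]] <- data.frame(
          factor = fc, annotation = a, enrichment = NA_real_, se = NA_real_,
          p = NA_real_, pRatio = NA_real_, retained = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bonferroni") <- 0.05 / (length(report) * length(facs))
  out
}

#' Bonferroni family threshold
#'
#' Convenience for the multiple-testing schemes used throughout:
#' \code{0.05 / (nTests1 * nTests2)}.
#'
#' @param n1,n2 family dimensions (e.g. 152 annotations x 6 factors, or
#'   34 brain regions x 11 disorders).
#' @param alpha family-wise error rate (default 0.05).
#' @return The per-test threshold.
#' @examples
#' bonferroniThreshold(152, 6)   # enrichment family
#' bonferroniThreshold(34, 11)   # psychiatric family
#' @export
bonferroniThreshold <- function(n1, n2 = 1, alpha = 0.05) {
  alpha / (n1 * n2)
}
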