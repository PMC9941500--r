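## Deciding the number of genomic factors and producing an EFA-based
## assignment of indicators (traits / brain regions) to factors.

## validate + clean a genetic correlation matrix for eigen/EFA work;
## entries can exceed [-1,1] when estimated by LDSC -- clipped here with a
## warning (confirmatory models use the unclipped S/V instead)
.cleanCorr <- function(R) {
  R <- as.matrix(R)
  if (any(!is.finite(R))) stop("non-finite entries in correlation matrix")
  if (any(abs(R) > 1)) {
    warning("correlation entries outside [-1,1] clipped for eigen/EFA use")
    R[R > 1] <- 1; R[R < -1] <- -1
  }
  R <- (R + t(R)) / 2
  diag(R) <- 1
  R
}

#' Decide the number of factors with non-graphical scree rules
#'
#' Applies three rules to the eigenvalues of a genetic correlation matrix:
#' the Kaiser rule (eigenvalues strictly greater than 1), the acceleration
#' factor (the scree position preceding the maximum second difference of
#' the eigenvalue curve) and optimal coordinates (eigenvalues exceeding
#' the value predicted by extrapolating the line through the following
#' eigenvalue and the last one).
#'
#' @param R correlation matrix (symmetrized; unit diagonal enforced).
#' @return List with \code{kaiser}, \code{accelerationFactor},
#'   \code{optimalCoordinates} and the sorted \code{eigenvalues}.
#' @export
factorCount <- function(R) {
  R <- .cleanCorr(R)
  ev <- sort(eigen(R, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  k <- length(ev)
  kaiser <- sum(ev > 1)
  ## acceleration factor: second differences of the scree
  af <- 1L
  if (k >= 3) {
    acc <- ev[3:k] - 2 * ev[2:(k - 1)] + ev[1:(k - 2)]   # f''(i) at i=2..k-1
    af <- max(1L, which.max(acc) + 1L - 1L)              # position before max
  }
  ## optimal coordinates: predicted eigenvalue at i from the line through
  ## (i+1, ev[i+1]) and (k, ev[k]); count consecutive exceedances
  oc <- 1L
  if (k >= 3) {
    oc <- 0L
    for (i in seq_len(k - 2L)) {
      slope <- (ev[k] - ev[i + 1L]) / (k - (i + 1L))
      pred <- ev[i + 1L] - slope
      if (ev[i] > pred) oc <- oc + 1L else break
    }
    oc <- max(oc, 1L)
  }
  list(kaiser = kaiser, accelerationFactor = af, optimalCoordinates = oc,
       eigenvalues = ev)
}

#' Exploratory factor analysis of a genetic correlation matrix
#'
#' Maximum-likelihood factor extraction (\code{\link[stats]{factanal}})
#' followed by an oblique promax rotation (varimax then promax, power 4 by
#' default). Non-positive-definite inputs are smoothed by eigenvalue
#' clipping before extraction. The sign convention fixes each factor's
#' largest-magnitude loading positive, making the result deterministic
#' given R and m.
#'
#' @param R correlation matrix.
#' @param m number of factors (< ncol(R)).
#' @param promaxPower promax power parameter (default 4).
#' @param rotation "promax" (default) or "none".
#' @return List with \code{loadings} (k x m pattern matrix),
#'   \code{factorCor} (m x m), \code{uniquenesses} and
#'   \code{heywood} (indicators at the uniqueness boundary).
#' @export
runEFA <- function(R, m, promaxPower = 4, rotation = c("promax", "none")) {
  rotation <- match.arg(rotation)
  R <- .cleanCorr(R)
  k <- ncol(R)
  if (m >= k) stop("factor count m must be smaller than the indicator count")
  sm <- eigenClip(R, floor = 1e-8)
  if (sm$clipped) {
    warning(sprintf(
      "correlation matrix not positive definite; smoothed (max delta %.2e)",
      sm$delta))
    R <- stats::cov2cor(sm$mat)
  }
  fa <- stats::factanal(covmat = R, factors = m, rotation = "none")
  L <- unclass(fa$loadings)
  Phi <- diag(m)
  if (m > 1L && rotation == "promax") {
    pm <- stats::promax(L, m = promaxPower)
    L <- unclass(pm$loadings)
    Phi <- solve(crossprod(pm$rotmat))
    Phi <- (Phi + t(Phi)) / 2
  }
  ## sign convention: largest-magnitude loading per factor positive
  for (f in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, f])), f] < 0) {
      L[, f] <- -L[, f]
      Phi[f, ] <- -Phi[f, ]; Phi[, f] <- -Phi[, f]
    }
  }
  rownames(L) <- colnames(R)
  colnames(L) <- colnames(Phi) <- rownames(Phi) <- paste0("F", seq_len(m))
  heywood <- colnames(R)[fa$uniquenesses <= 0.005 + 1e-12]
  if (length(heywood))
    warning("uniqueness at boundary (Heywood case) for: ",
            paste(heywood, collapse = ", "))
  list(loadings = L, factorCor = Phi, uniquenesses = fa$uniquenesses,
       heywood = heywood)
}

#' Assign indicators to factors from a rotated loading matrix
#'
#' An indicator joins the factor with its largest absolute standardized
#' loading. Indicators whose loading exceeds \code{threshold} on two or
#' more factors are flagged as cross-loading (the cross-loading itself is
#' not carried into confirmatory models; the indicator is assigned to the
#' factor with the highest loading). Ties break toward the lower factor
#' index, with a message.
#'
#' @param loadings k x m pattern matrix.
#' @param threshold qualifying-loading threshold (default 0.5).
#' @return List with \code{assignment} (named factor labels),
#'   \code{crossLoading} (flagged indicators) and \code{qualifying}
#'   (per flagged indicator, all loadings above threshold).
#' @export
assignFactors <- function(loadings, threshold = 0.5) {
  L <- as.matrix(loadings)
  if (any(!is.finite(L))) stop("non-finite loadings")
  if (is.null(colnames(L))) colnames(L) <- paste0("F", seq_len(ncol(L)))
  if (is.null(rownames(L))) rownames(L) <- paste0("x", seq_len(nrow(L)))
  aL <- abs(L)
  assignment <- character(nrow(L))
  flagged <- character(0)
  qualifying <- list()
  for (i in seq_len(nrow(L))) {
    best <- which(aL[i, ] == max(aL[i, ]))[1L]
    if (sum(aL[i, ] == max(aL[i, ])) > 1L)
      message("tie for indicator ", rownames(L)[i],
              "; assigned to lower factor index")
    assignment[i] <- colnames(L)[best]
    qual <- which(aL[i, ] > threshold)
    if (length(qual) >= 2L) {
      flagged <- c(flagged, rownames(L)[i])
      qualifying[[rownames(L)[i]]] <- L[i, qual]
    }
  }
  names(assignment) <- rownames(L)
  list(assignment = assignment, crossLoading = flagged,
       qualifying = qualifying)
}
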