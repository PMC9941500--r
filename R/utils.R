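#' Half-vectorization of a symmetric matrix
#'
#' Stacks the lower triangle (including the diagonal) of a symmetric matrix
#' in column-major order. This ordering is the package-wide convention for
#' indexing sampling covariance matrices of genetic covariance estimates.
#'
#' @param S symmetric numeric matrix.
#' @return Numeric vector of length \code{k(k+1)/2}.
#' @export
vech <- function(S) {
  S[lower.tri(S, diag = TRUE)]
}

#' Index pairs corresponding to the half-vectorization
#'
#' @param k matrix dimension.
#' @return Two-column integer matrix (row, col) with row >= col, in the
#'   same column-major order as \code{\link{vech}}.
#' @export
vechIndices <- function(k) {
  idx <- which(lower.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  idx[, c(1L, 2L), drop = FALSE]
}

## inverse of vech: rebuild the symmetric matrix
unvech <- function(v, k) {
  S <- matrix(0, k, k)
  S[lower.tri(S, diag = TRUE)] <- v
  S <- S + t(S)
  diag(S) <- diag(S) / 2
  S
}

#' Nearest positive semidefinite matrix by eigenvalue clipping
#'
#' Replaces negative eigenvalues with \code{floor} and reconstructs the
#' matrix. Used both to smooth non-positive-definite genetic correlation
#' matrices before factor extraction and to screen stratified covariance
#' matrices.
#'
#' @param S symmetric matrix.
#' @param floor eigenvalue floor (default 0).
#' @return List with elements \code{mat} (clipped matrix), \code{delta}
#'   (max absolute elementwise change) and \code{clipped} (logical).
#' @export
eigenClip <- function(S, floor = 0) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (all(e$values >= floor)) {
    return(list(mat = S, delta = 0, clipped = FALSE))
  }
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(S)
  list(mat = out, delta = max(abs(out - S)), clipped = TRUE)
}

## Moore-Penrose style inverse via eigen decomposition; eigenvalues below
## tol * max are dropped.  Symmetric input assumed.
.pseudoSolve <- function(A, tol = 1e-12) {
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), .Machine$double.eps)
  if (!any(keep)) stop("matrix numerically zero; cannot invert")
  e$vectors[, keep, drop = FALSE] %*%
    ((1 / e$values[keep]) * t(e$vectors[, keep, drop = FALSE]))
}

## run code with a private RNG stream so public API functions are seeded
## without disturbing the caller's RNG state
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(expr)
}

## equal-count contiguous block assignment used by the jackknife
.blockIds <- function(n, nBlocks) {
  if (n < nBlocks) stop("fewer observations (", n, ") than jackknife blocks (",
                        nBlocks, ")")
  sort(rep_len(seq_len(nBlocks), n))
}

## delete-one-block jackknife covariance from a B x p replicate matrix
.jackknifeCov <- function(reps) {
  B <- nrow(reps)
  ctr <- sweep(reps, 2L, colMeans(reps))
  (B - 1) / B * crossprod(ctr)
}
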