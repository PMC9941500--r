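## Diagonally weighted least squares estimation on a genetic covariance
## matrix S with jackknife sampling covariance V: sandwich standard errors
## use the full V, the model test statistic is the residual-based
## quadratic form, and optimization is Gauss-Newton with an analytic
## Jacobian, damped by step halving, from a fixed deterministic start.

#' SEMFit: a fitted structural model
#'
#' @slot model the \code{\link{SEMModel-class}} fitted.
#' @slot estimates named free-parameter estimates.
#' @slot se sandwich standard errors.
#' @slot chi2,df residual-based model test statistic and its degrees of
#'   freedom.
#' @slot converged logical convergence flag; a non-converged fit is a
#'   reportable outcome, not an error.
#' @slot Sigma model-implied covariance matrix.
#' @slot S,V the data the model was fitted to.
#' @slot details list of optimizer diagnostics.
#' @export
setClass("SEMFit",
  slots = c(model = "SEMModel", estimates = "numeric", se = "numeric",
            chi2 = "numeric", df = "integer", converged = "logical",
            Sigma = "matrix", S = "matrix", V = "matrix", details = "list"))

setMethod("show", "SEMFit", function(object) {
  cat("SEMFit (", object@model@kind, "): chi2 =",
      format(object@chi2, digits = 5), "on", object@df, "df;",
      if (object@converged) "converged" else "NOT converged", "\n")
})

#' Accessors for SEMFit
#' @param x a \code{\link{SEMFit-class}}.
#' @return \code{semEstimates}/\code{semSE} named numeric vectors;
#'   \code{impliedCov} the model-implied covariance matrix;
#'   \code{isConverged} the convergence flag.
#' @export
semEstimates <- function(x) x@estimates

#' @rdname semEstimates
#' @export
semSE <- function(x) x@se

#' @rdname semEstimates
#' @export
impliedCov <- function(x) x@Sigma

#' @rdname semEstimates
#' @export
isConverged <- function(x) x@converged

## ---- internal parameter bookkeeping ---------------------------------------

## free-parameter labels in first-appearance order
.freeLabels <- function(model) unique(model@ptable$label[model@ptable$free])

## deterministic start values: loadings 0.5, free factor variances 1,
## factor covariances 0, residual variances 0.5 * diag(S), residual
## covariances 0
.startValues <- function(model, S) {
  labs <- .freeLabels(model)
  pt <- model@ptable
  st <- numeric(length(labs)); names(st) <- labs
  for (i in which(pt$free)) {
    lab <- pt$label[i]
    st[lab] <- switch(pt$mat[i],
      lambda = 0.5,
      psi = if (pt$row[i] == pt$col[i]) 1 else 0,
      theta = if (pt$row[i] == pt$col[i]) 0.5 * S[pt$row[i], pt$row[i]] else 0)
  }
  st
}

## fill lambda/psi/theta from a parameter vector
.modelMatrices <- function(model, par) {
  k <- length(model@indicators); m <- length(model@factors)
  L <- matrix(0, k, m); Psi <- matrix(0, m, m); Th <- matrix(0, k, k)
  pt <- model@ptable
  val <- ifelse(pt$free, par[pt$label], pt$value)
  for (i in seq_len(nrow(pt))) {
    r <- pt$row[i]; c <- pt$col[i]
    switch(pt$mat[i],
      lambda = { L[r, c] <- val[i] },
      psi = { Psi[r, c] <- val[i]; Psi[c, r] <- val[i] },
      theta = { Th[r, c] <- val[i]; Th[c, r] <- val[i] })
  }
  dimnames(L) <- list(model@indicators, model@factors)
  dimnames(Psi) <- list(model@factors, model@factors)
  dimnames(Th) <- list(model@indicators, model@indicators)
  list(L = L, Psi = Psi, Th = Th)
}

.implied <- function(mats) mats$L %*% mats$Psi %*% t(mats$L) + mats$Th

## analytic Jacobian d vech(Sigma) / d theta  (p* x q)
.deltaMatrix <- function(model, mats) {
  k <- length(model@indicators)
  labs <- .freeLabels(model)
  q <- length(labs)
  lt <- lower.tri(matrix(0, k, k), diag = TRUE)
  D <- matrix(0, sum(lt), q)
  pt <- model@ptable
  LP <- mats$L %*% mats$Psi            # k x m
  for (i in which(pt$free)) {
    ci <- match(pt$label[i], labs)
    r <- pt$row[i]; c <- pt$col[i]
    dS <- matrix(0, k, k)
    switch(pt$mat[i],
      lambda = {
        u <- LP[, c]
        dS[r, ] <- dS[r, ] + u
        dS[, r] <- dS[, r] + u
        ## when r loads on factor c the diagonal term picks up 2*lambda*psi
        ## which the two additions above already produce (u[r] counted twice)
      },
      psi = {
        lf <- mats$L[, r]; lg <- mats$L[, c]
        if (r == c) dS <- lf %o% lf
        else dS <- lf %o% lg + lg %o% lf
      },
      theta = {
        if (r == c) dS[r, c] <- 1
        else { dS[r, c] <- 1; dS[c, r] <- 1 }
      })
    D[, ci] <- D[, ci] + dS[lt]
  }
  D
}

## ---- the fitter ------------------------------------------------------------

#' Fit a structural model to (S, V) by diagonally weighted least squares
#'
#' Minimizes \eqn{(s - \sigma(\theta))' W (s - \sigma(\theta))} with
#' \eqn{s = vech(S)} and \eqn{W = diag(V)^{-1}}, via damped Gauss-Newton
#' with an analytic Jacobian from a fixed deterministic start. Standard
#' errors apply the sandwich correction with the full sampling covariance
#' V; the model test statistic is the residual-based quadratic form
#' \eqn{e' [V^{-1} - V^{-1}\Delta(\Delta'V^{-1}\Delta)^{-1}\Delta'V^{-1}] e},
#' asymptotically chi-square on \eqn{p^* - q} degrees of freedom.
#'
#' Non-convergence is reported through the \code{converged} slot rather
#' than raised as an error.
#'
#' @param S genetic covariance matrix (dimnames must cover the model's
#'   indicators) or a \code{\link{GeneticCovariance-class}}.
#' @param V sampling covariance of \code{vech(S)}; ignored when \code{S}
#'   is a \code{GeneticCovariance}.
#' @param model a \code{\link{SEMModel-class}}.
#' @param tol gradient tolerance (default 1e-8).
#' @param maxIter iteration cap (default 5000).
#' @return A \code{\link{SEMFit-class}}.
#' @export
fitGenomicSEM <- function(S, V = NULL, model, tol = 1e-8, maxIter = 5000L) {
  if (is(S, "GeneticCovariance")) { V <- S@V; S <- S@S }
  k <- length(model@indicators)
  if (!is.null(rownames(S)) && !identical(rownames(S), model@indicators)) {
    ord <- match(model@indicators, rownames(S))
    if (any(is.na(ord))) stop("S lacks indicators: ",
      paste(setdiff(model@indicators, rownames(S)), collapse = ", "))
    perm <- .vechPermutation(nrow(S), ord)
    S <- S[ord, ord, drop = FALSE]
    V <- V[perm, perm, drop = FALSE]
  }
  stopifnot(nrow(S) == k)
  s <- vech(S)
  w <- 1 / pmax(diag(V), 1e-12)
  labs <- .freeLabels(model)
  par <- .startValues(model, S)

  obj <- function(p) {
    e <- s - vech(.implied(.modelMatrices(model, p)))
    sum(w * e * e)
  }
  F0 <- obj(par)
  iter <- 0L; gnorm <- Inf
  repeat {
    iter <- iter + 1L
    mats <- .modelMatrices(model, par)
    e <- s - vech(.implied(mats))
    D <- .deltaMatrix(model, mats)
    g <- crossprod(D, w * e)            # (negative half-gradient)
    gnorm <- max(abs(2 * g))
    if (gnorm < tol * (1 + F0) || iter > maxIter) break
    A <- crossprod(D * sqrt(w))
    step <- tryCatch(solve(A + diag(1e-10, ncol(A)), g),
                     error = function(e2) NULL)
    if (is.null(step)) break
    t <- 1; Fcur <- sum(w * e * e); improved <- FALSE
    for (h in 1:30) {
      Fnew <- obj(par + t * as.numeric(step))
      if (is.finite(Fnew) && Fnew <= Fcur - 1e-16) { improved <- TRUE; break }
      t <- t / 2
    }
    if (!improved) break
    par <- par + t * as.numeric(step)
    if (Fcur - Fnew < 1e-14 * (1 + Fcur) && gnorm < sqrt(tol)) break
  }
  mats <- .modelMatrices(model, par)
  Sigma <- .implied(mats)
  e <- s - vech(Sigma)
  D <- .deltaMatrix(model, mats)
  g <- crossprod(D, w * e)
  gnorm <- max(abs(2 * g))
  Ffinal <- sum(w * e * e)
  converged <- is.finite(gnorm) && gnorm < sqrt(tol) * (1 + Ffinal) &&
    iter <= maxIter

  ## sandwich standard errors with the full V
  A <- crossprod(D * sqrt(w))
  se <- rep(NA_real_, length(labs)); names(se) <- labs
  covTheta <- matrix(NA_real_, length(labs), length(labs))
  bread <- tryCatch(solve(A + diag(1e-12, ncol(A))), error = function(e2) NULL)
  if (!is.null(bread)) {
    WD <- D * w
    meat <- crossprod(WD, V %*% WD)
    covTheta <- bread %*% meat %*% bread
    se <- sqrt(pmax(diag(covTheta), 0))
    names(se) <- labs
  }

  df <- modelDf(model)
  chi2 <- 0
  if (df > 0L) {
    Vi <- .pseudoSolve(V)
    ViD <- Vi %*% D
    U <- Vi - ViD %*% .pseudoSolve(crossprod(D, ViD)) %*% t(ViD)
    chi2 <- max(0, drop(crossprod(e, U %*% e)))
  }
  dimnames(Sigma) <- list(model@indicators, model@indicators)
  est <- as.numeric(par); names(est) <- labs
  new("SEMFit", model = model, estimates = est, se = se, chi2 = chi2,
      df = as.integer(df), converged = converged, Sigma = Sigma,
      S = S, V = V,
      details = list(iterations = iter, gradNorm = gnorm,
                     discrepancy = sum(w * e * e), covTheta = covTheta))
}

## permutation of vech indices under a row/col reordering of S
.vechPermutation <- function(k, ord) {
  pos <- matrix(0L, k, k)
  idx <- vechIndices(k)
  for (r in seq_len(nrow(idx))) {
    pos[idx[r, 1L], idx[r, 2L]] <- r
    pos[idx[r, 2L], idx[r, 1L]] <- r
  }
  newIdx <- vechIndices(k)
  vapply(seq_len(nrow(newIdx)), function(r)
    pos[ord[newIdx[r, 1L]], ord[newIdx[r, 2L]]], 1L)
}

#' Standardized solution of a fitted model
#'
#' Rescales loadings to the correlation metric of the model-implied
#' covariance matrix (factors keep their unit variances).
#'
#' @param fit a \code{\link{SEMFit-class}}.
#' @return List with standardized \code{loadings}, \code{factorCor} and
#'   \code{residualVar}.
#' @export
standardizedSolution <- function(fit) {
  mats <- .modelMatrices(fit@model, fit@estimates)
  sd <- sqrt(pmax(diag(fit@Sigma), .Machine$double.eps))
  fsd <- sqrt(pmax(diag(mats$Psi), .Machine$double.eps))
  Lstd <- sweep(sweep(mats$L, 1, sd, "/"), 2, fsd, "*")
  Phi <- stats::cov2cor(mats$Psi)
  list(loadings = Lstd, factorCor = Phi,
       residualVar = diag(mats$Th) / sd^2)
}

#' Fit indices: CFI, SRMR, AIC
#'
#' CFI compares the model statistic with an independence model (all
#' covariances fixed to 0, variances free), clamped to [0,1]; SRMR is the
#' root mean square of correlation-metric residuals over the unique
#' elements; AIC is \eqn{\chi^2 + 2q}. Model fit is conventionally deemed
#' acceptable at CFI > 0.9 and SRMR < 0.10.
#'
#' @param fit a \code{\link{SEMFit-class}}.
#' @return List with \code{CFI}, \code{SRMR}, \code{AIC}, \code{chi2},
#'   \code{df} and the independence-model statistic. Indices are NA when
#'   the independence fit does not converge.
#' @export
fitIndices <- function(fit) {
  model <- fit@model
  k <- length(model@indicators)
  ## independence model: variances free, everything else absent
  pt <- do.call(rbind, c(
    lapply(seq_len(k), function(i)
      .prow("theta", i, i, TRUE, NA_real_, paste0("v", i))),
    list(.prow("psi", 1L, 1L, FALSE, 1, ""))))
  indep <- new("SEMModel", indicators = model@indicators, factors = "F0",
               kind = "custom", ptable = pt)
  fit0 <- fitGenomicSEM(fit@S, fit@V, indep)
  if (!fit0@converged)
    return(list(CFI = NA_real_, SRMR = NA_real_, AIC = NA_real_,
                chi2 = fit@chi2, df = fit@df,
                chi2Indep = NA_real_, dfIndep = NA_integer_))
  CFI <- .cfi(fit@chi2, fit@df, fit0@chi2, fit0@df)
  so <- sqrt(diag(fit@S)); si <- sqrt(pmax(diag(fit@Sigma), 1e-12))
  Ro <- fit@S / (so %o% so)
  Ri <- fit@Sigma / (si %o% si)
  lt <- lower.tri(Ro, diag = TRUE)
  SRMR <- sqrt(mean((Ro[lt] - Ri[lt])^2))
  q <- nFreeParameters(model)
  list(CFI = CFI, SRMR = SRMR, AIC = fit@chi2 + 2 * q,
       chi2 = fit@chi2, df = fit@df, chi2Indep = fit0@chi2,
       dfIndep = fit0@df)
}

## comparative fit index with the small-sample guards: numerator floored
## at 0 (chi2 < df), denominator guarded against a degenerate independence
## model (chi2_i < df_i), result clamped to [0, 1]
.cfi <- function(chi2m, dfm, chi2i, dfi) {
  num <- max(0, chi2m - dfm)
  den <- max(chi2m - dfm, chi2i - dfi, .Machine$double.eps)
  min(1, max(0, 1 - num / den))
}

#' Iterative residual-covariance search
#'
#' Repeatedly (i) fits the model, (ii) forms the residual matrix
#' \eqn{S - \Sigma(\hat\theta)}, (iii) frees the residual covariance of
#' the indicator pair with the largest absolute standardized residual not
#' yet free, and (iv) keeps it if its Wald p-value is below \code{alpha},
#' otherwise stops. A refit that fails to converge rejects the candidate,
#' blacklists the pair and continues with the next-largest residual.
#'
#' @param S,V covariance and sampling covariance (or a
#'   \code{\link{GeneticCovariance-class}} as \code{S}).
#' @param model base \code{\link{SEMModel-class}} (must converge).
#' @param alpha retention threshold on the Wald p (default 0.01).
#' @param maxAdd safety cap on added covariances (default 20).
#' @param candidates optional two-column matrix of indicator-label pairs
#'   restricting the search (used for indicator-trait searches in joint
#'   models).
#' @return List with \code{model} (augmented), \code{fit} (final) and
#'   \code{trace} (data.frame: pair, estimate, se, p, kept).
#' @export
residualSearch <- function(S, V = NULL, model, alpha = 0.01, maxAdd = 20L,
                           candidates = NULL) {
  if (is(S, "GeneticCovariance")) { V <- S@V; S <- S@S }
  fit <- fitGenomicSEM(S, V, model)
  if (!fit@converged) stop("base model did not converge")
  trace <- list()
  blacklist <- character(0)
  inds <- model@indicators
  allowed <- NULL
  if (!is.null(candidates))
    allowed <- paste(pmin(candidates[, 1], candidates[, 2]),
                     pmax(candidates[, 1], candidates[, 2]))
  repeat {
    if (length(trace) >= maxAdd) break
    Sf <- fit@S
    res <- Sf - fit@Sigma
    sd <- sqrt(diag(Sf))
    std <- res / (sd %o% sd)
    pt <- fit@model@ptable
    freePairs <- pt[pt$mat == "theta" & pt$row != pt$col, , drop = FALSE]
    busy <- paste(pmin(inds[freePairs$row], inds[freePairs$col]),
                  pmax(inds[freePairs$row], inds[freePairs$col]))
    cand <- which(lower.tri(std), arr.ind = TRUE)
    key <- paste(pmin(inds[cand[, 1]], inds[cand[, 2]]),
                 pmax(inds[cand[, 1]], inds[cand[, 2]]))
    ok <- !(key %in% c(busy, blacklist))
    if (!is.null(allowed)) ok <- ok & key %in% allowed
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0L) break
    vals <- abs(std[cand])
    pick <- cand[which.max(vals), ]
    i1 <- inds[pick[1]]; i2 <- inds[pick[2]]
    lab <- sprintf("%s~~%s", inds[min(pick)], inds[max(pick)])
    newModel <- addResidualCovariance(fit@model, i1, i2)
    newFit <- fitGenomicSEM(Sf, fit@V, newModel)
    if (!newFit@converged) {
      blacklist <- c(blacklist, paste(min(i1, i2), max(i1, i2)))
      next
    }
    est <- newFit@estimates[lab]; se <- newFit@se[lab]
    p <- 2 * stats::pnorm(-abs(est / se))
    keep <- is.finite(p) && p < alpha
    trace[[length(trace) + 1L]] <- data.frame(
      ind1 = i1, ind2 = i2, estimate = est, se = se, p = p, kept = keep,
      stringsAsFactors = FALSE)
    if (!keep) break
    fit <- newFit
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(ind1 = character(), ind2 = character(), estimate = numeric(),
               se = numeric(), p = numeric(), kept = logical())
  rownames(trace) <- NULL
  list(model = fit@model, fit = fit, trace = trace)
}

#' Share of genetic variance explained by the general factor
#'
#' For a bifactor fit: per indicator, the squared standardized general
#' factor loading; plus their average.
#'
#' @param fit a converged bifactor \code{\link{SEMFit-class}}.
#' @return List with \code{share} (per indicator) and \code{average}.
#' @export
generalFactorShare <- function(fit) {
  if (fit@model@kind != "bifactor")
    stop("general-factor share requires a bifactor model")
  std <- standardizedSolution(fit)
  lg <- std$loadings[, 1L]   # general factor is the first factor
  share <- lg^2
  list(share = share, average = mean(share))
}

#' Joint model of brain factors and an external trait factor structure
#'
#' Combines two standalone measurement models over a joint (S, V), frees
#' all cross-block factor correlations, optionally runs the
#' residual-covariance search over indicator-trait pairs, and flags
#' factor correlations against a Bonferroni threshold whose family size
#' defaults to (#indicators block 1) x (#indicators block 2).
#'
#' @param brainModel,externalModel \code{\link{SEMModel-class}} objects.
#' @param S,V joint covariance and sampling covariance over both indicator
#'   blocks (or a \code{GeneticCovariance} as \code{S}).
#' @param searchResiduals run the indicator-trait residual search
#'   (default TRUE).
#' @param alpha residual-search threshold (default 0.01).
#' @param bonferroniFamily family size for the correlation flags;
#'   default \code{length(brain indicators) * length(external indicators)}.
#' @return List with \code{fit}, \code{correlations} (data.frame with
#'   estimate, se, p, significant), \code{trace} (residual search) and
#'   \code{threshold}.
#' @export
jointExternalModel <- function(brainModel, externalModel, S, V = NULL,
                               searchResiduals = TRUE, alpha = 0.01,
                               bonferroniFamily = NULL) {
  if (is(S, "GeneticCovariance")) { V <- S@V; S <- S@S }
  joint <- combineModels(brainModel, externalModel)
  trace <- NULL
  if (searchResiduals) {
    cand <- as.matrix(expand.grid(brainModel@indicators,
                                  externalModel@indicators,
                                  stringsAsFactors = FALSE))
    rs <- residualSearch(S, V, joint, alpha = alpha, candidates = cand)
    fit <- rs$fit; trace <- rs$trace
  } else {
    fit <- fitGenomicSEM(S, V, joint)
  }
  if (is.null(bonferroniFamily))
    bonferroniFamily <- length(brainModel@indicators) *
      length(externalModel@indicators)
  thr <- 0.05 / bonferroniFamily
  rows <- list()
  for (f1 in brainModel@factors) for (f2 in externalModel@factors) {
    lab <- sprintf("%s~~%s", f1, f2)
    if (!lab %in% names(fit@estimates)) next
    est <- fit@estimates[lab]; se <- fit@se[lab]
    p <- 2 * stats::pnorm(-abs(est / se))
    rows[[length(rows) + 1L]] <- data.frame(
      brainFactor = f1, externalFactor = f2, estimate = est, se = se,
      p = p, significant = is.finite(p) && p < thr,
      stringsAsFactors = FALSE)
  }
  correlations <- do.call(rbind, rows)
  rownames(correlations) <- NULL
  list(fit = fit, correlations = correlations, trace = trace,
       threshold = thr)
}

#' Omnibus equality test of factor correlations
#'
#' Chi-square difference test between a joint fit with cross-block factor
#' correlations freely estimated and a nested fit with them constrained to
#' equality. A non-converged constrained model is itself a reportable
#' outcome (returned with \code{p = NA}).
#'
#' @param fitFree,fitConstrained \code{\link{SEMFit-class}} objects on the
#'   same (S, V), the constrained model nested in the free one.
#' @return List with \code{dChi2}, \code{dDf}, \code{p} and
#'   \code{constrainedConverged}.
#' @export
omnibusEqualityTest <- function(fitFree, fitConstrained) {
  if (!identical(fitFree@model@indicators, fitConstrained@model@indicators))
    stop("fits are not on the same indicator set")
  if (!isTRUE(all.equal(fitFree@S, fitConstrained@S, tolerance = 1e-10)))
    stop("fits must be on identical S")
  dDf <- fitConstrained@df - fitFree@df
  if (dDf < 0L) stop("constrained model must be nested in the free model")
  if (!fitConstrained@converged)
    return(list(dChi2 = NA_real_, dDf = dDf, p = NA_real_,
                constrainedConverged = FALSE))
  dChi2 <- max(0, fitConstrained@chi2 - fitFree@chi2)
  p <- if (dDf == 0L) 1 else stats::pchisq(dChi2, dDf, lower.tail = FALSE)
  list(dChi2 = dChi2, dDf = dDf, p = p, constrainedConverged = TRUE)
}

#' Constrain the cross-block correlations of a joint model to equality
#'
#' @param model a joint \code{\link{SEMModel-class}} from
#'   \code{\link{combineModels}}.
#' @param externalFactor the external factor whose correlations with all
#'   other factors are constrained equal.
#' @param brainFactors the factors on the other side (default: all other
#'   factors appearing in cross labels).
#' @return The constrained model.
#' @export
constrainFactorCorrelations <- function(model, externalFactor,
                                        brainFactors = NULL) {
  if (is.null(brainFactors))
    brainFactors <- setdiff(model@factors, externalFactor)
  labs <- c(sprintf("%s~~%s", brainFactors, externalFactor),
            sprintf("%s~~%s", externalFactor, brainFactors))
  labs <- intersect(labs, model@ptable$label[model@ptable$free])
  constrainEqual(model, labs)
}
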