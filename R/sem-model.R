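## Structural model specification for confirmatory genomic factor models.
##
## A model is a parameter table over three matrices: lambda (k x m factor
## loadings), psi (m x m factor covariance) and theta (k x k residual
## covariance).  Cells absent from the table are fixed at zero; psi and
## theta entries are stored on the lower triangle.  Free parameters carry
## labels; parameters sharing a label are constrained equal.

#' SEMModel: structural model specification
#'
#' @slot indicators indicator labels (must match the rows of S).
#' @slot factors factor labels.
#' @slot kind "common", "correlated", "bifactor" or "custom".
#' @slot ptable parameter table: columns \code{mat} ("lambda", "psi",
#'   "theta"), \code{row}, \code{col}, \code{free}, \code{value} (fixed
#'   value when not free), \code{label} (shared label = equality
#'   constraint).
#' @export
setClass("SEMModel",
  slots = c(indicators = "character", factors = "character",
            kind = "character", ptable = "data.frame"))

setValidity("SEMModel", function(object) {
  pt <- object@ptable
  need <- c("mat", "row", "col", "free", "value", "label")
  if (!all(need %in% names(pt))) return("malformed parameter table")
  k <- length(object@indicators); m <- length(object@factors)
  if (any(pt$mat == "lambda" & (pt$row > k | pt$col > m)))
    return("lambda index out of range")
  if (any(pt$mat == "psi" & (pt$row > m | pt$col > m)))
    return("psi index out of range")
  if (any(pt$mat == "theta" & (pt$row > k | pt$col > k)))
    return("theta index out of range")
  if (any(pt$mat %in% c("psi", "theta") & pt$row < pt$col))
    return("psi/theta entries must be on the lower triangle (row >= col)")
  if (any(pt$free & !nzchar(pt$label)))
    return("free parameters need labels")
  ## every factor needs an identified variance scale
  psiDiag <- pt[pt$mat == "psi" & pt$row == pt$col, ]
  if (!all(seq_len(m) %in% psiDiag$row))
    return("every factor needs a psi diagonal entry")
  TRUE
})

setMethod("show", "SEMModel", function(object) {
  pt <- object@ptable
  cat("SEMModel (", object@kind, "): ", length(object@indicators),
      " indicators, ", length(object@factors), " factors, ",
      length(unique(pt$label[pt$free])), " free parameters\n", sep = "")
})

#' Number of free parameters of a model
#' @param model a \code{\link{SEMModel-class}}.
#' @return Count of unique free parameter labels.
#' @export
nFreeParameters <- function(model) {
  length(unique(model@ptable$label[model@ptable$free]))
}

#' Model degrees of freedom against a covariance target
#' @param model a \code{\link{SEMModel-class}}.
#' @return \code{k(k+1)/2 - } number of free parameters.
#' @export
modelDf <- function(model) {
  k <- length(model@indicators)
  as.integer(k * (k + 1L) / 2L - nFreeParameters(model))
}

.prow <- function(mat, row, col, free, value, label) {
  data.frame(mat = mat, row = as.integer(row), col = as.integer(col),
             free = free, value = value, label = label,
             stringsAsFactors = FALSE)
}

#' Build a confirmatory factor model from an indicator-to-factor assignment
#'
#' Constructs one of the three standard confirmatory structures with the
#' full set of identification rules applied automatically:
#' \itemize{
#'   \item unit-variance identification: every factor variance fixed to 1;
#'   \item a factor with exactly two indicators gets its loadings
#'     constrained to equality;
#'   \item a factor with exactly one indicator gets that indicator's
#'     residual variance fixed to 0;
#'   \item in bifactor models the general factor loads on every indicator
#'     and all factor covariances (general-residual and residual-residual)
#'     are fixed to 0; in correlated-factors models the factor covariances
#'     are free; the common model has a single factor.
#' }
#'
#' @param assignment named character vector: indicator -> factor label
#'   (ignored except for indicator names when \code{kind = "common"}).
#' @param kind "common", "correlated" or "bifactor".
#' @param generalName label for the bifactor general factor (default "g").
#' @return A \code{\link{SEMModel-class}}.
#' @export
buildFactorModel <- function(assignment,
                             kind = c("common", "correlated", "bifactor"),
                             generalName = "g") {
  kind <- match.arg(kind)
  indicators <- names(assignment)
  if (is.null(indicators)) stop("assignment must be a named vector")
  k <- length(indicators)
  groups <- unique(assignment)
  if (kind == "common") {
    factors <- "F1"
    memb <- list(F1 = indicators)
  } else {
    factors <- groups
    memb <- split(indicators, factor(assignment, levels = groups))
    if (any(lengths(memb) == 0L)) stop("empty factor after assignment")
    if (kind == "bifactor") factors <- c(generalName, factors)
  }
  pt <- list()
  thetaFixedZero <- character(0)
  addLoadings <- function(fac, inds) {
    fi <- match(fac, factors)
    lab <- if (length(inds) == 2L) {
      rep(sprintf("%s=~{eq}", fac), 2L)
    } else sprintf("%s=~%s", fac, inds)
    pt[[length(pt) + 1L]] <<- .prow("lambda", match(inds, indicators), fi,
                                    TRUE, NA_real_, lab)
    if (length(inds) == 1L) thetaFixedZero <<- c(thetaFixedZero, inds)
  }
  if (kind == "bifactor")
    addLoadings(generalName, indicators)
  for (f in names(memb)) addLoadings(f, memb[[f]])

  m <- length(factors)
  for (f in seq_len(m))      # unit-variance identification
    pt[[length(pt) + 1L]] <- .prow("psi", f, f, FALSE, 1, "")
  if (kind == "correlated" && m > 1L) {
    for (f in 2:m) for (g in seq_len(f - 1L))
      pt[[length(pt) + 1L]] <- .prow("psi", f, g, TRUE, NA_real_,
                                     sprintf("%s~~%s", factors[g], factors[f]))
  }
  ## bifactor: covariances absent from the table, i.e. fixed 0
  for (i in seq_len(k)) {
    ind <- indicators[i]
    if (ind %in% thetaFixedZero) {
      pt[[length(pt) + 1L]] <- .prow("theta", i, i, FALSE, 0, "")
    } else {
      pt[[length(pt) + 1L]] <- .prow("theta", i, i, TRUE, NA_real_,
                                     sprintf("%s~~%s", ind, ind))
    }
  }
  new("SEMModel", indicators = indicators, factors = factors, kind = kind,
      ptable = do.call(rbind, pt))
}

#' Free a residual covariance between two indicators
#'
#' @param model a \code{\link{SEMModel-class}}.
#' @param ind1,ind2 indicator labels.
#' @return The augmented model.
#' @export
addResidualCovariance <- function(model, ind1, ind2) {
  i <- match(ind1, model@indicators); j <- match(ind2, model@indicators)
  if (is.na(i) || is.na(j)) stop("unknown indicator")
  r <- max(i, j); c <- min(i, j)
  pt <- model@ptable
  hit <- pt$mat == "theta" & pt$row == r & pt$col == c
  if (any(hit)) { pt$free[hit] <- TRUE; pt$label[hit] <-
    sprintf("%s~~%s", model@indicators[c], model@indicators[r]) }
  else pt <- rbind(pt, .prow("theta", r, c, TRUE, NA_real_,
                             sprintf("%s~~%s", model@indicators[c],
                                     model@indicators[r])))
  initialize(model, ptable = pt)
}

#' Constrain a set of free parameters to equality
#'
#' @param model a \code{\link{SEMModel-class}}.
#' @param labels labels of free parameters to merge into one.
#' @return Model with the parameters sharing a single label.
#' @export
constrainEqual <- function(model, labels) {
  pt <- model@ptable
  hit <- pt$label %in% labels & pt$free
  if (sum(hit) < 2L) stop("need at least two free parameters to constrain")
  pt$label[hit] <- paste0("{eq}", paste(sort(unique(labels)), collapse = "="))
  initialize(model, ptable = pt)
}

#' Combine two measurement models over a joint covariance matrix
#'
#' Concatenates the indicator blocks of two fitted-standalone measurement
#' models and frees every cross-block factor covariance (the factor
#' correlations of interest). Within-block structure is preserved,
#' including bifactor orthogonality constraints.
#'
#' @param model1,model2 \code{\link{SEMModel-class}} objects with disjoint
#'   indicator and factor labels.
#' @return A joint \code{\link{SEMModel-class}} of kind "custom"; the
#'   cross-block psi parameters carry labels \code{"f1~~f2"}.
#' @export
combineModels <- function(model1, model2) {
  if (length(intersect(model1@indicators, model2@indicators)))
    stop("indicator labels must be disjoint")
  if (length(intersect(model1@factors, model2@factors)))
    stop("factor labels must be disjoint")
  indicators <- c(model1@indicators, model2@indicators)
  factors <- c(model1@factors, model2@factors)
  k1 <- length(model1@indicators); m1 <- length(model1@factors)
  pt1 <- model1@ptable
  pt2 <- model2@ptable
  pt2$row <- pt2$row + ifelse(pt2$mat == "psi", m1, k1)
  pt2$col <- pt2$col + ifelse(pt2$mat == "lambda", m1,
                       ifelse(pt2$mat == "psi", m1, k1))
  pt <- rbind(pt1, pt2)
  for (f1 in seq_len(m1)) for (f2 in (m1 + 1L):length(factors))
    pt <- rbind(pt, .prow("psi", f2, f1, TRUE, NA_real_,
                          sprintf("%s~~%s", factors[f1], factors[f2])))
  new("SEMModel", indicators = indicators, factors = factors,
      kind = "custom", ptable = pt)
}

#' Fix the loadings of a fitted model at their estimates
#'
#' Used by stratified enrichment: the factor loadings are fixed from the
#' genome-wide model while the factor variances and residual indicator
#' variances are freed, so that each annotation's factor variance measures
#' the pleiotropic signal it carries.
#'
#' @param model a \code{\link{SEMModel-class}}.
#' @param estimates named parameter estimates (from a
#'   \code{\link{SEMFit-class}}).
#' @return Model with loadings fixed and psi diagonal freed.
#' @export
fixedLoadingModel <- function(model, estimates) {
  pt <- model@ptable
  lam <- pt$mat == "lambda" & pt$free
  pt$value[lam] <- estimates[pt$label[lam]]
  pt$free[lam] <- FALSE
  pt$label[lam] <- ""
  psiD <- pt$mat == "psi" & pt$row == pt$col
  pt$free[psiD] <- TRUE
  pt$label[psiD] <- sprintf("var(%s)", model@factors[pt$row[psiD]])
  pt$value[psiD] <- NA_real_
  ## previously free psi off-diagonals stay free; fixed ones stay fixed
  initialize(model, ptable = pt, kind = "custom")
}

#' Parse a compact model-specification syntax
#'
#' Supports lines \code{F1 =~ A + B + C} (free loadings),
#' \code{A ~~ B} (free residual covariance between indicators, or free
#' factor covariance between factors; \code{A ~~ A} frees a residual
#' variance), fixed values as \code{F1 ~~ 0*F2} or \code{F1 =~ 1*A}, and
#' \code{equal("F1=~A","F1=~B")} equality constraints. Factor variances
#' default to fixed 1 (unit-variance identification); indicator residual
#' variances default to free.
#'
#' @param text model syntax (one statement per line; \code{#} comments).
#' @param indicators indicator labels in S order.
#' @return A \code{\link{SEMModel-class}}.
#' @export
parseModelSyntax <- function(text, indicators) {
  lines <- trimws(strsplit(paste(text, collapse = "\n"), "\n")[[1]])
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  loadRows <- list(); covRows <- list(); equalities <- list()
  factors <- character(0)
  for (ln in lines) {
    if (grepl("^equal\\(", ln)) {
      labs <- regmatches(ln, gregexpr('"[^"]+"', ln))[[1]]
      equalities[[length(equalities) + 1L]] <- gsub('"', "", labs)
    } else if (grepl("=~", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "=~", fixed = TRUE)[[1]]
      f <- trimws(parts[1])
      factors <- union(factors, f)
      rhs <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
      for (term in rhs) {
        fx <- NA_real_; ind <- term
        if (grepl("*", term, fixed = TRUE)) {
          bits <- trimws(strsplit(term, "*", fixed = TRUE)[[1]])
          fx <- as.numeric(bits[1]); ind <- bits[2]
        }
        loadRows[[length(loadRows) + 1L]] <- list(f = f, ind = ind, fix = fx)
      }
    } else if (grepl("~~", ln, fixed = TRUE)) {
      parts <- trimws(strsplit(ln, "~~", fixed = TRUE)[[1]])
      fx <- NA_real_; rhs <- parts[2]
      if (grepl("*", rhs, fixed = TRUE)) {
        bits <- trimws(strsplit(rhs, "*", fixed = TRUE)[[1]])
        fx <- as.numeric(bits[1]); rhs <- bits[2]
      }
      covRows[[length(covRows) + 1L]] <- list(a = parts[1], b = rhs, fix = fx)
    } else stop("cannot parse model line: ", ln)
  }
  pt <- list()
  for (r in loadRows) {
    i <- match(r$ind, indicators)
    if (is.na(i)) stop("unknown indicator in model syntax: ", r$ind)
    f <- match(r$f, factors)
    pt[[length(pt) + 1L]] <- .prow("lambda", i, f, is.na(r$fix),
                                   if (is.na(r$fix)) NA_real_ else r$fix,
                                   if (is.na(r$fix))
                                     sprintf("%s=~%s", r$f, r$ind) else "")
  }
  psiSeen <- matrix(FALSE, length(factors), length(factors))
  for (r in covRows) {
    if (r$a %in% factors && r$b %in% factors) {
      f1 <- match(r$a, factors); f2 <- match(r$b, factors)
      rr <- max(f1, f2); cc <- min(f1, f2)
      psiSeen[rr, cc] <- TRUE
      pt[[length(pt) + 1L]] <- .prow("psi", rr, cc, is.na(r$fix),
                                     if (is.na(r$fix)) NA_real_ else r$fix,
                                     if (is.na(r$fix))
                                       sprintf("%s~~%s", factors[cc],
                                               factors[rr]) else "")
    } else {
      i <- match(r$a, indicators); j <- match(r$b, indicators)
      if (is.na(i) || is.na(j)) stop("unknown variable in: ", r$a, " ~~ ", r$b)
      rr <- max(i, j); cc <- min(i, j)
      pt[[length(pt) + 1L]] <- .prow("theta", rr, cc, is.na(r$fix),
                                     if (is.na(r$fix)) NA_real_ else r$fix,
                                     if (is.na(r$fix))
                                       sprintf("%s~~%s", indicators[cc],
                                               indicators[rr]) else "")
    }
  }
  for (f in seq_along(factors))   # default unit-variance identification
    if (!psiSeen[f, f]) pt[[length(pt) + 1L]] <- .prow("psi", f, f, FALSE, 1, "")
  ptab <- do.call(rbind, pt)
  for (i in seq_along(indicators)) {  # default free residual variances
    if (!any(ptab$mat == "theta" & ptab$row == i & ptab$col == i))
      ptab <- rbind(ptab, .prow("theta", i, i, TRUE, NA_real_,
                                sprintf("%s~~%s", indicators[i],
                                        indicators[i])))
  }
  mod <- new("SEMModel", indicators = indicators, factors = factors,
             kind = "custom", ptable = ptab)
  for (eq in equalities) mod <- constrainEqual(mod, eq)
  mod
}
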