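#' @import methods
#' @rawNamespace exportMethods(show)
NULL

## ---------------------------------------------------------------------------
## CleanedSumstats: one trait's QC'd, reference-aligned summary statistics
## ---------------------------------------------------------------------------

#' CleanedSumstats: quality-controlled GWAS summary statistics
#'
#' Holds one trait's per-SNP z-statistics after munging: restricted to the
#' reference SNP list, alleles aligned to the reference orientation, and all
#' QC filters applied. Rows are ordered as in the reference list so that
#' jackknife blocks are comparable across traits.
#'
#' @slot records data.frame with columns \code{snp, a1, a2, z, n, maf} and
#'   optionally \code{info}.
#' @slot trait list of trait metadata (see \code{\link{traitMeta}}).
#' @slot log named numeric vector of per-filter removal counts.
#' @export
setClass("CleanedSumstats",
  slots = c(records = "data.frame", trait = "list", log = "numeric"))

setValidity("CleanedSumstats", function(object) {
  r <- object@records
  need <- c("snp", "a1", "a2", "z", "n", "maf")
  if (!all(need %in% names(r)))
    return(paste("records must contain columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(r$snp)) return("duplicated SNP ids in records")
  if (nrow(r) > 0) {
    if (any(!is.finite(r$z))) return("non-finite z-statistics")
    if (any(r$maf <= 0 | r$maf > 0.5)) return("maf outside (0, 0.5]")
    if (any(r$a1 == r$a2)) return("a1 == a2 for some record")
  }
  TRUE
})

#' @describeIn CleanedSumstats number of retained SNPs
#' @param x,object a \code{CleanedSumstats}
#' @export
setMethod("length", "CleanedSumstats", function(x) nrow(x@records))

#' Accessors for CleanedSumstats
#' @param x a \code{CleanedSumstats} object.
#' @return \code{sumstatsRecords} returns the per-SNP data.frame;
#'   \code{traitInfo} the trait metadata list; \code{mungeLog} the named
#'   vector of per-filter removal counts.
#' @export
sumstatsRecords <- function(x) x@records

#' @rdname sumstatsRecords
#' @export
traitInfo <- function(x) x@trait

#' @rdname sumstatsRecords
#' @export
mungeLog <- function(x) x@log

setMethod("show", "CleanedSumstats", function(object) {
  cat("CleanedSumstats:", object@trait$name %||% "<unnamed>",
      "-", nrow(object@records), "SNPs retained\n")
  if (length(object@log))
    cat("  removed:", paste(names(object@log), object@log,
                            sep = "=", collapse = ", "), "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## LDScorePanel: genome-wide and stratified LD scores plus annotation sizes
## ---------------------------------------------------------------------------

#' LDScorePanel: LD scores and annotation bookkeeping
#'
#' @slot scores data.frame with columns \code{snp}, \code{L2} (genome-wide
#'   LD score) and one column per annotation holding stratified scores
#'   \eqn{l(j,c)}. The whole-genome annotation column must equal \code{L2}.
#' @slot sizes named numeric: SNP count \eqn{M_c} per annotation.
#' @slot overlaps named square matrix of pairwise annotation overlap counts.
#' @slot M total SNP count of the regression universe.
#' @slot members optional logical matrix (SNP x annotation) of memberships;
#'   populated by the synthetic generator, empty for external panels.
#' @export
setClass("LDScorePanel",
  slots = c(scores = "data.frame", sizes = "numeric", overlaps = "matrix",
            M = "numeric", members = "matrix"))

setValidity("LDScorePanel", function(object) {
  if (!all(c("snp", "L2") %in% names(object@scores)))
    return("scores must contain columns snp and L2")
  ann <- names(object@sizes)
  if (length(ann)) {
    if (!all(ann %in% names(object@scores)))
      return("every annotation in sizes needs a stratified score column")
    if (!identical(dim(object@overlaps), c(length(ann), length(ann))))
      return("overlaps must be square over the annotations")
    if (any(object@sizes <= 0) || any(object@sizes > object@M))
      return("annotation sizes must lie in (0, M]")
    d <- diag(object@overlaps)
    if (any(abs(d - object@sizes) > 1e-8))
      return("diag(overlaps) must equal annotation sizes")
    if (max(abs(object@overlaps - t(object@overlaps))) > 1e-8)
      return("overlaps must be symmetric")
  }
  TRUE
})

#' Accessors for LDScorePanel
#' @param x an \code{LDScorePanel}.
#' @return \code{ldScores} the per-SNP score table; \code{annotationSizes}
#'   the named \eqn{M_c} vector; \code{annotationOverlaps} the overlap-count
#'   matrix; \code{totalSNPs} the regression universe size \eqn{M}.
#' @export
ldScores <- function(x) x@scores

#' @rdname ldScores
#' @export
annotationSizes <- function(x) x@sizes

#' @rdname ldScores
#' @export
annotationOverlaps <- function(x) x@overlaps

#' @rdname ldScores
#' @export
totalSNPs <- function(x) x@M

setMethod("show", "LDScorePanel", function(object) {
  cat("LDScorePanel:", nrow(object@scores), "SNPs, M =", object@M, "\n")
  if (length(object@sizes))
    cat("  annotations:", paste(names(object@sizes), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## GeneticCovariance: the (S, V) pair plus LDSC intercepts
## ---------------------------------------------------------------------------

#' GeneticCovariance: genetic covariance and its sampling covariance
#'
#' The central multivariable LDSC output: \code{S} holds SNP heritabilities
#' on the diagonal and genetic covariances off it; \code{V} is the sampling
#' covariance of the unique elements of \code{S} (half-vectorization order,
#' see \code{\link{vech}}) from a multivariate delete-one-block jackknife;
#' \code{intercepts} holds univariate intercepts on the diagonal and
#' cross-trait intercepts (the sample-overlap index
#' \eqn{\rho N_s / \sqrt{N_1 N_2}}) off it.
#'
#' @slot S k x k genetic covariance matrix.
#' @slot V sampling covariance of \code{vech(S)}.
#' @slot intercepts k x k LDSC intercept matrix.
#' @slot interceptSE k x k jackknife SEs of the intercepts.
#' @slot nSNPs number of regression SNPs.
#' @slot nBlocks jackknife block count.
#' @slot flagged traits with non-positive estimated heritability.
#' @export
setClass("GeneticCovariance",
  slots = c(S = "matrix", V = "matrix", intercepts = "matrix",
            interceptSE = "matrix", nSNPs = "numeric", nBlocks = "integer",
            flagged = "character"))

setValidity("GeneticCovariance", function(object) {
  k <- nrow(object@S)
  p <- k * (k + 1L) / 2L
  if (ncol(object@S) != k) return("S must be square")
  if (max(abs(object@S - t(object@S))) > 1e-8) return("S must be symmetric")
  if (!all(dim(object@V) == p))
    return("V must be k(k+1)/2 square")
  if (any(diag(object@V) < -1e-12)) return("diag(V) must be non-negative")
  TRUE
})

#' Accessors for GeneticCovariance
#' @param x a \code{GeneticCovariance}.
#' @return \code{covMatrix} the genetic covariance matrix S;
#'   \code{samplingCov} the jackknife sampling covariance V of
#'   \code{vech(S)}; \code{ldscIntercepts} the intercept matrix;
#'   \code{traitNames} the trait labels; \code{geneticCorrelation} the
#'   standardized (correlation-metric) S.
#' @export
covMatrix <- function(x) x@S

#' @rdname covMatrix
#' @export
samplingCov <- function(x) x@V

#' @rdname covMatrix
#' @export
ldscIntercepts <- function(x) x@intercepts

#' @rdname covMatrix
#' @export
traitNames <- function(x) rownames(x@S)

#' @rdname covMatrix
#' @export
geneticCorrelation <- function(x) {
  h2 <- diag(x@S)
  if (any(h2 <= 0))
    stop("standardization refused: non-positive heritability for trait(s) ",
         paste(rownames(x@S)[h2 <= 0], collapse = ", "))
  stats::cov2cor(x@S)
}

setMethod("show", "GeneticCovariance", function(object) {
  k <- nrow(object@S)
  cat("GeneticCovariance over", k, "traits (", object@nSNPs, "SNPs,",
      object@nBlocks, "jackknife blocks )\n")
  cat("  h2:", paste(rownames(object@S),
                     sprintf("%.3f", diag(object@S)), sep = "=",
                     collapse = ", "), "\n")
  if (length(object@flagged))
    cat("  flagged non-positive h2:", paste(object@flagged, collapse = ", "),
        "\n")
})

## ---------------------------------------------------------------------------
## SphericalParcellation
## ---------------------------------------------------------------------------

#' SphericalParcellation: region centroids on the unit sphere
#'
#' @slot regions region labels.
#' @slot centroids n x 3 matrix of unit-norm centroid coordinates.
#' @slot hemisphere "left" or "right" per region.
#' @export
setClass("SphericalParcellation",
  slots = c(regions = "character", centroids = "matrix",
            hemisphere = "character"))

setValidity("SphericalParcellation", function(object) {
  n <- length(object@regions)
  if (anyDuplicated(object@regions)) return("region labels must be unique")
  if (!identical(dim(object@centroids), c(n, 3L)) &&
      !identical(dim(object@centroids), as.integer(c(n, 3))))
    return("centroids must be n x 3")
  nrm <- sqrt(rowSums(object@centroids^2))
  if (any(abs(nrm - 1) > 1e-6)) return("centroids must be unit-norm")
  if (!all(object@hemisphere %in% c("left", "right")))
    return("hemisphere must be 'left' or 'right'")
  if (length(object@hemisphere) != n)
    return("one hemisphere label per region")
  TRUE
})

#' Construct a spherical parcellation
#'
#' @param regions character region labels.
#' @param centroids n x 3 coordinate matrix; rows are normalized to unit
#'   length.
#' @param hemisphere per-region hemisphere ("left"/"right"); defaults to
#'   all "left", the convention for bilateral (hemisphere-averaged) maps.
#' @return A \code{\link{SphericalParcellation-class}} object.
#' @export
sphericalParcellation <- function(regions, centroids,
                                  hemisphere = rep("left", length(regions))) {
  centroids <- as.matrix(centroids)
  storage.mode(centroids) <- "double"
  nrm <- sqrt(rowSums(centroids^2))
  if (any(nrm == 0)) stop("zero-length centroid")
  centroids <- centroids / nrm
  rownames(centroids) <- regions
  new("SphericalParcellation", regions = as.character(regions),
      centroids = centroids, hemisphere = as.character(hemisphere))
}

setMethod("show", "SphericalParcellation", function(object) {
  cat("SphericalParcellation:", length(object@regions), "regions (",
      sum(object@hemisphere == "left"), "left /",
      sum(object@hemisphere == "right"), "right )\n")
})

#' Read a parcellation from CSV
#'
#' Expects columns \code{region, hemisphere, x, y, z}.
#' @param path CSV file path.
#' @return A \code{\link{SphericalParcellation-class}}.
#' @export
readParcellation <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "hemisphere", "x", "y", "z")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("parcellation CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  sphericalParcellation(d$region, as.matrix(d[, c("x", "y", "z")]),
                        d$hemisphere)
}
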