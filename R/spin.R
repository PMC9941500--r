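## Spin-permutation comparison of a factor parcellation against
## categorical and continuous cortical maps.  Spins are computed at the
## region-centroid level: each permutation draws a uniform random 3D
## rotation, applies it to left-hemisphere centroids and its x-mirrored
## counterpart to right-hemisphere centroids, and relabels every region by
## its nearest original centroid within the same hemisphere.

## uniform random proper rotation (QR of a Gaussian matrix, sign-corrected)
.randomRotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  Q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 3L] <- -Q[, 3L]
  Q
}

## relabeling induced by rotation Q: index vector idx with spun map value
## for region r = map[idx[r]]; ties broken toward lower region order
.nearestRelabel <- function(parc, Q) {
  Fm <- diag(c(-1, 1, 1))
  idx <- integer(length(parc@regions))
  for (h in c("left", "right")) {
    sel <- which(parc@hemisphere == h)
    if (!length(sel)) next
    R <- if (h == "left") Q else Fm %*% Q %*% Fm
    rot <- parc@centroids[sel, , drop = FALSE] %*% t(R)
    ## nearest original centroid within hemisphere = max inner product
    ip <- rot %*% t(parc@centroids[sel, , drop = FALSE])
    idx[sel] <- sel[max.col(ip, ties.method = "first")]
  }
  idx
}

#' Generate spin permutations of a spherical parcellation
#'
#' Draws \code{nSpins} uniform random rotations; each left-hemisphere
#' centroid is rotated by the rotation and each right-hemisphere centroid
#' by its x-mirrored counterpart (preserving hemispheric symmetry), then
#' every region is relabeled by the nearest original centroid within its
#' hemisphere. Relabelings are surjections onto the original regions
#' (repeated labels are permitted); hemisphere membership is preserved.
#'
#' @param parc a \code{\link{SphericalParcellation-class}} with at least 3
#'   regions per populated hemisphere.
#' @param nSpins number of spins (default 10000).
#' @param seed integer seed (mandatory: results are byte-identical under
#'   a fixed seed).
#' @return Integer matrix (nSpins x nRegions) of relabeling indices with
#'   attribute \code{seed}.
#' @export
spinPermutations <- function(parc, nSpins = 10000L, seed) {
  n <- length(parc@regions)
  for (h in c("left", "right")) {
    sel <- parc@hemisphere == h
    if (any(sel)) {
      if (sum(sel) < 3L) stop("need at least 3 regions per hemisphere")
      cc <- round(parc@centroids[sel, , drop = FALSE], 12)
      if (anyDuplicated(cc)) stop("duplicate centroids within hemisphere")
    }
  }
  .withSeed(seed, {
    out <- matrix(NA_integer_, nSpins, n)
    for (s in seq_len(nSpins)) out[s, ] <- .nearestRelabel(parc, .randomRotation())
    attr(out, "seed") <- as.integer(seed)
    colnames(out) <- parc@regions
    out
  })
}

## Fisher exact dependence p for an r x c contingency table, Monte-Carlo
## over tables with fixed margins using the hypergeometric probability
## ordering (the same ordering as the exact network algorithm) with the
## mid-p convention: tables exactly as probable as the observed one count
## half.  The mid-p form keeps p-values comparable across tables of very
## different granularity, which matters here because spun (coarsened)
## relabelings are compared against the finer observed table.
## `lfact` is a precomputed log-factorial table.
.fisherMC <- function(tab, draws, lfact) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(1)
  obs <- sum(lfact[tab + 1L])
  sims <- stats::r2dtable(draws, rowSums(tab), colSums(tab))
  simStat <- colSums(matrix(lfact[unlist(sims, use.names = FALSE) + 1L],
                            ncol = draws))
  above <- sum(simStat > obs + 1e-9)
  ties <- sum(abs(simStat - obs) <= 1e-9)
  (0.5 + above + 0.5 * ties) / (draws + 1)
}

#' SpinResult: a spin-permutation test outcome
#'
#' @slot observed observed test statistic.
#' @slot null null statistics, one per spin.
#' @slot pSpin plus-one-corrected permutation p-value, in (0, 1]; the
#'   attainable floor is \code{1/(nSpins+1)}.
#' @slot nSpins spin count.
#' @slot seed RNG seed used.
#' @export
setClass("SpinResult",
  slots = c(observed = "numeric", null = "numeric", pSpin = "numeric",
            nSpins = "integer", seed = "integer"))

setValidity("SpinResult", function(object) {
  if (object@pSpin <= 0 || object@pSpin > 1) return("pSpin must be in (0,1]")
  TRUE
})

setMethod("show", "SpinResult", function(object) {
  cat("SpinResult: observed =", format(object@observed, digits = 4),
      ", P_spin =", format(object@pSpin, digits = 4),
      "(", object@nSpins, "spins )\n")
})

#' Categorical-map spin test (Fisher exact dependence)
#'
#' The observed statistic is the Fisher exact dependence p-value of the
#' contingency table of map A versus map B (Monte-Carlo over tables with
#' fixed margins, seeded; an exact p for larger tables is infeasible).
#' The null distribution recomputes the statistic with A spun; the
#' reported \eqn{P_{spin}} is the plus-one-corrected fraction of spins
#' whose p is at most the observed p.
#'
#' @param mapA,mapB named vectors/factors of class labels on the
#'   parcellation's regions (names must match the spin columns).
#' @param spins relabeling matrix from \code{\link{spinPermutations}}.
#' @param fisherDraws Monte-Carlo tables for the observed Fisher p
#'   (default 100000; an exact p is used for tables with a dimension of 2
#'   or less).
#' @param nullDraws Monte-Carlo tables per spun Fisher p (default 2000;
#'   set equal to \code{fisherDraws} for strict exchangeability of the
#'   observed and null statistics, e.g. in calibration studies).
#' @param seed integer seed for the Monte-Carlo Fisher draws.
#' @return A \code{\link{SpinResult-class}} (statistics are Fisher p's).
#' @export
categoricalSpinTest <- function(mapA, mapB, spins, fisherDraws = 100000L,
                                nullDraws = 2000L, seed = 1L) {
  regions <- colnames(spins)
  A <- .alignMap(mapA, regions); B <- .alignMap(mapB, regions)
  keep <- !is.na(A) & !is.na(B)
  if (!all(keep)) warning(sum(!keep), " regions missing from a map; ",
                          "excluded pairwise")
  nSpins <- nrow(spins)
  if (length(unique(A[keep])) < 2L || length(unique(B[keep])) < 2L) {
    warning("a map has a single class; spin test degenerate, pSpin = 1")
    return(new("SpinResult", observed = 1, null = rep(1, nSpins), pSpin = 1,
               nSpins = as.integer(nSpins), seed = as.integer(seed)))
  }
  lfact <- lgamma(seq_len(length(A) + 2L))
  .withSeed(seed, {
    obs <- .fisherMC(table(A[keep], B[keep]), fisherDraws, lfact)
    null <- numeric(nSpins)
    for (s in seq_len(nSpins)) {
      As <- A[spins[s, ]]
      ok <- !is.na(As) & !is.na(B)
      null[s] <- .fisherMC(table(As[ok], B[ok]), nullDraws, lfact)
    }
    pSpin <- (1 + sum(null <= obs + 1e-12)) / (nSpins + 1)
    new("SpinResult", observed = obs, null = null, pSpin = pSpin,
        nSpins = as.integer(nSpins), seed = as.integer(seed))
  })
}

.alignMap <- function(map, regions) {
  v <- if (is.factor(map)) as.character(map) else map
  if (!is.null(names(map))) {
    out <- v[match(regions, names(map))]
  } else {
    if (length(v) != length(regions))
      stop("unnamed map must cover every region")
    out <- v
  }
  out
}

#' Continuous-map spin tests (omnibus F) with FDR adjustment
#'
#' For each continuous map, the observed statistic is the one-way omnibus
#' F of the map values grouped by the factor labels; the null recomputes
#' F with the labels spun. \eqn{P_{spin}} values are plus-one corrected
#' and Benjamini-Hochberg adjusted across the map collection. A constant
#' map (undefined F) is reported with \code{pSpin = 1} and flagged.
#'
#' @param labels named factor labels on the regions (the parcellation's
#'   factor assignment).
#' @param maps named list of named numeric maps, or a region x map matrix.
#' @param spins relabeling matrix from \code{\link{spinPermutations}}.
#' @return data.frame (map, F, pSpin, q, degenerate).
#' @export
continuousSpinTest <- function(labels, maps, spins) {
  regions <- colnames(spins)
  g <- factor(.alignMap(labels, regions))
  if (nlevels(droplevels(g[!is.na(g)])) < 2L) {
    warning("single-group labeling; all pSpin = 1")
  }
  if (is.matrix(maps)) maps <- as.data.frame(maps)
  if (is.numeric(maps) && is.null(dim(maps))) maps <- list(map = maps)
  if (is.null(names(maps))) names(maps) <- paste0("map", seq_along(maps))
  nSpins <- nrow(spins)
  omnibusF <- function(y, grp) {
    ok <- !is.na(y) & !is.na(grp)
    y <- y[ok]; grp <- droplevels(grp[ok])
    if (nlevels(grp) < 2L) return(NA_real_)
    n <- length(y)
    gm <- tapply(y, grp, mean); gn <- tabulate(grp)
    ssb <- sum(gn * (gm - mean(y))^2)
    ssw <- sum((y - gm[as.integer(grp)])^2)
    if (ssw <= 0) return(if (ssb > 0) Inf else NA_real_)
    (ssb / (nlevels(grp) - 1)) / (ssw / (n - nlevels(grp)))
  }
  out <- lapply(names(maps), function(nmap) {
    y <- .alignMap(maps[[nmap]], regions)
    y <- as.numeric(y)
    if (sum(!is.na(y)) < length(regions))
      warning("map '", nmap, "' missing regions; excluded pairwise")
    Fobs <- omnibusF(y, g)
    if (!is.finite(Fobs) && !identical(Fobs, Inf)) {
      return(data.frame(map = nmap, F = NA_real_, pSpin = 1,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    nullF <- vapply(seq_len(nSpins), function(s)
      omnibusF(y, g[spins[s, ]]), 0)
    pSpin <- (1 + sum(nullF >= Fobs - 1e-12, na.rm = TRUE)) / (nSpins + 1)
    data.frame(map = nmap, F = Fobs, pSpin = pSpin, degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$q <- stats::p.adjust(out$pSpin, method = "BH")
  rownames(out) <- NULL
  out[, c("map", "F", "pSpin", "q", "degenerate")]
}
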