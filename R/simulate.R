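## Synthetic-study generator with machine-readable ground truth.
##
## Generation happens at the z-statistic level: for each SNP the k-vector
## of z-statistics is drawn from a zero-mean multivariate normal whose
## covariance follows the stratified-LDSC expectation, so the generator and
## the estimator are exact inverses in expectation. LD enters only through
## the LD scores, per-SNP draws are independent (the standard LDSC design
## approximation).

#' Simulate an LD-score panel with annotations
#'
#' Genome-wide LD scores are drawn from a right-skewed positive
#' distribution with block structure: contiguous blocks of SNPs share a
#' gamma-distributed block mean, supporting the contiguous-block jackknife.
#' Annotations other than the whole-genome annotation are assigned
#' contiguous disjoint SNP stretches; stratified scores are additive by
#' construction (\eqn{l(j,c) = l_j} for the annotation containing SNP j,
#' else 0), so disjoint covering annotations sum to the genome-wide score.
#'
#' @param M SNP count (>= 1000).
#' @param annotations named numeric vector of SNP fractions per annotation
#'   (excluding the automatic whole-genome annotation "base"); fractions
#'   must sum to at most 1; the remainder forms an unannotated stretch that
#'   still contributes to "base".
#' @param ldShape list with \code{meanL2} (mean LD score, default 2),
#'   \code{blockSize} (SNPs per LD block, default 100) and \code{shape}
#'   (gamma shape of block means, default 4).
#' @param seed integer seed (mandatory).
#' @return An \code{\link{LDScorePanel-class}} with membership matrix
#'   populated.
#' @export
simulateLDScores <- function(M, annotations = numeric(),
                             ldShape = list(), seed) {
  if (M < 1000) stop("M must be at least 1000")
  if (length(annotations) && sum(annotations) > 1 + 1e-12)
    stop("annotation fractions must sum to at most 1")
  meanL2 <- ldShape$meanL2 %||% 2
  blockSize <- ldShape$blockSize %||% 100
  shape <- ldShape$shape %||% 4
  .withSeed(seed, {
    nb <- ceiling(M / blockSize)
    bm <- stats::rgamma(nb, shape = shape, scale = (meanL2 - 1) / shape)
    mu <- rep(bm, each = blockSize)[seq_len(M)]
    l2 <- 1 + stats::rgamma(M, shape = 2, scale = mu / 2)
    annNames <- c("base", names(annotations))
    members <- matrix(FALSE, M, length(annNames),
                      dimnames = list(NULL, annNames))
    members[, "base"] <- TRUE
    if (length(annotations)) {
      sizes <- round(annotations * M)
      start <- 1L
      for (a in seq_along(sizes)) {
        stop_ <- start + sizes[a] - 1L
        members[start:stop_, names(annotations)[a]] <- TRUE
        start <- stop_ + 1L
      }
    }
    scores <- data.frame(snp = paste0("rs", seq_len(M)), L2 = l2)
    for (a in annNames) scores[[a]] <- l2 * members[, a]
    sizes <- colSums(members)
    overlaps <- crossprod(members)
    new("LDScorePanel", scores = scores, sizes = sizes,
        overlaps = overlaps, M = as.numeric(M), members = members)
  })
}

#' Specify a generative model for multi-trait GWAS summary statistics
#'
#' Describes a factor model over k traits together with the sampling design
#' (per-trait N, pairwise sample overlap and confounding) and the genomic
#' design (LD scores, annotations, per-annotation variance shares). The
#' implied per-SNP z-score covariance instantiates the stratified-LDSC
#' expectation exactly, so every downstream estimate has a known truth.
#'
#' @param loadings k x m matrix of true standardized loadings.
#' @param factorCor m x m factor correlation matrix (default identity).
#' @param h2 length-k SNP heritabilities in (0,1).
#' @param N length-k GWAS sample sizes.
#' @param M SNP count (panel is simulated when \code{ld} is NULL).
#' @param ld optional \code{\link{LDScorePanel-class}} from
#'   \code{\link{simulateLDScores}} (must carry memberships).
#' @param annotShares named numeric vector of genetic-variance shares per
#'   generating annotation (summing to 1 over the disjoint generating set);
#'   default: all variance in the whole-genome annotation.
#' @param overlapRho,overlapN k x k matrices of pairwise phenotypic
#'   correlation in overlapping participants and overlap counts (default:
#'   no overlap).
#' @param confound k x k matrix of constant confounding terms (default 0).
#' @param traitNames labels (default trait1..k).
#' @param seed integer seed (mandatory).
#' @return List of class \code{generativeSpec}.
#' @export
generativeSpec <- function(loadings, factorCor = NULL, h2, N, M = 20000,
                           ld = NULL, annotShares = NULL,
                           overlapRho = NULL, overlapN = NULL,
                           confound = NULL, traitNames = NULL, seed) {
  loadings <- as.matrix(loadings)
  k <- nrow(loadings); m <- ncol(loadings)
  if (is.null(factorCor)) factorCor <- diag(m)
  if (length(h2) == 1L) h2 <- rep(h2, k)
  if (length(N) == 1L) N <- rep(N, k)
  stopifnot(length(h2) == k, length(N) == k)
  if (any(h2 <= 0 | h2 >= 1)) stop("h2 must lie in (0,1)")
  if (is.null(overlapRho)) overlapRho <- matrix(0, k, k)
  if (is.null(overlapN)) overlapN <- matrix(0, k, k)
  if (is.null(confound)) confound <- matrix(0, k, k)
  if (any(overlapN > outer(N, N, pmin) + 1e-9))
    stop("sample overlap cannot exceed the smaller of the two sample sizes")
  if (any(abs(overlapRho) > 1)) stop("|rho| must be <= 1")
  if (is.null(traitNames)) traitNames <- paste0("trait", seq_len(k))
  comm <- diag(loadings %*% factorCor %*% t(loadings))
  if (any(comm > 1 + 1e-9)) stop("communalities exceed 1")
  Rg <- loadings %*% factorCor %*% t(loadings) + diag(pmax(1 - comm, 0), k)
  ev <- eigen(Rg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("implied genetic correlation matrix not PSD")
  Strue <- sqrt(h2) %o% sqrt(h2) * Rg
  dimnames(Strue) <- list(traitNames, traitNames)
  structure(list(k = k, m = m, loadings = loadings, factorCor = factorCor,
                 h2 = h2, N = N, M = M, ld = ld, annotShares = annotShares,
                 overlapRho = overlapRho, overlapN = overlapN,
                 confound = confound, traitNames = traitNames,
                 Strue = Strue, Rg = Rg, seed = as.integer(seed)),
            class = "generativeSpec")
}

#' Simulate multi-trait GWAS summary statistics from a generative spec
#'
#' For each SNP j the k-vector of z-statistics is drawn from
#' \eqn{N(0, \Sigma_j)} with
#' \deqn{\Sigma_j[i,i'] = \sqrt{N_i N_{i'}} \sum_c \tau_{c,ii'}
#'   \frac{l(j,c)}{M_c} + \rho_{ii'} \frac{N_{s,ii'}}{\sqrt{N_i N_{i'}}}
#'   + a_{ii'}} (diagonal terms add 1). The \eqn{\tau_c} matrices follow
#' from the factor model and the per-annotation variance shares:
#' \eqn{\tau_c = q_c S_{true}}.
#'
#' @param spec a \code{\link{generativeSpec}}.
#' @return List with elements \code{sumstats} (list of
#'   \code{\link{CleanedSumstats-class}}), \code{ld} (the panel used) and
#'   \code{truth} (a truth record, see \code{\link{truthRecord}}).
#' @export
simulateSumstats <- function(spec) {
  stopifnot(inherits(spec, "generativeSpec"))
  ld <- spec$ld
  shares <- spec$annotShares
  if (is.null(ld)) {
    fracs <- numeric()
    ld <- simulateLDScores(spec$M, fracs, seed = spec$seed + 1L)
  }
  if (is.null(shares)) shares <- c(base = 1)
  if (abs(sum(shares) - 1) > 1e-9)
    stop("annotation variance shares must sum to 1")
  if (!all(names(shares) %in% names(ld@sizes)))
    stop("annotation shares refer to annotations absent from the panel")
  M <- ld@M
  k <- spec$k
  Mgen <- nrow(ld@scores)
  tau <- lapply(shares, function(q) q * spec$Strue)

  ## cross-sectional constant part of Sigma_j
  C <- diag(k) + spec$confound +
    spec$overlapRho * spec$overlapN / sqrt(spec$N %o% spec$N)
  C[!is.finite(C)] <- 0
  diag(C) <- 1 + diag(spec$confound)
  sqN <- sqrt(spec$N)

  ## per-annotation scaled tau: B_c = sqrt(N N') tau_c / M_c
  B <- lapply(names(shares), function(a)
    (sqN %o% sqN) * tau[[a]] / ld@sizes[[a]])
  names(B) <- names(shares)
  W <- as.matrix(ld@scores[, names(shares), drop = FALSE])  # l(j,c)

  Z <- .withSeed(spec$seed, {
    Zm <- matrix(stats::rnorm(Mgen * k), Mgen, k)
    out <- matrix(NA_real_, Mgen, k)
    for (j in seq_len(Mgen)) {
      Sig <- C
      for (a in seq_along(B)) {
        wj <- W[j, a]
        if (wj != 0) Sig <- Sig + wj * B[[a]]
      }
      ch <- tryCatch(chol(Sig), error = function(e)
        stop("per-SNP z covariance not positive definite at SNP ",
             ld@scores$snp[j], call. = FALSE))
      out[j, ] <- Zm[j, ] %*% ch
    }
    out
  })

  snp <- ld@scores$snp
  maf <- 0.05 + 0.45 * (seq_len(Mgen) %% 97) / 97   # deterministic filler
  sumstats <- lapply(seq_len(k), function(i) {
    new("CleanedSumstats",
        records = data.frame(snp = snp, a1 = "A", a2 = "G",
                             z = Z[, i], n = spec$N[i], maf = maf,
                             stringsAsFactors = FALSE),
        trait = traitMeta(spec$traitNames[i]),
        log = numeric())
  })
  names(sumstats) <- spec$traitNames
  truth <- truthRecord(spec, ld, tau)
  list(sumstats = sumstats, ld = ld, truth = truth)
}

#' Ground-truth record for a synthetic study
#'
#' Collects the generative parameters and all derived targets needed to
#' judge downstream estimates: the true genetic covariance matrix, the
#' per-annotation tau matrices, true enrichment per annotation, and the
#' true cross-trait intercepts. Serializes losslessly through JSON.
#'
#' @param spec a \code{\link{generativeSpec}}.
#' @param ld the LD panel used.
#' @param tau named list of true per-annotation tau matrices.
#' @return A list of class \code{truthRecord}.
#' @export
truthRecord <- function(spec, ld, tau) {
  shares <- vapply(tau, function(t) t[1, 1] / spec$Strue[1, 1], 0)
  enrich <- shares / (ld@sizes[names(tau)] / ld@M)
  crossInt <- spec$overlapRho * spec$overlapN / sqrt(spec$N %o% spec$N) +
    spec$confound
  diag(crossInt) <- 1 + diag(spec$confound)
  structure(list(
    k = spec$k, h2 = spec$h2, N = spec$N, M = spec$M,
    loadings = spec$loadings, factorCor = spec$factorCor,
    Strue = spec$Strue, Rg = spec$Rg, tau = tau,
    annotSizes = as.list(ld@sizes), enrichment = as.list(enrich),
    intercepts = crossInt, seed = spec$seed), class = "truthRecord")
}

#' Serialize / restore a truth record
#'
#' @param truth a \code{truthRecord}.
#' @param path JSON file path.
#' @return \code{writeTruthRecord} the path invisibly;
#'   \code{readTruthRecord} the restored record.
#' @export
writeTruthRecord <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeTruthRecord
#' @export
readTruthRecord <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$loadings <- as.matrix(x$loadings)
  x$factorCor <- as.matrix(x$factorCor)
  x$Strue <- as.matrix(x$Strue)
  x$Rg <- as.matrix(x$Rg)
  x$intercepts <- as.matrix(x$intercepts)
  x$tau <- lapply(x$tau, as.matrix)
  structure(x, class = "truthRecord")
}

#' Simulate a spherical parcellation with coupled maps
#'
#' Region centroids are drawn uniformly on the left-hemisphere half of the
#' unit sphere (the convention for bilateral, hemisphere-averaged maps).
#' A categorical map assigns each region one of \code{nClasses} classes; a
#' second map copies the first with probability \code{coupling} per region
#' and resamples uniformly otherwise. A continuous map equals the first
#' map's class means plus unit-variance noise.
#'
#' @param nRegions region count (>= nClasses).
#' @param nClasses class count.
#' @param coupling per-region copy probability in [0,1].
#' @param seed integer seed.
#' @return List with \code{parcellation}
#'   (\code{\link{SphericalParcellation-class}}), \code{mapA},
#'   \code{mapB} (named class labels) and \code{mapContinuous}.
#' @export
simulateParcellation <- function(nRegions, nClasses, coupling = 0, seed) {
  if (nRegions < nClasses) stop("need at least as many regions as classes")
  .withSeed(seed, {
    xyz <- matrix(stats::rnorm(nRegions * 3), nRegions, 3)
    xyz[, 1] <- -abs(xyz[, 1])   # left hemisphere: x < 0
    regions <- paste0("region", seq_len(nRegions))
    parc <- sphericalParcellation(regions, xyz)
    A <- sample(nClasses, nRegions, replace = TRUE)
    copy <- stats::runif(nRegions) < coupling
    Bm <- ifelse(copy, A, sample(nClasses, nRegions, replace = TRUE))
    cont <- as.numeric(A) + stats::rnorm(nRegions)
    mapA <- paste0("c", A); mapB <- paste0("c", Bm)
    names(mapA) <- names(mapB) <- names(cont) <- regions
    list(parcellation = parc, mapA = mapA, mapB = mapB,
         mapContinuous = cont)
  })
}
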