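## Reading, QC-filtering and harmonizing GWAS summary statistics.

#' Trait metadata
#'
#' Carries the descriptive information needed downstream: the measurement
#' scale, sample sizes and the prevalences used for the observed-to-liability
#' scale conversion of binary traits. When a sum of effective sample sizes
#' is used for a binary trait, the sample prevalence is fixed at 0.5 because
#' the effective N already accounts for case/control ascertainment.
#'
#' @param name trait label.
#' @param measurement "continuous" or "binary".
#' @param nTotal total sample size (optional when the sumstats carry a
#'   per-SNP N column, which always takes precedence).
#' @param nCases,nControls per-cohort case/control counts (binary traits);
#'   used to compute the effective sample size.
#' @param samplePrev sample prevalence; defaults to 0.5 when an effective N
#'   is supplied.
#' @param popPrev population prevalence K in (0,1) for liability conversion.
#' @return A list of class-free trait metadata, validated.
#' @export
traitMeta <- function(name, measurement = c("continuous", "binary"),
                      nTotal = NA_real_, nCases = NULL, nControls = NULL,
                      samplePrev = NA_real_, popPrev = NA_real_) {
  measurement <- match.arg(measurement)
  if (measurement == "binary") {
    hasEff <- !is.null(nCases) && !is.null(nControls)
    if (!hasEff && is.na(nTotal))
      stop("binary trait '", name,
           "' needs cohort case/control counts or a precomputed effective N")
    if (hasEff) {
      nTotal <- effectiveN(nCases, nControls)
      if (is.na(samplePrev)) samplePrev <- 0.5
    }
    if (!is.na(popPrev) && (popPrev <= 0 || popPrev >= 1))
      stop("population prevalence must lie in (0,1)")
  }
  list(name = name, measurement = measurement, nTotal = nTotal,
       nCases = nCases, nControls = nControls,
       samplePrev = samplePrev, popPrev = popPrev)
}

#' Sum of effective sample sizes over cohorts
#'
#' For a case/control GWAS meta-analysis the effective sample size of each
#' cohort is \eqn{4 v (1-v) N = 4 / (1/cases + 1/controls)} with
#' \eqn{v} the cohort case fraction; the trait-level effective N is the sum
#' over cohorts. Using it with a sample prevalence of 0.5 yields liability
#' heritabilities that correctly account for ascertainment differences
#' across contributing cohorts.
#'
#' @param nCases,nControls numeric vectors of per-cohort counts.
#' @return The summed effective sample size.
#' @examples
#' effectiveN(100, 100)            # balanced: equals total N
#' effectiveN(c(100, 50), c(100, 150))
#' @export
effectiveN <- function(nCases, nControls) {
  if (length(nCases) == 0L) stop("empty cohort list")
  if (length(nCases) != length(nControls))
    stop("nCases and nControls must have equal length")
  if (any(nCases <= 0) || any(nControls <= 0))
    stop("all cohort counts must be positive")
  sum(4 / (1 / nCases + 1 / nControls))
}

## column alias tables (matched case-insensitively)
.ALIASES <- list(
  snp  = c("SNP", "RSID", "RS_ID", "MARKERNAME", "SNPID", "RS"),
  a1   = c("A1", "EFFECT_ALLELE", "ALLELE1", "EA", "REF"),
  a2   = c("A2", "OTHER_ALLELE", "ALLELE2", "NON_EFFECT_ALLELE", "OA", "ALT"),
  z    = c("Z", "ZSCORE", "Z_STAT", "ZSTAT"),
  beta = c("BETA", "B", "EFFECT", "EST"),
  or   = c("OR", "ODDS_RATIO"),
  se   = c("SE", "STDERR", "STD_ERR", "STANDARD_ERROR"),
  n    = c("N", "NTOT", "N_TOTAL", "NEFF", "N_EFF", "TOTALN"),
  maf  = c("MAF", "FREQ", "EAF", "FRQ", "AF", "A1FREQ"),
  info = c("INFO", "IMPINFO", "INFO_SCORE"))

.findCol <- function(nms, key) {
  hit <- which(toupper(nms) %in% .ALIASES[[key]])
  if (length(hit)) hit[1L] else NA_integer_
}

.AMBIGUOUS <- c(AT = TRUE, TA = TRUE, CG = TRUE, GC = TRUE)

#' Munge GWAS summary statistics against a reference SNP list
#'
#' Applies the standard LDSC quality-control pipeline: restrict to the
#' reference SNP list (e.g. HapMap3), drop strand-ambiguous (A/T, C/G)
#' variants, drop MAF below \code{mafMin} and INFO below \code{infoMin}
#' (the INFO filter is skipped with a warning when no INFO column exists),
#' align the effect allele to the reference orientation flipping the sign
#' of z where needed, and convert beta/SE (or OR/SE on the log scale) to
#' z-statistics when no Z column exists. Duplicate SNP ids are dropped
#' entirely with a warning. The output is ordered as in the reference list,
#' making the result invariant to row permutations of the input.
#'
#' @param raw data.frame or path to a (possibly gzipped) delimited file with
#'   a header. Recognized column aliases: SNP/RSID, A1/EFFECT_ALLELE,
#'   A2/OTHER_ALLELE, Z or BETA+SE or OR+SE, N, MAF/FREQ, INFO.
#' @param reference data.frame or path with columns SNP, A1, A2 giving the
#'   reference orientation.
#' @param trait \code{\link{traitMeta}} list.
#' @param mafMin,infoMin filter thresholds (defaults 0.01 and 0.9).
#' @return A \code{\link{CleanedSumstats-class}} object; its \code{log}
#'   accounts for every input row (retained + per-filter removals = input).
#' @export
mungeSumstats <- function(raw, reference, trait = traitMeta("trait"),
                          mafMin = 0.01, infoMin = 0.9) {
  if (is.character(raw))
    raw <- as.data.frame(data.table::fread(raw))
  if (is.character(reference))
    reference <- as.data.frame(data.table::fread(reference))
  raw <- as.data.frame(raw)
  names(reference) <- toupper(names(reference))
  if (!all(c("SNP", "A1", "A2") %in% names(reference)))
    stop("reference must have columns SNP, A1, A2")
  if (nrow(reference) == 0L) stop("reference SNP list is empty")

  nms <- names(raw)
  ci <- vapply(names(.ALIASES), function(k) .findCol(nms, k), 1L)
  for (key in c("snp", "a1", "a2")) {
    if (is.na(ci[[key]]))
      stop("missing mandatory column '", toupper(key),
           "' (or a recognized alias) in summary statistics")
  }
  hasZ <- !is.na(ci[["z"]])
  if (!hasZ && (is.na(ci[["beta"]]) && is.na(ci[["or"]])))
    stop("missing mandatory column 'Z' (or BETA/OR with SE)")
  if (!hasZ && is.na(ci[["se"]]))
    stop("missing mandatory column 'SE' needed to derive z from effect sizes")

  nIn <- nrow(raw)
  log <- c(duplicate = 0, not_in_reference = 0, allele_mismatch = 0,
           strand_ambiguous = 0, maf = 0, info = 0, bad_z = 0)

  d <- data.frame(
    snp = as.character(raw[[ci[["snp"]]]]),
    a1 = toupper(as.character(raw[[ci[["a1"]]]])),
    a2 = toupper(as.character(raw[[ci[["a2"]]]])),
    stringsAsFactors = FALSE)
  if (hasZ) {
    d$z <- as.numeric(raw[[ci[["z"]]]])
  } else if (!is.na(ci[["beta"]])) {
    d$z <- as.numeric(raw[[ci[["beta"]]]]) / as.numeric(raw[[ci[["se"]]]])
  } else {
    d$z <- log(as.numeric(raw[[ci[["or"]]]])) / as.numeric(raw[[ci[["se"]]]])
  }
  d$n <- if (!is.na(ci[["n"]])) as.numeric(raw[[ci[["n"]]]]) else
    rep(trait$nTotal, nIn)
  if (all(is.na(d$n)))
    stop("no per-SNP N column and no nTotal in trait metadata")
  d$maf <- if (!is.na(ci[["maf"]])) as.numeric(raw[[ci[["maf"]]]]) else
    rep(NA_real_, nIn)
  hasInfo <- !is.na(ci[["info"]])
  if (hasInfo) d$info <- as.numeric(raw[[ci[["info"]]]])
  ## fold allele frequencies to minor allele frequencies
  d$maf <- ifelse(!is.na(d$maf) & d$maf > 0.5, 1 - d$maf, d$maf)

  ## drop-all duplicate ids
  dup <- d$snp %in% d$snp[duplicated(d$snp)]
  if (any(dup)) {
    warning(sum(dup), " rows with duplicated SNP ids dropped")
    log["duplicate"] <- sum(dup)
    d <- d[!dup, , drop = FALSE]
  }

  keep <- is.finite(d$z)
  log["bad_z"] <- sum(!keep)
  d <- d[keep, , drop = FALSE]

  ref <- reference
  m <- match(d$snp, ref$SNP)
  inref <- !is.na(m)
  log["not_in_reference"] <- sum(!inref)
  d <- d[inref, , drop = FALSE]
  m <- m[inref]
  refA1 <- toupper(ref$A1[m]); refA2 <- toupper(ref$A2[m])

  amb <- !is.na(.AMBIGUOUS[paste0(d$a1, d$a2)])
  log["strand_ambiguous"] <- sum(amb)
  d <- d[!amb, , drop = FALSE]; refA1 <- refA1[!amb]; refA2 <- refA2[!amb]

  same <- d$a1 == refA1 & d$a2 == refA2
  swap <- d$a1 == refA2 & d$a2 == refA1
  bad <- !(same | swap) |
    !(d$a1 %in% c("A", "C", "G", "T") & d$a2 %in% c("A", "C", "G", "T"))
  log["allele_mismatch"] <- sum(bad)
  d <- d[!bad, , drop = FALSE]
  swap <- swap[!bad]; refA1 <- refA1[!bad]; refA2 <- refA2[!bad]
  d$z[swap] <- -d$z[swap]
  d$a1 <- refA1; d$a2 <- refA2

  if (any(!is.na(d$maf))) {
    mafFail <- !is.na(d$maf) & d$maf < mafMin
    log["maf"] <- sum(mafFail)
    d <- d[!mafFail, , drop = FALSE]
  }
  if (hasInfo) {
    infoFail <- !is.na(d$info) & d$info < infoMin
    log["info"] <- sum(infoFail)
    d <- d[!infoFail, , drop = FALSE]
  } else {
    warning("no INFO column found; INFO filter skipped")
  }

  if (nrow(d) == 0L) stop("zero SNPs survive quality control")
  d$maf[is.na(d$maf)] <- 0.5   # absent MAF treated as common after QC

  ## order by reference for cross-trait comparability
  d <- d[order(match(d$snp, ref$SNP)), , drop = FALSE]
  rownames(d) <- NULL
  new("CleanedSumstats", records = d, trait = trait, log = log)
}

#' Write munged summary statistics
#'
#' Writes the fixed-column (SNP, A1, A2, Z, N) gzip-compressed table.
#' @param x a \code{\link{CleanedSumstats-class}}.
#' @param path output path; ".gz" appended if absent.
#' @return The path, invisibly.
#' @export
writeMunged <- function(x, path) {
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  out <- data.frame(SNP = x@records$snp, A1 = x@records$a1,
                    A2 = x@records$a2, Z = x@records$z, N = x@records$n)
  data.table::fwrite(out, path, sep = "\t", compress = "gzip")
  invisible(path)
}
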