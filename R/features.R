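# Per-scenario sequence features.
#
# All cut-site features are computed on the P-extended sequence in the
# "mirrored" orientation (V as stored; J reverse-complemented), in which
# trimming always removes nucleotides from the right end. With germline
# length L and deletion d, the cut falls after mirrored position c = L - d;
# motif positions -k (retained side) map to index c - k + 1 and +k (trimmed
# side) to index c + k. Indices outside [1, L + 2] are a padding level "X".

.motifPositions <- function(config) {
  c(
    if (config$motifUpstream > 0) paste0("m", config$motifUpstream:1),
    if (config$motifDownstream > 0) paste0("p", seq_len(config$motifDownstream))
  )
}

# Non-reference one-hot levels per motif position (A is the dropped
# reference; X is the out-of-bounds padding symbol).
.motifLevels <- c("C", "G", "T", "X")

.geneFeaturePrefix <- function(gene) tolower(gene@side)

.geneFeatureNames <- function(prefix, config) {
  pos <- .motifPositions(config)
  motif <- as.vector(t(outer(pos, .motifLevels, function(p, l) {
    paste0(prefix, "_motif_", p, "_", l)
  })))
  base <- paste0(prefix, "_", c(
    "fivep_gc", if (config$includeFivepAT) "fivep_at",
    "threep_at", "threep_gc"
  ))
  c(motif, base)
}

#' Feature names of the scenario feature vector
#'
#' The full, ordered feature registry for a given configuration: per gene
#' (prefix `v_` / `j_`) the trimming-motif one-hot indicators (positions
#' `m2`, `m1` retained-side and `p1` trimmed-side of the cut; levels C, G, T
#' with A as the dropped reference and X for out-of-bounds padding), the
#' base-count features (`fivep_gc`, `threep_at`, `threep_gc`, plus
#' `fivep_at` when `includeFivepAT` is set), and finally the two shared
#' microhomology features `mh_trim` (average microhomology of the trimmed
#' pair) and `mh_lig` (microhomology used in the ligation).
#'
#' @param config See [mhConfig()].
#' @return Character vector of feature names.
#' @export
mhFeatureNames <- function(config = mhConfig()) {
  config <- .asConfig(config)
  c(
    .geneFeatureNames("v", config), .geneFeatureNames("j", config),
    "mh_trim", "mh_lig"
  )
}

# Motif characters and base-count regions at one cut site.
.cutSite <- function(gene, d, config) {
  L <- nchar(gene@seq)
  mext <- .mirroredExt(gene)
  Lx <- L + 2L
  cpos <- L - as.integer(d)
  U <- config$motifUpstream
  D <- config$motifDownstream
  idx <- c(
    if (U > 0) cpos - (U:1) + 1L,
    if (D > 0) cpos + seq_len(D)
  )
  chars <- ifelse(idx >= 1L & idx <= Lx,
    substring(mext, idx, idx), "X"
  )
  span <- config$maxSpan
  fiveHi <- cpos - U
  fiveLo <- max(1L, if (is.finite(span)) fiveHi - as.integer(span) + 1L else 1L)
  threeLo <- cpos + D + 1L
  threeHi <- min(Lx, if (is.finite(span)) threeLo + as.integer(span) - 1L else Lx)
  fivep <- if (fiveHi >= fiveLo && fiveHi >= 1L) substr(mext, fiveLo, fiveHi) else ""
  threep <- if (threeHi >= threeLo && threeLo <= Lx) substr(mext, max(1L, threeLo), threeHi) else ""
  list(chars = chars, fivep = fivep, threep = threep)
}

.countGC <- function(s) nchar(gsub("[AT]", "", s))
.countAT <- function(s) nchar(gsub("[GC]", "", s))

.geneFeatureRow <- function(gene, d, config) {
  prefix <- .geneFeaturePrefix(gene)
  cut <- .cutSite(gene, d, config)
  pos <- .motifPositions(config)
  out <- numeric(0)
  for (i in seq_along(pos)) {
    ind <- as.numeric(.motifLevels == cut$chars[i])
    names(ind) <- paste0(prefix, "_motif_", pos[i], "_", .motifLevels)
    out <- c(out, ind)
  }
  base <- c(
    .countGC(cut$fivep),
    if (config$includeFivepAT) .countAT(cut$fivep),
    .countAT(cut$threep),
    .countGC(cut$threep)
  )
  names(base) <- paste0(prefix, "_", c(
    "fivep_gc", if (config$includeFivepAT) "fivep_at",
    "threep_at", "threep_gc"
  ))
  c(out, base)
}

#' Trimming-motif one-hot features at a cut site
#'
#' One-hot indicators for the nucleotides in the trimming-motif window
#' (default two retained-side and one trimmed-side position), read on the
#' P-extended sequence. Level A is the dropped reference (all indicators 0);
#' positions beyond the extended sequence take the padding level `X`.
#'
#' @param gene A [GermlineGene-class].
#' @param d Deletion value.
#' @param config See [mhConfig()].
#' @return Named numeric vector of indicators.
#' @examples
#' v <- germlineGene("toyV", "V", "CACAG")
#' motifFeatures(v, 2) # only v_motif_m1_C is 1
#' @export
motifFeatures <- function(gene, d, config = mhConfig()) {
  config <- .asConfig(config)
  row <- .geneFeatureRow(gene, d, config)
  row[grepl("_motif_", names(row))]
}

#' Base-count features beyond the trimming motif
#'
#' Raw AT and GC nucleotide counts 5' (retained side) and 3' (trimmed side)
#' of the trimming-motif window, computed on the P-extended sequence. The 5'
#' counts proxy sequence-breathing capacity upstream of the cut; the 3'
#' counts grow one-for-one with the deletion amount and therefore also encode
#' the absolute position of the trimming site. The 5' AT count is computed
#' only when `includeFivepAT` is enabled (the default model excludes it).
#'
#' @inheritParams motifFeatures
#' @return Named numeric vector of counts.
#' @examples
#' v <- germlineGene("toyV", "V", "CACAG")
#' baseCountFeatures(v, 2) # fivep_gc 1, threep_at 1, threep_gc 2
#' @export
baseCountFeatures <- function(gene, d, config = mhConfig()) {
  config <- .asConfig(config)
  row <- .geneFeatureRow(gene, d, config)
  row[!grepl("_motif_", names(row))]
}

#' Full feature vector of one scenario
#'
#' Concatenates both genes' motif and base-count features at their respective
#' cut sites with the two microhomology features: `mh_trim`, the average
#' microhomology over the ligation scenarios available to the trimmed pair
#' (a function of the trimming scenario only), and `mh_lig`, the number of
#' microhomologous nucleotides used in this scenario's ligation.
#'
#' @param delV,delJ Deletion values.
#' @param mh Ligation scenario (must be admissible for the trimmed pair).
#' @param v,j [GermlineGene-class] pair.
#' @param config See [mhConfig()].
#' @return Named numeric vector in [mhFeatureNames()] order.
#' @export
scenarioFeatures <- function(delV, delJ, mh, v, j, config = mhConfig()) {
  config <- .asConfig(config)
  tv <- trimGene(v, delV)
  tj <- trimGene(j, delJ)
  ms <- ligationScenarios(tv, tj)
  if (!(as.integer(mh) %in% ms)) {
    stop("inadmissible scenario: mh = ", mh, " not available at (",
      delV, ", ", delJ, ")",
      call. = FALSE
    )
  }
  c(
    .geneFeatureRow(v, delV, config), .geneFeatureRow(j, delJ, config),
    mh_trim = mean(ms), mh_lig = as.numeric(mh)
  )
}

# Feature matrix for a scenario table (expects an mh_trim column; used by
# buildChoiceSet, where per-deletion gene rows are shared across scenarios).
.choiceSetFeatures <- function(v, j, sc, config) {
  gridV <- sort(unique(sc$del_v))
  gridJ <- sort(unique(sc$del_j))
  rowsV <- t(vapply(gridV, function(d) .geneFeatureRow(v, d, config),
    numeric(length(.geneFeatureNames("v", config)))
  ))
  rowsJ <- t(vapply(gridJ, function(d) .geneFeatureRow(j, d, config),
    numeric(length(.geneFeatureNames("j", config)))
  ))
  m <- cbind(
    rowsV[match(sc$del_v, gridV), , drop = FALSE],
    rowsJ[match(sc$del_j, gridJ), , drop = FALSE],
    mh_trim = sc$mh_trim,
    mh_lig = as.numeric(sc$mh)
  )
  colnames(m) <- mhFeatureNames(config)
  rownames(m) <- NULL
  m
}

#' Standardize a feature matrix
#'
#' Centers and scales each column to mean 0 and (population) standard
#' deviation 1 across all scenario rows pooled over choice sets, so that
#' coefficient magnitudes of a model fitted on the result directly reflect
#' relative feature importance. Zero-variance columns are dropped with a
#' warning. The returned statistics can be re-applied to held-out data with
#' [applyStandardization()].
#'
#' @param mat Numeric feature matrix (>= 2 rows).
#' @return `list(matrix, stats)` where `stats` has `mean`, `sd` and the kept
#'   column names.
#' @export
standardizeFeatures <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L)
  mu <- colMeans(mat)
  sdev <- sqrt(colMeans(sweep(mat, 2L, mu)^2))
  keep <- sdev > 0
  if (any(!keep)) {
    warning(
      "dropping zero-variance feature(s): ",
      paste(colnames(mat)[!keep], collapse = ", ")
    )
  }
  stats <- list(mean = mu[keep], sd = sdev[keep], features = colnames(mat)[keep])
  list(matrix = applyStandardization(mat, stats), stats = stats)
}

#' @describeIn standardizeFeatures Apply stored standardization statistics to
#'   a (new) feature matrix; columns are subset to the kept features.
#' @param stats The `stats` element returned by [standardizeFeatures()].
#' @export
applyStandardization <- function(mat, stats) {
  m <- mat[, stats$features, drop = FALSE]
  sweep(sweep(m, 2L, stats$mean), 2L, stats$sd, `/`)
}
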