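# Two-step conditional logit on the base-10 odds scale.

.LN10 <- log(10)

.logSumExp <- function(x) {
  a <- max(x)
  a + log(sum(exp(x - a)))
}

#' Construct a parameter vector
#'
#' Builds a [ParameterVector-class] from named log10-odds coefficients. Any
#' feature of the registry not named in `beta` gets coefficient 0. `mh_lig`
#' is the (single) ligation-step coefficient; everything else belongs to the
#' trimming step. Excluded microhomology terms (via the flags) are pinned at
#' zero.
#'
#' @param beta Named numeric vector of coefficients (subset of
#'   [mhFeatureNames()]).
#' @param includeMHTrim,includeMHLig Whether the `mh_trim` / `mh_lig` terms
#'   are part of the model.
#' @param config See [mhConfig()].
#' @return A [ParameterVector-class].
#' @examples
#' p <- mhParameters(c(mh_trim = 0.45, mh_lig = 0.13))
#' coef(p)[c("mh_trim", "mh_lig")]
#' @export
mhParameters <- function(beta = numeric(0), includeMHTrim = TRUE,
                         includeMHLig = TRUE, config = mhConfig()) {
  registry <- mhFeatureNames(config)
  if (length(beta)) {
    if (is.null(names(beta)) || !all(names(beta) %in% registry)) {
      bad <- setdiff(names(beta), registry)
      stop("unknown feature name(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  full <- stats::setNames(numeric(length(registry)), registry)
  full[names(beta)] <- beta
  if (!includeMHTrim) full["mh_trim"] <- 0
  if (!includeMHLig) full["mh_lig"] <- 0
  new("ParameterVector",
    betaTrim = full[setdiff(registry, "mh_lig")],
    betaLig = full["mh_lig"],
    includeMHTrim = isTRUE(includeMHTrim),
    includeMHLig = isTRUE(includeMHLig)
  )
}

#' @describeIn mhParameters Combined named coefficient vector (trimming then
#'   ligation terms).
#' @param object A [ParameterVector-class].
#' @param ... Ignored.
#' @export
setMethod("coef", "ParameterVector", function(object, ...) {
  c(object@betaTrim, object@betaLig)
})

# Names of the coefficients that are free parameters of the model variant.
.activeNames <- function(params) {
  nm <- names(coef(params))
  if (!params@includeMHTrim) nm <- setdiff(nm, "mh_trim")
  if (!params@includeMHLig) nm <- setdiff(nm, "mh_lig")
  nm
}

# Full coefficient vector aligned to a feature-name registry.
.alignBeta <- function(params, featNames) {
  b <- coef(params)
  if (!all(featNames %in% names(b)) || !all(names(b) %in% featNames)) {
    stop("schema error: parameter names do not match the feature registry",
      call. = FALSE
    )
  }
  b[featNames]
}

#' Linear predictor of one or more scenarios
#'
#' The scenario score is the linear predictor
#' `eta = beta_trim . f_trim + beta_lig . f_lig` on the log10 scale; the
#' unnormalized choice weight is `10^eta`. A coefficient of `b` therefore
#' multiplies a scenario's odds by `10^b` per unit of feature.
#'
#' @param features Named numeric vector, or matrix with feature columns.
#' @param params A [ParameterVector-class].
#' @return Numeric score(s) on the log10 scale.
#' @examples
#' p <- mhParameters(c(mh_lig = 0.1272))
#' scenarioScore(c(mh_lig = 2), p) # 0.2544
#' @export
scenarioScore <- function(features, params) {
  stopifnot(is(params, "ParameterVector"))
  b <- coef(params)
  if (is.matrix(features)) {
    if (!all(colnames(features) %in% names(b))) {
      stop("schema error: unknown feature column(s)", call. = FALSE)
    }
    return(as.numeric(features %*% b[colnames(features)]))
  }
  if (is.null(names(features)) || !all(names(features) %in% names(b))) {
    stop("schema error: features must be named with registry names", call. = FALSE)
  }
  sum(b[names(features)] * features)
}

#' Joint scenario distribution over a choice set
#'
#' Computes `P(delVJ, MH | VJ, Q) = 10^eta(s) / sum(10^eta(s'))` over the
#' productivity-restricted choice set (log-sum-exp stabilized), together with
#' its factorization: the trimming marginal `P(delVJ | VJ, Q)` (sum over
#' ligation scenarios) and the ligation conditional `P(MH | delVJ, VJ, Q)`,
#' computed from the ligation term alone and normalized within each trimming
#' scenario's productivity-consistent ligation options. Because productivity
#' conditioning is realized as choice-set restriction before normalization,
#' the product of the two factors reproduces the joint exactly.
#'
#' @param cs A [ChoiceSet-class].
#' @param params A [ParameterVector-class].
#' @return A [ScenarioDistribution-class].
#' @examples
#' v <- germlineGene("toyV", "V", "CACAG")
#' j <- germlineGene("toyJ", "J", "AGGTA")
#' cs <- buildChoiceSet(v, j, "non-productive")
#' d <- jointDistribution(cs, mhParameters(c(mh_lig = log10(2))))
#' sum(scenarioProbs(d)) # 1
#' @export
jointDistribution <- function(cs, params) {
  stopifnot(is(cs, "ChoiceSet"), is(params, "ParameterVector"))
  F <- cs@features
  if (nrow(F) == 0L) {
    stop("empty choice set", call. = FALSE)
  }
  beta <- .alignBeta(params, colnames(F))
  etaN <- .LN10 * as.numeric(F %*% beta)
  p <- exp(etaN - .logSumExp(etaN))
  p <- p / sum(p)

  sc <- cs@scenarios
  grp <- interaction(sc$del_v, sc$del_j, drop = TRUE)
  margP <- as.numeric(tapply(p, grp, sum))
  margKey <- !duplicated(grp)
  trimMarginal <- data.frame(
    del_v = sc$del_v[margKey], del_j = sc$del_j[margKey],
    prob = margP[match(grp[margKey], levels(grp))]
  )
  # Ligation conditional from the ligation term alone.
  etaLig <- .LN10 * as.numeric(F[, "mh_lig"] * beta["mh_lig"])
  wLig <- exp(etaLig - max(etaLig))
  denom <- as.numeric(tapply(wLig, grp, sum))[as.integer(grp)]
  ligConditional <- wLig / denom

  new("ScenarioDistribution",
    choiceSet = cs, prob = p,
    trimMarginal = trimMarginal, ligConditional = ligConditional
  )
}

#' @describeIn jointDistribution Joint probability per scenario row.
#' @param x A [ScenarioDistribution-class].
#' @export
setMethod("scenarioProbs", "ScenarioDistribution", function(x) x@prob)

#' @describeIn jointDistribution The trimming marginal `P(delVJ | VJ, Q)`.
#' @param dist A [ScenarioDistribution-class].
#' @export
trimmingMarginal <- function(dist) {
  stopifnot(is(dist, "ScenarioDistribution"))
  dist@trimMarginal
}

#' @describeIn jointDistribution The ligation conditional `P(MH | delVJ)`
#'   aligned with scenario rows.
#' @export
ligationConditional <- function(dist) {
  stopifnot(is(dist, "ScenarioDistribution"))
  dist@ligConditional
}

#' Likelihood of one observed sequence
#'
#' The observed-data likelihood contribution of a zero-N-insertion sequence:
#' the sum of the joint scenario probabilities over its annotation set.
#'
#' @param ax An [AnnotationSet-class].
#' @param dist A [ScenarioDistribution-class] over the same choice set.
#' @return A probability in (0, 1\].
#' @export
sequenceLikelihood <- function(ax, dist) {
  stopifnot(is(ax, "AnnotationSet"), is(dist, "ScenarioDistribution"))
  scA <- ax@choiceSet@scenarios
  scD <- dist@choiceSet@scenarios
  if (nrow(scA) != nrow(scD) || !identical(scA$junction, scD$junction)) {
    stop("annotation set and distribution refer to different choice sets",
      call. = FALSE
    )
  }
  sum(dist@prob[ax@indices])
}

#' Empirical conditional scenario probabilities
#'
#' Relative frequency of each scenario within one (VJ, Q, I = 0) stratum:
#' the scenario count divided by the stratum total. Counts may be fractional
#' (latent annotations split a sequence's count across its annotation set).
#'
#' @param counts Non-negative numeric vector of scenario counts.
#' @param total Positive stratum total.
#' @return Numeric probabilities summing to `sum(counts) / total`.
#' @export
empiricalPdf <- function(counts, total) {
  if (length(total) != 1L || !is.finite(total) || total <= 0) {
    stop("undefined stratum: total count must be positive", call. = FALSE)
  }
  stopifnot(all(counts >= 0))
  counts / total
}

#' Percent change in odds per unit of feature
#'
#' Converts a log10-odds coefficient `b` to the percent increase in the odds
#' of a scenario per unit increase of its feature: `100 * (10^b - 1)`,
#' rounded for reporting.
#'
#' @param beta Coefficient(s) on the log10-odds scale.
#' @param digits Rounding digits (default 0, i.e. whole percent).
#' @return Percent change(s).
#' @examples
#' oddsPercent(0.4484) # 181
#' oddsPercent(0.1272) # 34
#' @export
oddsPercent <- function(beta, digits = 0) {
  round(100 * (10^beta - 1), digits)
}

# Per-choice-set distributions for a RepertoireData object.
.dataDistributions <- function(data, params) {
  lapply(data@choiceSets, jointDistribution, params = params)
}

# Per-unit observed likelihoods.
.unitLikelihoods <- function(data, params) {
  dists <- .dataDistributions(data, params)
  vapply(seq_len(nrow(data@units)), function(i) {
    p <- dists[[data@units$cs_key[i]]]@prob
    sum(p[data@ax[[i]]])
  }, numeric(1))
}

#' Expected per-sequence log loss
#'
#' Minus the mean natural-log likelihood of the observed sequences under the
#' model: `-(1/N) * sum(log sequenceLikelihood)`. Lower is better; a model
#' assigning likelihood 1 to every sequence scores 0. Likelihoods are clipped
#' at 1e-300 before the log; if any clip occurs the result carries attribute
#' `degenerate = TRUE`.
#'
#' @param data A [RepertoireData-class].
#' @param params A [ParameterVector-class].
#' @return Per-sequence log loss (natural-log scale).
#' @export
evalLogLoss <- function(data, params) {
  stopifnot(is(data, "RepertoireData"))
  lik <- .unitLikelihoods(data, params)
  degenerate <- any(lik < 1e-300)
  lik <- pmax(lik, 1e-300)
  out <- -sum(data@units$count * log(lik)) / data@nSequences
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}

#' Mean absolute error against the empirical scenario distribution
#'
#' Compares model scenario probabilities to an empirical reference within
#' each (VJ, Q) stratum and averages the absolute errors over all scenarios
#' of all retained strata. Because the true annotation of each sequence is
#' latent, the empirical reference splits each sequence's count uniformly
#' across its annotation set (a deterministic, model-independent choice).
#' Strata with fewer than `minCount` sequences are excluded (with a message
#' naming how many).
#'
#' @param data A [RepertoireData-class].
#' @param params A [ParameterVector-class].
#' @param minCount Minimum sequences per stratum (default from the data's
#'   config, normally 10).
#' @return Mean absolute error.
#' @export
evalMAE <- function(data, params, minCount = NULL) {
  stopifnot(is(data, "RepertoireData"))
  if (is.null(minCount)) minCount <- data@config$minStratumCount
  errs <- numeric(0)
  skipped <- 0L
  for (key in names(data@choiceSets)) {
    rows <- which(data@units$cs_key == key)
    mass <- sum(data@units$count[rows])
    if (mass < minCount) {
      skipped <- skipped + 1L
      next
    }
    cs <- data@choiceSets[[key]]
    emp <- numeric(nrow(cs@scenarios))
    for (i in rows) {
      idx <- data@ax[[i]]
      emp[idx] <- emp[idx] + data@units$count[i] / length(idx)
    }
    emp <- empiricalPdf(emp, mass)
    mod <- jointDistribution(cs, params)@prob
    errs <- c(errs, abs(mod - emp))
  }
  if (!length(errs)) {
    stop("no stratum meets the minimum count of ", minCount, call. = FALSE)
  }
  if (skipped > 0L) {
    message(skipped, " stratum/strata below the minimum count were excluded")
  }
  mean(errs)
}

#' Write / read model parameters as JSON
#'
#' Serializes a [ParameterVector-class] (coefficient names and values on the
#' log10-odds scale, plus the microhomology inclusion flags) to JSON, and
#' back.
#'
#' @param params A [ParameterVector-class].
#' @param path File path.
#' @return `readParametersJSON` returns a [ParameterVector-class];
#'   `writeParametersJSON` returns `path` invisibly.
#' @export
writeParametersJSON <- function(params, path) {
  stopifnot(is(params, "ParameterVector"))
  obj <- list(
    scale = "log10_odds",
    coefficients = as.list(coef(params)),
    include_mh_trim = params@includeMHTrim,
    include_mh_lig = params@includeMHLig
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeParametersJSON
#' @export
readParametersJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mhParameters(
    beta = unlist(obj$coefficients),
    includeMHTrim = isTRUE(obj$include_mh_trim),
    includeMHLig = isTRUE(obj$include_mh_lig)
  )
}
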