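# Per-sequence annotation probabilities and model-to-model comparisons.

# Deterministic top pick among annotation rows: maximum posterior, ties
# (within 1e-12) broken toward higher mh, then smaller total trim, then
# enumeration order.
.topAnnotation <- function(prob, sc) {
  cand <- which(prob >= max(prob) - 1e-12)
  if (length(cand) > 1L) {
    cand <- cand[sc$mh[cand] == max(sc$mh[cand])]
  }
  if (length(cand) > 1L) {
    tot <- sc$del_v[cand] + sc$del_j[cand]
    cand <- cand[tot == min(tot)]
  }
  cand[1]
}

#' Posterior annotation probabilities for one sequence
#'
#' The normalized probability of each annotation in the sequence's
#' annotation set: the joint scenario probabilities restricted to the set
#' and renormalized (the choice-set normalizer cancels, so only the relative
#' scenario weights matter). The top-ranked annotation uses a deterministic
#' tie-break: maximum probability, then higher `mh`, then smaller
#' `del_v + del_j`, then enumeration order.
#'
#' @param ax An [AnnotationSet-class].
#' @param params A [ParameterVector-class].
#' @return A list with `annotations` (the annotation table plus a `prob`
#'   column), `top` (row index of the top annotation within that table), and
#'   `multiple` (`TRUE` when the set has more than one annotation).
#' @examples
#' v <- germlineGene("toyV", "V", "CACAG")
#' j <- germlineGene("toyJ", "J", "AGGTA")
#' ax <- enumerateAnnotations("CACAGGTA", v, j)
#' r <- annotationPosteriors(ax, mhParameters(c(mh_lig = log10(2))))
#' r$annotations$prob # proportional to 1,2,4,1,2,1
#' @export
annotationPosteriors <- function(ax, params) {
  stopifnot(is(ax, "AnnotationSet"), is(params, "ParameterVector"))
  F <- ax@choiceSet@features[ax@indices, , drop = FALSE]
  beta <- .alignBeta(params, colnames(F))
  eta <- .LN10 * as.numeric(F %*% beta)
  p <- exp(eta - .logSumExp(eta))
  p <- p / sum(p)
  ann <- annotations(ax)
  ann$prob <- p
  list(
    annotations = ann,
    top = .topAnnotation(p, ann),
    multiple = nrow(ann) > 1L
  )
}

#' Compare annotation rankings under two parameterizations
#'
#' Ranks every sequence's annotations under two models (typically the full
#' microhomology model and the no-microhomology variant) and summarizes how
#' the parameterization changes the top-ranked annotation. Per sequence the
#' comparison records whether the top annotation flips and the relative
#' confidence under each model, defined as the absolute difference of that
#' model's probabilities for the two models' top annotations. Aggregates
#' (all count-weighted) include the fraction of sequences with a single
#' possible annotation, the flip fraction among all and among
#' multi-annotation sequences, the mean relative confidence among flipped
#' sequences, and per-gene-pair flip proportions with the pair's mean
#' per-sequence average microhomology across potential annotations.
#'
#' @param data A [RepertoireData-class].
#' @param paramsMH,paramsNoMH Two [ParameterVector-class] objects sharing the
#'   feature schema.
#' @return A list with `units` (per-unit comparison table), `perPair`
#'   (per-gene-pair flip proportion and mean average microhomology), and the
#'   scalar aggregates `fracSingle`, `fracFlipped`, `fracFlippedMulti`,
#'   `meanRelConfMHFlipped`.
#' @export
compareModels <- function(data, paramsMH, paramsNoMH) {
  stopifnot(is(data, "RepertoireData"))
  nu <- nrow(data@units)
  topMH <- topNo <- integer(nu)
  relMH <- relNo <- numeric(nu)
  multiple <- logical(nu)
  meanMH <- numeric(nu)
  for (i in seq_len(nu)) {
    ax <- unitAnnotationSet(data, i)
    rMH <- annotationPosteriors(ax, paramsMH)
    rNo <- annotationPosteriors(ax, paramsNoMH)
    topMH[i] <- rMH$top
    topNo[i] <- rNo$top
    relMH[i] <- abs(rMH$annotations$prob[rMH$top] - rMH$annotations$prob[rNo$top])
    relNo[i] <- abs(rNo$annotations$prob[rMH$top] - rNo$annotations$prob[rNo$top])
    multiple[i] <- rMH$multiple
    meanMH[i] <- mean(rMH$annotations$mh)
  }
  flipped <- topMH != topNo
  cnt <- data@units$count
  n <- data@nSequences
  pairKey <- sub("\\|\\|[^|]*$", "", data@units$cs_key)

  units <- data.frame(
    cs_key = data@units$cs_key,
    junction = data@units$junction,
    count = cnt,
    multiple = multiple,
    top_mh_model = topMH,
    top_nomh_model = topNo,
    flipped = flipped,
    rel_conf_mh = relMH,
    rel_conf_nomh = relNo,
    mean_avg_mh = meanMH
  )
  perPair <- do.call(rbind, lapply(split(seq_len(nu), pairKey), function(ix) {
    data.frame(
      pair = pairKey[ix[1]],
      n = sum(cnt[ix]),
      flip_prop = sum(cnt[ix] * flipped[ix]) / sum(cnt[ix]),
      mean_avg_mh = sum(cnt[ix] * meanMH[ix]) / sum(cnt[ix])
    )
  }))
  rownames(perPair) <- NULL
  nMulti <- sum(cnt[multiple])
  nFlip <- sum(cnt[flipped])
  list(
    units = units,
    perPair = perPair,
    fracSingle = sum(cnt[!multiple]) / n,
    fracFlipped = nFlip / n,
    fracFlippedMulti = if (nMulti > 0) nFlip / nMulti else NA_real_,
    meanRelConfMHFlipped = if (nFlip > 0) {
      sum(cnt[flipped] * relMH[flipped]) / nFlip
    } else {
      NA_real_
    }
  )
}

#' Correlation between per-pair flip proportion and microhomology content
#'
#' Pearson correlation, across gene pairs, between the proportion of
#' sequences whose top-ranked annotation differs between the two models and
#' the pair's mean per-sequence average microhomology across potential
#' annotations; the p-value comes from the t-distribution transform of r.
#'
#' @param comparison Output of [compareModels()].
#' @return `list(r, p, nPairs)`; `r` is `NA` (with a message) when fewer
#'   than 3 pairs have defined values or either vector has zero variance.
#' @export
pairFlipCorrelation <- function(comparison) {
  pp <- comparison$perPair
  ok <- is.finite(pp$flip_prop) & is.finite(pp$mean_avg_mh)
  pp <- pp[ok, , drop = FALSE]
  if (nrow(pp) < 3L ||
    stats::sd(pp$flip_prop) == 0 || stats::sd(pp$mean_avg_mh) == 0) {
    message("correlation undefined: need >= 3 gene pairs with variation in ",
      "both flip proportion and microhomology content")
    return(list(r = NA_real_, p = NA_real_, nPairs = nrow(pp)))
  }
  ct <- stats::cor.test(pp$flip_prop, pp$mean_avg_mh, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, nPairs = nrow(pp))
}
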