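# Uncertainty quantification and hypothesis tests for fitted models.

#' Bootstrap standard errors of the fitted coefficients
#'
#' Nonparametric bootstrap with observed sequences as the sampling unit:
#' each replicate resamples the `n` sequences with replacement (a multinomial
#' redraw of the per-unit counts), refits the model warm-started from the
#' point estimate, and the standard error of each active coefficient is the
#' sample standard deviation of the replicate estimates. All randomness goes
#' through `seed`, so reruns are byte-identical.
#'
#' @param data The [RepertoireData-class] the model was fitted on.
#' @param fit The point-estimate [MHFitResult-class] (provides the model
#'   variant and the warm start).
#' @param B Number of bootstrap replicates (the study-scale default is 1000;
#'   use fewer for exploratory work).
#' @param seed Integer RNG seed.
#' @param maxIter EM iteration cap per replicate (warm starts converge
#'   quickly).
#' @param maxRetry Failed replicate fits are logged and redrawn at most this
#'   many times each.
#' @return Named numeric vector of standard errors for the active
#'   coefficients, with the `B x p` matrix of replicate estimates attached as
#'   attribute `"estimates"`.
#' @export
bootstrapSE <- function(data, fit, B = 1000L, seed = 1L, maxIter = 25L,
                        maxRetry = 5L) {
  stopifnot(is(data, "RepertoireData"), is(fit, "MHFitResult"), B >= 2L)
  set.seed(seed)
  point <- modelParameters(fit)
  active <- .activeNames(point)
  n <- data@nSequences
  prob <- data@units$count / n
  est <- matrix(NA_real_, B, length(active), dimnames = list(NULL, active))
  nFlagged <- 0L
  for (b in seq_len(B)) {
    tries <- 0L
    repeat {
      tries <- tries + 1L
      countsB <- as.numeric(stats::rmultinom(1L, n, prob))
      dataB <- data
      dataB@units$count <- countsB
      dataB@nSequences <- as.integer(sum(countsB))
      # Resamples can lose all support for a rare one-hot level, whose
      # coefficient then runs away (separation); the per-fit flag is
      # expected here, so count it rather than warn B times.
      fitB <- tryCatch(
        withCallingHandlers(
          fitEM(dataB,
            includeMHTrim = point@includeMHTrim,
            includeMHLig = point@includeMHLig,
            maxIter = maxIter, init = point
          ),
          warning = function(w) {
            if (grepl("magnitude exceeds", conditionMessage(w))) {
              nFlagged <<- nFlagged + 1L
              invokeRestart("muffleWarning")
            }
          }
        ),
        error = function(e) e
      )
      if (!inherits(fitB, "error")) break
      message("bootstrap replicate ", b, " failed (", conditionMessage(fitB),
        "); redrawing")
      if (tries > maxRetry) {
        stop("bootstrap replicate ", b, " failed ", maxRetry,
          " times; aborting",
          call. = FALSE
        )
      }
    }
    est[b, ] <- coef(fitB)[active]
  }
  se <- apply(est, 2L, stats::sd)
  attr(se, "estimates") <- est
  attr(se, "nFlagged") <- nFlagged
  se
}

#' Wald tests of individual coefficients
#'
#' For each coefficient, `T = estimate / se` is compared with N(0, 1) to
#' give a two-sided p-value, and significance is called at the
#' Bonferroni-corrected threshold `alpha / nParams` (the total number of
#' model parameters). A zero standard error leaves the statistic and p-value
#' undefined (`NA`).
#'
#' @param estimates Named numeric vector of coefficient estimates.
#' @param ses Standard errors (same names/order).
#' @param alpha Family-wise level (default 0.05).
#' @param nParams Number of parameters adjusted for (default
#'   `length(estimates)`).
#' @return A data.frame with columns `parameter`, `estimate`, `se`,
#'   `statistic`, `p_value`, `significant`; the Bonferroni threshold is
#'   attached as attribute `"threshold"`.
#' @examples
#' waldTests(c(mh_trim = 0.4), c(mh_trim = 0.2))
#' @export
waldTests <- function(estimates, ses, alpha = 0.05, nParams = length(estimates)) {
  stopifnot(length(estimates) == length(ses), nParams >= 1L)
  tstat <- ifelse(ses > 0, estimates / ses, NA_real_)
  p <- 2 * stats::pnorm(-abs(tstat))
  threshold <- alpha / nParams
  out <- data.frame(
    parameter = if (!is.null(names(estimates))) {
      names(estimates)
    } else {
      paste0("b", seq_along(estimates))
    },
    estimate = as.numeric(estimates),
    se = as.numeric(ses),
    statistic = as.numeric(tstat),
    p_value = as.numeric(p),
    significant = ifelse(is.na(p), NA, p < threshold),
    row.names = NULL
  )
  attr(out, "threshold") <- threshold
  out
}

#' Likelihood ratio test of nested model variants
#'
#' `LR = 2 * (logLik(full) - logLik(reduced))`, referred to a chi-square
#' distribution with degrees of freedom equal to the number of extra
#' parameters in the full model (2 when both microhomology terms are added).
#' Both fits must come from the same data; a reduced-model likelihood above
#' the full model's beyond numerical tolerance is a nesting violation and an
#' error.
#'
#' @param fitFull,fitReduced [MHFitResult-class] objects with nested active
#'   coefficient sets, fitted on identical data.
#' @return `list(LR, df, p)`.
#' @examples
#' # LR = 20 on 2 df has p = exp(-10)
#' stats::pchisq(20, 2, lower.tail = FALSE)
#' @export
lrtTest <- function(fitFull, fitReduced) {
  stopifnot(is(fitFull, "MHFitResult"), is(fitReduced, "MHFitResult"))
  aF <- .activeNames(modelParameters(fitFull))
  aR <- .activeNames(modelParameters(fitReduced))
  if (!all(aR %in% aF)) {
    stop("models are not nested: reduced-model parameters must be a subset ",
      "of the full model's",
      call. = FALSE
    )
  }
  llF <- logLik(fitFull)
  llR <- logLik(fitReduced)
  LR <- 2 * (llF - llR)
  # Both fits stop at a relative log-likelihood tolerance, so an apparent
  # violation within that optimization slack is numerical, not structural;
  # it is clamped to 0. Anything larger indicates a genuine defect.
  if (LR < -1e-4 * max(1, abs(llF))) {
    stop("nesting violation: reduced model has higher likelihood (LR = ",
      signif(LR, 4), ")",
      call. = FALSE
    )
  }
  LR <- max(LR, 0)
  df <- length(aF) - length(aR)
  p <- if (df == 0L) {
    if (LR <= .Machine$double.eps^0.5) 1 else 0
  } else {
    stats::pchisq(LR, df = df, lower.tail = FALSE)
  }
  list(LR = LR, df = df, p = p)
}
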