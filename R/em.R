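# EM fitting of the two-step conditional logit with latent annotations.
#
# Internally the model is grouped by choice set: every sequence whose
# (V, J, Q, junction) matches shares the same annotation set, so the E-step
# aggregates responsibilities into one weight vector per choice set and the
# M-step is a weighted conditional-logit fit over full choice sets.

# Grouped view of a RepertoireData object.
.emState <- function(data) {
  keys <- names(data@choiceSets)
  F <- lapply(data@choiceSets, featureMatrix)
  byCs <- lapply(keys, function(k) which(data@units$cs_key == k))
  names(byCs) <- keys
  list(
    keys = keys, F = F, byCs = byCs,
    ax = data@ax, count = data@units$count, n = data@nSequences
  )
}

.stateEta <- function(state, beta) {
  lapply(state$F, function(F) .LN10 * as.numeric(F %*% beta))
}

# Observed-data log-likelihood (natural log) at a full coefficient vector.
.stateLogLik <- function(state, etaAll) {
  ll <- 0
  for (k in state$keys) {
    eta <- etaAll[[k]]
    lz <- .logSumExp(eta)
    for (i in state$byCs[[k]]) {
      ll <- ll + state$count[i] * (.logSumExp(eta[state$ax[[i]]]) - lz)
    }
  }
  ll
}

# Aggregated responsibilities: one weight vector per choice set with total
# mass equal to the number of sequences using that choice set.
.stateResp <- function(state, etaAll) {
  r <- lapply(state$F, function(F) numeric(nrow(F)))
  for (k in state$keys) {
    eta <- etaAll[[k]]
    for (i in state$byCs[[k]]) {
      idx <- state$ax[[i]]
      w <- exp(eta[idx] - max(eta[idx]))
      s <- sum(w)
      if (!is.finite(s) || s <= 0) {
        stop("degenerate model: zero posterior mass on an annotation set",
          call. = FALSE
        )
      }
      r[[k]][idx] <- r[[k]][idx] + state$count[i] * w / s
    }
  }
  r
}

#' Weighted conditional-logit fit over full choice sets
#'
#' Maximizes `sum_c [ sum_s r_c(s) * log P(s | c; beta) ]` where each choice
#' set `c` has feature matrix `features[[c]]`, non-negative scenario weights
#' `weights[[c]]` (total mass = number of sequences on that choice set), and
#' `P(s | c; beta)` is the base-10 conditional logit. This is the M-step
#' workhorse, exposed directly because it is a useful primitive (with
#' singleton weights it is an ordinary conditional-logit fit). Optimization
#' is quasi-Newton (BFGS) with the analytic gradient.
#'
#' @param features List of numeric matrices with identical column names.
#' @param weights List of numeric vectors, `weights[[i]]` of length
#'   `nrow(features[[i]])`.
#' @param init Optional named starting values (default all zero).
#' @param activeCols Columns to optimize over (default all); the rest stay 0
#'   (or at their `init` value).
#' @param maxit,reltol `stats::optim` control.
#' @return `list(beta, objective, converged, flagged)`: the full named
#'   coefficient vector, the attained weighted log-likelihood (natural log),
#'   the optimizer convergence flag, and whether any |coefficient| exceeded
#'   50 (a separation guard).
#' @examples
#' F <- matrix(c(1, 0), 2, 1, dimnames = list(NULL, "x"))
#' fit <- conditionalLogitFit(list(F), list(c(0.8, 0.2)))
#' fit$beta # log10(4)
#' @export
conditionalLogitFit <- function(features, weights, init = NULL,
                                activeCols = NULL, maxit = 500,
                                reltol = 1e-12) {
  stopifnot(length(features) == length(weights), length(features) >= 1L)
  featNames <- colnames(features[[1]])
  if (is.null(featNames)) {
    featNames <- paste0("f", seq_len(ncol(features[[1]])))
  }
  if (is.null(activeCols)) activeCols <- featNames
  stopifnot(all(activeCols %in% featNames))
  beta0 <- stats::setNames(numeric(length(featNames)), featNames)
  if (!is.null(init)) beta0[names(init)] <- init

  Fa <- lapply(features, function(F) F[, activeCols, drop = FALSE])
  mass <- vapply(weights, sum, numeric(1))
  S <- Reduce(`+`, Map(function(F, w) as.numeric(crossprod(F, w)), Fa, weights))
  # Inactive coefficients stay fixed at their init value; they shift the
  # linear predictor (and add a constant to the objective) but are not
  # optimized.
  fixed <- setdiff(featNames, activeCols)
  fixedOn <- length(fixed) > 0L && any(beta0[fixed] != 0)
  fixedEta <- lapply(features, function(F) {
    if (fixedOn) {
      .LN10 * as.numeric(F[, fixed, drop = FALSE] %*% beta0[fixed])
    } else {
      numeric(nrow(F))
    }
  })
  fixedS <- if (fixedOn) {
    sum(unlist(Map(function(e, w) sum(e * w), fixedEta, weights)))
  } else {
    0
  }

  negLL <- function(bA) {
    tot <- 0
    for (i in seq_along(Fa)) {
      eta <- .LN10 * as.numeric(Fa[[i]] %*% bA) + fixedEta[[i]]
      tot <- tot + mass[i] * .logSumExp(eta)
    }
    -(.LN10 * sum(S * bA) + fixedS - tot)
  }
  negGrad <- function(bA) {
    G <- numeric(length(bA))
    for (i in seq_along(Fa)) {
      eta <- .LN10 * as.numeric(Fa[[i]] %*% bA) + fixedEta[[i]]
      p <- exp(eta - .logSumExp(eta))
      G <- G + mass[i] * as.numeric(crossprod(Fa[[i]], p))
    }
    -(.LN10 * (S - G))
  }

  opt <- stats::optim(beta0[activeCols], negLL, negGrad,
    method = "BFGS",
    control = list(maxit = maxit, reltol = reltol)
  )
  if (opt$convergence != 0 && opt$convergence != 1) {
    stop("M-step optimizer failed (code ", opt$convergence, "): ",
      opt$message,
      call. = FALSE
    )
  }
  beta <- beta0
  beta[activeCols] <- opt$par
  flagged <- any(abs(opt$par) > 50)
  if (flagged) {
    warning("coefficient magnitude exceeds 50; possible separation/unbounded direction")
  }
  list(
    beta = beta, objective = -opt$value,
    converged = opt$convergence == 0, flagged = flagged
  )
}

#' E-step: posterior responsibilities over annotation sets
#'
#' For each unit (unique junction within its choice set), the posterior
#' probability of each annotation given the current parameters:
#' `w(s) = P(s | VJ, Q; params) / sum over the annotation set`. With all-zero
#' parameters the responsibilities are uniform; a singleton annotation set
#' always gets responsibility 1.
#'
#' @param data A [RepertoireData-class].
#' @param params A [ParameterVector-class].
#' @return List (class `"Responsibilities"`) of numeric vectors parallel to
#'   the units, each summing to 1 over the unit's annotation set.
#' @export
eStep <- function(data, params) {
  stopifnot(is(data, "RepertoireData"), is(params, "ParameterVector"))
  state <- .emState(data)
  beta <- .alignBeta(params, colnames(state$F[[1]]))
  etaAll <- .stateEta(state, beta)
  out <- vector("list", nrow(data@units))
  for (k in state$keys) {
    eta <- etaAll[[k]]
    for (i in state$byCs[[k]]) {
      idx <- state$ax[[i]]
      w <- exp(eta[idx] - max(eta[idx]))
      out[[i]] <- w / sum(w)
    }
  }
  class(out) <- "Responsibilities"
  out
}

#' Expected complete-data log-likelihood
#'
#' The EM surrogate objective
#' `sum_i sum_s w_i(s) log P(s | VJ_i, Q_i; params)` (natural log), with
#' responsibilities held fixed. The M-step maximizes this in `params`.
#'
#' @param data A [RepertoireData-class].
#' @param resp Responsibilities from [eStep()].
#' @param params A [ParameterVector-class].
#' @return Scalar objective value.
#' @export
emObjective <- function(data, resp, params) {
  state <- .emState(data)
  beta <- .alignBeta(params, colnames(state$F[[1]]))
  etaAll <- .stateEta(state, beta)
  tot <- 0
  for (k in state$keys) {
    eta <- etaAll[[k]]
    lz <- .logSumExp(eta)
    for (i in state$byCs[[k]]) {
      idx <- state$ax[[i]]
      tot <- tot + state$count[i] * sum(resp[[i]] * (eta[idx] - lz))
    }
  }
  tot
}

#' M-step: weighted conditional-logit refit
#'
#' Maximizes [emObjective()] over the model's active coefficients given
#' fixed responsibilities, via [conditionalLogitFit()] on per-choice-set
#' aggregated weights.
#'
#' @param data A [RepertoireData-class].
#' @param resp Responsibilities from [eStep()].
#' @param paramsInit A [ParameterVector-class] giving the starting point and
#'   the model variant flags.
#' @return A fitted [ParameterVector-class].
#' @export
mStep <- function(data, resp, paramsInit) {
  stopifnot(is(data, "RepertoireData"), is(paramsInit, "ParameterVector"))
  state <- .emState(data)
  r <- lapply(state$F, function(F) numeric(nrow(F)))
  for (k in state$keys) {
    for (i in state$byCs[[k]]) {
      idx <- state$ax[[i]]
      r[[k]][idx] <- r[[k]][idx] + state$count[i] * resp[[i]]
    }
  }
  fit <- conditionalLogitFit(
    features = state$F, weights = r,
    init = coef(paramsInit), activeCols = .activeNames(paramsInit)
  )
  mhParameters(fit$beta[.activeNames(paramsInit)],
    includeMHTrim = paramsInit@includeMHTrim,
    includeMHLig = paramsInit@includeMHLig
  )
}

#' Fit the model by expectation-maximization
#'
#' Alternates the E-step (posterior responsibilities over each sequence's
#' annotation set) and the M-step (weighted conditional-logit refit over full
#' choice sets) from a `beta = 0` initialization (uniform first E-step)
#' until the relative change of the observed-data log-likelihood falls below
#' `tol`, or `maxIter` iterations. The observed-data log-likelihood is
#' guaranteed non-decreasing; a decrease beyond numerical tolerance aborts
#' with an error (it would indicate an M-step defect).
#'
#' @param data A [RepertoireData-class].
#' @param includeMHTrim,includeMHLig Model variant flags (both `TRUE` gives
#'   the full model; both `FALSE` the no-microhomology model).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param maxIter Maximum EM iterations (default 100).
#' @param init Optional [ParameterVector-class] starting values (warm start).
#' @return An [MHFitResult-class].
#' @examples
#' \donttest{
#' pair <- generateGenePair(seed = 1)
#' rep <- sampleRepertoire(pair$v, pair$j, mhRegime("mh_both"), n = 500, seed = 2)
#' data <- prepareRepertoireData(rep, list(synthV = pair$v, synthJ = pair$j))
#' fit <- fitEM(data)
#' coef(modelParameters(fit))[c("mh_trim", "mh_lig")]
#' }
#' @export
fitEM <- function(data, includeMHTrim = TRUE, includeMHLig = TRUE,
                  tol = 1e-6, maxIter = 100L, init = NULL) {
  stopifnot(is(data, "RepertoireData"))
  state <- .emState(data)
  featNames <- colnames(state$F[[1]])
  active <- .activeNames(mhParameters(
    includeMHTrim = includeMHTrim, includeMHLig = includeMHLig
  ))
  b0 <- if (is.null(init)) {
    numeric(0)
  } else {
    stopifnot(is(init, "ParameterVector"))
    coef(init)[intersect(.activeNames(init), active)]
  }
  params <- mhParameters(b0,
    includeMHTrim = includeMHTrim, includeMHLig = includeMHLig
  )
  beta <- .alignBeta(params, featNames)

  llPrev <- .stateLogLik(state, .stateEta(state, beta))
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    r <- .stateResp(state, .stateEta(state, beta))
    fit <- conditionalLogitFit(state$F, r, init = beta, activeCols = active)
    beta <- fit$beta
    ll <- .stateLogLik(state, .stateEta(state, beta))
    trace <- c(trace, ll)
    if (ll < llPrev - 1e-9 * max(1, abs(llPrev))) {
      stop("EM log-likelihood decreased (", llPrev, " -> ", ll,
        "); non-monotonicity indicates an M-step defect",
        call. = FALSE
      )
    }
    if (abs(ll - llPrev) < tol * max(1, abs(llPrev))) {
      converged <- TRUE
      llPrev <- ll
      break
    }
    llPrev <- ll
  }
  new("MHFitResult",
    params = mhParameters(beta[active],
      includeMHTrim = params@includeMHTrim,
      includeMHLig = params@includeMHLig
    ),
    logLikTrace = trace,
    nIterations = it,
    converged = converged,
    config = list(
      tol = tol, maxIter = as.integer(maxIter),
      includeMHTrim = params@includeMHTrim,
      includeMHLig = params@includeMHLig,
      warmStart = !is.null(init)
    )
  )
}

#' @describeIn fitEM Fitted parameters of a fit result.
#' @param x An [MHFitResult-class].
#' @export
setMethod("modelParameters", "MHFitResult", function(x) x@params)

#' @describeIn fitEM Number of EM iterations performed.
#' @export
setMethod("nIterations", "MHFitResult", function(x) x@nIterations)

#' @describeIn fitEM Convergence flag.
#' @export
setMethod("isConverged", "MHFitResult", function(x) x@converged)

#' @describeIn fitEM Observed-data log-likelihood after each iteration.
#' @export
setMethod("logLikTrace", "MHFitResult", function(x) x@logLikTrace)

#' @describeIn fitEM Final observed-data log-likelihood.
#' @param object An [MHFitResult-class].
#' @param ... Ignored.
#' @export
setMethod("logLik", "MHFitResult", function(object, ...) {
  utils::tail(object@logLikTrace, 1)
})

#' @describeIn fitEM Coefficients of the fitted model.
#' @export
setMethod("coef", "MHFitResult", function(object, ...) {
  coef(object@params)
})
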