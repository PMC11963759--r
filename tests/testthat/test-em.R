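test_that("E-step responsibilities are annotation-set posteriors", {
  v <- toyV()
  j <- toyJ()
  rep <- data.frame(
    v_gene = "toyV", j_gene = "toyJ",
    junction = c("CACAGGTA", "CACAGGTA", "CACAGAGGTA")
  )
  data <- prepareRepertoireData(rep, list(toyV = v, toyJ = j))

  # zero parameters: uniform over each annotation set
  r0 <- eStep(data, mhParameters())
  for (i in seq_along(r0)) {
    expect_equal(r0[[i]], rep(1 / length(r0[[i]]), length(r0[[i]])))
    expect_equal(sum(r0[[i]]), 1)
  }

  # beta_lig = log10(2): proportional to 2^mh over the six annotations
  p <- mhParameters(c(mh_lig = log10(2)))
  r <- eStep(data, p)
  i8 <- which(data@units$junction == "CACAGGTA")
  mh <- scenarios(data@choiceSets[[data@units$cs_key[i8]]])$mh[data@ax[[i8]]]
  expect_equal(r[[i8]], 2^mh / sum(2^mh))

  # singleton annotation sets get responsibility 1 regardless of params
  single <- which(lengths(data@ax) == 1L)
  if (length(single)) {
    expect_equal(r[[single[1]]], 1)
  }
})

test_that("the weighted conditional-logit fit inverts known choice odds", {
  # one binary feature separating two scenarios with weights 0.8 / 0.2:
  # P = 0.8 inverts to beta = log10(4)
  F <- matrix(c(1, 0), 2, 1, dimnames = list(NULL, "x"))
  fit <- conditionalLogitFit(list(F), list(c(0.8, 0.2)))
  expect_equal(unname(fit$beta), log10(4), tolerance = 1e-6)

  # symmetric responsibilities give beta = 0
  fit0 <- conditionalLogitFit(list(F), list(c(0.5, 0.5)))
  expect_equal(unname(fit0$beta), 0, tolerance = 1e-8)

  # replicated choice sets do not move the optimum
  fit2 <- conditionalLogitFit(list(F, F), list(c(0.8, 0.2), c(0.8, 0.2)))
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-6)
})

test_that("the M-step ascends the expected complete-data objective", {
  data <- syntheticData(n = 300, regime = "mh_both", seed = 31)
  init <- mhParameters()
  r <- eStep(data, init)
  newP <- mStep(data, r, init)
  expect_gte(
    emObjective(data, r, newP),
    emObjective(data, r, init)
  )
  # and the no-MH variant keeps its excluded coefficients at zero
  init0 <- mhParameters(includeMHTrim = FALSE, includeMHLig = FALSE)
  new0 <- mStep(data, eStep(data, init0), init0)
  expect_equal(unname(coef(new0)[c("mh_trim", "mh_lig")]), c(0, 0))
})

test_that("EM is monotone, convergent, and trivial without latency", {
  data <- syntheticData(n = 400, regime = "mh_both", seed = 41)
  fit <- fitEM(data)
  expect_true(isConverged(fit))
  tr <- logLikTrace(fit)
  expect_true(all(diff(tr) >= -1e-9 * abs(tr[-length(tr)])))
  expect_equal(logLik(fit), tr[length(tr)])

  # a dataset whose annotation sets are all singletons has no latent
  # structure: EM reduces to one conditional-logit fit (<= 2 iterations)
  keep <- lengths(data@ax) == 1L
  expect_gt(sum(keep), 0)
  dataS <- data
  dataS@units <- data@units[keep, , drop = FALSE]
  dataS@ax <- data@ax[keep]
  dataS@nSequences <- as.integer(sum(dataS@units$count))
  # (suppress expected separation flags: the subset is small enough that
  # some one-hot levels lose support)
  fitS <- suppressWarnings(fitEM(dataS))
  expect_lte(nIterations(fitS), 2L)
})

test_that("nested model variants satisfy the likelihood ordering", {
  data <- syntheticData(n = 400, regime = "mh_both", seed = 41)
  # tight tolerance so both fits sit at their optima
  fitFull <- fitEM(data, tol = 1e-9)
  fitRed <- fitEM(data,
    includeMHTrim = FALSE, includeMHLig = FALSE,
    tol = 1e-9
  )
  expect_lte(logLik(fitRed), logLik(fitFull) + 1e-6 * abs(logLik(fitFull)))
  lt <- lrtTest(fitFull, fitRed)
  expect_equal(lt$df, 2)
  expect_gte(lt$LR, 0)

  # identical models: LR = 0, p = 1
  lt0 <- lrtTest(fitFull, fitFull)
  expect_equal(lt0$LR, 0)
  expect_equal(lt0$p, 1)

  # non-nested order is rejected
  expect_error(lrtTest(fitRed, fitFull), "not nested")
})

test_that("LRT reference distribution follows the chi-square tail", {
  # LR = 20 on 2 df: survival exp(-10)
  expect_equal(
    stats::pchisq(20, 2, lower.tail = FALSE),
    exp(-10)
  )
})

test_that("Wald tests standardize by the bootstrap SE with Bonferroni", {
  w <- waldTests(c(b1 = 0.4, b2 = 0), c(b1 = 0.2, b2 = 0.1), nParams = 2)
  expect_equal(w$statistic, c(2, 0))
  expect_equal(w$p_value[1], 2 * stats::pnorm(-2), tolerance = 1e-12)
  expect_equal(w$p_value[1], 0.0455, tolerance = 1e-3)
  expect_equal(w$p_value[2], 1)
  expect_equal(attr(w, "threshold"), 0.025)
  # zero SE leaves the test undefined
  w0 <- waldTests(c(b = 1), c(b = 0))
  expect_true(is.na(w0$statistic))
  expect_true(is.na(w0$p_value))
})

test_that("bootstrap SEs are deterministic and scale with sample size", {
  data <- syntheticData(n = 1000, regime = "mh_both", seed = 31)
  fit <- fitEM(data)
  se1 <- bootstrapSE(data, fit, B = 40, seed = 5)
  se2 <- bootstrapSE(data, fit, B = 40, seed = 5)
  expect_identical(se1, se2)
  expect_true(all(se1[c("mh_trim", "mh_lig")] > 0))
  est <- attr(se1, "estimates")
  expect_equal(dim(est), c(40L, length(se1)))

  # doubling every sequence shrinks the SE by about sqrt(2)
  data2 <- data
  data2@units$count <- data@units$count * 2L
  data2@nSequences <- data@nSequences * 2L
  fit2 <- fitEM(data2)
  se2x <- bootstrapSE(data2, fit2, B = 40, seed = 5)
  ratio <- se1[c("mh_trim", "mh_lig")] / se2x[c("mh_trim", "mh_lig")]
  expect_equal(unname(ratio), rep(sqrt(2), 2), tolerance = 0.2)
})

test_that("EM recovers planted microhomology effects within 2 bootstrap SE", {
  data <- syntheticData(n = 1500, regime = "mh_both", seed = 51)
  fit <- fitEM(data)
  se <- bootstrapSE(data, fit, B = 30, seed = 6)
  truth <- c(mh_trim = 0.45, mh_lig = 0.13)
  est <- coef(fit)[names(truth)]
  expect_true(all(abs(est - truth) <= 2 * se[names(truth)]))
})
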