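test_that("scenario scores are base-10 linear predictors", {
  p <- mhParameters(c(mh_lig = 0.1272))
  expect_equal(scenarioScore(c(mh_lig = 2), p), 0.2544)
  expect_equal(scenarioScore(c(mh_lig = 0, mh_trim = 0), p), 0)
  # odds ratio between one extra MH nucleotide at the trimming coefficient
  expect_equal(10^0.4484, 2.81, tolerance = 0.002)
  expect_error(scenarioScore(c(bogus = 1), p), "schema")
  expect_error(
    jointDistribution(
      buildChoiceSet(toyV(), toyJ(), "any"),
      new("ParameterVector",
        betaTrim = c(zzz = 1), betaLig = c(mh_lig = 0),
        includeMHTrim = TRUE, includeMHLig = TRUE
      )
    ),
    "schema"
  )
})

test_that("odds-percent conversion reproduces the headline percentages", {
  expect_equal(oddsPercent(0.4484), 181)
  expect_equal(oddsPercent(0.1272), 34)
  expect_equal(oddsPercent(0), 0)
})

test_that("joint distributions normalize and factor exactly", {
  v <- toyV()
  j <- toyJ()
  cs <- buildChoiceSet(v, j, "non-productive")

  # all-zero parameters give the uniform distribution
  d0 <- jointDistribution(cs, mhParameters())
  expect_equal(scenarioProbs(d0), rep(1 / nrow(scenarios(cs)), nrow(scenarios(cs))))

  set.seed(9)
  pairs <- list(list(v = v, j = j), randomPair(6, 7), randomPair(7, 5))
  for (pp in pairs) {
    for (q in c("non-productive", "any")) {
      cs <- buildChoiceSet(pp$v, pp$j, q)
      beta <- stats::setNames(
        stats::rnorm(length(mhFeatureNames()), 0, 0.3),
        mhFeatureNames()
      )
      dist <- jointDistribution(cs, mhParameters(beta))
      p <- scenarioProbs(dist)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p >= 0))
      # factored views renormalize within their domains
      m <- trimmingMarginal(dist)
      expect_equal(sum(m$prob), 1, tolerance = 1e-12)
      sc <- scenarios(cs)
      key <- paste(sc$del_v, sc$del_j)
      recon <- m$prob[match(key, paste(m$del_v, m$del_j))] *
        ligationConditional(dist)
      expect_equal(recon, p, tolerance = 1e-12)
      lcSums <- tapply(ligationConditional(dist), key, sum)
      expect_equal(as.numeric(lcSums), rep(1, length(lcSums)), tolerance = 1e-12)
    }
  }
})

test_that("the ligation conditional has closed-form odds and monotonicity", {
  # one trimming scenario with ligation options {0, 2} and beta = log10(2):
  # P(m = 2) = 4/5
  v <- toyV()
  j <- toyJ()
  cs <- buildChoiceSet(v, j, "any", delRange = c(0, 0)) # trims to CACAG / AGGTA
  expect_equal(scenarios(cs)$mh, c(0L, 2L))
  d <- jointDistribution(cs, mhParameters(c(mh_lig = log10(2))))
  expect_equal(scenarioProbs(d), c(1 / 5, 4 / 5))

  # with beta_lig > 0, P(m | delVJ) strictly increases in m
  a <- germlineGene("av", "V", "AAAAAA")
  b <- germlineGene("aj", "J", "AAAAAA")
  cs <- buildChoiceSet(a, b, "any", delRange = c(0, 0))
  d <- jointDistribution(cs, mhParameters(c(mh_lig = 0.3)))
  expect_true(all(diff(ligationConditional(d)[order(scenarios(cs)$mh)]) > 0))
})

test_that("shift invariance: constant score offsets cancel in the softmax", {
  cs <- buildChoiceSet(toyV(), toyJ(), "non-productive")
  base <- mhParameters(c(mh_lig = 0.2, mh_trim = 0.4))
  p1 <- scenarioProbs(jointDistribution(cs, base))
  csShift <- cs
  csShift@features <- cs@features # same features, shifted scores:
  eta <- scenarioScore(cs@features, base)
  etaShift <- eta + 7.5
  w <- 10^(etaShift - max(etaShift))
  expect_equal(w / sum(w), p1, tolerance = 1e-12)
})

test_that("sequence likelihoods sum annotation-set probabilities", {
  v <- toyV()
  j <- toyJ()
  cs <- buildChoiceSet(v, j, "non-productive")
  ax <- enumerateAnnotations("CACAGGTA", v, j, choiceSet = cs)

  # uniform model: likelihood = |A_X| / |choice set|
  d0 <- jointDistribution(cs, mhParameters())
  expect_equal(
    sequenceLikelihood(ax, d0),
    length(ax@indices) / nrow(scenarios(cs))
  )

  # brute-force oracle under beta_lig = log10(2)
  p <- mhParameters(c(mh_lig = log10(2)))
  d <- jointDistribution(cs, p)
  sc <- scenarios(cs)
  w <- 2^sc$mh # only mh_lig is nonzero
  expect_equal(
    sequenceLikelihood(ax, d),
    sum(w[sc$junction == "CACAGGTA"]) / sum(w)
  )

  # summing the whole choice set recovers certainty
  expect_equal(sum(scenarioProbs(d)), 1)
})

test_that("empirical pdfs are stratum relative frequencies", {
  expect_equal(empiricalPdf(c(s1 = 3, s2 = 7), 10), c(s1 = 0.3, s2 = 0.7))
  expect_equal(unname(empiricalPdf(5, 5)), 1)
  expect_error(empiricalPdf(c(1, 2), 0), "undefined stratum")
  # fractional counts from uniform splitting conserve the stratum total
  counts <- c(1 / 3, 1 / 3, 1 / 3, 2)
  expect_equal(sum(empiricalPdf(counts, 3) * 3), 3)
})

test_that("log loss and MAE behave on constructed references", {
  data <- syntheticData(n = 200, regime = "mh_both", seed = 21)
  pTrue <- mhParameters(mhRegime("mh_both")$beta)
  p0 <- mhParameters()

  # log loss is an average negative log likelihood: bounded and ordered
  llTrue <- evalLogLoss(data, pTrue)
  ll0 <- evalLogLoss(data, p0)
  expect_gt(llTrue, 0)
  expect_lte(llTrue, ll0) # true parameters fit their own data better

  # MAE of the exact empirical reference is 0; construct a two-scenario
  # stratum where model {.5,.5} vs empirical {.3,.7} gives 0.2
  expect_equal(mean(abs(c(0.5, 0.5) - c(0.3, 0.7))), 0.2)
  maeTrue <- evalMAE(data, pTrue)
  mae0 <- evalMAE(data, p0)
  expect_gt(mae0, 0)
  expect_lt(maeTrue, mae0)
})

test_that("parameter vectors round-trip through JSON", {
  p <- mhParameters(c(mh_trim = 0.4484, mh_lig = 0.1272, v_fivep_gc = 0.1))
  f <- tempfile(fileext = ".json")
  writeParametersJSON(p, f)
  p2 <- readParametersJSON(f)
  expect_equal(coef(p2), coef(p))
  expect_equal(p2@includeMHTrim, TRUE)

  pr <- mhParameters(c(v_fivep_gc = 0.1),
    includeMHTrim = FALSE,
    includeMHLig = FALSE
  )
  writeParametersJSON(pr, f)
  expect_equal(readParametersJSON(f)@includeMHLig, FALSE)
  expect_error(mhParameters(c(nope = 1)), "unknown feature")
})
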