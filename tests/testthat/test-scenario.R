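test_that("ligation scenarios are exactly the shared-overlap lengths", {
  expect_equal(ligationScenarios("CACAG", "AGGTA"), c(0L, 2L))
  expect_equal(ligationScenarios("CCC", "GGG"), 0L)
  expect_equal(ligationScenarios("AAA", "AAA"), 0:3)
  expect_equal(ligationScenarios("", "TTT"), 0L)
  expect_equal(avgMH("CACAG", "AGGTA"), 1.0)
  expect_equal(avgMH("CCC", "GGG"), 0.0)
  expect_equal(avgMH("AAA", "AAA"), 1.5)
})

test_that("junction assembly uses each shared nucleotide once", {
  expect_equal(assembleJunction("CACAG", "AGGTA", 2), "CACAGGTA")
  expect_equal(assembleJunction("CACAG", "AGGTA", 0), "CACAGAGGTA")
  expect_equal(assembleJunction("", "TTT", 0), "TTT")
  expect_error(assembleJunction("CACAG", "AGGTA", 1), "inadmissible")
})

test_that("choice sets partition the scenario grid by productivity", {
  v <- toyV()
  j <- toyJ()
  csN <- buildChoiceSet(v, j, "non-productive")
  csP <- buildChoiceSet(v, j, "productive")
  csA <- buildChoiceSet(v, j, "any")

  scN <- scenarios(csN)
  expect_true(any(scN$del_v == 0 & scN$del_j == 0 & scN$mh == 2 &
    scN$junction == "CACAGGTA"))
  expect_true(all(scN$productivity == "non-productive"))
  # the union over both labels is the unconstrained grid, the intersection empty
  keys <- function(sc) paste(sc$del_v, sc$del_j, sc$mh)
  expect_setequal(
    c(keys(scN), keys(scenarios(csP))),
    keys(scenarios(csA))
  )
  expect_length(intersect(keys(scN), keys(scenarios(csP))), 0)

  # deterministic ordering
  sc <- scenarios(csA)
  expect_false(is.unsorted(order(sc$del_v, sc$del_j, sc$mh)))

  # degenerate grid: only the fully P-extended ends
  cs0 <- buildChoiceSet(v, j, "any", delRange = c(-2, -2))
  sc0 <- scenarios(cs0)
  expect_true(all(sc0$del_v == -2 & sc0$del_j == -2))
  expect_equal(sort(sc0$mh), ligationScenarios(trimGene(v, -2), trimGene(j, -2)))
})

test_that("annotation enumeration matches the spec'd toy sets", {
  v <- toyV()
  j <- toyJ()
  ax <- enumerateAnnotations("CACAGGTA", v, j)
  ann <- annotations(ax)
  expect_equal(nrow(ann), 6)
  expect_equal(
    ann[, c("del_v", "del_j", "mh")],
    data.frame(
      del_v = c(0L, 0L, 0L, 1L, 1L, 2L),
      del_j = c(0L, 1L, 2L, 0L, 1L, 0L),
      mh = c(2L, 1L, 0L, 1L, 0L, 0L)
    )
  )
  expect_true(all(ann$junction == "CACAGGTA"))

  ax2 <- enumerateAnnotations("CACAGAGGTA", v, j)
  ann2 <- annotations(ax2)
  expect_true(any(ann2$del_v == 0 & ann2$del_j == 0 & ann2$mh == 0))

  expect_error(enumerateAnnotations("GGGGGGGG", v, j), "inconsistent")
})

test_that("annotation enumeration agrees with the brute-force grid oracle", {
  set.seed(7)
  for (rep in 1:60) {
    pair <- randomPair(sample(4:8, 1), sample(4:8, 1))
    # draw an arbitrary producible junction from the grid
    dv <- sample(-2:nchar(geneSeq(pair$v)), 1)
    dj <- sample(-2:nchar(geneSeq(pair$j)), 1)
    tv <- trimGene(pair$v, dv)
    tj <- trimGene(pair$j, dj)
    m <- sample(ligationScenarios(tv, tj), 1)
    x <- assembleJunction(tv, tj, m)
    if (!nchar(x)) next
    expected <- bruteAnnotations(x, pair$v, pair$j)
    got <- as.matrix(annotations(enumerateAnnotations(x, pair$v, pair$j))[
      , c("del_v", "del_j", "mh")
    ])
    dimnames(got) <- NULL
    dimnames(expected) <- NULL
    expect_equal(got, expected)
  }
})

test_that("assembling a choice-set scenario reproduces its stored junction", {
  pair <- randomPair(6, 6)
  cs <- buildChoiceSet(pair$v, pair$j, "any")
  sc <- scenarios(cs)
  set.seed(8)
  for (i in sample(nrow(sc), 25)) {
    expect_equal(
      assembleJunction(
        trimGene(pair$v, sc$del_v[i]),
        trimGene(pair$j, sc$del_j[i]), sc$mh[i]
      ),
      sc$junction[i]
    )
  }
})

test_that("pair summaries average microhomology over the trimming grid", {
  # non-complementary homopolymers never share germline nucleotides; on the
  # germline-only deletion grid every trimming scenario has only m = 0
  # (their P-nucleotides, being complements, do create overlaps at d < 0)
  v <- germlineGene("cv", "V", "CCCCC")
  j <- germlineGene("cj", "J", "GGGGG")
  s0 <- pairSummary(v, j, delRange = c(0, 5))
  expect_equal(s0$mean_n_ligation_scenarios, 1.0)
  expect_equal(s0$mean_avg_mh, 0.0)

  # toy pair against an exhaustive oracle
  v <- toyV()
  j <- toyJ()
  grid_v <- -2:5
  grid_j <- -2:5
  avgs <- nligs <- numeric(0)
  for (dv in grid_v) {
    for (dj in grid_j) {
      ms <- ligationScenarios(trimGene(v, dv), trimGene(j, dj))
      avgs <- c(avgs, mean(ms))
      nligs <- c(nligs, length(ms))
    }
  }
  s <- pairSummary(v, j)
  expect_equal(s$mean_avg_mh, mean(avgs))
  expect_equal(s$mean_n_ligation_scenarios, mean(nligs))

  med <- repertoireMHSummary(
    list(
      list(v = v, j = j),
      list(
        v = germlineGene("cv", "V", "CCCCC"),
        j = germlineGene("cj", "J", "GGGGG")
      )
    ),
    delRange = c(0, 5)
  )
  s05 <- pairSummary(v, j, delRange = c(0, 5))
  expect_equal(
    med$median_n_ligation_scenarios,
    mean(c(s05$mean_n_ligation_scenarios, 1))
  )
})
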