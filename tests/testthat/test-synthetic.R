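test_that("gene-pair generation plants controllable microhomology", {
  pair <- generateGenePair(
    lenV = 12, lenJ = 12, plantedOverlap = "AG",
    vOffset = 0, jOffset = 0, seed = 3
  )
  # terminal planting: the untrimmed germline ends share "AG"
  expect_gte(max(ligationScenarios(trimGene(pair$v, 0), trimGene(pair$j, 0))), 2)

  # interior planting: the shared motif is exposed at the offset trim depth
  pair2 <- generateGenePair(
    lenV = 12, lenJ = 12, plantedOverlap = "CCG",
    vOffset = 2, jOffset = 2, seed = 3
  )
  expect_gte(max(ligationScenarios(trimGene(pair2$v, 2), trimGene(pair2$j, 2))), 3)

  # single-letter alphabets with no complementarity never ligate with MH on
  # the germline-only grid (P-nucleotides are excluded: they complement)
  v <- germlineGene("cv", "V", "CCCCCCCC")
  j <- germlineGene("cj", "J", "GGGGGGGG")
  s <- pairSummary(v, j, delRange = c(0, 8))
  expect_equal(s$mean_n_ligation_scenarios, 1)

  # determinism and error guards
  pairA <- generateGenePair(seed = 9)
  pairB <- generateGenePair(seed = 9)
  expect_identical(geneSeq(pairA$v), geneSeq(pairB$v))
  expect_error(
    generateGenePair(lenV = 4, plantedOverlap = "AAAAA", vOffset = 0),
    "longer than"
  )
})

test_that("repertoire sampling follows the generative conditional logit", {
  pair <- generateGenePair(seed = 1)
  genes <- list(synthV = pair$v, synthJ = pair$j)

  # flat regime: scenario frequencies are uniform within multinomial error
  flat <- mhRegime("no_mh", background = c(v_fivep_gc = 0))
  expect_true(all(flat$beta == 0))
  rep <- sampleRepertoire(pair$v, pair$j, flat,
    n = 5000, qFilter = "non-productive", seed = 13
  )
  cs <- buildChoiceSet(pair$v, pair$j, "non-productive")
  sc <- scenarios(cs)
  key <- paste(sc$del_v, sc$del_j, sc$mh)
  obs <- table(factor(
    paste(rep$true_del_v, rep$true_del_j, rep$true_mh),
    levels = key
  ))
  gof <- suppressWarnings(stats::chisq.test(as.vector(obs)))
  expect_gt(gof$p.value, 0.01)

  # ligation-only regime: empirical odds of m = 2 vs m = 0 within a
  # two-option trimming scenario approximate 10^(2 * beta)
  reg <- mhRegime("mh_lig_only", betaMHLig = 0.3, background = c(v_fivep_gc = 0))
  repL <- sampleRepertoire(pair$v, pair$j, reg,
    n = 60000, qFilter = "any", seed = 14
  )
  csA <- buildChoiceSet(pair$v, pair$j, "any")
  scA <- scenarios(csA)
  tkey <- paste(scA$del_v, scA$del_j)
  twoOpt <- names(which(vapply(
    split(scA$mh, tkey),
    function(m) length(m) == 2 && all(sort(m) == c(0, 2)), logical(1)
  )))
  expect_gt(length(twoOpt), 0)
  sel <- paste(repL$true_del_v, repL$true_del_j) %in% twoOpt
  n2 <- sum(repL$true_mh[sel] == 2)
  n0 <- sum(repL$true_mh[sel] == 0)
  expect_gt(n0, 50)
  expect_equal(n2 / n0, 10^0.6, tolerance = 0.15)

  # reproducibility and q filtering
  repA <- sampleRepertoire(pair$v, pair$j, mhRegime("mh_both"), n = 50, seed = 15)
  repB <- sampleRepertoire(pair$v, pair$j, mhRegime("mh_both"), n = 50, seed = 15)
  expect_identical(repA, repB)
  expect_true(all(repA$productivity == "non-productive"))
  expect_true(all(vapply(
    repA$junction, classifyProductivity, character(1)
  ) == "non-productive"))
})

test_that("every sampled junction's annotation set contains its ground truth", {
  pair <- generateGenePair(seed = 2)
  rep <- sampleRepertoire(pair$v, pair$j, mhRegime("mh_both"), n = 100, seed = 16)
  for (i in seq_len(nrow(rep))) {
    ann <- annotations(enumerateAnnotations(rep$junction[i], pair$v, pair$j))
    expect_true(any(
      ann$del_v == rep$true_del_v[i] &
        ann$del_j == rep$true_del_j[i] &
        ann$mh == rep$true_mh[i]
    ))
  }
})

test_that("multiple gene pairs are sampled uniformly and kept consistent", {
  p1 <- generateGenePair(seed = 4)
  p2 <- generateGenePair(lenV = 14, lenJ = 14, seed = 5)
  p2$v@name <- "v2"
  p2$j@name <- "j2"
  rep <- sampleRepertoire(
    list(p1$v, p2$v), list(p1$j, p2$j),
    mhRegime("mh_both"),
    n = 400, seed = 17
  )
  expect_setequal(unique(rep$v_gene), c("synthV", "v2"))
  tab <- table(rep$v_gene)
  expect_gt(min(tab), 120) # roughly uniform pair usage
  # rows pair v and j genes coherently
  expect_true(all((rep$v_gene == "synthV") == (rep$j_gene == "synthJ")))
})

test_that("repertoire TSV round-trips and validates its schema", {
  pair <- generateGenePair(seed = 6)
  rep <- sampleRepertoire(pair$v, pair$j, mhRegime("mh_both"), n = 30, seed = 18)
  f <- tempfile(fileext = ".tsv")
  writeRepertoire(rep, f)
  back <- readRepertoire(f)
  expect_equal(back, rep, ignore_attr = TRUE)

  # ground-truth columns are optional for fitting
  slim <- rep[, c("v_gene", "j_gene", "junction")]
  writeRepertoire(slim, f)
  data <- prepareRepertoireData(
    readRepertoire(f),
    list(synthV = pair$v, synthJ = pair$j)
  )
  expect_equal(data@nSequences, 30L)

  # schema and shape errors are explicit
  writeLines(c("# some_other_schema", "a\tb"), f)
  expect_error(readRepertoire(f), "schema version")
  writeLines(
    c("# mh_repertoire_v1", "v_gene\tj_gene\tjunction", "only_two\tfields"),
    f
  )
  expect_error(readRepertoire(f), "line 3")
})

test_that("repertoire preparation validates genes, insertions and labels", {
  pair <- generateGenePair(seed = 7)
  genes <- list(synthV = pair$v, synthJ = pair$j)
  rep <- sampleRepertoire(pair$v, pair$j, mhRegime("mh_both"), n = 20, seed = 19)

  bad <- rep
  bad$n_insertions[3] <- 2L
  expect_error(prepareRepertoireData(bad, genes), "N-insertions")

  bad <- rep
  bad$v_gene[1] <- "missing"
  expect_error(prepareRepertoireData(bad, genes), "unknown gene")

  bad <- rep
  bad$productivity[2] <- "productive"
  expect_error(prepareRepertoireData(bad, genes), "disagrees")

  # inconsistent junctions: error by default, droppable on request
  bad <- rep
  bad$junction[5] <- strrep("G", 40) # longer than any assembled junction
  expect_error(prepareRepertoireData(bad, genes), "inconsistent")
  expect_message(
    d <- prepareRepertoireData(bad, genes, onInconsistent = "drop"),
    "dropped 1"
  )
  expect_equal(d@nSequences, 19L)
})
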