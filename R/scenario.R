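#' Enumerate ligation scenarios for a trimmed gene pair
#'
#' A ligation scenario with `m` germline-encoded microhomologous nucleotides
#' requires the last `m` nt of the trimmed V end to be identical (on the
#' coding strand; equivalently Watson-Crick complementary on the physical
#' overhangs) to the first `m` nt of the trimmed J end. `m = 0` (blunt,
#' microhomology-free joining) is always possible.
#'
#' @param trimV,trimJ Trimmed sequences on the coding strand.
#' @return Sorted integer vector of admissible `m` values, always containing
#'   0.
#' @examples
#' ligationScenarios("CACAG", "AGGTA") # 0 2
#' ligationScenarios("AAA", "AAA") # 0 1 2 3
#' @export
ligationScenarios <- function(trimV, trimJ) {
  nV <- nchar(trimV)
  nJ <- nchar(trimJ)
  mMax <- min(nV, nJ)
  if (mMax == 0L) {
    return(0L)
  }
  ok <- vapply(seq_len(mMax), function(m) {
    substr(trimV, nV - m + 1L, nV) == substr(trimJ, 1L, m)
  }, logical(1))
  c(0L, which(ok))
}

#' Assemble a junction from trimmed ends and a ligation scenario
#'
#' Joins the trimmed V and J ends with the last `m` nt of the V end
#' overlapping (appearing once) the first `m` nt of the J end, so the
#' junction has length `nchar(trimV) + nchar(trimJ) - m`.
#'
#' @param trimV,trimJ Trimmed sequences.
#' @param m A value from [ligationScenarios()].
#' @return The junction string.
#' @examples
#' assembleJunction("CACAG", "AGGTA", 2) # "CACAGGTA"
#' assembleJunction("CACAG", "AGGTA", 0) # "CACAGAGGTA"
#' @export
assembleJunction <- function(trimV, trimJ, m) {
  m <- as.integer(m)
  if (!(m %in% ligationScenarios(trimV, trimJ))) {
    stop(
      "inadmissible scenario: m = ", m, " is not a valid ligation scenario for ('",
      trimV, "', '", trimJ, "')",
      call. = FALSE
    )
  }
  paste0(trimV, substr(trimJ, m + 1L, nchar(trimJ)))
}

#' Average microhomology of a trimmed pair
#'
#' The arithmetic mean of the ligation scenarios (including 0) available to a
#' trimmed V/J pair. This is the trimming-step microhomology feature
#' (`mh_trim`): it depends only on the trimming scenario, not on which
#' ligation scenario is eventually chosen.
#'
#' @inheritParams ligationScenarios
#' @return Non-negative numeric.
#' @examples
#' avgMH("CACAG", "AGGTA") # 1.0
#' avgMH("AAA", "AAA") # 1.5
#' @export
avgMH <- function(trimV, trimJ) {
  mean(ligationScenarios(trimV, trimJ))
}

# Deletion grid for one gene: [delMin, min(delMax, germline length)].
.delGrid <- function(gene, config) {
  seq.int(config$delMin, min(config$delMax, nchar(gene@seq)))
}

#' Build the choice set for a (V, J, productivity) context
#'
#' Enumerates every (delV, delJ, mh) triple on the deletion grid whose
#' assembled junction has the requested productivity, computes each
#' scenario's feature vector, and returns the normalization domain of the
#' conditional logit model. Scenarios are ordered by (delV, delJ, mh)
#' ascending.
#'
#' @param v,j [GermlineGene-class] V and J genes.
#' @param q `"productive"`, `"non-productive"`, or `"any"` (no restriction).
#' @param delRange Length-2 integer vector overriding the config deletion
#'   grid.
#' @param config See [mhConfig()].
#' @return A [ChoiceSet-class].
#' @examples
#' v <- germlineGene("toyV", "V", "CACAG")
#' j <- germlineGene("toyJ", "J", "AGGTA")
#' cs <- buildChoiceSet(v, j, "non-productive")
#' head(scenarios(cs))
#' @export
buildChoiceSet <- function(v, j, q = "non-productive", delRange = NULL,
                           config = mhConfig()) {
  stopifnot(
    is(v, "GermlineGene"), v@side == "V",
    is(j, "GermlineGene"), j@side == "J",
    q %in% c("productive", "non-productive", "any")
  )
  config <- .asConfig(config)
  if (!is.null(delRange)) {
    stopifnot(length(delRange) == 2L)
    config$delMin <- as.integer(delRange[1])
    config$delMax <- as.integer(delRange[2])
  }
  gridV <- .delGrid(v, config)
  gridJ <- .delGrid(j, config)
  trimsV <- vapply(gridV, function(d) trimGene(v, d), character(1))
  trimsJ <- vapply(gridJ, function(d) trimGene(j, d), character(1))

  rows <- vector("list", length(gridV) * length(gridJ))
  k <- 0L
  for (iv in seq_along(gridV)) {
    for (ij in seq_along(gridJ)) {
      ms <- ligationScenarios(trimsV[iv], trimsJ[ij])
      junc <- vapply(ms, function(m) {
        paste0(trimsV[iv], substr(trimsJ[ij], m + 1L, nchar(trimsJ[ij])))
      }, character(1))
      k <- k + 1L
      rows[[k]] <- data.frame(
        del_v = gridV[iv], del_j = gridJ[ij], mh = ms,
        junction = junc, mh_trim = mean(ms),
        stringsAsFactors = FALSE
      )
    }
  }
  sc <- do.call(rbind, rows)
  sc$productivity <- vapply(sc$junction, classifyProductivity,
    character(1),
    frameOffset = config$frameOffset, USE.NAMES = FALSE
  )
  if (q != "any") {
    sc <- sc[sc$productivity == q, , drop = FALSE]
  }
  if (nrow(sc) == 0L) {
    stop(
      "empty choice set for pair (", v@name, ", ", j@name, "), q = ", q,
      call. = FALSE
    )
  }
  sc <- sc[order(sc$del_v, sc$del_j, sc$mh), , drop = FALSE]
  rownames(sc) <- NULL

  feats <- .choiceSetFeatures(v, j, sc, config)
  sc$mh_trim <- NULL
  new("ChoiceSet",
    vGene = v, jGene = j, productivity = q,
    scenarios = sc, features = feats
  )
}

#' @describeIn buildChoiceSet The scenario table.
#' @param x A [ChoiceSet-class].
#' @export
setMethod("scenarios", "ChoiceSet", function(x) x@scenarios)

#' @describeIn buildChoiceSet The per-scenario feature matrix.
#' @export
setMethod("featureMatrix", "ChoiceSet", function(x) x@features)

#' @describeIn buildChoiceSet The productivity restriction.
#' @export
setMethod("productivity", "ChoiceSet", function(x) x@productivity)

#' Enumerate the annotations consistent with an observed junction
#'
#' Constructs the annotation set A of an observed zero-N-insertion junction
#' `x` for a gene pair: every (delV, delJ, mh) on the deletion grid such that
#' the trimmed V end is a prefix of `x` (length `a`), the trimmed J end is a
#' suffix (length `b`), and `a + b - mh = nchar(x)` with `mh >= 0`. The
#' prefix/suffix overlap region then automatically satisfies the
#' microhomology identity, and the assembled junction equals `x` exactly.
#'
#' @param x Observed junction sequence.
#' @param v,j [GermlineGene-class] pair.
#' @param choiceSet Optional pre-built [ChoiceSet-class] for
#'   `(v, j, classifyProductivity(x))`; built on the fly if omitted.
#' @param config See [mhConfig()].
#' @return An [AnnotationSet-class].
#' @examples
#' v <- germlineGene("toyV", "V", "CACAG")
#' j <- germlineGene("toyJ", "J", "AGGTA")
#' ax <- enumerateAnnotations("CACAGGTA", v, j)
#' annotations(ax) # six annotations
#' @export
enumerateAnnotations <- function(x, v, j, choiceSet = NULL, config = mhConfig()) {
  stopifnot(nchar(x) > 0L, is(v, "GermlineGene"), is(j, "GermlineGene"))
  config <- .asConfig(config)
  if (grepl("[^ACGT]", x)) {
    stop("invalid sequence: junction contains non-ACGT characters", call. = FALSE)
  }
  nX <- nchar(x)
  gridV <- .delGrid(v, config)
  gridJ <- .delGrid(j, config)
  prefV <- gridV[vapply(gridV, function(d) {
    tv <- trimGene(v, d)
    nchar(tv) <= nX && substr(x, 1L, nchar(tv)) == tv
  }, logical(1))]
  sufJ <- gridJ[vapply(gridJ, function(d) {
    tj <- trimGene(j, d)
    nchar(tj) <= nX && substr(x, nX - nchar(tj) + 1L, nX) == tj
  }, logical(1))]

  found <- list()
  k <- 0L
  for (dv in prefV) {
    a <- nchar(v@seq) - dv
    for (dj in sufJ) {
      b <- nchar(j@seq) - dj
      m <- a + b - nX
      if (m >= 0L && m <= min(a, b)) {
        k <- k + 1L
        found[[k]] <- c(dv, dj, m)
      }
    }
  }
  if (k == 0L) {
    stop(
      "sequence inconsistent with pair: no annotation of '", x,
      "' by (", v@name, ", ", j@name, ")",
      call. = FALSE
    )
  }
  ann <- do.call(rbind, found)
  ann <- ann[order(ann[, 1], ann[, 2], ann[, 3]), , drop = FALSE]

  q <- classifyProductivity(x, config$frameOffset)
  if (is.null(choiceSet)) {
    choiceSet <- buildChoiceSet(v, j, q, config = config)
  }
  sc <- choiceSet@scenarios
  idx <- vapply(seq_len(nrow(ann)), function(i) {
    w <- which(sc$del_v == ann[i, 1] & sc$del_j == ann[i, 2] & sc$mh == ann[i, 3])
    if (length(w) != 1L) {
      stop("annotation not present in the supplied choice set", call. = FALSE)
    }
    w
  }, integer(1))
  new("AnnotationSet", x = x, choiceSet = choiceSet, indices = idx)
}

#' @describeIn enumerateAnnotations The annotation table (del_v, del_j, mh)
#'   with junction and productivity columns from the choice set.
#' @export
setMethod("annotations", "AnnotationSet", function(x) {
  sc <- x@choiceSet@scenarios[x@indices, , drop = FALSE]
  rownames(sc) <- NULL
  sc
})

#' Microhomology availability summary for a gene pair
#'
#' Averages, across all trimming scenarios on the deletion grid, the average
#' microhomology of the trimmed pair ([avgMH()]) and the number of available
#' ligation scenarios. A repertoire-level wrapper,
#' [repertoireMHSummary()], reports medians across gene pairs.
#'
#' @inheritParams buildChoiceSet
#' @return `list(mean_avg_mh, mean_n_ligation_scenarios)`.
#' @export
pairSummary <- function(v, j, delRange = NULL, config = mhConfig()) {
  config <- .asConfig(config)
  if (!is.null(delRange)) {
    config$delMin <- as.integer(delRange[1])
    config$delMax <- as.integer(delRange[2])
  }
  gridV <- .delGrid(v, config)
  gridJ <- .delGrid(j, config)
  avg <- matrix(0, length(gridV), length(gridJ))
  nlig <- matrix(0, length(gridV), length(gridJ))
  for (iv in seq_along(gridV)) {
    tv <- trimGene(v, gridV[iv])
    for (ij in seq_along(gridJ)) {
      ms <- ligationScenarios(tv, trimGene(j, gridJ[ij]))
      avg[iv, ij] <- mean(ms)
      nlig[iv, ij] <- length(ms)
    }
  }
  list(
    mean_avg_mh = mean(avg),
    mean_n_ligation_scenarios = mean(nlig)
  )
}

#' @describeIn pairSummary Median of the per-pair summaries across a list of
#'   `list(v = , j = )` gene pairs.
#' @param pairs List of `list(v = GermlineGene, j = GermlineGene)`.
#' @export
repertoireMHSummary <- function(pairs, delRange = NULL, config = mhConfig()) {
  sums <- lapply(pairs, function(p) pairSummary(p$v, p$j, delRange, config))
  list(
    median_avg_mh = stats::median(vapply(sums, `[[`, numeric(1), "mean_avg_mh")),
    median_n_ligation_scenarios =
      stats::median(vapply(sums, `[[`, numeric(1), "mean_n_ligation_scenarios"))
  )
}
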