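# Shared fixtures and independent brute-force oracles.
#
# The toy pair: V "CACAG" (extended "CACAGCT") and J "AGGTA" (extended
# "CTAGGTA") share the dinucleotide "AG", so the junction "CACAGGTA" has
# several annotations that differ in how the shared nucleotides are
# attributed.

toyV <- function() germlineGene("toyV", "V", "CACAG")
toyJ <- function() germlineGene("toyJ", "J", "AGGTA")

# Brute-force annotation oracle: filter the full (delV, delJ, m) grid by
# direct string construction, independent of the package's prefix/suffix
# enumeration and of assembleJunction().
bruteAnnotations <- function(x, v, j, delMin = -2, delMax = 14) {
  out <- list()
  k <- 0
  for (dv in delMin:min(delMax, nchar(geneSeq(v)))) {
    tv <- trimGene(v, dv)
    a <- nchar(tv)
    for (dj in delMin:min(delMax, nchar(geneSeq(j)))) {
      tj <- trimGene(j, dj)
      b <- nchar(tj)
      for (m in 0:min(a, b)) {
        overlapOK <- m == 0 ||
          substr(tv, a - m + 1, a) == substr(tj, 1, m)
        if (overlapOK) {
          junc <- paste0(tv, substr(tj, m + 1, b))
          if (junc == x) {
            k <- k + 1
            out[[k]] <- c(dv, dj, m)
          }
        }
      }
    }
  }
  if (k == 0) {
    return(matrix(numeric(0), 0, 3))
  }
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# Random gene pair with a compressible alphabet (more shared content).
randomPair <- function(lenV, lenJ) {
  nuc <- c("A", "C", "G", "T")
  pr <- c(0.4, 0.3, 0.2, 0.1)
  v <- paste(sample(nuc, lenV, replace = TRUE, prob = pr), collapse = "")
  j <- paste(sample(nuc, lenJ, replace = TRUE, prob = pr), collapse = "")
  list(
    v = germlineGene("rv", "V", v),
    j = germlineGene("rj", "J", j)
  )
}

# Small prepared synthetic dataset, cached per session for reuse.
syntheticData <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 500, regime = "mh_both", seed = 11, pairSeed = 1) {
    key <- paste(n, regime, seed, pairSeed, sep = "_")
    if (is.null(cache[[key]])) {
      pair <- generateGenePair(seed = pairSeed)
      rep <- sampleRepertoire(pair$v, pair$j, mhRegime(regime),
        n = n, seed = seed
      )
      cache[[key]] <- prepareRepertoireData(
        rep, list(synthV = pair$v, synthJ = pair$j)
      )
    }
    cache[[key]]
  }
})
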