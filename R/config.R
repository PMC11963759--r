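#' Configuration for junction modeling
#'
#' Central knob list shared by choice-set construction, feature computation
#' and fitting. Defaults follow the conventions used throughout the package:
#'
#' * `frameOffset` — number of nucleotides of an upstream codon completed by
#'   the junction (0-2). Productivity is called on the junction alone: a
#'   junction is productive iff `(nchar(junction) + frameOffset) %% 3 == 0`
#'   and no stop codon occurs in a complete codon of that frame.
#' * `delMin`, `delMax` — deletion grid per gene, default \[-2, 14\]
#'   (IGoR-style indexing; -2 keeps both P-nucleotides, 0 removes exactly the
#'   P-nucleotides).
#' * `motifUpstream`, `motifDownstream` — trimming-motif window: nucleotides
#'   retained-side and trimmed-side of the cut (default 2 + 1, a
#'   three-nucleotide window), read on the P-extended sequence.
#' * `includeFivepAT` — whether the 5' AT base count enters the feature set
#'   (default `FALSE`; the default model excludes 5' AT counts).
#' * `maxSpan` — optional cap on the number of nucleotides scanned for the
#'   5'/3' base counts beyond the motif (default `Inf`, i.e. the whole
#'   supplied germline end).
#' * `minStratumCount` — minimum sequences per (V, J, Q) stratum for the
#'   empirical reference used by [evalMAE()].
#'
#' @param frameOffset Integer 0-2.
#' @param delMin,delMax Integer deletion bounds.
#' @param motifUpstream,motifDownstream Motif window sizes (nt).
#' @param includeFivepAT Logical.
#' @param maxSpan Positive number or `Inf`.
#' @param minStratumCount Positive integer.
#' @return A named list of settings.
#' @examples
#' cfg <- mhConfig(frameOffset = 1)
#' cfg$frameOffset
#' @export
mhConfig <- function(frameOffset = 0L,
                     delMin = -2L,
                     delMax = 14L,
                     motifUpstream = 2L,
                     motifDownstream = 1L,
                     includeFivepAT = FALSE,
                     maxSpan = Inf,
                     minStratumCount = 10L) {
  stopifnot(
    frameOffset %in% 0:2,
    delMin <= delMax,
    motifUpstream >= 0, motifDownstream >= 0,
    maxSpan > 0,
    minStratumCount >= 1
  )
  list(
    frameOffset = as.integer(frameOffset),
    delMin = as.integer(delMin),
    delMax = as.integer(delMax),
    motifUpstream = as.integer(motifUpstream),
    motifDownstream = as.integer(motifDownstream),
    includeFivepAT = isTRUE(includeFivepAT),
    maxSpan = maxSpan,
    minStratumCount = as.integer(minStratumCount)
  )
}

# Fill in defaults for a partially specified config.
.asConfig <- function(config) {
  if (is.null(config)) {
    return(mhConfig())
  }
  base <- mhConfig()
  stopifnot(is.list(config))
  base[names(config)] <- config
  do.call(mhConfig, base)
}
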