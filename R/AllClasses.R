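#' GermlineGene: a V- or J-gene coding end with its P-nucleotide extension
#'
#' Represents the coding-end segment of a germline V or J gene on the coding
#' (top) strand, 5'->3', together with its P-nucleotide-extended form. The
#' +2 hairpin nick leaves a 4-nt 3' overhang whose two 3'-most nucleotides are
#' P-nucleotides: for a V gene the extension appends the reverse complement of
#' the last two germline nucleotides; for a J gene (whose physical overhang is
#' on the bottom strand) it prepends the reverse complement of the first two.
#' The 4-nt window spanning the germline/P boundary is always palindromic.
#'
#' @slot name Gene identifier.
#' @slot side `"V"` or `"J"`.
#' @slot seq Germline coding-end sequence over A/C/G/T, top strand.
#' @slot extendedSeq `seq` with the two P-nucleotides attached.
#'
#' @seealso [germlineGene()], [trimGene()], [readGermlineFasta()]
#' @export
setClass("GermlineGene",
  representation(
    name = "character",
    side = "character",
    seq = "character",
    extendedSeq = "character"
  )
)

setValidity("GermlineGene", function(object) {
  msg <- character()
  if (length(object@side) != 1L || !object@side %in% c("V", "J")) {
    msg <- c(msg, "side must be \"V\" or \"J\"")
  }
  if (length(object@seq) != 1L || nchar(object@seq) < 2L) {
    msg <- c(msg, "seq must be a single string of length >= 2")
  } else if (grepl("[^ACGT]", object@seq)) {
    msg <- c(msg, "seq must contain only A, C, G, T")
  } else {
    expected <- .pExtendSeq(object@seq, object@side)
    if (!identical(object@extendedSeq, expected)) {
      msg <- c(msg, "extendedSeq does not match the P-nucleotide extension rule")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ChoiceSet: all admissible scenarios for one (V, J, productivity) context
#'
#' The normalization domain of the conditional logit model: every trimming
#' scenario (delV, delJ) on the deletion grid combined with every ligation
#' scenario (number of germline-encoded microhomologous nucleotides, `mh`)
#' admissible for the trimmed pair, restricted to junctions with the stated
#' productivity. Scenarios are ordered by (delV, delJ, mh) ascending so all
#' downstream tie-breaks are reproducible.
#'
#' @slot vGene,jGene The [GermlineGene-class] pair.
#' @slot productivity `"productive"`, `"non-productive"`, or `"any"`.
#' @slot scenarios `data.frame` with columns `del_v`, `del_j`, `mh`,
#'   `junction`, `productivity`.
#' @slot features Numeric matrix, one row per scenario (see
#'   [mhFeatureNames()]).
#'
#' @seealso [buildChoiceSet()]
#' @export
setClass("ChoiceSet",
  representation(
    vGene = "GermlineGene",
    jGene = "GermlineGene",
    productivity = "character",
    scenarios = "data.frame",
    features = "matrix"
  )
)

setValidity("ChoiceSet", function(object) {
  sc <- object@scenarios
  msg <- character()
  need <- c("del_v", "del_j", "mh", "junction", "productivity")
  if (!all(need %in% names(sc))) {
    msg <- c(msg, "scenarios must have columns del_v, del_j, mh, junction, productivity")
  } else if (anyDuplicated(sc[, c("del_v", "del_j", "mh")])) {
    msg <- c(msg, "duplicate (del_v, del_j, mh) triples")
  }
  if (nrow(sc) && nrow(object@features) != nrow(sc)) {
    msg <- c(msg, "feature matrix rows must match scenario rows")
  }
  if (length(msg)) msg else TRUE
})

#' AnnotationSet: the annotations consistent with one observed junction
#'
#' The set A of all (delV, delJ, mh) triples whose assembled junction equals
#' the observed sequence `x` exactly, for a given gene pair. Items are stored
#' as row indices into the corresponding [ChoiceSet-class] (the one for
#' `productivity(x)`), of which they are a subset.
#'
#' @slot x Observed junction sequence.
#' @slot choiceSet The [ChoiceSet-class] the annotations live in.
#' @slot indices Integer rows of `scenarios(choiceSet)` whose junction is `x`.
#'
#' @seealso [enumerateAnnotations()], [annotationPosteriors()]
#' @export
setClass("AnnotationSet",
  representation(
    x = "character",
    choiceSet = "ChoiceSet",
    indices = "integer"
  )
)

setValidity("AnnotationSet", function(object) {
  sc <- object@choiceSet@scenarios
  if (length(object@indices) == 0L) {
    return("annotation set is empty")
  }
  if (any(object@indices < 1L) || any(object@indices > nrow(sc))) {
    return("indices out of range of the choice set")
  }
  if (!all(sc$junction[object@indices] == object@x)) {
    return("every annotation's junction must equal x")
  }
  TRUE
})

#' ParameterVector: conditional-logit coefficients on the log10-odds scale
#'
#' Holds the trimming-step coefficients (trimming motif, 5'/3' base counts,
#' and the trimming microhomology feature `mh_trim`) and the ligation-step
#' coefficient (`mh_lig`). Each coefficient is the change in the log10 odds of
#' a scenario per unit increase of its feature, all else held constant. The
#' `includeMHTrim` / `includeMHLig` flags select the full model versus the
#' nested no-microhomology variants: an excluded term is pinned at zero and
#' not counted as a model parameter.
#'
#' @slot betaTrim Named numeric: coefficients for all trimming-step features.
#' @slot betaLig Named numeric: coefficient(s) for the ligation-step feature.
#' @slot includeMHTrim,includeMHLig Logical flags for the two MH terms.
#'
#' @seealso [mhParameters()], [jointDistribution()], [fitEM()]
#' @export
setClass("ParameterVector",
  representation(
    betaTrim = "numeric",
    betaLig = "numeric",
    includeMHTrim = "logical",
    includeMHLig = "logical"
  )
)

setValidity("ParameterVector", function(object) {
  msg <- character()
  if (is.null(names(object@betaTrim)) || is.null(names(object@betaLig))) {
    msg <- c(msg, "coefficients must be named")
  } else if (length(intersect(names(object@betaTrim), names(object@betaLig)))) {
    msg <- c(msg, "trimming and ligation coefficient names must be disjoint")
  }
  if (!object@includeMHTrim && any(object@betaTrim[names(object@betaTrim) == "mh_trim"] != 0)) {
    msg <- c(msg, "mh_trim coefficient must be 0 when includeMHTrim is FALSE")
  }
  if (!object@includeMHLig && any(object@betaLig != 0)) {
    msg <- c(msg, "mh_lig coefficient must be 0 when includeMHLig is FALSE")
  }
  if (length(msg)) msg else TRUE
})

#' ScenarioDistribution: model probabilities over one choice set
#'
#' The joint distribution P(delVJ, MH | VJ, Q) over a [ChoiceSet-class] under
#' a [ParameterVector-class], together with its exact factorization into the
#' trimming marginal P(delVJ | VJ, Q) and the ligation conditional
#' P(MH | delVJ, VJ, Q). The productivity conditioning is realized as
#' choice-set restriction before normalization, which makes the factorization
#' exact (the product of the two factors reproduces the joint).
#'
#' @slot choiceSet The underlying [ChoiceSet-class].
#' @slot prob Joint probability per scenario row.
#' @slot trimMarginal `data.frame(del_v, del_j, prob)`.
#' @slot ligConditional Per-row P(mh | delVJ), aligned with scenario rows.
#'
#' @seealso [jointDistribution()]
#' @export
setClass("ScenarioDistribution",
  representation(
    choiceSet = "ChoiceSet",
    prob = "numeric",
    trimMarginal = "data.frame",
    ligConditional = "numeric"
  )
)

#' RepertoireData: a repertoire prepared for model fitting
#'
#' Holds a zero-N-insertion repertoire after annotation-set construction:
#' sequences are aggregated into units sharing the same (V, J, Q) choice set
#' and junction (identical junctions have identical annotation sets), each
#' unit carrying its sequence count and the row indices of its annotations in
#' the corresponding choice set.
#'
#' @slot units `data.frame(cs_key, junction, count)`.
#' @slot ax List of integer vectors parallel to `units` rows.
#' @slot choiceSets Named list of [ChoiceSet-class], keyed by `cs_key`.
#' @slot nSequences Total number of sequences.
#' @slot config The [mhConfig()] list used during preparation.
#'
#' @seealso [prepareRepertoireData()], [fitEM()]
#' @export
setClass("RepertoireData",
  representation(
    units = "data.frame",
    ax = "list",
    choiceSets = "list",
    nSequences = "integer",
    config = "list"
  )
)

setValidity("RepertoireData", function(object) {
  msg <- character()
  if (length(object@ax) != nrow(object@units)) {
    msg <- c(msg, "ax must have one element per unit row")
  }
  if (!all(object@units$cs_key %in% names(object@choiceSets))) {
    msg <- c(msg, "every unit must reference a known choice set")
  }
  if (length(msg)) msg else TRUE
})

#' MHFitResult: an EM fit of the conditional logit model
#'
#' @slot params Fitted [ParameterVector-class].
#' @slot logLikTrace Observed-data log-likelihood (natural log) after each EM
#'   iteration; non-decreasing up to numerical tolerance.
#' @slot nIterations Number of E/M cycles performed.
#' @slot converged Whether the relative log-likelihood change fell below
#'   tolerance before `maxIter`.
#' @slot config Fit settings snapshot (tolerances, flags, seed if any).
#'
#' @seealso [fitEM()], [lrtTest()], [bootstrapSE()]
#' @export
setClass("MHFitResult",
  representation(
    params = "ParameterVector",
    logLikTrace = "numeric",
    nIterations = "integer",
    converged = "logical",
    config = "list"
  )
)
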