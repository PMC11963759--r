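#' @describeIn germlineGene Compact display.
#' @param object A [GermlineGene-class].
#' @export
setMethod("show", "GermlineGene", function(object) {
  cat(
    "GermlineGene ", object@name, " (", object@side, " end, ",
    nchar(object@seq), " nt)\n",
    "  germline: 5'-", object@seq, "-3'\n",
    "  extended: ", object@extendedSeq, "\n",
    sep = ""
  )
})

#' @describeIn buildChoiceSet Compact display.
#' @param object A [ChoiceSet-class].
#' @export
setMethod("show", "ChoiceSet", function(object) {
  sc <- object@scenarios
  cat(
    "ChoiceSet for (", object@vGene@name, ", ", object@jGene@name,
    "), Q = ", object@productivity, "\n",
    "  ", nrow(sc), " scenarios over ",
    length(unique(paste(sc$del_v, sc$del_j))), " trimming scenarios; mh up to ",
    max(sc$mh), "\n",
    sep = ""
  )
})

#' @describeIn enumerateAnnotations Compact display.
#' @param object An [AnnotationSet-class].
#' @export
setMethod("show", "AnnotationSet", function(object) {
  cat(
    "AnnotationSet for junction ", object@x, " (",
    length(object@indices), " annotation(s))\n",
    sep = ""
  )
  print(annotations(object))
})

#' @describeIn mhParameters Compact display of the non-zero coefficients.
#' @export
setMethod("show", "ParameterVector", function(object) {
  b <- coef(object)
  cat("ParameterVector (log10-odds scale); MH terms: trim ",
    if (object@includeMHTrim) "on" else "off", ", lig ",
    if (object@includeMHLig) "on" else "off", "\n",
    sep = ""
  )
  nz <- b[b != 0]
  if (length(nz)) print(round(nz, 4)) else cat("  all coefficients zero\n")
})

#' @describeIn jointDistribution Compact display.
#' @param object A [ScenarioDistribution-class].
#' @export
setMethod("show", "ScenarioDistribution", function(object) {
  cat(
    "ScenarioDistribution over ", length(object@prob), " scenarios (sum = ",
    format(sum(object@prob)), ")\n",
    sep = ""
  )
})

#' @describeIn prepareRepertoireData Compact display.
#' @param object A [RepertoireData-class].
#' @export
setMethod("show", "RepertoireData", function(object) {
  cat(
    "RepertoireData: ", object@nSequences, " sequences in ",
    nrow(object@units), " units over ", length(object@choiceSets),
    " choice set(s)\n",
    sep = ""
  )
})

#' @describeIn fitEM Compact display.
#' @export
setMethod("show", "MHFitResult", function(object) {
  cat(
    "MHFitResult: ", object@nIterations, " EM iteration(s), ",
    if (object@converged) "converged" else "not converged",
    "; logLik = ", format(logLik(object)), "\n",
    sep = ""
  )
  b <- coef(object@params)
  mh <- b[c("mh_trim", "mh_lig")]
  cat("  MH coefficients: ", paste(names(mh), round(mh, 4),
    sep = " = ", collapse = ", "
  ), "\n", sep = "")
})
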