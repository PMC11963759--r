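# Preparing a repertoire table for fitting: choice sets + annotation sets.

.csKey <- function(v, j, q) paste(v, j, q, sep = "||")

#' Prepare a repertoire for model fitting
#'
#' Takes a zero-N-insertion repertoire table (columns `v_gene`, `j_gene`,
#' `junction`; optional `productivity`, `n_insertions`, `sequence_id`) and a
#' named list of germline genes, builds the (V, J, Q) choice sets touched by
#' the data, enumerates each junction's annotation set, and aggregates
#' sequences into units sharing the same choice set and junction (such
#' sequences are interchangeable for the likelihood).
#'
#' Rows with `n_insertions > 0` are outside the model's scope and rejected.
#' Productivity, if supplied, must agree with [classifyProductivity()] of the
#' junction; if absent it is computed. A junction that no (delV, delJ, mh)
#' combination of its assigned pair can produce is an error by default
#' (`onInconsistent = "drop"` instead drops such rows with a message).
#'
#' @param repertoire A data.frame as above (e.g. from [sampleRepertoire()] or
#'   [readRepertoire()]).
#' @param genes Named list of [GermlineGene-class], keyed by the names used
#'   in `v_gene` / `j_gene`.
#' @param config See [mhConfig()].
#' @param onInconsistent `"error"` (default) or `"drop"`.
#' @return A [RepertoireData-class].
#' @export
prepareRepertoireData <- function(repertoire, genes, config = mhConfig(),
                                  onInconsistent = c("error", "drop")) {
  onInconsistent <- match.arg(onInconsistent)
  config <- .asConfig(config)
  stopifnot(
    is.data.frame(repertoire),
    all(c("v_gene", "j_gene", "junction") %in% names(repertoire))
  )
  missing <- setdiff(
    unique(c(repertoire$v_gene, repertoire$j_gene)),
    names(genes)
  )
  if (length(missing)) {
    stop("unknown gene(s) in repertoire: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.null(repertoire$n_insertions) && any(repertoire$n_insertions != 0)) {
    stop("repertoire contains sequences with N-insertions; the model covers ",
      "zero-insertion sequences only",
      call. = FALSE
    )
  }

  q <- vapply(repertoire$junction, classifyProductivity, character(1),
    frameOffset = config$frameOffset, USE.NAMES = FALSE
  )
  if (!is.null(repertoire$productivity)) {
    bad <- which(repertoire$productivity != q)
    if (length(bad)) {
      stop(
        "productivity label disagrees with the junction frame/stop rule for ",
        length(bad), " row(s), first at row ", bad[1],
        call. = FALSE
      )
    }
  }

  key <- .csKey(repertoire$v_gene, repertoire$j_gene, q)
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(repertoire))),
    by = list(cs_key = key, junction = repertoire$junction),
    FUN = sum
  )
  agg <- agg[order(agg$cs_key, agg$junction), , drop = FALSE]
  rownames(agg) <- NULL

  meta <- do.call(rbind, strsplit(unique(agg$cs_key), "||", fixed = TRUE))
  choiceSets <- stats::setNames(vector("list", nrow(meta)), unique(agg$cs_key))
  for (i in seq_len(nrow(meta))) {
    choiceSets[[i]] <- buildChoiceSet(
      genes[[meta[i, 1]]], genes[[meta[i, 2]]], meta[i, 3],
      config = config
    )
  }

  ax <- vector("list", nrow(agg))
  drop <- logical(nrow(agg))
  for (i in seq_len(nrow(agg))) {
    cs <- choiceSets[[agg$cs_key[i]]]
    idx <- which(cs@scenarios$junction == agg$junction[i])
    if (!length(idx)) {
      if (onInconsistent == "error") {
        stop("sequence inconsistent with pair: junction '", agg$junction[i],
          "' cannot be produced by its assigned genes",
          call. = FALSE
        )
      }
      drop[i] <- TRUE
    }
    ax[[i]] <- idx
  }
  if (any(drop)) {
    message(
      "dropped ", sum(agg$count[drop]),
      " sequence(s) inconsistent with their assigned gene pair"
    )
    ax <- ax[!drop]
    agg <- agg[!drop, , drop = FALSE]
    rownames(agg) <- NULL
    choiceSets <- choiceSets[unique(agg$cs_key)]
  }
  if (!nrow(agg)) {
    stop("no usable sequences after filtering", call. = FALSE)
  }

  new("RepertoireData",
    units = agg, ax = ax, choiceSets = choiceSets,
    nSequences = sum(agg$count), config = config
  )
}

#' Annotation set of one prepared unit
#'
#' Convenience accessor: the [AnnotationSet-class] of the `i`-th unit of a
#' [RepertoireData-class].
#'
#' @param data A [RepertoireData-class].
#' @param i Unit row index.
#' @return An [AnnotationSet-class].
#' @export
unitAnnotationSet <- function(data, i) {
  stopifnot(is(data, "RepertoireData"), i >= 1L, i <= nrow(data@units))
  new("AnnotationSet",
    x = data@units$junction[i],
    choiceSet = data@choiceSets[[data@units$cs_key[i]]],
    indices = as.integer(data@ax[[i]])
  )
}
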