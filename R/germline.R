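#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet reverseComplement
NULL

# Reverse complement for plain character strings (hot path; avoids object
# construction in inner loops).
.revComp <- function(s) {
  if (!nchar(s)) {
    return(s)
  }
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# Side-specific P-nucleotide extension of a coding-strand sequence.
.pExtendSeq <- function(seq, side) {
  n <- nchar(seq)
  if (side == "V") {
    paste0(seq, .revComp(substr(seq, n - 1L, n)))
  } else {
    paste0(.revComp(substr(seq, 1L, 2L)), seq)
  }
}

.validateNucleotides <- function(seq, what = "sequence") {
  seq <- toupper(seq)
  if (nchar(seq) < 2L) {
    stop("invalid gene: ", what, " must be at least 2 nt long", call. = FALSE)
  }
  if (grepl("[^ACGT]", seq)) {
    stop("invalid gene: ", what, " contains non-ACGT characters", call. = FALSE)
  }
  seq
}

#' Construct a germline gene end with its P-nucleotide extension
#'
#' Builds a [GermlineGene-class] from a coding-strand sequence and applies the
#' P-nucleotide extension corresponding to a +2 hairpin nick: two palindromic
#' nucleotides appended 3' of a V end, or prepended 5' of a J end (the J
#' overhang physically sits on the bottom strand; storing the top strand and
#' mirroring gives identical results).
#'
#' @param name Gene identifier.
#' @param side `"V"` or `"J"`.
#' @param seq Nucleotide string over A/C/G/T (case-insensitive), coding
#'   strand, 5'->3', at least 2 nt.
#' @return A [GermlineGene-class].
#' @examples
#' v <- germlineGene("toyV", "V", "CACAG")
#' extendedSeq(v) # "CACAGCT"
#' j <- germlineGene("toyJ", "J", "AGGTA")
#' extendedSeq(j) # "CTAGGTA"
#' @export
germlineGene <- function(name, side, seq) {
  side <- toupper(side)
  if (!side %in% c("V", "J")) {
    stop("side must be \"V\" or \"J\"", call. = FALSE)
  }
  seq <- .validateNucleotides(seq, paste0("gene '", name, "'"))
  new("GermlineGene",
    name = as.character(name), side = side, seq = seq,
    extendedSeq = .pExtendSeq(seq, side)
  )
}

#' Apply the P-nucleotide extension to a gene
#'
#' Recomputes the `extendedSeq` slot from the germline sequence; exposed
#' mainly so the extension rule is directly testable. [germlineGene()]
#' already applies it.
#'
#' @param gene A [GermlineGene-class].
#' @return The gene with `extendedSeq` set.
#' @export
pExtend <- function(gene) {
  stopifnot(is(gene, "GermlineGene"))
  gene@extendedSeq <- .pExtendSeq(gene@seq, gene@side)
  validObject(gene)
  gene
}

#' @describeIn germlineGene The gene identifier.
#' @param x A [GermlineGene-class].
#' @export
setMethod("geneName", "GermlineGene", function(x) x@name)

#' @describeIn germlineGene `"V"` or `"J"`.
#' @export
setMethod("geneSide", "GermlineGene", function(x) x@side)

#' @describeIn germlineGene The germline coding-end sequence.
#' @export
setMethod("geneSeq", "GermlineGene", function(x) x@seq)

#' @describeIn germlineGene The P-nucleotide-extended sequence.
#' @export
setMethod("extendedSeq", "GermlineGene", function(x) x@extendedSeq)

# Extended sequence in the "mirrored" orientation in which trimming always
# removes from the string's 3' (right) end: the V extended sequence itself,
# or the reverse complement of the J extended sequence (i.e. the J bottom
# strand read 5'->3'). All cut-site feature computation uses this view.
.mirroredExt <- function(gene) {
  if (gene@side == "V") gene@extendedSeq else .revComp(gene@extendedSeq)
}

#' Trim a germline gene end
#'
#' Removes `d` nucleotides under IGoR-style deletion indexing on the
#' P-extended end: `d = -2` retains both P-nucleotides (returns the full
#' extended sequence), `d = 0` stops exactly at the germline boundary
#' (returns the germline sequence; the two P-nucleotides are removed, since
#' any germline deletion also deletes all P-nucleotides), and `d > 0` removes
#' germline nucleotides. V genes are trimmed from the 3' end, J genes from
#' the 5' coding end (their physical 3' bottom-strand end).
#'
#' @param gene A [GermlineGene-class].
#' @param d Integer deletion in `[-2, nchar(geneSeq(gene))]`.
#' @return The trimmed sequence on the coding strand (possibly `""`).
#' @examples
#' v <- germlineGene("toyV", "V", "CACAG")
#' trimGene(v, -2) # "CACAGCT"
#' trimGene(v, 0) # "CACAG"
#' trimGene(germlineGene("toyJ", "J", "AGGTA"), 2) # "GTA"
#' @export
trimGene <- function(gene, d) {
  stopifnot(is(gene, "GermlineGene"), length(d) == 1L)
  d <- as.integer(d)
  n <- nchar(gene@seq)
  if (d < -2L || d > n) {
    stop(
      "inadmissible scenario: deletion ", d, " outside [-2, ", n,
      "] for gene '", gene@name, "'",
      call. = FALSE
    )
  }
  keep <- n - d
  ext <- gene@extendedSeq
  if (gene@side == "V") {
    substr(ext, 1L, keep)
  } else {
    substr(ext, nchar(ext) - keep + 1L, nchar(ext))
  }
}

#' Classify junction productivity
#'
#' A junction is `"productive"` iff its length plus `frameOffset` is a
#' multiple of 3 and no stop codon (TAA, TAG, TGA) occurs in any complete
#' codon of the frame defined by `frameOffset`; otherwise
#' `"non-productive"` (out-of-frame recombination or a stop codon).
#' `frameOffset` is the number of nucleotides of an upstream codon that the
#' junction completes, so complete codons start at junction position
#' `(3 - frameOffset) %% 3 + 1`.
#'
#' @param junction Nucleotide string over A/C/G/T.
#' @param frameOffset Integer 0-2 (default 0).
#' @return `"productive"` or `"non-productive"`.
#' @examples
#' classifyProductivity("CACGGG") # productive
#' classifyProductivity("CACTAAGGG") # non-productive (TAA stop)
#' classifyProductivity("CACAGGTA") # non-productive (out of frame)
#' @export
classifyProductivity <- function(junction, frameOffset = 0L) {
  stopifnot(length(junction) == 1L, frameOffset %in% 0:2)
  if (grepl("[^ACGT]", junction)) {
    stop("invalid sequence: junction contains non-ACGT characters", call. = FALSE)
  }
  n <- nchar(junction)
  if ((n + frameOffset) %% 3L != 0L) {
    return("non-productive")
  }
  start <- (3L - as.integer(frameOffset)) %% 3L + 1L
  while (start + 2L <= n) {
    if (substr(junction, start, start + 2L) %in% c("TAA", "TAG", "TGA")) {
      return("non-productive")
    }
    start <- start + 3L
  }
  "productive"
}

#' Read germline genes from a FASTA file
#'
#' Reads a multi-record FASTA of germline V/J coding ends and returns
#' P-extended [GermlineGene-class] objects. The side of each record is taken
#' from a `|V` / `|J` suffix on its header, or from the `sides` map.
#' Lowercase sequence is uppercased; any non-ACGT symbol is an error.
#'
#' @param path FASTA file path.
#' @param sides Optional named character vector mapping record name to
#'   `"V"`/`"J"`; overrides header suffixes.
#' @return Named list of [GermlineGene-class] objects (names without the side
#'   suffix).
#' @export
readGermlineFasta <- function(path, sides = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  headers <- sub("\\s.*$", "", names(set))
  hasSuffix <- grepl("\\|[VJvj]$", headers)
  names_ <- ifelse(hasSuffix, sub("\\|[VJvj]$", "", headers), headers)
  if (anyDuplicated(names_)) {
    stop("duplicate gene names in FASTA: ",
      paste(unique(names_[duplicated(names_)]), collapse = ", "),
      call. = FALSE
    )
  }
  side_ <- toupper(ifelse(hasSuffix, sub("^.*\\|", "", headers), NA_character_))
  if (!is.null(sides)) {
    side_ <- ifelse(names_ %in% names(sides), toupper(sides[names_]), side_)
  }
  if (anyNA(side_)) {
    stop(
      "cannot infer V/J side for record(s): ",
      paste(names_[is.na(side_)], collapse = ", "),
      "; use a '|V'/'|J' header suffix or the `sides` argument",
      call. = FALSE
    )
  }
  seqs <- toupper(as.character(set))
  genes <- mapply(function(nm, sd, sq) germlineGene(nm, sd, sq),
    names_, side_, seqs,
    SIMPLIFY = FALSE
  )
  names(genes) <- names_
  genes
}
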