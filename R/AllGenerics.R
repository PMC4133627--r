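#' @rdname MetaAlignment-class
#' @param x a MetaAlignment.
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' @rdname MetaAlignment-class
#' @export
setGeneric("gappedRows", function(x) standardGeneric("gappedRows"))

#' @rdname MetaAlignment-class
#' @export
setGeneric("alignmentWidth", function(x) standardGeneric("alignmentWidth"))

#' @rdname MetaAlignment-class
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' Remove all gaps from every alignment row
#'
#' @param x a [MetaAlignment-class].
#' @return named character vector of ungapped sequences, in row order.
#' @export
setGeneric("degap", function(x) standardGeneric("degap"))

#' @rdname ResidueProfile-class
#' @param x a ResidueProfile.
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @rdname ResidueProfile-class
#' @export
setGeneric("profileLength", function(x) standardGeneric("profileLength"))

#' Profile conservation rate (PCR) of each profile position
#'
#' The conservation rate of a position is the maximum residue weight at that
#' position divided by the sum of all weights there. It lies in (0, 1] and
#' equals 1 exactly when the position holds a single residue type; an evenly
#' split four-residue position attains the minimum 0.25. The aligner uses it
#' to raise gap-opening cost against well-conserved columns.
#'
#' @param x a [ResidueProfile-class].
#' @return numeric vector, one rate in (0, 1] per profile position.
#' @examples
#' prof <- buildProfile(MetaAlignment(c(s1 = "AC", s2 = "AG")))
#' conservationRate(prof)   # 1.0, 0.5
#' @export
setGeneric("conservationRate", function(x) standardGeneric("conservationRate"))
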