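#' @rdname CodonAlignment-class
#' @param x,object a \code{CodonAlignment}, \code{LabeledTree} or related
#'   object.
#' @export
setGeneric("taxonNames", function(x) standardGeneric("taxonNames"))

#' @rdname CodonAlignment-class
#' @export
setGeneric("nCodonSites", function(x) standardGeneric("nCodonSites"))

#' @rdname CodonAlignment-class
#' @export
setGeneric("codonMatrix", function(x) standardGeneric("codonMatrix"))

#' @rdname CodonAlignment-class
#' @export
setGeneric("codonStrings", function(x) standardGeneric("codonStrings"))

#' @rdname LabeledTree-class
#' @export
setGeneric("edgeLabels", function(x) standardGeneric("edgeLabels"))

#' @rdname LabeledTree-class
#' @export
setGeneric("treePhylo", function(x) standardGeneric("treePhylo"))

#' @rdname DielHistory-class
#' @export
setGeneric("dielStates", function(x) standardGeneric("dielStates"))

#' @rdname FocalTree-class
#' @export
setGeneric("branchNames", function(x) standardGeneric("branchNames"))

#' @rdname FocalTree-class
#' @export
setGeneric("psgSets", function(x) standardGeneric("psgSets"))
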