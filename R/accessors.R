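#' @describeIn CodonAlignment-class taxon identifiers.
#' @export
setMethod("taxonNames", "CodonAlignment", function(x) x@taxa)

#' @describeIn CodonAlignment-class number of codon sites.
#' @export
setMethod("nCodonSites", "CodonAlignment", function(x) ncol(x@codons))

#' @describeIn CodonAlignment-class integer codon-index matrix
#'   (taxa x sites, NA = missing).
#' @export
setMethod("codonMatrix", "CodonAlignment", function(x) {
  m <- x@codons
  rownames(m) <- x@taxa
  m
})

#' @describeIn CodonAlignment-class per-taxon codon character strings
#'   (missing codons rendered as \code{NNN}).
#' @export
setMethod("codonStrings", "CodonAlignment", function(x) {
  ct <- .codonTable()
  out <- apply(x@codons, 1L, function(row) {
    s <- ifelse(is.na(row), "NNN", ct$codons[row])
    paste(s, collapse = "")
  })
  names(out) <- x@taxa
  out
})

setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf("CodonAlignment: %d taxa, %d codon sites (%s code)\n",
              length(object@taxa), ncol(object@codons), object@geneticCode))
  miss <- mean(is.na(object@codons))
  cat(sprintf("  missing/gap codons: %.1f%%\n", 100 * miss))
  cat("  taxa:", paste(utils::head(object@taxa, 5), collapse = ", "),
      if (length(object@taxa) > 5) "..." else "", "\n")
})

#' @describeIn LabeledTree-class per-edge partition tags.
#' @export
setMethod("edgeLabels", "LabeledTree", function(x) x@labels)

#' @describeIn LabeledTree-class the underlying \code{phylo} object.
#' @export
setMethod("treePhylo", "LabeledTree", function(x) x@phy)

#' @describeIn LabeledTree-class taxon (tip) names.
#' @export
setMethod("taxonNames", "LabeledTree", function(x) x@phy$tip.label)

setMethod("show", "LabeledTree", function(object) {
  tab <- table(object@labels)
  cat(sprintf("LabeledTree: %d tips, %d edges (%s)\n",
              length(object@phy$tip.label), nrow(object@phy$edge),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "CodonFit", function(object) {
  cat(sprintf("CodonFit [%s]: logLik = %.4f (%d start%s%s)\n",
              object@model, object@logLik, object@nStarts,
              if (object@nStarts > 1L) "s" else "",
              if (object@capped) ", omega at bound" else ""))
  if (nrow(object@mixture)) {
    print(object@mixture, digits = 4)
  }
})

#' @describeIn CodonFit-class maximized log-likelihood.
#' @param object a \code{CodonFit}.
#' @export
setMethod("logLik", "CodonFit", function(object) object@logLik)

setMethod("show", "LRTResult", function(object) {
  cat(sprintf(
    "LRT: logL0 = %.4f, logL1 = %.4f, 2dL = %.4f, df = %d, p = %.4g\n",
    object@logLikNull, object@logLikAlt, object@twoDeltaL, object@df,
    object@pValue))
})

#' @describeIn FocalTree-class branch names.
#' @export
setMethod("branchNames", "FocalTree", function(x) x@branch)

#' @describeIn FocalTree-class named list of per-branch PSG sets.
#' @export
setMethod("psgSets", "FocalTree", function(x) {
  out <- setNames(vector("list", length(x@branch)), x@branch)
  for (b in names(x@psg)) out[[b]] <- x@psg[[b]]
  for (b in names(out)) if (is.null(out[[b]])) out[[b]] <- character()
  out
})

setMethod("show", "FocalTree", function(object) {
  cat(sprintf("FocalTree: %d branches, root = %s\n",
              length(object@branch),
              object@branch[is.na(object@parent)]))
  np <- sum(lengths(psgSets(object)) > 0)
  cat(sprintf("  branches with PSG calls: %d\n", np))
})

#' @describeIn DielHistory-class named per-branch state vector.
#' @export
setMethod("dielStates", "DielHistory", function(x) x@states)

setMethod("show", "DielHistory", function(object) {
  tab <- table(factor(object@states, levels = .dielStates()))
  cat("DielHistory:",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
})
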