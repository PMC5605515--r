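setOldClass("phylo")

#' In-frame codon alignment
#'
#' Holds an aligned set of in-frame coding sequences over the 61 sense codons
#' of the standard genetic code. Codon columns are stored as integer indices
#' into \code{\link{senseCodons}}; gap codons (\code{---}) and codons
#' containing ambiguous bases (\code{N}) are stored as \code{NA} and treated
#' as fully missing by the likelihood machinery, never dropped.
#'
#' @slot taxa character vector of unique taxon identifiers.
#' @slot codons integer matrix (taxa x codon sites) of sense-codon indices,
#'   \code{NA} for missing/gap/ambiguous codons.
#' @slot geneticCode identifier of the genetic code (only \code{"standard"}
#'   is implemented).
#' @export
setClass("CodonAlignment",
  representation(taxa = "character", codons = "matrix",
                 missingText = "matrix", geneticCode = "character"),
  prototype(missingText = matrix(character(), 0, 0),
            geneticCode = "standard"))

setValidity("CodonAlignment", function(object) {
  msg <- character()
  if (anyDuplicated(object@taxa))
    msg <- c(msg, "duplicate taxon identifiers")
  if (nrow(object@codons) != length(object@taxa))
    msg <- c(msg, "codon matrix rows must match taxa")
  v <- object@codons[!is.na(object@codons)]
  if (length(v) && (any(v < 1L) || any(v > 61L)))
    msg <- c(msg, "codon indices must lie in 1..61")
  if (!identical(object@geneticCode, "standard"))
    msg <- c(msg, "only the standard genetic code is supported")
  if (length(msg)) msg else TRUE
})

#' Phylogeny with branch partition labels
#'
#' An \pkg{ape} \code{phylo} tree whose edges carry partition tags used by
#' the selection machinery: \code{"background"}, \code{"foreground"},
#' \code{"test"} or \code{"reference"}. Untagged edges are background.
#'
#' @slot phy a rooted binary \code{phylo} object with branch lengths in
#'   expected substitutions per codon.
#' @slot labels character vector of per-edge tags, parallel to
#'   \code{phy$edge}.
#' @export
setClass("LabeledTree",
  representation(phy = "phylo", labels = "character"))

setValidity("LabeledTree", function(object) {
  msg <- character()
  if (length(object@labels) != nrow(object@phy$edge))
    msg <- c(msg, "one label per edge required")
  bad <- setdiff(unique(object@labels),
                 c("background", "foreground", "test", "reference"))
  if (length(bad))
    msg <- c(msg, paste("unknown edge labels:", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Fitted codon model
#'
#' Result of \code{\link{fitCodonModel}}: the maximized log-likelihood, the
#' fitted parameters (kappa, per-class/per-partition omegas, site-class
#' proportions), and bookkeeping about the multi-start optimization.
#'
#' @slot model model identifier (e.g. \code{"modelA"}).
#' @slot logLik maximized log-likelihood (best start).
#' @slot params named list of fitted parameters.
#' @slot mixture data.frame of site classes: proportion and omega on the
#'   background and foreground partitions.
#' @slot converged logical, optimizer convergence of the best start.
#' @slot nStarts number of start combinations run.
#' @slot startSpread spread of log-likelihoods across starts.
#' @slot capped logical, TRUE when a free omega hit its upper bound.
#' @export
setClass("CodonFit",
  representation(model = "character", logLik = "numeric", params = "list",
                 mixture = "data.frame", converged = "logical",
                 nStarts = "integer", startSpread = "numeric",
                 capped = "logical"))

#' Likelihood ratio test result
#'
#' @slot logLikNull,logLikAlt log-likelihoods of the nested pair.
#' @slot twoDeltaL twice the log-likelihood difference, clamped at zero.
#' @slot df degrees of freedom of the chi-square reference.
#' @slot pValue upper-tail chi-square p-value.
#' @export
setClass("LRTResult",
  representation(logLikNull = "numeric", logLikAlt = "numeric",
                 twoDeltaL = "numeric", df = "integer", pValue = "numeric"))

setValidity("LRTResult", function(object) {
  msg <- character()
  if (object@twoDeltaL < 0) msg <- c(msg, "twoDeltaL must be >= 0")
  if (object@df < 1L) msg <- c(msg, "df must be >= 1")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Tree of named focal lineages
#'
#' A rooted tree over named focal branches (e.g. Euarchontoglires ->
#' Euarchonta -> Primatomorpha -> ...) given as a parent map, optionally
#' decorated with the positively-selected-gene set detected on each branch.
#'
#' @slot branch character vector of unique branch names.
#' @slot parent character vector of parent branch names (NA for the root),
#'   parallel to \code{branch}.
#' @slot psg named list mapping branch name to a character vector of PSG
#'   gene ids (possibly empty).
#' @export
setClass("FocalTree",
  representation(branch = "character", parent = "character", psg = "list"))

setValidity("FocalTree", function(object) {
  msg <- character()
  if (anyDuplicated(object@branch)) msg <- c(msg, "duplicate branch names")
  if (length(object@parent) != length(object@branch))
    msg <- c(msg, "parent vector must parallel branch vector")
  if (sum(is.na(object@parent)) != 1L)
    msg <- c(msg, "exactly one root (parent NA) required")
  known <- object@parent[!is.na(object@parent)]
  if (!all(known %in% object@branch))
    msg <- c(msg, "parents must name existing branches")
  if (!all(names(object@psg) %in% object@branch))
    msg <- c(msg, "psg names must be branch names")
  # cycle check via repeated parent hops
  root <- object@branch[is.na(object@parent)]
  if (length(root) == 1L) {
    for (b in object@branch) {
      seen <- character(); cur <- b
      while (!is.na(cur)) {
        if (cur %in% seen) { msg <- c(msg, "cyclic parent structure"); break }
        seen <- c(seen, cur)
        cur <- object@parent[match(cur, object@branch)]
      }
    }
  }
  if (length(msg)) unique(msg) else TRUE
})

#' Diel activity history over a focal tree
#'
#' @slot tree the \code{\linkS4class{FocalTree}} the states refer to.
#' @slot states named character vector, one of \code{"diurnal"},
#'   \code{"nocturnal"}, \code{"cathemeral"}, \code{"unresolved"} per branch.
#' @export
setClass("DielHistory",
  representation(tree = "FocalTree", states = "character"))

setValidity("DielHistory", function(object) {
  msg <- character()
  if (!identical(sort(names(object@states)), sort(object@tree@branch)))
    msg <- c(msg, "states must cover exactly the focal branches")
  bad <- setdiff(unique(object@states), .dielStates())
  if (length(bad))
    msg <- c(msg, paste("unknown diel states:", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

.dielStates <- function() c("diurnal", "nocturnal", "cathemeral", "unresolved")
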