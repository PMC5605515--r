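# The diel-state rule: per-branch positive-selection signals on cone- vs
# rod-expressed genes vote for diurnality vs nocturnality (both together:
# cathemerality); branches without signal inherit the state of their most
# recent ancestor.

#' Construct a focal-lineage tree
#'
#' @param branch character vector of branch names.
#' @param parent parallel vector of parent names (NA for the root).
#' @param psg optional named list mapping branch names to PSG gene-id
#'   vectors.
#' @return a \code{\linkS4class{FocalTree}}.
#' @export
focalTree <- function(branch, parent, psg = list()) {
  new("FocalTree", branch = as.character(branch),
      parent = as.character(parent), psg = psg)
}

#' Classify the selection signal of one branch
#'
#' Positively selected cone-expressed genes only vote diurnal; rod-expressed
#' only vote nocturnal; at least one of each votes cathemeral. Genes whose
#' photoreceptor class is \code{"both"} (e.g. recovery genes expressed in
#' cones and rods alike) never vote, so a branch whose only PSGs are such
#' genes yields \code{"none"} (no state change), as does an empty PSG set.
#'
#' @param psgs character vector of positively selected gene ids.
#' @param annotation gene annotation data.frame (\code{gene}, \code{class},
#'   \code{role}).
#' @param votingClasses photoreceptor classes allowed to vote (default
#'   cone and rod; override to let \code{"both"} genes vote).
#' @return one of \code{"diurnal"}, \code{"nocturnal"},
#'   \code{"cathemeral"}, \code{"none"}.
#' @export
#' @examples
#' ann <- data.frame(gene = c("SWS1", "GRK1", "RCVRN"),
#'                   class = c("cone", "rod", "both"),
#'                   role = c("activation", "recovery", "recovery"))
#' classifyBranchSignal(c("SWS1", "GRK1"), ann)  # cathemeral
classifyBranchSignal <- function(psgs, annotation,
                                 votingClasses = c("cone", "rod")) {
  if (!length(psgs)) return("none")
  i <- match(psgs, annotation$gene)
  if (anyNA(i))
    stop("unannotated gene(s): ", paste(psgs[is.na(i)], collapse = ", "))
  cls <- annotation$class[i]
  cone <- any(cls == "cone" & "cone" %in% votingClasses)
  rod <- any(cls == "rod" & "rod" %in% votingClasses)
  if ("both" %in% votingClasses && any(cls == "both")) {
    cone <- TRUE; rod <- TRUE
  }
  if (cone && rod) "cathemeral"
  else if (cone) "diurnal"
  else if (rod) "nocturnal"
  else "none"
}

#' Propagate diel states over a focal tree
#'
#' Preorder traversal: each branch takes its own classification when the
#' classification is not \code{"none"}, and otherwise inherits its
#' parent's state (lack of selection signal is read as retention of the
#' ancestral diel pattern). A root without signal takes \code{rootPrior}.
#'
#' @param ft a \code{\linkS4class{FocalTree}} carrying PSG sets.
#' @param annotation gene annotation data.frame.
#' @param rootPrior state assumed for a signal-less root (default
#'   \code{"unresolved"}).
#' @param votingClasses passed to \code{\link{classifyBranchSignal}}.
#' @return a \code{\linkS4class{DielHistory}}.
#' @export
propagateStates <- function(ft, annotation, rootPrior = "unresolved",
                            votingClasses = c("cone", "rod")) {
  stopifnot(rootPrior %in% .dielStates())
  validObject(ft)
  psg <- psgSets(ft)
  own <- vapply(ft@branch, function(b)
    classifyBranchSignal(psg[[b]], annotation, votingClasses), character(1))
  states <- setNames(rep(NA_character_, length(ft@branch)), ft@branch)
  # preorder: repeatedly assign branches whose parent is resolved
  remaining <- ft@branch
  while (length(remaining)) {
    progress <- FALSE
    for (b in remaining) {
      p <- ft@parent[match(b, ft@branch)]
      if (is.na(p)) {
        states[b] <- if (own[b] == "none") rootPrior else own[b]
        progress <- TRUE
      } else if (!is.na(states[p])) {
        states[b] <- if (own[b] == "none") states[p] else own[b]
        progress <- TRUE
      }
    }
    remaining <- names(states)[is.na(states)]
    if (!progress) stop("cyclic or disconnected focal tree")
  }
  new("DielHistory", tree = ft, states = states)
}

#' Compare an inferred diel history with the truth
#'
#' @param inferred,truth \code{\linkS4class{DielHistory}} objects over the
#'   same focal tree.
#' @return list with \code{table} (branch, inferred, truth, agree),
#'   \code{fractionCorrect} (agreeing branches / all branches) and
#'   \code{nUnresolved} (inferred unresolved branches, also counted in the
#'   denominator).
#' @export
compareHistories <- function(inferred, truth) {
  bi <- sort(names(inferred@states))
  bt <- sort(names(truth@states))
  if (!identical(bi, bt)) stop("histories are over different focal trees")
  b <- names(inferred@states)
  tab <- data.frame(branch = b, inferred = unname(inferred@states),
                    truth = unname(truth@states[b]))
  tab$agree <- tab$inferred == tab$truth
  list(table = tab, fractionCorrect = mean(tab$agree),
       nUnresolved = sum(tab$inferred == "unresolved"))
}

#' Bundled primate phototransduction case study
#'
#' Loads the packaged focal-lineage tree of Euarchontoglires (root) down
#' through the primate clades, the branch-site PSG calls reported for the
#' 33-gene phototransduction panel on those branches, and the cone/rod
#' annotation of the genes involved. The stem branch of the Cebidae clade
#' is named \code{"Cebidae-stem"} (it is occasionally referred to by the
#' wider clade name Platyrrhini; only Cebidae representatives inform it).
#'
#' @return list with \code{focalTree} (a \code{\linkS4class{FocalTree}}
#'   with PSG sets attached) and \code{annotation}.
#' @export
examplePrimateStudy <- function() {
  d <- system.file("extdata", package = "photodiel")
  ft <- utils::read.table(file.path(d, "primate_focal_tree.tsv"),
                          header = TRUE, sep = "\t", na.strings = "NA",
                          stringsAsFactors = FALSE)
  calls <- utils::read.table(file.path(d, "primate_psg_calls.tsv"),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  ann <- readGeneAnnotation(file.path(d, "primate_gene_classes.tsv"))
  psg <- split(calls$gene, calls$branch)
  list(focalTree = focalTree(ft$branch, ft$parent, psg),
       annotation = ann)
}

#' Export a diel history as an annotated Newick string
#'
#' @param history a \code{\linkS4class{DielHistory}}.
#' @return a Newick string in which each focal branch is a labeled node
#'   \code{name|state}.
#' @export
dielHistoryToNewick <- function(history) {
  ft <- history@tree
  states <- history@states
  children <- split(ft@branch, ft@parent[match(ft@branch, ft@branch)])
  kids <- function(b) ft@branch[!is.na(ft@parent) & ft@parent == b]
  rec <- function(b) {
    k <- kids(b)
    lab <- paste0(b, "|", states[b])
    if (!length(k)) return(lab)
    paste0("(", paste(vapply(k, rec, character(1)), collapse = ","), ")",
           lab)
  }
  root <- ft@branch[is.na(ft@parent)]
  paste0(rec(root), ";")
}
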