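# Ground-truth multi-gene diel studies: a prescribed diel history over the
# focal lineages is inverted into per-gene, per-branch selection regimes
# (state-change branches get episodic positive selection on genes of the
# class that votes for the new state), and codon alignments are simulated
# accordingly.

#' Species tree for the focal-lineage layout
#'
#' A 12-taxon species tree (one outgroup plus representatives of
#' Scandentia, Dermoptera, the major primate clades and Glires) in which
#' every focal branch of the bundled focal-lineage tree corresponds to one
#' edge. Two alternative topologies are provided, differing in the
#' position of the tree shrew: \code{"A"} places Scandentia sister to
#' Primatomorpha (so an Euarchonta branch exists), \code{"B"} places it
#' sister to Glires. Branch lengths are plausible desk-scale values in
#' expected substitutions per codon.
#'
#' @param topology \code{"A"} or \code{"B"}.
#' @return list with \code{phy} (an unrooted \code{phylo}, trifurcation at
#'   the base) and \code{clades} (named list: focal branch name -> tip set
#'   whose stem edge it is; the Euarchontoglires stem is represented by
#'   the outgroup terminal edge, its unrooted equivalent).
#' @export
focalSpeciesTree <- function(topology = c("A", "B")) {
  topology <- match.arg(topology)
  prim <- paste0("(Lemur:0.30,(Tarsius:0.30,((Aotus:0.12,Cebus:0.12)",
                 ":0.15,(Macaca:0.15,(Homo:0.08,Hylobates:0.08):0.10)",
                 ":0.10):0.15):0.15):0.12")
  nwk <- if (topology == "A") paste0(
    "(Outgroup:0.55,(Tupaia:0.25,(Galeopterus:0.25,", prim,
    ":0.10):0.10):0.08,(Mouse:0.35,Rabbit:0.30):0.15);")
  else paste0(
    "(Outgroup:0.55,(Tupaia:0.25,(Mouse:0.35,Rabbit:0.30):0.15):0.08,",
    "(Galeopterus:0.25,", prim, ":0.10):0.10);")
  phy <- ape::read.tree(text = nwk)
  primates <- c("Lemur", "Tarsius", "Aotus", "Cebus", "Macaca", "Homo",
                "Hylobates")
  clades <- list(
    Euarchontoglires = "Outgroup",
    Glires = c("Mouse", "Rabbit"),
    Primatomorpha = c("Galeopterus", primates),
    Dermoptera = "Galeopterus",
    Primates = primates,
    Strepsirrhini = "Lemur",
    Haplorrhini = setdiff(primates, "Lemur"),
    Tarsiidae = "Tarsius",
    Simiiformes = setdiff(primates, c("Lemur", "Tarsius")),
    `Cebidae-stem` = c("Aotus", "Cebus"),
    Aotus = "Aotus",
    Catarrhini = c("Macaca", "Homo", "Hylobates"),
    Cercopithecidae = "Macaca",
    Hominoidae = c("Homo", "Hylobates"))
  if (topology == "A")
    clades$Euarchonta <- c("Tupaia", "Galeopterus", primates)
  list(phy = phy, clades = clades)
}

#' Default diel history for simulation studies
#'
#' The focal-lineage history used by the flagship end-to-end simulation:
#' diurnality from the root through the primate stem, nocturnal
#' strepsirrhines/haplorrhines/tarsiers, cathemeral simians, a nocturnal
#' Cebidae stem retained in Aotus, cathemeral catarrhines/hominoids,
#' diurnal cercopithecids and Glires, cathemeral colugos.
#'
#' @return named character vector of states over the bundled focal tree.
#' @export
defaultDielHistory <- function() {
  c(Euarchontoglires = "diurnal", Euarchonta = "diurnal",
    Glires = "diurnal", Primatomorpha = "diurnal",
    Dermoptera = "cathemeral", Primates = "diurnal",
    Strepsirrhini = "nocturnal", Haplorrhini = "nocturnal",
    Tarsiidae = "nocturnal", Simiiformes = "cathemeral",
    `Cebidae-stem` = "nocturnal", Aotus = "nocturnal",
    Catarrhini = "cathemeral", Cercopithecidae = "diurnal",
    Hominoidae = "cathemeral")
}

.defaultStudyPanel <- function() {
  data.frame(
    gene = c(paste0("CONE", 1:5), paste0("ROD", 1:5), "REC1", "REC2"),
    class = c(rep("cone", 5), rep("rod", 5), "both", "both"),
    role = c(rep("activation", 4), "recovery", rep("activation", 4),
             "recovery", "recovery", "recovery"))
}

#' Generate a ground-truth diel study
#'
#' Inverts a diel history into gene-level selection regimes and simulates
#' one codon alignment per gene. Every branch whose state differs from
#' its parent's (and the root, when its state differs from
#' \code{rootPrior}) carries episodic positive selection on sampled genes
#' of the class that votes for the new state: a cone gene for a diurnal
#' shift, a rod gene for a nocturnal shift, one of each for a cathemeral
#' shift. All other gene x branch combinations evolve under the purifying
#' background mixture. Recovery-role genes of class \code{"both"} can
#' optionally evolve under a relaxed (k < 1) regime on the primate stem.
#'
#' @param history named state vector over the focal branches (default
#'   \code{\link{defaultDielHistory}}).
#' @param genes annotation data.frame (default: a 12-gene panel of 5 cone,
#'   5 rod and 2 both-class genes).
#' @param effect foreground omega2 of the selected site classes.
#' @param pSelected total proportion of selected sites (classes 2a + 2b).
#' @param nCodons codons per gene.
#' @param kappa transition/transversion ratio of the simulation.
#' @param omega0,p0,p1 purifying-mixture parameters (class-0 omega and the
#'   proportions of classes 0 and 1).
#' @param topology species-tree topology (\code{"A"} or \code{"B"}).
#' @param rootPrior state against which the root is compared.
#' @param relaxRecovery simulate class-"both" genes under a relaxed regime
#'   (k = 0.3) on the primate stem instead of the plain background.
#' @param seed integer seed.
#' @return list of class \code{"DielStudy"}: \code{alignments} (named list
#'   of \code{CodonAlignment}), \code{annotation}, \code{history}
#'   (a \code{\linkS4class{DielHistory}}), \code{trueRegimes} (data.frame
#'   gene/branch/omega2), \code{speciesTree}, \code{clades},
#'   \code{focalTree}, and the generator settings.
#' @export
generateDielStudy <- function(history = defaultDielHistory(),
                              genes = .defaultStudyPanel(),
                              effect = 8, pSelected = 0.1, nCodons = 400,
                              kappa = 2, omega0 = 0.1, p0 = 0.75,
                              p1 = 0.15, topology = "A",
                              rootPrior = "unresolved",
                              relaxRecovery = FALSE, seed = 42) {
  genes <- validateGeneAnnotation(genes)
  st <- focalSpeciesTree(topology)
  fx <- examplePrimateStudy()$focalTree
  branches <- intersect(fx@branch, names(history))
  if (!setequal(branches, fx@branch))
    stop("history must cover every focal branch")
  ft <- focalTree(fx@branch, fx@parent)
  coneGenes <- genes$gene[genes$class == "cone"]
  rodGenes <- genes$gene[genes$class == "rod"]
  if (!length(coneGenes) || !length(rodGenes))
    stop("need at least one cone and one rod gene")
  if (any(history == "unresolved" & !is.na(ft@parent[match(names(history),
                                                           ft@branch)])))
    stop("non-root branches must have resolved states")

  .withSeed(seed, {
    # which branches change state (root compared against rootPrior)
    regimes <- data.frame(gene = character(), branch = character(),
                          omega2 = numeric())
    for (b in ft@branch) {
      p <- ft@parent[match(b, ft@branch)]
      parentState <- if (is.na(p)) rootPrior else history[[p]]
      s <- history[[b]]
      if (identical(s, parentState) || s == "unresolved") next
      pick <- switch(s,
        diurnal = sample(coneGenes, 1),
        nocturnal = sample(rodGenes, 1),
        cathemeral = c(sample(coneGenes, 1), sample(rodGenes, 1)))
      for (g in pick)
        regimes <- rbind(regimes, data.frame(gene = g, branch = b,
                                             omega2 = effect))
    }
    p2 <- pSelected
    p0r <- p0 / (p0 + p1) # split of classes 2a/2b
    mixtureFor <- function(w2) data.frame(
      prop = c(p0, p1, p2 * p0r, p2 * (1 - p0r)),
      omegaBackground = c(omega0, 1, omega0, 1),
      omegaForeground = c(omega0, 1, w2, w2))
    alignments <- list()
    geneSeeds <- sample.int(2^30, nrow(genes))
    for (i in seq_len(nrow(genes))) {
      g <- genes$gene[i]
      sigBranches <- regimes$branch[regimes$gene == g]
      labels <- rep("background", nrow(st$phy$edge))
      for (b in sigBranches) {
        tips <- st$clades[[b]]
        node <- if (length(tips) == 1L) match(tips, st$phy$tip.label)
                else ape::getMRCA(st$phy, tips)
        labels[which(st$phy$edge[, 2] == node)] <- "foreground"
      }
      ltree <- new("LabeledTree", phy = st$phy, labels = labels)
      if (relaxRecovery && genes$class[i] == "both") {
        prTips <- st$clades$Primates
        node <- ape::getMRCA(st$phy, prTips)
        labels2 <- rep("background", nrow(st$phy$edge))
        labels2[which(st$phy$edge[, 2] == node)] <- "test"
        ltree2 <- new("LabeledTree", phy = st$phy, labels = labels2)
        sim <- simulateRelaxDataset(ltree2, k = 0.3,
                                    baseOmegas = c(omega0, 1, 2),
                                    proportions = c(p0, p1 + p2, 0),
                                    kappa = kappa, nCodons = nCodons,
                                    seed = geneSeeds[i])
      } else {
        w2 <- if (length(sigBranches)) effect else 1
        sim <- simulateCodonAlignment(ltree, mixtureFor(w2),
                                      kappa = kappa, nCodons = nCodons,
                                      seed = geneSeeds[i])
      }
      alignments[[g]] <- sim$alignment
    }
    hist <- new("DielHistory", tree = ft,
                states = history[ft@branch])
    structure(list(alignments = alignments, annotation = genes,
                   history = hist, trueRegimes = regimes,
                   speciesTree = st$phy, clades = st$clades,
                   focalTree = ft, topology = topology,
                   effect = effect, pSelected = pSelected,
                   nCodons = nCodons, kappa = kappa, seed = seed,
                   rootPrior = rootPrior),
              class = "DielStudy")
  })
}

#' @export
print.DielStudy <- function(x, ...) {
  cat(sprintf(
    "DielStudy: %d genes x %d codons, %d focal branches, seed %d\n",
    length(x$alignments), x$nCodons, length(x$focalTree@branch), x$seed))
  cat(sprintf("  true selection regimes: %d gene x branch signals\n",
              nrow(x$trueRegimes)))
  invisible(x)
}

#' Oracle PSG calls of a ground-truth study
#'
#' Returns the focal tree decorated with the study's true selection
#' regimes as PSG calls, bypassing the statistical tests. Propagating
#' these calls must recover the generating history exactly; this isolates
#' test error from reconstruction error.
#'
#' @param study a \code{"DielStudy"}.
#' @return a \code{\linkS4class{FocalTree}} with PSG sets.
#' @export
oraclePsgCalls <- function(study) {
  psg <- split(study$trueRegimes$gene, study$trueRegimes$branch)
  focalTree(study$focalTree@branch, study$focalTree@parent, psg)
}
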