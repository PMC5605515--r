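# Simulators with known ground truth: codon alignments under site-class
# mixtures with partition-specific omegas, RELAX-style k-exponentiated
# datasets, amino-acid alignments, and full multi-gene diel studies.
#
# All randomness is locally seeded: the caller's RNG state is saved and
# restored, and identical (spec, seed) pairs give identical output.

.withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# sample child states along one edge: parent states (int vector), P matrix
.evolveStates <- function(parent, P) {
  child <- integer(length(parent))
  for (s in unique(parent)) {
    i <- which(parent == s)
    child[i] <- sample.int(ncol(P), length(i), replace = TRUE,
                           prob = P[s, ])
  }
  child
}

#' Simulate a codon alignment under a site-class mixture
#'
#' Root codons are drawn from the equilibrium frequencies; each site is
#' assigned a class by the mixture proportions and evolves along every
#' edge under the transition matrix of that class on the edge's partition
#' (background vs foreground). Rate matrices are rescaled exactly as in
#' the likelihood engine (common background-mixture rate), so branch
#' lengths mean expected substitutions per codon and refitting simulated
#' data recovers the generating parameters.
#'
#' @param tree a \code{\linkS4class{LabeledTree}} with branch lengths.
#' @param mixture data.frame with \code{prop}, \code{omegaBackground},
#'   \code{omegaForeground} (one row per site class).
#' @param kappa transition/transversion ratio.
#' @param codonFreqs 61-vector (default equal).
#' @param nCodons number of codon sites.
#' @param seed integer seed (local RNG; caller state untouched).
#' @return list with \code{alignment} (a
#'   \code{\linkS4class{CodonAlignment}}), \code{siteClass} (true class
#'   index per site) and \code{nodeStates} (codon indices at internal
#'   nodes, rows named by node id).
#' @export
simulateCodonAlignment <- function(tree, mixture, kappa = 2,
                                   codonFreqs = rep(1 / 61, 61),
                                   nCodons = 300, seed = 1) {
  stopifnot(all(mixture$prop >= 0))
  if (abs(sum(mixture$prop) - 1) > 1e-8)
    stop("mixture proportions must sum to 1")
  .withSeed(seed, {
    td <- .treeData(tree)
    phy <- td$phy
    ntaxa <- length(phy$tip.label)
    nnode <- ntaxa + phy$Nnode
    co <- cbind(mixture$omegaBackground, mixture$omegaForeground)
    f <- .mixtureScaleFactor(kappa, codonFreqs, co, mixture$prop)
    siteClass <- sample.int(nrow(mixture), nCodons, replace = TRUE,
                            prob = mixture$prop)
    states <- matrix(NA_integer_, nnode, nCodons)
    root <- ntaxa + 1L
    states[root, ] <- sample.int(61L, nCodons, replace = TRUE,
                                 prob = codonFreqs)
    # preorder = reverse postorder
    Pcache <- new.env(parent = emptyenv())
    for (e in rev(seq_len(nrow(phy$edge)))) {
      par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
      t <- phy$edge.length[e] / f
      for (c in unique(siteClass)) {
        w <- co[c, td$part[e] + 1L]
        key <- paste(e, w)
        P <- Pcache[[key]]
        if (is.null(P)) {
          Q <- buildRateMatrix(kappa, w, codonFreqs, rescale = FALSE)
          P <- transitionMatrix(Q, t, pi = codonFreqs)
          Pcache[[key]] <- P
        }
        idx <- which(siteClass == c)
        states[ch, idx] <- .evolveStates(states[par, idx], P)
      }
    }
    cod <- states[seq_len(ntaxa), , drop = FALSE]
    aln <- new("CodonAlignment", taxa = phy$tip.label, codons = unname(cod),
               missingText = matrix(character(), 0, 0),
               geneticCode = "standard")
    internal <- states[(ntaxa + 1L):nnode, , drop = FALSE]
    rownames(internal) <- as.character((ntaxa + 1L):nnode)
    list(alignment = aln, siteClass = siteClass, nodeStates = internal,
         scaleFactor = f)
  })
}

#' Simulate a RELAX-style dataset
#'
#' Reference branches evolve under the base omega distribution; test
#' branches under the base omegas raised to the power \code{k} (k < 1
#' relaxes selection toward neutrality, k > 1 intensifies it).
#'
#' @param tree a \code{\linkS4class{LabeledTree}} whose test branches are
#'   labeled \code{"test"} (or \code{"foreground"}).
#' @param k selection intensity exponent (>= 0).
#' @param baseOmegas omega values of the reference distribution.
#' @param proportions class proportions (same length).
#' @param kappa,codonFreqs,nCodons,seed as in
#'   \code{\link{simulateCodonAlignment}}.
#' @return as \code{\link{simulateCodonAlignment}}, plus the true \code{k}
#'   and the generating \code{mixture}.
#' @export
simulateRelaxDataset <- function(tree, k, baseOmegas = c(0.2, 1, 2),
                                 proportions = c(0.7, 0.2, 0.1), kappa = 2,
                                 codonFreqs = rep(1 / 61, 61),
                                 nCodons = 400, seed = 1) {
  stopifnot(k >= 0, length(baseOmegas) == length(proportions))
  mixture <- data.frame(prop = proportions,
                        omegaBackground = baseOmegas,
                        omegaForeground = baseOmegas^k)
  out <- simulateCodonAlignment(tree, mixture, kappa = kappa,
                                codonFreqs = codonFreqs,
                                nCodons = nCodons, seed = seed)
  out$k <- k
  out$mixture <- mixture
  out
}

#' Simulate an amino-acid alignment with known ancestral states
#'
#' @param phy a \code{phylo} tree with branch lengths (expected
#'   substitutions per site).
#' @param model an \code{\link{aminoAcidModel}} or model name
#'   (\code{"JTT"}, \code{"Poisson"}).
#' @param nSites number of sites.
#' @param seed integer seed.
#' @return list with \code{alignment} (named character vector of tip
#'   sequences), \code{ancestral} (character matrix of true states at
#'   internal nodes, rows named by node id) and the \code{model} used.
#' @export
simulateAAAlignment <- function(phy, model = "JTT", nSites = 200, seed = 1) {
  if (is.character(model)) model <- aminoAcidModel(model)
  .withSeed(seed, {
    phy <- ape::reorder.phylo(phy, "postorder")
    ntaxa <- length(phy$tip.label)
    nnode <- ntaxa + phy$Nnode
    states <- matrix(NA_integer_, nnode, nSites)
    root <- ntaxa + 1L
    states[root, ] <- sample.int(20L, nSites, replace = TRUE,
                                 prob = model$pi)
    for (e in rev(seq_len(nrow(phy$edge)))) {
      par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
      P <- transitionMatrix(model$Q, phy$edge.length[e], pi = model$pi)
      states[ch, ] <- .evolveStates(states[par, ], P)
    }
    aa <- .aaAlphabet()
    tipSeq <- apply(states[seq_len(ntaxa), , drop = FALSE], 1L,
                    function(s) paste(aa[s], collapse = ""))
    names(tipSeq) <- phy$tip.label
    anc <- matrix(aa[states[(ntaxa + 1L):nnode, , drop = FALSE]],
                  nrow = phy$Nnode)
    rownames(anc) <- as.character((ntaxa + 1L):nnode)
    list(alignment = tipSeq, ancestral = anc, model = model$name,
         tree = phy)
  })
}
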