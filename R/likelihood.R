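# Likelihood machinery: R-level pruning (small problems, oracles, amino
# acids) and the bridge to the compiled codon mixture engine.

# Compress alignment columns into unique site patterns with weights.
.sitePatterns <- function(codons) {
  keys <- apply(codons, 2L, function(col) paste(ifelse(is.na(col), 0L, col),
                                                collapse = ","))
  u <- !duplicated(keys)
  map <- match(keys, keys[u])
  pat <- codons[, u, drop = FALSE]
  w <- tabulate(map, nbins = sum(u))
  list(patterns = pat, weights = w, map = map)
}

# postorder edge structures for a LabeledTree
.treeData <- function(tree) {
  phy <- ape::reorder.phylo(tree@phy, "postorder")
  ord <- match(paste(phy$edge[, 1], phy$edge[, 2]),
               paste(tree@phy$edge[, 1], tree@phy$edge[, 2]))
  list(phy = phy,
       labels = tree@labels[ord],
       part = as.integer(tree@labels[ord] %in% c("foreground", "test")))
}

# Core bridge: mixture log-likelihood through the compiled engine.
# classOmega: nclass x 2 matrix (background, foreground), classProp: simplex.
.codonLoglik <- function(aln, tree, kappa, pi, classOmega, classProp,
                         wantPosteriors = FALSE, patterns = NULL) {
  ct <- .codonTable()
  td <- .treeData(tree)
  phy <- td$phy
  o <- match(phy$tip.label, aln@taxa)
  if (anyNA(o)) stop("tree tips missing from alignment: ",
                     paste(phy$tip.label[is.na(o)], collapse = ", "))
  if (is.null(patterns)) patterns <- .sitePatterns(aln@codons[o, , drop = FALSE])
  tips <- patterns$patterns
  tips[is.na(tips)] <- 0L
  storage.mode(tips) <- "integer"
  res <- .pd_mixture_loglik(tips, patterns$weights, phy$edge,
                            phy$edge.length, td$part,
                            kappa, pi, classOmega, classProp,
                            ct$step, ct$ti, ct$ns, wantPosteriors)
  res$patterns <- patterns
  res
}

# expected substitution rate of the background mixture (same convention as
# the compiled engine): used to put simulation and likelihood on one scale
.mixtureScaleFactor <- function(kappa, pi, classOmega, classProp) {
  r <- vapply(classOmega[, 1], function(w) {
    Q <- buildRateMatrix(kappa, w, pi, rescale = FALSE)
    -sum(pi * diag(Q))
  }, numeric(1))
  f <- sum(classProp * r)
  if (f < 1e-300) 1 else f
}

# Plain R pruning over arbitrary per-edge transition matrices; generic in
# the number of states. tipStates: ntaxa x nsites integer (NA missing),
# rows ordered as phy$tip.label. Returns per-site log-likelihoods.
.pruneR <- function(phy, tipStates, Plist, rootFreqs) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ns <- length(rootFreqs)
  nsite <- ncol(tipStates)
  ntaxa <- length(phy$tip.label)
  nnode <- ntaxa + phy$Nnode
  partial <- vector("list", nnode)
  logscale <- matrix(0, nnode, nsite)
  tipPartial <- function(i) {
    m <- matrix(1, ns, nsite)
    s <- tipStates[i, ]
    ok <- !is.na(s)
    m[, ok] <- 0
    m[cbind(s[ok], which(ok))] <- 1
    m
  }
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    P <- Plist[[e]]
    chp <- if (ch <= ntaxa) tipPartial(ch) else partial[[ch]]
    msg <- P %*% chp
    if (is.null(partial[[par]])) {
      partial[[par]] <- msg
      logscale[par, ] <- if (ch <= ntaxa) 0 else logscale[ch, ]
    } else {
      partial[[par]] <- partial[[par]] * msg
      if (ch > ntaxa) logscale[par, ] <- logscale[par, ] + logscale[ch, ]
    }
    mx <- apply(partial[[par]], 2L, max)
    mx[mx <= 0] <- 1
    partial[[par]] <- sweep(partial[[par]], 2L, mx, "/")
    logscale[par, ] <- logscale[par, ] + log(mx)
  }
  root <- ntaxa + 1L
  drop(log(rootFreqs %*% partial[[root]])) + logscale[root, ]
}

# per-edge P list for the R pruning path, reordered to postorder
.edgePmats <- function(tree, kappa, pi, omegaByEdge, scaleFactor) {
  td <- .treeData(tree)
  phy <- td$phy
  lapply(seq_len(nrow(phy$edge)), function(e) {
    Q <- buildRateMatrix(kappa, omegaByEdge[e], pi, rescale = FALSE)
    transitionMatrix(Q, phy$edge.length[e] / scaleFactor, pi = pi)
  })
}

#' Single-site pruning log-likelihood
#'
#' Felsenstein-pruning log-likelihood of one codon site given explicit
#' per-edge transition matrices (postorder edge order of
#' \code{ape::reorder.phylo(phy, "postorder")}). Missing codons contribute
#' all-ones partials; a site missing in every taxon has log-likelihood 0.
#'
#' @param aln a \code{\linkS4class{CodonAlignment}}.
#' @param tree a \code{\linkS4class{LabeledTree}} (branch lengths are not
#'   used; the \code{PByEdge} matrices already embody them).
#' @param PByEdge list of 61x61 stochastic matrices, one per postorder edge.
#' @param site 1-based codon site index.
#' @param rootFreqs root state frequencies (default: equal).
#' @return the site log-likelihood (a single number).
#' @export
siteLogLikelihood <- function(aln, tree, PByEdge, site,
                              rootFreqs = rep(1 / 61, 61)) {
  phy <- ape::reorder.phylo(tree@phy, "postorder")
  o <- match(phy$tip.label, aln@taxa)
  if (anyNA(o)) stop("tree tips missing from alignment")
  st <- aln@codons[o, site, drop = FALSE]
  if (length(phy$tip.label) == 1L) {
    s <- st[1, 1]
    return(if (is.na(s)) 0 else log(rootFreqs[s]))
  }
  .pruneR(phy, st, PByEdge, rootFreqs)
}

#' Site-class mixture log-likelihood
#'
#' Log-likelihood of a codon alignment under a site-class mixture: each
#' class has a proportion and one omega per branch partition (background
#' vs foreground). Rate matrices share kappa and codon frequencies and are
#' jointly rescaled by the expected rate of the background mixture.
#'
#' @param aln a \code{\linkS4class{CodonAlignment}}.
#' @param tree a \code{\linkS4class{LabeledTree}} with branch lengths.
#' @param mixture data.frame with columns \code{prop},
#'   \code{omegaBackground}, \code{omegaForeground} (one row per class).
#' @param kappa transition/transversion ratio.
#' @param codonFreqs 61-vector of codon frequencies.
#' @return the total log-likelihood (a single number).
#' @export
mixtureLogLikelihood <- function(aln, tree, mixture, kappa, codonFreqs) {
  stopifnot(all(c("prop", "omegaBackground", "omegaForeground") %in%
                names(mixture)))
  p <- mixture$prop
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("mixture proportions must form a simplex")
  co <- cbind(mixture$omegaBackground, mixture$omegaForeground)
  .codonLoglik(aln, tree, kappa, codonFreqs, co, p)$logLik
}
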