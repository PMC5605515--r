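# canonical bipartition key per edge: the tip set on the child side,
# complemented when it contains the lexicographically smallest tip, so the
# key is invariant to rooting and edge orientation
.edgeKeys <- function(phy) {
  ntip <- length(phy$tip.label)
  ref <- min(phy$tip.label)
  below <- function(node) {
    if (node <= ntip) return(phy$tip.label[node])
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  vapply(seq_len(nrow(phy$edge)), function(e) {
    s <- below(phy$edge[e, 2])
    if (ref %in% s) s <- setdiff(phy$tip.label, s)
    paste(sort(s), collapse = "|")
  }, character(1))
}

# Bounded maximum-likelihood fitting of codon site-class models.
#
# Branch lengths are treated as fixed inputs of a fit (see
# estimateBranchLengths for the recommended two-step profile); an optional
# global scale can be freed. Optimization is L-BFGS-B on log/ALR
# transformed parameters with a cached forward-difference gradient, run
# from several start values of kappa and omega.

.fitControlDefaults <- function(control) {
  utils::modifyList(list(maxit = 500, factr = 1e8, ndeps = 1e-5,
                         warmOnly = FALSE), control)
}

#' Fit a codon site-class model by maximum likelihood
#'
#' Fits one of the catalogued codon models: \code{"M0"} (single ratio),
#' \code{"twoRatio"} / \code{"twoRatioNeutralFg"} (branch models),
#' \code{"modelA"} / \code{"modelANull"} (branch-site, four site classes),
#' \code{"busted"} / \code{"bustedNull"} (three unconstrained classes with
#' the largest foreground omega free or capped at one), \code{"relaxAlt"} /
#' \code{"relaxNull"} (selection-intensity exponent k free or fixed at
#' one). All start-value combinations of \code{starts} are run and the
#' best retained; a spread of best log-likelihoods above 0.01 units across
#' starts is flagged.
#'
#' @param aln a \code{\linkS4class{CodonAlignment}}.
#' @param tree a \code{\linkS4class{LabeledTree}} with branch lengths in
#'   expected substitutions/codon (see \code{\link{estimateBranchLengths}}).
#' @param model model identifier.
#' @param starts list with elements \code{kappa} and \code{omega}: vectors
#'   of initial values; all combinations are run (default the conventional
#'   four: kappa 0.5/3, omega 0.5/2).
#' @param fix named list of parameters to hold fixed at given natural-scale
#'   values (e.g. \code{list(kappa = 2.5)}).
#' @param codonFreqs 61-vector; computed from \code{aln} under
#'   \code{freqModel} when NULL.
#' @param freqModel frequency scheme passed to
#'   \code{\link{buildCodonFrequencies}}.
#' @param optimizeScale also free a global branch-length scale factor.
#' @param optimizeFgScale also free a multiplier on the foreground/test
#'   edge lengths (used by the branch-model chain, where the foreground
#'   substitution load would otherwise be confounded with its omega).
#' @param warmStart optional \code{\linkS4class{CodonFit}} (typically the
#'   null of a nested pair) whose parameters seed an additional start.
#' @param control optimizer control: \code{maxit}, \code{factr},
#'   \code{ndeps}.
#' @return a \code{\linkS4class{CodonFit}}.
#' @export
fitCodonModel <- function(aln, tree, model = .codonModels,
                          starts = list(kappa = c(0.5, 3), omega = c(0.5, 2)),
                          fix = list(), codonFreqs = NULL,
                          freqModel = "F3x4", optimizeScale = FALSE,
                          optimizeFgScale = FALSE,
                          warmStart = NULL, control = list()) {
  model <- match.arg(model)
  control <- .fitControlDefaults(control)
  if (is.null(codonFreqs)) codonFreqs <- buildCodonFrequencies(aln, freqModel)
  if (is.null(tree@phy$edge.length))
    stop("tree must carry branch lengths; see estimateBranchLengths()")

  ct <- .codonTable()
  td <- .treeData(tree)
  phy <- td$phy
  o <- match(phy$tip.label, aln@taxa)
  if (anyNA(o)) stop("tree tips missing from alignment")
  pat <- .sitePatterns(aln@codons[o, , drop = FALSE])
  tips <- pat$patterns
  tips[is.na(tips)] <- 0L
  storage.mode(tips) <- "integer"

  spec <- .parSpec(model)
  if (optimizeScale)
    spec <- c(spec, list(list(name = "scale", lower = log(1e-4),
                              upper = log(1e4), init = log(1))))
  if (optimizeFgScale)
    spec <- c(spec, list(list(name = "fgScale", lower = log(1e-3),
                              upper = log(1e3), init = log(1))))
  free <- Filter(function(s) !(s$name %in% names(fix)), spec)
  lower <- vapply(free, `[[`, numeric(1), "lower")
  upper <- vapply(free, `[[`, numeric(1), "upper")

  evalTheta <- function(theta) {
    par <- .thetaToPar(model, theta, spec, fix)
    if (optimizeScale && is.null(par$scale)) par$scale <- 1
    st <- .modelStructure(model, par)
    el <- phy$edge.length * (par$scale %||% 1)
    if (optimizeFgScale)
      el[td$part == 1L] <- el[td$part == 1L] * (par$fgScale %||% 1)
    res <- tryCatch(
      .pd_mixture_loglik(tips, pat$weights, phy$edge, el, td$part,
                         st$kappa, codonFreqs, st$classOmega, st$classProp,
                         ct$step, ct$ti, ct$ns, FALSE),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$logLik)) return(1e10)
    -res$logLik
  }
  # forward-difference gradient reusing the cached objective value
  lastTheta <- NULL; lastVal <- NULL
  fn <- function(theta) {
    v <- evalTheta(theta)
    lastTheta <<- theta; lastVal <<- v
    v
  }
  gr <- function(theta) {
    f0 <- if (!is.null(lastTheta) && identical(theta, lastTheta)) lastVal
          else evalTheta(theta)
    h <- control$ndeps
    vapply(seq_along(theta), function(i) {
      ti <- theta
      ti[i] <- ti[i] + if (ti[i] + h <= upper[i]) h else -h
      (evalTheta(ti) - f0) / (ti[i] - theta[i])
    }, numeric(1))
  }

  # start grid: all kappa x omega combinations (plus optional warm start)
  thetaFor <- function(k0, w0) {
    vapply(free, function(s) {
      v <- switch(s$name,
        kappa = log(k0),
        omega = , omegaBg = , omegaFg = log(w0),
        omega0 = log(min(w0, 0.9)),
        omega2 = , omega3 = log(max(w0, 1.001)),
        omega_ratio1 = , omegaRatio1 = log(0.5),
        k = log(1),
        s$init)
      min(max(v, s$lower), s$upper)
    }, numeric(1))
  }
  startList <- list()
  warmOnly <- isTRUE(control$warmOnly) && !is.null(warmStart)
  if (!warmOnly)
    for (k0 in starts$kappa) for (w0 in starts$omega)
      startList[[length(startList) + 1L]] <- thetaFor(k0, w0)
  if (!is.null(warmStart)) {
    wp <- warmStart@params$natural
    th <- vapply(free, function(s) {
      v <- wp[[s$name]]
      if (is.null(v)) {
        v <- switch(s$name, omega2 = 1, omega3 = 1, k = 1,
                    omegaFg = wp$omegaBg %||% 0.5, scale = 1,
                    fgScale = 1, NULL)
      }
      if (is.null(v)) return(s$init)
      .toTheta(s, v)
    }, numeric(1))
    startList[[length(startList) + 1L]] <- th
  }

  startList <- startList[!duplicated(lapply(startList, round, 10))]
  fits <- lapply(startList, function(th0) {
    tryCatch(
      optim(th0, fn, gr, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = control$maxit, factr = control$factr)),
      error = function(e) NULL)
  })
  if (!is.null(warmStart)) {
    # the warm-start point itself stays a candidate: when the null optimum
    # lies on the alternative's boundary this guarantees logL_alt >=
    # logL_null exactly
    th <- startList[[length(startList)]]
    fits[[length(fits) + 1L]] <- list(par = th, value = evalTheta(th),
                                      convergence = 0L)
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("optimizer failed on all starts for model ", model)
  vals <- vapply(fits[ok], function(f) -f$value, numeric(1))
  best <- fits[ok][[which.max(vals)]]
  # spread over genuine optimizer runs only (not the warm-start candidate)
  nopt <- length(startList)
  optVals <- vals[seq_len(min(nopt, length(vals)))]
  spread <- if (length(optVals) > 1L) max(optVals) - min(optVals) else 0

  par <- .thetaToPar(model, best$par, spec, fix)
  st <- .modelStructure(model, par)
  wmax <- max(st$classOmega)
  capped <- wmax >= .OMEGA_MAX * (1 - 1e-4)
  new("CodonFit", model = model, logLik = -best$value,
      params = list(natural = par, kappa = st$kappa, k = st$k,
                    codonFreqs = codonFreqs,
                    scale = par$scale %||% 1,
                    startLogLik = vals),
      mixture = st$mixture, converged = best$convergence == 0L,
      nStarts = length(startList), startSpread = spread, capped = capped)
}

#' Estimate branch lengths for codon-model fitting
#'
#' Two-step profile used throughout the package: (1) maximum-likelihood
#' branch lengths under a nucleotide GTR model on the underlying
#' nucleotides (via \pkg{phangorn}), giving the relative edge lengths;
#' (2) a codon M0 fit with a free global scale (and free kappa and omega)
#' that converts them to expected substitutions per codon. The returned
#' tree is then held fixed in all nested model comparisons of a gene, so
#' every pair stays exactly nested.
#'
#' @param aln a \code{\linkS4class{CodonAlignment}}.
#' @param tree a \code{\linkS4class{LabeledTree}} (topology and labels are
#'   kept; any branch lengths are discarded).
#' @param starts start values for the codon-scale step.
#' @return list with \code{tree} (a \code{LabeledTree} with calibrated
#'   branch lengths), \code{m0} (the scaling \code{CodonFit}) and
#'   \code{kappa} (its kappa estimate).
#' @export
estimateBranchLengths <- function(aln, tree,
                                  starts = list(kappa = 2, omega = 0.4)) {
  ct <- .codonTable()
  phy <- tree@phy
  o <- match(phy$tip.label, aln@taxa)
  if (anyNA(o)) stop("tree tips missing from alignment")
  # nucleotide matrix (characters; missing codons as gaps)
  cod <- aln@codons[o, , drop = FALSE]
  ntaxa <- nrow(cod)
  nt <- matrix("-", ntaxa, 3L * ncol(cod))
  bases <- .codonBases
  for (i in seq_len(ntaxa)) {
    okc <- which(!is.na(cod[i, ]))
    for (p in 1:3)
      nt[i, 3L * (okc - 1L) + p] <- bases[ct$nucIndex[cod[i, okc], p]]
  }
  rownames(nt) <- phy$tip.label
  dat <- phangorn::phyDat(nt, type = "DNA")
  phy0 <- phy
  phy0$edge.length <- rep(0.1, nrow(phy0$edge))
  fit0 <- phangorn::pml(phy0, dat)
  fit1 <- suppressWarnings(phangorn::optim.pml(
    fit0, optEdge = TRUE, optQ = TRUE, optBf = TRUE,
    control = phangorn::pml.control(trace = 0, epsilon = 1e-7,
                                    maxit = 20)))
  phyN <- fit1$tree
  # map estimated lengths back onto the original edge order (by the tip
  # bipartition each edge induces; robust to re-rooting/reordering)
  m <- match(.edgeKeys(phy), .edgeKeys(phyN))
  if (anyNA(m)) stop("branch-length estimation changed the topology")
  phy$edge.length <- pmax(phyN$edge.length[m], 1e-8)
  ltree <- new("LabeledTree", phy = phy, labels = tree@labels)
  m0 <- fitCodonModel(aln, ltree, "M0",
                      starts = list(kappa = starts$kappa,
                                    omega = starts$omega),
                      optimizeScale = TRUE)
  s <- m0@params$natural$scale %||% 1
  phy$edge.length <- phy$edge.length * s
  list(tree = new("LabeledTree", phy = phy, labels = tree@labels),
       m0 = m0, kappa = m0@params$kappa)
}
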