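# Likelihood-ratio selection tests: branch-model chain, branch-site test
# with NEB/BEB site posteriors, BUSTED-style episodic test with Bonferroni
# correction, RELAX-style selection-intensity test, and the robustness
# battery over alternative topologies and start values.

#' Chi-square LRT p-value
#'
#' Upper-tail probability of the chi-square distribution with \code{df}
#' degrees of freedom at the statistic \code{twoDeltaL}. Tiny negative
#' statistics (> -1e-6, numerical round-off of a boundary fit) are clamped
#' to zero; larger negative values are an error, since they signal an
#' optimizer failure in a nested pair.
#'
#' @param twoDeltaL twice the log-likelihood difference of nested models.
#' @param df degrees of freedom (>= 1).
#' @return the p-value.
#' @export
#' @examples
#' chi2LrtPvalue(4.02, 1)   # 0.045
chi2LrtPvalue <- function(twoDeltaL, df) {
  stopifnot(df >= 1)
  if (any(twoDeltaL < -1e-6))
    stop("negative LRT statistic beyond round-off tolerance: ",
         min(twoDeltaL))
  twoDeltaL <- pmax(twoDeltaL, 0)
  pchisq(twoDeltaL, df = df, lower.tail = FALSE)
}

.makeLRT <- function(fitNull, fitAlt, df) {
  l0 <- fitNull@logLik; l1 <- fitAlt@logLik
  td <- 2 * (l1 - l0)
  if (td < -1e-6)
    stop("alternative fit worse than null by ", -td / 2,
         " log-units; optimizer failure")
  td <- max(td, 0)
  new("LRTResult", logLikNull = l0, logLikAlt = l1, twoDeltaL = td,
      df = as.integer(df), pValue = chi2LrtPvalue(td, df))
}

# shared preamble: calibrate branch lengths unless told to keep them
.geneTree <- function(aln, tree, branchLengths = c("estimate", "keep")) {
  branchLengths <- match.arg(branchLengths)
  if (branchLengths == "keep" && !is.null(tree@phy$edge.length))
    return(list(tree = tree, kappa = NULL, m0 = NULL))
  bl <- estimateBranchLengths(aln, tree)
  list(tree = bl$tree, kappa = bl$kappa, m0 = bl$m0)
}

#' Branch-model positive selection test
#'
#' Two-stage likelihood ratio chain on the foreground branches: stage 1
#' compares the two-ratio branch model against the one-ratio model (df 1);
#' when stage 1 is significant at \code{alpha}, stage 2 compares the
#' two-ratio model against the same model with the foreground omega fixed
#' at one (df 1). A positively selected gene call requires both stages
#' significant and a fitted foreground omega above one.
#'
#' @param aln a \code{\linkS4class{CodonAlignment}}.
#' @param tree a \code{\linkS4class{LabeledTree}} with foreground edges
#'   labeled.
#' @param alpha significance level (default 0.05, uncorrected).
#' @param starts start-value grid (see \code{\link{fitCodonModel}}).
#' @param branchLengths \code{"estimate"} (default; nucleotide GTR + codon
#'   rescale) or \code{"keep"} (use the lengths on \code{tree}).
#' @param fixKappa FALSE (kappa free in every fit, the default), TRUE
#'   (profile kappa at the branch-length M0 estimate) or a numeric value
#'   to fix kappa at.
#' @return list with \code{stage1}, \code{stage2}
#'   (\code{\linkS4class{LRTResult}} or NULL), \code{omegaFg},
#'   \code{psg} (logical call) and the three fits.
#' @export
branchModelTest <- function(aln, tree, alpha = 0.05,
                            starts = list(kappa = c(0.5, 3),
                                          omega = c(0.5, 2)),
                            branchLengths = "estimate", fixKappa = FALSE) {
  gt <- .geneTree(aln, tree, branchLengths)
  fx <- if (is.numeric(fixKappa)) list(kappa = fixKappa)
        else if (isTRUE(fixKappa) && !is.null(gt$kappa))
          list(kappa = gt$kappa)
        else list()
  f0 <- fitCodonModel(aln, gt$tree, "M0", starts = starts, fix = fx,
                      optimizeFgScale = TRUE)
  f2 <- fitCodonModel(aln, gt$tree, "twoRatio", starts = starts, fix = fx,
                      optimizeFgScale = TRUE, warmStart = f0)
  stage1 <- .makeLRT(f0, f2, 1L)
  stage2 <- NULL
  omegaFg <- f2@mixture$omegaForeground[1]
  psg <- FALSE
  if (stage1@pValue < alpha) {
    f1fg <- fitCodonModel(aln, gt$tree, "twoRatioNeutralFg",
                          starts = starts, fix = fx,
                          optimizeFgScale = TRUE, warmStart = f2)
    stage2 <- .makeLRT(f1fg, f2, 1L)
    psg <- stage2@pValue < alpha && omegaFg > 1
  }
  list(stage1 = stage1, stage2 = stage2, omegaFg = omegaFg, psg = psg,
       fits = list(oneRatio = f0, twoRatio = f2))
}

# site posteriors of the positively selected classes (2a + 2b) of the
# branch-site model, by plug-in NEB or a grid-integrated empirical Bayes
.modelAPosteriors <- function(aln, tree, fitAlt, method = c("NEB", "BEB"),
                              bebGrid = list(nOmega0 = 5, nOmega2 = 5,
                                             nProp = 5)) {
  method <- match.arg(method)
  ct <- .codonTable()
  td <- .treeData(tree)
  phy <- td$phy
  o <- match(phy$tip.label, aln@taxa)
  pat <- .sitePatterns(aln@codons[o, , drop = FALSE])
  tips <- pat$patterns; tips[is.na(tips)] <- 0L
  storage.mode(tips) <- "integer"
  pi <- fitAlt@params$codonFreqs
  kappa <- fitAlt@params$kappa
  evalAt <- function(w0, w2, p) {   # p = (p0, p1, p2a, p2b)
    co <- rbind(c(w0, w0), c(1, 1), c(w0, w2), c(1, w2))
    .pd_mixture_loglik(tips, pat$weights, phy$edge, phy$edge.length,
                       td$part, kappa, pi, co, p, ct$step, ct$ti, ct$ns,
                       TRUE)
  }
  classPost <- function(res, p) {
    lw <- sweep(res$patClassLog, 2L, log(p), "+")
    mx <- apply(lw, 1L, max)
    w <- exp(lw - mx)
    (w[, 3] + w[, 4]) / rowSums(w)
  }
  if (method == "NEB") {
    mixp <- fitAlt@mixture$prop
    res <- evalAt(fitAlt@mixture$omegaBackground[1],
                  fitAlt@mixture$omegaForeground[3], mixp)
    post <- classPost(res, mixp)[pat$map]
  } else {
    g <- bebGrid
    w0g <- (seq_len(g$nOmega0) - 0.5) / g$nOmega0
    w2g <- 1 + 2^(seq_len(g$nOmega2) - 1)        # 2, 3, 5, 9, 17
    n <- g$nProp
    combos <- list(); logml <- c(); posts <- list()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      p0 <- (i - 0.5) / n; p1 <- (j - 0.5) / n
      if (p0 + p1 >= 1) next
      p2 <- 1 - p0 - p1
      p <- c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1))
      for (w0 in w0g) for (w2 in w2g) {
        res <- evalAt(w0, w2, p)
        lw <- sweep(res$patClassLog, 2L, log(p), "+")
        mx <- apply(lw, 1L, max)
        sitelog <- mx + log(rowSums(exp(lw - mx)))
        logml[[length(logml) + 1L]] <- sum(pat$weights * sitelog)
        posts[[length(posts) + 1L]] <- classPost(res, p)
      }
    }
    logml <- unlist(logml)
    wgt <- exp(logml - max(logml))
    wgt <- wgt / sum(wgt)
    postPat <- Reduce(`+`, Map(`*`, posts, wgt))
    post <- postPat[pat$map]
  }
  data.frame(site = seq_along(post), posterior = post, method = method)
}

#' Branch-site positive selection test
#'
#' The branch-site test for episodic positive selection on the foreground
#' branches: the alternative is the four-class branch-site model (classes
#' 2a/2b free to have omega2 >= 1 on the foreground), the null fixes
#' omega2 = 1; the statistic is referred to chi-square with one degree of
#' freedom. Site posteriors for membership in the positively selected
#' classes are computed by naive empirical Bayes (plug-in MLEs) or by a
#' grid-integrated Bayes empirical Bayes approximation.
#'
#' @inheritParams branchModelTest
#' @param posterior \code{"NEB"} (default) or \code{"BEB"}.
#' @return list with \code{lrt}, \code{fitNull}, \code{fitAlt},
#'   \code{omega2}, \code{psg} (logical), and \code{sites} (data.frame of
#'   per-site posteriors).
#' @export
branchSiteTest <- function(aln, tree, alpha = 0.05,
                           starts = list(kappa = c(0.5, 3),
                                         omega = c(0.5, 2)),
                           posterior = "NEB", branchLengths = "estimate",
                           fixKappa = FALSE) {
  gt <- .geneTree(aln, tree, branchLengths)
  fx <- if (is.numeric(fixKappa)) list(kappa = fixKappa)
        else if (isTRUE(fixKappa) && !is.null(gt$kappa))
          list(kappa = gt$kappa)
        else list()
  fitNull <- fitCodonModel(aln, gt$tree, "modelANull", starts = starts,
                           fix = fx)
  fitAlt <- fitCodonModel(aln, gt$tree, "modelA", starts = starts,
                          fix = fx, warmStart = fitNull,
                          control = list(warmOnly = TRUE))
  lrt <- .makeLRT(fitNull, fitAlt, 1L)
  omega2 <- fitAlt@mixture$omegaForeground[3]
  sites <- .modelAPosteriors(aln, gt$tree, fitAlt, posterior)
  list(lrt = lrt, fitNull = fitNull, fitAlt = fitAlt, omega2 = omega2,
       psg = lrt@pValue < alpha && omega2 > 1, sites = sites,
       tree = gt$tree)
}

#' BUSTED-style episodic selection test
#'
#' Three site classes with omega1 <= omega2 <= 1; the third class is free
#' (>= 1) on the foreground branches in the alternative and capped at one
#' in the null (background branches never exceed one). The statistic is
#' referred to chi-square with one degree of freedom and the p-value is
#' Bonferroni-adjusted for the number of genes tested.
#'
#' @inheritParams branchModelTest
#' @param nTests number of tests in the battery for the Bonferroni
#'   correction (corrected p = min(1, p * nTests)).
#' @return list with \code{lrt}, \code{correctedP}, \code{omega3},
#'   \code{psg} (significant after correction), and the two fits.
#' @export
bustedTest <- function(aln, tree, nTests = 1, alpha = 0.05,
                       starts = list(kappa = c(0.5, 3), omega = c(0.5, 2)),
                       branchLengths = "estimate", fixKappa = FALSE) {
  gt <- .geneTree(aln, tree, branchLengths)
  fx <- if (is.numeric(fixKappa)) list(kappa = fixKappa)
        else if (isTRUE(fixKappa) && !is.null(gt$kappa))
          list(kappa = gt$kappa)
        else list()
  fitNull <- fitCodonModel(aln, gt$tree, "bustedNull", starts = starts,
                           fix = fx)
  fitAlt <- fitCodonModel(aln, gt$tree, "busted", starts = starts,
                          fix = fx, warmStart = fitNull,
                          control = list(warmOnly = TRUE))
  lrt <- .makeLRT(fitNull, fitAlt, 1L)
  correctedP <- min(1, lrt@pValue * nTests)
  omega3 <- fitAlt@mixture$omegaForeground[3]
  list(lrt = lrt, correctedP = correctedP, omega3 = omega3,
       psg = correctedP < alpha && omega3 > 1,
       fits = list(null = fitNull, alt = fitAlt))
}

#' RELAX-style selection intensity test
#'
#' Test branches share the reference omega distribution raised to the
#' power k (the selection intensity). The null fixes k = 1; the
#' alternative frees k in [0.01, 50]; df = 1. k < 1 with a significant
#' test is relaxation (omegas converge to neutrality), k > 1
#' intensification.
#'
#' @inheritParams branchModelTest
#' @param tree a \code{\linkS4class{LabeledTree}} whose test branches are
#'   labeled \code{"test"}; unlabeled branches form the reference set.
#' @return list with \code{k}, \code{lrt}, \code{classification}
#'   (\code{"relaxed"}, \code{"intensified"} or \code{"ns"}), and fits.
#' @export
relaxTest <- function(aln, tree, alpha = 0.05,
                      starts = list(kappa = c(0.5, 3), omega = c(0.5, 2)),
                      branchLengths = "estimate", fixKappa = FALSE) {
  gt <- .geneTree(aln, tree, branchLengths)
  fx <- if (is.numeric(fixKappa)) list(kappa = fixKappa)
        else if (isTRUE(fixKappa) && !is.null(gt$kappa))
          list(kappa = gt$kappa)
        else list()
  fitNull <- fitCodonModel(aln, gt$tree, "relaxNull", starts = starts,
                           fix = fx)
  fitAlt <- fitCodonModel(aln, gt$tree, "relaxAlt", starts = starts,
                          fix = fx, warmStart = fitNull)
  lrt <- .makeLRT(fitNull, fitAlt, 1L)
  k <- fitAlt@params$k
  cls <- if (lrt@pValue >= alpha) "ns"
         else if (k < 1) "relaxed" else "intensified"
  list(k = k, lrt = lrt, classification = cls,
       fits = list(null = fitNull, alt = fitAlt))
}

#' Robustness battery over topologies and start values
#'
#' Reruns a selection test under alternative tree topologies with the full
#' start-value grid. A call is labeled robust only when it is significant
#' under every topology; runs whose best log-likelihoods spread more than
#' 0.01 units across starts are flagged.
#'
#' @param aln a \code{\linkS4class{CodonAlignment}}.
#' @param trees list of \code{\linkS4class{LabeledTree}} objects (the
#'   alternative topologies, foreground already labeled).
#' @param test \code{"branchSite"}, \code{"branchModel"} or
#'   \code{"busted"}.
#' @param alpha significance level.
#' @param starts start-value grid (default the conventional four).
#' @param branchLengths passed to the test.
#' @return data.frame with one row per topology plus attributes
#'   \code{robust} (logical) and \code{discordant} (logical).
#' @export
robustnessBattery <- function(aln, trees, test = c("branchSite",
                                                   "branchModel", "busted"),
                              alpha = 0.05,
                              starts = list(kappa = c(0.5, 3),
                                            omega = c(0.5, 2)),
                              branchLengths = "estimate") {
  test <- match.arg(test)
  rows <- lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    res <- switch(test,
      branchSite = {
        r <- branchSiteTest(aln, tr, alpha, starts,
                            branchLengths = branchLengths)
        data.frame(topology = i, p = r$lrt@pValue, psg = r$psg,
                   startSpreadFlag = r$fitAlt@startSpread > 0.01)
      },
      branchModel = {
        r <- branchModelTest(aln, tr, alpha, starts,
                             branchLengths = branchLengths)
        data.frame(topology = i, p = r$stage1@pValue, psg = r$psg,
                   startSpreadFlag = r$fits$twoRatio@startSpread > 0.01)
      },
      busted = {
        r <- bustedTest(aln, tr, 1, alpha, starts,
                        branchLengths = branchLengths)
        data.frame(topology = i, p = r$lrt@pValue, psg = r$psg,
                   startSpreadFlag = r$fits$alt@startSpread > 0.01)
      })
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "robust") <- all(out$psg)
  attr(out, "discordant") <- length(unique(out$psg)) > 1L
  out
}
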