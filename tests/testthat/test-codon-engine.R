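test_that("codon frequency models behave as defined", {
  aln <- exampleToyAlignment()
  fe <- buildCodonFrequencies(aln, "equal")
  expect_equal(unname(fe), rep(1 / 61, 61))

  mono <- codonAlignment(c(a = "AAAAAAAAA", b = "AAAAAAAAA"))
  f61 <- buildCodonFrequencies(mono, "F61", pseudocount = 0)
  expect_equal(unname(f61["AAA"]), 1)
  expect_equal(sum(f61), 1)

  # F3x4 equals the hand-computed position-frequency product
  f34 <- buildCodonFrequencies(aln, "F3x4")
  cods <- senseCodons()
  obs <- cods[aln@codons[!is.na(aln@codons)]]
  posf <- sapply(1:3, function(p) {
    tab <- table(factor(substr(obs, p, p), levels = c("T", "C", "A", "G")))
    (tab + 1e-8) / sum(tab + 1e-8)
  })
  hand <- posf[substr(cods, 1, 1), 1] * posf[substr(cods, 2, 2), 2] *
    posf[substr(cods, 3, 3), 3]
  hand <- hand / sum(hand)
  expect_equal(unname(f34), unname(hand), tolerance = 1e-12)
})

test_that("rate matrix has GY structure, reversibility and unit scaling", {
  pi <- buildCodonFrequencies(exampleToyAlignment(), "F3x4")
  Q <- buildRateMatrix(2.5, 0.4, pi)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  M <- pi * Q                                    # pi_i q_ij
  expect_lt(max(abs(M - t(M))), 1e-14)           # detailed balance
  expect_equal(sum(pi * -diag(Q)), 1, tolerance = 1e-12)

  # omega = 0 kills exactly the nonsynonymous entries
  Q0 <- buildRateMatrix(2, 0, rep(1 / 61, 61), rescale = FALSE)
  cods <- codonInfo$codons
  aa <- codonInfo$aa
  for (i in seq_len(61)) for (j in seq_len(61)) {
    if (i == j) next
    d <- mapply(function(x, y) x != y, strsplit(cods[i], "")[[1]],
                strsplit(cods[j], "")[[1]])
    if (sum(d) != 1L) {
      expect_identical(Q0[i, j], 0)
    } else if (aa[i] != aa[j]) {
      expect_identical(Q0[i, j], 0)
    }
  }

  # kappa/omega structure against the brute-force pair classifier:
  # AAA->AAG is a synonymous transition, AAA->AAT a nonsynonymous
  # transversion, so the ratio is kappa / omega
  Qk <- buildRateMatrix(2, 0.5, rep(1 / 61, 61), rescale = FALSE)
  expect_equal(Qk["AAA", "AAG"] / Qk["AAA", "AAT"], 2 / 0.5,
               tolerance = 1e-12)

  expect_error(buildRateMatrix(2, 0.5, rep(1, 61)), "summing to 1")
})

test_that("transition matrix: identity, semigroup and ergodic limits", {
  pi <- rep(1 / 61, 61)
  Q <- buildRateMatrix(2, 0.5, pi)
  expect_equal(transitionMatrix(Q, 0, pi), diag(61), tolerance = 1e-12,
               ignore_attr = TRUE)
  P1 <- transitionMatrix(Q, 0.17, pi)
  P2 <- transitionMatrix(Q, 0.4, pi)
  P12 <- transitionMatrix(Q, 0.57, pi)
  expect_equal(P1 %*% P2, P12, tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(max(abs(rowSums(P1) - 1)), 1e-10)
  Pbig <- transitionMatrix(Q, 500, pi)
  expect_lt(max(abs(sweep(Pbig, 2, pi, "-"))), 1e-6)
  expect_error(transitionMatrix(Q, -1, pi), ">= 0")
})

test_that("pruning equals exhaustive state enumeration on small trees", {
  pi <- rep(1 / 61, 61)
  for (cse in list(
    list(tree = readLabeledTree(text = "((A:0.12,B:0.2):0.1,C:0.3);"),
         n = 2),
    list(tree = fourTaxonTree(), n = 3))) {
    tree <- cse$tree
    mix <- data.frame(prop = 1, omegaBackground = 0.4,
                      omegaForeground = 0.4)
    sim <- simulateCodonAlignment(tree, mix, kappa = 1.7, nCodons = 2,
                                  seed = 2)
    phy <- ape::reorder.phylo(treePhylo(tree), "postorder")
    f <- photodiel:::.mixtureScaleFactor(1.7, pi, cbind(0.4, 0.4), 1)
    Pl <- photodiel:::.edgePmats(tree, 1.7, pi,
                                 rep(0.4, nrow(phy$edge)), f)
    o <- match(phy$tip.label, taxonNames(sim$alignment))
    cod <- codonMatrix(sim$alignment)[o, , drop = FALSE]
    for (s in 1:2) {
      pruned <- siteLogLikelihood(sim$alignment, tree, Pl, s, pi)
      brute <- bruteSiteLogLik(phy, cod[, s], Pl, pi)
      expect_equal(pruned, brute, tolerance = 1e-10)
    }
  }
})

test_that("single-taxon and all-missing sites have closed-form likelihood", {
  a <- codonAlignment(c(solo = "ATG"))
  tree <- new("LabeledTree",
              phy = structure(list(edge = matrix(numeric(0), 0, 2),
                                   tip.label = "solo", Nnode = 0L),
                              class = "phylo"),
              labels = character(0))
  pi <- rep(1 / 61, 61)
  expect_equal(siteLogLikelihood(a, tree, list(), 1, pi),
               log(pi[match("ATG", senseCodons())]))

  # a site missing in every taxon contributes likelihood one
  lt <- toyTree()
  aMiss <- codonAlignment(c(A = "ATGNNN", B = "ATGNNN", C = "ATGNNN",
                            D = "ATGNNN", E = "ATGNNN"))
  mix <- data.frame(prop = 1, omegaBackground = 0.3, omegaForeground = 0.3)
  llBoth <- mixtureLogLikelihood(aMiss, lt, mix, 2, pi)
  aOne <- codonAlignment(c(A = "ATG", B = "ATG", C = "ATG", D = "ATG",
                           E = "ATG"))
  llOne <- mixtureLogLikelihood(aOne, lt, mix, 2, pi)
  expect_equal(llBoth, llOne, tolerance = 1e-10)
})

test_that("mixture likelihood collapses and matches per-class brute force", {
  lt <- toyTree(fg = TRUE)
  pi <- rep(1 / 61, 61)
  mix1 <- data.frame(prop = 1, omegaBackground = 0.3,
                     omegaForeground = 0.3)
  sim <- simulateCodonAlignment(lt, mix1, nCodons = 30, seed = 4)
  ll1 <- mixtureLogLikelihood(sim$alignment, lt, mix1, 2, pi)
  # two identical classes at 0.5/0.5 equal the single-class value
  mix2 <- data.frame(prop = c(0.5, 0.5), omegaBackground = c(0.3, 0.3),
                     omegaForeground = c(0.3, 0.3))
  expect_equal(mixtureLogLikelihood(sim$alignment, lt, mix2, 2, pi), ll1,
               tolerance = 1e-10)

  # four-class branch-site structure equals the independent per-class sum
  mixA <- branchSiteMixture(6)
  simA <- simulateCodonAlignment(lt, mixA, nCodons = 25, seed = 5)
  llEngine <- mixtureLogLikelihood(simA$alignment, lt, mixA, 2, pi)
  f <- photodiel:::.mixtureScaleFactor(
    2, pi, cbind(mixA$omegaBackground, mixA$omegaForeground), mixA$prop)
  td <- photodiel:::.treeData(lt)
  o <- match(td$phy$tip.label, taxonNames(simA$alignment))
  cod <- codonMatrix(simA$alignment)[o, , drop = FALSE]
  perClass <- sapply(seq_len(nrow(mixA)), function(c) {
    om <- ifelse(td$part == 1, mixA$omegaForeground[c],
                 mixA$omegaBackground[c])
    Pl <- photodiel:::.edgePmats(lt, 2, pi, om, f)
    photodiel:::.pruneR(td$phy, cod, Pl, pi)
  })
  llBrute <- sum(log(exp(perClass) %*% mixA$prop))
  expect_equal(llEngine, llBrute, tolerance = 1e-8)
})

test_that("likelihood is invariant to root placement and missing taxa", {
  pi <- rep(1 / 61, 61)
  mix <- data.frame(prop = 1, omegaBackground = 0.3, omegaForeground = 0.3)
  base <- "((A:0.1,B:0.2):0.15,(C:0.3,D:0.1):0.2,E:0.25);"
  lt <- readLabeledTree(text = base)
  sim <- simulateCodonAlignment(lt, mix, nCodons = 40, seed = 8)
  ll0 <- mixtureLogLikelihood(sim$alignment, lt, mix, 2, pi)
  phy <- treePhylo(lt)
  for (node in c(7, 8)) {
    re <- ape::root(phy, node = node, resolve.root = TRUE)
    ltr <- new("LabeledTree", phy = re,
               labels = rep("background", nrow(re$edge)))
    expect_equal(mixtureLogLikelihood(sim$alignment, ltr, mix, 2, pi),
                 ll0, tolerance = 1e-8)
  }

  # an all-missing extra taxon does not change the likelihood
  aPlus <- codonAlignment(c(codonStrings(sim$alignment),
                            X = strrep("NNN", nCodonSites(sim$alignment))))
  ltX <- readLabeledTree(
    text = "((A:0.1,B:0.2):0.15,(C:0.3,D:0.1):0.2,(E:0.15,X:0.1):0.1);")
  llX <- mixtureLogLikelihood(aPlus, ltX, mix, 2, pi)
  ltE <- readLabeledTree(
    text = "((A:0.1,B:0.2):0.15,(C:0.3,D:0.1):0.2,E:0.25);")
  llE <- mixtureLogLikelihood(sim$alignment, ltE, mix, 2, pi)
  expect_equal(llX, llE, tolerance = 1e-8)
})

test_that("M0 fitting recovers the generating omega and is deterministic", {
  st <- focalSpeciesTree("A")
  lt <- new("LabeledTree", phy = st$phy,
            labels = rep("background", nrow(st$phy$edge)))
  mix <- data.frame(prop = 1, omegaBackground = 0.2, omegaForeground = 0.2)
  sim <- simulateCodonAlignment(lt, mix, kappa = 2, nCodons = 500,
                                seed = 7)
  f1 <- fitCodonModel(sim$alignment, lt, "M0",
                      starts = list(kappa = 2, omega = 0.5))
  expect_gt(f1@mixture$omegaBackground[1], 0.15)
  expect_lt(f1@mixture$omegaBackground[1], 0.25)
  expect_true(f1@converged)
  f2 <- fitCodonModel(sim$alignment, lt, "M0",
                      starts = list(kappa = 2, omega = 0.5))
  expect_equal(f1@logLik, f2@logLik, tolerance = 1e-8)

  # nested models never lose likelihood, and an omega fixed at the cap is
  # flagged
  fg <- labeledFromClade(st$phy, st$clades$Simiiformes)
  fn <- fitCodonModel(sim$alignment, fg, "modelANull",
                      starts = list(kappa = 2, omega = 0.5))
  fa <- fitCodonModel(sim$alignment, fg, "modelA",
                      starts = list(kappa = 2, omega = 0.5),
                      warmStart = fn, control = list(warmOnly = TRUE))
  expect_gte(fa@logLik, fn@logLik)
  fcap <- fitCodonModel(sim$alignment, lt, "M0",
                        starts = list(kappa = 2, omega = 0.5),
                        fix = list(omega = 999))
  expect_true(fcap@capped)
})
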