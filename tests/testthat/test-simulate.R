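test_that("simulation is seed-deterministic and leaves the caller's RNG
           alone", {
  lt <- toyTree()
  mix <- data.frame(prop = 1, omegaBackground = 0.3, omegaForeground = 0.3)
  set.seed(99); before <- runif(1)
  set.seed(99)
  s1 <- simulateCodonAlignment(lt, mix, nCodons = 50, seed = 5)
  after <- runif(1)
  expect_identical(before, after)   # caller RNG stream untouched
  s2 <- simulateCodonAlignment(lt, mix, nCodons = 50, seed = 5)
  expect_identical(s1$alignment@codons, s2$alignment@codons)
  s3 <- simulateCodonAlignment(lt, mix, nCodons = 50, seed = 6)
  expect_false(identical(s1$alignment@codons, s3$alignment@codons))
})

test_that("zero-length edges copy states and omega = 0 forbids
           nonsynonymous change", {
  lt0 <- readLabeledTree(text = "((A:0,B:0.2):0.1,C:0.3,D:0.2);")
  mix <- data.frame(prop = 1, omegaBackground = 0.4, omegaForeground = 0.4)
  sim <- simulateCodonAlignment(lt0, mix, nCodons = 80, seed = 2)
  phy <- ape::reorder.phylo(treePhylo(lt0), "postorder")
  e0 <- which(phy$edge.length == 0)
  par <- phy$edge[e0, 1]; ch <- phy$edge[e0, 2]
  parStates <- sim$nodeStates[as.character(par), ]
  chStates <- codonMatrix(sim$alignment)[phy$tip.label[ch], ]
  expect_identical(unname(chStates), unname(parStates))

  mix0 <- data.frame(prop = 1, omegaBackground = 0, omegaForeground = 0)
  sim0 <- simulateCodonAlignment(toyTree(), mix0, nCodons = 120, seed = 4)
  cod <- codonMatrix(sim0$alignment)
  aa <- apply(cod, 1:2, function(i) codonInfo$aa[i])
  for (i in 1:4) for (j in (i + 1):5)
    expect_identical(unname(aa[i, ]), unname(aa[j, ]))
})

test_that("pair frequencies on a long two-taxon alignment match pi P(t)", {
  lt <- readLabeledTree(text = "(A:0.15,B:0.15);")
  mix <- data.frame(prop = 1, omegaBackground = 0.5, omegaForeground = 0.5)
  n <- 50000
  sim <- simulateCodonAlignment(lt, mix, kappa = 2, nCodons = n, seed = 10)
  pi <- rep(1 / 61, 61)
  f <- photodiel:::.mixtureScaleFactor(2, pi, cbind(0.5, 0.5), 1)
  Q <- buildRateMatrix(2, 0.5, pi, rescale = FALSE)
  P <- transitionMatrix(Q, 0.3 / f, pi = pi)    # A to B via the root
  cod <- codonMatrix(sim$alignment)
  joint <- pi * P                                # expected pair density
  obs <- table(factor(cod[1, ], levels = 1:61),
               factor(cod[2, ], levels = 1:61)) / n
  se <- sqrt(joint * (1 - joint) / n)
  dev <- abs(obs - joint) / pmax(se, 1e-12)
  keep <- joint > 1e-5
  # simultaneous bound over the ~3700 compared cells (99.9% family level)
  bound <- qnorm(1 - 0.001 / (2 * sum(keep)))
  expect_lt(max(dev[keep]), bound)
})

test_that("RELAX datasets exponentiate the test-branch omegas", {
  st <- focalSpeciesTree("A")
  tr <- labeledFromClade(st$phy, st$clades$Primates, tag = "test")
  s1 <- simulateRelaxDataset(tr, k = 1, baseOmegas = c(0.2, 1, 2),
                             proportions = c(0.7, 0.2, 0.1),
                             nCodons = 40, seed = 3)
  plain <- simulateCodonAlignment(tr,
    data.frame(prop = c(0.7, 0.2, 0.1), omegaBackground = c(0.2, 1, 2),
               omegaForeground = c(0.2, 1, 2)), nCodons = 40, seed = 3)
  expect_identical(s1$alignment@codons, plain$alignment@codons)
  s3 <- simulateRelaxDataset(tr, k = 3, baseOmegas = c(0.2, 1, 2),
                             proportions = c(0.7, 0.2, 0.1),
                             nCodons = 10, seed = 3)
  expect_equal(s3$mixture$omegaForeground, c(0.008, 1, 8))
})

test_that("diel study generation is consistent with its history", {
  # no state changes anywhere: no gene carries foreground selection
  flat <- defaultDielHistory()
  flat[] <- "diurnal"
  s <- generateDielStudy(history = flat, rootPrior = "diurnal",
                         nCodons = 30, seed = 1)
  expect_equal(nrow(s$trueRegimes), 0L)

  study <- generateDielStudy(nCodons = 30, seed = 42)
  # every cathemeral state change carries one cone and one rod gene
  reg <- merge(study$trueRegimes, study$annotation, by = "gene")
  cat1 <- reg[reg$branch == "Simiiformes", ]
  expect_setequal(cat1$class, c("cone", "rod"))
  # regimes only on state-change branches, with the configured effect
  expect_true(all(reg$omega2 == 8))

  # oracle PSG calls reproduce the generating history exactly
  oracle <- propagateStates(oraclePsgCalls(study), study$annotation)
  expect_equal(compareHistories(oracle, study$history)$fractionCorrect, 1)
})

test_that("amino-acid simulation records true ancestors and obeys limits", {
  phy0 <- ape::read.tree(text = "(a:0,b:0,c:0);")
  s0 <- simulateAAAlignment(phy0, "Poisson", nSites = 30, seed = 1)
  rootSeq <- paste(s0$ancestral[1, ], collapse = "")
  expect_true(all(s0$alignment == rootSeq))

  # long star branches drive the composition toward the model equilibrium
  phyL <- ape::read.tree(text = "(a:30,b:30,c:30);")
  sL <- simulateAAAlignment(phyL, "Poisson", nSites = 20000, seed = 2)
  freq <- table(strsplit(paste(sL$alignment, collapse = ""), "")[[1]])
  expect_lt(max(abs(freq / sum(freq) - 1 / 20)), 0.01)

  # reconstruction is more accurate on shallow than on deep trees
  shallow <- ape::read.tree(
    text = "((a:0.05,b:0.05):0.05,(c:0.05,d:0.05):0.05);")
  deep <- ape::read.tree(text = "((a:0.5,b:0.5):0.5,(c:0.5,d:0.5):0.5);")
  acc <- function(phy) {
    sim <- simulateAAAlignment(phy, "Poisson", nSites = 300, seed = 9)
    rec <- reconstructAncestors(sim$alignment, sim$tree, "Poisson",
                                estimateBranchLengths = FALSE)
    mean(rec$best == sim$ancestral[rownames(rec$best), ])
  }
  expect_gt(acc(shallow), acc(deep))
})
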