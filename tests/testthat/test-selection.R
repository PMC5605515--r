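test_that("chi-square LRT p-values are correct and monotone", {
  expect_equal(chi2LrtPvalue(0, 1), 1)
  expect_equal(chi2LrtPvalue(3.84, 1), pchisq(3.84, 1, lower.tail = FALSE))
  x <- seq(0.1, 20, length.out = 40)
  p <- chi2LrtPvalue(x, 1)
  expect_true(all(diff(p) < 0))
  expect_equal(chi2LrtPvalue(-1e-8, 1), 1)    # round-off clamped
  expect_error(chi2LrtPvalue(-0.01, 1), "negative")
})

test_that("Bonferroni correction respects its bounds", {
  st <- focalSpeciesTree("A")
  tr <- labeledFromClade(st$phy, st$clades$Simiiformes)
  mixE <- data.frame(prop = c(0.6, 0.3, 0.1),
                     omegaBackground = c(0.05, 0.5, 1),
                     omegaForeground = c(0.05, 0.5, 9))
  sim <- simulateCodonAlignment(tr, mixE, nCodons = 300, seed = 5)
  r <- bustedTest(sim$alignment, tr, nTests = 33, fixKappa = TRUE,
                  starts = list(kappa = 2, omega = 0.5))
  expect_gte(r$correctedP, r$lrt@pValue)
  expect_lte(r$correctedP, 1)
  expect_equal(r$correctedP, min(1, r$lrt@pValue * 33))
  # the episodic simulation is detected at the raw level
  expect_lt(r$lrt@pValue, 0.05)
})

test_that("branch model chain detects foreground selection and the
           constrained alternative is a null identity", {
  st <- focalSpeciesTree("A")
  tr <- labeledFromClade(st$phy, st$clades$Simiiformes)
  mix <- data.frame(prop = 1, omegaBackground = 0.2, omegaForeground = 4)
  sim <- simulateCodonAlignment(tr, mix, nCodons = 600, seed = 11)
  r <- branchModelTest(sim$alignment, tr, fixKappa = TRUE,
                       starts = list(kappa = 2, omega = 0.5))
  expect_lt(r$stage1@pValue, 0.05)
  expect_false(is.null(r$stage2))
  expect_lt(r$stage2@pValue, 0.05)
  expect_gt(r$omegaFg, 1)
  expect_true(r$psg)

  # comparing a fit against itself gives a zero statistic
  id <- photodiel:::.makeLRT(r$fits$oneRatio, r$fits$oneRatio, 1L)
  expect_equal(id@twoDeltaL, 0)
  expect_equal(id@pValue, 1)
})

test_that("branch-site test finds selected sites where simulated and not
           on mislabeled foregrounds", {
  st <- focalSpeciesTree("A")
  tr <- labeledFromClade(st$phy, st$clades$Simiiformes)
  mixA <- branchSiteMixture(8)
  sim <- simulateCodonAlignment(tr, mixA, nCodons = 300, seed = 21)
  r <- branchSiteTest(sim$alignment, tr, fixKappa = TRUE,
                      starts = list(kappa = 2, omega = 0.5))
  expect_lt(r$lrt@pValue, 0.05)
  expect_gt(r$omega2, 1)
  truly <- which(sim$siteClass >= 3)
  expect_gte(max(r$sites$posterior[truly]), 0.9)

  # same data, foreground moved to an unrelated branch: signal vanishes
  wrong <- labeledFromClade(st$phy, st$clades$Glires)
  ps <- vapply(1:3, function(i) {
    simW <- simulateCodonAlignment(tr, mixA, nCodons = 300,
                                   seed = 300 + i)
    rw <- branchSiteTest(simW$alignment, wrong, fixKappa = TRUE,
                         starts = list(kappa = 2, omega = 0.5))
    rw$lrt@pValue
  }, numeric(1))
  expect_gte(sum(ps > 0.05), 2L)
})

test_that("NEB and BEB site posteriors agree on well-separated data", {
  st <- focalSpeciesTree("A")
  tr <- labeledFromClade(st$phy, st$clades$Simiiformes)
  sim <- simulateCodonAlignment(tr, branchSiteMixture(8), nCodons = 300,
                                seed = 21)
  r <- branchSiteTest(sim$alignment, tr, fixKappa = TRUE,
                      starts = list(kappa = 2, omega = 0.5))
  beb <- photodiel:::.modelAPosteriors(sim$alignment, r$tree, r$fitAlt,
                                       "BEB")
  expect_true(all(beb$posterior >= 0 & beb$posterior <= 1))
  expect_lt(mean(abs(r$sites$posterior - beb$posterior)), 0.15)
})

test_that("RELAX recovers relaxation and intensification; k = 1 is exact", {
  st <- focalSpeciesTree("A")
  tr <- labeledFromClade(st$phy, st$clades$Primates, tag = "test")
  simR <- simulateRelaxDataset(tr, k = 0.2, nCodons = 400, seed = 13)
  r <- relaxTest(simR$alignment, tr, fixKappa = TRUE,
                 starts = list(kappa = 2, omega = 0.5))
  expect_lt(r$k, 1)
  expect_lt(r$lrt@pValue, 0.05)
  expect_equal(r$classification, "relaxed")

  # k = 3 intensification recovered within a factor
  simI <- simulateRelaxDataset(tr, k = 3, nCodons = 400, seed = 13)
  ri <- relaxTest(simI$alignment, tr, fixKappa = TRUE,
                  starts = list(kappa = 2, omega = 0.5))
  expect_gt(ri$k, 1.5)
  expect_lt(ri$k, 6)
  expect_equal(ri$classification, "intensified")

  # alternative evaluated at k fixed to 1 equals the null exactly
  gt <- photodiel:::.geneTree(simR$alignment, tr, "keep")
  fn <- fitCodonModel(simR$alignment, gt$tree, "relaxNull",
                      starts = list(kappa = 2, omega = 0.5))
  pn <- fn@params$natural
  fa <- fitCodonModel(simR$alignment, gt$tree, "relaxAlt",
                      starts = list(kappa = 2, omega = 0.5),
                      fix = c(pn[c("kappa", "omegaRatio1", "omega2",
                                   "omega3", "alr0", "alr1")],
                              list(k = 1)),
                      control = list(maxit = 0))
  expect_identical(fa@logLik, fn@logLik)

  # k = 0 simulation drives the test-branch omegas to neutrality
  sim0 <- simulateRelaxDataset(tr, k = 0, nCodons = 10, seed = 1)
  expect_equal(sim0$mixture$omegaForeground, c(1, 1, 1))
})

test_that("robustness battery reports per-topology calls and start flags", {
  stA <- focalSpeciesTree("A")
  stB <- focalSpeciesTree("B")
  trA <- labeledFromClade(stA$phy, stA$clades$Simiiformes)
  trB <- labeledFromClade(stB$phy, stB$clades$Simiiformes)
  sim <- simulateCodonAlignment(trA, branchSiteMixture(8), nCodons = 300,
                                seed = 21)
  rep <- robustnessBattery(sim$alignment, list(trA, trB),
                           test = "branchSite",
                           starts = list(kappa = c(0.5, 3),
                                         omega = c(0.5, 2)))
  expect_equal(nrow(rep), 2L)
  expect_type(attr(rep, "robust"), "logical")
  expect_identical(attr(rep, "discordant"),
                   length(unique(rep$psg)) > 1L)
  # the foreground clade exists in both topologies: calls agree
  expect_true(attr(rep, "robust") || !any(rep$psg))
})
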