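star3 <- ape::read.tree(text = "(t1:0.1,t2:0.1,t3:0.1);")

test_that("marginal reconstruction matches the exhaustive Bayes sum", {
  rec <- reconstructAncestors(c(t1 = "A", t2 = "A", t3 = "V"), star3,
                              "Poisson", estimateBranchLengths = FALSE)
  m <- aminoAcidModel("Poisson")
  P <- transitionMatrix(m$Q, 0.1, pi = m$pi)
  ia <- match(c("A", "A", "V"), m$alphabet)
  brute <- vapply(1:20, function(r) m$pi[r] * prod(P[r, ia]), numeric(1))
  brute <- brute / sum(brute)
  expect_equal(unname(rec$posterior[["4"]][, 1]), brute,
               tolerance = 1e-10)
  expect_equal(unname(rec$best[1, 1]), "A")

  # unanimous tips give near-certain ancestors on short branches
  rec2 <- reconstructAncestors(c(t1 = "AAAA", t2 = "AAAA", t3 = "AAAA"),
                               star3, "Poisson",
                               estimateBranchLengths = FALSE)
  expect_gt(min(rec2$maxPosterior), 0.99)
})

test_that("posteriors are normalized and invariant to taxon input order", {
  sim <- simulateAAAlignment(ape::read.tree(
    text = "((a:0.2,b:0.3):0.1,(c:0.15,d:0.25):0.1);"), "JTT",
    nSites = 60, seed = 3)
  rec <- reconstructAncestors(sim$alignment, sim$tree, "JTT",
                              estimateBranchLengths = FALSE)
  for (p in rec$posterior)
    expect_lt(max(abs(colSums(p) - 1)), 1e-9)
  recPerm <- reconstructAncestors(sim$alignment[c(3, 1, 4, 2)], sim$tree,
                                  "JTT", estimateBranchLengths = FALSE)
  expect_equal(rec$best, recPerm$best)
  expect_equal(rec$maxPosterior, recPerm$maxPosterior, tolerance = 1e-10)
})

test_that("short-branch reconstruction converges to the majority state", {
  tiny <- ape::read.tree(text = "(t1:0.001,t2:0.001,t3:0.001);")
  rec <- reconstructAncestors(c(t1 = "L", t2 = "L", t3 = "P"), tiny,
                              "Poisson", estimateBranchLengths = FALSE)
  expect_equal(unname(rec$best[1, 1]), "L")
  expect_gt(rec$maxPosterior[1, 1], 0.95)
})

test_that("JTT and Poisson reconstructions are compared, not conflated", {
  sim <- simulateAAAlignment(ape::read.tree(
    text = "((a:0.6,b:0.7):0.3,(c:0.5,d:0.8):0.2);"), "JTT",
    nSites = 80, seed = 9)
  rj <- reconstructAncestors(sim$alignment, sim$tree, "JTT",
                             estimateBranchLengths = FALSE)
  rp <- reconstructAncestors(sim$alignment, sim$tree, "Poisson",
                             estimateBranchLengths = FALSE)
  expect_identical(dim(rj$best), dim(rp$best))
  expect_identical(rj$model, "JTT")
  expect_identical(rp$model, "Poisson")
})

test_that("bovine position map is monotone and handles indels", {
  ref <- bovineRhodopsin()
  expect_equal(nchar(ref), 348L)
  m <- mapToBovine(ref)
  expect_equal(as.integer(m), seq_len(348))
  del <- substr(ref, 6, 348)
  m2 <- mapToBovine(del)
  expect_equal(as.integer(m2), 6:348)
  # gapped query coordinates are preserved
  gapped <- paste0(substr(ref, 1, 10), "-----", substr(ref, 11, 348))
  m3 <- mapToBovine(gapped)
  expect_true(all(is.na(m3[11:15])))
  expect_equal(m3[16], 11L)
  expect_error(mapToBovine("MNGTEGPNFY"), "wrong input")
})

test_that("tuning shifts follow the rules, with reverse negation and gaps", {
  ref <- bovineRhodopsin()
  map <- mapToBovine(ref)
  rules <- tuningRules("LWS")
  expect_equal(nrow(rules), 10L)
  expect_equal(nrow(tuningRules("SWS1")), 13L)

  child <- ref; substr(child, 164, 164) <- "S"
  d <- detectTuningShifts(ref, child, map, rules)
  expect_equal(d$netShift, 6)
  dRev <- detectTuningShifts(child, ref, map, rules)
  expect_equal(dRev$netShift, -7)   # explicit asymmetric reverse rule

  # reverse negation when only the forward rule exists
  sws <- tuningRules("SWS1")
  p <- ref; substr(p, 86, 86) <- "Y"
  c2 <- ref; substr(c2, 86, 86) <- "F"
  dn <- detectTuningShifts(p, c2, map, sws)
  expect_equal(dn$netShift, -60)
  expect_match(dn$shifts$status, "reverse")

  # identical sequences produce an empty report
  d0 <- detectTuningShifts(ref, ref, map, rules)
  expect_equal(nrow(d0$shifts), 0L)
  expect_equal(d0$netShift, 0)

  # a gap at a critical position is not a zero shift
  gp <- ref; substr(gp, 164, 164) <- "-"
  dg <- detectTuningShifts(gp, child, map, rules)
  expect_match(dg$shifts$status, "not assessable")
  expect_true(is.na(dg$shifts$delta_nm))

  # unmatched replacement at a critical site is reported unknown
  ku <- ref; substr(ku, 164, 164) <- "W"
  du <- detectTuningShifts(ref, ku, map, rules)
  expect_match(du$shifts$status, "effect unknown")
})
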