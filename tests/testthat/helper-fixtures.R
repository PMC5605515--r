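# Shared fixtures: all built in code at test time.

equalFreqs <- rep(1 / 61, 61)

# small unrooted trees
toyTree <- function(fg = FALSE) {
  txt <- if (fg) "((A:0.1,B:0.2)#1:0.15,(C:0.3,D:0.1):0.2,E:0.25);"
         else "((A:0.1,B:0.2):0.15,(C:0.3,D:0.1):0.2,E:0.25);"
  readLabeledTree(text = txt)
}

# four-taxon rooted toy (three internal nodes when read as rooted)
fourTaxonTree <- function() {
  readLabeledTree(text = "((A:0.1,B:0.2):0.15,(C:0.3,D:0.1):0.2);")
}

# background purifying mixture and the branch-site alternative
purifyingMixture <- data.frame(prop = c(0.75, 0.15, 0.0833, 0.0167),
                               omegaBackground = c(0.1, 1, 0.1, 1),
                               omegaForeground = c(0.1, 1, 1, 1))
branchSiteMixture <- function(omega2 = 8) {
  m <- purifyingMixture
  m$omegaForeground <- c(0.1, 1, omega2, omega2)
  m
}

# exhaustive-state-sum oracle: log-likelihood of one site by enumerating
# every internal-node state combination (independent of the pruning code)
bruteSiteLogLik <- function(phy, tipStates, Plist, rootFreqs) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntaxa <- length(phy$tip.label)
  nint <- phy$Nnode
  ns <- length(rootFreqs)
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), nint)))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    st <- c(tipStates, grid[g, ])
    p <- rootFreqs[grid[g, 1]]   # node ntaxa+1 is the first internal
    for (e in seq_len(nrow(phy$edge))) {
      a <- st[phy$edge[e, 1]]; b <- st[phy$edge[e, 2]]
      if (is.na(b)) next       # missing tip: marginalized by summation
      p <- p * Plist[[e]][a, b]
    }
    tot <- tot + p
  }
  log(tot)
}

# genetic-code classifier used as an independent oracle for rate-matrix
# structure and for counting nonsynonymous differences
codonInfo <- local({
  b <- c("T", "C", "A", "G")
  cods <- character(64); k <- 0
  for (i in b) for (j in b) for (l in b) { k <- k + 1; cods[k] <- paste0(i, j, l) }
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[cods])
  sense <- cods[aa != "*"]
  list(codons = sense, aa = aa[aa != "*"])
})

labeledFromClade <- function(phy, tips, tag = "foreground") {
  photodiel:::.labelForClade(phy, tips, tag)
}
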