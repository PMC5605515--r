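test_that("codon FASTA parsing validates frame, stops and duplicates", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">A", "ATGAAACCC", ">B", "ATGAAGCCG"), f)
  a <- readCodonFasta(f)
  expect_s4_class(a, "CodonAlignment")
  expect_equal(length(taxonNames(a)), 2L)
  expect_equal(nCodonSites(a), 3L)

  writeLines(c(">A", "ATGAAACC", ">B", "ATGAAGCC"), f)
  expect_error(readCodonFasta(f), "divisible by 3")

  writeLines(c(">A", "ATGAAA", ">A", "ATGAAG"), f)
  expect_error(readCodonFasta(f), "duplicate")

  writeLines(c(">A", "ATGTGACCC", ">B", "ATGAAGCCG"), f)
  expect_error(readCodonFasta(f), "internal stop codon in A at codon 2")

  # terminal stops are stripped and the alignment shortens by one codon
  writeLines(c(">A", "ATGAAATAA", ">B", "ATGAAGTAA"), f)
  expect_warning(a2 <- readCodonFasta(f), "terminal stop")
  expect_equal(nCodonSites(a2), 2L)
})

test_that("gap and ambiguous codons are stored missing, never dropped", {
  a <- codonAlignment(c(A = "ATGAA-CCCNNN", B = "ATG---CCGAAA"))
  m <- codonMatrix(a)
  expect_equal(ncol(m), 4L)
  expect_true(is.na(m["A", 2]) && is.na(m["A", 4]) && is.na(m["B", 2]))
  expect_false(is.na(m["B", 4]))
})

test_that("read/write round trip preserves sequences and labels", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">A", "ATGAA-CCCNNN", ">B", "ATG---CCGAAA"), f)
  a <- readCodonFasta(f)
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeCodonFasta(a, f2)
  expect_identical(readLines(f2),
                   c(">A", "ATGAA-CCCNNN", ">B", "ATG---CCGAAA"))
  a2 <- readCodonFasta(f2)
  expect_identical(a@codons, a2@codons)
  expect_identical(a@taxa, a2@taxa)

  # labeled tree round trip
  t1 <- readLabeledTree(text = "((A:1,B:1)#1:1,(C:1,D:1):1,E:1);")
  f3 <- withr::local_tempfile(fileext = ".nwk")
  writeLabeledTree(t1, f3)
  t2 <- readLabeledTree(f3)
  expect_identical(edgeLabels(t1), edgeLabels(t2))
  expect_identical(ape::write.tree(treePhylo(t1)),
                   ape::write.tree(treePhylo(t2)))
})

test_that("transcript selection follows the longest / second-longest rule", {
  tr <- data.frame(id = c("x", "y"),
                   sequence = c(strrep("A", 900), strrep("C", 600)))
  expect_equal(selectTranscript(tr)$id, "x")

  trN <- data.frame(id = c("x", "y"),
                    sequence = c(paste0(strrep("A", 897), "NNN"),
                                 strrep("C", 600)))
  expect_equal(selectTranscript(trN)$id, "y")

  one <- data.frame(id = "solo",
                    sequence = paste0(strrep("A", 100), strrep("N", 5)))
  expect_warning(r <- selectTranscript(one), "no shorter alternative")
  expect_equal(r$id, "solo")

  expect_error(selectTranscript(data.frame(id = character(),
                                           sequence = character())),
               "empty")

  # permutation invariance
  set.seed(1)
  trs <- data.frame(id = c("a", "b", "c"),
                    sequence = c(paste0(strrep("G", 300), "NN"),
                                 strrep("T", 300), strrep("C", 240)))
  picks <- vapply(1:10, function(i) {
    p <- sample(nrow(trs))
    selectTranscript(trs[p, , drop = FALSE])$sequence
  }, character(1))
  expect_equal(length(unique(picks)), 1L)
})

test_that("QC filter removes short, gappy and low-identity sequences", {
  lt <- toyTree()
  sim <- simulateCodonAlignment(lt, data.frame(prop = 1,
    omegaBackground = 0.3, omegaForeground = 0.3), nCodons = 150, seed = 3)
  cod <- sim$alignment@codons
  # taxon with 40% of codons gapped fails the length threshold
  gappy <- cod[1, ]; gappy[1:60] <- NA
  set.seed(11)
  shuffled <- sample(cod[1, ])
  a <- new("CodonAlignment",
           taxa = c(sim$alignment@taxa, "GAPPY", "SHUF"),
           codons = rbind(cod, gappy, shuffled),
           missingText = matrix(character(), 0, 0),
           geneticCode = "standard")
  q <- qcFilterAlignment(a, minLenFrac = 0.7, maxMissingFrac = 0.3,
                         minIdentity = 0.5)
  expect_setequal(q$report$taxon, c("GAPPY", "SHUF"))
  # identity value in the report matches a direct pairwise count
  shufRow <- q$report[q$report$taxon == "SHUF", ]
  keep <- match(taxonNames(q$alignment), a@taxa)
  direct <- photodiel:::.pairIdentity(a@codons, 7L, keep)
  expect_equal(shufRow$value, direct, tolerance = 1e-12)

  # identical alignment passes untouched; filtering is idempotent
  same <- codonAlignment(c(a1 = "ATGAAACCC", a2 = "ATGAAACCC",
                           a3 = "ATGAAACCC", a4 = "ATGAAACCC"))
  q2 <- qcFilterAlignment(same, 1, 0, 1)
  expect_equal(nrow(q2$report), 0L)
  q3 <- qcFilterAlignment(q$alignment, minLenFrac = 0.7,
                          maxMissingFrac = 0.3, minIdentity = 0.5)
  expect_equal(nrow(q3$report), 0L)

  expect_error(qcFilterAlignment(same, minIdentity = 1.5), "minIdentity")
})

test_that("branch labels come equivalently from #1 marks or clade tables", {
  t1 <- readLabeledTree(text = "((A:1,B:1)#1:1,(C:1,D:1):1);")
  t2 <- readLabeledTree(text = "((A:1,B:1):1,(C:1,D:1):1);",
                        labelSpec = list(foreground = c("A", "B")))
  expect_identical(edgeLabels(t1), edgeLabels(t2))
  expect_equal(sum(edgeLabels(t1) == "foreground"), 1L)

  t3 <- readLabeledTree(text = "((A:1,B:1):1,(C#1:1,D:1):1);")
  e <- which(treePhylo(t3)$edge[, 2] == match("C", taxonNames(t3)))
  expect_equal(edgeLabels(t3)[e], "foreground")

  expect_error(readLabeledTree(text = "((A:1,B:1):1,C:1);",
                               labelSpec = list(foreground = "Z")),
               "absent from tree")
})
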