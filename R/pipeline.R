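# End-to-end orchestration: per-gene x per-branch test batteries, diel
# inference from a results table, and the opsin tuning report.

.labelForClade <- function(phy, tips, tag = "foreground") {
  labels <- rep("background", nrow(phy$edge))
  node <- if (length(tips) == 1L) match(tips, phy$tip.label)
          else ape::getMRCA(phy, tips)
  e <- which(phy$edge[, 2] == node)
  if (!length(e)) stop("clade has no stem edge (is it the root?)")
  labels[e] <- tag
  new("LabeledTree", phy = phy, labels = labels)
}

#' Run a selection-test battery over genes and focal branches
#'
#' For every gene x focal branch (x test) combination, labels the branch
#' as foreground on the species tree, runs the test and records one row.
#' Branch lengths are calibrated once per gene (nucleotide GTR + codon
#' rescale) and reused across branches and tests. Per-gene failures are
#' caught, logged in the \code{error} column and do not stop the run.
#'
#' @param alignments named list of \code{\linkS4class{CodonAlignment}}s.
#' @param phy species tree (\code{phylo}); branch lengths are
#'   re-estimated per gene.
#' @param clades named list: focal branch name -> tip set of the clade
#'   whose stem edge is tested.
#' @param tests subset of \code{c("branchSite", "branchModel", "busted")}.
#' @param alpha significance level for PSG calls.
#' @param correction \code{"none"} (branch/branch-site convention) or
#'   \code{"bonferroni"} (applied per test over the gene battery).
#' @param starts start-value grid for the fits (default a single start;
#'   pass the four-combination grid for robustness runs).
#' @param seed integer seed recorded with the run (the battery itself is
#'   deterministic).
#' @return data.frame with one row per gene x branch x test.
#' @export
runGeneBattery <- function(alignments, phy, clades,
                           tests = "branchSite", alpha = 0.05,
                           correction = c("none", "bonferroni"),
                           starts = list(kappa = 2, omega = 0.5),
                           seed = 1) {
  correction <- match.arg(correction)
  stopifnot(all(tests %in% c("branchSite", "branchModel", "busted")))
  nTests <- length(alignments)
  rows <- list()
  for (g in names(alignments)) {
    aln <- alignments[[g]]
    base <- tryCatch({
      lt <- new("LabeledTree", phy = phy,
                labels = rep("background", nrow(phy$edge)))
      estimateBranchLengths(aln, lt)
    }, error = function(e) e)
    for (b in names(clades)) {
      for (tst in tests) {
        row <- data.frame(gene = g, branch = b, test = tst,
                          logL0 = NA_real_, logL1 = NA_real_,
                          twoDeltaL = NA_real_, df = 1L, p = NA_real_,
                          correctedP = NA_real_, omegaFg = NA_real_,
                          kappa = NA_real_, propSelected = NA_real_,
                          psg = NA, capped = NA, startSpread = NA_real_,
                          error = NA_character_)
        res <- tryCatch({
          if (inherits(base, "error")) stop(conditionMessage(base))
          tr <- .labelForClade(base$tree@phy, clades[[b]])
          kap <- base$kappa
          switch(tst,
            branchSite = {
              r <- branchSiteTest(aln, tr, alpha, starts,
                                  branchLengths = "keep", fixKappa = kap)
              row$logL0 <- r$lrt@logLikNull; row$logL1 <- r$lrt@logLikAlt
              row$twoDeltaL <- r$lrt@twoDeltaL; row$p <- r$lrt@pValue
              row$omegaFg <- r$omega2
              row$kappa <- r$fitAlt@params$kappa
              row$propSelected <- sum(r$fitAlt@mixture$prop[3:4])
              row$capped <- r$fitAlt@capped
              row$startSpread <- r$fitAlt@startSpread
              row$psg <- r$psg
            },
            branchModel = {
              r <- branchModelTest(aln, tr, alpha, starts,
                                   branchLengths = "keep",
                                   fixKappa = kap)
              row$logL0 <- r$stage1@logLikNull
              row$logL1 <- r$stage1@logLikAlt
              row$twoDeltaL <- r$stage1@twoDeltaL; row$p <- r$stage1@pValue
              row$omegaFg <- r$omegaFg
              row$kappa <- r$fits$twoRatio@params$kappa
              row$capped <- r$fits$twoRatio@capped
              row$startSpread <- r$fits$twoRatio@startSpread
              row$psg <- r$psg
            },
            busted = {
              r <- bustedTest(aln, tr, nTests = nTests, alpha = alpha,
                              starts = starts, branchLengths = "keep",
                              fixKappa = kap)
              row$logL0 <- r$lrt@logLikNull; row$logL1 <- r$lrt@logLikAlt
              row$twoDeltaL <- r$lrt@twoDeltaL; row$p <- r$lrt@pValue
              row$correctedP <- r$correctedP
              row$omegaFg <- r$omega3
              row$kappa <- r$fits$alt@params$kappa
              row$capped <- r$fits$alt@capped
              row$startSpread <- r$fits$alt@startSpread
              row$psg <- r$psg
            })
          row
        }, error = function(e) {
          row$error <- conditionMessage(e)
          row
        })
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  if (correction == "bonferroni") {
    n <- length(unique(out$gene))
    out$correctedP <- pmin(1, out$p * n)
    out$psg <- !is.na(out$correctedP) & out$correctedP < alpha &
      out$omegaFg > 1
  }
  attr(out, "seed") <- seed
  attr(out, "log") <- list(
    package = as.character(utils::packageVersion("photodiel")),
    r = R.version.string,
    settings = list(tests = tests, alpha = alpha,
                    correction = correction, starts = starts),
    configHash = sum(utf8ToInt(paste(names(alignments),
                                     names(clades), collapse = "|"))))
  out
}

#' Infer a diel history from a battery results table
#'
#' Collects the significant PSG calls of the configured test per focal
#' branch, classifies each branch's signal by the cone/rod voting rule
#' and propagates states over the focal tree.
#'
#' @param results data.frame from \code{\link{runGeneBattery}}.
#' @param annotation gene annotation data.frame.
#' @param ft a \code{\linkS4class{FocalTree}} (PSG slots ignored).
#' @param test which test's calls to use (default \code{"branchSite"}).
#' @param useCorrected use the Bonferroni-corrected p-values.
#' @param alpha significance level.
#' @param rootPrior state for a signal-less root.
#' @return list with \code{history} (a
#'   \code{\linkS4class{DielHistory}}), \code{psgTree} (focal tree with
#'   call sets) and \code{stateTable} (data.frame).
#' @export
runDielInference <- function(results, annotation, ft,
                             test = "branchSite", useCorrected = FALSE,
                             alpha = 0.05, rootPrior = "unresolved") {
  r <- results[results$test == test & !is.na(results$p), , drop = FALSE]
  pcol <- if (useCorrected) r$correctedP else r$p
  sel <- !is.na(r$psg) & r$psg
  calls <- r[sel, c("gene", "branch")]
  psg <- split(calls$gene, calls$branch)
  tree <- focalTree(ft@branch, ft@parent, psg)
  history <- propagateStates(tree, annotation, rootPrior = rootPrior)
  tab <- data.frame(branch = ft@branch,
                    state = unname(history@states[ft@branch]),
                    psg = vapply(psgSets(tree)[ft@branch],
                                 paste, character(1), collapse = ","))
  list(history = history, psgTree = tree, stateTable = tab)
}

#' Ancestral opsin tuning report
#'
#' Reconstructs ancestral amino-acid sequences of an opsin alignment under
#' both the JTT and Poisson models, lists the amino-acid replacements
#' along every branch at the critical tuning positions, and annotates them
#' with wavelength shifts from the rule set. Replacements whose best
#' reconstruction differs between the two models are flagged
#' model-dependent.
#'
#' @param sequences named character vector of aligned opsin amino-acid
#'   sequences.
#' @param phy tree over the sequences.
#' @param opsin \code{"LWS"} or \code{"SWS1"} (selects the bundled rule
#'   set).
#' @param rules optional explicit rule data.frame.
#' @param reference numbering reference (default bovine rhodopsin).
#' @return data.frame: one row per branch and critical-site replacement
#'   (possibly zero rows), with columns \code{parent}, \code{child},
#'   \code{bovine_pos}, \code{from}, \code{to}, \code{delta_nm},
#'   \code{status}, \code{modelDependent}; attribute \code{netShift}
#'   gives the per-branch net shifts under JTT.
#' @export
runOpsinReport <- function(sequences, phy, opsin = c("LWS", "SWS1"),
                           rules = NULL, reference = bovineRhodopsin()) {
  opsin <- match.arg(opsin)
  if (is.null(rules)) rules <- tuningRules(opsin)
  recJ <- reconstructAncestors(sequences, phy, "JTT")
  recP <- reconstructAncestors(sequences, phy, "Poisson")
  phy <- recJ$tree
  ntaxa <- length(phy$tip.label)
  # representative (least-gapped) sequence anchors the bovine numbering
  gaps <- vapply(sequences, function(s)
    sum(strsplit(s, "")[[1]] == "-"), integer(1))
  map <- mapToBovine(sequences[[which.min(gaps)]], reference)
  seqAt <- function(rec, node) {
    if (node <= ntaxa) sequences[[phy$tip.label[node]]]
    else paste(rec$best[as.character(node), ], collapse = "")
  }
  rows <- list(); net <- numeric()
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    parSeqJ <- seqAt(recJ, par); chSeqJ <- seqAt(recJ, ch)
    parSeqP <- seqAt(recP, par); chSeqP <- seqAt(recP, ch)
    det <- detectTuningShifts(parSeqJ, chSeqJ, map, rules)
    chName <- if (ch <= ntaxa) phy$tip.label[ch] else as.character(ch)
    net[chName] <- det$netShift
    if (nrow(det$shifts)) {
      detP <- detectTuningShifts(parSeqP, chSeqP, map, rules)
      keyJ <- with(det$shifts, paste(bovine_pos, from, to))
      keyP <- if (nrow(detP$shifts))
        with(detP$shifts, paste(bovine_pos, from, to)) else character()
      df <- det$shifts
      df$parent <- as.character(par)
      df$child <- chName
      df$modelDependent <- !(keyJ %in% keyP)
      rows[[length(rows) + 1L]] <- df
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(bovine_pos = integer(), from = character(),
                         to = character(), delta_nm = numeric(),
                         status = character(), parent = character(),
                         child = character(), modelDependent = logical())
  attr(out, "netShift") <- net
  attr(out, "models") <- list(JTT = recJ, Poisson = recP)
  out
}

#' Write a battery results table as TSV
#'
#' @param results data.frame from \code{\link{runGeneBattery}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeResultsTable <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' YAML with fields: \code{genes} (name -> alignment FASTA path),
#' \code{tree} (Newick path), \code{clades} (branch -> tip vector),
#' \code{annotation} (TSV path), \code{tests}, \code{alpha},
#' \code{correction}, \code{seed}.
#'
#' @param path YAML file.
#' @return list ready for \code{\link{runGeneBattery}} /
#'   \code{\link{runDielInference}}.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("genes", "tree", "clades")) {
    if (is.null(cfg[[f]])) stop("config misses field: ", f)
  }
  missing <- Filter(Negate(file.exists), unlist(cfg$genes))
  if (length(missing))
    stop("alignment files not found: ", paste(missing, collapse = ", "))
  if (!file.exists(cfg$tree)) stop("tree file not found: ", cfg$tree)
  cfg$alignments <- lapply(cfg$genes, readCodonFasta)
  cfg$phy <- ape::read.tree(cfg$tree)
  if (!is.null(cfg$annotation))
    cfg$annotationTable <- readGeneAnnotation(cfg$annotation)
  cfg$tests <- cfg$tests %||% "branchSite"
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$correction <- cfg$correction %||% "none"
  cfg$seed <- cfg$seed %||% 1
  cfg
}
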