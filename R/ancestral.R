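# Marginal empirical-Bayes ancestral amino-acid reconstruction and opsin
# spectral-tuning annotation in bovine-rhodopsin numbering.

#' Amino-acid substitution model
#'
#' \code{"JTT"} uses the empirical JTT exchangeabilities and frequencies;
#' \code{"Poisson"} has equal rates and equal frequencies. The generator
#' is rescaled to one expected substitution per site per unit time.
#'
#' @param name \code{"JTT"} or \code{"Poisson"}.
#' @return list with \code{name}, \code{Q} (20x20 generator), \code{pi}
#'   and \code{alphabet}.
#' @export
aminoAcidModel <- function(name = c("JTT", "Poisson")) {
  name <- match.arg(name)
  aa <- .aaAlphabet()
  if (name == "Poisson") {
    S <- matrix(1, 20, 20)
    pi <- rep(1 / 20, 20)
  } else {
    jtt <- getFromNamespace(".JTT", "phangorn")
    S <- matrix(0, 20, 20)
    S[lower.tri(S)] <- jtt$Q
    S <- S + t(S)
    pi <- unname(jtt$bf)
  }
  Q <- S * rep(pi, each = 20)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  r <- -sum(pi * diag(Q))
  Q <- Q / r
  dimnames(Q) <- list(aa, aa)
  list(name = name, Q = Q, pi = pi, alphabet = aa)
}

.aaIndexMatrix <- function(sequences) {
  aa <- .aaAlphabet()
  n <- unique(nchar(sequences))
  if (length(n) != 1L) stop("amino-acid sequences must be aligned")
  m <- t(vapply(sequences,
                function(s) match(strsplit(toupper(s), "")[[1]], aa),
                integer(n)))
  if (n == 1L) m <- matrix(m, nrow = length(sequences))
  rownames(m) <- names(sequences)
  m
}

# branch lengths for reconstruction, re-estimated under the amino-acid
# model via phangorn (topology fixed)
.aaBranchLengths <- function(sequences, phy, model) {
  chars <- do.call(rbind, strsplit(toupper(sequences), ""))
  rownames(chars) <- names(sequences)
  dat <- phangorn::phyDat(chars, type = "AA")
  phy0 <- phy
  if (is.null(phy0$edge.length))
    phy0$edge.length <- rep(0.1, nrow(phy0$edge))
  fit0 <- phangorn::pml(phy0, dat, bf = model$pi,
                        Q = model$Q[lower.tri(model$Q)] /
                          rep(model$pi, each = 20)[lower.tri(model$Q)])
  fit1 <- suppressWarnings(phangorn::optim.pml(
    fit0, optEdge = TRUE,
    control = phangorn::pml.control(trace = 0, epsilon = 1e-7,
                                    maxit = 20)))
  phyN <- fit1$tree
  m <- match(.edgeKeys(phy), .edgeKeys(phyN))
  if (anyNA(m)) stop("branch-length estimation changed the topology")
  phy$edge.length <- pmax(phyN$edge.length[m], 1e-8)
  phy
}

#' Marginal ancestral amino-acid reconstruction
#'
#' Empirical-Bayes marginal reconstruction: for every internal node and
#' site, the posterior distribution over the 20 amino acids given the tip
#' data, computed by an up-down pruning pass under the chosen model. The
#' state with the highest posterior is the best reconstruction; exact
#' posterior ties are broken by alphabet order and flagged.
#'
#' @param sequences named character vector of aligned amino-acid
#'   sequences (gaps and unknown characters are treated as missing).
#' @param phy a \code{phylo} tree over the sequence names.
#' @param model an \code{\link{aminoAcidModel}} or name.
#' @param estimateBranchLengths re-estimate branch lengths under the model
#'   (default TRUE; otherwise \code{phy} must carry lengths).
#' @return object of class \code{"AncestralReconstruction"}: list with
#'   \code{best} (character matrix, internal nodes x sites),
#'   \code{posterior} (list of 20 x nsites matrices per internal node),
#'   \code{maxPosterior}, \code{ties} (data.frame node/site), \code{tree},
#'   \code{model}.
#' @export
reconstructAncestors <- function(sequences, phy, model = "JTT",
                                 estimateBranchLengths = TRUE) {
  if (is.character(model)) model <- aminoAcidModel(model)
  if (!setequal(names(sequences), phy$tip.label))
    stop("sequence names and tree tips differ")
  if (estimateBranchLengths)
    phy <- .aaBranchLengths(sequences, phy, model)
  else if (is.null(phy$edge.length))
    stop("tree has no branch lengths and estimateBranchLengths = FALSE")
  phy <- ape::reorder.phylo(phy, "postorder")
  idx <- .aaIndexMatrix(sequences)[phy$tip.label, , drop = FALSE]
  ntaxa <- nrow(idx); nsite <- ncol(idx)
  nnode <- ntaxa + phy$Nnode
  pi <- model$pi
  Plist <- lapply(phy$edge.length, function(t)
    transitionMatrix(model$Q, t, pi = pi))

  down <- vector("list", nnode)      # subtree partials (scaled)
  msg <- vector("list", nrow(phy$edge))  # child -> parent messages
  tipPartial <- function(i) {
    m <- matrix(1, 20, nsite)
    s <- idx[i, ]
    ok <- !is.na(s)
    m[, ok] <- 0
    m[cbind(s[ok], which(ok))] <- 1
    m
  }
  for (i in seq_len(ntaxa)) down[[i]] <- tipPartial(i)
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    msg[[e]] <- Plist[[e]] %*% down[[ch]]
    down[[par]] <- if (is.null(down[[par]])) msg[[e]]
                   else down[[par]] * msg[[e]]
    sc <- apply(down[[par]], 2L, max); sc[sc <= 0] <- 1
    down[[par]] <- sweep(down[[par]], 2L, sc, "/")
  }
  # outside pass (preorder): out[root] = pi
  root <- ntaxa + 1L
  out <- vector("list", nnode)
  out[[root]] <- matrix(pi, 20, nsite)
  childEdges <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  for (e in rev(seq_len(nrow(phy$edge)))) {   # preorder
    par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    if (ch <= ntaxa) next
    sibs <- setdiff(childEdges[[as.character(par)]], e)
    acc <- out[[par]]
    for (se in sibs) acc <- acc * msg[[se]]
    out[[ch]] <- crossprod(Plist[[e]], acc)
    sc <- apply(out[[ch]], 2L, max); sc[sc <= 0] <- 1
    out[[ch]] <- sweep(out[[ch]], 2L, sc, "/")
  }
  aa <- model$alphabet
  internals <- (ntaxa + 1L):nnode
  posterior <- list(); best <- NULL; mp <- NULL
  ties <- data.frame(node = integer(), site = integer())
  for (v in internals) {
    post <- down[[v]] * out[[v]]
    cs <- colSums(post)
    post <- sweep(post, 2L, cs, "/")
    posterior[[as.character(v)]] <- post
    # argmax with alphabet-order tie-break at 1e-12 tolerance
    b <- apply(post, 2L, function(col)
      which(col >= max(col) - 1e-12)[1])
    pm <- post[cbind(b, seq_len(nsite))]
    tied <- vapply(seq_len(nsite), function(j)
      sum(post[, j] >= pm[j] - 1e-12) > 1L, logical(1))
    if (any(tied))
      ties <- rbind(ties, data.frame(node = v, site = which(tied)))
    best <- rbind(best, unname(aa[b]))
    mp <- rbind(mp, unname(pm))
  }
  rownames(best) <- rownames(mp) <- as.character(internals)
  structure(list(best = best, posterior = posterior, maxPosterior = mp,
                 ties = ties, tree = phy, model = model$name),
            class = "AncestralReconstruction")
}

#' @export
print.AncestralReconstruction <- function(x, ...) {
  cat(sprintf(
    "AncestralReconstruction [%s]: %d internal nodes, %d sites\n",
    x$model, nrow(x$best), ncol(x$best)))
  cat(sprintf("  mean max posterior: %.3f; tied sites: %d\n",
              mean(x$maxPosterior), nrow(x$ties)))
  invisible(x)
}

#' Bundled bovine rhodopsin reference sequence
#'
#' The 348-residue bovine rhodopsin amino-acid sequence used as the
#' coordinate system for opsin residue numbering.
#'
#' @return single character string.
#' @export
bovineRhodopsin <- function() {
  p <- system.file("extdata", "bovine_rhodopsin.fasta",
                   package = "photodiel")
  ss <- Biostrings::readAAStringSet(p)
  as.character(ss)[[1]]
}

#' Map a query opsin sequence onto bovine-rhodopsin numbering
#'
#' Global pairwise alignment (affine gap penalties, BLOSUM62) of the query
#' against the bovine rhodopsin reference; returns the monotone map from
#' query positions to 1-based bovine positions (NA where the query aligns
#' to a gap).
#'
#' @param query amino-acid sequence (character string; may contain
#'   alignment gaps, which map to NA).
#' @param reference reference sequence (default
#'   \code{\link{bovineRhodopsin}}).
#' @return integer vector of length \code{nchar(query)} in the query's own
#'   (possibly gapped) coordinates; attribute \code{coverage} gives the
#'   fraction of reference residues aligned.
#' @export
mapToBovine <- function(query, reference = bovineRhodopsin()) {
  query <- toupper(query)
  qchars <- strsplit(query, "")[[1]]
  keep <- which(qchars != "-")
  stripped <- paste(qchars[keep], collapse = "")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(stripped),
    Biostrings::AAString(toupper(reference)),
    type = "global", substitutionMatrix = get("BLOSUM62",
                                              envir = environment()),
    gapOpening = 10, gapExtension = 0.5)
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  map <- rep(NA_integer_, length(qchars))
  qi <- 0L; ri <- 0L
  aligned <- 0L
  for (k in seq_along(qa)) {
    if (qa[k] != "-") qi <- qi + 1L
    if (ra[k] != "-") ri <- ri + 1L
    if (qa[k] != "-" && ra[k] != "-") {
      map[keep[qi]] <- ri
      aligned <- aligned + 1L
    }
  }
  coverage <- aligned / nchar(reference)
  if (coverage < 0.5)
    stop(sprintf(
      "query covers only %.0f%% of the reference; wrong input suspected",
      100 * coverage))
  ok <- !is.na(map)
  if (any(diff(map[ok]) <= 0)) stop("position map is not monotone")
  attr(map, "coverage") <- coverage
  map
}

#' Read a spectral-tuning rule table
#'
#' @param path TSV with columns \code{opsin}, \code{bovine_pos},
#'   \code{from}, \code{to}, \code{delta_nm}, \code{source}.
#' @return validated data.frame.
#' @export
readTuningRules <- function(path) {
  r <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("opsin", "bovine_pos", "from", "to", "delta_nm",
                  "source") %in% names(r)))
  r
}

#' Bundled opsin tuning rules
#'
#' Critical amino-acid replacements known to shift the wavelength of
#' maximal absorption: 10 rules for the long-wavelength-sensitive opsin
#' (LWS) and 13 for the short-wavelength-sensitive opsin (SWS1), keyed to
#' bovine-rhodopsin numbering. The LWS position-164 pair (A164S +6 nm;
#' S164A -7 nm) is fixed by direct measurement; entries marked
#' \code{synthetic-default} in the \code{source} column are editable
#' placeholders to be replaced from the tuning literature for new data.
#'
#' @param opsin \code{"LWS"} or \code{"SWS1"}.
#' @return data.frame of rules.
#' @export
tuningRules <- function(opsin = c("LWS", "SWS1")) {
  opsin <- match.arg(opsin)
  f <- file.path(system.file("extdata", package = "photodiel"),
                 sprintf("%s_tuning_rules.tsv", tolower(opsin)))
  readTuningRules(f)
}

#' Detect spectral-tuning shifts between two sequences
#'
#' Compares aligned parent and child sequences (e.g. ancestral
#' reconstructions at the two ends of a branch) at the critical positions
#' of a tuning rule set. Replacements matching a rule contribute the
#' tabulated wavelength shift; a replacement matching only the reverse of
#' a rule contributes the negated shift; other replacements at critical
#' positions are reported with unknown effect; a gap at a critical
#' position is reported as not assessable (never as a shift of zero).
#'
#' @param parentSeq,childSeq aligned amino-acid strings of equal length.
#' @param map bovine position map for this alignment's coordinates (from
#'   \code{\link{mapToBovine}}).
#' @param rules tuning rule data.frame (e.g. \code{\link{tuningRules}}).
#' @return list with \code{shifts} (data.frame: bovine_pos, from, to,
#'   delta_nm, status) and \code{netShift} (sum of matched shifts, nm).
#' @export
detectTuningShifts <- function(parentSeq, childSeq, map, rules) {
  if (nchar(parentSeq) != nchar(childSeq))
    stop("parent and child sequences must be aligned to equal length")
  p <- strsplit(toupper(parentSeq), "")[[1]]
  ch <- strsplit(toupper(childSeq), "")[[1]]
  out <- data.frame(bovine_pos = integer(), from = character(),
                    to = character(), delta_nm = numeric(),
                    status = character())
  for (pos in sort(unique(rules$bovine_pos))) {
    qi <- which(map == pos)
    if (!length(qi)) next
    a <- p[qi]; b <- ch[qi]
    if (a == b) next
    if (a == "-" || b == "-") {
      out <- rbind(out, data.frame(bovine_pos = pos, from = a, to = b,
                                   delta_nm = NA_real_,
                                   status = "not assessable (gap)"))
      next
    }
    fwd <- rules[rules$bovine_pos == pos & rules$from == a &
                   rules$to == b, ]
    rev <- rules[rules$bovine_pos == pos & rules$from == b &
                   rules$to == a, ]
    if (nrow(fwd)) {
      out <- rbind(out, data.frame(bovine_pos = pos, from = a, to = b,
                                   delta_nm = fwd$delta_nm[1],
                                   status = "matched"))
    } else if (nrow(rev)) {
      out <- rbind(out, data.frame(bovine_pos = pos, from = a, to = b,
                                   delta_nm = -rev$delta_nm[1],
                                   status = "matched (reverse rule)"))
    } else {
      out <- rbind(out, data.frame(bovine_pos = pos, from = a, to = b,
                                   delta_nm = NA_real_,
                                   status = "critical site, effect unknown"))
    }
  }
  list(shifts = out, netShift = sum(out$delta_nm, na.rm = TRUE))
}
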