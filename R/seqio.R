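# Readers, writers and data-preparation rules: in-frame codon FASTA,
# labeled Newick trees, transcript selection, alignment QC.

.splitCodons <- function(s) {
  n <- nchar(s)
  substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Construct a codon alignment from sequence strings
#'
#' @param sequences named character vector of aligned in-frame coding
#'   sequences (equal lengths, divisible by three). Gap codons (\code{---})
#'   and codons containing characters outside \code{ACGT} are stored as
#'   missing.
#' @param checkStops action for internal stop codons: \code{"error"}
#'   (default) or \code{"missing"} (replace by missing with a warning).
#' @return a \code{\linkS4class{CodonAlignment}}.
#' @export
codonAlignment <- function(sequences, checkStops = c("error", "missing")) {
  checkStops <- match.arg(checkStops)
  ct <- .codonTable()
  taxa <- names(sequences)
  if (is.null(taxa) || any(!nzchar(taxa)))
    stop("sequences must be named by taxon")
  if (anyDuplicated(taxa))
    stop("duplicate taxon ids: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  sequences <- toupper(sequences)
  len <- nchar(sequences)
  if (length(unique(len)) != 1L)
    stop("aligned sequences must have equal length")
  if (len[1] %% 3L != 0L)
    stop("alignment length ", len[1], " is not divisible by 3")
  nsite <- len[1] %/% 3L
  txt <- t(vapply(sequences, .splitCodons, character(nsite)))
  if (nsite == 1L) txt <- matrix(txt, nrow = length(sequences))
  idx <- matrix(ct$index[txt], nrow(txt), ncol(txt))

  # terminal stop codons: converted to missing; a trailing all-missing
  # column is then dropped so the stored alignment is shorter by one codon
  isStop <- matrix(txt %in% ct$stops, nrow(txt), ncol(txt))
  if (nsite > 0L && any(isStop[, nsite])) {
    warning("terminal stop codon(s) stripped for: ",
            paste(taxa[isStop[, nsite]], collapse = ", "))
    txt[isStop[, nsite], nsite] <- "---"
    idx[isStop[, nsite], nsite] <- NA_integer_
    isStop[, nsite] <- FALSE
  }
  if (any(isStop)) {
    w <- which(isStop, arr.ind = TRUE)
    msg <- sprintf("internal stop codon in %s at codon %d",
                   taxa[w[, 1]], w[, 2])
    if (checkStops == "error") stop(paste(msg, collapse = "; "))
    warning(paste(msg, collapse = "; "), "; treated as missing")
    txt[w] <- "---"
    idx[w] <- NA_integer_
  }
  # drop a trailing column that is now entirely missing (stripped stops)
  if (ncol(idx) > 0L && all(is.na(idx[, ncol(idx)])) &&
      all(txt[, ncol(txt)] == "---")) {
    idx <- idx[, -ncol(idx), drop = FALSE]
    txt <- txt[, -ncol(txt), drop = FALSE]
  }
  miss <- matrix(NA_character_, nrow(idx), ncol(idx))
  miss[is.na(idx)] <- txt[is.na(idx)]
  new("CodonAlignment", taxa = taxa, codons = unname(idx),
      missingText = miss, geneticCode = "standard")
}

#' Read an in-frame codon alignment from FASTA
#'
#' Parses and validates an aligned coding-sequence FASTA: sequence lengths
#' must be equal and divisible by three, taxon ids unique. Terminal stop
#' codons are stripped (with a warning); internal stop codons are an error
#' naming the taxon and codon index. Gap codons and codons containing
#' ambiguous bases are flagged missing, never dropped.
#'
#' @param path FASTA file path.
#' @param geneticCode only \code{"standard"} is supported.
#' @return a \code{\linkS4class{CodonAlignment}}.
#' @export
readCodonFasta <- function(path, geneticCode = "standard") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!identical(geneticCode, "standard"))
    stop("only the standard genetic code is supported")
  ss <- Biostrings::readBStringSet(path)
  seqs <- setNames(as.character(ss), names(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  codonAlignment(seqs)
}

#' Write a codon alignment to FASTA
#'
#' Missing codons are written back as their original text when the
#' alignment was read from file, otherwise as \code{---}.
#'
#' @param aln a \code{\linkS4class{CodonAlignment}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCodonFasta <- function(aln, path) {
  ct <- .codonTable()
  n <- ncol(aln@codons)
  lines <- character(0)
  for (i in seq_along(aln@taxa)) {
    cods <- ifelse(is.na(aln@codons[i, ]),
                   NA_character_, ct$codons[aln@codons[i, ]])
    if (length(aln@missingText))
      cods[is.na(cods)] <- aln@missingText[i, is.na(cods)]
    cods[is.na(cods)] <- "---"
    lines <- c(lines, paste0(">", aln@taxa[i]), paste(cods, collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Transcript selection rule
#'
#' Chooses one coding transcript per gene: the longest record; if the
#' longest carries multiple ambiguous bases (at least
#' \code{ambiguousThreshold} Ns) and a strictly shorter record exists, the
#' second-longest is used instead. With a single record the choice is
#' forced (a warning is raised when it is ambiguous). The choice is
#' invariant to the input order of records.
#'
#' @param transcripts data.frame with columns \code{id} and \code{sequence}
#'   (unaligned coding sequences).
#' @param ambiguousThreshold minimum number of Ns counting as "multiple"
#'   (default 2).
#' @return one row of \code{transcripts} (plus an \code{nAmbiguous}
#'   column).
#' @export
selectTranscript <- function(transcripts, ambiguousThreshold = 2L) {
  if (is.null(transcripts) || nrow(transcripts) == 0L)
    stop("empty transcript set")
  tr <- transcripts
  tr$nAmbiguous <- vapply(gregexpr("N", toupper(tr$sequence), fixed = TRUE),
                          function(m) sum(m > 0L), integer(1))
  tr$len <- nchar(tr$sequence)
  ord <- order(-tr$len, tr$nAmbiguous, tr$id)
  tr <- tr[ord, , drop = FALSE]
  best <- tr[1, , drop = FALSE]
  if (best$nAmbiguous >= ambiguousThreshold) {
    shorter <- tr[tr$len < best$len, , drop = FALSE]
    if (nrow(shorter)) {
      best <- shorter[1, , drop = FALSE]
    } else {
      warning("longest transcript has ", best$nAmbiguous,
              " ambiguous bases and no shorter alternative exists")
    }
  }
  best$len <- NULL
  rownames(best) <- NULL
  best
}

# mean pairwise nucleotide identity of taxon i against taxa in `others`,
# over codon sites where both are non-missing
.pairIdentity <- function(codons, i, others) {
  ct <- .codonTable()
  vals <- vapply(others, function(j) {
    ok <- !is.na(codons[i, ]) & !is.na(codons[j, ])
    if (!any(ok)) return(NA_real_)
    a <- ct$nucIndex[codons[i, ok], , drop = FALSE]
    b <- ct$nucIndex[codons[j, ok], , drop = FALSE]
    mean(a == b)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Alignment quality filter
#'
#' Removes sequences that are too short (ungapped length below
#' \code{minLenFrac} of the alignment length), too incomplete (missing
#' fraction above \code{maxMissingFrac}), or too divergent (mean pairwise
#' nucleotide identity to the remaining taxa below \code{minIdentity}).
#' The identity pass iterates until stable, so the filter is idempotent.
#'
#' @param aln a \code{\linkS4class{CodonAlignment}}.
#' @param minLenFrac,maxMissingFrac,minIdentity thresholds in [0, 1].
#' @return list with the filtered \code{alignment} and a \code{report}
#'   data.frame (taxon, reason, value) of removals.
#' @export
qcFilterAlignment <- function(aln, minLenFrac = 0.5, maxMissingFrac = 0.2,
                              minIdentity = 0.4) {
  stopifnot(minLenFrac >= 0, minLenFrac <= 1, maxMissingFrac >= 0,
            maxMissingFrac <= 1, minIdentity >= 0, minIdentity <= 1)
  cod <- aln@codons
  nsite <- ncol(cod)
  report <- data.frame(taxon = character(), reason = character(),
                       value = numeric())
  keep <- seq_along(aln@taxa)
  missFrac <- rowMeans(is.na(cod))
  lenFrac <- 1 - missFrac
  drop1 <- lenFrac < minLenFrac
  drop2 <- missFrac > maxMissingFrac
  for (i in which(drop1))
    report <- rbind(report, data.frame(taxon = aln@taxa[i],
      reason = "too short", value = lenFrac[i]))
  for (i in which(drop2 & !drop1))
    report <- rbind(report, data.frame(taxon = aln@taxa[i],
      reason = "too much missing data", value = missFrac[i]))
  keep <- keep[!(drop1 | drop2)[keep]]
  repeat {
    if (length(keep) <= 1L) break
    ids <- vapply(keep, function(i)
      .pairIdentity(cod, i, setdiff(keep, i)), numeric(1))
    bad <- which(!is.na(ids) & ids < minIdentity)
    if (!length(bad)) break
    worst <- bad[which.min(ids[bad])]
    report <- rbind(report, data.frame(taxon = aln@taxa[keep[worst]],
      reason = "low identity", value = ids[worst]))
    keep <- keep[-worst]
  }
  if (!length(keep)) stop("QC filter removed all sequences")
  out <- new("CodonAlignment", taxa = aln@taxa[keep],
             codons = aln@codons[keep, , drop = FALSE],
             missingText = if (length(aln@missingText))
               aln@missingText[keep, , drop = FALSE] else aln@missingText,
             geneticCode = aln@geneticCode)
  list(alignment = out, report = report)
}

#' Read a branch-labeled Newick tree
#'
#' Reads a Newick tree whose foreground/test branches are marked either by
#' PAML-style \code{#n} tags on nodes or tips, or by an external clade
#' table (\code{labelSpec}). Unlabeled edges are background.
#'
#' @param path Newick file path (or a Newick string via \code{text}).
#' @param labelSpec named list mapping a tag (\code{"foreground"},
#'   \code{"test"}, \code{"reference"}) to a character vector of tip names;
#'   the stem edge above that clade (or the terminal edge for one tip)
#'   receives the tag. May be NULL when \code{#n} marks are used.
#' @param markMap mapping of \code{#n} mark numbers to tags
#'   (default \code{c("1" = "foreground")}).
#' @param text Newick string, used instead of \code{path} when given.
#' @return a \code{\linkS4class{LabeledTree}}.
#' @export
readLabeledTree <- function(path = NULL, labelSpec = NULL,
                            markMap = c("1" = "foreground"), text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("file not found: ", path)
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("could not parse Newick input")
  labels <- rep("background", nrow(phy$edge))
  ntip <- length(phy$tip.label)

  tagEdgeOfNode <- function(node, tag) {
    e <- which(phy$edge[, 2] == node)
    if (!length(e)) stop("cannot label the root; mark a child branch")
    labels[e] <<- tag
  }
  # PAML-style marks on tips and node labels
  marks <- regmatches(phy$tip.label, regexpr("#\\d+$", phy$tip.label))
  if (length(marks)) {
    for (i in seq_along(phy$tip.label)) {
      m <- regmatches(phy$tip.label[i], regexpr("#(\\d+)$", phy$tip.label[i]))
      if (length(m)) {
        num <- sub("#", "", m)
        tag <- markMap[num]
        if (is.na(tag)) stop("no tag mapping for mark #", num)
        tagEdgeOfNode(i, tag)
        phy$tip.label[i] <- sub("#\\d+$", "", phy$tip.label[i])
      }
    }
  }
  if (!is.null(phy$node.label)) {
    for (k in seq_along(phy$node.label)) {
      nl <- phy$node.label[k]
      if (grepl("^#\\d+$", nl %||% "")) {
        num <- sub("#", "", nl)
        tag <- markMap[num]
        if (is.na(tag)) stop("no tag mapping for mark #", num)
        tagEdgeOfNode(ntip + k, tag)
        phy$node.label[k] <- ""
      }
    }
  }
  # external clade table
  if (!is.null(labelSpec)) {
    for (tag in names(labelSpec)) {
      spec <- labelSpec[[tag]]
      if (!is.list(spec)) spec <- list(spec)
      for (tipset in spec) {
        missing <- setdiff(tipset, phy$tip.label)
        if (length(missing))
          stop("label '", tag, "' names taxa absent from tree: ",
               paste(missing, collapse = ", "))
        node <- if (length(tipset) == 1L) match(tipset, phy$tip.label)
                else ape::getMRCA(phy, tipset)
        tagEdgeOfNode(node, tag)
      }
    }
  }
  new("LabeledTree", phy = phy, labels = labels)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Write a labeled tree to Newick
#'
#' Foreground/test edges are written as PAML-style \code{#n} marks
#' (\code{foreground}/\code{test} as \code{#1}, \code{reference} as
#' \code{#2}); reading the file back restores identical labels under
#' \code{markMap = c("1" = <tag>, "2" = "reference")}.
#'
#' @param tree a \code{\linkS4class{LabeledTree}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeLabeledTree <- function(tree, path) {
  phy <- tree@phy
  ntip <- length(phy$tip.label)
  markFor <- c(foreground = "#1", test = "#1", reference = "#2")
  if (is.null(phy$node.label)) phy$node.label <- rep("", phy$Nnode)
  for (e in seq_len(nrow(phy$edge))) {
    tag <- tree@labels[e]
    if (tag == "background") next
    node <- phy$edge[e, 2]
    if (node <= ntip)
      phy$tip.label[node] <- paste0(phy$tip.label[node], markFor[tag])
    else
      phy$node.label[node - ntip] <- markFor[tag]
  }
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' @param path TSV with columns \code{gene}, \code{class} (one of
#'   \code{cone}, \code{rod}, \code{both}) and \code{role} (one of
#'   \code{activation}, \code{recovery}).
#' @return validated data.frame.
#' @export
readGeneAnnotation <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  validateGeneAnnotation(ann)
}

#' Validate a gene annotation table
#'
#' @param ann data.frame with columns \code{gene}, \code{class},
#'   \code{role}.
#' @return the validated data.frame (invisibly unchanged).
#' @export
validateGeneAnnotation <- function(ann) {
  stopifnot(all(c("gene", "class", "role") %in% names(ann)))
  if (anyDuplicated(ann$gene))
    stop("genes annotated more than once: ",
         paste(unique(ann$gene[duplicated(ann$gene)]), collapse = ", "))
  bad <- setdiff(unique(ann$class), c("cone", "rod", "both"))
  if (length(bad)) stop("unknown photoreceptor class: ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(unique(ann$role), c("activation", "recovery"))
  if (length(bad)) stop("unknown functional role: ",
                        paste(bad, collapse = ", "))
  ann
}

#' Small built-in example alignment
#'
#' A four-taxon, eight-codon in-frame toy alignment used in examples and
#' tests; constructed in code, no file involved.
#'
#' @return a \code{\linkS4class{CodonAlignment}}.
#' @export
exampleToyAlignment <- function() {
  codonAlignment(c(
    t1 = "ATGAAACCCGGGTTTCTAGCAACC",
    t2 = "ATGAAGCCCGGATTTCTAGCAACC",
    t3 = "ATGAAACCGGGGTTCCTAGCGACC",
    t4 = "ATGAAGCCGGGATTCTTAGCGACA"))
}
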