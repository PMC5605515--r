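# Static genetic-code machinery shared by the whole engine.
#
# Codons are ordered by base order T, C, A, G (the conventional codon-model
# ordering); the three standard-code stop codons are removed, leaving the 61
# sense codons every rate matrix and alignment column is indexed by.

.codonBases <- c("T", "C", "A", "G")

.buildCodonTable <- function() {
  b <- .codonBases
  all64 <- character(64)
  k <- 0L
  for (i in b) for (j in b) for (l in b) {
    k <- k + 1L
    all64[k] <- paste0(i, j, l)
  }
  gc <- Biostrings::GENETIC_CODE
  aa64 <- unname(gc[all64])
  sense <- all64[aa64 != "*"]
  aa <- aa64[aa64 != "*"]
  n <- length(sense)
  stopifnot(n == 61L)
  idx <- seq_len(n)
  names(idx) <- sense
  nucIdx <- matrix(0L, n, 3L)
  for (p in 1:3)
    nucIdx[, p] <- match(substr(sense, p, p), b)
  # pairwise classification: single-nucleotide step, transition, nonsynonymous
  stepM <- matrix(0, n, n)
  tiM <- matrix(0, n, n)
  nsM <- matrix(0, n, n)
  isTi <- function(x, y) (x == "A" && y == "G") || (x == "G" && y == "A") ||
    (x == "C" && y == "T") || (x == "T" && y == "C")
  for (i in idx) for (j in idx) {
    if (i == j) next
    d <- which(strsplit(sense[i], "")[[1]] != strsplit(sense[j], "")[[1]])
    if (length(d) == 1L) {
      stepM[i, j] <- 1
      x <- substr(sense[i], d, d)
      y <- substr(sense[j], d, d)
      if (isTi(x, y)) tiM[i, j] <- 1
      if (aa[i] != aa[j]) nsM[i, j] <- 1
    }
  }
  list(codons = sense, index = idx, aa = aa, nucIndex = nucIdx,
       step = stepM, ti = tiM, ns = nsM,
       stops = all64[aa64 == "*"])
}

.pd <- new.env(parent = emptyenv())

.codonTable <- function() {
  if (is.null(.pd$codon)) .pd$codon <- .buildCodonTable()
  .pd$codon
}

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 sense codons in engine order
#'   (base order T, C, A, G).
#' @export
#' @examples
#' head(senseCodons())
senseCodons <- function() .codonTable()$codons

# amino-acid alphabet in the conventional rate-matrix order
.aaAlphabet <- function() c("A","R","N","D","C","Q","E","G","H","I",
                            "L","K","M","F","P","S","T","W","Y","V")

# translate a vector of codon indices (NA allowed) to one-letter amino acids
.translateCodonIndex <- function(i) {
  ct <- .codonTable()
  out <- rep(NA_character_, length(i))
  ok <- !is.na(i)
  out[ok] <- ct$aa[i[ok]]
  out
}
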