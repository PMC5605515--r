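#' Codon frequency estimation
#'
#' Computes the equilibrium frequencies of the 61 sense codons from an
#' alignment under one of three schemes: \code{"F3x4"} (product of
#' position-specific nucleotide frequencies, renormalized over sense
#' codons; the default used throughout the package), \code{"F61"}
#' (empirical codon frequencies with a pseudocount) or \code{"equal"}.
#'
#' @param aln a \code{\linkS4class{CodonAlignment}}.
#' @param freqModel one of \code{"F3x4"}, \code{"F61"}, \code{"equal"}.
#' @param pseudocount added to every codon count under \code{"F61"}
#'   (default 1; 0 gives the raw empirical frequencies).
#' @return numeric vector of length 61, positive entries summing to one,
#'   named by codon.
#' @export
#' @examples
#' aln <- exampleToyAlignment()
#' f <- buildCodonFrequencies(aln, "equal")
#' stopifnot(abs(sum(f) - 1) < 1e-12)
buildCodonFrequencies <- function(aln,
                                  freqModel = c("F3x4", "F61", "equal"),
                                  pseudocount = 1) {
  freqModel <- match.arg(freqModel)
  ct <- .codonTable()
  n <- 61L
  if (freqModel == "equal") {
    f <- rep(1 / n, n)
  } else if (freqModel == "F61") {
    obs <- aln@codons[!is.na(aln@codons)]
    cnt <- tabulate(obs, nbins = n) + pseudocount
    if (sum(cnt) == 0) stop("no observed codons and zero pseudocount")
    f <- cnt / sum(cnt)
    if (any(f == 0)) { # raw empirical with unseen codons: keep mass as-is
      f <- f
    }
  } else {
    obs <- aln@codons[!is.na(aln@codons)]
    if (!length(obs)) stop("alignment has no observed codons")
    # position-specific nucleotide counts over observed codons
    posFreq <- matrix(0, 3, 4)
    for (p in 1:3) {
      tab <- tabulate(ct$nucIndex[obs, p], nbins = 4)
      posFreq[p, ] <- (tab + 1e-8) / sum(tab + 1e-8)
    }
    f <- posFreq[1, ct$nucIndex[, 1]] *
         posFreq[2, ct$nucIndex[, 2]] *
         posFreq[3, ct$nucIndex[, 3]]
    f <- f / sum(f)
  }
  names(f) <- ct$codons
  f
}

#' Goldman-Yang codon rate matrix
#'
#' Builds the 61x61 generator with entries
#' \eqn{q_{ij} = \pi_j \kappa^{I[ti]} \omega^{I[ns]}} for codon pairs
#' differing at exactly one nucleotide position (zero otherwise), diagonal
#' set to minus the row sum. By default the matrix is rescaled so the
#' expected substitution rate \eqn{\sum_i \pi_i (-q_{ii})} equals one
#' (branch lengths then read as expected substitutions per codon).
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param codonFreqs positive 61-vector summing to one.
#' @param rescale rescale to unit expected rate (default TRUE).
#' @return 61x61 generator matrix with codon dimnames.
#' @export
buildRateMatrix <- function(kappa, omega, codonFreqs, rescale = TRUE) {
  stopifnot(kappa > 0, omega >= 0, length(codonFreqs) == 61L)
  if (abs(sum(codonFreqs) - 1) > 1e-8 || any(codonFreqs <= 0))
    stop("codonFreqs must be a positive vector summing to 1")
  ct <- .codonTable()
  Q <- ct$step * (ct$ti * kappa + (1 - ct$ti)) *
       ((1 - ct$ns) + ct$ns * omega)
  Q <- sweep(Q, 2L, codonFreqs, "*")
  diag(Q) <- -rowSums(Q)
  if (rescale) {
    r <- -sum(codonFreqs * diag(Q))
    if (r > 0) Q <- Q / r
  }
  dimnames(Q) <- list(ct$codons, ct$codons)
  Q
}

#' Transition probability matrix
#'
#' Computes \eqn{P(t) = \exp(Qt)} for a reversible generator via the
#' symmetric eigendecomposition in the \eqn{\pi}-weighted inner product.
#' Small negative entries produced by round-off are clamped at zero.
#'
#' @param Q reversible generator from \code{\link{buildRateMatrix}} (or any
#'   generator reversible with respect to \code{pi}).
#' @param t branch length (>= 0).
#' @param pi stationary frequencies of \code{Q}; if missing, recovered from
#'   the null left eigenvector.
#' @return stochastic matrix of the same dimension as \code{Q}.
#' @export
transitionMatrix <- function(Q, t, pi = NULL) {
  if (t < 0) stop("branch length t must be >= 0")
  n <- nrow(Q)
  if (is.null(pi)) {
    e <- eigen(t(Q))
    i <- which.min(abs(e$values))
    pi <- Re(e$vectors[, i])
    pi <- pi / sum(pi)
  }
  sq <- sqrt(pi)
  A <- Q * (sq %o% (1 / sq))
  A <- (A + t(A)) / 2
  es <- eigen(A, symmetric = TRUE)
  P <- es$vectors %*% (exp(es$values * t) * t(es$vectors))
  P <- P * ((1 / sq) %o% sq)
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P
}
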