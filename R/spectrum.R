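#' Build the k-mer spectrum of a sequence
#'
#' Counts every length-\code{k} window consisting solely of
#' \code{A,C,G,T}. Input is uppercased first, so soft-masked sequence is
#' handled; windows containing any other character (\code{N}, IUPAC codes,
#' gaps) are skipped and excluded from \code{L}. When \code{sequence} has
#' several elements (e.g. the contigs of one genome) k-mers are extracted
#' per element and pooled, so no window spans a boundary.
#'
#' @param sequence character vector of DNA sequence(s).
#' @param k k-mer length, a single integer >= 1.
#' @param canonical if \code{TRUE}, each window is replaced by the
#'   lexicographic minimum of itself and its reverse complement. The
#'   mutation model and the bias theorems are strand-fixed, so this is
#'   \code{FALSE} by default and intended for the double-stranded ANI mode.
#' @return a [KmerSpectrum-class].
#' @examples
#' sp <- kmerSpectrum("ACGTA", k = 2)
#' kmerCounts(sp)
#' @export
kmerSpectrum <- function(sequence, k, canonical = FALSE) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 ||
      k != as.integer(k))
    stop("invalid k: must be a single positive integer")
  k <- as.integer(k)
  if (!is.character(sequence) || length(sequence) < 1L)
    stop("'sequence' must be a non-empty character vector")
  sequence <- toupper(sequence)
  if (all(nchar(sequence) < k))
    stop("sequence too short: no window of length k available")
  res <- cpp_count_kmers(sequence, k, isTRUE(canonical))
  counts <- res$counts
  names(counts) <- res$kmers
  new("KmerSpectrum", k = k, L = res$L, counts = counts,
      canonical = isTRUE(canonical))
}

#' @describeIn kmerSpectrum k-mer length accessor.
#' @param x a \code{KmerSpectrum}.
#' @export
kmerSize <- function(x) x@k

#' @describeIn kmerSpectrum total number of counted k-mer positions L.
#' @export
totalKmers <- function(x) x@L

#' @describeIn kmerSpectrum named integer vector of occurrence counts.
#' @export
kmerCounts <- function(x) x@counts

#' @describeIn kmerSpectrum character vector of the distinct k-mers sp(s).
#' @export
distinctKmers <- function(x) names(x@counts)

setMethod("show", "KmerSpectrum", function(object) {
  cat(sprintf("KmerSpectrum: k=%d, L=%s, %d distinct k-mers%s\n",
              object@k, format(object@L, big.mark = ","),
              length(object@counts),
              if (object@canonical) " (canonical)" else ""))
})

#' Hamming distance between two equal-length k-mers
#'
#' @param a,b character strings of equal length.
#' @return number of positions at which they differ.
#' @examples
#' hammingDistance("ACG", "TGC")
#' @export
hammingDistance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("k-mers must have equal length")
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Hamming-distance-1 neighbor table of a spectrum
#'
#' For each distinct k-mer tau of the spectrum, counts the distinct
#' spectrum members at Hamming distance exactly 1 from tau (tau itself is
#' at distance 0 and never counted), by enumerating all 3k single-base
#' substitution neighbors and testing membership. Also computes the
#' occurrence-weighted sum \eqn{C = \sum_\tau occ(\tau) d_1(\tau)}, the
#' precomputed constant of the count-count estimator's correction term.
#'
#' @param spec a [KmerSpectrum-class].
#' @return a [D1Summary-class].
#' @examples
#' d1Table(kmerSpectrum("AATA", 2))
#' @export
d1Table <- function(spec) {
  stopifnot(is(spec, "KmerSpectrum"))
  d1 <- cpp_d1_counts(names(spec@counts))
  names(d1) <- names(spec@counts)
  C <- sum(as.numeric(spec@counts) * as.numeric(d1))
  new("D1Summary", k = spec@k, d1 = d1, weightedSumC = C)
}

#' @describeIn d1Table named integer vector of d1 values.
#' @param x a \code{D1Summary}.
#' @export
d1Counts <- function(x) x@d1

#' @describeIn d1Table the weighted sum C.
#' @export
weightedNeighborSum <- function(x) x@weightedSumC

setMethod("show", "D1Summary", function(object) {
  cat(sprintf("D1Summary: k=%d, %d k-mers, C=%s\n", object@k,
              length(object@d1), format(object@weightedSumC)))
})

#' Hamming-distance profile of a k-mer against a spectrum
#'
#' Entry j (j = 1..k) is the number of distinct spectrum members at
#' Hamming distance exactly j from \code{tau}. Brute force over all
#' spectrum members; intended for the exact-expectation oracle on tiny
#' inputs.
#'
#' @param tau a k-mer string of length \code{kmerSize(spec)}.
#' @param spec a [KmerSpectrum-class].
#' @return integer vector of length k.
#' @examples
#' djCounts("AA", kmerSpectrum("AATA", 2))
#' @export
djCounts <- function(tau, spec) {
  stopifnot(is(spec, "KmerSpectrum"))
  k <- spec@k
  if (nchar(tau) != k) stop("k-mers must have equal length")
  tau <- toupper(tau)
  members <- names(spec@counts)
  tchars <- strsplit(tau, "", fixed = TRUE)[[1]]
  d <- vapply(strsplit(members, "", fixed = TRUE),
              function(m) sum(m != tchars), integer(1))
  tabulate(d[d >= 1L], nbins = k)
}
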