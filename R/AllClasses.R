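#' @import methods
NULL

#' KmerSpectrum: the multiset of k-mers of a sequence
#'
#' A \code{KmerSpectrum} stores the distinct k-mers of one (or a pool of)
#' DNA sequence(s) together with their occurrence counts and the total
#' number of counted k-mer positions \code{L}. Only windows consisting
#' solely of \code{A,C,G,T} are counted; windows containing any other
#' character (e.g. \code{N}) are skipped and do not contribute to \code{L}.
#'
#' @slot k k-mer length.
#' @slot L total number of counted k-mer positions (for a clean single
#'   sequence, \code{nchar(s) - k + 1}).
#' @slot counts named integer vector: occurrence count per distinct k-mer,
#'   names sorted lexicographically.
#' @slot canonical logical; if \code{TRUE} each window was replaced by the
#'   lexicographic minimum of itself and its reverse complement before
#'   counting.
#' @seealso [kmerSpectrum()]
#' @exportClass KmerSpectrum
setClass("KmerSpectrum",
  representation(k = "integer", L = "numeric", counts = "integer",
                 canonical = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
      msg <- c(msg, "'k' must be a single positive integer")
    if (length(object@L) != 1L || is.na(object@L) || object@L < 0)
      msg <- c(msg, "'L' must be a single non-negative number")
    cnt <- object@counts
    if (length(cnt)) {
      nm <- names(cnt)
      if (is.null(nm)) return("'counts' must be named by k-mer")
      if (any(nchar(nm) != object@k))
        msg <- c(msg, "every k-mer must have length k")
      if (any(grepl("[^ACGT]", nm)))
        msg <- c(msg, "k-mers must be over the alphabet {A,C,G,T}")
      if (any(cnt < 1L)) msg <- c(msg, "occurrence counts must be positive")
      if (sum(as.numeric(cnt)) != object@L)
        msg <- c(msg, "sum of counts must equal L")
      if (length(cnt) > object@L)
        msg <- c(msg, "number of distinct k-mers cannot exceed L")
    } else if (object@L != 0) {
      msg <- c(msg, "empty counts require L == 0")
    }
    if (length(msg)) msg else TRUE
  })

#' D1Summary: Hamming-distance-1 neighborhood of a spectrum
#'
#' For each distinct k-mer tau of a source spectrum, the number
#' \eqn{d_1(\tau, s)} of distinct spectrum members at Hamming distance
#' exactly 1 from tau, plus the occurrence-weighted sum
#' \eqn{C = \sum_\tau occ(\tau, s) d_1(\tau, s)} used by the count-count
#' estimator's bias-correction term.
#'
#' @slot k k-mer length of the source spectrum.
#' @slot d1 named integer vector over the spectrum's distinct k-mers.
#' @slot weightedSumC the constant \eqn{C}.
#' @seealso [d1Table()], [qCc()]
#' @exportClass D1Summary
setClass("D1Summary",
  representation(k = "integer", d1 = "integer", weightedSumC = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@d1) && is.null(names(object@d1)))
      msg <- c(msg, "'d1' must be named by k-mer")
    if (any(object@d1 < 0L) || any(object@d1 > 3L * object@k))
      msg <- c(msg, "d1 values must lie in [0, 3k]")
    if (length(msg)) msg else TRUE
  })

#' KmerObservations: raw pair statistics for the estimators
#'
#' The sufficient statistics extracted from a pair of spectra (or sketches)
#' of a source sequence s and a target sequence t:
#' \describe{
#'   \item{Ipp}{\eqn{|sp(s) \cap sp(t)|}, the shared distinct k-mers.}
#'   \item{Npp}{\eqn{|sp(t) \setminus sp(s)|}, the novel distinct k-mers.}
#'   \item{Npc}{\eqn{\sum_{\tau \in sp(t) \setminus sp(s)} occ(\tau, t)},
#'     the occurrence-weighted novel k-mers.}
#'   \item{Icc}{\eqn{\sum_\tau \min(occ(\tau,s), occ(\tau,t))}, the weighted
#'     intersection.}
#' }
#' For sketched observations, the set statistics are computed over the
#' retained k-mers only while \code{L} carries the full (unsketched) k-mer
#' count of the source, as required by the \eqn{\theta L} denominators.
#'
#' @slot k k-mer length.
#' @slot L k-mer count of the source sequence s (full L when sketched).
#' @slot Lt k-mer count of the target sequence t (full L when sketched).
#' @slot Ipp,Npp,Npc,Icc,unionSize the pair statistics.
#' @slot theta FracMinHash sampling fraction under which the statistics
#'   were observed; 1 for unsketched observations.
#' @seealso [kmerObservations()], [sketchedObservations()]
#' @exportClass KmerObservations
setClass("KmerObservations",
  representation(k = "integer", L = "numeric", Lt = "numeric",
                 Ipp = "numeric", Npp = "numeric", Npc = "numeric",
                 Icc = "numeric", unionSize = "numeric", theta = "numeric"),
  validity = function(object) {
    msg <- character()
    for (sl in c("L", "Lt", "Ipp", "Npp", "Npc", "Icc", "unionSize")) {
      v <- slot(object, sl)
      if (length(v) != 1L || is.na(v) || v < 0)
        msg <- c(msg, sprintf("'%s' must be a single non-negative number", sl))
    }
    if (length(msg)) return(msg)
    if (object@Npp > object@Npc)
      msg <- c(msg, "Npp cannot exceed Npc (each novel distinct k-mer has count >= 1)")
    if (object@theta >= 1) {
      if (object@Icc > object@L || object@Icc > object@Lt)
        msg <- c(msg, "Icc cannot exceed L or Lt")
    }
    if (length(object@theta) != 1L || object@theta <= 0 || object@theta > 1)
      msg <- c(msg, "'theta' must be in (0, 1]")
    if (length(msg)) msg else TRUE
  })

#' FracMinHashSketch: a fraction-thresholded subsample of a spectrum
#'
#' Retains exactly the k-mers whose seeded 64-bit hash falls below
#' \code{theta} times the hash range, carrying occurrence counts over
#' unchanged. The full-sequence k-mer count \code{fullL} is stored because
#' the sketched estimators divide by \eqn{\theta L} with the true L.
#'
#' @slot k k-mer length.
#' @slot theta sampling fraction in (0, 1].
#' @slot hashSeed integer seed of the hash function.
#' @slot fullL L of the unsketched source spectrum.
#' @slot retained named integer vector of retained k-mers and their counts.
#' @seealso [sketchSpectrum()]
#' @exportClass FracMinHashSketch
setClass("FracMinHashSketch",
  representation(k = "integer", theta = "numeric", hashSeed = "integer",
                 fullL = "numeric", retained = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@theta) != 1L || object@theta <= 0 || object@theta > 1)
      msg <- c(msg, "'theta' must be in (0, 1]")
    if (length(object@retained) && is.null(names(object@retained)))
      msg <- c(msg, "'retained' must be named by k-mer")
    if (length(msg)) msg else TRUE
  })

#' MutationRateEstimate: a point estimate of q and r
#'
#' The result of one estimator applied to one pair of observations:
#' the estimate \eqn{\hat q} of the k-mer mutation probability
#' \eqn{q = 1 - (1-r)^k}, clamped into [0, 1], and the implied substitution
#' rate \eqn{\hat r = 1 - (1 - \hat q)^{1/k}}.
#'
#' @slot estimator one of \code{"obl"}, \code{"mash"}, \code{"pp"},
#'   \code{"pc"}, \code{"wi"}, \code{"cc"}, \code{"pp_theta"},
#'   \code{"pc_theta"}, \code{"cc_theta"}.
#' @slot k k-mer length.
#' @slot qHat estimate of q in [0, 1].
#' @slot rHat estimate of r, \code{rOfQ(qHat, k)} exactly.
#' @exportClass MutationRateEstimate
setClass("MutationRateEstimate",
  representation(estimator = "character", k = "integer", qHat = "numeric",
                 rHat = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@qHat < 0 || object@qHat > 1)
      msg <- c(msg, "'qHat' must lie in [0, 1]")
    if (object@rHat != rOfQ(object@qHat, object@k))
      msg <- c(msg, "'rHat' must equal rOfQ(qHat, k)")
    if (length(msg)) msg else TRUE
  })

#' ExactExpectation: an exhaustively enumerated expectation
#'
#' @slot value the expectation.
#' @slot nOutcomes number of enumerated mutation outcomes (\eqn{4^{|s|}}).
#' @seealso [exactExpectation()]
#' @exportClass ExactExpectation
setClass("ExactExpectation",
  representation(value = "numeric", nOutcomes = "numeric"))
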