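# Exact expectations by exhaustive enumeration of every mutation outcome
# of a tiny string; the independent check of the Lemma-1 / Theorem-1 bias
# algebra. Per-outcome statistics are cached per (s, k) so sweeping r costs
# one enumeration.

.oracleCache <- new.env(parent = emptyenv())

.enumerateStrings <- function(n) {
  m <- 4^n
  cols <- lapply(seq_len(n), function(j)
    rep(.BASES, each = 4^(n - j), times = 4^(j - 1)))
  list(outcomes = do.call(paste0, cols), cols = cols, m = m)
}

#' Enumerate all outcomes of the mutation process on a tiny string
#'
#' Yields every string t of the same length as \code{s} over
#' \code{A,C,G,T} with its probability \eqn{\prod_i p_i} under the
#' substitution process, where \eqn{p_i = 1 - r} if \eqn{t_i = s_i} and
#' \eqn{r/3} otherwise. Probabilities sum to 1. Practical ceiling
#' \code{nchar(s) <= 12} (about 1.7e7 outcomes).
#'
#' @param s a DNA string, at most 12 characters.
#' @param r substitution rate in [0, 1].
#' @return data.frame with columns \code{outcome}, \code{probability}.
#' @examples
#' enumerateOutcomes("A", 0.3)
#' @export
enumerateOutcomes <- function(s, r) {
  s <- .checkDna(s)
  n <- nchar(s)
  if (n > 12)
    stop("string too long for exhaustive enumeration (max length 12)")
  en <- .enumerateStrings(n)
  sChars <- strsplit(s, "", fixed = TRUE)[[1]]
  h <- Reduce(`+`, lapply(seq_len(n),
                          function(j) as.integer(en$cols[[j]] != sChars[j])))
  data.frame(outcome = en$outcomes,
             probability = (1 - r)^(n - h) * (r / 3)^h)
}

# per-outcome Hamming distances to s and pair statistics, computed through
# the production counting (cpp_count_kmers) and aggregation (.pairStats)
# code paths; cached per (s, k)
.outcomeStats <- function(s, k) {
  key <- paste(s, k, sep = "|")
  hit <- .oracleCache[[key]]
  if (!is.null(hit)) return(hit)
  n <- nchar(s)
  en <- .enumerateStrings(n)
  sChars <- strsplit(s, "", fixed = TRUE)[[1]]
  h <- Reduce(`+`, lapply(seq_len(n),
                          function(j) as.integer(en$cols[[j]] != sChars[j])))
  countsS <- kmerCounts(kmerSpectrum(s, k))
  L <- nchar(s) - k + 1
  stat <- matrix(0, nrow = en$m, ncol = 4,
                 dimnames = list(NULL, c("Ipp", "Npp", "Npc", "Icc")))
  for (i in seq_len(en$m)) {
    res <- cpp_count_kmers(en$outcomes[i], k, FALSE)
    ct <- res$counts
    names(ct) <- res$kmers
    st <- .pairStats(countsS, ct)
    stat[i, ] <- c(st$Ipp, st$Npp, st$Npc, st$Icc)
  }
  out <- list(h = h, stat = stat, L = L, n = n, m = en$m)
  .oracleCache[[key]] <- out
  out
}

#' Exact expectation of a pair statistic under the mutation process
#'
#' Computes \eqn{\sum_t P(t) \cdot statistic(s, t)} over all \eqn{4^{|s|}}
#' mutation outcomes, with the statistics evaluated through the same
#' counting and aggregation code used by the estimators.
#'
#' @param s a DNA string (enumeration must be feasible, \code{nchar(s) <=
#'   12}).
#' @param k k-mer length.
#' @param r substitution rate.
#' @param statistic one of \code{"Npp"}, \code{"Npc"}, \code{"Icc"},
#'   \code{"Ipp"}, \code{"q_pp"}, \code{"q_pc"}.
#' @return an [ExactExpectation-class].
#' @examples
#' exactExpectation("AAAAA", 2, 0.2, "Npc")
#' @export
exactExpectation <- function(s, k, r,
                             statistic = c("Npp", "Npc", "Icc", "Ipp",
                                           "q_pp", "q_pc")) {
  statistic <- match.arg(statistic)
  s <- .checkDna(s)
  if (nchar(s) > 12)
    stop("string too long for exhaustive enumeration (max length 12)")
  if (nchar(s) < k) stop("sequence too short")
  os <- .outcomeStats(s, k)
  probs <- (1 - r)^(os$n - os$h) * (r / 3)^os$h
  tot <- sum(probs)
  if (abs(tot - 1) > 1e-12)
    stop("internal error: outcome probabilities do not sum to 1")
  vals <- switch(statistic,
    Npp = os$stat[, "Npp"],
    Npc = os$stat[, "Npc"],
    Icc = os$stat[, "Icc"],
    Ipp = os$stat[, "Ipp"],
    q_pp = .clamp01(os$stat[, "Npp"] / os$L),
    q_pc = .clamp01(os$stat[, "Npc"] / os$L))
  new("ExactExpectation", value = sum(probs * vals), nOutcomes = os$m)
}

setMethod("show", "ExactExpectation", function(object) {
  cat(sprintf("ExactExpectation: value=%.10g over %s outcomes\n",
              object@value, format(object@nOutcomes, big.mark = ",")))
})

#' @describeIn exactExpectation the expectation value.
#' @param x an \code{ExactExpectation}.
#' @export
expectationValue <- function(x) x@value

# R_j(tau, s) = d_j(tau, s) (1-r)^(k-j) (r/3)^j summed over j = 1..k
.neighborReturnProb <- function(dj, k, r) {
  j <- seq_len(k)
  sum(dj * (1 - r)^(k - j) * (r / 3)^j)
}

#' Closed-form expectation of the occurrence-weighted novel k-mer count
#'
#' Computes \eqn{L q - \sum_{\tau \in sp(s)} occ(\tau, s) R(\tau, s)},
#' where \eqn{R(\tau, s) = \sum_{j=1}^k d_j(\tau, s) (1-r)^{k-j}
#' (r/3)^j} is the probability that \eqn{\tau} mutates into a different
#' k-mer already present in s. This closed form must agree with
#' \code{exactExpectation(s, k, r, "Npc")}; the agreement is the exactness
#' check of the expectation lemma underlying the presence-count estimator.
#'
#' @param s a DNA string.
#' @param k k-mer length.
#' @param r substitution rate.
#' @return the expectation as a number.
#' @export
lemma1Rhs <- function(s, k, r) {
  s <- .checkDna(s)
  spec <- kmerSpectrum(s, k)
  q <- qOfR(r, k)
  Rvals <- vapply(distinctKmers(spec),
                  function(tau) .neighborReturnProb(djCounts(tau, spec), k, r),
                  numeric(1))
  spec@L * q - sum(as.numeric(kmerCounts(spec)) * Rvals)
}

#' Exact bias of the presence-count estimator
#'
#' Returns \eqn{-\sum_{j=1}^k \sum_{\tau \in sp(s)} occ(\tau, s)
#' R_j(\tau, s) / L}, the bias \eqn{E[\hat q^{pc}] - q}. It is a sum of
#' non-positive terms, zero exactly when no spectrum member has another
#' member within Hamming distance k, and must match the enumerated
#' \code{exactExpectation(s, k, r, "q_pc")} minus q.
#'
#' @inheritParams lemma1Rhs
#' @return the (non-positive) bias.
#' @export
theorem1Bias <- function(s, k, r) {
  s <- .checkDna(s)
  spec <- kmerSpectrum(s, k)
  Rvals <- vapply(distinctKmers(spec),
                  function(tau) .neighborReturnProb(djCounts(tau, spec), k, r),
                  numeric(1))
  -sum(as.numeric(kmerCounts(spec)) * Rvals) / spec@L
}
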