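#' Apply the substitution mutation process to a sequence
#'
#' Each position, independently, is left unchanged with probability
#' \eqn{1 - r} and otherwise replaced by one of the three other
#' nucleotides, each with probability \eqn{r/3}. A substituted character
#' is never equal to the original. The output has the same length as the
#' input. Deterministic given \code{(sequence, r, seed)}.
#'
#' @param sequence a single DNA string over \code{A,C,G,T} (case
#'   insensitive; the mutation process is defined only on clean sequences).
#' @param r per-position substitution rate in [0, 1].
#' @param seed optional integer seed; when given, the caller's RNG state is
#'   left untouched.
#' @return the mutated DNA string (uppercase).
#' @examples
#' mutateSequence("ACGTACGT", r = 0.5, seed = 1)
#' @export
mutateSequence <- function(sequence, r, seed = NULL) {
  sequence <- .checkDna(sequence)
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 1)
    stop("'r' must be a single number in [0, 1]")
  withLocalSeed(seed, {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    n <- length(chars)
    hit <- stats::runif(n) < r
    if (any(hit)) {
      idx <- match(chars[hit], .BASES)
      # the three alternatives of base b, in fixed order
      alt <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                   c("A", "C", "T"), c("A", "C", "G"))
      pick <- sample.int(3L, sum(hit), replace = TRUE)
      chars[hit] <- alt[cbind(idx, pick)]
    }
    paste(chars, collapse = "")
  })
}

#' k-mer mutation probability q and its inverse
#'
#' \code{qOfR} maps the per-position substitution rate r to the probability
#' \eqn{q = 1 - (1-r)^k} that a k-mer contains at least one substitution.
#' \code{rOfQ} is its exact inverse \eqn{r = 1 - (1-q)^{1/k}}; inputs
#' outside [0, 1] are clamped before inversion, so estimator plug-ins are
#' always well defined.
#'
#' @param r,q rates/probabilities in [0, 1] (vectorized).
#' @param k k-mer length.
#' @return numeric vector in [0, 1].
#' @examples
#' qOfR(0.1, 2)          # 0.19
#' rOfQ(qOfR(0.3, 21), 21)
#' @export
qOfR <- function(r, k) 1 - (1 - r)^k

#' @rdname qOfR
#' @export
rOfQ <- function(q, k) 1 - (1 - .clamp01(q))^(1 / k)
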