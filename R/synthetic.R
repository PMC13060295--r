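#' Random i.i.d. DNA sequence
#'
#' Uniform i.i.d. characters over \code{A,C,G,T}; deterministic given
#' \code{seed}.
#'
#' @param length sequence length, >= 1.
#' @param seed optional integer seed.
#' @return a DNA string.
#' @export
randomSequence <- function(length, seed = NULL) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
      length < 1)
    stop("'length' must be a positive integer")
  withLocalSeed(seed,
    paste(sample(.BASES, length, replace = TRUE), collapse = ""))
}

#' Tandem-repeat array emulating alpha-satellite structure
#'
#' Draws one random monomer (default 171 bp, the alpha-satellite monomer
#' length) and emits \code{nCopies} diverged tandem copies, about 100 kbp
#' at the defaults. Two divergence models are available:
#' \describe{
#'   \item{\code{"lineage"} (default)}{copy i is the previous copy passed
#'     through the substitution process at rate
#'     \code{perCopyDivergence}. Substitution variants are inherited by
#'     later copies, emulating the concerted evolution of satellite
#'     arrays. The default divergence (0.0013) is calibrated so the
#'     100 kbp array reproduces the repetitiveness profile of a hard
#'     centromeric alpha-satellite extraction at k = 30: about 4,000
#'     distinct 30-mers, well over 70\% of them occurring more than
#'     once, and at least one spectrum member at Hamming distance 1 from
#'     the average distinct 30-mer.}
#'   \item{\code{"independent"}}{every copy is the root monomer mutated
#'     independently at rate \code{perCopyDivergence}. Variants are only
#'     shared when two copies happen to draw the same substitution, which
#'     caps the repeated fraction well below one half; retained as the
#'     simpler null model.}
#' }
#'
#' @param monomerLength monomer length in bp (default 171).
#' @param nCopies number of tandem copies.
#' @param perCopyDivergence per-copy substitution rate in [0, 1].
#' @param seed optional integer seed.
#' @param mode divergence model, \code{"lineage"} or \code{"independent"}.
#' @param check if \code{TRUE} (default) and the output is at least 1 kbp,
#'   the two repetitiveness hallmarks are verified at k = 30 and a warning
#'   is emitted if either fails (expected for parameter corners such as
#'   zero divergence, where the array is perfectly periodic, and for the
#'   independent model).
#' @return a DNA string of length \code{monomerLength * nCopies}.
#' @export
tandemRepeatSequence <- function(monomerLength = 171L, nCopies = 585L,
                                 perCopyDivergence = 0.0013, seed = NULL,
                                 mode = c("lineage", "independent"),
                                 check = TRUE) {
  mode <- match.arg(mode)
  stopifnot(monomerLength >= 1, nCopies >= 1,
            perCopyDivergence >= 0, perCopyDivergence <= 1)
  out <- withLocalSeed(seed, {
    monomer <- paste(sample(.BASES, monomerLength, replace = TRUE),
                     collapse = "")
    if (mode == "lineage") {
      copies <- character(nCopies)
      cur <- monomer
      for (i in seq_len(nCopies)) {
        cur <- mutateSequence(cur, perCopyDivergence)
        copies[i] <- cur
      }
    } else {
      copies <- vapply(seq_len(nCopies),
                       function(i) mutateSequence(monomer, perCopyDivergence),
                       character(1))
    }
    paste(copies, collapse = "")
  })
  if (isTRUE(check) && nchar(out) >= 1000L && nchar(out) >= 30L) {
    st <- repeatArrayStats(out, k = 30L)
    if (st$fracRepeated <= 0.5 || st$meanD1 < 1)
      warning(sprintf(paste0(
        "generated array misses the hard-repeat hallmarks at k=30 ",
        "(fraction of distinct k-mers with count >= 2: %.3f; mean d1: %.3f)"),
        st$fracRepeated, st$meanD1))
  }
  out
}

#' @describeIn tandemRepeatSequence repetitiveness statistics of a
#'   sequence at a given k: number of distinct k-mers, fraction of
#'   distinct k-mers occurring more than once, and the mean number of
#'   Hamming-distance-1 neighbors per distinct k-mer.
#' @param sequence a DNA string.
#' @param k k-mer length (default 30).
#' @export
repeatArrayStats <- function(sequence, k = 30L) {
  spec <- kmerSpectrum(sequence, k)
  d1 <- d1Counts(d1Table(spec))
  list(nDistinct = length(kmerCounts(spec)),
       fracRepeated = mean(kmerCounts(spec) >= 2L),
       meanD1 = mean(d1))
}

#' Sequence with all-distinct, well-separated k-mers
#'
#' Rejection-samples random sequences until every one of the L k-mers is
#' distinct and (if \code{minPairwiseHd >= 2}) all pairs of k-mers are at
#' Hamming distance at least \code{minPairwiseHd}. Such sequences realize
#' the idealized model in which every k-mer of s is unique, used to
#' construct instances where the three presence-presence estimators must
#' coincide.
#'
#' @param length sequence length.
#' @param k k-mer length.
#' @param minPairwiseHd minimum pairwise Hamming distance between distinct
#'   k-mers (1 = merely distinct).
#' @param seed optional integer seed.
#' @param maxTries rejection-sampling cap.
#' @return a DNA string whose spectrum has \code{|sp| = L}.
#' @export
distinctKmerSequence <- function(length, k, minPairwiseHd = 1L, seed = NULL,
                                 maxTries = 1000L) {
  stopifnot(length >= k, minPairwiseHd >= 1)
  withLocalSeed(seed, {
    for (i in seq_len(maxTries)) {
      s <- paste(sample(.BASES, length, replace = TRUE), collapse = "")
      spec <- kmerSpectrum(s, k)
      if (base::length(kmerCounts(spec)) != spec@L) next
      if (minPairwiseHd >= 2L) {
        km <- distinctKmers(spec)
        mat <- do.call(rbind, strsplit(km, "", fixed = TRUE))
        ok <- TRUE
        for (a in seq_len(nrow(mat) - 1L)) {
          hd <- rowSums(mat[(a + 1L):nrow(mat), , drop = FALSE] !=
                          matrix(mat[a, ], nrow = nrow(mat) - a,
                                 ncol = k, byrow = TRUE))
          if (any(hd < minPairwiseHd)) { ok <- FALSE; break }
        }
        if (!ok) next
      }
      return(s)
    }
    stop("could not generate an all-distinct k-mer sequence; ",
         "reduce 'length' or 'minPairwiseHd', or increase 'k'")
  })
}
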