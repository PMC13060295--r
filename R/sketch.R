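#' FracMinHash-sketch a k-mer spectrum
#'
#' Retains exactly the k-mers whose seeded 64-bit hash falls below
#' \code{theta} times the hash range (integer comparison against
#' \code{floor(theta * 2^64)}), carrying occurrence counts over unchanged.
#' At \code{theta = 1} the sketch is the full spectrum. Deterministic
#' given \code{hashSeed}.
#'
#' @param spec a [KmerSpectrum-class].
#' @param theta sampling fraction in (0, 1].
#' @param hashSeed integer seed of the hash function. Two sketches are
#'   comparable only if they share \code{k}, \code{theta} and
#'   \code{hashSeed}; this is enforced by [sketchedObservations()].
#' @return a [FracMinHashSketch-class].
#' @examples
#' sk <- sketchSpectrum(kmerSpectrum("ACGTACGTTGCA", 4), theta = 0.5)
#' sk
#' @export
sketchSpectrum <- function(spec, theta, hashSeed = 0L) {
  stopifnot(is(spec, "KmerSpectrum"))
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta <= 0 || theta > 1)
    stop("'theta' must be a single number in (0, 1]")
  hashSeed <- as.integer(hashSeed)
  keep <- cpp_hash_keep(names(spec@counts), theta, hashSeed)
  new("FracMinHashSketch", k = spec@k, theta = theta, hashSeed = hashSeed,
      fullL = spec@L, retained = spec@counts[keep])
}

#' @describeIn sketchSpectrum named integer vector of retained counts.
#' @param x a \code{FracMinHashSketch}.
#' @export
retainedKmers <- function(x) x@retained

#' @describeIn sketchSpectrum sampling fraction theta.
#' @export
samplingFraction <- function(x) x@theta

setMethod("show", "FracMinHashSketch", function(object) {
  cat(sprintf(
    "FracMinHashSketch: k=%d, theta=%g, seed=%d, %d retained of full L=%s\n",
    object@k, object@theta, object@hashSeed, length(object@retained),
    format(object@fullL)))
})

#' Pair statistics over two FracMinHash sketches
#'
#' Computes the novel-k-mer statistics restricted to the retained k-mers,
#' \eqn{N^{pp}_\theta} and \eqn{N^{pc}_\theta}. The returned object
#' carries the FULL source L (the sketched estimators divide by
#' \eqn{\theta L}) and records theta, so [qPpTheta()] and friends apply
#' the right denominator. Both sketches must share k, theta and hash seed;
#' differing hash universes would make the set operations meaningless.
#'
#' @param skS,skT [FracMinHashSketch-class] objects of source and target.
#' @return a [KmerObservations-class] with \code{theta < 1} semantics.
#' @export
sketchedObservations <- function(skS, skT) {
  stopifnot(is(skS, "FracMinHashSketch"), is(skT, "FracMinHashSketch"))
  if (skS@k != skT@k) stop("k mismatch between sketches")
  if (skS@theta != skT@theta) stop("theta mismatch between sketches")
  if (skS@hashSeed != skT@hashSeed) stop("hash seed mismatch between sketches")
  st <- .pairStats(skS@retained, skT@retained)
  new("KmerObservations", k = skS@k, L = skS@fullL, Lt = skT@fullL,
      Ipp = st$Ipp, Npp = st$Npp, Npc = st$Npc, Icc = st$Icc,
      unionSize = st$unionSize, theta = skS@theta)
}

#' Sketched estimators of q
#'
#' The FracMinHash variants \eqn{\hat q^{pp}_\theta = N^{pp}_\theta /
#' (\theta L)}, \eqn{\hat q^{pc}_\theta = N^{pc}_\theta / (\theta L)} and
#' the corrected \eqn{\hat q^{cc}_\theta}. Sketching variance can push the
#' observed counts above \eqn{\theta L}, so all three are capped at 1.
#' Sketching leaves the bias of the pp and pc estimators unchanged; it
#' only adds variance (larger for smaller theta).
#'
#' For \code{qCcTheta} the d1 constant \eqn{C} must come from the FULL
#' (unsketched) source spectrum: it is precomputed prior to sketching and
#' enters the estimator as a single constant.
#'
#' @param obs a [KmerObservations-class] from [sketchedObservations()]
#'   (or from [kmerObservations()], in which case theta = 1 and the
#'   unsketched estimators are reproduced exactly).
#' @param d1sumFull a [D1Summary-class] of the full source spectrum.
#' @return a [MutationRateEstimate-class].
#' @name sketchedEstimators
NULL

#' @rdname sketchedEstimators
#' @export
qPpTheta <- function(obs) .obsToEstimate("pp", obs)

#' @rdname sketchedEstimators
#' @export
qPcTheta <- function(obs) .obsToEstimate("pc", obs)

#' @rdname sketchedEstimators
#' @export
qCcTheta <- function(obs, d1sumFull) {
  stopifnot(is(d1sumFull, "D1Summary"))
  if (d1sumFull@k != obs@k)
    stop("k mismatch between observations and d1 table")
  .obsToEstimate("cc", obs, C = d1sumFull@weightedSumC)
}

#' Write / read a sketch as a small JSON document
#'
#' The on-disk form records k, theta, the hash seed, the full-sequence L,
#' optionally the precomputed d1 constant C of the full spectrum, and the
#' retained (k-mer, count) pairs, so a genome can be sketched once and
#' compared many times. Sketch files are only comparable across runs that
#' use the same hash function and seed.
#'
#' @param sketch a [FracMinHashSketch-class].
#' @param path file path.
#' @param cFull optional d1 constant of the full source spectrum.
#' @return \code{readSketch} returns a list with elements \code{sketch}
#'   (the [FracMinHashSketch-class]) and \code{cFull} (or NULL).
#' @export
writeSketch <- function(sketch, path, cFull = NULL) {
  stopifnot(is(sketch, "FracMinHashSketch"))
  doc <- list(k = sketch@k, theta = sketch@theta,
              hash_seed = sketch@hashSeed, full_L = sketch@fullL,
              retained = Map(function(km, ct) list(km, ct),
                             names(sketch@retained),
                             unname(as.integer(sketch@retained))))
  names(doc$retained) <- NULL
  if (!is.null(cFull)) doc$C_full <- cFull
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSketch
#' @export
readSketch <- function(path) {
  doc <- jsonlite::read_json(path)
  retained <- vapply(doc$retained, function(p) as.integer(p[[2]]), integer(1))
  names(retained) <- vapply(doc$retained, function(p) as.character(p[[1]]),
                            character(1))
  sk <- new("FracMinHashSketch", k = as.integer(doc$k),
            theta = as.numeric(doc$theta),
            hashSeed = as.integer(doc$hash_seed),
            fullL = as.numeric(doc$full_L), retained = retained)
  list(sketch = sk,
       cFull = if (is.null(doc$C_full)) NULL else as.numeric(doc$C_full))
}
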