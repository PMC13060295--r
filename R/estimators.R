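# Shared statistic and estimator arithmetic. Every public estimator (and
# the evaluation fast path) funnels through .pairStats / .qFromStats so the
# formulas exist in exactly one place.

.pairStats <- function(countsS, countsT) {
  m <- match(names(countsT), names(countsS))
  shared <- !is.na(m)
  Ipp <- sum(shared)
  Npp <- length(countsT) - Ipp
  Npc <- sum(as.numeric(countsT[!shared]))
  Icc <- sum(pmin(as.numeric(countsT[shared]),
                  as.numeric(countsS[m[shared]])))
  list(Ipp = Ipp, Npp = Npp, Npc = Npc, Icc = Icc,
       unionSize = length(countsS) + Npp)
}

# q-hat for one estimator from raw statistics. `theta` = 1 reproduces the
# unsketched formulas; for "pp"/"pc"/"cc" the denominator is theta * L.
.qFromStats <- function(name, Ipp, Npp, Npc, Icc, unionSize, L, k,
                        theta = 1, C = NULL) {
  switch(name,
    obl = .clamp01((L - Ipp) / L),
    mash = {
      # (1 - J)/(1 + J) with J = Ipp/union, computed in the integer form
      # (U - Ipp)/(U + Ipp): one rounding instead of three, so in the
      # k-span regime (union = 2L - Ipp) it is bit-identical to (L - Ipp)/L
      if (unionSize > 0)
        .clamp01((unionSize - Ipp) / (unionSize + Ipp))
      else 1
    },
    pp = .clamp01(Npp / (theta * L)),
    pc = .clamp01(Npc / (theta * L)),
    wi = .clamp01(1 - Icc / L),
    cc = {
      if (is.null(C))
        stop("the count-count estimator needs the d1 constant C of the source spectrum")
      qpc <- .clamp01(Npc / (theta * L))
      rpc <- rOfQ(qpc, k)
      # when qpc has been capped to 1, (1 - rpc)^(k-1) = 0 and the
      # correction vanishes (blow-up limit); clamp handles k = 1
      .clamp01(qpc + (1 - rpc)^(k - 1) * rpc / (3 * L) * C)
    },
    stop("unknown estimator: ", name))
}

.estimate <- function(name, qHat, k, theta = 1) {
  label <- if (theta < 1) paste0(name, "_theta") else name
  new("MutationRateEstimate", estimator = label, k = as.integer(k),
      qHat = qHat, rHat = rOfQ(qHat, k))
}

.obsToEstimate <- function(name, obs, C = NULL) {
  qHat <- .qFromStats(name, obs@Ipp, obs@Npp, obs@Npc, obs@Icc,
                      obs@unionSize, obs@L, obs@k, obs@theta, C)
  .estimate(name, qHat, obs@k, obs@theta)
}

#' Extract pair statistics from two k-mer spectra
#'
#' Computes the sufficient statistics Ipp, Npp, Npc, Icc and the union
#' size from the spectra of a source sequence s and a target sequence t
#' (conventionally, t is the mutated copy of s). \code{L} is taken from
#' the source spectrum.
#'
#' @param specS,specT [KmerSpectrum-class] objects with the same k.
#' @return a [KmerObservations-class].
#' @examples
#' obs <- kmerObservations(kmerSpectrum("AAAA", 2), kmerSpectrum("AATA", 2))
#' obs
#' @export
kmerObservations <- function(specS, specT) {
  stopifnot(is(specS, "KmerSpectrum"), is(specT, "KmerSpectrum"))
  if (specS@k != specT@k)
    stop("k mismatch between the two spectra")
  st <- .pairStats(specS@counts, specT@counts)
  new("KmerObservations", k = specS@k, L = specS@L, Lt = specT@L,
      Ipp = st$Ipp, Npp = st$Npp, Npc = st$Npc, Icc = st$Icc,
      unionSize = st$unionSize, theta = 1)
}

setMethod("show", "KmerObservations", function(object) {
  cat(sprintf(
    "KmerObservations: k=%d, L=%s, Lt=%s, Ipp=%s, Npp=%s, Npc=%s, Icc=%s, union=%s%s\n",
    object@k, format(object@L), format(object@Lt), format(object@Ipp),
    format(object@Npp), format(object@Npc), format(object@Icc),
    format(object@unionSize),
    if (object@theta < 1) sprintf(", theta=%g", object@theta) else ""))
})

setMethod("show", "MutationRateEstimate", function(object) {
  cat(sprintf("MutationRateEstimate [%s]: k=%d, q_hat=%.6g, r_hat=%.6g\n",
              object@estimator, object@k, object@qHat, object@rHat))
})

#' @describeIn kmerObservations Jaccard index Ipp / |union|.
#' @param obs a \code{KmerObservations}.
#' @export
jaccard <- function(obs) {
  if (obs@unionSize == 0) return(0)
  obs@Ipp / obs@unionSize
}

#' Point estimators of the k-mer mutation probability q
#'
#' All estimators return a [MutationRateEstimate-class] holding
#' \eqn{\hat q} (clamped into [0, 1]) and \eqn{\hat r = 1 - (1-\hat
#' q)^{1/k}}. With \code{L} the k-mer count of the source s and the pair
#' statistics of [kmerObservations()]:
#' \describe{
#'   \item{\code{qObl}}{\eqn{(L - I^{pp}) / L}: the oblivious
#'     intersection-based estimator.}
#'   \item{\code{qMash}}{\eqn{(1 - J)/(1 + J)} with Jaccard index J: the
#'     Jaccard-transform estimator popularized by Mash-style sketching.}
#'   \item{\code{qPp}}{\eqn{N^{pp} / L}: novel distinct k-mers
#'     (presence-presence).}
#'   \item{\code{qPc}}{\eqn{N^{pc} / L}: occurrence-weighted novel k-mers
#'     (presence-count).}
#'   \item{\code{qWi}}{\eqn{1 - I^{cc}/L}: weighted-intersection
#'     count-count comparator.}
#'   \item{\code{qCc}}{\eqn{N^{pc}/L + (1-\hat r_{pc})^{k-1} \hat r_{pc}
#'     / (3L) \cdot C}: the presence-count estimate plus a plug-in
#'     correction for mutations landing on a Hamming-distance-1 neighbor
#'     already present in s, with \eqn{C = \sum_\tau occ(\tau,s)
#'     d_1(\tau,s)} from [d1Table()].}
#' }
#' The three presence-presence estimators coincide when all k-mers of both
#' sequences are distinct and no mutated k-mer falls back into sp(s); on
#' repetitive sequences they diverge and \code{qPp} (and, with counts,
#' \code{qCc}) are the robust choices.
#'
#' @param obs a [KmerObservations-class].
#' @param d1sum a [D1Summary-class] computed from the SAME source spectrum
#'   as \code{obs} (for \code{qCc}).
#' @return a [MutationRateEstimate-class].
#' @examples
#' obs <- kmerObservations(kmerSpectrum("AAAA", 2), kmerSpectrum("AATA", 2))
#' qPp(obs)
#' @name estimators
NULL

#' @rdname estimators
#' @export
qObl <- function(obs) .obsToEstimate("obl", obs)

#' @rdname estimators
#' @export
qMash <- function(obs) .obsToEstimate("mash", obs)

#' @rdname estimators
#' @export
qPp <- function(obs) .obsToEstimate("pp", obs)

#' @rdname estimators
#' @export
qPc <- function(obs) .obsToEstimate("pc", obs)

#' @rdname estimators
#' @export
qWi <- function(obs) .obsToEstimate("wi", obs)

#' @rdname estimators
#' @export
qCc <- function(obs, d1sum) {
  stopifnot(is(d1sum, "D1Summary"))
  if (d1sum@k != obs@k) stop("k mismatch between observations and d1 table")
  .obsToEstimate("cc", obs, C = d1sum@weightedSumC)
}

#' Run several estimators on one pair of spectra
#'
#' Convenience wrapper computing any subset of the estimators on a pair of
#' spectra and returning a tidy data.frame row per estimator (the TSV/JSON
#' report shape).
#'
#' @param specS,specT [KmerSpectrum-class] objects.
#' @param estimators character subset of
#'   \code{c("obl","mash","pp","pc","wi","cc")}.
#' @param d1sum optional precomputed [D1Summary-class] of \code{specS};
#'   computed on the fly if \code{"cc"} is requested without one.
#' @return data.frame with columns estimator, k, q_hat, r_hat, L, Npp,
#'   Npc, Icc, Ipp.
#' @export
estimateRates <- function(specS, specT,
                          estimators = c("obl", "mash", "pp", "pc", "wi", "cc"),
                          d1sum = NULL) {
  estimators <- match.arg(estimators,
                          c("obl", "mash", "pp", "pc", "wi", "cc"),
                          several.ok = TRUE)
  obs <- kmerObservations(specS, specT)
  if ("cc" %in% estimators && is.null(d1sum)) d1sum <- d1Table(specS)
  rows <- lapply(estimators, function(nm) {
    est <- if (nm == "cc") qCc(obs, d1sum) else .obsToEstimate(nm, obs)
    data.frame(estimator = nm, k = obs@k, q_hat = est@qHat,
               r_hat = est@rHat, L = obs@L, Npp = obs@Npp, Npc = obs@Npc,
               Icc = obs@Icc, Ipp = obs@Ipp)
  })
  do.call(rbind, rows)
}
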