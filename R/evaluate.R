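#' Replicate distribution of the estimators on one (k, r) condition
#'
#' Mutates the base sequence \code{s} independently \code{nReplicates}
#' times at rate \code{r} and computes the requested estimators on each
#' (s, t_i) pair. Replicate i uses the deterministic substream
#' \code{mixSeed(baseSeed, i)}, so any cell can be re-run in isolation,
#' bit-for-bit. With \code{theta < 1} both spectra are FracMinHash-
#' sketched with a fresh per-replicate hash seed and the sketched
#' estimators (restricted to \code{"pp"}, \code{"pc"}, \code{"cc"}) are
#' used; the d1 constant for \code{"cc"} is always precomputed from the
#' full source spectrum.
#'
#' @param s base DNA string.
#' @param k k-mer length.
#' @param r substitution rate in (0, 1].
#' @param nReplicates number of mutation replicates.
#' @param baseSeed integer seed of the replicate stream.
#' @param theta FracMinHash fraction in (0, 1]; 1 disables sketching.
#' @param estimators character subset of
#'   \code{c("obl","mash","pp","pc","wi","cc")} (only
#'   \code{c("pp","pc","cc")} when \code{theta < 1}).
#' @return data.frame with columns replicate, estimator, q_hat, r_hat.
#' @export
runReplicates <- function(s, k, r, nReplicates = 100L, baseSeed = 1L,
                          theta = 1,
                          estimators = c("obl", "mash", "pp", "pc", "wi", "cc")) {
  s <- .checkDna(s)
  stopifnot(nReplicates >= 1, r >= 0, r <= 1)
  estimators <- match.arg(estimators,
                          c("obl", "mash", "pp", "pc", "wi", "cc"),
                          several.ok = TRUE)
  if (theta < 1 && !all(estimators %in% c("pp", "pc", "cc")))
    stop("sketched runs support only the 'pp', 'pc' and 'cc' estimators")
  specS <- kmerSpectrum(s, k)
  countsS <- specS@counts
  L <- specS@L
  C <- if ("cc" %in% estimators) d1Table(specS)@weightedSumC else NULL
  rows <- vector("list", nReplicates)
  for (i in seq_len(nReplicates)) {
    seedI <- mixSeed(baseSeed, i)
    t <- mutateSequence(s, r, seed = seedI)
    res <- cpp_count_kmers(t, as.integer(k), FALSE)
    countsT <- res$counts
    names(countsT) <- res$kmers
    if (theta < 1) {
      hseed <- mixSeed(seedI, 777L)
      cs <- countsS[cpp_hash_keep(names(countsS), theta, hseed)]
      ct <- countsT[cpp_hash_keep(names(countsT), theta, hseed)]
      st <- .pairStats(cs, ct)
    } else {
      st <- .pairStats(countsS, countsT)
    }
    qh <- vapply(estimators, function(nm)
      .qFromStats(nm, st$Ipp, st$Npp, st$Npc, st$Icc, st$unionSize,
                  L, k, theta, C), numeric(1))
    rows[[i]] <- data.frame(replicate = i, estimator = estimators,
                            q_hat = unname(qh),
                            r_hat = rOfQ(unname(qh), k))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average relative absolute error over a (k, r) grid
#'
#' For each combination of \code{kValues}, \code{rValues} and estimator,
#' runs \code{nReplicates} mutation replicates and summarizes the
#' replicate estimates \eqn{\hat r_i} into the average relative absolute
#' error \eqn{\frac{1}{n} \sum_i |\hat r_i - r| / r}, plus the replicate
#' mean and variance of \eqn{\hat r}. In the blow-up regime (large
#' \eqn{k r}) every \eqn{\hat r_i} saturates at 1 and the cell error
#' approaches \eqn{(1 - r)/r}. The default r grid follows the benchmark
#' convention 0.001 to 0.251 in steps of 0.02; \code{r = 0} is rejected
#' (the metric is undefined there).
#'
#' @param s base DNA string.
#' @param kValues integer vector of k values.
#' @param rValues numeric vector of rates, strictly increasing in (0, 1).
#' @param nReplicates replicates per cell (default 100).
#' @param theta FracMinHash fraction (default 1 = no sketching).
#' @param baseSeed integer seed; cell (k-index, r-index) derives its
#'   substream as \code{mixSeed(baseSeed, ki, ri)}.
#' @param estimators estimator subset, as in [runReplicates()].
#' @return data.frame with one row per (k, r, estimator):
#'   \code{mean_rel_abs_error}, \code{mean_r_hat}, \code{var_r_hat}.
#' @export
errorGrid <- function(s, kValues = c(12L, 16L, 20L, 24L, 28L, 32L),
                      rValues = seq(0.001, 0.251, by = 0.02),
                      nReplicates = 100L, theta = 1, baseSeed = 1L,
                      estimators = c("obl", "mash", "pp", "pc", "wi", "cc")) {
  if (any(rValues <= 0))
    stop("relative error is undefined at r = 0; use r >= 0.001")
  if (is.unsorted(rValues, strictly = TRUE) || any(rValues >= 1))
    stop("'rValues' must be strictly increasing within (0, 1)")
  cells <- list()
  for (ki in seq_along(kValues)) {
    for (ri in seq_along(rValues)) {
      k <- kValues[ki]
      r <- rValues[ri]
      reps <- runReplicates(s, k, r, nReplicates,
                            baseSeed = mixSeed(baseSeed, ki, ri),
                            theta = theta, estimators = estimators)
      agg <- split(reps, reps$estimator)
      cells[[length(cells) + 1L]] <- do.call(rbind, lapply(agg, function(g)
        data.frame(k = k, r = r, estimator = g$estimator[1],
                   mean_rel_abs_error = mean(abs(g$r_hat - r)) / r,
                   mean_r_hat = mean(g$r_hat),
                   var_r_hat = stats::var(g$r_hat))))
    }
  }
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  out
}

#' Pivot grid cells into an estimator-by-condition table
#'
#' One row per estimator, one column per (k, r) condition, holding the
#' chosen metric (mean relative absolute error by default).
#'
#' @param cells data.frame from [errorGrid()].
#' @param metric which cell column to tabulate.
#' @return data.frame, first column \code{estimator}.
#' @export
summarizeGrid <- function(cells, metric = "mean_rel_abs_error") {
  if (nrow(cells) == 0L) return(data.frame(estimator = character()))
  cells$cond <- sprintf("k%d_r%g", cells$k, cells$r)
  conds <- unique(cells$cond)
  ests <- unique(cells$estimator)
  out <- data.frame(estimator = ests)
  for (cond in conds) {
    sub <- cells[cells$cond == cond, ]
    out[[cond]] <- sub[[metric]][match(ests, sub$estimator)]
  }
  out
}

#' Write / read evaluation tables as TSV
#'
#' @param x data.frame ([errorGrid()] cells or a [summarizeGrid()] table).
#' @param path file path.
#' @return \code{readGridTsv} returns the data.frame.
#' @export
writeGridTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGridTsv
#' @export
readGridTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
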