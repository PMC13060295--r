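#' Read DNA sequences from a FASTA file
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet} returning a named
#' character vector, uppercased (soft-masked lowercase is accepted).
#' Record descriptions are truncated to the first whitespace-delimited
#' token. An empty file yields an empty vector. A file whose first
#' non-empty line is not a header is rejected with the offending line
#' number.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
readFastaSequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  nonblank <- which(nzchar(trimws(head_lines)))
  if (length(nonblank) && !startsWith(trimws(head_lines[nonblank[1]]), ">"))
    stop(sprintf("malformed FASTA in '%s': line %d does not start a record",
                 path, nonblank[1]))
  if (!length(nonblank)) return(stats::setNames(character(0), character(0)))
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  seqs
}

#' Write DNA sequences to a FASTA file
#'
#' @param sequences named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @export
writeFastaSequences <- function(sequences, path, width = 70L) {
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Estimate average nucleotide identity between two genomes
#'
#' Pools the k-mers of all records of each genome (no k-mer spans a record
#' boundary), optionally FracMinHash-sketches both spectra, and reports
#' \eqn{ANI = 1 - \hat r} for the presence-count and count-count
#' estimators. Defaults follow common sketched-ANI practice: k = 19,
#' theta = 0.01, canonical k-mers ON (real genomes are double-stranded;
#' this deviates from the strand-fixed mutation model and can be turned
#' off). \code{L} is taken from the query (first) genome; with
#' \code{symmetric = TRUE} both directions are computed and the ANI values
#' averaged, making the result symmetric in its arguments.
#'
#' A pair is flagged uncomputable when an estimator saturates at
#' \eqn{\hat r = 1} (ANI 0), e.g. when the sketches share no k-mers; the
#' row is still reported so that downstream accounting is explicit.
#'
#' @param query,reference character vectors of DNA sequence(s) (the
#'   records of each genome), or single strings.
#' @param k k-mer length (default 19).
#' @param theta FracMinHash fraction (default 0.01; 1 disables sketching).
#' @param hashSeed integer hash seed shared by both sketches.
#' @param canonical use canonical (strand-folded) k-mers (default TRUE).
#' @param symmetric average the two directions (default FALSE).
#' @param queryId,referenceId identifiers for the report row.
#' @return data.frame with columns query_id, reference_id, ani_pc,
#'   ani_cc, r_pc, r_cc, uncomputable.
#' @export
estimateANI <- function(query, reference, k = 19L, theta = 0.01,
                        hashSeed = 0L, canonical = TRUE, symmetric = FALSE,
                        queryId = "query", referenceId = "reference") {
  one_direction <- function(a, b) {
    specA <- kmerSpectrum(a, k, canonical = canonical)
    specB <- kmerSpectrum(b, k, canonical = canonical)
    d1A <- d1Table(specA)
    if (theta < 1) {
      obs <- sketchedObservations(sketchSpectrum(specA, theta, hashSeed),
                                  sketchSpectrum(specB, theta, hashSeed))
    } else {
      obs <- kmerObservations(specA, specB)
    }
    c(pc = qPcTheta(obs)@rHat, cc = qCcTheta(obs, d1A)@rHat)
  }
  fwd <- one_direction(query, reference)
  if (isTRUE(symmetric)) {
    rev <- one_direction(reference, query)
    ani <- ((1 - fwd) + (1 - rev)) / 2
    rhat <- 1 - ani
  } else {
    rhat <- fwd
    ani <- 1 - fwd
  }
  data.frame(query_id = queryId, reference_id = referenceId,
             ani_pc = unname(ani["pc"]), ani_cc = unname(ani["cc"]),
             r_pc = unname(rhat["pc"]), r_cc = unname(rhat["cc"]),
             uncomputable = unname(ani["pc"] == 0 | ani["cc"] == 0))
}

#' @describeIn estimateANI convenience wrapper reading the two genomes
#'   from FASTA files; record identifiers default to the file base names.
#' @param queryPath,referencePath FASTA file paths.
#' @param ... passed on to \code{estimateANI}.
#' @export
aniFromFasta <- function(queryPath, referencePath, ...) {
  q <- readFastaSequences(queryPath)
  r <- readFastaSequences(referencePath)
  if (!length(q)) stop("no sequences in ", queryPath)
  if (!length(r)) stop("no sequences in ", referencePath)
  args <- list(...)
  if (is.null(args$queryId))
    args$queryId <- sub("\\.(fa|fasta|fna)$", "", basename(queryPath))
  if (is.null(args$referenceId))
    args$referenceId <- sub("\\.(fa|fasta|fna)$", "", basename(referencePath))
  do.call(estimateANI, c(list(query = q, reference = r), args))
}
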