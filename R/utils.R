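# internal helpers shared across modules

.clamp01 <- function(x) pmin(1, pmax(0, x))

.BASES <- c("A", "C", "G", "T")

# Deterministic 31-bit seed mixing for reproducible substreams: replicate i
# of cell (k-index, r-index) under base seed b gets mixSeed(b, ki, ri, i).
# Arithmetic stays below 2^53 so doubles are exact.
mixSeed <- function(...) {
  v <- c(...)
  h <- 0
  for (x in v) h <- (h * 69069 + (abs(x) %% 2147483647) + 1) %% 2147483647
  as.integer(h)
}

# Run expr under a local RNG state: seeds if `seed` is non-NULL, and always
# restores the caller's .Random.seed afterwards.
withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.checkDna <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop(sprintf("'%s' must be a single character string", what))
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence))
    stop(sprintf("'%s' contains characters outside {A,C,G,T}", what))
  sequence
}
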