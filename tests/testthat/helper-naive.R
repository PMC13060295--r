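# Naive, independent re-implementations used as oracles. Deliberately
# written with plain R loops and base table() so they share no code with
# the package's counting/aggregation paths.

naiveSpectrumCounts <- function(s, k) {
  s <- toupper(s)
  n <- nchar(s)
  w <- substring(s, 1:(n - k + 1), k:n)
  w <- w[!grepl("[^ACGT]", w)]
  tab <- table(w)
  stats::setNames(as.integer(tab), names(tab))
}

naivePairStats <- function(cs, ct) {
  all_kmers <- union(names(cs), names(ct))
  Ipp <- 0L; Npp <- 0L; Npc <- 0; Icc <- 0
  for (km in all_kmers) {
    a <- if (km %in% names(cs)) cs[[km]] else 0L
    b <- if (km %in% names(ct)) ct[[km]] else 0L
    if (a > 0 && b > 0) Ipp <- Ipp + 1L
    if (a == 0 && b > 0) { Npp <- Npp + 1L; Npc <- Npc + b }
    Icc <- Icc + min(a, b)
  }
  list(Ipp = Ipp, Npp = Npp, Npc = Npc, Icc = Icc,
       unionSize = length(all_kmers))
}

# O(m^2) all-pairs Hamming distances among a set of distinct k-mers
naiveD1 <- function(kmers) {
  m <- length(kmers)
  chars <- do.call(rbind, strsplit(kmers, "", fixed = TRUE))
  out <- integer(m)
  for (i in seq_len(m)) {
    hd <- rowSums(chars != matrix(chars[i, ], nrow = m,
                                  ncol = ncol(chars), byrow = TRUE))
    out[i] <- sum(hd == 1L)
  }
  stats::setNames(out, kmers)
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
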