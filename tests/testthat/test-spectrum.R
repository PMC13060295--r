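test_that("spectrum counts windows, skips invalid ones, and tracks L", {
  sp <- kmerSpectrum("ACGTA", 2)
  expect_equal(kmerCounts(sp), c(AC = 1L, CG = 1L, GT = 1L, TA = 1L))
  expect_equal(totalKmers(sp), 4)

  expect_equal(kmerCounts(kmerSpectrum("AAAA", 2)), c(AA = 3L))
  expect_equal(totalKmers(kmerSpectrum("AAAA", 2)), 3)

  # windows containing non-ACGT characters are excluded from L
  sp <- kmerSpectrum("ACNGT", 2)
  expect_equal(kmerCounts(sp), c(AC = 1L, GT = 1L))
  expect_equal(totalKmers(sp), 2)

  expect_error(kmerSpectrum("ACG", 4), "too short")
  expect_error(kmerSpectrum("ACG", 0), "invalid k")
  expect_error(kmerSpectrum("ACG", 2.5), "invalid k")
})

test_that("spectrum is case-insensitive and pools multiple records", {
  expect_equal(kmerCounts(kmerSpectrum("acgTA", 2)),
               kmerCounts(kmerSpectrum("ACGTA", 2)))
  # pooling: no window spans the record boundary
  pooled <- kmerSpectrum(c("ACGT", "TTTT"), 3)
  expect_equal(totalKmers(pooled), 2 + 2)
  expect_false("TTT" %in% names(kmerCounts(kmerSpectrum(c("AT", "TT"), 2))))
})

test_that("counts conserve L on clean sequences (property)", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    k <- sample(1:8, 1)
    if (n < k) next
    s <- randomDna(n)
    sp <- kmerSpectrum(s, k)
    expect_equal(sum(kmerCounts(sp)), n - k + 1)
    expect_equal(totalKmers(sp), n - k + 1)
    expect_lte(length(kmerCounts(sp)), totalKmers(sp))
    # agreement with the naive window counter
    expect_equal(kmerCounts(sp), naiveSpectrumCounts(s, k))
  }
})

test_that("canonical counting folds reverse complements", {
  s <- "AACGTT"
  spc <- kmerSpectrum(s, 3, canonical = TRUE)
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  expect_equal(kmerCounts(spc), kmerCounts(kmerSpectrum(rc(s), 3,
                                                        canonical = TRUE)))
  expect_true(all(vapply(names(kmerCounts(spc)),
                         function(km) km <= rc(km), logical(1))))
})

test_that("hammingDistance counts differing positions", {
  expect_equal(hammingDistance("AA", "AA"), 0)
  expect_equal(hammingDistance("AA", "AT"), 1)
  expect_equal(hammingDistance("ACG", "TGC"), 3)
  expect_error(hammingDistance("AC", "ACG"), "equal length")
})

test_that("d1 table matches spec examples and the all-pairs oracle", {
  d <- d1Table(kmerSpectrum("AAAA", 2))
  expect_equal(d1Counts(d), c(AA = 0L))
  expect_equal(weightedNeighborSum(d), 0)

  d <- d1Table(kmerSpectrum("AATA", 2))
  expect_equal(d1Counts(d), c(AA = 2L, AT = 1L, TA = 1L))
  expect_equal(weightedNeighborSum(d), 1 * 2 + 1 * 1 + 1 * 1)

  # spectra whose members are pairwise at HD >= 2 have d1 == 0 everywhere
  d <- d1Table(kmerSpectrum("AAATTT", 3))
  expect_true(hammingDistance("AAA", "TTT") >= 2)

  set.seed(22)
  for (i in 1:8) {
    s <- randomDna(sample(50:200, 1))
    k <- sample(2:5, 1)
    sp <- kmerSpectrum(s, k)
    d <- d1Table(sp)
    expect_equal(d1Counts(d), naiveD1(distinctKmers(sp)))
    expect_equal(weightedNeighborSum(d),
                 sum(as.numeric(kmerCounts(sp)) * d1Counts(d)))
  }
})

test_that("djCounts profiles distances and partitions the spectrum", {
  expect_equal(djCounts("AA", kmerSpectrum("AA", 2)), c(0L, 0L))
  expect_equal(djCounts("AA", kmerSpectrum("AATA", 2)), c(2L, 0L))

  set.seed(33)
  for (i in 1:5) {
    s <- randomDna(60)
    k <- sample(2:4, 1)
    sp <- kmerSpectrum(s, k)
    km <- distinctKmers(sp)
    for (tau in sample(km, 3)) {
      dj <- djCounts(tau, sp)
      # distances partition the spectrum members
      expect_equal(sum(dj) + as.integer(tau %in% km), length(km))
      # j = 1 agrees with the d1 table
      expect_equal(dj[1], unname(d1Counts(d1Table(sp))[tau]))
    }
  }
  expect_error(djCounts("AAA", kmerSpectrum("AATA", 2)), "equal length")
})
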