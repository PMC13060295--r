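test_that("theta = 1 retains the full spectrum; bounds are enforced", {
  set.seed(101)
  sp <- kmerSpectrum(randomDna(300), 5)
  sk <- sketchSpectrum(sp, 1)
  expect_identical(retainedKmers(sk), kmerCounts(sp))
  expect_error(sketchSpectrum(sp, 0), "in \\(0, 1\\]")
  expect_error(sketchSpectrum(sp, 1.2), "in \\(0, 1\\]")
  # tiny theta on a finite spectrum: eventually empty
  expect_equal(length(retainedKmers(sketchSpectrum(sp, 1e-12))), 0)
})

test_that("sketching is deterministic and retains about theta of the k-mers", {
  set.seed(102)
  sp <- kmerSpectrum(randomDna(500), 6)
  a <- sketchSpectrum(sp, 0.3, hashSeed = 5)
  b <- sketchSpectrum(sp, 0.3, hashSeed = 5)
  expect_identical(retainedKmers(a), retainedKmers(b))
  # over many seeds the mean retained fraction concentrates on theta
  m <- length(kmerCounts(sp))
  theta <- 0.25
  nseed <- 2000
  kept <- vapply(seq_len(nseed), function(sd)
    length(retainedKmers(sketchSpectrum(sp, theta, hashSeed = sd))),
    integer(1))
  phat <- sum(kept) / (as.numeric(m) * nseed)
  se <- sqrt(theta * (1 - theta) / (as.numeric(m) * nseed))
  expect_lt(abs(phat - theta), 5 * se)
})

test_that("sketched observations match a brute-force recomputation", {
  set.seed(103)
  s <- randomDna(400)
  t <- mutateSequence(s, 0.2, seed = 3)
  spS <- kmerSpectrum(s, 6)
  spT <- kmerSpectrum(t, 6)
  skS <- sketchSpectrum(spS, 0.5, hashSeed = 1)
  skT <- sketchSpectrum(spT, 0.5, hashSeed = 1)
  obs <- sketchedObservations(skS, skT)
  ref <- naivePairStats(as.list(retainedKmers(skS)),
                        as.list(retainedKmers(skT)))
  expect_equal(obs@Ipp, ref$Ipp)
  expect_equal(obs@Npp, ref$Npp)
  expect_equal(obs@Npc, ref$Npc)
  expect_equal(obs@Icc, ref$Icc)
  # L carries the FULL source k-mer count, not the sketched size
  expect_equal(obs@L, totalKmers(spS))
  expect_equal(obs@theta, 0.5)

  expect_error(sketchedObservations(skS, sketchSpectrum(spT, 0.4, 1)),
               "theta mismatch")
  expect_error(sketchedObservations(skS, sketchSpectrum(spT, 0.5, 2)),
               "hash seed mismatch")
})

test_that("theta = 1 sketched estimators equal the unsketched ones bit-for-bit", {
  set.seed(104)
  s <- randomDna(600)
  t <- mutateSequence(s, 0.15, seed = 8)
  spS <- kmerSpectrum(s, 9)
  spT <- kmerSpectrum(t, 9)
  d1 <- d1Table(spS)
  plain <- kmerObservations(spS, spT)
  sk <- sketchedObservations(sketchSpectrum(spS, 1), sketchSpectrum(spT, 1))
  expect_identical(qPpTheta(sk)@qHat, qPp(plain)@qHat)
  expect_identical(qPcTheta(sk)@qHat, qPc(plain)@qHat)
  expect_identical(qCcTheta(sk, d1)@qHat, qCc(plain, d1)@qHat)
})

test_that("sketched estimators are capped at 1 when counts exceed theta*L", {
  # sketching variance can push N above theta*L; construct the regime
  obs <- new("KmerObservations", k = 5L, L = 100, Lt = 100, Ipp = 0,
             Npp = 60, Npc = 70, Icc = 0, unionSize = 80, theta = 0.5)
  expect_equal(qPpTheta(obs)@qHat, 1)  # 60 > 0.5 * 100
  expect_equal(qPcTheta(obs)@qHat, 1)
  # capped pc: the cc correction vanishes, q_cc_theta = 1
  d1 <- new("D1Summary", k = 5L, d1 = c(AAAAA = 3L), weightedSumC = 30)
  expect_equal(qCcTheta(obs, d1)@qHat, 1)
  expect_equal(qCcTheta(obs, d1)@rHat, 1)
})

test_that("sketch JSON round-trips with the precomputed constant", {
  set.seed(105)
  sp <- kmerSpectrum(randomDna(200), 7)
  sk <- sketchSpectrum(sp, 0.4, hashSeed = 11)
  path <- withr::local_tempfile(fileext = ".json")
  writeSketch(sk, path, cFull = weightedNeighborSum(d1Table(sp)))
  back <- readSketch(path)
  expect_identical(retainedKmers(back$sketch), retainedKmers(sk))
  expect_equal(back$sketch@theta, 0.4)
  expect_equal(back$sketch@hashSeed, 11L)
  expect_equal(back$sketch@fullL, totalKmers(sp))
  expect_equal(back$cFull, weightedNeighborSum(d1Table(sp)))
})
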