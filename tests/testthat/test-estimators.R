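worked_obs <- function() {
  kmerObservations(kmerSpectrum("AAAA", 2), kmerSpectrum("AATA", 2))
}

test_that("observations aggregate the pair statistics correctly", {
  obs <- worked_obs()
  expect_equal(obs@L, 3)
  expect_equal(obs@Ipp, 1)
  expect_equal(obs@Npp, 2)
  expect_equal(obs@Npc, 2)
  expect_equal(obs@Icc, 1)
  expect_equal(obs@unionSize, 3)

  # identity: no novel k-mers, full weighted intersection
  sp <- kmerSpectrum("ACGTACGT", 3)
  obs <- kmerObservations(sp, sp)
  expect_equal(obs@Npp, 0)
  expect_equal(obs@Npc, 0)
  expect_equal(obs@Ipp, length(kmerCounts(sp)))
  expect_equal(obs@Icc, totalKmers(sp))

  expect_error(kmerObservations(kmerSpectrum("ACGT", 2),
                                kmerSpectrum("ACGT", 3)), "k mismatch")
})

test_that("observations agree with an independent set/multiset oracle", {
  set.seed(44)
  for (i in 1:10) {
    s <- randomDna(sample(30:120, 1))
    t <- randomDna(sample(30:120, 1))
    k <- sample(2:6, 1)
    obs <- kmerObservations(kmerSpectrum(s, k), kmerSpectrum(t, k))
    ref <- naivePairStats(naiveSpectrumCounts(s, k),
                          naiveSpectrumCounts(t, k))
    expect_equal(obs@Ipp, ref$Ipp)
    expect_equal(obs@Npp, ref$Npp)
    expect_equal(obs@Npc, ref$Npc)
    expect_equal(obs@Icc, ref$Icc)
    expect_equal(obs@unionSize, ref$unionSize)
  }
})

test_that("the point estimators reproduce the worked example", {
  obs <- worked_obs()
  expect_equal(qObl(obs)@qHat, 2 / 3)
  expect_equal(qMash(obs)@qHat, 0.5)  # J = 1/3
  expect_equal(qPp(obs)@qHat, 2 / 3)
  expect_equal(qPc(obs)@qHat, 2 / 3)
  expect_equal(qWi(obs)@qHat, 2 / 3)
})

test_that("estimators hit their boundary values", {
  # all-distinct k-mers: on identical inputs every estimator is exactly 0
  # (on repetitive identical inputs obl/mash stay positive -- the repeat
  # pathology they suffer from)
  sp <- kmerSpectrum("ACGGTCA", 3)
  stopifnot(length(kmerCounts(sp)) == totalKmers(sp))
  same <- kmerObservations(sp, sp)
  expect_equal(qObl(same)@qHat, 0)
  expect_equal(qMash(same)@qHat, 0)  # J = 1
  expect_equal(qPp(same)@qHat, 0)
  expect_equal(qWi(same)@qHat, 0)
  expect_equal(qCc(same, d1Table(sp))@qHat, 0)  # Npc = 0, correction 0

  disjoint <- kmerObservations(kmerSpectrum("AAAA", 2),
                               kmerSpectrum("CCCC", 2))
  expect_equal(qObl(disjoint)@qHat, 1)   # Ipp = 0
  expect_equal(qMash(disjoint)@qHat, 1)  # J = 0
  expect_equal(qWi(disjoint)@qHat, 1)    # Icc = 0
})

test_that("occurrence weighting separates pc from pp on doubled novel k-mers", {
  # both copies of AA in s mutate "to" the same novel k-mer ν in t:
  # sp(t) counts ν twice in Npc but once in Npp
  obs <- kmerObservations(kmerSpectrum("AAAA", 2), kmerSpectrum("ACAC", 2))
  expect_equal(obs@Npp, 2)
  expect_equal(obs@Npc, 3)
  expect_gt(qPc(obs)@qHat, qPp(obs)@qHat)
})

test_that("the count-count correction is positive and reduces to pc when C = 0", {
  # C = 0 (k-mers pairwise at HD >= 3): q_cc == q_pc
  s <- distinctKmerSequence(30, 8, minPairwiseHd = 3, seed = 9)
  spS <- kmerSpectrum(s, 8)
  expect_equal(weightedNeighborSum(d1Table(spS)), 0)
  obs <- kmerObservations(spS, kmerSpectrum(mutateSequence(s, 0.05, seed = 2), 8))
  expect_equal(qCc(obs, d1Table(spS))@qHat, qPc(obs)@qHat)

  # C > 0 and 0 < r_pc < 1: strictly positive correction
  spS <- kmerSpectrum("AATA", 2)
  expect_gt(weightedNeighborSum(d1Table(spS)), 0)
  obs <- kmerObservations(spS, kmerSpectrum("AATT", 2))
  expect_gt(qPc(obs)@qHat, 0)
  expect_lt(qPc(obs)@qHat, 1)
  expect_gt(qCc(obs, d1Table(spS))@qHat, qPc(obs)@qHat)
})

test_that("estimates stay in [0,1], round-trip r, and are monotone in Npc", {
  set.seed(55)
  for (i in 1:10) {
    s <- randomDna(80)
    t <- mutateSequence(s, runif(1, 0, 0.6))
    k <- sample(2:8, 1)
    spS <- kmerSpectrum(s, k)
    res <- estimateRates(spS, kmerSpectrum(t, k))
    expect_true(all(res$q_hat >= 0 & res$q_hat <= 1))
    expect_equal(res$r_hat, rOfQ(res$q_hat, k))
  }
  # monotonicity of q_pc / q_cc in Npc, everything else fixed
  qs <- vapply(0:20, function(npc)
    kmerrate:::.qFromStats("pc", Ipp = 3, Npp = min(npc, 5), Npc = npc,
                           Icc = 3, unionSize = 10, L = 20, k = 4),
    numeric(1))
  expect_true(all(diff(qs) >= 0))
  qcs <- vapply(0:20, function(npc)
    kmerrate:::.qFromStats("cc", Ipp = 3, Npp = min(npc, 5), Npc = npc,
                           Icc = 3, unionSize = 10, L = 20, k = 4, C = 12),
    numeric(1))
  expect_true(all(diff(qcs) >= -1e-12))
})

test_that("tidy report has one row per estimator with the raw statistics", {
  res <- estimateRates(kmerSpectrum("AAAA", 2), kmerSpectrum("AATA", 2))
  expect_equal(nrow(res), 6)
  expect_setequal(res$estimator, c("obl", "mash", "pp", "pc", "wi", "cc"))
  expect_true(all(c("q_hat", "r_hat", "L", "Npp", "Npc", "Icc", "Ipp")
                  %in% names(res)))
})
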