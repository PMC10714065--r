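test_that("model constructors validate their invariants", {
  expect_error(demographicModel(c(0, 5, 3), c(10, 10, 10)), "increasing")
  expect_error(demographicModel(c(1, 5), c(10, 10)), "time 0")
  expect_error(demographicModel(0, -5), "> 0")
  expect_error(samplingScheme(n = 0, times = 0, L = 10), ">= 1")
  expect_error(mutationModel(-1e-8), ">= 0")
  m <- demographicModel(c(0, 3, 2000), c(400, 10000, 600))
  expect_equal(TempoPopGen:::.sizeAt(m, c(0, 2.9, 3, 1999, 2000, 1e6)),
               c(400, 400, 10000, 10000, 600, 600))
})

test_that("two serial samples can only coalesce once both exist", {
  sch <- samplingScheme(n = c(1, 1), times = c(0, 50), L = 10)
  t2 <- replicate(300, tmrca(simulateGenealogy(demographicModel(0, 100),
                                               sch)))
  expect_true(all(t2 >= 50))
  # E[TMRCA] = tau + Ne for this design
  expect_lt(abs(mean(t2) - 150), 3 * sd(t2) / sqrt(length(t2)))
})

test_that("pairwise TMRCA and total tree length match coalescent theory", {
  set.seed(2024)
  ne <- 500
  t2 <- replicate(3000, tmrca(simulateGenealogy(demographicModel(0, ne),
                                                samplingScheme(2, 0, L = 1))))
  expect_lt(abs(mean(t2) - ne), 3 * sd(t2) / sqrt(3000))
  n <- 10
  tl <- replicate(2000, totalLength(simulateGenealogy(
    demographicModel(0, ne), samplingScheme(n, 0, L = 1))))
  expTL <- 2 * ne * sum(1 / seq_len(n - 1))
  expect_lt(abs(mean(tl) - expTL), 3 * sd(tl) / sqrt(2000))
})

test_that("genealogies are reproducible under a seed and well-formed", {
  m <- demographicModel(c(0, 10), c(100, 1000))
  sch <- samplingScheme(n = c(4, 3), times = c(0, 5), L = 100)
  a <- simulateGenealogy(m, sch, seed = 99)
  b <- simulateGenealogy(m, sch, seed = 99)
  expect_identical(a, b)
  # parent times exceed child times; single root
  nz <- a$parent > 0
  expect_true(all(a$times[a$parent[nz]] > a$times[nz] - 1e-12))
  expect_identical(sum(!nz), 1L)
})

test_that("mutation layer: mu = 0 gives identical sequences; counts are
           Poisson-thinned along branches", {
  tr <- simulateGenealogy(demographicModel(0, 100),
                          samplingScheme(6, 0, L = 50), seed = 4)
  sim0 <- dropMutations(tr, mutationModel(0), seed = 5)
  expect_identical(length(sim0$sites), 0L)
  aln0 <- renderAlignment(sim0, seed = 6)
  expect_identical(length(unique(as.character(sequences(aln0)))), 1L)
  # expected S and pi under constant size (Watterson / pairwise theory)
  set.seed(12)
  ne <- 300; mu <- 2e-5; L <- 500; n <- 8
  reps <- 1500
  sims <- replicate(reps, {
    sim <- simulateAlignment(demographicModel(0, ne),
                             samplingScheme(n, 0, L = L),
                             mutationModel(mu, kappa = 10))
    cc <- TempoPopGen:::.colBaseCounts(sim$states)
    cls <- TempoPopGen:::.classifyCounts(cc)
    c(S = sum(cls != "monomorphic"),
      k = TempoPopGen:::.khatFromCounts(cc, n))
  })
  thetaLocus <- 2 * ne * mu * L
  expS <- thetaLocus * sum(1 / seq_len(n - 1))
  expect_lt(abs(mean(sims["S", ]) - expS),
            3 * sd(sims["S", ]) / sqrt(reps) + 0.02 * expS)
  expect_lt(abs(mean(sims["k", ]) - thetaLocus),
            3 * sd(sims["k", ]) / sqrt(reps) + 0.02 * thetaLocus)
})

test_that("transition bias shapes the substitution spectrum", {
  # with kappa large almost every difference is a transition
  set.seed(8)
  tr <- simulateGenealogy(demographicModel(0, 2000),
                          samplingScheme(2, 0, L = 2000))
  sim <- dropMutations(tr, mutationModel(5e-5, kappa = 1000))
  st <- sim$states
  diffs <- which(st[1, ] != st[2, ])
  isTs <- abs(st[1, diffs] - st[2, diffs]) == 2   # A<->G, C<->T
  expect_gt(mean(isTs), 0.9)
})

test_that("between-cohort divergence grows with the sampling gap", {
  set.seed(21)
  gaps <- c(0, 100, 300)
  mns <- vapply(gaps, function(g) {
    k <- replicate(250, {
      sim <- simulateAlignment(
        demographicModel(0, 200),
        samplingScheme(c(5, 5), c(0, g), groups = c("new", "old"), L = 500),
        mutationModel(2e-5))
      computeSumstats(sim)[["kBetween"]]
    })
    mean(k)
  }, 0)
  expect_true(all(diff(mns) > 0))
})

test_that("a strong recent decline depresses younger-cohort haplotype counts", {
  set.seed(33)
  H <- replicate(250, {
    sim <- simulateAlignment(
      demographicModel(c(0, 3), c(100, 1000)),   # 10-fold crash 3 gen BP
      samplingScheme(c(19, 19), c(0, 3.5), groups = c("new", "old"),
                     L = 1000),
      mutationModel(1e-5))
    ss <- computeSumstats(sim)
    c(new = ss[["H_new"]], old = ss[["H_old"]])
  })
  expect_lt(mean(H["new", ]), mean(H["old", ]))
})

test_that("simulated S distribution matches an independent coalescent
           simulator (msprime) by Kolmogorov-Smirnov", {
  ne <- 1000; mu <- 1e-5; L <- 1000; n <- 10; reps <- 800
  py <- sprintf('
import msprime, sys
out = []
for rep in range(%d):
    ts = msprime.sim_ancestry(samples=%d, ploidy=1, population_size=%d,
                              sequence_length=%d, random_seed=rep + 1)
    mts = msprime.sim_mutations(ts, rate=%g, random_seed=rep + 101)
    S = 0
    for v in mts.variants():
        if len(set(v.genotypes)) > 1:
            S += 1
    out.append(S)
print(" ".join(str(s) for s in out))
', reps, n, ne, L, mu)
  pyf <- withr::local_tempfile(fileext = ".py")
  writeLines(py, pyf)
  res <- suppressWarnings(system2("python", pyf, stdout = TRUE))
  expect_gt(length(res), 0)
  mspS <- as.integer(strsplit(res[length(res)], " ")[[1]])
  expect_length(mspS, reps)
  set.seed(55)
  ourS <- replicate(reps, {
    sim <- simulateAlignment(demographicModel(0, ne),
                             samplingScheme(n, 0, L = L),
                             mutationModel(mu))
    cc <- TempoPopGen:::.colBaseCounts(sim$states)
    sum(TempoPopGen:::.classifyCounts(cc) != "monomorphic")
  })
  ks <- suppressWarnings(stats::ks.test(ourS, mspS))
  expect_gt(ks$p.value, 0.01)
})

test_that("fixture presets have the documented structure", {
  ib <- makeFixture("iberia_like", seed = 2)$alignment
  expect_identical(nSequences(ib), 71L)
  expect_identical(alignmentWidth(ib), 4175L)
  expect_identical(sort(unique(groups(ib))), c("IB_N", "IB_O"))
  expect_identical(as.integer(table(groups(ib))[c("IB_N", "IB_O")]),
                   c(52L, 19L))
  expect_identical(sort(unique(samplingTimes(ib))), c(0, 2))
  np <- makeFixture("null_panmixia", seed = 3)$alignment
  expect_identical(nSequences(np), 30L)
  toy <- makeFixture("two_pop_toy", seed = 4)$alignment
  expect_gt(hudsonFst(toy), 0.15)
  expect_lte(permutationTest(toy, "fst", n_perm = 199, seed = 1)$p.value,
             0.01)
  # files written and readable back
  dir <- withr::local_tempdir()
  fx <- makeFixture("null_panmixia", seed = 5, dir = dir)
  back <- readCohortAlignment(fx$fasta, fx$metadata)
  expect_identical(as.character(sequences(back)),
                   as.character(sequences(fx$alignment)))
  expect_error(makeFixture("nope"), "arg")
})

test_that("the iberia_like history is calibrated to ~0.05% pooled
           nucleotide diversity", {
  # same demographic model as the preset, evaluated over many seeds on the
  # compact path; a single non-recombining locus has large genealogical
  # variance, so the calibration is asserted on the median and on the bulk
  # of seeds, not on every draw
  model <- demographicModel(c(0, 3, 2000), c(400, 10000, 600))
  sch <- samplingScheme(n = c(52L, 19L), times = c(0, 2),
                        groups = c("IB_N", "IB_O"), L = 4175L)
  pis <- vapply(1:100, function(s) withSeed(s, {
    sim <- TempoPopGen:::.dropMut(TempoPopGen:::.simGenealogy(model, sch),
                                  mutationModel(1e-7, 10), NULL)
    100 * computeSumstats(sim)[["pi_pool"]]
  }), 0)
  expect_gt(median(pis), 0.025)
  expect_lt(median(pis), 0.1)
  expect_gte(mean(pis > 0.025 & pis < 0.1), 0.75)
  # and the rendered fixture computes the same statistic through the
  # full-alignment path
  aln <- makeFixture("iberia_like", seed = 3)$alignment
  expect_lt(abs(100 * nucleotideDiversity(aln) -
                  withSeed(3, {
                    sim <- TempoPopGen:::.dropMut(
                      TempoPopGen:::.simGenealogy(model, sch),
                      mutationModel(1e-7, 10), NULL)
                    100 * computeSumstats(sim)[["pi_pool"]]
                  })), 1e-9)
})
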