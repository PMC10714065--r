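randSeqs <- function(n, L, p = c(.4, .3, .2, .1)) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p),
          collapse = ""), "")
}

test_that("haplotype diversity follows the bias-corrected estimator", {
  expect_identical(haplotypeDiversity(c(4)), 0)
  expect_identical(haplotypeDiversity(c(1, 1)), 1)
  # counts (3,2,1): n=6, Hd = 6/5 * (1 - (9+4+1)/36)
  expect_equal(haplotypeDiversity(c(3, 2, 1)), 6 / 5 * (1 - 14 / 36))
  expect_error(haplotypeDiversity(c(1)), "at least 2")
  # alignment route agrees with the counts route
  aln <- makeAln(c("AACT", "AACT", "AGGT", "TTTT", "AGGT", "AACT"))
  expect_equal(haplotypeDiversity(aln), 6 / 5 * (1 - 14 / 36))
})

test_that("nucleotide diversity equals the brute-force pairwise mean", {
  expect_equal(nucleotideDiversity(makeAln(c("AAAAAAAAAT", "AAAAAAAAAC"))),
               0.1)
  toy <- c("AACA", "AACT", "AGCT", "AGTT")
  expect_equal(nucleotideDiversity(makeAln(toy)), oraclePi(toy))
  set.seed(11)
  for (rep in 1:10) {
    seqs <- randSeqs(sample(3:9, 1), 25)
    expect_equal(nucleotideDiversity(makeAln(seqs)), oraclePi(seqs),
                 tolerance = 1e-12)
  }
  expect_error(nucleotideDiversity(makeAln(c("----", "AAAA"))), "usable")
})

test_that("Watterson's theta evaluates the harmonic formula", {
  expect_identical(wattersonTheta(0, 10, 100), 0)
  expect_equal(wattersonTheta(3, 4, 100), 3 / ((1 + 1 / 2 + 1 / 3) * 100))
})

test_that("Tajima's D is zero when pi equals Watterson per locus", {
  # n = 4 with a 1/i-proportional spectrum: xi = (6, 3, 2) makes both
  # theta estimators equal 6 per locus
  cols <- c(rep(list(c("C", "A", "A", "A")), 6),
            rep(list(c("C", "C", "A", "A")), 3),
            rep(list(c("C", "C", "C", "A")), 2))
  seqs <- apply(do.call(cbind, cols), 1L, paste, collapse = "")
  expect_equal(tajimasD(makeAln(seqs)), 0)
  expect_warning(d0 <- tajimasD(makeAln(rep("AAAA", 4))), "undefined")
  expect_true(is.na(d0))
  # n = 3 is degenerate (the variance normalisation vanishes): NA, not Inf
  expect_true(is.na(tajimasD(makeAln(c("AAC", "ACA", "CAT")))))
})

test_that("Tajima's D matches the independent variance-route oracle", {
  toy6 <- c("AACATGGCAT", "AACTTGGCAT", "AGCTTGGCAT", "AGCTTGGTAT",
            "AACATGGCAA", "AACATGCCAT")
  expect_equal(tajimasD(makeAln(toy6)), oracleTajimaD(toy6),
               tolerance = 1e-12)
  set.seed(13)
  for (rep in 1:10) {
    seqs <- randSeqs(sample(4:12, 1), 30)
    if (oracleSiteCounts(seqs)$S == 0) next
    expect_equal(tajimasD(makeAln(seqs)), oracleTajimaD(seqs),
                 tolerance = 1e-10)
  }
})

test_that("Fu sigma coefficients satisfy the classical variance identities", {
  for (n in c(4, 5, 8, 13, 20)) {
    sig <- TempoPopGen:::fuSigmaMatrix(n)
    expect_equal(sig, oracleFuSigma(n), tolerance = 1e-12)
    i <- seq_len(n - 1)
    # sum of all sigma entries is a2 (Watterson variance theta^2 term)
    expect_equal(sum(sig), sum(1 / i^2), tolerance = 1e-10)
    # pi-weight quadratic forms recover Tajima's b1, b2
    cpi <- i * (n - i) / choose(n, 2)
    expect_equal(sum(cpi^2 / i), (n + 1) / (3 * (n - 1)), tolerance = 1e-10)
    expect_equal(drop(t(cpi) %*% sig %*% cpi),
                 2 * (n^2 + n + 3) / (9 * n * (n - 1)), tolerance = 1e-10)
  }
})

test_that("Achaz's Y matches the SFS-based oracle and is undefined on
           singleton-only data", {
  only_singl <- c("AAAAAAAAAA", "AAAAAAAAAT", "AAAAAAAACA", "AAAAAAGAAA")
  expect_warning(y <- achazY(makeAln(only_singl)), "undefined")
  expect_true(is.na(y))
  set.seed(17)
  hits <- 0
  while (hits < 8) {
    seqs <- randSeqs(sample(5:12, 1), 30)
    yo <- oracleAchazY(seqs)
    if (is.na(yo)) next
    hits <- hits + 1
    expect_equal(achazY(makeAln(seqs)), yo, tolerance = 1e-10)
  }
  # SFS entry route, folded and unfolded
  expect_equal(achazY(c(3, 2, 1, 0), folded = TRUE, n = 9),
               TempoPopGen:::.achazYFromFolded(c(3, 2, 1, 0), 9))
  expect_true(is.finite(achazY(c(2, 3, 1, 0, 0, 0, 0), folded = FALSE,
                               n = 8)))
})

test_that("pi and thetaW coincide on a 1/i-proportional spectrum", {
  # n = 4 with xi = (6, 3, 2): both estimators give 6 per locus
  cols <- c(rep(list(c("C", "A", "A", "A")), 6),
            rep(list(c("C", "C", "A", "A")), 3),
            rep(list(c("C", "C", "C", "A")), 2))
  m <- do.call(cbind, cols)
  seqs <- apply(m, 1L, paste, collapse = "")
  L <- ncol(m)
  aln <- makeAln(seqs)
  piL <- nucleotideDiversity(aln) * L
  thL <- wattersonTheta(classifySites(aln)@counts[["S"]], 4, L) * L
  expect_equal(piL, 6)
  expect_equal(thL, 6)
  expect_equal(tajimasD(aln), 0)
})

test_that("Hudson's FST and phiST match brute-force oracles and bounds", {
  # exchangeable labels on one pool: both statistics centred near 0
  set.seed(101)
  pool <- randSeqs(12, 40)
  fstNull <- replicate(200, {
    labs <- sample(rep(c("X", "Y"), each = 6))
    a <- makeAln(pool, groups = labs)
    c(hudsonFst(a), phiSt(a))
  })
  expect_lt(abs(mean(fstNull[1, ])), 0.05)
  expect_lt(abs(mean(fstNull[2, ])), 0.05)
  # fixed groups differing at every site
  fixed <- c("AAAA", "AAAA", "TTTT", "TTTT")
  expect_equal(hudsonFst(makeAln(fixed, groups = c("X", "X", "Y", "Y"))), 1)
  expect_equal(phiSt(makeAln(fixed, groups = c("X", "X", "Y", "Y"))), 1)
  set.seed(23)
  for (rep in 1:10) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    seqs <- randSeqs(n1 + n2, 20)
    labels <- c(rep("X", n1), rep("Y", n2))
    d <- oracleDiffMat(seqs)
    if (mean(d[1:n1, (n1 + 1):(n1 + n2)]) == 0) next
    aln <- makeAln(seqs, groups = labels)
    expect_equal(hudsonFst(aln), oracleFst(seqs, labels), tolerance = 1e-12)
    expect_equal(phiSt(aln), oraclePhiSt(seqs, labels), tolerance = 1e-12)
    expect_lte(hudsonFst(aln), 1)
    expect_lte(phiSt(aln), 1)
  }
})

test_that("statistics are invariant to sequence order", {
  set.seed(29)
  seqs <- randSeqs(8, 40)
  labels <- rep(c("X", "Y"), each = 4)
  perm <- sample(8)
  a <- makeAln(seqs, groups = labels)
  b <- makeAln(seqs[perm], groups = labels[perm])
  expect_equal(nucleotideDiversity(a), nucleotideDiversity(b))
  expect_equal(tajimasD(a), tajimasD(b))
  expect_equal(suppressWarnings(achazY(a)), suppressWarnings(achazY(b)))
  expect_equal(hudsonFst(a), hudsonFst(b))
  expect_equal(phiSt(a), phiSt(b))
})

test_that("permutation test handles ties, seeds, and degenerate labels", {
  seqs <- randSeqs(8, 30)
  aln <- makeAln(seqs, groups = rep(c("X", "Y"), each = 4))
  # statistic constant under relabelling: p must be exactly 1
  const <- permutationTest(aln, statistic = function(d, l) 0.5, n_perm = 99,
                           seed = 1)
  expect_identical(const$p.value, 1)
  # reproducible under seed, and p within the attainable range
  p1 <- permutationTest(aln, "fst", n_perm = 99, seed = 42)
  p2 <- permutationTest(aln, "fst", n_perm = 99, seed = 42)
  expect_identical(p1$p.value, p2$p.value)
  expect_identical(p1$perm, p2$perm)
  expect_gte(p1$p.value, 1 / 100)
  expect_lte(p1$p.value, 1)
  expect_error(permutationTest(makeAln(seqs, groups = rep("X", 8)), "fst"),
               "two")
})

test_that("diversity table mirrors the per-group statistics", {
  seqs <- randSeqs(10, 50)
  aln <- makeAln(seqs, groups = rep(c("P1", "P2"), each = 5),
                 times = rep(c(2, 0), each = 5))
  tab <- diversityTable(aln)
  expect_identical(tab$group, c("P1", "P2", "All"))
  expect_identical(tab$N, c(5L, 5L, 10L))
  sub <- aln[1:5]
  expect_equal(tab$pi_pct[1], 100 * nucleotideDiversity(sub))
  expect_equal(tab$Hd[1], haplotypeDiversity(sub))
  expect_equal(tab$D[3], tajimasD(aln))
  expect_identical(tab$Hap[3],
                   length(collapseHaplotypes(aln)@haplotypes))
})
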