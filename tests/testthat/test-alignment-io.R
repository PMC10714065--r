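test_that("well-formed FASTA + metadata round-trips through the reader", {
  dir <- withr::local_tempdir()
  seqs <- c(a1 = "AACATGGCAT", a2 = "AACTTGGCAT", a3 = "AGCTTGGCAT")
  writeLines(c(rbind(paste0(">", names(seqs)), unname(seqs))),
             file.path(dir, "aln.fasta"))
  meta <- data.frame(id = names(seqs), group = c("P1", "P1", "P2"),
                     time_gen = c(2, 2, 0), year = c(1996, 1996, 2013))
  write.table(meta, file.path(dir, "meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  aln <- readCohortAlignment(file.path(dir, "aln.fasta"),
                             file.path(dir, "meta.tsv"))
  expect_s4_class(aln, "CohortAlignment")
  expect_identical(nSequences(aln), 3L)
  expect_identical(alignmentWidth(aln), 10L)
  expect_identical(groups(aln), c("P1", "P1", "P2"))
  expect_identical(samplingTimes(aln), c(2, 2, 0))
})

test_that("lower case and U are normalised to uppercase DNA", {
  aln <- makeAln(c("aacu", "AACT"))
  expect_identical(as.character(sequences(aln)),
                   c(s1 = "AACT", s2 = "AACT"))
})

test_that("malformed inputs raise errors naming the offender", {
  dir <- withr::local_tempdir()
  writeLines(c(">ok1", "AACATGGCAT", ">trunc", "AACTTG", ">ok2",
               "AGCTTGGCAT"), file.path(dir, "bad.fasta"))
  meta <- data.frame(id = c("ok1", "trunc", "ok2"), group = "P",
                     time_gen = 0)
  write.table(meta, file.path(dir, "meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(readCohortAlignment(file.path(dir, "bad.fasta"),
                                   file.path(dir, "meta.tsv")), "trunc")
  expect_error(makeAln(c("AACA", "AACT"), ids = c("x1", "x1")),
               "duplicated")
  expect_error(
    cohortAlignment(c(s1 = "AACA", s2 = "AACT"),
                    data.frame(id = "s1", group = "P", time_gen = 0)), "s2")
  expect_error(
    cohortAlignment(c(s1 = "AACA"),
                    data.frame(id = "s1", group = "P", time_gen = -1)),
    "time")
})

test_that("site classification matches hand counts and the brute-force oracle", {
  # monomorphic alignment
  mono <- classifySites(makeAln(rep("AACA", 4)))
  expect_identical(unname(mono@counts[c("S", "singletons", "parsim")]),
                   c(0L, 0L, 0L))
  # the worked 4-sequence example: S=3 of which 2 singleton, 1 parsimony
  toy <- makeAln(c("AACA", "AACT", "AGCT", "AGTT"))
  cs <- classifySites(toy)
  expect_identical(unname(cs@counts[c("S", "singletons", "parsim")]),
                   c(3L, 2L, 1L))
  # random alignments against the oracle, including gaps/ambiguity and
  # multi-allelic columns
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    L <- sample(10:40, 1)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T", "-", "N"), L, replace = TRUE,
                   prob = c(.3, .3, .15, .15, .05, .05)), collapse = ""), "")
    aln <- makeAln(seqs)
    got <- classifySites(aln)@counts
    want <- oracleSiteCounts(seqs)
    expect_identical(unname(got["usable"]), want$usable)
    expect_identical(unname(got["S"]), want$S)
    expect_identical(unname(got["singletons"]), want$singl)
    expect_identical(unname(got["parsim"]), want$parsim)
  }
})

test_that("site classes partition and respect removal monotonicity", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE,
                   prob = c(.4, .4, .1, .1)), collapse = ""), "")
    cs <- classifySites(makeAln(seqs))
    ct <- cs@counts
    expect_identical(ct[["S"]], ct[["singletons"]] + ct[["parsim"]])
    expect_lte(ct[["parsim"]], ct[["S"]])
    # row order invariance
    perm <- sample(n)
    cs2 <- classifySites(makeAln(seqs[perm]))
    expect_identical(cs2@counts, ct)
    # removing one sequence never increases S (complete deletion on pure
    # ACGT data keeps the same usable set)
    drop1 <- classifySites(makeAln(seqs[-sample(n, 1)]))
    expect_lte(drop1@counts[["S"]], ct[["S"]])
  }
})

test_that("pairwise deletion keeps columns complete deletion discards", {
  seqs <- c("AAC-", "AACT", "AGCT", "AG-T")
  comp <- classifySites(makeAln(seqs), deletion = "complete")
  pair <- classifySites(makeAln(seqs), deletion = "pairwise")
  expect_identical(comp@counts[["usable"]], 2L)
  expect_identical(pair@counts[["usable"]], 4L)
  expect_gte(pair@counts[["S"]], comp@counts[["S"]])
})

test_that("haplotype collapsing is deterministic and consistent with groups", {
  expect_identical(length(collapseHaplotypes(makeAln(rep("AACA", 4)))@haplotypes),
                   1L)
  toy <- makeAln(c("AACA", "AACT", "AGCT", "AGTT"))
  expect_identical(length(collapseHaplotypes(toy)@haplotypes), 4L)
  # duplicates collapse; numbering follows first occurrence
  aln <- makeAln(c("AACT", "AGGT", "AACT", "TTTT", "AGGT"),
                 groups = c("X", "X", "Y", "Y", "Y"))
  hs <- collapseHaplotypes(aln)
  expect_identical(length(hs@haplotypes), 3L)
  expect_identical(unname(haplotypeCounts(hs)), c(2L, 2L, 1L))
  expect_identical(hs@members$Hap_1, c("s1", "s3"))
  # per-group haplotype counts sum to group sizes
  expect_identical(as.integer(colSums(groupHaplotypeCounts(hs))), c(2L, 3L))
  # gap column excluded from haplotype identity
  gapd <- makeAln(c("AAC-", "AACT"))
  expect_identical(length(collapseHaplotypes(gapd)@haplotypes), 1L)
})

test_that("outgroup sequences are excluded from statistics", {
  aln <- makeAln(c("AACA", "AACT", "GGGG"),
                 outgroup = c(FALSE, FALSE, TRUE))
  cs <- classifySites(aln)
  expect_identical(cs@counts[["S"]], 1L)
  expect_identical(length(collapseHaplotypes(aln)@haplotypes), 2L)
})

test_that("divergent haplotypes are flagged by minimum pairwise distance", {
  # all haplotypes within 2 steps: nothing flagged at min_steps = 10
  near <- collapseHaplotypes(makeAln(c("AACAAAAAAAAA", "AACTAAAAAAAA",
                                       "AGCTAAAAAAAA")))
  expect_identical(flagDivergentHaplotypes(near, min_steps = 10),
                   character(0))
  # one haplotype >= 12 differences from all others
  base <- strrep("A", 20)
  far <- paste(c(rep("T", 12), rep("A", 8)), collapse = "")
  med <- paste(c("C", rep("A", 19)), collapse = "")
  hs <- collapseHaplotypes(makeAln(c(base, med, far)))
  flagged <- flagDivergentHaplotypes(hs, min_steps = 10)
  expect_identical(flagged, "Hap_3")
  expect_error(flagDivergentHaplotypes(
    collapseHaplotypes(makeAln(rep(base, 3))), min_steps = 10),
    "at least 2")
  # removing the flagged haplotype drops its carriers
  aln <- makeAln(c(base, med, far, far))
  hs2 <- collapseHaplotypes(aln)
  red <- removeHaplotypes(aln, hs2, flagDivergentHaplotypes(hs2, min_steps = 10))
  expect_identical(nSequences(red), 2L)
})
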