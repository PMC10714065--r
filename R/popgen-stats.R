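#' @include AllClasses.R AllGenerics.R alignment-io.R
NULL

# ---- low-level core on integer matrices (no NA: usable columns only) ------
#
# All per-group statistics reduce to per-column base counts, so nothing here
# materialises an n x n distance matrix except the permutation machinery,
# which reuses one precomputed pairwise-difference matrix.

# Mean pairwise differences per locus (khat): per column, the number of
# unequal pairs is C(n,2) - sum_b C(c_b,2).
.khatFromCounts <- function(cc, n) {
  if (ncol(cc) == 0L) return(0)
  unequal <- choose(n, 2) - colSums(choose(cc, 2))
  sum(unequal) / choose(n, 2)
}

# Folded site-frequency spectrum counted per minor allele: a column with
# allele counts (5,3,1) contributes one mutation of class 3 and one of class
# 1. eta has length floor(n/2).
.foldedSfsFromCounts <- function(cc, n) {
  eta <- integer(max(1L, n %/% 2L))
  poly <- which(colSums(cc > 0L) >= 2L)
  for (j in poly) {
    c4 <- cc[, j]
    major <- which.max(c4)
    for (b in seq_len(4L)[-major]) {
      if (c4[b] > 0L) {
        cls <- min(c4[b], n - c4[b])
        eta[cls] <- eta[cls] + 1L
      }
    }
  }
  eta
}

# Tajima (1989) normalisation.
.tajimaConstants <- function(n) {
  a1 <- .harmonic(n - 1L); a2 <- .harmonic2(n - 1L)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

.tajimaDFromSk <- function(S, khat, n) {
  if (S < 1L) return(NA_real_)
  k <- .tajimaConstants(n)
  v <- k$e1 * S + k$e2 * S * (S - 1)
  if (!is.finite(v) || v <= 0) return(NA_real_)   # degenerate at n = 3
  (khat - S / k$a1) / sqrt(v)
}

# ---- Fu (1995) second-order moments of the site-frequency spectrum --------
#
# Cov(xi_i, xi_j) = theta * delta_ij / i + theta^2 * sigma_ij. These exact
# coefficients drive the variance of any linear SFS statistic, and hence the
# normalisation of the singleton-free Tajima-type test below.

.sigmaCache <- new.env(parent = emptyenv())

fuSigmaMatrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.sigmaCache[[key]])) return(.sigmaCache[[key]]$sigma)
  avec <- c(0, cumsum(1 / seq_len(n)))   # avec[i] = a_i = sum_{k<i} 1/k
  an <- avec[n]
  bet <- function(i)
    2 * n * (avec[n + 1L] - avec[i]) / ((n - i + 1) * (n - i)) - 2 / (n - i)
  m <- n - 1L
  sig <- matrix(0, m, m)
  for (i in seq_len(m)) {
    sig[i, i] <- if (2L * i < n) bet(i + 1L)
      else if (2L * i == n) 2 * (an - avec[i]) / (n - i) - 1 / i^2
      else bet(i) - 1 / i^2
  }
  if (m >= 2L) for (i in 2:m) for (j in 1:(i - 1L)) {
    v <- if (i + j < n) (bet(i + 1L) - bet(i)) / 2
      else if (i + j == n)
        (an - avec[i]) / (n - i) + (an - avec[j]) / (n - j) -
          (bet(i) + bet(j + 1L)) / 2 - 1 / (i * j)
      else (bet(j) - bet(j + 1L)) / 2 - 1 / (i * j)
    sig[i, j] <- sig[j, i] <- v
  }
  .sigmaCache[[key]] <- list(sigma = sig)
  sig
}

# Precomputed constants of the folded singleton-free Tajima-type test for a
# given n (cached; rarefaction re-enters here for every resampled k).
.yConstants <- function(n) {
  key <- paste0("y", n)
  if (!is.null(.sigmaCache[[key]])) return(.sigmaCache[[key]])
  if (n < 4L) return(NULL)
  sig <- fuSigmaMatrix(n)
  idx <- 2:(n - 2L)
  Pn <- n * (n - 1) / 2 - n
  cpi <- idx * (n - idx) / Pn
  cwNorm <- .harmonic(n - 1L) - 1 - 1 / (n - 1)
  cw <- rep(1 / cwNorm, length(idx))
  d <- cpi - cw
  out <- list(idx = idx, Pn = Pn, cwNorm = cwNorm,
              alpha = sum(d^2 / idx),
              beta = drop(t(d) %*% sig[idx, idx] %*% d),
              sumSigma = sum(sig[idx, idx]))
  .sigmaCache[[key]] <- out
  out
}

# Folded, singleton-free Tajima-type test (Achaz-style Y) from the folded
# SFS. Returns NA when undefined (n < 4 or no non-singleton mutations).
.achazYFromFolded <- function(eta, n) {
  yc <- .yConstants(n)
  if (is.null(yc)) return(NA_real_)
  jmax <- n %/% 2L
  j <- seq_len(jmax)
  keep <- j >= 2L
  Sstar <- sum(eta[keep])
  if (Sstar < 1L) return(NA_real_)
  thPi <- sum((j[keep] * (n - j[keep]) / yc$Pn) * eta[keep])
  thW <- Sstar / yc$cwNorm
  th <- thW
  th2 <- Sstar * (Sstar - 1) / (yc$cwNorm^2 + yc$sumSigma)
  v <- yc$alpha * th + yc$beta * th2
  if (!is.finite(v) || v <= 0) return(NA_real_)
  (thPi - thW) / sqrt(v)
}

# Unfolded variant: singleton class xi_1 removed only (requires a polarised
# spectrum, i.e. an outgroup).
.achazYFromUnfolded <- function(xi, n) {
  if (n < 3L) return(NA_real_)
  sig <- fuSigmaMatrix(n)
  idx <- 2:(n - 1L)
  Pn <- n * (n - 1) / 2 - (n - 1)
  cwNorm <- .harmonic(n - 1L) - 1
  cpi <- idx * (n - idx) / Pn
  d <- cpi - 1 / cwNorm
  Sstar <- sum(xi[idx])
  if (Sstar < 1L) return(NA_real_)
  thPi <- sum(cpi * xi[idx])
  thW <- Sstar / cwNorm
  th2 <- Sstar * (Sstar - 1) / (cwNorm^2 + sum(sig[idx, idx]))
  v <- sum(d^2 / idx) * thW + drop(t(d) %*% sig[idx, idx] %*% d) * th2
  if (!is.finite(v) || v <= 0) return(NA_real_)
  (thPi - thW) / sqrt(v)
}

# One-stop per-group statistics bundle from a no-NA integer matrix restricted
# to usable columns. L is the usable length for per-site scaling.
.groupStats <- function(im, L) {
  n <- nrow(im)
  cc <- .colBaseCounts(im)
  cls <- .classifyCounts(cc)
  S <- sum(cls != "monomorphic")
  khat <- .khatFromCounts(cc, n)
  key <- if (ncol(im)) apply(im, 1L, paste, collapse = ",") else rep("", n)
  hapid <- match(key, unique(key))
  hcounts <- tabulate(hapid)
  eta <- .foldedSfsFromCounts(cc, n)
  list(n = n, S = S,
       singletons = sum(cls == "singleton"),
       parsim = sum(cls == "parsimony"),
       H = length(hcounts),
       Hd = if (n >= 2L) n / (n - 1) * (1 - sum((hcounts / n)^2)) else NA_real_,
       khat = khat,
       pi = khat / L,
       thetaW = S / (.harmonic(n - 1L) * L),
       D = .tajimaDFromSk(S, khat, n),
       Y = .achazYFromFolded(eta, n),
       eta = eta, hapCounts = hcounts)
}

# Alignment-like input -> list(im = usable-column integer matrix, L = usable
# length, groups, n). Outgroup rows of a CohortAlignment are dropped.
.usableData <- function(x, groups = NULL) {
  if (is(x, "CohortAlignment")) {
    x <- dropOutgroup(x)
    if (is.null(groups)) groups <- groups(x)
  }
  im <- .alnIntMatrix(x)
  usable <- .usableMask(im)
  list(im = im[, usable, drop = FALSE], L = sum(usable),
       groups = groups, n = nrow(im))
}

# ---- exported statistics ---------------------------------------------------

#' Haplotype diversity (Nei's bias-corrected estimator)
#'
#' `Hd = n/(n-1) * (1 - sum(p_i^2))` with `p_i` the haplotype frequencies:
#' the probability that two sequences drawn without replacement carry
#' different haplotypes.
#'
#' @param x A vector of haplotype counts, a [HaplotypeSet-class], or a
#'   [CohortAlignment-class] (collapsed internally).
#' @return Haplotype diversity in `[0, 1]`.
#' @examples
#' haplotypeDiversity(c(1, 1))   # 1
#' haplotypeDiversity(c(4))      # 0
#' @export
haplotypeDiversity <- function(x) {
  counts <- if (is(x, "HaplotypeSet")) haplotypeCounts(x)
    else if (is(x, "CohortAlignment")) haplotypeCounts(collapseHaplotypes(x))
    else x
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity needs a sample of at least 2 sequences")
  n / (n - 1) * (1 - sum((counts / n)^2))
}

#' Nucleotide diversity per site
#'
#' Mean number of pairwise nucleotide differences per usable site over all
#' `C(n,2)` sequence pairs. With `"complete"` deletion the denominator is the
#' shared usable length; with `"pairwise"` deletion each pair is scored over
#' the columns where both sequences carry unambiguous bases.
#'
#' @param x A [CohortAlignment-class] or alignment matrix.
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return Nucleotide diversity per site (multiply by 100 for the
#'   conventional percentage).
#' @export
nucleotideDiversity <- function(x, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  if (is(x, "CohortAlignment")) x <- dropOutgroup(x)
  im <- .alnIntMatrix(x)
  if (nrow(im) < 2L) stop("nucleotide diversity needs at least 2 sequences")
  if (deletion == "complete") {
    usable <- .usableMask(im)
    if (!any(usable)) stop("no usable columns under complete deletion")
    cc <- .colBaseCounts(im[, usable, drop = FALSE])
    return(.khatFromCounts(cc, nrow(im)) / sum(usable))
  }
  n <- nrow(im)
  eq <- matrix(0, n, n); both <- matrix(0, n, n)
  def <- !is.na(im)
  both <- tcrossprod(def * 1)
  for (b in 1:4) {
    ib <- (im == b) & def
    eq <- eq + tcrossprod(ib * 1)
  }
  up <- upper.tri(both)
  if (any(both[up] == 0))
    stop("some sequence pairs share no usable columns under pairwise deletion")
  mean((both - eq)[up] / both[up])
}

#' Watterson's theta per site
#'
#' `thetaW = S / (a_n * L)` with `a_n = sum(1/i, i = 1..n-1)`.
#'
#' @param S Number of segregating sites.
#' @param n Sample size (>= 2).
#' @param L Number of usable sites (>= 1).
#' @return Watterson's estimator per site.
#' @examples
#' wattersonTheta(3, 4, 100)
#' @export
wattersonTheta <- function(S, n, L) {
  n <- .checkCount(n, "n", 2L); L <- .checkCount(L, "L", 1L)
  if (S < 0) stop("S must be >= 0")
  S / (.harmonic(n - 1L) * L)
}

#' Tajima's D
#'
#' The normalised difference between the mean-pairwise-difference estimator
#' of theta and Watterson's `S/a_n`, with Tajima's (1989) variance
#' normalisation. Negative values indicate an excess of rare variants
#' (expansion-like spectra); values rising toward 0 accompany the loss of
#' rare variants.
#'
#' @param x A [CohortAlignment-class] or alignment matrix (complete
#'   deletion).
#' @return Tajima's D, or `NA` (with a warning) when `S = 0`.
#' @export
tajimasD <- function(x) {
  ud <- .usableData(x)
  if (ud$n < 3L) stop("Tajima's D needs at least 3 sequences")
  st <- .groupStats(ud$im, ud$L)
  if (st$S < 1L) {
    warning("Tajima's D undefined: no segregating sites")
    return(NA_real_)
  }
  .tajimaDFromSk(st$S, st$khat, ud$n)
}

#' Achaz's Y neutrality statistic
#'
#' A Tajima-type test computed after removing the singleton classes of the
#' site-frequency spectrum, which makes it robust to sequencing errors (these
#' mostly inflate singletons). Both theta estimators are re-normalised to
#' stay unbiased without singletons and the variance uses Fu's (1995) exact
#' second-order moments of the spectrum. By default the folded spectrum is
#' used (no outgroup polarisation): the removed class is the minor-allele
#' singletons. When `folded = FALSE`, `x` must be a polarised (unfolded)
#' spectrum and only the derived-singleton class is removed.
#'
#' @param x A [CohortAlignment-class], an alignment matrix, or (with
#'   `folded = FALSE`) an unfolded SFS vector of length `n - 1`.
#' @param folded Logical; use the folded spectrum (default `TRUE`).
#' @param n Sample size, required when `x` is an SFS vector.
#' @return Y, or `NA` (with a warning) when no non-singleton polymorphism
#'   remains.
#' @export
achazY <- function(x, folded = TRUE, n = NULL) {
  if (is.numeric(x) && is.null(dim(x))) {
    if (is.null(n)) stop("n is required when x is an SFS vector")
    y <- if (folded) .achazYFromFolded(x, n) else .achazYFromUnfolded(x, n)
    if (is.na(y)) warning("Achaz's Y undefined for this spectrum")
    return(y)
  }
  ud <- .usableData(x)
  if (ud$n < 4L) stop("Achaz's Y needs at least 4 sequences")
  st <- .groupStats(ud$im, ud$L)
  if (!folded)
    stop("unfolded Y requires a polarised SFS; pass the spectrum directly")
  if (is.na(st$Y)) warning("Achaz's Y undefined: all polymorphisms are singletons")
  st$Y
}

# ---- differentiation -------------------------------------------------------

# n x n pairwise difference matrix over usable columns (counts per locus).
.pairDiffMatrix <- function(im) {
  n <- nrow(im)
  eq <- matrix(0, n, n)
  for (b in 1:4) eq <- eq + tcrossprod((im == b) * 1)
  ncol(im) - eq
}

.fstFromDiff <- function(d, labels) {
  gl <- unique(labels)
  if (length(gl) != 2L) stop("Hudson's FST needs exactly two groups")
  i1 <- which(labels == gl[1L]); i2 <- which(labels == gl[2L])
  if (length(i1) < 2L || length(i2) < 2L)
    stop("both groups need at least 2 sequences")
  hw1 <- mean(d[i1, i1][upper.tri(d[i1, i1])])
  hw2 <- mean(d[i2, i2][upper.tri(d[i2, i2])])
  hb <- mean(d[i1, i2])
  if (hb == 0) {
    warning("between-group mean difference is 0: FST undefined")
    return(NA_real_)
  }
  1 - 0.5 * (hw1 + hw2) / hb
}

.phistFromDiff <- function(d, labels) {
  gl <- unique(labels)
  if (length(gl) != 2L) stop("phiST needs exactly two groups")
  idx <- split(seq_along(labels), factor(labels, levels = gl))
  ng <- lengths(idx)
  if (any(ng < 2L)) stop("both groups need at least 2 sequences")
  N <- sum(ng); P <- 2L
  ssdTotal <- sum(d[upper.tri(d)]) / N
  ssdWithin <- sum(vapply(idx, function(i)
    sum(d[i, i][upper.tri(d[i, i])]) / length(i), 0))
  ssdAmong <- ssdTotal - ssdWithin
  msWithin <- ssdWithin / (N - P)
  msAmong <- ssdAmong / (P - 1)
  nprime <- (N - sum(ng^2) / N) / (P - 1)
  sigmaA <- (msAmong - msWithin) / nprime
  tot <- sigmaA + msWithin
  if (tot == 0) {
    warning("total molecular variance is 0: phiST undefined")
    return(NA_real_)
  }
  sigmaA / tot
}

#' Hudson's FST between two groups
#'
#' `1 - Hw/Hb` with `Hw` the average of the two within-group mean pairwise
#' difference counts and `Hb` the between-group mean.
#'
#' @param x A [CohortAlignment-class] or alignment matrix.
#' @param labels Group label per sequence; defaults to the sample table's
#'   groups. Exactly two groups, each with >= 2 sequences.
#' @return FST (<= 1), `NA` with a warning when undefined.
#' @export
hudsonFst <- function(x, labels = NULL) {
  ud <- .usableData(x, labels)
  .fstFromDiff(.pairDiffMatrix(ud$im), ud$groups)
}

#' phiST between two groups (AMOVA on pairwise differences)
#'
#' Variance decomposition of the pairwise nucleotide-difference matrix into
#' among- and within-group components; `phiST` is the among-group fraction.
#' Unlike a frequency-based FST it weights haplotypes by their molecular
#' distance.
#'
#' @inheritParams hudsonFst
#' @return phiST (<= 1), `NA` with a warning when undefined.
#' @export
phiSt <- function(x, labels = NULL) {
  ud <- .usableData(x, labels)
  .phistFromDiff(.pairDiffMatrix(ud$im), ud$groups)
}

#' Permutation test for a differentiation statistic
#'
#' Shuffles group labels (preserving group sizes), recomputes the statistic,
#' and reports the add-one p-value
#' `(1 + #\{permuted >= observed\}) / (n_perm + 1)`; ties count as extreme.
#'
#' @param x A [CohortAlignment-class] or alignment matrix.
#' @param statistic `"fst"`, `"phist"`, or a function
#'   `(diffMatrix, labels) -> numeric`.
#' @param labels Group label per sequence (two groups); defaults to sample
#'   table groups.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @return A list with `observed`, `p.value`, `n_perm`, and the permuted
#'   values `perm`.
#' @export
permutationTest <- function(x, statistic = c("fst", "phist"), labels = NULL,
                            n_perm = 1000, seed = NULL) {
  fun <- if (is.function(statistic)) statistic
    else switch(match.arg(statistic), fst = .fstFromDiff,
                phist = .phistFromDiff)
  ud <- .usableData(x, labels)
  labels <- ud$groups
  if (length(unique(labels)) < 2L || min(table(labels)) < 1L)
    stop("permutation test needs two non-empty groups")
  n_perm <- .checkCount(n_perm, "n_perm", 1L)
  d <- .pairDiffMatrix(ud$im)
  obs <- fun(d, labels)
  perm <- withSeed(seed, vapply(seq_len(n_perm), function(i)
    fun(d, sample(labels)), 0))
  p <- (1 + sum(perm >= obs, na.rm = TRUE)) / (n_perm + 1)
  list(observed = obs, p.value = p, n_perm = n_perm, perm = perm)
}

#' Per-group diversity and neutrality table
#'
#' Computes, for each group of the alignment (outgroup excluded) and
#' optionally for the pooled sample, the summary familiar from mtDNA
#' diversity tables: sample size, segregating sites split into singleton and
#' parsimony-informative columns, number of haplotypes, haplotype diversity,
#' nucleotide diversity and Watterson's theta in percent per site, Tajima's
#' D, and Achaz's Y. Usable columns (complete deletion) are determined
#' within each group.
#'
#' @param x A [CohortAlignment-class].
#' @param pooled Add an `All` row over every non-outgroup sequence
#'   (default `TRUE`).
#' @return A data frame with columns `group, N, S, Singl, Parsim, Hap, Hd,
#'   pi_pct, thetaW_pct, D, Y`.
#' @export
diversityTable <- function(x, pooled = TRUE) {
  x <- dropOutgroup(x)
  gl <- unique(groups(x))
  rows <- lapply(gl, function(g) {
    sub <- x[which(groups(x) == g)]
    .diversityRow(g, sub)
  })
  if (pooled && length(gl) > 1L) rows <- c(rows, list(.diversityRow("All", x)))
  do.call(rbind, rows)
}

.diversityRow <- function(label, sub) {
  ud <- .usableData(sub)
  st <- .groupStats(ud$im, ud$L)
  data.frame(group = label, N = st$n, S = st$S, Singl = st$singletons,
             Parsim = st$parsim, Hap = st$H, Hd = st$Hd,
             pi_pct = 100 * st$pi, thetaW_pct = 100 * st$thetaW,
             D = st$D, Y = st$Y)
}

#' Write a diversity table as tab-separated text
#'
#' @param tab Result of [diversityTable()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDiversityTable <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
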