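# Independent brute-force oracles. These deliberately re-derive every
# statistic from first principles with explicit loops, sharing no code with
# the package internals, so that implementation and oracle can only agree if
# both are right.

makeAln <- function(seqs, groups = NULL, times = NULL, ids = NULL,
                    outgroup = NULL) {
  n <- length(seqs)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  names(seqs) <- ids
  meta <- data.frame(
    id = ids,
    group = if (is.null(groups)) rep("A", n) else groups,
    time_gen = if (is.null(times)) rep(0, n) else times)
  if (!is.null(outgroup)) meta$outgroup <- outgroup
  cohortAlignment(seqs, meta)
}

charMat <- function(seqs) do.call(rbind, strsplit(toupper(seqs), ""))

# Complete-deletion column classification by per-column counting.
oracleSiteCounts <- function(seqs) {
  m <- charMat(seqs)
  S <- 0L; singl <- 0L; parsim <- 0L; usable <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (any(!col %in% c("A", "C", "G", "T"))) next
    usable <- usable + 1L
    tab <- table(col)
    if (length(tab) < 2L) next
    S <- S + 1L
    if (sum(tab >= 2L) >= 2L) parsim <- parsim + 1L
    else singl <- singl + 1L      # every minor allele occurs exactly once
  }
  list(S = S, singl = singl, parsim = parsim, usable = usable)
}

# Pairwise difference count over complete-deletion columns.
oracleDiffMat <- function(seqs) {
  m <- charMat(seqs)
  keep <- apply(m, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) d[i, j] <- sum(m[i, ] != m[j, ])
  d
}

oraclePi <- function(seqs) {
  m <- charMat(seqs)
  keep <- apply(m, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  d <- oracleDiffMat(seqs)
  n <- nrow(d)
  tot <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) { tot <- tot + d[i, j]; np <- np + 1 }
  (tot / np) / sum(keep)
}

# Fu (1995) sigma coefficients, scalar transliteration.
oracleFuSigma <- function(n) {
  aa <- function(i) if (i <= 1) 0 else sum(1 / seq_len(i - 1))
  bet <- function(i) 2 * n * (aa(n + 1) - aa(i)) / ((n - i + 1) * (n - i)) -
    2 / (n - i)
  sig <- matrix(0, n - 1, n - 1)
  for (i in seq_len(n - 1)) for (j in seq_len(n - 1)) {
    if (i == j) {
      sig[i, j] <- if (2 * i < n) bet(i + 1)
        else if (2 * i == n) 2 * (aa(n) - aa(i)) / (n - i) - 1 / i^2
        else bet(i) - 1 / i^2
    } else {
      hi <- max(i, j); lo <- min(i, j)
      sig[i, j] <- if (hi + lo < n) (bet(hi + 1) - bet(hi)) / 2
        else if (hi + lo == n)
          (aa(n) - aa(hi)) / (n - hi) + (aa(n) - aa(lo)) / (n - lo) -
            (bet(hi) + bet(lo + 1)) / 2 - 1 / (hi * lo)
        else (bet(lo) - bet(lo + 1)) / 2 - 1 / (hi * lo)
    }
  }
  sig
}

# Tajima's D via the SFS-weight variance route (independent of the 1989
# e1/e2 constants used by the implementation).
oracleTajimaD <- function(seqs) {
  m <- charMat(seqs)
  n <- nrow(m)
  sc <- oracleSiteCounts(seqs)
  S <- sc$S
  if (S == 0) return(NA_real_)
  khat <- oraclePi(seqs) * sc$usable
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  sig <- oracleFuSigma(n)
  i <- seq_len(n - 1)
  dwt <- i * (n - i) / choose(n, 2) - 1 / a1       # pi-weights minus W-weights
  alpha <- sum(dwt^2 / i)
  beta <- 0
  for (a in i) for (b in i) beta <- beta + dwt[a] * dwt[b] * sig[a, b]
  th <- S / a1
  th2 <- S * (S - 1) / (a1^2 + a2)
  (khat - S / a1) / sqrt(alpha * th + beta * th2)
}

# Folded SFS counted per minor allele, by loops.
oracleFoldedSfs <- function(seqs) {
  m <- charMat(seqs)
  keep <- apply(m, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  eta <- rep(0L, floor(n / 2))
  for (j in seq_len(ncol(m))) {
    tab <- sort(table(m[, j]), decreasing = TRUE)
    if (length(tab) < 2L) next
    for (k in 2:length(tab)) {
      cls <- min(tab[k], n - tab[k])
      eta[cls] <- eta[cls] + 1L
    }
  }
  eta
}

# Folded singleton-free Tajima-type statistic (Achaz-style Y), loop
# transliteration of the omega-weight framework.
oracleAchazY <- function(seqs) {
  m <- charMat(seqs)
  n <- nrow(m)
  if (n < 4) return(NA_real_)
  eta <- oracleFoldedSfs(seqs)
  jmax <- floor(n / 2)
  Sstar <- sum(eta[2:jmax])
  if (Sstar < 1) return(NA_real_)
  an <- sum(1 / seq_len(n - 1))
  Pn <- n * (n - 1) / 2 - n
  cwNorm <- an - 1 - 1 / (n - 1)
  thPi <- 0
  for (j in 2:jmax) thPi <- thPi + j * (n - j) / Pn * eta[j]
  thW <- Sstar / cwNorm
  sig <- oracleFuSigma(n)
  idx <- 2:(n - 2)
  dwt <- idx * (n - idx) / Pn - 1 / cwNorm
  alpha <- sum(dwt^2 / idx)
  beta <- 0; ssig <- 0
  for (a in seq_along(idx)) for (b in seq_along(idx)) {
    beta <- beta + dwt[a] * dwt[b] * sig[idx[a], idx[b]]
    ssig <- ssig + sig[idx[a], idx[b]]
  }
  th <- thW
  th2 <- Sstar * (Sstar - 1) / (cwNorm^2 + ssig)
  (thPi - thW) / sqrt(alpha * th + beta * th2)
}

oracleFst <- function(seqs, labels) {
  d <- oracleDiffMat(seqs)
  gl <- unique(labels)
  w <- numeric(2)
  for (g in 1:2) {
    idx <- which(labels == gl[g])
    tot <- 0; np <- 0
    for (i in idx) for (j in idx) if (i < j) { tot <- tot + d[i, j]; np <- np + 1 }
    w[g] <- tot / np
  }
  i1 <- which(labels == gl[1]); i2 <- which(labels == gl[2])
  tot <- 0; np <- 0
  for (i in i1) for (j in i2) { tot <- tot + d[i, j]; np <- np + 1 }
  hb <- tot / np
  1 - mean(w) / hb
}

oraclePhiSt <- function(seqs, labels) {
  d <- oracleDiffMat(seqs)
  n <- nrow(d)
  gl <- unique(labels)
  ssdT <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ssdT <- ssdT + d[i, j]
  ssdT <- ssdT / n
  ssdW <- 0
  for (g in gl) {
    idx <- which(labels == g)
    s <- 0
    for (i in idx) for (j in idx) if (i < j) s <- s + d[i, j]
    ssdW <- ssdW + s / length(idx)
  }
  ng <- as.numeric(table(factor(labels, levels = gl)))
  msW <- ssdW / (n - 2)
  msA <- (ssdT - ssdW) / 1
  nprime <- (n - sum(ng^2) / n) / 1
  sigA <- (msA - msW) / nprime
  sigA / (sigA + msW)
}

# Exact with-replacement resampling expectation of a statistic by exhaustive
# enumeration of all n^k equiprobable index tuples.
oracleResampleExpectation <- function(n, k, statFun) {
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), k)))
  mean(apply(grid, 1L, statFun))
}
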