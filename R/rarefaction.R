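#' @include popgen-stats.R
NULL

.RAREFY_STATS <- c("H", "Hd", "pi", "thetaW", "D", "Y")

#' Rarefaction curves by with-replacement resampling
#'
#' Standardises diversity and neutrality statistics to common sample sizes
#' so that groups of unequal n can be compared: for each sample size `k`,
#' `n_resamples` multisets of `k` sequences are drawn *with replacement* from
#' the group and the statistic is recomputed on each draw; the curve reports
#' the mean and standard error of the resample distribution. Resamples where
#' a statistic is undefined (e.g. Tajima's D with no segregating site, or Y
#' with only singletons) are dropped and counted, not imputed.
#'
#' Usable columns (complete deletion) are fixed at the group level before
#' resampling. Note that with-replacement draws at `k = n` do not reproduce
#' the group totals: duplicated draws hide haplotypes, so the mean H curve
#' stays below the group's total H (coupon-collector effect).
#'
#' @param x A [CohortAlignment-class] or alignment matrix.
#' @param group Optional single group label to resample from (default: use
#'   all non-outgroup sequences of `x`).
#' @param stats Statistics to compute; subset of
#'   `c("H","Hd","pi","thetaW","D","Y")`. `pi` and `thetaW` are per site.
#' @param k_min,k_max Sample-size range. Defaults: `k_min = 2` (3 for D and
#'   Y, whose variance terms degenerate below), `k_max = min(n, 50)`.
#' @param n_resamples Resamples per k (default 5000).
#' @param seed Optional integer seed; curves are bit-reproducible given the
#'   seed and resample count.
#' @return A data frame `stat, group, k, mean, se, n_valid` with attributes
#'   `seed` and `n_resamples`.
#' @export
rarefactionCurve <- function(x, group = NULL, stats = .RAREFY_STATS,
                             k_min = NULL, k_max = NULL, n_resamples = 5000,
                             seed = NULL) {
  stats <- match.arg(stats, .RAREFY_STATS, several.ok = TRUE)
  if (is(x, "CohortAlignment")) {
    x <- dropOutgroup(x)
    if (!is.null(group)) {
      idx <- which(groups(x) == group)
      if (!length(idx)) stop(sprintf("no sequences in group '%s'", group))
      x <- x[idx]
    }
  }
  glabel <- if (is.null(group)) "all" else group
  ud <- .usableData(x)
  n <- ud$n
  if (n < 2L) stop("rarefaction needs a group of at least 2 sequences")
  kloDefault <- if (any(stats %in% c("D", "Y"))) 3L else 2L
  if (is.null(k_min)) k_min <- kloDefault
  if (is.null(k_max)) k_max <- min(n, 50L)
  k_min <- .checkCount(k_min, "k_min", 1L)
  k_max <- .checkCount(k_max, "k_max", k_min)
  n_resamples <- .checkCount(n_resamples, "n_resamples", 1L)

  prep <- .rarefyPrep(ud)
  needSfs <- any(stats %in% c("D", "thetaW", "Y"))
  rows <- withSeed(seed, {
    out <- vector("list", k_max - k_min + 1L)
    for (k in k_min:k_max) {
      draws <- matrix(sample.int(n, n_resamples * k, replace = TRUE),
                      nrow = n_resamples)
      vals <- matrix(NA_real_, n_resamples, length(stats),
                     dimnames = list(NULL, stats))
      for (r in seq_len(n_resamples))
        vals[r, ] <- .rarefyEval(prep, draws[r, ], k, stats, needSfs)
      out[[k - k_min + 1L]] <- data.frame(
        stat = stats, group = glabel, k = k,
        mean = colMeans(vals, na.rm = TRUE),
        se = apply(vals, 2L, function(v) {
          nv <- sum(!is.na(v))
          if (nv >= 2L) stats::sd(v, na.rm = TRUE) / sqrt(nv) else NA_real_
        }),
        n_valid = as.integer(colSums(!is.na(vals))), row.names = NULL)
    }
    do.call(rbind, out)
  })
  rows$mean[rows$n_valid == 0L] <- NA_real_
  attr(rows, "seed") <- seed
  attr(rows, "n_resamples") <- n_resamples
  rows
}

# Precompute the group's haplotype structure so each resample only needs the
# haplotype multiplicity vector: column base counts are mult %*% indicator.
.rarefyPrep <- function(ud) {
  im <- ud$im
  v <- which(apply(im, 2L, function(col) length(unique(col))) > 1L)
  imv <- im[, v, drop = FALSE]
  key <- if (ncol(imv)) apply(imv, 1L, paste, collapse = ",") else
    rep("", nrow(im))
  hapid <- match(key, unique(key))
  H <- max(hapid)
  reps <- imv[match(seq_len(H), hapid), , drop = FALSE]
  ind <- lapply(1:4, function(b) (reps == b) * 1)
  list(L = ud$L, hapid = hapid, H = H, ind = ind, Sv = ncol(imv))
}

.rarefyEval <- function(prep, idx, k, stats, needSfs) {
  mult <- tabulate(prep$hapid[idx], prep$H)
  present <- mult > 0L
  out <- numeric(length(stats)); names(out) <- stats
  if (prep$Sv) {
    cc <- do.call(rbind, lapply(prep$ind, function(m) drop(mult %*% m)))
  } else {
    cc <- matrix(0L, 4L, 0L)
  }
  nAll <- if (ncol(cc)) colSums(cc > 0L) else integer()
  S <- sum(nAll >= 2L)
  for (s in stats) {
    out[s] <- switch(s,
      H = sum(present),
      Hd = if (k >= 2L) k / (k - 1) * (1 - sum((mult[present] / k)^2))
           else NA_real_,
      pi = .khatFromCounts(cc, k) / prep$L,
      thetaW = S / (.harmonic(k - 1L) * prep$L),
      D = if (k >= 3L && S >= 1L)
            .tajimaDFromSk(S, .khatFromCounts(cc, k), k) else NA_real_,
      Y = if (k >= 4L) .achazYFromFolded(.foldedSfsFromCounts(cc, k), k)
          else NA_real_)
  }
  out
}

#' Compare two rarefaction curves
#'
#' Flags, per statistic and sample size k, whether the `mean +/- se`
#' intervals of the two curves are disjoint, and in which direction the
#' difference points. Non-overlapping standard errors over a run of k values
#' are the working criterion for a real difference between cohorts.
#'
#' @param curve_a,curve_b Results of [rarefactionCurve()] sharing the same
#'   statistics and k grid.
#' @return A data frame `stat, k, mean_a, se_a, mean_b, se_b, nonoverlap,
#'   direction` where `direction` is `-1`, `0`, `1` for a below / overlap /
#'   a above.
#' @export
compareCurves <- function(curve_a, curve_b) {
  key_a <- paste(curve_a$stat, curve_a$k)
  key_b <- paste(curve_b$stat, curve_b$k)
  if (!setequal(key_a, key_b))
    stop("curves must share the same statistic and k grid")
  curve_b <- curve_b[match(key_a, key_b), ]
  lo_a <- curve_a$mean - curve_a$se; hi_a <- curve_a$mean + curve_a$se
  lo_b <- curve_b$mean - curve_b$se; hi_b <- curve_b$mean + curve_b$se
  nonov <- (lo_a > hi_b) | (lo_b > hi_a)
  dirn <- ifelse(!nonov | is.na(nonov), 0L, ifelse(lo_a > hi_b, 1L, -1L))
  data.frame(stat = curve_a$stat, k = curve_a$k,
             mean_a = curve_a$mean, se_a = curve_a$se,
             mean_b = curve_b$mean, se_b = curve_b$se,
             nonoverlap = nonov, direction = dirn, row.names = NULL)
}
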