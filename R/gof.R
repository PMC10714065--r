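#' @include abc-rf.R
NULL

#' Goodness-of-fit envelope test
#'
#' Compares each observed summary statistic to the central `1 - alpha`
#' interval of its distribution over a scenario's simulations (empirical
#' order statistics, linear interpolation). A statistic is flagged as an
#' outlier when the observed value falls outside the envelope; a scenario
#' compatible with the data should leave (almost) no statistic flagged,
#' while even the best-voted scenario may be rejected wholesale if it
#' cannot reproduce the observation. For a constant simulated column the
#' statistic is flagged only if the observed value differs from the
#' constant.
#'
#' @param tab Training table from [buildTrainingTable()], or any data frame
#'   of simulated statistics.
#' @param observed Named numeric vector from [computeSumstats()].
#' @param scenario Optional scenario id to restrict `tab` to (default: use
#'   all rows of `tab`).
#' @param alpha Envelope tail mass (default 0.05, i.e. a 95% interval).
#' @return A data frame `stat, observed, lower, upper, outlier` with
#'   attribute `nOutliers`.
#' @export
gofOutliers <- function(tab, observed, scenario = NULL, alpha = 0.05) {
  manifest <- attr(tab, "manifest") %||% intersect(colnames(tab),
                                                   names(observed))
  if (!is.null(scenario)) {
    tab <- tab[tab$scenario == scenario, , drop = FALSE]
    if (!nrow(tab)) stop(sprintf("no simulations for scenario '%s'", scenario))
  }
  if (nrow(tab) < 100L)
    warning("fewer than 100 simulations: envelope quantiles are unstable")
  rows <- lapply(manifest, function(s) {
    sims <- tab[[s]]
    obs <- unname(observed[s])
    sims <- sims[!is.na(sims)]
    if (!length(sims) || is.na(obs))
      return(data.frame(stat = s, observed = obs, lower = NA_real_,
                        upper = NA_real_, outlier = NA))
    if (max(sims) == min(sims)) {
      lo <- hi <- sims[1L]
    } else {
      q <- stats::quantile(sims, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                           type = 7)
      lo <- q[1L]; hi <- q[2L]
    }
    data.frame(stat = s, observed = obs, lower = lo, upper = hi,
               outlier = obs < lo | obs > hi)
  })
  out <- do.call(rbind, rows)
  attr(out, "nOutliers") <- sum(out$outlier, na.rm = TRUE)
  out
}

#' Per-scenario outlier counts
#'
#' Runs [gofOutliers()] for every scenario of a training table.
#'
#' @inheritParams gofOutliers
#' @return A data frame `scenario, nOutliers, nStats`.
#' @export
gofSummary <- function(tab, observed, alpha = 0.05) {
  scen <- levels(droplevels(tab$scenario))
  rows <- lapply(scen, function(sc) {
    g <- gofOutliers(tab, observed, scenario = sc, alpha = alpha)
    data.frame(scenario = sc, nOutliers = attr(g, "nOutliers"),
               nStats = sum(!is.na(g$outlier)))
  })
  do.call(rbind, rows)
}

#' Project simulated clouds and the observed point on PCA and LDA axes
#'
#' The visual prior-compatibility check: simulations of every scenario and
#' the observed dataset are projected on the first two principal components
#' (centred and scaled) and on the first two linear-discriminant axes. If
#' the observed point falls outside every scenario's cloud, the priors
#' cannot produce data like the observation and the model choice is
#' meaningless.
#'
#' @inheritParams gofOutliers
#' @return A list of two data frames, `pca` and `lda`, each with columns
#'   `axis1, axis2, scenario` (the observed point has scenario
#'   `"observed"`).
#' @export
projectClouds <- function(tab, observed) {
  if (nrow(tab) < 3L) stop("projection needs at least 3 simulated rows")
  manifest <- attr(tab, "manifest") %||% intersect(colnames(tab),
                                                   names(observed))
  imp <- .imputeStats(tab[manifest])
  obs <- observed[manifest]
  obs[is.na(obs)] <- imp$medians[manifest][is.na(obs)]
  keepVar <- vapply(imp$df, function(v) stats::sd(v) > 0, TRUE)
  if (any(!keepVar))
    warning(sprintf("%d zero-variance columns dropped", sum(!keepVar)))
  X <- as.matrix(imp$df[keepVar])
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  pcSim <- pc$x[, 1:2, drop = FALSE]
  pcObs <- stats::predict(pc, t(obs[keepVar]))[, 1:2]
  keep <- .ldaKeep(imp$df)
  ld <- MASS::lda(imp$df[keep], grouping = tab$scenario)
  ldSim <- stats::predict(ld, imp$df[keep])$x
  ldObs <- stats::predict(ld, as.data.frame(as.list(obs))[keep])$x
  naxes <- min(2L, ncol(ldSim))
  mk <- function(sim, ob) {
    ax <- cbind(sim[, 1L], if (ncol(sim) >= 2L) sim[, 2L] else 0)
    data.frame(axis1 = c(ax[, 1L], ob[1L]),
               axis2 = c(ax[, 2L], if (length(ob) >= 2L) ob[2L] else 0),
               scenario = c(as.character(tab$scenario), "observed"))
  }
  list(pca = mk(pcSim, pcObs), lda = mk(ldSim[, seq_len(naxes), drop = FALSE],
                                        drop(ldObs)[seq_len(naxes)]))
}
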