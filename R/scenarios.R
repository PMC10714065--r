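#' @include coalescent.R popgen-stats.R
NULL

.luDraw <- function(p) {
  u <- stats::runif(1L)
  if (p$dist == "logunif") exp(log(p$lower) + u * (log(p$upper) - log(p$lower)))
  else p$lower + u * (p$upper - p$lower)
}

.prior <- function(dist, lower, upper) list(dist = dist, lower = lower,
                                            upper = upper)

#' The six competing demographic scenarios
#'
#' Builds the default scenario set for single-population mtDNA decline
#' testing. All histories are piecewise-constant haploid models; priors are
#' log-uniform for sizes, rates and fold changes and uniform for event
#' times:
#'
#' * `SC1` constant large Ne (log-U `[2000, 20000]`);
#' * `SC2` constant small Ne (log-U `[100, 2000]`);
#' * `SC3` old expansion: current Ne grew by a factor f at `T_old >= 150`
#'   generations BP;
#' * `SC4` old decline: current Ne shrank by a factor f at `T_old >= 150`;
#' * `SC5` recent decline: an f-fold crash within the last `T_rec <= 3`
#'   generations;
#' * `SC6` old expansion (`T_old > 150`) followed by a recent `>= 10`-fold
#'   decline (`T_rec <= 3`).
#'
#' Shared priors: `N ~ log-U[100, 20000]` (where not stated otherwise),
#' `T_old ~ U[150, 2000]`, `T_rec ~ U[1, 3]`, factors `~ log-U[10, 100]`,
#' and the per-site mutation rate `mu ~ log-U[1e-8, 1e-7]` per generation.
#'
#' @return Named list of [ScenarioSpec-class] objects (`SC1` ... `SC6`).
#' @export
scenarioSet <- function() {
  muPrior <- .prior("logunif", 1e-8, 1e-7)
  sc <- list()
  sc$SC1 <- new("ScenarioSpec", id = "SC1",
    description = "constant large Ne",
    priors = list(N = .prior("logunif", 2000, 20000), mu = muPrior),
    constraint = function(d) TRUE,
    build = function(d) list(model = demographicModel(0, d[["N"]]),
                             mu = d[["mu"]]))
  sc$SC2 <- new("ScenarioSpec", id = "SC2",
    description = "constant small Ne",
    priors = list(N = .prior("logunif", 100, 2000), mu = muPrior),
    constraint = function(d) TRUE,
    build = function(d) list(model = demographicModel(0, d[["N"]]),
                             mu = d[["mu"]]))
  sc$SC3 <- new("ScenarioSpec", id = "SC3",
    description = "old expansion (>= 150 gen BP)",
    priors = list(N = .prior("logunif", 100, 20000),
                  T_old = .prior("unif", 150, 2000),
                  f_old = .prior("logunif", 10, 100), mu = muPrior),
    constraint = function(d) d[["T_old"]] >= 150,
    build = function(d) list(
      model = demographicModel(c(0, d[["T_old"]]),
                               c(d[["N"]], d[["N"]] / d[["f_old"]])),
      mu = d[["mu"]]))
  sc$SC4 <- new("ScenarioSpec", id = "SC4",
    description = "old decline (>= 150 gen BP)",
    priors = list(N = .prior("logunif", 100, 20000),
                  T_old = .prior("unif", 150, 2000),
                  f_old = .prior("logunif", 10, 100), mu = muPrior),
    constraint = function(d) d[["T_old"]] >= 150,
    build = function(d) list(
      model = demographicModel(c(0, d[["T_old"]]),
                               c(d[["N"]], d[["N"]] * d[["f_old"]])),
      mu = d[["mu"]]))
  sc$SC5 <- new("ScenarioSpec", id = "SC5",
    description = "recent decline (<= 3 gen BP)",
    priors = list(N = .prior("logunif", 100, 20000),
                  T_rec = .prior("unif", 1, 3),
                  f_rec = .prior("logunif", 10, 100), mu = muPrior),
    constraint = function(d) d[["T_rec"]] <= 3,
    build = function(d) list(
      model = demographicModel(c(0, d[["T_rec"]]),
                               c(d[["N"]] / d[["f_rec"]], d[["N"]])),
      mu = d[["mu"]]))
  sc$SC6 <- new("ScenarioSpec", id = "SC6",
    description = "old expansion then recent >= 10-fold decline",
    priors = list(N = .prior("logunif", 100, 20000),
                  T_old = .prior("unif", 150, 2000),
                  f_old = .prior("logunif", 10, 100),
                  T_rec = .prior("unif", 1, 3),
                  f_rec = .prior("logunif", 10, 100), mu = muPrior),
    constraint = function(d) d[["T_old"]] > 150 && d[["T_rec"]] <= 3 &&
      d[["N"]] / d[["f_rec"]] <= d[["N"]] / 10,
    build = function(d) list(
      model = demographicModel(c(0, d[["T_rec"]], d[["T_old"]]),
                               c(d[["N"]] / d[["f_rec"]], d[["N"]],
                                 d[["N"]] / d[["f_old"]])),
      mu = d[["mu"]]))
  sc
}

#' Draw one parameter set from a scenario's priors
#'
#' Independent draws from each prior, accepted only when the scenario's
#' constraints hold (rejection sampling). If fewer than 0.1% of attempts are
#' accepted the priors are considered incompatible with the constraints and
#' an error asks for prior revision.
#'
#' @param spec A [ScenarioSpec-class].
#' @param seed Optional integer seed.
#' @return Named numeric vector of parameter values (including `mu`).
#' @export
sampleParameters <- function(spec, seed = NULL) {
  stopifnot(is(spec, "ScenarioSpec"))
  withSeed(seed, {
    for (try in seq_len(1000L)) {
      d <- vapply(spec@priors, .luDraw, 0)
      if (isTRUE(spec@constraint(d))) return(d)
    }
    stop(sprintf(paste0("scenario %s: constraint acceptance rate below 0.1%%",
                        " -- revise the priors"), spec@id))
  })
}

# Identify the two cohorts by sampling time: "old" is the larger
# generations-BP value.
.cohortSplit <- function(grps, times) {
  tb <- tapply(times, grps, unique)
  if (length(tb) != 2L)
    stop("summary statistics require exactly two cohorts")
  tvals <- vapply(tb, function(v) v[1L], 0)
  list(old = names(tb)[which.max(tvals)], new = names(tb)[which.min(tvals)])
}

#' Summary-statistic vector for a two-cohort dataset
#'
#' Computes a fixed-order named vector of population-genetic summary
#' statistics from a two-cohort alignment (observed or simulated): for the
#' old cohort, the new cohort and the pooled sample -- segregating sites,
#' singleton columns, number of haplotypes, haplotype diversity, nucleotide
#' diversity and Watterson's theta per site, mean pairwise differences,
#' Tajima's D and Achaz's Y -- plus between-cohort statistics: Hudson's
#' FST, phiST, mean between-cohort pairwise differences, and shared /
#' private haplotype counts. Undefined entries (D with `S = 0`, Y with only
#' singletons, FST with no between-cohort differences) are encoded as `NA`
#' and imputed identically for simulated and observed data downstream.
#'
#' The cohorts are identified by sampling time (`old` = larger
#' generations-BP value); usable columns are determined on the pooled
#' sample so observed and simulated data get identical treatment.
#'
#' @param x A [CohortAlignment-class] or a `simAlignment` from
#'   [simulateAlignment()].
#' @return Named numeric vector of length 33 with attribute `manifest`.
#' @export
computeSumstats <- function(x) {
  if (inherits(x, "simAlignment")) {
    im <- x$states; L <- x$L; grps <- x$groups; tms <- x$times
  } else {
    x <- dropOutgroup(x)
    ud <- .usableData(x)
    im <- ud$im; L <- ud$L; grps <- ud$groups; tms <- samplingTimes(x)
  }
  ch <- .cohortSplit(grps, tms)
  iOld <- which(grps == ch$old); iNew <- which(grps == ch$new)
  units <- list(old = im[iOld, , drop = FALSE],
                new = im[iNew, , drop = FALSE],
                pool = im)
  per <- lapply(units, .groupStats, L = L)
  vec <- unlist(lapply(names(per), function(u) {
    st <- per[[u]]
    stats::setNames(
      c(st$S, st$singletons, st$H, st$Hd, st$pi, st$thetaW, st$khat,
        st$D, st$Y),
      paste0(c("S", "singl", "H", "Hd", "pi", "thetaW", "khat", "D", "Y"),
             "_", u))
  }))
  d <- .pairDiffMatrix(im)
  labels <- ifelse(seq_len(nrow(im)) %in% iOld, "old", "new")
  fst <- withCallingHandlers(.fstFromDiff(d, labels),
                             warning = function(w) invokeRestart("muffleWarning"))
  phist <- withCallingHandlers(.phistFromDiff(d, labels),
                               warning = function(w) invokeRestart("muffleWarning"))
  keyAll <- if (ncol(im)) apply(im, 1L, paste, collapse = ",") else
    rep("", nrow(im))
  hOld <- unique(keyAll[iOld]); hNew <- unique(keyAll[iNew])
  between <- c(fst = fst, phist = phist,
               kBetween = mean(d[iOld, iNew]),
               hapShared = length(intersect(hOld, hNew)),
               hapPrivOld = length(setdiff(hOld, hNew)),
               hapPrivNew = length(setdiff(hNew, hOld)))
  out <- c(vec, between)
  attr(out, "manifest") <- names(out)
  out
}

#' Build an ABC training table of simulated summary statistics
#'
#' For each scenario and each of `n_per_scenario` rows: draw parameters from
#' the priors, simulate a serial-sampling alignment under the implied
#' demography, and summarise it with [computeSumstats()]. Every row gets a
#' seed derived deterministically from the master seed, so the table is
#' reproducible and rows are independent.
#'
#' @param scenarios Named list of [ScenarioSpec-class] (default
#'   [scenarioSet()]).
#' @param n_per_scenario Simulations per scenario.
#' @param scheme A [SamplingScheme-class] describing the observed sampling
#'   design (sizes, times, locus length).
#' @param kappa Transition/transversion bias for the mutation layer
#'   (default 10).
#' @param seed Master integer seed.
#' @return A data frame with columns `scenario`, the parameter draws
#'   (`par_*`, `NA` where a scenario lacks the parameter), and the summary
#'   statistics; attribute `manifest` names the statistic columns.
#' @export
buildTrainingTable <- function(scenarios = scenarioSet(), n_per_scenario,
                               scheme, kappa = 10, seed = NULL) {
  n_per_scenario <- .checkCount(n_per_scenario, "n_per_scenario", 1L)
  stopifnot(is(scheme, "SamplingScheme"))
  allPars <- unique(unlist(lapply(scenarios, function(s) names(s@priors))))
  total <- n_per_scenario * length(scenarios)
  rowSeeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, total))
  rows <- vector("list", total)
  labs <- character(total)
  r <- 0L
  for (scName in names(scenarios)) {
    spec <- scenarios[[scName]]
    for (i in seq_len(n_per_scenario)) {
      r <- r + 1L
      rows[[r]] <- withSeed(rowSeeds[r], {
        draw <- sampleParameters(spec)
        built <- spec@build(draw)
        sim <- .dropMut(.simGenealogy(built$model, scheme),
                        mutationModel(built$mu, kappa), NULL)
        ss <- computeSumstats(sim)
        pars <- stats::setNames(rep(NA_real_, length(allPars)),
                                paste0("par_", allPars))
        pars[paste0("par_", names(draw))] <- draw
        c(pars, ss)
      })
      labs[r] <- scName
    }
  }
  tab <- as.data.frame(do.call(rbind, rows))
  out <- cbind(data.frame(scenario = factor(labs, levels = names(scenarios))),
               tab)
  attr(out, "manifest") <- setdiff(colnames(tab), paste0("par_", allPars))
  attr(out, "rowSeeds") <- rowSeeds
  attr(out, "seed") <- seed
  out
}

# Canonical statistic ordering (for documentation and table headers).
computeSumstatsManifest <- function() {
  nm <- c(outer(c("S", "singl", "H", "Hd", "pi", "thetaW", "khat", "D", "Y"),
                c("old", "new", "pool"), paste, sep = "_"))
  c(nm, "fst", "phist", "kBetween", "hapShared", "hapPrivOld", "hapPrivNew")
}

#' Write a training table with its manifest header
#'
#' Tab-separated output preceded by `#` comment lines recording the
#' scenario ids, the statistic manifest and the master seed.
#'
#' @param tab Result of [buildTrainingTable()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTrainingTable <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scenarios: %s",
                     paste(levels(tab$scenario), collapse = ",")), con)
  writeLines(sprintf("# statistics: %s",
                     paste(attr(tab, "manifest"), collapse = ",")), con)
  writeLines(sprintf("# master_seed: %s",
                     as.character(attr(tab, "seed") %||% NA)), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shrink every prior range symmetrically
#'
#' Returns a copy of a scenario set in which each prior's range is reduced
#' to a fraction of its original width around its midpoint (geometric
#' midpoint for log-uniform priors). `factor = 1` returns the set
#' unchanged; smaller factors give increasingly informative priors.
#'
#' @param scenarios Named list of [ScenarioSpec-class].
#' @param factor Width fraction in `(0, 1]`.
#' @return The shrunk scenario list.
#' @export
shrinkPriors <- function(scenarios, factor) {
  stopifnot(factor > 0, factor <= 1)
  lapply(scenarios, function(sp) {
    sp@priors <- lapply(sp@priors, function(p) {
      if (p$dist == "logunif") {
        mid <- sqrt(p$lower * p$upper)
        half <- (log(p$upper) - log(p$lower)) / 2 * factor
        p$lower <- mid * exp(-half); p$upper <- mid * exp(half)
      } else {
        mid <- (p$lower + p$upper) / 2
        half <- (p$upper - p$lower) / 2 * factor
        p$lower <- mid - half; p$upper <- mid + half
      }
      p
    })
    sp
  })
}

#' Prior-sensitivity report for the scenario-choice error rates
#'
#' The forest's out-of-bag prior error rate measures how distinguishable
#' the scenarios are *under the priors*: broad, weakly informative priors
#' put much simulation mass in regions where different demographies produce
#' statistically equivalent data, inflating the error regardless of the
#' classifier. This report retrains the forest on training tables simulated
#' under progressively narrower priors and tabulates the error rates, which
#' quantifies how much of the error is prior diffuseness rather than
#' statistic weakness.
#'
#' @param scheme A [SamplingScheme-class].
#' @param factors Prior width fractions to scan (default `c(1, 0.5, 0.25)`).
#' @param n_per_scenario Simulations per scenario per level (default 500).
#' @param num.trees Forest size (default 500).
#' @param seed Master seed.
#' @return A data frame `factor, priorError, typeII_SC6, minAccuracy`.
#' @export
priorSensitivity <- function(scheme, factors = c(1, 0.5, 0.25),
                             n_per_scenario = 500, num.trees = 500,
                             seed = 1) {
  rows <- lapply(factors, function(f) {
    sc <- shrinkPriors(scenarioSet(), f)
    tab <- buildTrainingTable(sc, n_per_scenario, scheme,
                              seed = deriveSeed(seed, paste0("ps", f)))
    fit <- trainScenarioClassifier(tab, num.trees = num.trees,
                                   seed = deriveSeed(seed, paste0("psf", f)))
    data.frame(factor = f, priorError = priorErrorRate(fit),
               typeII_SC6 = unname(typeIIError(fit)["SC6"]),
               minAccuracy = 1 - max(typeIIError(fit)))
  })
  do.call(rbind, rows)
}
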