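#' @include gof.R rarefaction.R
NULL

#' Remove sequences carrying given haplotypes
#'
#' Convenience for the divergent-haplotype exclusion rule: drops from the
#' alignment every sequence assigned to one of the named haplotypes
#' (typically those returned by [flagDivergentHaplotypes()]).
#'
#' @param x A [CohortAlignment-class].
#' @param hapset The [HaplotypeSet-class] computed from `x`.
#' @param haps Character vector of haplotype names to exclude.
#' @return The reduced [CohortAlignment-class].
#' @export
removeHaplotypes <- function(x, hapset, haps) {
  stopifnot(is(hapset, "HaplotypeSet"))
  bad <- unlist(hapset@members[haps], use.names = FALSE)
  keep <- setdiff(names(sequences(dropOutgroup(x))), bad)
  x[keep]
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the study-scale
#' defaults: 5000 rarefaction resamples, 10,000 simulations per scenario,
#' a 1000-tree forest, 10 forest replicates, 1000 permutations. Smaller
#' values are appropriate for exploratory runs.
#'
#' @param n_per_scenario Simulations per scenario (default 10000).
#' @param num.trees Forest size (default 1000).
#' @param replicates Forest replicates for convergence (default 10).
#' @param n_resamples Rarefaction resamples (default 5000).
#' @param n_perm Label permutations for FST/phiST tests (default 1000).
#' @param kappa Transition/transversion bias (default 10).
#' @param alpha Goodness-of-fit envelope tail mass (default 0.05).
#' @param seed Master seed; every stage derives its own logged seed from it.
#' @return A named list of class `RunConfig`.
#' @export
abcConfig <- function(n_per_scenario = 10000, num.trees = 1000,
                      replicates = 10, n_resamples = 5000, n_perm = 1000,
                      kappa = 10, alpha = 0.05, seed = 1) {
  structure(list(n_per_scenario = n_per_scenario, num.trees = num.trees,
                 replicates = replicates, n_resamples = n_resamples,
                 n_perm = n_perm, kappa = kappa, alpha = alpha,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Infer the serial-sampling scheme of an alignment
#'
#' Reads group sizes and sampling times off the sample table and uses the
#' pooled usable length as the locus length, so that simulations and the
#' observed data are summarised over the same number of sites.
#'
#' @param x A [CohortAlignment-class].
#' @return A [SamplingScheme-class].
#' @export
schemeFromAlignment <- function(x) {
  x <- dropOutgroup(x)
  g <- groups(x); tt <- samplingTimes(x)
  gl <- unique(g)
  tg <- vapply(gl, function(gg) unique(tt[g == gg])[1L], 0)
  ud <- .usableData(x)
  samplingScheme(n = as.integer(table(factor(g, levels = gl))), times = tg,
                 groups = gl, L = ud$L)
}

#' Cohort diversity report
#'
#' The statistics stage of the pipeline: the per-group diversity table plus
#' between-cohort differentiation (Hudson's FST and phiST with permutation
#' p-values) when exactly two groups are present.
#'
#' @param x A [CohortAlignment-class].
#' @param config A `RunConfig` from [abcConfig()].
#' @param out Optional directory; writes `diversity.tsv`.
#' @return A list: `table`, and with two groups `fst`, `phist` (each the
#'   [permutationTest()] result).
#' @export
runDiversityReport <- function(x, config = abcConfig(), out = NULL) {
  tab <- diversityTable(x)
  res <- list(table = tab)
  gl <- unique(groups(dropOutgroup(x)))
  if (length(gl) == 2L) {
    res$fst <- permutationTest(x, "fst", n_perm = config$n_perm,
                               seed = deriveSeed(config$seed, "fst"))
    res$phist <- permutationTest(x, "phist", n_perm = config$n_perm,
                                 seed = deriveSeed(config$seed, "phist"))
  }
  if (!is.null(out)) {
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    writeDiversityTable(tab, file.path(out, "diversity.tsv"))
  }
  res
}

#' Rarefaction stage
#'
#' Rarefaction curves for every group of the alignment on a shared k grid,
#' plus the pairwise non-overlap comparison when there are two groups.
#'
#' @inheritParams runDiversityReport
#' @param stats Statistics to rarefy (default all six).
#' @param k_max Upper end of the k grid (default `min(max group n, 50)`).
#' @return A list: `curves` (named by group) and optionally `comparison`.
#' @export
runRarefaction <- function(x, config = abcConfig(), stats = .RAREFY_STATS,
                           k_max = NULL, out = NULL) {
  x <- dropOutgroup(x)
  gl <- unique(groups(x))
  if (is.null(k_max))
    k_max <- min(max(table(groups(x))), 50L)
  curves <- lapply(gl, function(g) {
    kg <- min(k_max, sum(groups(x) == g))
    rarefactionCurve(x, group = g, stats = stats, k_max = kg,
                     n_resamples = config$n_resamples,
                     seed = deriveSeed(config$seed, paste0("rarefy_", g)))
  })
  names(curves) <- gl
  res <- list(curves = curves)
  if (length(gl) == 2L) {
    kShared <- min(vapply(curves, function(cv) max(cv$k), 0))
    cA <- curves[[1L]][curves[[1L]]$k <= kShared, ]
    cB <- curves[[2L]][curves[[2L]]$k <= kShared, ]
    res$comparison <- compareCurves(cA, cB)
  }
  if (!is.null(out)) {
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    all <- do.call(rbind, curves)
    utils::write.table(all, file.path(out, "rarefaction.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  res
}

#' End-to-end ABC-RF scenario choice
#'
#' The full demographic-inference pipeline: summarise the observed
#' two-cohort alignment, simulate the training table under the six
#' scenarios with the observed sampling design, LDA-augment, train the
#' forest, classify the observation, estimate its posterior probability,
#' check goodness of fit against every scenario, and (optionally) replicate
#' the forest to assess convergence. Every stochastic stage uses a seed
#' derived from `config$seed`.
#'
#' @param observed A [CohortAlignment-class] with exactly two cohorts, or a
#'   named summary-statistic vector (then `scheme` is required).
#' @param config A `RunConfig` from [abcConfig()].
#' @param scenarios Scenario set (default [scenarioSet()]).
#' @param scheme Optional [SamplingScheme-class]; inferred from `observed`
#'   when it is an alignment.
#' @return A list of class `abcRun`: `observedStats`, `table`, `fit`
#'   ([AbcRfFit-class]), `classification` (votes, selected), `posterior`,
#'   `gof` (per-scenario outlier counts), `replicates` (or `NULL`),
#'   `config`.
#' @export
runAbcPipeline <- function(observed, config = abcConfig(),
                           scenarios = scenarioSet(), scheme = NULL) {
  if (is(observed, "CohortAlignment")) {
    if (is.null(scheme)) scheme <- schemeFromAlignment(observed)
    obsStats <- computeSumstats(observed)
  } else {
    if (is.null(scheme))
      stop("scheme is required when observed is a statistic vector")
    obsStats <- observed
  }
  tab <- buildTrainingTable(scenarios, config$n_per_scenario, scheme,
                            kappa = config$kappa,
                            seed = deriveSeed(config$seed, "table"))
  aug <- augmentWithLda(tab, obsStats)
  fit <- trainScenarioClassifier(aug, num.trees = config$num.trees,
                                 seed = deriveSeed(config$seed, "forest"))
  cl <- classifyObserved(fit, obsStats)
  post <- posteriorProbability(fit, obsStats,
                               seed = deriveSeed(config$seed, "posterior"))
  gof <- gofSummary(tab, obsStats, alpha = config$alpha)
  reps <- if (config$replicates >= 2L)
    replicateAnalysis(tab, obsStats, R = config$replicates,
                      num.trees = config$num.trees,
                      master_seed = deriveSeed(config$seed, "replicates"))
  structure(list(observedStats = obsStats, table = tab, fit = fit,
                 classification = cl, posterior = post, gof = gof,
                 replicates = reps, config = config, scheme = scheme),
            class = "abcRun")
}

#' @export
print.abcRun <- function(x, ...) {
  cat("ABC-RF scenario choice\n")
  cat(sprintf("  training: %d simulations (%d scenarios), %d trees\n",
              nrow(x$table), nlevels(x$table$scenario), x$fit@numTrees))
  v <- sort(x$classification$votes, decreasing = TRUE)
  cat("  votes: ", paste(sprintf("%s %.1f%%", names(v), 100 * v),
                         collapse = ", "), "\n", sep = "")
  cat(sprintf("  selected scenario: %s (posterior probability %.1f%%)\n",
              x$classification$selected, 100 * x$posterior))
  cat(sprintf("  OOB prior error rate: %.2f%%\n", 100 * priorErrorRate(x$fit)))
  gofBest <- x$gof$nOutliers[x$gof$scenario == x$classification$selected]
  cat(sprintf("  GOF outliers for selected scenario: %d of %d statistics\n",
              gofBest, x$gof$nStats[1L]))
  if (!is.null(x$replicates))
    cat(sprintf("  replicates: %d/%d select %s; vote SD %.1f points\n",
                x$replicates$agreement, x$replicates$R,
                names(which.max(x$replicates$voteMean)),
                100 * max(x$replicates$voteSD)))
  invisible(x)
}
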