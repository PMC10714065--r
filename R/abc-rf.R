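#' @include scenarios.R
NULL

# Median imputation of the NA sentinels, with training-column medians
# applied identically to simulated rows and the observed vector.
.imputeStats <- function(df, medians = NULL) {
  if (is.null(medians)) {
    medians <- vapply(df, function(col) {
      m <- stats::median(col, na.rm = TRUE)
      if (is.na(m)) 0 else m
    }, 0)
  }
  for (j in seq_along(df)) {
    nas <- is.na(df[[j]])
    if (any(nas)) df[[j]][nas] <- medians[[colnames(df)[j]]]
  }
  list(df = df, medians = medians)
}

# Columns suitable for LDA: non-constant and jointly full rank.
.ldaKeep <- function(X) {
  keep <- colnames(X)[vapply(X, function(v) stats::sd(v) > 0, TRUE)]
  if (length(keep) < 2L) return(keep)
  M <- scale(as.matrix(X[keep]))
  q <- qr(M)
  keep[q$pivot[seq_len(q$rank)]]
}

#' Augment summary statistics with linear-discriminant axes
#'
#' Fits a linear discriminant analysis on the (imputed) training statistics
#' with the scenario labels and appends the `k - 1` discriminant
#' coordinates as extra predictor columns to both the training rows and the
#' observed vector. The LDA is fitted on the training set only; the
#' observed point is projected afterwards, so no information leaks from the
#' observation into the discriminant axes. Constant or collinear columns
#' are dropped from the LDA fit (with a warning when any are dropped).
#'
#' @param tab A training table from [buildTrainingTable()].
#' @param observed Named numeric summary-statistic vector from
#'   [computeSumstats()].
#' @return A list: `training` (imputed statistics + `LD*` columns),
#'   `labels`, `observed` (imputed + projected named vector), `lda`,
#'   `ldaKeep`, `medians`, `manifest`.
#' @export
augmentWithLda <- function(tab, observed) {
  manifest <- attr(tab, "manifest")
  if (is.null(manifest))
    manifest <- setdiff(colnames(tab),
                        c("scenario", grep("^par_", colnames(tab), value = TRUE)))
  labels <- tab$scenario
  if (nlevels(droplevels(labels)) < 2L) stop("LDA needs at least 2 scenarios")
  X <- tab[manifest]
  if (nrow(X) <= length(manifest))
    stop("LDA augmentation needs more training rows than statistics")
  imp <- .imputeStats(X)
  keep <- .ldaKeep(imp$df)
  if (length(keep) < length(manifest))
    warning(sprintf("%d constant/collinear columns dropped from the LDA fit",
                    length(manifest) - length(keep)))
  fit <- MASS::lda(imp$df[keep], grouping = labels)
  proj <- stats::predict(fit, imp$df[keep])$x
  colnames(proj) <- paste0("LD", seq_len(ncol(proj)))
  training <- cbind(imp$df, as.data.frame(proj))
  miss <- setdiff(manifest, names(observed))
  if (length(miss))
    stop(sprintf("observed vector lacks statistics: %s",
                 paste(miss, collapse = ", ")))
  obs <- observed[manifest]
  nas <- is.na(obs)
  if (all(nas)) stop("observed vector is entirely undefined")
  obs[nas] <- imp$medians[manifest][nas]
  obsProj <- stats::predict(fit, as.data.frame(as.list(obs))[keep])$x
  observedAug <- c(obs, stats::setNames(drop(obsProj),
                                        paste0("LD", seq_len(ncol(obsProj)))))
  list(training = training, labels = labels, observed = observedAug,
       lda = fit, ldaKeep = keep, medians = imp$medians, manifest = manifest)
}

#' Train the ABC model-choice random forest
#'
#' Grows a classification forest on the (optionally LDA-augmented)
#' simulated summary statistics with scenario labels, and extracts the
#' out-of-bag (OOB) diagnostics used for ABC model choice: the *prior error
#' rate* (OOB misclassification fraction, i.e. the error expected for data
#' drawn from the prior), the row-normalised confusion matrix, and the
#' per-scenario type II error (the fraction of a scenario's simulations
#' OOB-classified as some other scenario).
#'
#' @param aug Result of [augmentWithLda()], or a raw training table from
#'   [buildTrainingTable()] (then no LDA columns are used).
#' @param num.trees Number of trees (default 1000).
#' @param seed Optional integer seed for the forest.
#' @return An [AbcRfFit-class].
#' @export
trainScenarioClassifier <- function(aug, num.trees = 1000, seed = NULL) {
  num.trees <- .checkCount(num.trees, "num.trees", 1L)
  if (is.data.frame(aug) && "scenario" %in% colnames(aug)) {
    manifest <- attr(aug, "manifest")
    imp <- .imputeStats(aug[manifest])
    aug <- list(training = imp$df, labels = aug$scenario, lda = NULL,
                ldaKeep = character(), medians = imp$medians,
                manifest = manifest, observed = NULL)
  }
  labels <- droplevels(aug$labels)
  seed <- if (is.null(seed)) sample.int(2^31 - 2, 1L) else as.integer(seed)
  rf <- ranger::ranger(x = aug$training, y = labels, num.trees = num.trees,
                       seed = seed, num.threads = 1L, verbose = FALSE)
  oob <- rf$predictions
  ok <- !is.na(oob)
  priorError <- mean(oob[ok] != labels[ok])
  conf <- table(truth = labels[ok], predicted = oob[ok])
  conf <- sweep(conf, 1L, pmax(rowSums(conf), 1L), "/")
  typeII <- 1 - diag(as.matrix(conf))
  names(typeII) <- rownames(conf)
  new("AbcRfFit", forest = rf, lda = aug$lda, ldaKeep = aug$ldaKeep,
      manifest = aug$manifest, medians = aug$medians,
      training = aug$training, labels = labels,
      oobPred = factor(oob, levels = levels(labels)),
      priorError = priorError, confusion = unclass(as.matrix(conf)),
      typeII = typeII, numTrees = num.trees, seed = seed)
}

# Impute + project a raw observed vector into the fit's predictor space.
.augmentObserved <- function(fit, observed) {
  if (length(observed) == ncol(fit@training) &&
      all(names(observed) == colnames(fit@training)))
    return(observed)                                 # already augmented
  miss <- setdiff(fit@manifest, names(observed))
  if (length(miss))
    stop(sprintf("observed vector lacks statistics: %s",
                 paste(miss, collapse = ", ")))
  obs <- observed[fit@manifest]
  nas <- is.na(obs)
  if (all(nas)) stop("observed vector is entirely undefined")
  obs[nas] <- fit@medians[fit@manifest][nas]
  if (!is.null(fit@lda)) {
    pr <- stats::predict(fit@lda, as.data.frame(as.list(obs))[fit@ldaKeep])$x
    obs <- c(obs, stats::setNames(drop(pr), paste0("LD", seq_len(ncol(pr)))))
  }
  obs
}

#' Classify an observed dataset with a trained forest
#'
#' Runs the observed summary-statistic vector down every tree and reports
#' the fraction of trees voting for each scenario; the scenario with the
#' most votes is selected.
#'
#' @param fit An [AbcRfFit-class].
#' @param observed Named numeric vector from [computeSumstats()] (raw; it
#'   is imputed and LDA-projected exactly like the training rows).
#' @return A list: `votes` (named fractions summing to 1), `selected`,
#'   `nTrees`.
#' @export
classifyObserved <- function(fit, observed) {
  stopifnot(is(fit, "AbcRfFit"))
  obs <- .augmentObserved(fit, observed)
  df <- as.data.frame(as.list(obs))[colnames(fit@training)]
  pr <- stats::predict(fit@forest, data = df, predict.all = TRUE,
                       num.threads = 1L)
  lev <- fit@forest$forest$levels
  votes <- tabulate(as.integer(pr$predictions), nbins = length(lev)) /
    fit@numTrees
  names(votes) <- lev
  list(votes = votes, selected = names(which.max(votes)),
       nTrees = fit@numTrees)
}

#' Posterior probability of the selected scenario
#'
#' Following the regression-forest construction of ABC-RF model choice: a
#' regression forest is trained to predict, from the same predictors, the
#' indicator that a training simulation's OOB classification was correct;
#' evaluated at the observed point it estimates the local probability that
#' the forest's selection is correct, i.e. the posterior probability of the
#' selected scenario.
#'
#' @param fit An [AbcRfFit-class].
#' @param observed Named numeric vector from [computeSumstats()].
#' @param num.trees Trees of the regression forest (default 1000).
#' @param seed Optional integer seed.
#' @return Probability in `[0, 1]`.
#' @export
posteriorProbability <- function(fit, observed, num.trees = 1000,
                                 seed = NULL) {
  stopifnot(is(fit, "AbcRfFit"))
  ok <- !is.na(fit@oobPred)
  y <- as.numeric(fit@oobPred[ok] == fit@labels[ok])
  seed <- if (is.null(seed)) sample.int(2^31 - 2, 1L) else as.integer(seed)
  reg <- ranger::ranger(x = fit@training[ok, , drop = FALSE], y = y,
                        num.trees = num.trees, seed = seed,
                        num.threads = 1L, verbose = FALSE)
  obs <- .augmentObserved(fit, observed)
  df <- as.data.frame(as.list(obs))[colnames(fit@training)]
  p <- stats::predict(reg, data = df, num.threads = 1L)$predictions
  min(max(p, 0), 1)
}

#' Replicate the forest analysis to assess convergence
#'
#' Repeats forest training and observed-data classification `R` times with
#' independent derived seeds and summarises the spread of the votes, the
#' posterior probability, and how often the same scenario is selected. By
#' default the training table is fixed and only the forest randomness is
#' replicated (cheap); supply `regenerate` to re-simulate a fresh training
#' table per replicate (full pipeline variance).
#'
#' @param tab Training table from [buildTrainingTable()].
#' @param observed Named numeric vector from [computeSumstats()].
#' @param R Number of replicates (default 10).
#' @param num.trees Trees per forest (default 1000).
#' @param master_seed Integer; per-replicate seeds are derived from it.
#' @param regenerate Optional `function(seed)` returning a fresh training
#'   table (enables full re-simulation replicates).
#' @param posterior Also compute the posterior probability per replicate
#'   (default TRUE).
#' @return A list: `votes` (R x scenarios matrix), `voteMean`, `voteSD`,
#'   `posterior` (vector), `posteriorMean`, `posteriorSD`, `selected`
#'   (character vector), `agreement` (count of the modal selection).
#' @export
replicateAnalysis <- function(tab, observed, R = 10, num.trees = 1000,
                              master_seed = 1, regenerate = NULL,
                              posterior = TRUE) {
  R <- .checkCount(R, "R", 1L)
  votes <- NULL; sel <- character(R); post <- rep(NA_real_, R)
  for (r in seq_len(R)) {
    tabR <- if (is.null(regenerate)) tab else
      regenerate(deriveSeed(master_seed, paste0("table", r)))
    aug <- augmentWithLda(tabR, observed)
    fit <- trainScenarioClassifier(aug, num.trees = num.trees,
                                   seed = deriveSeed(master_seed,
                                                     paste0("forest", r)))
    cl <- classifyObserved(fit, observed)
    if (is.null(votes))
      votes <- matrix(NA_real_, R, length(cl$votes),
                      dimnames = list(NULL, names(cl$votes)))
    votes[r, ] <- cl$votes
    sel[r] <- cl$selected
    if (posterior)
      post[r] <- posteriorProbability(fit, observed,
                                      seed = deriveSeed(master_seed,
                                                        paste0("post", r)))
  }
  modal <- names(sort(table(sel), decreasing = TRUE))[1L]
  list(votes = votes,
       voteMean = colMeans(votes),
       voteSD = if (R >= 2L) apply(votes, 2L, stats::sd) else
         stats::setNames(rep(NA_real_, ncol(votes)), colnames(votes)),
       posterior = post, posteriorMean = mean(post),
       posteriorSD = if (R >= 2L) stats::sd(post) else NA_real_,
       selected = sel, agreement = sum(sel == modal), R = R)
}
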