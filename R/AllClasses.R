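#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' CohortAlignment: an aligned set of haploid sequences with cohort metadata
#'
#' The central container of the package: a rectangular multiple-sequence
#' alignment (one row per individual, typically mtDNA haplotype sequences)
#' together with per-sequence sample information. Each sequence belongs to a
#' group (a population or a temporal cohort of one population) and carries a
#' sampling time expressed in generations before present, which is what the
#' serial-sampling coalescent machinery consumes.
#'
#' @slot seqs A [Biostrings::DNAStringSet] of equal-width aligned sequences;
#'   names are the (unique) sequence identifiers.
#' @slot samples A [S4Vectors::DataFrame] with one row per sequence, columns
#'   `id`, `group`, `time_gen` (generations before present, >= 0), optional
#'   `year`, and logical `outgroup` marking sequences excluded from all
#'   statistics (e.g. an outgroup used only to root a phylogeny).
#'
#' @seealso [readCohortAlignment()], [classifySites()], [collapseHaplotypes()]
#' @exportClass CohortAlignment
setClass("CohortAlignment",
  slots = c(seqs = "DNAStringSet", samples = "DataFrame"))

setValidity("CohortAlignment", function(object) {
  msg <- character()
  n <- length(object@seqs)
  if (n < 1L) msg <- c(msg, "alignment must contain at least one sequence")
  w <- Biostrings::width(object@seqs)
  if (n >= 1L && length(unique(w)) > 1L) {
    bad <- names(object@seqs)[w != stats::median(w)][1L]
    msg <- c(msg, sprintf("sequences have unequal aligned lengths (e.g. '%s')", bad))
  }
  ids <- names(object@seqs)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "sequence identifiers must be present and unique")
  req <- c("id", "group", "time_gen", "outgroup")
  if (!all(req %in% colnames(object@samples))) {
    msg <- c(msg, sprintf("sample table must have columns %s",
                          paste(req, collapse = ", ")))
  } else {
    if (nrow(object@samples) != n || !identical(as.character(object@samples$id), ids))
      msg <- c(msg, "sample table rows must match sequence ids in order")
    tg <- object@samples$time_gen
    if (any(!is.finite(tg)) || any(tg < 0))
      msg <- c(msg, "sampling times must be finite and >= 0 generations before present")
  }
  if (length(msg)) msg else TRUE
})

#' SiteClasses: per-column classification of an alignment
#'
#' Result of [classifySites()]. Columns are classified under a deletion rule:
#' with complete deletion a column is *usable* only if it is free of gaps and
#' ambiguity codes in every retained sequence. Among usable columns,
#' *segregating* columns carry >= 2 distinct bases; a segregating column is a
#' *singleton* column when every minor allele occurs in exactly one sequence,
#' and *parsimony-informative* when >= 2 alleles each occur in >= 2 sequences.
#' These two categories partition the segregating columns.
#'
#' @slot usable Logical mask over alignment columns.
#' @slot category Factor over columns: `unusable`, `monomorphic`, `singleton`,
#'   `parsimony`.
#' @slot counts Named integer vector: `usable`, `S`, `singletons`, `parsim`,
#'   `monomorphic`.
#' @slot deletion Character, `"complete"` or `"pairwise"`.
#' @exportClass SiteClasses
setClass("SiteClasses",
  slots = c(usable = "logical", category = "factor",
            counts = "integer", deletion = "character"))

setValidity("SiteClasses", function(object) {
  cn <- c("usable", "S", "singletons", "parsim", "monomorphic")
  if (!all(cn %in% names(object@counts)))
    return(sprintf("counts must be named %s", paste(cn, collapse = ", ")))
  ct <- object@counts
  if (ct["S"] != ct["singletons"] + ct["parsim"])
    return("segregating sites must split into singleton + parsimony-informative")
  if (ct["usable"] != ct["S"] + ct["monomorphic"])
    return("usable columns must split into segregating + monomorphic")
  TRUE
})

#' HaplotypeSet: sequences collapsed to unique haplotypes
#'
#' Result of [collapseHaplotypes()]: equivalence classes of sequence identity
#' over the usable columns, numbered by first occurrence in the alignment.
#'
#' @slot haplotypes Character vector of representative sequences (usable
#'   columns only), named `Hap_1`, `Hap_2`, ... by first occurrence.
#' @slot assignment Integer vector mapping each alignment row to a haplotype.
#' @slot members List of sequence-id character vectors per haplotype.
#' @slot groupCounts Integer matrix, haplotypes x groups.
#' @slot usable Logical column mask the collapse was computed under.
#' @exportClass HaplotypeSet
setClass("HaplotypeSet",
  slots = c(haplotypes = "character", assignment = "integer",
            members = "list", groupCounts = "matrix", usable = "logical"))

setValidity("HaplotypeSet", function(object) {
  H <- length(object@haplotypes)
  if (anyDuplicated(object@haplotypes))
    return("haplotype representatives must be pairwise distinct")
  if (length(object@members) != H || nrow(object@groupCounts) != H)
    return("members and groupCounts must have one entry per haplotype")
  if (sum(object@groupCounts) != length(object@assignment))
    return("group counts must sum to the number of sequences")
  TRUE
})

#' DemographicModel: piecewise-constant haploid population size
#'
#' A single-population demographic history as an ordered sequence of epochs,
#' each with a constant haploid effective size Ne (for mtDNA, the effective
#' number of transmitting females). Epoch `i` spans times
#' `[time[i], time[i+1])` in generations before present; sizes change
#' instantaneously at epoch starts. The most ancient epoch extends to
#' infinity.
#'
#' @slot times Numeric, strictly increasing epoch start times, `times[1] == 0`.
#' @slot sizes Numeric haploid Ne per epoch, all > 0.
#' @exportClass DemographicModel
setClass("DemographicModel", slots = c(times = "numeric", sizes = "numeric"))

setValidity("DemographicModel", function(object) {
  if (length(object@times) != length(object@sizes))
    return("times and sizes must have equal length")
  if (length(object@times) < 1L || object@times[1L] != 0)
    return("first epoch must start at time 0")
  if (is.unsorted(object@times, strictly = TRUE))
    return("epoch start times must be strictly increasing")
  if (any(!is.finite(object@sizes)) || any(object@sizes <= 0))
    return("all effective sizes must be finite and > 0")
  TRUE
})

#' SamplingScheme: serial (heterochronous) sampling design
#'
#' How many sequences are drawn and when, plus the locus length. Sampling
#' times are in generations before present, so `time = 0` is the most recent
#' cohort.
#'
#' @slot n Integer sample sizes, all >= 1.
#' @slot times Numeric sampling times in generations before present, >= 0.
#' @slot groups Character cohort labels, one per sampling event.
#' @slot L Integer locus length in bp.
#' @exportClass SamplingScheme
setClass("SamplingScheme",
  slots = c(n = "integer", times = "numeric", groups = "character",
            L = "integer"))

setValidity("SamplingScheme", function(object) {
  if (length(object@n) != length(object@times) ||
      length(object@n) != length(object@groups))
    return("n, times and groups must have equal length")
  if (any(object@n < 1L)) return("sample sizes must be >= 1")
  if (any(object@times < 0) || any(!is.finite(object@times)))
    return("sampling times must be finite and >= 0")
  if (object@L < 1L) return("locus length must be >= 1")
  TRUE
})

#' MutationModel: finite-sites mutation with transition bias
#'
#' Kimura-type two-parameter substitution process applied over a finite
#' number of sites: mutations arrive on a branch as a Poisson process of rate
#' `mu * L` per generation, hit a uniformly chosen site, and replace the
#' current base by a transition with probability `kappa / (kappa + 2)` or by
#' either transversion with equal probability otherwise. Recurrent hits are
#' allowed.
#'
#' @slot mu Per-site mutation rate per generation, >= 0.
#' @slot kappa Transition/transversion bias, > 0.
#' @exportClass MutationModel
setClass("MutationModel", slots = c(mu = "numeric", kappa = "numeric"))

setValidity("MutationModel", function(object) {
  if (object@mu < 0 || !is.finite(object@mu)) return("mu must be finite and >= 0")
  if (object@kappa <= 0 || !is.finite(object@kappa)) return("kappa must be > 0")
  TRUE
})

#' ScenarioSpec: a demographic scenario template with priors
#'
#' One competing demographic hypothesis: named parameter priors (uniform or
#' log-uniform), a constraint predicate enforced by rejection at draw time,
#' and a builder mapping an accepted draw to a [DemographicModel-class] and a
#' per-site mutation rate.
#'
#' @slot id Scenario identifier, e.g. `"SC6"`.
#' @slot description One-line human description.
#' @slot priors Named list; each element is `list(dist = "unif"|"logunif",
#'   lower =, upper =)`.
#' @slot constraint Function(draw) -> logical.
#' @slot build Function(draw) -> `list(model = DemographicModel, mu = numeric)`.
#' @exportClass ScenarioSpec
setClass("ScenarioSpec",
  slots = c(id = "character", description = "character", priors = "list",
            constraint = "function", build = "function"))

setValidity("ScenarioSpec", function(object) {
  for (p in object@priors) {
    if (!is.list(p) || !all(c("dist", "lower", "upper") %in% names(p)))
      return("each prior needs dist, lower, upper")
    if (!p$dist %in% c("unif", "logunif")) return("prior dist must be unif or logunif")
    if (!is.finite(p$lower) || !is.finite(p$upper) || p$lower >= p$upper)
      return("prior bounds must be finite with lower < upper")
    if (p$dist == "logunif" && p$lower <= 0)
      return("log-uniform priors need a positive lower bound")
  }
  TRUE
})

#' AbcRfFit: a trained ABC random-forest model-choice analysis
#'
#' Holds the classification forest trained on scenario-labelled simulated
#' summary statistics (optionally LDA-augmented), its out-of-bag diagnostics,
#' and everything needed to classify an observed dataset: the statistic
#' manifest, training-column medians used for sentinel imputation, and the
#' fitted discriminant projection.
#'
#' @slot forest A [ranger::ranger] classification forest.
#' @slot lda Fitted `MASS::lda` object, or `NULL` when not augmented.
#' @slot ldaKeep Character, statistic columns the LDA was fitted on.
#' @slot manifest Character, ordered names of the predictor columns.
#' @slot medians Named numeric, training medians for imputation.
#' @slot training Data frame of predictors used for training (for the
#'   posterior-probability regression forest and GOF projections).
#' @slot labels Factor of true scenario labels per training row.
#' @slot oobPred Factor of out-of-bag predicted labels per training row.
#' @slot priorError Numeric, out-of-bag misclassification rate.
#' @slot confusion Row-normalised confusion matrix from OOB predictions.
#' @slot typeII Named numeric, per-scenario type II error (1 - diagonal).
#' @slot numTrees Integer.
#' @slot seed Integer seed the forest was trained under.
#' @exportClass AbcRfFit
setClass("AbcRfFit",
  slots = c(forest = "ANY", lda = "ANY", ldaKeep = "character",
            manifest = "character", medians = "numeric",
            training = "data.frame", labels = "factor", oobPred = "factor",
            priorError = "numeric", confusion = "matrix", typeII = "numeric",
            numTrees = "integer", seed = "integer"))

setValidity("AbcRfFit", function(object) {
  if (nrow(object@confusion) > 0) {
    rs <- rowSums(object@confusion)
    if (any(abs(rs - 1) > 1e-8)) return("confusion matrix rows must sum to 1")
  }
  if (length(object@priorError) == 1 &&
      (object@priorError < 0 || object@priorError > 1))
    return("prior error rate must lie in [0, 1]")
  TRUE
})
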