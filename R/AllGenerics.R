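#' @include AllClasses.R
NULL

#' Accessors for CohortAlignment and friends
#'
#' `sequences()` returns the aligned sequences, `sampleInfo()` the sample
#' table, `groups()` the per-sequence group labels, `samplingTimes()` the
#' sampling times in generations before present, and `isOutgroup()` the
#' outgroup flags. `nSequences()` and `alignmentWidth()` give the dimensions.
#'
#' @param x A [CohortAlignment-class].
#' @return See individual descriptions.
#' @name cohort-accessors
#' @aliases sequences sampleInfo groups samplingTimes isOutgroup nSequences
#'   alignmentWidth
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname cohort-accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname cohort-accessors
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))

#' @rdname cohort-accessors
#' @export
setGeneric("samplingTimes", function(x) standardGeneric("samplingTimes"))

#' @rdname cohort-accessors
#' @export
setGeneric("isOutgroup", function(x) standardGeneric("isOutgroup"))

#' @rdname cohort-accessors
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' @rdname cohort-accessors
#' @export
setGeneric("alignmentWidth", function(x) standardGeneric("alignmentWidth"))

#' @rdname cohort-accessors
setMethod("sequences", "CohortAlignment", function(x) x@seqs)

#' @rdname cohort-accessors
setMethod("sampleInfo", "CohortAlignment", function(x) x@samples)

#' @rdname cohort-accessors
setMethod("groups", "CohortAlignment",
          function(x) as.character(x@samples$group))

#' @rdname cohort-accessors
setMethod("samplingTimes", "CohortAlignment",
          function(x) as.numeric(x@samples$time_gen))

#' @rdname cohort-accessors
setMethod("isOutgroup", "CohortAlignment",
          function(x) as.logical(x@samples$outgroup))

#' @rdname cohort-accessors
setMethod("nSequences", "CohortAlignment", function(x) length(x@seqs))

#' @rdname cohort-accessors
setMethod("alignmentWidth", "CohortAlignment", function(x)
  if (length(x@seqs)) Biostrings::width(x@seqs)[1L] else 0L)

#' Subset a CohortAlignment by sequence
#'
#' @param x A [CohortAlignment-class].
#' @param i Index vector (logical, integer, or sequence ids).
#' @param j,drop,... Ignored.
#' @return A [CohortAlignment-class] with the selected sequences.
#' @export
setMethod("[", "CohortAlignment", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@seqs))
  new("CohortAlignment", seqs = x@seqs[i], samples = x@samples[i, , drop = FALSE])
})

setMethod("show", "CohortAlignment", function(object) {
  og <- sum(isOutgroup(object))
  cat(sprintf("CohortAlignment: %d sequences x %d bp\n",
              nSequences(object), alignmentWidth(object)))
  tb <- table(groups(object))
  cat("  groups: ",
      paste(sprintf("%s (n=%d)", names(tb), as.integer(tb)), collapse = ", "),
      "\n", sep = "")
  tt <- sort(unique(samplingTimes(object)))
  cat("  sampling times (gen BP): ", paste(tt, collapse = ", "), "\n", sep = "")
  if (og) cat(sprintf("  outgroup sequences: %d (excluded from statistics)\n", og))
})

setMethod("show", "SiteClasses", function(object) {
  ct <- object@counts
  cat(sprintf(paste0("SiteClasses (%s deletion): %d usable columns; S = %d ",
                     "(%d singleton + %d parsimony-informative), %d monomorphic\n"),
              object@deletion, ct["usable"], ct["S"], ct["singletons"],
              ct["parsim"], ct["monomorphic"]))
})

setMethod("show", "HaplotypeSet", function(object) {
  cat(sprintf("HaplotypeSet: %d haplotypes among %d sequences\n",
              length(object@haplotypes), length(object@assignment)))
  tab <- sort(table(object@assignment), decreasing = TRUE)
  cat("  counts: ", paste(utils::head(as.integer(tab), 12), collapse = " "),
      if (length(tab) > 12) " ..." else "", "\n", sep = "")
})

setMethod("show", "DemographicModel", function(object) {
  cat("DemographicModel (haploid, piecewise constant):\n")
  k <- length(object@times)
  ends <- c(object@times[-1L], Inf)
  for (i in seq_len(k))
    cat(sprintf("  [%g, %g) gen BP: Ne = %g\n", object@times[i], ends[i],
                object@sizes[i]))
})

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf("ScenarioSpec %s: %s\n", object@id, object@description))
  for (nm in names(object@priors)) {
    p <- object@priors[[nm]]
    cat(sprintf("  %s ~ %s[%g, %g]\n", nm,
                if (p$dist == "logunif") "log-U" else "U", p$lower, p$upper))
  }
})

setMethod("show", "AbcRfFit", function(object) {
  cat(sprintf("AbcRfFit: %d trees, %d training simulations, %d scenarios\n",
              object@numTrees, nrow(object@training), nlevels(object@labels)))
  cat(sprintf("  OOB prior error rate: %.2f%%\n", 100 * object@priorError))
  cat(sprintf("  type II error by scenario: %s\n",
              paste(sprintf("%s %.1f%%", names(object@typeII),
                            100 * object@typeII), collapse = ", ")))
})

#' Haplotype count accessors
#'
#' `haplotypeCounts()` returns the total count per haplotype;
#' `groupHaplotypeCounts()` the haplotypes x groups count matrix.
#'
#' @param x A [HaplotypeSet-class].
#' @return Integer vector or matrix.
#' @export
setGeneric("haplotypeCounts", function(x) standardGeneric("haplotypeCounts"))

#' @rdname haplotypeCounts
#' @export
setGeneric("groupHaplotypeCounts",
           function(x) standardGeneric("groupHaplotypeCounts"))

#' @rdname haplotypeCounts
setMethod("haplotypeCounts", "HaplotypeSet", function(x) {
  out <- as.integer(rowSums(x@groupCounts))
  names(out) <- names(x@haplotypes)
  out
})

#' @rdname haplotypeCounts
setMethod("groupHaplotypeCounts", "HaplotypeSet", function(x) x@groupCounts)

#' ABC-RF fit accessors
#'
#' @param x An [AbcRfFit-class].
#' @return `priorErrorRate()`: numeric OOB misclassification rate;
#'   `oobConfusion()`: row-normalised confusion matrix; `typeIIError()`:
#'   named per-scenario type II error rates.
#' @name abcrf-accessors
NULL

#' @rdname abcrf-accessors
#' @export
setGeneric("priorErrorRate", function(x) standardGeneric("priorErrorRate"))

#' @rdname abcrf-accessors
#' @export
setGeneric("oobConfusion", function(x) standardGeneric("oobConfusion"))

#' @rdname abcrf-accessors
#' @export
setGeneric("typeIIError", function(x) standardGeneric("typeIIError"))

#' @rdname abcrf-accessors
setMethod("priorErrorRate", "AbcRfFit", function(x) x@priorError)

#' @rdname abcrf-accessors
setMethod("oobConfusion", "AbcRfFit", function(x) x@confusion)

#' @rdname abcrf-accessors
setMethod("typeIIError", "AbcRfFit", function(x) x@typeII)
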