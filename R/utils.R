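# Internal base encoding: A=1, C=2, G=3, T=4. With this coding transitions
# are 1<->3 and 2<->4, i.e. partners differ by 2 (mod 4) -- used by the
# mutation sampler. Gaps and ambiguity codes map to NA.
.BASES <- c("A", "C", "G", "T")

.encodeBase <- function(ch) {
  m <- match(ch, .BASES)
  m
}

# Character matrix (or DNAStringSet / CohortAlignment) -> integer matrix with
# NA at gaps/ambiguities. Rows keep sequence names.
.alnIntMatrix <- function(x) {
  if (is(x, "CohortAlignment")) x <- x@seqs
  if (is(x, "DNAStringSet")) {
    cm <- as.matrix(x)
  } else if (is.matrix(x) && is.character(x)) {
    cm <- toupper(x)
    cm[cm == "U"] <- "T"
  } else if (is.matrix(x) && is.numeric(x)) {
    return(x)
  } else {
    stop("cannot interpret input as an alignment matrix")
  }
  im <- matrix(.encodeBase(cm), nrow = nrow(cm), dimnames = dimnames(cm))
  im
}

# Complete-deletion usable-column mask: no NA anywhere in the column.
.usableMask <- function(im) colSums(is.na(im)) == 0L

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded at `seed` and restores the caller's
#' random-number stream afterwards; with `seed = NULL` the expression is
#' evaluated in the ambient stream. Every stochastic operation in the
#' package routes its optional `seed` argument through this helper.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}

#' Derive a stage seed from a master seed
#'
#' Deterministically maps a master seed and a stage tag to a 31-bit seed, so
#' that every stochastic stage of a pipeline gets an independent, logged,
#' reproducible stream.
#'
#' @param master Integer master seed.
#' @param tag Character stage name.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(master, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(master) * 48271 + h * 16807) %% (2^31 - 2) + 1)
}

# Harmonic sums used throughout (Watterson a_n, Tajima/Fu constants).
.harmonic <- function(k) if (k < 1L) 0 else sum(1 / seq_len(k))
.harmonic2 <- function(k) if (k < 1L) 0 else sum(1 / seq_len(k)^2)

.checkCount <- function(x, nm, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min)
    stop(sprintf("%s must be a single number >= %d", nm, min))
  as.integer(x)
}
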