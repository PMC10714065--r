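#' @include AllClasses.R utils.R alignment-io.R
NULL

#' Constructors for the simulation model objects
#'
#' `demographicModel(times, sizes)` builds a piecewise-constant haploid
#' demography (epoch `i` runs from `times[i]` backwards to `times[i+1]`
#' generations before present; the last epoch is unbounded).
#' `samplingScheme(n, times, groups, L)` describes serial sampling: how many
#' sequences are taken at which times (generations before present) for a
#' locus of `L` bp. `mutationModel(mu, kappa)` sets the per-site mutation
#' rate per generation and the transition/transversion bias.
#'
#' @param times Epoch start times / sampling times, generations before
#'   present.
#' @param sizes Haploid effective sizes per epoch.
#' @param n Integer sample sizes.
#' @param groups Cohort labels (default `cohort1`, `cohort2`, ...).
#' @param L Locus length in bp.
#' @param mu Per-site mutation rate per generation.
#' @param kappa Transition/transversion bias (default 10, a typical mtDNA
#'   value).
#' @return The corresponding S4 object.
#' @examples
#' demographicModel(c(0, 3, 2000), c(400, 8000, 300))
#' samplingScheme(n = c(52, 19), times = c(0, 2), L = 4175)
#' @name sim-constructors
NULL

#' @rdname sim-constructors
#' @export
demographicModel <- function(times, sizes)
  new("DemographicModel", times = as.numeric(times), sizes = as.numeric(sizes))

#' @rdname sim-constructors
#' @export
samplingScheme <- function(n, times, groups = NULL, L) {
  if (is.null(groups)) groups <- paste0("cohort", seq_along(n))
  new("SamplingScheme", n = as.integer(n), times = as.numeric(times),
      groups = as.character(groups), L = as.integer(L))
}

#' @rdname sim-constructors
#' @export
mutationModel <- function(mu, kappa = 10)
  new("MutationModel", mu = as.numeric(mu), kappa = as.numeric(kappa))

# Haploid size at time t (generations BP).
.sizeAt <- function(model, t) {
  model@sizes[findInterval(t, model@times)]
}

#' Simulate a serial-sampling coalescent genealogy
#'
#' Standard continuous-time single-population coalescent with heterochronous
#' samples and piecewise-constant haploid size: while `j` lineages are
#' active in an epoch of size `Ne`, the waiting time to the next coalescence
#' is exponential with rate `j(j-1)/(2 Ne)` per generation; lineages enter
#' the genealogy at their sampling times, and epoch boundaries truncate and
#' re-draw the waiting time (valid by the memorylessness of the
#' exponential). With these haploid rates `E[TMRCA] = Ne` for two
#' isochronous sequences.
#'
#' @param model A [DemographicModel-class].
#' @param scheme A [SamplingScheme-class].
#' @param seed Optional integer seed.
#' @return A `genealogy` list: `parent` (0 for the root), `times` (node
#'   times in generations BP), `nTips`, `tipTimes`, `tipGroups`, `L`. Tips
#'   are nodes `1..nTips` in scheme order.
#' @export
simulateGenealogy <- function(model, scheme, seed = NULL) {
  stopifnot(is(model, "DemographicModel"), is(scheme, "SamplingScheme"))
  withSeed(seed, .simGenealogy(model, scheme))
}

.simGenealogy <- function(model, scheme) {
  nTips <- sum(scheme@n)
  tipTimes <- rep(scheme@times, scheme@n)
  tipGroups <- rep(scheme@groups, scheme@n)
  ord <- order(tipTimes)
  nNodes <- 2L * nTips - 1L
  parent <- integer(nNodes)
  times <- numeric(nNodes)
  times[seq_len(nTips)] <- tipTimes
  pending <- ord                    # tip ids by increasing sampling time
  boundaries <- model@times[-1L]
  active <- integer(0)
  t <- tipTimes[pending[1L]]
  nextNode <- nTips + 1L
  repeat {
    while (length(pending) && tipTimes[pending[1L]] <= t) {
      active <- c(active, pending[1L]); pending <- pending[-1L]
    }
    k <- length(active)
    if (k <= 1L && !length(pending)) break
    tSample <- if (length(pending)) tipTimes[pending[1L]] else Inf
    bAhead <- boundaries[boundaries > t]
    tEpoch <- if (length(bAhead)) bAhead[1L] else Inf
    tEvent <- min(tSample, tEpoch)
    if (k >= 2L) {
      Ne <- .sizeAt(model, t)
      w <- stats::rexp(1L, rate = k * (k - 1) / (2 * Ne))
      if (t + w < tEvent) {
        pick <- sample.int(k, 2L)
        ch <- active[pick]
        t <- t + w
        times[nextNode] <- t
        parent[ch] <- nextNode
        active <- c(active[-pick], nextNode)
        nextNode <- nextNode + 1L
        next
      }
    }
    t <- tEvent
  }
  structure(list(parent = parent, times = times, nTips = nTips,
                 tipTimes = tipTimes, tipGroups = tipGroups, L = scheme@L),
            class = "genealogy")
}

#' Branch lengths and tree summaries
#'
#' @param tree A `genealogy` from [simulateGenealogy()].
#' @return `branchLengths()`: per-node length to its parent (root 0);
#'   `totalLength()`: the summed branch length; `tmrca()`: root time in
#'   generations BP.
#' @export
branchLengths <- function(tree) {
  len <- numeric(length(tree$parent))
  nz <- tree$parent > 0L
  len[nz] <- tree$times[tree$parent[nz]] - tree$times[nz]
  len
}

#' @rdname branchLengths
#' @export
totalLength <- function(tree) sum(branchLengths(tree))

#' @rdname branchLengths
#' @export
tmrca <- function(tree) max(tree$times)

#' Drop mutations on a genealogy (finite sites, transition bias)
#'
#' The number of mutations on a branch is Poisson with mean
#' `mu * L * length`; each mutation hits a uniformly chosen site and
#' replaces the current base by its transition partner with probability
#' `kappa/(kappa + 2)`, otherwise by one of the two transversions. The root
#' sequence is uniform random. Recurrent hits at a site are allowed and
#' resolved in event order along each lineage.
#'
#' @param tree A `genealogy`.
#' @param mut A [MutationModel-class].
#' @param seed Optional integer seed.
#' @param rootBases Optional integer vector (codes 1:4 = A,C,G,T) giving the
#'   root base at each *mutated* site, in order of the site positions;
#'   drawn uniformly when `NULL`.
#' @return A `simAlignment` list: `states` (tips x mutated-sites integer
#'   matrix), `sites` (1-based positions), `rootBases`, `L`, `groups`,
#'   `times`.
#' @export
dropMutations <- function(tree, mut, seed = NULL, rootBases = NULL) {
  stopifnot(inherits(tree, "genealogy"), is(mut, "MutationModel"))
  withSeed(seed, .dropMut(tree, mut, rootBases))
}

.dropMut <- function(tree, mut, rootBases) {
  L <- tree$L
  len <- branchLengths(tree)
  M <- stats::rpois(1L, mut@mu * L * sum(len))
  nTips <- tree$nTips
  if (M > 0L) {
    branch <- sample.int(length(len), M, replace = TRUE, prob = len)
    pos <- sample.int(L, M, replace = TRUE)
  } else {
    branch <- integer(0); pos <- integer(0)
  }
  sites <- sort(unique(pos))
  m <- length(sites)
  if (is.null(rootBases)) {
    rootBases <- sample.int(4L, m, replace = TRUE)
  } else if (length(rootBases) == L) {
    rootBases <- as.integer(rootBases)[sites]   # full-genome root supplied
  } else {
    stopifnot(length(rootBases) == m)
  }
  siteIdx <- match(pos, sites)
  mutsBy <- split(seq_len(M), branch)
  states <- matrix(0L, nTips, m)
  root <- which(tree$parent == 0L)
  kids <- split(seq_along(tree$parent), tree$parent)
  pTs <- mut@kappa / (mut@kappa + 2)
  # iterative preorder walk carrying the current sequence state
  stack <- list(list(node = root, state = as.integer(rootBases)))
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    v <- top$node; st <- top$state
    mu_i <- mutsBy[[as.character(v)]]
    if (!is.null(mu_i)) for (i in mu_i) {
      s <- siteIdx[i]; b <- st[s]
      st[s] <- if (stats::runif(1L) < pTs) {
        if (b <= 2L) b + 2L else b - 2L          # transition partner
      } else {
        others <- setdiff(1:4, c(b, if (b <= 2L) b + 2L else b - 2L))
        others[sample.int(2L, 1L)]
      }
    }
    if (v <= nTips) states[v, ] <- st
    for (ch in kids[[as.character(v)]])
      stack[[length(stack) + 1L]] <- list(node = ch, state = st)
  }
  structure(list(states = states, sites = sites, rootBases = rootBases,
                 L = L, groups = tree$tipGroups, times = tree$tipTimes),
            class = "simAlignment")
}

#' Simulate an alignment under a demographic model
#'
#' Convenience wrapper: genealogy plus mutations in one call.
#'
#' @inheritParams simulateGenealogy
#' @param mut A [MutationModel-class].
#' @param output `"compact"` (a `simAlignment`, the fast path used by the
#'   scenario engine) or `"CohortAlignment"` (fully rendered sequences).
#' @param seed Optional integer seed.
#' @return A `simAlignment` or [CohortAlignment-class].
#' @export
simulateAlignment <- function(model, scheme, mut, seed = NULL,
                              output = c("compact", "CohortAlignment")) {
  output <- match.arg(output)
  sim <- withSeed(seed, .dropMut(.simGenealogy(model, scheme), mut, NULL))
  if (output == "compact") sim else renderAlignment(sim, seed = seed)
}

#' Render a compact simulated alignment as a CohortAlignment
#'
#' Fills the non-mutated sites with a (random or supplied) constant
#' background sequence and returns full-length sequences.
#'
#' @param sim A `simAlignment`.
#' @param rootSeq Optional integer vector of length `L` (codes 1:4) for the
#'   background; random uniform when `NULL`. At mutated sites the
#'   simulation's own root bases take precedence.
#' @param seed Optional integer seed for the random background.
#' @param ids Optional sequence identifiers.
#' @return A [CohortAlignment-class].
#' @export
renderAlignment <- function(sim, rootSeq = NULL, seed = NULL, ids = NULL) {
  stopifnot(inherits(sim, "simAlignment"))
  n <- nrow(sim$states)
  if (is.null(rootSeq))
    rootSeq <- withSeed(seed, sample.int(4L, sim$L, replace = TRUE))
  stopifnot(length(rootSeq) == sim$L)
  full <- matrix(rep(as.integer(rootSeq), each = n), nrow = n)
  if (length(sim$sites)) full[, sim$sites] <- sim$states
  if (is.null(ids)) ids <- sprintf("sim_%03d", seq_len(n))
  chars <- matrix(.BASES[full], nrow = n)
  seqs <- apply(chars, 1L, paste, collapse = "")
  names(seqs) <- ids
  meta <- data.frame(id = ids, group = sim$groups, time_gen = sim$times)
  cohortAlignment(seqs, meta)
}

#' Write simulation presets as FASTA + metadata fixtures
#'
#' Generates a synthetic dataset emulating one of three study designs and
#' (optionally) writes it in the package's standard file dialect. All
#' presets are synthetic data produced by the package's own simulator.
#'
#' * `iberia_like` emulates the temporal study design this package was built
#'   around: one haploid (mtDNA) population sampled twice -- an old cohort
#'   of 19 sequences 2 generations before present and a new cohort of 52
#'   sequences at present -- for a 4175-bp non-recombining locus, under an
#'   old-expansion-then-recent-decline history (ancestral Ne 600, expansion
#'   to 10000 at 2000 generations BP, 25-fold crash to 400 at 3 generations
#'   BP, mu = 1e-7/site/gen, kappa = 10), calibrated by pilot simulation so
#'   that pooled nucleotide diversity is around 0.05%.
#' * `null_panmixia`: one panmictic constant population (Ne 2000) sampled
#'   once, arbitrarily split into two labelled groups of 15 -- the null for
#'   permutation-test calibration.
#' * `two_pop_toy`: two independent populations (Ne 500 each) sharing only
#'   their root sequence, 10 + 10 sequences -- a strongly structured toy
#'   (between-group divergence reflects the two independent root depths).
#'
#' @param preset One of `"iberia_like"`, `"null_panmixia"`, `"two_pop_toy"`.
#' @param seed Integer seed.
#' @param dir Optional output directory; when given, `<preset>.fasta` and
#'   `<preset>.tsv` are written there.
#' @return A list with `alignment` (a [CohortAlignment-class]) and, when
#'   written, `fasta` and `metadata` paths.
#' @export
makeFixture <- function(preset = c("iberia_like", "null_panmixia",
                                   "two_pop_toy"),
                        seed = NULL, dir = NULL) {
  preset <- match.arg(preset)
  aln <- withSeed(seed, switch(preset,
    iberia_like = {
      model <- demographicModel(c(0, 3, 2000), c(400, 10000, 600))
      scheme <- samplingScheme(n = c(52L, 19L), times = c(0, 2),
                               groups = c("IB_N", "IB_O"), L = 4175L)
      sim <- .dropMut(.simGenealogy(model, scheme), mutationModel(1e-7, 10),
                      NULL)
      renderAlignment(sim, rootSeq = sample.int(4L, sim$L, replace = TRUE),
                      ids = sprintf("ib_%03d", seq_len(71L)))
    },
    null_panmixia = {
      model <- demographicModel(0, 2000)
      scheme <- samplingScheme(n = c(15L, 15L), times = c(0, 0),
                               groups = c("grpA", "grpB"), L = 2000L)
      sim <- .dropMut(.simGenealogy(model, scheme), mutationModel(5e-7, 10),
                      NULL)
      renderAlignment(sim, rootSeq = sample.int(4L, sim$L, replace = TRUE))
    },
    two_pop_toy = {
      L <- 1000L
      rootSeq <- sample.int(4L, L, replace = TRUE)
      mkpop <- function(g) {
        scheme <- samplingScheme(n = 10L, times = 0, groups = g, L = L)
        tree <- .simGenealogy(demographicModel(0, 500), scheme)
        sim <- .dropMut(tree, mutationModel(1e-6, 10), rootSeq)
        renderAlignment(sim, rootSeq = rootSeq,
                        ids = sprintf("%s_%02d", g, 1:10))
      }
      a <- mkpop("popA"); b <- mkpop("popB")
      seqs <- c(as.character(sequences(a)), as.character(sequences(b)))
      meta <- rbind(as.data.frame(sampleInfo(a)), as.data.frame(sampleInfo(b)))
      cohortAlignment(seqs, meta)
    }))
  out <- list(alignment = aln)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, paste0(preset, ".fasta"))
    md <- file.path(dir, paste0(preset, ".tsv"))
    Biostrings::writeXStringSet(sequences(aln), fa)
    utils::write.table(as.data.frame(sampleInfo(aln)), md, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$fasta <- fa; out$metadata <- md
  }
  out
}
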