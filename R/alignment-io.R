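#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a CohortAlignment
#'
#' @param seqs A [Biostrings::DNAStringSet] (or named character vector) of
#'   aligned, equal-length sequences.
#' @param samples A data frame with columns `id`, `group`, `time_gen`
#'   (generations before present), and optionally `year` and logical
#'   `outgroup`. Rows are matched to sequences by `id`.
#' @return A validated [CohortAlignment-class].
#' @examples
#' seqs <- c(s1 = "AACA", s2 = "AACT", s3 = "AGCT")
#' meta <- data.frame(id = c("s1", "s2", "s3"), group = "P",
#'                    time_gen = 0)
#' cohortAlignment(seqs, meta)
#' @export
cohortAlignment <- function(seqs, samples) {
  if (is.character(seqs)) {
    seqs <- chartr("u", "U", toupper(seqs))
    seqs <- chartr("U", "T", seqs)
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  ids <- names(seqs)
  if (is.null(ids)) stop("sequences must be named with unique identifiers")
  samples <- as.data.frame(samples)
  if (!all(c("id", "group", "time_gen") %in% colnames(samples)))
    stop("sample table must have columns id, group, time_gen")
  if (anyDuplicated(samples$id))
    stop(sprintf("duplicated metadata rows for id '%s'",
                 samples$id[duplicated(samples$id)][1L]))
  miss <- setdiff(ids, samples$id)
  if (length(miss))
    stop(sprintf("sequence '%s' has no metadata row", miss[1L]))
  extra <- setdiff(samples$id, ids)
  if (length(extra)) {
    warning(sprintf("%d metadata rows without sequences dropped", length(extra)))
    samples <- samples[samples$id %in% ids, , drop = FALSE]
  }
  samples <- samples[match(ids, samples$id), , drop = FALSE]
  if (is.null(samples$outgroup)) samples$outgroup <- FALSE
  if (is.null(samples$year)) samples$year <- NA_real_
  df <- DataFrame(id = as.character(samples$id),
                  group = as.character(samples$group),
                  time_gen = as.numeric(samples$time_gen),
                  year = as.numeric(samples$year),
                  outgroup = as.logical(samples$outgroup))
  rownames(df) <- df$id
  new("CohortAlignment", seqs = seqs, samples = df)
}

#' Read an aligned FASTA plus sample metadata
#'
#' Reads a pre-aligned multi-FASTA and a tab-separated metadata table with
#' header `id  group  time_gen  year` (optional columns `year`, `outgroup`).
#' Sequences are uppercased and `U` is mapped to `T`. Every FASTA identifier
#' must have exactly one metadata row; ragged sequence lengths and missing
#' metadata raise errors naming the offending identifier.
#'
#' @param fasta_path Path to the aligned FASTA file.
#' @param metadata_path Path to the tab-separated metadata file.
#' @return A [CohortAlignment-class].
#' @export
readCohortAlignment <- function(fasta_path, metadata_path) {
  raw <- Biostrings::readBStringSet(fasta_path)
  ch <- toupper(as.character(raw))
  ch <- chartr("U", "T", ch)
  # first word of the FASTA header is the identifier
  names(ch) <- sub("\\s.*$", "", names(raw))
  w <- nchar(ch)
  if (length(unique(w)) > 1L) {
    ref <- as.integer(names(sort(table(w), decreasing = TRUE))[1L])
    bad <- names(ch)[w != ref][1L]
    stop(sprintf("sequence '%s' has length %d, expected %d (ragged alignment)",
                 bad, nchar(ch[[bad]]), ref))
  }
  meta <- utils::read.delim(metadata_path, header = TRUE,
                            stringsAsFactors = FALSE)
  cohortAlignment(ch, meta)
}

#' Drop outgroup sequences
#'
#' @param x A [CohortAlignment-class].
#' @return `x` without the rows flagged `outgroup` in the sample table.
#' @export
dropOutgroup <- function(x) {
  keep <- !isOutgroup(x)
  if (all(keep)) x else x[which(keep)]
}

#' Classify alignment columns
#'
#' Applies the deletion rule, then classifies every usable column as
#' monomorphic, singleton, or parsimony-informative. Under `"complete"`
#' deletion (the default, matching common DnaSP practice) a column is usable
#' only if every retained sequence carries an unambiguous base there; under
#' `"pairwise"` deletion a column is usable when at least two sequences carry
#' unambiguous bases, and allele counts ignore the missing entries. A column
#' with k >= 2 alleles counts as one segregating site; it is a singleton
#' column when every minor allele occurs exactly once, and
#' parsimony-informative when at least two alleles occur at least twice.
#'
#' @param x A [CohortAlignment-class] (outgroup rows are excluded first) or a
#'   character/integer alignment matrix.
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return A [SiteClasses-class].
#' @export
classifySites <- function(x, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  if (is(x, "CohortAlignment")) x <- dropOutgroup(x)
  im <- .alnIntMatrix(x)
  if (nrow(im) < 2L) stop("site classification needs at least 2 sequences")
  cc <- .colBaseCounts(im)
  def <- colSums(cc)                       # defined (unambiguous) bases/column
  usable <- if (deletion == "complete") def == nrow(im) else def >= 2L
  cat_ <- rep("unusable", ncol(im))
  cls <- .classifyCounts(cc[, usable, drop = FALSE])
  cat_[usable] <- cls
  category <- factor(cat_, levels = c("unusable", "monomorphic", "singleton",
                                      "parsimony"))
  counts <- c(usable = sum(usable),
              S = sum(cls != "monomorphic"),
              singletons = sum(cls == "singleton"),
              parsim = sum(cls == "parsimony"),
              monomorphic = sum(cls == "monomorphic"))
  new("SiteClasses", usable = unname(usable), category = category,
      counts = vapply(counts, as.integer, 1L), deletion = deletion)
}

# 4 x L matrix of base counts per column (NA entries ignored).
.colBaseCounts <- function(im) {
  out <- matrix(0L, 4L, ncol(im))
  for (b in 1:4) out[b, ] <- colSums(im == b, na.rm = TRUE)
  out
}

# Category per column from a 4 x L count matrix: "monomorphic", "singleton"
# (all minor alleles occur once), or "parsimony" (>= 2 alleles with count
# >= 2).
.classifyCounts <- function(cc) {
  if (ncol(cc) == 0L) return(character())
  nAll <- colSums(cc > 0L)
  nBig <- colSums(cc >= 2L)
  maxc <- apply(cc, 2L, max)
  out <- rep("singleton", ncol(cc))
  out[nAll <= 1L] <- "monomorphic"
  out[nAll >= 2L & nBig >= 2L] <- "parsimony"
  # remaining polymorphic columns have exactly one allele with count >= 2 (or
  # all alleles singletons), i.e. every minor allele is a singleton
  out
}

#' Collapse sequences into haplotypes
#'
#' Haplotypes are equivalence classes of sequence identity over the usable
#' (complete-deletion) columns; they are numbered `Hap_1`, `Hap_2`, ... by
#' first occurrence in the alignment, which makes the labelling deterministic
#' and invariant under re-runs.
#'
#' @param x A [CohortAlignment-class]; outgroup rows are excluded first.
#' @param groups Optional group label per retained sequence (defaults to the
#'   sample table's `group` column).
#' @return A [HaplotypeSet-class].
#' @export
collapseHaplotypes <- function(x, groups = NULL) {
  if (is(x, "CohortAlignment")) {
    x <- dropOutgroup(x)
    if (is.null(groups)) groups <- groups(x)
    ids <- names(sequences(x))
  } else {
    ids <- rownames(x)
  }
  im <- .alnIntMatrix(x)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(im)))
  if (is.null(groups)) groups <- rep("all", nrow(im))
  usable <- .usableMask(im)
  key <- apply(im[, usable, drop = FALSE], 1L, function(r)
    paste(.BASES[r], collapse = ""))
  if (!any(usable)) key <- rep("", nrow(im))
  assignment <- match(key, unique(key))
  H <- max(assignment)
  reps <- unique(key)
  names(reps) <- paste0("Hap_", seq_len(H))
  members <- split(ids, assignment)
  names(members) <- names(reps)
  gl <- sort(unique(groups))
  gc <- matrix(0L, H, length(gl), dimnames = list(names(reps), gl))
  tb <- table(assignment, factor(groups, levels = gl))
  gc[as.integer(rownames(tb)), ] <- as.integer(tb)
  new("HaplotypeSet", haplotypes = reps, assignment = assignment,
      members = members, groupCounts = gc, usable = unname(usable))
}

#' Flag divergent haplotypes
#'
#' Identifies haplotypes separated from *every* other haplotype of a
#' comparison set by at least `min_steps` nucleotide differences. The study
#' design motivating this rule: a haplotype many mutational steps away from
#' all haplotypes of its lineage is plausibly a migrant from an unsampled
#' population and would artificially inflate diversity, so it is excluded
#' before the diversity and simulation stages.
#'
#' @param hapset A [HaplotypeSet-class].
#' @param groups Optional character vector of group labels defining the
#'   comparison set (haplotypes observed in those groups); default all.
#' @param min_steps Minimum nucleotide distance to every other haplotype for
#'   a haplotype to be flagged (default 10).
#' @return Character vector of flagged haplotype names (possibly empty).
#' @export
flagDivergentHaplotypes <- function(hapset, groups = NULL, min_steps = 10) {
  stopifnot(is(hapset, "HaplotypeSet"))
  gc <- hapset@groupCounts
  keep <- if (is.null(groups)) seq_len(nrow(gc)) else {
    bad <- setdiff(groups, colnames(gc))
    if (length(bad)) stop(sprintf("unknown group '%s'", bad[1L]))
    which(rowSums(gc[, groups, drop = FALSE]) > 0L)
  }
  if (length(keep) < 2L)
    stop("comparison set must contain at least 2 haplotypes")
  seqs <- hapset@haplotypes[keep]
  m <- do.call(rbind, strsplit(seqs, ""))
  d <- .hammingMatrix(m)
  diag(d) <- Inf
  mind <- apply(d, 1L, min)
  names(seqs)[mind >= min_steps]
}

.hammingMatrix <- function(chm) {
  n <- nrow(chm)
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- sum(chm[i, ] != chm[j, ])
  d
}

#' Write haplotype representatives as FASTA
#'
#' @param hapset A [HaplotypeSet-class].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
writeHaplotypeFasta <- function(hapset, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(hapset@haplotypes), path)
  invisible(path)
}

#' Write a per-column site-classification report
#'
#' Tab-separated with 1-based column coordinates and the category of each
#' column.
#'
#' @param sites A [SiteClasses-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSiteReport <- function(sites, path) {
  df <- data.frame(column = seq_along(sites@category),
                   usable = sites@usable,
                   category = as.character(sites@category))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
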