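#' Dominance filter: abundant in one sample, prevalent in one group
#'
#' Retains OTUs that (a) exceed `rel_thresh` of the reads in at least
#' one sample (strict inequality, relative to the full-table sample
#' depth) and (b) are present (count >= 1) in at least
#' `ceiling(prevalence * n_k)` replicates of at least one treatment
#' group. Counts and samples pass through unchanged; the filter is
#' idempotent.
#'
#' @param counts Count matrix (OTUs x samples).
#' @param design Design covering every sample in `counts`.
#' @param rel_thresh Relative-abundance threshold (default 0.005, half
#'   a percent of a sample's reads).
#' @param prevalence Required fraction of a group's replicates
#'   (default 0.6).
#' @return The count matrix restricted to retained OTUs.
#' @export
filter_dominant <- function(counts, design, rel_thresh = 0.005,
                            prevalence = 0.6) {
  validate_count_table(counts)
  missing <- setdiff(colnames(counts), design$sample)
  if (length(missing)) {
    stop("design lacks sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  grp <- paste(design$step, design$group)
  if (any(table(grp) < 1L)) stop("group with zero replicates", call. = FALSE)

  depth <- colSums(counts)
  rel <- sweep(counts, 2, pmax(depth, 1), "/")
  abundant <- apply(rel > rel_thresh, 1, any)

  present <- counts >= 1L
  prevalent <- rep(FALSE, nrow(counts))
  for (g in unique(grp)) {
    idx <- grp == g
    need <- ceiling(prevalence * sum(idx))
    prevalent <- prevalent | rowSums(present[, idx, drop = FALSE]) >= need
  }
  counts[abundant & prevalent, , drop = FALSE]
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly
#' `depth` (a single draw per sample with a recorded seed). Samples
#' whose depth is below the target are dropped with a warning.
#'
#' @param counts Count matrix (OTUs x samples).
#' @param depth Target depth (>= 1).
#' @param seed Integer seed.
#' @return Rarefied count matrix; every remaining column sums to
#'   `depth`.
#' @export
rarefy_counts <- function(counts, depth, seed) {
  validate_count_table(counts)
  stopifnot(depth >= 1)
  depths <- colSums(counts)
  keep <- depths >= depth
  if (!any(keep)) stop("all samples are below the rarefaction depth",
                       call. = FALSE)
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(colnames(counts)[!keep], collapse = ", "))
  }
  kept <- counts[, keep, drop = FALSE]
  set.seed(as.integer(seed))
  out <- t(suppressWarnings(vegan::rrarefy(t(kept), depth)))
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(kept)
  out
}
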