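# Community-level diversity, phylogenetic distance and recovery calls.

#' Per-sample alpha diversity
#'
#' `observed` counts OTUs with at least one read; `shannon` is
#' \eqn{-\sum p \ln p} (natural log); `inv_simpson` is
#' \eqn{1 / \sum p^2}. A warning is issued when sample depths are
#' unequal, since these metrics are conventionally compared on
#' rarefied tables.
#'
#' @param counts Count matrix (OTUs x samples).
#' @param metric One of `"observed"`, `"shannon"`, `"inv_simpson"`.
#' @return Named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(counts,
                            metric = c("observed", "shannon",
                                       "inv_simpson")) {
  metric <- match.arg(metric)
  validate_count_table(counts)
  depths <- colSums(counts)
  if (any(depths == 0)) {
    stop("empty sample(s): ",
         paste(colnames(counts)[depths == 0], collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(depths)) > 1L) {
    warning("sample depths are unequal; consider rarefying first")
  }
  switch(metric,
         observed = colSums(counts >= 1L),
         shannon = vegan::diversity(t(counts), index = "shannon"),
         inv_simpson = vegan::diversity(t(counts), index = "invsimpson"))
}

check_tree_coverage <- function(counts, tree) {
  missing <- setdiff(rownames(counts), tree$tip.label)
  if (length(missing)) {
    stop("tree lacks OTU(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}

#' Faith's phylogenetic diversity per sample
#'
#' Sum of branch lengths of the minimal subtree spanning the root and
#' the OTUs present in the sample.
#'
#' @param counts Count matrix (OTUs x samples).
#' @param tree Rooted tree covering all OTUs.
#' @return Named numeric vector of PD values.
#' @export
faith_pd <- function(counts, tree) {
  validate_count_table(counts)
  check_tree_coverage(counts, tree)
  if (!ape::is.rooted(tree)) {
    # a basal polytomy is conceptually rooted at the polytomy; resolve
    # it with zero-length branches, which leaves PD unchanged
    tree <- ape::multi2di(tree, random = FALSE)
  }
  pd <- picante::pd(t(counts), tree, include.root = TRUE)
  stats::setNames(pd$PD, rownames(pd))
}

#' Weighted UniFrac distances and similarities
#'
#' Normalized weighted UniFrac: branch lengths weight the absolute
#' difference in the relative abundance subtended by each branch,
#' divided by the maximum attainable weighted difference, so distances
#' lie in \[0, 1\]; similarity is one minus distance.
#'
#' @param counts Count matrix (OTUs x samples).
#' @param tree Rooted tree covering all OTUs.
#' @return List with `distance` and `similarity` matrices.
#' @export
weighted_unifrac <- function(counts, tree) {
  validate_count_table(counts)
  check_tree_coverage(counts, tree)
  if (any(colSums(counts) == 0)) {
    stop("zero-total sample(s) have no relative abundances",
         call. = FALSE)
  }
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(counts, taxa_are_rows = TRUE),
    phyloseq::phy_tree(tree))
  d <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  d <- d[colnames(counts), colnames(counts)]
  list(distance = d, similarity = 1 - d)
}

# among/within decomposition of squared distances -> pseudo-F
pseudo_f <- function(d2, groups) {
  n <- nrow(d2)
  a <- length(unique(groups))
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ssa <- sst - ssw
  (ssa / (a - 1)) / (ssw / (n - a))
}

#' Permutational multivariate analysis of variance on a distance matrix
#'
#' Pseudo-F from the among/within decomposition of squared distances;
#' the p-value comes from label permutations with a fixed seed:
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`. With
#' `exhaustive = TRUE` every distinct permutation is enumerated and the
#' exact tail `#\{F >= F_obs\} / n!` (the identity included) is
#' returned instead.
#'
#' @param dist Square symmetric distance matrix with zero diagonal (or
#'   a [stats::dist]).
#' @param groups Group labels, one per row.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @param exhaustive Enumerate all permutations (only feasible for
#'   small n).
#' @return List with `f`, `p`, `n_perm`.
#' @export
permanova <- function(dist, groups, n_perm = 999L, seed = 1L,
                      exhaustive = FALSE) {
  d <- as.matrix(dist)
  if (!isSymmetric(unname(d)) || any(abs(diag(d)) > 1e-12)) {
    stop("need a square symmetric distance matrix with zero diagonal",
         call. = FALSE)
  }
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(d))
  if (any(table(groups) < 2L)) {
    stop("every group needs at least 2 members", call. = FALSE)
  }
  d2 <- d^2
  f_obs <- pseudo_f(d2, groups)
  n <- nrow(d)
  if (exhaustive) {
    perms <- all_permutations(n)
    f_perm <- apply(perms, 1, function(p) pseudo_f(d2, groups[p]))
    p_val <- sum(f_perm >= f_obs - 1e-12) / nrow(perms)
    n_used <- nrow(perms)
  } else {
    f_perm <- with_local_seed(seed, vapply(seq_len(n_perm), function(i)
      pseudo_f(d2, groups[sample.int(n)]), numeric(1)))
    p_val <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  list(f = f_obs, p = p_val, n_perm = n_used)
}

all_permutations <- function(n) {
  if (n > 8L) stop("exhaustive enumeration limited to n <= 8",
                   call. = FALSE)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Pairwise PERMANOVA with Benjamini-Hochberg correction
#'
#' One PERMANOVA per pair of groups on the corresponding submatrix;
#' p-values are BH-corrected across pairs.
#'
#' @inheritParams permanova
#' @return Data frame: `group_a`, `group_b`, `f`, `p_raw`, `p_adj`.
#' @export
pairwise_permanova <- function(dist, groups, n_perm = 999L, seed = 1L) {
  d <- as.matrix(dist)
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  cmb <- utils::combn(lev, 2L)
  out <- data.frame(group_a = cmb[1L, ], group_b = cmb[2L, ],
                    f = NA_real_, p_raw = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(cmb))) {
    idx <- groups %in% cmb[, i]
    res <- permanova(d[idx, idx], groups[idx], n_perm = n_perm,
                     seed = seed + i)
    out$f[i] <- res$f
    out$p_raw[i] <- res$p
  }
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  out
}

#' Community-level recovery call per coalescence treatment
#'
#' From the pairwise comparisons of each coalescence community with the
#' Step-2 control (C+C) and with its self-mixed source (R+R), at
#' BH-corrected p <= `alpha`:
#' * `full` - not distinguishable from the control;
#' * `partial` - distinguishable from both control and source;
#' * `none` - distinguishable from the control only.
#'
#' @param pairwise Data frame from [pairwise_permanova()] over Step-2
#'   groups.
#' @param design The experimental design.
#' @param alpha Significance level on `p_adj` (default 0.05).
#' @return Data frame: `treatment`, `vs_control_sig`, `vs_self_sig`,
#'   `recovery`.
#' @export
community_recovery <- function(pairwise, design, alpha = 0.05) {
  groups2 <- unique(design$group[design$step == 2L])
  coal <- sort(groups2[is_coalescence(groups2)])
  find_pair <- function(a, b) {
    hit <- (pairwise$group_a == a & pairwise$group_b == b) |
      (pairwise$group_a == b & pairwise$group_b == a)
    if (!any(hit)) stop("missing pairwise test ", a, " vs ", b,
                        call. = FALSE)
    pairwise$p_adj[which(hit)[1L]]
  }
  out <- list()
  for (g in coal) {
    r <- group_parts(g)[[1L]][1L]
    self <- paste0(r, "+", r)
    sig_ctrl <- find_pair(g, "C+C") <= alpha
    sig_self <- find_pair(g, self) <= alpha
    recovery <- if (!sig_ctrl) "full"
                else if (sig_self) "partial"
                else "none"
    out[[length(out) + 1L]] <- data.frame(
      treatment = r, vs_control_sig = sig_ctrl, vs_self_sig = sig_self,
      recovery = recovery, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
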