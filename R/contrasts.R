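# Estimated marginal means, single-step (Tukey-style) adjusted pairwise
# comparisons, the four selected contrast families, and the
# zero-abundance likelihood-ratio fallback.

#' Estimated marginal means of a fitted model
#'
#' Per-level linear predictors at a common reference offset of zero
#' (i.e. log expected relative abundance), with the fixed-effect
#' covariance propagated through the level map.
#'
#' @param fit A converged [fit_step1()] / [fit_step2()] object.
#' @return List with `means` (named by level), `vcov` (levels x
#'   levels) and `levels`.
#' @export
estimated_means <- function(fit) {
  if (!isTRUE(fit$converged)) {
    stop("refusing to compute marginal means from a non-converged fit",
         call. = FALSE)
  }
  lev <- fit$levels
  p <- length(fit$estimates)
  L <- matrix(0, length(lev), p, dimnames = list(lev, names(fit$estimates)))
  L[, "mu"] <- 1
  for (l in lev[-1L]) L[l, paste0("effect_", l)] <- 1
  means <- drop(L %*% fit$estimates)
  V <- L %*% fit$vcov %*% t(L)
  list(means = means, vcov = (V + t(V)) / 2, levels = lev)
}

# restore the caller's RNG state after locally seeded draws
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' All pairwise comparisons with single-step familywise adjustment
#'
#' Wald z statistics for every pair of levels; the adjusted p-value of
#' a contrast is the probability that the maximum absolute standardized
#' contrast over the whole family exceeds the observed one, under the
#' joint normal law implied by the estimated covariance. The joint tail
#' is evaluated by Monte-Carlo integration with a fixed seed so results
#' are reproducible bit for bit; when the observed statistic is beyond
#' Monte-Carlo resolution the Bonferroni bound (an upper bound on the
#' single-step p) is substituted. An asymptotic z (not t) reference is
#' used, as appropriate for a Poisson mixed model without a residual
#' degrees-of-freedom notion.
#'
#' @param means Result of [estimated_means()].
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @param pairs Optional data frame (`level_a`, `level_b`) restricting
#'   the family to a subset of comparisons (adjustment is then computed
#'   over that subset only).
#' @param nsim Monte-Carlo draws for the joint tail (default 2e4).
#' @param seed Fixed seed for the draws (default 20230304).
#' @return A contrast table: `level_a`, `level_b`, `estimate` (a minus
#'   b on the log scale), `se`, `statistic`, `p_raw`, `p_adj`,
#'   `method`, `direction`.
#' @export
tukey_pairwise <- function(means, alpha = 0.05, pairs = NULL, nsim = 2e4,
                           seed = 20230304) {
  lev <- means$levels
  if (length(lev) < 2L) stop("need at least 2 levels", call. = FALSE)
  V <- means$vcov
  if (anyNA(V) || any(!is.finite(V))) {
    stop("singular covariance of the marginal means", call. = FALSE)
  }
  if (is.null(pairs)) {
    cmb <- utils::combn(lev, 2L)
    pairs <- data.frame(level_a = cmb[1L, ], level_b = cmb[2L, ],
                        stringsAsFactors = FALSE)
  }
  n_pair <- nrow(pairs)
  Cm <- matrix(0, n_pair, length(lev), dimnames = list(NULL, lev))
  for (i in seq_len(n_pair)) {
    Cm[i, pairs$level_a[i]] <- 1
    Cm[i, pairs$level_b[i]] <- -1
  }
  est <- drop(Cm %*% means$means)
  se <- sqrt(pmax(rowSums((Cm %*% V) * Cm), 0))
  if (any(se == 0 & est != 0)) {
    stop("singular covariance: zero-variance contrast with nonzero estimate",
         call. = FALSE)
  }
  z <- ifelse(se > 0, est / se, 0)
  p_raw <- 2 * stats::pnorm(-abs(z))

  if (n_pair == 1L) {
    p_adj <- p_raw
  } else {
    eg <- eigen(V, symmetric = TRUE)
    pos <- pmax(eg$values, 0)
    A <- eg$vectors %*% diag(sqrt(pos), length(pos))
    maxabs <- with_local_seed(seed, {
      E <- matrix(stats::rnorm(length(lev) * nsim), length(lev), nsim)
      D <- (Cm %*% A) %*% E
      D <- abs(D / ifelse(se > 0, se, 1))
      apply(D, 2, max)
    })
    count <- vapply(abs(z), function(zz) sum(maxabs >= zz), numeric(1))
    p_adj <- ifelse(count > 0, pmax(p_raw, count / nsim),
                    pmin(1, n_pair * p_raw))
  }
  direction <- ifelse(p_adj > alpha, "=", ifelse(est > 0, ">", "<"))
  data.frame(level_a = pairs$level_a, level_b = pairs$level_b,
             estimate = est, se = se, statistic = z, p_raw = p_raw,
             p_adj = p_adj, method = "wald_tukey", direction = direction,
             stringsAsFactors = FALSE)
}

lrt_trigger <- function(y_a, y_b) {
  (all(y_a == 0) && stats::median(y_b) >= 5) ||
    (all(y_b == 0) && stats::median(y_a) >= 5)
}

#' Zero-abundance likelihood-ratio fallback for one pair of groups
#'
#' The Wald contrast is undefined in practice when an OTU is entirely
#' absent from one group; when additionally the other group's median
#' count is at least 5, a 1-df likelihood-ratio test of equal versus
#' group-specific rates replaces it. The mixed (Poisson-lognormal)
#' likelihood is used by default; `likelihood = "poisson"` gives the
#' plain-Poisson variant with closed-form rate estimates.
#'
#' @param y_a,y_b Counts in the two groups.
#' @param offsets_a,offsets_b Matching log read sums.
#' @param level_a,level_b Group labels for the output row.
#' @param alpha Significance level.
#' @param likelihood `"mixed"` (default) or `"poisson"`.
#' @param nodes Quadrature nodes for the mixed likelihood.
#' @return A one-row contrast table with `method = "lrt"` and the
#'   direction pointing toward the nonzero group.
#' @export
zero_case_lrt <- function(y_a, y_b, offsets_a, offsets_b,
                          level_a = "a", level_b = "b", alpha = 0.05,
                          likelihood = c("mixed", "poisson"), nodes = 25L) {
  likelihood <- match.arg(likelihood)
  if (!lrt_trigger(y_a, y_b)) {
    stop(structure(class = c("microcoalesce_lrt_refused", "error",
                             "condition"),
                   list(message = paste("zero-abundance trigger not met:",
                                        "need one all-zero group and the",
                                        "other with median >= 5"),
                        call = NULL)))
  }
  y <- c(y_a, y_b)
  off <- c(offsets_a, offsets_b)
  g <- rep(c(0, 1), c(length(y_a), length(y_b)))
  X0 <- matrix(1, length(y), 1L, dimnames = list(NULL, "mu"))
  X1 <- cbind(X0, effect = g)
  if (likelihood == "mixed") {
    ll0 <- agq_optimize(y, off, X0, nodes)
    ll1 <- agq_optimize(y, off, X1, nodes)
    stat <- max(0, 2 * (ll1$loglik - ll0$loglik))
    estimate <- ll1$coef[2L]
  } else {
    rate0 <- sum(y) / sum(exp(off))
    ll0 <- sum(stats::dpois(y, rate0 * exp(off), log = TRUE))
    ra <- sum(y_a) / sum(exp(offsets_a))
    rb <- sum(y_b) / sum(exp(offsets_b))
    ll1 <- sum(stats::dpois(y_a, ra * exp(offsets_a), log = TRUE)) +
      sum(stats::dpois(y_b, rb * exp(offsets_b), log = TRUE))
    stat <- max(0, 2 * (ll1 - ll0))
    estimate <- if (all(y_a == 0)) -Inf else Inf
  }
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  dir_sig <- if (all(y_a == 0)) "<" else ">"
  data.frame(level_a = level_a, level_b = level_b,
             estimate = as.numeric(estimate), se = NA_real_,
             statistic = stat, p_raw = p, p_adj = p, method = "lrt",
             direction = if (p <= alpha) dir_sig else "=",
             stringsAsFactors = FALSE)
}

# The four selected contrast families. Given the design, returns for one
# model the (family, level_a, level_b) rows to retain.
family_pairs <- function(design, step) {
  if (step == 1L) {
    removals <- sort(setdiff(unique(design$group[design$step == 1L]), "C"))
    return(data.frame(family = "R_vs_C", level_a = removals, level_b = "C",
                      stringsAsFactors = FALSE))
  }
  groups <- unique(design$group[design$step == 2L])
  coal <- sort(groups[is_coalescence(groups)])
  out <- list()
  for (g in coal) {
    r <- group_parts(g)[[1L]][1L]
    self <- paste0(r, "+", r)
    if (!self %in% groups) {
      stop("missing matching self-mix '", self, "' for coalescence group '",
           g, "'", call. = FALSE)
    }
    out[[length(out) + 1L]] <- data.frame(
      family = c("RR_vs_CC", "RC_vs_RR", "RC_vs_CC"),
      level_a = c(self, g, g),
      level_b = c("C+C", self, "C+C"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Select the four analysis contrast families from a full pairwise table
#'
#' Retains exactly (i) each removal treatment vs the Step-1 control,
#' (ii) each self-mixed removal treatment vs the Step-2 control, (iii)
#' each coalescence treatment vs its matching self-mix, and (iv) each
#' coalescence treatment vs the Step-2 control. Rows are re-oriented so
#' `level_a` is the family's first element (estimate and statistic flip
#' sign, p-values are untouched: selection does not re-adjust).
#'
#' @param contrasts Full pairwise contrast table (from
#'   [tukey_pairwise()], optionally with an `otu_id` column).
#' @param design The experimental design.
#' @param step 1 or 2: which model the table came from.
#' @return The retained rows with a `family` column.
#' @export
select_families <- function(contrasts, design, step) {
  fam <- family_pairs(design, step)
  key_fwd <- paste(contrasts$level_a, contrasts$level_b)
  key_rev <- paste(contrasts$level_b, contrasts$level_a)
  out <- list()
  for (i in seq_len(nrow(fam))) {
    want <- paste(fam$level_a[i], fam$level_b[i])
    hit <- key_fwd == want
    flip <- key_rev == want
    rows <- contrasts[hit | flip, , drop = FALSE]
    if (!nrow(rows)) next
    fl <- flip[hit | flip]
    rows$level_a <- fam$level_a[i]
    rows$level_b <- fam$level_b[i]
    rows$estimate[fl] <- -rows$estimate[fl]
    rows$statistic[fl] <- -rows$statistic[fl]
    rows$direction[fl] <- chartr("<>", "><", rows$direction[fl])
    rows$family <- fam$family[i]
    out[[length(out) + 1L]] <- rows
  }
  res <- do.call(rbind, out)
  front <- intersect(c("otu_id", "family"), names(res))
  res <- res[, c(front, setdiff(names(res), front)), drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-OTU model fits and selected contrasts for one experiment step
#'
#' Fits the step's Poisson mixed model OTU by OTU on filtered,
#' unrarefied counts with log read-sum offsets, forms all pairwise
#' comparisons with single-step adjustment, retains the four analysis
#' families, and substitutes the zero-abundance likelihood-ratio test
#' where its trigger holds. Fit failures never abort the run; affected
#' OTUs are reported with degenerate rows (`method = "none"`).
#'
#' @param counts Filtered count matrix (all steps' samples).
#' @param design The experimental design.
#' @param step 1 or 2.
#' @param depths Full-table read depths for the offsets; defaults to
#'   the column sums of `counts` (pass the pre-filter depths to mirror
#'   the offset definition on quality-controlled totals).
#' @param alpha Significance level (default 0.05).
#' @param scope `"all-pairs"` adjusts over every pairwise comparison of
#'   the fitted factor before selection (default); `"selected"` adjusts
#'   only within the retained families.
#' @param nsim,seed Monte-Carlo settings for the adjustment.
#' @param nodes Quadrature nodes.
#' @return Contrast table with `otu_id` and `family` columns.
#' @export
run_contrasts <- function(counts, design, step, depths = NULL,
                          alpha = 0.05, scope = c("all-pairs", "selected"),
                          nsim = 2e4, seed = 20230304, nodes = 25L) {
  scope <- match.arg(scope)
  validate_count_table(counts)
  if (is.null(depths)) depths <- colSums(counts)
  idx <- design$step == step
  samples <- intersect(design$sample[idx], colnames(counts))
  if (!length(samples)) stop("no samples for step ", step, call. = FALSE)
  sub <- counts[, samples, drop = FALSE]
  des <- design[match(samples, design$sample), , drop = FALSE]
  groups <- des$group
  offsets <- log(pmax(depths[samples], 1))
  fam <- family_pairs(design, step)
  K <- if (step == 2L) kinship_matrix(design) else NULL
  sel_pairs <- if (scope == "selected") {
    fam[, c("level_a", "level_b")]
  } else NULL

  out <- list()
  for (otu in rownames(sub)) {
    y <- sub[otu, ]
    tab <- tryCatch({
      fit <- if (step == 1L) {
        fit_step1(y, offsets, groups, nodes = nodes)
      } else {
        fit_step2(y, offsets, groups, kinship = K, nodes = nodes)
      }
      full <- tukey_pairwise(estimated_means(fit), alpha = alpha,
                             pairs = sel_pairs, nsim = nsim, seed = seed)
      select_families(full, design, step)
    }, error = function(e) degenerate_rows(fam, alpha))
    # zero-abundance fallback, per retained pair
    for (i in seq_len(nrow(tab))) {
      ya <- y[groups == tab$level_a[i]]
      yb <- y[groups == tab$level_b[i]]
      if (lrt_trigger(ya, yb)) {
        row <- zero_case_lrt(ya, yb, offsets[groups == tab$level_a[i]],
                             offsets[groups == tab$level_b[i]],
                             level_a = tab$level_a[i],
                             level_b = tab$level_b[i], alpha = alpha,
                             nodes = nodes)
        tab[i, names(row)] <- row
      }
    }
    tab$otu_id <- otu
    out[[otu]] <- tab[, c("otu_id", setdiff(names(tab), "otu_id"))]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

degenerate_rows <- function(fam, alpha) {
  data.frame(family = fam$family, level_a = fam$level_a,
             level_b = fam$level_b, estimate = NA_real_, se = NA_real_,
             statistic = NA_real_, p_raw = 1, p_adj = 1, method = "none",
             direction = "=", stringsAsFactors = FALSE)
}
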