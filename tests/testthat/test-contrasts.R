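fake_fit <- function(estimates, vcov = NULL) {
  lev <- c("C", sub("^effect_", "", names(estimates)[-1]))
  if (is.null(vcov)) vcov <- diag(0.01, length(estimates))
  dimnames(vcov) <- list(names(estimates), names(estimates))
  structure(list(model = "step1", estimates = estimates, levels = lev,
                 reference = "C", sigma2 = 0.1, sigma2_C = NA,
                 loglik = -10, vcov = vcov, converged = TRUE,
                 n_quad = 25L), class = "glmm_fit")
}

test_that("marginal means map effects onto levels with their covariance", {
  est <- c(mu = -3, effect_Ram = 1)
  V <- matrix(c(0.04, -0.01, -0.01, 0.09), 2, 2)
  fit <- fake_fit(est, V)
  em <- estimated_means(fit)
  expect_equal(unname(em$means), c(-3, -2))
  # covariance of the difference equals v' V v for the contrast vector
  v <- c(0, 1)  # (mu + effect) - mu
  expect_equal(em$vcov["Ram", "Ram"] + em$vcov["C", "C"] -
                 2 * em$vcov["Ram", "C"],
               drop(t(v) %*% V %*% v))
  fit$converged <- FALSE
  expect_error(estimated_means(fit), "non-converged")
})

test_that("marginal means are invariant to the reference level", {
  set.seed(19)
  g <- rep(c("C", "Cip", "Ram"), each = 8)
  off <- rep(log(4000), length(g))
  y <- rpois(length(g), exp(off + log(0.01) + (g == "Cip") * 0.7 +
                              rnorm(length(g), 0, 0.3)))
  m1 <- estimated_means(fit_step1(y, off, g, reference = "C"))
  m2 <- estimated_means(fit_step1(y, off, g, reference = "Ram"))
  expect_equal(m1$means[sort(m1$levels)], m2$means[sort(m2$levels)],
               tolerance = 1e-4)
})

test_that("identical groups yield a null contrast; single pairs skip the
           multiplicity adjustment", {
  em <- list(means = c(C = -2, A = -2), vcov = diag(0.02, 2),
             levels = c("C", "A"))
  dimnames(em$vcov) <- list(c("C", "A"), c("C", "A"))
  tab <- tukey_pairwise(em)
  expect_equal(tab$estimate, 0)
  expect_equal(tab$direction, "=")
  expect_equal(tab$p_adj, tab$p_raw)  # one pair: no multiplicity

  em3 <- list(means = c(C = -2, A = -1.5, B = -2.2),
              vcov = diag(0.02, 3), levels = c("C", "A", "B"))
  dimnames(em3$vcov) <- list(em3$levels, em3$levels)
  tab3 <- tukey_pairwise(em3)
  expect_equal(nrow(tab3), 3)
  expect_true(all(tab3$p_adj >= tab3$p_raw))
  # antisymmetry of the estimate under pair reversal is built into
  # orientation: check sign consistency
  expect_equal(tab3$estimate[tab3$level_a == "C" & tab3$level_b == "A"],
               -0.5)
})

test_that("single-step adjusted p matches a large-sample max-|Z| null", {
  # three balanced independent groups: exchangeable pairwise contrasts
  v <- 0.05
  em <- list(means = c(C = 0, A = 0.35, B = 0.1), vcov = diag(v, 3),
             levels = c("C", "A", "B"))
  dimnames(em$vcov) <- list(em$levels, em$levels)
  tab <- tukey_pairwise(em, nsim = 1e6)

  # independent oracle: simulate the joint null of all three contrasts
  set.seed(2024)
  n_oracle <- 1e6
  M <- matrix(rnorm(3 * n_oracle, 0, sqrt(v)), ncol = 3)
  zmax <- apply(abs(cbind(M[, 1] - M[, 2], M[, 1] - M[, 3],
                          M[, 2] - M[, 3]) / sqrt(2 * v)), 1, max)
  for (i in seq_len(nrow(tab))) {
    p_oracle <- mean(zmax >= abs(tab$statistic[i]))
    expect_lt(abs(tab$p_adj[i] - p_oracle), 0.002)
  }
})

test_that("the zero-abundance LRT fires only on its trigger", {
  off <- rep(log(1000), 4)
  expect_error(zero_case_lrt(rep(0L, 4), rep(0L, 4), off, off),
               class = "microcoalesce_lrt_refused")
  # median 4 in the nonzero group is below the threshold
  expect_error(zero_case_lrt(rep(0L, 4), c(3L, 4L, 4L, 5L), off, off),
               class = "microcoalesce_lrt_refused")
  # median exactly 5 triggers
  row <- zero_case_lrt(rep(0L, 4), c(4L, 5L, 5L, 6L), off, off)
  expect_equal(row$method, "lrt")
  expect_equal(row$direction, "<")
})

test_that("plain-Poisson LRT equals the closed-form two-rate fit", {
  y_a <- rep(0L, 4)
  y_b <- c(6L, 7L, 8L, 9L)
  off <- rep(log(1000), 4)
  row <- zero_case_lrt(y_a, y_b, off, off, likelihood = "poisson")

  # closed-form: one common rate vs group-specific rates
  y <- c(y_a, y_b)
  rate1 <- sum(y) / (8 * 1000)
  ll1 <- sum(dpois(y, rate1 * 1000, log = TRUE))
  rate_b <- sum(y_b) / (4 * 1000)
  ll2 <- sum(dpois(y_a, 0, log = TRUE)) +
    sum(dpois(y_b, rate_b * 1000, log = TRUE))
  expect_equal(row$statistic, 2 * (ll2 - ll1), tolerance = 1e-8)
  expect_equal(row$p_raw, pchisq(2 * (ll2 - ll1), 1, lower.tail = FALSE))
  expect_equal(row$direction, "<")
  expect_equal(row$p_adj, row$p_raw)

  # the mixed-likelihood variant agrees on direction and significance
  row_m <- zero_case_lrt(y_a, y_b, off, off, likelihood = "mixed")
  expect_equal(row_m$direction, "<")
  expect_lt(row_m$p_raw, 0.05)
})

test_that("family selection keeps 30 oriented rows per OTU and never
           re-adjusts", {
  design <- build_design(n_removal = 18, n_step2 = 10, replicates = 2)
  groups2 <- unique(design$group[design$step == 2])
  expect_length(groups2, 21)
  cmb <- combn(sort(groups2), 2)
  set.seed(5)
  full <- data.frame(otu_id = "OTU1", level_a = cmb[1, ],
                     level_b = cmb[2, ], estimate = rnorm(ncol(cmb)),
                     se = 0.3, statistic = rnorm(ncol(cmb)),
                     p_raw = runif(ncol(cmb)), p_adj = runif(ncol(cmb)),
                     method = "wald_tukey", direction = "=",
                     stringsAsFactors = FALSE)
  full$p_adj <- pmax(full$p_adj, full$p_raw)
  expect_equal(nrow(full), 210)  # all pairwise contrasts of 21 levels

  sel <- select_families(full, design, step = 2)
  expect_equal(nrow(sel), 30)
  expect_equal(as.vector(table(sel$family)[c("RC_vs_CC", "RC_vs_RR",
                                             "RR_vs_CC")]), rep(10L, 3))
  # no cross-removal self-mix pairs survive
  expect_false(any(microcoalesce:::is_self_mix(sel$level_a) &
                     microcoalesce:::is_self_mix(sel$level_b) &
                     sel$level_a != "C+C" & sel$level_b != "C+C"))
  # p values are untouched by selection, estimates only re-oriented
  for (i in seq_len(nrow(sel))) {
    orig <- full[(full$level_a == sel$level_a[i] &
                    full$level_b == sel$level_b[i]) |
                   (full$level_a == sel$level_b[i] &
                      full$level_b == sel$level_a[i]), ]
    expect_equal(sel$p_adj[i], orig$p_adj)
    expect_equal(abs(sel$estimate[i]), abs(orig$estimate))
  }

  # a design lacking the matching self-mix is an error
  broken <- design[!(design$group == "Cip+Cip"), ]
  expect_error(select_families(full, broken, step = 2),
               "missing matching self-mix 'Cip\\+Cip'")
})

test_that("run_contrasts substitutes the LRT exactly where the trigger
           holds", {
  design <- build_design(n_removal = 2, n_step2 = 1, replicates = 6)
  s1 <- design[design$step == 1, ]
  set.seed(10)
  counts <- matrix(rpois(3 * nrow(design), 40), 3, nrow(design),
                   dimnames = list(c("OTUa", "OTUb", "OTUc"),
                                   design$sample))
  # OTUb: absent under Cip, abundant elsewhere
  counts["OTUb", s1$sample[s1$group == "Cip"]] <- 0L
  depths <- pmax(colSums(counts), 1000)
  tab <- run_contrasts(counts, design, step = 1, depths = depths,
                       nsim = 5000)
  expect_true(all(tab$family == "R_vs_C"))
  expect_equal(nrow(tab), 3 * 2)

  # brute-force scan of the trigger rule over OTU x retained pair
  for (i in seq_len(nrow(tab))) {
    ya <- counts[tab$otu_id[i], s1$sample[s1$group == tab$level_a[i]]]
    yb <- counts[tab$otu_id[i], s1$sample[s1$group == tab$level_b[i]]]
    should_lrt <- (all(ya == 0) && median(yb) >= 5) ||
      (all(yb == 0) && median(ya) >= 5)
    expect_equal(tab$method[i] == "lrt", should_lrt)
  }
  expect_equal(tab$method[tab$otu_id == "OTUb" & tab$level_a == "Cip"],
               "lrt")
  expect_equal(tab$direction[tab$otu_id == "OTUb" & tab$level_a == "Cip"],
               "<")
})
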