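test_that("a constant dataset pins the intercept and kills the variance", {
  y <- rep(10L, 8)
  off <- rep(log(1000), 8)
  g <- rep(c("C", "Ram"), each = 4)
  fit <- fit_step1(y, off, g)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["mu"]), log(0.01), tolerance = 1e-6)
  expect_equal(unname(fit$estimates["effect_Ram"]), 0, tolerance = 1e-6)
  expect_lt(fit$sigma2, 1e-6)
})

test_that("all-zero OTUs are refused and routed to the zero case", {
  expect_error(fit_step1(rep(0L, 8), rep(0, 8), rep(c("a", "b"), 4)),
               class = "microcoalesce_all_zero")
})

test_that("fitted loglik matches dense-grid trapezoid integration", {
  y <- c(2L, 9L, 1L, 30L)
  off <- rep(log(100), 4)
  g <- c("a", "a", "b", "b")
  fit <- fit_step1(y, off, g, reference = "a")
  expect_true(fit$converged)
  expect_gt(fit$sigma2, 0)
  X <- cbind(mu = 1, effect_b = c(0, 0, 1, 1))
  oracle <- trapezoid_marginal_loglik(fit$estimates, fit$sigma2, y, off, X)
  expect_equal(fit$loglik, oracle, tolerance = 1e-6)

  # quadrature refinement: 25 vs 41 nodes agree far below tolerance
  par <- list(mu = fit$estimates[["mu"]],
              effects = c(b = fit$estimates[["effect_b"]]),
              sigma2 = fit$sigma2)
  l25 <- marginal_loglik(par, y, off, g, reference = "a", nodes = 25)
  l41 <- marginal_loglik(par, y, off, g, reference = "a", nodes = 41)
  expect_lt(abs(l25 - l41), 1e-6)
  expect_equal(fit$loglik, l25, tolerance = 1e-9)
})

test_that("marginal likelihood degenerates to plain Poisson at sigma2 = 0", {
  y <- c(3L, 5L, 2L, 8L)
  off <- rep(log(500), 4)
  g <- c("a", "a", "b", "b")
  par <- list(mu = -4, effects = c(b = 0.5), sigma2 = 0)
  eta <- off - 4 + c(0, 0, 0.5, 0.5)
  expect_identical(marginal_loglik(par, y, off, g, reference = "a"),
                   sum(dpois(y, exp(eta), log = TRUE)))
  expect_error(marginal_loglik(list(mu = -4, effects = NULL, sigma2 = -1),
                               y, off, g), "sigma2")
})

test_that("the optimum dominates the truth and nested models never lose", {
  set.seed(14)
  g <- rep(c("C", "Ram", "HS"), each = 200)
  off <- rep(log(16000), length(g))
  alpha <- c(C = 0, Ram = 1, HS = -1)
  eta <- off + log(0.005) + alpha[g] + rnorm(length(g), 0, sqrt(0.3))
  y <- rpois(length(g), exp(eta))
  fit <- fit_step1(y, off, g)
  expect_true(fit$converged)

  # parameter recovery at 200 replicates: within 3 SEs of the truth
  for (lev in c("Ram", "HS")) {
    est <- fit$estimates[[paste0("effect_", lev)]]
    se <- sqrt(fit$vcov[paste0("effect_", lev), paste0("effect_", lev)])
    expect_lt(abs(est - alpha[[lev]]), 3 * se)
  }
  expect_lt(abs(fit$sigma2 - 0.3), 0.1)

  # MLE dominates the generating parameters on the same data
  at_truth <- marginal_loglik(list(mu = log(0.005),
                                   effects = c(Ram = 1, HS = -1),
                                   sigma2 = 0.3), y, off, g)
  expect_gte(fit$loglik, at_truth)

  # likelihood ratio of nested models is non-negative
  null_fit <- microcoalesce:::agq_optimize(y, off,
                                           matrix(1, length(y), 1,
                                                  dimnames = list(NULL, "mu")))
  expect_gte(fit$loglik, null_fit$loglik)
})

test_that("offset equivariance: a constant shift moves only the intercept", {
  set.seed(3)
  g <- rep(c("C", "Cip"), each = 6)
  off <- log(rpois(12, 8000))
  y <- rpois(12, exp(off + log(0.01) + (g == "Cip") * 0.8))
  f1 <- fit_step1(y, off, g)
  f2 <- fit_step1(y, off + 2, g)
  expect_equal(f2$estimates[["mu"]], f1$estimates[["mu"]] - 2,
               tolerance = 1e-5)
  expect_equal(f2$estimates[["effect_Cip"]], f1$estimates[["effect_Cip"]],
               tolerance = 1e-5)
  expect_equal(f2$sigma2, f1$sigma2, tolerance = 1e-5)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-6)
})

test_that("equidispersed data reduce to the Poisson regression oracle", {
  set.seed(8)
  g <- rep(c("C", "Ram"), each = 10)
  off <- rep(log(2000), 20)
  # large means, simulated exactly Poisson; chosen seed gives an
  # underdispersed Pearson statistic so sigma2 sits at the boundary
  y <- rpois(20, exp(off + log(0.05) + (g == "Ram") * 0.3))
  stopifnot(sum((y - mean(y))^2) > 0)
  fit <- fit_step1(y, off, g)
  glm_fit <- glm(y ~ relevel(factor(g), "C") + offset(off),
                 family = poisson)
  if (fit$sigma2 == 0) {
    expect_equal(unname(fit$estimates), unname(coef(glm_fit)),
                 tolerance = 1e-6)
    expect_equal(fit$loglik, as.numeric(logLik(glm_fit)),
                 tolerance = 1e-6)
  } else {
    succeed("sigma2 did not hit the boundary for this draw")
  }
})

test_that("estimates agree with an independent mixed-model fitter", {
  skip_if_not_installed("lme4")
  set.seed(31)
  g <- rep(c("C", "Cip", "Ram", "HS"), each = 10)
  off <- log(rpois(40, 16000))
  alpha <- c(C = 0, Cip = 0.8, Ram = -0.6, HS = 0)
  y <- rpois(40, exp(off + log(0.004) + alpha[g] +
                       rnorm(40, 0, sqrt(0.25))))
  fit <- fit_step1(y, off, g)
  d <- data.frame(y = y, g = relevel(factor(g), "C"), off = off,
                  obs = factor(seq_along(y)))
  ref <- suppressMessages(lme4::glmer(y ~ g + (1 | obs), offset = off,
                                      data = d, family = poisson))
  expect_equal(unname(fit$estimates), unname(lme4::fixef(ref)),
               tolerance = 0.01)
  expect_equal(unname(fit$sigma2), unname(lme4::VarCorr(ref)$obs[1]),
               tolerance = 0.02)
  # adaptive quadrature can only improve on the Laplace loglik
  expect_gte(fit$loglik + 1e-6, as.numeric(stats::logLik(ref)))
})

test_that("step-2 fit with sigma2_C = 0 reduces exactly to step 1", {
  set.seed(12)
  design <- build_design(n_removal = 3, n_step2 = 2, replicates = 5)
  K <- kinship_matrix(design)
  s2 <- design[design$step == 2, ]
  off <- rep(log(8000), nrow(s2))
  y <- rpois(nrow(s2), exp(off + log(0.003) +
                             (s2$group == "Cip+Cip") * 0.8 +
                             rnorm(nrow(s2), 0, sqrt(0.2))))
  f0 <- fit_step2(y, off, s2$group, K, fix_sigma2C = 0)
  f1 <- fit_step1(y, off, s2$group, reference = "C+C")
  expect_equal(f0$estimates, f1$estimates, tolerance = 1e-8)
  expect_equal(f0$loglik, f1$loglik, tolerance = 1e-8)
  expect_identical(f0$sigma2_C, 0)
  expect_identical(f0$model, "step2")
})

test_that("kinship matrix encodes shared sources with unit diagonal", {
  design <- build_design(n_removal = 3, n_step2 = 2, replicates = 2)
  K <- kinship_matrix(design)
  expect_true(all(diag(K) == 1))
  expect_equal(K["Cip+Cip", "Cip+C"], 0.5)
  expect_equal(K["Cip+C", "C+C"], 0.5)
  expect_equal(K["Cip+Cip", "Ram+Ram"], 0)
  expect_equal(K["Cip+C", "Ram+C"], 0.25)
  expect_true(all(eigen(K, symmetric = TRUE, only.values = TRUE)$values >
                    1e-8))
})

test_that("Laplace loglik matches brute-force Monte-Carlo integration", {
  # tiny two-group fixture with K = I, evaluated at fixed parameters
  set.seed(4)
  y <- c(4L, 7L, 2L, 12L, 9L, 15L)
  off <- rep(log(100), 6)
  g <- rep(c("A", "B"), each = 3)
  K <- diag(2)
  dimnames(K) <- list(c("A", "B"), c("A", "B"))
  sigma2 <- 0.3
  sigma2C <- 0.4
  par <- list(mu = -2.5, effects = c(B = 0.5), sigma2 = sigma2,
              sigma2_C = sigma2C)
  lap <- marginal_loglik(par, y, off, g, model = "step2", reference = "A",
                         kinship = K)

  set.seed(99)
  n_mc <- 1e6
  eta0 <- off - 2.5 + (g == "B") * 0.5
  Cdr <- matrix(rnorm(2 * n_mc, 0, sqrt(sigma2C)), n_mc, 2)
  ll <- numeric(n_mc)
  Z <- matrix(rnorm(6 * n_mc, 0, sqrt(sigma2)), n_mc, 6)
  gi <- as.integer(factor(g, c("A", "B")))
  for (i in 1:6) {
    ll <- ll + dpois(y[i], exp(eta0[i] + Cdr[, gi[i]] + Z[, i]),
                     log = TRUE)
  }
  m <- max(ll)
  mc <- m + log(mean(exp(ll - m)))
  expect_lt(abs(lap - mc), 0.05)
})

test_that("sigma2_C estimates sit at the boundary when the truth is zero", {
  set.seed(55)
  design <- build_design(n_removal = 2, n_step2 = 2, replicates = 4)
  K <- kinship_matrix(design)
  s2 <- design[design$step == 2, ]
  off <- rep(log(5000), nrow(s2))
  hits <- 0L
  n_sim <- 100L
  for (i in seq_len(n_sim)) {
    y <- rpois(nrow(s2), exp(off + log(0.004) +
                               rnorm(nrow(s2), 0, sqrt(0.2))))
    fit <- suppressMessages(fit_step2(y, off, s2$group, K))
    if (fit$sigma2_C < 1e-3) hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.9)
})

test_that("doubling replication shrinks the error of effect estimates", {
  err_at <- function(n_rep, seed) {
    set.seed(seed)
    g <- rep(c("C", "Ram"), each = n_rep)
    off <- rep(log(16000), length(g))
    errs <- vapply(1:30, function(i) {
      y <- rpois(length(g), exp(off + log(0.005) + (g == "Ram") * 0.5 +
                                  rnorm(length(g), 0, sqrt(0.2))))
      fit <- fit_step1(y, off, g)
      abs(fit$estimates[["effect_Ram"]] - 0.5)
    }, numeric(1))
    median(errs)
  }
  expect_lt(err_at(20, 77), err_at(10, 77))
})
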