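# Per-OTU Poisson mixed models with read-sum offsets.
#
# Step 1: log(Lambda) = o + mu + alpha_g + Z,  Z ~ N(0, sigma2) per
# observation. The observation-level effect factorizes the marginal
# likelihood per observation; each one-dimensional integral is evaluated
# by adaptive Gauss-Hermite quadrature.
#
# Step 2: log(Lambda) = o + mu + beta_g + C_g + Z, with C ~ N(0,
# sigma2_C * K) over groups (K the mixing-fraction kinship) and Z as
# above; the joint random-effect vector no longer factorizes and is
# integrated by a Laplace approximation (mode by penalized Poisson
# regression, curvature from the negative Hessian).

SIGMA2_FLOOR <- 1e-8
BOUNDARY_TOL <- 1e-6

gh_rule <- function(nodes) statmod::gauss.quad(nodes, kind = "hermite")

row_log_sum_exp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# Adaptive GH evaluation of log integral_z Pois(y | exp(eta + z)) N(z; 0,
# sigma2) dz per observation, plus the posterior moments needed for the
# gradient of the marginal likelihood.
agq_observations <- function(y, eta, sigma2, gh, moments = FALSE) {
  if (sigma2 < SIGMA2_FLOOR) {
    ll <- stats::dpois(y, exp(eta), log = TRUE)
    if (!moments) return(list(loglik = ll))
    return(list(loglik = ll, e_lambda = exp(eta), e_z2 = rep(0, length(y))))
  }
  # mode of y*z - exp(eta+z) - z^2/(2 sigma2): damped Newton, concave in z
  m <- rep(0, length(y))
  f <- function(z) y * z - exp(eta + z) - z^2 / (2 * sigma2)
  fm <- f(m)
  for (it in 1:100) {
    g1 <- y - exp(eta + m) - m / sigma2
    g2 <- exp(eta + m) + 1 / sigma2
    step <- g1 / g2
    repeat {
      m_new <- m + step
      fm_new <- f(m_new)
      if (all(fm_new >= fm - 1e-12) || max(abs(step)) < 1e-14) break
      step <- step / 2
    }
    m <- m_new
    fm <- fm_new
    if (max(abs(g1 / g2)) < 1e-11) break
  }
  s <- 1 / sqrt(exp(eta + m) + 1 / sigma2)
  z <- outer(m, rep(1, length(gh$nodes))) +
    sqrt(2) * outer(s, gh$nodes)
  gmat <- y * (eta + z) - exp(eta + z) - lgamma(y + 1) -
    0.5 * log(2 * pi * sigma2) - z^2 / (2 * sigma2)
  lw <- sweep(gmat + outer(rep(1, length(y)), gh$nodes^2), 2,
              -log(gh$weights), "-")
  ll <- log(sqrt(2) * s) + row_log_sum_exp(lw)
  out <- list(loglik = ll)
  if (moments) {
    p <- exp(lw - row_log_sum_exp(lw))
    out$e_lambda <- rowSums(p * exp(eta + z))
    out$e_z2 <- rowSums(p * z^2)
  }
  out
}

make_model_matrix <- function(groups, reference) {
  g <- factor(groups)
  if (!reference %in% levels(g)) {
    stop("reference level '", reference, "' not among groups", call. = FALSE)
  }
  g <- stats::relevel(g, ref = reference)
  X <- stats::model.matrix(~g)
  colnames(X) <- c("mu", paste0("effect_", levels(g)[-1L]))
  list(X = X, levels = levels(g), factor = g)
}

default_reference <- function(groups) {
  lv <- unique(as.character(groups))
  if ("C" %in% lv) "C" else if ("C+C" %in% lv) "C+C" else sort(lv)[1L]
}

check_fit_inputs <- function(y, offsets, groups) {
  stopifnot(length(y) == length(offsets), length(y) == length(groups))
  if (all(y == 0)) {
    stop(structure(class = c("microcoalesce_all_zero", "error", "condition"),
                   list(message = "all-zero OTU: fit refused, use the zero-abundance likelihood-ratio path",
                        call = NULL)))
  }
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(tab < 2L)) stop("every group needs at least 2 replicates",
                          call. = FALSE)
  invisible(TRUE)
}

#' Fit the Step-1 Poisson mixed model for one OTU
#'
#' Maximizes the marginal likelihood of a Poisson model with a known
#' offset (log read sum), a treatment factor with the control as
#' reference level, and an observation-level Gaussian random effect
#' absorbing overdispersion. The per-observation integrals use adaptive
#' Gauss-Hermite quadrature; `sigma2` is optimized on the log scale with
#' boundary handling as it approaches zero.
#'
#' @param y Counts for one OTU.
#' @param offsets Per-sample log read sums.
#' @param groups Treatment labels.
#' @param reference Reference level (default "C" when present).
#' @param nodes Quadrature nodes (default 25).
#' @return A `glmm_fit` object: `estimates` (mu and per-level effects),
#'   `sigma2`, `loglik`, `vcov` of the fixed effects, `converged`,
#'   `n_quad`.
#' @export
fit_step1 <- function(y, offsets, groups, reference = NULL, nodes = 25L) {
  check_fit_inputs(y, offsets, groups)
  if (is.null(reference)) reference <- default_reference(groups)
  mm <- make_model_matrix(groups, reference)
  opt <- agq_optimize(y, offsets, mm$X, nodes)

  est <- opt$coef
  names(est) <- colnames(mm$X)
  dimnames(opt$vcov) <- list(colnames(mm$X), colnames(mm$X))
  structure(list(model = "step1", estimates = est, levels = mm$levels,
                 reference = mm$levels[1L], sigma2 = opt$sigma2,
                 sigma2_C = NA_real_, loglik = opt$loglik, vcov = opt$vcov,
                 converged = opt$converged, n_quad = nodes,
                 groups = as.character(groups), y = y, offsets = offsets),
            class = "glmm_fit")
}

# Maximum marginal likelihood for the factorized (observation-level
# random effect only) Poisson-lognormal model with arbitrary design
# matrix X; shared by fit_step1 and the zero-abundance LRT.
agq_optimize <- function(y, offsets, X, nodes = 25L) {
  gh <- gh_rule(nodes)
  p <- ncol(X)

  negloglik <- function(par) {
    eta <- offsets + drop(X %*% par[1:p])
    -sum(agq_observations(y, eta, exp(2 * par[p + 1L]), gh)$loglik)
  }
  neggrad <- function(par) {
    sigma2 <- exp(2 * par[p + 1L])
    eta <- offsets + drop(X %*% par[1:p])
    mom <- agq_observations(y, eta, sigma2, gh, moments = TRUE)
    gc <- -drop(crossprod(X, y - mom$e_lambda))
    gs <- if (sigma2 < SIGMA2_FLOOR) 0 else -sum(mom$e_z2 / sigma2 - 1)
    c(gc, gs)
  }

  start_glm <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::poisson(), offset = offsets))
  start <- c(pmin(pmax(start_glm$coefficients, -25), 25), log(0.5))
  start[is.na(start)] <- 0
  lower <- c(rep(-30, p), log(1e-4))
  upper <- c(rep(30, p), log(10))

  fit <- NULL
  restart_seeds <- c(NA_integer_, 101L, 102L, 103L)
  for (attempt in seq_along(restart_seeds)) {
    st <- start
    if (attempt > 1L) {
      set.seed(restart_seeds[attempt])
      st <- start + stats::rnorm(length(start), 0, 0.5)
      st <- pmin(pmax(st, lower + 0.01), upper - 0.01)
    }
    cand <- stats::nlminb(st, negloglik, gradient = neggrad,
                          lower = lower, upper = upper,
                          control = list(iter.max = 500, eval.max = 1000,
                                         rel.tol = 1e-10))
    if (is.null(fit) || cand$objective < fit$objective - 1e-8) fit <- cand
    if (fit$convergence == 0) break
  }
  converged <- fit$convergence == 0
  par <- fit$par
  sigma2_hat <- exp(2 * par[p + 1L])
  if (sigma2_hat < BOUNDARY_TOL) sigma2_hat <- 0

  vcov <- matrix(NA_real_, p, p)
  singular <- FALSE
  H <- tryCatch(stats::optimHess(par, negloglik, neggrad),
                error = function(e) NULL)
  if (!is.null(H)) {
    Vi <- tryCatch(solve(H), error = function(e) NULL)
    if (sigma2_hat == 0 || is.null(Vi)) {
      # at the boundary the sigma row of H degenerates; condition on it
      Vi2 <- tryCatch(solve(H[1:p, 1:p, drop = FALSE]),
                      error = function(e) NULL)
      if (!is.null(Vi2)) vcov <- Vi2 else singular <- TRUE
    } else {
      vcov <- Vi[1:p, 1:p, drop = FALSE]
    }
  } else singular <- TRUE
  vcov <- (vcov + t(vcov)) / 2

  list(coef = unname(par[1:p]), sigma2 = unname(sigma2_hat),
       loglik = -fit$objective, vcov = vcov,
       converged = converged && !singular)
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Poisson mixed model (", x$model, "), ", length(x$levels),
      " levels, reference '", x$reference, "'\n", sep = "")
  cat("  loglik ", format(x$loglik), ", sigma2 ", format(x$sigma2), sep = "")
  if (!is.na(x$sigma2_C)) cat(", sigma2_C ", format(x$sigma2_C), sep = "")
  cat(", converged ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Kinship matrix of Step-2 groups from mixing fractions
#'
#' Builds the groups-by-sources mixing matrix S from the design (each
#' Step-2 group's source communities and fractions) and returns
#' `K = S %*% t(S)` with the diagonal set to 1. Under this reading of
#' kinship, a self-mix R+R and the coalescence R+C of the same removal
#' treatment have kinship 0.5, as do R+C and C+C, while self-mixes of
#' different removal treatments have kinship 0.
#'
#' @param design Design data frame with Step-2 rows.
#' @return Symmetric positive-definite matrix indexed by Step-2 group.
#' @export
kinship_matrix <- function(design) {
  s2 <- unique(design[design$step == 2L,
                      c("group", "source_a", "source_b", "frac_a")])
  if (!nrow(s2)) stop("design has no Step-2 groups", call. = FALSE)
  sources <- sort(unique(c(s2$source_a, s2$source_b)))
  S <- matrix(0, nrow(s2), length(sources),
              dimnames = list(s2$group, sources))
  for (i in seq_len(nrow(s2))) {
    S[i, s2$source_a[i]] <- S[i, s2$source_a[i]] + s2$frac_a[i]
    S[i, s2$source_b[i]] <- S[i, s2$source_b[i]] + 1 - s2$frac_a[i]
  }
  K <- S %*% t(S)
  diag(K) <- 1
  K
}

# Penalized Poisson regression: joint mode over (free fixed effects,
# random effects u), u ~ N(0, Sigma) with precision Omega. Returns mode,
# penalized loglik pieces and the curvature blocks for Laplace.
laplace_mode <- function(y, offsets, X, Z, Omega, coef, u,
                         coef_free = TRUE) {
  p <- if (coef_free) ncol(X) else 0L
  q <- ncol(Z)
  pen_ll <- function(coef, u) {
    eta <- offsets + drop(X %*% coef) + drop(Z %*% u)
    sum(y * eta - exp(eta) - lgamma(y + 1)) -
      0.5 * drop(crossprod(u, Omega %*% u))
  }
  cur <- pen_ll(coef, u)
  for (it in 1:200) {
    eta <- offsets + drop(X %*% coef) + drop(Z %*% u)
    w <- exp(eta)
    w <- pmin(w, 1e10)
    resid <- y - w
    if (coef_free) {
      gr <- c(drop(crossprod(X, resid)), drop(crossprod(Z, resid)) -
                drop(Omega %*% u))
      XW <- X * w
      ZW <- Z * w
      H <- rbind(cbind(crossprod(XW, X), crossprod(XW, Z)),
                 cbind(crossprod(ZW, X), crossprod(ZW, Z) + Omega))
    } else {
      gr <- drop(crossprod(Z, resid)) - drop(Omega %*% u)
      ZW <- Z * w
      H <- crossprod(ZW, Z) + Omega
    }
    step <- tryCatch(solve(H + diag(1e-10, nrow(H)), gr),
                     error = function(e) NULL)
    if (is.null(step)) return(NULL)
    alpha <- 1
    repeat {
      coef_new <- coef
      u_new <- u
      if (coef_free) {
        coef_new <- coef + alpha * step[seq_len(p)]
        u_new <- u + alpha * step[p + seq_len(q)]
      } else u_new <- u + alpha * step
      new_ll <- pen_ll(coef_new, u_new)
      if (is.finite(new_ll) && new_ll >= cur - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) break
    }
    moved <- max(abs(c(coef_new - coef, u_new - u)))
    coef <- coef_new
    u <- u_new
    cur <- new_ll
    if (moved < 1e-10) break
  }
  eta <- offsets + drop(X %*% coef) + drop(Z %*% u)
  w <- exp(eta)
  ZW <- Z * w
  Mu <- crossprod(ZW, Z) + Omega
  list(coef = coef, u = u, eta = eta, w = w, Mu = Mu,
       cond_loglik = sum(y * eta - exp(eta) - lgamma(y + 1)),
       penalty = 0.5 * drop(crossprod(u, Omega %*% u)))
}

logdet <- function(M) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  2 * sum(log(diag(ch)))
}

# Laplace marginal log-likelihood for the Step-2 model at given variance
# parameters; optionally profiles the fixed effects into the mode.
laplace_objective <- function(y, offsets, X, Zg, K, sigma2, sigma2C,
                              coef, u, coef_free = TRUE) {
  N <- length(y)
  G <- ncol(Zg)
  with_C <- sigma2C >= SIGMA2_FLOOR
  if (with_C) {
    Z <- cbind(Zg, diag(N))
    Kinv <- solve(K)
    Omega <- matrix(0, G + N, G + N)
    Omega[1:G, 1:G] <- Kinv / sigma2C
    diag(Omega)[G + 1:N] <- 1 / sigma2
    ld_sigma <- G * log(sigma2C) + logdet(K) + N * log(sigma2)
  } else {
    Z <- diag(N)
    Omega <- diag(1 / sigma2, N)
    ld_sigma <- N * log(sigma2)
    if (length(u) != N) u <- rep(0, N)
  }
  mode <- laplace_mode(y, offsets, X, Z, Omega, coef, u, coef_free)
  if (is.null(mode)) return(list(value = -Inf))
  ld_M <- logdet(mode$Mu)
  if (!is.finite(ld_M)) return(list(value = -Inf))
  value <- mode$cond_loglik - mode$penalty - 0.5 * ld_sigma - 0.5 * ld_M
  c(mode, list(value = value, with_C = with_C))
}

#' Fit the Step-2 Poisson mixed model with kinship-correlated groups
#'
#' Adds to the Step-1 model a group-level Gaussian effect with
#' covariance `sigma2_C * K`, `K` the mixing-fraction kinship between
#' Step-2 groups. The joint random-effect vector (group effects plus
#' observation-level effects) is integrated by a Laplace approximation;
#' fixed effects are profiled into the joint mode, and the two variance
#' parameters are optimized on the log scale. With `fix_sigma2C = 0` the
#' group effect is dropped and the fit reduces exactly to the Step-1
#' adaptive-quadrature fit.
#'
#' @inheritParams fit_step1
#' @param kinship Kinship matrix indexed by the Step-2 groups present.
#' @param fix_sigma2C Optional fixed value for the kinship variance
#'   (only 0 is special-cased to the exact factorized fit).
#' @return A `glmm_fit` with `sigma2_C` filled in.
#' @export
fit_step2 <- function(y, offsets, groups, kinship, reference = NULL,
                      fix_sigma2C = NULL, nodes = 25L) {
  check_fit_inputs(y, offsets, groups)
  if (is.null(reference)) reference <- default_reference(groups)
  lev <- unique(as.character(groups))
  if (!all(lev %in% rownames(kinship))) {
    stop("kinship matrix lacks group(s): ",
         paste(setdiff(lev, rownames(kinship)), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(fix_sigma2C) && fix_sigma2C == 0) {
    fit <- fit_step1(y, offsets, groups, reference = reference,
                     nodes = nodes)
    fit$model <- "step2"
    fit$sigma2_C <- 0
    return(fit)
  }
  mm <- make_model_matrix(groups, reference)
  X <- mm$X
  p <- ncol(X)
  K <- kinship[mm$levels, mm$levels]
  Zg <- stats::model.matrix(~ 0 + mm$factor)
  colnames(Zg) <- mm$levels
  N <- length(y)
  G <- ncol(Zg)

  state <- new.env()
  start_glm <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::poisson(), offset = offsets))
  state$coef <- pmin(pmax(ifelse(is.na(start_glm$coefficients), 0,
                                 start_glm$coefficients), -25), 25)
  state$u <- rep(0, G + N)

  objective <- function(par) {
    sigma2 <- exp(2 * par[1L])
    sigma2C <- if (is.null(fix_sigma2C)) exp(2 * par[2L]) else fix_sigma2C
    u0 <- if (sigma2C >= SIGMA2_FLOOR) state$u else state$u[G + 1:N]
    res <- laplace_objective(y, offsets, X, Zg, K, sigma2, sigma2C,
                             state$coef, u0, coef_free = TRUE)
    if (!is.finite(res$value)) return(1e10)
    state$coef <- res$coef
    state$u <- if (res$with_C) res$u else c(rep(0, G), res$u)
    state$last <- res
    -res$value
  }

  npar <- if (is.null(fix_sigma2C)) 2L else 1L
  start <- if (npar == 2L) c(log(0.5), log(0.3)) else log(0.5)
  opt <- stats::nlminb(start, objective,
                       lower = rep(log(1e-3), npar),
                       upper = rep(log(10), npar),
                       control = list(iter.max = 300, eval.max = 600,
                                      rel.tol = 1e-9))
  converged <- opt$convergence == 0
  sigma2_hat <- exp(2 * opt$par[1L])
  sigma2C_hat <- if (npar == 2L) exp(2 * opt$par[2L]) else fix_sigma2C
  # re-evaluate at the optimum so the stored mode matches it
  objective(opt$par)
  res <- state$last
  if (sigma2_hat < BOUNDARY_TOL) sigma2_hat <- 0
  boundaryC <- sigma2C_hat < 1e-4
  if (sigma2C_hat < 1e-5) sigma2C_hat <- 0

  # fixed-effect covariance from the joint-mode Hessian (Schur block)
  Z <- if (res$with_C) cbind(Zg, diag(N)) else diag(N)
  XW <- X * res$w
  A <- crossprod(XW, X)
  B <- crossprod(XW, Z)
  Vfix <- tryCatch({
    S <- A - B %*% solve(res$Mu, t(B))
    solve(S)
  }, error = function(e) matrix(NA_real_, p, p))
  singular <- anyNA(Vfix)
  Vfix <- (Vfix + t(Vfix)) / 2
  dimnames(Vfix) <- list(colnames(X), colnames(X))
  if (boundaryC) {
    message("profile likelihood flat in sigma2_C (estimate at boundary)")
  }

  est <- res$coef
  names(est) <- colnames(X)
  structure(list(model = "step2", estimates = est, levels = mm$levels,
                 reference = mm$levels[1L], sigma2 = sigma2_hat,
                 sigma2_C = sigma2C_hat, loglik = res$value, vcov = Vfix,
                 converged = converged && !singular, n_quad = NA_integer_,
                 groups = as.character(groups), y = y, offsets = offsets),
            class = "glmm_fit")
}

#' Marginal log-likelihood of either model at arbitrary parameters
#'
#' Exposes the objective the fitters maximize: the adaptive-quadrature
#' marginal likelihood for the Step-1 model, and the Laplace
#' approximation (mode over the random effects at the given fixed
#' effects) for the Step-2 model.
#'
#' @param params List with `mu`, `effects` (named by non-reference
#'   level; missing levels are 0), `sigma2`, and for step2 `sigma2_C`.
#' @param y,offsets,groups As in [fit_step1()].
#' @param model `"step1"` or `"step2"`.
#' @param reference Reference level.
#' @param kinship Kinship matrix (step2 only).
#' @param nodes Quadrature nodes (step1 only).
#' @return The marginal log-likelihood value.
#' @export
marginal_loglik <- function(params, y, offsets, groups, model = "step1",
                            reference = NULL, kinship = NULL, nodes = 25L) {
  if (params$sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  if (is.null(reference)) reference <- default_reference(groups)
  mm <- make_model_matrix(groups, reference)
  coef <- c(params$mu, rep(0, length(mm$levels) - 1L))
  names(coef) <- colnames(mm$X)
  if (!is.null(params$effects)) {
    nm <- paste0("effect_", names(params$effects))
    bad <- setdiff(nm, names(coef))
    if (length(bad)) stop("unknown effect level(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    coef[nm] <- params$effects
  }
  eta <- offsets + drop(mm$X %*% coef)
  if (model == "step1") {
    return(sum(agq_observations(y, eta, params$sigma2, gh_rule(nodes))$loglik))
  }
  sigma2C <- if (is.null(params$sigma2_C)) 0 else params$sigma2_C
  if (sigma2C < 0) stop("sigma2_C must be >= 0", call. = FALSE)
  if (sigma2C < SIGMA2_FLOOR && params$sigma2 < SIGMA2_FLOOR) {
    return(sum(stats::dpois(y, exp(eta), log = TRUE)))
  }
  if (is.null(kinship)) stop("step2 requires a kinship matrix",
                             call. = FALSE)
  K <- kinship[mm$levels, mm$levels]
  Zg <- stats::model.matrix(~ 0 + mm$factor)
  N <- length(y)
  G <- ncol(Zg)
  sigma2 <- max(params$sigma2, SIGMA2_FLOOR)
  u0 <- if (sigma2C >= SIGMA2_FLOOR) rep(0, G + N) else rep(0, N)
  res <- laplace_objective(y, offsets, mm$X, Zg, K, sigma2, sigma2C,
                           coef, u0, coef_free = FALSE)
  res$value
}
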