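# Treatment roster used when the design matches the 18-removal soil
# experiment; arbitrary sizes fall back to generic R labels.
removal_roster <- function(n_removal) {
  full <- c("Cip", "Gen", "Ram", "Cic", "Mic", "Mil", "F1", "F2", "F3",
            "FT", "HS", "Na", "Ox1", "Ox2", "pH11", "pH2", "US", "UV")
  if (n_removal <= length(full)) full[seq_len(n_removal)]
  else sprintf("R%02d", seq_len(n_removal))
}

# The ten treatments carried into the coalescence step, spanning the
# removal-treatment types (antibiotics, fungicide, protisticide,
# filtration, heat, oxidative, pH, shortwave).
step2_roster <- function(labels, n_step2) {
  pref <- c("Cip", "Ram", "Cic", "Mil", "F3", "HS", "Ox1", "pH2", "pH11",
            "UV")
  sel <- intersect(pref, labels)
  if (length(sel) >= n_step2) sel[seq_len(n_step2)]
  else labels[seq_len(n_step2)]
}

#' Build the two-step removal/coalescence sample design
#'
#' Step 1 has `n_removal` removal treatments plus the untreated control
#' `C`, each with `replicates` microcosms. Step 2 carries `n_step2`
#' removal treatments forward: each contributes a self-mix (`R+R`) and a
#' coalescence mix with the control (`R+C`), and a self-mixed control
#' `C+C` closes the roster. Step-2 mixtures pair replicate k of one
#' source with replicate k of the other (fixed pairing).
#'
#' @param n_removal Number of Step-1 removal treatments (default 18).
#' @param n_step2 Number carried into Step 2 (default 10).
#' @param replicates Replicates per group (default 10, minimum 2).
#' @return Design data frame (see [read_sample_metadata()]); with the
#'   defaults, 190 Step-1 and 210 Step-2 samples.
#' @export
build_design <- function(n_removal = 18L, n_step2 = 10L, replicates = 10L) {
  if (replicates < 2L) stop("need at least 2 replicates", call. = FALSE)
  if (n_step2 > n_removal) stop("n_step2 must not exceed n_removal",
                                call. = FALSE)
  removals <- removal_roster(n_removal)
  step2 <- step2_roster(removals, n_step2)
  reps <- seq_len(replicates)

  row <- function(sample, step, group, a, b, fa, k) {
    data.frame(sample = sample, step = step, group = group, source_a = a,
               source_b = b, frac_a = fa, replicate = k,
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (g in c("C", removals)) {
    out[[length(out) + 1L]] <-
      row(sprintf("S1_%s_r%02d", g, reps), 1L, g, g, g, 1, reps)
  }
  for (g in step2) {
    out[[length(out) + 1L]] <-
      row(sprintf("S2_%s+%s_r%02d", g, g, reps), 2L, paste0(g, "+", g),
          g, g, 0.5, reps)
    out[[length(out) + 1L]] <-
      row(sprintf("S2_%s+C_r%02d", g, reps), 2L, paste0(g, "+C"),
          g, "C", 0.5, reps)
  }
  out[[length(out) + 1L]] <-
    row(sprintf("S2_C+C_r%02d", reps), 2L, "C+C", "C", "C", 0.5, reps)
  design <- do.call(rbind, out)
  rownames(design) <- NULL
  design$frac_b <- 1 - design$frac_a
  validate_design(design)
}

# Group-type helpers over Step-2 labels built as "A+B"
group_parts <- function(group) strsplit(group, "+", fixed = TRUE)
is_coalescence <- function(group) {
  vapply(group_parts(group), function(p)
    length(p) == 2L && p[2] == "C" && p[1] != "C", logical(1))
}
is_self_mix <- function(group) {
  vapply(group_parts(group), function(p)
    length(p) == 2L && p[1] == p[2], logical(1))
}

#' Per-OTU generative truth for the parametric simulator
#'
#' Describes one OTU under the two-step Poisson-lognormal model: a
#' baseline log relative abundance `mu`, Step-1 treatment effects
#' `alpha` (control fixed at 0), Step-2 group effects `beta` (self-mixed
#' control fixed at 0), observation-level variance `sigma2`, kinship
#' variance `sigma2_C`, and a lognormal law for per-sample read sums.
#'
#' @param mu Baseline log relative abundance.
#' @param alpha Named vector of Step-1 effects; missing groups are 0.
#' @param beta Named vector of Step-2 effects; missing groups are 0.
#' @param sigma2 Observation-level variance (>= 0).
#' @param sigma2_C Step-2 kinship variance (>= 0).
#' @param depth_meanlog,depth_sdlog Lognormal read-depth parameters;
#'   defaults give a mean depth near 16215 reads per sample.
#' @return A `glmm_truth` list.
#' @export
glmm_truth <- function(mu, alpha = NULL, beta = NULL, sigma2 = 0.2,
                       sigma2_C = 0, depth_meanlog = log(16215),
                       depth_sdlog = 0.3) {
  stopifnot(sigma2 >= 0, sigma2_C >= 0)
  if (!is.null(alpha) && "C" %in% names(alpha) && alpha[["C"]] != 0) {
    stop("alpha for the control must be 0", call. = FALSE)
  }
  structure(list(mu = mu, alpha = alpha, beta = beta, sigma2 = sigma2,
                 sigma2_C = sigma2_C, depth_meanlog = depth_meanlog,
                 depth_sdlog = depth_sdlog), class = "glmm_truth")
}

effect_for <- function(effects, group) {
  if (is.null(effects) || !group %in% names(effects)) 0 else effects[[group]]
}

#' Simulate counts directly from the two-step Poisson mixed model
#'
#' Per sample, a read depth is drawn from the truth's lognormal law.
#' For each OTU and sample the expected count is
#' `exp(log(depth) + mu + effect + C + Z)` with `Z ~ N(0, sigma2)` per
#' observation and, for Step-2 samples, a per-OTU group-level `C` drawn
#' from `N(0, sigma2_C * K)` with `K` the mixing-fraction kinship of the
#' Step-2 groups; the count is Poisson with that mean. Truth labels mark
#' OTUs with nonzero Step-1 effects as released (positive) or suppressed
#' (negative).
#'
#' @param truth List of [glmm_truth()] objects, one per OTU, named by
#'   OTU id.
#' @param design Design from [build_design()].
#' @param seed Integer seed fixing every random draw.
#' @return List with `counts` (integer matrix), `labels` (data frame
#'   otu_id, treatment, label) and `depths`.
#' @export
simulate_parametric <- function(truth, design, seed) {
  stopifnot(length(truth) >= 1L)
  if (is.null(names(truth))) {
    names(truth) <- sprintf("OTU%04d", seq_along(truth))
  }
  set.seed(as.integer(seed))
  n_s <- nrow(design)
  otus <- names(truth)
  t1 <- truth[[1L]]
  depths <- round(stats::rlnorm(n_s, t1$depth_meanlog, t1$depth_sdlog))
  depths <- pmax(depths, 1)
  names(depths) <- design$sample

  s2_groups <- unique(design$group[design$step == 2L])
  K <- if (length(s2_groups)) kinship_matrix(design) else NULL

  counts <- matrix(0L, nrow = length(otus), ncol = n_s,
                   dimnames = list(otus, design$sample))
  for (oi in seq_along(otus)) {
    tr <- truth[[oi]]
    eff <- numeric(n_s)
    for (r in seq_len(n_s)) {
      g <- design$group[r]
      eff[r] <- if (design$step[r] == 1L) effect_for(tr$alpha, g)
                else effect_for(tr$beta, g)
    }
    grp_re <- numeric(n_s)
    if (!is.null(K) && tr$sigma2_C > 0) {
      L <- chol(tr$sigma2_C * K + diag(1e-10, nrow(K)))
      C <- drop(t(L) %*% stats::rnorm(nrow(K)))
      names(C) <- rownames(K)
      idx <- design$step == 2L
      grp_re[idx] <- C[design$group[idx]]
    }
    z <- if (tr$sigma2 > 0) stats::rnorm(n_s, 0, sqrt(tr$sigma2))
         else numeric(n_s)
    lambda <- exp(log(depths) + tr$mu + eff + grp_re + z)
    if (any(!is.finite(lambda))) {
      stop("non-finite linear predictor for OTU '", otus[oi], "'",
           call. = FALSE)
    }
    counts[oi, ] <- stats::rpois(n_s, lambda)
  }

  removals <- setdiff(unique(design$group[design$step == 1L]), "C")
  labels <- expand.grid(otu_id = otus, treatment = removals,
                        stringsAsFactors = FALSE)
  labels$label <- vapply(seq_len(nrow(labels)), function(r) {
    a <- effect_for(truth[[labels$otu_id[r]]]$alpha, labels$treatment[r])
    if (a > 0) "released" else if (a < 0) "suppressed" else "neutral"
  }, character(1))
  labels <- labels[order(labels$otu_id, labels$treatment), ]
  rownames(labels) <- NULL
  list(counts = counts, labels = labels, depths = depths)
}

#' Parameters of the mechanistic Ricker community simulator
#'
#' Discrete Lotka-Volterra (Ricker) dynamics
#' `n_s(t+1) = n_s(t) * exp(r_s + sum_u A[s,u] * n_u(t))`, one step per
#' incubation day. `A[s,u]` is the per-capita effect of species u on
#' species s; the diagonal must be negative (self-limitation) and a
#' negative off-diagonal entry marks antagonism of u on s.
#'
#' @param S Number of species.
#' @param r Growth rates (length S, recycled).
#' @param A S x S interaction matrix; default diag(-0.5).
#' @param x0 Inoculum composition (positive, length S).
#' @param survival Named list / matrix of per-treatment survival
#'   fractions in \[0,1\] (rows or elements named by treatment; control
#'   "C" defaults to 1).
#' @param T_steps Number of growth steps (default 45, one per day).
#' @param dilution Transfer dilution into sterile soil (default 0.1).
#' @param depth_meanlog,depth_sdlog Lognormal read-depth law.
#' @param jitter_sd Lognormal replicate jitter on initial abundances
#'   (default 0.1), the within-group variability the observation-level
#'   random effect is meant to absorb.
#' @return A `mechanistic_params` list.
#' @export
mechanistic_params <- function(S, r = 0.5, A = NULL, x0 = NULL,
                               survival = list(), T_steps = 45L,
                               dilution = 0.1, depth_meanlog = log(16215),
                               depth_sdlog = 0.3, jitter_sd = 0.1) {
  if (is.null(A)) A <- diag(-0.5, S)
  stopifnot(nrow(A) == S, ncol(A) == S)
  if (any(diag(A) >= 0)) stop("A must have negative diagonal", call. = FALSE)
  if (dilution <= 0 || dilution >= 1) stop("dilution must be in (0,1)",
                                           call. = FALSE)
  if (is.null(x0)) x0 <- rep(1 / S, S)
  r <- rep_len(r, S)
  for (s in survival) {
    if (any(s < 0 | s > 1)) stop("survival fractions must be in [0,1]",
                                 call. = FALSE)
  }
  structure(list(S = S, r = r, A = A, x0 = x0, survival = survival,
                 T_steps = as.integer(T_steps), dilution = dilution,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 jitter_sd = jitter_sd),
            class = "mechanistic_params")
}

ricker_run <- function(n0, r, A, T_steps, context = "") {
  n <- n0
  for (t in seq_len(T_steps)) {
    n <- n * exp(r + drop(A %*% n))
    if (any(!is.finite(n)) || sum(n) > 1e12) {
      stop("community dynamics overflow", context, " at step ", t,
           call. = FALSE)
    }
  }
  n
}

survival_of <- function(params, treatment) {
  if (treatment %in% names(params$survival)) {
    rep_len(params$survival[[treatment]], params$S)
  } else {
    rep(1, params$S)
  }
}

# Noise-free Step-1 and Step-2 endpoints for every group in the design
mechanistic_endpoints <- function(params, design, jitter = NULL) {
  s1_groups <- unique(design$group[design$step == 1L])
  end1 <- list()
  for (g in s1_groups) {
    n0 <- params$x0 * survival_of(params, g)
    if (!is.null(jitter)) n0 <- n0 * jitter[[g]]
    end1[[g]] <- ricker_run(n0, params$r, params$A, params$T_steps,
                            paste0(" (step 1, ", g, ")"))
  }
  s2 <- unique(design[design$step == 2L,
                      c("group", "source_a", "source_b", "frac_a")])
  end2 <- list()
  for (i in seq_len(nrow(s2))) {
    g <- s2$group[i]
    n0 <- params$dilution * (s2$frac_a[i] * end1[[s2$source_a[i]]] +
                             (1 - s2$frac_a[i]) * end1[[s2$source_b[i]]])
    end2[[g]] <- ricker_run(n0, params$r, params$A, params$T_steps,
                            paste0(" (step 2, ", g, ")"))
  }
  list(step1 = end1, step2 = end2)
}

#' Simulate a removal/coalescence experiment from community dynamics
#'
#' Step-1 samples start from the inoculum thinned by the treatment's
#' survival fractions (with lognormal replicate jitter) and run `T_steps`
#' Ricker updates. Step-2 samples start from the dilution of the mixture
#' of the matching replicate's Step-1 endpoints and run `T_steps` more.
#' Reads are multinomial draws of the endpoint composition at a
#' lognormal depth.
#'
#' @param params [mechanistic_params()].
#' @param design Design from [build_design()].
#' @param seed Integer seed.
#' @return List with `counts`, `labels` (from [derive_truth_labels()]),
#'   `antagonists` (per species, the species that suppress it) and
#'   `depths`.
#' @export
simulate_mechanistic <- function(params, design, seed) {
  set.seed(as.integer(seed))
  S <- params$S
  otus <- sprintf("OTU%04d", seq_len(S))
  s1 <- design[design$step == 1L, , drop = FALSE]
  s2 <- design[design$step == 2L, , drop = FALSE]

  # per (group, replicate) Step-1 trajectory, jittered
  end1 <- list()
  for (i in seq_len(nrow(s1))) {
    n0 <- params$x0 * survival_of(params, s1$group[i]) *
      stats::rlnorm(S, 0, params$jitter_sd)
    end1[[paste(s1$group[i], s1$replicate[i])]] <-
      ricker_run(n0, params$r, params$A, params$T_steps,
                 paste0(" (step 1, ", s1$group[i], ")"))
  }
  endpoints <- matrix(0, nrow = S, ncol = nrow(design),
                      dimnames = list(otus, design$sample))
  for (i in seq_len(nrow(s1))) {
    endpoints[, s1$sample[i]] <- end1[[paste(s1$group[i], s1$replicate[i])]]
  }
  for (i in seq_len(nrow(s2))) {
    a <- end1[[paste(s2$source_a[i], s2$replicate[i])]]
    b <- end1[[paste(s2$source_b[i], s2$replicate[i])]]
    n0 <- params$dilution * (s2$frac_a[i] * a + (1 - s2$frac_a[i]) * b)
    endpoints[, s2$sample[i]] <-
      ricker_run(n0, params$r, params$A, params$T_steps,
                 paste0(" (step 2, ", s2$group[i], ")"))
  }

  depths <- pmax(round(stats::rlnorm(nrow(design), params$depth_meanlog,
                                     params$depth_sdlog)), 1)
  names(depths) <- design$sample
  counts <- matrix(0L, nrow = S, ncol = nrow(design),
                   dimnames = list(otus, design$sample))
  for (j in seq_len(nrow(design))) {
    p <- endpoints[, j] / sum(endpoints[, j])
    counts[, j] <- as.integer(stats::rmultinom(1, depths[j], p))
  }

  labels <- derive_truth_labels(params, design)
  antagonists <- lapply(seq_len(S), function(s) {
    otus[which(params$A[s, ] < 0 & seq_len(S) != s)]
  })
  names(antagonists) <- otus
  list(counts = counts, labels = labels, antagonists = antagonists,
       depths = depths)
}

#' Ground-truth released/suppressed labels from noise-free dynamics
#'
#' Runs the deterministic dynamics (no jitter, no sampling) and labels
#' an OTU released under a removal treatment when its endpoint relative
#' abundance exceeds the control's by a factor of at least `theta`,
#' suppressed when below by the same factor, and neutral otherwise.
#' Labels are independent of any seed.
#'
#' @param params [mechanistic_params()].
#' @param design Design from [build_design()].
#' @param theta Fold-change threshold (default 1.5).
#' @return Data frame otu_id, treatment, label.
#' @export
derive_truth_labels <- function(params, design, theta = 1.5) {
  otus <- sprintf("OTU%04d", seq_len(params$S))
  ends <- mechanistic_endpoints(params, design)
  ctrl <- ends$step1[["C"]]
  ctrl_rel <- ctrl / sum(ctrl)
  removals <- setdiff(unique(design$group[design$step == 1L]), "C")
  out <- list()
  for (g in removals) {
    rel <- ends$step1[[g]] / sum(ends$step1[[g]])
    ratio <- rel / ctrl_rel
    lab <- ifelse(ratio >= theta, "released",
                  ifelse(ratio <= 1 / theta, "suppressed", "neutral"))
    lab[ctrl_rel == 0 & rel == 0] <- "neutral"
    out[[g]] <- data.frame(otu_id = otus, treatment = g, label = lab,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$otu_id, res$treatment), ]
  rownames(res) <- NULL
  res
}
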