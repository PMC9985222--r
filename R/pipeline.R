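# One reproducible run: simulate -> filter -> fit/contrasts -> classify
# -> diversity, from a hierarchical YAML config.

default_config <- function() {
  list(
    seed = 1L,
    alpha = 0.05,
    design = list(n_removal = 18L, n_step2 = 10L, replicates = 10L),
    simulate = list(generator = "parametric", n_otus = 50L,
                    n_affected = 10L, effect_size = 1.5, mu = log(0.005),
                    sigma2 = 0.2, sigma2_C = 0, depth_meanlog = log(16215),
                    depth_sdlog = 0.3),
    filter = list(rel_thresh = 0.005, prevalence = 0.6),
    rarefy = list(depth = 9000L),
    contrasts = list(nsim = 2e4, mc_seed = 20230304, scope = "all-pairs",
                     nodes = 25L),
    diversity = list(enabled = TRUE, n_perm = 999L))
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      merge_config(base[[nm]], user[[nm]])
    } else user[[nm]]
  }
  base
}

read_config <- function(config) {
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(user)) stop("config must be a YAML file or a list",
                           call. = FALSE)
  known <- names(default_config())
  unknown <- setdiff(names(user), c(known, "out_dir"))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- merge_config(default_config(), user)
  if (is.null(user$alpha)) message("alpha not set; defaulting to 0.05")
  cfg
}

stage_hash <- function(params) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(params, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline from a config
#'
#' Executes simulate, filter, per-step model fits with selected
#' contrasts, classification, and community diversity in order, writing
#' every output (count table, metadata, truth labels, contrasts,
#' classifications, diversity, distances, recovery calls) plus a
#' `summary.json` recording all parameters and seeds to the run
#' directory. Stages are cached: a rerun with unchanged parameters
#' reuses the existing stage outputs, and a rerun with an identical
#' config is byte-identical. Per-OTU fit failures are tallied, never
#' fatal.
#'
#' @param config Path to a YAML config or an equivalent nested list.
#'   Unknown keys are rejected with a message naming the key; missing
#'   keys take documented defaults.
#' @param out_dir Run directory (overrides the config's `out_dir`).
#' @return Invisibly, the run summary list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_config(config)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("no output directory given", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(stage, event, ...) {
    line <- sprintf("[%s] %s: %s", stage, event, paste0(...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
  cached <- function(stage, params, produce, files) {
    hfile <- file.path(cache_dir, paste0(stage, ".hash"))
    h <- stage_hash(params)
    if (file.exists(hfile) && readLines(hfile, warn = FALSE)[1L] == h &&
        all(file.exists(file.path(out_dir, files)))) {
      logf(stage, "cached", "inputs unchanged, reusing outputs")
      return(FALSE)
    }
    produce()
    writeLines(h, hfile)
    TRUE
  }
  unlink(log_path)
  logf("pipeline", "start", format(Sys.time(), tz = "UTC"))
  summary <- list(config = cfg)

  # ---- simulate ----------------------------------------------------
  design <- do.call(build_design, cfg$design)
  sim_env <- new.env()
  run_sim <- function() {
    sc <- cfg$simulate
    set.seed(cfg$seed)
    if (identical(sc$generator, "mechanistic")) {
      params <- build_mechanistic(sc, design, cfg$seed)
      sim <- simulate_mechanistic(params, design, seed = cfg$seed)
    } else {
      truth <- build_parametric_truth(sc, design, cfg$seed)
      sim <- simulate_parametric(truth, design, seed = cfg$seed)
    }
    write_count_table(sim$counts, file.path(out_dir, "counts.tsv"))
    write_sample_metadata(design, file.path(out_dir, "metadata.tsv"))
    utils::write.table(sim$labels, file.path(out_dir, "truth_labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("simulate", "done", nrow(sim$counts), " OTUs x ",
         ncol(sim$counts), " samples")
  }
  cached("simulate", list(cfg$design, cfg$simulate, cfg$seed), run_sim,
         c("counts.tsv", "metadata.tsv", "truth_labels.tsv"))
  counts <- read_count_table(file.path(out_dir, "counts.tsv"))
  design <- read_sample_metadata(file.path(out_dir, "metadata.tsv"))
  depths <- sample_depths(counts)

  # ---- filter ------------------------------------------------------
  filtered <- filter_dominant(counts, design,
                              rel_thresh = cfg$filter$rel_thresh,
                              prevalence = cfg$filter$prevalence)
  logf("filter", "done", nrow(filtered), " of ", nrow(counts),
       " OTUs retained")
  summary$n_filtered <- nrow(filtered)

  # ---- contrasts (both steps) --------------------------------------
  run_fit <- function() {
    cc <- cfg$contrasts
    tabs <- lapply(c(1L, 2L), function(step) {
      run_contrasts(filtered, design, step, depths = depths,
                    alpha = cfg$alpha, scope = cc$scope, nsim = cc$nsim,
                    seed = cc$mc_seed, nodes = cc$nodes)
    })
    tab <- rbind(tabs[[1L]], tabs[[2L]])
    n_fail <- length(unique(tab$otu_id[tab$method == "none"]))
    logf("contrasts", "done", nrow(tab), " rows; ", n_fail,
         " OTU(s) with degenerate fits")
    utils::write.table(tab, file.path(out_dir, "contrasts_raw.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cached("contrasts", list(cfg$design, cfg$simulate, cfg$filter,
                           cfg$contrasts, cfg$alpha, cfg$seed), run_fit,
         "contrasts_raw.tsv")
  contrasts <- utils::read.delim(file.path(out_dir, "contrasts_raw.tsv"),
                                 stringsAsFactors = FALSE)

  # ---- classify ----------------------------------------------------
  assignments <- classify_otus(contrasts, design)
  cat_summary <- summarize_categories(assignments,
                                      n_total = nrow(filtered))
  logf("classify", "done", nrow(assignments), " OTU x treatment calls")
  summary$categories <- cat_summary

  # ---- diversity ---------------------------------------------------
  diversity_tab <- NULL
  if (isTRUE(cfg$diversity$enabled)) {
    dep <- cfg$rarefy$depth
    rare <- rarefy_counts(counts, dep, seed = cfg$seed)
    tree <- with_local_seed(cfg$seed, ape::rtree(nrow(counts),
                                                 tip.label = rownames(counts)))
    diversity_tab <- do.call(rbind, lapply(
      c("observed", "shannon", "inv_simpson"), function(m) {
        data.frame(sample = colnames(rare), metric = m,
                   value = as.numeric(alpha_diversity(rare, m)),
                   stringsAsFactors = FALSE)
      }))
    pdv <- faith_pd(rare, tree)
    diversity_tab <- rbind(diversity_tab,
                           data.frame(sample = names(pdv),
                                      metric = "faith_pd",
                                      value = as.numeric(pdv),
                                      stringsAsFactors = FALSE))
    uf <- weighted_unifrac(rare, tree)
    s2 <- design$sample[design$step == 2L]
    s2 <- intersect(s2, colnames(rare))
    pw <- pairwise_permanova(uf$distance[s2, s2],
                             design$group[match(s2, design$sample)],
                             n_perm = cfg$diversity$n_perm,
                             seed = cfg$seed)
    rec <- community_recovery(pw, design, alpha = cfg$alpha)
    utils::write.table(pw, file.path(out_dir, "permanova_pairwise.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rec, file.path(out_dir, "recovery.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("diversity", "done", "rarefied at ", dep, "; ",
         nrow(rec), " recovery calls")
    summary$recovery = as.list(table(rec$recovery))
  }

  summary$seeds <- list(simulate = cfg$seed, rarefy = cfg$seed,
                        mc_adjustment = cfg$contrasts$mc_seed,
                        permanova = cfg$seed)
  write_results(c(list(contrasts = contrasts,
                       classifications = assignments,
                       summary = summary),
                  if (!is.null(diversity_tab))
                    list(diversity = diversity_tab)),
                out_dir)
  logf("pipeline", "complete", "outputs in ", out_dir)
  invisible(summary)
}

# Parametric truth set for a pipeline run: `n_affected` OTUs get a
# released effect of `effect_size` under every removal treatment
# carried into Step 2, mirrored into the matching Step-2 groups.
build_parametric_truth <- function(sc, design, seed) {
  groups2 <- unique(design$group[design$step == 2L])
  coal <- groups2[is_coalescence(groups2)]
  removals <- vapply(group_parts(coal), `[`, character(1), 1L)
  selfs <- paste0(removals, "+", removals)
  with_local_seed(seed + 1L, {
    lapply(stats::setNames(seq_len(sc$n_otus),
                           sprintf("OTU%04d", seq_len(sc$n_otus))),
           function(i) {
             affected <- i <= sc$n_affected
             alpha <- if (affected) {
               stats::setNames(rep(sc$effect_size, length(removals)),
                               removals)
             } else NULL
             beta <- if (affected) {
               stats::setNames(rep(sc$effect_size, length(selfs)), selfs)
             } else NULL
             glmm_truth(mu = sc$mu + stats::rnorm(1, 0, 0.5),
                        alpha = alpha, beta = beta, sigma2 = sc$sigma2,
                        sigma2_C = sc$sigma2_C,
                        depth_meanlog = sc$depth_meanlog,
                        depth_sdlog = sc$depth_sdlog)
           })
  })
}

# Mechanistic parameter set: planted antagonist pairs where the second
# species suppresses the first and a treatment removes the antagonist.
build_mechanistic <- function(sc, design, seed) {
  S <- sc$n_otus
  n_pairs <- max(1L, sc$n_affected %/% 2L)
  A <- diag(-0.5, S)
  removals <- setdiff(unique(design$group[design$step == 1L]), "C")
  survival <- list()
  for (k in seq_len(min(n_pairs, length(removals)))) {
    victim <- 2L * k - 1L
    antagonist <- 2L * k
    A[victim, antagonist] <- -0.45
    surv <- rep(1, S)
    surv[antagonist] <- 0
    survival[[removals[k]]] <- surv
  }
  mechanistic_params(S = S, r = 0.5, A = A, survival = survival,
                     depth_meanlog = sc$depth_meanlog,
                     depth_sdlog = sc$depth_sdlog)
}
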