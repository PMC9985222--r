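# Set-algebra classification of OTUs across the two experiment steps.
#
# Four directional calls feed the classifier, all per OTU x removal
# treatment: R vs C (step 1), R+R vs C+C (step 2), R+C vs R+R
# (coalescence vs self-mix) and R+C vs C+C (coalescence vs control).

CATEGORY_LEVELS <- c("unaffected", "transient", "persistent_recovered",
                     "persistent_unrecovered", "step2_only",
                     "sign_reversed")

#' Classify one OTU x treatment call pattern
#'
#' Pure function of the four directional calls (`">"`, `"<"`, `"="`):
#' * `unaffected` - no step-1 and no step-2 difference;
#' * `transient` - a step-1 difference that is gone in the self-mix
#'   (R vs C but not R+R vs C+C);
#' * `persistent_recovered` - same-direction differences in both steps
#'   and no difference left between coalescence and control
#'   (R vs C \eqn{\cap} R+R vs C+C \eqn{\cap} R+C = C+C), the pattern
#'   validating a biotic interaction;
#' * `persistent_unrecovered` - same-direction differences in both
#'   steps with the coalescence still differing from the control;
#' * `step2_only` - a difference appearing only in step 2;
#' * `sign_reversed` - significant in both steps but in opposite
#'   directions (not covered by the interaction logic above; kept so
#'   the categories partition all call patterns).
#'
#' Alongside the category, emergent density-dependence flags are
#' recorded (not exclusive of the category): `emergent_high` when the
#' coalescence exceeds both of its sources (R+C > C+C and R+C > R+R),
#' `emergent_low` for the mirror pattern.
#'
#' @param step1,step2,coal_vs_self,coal_vs_ctrl Directional calls.
#' @return List with `category`, `emergent_high`, `emergent_low`.
#' @export
classify_calls <- function(step1, step2, coal_vs_self, coal_vs_ctrl) {
  calls <- c(step1 = step1, step2 = step2, coal_vs_self = coal_vs_self,
             coal_vs_ctrl = coal_vs_ctrl)
  bad <- !calls %in% c(">", "<", "=") | is.na(calls)
  if (any(bad)) {
    stop("missing or invalid call for: ",
         paste(names(calls)[bad], collapse = ", "), call. = FALSE)
  }
  category <- if (step1 == "=" && step2 == "=") {
    "unaffected"
  } else if (step1 != "=" && step2 == "=") {
    "transient"
  } else if (step1 == "=" && step2 != "=") {
    "step2_only"
  } else if (step1 == step2) {
    if (coal_vs_ctrl == "=") "persistent_recovered"
    else "persistent_unrecovered"
  } else {
    "sign_reversed"
  }
  list(category = category,
       emergent_high = coal_vs_ctrl == ">" && coal_vs_self == ">",
       emergent_low = coal_vs_ctrl == "<" && coal_vs_self == "<")
}

#' Build category assignments from a selected contrast table
#'
#' Joins the four contrast families per OTU x removal treatment and
#' classifies each combination. Only treatments carried into Step 2
#' (those with a coalescence group) can be classified.
#'
#' @param contrasts Selected contrast table covering both steps (rows
#'   from [run_contrasts()] for step 1 and step 2 combined, with
#'   `otu_id`, `family`, `level_a`, `level_b`, `direction`).
#' @param design The experimental design.
#' @return Data frame: `otu_id`, `treatment`, `step1_call`,
#'   `step2_call`, `coal_vs_self`, `coal_vs_ctrl`, `category`,
#'   `emergent_high`, `emergent_low`.
#' @export
classify_otus <- function(contrasts, design) {
  groups2 <- unique(design$group[design$step == 2L])
  coal <- sort(groups2[is_coalescence(groups2)])
  treatments <- vapply(group_parts(coal), `[`, character(1), 1L)
  otus <- sort(unique(contrasts$otu_id))
  call_of <- function(otu, family, a) {
    row <- contrasts[contrasts$otu_id == otu & contrasts$family == family &
                       contrasts$level_a == a, , drop = FALSE]
    if (nrow(row) != 1L) {
      stop("missing ", family, " call for OTU '", otu, "', level '", a, "'",
           call. = FALSE)
    }
    row$direction
  }
  out <- list()
  for (otu in otus) {
    sub <- contrasts[contrasts$otu_id == otu, , drop = FALSE]
    for (i in seq_along(treatments)) {
      r <- treatments[i]
      self <- paste0(r, "+", r)
      s1 <- call_of(otu, "R_vs_C", r)
      s2 <- call_of(otu, "RR_vs_CC", self)
      cs <- call_of(otu, "RC_vs_RR", coal[i])
      cc <- call_of(otu, "RC_vs_CC", coal[i])
      cl <- classify_calls(s1, s2, cs, cc)
      out[[length(out) + 1L]] <- data.frame(
        otu_id = otu, treatment = r, step1_call = s1, step2_call = s2,
        coal_vs_self = cs, coal_vs_ctrl = cc, category = cl$category,
        emergent_high = cl$emergent_high, emergent_low = cl$emergent_low,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$otu_id, res$treatment), ]
  rownames(res) <- NULL
  res
}

round_half_away <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Summaries and headline ratios of the category assignments
#'
#' Reports, per category, both the per-treatment tally (an OTU counted
#' once per treatment where it holds) and the unique-OTU tally (counted
#' once however many treatments it holds under) - the two differ
#' whenever an OTU reacts under several treatments. Headline ratios:
#'
#' * `released_fraction`: unique OTUs with a positive step-1 call over
#'   all classified OTUs;
#' * `recovered_fraction`: unique `persistent_recovered` OTUs (either
#'   direction) over unique persistent OTUs (either direction);
#' * `validated_positive_fraction`: unique OTUs with the full
#'   positive-interaction pattern (step1 >, step2 >, coalescence = )
#'   over all classified OTUs.
#'
#' Percentages are rounded to one decimal, half away from zero.
#'
#' @param assignments Data frame from [classify_otus()].
#' @param n_total Denominator for fractions over "all OTUs"; defaults
#'   to the number of distinct OTUs in `assignments` (pass the filtered
#'   OTU count when some OTUs never received a call).
#' @return List with `per_treatment` and `unique_otus` count tables,
#'   the ratios above (with their numerators and denominators), and
#'   percentage versions.
#' @export
summarize_categories <- function(assignments, n_total = NULL) {
  a <- assignments
  if (is.null(n_total)) n_total <- length(unique(a$otu_id))
  per_treatment <- table(factor(a$category, levels = CATEGORY_LEVELS))
  uniq <- function(cond) length(unique(a$otu_id[cond]))
  unique_otus <- vapply(CATEGORY_LEVELS, function(cat)
    uniq(a$category == cat), numeric(1))

  persistent <- a$category %in% c("persistent_recovered",
                                  "persistent_unrecovered")
  n_persistent <- uniq(persistent)
  n_recovered <- uniq(a$category == "persistent_recovered")
  n_released <- uniq(a$step1_call == ">")
  n_validated <- uniq(a$category == "persistent_recovered" &
                        a$step1_call == ">" & a$step2_call == ">")

  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  list(
    per_treatment = as.list(per_treatment),
    unique_otus = as.list(unique_otus),
    n_total = n_total,
    released = list(n = n_released, total = n_total,
                    fraction = ratio(n_released, n_total),
                    pct = round_half_away(100 * ratio(n_released, n_total))),
    recovered = list(n = n_recovered, total = n_persistent,
                     fraction = ratio(n_recovered, n_persistent),
                     pct = round_half_away(
                       100 * ratio(n_recovered, n_persistent))),
    validated_positive = list(n = n_validated, total = n_total,
                              fraction = ratio(n_validated, n_total),
                              pct = round_half_away(
                                100 * ratio(n_validated, n_total))),
    emergent = list(per_treatment = sum(a$emergent_high | a$emergent_low),
                    unique = uniq(a$emergent_high | a$emergent_low)))
}

#' Benchmark category assignments against planted ground truth
#'
#' Compares step-1 directional calls with the simulator's
#' released/suppressed/neutral labels per OTU x treatment, and reports
#' a confusion matrix plus sensitivity (released detected as `">"`,
#' suppressed as `"<"`) and the false-positive rate on neutral pairs.
#'
#' @param assignments Data frame from [classify_otus()] (or any frame
#'   with `otu_id`, `treatment`, `step1_call`).
#' @param truth Truth labels (`otu_id`, `treatment`, `label`).
#' @return List with `confusion` (label x call table),
#'   `sensitivity_released`, `sensitivity_suppressed` (NA when no such
#'   pairs exist) and `false_positive_rate`.
#' @export
benchmark_against_truth <- function(assignments, truth) {
  m <- merge(assignments[, c("otu_id", "treatment", "step1_call")],
             truth, by = c("otu_id", "treatment"))
  if (!nrow(m)) stop("truth and assignment OTU sets are disjoint",
                     call. = FALSE)
  confusion <- table(label = factor(m$label, c("released", "suppressed",
                                               "neutral")),
                     call = factor(m$step1_call, c(">", "<", "=")))
  rate <- function(cond, hit) {
    n <- sum(cond)
    if (n == 0) NA_real_ else sum(cond & hit) / n
  }
  list(confusion = confusion,
       sensitivity_released = rate(m$label == "released",
                                   m$step1_call == ">"),
       sensitivity_suppressed = rate(m$label == "suppressed",
                                     m$step1_call == "<"),
       false_positive_rate = rate(m$label == "neutral",
                                  m$step1_call != "="))
}
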