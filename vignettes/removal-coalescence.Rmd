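---
title: "Methods: differential fitness in removal/coalescence experiments"
author: "microcoalesce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential fitness in removal/coalescence experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(microcoalesce)
```

## The experimental design and what the package estimates

A soil community is depleted by one of 18 removal treatments and
reinoculated into sterile soil beside an untreated control `C`
(Step 1, 19 groups x 10 replicates = 190 microcosms, incubated 45
days). Ten removal treatments are carried forward: each is mixed with
itself (`R+R`), mixed with the control community (`R+C`), and the
control is mixed with itself (`C+C`), giving 21 Step-2 groups x 10
replicates = 210 microcosms incubated for another 45 days
(`build_design()` reproduces exactly this layout and its treatment
roster).

The quantity of interest is an OTU's *relative fitness*: the change in
its relative abundance in a manipulated community compared with the
control after recolonization. An OTU that rises when part of the
community is removed (`R > C`), keeps that gain when the depleted
community is mixed with itself (`R+R > C+C`), and loses it when the
full community is reintroduced (`R+C = C+C`) behaves exactly as if a
suppressive biotic interaction had been removed and then restored;
the package's classifier makes that chain of reasoning explicit and
countable.

## Per-OTU count model

Counts are fitted OTU by OTU. For Step 1,

$$Y_{ik} \sim \mathcal{P}(\Lambda_{ik}), \qquad
\log \Lambda_{ik} = o_{ik} + \mu + \alpha_i + Z_{ik}, \qquad
Z_{ik} \overset{iid}{\sim} \mathcal{N}(0, \sigma^2)$$

with $o_{ik}$ the log read sum of the sample, so that $\mu$ and
$\alpha_i$ act on log relative abundance, and $Z$ an observation-level
random effect that turns the Poisson into a Poisson-lognormal and
absorbs the overdispersion amplicon counts always show. The control is
the reference level ($\alpha_C = 0$). For Step 2 a group-level term is
added:

$$\log \Lambda_{ijk} = o_{ijk} + \mu + \beta_{ij} + C_{ij} + Z_{ijk},
\qquad C \sim \mathcal{N}(0, \sigma_C^2 K).$$

**Kinship matrix.** $K$ encodes how much two Step-2 groups share
source material. We build the groups-by-sources mixing matrix $S$
(rows are Step-2 groups, entries the mixing fractions of each Step-1
parent) and set $K = S S^\top$ with the diagonal then fixed at 1: a
self-mix `R+R` and the coalescence `R+C` of the same removal have
kinship 0.5, as do `R+C` and `C+C`, while self-mixes of different
removals are unrelated. This is one defensible reading of "degree of
kinship"; it is configurable (`kinship_matrix()` output can be
replaced) because group-level effect and fixed effect share indexing
here, so $\sigma_C^2$ is identified only through the correlation
structure of $K$. A boundary estimate $\hat\sigma_C^2 = 0$ is
expected and common — the fit logs a message when the profile
likelihood is flat in $\sigma_C^2$ — and `fit_step2()` then reduces
exactly to the Step-1 fit.

**Estimation.** The observation-level effect makes the Step-1 marginal
likelihood factor into one-dimensional integrals, evaluated by
adaptive Gauss–Hermite quadrature (25 nodes by default; 41 nodes
changes shipped fixtures by under 1e-6). The Step-2 joint random
vector does not factor and is integrated by a Laplace approximation:
the mode comes from a damped penalized Poisson (Newton/IRLS)
regression with the fixed effects profiled in, the curvature from the
negative Hessian of the random-effect block. Optimization is bounded
quasi-Newton on (fixed effects, $\log\sigma$, $\log\sigma_C$) with
relative tolerance 1e-10, up to three seeded random restarts on
non-convergence; $\sigma^2$ is reported as exactly 0 below 1e-6
(1e-5 for $\sigma_C^2$, whose profile is flatter). Fixed-effect
covariance comes from the full observed information (Step 1) or the
Schur complement of the joint-mode Hessian (Step 2). All-zero OTUs are
refused by the fitters and routed to the zero-abundance test.

## Contrasts

`estimated_means()` maps the fit onto per-level linear predictors at a
common offset of zero. `tukey_pairwise()` computes Wald z statistics
for every pair of levels — an asymptotic z, not t, reference, since a
Poisson GLMM has no residual-degrees-of-freedom notion — and adjusts
them single-step: the adjusted p of a contrast is the probability that
the maximum absolute standardized contrast across the whole family
exceeds the observed one under the joint normal law with the estimated
correlation. That tail is evaluated by Monte-Carlo with a fixed seed
(20230304, 2e4 draws by default) so results are reproducible bit for
bit; observed statistics beyond Monte-Carlo resolution fall back to
the Bonferroni bound, which upper-bounds the single-step p. The
adjustment family is *all* pairwise contrasts of the fitted factor
(171 pairs in Step 1, 210 in Step 2); the four analysis families —
`R vs C`, `R+R vs C+C`, `R+C vs R+R`, `R+C vs C+C` — are selected
*afterwards* without re-adjustment (`scope = "selected"` flips this
and adjusts only within the selected families). Significance is
`p_adj <= 0.05` on the adjusted scale. No adjustment is made across
OTUs: the familywise guarantee is per OTU and model, which is the
convention this analysis follows; consumers wanting genome-wide error
control should correct downstream.

**Zero-abundance fallback.** Wald contrasts degenerate when an OTU is
entirely absent from a group. When additionally the other group's
median count is at least 5, a 1-df likelihood-ratio test of equal
versus group-specific rates replaces the Wald row ("null abundance"
is read as all replicates zero; the median is over the comparison
group's replicates). The mixed (Poisson-lognormal) likelihood is used
by default since that is the model everywhere else; a closed-form
plain-Poisson variant is available (`likelihood = "poisson"`) for
comparison. Its p-value is not multiplicity-adjusted (`p_adj =
p_raw`), which the output marks via `method = "lrt"`.

## Dominance filter and rarefaction

`filter_dominant()` keeps OTUs that (a) exceed 0.5% of a sample's
reads in at least one sample — strictly, and against the *full-table*
sample depth, since computing the share against a post-filter depth
would make the filter circular — and (b) occur (count ≥ 1) in at least
`ceiling(0.6 * n_k)` replicates of some treatment group. Differential
abundance models run on filtered, *unrarefied* counts with read-sum
offsets; diversity metrics run on rarefied tables
(`rarefy_counts()`, a single recorded-seed draw without replacement,
dropping samples below the target with a warning) — mirroring the
usual separation between model-based and resampling-based
normalization.

## Classifier and summaries

Four directional calls per OTU x removal treatment — `R vs C`,
`R+R vs C+C`, `R+C vs R+R`, `R+C vs C+C` — determine one category:

| step1 | step2 | R+C vs C+C | category |
|-------|-------|------------|----------|
| = | = | any | unaffected |
| >/< | = | any | transient |
| = | >/< | any | step2_only |
| same direction | same direction | = | persistent_recovered |
| same direction | same direction | >/< | persistent_unrecovered |
| > | < (or < / >) | any | sign_reversed |

`sign_reversed` is not part of the interaction-validation logic but is
needed so categories partition all $3^4 = 81$ call patterns; it is
rare in practice and worth inspecting when it occurs. Emergent
density-dependence flags (`R+C` above or below *both* sources) are
recorded alongside, not instead of, the category.

`summarize_categories()` reports every tally twice: per treatment (an
OTU counts once per treatment where the pattern holds) and unique OTUs
(once regardless). The two differ exactly when OTUs respond under
several treatments — including in opposite directions, which is why
per-direction tallies can sum to more than their unique union; both
are always reported to avoid the ambiguity. An OTU significant in
opposite directions under different treatments enters the unique
persistent pool once (union over both directions). Headline ratios:
released fraction (unique `step1 >` over all filtered OTUs), recovered
fraction (unique persistent-recovered over unique persistent), and the
validated-positive fraction (the full `> / > / =` chain over all
filtered OTUs). Percentages round to one decimal, half away from zero.

## Community metrics

Alpha diversity: observed OTUs, Shannon ($-\sum p \ln p$, natural log
— the base is a convention and is stated rather than assumed), inverse
Simpson, and Faith PD (branch lengths of the subtree spanning root and
present leaves). Beta diversity: *normalized* weighted UniFrac, chosen
because its distances live in [0, 1] so similarity can be reported as
one minus distance; the variant question (raw vs normalized) is
settled by that range requirement. PERMANOVA uses the among/within
decomposition of squared distances with label permutations
(`p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})`, 999 permutations and a
recorded seed by default; an exhaustive mode enumerates all
permutations for exact tails on small problems). Community recovery
per coalescence treatment, from BH-corrected pairwise PERMANOVA at
0.05: *full* if `R+C` is indistinguishable from `C+C`; *partial* if
distinguishable from both `C+C` and `R+R`; *none* otherwise.

## Synthetic data: what it emulates and what it does not

The parametric generator draws straight from the fitted model
(lognormal depths, Poisson-lognormal counts, kinship-correlated
Step-2 group effects) and is the oracle for estimator calibration. The
mechanistic generator grows each community with Ricker (discrete
Lotka–Volterra) dynamics,
$n_s(t+1) = n_s(t)\exp(r_s + \sum_u A_{su} n_u(t))$ — chosen over ODE
integration because it is exact, fast and positivity-preserving, with
one step per incubation day (T = 45). Removal treatments act as
survival fractions on the inoculum; Step-2 microcosms start from the
dilution (0.1) of a 50/50 mixture of Step-1 endpoints, pairing
replicate k with replicate k (the physical pairing of microcosms is
not recorded in such experiments; fixed pairing is an assumption that
keeps the kinship structure simple). Reads are multinomial at
lognormal depth (median 16215 reads, log-sd 0.3, the prokaryote-like
profile). Replicate variability enters as lognormal jitter (sd 0.1) on
initial abundances, producing exactly the within-group extra-Poisson
noise the observation-level effect is meant to absorb. Ground-truth
labels come from the noise-free dynamics: released (suppressed) if the
endpoint relative abundance is at least θ = 1.5-fold above (below) the
control's — θ is arbitrary, documented, and configurable.

What the generators do *not* emulate: taxon-specific sequencing bias,
spatial structure, dormancy, abiotic feedbacks (the pH shifts real
heat/pH treatments cause are a finding about soil, not a property of
the samplers), or taxonomy (class-level summaries need real
assignments and are out of scope). Passing tests therefore demonstrate
statistical correctness of the estimators and the classifier under the
stated model, not robustness to every artifact of real amplicon data.

One property of the *analysis* (not a simulator artifact) deserves
emphasis: because effects act on relative abundance, strongly released
OTUs depress everyone else's share. In simulations where a large
fraction of the community is planted with gains, unaffected OTUs are
legitimately called depleted. The shipped toy configuration keeps the
planted mass small so this compositional coupling stays below the
detection threshold; real analyses should read `<` calls with the same
caveat in mind.

## Numerical choices and test problem sizes

Fits use 25 quadrature nodes, tolerance 1e-10, effects bounded in
[-30, 30] (an all-zero *group* drives its effect to the bound; the
likelihood plateaus and the fit converges). Monte-Carlo adjustment
seed 20230304. Degenerate per-OTU fits never abort a pipeline run;
they are tallied and emitted as `method = "none"` rows.

The test suite validates estimator calibration at the experiment's own
scale where the claim depends on it — 200 simulated OTUs at the full
190-sample Step-1 design for effect recovery and a 500-OTU global null
for familywise error (observed in the low percents, well inside the 7%
tolerance the calibration test enforces) —
and uses reduced designs (2–8 treatments, 3–10 replicates) everywhere
the property being checked is scale-free, keeping the default suite
around four minutes on one core. Oracles are independent of the code
paths they check: dense-grid trapezoid and brute-force Monte-Carlo
integration for the marginal likelihoods, an independently written
81-row truth table for the classifier, naive double-loop
reimplementations for UniFrac and diversity, exhaustive permutation
enumeration for PERMANOVA, and lme4/vegan as external cross-checks.

## Known limitations

* $\beta_{ij}$ and $C_{ij}$ are confounded at $\sigma_C^2 > 0$;
  identification rests entirely on $K$, and the package deliberately
  reports boundary estimates rather than forcing a positive variance.
* The single-step adjustment treats the estimated contrast covariance
  as known (as all Wald-type post hoc procedures do); with 10
  replicates this is an approximation, and the global-null calibration
  test is the guard on its practical error rate.
* The LRT fallback's chi-square reference is asymptotic and its
  boundary case (a rate tending to zero) is handled by bounding the
  effect scale; its p-values are intentionally left unadjusted.
* No correction across OTUs; see the contrasts section.
* `sign_reversed` and emergent flags are descriptive outputs without a
  mechanistic interpretation in the two-step logic.
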