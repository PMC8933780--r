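#' Specify a synthetic respondent group
#'
#' @param label Group label (`"HC"`, `"IA"`, or any string).
#' @param n_participants Number of respondents (>= 1).
#' @param cni Numeric `c(C, N, I)`, the group-level tree parameters driving
#'   every response.
#' @param heterogeneity_sd Between-participant SD on the logit scale; 0 gives
#'   a homogeneous group whose responses are exactly Bernoulli draws at the
#'   group tree probabilities.
#' @param yiat_range Integer interval the simulated YIAT score is drawn from
#'   uniformly; defaults to the label's cutoff region (`HC`: 20-40, `IA`:
#'   50-100, otherwise 20-100).
#' @return A `group_spec` list.
#' @export
group_spec <- function(label, n_participants, cni,
                       heterogeneity_sd = 0, yiat_range = NULL) {
  stopifnot(n_participants >= 1, length(cni) == 3,
            all(cni >= 0 & cni <= 1), heterogeneity_sd >= 0)
  if (is.null(yiat_range)) {
    yiat_range <- switch(label, HC = c(20L, 40L), IA = c(50L, 100L),
                         c(20L, 100L))
  }
  stopifnot(yiat_range[1] >= 20, yiat_range[2] <= 100,
            yiat_range[1] <= yiat_range[2])
  structure(list(label = label, n_participants = n_participants,
                 cni = stats::setNames(as.numeric(cni), c("C", "N", "I")),
                 heterogeneity_sd = heterogeneity_sd,
                 yiat_range = yiat_range),
            class = "group_spec")
}

# logit-normal perturbation keeping draws in (0,1); exact identity when sd = 0
# so degenerate parameters 0 and 1 are preserved
perturb_logit <- function(p, sd) {
  if (sd == 0) return(p)
  eps <- 1e-6
  stats::plogis(stats::qlogis(pmin(pmax(p, eps), 1 - eps)) +
                  stats::rnorm(length(p), 0, sd))
}

#' Simulate trial-level dilemma batteries for one or more groups
#'
#' Each participant receives individual `(C, N, I)` values — the group values
#' perturbed logit-normally when `heterogeneity_sd > 0` — and answers all 24
#' scenarios of [battery_design()] with independent Bernoulli draws at the
#' CNI tree probability of the scenario's condition. YIAT scores are drawn
#' uniformly within each group's range; the remaining covariates are filled
#' with unremarkable values (age about 19, no nicotine/alcohol dependence)
#' so the profile table is complete.
#'
#' @param specs A `group_spec` or list of them.
#' @param seed Integer seed; the whole simulation runs off one stream, so a
#'   given seed reproduces the output exactly.
#' @return List with `trials` and `profiles` data frames in the formats
#'   consumed by [aggregate_counts()] and friends.
#' @examples
#' sim <- simulate_trials(group_spec("HC", 5, c(0.2, 0.3, 0.45)), seed = 1)
#' nrow(sim$trials)  # 120
#' @export
simulate_trials <- function(specs, seed) {
  if (inherits(specs, "group_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1, is.numeric(seed))
  set.seed(as.integer(seed))
  design <- battery_design()
  trials <- list(); profiles <- list()
  pid <- 0L
  for (sp in specs) {
    for (i in seq_len(sp$n_participants)) {
      pid <- pid + 1L
      id <- sprintf("P%04d", pid)
      par <- perturb_logit(sp$cni, sp$heterogeneity_sd)
      p <- cni_probability(par[1], par[2], par[3],
                           design$norm_type, design$consequence_dir)
      trials[[pid]] <- data.frame(
        participant_id = id,
        dilemma_id = design$dilemma_id,
        norm_type = design$norm_type,
        consequence_dir = design$consequence_dir,
        response = stats::rbinom(nrow(design), 1L, p),
        stringsAsFactors = FALSE)
      profiles[[pid]] <- data.frame(
        participant_id = id,
        yiat = sample(sp$yiat_range[1]:sp$yiat_range[2], 1L),
        age = round(stats::rnorm(1, 19.1, 0.75), 1),
        education_years = sample(12:16, 1L),
        gender = sample(c("male", "female"), 1L),
        ftnd = 0L,
        audit = sample(0:3, 1L),
        stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, trials)
  profiles <- do.call(rbind, profiles)
  profiles$group <- classify_group(profiles$yiat)
  list(trials = trials, profiles = profiles)
}

#' Fill simulated difficulty ratings
#'
#' A simple additive rating model on the 1-5 scale:
#' `clip(round(3 + conflict_effect * [proscriptive & benefits greater]
#' + group_effect * [IA] + noise), 1, 5)`. The conflict indicator marks the
#' incongruent proscriptive dilemmas, where norm and consequences pull in
#' opposite directions.
#'
#' @param trials Trial data frame.
#' @param profiles Profile data frame with `group` (for the IA indicator).
#' @param conflict_effect,group_effect Additive shifts in rating points.
#' @param noise_sd SD of the Gaussian rating noise.
#' @param seed Integer seed.
#' @return `trials` with a `difficulty` column filled.
#' @export
simulate_difficulty <- function(trials, profiles, conflict_effect = 0,
                                group_effect = 0, noise_sd = 0, seed = 1) {
  set.seed(as.integer(seed))
  conflict <- trials$norm_type == "proscriptive" &
    trials$consequence_dir == "benefits_greater"
  ia <- profiles$group[match(trials$participant_id,
                             profiles$participant_id)] == "IA"
  raw <- 3 + conflict_effect * conflict + group_effect * ia +
    stats::rnorm(nrow(trials), 0, noise_sd)
  trials$difficulty <- pmin(pmax(as.integer(round(raw)), 1L), 5L)
  trials
}

#' Parameter-recovery experiment for the CNI estimator
#'
#' Repeatedly simulates a battery at known `(C, N, I)`, aggregates it, refits
#' the model, and summarizes estimation error and Wald interval coverage —
#' the standard validation for processing-tree estimators.
#'
#' @param cni True `c(C, N, I)`.
#' @param n_participants Respondents per replicate (6 trials per condition
#'   each).
#' @param replicates Number of Monte Carlo replicates.
#' @param seed Integer seed for the whole experiment.
#' @param heterogeneity_sd Between-participant SD on the logit scale.
#' @param n_starts Optimizer starts per fit (recovery surfaces are smooth;
#'   fewer starts than [fit_cni()]'s default are typically enough).
#' @param level Nominal confidence level whose coverage is tracked.
#' @return List: `results` (one row per replicate and parameter: estimate,
#'   error, CI, covered), `summary` (per parameter: bias, RMSE, coverage),
#'   `n_failed`.
#' @export
recovery_experiment <- function(cni, n_participants, replicates, seed,
                                heterogeneity_sd = 0, n_starts = 4,
                                level = 0.95) {
  stopifnot(replicates >= 1)
  set.seed(as.integer(seed))
  truth <- stats::setNames(as.numeric(cni), c("C", "N", "I"))
  rows <- list(); n_failed <- 0L
  for (r in seq_len(replicates)) {
    rep_seed <- sample.int(2^31 - 1, 1)
    sim <- simulate_trials(
      group_spec("sim", n_participants, truth,
                 heterogeneity_sd = heterogeneity_sd), seed = rep_seed)
    counts <- aggregate_counts(sim$trials)
    fit <- tryCatch(fit_cni(counts, n_starts = n_starts, level = level),
                    error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    est <- fit$estimates
    rows[[length(rows) + 1L]] <- data.frame(
      replicate = r, parameter = est$parameter,
      truth = unname(truth[est$parameter]),
      estimate = est$estimate,
      error = est$estimate - unname(truth[est$parameter]),
      lower = est$lower, upper = est$upper,
      covered = est$lower <= unname(truth[est$parameter]) &
        unname(truth[est$parameter]) <= est$upper,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(c("C", "N", "I"), function(p) {
    e <- results$error[results$parameter == p]
    data.frame(parameter = p, bias = mean(e), rmse = sqrt(mean(e^2)),
               coverage = mean(results$covered[results$parameter == p]),
               stringsAsFactors = FALSE)
  }))
  list(results = results, summary = summary, n_failed = n_failed)
}
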