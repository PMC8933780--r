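#' Run the full moral-dilemma analysis pipeline
#'
#' Executes the four analysis stages in order on a trial-level battery:
#' traditional utilitarian scores (one-sample tests against the neutral
#' point of 3 per group, pooled-variance between-group test), process
#' dissociation (U/D per participant, pooled standardization, mixed 2x2
#' group-by-parameter ANOVA with simple effects, YIAT correlations by both
#' Spearman and Pearson), the CNI model (pooled fit with C=0, N=0, I=0.5
#' constraint tests; per-group fit with cross-group equality tests), and —
#' when difficulty ratings are present — the mixed ANOVA on decision
#' difficulty in the congruent vs incongruent proscriptive dilemmas.
#'
#' @param trials Trial data frame, or `NULL` to read from `trials_path`.
#' @param profiles Profile data frame with `yiat` (a `group` column is
#'   recomputed from `cutoffs`), or `NULL` to read from `profiles_path`.
#' @param trials_path,profiles_path CSV paths used when the data frames are
#'   not given directly.
#' @param cutoffs YIAT group cutoffs, see [classify_group()].
#' @param n_starts Optimizer starts for every CNI fit.
#' @param out_dir If non-`NULL`, per-stage tables are written there as CSV
#'   (`pd_scores.csv`, `condition_counts.csv`, `cni_estimates.csv`).
#' @return Object of class `dilemma_report`; print it for the full summary.
#' @export
run_full_analysis <- function(trials = NULL, profiles = NULL,
                              trials_path = NULL, profiles_path = NULL,
                              cutoffs = c(40L, 50L), n_starts = 10,
                              out_dir = NULL) {
  if (is.null(trials)) {
    loaded <- read_trials(trials_path, profiles_path, cutoffs = cutoffs)
    trials <- loaded$trials
    profiles <- loaded$profiles
  }
  if (is.null(profiles)) stop("a participant table with yiat scores is required")
  profiles$group <- classify_group(profiles$yiat, cutoffs = cutoffs)
  n_excluded <- sum(profiles$group == "excluded")
  keep <- profiles$participant_id[profiles$group != "excluded"]
  trials <- trials[trials$participant_id %in% keep, , drop = FALSE]
  analyzed <- profiles[profiles$group != "excluded", , drop = FALSE]
  grp_of <- function(ids) analyzed$group[match(ids, analyzed$participant_id)]

  # --- traditional analysis -------------------------------------------------
  ts <- traditional_scores(trials)
  ts$group <- grp_of(ts$participant_id)
  by_grp <- split(ts$score, ts$group)
  traditional <- list(
    scores = ts,
    neutral = lapply(by_grp, neutral_point_test, mu0 = 3),
    between = if (length(by_grp) == 2) {
      group_difference_test(by_grp[["HC"]], by_grp[["IA"]])
    })

  # --- process dissociation -------------------------------------------------
  pd <- standardize_pd(pd_scores(pd_probabilities(trials)))
  pd$group <- grp_of(pd$participant_id)
  pd_long <- rbind(
    data.frame(participant_id = pd$participant_id, group = pd$group,
               condition = "U", value = pd$z_U, stringsAsFactors = FALSE),
    data.frame(participant_id = pd$participant_id, group = pd$group,
               condition = "D", value = pd$z_D, stringsAsFactors = FALSE))
  pd_anova <- if (length(unique(pd$group)) == 2) mixed_anova_2x2(pd_long)
  yiat <- analyzed$yiat[match(pd$participant_id, analyzed$participant_id)]
  correlations <- list(
    yiat_D_spearman = correlation_test(yiat, pd$D, method = "spearman"),
    yiat_D_pearson = correlation_test(yiat, pd$D, method = "pearson"),
    yiat_U_spearman = correlation_test(yiat, pd$U, method = "spearman"),
    yiat_U_pearson = correlation_test(yiat, pd$U, method = "pearson"))

  # --- CNI model ------------------------------------------------------------
  pooled_counts <- aggregate_counts(trials, analyzed, grouping = "pooled")
  group_counts <- aggregate_counts(trials, analyzed, grouping = "by_group")
  cni <- list(
    pooled = fit_cni(pooled_counts, n_starts = n_starts),
    pooled_tests = list(
      C0 = test_cni_constraint(pooled_counts, "C", "fix_value", 0,
                               n_starts = n_starts),
      N0 = test_cni_constraint(pooled_counts, "N", "fix_value", 0,
                               n_starts = n_starts),
      I_half = test_cni_constraint(pooled_counts, "I", "fix_value", 0.5,
                                   n_starts = n_starts)),
    by_group = fit_cni(group_counts, n_starts = n_starts),
    group_tests = if (length(unique(group_counts$group)) == 2) {
      lapply(stats::setNames(nm = c("C", "N", "I")), function(p)
        test_cni_constraint(group_counts, p, "equate_across_groups",
                            n_starts = n_starts))
    })

  # --- difficulty -----------------------------------------------------------
  difficulty <- NULL
  if ("difficulty" %in% names(trials) && any(!is.na(trials$difficulty))) {
    pro <- trials[trials$norm_type == "proscriptive" &
                    !is.na(trials$difficulty), , drop = FALSE]
    mean_diff <- stats::aggregate(
      difficulty ~ participant_id + consequence_dir, data = pro, FUN = mean)
    diff_long <- data.frame(
      participant_id = mean_diff$participant_id,
      group = grp_of(mean_diff$participant_id),
      condition = ifelse(mean_diff$consequence_dir == "benefits_greater",
                         "incongruent", "congruent"),
      value = mean_diff$difficulty, stringsAsFactors = FALSE)
    difficulty <- if (length(unique(diff_long$group)) == 2) {
      mixed_anova_2x2(diff_long)
    }
  }

  report <- structure(
    list(n_by_group = table(analyzed$group), n_excluded = n_excluded,
         cutoffs = cutoffs, traditional = traditional, pd = pd,
         pd_anova = pd_anova, correlations = correlations, cni = cni,
         difficulty = difficulty, counts = group_counts),
    class = "dilemma_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(pd, file.path(out_dir, "pd_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(group_counts,
                     file.path(out_dir, "condition_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(cni$by_group$estimates,
                     file.path(out_dir, "cni_estimates.csv"),
                     row.names = FALSE)
  }
  report
}

#' @export
print.dilemma_report <- function(x, ...) {
  cat("== Moral dilemma analysis report ==\n")
  cat("Participants:", paste(names(x$n_by_group), as.integer(x$n_by_group),
                             sep = " = ", collapse = ", "),
      sprintf("(%d excluded by YIAT cutoffs %d-%d)\n", x$n_excluded,
              x$cutoffs[1], x$cutoffs[2]))
  cat("\n-- Traditional utilitarian score (0-6, neutral 3) --\n")
  for (g in names(x$traditional$neutral)) {
    cat(sprintf("  %s vs 3: ", g)); print(x$traditional$neutral[[g]])
  }
  if (!is.null(x$traditional$between)) {
    cat("  HC vs IA: "); print(x$traditional$between)
  }
  cat("\n-- Process dissociation (standardized U, D) --\n")
  if (!is.null(x$pd_anova)) print(x$pd_anova)
  for (nm in names(x$correlations)) {
    cat("  YIAT ~", sub("yiat_", "", nm), ": ")
    print(x$correlations[[nm]])
  }
  cat("\n-- CNI model --\n")
  print(x$cni$pooled)
  for (nm in names(x$cni$pooled_tests)) print(x$cni$pooled_tests[[nm]])
  print(x$cni$by_group)
  if (!is.null(x$cni$group_tests)) {
    for (nm in names(x$cni$group_tests)) print(x$cni$group_tests[[nm]])
  }
  if (!is.null(x$difficulty)) {
    cat("\n-- Decision difficulty (proscriptive congruent vs incongruent) --\n")
    print(x$difficulty)
  }
  invisible(x)
}
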