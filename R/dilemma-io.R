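#' Read a trial-level dilemma battery and its participant table
#'
#' Both files are comma-separated UTF-8 text with a mandatory header row.
#' The trial file has columns `participant_id`, `dilemma_id`, `norm_type`
#' (`proscriptive`/`prescriptive`), `consequence_dir`
#' (`benefits_greater`/`benefits_smaller`), `response` (0 = refuse,
#' 1 = accept) and optionally `difficulty` (integer 1-5, may be empty).
#' The participant file has columns `participant_id`, `yiat`, and optionally
#' `age`, `education_years`, `gender`, `ftnd`, `audit`.
#'
#' Every participant is expected to contribute one trial per cell of
#' [battery_design()] (24 in all); participants with incomplete batteries are
#' reported in the `incomplete` attribute and via a warning listing the
#' missing (dilemma, norm, consequence) triples.
#'
#' @param trials_path Path to the trial-level CSV.
#' @param profiles_path Path to the participant CSV, or `NULL` to read trials
#'   only.
#' @param cutoffs Length-2 numeric, the YIAT group cutoffs passed to
#'   [classify_group()].
#' @return A list with elements `trials` (data frame of validated trial
#'   records, row order preserved), `profiles` (data frame with a `group`
#'   column added, or `NULL`), and `incomplete` (data frame of missing
#'   scenario triples, zero rows when all batteries are complete).
#' @seealso [write_trials()], [aggregate_counts()]
#' @export
read_trials <- function(trials_path, profiles_path = NULL,
                        cutoffs = c(40L, 50L)) {
  if (!file.exists(trials_path)) {
    stop("trial file not found: ", trials_path)
  }
  trials <- utils::read.csv(trials_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  required <- c("participant_id", "dilemma_id", "norm_type",
                "consequence_dir", "response")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols)) {
    stop("trial file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  # +1 for the header row so reported line numbers match the file
  line_of <- function(i) i + 1L

  check_enum <- function(values, allowed, column) {
    bad <- which(!values %in% allowed)
    if (length(bad)) {
      stop(sprintf("line %d, column '%s': unknown value '%s' (expected %s)",
                   line_of(bad[1]), column, values[bad[1]],
                   paste(allowed, collapse = "/")))
    }
  }
  check_enum(trials$norm_type, NORM_TYPES, "norm_type")
  check_enum(trials$consequence_dir, CONSEQUENCE_DIRS, "consequence_dir")
  check_enum(trials$response, c("0", "1"), "response")
  trials$response <- as.integer(trials$response)

  if ("difficulty" %in% names(trials)) {
    diff_chr <- trials$difficulty
    blank <- is.na(diff_chr) | diff_chr == ""
    bad <- which(!blank & !diff_chr %in% as.character(1:5))
    if (length(bad)) {
      stop(sprintf("line %d, column 'difficulty': value '%s' not in 1..5",
                   line_of(bad[1]), diff_chr[bad[1]]))
    }
    trials$difficulty <- ifelse(blank, NA_integer_, as.integer(diff_chr))
  }

  incomplete <- battery_completeness(trials)
  if (nrow(incomplete)) {
    warning(sprintf(
      "%d participant(s) with incomplete batteries; first missing scenario: %s / %s / %s",
      length(unique(incomplete$participant_id)),
      incomplete$dilemma_id[1], incomplete$norm_type[1],
      incomplete$consequence_dir[1]))
  }

  profiles <- NULL
  if (!is.null(profiles_path)) {
    if (!file.exists(profiles_path)) {
      stop("participant file not found: ", profiles_path)
    }
    profiles <- utils::read.csv(profiles_path, stringsAsFactors = FALSE)
    if (!all(c("participant_id", "yiat") %in% names(profiles))) {
      stop("participant file must have columns participant_id and yiat")
    }
    profiles$participant_id <- as.character(profiles$participant_id)
    profiles$group <- classify_group(profiles$yiat, cutoffs = cutoffs)
    unknown <- setdiff(unique(trials$participant_id), profiles$participant_id)
    if (length(unknown)) {
      stop("trials reference participant(s) absent from the profile table: ",
           paste(utils::head(unknown, 3), collapse = ", "))
    }
  }

  list(trials = trials, profiles = profiles, incomplete = incomplete)
}

#' Write trial records back to delimited text
#'
#' Inverse of the trial half of [read_trials()]: a written file read back
#' reproduces the records field for field.
#'
#' @param trials Data frame of trial records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# missing (participant, dilemma, norm, consequence) combinations vs the
# 24-cell design grid
battery_completeness <- function(trials) {
  design <- battery_design()
  out <- lapply(split(trials, trials$participant_id), function(tp) {
    have <- paste(tp$dilemma_id, tp$norm_type, tp$consequence_dir)
    need <- paste(design$dilemma_id, design$norm_type, design$consequence_dir)
    miss <- design[!need %in% have, , drop = FALSE]
    if (nrow(miss)) cbind(participant_id = tp$participant_id[1], miss)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(participant_id = character(), dilemma_id = character(),
                      norm_type = character(), consequence_dir = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Assign study group from a YIAT total score
#'
#' Young's Internet Addiction Test totals range over 20-100. Scores at or
#' below the lower cutoff are healthy controls (`HC`), scores at or above the
#' upper cutoff are the internet-addiction group (`IA`), and scores in the
#' gap are `excluded` from analysis.
#'
#' @param yiat Integer vector of YIAT total scores in \[20, 100\].
#' @param cutoffs Length-2 numeric `c(low, high)`; defaults to `c(40, 50)`.
#' @return Character vector in `{"HC", "IA", "excluded"}`.
#' @examples
#' classify_group(c(40, 45, 50))
#' @export
classify_group <- function(yiat, cutoffs = c(40L, 50L)) {
  stopifnot(length(cutoffs) == 2, cutoffs[1] < cutoffs[2])
  if (any(is.na(yiat)) || any(yiat < 20 | yiat > 100)) {
    stop("yiat scores must lie in [20, 100]")
  }
  ifelse(yiat <= cutoffs[1], "HC", ifelse(yiat >= cutoffs[2], "IA", "excluded"))
}

#' Aggregate trial-level responses to condition counts
#'
#' Pools acceptances within each (norm, consequence) condition, the
#' sufficient statistic for the CNI binomial likelihood. Participants whose
#' profile group is `excluded` are dropped before counting.
#'
#' @param trials Data frame of trial records.
#' @param profiles Participant table with `participant_id` and `group`
#'   columns, or `NULL` (then all participants are pooled under group
#'   `"pooled"`).
#' @param grouping `"pooled"` to collapse groups or `"by_group"` to keep one
#'   set of four condition counts per group.
#' @return Data frame with columns `group`, `norm_type`, `consequence_dir`,
#'   `action_count`, `total`, four rows per group in the canonical condition
#'   order.
#' @export
aggregate_counts <- function(trials, profiles = NULL,
                             grouping = c("pooled", "by_group")) {
  grouping <- match.arg(grouping)
  trials <- as.data.frame(trials)
  if (is.null(profiles)) {
    if (grouping == "by_group") stop("by_group aggregation requires profiles")
    trials$group <- "pooled"
  } else {
    unknown <- setdiff(unique(trials$participant_id), profiles$participant_id)
    if (length(unknown)) {
      stop("trial references unknown participant: ", unknown[1])
    }
    grp <- profiles$group[match(trials$participant_id,
                                profiles$participant_id)]
    trials$group <- if (grouping == "pooled") "pooled" else grp
    trials <- trials[grp != "excluded", , drop = FALSE]
  }
  cells <- expand.grid(group = unique(trials$group),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(unique(trials$group), function(g) {
    tg <- trials[trials$group == g, , drop = FALSE]
    cg <- condition_grid()
    cg$group <- g
    key_t <- condition_key(tg$norm_type, tg$consequence_dir)
    key_c <- condition_key(cg$norm_type, cg$consequence_dir)
    cg$action_count <- vapply(key_c, function(k)
      sum(tg$response[key_t == k]), integer(1))
    cg$total <- vapply(key_c, function(k) sum(key_t == k), integer(1))
    cg[, c("group", "norm_type", "consequence_dir", "action_count", "total")]
  }))
  rownames(out) <- NULL
  out
}

#' Reconstruct an aggregate acceptance count from a printed condition mean
#'
#' Published summaries report each condition as a mean 0-6 score (acceptances
#' out of 6 trials) per participant, to two decimals. With the group size
#' known, the underlying aggregate acceptance count is the integer `a`
#' minimizing `|a/n - mean|`; it is accepted only when it is the unique
#' integer whose recomputed mean rounds back to the printed value (half-cent
#' window, since two decimals are printed).
#'
#' @param mean Printed condition mean in \[0, 6\].
#' @param n_participants Group size.
#' @return A list with `action_count` (acceptances summed over the group) and
#'   `total` (`6 * n_participants`).
#' @examples
#' counts_from_condition_means(2.29, 38)  # 87 of 228
#' @export
counts_from_condition_means <- function(mean, n_participants) {
  stopifnot(length(mean) == 1, length(n_participants) == 1)
  if (mean < 0 || mean > 6) stop("condition mean must lie in [0, 6]")
  if (n_participants < 1) stop("n_participants must be positive")
  n <- as.integer(n_participants)
  cand <- 0:(6L * n)
  ok <- cand[abs(cand / n - mean) < 0.005]
  ok <- ok[round(ok / n, 2) == round(mean, 2)]
  if (length(ok) == 0) {
    stop(sprintf("no integer count reproduces the printed mean %.2f for n = %d",
                 mean, n))
  }
  if (length(ok) > 1) {
    stop(sprintf(
      "ambiguous reconstruction: counts %s all round to mean %.2f for n = %d",
      paste(ok, collapse = ", "), mean, n))
  }
  list(action_count = ok, total = 6L * n)
}

#' Reconstruct a full condition-count table from printed group means
#'
#' Applies [counts_from_condition_means()] to a table of printed condition
#' means, one row per group, producing the count table consumed by
#' [fit_cni()].
#'
#' @param means Data frame with columns `group`, `n`, and the four condition
#'   means `pro_greater`, `pro_smaller`, `pre_greater`, `pre_smaller`
#'   (proscriptive/prescriptive norm crossed with benefits greater/smaller),
#'   e.g. [example_study_means()].
#' @param pooled If `TRUE`, additionally sum the per-group counts into a
#'   single `"pooled"` group and return only that.
#' @return Condition-count data frame as from [aggregate_counts()].
#' @examples
#' counts_from_means_table(example_study_means(), pooled = TRUE)
#' @export
counts_from_means_table <- function(means, pooled = FALSE) {
  cols <- c("pro_greater", "pro_smaller", "pre_greater", "pre_smaller")
  stopifnot(all(c("group", "n", cols) %in% names(means)))
  out <- do.call(rbind, lapply(seq_len(nrow(means)), function(i) {
    cg <- condition_grid()
    cg$group <- means$group[i]
    rec <- lapply(cols, function(cl)
      counts_from_condition_means(means[[cl]][i], means$n[i]))
    cg$action_count <- vapply(rec, `[[`, integer(1), "action_count")
    cg$total <- vapply(rec, `[[`, integer(1), "total")
    cg[, c("group", "norm_type", "consequence_dir", "action_count", "total")]
  }))
  rownames(out) <- NULL
  if (pooled) {
    cg <- condition_grid()
    key <- condition_key(out$norm_type, out$consequence_dir)
    keyc <- condition_key(cg$norm_type, cg$consequence_dir)
    cg$group <- "pooled"
    cg$action_count <- vapply(keyc, function(k)
      sum(out$action_count[key == k]), integer(1))
    cg$total <- vapply(keyc, function(k) sum(out$total[key == k]), integer(1))
    out <- cg[, c("group", "norm_type", "consequence_dir", "action_count",
                  "total")]
    rownames(out) <- NULL
  }
  out
}

#' Bundled condition means from a two-group internet-addiction study
#'
#' Published condition means (acceptances out of 6, two decimals) for a moral
#' dilemma battery administered to 38 healthy controls and 89 participants
#' meeting an internet-addiction cutoff. These summaries are sufficient to
#' reconstruct the aggregate condition counts exactly via
#' [counts_from_means_table()] and hence to refit the CNI model.
#'
#' @return Data frame with one row per group: `group`, `n`, and the four
#'   condition means `pro_greater`, `pro_smaller`, `pre_greater`,
#'   `pre_smaller`.
#' @export
example_study_means <- function() {
  data.frame(
    group = c("HC", "IA"),
    n = c(38L, 89L),
    pro_greater = c(2.29, 3.24),
    pro_smaller = c(1.82, 2.26),
    pre_greater = c(4.34, 4.09),
    pre_smaller = c(3.74, 3.46),
    stringsAsFactors = FALSE
  )
}
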