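#' Traditional utilitarian scores
#'
#' The traditional dependent variable counts, per participant, the accepted
#' actions among the six scenarios in which a proscriptive norm forbids the
#' action but its benefits exceed its costs; acceptance there is read as a
#' utilitarian judgment, refusal as a deontological one. Scores range 0-6
#' with 3 the neutral point.
#'
#' @param trials Data frame of trial records.
#' @return Data frame with columns `participant_id`, `score`.
#' @export
traditional_scores <- function(trials) {
  rel <- trials[trials$norm_type == "proscriptive" &
                  trials$consequence_dir == "benefits_greater", , drop = FALSE]
  n_per <- table(rel$participant_id)
  if (any(n_per != 6)) {
    stop("participant(s) missing proscriptive/benefits-greater trials: ",
         paste(names(n_per)[n_per != 6], collapse = ", "))
  }
  agg <- stats::aggregate(response ~ participant_id, data = rel, FUN = sum)
  data.frame(participant_id = agg$participant_id,
             score = as.integer(agg$response),
             stringsAsFactors = FALSE)
}

#' One-sample t-test of scores against a neutral reference point
#'
#' @param scores Numeric vector (e.g. the `score` column of
#'   [traditional_scores()]).
#' @param mu0 Null value; 3 is the action/inaction-neutral battery score.
#' @return A `dilemma_ttest` list: `statistic`, `df`, `p`, `effect_size_d`
#'   (Cohen's d = (mean - mu0) / sd), `mean`, `sd`, `n`, `kind`.
#' @examples
#' neutral_point_test(c(2, 2, 2, 4))
#' @export
neutral_point_test <- function(scores, mu0 = 3) {
  scores <- as.numeric(scores)
  if (length(scores) < 2) stop("need at least two scores")
  if (stats::sd(scores) == 0) stop("scores have zero variance")
  tt <- stats::t.test(scores, mu = mu0)
  ttest_result(statistic = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               effect_size_d = (mean(scores) - mu0) / stats::sd(scores),
               kind = "one_sample",
               mean = mean(scores), sd = stats::sd(scores),
               n = length(scores))
}

#' Pooled-variance independent-samples t-test
#'
#' Student (equal-variance) t with `df = n1 + n2 - 2`; Cohen's d uses the
#' pooled SD.
#'
#' @param scores_a,scores_b Numeric vectors for the two groups.
#' @return A `dilemma_ttest` list (see [neutral_point_test()]).
#' @export
group_difference_test <- function(scores_a, scores_b) {
  a <- as.numeric(scores_a); b <- as.numeric(scores_b)
  if (length(a) < 2 || length(b) < 2) stop("both groups need >= 2 scores")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) stop("zero pooled variance; groups are degenerate")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  ttest_result(statistic = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               effect_size_d = (mean(a) - mean(b)) / sqrt(sp2),
               kind = "two_sample_pooled",
               mean = c(mean(a), mean(b)), sd = c(stats::sd(a), stats::sd(b)),
               n = c(length(a), length(b)))
}

ttest_result <- function(statistic, df, p, effect_size_d, kind, ...) {
  structure(list(statistic = statistic, df = df, p = p,
                 effect_size_d = effect_size_d, kind = kind, ...),
            class = "dilemma_ttest")
}

#' @export
print.dilemma_ttest <- function(x, ...) {
  cat(sprintf("t(%s) = %.3f, p = %.4g, Cohen's d = %.3f [%s]\n",
              format(x$df), x$statistic, x$p, x$effect_size_d, x$kind))
  invisible(x)
}

#' Recover a standard deviation from a printed confidence interval of a mean
#'
#' Published tables often report a mean with a t-based confidence interval
#' instead of an SD. The half-width equals `qt((1+level)/2, n-1) * sd /
#' sqrt(n)`, which this inverts.
#'
#' @param lower,upper Interval endpoints.
#' @param n Sample size.
#' @param level Confidence level of the printed interval.
#' @return The implied sample standard deviation.
#' @export
sd_from_ci <- function(lower, upper, n, level = 0.95) {
  stopifnot(upper >= lower, n >= 2)
  half <- (upper - lower) / 2
  half / stats::qt(1 - (1 - level) / 2, n - 1) * sqrt(n)
}
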