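#' Process-dissociation unacceptability proportions per participant
#'
#' The PD analysis uses only the two proscriptive-norm conditions: congruent
#' dilemmas (benefits smaller than costs, so norm and consequences agree in
#' rejecting the action) and incongruent dilemmas (benefits greater, so they
#' conflict). Each proportion is the fraction of the 6 condition trials whose
#' action was judged unacceptable (refused).
#'
#' @param trials Data frame of trial records.
#' @return Data frame with columns `participant_id`, `p_unacc_congruent`,
#'   `p_unacc_incongruent`.
#' @export
pd_probabilities <- function(trials) {
  pro <- trials[trials$norm_type == "proscriptive", , drop = FALSE]
  out <- lapply(split(pro, pro$participant_id), function(tp) {
    cong <- tp$response[tp$consequence_dir == "benefits_smaller"]
    incong <- tp$response[tp$consequence_dir == "benefits_greater"]
    if (length(cong) != 6 || length(incong) != 6) {
      stop("participant ", tp$participant_id[1],
           " lacks a complete proscriptive condition (6 trials each)")
    }
    data.frame(participant_id = tp$participant_id[1],
               p_unacc_congruent = 1 - mean(cong),
               p_unacc_incongruent = 1 - mean(incong),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Process-dissociation U and D parameters
#'
#' The PD model writes the probability of judging the action unacceptable as
#' `U + (1 - U) D` in congruent dilemmas and `(1 - U) D` in incongruent
#' dilemmas, where `U` is the utilitarian and `D` the deontological
#' inclination. Solving: `U = p_congruent - p_incongruent` (may be negative
#' in noisy data) and `D = p_incongruent / (1 - U)` when `U < 1`; at the
#' pure-utilitarian corner `U = 1`, `D` is undefined and returned as `NA`.
#'
#' @param p_unacc_congruent,p_unacc_incongruent Proportions in \[0, 1\], or a
#'   data frame from [pd_probabilities()] as the first argument.
#' @return Data frame with columns `p_unacc_congruent`,
#'   `p_unacc_incongruent`, `U`, `D` (plus `participant_id` when the input
#'   carried one).
#' @examples
#' pd_scores(5 / 6, 1 / 2)  # U = 1/3, D = 0.75
#' @export
pd_scores <- function(p_unacc_congruent, p_unacc_incongruent = NULL) {
  if (is.data.frame(p_unacc_congruent)) {
    df <- p_unacc_congruent
    a <- df$p_unacc_congruent
    b <- df$p_unacc_incongruent
    id <- df$participant_id
  } else {
    a <- p_unacc_congruent
    b <- p_unacc_incongruent
    id <- NULL
  }
  stopifnot(all(a >= 0 & a <= 1), all(b >= 0 & b <= 1),
            length(a) == length(b))
  U <- a - b
  D <- ifelse(U < 1, b / (1 - U), NA_real_)
  out <- data.frame(p_unacc_congruent = a, p_unacc_incongruent = b,
                    U = U, D = D)
  if (!is.null(id)) out <- cbind(participant_id = id, out)
  out
}

#' Standardize PD parameters over the analyzed sample
#'
#' Adds z-scored columns `z_U` and `z_D` (mean 0, sample SD 1 with the n-1
#' denominator) computed over all participants jointly — both groups pooled —
#' so that group means of the z-scores weight to zero. Missing `D` values
#' (participants at the `U = 1` corner) stay missing and are excluded from
#' the standardization.
#'
#' @param pd Data frame from [pd_scores()].
#' @return The input with `z_U`, `z_D` columns appended.
#' @export
standardize_pd <- function(pd) {
  zscore <- function(x) {
    ok <- !is.na(x)
    if (sum(ok) < 2) stop("need >= 2 non-missing values to standardize")
    s <- stats::sd(x[ok])
    if (s == 0) stop("zero variance; cannot standardize")
    (x - mean(x[ok])) / s
  }
  pd$z_U <- zscore(pd$U)
  pd$z_D <- zscore(pd$D)
  pd
}
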