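#' Mixed 2 (between) x 2 (within) ANOVA with simple effects
#'
#' Standard least-squares partitioning for one between-subject factor (two
#' groups, possibly unequal n) crossed with one within-subject factor (two
#' levels, one observation per participant per level), as produced by
#' [stats::aov()] with a participant error stratum. With two within levels
#' sphericity holds trivially. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` within each error stratum. Simple
#' effects are between-group contrasts at each within level (pooled-variance
#' F with 1 and n - 2 df).
#'
#' @param data Long data frame with columns `participant_id`, `group` (two
#'   levels), `condition` (the within factor, two levels), `value`.
#'   Participants missing either within level are dropped with a warning.
#' @return Object of class `dilemma_anova`: data frame `effects` with rows
#'   `group`, `condition`, `group:condition` and the simple effects, columns
#'   `F`, `df_num`, `df_den`, `p`, `eta_p_sq`.
#' @export
mixed_anova_2x2 <- function(data) {
  stopifnot(all(c("participant_id", "group", "condition", "value") %in%
                  names(data)))
  data <- data[!is.na(data$value), , drop = FALSE]
  n_lev <- tapply(data$condition, data$participant_id,
                  function(x) length(unique(x)))
  bad <- names(n_lev)[n_lev < 2]
  if (length(bad)) {
    warning(length(bad), " participant(s) missing a within-condition value; excluded")
    data <- data[!data$participant_id %in% bad, , drop = FALSE]
  }
  if (length(unique(data$group)) != 2 || length(unique(data$condition)) != 2) {
    stop("design must have exactly two groups and two within conditions")
  }
  data$participant_id <- factor(data$participant_id)
  data$group <- factor(data$group)
  data$condition <- factor(data$condition)

  fit <- stats::aov(value ~ group * condition + Error(participant_id),
                    data = data)
  s <- summary(fit)
  between <- as.data.frame(s[["Error: participant_id"]][[1]])
  within <- as.data.frame(s[["Error: Within"]][[1]])
  row_of <- function(tab, name) {
    i <- match(name, trimws(rownames(tab)))
    tab[i, , drop = FALSE]
  }
  eff_row <- function(tab, name) {
    e <- row_of(tab, name)
    res <- row_of(tab, "Residuals")
    data.frame(
      effect = name,
      F = e[["F value"]], df_num = e[["Df"]], df_den = res[["Df"]],
      p = e[["Pr(>F)"]],
      eta_p_sq = e[["Sum Sq"]] / (e[["Sum Sq"]] + res[["Sum Sq"]]),
      stringsAsFactors = FALSE)
  }
  effects <- rbind(eff_row(between, "group"),
                   eff_row(within, "condition"),
                   eff_row(within, "group:condition"))

  # simple between-group effects at each within level
  simple <- do.call(rbind, lapply(levels(data$condition), function(lv) {
    d <- data[data$condition == lv, , drop = FALSE]
    g <- split(d$value, d$group)
    tt <- tryCatch(group_difference_test(g[[1]], g[[2]]),
                   error = function(e) NULL)
    if (is.null(tt)) {
      return(data.frame(effect = paste0("group @ ", lv), F = NA_real_,
                        df_num = 1, df_den = NA_real_, p = NA_real_,
                        eta_p_sq = NA_real_, stringsAsFactors = FALSE))
    }
    data.frame(effect = paste0("group @ ", lv),
               F = tt$statistic^2, df_num = 1, df_den = tt$df,
               p = tt$p,
               eta_p_sq = tt$statistic^2 / (tt$statistic^2 + tt$df),
               stringsAsFactors = FALSE)
  }))
  effects <- rbind(effects, simple)
  rownames(effects) <- NULL
  structure(list(effects = effects, n = nlevels(data$participant_id)),
            class = "dilemma_anova")
}

#' @export
print.dilemma_anova <- function(x, ...) {
  cat(sprintf("Mixed 2x2 ANOVA (n = %d)\n", x$n))
  e <- x$effects
  e$F <- round(e$F, 3); e$p <- signif(e$p, 3); e$eta_p_sq <- round(e$eta_p_sq, 3)
  print(e, row.names = FALSE)
  invisible(x)
}

#' Rank or product-moment correlation test
#'
#' Spearman's rho is the Pearson correlation of average ranks; its two-sided
#' p-value uses the t approximation `t = rho sqrt((n-2)/(1-rho^2))` on n - 2
#' df, or an exhaustive permutation distribution for small n
#' (`p_method = "permutation"`, n <= 8), which remains exact under ties.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param p_method `"t"` or `"permutation"` (Spearman only).
#' @return List of class `dilemma_cor`: `rho`, `p`, `n`, `method`.
#' @examples
#' correlation_test(c(1, 2, 3, 4), c(2, 1, 4, 3))  # rho = 0.6
#' @export
correlation_test <- function(x, y, method = c("spearman", "pearson"),
                             p_method = c("t", "permutation")) {
  method <- match.arg(method)
  p_method <- match.arg(p_method)
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input vector; correlation undefined")
  }
  u <- if (method == "spearman") rank(x) else x
  v <- if (method == "spearman") rank(y) else y
  rho <- stats::cor(u, v)
  if (p_method == "permutation") {
    if (method != "spearman") stop("permutation p is for Spearman only")
    if (n > 8) stop("exhaustive permutation limited to n <= 8")
    perms <- permutations_of(n)
    obs <- abs(rho)
    stats_perm <- apply(perms, 1, function(ix) abs(stats::cor(u, v[ix])))
    p <- mean(stats_perm >= obs - 1e-12)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  structure(list(rho = rho, p = p, n = n, method = method,
                 p_method = p_method), class = "dilemma_cor")
}

#' @export
print.dilemma_cor <- function(x, ...) {
  cat(sprintf("%s rho = %.3f, p = %.4g (n = %d)\n", x$method, x$rho, x$p, x$n))
  invisible(x)
}

# all n! permutations of 1..n as rows (n small)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Pearson chi-squared test for a 2x2 table
#'
#' Without continuity correction, df = 1. All four margins must be positive.
#'
#' @param tab 2x2 matrix of nonnegative counts.
#' @return List: `statistic`, `df`, `p`.
#' @examples
#' chi_square_2x2(matrix(c(13, 25, 31, 58), 2))
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin; chi-squared undefined")
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Pooled t-test from printed group summaries
#'
#' Student t computed from means, SDs and group sizes alone, `df = n1 + n2 -
#' 2`; equals the raw-data pooled t when fed matching summaries. Cohen's d
#' uses the pooled SD.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return A `dilemma_ttest` list (see [neutral_point_test()]).
#' @examples
#' t_from_summary(19.09, 0.74, 38, 19.17, 0.73, 89)
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 > 0, sd2 > 0, n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (mean1 - mean2) / se
  df <- n1 + n2 - 2
  ttest_result(statistic = tstat, df = df,
               p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
               effect_size_d = (mean1 - mean2) / sqrt(sp2),
               kind = "from_summary",
               mean = c(mean1, mean2), sd = c(sd1, sd2), n = c(n1, n2))
}
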