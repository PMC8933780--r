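#' CNI processing-tree probability of choosing action
#'
#' The CNI model assumes that with probability `C` a respondent acts on the
#' consequences (accepting the action when its benefits exceed its costs,
#' refusing otherwise); failing that, with probability `N` they follow the
#' moral norm (refusing under a proscriptive norm, accepting under a
#' prescriptive one); failing both, with probability `I` they default to
#' inaction and with probability `1 - I` to action. The resulting
#' action-choice probabilities are
#'
#' \describe{
#'   \item{proscriptive, benefits greater}{`C + (1-C)(1-N)(1-I)`}
#'   \item{proscriptive, benefits smaller}{`(1-C)(1-N)(1-I)`}
#'   \item{prescriptive, benefits greater}{`C + (1-C)N + (1-C)(1-N)(1-I)`}
#'   \item{prescriptive, benefits smaller}{`(1-C)N + (1-C)(1-N)(1-I)`}
#' }
#'
#' @param C,N,I Tree parameters, each a probability in \[0, 1\]. Recycled
#'   against the condition arguments.
#' @param norm_type `"proscriptive"` or `"prescriptive"`.
#' @param consequence_dir `"benefits_greater"` or `"benefits_smaller"`.
#' @return Probability of accepting the action, in \[0, 1\].
#' @examples
#' cni_probability(0.12, 0.25, 0.45, "proscriptive", "benefits_greater")
#' @export
cni_probability <- function(C, N, I, norm_type, consequence_dir) {
  stopifnot(all(norm_type %in% NORM_TYPES),
            all(consequence_dir %in% CONSEQUENCE_DIRS))
  base <- (1 - C) * (1 - N) * (1 - I)       # neither C nor N engaged, acts
  p <- base +
    C * (consequence_dir == "benefits_greater") +
    (1 - C) * N * (norm_type == "prescriptive")
  unname(p)
}

# probabilities for the 4 canonical conditions (pro/greater, pro/smaller,
# pre/greater, pre/smaller), as a vector
cni_cell_probs <- function(par) {
  cg <- condition_grid()
  cni_probability(par[1], par[2], par[3], cg$norm_type, cg$consequence_dir)
}

#' Binomial log-likelihood of CNI parameters on condition counts
#'
#' Sum over cells of `a * log(p) + (n - a) * log(1 - p)` with `p` the tree
#' probability for the cell (binomial coefficients omitted; they cancel in
#' every likelihood-ratio statistic). Probabilities are clamped to
#' `[1e-9, 1 - 1e-9]` for evaluation.
#'
#' @param params Numeric `c(C, N, I)`.
#' @param counts Condition-count data frame for a single group
#'   (see [aggregate_counts()]).
#' @return Scalar log-likelihood.
#' @export
cni_loglik <- function(params, counts) {
  p <- cni_probability(params[1], params[2], params[3],
                       counts$norm_type, counts$consequence_dir)
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  sum(counts$action_count * log(p) +
        (counts$total - counts$action_count) * log1p(-p))
}

# saturated log-likelihood: one free probability per cell
saturated_loglik <- function(counts) {
  a <- counts$action_count
  n <- counts$total
  p <- pmin(pmax(a / n, 1e-9), 1 - 1e-9)
  sum(a * log(p) + (n - a) * log1p(-p))
}

#' Closed-form moment estimates of the CNI parameters
#'
#' Inverts the tree algebra on the four observed cell proportions
#' `p1..p4` (canonical order): `C = (p1 - p2 + p3 - p4) / 2`,
#' `N = (p3 - p1 + p4 - p2) / (2 (1 - C))`, and `1 - I` as the mean of the
#' four cell-wise solutions. Exact when the proportions sit exactly on the
#' model surface; otherwise a good optimizer start. Estimates are clipped to
#' \[0, 1\]; degenerate denominators fall back to `(0.5, 0.5, 0.5)`.
#'
#' @param counts Condition-count data frame for a single group.
#' @return Named numeric `c(C, N, I)`.
#' @export
cni_moment_estimates <- function(counts) {
  counts <- canonical_counts(counts)
  p <- counts$action_count / counts$total
  C <- (p[1] - p[2] + p[3] - p[4]) / 2
  if (1 - C < 1e-6) return(c(C = 0.5, N = 0.5, I = 0.5))
  N <- (p[3] - p[1] + p[4] - p[2]) / (2 * (1 - C))
  denom <- (1 - C) * (1 - max(min(N, 1), 0))
  if (denom < 1e-6) return(c(C = 0.5, N = 0.5, I = 0.5))
  one_minus_I <- mean(c(p[1] - C, p[2],
                        p[3] - C - (1 - C) * N,
                        p[4] - (1 - C) * N) / denom)
  clip01 <- function(x) max(min(x, 1), 0)
  c(C = clip01(C), N = clip01(N), I = clip01(1 - one_minus_I))
}

# reorder a one-group count table into the canonical condition order
canonical_counts <- function(counts) {
  cg <- condition_grid()
  idx <- match(condition_key(cg$norm_type, cg$consequence_dir),
               condition_key(counts$norm_type, counts$consequence_dir))
  if (any(is.na(idx))) stop("counts must contain all four conditions")
  counts[idx, , drop = FALSE]
}

# deterministic Halton sequence (bases 2, 3, 5) for extra optimizer starts
halton_starts <- function(n, dim = 3) {
  radical_inverse <- function(i, base) {
    f <- 1; r <- 0
    while (i > 0) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    r
  }
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29)
  stopifnot(dim <= length(primes))
  bases <- primes[seq_len(dim)]
  t(vapply(seq_len(n), function(i)
    vapply(bases, function(b) radical_inverse(i, b), numeric(1)),
    numeric(dim)))
}

#' Fit the CNI model to aggregate condition counts by maximum likelihood
#'
#' Maximizes the binomial likelihood over `(C, N, I)` per group with bounded
#' quasi-Newton (`L-BFGS-B`) from multiple starts: the closed-form moment
#' estimate plus quasi-random points. Reports `G^2 = 2 (LL_saturated -
#' LL_model)` with `df = cells - free parameters` (4 - 3 = 1 for one group,
#' 8 - 6 = 2 for two groups with free parameters), Wald 95% confidence
#' intervals from the observed information, boundary flags, and the number
#' of starts agreeing with the best optimum.
#'
#' Constraints: `fix` pins parameters at a value in every group (e.g.
#' `c(C = 0)` for the no-consequence-sensitivity null, `c(I = 0.5)` for the
#' action/inaction neutrality null); `equate` names parameters shared across
#' groups (one free value instead of one per group).
#'
#' @param counts Condition-count data frame with columns `group`,
#'   `norm_type`, `consequence_dir`, `action_count`, `total` (the `group`
#'   column may be absent for a single battery).
#' @param fix Named numeric of parameters fixed at a value, or `NULL`.
#' @param equate Character vector of parameter names equated across groups.
#' @param n_starts Number of optimizer starts (>= 1).
#' @param level Confidence level for the Wald intervals.
#' @return An object of class `cni_fit`: list with `estimates` (data frame
#'   `group`, `parameter`, `estimate`, `se`, `lower`, `upper`, `boundary`,
#'   `fixed`), `loglik`, `g_squared`, `df`, `p_value`, `converged`,
#'   `n_starts_agreeing`, `counts`.
#' @examples
#' counts <- counts_from_means_table(example_study_means(), pooled = TRUE)
#' fit_cni(counts)
#' @export
fit_cni <- function(counts, fix = NULL, equate = character(0),
                    n_starts = 10, level = 0.95) {
  counts <- as.data.frame(counts)
  if (is.null(counts$group)) counts$group <- "pooled"
  stopifnot(n_starts >= 1, all(counts$total >= counts$action_count),
            all(counts$action_count >= 0))
  if (!is.null(fix)) {
    stopifnot(all(names(fix) %in% c("C", "N", "I")),
              all(fix >= 0 & fix <= 1))
    bad <- intersect(names(fix), equate)
    if (length(bad)) stop("parameter both fixed and equated: ", bad[1])
  }
  stopifnot(all(equate %in% c("C", "N", "I")))

  groups <- unique(counts$group)
  params <- c("C", "N", "I")
  # map (group, parameter) -> index in the free-parameter vector, or 0 if fixed
  slot <- matrix(0L, nrow = length(groups), ncol = 3,
                 dimnames = list(groups, params))
  nfree <- 0L
  for (p in params) {
    if (p %in% names(fix)) next
    if (p %in% equate || length(groups) == 1L) {
      nfree <- nfree + 1L
      slot[, p] <- nfree
    } else {
      for (g in groups) {
        nfree <- nfree + 1L
        slot[g, p] <- nfree
      }
    }
  }
  expand <- function(theta) {
    # full (group x 3) parameter matrix from the free vector
    m <- matrix(0, nrow = length(groups), ncol = 3,
                dimnames = list(groups, params))
    for (p in params) {
      m[, p] <- if (p %in% names(fix)) fix[[p]] else theta[slot[, p]]
    }
    m
  }
  negll <- function(theta) {
    m <- expand(theta)
    -sum(vapply(groups, function(g)
      cni_loglik(m[g, ], counts[counts$group == g, , drop = FALSE]),
      numeric(1)))
  }

  # starts: per-group moment estimates projected onto the constraints,
  # then quasi-random points
  moment <- do.call(rbind, lapply(groups, function(g)
    cni_moment_estimates(counts[counts$group == g, , drop = FALSE])))
  rownames(moment) <- groups
  start1 <- numeric(nfree)
  for (p in params) for (g in groups) {
    s <- slot[g, p]
    if (s > 0) start1[s] <- if (p %in% equate) mean(moment[, p]) else moment[g, p]
  }
  starts <- rbind(start1,
                  if (n_starts > 1) halton_starts(n_starts - 1, nfree))
  starts <- pmin(pmax(starts, 1e-4), 1 - 1e-4)

  fits <- apply(starts, 1, function(s) {
    tryCatch(
      stats::optim(s, negll, method = "L-BFGS-B",
                   lower = rep(1e-9, nfree), upper = rep(1 - 1e-9, nfree),
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) stop("CNI optimization failed from every start")
  values <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(values)]]
  converged <- best$convergence == 0
  n_agree <- sum(values < min(values) + 1e-6)

  m <- expand(best$par)
  loglik <- -best$value
  sat <- sum(vapply(groups, function(g)
    saturated_loglik(counts[counts$group == g, , drop = FALSE]), numeric(1)))
  g2 <- max(2 * (sat - loglik), 0)
  df <- 4L * length(groups) - nfree
  p_value <- if (df > 0) stats::pchisq(g2, df, lower.tail = FALSE) else NA_real_

  # Wald intervals from the observed information (numerical Hessian)
  se_free <- rep(NA_real_, nfree)
  if (nfree > 0) {
    H <- stats::optimHess(best$par, negll)
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov)) {
      v <- diag(as.matrix(cov))
      se_free[v > 0] <- sqrt(v[v > 0])
    }
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- do.call(rbind, lapply(groups, function(g) {
    data.frame(group = g, parameter = params,
               estimate = unname(m[g, ]),
               se = vapply(params, function(p) {
                 s <- slot[g, p]
                 if (s > 0) se_free[s] else NA_real_
               }, numeric(1)),
               fixed = params %in% names(fix),
               stringsAsFactors = FALSE)
  }))
  est$lower <- pmax(est$estimate - z * est$se, 0)
  est$upper <- pmin(est$estimate + z * est$se, 1)
  est$boundary <- !est$fixed &
    (est$estimate < 1e-4 | est$estimate > 1 - 1e-4)
  rownames(est) <- NULL

  structure(list(estimates = est, loglik = loglik, g_squared = g2, df = df,
                 p_value = p_value, converged = converged,
                 n_starts_agreeing = n_agree, level = level,
                 fix = fix, equate = equate, counts = counts),
            class = "cni_fit")
}

#' @export
print.cni_fit <- function(x, ...) {
  cat("CNI model fit (binomial ML on aggregate condition counts)\n")
  if (!is.null(x$fix) && length(x$fix)) {
    cat("  fixed:", paste(names(x$fix), "=", x$fix, collapse = ", "), "\n")
  }
  if (length(x$equate)) {
    cat("  equated across groups:", paste(x$equate, collapse = ", "), "\n")
  }
  est <- x$estimates
  est$estimate <- round(est$estimate, 3)
  est$lower <- round(est$lower, 3)
  est$upper <- round(est$upper, 3)
  print(est[, c("group", "parameter", "estimate", "lower", "upper")],
        row.names = FALSE)
  cat(sprintf("  G^2(%d) = %.3f, p = %.3f; logLik = %.3f%s\n",
              x$df, x$g_squared, x$p_value, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Extract CNI parameter estimates as a named vector or matrix
#'
#' @param object A `cni_fit` object.
#' @param group Group label; defaults to the first group.
#' @param ... Unused.
#' @return Named numeric `c(C, N, I)` for the requested group.
#' @export
coef.cni_fit <- function(object, group = NULL, ...) {
  est <- object$estimates
  g <- if (is.null(group)) est$group[1] else group
  out <- est$estimate[est$group == g]
  names(out) <- est$parameter[est$group == g]
  out
}

#' Likelihood-ratio test of a constraint on the CNI model
#'
#' Refits the model under a nested constraint and reports
#' `dG^2 = G^2_constrained - G^2_free`, referred to a chi-squared
#' distribution with `df` equal to the number of constraints imposed.
#' Two kinds of constraint are supported: `fix_value` pins one parameter at
#' a reference value in every group (for one group this is 1 constraint; for
#' k groups, k constraints), and `equate_across_groups` replaces a
#' per-group parameter by a single shared value (k - 1 constraints).
#'
#' Note that some published multinomial-tree analyses report group-equality
#' tests with df equal to the number of groups rather than the number of
#' equality constraints; the df used here is always the constraint count and
#' is returned explicitly.
#'
#' @param counts Condition-count data frame (see [fit_cni()]).
#' @param parameter `"C"`, `"N"` or `"I"`.
#' @param kind `"fix_value"` or `"equate_across_groups"`.
#' @param value Reference value for `fix_value` (e.g. 0, or 0.5 for the
#'   inaction-neutrality null).
#' @param ... Passed to [fit_cni()] (both fits).
#' @return Object of class `cni_test`: list with `delta_g_squared`, `df`,
#'   `p_value`, `free` and `constrained` (`cni_fit` objects), `parameter`,
#'   `kind`, `value`.
#' @examples
#' counts <- counts_from_means_table(example_study_means(), pooled = TRUE)
#' test_cni_constraint(counts, "C", kind = "fix_value", value = 0)
#' @export
test_cni_constraint <- function(counts,
                                parameter = c("C", "N", "I"),
                                kind = c("fix_value", "equate_across_groups"),
                                value = NULL, ...) {
  parameter <- match.arg(parameter)
  kind <- match.arg(kind)
  counts <- as.data.frame(counts)
  if (is.null(counts$group)) counts$group <- "pooled"
  k <- length(unique(counts$group))

  free <- fit_cni(counts, ...)
  if (kind == "fix_value") {
    if (is.null(value)) stop("fix_value constraints need a value")
    fix <- stats::setNames(value, parameter)
    constrained <- fit_cni(counts, fix = fix, ...)
    df <- k
  } else {
    if (k < 2) stop("equate_across_groups needs at least two groups")
    constrained <- fit_cni(counts, equate = parameter, ...)
    df <- k - 1L
  }
  dg2 <- constrained$g_squared - free$g_squared
  if (dg2 < -1e-6) {
    warning("constrained fit beat the free fit; optimization is suspect")
  }
  dg2 <- max(dg2, 0)
  structure(list(delta_g_squared = dg2, df = df,
                 p_value = stats::pchisq(dg2, df, lower.tail = FALSE),
                 free = free, constrained = constrained,
                 parameter = parameter, kind = kind, value = value),
            class = "cni_test")
}

#' @export
print.cni_test <- function(x, ...) {
  lab <- if (x$kind == "fix_value") {
    sprintf("%s = %g", x$parameter, x$value)
  } else {
    sprintf("%s equal across groups", x$parameter)
  }
  cat(sprintf("CNI constraint test [%s]: dG^2(%d) = %.3f, p = %.4g\n",
              lab, x$df, x$delta_g_squared, x$p_value))
  invisible(x)
}
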