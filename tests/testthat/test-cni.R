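test_that("tree probabilities are degenerate at the pure-process corners", {
  cg <- expand.grid(norm_type = c("proscriptive", "prescriptive"),
                    consequence_dir = c("benefits_greater", "benefits_smaller"),
                    stringsAsFactors = FALSE)
  # pure consequence-following
  p <- cni_probability(1, 0.3, 0.7, cg$norm_type, cg$consequence_dir)
  expect_equal(p, as.numeric(cg$consequence_dir == "benefits_greater"))
  # pure norm-following
  p <- cni_probability(0, 1, 0.2, cg$norm_type, cg$consequence_dir)
  expect_equal(p, as.numeric(cg$norm_type == "prescriptive"))
  # pure inaction
  p <- cni_probability(0, 0, 1, cg$norm_type, cg$consequence_dir)
  expect_equal(p, rep(0, 4))
  # hand-evaluated tree product
  expect_equal(cni_probability(0.120, 0.249, 0.451,
                               "proscriptive", "benefits_greater"),
               0.120 + 0.880 * 0.751 * 0.549)
})

test_that("tree probabilities stay in [0,1] with the expected monotonicities", {
  grid <- seq(0.05, 0.95, by = 0.15)
  cg <- counts_table(0, 1)[, c("norm_type", "consequence_dir")]
  h <- 1e-6
  for (C in grid) for (N in grid) for (I in grid) {
    p <- cni_probability(C, N, I, cg$norm_type, cg$consequence_dir)
    expect_true(all(p >= 0 & p <= 1))
    dI <- (cni_probability(C, N, I + h, cg$norm_type, cg$consequence_dir) - p) / h
    expect_true(all(dI < 0))
    dC <- (cni_probability(C + h, N, I, cg$norm_type, cg$consequence_dir) - p) / h
    expect_true(all(dC[cg$consequence_dir == "benefits_greater"] > 0))
    expect_true(all(dC[cg$consequence_dir == "benefits_smaller"] < 0))
    dN <- (cni_probability(C, N + h, I, cg$norm_type, cg$consequence_dir) - p) / h
    expect_true(all(dN[cg$norm_type == "prescriptive"] > 0))
    expect_true(all(dN[cg$norm_type == "proscriptive"] < 0))
  }
})

test_that("log-likelihood is bounded by the saturated model", {
  counts <- counts_table(c(30, 10, 50, 35), 60)
  sat <- sum(dbinom(counts$action_count, counts$total,
                    counts$action_count / counts$total, log = TRUE)) -
    sum(lchoose(counts$total, counts$action_count))
  set.seed(4)
  for (i in 1:25) {
    ll <- cni_loglik(runif(3), counts)
    expect_lte(ll, sat + 1e-9)
  }
  # closed form: p = 0.5 in all cells at C = 0, N = 0, I = 0.5
  half <- counts_table(c(30, 30, 30, 30), 60)
  expect_equal(cni_loglik(c(0, 0, 0.5), half), 4 * 60 * log(0.5))
  # params whose tree probabilities equal a/n attain the saturated value
  p <- cni_probability(0.3, 0.4, 0.5, counts$norm_type, counts$consequence_dir)
  exact <- counts_table(p * 1000, 1000)
  a <- exact$action_count; n <- exact$total
  expect_equal(cni_loglik(c(0.3, 0.4, 0.5), exact),
               sum(a * log(a / n) + (n - a) * log(1 - a / n)))
})

test_that("moment estimates invert the tree exactly on model-consistent proportions", {
  p <- cni_probability(0.3, 0.4, 0.5,
                       counts_table(0, 1)$norm_type,
                       counts_table(0, 1)$consequence_dir)
  counts <- counts_table(p * 1000, 1000)
  expect_equal(cni_moment_estimates(counts), c(C = 0.3, N = 0.4, I = 0.5),
               tolerance = 1e-9)
  # closed-form arithmetic on the pooled reconstructed proportions
  pooled <- counts_table(c(375, 270, 529, 450), 762)
  m <- cni_moment_estimates(pooled)
  expect_equal(unname(m["C"]), 0.1207, tolerance = 1e-3)
  expect_equal(unname(m["N"]), 0.2493, tolerance = 1e-3)
  # no consequence effect: p1 = p2, p3 = p4
  flat <- counts_table(c(40, 40, 70, 70), 100)
  expect_equal(unname(cni_moment_estimates(flat)["C"]), 0)
})

test_that("ML fit recovers exact-model data with near-zero G^2", {
  p <- cni_probability(0.3, 0.4, 0.5,
                       counts_table(0, 1)$norm_type,
                       counts_table(0, 1)$consequence_dir)
  counts <- counts_table(p * 6000, 6000)  # 3060, 1260, 4740, 2940
  expect_equal(counts$action_count, c(3060L, 1260L, 4740L, 2940L))
  fit <- fit_cni(counts)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(0.3, 0.4, 0.5), tolerance = 1e-4)
  expect_lte(fit$g_squared, 1e-4)
  expect_equal(fit$df, 1)
})

test_that("constraint tests give nonnegative deviance differences and exact nulls", {
  # data generated exactly under C = 0
  p <- cni_probability(0, 0.4, 0.55,
                       counts_table(0, 1)$norm_type,
                       counts_table(0, 1)$consequence_dir)
  counts <- counts_table(round(p * 2000), 2000)
  t0 <- test_cni_constraint(counts, "C", "fix_value", 0)
  expect_lt(t0$delta_g_squared, 0.05)
  # nested pairs on arbitrary counts
  set.seed(8)
  for (i in 1:5) {
    n <- sample(100:400, 1)
    counts <- counts_table(rbinom(4, n, runif(4, 0.2, 0.8)), n)
    for (spec in list(list("C", 0), list("N", 0), list("I", 0.5))) {
      tt <- test_cni_constraint(counts, spec[[1]], "fix_value", spec[[2]])
      expect_gte(tt$delta_g_squared, -1e-6)
      expect_equal(tt$df, 1)
    }
  }
  expect_error(test_cni_constraint(counts_table(c(10, 10, 10, 10), 20),
                                   "N", "equate_across_groups"),
               "two groups")
})

test_that("maximized likelihood matches an exhaustive grid search", {
  set.seed(12)
  count_list <- lapply(1:6, function(i) {
    truth <- runif(3, 0.1, 0.9)
    n <- sample(150:400, 1)
    p <- cni_probability(truth[1], truth[2], truth[3],
                         counts_table(0, 1)$norm_type,
                         counts_table(0, 1)$consequence_dir)
    counts_table(rbinom(4, n, p), n)
  })
  grid_best <- cni_grid_search(count_list, step = 0.01)
  for (j in seq_along(count_list)) {
    fit <- fit_cni(count_list[[j]])
    expect_gte(fit$loglik, grid_best[j] - 1e-6)
    # grid resolution bound: curvature x step^2 stays well under 1
    expect_lte(grid_best[j], fit$loglik)
    expect_gte(grid_best[j], fit$loglik - 1)
  }
})

test_that("Wald intervals tighten with sample size and flag boundary fits", {
  p <- cni_probability(0.25, 0.35, 0.45,
                       counts_table(0, 1)$norm_type,
                       counts_table(0, 1)$consequence_dir)
  widths <- sapply(c(600, 60000), function(n) {
    fit <- fit_cni(counts_table(round(p * n), n))
    mean(fit$estimates$upper - fit$estimates$lower)
  })
  expect_lt(widths[2], widths[1] / 5)
  # large-n interval covers the truth
  fit <- fit_cni(counts_table(round(p * 1e5), 1e5))
  est <- fit$estimates
  truth <- c(0.25, 0.35, 0.45)
  expect_true(all(est$lower <= truth & truth <= est$upper))
  expect_true(all(est$upper - est$lower < 0.02))
  # degenerate data push C to the boundary
  p0 <- cni_probability(0, 0.5, 0.5,
                        counts_table(0, 1)$norm_type,
                        counts_table(0, 1)$consequence_dir)
  fit0 <- fit_cni(counts_table(round(p0 * 5000), 5000))
  expect_true(fit0$estimates$boundary[fit0$estimates$parameter == "C"])
})

test_that("two-group fits report per-group parameters and equality constraints", {
  counts <- counts_from_means_table(example_study_means())
  fit <- fit_cni(counts)
  expect_equal(fit$df, 2)
  expect_equal(nrow(fit$estimates), 6)
  eq <- fit_cni(counts, equate = "N")
  expect_equal(sum(!eq$estimates$fixed), 6)  # 6 rows but N shared
  nN <- eq$estimates$estimate[eq$estimates$parameter == "N"]
  expect_equal(nN[1], nN[2])
  expect_equal(eq$df, 3)
  tt <- test_cni_constraint(counts, "N", "equate_across_groups")
  expect_equal(tt$df, 1)
  expect_gt(tt$delta_g_squared, 10)  # groups clearly differ in N
  expect_error(fit_cni(counts, fix = c(N = 0), equate = "N"),
               "both fixed and equated")
})
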