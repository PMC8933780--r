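test_that("degenerate tree parameters silence every response", {
  sim <- simulate_trials(group_spec("G", 4, c(0, 0, 1)), seed = 2)
  expect_true(all(sim$trials$response == 0L))
  # and the opposite corner: always act
  sim2 <- simulate_trials(group_spec("G", 4, c(0, 0, 0)), seed = 2)
  expect_true(all(sim2$trials$response == 1L))
})

test_that("a fixed seed reproduces the simulation exactly", {
  sp <- list(group_spec("HC", 6, c(0.1, 0.4, 0.5), heterogeneity_sd = 0.4),
             group_spec("IA", 9, c(0.2, 0.2, 0.45)))
  a <- simulate_trials(sp, seed = 99)
  b <- simulate_trials(sp, seed = 99)
  expect_identical(a, b)
  c <- simulate_trials(sp, seed = 100)
  expect_false(identical(a$trials$response, c$trials$response))
})

test_that("homogeneous cell proportions stay within 3 binomial SEs of the tree", {
  truth <- c(0.2, 0.3, 0.45)
  sim <- simulate_trials(group_spec("G", 200, truth), seed = 17)
  counts <- aggregate_counts(sim$trials)
  p_true <- cni_probability(truth[1], truth[2], truth[3],
                            counts$norm_type, counts$consequence_dir)
  se <- sqrt(p_true * (1 - p_true) / counts$total)
  expect_true(all(abs(counts$action_count / counts$total - p_true) <= 3 * se))
})

test_that("empirical proportions converge to the tree probabilities", {
  truth <- c(0.15, 0.35, 0.5)
  err <- sapply(seq_along(c(20, 200, 2000)), function(i) {
    n <- c(20, 200, 2000)[i]
    sim <- simulate_trials(group_spec("G", n, truth), seed = 100 + i)
    counts <- aggregate_counts(sim$trials)
    p_true <- cni_probability(truth[1], truth[2], truth[3],
                              counts$norm_type, counts$consequence_dir)
    max(abs(counts$action_count / counts$total - p_true))
  })
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.03)
})

test_that("difficulty ratings follow the additive construction", {
  sim <- simulate_trials(list(group_spec("HC", 3, c(0.2, 0.3, 0.45)),
                              group_spec("IA", 3, c(0.2, 0.3, 0.45))),
                         seed = 23)
  flat <- simulate_difficulty(sim$trials, sim$profiles, 0, 0, 0, seed = 1)
  expect_true(all(flat$difficulty == 3L))
  conf <- simulate_difficulty(sim$trials, sim$profiles, 1, 0, 0, seed = 1)
  incong <- conf$norm_type == "proscriptive" &
    conf$consequence_dir == "benefits_greater"
  expect_true(all(conf$difficulty[incong] == 4L))
  expect_true(all(conf$difficulty[!incong] == 3L))
  expect_true(all(simulate_difficulty(sim$trials, sim$profiles, 9, 9, 0,
                                      seed = 1)$difficulty <= 5L))
})

test_that("a group difficulty effect is detectable at realistic power", {
  hits <- 0L
  set.seed(27)
  for (r in 1:40) {
    sim <- simulate_trials(list(group_spec("HC", 100, c(0.1, 0.35, 0.5)),
                                group_spec("IA", 100, c(0.15, 0.2, 0.45))),
                           seed = 2000 + r)
    sim$trials <- simulate_difficulty(sim$trials, sim$profiles,
                                      conflict_effect = 0.5,
                                      group_effect = 0.3, noise_sd = 1,
                                      seed = 3000 + r)
    pro <- sim$trials[sim$trials$norm_type == "proscriptive", ]
    md <- stats::aggregate(difficulty ~ participant_id + consequence_dir,
                           data = pro, FUN = mean)
    d <- data.frame(participant_id = md$participant_id,
                    group = sim$profiles$group[match(md$participant_id,
                                                     sim$profiles$participant_id)],
                    condition = md$consequence_dir,
                    value = md$difficulty)
    res <- mixed_anova_2x2(d)$effects
    if (res$p[res$effect == "group"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.8)
})

test_that("simulation at the fitted group parameters reproduces the condition ordering", {
  sim <- simulate_trials(list(group_spec("HC", 150, c(0.090, 0.364, 0.486)),
                              group_spec("IA", 150, c(0.133, 0.197, 0.438))),
                         seed = 29)
  counts <- aggregate_counts(sim$trials, sim$profiles, grouping = "by_group")
  for (g in c("HC", "IA")) {
    cg <- counts[counts$group == g, ]
    p <- with(cg, action_count / total)
    names(p) <- paste(cg$norm_type, cg$consequence_dir)
    # prescriptive above proscriptive within consequence direction
    expect_gt(p["prescriptive benefits_greater"],
              p["proscriptive benefits_greater"])
    expect_gt(p["prescriptive benefits_smaller"],
              p["proscriptive benefits_smaller"])
    # benefits-greater above benefits-smaller within norm type
    expect_gt(p["proscriptive benefits_greater"],
              p["proscriptive benefits_smaller"])
    expect_gt(p["prescriptive benefits_greater"],
              p["prescriptive benefits_smaller"])
  }
})

test_that("recovery experiment tracks bias, RMSE and scaling with n", {
  rec <- recovery_experiment(c(0.120, 0.249, 0.451), n_participants = 127,
                             replicates = 40, seed = 33)
  expect_equal(rec$n_failed, 0)
  expect_true(all(abs(rec$summary$bias) < 0.03))
  rmse_small <- recovery_experiment(c(0.2, 0.3, 0.45), 50, 25,
                                    seed = 35)$summary$rmse
  rmse_big <- recovery_experiment(c(0.2, 0.3, 0.45), 800, 25,
                                  seed = 36)$summary$rmse
  expect_true(all(rmse_big < rmse_small / 2))  # roughly 1/sqrt(n)
})
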