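# build a trial table from per-participant response vectors ordered as
# battery_design() (24 responses per participant)
trials_from_responses <- function(responses) {
  design <- battery_design()
  do.call(rbind, lapply(names(responses), function(id) {
    stopifnot(length(responses[[id]]) == nrow(design))
    cbind(participant_id = id, design, response = responses[[id]])
  }))
}

# trial table in which a participant accepts `k` actions in the given
# condition and refuses everything else
trials_condition_pattern <- function(id, accept_by_condition) {
  design <- battery_design()
  key <- paste(design$norm_type, design$consequence_dir)
  resp <- integer(nrow(design))
  for (cond in names(accept_by_condition)) {
    idx <- which(key == cond)
    k <- accept_by_condition[[cond]]
    if (k > 0) resp[idx[seq_len(k)]] <- 1L
  }
  cbind(participant_id = id, design, response = resp)
}

# counts table for a single pooled cell set, canonical condition order
counts_table <- function(action, total, group = "pooled") {
  cg <- data.frame(
    norm_type = rep(c("proscriptive", "prescriptive"), each = 2),
    consequence_dir = rep(c("benefits_greater", "benefits_smaller"), 2),
    stringsAsFactors = FALSE)
  cg$group <- group
  cg$action_count <- as.integer(action)
  cg$total <- as.integer(rep(total, length.out = 4))
  cg[, c("group", "norm_type", "consequence_dir", "action_count", "total")]
}

# exhaustive grid search over (C, N, I) maximizing the binomial
# log-likelihood, independent of the package optimizer; `count_list` is a
# list of 4-row canonical count tables, step the grid spacing
cni_grid_search <- function(count_list, step = 0.005) {
  grid1 <- seq(0, 1, by = step)
  NI <- expand.grid(N = grid1, I = grid1)
  best <- rep(-Inf, length(count_list))
  eps <- 1e-9
  amat <- lapply(count_list, function(ct) ct$action_count)
  nmat <- lapply(count_list, function(ct) ct$total)
  for (C in grid1) {
    base <- (1 - C) * (1 - NI$N) * (1 - NI$I)
    p <- list(pmin(pmax(C + base, eps), 1 - eps),                     # pro/greater
              pmin(pmax(base, eps), 1 - eps),                         # pro/smaller
              pmin(pmax(C + (1 - C) * NI$N + base, eps), 1 - eps),    # pre/greater
              pmin(pmax((1 - C) * NI$N + base, eps), 1 - eps))        # pre/smaller
    lp <- lapply(p, log)
    lq <- lapply(p, function(x) log1p(-x))
    for (j in seq_along(count_list)) {
      ll <- amat[[j]][1] * lp[[1]] + (nmat[[j]][1] - amat[[j]][1]) * lq[[1]] +
        amat[[j]][2] * lp[[2]] + (nmat[[j]][2] - amat[[j]][2]) * lq[[2]] +
        amat[[j]][3] * lp[[3]] + (nmat[[j]][3] - amat[[j]][3]) * lq[[3]] +
        amat[[j]][4] * lp[[4]] + (nmat[[j]][4] - amat[[j]][4]) * lq[[4]]
      m <- max(ll)
      if (m > best[j]) best[j] <- m
    }
  }
  best
}

# expected counts placed exactly on the CNI model surface (rounded only if
# round = TRUE)
exact_model_counts <- function(C, N, I, n_per_cell) {
  cg <- counts_table(0, n_per_cell)
  p <- cni_probability(C, N, I, cg$norm_type, cg$consequence_dir)
  cg$action_count <- as.integer(round(p * n_per_cell))
  cg
}
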