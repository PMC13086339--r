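# Build an intake_fit-shaped object with hand-chosen "posterior" draws so
# derived quantities can be checked against closed forms.
fake_fit <- function(data, variant = "stress", n_draws = 10L,
                     modify = identity) {
  md <- mealshare:::build_model_data(data, variant)
  n_cage <- length(md$cages)
  cols <- c(md$x_cols, "beta_L2", "sigma_fish", "sigma_replicate",
            paste0("fish_effect[", rep(md$cages, times = 8L), ",",
                   rep(1:8, each = n_cage), "]"),
            paste0("replicate_effect[", md$trial_key, "]"))
  draws <- matrix(0, n_draws, length(cols), dimnames = list(NULL, cols))
  draws[, c("sigma_fish", "sigma_replicate")] <- 1
  draws <- modify(draws)
  structure(list(draws = draws, chain = rep(1L, n_draws), variant = variant,
                 data = data, model_data = md,
                 diagnostics = data.frame(parameter = cols, rhat = 1,
                                          ess = n_draws)),
            class = "intake_fit")
}

test_that("variance partition reproduces the dispersion ratio", {
  expect_equal(round(variance_partition(0.431, 0.183), 3), 0.702)
  expect_equal(variance_partition(2.7, 2.7), 0.5)
  expect_gt(variance_partition(1, 1e-9), 0.999)
  # complementarity
  for (ab in list(c(0.4, 0.2), c(1.3, 2.2), c(5, 0.01))) {
    expect_equal(variance_partition(ab[1], ab[2]) +
                   variance_partition(ab[2], ab[1]), 1, tolerance = 1e-12)
  }
  # variance-scale alternative squares the inputs first
  expect_equal(variance_partition(0.431, 0.183, scale = "variance"),
               0.431^2 / (0.431^2 + 0.183^2))
  expect_error(variance_partition(0, 1), "positive")
  expect_error(variance_partition(0.4, -1), "positive")
})

test_that("meal shares are per delivered pellet and sum with waste to 100%", {
  # each of 8 fish eats exactly 2 of 16 pellets
  even <- manual_data(list(rep(1:8, each = 2L)))
  ms <- meal_shares(even)
  expect_true(all(abs(ms$per_fish$median_share - 12.5) < 1e-12))

  # one fish monopolises the meal
  mono <- manual_data(list(rep(1L, 10L)))
  msm <- meal_shares(mono)
  pf <- msm$per_fish
  expect_equal(pf$median_share[pf$fish_index == 1], 100)
  expect_true(all(pf$median_share[pf$fish_index != 1] == 0))
  expect_equal(msm$waste_by_diet$waste_pct, 0)

  # shares + waste conserve the delivered ration in every trial
  sim <- tiny_sim(seed = 33)
  mss <- meal_shares(sim$data)
  tot <- tapply(mss$per_trial$share_pct,
                paste(mss$per_trial$cage_id, mss$per_trial$replicate_index),
                sum)
  expect_true(all(abs(tot - 100) < 1e-9))
  expect_true(all(mss$waste_by_diet$waste_pct >= 0 &
                    mss$waste_by_diet$waste_pct <= 100))
  # ordering: within diet level, decreasing median share
  for (dl in unique(mss$per_fish$diet_level)) {
    sh <- mss$per_fish$median_share[mss$per_fish$diet_level == dl]
    expect_true(all(diff(sh) <= 0))
  }
})

test_that("zero-pellet trials are excluded from shares with a notice", {
  d <- manual_data(list(rep(1:8, 2L), integer(0)))
  expect_message(ms <- meal_shares(d), "zero delivered")
  expect_false(2L %in% ms$per_trial$replicate_index)
})

test_that("fish effect table summarises the posterior per fish", {
  sim <- tiny_sim(seed = 35)
  fit0 <- fake_fit(standardize_covariates(sim$data))
  fe <- suppressMessages(fish_effect_table(fit0))
  expect_equal(nrow(fe), 24L)
  expect_true(all(fe$effect_median == 0))
  expect_true(all(fe$effect_q05 == 0) && all(fe$effect_q95 == 0))
  expect_true(all(c("diet_level", "median_share") %in% names(fe)))
})

test_that("expected pellet counts conserve the delivered ration", {
  sim <- tiny_sim(seed = 36)
  fit0 <- fake_fit(sim$data)
  pc <- predicted_counts(fit0)
  # symmetric null: every category expects delivered/9
  expect_equal(pc$predicted, pc$delivered / 9, tolerance = 1e-12)
  # conservation per trial over the 9 categories
  tot <- tapply(pc$predicted, paste(pc$cage_id, pc$replicate_index), sum)
  del <- tapply(pc$delivered, paste(pc$cage_id, pc$replicate_index),
                function(v) v[1])
  expect_equal(as.numeric(tot), as.numeric(del), tolerance = 1e-9)
  expect_equal(sum(pc$observed), sum(sim$data$trials$delivered_pellets))
})

test_that("clone curves collapse to closed form and known limits", {
  # closed form e^s/(8 e^s + e^(-8s)) equals the generic softmax pipeline
  for (s in seq(-3, 3, by = 0.5)) {
    p <- consumption_probs(complete_scores(rep(s, 8)))
    expect_equal(mealshare:::clone_probability(s), p[1], tolerance = 1e-12)
  }
  # saturation: all-willing clones split the meal 8 ways, no waste
  expect_equal(mealshare:::clone_probability(60), 1 / 8, tolerance = 1e-12)
  expect_lt(mealshare:::clone_probability(-60), 1e-12)

  sim <- tiny_sim(seed = 37)
  fit0 <- fake_fit(sim$data)
  cc <- clone_curve(fit0, "S", n_grid = 11L)
  expect_true(all(abs(cc$median - 1 / 9) < 1e-12))

  # monotone decreasing in stress when beta_S < 0 in every draw
  fit_neg <- fake_fit(sim$data, modify = function(d) {
    d[, "beta_S"] <- -abs(rnorm(nrow(d), 0.3, 0.05)); d
  })
  ccn <- clone_curve(fit_neg, "S", n_grid = 21L)
  expect_true(all(diff(ccn$median) < 0))
  expect_true(all(diff(ccn$q05) < 0) && all(diff(ccn$q95) < 0))

  # variable/variant mismatch
  expect_error(clone_curve(fit0, "T"), "not in the stress variant")

  # temperature curves report the optimum of the median curve
  fit_t <- fake_fit(sim$data, variant = "temperature", modify = function(d) {
    d[, "beta_T"] <- 0.1; d[, "beta_T2"] <- -0.4; d
  })
  ct <- clone_curve(fit_t, "T", n_grid = 101L)
  expect_false(is.null(attr(ct, "argmax")))
  z_opt <- covariate_scale(sim$data, "T", attr(ct, "argmax"))
  expect_equal(z_opt, 0.1 / (2 * 0.4), tolerance = 0.1)
})

test_that("plot helpers return ggplot objects", {
  sim <- tiny_sim(seed = 38)
  ms <- meal_shares(sim$data)
  expect_s3_class(plot_meal_shares(ms), "ggplot")
  fit0 <- fake_fit(sim$data)
  expect_s3_class(plot_predicted_counts(predicted_counts(fit0)), "ggplot")
  expect_s3_class(plot_clone_curve(clone_curve(fit0, "S")), "ggplot")
})
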