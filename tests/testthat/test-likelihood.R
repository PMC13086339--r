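test_that("fish score assembles the linear predictor per variant", {
  p0 <- intake_params()
  cv <- list(L2_std = 0, T_std = 0, S_std = 0, R_std = 0, diet_level = 60)
  expect_equal(fish_score(cv, p0), 0)

  p <- default_true_params()
  expect_equal(fish_score(list(L2_std = 0, S_std = 0, R_std = 0,
                               diet_level = 60), p, variant = "stress"),
               0.266)
  ps <- intake_params(beta_S = -0.104)
  expect_equal(fish_score(list(S_std = 1, diet_level = 60), ps,
                          variant = "stress"), -0.104)
  # the temperature variant ignores S and uses T + T^2 instead
  pt <- intake_params(beta_T = 0.3, beta_T2 = -0.2, beta_S = 99)
  expect_equal(fish_score(list(T_std = 2, S_std = 1, diet_level = 60), pt,
                          variant = "temperature"), 0.3 * 2 - 0.2 * 4)
  expect_error(fish_score(list(diet_level = 80), p0), "unknown diet level")
})

test_that("score completion pins the waste score to minus the fish sum", {
  expect_equal(complete_scores(rep(0, 8))[9], 0)
  expect_equal(complete_scores(rep(1, 8))[9], -8)
  expect_equal(complete_scores(c(0.5, -0.5, rep(0, 6)))[9], 0)
  set.seed(42)
  for (i in 1:20) {
    s <- rnorm(8, sd = 2)
    expect_lt(abs(sum(complete_scores(s))), 1e-12)
  }
  expect_error(complete_scores(c(rep(0, 7), NA)), "finite")
  expect_error(complete_scores(rep(0, 7)), "length 8")
})

test_that("softmax probabilities normalize, stay positive and are stable", {
  expect_equal(consumption_probs(rep(0, 9)), rep(1 / 9, 9))
  p <- consumption_probs(complete_scores(c(log(2), rep(0, 7))))
  expect_equal(p[1], 2 / 9.5, tolerance = 1e-12)
  set.seed(1)
  for (i in 1:50) {
    pr <- consumption_probs(complete_scores(rnorm(8, sd = 5)))
    expect_lt(abs(sum(pr) - 1), 1e-12)
    expect_true(all(pr > 0))
  }
  # extreme scores must not overflow
  expect_equal(sum(consumption_probs(complete_scores(rep(200, 8)))), 1)
})

test_that("equal fish scores give a 12.5% conditional share", {
  for (s in c(-3, 0, 0.7, 5)) {
    p <- consumption_probs(complete_scores(rep(s, 8)))
    cond <- p[1] / sum(p[1:8])
    expect_equal(cond, 0.125, tolerance = 1e-12)
  }
})

test_that("a common score shift trades consumption against waste", {
  # identifiability gauge: raising all 8 fish scores by c drives the pinned
  # waste score down, so prob(NC) strictly decreases
  base <- rnorm(8)
  shifts <- seq(-2, 2, by = 0.5)
  p_nc <- vapply(shifts, function(cc) {
    consumption_probs(complete_scores(base + cc))[9]
  }, 0)
  expect_true(all(diff(p_nc) < 0))
})

test_that("raising one score raises its probability and lowers the rest", {
  s <- rnorm(8)
  p1 <- consumption_probs(complete_scores(s))
  s2 <- s; s2[3] <- s2[3] + 0.5
  p2 <- consumption_probs(complete_scores(s2))
  expect_gt(p2[3], p1[3])
  expect_true(all(p2[-3] < p1[-3]))
})

test_that("dataset log-likelihood matches the symmetric null and adds up", {
  # one pellet, eaten by fish 5 (second trial empty, keeps covariates
  # non-degenerate)
  d <- manual_data(list(5L, integer(0)))
  d <- standardize_covariates(d)
  p_null <- null_truth(n_cages = 1L, replicates = 2L)
  p_null$fish_effects <- matrix(0, 1, 8, dimnames = list("A", NULL))
  p_null$replicate_effects <- matrix(0, 1, 2, dimnames = list("A", NULL))
  ll <- intake_loglik(d, p_null)
  expect_equal(ll$loglik, log(1 / 9), tolerance = 1e-12)

  # duplicating the event table doubles the log-likelihood
  d2 <- manual_data(list(c(5L, 5L), integer(0)))
  d2 <- standardize_covariates(d2)
  ll2 <- intake_loglik(d2, p_null)
  expect_equal(ll2$loglik, 2 * ll$loglik, tolerance = 1e-12)
})

test_that("vectorized likelihood equals the straight-loop oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    n_rep <- 3L
    outcomes <- replicate(n_rep, sample.int(9L, sample(1:4, 1), replace = TRUE),
                          simplify = FALSE)
    d <- standardize_covariates(manual_data(outcomes))
    params <- random_effects_params(default_true_params(), "A", n_rep,
                                    seed = seed + 100)
    got <- intake_loglik(d, params, "stress")
    expect_equal(got$loglik, loglik_oracle(d, params, "stress"),
                 tolerance = 1e-10)
    expect_equal(sum(got$pointwise), got$loglik, tolerance = 1e-12)
  }
})

test_that("pellet likelihood equals the multinomial pmf up to the coefficient", {
  sim <- tiny_sim(seed = 31)
  ll <- intake_loglik(sim$data, sim$truth, "stress")
  sc <- mealshare:::score_matrix(sim$data, sim$truth, "stress")
  pr <- mealshare:::softmax_rows(sc)
  ev <- sim$data$events
  ekey <- paste(ev$cage_id, ev$replicate_index, sep = ":")
  total <- 0
  for (key in rownames(pr)) {
    cnt <- tabulate(ev$outcome[ekey == key], nbins = 9L)
    if (sum(cnt) == 0) next
    coef <- lfactorial(sum(cnt)) - sum(lfactorial(cnt))
    total <- total + dmultinom(cnt, prob = pr[key, ], log = TRUE) - coef
  }
  expect_equal(ll$loglik, total, tolerance = 1e-8)
})
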