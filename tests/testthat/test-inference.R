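# Small-protocol fits are used here to keep the suite quick; the full
# 3 x 2000 + 2000 protocol is exercised by the acceptance tests.

test_that("empty event tables are refused", {
  sim <- tiny_sim(seed = 2)
  d <- sim$data
  d$events <- d$events[0, ]
  d$trials$delivered_pellets <- 0L
  expect_error(fit_intake(d, "stress"), "no observations")
})

test_that("the sampler's likelihood equals the public likelihood", {
  sim <- tiny_sim(seed = 13)
  md <- mealshare:::build_model_data(sim$data, "stress")
  lay <- mealshare:::par_layout(md)
  pri <- prior_spec()
  lpg <- mealshare:::make_lp_grad(md, pri)
  set.seed(77)
  par <- rnorm(lay$d, 0, 0.5)
  sf <- exp(par[lay$i_lsf]); sr <- exp(par[lay$i_lsr])
  cages <- md$cages
  fe <- matrix(par[lay$i_zf], length(cages), 8,
               dimnames = list(cages, NULL)) * sf
  re <- matrix(NA_real_, length(cages), max(sim$data$trials$replicate_index),
               dimnames = list(cages, NULL))
  for (t in seq_len(md$n_trials)) {
    re[sim$data$trials$cage_id[t], sim$data$trials$replicate_index[t]] <-
      par[lay$i_zr[t]] * sr
  }
  params <- intake_params(
    beta0 = par[1], diet_offsets = c("60" = 0, "75" = par[2], "90" = par[3]),
    beta_S = par[4], beta_R = par[5], beta_L2 = par[lay$i_bL2],
    sigma_fish = sf, sigma_replicate = sr,
    fish_effects = fe, replicate_effects = re)
  ll <- intake_loglik(sim$data, params, "stress")$loglik
  log_prior <- -0.5 * sum(par[c(seq_len(lay$kx), lay$i_bL2)]^2) -
    0.5 * sf^2 + par[lay$i_lsf] - 0.5 * sr^2 + par[lay$i_lsr] -
    0.5 * sum(par[lay$i_zf]^2) - 0.5 * sum(par[lay$i_zr]^2)
  expect_equal(lpg(par)$lp - log_prior, ll, tolerance = 1e-8)
})

test_that("analytic gradients agree with finite differences", {
  sim <- tiny_sim(seed = 14)
  for (variant in c("stress", "temperature")) {
    md <- mealshare:::build_model_data(sim$data, variant)
    lay <- mealshare:::par_layout(md)
    lpg <- mealshare:::make_lp_grad(md, prior_spec())
    set.seed(99)
    par <- rnorm(lay$d, 0, 0.3)
    g <- lpg(par)$grad
    idx <- c(seq_len(lay$kx), lay$i_bL2, lay$i_lsf, lay$i_lsr,
             lay$i_zf[c(1, 10)], lay$i_zr[c(2, 7)])
    h <- 1e-6
    for (i in idx) {
      pp <- par; pp[i] <- pp[i] + h
      pm <- par; pm[i] <- pm[i] - h
      expect_equal(g[i], (lpg(pp)$lp - lpg(pm)$lp) / (2 * h),
                   tolerance = 1e-4)
    }
  }
})

test_that("posterior summaries report the tabulated quantiles", {
  fake_draws <- function(gen) {
    cols <- c("beta0", "diet75", "diet90", "beta_S", "beta_R", "beta_L2",
              "sigma_fish", "sigma_replicate")
    m <- vapply(cols, function(x) gen(), numeric(length(gen())))
    colnames(m) <- cols
    m
  }
  mk_fit <- function(draws) {
    structure(list(
      draws = draws, variant = "stress",
      diagnostics = data.frame(parameter = colnames(draws),
                               rhat = 1, ess = nrow(draws))),
      class = "intake_fit")
  }
  const <- mk_fit(fake_draws(function() rep(3.25, 100)))
  s <- summary(const)
  got <- s[s$parameter == "beta_S", c("q05", "median", "q95")]
  expect_equal(as.numeric(got), c(3.25, 3.25, 3.25))

  set.seed(123)
  norm <- mk_fit(fake_draws(function() rnorm(20000)))
  s2 <- summary(norm)
  expect_equal(s2$median[s2$parameter == "beta0"], 0, tolerance = 0.05)
  expect_equal(s2$q05[s2$parameter == "beta0"], qnorm(0.05), tolerance = 0.05)
  expect_equal(s2$q95[s2$parameter == "beta0"], qnorm(0.95), tolerance = 0.05)
  # the reference diet row is pinned at zero
  expect_equal(as.numeric(s2[s2$parameter == "diet60",
                             c("q05", "median", "q95")]), c(0, 0, 0))
})

test_that("a short fit returns consistent shapes and diagnostics", {
  sim <- tiny_sim(seed = 3, replicates = 6L, planned = 20L)
  fit <- fit_intake(sim$data, "stress", chains = 2L, iter = 200L,
                    warmup = 200L, seed = 5, quiet = TRUE)
  expect_s3_class(fit, "intake_fit")
  expect_equal(nrow(fit$draws), 400L)
  expect_equal(max(fit$chain), 2L)
  expect_true(all(is.finite(fit$diagnostics$rhat)))
  expect_true(all(fit$draws[, "sigma_fish"] > 0))
  expect_equal(ncol(fit$loglik), nrow(sim$data$events))
  expect_equal(nrow(fit$loglik), 400L)
  # pointwise log-likelihood at each draw is a true log probability
  expect_true(all(fit$loglik < 0))
  s <- summary(fit)
  expect_equal(s$parameter[1:3], c("beta0", "sigma_fish", "sigma_replicate"))
})

test_that("temperature-variant fits expose the quadratic temperature term", {
  sim <- tiny_sim(seed = 4, replicates = 6L, planned = 20L)
  fit <- fit_intake(sim$data, "temperature", chains = 2L, iter = 150L,
                    warmup = 150L, seed = 6, quiet = TRUE)
  expect_true(all(c("beta_T", "beta_T2") %in% colnames(fit$draws)))
  expect_false("beta_S" %in% colnames(fit$draws))
})

test_that("prior predictive waste probability is centred near 1/9", {
  set.seed(31)
  n <- 4000
  p9 <- vapply(seq_len(n), function(i) {
    beta0 <- rnorm(1); sf <- abs(rnorm(1))
    fish <- rnorm(8, 0, sf)
    consumption_probs(complete_scores(beta0 + fish))[9]
  }, 0)
  expect_lt(abs(median(p9) - 1 / 9), 0.05)
})
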