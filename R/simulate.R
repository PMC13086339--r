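#' Design configuration for the synthetic feeding-trial generator
#'
#' Encodes the sea-cage experimental design the generator emulates: 6 cages
#' of 8 adult fish (total length ~ Normal(57.3, 3.2) cm), 8 monitored
#' feeding trials per cage spread over 4 months of seasonal cooling
#' (21.8-27.6 C), a boat-traffic stress proxy strongly correlated with
#' temperature (target Pearson r = 0.83), chronic diet levels 60/75/90% of
#' the recommended ration (2 cages each), and a per-trial delivered ration
#' drawn uniformly between 10% and 80% of the planned ration.
#'
#' @param n_cages Number of cages.
#' @param fish_per_cage Fish per cage (the score model is specific to 8).
#' @param replicates_per_cage Feeding trials per cage.
#' @param length_mean_cm,length_sd_cm Total-length distribution (truncated
#'   at 0).
#' @param temp_range_C Length-2 numeric, seasonal min/max water temperature.
#' @param boat_temp_correlation_target Target Pearson correlation between
#'   temperature and boat count.
#' @param boat_mean Mean boat count per trial window (Poisson rate at the
#'   average temperature).
#' @param diet_levels Diet levels (%), assigned in blocks of equal numbers
#'   of cages.
#' @param ration_fraction_range Length-2 numeric in (0, 1]: the delivered
#'   ration is `round(planned * U(range))`.
#' @param planned_pellets_base Planned pellets per trial.
#' @param start_date First trial date (trials span ~4 months from it).
#' @param delta Shape coefficient for structural surface.
#' @return A validated `design_config` list.
#' @export
design_config <- function(n_cages = 6L,
                          fish_per_cage = 8L,
                          replicates_per_cage = 8L,
                          length_mean_cm = 57.3,
                          length_sd_cm = 3.2,
                          temp_range_C = c(21.8, 27.6),
                          boat_temp_correlation_target = 0.83,
                          boat_mean = 12,
                          diet_levels = c(60L, 75L, 90L),
                          ration_fraction_range = c(0.10, 0.80),
                          planned_pellets_base = 40L,
                          start_date = as.Date("2021-08-01"),
                          delta = 0.148) {
  stopifnot(n_cages >= 1L, fish_per_cage >= 1L, replicates_per_cage >= 2L,
            length_mean_cm > 0, length_sd_cm >= 0,
            length(temp_range_C) == 2L, diff(temp_range_C) > 0,
            abs(boat_temp_correlation_target) <= 0.99, boat_mean > 0,
            length(ration_fraction_range) == 2L,
            ration_fraction_range[1] > 0,
            diff(ration_fraction_range) >= 0,
            planned_pellets_base >= 1L, delta > 0)
  structure(
    list(n_cages = as.integer(n_cages),
         fish_per_cage = as.integer(fish_per_cage),
         replicates_per_cage = as.integer(replicates_per_cage),
         length_mean_cm = length_mean_cm, length_sd_cm = length_sd_cm,
         temp_range_C = temp_range_C,
         boat_temp_correlation_target = boat_temp_correlation_target,
         boat_mean = boat_mean,
         diet_levels = as.integer(diet_levels),
         ration_fraction_range = ration_fraction_range,
         planned_pellets_base = as.integer(planned_pellets_base),
         start_date = start_date, delta = delta),
    class = "design_config"
  )
}

# Seasonal half-cosine from the range maximum (first trial, late summer) to
# the range minimum (last trial, autumn).
seasonal_temperature <- function(config) {
  j <- seq_len(config$replicates_per_cage)
  half <- (1 + cos(pi * (j - 1) / (config$replicates_per_cage - 1))) / 2
  config$temp_range_C[1] + diff(config$temp_range_C) * half
}

# Deterministic calibration of the boat-count log-rate slope: with
# B ~ Poisson(exp(a + b * z)) over the fixed standardized temperatures z,
# the population Pearson correlation between temperature and B is
#   cov(z, lambda) / sqrt(var(z) * (mean(lambda) + var(lambda)))
# the slope is chosen on a fine grid as the value whose population
# correlation is closest to the target (the relation saturates at large |b|,
# so a bracketing root-finder is not reliable there).
calibrate_boat_slope <- function(z, mean_boats, target) {
  if (target == 0) return(0)
  pop_corr <- function(b) {
    lam <- exp(b * z)
    lam <- lam * mean_boats / mean(lam)  # keep the mean rate fixed
    cv <- mean(z * lam) - mean(z) * mean(lam)
    vb <- mean(lam) + mean(lam^2) - mean(lam)^2
    cv / sqrt((mean(z^2) - mean(z)^2) * vb)
  }
  grid <- seq(-3, 3, by = 0.005)
  grid[which.min(abs(vapply(grid, pop_corr, 0) - target))]
}

#' Generate the fish table of a synthetic dataset
#'
#' Draws total lengths from Normal(`length_mean_cm`, `length_sd_cm`)
#' truncated at 0 and lays out `fish_per_cage` fish in each cage.
#'
#' @param config A [design_config()].
#' @return A fish data frame (see [intake_data]).
#' @export
generate_fish <- function(config = design_config()) {
  n <- config$n_cages * config$fish_per_cage
  len <- stats::rnorm(n, config$length_mean_cm, config$length_sd_cm)
  while (any(len <= 0)) {
    bad <- len <= 0
    len[bad] <- stats::rnorm(sum(bad), config$length_mean_cm,
                             config$length_sd_cm)
  }
  cage <- rep(sprintf("C%d", seq_len(config$n_cages)),
              each = config$fish_per_cage)
  idx <- rep(seq_len(config$fish_per_cage), times = config$n_cages)
  data.frame(
    fish_id = sprintf("%s-F%d", cage, idx),
    cage_id = cage,
    fish_index = idx,
    total_length_cm = len,
    structural_surface_cm2 = structural_surface(len, config$delta)
  )
}

#' Generate the trial table of a synthetic dataset
#'
#' Temperature follows a smooth seasonal half-cosine from the range maximum
#' down to the range minimum across the trial sequence (all cages are
#' monitored on the same days).  Boat counts are Poisson with log-rate
#' affine in standardized temperature, the slope calibrated
#' (deterministically, from the Poisson population correlation) so the
#' realized temperature-boat correlation approaches the configured target.
#' Delivered pellets are `round(planned * U(ration_fraction_range))`.
#'
#' @param config A [design_config()]; `n_cages` must be divisible by the
#'   number of diet levels.
#' @return A trial data frame (see [intake_data]).
#' @export
generate_environment <- function(config = design_config()) {
  nd <- length(config$diet_levels)
  if (config$n_cages %% nd != 0L) {
    stop("diet assignment must partition cages evenly")
  }
  cages <- sprintf("C%d", seq_len(config$n_cages))
  diet_by_cage <- rep(config$diet_levels, each = config$n_cages / nd)
  temps <- seasonal_temperature(config)
  days <- round(seq(0, 119, length.out = config$replicates_per_cage))
  z <- (temps - mean(temps)) / stats::sd(temps)
  b <- calibrate_boat_slope(z, config$boat_mean,
                            config$boat_temp_correlation_target)
  lam <- exp(b * z)
  lam <- lam * config$boat_mean / mean(lam)
  tr <- expand.grid(replicate_index = seq_len(config$replicates_per_cage),
                    cage_id = cages, stringsAsFactors = FALSE)
  tr <- tr[, c("cage_id", "replicate_index")]
  tr$date <- config$start_date + days[tr$replicate_index]
  tr$temperature_C <- temps[tr$replicate_index]
  tr$boat_count <- stats::rpois(nrow(tr), lam[tr$replicate_index])
  tr$diet_level <- diet_by_cage[match(tr$cage_id, cages)]
  tr$planned_pellets <- config$planned_pellets_base
  frac <- stats::runif(nrow(tr), config$ration_fraction_range[1],
                       config$ration_fraction_range[2])
  tr$delivered_pellets <- as.integer(round(tr$planned_pellets * frac))
  rownames(tr) <- NULL
  tr
}

#' Simulate per-pellet outcomes from the score model
#'
#' For every trial, draws `delivered_pellets` independent outcomes from the
#' 9-way categorical distribution implied by the score model at the supplied
#' (true) parameters, using the dataset's own covariate standardization.
#'
#' @param data A standardized `intake_data` object (its `events` slot is
#'   ignored).
#' @param params An [intake_params()] with realized random effects.
#' @param variant Model variant used to score fish.
#' @return An events data frame.
#' @export
simulate_events <- function(data, params,
                            variant = c("stress", "temperature")) {
  variant <- match.arg(variant)
  pr <- softmax_rows(score_matrix(data, params, variant))
  tr <- data$trials
  out <- vector("list", nrow(tr))
  for (t in seq_len(nrow(tr))) {
    n <- tr$delivered_pellets[t]
    if (n == 0L) next
    key <- paste(tr$cage_id[t], tr$replicate_index[t], sep = ":")
    outcome <- sample.int(9L, n, replace = TRUE, prob = pr[key, ])
    out[[t]] <- data.frame(
      cage_id = tr$cage_id[t],
      replicate_index = tr$replicate_index[t],
      pellet_index = seq_len(n),
      outcome = outcome
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(cage_id = character(), replicate_index = integer(),
                      pellet_index = integer(), outcome = integer()))
  }
  ev <- do.call(rbind, out)
  rownames(ev) <- NULL
  ev
}

#' Generate a complete synthetic dataset with known ground truth
#'
#' Runs the full generative pipeline -- fish, environment, covariate
#' standardization, random-effect draws, per-pellet outcomes -- and returns
#' both the validated dataset and the exact parameters that produced it,
#' for parameter-recovery testing.  Reproducible: the same `seed` yields a
#' byte-identical dataset.
#'
#' @param config A [design_config()].
#' @param truth An [intake_params()]; defaults to [default_true_params()]
#'   (the stress-model posterior medians of the emulated study).  Its
#'   `fish_effects`/`replicate_effects`, if `NULL`, are drawn from
#'   Normal(0, sigma) here and returned in the truth.
#' @param seed Integer RNG seed.
#' @param variant Variant used to generate outcomes.
#' @return A list with `data` (standardized, validated `intake_data`) and
#'   `truth` (the `intake_params` actually used, effects realized).
#' @examples
#' sim <- simulate_intake_data(seed = 1)
#' sim$data
#' @export
simulate_intake_data <- function(config = design_config(),
                                 truth = default_true_params(),
                                 seed = 1L,
                                 variant = c("stress", "temperature")) {
  variant <- match.arg(variant)
  set.seed(seed)
  fish <- generate_fish(config)
  trials <- generate_environment(config)
  skel <- new_intake_data(fish, trials,
                          data.frame(cage_id = character(),
                                     replicate_index = integer(),
                                     pellet_index = integer(),
                                     outcome = integer()))
  skel <- standardize_covariates(skel)
  cages <- sprintf("C%d", seq_len(config$n_cages))
  if (is.null(truth$fish_effects)) {
    truth$fish_effects <- matrix(
      stats::rnorm(config$n_cages * config$fish_per_cage, 0,
                   truth$sigma_fish),
      config$n_cages, config$fish_per_cage, dimnames = list(cages, NULL))
  }
  if (is.null(truth$replicate_effects)) {
    truth$replicate_effects <- matrix(
      stats::rnorm(config$n_cages * config$replicates_per_cage, 0,
                   truth$sigma_replicate),
      config$n_cages, config$replicates_per_cage,
      dimnames = list(cages, NULL))
  }
  ev <- simulate_events(skel, truth, variant)
  dat <- intake_data(fish, trials, ev, delta = config$delta)
  dat <- standardize_covariates(dat)
  list(data = dat, truth = truth)
}
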