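# Shared fixtures: all synthetic, generated in code at test time.

# Small three-cage design, one cage per diet level, short trials: fast to
# simulate and fit while exercising every covariate.
tiny_config <- function(replicates = 4L, planned = 12L) {
  design_config(n_cages = 3L, replicates_per_cage = replicates,
                planned_pellets_base = planned)
}

tiny_sim <- function(seed = 1L, replicates = 4L, planned = 12L,
                     truth = default_true_params()) {
  simulate_intake_data(tiny_config(replicates, planned), truth, seed = seed)
}

# Truth with all score terms at zero (tiny dispersions, zero effects):
# every pellet outcome is uniform over the 9 categories.
null_truth <- function(n_cages = 3L, replicates = 4L) {
  cages <- sprintf("C%d", seq_len(n_cages))
  intake_params(
    sigma_fish = 1e-9, sigma_replicate = 1e-9,
    fish_effects = matrix(0, n_cages, 8L, dimnames = list(cages, NULL)),
    replicate_effects = matrix(0, n_cages, replicates,
                               dimnames = list(cages, NULL))
  )
}

# Hand-built single-cage dataset with fully controlled pellet outcomes.
# `outcomes` is a list (one element per replicate) of integer vectors in
# 1..9; delivered_pellets is their length.
manual_data <- function(outcomes, diet = 60L, lengths = seq(50, 64, 2)) {
  fish <- data.frame(
    fish_id = sprintf("A-F%d", 1:8), cage_id = "A", fish_index = 1:8,
    total_length_cm = lengths
  )
  trials <- data.frame(
    cage_id = "A", replicate_index = seq_along(outcomes),
    date = as.Date("2021-08-01") + seq_along(outcomes),
    temperature_C = seq(27, 22, length.out = length(outcomes)),
    boat_count = rev(seq_along(outcomes)) * 3L,
    diet_level = diet, planned_pellets = 20L,
    delivered_pellets = lengths(outcomes)
  )
  events <- do.call(rbind, lapply(seq_along(outcomes), function(j) {
    if (length(outcomes[[j]]) == 0L) return(NULL)
    data.frame(cage_id = "A", replicate_index = j,
               pellet_index = seq_along(outcomes[[j]]),
               outcome = as.integer(outcomes[[j]]))
  }))
  if (is.null(events)) {
    events <- data.frame(cage_id = character(), replicate_index = integer(),
                         pellet_index = integer(), outcome = integer())
  }
  intake_data(fish, trials, events)
}

# Straight-loop likelihood oracle: recomputes the score, completion and
# softmax pellet by pellet through the scalar API, no vectorization.
loglik_oracle <- function(data, params, variant = "stress") {
  ev <- data$events
  total <- 0
  for (r in seq_len(nrow(ev))) {
    tr <- data$trials[data$trials$cage_id == ev$cage_id[r] &
                        data$trials$replicate_index == ev$replicate_index[r], ]
    sc8 <- numeric(8)
    for (i in 1:8) {
      fi <- data$fish[data$fish$cage_id == ev$cage_id[r] &
                        data$fish$fish_index == i, ]
      sc8[i] <- fish_score(
        list(L2_std = fi$L2_std, T_std = tr$T_std, S_std = tr$S_std,
             R_std = tr$R_std, diet_level = tr$diet_level),
        params,
        fish_effect = params$fish_effects[ev$cage_id[r], i],
        replicate_effect = params$replicate_effects[ev$cage_id[r],
                                                    tr$replicate_index],
        variant = variant)
    }
    p <- consumption_probs(complete_scores(sc8))
    total <- total + log(p[ev$outcome[r]])
  }
  total
}

# Random realized effects for a dataset shape.
random_effects_params <- function(base, cages, replicates, seed) {
  set.seed(seed)
  base$fish_effects <- matrix(rnorm(length(cages) * 8, 0, base$sigma_fish),
                              length(cages), 8,
                              dimnames = list(cages, NULL))
  base$replicate_effects <- matrix(
    rnorm(length(cages) * replicates, 0, base$sigma_replicate),
    length(cages), replicates, dimnames = list(cages, NULL))
  base
}
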