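#' Share of residual variance attributable to fish-specific effects
#'
#' The repeatability-style partition `a / (a + b)` of the residual
#' variability between the fish-level and the replicate-level dispersion.
#' By default the two inputs are consumed exactly as the study tabulates
#' them (posterior-median dispersion values 0.431 and 0.183 give 0.702,
#' the headline 70.2%); `scale = "variance"` instead squares them first,
#' the textbook repeatability on sd inputs (documented, non-default --
#' only the unsquared ratio reproduces the published percentage).
#'
#' @param disp_fish,disp_replicate Positive dispersion values.
#' @param scale `"as_reported"` (default) or `"variance"`.
#' @return Fraction in (0, 1).
#' @examples
#' variance_partition(0.431, 0.183) # 0.702
#' @export
variance_partition <- function(disp_fish, disp_replicate,
                               scale = c("as_reported", "variance")) {
  scale <- match.arg(scale)
  if (!is.numeric(disp_fish) || !is.numeric(disp_replicate) ||
      any(disp_fish <= 0) || any(disp_replicate <= 0)) {
    stop("dispersion inputs must be positive")
  }
  if (scale == "variance") {
    disp_fish <- disp_fish^2
    disp_replicate <- disp_replicate^2
  }
  disp_fish / (disp_fish + disp_replicate)
}

#' Individual meal shares per fish and trial
#'
#' For every trial, each fish's share is its consumed pellet count divided
#' by the pellets *delivered* (not consumed), in percent, so feed waste
#' depresses all eight shares and per trial the eight shares plus the waste
#' share total 100%.  Fish-level medians and quartiles are computed across
#' each fish's trials; fish are ordered within diet level by decreasing
#' median share (the reference share under even distribution and no waste
#' is 12.5%).  Trials with zero delivered pellets are excluded with a
#' notice.
#'
#' @param data An `intake_data` object.
#' @return A `meal_share_table`: list with `per_trial` (fish x trial
#'   shares), `per_fish` (median and quartiles, in display order),
#'   `waste_by_diet` (% of pellets not consumed per diet level).
#' @export
meal_shares <- function(data) {
  tr <- data$trials
  ev <- data$events
  fi <- data$fish
  keep <- tr$delivered_pellets > 0
  if (any(!keep)) {
    message(sprintf("excluding %d trial(s) with zero delivered pellets",
                    sum(!keep)))
  }
  tr <- tr[keep, , drop = FALSE]
  tkey <- paste(tr$cage_id, tr$replicate_index, sep = ":")
  ekey <- paste(ev$cage_id, ev$replicate_index, sep = ":")

  per_trial <- do.call(rbind, lapply(seq_along(tkey), function(t) {
    cnt <- tabulate(ev$outcome[ekey == tkey[t]], nbins = 9L)
    data.frame(
      cage_id = tr$cage_id[t],
      replicate_index = tr$replicate_index[t],
      diet_level = tr$diet_level[t],
      fish_index = c(1:8, NA_integer_),
      consumed = cnt,
      delivered = tr$delivered_pellets[t],
      share_pct = 100 * cnt / tr$delivered_pellets[t],
      waste = c(rep(FALSE, 8L), TRUE)
    )
  }))
  rownames(per_trial) <- NULL

  fish_rows <- per_trial[!per_trial$waste, ]
  key <- paste(fish_rows$cage_id, fish_rows$fish_index, sep = ":")
  agg <- function(f) tapply(fish_rows$share_pct, key, f)
  med <- agg(stats::median)
  per_fish <- data.frame(
    cage_id = sub(":.*", "", names(med)),
    fish_index = as.integer(sub(".*:", "", names(med))),
    median_share = as.numeric(med),
    q25 = as.numeric(agg(function(v) stats::quantile(v, 0.25))),
    q75 = as.numeric(agg(function(v) stats::quantile(v, 0.75))),
    n_trials = as.numeric(tapply(fish_rows$share_pct, key, length))
  )
  per_fish$fish_id <- fi$fish_id[match(
    paste(per_fish$cage_id, per_fish$fish_index),
    paste(fi$cage_id, fi$fish_index))]
  diet_of_cage <- tr$diet_level[match(per_fish$cage_id, tr$cage_id)]
  per_fish$diet_level <- diet_of_cage
  per_fish <- per_fish[order(per_fish$diet_level, -per_fish$median_share), ]
  rownames(per_fish) <- NULL

  waste_rows <- per_trial[per_trial$waste, ]
  waste_by_diet <- data.frame(
    diet_level = sort(unique(waste_rows$diet_level)),
    waste_pct = as.numeric(tapply(
      waste_rows$consumed, waste_rows$diet_level, sum) /
        tapply(waste_rows$delivered, waste_rows$diet_level, sum) * 100)
  )

  structure(list(per_trial = per_trial, per_fish = per_fish,
                 waste_by_diet = waste_by_diet),
            class = "meal_share_table")
}

#' @export
print.meal_share_table <- function(x, ...) {
  cat(sprintf("Meal shares: %d fish, %d trials\n",
              nrow(x$per_fish), length(unique(paste(
                x$per_trial$cage_id, x$per_trial$replicate_index)))))
  cat("Waste by diet level (%):\n")
  print(x$waste_by_diet, digits = 2, row.names = FALSE)
  cat("Top fish by median share (reference under even split: 12.5%):\n")
  print(utils::head(x$per_fish[, c("fish_id", "diet_level", "median_share",
                                   "q25", "q75")], 6),
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' Posterior summaries of the fish-specific effects
#'
#' Median and 5th/95th percentiles of each fish's random effect (the
#' size- and environment-independent component of its willingness to
#' feed), grouped by diet level and cage and sorted in the same order as
#' the observed meal shares, so effect ranking and share ranking can be
#' compared directly.
#'
#' @param fit An `intake_fit`.
#' @param shares Optionally a precomputed [meal_shares()] table for the
#'   fitted dataset (computed on the fly otherwise).
#' @return Data frame with one row per fish: effect quantiles, diet, cage
#'   and the fish's observed median meal share.
#' @export
fish_effect_table <- function(fit, shares = NULL) {
  if (is.null(shares)) shares <- meal_shares(fit$data)
  pf <- shares$per_fish
  cols <- sprintf("fish_effect[%s,%d]", pf$cage_id, pf$fish_index)
  qs <- t(apply(fit$draws[, cols, drop = FALSE], 2L,
                stats::quantile, probs = c(0.05, 0.5, 0.95), names = FALSE))
  out <- data.frame(
    fish_id = pf$fish_id, cage_id = pf$cage_id,
    fish_index = pf$fish_index, diet_level = pf$diet_level,
    effect_q05 = qs[, 1], effect_median = qs[, 2], effect_q95 = qs[, 3],
    median_share = pf$median_share
  )
  rownames(out) <- NULL
  out
}

#' Observed versus model-expected pellet counts
#'
#' For every (fish, trial) pair the expectation is the trial's delivered
#' pellet count times the posterior-mean consumption probability of that
#' fish under its trial covariates and realized effects; the waste
#' category is included, so per trial the nine expectations sum exactly to
#' the delivered count (per posterior draw, since the probabilities sum to
#' one).
#'
#' @param fit An `intake_fit`.
#' @return Data frame with observed and predicted counts per trial and
#'   category (fish 1..8 and waste = category 9).
#' @export
predicted_counts <- function(fit) {
  md <- fit$model_data
  lay <- par_layout(md)
  raw <- posterior_raw(fit)
  pmean <- matrix(0, md$n_trials, 9L)
  for (i in seq_len(nrow(raw))) {
    s8 <- model_scores(raw[i, ], md, lay)
    pmean <- pmean + softmax_rows(cbind(s8, -rowSums(s8)))
  }
  pmean <- pmean / nrow(raw)
  tr <- fit$data$trials
  out <- do.call(rbind, lapply(seq_len(md$n_trials), function(t) {
    data.frame(
      cage_id = tr$cage_id[t],
      replicate_index = tr$replicate_index[t],
      category = c(1:8, 9L),
      is_waste = c(rep(FALSE, 8L), TRUE),
      observed = md$counts[t, ],
      predicted = md$n_tot[t] * pmean[t, ],
      delivered = md$n_tot[t]
    )
  }))
  rownames(out) <- NULL
  out
}

# Reconstruct unconstrained draws from the natural-scale draw matrix (the
# mapping is invertible: z = effect / sigma, log sigma).
posterior_raw <- function(fit) {
  md <- fit$model_data
  lay <- par_layout(md)
  d <- fit$draws
  n_cage <- length(md$cages)
  fish_cols <- paste0("fish_effect[", rep(md$cages, times = 8L), ",",
                      rep(1:8, each = n_cage), "]")
  rep_cols <- paste0("replicate_effect[", md$trial_key, "]")
  raw <- matrix(NA_real_, nrow(d), lay$d)
  raw[, seq_len(lay$kx)] <- d[, md$x_cols]
  raw[, lay$i_bL2] <- d[, "beta_L2"]
  raw[, lay$i_lsf] <- log(d[, "sigma_fish"])
  raw[, lay$i_lsr] <- log(d[, "sigma_replicate"])
  raw[, lay$i_zf] <- d[, fish_cols] / d[, "sigma_fish"]
  raw[, lay$i_zr] <- d[, rep_cols] / d[, "sigma_replicate"]
  raw
}

#' Clone-cage marginal-effect curve for one covariate
#'
#' Isolates one covariate's effect on the per-fish consumption probability
#' by pretending the cage holds eight identical fish: all eight scores
#' equal `s`, the waste score is `-8s` by the sum-to-zero completion, and
#' each clone's probability has the closed form
#' \eqn{e^s / (8 e^s + e^{-8 s})}.  The score is evaluated at the reference
#' diet (60%), with every other covariate at its mean (0 on the
#' standardized scale) and fish/replicate effects at 0 (the
#' population-typical individual), for each posterior draw; the curve
#' reports the median and 5th/95th percentiles across draws.
#'
#' @param fit An `intake_fit`.
#' @param variable `"L2"`, `"S"`, `"T"` or `"R"` (must be present in the
#'   fitted variant: `"S"` requires the stress variant, `"T"` the
#'   temperature variant).
#' @param grid Natural-scale grid values; defaults to an even grid over the
#'   observed covariate range.
#' @param n_grid Grid length when `grid` is `NULL`.
#' @return Data frame `grid`, `median`, `q05`, `q95` (consumption
#'   probability per fish).  For temperature curves the attribute
#'   `"argmax"` holds the grid value maximising the median curve.
#' @export
clone_curve <- function(fit, variable = c("L2", "S", "T", "R"),
                        grid = NULL, n_grid = 101L) {
  variable <- match.arg(variable)
  if (variable == "S" && fit$variant != "stress") {
    stop("covariate S is not in the temperature variant")
  }
  if (variable == "T" && fit$variant != "temperature") {
    stop("covariate T is not in the stress variant")
  }
  data <- fit$data
  st <- data$standardization
  i <- match(variable, st$covariate)
  if (is.null(grid)) {
    src <- switch(variable,
                  L2 = data$fish$structural_surface_cm2,
                  T = data$trials$temperature_C,
                  S = data$trials$boat_count,
                  R = data$trials$delivered_pellets)
    grid <- seq(min(src), max(src), length.out = n_grid)
  }
  z <- (grid - st$mean[i]) / st$sd[i]
  dr <- fit$draws
  slope_term <- switch(variable,
    L2 = outer(dr[, "beta_L2"], z),
    S = outer(dr[, "beta_S"], z),
    R = outer(dr[, "beta_R"], z),
    T = outer(dr[, "beta_T"], z) + outer(dr[, "beta_T2"], z^2)
  )
  s <- dr[, "beta0"] + slope_term              # draws x grid
  p <- clone_probability(s)
  qs <- apply(p, 2L, stats::quantile, probs = c(0.05, 0.5, 0.95),
              names = FALSE)
  out <- data.frame(grid = grid, median = qs[2, ], q05 = qs[1, ],
                    q95 = qs[3, ])
  attr(out, "argmax") <- grid[which.max(out$median)]
  attr(out, "variable") <- variable
  out
}

# Closed-form per-clone consumption probability at common score s,
# e^s / (8 e^s + e^(-8s)), computed as 1 / (8 + e^(-9s)) so large positive
# scores cannot overflow (the limit is the even 8-way split, 1/8).
clone_probability <- function(s) {
  1 / (8 + exp(-9 * s))
}
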