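#' Structural surface of a fish
#'
#' Body size enters the ingestion model through the structural surface, the
#' squared structural length \eqn{L^2 = (L_T \delta)^2}, where \eqn{L_T} is
#' total length in cm and \eqn{\delta} is a species-specific shape
#' coefficient (0.148 for European seabass).  Surface-proportional ingestion
#' is the standard bioenergetic assumption for feeding rates.
#'
#' @param total_length_cm Total length(s) in cm, non-negative.
#' @param delta Shape coefficient, > 0. Default 0.148 (European seabass).
#' @return Structural surface(s) in cm^2.
#' @examples
#' structural_surface(57.3) # mean fish of the emulated study, ~71.9 cm^2
#' @export
structural_surface <- function(total_length_cm, delta = 0.148) {
  if (!is.numeric(total_length_cm) || any(!is.finite(total_length_cm))) {
    stop("`total_length_cm` must be finite numeric")
  }
  if (any(total_length_cm < 0)) {
    stop("`total_length_cm` must be non-negative")
  }
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0) {
    stop("`delta` must be a single positive number")
  }
  (total_length_cm * delta)^2
}

#' Linear score of one fish for one feeding trial
#'
#' Evaluates the fish's linear predictor ("score") given standardized trial
#' covariates and realized random effects.  The model variant determines
#' which member of the collinear pair {stress, temperature} is active: the
#' stress variant uses the boat-count slope, the temperature variant uses
#' the linear + quadratic temperature terms; the two are never combined.
#'
#' @param covariates List or named vector with `L2_std`, `T_std`, `S_std`,
#'   `R_std` (standardized covariates; unused entries may be omitted) and
#'   `diet_level` (60, 75 or 90).
#' @param params An [intake_params()] object (its `fish_effects` /
#'   `replicate_effects` fields are not consulted; pass effects explicitly).
#' @param fish_effect,replicate_effect Realized random effects for this fish
#'   and trial.
#' @param variant `"stress"` or `"temperature"`.
#' @return The scalar score; larger values mean greater willingness to take
#'   the pellet.
#' @export
fish_score <- function(covariates, params, fish_effect = 0,
                       replicate_effect = 0,
                       variant = c("stress", "temperature")) {
  variant <- match.arg(variant)
  cv <- as.list(covariates)
  diet <- as.character(cv$diet_level)
  if (length(diet) != 1L || !diet %in% names(params$diet_offsets)) {
    stop(sprintf("unknown diet level: %s", paste(diet, collapse = ", ")))
  }
  grab <- function(nm) {
    v <- cv[[nm]]
    if (is.null(v)) 0 else v
  }
  s <- params$beta0 + params$diet_offsets[[diet]] +
    params$beta_L2 * grab("L2_std") +
    params$beta_R * grab("R_std") +
    fish_effect + replicate_effect
  if (variant == "stress") {
    s <- s + params$beta_S * grab("S_std")
  } else {
    tz <- grab("T_std")
    s <- s + params$beta_T * tz + params$beta_T2 * tz^2
  }
  unname(s)
}

#' Complete an 8-fish score vector with the not-consumed score
#'
#' The ninth category (pellet sinks uneaten) has its score pinned to minus
#' the sum of the eight fish scores.  This sum-to-zero completion fixes the
#' additive gauge freedom of the softmax: a common shift of all fish scores
#' is no longer unidentifiable but instead trades consumption off against
#' waste.
#'
#' @param fish_scores Numeric vector of 8 finite fish scores.
#' @return Numeric vector of 9 scores summing to zero.
#' @export
complete_scores <- function(fish_scores) {
  if (length(fish_scores) != 8L) {
    stop("`fish_scores` must have length 8 (one score per fish)")
  }
  if (!is.numeric(fish_scores) || any(!is.finite(fish_scores))) {
    stop("`fish_scores` must be finite")
  }
  c(fish_scores, -sum(fish_scores))
}

#' Softmax consumption probabilities
#'
#' Maps a completed 9-score vector to the categorical probability that a
#' delivered pellet is taken by fish 1..8 or not consumed (category 9):
#' \eqn{p_k = e^{s_k} / \sum_m e^{s_m}}.  Computed with max-subtraction so
#' large scores cannot overflow.
#'
#' @param scores Numeric vector of 9 finite scores (see [complete_scores()]).
#' @return Probability vector of length 9 summing to 1, all entries > 0.
#' @examples
#' consumption_probs(complete_scores(rep(0, 8))) # uniform 1/9
#' @export
consumption_probs <- function(scores) {
  if (length(scores) != 9L) {
    stop("`scores` must have length 9 (8 fish + not-consumed)")
  }
  if (!is.numeric(scores) || any(!is.finite(scores))) {
    stop("`scores` must be finite")
  }
  e <- exp(scores - max(scores))
  e / sum(e)
}

# Row-wise softmax for a trials x 9 score matrix.
softmax_rows <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m - mx)
  e / rowSums(e)
}

# Score matrix (one row per trial, 9 columns) for a standardized dataset at
# given parameters.  Requires realized random effects in `params` (matrices
# indexed by cage id); zero matrices are substituted when absent.
score_matrix <- function(data, params, variant = c("stress", "temperature")) {
  variant <- match.arg(variant)
  tr <- data$trials
  fi <- data$fish
  if (is.null(tr$T_std)) {
    stop("dataset is not standardized; call standardize_covariates() first")
  }
  cages <- sort(unique(fi$cage_id))
  n_rep <- max(tr$replicate_index)
  fe <- params$fish_effects
  re <- params$replicate_effects
  if (is.null(fe)) {
    fe <- matrix(0, length(cages), 8L, dimnames = list(cages, NULL))
  }
  if (is.null(re)) {
    re <- matrix(0, length(cages), n_rep, dimnames = list(cages, NULL))
  }
  # fish-level terms per cage: 6 x 8 matrices indexed [cage, fish_index]
  l2_mat <- matrix(NA_real_, length(cages), 8L, dimnames = list(cages, NULL))
  for (r in seq_len(nrow(fi))) {
    l2_mat[fi$cage_id[r], fi$fish_index[r]] <- fi$L2_std[r]
  }
  ci <- match(tr$cage_id, cages)
  trial_const <- params$beta0 +
    params$diet_offsets[as.character(tr$diet_level)] +
    params$beta_R * tr$R_std
  if (variant == "stress") {
    trial_const <- trial_const + params$beta_S * tr$S_std
  } else {
    trial_const <- trial_const + params$beta_T * tr$T_std +
      params$beta_T2 * tr$T_std^2
  }
  trial_const <- trial_const + re[cbind(ci, tr$replicate_index)]
  sc <- trial_const + params$beta_L2 * l2_mat[ci, , drop = FALSE] +
    fe[ci, , drop = FALSE]
  sc <- cbind(sc, -rowSums(sc))
  dimnames(sc) <- list(paste(tr$cage_id, tr$replicate_index, sep = ":"),
                       c(paste0("fish", 1:8), "NC"))
  sc
}

#' Dataset log-likelihood under the multinomial softmax model
#'
#' Sums, over every delivered pellet, the log probability of its observed
#' outcome (consuming fish or waste) under the score model at the supplied
#' parameters.  Because pellets are conditionally independent given the
#' trial, this equals the multinomial log-pmf of the per-trial outcome
#' counts up to the additive multinomial coefficient.
#'
#' @param data A standardized [intake_data] object.
#' @param params An [intake_params()] object with realized random effects.
#' @param variant `"stress"` or `"temperature"`.
#' @return A list with `loglik` (total) and `pointwise` (per-pellet log
#'   likelihoods, in `data$events` row order; retained for LOO).
#' @export
intake_loglik <- function(data, params,
                          variant = c("stress", "temperature")) {
  variant <- match.arg(variant)
  ev <- data$events
  sc <- score_matrix(data, params, variant)
  pr <- softmax_rows(sc)
  key <- paste(ev$cage_id, ev$replicate_index, sep = ":")
  row <- match(key, rownames(pr))
  if (anyNA(row)) {
    bad <- which(is.na(row))[1L]
    stop(sprintf("event row %d references unknown trial %s", bad, key[bad]))
  }
  pointwise <- log(pr[cbind(row, ev$outcome)])
  list(loglik = sum(pointwise), pointwise = pointwise)
}
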