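#' Model parameters for the ingestion-rate score model
#'
#' Bundles every coefficient of the linear score for a pellet being taken by
#' fish \eqn{i} in replicate \eqn{j} of cage \eqn{c}:
#' \deqn{sco_{i,j,c} = \beta_{0,D} + \beta_{L^2} L^2_{i,c} + \beta_T T_{j,c}
#'   + \beta_{T^2} T^2_{j,c} + \beta_S S_{j,c} + \beta_R R_{j,c}
#'   + Fish_{i,c} + Replicate_{j,c}}
#' together with the dispersions of the two crossed random effects and the
#' realized effects themselves.  The same object is used as ground truth by
#' the simulator and as a point at which to evaluate the likelihood.
#'
#' Continuous covariates (\eqn{L^2}, \eqn{T}, \eqn{S}, \eqn{R}) are expected
#' on the standardized scale; the temperature curvature term is the square of
#' standardized \eqn{T}.  Diet enters as an intercept per level with the 60%
#' level as reference (offset pinned at 0).
#'
#' @param beta0 General intercept (reference diet level, 60%).
#' @param diet_offsets Named numeric of length 3 (`"60"`, `"75"`, `"90"`):
#'   additive intercept offsets per diet level; the `"60"` entry must be 0.
#' @param beta_L2 Slope for structural surface (standardized \eqn{L^2}).
#' @param beta_T,beta_T2 Linear and quadratic slopes for standardized
#'   temperature (used by the temperature model variant only).
#' @param beta_S Slope for the anthropogenic stress proxy (standardized boat
#'   count; stress variant only).
#' @param beta_R Slope for standardized delivered ration.
#' @param sigma_fish Between-fish standard deviation (> 0).
#' @param sigma_replicate Between-replicate standard deviation (> 0).
#' @param fish_effects Matrix (cages x 8) of fish random effects, rownames =
#'   cage ids, or `NULL` if not yet drawn.
#' @param replicate_effects Matrix (cages x replicates) of trial random
#'   effects, rownames = cage ids, or `NULL`.
#'
#' @return An object of class `intake_params` (a validated list).
#' @seealso [default_true_params()] for the values used as simulation truth.
#' @export
intake_params <- function(beta0 = 0,
                          diet_offsets = c("60" = 0, "75" = 0, "90" = 0),
                          beta_L2 = 0,
                          beta_T = 0,
                          beta_T2 = 0,
                          beta_S = 0,
                          beta_R = 0,
                          sigma_fish = 1,
                          sigma_replicate = 1,
                          fish_effects = NULL,
                          replicate_effects = NULL) {
  if (is.null(names(diet_offsets)) ||
      !setequal(names(diet_offsets), c("60", "75", "90"))) {
    stop("`diet_offsets` must be named with levels \"60\", \"75\", \"90\"")
  }
  diet_offsets <- diet_offsets[c("60", "75", "90")]
  if (diet_offsets[["60"]] != 0) {
    stop("reference diet level (60%) must have offset 0")
  }
  if (!is.numeric(sigma_fish) || sigma_fish <= 0) {
    stop("`sigma_fish` must be > 0")
  }
  if (!is.numeric(sigma_replicate) || sigma_replicate <= 0) {
    stop("`sigma_replicate` must be > 0")
  }
  for (nm in c("beta0", "beta_L2", "beta_T", "beta_T2", "beta_S", "beta_R")) {
    v <- get(nm, inherits = FALSE)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("`%s` must be a single finite number", nm))
    }
  }
  structure(
    list(
      beta0 = beta0,
      diet_offsets = diet_offsets,
      beta_L2 = beta_L2,
      beta_T = beta_T,
      beta_T2 = beta_T2,
      beta_S = beta_S,
      beta_R = beta_R,
      sigma_fish = sigma_fish,
      sigma_replicate = sigma_replicate,
      fish_effects = fish_effects,
      replicate_effects = replicate_effects
    ),
    class = "intake_params"
  )
}

#' Default simulation truth: posterior medians of the fitted stress model
#'
#' The generator's default ground truth uses the posterior medians estimated
#' for the stress-based model on the sea-cage study this package emulates:
#' intercept 0.266, between-fish sd 0.431, between-replicate sd 0.183, size
#' slope 0.101, stress slope -0.104, ration slope -0.050, diet offsets
#' -0.072 (75%) and -0.136 (90%).  Temperature slopes are 0 (the stress
#' variant omits them).
#'
#' @return An `intake_params` object without realized random effects (these
#'   are drawn by the simulator from the two dispersions).
#' @export
default_true_params <- function() {
  intake_params(
    beta0 = 0.266,
    diet_offsets = c("60" = 0, "75" = -0.072, "90" = -0.136),
    beta_L2 = 0.101,
    beta_T = 0,
    beta_T2 = 0,
    beta_S = -0.104,
    beta_R = -0.050,
    sigma_fish = 0.431,
    sigma_replicate = 0.183
  )
}

#' @export
print.intake_params <- function(x, ...) {
  cat("Ingestion-rate score model parameters\n")
  cat(sprintf("  beta0 (60%% diet): %.3f  | diet 75%%: %+.3f  diet 90%%: %+.3f\n",
              x$beta0, x$diet_offsets[["75"]], x$diet_offsets[["90"]]))
  cat(sprintf("  beta_L2: %+.3f  beta_T: %+.3f  beta_T2: %+.3f  beta_S: %+.3f  beta_R: %+.3f\n",
              x$beta_L2, x$beta_T, x$beta_T2, x$beta_S, x$beta_R))
  cat(sprintf("  sigma_fish: %.3f  sigma_replicate: %.3f\n",
              x$sigma_fish, x$sigma_replicate))
  cat(sprintf("  random effects: %s\n",
              if (is.null(x$fish_effects)) "not drawn" else "realized"))
  invisible(x)
}
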