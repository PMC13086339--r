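#' @title Feeding-trial dataset container
#' @description An `intake_data` object bundles the three tables of a
#'   per-pellet feeding-trial study:
#'   \describe{
#'     \item{fish}{one row per tagged fish: `fish_id`, `cage_id`,
#'       `fish_index` (1..8 within cage), `total_length_cm`,
#'       `structural_surface_cm2` (computed, \eqn{(L_T\delta)^2}).}
#'     \item{trials}{one row per monitored meal: `cage_id`,
#'       `replicate_index` (1..8), `date`, `temperature_C`, `boat_count`
#'       (anthropogenic stress proxy), `diet_level` (60/75/90),
#'       `planned_pellets`, `delivered_pellets`.}
#'     \item{events}{one row per delivered pellet: `cage_id`,
#'       `replicate_index`, `pellet_index` (delivery order), `outcome`
#'       (1..8 = consuming fish index, 9 = not consumed).}
#'   }
#'   After [standardize_covariates()] the object additionally carries a
#'   `standardization` table and standardized covariate columns `L2_std`
#'   (fish) and `T_std`, `S_std`, `R_std` (trials).
#' @name intake_data
NULL

NOT_CONSUMED <- 9L

new_intake_data <- function(fish, trials, events, standardization = NULL) {
  structure(
    list(fish = fish, trials = trials, events = events,
         standardization = standardization),
    class = "intake_data"
  )
}

#' Assemble and validate a feeding-trial dataset from data frames
#'
#' @param fish,trials,events Data frames with the columns documented in
#'   [intake_data] (events `outcome` already integer-coded, 9 = waste).
#' @param delta Shape coefficient used to (re)compute structural surface.
#' @return A validated `intake_data` object.
#' @export
intake_data <- function(fish, trials, events, delta = 0.148) {
  fish <- as.data.frame(fish)
  trials <- as.data.frame(trials)
  events <- as.data.frame(events)
  fish$cage_id <- as.character(fish$cage_id)
  fish$fish_id <- as.character(fish$fish_id)
  trials$cage_id <- as.character(trials$cage_id)
  events$cage_id <- as.character(events$cage_id)
  fish$structural_surface_cm2 <- structural_surface(fish$total_length_cm, delta)
  x <- new_intake_data(fish, trials, events)
  validate_intake_data(x)
  x
}

#' Validate the referential and design invariants of a dataset
#'
#' Checks, erroring with the offending row where possible: exactly 8 fish
#' per cage with indices 1..8; positive lengths; outcomes in 1..9; every
#' event's (cage, replicate) present in the trial table; per-trial event
#' counts equal to `delivered_pellets`; diet level constant within cage.
#'
#' @param x An `intake_data` object.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_intake_data <- function(x) {
  fish <- x$fish; trials <- x$trials; events <- x$events
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s table: missing column(s) %s", what,
                   paste(miss, collapse = ", ")))
    }
  }
  need(fish, c("fish_id", "cage_id", "fish_index", "total_length_cm"), "fish")
  need(trials, c("cage_id", "replicate_index", "temperature_C", "boat_count",
                 "diet_level", "planned_pellets", "delivered_pellets"),
       "trials")
  need(events, c("cage_id", "replicate_index", "pellet_index", "outcome"),
       "events")

  if (any(fish$total_length_cm <= 0)) {
    stop(sprintf("fish row %d: total_length_cm must be > 0",
                 which(fish$total_length_cm <= 0)[1L]))
  }
  sizes <- table(fish$cage_id)
  if (any(sizes != 8L)) {
    bad <- names(sizes)[sizes != 8L][1L]
    stop(sprintf("cage %s: cage size != 8 (%d fish)", bad, sizes[[bad]]))
  }
  by_cage <- split(fish$fish_index, fish$cage_id)
  for (cg in names(by_cage)) {
    if (!identical(sort(as.integer(by_cage[[cg]])), 1:8)) {
      stop(sprintf("cage %s: fish_index must be exactly 1..8", cg))
    }
  }
  if (anyDuplicated(fish$fish_id)) {
    stop("duplicated fish_id")
  }
  if (!all(trials$cage_id %in% fish$cage_id)) {
    stop("trial table references a cage with no fish")
  }
  if (any(trials$delivered_pellets < 0)) {
    stop("delivered_pellets must be non-negative")
  }
  dl <- tapply(trials$diet_level, trials$cage_id,
               function(v) length(unique(v)))
  if (any(dl != 1L)) {
    stop(sprintf("cage %s: diet_level must be constant within cage",
                 names(dl)[dl != 1L][1L]))
  }
  if (!all(trials$diet_level %in% c(60, 75, 90))) {
    stop("diet_level must be one of 60, 75, 90")
  }
  tkey <- paste(trials$cage_id, trials$replicate_index, sep = ":")
  if (anyDuplicated(tkey)) {
    stop("duplicated (cage_id, replicate_index) in trial table")
  }
  bad <- which(!(events$outcome %in% 1:9))
  if (length(bad)) {
    stop(sprintf("event row %d: outcome out of range (must be 1..8 or NC)",
                 bad[1L]))
  }
  ekey <- paste(events$cage_id, events$replicate_index, sep = ":")
  bad <- which(!(ekey %in% tkey))
  if (length(bad)) {
    stop(sprintf("event row %d: references unknown trial %s",
                 bad[1L], ekey[bad[1L]]))
  }
  ec <- table(factor(ekey, levels = tkey))
  mism <- which(as.integer(ec) != trials$delivered_pellets)
  if (length(mism)) {
    stop(sprintf(
      "trial %s: %d events but delivered_pellets = %d",
      tkey[mism[1L]], as.integer(ec)[mism[1L]],
      trials$delivered_pellets[mism[1L]]))
  }
  invisible(x)
}

#' Read a dataset from the three CSV tables
#'
#' Expects `fish.csv` (`fish_id, cage_id, fish_index, total_length_cm`),
#' `trials.csv` (`cage_id, replicate_index, date, temperature_C, boat_count,
#' diet_level, planned_pellets, delivered_pellets`) and `events.csv`
#' (`cage_id, replicate_index, pellet_index, outcome`), comma-separated
#' UTF-8 with a single header row.  The events `outcome` column holds the
#' consuming fish index 1..8 or the literal `"NC"` for a wasted pellet.
#' Structural surface is computed from length on read.
#'
#' @param fish_table,trial_table,event_table File paths.
#' @param delta Shape coefficient for structural surface.
#' @param quiet Suppress the row-count message.
#' @return A validated `intake_data` object.
#' @examples
#' ex <- system.file("extdata", "synthetic-example", package = "mealshare")
#' d <- read_intake_data(file.path(ex, "fish.csv"),
#'                       file.path(ex, "trials.csv"),
#'                       file.path(ex, "events.csv"))
#' d
#' @export
read_intake_data <- function(fish_table, trial_table, event_table,
                             delta = 0.148, quiet = FALSE) {
  for (p in c(fish_table, trial_table, event_table)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
  }
  fish <- utils::read.csv(fish_table, stringsAsFactors = FALSE)
  trials <- utils::read.csv(trial_table, stringsAsFactors = FALSE)
  events <- utils::read.csv(event_table, stringsAsFactors = FALSE)
  if (!"outcome" %in% names(events)) {
    stop("events table: missing column(s) outcome")
  }
  oc <- as.character(events$outcome)
  out <- ifelse(toupper(oc) == "NC", NOT_CONSUMED, suppressWarnings(as.integer(oc)))
  if (anyNA(out)) {
    stop(sprintf("event row %d: outcome out of range (must be 1..8 or NC)",
                 which(is.na(out))[1L]))
  }
  events$outcome <- as.integer(out)
  if ("date" %in% names(trials)) trials$date <- as.Date(trials$date)
  x <- intake_data(fish, trials, events, delta = delta)
  if (!quiet) {
    message(sprintf("read %d fish, %d trials, %d pellet events",
                    nrow(x$fish), nrow(x$trials), nrow(x$events)))
  }
  x
}

#' Write a dataset to the three CSV tables
#'
#' Inverse of [read_intake_data()]: writes `fish.csv`, `trials.csv` and
#' `events.csv` into `dir` (created if needed), encoding wasted pellets as
#' `"NC"`.  Standardized columns are not written; standardization is
#' recomputed from the raw covariates on read.
#'
#' @param x An `intake_data` object.
#' @param dir Output directory.
#' @return The directory path, invisibly.
#' @export
write_intake_data <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fish <- x$fish[, c("fish_id", "cage_id", "fish_index", "total_length_cm")]
  tcols <- intersect(
    c("cage_id", "replicate_index", "date", "temperature_C", "boat_count",
      "diet_level", "planned_pellets", "delivered_pellets"),
    names(x$trials))
  trials <- x$trials[, tcols]
  events <- x$events[, c("cage_id", "replicate_index", "pellet_index",
                         "outcome")]
  events$outcome <- ifelse(events$outcome == NOT_CONSUMED, "NC",
                           as.character(events$outcome))
  utils::write.csv(fish, file.path(dir, "fish.csv"), row.names = FALSE)
  utils::write.csv(trials, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(events, file.path(dir, "events.csv"), row.names = FALSE)
  invisible(dir)
}

#' Standardize the continuous covariates of a dataset
#'
#' Centres and scales the four continuous covariates to sample mean 0 and
#' sample sd 1 (denominator n - 1): structural surface \eqn{L^2} over fish,
#' and temperature, boat count and delivered ration over trials.  The means
#' and sds are stored in the `standardization` table so the transform is
#' invertible and can be applied to new values (e.g. marginal-effect
#' grids).  The squared-temperature term of the model is the square of the
#' standardized temperature, so no separate entry is kept for it.
#'
#' @param x An `intake_data` object.
#' @return `x` with `L2_std`, `T_std`, `S_std`, `R_std` columns and a
#'   populated `standardization` table.
#' @export
standardize_covariates <- function(x) {
  spec <- list(
    L2 = list(tab = "fish", col = "structural_surface_cm2", std = "L2_std"),
    T  = list(tab = "trials", col = "temperature_C", std = "T_std"),
    S  = list(tab = "trials", col = "boat_count", std = "S_std"),
    R  = list(tab = "trials", col = "delivered_pellets", std = "R_std")
  )
  st <- data.frame(covariate = names(spec), mean = NA_real_, sd = NA_real_)
  for (k in seq_along(spec)) {
    s <- spec[[k]]
    v <- x[[s$tab]][[s$col]]
    if (length(unique(v)) < 2L) {
      stop(sprintf("covariate %s is constant; cannot standardize",
                   names(spec)[k]))
    }
    m <- mean(v); sd_ <- stats::sd(v)
    st$mean[k] <- m; st$sd[k] <- sd_
    x[[s$tab]][[s$std]] <- (v - m) / sd_
  }
  x$standardization <- st
  x
}

#' Map values between natural and standardized covariate scales
#'
#' @param x A standardized `intake_data` object.
#' @param covariate One of `"L2"`, `"T"`, `"S"`, `"R"`.
#' @param values Numeric values to transform.
#' @param to `"standardized"` (natural -> z) or `"natural"` (z -> natural).
#' @return Transformed numeric vector.
#' @export
covariate_scale <- function(x, covariate, values,
                            to = c("standardized", "natural")) {
  to <- match.arg(to)
  st <- x$standardization
  if (is.null(st)) stop("dataset is not standardized")
  i <- match(covariate, st$covariate)
  if (is.na(i)) stop(sprintf("unknown covariate: %s", covariate))
  if (to == "standardized") (values - st$mean[i]) / st$sd[i]
  else values * st$sd[i] + st$mean[i]
}

#' @export
print.intake_data <- function(x, ...) {
  cat(sprintf(
    "Feeding-trial dataset: %d fish in %d cages, %d trials, %d pellet events\n",
    nrow(x$fish), length(unique(x$fish$cage_id)), nrow(x$trials),
    nrow(x$events)))
  waste <- if (nrow(x$events)) mean(x$events$outcome == NOT_CONSUMED) else NA
  cat(sprintf("  diet levels: %s | waste fraction: %s\n",
              paste(sort(unique(x$trials$diet_level)), collapse = "/"),
              if (is.na(waste)) "NA" else sprintf("%.1f%%", 100 * waste)))
  cat(sprintf("  covariates %sstandardized\n",
              if (is.null(x$standardization)) "not " else ""))
  invisible(x)
}
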