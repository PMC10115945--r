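#' Clock-time helpers
#'
#' Convert `"HH:MM"` clock strings to minutes from midnight and back. All
#' scheduling in the package uses minutes from 00:00 of the scored day.
#'
#' @param x character vector of `"HH:MM"` times, or numeric minutes.
#' @return `hm_to_min()` a numeric vector of minutes; `min_to_hm()` a
#'   character vector.
#' @export
#' @examples
#' hm_to_min("06:30")
#' min_to_hm(1200)
hm_to_min <- function(x) {
  if (is.numeric(x)) return(x)
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2) stop("malformed clock time: ", paste(p, collapse = ":"))
    as.numeric(p[1]) * 60 + as.numeric(p[2])
  }, numeric(1))
}

#' @rdname hm_to_min
#' @export
min_to_hm <- function(x) {
  sprintf("%02d:%02d", floor(x / 60) %% 24, round(x) %% 60)
}

#' Construct a daily dosing plan
#'
#' A plan is the unit the optimizer evolves: up to five meals (start time and
#' glucose mass), one prandial insulin bolus paired with each meal and
#' delivered 15 min before it, and a constant basal pump infusion. Meal
#' ingestion is modelled as a square pulse of fixed duration (default
#' 20 min); a bolus is a 1-min square pulse into the subcutaneous depot.
#'
#' Meals lighter than 0.5 g are treated as skipped: neither the meal nor its
#' paired bolus is delivered, which lets the optimizer effectively choose
#' fewer than five meals while the plan genotype keeps five slots.
#'
#' @param meal_times_min numeric vector of meal start times (minutes from
#'   00:00) or `"HH:MM"` strings.
#' @param meal_grams glucose mass of each meal (g), same length.
#' @param bolus_U prandial bolus paired with each meal (U), same length.
#' @param basal_U_per_h constant basal infusion rate (U/h).
#' @param duration_min ingestion duration of each meal (min).
#' @return An object of class `dose_plan`: list with `meals` (data.frame
#'   `time_min`, `grams`, `duration_min`), `boluses` (data.frame `time_min`,
#'   `dose_U`, delivery 15 min before the paired meal), `basal_U_per_h`.
#' @export
#' @examples
#' new_plan(c("07:00", "13:00"), c(90, 105), c(0, 0), 0)
new_plan <- function(meal_times_min = numeric(0), meal_grams = numeric(0),
                     bolus_U = NULL, basal_U_per_h = 0, duration_min = 20) {
  meal_times_min <- hm_to_min(meal_times_min)
  n <- length(meal_times_min)
  if (length(meal_grams) != n) stop("meal_times_min and meal_grams lengths differ")
  if (is.null(bolus_U)) bolus_U <- rep(0, n)
  if (length(bolus_U) != n) stop("one bolus per meal is required")
  if (any(meal_grams < 0) || any(bolus_U < 0) || basal_U_per_h < 0)
    stop("meal sizes, boluses and basal rate must be non-negative")
  if (any(duration_min <= 0)) stop("duration_min must be positive")
  structure(
    list(
      meals = data.frame(time_min = as.numeric(meal_times_min),
                         grams = as.numeric(meal_grams),
                         duration_min = rep_len(as.numeric(duration_min), n)),
      boluses = data.frame(time_min = as.numeric(meal_times_min) - 15,
                           dose_U = as.numeric(bolus_U)),
      basal_U_per_h = as.numeric(basal_U_per_h)
    ),
    class = "dose_plan"
  )
}

#' @rdname new_plan
#' @export
empty_plan <- function() new_plan()

#' @export
print.dose_plan <- function(x, ...) {
  cat("<dose_plan>\n")
  if (nrow(x$meals) == 0) {
    cat("  no meals\n")
  } else {
    for (i in seq_len(nrow(x$meals))) {
      cat(sprintf("  meal %d: %s  %6.1f g   bolus %5.2f U\n", i,
                  min_to_hm(x$meals$time_min[i]), x$meals$grams[i],
                  x$boluses$dose_U[i]))
    }
  }
  cat(sprintf("  basal: %.3f U/h (%.2f U/day)\n", x$basal_U_per_h,
              24 * x$basal_U_per_h))
  invisible(x)
}

# Meals/boluses actually delivered: drops skipped (< 0.5 g) meals and their
# paired boluses.
delivered_events <- function(plan, min_meal_g = 0.5) {
  keep <- plan$meals$grams >= min_meal_g
  list(meals = plan$meals[keep, , drop = FALSE],
       boluses = plan$boluses[keep, , drop = FALSE])
}

#' Meal glucose appearance rate of a plan
#'
#' Rate of glucose ingestion at time `t`: each delivered meal contributes a
#' square pulse of height `grams/duration` over the half-open interval
#' `[time, time + duration)`; overlapping meals superpose additively. The
#' integral over the day equals the total delivered mass exactly.
#'
#' @param plan a [new_plan()] object (or a `meals` data.frame with columns
#'   `time_min`, `grams`, `duration_min`).
#' @param t numeric vector of times (minutes).
#' @return grams/min at each `t`.
#' @export
#' @examples
#' p <- new_plan(480, 60, 0, 0)
#' meal_rate(p, c(479, 480, 499, 500))
meal_rate <- function(plan, t) {
  meals <- if (inherits(plan, "dose_plan")) delivered_events(plan)$meals else plan
  out <- numeric(length(t))
  for (i in seq_len(nrow(meals))) {
    on <- t >= meals$time_min[i] & t < meals$time_min[i] + meals$duration_min[i]
    out[on] <- out[on] + meals$grams[i] / meals$duration_min[i]
  }
  out
}

#' Exogenous insulin delivery rate of a plan
#'
#' Subcutaneous insulin delivery at time `t` in U/min: the basal pump
#' contributes `basal_U_per_h / 60` at every minute; each delivered bolus is
#' a 1-min square pulse of height `dose_U` at its delivery time (15 min
#' before its meal). The daily integral equals
#' `24 * basal_U_per_h + sum(doses)` exactly.
#'
#' @inheritParams meal_rate
#' @param bolus_pulse_min width of the bolus pulse (min).
#' @return U/min at each `t`.
#' @export
#' @examples
#' p <- new_plan(480, 60, 5, 1)
#' insulin_delivery_rate(p, c(400, 465, 466))
insulin_delivery_rate <- function(plan, t, bolus_pulse_min = 1) {
  stopifnot(inherits(plan, "dose_plan"))
  ev <- delivered_events(plan)
  out <- rep(plan$basal_U_per_h / 60, length(t))
  for (i in seq_len(nrow(ev$boluses))) {
    on <- t >= ev$boluses$time_min[i] & t < ev$boluses$time_min[i] + bolus_pulse_min
    out[on] <- out[on] + ev$boluses$dose_U[i] / bolus_pulse_min
  }
  out
}

#' Total insulin of a plan
#'
#' Total daily delivered insulin: basal (24 h at the pump rate) plus the sum
#' of delivered prandial boluses, in U.
#'
#' @param plan a [new_plan()] object.
#' @return numeric scalar, U/day.
#' @export
total_insulin <- function(plan) {
  24 * plan$basal_U_per_h + sum(delivered_events(plan)$boluses$dose_U)
}

#' Read and write plan files
#'
#' Plans round-trip through a small YAML format: a `meals` list with `time`
#' (`"HH:MM"`), `grams` and optional `bolus_U` per entry, and a scalar
#' `basal_U_per_h`.
#'
#' @param path file path.
#' @param plan a [new_plan()] object.
#' @return `read_plan()` a `dose_plan`; `write_plan()` `path`, invisibly.
#' @export
read_plan <- function(path) {
  if (!file.exists(path)) stop("plan file not found: ", path)
  kv <- yaml::read_yaml(path)
  meals <- kv$meals
  if (is.null(meals)) meals <- list()
  times <- vapply(meals, function(m) hm_to_min(m$time), numeric(1))
  grams <- vapply(meals, function(m) as.numeric(m$grams), numeric(1))
  bolus <- vapply(meals, function(m) {
    if (is.null(m$bolus_U)) 0 else as.numeric(m$bolus_U)
  }, numeric(1))
  dur <- vapply(meals, function(m) {
    if (is.null(m$duration_min)) 20 else as.numeric(m$duration_min)
  }, numeric(1))
  basal <- if (is.null(kv$basal_U_per_h)) 0 else as.numeric(kv$basal_U_per_h)
  p <- new_plan(times, grams, bolus, basal)
  p$meals$duration_min <- dur
  p
}

#' @rdname read_plan
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "dose_plan"))
  meals <- lapply(seq_len(nrow(plan$meals)), function(i) {
    list(time = min_to_hm(plan$meals$time_min[i]),
         grams = plan$meals$grams[i],
         bolus_U = plan$boluses$dose_U[i],
         duration_min = plan$meals$duration_min[i])
  })
  yaml::write_yaml(list(meals = meals, basal_U_per_h = plan$basal_U_per_h),
                   path)
  invisible(path)
}
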