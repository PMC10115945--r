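#' Glycemic scoring of a simulated day
#'
#' Computes the quantities that score a dosing plan: the daily glucose
#' extrema (over the grid samples of the scored day), plasma glucose 2 h
#' after the start of each delivered meal, glucose at each meal start
#' (preprandial), total basal and prandial insulin, and the fraction of the
#' day spent in four glucose bands: below 80, 80-130, 130-180 and above
#' 180 mg/dL. Band edges follow a fixed half-open convention so the bands
#' partition the glucose axis: `[0,80)`, `[80,130]`, `(130,180]`,
#' `(180,Inf)`.
#'
#' If a meal starts less than 2 h before midnight the postprandial lookup
#' wraps into the start of the (identical, periodically scored) day.
#'
#' @param trace a `glycemic_trace` from [simulate_day()].
#' @param plan the [new_plan()] the trace was simulated under.
#' @return A list of class `day_metrics`: `g_min`, `g_max` (mg/dL),
#'   `postprandial_2h`, `preprandial` (mg/dL, one per delivered meal),
#'   `basal_total`, `prandial_total` (U), and `tir` (named fractions
#'   `below_80`, `in_80_130`, `in_130_180`, `above_180` summing to 1).
#' @export
#' @examples
#' tr <- simulate_day(patient_preset("T2DMA"), empty_plan())
#' compute_day_metrics(tr, empty_plan())$tir
compute_day_metrics <- function(trace, plan) {
  stopifnot(is.data.frame(trace), inherits(plan, "dose_plan"))
  g <- trace$glucose_mg_dl
  t <- trace$time_min
  ev <- delivered_events(plan)

  glucose_at <- function(tq) {
    tq <- tq %% 1440
    g[which.min(abs(t - tq))]
  }
  post <- vapply(ev$meals$time_min + 120, glucose_at, numeric(1))
  pre <- vapply(ev$meals$time_min, glucose_at, numeric(1))

  # band occupancy over one full day: drop the duplicated midnight sample
  gday <- if (abs(t[length(t)] - t[1] - 1440) < 1e-9) g[-length(g)] else g
  n <- length(gday)
  tir <- c(below_80 = sum(gday < 80) / n,
           in_80_130 = sum(gday >= 80 & gday <= 130) / n,
           in_130_180 = sum(gday > 130 & gday <= 180) / n,
           above_180 = sum(gday > 180) / n)

  structure(
    list(g_min = min(g), g_max = max(g),
         postprandial_2h = post, preprandial = pre,
         basal_total = 24 * plan$basal_U_per_h,
         prandial_total = sum(ev$boluses$dose_U),
         tir = tir),
    class = "day_metrics"
  )
}

#' @export
print.day_metrics <- function(x, ...) {
  cat(sprintf("<day_metrics> G %.1f-%.1f mg/dL | insulin %.2f U basal + %.2f U prandial\n",
              x$g_min, x$g_max, x$basal_total, x$prandial_total))
  cat(sprintf("  time in range: <80: %.1f%% | 80-130: %.1f%% | 130-180: %.1f%% | >180: %.1f%%\n",
              100 * x$tir[1], 100 * x$tir[2], 100 * x$tir[3], 100 * x$tir[4]))
  invisible(x)
}

#' ADA glycemic-target compliance
#'
#' Checks a scored day against the American Diabetes Association criteria:
#' preprandial plasma glucose between 80 and 130 mg/dL at every meal start,
#' and below 180 mg/dL two hours after every meal.
#'
#' @param metrics a [compute_day_metrics()] result.
#' @return list with logicals `preprandial_ok` and `postprandial_ok`
#'   (vacuously `TRUE` when there are no meals).
#' @export
ada_compliance <- function(metrics) {
  stopifnot(inherits(metrics, "day_metrics"))
  list(
    preprandial_ok = all(metrics$preprandial >= 80 &
                           metrics$preprandial <= 130),
    postprandial_ok = all(metrics$postprandial_2h < 180)
  )
}
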