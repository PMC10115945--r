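# Shared fixtures: plans and patients used across test files.

five_meal_plan <- function(bolus = rep(0, 5), basal = 0) {
  new_plan(c("06:00", "10:00", "13:00", "17:00", "20:00"),
           c(35, 15, 70, 20, 55), bolus, basal)
}

spread_plan <- function() {
  new_plan(c(360, 600, 780, 1020, 1200), rep(39, 5), rep(0, 5), 0)
}

# constant synthetic trace over a full day at 1-min resolution
constant_trace <- function(glucose, insulin = 60) {
  out <- data.frame(time_min = 0:1440,
                    glucose_mg_dl = rep(glucose, 1441),
                    insulin_pmol_l = rep(insulin, 1441))
  class(out) <- c("glycemic_trace", "data.frame")
  out
}
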