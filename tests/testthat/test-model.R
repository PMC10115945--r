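test_that("presets reproduce the published severity parameters", {
  a <- patient_preset("T2DMA")
  expect_equal(c(a$Ib, a$Gb, a$Vmax, a$K, a$beta, a$kp3, a$body_mass),
               c(57.9, 120.8, 0.042, 397, 27.3, 0.007, 74))
  c_ <- patient_preset("T2DMC")
  expect_equal(c(c_$Ib, c_$Gb, c_$Vmax, c_$K, c_$beta, c_$kp3),
               c(60.3, 161.8, 0.032, 150.2, 12.1, 0.005))
})

test_that("shipped preset files equal the built-in presets", {
  dir <- system.file("extdata", "patients", package = "glycopt")
  for (nm in c("T2DMA", "T2DMB", "T2DMC")) {
    f <- read_patient(file.path(dir, paste0(nm, ".yaml")))
    b <- patient_preset(nm)
    expect_equal(f$derived, b$derived, info = nm)
  }
})

test_that("basal state is an equilibrium with glucose Gb and insulin Ib", {
  for (nm in c("T2DMA", "T2DMB", "T2DMC")) {
    p <- patient_preset(nm)
    s <- basal_steady_state(p)
    expect_true(all(s >= 0))
    expect_equal(unname(s["Gp"]) / p$constants[["VG"]], p$Gb,
                 tolerance = 1e-10, info = nm)
    expect_equal(unname(s["Ip"]) / p$constants[["VI"]], p$Ib,
                 tolerance = 1e-10, info = nm)
    d <- model_derivatives(0, s, p)
    expect_lt(max(abs(d)), 1e-6 * max(abs(s)))
  }
})

test_that("inconsistent parameter sets are rejected, not returned", {
  # EGPb below insulin-independent utilization leaves no basal flux balance
  expect_error(
    patient_params(Ib = 57.9, Gb = 120.8, Vmax = 0.042, K = 397,
                   beta = 27.3, kp3 = 0.007,
                   constants = c(EGPb = 0.5)),
    "inconsistent")
})

test_that("derivatives respond to exogenous inputs with the right sign", {
  p <- patient_preset("T2DMA")
  s <- basal_steady_state(p)
  d_meal <- model_derivatives(0, s, p,
                              inputs = list(meal_mg_min = 3000,
                                            meal_total_mg = 60000,
                                            sc_insulin_pmol_kg_min = 0))
  expect_gt(d_meal[["Qsto1"]], 0)
  d_ins <- model_derivatives(0, s, p,
                             inputs = list(meal_mg_min = 0, meal_total_mg = 0,
                                           sc_insulin_pmol_kg_min = 5))
  expect_gt(d_ins[["Isc1"]], 0)
})

test_that("zero-input simulation preserves the basal state all day", {
  for (nm in c("T2DMA", "T2DMB", "T2DMC")) {
    p <- patient_preset(nm)
    tr <- simulate_day(p, empty_plan())
    expect_equal(tr$time_min, 0:1440)
    expect_lt(max(abs(tr$glucose_mg_dl - p$Gb)) / p$Gb, 0.005)
    expect_lt(max(abs(tr$insulin_pmol_l - p$Ib)) / p$Ib, 0.005)
  }
})

test_that("glucose rises after a meal and returns toward baseline", {
  p <- patient_preset("T2DMA")
  tr <- simulate_day(p, new_plan(480, 115, 0, 0))
  g <- tr$glucose_mg_dl
  expect_gt(max(g[tr$time_min > 480 & tr$time_min < 720]), p$Gb + 30)
  # back near (or below, post-meal undershoot) baseline by end of day
  expect_lt(abs(g[length(g)] - p$Gb), 25)
})

test_that("postprandial peak orders with disease severity", {
  peaks <- vapply(c("T2DMA", "T2DMB", "T2DMC"), function(nm) {
    max(simulate_day(patient_preset(nm),
                     new_plan(480, 115, 0, 0))$glucose_mg_dl)
  }, numeric(1))
  expect_true(all(peaks > 180))
  expect_true(peaks[["T2DMA"]] < peaks[["T2DMB"]])
  expect_true(peaks[["T2DMB"]] < peaks[["T2DMC"]])
})

test_that("absorbed glucose never exceeds the ingested amount", {
  p <- patient_preset("T2DMB")
  plan <- new_plan(480, 80, 0, 0)
  pp <- glycopt:::pack_params(p)
  s0 <- as.numeric(basal_steady_state(p))
  res <- glycopt:::.simulate_cpp(pp, s0,
                                 cbind(480, 80000, 20),
                                 matrix(numeric(0), ncol = 2), 0, 1440, 1)
  # rate of appearance in plasma = f*kabs*Qgut/BW; reconstruct its integral
  # from the gut balance: everything absorbed passed through Qgut
  absorbed_mg <- 80000 - sum(res$state_end[1:3])
  expect_lt(absorbed_mg * pp[["f"]], 80000)
  expect_gt(absorbed_mg, 0)
})

test_that("halving the integration step barely moves the daily extrema", {
  p <- patient_preset("T2DMB")
  plan <- five_meal_plan(bolus = rep(2, 5), basal = 0.5)
  tr1 <- simulate_day(p, plan, sim_config(dt = 1))
  tr2 <- simulate_day(p, plan, sim_config(dt = 0.5))
  expect_lt(abs(min(tr1$glucose_mg_dl) - min(tr2$glucose_mg_dl)), 0.1)
  expect_lt(abs(max(tr1$glucose_mg_dl) - max(tr2$glucose_mg_dl)), 0.1)
})

test_that("compiled integrator matches an adaptive reference solver", {
  skip_if_not_installed("deSolve")
  p <- patient_preset("T2DMA")
  plan <- new_plan(c(420, 780), c(60, 75), c(2, 3), 0.5)

  rhs <- function(t, y, parms) {
    names(y) <- model_state_names()
    inputs <- list(
      meal_mg_min = 1000 * meal_rate(plan, t),
      meal_total_mg = 1000 * if (t >= 780) 75 else if (t >= 420) 60 else 0,
      sc_insulin_pmol_kg_min =
        insulin_delivery_rate(plan, t) * 6000 / p$body_mass
    )
    list(model_derivatives(t, y, p, inputs))
  }
  s0 <- as.numeric(basal_steady_state(p))
  names(s0) <- model_state_names()
  # hmax keeps the adaptive solver from stepping over the 1-min bolus pulses
  ref <- deSolve::lsoda(s0, seq(0, 1440, by = 1), rhs, parms = NULL,
                        rtol = 1e-8, atol = 1e-8, maxsteps = 50000,
                        hmax = 0.5)
  g_ref <- ref[, "Gp"] / p$constants[["VG"]]

  ev <- glycopt:::delivered_events(plan)
  res <- glycopt:::.simulate_cpp(
    glycopt:::pack_params(p), s0,
    cbind(ev$meals$time_min, ev$meals$grams * 1000, ev$meals$duration_min),
    cbind(ev$boluses$time_min, ev$boluses$dose_U),
    plan$basal_U_per_h, 1440, 1)

  expect_lt(max(abs(res$glucose - g_ref)), 0.5) # mg/dL over the whole day
})

test_that("divergent integrations raise an error naming the plan", {
  p <- patient_preset("T2DMA")
  # a physically impossible bolus drives glucose to the clamp boundary
  expect_error(simulate_day(p, new_plan(480, 115, 1e5, 0)),
               "instab|diverged")
})
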