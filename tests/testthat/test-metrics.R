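test_that("constant traces land in a single glucose band", {
  m <- compute_day_metrics(constant_trace(100), empty_plan())
  expect_equal(m$g_min, 100)
  expect_equal(m$g_max, 100)
  expect_equal(unname(m$tir), c(0, 1, 0, 0))

  m200 <- compute_day_metrics(constant_trace(200), empty_plan())
  expect_equal(unname(m200$tir), c(0, 0, 0, 1))
})

test_that("band occupancy reflects duration fractions", {
  # 6 h at 75 mg/dL, 18 h at 120 mg/dL
  tr <- constant_trace(75)
  tr$glucose_mg_dl[tr$time_min >= 360] <- 120
  m <- compute_day_metrics(tr, empty_plan())
  expect_equal(unname(m$tir), c(0.25, 0.75, 0, 0))
  expect_equal(sum(m$tir), 1, tolerance = 1e-9)
})

test_that("band edges follow the fixed half-open convention", {
  tr <- constant_trace(75)
  g <- c(79.999, 80, 130, 130.001, 180, 180.001)
  tr$glucose_mg_dl <- rep(g, length.out = nrow(tr))
  m <- compute_day_metrics(tr, empty_plan())
  expect_equal(sum(m$tir), 1, tolerance = 1e-9)
  expect_equal(unname(m$tir), c(1, 2, 2, 1) / 6, tolerance = 1e-3)
})

test_that("band occupancy is grid-refinement consistent", {
  p <- patient_preset("T2DMB")
  plan <- five_meal_plan(bolus = rep(1, 5), basal = 0.5)
  m1 <- compute_day_metrics(simulate_day(p, plan, sim_config(dt = 1)), plan)
  m2 <- compute_day_metrics(simulate_day(p, plan, sim_config(dt = 0.5)), plan)
  # agreement within one grid cell per band
  expect_true(all(abs(m1$tir - m2$tir) <= 2 / 1440))
})

test_that("postprandial values are read 2 h after each delivered meal", {
  tr <- constant_trace(100)
  tr$glucose_mg_dl[tr$time_min == 600] <- 155  # 2 h after the 08:00 meal
  plan <- new_plan(c(480, 1380), c(60, 60), c(0, 0), 0)
  m <- compute_day_metrics(tr, plan)
  expect_equal(length(m$postprandial_2h), 2)
  expect_equal(m$postprandial_2h[1], 155)
  # meal at 23:00 wraps into the start of the periodic day (01:00)
  tr$glucose_mg_dl[tr$time_min == 60] <- 140
  m <- compute_day_metrics(tr, plan)
  expect_equal(m$postprandial_2h[2], 140)
})

test_that("insulin totals come from the plan exactly", {
  plan <- five_meal_plan(bolus = c(1, 2, 3, 0, 0.5), basal = 0.8)
  m <- compute_day_metrics(constant_trace(110), plan)
  expect_equal(m$basal_total, 24 * 0.8)
  expect_equal(m$prandial_total, 6.5)
})

test_that("ADA compliance flags both criteria", {
  plan <- new_plan(c(480, 780), c(60, 60), c(0, 0), 0)
  tr <- constant_trace(100)
  m <- compute_day_metrics(tr, plan)
  ok <- ada_compliance(m)
  expect_true(ok$preprandial_ok)
  expect_true(ok$postprandial_ok)

  tr$glucose_mg_dl[tr$time_min == 600] <- 185  # one 2-h value over the limit
  m <- compute_day_metrics(tr, plan)
  expect_false(ada_compliance(m)$postprandial_ok)

  tr2 <- constant_trace(100)
  tr2$glucose_mg_dl[tr2$time_min == 780] <- 135  # preprandial above 130
  m2 <- compute_day_metrics(tr2, plan)
  expect_false(ada_compliance(m2)$preprandial_ok)
  expect_true(ada_compliance(m2)$postprandial_ok)
})
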