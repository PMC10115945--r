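make_metrics <- function(g_min, g_max, basal_total, prandial_total) {
  structure(list(g_min = g_min, g_max = g_max,
                 postprandial_2h = numeric(0), preprandial = numeric(0),
                 basal_total = basal_total, prandial_total = prandial_total,
                 tir = c(below_80 = 0, in_80_130 = 1, in_130_180 = 0,
                         above_180 = 0)),
            class = "day_metrics")
}

test_that("hypoglycemia penalty is zero in band, absolute deviation outside", {
  expect_equal(fitness_fL(90), 0)
  expect_equal(fitness_fL(80), 0)   # band edges inclusive
  expect_equal(fitness_fL(100), 0)
  expect_equal(fitness_fL(75), 15)
  expect_equal(fitness_fL(110), 20) # above the band also penalized
  expect_equal(fitness_fL(60), 30)  # |60 - 90|, not negative
})

test_that("hyperglycemia penalty is the excess over the target", {
  expect_equal(fitness_fH(160), 0)
  expect_equal(fitness_fH(170), 0)  # boundary: zero excess
  expect_equal(fitness_fH(185), 15)
})

test_that("fitness combines the four weighted terms", {
  w <- fitness_weights()
  expect_equal(plan_fitness(make_metrics(90, 160, 0, 0), w), 0)
  # 0.35*0 + 0.35*5 + 0.15*10 + 0.15*5
  expect_equal(plan_fitness(make_metrics(85, 175, 10, 5), w), 4.0)
  # 0.35*20 + 0.35*30
  expect_equal(plan_fitness(make_metrics(70, 200, 0, 0), w), 17.5)
})

test_that("selection probabilities follow reciprocal fitness", {
  expect_equal(selection_probabilities(c(1, 2, 4)), c(4, 2, 1) / 7)
  expect_equal(selection_probabilities(c(2, 2)), c(0.5, 0.5))
  expect_equal(selection_probabilities(5), 1)
  # zero-fitness plans take the whole selection mass, split uniformly
  expect_equal(selection_probabilities(c(0, 1, 0)), c(0.5, 0, 0.5))
  expect_error(selection_probabilities(numeric(0)), "empty")
  # normalization holds for arbitrary positive lists
  set.seed(1)
  for (i in 1:20) {
    f <- stats::rexp(sample(1:30, 1))
    expect_equal(sum(selection_probabilities(f)), 1, tolerance = 1e-12)
  }
})

test_that("size mutation transfers mass between meals, conserving the total", {
  cfg <- ea_config(population_size = 10, generations = 1, rng_seed = 1)
  plan <- new_plan(c(360, 600, 780, 1020, 1200), c(50, 30, 45, 40, 30),
                   rep(0, 5), 0)
  # additive transfer: Qi' = Qi*(1+eps), Qk' = Qk - eps*Qi
  set.seed(42)
  for (i in 1:500) {
    plan <- mutate_plan(plan, cfg)
    expect_equal(sum(plan$meals$grams), 195, tolerance = 195 * 1e-9)
    expect_true(all(plan$meals$grams >= 0))
    expect_true(all(plan$boluses$dose_U >= 0))
    expect_true(all(plan$meals$time_min >= cfg$window_start &
                      plan$meals$time_min <= cfg$window_end))
    expect_equal(plan$boluses$time_min, plan$meals$time_min - 15)
  }
})

test_that("restricted scenarios mask locked elements from mutation", {
  plan <- five_meal_plan(bolus = rep(2, 5), basal = 1)
  t0 <- plan$meals$time_min
  g0 <- plan$meals$grams

  cfg_t <- ea_config(population_size = 10, generations = 1, rng_seed = 1,
                     scenario = "time_restricted")
  set.seed(7)
  p <- plan
  for (i in 1:200) {
    p <- mutate_plan(p, cfg_t)
    expect_identical(p$meals$time_min, t0)
  }
  expect_false(identical(p$meals$grams, g0)) # sizes do evolve here

  cfg_tq <- ea_config(population_size = 10, generations = 1, rng_seed = 1,
                      scenario = "time_and_quantity_restricted")
  q <- new_plan(cfg_tq$fixed_times, cfg_tq$fixed_grams, rep(2, 5), 1)
  set.seed(8)
  for (i in 1:200) {
    q <- mutate_plan(q, cfg_tq)
    expect_identical(q$meals$time_min, cfg_tq$fixed_times)
    expect_identical(q$meals$grams, cfg_tq$fixed_grams)
  }
  expect_false(identical(q$boluses$dose_U, rep(2, 5)))
})

test_that("ranking keeps the lowest fitness, ties broken by total insulin", {
  cfg <- ea_config(population_size = 4, generations = 1,
                   survivor_fraction = 0.25)
  expect_equal(rank_and_select(c(3, 1, 2, 5), c(0, 0, 0, 0), cfg), 2L)
  # equal fitness: lower total insulin wins
  expect_equal(rank_and_select(c(1, 1, 2, 3), c(20, 10, 0, 0), cfg), 2L)
  # full tie: stable order keeps the first
  expect_equal(rank_and_select(c(1, 1, 1, 1), c(5, 5, 5, 5), cfg), 1L)

  # oracle check on 5 hand-scored plans: exhaustive sort by (f, insulin)
  f <- c(2.5, 0.7, 2.5, 0.7, 1.0)
  ins <- c(4, 9, 3, 2, 1)
  cfg5 <- ea_config(population_size = 5, generations = 1,
                    survivor_fraction = 0.9)
  expect_equal(rank_and_select(f, ins, cfg5), c(4L, 2L, 5L, 3L))
})

test_that("a short evolution run is elitist, constrained and deterministic", {
  p <- patient_preset("T2DMA")
  cfg <- ea_config(population_size = 24, generations = 6, rng_seed = 99)
  # failed integrations inside the population warn and get worst fitness;
  # that is expected behavior, not a test failure
  r1 <- suppressWarnings(evolve_plans(p, cfg))
  r2 <- suppressWarnings(evolve_plans(p, cfg))

  expect_true(all(diff(r1$history$best_fitness) <= 1e-12))
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best_plan, r2$best_plan)
  expect_equal(sum(r1$best_plan$meals$grams), 195, tolerance = 195 * 1e-9)
  expect_true(all(r1$best_plan$meals$time_min >= cfg$window_start &
                    r1$best_plan$meals$time_min <= cfg$window_end))

  # a different seed explores differently
  r3 <- suppressWarnings(
    evolve_plans(p, ea_config(population_size = 24, generations = 6,
                              rng_seed = 100)))
  expect_false(identical(r1$history$best_fitness, r3$history$best_fitness))
})

test_that("random plans respect their scenario from initialization on", {
  cfg <- ea_config(population_size = 10, generations = 1, rng_seed = 1,
                   scenario = "time_and_quantity_restricted")
  set.seed(5)
  for (i in 1:20) {
    pl <- random_plan(cfg)
    expect_identical(pl$meals$time_min, cfg$fixed_times)
    expect_identical(pl$meals$grams, cfg$fixed_grams)
  }
  cfg_free <- ea_config(population_size = 10, generations = 1, rng_seed = 1)
  set.seed(6)
  for (i in 1:20) {
    pl <- random_plan(cfg_free)
    expect_equal(sum(pl$meals$grams), 195, tolerance = 195 * 1e-9)
    expect_true(all(pl$meals$time_min >= cfg_free$window_start &
                      pl$meals$time_min <= cfg_free$window_end))
  }
})
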