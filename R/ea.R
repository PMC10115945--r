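#' Fitness weights and glycemic targets
#'
#' Weights of the scalar objective minimized by the evolutionary algorithm:
#' `mu1` scales the hypoglycemia penalty, `mu2` the hyperglycemia penalty,
#' `mu3` the daily basal insulin dose, and the remainder `1 - mu1 - mu2 -
#' mu3` the total prandial dose. `G0t` is the target daily glucose minimum,
#' `G1t` the target 2-h postprandial concentration, and `hypo_band` the
#' minimum-glucose band inside which no hypoglycemia penalty accrues.
#'
#' @param mu1,mu2,mu3 non-negative weights with `mu1 + mu2 + mu3 <= 1`.
#' @param G0t,G1t glycemic targets (mg/dL).
#' @param hypo_band length-2 numeric, the penalty-free band for the daily
#'   minimum (mg/dL, inclusive at both edges).
#' @return list of class `fitness_weights`.
#' @export
fitness_weights <- function(mu1 = 0.35, mu2 = 0.35, mu3 = 0.15,
                            G0t = 90, G1t = 170, hypo_band = c(80, 100)) {
  stopifnot(mu1 >= 0, mu2 >= 0, mu3 >= 0, mu1 + mu2 + mu3 <= 1,
            length(hypo_band) == 2, hypo_band[1] <= hypo_band[2])
  structure(list(mu1 = mu1, mu2 = mu2, mu3 = mu3, G0t = G0t, G1t = G1t,
                 hypo_band = hypo_band),
            class = "fitness_weights")
}

#' Hypoglycemia penalty term
#'
#' Zero when the daily glucose minimum lies inside the penalty-free band
#' (80-100 mg/dL by default, both edges inclusive); otherwise the absolute
#' deviation of the minimum from the target `G0t`. The absolute value makes
#' dips below target penalizing rather than rewarding.
#'
#' @param g_min daily minimum plasma glucose (mg/dL).
#' @param weights a [fitness_weights()] object.
#' @return non-negative penalty (mg/dL).
#' @export
#' @examples
#' fitness_fL(75)  # 15
fitness_fL <- function(g_min, weights = fitness_weights()) {
  ifelse(g_min >= weights$hypo_band[1] & g_min <= weights$hypo_band[2],
         0, abs(g_min - weights$G0t))
}

#' Hyperglycemia penalty term
#'
#' Zero when the daily glucose maximum is below the postprandial target
#' `G1t`; otherwise the excess `g_max - G1t`.
#'
#' @param g_max daily maximum plasma glucose (mg/dL).
#' @inheritParams fitness_fL
#' @return non-negative penalty (mg/dL).
#' @export
#' @examples
#' fitness_fH(185) # 15
fitness_fH <- function(g_max, weights = fitness_weights()) {
  pmax(0, g_max - weights$G1t)
}

#' Fitness of a scored day
#'
#' The scalar the evolutionary algorithm minimizes:
#' `mu1 * fL + mu2 * fH + mu3 * IB + (1 - mu1 - mu2 - mu3) * sum(D)`,
#' where `fL` and `fH` are the hypo- and hyperglycemia penalties, `IB` the
#' total daily basal dose (U) and `sum(D)` the total delivered prandial dose
#' (U). It is zero exactly when glycemia meets both targets with no insulin.
#'
#' @param metrics a [compute_day_metrics()] result for the plan's own trace.
#' @inheritParams fitness_fL
#' @return non-negative scalar.
#' @export
plan_fitness <- function(metrics, weights = fitness_weights()) {
  stopifnot(inherits(metrics, "day_metrics"))
  weights$mu1 * fitness_fL(metrics$g_min, weights) +
    weights$mu2 * fitness_fH(metrics$g_max, weights) +
    weights$mu3 * metrics$basal_total +
    (1 - weights$mu1 - weights$mu2 - weights$mu3) * metrics$prandial_total
}

#' Fitness-proportional selection probabilities
#'
#' Reproduction probabilities over the survivor set: proportional to the
#' reciprocal fitness, `(1/f_j) / sum(1/f_k)`. Plans with fitness exactly
#' zero are already optimal; when any are present the whole selection mass
#' is split uniformly among them.
#'
#' @param fitnesses non-negative numeric vector.
#' @return probability vector of the same length, summing to 1.
#' @export
#' @examples
#' selection_probabilities(c(1, 2, 4)) # 4/7, 2/7, 1/7
selection_probabilities <- function(fitnesses) {
  if (length(fitnesses) == 0) stop("empty fitness list")
  if (any(fitnesses < 0)) stop("fitnesses must be non-negative")
  zero <- fitnesses == 0
  if (any(zero)) {
    p <- as.numeric(zero) / sum(zero)
  } else {
    inv <- 1 / fitnesses
    p <- inv / sum(inv)
  }
  p
}

#' Evolutionary-algorithm configuration
#'
#' Defaults reproduce the published full-scale setting (population 10,000
#' over 600 generations); scaled-down runs for quick exploration typically
#' use a few hundred plans over 50-100 generations. Meals are confined to a
#' 14-h eating window (06:00-20:00 by default). Three scenarios are
#' supported: `free` (times, sizes and doses all evolve),
#' `time_restricted` (meal times fixed at 06:00, 10:00, 13:00, 17:00,
#' 20:00) and `time_and_quantity_restricted` (times fixed at 06:00, 09:00,
#' 12:00, 16:00, 19:00 and sizes at 35, 15, 70, 20, 55 g, only the insulin
#' doses evolve).
#'
#' Initial plans are drawn uniformly within the constraints; each bolus is
#' absent (0 U) with probability `p_zero_insulin`, otherwise uniform on
#' `(0, init_bolus_max)`, and likewise the basal rate on
#' `(0, init_basal_max)`. The zero point-mass matters structurally: the
#' multiplicative mutation of Table-2 type preserves zeros, so insulin-free
#' schedules are reachable only if present from the start.
#'
#' @param population_size number of plans per generation (N).
#' @param generations number of generations.
#' @param survivor_fraction elite fraction retained each generation.
#' @param rho maximum relative mutation amplitude.
#' @param total_intake_g total daily glucose intake, conserved by mutation.
#' @param n_meals meal slots per plan.
#' @param window_start,window_end eating window, `"HH:MM"` or minutes.
#' @param scenario one of `"free"`, `"time_restricted"`,
#'   `"time_and_quantity_restricted"`.
#' @param fixed_times,fixed_grams the scenario's fixed schedule; defaults as
#'   above.
#' @param rng_seed integer seed; all randomness of a run flows from it.
#' @param init_bolus_max,init_basal_max,p_zero_insulin initialization
#'   ranges (U, U/h, probability).
#' @return list of class `ea_config`.
#' @export
ea_config <- function(population_size = 10000, generations = 600,
                      survivor_fraction = 0.25, rho = 0.1,
                      total_intake_g = 195, n_meals = 5,
                      window_start = "06:00", window_end = "20:00",
                      scenario = c("free", "time_restricted",
                                   "time_and_quantity_restricted"),
                      fixed_times = NULL, fixed_grams = NULL,
                      rng_seed = 1L,
                      init_bolus_max = 15, init_basal_max = 2,
                      p_zero_insulin = 0.5) {
  scenario <- match.arg(scenario)
  window_start <- hm_to_min(window_start)
  window_end <- hm_to_min(window_end)
  stopifnot(population_size >= 4, generations >= 1,
            survivor_fraction > 0, survivor_fraction < 1,
            rho > 0, total_intake_g > 0, n_meals >= 1,
            window_end > window_start,
            window_end - window_start <= 14 * 60)
  if (is.null(fixed_times)) {
    fixed_times <- if (scenario == "time_and_quantity_restricted") {
      hm_to_min(c("06:00", "09:00", "12:00", "16:00", "19:00"))
    } else {
      hm_to_min(c("06:00", "10:00", "13:00", "17:00", "20:00"))
    }
  } else {
    fixed_times <- hm_to_min(fixed_times)
  }
  if (is.null(fixed_grams)) fixed_grams <- c(35, 15, 70, 20, 55)
  if (scenario != "free") {
    stopifnot(length(fixed_times) == n_meals)
    if (scenario == "time_and_quantity_restricted") {
      stopifnot(length(fixed_grams) == n_meals,
                abs(sum(fixed_grams) - total_intake_g) < 1e-9)
    }
  }
  structure(
    list(population_size = as.integer(population_size),
         generations = as.integer(generations),
         survivor_fraction = as.numeric(survivor_fraction),
         rho = as.numeric(rho),
         total_intake_g = as.numeric(total_intake_g),
         n_meals = as.integer(n_meals),
         window_start = as.numeric(window_start),
         window_end = as.numeric(window_end),
         scenario = scenario, fixed_times = as.numeric(fixed_times),
         fixed_grams = as.numeric(fixed_grams),
         rng_seed = as.integer(rng_seed),
         init_bolus_max = as.numeric(init_bolus_max),
         init_basal_max = as.numeric(init_basal_max),
         p_zero_insulin = as.numeric(p_zero_insulin)),
    class = "ea_config"
  )
}

# Element classes the mutation operator may touch under each scenario.
mutable_elements <- function(cfg) {
  switch(cfg$scenario,
         free = c("Q", "T", "D", "IB"),
         time_restricted = c("Q", "D", "IB"),
         time_and_quantity_restricted = c("D", "IB"))
}

#' Draw a random plan within the scenario constraints
#'
#' @param cfg an [ea_config()] object.
#' @return a [new_plan()] object.
#' @export
random_plan <- function(cfg) {
  n <- cfg$n_meals
  if (cfg$scenario == "free") {
    times <- sort(stats::runif(n, cfg$window_start, cfg$window_end))
  } else {
    times <- cfg$fixed_times
  }
  if (cfg$scenario == "time_and_quantity_restricted") {
    grams <- cfg$fixed_grams
  } else {
    w <- stats::runif(n)
    grams <- cfg$total_intake_g * w / sum(w)
  }
  doses <- ifelse(stats::runif(n) < cfg$p_zero_insulin, 0,
                  stats::runif(n, 0, cfg$init_bolus_max))
  basal <- if (stats::runif(1) < cfg$p_zero_insulin) 0 else
    stats::runif(1, 0, cfg$init_basal_max)
  new_plan(times, grams, doses, basal)
}

#' Mutate one element of a plan
#'
#' Applies exactly one mutation: an element class is drawn uniformly among
#' those the scenario leaves free (`Q` meal size, `T` meal time, `D` bolus
#' dose, `IB` basal rate), a meal slot is drawn uniformly where applicable,
#' and a relative perturbation `eps ~ U(-rho, rho)` is applied
#' multiplicatively. A size mutation moves the mass change `eps * Q_i` from
#' a second, randomly chosen meal `k` onto meal `i` (truncated so neither
#' goes negative), which conserves the total daily intake exactly. Mutated
#' times are clamped to the eating window; the paired bolus moves with its
#' meal.
#'
#' @param plan a [new_plan()] object.
#' @param cfg an [ea_config()] object.
#' @return the mutated plan.
#' @export
mutate_plan <- function(plan, cfg) {
  elements <- mutable_elements(cfg)
  el <- elements[sample.int(length(elements), 1)]
  eps <- stats::runif(1, -cfg$rho, cfg$rho)
  n <- nrow(plan$meals)
  if (el == "Q") {
    i <- sample.int(n, 1)
    k <- sample.int(n - 1, 1)
    k <- if (k >= i) k + 1L else k
    dq <- eps * plan$meals$grams[i]
    dq <- min(dq, plan$meals$grams[k]) # donor cannot go negative
    plan$meals$grams[i] <- plan$meals$grams[i] + dq
    plan$meals$grams[k] <- plan$meals$grams[k] - dq
  } else if (el == "T") {
    i <- sample.int(n, 1)
    ti <- plan$meals$time_min[i] * (1 + eps)
    ti <- min(max(ti, cfg$window_start), cfg$window_end)
    plan$meals$time_min[i] <- ti
    plan$boluses$time_min[i] <- ti - 15
  } else if (el == "D") {
    i <- sample.int(n, 1)
    plan$boluses$dose_U[i] <- plan$boluses$dose_U[i] * (1 + eps)
  } else {
    plan$basal_U_per_h <- plan$basal_U_per_h * (1 + eps)
  }
  plan
}

#' Rank a population and keep the elite
#'
#' Sorts plans by ascending fitness, breaking ties by ascending total
#' insulin (basal + prandial), with a stable sort so equal plans keep their
#' population order; returns the indices of the elite
#' `floor(survivor_fraction * N)` plans in rank order.
#'
#' @param fitnesses numeric vector.
#' @param total_insulin_U numeric vector, same length, used for ties.
#' @param cfg an [ea_config()] object (its `survivor_fraction` and the
#'   vector length give the elite size).
#' @return integer vector of surviving indices, best first.
#' @export
rank_and_select <- function(fitnesses, total_insulin_U, cfg) {
  stopifnot(length(fitnesses) == length(total_insulin_U))
  n_keep <- max(1L, floor(cfg$survivor_fraction * length(fitnesses)))
  ord <- order(fitnesses, total_insulin_U) # stable (radix) sort
  ord[seq_len(n_keep)]
}

#' Optimize a dosing plan with the evolutionary algorithm
#'
#' Runs the elitist evolutionary search: a population of random plans is
#' simulated on the virtual patient and scored with [plan_fitness()]; each
#' generation the best quarter survives unchanged and the rest of the
#' population is refilled with mutated copies of survivors drawn with
#' probability proportional to reciprocal fitness
#' ([selection_probabilities()]). There is no crossover: recombining two
#' plans would break the conservation of total daily intake. Elite plans
#' keep their cached scores, so only new mutants are re-simulated.
#'
#' @param patient a [patient_params()] object.
#' @param cfg an [ea_config()] object; `cfg$rng_seed` seeds all randomness.
#' @param weights a [fitness_weights()] object.
#' @param sim a [sim_config()] object.
#' @param verbose print a progress line every 10 generations.
#' @param checkpoint_dir if non-`NULL`, the population and RNG state are
#'   saved there every `checkpoint_every` generations so long runs can be
#'   resumed.
#' @param checkpoint_every generations between checkpoints.
#' @return list of class `ea_result`: `best_plan`, `best_metrics`,
#'   `best_fitness`, and `history` (data.frame `generation`,
#'   `best_fitness`, `gmin`, `gmax`, `basal_U_per_h`, `prandial_U_total`).
#' @export
#' @examples
#' \donttest{
#' cfg <- ea_config(population_size = 20, generations = 5, rng_seed = 7)
#' res <- evolve_plans(patient_preset("T2DMA"), cfg)
#' res$history$best_fitness
#' }
evolve_plans <- function(patient, cfg, weights = fitness_weights(),
                         sim = sim_config(), verbose = FALSE,
                         checkpoint_dir = NULL, checkpoint_every = 10) {
  stopifnot(inherits(patient, "patient_params"), inherits(cfg, "ea_config"))
  set.seed(cfg$rng_seed)
  N <- cfg$population_size

  evaluate <- function(plan) {
    m <- tryCatch(compute_day_metrics(simulate_day(patient, plan, sim), plan),
                  error = function(e) e)
    if (inherits(m, "error")) {
      warning("plan evaluation failed, assigning worst fitness: ",
              conditionMessage(m))
      return(list(fitness = Inf, metrics = NULL,
                  insulin = total_insulin(plan)))
    }
    list(fitness = plan_fitness(m, weights), metrics = m,
         insulin = m$basal_total + m$prandial_total)
  }

  population <- lapply(seq_len(N), function(i) random_plan(cfg))
  scores <- lapply(population, evaluate)
  fit <- vapply(scores, `[[`, numeric(1), "fitness")
  ins <- vapply(scores, `[[`, numeric(1), "insulin")

  history <- data.frame(generation = seq_len(cfg$generations),
                        best_fitness = NA_real_, gmin = NA_real_,
                        gmax = NA_real_, basal_U_per_h = NA_real_,
                        prandial_U_total = NA_real_)

  for (gen in seq_len(cfg$generations)) {
    surv <- rank_and_select(fit, ins, cfg)
    eta <- selection_probabilities(fit[surv])
    n_new <- N - length(surv)
    parents <- surv[sample.int(length(surv), n_new, replace = TRUE,
                               prob = eta)]
    offspring <- lapply(parents, function(j) mutate_plan(population[[j]], cfg))
    off_scores <- lapply(offspring, evaluate)

    population <- c(population[surv], offspring)
    scores <- c(scores[surv], off_scores)
    fit <- vapply(scores, `[[`, numeric(1), "fitness")
    ins <- vapply(scores, `[[`, numeric(1), "insulin")

    best <- rank_and_select(fit, ins, cfg)[1]
    bm <- scores[[best]]$metrics
    history$best_fitness[gen] <- fit[best]
    history$gmin[gen] <- if (is.null(bm)) NA_real_ else bm$g_min
    history$gmax[gen] <- if (is.null(bm)) NA_real_ else bm$g_max
    history$basal_U_per_h[gen] <- population[[best]]$basal_U_per_h
    history$prandial_U_total[gen] <- if (is.null(bm)) NA_real_ else bm$prandial_total
    if (verbose && gen %% 10 == 0) {
      message(sprintf("gen %d: best fitness %.4f, insulin %.2f U",
                      gen, fit[best], ins[best]))
    }
    if (!is.null(checkpoint_dir) && gen %% checkpoint_every == 0) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(list(generation = gen, population = population, fit = fit,
                   ins = ins, rng_state = .Random.seed, cfg = cfg),
              file.path(checkpoint_dir, "checkpoint.rds"))
    }
  }

  best <- rank_and_select(fit, ins, cfg)[1]
  structure(
    list(best_plan = population[[best]],
         best_metrics = scores[[best]]$metrics,
         best_fitness = fit[best],
         history = history,
         weights = weights, config = cfg, patient_name = patient$name),
    class = "ea_result"
  )
}

#' @export
print.ea_result <- function(x, ...) {
  cat(sprintf("<ea_result> %s, scenario %s: best fitness %.4f after %d generations\n",
              x$patient_name, x$config$scenario, x$best_fitness,
              nrow(x$history)))
  print(x$best_plan)
  invisible(x)
}
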