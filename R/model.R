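#' Names of the model compartments
#'
#' Order of the 14 compartments of the state vector used throughout the
#' package. `X` and `Y` are deviation variables (insulin action above basal
#' and beta-cell response above basal secretion) and may be negative; all
#' other compartments are non-negative masses.
#'
#' @return Character vector of length 14.
#' @export
model_state_names <- function() {
  c("Qsto1", "Qsto2", "Qgut", "Gp", "Gt", "Ip", "Il", "Ipo",
    "I1", "Id", "X", "Y", "Isc1", "Isc2")
}

# Flat parameter vector consumed by the compiled integrator and the R
# reference derivative function.
pack_params <- function(patient) {
  stopifnot(inherits(patient, "patient_params"))
  cst <- patient$constants
  c(cst[c("VG", "k1", "k2", "VI", "m1", "m2", "m3", "m4",
          "kmax", "kmin", "kabs", "kgri", "b", "d", "f",
          "kp2", "ki", "Fcns", "Km0", "p2U", "alpha", "gamma",
          "ke1", "ke2", "kd", "ka1", "ka2", "pmol_per_U")],
    kp1 = unname(patient$derived["kp1"]),
    Vm0 = unname(patient$derived["Vm0"]),
    Sb = unname(patient$derived["Sb"]),
    Vmx = patient$Vmax, Kresp = patient$K, beta = patient$beta,
    kp3 = patient$kp3, Gb = patient$Gb, Ib = patient$Ib,
    BW = patient$body_mass)
}

#' Basal steady state of a virtual patient
#'
#' Assembles the zero-input equilibrium of the model: empty gastrointestinal
#' tract and subcutaneous depots, plasma glucose at `Gb`, plasma insulin at
#' `Ib`, delayed insulin signals at their basal values and deviation states
#' at zero. The basal-calibrated constants (`kp1`, `Vm0`, `Sb`, computed in
#' [patient_params()]) make this an exact equilibrium; the function verifies
#' it by evaluating the derivative and errors if the residual exceeds
#' `tol` times the state scale, which signals an inconsistent parameter set.
#'
#' @param patient a [patient_params()] object.
#' @param tol relative tolerance on the derivative max-norm.
#' @return Named numeric state vector of class `model_state` (see
#'   [model_state_names()]).
#' @export
#' @examples
#' s <- basal_steady_state(patient_preset("T2DMA"))
#' s["Gp"] / default_model_params()["VG"] # plasma glucose, mg/dL
basal_steady_state <- function(patient, tol = 1e-8) {
  stopifnot(inherits(patient, "patient_params"))
  d <- patient$derived
  cst <- patient$constants
  state <- c(
    Qsto1 = 0, Qsto2 = 0, Qgut = 0,
    Gp = unname(d["Gpb"]), Gt = unname(d["Gtb"]),
    Ip = unname(d["Ipb"]), Il = unname(d["Ilb"]),
    Ipo = unname(d["Sb"] / cst[["gamma"]]),
    I1 = patient$Ib, Id = patient$Ib,
    X = 0, Y = 0, Isc1 = 0, Isc2 = 0
  )
  deriv <- model_derivatives(0, state, patient)
  scale <- max(abs(state))
  if (max(abs(deriv)) > tol * scale) {
    stop("basal state of '", patient$name, "' is not an equilibrium ",
         "(residual ", format(max(abs(deriv))), "); parameter set is ",
         "inconsistent")
  }
  structure(state, class = "model_state")
}

#' Model derivatives (reference implementation)
#'
#' Time derivative of the 14-compartment state under given exogenous inputs.
#' This is the plain-R reference for the compiled integrator and is suitable
#' for use with general-purpose ODE solvers; the forcing inputs are the
#' instantaneous meal ingestion rate, the size of the meal currently being
#' digested (which sets the nonlinear gastric emptying curve) and the
#' subcutaneous insulin delivery rate.
#'
#' @param t time (min); unused, the system is autonomous given the inputs.
#' @param state named numeric state vector (see [model_state_names()]).
#' @param patient a [patient_params()] object.
#' @param inputs list with `meal_mg_min` (glucose ingestion rate, mg/min),
#'   `meal_total_mg` (reference meal size for the emptying curve, mg) and
#'   `sc_insulin_pmol_kg_min` (subcutaneous insulin delivery, pmol/kg/min).
#' @return Named numeric vector of derivatives, same order as `state`.
#' @export
#' @examples
#' p <- patient_preset("T2DMA")
#' max(abs(model_derivatives(0, basal_steady_state(p), p)))
model_derivatives <- function(t, state, patient,
                              inputs = list(meal_mg_min = 0,
                                            meal_total_mg = 0,
                                            sc_insulin_pmol_kg_min = 0)) {
  P <- as.list(pack_params(patient))
  y <- as.numeric(state)
  names(y) <- model_state_names()
  G <- y[["Gp"]] / P$VG
  I <- y[["Ip"]] / P$VI

  kempt <- P$kmax
  Qsto <- y[["Qsto1"]] + y[["Qsto2"]]
  D <- inputs$meal_total_mg
  if (!is.null(D) && D > 0) {
    aa <- 5 / (2 * D * (1 - P$b))
    cc <- 5 / (2 * D * P$d)
    kempt <- P$kmin + (P$kmax - P$kmin) / 2 *
      (tanh(aa * (Qsto - P$b * D)) - tanh(cc * (Qsto - P$d * D)) + 2)
  }
  dQsto1 <- -P$kgri * y[["Qsto1"]] + inputs$meal_mg_min
  dQsto2 <- P$kgri * y[["Qsto1"]] - kempt * y[["Qsto2"]]
  dQgut <- kempt * y[["Qsto2"]] - P$kabs * y[["Qgut"]]
  Ra <- P$f * P$kabs * y[["Qgut"]] / P$BW

  EGP <- max(0, P$kp1 - P$kp2 * y[["Gp"]] - P$kp3 * y[["Id"]])
  E <- if (y[["Gp"]] > P$ke2) P$ke1 * (y[["Gp"]] - P$ke2) else 0
  Uid <- max(0, P$Vm0 + P$Vmx * y[["X"]]) * y[["Gt"]] / (P$Km0 + y[["Gt"]])
  dGp <- EGP + Ra - P$Fcns - E - P$k1 * y[["Gp"]] + P$k2 * y[["Gt"]]
  dGt <- -Uid + P$k1 * y[["Gp"]] - P$k2 * y[["Gt"]]
  dG <- dGp / P$VG

  Ytarget <- max(P$beta / P$BW * (G - P$Gb), -P$Sb)
  dY <- -P$alpha * (y[["Y"]] - Ytarget)
  Spo <- max(0, y[["Y"]] + P$Sb + if (dG > 0) P$Kresp / P$BW * dG else 0)
  dIpo <- -P$gamma * y[["Ipo"]] + Spo
  S <- P$gamma * y[["Ipo"]]

  Rai <- P$ka1 * y[["Isc1"]] + P$ka2 * y[["Isc2"]]
  dIl <- -(P$m1 + P$m3) * y[["Il"]] + P$m2 * y[["Ip"]] + S
  dIp <- -(P$m2 + P$m4) * y[["Ip"]] + P$m1 * y[["Il"]] + Rai
  dI1 <- -P$ki * (y[["I1"]] - I)
  dId <- -P$ki * (y[["Id"]] - y[["I1"]])
  dX <- -P$p2U * y[["X"]] + P$p2U * (I - P$Ib)
  iir <- inputs$sc_insulin_pmol_kg_min
  if (is.null(iir)) iir <- 0
  dIsc1 <- -(P$kd + P$ka1) * y[["Isc1"]] + iir
  dIsc2 <- P$kd * y[["Isc1"]] - P$ka2 * y[["Isc2"]]

  c(Qsto1 = dQsto1, Qsto2 = dQsto2, Qgut = dQgut, Gp = dGp, Gt = dGt,
    Ip = dIp, Il = dIl, Ipo = dIpo, I1 = dI1, Id = dId, X = dX, Y = dY,
    Isc1 = dIsc1, Isc2 = dIsc2)
}

#' Simulation settings
#'
#' The plan is applied identically on consecutive days; the first
#' `burnin_days` are discarded so the scored day is free of
#' initial-condition transients (overnight carryover is the model's own).
#'
#' @param dt integration step (min). Must divide the bolus pulse width
#'   (1 min) evenly for exact dose bookkeeping.
#' @param burnin_days days simulated and discarded before the scored day.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(dt = 1, burnin_days = 1) {
  stopifnot(dt > 0, dt <= 1, abs(1 / dt - round(1 / dt)) < 1e-12,
            burnin_days >= 0)
  structure(list(dt = dt, burnin_days = burnin_days), class = "sim_config")
}

#' Simulate a day under a dosing plan
#'
#' Integrates the virtual patient from its basal steady state over
#' `burnin_days + 1` days with the plan repeated daily, and returns the
#' glucose and insulin trace of the final (scored) day on a uniform grid.
#'
#' @param patient a [patient_params()] object.
#' @param plan a [new_plan()] object.
#' @param sim a [sim_config()] object.
#' @return A `glycemic_trace`: data.frame with columns `time_min` (0 to 1440,
#'   minutes from 00:00 of the scored day), `glucose_mg_dl`, and
#'   `insulin_pmol_l`, with the plan and patient name attached as attributes.
#' @export
#' @examples
#' tr <- simulate_day(patient_preset("T2DMA"), empty_plan())
#' range(tr$glucose_mg_dl)
simulate_day <- function(patient, plan = empty_plan(), sim = sim_config()) {
  stopifnot(inherits(patient, "patient_params"), inherits(plan, "dose_plan"),
            inherits(sim, "sim_config"))
  ev <- delivered_events(plan)
  ndays <- sim$burnin_days + 1
  offs <- rep(1440 * (seq_len(ndays) - 1), each = nrow(ev$meals))
  meals <- cbind(rep(ev$meals$time_min, ndays) + offs,
                 rep(ev$meals$grams, ndays) * 1000,
                 rep(ev$meals$duration_min, ndays))
  boluses <- cbind(rep(ev$boluses$time_min, ndays) + offs,
                   rep(ev$boluses$dose_U, ndays))
  if (nrow(ev$meals) == 0) {
    meals <- matrix(numeric(0), ncol = 3)
    boluses <- matrix(numeric(0), ncol = 2)
  }
  state0 <- basal_steady_state(patient)
  res <- .simulate_cpp(pack_params(patient), as.numeric(state0),
                       meals, boluses, plan$basal_U_per_h,
                       t_end = 1440 * ndays, dt = sim$dt)
  if (!res$ok) {
    stop("integration diverged (non-finite state) for patient '",
         patient$name, "' under plan with ", nrow(ev$meals), " meals, ",
         "basal ", plan$basal_U_per_h, " U/h")
  }
  scale <- max(abs(state0))
  if (res$max_clamp > 1e-6 * scale) {
    stop("integration instability for patient '", patient$name,
         "' under plan with ", nrow(ev$meals), " meals, basal ",
         plan$basal_U_per_h, " U/h: negative compartment of magnitude ",
         format(res$max_clamp), " exceeded the clamp tolerance")
  }
  keep <- res$time >= 1440 * sim$burnin_days
  out <- data.frame(time_min = res$time[keep] - 1440 * sim$burnin_days,
                    glucose_mg_dl = res$glucose[keep],
                    insulin_pmol_l = res$insulin[keep])
  class(out) <- c("glycemic_trace", "data.frame")
  attr(out, "plan") <- plan
  attr(out, "patient_name") <- patient$name
  attr(out, "dt") <- sim$dt
  out
}

#' @export
print.glycemic_trace <- function(x, ...) {
  cat(sprintf("<glycemic_trace> %s: %d samples, glucose %.1f-%.1f mg/dL\n",
              attr(x, "patient_name") %||% "?", nrow(x),
              min(x$glucose_mg_dl), max(x$glucose_mg_dl)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
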