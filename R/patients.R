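#' Default physiological rate constants of the virtual patient
#'
#' Returns the complete set of rate constants of the compartmental
#' glucose-insulin model that are shared by all virtual patients. The six
#' severity parameters (`Ib`, `Gb`, `Vmax`, `K`, `beta`, `kp3`) and body mass
#' are patient-specific and supplied through [patient_params()]; everything
#' else defaults to the values below, drawn from the published
#' meal-simulation literature. Units follow the usual per-kilogram
#' normalization: glucose masses in mg/kg, insulin masses in pmol/kg,
#' concentrations in mg/dL (glucose) and pmol/L (insulin), time in minutes.
#'
#' @return Named numeric vector of rate constants:
#' \describe{
#'   \item{VG, k1, k2}{glucose distribution volume (dL/kg) and plasma/tissue
#'     exchange rates (1/min)}
#'   \item{VI, m1, m2, m3, m4}{insulin distribution volume (L/kg) and
#'     plasma/liver exchange and degradation rates (1/min)}
#'   \item{kmax, kmin, kabs, kgri, b, d, f}{gastric emptying bounds (1/min),
#'     intestinal absorption rate (1/min), grinding rate (1/min), emptying
#'     curve shape fractions, and bioavailability fraction}
#'   \item{kp2, ki}{EGP glucose feedback (1/min) and delayed insulin signal
#'     rate (1/min); the liver insulin sensitivity kp3 is patient-specific}
#'   \item{Fcns, Km0, p2U}{insulin-independent utilization (mg/kg/min),
#'     utilization Michaelis constant (mg/kg), insulin action rate (1/min)}
#'   \item{alpha, gamma}{beta-cell response delay and portal insulin release
#'     rates (1/min)}
#'   \item{ke1, ke2}{renal clearance slope (1/min) and threshold (mg/kg)}
#'   \item{kd, ka1, ka2}{subcutaneous depot transfer and absorption rates
#'     (1/min)}
#'   \item{EGPb}{basal endogenous glucose production (mg/kg/min)}
#'   \item{pmol_per_U}{conversion from insulin Units to pmol}
#' }
#' @export
#' @examples
#' default_model_params()["kabs"]
default_model_params <- function() {
  c(
    # glucose kinetics
    VG = 1.88, k1 = 0.065, k2 = 0.079,
    # insulin kinetics (m3 fixed at its basal hepatic-extraction value)
    VI = 0.05, m1 = 0.190, m2 = 0.484, m3 = 0.285, m4 = 0.194,
    # gastrointestinal transit
    kmax = 0.0558, kmin = 0.0080, kabs = 0.057, kgri = 0.0558,
    b = 0.82, d = 0.010, f = 0.90,
    # endogenous glucose production
    kp2 = 0.0021, ki = 0.0079, EGPb = 2.0,
    # utilization
    Fcns = 1.0, Km0 = 225.59, p2U = 0.0331,
    # secretion dynamics
    alpha = 0.050, gamma = 0.5,
    # renal excretion
    ke1 = 0.0005, ke2 = 339,
    # subcutaneous insulin absorption
    kd = 0.0164, ka1 = 0.0018, ka2 = 0.0182,
    # dose conversion: 1 U = 6 nmol
    pmol_per_U = 6000
  )
}

#' Construct a virtual-patient parameter set
#'
#' Combines the six patient-specific severity parameters with the shared rate
#' constants and calibrates the basal state: the derived constants `kp1`
#' (EGP intercept), `Vm0` (basal insulin-dependent utilization capacity) and
#' `Sb` (basal insulin secretion) are computed so that plasma glucose `Gb`
#' and plasma insulin `Ib` are an exact equilibrium of the zero-input system.
#'
#' @param Ib basal plasma insulin concentration (pmol/L).
#' @param Gb basal plasma glucose concentration (mg/dL).
#' @param Vmax insulin-dependent glucose utilization capacity
#'   (mg/kg/min per pmol/L).
#' @param K pancreatic responsivity to the glucose rate of change
#'   (pmol/min per mg/dL/min, whole body).
#' @param beta pancreatic insulin secretion responsivity to glucose above
#'   basal (pmol/min per mg/dL, whole body).
#' @param kp3 liver insulin sensitivity of endogenous glucose production
#'   (mg/kg/min per pmol/L).
#' @param body_mass body mass in kg.
#' @param name label for the patient.
#' @param constants named vector of shared rate constants; entries override
#'   [default_model_params()].
#' @return An object of class `patient_params`: a named list with all rate
#'   constants, the severity parameters, and the derived basal constants.
#' @export
#' @examples
#' p <- patient_params(Ib = 57.9, Gb = 120.8, Vmax = 0.042, K = 397,
#'                     beta = 27.3, kp3 = 0.007)
#' p$derived["Sb"]
patient_params <- function(Ib, Gb, Vmax, K, beta, kp3, body_mass = 74,
                           name = "custom", constants = NULL) {
  stopifnot(Ib > 0, Gb > 0, Vmax >= 0, K >= 0, beta >= 0, kp3 >= 0,
            body_mass > 0)
  cst <- default_model_params()
  if (!is.null(constants)) {
    bad <- setdiff(names(constants), names(cst))
    if (length(bad) > 0) {
      stop("unknown model constants: ", paste(bad, collapse = ", "))
    }
    cst[names(constants)] <- constants
  }
  if (any(cst < 0)) stop("all rate constants must be non-negative")

  # Basal calibration. At equilibrium with no meal and no exogenous insulin:
  #   dGp = EGPb - Fcns - Eb - k1*Gpb + k2*Gtb = 0   fixes Gtb
  #   dGt = 0 with Uid_b = Vm0*Gtb/(Km0+Gtb)         fixes Vm0
  #   EGPb = kp1 - kp2*Gpb - kp3*Ib                  fixes kp1
  #   insulin chain at (Ipb, Ilb)                    fixes Sb
  Gpb <- Gb * cst[["VG"]]
  Eb <- cst[["ke1"]] * max(0, Gpb - cst[["ke2"]])
  Gtb <- (cst[["Fcns"]] + Eb + cst[["k1"]] * Gpb - cst[["EGPb"]]) / cst[["k2"]]
  Uidb <- cst[["EGPb"]] - cst[["Fcns"]] - Eb
  if (Gtb <= 0 || Uidb <= 0) {
    stop("inconsistent parameter set: basal fluxes give non-positive ",
         "tissue glucose or utilization (Gb = ", Gb, ", EGPb = ",
         cst[["EGPb"]], ")")
  }
  Vm0 <- Uidb * (cst[["Km0"]] + Gtb) / Gtb
  kp1 <- cst[["EGPb"]] + cst[["kp2"]] * Gpb + kp3 * Ib
  Ipb <- Ib * cst[["VI"]]
  Ilb <- (cst[["m2"]] + cst[["m4"]]) * Ipb / cst[["m1"]]
  Sb <- (cst[["m1"]] + cst[["m3"]]) * Ilb - cst[["m2"]] * Ipb
  if (Sb <= 0) stop("inconsistent parameter set: basal secretion <= 0")

  structure(
    list(
      name = name,
      Ib = Ib, Gb = Gb, Vmax = Vmax, K = K, beta = beta, kp3 = kp3,
      body_mass = body_mass,
      constants = cst,
      derived = c(kp1 = kp1, Vm0 = Vm0, Sb = Sb, Gpb = unname(Gpb),
                  Gtb = unname(Gtb), Ipb = unname(Ipb), Ilb = unname(Ilb))
    ),
    class = "patient_params"
  )
}

#' @export
print.patient_params <- function(x, ...) {
  cat("<patient_params> ", x$name, "\n", sep = "")
  cat(sprintf("  Gb %.1f mg/dL | Ib %.1f pmol/L | body mass %.0f kg\n",
              x$Gb, x$Ib, x$body_mass))
  cat(sprintf("  Vmax %.3f | K %.1f | beta %.1f | kp3 %.3f\n",
              x$Vmax, x$K, x$beta, x$kp3))
  invisible(x)
}

# Characteristics of the three built-in virtual patients: increasing disease
# severity from prediabetes (T2DMA) to advanced T2DM (T2DMC).
.preset_table <- list(
  T2DMA = list(Ib = 57.9, Gb = 120.8, Vmax = 0.042, K = 397,   beta = 27.3, kp3 = 0.007),
  T2DMB = list(Ib = 59.3, Gb = 146.1, Vmax = 0.039, K = 270.1, beta = 20,   kp3 = 0.006),
  T2DMC = list(Ib = 60.3, Gb = 161.8, Vmax = 0.032, K = 150.2, beta = 12.1, kp3 = 0.005)
)

#' Built-in virtual patients
#'
#' Three virtual patients of increasing type 2 diabetes severity: `T2DMA`
#' (prediabetes), `T2DMB` (intermediate) and `T2DMC` (advanced). They differ
#' in basal insulin `Ib`, basal glucose `Gb`, insulin-dependent utilization
#' capacity `Vmax`, beta-cell responsivities `K` (rate of change) and `beta`
#' (level), and liver insulin sensitivity `kp3`; all weigh 74 kg and share
#' the remaining rate constants.
#'
#' @param name one of `"T2DMA"`, `"T2DMB"`, `"T2DMC"`.
#' @return A [patient_params()] object.
#' @export
#' @examples
#' patient_preset("T2DMB")$Gb
patient_preset <- function(name = c("T2DMA", "T2DMB", "T2DMC")) {
  name <- match.arg(name)
  p <- .preset_table[[name]]
  patient_params(Ib = p$Ib, Gb = p$Gb, Vmax = p$Vmax, K = p$K,
                 beta = p$beta, kp3 = p$kp3, body_mass = 74, name = name)
}

#' Read a patient parameter file
#'
#' Patient files are flat YAML key-value maps with at least the six severity
#' parameters (`Ib`, `Gb`, `Vmax`, `K`, `beta`, `kp3`); `body_mass`, `name`
#' and any shared rate constant may also be given. The three built-in presets
#' ship under `system.file("extdata", "patients", package = "glycopt")`.
#'
#' @param path path to a YAML patient file.
#' @return A [patient_params()] object.
#' @export
read_patient <- function(path) {
  if (!file.exists(path)) stop("patient file not found: ", path)
  kv <- yaml::read_yaml(path)
  need <- c("Ib", "Gb", "Vmax", "K", "beta", "kp3")
  miss <- setdiff(need, names(kv))
  if (length(miss) > 0) {
    stop("patient file ", path, " is missing fields: ",
         paste(miss, collapse = ", "))
  }
  extra <- setdiff(names(kv), c(need, "body_mass", "name"))
  constants <- if (length(extra) > 0) unlist(kv[extra]) else NULL
  patient_params(Ib = kv$Ib, Gb = kv$Gb, Vmax = kv$Vmax, K = kv$K,
                 beta = kv$beta, kp3 = kv$kp3,
                 body_mass = if (is.null(kv$body_mass)) 74 else kv$body_mass,
                 name = if (is.null(kv$name)) basename(path) else kv$name,
                 constants = constants)
}

#' Write a patient parameter file
#'
#' @param patient a [patient_params()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_patient <- function(patient, path) {
  stopifnot(inherits(patient, "patient_params"))
  kv <- list(name = patient$name, Ib = patient$Ib, Gb = patient$Gb,
             Vmax = patient$Vmax, K = patient$K, beta = patient$beta,
             kp3 = patient$kp3, body_mass = patient$body_mass)
  yaml::write_yaml(kv, path)
  invisible(path)
}
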