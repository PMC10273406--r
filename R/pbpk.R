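# Whole-body physiologically based pharmacokinetics. Flow-limited
# (perfusion-rate-limited) 14-compartment model: gut lumen, gut tissue,
# liver, kidney, brain, heart, lung, spleen, muscle, adipose, skin, bone,
# arterial and venous blood. Oral absorption is first order from the gut
# lumen; the bioavailable fraction F is applied to the absorption flux
# (lumping first-pass loss), and elimination is renal (kidney as the main
# clearance organ). The system is linear, so AUC is proportional to dose and
# the realized oral/iv AUC ratio equals F by construction.

pbpk_compartments <- c("gut_lumen", "gut_tissue", "liver", "kidney", "brain",
                       "heart", "lung", "spleen", "muscle", "adipose", "skin",
                       "bone", "arterial_blood", "venous_blood")

# organs perfused directly from arterial blood (their flows sum to cardiac
# output together with the hepatic-artery flow carried by "liver")
perfused_organs <- c("gut_tissue", "spleen", "liver", "kidney", "brain",
                     "heart", "muscle", "adipose", "skin", "bone")
portal_organs <- c("gut_tissue", "spleen")   # drain into the liver

#' Reference adult compartment table
#'
#' Volumes (L) and regional blood flows (L/h) for a 70 kg reference adult.
#' The liver flow is the hepatic-artery contribution; portal inflow arrives
#' through gut tissue and spleen. Flows of the perfused organs sum to the
#' cardiac output (322 L/h).
#'
#' @return Data frame with columns `compartment`, `volume`, `flow`.
#' @export
reference_pbpk_table <- function() {
  data.frame(
    compartment = pbpk_compartments,
    volume = c(1.0, 1.1, 1.8, 0.31, 1.45, 0.33, 0.5, 0.15, 29, 13, 3.4, 10,
               1.8, 3.6),
    flow   = c(0,   70,  12,  74,   46,   16,   0,   8,    45, 19, 20,  12,
               0,   0)
  )
}

#' Demographic flow multipliers
#'
#' Shipped sex/age-block multipliers applied to blood flows and clearance on
#' top of allometric weight scaling. The allometric exponent already carries
#' the age trend, so the age-block factors are neutral by default; the female
#' factor reflects the lower reference cardiac output.
#'
#' @return Data frame with columns `key`, `flow_mult`.
#' @export
demographic_multipliers <- function() {
  data.frame(
    key = c("sex:male", "sex:female", "cohort:child", "cohort:adolescent",
            "cohort:adult"),
    flow_mult = c(1.0, 0.95, 1.0, 1.0, 1.0)
  )
}

#' Construct drug PK parameters
#'
#' @param name Drug name.
#' @param F_oral Oral bioavailability, in (0, 1\].
#' @param ka First-order absorption rate (1/h), > 0.
#' @param CL Renal clearance for the reference adult (L/h), > 0.
#' @param Kp Tissue:plasma partition coefficient(s): a positive scalar applied
#'   to every tissue, or a named vector per compartment.
#' @param dose Dose per administration (mg).
#' @param doses_per_day,days Dosing regimen.
#' @param ec50 Optional per-target (or scalar) EC50 in mg/L for target
#'   modulation.
#' @return An object of class `pk_parameters`.
#' @export
pk_parameters <- function(name, F_oral, ka, CL, Kp = 1, dose,
                          doses_per_day = 1L, days = 1L, ec50 = NULL) {
  stopifnot(F_oral > 0, F_oral <= 1, ka > 0, CL > 0, dose >= 0,
            doses_per_day >= 1L, days >= 1L, all(Kp > 0))
  structure(list(name = name, F_oral = F_oral, ka = ka, CL = CL, Kp = Kp,
                 dose = dose, doses_per_day = as.integer(doses_per_day),
                 days = as.integer(days), ec50 = ec50),
            class = "pk_parameters")
}

#' Read PK parameters from YAML
#'
#' @param path YAML file with fields `name`, `F_oral`, `ka`, `CL`, `Kp`,
#'   `dose`, `doses_per_day`, `days` and optional `ec50`.
#' @return A [pk_parameters] object.
#' @examples
#' pk <- read_pk_parameters(system.file("extdata", "pk", "elvanse.yaml",
#'                                      package = "virtrial"))
#' pk$F_oral
#' @export
read_pk_parameters <- function(path) {
  y <- yaml::read_yaml(path)
  kp <- y$Kp
  if (is.list(kp)) kp <- unlist(kp)
  ec50 <- y$ec50
  if (is.list(ec50)) ec50 <- unlist(ec50)
  pk_parameters(y$name, y$F_oral, y$ka, y$CL, Kp = kp, dose = y$dose,
                doses_per_day = y$doses_per_day %||% 1L,
                days = y$days %||% 1L, ec50 = ec50)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scale the reference PBPK parameters to a patient
#'
#' Volumes scale linearly with body weight (`W / 70`), blood flows and
#' clearance allometrically (`(W / 70)^0.75`), with the sex and age-block
#' multipliers of [demographic_multipliers] applied to flows. A 70 kg
#' reference adult male reproduces the reference table exactly.
#'
#' @param patient One-row `virtual_cohort` data frame (or list) with fields
#'   `weight`, `sex`, `cohort`.
#' @param pk A [pk_parameters] object.
#' @return An object of class `pbpk_params`: the scaled compartment table,
#'   `cardiac_output`, and `cl_scale` (the factor applied to the drug's
#'   reference clearance).
#' @export
build_patient_params <- function(patient, pk) {
  stopifnot(is.numeric(patient$weight), patient$weight > 0)
  w_ratio <- patient$weight[1] / 70
  mult <- demographic_multipliers()
  fm <- function(key) {
    i <- match(key, mult$key)
    if (is.na(i)) 1 else mult$flow_mult[i]
  }
  flow_mult <- w_ratio^0.75 *
    fm(paste0("sex:", patient$sex[1] %||% "male")) *
    fm(paste0("cohort:", patient$cohort[1] %||% "adult"))
  tab <- reference_pbpk_table()
  tab$volume <- tab$volume * w_ratio
  tab$flow <- tab$flow * flow_mult
  co <- sum(tab$flow[tab$compartment %in% perfused_organs])
  structure(list(compartments = tab, cardiac_output = co,
                 cl_scale = flow_mult, weight = patient$weight[1]),
            class = "pbpk_params")
}

#' Reference adult PBPK parameters
#'
#' Convenience wrapper: [build_patient_params] for the 70 kg adult male.
#' @param pk A [pk_parameters] object.
#' @return A `pbpk_params` object.
#' @export
reference_patient_params <- function(pk) {
  build_patient_params(list(weight = 70, sex = "male", cohort = "adult"), pk)
}

pbpk_derivs <- function(t, A, p) {
  C <- A[p$comp] / p$V                      # mg/L per compartment
  kp <- p$Kp
  art <- C["arterial_blood"]; ven <- C["venous_blood"]
  Q <- p$Q
  dA <- stats::setNames(numeric(length(p$comp)), p$comp)

  absorbed <- p$ka * A["gut_lumen"]
  dA["gut_lumen"] <- -absorbed
  dA["gut_tissue"] <- p$F_oral * absorbed +
    Q["gut_tissue"] * (art - C["gut_tissue"] / kp["gut_tissue"])
  dA["spleen"] <- Q["spleen"] * (art - C["spleen"] / kp["spleen"])
  q_hep <- Q["liver"] + Q["gut_tissue"] + Q["spleen"]
  dA["liver"] <- Q["liver"] * art +
    Q["gut_tissue"] * C["gut_tissue"] / kp["gut_tissue"] +
    Q["spleen"] * C["spleen"] / kp["spleen"] -
    q_hep * C["liver"] / kp["liver"]
  for (org in c("brain", "heart", "muscle", "adipose", "skin", "bone")) {
    dA[org] <- Q[org] * (art - C[org] / kp[org])
  }
  dA["kidney"] <- Q["kidney"] * (art - C["kidney"] / kp["kidney"]) -
    p$CL * C["kidney"] / kp["kidney"]
  dA["lung"] <- p$CO * (ven - C["lung"] / kp["lung"])
  dA["arterial_blood"] <- p$CO * (C["lung"] / kp["lung"] - art)
  dA["venous_blood"] <- q_hep * C["liver"] / kp["liver"] +
    sum(Q[c("kidney", "brain", "heart", "muscle", "adipose", "skin", "bone")] *
          C[c("kidney", "brain", "heart", "muscle", "adipose", "skin", "bone")] /
          kp[c("kidney", "brain", "heart", "muscle", "adipose", "skin", "bone")]) -
    p$CO * ven
  list(c(dA,
         eliminated = unname(p$CL * C["kidney"] / kp["kidney"]),
         unabsorbed = unname((1 - p$F_oral) * absorbed),
         auc_venous = unname(ven)))   # exact AUC, immune to output-grid error
}

expand_kp <- function(Kp) {
  kp <- stats::setNames(rep(1, length(pbpk_compartments)), pbpk_compartments)
  if (length(Kp) == 1L && is.null(names(Kp))) {
    tissues <- setdiff(pbpk_compartments,
                       c("gut_lumen", "arterial_blood", "venous_blood"))
    kp[tissues] <- Kp
  } else {
    bad <- setdiff(names(Kp), pbpk_compartments)
    if (length(bad)) stop("unknown Kp compartment(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    kp[names(Kp)] <- Kp
  }
  kp
}

#' Simulate the 14-compartment PBPK model
#'
#' Integrates the flow-limited system over the dosing regimen (oral doses
#' added to the gut lumen at each administration time; intravenous bolus
#' placed in venous blood at time zero) and returns per-compartment
#' concentration trajectories plus the cumulative renally eliminated and
#' unabsorbed amounts.
#'
#' @param params A `pbpk_params` ([build_patient_params]).
#' @param pk A [pk_parameters] object.
#' @param route `"oral"` or `"iv"` (single bolus of `pk$dose`).
#' @param horizon End of the output grid in hours (default: regimen length).
#' @param dt Output grid resolution (h), default 0.1.
#' @param rtol,atol Integrator tolerances.
#' @return A `concentration_curve`: `time` (h), `conc` (time × 14 matrix,
#'   mg/L), `eliminated` and `unabsorbed` (cumulative mg), `administered`
#'   (total mg) and regimen metadata.
#' @export
simulate_pbpk <- function(params, pk, route = c("oral", "iv"), horizon = NULL,
                          dt = 0.1, rtol = 1e-8, atol = 1e-10) {
  route <- match.arg(route)
  stopifnot(inherits(params, "pbpk_params"), inherits(pk, "pk_parameters"))
  tab <- params$compartments
  if (is.null(horizon)) horizon <- 24 * pk$days
  p <- list(comp = pbpk_compartments,
            V = stats::setNames(tab$volume, tab$compartment),
            Q = stats::setNames(tab$flow, tab$compartment),
            Kp = expand_kp(pk$Kp),
            CO = params$cardiac_output,
            CL = pk$CL * params$cl_scale,
            ka = pk$ka,
            F_oral = if (route == "oral") pk$F_oral else 1)
  y0 <- stats::setNames(numeric(length(pbpk_compartments) + 3L),
                        c(pbpk_compartments, "eliminated", "unabsorbed",
                          "auc_venous"))
  times <- seq(0, horizon, by = dt)
  events <- NULL
  if (route == "iv") {
    y0["venous_blood"] <- pk$dose
    administered <- pk$dose
  } else {
    dose_times <- as.vector(outer(seq(0, by = 24 / pk$doses_per_day,
                                      length.out = pk$doses_per_day),
                                  24 * (seq_len(pk$days) - 1L), `+`))
    dose_times <- sort(dose_times[dose_times < horizon])
    administered <- pk$dose * length(dose_times)
    if (pk$dose > 0 && length(dose_times)) {
      events <- list(data = data.frame(var = "gut_lumen", time = dose_times,
                                       value = pk$dose, method = "add"))
      times <- sort(unique(c(times, dose_times)))
    }
  }
  sol <- deSolve::ode(y = y0, times = times, func = pbpk_derivs, parms = p,
                      method = "lsoda", rtol = rtol, atol = atol,
                      events = events)
  if (attr(sol, "istate")[1] < 0) {
    stop("PBPK integrator failure (istate = ", attr(sol, "istate")[1], ")",
         call. = FALSE)
  }
  amounts <- sol[, pbpk_compartments, drop = FALSE]
  conc <- sweep(amounts, 2, p$V[pbpk_compartments], "/")
  structure(list(time = sol[, "time"], conc = conc, amounts = amounts,
                 eliminated = sol[, "eliminated"],
                 unabsorbed = sol[, "unabsorbed"],
                 auc_venous = sol[, "auc_venous"],
                 administered = administered, route = route,
                 F_oral = pk$F_oral, doses_per_day = pk$doses_per_day),
            class = "concentration_curve")
}

#' Mass balance of a simulated curve
#'
#' Decomposes the administered dose into drug still in the system, renally
#' eliminated, unabsorbed (first-pass/non-bioavailable) and gut-lumen
#' residue at the end of the horizon, and reports the relative closure error
#' of `in-system + eliminated` against the absorbed amount `F x dose` (oral)
#' or the dose (iv).
#'
#' @param curve A `concentration_curve`.
#' @return List with the components (mg) and `rel_error`.
#' @export
mass_balance <- function(curve) {
  stopifnot(inherits(curve, "concentration_curve"))
  i <- length(curve$time)
  lumen <- curve$amounts[i, "gut_lumen"]
  in_system <- sum(curve$amounts[i, setdiff(pbpk_compartments, "gut_lumen")])
  target <- if (curve$route == "oral") curve$F_oral * curve$administered
            else curve$administered
  rel <- if (target > 0) {
    abs(in_system + curve$eliminated[i] + curve$F_oral * lumen - target) / target
  } else {
    max(abs(c(in_system, curve$eliminated[i])))
  }
  list(in_system = in_system, eliminated = curve$eliminated[i],
       unabsorbed = curve$unabsorbed[i], gut_lumen = lumen,
       administered = curve$administered, rel_error = rel)
}

auc_trapz <- function(t, y) sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Realized oral bioavailability
#'
#' `AUC(venous, oral single dose) / AUC(venous, equal iv bolus)` over a
#' horizon of at least `n_half_lives` elimination half-lives (estimated from
#' the distribution volume and scaled clearance) plus an absorption margin.
#'
#' @param params A `pbpk_params`.
#' @param pk A [pk_parameters] object.
#' @param n_half_lives Horizon length in elimination half-lives (default 10).
#' @return Fraction in (0, 1\].
#' @export
realized_bioavailability <- function(params, pk, n_half_lives = 10) {
  stopifnot(n_half_lives >= 5)
  if (pk$dose <= 0) stop("needs a positive dose", call. = FALSE)
  kp <- expand_kp(pk$Kp)
  v_ss <- sum(params$compartments$volume * kp[params$compartments$compartment])
  t_half <- log(2) * v_ss / (pk$CL * params$cl_scale)
  horizon <- n_half_lives * t_half + 10 / pk$ka
  single <- pk
  single$doses_per_day <- 1L; single$days <- 1L
  # coarse output grid: the AUC accumulates as an ODE state, not by trapezoid
  oral <- simulate_pbpk(params, single, route = "oral", horizon = horizon,
                        dt = horizon / 50)
  iv <- simulate_pbpk(params, single, route = "iv", horizon = horizon,
                      dt = horizon / 50)
  auc_iv <- iv$auc_venous[length(iv$time)]
  if (auc_iv <= 0) stop("iv AUC is zero", call. = FALSE)
  oral$auc_venous[length(oral$time)] / auc_iv
}

#' Per-target modulation intensity from a concentration curve
#'
#' Summarizes exposure at the effect site (brain by default) as the mean
#' receptor occupancy `C / (C + EC50)` over the final dosing interval, and
#' signs it with the drug's per-target effect.
#'
#' @param curve A `concentration_curve`.
#' @param drug A [drug_definition].
#' @param ec50 Scalar or per-gene named vector of EC50 values (mg/L); also
#'   taken from the drug's PK record when attached there.
#' @param site Effect-site compartment (default `"brain"`).
#' @return A `target_modulation` data frame: `gene`, `effect`, `intensity`
#'   (in \[0, 1\]), `signed`.
#' @export
modulation_from_curve <- function(curve, drug, ec50, site = "brain") {
  stopifnot(inherits(curve, "concentration_curve"),
            inherits(drug, "drug_definition"),
            site %in% colnames(curve$conc))
  genes <- drug$targets$gene
  if (length(ec50) == 1L && is.null(names(ec50))) {
    ec <- stats::setNames(rep(ec50, length(genes)), genes)
  } else {
    ec <- ec50[genes]
    if (any(is.na(ec))) {
      stop("missing EC50 for target(s): ",
           paste(genes[is.na(ec)], collapse = ", "), call. = FALSE)
    }
  }
  if (any(ec <= 0)) stop("EC50 must be positive", call. = FALSE)
  t_end <- max(curve$time)
  window <- curve$time >= t_end - 24 / curve$doses_per_day
  cc <- curve$conc[window, site]
  tt <- curve$time[window]
  occ <- function(e) {
    if (length(tt) < 2L) return(mean(cc / (cc + e)))
    auc_trapz(tt, cc / (cc + e)) / (max(tt) - min(tt))
  }
  intensity <- vapply(ec, occ, numeric(1))
  out <- data.frame(gene = genes, effect = drug$targets$effect,
                    intensity = unname(intensity),
                    signed = drug$targets$effect * unname(intensity))
  class(out) <- c("target_modulation", "data.frame")
  out
}
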