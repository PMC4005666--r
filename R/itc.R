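# One-site isothermal titration calorimetry: the Wiseman model as used by
# MicroCal ORIGIN. Per injection, total cell concentrations are updated with
# the perfusion (displaced-volume) bookkeeping, the bound-ligand
# concentration follows from the one-site quadratic, and the differential
# heat carries the conventional displaced-volume correction
#   dQ_i = Q_i - Q_{i-1} + (v_i / V0) * (Q_i + Q_{i-1}) / 2.
#
# Units: energies carry a declared label (default kJ/mol); entropies are in
# milli-units of that label per kelvin (J/K/mol alongside kJ/mol), the
# convention of calorimetric tables. Per-injection heats are reported in
# microjoules when the energy unit is kJ/mol (the natural instrument scale).

.R_GAS <- 8.31446  # J / (K mol)

#' Titration protocol
#'
#' Defaults reproduce a typical riboswitch titration: 1.4 ml cell of 15 uM
#' RNA, 150 uM ligand in the syringe, one initial 1 ul injection followed by
#' 24 x 8 ul, at 303.15 K.
#'
#' @param cellVolume cell volume, litres.
#' @param cellConc cell (macromolecule) concentration, mol/L.
#' @param syringeConc syringe (ligand) concentration, mol/L.
#' @param injections ordered injection volumes, litres.
#' @param temperature kelvin.
#' @return a `TitrationProtocol`.
#' @export
titrationProtocol <- function(cellVolume = 1.4e-3, cellConc = 15e-6,
                              syringeConc = 150e-6,
                              injections = c(1e-6, rep(8e-6, 24L)),
                              temperature = 303.15) {
  new("TitrationProtocol", cellVolume = cellVolume, cellConc = cellConc,
      syringeConc = syringeConc, injections = injections,
      temperature = temperature)
}

#' Derive one-site binding thermodynamics
#'
#' Completes a parameter set from (n, dH, Ka, T): Kd = 1/Ka, and either
#' dG = dH - T*dS/1000 when the entropy is supplied, dS from a supplied dG,
#' or both from the mass-action free energy -RT ln(Ka). The audit value
#' -RT ln(Ka) is always attached (attribute `dGfromKa`, in the declared
#' energy unit, plus `dGfromKa_kcal`), so internal inconsistencies in
#' published tables surface instead of being silently reconciled.
#'
#' @param n stoichiometry.
#' @param dH binding enthalpy, in `energyUnit` per mol.
#' @param Ka association constant, 1/M.
#' @param T temperature, kelvin.
#' @param dS optional entropy, milli-`energyUnit`/K/mol (e.g. J/K/mol with
#'   kJ/mol energies).
#' @param dG optional free energy, `energyUnit`/mol.
#' @param energyUnit `"kJ/mol"` or `"kcal/mol"`.
#' @return a `BindingParams`.
#' @export
deriveThermodynamics <- function(n = 1, dH, Ka, T, dS = NULL, dG = NULL,
                                 energyUnit = c("kJ/mol", "kcal/mol")) {
  energyUnit <- match.arg(energyUnit)
  stopifnot(Ka > 0, T > 0)
  rGas <- if (energyUnit == "kJ/mol") .R_GAS / 1000 else .R_GAS / 4184
  dGKa <- -rGas * T * log(Ka)
  if (!is.null(dS)) {
    dGv <- dH - T * dS / 1000
    dSv <- dS
  } else if (!is.null(dG)) {
    dGv <- dG
    dSv <- (dH - dG) / T * 1000
  } else {
    dGv <- dGKa
    dSv <- (dH - dGv) / T * 1000
  }
  out <- new("BindingParams", n = n, dH = dH, Ka = Ka, Kd = 1 / Ka,
             dG = dGv, dS = dSv, T = T, energyUnit = energyUnit)
  attr(out, "dGfromKa") <- dGKa
  attr(out, "dGfromKa_kcal") <- -(.R_GAS / 4184) * T * log(Ka)
  out
}

# Total concentrations in the cell after cumulative injected volume dV, with
# the ORIGIN displaced-volume bookkeeping.
.cellTotals <- function(protocol, cumVol) {
  V0 <- protocol@cellVolume
  f <- cumVol / (2 * V0)
  list(Mt = protocol@cellConc * (1 - f) / (1 + f),
       Xt = protocol@syringeConc * (cumVol / V0) / (1 + f))
}

# Bound-ligand concentration from the one-site closed form: the quadratic
# root in [0, min(Xt, n*Mt)].
.boundConc <- function(n, Ka, Mt, Xt) {
  s <- Xt + n * Mt + 1 / Ka
  disc <- pmax(0, s^2 - 4 * Xt * n * Mt)
  (s - sqrt(disc)) / 2
}

# Noise-free per-injection heats (microjoules for kJ/mol enthalpies) and the
# running molar ratio. Shared by the simulator and the fit model.
.titrationHeats <- function(n, dH, Ka, protocol, displacementCorrection = TRUE) {
  V0 <- protocol@cellVolume
  cum <- cumsum(protocol@injections)
  tot <- .cellTotals(protocol, cum)
  B <- .boundConc(n, Ka, tot$Mt, tot$Xt)
  Q <- V0 * dH * B * 1e9  # kJ -> microjoule
  Qprev <- c(0, Q[-length(Q)])
  dQ <- Q - Qprev
  # without the correction the increments telescope exactly to V0*dH*B_final
  if (displacementCorrection)
    dQ <- dQ + (protocol@injections / V0) * (Q + Qprev) / 2
  list(heat = dQ, molarRatio = tot$Xt / tot$Mt)
}

#' Simulate a one-site ITC titration
#'
#' @param params a `BindingParams` (only `n`, `dH`, `Ka` are used; `dH` in
#'   kJ/mol).
#' @param protocol a [titrationProtocol()].
#' @param noiseSd Gaussian noise standard deviation on the per-injection
#'   heats, microjoules. A `seed` is mandatory when `noiseSd > 0`.
#' @param seed integer seed controlling the noise; the simulation is
#'   deterministic given (params, protocol, noiseSd, seed).
#' @param displacementCorrection apply the conventional displaced-volume
#'   heat correction. With it off, the noiseless per-injection heats
#'   telescope exactly to `V0 * dH * [bound]_final` (heat conservation).
#' @return data.frame with `index` (1-based injection), `volume` (litres),
#'   `molarRatio` (total ligand / total macromolecule after the injection,
#'   strictly increasing) and `heat` (microjoules, signed; exothermic
#'   negative).
#' @export
simulateTitration <- function(params, protocol = titrationProtocol(),
                              noiseSd = 0, seed = NULL,
                              displacementCorrection = TRUE) {
  stopifnot(is(params, "BindingParams"), is(protocol, "TitrationProtocol"))
  sim <- .titrationHeats(params@n, params@dH, params@Ka, protocol,
                         displacementCorrection = displacementCorrection)
  heat <- sim$heat
  if (noiseSd > 0) {
    if (is.null(seed))
      stop("noiseSd > 0 requires an explicit seed (reproducibility contract)")
    heat <- heat + withr::with_seed(seed,
                                    stats::rnorm(length(heat), 0, noiseSd))
  }
  data.frame(index = seq_along(heat), volume = protocol@injections,
             molarRatio = sim$molarRatio, heat = heat)
}

#' Fit the one-site binding model to injection heats
#'
#' Nonlinear least squares (Levenberg-Marquardt) over (n, dH, Ka). The first
#' injection (conventionally a small priming injection) is excluded by
#' default. Initial values: n = 1, dH from the largest-magnitude early heat
#' per mole injected, Ka = 1/cellConc. Non-convergence or non-identifiable
#' data yield a flagged result, not an exception.
#'
#' @param heats data.frame with columns `index` and `heat` (microjoules),
#'   e.g. from [simulateTitration()] or read from CSV.
#' @param protocol the [titrationProtocol()] used.
#' @param excludeFirst drop injection 1 from the fit.
#' @return an `ItcFit`; see [fitParams()], [fitSE()], [fitConverged()],
#'   [fitFlags()].
#' @export
fitOneSite <- function(heats, protocol = titrationProtocol(),
                       excludeFirst = TRUE) {
  stopifnot(all(c("index", "heat") %in% names(heats)))
  use <- heats$index
  if (excludeFirst) use <- setdiff(use, 1L)
  if (length(use) < 5L)
    stop("need at least 5 usable injections to fit a one-site model")
  y <- heats$heat[match(use, heats$index)]
  if (max(abs(y)) < 1e-9) {
    return(new("ItcFit",
               params = new("BindingParams", n = 1, dH = 0, Ka = NA_real_,
                            Kd = NA_real_, dG = NA_real_, dS = NA_real_,
                            T = protocol@temperature, energyUnit = "kJ/mol"),
               se = c(n = NA_real_, dH = NA_real_, Ka = NA_real_),
               converged = FALSE, flags = "non-identifiable: all heats ~ 0",
               residualNorm = 0, nUsed = length(use),
               fitted = data.frame(index = use, heat = y, fitted = 0)))
  }
  predict_ <- function(n, dH, Ka) {
    .titrationHeats(n, dH, Ka, protocol)$heat[use]
  }
  molesPerInj <- protocol@syringeConc * stats::median(protocol@injections)
  dH0 <- y[which.max(abs(y[seq_len(min(5L, length(y)))]))] / (molesPerInj * 1e9)
  start <- list(n = 1, dH = if (is.finite(dH0) && dH0 != 0) dH0 else -10,
                Ka = 1 / protocol@cellConc)
  df <- data.frame(y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ predict_(n, dH, Ka), data = df, start = start,
                      lower = c(n = 1e-3, dH = -Inf, Ka = 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(new("ItcFit",
               params = new("BindingParams", n = start$n, dH = start$dH,
                            Ka = start$Ka, Kd = 1 / start$Ka, dG = NA_real_,
                            dS = NA_real_, T = protocol@temperature,
                            energyUnit = "kJ/mol"),
               se = c(n = NA_real_, dH = NA_real_, Ka = NA_real_),
               converged = FALSE,
               flags = paste("optimizer failure:", conditionMessage(fit)),
               residualNorm = NA_real_, nUsed = length(use),
               fitted = data.frame(index = use, heat = y, fitted = NA_real_)))
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(n = NA_real_, dH = NA_real_, Ka = NA_real_))
  conv <- isTRUE(fit$convInfo$isConv)
  pred <- predict_(est["n"], est["dH"], est["Ka"])
  flags <- character(0)
  if (!conv) flags <- c(flags, "did not converge")
  params <- deriveThermodynamics(n = unname(est["n"]), dH = unname(est["dH"]),
                                 Ka = unname(est["Ka"]),
                                 T = protocol@temperature)
  new("ItcFit", params = params,
      se = c(n = unname(se["n"]), dH = unname(se["dH"]), Ka = unname(se["Ka"])),
      converged = conv, flags = flags,
      residualNorm = sqrt(sum((y - pred)^2)), nUsed = length(use),
      fitted = data.frame(index = use, heat = y, fitted = pred))
}

#' Reference one-site binding parameters for the E. coli TPP riboswitch
#'
#' Published calorimetric parameters (303.15 K) for TPP binding to the
#' natural-sequence E. coli TPP riboswitch and to k-junction sequence
#' variants, used as simulation inputs and for the Gibbs-Helmholtz audit.
#' Energies in kJ/mol, entropies in J/K/mol, Kd in uM.
#'
#' @return data.frame with one row per sequence variant.
#' @export
tppItcParams <- function() {
  data.frame(
    variant = c("natural", "A1bG", "dUC", "A1nU", "A2bC", "A2bU"),
    n = c(1.07, 0.56, 0.82, 0.93, 0.91, 0.88),
    n_se = c(0.07, 0.01, 0.01, 0.04, 0.02, 0.01),
    dH = c(-18.29, -17.82, -8.72, -11.81, -21.85, -21.18),
    dH_se = c(0.18, 0.45, 0.12, 0.79, 0.47, 0.24),
    dS = c(-30, -33.1, 1.24, -14.3, -44.3, -41.2),
    dS_se = c(0.63, 1.50, 0.47, 2.63, 1.57, 0.81),
    dG = c(-9.20, -7.79, -9.09, -7.48, -8.42, -8.69),
    dG_se = c(0.06, 0.06, 0.08, 0.11, 0.08, 0.05),
    Kd_uM = c(0.23, 2.44, 0.28, 4.07, 0.85, 0.55),
    Kd_se = c(0.02, 0.23, 0.04, 0.73, 0.11, 0.04),
    stringsAsFactors = FALSE)
}

#' Gibbs-Helmholtz audit of a binding-parameter table
#'
#' For each row computes dH - T*dS and its deviation from the tabulated dG,
#' plus the mass-action free energy -RT ln(Ka) from Kd on both the kJ and
#' kcal scales. Reporting both exposes unit inconsistencies in published
#' tables rather than deciding which header is in error.
#'
#' @param table a data.frame like [tppItcParams()] (columns `dH` kJ/mol,
#'   `dS` J/K/mol, `dG` kJ/mol, `Kd_uM`).
#' @param T temperature, kelvin.
#' @return the table augmented with `dG_gh`, `dG_dev`, `dG_from_Kd_kJ`,
#'   `dG_from_Kd_kcal`.
#' @export
gibbsAudit <- function(table = tppItcParams(), T = 303.15) {
  dGgh <- table$dH - T * table$dS / 1000
  Ka <- 1 / (table$Kd_uM * 1e-6)
  cbind(table,
        dG_gh = dGgh,
        dG_dev = dGgh - table$dG,
        dG_from_Kd_kJ = -(.R_GAS / 1000) * T * log(Ka),
        dG_from_Kd_kcal = -(.R_GAS / 4184) * T * log(Ka))
}

#' Read / write per-injection heats as CSV
#'
#' Columns: `injection_index`, `volume_uL`, `heat_uJ`.
#'
#' @param heats data.frame from [simulateTitration()].
#' @param path CSV path.
#' @return `writeHeatsCSV`: `path` invisibly; `readHeatsCSV`: a data.frame
#'   with `index`, `volume` (litres), `heat` (microjoules).
#' @export
writeHeatsCSV <- function(heats, path) {
  utils::write.csv(data.frame(injection_index = heats$index,
                              volume_uL = heats$volume * 1e6,
                              heat_uJ = heats$heat),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHeatsCSV
#' @export
readHeatsCSV <- function(path) {
  x <- utils::read.csv(path)
  data.frame(index = x$injection_index, volume = x$volume_uL * 1e-6,
             heat = x$heat_uJ)
}
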