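#' @include AllClasses.R
NULL

#' Fit a linear spectroscopic calibration
#'
#' Ordinary least-squares line through (concentration, absorbance) pairs, as
#' used for UV/VIS quantitation of the eluted analyte. Concentrations are in
#' mmol/L (the working range of the seven-point calibration is
#' 0.10-0.50 mmol/L).
#'
#' @param concentrations numeric, calibration levels (mmol/L), at least two
#'   distinct values.
#' @param absorbances numeric, same length.
#' @return a [CalibrationCurve-class].
#' @examples
#' fitCalibration(c(0.1, 0.2, 0.3), c(0.19, 0.37, 0.55))
#' @export
fitCalibration <- function(concentrations, absorbances) {
  stopifnot(length(concentrations) == length(absorbances),
            length(concentrations) >= 2L)
  if (length(unique(concentrations)) < 2L)
    stop("unusable calibration: all concentration levels are equal")
  fit <- stats::lm(absorbances ~ concentrations)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((absorbances - mean(absorbances))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  new("CalibrationCurve",
      concentrations = as.numeric(concentrations),
      absorbances = as.numeric(absorbances),
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      rSquared = r2)
}

#' Back-calculate concentration from absorbance
#'
#' Inverts the calibration line and converts to SI: returns mol/L. Negative
#' back-calculated concentrations (absorbance below the intercept, as happens
#' with blank-corrected readings) are clamped to zero with a warning.
#'
#' @param curve a [CalibrationCurve-class].
#' @param absorbance numeric, measured absorbance(s).
#' @return numeric, concentration(s) in mol/L.
#' @export
absorbanceToConcentration <- function(curve, absorbance) {
  stopifnot(is(curve, "CalibrationCurve"))
  if (curve@slope == 0) stop("calibration slope is zero; cannot invert")
  c_mmol <- (absorbance - curve@intercept) / curve@slope
  if (any(c_mmol < 0)) {
    warning("negative back-calculated concentration clamped to zero")
    c_mmol <- pmax(c_mmol, 0)
  }
  c_mmol * 1e-3
}

#' Construct a batch-binding experiment
#'
#' @param cIncubation incubation concentration (mol/L).
#' @param vIncubation bath volume (L).
#' @param vElution elution volume (L).
#' @param cElution eluted concentration(s), one per replicate (mol/L).
#' @param molarMass analyte molar mass (g/mol); defaults to cannabidiol.
#' @param polymerMass dry polymer mass (g).
#' @return a [BindingExperiment-class]. A warning is raised if the eluted
#'   moles exceed the moles initially in the bath (mass-balance violation).
#' @export
bindingExperiment <- function(cIncubation, vIncubation, vElution, cElution,
                              molarMass = 314.46, polymerMass) {
  obj <- new("BindingExperiment", cIncubation = cIncubation,
             vIncubation = vIncubation, vElution = vElution,
             cElution = as.numeric(cElution), molarMass = molarMass,
             polymerMass = polymerMass)
  if (any(cElution * vElution > cIncubation * vIncubation * (1 + 1e-9)))
    warning("mass balance violated: eluted moles exceed incubated moles")
  obj
}

#' Adsorption capacity Q
#'
#' Q = C_s * V_s * M / m_p in mg per g polymer, from the eluted concentration
#' C_s (mol/L), elution volume V_s (L), analyte molar mass M (g/mol) and the
#' polymer mass m_p (g). Vectorized over replicate elution concentrations.
#'
#' @param exp a [BindingExperiment-class].
#' @return numeric, Q in mg/g (one value per replicate).
#' @examples
#' e <- bindingExperiment(2.4e-5, 0.1, 0.003, 8e-5, polymerMass = 0.15)
#' adsorptionCapacity(e)  # ~0.503 mg/g
#' @export
adsorptionCapacity <- function(exp) {
  stopifnot(is(exp, "BindingExperiment"))
  if (exp@polymerMass <= 0) stop("polymer mass must be > 0")
  exp@cElution * exp@vElution * exp@molarMass / exp@polymerMass * 1e3
}

#' Imprinting factor
#'
#' Ratio of the imprinted to the nonimprinted polymer's adsorption capacity;
#' values > 1 indicate template-specific binding sites.
#'
#' @param qMip,qNip adsorption capacities (mg/g); `qNip` must be > 0.
#' @return numeric, Q_MIP / Q_NIP.
#' @export
imprintingFactor <- function(qMip, qNip) {
  if (any(qNip <= 0)) stop("imprinting factor undefined for Q_NIP <= 0")
  qMip / qNip
}

#' Enrichment factor
#'
#' Eluted analyte concentration divided by the original incubation
#' concentration; measures preconcentration by the bind-and-elute cycle.
#'
#' @param cElution eluted concentration (mol/L).
#' @param cIncubation incubation concentration (mol/L), > 0.
#' @return numeric, dimensionless.
#' @export
enrichmentFactor <- function(cElution, cIncubation) {
  if (any(cIncubation <= 0)) stop("incubation concentration must be > 0")
  cElution / cIncubation
}

#' Replicate summary of a binding experiment
#'
#' Reduces the per-replicate capacities to mean and sample standard
#' deviation (n - 1 denominator) and reports the enrichment factor per
#' replicate mean.
#'
#' @param exp a [BindingExperiment-class] with one `cElution` per replicate.
#' @return list with elements `q` (per replicate, mg/g), `qMean`, `qSd`,
#'   `enrichmentFactor`, `n`, and `massBalanceOk`.
#' @export
bindingResult <- function(exp) {
  q <- adsorptionCapacity(exp)
  ok <- all(exp@cElution * exp@vElution <=
              exp@cIncubation * exp@vIncubation * (1 + 1e-9))
  list(q = q, qMean = mean(q),
       qSd = if (length(q) > 1L) stats::sd(q) else NA_real_,
       enrichmentFactor = enrichmentFactor(mean(exp@cElution),
                                           exp@cIncubation),
       n = length(q), massBalanceOk = ok)
}

#' Read a calibration table from CSV
#'
#' Expects columns `concentration_mmol_per_L` and `absorbance`.
#'
#' @param path CSV file path.
#' @return a [CalibrationCurve-class].
#' @export
readCalibrationCsv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("concentration_mmol_per_L", "absorbance") %in% names(df)))
  fitCalibration(df$concentration_mmol_per_L, df$absorbance)
}

#' Read a binding-experiment descriptor (JSON) with replicate elutions
#'
#' The JSON object must carry `c_incubation_mol_per_L`,
#' `v_incubation_L`, `v_elution_L`, `c_elution_mol_per_L` (array, one per
#' replicate), `molar_mass_g_per_mol` and `polymer_mass_g`.
#'
#' @param path JSON file path.
#' @return a [BindingExperiment-class].
#' @export
readBindingJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bindingExperiment(cIncubation = x$c_incubation_mol_per_L,
                    vIncubation = x$v_incubation_L,
                    vElution = x$v_elution_L,
                    cElution = x$c_elution_mol_per_L,
                    molarMass = x$molar_mass_g_per_mol,
                    polymerMass = x$polymer_mass_g)
}
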