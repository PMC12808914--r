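#' @include AllClasses.R
NULL

#' Washburn pore-throat diameter
#'
#' d = -4 * gamma * cos(theta) / P for a non-wetting liquid (theta > 90 deg,
#' so the result is positive). Defaults are the mercury constants used for
#' the intrusion analysis: gamma = 0.484 N/m, theta = 130 deg. A pressure of
#' ~4.15e8 Pa maps to ~3 nm and ~3.11e3 Pa to ~400 um, the working range of
#' a mercury porosimeter.
#'
#' @param pressure applied pressure (Pa), > 0; vectorized.
#' @param gamma surface tension (N/m).
#' @param thetaDeg contact angle (degrees), in (90, 180].
#' @return pore-throat diameter in nm.
#' @export
washburnDiameter <- function(pressure, gamma = 0.484, thetaDeg = 130) {
  if (any(pressure <= 0)) stop("pressure must be > 0")
  if (thetaDeg <= 90 || thetaDeg > 180)
    stop("Washburn intrusion undefined for wetting contact angles (<= 90 deg)")
  d_m <- -4 * gamma * cos(thetaDeg * pi / 180) / pressure
  d_m * 1e9
}

#' Pressure corresponding to a Washburn diameter
#'
#' Exact inverse of [washburnDiameter()]; used by the synthetic intrusion
#' generator and for round-trip checks.
#'
#' @param diameterNm pore-throat diameter (nm), > 0.
#' @inheritParams washburnDiameter
#' @return pressure in Pa.
#' @export
washburnPressure <- function(diameterNm, gamma = 0.484, thetaDeg = 130) {
  if (any(diameterNm <= 0)) stop("diameter must be > 0")
  if (thetaDeg <= 90 || thetaDeg > 180)
    stop("Washburn intrusion undefined for wetting contact angles (<= 90 deg)")
  -4 * gamma * cos(thetaDeg * pi / 180) / (diameterNm * 1e-9)
}

#' Construct an intrusion curve
#'
#' @param pressures Pa, strictly increasing.
#' @param cumulativeVolume cm^3/g, nondecreasing.
#' @param label optional sample identifier.
#' @return an [IntrusionCurve-class].
#' @export
intrusionCurve <- function(pressures, cumulativeVolume,
                           label = NA_character_) {
  new("IntrusionCurve", pressures = as.numeric(pressures),
      cumulativeVolume = as.numeric(cumulativeVolume),
      label = as.character(label))
}

#' Invert an intrusion curve into a pore-size distribution
#'
#' Each pressure step's incremental volume dV is assigned to the Washburn
#' diameter at the step's higher pressure (the smaller pore, the standard
#' intrusion convention); the first point's volume is assigned to its own
#' diameter. The volume-weighted median diameter is taken at 50% of the
#' total intruded volume by log-linear interpolation on the cumulative
#' curve; the modal diameter is the argmax of dV/dlog10(D) after a 3-point
#' moving average.
#'
#' @param curve an [IntrusionCurve-class].
#' @inheritParams washburnDiameter
#' @return a [PoreSizeDistribution-class]; its total specific volume equals
#'   the curve's final cumulative volume exactly.
#' @export
invertIntrusion <- function(curve, gamma = 0.484, thetaDeg = 130) {
  stopifnot(is(curve, "IntrusionCurve"))
  v <- curve@cumulativeVolume
  total <- v[length(v)]
  if (total <= 0) stop("zero total intruded volume")
  d <- washburnDiameter(curve@pressures, gamma, thetaDeg)  # decreasing
  inc <- diff(c(0, v))
  # dV/dlog10(D): bin width from consecutive diameters (first bin reuses
  # the second's width)
  dlog <- abs(diff(log10(d)))
  dlog <- c(if (length(dlog)) dlog[1] else 1, dlog)
  dens <- inc / pmax(dlog, .Machine$double.eps)
  if (length(dens) >= 3) dens_s <- stats::filter(dens, rep(1 / 3, 3),
                                                 sides = 2)
  else dens_s <- dens
  dens_s[is.na(dens_s)] <- dens[is.na(dens_s)]
  mode_d <- d[which.max(dens_s)]
  # volume-weighted median at 50% of the total intruded volume. On a finely
  # sampled curve this is log-linear interpolation between measured points
  # (the porosimeter-report convention). A degenerate jump -- one pressure
  # step carrying the majority of the volume -- gives no information about
  # spread inside the step, so its whole volume sits at the step's diameter
  # (the incremental-assignment convention) and the median is that diameter.
  half <- total / 2
  i <- which(v >= half)[1]
  if (i == 1L || v[i] == v[i - 1L] || inc[i] >= half) {
    med <- d[i]
  } else {
    f <- (half - v[i - 1L]) / (v[i] - v[i - 1L])
    med <- 10^(log10(d[i - 1L]) + f * (log10(d[i]) - log10(d[i - 1L])))
  }
  new("PoreSizeDistribution", diameters = d, incrementalVolume = inc,
      logDensity = as.numeric(dens_s), medianDiameter = med,
      modalDiameter = mode_d, totalSpecificVolume = total)
}

#' Skeletal density from pycnometry replicates
#'
#' Density replicates mass/V_i, reduced to mean and sample standard
#' deviation (n - 1 denominator).
#'
#' @param mass sample mass (g), > 0.
#' @param volumes replicate skeletal volumes (cm^3), all > 0.
#' @return a [PycnometryResult-class].
#' @export
skeletalDensity <- function(mass, volumes) {
  if (length(volumes) < 1L || any(volumes <= 0))
    stop("need >= 1 positive replicate volume")
  if (mass <= 0) stop("mass must be > 0")
  dens <- mass / volumes
  new("PycnometryResult", sampleMass = mass,
      skeletalVolumes = as.numeric(volumes),
      density = mean(dens),
      densitySd = if (length(dens) > 1L) stats::sd(dens) else NA_real_)
}

#' Total porosity from specific pore volume and skeletal density
#'
#' Porosity[%] = V / (V + 1/rho) * 100, combining the mercury-intrusion
#' specific pore volume V (cm^3/g) with the pycnometric skeletal density
#' rho (g/cm^3). Strictly increasing in both arguments.
#'
#' @param specificPoreVolume cm^3/g, >= 0.
#' @param skeletalDensity g/cm^3, > 0.
#' @return porosity in percent.
#' @examples
#' totalPorosity(0.609, 1.343)  # ~45%
#' @export
totalPorosity <- function(specificPoreVolume, skeletalDensity) {
  if (any(specificPoreVolume < 0)) stop("specific pore volume must be >= 0")
  if (any(skeletalDensity <= 0)) stop("skeletal density must be > 0")
  specificPoreVolume / (specificPoreVolume + 1 / skeletalDensity) * 100
}

#' Read an intrusion curve from CSV
#'
#' Columns: `pressure_Pa` (or `pressure_psia` with `units = "psia"`) and
#' `cumulative_volume_cm3_per_g`.
#'
#' @param path CSV file path.
#' @param units "Pa" or "psia" (1 psia = 6894.757 Pa).
#' @return an [IntrusionCurve-class].
#' @export
readIntrusionCsv <- function(path, units = c("Pa", "psia")) {
  units <- match.arg(units)
  df <- utils::read.csv(path)
  p <- if (units == "Pa") df$pressure_Pa else df$pressure_psia * 6894.757
  intrusionCurve(p, df$cumulative_volume_cm3_per_g)
}

#' Read pycnometry replicates from CSV
#'
#' Columns: `mass_g`, `volume_cm3` (one row per replicate; the mass must be
#' identical across rows).
#'
#' @param path CSV file path.
#' @return a [PycnometryResult-class].
#' @export
readPycnometryCsv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("mass_g", "volume_cm3") %in% names(df)))
  skeletalDensity(df$mass_g[1], df$volume_cm3)
}
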