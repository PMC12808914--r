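#' @import methods
NULL

#' Linear UV/VIS calibration
#'
#' Ordinary least-squares calibration line mapping molar concentration
#' (mmol/L) to absorbance, as fitted by [fitCalibration()].
#'
#' @slot concentrations numeric, calibration levels in mmol/L.
#' @slot absorbances numeric, measured absorbances (dimensionless).
#' @slot slope,intercept numeric(1), fitted line (absorbance per mmol/L).
#' @slot rSquared numeric(1), coefficient of determination.
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  representation(concentrations = "numeric", absorbances = "numeric",
                 slope = "numeric", intercept = "numeric",
                 rSquared = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@concentrations) < 2L ||
        length(unique(object@concentrations)) < 2L)
      msg <- c(msg, "need >= 2 distinct concentrations")
    if (length(object@concentrations) != length(object@absorbances))
      msg <- c(msg, "concentrations and absorbances differ in length")
    if (length(object@slope) == 1L && !is.na(object@slope) &&
        object@slope <= 0)
      msg <- c(msg, "slope must be > 0 for a valid analyte calibration")
    if (length(object@rSquared) == 1L && !is.na(object@rSquared) &&
        (object@rSquared < 0 || object@rSquared > 1))
      msg <- c(msg, "rSquared must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' Batch-binding experiment description
#'
#' Everything the adsorption-capacity computation needs: incubation bath,
#' elution, analyte molar mass and polymer mass. All concentrations are in
#' mol/L and volumes in L (SI internally; mg/g appears only in results).
#' `cElution` may hold one value per replicate.
#'
#' @slot cIncubation numeric(1), incubation concentration (mol/L).
#' @slot vIncubation numeric(1), bath volume (L).
#' @slot vElution numeric(1), elution volume (L).
#' @slot cElution numeric, eluted analyte concentration(s) (mol/L), one per
#'   replicate.
#' @slot molarMass numeric(1), analyte molar mass (g/mol).
#' @slot polymerMass numeric(1), dry polymer mass (g).
#' @exportClass BindingExperiment
setClass("BindingExperiment",
  representation(cIncubation = "numeric", vIncubation = "numeric",
                 vElution = "numeric", cElution = "numeric",
                 molarMass = "numeric", polymerMass = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(c(object@vIncubation, object@vElution, object@polymerMass,
              object@molarMass) <= 0))
      msg <- c(msg, "volumes, masses and molar mass must be > 0")
    if (any(object@cElution < 0))
      msg <- c(msg, "cElution must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' Time-resolved uptake series
#'
#' Mean adsorption capacity Q_t (mg/g) at increasing incubation times
#' (minutes), optionally with replicate standard deviations.
#'
#' @slot times numeric, minutes, strictly increasing, >= 0.
#' @slot qT numeric, mean capacity at each time (mg/g), >= 0.
#' @slot qSd numeric, optional standard deviations (mg/g); length 0 or
#'   matching `times`.
#' @slot label character(1), polymer identifier.
#' @exportClass UptakeSeries
setClass("UptakeSeries",
  representation(times = "numeric", qT = "numeric", qSd = "numeric",
                 label = "character"),
  prototype(qSd = numeric(0), label = NA_character_),
  validity = function(object) {
    msg <- NULL
    if (length(object@times) != length(object@qT))
      msg <- c(msg, "times and qT differ in length")
    if (any(object@times < 0) || is.unsorted(object@times, strictly = TRUE))
      msg <- c(msg, "times must be strictly increasing and >= 0")
    if (any(object@qT < 0)) msg <- c(msg, "qT must be >= 0")
    if (length(object@qSd) &&
        length(object@qSd) != length(object@times))
      msg <- c(msg, "qSd must be empty or match times in length")
    if (is.null(msg)) TRUE else msg
  })

#' Empirical kinetic fit (PFO or PSO)
#'
#' @slot model character(1), "PFO" or "PSO".
#' @slot qE numeric(1), equilibrium capacity (mg/g).
#' @slot k numeric(1), rate constant (1/min for PFO, g/mg/min for PSO).
#' @slot rSquared,rmse numeric(1), fit quality (RMSE in mg/g, denominator n).
#' @slot paramSe numeric, named standard errors for qE and k.
#' @exportClass KineticFit
setClass("KineticFit",
  representation(model = "character", qE = "numeric", k = "numeric",
                 rSquared = "numeric", rmse = "numeric", paramSe = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@model %in% c("PFO", "PSO"))
      msg <- c(msg, "model must be 'PFO' or 'PSO'")
    if (object@qE <= 0 || object@k <= 0)
      msg <- c(msg, "qE and k must be > 0")
    if (object@rmse < 0) msg <- c(msg, "rmse must be >= 0")
    if (object@rSquared > 1) msg <- c(msg, "rSquared must be <= 1")
    if (is.null(msg)) TRUE else msg
  })

#' Finite-bath plane-sheet diffusion fit
#'
#' Result of fitting the truncated finite-volume plane-sheet series to
#' fractional uptake data: the apparent diffusion coefficient together with
#' the fixed geometry (half-thickness l), the bath/polymer equilibrium mass
#' ratio alpha and the series roots used.
#'
#' @slot alpha numeric(1), bath-to-polymer equilibrium mass ratio.
#' @slot l numeric(1), characteristic half-thickness (m).
#' @slot qRoots numeric, first n positive roots of tan(q) = -alpha*q.
#' @slot nTerms integer(1), series truncation length.
#' @slot dApparent numeric(1), apparent diffusion coefficient (m^2/s).
#' @slot qInf numeric(1), equilibrium capacity used for normalization (mg/g).
#' @slot rSquared,rmse numeric(1), quality on the fractional-uptake scale.
#' @exportClass CrankFit
setClass("CrankFit",
  representation(alpha = "numeric", l = "numeric", qRoots = "numeric",
                 nTerms = "integer", dApparent = "numeric", qInf = "numeric",
                 rSquared = "numeric", rmse = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
    if (object@l <= 0) msg <- c(msg, "l must be > 0")
    if (object@dApparent <= 0) msg <- c(msg, "dApparent must be > 0")
    if (is.unsorted(object@qRoots, strictly = TRUE))
      msg <- c(msg, "qRoots must be strictly increasing")
    if (is.null(msg)) TRUE else msg
  })

#' Parametric lattice-cube specification
#'
#' Cube of edge `a` minus three orthogonal families of square-section beams
#' (section `window` x `window`) on a grid of pitch t = window + wall. The
#' beam offsets along each axis are t*c for c in {-z, ..., z} (step 1); the
#' offset rule differs between the fine (S1) and coarse (S2) designs:
#' S1 uses z = -0.5 + round(0.5*a/t) (half-integer offsets), S2 uses
#' z = floor((a - t)/(2*t)) (integer offsets).
#'
#' @slot shape character(1), "S1", "S2" or "custom".
#' @slot a numeric(1), cube edge (mm).
#' @slot window numeric(1), lattice spacing / window edge (mm).
#' @slot wall numeric(1), lattice wall (mm).
#' @slot z numeric(1), half-count of beam offsets (may be half-integer).
#' @slot offsets numeric, beam center offsets t*c (mm).
#' @exportClass LatticeSpec
setClass("LatticeSpec",
  representation(shape = "character", a = "numeric", window = "numeric",
                 wall = "numeric", z = "numeric", offsets = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(c(object@a, object@window, object@wall) <= 0))
      msg <- c(msg, "a, window and wall must be > 0")
    if (object@window >= object@a)
      msg <- c(msg, "window must be smaller than the cube edge")
    if (object@z < 0) msg <- c(msg, "degenerate lattice: z < 0")
    if (length(object@offsets) &&
        any(abs(object@offsets) > object@a / 2))
      msg <- c(msg, "beam offsets must lie inside the cube")
    if (is.null(msg)) TRUE else msg
  })

#' Labeled voxel volume
#'
#' 3D label grid with 0 = solid (polymer) and 1 = pore (void), plus the
#' physical voxel size per axis. Used both at mm scale (voxelized lattice
#' cubes) and at nm scale (segmented FIB/SEM stacks).
#'
#' @slot data 3D integer/logical array, 0 = solid, 1 = pore.
#' @slot voxelSize numeric(3), voxel edge length per axis (same length unit
#'   throughout one volume).
#' @slot origin numeric(3), physical coordinate of the (1,1,1) voxel corner.
#' @exportClass VoxelVolume
setClass("VoxelVolume",
  representation(data = "array", voxelSize = "numeric", origin = "numeric"),
  prototype(origin = c(0, 0, 0)),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L || any(dim(object@data) < 1L))
      msg <- c(msg, "data must be a 3D array with all dims >= 1")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive lengths")
    if (!all(object@data %in% c(0, 1)))
      msg <- c(msg, "data must contain only 0 (solid) and 1 (pore)")
    if (is.null(msg)) TRUE else msg
  })

#' 8-bit grayscale voxel stack
#'
#' @slot data 3D numeric array, intensities in [0, 255].
#' @slot voxelSize numeric(3), voxel edge length per axis (nm for FIB/SEM).
#' @exportClass GrayscaleStack
setClass("GrayscaleStack",
  representation(data = "array", voxelSize = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L || any(dim(object@data) < 1L))
      msg <- c(msg, "data must be a 3D array with all dims >= 1")
    if (min(object@data) < 0 || max(object@data) > 255)
      msg <- c(msg, "intensities must lie in [0, 255]")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive lengths")
    if (is.null(msg)) TRUE else msg
  })

#' Mercury-intrusion curve
#'
#' @slot pressures numeric, applied pressures (Pa), strictly increasing.
#' @slot cumulativeVolume numeric, cumulative intruded specific volume
#'   (cm^3/g), nondecreasing.
#' @slot label character(1), sample identifier.
#' @exportClass IntrusionCurve
setClass("IntrusionCurve",
  representation(pressures = "numeric", cumulativeVolume = "numeric",
                 label = "character"),
  prototype(label = NA_character_),
  validity = function(object) {
    msg <- NULL
    if (length(object@pressures) != length(object@cumulativeVolume))
      msg <- c(msg, "pressures and cumulativeVolume differ in length")
    if (any(object@pressures <= 0) ||
        is.unsorted(object@pressures, strictly = TRUE))
      msg <- c(msg, "pressures must be positive and strictly increasing")
    if (is.unsorted(object@cumulativeVolume))
      msg <- c(msg, "cumulativeVolume must be nondecreasing")
    if (is.null(msg)) TRUE else msg
  })

#' Volume-weighted pore-size distribution
#'
#' Washburn-inverted intrusion data: per-bin incremental volumes at the bin
#' diameters (decreasing with pressure), the log-diameter density, and the
#' volume-weighted median and modal diameters.
#'
#' @slot diameters numeric, bin diameters (nm), decreasing with pressure.
#' @slot incrementalVolume numeric, cm^3/g per bin, >= 0.
#' @slot logDensity numeric, dV/dlog10(D) per bin.
#' @slot medianDiameter,modalDiameter numeric(1), nm.
#' @slot totalSpecificVolume numeric(1), cm^3/g.
#' @exportClass PoreSizeDistribution
setClass("PoreSizeDistribution",
  representation(diameters = "numeric", incrementalVolume = "numeric",
                 logDensity = "numeric", medianDiameter = "numeric",
                 modalDiameter = "numeric", totalSpecificVolume = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(object@diameters <= 0)) msg <- c(msg, "diameters must be > 0")
    if (any(object@incrementalVolume < -1e-12))
      msg <- c(msg, "incremental volumes must be >= 0")
    if (abs(sum(object@incrementalVolume) - object@totalSpecificVolume) >
        1e-9 * max(1, object@totalSpecificVolume))
      msg <- c(msg, "incremental volumes must sum to the total")
    if (is.null(msg)) TRUE else msg
  })

#' Pycnometry result
#'
#' @slot sampleMass numeric(1), g.
#' @slot skeletalVolumes numeric, replicate volumes (cm^3), > 0.
#' @slot density numeric(1), mean skeletal density (g/cm^3).
#' @slot densitySd numeric(1), sample sd over replicates (NA for n = 1).
#' @exportClass PycnometryResult
setClass("PycnometryResult",
  representation(sampleMass = "numeric", skeletalVolumes = "numeric",
                 density = "numeric", densitySd = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@sampleMass <= 0) msg <- c(msg, "sampleMass must be > 0")
    if (length(object@skeletalVolumes) < 1L ||
        any(object@skeletalVolumes <= 0))
      msg <- c(msg, "need >= 1 positive replicate volume")
    if (is.null(msg)) TRUE else msg
  })

#' Instrumented indentation curve
#'
#' Load-displacement record with segment markers. Loads in uN, depths in nm.
#'
#' @slot load numeric, uN, >= 0.
#' @slot depth numeric, nm, >= 0.
#' @slot segment character, per-point marker: "loading", "hold", "unloading".
#' @slot pMax numeric(1), peak load (uN).
#' @exportClass IndentationCurve
setClass("IndentationCurve",
  representation(load = "numeric", depth = "numeric", segment = "character",
                 pMax = "numeric"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@load)
    if (length(object@depth) != n || length(object@segment) != n)
      msg <- c(msg, "load, depth and segment differ in length")
    if (any(object@load < 0) || any(object@depth < 0))
      msg <- c(msg, "load and depth must be >= 0")
    if (!all(object@segment %in% c("loading", "hold", "unloading")))
      msg <- c(msg, "segment markers must be loading/hold/unloading")
    un <- object@load[object@segment == "unloading"]
    if (length(un) > 1L && any(diff(un) >= 0))
      msg <- c(msg, "unloading segment must have strictly decreasing load")
    if (is.null(msg)) TRUE else msg
  })

#' Oliver-Pharr indentation result
#'
#' @slot stiffness numeric(1), unloading stiffness S at peak (uN/nm).
#' @slot contactDepth numeric(1), h_c (nm).
#' @slot contactArea numeric(1), projected contact area (nm^2).
#' @slot reducedModulus numeric(1), E_r (MPa).
#' @slot hardness numeric(1), H (MPa).
#' @slot sampleModulus numeric(1), E_s (MPa).
#' @slot nuSample,indenterE,indenterNu numeric(1), elastic constants used
#'   (E in MPa).
#' @slot powerLaw numeric, named fitted unloading parameters (B, hF, m).
#' @exportClass IndentResult
setClass("IndentResult",
  representation(stiffness = "numeric", contactDepth = "numeric",
                 contactArea = "numeric", reducedModulus = "numeric",
                 hardness = "numeric", sampleModulus = "numeric",
                 nuSample = "numeric", indenterE = "numeric",
                 indenterNu = "numeric", powerLaw = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(c(object@stiffness, object@contactArea, object@reducedModulus,
              object@hardness) <= 0))
      msg <- c(msg, "S, A, E_r and H must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Reversible-heat-flow DSC trace
#'
#' @slot temperature numeric, deg C, strictly increasing.
#' @slot revHeatFlow numeric, mW.
#' @slot label character(1).
#' @exportClass DscTrace
setClass("DscTrace",
  representation(temperature = "numeric", revHeatFlow = "numeric",
                 label = "character"),
  prototype(label = NA_character_),
  validity = function(object) {
    msg <- NULL
    if (length(object@temperature) != length(object@revHeatFlow))
      msg <- c(msg, "temperature and revHeatFlow differ in length")
    if (is.unsorted(object@temperature, strictly = TRUE))
      msg <- c(msg, "temperature must be strictly increasing")
    if (is.null(msg)) TRUE else msg
  })

#' Local-thickness map
#'
#' Per-voxel diameter of the largest sphere fully contained in the chosen
#' phase that covers the voxel, with a volume-weighted histogram
#' (fixed bin width of 2 voxels).
#'
#' @slot thickness 3D numeric array, physical thickness inside the phase,
#'   0 outside.
#' @slot phase character(1), "pore" or "solid".
#' @slot voxelSize numeric(1), isotropic voxel size used for the analysis.
#' @slot histogram data.frame with columns mid, fraction (volume-weighted).
#' @slot meanThickness,maxThickness numeric(1), same unit as voxelSize.
#' @exportClass ThicknessMap
setClass("ThicknessMap",
  representation(thickness = "array", phase = "character",
                 voxelSize = "numeric", histogram = "data.frame",
                 meanThickness = "numeric", maxThickness = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@phase %in% c("pore", "solid"))
      msg <- c(msg, "phase must be 'pore' or 'solid'")
    if (any(object@thickness < 0))
      msg <- c(msg, "thickness must be >= 0")
    if (is.null(msg)) TRUE else msg
  })
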