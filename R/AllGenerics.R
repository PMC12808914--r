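#' @include AllClasses.R
NULL

#' Accessors for fitted-parameter and container classes
#'
#' Small accessor family in place of direct slot access: `qE()` and
#' `rateConstant()` for [KineticFit-class], `dApparent()` and `qRoots()` for
#' [CrankFit-class], `medianDiameter()`, `modalDiameter()` and
#' `totalSpecificVolume()` for [PoreSizeDistribution-class], `voxelData()`
#' and `voxelSize()` for voxel containers, `meanThickness()` and
#' `maxThickness()` for [ThicknessMap-class].
#'
#' @param x object of the matching class.
#' @return the corresponding scalar, vector or array.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("qE", function(x) standardGeneric("qE"))
#' @rdname accessors
#' @export
setGeneric("rateConstant", function(x) standardGeneric("rateConstant"))
#' @rdname accessors
#' @export
setGeneric("dApparent", function(x) standardGeneric("dApparent"))
#' @rdname accessors
#' @export
setGeneric("qRoots", function(x) standardGeneric("qRoots"))
#' @rdname accessors
#' @export
setGeneric("medianDiameter", function(x) standardGeneric("medianDiameter"))
#' @rdname accessors
#' @export
setGeneric("modalDiameter", function(x) standardGeneric("modalDiameter"))
#' @rdname accessors
#' @export
setGeneric("totalSpecificVolume",
           function(x) standardGeneric("totalSpecificVolume"))
#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("meanThickness", function(x) standardGeneric("meanThickness"))
#' @rdname accessors
#' @export
setGeneric("maxThickness", function(x) standardGeneric("maxThickness"))

#' @rdname accessors
setMethod("qE", "KineticFit", function(x) x@qE)
#' @rdname accessors
setMethod("rateConstant", "KineticFit", function(x) x@k)
#' @rdname accessors
setMethod("dApparent", "CrankFit", function(x) x@dApparent)
#' @rdname accessors
setMethod("qRoots", "CrankFit", function(x) x@qRoots)
#' @rdname accessors
setMethod("medianDiameter", "PoreSizeDistribution",
          function(x) x@medianDiameter)
#' @rdname accessors
setMethod("modalDiameter", "PoreSizeDistribution",
          function(x) x@modalDiameter)
#' @rdname accessors
setMethod("totalSpecificVolume", "PoreSizeDistribution",
          function(x) x@totalSpecificVolume)
#' @rdname accessors
setMethod("voxelData", "VoxelVolume", function(x) x@data)
#' @rdname accessors
setMethod("voxelData", "GrayscaleStack", function(x) x@data)
#' @rdname accessors
setMethod("voxelSize", "VoxelVolume", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "GrayscaleStack", function(x) x@voxelSize)
#' @rdname accessors
setMethod("meanThickness", "ThicknessMap", function(x) x@meanThickness)
#' @rdname accessors
setMethod("maxThickness", "ThicknessMap", function(x) x@maxThickness)

setMethod("show", "CalibrationCurve", function(object) {
  cat("CalibrationCurve:", length(object@concentrations), "levels\n")
  cat(sprintf("  absorbance = %.5g * c[mmol/L] + %.5g   (R^2 = %.5f)\n",
              object@slope, object@intercept, object@rSquared))
})

setMethod("show", "UptakeSeries", function(object) {
  cat("UptakeSeries", if (!is.na(object@label)) sQuote(object@label) else "",
      ":", length(object@times), "time points,",
      sprintf("t in [%g, %g] min, Q_t in [%.3g, %.3g] mg/g\n",
              min(object@times), max(object@times),
              min(object@qT), max(object@qT)))
})

setMethod("show", "KineticFit", function(object) {
  unit <- if (object@model == "PFO") "1/min" else "g/mg/min"
  cat(sprintf("KineticFit (%s): Q_e = %.4g mg/g, k = %.4g %s\n",
              object@model, object@qE, object@k, unit))
  cat(sprintf("  R^2 = %.4f, RMSE = %.4g mg/g\n",
              object@rSquared, object@rmse))
})

setMethod("show", "CrankFit", function(object) {
  cat(sprintf(
    "CrankFit: D = %.4g m^2/s (alpha = %.4g, l = %.3g m, %d terms)\n",
    object@dApparent, object@alpha, object@l, object@nTerms))
  cat(sprintf("  R^2 = %.4f, RMSE = %.4g (fractional uptake)\n",
              object@rSquared, object@rmse))
})

setMethod("show", "LatticeSpec", function(object) {
  cat(sprintf(
    "LatticeSpec %s: a = %g mm, window = %g mm, wall = %g mm, %d beam offsets\n",
    object@shape, object@a, object@window, object@wall,
    length(object@offsets)))
})

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelVolume %d x %d x %d, voxel %s, pore fraction %.3f\n",
              d[1], d[2], d[3],
              paste(signif(object@voxelSize, 4), collapse = " x "),
              mean(object@data)))
})

setMethod("show", "GrayscaleStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("GrayscaleStack %d x %d x %d, voxel %s, range [%g, %g]\n",
              d[1], d[2], d[3],
              paste(signif(object@voxelSize, 4), collapse = " x "),
              min(object@data), max(object@data)))
})

setMethod("show", "IntrusionCurve", function(object) {
  cat(sprintf(
    "IntrusionCurve%s: %d points, P in [%.3g, %.3g] Pa, V_final = %.4g cm^3/g\n",
    if (!is.na(object@label)) paste0(" ", sQuote(object@label)) else "",
    length(object@pressures), min(object@pressures), max(object@pressures),
    object@cumulativeVolume[length(object@cumulativeVolume)]))
})

setMethod("show", "PoreSizeDistribution", function(object) {
  cat(sprintf(
    "PoreSizeDistribution: median %.3g nm, mode %.3g nm, V = %.4g cm^3/g (%d bins)\n",
    object@medianDiameter, object@modalDiameter,
    object@totalSpecificVolume, length(object@diameters)))
})

setMethod("show", "PycnometryResult", function(object) {
  cat(sprintf(
    "PycnometryResult: rho_skel = %.4g +/- %.2g g/cm^3 (n = %d)\n",
    object@density, object@densitySd, length(object@skeletalVolumes)))
})

setMethod("show", "IndentationCurve", function(object) {
  cat(sprintf(
    "IndentationCurve: %d points, P_max = %.4g uN, h_max = %.4g nm\n",
    length(object@load), object@pMax, max(object@depth)))
})

setMethod("show", "IndentResult", function(object) {
  cat(sprintf(
    "IndentResult: E_s = %.4g MPa, E_r = %.4g MPa, H = %.4g MPa, S = %.4g uN/nm\n",
    object@sampleModulus, object@reducedModulus, object@hardness,
    object@stiffness))
})

setMethod("show", "DscTrace", function(object) {
  cat(sprintf("DscTrace%s: %d points, T in [%g, %g] degC\n",
              if (!is.na(object@label)) paste0(" ", sQuote(object@label)) else "",
              length(object@temperature), min(object@temperature),
              max(object@temperature)))
})

setMethod("show", "ThicknessMap", function(object) {
  cat(sprintf(
    "ThicknessMap (%s phase): mean %.4g, max %.4g (voxel %.4g)\n",
    object@phase, object@meanThickness, object@maxThickness,
    object@voxelSize))
})
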