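#' @include AllClasses.R
NULL

# Independent, reproducible stream per (seed, generator name): the name is
# hashed into a small integer so adding generators never perturbs existing
# fixtures. All values stay below 2^31.
streamSeed <- function(seed, name) {
  ch <- utf8ToInt(name)
  h <- 0
  for (v in ch) h <- (h * 31 + v) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Generate a synthetic uptake series
#'
#' Draws replicate uptake curves from the chosen model plus Gaussian noise,
#' clamped at zero, and returns the replicate mean (and sd) at each time
#' point. Default times are the batch study's incubation grid
#' \{15, 30, 60, 240, 1260\} minutes.
#'
#' Models and their `params`:
#' * `"PFO"`: `qE` (mg/g), `k1` (1/min).
#' * `"PSO"`: `qE` (mg/g), `k2` (g/mg/min).
#' * `"crank"`: `d` (m^2/s), `l` (m), `alpha`, `nTerms` (default 6) and
#'   `qInf` (default 1, i.e. fractional uptake).
#'
#' @param model "PFO", "PSO" or "crank".
#' @param params named list of model parameters (see Details).
#' @param times minutes.
#' @param noiseSd Gaussian noise sd (mg/g); 0 gives the exact model curve.
#' @param replicates number of replicates averaged.
#' @param seed integer seed; fixed seed implies identical output.
#' @param label series label.
#' @return an [UptakeSeries-class].
#' @export
genUptake <- function(model = c("PSO", "PFO", "crank"), params,
                      times = c(15, 30, 60, 240, 1260), noiseSd = 0,
                      replicates = 3L, seed = 1L, label = model) {
  model <- match.arg(model)
  stopifnot(noiseSd >= 0, replicates >= 1L)
  mu <- switch(model,
    PFO = pfoModel(times, params$qE, params$k1),
    PSO = psoModel(times, params$qE, params$k2),
    crank = {
      nT <- if (is.null(params$nTerms)) 6L else params$nTerms
      qInf <- if (is.null(params$qInf)) 1 else params$qInf
      stopifnot(params$d > 0, params$l > 0, params$alpha > 0)
      qInf * crankUptakeFraction(times * 60, params$d, params$l,
                                 params$alpha, crankRoots(params$alpha, nT))
    })
  set.seed(streamSeed(seed, paste0("uptake-", model)))
  reps <- matrix(stats::rnorm(length(times) * replicates, mean = mu,
                              sd = noiseSd),
                 nrow = length(times))
  reps <- pmax(reps, 0)
  uptakeSeries(times, rowMeans(reps),
               qSd = if (replicates > 1L) apply(reps, 1, stats::sd)
                     else numeric(0),
               label = label[1])
}

#' Generate a synthetic mercury-intrusion curve
#'
#' Integrates a volume-weighted lognormal pore-size distribution against
#' log-spaced diameters, maps diameters to pressures through the Washburn
#' relation (theta = 130 deg, gamma = 0.484 N/m), applies multiplicative
#' noise to the cumulative volume and restores monotonicity by a cumulative
#' maximum. The final cumulative volume equals `totalVolume` exactly.
#'
#' @param medianNm volume-weighted median diameter (nm), > 0.
#' @param sigmaLog10 lognormal width in log10 units.
#' @param totalVolume total specific volume (cm^3/g), > 0.
#' @param nPoints number of pressure points, >= 10.
#' @param noiseFrac multiplicative noise fraction on cumulative volume.
#' @param seed integer seed.
#' @param decades half-width of the diameter grid around the median, in
#'   log10 decades.
#' @inheritParams washburnDiameter
#' @return an [IntrusionCurve-class].
#' @export
genIntrusion <- function(medianNm, sigmaLog10 = 0.5, totalVolume,
                         nPoints = 100L, noiseFrac = 0, seed = 1L,
                         gamma = 0.484, thetaDeg = 130, decades = 3) {
  stopifnot(medianNm > 0, totalVolume > 0)
  if (nPoints < 10L) stop("need >= 10 pressure points")
  lg <- seq(log10(medianNm) + decades, log10(medianNm) - decades,
            length.out = nPoints)        # diameters decreasing
  d <- 10^lg
  # cumulative intruded volume at pressure P(d): all pores with diameter
  # >= d, i.e. the lognormal upper tail in log10-diameter
  cum <- totalVolume * stats::pnorm(log10(medianNm), mean = lg,
                                    sd = sigmaLog10)
  if (noiseFrac > 0) {
    set.seed(streamSeed(seed, "intrusion"))
    cum <- cum * (1 + stats::rnorm(nPoints, sd = noiseFrac))
    cum <- pmin(cummax(pmax(cum, 0)), totalVolume)
  }
  cum[nPoints] <- totalVolume
  intrusionCurve(washburnPressure(d, gamma, thetaDeg), cum)
}

#' Generate a synthetic porous volume (Gaussian random field)
#'
#' Spectral synthesis: white Gaussian noise is low-pass filtered with a
#' Gaussian transfer function of the requested correlation length (FFT),
#' then thresholded at the exact empirical quantile so the pore fraction
#' equals `targetPorosity` to within one voxel. The grayscale companion
#' renders pore/solid at two intensity levels, Gaussian-blurred, with
#' additive noise, for exercising [binarize()].
#'
#' @param shape integer(3), grid dimensions.
#' @param voxelSize numeric(3), physical voxel size (nm); may be
#'   anisotropic (e.g. the FIB/SEM 2.7 x 3.4 x 3.0 nm).
#' @param targetPorosity percent, in (0, 100).
#' @param correlationLength physical correlation length (same unit as
#'   `voxelSize`).
#' @param seed integer seed.
#' @param levels intensity levels c(pore, solid) for the grayscale render.
#' @param grayNoiseSd additive intensity noise sd.
#' @param blurSigma render blur sigma (voxels).
#' @return list with `stack` (a [GrayscaleStack-class]) and `truth`
#'   (the ground-truth [VoxelVolume-class]).
#' @export
genVolume <- function(shape = c(64L, 64L, 64L), voxelSize = c(1, 1, 1),
                      targetPorosity = 50, correlationLength = 8,
                      seed = 1L, levels = c(60, 160), grayNoiseSd = 8,
                      blurSigma = 1) {
  stopifnot(length(shape) == 3L, all(shape >= 4L))
  if (targetPorosity <= 0 || targetPorosity >= 100)
    stop("target porosity must be in (0, 100)")
  set.seed(streamSeed(seed, "volume"))
  w <- array(stats::rnorm(prod(shape)), shape)
  # Gaussian low-pass in Fourier space, per-axis sigma in voxels
  sig_vox <- correlationLength / voxelSize
  tf <- function(n, s) {
    k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n] / n
    exp(-2 * (pi * k * s)^2)
  }
  H <- outer(outer(tf(shape[1], sig_vox[1]), tf(shape[2], sig_vox[2])),
             tf(shape[3], sig_vox[3]))
  field <- Re(stats::fft(stats::fft(w) * H, inverse = TRUE)) / prod(shape)
  thr <- stats::quantile(field, targetPorosity / 100, names = FALSE)
  pore <- field <= thr
  truth <- voxelVolume(pore + 0L, voxelSize = voxelSize)
  gray <- ifelse(pore, levels[1], levels[2])
  if (blurSigma > 0) gray <- gaussianBlur3d(gray, blurSigma)
  gray <- gray + array(stats::rnorm(prod(shape), sd = grayNoiseSd), shape)
  gray <- pmin(pmax(round(gray), 0), 255)
  list(stack = grayscaleStack(gray, voxelSize = voxelSize), truth = truth)
}

#' Generate a synthetic indentation curve with a known sample modulus
#'
#' Forward construction: given the unloading exponent `m` and residual-depth
#' fraction `hFfrac`, the peak depth is solved in closed form so that
#' Oliver-Pharr analysis under this package's conventions (epsilon = 0.75,
#' A = 24.56 h_c^2, beta = 1) returns exactly `targetEs` in the noiseless
#' limit; B follows from P(h_max) = p_max. The loading branch is a monotone
#' power law to (h_max, p_max).
#'
#' @param targetEs target sample modulus (MPa), > 0.
#' @param nuS sample Poisson ratio.
#' @param eI,nuI indenter constants (MPa, -).
#' @param pMax peak load (uN); the study's quasi-static protocol uses 400.
#' @param hFfrac residual depth as a fraction of peak depth, in (0, 1).
#' @param mExp unloading exponent, in (1, 2].
#' @param noiseFrac multiplicative load noise fraction.
#' @param nPoints points per segment.
#' @param seed integer seed.
#' @return an [IndentationCurve-class].
#' @export
genIndentation <- function(targetEs, nuS = 0.4, eI = 1.14e6, nuI = 0.07,
                           pMax = 400, hFfrac = 0.4, mExp = 1.5,
                           noiseFrac = 0, nPoints = 100L, seed = 1L) {
  stopifnot(targetEs > 0, hFfrac > 0, hFfrac < 1, mExp > 1, mExp <= 2)
  eR <- reducedModulus(targetEs, nuS, eI, nuI)      # MPa
  eR_un <- eR / 1e6                                  # uN/nm^2
  f <- hFfrac; m <- mExp
  hc_fac <- 1 - 0.75 * (1 - f) / m                   # h_c = hc_fac * h_max
  if (hc_fac <= 0) stop("no positive solution for the peak depth")
  # E_r = (sqrt(pi)/2) * S / sqrt(A), S = m pMax / (hmax (1-f)),
  # A = 24.56 (hc_fac hmax)^2  =>  hmax^2 = (sqrt(pi)/2) m pMax /
  #                                ((1-f) sqrt(24.56) hc_fac E_r)
  hmax2 <- (sqrt(pi) / 2) * m * pMax /
    ((1 - f) * sqrt(24.56) * hc_fac * eR_un)
  hmax <- sqrt(hmax2)
  hF <- f * hmax
  B <- pMax / (hmax - hF)^m
  h_un <- seq(hmax, hF + 0.02 * (hmax - hF), length.out = nPoints)
  p_un <- B * (h_un - hF)^m
  h_lo <- seq(0, hmax, length.out = nPoints)
  p_lo <- pMax * (h_lo / hmax)^1.5
  h_hold <- rep(hmax, 5L)
  p_hold <- rep(pMax, 5L)
  if (noiseFrac > 0) {
    set.seed(streamSeed(seed, "indentation"))
    p_un <- p_un * (1 + stats::rnorm(length(p_un), sd = noiseFrac))
    p_un[1] <- pMax
    p_un <- rev(cummax(rev(pmax(p_un, 0))))
    dup <- duplicated(p_un)
    p_un[dup] <- p_un[dup] - 1e-9 * seq_len(sum(dup))
  }
  indentationCurve(c(p_lo, p_hold, p_un), c(h_lo, h_hold, h_un),
                   c(rep("loading", nPoints), rep("hold", 5L),
                     rep("unloading", nPoints)))
}

#' Generate a synthetic reversible-heat-flow DSC trace
#'
#' Logistic step of height `stepHeight` centered at `tg` between two linear
#' baselines on a 30-250 deg C grid, plus Gaussian noise. The default
#' logistic scale of 20 deg C places onset/endset (tangent constructions)
#' near 100/180 deg C, emulating the breadth of the crosslinked network's
#' transition.
#'
#' @param tg step center (deg C).
#' @param stepHeight signed step height (mW); the reversible heat flow of a
#'   glass transition steps downward, hence the negative default.
#' @param transitionWidth logistic scale (deg C).
#' @param baselineSlopes numeric(2), slopes of the pre/post baselines
#'   (mW per deg C).
#' @param baselineIntercept pre-baseline value at 0 deg C (mW).
#' @param noiseSd additive noise sd (mW).
#' @param nPoints grid points on [30, 250] deg C.
#' @param seed integer seed.
#' @return a [DscTrace-class].
#' @export
genDsc <- function(tg = 140.3, stepHeight = -0.3, transitionWidth = 20,
                   baselineSlopes = c(-0.002, -0.002),
                   baselineIntercept = -0.5, noiseSd = 0, nPoints = 441L,
                   seed = 1L) {
  stopifnot(transitionWidth > 0)
  tt <- seq(30, 250, length.out = nPoints)
  frac <- stats::plogis((tt - tg) / transitionWidth)
  base1 <- baselineIntercept + baselineSlopes[1] * tt
  step_extra <- (baselineSlopes[2] - baselineSlopes[1]) * (tt - tg)
  y <- base1 + frac * (stepHeight + step_extra)
  if (noiseSd > 0) {
    set.seed(streamSeed(seed, "dsc"))
    y <- y + stats::rnorm(nPoints, sd = noiseSd)
  }
  dscTrace(tt, y)
}

#' Generate a synthetic calibration table
#'
#' Absorbance = slope * c + intercept + noise at the given concentration
#' levels; defaults to seven equispaced levels spanning 0.10-0.50 mmol/L.
#'
#' @param slope,intercept generating line (absorbance per mmol/L).
#' @param levels concentration levels (mmol/L), >= 2.
#' @param noiseSd additive absorbance noise sd.
#' @param seed integer seed.
#' @return data.frame with columns `concentration_mmol_per_L`, `absorbance`.
#' @export
genCalibration <- function(slope = 1.8, intercept = 0.01,
                           levels = seq(0.10, 0.50, length.out = 7),
                           noiseSd = 0, seed = 1L) {
  stopifnot(length(levels) >= 2L)
  set.seed(streamSeed(seed, "calibration"))
  data.frame(concentration_mmol_per_L = levels,
             absorbance = slope * levels + intercept +
               stats::rnorm(length(levels), sd = noiseSd))
}
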