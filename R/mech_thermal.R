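#' @include AllClasses.R
NULL

#' Construct an indentation curve
#'
#' @param load uN, per point.
#' @param depth nm, per point.
#' @param segment per-point marker: "loading", "hold", "unloading".
#' @return an [IndentationCurve-class]; `pMax` is taken as the maximum load.
#' @export
indentationCurve <- function(load, depth, segment) {
  new("IndentationCurve", load = as.numeric(load), depth = as.numeric(depth),
      segment = as.character(segment), pMax = max(load))
}

#' Sample modulus from reduced modulus
#'
#' E_s = (1 - nu_s^2) / (1/E_r - (1 - nu_i^2)/E_i): removes the indenter
#' compliance from the reduced (contact) modulus. With a rigid indenter
#' (E_i -> Inf) and nu_s = 0 this reduces to E_s = E_r.
#'
#' @param eR reduced modulus (MPa), > 0.
#' @param nuS sample Poisson ratio (0.4 for the printed copolymer).
#' @param eI indenter modulus (MPa); default diamond, 1.14e6 MPa.
#' @param nuI indenter Poisson ratio; default diamond, 0.07.
#' @return E_s in MPa.
#' @examples
#' sampleModulus(110.7, 0.4)  # ~93 MPa
#' @export
sampleModulus <- function(eR, nuS, eI = 1.14e6, nuI = 0.07) {
  stopifnot(eR > 0, eI > 0, abs(nuS) < 0.5, abs(nuI) < 0.5)
  denom <- 1 / eR - (1 - nuI^2) / eI
  if (denom <= 0)
    stop("nonphysical input: sample compliance 1/E_r does not exceed the ",
         "indenter term")
  (1 - nuS^2) / denom
}

#' Reduced modulus from sample modulus
#'
#' Exact inverse of [sampleModulus()] (used for round-trip checks and by the
#' synthetic indentation generator).
#'
#' @inheritParams sampleModulus
#' @param eS sample modulus (MPa), > 0.
#' @return E_r in MPa.
#' @export
reducedModulus <- function(eS, nuS, eI = 1.14e6, nuI = 0.07) {
  stopifnot(eS > 0, eI > 0, abs(nuS) < 0.5, abs(nuI) < 0.5)
  1 / ((1 - nuS^2) / eS + (1 - nuI^2) / eI)
}

#' Oliver-Pharr analysis of an indentation curve
#'
#' Fits P = B (h - h_f)^m to the unloading branch restricted to
#' `fitWindow` of the peak load (default 20-95%), evaluates the contact
#' stiffness S = dP/dh at h_max, the contact depth
#' h_c = h_max - epsilon P_max / S (epsilon = 0.75, Berkovich), the ideal
#' Berkovich area A = 24.56 h_c^2, the reduced modulus
#' E_r = (sqrt(pi)/2) S / sqrt(A) (beta = 1), hardness H = P_max / A, and
#' the sample modulus via [sampleModulus()]. No tip-rounding area
#' calibration is applied.
#'
#' Units: load uN, depth nm; moduli and hardness are returned in MPa
#' (1 uN/nm^2 = 1e6 MPa).
#'
#' @param curve an [IndentationCurve-class] with >= 10 unloading points.
#' @param nuS sample Poisson ratio (default 0.4).
#' @param eI,nuI indenter constants (default diamond: 1.14e6 MPa, 0.07).
#' @param fitWindow numeric(2), fraction-of-peak-load window for the
#'   power-law fit.
#' @param epsilon geometric constant in h_c (0.75 for Berkovich).
#' @return an [IndentResult-class].
#' @export
oliverPharr <- function(curve, nuS = 0.4, eI = 1.14e6, nuI = 0.07,
                        fitWindow = c(0.20, 0.95), epsilon = 0.75) {
  stopifnot(is(curve, "IndentationCurve"))
  un <- curve@segment == "unloading"
  if (sum(un) < 10L) stop("need >= 10 unloading points")
  p <- curve@load[un]; h <- curve@depth[un]
  pmax_ <- curve@pMax
  keep <- p >= fitWindow[1] * pmax_ & p <= fitWindow[2] * pmax_
  if (sum(keep) < 5L) stop("too few unloading points inside the fit window")
  pf <- p[keep]; hf_ <- h[keep]
  hmax <- max(curve@depth)
  # deterministic start: grid over h_f, log-linear fit of log P ~ log(h-h_f)
  cand <- seq(0, 0.98 * min(hf_), length.out = 25)
  sse <- vapply(cand, function(h0) {
    X <- log(hf_ - h0)
    fit <- stats::lm(log(pf) ~ X)
    sum((exp(stats::fitted(fit)) - pf)^2)
  }, numeric(1))
  h0 <- cand[which.min(sse)]
  lfit <- stats::lm(log(pf) ~ log(hf_ - h0))
  m0 <- min(max(unname(stats::coef(lfit)[2L]), 1.01), 3)
  b0 <- exp(unname(stats::coef(lfit)[1L]))
  fit <- tryCatch(
    minpack.lm::nlsLM(pf ~ B * (hf_ - hF)^m,
                      start = list(B = b0, hF = h0, m = m0),
                      lower = c(1e-12, 0, 1.0001),
                      upper = c(Inf, 0.999 * min(hf_), 5),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("power-law unloading fit did not converge (start B = ",
           signif(b0, 4), ", h_f = ", signif(h0, 4), ", m = ",
           signif(m0, 3), "): ", conditionMessage(e)))
  cf <- stats::coef(fit)
  B <- unname(cf["B"]); hF <- unname(cf["hF"]); m <- unname(cf["m"])
  if (hF >= hmax) stop("fitted residual depth h_f >= h_max")
  S <- B * m * (hmax - hF)^(m - 1)                 # uN/nm
  hc <- hmax - epsilon * pmax_ / S                 # nm
  if (hc <= 0) stop("nonpositive contact depth")
  A <- 24.56 * hc^2                                # nm^2
  eR <- sqrt(pi) / 2 * S / sqrt(A) * 1e6           # MPa
  H <- pmax_ / A * 1e6                             # MPa
  eS <- sampleModulus(eR, nuS, eI, nuI)
  new("IndentResult", stiffness = S, contactDepth = hc, contactArea = A,
      reducedModulus = eR, hardness = H, sampleModulus = eS,
      nuSample = nuS, indenterE = eI, indenterNu = nuI,
      powerLaw = c(B = B, hF = hF, m = m))
}

#' Construct a DSC trace
#'
#' @param temperature deg C, strictly increasing.
#' @param revHeatFlow reversible heat flow (mW).
#' @param label optional identifier.
#' @return a [DscTrace-class].
#' @export
dscTrace <- function(temperature, revHeatFlow, label = NA_character_) {
  new("DscTrace", temperature = as.numeric(temperature),
      revHeatFlow = as.numeric(revHeatFlow), label = as.character(label))
}

#' Midpoint glass-transition temperature from a reversible-heat-flow trace
#'
#' Linear baselines are fitted on the pre- and post-transition windows; the
#' signal is smoothed by a Savitzky-Golay local polynomial (order 3), and
#' Tg is the temperature where the smoothed signal crosses the half-height
#' between the extrapolated baselines (linear interpolation between
#' samples). Onset and endset are the intersections of the tangent at Tg
#' with the two baselines. Invariant under adding a constant, or a common
#' linear tilt, to the whole trace.
#'
#' @param trace a [DscTrace-class] spanning the transition.
#' @param preWindow,postWindow numeric(2) temperature intervals (deg C) on
#'   which to fit the pre-/post-transition baselines.
#' @param sgWidth odd Savitzky-Golay window length (points).
#' @return list with `tg`, `onset`, `endset` (deg C) and `stepHeight` (mW,
#'   signed: post baseline minus pre baseline at Tg).
#' @export
tgMidpoint <- function(trace, preWindow = c(40, 90),
                       postWindow = c(190, 240), sgWidth = 11L) {
  stopifnot(is(trace, "DscTrace"))
  tt <- trace@temperature; y <- trace@revHeatFlow
  pre <- tt >= preWindow[1] & tt <= preWindow[2]
  post <- tt >= postWindow[1] & tt <= postWindow[2]
  if (sum(pre) < 2L || sum(post) < 2L)
    stop("baseline windows must each contain >= 2 points")
  b1 <- stats::lm(y[pre] ~ tt[pre])
  b2 <- stats::lm(y[post] ~ tt[post])
  base1 <- function(x) stats::coef(b1)[1] + stats::coef(b1)[2] * x
  base2 <- function(x) stats::coef(b2)[1] + stats::coef(b2)[2] * x
  step_scale <- stats::median(abs(base2(tt) - base1(tt)))
  noise <- stats::sd(stats::residuals(b1))
  if (step_scale < 3 * max(noise, 1e-300))
    stop("baselines indistinguishable: step height below noise")
  w <- min(sgWidth, length(y) - (1 - length(y) %% 2))
  if (w %% 2 == 0) w <- w - 1
  ys <- if (w >= 5) signal::sgolayfilt(y, p = 3, n = w) else y
  # half-height crossing restricted to between the baseline windows
  mid <- preWindow[2] <= tt & tt <= postWindow[1]
  frac <- (ys - base1(tt)) / (base2(tt) - base1(tt))
  idx <- which(mid)
  cross <- idx[which(frac[idx] < 0.5 & c(frac[idx[-1]], 1) >= 0.5)[1]]
  if (is.na(cross)) cross <- idx[which.min(abs(frac[idx] - 0.5))]
  i0 <- cross; i1 <- min(cross + 1L, length(tt))
  if (i1 > i0 && frac[i1] != frac[i0]) {
    tg <- tt[i0] + (0.5 - frac[i0]) / (frac[i1] - frac[i0]) *
      (tt[i1] - tt[i0])
  } else tg <- tt[i0]
  # tangent at Tg from the smoothed derivative
  di <- max(2L, min(which.min(abs(tt - tg)), length(tt) - 1L))
  slope <- (ys[di + 1L] - ys[di - 1L]) / (tt[di + 1L] - tt[di - 1L])
  ytg <- (base1(tg) + base2(tg)) / 2
  onset <- if (abs(slope - stats::coef(b1)[2]) > 1e-12)
    unname((stats::coef(b1)[1] - (ytg - slope * tg)) /
             (slope - stats::coef(b1)[2])) else NA_real_
  endset <- if (abs(slope - stats::coef(b2)[2]) > 1e-12)
    unname((stats::coef(b2)[1] - (ytg - slope * tg)) /
             (slope - stats::coef(b2)[2])) else NA_real_
  list(tg = tg, onset = onset, endset = endset,
       stepHeight = unname(base2(tg) - base1(tg)))
}

#' Read indentation / DSC CSV files
#'
#' Indentation columns: `depth_nm`, `load_uN`, `segment`; DSC columns:
#' `temperature_C`, `rev_heat_flow_mW`.
#'
#' @param path CSV file path.
#' @return an [IndentationCurve-class] or [DscTrace-class].
#' @export
readIndentationCsv <- function(path) {
  df <- utils::read.csv(path)
  indentationCurve(df$load_uN, df$depth_nm, df$segment)
}

#' @rdname readIndentationCsv
#' @export
readDscCsv <- function(path) {
  df <- utils::read.csv(path)
  dscTrace(df$temperature_C, df$rev_heat_flow_mW)
}
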