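#' @include AllClasses.R
NULL

#' Construct an uptake series
#'
#' @param times incubation times (minutes), strictly increasing.
#' @param qT mean adsorption capacity at each time (mg/g).
#' @param qSd optional replicate standard deviations (mg/g).
#' @param label optional polymer identifier.
#' @return an [UptakeSeries-class].
#' @export
uptakeSeries <- function(times, qT, qSd = numeric(0), label = NA_character_) {
  new("UptakeSeries", times = as.numeric(times), qT = as.numeric(qT),
      qSd = as.numeric(qSd), label = as.character(label))
}

#' Pseudo-first-order uptake model
#'
#' Q_t = Q_e (1 - exp(-k1 t)).
#'
#' @param t time (minutes), >= 0.
#' @param qE equilibrium capacity (mg/g), > 0.
#' @param k1 rate constant (1/min), > 0.
#' @return Q_t in mg/g.
#' @export
pfoModel <- function(t, qE, k1) {
  stopifnot(qE > 0, k1 > 0)
  if (any(t < 0)) stop("negative time")
  qE * (1 - exp(-k1 * t))
}

#' Pseudo-second-order uptake model
#'
#' Q_t = Q_e^2 k2 t / (1 + Q_e k2 t).
#'
#' @param t time (minutes), >= 0.
#' @param qE equilibrium capacity (mg/g), > 0.
#' @param k2 rate constant (g/mg/min), > 0.
#' @return Q_t in mg/g.
#' @export
psoModel <- function(t, qE, k2) {
  stopifnot(qE > 0, k2 > 0)
  if (any(t < 0)) stop("negative time")
  qE^2 * k2 * t / (1 + qE * k2 * t)
}

#' Fit an empirical kinetic model to an uptake series
#'
#' Nonlinear least squares (Levenberg-Marquardt via `minpack.lm::nlsLM`) of
#' the PFO or PSO model on (t, Q_t). Starting values come from the standard
#' linearizations so the fit is fully deterministic: for PSO the line
#' t/Q_t ~ t (slope 1/Q_e, intercept 1/(k2 Q_e^2)); for PFO the line
#' log(Q_e0 - Q_t) ~ t with Q_e0 slightly above max(Q_t).
#'
#' R^2 = 1 - SS_res/SS_tot; RMSE = sqrt(SS_res/n) (denominator n, not n - p).
#'
#' @param series an [UptakeSeries-class] with >= 3 points.
#' @param model "PFO" or "PSO".
#' @return a [KineticFit-class].
#' @export
fitKinetics <- function(series, model = c("PSO", "PFO")) {
  stopifnot(is(series, "UptakeSeries"))
  model <- match.arg(model)
  t <- series@times; q <- series@qT
  if (length(t) < 3L) stop("need at least 3 time points")
  pos <- t > 0 & q > 0
  if (model == "PSO") {
    ln <- stats::lm(I(t[pos] / q[pos]) ~ t[pos])
    sl <- unname(stats::coef(ln)[2L]); ic <- unname(stats::coef(ln)[1L])
    qe0 <- if (sl > 0) 1 / sl else max(q) * 1.1
    k0 <- if (ic > 0 && qe0 > 0) 1 / (ic * qe0^2) else 1e-3
    form <- q ~ qE^2 * k * t / (1 + qE * k * t)
  } else {
    qe0 <- max(q) * 1.05
    ln <- stats::lm(log(pmax(qe0 - q[pos], qe0 * 1e-6)) ~ t[pos])
    k0 <- max(-unname(stats::coef(ln)[2L]), 1e-6)
    form <- q ~ qE * (1 - exp(-k * t))
  }
  start <- list(qE = max(qe0, 1e-6), k = max(k0, 1e-8))
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(t = t, q = q), start = start,
                      lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("kinetic fit did not converge (start: qE = ", signif(start$qE, 4),
           ", k = ", signif(start$k, 4), "): ", conditionMessage(e)))
  cf <- stats::coef(fit)
  res <- q - stats::predict(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((q - mean(q))^2)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(qE = NA_real_, k = NA_real_))
  new("KineticFit", model = model, qE = unname(cf["qE"]), k = unname(cf["k"]),
      rSquared = 1 - ss_res / ss_tot, rmse = sqrt(ss_res / length(q)),
      paramSe = se)
}

#' Read/write uptake series CSV
#'
#' Columns: `time_min`, `q_mg_per_g`, optional `sd`.
#'
#' @param path CSV file path.
#' @param series an [UptakeSeries-class] (writer).
#' @return reader: an [UptakeSeries-class]; writer: `path`, invisibly.
#' @export
readUptakeCsv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_min", "q_mg_per_g") %in% names(df)))
  uptakeSeries(df$time_min, df$q_mg_per_g,
               qSd = if ("sd" %in% names(df)) df$sd else numeric(0))
}

#' @rdname readUptakeCsv
#' @export
writeUptakeCsv <- function(series, path) {
  df <- data.frame(time_min = series@times, q_mg_per_g = series@qT)
  if (length(series@qSd)) df$sd <- series@qSd
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
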