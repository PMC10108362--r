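# Mono-exponential build-up curves and their least-squares fit.

#' Build-up curve container
#'
#' @param times Strictly increasing times (s).
#' @param values Observable values (polarization fractions).
#' @return Data frame of class `buildUpCurve` with columns `time_s`,
#'   `value`.
#' @export
buildUpCurve <- function(times, values) {
  if (length(times) != length(values)) stop("times/values length mismatch")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!all(is.finite(values))) stop("values must be finite")
  structure(data.frame(time_s = times, value = values),
            class = c("buildUpCurve", "data.frame"))
}

#' Fit a mono-exponential build-up
#'
#' Least-squares fit of \eqn{p(t) = p_{max}(1 - e^{-t/T_{hyp}})} (plus an
#' optional constant offset, off by default). Standard errors come from the
#' local quadratic approximation of the objective at the optimum
#' (Gauss-Newton covariance).
#'
#' @param curve A [buildUpCurve()] or data frame with `time_s`, `value`.
#' @param offset If `TRUE`, fit an additive constant as well.
#' @return A `fitResult`: list with `p_max`, `T_hyp_s`, `se_p_max`,
#'   `se_T_hyp_s`, `residual_norm`, `offset`, `fitted`, and the underlying
#'   `nls` object.
#' @export
fitMonoexp <- function(curve, offset = FALSE) {
  t <- curve$time_s
  y <- curve$value
  if (length(unique(t)) < 3L) stop("need at least 3 distinct time points")
  if (!all(is.finite(t)) || !all(is.finite(y))) {
    stop("non-finite values in curve")
  }
  if (all(abs(y) < .Machine$double.eps * 10)) {
    stop("degenerate (all-zero) curve")
  }
  tmax <- max(t)
  p0 <- y[which.max(t)]
  if (p0 == 0) p0 <- y[which.max(abs(y))]
  # time to reach (1 - 1/e) of the final value as a T estimate
  target <- (1 - exp(-1)) * p0
  idx <- if (p0 > 0) which(y >= target) else which(y <= target)
  T0 <- if (length(idx)) max(t[min(idx)], tmax / 100) else tmax / 3
  df <- data.frame(t = t, y = y)
  if (offset) {
    fit <- minpack.lm::nlsLM(
      y ~ pmax * (1 - exp(-t / Th)) + c0, data = df,
      start = list(pmax = p0, Th = T0, c0 = 0),
      lower = c(-Inf, 1e-9, -Inf), upper = c(Inf, 10 * tmax, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    fit <- minpack.lm::nlsLM(
      y ~ pmax * (1 - exp(-t / Th)), data = df,
      start = list(pmax = p0, Th = T0),
      lower = c(-Inf, 1e-9), upper = c(Inf, 10 * tmax),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  cf <- summary(fit)$coefficients
  res <- stats::resid(fit)
  structure(list(p_max = cf["pmax", "Estimate"],
                 T_hyp_s = cf["Th", "Estimate"],
                 se_p_max = cf["pmax", "Std. Error"],
                 se_T_hyp_s = cf["Th", "Std. Error"],
                 offset = if (offset) cf["c0", "Estimate"] else 0,
                 residual_norm = sqrt(sum(res^2)),
                 fitted = stats::fitted(fit),
                 nls = fit),
            class = "fitResult")
}

#' @export
print.fitResult <- function(x, ...) {
  cat(sprintf(
    "fitResult: p_max = %.4g +/- %.2g, T_hyp = %.4g +/- %.2g s (|r| = %.3g)\n",
    x$p_max, x$se_p_max, x$T_hyp_s, x$se_T_hyp_s, x$residual_norm))
  invisible(x)
}

#' Write a fit result as JSON
#'
#' @param fit A `fitResult`.
#' @param path Output path.
#' @return The written list, invisibly.
#' @export
writeFitJson <- function(fit, path) {
  out <- list(p_max = fit$p_max, T_hyp_s = fit$T_hyp_s,
              se_p_max = fit$se_p_max, se_T_hyp_s = fit$se_T_hyp_s,
              offset = fit$offset, residual_norm = fit$residual_norm)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(out)
}
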