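# Fitness proxies from OD600 time series: baseline correction, empirical AUC,
# logistic fits and population doublings.

#' Baseline-correct growth curves
#'
#' Shifts every curve so its minimum OD600 equals zero (per-curve min-to-zero
#' correction), preserving curve shape. Idempotent.
#'
#' @param curves a \linkS4class{GrowthCurveSet}, or a numeric OD vector.
#' @return object of the same type with corrected OD values.
#' @examples
#' baselineCorrect(c(0.1, 0.2, 0.5))
#' @export
baselineCorrect <- function(curves) {
  if (is.numeric(curves)) return(curves - min(curves))
  .stopIfNot(is(curves, "GrowthCurveSet"),
             "curves must be a GrowthCurveSet or numeric vector")
  od <- odMatrix(curves)
  od <- od - apply(od, 1L, min)
  GrowthCurveSet(curveTimes(curves), od, curveData(curves))
}

#' Trapezoidal area under the growth curve
#'
#' Computes the empirical AUC (OD600 x hours) of each curve by the trapezoid
#' rule on the observed time stamps; exact for piecewise-linear signals, no
#' resampling. Curves are expected to be baseline-corrected first.
#'
#' @param curves a \linkS4class{GrowthCurveSet} or numeric OD vector.
#' @param times time grid in hours; required for the numeric-vector form.
#' @return numeric vector of AUC values, one per curve.
#' @examples
#' aucTrapezoid(seq(0, 1, length.out = 25), times = 0:24)  # 12
#' @export
aucTrapezoid <- function(curves, times = NULL) {
  if (is.numeric(curves)) {
    .stopIfNot(!is.null(times) && length(times) == length(curves),
               "numeric form needs matching 'times'")
    .stopIfNot(length(curves) >= 2L, "curve must have >= 2 points")
    dt <- diff(times)
    return(sum(dt * (curves[-length(curves)] + curves[-1L]) / 2))
  }
  od <- odMatrix(curves)
  t <- curveTimes(curves)
  dt <- diff(t)
  mid <- (od[, -ncol(od), drop = FALSE] + od[, -1L, drop = FALSE]) / 2
  as.numeric(mid %*% dt)
}

#' Fit a logistic growth model to one curve
#'
#' Least-squares fit of the three-parameter logistic
#' \eqn{N(t) = K / (1 + ((K - N0)/N0) e^{-rt})} (carrying capacity \eqn{K},
#' growth rate \eqn{r} per hour, initial population \eqn{N0}), the standard
#' model for microplate growth curves. The fitted-curve AUC is integrated
#' numerically over the observed time range. Fit failure or a flat curve
#' yields \code{converged = FALSE} rather than an error.
#'
#' @param times time grid (hours), at least 5 points.
#' @param od OD600 values, same length.
#' @param dynamic_floor minimum OD range below which the curve is treated as
#'   non-growing (default 0.02).
#' @return list with \code{K}, \code{r}, \code{N0}, \code{auc_fit},
#'   \code{converged}.
#' @export
fitLogistic <- function(times, od, dynamic_floor = 0.02) {
  .stopIfNot(length(times) >= 5L && length(od) == length(times),
             "logistic fit needs >= 5 points")
  fail <- list(K = NA_real_, r = NA_real_, N0 = NA_real_,
               auc_fit = NA_real_, converged = FALSE)
  if (diff(range(od)) < dynamic_floor) return(fail)
  n0 <- max(od[1L], 1e-4)
  k0 <- max(od)
  half <- times[which(od >= (min(od) + k0) / 2)[1L]]
  r0 <- if (is.finite(half) && half > 0) 4 / half else 0.5
  fit <- tryCatch(
    minpack.lm::nlsLM(
      od ~ K / (1 + ((K - N0) / N0) * exp(-r * times)),
      start = list(K = k0, r = r0, N0 = n0),
      lower = c(K = 1e-6, r = 0, N0 = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  p <- coef(fit)
  grid <- seq(min(times), max(times), length.out = 2001L)
  pred <- p["K"] / (1 + ((p["K"] - p["N0"]) / p["N0"]) * exp(-p["r"] * grid))
  auc <- aucTrapezoid(pred, times = grid)
  list(K = unname(p["K"]), r = unname(p["r"]), N0 = unname(p["N0"]),
       auc_fit = auc, converged = TRUE)
}

#' Fit logistic models to every curve in a set
#'
#' @param curves a \linkS4class{GrowthCurveSet}.
#' @param dynamic_floor see \code{\link{fitLogistic}}.
#' @return data.frame with one row per curve (K, r, N0, auc_fit, converged)
#'   alongside the curve metadata.
#' @export
fitLogisticSet <- function(curves, dynamic_floor = 0.02) {
  od <- odMatrix(curves)
  t <- curveTimes(curves)
  fits <- lapply(seq_len(nrow(od)), function(i)
    fitLogistic(t, od[i, ], dynamic_floor = dynamic_floor))
  out <- cbind(as.data.frame(curveData(curves)),
               do.call(rbind, lapply(fits, as.data.frame)))
  rownames(out) <- NULL
  out
}

#' Population doublings from a growth curve
#'
#' Number of doublings \eqn{G = \log_2(\max(OD_{final}, floor) /
#' \max(OD_{initial}, floor))}, clamped at zero, computed on absolute
#' (non-baseline-corrected) OD. The floor guards against log of near-zero
#' blank readings.
#'
#' @param curves a \linkS4class{GrowthCurveSet} or numeric OD vector.
#' @param floor OD600 floor, default 0.01.
#' @return numeric vector of doublings, one per curve.
#' @examples
#' doublings(c(0.05, 0.2, 0.8))  # 4
#' @export
doublings <- function(curves, floor = 0.01) {
  .stopIfNot(floor > 0, "floor must be > 0")
  if (is.numeric(curves)) {
    g <- log2(max(curves[length(curves)], floor) / max(curves[1L], floor))
    return(max(g, 0))
  }
  od <- odMatrix(curves)
  g <- log2(pmax(od[, ncol(od)], floor) / pmax(od[, 1L], floor))
  pmax(g, 0)
}

#' Summarize growth curves
#'
#' Convenience wrapper returning, per curve, the baseline-corrected empirical
#' AUC and the number of population doublings.
#'
#' @param curves a \linkS4class{GrowthCurveSet}.
#' @param floor doublings floor, see \code{\link{doublings}}.
#' @return data.frame of curve metadata plus \code{raw_auc} and \code{G}.
#' @export
growthSummary <- function(curves, floor = 0.01) {
  out <- as.data.frame(curveData(curves))
  out$raw_auc <- aucTrapezoid(baselineCorrect(curves))
  out$G <- doublings(curves, floor = floor)
  rownames(out) <- NULL
  out
}
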