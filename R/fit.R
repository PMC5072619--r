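#' Power-law fit object
#'
#' Container for a fitted (or externally reported) subdiffusion law
#' \eqn{\mathrm{MSD}(t) = D_{app} t^\beta}.  Use [fit_power_law()] to fit an
#' MSD curve; use this constructor directly to wrap published values such as
#' the HeLa interior fit (0.018, 0.44) or the periphery fit (0.013, 0.39).
#'
#' @param d_app apparent diffusion coefficient, um^2/s^beta (> 0).
#' @param beta subdiffusion exponent.  Values outside (0, 1) trigger a
#'   warning (the subdiffusive regime is the expected one) but are stored.
#' @param d_app_stderr,beta_stderr standard errors (NA when unknown).
#' @param window fit window `c(t_min, t_max)` in seconds.
#' @param n_points number of MSD points used in the fit.
#' @param weighting `"none"` or `"sem"`.
#' @return object of class `"power_law_fit"`.
#' @examples
#' interior <- power_law_fit(0.018, 0.44)
#' periphery <- power_law_fit(0.013, 0.39)
#' @export
power_law_fit <- function(d_app, beta, d_app_stderr = NA_real_,
                          beta_stderr = NA_real_,
                          window = c(NA_real_, NA_real_),
                          n_points = NA_integer_, weighting = "none") {
  d_app <- unname(d_app)
  beta <- unname(beta)
  if (!is.numeric(d_app) || length(d_app) != 1L || is.na(d_app) || d_app <= 0) {
    stop("`d_app` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta)) {
    stop("`beta` must be a single number", call. = FALSE)
  }
  if (beta <= 0 || beta >= 1) {
    warning(sprintf("beta = %.3g is outside the subdiffusive range (0, 1)",
                    beta))
  }
  if (!is.na(window[1]) && window[1] <= 0) {
    stop("fit window must start at t > 0", call. = FALSE)
  }
  structure(
    list(d_app = d_app, beta = beta,
         d_app_stderr = d_app_stderr, beta_stderr = beta_stderr,
         window = as.numeric(window), n_points = n_points,
         weighting = weighting, data = NULL),
    class = "power_law_fit")
}

#' Fit the subdiffusion power law to an MSD curve
#'
#' Nonlinear least squares for \eqn{\mathrm{MSD}(t) = D_{app} t^\beta} on the
#' (t, MSD) points inside `window`, initialized from an ordinary linear
#' regression of log MSD on log t.  Standard errors come from the fit
#' covariance.  Weighting by the per-point SEM (weights 1/SEM^2) is optional
#' and off by default.
#'
#' @param msd an [msd_curve()] or any data frame with columns `lag_s` and
#'   `msd_um2` (and `sem_um2` when `weighting = "sem"`).
#' @param window `c(t_min, t_max)` in seconds; points with `t = 0` are always
#'   excluded.  Default 0.05 to 0.5 s, the short-time window of the tracking
#'   experiment.
#' @param weighting `"none"` (default) or `"sem"`.
#' @return a [power_law_fit()] carrying the fitted data (for [plot.power_law_fit()]
#'   and [residuals.power_law_fit()]).
#' @examples
#' t <- seq(0.05, 0.5, by = 0.05)
#' curve <- data.frame(lag_s = t, msd_um2 = 0.018 * t^0.44)
#' fit_power_law(curve)
#' @export
fit_power_law <- function(msd, window = c(0.05, 0.5),
                          weighting = c("none", "sem")) {
  weighting <- match.arg(weighting)
  if (!is.data.frame(msd) || !all(c("lag_s", "msd_um2") %in% names(msd))) {
    stop("`msd` must be a data frame with columns lag_s and msd_um2",
         call. = FALSE)
  }
  keep <- msd$lag_s > 0 & msd$lag_s >= window[1] & msd$lag_s <= window[2] &
    is.finite(msd$msd_um2)
  d <- msd[keep, , drop = FALSE]
  if (nrow(d) < 3L) {
    stop("need at least 3 MSD points with t > 0 inside the fit window",
         call. = FALSE)
  }
  if (any(d$msd_um2 <= 0)) {
    stop("non-positive MSD values inside the fit window", call. = FALSE)
  }
  w <- NULL
  if (weighting == "sem") {
    if (!"sem_um2" %in% names(d)) {
      stop("`weighting = \"sem\"` requires a sem_um2 column", call. = FALSE)
    }
    if (any(!is.finite(d$sem_um2)) || any(d$sem_um2 <= 0)) {
      stop("SEM weighting requires finite positive sem_um2 values",
           call. = FALSE)
    }
    w <- 1 / d$sem_um2^2
  }
  start_lm <- stats::lm(log(msd_um2) ~ log(lag_s), data = d)
  start <- list(D = unname(exp(stats::coef(start_lm)[1])),
                b = unname(stats::coef(start_lm)[2]))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200)
  d <- as.data.frame(d)
  fit <- if (is.null(w)) {
    minpack.lm::nlsLM(msd_um2 ~ D * lag_s^b, data = d, start = start,
                      control = ctrl)
  } else {
    d$.w <- w
    minpack.lm::nlsLM(msd_um2 ~ D * lag_s^b, data = d, start = start,
                      weights = .w, control = ctrl)
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(D = NA_real_, b = NA_real_))
  # the stored window is the effective one: t = 0 is never part of a fit
  eff_window <- c(max(window[1], min(d$lag_s)), window[2])
  out <- power_law_fit(unname(est["D"]), unname(est["b"]),
                       d_app_stderr = unname(se["D"]),
                       beta_stderr = unname(se["b"]),
                       window = eff_window, n_points = nrow(d),
                       weighting = weighting)
  out$data <- d
  out
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("Subdiffusion power-law fit: MSD(t) = D_app * t^beta\n")
  cat(sprintf("  D_app = %.4g um^2/s^beta", x$d_app))
  if (is.finite(x$d_app_stderr)) cat(sprintf(" (se %.2g)", x$d_app_stderr))
  cat(sprintf("\n  beta  = %.4g", x$beta))
  if (is.finite(x$beta_stderr)) cat(sprintf(" (se %.2g)", x$beta_stderr))
  cat("\n")
  if (!is.na(x$window[1])) {
    cat(sprintf("  window [%.3g, %.3g] s, %d points, weighting: %s\n",
                x$window[1], x$window[2], x$n_points, x$weighting))
  }
  invisible(x)
}

#' @export
coef.power_law_fit <- function(object, ...) {
  c(d_app = object$d_app, beta = object$beta)
}

#' @export
summary.power_law_fit <- function(object, ...) {
  tab <- cbind(Estimate = c(object$d_app, object$beta),
               `Std. Error` = c(object$d_app_stderr, object$beta_stderr))
  rownames(tab) <- c("d_app", "beta")
  structure(list(coefficients = tab, window = object$window,
                 n_points = object$n_points, weighting = object$weighting),
            class = "summary.power_law_fit")
}

#' @export
print.summary.power_law_fit <- function(x, ...) {
  cat("Power-law MSD fit\n")
  stats::printCoefmat(x$coefficients)
  if (!is.na(x$window[1])) {
    cat(sprintf("Fit window: [%.3g, %.3g] s; %s points; weighting: %s\n",
                x$window[1], x$window[2], x$n_points, x$weighting))
  }
  invisible(x)
}

#' @export
predict.power_law_fit <- function(object, t, ...) {
  object$d_app * t^object$beta
}

#' @export
residuals.power_law_fit <- function(object, ...) {
  if (is.null(object$data)) {
    stop("this fit carries no data (constructed from reported values)",
         call. = FALSE)
  }
  object$data$msd_um2 - predict(object, object$data$lag_s)
}

#' Plot an MSD power-law fit
#'
#' Fitted points with SEM bars (when available) and the fitted power law,
#' on log-log axes by default.
#'
#' @param x a [power_law_fit()] from [fit_power_law()].
#' @param log axes log specification passed to [plot()] (default `"xy"`).
#' @param ... further graphical parameters.
#' @export
plot.power_law_fit <- function(x, log = "xy", ...) {
  if (is.null(x$data)) {
    stop("this fit carries no data to plot", call. = FALSE)
  }
  d <- x$data
  plot(d$lag_s, d$msd_um2, log = log, xlab = "lag time (s)",
       ylab = expression(MSD ~ (mu * m^2)), pch = 19, ...)
  if ("sem_um2" %in% names(d) && any(is.finite(d$sem_um2) & d$sem_um2 > 0)) {
    graphics::arrows(d$lag_s, d$msd_um2 - d$sem_um2,
                     d$lag_s, d$msd_um2 + d$sem_um2,
                     angle = 90, code = 3, length = 0.03)
  }
  tt <- exp(seq(log(min(d$lag_s)), log(max(d$lag_s)), length.out = 100))
  graphics::lines(tt, predict(x, tt), col = "red3", lwd = 2)
  graphics::legend("topleft", bty = "n", legend = sprintf(
    "D_app = %.3g, beta = %.3g", x$d_app, x$beta))
  invisible(x)
}
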