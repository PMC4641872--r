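#' Parameters of the 2D anomalous-diffusion + triplet FCS model
#'
#' The model fitted throughout this package is the one-component,
#' two-dimensional diffusion correlation function with a single dark
#' (triplet) state and an anomaly exponent:
#'
#' \deqn{G(t_c) = G(0) \, \frac{1}{1 + (t_c/\tau_D)^\alpha}
#'   \left[1 - T + T e^{-t_c/\tau_T}\right]}
#'
#' with amplitude `G0`, average transit time `tau_D`, anomaly factor
#' `alpha` (1 for free diffusion through a Gaussian spot; below 1 for,
#' e.g., the pedestal-distorted ungated CW-STED spot), triplet fraction
#' `T` and triplet correlation time `tau_T`. Note the triplet bracket is
#' used exactly in this form, without the conventional `1/(1-T)`
#' prefactor; users converting `G0` to a molecule number must account for
#' that.
#'
#' @param G0 amplitude, dimensionless, `>= 0` (fluctuation convention:
#'   `G` decays to 0, so `G0` is the zero-lag excess above 0, not
#'   above 1).
#' @param tau_D average transit time, seconds, `> 0`.
#' @param alpha anomaly factor, dimensionless, `> 0`.
#' @param T_trip triplet fraction in `[0, 1)`.
#' @param tau_T triplet correlation time, seconds, `> 0`.
#' @return An object of class `fcs_model_params`.
#' @export
fcs_model_params <- function(G0, tau_D, alpha = 1, T_trip = 0, tau_T = 5e-6) {
  p <- list(G0 = as.numeric(G0), tau_D = as.numeric(tau_D),
            alpha = as.numeric(alpha), T_trip = as.numeric(T_trip),
            tau_T = as.numeric(tau_T))
  if (!is.finite(p$G0) || p$G0 < 0) stop("G0 must be >= 0", call. = FALSE)
  if (!is.finite(p$tau_D) || p$tau_D <= 0)
    stop("tau_D must be > 0", call. = FALSE)
  if (!is.finite(p$alpha) || p$alpha <= 0)
    stop("alpha must be > 0", call. = FALSE)
  if (!is.finite(p$T_trip) || p$T_trip < 0 || p$T_trip >= 1)
    stop("T_trip must be in [0, 1)", call. = FALSE)
  if (!is.finite(p$tau_T) || p$tau_T <= 0)
    stop("tau_T must be > 0", call. = FALSE)
  structure(p, class = "fcs_model_params")
}

#' @export
print.fcs_model_params <- function(x, ...) {
  cat(sprintf(
    "<fcs_model_params> G0=%.4g, tau_D=%.4g s, alpha=%.3f, T=%.3f, tau_T=%.3g s\n",
    x$G0, x$tau_D, x$alpha, x$T_trip, x$tau_T))
  invisible(x)
}

#' Evaluate the FCS model
#'
#' @param params an [fcs_model_params()].
#' @param t_c correlation times in seconds, all `> 0`.
#' @return G values, finite and non-negative for `T_trip < 1`.
#' @export
evaluate_model <- function(params, t_c) {
  stopifnot(inherits(params, "fcs_model_params"))
  t_c <- as.numeric(t_c)
  if (any(!is.finite(t_c)) || any(t_c <= 0))
    stop("correlation times must be positive", call. = FALSE)
  params$G0 / (1 + (t_c / params$tau_D)^params$alpha) *
    (1 - params$T_trip + params$T_trip * exp(-t_c / params$tau_T))
}

#' Counts per molecule (molecular brightness)
#'
#' The zero-lag amplitude of the fluctuation-convention FCS curve times
#' the mean count rate gives the detected photon rate per molecule,
#' `cpm = G(0) * <F>`.
#'
#' @param G0 fitted amplitude, `>= 0`.
#' @param mean_rate mean detected count rate in counts/s, `>= 0`.
#' @return cpm in counts/s.
#' @export
compute_cpm <- function(G0, mean_rate) {
  if (!is.finite(G0) || G0 < 0) stop("G0 must be >= 0", call. = FALSE)
  if (!is.finite(mean_rate) || mean_rate < 0)
    stop("mean_rate must be >= 0", call. = FALSE)
  G0 * mean_rate
}

# parameter box constraints for the bounded least-squares fit
.fit_bounds <- list(
  lower = c(G0 = 0,    tau_D = 1e-6, alpha = 0.3, T_trip = 0,    tau_T = 1e-7),
  upper = c(G0 = Inf,  tau_D = 10,   alpha = 3,   T_trip = 0.99, tau_T = 1e-3))

.param_names <- c("G0", "tau_D", "alpha", "T_trip", "tau_T")

#' Fit the FCS model to a correlation curve
#'
#' Bounded Levenberg-Marquardt least squares of the model in
#' [fcs_model_params()] against a correlation curve, restricted to a fit
#' window in correlation time (default 1 us to 200 ms). Any subset of the
#' five parameters can be held fixed; the two-stage protocol for gated
#' STED-FCS fixes the triplet parameters `T_trip` and `tau_T` at values
#' fitted to a confocal reference, leaving `G0`, `tau_D` and `alpha` free
#' in the STED stage.
#'
#' Residuals are weighted by `1/G_err` when the curve carries segment
#' errors and `weights = "auto"` (lags with zero or missing error get the
#' median weight); `weights = "none"` forces an unweighted fit.
#'
#' Initialization: `G0` from the mean G over the first decade of lags in
#' the window, `tau_D` from the first lag where G drops below half of
#' that, `alpha = 1`.
#'
#' @param curve a `correlation_curve`.
#' @param init optional [fcs_model_params()] starting point; `NULL` uses
#'   the heuristics above.
#' @param fixed named logical vector over
#'   `c("G0","tau_D","alpha","T_trip","tau_T")`; `TRUE` entries are held
#'   at their `init` value. Default: all free.
#' @param window fit window `c(t_min, t_max)` in seconds.
#' @param weights `"auto"` or `"none"`.
#' @param qc_bounds open interval on the fitted anomaly factor used for
#'   the quality verdict (default `(0.8, 1.2)`).
#' @return An `fcs_fit_result`: `params`, `fixed`, `param_errors` (1-sigma,
#'   NA for fixed parameters), `fit_window`, `chi2_reduced`, `cpm`,
#'   `mean_rate`, `qc_pass`, `converged`, `message`, `n_lags`.
#' @export
fit_fcs <- function(curve, init = NULL, fixed = NULL,
                    window = c(1e-6, 0.2), weights = c("auto", "none"),
                    qc_bounds = c(0.8, 1.2)) {
  stopifnot(inherits(curve, "correlation_curve"))
  weights <- match.arg(weights)
  if (length(window) != 2 || window[1] <= 0 || window[1] >= window[2])
    stop("window must be c(t_min, t_max) with 0 < t_min < t_max",
         call. = FALSE)
  if (!length(curve$lags_s))
    stop("cannot fit an empty correlation curve", call. = FALSE)
  if (window[1] > max(curve$lags_s) || window[2] < min(curve$lags_s))
    stop("fit window lies outside the curve's lag range", call. = FALSE)

  sel <- curve$lags_s >= window[1] & curve$lags_s <= window[2] &
    is.finite(curve$G)
  t_c <- curve$lags_s[sel]
  G <- curve$G[sel]
  if (length(t_c) < 8)
    stop("need at least 8 finite lags inside the fit window", call. = FALSE)

  w <- rep(1, length(t_c))
  if (weights == "auto" && any(is.finite(curve$G_err[sel]) &
                               curve$G_err[sel] > 0)) {
    e <- curve$G_err[sel]
    ok <- is.finite(e) & e > 0
    w[ok] <- 1 / e[ok]
    w[!ok] <- stats::median(w[ok])
  }

  fx <- stats::setNames(rep(FALSE, 5), .param_names)
  if (!is.null(fixed)) {
    if (is.null(names(fixed)) || !all(names(fixed) %in% .param_names))
      stop("'fixed' must be a named logical over the model parameters",
           call. = FALSE)
    fx[names(fixed)] <- as.logical(fixed)
  }

  if (is.null(init)) init <- .init_heuristic(t_c, G)
  stopifnot(inherits(init, "fcs_model_params"))
  full0 <- unlist(init[.param_names])

  degenerate <- max(abs(G)) < 1e-12
  if (degenerate || all(fx)) {
    pars <- init
    if (degenerate) pars$G0 <- 0
    return(.finish_fit(pars, fx, rep(NA_real_, 5), window, t_c, G, w, curve,
                       qc_bounds,
                       converged = FALSE,
                       message = if (degenerate)
                         "degenerate curve (all ~0): tau_D unidentifiable"
                       else "all parameters fixed; nothing to fit"))
  }

  free <- !fx
  resid_fn <- function(theta) {
    full <- full0
    full[free] <- theta
    (G - .eval_raw(full, t_c)) * w
  }
  lower <- .fit_bounds$lower[free]
  upper <- .fit_bounds$upper[free]
  start <- pmin(pmax(full0[free], lower), pmax(lower, pmin(upper, 1e6)))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-12, ptol = 1e-12, gtol = 0,
                         maxfev = 5000, maxiter = 1000)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(.finish_fit(init, fx, rep(NA_real_, 5), window, t_c, G, w, curve,
                       qc_bounds, converged = FALSE,
                       message = paste("optimizer error:",
                                       conditionMessage(fit))))
  }
  # no uphill returns: keep whichever of start/fit has the lower cost
  cost_fit <- sum(resid_fn(fit$par)^2)
  cost_init <- sum(resid_fn(start)^2)
  theta <- if (cost_fit <= cost_init) fit$par else start
  full <- full0
  full[free] <- theta
  pars <- fcs_model_params(full[["G0"]], full[["tau_D"]], full[["alpha"]],
                           full[["T_trip"]], full[["tau_T"]])

  perr <- rep(NA_real_, 5)
  names(perr) <- .param_names
  se <- tryCatch({
    sm <- summary(fit)
    sm$coefficients[, "Std. Error"]
  }, error = function(e) NULL)
  if (!is.null(se) && cost_fit <= cost_init) perr[free] <- se

  converged <- fit$info %in% 1:4 && cost_fit <= cost_init
  .finish_fit(pars, fx, perr, window, t_c, G, w, curve, qc_bounds,
              converged = converged,
              message = if (converged) "" else fit$message)
}

.eval_raw <- function(full, t_c) {
  full[["G0"]] / (1 + (t_c / full[["tau_D"]])^full[["alpha"]]) *
    (1 - full[["T_trip"]] + full[["T_trip"]] * exp(-t_c / full[["tau_T"]]))
}

.init_heuristic <- function(t_c, G) {
  first_decade <- t_c <= min(t_c) * 10
  G0 <- max(mean(G[first_decade]), 1e-6)
  below <- which(G < G0 / 2)
  tau_D <- if (length(below)) t_c[below[1]] else max(t_c) / 2
  tau_D <- min(max(tau_D, .fit_bounds$lower[["tau_D"]]),
               .fit_bounds$upper[["tau_D"]])
  fcs_model_params(G0 = G0, tau_D = tau_D, alpha = 1, T_trip = 0,
                   tau_T = 5e-6)
}

.finish_fit <- function(pars, fx, perr, window, t_c, G, w, curve, qc_bounds,
                        converged, message) {
  full <- unlist(pars[.param_names])
  resid <- (G - .eval_raw(full, t_c)) * w
  dof <- max(length(t_c) - sum(!fx), 1)
  structure(list(
    params = pars,
    fixed = fx,
    param_errors = stats::setNames(perr, .param_names),
    fit_window = window,
    chi2_reduced = sum(resid^2) / dof,
    cpm = compute_cpm(pars$G0, curve$mean_rate),
    mean_rate = curve$mean_rate,
    qc_pass = isTRUE(pars$alpha > qc_bounds[1] && pars$alpha < qc_bounds[2] &&
                     converged),
    qc_bounds = qc_bounds,
    converged = converged,
    message = message,
    n_lags = length(t_c)
  ), class = "fcs_fit_result")
}

#' @export
print.fcs_fit_result <- function(x, ...) {
  cat(sprintf(
    paste0("<fcs_fit_result> G0=%.4g, tau_D=%.4g s, alpha=%.3f",
           " (T=%.3f%s, tau_T=%.3g s%s)\n  cpm=%.4g kHz, chi2_red=%.3g,",
           " qc_pass=%s%s\n"),
    x$params$G0, x$params$tau_D, x$params$alpha,
    x$params$T_trip, if (x$fixed[["T_trip"]]) " fixed" else "",
    x$params$tau_T, if (x$fixed[["tau_T"]]) " fixed" else "",
    x$cpm / 1e3, x$chi2_reduced, x$qc_pass,
    if (x$converged) "" else paste0("\n  NOT converged: ", x$message)))
  invisible(x)
}

#' Retain fits with a credible anomaly factor
#'
#' Applies the strict open window on the fitted anomaly factor used as a
#' quality filter for free-diffusion data: fits with
#' `lo < alpha < hi` (default `0.8 < alpha < 1.2`) are retained, all
#' others dropped. Order is preserved.
#'
#' @param results list of `fcs_fit_result`.
#' @param bounds numeric `c(lo, hi)`, strict bounds.
#' @return The retained sub-list.
#' @export
qc_filter <- function(results, bounds = c(0.8, 1.2)) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  keep <- vapply(results, function(r) {
    stopifnot(inherits(r, "fcs_fit_result"))
    a <- r$params$alpha
    is.finite(a) && a > bounds[1] && a < bounds[2]
  }, logical(1))
  results[keep]
}

#' Tabulate fit results
#'
#' One row per fit with all parameters, their uncertainties, fixed flags,
#' cpm, reduced chi-square and the QC verdict; ready for CSV export.
#'
#' @param results list of `fcs_fit_result`.
#' @return A data.frame.
#' @export
fit_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      G0 = r$params$G0, tau_D_s = r$params$tau_D, alpha = r$params$alpha,
      T_trip = r$params$T_trip, tau_T_s = r$params$tau_T,
      G0_err = r$param_errors[["G0"]], tau_D_err = r$param_errors[["tau_D"]],
      alpha_err = r$param_errors[["alpha"]],
      fixed_T = r$fixed[["T_trip"]], fixed_tau_T = r$fixed[["tau_T"]],
      cpm_hz = r$cpm, mean_rate_hz = r$mean_rate,
      chi2_reduced = r$chi2_reduced, converged = r$converged,
      qc_pass = r$qc_pass, row.names = NULL)
  }))
}
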