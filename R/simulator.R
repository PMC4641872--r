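#' Configuration of a synthetic gated STED-FCS measurement
#'
#' Defines a Brownian-dynamics + photophysics experiment: labelled lipids
#' diffusing in a 2D periodic box, observed through a Gaussian excitation
#' spot under pulsed excitation, with an optional continuous-wave
#' depletion doughnut that raises the total excited-state decay rate in
#' the periphery (shortening the fluorescence lifetime there, which is
#' what microtime gating exploits), plus triplet blinking, photobleaching
#' with re-insertion, uncorrelated background, and an optional Gaussian
#' instrument response.
#'
#' Defaults mirror a typical supported-lipid-bilayer calibration
#' measurement: DOPC-like free diffusion at 5 um^2/s, 80 MHz pulsed
#' excitation, a 240 nm FWHM confocal spot (1/e^2 radius 204 nm) and a
#' 3.5 ns fluorescence lifetime.
#'
#' @param D diffusion coefficient, um^2/s.
#' @param n_molecules number of molecules kept in the box (constant).
#'   The default with `box_um = 6` gives ~5.6 molecules/um^2, a typical
#'   dilute labelling density for SLB calibration measurements.
#' @param box_um side of the periodic square box, um; must be at least
#'   10 excitation waists. Because the molecule number is fixed (closed
#'   box), occupancy is slightly anti-correlated at long lag (offset
#'   about `-G0 * pi w^2 / L^2`); the box must be large enough that this
#'   stays far below the model tail over the fit window.
#' @param duration_s acquisition length, seconds.
#' @param rep_rate_hz excitation repetition rate, Hz.
#' @param exc_waist_nm 1/e^2 radius of the Gaussian excitation profile,
#'   nm (204 nm gives a 240 nm FWHM).
#' @param exc_prob_peak per-pulse excitation probability on the optical
#'   axis, in (0, 1]; the excitation-power proxy.
#' @param tau_fl_ns spontaneous fluorescence lifetime, ns
#'   (`k_fl = 1/tau_fl_ns`).
#' @param zeta peak stimulated-decay rate over `k_fl`, dimensionless;
#'   the depletion-power proxy (0 = confocal). `zeta` is proportional to
#'   the depletion power; the mW-to-zeta map is instrument-specific.
#' @param sted_waist_nm scale of the depletion doughnut
#'   `d(r) = (2 e r^2/w_d^2) exp(-2 r^2/w_d^2)` (peak 1 at
#'   `r = w_d/sqrt(2)`, exact zero on axis), nm.
#' @param detection_efficiency probability that a spontaneously emitted
#'   photon is detected, in (0, 1].
#' @param isc_prob per-excitation probability of crossing to the dark
#'   (triplet) state; 0 disables blinking.
#' @param tau_dark_s mean dark dwell, seconds.
#' @param bleach_prob per-excitation photobleaching probability; a
#'   bleached molecule is replaced by a fresh one at a uniformly random
#'   position (stationary concentration).
#' @param background_rate uncorrelated background, counts/s, uniform in
#'   microtime.
#' @param irf_sigma_ns Gaussian IRF jitter added to microtimes, ns;
#'   0 disables.
#' @param timestep_s Brownian position-update interval, seconds
#'   (positions are frozen between updates); must be at most a hundredth
#'   of the expected confocal transit time.
#' @param seed integer RNG seed; identical configs give identical
#'   streams.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(D = 5, n_molecules = 200, box_um = 6,
                              duration_s = 10, rep_rate_hz = 8e7,
                              exc_waist_nm = 204, exc_prob_peak = 0.01,
                              tau_fl_ns = 3.5, zeta = 0,
                              sted_waist_nm = 300,
                              detection_efficiency = 0.5,
                              isc_prob = 0, tau_dark_s = 5e-6,
                              bleach_prob = 0, background_rate = 0,
                              irf_sigma_ns = 0, timestep_s = 2e-6,
                              seed = 1) {
  cfg <- structure(as.list(environment()), class = "simulation_config")
  validate_simulation_config(cfg)
}

#' Validate a simulation configuration
#' @param cfg a `simulation_config`.
#' @return `cfg` invisibly, or an error naming the violated constraint.
#' @export
validate_simulation_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  chk(cfg$D > 0, "D must be positive")
  chk(cfg$n_molecules >= 1, "need at least one molecule")
  chk(cfg$box_um >= 10 * cfg$exc_waist_nm / 1000,
      "box_um must be at least 10 excitation waists")
  chk(cfg$duration_s > 0, "duration_s must be positive")
  chk(cfg$rep_rate_hz > 0, "rep_rate_hz must be positive")
  chk(cfg$exc_prob_peak >= 0 && cfg$exc_prob_peak <= 1,
      "exc_prob_peak must be in [0, 1]")
  chk(cfg$tau_fl_ns > 0, "tau_fl_ns must be positive")
  chk(cfg$zeta >= 0, "zeta must be non-negative")
  chk(cfg$sted_waist_nm > 0, "sted_waist_nm must be positive")
  chk(cfg$detection_efficiency > 0 && cfg$detection_efficiency <= 1,
      "detection_efficiency must be in (0, 1]")
  chk(cfg$isc_prob >= 0 && cfg$isc_prob < 1, "isc_prob must be in [0, 1)")
  chk(cfg$tau_dark_s > 0, "tau_dark_s must be positive")
  chk(cfg$bleach_prob >= 0 && cfg$bleach_prob < 1,
      "bleach_prob must be in [0, 1)")
  chk(cfg$background_rate >= 0, "background_rate must be non-negative")
  chk(cfg$irf_sigma_ns >= 0, "irf_sigma_ns must be non-negative")
  tau_D_expected <- (cfg$exc_waist_nm / 1000)^2 / (4 * cfg$D)
  chk(cfg$timestep_s > 0 && cfg$timestep_s <= tau_D_expected / 100,
      sprintf("timestep_s must be <= expected transit time / 100 (%.3g s)",
              tau_D_expected / 100))
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    paste0("<simulation_config> D=%.3g um^2/s, %d molecules, %.3g um box,",
           " %.3g s\n  exc: waist %.0f nm, p0=%.3g @ %.3g MHz;",
           " tau_fl=%.3g ns; zeta=%.3g (w_d=%.0f nm)\n",
           "  det_eff=%.2g, isc=%.3g, bleach=%.2g, bg=%.3g /s, seed=%d\n"),
    x$D, x$n_molecules, x$box_um, x$duration_s, x$exc_waist_nm,
    x$exc_prob_peak, x$rep_rate_hz / 1e6, x$tau_fl_ns, x$zeta,
    x$sted_waist_nm, x$detection_efficiency, x$isc_prob, x$bleach_prob,
    x$background_rate, as.integer(x$seed)))
  invisible(x)
}

#' Simulate a TCSPC photon stream
#'
#' Runs the Brownian-dynamics / photophysics model of
#' [simulation_config()] and returns the detected photon stream together
#' with a ground-truth record (the config plus analytic expectations:
#' the expected confocal transit time `w^2/(4D)`, the effective-spot
#' FWHM from [effective_spot_profile()], the expected molecular
#' brightness and the bleaching tally). Deterministic given
#' `config$seed`.
#'
#' @param config a `simulation_config`.
#' @return A `photon_stream` with attribute `"ground_truth"` (also
#'   retrievable via [ground_truth()]).
#' @export
simulate_photon_stream <- function(config) {
  validate_simulation_config(config)
  res <- .simulate_stream_cpp(
    config$D, as.integer(config$n_molecules), config$box_um,
    config$duration_s, config$rep_rate_hz, config$exc_waist_nm / 1000,
    config$exc_prob_peak, 1 / config$tau_fl_ns, config$zeta,
    config$sted_waist_nm / 1000, config$detection_efficiency,
    config$isc_prob, config$tau_dark_s, config$bleach_prob,
    config$background_rate, config$irf_sigma_ns, config$timestep_s,
    as.numeric(config$seed))
  if (!length(res$macro_ticks))
    warning("simulation produced zero photons", call. = FALSE)
  stream <- photon_stream(
    macro_ticks = res$macro_ticks, microtimes_ns = res$microtimes_ns,
    rep_rate_hz = config$rep_rate_hz, duration_s = config$duration_s,
    tick_s = res$tick_s,
    label = sprintf("sim seed=%d zeta=%.3g", as.integer(config$seed),
                    config$zeta))
  w_um <- config$exc_waist_nm / 1000
  gt <- list(
    config = config,
    tau_D_confocal_s = w_um^2 / (4 * config$D),
    fwhm_confocal_nm = config$exc_waist_nm * sqrt(2 * log(2)),
    cpm_expected_hz = config$rep_rate_hz * config$exc_prob_peak *
      config$detection_efficiency / 2,
    n_bleached = res$n_bleached,
    n_background = res$n_background)
  attr(stream, "ground_truth") <- gt
  stream
}

#' Ground-truth record of a simulated stream
#' @param stream a `photon_stream` produced by [simulate_photon_stream()].
#' @return The ground-truth list, or `NULL` for experimental streams.
#' @export
ground_truth <- function(stream) attr(stream, "ground_truth")

#' Effective observation-spot profile and FWHM (analytic ground truth)
#'
#' Computes the radial detection profile of the (optionally gated)
#' effective observation spot, independently of any simulation run:
#'
#' \deqn{\eta(r) = p(r)\,\frac{k_{fl}}{k_{tot}(r)}\,
#'   \frac{e^{-k_{tot}(r) t_1} - e^{-k_{tot}(r) t_2}}
#'        {1 - e^{-k_{tot}(r) P}}}
#'
#' i.e. excitation probability times the spontaneous branching ratio
#' times the probability that the (period-wrapped) microtime falls in
#' the gate `[t_1, t_2)`; `P` is the excitation period. Without STED
#' (`zeta = 0`) the decay rate is position independent, so gating scales
#' the profile but cannot change its shape; with STED the slow-decaying
#' centre is favoured and the ungated pedestal is suppressed. The FWHM
#' is located by bisection on `eta(r) = eta(0)/2`.
#'
#' @param config a `simulation_config`.
#' @param gate a [gate_window()] or `NULL` for ungated detection.
#' @param r_max_nm outer radius of the evaluation grid (default: half
#'   the box).
#' @param n_r grid size.
#' @return A list: data.frame `profile` (`r_nm`, `eta` normalized to 1
#'   on axis) and `fwhm_nm`.
#' @export
effective_spot_profile <- function(config, gate = NULL, r_max_nm = NULL,
                                   n_r = 4096) {
  validate_simulation_config(config)
  period <- excitation_period_ns(config$rep_rate_hz)
  if (is.null(gate)) gate <- gate_window(0, period, period)
  if (is.null(r_max_nm)) r_max_nm <- config$box_um * 500
  eta_fn <- function(r_nm) {
    k_tot <- .k_tot_ns(config, r_nm)
    p_exc <- exp(-2 * r_nm^2 / config$exc_waist_nm^2)
    gate_frac <- (exp(-k_tot * gate$t_start) - exp(-k_tot * gate$t_end)) /
      (1 - exp(-k_tot * period))
    p_exc * (1 / (config$tau_fl_ns * k_tot)) * gate_frac
  }
  eta0 <- eta_fn(0)
  r <- seq(0, r_max_nm, length.out = n_r)
  eta <- eta_fn(r) / eta0
  # bisection for the first half-maximum crossing
  above <- eta >= 0.5
  if (all(above)) {
    fwhm <- NA_real_
  } else {
    i <- which(!above)[1]
    lo <- r[i - 1]; hi <- r[i]
    f <- function(x) eta_fn(x) / eta0 - 0.5
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    fwhm <- lo + hi  # 2 * half-width-at-half-maximum radius
  }
  list(profile = data.frame(r_nm = r, eta = eta), fwhm_nm = fwhm)
}

# total excited-state decay rate (1/ns) at radius r_nm
.k_tot_ns <- function(config, r_nm) {
  k_fl <- 1 / config$tau_fl_ns
  d <- (2 * exp(1) * r_nm^2 / config$sted_waist_nm^2) *
    exp(-2 * r_nm^2 / config$sted_waist_nm^2)
  k_fl * (1 + config$zeta * d)
}

#' Microtime mixture density of a simulated configuration
#'
#' Analytic density of detected microtimes for a config: a mixture of
#' period-wrapped exponentials over molecule radii, weighted by the
#' local excitation probability and spontaneous branching ratio. Used as
#' the quadrature oracle against which the simulator's photon microtimes
#' are checked (and by gate-selection what-if analysis). Background
#' contributes a uniform component if `background_rate > 0` and
#' `signal_rate` is supplied.
#'
#' @param config a `simulation_config`.
#' @param t_ns evaluation points in `[0, period)`.
#' @param n_r radial quadrature size.
#' @return Density values (integrating to 1 over the period).
#' @export
microtime_density <- function(config, t_ns, n_r = 4000) {
  validate_simulation_config(config)
  period <- excitation_period_ns(config$rep_rate_hz)
  r <- seq(0, config$box_um * 500, length.out = n_r)
  k <- .k_tot_ns(config, r)
  w <- r * exp(-2 * r^2 / config$exc_waist_nm^2) / (config$tau_fl_ns * k)
  w <- w / sum(w)
  dens <- vapply(t_ns, function(t) {
    sum(w * k * exp(-k * t) / (1 - exp(-k * period)))
  }, numeric(1))
  dens
}

#' Named, seeded fixture suites mirroring the standard experiment designs
#'
#' Generates configuration sets for the measurement series a gated
#' STED-FCS study runs: a confocal reference, a CW-STED acquisition, an
#' excitation-power series (triplet enabled, three repetitions per
#' power, for the brightness/bleaching screen), a gate-scan acquisition
#' with the graded gate template of [default_gate_scan()], and a
#' photobleaching series. Durations default to 10 s per measurement with
#' 3 repetitions per condition.
#'
#' @param kind one of `"confocal"`, `"cw_sted"`, `"power_series"`,
#'   `"gate_scan"`, `"bleach_series"`.
#' @param seed base seed; replicate r of condition c uses
#'   `seed + 1000*c + r`.
#' @param duration_s measurement duration (default 10 s).
#' @param n_rep repetitions per condition (default 3).
#' @param simulate also run the simulator and attach streams.
#' @return A list with `kind`, `configs` (list of `simulation_config`),
#'   per-config `condition` labels, `gates` (gate-scan template, where
#'   applicable) and, if `simulate = TRUE`, `streams`.
#' @export
make_fixture_suite <- function(kind = c("confocal", "cw_sted",
                                        "power_series", "gate_scan",
                                        "bleach_series"),
                               seed = 1, duration_s = 10, n_rep = 3,
                               simulate = FALSE) {
  kind <- match.arg(kind)
  base <- function(cond, rep, ...) {
    simulation_config(duration_s = duration_s,
                      seed = seed + 1000 * cond + rep, ...)
  }
  configs <- list(); condition <- character(0); gates <- NULL
  if (kind == "confocal") {
    for (r in seq_len(n_rep)) {
      configs <- c(configs, list(base(1, r, zeta = 0)))
      condition <- c(condition, "confocal")
    }
  } else if (kind == "cw_sted") {
    for (r in seq_len(n_rep)) {
      configs <- c(configs, list(base(1, r, zeta = 20)))
      condition <- c(condition, "zeta=20")
    }
  } else if (kind == "power_series") {
    p_grid <- c(0.0025, 0.005, 0.01, 0.02, 0.04, 0.08)
    for (ci in seq_along(p_grid)) for (r in seq_len(n_rep)) {
      configs <- c(configs, list(base(ci, r, exc_prob_peak = p_grid[ci],
                                      isc_prob = 0.02,
                                      bleach_prob = 2e-6)))
      condition <- c(condition, sprintf("p_exc=%g", p_grid[ci]))
    }
  } else if (kind == "gate_scan") {
    gates <- default_gate_scan()
    configs <- list(base(1, 1, zeta = 20))
    condition <- "zeta=20 gate scan"
  } else if (kind == "bleach_series") {
    # high-power screen: strong excitation with attenuated detection
    # (photobleaching depends on excitation only; detection merely
    # scales the photon count), same seed across bleach levels per
    # replicate for a paired comparison
    b_grid <- c(0, 1e-6, 1e-5, 1e-4)
    for (ci in seq_along(b_grid)) for (r in seq_len(n_rep)) {
      configs <- c(configs, list(
        simulation_config(duration_s = duration_s, seed = seed + r,
                          exc_prob_peak = 0.4,
                          detection_efficiency = 0.05,
                          bleach_prob = b_grid[ci])))
      condition <- c(condition, sprintf("bleach=%g", b_grid[ci]))
    }
  }
  out <- list(kind = kind, configs = configs, condition = condition,
              gates = gates)
  if (simulate)
    out$streams <- lapply(configs, simulate_photon_stream)
  out
}
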