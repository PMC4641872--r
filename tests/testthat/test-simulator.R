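test_that("config invariants are enforced", {
  expect_error(simulation_config(D = -1), "D must")
  expect_error(simulation_config(box_um = 1), "10 excitation waists")
  expect_error(simulation_config(exc_prob_peak = 2), "exc_prob_peak")
  expect_error(simulation_config(timestep_s = 1e-3), "timestep")
  expect_error(simulation_config(detection_efficiency = 0), "detection")
})

test_that("identical seeds give identical streams; seeds matter", {
  cfg <- simulation_config(duration_s = 0.2, seed = 42)
  a <- simulate_photon_stream(cfg)
  b <- simulate_photon_stream(cfg)
  expect_identical(a$macro_ticks, b$macro_ticks)
  expect_identical(a$microtimes_ns, b$microtimes_ns)
  cfg2 <- simulation_config(duration_s = 0.2, seed = 43)
  c_ <- simulate_photon_stream(cfg2)
  expect_false(identical(a$macro_ticks, c_$macro_ticks))
})

test_that("zero excitation yields only background photons", {
  cfg <- simulation_config(duration_s = 0.5, exc_prob_peak = 0,
                           background_rate = 2000, seed = 5)
  st <- simulate_photon_stream(cfg)
  expect_equal(n_photons(st), ground_truth(st)$n_background)
  expect_gt(n_photons(st), 500)
  # background microtimes are uniform over the period
  expect_gt(ks.test(st$microtimes_ns, "punif", 0, 12.5)$p.value, 0.01)

  silent <- simulation_config(duration_s = 0.05, exc_prob_peak = 0,
                              background_rate = 0, seed = 5)
  expect_warning(st0 <- simulate_photon_stream(silent), "zero photons")
  expect_equal(n_photons(st0), 0L)
})

test_that("without STED the microtimes are exponential at every radius", {
  cfg <- simulation_config(duration_s = 0.5, zeta = 0, seed = 6)
  st <- simulate_photon_stream(cfg)
  m <- st$microtimes_ns
  # wrapped exponential CDF on [0, period)
  tau <- cfg$tau_fl_ns; P <- 12.5
  pwexp <- function(q) (1 - exp(-q / tau)) / (1 - exp(-P / tau))
  expect_gt(ks.test(m, pwexp)$p.value, 0.01)
})

test_that("with STED the microtime mixture matches the quadrature oracle", {
  cfg <- simulation_config(duration_s = 10, zeta = 20, seed = 7)
  st <- simulate_photon_stream(cfg)
  expect_gt(n_photons(st), 1e5)
  tgrid <- seq(0, 12.5, length.out = 5001)
  dens <- microtime_density(cfg, tgrid)
  dt <- diff(tgrid[1:2])
  cdf <- c(0, cumsum((head(dens, -1) + dens[-1]) / 2 * dt))  # trapezoid
  cdf <- cdf / cdf[length(cdf)]
  Fm <- approxfun(tgrid, cdf, yleft = 0, yright = 1)
  # photons arrive in bursts (one transit shares a radius and hence a
  # decay rate), so an iid KS p-value would be anti-conservative; the
  # check is the KS *distance* against a 1% absolute band instead
  D <- max(abs(ecdf(st$microtimes_ns)(tgrid) - cdf))
  expect_lt(D, 0.01)
  # and the mean microtime agrees with the mixture expectation
  mean_theor <- sum((head(tgrid, -1) + dt / 2) *
                    (head(dens, -1) + dens[-1]) / 2 * dt) /
    sum((head(dens, -1) + dens[-1]) / 2 * dt)
  expect_equal(mean(st$microtimes_ns), mean_theor, tolerance = 0.03)
})

test_that("STED shortens the mean microtime; gating favours the centre", {
  cfg0 <- simulation_config(duration_s = 0.5, zeta = 0, seed = 8)
  cfg1 <- simulation_config(duration_s = 0.5, zeta = 20, seed = 8)
  m0 <- simulate_photon_stream(cfg0)$microtimes_ns
  m1 <- simulate_photon_stream(cfg1)$microtimes_ns
  expect_lt(mean(m1), mean(m0))
})

test_that("fitted transit time matches the 2D closed form w^2/(4D)", {
  cfg <- simulation_config(duration_s = 10, seed = 9)
  st <- simulate_photon_stream(cfg)
  f <- fit_fcs(correlate(st), fixed = c(T_trip = TRUE, tau_T = TRUE))
  expected <- (cfg$exc_waist_nm / 1000)^2 / (4 * cfg$D)
  expect_equal(f$params$tau_D, expected, tolerance = 0.15)
  expect_equal(ground_truth(st)$tau_D_confocal_s, expected)
})

test_that("effective spot: confocal FWHM is the Gaussian closed form", {
  cfg <- simulation_config(zeta = 0)
  esp <- effective_spot_profile(cfg)
  expect_equal(esp$fwhm_nm, cfg$exc_waist_nm * sqrt(2 * log(2)),
               tolerance = 1e-6)
  # gating cannot change the spot when the decay rate is uniform
  esp_g <- effective_spot_profile(cfg, gate_window(2.4, 6.4))
  expect_equal(esp_g$fwhm_nm, esp$fwhm_nm, tolerance = 1e-9)
})

test_that("effective spot: gating shrinks the CW-STED spot", {
  cfg <- simulation_config(zeta = 20)
  ungated <- effective_spot_profile(cfg)
  gated <- effective_spot_profile(cfg, gate_window(2.4, 6.4))
  expect_lt(gated$fwhm_nm, ungated$fwhm_nm)
  expect_lt(ungated$fwhm_nm, 240 * sqrt(2 * log(2)) / sqrt(2))
})

test_that("ungated CW-STED spot has a pedestal (heavier than Gaussian)", {
  cfg <- simulation_config(zeta = 20)
  esp <- effective_spot_profile(cfg)
  prof <- esp$profile
  # Gaussian with the same FWHM would be exp(-4 ln2 r^2 / fwhm^2):
  sigma_like <- esp$fwhm_nm
  gauss <- exp(-4 * log(2) * prof$r_nm^2 / sigma_like^2)
  mid <- prof$r_nm > sigma_like & prof$r_nm < 4 * sigma_like
  expect_true(all(prof$eta[mid] > gauss[mid]))
  # and the gated profile suppresses that pedestal
  gated <- effective_spot_profile(cfg, gate_window(2.4, 6.4))
  sel <- prof$r_nm > 100 & prof$r_nm < 300
  expect_true(all(gated$profile$eta[sel] < prof$eta[sel]))
})

test_that("triplet blinking saturates the molecular brightness", {
  # cpm here is the time-averaged brightness: amplitude of the diffusion
  # part of the curve (fit past the triplet correlation time, T fixed 0)
  # times the mean rate.  Dark-state dwell dims it at high excitation.
  base <- list(duration_s = 4, n_molecules = 50, seed = 10)
  cpm_at <- function(p0, isc) {
    cfg <- do.call(simulation_config,
                   c(base, list(exc_prob_peak = p0, isc_prob = isc)))
    st <- simulate_photon_stream(cfg)
    f <- fit_fcs(correlate(st), window = c(5e-5, 0.2),
                 fixed = c(alpha = TRUE, T_trip = TRUE, tau_T = TRUE))
    f$cpm
  }
  # brightness saturates: cpm per unit excitation drops at high power
  lo <- cpm_at(0.005, 0.05)
  hi <- cpm_at(0.08, 0.05)
  expect_lt(hi / 0.08, lo / 0.005 * 0.9)
})

test_that("bleaching tally grows with the bleach probability", {
  mk <- function(b) {
    cfg <- simulation_config(duration_s = 1, n_molecules = 50,
                             bleach_prob = b, seed = 11)
    ground_truth(simulate_photon_stream(cfg))$n_bleached
  }
  counts <- vapply(c(0, 1e-4, 1e-2), mk, numeric(1))
  expect_equal(counts[1], 0)
  expect_true(all(diff(counts) > 0))
})

test_that("fixture suites have the documented structure", {
  ps <- make_fixture_suite("power_series", seed = 3, duration_s = 1)
  expect_equal(length(ps$configs), 18L)   # 6 powers x 3 repetitions
  expect_equal(length(unique(ps$condition)), 6L)
  seeds <- vapply(ps$configs, function(c) c$seed, numeric(1))
  expect_equal(length(unique(seeds)), 18L)

  gs <- make_fixture_suite("gate_scan", seed = 3, duration_s = 1)
  expect_equal(length(gs$gates), 7L)
  expect_equal(gs$gates[[1]]$t_start, 1.12)
  expect_equal(gs$configs[[1]]$zeta, 20)

  cf <- make_fixture_suite("confocal", seed = 3, duration_s = 1)
  expect_true(all(vapply(cf$configs, function(c) c$zeta, numeric(1)) == 0))

  bl <- make_fixture_suite("bleach_series", seed = 3, duration_s = 1)
  bp <- vapply(bl$configs, function(c) c$bleach_prob, numeric(1))
  expect_equal(sort(unique(bp)), c(0, 1e-6, 1e-5, 1e-4))
  # replicate seeds are shared across bleach levels (paired design)
  sd1 <- vapply(bl$configs[bp == 0], function(c) c$seed, numeric(1))
  sd2 <- vapply(bl$configs[bp == 1e-4], function(c) c$seed, numeric(1))
  expect_identical(sd1, sd2)
})
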