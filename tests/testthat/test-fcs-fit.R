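test_that("model evaluation matches hand-computed values", {
  p <- fcs_model_params(G0 = 1, tau_D = 1e-3, alpha = 1, T_trip = 0)
  expect_equal(evaluate_model(p, 1e-3), 0.5)
  expect_equal(evaluate_model(p, 1e-6), 1 / 1.001, tolerance = 1e-12)

  pt <- fcs_model_params(G0 = 1, tau_D = 1e-3, alpha = 1, T_trip = 0.5,
                         tau_T = 1e-5)
  # at t = 1 ms the triplet term is 0.5 + 0.5 e^-100 ~ 0.5
  expect_equal(evaluate_model(pt, 1e-3), 0.25, tolerance = 1e-6)

  expect_error(evaluate_model(p, 0), "positive")
  expect_error(evaluate_model(p, c(1e-3, -1)), "positive")
})

test_that("model is monotone decreasing without triplet, G -> G0 at 0+", {
  p <- fcs_model_params(G0 = 0.7, tau_D = 2e-3, alpha = 0.85)
  t <- 10^seq(-7, 0, length.out = 200)
  g <- evaluate_model(p, t)
  expect_true(all(diff(g) < 0))
  expect_equal(evaluate_model(p, 1e-12), 0.7, tolerance = 1e-6)
  expect_true(all(g >= 0))
})

test_that("parameter containers validate ranges", {
  expect_error(fcs_model_params(-1, 1e-3), "G0")
  expect_error(fcs_model_params(1, 0), "tau_D")
  expect_error(fcs_model_params(1, 1e-3, alpha = 0), "alpha")
  expect_error(fcs_model_params(1, 1e-3, T_trip = 1), "T_trip")
})

make_noiseless_curve <- function(params, n = 200, t_min = 1e-6,
                                 t_max = 0.19) {
  lags <- 10^seq(log10(t_min), log10(t_max), length.out = n)
  structure(list(lags_s = lags, G = evaluate_model(params, lags),
                 G_err = rep(NA_real_, n), n_pairs = rep(1e6, n),
                 lag_ticks = lags / 1.25e-8, coarsening = rep(1, n),
                 mean_rate = 1e5, duration_s = 10, n_photons = 1e6,
                 n_segments = 1L, label = "synthetic"),
            class = "correlation_curve")
}

test_that("noiseless round trip recovers all five parameters exactly", {
  truth <- fcs_model_params(G0 = 0.05, tau_D = 2e-3, alpha = 1,
                            T_trip = 0.2, tau_T = 5e-6)
  curve <- make_noiseless_curve(truth)

  # stage 1: everything free
  fit_all <- fit_fcs(curve)
  for (nm in c("G0", "tau_D", "alpha", "T_trip", "tau_T"))
    expect_equal(fit_all$params[[nm]], truth[[nm]], tolerance = 1e-6,
                 label = paste("free-fit", nm))

  # stage 2: triplet fixed at truth (the STED-stage protocol)
  fit_fixed <- fit_fcs(curve,
                       init = fcs_model_params(0.1, 1e-3, 1.2, 0.2, 5e-6),
                       fixed = c(T_trip = TRUE, tau_T = TRUE))
  expect_equal(fit_fixed$params$G0, truth$G0, tolerance = 1e-6)
  expect_equal(fit_fixed$params$tau_D, truth$tau_D, tolerance = 1e-6)
  expect_equal(fit_fixed$params$alpha, truth$alpha, tolerance = 1e-6)
  expect_equal(sum(!fit_fixed$fixed), 3L)   # exactly G0, tau_D, alpha free
  expect_true(fit_fixed$converged)
})

test_that("anomalous decay (alpha = 0.85) is recovered exactly", {
  truth <- fcs_model_params(G0 = 0.05, tau_D = 2e-3, alpha = 0.85,
                            T_trip = 0.2, tau_T = 5e-6)
  curve <- make_noiseless_curve(truth)
  fit <- fit_fcs(curve, fixed = c(T_trip = TRUE, tau_T = TRUE),
                 init = fcs_model_params(0.1, 1e-3, 1, 0.2, 5e-6))
  expect_equal(fit$params$alpha, 0.85, tolerance = 1e-6)
})

test_that("an all-zero curve is flagged, not silently fitted", {
  curve <- make_noiseless_curve(fcs_model_params(1, 1e-3))
  curve$G[] <- 0
  fit <- fit_fcs(curve)
  expect_equal(fit$params$G0, 0)
  expect_false(fit$converged)
  expect_false(fit$qc_pass)
  expect_match(fit$message, "unidentifiable")
})

test_that("fit never returns a worse objective than its start", {
  set.seed(31)
  truth <- fcs_model_params(G0 = 0.8, tau_D = 1e-3, alpha = 1)
  curve <- make_noiseless_curve(truth)
  curve$G <- curve$G + rnorm(length(curve$G), 0, 0.02)
  for (i in 1:5) {
    init <- fcs_model_params(G0 = runif(1, 0.01, 5),
                             tau_D = 10^runif(1, -5, -1),
                             alpha = runif(1, 0.5, 1.5))
    fit <- fit_fcs(curve, init = init, fixed = c(T_trip = TRUE, tau_T = TRUE))
    obj <- function(p) sum((curve$G - evaluate_model(p, curve$lags_s))^2)
    expect_lte(obj(fit$params), obj(init) + 1e-12)
  }
})

test_that("fit window is validated and respected", {
  curve <- make_noiseless_curve(fcs_model_params(1, 1e-3))
  expect_error(fit_fcs(curve, window = c(10, 20)), "outside")
  expect_error(fit_fcs(curve, window = c(0.1, 0.001)), "t_min < t_max")
  f <- fit_fcs(curve, window = c(1e-5, 0.1))
  expect_equal(f$fit_window, c(1e-5, 0.1))
  expect_lt(f$n_lags, length(curve$lags_s))
})

test_that("cpm is the product of amplitude and count rate", {
  expect_equal(compute_cpm(0.1, 1e5), 1e4)
  expect_equal(compute_cpm(0, 1e5), 0)
  expect_equal(compute_cpm(0.2, 5e4), 1e4)
  expect_error(compute_cpm(-0.1, 1e5), "G0")
  expect_error(compute_cpm(0.1, -1), "mean_rate")
})

test_that("qc filter applies the strict anomaly window", {
  mk <- function(a) {
    curve <- make_noiseless_curve(fcs_model_params(1, 1e-3, alpha = a))
    fit_fcs(curve, fixed = c(T_trip = TRUE, tau_T = TRUE))
  }
  fits <- lapply(c(0.7, 0.9, 1.0, 1.19, 1.3), mk)
  kept <- qc_filter(fits)
  expect_equal(vapply(kept, function(f) f$params$alpha, numeric(1)),
               c(0.9, 1.0, 1.19), tolerance = 1e-4)

  # exact boundary is rejected (strict inequality)
  fits[[1]]$params$alpha <- 0.8
  expect_equal(length(qc_filter(fits[1])), 0L)
  expect_equal(qc_filter(list()), list())
})

test_that("parameter recovery from simulated photon noise is accurate", {
  # moderate trace at >= 20 kHz: median tau_D error well under 10%
  taus <- sapply(1:3, function(s) {
    cfg <- simulation_config(duration_s = 4, seed = 600 + s)
    st <- simulate_photon_stream(cfg)
    expect_gt(mean_count_rate(st), 2e4)
    f <- fit_fcs(correlate(st), fixed = c(T_trip = TRUE, tau_T = TRUE))
    f$params$tau_D
  })
  expected <- (0.204)^2 / (4 * 5)
  expect_lt(median(abs(taus - expected) / expected), 0.10)
})

test_that("fit tables carry one row per fit with the qc verdict", {
  curve <- make_noiseless_curve(fcs_model_params(0.5, 1e-3))
  tab <- fit_table(list(fit_fcs(curve), fit_fcs(curve)))
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("alpha", "cpm_hz", "qc_pass") %in% names(tab)))
})
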