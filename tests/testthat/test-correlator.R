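test_that("a deterministic constant-rate stream has zero correlation", {
  # one photon on every macrotime tick: no fluctuations at all
  s <- tiny_stream(0:4095, rep(1, 4096), duration = 4096 * 1.25e-8)
  cv <- correlate(s, lag_scheme(max_lag_s = 400 * 1.25e-8))
  expect_true(all(is.finite(cv$G)))
  expect_true(all(abs(cv$G) < 1e-12))
})

test_that("two photons put all pair mass in the bin containing their lag", {
  s <- tiny_stream(c(100, 137), c(1, 1), duration = 300 * 1.25e-8)
  cv <- brute_force_correlate(s, lag_ticks = c(10, 36, 37, 38, 90))
  expect_equal(cv$n_pairs, c(0, 0, 1, 0, 0))
  # bins beyond reach of both photons have empty normalization windows:
  # undefined, flagged NA, not zero-filled
  far <- brute_force_correlate(s, lag_ticks = c(250))
  expect_true(is.na(far$G))
})

test_that("multi-tau agrees with the brute-force oracle on seeded streams", {
  set.seed(21)
  for (rep in 1:10) {
    s <- poisson_stream(rate = runif(1, 2e4, 2e5), duration = 0.01)
    fast <- correlate(s)
    slow <- brute_force_correlate(s)
    expect_equal(fast$lags_s, slow$lags_s)
    expect_equal(fast$n_pairs, slow$n_pairs)
    expect_equal(fast$G, slow$G, tolerance = 1e-9)
  }
})

test_that("oracle agreement holds for clumped (correlated) streams too", {
  set.seed(22)
  for (rep in 1:5) {
    s <- telegraph_stream(rate_on = 4e5, tau_on = 1e-3, tau_off = 1e-3,
                          duration = 0.01)
    fast <- correlate(s)
    slow <- brute_force_correlate(s)
    expect_equal(fast$G, slow$G, tolerance = 1e-9)
  }
})

test_that("homogeneous Poisson stream correlates to statistical zero", {
  set.seed(23)
  s <- poisson_stream(rate = 1e5, duration = 1)   # 1e5 photons
  cv <- correlate(s)
  ok <- is.finite(cv$G) & cv$n_pairs > 0
  expect_true(all(abs(cv$G[ok]) < 4 / sqrt(cv$n_pairs[ok])))
})

test_that("bursty emission decorrelates on the telegraph timescale", {
  # two-state telegraph with equal mean dwells tau_b: the intensity ACF is
  # exp(-t / tau_c) with tau_c = tau_b / 2 (sum of the switching rates)
  set.seed(24)
  tau_b <- 2e-3
  s <- telegraph_stream(rate_on = 2e5, tau_on = tau_b, tau_off = tau_b,
                        duration = 5)
  cv <- correlate(s)
  sel <- cv$lags_s > 5e-5 & cv$lags_s < 4e-3 & cv$G > 0.05
  fit <- lm(log(cv$G[sel]) ~ cv$lags_s[sel])
  tau_fit <- -1 / coef(fit)[2]
  expect_equal(unname(tau_fit), tau_b / 2, tolerance = 0.2)
  # amplitude ~ p_off/p_on = 1
  expect_equal(mean(cv$G[cv$lags_s < 2e-5]), 1, tolerance = 0.15)
})

test_that("autocorrelation is invariant under time reversal", {
  set.seed(25)
  T_ticks <- 2^20   # power of two so every coarsening level mirrors exactly
  n <- 3000
  ticks <- sort(floor(runif(n, 0, T_ticks)))
  s <- tiny_stream(ticks, rep(1, n), duration = T_ticks * 1.25e-8)
  rev_s <- tiny_stream(sort(T_ticks - 1 - ticks), rep(1, n),
                       duration = T_ticks * 1.25e-8)
  a <- correlate(s)
  b <- correlate(rev_s)
  expect_equal(a$G, b$G, tolerance = 1e-12)
})

test_that("fewer than two photons yields an empty curve with a warning", {
  s <- tiny_stream(5, 1, duration = 1)
  expect_warning(cv <- correlate(s), "fewer than 2")
  expect_equal(length(cv$lags_s), 0L)
})

test_that("lag grids beyond the trace duration are truncated with warning", {
  set.seed(26)
  s <- poisson_stream(rate = 1e5, duration = 0.01)
  expect_warning(cv <- correlate(s, lag_scheme(max_lag_s = 1)), "truncated")
  expect_true(max(cv$lags_s) <= 0.01)
})

test_that("segment errors: identical segments give zero error", {
  # same photon pattern repeated in each of 4 segments
  seg_ticks <- 1000
  pat <- c(10, 55, 230, 300, 612)
  ticks <- as.vector(outer(pat, (0:3) * seg_ticks, "+"))
  s <- tiny_stream(sort(ticks), rep(1, length(ticks)),
                   duration = 4 * seg_ticks * 1.25e-8)
  cv <- segment_errors(s, n_segments = 4)
  expect_true(all(cv$G_err[is.finite(cv$G_err)] < 1e-12))
  expect_error(segment_errors(s, n_segments = 1), "at least 2")
})

test_that("segment mean is consistent with the full-trace curve", {
  set.seed(27)
  s <- telegraph_stream(rate_on = 3e5, tau_on = 5e-4, tau_off = 5e-4,
                        duration = 2)
  seg <- segment_errors(s, n_segments = 10)
  full <- correlate(s, lag_scheme(max_lag_s = max(seg$lags_s)))
  shared <- match(seg$lags_s, full$lags_s)
  ok <- is.finite(seg$G_err) & seg$G_err > 0 & !is.na(shared)
  cover <- abs(seg$G[ok] - full$G[shared[ok]]) <= 3 * seg$G_err[ok]
  expect_gte(mean(cover), 0.95)
})

test_that("gating commutes with segmentation", {
  set.seed(28)
  s <- poisson_stream(rate = 2e5, duration = 0.5)
  g <- gate_window(2.4, 6.4)
  a <- segment_errors(apply_gate(s, g), n_segments = 5)
  # manual per-segment gating
  seg_dur <- s$duration_s / 5
  manual <- lapply(1:5, function(i) {
    keep <- s$macro_ticks >= (i - 1) * seg_dur / s$tick_s &
      s$macro_ticks < i * seg_dur / s$tick_s
    seg <- photon_stream(s$macro_ticks[keep] - floor((i - 1) * seg_dur / s$tick_s),
                         s$microtimes_ns[keep], s$rep_rate_hz, seg_dur)
    correlate(apply_gate(seg, g))
  })
  Gbar <- rowMeans(sapply(manual, function(cv) cv$G), na.rm = TRUE)
  expect_equal(a$G, Gbar, tolerance = 1e-12)
})

test_that("curves serialize to csv with their metadata", {
  set.seed(29)
  s <- poisson_stream(rate = 5e4, duration = 0.05)
  cv <- correlate(s)
  path <- withr::local_tempfile(fileext = ".csv")
  write_correlation_csv(cv, path)
  lines <- readLines(path)
  expect_true(any(grepl("n_photons", lines)))
  tab <- read.csv(path, comment.char = "#")
  expect_equal(nrow(tab), length(cv$lags_s))
  expect_equal(tab$G, cv$G, tolerance = 1e-9)
})
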