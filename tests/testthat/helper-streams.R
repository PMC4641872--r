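# Small stream constructors used across the test files.  All randomness
# goes through R's RNG under withr::local_seed / set.seed in the tests.

# stream with explicitly given times (ticks at the excitation period)
tiny_stream <- function(ticks, micro, rep_rate = 8e7,
                        duration = (max(ticks, 0) + 1) * 1 / rep_rate * 1.0001) {
  photon_stream(macro_ticks = ticks, microtimes_ns = micro,
                rep_rate_hz = rep_rate, duration_s = duration)
}

# homogeneous Poisson photon stream: rate in counts/s, exponential
# microtimes with lifetime tau_ns wrapped into the period
poisson_stream <- function(rate, duration, rep_rate = 8e7, tau_ns = 3.5,
                           label = "poisson") {
  n <- rpois(1, rate * duration)
  tick_s <- 1 / rep_rate
  ticks <- sort(floor(runif(n, 0, duration / tick_s)))
  period <- 1e9 / rep_rate
  micro <- rexp(n, rate = 1 / tau_ns) %% period
  photon_stream(macro_ticks = ticks, microtimes_ns = micro,
                rep_rate_hz = rep_rate, duration_s = duration,
                label = label)
}

# two-state telegraph emitter: exponential on/off dwells (mean tau_on,
# tau_off seconds), Poisson photons at rate_on while on
telegraph_stream <- function(rate_on, tau_on, tau_off, duration,
                             rep_rate = 8e7) {
  t <- 0; on <- runif(1) < tau_on / (tau_on + tau_off)
  times <- numeric(0)
  while (t < duration) {
    dwell <- rexp(1, 1 / if (on) tau_on else tau_off)
    dwell <- min(dwell, duration - t)
    if (on && dwell > 0) {
      k <- rpois(1, rate_on * dwell)
      times <- c(times, t + runif(k, 0, dwell))
    }
    t <- t + dwell; on <- !on
  }
  tick_s <- 1 / rep_rate
  ticks <- sort(floor(times / tick_s))
  photon_stream(macro_ticks = ticks,
                microtimes_ns = rep(1, length(ticks)),
                rep_rate_hz = rep_rate, duration_s = duration,
                label = "telegraph")
}

expect_same_stream <- function(a, b) {
  expect_equal(a$macro_ticks, b$macro_ticks)
  expect_equal(a$microtimes_ns, b$microtimes_ns, tolerance = 1e-12)
  expect_equal(a$rep_rate_hz, b$rep_rate_hz)
  expect_equal(a$duration_s, b$duration_s)
  expect_equal(a$tick_s, b$tick_s)
}
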