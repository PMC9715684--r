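# Shared fixtures, built in code.

# ideal uniform tapped-delay-line calibration (87 taps of T/87)
uniform_calibration <- function(n_codes = 87L,
                                clock_period_ns = ttm_clock_period()) {
  w <- rep(clock_period_ns / n_codes, n_codes)
  structure(list(widths_ns = w, time_ns = cumsum(w) - w / 2,
                 counts = rep(1L, n_codes), n_codes = n_codes,
                 clock_period_ns = clock_period_ns),
            class = "tdl_calibration")
}

# calibration measured from a TDL model line (asynchronous code density)
measured_calibration <- function(widths_ps, n_events = 2e5,
                                 clock_period_ns = ttm_clock_period()) {
  ev <- runif(n_events, 0, n_events * clock_period_ns / 3)
  enc <- tdc_encode(ev, widths_ps, clock_period_ns,
                    apply_dead_time = FALSE)
  code_density_calibrate(enc$code, n_codes = length(widths_ps),
                         clock_period_ns = clock_period_ns,
                         min_events = 1e4)
}

# zero-fingerprint helper
zero_fingerprint <- function(fp) {
  fp$sx[] <- 0
  fp$sy[] <- 0
  fp
}

expect_rel_error <- function(value, truth, tol) {
  expect_lt(abs(value - truth) / abs(truth), tol)
}
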