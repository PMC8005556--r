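# shared fixtures: all synthetic, generated in code at test time

sine_trace <- function(freq, rate, dur = 1, amp = 1, phase = 0,
                       units = "dimensionless") {
  t <- seq(0, dur, by = 1 / rate)
  sampled_trace(amp * sin(2 * pi * freq * t + phase), rate, units = units)
}

# dominant spectral frequency of a trace (periodogram argmax)
peak_freq <- function(trace) {
  x <- trace$samples - mean(trace$samples)
  n <- length(x)
  sp <- Mod(stats::fft(x))[2:(n %/% 2)]
  which.max(sp) * trace$rate / n
}

# memoized pipeline runs shared across test files (same R session)
.cache <- new.env(parent = emptyenv())

cached_analysis <- function(key, seed, ...) {
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  sc <- articulation_scenario(seed = seed, ...)
  an <- analyze_recording(make_recording(sc))
  .cache[[key]] <- list(scenario = sc, analysis = an)
  .cache[[key]]
}

# the standard noiseless validation run used by several files
clean_run <- function() {
  cached_analysis("clean6", seed = 1, duration = 6,
                  noise_accel = 0, noise_semg = 0)
}

second_diff_for_test <- function(x, dt) {
  n <- length(x)
  d2 <- numeric(n)
  d2[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / dt^2
  d2[1] <- d2[2]; d2[n] <- d2[n - 1]
  d2
}
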