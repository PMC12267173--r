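#' Stimulus specification
#'
#' Seeded, reproducible generator spec for the external current injected
#' into the stimulated neuron.  Waveforms:
#'
#' * `"sine"` — `amplitude * sin(omega * t) + offset`.  The defaults
#'   (60 uA/cm^2 amplitude, 30 uA/cm^2 DC offset, omega = 0.1*pi rad/ms,
#'   i.e. a 20 ms period) are the study's driving signal.
#' * `"square"` — 10 uA/cm^2 during the first 10 ms of every 20 ms period,
#'   0 otherwise (the two-neuron validation input; see [square_wave()]).
#' * `"sine_plus_noise"` — the sine plus Gaussian white noise (mean
#'   `noise_mean`, sd `noise_sd`, default 0 and 20), drawn per
#'   `noise_sample_dt` interval and held constant within it.  The noise is a
#'   sampled interference signal, not an SDE diffusion term, so it is not
#'   rescaled by the integration step.
#' * `"none"` — zero current.
#'
#' @param waveform one of `"sine"`, `"square"`, `"sine_plus_noise"`, `"none"`.
#' @param amplitude,offset sine amplitude and DC offset, uA/cm^2.
#' @param omega sine angular frequency, rad/ms.
#' @param noise_mean,noise_sd Gaussian noise mean and standard deviation,
#'   uA/cm^2 (`noise_sd >= 0`).
#' @param seed RNG seed for the noise stream; identical seeds give
#'   bit-identical stimuli.
#' @param noise_sample_dt noise sampling interval, ms (> 0).  `NULL` means
#'   "use the integration step", resolved by [simulate_network()].
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(waveform = c("sine", "square", "sine_plus_noise", "none"),
                          amplitude = 60, offset = 30, omega = 0.1 * pi,
                          noise_mean = 0, noise_sd = 20, seed = NULL,
                          noise_sample_dt = NULL) {
  waveform <- match.arg(waveform)
  stopifnot(is.numeric(amplitude), is.numeric(offset), is.numeric(omega),
            is.numeric(noise_mean), is.numeric(noise_sd))
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!is.null(noise_sample_dt) &&
      (!is.numeric(noise_sample_dt) || noise_sample_dt <= 0))
    stop("`noise_sample_dt` must be > 0", call. = FALSE)
  structure(list(waveform = waveform, amplitude = amplitude, offset = offset,
                 omega = omega, noise_mean = noise_mean, noise_sd = noise_sd,
                 seed = seed, noise_sample_dt = noise_sample_dt),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat("<stimulus_spec>", x$waveform, "\n")
  invisible(x)
}

#' Square-wave validation stimulus
#'
#' 10 uA/cm^2 during `20k <= t < 20k + 10` for integer `k`, 0 during the
#' second half of each 20 ms period.
#'
#' @param t time(s), ms, >= 0.
#' @return Current density, uA/cm^2.
#' @examples
#' square_wave(c(5, 15, 25))  # 10 0 10
#' @export
square_wave <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("`t` must be finite and >= 0", call. = FALSE)
  ifelse(t %% 20 < 10, 10, 0)
}

#' Sine stimulus
#'
#' `amplitude * sin(omega * t) + offset`; with the defaults,
#' `60 sin(0.1 pi t) + 30` uA/cm^2 (20 ms period).
#'
#' @param t time(s), ms, >= 0.
#' @param spec a [stimulus_spec()] supplying amplitude, offset and omega.
#' @return Current density, uA/cm^2.
#' @export
sine_wave <- function(t, spec = stimulus_spec("sine")) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("`t` must be finite and >= 0", call. = FALSE)
  spec$amplitude * sin(spec$omega * t) + spec$offset
}

#' Gaussian interference samples
#'
#' `n` i.i.d. draws from N(`noise_mean`, `noise_sd`), reproducible for a
#' fixed `spec$seed` (the caller's RNG state is preserved).
#'
#' @param n number of samples, >= 1.
#' @param spec a [stimulus_spec()].
#' @return Numeric vector of current densities, uA/cm^2.
#' @export
noise_samples <- function(n, spec = stimulus_spec("sine_plus_noise")) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  with_seed(spec$seed, rnorm(n, mean = spec$noise_mean, sd = spec$noise_sd))
}

#' Render a stimulus onto a time grid
#'
#' Evaluates the spec's waveform at each grid point.  Noise is drawn once
#' per `noise_sample_dt` interval and held constant across the grid points
#' inside it (zero-order hold), so the rendered trace is deterministic given
#' the spec, the grid and the seed.
#'
#' @param spec a [stimulus_spec()].
#' @param times uniform, increasing time grid, ms, starting at >= 0.
#' @return Numeric vector of current densities, one per grid point.
#' @export
render_stimulus <- function(spec, times) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (!is.numeric(times) || length(times) < 1 || any(!is.finite(times)) ||
      any(times < 0))
    stop("`times` must be a finite non-negative time grid", call. = FALSE)
  if (length(times) > 1) {
    dts <- diff(times)
    if (any(dts <= 0) || max(dts) - min(dts) > 1e-9)
      stop("`times` must be a uniform increasing grid", call. = FALSE)
  }
  switch(spec$waveform,
    none = rep(0, length(times)),
    square = square_wave(times),
    sine = sine_wave(times, spec),
    sine_plus_noise = {
      ndt <- spec$noise_sample_dt
      if (is.null(ndt))
        ndt <- if (length(times) > 1) times[2] - times[1] else 1
      nsam <- floor(max(times) / ndt + 1e-9) + 1
      idx <- pmin(floor(times / ndt + 1e-9) + 1, nsam)
      sine_wave(times, spec) + noise_samples(nsam, spec)[idx]
    })
}
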