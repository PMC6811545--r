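#' ZAP (chirp) stimulus specification and waveform
#'
#' A sinusoidal current whose instantaneous frequency increases linearly
#' from `f_start` to `f_end` over the stimulus duration.  The phase is the
#' integral of the instantaneous frequency,
#' `phi(t) = 2 pi (f_start t + (f_end - f_start) t^2 / (2 T))`; evaluating
#' the naive `sin(2 pi f(t) t)` instead would sweep frequency at twice the
#' intended rate (see [zap_naive()] for the comparison).
#'
#' @param amplitude peak current (pA); default 40
#' @param f_start,f_end sweep limits (Hz); defaults 0.5 and 50
#' @param duration_s sweep duration (s); default 25
#' @param fs_khz sample rate (kHz); default 10
#' @return `zap_spec()` returns a spec list; `make_zap()` returns a list
#'   with `t_ms`, `i_pa` and `f_inst_hz` (instantaneous frequency)
#' @export
zap_spec <- function(amplitude = 40, f_start = 0.5, f_end = 50,
                     duration_s = 25, fs_khz = 10) {
  stopifnot(f_start <= f_end, duration_s > 0, fs_khz > 0, amplitude > 0)
  structure(list(amplitude = amplitude, f_start = f_start, f_end = f_end,
                 duration_s = duration_s, fs_khz = fs_khz),
            class = "zap_spec")
}

#' @rdname zap_spec
#' @param spec a `zap_spec()`
#' @export
make_zap <- function(spec = zap_spec()) {
  dt <- 1 / spec$fs_khz                       # ms
  t_ms <- seq(0, spec$duration_s * 1000, by = dt)
  t_s <- t_ms / 1000
  sweep_rate <- (spec$f_end - spec$f_start) / spec$duration_s
  phase <- 2 * pi * (spec$f_start * t_s + sweep_rate * t_s^2 / 2)
  list(t_ms = t_ms,
       i_pa = spec$amplitude * sin(phase),
       f_inst_hz = spec$f_start + sweep_rate * t_s)
}

#' @rdname zap_spec
#' @export
zap_naive <- function(spec = zap_spec()) {
  dt <- 1 / spec$fs_khz
  t_ms <- seq(0, spec$duration_s * 1000, by = dt)
  t_s <- t_ms / 1000
  f_t <- spec$f_start + (spec$f_end - spec$f_start) * t_s / spec$duration_s
  list(t_ms = t_ms, i_pa = spec$amplitude * sin(2 * pi * f_t * t_s))
}

#' Simulate the voltage response of a passive RC membrane
#'
#' Integrates `C dV/dt = I - V/R` (V relative to rest) with the exact
#' exponential update for a piecewise-constant injected current.  Used as
#' the synthetic test cell for impedance analysis.
#'
#' @param R input resistance (MOhm)
#' @param C capacitance (pF)
#' @param i_pa injected current samples (pA)
#' @param fs_khz sample rate (kHz)
#' @return voltage samples (mV, relative to rest)
#' @export
simulate_rc_voltage <- function(R, C, i_pa, fs_khz) {
  stopifnot(R > 0, C > 0)
  dt <- 1 / fs_khz
  tau <- tau_m_ms(R, C)
  a <- exp(-dt / tau)
  v <- numeric(length(i_pa))
  rinf <- R / 1000                            # MOhm * pA -> mV needs /1000
  for (i in seq_along(i_pa)[-1]) {
    v[i] <- v[i - 1] * a + rinf * i_pa[i - 1] * (1 - a)
  }
  v
}

#' Closed-form impedance of a first-order RC membrane
#'
#' `|Z(f)| = R / sqrt(1 + (2 pi f tau)^2)`, with `tau = RC`; the DC limit
#' is the membrane resistance.
#'
#' @param f frequency (Hz)
#' @param R resistance (MOhm)
#' @param C capacitance (pF)
#' @return impedance magnitude (MOhm)
#' @export
rc_impedance <- function(f, R, C) {
  tau_s <- R * C * 1e-6
  R / sqrt(1 + (2 * pi * f * tau_s)^2)
}

#' Frequency-resolved membrane impedance from voltage and current traces
#'
#' The complex impedance is the ratio of the Fourier-transformed voltage
#' and current, evaluated on the swept band.  Magnitude is returned in
#' MOhm (voltage in mV, current in pA), phase via the four-quadrant
#' arctangent (continuous through zero crossings; voltage lag is
#' negative), and Bode gain in dB relative to the lowest band frequency.
#' A running-mean smoother of configurable width stabilises the spectral
#' ratio.
#'
#' @param v voltage trace (mV)
#' @param i current trace (pA)
#' @param fs_khz sample rate (kHz)
#' @param band evaluation band `c(f_lo, f_hi)` (Hz); default `c(0.5, 50)`
#' @param smooth_hz running-mean window (Hz); 0 disables smoothing
#' @param f_ref Bode reference frequency (Hz); default the low band edge
#' @return a data.frame of class `impedance_profile`: `frequency_hz`,
#'   `z_mohm`, `phase_rad`, `gain_db`
#' @export
impedance_profile <- function(v, i, fs_khz, band = c(0.5, 50),
                              smooth_hz = 0.25, f_ref = band[1]) {
  if (length(v) != length(i)) stop("v and i must have equal length",
                                   call. = FALSE)
  n <- length(v)
  fs_hz <- fs_khz * 1000
  freqs <- (seq_len(n) - 1) * fs_hz / n
  half <- freqs <= fs_hz / 2
  V <- stats::fft(v)[half]
  I <- stats::fft(i)[half]
  f <- freqs[half]
  in_band <- f >= band[1] & f <= band[2]
  if (!any(in_band) || all(Mod(I[in_band]) < .Machine$double.eps)) {
    stop("current spectrum has no power in the requested band",
         call. = FALSE)
  }
  Z <- V[in_band] / I[in_band] * 1000        # mV/pA = GOhm -> MOhm
  f <- f[in_band]
  if (smooth_hz > 0) {
    df <- f[2] - f[1]
    k <- max(1L, as.integer(round(smooth_hz / df)))
    if (k > 1) {
      kern <- rep(1 / k, k)
      sm <- function(x) as.numeric(stats::filter(x, kern, sides = 2))
      Zs <- complex(real = sm(Re(Z)), imaginary = sm(Im(Z)))
      ok <- !is.na(Re(Zs))
      Z <- Zs[ok]; f <- f[ok]
    }
  }
  mag <- Mod(Z)
  iref <- which.min(abs(f - f_ref))
  out <- data.frame(
    frequency_hz = f,
    z_mohm = mag,
    phase_rad = atan2(Im(Z), Re(Z)),
    gain_db = 20 * log10(mag / mag[iref])
  )
  class(out) <- c("impedance_profile", class(out))
  out
}

#' RC low-pass cut-off frequency
#'
#' `f_cutoff = 1 / (2 pi R C)`: the frequency above which a first-order
#' low-pass filter attenuates by more than -3 dB, rolling off at
#' -20 dB/decade.
#'
#' @param R resistance (MOhm)
#' @param C capacitance (pF)
#' @return cut-off frequency (Hz)
#' @examples
#' rc_cutoff(412, 94)  # ~4.11 Hz
#' @export
rc_cutoff <- function(R, C) {
  stopifnot(R > 0, C > 0)
  1 / (2 * pi * R * C * 1e-6)
}

#' Bode gain relative to a reference frequency
#'
#' `gain(f) = 20 log10(|Z(f)| / |Z(f_ref)|)`.  (The equivalent power
#' convention, `10 log10` of the squared ratio, gives identical values.)
#'
#' @param profile an [impedance_profile()]
#' @param f_ref reference frequency (Hz)
#' @return the profile with its `gain_db` column recomputed
#' @export
bode_gain <- function(profile, f_ref = 0.5) {
  iref <- which.min(abs(profile$frequency_hz - f_ref))
  profile$gain_db <- 20 * log10(profile$z_mohm / profile$z_mohm[iref])
  profile
}

# Analytic signal via the frequency-domain Hilbert construction.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Phase locking of spikes to a sinusoidal stimulus
#'
#' Registers each spike to the instantaneous phase of the injected current
#' waveform, obtained from the Hilbert (analytic-signal) transform.
#' Phases are reported in the sine convention -- a spike exactly at a
#' current peak has phase pi/2 -- together with the circular mean and the
#' resultant vector strength.
#'
#' @param spike_times spike times (ms)
#' @param stim_trace injected current samples
#' @param fs_khz sample rate of the stimulus (kHz)
#' @return list: `phases` (radians, one per spike), `circ_mean_rad`,
#'   `vector_strength` (0..1); all empty/NA if there are no spikes
#' @export
phase_lock <- function(spike_times, stim_trace, fs_khz) {
  if (!length(spike_times)) {
    return(list(phases = numeric(0), circ_mean_rad = NA_real_,
                vector_strength = NA_real_))
  }
  an <- analytic_signal(stim_trace)
  inst_phase <- Arg(an) + pi / 2              # sine-argument convention
  inst_phase <- atan2(sin(inst_phase), cos(inst_phase))
  idx <- pmin(pmax(as.integer(round(spike_times * fs_khz)) + 1L, 1L),
              length(stim_trace))
  phases <- inst_phase[idx]
  z <- mean(exp(1i * phases))
  list(phases = phases, circ_mean_rad = Arg(z), vector_strength = Mod(z))
}
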