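#' Gaussian spike density function
#'
#' Discretises spike times into 1 ms bins and convolves each spike with a
#' Gaussian kernel (default SD 5 ms) truncated at `truncation` standard
#' deviations.  Each spike's kernel mass is renormalised to exactly 1
#' within its in-bounds truncation window, so kernels clipped by the
#' raster edges do not lose mass.  The trial-averaged curve is the mean
#' across trials.
#'
#' @param trials a list of numeric spike-time vectors (one per trial), or a
#'   single numeric vector
#' @param duration raster duration (ms); bins cover `[0, duration)`
#' @param sigma kernel standard deviation (ms)
#' @param truncation kernel support half-width in multiples of `sigma`
#' @param bin bin width (ms)
#' @return a list of class `sdf`: `t` (bin centres), `per_trial`
#'   (bins x trials matrix of spikes per bin), `mean` (trial average),
#'   `sigma`, `truncation`
#' @export
spike_density <- function(trials, duration, sigma = 5, truncation = 3,
                          bin = 1) {
  if (is.numeric(trials)) trials <- list(trials)
  n_bins <- as.integer(ceiling(duration / bin))
  centres <- (seq_len(n_bins) - 0.5) * bin
  half <- as.integer(ceiling(truncation * sigma / bin))
  offsets <- (-half):half
  kern <- stats::dnorm(offsets * bin, 0, sigma)
  per_trial <- matrix(0, n_bins, length(trials))
  for (j in seq_along(trials)) {
    for (ts in trials[[j]]) {
      b <- as.integer(floor(ts / bin)) + 1L
      idx <- b + offsets
      ok <- idx >= 1L & idx <= n_bins
      w <- kern[ok]
      per_trial[idx[ok], j] <- per_trial[idx[ok], j] + w / sum(w)
    }
  }
  structure(
    list(t = centres,
         per_trial = per_trial,
         mean = rowMeans(per_trial),
         sigma = sigma, truncation = truncation),
    class = "sdf"
  )
}

#' First-spike latency and inter-trial precision
#'
#' Per trial, the latency is the time from the window start to the first
#' spike inside the window; trials with no in-window spike are excluded and
#' counted.  Precision is reported as the sample SD of latencies.
#'
#' @param trials list of spike-time vectors, one per trial
#' @param window two-element numeric `c(start, end)` (ms)
#' @return list: `latencies` (per responding trial), `mean_latency_ms`,
#'   `sd_latency_ms`, `n_silent`
#' @export
first_spike_stats <- function(trials, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  lat <- vapply(trials, function(ts) {
    ts <- ts[ts >= window[1] & ts <= window[2]]
    if (length(ts)) min(ts) - window[1] else NA_real_
  }, numeric(1))
  ok <- !is.na(lat)
  list(
    latencies = lat[ok],
    mean_latency_ms = if (any(ok)) mean(lat[ok]) else NA_real_,
    sd_latency_ms = if (sum(ok) > 1) stats::sd(lat[ok]) else
      if (sum(ok) == 1) 0 else NA_real_,
    n_silent = sum(!ok)
  )
}

#' van Rossum spike-train distance
#'
#' Maps each train to a sum of causal exponentials
#' `exp(-(t - t_i)/tau)` and computes
#' `D^2 = (1/tau) * integral (f_A - f_B)^2 dt` via the closed-form
#' pairwise-exponential sum.  Under this normalisation the distance between
#' a single spike and the empty train is `sqrt(1/2)`, and two well-separated
#' spikes versus the empty train give 1.  Symmetric; zero iff the trains
#' are identical.
#'
#' @param a,b numeric spike-time vectors (ms)
#' @param tau exponential decay constant (ms); default 50
#' @return the distance (dimensionless)
#' @export
van_rossum <- function(a, b, tau = 50) {
  stopifnot(tau > 0)
  cross <- function(x, y) {
    if (!length(x) || !length(y)) return(0)
    sum(exp(-abs(outer(x, y, `-`)) / tau))
  }
  d2 <- 0.5 * (cross(a, a) + cross(b, b) - 2 * cross(a, b))
  sqrt(max(d2, 0))
}

#' Rate and rate-variability statistics
#'
#' Per-trial spike counts, the mean instantaneous frequency (1/ISI, in Hz,
#' over trials with at least two spikes) and the trial-to-trial coefficient
#' of variation of the spike count (population SD / mean).
#'
#' @param trials list of spike-time vectors, one per trial
#' @return list: `counts`, `mean_count`, `cv_count`,
#'   `mean_inst_freq_hz` (`NA` if no trial has >= 2 spikes)
#' @export
rate_stats <- function(trials) {
  counts <- vapply(trials, length, integer(1))
  inst <- unlist(lapply(trials, function(ts) {
    if (length(ts) >= 2) 1000 / diff(sort(ts)) else numeric(0)
  }))
  m <- mean(counts)
  pop_sd <- sqrt(mean((counts - m)^2))
  list(
    counts = counts,
    mean_count = m,
    cv_count = if (m > 0) pop_sd / m else NA_real_,
    mean_inst_freq_hz = if (length(inst)) mean(inst) else NA_real_
  )
}

#' Population synchrony and Ex/In rate trajectories
#'
#' Synchrony is the fraction of the (sub)population spiking in each time
#' bin; the phase trajectory pairs the Ex and In per-bin rates for phase-
#' plane display of the population interaction.
#'
#' @param raster a `spike_raster` from [simulate_network()]
#' @param bin bin width (ms)
#' @return list: `t` (bin starts), `sync_ex`, `sync_in` (fractions in
#'   `[0, 1]`), `rate_ex`, `rate_in` (spikes per bin per neuron)
#' @export
population_summary <- function(raster, bin = 1) {
  stopifnot(inherits(raster, "spike_raster"))
  n_bins <- as.integer(ceiling(raster$duration / bin))
  edges <- seq(0, n_bins * bin, by = bin)
  count_pop <- function(pop, n_pop) {
    sp <- raster$spikes[raster$spikes$population == pop, , drop = FALSE]
    if (!nrow(sp)) return(numeric(n_bins))
    # fraction of distinct neurons active per bin
    b <- pmin(as.integer(floor(sp$t_ms / bin)) + 1L, n_bins)
    vapply(seq_len(n_bins), function(i) {
      length(unique(sp$neuron[b == i]))
    }, numeric(1)) / n_pop
  }
  sync_ex <- count_pop("Ex", raster$n_ex)
  sync_in <- count_pop("In", raster$n_in)
  list(t = edges[-length(edges)], sync_ex = sync_ex, sync_in = sync_in,
       rate_ex = sync_ex, rate_in = sync_in)
}
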