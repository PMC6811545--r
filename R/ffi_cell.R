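#' Single-cell thalamocortical feed-forward-inhibition model configuration
#'
#' A single-compartment conductance-based leaky integrate-and-fire neuron
#' receiving two somatic synapses: a thalamocortical (TC) excitatory input
#' (reversal 0 mV, peak conductance 1 nS, yielding ~60 pA peak inward
#' current from the -60 mV leak reversal) and a feed-forward inhibitory
#' (FFI) input (reversal -71 mV) whose peak conductance is `ga_ratio` times
#' the TC peak conductance and which is activated `ei_lag` ms after each
#' TC stimulus.  Both synapses depress independently.
#'
#' @param gen a [default_genotype_params()] object, or `NULL` to supply the
#'   components directly
#' @param cell a [neuron_params()]; defaults to the genotype Ex cell means
#' @param tc_syn,ffi_syn [synapse_spec()] objects for the TC and FFI inputs
#' @param leak_rev leak reversal potential (mV); the single-cell model is
#'   referenced to -60 mV
#' @param ga_ratio FFI-to-TC peak conductance ratio (>= 0)
#' @param ei_lag FFI onset delay after each TC stimulus (ms)
#' @return an object of class `ffi_cell_config`
#' @export
ffi_cell_config <- function(gen = NULL, cell = NULL, tc_syn = NULL,
                            ffi_syn = NULL, leak_rev = -60, ga_ratio = 0,
                            ei_lag = NULL) {
  stopifnot(ga_ratio >= 0)
  if (!is.null(gen)) {
    stopifnot(inherits(gen, "genotype_params"))
    m <- gen$ex_cell$mean
    if (is.null(cell)) cell <- m
    if (is.null(tc_syn)) {
      tc <- gen$synapses[["TC->Ex"]]
      tc_syn <- synapse_spec(tc$tau_rise, tc$tau_decay, t_conduct = 0,
                             g_max = 1, E_rev = 0, stp = tc$stp)
    }
    if (is.null(ffi_syn)) {
      ff <- gen$synapses[["In->Ex"]]
      ffi_syn <- synapse_spec(ff$tau_rise, ff$tau_decay, t_conduct = 0,
                              g_max = 1, E_rev = -71, stp = ff$stp)
    }
    if (is.null(ei_lag)) ei_lag <- gen$ei_lag
  }
  stopifnot(inherits(cell, "neuron_params"),
            inherits(tc_syn, "synapse_spec"),
            inherits(ffi_syn, "synapse_spec"),
            ei_lag >= 0)
  bad <- vapply(list(cell$R_in, cell$C_m, leak_rev, ga_ratio, ei_lag),
                function(x) !is.finite(x), logical(1))
  if (any(bad)) stop("non-finite parameter in FFI cell config", call. = FALSE)
  structure(
    list(cell = cell, tc_syn = tc_syn, ffi_syn = ffi_syn,
         leak_rev = leak_rev, ga_ratio = ga_ratio, ei_lag = ei_lag),
    class = "ffi_cell_config"
  )
}

# Per-event depression amplitudes for arbitrary (possibly irregular) event
# times, reading the amplitude before each event's depression step.
stp_event_amplitudes <- function(stp, event_times) {
  if (is.null(stp)) return(rep(1, length(event_times)))
  st <- stp_state(if (length(event_times)) event_times[1] else 0)
  amps <- numeric(length(event_times))
  for (k in seq_along(event_times)) {
    if (k > 1) st <- stp_recover(st, event_times[k] - event_times[k - 1], stp)
    amps[k] <- st$D1 * st$D2
    st <- stp_on_spike(st, stp)
  }
  amps
}

# Core integrator: exponential-Euler conductance-based LIF, vectorised over
# a set of FFI strengths that share the same conductance time courses.
# Returns a list of spike-time vectors, one per ga value, plus the voltage
# matrix if requested.
ffi_integrate <- function(cfg, ga_vec, times, g_tc, g_ffi, dt,
                          record_voltages = FALSE) {
  cell <- cfg$cell
  gL <- leak_conductance_ns(cell$R_in)
  nga <- length(ga_vec)
  nt <- length(times)
  v <- rep(cfg$leak_rev, nga)
  refrac_until <- rep(-Inf, nga)
  spikes <- vector("list", nga)
  vs <- if (record_voltages) matrix(NA_real_, nt, nga) else NULL
  E_tc <- cfg$tc_syn$E_rev
  E_ff <- cfg$ffi_syn$E_rev
  g_tc_abs <- cfg$tc_syn$g_max * g_tc

  for (i in seq_len(nt)) {
    t <- times[i]
    gff <- ga_vec * (cfg$ffi_syn$g_max * g_ffi[i])
    Gtot <- gL + g_tc_abs[i] + gff
    v_inf <- (gL * cfg$leak_rev + g_tc_abs[i] * E_tc + gff * E_ff) / Gtot
    active <- t >= refrac_until
    v[active] <- v_inf[active] +
      (v[active] - v_inf[active]) * exp(-dt * Gtot[active] / cell$C_m)
    fired <- active & v >= cell$v_thresh
    if (any(fired)) {
      for (j in which(fired)) spikes[[j]] <- c(spikes[[j]], t)
      v[fired] <- cell$v_reset
      refrac_until[fired] <- t + cell$t_ref
    }
    if (record_voltages) vs[i, ] <- v
  }
  list(spikes = spikes, voltages = vs)
}

#' Simulate one trial of the single-cell FFI model
#'
#' Integrates the conductance-based LIF dynamics with exponential Euler at
#' a fine time step (single-cell sweeps are threshold-sensitive, so the
#' default step is 0.025 ms).  The TC synapse is driven at each stimulus
#' time and the FFI synapse `ei_lag` ms later; both amplitude sequences
#' carry their own short-term depression.
#'
#' @param cfg an [ffi_cell_config()]
#' @param stim_times stimulus times (ms), strictly increasing (or a
#'   `stimulus_train` from [make_train()])
#' @param dt integration step (ms); must be <= 0.1
#' @param t_max simulation end (ms); default last stimulus + 150 ms
#' @return a list with `times`, `v` (voltage trace, mV) and `spike_times`
#' @export
simulate_ffi_trial <- function(cfg, stim_times, dt = 0.025, t_max = NULL) {
  stopifnot(inherits(cfg, "ffi_cell_config"), dt > 0, dt <= 0.1)
  if (inherits(stim_times, "stimulus_train")) stim_times <- stim_times$times
  if (length(stim_times)) stopifnot(all(diff(stim_times) > 0))
  t_max <- t_max %||% if (length(stim_times)) max(stim_times) + 150 else 100
  times <- seq(0, t_max, by = dt)
  tc_amp <- stp_event_amplitudes(cfg$tc_syn$stp, stim_times)
  ff_times <- stim_times + cfg$ei_lag
  ff_amp <- stp_event_amplitudes(cfg$ffi_syn$stp, ff_times)
  g_tc <- conductance_train(times, cfg$tc_syn, stim_times, tc_amp)
  g_ff <- conductance_train(times, cfg$ffi_syn, ff_times, ff_amp)
  out <- ffi_integrate(cfg, cfg$ga_ratio, times, g_tc, g_ff, dt,
                       record_voltages = TRUE)
  list(times = times, v = out$voltages[, 1], spike_times = out$spikes[[1]])
}

#' Sweep FFI strength against stimulation frequency
#'
#' Runs the single-cell FFI model over a grid of G/A ratios and regular
#' 5-stimulus train frequencies, recording for each condition the spike
#' count and first-spike latency (ms, relative to the first stimulus).
#' The model is deterministic given its parameters.
#'
#' @param gen a [default_genotype_params()] object or an
#'   [ffi_cell_config()] (whose `ga_ratio` is then overridden per grid
#'   point)
#' @param ga_grid G/A ratios; default `seq(0, 10, by = 0.5)`
#' @param frequencies train frequencies (Hz); default `seq(5, 50, by = 5)`
#' @param n_stim number of stimuli per train; default 5
#' @param dt integration step (ms)
#' @return a data.frame of class `sweep_result` with columns `ga_ratio`,
#'   `frequency_hz`, `n_spikes`, `first_latency_ms`; attribute `label`
#' @export
sweep_ga_frequency <- function(gen, ga_grid = seq(0, 10, by = 0.5),
                               frequencies = seq(5, 50, by = 5),
                               n_stim = 5, dt = 0.025) {
  stopifnot(length(ga_grid) > 0, length(frequencies) > 0)
  cfg <- if (inherits(gen, "ffi_cell_config")) gen else ffi_cell_config(gen)
  rows <- vector("list", length(frequencies))
  for (fi in seq_along(frequencies)) {
    f <- frequencies[fi]
    train <- make_train(f, n_stim, t0 = 20)
    t_max <- max(train$times) + 150
    times <- seq(0, t_max, by = dt)
    tc_amp <- stp_event_amplitudes(cfg$tc_syn$stp, train$times)
    ff_times <- train$times + cfg$ei_lag
    ff_amp <- stp_event_amplitudes(cfg$ffi_syn$stp, ff_times)
    g_tc <- conductance_train(times, cfg$tc_syn, train$times, tc_amp)
    g_ff <- conductance_train(times, cfg$ffi_syn, ff_times, ff_amp)
    out <- ffi_integrate(cfg, ga_grid, times, g_tc, g_ff, dt)
    n_sp <- vapply(out$spikes, length, integer(1))
    lat <- vapply(out$spikes, function(s) {
      if (length(s)) s[1] - train$times[1] else NA_real_
    }, numeric(1))
    rows[[fi]] <- data.frame(ga_ratio = ga_grid, frequency_hz = f,
                             n_spikes = n_sp, first_latency_ms = lat)
  }
  res <- do.call(rbind, rows)
  attr(res, "label") <- if (inherits(gen, "genotype_params")) gen$label else NA
  class(res) <- c("sweep_result", class(res))
  res
}

#' Enumerate the 16 rescue scenarios
#'
#' Each scenario selects, for four parameter groups, whether the KO model
#' keeps its own values (`FALSE`) or has them replaced by WT values
#' (`TRUE`).  Groups: `stp` (depression coefficients of both synapses),
#' `delay` (E-I input lag), `intrinsic` (leak conductance and capacitance,
#' i.e. R_in and C_m), `kinetics` (rise/decay constants of both synapses).
#'
#' @return a data.frame of 16 rows with logical columns `stp`, `delay`,
#'   `intrinsic`, `kinetics`
#' @export
rescue_scenarios <- function() {
  expand.grid(stp = c(FALSE, TRUE), delay = c(FALSE, TRUE),
              intrinsic = c(FALSE, TRUE), kinetics = c(FALSE, TRUE))
}

#' Build a single-cell config for one rescue scenario
#'
#' Starts from the KO parameter set and substitutes WT values for the
#' parameter groups flagged `TRUE`.
#'
#' @param wt,ko genotype parameter sets
#' @param flags a 1-row data.frame or named logical vector with entries
#'   `stp`, `delay`, `intrinsic`, `kinetics`
#' @return an [ffi_cell_config()]
#' @export
scenario_config <- function(wt, ko, flags) {
  flags <- as.list(flags)
  pick <- function(use_wt) if (isTRUE(use_wt)) wt else ko
  gi <- pick(flags$intrinsic)$ex_cell$mean
  base <- ko$ex_cell$mean
  cell <- neuron_params(gi$R_in, gi$C_m, base$v_rest, base$v_thresh,
                        base$v_reset, base$t_ref)
  gk <- pick(flags$kinetics)$synapses
  gs <- pick(flags$stp)$synapses
  tc_syn <- synapse_spec(gk[["TC->Ex"]]$tau_rise, gk[["TC->Ex"]]$tau_decay,
                         t_conduct = 0, g_max = 1, E_rev = 0,
                         stp = gs[["TC->Ex"]]$stp)
  ffi_syn <- synapse_spec(gk[["In->Ex"]]$tau_rise, gk[["In->Ex"]]$tau_decay,
                          t_conduct = 0, g_max = 1, E_rev = -71,
                          stp = gs[["In->Ex"]]$stp)
  ffi_cell_config(cell = cell, tc_syn = tc_syn, ffi_syn = ffi_syn,
                  ei_lag = pick(flags$delay)$ei_lag)
}

#' Run the 16-scenario rescue matrix
#'
#' Sweeps every combination of WT/KO values for the four parameter groups
#' over the G/A x frequency grid and summarises, per scenario, the number
#' of conditions with at least one spike and the total spike output, both
#' as raw counts and as percentages relative to the all-WT scenario.
#'
#' @inheritParams sweep_ga_frequency
#' @param wt,ko genotype parameter sets from [default_genotype_params()]
#' @return a list with `sweeps` (list of 16 [sweep_ga_frequency()]
#'   results) and `summary` (data.frame with the four flags,
#'   `n_spiking_conditions`, `total_spikes`, `pct_conditions_vs_wt`,
#'   `pct_spikes_vs_wt`)
#' @export
rescue_matrix <- function(wt, ko, ga_grid = seq(0, 10, by = 0.5),
                          frequencies = seq(5, 50, by = 5), n_stim = 5,
                          dt = 0.025) {
  stopifnot(inherits(wt, "genotype_params"), inherits(ko, "genotype_params"))
  scen <- rescue_scenarios()
  sweeps <- vector("list", nrow(scen))
  for (i in seq_len(nrow(scen))) {
    cfg <- scenario_config(wt, ko, scen[i, ])
    sweeps[[i]] <- sweep_ga_frequency(cfg, ga_grid, frequencies, n_stim, dt)
  }
  n_cond <- vapply(sweeps, function(s) sum(s$n_spikes >= 1), integer(1))
  n_spk <- vapply(sweeps, function(s) sum(s$n_spikes), integer(1))
  i_wt <- which(scen$stp & scen$delay & scen$intrinsic & scen$kinetics)
  summary <- cbind(
    scen,
    n_spiking_conditions = n_cond,
    total_spikes = n_spk,
    pct_conditions_vs_wt = 100 * (n_cond - n_cond[i_wt]) / n_cond[i_wt],
    pct_spikes_vs_wt = 100 * (n_spk - n_spk[i_wt]) / n_spk[i_wt]
  )
  list(sweeps = sweeps, summary = summary)
}

#' Spike statistics over the spiking conditions of a sweep
#'
#' @param sweep a [sweep_ga_frequency()] result
#' @return a list with `n_spiking_conditions`, and the `latencies` and
#'   `counts` over conditions that fired (empty vectors if none did)
#' @export
condition_spike_stats <- function(sweep) {
  fired <- sweep$n_spikes >= 1
  list(
    n_spiking_conditions = sum(fired),
    latencies = sweep$first_latency_ms[fired],
    counts = sweep$n_spikes[fired],
    median_latency_ms = if (any(fired))
      stats::median(sweep$first_latency_ms[fired]) else NA_real_,
    mean_count = if (any(fired)) mean(sweep$n_spikes[fired]) else NA_real_
  )
}

#' Write a sweep result as tidy CSV
#' @param sweep a [sweep_ga_frequency()] result
#' @param path file path
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}
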