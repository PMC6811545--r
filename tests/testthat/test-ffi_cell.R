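test_that("the cell sits at its leak reversal without input", {
  cfg <- ffi_cell_config(default_genotype_params("WT"))
  out <- simulate_ffi_trial(cfg, numeric(0), t_max = 100)
  expect_true(all(abs(out$v - cfg$leak_rev) < 1e-9))
  expect_length(out$spike_times, 0)
})

test_that("subthreshold EPSPs match an independent ODE-solver oracle", {
  wt <- default_genotype_params("WT")
  tc <- wt$synapses[["TC->Ex"]]
  # scale the conductance down to stay well below threshold
  tc_small <- synapse_spec(tc$tau_rise, tc$tau_decay, t_conduct = 0,
                           g_max = 0.2, E_rev = 0, stp = NULL)
  cfg <- ffi_cell_config(cell = wt$ex_cell$mean, tc_syn = tc_small,
                         ffi_syn = synapse_spec(0.8, 5, t_conduct = 0,
                                                g_max = 1, E_rev = -71),
                         ga_ratio = 0, ei_lag = 2)
  out <- simulate_ffi_trial(cfg, 20, t_max = 120)

  gL <- leak_conductance_ns(wt$ex_cell$mean$R_in)
  rhs <- function(t, y, parms) {
    g <- 0.2 * alpha_conductance(t, tc_small, 20)
    list((-gL * (y[1] + 60) - g * y[1]) / wt$ex_cell$mean$C_m)
  }
  sol <- deSolve::lsoda(c(v = -60), times = seq(0, 120, by = 0.025), rhs,
                        parms = NULL, rtol = 1e-9, atol = 1e-9)
  peak_pkg <- max(out$v) - (-60)
  peak_ode <- max(sol[, "v"]) - (-60)
  expect_lt(abs(peak_pkg - peak_ode) / peak_ode, 0.01)
})

test_that("a 1 nS TC conductance yields ~60 pA peak inward current", {
  wt <- default_genotype_params("WT")
  cell <- wt$ex_cell$mean
  hi <- neuron_params(cell$R_in, cell$C_m, cell$v_rest, 0, -57.5, 1.5)
  cfg <- ffi_cell_config(wt, cell = hi, ga_ratio = 0)
  out <- simulate_ffi_trial(cfg, 50, t_max = 120)
  g <- cfg$tc_syn$g_max *
    alpha_conductance(out$times, cfg$tc_syn, 50)
  i_syn <- g * (out$v - 0)
  expect_gt(-min(i_syn), 50)  # ~60 pA inward, reduced by depolarisation
  expect_lt(-min(i_syn), 62)
})

test_that("the membrane relaxes with time constant R_in * C_m", {
  wt <- default_genotype_params("WT")
  tc <- wt$synapses[["TC->Ex"]]
  cfg <- ffi_cell_config(
    cell = wt$ex_cell$mean,
    tc_syn = synapse_spec(tc$tau_rise, tc$tau_decay, t_conduct = 0,
                          g_max = 0.2, E_rev = 0),
    ffi_syn = synapse_spec(0.8, 5, t_conduct = 0, g_max = 1, E_rev = -71),
    ga_ratio = 0, ei_lag = 2
  )
  out <- simulate_ffi_trial(cfg, 10, t_max = 400)
  # fit the exponential tail after the synaptic conductance has vanished
  sel <- out$times >= 150 & out$times <= 250
  slope <- coef(lm(log(out$v[sel] + 60) ~ out$times[sel]))[2]
  tau_fit <- -1 / slope
  tau_true <- tau_m_ms(412, 94)
  expect_lt(abs(tau_fit - tau_true) / tau_true, 0.001)
})

test_that("infinitely late FFI is equivalent to silenced FFI", {
  wt <- default_genotype_params("WT")
  cfg_late <- ffi_cell_config(wt, ga_ratio = 8, ei_lag = 1e6)
  cfg_off <- ffi_cell_config(wt, ga_ratio = 0)
  tr <- make_train(20, 5, 20)
  a <- simulate_ffi_trial(cfg_late, tr)
  b <- simulate_ffi_trial(cfg_off, tr)
  expect_equal(a$spike_times, b$spike_times)
  expect_equal(a$v, b$v, tolerance = 1e-12)
})

test_that("more inhibition never recruits additional spiking conditions", {
  wt <- default_genotype_params("WT")
  s <- sweep_ga_frequency(wt)
  for (f in unique(s$frequency_hz)) {
    fired <- s$n_spikes[s$frequency_hz == f][order(s$ga_ratio[s$frequency_hz == f])] >= 1
    expect_true(all(diff(as.integer(fired)) <= 0))
  }
})

test_that("rescue scenarios include the pure-genotype identities", {
  wt <- default_genotype_params("WT")
  ko <- default_genotype_params("KO")
  scen <- rescue_scenarios()
  expect_equal(nrow(scen), 16)
  expect_equal(nrow(unique(scen)), 16)
  ga <- c(0, 1, 2); fr <- c(10, 50)
  all_wt <- scenario_config(wt, ko, list(stp = TRUE, delay = TRUE,
                                         intrinsic = TRUE, kinetics = TRUE))
  all_ko <- scenario_config(wt, ko, list(stp = FALSE, delay = FALSE,
                                         intrinsic = FALSE, kinetics = FALSE))
  s_wt <- sweep_ga_frequency(all_wt, ga, fr)
  s_wt_ref <- sweep_ga_frequency(wt, ga, fr)
  expect_equal(s_wt$n_spikes, s_wt_ref$n_spikes)
  expect_equal(s_wt$first_latency_ms, s_wt_ref$first_latency_ms)
  s_ko <- sweep_ga_frequency(all_ko, ga, fr)
  s_ko_ref <- sweep_ga_frequency(ko, ga, fr)
  expect_equal(s_ko$n_spikes, s_ko_ref$n_spikes)
})

test_that("halving the integration step barely perturbs the sweep", {
  wt <- default_genotype_params("WT")
  ga <- seq(0, 10, by = 1); fr <- c(10, 30, 50)
  s1 <- sweep_ga_frequency(wt, ga, fr, dt = 0.025)
  s2 <- sweep_ga_frequency(wt, ga, fr, dt = 0.0125)
  expect_lt(mean(s1$n_spikes != s2$n_spikes), 0.01 + 1e-9)
})

test_that("condition spike statistics summarise only firing conditions", {
  wt <- default_genotype_params("WT")
  s <- sweep_ga_frequency(wt, c(0, 5), c(5, 50))
  st <- condition_spike_stats(s)
  expect_equal(st$n_spiking_conditions, sum(s$n_spikes >= 1))
  expect_length(st$latencies, st$n_spiking_conditions)
  expect_true(all(st$counts >= 1))
  # an all-silent sweep yields empty distributions, not an error
  silent <- s; silent$n_spikes <- 0L
  st0 <- condition_spike_stats(silent)
  expect_equal(st0$n_spiking_conditions, 0)
  expect_true(is.na(st0$median_latency_ms))
})
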