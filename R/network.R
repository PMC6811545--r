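#' Regular stimulus trains and oddball insertion
#'
#' `make_train()` builds a deterministic regular train of `n_stim` events
#' starting at `t0` with the given frequency.  `insert_oddball()` inserts
#' one extra event at the midpoint of the `k`th inter-stimulus interval,
#' leaving all original event times unchanged.
#'
#' @param frequency base frequency (Hz), > 0
#' @param n_stim number of stimuli (>= 1)
#' @param t0 time of the first stimulus (ms)
#' @return an object of class `stimulus_train`: `times`, `frequency`,
#'   `n_base`, `oddball_index` (`NA` if regular), `oddball_time`
#' @examples
#' make_train(50, 5, 100)$times  # 100 120 140 160 180
#' @export
make_train <- function(frequency, n_stim, t0 = 100) {
  stopifnot(frequency > 0, n_stim >= 1, t0 >= 0)
  times <- t0 + (seq_len(n_stim) - 1) * 1000 / frequency
  structure(list(times = times, frequency = frequency, n_base = n_stim,
                 oddball_index = NA_integer_, oddball_time = NA_real_),
            class = "stimulus_train")
}

#' @rdname make_train
#' @param train a regular `stimulus_train`
#' @param k interval index in `1 .. (n_base - 1)`; the oddball is inserted
#'   midway between stimuli `k` and `k + 1`
#' @export
insert_oddball <- function(train, k) {
  stopifnot(inherits(train, "stimulus_train"))
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k >= train$n_base) {
    stop("oddball interval k must satisfy 1 <= k < n_stim", call. = FALSE)
  }
  base <- make_train(train$frequency, train$n_base, train$times[1])$times
  odd_t <- (base[k] + base[k + 1]) / 2
  times <- sort(c(base, odd_t))
  structure(list(times = times, frequency = train$frequency,
                 n_base = train$n_base, oddball_index = as.integer(k),
                 oddball_time = odd_t),
            class = "stimulus_train")
}

#' Layer-4 network configuration
#'
#' Population sizes, integration settings and trial-variability settings of
#' the recurrent barrel model: 800 excitatory and 150 inhibitory neurons,
#' external thalamocortical drive to 80% of each population, forward Euler
#' integration at 0.5 ms over 1000 ms, spike times discretised to 1 ms.
#'
#' @param n_ex,n_in population sizes
#' @param tc_fraction fraction of each population receiving external TC
#'   input
#' @param dt integration step (ms)
#' @param duration simulation length (ms)
#' @param spike_time_resolution raster resolution (ms), >= dt
#' @param jitter_cv multiplicative trial-to-trial jitter (coefficient of
#'   variation) of the external AMPA and NMDA peak conductances
#' @param sigma_log log-SD of the log-normal Ex->Ex weight distribution
#' @param rho_RC correlation of sampled R_in and C_m
#' @return an object of class `network_config`
#' @export
network_config <- function(n_ex = 800, n_in = 150, tc_fraction = 0.8,
                           dt = 0.5, duration = 1000,
                           spike_time_resolution = 1, jitter_cv = 0.2,
                           sigma_log = 1.0, rho_RC = 0.5) {
  stopifnot(n_ex > 0, n_in > 0, tc_fraction >= 0, tc_fraction <= 1,
            dt > 0, duration > 0, spike_time_resolution >= dt,
            jitter_cv >= 0, sigma_log > 0)
  structure(
    list(n_ex = as.integer(n_ex), n_in = as.integer(n_in),
         tc_fraction = tc_fraction, dt = dt, duration = duration,
         spike_time_resolution = spike_time_resolution,
         jitter_cv = jitter_cv, sigma_log = sigma_log, rho_RC = rho_RC),
    class = "network_config"
  )
}

# Random weight matrix for one connection class.  Each ordered pair is
# connected independently with probability p; autapses are excluded for
# within-population classes.  Ex->Ex weights are log-normal (capped at
# g_max so the upper tail respects the class maximum); all other classes
# draw uniform fractional weights on (0, 1] of g_max.
random_weights <- function(n_pre, n_post, p, g_max, lognormal = FALSE,
                           sigma_log = 1, autapse_free = FALSE) {
  W <- matrix(0, n_pre, n_post)
  if (p > 0 && g_max > 0) {
    conn <- matrix(stats::runif(n_pre * n_post) < p, n_pre, n_post)
    if (autapse_free && n_pre == n_post) diag(conn) <- FALSE
    k <- sum(conn)
    if (k > 0) {
      w <- if (lognormal) {
        pmin(g_max * stats::rlnorm(k, meanlog = -1, sdlog = sigma_log), g_max)
      } else {
        g_max * stats::runif(k)
      }
      W[conn] <- w
    }
  } else if (autapse_free && n_pre == n_post) {
    # nothing to do; kept for symmetry
  }
  W
}

#' Build a randomly connected layer-4 network
#'
#' Realises one network: per-neuron intrinsic parameters sampled from the
#' genotype distributions (R_in and C_m jointly, see
#' [sample_neuron_population()]), directed weight matrices per connection
#' class (no autapses), per-neuron external TC weights, and the
#' thalamorecipient subsets.
#'
#' @param cfg a [network_config()]
#' @param gen a [default_genotype_params()] object
#' @param seed integer network seed
#' @return an object of class `l4_network`
#' @export
build_network <- function(cfg, gen, seed = 1L) {
  stopifnot(inherits(cfg, "network_config"), inherits(gen, "genotype_params"))
  ex <- sample_neuron_population(gen, "ex", cfg$n_ex, seed = child_seed(seed, 1),
                                 rho_RC = cfg$rho_RC)
  inn <- sample_neuron_population(gen, "in", cfg$n_in, seed = child_seed(seed, 2),
                                  rho_RC = cfg$rho_RC)
  cells <- c(ex, inn)
  field <- function(f) vapply(cells, `[[`, numeric(1), f)
  syn <- gen$synapses
  p <- gen$p_connect
  W <- with_seed(child_seed(seed, 3), list(
    `Ex->Ex` = random_weights(cfg$n_ex, cfg$n_ex, p[["Ex->Ex"]],
                              syn[["Ex->Ex"]]$g_max, lognormal = TRUE,
                              sigma_log = cfg$sigma_log, autapse_free = TRUE),
    `Ex->In` = random_weights(cfg$n_ex, cfg$n_in, p[["Ex->In"]],
                              syn[["Ex->In"]]$g_max),
    `In->Ex` = random_weights(cfg$n_in, cfg$n_ex, p[["In->Ex"]],
                              syn[["In->Ex"]]$g_max),
    `In->In` = random_weights(cfg$n_in, cfg$n_in, p[["In->In"]],
                              syn[["In->In"]]$g_max, autapse_free = TRUE)
  ))
  w_ext <- with_seed(child_seed(seed, 4), list(
    ex = syn[["TC->Ex"]]$g_max * stats::runif(cfg$n_ex),
    inn = syn[["TC->In"]]$g_max * stats::runif(cfg$n_in)
  ))
  structure(
    list(
      cfg = cfg, gen = gen, seed = as.integer(seed),
      R_in = field("R_in"), C_m = field("C_m"),
      v_rest = field("v_rest"), v_thresh = field("v_thresh"),
      v_reset = field("v_reset"), t_ref = field("t_ref"),
      W = W, w_ext = w_ext
    ),
    class = "l4_network"
  )
}

# Precompute the normalised (unit peak per undepressed event) conductance
# trace of an external stimulus train for one kinetic scheme.
external_trace <- function(times, tau_rise, tau_decay, t_conduct,
                           event_times, amplitudes) {
  spec <- synapse_spec(tau_rise, tau_decay, t_conduct = t_conduct, g_max = 1)
  conductance_train(times, spec, event_times, amplitudes)
}

#' Simulate one trial of the layer-4 network
#'
#' Forward-Euler integration of all membrane potentials at `cfg$dt`.
#' Recurrent synapses (AMPA + NMDA from Ex, GABA-A from In) are driven by
#' emitted spikes after their class conduction delays, with per-presynaptic
#' short-term depression; external TC synapses (AMPA + NMDA, depressing)
#' are driven by the stimulus train.  NMDA currents carry the
#' voltage-dependent magnesium block.  Per trial, the external peak
#' conductances are jittered multiplicatively and the thalamorecipient
#' subsets reshuffled (both governed by `seed`).  Spike times are
#' discretised to the raster resolution; threshold crossings trigger reset
#' and a 1.5 ms refractory period.
#'
#' @param net an [build_network()] object
#' @param train a [make_train()] stimulus train
#' @param seed integer trial seed
#' @param record_voltages record the membrane potential of every neuron
#'   (memory-heavy; default `FALSE`)
#' @param I_inject optional constant injected current (pA, inward
#'   positive), a scalar or one value per neuron; useful for calibration
#'   against closed-form LIF firing rates
#' @return an object of class `spike_raster`: data.frame `spikes`
#'   (`neuron`, `population`, `t_ms`), plus metadata and optionally `v`
#'   (time x neuron matrix)
#' @export
simulate_network <- function(net, train, seed = 1L, record_voltages = FALSE,
                             I_inject = 0) {
  stopifnot(inherits(net, "l4_network"), inherits(train, "stimulus_train"))
  cfg <- net$cfg
  gen <- net$gen
  syn <- gen$synapses
  dt <- cfg$dt
  n_steps <- as.integer(round(cfg$duration / dt))
  times <- (seq_len(n_steps) - 1) * dt
  n_ex <- cfg$n_ex; n_in <- cfg$n_in; n <- n_ex + n_in
  ex_idx <- seq_len(n_ex); in_idx <- n_ex + seq_len(n_in)

  # Trial randomness: per-neuron multiplicative jitter of the external
  # AMPA and NMDA peak conductances, and reshuffled thalamorecipient sets.
  trial <- with_seed(seed, {
    jit <- function(k) pmax(stats::rnorm(k, 1, cfg$jitter_cv), 0)
    list(
      jit_ampa_ex = jit(n_ex), jit_nmda_ex = jit(n_ex),
      jit_ampa_in = jit(n_in), jit_nmda_in = jit(n_in),
      recip_ex = sample(n_ex, round(cfg$tc_fraction * n_ex)),
      recip_in = sample(n_in, round(cfg$tc_fraction * n_in))
    )
  })

  # External conductance traces (shared stimulus history => scalar traces,
  # scaled per neuron by its external weight).  The NMDA component shares
  # the depression state of the AMPA component of its class.
  ext <- list()
  for (pop in c("ex", "inn")) {
    cls <- if (pop == "ex") "TC->Ex" else "TC->In"
    sp <- syn[[cls]]
    amps <- stp_event_amplitudes(sp$stp, train$times)
    ext[[pop]] <- list(
      ampa = external_trace(times, sp$tau_rise, sp$tau_decay, sp$t_conduct,
                            train$times, amps),
      nmda = external_trace(times, sp$nmda$tau_rise, sp$nmda$tau_decay,
                            sp$t_conduct, train$times, amps) * sp$nmda$ratio
    )
  }
  w_ext_ex <- numeric(n_ex); w_ext_in <- numeric(n_in)
  w_ext_ex[trial$recip_ex] <- net$w_ext$ex[trial$recip_ex]
  w_ext_in[trial$recip_in] <- net$w_ext$inn[trial$recip_in]
  w_ampa_ex <- w_ext_ex * trial$jit_ampa_ex
  w_nmda_ex <- w_ext_ex * trial$jit_nmda_ex
  w_ampa_in <- w_ext_in * trial$jit_ampa_in
  w_nmda_in <- w_ext_in * trial$jit_nmda_in

  # Recurrent class bookkeeping: kinetics, normalisation, delay (in steps),
  # decay multipliers for the rise/decay state pair.
  rec_classes <- list(
    list(name = "Ex->Ex", pre = "ex", post = ex_idx, W = net$W[["Ex->Ex"]]),
    list(name = "Ex->In", pre = "ex", post = in_idx, W = net$W[["Ex->In"]]),
    list(name = "In->Ex", pre = "in", post = ex_idx, W = net$W[["In->Ex"]]),
    list(name = "In->In", pre = "in", post = in_idx, W = net$W[["In->In"]])
  )
  st <- lapply(rec_classes, function(cl) {
    sp <- syn[[cl$name]]
    dly <- max(1L, as.integer(round(sp$t_conduct / dt)))
    n_post <- length(cl$post)
    ring_n <- dly + 1L
    kin <- list(
      dec_r = exp(-dt / sp$tau_rise), dec_d = exp(-dt / sp$tau_decay),
      f = syn_norm_factor(sp$tau_rise, sp$tau_decay),
      E = sp$E_rev, has_nmda = !is.null(sp$nmda)
    )
    if (kin$has_nmda) {
      kin$ndec_r <- exp(-dt / sp$nmda$tau_rise)
      kin$ndec_d <- exp(-dt / sp$nmda$tau_decay)
      kin$nf <- syn_norm_factor(sp$nmda$tau_rise, sp$nmda$tau_decay)
      kin$nratio <- sp$nmda$ratio
    }
    n_pre <- nrow(cl$W)
    list(
      kin = kin, dly = dly, ring = matrix(0, ring_n, n_post), ring_n = ring_n,
      x_r = numeric(n_post), x_d = numeric(n_post),
      nx_r = numeric(n_post), nx_d = numeric(n_post),
      D1 = rep(1, n_pre), D2 = rep(1, n_pre),
      t_last = rep(-Inf, n_pre), stp = sp$stp
    )
  })

  # External kinetics for current evaluation.
  ext_kin <- lapply(c(ex = "TC->Ex", inn = "TC->In"), function(cls) {
    sp <- syn[[cls]]
    list(E = sp$E_rev)
  })

  tau_m <- tau_m_ms(net$R_in, net$C_m)
  v <- net$v_rest
  refrac_until <- rep(-Inf, n)
  mg <- gen$mg
  res <- cfg$spike_time_resolution
  spike_neuron <- integer(0); spike_time <- numeric(0)
  vrec <- if (record_voltages) matrix(NA_real_, n_steps, n) else NULL

  for (i in seq_len(n_steps)) {
    t <- times[i]
    # Deliver arrivals scheduled for this step and decay synaptic states.
    for (ci in seq_along(st)) {
      s <- st[[ci]]
      ptr <- (i %% s$ring_n) + 1L
      arr <- s$ring[ptr, ]
      if (any(arr != 0)) s$ring[ptr, ] <- 0
      s$x_r <- s$x_r * s$kin$dec_r + arr
      s$x_d <- s$x_d * s$kin$dec_d + arr
      if (s$kin$has_nmda) {
        s$nx_r <- s$nx_r * s$kin$ndec_r + arr
        s$nx_d <- s$nx_d * s$kin$ndec_d + arr
      }
      st[[ci]] <- s
    }

    # Total synaptic current per neuron (outward positive).
    I <- numeric(n)
    gmb <- mg_block(v, mg)
    for (ci in seq_along(st)) {
      s <- st[[ci]]; post <- rec_classes[[ci]]$post
      g_ampa <- s$kin$f * (s$x_d - s$x_r)
      I[post] <- I[post] + g_ampa * (v[post] - s$kin$E)
      if (s$kin$has_nmda) {
        g_nmda <- s$kin$nratio * s$kin$nf * (s$nx_d - s$nx_r)
        I[post] <- I[post] + gmb[post] * g_nmda * v[post]
      }
    }
    I[ex_idx] <- I[ex_idx] +
      w_ampa_ex * ext$ex$ampa[i] * (v[ex_idx] - ext_kin$ex$E) +
      w_nmda_ex * gmb[ex_idx] * ext$ex$nmda[i] * v[ex_idx]
    I[in_idx] <- I[in_idx] +
      w_ampa_in * ext$inn$ampa[i] * (v[in_idx] - ext_kin$inn$E) +
      w_nmda_in * gmb[in_idx] * ext$inn$nmda[i] * v[in_idx]

    # Forward Euler subthreshold update (refractory neurons clamped).
    active <- t >= refrac_until
    dv <- dt * (-(v - net$v_rest) / tau_m - (I - I_inject) / net$C_m)
    v[active] <- v[active] + dv[active]
    if (any(abs(v) > 200)) {
      stop("numerical blow-up: |v| exceeded 200 mV at t = ", t,
           " ms; reduce dt or conductances", call. = FALSE)
    }

    fired <- active & v >= net$v_thresh
    if (any(fired)) {
      idx <- which(fired)
      spike_neuron <- c(spike_neuron, idx)
      spike_time <- c(spike_time, rep(floor(t / res) * res, length(idx)))
      v[idx] <- net$v_reset[idx]
      refrac_until[idx] <- t + net$t_ref[idx]
      fired_ex <- idx[idx <= n_ex]
      fired_in <- idx[idx > n_ex] - n_ex
      for (ci in seq_along(st)) {
        cl <- rec_classes[[ci]]
        pre_f <- if (cl$pre == "ex") fired_ex else fired_in
        if (!length(pre_f)) next
        s <- st[[ci]]
        # Event-wise depression update for the firing presynaptic neurons.
        if (!is.null(s$stp)) {
          dtp <- t - s$t_last[pre_f]
          seen <- is.finite(dtp)
          if (any(seen)) {
            s$D1[pre_f[seen]] <- 1 - (1 - s$D1[pre_f[seen]]) *
              exp(-dtp[seen] / s$stp$tau_D1)
            s$D2[pre_f[seen]] <- 1 - (1 - s$D2[pre_f[seen]]) *
              exp(-dtp[seen] / s$stp$tau_D2)
          }
          A <- s$D1[pre_f] * s$D2[pre_f]
          s$D1[pre_f] <- s$D1[pre_f] * s$stp$d1
          s$D2[pre_f] <- s$D2[pre_f] * s$stp$d2
          s$t_last[pre_f] <- t
        } else A <- rep(1, length(pre_f))
        inc <- if (length(pre_f) == 1L) {
          A * cl$W[pre_f, ]
        } else {
          colSums(A * cl$W[pre_f, , drop = FALSE])
        }
        slot <- ((i + s$dly) %% s$ring_n) + 1L
        s$ring[slot, ] <- s$ring[slot, ] + inc
        st[[ci]] <- s
      }
    }
    if (record_voltages) vrec[i, ] <- v
  }

  spikes <- data.frame(
    neuron = spike_neuron,
    population = ifelse(spike_neuron <= n_ex, "Ex", "In"),
    t_ms = spike_time
  )
  spikes <- spikes[order(spikes$t_ms, spikes$neuron), , drop = FALSE]
  rownames(spikes) <- NULL
  structure(
    list(spikes = spikes, n_ex = n_ex, n_in = n_in,
         duration = cfg$duration, train = train, seed = as.integer(seed),
         v = vrec, times = if (record_voltages) times else NULL),
    class = "spike_raster"
  )
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike_raster: %d spikes (%d Ex, %d In) over %g ms\n",
              nrow(x$spikes), sum(x$spikes$population == "Ex"),
              sum(x$spikes$population == "In"), x$duration))
  invisible(x)
}

#' Run a multi-seed, multi-trial network experiment
#'
#' Builds one network per network seed and genotype, then simulates every
#' combination of stimulation condition (frequency x regular/oddball
#' position) and trial.  Every random draw derives from `seed`, so the full
#' dataset is reproducible from the arguments alone.
#'
#' @param genotypes character vector of genotype labels
#' @param frequencies stimulation frequencies (Hz)
#' @param n_seeds number of random network realisations per genotype
#' @param n_trials trials per condition
#' @param oddball_positions integer vector of oddball interval positions
#'   (empty for regular-only experiments)
#' @param cfg a [network_config()]
#' @param n_stim stimuli per train
#' @param t0 first stimulus time (ms)
#' @param seed master integer seed
#' @return a list of class `l4_experiment` with elements `runs` (list of
#'   records: `genotype`, `net_seed`, `frequency`, `oddball` (NA or
#'   position), `trial`, `raster`) and `manifest` (all seeds and settings)
#' @export
run_experiment <- function(genotypes = c("WT", "KO"), frequencies = 20,
                           n_seeds = 1, n_trials = 10,
                           oddball_positions = integer(0),
                           cfg = network_config(), n_stim = 5, t0 = 100,
                           seed = 1L) {
  runs <- list()
  manifest <- list(seed = as.integer(seed), genotypes = genotypes,
                   frequencies = frequencies, n_seeds = n_seeds,
                   n_trials = n_trials, oddball_positions = oddball_positions,
                   n_stim = n_stim, t0 = t0, cfg = unclass(cfg))
  k <- 0L
  for (gl in genotypes) {
    gen <- default_genotype_params(gl)
    for (si in seq_len(n_seeds)) {
      net_seed <- child_seed(seed, 100 + si + 1000 * match(gl, genotypes))
      net <- build_network(cfg, gen, seed = net_seed)
      conds <- c(list(list(odd = NA_integer_)),
                 lapply(oddball_positions, function(p)
                   list(odd = as.integer(p))))
      for (f in frequencies) {
        base <- make_train(f, n_stim, t0)
        for (cond in conds) {
          train <- if (is.na(cond$odd)) base else insert_oddball(base, cond$odd)
          for (tr in seq_len(n_trials)) {
            k <- k + 1L
            raster <- simulate_network(net, train,
                                       seed = child_seed(net_seed, k))
            runs[[k]] <- list(genotype = gl, net_seed = net_seed,
                              frequency = f, oddball = cond$odd,
                              trial = tr, raster = raster)
          }
        }
      }
    }
  }
  structure(list(runs = runs, manifest = manifest), class = "l4_experiment")
}

#' Write / read a raster as tidy CSV
#'
#' Columns: `trial`, `neuron`, `population`, `t_ms`.
#'
#' @param raster a `spike_raster` (or a data.frame already in tidy form)
#' @param path file path
#' @param trial trial id recorded in the file
#' @export
write_raster_csv <- function(raster, path, trial = 1L) {
  df <- if (inherits(raster, "spike_raster")) raster$spikes else raster
  if (!("trial" %in% names(df))) df <- cbind(trial = trial, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("trial", "neuron", "population", "t_ms")
  if (!all(need %in% names(df))) {
    stop("malformed raster CSV; expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df
}
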