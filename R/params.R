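#' Passive and threshold parameters of one leaky integrate-and-fire cell
#'
#' Container for the subthreshold and spiking parameters of a single model
#' neuron.  The membrane time constant is derived as `R_in * C_m` (with the
#' MOhm.pF -> ms conversion, see [tau_m_ms()]) rather than stored, so the
#' three passive quantities can never fall out of step.
#'
#' @param R_in input resistance (MOhm), > 0
#' @param C_m whole-cell capacitance (pF), > 0
#' @param v_rest resting membrane potential (mV)
#' @param v_thresh spike threshold (mV)
#' @param v_reset post-spike reset potential (mV), must be < `v_thresh`
#' @param t_ref absolute refractory period (ms), >= 0
#' @return an object of class `neuron_params`
#' @examples
#' np <- neuron_params(412, 94, -64, -58, -60, 1.5)
#' tau_m_ms(np$R_in, np$C_m)
#' @export
neuron_params <- function(R_in, C_m, v_rest = -64, v_thresh = -55.8,
                          v_reset = -57.5, t_ref = 1.5) {
  stopifnot(
    is.finite(R_in), R_in > 0,
    is.finite(C_m), C_m > 0,
    is.finite(v_rest), is.finite(v_thresh), is.finite(v_reset),
    v_reset < v_thresh,
    is.finite(t_ref), t_ref >= 0
  )
  structure(
    list(R_in = R_in, C_m = C_m, v_rest = v_rest, v_thresh = v_thresh,
         v_reset = v_reset, t_ref = t_ref),
    class = "neuron_params"
  )
}

#' Two-factor short-term depression parameters
#'
#' Each presynaptic spike multiplies two depression state variables by the
#' per-spike factors `d1` and `d2`; between spikes each state recovers
#' exponentially towards 1 with its own time constant.
#'
#' @param d1,d2 per-spike depression factors, each in (0, 1]
#' @param tau_D1,tau_D2 recovery time constants (ms), > 0
#' @return an object of class `stp_params`
#' @export
stp_params <- function(d1, d2, tau_D1, tau_D2) {
  stopifnot(
    d1 > 0, d1 <= 1, d2 > 0, d2 <= 1,
    tau_D1 > 0, tau_D2 > 0
  )
  structure(list(d1 = d1, d2 = d2, tau_D1 = tau_D1, tau_D2 = tau_D2),
            class = "stp_params")
}

#' Synaptic connection class specification
#'
#' Kinetics, conduction delay, peak conductance and reversal potential of a
#' delayed-difference-of-exponentials conductance synapse, optionally with
#' short-term depression.
#'
#' @param tau_rise,tau_decay rise and decay time constants (ms);
#'   `tau_rise < tau_decay` is required (the normalised waveform is singular
#'   at equality)
#' @param t_conduct axonal/synaptic conduction delay (ms), >= 0
#' @param g_max peak conductance (nS), >= 0
#' @param E_rev reversal potential (mV)
#' @param stp an [stp_params()] object, or `NULL` for a static synapse
#' @param nmda optional list describing a co-released NMDA component
#'   (`ratio` of NMDA to AMPA peak conductance, `tau_rise`, `tau_decay`)
#' @return an object of class `synapse_spec`
#' @export
synapse_spec <- function(tau_rise, tau_decay, t_conduct = 1, g_max = 1,
                         E_rev = 0, stp = NULL, nmda = NULL) {
  if (tau_rise >= tau_decay) {
    stop("tau_rise must be strictly less than tau_decay; use ",
         "epsilon-separated constants for an effectively single-exponential ",
         "synapse", call. = FALSE)
  }
  stopifnot(tau_rise > 0, t_conduct >= 0, g_max >= 0, is.finite(E_rev))
  if (!is.null(stp)) stopifnot(inherits(stp, "stp_params"))
  structure(
    list(tau_rise = tau_rise, tau_decay = tau_decay, t_conduct = t_conduct,
         g_max = g_max, E_rev = E_rev, stp = stp, nmda = nmda),
    class = "synapse_spec"
  )
}

#' Voltage-dependent magnesium block of NMDA receptors
#'
#' Parameters of the sigmoidal blockade factor
#' `G(v) = 1 / (1 + exp(-a v) [Mg]_out / b)`.
#'
#' @param a voltage sensitivity (1/mV); default 0.062
#' @param b magnesium sensitivity constant (mM); default 3.57
#' @param mg_out extracellular magnesium concentration (mM); default 1.3
#' @return an object of class `mg_block_params`
#' @export
mg_block_params <- function(a = 0.062, b = 3.57, mg_out = 1.3) {
  stopifnot(a > 0, b > 0, mg_out >= 0)
  structure(list(a = a, b = b, mg_out = mg_out), class = "mg_block_params")
}

# Connection-class labels used throughout the package.
SYNAPSE_CLASSES <- c("TC->Ex", "TC->In", "Ex->Ex", "Ex->In", "In->Ex", "In->In")

# Fractional standard deviation applied to jittered scalar parameters when a
# measured dispersion is not printed in the main text (placeholder).
DEFAULT_CV <- 0.15

#' Default genotype parameter sets
#'
#' Returns the full parameter table for the wild-type (`"WT"`) or Fmr1
#' knock-out (`"KO"`) layer-4 circuit model: intrinsic parameters of
#' excitatory stellate cells (Ex) and fast-spiking interneurons (In) with
#' per-field dispersions, one [synapse_spec()] per connection class,
#' connection probabilities, and the onset lag of feed-forward inhibition
#' relative to thalamocortical excitation (`ei_lag`).
#'
#' Values printed in the source study are used directly: Ex input resistance
#' (WT 412 MOhm, KO 609 MOhm), Ex capacitance (WT 94 pF, KO 89 pF), resting
#' potential -64 mV, refractory period 1.5 ms, FFI reversal -71 mV,
#' glutamatergic reversal 0 mV, extracellular Mg 1.3 mM.  All remaining
#' entries (interneuron passives, connection probabilities, synaptic
#' kinetics, short-term depression coefficients, E-I lag, spike threshold
#' and reset) are placeholders chosen once from the qualitative genotype
#' contrasts reported for P10-11 tissue -- KO: slower feed-forward IPSC
#' kinetics and longer onset lag, stronger short-term depression
#' (disproportionately of the FF-IPSC), reduced FS<->SC connectivity,
#' unchanged EPSC kinetics and SC-SC connectivity -- and are flagged in the
#' `placeholders` attribute.
#'
#' @param label `"WT"` or `"KO"`
#' @return an object of class `genotype_params`
#' @examples
#' wt <- default_genotype_params("WT")
#' wt$ex_cell$mean$R_in   # 412
#' @export
default_genotype_params <- function(label) {
  if (!is.character(label) || length(label) != 1 || !label %in% c("WT", "KO")) {
    stop("unknown genotype label ", deparse(substitute(label)),
         "; valid labels are \"WT\" and \"KO\"", call. = FALSE)
  }
  wt <- identical(label, "WT")

  ex_mean <- if (wt) neuron_params(412, 94) else neuron_params(609, 89)
  in_mean <- if (wt) neuron_params(300, 40) else neuron_params(400, 38)
  cell_sd <- function(m) {
    c(R_in = DEFAULT_CV * m$R_in, C_m = DEFAULT_CV * m$C_m,
      v_rest = 2, v_thresh = 1, v_reset = 0, t_ref = 0)
  }

  # Short-term depression per class.  KO depresses more at thalamocortical
  # and FFI-pathway synapses, most strongly for the feed-forward IPSC;
  # Ex->Ex depression does not differ between genotypes.
  stp_tab <- if (wt) {
    list(
      `TC->Ex` = stp_params(0.85, 0.98, 50, 800),
      `TC->In` = stp_params(0.70, 0.97, 60, 800),
      `Ex->Ex` = stp_params(0.80, 0.97, 60, 800),
      `Ex->In` = stp_params(0.75, 0.96, 60, 800),
      `In->Ex` = stp_params(0.85, 0.96, 70, 900),
      `In->In` = stp_params(0.80, 0.97, 60, 800)
    )
  } else {
    list(
      `TC->Ex` = stp_params(0.81, 0.975, 60, 900),
      `TC->In` = stp_params(0.50, 0.93, 80, 1000),
      `Ex->Ex` = stp_params(0.80, 0.97, 60, 800),
      `Ex->In` = stp_params(0.60, 0.94, 70, 900),
      `In->Ex` = stp_params(0.48, 0.92, 80, 1000),
      `In->In` = stp_params(0.80, 0.97, 60, 800)
    )
  }

  nmda_comp <- list(ratio = 0.5, tau_rise = 5, tau_decay = 75)
  nmda_rec <- list(ratio = 0.25, tau_rise = 5, tau_decay = 75)
  gaba_rise  <- if (wt) 0.8 else 1.2
  gaba_decay <- if (wt) 5.0 else 7.0

  synapses <- list(
    `TC->Ex` = synapse_spec(1.0, 8.0, t_conduct = 1.0, g_max = 2.2,
                            E_rev = 0, stp = stp_tab[["TC->Ex"]],
                            nmda = nmda_comp),
    `TC->In` = synapse_spec(0.5, 2.5, t_conduct = 1.0, g_max = 0.8,
                            E_rev = 0, stp = stp_tab[["TC->In"]],
                            nmda = nmda_comp),
    `Ex->Ex` = synapse_spec(1.0, 4.0, t_conduct = 1.5, g_max = 0.15,
                            E_rev = 0, stp = stp_tab[["Ex->Ex"]],
                            nmda = nmda_rec),
    `Ex->In` = synapse_spec(0.4, 1.8, t_conduct = 1.0, g_max = 0.4,
                            E_rev = 0, stp = stp_tab[["Ex->In"]],
                            nmda = nmda_rec),
    `In->Ex` = synapse_spec(gaba_rise, gaba_decay, t_conduct = 1.0,
                            g_max = 3.0, E_rev = -71,
                            stp = stp_tab[["In->Ex"]]),
    `In->In` = synapse_spec(0.8, 6.0, t_conduct = 1.0, g_max = 2.0,
                            E_rev = -71, stp = stp_tab[["In->In"]])
  )

  p_connect <- if (wt) {
    c(`Ex->Ex` = 0.28, `Ex->In` = 0.50, `In->Ex` = 0.55, `In->In` = 0)
  } else {
    c(`Ex->Ex` = 0.28, `Ex->In` = 0.30, `In->Ex` = 0.35, `In->In` = 0)
  }

  structure(
    list(
      label = label,
      ex_cell = list(mean = ex_mean, sd = cell_sd(ex_mean)),
      in_cell = list(mean = in_mean, sd = cell_sd(in_mean)),
      synapses = synapses,
      synapse_cv = DEFAULT_CV,
      p_connect = p_connect,
      ei_lag = if (wt) 2.2 else 3.5,
      mg = mg_block_params()
    ),
    class = "genotype_params",
    placeholders = c(
      "in_cell passives", "v_thresh", "v_reset", "p_connect",
      "synaptic kinetics and g_max", "STP coefficients", "ei_lag",
      "all dispersions"
    )
  )
}

#' @export
print.genotype_params <- function(x, ...) {
  cat("Layer-4 genotype parameter set:", x$label, "\n")
  cat(sprintf("  Ex: R_in %.0f MOhm, C_m %.0f pF (tau_m %.1f ms)\n",
              x$ex_cell$mean$R_in, x$ex_cell$mean$C_m,
              tau_m_ms(x$ex_cell$mean$R_in, x$ex_cell$mean$C_m)))
  cat(sprintf("  In: R_in %.0f MOhm, C_m %.0f pF (tau_m %.1f ms)\n",
              x$in_cell$mean$R_in, x$in_cell$mean$C_m,
              tau_m_ms(x$in_cell$mean$R_in, x$in_cell$mean$C_m)))
  cat("  E-I lag:", x$ei_lag, "ms\n")
  cat("  Placeholder (non-printed) fields:",
      paste(attr(x, "placeholders"), collapse = ", "), "\n")
  invisible(x)
}

#' Sample a population of neurons from a genotype parameter set
#'
#' Draws `n` neuron parameter records.  Input resistance and capacitance are
#' sampled jointly from a bivariate Gaussian with correlation `rho_RC`
#' ("private and shared variance"); all other fields vary independently
#' (truncated Gaussian).  Sampled positives are clipped away from zero and
#' thresholds kept above resets.
#'
#' @param gen a [default_genotype_params()] object
#' @param which `"ex"` or `"in"`
#' @param n number of neurons (>= 0)
#' @param seed integer seed; identical seeds give identical populations
#' @param rho_RC correlation between R_in and C_m, in `[0, 1]`; default 0.5
#' @return a list of `n` [neuron_params()] objects
#' @export
sample_neuron_population <- function(gen, which = c("ex", "in"), n,
                                     seed = 1L, rho_RC = 0.5) {
  stopifnot(inherits(gen, "genotype_params"))
  which <- match.arg(which)
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != round(n)) {
    stop("n must be a non-negative integer", call. = FALSE)
  }
  stopifnot(rho_RC >= 0, rho_RC <= 1)
  n <- as.integer(n)
  if (n == 0L) return(list())
  cell <- if (which == "ex") gen$ex_cell else gen$in_cell
  m <- cell$mean; s <- cell$sd

  with_seed(seed, {
    # Bivariate Gaussian via 2x2 Cholesky: C_m correlated with R_in.
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    R_in <- m$R_in + s[["R_in"]] * z1
    C_m  <- m$C_m + s[["C_m"]] * (rho_RC * z1 + sqrt(1 - rho_RC^2) * z2)
    v_rest   <- stats::rnorm(n, m$v_rest, s[["v_rest"]])
    v_thresh <- stats::rnorm(n, m$v_thresh, s[["v_thresh"]])
    v_reset  <- rep(m$v_reset, n)
    t_ref    <- rep(m$t_ref, n)

    R_in <- pmax(R_in, 1)
    C_m <- pmax(C_m, 1)
    v_thresh <- pmax(v_thresh, v_reset + 0.5)
    lapply(seq_len(n), function(i) {
      neuron_params(R_in[i], C_m[i], v_rest[i], v_thresh[i],
                    v_reset[i], t_ref[i])
    })
  })
}

#' Synthetic short-term depression curves with known ground truth
#'
#' Generates normalised amplitude trains at several stimulation frequencies
#' from a known set of depression parameters, optionally corrupted by
#' additive Gaussian noise.  Used as a fit-recovery fixture for [fit_stp()].
#'
#' @param stp ground-truth [stp_params()]
#' @param frequencies stimulation frequencies (Hz), all > 0
#' @param n_stim number of stimuli per train (>= 2)
#' @param noise_sd additive Gaussian noise SD on each amplitude (>= 0)
#' @param seed integer seed for the noise
#' @return a list of class `depression_fixture` with elements `curves`
#'   (data.frame: `frequency_hz`, `stimulus_index`, `amplitude_norm`),
#'   `truth`, `noise_sd`, `seed`
#' @export
generate_depression_fixture <- function(stp, frequencies, n_stim = 5,
                                        noise_sd = 0, seed = 1L) {
  stopifnot(inherits(stp, "stp_params"), all(frequencies > 0), n_stim >= 2)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  curves <- do.call(rbind, lapply(frequencies, function(f) {
    data.frame(frequency_hz = f, stimulus_index = seq_len(n_stim),
               amplitude_norm = simulate_amplitude_train(stp, f, n_stim))
  }))
  if (noise_sd > 0) {
    curves$amplitude_norm <- with_seed(seed, {
      curves$amplitude_norm + stats::rnorm(nrow(curves), 0, noise_sd)
    })
  }
  structure(list(curves = curves, truth = stp, noise_sd = noise_sd,
                 seed = seed),
            class = "depression_fixture")
}

# ---- JSON serialisation -----------------------------------------------------

BARRELSIM_SCHEMA_VERSION <- 1L

#' Write / read a genotype parameter set as JSON
#'
#' The file carries a mandatory `schema_version` field; reading a file with
#' a different major schema is an error.
#'
#' @param gen a `genotype_params` object
#' @param path file path
#' @return `write_genotype_json` returns `path` invisibly;
#'   `read_genotype_json` returns a `genotype_params` object.
#' @export
write_genotype_json <- function(gen, path) {
  stopifnot(inherits(gen, "genotype_params"))
  strip <- function(x) {
    if (is.list(x)) return(lapply(unclass(x), strip))
    # named atomic vectors must serialise as objects, not bare arrays
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    x
  }
  obj <- list(schema_version = BARRELSIM_SCHEMA_VERSION, genotype = strip(gen))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_genotype_json
#' @export
read_genotype_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version)) {
    stop("config file lacks the mandatory schema_version field", call. = FALSE)
  }
  if (obj$schema_version != BARRELSIM_SCHEMA_VERSION) {
    stop("unsupported schema_version ", obj$schema_version, call. = FALSE)
  }
  g <- obj$genotype
  restore_syn <- function(s) {
    synapse_spec(s$tau_rise, s$tau_decay, s$t_conduct, s$g_max, s$E_rev,
                 stp = if (!is.null(s$stp))
                   stp_params(s$stp$d1, s$stp$d2, s$stp$tau_D1, s$stp$tau_D2),
                 nmda = s$nmda)
  }
  restore_cell <- function(cl) {
    list(mean = do.call(neuron_params, cl$mean), sd = unlist(cl$sd))
  }
  structure(
    list(
      label = g$label,
      ex_cell = restore_cell(g$ex_cell),
      in_cell = restore_cell(g$in_cell),
      synapses = lapply(g$synapses, restore_syn),
      synapse_cv = g$synapse_cv,
      p_connect = unlist(g$p_connect),
      ei_lag = g$ei_lag,
      mg = mg_block_params(g$mg$a, g$mg$b, g$mg$mg_out)
    ),
    class = "genotype_params"
  )
}
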