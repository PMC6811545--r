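#' Two-factor short-term synaptic depression
#'
#' The stimulus-evoked response amplitude of a depressing synapse is the
#' product of a steady-state amplitude and two dynamic depression factors,
#' `A = A0 * D1 * D2`.  After each presynaptic spike each factor is
#' multiplied by its per-spike constant (`D1 -> D1 d1`, `D2 -> D2 d2`);
#' between spikes each factor recovers exponentially back towards 1 with
#' first-order kinetics (`tau_D dD/dt = 1 - D`).  Depression accumulates
#' whenever the inter-stimulus interval is short relative to recovery.
#'
#' @name stp-model
NULL

#' Fresh depression state
#' @return a list with `D1`, `D2` (both 1) and `t_last` (ms)
#' @param t0 time of state initialisation (ms)
#' @export
stp_state <- function(t0 = 0) list(D1 = 1, D2 = 1, t_last = t0)

#' Apply the per-spike depression step
#'
#' @param state a depression state from [stp_state()]
#' @param p an [stp_params()] object
#' @return the updated state
#' @export
stp_on_spike <- function(state, p) {
  state$D1 <- state$D1 * p$d1
  state$D2 <- state$D2 * p$d2
  state
}

#' Recover the depression state over an interval
#'
#' Uses the exact solution of the first-order recovery ODE,
#' `D(t + dt) = 1 - (1 - D(t)) exp(-dt / tau_D)`, applied to each factor
#' with its own time constant (the equation is linear, so the closed form
#' is exact; no Euler stepping).
#'
#' @param state a depression state
#' @param dt elapsed time (ms), >= 0
#' @param p an [stp_params()] object
#' @return the updated state
#' @export
stp_recover <- function(state, dt, p) {
  if (dt < 0) stop("dt must be >= 0", call. = FALSE)
  state$D1 <- 1 - (1 - state$D1) * exp(-dt / p$tau_D1)
  state$D2 <- 1 - (1 - state$D2) * exp(-dt / p$tau_D2)
  state$t_last <- state$t_last + dt
  state
}

#' Normalised amplitude train of a depressing synapse
#'
#' Simulates the per-stimulus response amplitudes of a regular stimulus
#' train.  The amplitude at each stimulus is read out *before* that
#' stimulus' depression step is applied, so the first amplitude is always 1.
#'
#' @param p an [stp_params()] object
#' @param frequency stimulation frequency (Hz), > 0
#' @param n_stim number of stimuli (>= 1)
#' @return numeric vector of `n_stim` normalised amplitudes in (0, 1]
#' @examples
#' simulate_amplitude_train(stp_params(0.7, 0.9, 200, 50), 20, 5)
#' @export
simulate_amplitude_train <- function(p, frequency, n_stim) {
  stopifnot(inherits(p, "stp_params"), frequency > 0, n_stim >= 1)
  isi <- 1000 / frequency
  D1 <- 1; D2 <- 1
  amps <- numeric(n_stim)
  for (k in seq_len(n_stim)) {
    amps[k] <- D1 * D2
    D1 <- D1 * p$d1
    D2 <- D2 * p$d2
    if (k < n_stim) {
      D1 <- 1 - (1 - D1) * exp(-isi / p$tau_D1)
      D2 <- 1 - (1 - D2) * exp(-isi / p$tau_D2)
    }
  }
  amps
}

#' Fit depression parameters to multi-frequency amplitude curves
#'
#' Least-squares fit of the two-factor depression model to normalised
#' amplitude trains recorded at several stimulation frequencies, all
#' frequencies equally weighted, using a Levenberg-Marquardt search.  The
#' per-spike factors are constrained to (0, 1] by a logistic
#' reparameterisation and the recovery time constants to positivity by a
#' log transform; three start points guard against local minima.
#'
#' @param curves a `depression_fixture` from
#'   [generate_depression_fixture()], or a data.frame with columns
#'   `frequency_hz`, `stimulus_index`, `amplitude_norm`
#' @return a list of class `stp_fit`: `params` ([stp_params()]),
#'   `residual_norm`, `converged`, `n_points`
#' @export
fit_stp <- function(curves) {
  if (inherits(curves, "depression_fixture")) curves <- curves$curves
  stopifnot(is.data.frame(curves),
            all(c("frequency_hz", "stimulus_index", "amplitude_norm") %in%
                  names(curves)))
  freqs <- sort(unique(curves$frequency_hz))
  if (length(freqs) < 2) stop("need curves at >= 2 frequencies", call. = FALSE)
  if (min(table(curves$frequency_hz)) < 3) {
    stop("need >= 3 stimuli per frequency", call. = FALSE)
  }

  logistic <- function(x) 1 / (1 + exp(-x))
  predict_all <- function(theta) {
    p <- stp_params(logistic(theta[1]), logistic(theta[2]),
                    exp(theta[3]), exp(theta[4]))
    unlist(lapply(freqs, function(f) {
      idx <- curves$stimulus_index[curves$frequency_hz == f]
      simulate_amplitude_train(p, f, max(idx))[idx]
    }))
  }
  obs <- unlist(lapply(freqs, function(f) {
    curves$amplitude_norm[curves$frequency_hz == f]
  }))

  starts <- list(
    c(qlogis(0.7), qlogis(0.95), log(100), log(500)),
    c(qlogis(0.5), qlogis(0.85), log(50), log(1000)),
    c(qlogis(0.9), qlogis(0.7), log(300), log(80))
  )
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = th0,
        fn = function(theta) predict_all(theta) - obs,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) {
    return(structure(list(params = NULL, residual_norm = NA_real_,
                          converged = FALSE, n_points = length(obs)),
                     class = "stp_fit"))
  }
  th <- best$fit$par
  # the two factors are exchangeable; canonicalise with tau_D1 <= tau_D2
  fac <- list(c(logistic(th[1]), exp(th[3])), c(logistic(th[2]), exp(th[4])))
  fac <- fac[order(vapply(fac, `[`, numeric(1), 2))]
  structure(
    list(
      params = stp_params(fac[[1]][1], fac[[2]][1],
                          fac[[1]][2], fac[[2]][2]),
      residual_norm = best$rn,
      converged = best$fit$info %in% 1:4,
      n_points = length(obs)
    ),
    class = "stp_fit"
  )
}

#' Bi-exponential decay fit
#'
#' Fits `y = a1 exp(-x / tau1) + a2 exp(-x / tau2) + c` by
#' Levenberg-Marquardt least squares, the convention used to quantify
#' per-stimulus depression curves (the abscissa is the stimulus number).
#' Time constants are returned with `tau1 <= tau2`.
#'
#' @param x abscissa (stimulus index or time)
#' @param y ordinate (normalised amplitude)
#' @return a list of class `biexp_fit`: `a1`, `tau1`, `a2`, `tau2`, `c`,
#'   `residual_norm`, `converged`
#' @export
fit_biexponential <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  span <- max(x) - min(x)
  if (span <= 0) stop("x values must not be constant", call. = FALSE)
  model <- function(th) {
    th[1] * exp(-x / exp(th[2])) + th[3] * exp(-x / exp(th[4])) + th[5]
  }
  amp0 <- max(y) - min(y)
  starts <- list(
    c(amp0 / 2, log(span / 5), amp0 / 2, log(span), min(y)),
    c(amp0, log(span / 10), amp0 / 4, log(2 * span), min(y)),
    c(amp0 / 4, log(span / 2), amp0, log(span / 3), mean(y))
  )
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = function(th) model(th) - y,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) {
    return(structure(list(a1 = NA_real_, tau1 = NA_real_, a2 = NA_real_,
                          tau2 = NA_real_, c = NA_real_,
                          residual_norm = NA_real_, converged = FALSE),
                     class = "biexp_fit"))
  }
  th <- best$fit$par
  comps <- list(c(a = th[1], tau = exp(th[2])), c(a = th[3], tau = exp(th[4])))
  ord <- order(vapply(comps, `[[`, numeric(1), "tau"))
  comps <- comps[ord]
  structure(
    list(a1 = comps[[1]][["a"]], tau1 = comps[[1]][["tau"]],
         a2 = comps[[2]][["a"]], tau2 = comps[[2]][["tau"]],
         c = th[5], residual_norm = best$rn,
         converged = best$fit$info %in% 1:4),
    class = "biexp_fit"
  )
}

#' Write / read depression curves as tidy CSV
#'
#' Columns: `frequency_hz`, `stimulus_index`, `amplitude_norm`.
#'
#' @param curves data.frame of depression curves
#' @param path file path
#' @return `read_depression_csv` returns the data.frame.
#' @export
write_depression_csv <- function(curves, path) {
  if (inherits(curves, "depression_fixture")) curves <- curves$curves
  stopifnot(all(c("frequency_hz", "stimulus_index", "amplitude_norm") %in%
                  names(curves)))
  utils::write.csv(curves, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_depression_csv
#' @export
read_depression_csv <- function(path) {
  curves <- utils::read.csv(path)
  need <- c("frequency_hz", "stimulus_index", "amplitude_norm")
  if (!all(need %in% names(curves))) {
    stop("malformed depression CSV; expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  curves
}
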