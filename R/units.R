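#' Unit conventions
#'
#' All quantities in this package use a single internal unit system:
#' millivolts (mV), milliseconds (ms), nanosiemens (nS), picoamps (pA),
#' picofarads (pF) and megaohms (MOhm).  These combine consistently:
#' `nS * mV = pA`, `pA * ms / pF = mV`.  The only conversion that needs
#' care is the membrane time constant, `MOhm * pF = microseconds`, so a
#' division by 1000 is required to express it in ms.  That conversion is
#' centralised here.
#'
#' @param R_in input resistance (MOhm)
#' @param C_m membrane capacitance (pF)
#' @return membrane time constant in ms
#' @examples
#' tau_m_ms(412, 94) # ~38.7 ms
#' @export
tau_m_ms <- function(R_in, C_m) {
  stopifnot(all(R_in > 0), all(C_m > 0))
  R_in * C_m / 1000
}

#' Leak conductance from input resistance
#'
#' `mV / MOhm = nA`, so the leak conductance in nS is `1000 / R_in`.
#'
#' @param R_in input resistance (MOhm)
#' @return leak conductance in nS
#' @export
leak_conductance_ns <- function(R_in) {
  stopifnot(all(R_in > 0))
  1000 / R_in
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards.  Every stochastic operation in the package
# funnels through this, so results are pure functions of (inputs, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    stopifnot(length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a bounded child seed from a parent seed and a stream index, so a
# single user-facing seed can drive independent sub-streams while staying
# within 32-bit integer range.
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 7L + 11L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
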