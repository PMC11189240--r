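#' KLVA channel opening and closing rates
#'
#' First-order kinetics of the low-voltage-activated potassium (KLVA)
#' conductance. The opening rate is `alpha(V) = 0.5 exp(+(V + 50)/16)` and the
#' closing rate `beta(V) = 0.5 exp(-(V + 50)/16)`, both in 1/ms.
#'
#' @param V Membrane potential (mV); vectorized.
#' @return A list with numeric components `alpha` and `beta` (1/ms).
#' @seealso [klva_steady_state()]
#' @export
klva_rates <- function(V) {
  if (!is.numeric(V) || any(!is.finite(V)))
    stop("V must be finite numeric")
  e <- exp((V + 50) / 16)
  list(alpha = 0.5 * e, beta = 0.5 / e)
}

#' KLVA steady-state activation and time constant
#'
#' @param V Membrane potential (mV); vectorized.
#' @return A list with `d_inf` (steady-state open fraction, in (0,1)) and
#'   `tau_d` (relaxation time constant, ms).
#' @export
klva_steady_state <- function(V) {
  r <- klva_rates(V)
  list(d_inf = r$alpha / (r$alpha + r$beta), tau_d = 1 / (r$alpha + r$beta))
}

# dd_inf/dV in 1/mV; d_inf is a logistic in V with slope parameter 8 mV
klva_dinf_slope <- function(V) {
  d <- klva_steady_state(V)$d_inf
  d * (1 - d) / 8
}

#' Exponential spike-generating current
#'
#' The depolarizing current of the exponential IF variants,
#' `I_exp = g_T K_T exp((V - V_T)/K_T)` (pA). To keep forward-Euler
#' integration finite during the spike upswing, the exponent is clipped at
#' `clip` before exponentiation.
#'
#' @param V Membrane potential (mV); vectorized.
#' @param p An [lso_params()] object.
#' @param clip Ceiling on the exponent `(V - V_T)/K_T` (default 20).
#' @return Current in pA (0 for variants with `g_T = 0`).
#' @export
exp_current <- function(V, p, clip = 20) {
  if (p$g_T < 0) stop("g_T must be non-negative")
  if (p$g_T == 0) return(rep(0, length(V)))
  x <- pmin((V - p$V_T) / p$K_T, clip)
  p$g_T * p$K_T * exp(x)
}

#' Spike-mimicking current
#'
#' Biexponential current triggered at each threshold crossing of the `PSp`
#' and `ASp` variants:
#' `I_spike(t) = sum_s A_1 exp(-(t-s)/tau_1) - A_2 exp(-(t-s)/tau_2)`
#' over past onset times `s <= t`.
#'
#' @param t Evaluation time (ms, scalar).
#' @param onsets Sorted vector of past threshold-crossing times (ms).
#' @param p An [lso_params()] object (amplitudes in pA).
#' @return Current in pA.
#' @export
spike_current <- function(t, onsets, p) {
  if (is.unsorted(onsets)) stop("onsets must be sorted ascending")
  onsets <- onsets[onsets <= t]
  if (!length(onsets)) return(0)
  dt <- t - onsets
  sum(p$A_1 * exp(-dt / p$tau_1) - p$A_2 * exp(-dt / p$tau_2))
}

#' Total membrane current of a model variant
#'
#' Sums the synaptic, leak, and variant-specific currents at a given state:
#' excitatory/inhibitory synaptic drive, leak, and (per variant) the KLVA
#' current, the exponential spike-generating current, and the spike-mimicking
#' current.
#'
#' @param V Membrane potential (mV).
#' @param d KLVA open fraction (ignored for passive variants).
#' @param g_E,g_I Instantaneous excitatory/inhibitory synaptic conductances
#'   (nS).
#' @param p An [lso_params()] object.
#' @param t Current time (ms), needed only when spike onsets are active.
#' @param onsets Past spike-current onset times (ms), for PSp/ASp.
#' @param E_E,E_I Synaptic reversal potentials (mV).
#' @return Total current in pA.
#' @export
total_current <- function(V, d, g_E, g_I, p, t = 0, onsets = numeric(0),
                          E_E = 0, E_I = -75) {
  if (g_E < 0 || g_I < 0) stop("synaptic conductances must be non-negative")
  fl <- variant_flags(p$variant)
  I <- g_E * (E_E - V) + g_I * (E_I - V) + p$g_L * (p$E_L - V)
  if (fl$use_klva) I <- I + p$g_K * d * (p$E_K - V)
  if (fl$use_exp) I <- I + exp_current(V, p)
  if (fl$use_spk) I <- I + spike_current(t, onsets, p)
  I
}

#' Resting potential of a model variant
#'
#' The membrane potential at which the total intrinsic current vanishes:
#' `E_L` for passive variants; for active variants the root of
#' `g_L (E_L - V) + g_K d_inf(V) (E_K - V) = 0`, found numerically.
#'
#' @param p An [lso_params()] object.
#' @return Resting potential (mV).
#' @export
resting_potential <- function(p) {
  if (p$g_K == 0) return(p$E_L)
  f <- function(V) {
    p$g_L * (p$E_L - V) + p$g_K * klva_steady_state(V)$d_inf * (p$E_K - V)
  }
  uniroot(f, lower = p$E_K + 1e-6, upper = p$E_L + 20, tol = 1e-10)$root
}
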