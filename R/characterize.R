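#' Steady-state current-voltage relation
#'
#' Holding current needed to clamp the membrane at each potential, with the
#' spike-generation mechanisms disabled:
#' `I(V) = g_L (V - E_L) + g_K d_inf(V) (V - E_K)`. The passive curve is a
#' straight line of slope `g_L`; the KLVA conductance makes the active curve
#' supralinear above rest.
#'
#' @param variant One of [model_variants()].
#' @param V_grid Potentials to probe (mV).
#' @param params Membrane parameters.
#' @return Data frame with columns `V` (mV) and `I` (pA).
#' @export
iv_curve <- function(variant, V_grid = seq(-80, -40, by = 1),
                     params = lso_params(variant)) {
  p <- as_lso_params(params)
  I <- p$g_L * (V_grid - p$E_L)
  if (p$g_K > 0)
    I <- I + p$g_K * klva_steady_state(V_grid)$d_inf * (V_grid - p$E_K)
  data.frame(V = V_grid, I = I)
}

#' Linearized membrane impedance spectrum
#'
#' Quasi-active linearization about an operating point `V_op`. The passive
#' admittance is `g_L + i 2 pi f C`; the KLVA branch of the active models
#' adds `g_K (d_inf + (V_op - E_K) d_inf'(V_op) / (1 + i 2 pi f tau_d))`.
#' The KLVA term makes the active models' impedance exceed the passive
#' models' over roughly 40--400 Hz near -60 mV even though their
#' zero-frequency resistances are comparable.
#'
#' @param variant One of [model_variants()].
#' @param f_grid Frequencies (Hz).
#' @param V_op Operating point (mV), default -60.
#' @param params Membrane parameters.
#' @return Data frame with columns `f` (Hz) and `Z` (|Z| in MOhm).
#' @export
impedance <- function(variant, f_grid = c(10, 2 * 10^seq(1, 3, by = 0.1)),
                      V_op = -60, params = lso_params(variant)) {
  p <- as_lso_params(params)
  omega <- 2 * pi * f_grid / 1000  # rad/ms
  Y <- complex(real = p$g_L, imaginary = omega * p$C)
  if (p$g_K > 0) {
    ss <- klva_steady_state(V_op)
    slope <- klva_dinf_slope(V_op)
    Y <- Y + p$g_K * (ss$d_inf +
      (V_op - p$E_K) * slope / complex(real = 1, imaginary = omega * ss$tau_d))
  }
  data.frame(f = f_grid, Z = 1000 / Mod(Y))  # nS -> GOhm -> MOhm
}

#' Low-frequency membrane resistance at an operating point
#'
#' Reciprocal of the total slope conductance: `1/g_L` for passive variants;
#' for active variants `1 / (g_L + g_K (d_inf + (V - E_K) d_inf'(V)))`.
#'
#' @param variant One of [model_variants()].
#' @param V_op Operating point (mV), default -60.
#' @param params Membrane parameters.
#' @return Resistance in MOhm.
#' @export
membrane_resistance <- function(variant, V_op = -60,
                                params = lso_params(variant)) {
  impedance(variant, f_grid = 0, V_op = V_op, params = params)$Z
}

#' Postsynaptic potential / spike-shape response to synchronized inputs
#'
#' Delivers `n_inputs` simultaneous unitary synaptic events of one polarity
#' to a model at rest and returns the voltage trace. Sufficiently many
#' coincident excitatory inputs evoke the variant's spike signature (reset,
#' spike-current waveform, or exponential upswing).
#'
#' @param variant One of [model_variants()].
#' @param n_inputs Number of synchronized unitary inputs (>= 1).
#' @param polarity `"exc"` or `"inh"`.
#' @param dt Euler step (ms).
#' @param t_on Event time (ms).
#' @param duration Trace length (ms).
#' @param spiking Set `FALSE` to disable spike detection (subthreshold
#'   linearity checks).
#' @param params Membrane parameters.
#' @return A [voltage_trace()].
#' @export
psp_response <- function(variant, n_inputs, polarity = c("exc", "inh"),
                         dt = 0.002, t_on = 1, duration = 10,
                         spiking = TRUE, params = lso_params(variant)) {
  polarity <- match.arg(polarity)
  if (n_inputs < 1) stop("n_inputs must be >= 1")
  times <- rep(t_on, n_inputs)
  inputs <- if (polarity == "exc") list(exc = times, inh = numeric(0))
            else list(exc = numeric(0), inh = times)
  simulate_lso(variant, inputs, duration, dt = dt, params = params,
               record_voltage = TRUE, spiking = spiking)$voltage
}
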