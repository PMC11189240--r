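#' Voltage trace container
#'
#' @param values Sampled membrane potentials (mV).
#' @param dt Sample interval (ms).
#' @param t0 Time of the first sample (ms).
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(values, dt, t0 = 0) {
  if (dt <= 0) stop("dt must be positive")
  if (any(!is.finite(values))) stop("voltage trace contains non-finite values")
  structure(list(dt = dt, values = as.numeric(values), t0 = t0),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples, dt = %g ms, range [%.2f, %.2f] mV\n",
              length(x$values), x$dt, min(x$values), max(x$values)))
  invisible(x)
}

#' Time axis of a voltage trace
#' @param trace A [voltage_trace()].
#' @return Sample times (ms).
#' @export
trace_times <- function(trace) trace$t0 + trace$dt * (seq_along(trace$values) - 1)

pool_times <- function(x) {
  if (is.numeric(x)) return(sort(x))
  if (inherits(x, "spike_train")) return(x$times)
  sort(unlist(lapply(x, function(tr)
    if (inherits(tr, "spike_train")) tr$times else tr)))
}

#' Simulate an LSO integrate-and-fire model
#'
#' Integrates the membrane equation `C dV/dt = I_all` by the forward Euler
#' method, where `I_all` sums the excitatory and inhibitory synaptic
#' currents, the leak, and the variant-specific KLVA, exponential, and
#' spike-mimicking currents. Spikes are detected when `V` first reaches
#' `V_th`; the reset variants (PLk/PEx/ALk/AEx) are then clamped at `V_ref`
#' for the refractory period `T_ref` (the KLVA gating variable keeps
#' evolving at the clamped potential), while the spike-current variants
#' (PSp/ASp) trigger the biexponential spike current without a reset and
#' only suspend spike detection for `T_ref`.
#'
#' @param variant One of [model_variants()].
#' @param inputs List with `exc` and `inh` afferent spike times: each either
#'   a numeric vector of pooled times (ms), a [spike_train()], or a list of
#'   spike trains (as returned by [generate_input_trains()]).
#' @param duration Simulated time (ms).
#' @param dt Euler time step (ms); must be in (0, 0.01]. Default 0.002.
#' @param params Membrane parameters; defaults to the variant preset.
#' @param record_voltage If `TRUE`, return the sampled voltage (and, for
#'   active variants, gating) trace.
#' @param i_inj Optional injected current (pA): a scalar or a vector with one
#'   value per step.
#' @param spiking Set `FALSE` to disable spike detection (subthreshold
#'   characterization).
#' @param v0,d0 Initial membrane potential and KLVA open fraction; default to
#'   the variant's resting state.
#' @param exp_clip Ceiling on the exponential-current exponent (see
#'   [exp_current()]).
#' @return A list with `spikes` (a [spike_train()]), `voltage` (a
#'   [voltage_trace()] or `NULL`), `gating` (numeric vector or `NULL`), and
#'   `state` (final `V` and `d`).
#' @examples
#' inp <- generate_input_trains(fiber_drive(171, 0.6, 300),
#'                              fiber_drive(171, 0.6, 300, phase = -135),
#'                              duration = 500, seed = 1)
#' res <- simulate_lso("ALk", inp, duration = 500)
#' firing_rate(res$spikes)
#' @export
simulate_lso <- function(variant, inputs, duration, dt = 0.002,
                         params = lso_params(variant),
                         record_voltage = FALSE, i_inj = NULL,
                         spiking = TRUE, v0 = NULL, d0 = NULL,
                         exp_clip = 20) {
  variant <- match.arg(variant, model_variants())
  if (dt <= 0 || dt > 0.01)
    stop("dt must lie in (0, 0.01] ms for accurate forward-Euler integration")
  p <- as_lso_params(params)
  fl <- variant_flags(variant)
  exc <- pool_times(inputs$exc)
  inh <- pool_times(inputs$inh)
  n_steps <- as.integer(round(duration / dt))
  if (is.null(v0)) v0 <- resting_potential(p)
  if (is.null(d0)) d0 <- if (fl$use_klva) klva_steady_state(v0)$d_inf else 0
  synE <- synapse_params("excitatory")
  synI <- synapse_params("inhibitory")
  out <- cpp_simulate_lso(
    p$C, p$g_L, p$E_L, p$g_K, p$E_K, p$g_T, p$V_T, p$K_T,
    p$V_th, p$V_ref, p$T_ref, p$A_1, p$A_2, p$tau_1, p$tau_2,
    fl$use_klva, fl$use_exp, fl$use_spk,
    exc, inh,
    synE$A_syn, synE$tau_syn, synE$E_syn,
    synI$A_syn, synI$tau_syn, synI$E_syn,
    dt, n_steps, v0, d0,
    if (is.null(i_inj)) numeric(0) else as.numeric(i_inj),
    spiking, record_voltage, exp_clip
  )
  list(
    spikes = spike_train(out$spike_times, duration),
    voltage = if (record_voltage) voltage_trace(out$v, dt) else NULL,
    gating = if (record_voltage && fl$use_klva) out$d else NULL,
    state = list(V = out$v_final, d = out$d_final)
  )
}
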