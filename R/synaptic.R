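#' Spike train container
#'
#' @param times Event times in ms (will be sorted).
#' @param duration Total simulated time (ms).
#' @return An object of class `spike_train`: a list with sorted `times` and
#'   `duration`.
#' @export
spike_train <- function(times, duration) {
  times <- sort(as.numeric(times))
  if (length(times) && (times[1] < 0 || times[length(times)] > duration))
    stop("spike times must lie within [0, duration]")
  structure(list(times = times, duration = duration), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %g ms (%.1f spikes/s)\n",
              length(x$times), x$duration,
              1000 * length(x$times) / x$duration))
  invisible(x)
}

#' Mean firing rate of a spike train
#' @param train A [spike_train()].
#' @return Rate in spikes/s.
#' @export
firing_rate <- function(train) 1000 * length(train$times) / train$duration

#' Synaptic parameters
#'
#' Unitary alpha-function synapse parameters for the LSO input stage.
#' Defaults: excitatory `A_syn` = 3.5 nS, `tau_syn` = 0.16 ms, `E_syn` = 0 mV,
#' 20 fibers; inhibitory `A_syn` = 12 nS, `tau_syn` = 0.32 ms,
#' `E_syn` = -75 mV, 8 fibers.
#'
#' @param type `"excitatory"` or `"inhibitory"`.
#' @return List with `A_syn` (nS), `tau_syn` (ms), `E_syn` (mV), `n_fibers`.
#' @export
synapse_params <- function(type = c("excitatory", "inhibitory")) {
  type <- match.arg(type)
  if (type == "excitatory")
    list(A_syn = 3.5, tau_syn = 0.16, E_syn = 0, n_fibers = 20L)
  else
    list(A_syn = 12, tau_syn = 0.32, E_syn = -75, n_fibers = 8L)
}

#' Afferent rate for AM-tone stimulation
#'
#' Mean per-fiber input rate as a function of modulation frequency:
#' `180 - 0.03 fm` spikes/s.
#'
#' @param fm Modulation frequency (Hz); vectorized.
#' @return Rate in spikes/s.
#' @export
am_rate <- function(fm) {
  r <- 180 - 0.03 * fm
  if (any(r < 0)) stop("modulation frequency gives a negative rate")
  r
}

#' Afferent vector strength for AM-tone stimulation
#'
#' Degree of input phase locking as a function of modulation frequency:
#' `0.65 (1 - exp((fm-2000)/500)) / (1 + exp((fm-2000)/500))`, floored at 0
#' above 2000 Hz.
#'
#' @param fm Modulation frequency (Hz); vectorized.
#' @return Vector strength in \[0, 0.65).
#' @export
am_vs <- function(fm) {
  z <- exp((fm - 2000) / 500)
  pmax(0.65 * (1 - z) / (1 + z), 0)
}

#' Afferent rate for unmodulated tones
#'
#' Sigmoidal rate-level function: `30 + 240 / (1 + exp(-(s - 20)/6))`
#' spikes/s, rising from a 30 spikes/s spontaneous floor to a 270 spikes/s
#' saturation.
#'
#' @param s Sound level (dB); vectorized.
#' @return Rate in spikes/s.
#' @export
level_rate <- function(s) {
  if (any(!is.finite(s))) stop("level must be finite")
  30 + 240 / (1 + exp(-(s - 20) / 6))
}

#' Von Mises concentration for a target vector strength
#'
#' Inverts the Bessel-function ratio `I1(kappa)/I0(kappa) = vs` numerically.
#'
#' @param vs Vector strength in \[0, 1).
#' @return Concentration parameter `kappa` (0 when `vs` = 0).
#' @export
vs_to_kappa <- function(vs) {
  if (vs < 0 || vs >= 1) stop("vs must lie in [0, 1)")
  if (vs == 0) return(0)
  f <- function(k) kappa_to_vs(k) - vs
  upper <- 2
  while (f(upper) < 0) upper <- upper * 2
  uniroot(f, lower = 1e-12, upper = upper, tol = 1e-12)$root
}

#' Vector strength of a von Mises distribution
#' @param kappa Concentration parameter (>= 0).
#' @return Mean resultant length `I1(kappa)/I0(kappa)`.
#' @export
kappa_to_vs <- function(kappa) {
  if (kappa == 0) return(0)
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}

#' Specification of one afferent fiber's drive
#'
#' @param rate Mean (cycle-averaged) rate in spikes/s.
#' @param vs Vector strength in \[0, 1); 0 gives a homogeneous Poisson train.
#' @param fm Modulation frequency (Hz); 0 for unmodulated drive.
#' @param phase Locking phase in degrees. The sign convention is anchored to
#'   the binaural experiments: with excitation locked at phase 0 and
#'   inhibition at the phase difference, the 300-Hz phase tuning curve of
#'   these models peaks near -135 degrees.
#' @return A list of class `fiber_drive`.
#' @export
fiber_drive <- function(rate, vs = 0, fm = 0, phase = 0) {
  if (rate < 0) stop("rate must be non-negative")
  if (vs < 0 || vs >= 1) stop("vs must lie in [0, 1)")
  structure(list(rate = rate, vs = vs, fm = fm, phase = phase),
            class = "fiber_drive")
}

#' Generate one afferent spike train
#'
#' Realizes an (in)homogeneous Poisson process. For phase-locked drive the
#' intensity is `rate * exp(kappa (cos(2 pi fm t/1000 - phase) - ... ))`
#' normalized as a von Mises density over the modulation cycle, so the
#' cycle-averaged rate equals `rate` and the spike-phase distribution has the
#' requested vector strength. Sampling is by thinning of a homogeneous
#' envelope at the intensity maximum, which is exact.
#'
#' @param drive A [fiber_drive()].
#' @param duration Duration (ms).
#' @param seed Optional integer seed for this fiber's stream.
#' @return A [spike_train()].
#' @export
generate_fiber_train <- function(drive, duration, seed = NULL) {
  if (duration <= 0) stop("duration must be positive")
  if (!is.null(seed)) set.seed(seed)
  dur_s <- duration / 1000
  if (drive$rate == 0) return(spike_train(numeric(0), duration))
  if (drive$vs == 0 || drive$fm == 0) {
    n <- rpois(1, drive$rate * dur_s)
    return(spike_train(runif(n, 0, duration), duration))
  }
  kappa <- vs_to_kappa(drive$vs)
  # peak intensity rate*exp(kappa)/I0(kappa), via the scaled Bessel function
  lambda_max <- drive$rate / besselI(kappa, 0, expon.scaled = TRUE)
  n_cand <- rpois(1, lambda_max * dur_s)
  t_cand <- runif(n_cand, 0, duration)
  ph <- 2 * pi * drive$fm * t_cand / 1000 + drive$phase * pi / 180
  accept <- runif(n_cand) < exp(kappa * (cos(ph) - 1))
  spike_train(t_cand[accept], duration)
}

#' Generate the full LSO afferent input set
#'
#' Draws independent spike trains for a bank of fibers, one RNG substream per
#' fiber (substream seeds are drawn deterministically from the master seed),
#' so the identical input realization can be replayed into every model
#' variant.
#'
#' @param exc_drive A [fiber_drive()] applied to every excitatory fiber.
#' @param inh_drive A [fiber_drive()] applied to every inhibitory fiber.
#' @param duration Duration (ms).
#' @param seed Master integer seed.
#' @param n_exc,n_inh Fiber counts (defaults 20 and 8).
#' @return A list with `exc` and `inh`: lists of [spike_train()] objects.
#' @export
generate_input_trains <- function(exc_drive, inh_drive, duration, seed,
                                  n_exc = 20L, n_inh = 8L) {
  set.seed(seed)
  fiber_seeds <- sample.int(.Machine$integer.max - 1L, n_exc + n_inh)
  exc <- lapply(seq_len(n_exc), function(i)
    generate_fiber_train(exc_drive, duration, fiber_seeds[i]))
  inh <- lapply(seq_len(n_inh), function(i)
    generate_fiber_train(inh_drive, duration, fiber_seeds[n_exc + i]))
  list(exc = exc, inh = inh)
}

#' Summed alpha-function conductance trace
#'
#' Converts spike trains into a total synaptic conductance sampled on the
#' integration grid: each spike contributes
#' `A_syn ((t - t_s)/tau_syn) exp(1 - (t - t_s)/tau_syn)` for `t >= t_s`, and
#' all fibers are summed. Spike times are quantized to the grid.
#'
#' @param trains A [spike_train()] or list of them.
#' @param p Synapse parameters from [synapse_params()].
#' @param dt Sample interval (ms).
#' @param duration Trace duration (ms); samples at `0, dt, ..., duration`.
#' @return Numeric vector of conductances (nS), length `duration/dt + 1`.
#' @export
conductance_trace <- function(trains, p, dt, duration) {
  if (dt <= 0) stop("dt must be positive")
  if (inherits(trains, "spike_train")) trains <- list(trains)
  times <- unlist(lapply(trains, function(tr) tr$times))
  n <- as.integer(round(duration / dt)) + 1L
  cpp_alpha_trace(sort(times), p$A_syn, p$tau_syn, dt, n)
}

#' Synaptic current from a conductance and driving force
#'
#' @param g Conductance (nS).
#' @param V Membrane potential (mV).
#' @param E_syn Synaptic reversal potential (mV).
#' @return Current in pA (`g * (E_syn - V)`).
#' @export
synaptic_current <- function(g, V, E_syn) {
  if (any(g < 0)) stop("conductance must be non-negative")
  g * (E_syn - V)
}

#' Vector strength of a spike train at a given frequency
#'
#' @param times Spike times (ms) or a [spike_train()].
#' @param fm Frequency (Hz).
#' @return Mean resultant length of the spike phases.
#' @export
vector_strength <- function(times, fm) {
  if (inherits(times, "spike_train")) times <- times$times
  if (!length(times)) return(NA_real_)
  ph <- 2 * pi * fm * times / 1000
  sqrt(mean(cos(ph))^2 + mean(sin(ph))^2)
}
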