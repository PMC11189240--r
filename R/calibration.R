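#' Paper-scale grid for exponential-model calibration
#'
#' The search ranges used to fit the free parameters of the exponential
#' variants: threshold factor `V_T` from -50 to -40 mV (coarse step 0.5 mV,
#' fine step 0.1 mV), slope factor `K_T` from 1.2 to 4.0 mV in 0.2-mV
#' steps, and detection threshold `V_th` from -30 to 0 mV in 5-mV steps,
#' with the spike-generating conductance fixed at 26.4 nS.
#'
#' @param fine If `TRUE`, use the 0.1-mV `V_T` step instead of 0.5 mV.
#' @return List with `V_T`, `K_T`, `V_th` grids and `g_T`.
#' @export
grid_search_spec <- function(fine = FALSE) {
  list(
    V_T = seq(-50, -40, by = if (fine) 0.1 else 0.5),
    K_T = seq(1.2, 4.0, by = 0.2),
    V_th = seq(-30, 0, by = 5),
    g_T = 26.4
  )
}

#' Grid search for exponential-model spiking parameters
#'
#' Evaluates the binaural response criteria (phase-difference tuning at
#' 300 Hz and ILD tuning at an ipsilateral level of 35 dB) for every
#' combination of `V_T`, `K_T`, and `V_th` on the grid and flags parameter
#' sets whose six binaural metrics all fall inside the required bands
#' (targeted bands for the active AEx variant, accepted bands for the
#' passive PEx variant). More than one combination can pass; no ranking is
#' implied.
#'
#' @param variant `"PEx"` or `"AEx"`.
#' @param spec Grid specification, see [grid_search_spec()].
#' @param duration Simulated time per condition (ms).
#' @param seed Master seed (shared across grid points so that every
#'   candidate sees identical inputs).
#' @param dt Euler step (ms).
#' @param level Criteria level to require; defaults to `"targeted"` for AEx
#'   and `"accepted"` for PEx.
#' @param phase_grid,ild_grid Experiment abscissa grids.
#' @return Data frame with one row per grid point: the three searched
#'   parameters, the six binaural metrics, and a logical `pass`.
#' @export
grid_search <- function(variant = c("PEx", "AEx"), spec = grid_search_spec(),
                        duration = 40000, seed = 1, dt = 0.002,
                        level = NULL,
                        phase_grid = phase_grid_default(),
                        ild_grid = ild_grid_default()) {
  variant <- match.arg(variant)
  if (!length(spec$V_T) || !length(spec$K_T) || !length(spec$V_th))
    stop("grid must be non-empty")
  if (is.null(level))
    level <- if (variant == "AEx") "targeted" else "accepted"
  ranges <- criteria_ranges()
  grid <- expand.grid(V_T = spec$V_T, K_T = spec$K_T, V_th = spec$V_th,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    params <- lso_params(variant, g_T = spec$g_T, V_T = grid$V_T[i],
                         K_T = grid$K_T[i], V_th = grid$V_th[i])
    ph <- tuning_metrics(phase_tuning(variant, phase_grid = phase_grid,
                                      duration = duration, seed = seed,
                                      dt = dt, params = params))
    il <- tuning_metrics(ild_tuning(variant, ild_grid = ild_grid,
                                    duration = duration, seed = seed,
                                    dt = dt, params = params))
    pass <- all(
      in_band(ph$peak, ranges$phase$peak[[level]]),
      in_band(ph$trough, ranges$phase$trough[[level]]),
      in_band(ph$depth, ranges$phase$depth[[level]]),
      in_band(il$peak, ranges$ild$peak[[level]]),
      in_band(il$trough, ranges$ild$trough[[level]]),
      in_band(il$depth, ranges$ild$depth[[level]])
    )
    data.frame(V_T = grid$V_T[i], K_T = grid$K_T[i], V_th = grid$V_th[i],
               phase_peak = ph$peak, phase_trough = ph$trough,
               phase_depth = ph$depth,
               ild_peak = il$peak, ild_trough = il$trough,
               ild_depth = il$depth, pass = pass)
  })
  do.call(rbind, res)
}

#' Refractory-period sensitivity sweep
#'
#' Recomputes the binaural phase (300 Hz) and ILD (35 dB) tuning metrics
#' while varying the absolute refractory period. For the reset variants the
#' ILD peak falls approximately linearly with `T_ref`, whereas the
#' spike-current variants are nearly insensitive because their post-spike
#' recovery is dominated by the spike-mimicking current.
#'
#' @param variant One of [model_variants()].
#' @param T_ref_grid Refractory periods to test (ms); the physiological
#'   bracket is roughly 1.1--2.8 ms.
#' @inheritParams grid_search
#' @return Data frame with `T_ref` and the phase/ILD peak and trough rates.
#' @export
refractory_sweep <- function(variant, T_ref_grid = seq(1.2, 2.8, by = 0.4),
                             duration = 40000, seed = 1, dt = 0.002,
                             phase_grid = phase_grid_default(),
                             ild_grid = ild_grid_default()) {
  res <- lapply(T_ref_grid, function(tr) {
    params <- lso_params(variant, T_ref = tr)
    ph <- tuning_metrics(phase_tuning(variant, phase_grid = phase_grid,
                                      duration = duration, seed = seed,
                                      dt = dt, params = params))
    il <- tuning_metrics(ild_tuning(variant, ild_grid = ild_grid,
                                    duration = duration, seed = seed,
                                    dt = dt, params = params))
    data.frame(T_ref = tr, phase_peak = ph$peak, phase_trough = ph$trough,
               ild_peak = il$peak, ild_trough = il$trough)
  })
  do.call(rbind, res)
}
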