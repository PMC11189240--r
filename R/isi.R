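#' Interspike-interval histogram
#'
#' Histogram of successive interspike intervals with bins of width
#' `bin_width` starting at 0. The density is the per-bin count divided by
#' (bin width in seconds times the total ISI count), giving units of 1/s.
#'
#' @param train A [spike_train()] (needs at least 2 spikes) or a numeric
#'   vector of spike times (ms).
#' @param bin_width Bin width in ms (default 0.2).
#' @return An object of class `isi_histogram`: list with `bin_width` (ms),
#'   `bin_left` (left edges, ms), `counts`, `density` (1/s), and `n_isi`.
#' @export
isi_histogram <- function(train, bin_width = 0.2) {
  times <- if (inherits(train, "spike_train")) train$times else sort(train)
  if (length(times) < 2)
    stop("at least 2 spikes are needed for an ISI histogram")
  if (bin_width <= 0) stop("bin_width must be positive")
  isi <- diff(times)
  n_bins <- floor(max(isi) / bin_width) + 1L
  idx <- pmin(floor(isi / bin_width), n_bins - 1L) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(
    bin_width = bin_width,
    bin_left = (seq_len(n_bins) - 1L) * bin_width,
    counts = counts,
    density = counts / (bin_width / 1000 * length(isi)),
    n_isi = length(isi)
  ), class = "isi_histogram")
}

#' @export
print.isi_histogram <- function(x, ...) {
  cat(sprintf("<isi_histogram> %d ISIs, %d bins of %g ms\n",
              x$n_isi, length(x$counts), x$bin_width))
  invisible(x)
}

#' Hazard rate function of an ISI histogram
#'
#' The hazard in bin i is `H_i = N_i / (T_bin * S_i)` with `T_bin` in
#' seconds and survivor mass `S_i = sum_(j>=i) N_j`. The function is
#' truncated before the first bin whose survivor mass drops below 2% of the
#' total ISI count (estimates beyond that point are too noisy).
#'
#' @param hist An [isi_histogram()].
#' @param survivor_floor Truncation threshold as a fraction of the total
#'   count (default 0.02).
#' @return An object of class `hazard_function`: list with `bin_left`,
#'   `bin_center` (ms), `hazard` (1/s), `survivor` counts, and
#'   `truncation_index`.
#' @export
hazard_rate <- function(hist, survivor_floor = 0.02) {
  stopifnot(inherits(hist, "isi_histogram"))
  N <- hist$counts
  S <- rev(cumsum(rev(N)))
  total <- sum(N)
  keep <- S >= survivor_floor * total
  k <- if (all(keep)) length(N) else which(!keep)[1] - 1L
  idx <- seq_len(k)
  structure(list(
    bin_left = hist$bin_left[idx],
    bin_center = hist$bin_left[idx] + hist$bin_width / 2,
    hazard = N[idx] / (hist$bin_width / 1000 * S[idx]),
    survivor = S[idx],
    truncation_index = k
  ), class = "hazard_function")
}

#' Conditional mean of successive interspike intervals
#'
#' For each bin of the preceding interval `ISI_n`, the mean of the following
#' interval `ISI_(n+1)`. For a renewal process this curve is flat at the
#' marginal mean ISI; a serial dependence of neighboring intervals bends it.
#' Bins are reported only when they hold more than `occupancy_floor` of the
#' total ISI count.
#'
#' @param train A [spike_train()] (needs at least 3 spikes) or numeric spike
#'   times (ms).
#' @param bin_width Bin width for `ISI_n` (ms).
#' @param occupancy_floor Minimum bin occupancy as a fraction of the total
#'   ISI count (default 0.005, strict).
#' @return Data frame with `bin_left`, `bin_center` (ms), `n` (pairs in the
#'   bin), and `mean_next` (ms).
#' @export
conditional_mean <- function(train, bin_width = 0.2, occupancy_floor = 0.005) {
  times <- if (inherits(train, "spike_train")) train$times else sort(train)
  if (length(times) < 3)
    stop("at least 3 spikes are needed for conditional ISI means")
  isi <- diff(times)
  n <- length(isi)
  prev <- isi[-n]
  nxt <- isi[-1]
  bin <- floor(prev / bin_width)
  agg_n <- tapply(nxt, bin, length)
  agg_mean <- tapply(nxt, bin, mean)
  lefts <- as.numeric(names(agg_n)) * bin_width
  keep <- agg_n > occupancy_floor * n
  data.frame(
    bin_left = lefts[keep],
    bin_center = lefts[keep] + bin_width / 2,
    n = as.integer(agg_n[keep]),
    mean_next = as.numeric(agg_mean[keep])
  )
}

#' Spike train for monaural ISI-statistics experiments
#'
#' Drives a model with the ipsilateral excitatory input used for the ILD
#' experiment at a given level, while the contralateral inhibition stays at
#' its 30 spikes/s spontaneous floor.
#'
#' @inheritParams phase_tuning
#' @param level Ipsilateral sound level (dB; 25 or 35 in typical use).
#' @return A [spike_train()].
#' @export
monaural_isi_train <- function(variant, level = 35, duration = 40000,
                               seed = 1, dt = 0.002,
                               params = lso_params(variant)) {
  run_condition(variant, fiber_drive(level_rate(level)), fiber_drive(30),
                duration, seed, dt, params)
}
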