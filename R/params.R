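#' Model variant names
#'
#' The six integrate-and-fire LSO model variants. The first letter denotes the
#' subthreshold membrane: `P` (passive, leak only) or `A` (active, leak plus a
#' low-voltage-activated potassium conductance, KLVA). The suffix denotes the
#' spike-generation mechanism: `Lk` (threshold crossing with voltage reset),
#' `Sp` (threshold crossing triggering a spike-mimicking current, no reset),
#' `Ex` (exponential spike-generating current with reset).
#'
#' @return Character vector `c("PLk", "PSp", "PEx", "ALk", "ASp", "AEx")`.
#' @export
model_variants <- function() c("PLk", "PSp", "PEx", "ALk", "ASp", "AEx")

#' Membrane parameters for an LSO IF model variant
#'
#' Returns the preset membrane parameter set for one of the six model
#' variants. All parameters use the internal unit system mV / ms / nS / pF /
#' pA; the spike-mimicking current amplitudes are stored in pA.
#'
#' @param variant One of [model_variants()].
#' @param ... Named overrides for individual parameters (e.g. `T_ref = 1.6`).
#'
#' @return An object of class `lso_params`: a list with elements
#'   `variant`, `C` (pF), `g_L` (nS), `E_L` (mV), `g_K` (nS), `E_K` (mV),
#'   `g_T` (nS), `V_T` (mV), `K_T` (mV), `V_th` (mV), `V_ref` (mV),
#'   `T_ref` (ms), `A_1`, `A_2` (pA), `tau_1`, `tau_2` (ms).
#'
#' @details The passive variants (PLk/PSp/PEx) share `g_L` = 26.4 nS and
#'   `E_L` = -60 mV; the active variants (ALk/ASp/AEx) have `g_L` = 14.4 nS,
#'   `E_L` = -56 mV and a KLVA conductance `g_K` = 21.6 nS with reversal
#'   `E_K` = -75 mV. All variants share `C` = 24 pF, `V_ref` = -60 mV and
#'   `T_ref` = 2 ms. The exponential variants use `g_T` = 26.4 nS,
#'   `K_T` = 1.8 mV, with threshold factor `V_T` = -46.6 mV (PEx) or
#'   -47.3 mV (AEx) and detection threshold -10 mV. The spike-current
#'   variants use amplitudes 24 nA / 12 nA with time constants 0.17/0.37 ms
#'   (PSp) or 0.15/0.30 ms (ASp).
#'
#' @examples
#' p <- lso_params("ALk")
#' p$g_K
#' @export
lso_params <- function(variant = model_variants(), ...) {
  variant <- match.arg(variant)
  passive <- substr(variant, 1, 1) == "P"
  base <- list(
    variant = variant,
    C = 24,
    g_L = if (passive) 26.4 else 14.4,
    E_L = if (passive) -60 else -56,
    g_K = if (passive) 0 else 21.6,
    E_K = if (passive) 0 else -75,
    g_T = 0, V_T = 0, K_T = 1,
    V_th = NA_real_,
    V_ref = -60,
    T_ref = 2.0,
    A_1 = 0, A_2 = 0, tau_1 = 1, tau_2 = 1
  )
  base$V_th <- switch(variant,
    PLk = -45.1, PSp = -45.1,
    ALk = -45.8, ASp = -45.8,
    PEx = -10.0, AEx = -10.0
  )
  if (variant %in% c("PEx", "AEx")) {
    base$g_T <- 26.4
    base$V_T <- if (variant == "PEx") -46.6 else -47.3
    base$K_T <- 1.8
  }
  if (variant %in% c("PSp", "ASp")) {
    base$A_1 <- 24 * 1000  # 24 nA in pA
    base$A_2 <- 12 * 1000
    if (variant == "PSp") {
      base$tau_1 <- 0.17
      base$tau_2 <- 0.37
    } else {
      base$tau_1 <- 0.15
      base$tau_2 <- 0.30
    }
  }
  p <- modifyList(base, list(...))
  as_lso_params(p)
}

#' Validate a membrane parameter list
#'
#' @param p A named list with the fields documented in [lso_params()].
#' @return The validated object with class `lso_params`.
#' @export
as_lso_params <- function(p) {
  stopifnot(is.list(p))
  required <- c("variant", "C", "g_L", "E_L", "g_K", "E_K", "g_T", "V_T",
                "K_T", "V_th", "V_ref", "T_ref", "A_1", "A_2", "tau_1",
                "tau_2")
  missing <- setdiff(required, names(p))
  if (length(missing))
    stop("missing parameter fields: ", paste(missing, collapse = ", "))
  if (!p$variant %in% model_variants())
    stop("unknown variant '", p$variant, "'; valid variants are: ",
         paste(model_variants(), collapse = ", "))
  num <- setdiff(required, "variant")
  for (f in num) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]))
      stop("parameter '", f, "' must be a single finite number")
  }
  if (p$C <= 0) stop("C must be positive")
  if (p$g_L <= 0) stop("g_L must be positive")
  if (p$g_K < 0 || p$g_T < 0) stop("conductances must be non-negative")
  if (p$g_T > 0 && p$K_T <= 0) stop("K_T must be positive when g_T > 0")
  if (p$T_ref < 0) stop("T_ref must be non-negative")
  if (p$V_ref >= p$V_th) stop("V_ref must be below V_th")
  if ((p$A_1 != 0 || p$A_2 != 0) && (p$tau_1 <= 0 || p$tau_2 <= 0))
    stop("tau_1 and tau_2 must be positive when the spike current is enabled")
  structure(p[required], class = "lso_params")
}

#' @export
print.lso_params <- function(x, ...) {
  cat("<lso_params> variant", x$variant, "\n")
  cat(sprintf("  membrane: C = %g pF, g_L = %g nS, E_L = %g mV\n",
              x$C, x$g_L, x$E_L))
  if (x$g_K > 0)
    cat(sprintf("  KLVA:     g_K = %g nS, E_K = %g mV\n", x$g_K, x$E_K))
  if (x$g_T > 0)
    cat(sprintf("  EIF:      g_T = %g nS, V_T = %g mV, K_T = %g mV\n",
                x$g_T, x$V_T, x$K_T))
  if (x$A_1 != 0)
    cat(sprintf("  spike I:  A_1 = %g pA, A_2 = %g pA, tau_1 = %g, tau_2 = %g ms\n",
                x$A_1, x$A_2, x$tau_1, x$tau_2))
  cat(sprintf("  spiking:  V_th = %g mV, V_ref = %g mV, T_ref = %g ms\n",
              x$V_th, x$V_ref, x$T_ref))
  invisible(x)
}

# which dynamical terms a variant uses
variant_flags <- function(variant) {
  list(
    use_klva = substr(variant, 1, 1) == "A",
    use_exp = substr(variant, 2, 3) == "Ex",
    use_spk = substr(variant, 2, 3) == "Sp"
  )
}
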