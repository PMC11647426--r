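#' Pharmacodynamic parameters for locomotor suppression
#'
#' Drug effect is modelled as a separable Emax/Hill dose term times a
#' normalized Bateman time course,
#' \deqn{E(t, d) = E_{max} \frac{d^h}{d^h + ED_{50}^h} \cdot B(t), \qquad
#'       B(t) = \frac{e^{-k_e t} - e^{-k_a t}}{\max_s (e^{-k_e s} - e^{-k_a s})}.}
#' `B` peaks at \eqn{t^* = \ln(k_a/k_e) / (k_a - k_e)} with value 1, so at the
#' peak and at `dose = ed50` the suppression is exactly `emax / 2`.
#'
#' Default ED50 values are 0.02 mg/kg for SCH23390 and 0.2 mg/kg for
#' haloperidol, placing the half-maximal dose at the low end of the doses
#' that produce clear hypokinesia for each compound; onset (`ka`) and washout
#' (`ke`) rates are set so the effect is established by ~10 min
#' post-injection and largely washed out by 60-75 min.
#'
#' @param emax Maximal fractional suppression of locomotor drive, in `[0, 1]`.
#' @param ed50 Dose producing half-maximal suppression at the Bateman peak,
#'   mg/kg, > 0.
#' @param hill Hill coefficient, > 0.
#' @param ka Absorption/onset rate, 1/min; must exceed `ke`.
#' @param ke Elimination/washout rate, 1/min, > 0.
#' @return Object of class `pd_params`.
#' @export
pd_params <- function(emax = 0.97, ed50 = 0.02, hill = 1.5, ka = 0.30, ke = 0.04) {
  stopifnot(is.numeric(emax), emax >= 0, emax <= 1,
            is.numeric(ed50), ed50 > 0,
            is.numeric(hill), hill > 0,
            is.numeric(ka), is.numeric(ke), ke > 0)
  if (ka <= ke)
    stop("onset rate ka must exceed washout rate ke", call. = FALSE)
  structure(list(emax = emax, ed50 = ed50, hill = hill, ka = ka, ke = ke),
            class = "pd_params")
}

#' @export
print.pd_params <- function(x, ...) {
  cat(sprintf("<pd_params> emax %.3g, ed50 %.3g mg/kg, hill %.3g, ka %.3g /min, ke %.3g /min (peak at %.1f min)\n",
              x$emax, x$ed50, x$hill, x$ka, x$ke, bateman_peak_time(x)))
  invisible(x)
}

#' Time of peak drug effect, in minutes
#' @param pd A [pd_params()].
#' @export
bateman_peak_time <- function(pd) log(pd$ka / pd$ke) / (pd$ka - pd$ke)

#' Normalized Bateman time course
#'
#' @param t Time post-injection in minutes (vectorized).
#' @param pd A [pd_params()].
#' @return `B(t)` in `[0, 1]`, with maximum exactly 1 at the peak time.
#' @export
bateman <- function(t, pd) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  tstar <- bateman_peak_time(pd)
  norm <- exp(-pd$ke * tstar) - exp(-pd$ka * tstar)
  (exp(-pd$ke * t) - exp(-pd$ka * t)) / norm
}

#' Fractional locomotor suppression at a time and dose
#'
#' @param t Time post-injection in minutes (vectorized).
#' @param dose Dose in mg/kg (scalar or vectorized with `t`).
#' @param pd A [pd_params()].
#' @return Suppression in `[0, emax]`; identically 0 for `dose = 0`.
#' @examples
#' pd <- pd_params()
#' dose_effect(bateman_peak_time(pd), pd$ed50, pd)  # emax / 2
#' @export
dose_effect <- function(t, dose, pd) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (any(dose < 0)) stop("dose must be >= 0", call. = FALSE)
  hillterm <- ifelse(dose == 0, 0,
                     dose^pd$hill / (dose^pd$hill + pd$ed50^pd$hill))
  pd$emax * hillterm * bateman(t, pd)
}

#' Shipped per-drug pharmacodynamic defaults
#'
#' @return Named list with `pd_params` for `SCH23390` and `haloperidol`.
#' @export
default_pd <- function() {
  list(SCH23390 = pd_params(ed50 = 0.02),
       haloperidol = pd_params(ed50 = 0.2))
}
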