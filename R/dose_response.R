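#' Expected TOI distance under the generative model
#'
#' Semi-analytic expectation of distance travelled in a time window from the
#' alternating-renewal approximation: at time t (minutes) the expected mobile
#' fraction is `h(t) * dbar / (1 + h(t) * dbar)` with `h` the suppressed,
#' habituating bout hazard and `dbar` the mean bout duration, and the
#' expected frame speed while mobile is
#' `speed_scale * (1 - E) * exp(speed_sdlog^2 / 2)`.
#'
#' @param dose Dose in mg/kg (vectorized).
#' @param pd A [pd_params()].
#' @param bp A [behavior_params()].
#' @param toi_min Window in minutes (default the 10-60 min TOI).
#' @param test_round Test round (habituation across rounds).
#' @return Expected distance in cm.
#' @export
predict_toi_distance <- function(dose, pd, bp, toi_min = c(10, 60),
                                 test_round = 1) {
  dbar <- bp$bout_mean_dur / 60 # min
  one <- function(d) {
    rate_cm_per_min <- function(t) {
      e <- if (d > 0) dose_effect(t, d, pd) else 0
      h <- bp$bout_rate0 * bp$round_factor^(test_round - 1) *
        exp(-t / bp$habituation_tau) * (1 - e)
      frac_mobile <- h * dbar / (1 + h * dbar)
      vbar <- bp$speed_scale * (1 - e) * exp(bp$speed_sdlog^2 / 2)
      frac_mobile * vbar * 60
    }
    stats::integrate(rate_cm_per_min, toi_min[1], toi_min[2],
                     rel.tol = 1e-8)$value
  }
  vapply(dose, one, 0)
}

#' Recover Emax and ED50 from seed-averaged TOI distances
#'
#' Least-squares refit of the dose-response parameters from mean TOI
#' distances across a dose grid (saline included), using
#' [predict_toi_distance()] as the model with `emax`, `ed50` and a free
#' multiplicative scale (absorbing the renewal approximation's constant
#' bias); onset/washout rates and the Hill coefficient are held at the
#' generating values.
#'
#' @param doses Numeric vector of doses (include 0 for saline).
#' @param mean_distance Mean TOI distance per dose, same order, cm.
#' @param pd [pd_params()] supplying the fixed `hill`, `ka`, `ke` and the
#'   starting values; also the reference for recovery checks.
#' @param bp The [behavior_params()] used to generate the data.
#' @param toi_min TOI in minutes.
#' @param test_round Test round of the fitted sessions.
#' @return List with `emax`, `ed50`, `scale`, `sse`, and `convergence`.
#' @export
fit_dose_response <- function(doses, mean_distance, pd, bp,
                              toi_min = c(10, 60), test_round = 1) {
  stopifnot(length(doses) == length(mean_distance), length(doses) >= 3)
  obj <- function(par) {
    pdi <- pd_params(emax = stats::plogis(par[1]), ed50 = exp(par[2]),
                     hill = pd$hill, ka = pd$ka, ke = pd$ke)
    pred <- exp(par[3]) *
      predict_toi_distance(doses, pdi, bp, toi_min, test_round)
    sum((pred - mean_distance)^2)
  }
  start <- c(stats::qlogis(min(max(pd$emax, 0.05), 0.95)), log(pd$ed50), 0)
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  list(emax = stats::plogis(opt$par[1]), ed50 = exp(opt$par[2]),
       scale = exp(opt$par[3]), sse = opt$value, convergence = opt$convergence)
}
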