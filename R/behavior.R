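#' Behavioural parameters of the locomotion generator
#'
#' Parameters of the two-state (immobile / mobile) semi-Markov model used by
#' [simulate_session()].  The effective mobile-bout initiation hazard at time
#' t (minutes) in test round r is
#' `bout_rate0 * round_factor^(r - 1) * exp(-t / habituation_tau) * (1 - E(t, dose))`,
#' which encodes within-session habituation, across-round habituation, and
#' pharmacological suppression; the within-bout speed scale is suppressed by
#' the same `(1 - E)` factor.
#'
#' Defaults are the shipped saline calibration (see the methods vignette):
#' they put mean measured immobility near 70% of the 10-60 min window and
#' above 80% in the final 30 minutes, with a corner-zone occupancy plurality.
#'
#' @param bout_rate0 Baseline mobile-bout initiation hazard, bouts/min.
#' @param bout_mean_dur Mean mobile-bout duration, s.
#' @param speed_scale Log-normal scale (median) of within-bout frame speed, cm/s.
#' @param speed_sdlog Log-normal sdlog of within-bout frame speed (unitless).
#' @param habituation_tau Within-session exponential decline constant of the
#'   bout hazard, min.
#' @param round_factor Multiplicative hazard factor per prior open-field
#'   exposure, in `(0, 1]`.
#' @param thigmotaxis_strength Wall/corner attraction weight, rad/s of heading
#'   pull toward the nearest corner.
#' @param heading_persistence Turning-angle concentration; per-frame heading
#'   increments have sd `sqrt(dt / heading_persistence)` rad.
#' @param freeze_frac Probability that an immobile period is a freeze (head
#'   and tail fully still) rather than stationary with head/tail movement.
#' @param posture_noise Isotropic sd (cm) of head/tail wobble during
#'   non-freezing immobility and locomotion.
#' @param body_length Nose-to-tail-base distance, cm.
#' @return Object of class `behavior_params`.
#' @export
behavior_params <- function(bout_rate0 = 10.5, bout_mean_dur = 4,
                            speed_scale = 14, speed_sdlog = 0.45,
                            habituation_tau = 45, round_factor = 0.85,
                            thigmotaxis_strength = 2,
                            heading_persistence = 0.15,
                            freeze_frac = 0.35, posture_noise = 0.25,
                            body_length = 8) {
  stopifnot(bout_rate0 > 0, bout_mean_dur > 0, speed_scale > 0,
            speed_sdlog > 0, habituation_tau > 0,
            round_factor > 0, round_factor <= 1,
            thigmotaxis_strength >= 0, heading_persistence > 0,
            freeze_frac >= 0, freeze_frac <= 1,
            posture_noise >= 0, body_length > 0)
  structure(list(bout_rate0 = bout_rate0, bout_mean_dur = bout_mean_dur,
                 speed_scale = speed_scale, speed_sdlog = speed_sdlog,
                 habituation_tau = habituation_tau, round_factor = round_factor,
                 thigmotaxis_strength = thigmotaxis_strength,
                 heading_persistence = heading_persistence,
                 freeze_frac = freeze_frac, posture_noise = posture_noise,
                 body_length = body_length),
            class = "behavior_params")
}

#' @export
print.behavior_params <- function(x, ...) {
  cat(sprintf("<behavior_params> bout rate %.3g /min (tau %.3g min, round factor %.2f), bout %.3g s, speed %.3g cm/s\n",
              x$bout_rate0, x$habituation_tau, x$round_factor,
              x$bout_mean_dur, x$speed_scale))
  invisible(x)
}
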