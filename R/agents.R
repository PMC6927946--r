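# Stochastic learning agents.
#
# Each virtual mouse licks on a trial with a probability that relaxes
# exponentially, over completed discrimination trials n, from a naive level
# to an asymptote: animals keep licking for the rewarded odor and gradually
# cease licking for the unrewarded one. Trial initiations follow an
# inhomogeneous Poisson process with an hourly circadian rate profile.

#' Virtual-mouse parameters
#'
#' @param h0,h_inf Initial and asymptotic lick probability on S+ trials.
#' @param f0,f_inf Initial and asymptotic lick probability on S- trials.
#' @param tau Learning time constant in completed discrimination trials.
#' @param activity_rate Length-24 vector of hourly trial-initiation rates
#'   (trials/hour), hour 0 = midnight. Default: a nocturnal profile peaking
#'   in the fourth hour of the dark phase (21:00) totalling ~300 trials/day.
#' @param p_rfid_fail Probability a port entry yields an incomplete RFID
#'   read (entry aborted).
#' @param p_presample_fail Probability a started trial fails the
#'   pre-sampling occupancy gate.
#' @return Object of class `agent_params`.
#' @export
agent_params <- function(h0 = 0.85, h_inf = 0.99, f0 = 0.85, f_inf = 0.02,
                         tau = 120, activity_rate = nocturnal_activity(),
                         p_rfid_fail = 0.05, p_presample_fail = 0.05) {
  probs <- c(h0, h_inf, f0, f_inf, p_rfid_fail, p_presample_fail)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  if (length(activity_rate) != 24L || any(activity_rate < 0))
    stop("activity_rate must be a non-negative length-24 vector", call. = FALSE)
  structure(list(h0 = h0, h_inf = h_inf, f0 = f0, f_inf = f_inf, tau = tau,
                 activity_rate = activity_rate,
                 p_rfid_fail = p_rfid_fail,
                 p_presample_fail = p_presample_fail),
            class = "agent_params")
}

#' Nocturnal circadian activity profile
#'
#' Hourly trial-initiation rates shaped as a circular von-Mises-like bump:
#' `exp(kappa * cos(2 * pi * (h - peak_hour) / 24))`, normalized to
#' `daily_trials` per day. With the defaults the peak hour carries about
#' 17% of daily trials, in the fourth hour of an 18:00-06:00 dark phase.
#'
#' @param daily_trials Expected initiations per day.
#' @param peak_hour Hour of maximal activity (default 21).
#' @param kappa Concentration of the profile (0 = uniform).
#' @return Length-24 numeric vector of rates (trials/hour).
#' @export
nocturnal_activity <- function(daily_trials = 300, peak_hour = 21, kappa = 3) {
  h <- 0:23
  w <- exp(kappa * cos(2 * pi * (h - peak_hour) / 24))
  daily_trials * w / sum(w)
}

#' Lick probability of the exponential learning model
#'
#' On S+ trials the probability rises from `h0` toward `h_inf`; on S- it
#' decays from `f0` toward `f_inf`, both with time constant `tau` in
#' completed discrimination trials:
#' `p_hit(n) = h_inf - (h_inf - h0) * exp(-n / tau)` and
#' `p_fa(n) = f_inf + (f0 - f_inf) * exp(-n / tau)`.
#'
#' @param params An [agent_params()] object.
#' @param n Completed discrimination trials so far (vectorized).
#' @param label `"S+"` or `"S-"`.
#' @return Lick probability (vector over `n`).
#' @export
lick_probability <- function(params, n, label) {
  stopifnot(label %in% c(S_PLUS, S_MINUS))
  if (identical(label, S_PLUS))
    params$h_inf - (params$h_inf - params$h0) * exp(-n / params$tau)
  else
    params$f_inf + (params$f0 - params$f_inf) * exp(-n / params$tau)
}

#' Draw an agent's response to a stimulus
#'
#' A licking response produces enough licked 500 ms blocks to meet the
#' phase criterion and keeps the head in the port; a non-licking response
#' produces no licked blocks and, on S- trials, an early head retraction.
#' Pre-training (clean air, label `"NONE"`) uses the S+ policy: compliant
#' animals lick for the reward.
#'
#' @param params An [agent_params()] object.
#' @param n Completed discrimination trials so far.
#' @param label `"S+"`, `"S-"` or `"NONE"`.
#' @param criterion Phase lick criterion (0-3).
#' @return List with `lick_blocks` (0-4) and `head_retract_ms` (`NA` when
#'   the head stays in the port for the full response window).
#' @export
agent_response <- function(params, n, label, criterion = 3L) {
  p <- lick_probability(params, n, if (identical(label, S_MINUS)) S_MINUS else S_PLUS)
  licks <- stats::runif(1) < p
  if (licks) {
    lo <- max(criterion, 1L)
    list(lick_blocks = sample(lo:4L, 1L), head_retract_ms = NA_real_)
  } else {
    retract <- if (identical(label, S_MINUS))
      stats::runif(1, 250, 1200) else NA_real_
    list(lick_blocks = 0L, head_retract_ms = retract)
  }
}

#' Sample trial-initiation times from a circadian Poisson process
#'
#' Inhomogeneous Poisson process with piecewise-constant hourly rate
#' `activity_rate[h]`: each simulated hour contributes a Poisson count of
#' events placed uniformly within the hour.
#'
#' @param params An [agent_params()] object (supplies `activity_rate`).
#' @param duration_h Simulated duration in hours (the clock starts at
#'   midnight, hour 0).
#' @param seed Integer seed.
#' @return Sorted numeric vector of event times in hours since start.
#' @export
sample_initiations <- function(params, duration_h, seed = 1L) {
  if (duration_h <= 0) stop("duration must be positive", call. = FALSE)
  with_local_seed(seed, {
    times <- numeric(0)
    n_hours <- ceiling(duration_h)
    for (i in seq_len(n_hours) - 1L) {
      lambda <- params$activity_rate[(i %% 24L) + 1L]
      width <- min(1, duration_h - i)
      n_ev <- stats::rpois(1, lambda * width)
      if (n_ev > 0) times <- c(times, i + stats::runif(n_ev, 0, width))
    }
    sort(times)
  })
}
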