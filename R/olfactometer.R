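# Synthetic dual-channel olfactometer.
#
# Odor pulses are modeled as a saturating-exponential rise beginning
# shortly after final-valve opening, a peak at the valve's time-to-peak,
# and a slow exponential decay, with amplitude proportional to the
# commanded dilution fraction plus additive Gaussian detector noise. The
# model is calibrated so the 10%-of-maximum crossing of a noise-free trace
# lands on the configured onset latency.

#' Olfactometer pulse model
#'
#' @param onset_ms Odor onset latency after final-valve opening (ms),
#'   defined as the time the concentration crosses 10% of its maximum;
#'   default 15.91 ms, shared across valves.
#' @param peak_ms Per-valve time-to-peak (ms). Default: six valves spanning
#'   65.38-91.38 ms (peak time grows with the valve's distance from the
#'   final valve).
#' @param rise_tau_ms Time constant of the saturating-exponential rise; by
#'   default a third of the onset-to-peak interval per valve.
#' @param decay_tau_ms Time constant of the post-peak decay (ms).
#' @param gain Peak concentration per unit dilution fraction (detector
#'   units).
#' @param noise_sd Additive Gaussian noise SD (detector units).
#' @return Object of class `olfactometer_model`.
#' @export
olfactometer_model <- function(onset_ms = 15.91,
                               peak_ms = seq(65.38, 91.38, length.out = 6),
                               rise_tau_ms = (peak_ms - onset_ms) / 3,
                               decay_tau_ms = 400,
                               gain = 1, noise_sd = 0.02) {
  if (any(onset_ms >= peak_ms))
    stop("onset latency must precede every valve's time-to-peak", call. = FALSE)
  structure(list(onset_ms = onset_ms, peak_ms = peak_ms,
                 rise_tau_ms = rise_tau_ms, decay_tau_ms = decay_tau_ms,
                 gain = gain, noise_sd = noise_sd),
            class = "olfactometer_model")
}

#' Synthesize an odor-pulse concentration trace
#'
#' @param model An [olfactometer_model()] object.
#' @param valve_id Valve index (1-based) selecting the odor reservoir.
#' @param dilution_fraction Commanded dilution in `[0, 1]` (1 = undiluted).
#' @param duration_ms Trace length (ms).
#' @param dt_ms Sampling interval (ms).
#' @param seed Integer seed for the detector noise (`NULL`: use the current
#'   RNG stream).
#' @return Object of class `pulse_trace`: list with `time_ms` and
#'   `concentration` vectors and the generating settings.
#' @export
synth_odor_trace <- function(model, valve_id, dilution_fraction,
                             duration_ms = 400, dt_ms = 1, seed = NULL) {
  if (valve_id < 1 || valve_id > length(model$peak_ms))
    stop("configuration error: unknown valve_id ", valve_id, call. = FALSE)
  if (dilution_fraction < 0 || dilution_fraction > 1)
    stop("dilution_fraction must lie in [0, 1]", call. = FALSE)
  tp <- model$peak_ms[valve_id]
  tau <- model$rise_tau_ms[min(valve_id, length(model$rise_tau_ms))]
  # Start the rise before the nominal onset so that the 10%-of-max crossing
  # of the noise-free trace falls on onset_ms: for a saturating exponential
  # capped at the peak, 10% of max is reached tau * ln(1 - 0.1 * M) after
  # the start, with M the attained fraction of the asymptote at the peak.
  m_frac <- 1 - exp(-(tp - model$onset_ms) / tau)
  t_start <- model$onset_ms + tau * log(1 - 0.1 * m_frac)
  time_ms <- seq(0, duration_ms, by = dt_ms)
  amp <- model$gain * dilution_fraction
  rise <- 1 - exp(-pmax(time_ms - t_start, 0) / tau)
  peak_val <- 1 - exp(-(tp - t_start) / tau)
  shape <- ifelse(time_ms <= tp, rise,
                  peak_val * exp(-(time_ms - tp) / model$decay_tau_ms))
  conc <- amp * shape / peak_val
  if (model$noise_sd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(length(conc), 0, model$noise_sd)
             else with_local_seed(seed, stats::rnorm(length(conc), 0, model$noise_sd))
    conc <- conc + noise
  }
  structure(list(time_ms = time_ms, concentration = conc,
                 valve_id = valve_id, dilution_fraction = dilution_fraction,
                 dt_ms = dt_ms),
            class = "pulse_trace")
}
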