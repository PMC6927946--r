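# Seven-phase pre-training curriculum.
#
# Phases gradually introduce the conditions for earning a water reward:
# pre-sampling occupancy threshold, lick criterion, reward delay, reward
# volume and inter-trial interval. Fields printed as ranges ramp linearly
# over the phase's minimal trial count and clamp at the end value.

#' Default pre-training curriculum
#'
#' The packaged seven-phase curriculum. Each row gives one phase:
#' \describe{
#'   \item{phase_id}{1..7.}
#'   \item{threshold}{Pre-sampling occupancy threshold (fraction of the
#'     500 ms pre-period the beam must be broken before the final valve
#'     opens); 0 to 0.875.}
#'   \item{criterion}{Lick criterion: number of 500 ms response-window
#'     blocks that must contain at least one lick; 0 to 3.}
#'   \item{delay_start_ms, delay_end_ms}{Delay until water reward (ms);
#'     equal values mean a fixed delay, unequal a linear ramp.}
#'   \item{min_trials}{Minimal completed trials before the phase can end.}
#'   \item{reward_start_ul, reward_end_ul}{Water reward volume (microliters),
#'     possibly ramped.}
#'   \item{iti_start_s, iti_end_s}{Inter-trial interval (s), possibly ramped.}
#' }
#'
#' @return Data frame with one row per phase.
#' @export
default_curriculum <- function() {
  data.frame(
    phase_id        = 1:7,
    threshold       = c(0, 0, 0.125, 0.25, 0.50, 0.75, 0.875),
    criterion       = c(0L, 0L, 0L, 0L, 1L, 2L, 3L),
    delay_start_ms  = c(0, 0, 21, 500, 2000, 2000, 2000),
    delay_end_ms    = c(0, 0, 500, 1980, 2000, 2000, 2000),
    min_trials      = c(50L, 50L, 100L, 100L, 100L, 100L, 100L),
    reward_start_ul = c(20, 20, 10, 10, 10, 10, 15),
    reward_end_ul   = c(20, 10.5, 10, 10, 10, 10, 15),
    iti_start_s     = c(0, 0.5, 1, 1, 1, 1, 1),
    iti_end_s       = c(0.5, 3.9, 1, 1, 1, 1, 1)
  )
}

validate_curriculum <- function(cur) {
  need <- names(default_curriculum())
  miss <- setdiff(need, names(cur))
  if (length(miss))
    stop("curriculum is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(cur$threshold < 0 | cur$threshold > 1))
    stop("curriculum thresholds must lie in [0, 1]", call. = FALSE)
  if (any(cur$min_trials < 1))
    stop("curriculum min_trials must be positive", call. = FALSE)
  if (any(!is.finite(as.matrix(cur[setdiff(need, "phase_id")]))))
    stop("curriculum contains non-finite values", call. = FALSE)
  invisible(cur)
}

ramp <- function(start, end, index, span) {
  if (start == end) return(start)
  frac <- min(max(index / span, 0), 1)
  start + (end - start) * frac
}

#' Effective phase parameters at a trial index
#'
#' Resolves ramped curriculum fields at a given position within the phase:
#' linear interpolation from the start to the end value over the phase's
#' `min_trials`, clamped at the end value thereafter. Scalar fields are
#' returned as-is.
#'
#' @param curriculum Curriculum data frame (see [default_curriculum()]).
#' @param phase_id Phase number (1..7).
#' @param trial_index 0-based index of the trial within the phase.
#' @return List with `threshold`, `criterion`, `delay_ms`, `reward_ul`,
#'   `iti_s`, `min_trials`.
#' @examples
#' phase_parameters(default_curriculum(), 3, 0)$delay_ms    # 21
#' phase_parameters(default_curriculum(), 3, 100)$delay_ms  # 500
#' @export
phase_parameters <- function(curriculum, phase_id, trial_index = 0L) {
  row <- curriculum[curriculum$phase_id == phase_id, ]
  if (nrow(row) != 1L)
    stop("configuration error: unknown phase ", phase_id, call. = FALSE)
  if (trial_index < 0L) stop("trial_index must be >= 0", call. = FALSE)
  span <- row$min_trials
  list(threshold = row$threshold,
       criterion = row$criterion,
       delay_ms  = ramp(row$delay_start_ms, row$delay_end_ms, trial_index, span),
       reward_ul = ramp(row$reward_start_ul, row$reward_end_ul, trial_index, span),
       iti_s     = ramp(row$iti_start_s, row$iti_end_s, trial_index, span),
       min_trials = row$min_trials)
}

#' Curriculum state for one animal
#'
#' Tracks the animal's current phase, the number of completed trials in the
#' phase and a rolling window of the last 20 completed-trial results.
#'
#' @param animal_id Animal identifier.
#' @param phase Starting phase (default 1); `"DISCRIMINATION"` once
#'   pre-training is complete.
#' @return Object of class `curriculum_state`.
#' @export
curriculum_state <- function(animal_id, phase = 1L) {
  structure(list(animal_id = as.character(animal_id),
                 phase = phase,
                 trials_in_phase = 0L,
                 window = logical(0)),
            class = "curriculum_state")
}

#' Advance the curriculum after a completed trial
#'
#' Aborted entries carry no curriculum credit and must not be passed here.
#' The phase advances when at least `min_trials` trials are completed in the
#' phase and at least 16 of the last 20 completed trials were correct
#' (80% accuracy); after phase 7 the state becomes `"DISCRIMINATION"`.
#' In pre-training, a completed trial that ends in reward collection counts
#' as correct; in discrimination, Hits and Correct Rejections do.
#'
#' @param state A [curriculum_state()] object.
#' @param correct Logical: was the completed trial correct?
#' @param curriculum Curriculum data frame.
#' @return Updated `curriculum_state`; `$advanced` is `TRUE` on the call
#'   that triggered a phase transition.
#' @export
update_curriculum <- function(state, correct, curriculum = default_curriculum()) {
  state$advanced <- FALSE
  if (identical(state$phase, "DISCRIMINATION")) {
    state$trials_in_phase <- state$trials_in_phase + 1L
    return(state)
  }
  state$trials_in_phase <- state$trials_in_phase + 1L
  state$window <- c(state$window, isTRUE(correct))
  if (length(state$window) > 20L)
    state$window <- state$window[(length(state$window) - 19L):length(state$window)]
  row <- curriculum[curriculum$phase_id == state$phase, ]
  if (state$trials_in_phase >= row$min_trials &&
      length(state$window) == 20L && sum(state$window) >= 16L) {
    state$phase <- if (state$phase >= max(curriculum$phase_id))
      "DISCRIMINATION" else state$phase + 1L
    state$trials_in_phase <- 0L
    state$window <- logical(0)
    state$advanced <- TRUE
  }
  state
}
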