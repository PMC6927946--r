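# Trial state machine.
#
# A port entry with a complete RFID read starts a trial: a 500 ms
# pre-sampling period gates the final valve on port occupancy; the odor (or
# clean air during pre-training) is applied for at most 2 s or until head
# retraction; licks are counted in four 500 ms response blocks; the outcome
# determines reward and inter-trial interval. Incorrect responses (Miss,
# False Alarm) add a 3 s time penalty to the 1 s base ITI.

#' Trial timing constants
#'
#' Fixed timings of the trial state machine, in milliseconds unless noted:
#' 500 ms pre-sampling period, at most 2000 ms odor application, 500 ms
#' response blocks, 1 s base inter-trial interval, 3 s penalty added after
#' Miss or False Alarm, and the 120 ms high-pressure pre-pulse that loads
#' the odor line before the final valve opens.
#'
#' @param presampling_ms,odor_max_ms,response_block_ms,prepulse_ms
#'   Durations in milliseconds.
#' @param base_iti_s,penalty_s Durations in seconds.
#' @param sample_rate_hz Beam-state sampling rate used for occupancy traces.
#' @return List of class `trial_timings`.
#' @export
trial_timings <- function(presampling_ms = 500, odor_max_ms = 2000,
                          response_block_ms = 500, base_iti_s = 1,
                          penalty_s = 3, prepulse_ms = 120,
                          sample_rate_hz = 1000) {
  t <- list(presampling_ms = presampling_ms, odor_max_ms = odor_max_ms,
            response_block_ms = response_block_ms, base_iti_s = base_iti_s,
            penalty_s = penalty_s, prepulse_ms = prepulse_ms,
            sample_rate_hz = sample_rate_hz)
  if (any(unlist(t) <= 0)) stop("all trial timings must be positive", call. = FALSE)
  class(t) <- "trial_timings"
  t
}

#' Trial outcome constants
#'
#' The five outcomes of a port entry: respond to S+ (`HIT`), withhold to S+
#' (`MISS`), respond to S- (`FALSE_ALARM`), withhold to S-
#' (`CORRECT_REJECTION`), or an entry that never became a completed trial
#' (`ABORTED`: incomplete RFID read or failed pre-sampling).
#'
#' @format Character vector of the five outcome tokens.
#' @export
OUTCOMES <- c("HIT", "MISS", "FALSE_ALARM", "CORRECT_REJECTION", "ABORTED")

#' Gate the final valve on pre-sampling occupancy
#'
#' The pre-sampling rate is the fraction of beam-state samples in the 500 ms
#' pre-period during which the beam is broken (head in port). The final
#' valve opens only if it reaches the phase's threshold.
#'
#' @param occupancy_trace Logical or 0/1 vector of beam-state samples
#'   spanning exactly the pre-sampling period at the configured rate.
#' @param threshold Occupancy fraction in `[0, 1]` required to pass.
#' @param timings A [trial_timings()] object.
#' @return `"PASS"` or `"FAIL"`.
#' @examples
#' evaluate_presampling(c(rep(1, 450), rep(0, 50)), threshold = 0.875)  # PASS
#' @export
evaluate_presampling <- function(occupancy_trace, threshold,
                                 timings = trial_timings()) {
  expected <- round(timings$presampling_ms / 1000 * timings$sample_rate_hz)
  if (length(occupancy_trace) != expected)
    stop("occupancy trace has ", length(occupancy_trace), " samples; expected ",
         expected, " (", timings$presampling_ms, " ms at ",
         timings$sample_rate_hz, " Hz)", call. = FALSE)
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]", call. = FALSE)
  if (mean(as.numeric(occupancy_trace) > 0) >= threshold) "PASS" else "FAIL"
}

#' Classify a completed trial outcome
#'
#' A lick response is at least `max(criterion, 1)` response blocks
#' containing licks (a criterion of 0, used in early pre-training, still
#' requires one licked block to count as a response in discrimination).
#'
#' @param label `"S+"` or `"S-"`.
#' @param lick_blocks Number of 500 ms response blocks with at least one
#'   lick contact (0-4).
#' @param lick_criterion Phase lick criterion (0-3).
#' @return One of `"HIT"`, `"MISS"`, `"FALSE_ALARM"`, `"CORRECT_REJECTION"`.
#' @export
classify_outcome <- function(label, lick_blocks, lick_criterion = 1L) {
  stopifnot(label %in% c(S_PLUS, S_MINUS),
            lick_blocks >= 0, lick_blocks <= 4,
            lick_criterion >= 0, lick_criterion <= 3)
  responded <- lick_blocks >= max(lick_criterion, 1L)
  if (identical(label, S_PLUS)) {
    if (responded) "HIT" else "MISS"
  } else {
    if (responded) "FALSE_ALARM" else "CORRECT_REJECTION"
  }
}

#' Schedule the inter-trial interval for an outcome
#'
#' Correct outcomes (Hit, Correct Rejection) incur the base ITI only; any
#' false response to an odor (Miss, False Alarm) adds the time penalty.
#' Aborted entries impose no ITI and are a contract error here.
#'
#' @param outcome One of the completed-trial outcomes.
#' @param base_iti_s Base inter-trial interval (s).
#' @param penalty_s Penalty added after an incorrect response (s).
#' @return ITI in seconds.
#' @examples
#' schedule_iti("HIT")          # 1
#' schedule_iti("FALSE_ALARM")  # 4
#' @export
schedule_iti <- function(outcome, base_iti_s = 1, penalty_s = 3) {
  if (identical(outcome, "ABORTED"))
    stop("aborted entries impose no ITI; schedule_iti is undefined for them",
         call. = FALSE)
  stopifnot(outcome %in% OUTCOMES)
  if (outcome %in% c("MISS", "FALSE_ALARM")) base_iti_s + penalty_s else base_iti_s
}

#' Gate trial initiation on the RFID read
#'
#' A port entry (IR beam break) starts a trial only when a complete RFID
#' read identifies a registered animal. An incomplete or absent read aborts
#' the entry and returns the controller to baseline with no ITI penalty.
#'
#' @param beam_break Logical: was a beam break detected?
#' @param rfid RFID read result: the animal id (complete read) or `NA`
#'   (incomplete/no read).
#' @param registered Character vector of registered animal ids.
#' @return List with `status` (`"TRIAL"`, `"ABORTED"`, `"IGNORED"` or
#'   `"UNREGISTERED"`) and `animal_id` (`NA` unless a trial starts).
#' @export
begin_trial <- function(beam_break, rfid, registered) {
  if (!isTRUE(beam_break))
    return(list(status = "IGNORED", animal_id = NA_character_))
  if (is.na(rfid) || !nzchar(rfid))
    return(list(status = "ABORTED", animal_id = NA_character_))
  if (!rfid %in% registered) {
    warning("RFID read for unregistered animal: ", rfid, call. = FALSE)
    return(list(status = "UNREGISTERED", animal_id = as.character(rfid)))
  }
  list(status = "TRIAL", animal_id = as.character(rfid))
}

# Assemble one trial record row. Internal: all fields already decided.
trial_record <- function(time_s, animal_id, phase, label, odor_id, occupancy,
                         lick_blocks, head_retract_ms, outcome, reward_ul,
                         iti_s, odor_on_ms = 0,
                         block_id = NA_integer_, block_index = NA_integer_) {
  data.frame(time_s = time_s, animal_id = animal_id,
             phase = as.character(phase),
             trial_label = label, odor_id = odor_id,
             presampling_occupancy = occupancy,
             lick_blocks = as.integer(lick_blocks),
             head_retract_ms = head_retract_ms,
             outcome = outcome, reward_ul = reward_ul, iti_s = iti_s,
             odor_on_ms = odor_on_ms,
             block_id = as.integer(block_id),
             block_index = as.integer(block_index),
             stringsAsFactors = FALSE)
}

#' Run one trial through the state machine
#'
#' Orchestrates a single initiated trial: pre-sampling gate, final-valve
#' opening, stimulus (a sequencer label in discrimination, clean air with
#' label `NONE` in pre-training), response classification, reward and ITI
#' scheduling. Emits exactly one trial record.
#'
#' In pre-training, a completed trial is rewarded when the lick criterion is
#' met (phases with criterion 0 reward every completed trial); rewarded
#' completions are logged as `HIT`, unrewarded as `MISS`. A failed
#' pre-sampling gate aborts the trial with no reward and no ITI penalty.
#'
#' @param animal_id Animal identifier.
#' @param phase Phase id 1..7 or `"DISCRIMINATION"`.
#' @param trial_index 0-based index within the phase (drives ramps).
#' @param occupancy Pre-sampling occupancy fraction in `[0, 1]`.
#' @param lick_blocks Response blocks containing licks (0-4).
#' @param head_retract_ms Head retraction time after final-valve opening
#'   (ms), or `NA` if the head stayed in past the response window.
#' @param label Trial label (`"S+"`/`"S-"`) in discrimination; ignored in
#'   pre-training.
#' @param odor_id Odor identifier (or `"clean_air"`).
#' @param curriculum Curriculum data frame.
#' @param timings A [trial_timings()] object.
#' @param time_s Trial start time (s from session start), logged as-is.
#' @param block_id,block_index Sequencer provenance for discrimination
#'   trials.
#' @return One-row data frame (trial record).
#' @export
run_trial <- function(animal_id, phase, trial_index, occupancy, lick_blocks,
                      head_retract_ms = NA_real_, label = "NONE",
                      odor_id = "clean_air",
                      curriculum = default_curriculum(),
                      timings = trial_timings(), time_s = 0,
                      block_id = NA_integer_, block_index = NA_integer_) {
  disc <- identical(phase, "DISCRIMINATION")
  pp <- phase_parameters(curriculum, if (disc) max(curriculum$phase_id) else phase,
                         trial_index)
  if (occupancy < pp$threshold) {
    return(trial_record(time_s, animal_id, phase,
                        if (disc) label else "NONE", odor_id, occupancy,
                        0L, NA_real_, "ABORTED", 0, 0, 0,
                        block_id, block_index))
  }
  odor_on_ms <- min(timings$odor_max_ms,
                    if (is.na(head_retract_ms)) timings$odor_max_ms
                    else max(head_retract_ms, 0))
  if (disc) {
    outcome <- classify_outcome(label, lick_blocks, pp$criterion)
    reward <- if (outcome == "HIT") pp$reward_ul else 0
    iti <- schedule_iti(outcome, pp$iti_s, timings$penalty_s)
    rec_label <- label
  } else {
    rewarded <- lick_blocks >= pp$criterion
    outcome <- if (rewarded) "HIT" else "MISS"
    reward <- if (rewarded) pp$reward_ul else 0
    iti <- schedule_iti(outcome, pp$iti_s, timings$penalty_s)
    rec_label <- "NONE"
  }
  trial_record(time_s, animal_id, phase, rec_label, odor_id, occupancy,
               lick_blocks, head_retract_ms, outcome, reward, iti,
               odor_on_ms, block_id, block_index)
}
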