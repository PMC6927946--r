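# End-to-end cohort simulation.
#
# Drives the trial controller with events from the virtual rig: per-animal
# circadian initiations, RFID read failures, pre-sampling failures and
# learning-agent responses, under single-port mutual exclusion. Produces a
# schema-valid event log reproducible under a fixed seed.

#' Simulation configuration
#'
#' @param animal_ids Character vector of animal identifiers.
#' @param groups Treatment group label per animal (recycled; default one
#'   group).
#' @param agents A single [agent_params()] shared by the cohort, or a named
#'   list of per-animal `agent_params`.
#' @param curriculum Curriculum data frame (default: packaged seven-phase
#'   table).
#' @param sequence [sequence_params()] for the discrimination sequencer.
#' @param odor_pair Two odor identifiers used in discrimination.
#' @param start_phase `1` to run the full pre-training, or
#'   `"DISCRIMINATION"` to start with trained-compliance animals.
#' @param timings A [trial_timings()] object.
#' @param retry_mean_s Mean of the exponential re-try delay after a blocked
#'   (port busy) initiation; a re-tried initiation that is blocked again is
#'   dropped.
#' @param seed Master seed; all per-animal streams derive from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(animal_ids, groups = "all",
                       agents = agent_params(),
                       curriculum = default_curriculum(),
                       sequence = sequence_params(),
                       odor_pair = c("odorA", "odorB"),
                       start_phase = 1L,
                       timings = trial_timings(),
                       retry_mean_s = 60,
                       seed = 1L) {
  animal_ids <- as.character(animal_ids)
  if (length(animal_ids) == 0L) stop("cohort must be non-empty", call. = FALSE)
  if (anyDuplicated(animal_ids)) stop("duplicate animal_id", call. = FALSE)
  if (inherits(agents, "agent_params"))
    agents <- stats::setNames(rep(list(agents), length(animal_ids)), animal_ids)
  if (!setequal(names(agents), animal_ids))
    stop("agents must be named for every animal", call. = FALSE)
  validate_curriculum(curriculum)
  structure(list(animal_ids = animal_ids,
                 groups = rep_len(groups, length(animal_ids)),
                 agents = agents, curriculum = curriculum,
                 sequence = sequence, odor_pair = odor_pair,
                 start_phase = start_phase, timings = timings,
                 retry_mean_s = retry_mean_s, seed = as.integer(seed)),
            class = "run_config")
}

#' Simulate a cohort on the automated training system
#'
#' Runs every port entry of every animal through the RFID gate, the
#' pre-sampling gate, the curriculum (or the discrimination task) and the
#' response classifier, enforcing that only one animal occupies the single
#' odor port at a time. A blocked initiation is re-tried once after an
#' exponential delay and dropped if still blocked.
#'
#' @param config A [run_config()] object.
#' @param duration_h Simulated duration in hours (clock starts at midnight).
#' @param seed Overrides `config$seed` when non-`NULL`.
#' @return Object of class `event_log`: list with `records` (data frame,
#'   one row per port entry that engaged the controller) and `meta`
#'   (seed, config hash, start time, counterbalance assignment).
#' @export
simulate_cohort <- function(config, duration_h = 24, seed = NULL) {
  if (!inherits(config, "run_config")) stop("config must be a run_config", call. = FALSE)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  cb <- assign_counterbalance(
    data.frame(animal_id = config$animal_ids, group = config$groups,
               stringsAsFactors = FALSE),
    config$odor_pair, seed = config$seed)

  # Per-animal initiation streams, merged into one time-ordered queue.
  inits <- vector("list", length(config$animal_ids))
  for (i in seq_along(config$animal_ids)) {
    id <- config$animal_ids[i]
    t_h <- sample_initiations(config$agents[[id]], duration_h,
                              seed = derive_seed(config$seed, i, 0L))
    if (length(t_h))
      inits[[i]] <- data.frame(time_s = t_h * 3600, animal_id = id,
                               stringsAsFactors = FALSE)
  }
  queue <- do.call(rbind, inits)
  if (is.null(queue) || nrow(queue) == 0L)
    return(new_event_log(empty_records(), config, cb))
  queue <- queue[order(queue$time_s), , drop = FALSE]

  sched <- trial_scheduler(config$sequence, config$animal_ids)
  states <- lapply(config$animal_ids, curriculum_state,
                   phase = config$start_phase)
  names(states) <- config$animal_ids
  counts_n <- stats::setNames(rep(0L, length(config$animal_ids)),
                              config$animal_ids)  # completed discrimination trials
  records <- vector("list", nrow(queue) + 64L)
  n_rec <- 0L
  port_free_at <- -Inf

  ev_time <- queue$time_s
  ev_animal <- queue$animal_id

  with_local_seed(config$seed + 1L, {
    i <- 1L
    retry_time <- numeric(0)   # small sorted buffer of re-tried initiations
    retry_animal <- character(0)
    repeat {
      from_retry <- length(retry_time) > 0L &&
        (i > length(ev_time) || retry_time[1] <= ev_time[i])
      if (!from_retry && i > length(ev_time)) break
      if (from_retry) {
        t_now <- retry_time[1]; id <- retry_animal[1]
        retry_time <- retry_time[-1]; retry_animal <- retry_animal[-1]
        if (t_now < port_free_at) next  # blocked twice: dropped
      } else {
        t_now <- ev_time[i]; id <- ev_animal[i]
        i <- i + 1L
        if (t_now < port_free_at) {
          # Port occupied: one exponential re-try, then drop.
          rt <- t_now + stats::rexp(1, 1 / config$retry_mean_s)
          if (rt <= duration_h * 3600) {
            pos <- findInterval(rt, retry_time)
            retry_time <- append(retry_time, rt, after = pos)
            retry_animal <- append(retry_animal, id, after = pos)
          }
          next
        }
      }
      ev <- list(time_s = t_now, animal_id = id)
      ag <- config$agents[[id]]
      st <- states[[id]]

      # RFID gate: incomplete read aborts the entry, no trial context.
      if (stats::runif(1) < ag$p_rfid_fail) {
        n_rec <- n_rec + 1L
        records[[n_rec]] <- trial_record(ev$time_s, id, as.character(st$phase),
                                         "NONE", "none", 0, 0L, NA_real_,
                                         "ABORTED", 0, 0, 0)
        port_free_at <- ev$time_s + 0.5
        next
      }

      disc <- identical(st$phase, "DISCRIMINATION")
      pp <- phase_parameters(config$curriculum,
                             if (disc) max(config$curriculum$phase_id) else st$phase,
                             st$trials_in_phase)
      # Pre-sampling occupancy: compliant entries sample above threshold.
      occ <- if (stats::runif(1) < ag$p_presample_fail)
        stats::runif(1, 0, max(pp$threshold, 1e-6)) * 0.999
      else stats::runif(1, pp$threshold, 1)

      if (disc) {
        drawn <- scheduler_draw(sched, id)
        sched <- drawn$scheduler
        label <- drawn$label
        odor <- if (identical(label, S_PLUS)) cb$splus_odor[cb$animal_id == id]
                else cb$sminus_odor[cb$animal_id == id]
        resp <- agent_response(ag, counts_n[[id]], label, pp$criterion)
        rec <- run_trial(id, "DISCRIMINATION", st$trials_in_phase, occ,
                         resp$lick_blocks, resp$head_retract_ms,
                         label = label, odor_id = odor,
                         curriculum = config$curriculum,
                         timings = config$timings, time_s = ev$time_s,
                         block_id = drawn$block_id, block_index = drawn$index)
        if (rec$outcome != "ABORTED") {
          counts_n[[id]] <- counts_n[[id]] + 1L
          st <- update_curriculum(st, rec$outcome %in% c("HIT", "CORRECT_REJECTION"),
                                  config$curriculum)
        }
      } else {
        resp <- agent_response(ag, counts_n[[id]], "NONE", pp$criterion)
        rec <- run_trial(id, st$phase, st$trials_in_phase, occ,
                         resp$lick_blocks, resp$head_retract_ms,
                         curriculum = config$curriculum,
                         timings = config$timings, time_s = ev$time_s)
        if (rec$outcome != "ABORTED")
          st <- update_curriculum(st, rec$reward_ul > 0, config$curriculum)
      }
      states[[id]] <- st
      n_rec <- n_rec + 1L
      records[[n_rec]] <- rec
      busy <- 0.5 + rec$odor_on_ms / 1000 + rec$iti_s
      port_free_at <- ev$time_s + busy
    }
  })
  recs <- if (n_rec > 0L) do.call(rbind, records[seq_len(n_rec)]) else empty_records()
  rownames(recs) <- NULL
  new_event_log(recs, config, cb)
}

empty_records <- function() {
  trial_record(numeric(0), character(0), character(0), character(0),
               character(0), numeric(0), integer(0), numeric(0),
               character(0), numeric(0), numeric(0), numeric(0),
               integer(0), integer(0))
}

new_event_log <- function(records, config, counterbalance,
                          start_time = "2024-01-01T00:00:00.000") {
  structure(list(records = records,
                 meta = list(format_version = 1L,
                             seed = config$seed,
                             config_hash = config_hash(config),
                             start_time = start_time,
                             counterbalance = counterbalance)),
            class = "event_log")
}
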