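# Structured-text run configuration (YAML). An omitted curriculum section
# falls back to the packaged seven-phase defaults; unknown keys are
# rejected so that typos cannot silently change a run.

#' Stable hash of a run configuration
#'
#' @param config A [run_config()] object (or any R object).
#' @return Character hash; changes iff any configuration field changes.
#' @export
config_hash <- function(config) {
  rlang::hash(config)
}

config_keys <- c("cohort", "curriculum", "sequence", "agents", "odor_pair",
                 "start_phase", "retry_mean_s", "seed", "duration_h")

#' Load and validate a run configuration file
#'
#' YAML with sections `cohort` (list of `{animal_id, group}` or a plain id
#' list), optional `curriculum` (rows overriding the packaged defaults;
#' omitted = packaged seven-phase table), optional `sequence`, `agents`,
#' `odor_pair`, `start_phase`, `retry_mean_s`, `seed`. Constraint
#' violations are reported with their key path.
#'
#' @param path YAML file path.
#' @return A [run_config()] object; `$duration_h` attached when present.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(raw$cohort) || length(raw$cohort) == 0L)
    stop("config error at 'cohort': at least one animal required", call. = FALSE)
  if (is.list(raw$cohort[[1]])) {
    ids <- vapply(raw$cohort, function(a) as.character(a$animal_id), character(1))
    groups <- vapply(raw$cohort, function(a)
      as.character(a$group %||% "all"), character(1))
  } else {
    ids <- as.character(unlist(raw$cohort))
    groups <- "all"
  }
  curriculum <- default_curriculum()
  if (!is.null(raw$curriculum) && length(raw$curriculum)) {
    cur <- do.call(rbind, lapply(raw$curriculum, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    miss <- setdiff(names(default_curriculum()), names(cur))
    if (length(miss))
      stop("config error at 'curriculum': missing column(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    curriculum <- cur[, names(default_curriculum())]
  }
  tryCatch(validate_curriculum(curriculum),
           error = function(e) stop("config error at 'curriculum': ",
                                    conditionMessage(e), call. = FALSE))
  seq_par <- do.call(sequence_params, as.list(raw$sequence %||% list()))
  agent_args <- raw$agents %||% list()
  if (!is.null(agent_args$tau) && agent_args$tau <= 0)
    stop("config error at 'agents.tau': must be positive", call. = FALSE)
  agents <- tryCatch(do.call(agent_params, agent_args),
                     error = function(e) stop("config error at 'agents': ",
                                              conditionMessage(e), call. = FALSE))
  cfg <- run_config(
    animal_ids = ids, groups = groups, agents = agents,
    curriculum = curriculum, sequence = seq_par,
    odor_pair = as.character(raw$odor_pair %||% c("odorA", "odorB")),
    start_phase = raw$start_phase %||% 1L,
    retry_mean_s = raw$retry_mean_s %||% 60,
    seed = raw$seed %||% 1L)
  cfg$duration_h <- raw$duration_h %||% 24
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
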