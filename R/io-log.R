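# Event-log format: RFC-4180 CSV, UTF-8, one trial record per row, with
# '#'-prefixed header lines carrying format version, config hash, seed and
# session start time. Schema versioned from 1; readers reject unknown major
# versions.

LOG_COLUMNS <- c("time_s", "animal_id", "phase", "trial_label", "odor_id",
                 "presampling_occupancy", "lick_blocks", "head_retract_ms",
                 "outcome", "reward_ul", "iti_s", "odor_on_ms",
                 "block_id", "block_index")

#' Convert session-relative times to ISO-8601 timestamps
#'
#' @param time_s Seconds since session start.
#' @param start_time Session start as an ISO-8601 string.
#' @return Character vector of ISO-8601 timestamps with millisecond
#'   precision.
#' @export
iso_timestamp <- function(time_s, start_time = "2024-01-01T00:00:00.000") {
  t0 <- as.POSIXct(sub("T", " ", start_time), tz = "UTC")
  format(t0 + time_s, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
}

#' Validate an event log against the record schema
#'
#' Checks column presence, enumeration values, the reward invariant
#' (a positive reward volume exactly on rewarded completions), the ITI
#' structure and per-animal time ordering.
#'
#' @param log An `event_log` object or a trial-record data frame.
#' @return `TRUE` invisibly when valid; otherwise a character vector of
#'   violations naming row numbers and fields.
#' @export
validate_event_log <- function(log) {
  rec <- if (inherits(log, "event_log")) log$records else log
  problems <- character(0)
  miss <- setdiff(LOG_COLUMNS, names(rec))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  bad <- which(!rec$outcome %in% OUTCOMES)
  if (length(bad))
    problems <- c(problems, sprintf("row %d: unknown outcome '%s'",
                                    bad, rec$outcome[bad]))
  bad <- which((rec$reward_ul > 0) != (rec$outcome == "HIT"))
  if (length(bad))
    problems <- c(problems,
                  sprintf("row %d: field reward_ul (%g) inconsistent with outcome %s",
                          bad, rec$reward_ul[bad], rec$outcome[bad]))
  bad <- which(rec$outcome == "ABORTED" & rec$iti_s != 0)
  if (length(bad))
    problems <- c(problems, sprintf("row %d: aborted entry with nonzero iti_s", bad))
  bad <- which(rec$odor_on_ms > 2000 + 1e-9)
  if (length(bad))
    problems <- c(problems, sprintf("row %d: odor_on_ms exceeds 2000", bad))
  for (id in unique(rec$animal_id)) {
    t <- rec$time_s[rec$animal_id == id]
    if (is.unsorted(t))
      problems <- c(problems, sprintf("records for animal %s are not time-ordered", id))
  }
  if (length(problems) == 0L) invisible(TRUE) else problems
}

#' Write an event log to delimited text
#'
#' Comma-separated, RFC-4180, UTF-8; `#`-prefixed header lines carry the
#' format version, config hash, seed and start time. A JSON-lines
#' alternative is available behind `format = "jsonl"`.
#'
#' @param log An `event_log` object.
#' @param path Output file path.
#' @param format `"csv"` (default) or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  stopifnot(inherits(log, "event_log"))
  v <- validate_event_log(log)
  if (!isTRUE(v))
    stop("refusing to write invalid log:\n", paste(v, collapse = "\n"),
         call. = FALSE)
  header <- c(paste0("# format_version: ", log$meta$format_version),
              paste0("# config_hash: ", log$meta$config_hash),
              paste0("# seed: ", log$meta$seed),
              paste0("# start_time: ", log$meta$start_time))
  rec <- log$records
  rec$timestamp <- iso_timestamp(rec$time_s, log$meta$start_time)
  rec <- rec[, c("timestamp", LOG_COLUMNS)]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  if (format == "csv") {
    utils::write.csv(rec, con, row.names = FALSE, quote = TRUE, na = "")
  } else {
    writeLines(vapply(seq_len(nrow(rec)), function(i)
      jsonlite::toJSON(as.list(rec[i, ]), auto_unbox = TRUE, digits = NA,
                       na = "null"),
      character(1)), con)
  }
  invisible(path)
}

parse_log_header <- function(lines) {
  meta <- list()
  for (l in lines) {
    m <- regmatches(l, regexec("^# *([a-z_]+): *(.*)$", l))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  if (is.null(meta$format_version))
    stop("malformed log: missing '# format_version' header line", call. = FALSE)
  meta$format_version <- as.integer(meta$format_version)
  if (is.na(meta$format_version) || meta$format_version != 1L)
    stop("unsupported log format version: ", meta$format_version, call. = FALSE)
  if (!is.null(meta$seed)) meta$seed <- as.integer(meta$seed)
  meta
}

#' Read an event log written by [write_event_log()]
#'
#' Round-trips all record fields. Malformed rows raise an error naming the
#' line number and field; an unrecognized format version is rejected.
#'
#' @param path Log file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return An `event_log` object.
#' @export
read_event_log <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines)
  meta <- parse_log_header(lines[hdr])
  body <- lines[setdiff(seq_along(lines), hdr)]
  body <- body[nzchar(body)]
  if (format == "csv") {
    if (length(body) == 0L)
      stop("malformed log: no column header row", call. = FALSE)
    rec <- tryCatch(
      utils::read.csv(text = body, stringsAsFactors = FALSE,
                      colClasses = c(timestamp = "character",
                                     animal_id = "character",
                                     phase = "character",
                                     trial_label = "character",
                                     odor_id = "character",
                                     outcome = "character")),
      error = function(e) stop("malformed log: ", conditionMessage(e),
                               call. = FALSE))
    n_fields <- lengths(regmatches(body, gregexpr(",", body))) + 1L
    bad <- which(n_fields != n_fields[1])
    if (length(bad))
      stop("malformed row at line ", bad[1] + length(hdr),
           ": expected ", n_fields[1], " fields, found ", n_fields[bad[1]],
           call. = FALSE)
  } else {
    rows <- lapply(seq_along(body), function(i) {
      tryCatch(jsonlite::fromJSON(body[i]),
               error = function(e) stop("malformed row at line ",
                                        i + length(hdr), ": ",
                                        conditionMessage(e), call. = FALSE))
    })
    rec <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(lapply(r, function(x) if (is.null(x)) NA else x),
                    stringsAsFactors = FALSE)))
  }
  miss <- setdiff(c("timestamp", LOG_COLUMNS), names(rec))
  if (length(miss))
    stop("malformed log: missing field(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  rec$lick_blocks <- as.integer(rec$lick_blocks)
  rec$block_id <- as.integer(rec$block_id)
  rec$block_index <- as.integer(rec$block_index)
  for (col in c("time_s", "presampling_occupancy", "head_retract_ms",
                "reward_ul", "iti_s", "odor_on_ms"))
    rec[[col]] <- as.numeric(rec[[col]])
  records <- rec[, LOG_COLUMNS]
  v <- validate_event_log(records)
  if (!isTRUE(v))
    stop("invalid log ", path, ":\n", paste(v, collapse = "\n"), call. = FALSE)
  structure(list(records = records,
                 meta = list(format_version = meta$format_version,
                             seed = meta$seed,
                             config_hash = meta$config_hash,
                             start_time = meta$start_time)),
            class = "event_log")
}
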