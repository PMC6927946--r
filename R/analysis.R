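# Performance and signal-detection analytics.

#' Fraction of correct trials
#'
#' Hits plus Correct Rejections over the number of completed trials in the
#' window. Empty windows are undefined (`NA`), never silently zero.
#'
#' @param outcomes Character vector of completed-trial outcomes.
#' @return Fraction in `[0, 1]`, or `NA_real_` for an empty window.
#' @export
fraction_correct <- function(outcomes) {
  if (length(outcomes) == 0L) return(NA_real_)
  if (any(outcomes == "ABORTED"))
    stop("fraction_correct expects completed trials only", call. = FALSE)
  mean(outcomes %in% c("HIT", "CORRECT_REJECTION"))
}

#' Signal-detection d-prime
#'
#' `d' = qnorm(H*) - qnorm(F*)` with the hit rate `H* = hits / (hits +
#' misses)` and false-alarm rate `F* = fa / (fa + cr)`, each clamped to
#' `[1 / (2N), 1 - 1 / (2N)]` for its own response class so that perfect
#' rates stay finite.
#'
#' @param hits,misses,false_alarms,correct_rejections Outcome counts.
#' @return d-prime, or `NA_real_` when either stimulus class has no trials.
#' @examples
#' dprime(95, 5, 5, 95)  # ~3.29
#' @export
dprime <- function(hits, misses, false_alarms, correct_rejections) {
  stopifnot(hits >= 0, misses >= 0, false_alarms >= 0, correct_rejections >= 0)
  n_plus <- hits + misses
  n_minus <- false_alarms + correct_rejections
  if (n_plus == 0L || n_minus == 0L) return(NA_real_)
  clamp <- function(rate, n) pmin(pmax(rate, 1 / (2 * n)), 1 - 1 / (2 * n))
  h <- clamp(hits / n_plus, n_plus)
  f <- clamp(false_alarms / n_minus, n_minus)
  stats::qnorm(h) - stats::qnorm(f)
}

#' Sliding-window performance series
#'
#' Windowed fraction correct and d-prime over the completed discrimination
#' trials of one animal-task, defined only where the window is full.
#'
#' @param records Trial-record data frame (single animal-task); aborted
#'   entries are dropped.
#' @param window Sliding window size in completed trials (default 100).
#' @return Data frame with `trial` (index of the window's last trial),
#'   `fraction_correct`, `dprime`, and attribute-free `window` column.
#' @export
performance_series <- function(records, window = 100L) {
  records <- records[records$outcome != "ABORTED", , drop = FALSE]
  n <- nrow(records)
  if (n < window)
    return(data.frame(trial = integer(0), fraction_correct = numeric(0),
                      dprime = numeric(0), window = integer(0)))
  is_hit <- as.integer(records$outcome == "HIT")
  is_cr <- as.integer(records$outcome == "CORRECT_REJECTION")
  is_miss <- as.integer(records$outcome == "MISS")
  is_fa <- as.integer(records$outcome == "FALSE_ALARM")
  roll <- function(x) {
    cs <- cumsum(x)
    cs[window:n] - c(0, cs)[1:(n - window + 1L)]
  }
  h <- roll(is_hit); cr <- roll(is_cr); m <- roll(is_miss); fa <- roll(is_fa)
  dp <- mapply(dprime, h, m, fa, cr)
  data.frame(trial = window:n,
             fraction_correct = (h + cr) / window,
             dprime = dp,
             window = window)
}

#' Trials to reach a performance criterion
#'
#' Index of the first completed trial at which the windowed metric reaches
#' the threshold (e.g., fraction correct 0.95, or d-prime 3).
#'
#' @param series A [performance_series()] data frame.
#' @param threshold Criterion value.
#' @param metric `"fraction_correct"` or `"dprime"`.
#' @return Trial count, or `NA_integer_` if the criterion is never reached
#'   (including a window larger than the series).
#' @export
trials_to_criterion <- function(series, threshold,
                                metric = c("fraction_correct", "dprime")) {
  metric <- match.arg(metric)
  if (nrow(series) == 0L) return(NA_integer_)
  idx <- which(!is.na(series[[metric]]) & series[[metric]] >= threshold)
  if (length(idx) == 0L) NA_integer_ else as.integer(series$trial[idx[1]])
}

# Hour of day (0-23) and day index (1-based) from record times in seconds
# since a midnight-aligned session start.
record_hour <- function(time_s) floor((time_s / 3600) %% 24)
record_day <- function(time_s) floor(time_s / 86400) + 1L

#' Circadian activity profile of one animal
#'
#' Fraction of each day's trials falling in each hour of the day, averaged
#' over days with at least one trial. The day boundary is calendar midnight
#' of log-local time; the dark phase spans 18:00-06:00.
#'
#' @param records Trial-record data frame.
#' @param animal_id Animal to profile.
#' @return List with `animal_id`, `hourly_fraction` (length-24 vector
#'   averaging per-day fractions), `day_count`. Empty profile (all-`NA`
#'   fractions, `day_count` 0) when the animal has no trials.
#' @export
circadian_profile <- function(records, animal_id) {
  rec <- records[records$animal_id == animal_id, , drop = FALSE]
  if (nrow(rec) == 0L)
    return(list(animal_id = animal_id,
                hourly_fraction = rep(NA_real_, 24), day_count = 0L))
  hour <- record_hour(rec$time_s)
  day <- record_day(rec$time_s)
  per_day <- vapply(sort(unique(day)), function(d) {
    h <- hour[day == d]
    tabulate(h + 1L, 24L) / length(h)
  }, numeric(24))
  list(animal_id = animal_id,
       hourly_fraction = rowMeans(per_day),
       day_count = ncol(per_day))
}

#' Hourly pooled performance
#'
#' Fraction correct of completed discrimination trials pooled per hour of
#' day across all animals.
#'
#' @param records Trial-record data frame.
#' @return Length-24 vector of fraction correct (`NA` for hours with no
#'   completed trials).
#' @export
hourly_performance <- function(records) {
  rec <- records[records$outcome %in% c("HIT", "MISS", "FALSE_ALARM",
                                        "CORRECT_REJECTION"), , drop = FALSE]
  hour <- record_hour(rec$time_s)
  vapply(0:23, function(h) {
    o <- rec$outcome[hour == h]
    if (length(o) == 0L) NA_real_ else fraction_correct(o)
  }, numeric(1))
}

#' Trials per animal per day
#'
#' @param records Trial-record data frame.
#' @return Data frame with `animal_id`, `day`, `trials` (completed trials
#'   only); empty for an empty log.
#' @export
daily_counts <- function(records) {
  rec <- records[records$outcome != "ABORTED", , drop = FALSE]
  if (nrow(rec) == 0L)
    return(data.frame(animal_id = character(0), day = integer(0),
                      trials = integer(0)))
  tab <- as.data.frame(table(animal_id = rec$animal_id,
                             day = record_day(rec$time_s)),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  out <- data.frame(animal_id = tab$animal_id, day = as.integer(tab$day),
                    trials = as.integer(tab$Freq))
  out[order(out$animal_id, out$day), , drop = FALSE]
}

#' Group-size effect on daily summaries
#'
#' Pearson correlation and least-squares slope of a daily summary statistic
#' (mean accuracy, or trials per animal) against group size.
#'
#' @param group_size Numeric vector of group sizes.
#' @param value Numeric vector of the summary statistic.
#' @return List with `r`, `slope`, `p`; `r` and `p` are `NA` with a warning
#'   when either variable has zero variance.
#' @export
groupsize_effect <- function(group_size, value) {
  stopifnot(length(group_size) == length(value))
  if (length(unique(group_size)) < 3L)
    stop("need at least 3 distinct group sizes", call. = FALSE)
  if (stats::sd(group_size) == 0 || stats::sd(value) == 0) {
    warning("zero variance: Pearson r undefined", call. = FALSE)
    return(list(r = NA_real_, slope = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(group_size, value, method = "pearson")
  slope <- unname(stats::coef(stats::lm(value ~ group_size))[2])
  list(r = unname(ct$estimate), slope = slope, p = ct$p.value)
}

#' Odor-pulse onset and peak metrics
#'
#' Onset is the first crossing of 10% of the maximal concentration after
#' time zero (final-valve opening), linearly interpolated between samples;
#' the peak is the time and amplitude of the maximum.
#'
#' @param trace A `pulse_trace` (see [synth_odor_trace()]) or a list with
#'   `time_ms` and `concentration`.
#' @return List with `onset_ms`, `peak_ms`, `peak_amplitude`; all `NA` when
#'   the trace maximum is not positive.
#' @export
pulse_metrics <- function(trace) {
  t <- trace$time_ms
  y <- trace$concentration
  if (length(y) < 2L) stop("trace needs at least 2 samples", call. = FALSE)
  peak_i <- which.max(y)
  peak <- y[peak_i]
  if (!is.finite(peak) || peak <= 0)
    return(list(onset_ms = NA_real_, peak_ms = NA_real_,
                peak_amplitude = NA_real_))
  thr <- 0.1 * peak
  above <- which(y >= thr & t >= 0)
  if (length(above) == 0L)
    return(list(onset_ms = NA_real_, peak_ms = t[peak_i], peak_amplitude = peak))
  i <- above[1]
  onset <- if (i == 1L || y[i - 1L] >= thr) t[i] else {
    t[i - 1L] + (thr - y[i - 1L]) / (y[i] - y[i - 1L]) * (t[i] - t[i - 1L])
  }
  list(onset_ms = onset, peak_ms = t[peak_i], peak_amplitude = peak)
}
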