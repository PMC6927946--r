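# Constrained pseudo-random S+/S- sequencing.
#
# Blocks of trials are generated so that every fixed-size bin carries an
# exact balance of rewarded (S+) and unrewarded (S-) labels and no run of
# identical labels exceeds a maximum length, evaluated across bin boundaries
# within the block.

#' Trial label constants
#'
#' The two stimulus classes of a go/no-go task: `"S+"` is the rewarded
#' stimulus, `"S-"` the unrewarded one.
#'
#' @format Character scalars.
#' @export
S_PLUS <- "S+"

#' @rdname S_PLUS
#' @export
S_MINUS <- "S-"

#' Sequence generation parameters
#'
#' Parameters of the constrained pseudo-random trial sequence: blocks of
#' `block_length` trials, split into consecutive bins of `bin_size` trials
#' each containing exactly `per_bin_splus` rewarded labels, with no run of
#' identical labels longer than `max_run` anywhere in the block.
#'
#' @param block_length Total trials per block (default 1000).
#' @param bin_size Bin width for the balance constraint (default 100).
#' @param per_bin_splus Exact number of S+ labels per bin (default 50).
#' @param max_run Maximum allowed run of identical labels (default 3).
#' @param seed Integer seed making generation reproducible.
#' @return An object of class `sequence_params`.
#' @export
sequence_params <- function(block_length = 1000, bin_size = 100,
                            per_bin_splus = 50, max_run = 3, seed = 1L) {
  p <- list(block_length = as.integer(block_length),
            bin_size = as.integer(bin_size),
            per_bin_splus = as.integer(per_bin_splus),
            max_run = as.integer(max_run),
            seed = as.integer(seed))
  class(p) <- "sequence_params"
  validate_sequence_params(p)
  p
}

validate_sequence_params <- function(p) {
  if (p$block_length < 1L || p$bin_size < 1L)
    stop("sequence configuration error: block_length and bin_size must be positive",
         call. = FALSE)
  if (p$block_length %% p$bin_size != 0L)
    stop("sequence configuration error: block_length (", p$block_length,
         ") is not divisible by bin_size (", p$bin_size, ")", call. = FALSE)
  if (p$per_bin_splus < 0L || p$per_bin_splus > p$bin_size)
    stop("sequence configuration error: per_bin_splus (", p$per_bin_splus,
         ") must lie in [0, bin_size]", call. = FALSE)
  if (p$max_run < 1L)
    stop("sequence configuration error: max_run must be >= 1", call. = FALSE)
  n_plus <- p$per_bin_splus
  n_minus <- p$bin_size - p$per_bin_splus
  # Degenerate all-one-class bins chain runs across every bin of the block.
  if ((n_plus == 0L || n_minus == 0L) && p$block_length > p$max_run)
    stop("sequence configuration error: single-class bins force a run of ",
         p$block_length, " > max_run", call. = FALSE)
  # Two-symbol arrangement with run cap k exists iff each class fits into the
  # gaps left by the other: a <= k * (b + 1).
  if (n_plus > p$max_run * (n_minus + 1L) || n_minus > p$max_run * (n_plus + 1L))
    stop("sequence configuration error: max_run (", p$max_run,
         ") too small for bin balance ", n_plus, " S+ / ", n_minus,
         " S- per bin", call. = FALSE)
  invisible(p)
}

# Evaluate code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards; makes generation a pure function of its inputs.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Can `a` items of the label currently running (run length `run`) and `b` of
# the other label still be arranged with no run exceeding `k`?
runs_completable <- function(a, b, run, k) {
  a <= (k - run) + k * b && b <= k * (a + 1)
}

#' Generate one constrained trial block
#'
#' Draws a pseudo-random sequence of S+/S- labels satisfying the exact
#' per-bin balance and the maximum-run constraint (runs are checked across
#' bin boundaries). Generation is a randomized sequential construction with
#' one-step feasibility look-ahead; positions where both labels are
#' admissible are decided by a fair coin weighted by remaining counts.
#' Identical parameters (including seed) always yield the identical block.
#'
#' @param params A [sequence_params()] object.
#' @param block_id Integer identifier stored on the block (default 1).
#' @param max_attempts Attempts at a bin before giving up (default 10000).
#' @return An object of class `sequence_block`: list with `labels`
#'   (character vector of `"S+"`/`"S-"`), `params`, `block_id`.
#' @examples
#' b <- generate_block(sequence_params(seed = 1))
#' table(b$labels)
#' max(rle(b$labels)$lengths)
#' @export
generate_block <- function(params, block_id = 1L, max_attempts = 10000L) {
  validate_sequence_params(params)
  n_bins <- params$block_length %/% params$bin_size
  k <- params$max_run
  labels <- character(params$block_length)
  with_local_seed(params$seed + (as.integer(block_id) - 1L), {
    pos <- 0L
    run_label <- ""
    run_len <- 0L
    for (bin in seq_len(n_bins)) {
      done <- FALSE
      for (attempt in seq_len(max_attempts)) {
        res <- draw_bin(params$per_bin_splus, params$bin_size - params$per_bin_splus,
                        run_label, run_len, k)
        if (!is.null(res)) {
          labels[pos + seq_len(params$bin_size)] <- res$labels
          run_label <- res$run_label
          run_len <- res$run_len
          pos <- pos + params$bin_size
          done <- TRUE
          break
        }
      }
      if (!done)
        stop("sequence configuration error: could not complete bin ", bin,
             " within ", max_attempts, " attempts under the run constraint",
             call. = FALSE)
    }
  })
  structure(list(labels = labels, params = params,
                 block_id = as.integer(block_id)),
            class = "sequence_block")
}

# One bin via randomized sequential construction. Returns NULL when boxed in
# (possible only through the entry run carried over from the previous bin).
draw_bin <- function(n_plus, n_minus, run_label, run_len, k) {
  out <- character(n_plus + n_minus)
  rem <- c("S+" = n_plus, "S-" = n_minus)
  for (i in seq_along(out)) {
    cand <- character(0)
    for (lab in c(S_PLUS, S_MINUS)) {
      if (rem[[lab]] == 0L) next
      new_run <- if (identical(lab, run_label)) run_len + 1L else 1L
      if (new_run > k) next
      other <- if (identical(lab, S_PLUS)) S_MINUS else S_PLUS
      if (runs_completable(rem[[lab]] - 1L, rem[[other]], new_run, k)) cand <- c(cand, lab)
    }
    if (length(cand) == 0L) return(NULL)
    lab <- if (length(cand) == 1L) cand else {
      sample(cand, 1L, prob = c(rem[[cand[1]]], rem[[cand[2]]]))
    }
    out[i] <- lab
    run_len <- if (identical(lab, run_label)) run_len + 1L else 1L
    run_label <- lab
    rem[[lab]] <- rem[[lab]] - 1L
  }
  list(labels = out, run_label = run_label, run_len = run_len)
}

#' Check a label vector against block constraints
#'
#' @param labels Character vector of `"S+"`/`"S-"` labels.
#' @param params A [sequence_params()] object.
#' @return `TRUE` invisibly if valid; otherwise a character vector of
#'   violation messages (with `valid = FALSE` attribute semantics: use
#'   [validate_block_labels()] return length to test).
#' @export
validate_block_labels <- function(labels, params) {
  problems <- character(0)
  if (length(labels) != params$block_length)
    problems <- c(problems, sprintf("length %d != block_length %d",
                                    length(labels), params$block_length))
  bad <- setdiff(unique(labels), c(S_PLUS, S_MINUS))
  if (length(bad))
    problems <- c(problems, paste("unknown labels:", paste(bad, collapse = ", ")))
  if (length(problems) == 0L) {
    n_bins <- params$block_length %/% params$bin_size
    for (b in seq_len(n_bins)) {
      bin <- labels[((b - 1L) * params$bin_size + 1L):(b * params$bin_size)]
      n_sp <- sum(bin == S_PLUS)
      if (n_sp != params$per_bin_splus)
        problems <- c(problems, sprintf("bin %d has %d S+ (expected %d)",
                                        b, n_sp, params$per_bin_splus))
    }
    runs <- rle(labels)
    if (max(runs$lengths) > params$max_run)
      problems <- c(problems, sprintf("run of %d identical labels exceeds max_run %d",
                                      max(runs$lengths), params$max_run))
  }
  if (length(problems) == 0L) invisible(TRUE) else problems
}

#' Create a trial scheduler serving per-animal label streams
#'
#' Each registered animal consumes its own independently generated blocks;
#' a fresh block (new `block_id`) is generated only when the current one is
#' fully consumed, so no label repeats before a full block has been served.
#'
#' @param params A [sequence_params()] object (the `seed` seeds the
#'   scheduler's generator; per-animal/per-block streams are derived
#'   deterministically from it).
#' @param animal_ids Character vector of animal identifiers to register.
#' @return An object of class `trial_scheduler`.
#' @export
trial_scheduler <- function(params, animal_ids) {
  animal_ids <- as.character(animal_ids)
  if (anyDuplicated(animal_ids))
    stop("duplicate animal_id in scheduler registration", call. = FALSE)
  cursors <- stats::setNames(vector("list", length(animal_ids)), animal_ids)
  for (i in seq_along(animal_ids)) {
    cursors[[i]] <- list(block = NULL, index = 0L, blocks_served = 0L,
                         animal_index = i)
  }
  structure(list(params = params, cursors = cursors),
            class = "trial_scheduler")
}

# Deterministic sub-stream seed per animal and block; kept below 2^31.
derive_seed <- function(base_seed, animal_index, block_counter) {
  as.integer((as.numeric(base_seed) * 7919 + animal_index * 104729 +
                block_counter * 1299709) %% 2147483647)
}

#' Draw the next trial label for an animal
#'
#' Serves labels strictly in block order for that animal; generates and
#' switches to a new block when the current one is exhausted.
#'
#' @param scheduler A [trial_scheduler()] object.
#' @param animal_id Registered animal identifier.
#' @return List with `label` (`"S+"`/`"S-"`), `block_id`, `index`
#'   (1-based position within the block) and `scheduler` (updated state).
#' @export
scheduler_draw <- function(scheduler, animal_id) {
  animal_id <- as.character(animal_id)
  cur <- scheduler$cursors[[animal_id]]
  if (is.null(cur))
    stop("unknown animal_id: ", animal_id, call. = FALSE)
  if (is.null(cur$block) || cur$index >= scheduler$params$block_length) {
    cur$blocks_served <- cur$blocks_served + 1L
    p <- scheduler$params
    p$seed <- derive_seed(scheduler$params$seed, cur$animal_index,
                          cur$blocks_served)
    cur$block <- generate_block(p, block_id = cur$blocks_served)
    cur$index <- 0L
  }
  cur$index <- cur$index + 1L
  scheduler$cursors[[animal_id]] <- cur
  list(label = cur$block$labels[cur$index],
       block_id = cur$block$block_id,
       index = cur$index,
       scheduler = scheduler)
}

#' Counterbalance odor-reward assignment within treatment groups
#'
#' Assigns each animal one of two odors as the rewarded (S+) stimulus such
#' that within every treatment group the two odors are used as S+ by equally
#' many animals (difference at most 1 for odd group sizes; which odor gets
#' the extra animal is seed-determined).
#'
#' @param cohort Data frame with columns `animal_id` and `group` (treatment
#'   group label), or a character vector of animal ids (single group).
#' @param odor_pair Character vector of two distinct odor identifiers.
#' @param seed Integer seed.
#' @return Data frame with columns `animal_id`, `group`, `splus_odor`,
#'   `sminus_odor`.
#' @export
assign_counterbalance <- function(cohort, odor_pair, seed = 1L) {
  if (is.character(cohort))
    cohort <- data.frame(animal_id = cohort, group = "all",
                         stringsAsFactors = FALSE)
  stopifnot(is.data.frame(cohort), all(c("animal_id", "group") %in% names(cohort)))
  if (nrow(cohort) == 0L)
    stop("cohort must be non-empty", call. = FALSE)
  if (anyDuplicated(cohort$animal_id))
    stop("duplicate animal_id in cohort", call. = FALSE)
  if (length(odor_pair) != 2L || odor_pair[1] == odor_pair[2])
    stop("odor_pair must name two distinct odors", call. = FALSE)
  out <- with_local_seed(seed, {
    pieces <- lapply(split(cohort, cohort$group), function(g) {
      n <- nrow(g)
      ord <- sample.int(n)
      half <- n %/% 2L
      n_first <- half + (if (n %% 2L == 1L) sample(0:1, 1L) else 0L)
      splus <- character(n)
      splus[ord] <- c(rep(odor_pair[1], n_first), rep(odor_pair[2], n - n_first))
      data.frame(animal_id = g$animal_id, group = g$group,
                 splus_odor = splus,
                 sminus_odor = ifelse(splus == odor_pair[1],
                                      odor_pair[2], odor_pair[1]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, pieces)
  })
  rownames(out) <- NULL
  out
}
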