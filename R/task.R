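#' Task design for the occluded-motion temporal prediction paradigm
#'
#' Describes the timing skeleton of the task: a stimulus moves for a variable
#' interval (1000--1500 ms), disappears behind an occluder, and reappears after
#' the nominal 1500 ms interval shifted by a signed offset \eqn{\Delta t}
#' (\eqn{\pm}34 to \eqn{\pm}934 ms in 100 ms steps); the reappeared stimulus is
#' shown for 500 ms. Epochs are padded by 1240 ms on both sides.
#'
#' @param base_interval_ms nominal occlusion interval (ms).
#' @param movement_min_ms,movement_max_ms bounds of the visible-movement
#'   interval (ms).
#' @param delta_levels_ms signed reappearance offsets (ms); must be symmetric
#'   about zero.
#' @param reappearance_ms duration of the reappearance display (ms).
#' @param fixation_ms inter-trial fixation (ms).
#' @param epoch_pad_ms epoch padding before movement onset and after stimulus
#'   offset (ms).
#' @param trials_per_block,blocks_per_session block structure.
#' @param sampling_rate_hz EEG sampling rate (Hz).
#' @return an object of class `task_design`.
#' @export
task_design <- function(base_interval_ms = 1500,
                        movement_min_ms = 1000, movement_max_ms = 1500,
                        delta_levels_ms = c(seq(-934, -34, by = 100),
                                            seq(34, 934, by = 100)),
                        reappearance_ms = 500,
                        fixation_ms = 1500,
                        epoch_pad_ms = 1240,
                        trials_per_block = 60,
                        blocks_per_session = 8,
                        sampling_rate_hz = 1000) {
  delta_levels_ms <- sort(delta_levels_ms)
  if (!isTRUE(all.equal(sort(-delta_levels_ms), delta_levels_ms)))
    stopf("delta_levels_ms must be symmetric about 0")
  if (movement_min_ms > movement_max_ms) stopf("movement_min_ms > movement_max_ms")
  if (any(c(base_interval_ms, reappearance_ms, fixation_ms,
            epoch_pad_ms, sampling_rate_hz) <= 0))
    stopf("all durations and the sampling rate must be positive")
  structure(list(base_interval_ms = base_interval_ms,
                 movement_min_ms = movement_min_ms,
                 movement_max_ms = movement_max_ms,
                 delta_levels_ms = delta_levels_ms,
                 reappearance_ms = reappearance_ms,
                 fixation_ms = fixation_ms,
                 epoch_pad_ms = epoch_pad_ms,
                 trials_per_block = trials_per_block,
                 blocks_per_session = blocks_per_session,
                 sampling_rate_hz = sampling_rate_hz),
            class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat("Temporal prediction task design\n")
  cat(sprintf("  movement %g-%g ms, occlusion %g ms +/- delta, reappearance %g ms\n",
              x$movement_min_ms, x$movement_max_ms, x$base_interval_ms,
              x$reappearance_ms))
  cat(sprintf("  %d delta levels: %g..%g ms; %d x %d trials; fs %g Hz\n",
              length(x$delta_levels_ms), min(x$delta_levels_ms),
              max(x$delta_levels_ms), x$blocks_per_session,
              x$trials_per_block, x$sampling_rate_hz))
  invisible(x)
}

#' Session trial count implied by a design
#' @param design a [task_design()].
#' @return integer trial count (blocks x trials per block).
#' @export
session_trials <- function(design) design$trials_per_block * design$blocks_per_session

#' Closed-form range of epoch durations under a design
#'
#' An epoch runs from `epoch_pad_ms` before movement onset to `epoch_pad_ms`
#' after stimulus offset, so its span is
#' `2*pad + movement + (base_interval + delta) + reappearance`.
#'
#' @param design a [task_design()].
#' @return numeric length-2 vector `c(min, max)` in ms.
#' @export
epoch_span_range <- function(design) {
  fixed <- 2 * design$epoch_pad_ms + design$base_interval_ms + design$reappearance_ms
  c(fixed + design$movement_min_ms + min(design$delta_levels_ms),
    fixed + design$movement_max_ms + max(design$delta_levels_ms))
}

#' Build a balanced, randomized trial schedule
#'
#' Each \eqn{\Delta t} level occurs `floor(n/L)` or `ceiling(n/L)` times
#' (`L` = number of levels); movement intervals are drawn uniformly from the
#' design's bounds (rounded to the 1 ms sampling grid); trial order is permuted
#' by the seed and absolute event times are laid out with the design's fixation
#' interval between trials.
#'
#' @param design a [task_design()].
#' @param n_trials number of trials (default: one full session).
#' @param seed integer seed.
#' @return a `data.frame` of class `tp_schedule` with columns `trial_id`,
#'   `movement_ms`, `delta_ms` and event times `t_move_on`, `t_disappear`,
#'   `t_reappear`, `t_offset` (ms from recording start).
#' @export
build_schedule <- function(design = task_design(),
                           n_trials = session_trials(design), seed = 1L) {
  if (n_trials <= 0) stopf("n_trials must be positive")
  lev <- design$delta_levels_ms
  L <- length(lev)
  if (n_trials %% L != 0)
    warnf("n_trials (%d) not divisible by %d levels; filling round-robin", n_trials, L)
  deltas <- rep_len(rep(lev, ceiling(n_trials / L)), n_trials)
  with_seed(seed, {
    deltas <- sample(deltas)
    movement <- round(runif(n_trials, design$movement_min_ms, design$movement_max_ms))
  })
  fix <- design$fixation_ms
  occl <- design$base_interval_ms + deltas
  span <- movement + occl + design$reappearance_ms
  t_move_on <- fix + cumsum(c(0, head(span + fix, -1)))
  t_disappear <- t_move_on + movement
  t_reappear <- t_disappear + occl
  t_offset <- t_reappear + design$reappearance_ms
  out <- data.frame(trial_id = seq_len(n_trials), movement_ms = movement,
                    delta_ms = deltas, t_move_on = t_move_on,
                    t_disappear = t_disappear, t_reappear = t_reappear,
                    t_offset = t_offset)
  attr(out, "design") <- design
  class(out) <- c("tp_schedule", "data.frame")
  out
}
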