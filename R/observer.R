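#' Logistic observer parameters
#'
#' Behavioral ground truth for a simulated participant. The observer responds
#' "too late" with probability
#' \deqn{P(late | \Delta t) = \lambda/2 + (1-\lambda)\,
#'   \mathrm{logit}^{-1}\{\beta_1 (\Delta t - \mathrm{PSE})\}}
#' with \eqn{\beta_1 = 2\ln(3)\cdot s}, so that the conventional steepness
#' measure --- the reciprocal of the \eqn{\Delta t} span between the 25% and
#' 75% response points --- recovers `steepness` exactly.
#'
#' @param pse_ms point of subjective equality (ms); positive = "too late" bias.
#' @param steepness psychometric steepness (1/ms) on the 75-25 reciprocal scale.
#' @param lapse lapse rate in `[0, 0.5)`.
#' @param rt_mean_ms,rt_sd_ms reaction-time distribution (truncated normal).
#' @return an object of class `observer_params`.
#' @export
observer_params <- function(pse_ms = 0, steepness = 0.004, lapse = 0,
                            rt_mean_ms = 550, rt_sd_ms = 120) {
  if (steepness <= 0) stopf("steepness must be > 0")
  if (lapse < 0 || lapse >= 0.5) stopf("lapse must lie in [0, 0.5)")
  structure(list(pse_ms = pse_ms, steepness = steepness, lapse = lapse,
                 rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms),
            class = "observer_params")
}

#' Probability of a "too late" response under an observer
#' @param observer an [observer_params()].
#' @param delta_ms signed reappearance offsets (ms).
#' @return numeric vector of P(late).
#' @export
p_late <- function(observer, delta_ms) {
  b1 <- 2 * log(3) * observer$steepness
  observer$lapse / 2 +
    (1 - observer$lapse) * plogis(b1 * (delta_ms - observer$pse_ms))
}

#' Simulate behavioral responses for a schedule
#'
#' @param schedule a [build_schedule()] result.
#' @param observer an [observer_params()].
#' @param seed integer seed.
#' @return behavioral `data.frame` with `trial_id`, `delta_ms`,
#'   `response` ("early"/"late") and `rt_ms`.
#' @export
simulate_responses <- function(schedule, observer = observer_params(), seed = 1L) {
  p <- p_late(observer, schedule$delta_ms)
  with_seed(seed, {
    late <- rbinom(nrow(schedule), 1L, p)
    rt <- rtruncnorm_pos(nrow(schedule), observer$rt_mean_ms, observer$rt_sd_ms)
  })
  data.frame(trial_id = schedule$trial_id, delta_ms = schedule$delta_ms,
             response = ifelse(late == 1L, "late", "early"), rt_ms = rt)
}

#' Write / read a behavioral table as TSV
#' @param table behavioral `data.frame`.
#' @param path file path.
#' @return `read_behavior` returns the table.
#' @export
write_behavior <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
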