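#' Group-level t statistics with effect sizes
#'
#' Standard t tests on per-participant metrics: paired, independent-samples,
#' or one-sample against zero. Cohen's d uses the mean difference over the SD
#' of differences (paired/one-sample) or the pooled SD (independent). For the
#' independent design both the Welch test (default reporting) and the
#' pooled-variance test are returned, since their dfs differ. A
#' comparison-wise alpha of 0.05/3 is reported alongside the raw p for the
#' study's three primary contrasts.
#'
#' @param x numeric vector (group 1 / condition 1 / the only sample).
#' @param y numeric vector (group 2 / condition 2), or `NULL`.
#' @param design `"paired"`, `"independent"` or `"one_sample"`.
#' @param alpha_adjusted comparison-wise alpha (default `0.05/3`).
#' @return list with `t`, `df`, `p`, `cohens_d`, `alpha_adjusted`,
#'   `significant`, `flagged` (zero variance), and for the independent design
#'   also `t_pooled`, `df_pooled`, `p_pooled`.
#' @export
group_stats <- function(x, y = NULL,
                        design = c("paired", "independent", "one_sample"),
                        alpha_adjusted = 0.05 / 3) {
  design <- match.arg(design)
  if (design != "one_sample" && is.null(y)) stopf("design '%s' needs y", design)
  if (design %in% c("paired", "one_sample")) {
    d <- if (design == "paired") x - y else x
    if (length(d) < 2) stopf("need n >= 2")
    if (sd(d) == 0) {
      return(list(t = NA_real_, df = length(d) - 1, p = NA_real_,
                  cohens_d = NA_real_, alpha_adjusted = alpha_adjusted,
                  significant = NA, flagged = TRUE))
    }
    tt <- t.test(d)
    cd <- mean(d) / sd(d)
    return(list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, cohens_d = cd,
                alpha_adjusted = alpha_adjusted,
                significant = tt$p.value < alpha_adjusted, flagged = FALSE))
  }
  if (length(x) < 2 || length(y) < 2) stopf("need n >= 2 per group")
  if (sd(x) == 0 && sd(y) == 0) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                cohens_d = NA_real_, alpha_adjusted = alpha_adjusted,
                significant = NA, flagged = TRUE))
  }
  welch <- t.test(x, y)
  pooled <- t.test(x, y, var.equal = TRUE)
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
             (length(x) + length(y) - 2))
  cd <- (mean(x) - mean(y)) / sp
  list(t = unname(welch$statistic), df = unname(welch$parameter),
       p = welch$p.value,
       t_pooled = unname(pooled$statistic),
       df_pooled = unname(pooled$parameter), p_pooled = pooled$p.value,
       cohens_d = cd, alpha_adjusted = alpha_adjusted,
       significant = welch$p.value < alpha_adjusted, flagged = FALSE)
}
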