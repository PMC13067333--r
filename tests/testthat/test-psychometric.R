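make_table <- function(deltas, p, n_per = 24, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(deltas), function(i) {
    late <- rbinom(n_per, 1, p[i])
    data.frame(trial_id = seq_len(n_per), delta_ms = deltas[i],
               response = ifelse(late == 1, "late", "early"),
               rt_ms = 500)
  }))
}

test_that("proportions aggregates per level, sorted", {
  tab <- data.frame(delta_ms = c(934, 934, -934, 34),
                    response = c("late", "late", "early", "late"))
  p <- proportions(tab)
  expect_equal(p$delta_ms, c(-934, 34, 934))
  expect_equal(p$p_late, c(0, 1, 1))
  expect_equal(p$n, c(1, 1, 2))
  # alternating early/late at one level
  tab2 <- data.frame(delta_ms = 0, response = rep(c("early", "late"), 12))
  expect_equal(proportions(tab2)$p_late, 0.5)
  expect_error(proportions(tab[0, ]), "empty")
  # full design has 20 rows
  s <- build_schedule(task_design(), 480, 4)
  expect_equal(nrow(proportions(simulate_responses(s, observer_params(), 1))),
               20)
})

test_that("symmetric data give PSE 0 and the closed-form steepness identity holds", {
  deltas <- c(seq(-934, -34, 100), seq(34, 934, 100))
  half <- round(24 * plogis(0.01 * deltas[11:20]))
  lev <- data.frame(delta_ms = deltas, n = 24,
                    n_late = c(24 - rev(half), half)) # exactly mirrored counts
  fit <- fit_psychometric(lev)
  expect_lt(abs(fit$pse_ms), 1e-6)
  expect_equal(fit$steepness, fit$b1 / (2 * log(3)))

  # numeric inversion: steepness == 1/(dt@0.75 - dt@0.25) from the curve
  f75 <- uniroot(function(x) predict(fit, x) - 0.75, c(-3000, 3000),
                 tol = 1e-13)$root
  f25 <- uniroot(function(x) predict(fit, x) - 0.25, c(-3000, 3000),
                 tol = 1e-13)$root
  expect_equal(fit$steepness, 1 / (f75 - f25), tolerance = 1e-9)
  # predicted probability at the PSE is exactly one half
  expect_equal(predict(fit, fit$pse_ms), 0.5, tolerance = 1e-9)
})

test_that("PSE and steepness transform exactly under unit rescaling", {
  s <- build_schedule(task_design(), 480, 6)
  tab <- simulate_responses(s, observer_params(30, 0.003), 2)
  f_ms <- fit_psychometric(tab)
  tab_s <- tab
  tab_s$delta_ms <- tab$delta_ms / 1000 # express offsets in seconds
  f_s <- fit_psychometric(tab_s)
  expect_equal(f_s$b1, f_ms$b1 * 1000, tolerance = 1e-6)
  expect_equal(f_s$steepness, f_ms$steepness * 1000, tolerance = 1e-6)
  expect_equal(f_s$pse_ms, f_ms$pse_ms / 1000, tolerance = 1e-6)
  # fitted curve is monotone increasing when b1 > 0
  expect_true(all(diff(predict(f_ms, seq(-900, 900, 50))) > 0))
})

test_that("complete separation falls back to a flagged penalized fit", {
  lev <- data.frame(delta_ms = c(seq(-934, -34, 100), seq(34, 934, 100)),
                    n = 24, n_late = c(rep(0, 10), rep(24, 10)))
  expect_warning(fit <- fit_psychometric(lev), "Firth|penalized|separation")
  expect_false(fit$converged)
  expect_true(is.finite(fit$steepness) && fit$steepness > 0)
  expect_true(is.finite(fit$se_b1))
  expect_error(fit_psychometric(
    data.frame(delta_ms = 1:3, n = 5, n_late = 0)), "both response")
})

test_that("psychfit behaves like a standard fitted-model object", {
  s <- build_schedule(task_design(), 480, 8)
  fit <- fit_psychometric(simulate_responses(s, observer_params(20, 0.004), 3))
  expect_named(coef(fit), c("b0", "b1"))
  expect_equal(unname(coef(fit)[1]), fit$b0)
  expect_length(residuals(fit), 20)
  expect_length(fitted(fit), 20)
  sim <- simulate(fit, seed = 1)
  expect_equal(sim$n, fit$levels$n)
  out <- capture.output({print(fit); print(summary(fit))})
  expect_true(any(grepl("PSE", out)))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("subjectively correct classification follows the PSE rule", {
  fit0 <- list(pse_ms = 0)
  tab <- data.frame(delta_ms = c(534, -534, 134, -134),
                    response = c("late", "early", "early", "late"))
  expect_equal(subjectively_correct(tab, fit0), c(TRUE, TRUE, FALSE, FALSE))
  # a positive PSE moves the subjective boundary: +134 & early is correct
  fit200 <- list(pse_ms = 200)
  expect_true(subjectively_correct(
    data.frame(delta_ms = 134, response = "early"), fit200))
  # tie rule: exactly at the PSE counts as correct
  expect_true(subjectively_correct(
    data.frame(delta_ms = 200, response = "early"), fit200))
  # an ideal observer is 100% subjectively correct
  s <- build_schedule(task_design(), 480, 9)
  resp <- data.frame(trial_id = s$trial_id, delta_ms = s$delta_ms,
                     response = ifelse(s$delta_ms > 0, "late", "early"),
                     rt_ms = 400)
  fit <- suppressWarnings(fit_psychometric(resp))
  expect_true(all(subjectively_correct(resp, fit)))
})

test_that("rt_summary aggregates with flagged degenerate cells", {
  tab <- data.frame(delta_ms = c(34, 34, 134), rt_ms = c(400, 500, 600))
  rs <- rt_summary(tab)
  expect_equal(rs$mean_rt, c(450, 600))
  expect_equal(rs$sem_rt[1], sd(c(400, 500)) / sqrt(2))
  expect_true(is.na(rs$sem_rt[2]))
  tab2 <- data.frame(delta_ms = rep(34, 5), rt_ms = rep(300, 5))
  expect_equal(rt_summary(tab2)$sem_rt, 0)
  expect_error(rt_summary(data.frame(delta_ms = 1, rt_ms = -1)), "positive")
})
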