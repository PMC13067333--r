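#' Per-level proportions of "too late" responses
#'
#' @param table behavioral `data.frame` with `delta_ms` and `response`
#'   (`"early"`/`"late"`).
#' @return `data.frame` with `delta_ms`, `n`, `n_late`, `p_late`, sorted by
#'   ascending `delta_ms`.
#' @export
proportions <- function(table) {
  if (!nrow(table)) stopf("empty behavioral table")
  if (!all(table$response %in% c("early", "late")))
    stopf("responses must be coded 'early'/'late'")
  late <- as.integer(table$response == "late")
  agg <- aggregate(cbind(n = rep(1L, nrow(table)), n_late = late),
                   by = list(delta_ms = table$delta_ms), FUN = sum)
  agg <- agg[order(agg$delta_ms), ]
  agg$p_late <- agg$n_late / agg$n
  rownames(agg) <- NULL
  agg
}

# Firth-type (Jeffreys-prior) penalized logistic fit for separated data.
.firth_logistic <- function(X, y, n, maxit = 200, tol = 1e-10) {
  b <- c(qlogis(pmin(pmax(sum(y) / sum(n), 1e-3), 1 - 1e-3)), 0)
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% b)
    p <- plogis(eta)
    w <- n * p * (1 - p)
    XtWX <- crossprod(X, w * X)
    XtWXi <- solve(XtWX)
    # hat values of the weighted design
    h <- rowSums((X %*% XtWXi) * X) * w
    U <- crossprod(X, y - n * p + h * (0.5 - p))
    step <- XtWXi %*% U
    b <- b + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  pf <- plogis(as.vector(X %*% b))
  list(coef = b, vcov = solve(crossprod(X, (n * pf * (1 - pf)) * X)),
       iter = it)
}

#' Fit a psychometric function to temporal judgments
#'
#' Maximum-likelihood binomial logistic regression of P("too late") on the
#' timing offset \eqn{\Delta t} (fitted by iteratively reweighted least
#' squares via [stats::glm()]). The point of subjective equality is the offset
#' at 50\% "too late" responses, \eqn{PSE = -b_0/b_1}, and the steepness is
#' the reciprocal of the offset span between the 25\% and 75\% response
#' points, which for the logistic equals \eqn{b_1 / (2\ln 3)}. Complete
#' separation (ideal observers) is caught and refitted with a Firth-type
#' penalty; such fits are flagged `converged = FALSE`.
#'
#' @param x a behavioral table (`delta_ms`, `response`) or a per-level table
#'   from [proportions()].
#' @return an object of class `psychfit` with coefficients `b0`, `b1`,
#'   derived `pse_ms` and `steepness`, standard errors, the per-level table,
#'   and a `converged` flag.
#' @export
fit_psychometric <- function(x) {
  lev <- if (all(c("n", "n_late") %in% names(x))) x else proportions(x)
  if (sum(lev$n_late) == 0 || sum(lev$n_late) == sum(lev$n))
    stopf("both response categories must be present")
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(cbind(n_late, n - n_late) ~ delta_ms, family = binomial(), data = lev),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  if (sep || !fit$converged ||
      any(!is.finite(sqrt(diag(vcov(fit)))))) {
    warnf("separation or non-convergence detected; using Firth-type penalized fit")
    X <- cbind(1, lev$delta_ms)
    ff <- .firth_logistic(X, lev$n_late, lev$n)
    cf <- ff$coef
    V <- ff$vcov
    converged <- FALSE
  } else {
    V <- vcov(fit)
    converged <- TRUE
  }
  b0 <- unname(cf[1]); b1 <- unname(cf[2])
  structure(list(b0 = b0, b1 = b1,
                 pse_ms = -b0 / b1,
                 steepness = b1 / (2 * log(3)),
                 se_b0 = sqrt(V[1, 1]), se_b1 = sqrt(V[2, 2]),
                 vcov = V, levels = lev, converged = converged,
                 n_trials = sum(lev$n)),
            class = "psychfit")
}

#' @export
print.psychfit <- function(x, ...) {
  cat("Psychometric fit (binomial logistic)\n")
  cat(sprintf("  PSE = %.1f ms, steepness = %.5f /ms%s\n", x$pse_ms,
              x$steepness, if (x$converged) "" else "  [penalized fit]"))
  cat(sprintf("  b0 = %.4f (SE %.4f), b1 = %.6f (SE %.6f), n = %d\n",
              x$b0, x$se_b0, x$b1, x$se_b1, x$n_trials))
  invisible(x)
}

#' @export
summary.psychfit <- function(object, ...) {
  z0 <- object$b0 / object$se_b0
  z1 <- object$b1 / object$se_b1
  tab <- data.frame(estimate = c(object$b0, object$b1),
                    se = c(object$se_b0, object$se_b1),
                    z = c(z0, z1),
                    p = 2 * pnorm(-abs(c(z0, z1))),
                    row.names = c("(Intercept)", "delta_ms"))
  out <- list(coefficients = tab, pse_ms = object$pse_ms,
              steepness = object$steepness, converged = object$converged,
              levels = object$levels)
  class(out) <- "summary.psychfit"
  out
}

#' @export
print.summary.psychfit <- function(x, ...) {
  cat("Psychometric fit summary\n")
  print(round(x$coefficients, 6))
  cat(sprintf("PSE %.2f ms; steepness %.6f /ms; converged: %s\n",
              x$pse_ms, x$steepness, x$converged))
  invisible(x)
}

#' @export
coef.psychfit <- function(object, ...)
  c(b0 = object$b0, b1 = object$b1)

#' @export
predict.psychfit <- function(object, newdata = NULL,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  delta <- if (is.null(newdata)) object$levels$delta_ms
           else if (is.data.frame(newdata)) newdata$delta_ms else newdata
  eta <- object$b0 + object$b1 * delta
  if (type == "link") eta else plogis(eta)
}

#' @export
fitted.psychfit <- function(object, ...) predict(object)

#' @export
residuals.psychfit <- function(object, type = c("deviance", "pearson"), ...) {
  type <- match.arg(type)
  lev <- object$levels
  p <- predict(object)
  if (type == "pearson")
    return((lev$n_late - lev$n * p) / sqrt(lev$n * p * (1 - p)))
  s <- sign(lev$p_late - p)
  ll <- function(y, n, p) {
    t1 <- ifelse(y == 0, 0, y * log(y / (n * p)))
    t2 <- ifelse(y == n, 0, (n - y) * log((n - y) / (n * (1 - p))))
    t1 + t2
  }
  s * sqrt(2 * pmax(ll(lev$n_late, lev$n, p), 0))
}

#' @export
simulate.psychfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lev <- object$levels
  p <- predict(object)
  out <- lapply(seq_len(nsim), function(i) {
    y <- rbinom(nrow(lev), lev$n, p)
    data.frame(delta_ms = lev$delta_ms, n = lev$n, n_late = y,
               p_late = y / lev$n)
  })
  if (nsim == 1) out[[1]] else out
}

#' @export
plot.psychfit <- function(x, ...) {
  lev <- x$levels
  grid <- seq(min(lev$delta_ms), max(lev$delta_ms), length.out = 200)
  plot(lev$delta_ms, lev$p_late, pch = 19, xlab = "timing difference (ms)",
       ylab = "P(too late)", ylim = c(0, 1), ...)
  lines(grid, predict(x, grid), lwd = 2)
  graphics::abline(h = 0.5, lty = 3)
  graphics::abline(v = x$pse_ms, lty = 3)
  invisible(x)
}

#' Classify trials as subjectively correct
#'
#' A trial is subjectively correct when the response agrees with the side of
#' the offset relative to the individual PSE: `late` responses for
#' `delta_ms > PSE`, `early` responses for `delta_ms < PSE`. Offsets exactly
#' at the PSE count as correct (deterministic tie rule).
#'
#' @param table behavioral table.
#' @param fit a [fit_psychometric()] result.
#' @return logical vector, one element per trial.
#' @export
subjectively_correct <- function(table, fit) {
  d <- table$delta_ms - fit$pse_ms
  (d > 0 & table$response == "late") |
    (d < 0 & table$response == "early") |
    d == 0
}

#' Mean and SEM of reaction times per timing-difference level
#' @param table behavioral table with `rt_ms`.
#' @return `data.frame` with `delta_ms`, `n`, `mean_rt`, `sem_rt` (`NA` and
#'   flagged when a level has a single trial).
#' @export
rt_summary <- function(table) {
  if (any(table$rt_ms <= 0)) stopf("RTs must be positive")
  sp <- split(table$rt_ms, table$delta_ms)
  out <- data.frame(delta_ms = as.numeric(names(sp)),
                    n = lengths(sp),
                    mean_rt = vapply(sp, mean, 0),
                    sem_rt = vapply(sp, function(v)
                      if (length(v) < 2) NA_real_ else sd(v) / sqrt(length(v)), 0))
  out <- out[order(out$delta_ms), ]
  rownames(out) <- NULL
  out
}
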