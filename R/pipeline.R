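# Cohort-level orchestration: simulate -> filter -> epoch -> behavior ->
# spectral -> cluster statistics (-> source), fully deterministic given the
# config seed.

.fnv_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 216613626
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# collapse a binned map over a frequency band, keeping bins
.band_collapse <- function(map, band_hz) {
  fi <- which(map$freqs >= band_hz[1] & map$freqs <= band_hz[2])
  if (!length(fi)) stopf("empty band")
  out <- apply(map$values[, fi, , drop = FALSE], c(1, 3), mean)
  rownames(out) <- map$labels
  out
}

#' Assemble and validate a pipeline configuration
#'
#' Defaults describe a desk-scale cohort (reduced montage and sampling rate,
#' session shortened) with the study's group structure: patients recorded
#' with stimulation off and on (paired sessions) and an independent control
#' group. A YAML file with the same structure can be given instead of a list.
#'
#' @param config named list of overrides, or a path to a YAML file.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- list(
    seed = 1L,
    n_trials = 60,
    channels = 32,
    sampling_rate_hz = 250,
    filter = FALSE,
    groups = list(
      off = list(n = 6, paired_with = "on",
                 observer = list(pse_mean = 40, pse_sd = 30,
                                 steep_mean = 0.002, steep_sd = 4e-4),
                 truth = list(beta_suppression = -0.12, delta_kappa = 1.2,
                              kappa_sd = 0.5)),
      on = list(n = 6,
                observer = list(pse_mean = 10, pse_sd = 30,
                                steep_mean = 0.0035, steep_sd = 5e-4),
                truth = list(beta_suppression = -0.32, delta_kappa = 2,
                             kappa_sd = 0.8)),
      control = list(n = 8,
                     observer = list(pse_mean = 0, pse_sd = 25,
                                     steep_mean = 0.004, steep_sd = 5e-4),
                     truth = list(beta_suppression = -0.4, delta_kappa = 4,
                                  kappa_sd = 1))),
    spectral = list(n_wavelets = 16, f_min = 0.5, f_max = 40, decim_ms = 20),
    bands = list(beta = c(13, 30), delta = c(0.5, 4)),
    windows = list(beta_ms = c(-200, 600), delta_ms = c(-200, 900)),
    cluster = list(n_perm = 500, cluster_alpha = 0.05),
    source = list(enabled = FALSE, spacing_mm = 25, lambda_frac = 0.05),
    couple_itpc_behavior = NULL, # group name, or NULL
    out_dir = NULL)
  cfg <- utils::modifyList(base, config)
  d <- task_design(sampling_rate_hz = cfg$sampling_rate_hz)
  if (cfg$spectral$f_max > cfg$sampling_rate_hz / 2)
    stopf("spectral f_max above Nyquist")
  for (g in names(cfg$groups))
    if (cfg$groups[[g]]$n < 2) stopf("group '%s' needs n >= 2", g)
  cfg$design <- d
  class(cfg) <- "pipeline_config"
  cfg
}

# one simulated subject-session, through behavior and sensor-level maps
.run_subject <- function(cfg, group, subj, pars, head, layout, bank) {
  sseed <- substream_seed(cfg$seed, paste(group, subj, "session"))
  schedule <- build_schedule(cfg$design, cfg$n_trials,
                             substream_seed(sseed, "schedule"))
  truth <- do.call(oscillatory_truth, pars$truth)
  rec <- simulate_eeg(schedule, truth, layout, cfg$design, head,
                      seed = substream_seed(sseed, "noise"))
  if (isTRUE(cfg$filter)) rec <- filter_continuous(rec, filter_spec(
    lowpass_hz = min(95, cfg$sampling_rate_hz / 2 - 5)))
  epochs <- epoch_recording(rec, cfg$design)
  responses <- simulate_responses(schedule, pars$observer,
                                  substream_seed(sseed, "responses"))
  fit <- fit_psychometric(responses)
  correct <- subjectively_correct(responses, fit)
  keep <- correct[match(epochs$events$trial_id, responses$trial_id)]
  epochs <- subset_epochs(epochs, keep)
  tfr <- tfr_convolve(epochs, bank, cfg$spectral$decim_ms)
  base_map <- power_binned(tfr, "norm_baseline")
  dis_map <- baseline_normalize(power_binned(tfr, "disappearance"), base_map,
                                "relative")
  itpc_map <- itpc_binned(tfr, "disappearance")
  out <- list(
    group = group, subject = subj,
    pse_ms = fit$pse_ms, steepness = fit$steepness,
    truth_kappa = truth$delta_kappa,
    n_correct = sum(keep), n_epochs = length(keep),
    n_dropped = length(epochs$dropped %||% integer(0)),
    beta_bins = .band_collapse(dis_map, cfg$bands$beta),
    delta_itpc_bins = .band_collapse(itpc_map, cfg$bands$delta))
  if (isTRUE(cfg$source$enabled)) {
    grid <- build_grid(head, spacing_mm = cfg$source$spacing_mm)
    lf <- leadfield_sphere(grid, layout, head)
    cs <- csd_matrices(tfr, cfg$bands$delta, "disappearance")
    fl <- dics_filters(cs, lf, cfg$source$lambda_frac)
    out$source_itpc <- source_itpc(fl, tfr, cfg$bands$delta, "disappearance")
    out$grid <- grid
  }
  out
}

.draw_subject_pars <- function(cfg, group, subj) {
  g <- cfg$groups[[group]]
  pseed <- substream_seed(cfg$seed, paste(group, subj, "pars"))
  with_seed(pseed, {
    kappa <- max(0, rnorm(1, g$truth$delta_kappa, g$truth$kappa_sd %||% 0))
    steep <- if (identical(cfg$couple_itpc_behavior, group)) {
      # couple behavioral precision to the subject's phase-locking strength
      g$observer$steep_mean *
        (0.4 + 1.2 * kappa / max(g$truth$delta_kappa, 1e-6))
    } else max(5e-5, rnorm(1, g$observer$steep_mean, g$observer$steep_sd))
    pse <- rnorm(1, g$observer$pse_mean, g$observer$pse_sd)
  })
  tr <- g$truth
  tr$delta_kappa <- kappa
  tr$kappa_sd <- NULL
  list(observer = observer_params(pse_ms = pse, steepness = steep),
       truth = tr)
}

#' Run the full synthetic-cohort analysis
#'
#' Simulates every subject-session, runs filtering, epoching, behavioral
#' fitting, subjectively-correct trial selection, Morlet decomposition,
#' baseline-normalized beta power and delta ITPC, then the group-level
#' cluster permutation contrasts (stimulation off vs on paired; each patient
#' condition vs controls independent; ITPC-steepness correlation), at sensor
#' level and optionally at source level.
#'
#' @param config a [pipeline_config()] (or a list/YAML path accepted by it).
#' @return object of class `cohort_result`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  head <- head_model()
  layout <- sensor_layout(cfg$channels)
  bank <- build_bank(cfg$spectral$f_min, cfg$spectral$f_max,
                     cfg$spectral$n_wavelets, fs = cfg$sampling_rate_hz)
  subjects <- list()
  for (group in names(cfg$groups)) {
    for (s in seq_len(cfg$groups[[group]]$n)) {
      pars <- .draw_subject_pars(cfg, group, s)
      subjects[[paste(group, s, sep = "_")]] <-
        .run_subject(cfg, group, s, pars, head, layout, bank)
    }
  }
  adj <- adjacency_graph(layout)
  flat <- function(group, field) t(vapply(
    Filter(function(x) x$group == group, subjects),
    function(x) as.vector(x[[field]]), numeric(length(as.vector(
      subjects[[1]][[field]])))))
  dims <- c(length(layout$labels), 1,
            ncol(subjects[[1]]$beta_bins))
  np <- cfg$cluster$n_perm; ca <- cfg$cluster$cluster_alpha
  pseed <- substream_seed(cfg$seed, "permutations")
  tests <- list()
  has <- function(g) g %in% names(cfg$groups)
  for (field in c("beta_bins", "delta_itpc_bins")) {
    fx <- sub("_bins", "", field)
    if (has("off"))
      tests[[paste0(fx, "_off_vs_zero")]] <- permutation_p(
        flat("off", field), kind = "one_sample_t", adjacency = adj,
        dims = dims, cluster_alpha = ca, n_perm = np,
        seed = substream_seed(pseed, paste(field, "off0")))
    if (has("off") && has("on") &&
        cfg$groups$off$n == cfg$groups$on$n)
      tests[[paste0(fx, "_off_vs_on")]] <- permutation_p(
        flat("off", field), flat("on", field), kind = "paired_t",
        adjacency = adj, dims = dims, cluster_alpha = ca, n_perm = np,
        seed = substream_seed(pseed, paste(field, "offon")))
    for (g in intersect(c("off", "on"), names(cfg$groups)))
      if (has("control"))
        tests[[paste0(fx, "_", g, "_vs_control")]] <- permutation_p(
          flat(g, field), flat("control", field), kind = "independent_t",
          adjacency = adj, dims = dims, cluster_alpha = ca, n_perm = np,
          seed = substream_seed(pseed, paste(field, g, "ctrl")))
  }
  corr <- NULL
  cg <- cfg$couple_itpc_behavior %||% "on"
  if (has(cg)) {
    sel <- Filter(function(x) x$group == cg, subjects)
    steep <- vapply(sel, function(x) x$steepness, 0)
    if (isTRUE(cfg$source$enabled)) {
      maps <- t(vapply(sel, function(x) x$source_itpc,
                       numeric(length(sel[[1]]$source_itpc))))
      corr <- itpc_behavior_correlation(maps, steep, sel[[1]]$grid,
                                        n_perm = np, cluster_alpha = ca,
                                        seed = substream_seed(pseed, "corr"))
    } else if (length(sel) >= 4 && sd(steep) > 0) {
      maps <- flat(cg, "delta_itpc_bins")
      corr <- list(clusters = permutation_p(
        maps, scores = steep, kind = "pearson_r", adjacency = adj,
        dims = dims, cluster_alpha = ca, n_perm = np,
        seed = substream_seed(pseed, "corr")))
      corr$r <- corr$clusters$stat
    }
  }
  behav <- do.call(rbind, lapply(subjects, function(x)
    data.frame(group = x$group, subject = x$subject, pse_ms = x$pse_ms,
               steepness = x$steepness, truth_kappa = x$truth_kappa,
               n_correct = x$n_correct, n_epochs = x$n_epochs)))
  rownames(behav) <- NULL
  res <- structure(list(
    subjects = subjects, behavior = behav, tests = tests,
    correlation = corr, config = cfg, layout = layout,
    provenance = list(seed = cfg$seed, config_hash = .fnv_hash(
      cfg[setdiff(names(cfg), "design")]),
      package = as.character(utils::packageVersion("tpeeg")))),
    class = "cohort_result")
  if (!is.null(cfg$out_dir)) write_cohort_result(res, cfg$out_dir)
  res
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("Cohort result: %d subjects in %d groups, %d contrasts\n",
              nrow(x$behavior), length(unique(x$behavior$group)),
              length(x$tests)))
  for (nm in names(x$tests))
    cat(sprintf("  %-28s min cluster p = %.4f\n", nm,
                min_cluster_p(x$tests[[nm]])))
  if (!is.null(x$correlation) && !is.null(x$correlation$clusters))
    cat(sprintf("  %-28s min cluster p = %.4f\n", "itpc~steepness",
                min_cluster_p(x$correlation$clusters)))
  invisible(x)
}

#' JSON-serializable summary of a cohort run
#' @param object a `cohort_result`.
#' @param ... unused.
#' @export
summary.cohort_result <- function(object, ...) {
  list(behavior = object$behavior,
       contrasts = lapply(object$tests, function(tt) list(
         kind = tt$kind, n_perm = tt$n_perm,
         min_p = min_cluster_p(tt),
         n_clusters = nrow(tt$clusters),
         masses = tt$clusters$mass, p = tt$clusters$p_perm)),
       provenance = object$provenance)
}

#' Write cohort outputs (behavior TSV, summary JSON, figure)
#' @param res a `cohort_result`.
#' @param dir output directory (created if needed).
#' @export
write_cohort_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(res$behavior, file.path(dir, "behavior.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(summary(res), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  for (nm in names(res$tests))
    write_cluster_result(res$tests[[nm]],
                         file.path(dir, paste0("cluster_", nm, ".json")))
  grDevices::png(file.path(dir, "behavior.png"), 900, 600)
  on.exit(grDevices::dev.off())
  groups <- unique(res$behavior$group)
  cols <- seq_along(groups) + 1
  plot(NULL, xlim = c(1, length(groups)), ylim = range(res$behavior$steepness),
       xaxt = "n", xlab = "group", ylab = "steepness (1/ms)",
       main = "psychometric steepness by group")
  graphics::axis(1, at = seq_along(groups), labels = groups)
  for (i in seq_along(groups)) {
    v <- res$behavior$steepness[res$behavior$group == groups[i]]
    graphics::points(jitter(rep(i, length(v)), 0.3), v, col = cols[i], pch = 19)
  }
  invisible(dir)
}
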