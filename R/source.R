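#' Homogeneous spherical head model
#'
#' A single homogeneous conducting sphere with an insulating exterior. The
#' closed-form surface potential of an internal current dipole makes the
#' forward model exactly testable; externally computed leadfields can be
#' supplied to [dics_filters()] when a realistic model is available.
#'
#' @param radius_mm sphere radius (mm).
#' @param center_mm sphere center (mm, length 3).
#' @param conductivity_s_m homogeneous conductivity (S/m).
#' @return object of class `head_model`.
#' @export
head_model <- function(radius_mm = 85, center_mm = c(0, 0, 0),
                       conductivity_s_m = 0.33) {
  if (radius_mm <= 0) stopf("radius must be positive")
  structure(list(radius_mm = radius_mm, center_mm = center_mm,
                 conductivity_s_m = conductivity_s_m),
            class = "head_model")
}

#' Regular source grid inside a spherical head
#'
#' A cubic lattice (spacing in mm) clipped to the sphere interior. With
#' `target_count` given, the spacing is solved so the voxel count lands within
#' 2\% of the target.
#'
#' @param head a [head_model()].
#' @param spacing_mm lattice spacing (mm); ignored when `target_count` given.
#' @param target_count desired voxel count.
#' @param max_ecc voxels are kept strictly inside `max_ecc * radius` (keeps
#'   sources off the surface where the beamformer leadfield degenerates).
#' @return object of class `source_grid`: `positions` (n x 3 mm), `ijk`
#'   (integer lattice coordinates), `spacing_mm`, `head`.
#' @export
build_grid <- function(head = head_model(), spacing_mm = NULL,
                       target_count = NULL, max_ecc = 0.92) {
  R <- head$radius_mm * max_ecc
  count_at <- function(s) {
    k <- floor(R / s)
    g <- (-k:k) * s
    ijk <- as.matrix(expand.grid(x = g, y = g, z = g))
    sum(rowSums(ijk^2) < R^2)
  }
  if (is.null(spacing_mm)) {
    if (is.null(target_count)) stopf("give spacing_mm or target_count")
    s0 <- R * (4 * pi / (3 * target_count))^(1 / 3)
    lo <- s0 * 0.8; hi <- s0 * 1.25
    for (i in 1:40) { # bisection on the (step-wise monotone) count function
      mid <- (lo + hi) / 2
      if (count_at(mid) > target_count) lo <- mid else hi <- mid
    }
    cand <- seq(lo * 0.98, hi * 1.02, length.out = 61)
    cnt <- vapply(cand, count_at, 0L)
    spacing_mm <- cand[which.min(abs(cnt - target_count))]
    if (abs(count_at(spacing_mm) - target_count) > 0.02 * target_count)
      stopf("cannot reach voxel count %d within 2%%", target_count)
  }
  if (spacing_mm <= 0) stopf("spacing must be positive")
  k <- floor(R / spacing_mm)
  g <- -k:k
  ijk <- as.matrix(expand.grid(i = g, j = g, k = g))
  pos <- ijk * spacing_mm
  keep <- rowSums(pos^2) < R^2
  pos <- sweep(pos[keep, , drop = FALSE], 2, head$center_mm, `+`)
  colnames(pos) <- c("x", "y", "z")
  structure(list(positions = pos, ijk = ijk[keep, , drop = FALSE],
                 spacing_mm = spacing_mm, head = head),
            class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("Source grid: %d voxels, %.2f mm spacing, sphere radius %g mm\n",
              nrow(x$positions), x$spacing_mm, x$head$radius_mm))
  invisible(x)
}

# Closed-form surface potential of a dipole in a homogeneous sphere.
# Derived by summing the Legendre expansion
#   V = 1/(4 pi sigma a^2) sum_n (2n+1)/n f^(n-1) [n p_r P_n + p_t P_n^1]
# with the generating functions of P_n and P_n^1:
#   radial factor      A = 2 (c - f)/S^3 + (1/S - 1)/f
#   tangential factor  B = 2/S^3 + (S + 1)/(S D)
# where f = |r0|/a, c = cos(angle), S = sqrt(1 - 2 f c + f^2), D = 1 - f c + S.
# The tangential projection p_t sin(gamma) equals p . (rhat - c b0hat), which
# stays well defined when electrode and dipole are collinear.
.sphere_potential <- function(elec_unit, r0, moment, radius_m, sigma) {
  a <- radius_m
  b <- sqrt(sum(r0^2))
  f <- b / a
  if (f >= 1) stopf("source outside head radius")
  if (f < 1e-12) {                      # dipole at the center
    return(3 * as.vector(elec_unit %*% moment) / (4 * pi * sigma * a^2))
  }
  b0 <- r0 / b
  c <- as.vector(elec_unit %*% b0)
  S <- sqrt(pmax(1 - 2 * f * c + f^2, 1e-30))
  D <- 1 - f * c + S
  A <- 2 * (c - f) / S^3 + (1 / S - 1) / f
  B <- 2 / S^3 + (S + 1) / (S * D)
  pr <- sum(moment * b0)
  ptan <- as.vector(elec_unit %*% moment) - c * pr
  (pr * A + B * ptan) / (4 * pi * sigma * a^2)
}

#' Analytic EEG leadfield for a spherical head
#'
#' For each voxel, the average-referenced sensor potentials of unit dipoles
#' along the three canonical axes (closed-form homogeneous-sphere solution).
#' A voxel at the sphere center with radial orientation is silent; such
#' voxels are flagged, not errors.
#'
#' @param grid a [build_grid()] result.
#' @param layout a [sensor_layout()]; sensors are placed on the sphere
#'   surface at the layout's unit positions.
#' @param head a [head_model()].
#' @return object of class `leadfield`: `lf` (channels x 3 x voxels, V per
#'   A·m), `grid`, `layout`, `head`.
#' @export
leadfield_sphere <- function(grid, layout, head = grid$head) {
  a <- head$radius_mm / 1000
  sig <- head$conductivity_s_m
  E <- layout$positions                       # unit vectors = electrode dirs
  nvox <- nrow(grid$positions)
  nch <- nrow(E)
  lf <- array(0, dim = c(nch, 3, nvox))
  eye <- diag(3)
  for (v in seq_len(nvox)) {
    r0 <- (grid$positions[v, ] - head$center_mm) / 1000
    for (o in 1:3) {
      pot <- .sphere_potential(E, r0, eye[o, ], a, sig)
      lf[, o, v] <- pot - mean(pot)           # average reference
    }
  }
  dimnames(lf) <- list(layout$labels, c("x", "y", "z"), NULL)
  structure(list(lf = lf, grid = grid, layout = layout, head = head),
            class = "leadfield")
}

#' Leadfield (sensor topography) of one dipole
#' @param head a [head_model()].
#' @param layout a [sensor_layout()].
#' @param pos_mm dipole position (mm, head coordinates).
#' @param moment dipole moment direction (length 3).
#' @return average-referenced channel vector.
#' @export
dipole_topography <- function(head, layout, pos_mm, moment) {
  pot <- .sphere_potential(layout$positions,
                           (pos_mm - head$center_mm) / 1000,
                           moment, head$radius_mm / 1000,
                           head$conductivity_s_m)
  pot - mean(pot)
}

#' Cross-spectral density matrices from wavelet coefficients
#'
#' Trial-averaged channel x channel CSD per frequency and 100 ms step across
#' an event-aligned window, plus the band x window average used to compute
#' common beamformer filters.
#'
#' @param tfr a [tfr_convolve()] result.
#' @param band_hz frequency band `c(lo, hi)`.
#' @param window window name from [event_windows()] or
#'   `list(win = , event = )`.
#' @param bin_ms step width (ms).
#' @return object of class `csd_set`: `C` (list over freq of list over step),
#'   `common` (Hermitian matrix), `freqs`, `steps_ms`, `n_trials`.
#' @export
csd_matrices <- function(tfr, band_hz, window = "disappearance", bin_ms = 100) {
  wd <- .window_def(window)
  al <- .align_tfr(tfr, wd$win, wd$event)
  fi <- which(tfr$freqs >= band_hz[1] & tfr$freqs <= band_hz[2])
  if (!length(fi)) stopf("no frequencies in band")
  ntr <- length(tfr$coef)
  if (ntr < 2) stopf("CSD needs >= 2 trials")
  nch <- dim(tfr$coef[[1]])[1]
  bn <- .bin_of(al$grid, wd$win, bin_ms)
  C <- lapply(fi, function(f) lapply(seq_len(bn$n), function(b)
    matrix(0i, nch, nch)))
  counts <- matrix(0L, length(fi), bn$n)
  for (tr in seq_len(ntr)) {
    z <- tfr$coef[[tr]][, , al$idx[tr, ], drop = FALSE]
    for (k in seq_along(fi)) {
      for (b in seq_len(bn$n)) {
        sel <- which(bn$bin == b)
        for (s in sel) {
          x <- z[, fi[k], s]
          C[[k]][[b]] <- C[[k]][[b]] + x %*% Conj(t(x))
        }
        counts[k, b] <- counts[k, b] + length(sel)
      }
    }
  }
  for (k in seq_along(fi)) for (b in seq_len(bn$n))
    C[[k]][[b]] <- C[[k]][[b]] / counts[k, b]
  common <- Reduce(`+`, lapply(seq_along(fi), function(k)
    Reduce(`+`, C[[k]]))) / (length(fi) * bn$n)
  structure(list(C = C, common = common, freqs = tfr$freqs[fi],
                 steps_ms = bn$centers, n_trials = ntr,
                 band_hz = band_hz, window = wd$name),
            class = "csd_set")
}

.pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

#' DICS common spatial filters
#'
#' Filters are computed from the real part of the (regularized) common CSD:
#' vector filter \eqn{W = (L^T C_r^{-1} L)^{-1} L^T C_r^{-1}} per voxel, and a
#' scalar filter along the dominant orientation (leading eigenvector of the
#' 3 x 3 source-level CSD). The unit-gain property \eqn{W L = I_3} holds
#' exactly at \eqn{\lambda = 0}.
#'
#' @param csd_common Hermitian channel x channel CSD (e.g. `$common` of
#'   [csd_matrices()]), or a `csd_set`.
#' @param lf a [leadfield_sphere()] result (or any object with `$lf`).
#' @param lambda_frac Tikhonov regularization as a fraction of mean sensor
#'   power (`lambda = lambda_frac * mean(diag(Re(C)))`).
#' @return object of class `dics_filters`: `W_scalar` (voxels x channels),
#'   `W_vector` (3 x channels x voxels), `ori` (voxels x 3), `lambda`,
#'   `singular` (voxels where a pseudo-inverse was needed).
#' @export
dics_filters <- function(csd_common, lf, lambda_frac = 0.05) {
  if (inherits(csd_common, "csd_set")) csd_common <- csd_common$common
  Cr <- Re(csd_common)
  lambda <- lambda_frac * mean(diag(Cr))
  Creg <- Cr + diag(lambda, nrow(Cr))
  Ci <- solve(Creg)
  L <- lf$lf
  nvox <- dim(L)[3]; nch <- dim(L)[1]
  Wsc <- matrix(0, nvox, nch)
  Wv <- array(0, dim = c(3, nch, nvox))
  ori <- matrix(0, nvox, 3)
  singular <- logical(nvox)
  for (v in seq_len(nvox)) {
    Lv <- L[, , v]
    G <- crossprod(Lv, Ci) # 3 x ch
    A <- G %*% Lv
    Ainv <- tryCatch(solve(A), error = function(e) NULL)
    if (is.null(Ainv) || !all(is.finite(Ainv)) ||
        rcond(A) < 1e-12) {
      Ainv <- .pinv(A)
      singular[v] <- TRUE
    }
    W <- Ainv %*% G
    Cs <- Re(W %*% csd_common %*% t(W))
    e <- eigen(Cs, symmetric = TRUE)
    u <- e$vectors[, 1]
    Wv[, , v] <- W
    ori[v, ] <- u
    Wsc[v, ] <- as.vector(crossprod(u, W))
  }
  structure(list(W_scalar = Wsc, W_vector = Wv, ori = ori, lambda = lambda,
                 lambda_frac = lambda_frac, csd = csd_common,
                 grid = lf$grid, labels = dimnames(L)[[1]],
                 singular = singular),
            class = "dics_filters")
}

#' Source power map through DICS filters
#'
#' \eqn{P(v) = w_v \mathrm{Re}(C) w_v^T} with the scalar (dominant
#' orientation) filters.
#'
#' @param filters a [dics_filters()] result.
#' @param csd_condition condition CSD (matrix or `csd_set`), same band and
#'   window family as the filter CSD.
#' @param normalize `"none"`, `"nai"` (neural activity index: power divided
#'   by the filter's projected white-noise power, removing the beamformer's
#'   depth bias; use for localization), `"zscore"` (z across voxels) or
#'   `"relative"` (ratio to the mean voxel power minus one).
#' @return numeric voxel vector.
#' @export
source_power <- function(filters, csd_condition = filters$csd,
                         normalize = c("none", "nai", "zscore", "relative")) {
  normalize <- match.arg(normalize)
  if (inherits(csd_condition, "csd_set")) csd_condition <- csd_condition$common
  Cr <- Re(csd_condition)
  p <- rowSums((filters$W_scalar %*% Cr) * filters$W_scalar)
  switch(normalize,
         none = p,
         nai = p / rowSums(filters$W_scalar^2),
         zscore = (p - mean(p)) / sd(p),
         relative = p / mean(p) - 1)
}

#' Source-level ITPC map
#'
#' Projects each trial's channel coefficients through the scalar filter of
#' every voxel and computes the ITPC of the projected (source) phase across
#' trials, averaged over the frequency band and the event-aligned window.
#'
#' @param filters a [dics_filters()] result (scalar filters are used; phase
#'   of a 3-vector is ill-defined).
#' @param tfr a [tfr_convolve()] result.
#' @param band_hz frequency band `c(lo, hi)`.
#' @param window window name or `list(win = , event = )`.
#' @return numeric voxel vector in `[0, 1]`.
#' @export
source_itpc <- function(filters, tfr, band_hz, window = "disappearance") {
  wd <- .window_def(window)
  al <- .align_tfr(tfr, wd$win, wd$event)
  fi <- which(tfr$freqs >= band_hz[1] & tfr$freqs <= band_hz[2])
  if (!length(fi)) stopf("no frequencies in band")
  ntr <- length(tfr$coef)
  if (ntr < 2) stopf("ITPC needs >= 2 trials")
  W <- filters$W_scalar
  nvox <- nrow(W)
  ns <- length(al$grid)
  acc <- matrix(0, nvox, 1)
  total <- 0L
  X <- matrix(0i, ncol(W), ntr)
  for (k in fi) {
    for (s in seq_len(ns)) {
      for (tr in seq_len(ntr)) X[, tr] <- tfr$coef[[tr]][, k, al$idx[tr, s]]
      S <- W %*% X
      m <- Mod(S)
      m[m == 0] <- 1
      acc <- acc + Mod(rowSums(S / m)) / ntr
      total <- total + 1L
    }
  }
  as.vector(acc / total)
}

#' Voxel-wise correlation of source ITPC with behavioral steepness
#'
#' Per-voxel Pearson correlation across subjects between source ITPC and
#' psychometric steepness, with cluster-based permutation correction over the
#' voxel 26-connectivity adjacency.
#'
#' @param itpc_maps subjects x voxels matrix of source ITPC.
#' @param steepness per-subject psychometric steepness.
#' @param grid the [build_grid()] the maps live on.
#' @param n_perm,cluster_alpha,seed passed to [permutation_p()].
#' @return list with `r` (voxel correlation map) and `clusters`
#'   (a `cluster_result`).
#' @export
itpc_behavior_correlation <- function(itpc_maps, steepness, grid,
                                      n_perm = 1000, cluster_alpha = 0.05,
                                      seed = 1L) {
  if (sd(steepness) == 0) {
    warnf("steepness is constant across subjects; correlation undefined")
    return(list(r = rep(NA_real_, ncol(itpc_maps)), clusters = NULL))
  }
  adj <- adjacency_graph(grid)
  res <- permutation_p(itpc_maps, scores = steepness, kind = "pearson_r",
                       adjacency = adj, dims = c(ncol(itpc_maps), 1, 1),
                       cluster_alpha = cluster_alpha, n_perm = n_perm,
                       seed = seed)
  list(r = res$stat, clusters = res)
}

#' Export a voxel map as a flat TSV (voxel index, x, y, z, value)
#' @param values voxel vector.
#' @param grid a [build_grid()] result.
#' @param path output file.
#' @export
write_voxel_map <- function(values, grid, path) {
  d <- data.frame(voxel = seq_along(values), grid$positions, value = values)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
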