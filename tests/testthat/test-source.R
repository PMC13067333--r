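hm <- head_model()
lay32 <- sensor_layout(32)

test_that("source grids fill the sphere and hit target counts", {
  g <- build_grid(hm, spacing_mm = 20)
  expect_true(all(sqrt(rowSums(g$positions^2)) < hm$radius_mm))
  expect_equal(g$spacing_mm, 20)
  # spacing equal to the radius leaves only the center voxel
  g1 <- build_grid(hm, spacing_mm = hm$radius_mm)
  expect_equal(nrow(g1$positions), 1)
  expect_equal(unname(g1$positions[1, ]), c(0, 0, 0))
  # halving the spacing multiplies the count by roughly 8
  n10 <- nrow(build_grid(hm, spacing_mm = 10)$positions)
  expect_gt(n10 / nrow(g$positions), 6)
  expect_lt(n10 / nrow(g$positions), 10)
  # target count solved to within 2%
  g5 <- build_grid(hm, target_count = 5003)
  expect_gte(nrow(g5$positions), 4903)
  expect_lte(nrow(g5$positions), 5103)
})

test_that("closed-form leadfield matches the Legendre-series solution to 1e-10", {
  set.seed(12)
  a <- hm$radius_mm / 1000
  for (k in 1:10) {
    r0 <- rnorm(3); r0 <- r0 / sqrt(sum(r0^2)) * runif(1, 0, 0.88) * a
    p <- rnorm(3)
    topo <- dipole_topography(hm, lay32, r0 * 1000, p)
    ser <- vapply(seq_len(32), function(i)
      series_sphere_potential(lay32$positions[i, ], r0, p, a,
                              hm$conductivity_s_m), 0)
    ser <- ser - mean(ser)
    expect_lt(max(abs(topo - ser)) / max(abs(ser)), 1e-10)
  }
})

test_that("leadfield geometry: reference, radial maxima, depth attenuation", {
  grid <- build_grid(hm, spacing_mm = 25)
  lf <- leadfield_sphere(grid, lay32, hm)
  # average reference: channel mean of every column is zero
  expect_lt(max(abs(apply(lf$lf, c(2, 3), mean))), 1e-12)
  # a radial dipole's potential peaks at the nearest electrode
  pos <- lay32$positions[5, ] * 60 # 60 mm under electrode 5
  topo <- dipole_topography(hm, lay32, pos, lay32$positions[5, ])
  expect_equal(which.max(topo), 5)
  # deep sources are weaker than superficial ones at the same orientation
  ori <- c(1, 0, 0)
  deep <- dipole_topography(hm, lay32, c(0, 0, 5), ori)
  shallow <- dipole_topography(hm, lay32, c(0, 0, 65), ori)
  expect_lt(sqrt(sum(deep^2)), sqrt(sum(shallow^2)))
  # rotating sensors and dipole together leaves the pattern unchanged
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  lay_rot <- lay32
  lay_rot$positions <- lay32$positions %*% t(R)
  t1 <- dipole_topography(hm, lay32, c(20, 30, 40), c(0, 1, 0))
  t2 <- dipole_topography(hm, lay_rot, as.vector(R %*% c(20, 30, 40)),
                          as.vector(R %*% c(0, 1, 0)))
  expect_equal(t1, t2, tolerance = 1e-8)
})

test_that("CSD matrices are Hermitian with coherent duplicated channels", {
  fs <- 250
  ep <- make_epochs(4, 3, 750, fs, function(tr, t)
    rbind(sin(2 * pi * 9 * t + tr), sin(2 * pi * 9 * t + tr),
          rnorm(length(t))))
  bank <- build_bank(4, 30, 6, fs = fs)
  tfr <- tfr_convolve(ep, bank, 20)
  cs <- csd_matrices(tfr, c(6, 14), list(win = c(-400, 400),
                                         event = "disappear"))
  C <- cs$common
  expect_equal(C, Conj(t(C)), tolerance = 1e-12)
  expect_true(all(Re(diag(C)) >= 0))
  # duplicated channel: perfect coherence, |off-diag| = geometric mean of diag
  expect_equal(Mod(C[1, 2]), sqrt(Re(C[1, 1]) * Re(C[2, 2])),
               tolerance = 1e-8)
  expect_lt(Mod(C[1, 3]), 0.2 * Mod(C[1, 2]))
})

test_that("DICS filters satisfy unit gain and the minimum-variance identity", {
  grid <- build_grid(hm, spacing_mm = 30)
  lf <- leadfield_sphere(grid, lay32, hm)
  set.seed(5)
  # a well-conditioned full-rank CSD
  M <- matrix(rnorm(32 * 64), 32)
  C <- M %*% t(M) / 64 + diag(32)
  fl0 <- dics_filters(C, lf, lambda_frac = 0)
  for (v in c(1, 7, nrow(grid$positions))) {
    WL <- fl0$W_vector[, , v] %*% lf$lf[, , v]
    expect_lt(max(abs(WL - diag(3))), 1e-6)
  }
  # scalar power equals the minimum-variance estimate 1/(l' C^-1 l)
  p <- source_power(fl0, C)
  Ci <- solve(C)
  for (v in c(2, 11)) {
    l <- lf$lf[, , v] %*% fl0$ori[v, ]
    expect_equal(p[v], 1 / as.vector(t(l) %*% Ci %*% l), tolerance = 1e-6)
  }
  # doubling the condition CSD doubles power everywhere
  expect_equal(source_power(fl0, 2 * C), 2 * p, tolerance = 1e-10)
})

test_that("a simulated dipole is localized and a shared filter preserves power ratios", {
  grid <- build_grid(hm, spacing_mm = 20)
  lf <- leadfield_sphere(grid, lay32, hm)
  set.seed(9)
  inner <- which(sqrt(rowSums(grid$positions^2)) <= 0.8 * hm$radius_mm)
  v <- sample(inner, 1)
  ori <- rnorm(3); ori <- ori / sqrt(sum(ori^2))
  l <- as.vector(lf$lf[, , v] %*% ori)
  sigma <- sqrt(mean(l^2))
  X1 <- dipole_trials(l, 120, sigma, amp = 1)
  X2 <- dipole_trials(l, 120, sigma, amp = 2) # double amplitude: 4x power
  C1 <- X1 %*% Conj(t(X1)) / 120
  C2 <- X2 %*% Conj(t(X2)) / 120
  flc <- dics_filters((C1 + C2) / 2, lf, 0.05) # common filter
  p1 <- source_power(flc, C1); p2 <- source_power(flc, C2)
  nai <- source_power(flc, (C1 + C2) / 2, normalize = "nai")
  dist <- sqrt(sum((grid$positions[which.max(nai), ] -
                      grid$positions[v, ])^2))
  expect_lte(dist, grid$spacing_mm * 1.01)
  # injected power ratio at the true voxel: (4 s + n)/(s + n) with s = n
  ratio <- p2[v] / p1[v]
  expect_gt(ratio, 2.0)
  expect_lt(ratio, 3.1)
})

test_that("source ITPC is 1 for identical trials and flat for scrambled phases", {
  grid <- build_grid(hm, spacing_mm = 35)
  lf <- leadfield_sphere(grid, lay32, hm)
  set.seed(3)
  one <- array(complex(real = rnorm(32 * 2 * 41),
                       imaginary = rnorm(32 * 2 * 41)), dim = c(32, 2, 41))
  tfr <- make_tfr(rep(list(one), 10), 250, 20, c(1.5, 3))
  C <- diag(32) + 0i
  fl <- dics_filters(C, lf, 0.05)
  si <- source_itpc(fl, tfr, c(0.5, 4), list(win = c(-300, 300),
                                             event = "disappear"))
  expect_equal(max(abs(si - 1)), 0, tolerance = 1e-9)
  # independent random phases: close to the Rayleigh floor everywhere
  N <- 60
  set.seed(4)
  coef <- lapply(seq_len(N), function(i)
    array(complex(modulus = 1, argument = runif(32 * 2 * 41, -pi, pi)),
          dim = c(32, 2, 41)))
  tfr2 <- make_tfr(coef, 250, 20, c(1.5, 3))
  si2 <- source_itpc(fl, tfr2, c(0.5, 4), list(win = c(-300, 300),
                                               event = "disappear"))
  floor_exp <- sqrt(pi) / (2 * sqrt(N))
  expect_lt(abs(mean(si2) - floor_exp), 0.03)
})

test_that("ITPC-behavior correlation flags constant scores and respects sign flips", {
  grid <- build_grid(hm, spacing_mm = 35)
  set.seed(6)
  maps <- matrix(runif(8 * nrow(grid$positions)), 8)
  expect_warning(r0 <- itpc_behavior_correlation(maps, rep(0.004, 8), grid),
                 "constant")
  expect_true(all(is.na(r0$r)))
  steep <- rnorm(8)
  r1 <- itpc_behavior_correlation(maps, steep, grid, n_perm = 100, seed = 2)
  r2 <- itpc_behavior_correlation(maps, -steep, grid, n_perm = 100, seed = 2)
  expect_equal(r1$r, -r2$r, tolerance = 1e-12)
  expect_equal(sort(r1$clusters$clusters$p_perm),
               sort(r2$clusters$clusters$p_perm))
})
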