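# Orientation grids, projections, CTF filtering, whitening, the detection
# threshold and the template search.

test_that("orientation grids sample the sphere at the requested density", {
  g <- make_orientation_grid(90, 90)
  # directions: two poles plus an equatorial ring of 4; psi in {0,90,180,270}
  dirs <- unique(g$orientations[, c("phi", "theta")])
  expect_equal(nrow(dirs), 6)
  expect_equal(nrow(g$orientations), 6 * 4)
  expect_false(any(duplicated(g$orientations)))

  # full-scale grid count vs the solid-angle formula (4 pi / step^2) * 360
  n <- orientation_grid_size(1.5, 1.0)
  formula <- (4 * pi / (1.5 * pi / 180)^2) * 360
  expect_lt(abs(n - formula) / formula, 0.1)
  expect_equal(orientation_grid_size(20, 20),
               nrow(make_orientation_grid(20, 20)$orientations))
  expect_error(make_orientation_grid(0, 1), "steps")
})

test_that("projections conserve mass and rotate in-plane with psi", {
  tv <- fx_template()
  p0 <- project_template(tv, c(0, 0, 0))
  expect_equal(sum(p0), sum(tv$density), tolerance = 0.005)

  p <- project_template(tv, c(40, 70, 15))
  expect_equal(sum(p), sum(tv$density), tolerance = 0.005)

  p180 <- project_template(tv, c(0, 0, 180))
  r180 <- p0[nrow(p0):1, ncol(p0):1]
  expect_lt(sqrt(mean((p180 - r180)^2)), 0.01 * max(p0))
})

test_that("the CTF has the stated low-frequency limit and first zero", {
  ctf <- ctf_params(0.8, pixel_size = 1.5, amplitude_contrast = 0.07)
  expect_equal(ctf_value(0, ctf), -0.07, tolerance = 1e-12)

  # independent root-find of chi(s) = -pi for the first sin zero
  lambda <- electron_wavelength(300)
  chi <- function(s) pi * lambda * 8000 * s^2 - (pi / 2) * 2.7e7 * lambda^3 * s^4
  # first zero of sin(chi) + w cos(chi) ~ where CTF crosses zero
  s_zero_oracle <- uniroot(function(s) ctf_value(s, ctf), c(0.02, 0.09))$root
  # the zero lies close to where chi = -pi ... here chi is positive branch:
  s_chi <- uniroot(function(s) chi(s) - pi, c(0.02, 0.12))$root
  expect_lt(abs(s_zero_oracle - s_chi), 0.01)

  # B = 0 leaves the amplitude envelope identically 1
  proj <- project_template(fx_template(), c(0, 0, 0))
  f0 <- apply_ctf_and_bfactor(proj, fx_ctf(), 0, 0)
  fB <- apply_ctf_and_bfactor(proj, fx_ctf(), 0, 50)
  expect_gt(sd(f0), sd(fB))   # B-factor attenuates
  expect_error(apply_ctf_and_bfactor(proj, fx_ctf(), 0, 0, pixel_size = 3),
               "pixel")
})

test_that("whitening flattens white and pink noise spectra", {
  for (kind in c("white", "pink")) {
    img <- with_seed_test(13, matrix(rnorm(256 * 256), 256, 256))
    if (kind == "pink") {
      g <- tiledtm:::freq_grid(256, 256, 1)
      ft <- tiledtm:::fft2(img) / pmax(g$s, 1 / 256)
      ft[1, 1] <- 0
      img <- Re(tiledtm:::ifft2(ft))
    }
    w <- whiten(img + 100, NULL)
    ps <- Mod(tiledtm:::fft2(w))^2
    g <- tiledtm:::freq_grid(256, 256, 1)
    ra <- tiledtm:::radial_average(ps[-1], g$s[-1], nbins = 32)
    mid <- ra$mean[ra$r > 0.05 & ra$r < 0.45]
    expect_lt(max(abs(mid / mean(mid) - 1)), 0.05)
  }
  img <- with_seed_test(14, matrix(rnorm(64 * 64), 64, 64))
  expect_identical(whiten(img, NULL), whiten(img, NULL))
  expect_error(whiten(matrix(0, 64, 64), NULL), "power")
})

test_that("the one-false-positive threshold inverts the Gaussian tail", {
  expect_equal(one_fp_threshold(2, 1), 0, tolerance = 1e-12)
  expect_equal(one_fp_threshold(741, 1), 3.00, tolerance = 0.01 / 3)
  # strictly increasing in the number of search outcomes
  ns <- c(1e3, 1e5, 1e7, 1e9, 1e12)
  ts <- vapply(ns, function(n) one_fp_threshold(n, 1), numeric(1))
  expect_true(all(diff(ts) > 0))
  expect_warning(one_fp_threshold(1, 1), "threshold")
})

test_that("normalized correlation samples on noise are standard normal", {
  ff <- fx_flat_frame(192, 10, seed = 15)
  oris <- rbind(c(0, 0, 0), c(40, 60, 120), c(200, 110, 45))
  for (k in seq_len(nrow(oris))) {
    cc <- correlation_map(ff$image, ff$mask, fx_template(), fx_ctf(),
                          oris[k, ])
    expect_lt(abs(mean(cc)), 0.05)
    expect_gt(sd(cc), 0.93)
    expect_lt(sd(cc), 1.07)
  }
})

test_that("a planted on-grid target is found at its pixel, angle and defocus plane", {
  grid <- fx_grid_coarse()
  tv <- fx_template_wide()
  ori <- grid$orientations
  pick <- ori[ori$theta == 40 & ori$psi == 90, ][2, ]  # an actual grid row
  scene <- fx_scene_flat()
  scene$instances <- data.frame(x_nm = 5, y_nm = -8, z_nm = 60,
                                phi = pick$phi, theta = pick$theta,
                                psi = pick$psi)
  cam <- fx_camera()
  ctf <- fx_ctf()
  rt <- render_tile(scene, tv, c(0, 0), fx_beam(), cam, ctf, seed = 16,
                    signal_scale = 100)
  mask <- illumination_mask(rt$image, 8)
  img <- fill_dark_with_noise(rt$image, mask, 17)
  res <- match_template(img, mask, tv, ctf, grid, defocus_planes = 5,
                        defocus_step = 40, bank = fx_bank_wide())
  pk <- extract_peaks(res, mask, exclusion_radius_px = 8)
  expect_gt(nrow(pk), 0)
  best <- pk[1, ]
  expect_lte(abs(best$x_px - rt$truth$x_px), 1)
  expect_lte(abs(best$y_px - rt$truth$y_px), 1)
  # in-plane angle within one step, out-of-plane within 2 steps
  expect_lte(min(abs(best$psi - pick$psi), 360 - abs(best$psi - pick$psi)), 45)
  expect_lte(abs(best$theta - pick$theta), 80)
  # planted +60 nm offset lands on one of the adjacent 40 nm planes
  expect_lte(abs(best$defocus_offset - 60), 40)
})

test_that("scaled MIP is invariant under intensity scaling of the tile", {
  t1 <- fx_noise_tile(18)
  grid <- make_orientation_grid(90, 90)
  r1 <- match_template(t1$image, t1$mask, fx_template_wide(), fx_ctf(),
                       grid, defocus_planes = 1)
  r2 <- match_template(t1$image * 7.5, t1$mask, fx_template_wide(),
                       fx_ctf(), grid, defocus_planes = 1)
  expect_equal(r1$scaled_mip, r2$scaled_mip, tolerance = 1e-8)
})

test_that("peak extraction thresholds, suppresses and respects the mask", {
  sm <- matrix(0, 64, 64)
  mask <- list(binary = matrix(TRUE, 64, 64))
  class(mask) <- "illumination_mask"
  grid1 <- list(orientations = data.frame(phi = 0, theta = 0, psi = 0))
  res <- structure(list(scaled_mip = sm, threshold = 5,
                        best_orientation = matrix(1L, 64, 64),
                        best_defocus_offset = matrix(0, 64, 64),
                        grid = grid1, mask = mask), class = "match_result")
  expect_equal(nrow(extract_peaks(res)), 0)

  sm[30, 40] <- 6
  res$scaled_mip <- sm
  pk <- extract_peaks(res)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$x_px, pk$y_px), c(39, 29))

  # two peaks 3 px apart with exclusion radius 5: keep only the higher
  sm[30, 43] <- 5.5
  res$scaled_mip <- sm
  pk2 <- extract_peaks(res, exclusion_radius_px = 5)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$snr, 6)
  pk3 <- extract_peaks(res, exclusion_radius_px = 2)
  expect_equal(nrow(pk3), 2)

  # detections outside the binary mask are discarded
  mask2 <- mask; mask2$binary[, 33:64] <- FALSE
  expect_equal(nrow(extract_peaks(res, mask2, 5)), 0)
})

test_that("noise-only search is calibrated to about one false positive per tile", {
  grid <- fx_grid_coarse()
  bank <- fx_bank_wide()
  fp <- vapply(1:20, function(k) {
    t1 <- fx_noise_tile(100 + k)
    r <- match_template(t1$image, t1$mask, fx_template_wide(), fx_ctf(),
                        grid, defocus_planes = 1, bank = bank)
    nrow(extract_peaks(r))
  }, numeric(1))
  expect_gte(mean(fp), 0.3)
  expect_lte(mean(fp), 2.0)
})

test_that("planted targets above threshold + 1 are recovered with high sensitivity", {
  grid <- fx_grid_coarse()
  bank <- fx_bank_wide()
  tv <- fx_template_wide()
  ori <- grid$orientations
  hits <- vapply(1:15, function(k) {
    oi <- with_seed_test(300 + k, sample(nrow(ori), 1))
    scene <- fx_scene_flat()
    scene$instances <- with_seed_test(400 + k, data.frame(
      x_nm = runif(1, -15, 15), y_nm = runif(1, -15, 15), z_nm = 0,
      phi = ori$phi[oi], theta = ori$theta[oi], psi = ori$psi[oi]))
    rt <- render_tile(scene, tv, c(0, 0), fx_beam(), fx_camera(), fx_ctf(),
                      seed = 500 + k, signal_scale = 100)
    mask <- illumination_mask(rt$image, 8)
    img <- fill_dark_with_noise(rt$image, mask, 600 + k)
    r <- match_template(img, mask, tv, fx_ctf(), grid, defocus_planes = 1,
                        bank = bank)
    pk <- extract_peaks(r, mask, 8)
    # margin check: the recovered peak must clear threshold + 1
    ok <- nrow(pk) > 0 &&
      min(sqrt((pk$x_px - rt$truth$x_px)^2 +
               (pk$y_px - rt$truth$y_px)^2)) <= 1
    if (ok) {
      d <- sqrt((pk$x_px - rt$truth$x_px)^2 + (pk$y_px - rt$truth$y_px)^2)
      ok <- pk$snr[which.min(d)] >= r$threshold + 1
    }
    ok
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
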