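# 2D template matching: exhaustive search of each masked tile over template
# orientations and defocus planes, scaled maximum-intensity projections in
# SNR units, an extreme-value one-false-positive detection threshold, and
# peak extraction.

#' Build a uniform orientation grid
#'
#' Directions are sampled on latitude rings spaced by `out_step`, with the
#' per-ring azimuthal step widened by `1/sin(theta)` so the surface density
#' is uniform (poles included once); each direction is combined with all
#' in-plane angles spaced by `in_step`. Euler angles follow the ZYZ
#' convention with psi the in-plane rotation.
#'
#' @param out_step Out-of-plane angular step in degrees (0 < step <= 90).
#' @param in_step In-plane angular step in degrees (0 < step <= 90).
#' @param symmetry Point-group label; only "C1" (full sphere) is implemented.
#' @return An `orientation_grid`: data frame `orientations` with columns
#'   `phi, theta, psi` (degrees) plus the step metadata.
#' @export
make_orientation_grid <- function(out_step = 1.5, in_step = 1.0,
                                  symmetry = "C1") {
  if (out_step <= 0 || out_step > 90 || in_step <= 0 || in_step > 90)
    stop("angular steps must be in (0, 90] degrees")
  if (symmetry != "C1") stop("only C1 symmetry is implemented")
  thetas <- seq(0, 180, by = out_step)
  dirs <- do.call(rbind, lapply(thetas, function(th) {
    if (th < 1e-9 || th > 180 - 1e-9) return(data.frame(phi = 0, theta = th))
    n_phi <- max(1L, round(360 * sin(th * pi / 180) / out_step))
    data.frame(phi = seq(0, 360 - 360 / n_phi, by = 360 / n_phi), theta = th)
  }))
  psis <- seq(0, 360 - in_step, by = in_step)
  orientations <- data.frame(
    phi = rep(dirs$phi, each = length(psis)),
    theta = rep(dirs$theta, each = length(psis)),
    psi = rep(psis, times = nrow(dirs)))
  structure(list(orientations = orientations, out_of_plane_step = out_step,
                 in_plane_step = in_step, symmetry = symmetry),
            class = "orientation_grid")
}

#' Size of an orientation grid without materializing it
#'
#' @inheritParams make_orientation_grid
#' @return The number of orientations the grid would contain (close to the
#'   solid-angle estimate `(4 pi / step^2) * (360 / in_step)` with the
#'   out-of-plane step in radians).
#' @export
orientation_grid_size <- function(out_step = 1.5, in_step = 1.0) {
  thetas <- seq(0, 180, by = out_step)
  n_dir <- sum(vapply(thetas, function(th) {
    if (th < 1e-9 || th > 180 - 1e-9) return(1)
    max(1, round(360 * sin(th * pi / 180) / out_step))
  }, numeric(1)))
  n_dir * length(seq(0, 360 - in_step, by = in_step))
}

# ZYZ rotation matrix, angles in degrees; psi is the in-plane rotation
# (applied last, i.e. about the projection axis)
euler_zyz <- function(phi, theta, psi) {
  rz <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  }
  ry <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  }
  rz(psi) %*% ry(theta) %*% rz(phi)
}

# trilinear sampling of a 3D array at coords (3 x N, 1-based fractional)
trilinear_sample <- function(vol, coords) {
  d <- dim(vol)
  x <- coords[1, ]; y <- coords[2, ]; z <- coords[3, ]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  val <- numeric(length(x))
  ok <- x0 >= 1 & x0 + 1 <= d[1] & y0 >= 1 & y0 + 1 <= d[2] &
    z0 >= 1 & z0 + 1 <= d[3]
  if (!any(ok)) return(val)
  idx <- function(i, j, k) (k - 1) * d[1] * d[2] + (j - 1) * d[1] + i
  x0 <- x0[ok]; y0 <- y0[ok]; z0 <- z0[ok]
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  v <- as.vector(vol)
  val[ok] <-
    v[idx(x0,     y0,     z0)]     * (1 - fx) * (1 - fy) * (1 - fz) +
    v[idx(x0 + 1, y0,     z0)]     * fx       * (1 - fy) * (1 - fz) +
    v[idx(x0,     y0 + 1, z0)]     * (1 - fx) * fy       * (1 - fz) +
    v[idx(x0,     y0,     z0 + 1)] * (1 - fx) * (1 - fy) * fz +
    v[idx(x0 + 1, y0 + 1, z0)]     * fx       * fy       * (1 - fz) +
    v[idx(x0 + 1, y0,     z0 + 1)] * fx       * (1 - fy) * fz +
    v[idx(x0,     y0 + 1, z0 + 1)] * (1 - fx) * fy       * fz +
    v[idx(x0 + 1, y0 + 1, z0 + 1)] * fx       * fy       * fz
  val
}

#' Project a template volume along the beam axis at a given orientation
#'
#' Rotates the volume by the ZYZ Euler triple and integrates along z. The
#' first density index is the x (column) axis of the projection, the second
#' the y (row) axis, so `psi` rotates the projection in-plane.
#'
#' @param volume A `template_volume`.
#' @param orientation `c(phi, theta, psi)` in degrees.
#' @return Projection matrix (box x box), rows = y.
#' @export
project_template <- function(volume, orientation) {
  vol <- volume$density
  b <- dim(vol)[1]
  ctr <- (b + 1) / 2
  ax <- seq_len(b) - ctr
  R <- euler_zyz(orientation[1], orientation[2], orientation[3])
  # coords of the output grid (x, y, z), rotated back into the volume frame
  grid_x <- rep(ax, times = b)
  grid_y <- rep(ax, each = b)
  proj <- matrix(0, b, b)
  Rt <- t(R)
  for (iz in seq_len(b)) {
    pts <- Rt %*% rbind(grid_x, grid_y, ax[iz])
    slice <- trilinear_sample(vol, pts + ctr)
    proj <- proj + matrix(slice, b, b)
  }
  # projection indexed [x, y]; transpose to image convention [row=y, col=x]
  t(proj)
}

#' Apply CTF and B-factor envelope to a projection
#'
#' Multiplies the projection in Fourier space by
#' `CTF(s; defocus + offset) * exp(-B s^2 / 4)`.
#'
#' @param projection Projection image (matrix).
#' @param ctf A `ctf_params`; its `pixel_size` is used for the frequency
#'   grid.
#' @param defocus_offset Additional defocus in nm (a defocus-plane offset).
#' @param b_factor B-factor in Angstrom^2.
#' @param pixel_size Optional pixel size of the projection; must equal
#'   `ctf$pixel_size` when given.
#' @return Filtered projection (matrix).
#' @export
apply_ctf_and_bfactor <- function(projection, ctf, defocus_offset = 0,
                                  b_factor = 0, pixel_size = NULL) {
  if (!is.null(pixel_size) &&
      abs(pixel_size - ctf$pixel_size) > 1e-9 * ctf$pixel_size)
    stop("projection and CTF pixel sizes differ")
  g <- freq_grid(nrow(projection), ncol(projection), ctf$pixel_size)
  theta <- atan2(g$sy, g$sx)
  h <- ctf_value(g$s, ctf, theta, defocus_offset) * exp(-b_factor * g$s^2 / 4)
  Re(ifft2(fft2(projection) * h))
}

#' Whiten an image against its own rotationally averaged power spectrum
#'
#' Divides the Fourier amplitudes by the square root of the rotationally
#' averaged power spectrum (flattening the noise spectrum), zeroes the DC
#' term and rescales so the variance inside the mask is 1.
#'
#' @param image Tile image (noise-filled).
#' @param mask An `illumination_mask` (or NULL for the full frame).
#' @return Whitened image.
#' @export
whiten <- function(image, mask = NULL) {
  d <- dim(image)
  ft <- fft2(image)
  g <- freq_grid(d[1], d[2], 1)
  power <- Mod(ft)^2
  power[1, 1] <- NA
  ra <- radial_average(power[-1], g$s[-1], nbins = floor(min(d) / 2))
  if (all(!is.finite(ra$mean)) || sum(ra$mean, na.rm = TRUE) <= 0)
    stop("zero-power input cannot be whitened")
  amp <- sqrt(pmax(stats::approx(ra$r, ra$mean, xout = as.vector(g$s),
                                 rule = 2)$y, 1e-30))
  ft <- ft / matrix(amp, d[1], d[2])
  ft[1, 1] <- 0
  out <- Re(ifft2(ft))
  inside <- if (is.null(mask)) rep(TRUE, length(out)) else mask$binary
  s <- stats::sd(out[inside])
  out / s
}

#' Detection threshold from the one-false-positive-per-image criterion
#'
#' Solves `n_pixels * n_orientations * erfc(t / sqrt(2)) / 2 = 1` for `t`:
#' the SNR level at which the expected number of Gaussian-noise exceedances
#' over all independent search outcomes of one image equals one. Defocus
#' planes are deliberately not counted (their correlations are strongly
#' dependent); this counting convention reproduces the working threshold of
#' 7.75 for a full-frame search.
#'
#' @param n_pixels Number of (masked) pixels searched.
#' @param n_orientations Number of orientations searched.
#' @return Threshold in SNR units.
#' @export
one_fp_threshold <- function(n_pixels, n_orientations) {
  if (n_pixels < 1 || n_orientations < 1)
    stop("n_pixels and n_orientations must be >= 1")
  n <- as.numeric(n_pixels) * as.numeric(n_orientations)
  if (n < 2) {
    warning("fewer than 2 search outcomes; threshold set to 0")
    return(0)
  }
  stats::qnorm(1 / n, lower.tail = FALSE)
}

# bilinear in-plane rotation of an image about its center
rotate2d <- function(img, angle_deg) {
  b <- nrow(img)
  ctr <- (b + 1) / 2
  a <- -angle_deg * pi / 180    # inverse mapping
  ca <- cos(a); sa <- sin(a)
  gx <- rep(seq_len(b) - ctr, each = b)    # x = column
  gy <- rep(seq_len(b) - ctr, times = b)
  sx <- ca * gx - sa * gy + ctr
  sy <- sa * gx + ca * gy + ctr
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  ok <- x0 >= 1 & x0 + 1 <= b & y0 >= 1 & y0 + 1 <= b
  v <- numeric(b * b)
  idx <- function(r, c) (c - 1) * b + r
  x0k <- x0[ok]; y0k <- y0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
  v[ok] <- img[idx(y0k, x0k)] * (1 - fxk) * (1 - fyk) +
    img[idx(y0k, x0k + 1)] * fxk * (1 - fyk) +
    img[idx(y0k + 1, x0k)] * (1 - fxk) * fyk +
    img[idx(y0k + 1, x0k + 1)] * fxk * fyk
  matrix(v, b, b)   # gy varies fastest: column-major fill gives [row = y]
}

#' Precompute template projections for an orientation grid
#'
#' Projects each unique viewing direction once in 3D and generates the
#' in-plane (psi) variants by 2D rotation of the base projection.
#'
#' @param template A `template_volume`.
#' @param grid An `orientation_grid`.
#' @return List of projection matrices, one per grid row.
#' @export
project_bank <- function(template, grid) {
  ori <- grid$orientations
  key <- paste(ori$phi, ori$theta)
  out <- vector("list", nrow(ori))
  for (k in unique(key)) {
    rows <- which(key == k)
    base <- project_template(template,
                             c(ori$phi[rows[1]], ori$theta[rows[1]], 0))
    for (i in rows) {
      out[[i]] <- if (ori$psi[i] == 0) base else rotate2d(base, ori$psi[i])
    }
  }
  out
}

#' Normalized correlation map for a single orientation
#'
#' The building block of the search: the whitened tile cross-correlated with
#' the CTF-filtered, zero-mean, unit-norm template projection at one
#' orientation. For pure noise the values are standard normal, which is the
#' model behind the one-false-positive threshold.
#'
#' @param image Preprocessed tile image.
#' @param mask An `illumination_mask` (NULL for full frame).
#' @param template A `template_volume`.
#' @param ctf A `ctf_params`.
#' @param orientation `c(phi, theta, psi)` degrees.
#' @param defocus_offset Defocus plane offset in nm.
#' @return Matrix of correlation values (SNR units), same shape as `image`.
#' @export
correlation_map <- function(image, mask, template, ctf, orientation,
                            defocus_offset = 0) {
  d <- dim(image)
  img_w <- whiten(image, mask)
  proj <- project_template(template, orientation)
  ctr <- floor(d / 2) + 1L
  padded <- circ_to_origin(pad_center(proj, d[1], d[2]), ctr[1], ctr[2])
  g <- freq_grid(d[1], d[2], ctf$pixel_size)
  h <- ctf_value(g$s, ctf, atan2(g$sy, g$sx), defocus_offset) *
    exp(-template$b_factor * g$s^2 / 4)
  f_t <- fft2(padded) * h
  f_t[1, 1] <- 0
  f_t <- f_t / sqrt(sum(Mod(f_t)^2) / length(f_t))
  Re(ifft2(fft2(img_w) * Conj(f_t)))
}

#' Match a template against a tile over orientations and defocus planes
#'
#' For every orientation (and defocus plane) the whitened tile is
#' cross-correlated via FFT with the CTF-filtered, zero-mean, unit-norm
#' template projection, so each correlation value is a matched-filter SNR
#' sample. Per-pixel running mean and variance are accumulated over the
#' whole search; the maximum (MIP) is standardized to the scaled MIP in SNR
#' units and thresholded by the one-false-positive criterion computed from
#' the masked pixel count and the orientation count.
#'
#' @param image Preprocessed tile image (noise-filled; whitened internally).
#' @param mask An `illumination_mask` for the tile.
#' @param template A `template_volume` (its `b_factor` is applied).
#' @param ctf A `ctf_params` for the tile (pixel size must match the tile).
#' @param grid An `orientation_grid`.
#' @param defocus_planes Number of defocus planes searched (default 11).
#' @param defocus_step Defocus plane spacing in nm (default 20).
#' @param bank Optional precomputed [project_bank()] result (reused across
#'   tiles that share the template and grid).
#' @return A `match_result`: `mip`, `scaled_mip`, `best_orientation`
#'   (1-based grid row index), `best_defocus_offset` (nm), `per_pixel_mean`,
#'   `per_pixel_std`, `threshold`, `n_effective`, `grid`, `mask`.
#' @export
match_template <- function(image, mask, template, ctf, grid,
                           defocus_planes = 11, defocus_step = 20,
                           bank = NULL) {
  d <- dim(image)
  b <- dim(template$density)[1]
  if (b > min(d)) stop("template box exceeds tile size")
  img_w <- whiten(image, mask)
  f_img <- fft2(img_w)
  ori <- grid$orientations
  n_ori <- nrow(ori)
  offsets <- (seq_len(defocus_planes) - (defocus_planes + 1) / 2) *
    defocus_step
  g <- freq_grid(d[1], d[2], ctf$pixel_size)
  theta_g <- atan2(g$sy, g$sx)
  env <- exp(-template$b_factor * g$s^2 / 4)
  ctr <- floor(d / 2) + 1L

  mip <- matrix(-Inf, d[1], d[2])
  best_ori <- matrix(NA_integer_, d[1], d[2])
  best_off <- matrix(NA_real_, d[1], d[2])
  acc_sum <- matrix(0, d[1], d[2])
  acc_sq <- matrix(0, d[1], d[2])
  n_samples <- n_ori * defocus_planes

  filters <- lapply(offsets, function(off)
    ctf_value(g$s, ctf, theta_g, off) * env)

  for (i in seq_len(n_ori)) {
    proj <- if (is.null(bank)) {
      project_template(template, c(ori$phi[i], ori$theta[i], ori$psi[i]))
    } else bank[[i]]
    padded <- circ_to_origin(pad_center(proj, d[1], d[2]), ctr[1], ctr[2])
    f_t0 <- fft2(padded)
    for (p in seq_along(offsets)) {
      f_t <- f_t0 * filters[[p]]
      f_t[1, 1] <- 0
      nrm <- sqrt(sum(Mod(f_t)^2) / length(f_t))
      if (nrm == 0) next
      f_t <- f_t / nrm
      cc <- Re(ifft2(f_img * Conj(f_t)))
      acc_sum <- acc_sum + cc
      acc_sq <- acc_sq + cc * cc
      upd <- cc > mip
      if (any(upd)) {
        mip[upd] <- cc[upd]
        best_ori[upd] <- i
        best_off[upd] <- offsets[p]
      }
    }
  }
  ppm <- acc_sum / n_samples
  pps <- sqrt(pmax(acc_sq / n_samples - ppm^2, 0))
  scaled <- matrix(0, d[1], d[2])
  pos <- pps > 0
  scaled[pos] <- (mip[pos] - ppm[pos]) / pps[pos]
  thr <- one_fp_threshold(mask$area_px, n_ori)
  structure(list(mip = mip, scaled_mip = scaled, best_orientation = best_ori,
                 best_defocus_offset = best_off, per_pixel_mean = ppm,
                 per_pixel_std = pps, threshold = thr,
                 n_effective = as.numeric(mask$area_px) * n_ori,
                 grid = grid, defocus_offsets = offsets, mask = mask),
            class = "match_result")
}

#' Extract detections from a match result
#'
#' Greedy descending-SNR selection of local maxima of the scaled MIP at or
#' above the threshold, suppressing anything within `exclusion_radius_px` of
#' an accepted peak; candidates outside the binary illumination mask are
#' discarded.
#'
#' @param result A `match_result`.
#' @param mask An `illumination_mask` (defaults to the one in `result`).
#' @param exclusion_radius_px Minimum peak separation in pixels (>= 1).
#' @param threshold Override for the detection threshold.
#' @return Data frame of detections: `x_px, y_px` (0-based, x = column),
#'   `defocus_offset, phi, theta, psi, snr`.
#' @export
extract_peaks <- function(result, mask = result$mask,
                          exclusion_radius_px = 5,
                          threshold = result$threshold) {
  if (exclusion_radius_px < 1) stop("exclusion radius must be >= 1")
  sm <- result$scaled_mip
  d <- dim(sm)
  cand <- which(sm >= threshold & mask$binary, arr.ind = TRUE)
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      defocus_offset = numeric(0), phi = numeric(0),
                      theta = numeric(0), psi = numeric(0), snr = numeric(0))
  if (nrow(cand) == 0) return(empty)
  # local maximum within the 8-neighbourhood
  is_max <- vapply(seq_len(nrow(cand)), function(k) {
    r <- cand[k, 1]; c <- cand[k, 2]
    rr <- max(1, r - 1):min(d[1], r + 1)
    cc <- max(1, c - 1):min(d[2], c + 1)
    sm[r, c] >= max(sm[rr, cc])
  }, logical(1))
  cand <- cand[is_max, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  vals <- sm[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (k == 1) { keep[1] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    d2 <- (prev[, 1] - cand[k, 1])^2 + (prev[, 2] - cand[k, 2])^2
    keep[k] <- all(d2 >= exclusion_radius_px^2)
  }
  cand <- cand[keep, , drop = FALSE]
  vals <- vals[keep]
  ori <- result$grid$orientations
  oidx <- result$best_orientation[cand]
  data.frame(x_px = cand[, 2] - 1, y_px = cand[, 1] - 1,
             defocus_offset = result$best_defocus_offset[cand],
             phi = ori$phi[oidx], theta = ori$theta[oidx],
             psi = ori$psi[oidx], snr = vals)
}
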