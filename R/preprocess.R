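# Tile pre-processing: illumination masking, Gaussian noise fill of the
# unilluminated area, movie-frame alignment restricted to the camera center,
# exposure (dose) filtering, Fourier resampling, CTF estimation and
# Beer-Lambert ice-thickness estimation.

#' CTF parameter set
#'
#' @param defocus_1,defocus_2 Defocus along the major/minor astigmatism axes
#'   in microns (positive = underfocus); swapped if needed so that
#'   `defocus_1 >= defocus_2`.
#' @param astig_angle Astigmatism angle in degrees.
#' @param voltage Acceleration voltage in kV.
#' @param cs Spherical aberration in mm.
#' @param amplitude_contrast Amplitude contrast fraction in \[0, 1\].
#' @param pixel_size Pixel size in Angstrom.
#' @return A `ctf_params` object.
#' @export
ctf_params <- function(defocus_1, defocus_2 = defocus_1, astig_angle = 0,
                       voltage = 300, cs = 2.7, amplitude_contrast = 0.07,
                       pixel_size = 1.5) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (amplitude_contrast < 0 || amplitude_contrast > 1)
    stop("amplitude_contrast must be between 0 and 1")
  if (defocus_2 > defocus_1) {
    tmp <- defocus_1; defocus_1 <- defocus_2; defocus_2 <- tmp
    astig_angle <- astig_angle + 90
  }
  structure(list(defocus_1 = defocus_1, defocus_2 = defocus_2,
                 astig_angle = astig_angle %% 180, voltage = voltage,
                 cs = cs, amplitude_contrast = amplitude_contrast,
                 pixel_size = pixel_size),
            class = "ctf_params")
}

#' Electron wavelength
#' @param voltage Acceleration voltage in kV.
#' @return Relativistic electron wavelength in Angstrom (0.0197 at 300 kV).
#' @export
electron_wavelength <- function(voltage = 300) {
  v <- voltage * 1000
  12.2639 / sqrt(v + 0.97845e-6 * v^2)
}

#' Evaluate the contrast transfer function
#'
#' `CTF(s) = -(sqrt(1 - w^2) sin(chi) + w cos(chi))` with aberration phase
#' `chi = pi lambda z s^2 - (pi / 2) Cs lambda^3 s^4`, z the (possibly
#' astigmatic) defocus in Angstrom and w the amplitude contrast.
#'
#' @param s Spatial frequency magnitude in 1/Angstrom (vector or matrix).
#' @param ctf A `ctf_params`.
#' @param theta Azimuth of the frequency vector in radians (for astigmatism);
#'   default 0.
#' @param defocus_offset_nm Additional defocus in nm added to both axes.
#' @return CTF values, same shape as `s`.
#' @export
ctf_value <- function(s, ctf, theta = 0, defocus_offset_nm = 0) {
  lambda <- electron_wavelength(ctf$voltage)
  z_avg <- (ctf$defocus_1 + ctf$defocus_2) / 2 * 1e4 + defocus_offset_nm * 10
  z_dif <- (ctf$defocus_1 - ctf$defocus_2) / 2 * 1e4
  ang <- ctf$astig_angle * pi / 180
  z <- z_avg + z_dif * cos(2 * (theta - ang))
  cs_A <- ctf$cs * 1e7
  chi <- pi * lambda * z * s^2 - (pi / 2) * cs_A * lambda^3 * s^4
  w <- ctf$amplitude_contrast
  -(sqrt(1 - w^2) * sin(chi) + w * cos(chi))
}

#' Compute the illumination mask of a condensed-beam tile
#'
#' Lowpass filters the image at `lowpass_cutoff`, thresholds at
#' `threshold_fraction` of the maximum, and lowpass filters the thresholded
#' mask again at the same cutoff to smooth its edges.
#'
#' @param image Tile image (matrix).
#' @param pixel_size Pixel size in Angstrom.
#' @param lowpass_cutoff Resolution cutoff in Angstrom (default 100).
#' @param threshold_fraction Fraction of the maximum (default 0.1).
#' @return An `illumination_mask`: `weights` (smooth, in \[0, 1\]), `binary`
#'   (`weights > 0.5`), `area_px`.
#' @export
illumination_mask <- function(image, pixel_size, lowpass_cutoff = 100,
                              threshold_fraction = 0.1) {
  if (all(image == image[1])) {
    if (image[1] > 0) {
      w <- matrix(1, nrow(image), ncol(image))
      return(structure(list(weights = w, binary = w > 0.5,
                            area_px = length(w)),
                       class = "illumination_mask"))
    }
    stop("cannot compute an illumination mask of a constant non-positive image")
  }
  lp <- lowpass_filter(image, pixel_size, lowpass_cutoff)
  thr <- (lp >= threshold_fraction * max(lp)) * 1
  if (all(thr == 0)) stop("illumination mask is empty")
  w <- lowpass_filter(thr, pixel_size, lowpass_cutoff)
  w <- pmin(pmax(w, 0), 1)  # w first: pmin/pmax keep the first arg's dim
  binary <- w > 0.5
  structure(list(weights = w, binary = binary, area_px = sum(binary)),
            class = "illumination_mask")
}

#' Replace unilluminated pixels with matched Gaussian noise
#'
#' Pixels outside the illumination mask are replaced by i.i.d. Gaussian
#' draws with the sample mean and standard deviation of the illuminated
#' area; pixels inside the mask are untouched. This removes the sharp beam
#' edge that would otherwise dominate cross-correlations.
#'
#' @param image Tile image.
#' @param mask An `illumination_mask`.
#' @param seed Integer seed (deterministic fill).
#' @return Image with the dark area filled.
#' @export
fill_dark_with_noise <- function(image, mask, seed) {
  inside <- mask$binary
  if (!any(inside)) stop("empty illumination mask")
  if (all(inside)) return(image)
  m <- mean(image[inside]); s <- stats::sd(image[inside])
  n_out <- sum(!inside)
  image[!inside] <- with_seed(seed, stats::rnorm(n_out, m, s))
  image
}

#' Align movie frames using only the camera center
#'
#' Estimates per-frame translations by cross-correlating a centered crop
#' (default half the side length per axis, i.e. a quarter of the area)
#' of each frame against the first frame, then shifts the full frames and
#' sums them. Restricting the estimation to the center avoids the beam
#' edges, which do not move with the sample and would otherwise anchor the
#' alignment.
#'
#' @param movie 3D array `[row, col, frame]` with >= 2 frames.
#' @param central_fraction Fraction of each side used for estimation.
#' @return List with `shifts` (frames x 2, columns `dx, dy`, first frame
#'   zero) and `sum` (aligned sum).
#' @export
align_frames_central <- function(movie, central_fraction = 0.5) {
  d <- dim(movie)
  if (length(d) != 3 || d[3] < 2) stop("movie must have >= 2 frames")
  cr <- floor(d[1] * central_fraction); cc <- floor(d[2] * central_fraction)
  if (cr < 64 || cc < 64) stop("central crop smaller than 64 px")
  r0 <- floor((d[1] - cr) / 2); c0 <- floor((d[2] - cc) / 2)
  rows <- r0 + seq_len(cr); cols <- c0 + seq_len(cc)
  ref <- movie[rows, cols, 1]
  ref <- ref - mean(ref)
  fref <- fft2(ref)
  shifts <- matrix(0, d[3], 2, dimnames = list(NULL, c("dx", "dy")))
  total <- movie[, , 1]
  for (f in 2:d[3]) {
    cur <- movie[rows, cols, f]
    cur <- cur - mean(cur)
    cc_map <- Re(ifft2(fft2(cur) * Conj(fref)))
    pk <- which_max2(cc_map)
    pk_sub <- subpixel_peak(cc_map, pk)
    dyx <- pk_sub - 1
    dyx <- ifelse(dyx > c(cr, cc) / 2, dyx - c(cr, cc), dyx)
    # cc peak at d means frame = ref shifted by +d; undo it
    shifts[f, ] <- c(dyx[2], dyx[1])
    total <- total + fourier_shift(movie[, , f], -dyx[1], -dyx[2])
  }
  list(shifts = shifts, sum = total)
}

# critical exposure (e-/A^2) at spatial frequency k (1/A)
critical_exposure <- function(k) {
  0.24499 * k^(-1.6649) + 2.8141
}

#' Exposure-filtered sum of movie frames
#'
#' Weights each frame's Fourier amplitudes by
#' `exp(-cumulative_dose / (2 * Nc(k)))` with the empirical critical
#' exposure `Nc(k) = 0.24499 k^-1.6649 + 2.8141` (k in 1/Angstrom, Nc in
#' e-/Angstrom^2), attenuating high frequencies in late, radiation-damaged
#' frames. The zero-frequency gain equals the frame count.
#'
#' @param movie 3D array `[row, col, frame]`.
#' @param dose_per_frame Dose per frame in e-/Angstrom^2 (>= 0).
#' @param pixel_size Pixel size in Angstrom.
#' @return Filtered sum (matrix).
#' @export
dose_filter <- function(movie, dose_per_frame, pixel_size) {
  if (dose_per_frame < 0) stop("dose_per_frame must be >= 0")
  d <- dim(movie)
  if (length(d) == 2) movie <- array(movie, c(d, 1))
  d <- dim(movie)
  if (dose_per_frame == 0) return(apply(movie, c(1, 2), sum))
  g <- freq_grid(d[1], d[2], pixel_size)
  nc <- critical_exposure(pmax(g$s, 1e-10))
  acc <- matrix(0 + 0i, d[1], d[2])
  for (f in seq_len(d[3])) {
    w <- exp(-(f * dose_per_frame) / (2 * nc))
    w[1, 1] <- 1   # zero frequency untouched
    acc <- acc + fft2(movie[, , f]) * w
  }
  Re(ifft2(acc))
}

#' Resample an image to a target pixel size by Fourier cropping/padding
#'
#' The output side lengths are `round(n * pixel_size / target)` rounded to
#' even numbers; the mean intensity is preserved.
#'
#' @param image Input image.
#' @param pixel_size Source pixel size in Angstrom.
#' @param target Target pixel size in Angstrom (default 1.5).
#' @return List `image`, `pixel_size` (the realized pixel size,
#'   `n * pixel_size / n_new` per axis stored as the x-axis value).
#' @export
resample_to_pixel_size <- function(image, pixel_size, target = 1.5) {
  if (target <= 0) stop("target pixel size must be > 0")
  d <- dim(image)
  newd <- resampled_dims(d, pixel_size, target)
  if (all(newd == d))
    return(list(image = image, pixel_size = pixel_size))
  ft <- fftshift2(fft2(image))
  out <- matrix(0 + 0i, newd[1], newd[2])
  keep <- pmin(d, newd)
  src_r <- floor(d[1] / 2) + 1L + seq(-floor(keep[1] / 2), ceiling(keep[1] / 2) - 1L)
  src_c <- floor(d[2] / 2) + 1L + seq(-floor(keep[2] / 2), ceiling(keep[2] / 2) - 1L)
  dst_r <- floor(newd[1] / 2) + 1L + seq(-floor(keep[1] / 2), ceiling(keep[1] / 2) - 1L)
  dst_c <- floor(newd[2] / 2) + 1L + seq(-floor(keep[2] / 2), ceiling(keep[2] / 2) - 1L)
  out[dst_r, dst_c] <- ft[src_r, src_c]
  out <- fftshift2(out)
  img <- Re(ifft2(out)) * prod(newd) / prod(d)
  list(image = img, pixel_size = pixel_size * d[2] / newd[2])
}

#' Output dimensions of Fourier resampling
#' @param dims Integer vector of input side lengths.
#' @param pixel_size Source pixel size (Angstrom).
#' @param target Target pixel size (Angstrom).
#' @return Even integer side lengths after resampling.
#' @export
resampled_dims <- function(dims, pixel_size, target) {
  n <- dims * pixel_size / target
  pmax(2L, 2L * as.integer(round(n / 2)))
}

#' Estimate the CTF from a tile image
#'
#' Grid search over defocus maximizing the correlation between the
#' (high-pass detrended) rotationally averaged power spectrum and a CTF^2
#' model, with optional 2D astigmatic refinement.
#'
#' @param image Tile image (illumination-masked / noise-filled).
#' @param pixel_size Pixel size in Angstrom.
#' @param search Defocus search range in microns (default 0.2--2).
#' @param step Grid step in microns.
#' @param astig Refine defocus_1/defocus_2/angle in 2D?
#' @param voltage,cs,amplitude_contrast Microscope parameters.
#' @return A `ctf_params` with extra fields `cc` (fit correlation) and
#'   `low_confidence` (poor or boundary fit; a featureless spectrum flags
#'   rather than errors).
#' @export
estimate_ctf <- function(image, pixel_size, search = c(0.2, 2.0),
                         step = 0.01, astig = FALSE, voltage = 300,
                         cs = 2.7, amplitude_contrast = 0.07) {
  d <- dim(image)
  ps <- Mod(fft2(image - mean(image)))^2
  g <- freq_grid(d[1], d[2], pixel_size)
  nyq <- 0.5 / pixel_size
  smin <- max(0.03, 0.06 * nyq); smax <- 0.9 * nyq
  sel <- g$s > smin & g$s < smax
  nb <- 160
  ra <- radial_average(ps[sel], g$s[sel], nbins = nb)
  detrend <- function(v) {
    k <- max(5, round(length(v) / 10))
    base <- stats::filter(v, rep(1 / k, k), sides = 2)
    base[is.na(base)] <- stats::median(v)
    v - as.numeric(base)
  }
  obs <- detrend(ra$mean)
  defs <- seq(search[1], search[2], by = step)
  score <- vapply(defs, function(z) {
    model <- ctf_value(ra$r, ctf_params(z, z, 0, voltage, cs,
                                        amplitude_contrast, pixel_size))^2
    suppressWarnings(stats::cor(obs, detrend(model)))
  }, numeric(1))
  score[is.na(score)] <- -Inf
  best <- which.max(score)
  low_conf <- !is.finite(score[best]) || score[best] < 0.15 ||
    best == 1L || best == length(defs)
  z_hat <- defs[best]
  out <- ctf_params(z_hat, z_hat, 0, voltage, cs, amplitude_contrast,
                    pixel_size)
  out$cc <- score[best]
  if (astig && !low_conf) {
    theta <- atan2(g$sy, g$sx)
    sel2 <- sel
    obs2 <- ps[sel2]
    obs2 <- obs2 - mean(obs2)
    objective <- function(p) {
      cp <- ctf_params(p[1], p[2], p[3], voltage, cs, amplitude_contrast,
                       pixel_size)
      model <- ctf_value(g$s[sel2], cp, theta[sel2])^2
      -suppressWarnings(stats::cor(obs2, model - mean(model)))
    }
    fit <- stats::optim(c(z_hat, z_hat, 0), objective,
                        method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-8))
    cp <- ctf_params(fit$par[1], fit$par[2], fit$par[3], voltage, cs,
                     amplitude_contrast, pixel_size)
    cp$cc <- -fit$value
    cp$low_confidence <- low_conf
    return(cp)
  }
  out$low_confidence <- low_conf
  out
}

#' Beer-Lambert ice-thickness estimate for a tile
#'
#' `thickness = coefficient * ln(I0 / I)` with I the mean intensity inside
#' the illumination mask and I0 the vacuum (unattenuated) intensity. The
#' default coefficient of 322 nm is the empirical inelastic scattering
#' length of vitreous ice for a 300 kV energy-filtered setup.
#'
#' @param image Tile image.
#' @param mask An `illumination_mask`.
#' @param vacuum_intensity Vacuum reference intensity (> 0).
#' @param coefficient Apparent mean free path in nm (default 322).
#' @return Thickness in nm.
#' @export
estimate_thickness <- function(image, mask, vacuum_intensity,
                               coefficient = 322) {
  if (vacuum_intensity <= 0) stop("vacuum_intensity must be > 0")
  m <- mean(image[mask$binary])
  if (!is.finite(m) || m <= 0) stop("mean masked intensity must be > 0")
  coefficient * log(vacuum_intensity / m)
}

#' Gaussian filter constant equivalent to a B-factor
#'
#' The B-factor envelope `exp(-B s^2 / 4)` equals a Gaussian lowpass
#' `exp(-(a s)^2 / 2)` with `a = sqrt(B / 2)`; a B-factor of 120 Angstrom^2
#' corresponds to a filter constant of 7.7 Angstrom.
#'
#' @param b_factor B-factor in Angstrom^2 (>= 0).
#' @return Filter constant in Angstrom.
#' @export
bfactor_to_gaussian_constant <- function(b_factor) {
  if (b_factor < 0) stop("b_factor must be >= 0")
  sqrt(b_factor / 2)
}

#' Template B-factor from the atomic-model median
#'
#' The search template is sharpened or smoothed by scaling the median
#' atomic B-factor of the deposited model by an empirical multiplier before
#' the density map is generated (the workflow default boosts a median of
#' 80 Angstrom^2 by 1.5 to 120 Angstrom^2).
#'
#' @param median_atomic_b Median atomic B-factor (Angstrom^2).
#' @param multiplier Empirical scale factor (default 1.5).
#' @return Template B-factor in Angstrom^2.
#' @export
template_b_factor <- function(median_atomic_b, multiplier = 1.5) {
  if (median_atomic_b < 0 || multiplier < 0) stop("inputs must be >= 0")
  median_atomic_b * multiplier
}
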