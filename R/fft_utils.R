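# Internal Fourier helpers shared by the preprocessing, matching and montage
# code. Images are plain numeric matrices indexed [row, col]; user-facing
# pixel coordinates are 0-based with x = column and y = row (y down).

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# cycles per pixel, FFT layout (0, 1/n, ..., -1/n)
fft_freqs <- function(n) {
  k <- c(0:(ceiling(n / 2) - 1L), -(floor(n / 2):1))
  k / n
}

# spatial-frequency magnitude grid in 1/Angstrom, FFT layout
freq_grid <- function(nr, nc, pixel_size) {
  fy <- fft_freqs(nr) / pixel_size
  fx <- fft_freqs(nc) / pixel_size
  sy <- matrix(fy, nr, nc)
  sx <- matrix(fx, nr, nc, byrow = TRUE)
  list(sx = sx, sy = sy, s = sqrt(sx^2 + sy^2))
}

fftshift2 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  x[c((floor(nr / 2) + 1L):nr, 1:floor(nr / 2)),
    c((floor(nc / 2) + 1L):nc, 1:floor(nc / 2))]
}

# circularly shift so that element at (r0, c0) (1-based) moves to (1, 1)
circ_to_origin <- function(x, r0, c0) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- ((seq_len(nr) - 1L + r0 - 1L) %% nr) + 1L
  ci <- ((seq_len(nc) - 1L + c0 - 1L) %% nc) + 1L
  x[ri, ci, drop = FALSE]
}

# translate image by (dy, dx) pixels (can be fractional) via Fourier phase ramp
fourier_shift <- function(image, dy, dx) {
  nr <- nrow(image); nc <- ncol(image)
  fy <- fft_freqs(nr); fx <- fft_freqs(nc)
  ph <- exp(-2i * pi * (outer(fy * dy, rep(1, nc)) + outer(rep(1, nr), fx * dx)))
  Re(ifft2(fft2(image) * ph))
}

# smooth Fourier lowpass with a cosine edge around the cutoff (in Angstrom)
lowpass_filter <- function(image, pixel_size, cutoff, edge_width = 0.25) {
  g <- freq_grid(nrow(image), ncol(image), pixel_size)
  sc <- 1 / cutoff
  w <- sc * edge_width
  filt <- ifelse(g$s <= sc - w, 1,
                 ifelse(g$s >= sc + w, 0,
                        0.5 * (1 + cos(pi * (g$s - (sc - w)) / (2 * w)))))
  Re(ifft2(fft2(image) * filt))
}

# rotationally averaged profile of `values` over radius bins; returns bin
# centers and means. `radius` must have the same shape as `values`.
radial_average <- function(values, radius, nbins = NULL) {
  r <- as.vector(radius); v <- as.vector(values)
  if (is.null(nbins)) nbins <- floor(min(dim(values)) / 2)
  rmax <- max(r)
  idx <- pmin(nbins, pmax(1L, as.integer(ceiling(r / rmax * nbins))))
  idx[r == 0] <- 1L
  present <- sort(unique(idx))
  list(r = (present - 0.5) / nbins * rmax,
       mean = as.numeric(tapply(v, factor(idx, levels = present), mean)))
}

# raw circular cross-correlation map: cc[d] = sum_p a(p + d) * b(p)
cross_correlate <- function(a, b) {
  Re(ifft2(fft2(a) * Conj(fft2(b))))
}

# 1-based (row, col) of matrix maximum
which_max2 <- function(x) {
  i <- which.max(x)
  c(((i - 1L) %% nrow(x)) + 1L, ((i - 1L) %/% nrow(x)) + 1L)
}

# quadratic sub-pixel refinement around a peak (1-based integer location);
# returns c(row, col) with fractional offsets clamped to [-0.5, 0.5]
subpixel_peak <- function(x, peak) {
  ref <- function(m, z, p) {
    if (p <= 1 || p >= m) return(0)
    num <- 0.5 * (z[p - 1] - z[p + 1])
    den <- z[p - 1] - 2 * z[p] + z[p + 1]
    if (den == 0) return(0)
    max(-0.5, min(0.5, num / den))
  }
  dr <- ref(nrow(x), x[, peak[2]], peak[1])
  dc <- ref(ncol(x), x[peak[1], ], peak[2])
  c(peak[1] + dr, peak[2] + dc)
}

# embed a small matrix into an nr x nc frame with its center at the frame
# center (1-based center convention: floor(n/2) + 1)
pad_center <- function(small, nr, nc, fill = 0) {
  out <- matrix(fill, nr, nc)
  sr <- nrow(small); sc <- ncol(small)
  r0 <- floor(nr / 2) + 1L - floor(sr / 2) - 1L
  c0 <- floor(nc / 2) + 1L - floor(sc / 2) - 1L
  out[r0 + seq_len(sr), c0 + seq_len(sc)] <- small
  out
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must be finite", call. = FALSE)
}
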