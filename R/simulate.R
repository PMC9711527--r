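# Synthetic lamella scenes and tile exposures. These generators provide the
# statistical structure the rest of the pipeline assumes -- a polygonal
# lamella with a thickness map, planted rigid-body targets, an affine defocus
# field, a circular beam vignette with optional edge fringes, multiplicative
# camera shading and additive Gaussian noise -- so that every downstream
# stage can be exercised and validated without external data.

# run expr with a fixed RNG state, restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic template volume from Gaussian pseudo-atoms
#'
#' Builds a cubic density map from `n_blobs` randomly placed Gaussian blobs,
#' playing the role of a macromolecular search template (in real use the
#' template is simulated from an atomic model). The density is non-negative
#' and strictly confined to a central sphere of diameter `0.8 * box_size`
#' pixels, so projections fit comfortably inside the box at any orientation.
#'
#' @param box_size Cube side in pixels (>= 32).
#' @param pixel_size Pixel size in Angstrom.
#' @param n_blobs Number of Gaussian pseudo-atoms (>= 1).
#' @param seed Integer seed; the volume is deterministic given the seed.
#' @param b_factor Isotropic B-factor (Angstrom^2) carried as metadata and
#'   applied when projections are CTF-filtered.
#' @param blob_sigma Range (min, max) of pseudo-atom widths in pixels.
#'   Sharp scatterers make projections of distinct orientations decorrelate
#'   the way atomic-model projections do, which the extreme-value detection
#'   threshold assumes.
#' @param blob_spread Radius of the ball holding the pseudo-atom centers,
#'   as a fraction of the box (max 0.35). Together with `blob_sigma` this
#'   sets the template's angular correlation length (roughly
#'   `blob_sigma / (blob_spread * box_size)` radians): the orientation grid
#'   step should not exceed it.
#' @return A `template_volume`: list with `density` (box^3 array),
#'   `pixel_size`, `b_factor`.
#' @export
make_template_volume <- function(box_size, pixel_size, n_blobs, seed,
                                 b_factor = 0, blob_sigma = c(0.7, 1.1),
                                 blob_spread = 0.3) {
  if (box_size < 32) stop("box_size must be >= 32")
  if (n_blobs < 1) stop("n_blobs must be >= 1")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (b_factor < 0) stop("b_factor must be >= 0")
  if (blob_spread <= 0 || blob_spread > 0.35)
    stop("blob_spread must be in (0, 0.35]")
  with_seed(seed, {
    ctr <- (box_size + 1) / 2
    # pseudo-atom centers inside a ball of radius blob_spread * box: blob
    # tails stay inside the 0.4 * box support radius
    rmax <- blob_spread * box_size
    u <- matrix(stats::rnorm(3 * n_blobs), ncol = 3)
    u <- u / pmax(sqrt(rowSums(u^2)), 1e-12)
    rad <- rmax * stats::runif(n_blobs)^(1 / 3)
    centers <- u * rad
    sig <- stats::runif(n_blobs, blob_sigma[1], blob_sigma[2])
    amp <- stats::runif(n_blobs, 0.5, 2.0)
    ax <- seq_len(box_size) - ctr
    density <- array(0, dim = rep(box_size, 3))
    gx <- gy <- gz <- NULL
    for (b in seq_len(n_blobs)) {
      ex <- exp(-(ax - centers[b, 1])^2 / (2 * sig[b]^2))
      ey <- exp(-(ax - centers[b, 2])^2 / (2 * sig[b]^2))
      ez <- exp(-(ax - centers[b, 3])^2 / (2 * sig[b]^2))
      density <- density + amp[b] * (ex %o% ey %o% ez)
    }
    r2 <- ax^2 %o% rep(1, box_size) %o% rep(1, box_size) +
      rep(1, box_size) %o% ax^2 %o% rep(1, box_size) +
      rep(1, box_size) %o% rep(1, box_size) %o% ax^2
    density[sqrt(r2) > 0.4 * box_size] <- 0
    structure(list(density = density, pixel_size = pixel_size,
                   b_factor = b_factor),
              class = "template_volume")
  })
}

# even-odd rule point-in-polygon test; poly is an n x 2 matrix
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi + (yj == yi) * 1e-300) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

scene_thickness <- function(scene, x, y) {
  th <- scene$thickness
  base <- th[1] + th[2] * x + th[3] * y
  tex <- scene$texture
  if (!is.null(tex)) {
    v <- numeric(length(x))
    for (m in seq_along(tex$kx)) {
      v <- v + cos(tex$kx[m] * x + tex$ky[m] * y + tex$phase[m])
    }
    base <- base + tex$amp * v
  }
  pmax(0, base)
}

# stationary Gaussian-like random field (sum of random cosine waves) with a
# Gaussian autocorrelation of length corr_nm, emulating lamella surface
# roughness; exactly evaluable at any scene coordinate
make_thickness_texture <- function(sd_nm, corr_nm, seed, n_waves = 256) {
  with_seed(seed, {
    list(kx = stats::rnorm(n_waves, 0, 1 / corr_nm),
         ky = stats::rnorm(n_waves, 0, 1 / corr_nm),
         phase = stats::runif(n_waves, 0, 2 * pi),
         amp = sd_nm * sqrt(2 / n_waves))
  })
}

scene_defocus <- function(scene, x, y) {
  df <- scene$defocus_field
  df[1] + df[2] * x + df[3] * y
}

#' Build a synthetic lamella scene with planted target instances
#'
#' Target instances are placed by a homogeneous Poisson process inside the
#' lamella polygon, excluded from configured organelle sub-polygons
#' (emulating compartments such as the nucleus or mitochondria that contain
#' no cytoplasmic targets), with z uniform through the local ice thickness
#' and uniformly random orientations.
#'
#' @param config List with elements:
#'   * `lamella_polygon`: n x 2 matrix of vertices (nm);
#'   * `thickness_nm`: either a single base thickness or `c(base, gx, gy)`
#'     for an affine thickness map (nm, nm/nm);
#'   * `instance_density_um2`: expected instances per square micron;
#'   * `organelles`: optional list of exclusion polygons (nm);
#'   * `defocus_field_nm`: `c(intercept, gx, gy)` affine true-defocus offset
#'     over the stage plane (nm, nm/nm); default `c(0, 0, 0)`;
#'   * `thickness_texture_sd_nm`, `thickness_texture_corr_nm`: amplitude and
#'     correlation length of a smooth random roughness component added to
#'     the thickness map (defaults 35 nm and 5 nm; 0 disables). Through
#'     Beer-Lambert attenuation this produces the low-contrast specimen
#'     texture that tile-to-tile registration relies on;
#'   * `beam_radius_nm`: illuminated radius (default 250);
#'   * `pixel_size`: camera pixel size in Angstrom (default 3).
#' @param seed Integer seed.
#' @return A `ground_truth_scene` with the instance table
#'   (`x_nm, y_nm, z_nm, phi, theta, psi`).
#' @export
build_scene <- function(config, seed) {
  poly <- as.matrix(config$lamella_polygon)
  if (is.null(poly) || nrow(poly) < 3) stop("lamella polygon needs >= 3 vertices")
  stopifnot_finite(poly, "lamella polygon")
  th <- config$thickness_nm
  if (is.null(th)) th <- 150
  if (length(th) == 1) th <- c(th, 0, 0)
  dens <- config$instance_density_um2
  if (is.null(dens)) dens <- 0
  if (dens < 0) stop("instance density must be >= 0")
  defocus_field <- config$defocus_field_nm
  if (is.null(defocus_field)) defocus_field <- c(0, 0, 0)
  organelles <- config$organelles
  scene <- structure(list(
    lamella_polygon = poly,
    thickness = th,
    defocus_field = defocus_field,
    beam_radius_nm = if (is.null(config$beam_radius_nm)) 250 else config$beam_radius_nm,
    pixel_size = if (is.null(config$pixel_size)) 3 else config$pixel_size,
    organelles = organelles,
    instances = NULL), class = "ground_truth_scene")
  tex_sd <- config$thickness_texture_sd_nm
  if (is.null(tex_sd)) tex_sd <- 35
  tex_corr <- config$thickness_texture_corr_nm
  if (is.null(tex_corr)) tex_corr <- 5
  if (tex_sd > 0) {
    scene$texture <- make_thickness_texture(tex_sd, tex_corr, seed + 7919)
  }

  area_um2 <- polygon_area(poly) / 1e6
  with_seed(seed, {
    n_target <- stats::rpois(1, dens * area_um2)
    xs <- ys <- numeric(0)
    bb <- apply(poly, 2, range)
    n_try <- 0
    while (length(xs) < n_target && n_try < 1000) {
      m <- max(4 * (n_target - length(xs)), 64)
      cx <- stats::runif(m, bb[1, 1], bb[2, 1])
      cy <- stats::runif(m, bb[1, 2], bb[2, 2])
      keep <- point_in_polygon(cx, cy, poly)
      if (!is.null(organelles)) {
        for (org in organelles) {
          keep <- keep & !point_in_polygon(cx, cy, as.matrix(org))
        }
      }
      xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
      n_try <- n_try + 1
    }
    if (length(xs) > n_target) {
      xs <- xs[seq_len(n_target)]; ys <- ys[seq_len(n_target)]
    }
    n <- length(xs)
    thk <- scene_thickness(scene, xs, ys)
    scene$instances <- data.frame(
      x_nm = xs, y_nm = ys,
      z_nm = stats::runif(n) * thk,
      phi = stats::runif(n, 0, 360),
      theta = acos(stats::runif(n, -1, 1)) * 180 / pi,
      psi = stats::runif(n, 0, 360))
    scene
  })
}

#' Beam illumination profile
#'
#' Circular top-hat vignette with a smooth (cosine) edge and, optionally,
#' damped cosine fringes near the rim, emulating the edge ripples of a
#' condensed beam focused at the eucentric plane.
#'
#' @param radius_nm Illuminated radius in nm.
#' @param fringes Add edge fringes?
#' @param fringe_amplitude Fringe modulation amplitude (fraction, < 1).
#' @param fringe_period_nm Fringe period in nm.
#' @return A `beam_profile` parameter object.
#' @export
beam_profile <- function(radius_nm, fringes = FALSE, fringe_amplitude = 0.1,
                         fringe_period_nm = 10) {
  if (fringe_amplitude < 0 || fringe_amplitude >= 1)
    stop("fringe_amplitude must be in [0, 1)")
  structure(list(radius_nm = radius_nm, fringes = fringes,
                 fringe_amplitude = fringe_amplitude,
                 fringe_period_nm = fringe_period_nm),
            class = "beam_profile")
}

# evaluate beam profile over a camera grid; center in 1-based px (row, col)
beam_profile_image <- function(beam, shape, pixel_size, center_px = NULL) {
  px_nm <- pixel_size / 10
  if (is.null(center_px)) center_px <- (shape + 1) / 2
  yy <- (seq_len(shape[1]) - center_px[1]) * px_nm
  xx <- (seq_len(shape[2]) - center_px[2]) * px_nm
  r <- sqrt(outer(yy^2, rep(1, shape[2])) + outer(rep(1, shape[1]), xx^2))
  R <- beam$radius_nm
  edge <- 0.02 * R
  prof <- ifelse(r <= R - edge, 1,
                 ifelse(r >= R + edge, 0,
                        0.5 * (1 + cos(pi * (r - (R - edge)) / (2 * edge)))))
  if (isTRUE(beam$fringes)) {
    # ripples confined to the outer 5% of the disk, damped inward
    band <- 0.05 * R
    damp <- exp(-pmax(R - r, 0) / band)
    mod <- beam$fringe_amplitude * cos(2 * pi * (r - R) / beam$fringe_period_nm)
    prof <- prof * (1 + mod * damp * (r <= R))
  }
  prof
}

#' Camera model with multiplicative shading and Gaussian read noise
#'
#' @param shape `c(rows, cols)` in pixels (each >= 64).
#' @param pixel_size Pixel size in Angstrom.
#' @param noise_sigma Additive Gaussian noise sd (counts).
#' @param shading `"flat"` or `"annulus"` (a brighter ring near the periphery
#'   of the illuminated area, the static background artifact seen in tile
#'   averages); alternatively a full matrix of multiplicative gains.
#' @param shading_amplitude Relative amplitude of the annulus.
#' @param beam_radius_nm Radius used to place the annulus (needed for
#'   `"annulus"` shading).
#' @return A `camera_model`.
#' @export
camera_model <- function(shape, pixel_size, noise_sigma = 1,
                         shading = "flat", shading_amplitude = 0.08,
                         beam_radius_nm = 250) {
  if (any(shape < 64)) stop("camera shape must be at least 64 x 64")
  if (is.matrix(shading)) {
    gain <- shading
    if (any(gain <= 0)) stop("shading must be strictly positive")
  } else if (shading == "flat") {
    gain <- matrix(1, shape[1], shape[2])
  } else if (shading == "annulus") {
    px_nm <- pixel_size / 10
    ctr <- (shape + 1) / 2
    yy <- (seq_len(shape[1]) - ctr[1]) * px_nm
    xx <- (seq_len(shape[2]) - ctr[2]) * px_nm
    r <- sqrt(outer(yy^2, rep(1, shape[2])) + outer(rep(1, shape[1]), xx^2))
    gain <- 1 + shading_amplitude *
      exp(-(r - 0.85 * beam_radius_nm)^2 / (2 * (0.1 * beam_radius_nm)^2))
  } else stop("unknown shading model")
  structure(list(shape = shape, pixel_size = pixel_size,
                 noise_sigma = noise_sigma, shading = gain),
            class = "camera_model")
}

#' Render one synthetic tile exposure
#'
#' Projects every planted instance whose xy position falls inside the beam
#' disk, filters each projection by the CTF at the instance's local defocus
#' (tile defocus plus depth z), scales the background by Beer-Lambert
#' attenuation through the local ice thickness, applies the beam vignette and
#' camera shading, and adds Gaussian noise. Returns the tile image together
#' with a ground-truth table of the planted pixel positions.
#'
#' @param scene A `ground_truth_scene`.
#' @param template A `template_volume`.
#' @param beam_center_nm Scene coordinates (nm) the beam is pointed at.
#' @param beam A `beam_profile`.
#' @param camera A `camera_model`.
#' @param ctf A `ctf_params` object (see [ctf_params()]); its defocus is the
#'   tile defocus at the ice center.
#' @param seed Integer seed for the noise.
#' @param base_intensity Unattenuated (vacuum) mean intensity in counts.
#' @param signal_scale Amplitude multiplier for planted projections.
#' @return List with `image` (matrix), `truth` (data.frame: `x_px, y_px`
#'   0-based, `z_nm, phi, theta, psi, defocus_nm`), and `vacuum_intensity`.
#' @export
render_tile <- function(scene, template, beam_center_nm, beam, camera, ctf,
                        seed, base_intensity = 100, signal_scale = 1) {
  shape <- camera$shape
  px_nm <- camera$pixel_size / 10
  fov_nm <- shape * px_nm
  ctr <- (shape + 1) / 2
  if (beam$radius_nm > min(ctr - 1) * px_nm)
    stop("beam disk does not fit completely on the camera")

  # background: vacuum intensity attenuated by local ice thickness
  ys <- beam_center_nm[2] + (seq_len(shape[1]) - ctr[1]) * px_nm
  xs <- beam_center_nm[1] + (seq_len(shape[2]) - ctr[2]) * px_nm
  inside <- point_in_polygon(
    rep(xs, each = shape[1]), rep(ys, times = shape[2]),
    scene$lamella_polygon)
  thk <- scene_thickness(scene, rep(xs, each = shape[1]), rep(ys, times = shape[2]))
  thk[!inside] <- 0
  background <- base_intensity * exp(-matrix(thk, shape[1], shape[2]) / 322)

  img <- background
  inst <- scene$instances
  truth <- data.frame(x_px = numeric(0), y_px = numeric(0), z_nm = numeric(0),
                      phi = numeric(0), theta = numeric(0), psi = numeric(0),
                      defocus_nm = numeric(0))
  tile_defocus_nm <- mean(c(ctf$defocus_1, ctf$defocus_2)) * 1000
  if (!is.null(inst) && nrow(inst) > 0) {
    d <- sqrt((inst$x_nm - beam_center_nm[1])^2 +
              (inst$y_nm - beam_center_nm[2])^2)
    sel <- which(d < beam$radius_nm)
    for (k in sel) {
      col_px <- round((inst$x_nm[k] - beam_center_nm[1]) / px_nm + ctr[2])
      row_px <- round((inst$y_nm[k] - beam_center_nm[2]) / px_nm + ctr[1])
      def_nm <- tile_defocus_nm + inst$z_nm[k]
      proj <- project_template(template,
                               c(inst$phi[k], inst$theta[k], inst$psi[k]))
      ctf_k <- ctf
      ctf_k$defocus_1 <- ctf_k$defocus_2 <- def_nm / 1000
      ctf_k$pixel_size <- camera$pixel_size
      filt <- apply_ctf_and_bfactor(proj, ctf_k, 0, template$b_factor)
      b <- nrow(filt)
      r0 <- row_px - floor(b / 2); c0 <- col_px - floor(b / 2)
      rr <- seq_len(b) + r0 - 1L; cc <- seq_len(b) + c0 - 1L
      ok_r <- rr >= 1 & rr <= shape[1]; ok_c <- cc >= 1 & cc <= shape[2]
      img[rr[ok_r], cc[ok_c]] <- img[rr[ok_r], cc[ok_c]] +
        signal_scale * filt[ok_r, ok_c]
      truth <- rbind(truth, data.frame(
        x_px = col_px - 1, y_px = row_px - 1, z_nm = inst$z_nm[k],
        phi = inst$phi[k], theta = inst$theta[k], psi = inst$psi[k],
        defocus_nm = def_nm))
    }
  }
  prof <- beam_profile_image(beam, shape, camera$pixel_size)
  img <- img * prof * camera$shading
  if (camera$noise_sigma > 0) {
    img <- img + with_seed(seed, matrix(
      stats::rnorm(prod(shape), 0, camera$noise_sigma), shape[1], shape[2]))
  }
  list(image = img, truth = truth, vacuum_intensity = base_intensity,
       beam_center_nm = beam_center_nm)
}

#' Write a tile ground-truth table as TSV
#'
#' @param truth Data frame as returned in `render_tile()$truth` with an added
#'   `tile_id` column (added here if missing, using `tile_id`).
#' @param path Output file.
#' @param tile_id Tile id used when the table has no `tile_id` column.
#' @export
write_truth_tsv <- function(truth, path, tile_id = 0L) {
  if (is.null(truth$tile_id)) truth <- cbind(tile_id = tile_id, truth)
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
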