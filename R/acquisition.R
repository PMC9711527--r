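# Acquisition planning: four annotated lamella corners are turned into a
# serpentine hexagonal grid of beam-image-shift positions; per-exposure
# defocus feedback and beam-centering corrections are modelled so a full
# collection can be simulated.

# minimum distance from point (x, y) to a polygon (0 if inside)
dist_to_polygon <- function(x, y, poly) {
  if (nrow(poly) >= 3 && point_in_polygon(x, y, poly)[1]) return(0)
  n <- nrow(poly)
  dmin <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[j, 1]; by <- poly[j, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) 0 else max(0, min(1, ((x - ax) * vx + (y - ay) * vy) / L2))
    dmin <- min(dmin, sqrt((x - ax - t * vx)^2 + (y - ay - t * vy)^2))
  }
  dmin
}

#' Plan a serpentine hexagonal grid of beam-image-shift positions
#'
#' Computes a hexagonal lattice covering the quadrilateral spanned by four
#' annotated lamella corners, with in-row spacing `sqrt(3) * overlap_factor
#' * r` and row spacing `1.5 * overlap_factor * r` (alternate rows offset by
#' half the in-row spacing), and orders the positions serpentine so that
#' every exposure is adjacent to the previous one. The first row lies on the
#' edge between the first two corners, so the initial exposure -- taken
#' before any defocus feedback has been applied -- lands on expendable area
#' (in practice the platinum deposition edge).
#'
#' @param corners 4 x 2 matrix of corner positions in beam-image-shift
#'   microns. A degenerate quadrilateral (repeated corners) is allowed.
#' @param r Illuminated beam radius in nm (e.g. 250 for fringe-free, 230 for
#'   eucentric focus).
#' @param overlap_factor Spacing shrink factor in (0, 1]; 0.95 gives ~5%
#'   linear tile overlap.
#' @param mode `"fringe_free"` or `"eucentric"` (metadata only).
#' @return An `acquisition_plan`: data frame `positions` (`index, bis_x_um,
#'   bis_y_um, row, order`), plus `beam_radius_nm`, `overlap_factor`,
#'   `spacing_um` (in-row), `row_spacing_um`, `mode`.
#' @export
corners_to_plan <- function(corners, r, overlap_factor = 0.95,
                            mode = c("fringe_free", "eucentric")) {
  mode <- match.arg(mode)
  corners <- as.matrix(corners)
  if (!all(is.finite(corners)) || nrow(corners) != 4 || ncol(corners) != 2)
    stop("corners must be a finite 4 x 2 matrix")
  if (overlap_factor <= 0 || overlap_factor > 1)
    stop("overlap_factor must be in (0, 1]")
  r_um <- r / 1000
  a <- sqrt(3) * overlap_factor * r_um   # in-row spacing
  dy <- 1.5 * overlap_factor * r_um      # row spacing

  x0 <- corners[1, 1]; y0 <- corners[1, 2]
  bb <- apply(corners, 2, range)
  k_lo <- floor((bb[1, 2] - r_um - y0) / dy)
  k_hi <- ceiling((bb[2, 2] + r_um - y0) / dy)
  pts <- list()
  for (k in k_lo:k_hi) {
    y <- y0 + k * dy
    off <- (abs(k) %% 2) * a / 2
    j_lo <- floor((bb[1, 1] - r_um - x0 - off) / a)
    j_hi <- ceiling((bb[2, 1] + r_um - x0 - off) / a)
    xs <- x0 + off + (j_lo:j_hi) * a
    keep <- vapply(xs, function(x) dist_to_polygon(x, y, corners) <= r_um,
                   logical(1))
    if (any(keep))
      pts[[length(pts) + 1L]] <- data.frame(x = xs[keep], y = y, k = k)
  }
  if (length(pts) == 0)
    stop("no lattice position intersects the corner quadrilateral")
  grid <- do.call(rbind, pts)

  # traverse rows away from the start edge (the first corner pair)
  centroid_y <- mean(corners[, 2])
  ks <- sort(unique(grid$k), decreasing = centroid_y < y0)
  ordered <- list()
  for (i in seq_along(ks)) {
    row <- grid[grid$k == ks[i], ]
    row <- row[order(row$x, decreasing = (i %% 2 == 0)), ]
    row$row <- i
    ordered[[i]] <- row
  }
  grid <- do.call(rbind, ordered)
  positions <- data.frame(index = seq_len(nrow(grid)),
                          bis_x_um = grid$x, bis_y_um = grid$y,
                          row = grid$row, order = seq_len(nrow(grid)))
  structure(list(positions = positions, beam_radius_nm = r,
                 overlap_factor = overlap_factor,
                 spacing_um = a, row_spacing_um = dy, mode = mode),
            class = "acquisition_plan")
}

#' Serpentine ordering of hexagonal lattice positions
#'
#' Groups positions into rows by their y coordinate and visits rows bottom-up
#' with alternating x direction (first row left to right), so consecutive
#' positions are lattice neighbours.
#'
#' @param positions n x 2 matrix (x, y) of lattice positions.
#' @return Integer permutation such that `positions[order, ]` is serpentine.
#' @export
serpentine_order <- function(positions) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n == 0) return(integer(0))
  y <- positions[, 2]
  ys <- sort(unique(y))
  tol <- if (length(ys) > 1) min(diff(ys)[diff(ys) > 1e-9]) / 2 else Inf
  row_id <- integer(n)
  current <- 1L
  ord_y <- order(y)
  row_id[ord_y[1]] <- 1L
  for (i in seq_len(n - 1)) {
    if (y[ord_y[i + 1]] - y[ord_y[i]] > tol) current <- current + 1L
    row_id[ord_y[i + 1]] <- current
  }
  out <- integer(0)
  for (rr in seq_len(max(row_id))) {
    idx <- which(row_id == rr)
    idx <- idx[order(positions[idx, 1], decreasing = (rr %% 2 == 0))]
    out <- c(out, idx)
  }
  out
}

#' Initialize a defocus feedback state
#'
#' @param desired_defocus Setpoint in nm (default 800).
#' @return A `feedback_state`.
#' @export
feedback_state <- function(desired_defocus = 800) {
  structure(list(desired_defocus = desired_defocus, current_offset = 0,
                 history = data.frame(measured = numeric(0),
                                      correction = numeric(0))),
            class = "feedback_state")
}

#' One step of per-exposure defocus feedback
#'
#' After each exposure the defocus is measured and the focus for the next
#' exposure is corrected by the difference between the measured and the
#' desired defocus: `nominal_next = nominal - (measured - desired)`.
#'
#' @param state A `feedback_state`.
#' @param measured_defocus Measured defocus of the exposure just taken (nm).
#' @return Updated `feedback_state`; `$last_correction` holds the correction
#'   (`desired - measured`) applied to the next exposure and
#'   `$current_offset` the accumulated focus offset.
#' @export
defocus_feedback <- function(state, measured_defocus) {
  if (!is.finite(measured_defocus)) stop("measured defocus must be finite")
  correction <- state$desired_defocus - measured_defocus
  state$current_offset <- state$current_offset + correction
  state$last_correction <- correction
  state$history <- rbind(state$history,
                         data.frame(measured = measured_defocus,
                                    correction = correction))
  state
}

#' Simulate a serpentine acquisition under defocus feedback
#'
#' Runs the one-step feedback controller over the ordered plan positions on
#' a specimen whose true defocus offset varies as an affine function of the
#' beam-image shift, with Gaussian measurement noise. The first exposure is
#' taken at the plain setpoint (no feedback yet).
#'
#' @param plan An `acquisition_plan`.
#' @param defocus_field_nm `c(intercept, gx, gy)`: true defocus offset in nm
#'   as a function of beam-image shift in microns.
#' @param noise_sd Measurement noise sd in nm.
#' @param desired_defocus Setpoint in nm.
#' @param seed Integer seed.
#' @return Data frame per exposure: `index, bis_x_um, bis_y_um, applied_nm,
#'   true_nm, measured_nm`.
#' @export
simulate_feedback_acquisition <- function(plan, defocus_field_nm = c(0, 0, 0),
                                          noise_sd = 30,
                                          desired_defocus = 800, seed = 1) {
  pos <- plan$positions
  n <- nrow(pos)
  with_seed(seed, {
    state <- feedback_state(desired_defocus)
    applied <- true <- measured <- numeric(n)
    for (i in seq_len(n)) {
      applied[i] <- desired_defocus + state$current_offset
      offset <- defocus_field_nm[1] + defocus_field_nm[2] * pos$bis_x_um[i] +
        defocus_field_nm[3] * pos$bis_y_um[i]
      true[i] <- applied[i] + offset
      measured[i] <- true[i] + stats::rnorm(1, 0, noise_sd)
      state <- defocus_feedback(state, measured[i])
    }
    data.frame(index = pos$index, bis_x_um = pos$bis_x_um,
               bis_y_um = pos$bis_y_um, applied_nm = applied,
               true_nm = true, measured_nm = measured)
  })
}

#' Measure the offset of the illuminated disk from the camera center
#'
#' Emulates per-exposure beam recentering: the centroid of the illumination
#' mask is compared with the camera center; applying the negated offset
#' recenters the beam.
#'
#' @param image Tile image (matrix).
#' @param pixel_size Pixel size in Angstrom (for the mask lowpass).
#' @return `c(dx, dy)` in pixels (x = column, y = row).
#' @export
beam_center_offset <- function(image, pixel_size = 3) {
  if (all(image == 0)) stop("no illuminated area detected (empty mask)")
  mask <- illumination_mask(image, pixel_size)
  if (mask$area_px == 0) stop("no illuminated area detected (empty mask)")
  idx <- which(mask$binary, arr.ind = TRUE)
  ctr <- (dim(image) + 1) / 2
  c(mean(idx[, 2]) - ctr[2], mean(idx[, 1]) - ctr[1])
}

#' Write an acquisition plan as TSV
#' @param plan An `acquisition_plan`.
#' @param path Output file.
#' @export
write_plan_tsv <- function(plan, path) {
  utils::write.table(plan$positions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
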