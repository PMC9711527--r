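# Montage assembly: calibrated initialization of tile coordinates from
# beam-image shift, masked pairwise cross-correlation offsets, global
# least-squares refinement, feathered blending, and mapping of detections
# into 3D montage coordinates.

#' Initialize tile coordinates from beam-image shift
#'
#' `c_i = IC . b_i` with IC the 2 x 2 image-shift-to-camera calibration
#' matrix (px per micron).
#'
#' @param bis n x 2 matrix of beam-image-shift vectors (microns).
#' @param ic 2 x 2 calibration matrix.
#' @return n x 2 matrix of tile coordinates in px (columns `c_x, c_y`).
#' @export
init_tile_coords <- function(bis, ic) {
  ic <- as.matrix(ic)
  if (any(!is.finite(ic)) || abs(det(ic)) < 1e-12)
    stop("calibration matrix must be finite and invertible")
  bis <- as.matrix(bis)
  out <- t(ic %*% t(bis))
  colnames(out) <- c("c_x", "c_y")
  out
}

#' Find tile pairs whose beams overlap
#'
#' All unordered pairs with strict Euclidean distance `|c_i - c_j| <
#' d_beam_px`.
#'
#' @param coords n x 2 matrix of tile coordinates (px).
#' @param d_beam_px Beam diameter in px (> 0).
#' @return Data frame with columns `i, j` (1-based tile indices, i < j).
#' @export
find_overlapping_pairs <- function(coords, d_beam_px) {
  if (d_beam_px <= 0) stop("d_beam_px must be > 0")
  coords <- as.matrix(coords)
  n <- nrow(coords)
  out <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      dx <- coords[(i + 1):n, 1] - coords[i, 1]
      dy <- coords[(i + 1):n, 2] - coords[i, 2]
      js <- which(sqrt(dx^2 + dy^2) < d_beam_px) + i
      if (length(js)) out[[length(out) + 1L]] <- data.frame(i = i, j = js)
    }
  }
  if (length(out) == 0) return(data.frame(i = integer(0), j = integer(0)))
  do.call(rbind, out)
}

#' Refined offset between two overlapping tiles by masked cross-correlation
#'
#' Cross-correlates the two tiles restricted to their illuminated areas and
#' returns the offset `r_ij` estimating `c_i - c_j`, with sub-pixel
#' quadratic peak interpolation. The peak search is confined to a window
#' around the offset predicted by the current coordinates.
#'
#' @param tile_i,tile_j Tile images.
#' @param mask_i,mask_j Their `illumination_mask`s.
#' @param coord_i,coord_j Current coordinates (length-2, px).
#' @param search_radius_px Half-width of the peak search window around the
#'   predicted offset (default 20).
#' @param erode_px Erosion of the binary masks (px) before correlating;
#'   removes the beam-edge rim, whose static structure would otherwise bias
#'   the offset (default 4).
#' @return List `r_ij` (length 2: x, y), `correlation_score` in \[-1, 1\],
#'   `overlap_area_px`.
#' @export
masked_pair_offset <- function(tile_i, tile_j, mask_i, mask_j,
                               coord_i, coord_j, search_radius_px = 20,
                               erode_px = 4) {
  d <- dim(tile_i)
  pred <- coord_j - coord_i      # displacement d maximizing sum a(p+d) b(p)
  # predicted overlap of the illuminated disks (integer shift, no wrap):
  # tile_j pixel q matches tile_i pixel p when q = p - pred
  sh <- round(pred)
  ri <- seq_len(d[1]); ci <- seq_len(d[2])
  rj <- ri - sh[2]; cj <- ci - sh[1]
  ok_r <- rj >= 1 & rj <= d[1]; ok_c <- cj >= 1 & cj <= d[2]
  ov <- if (any(ok_r) && any(ok_c))
    sum(mask_i$binary[ri[ok_r], ci[ok_c]] &
        mask_j$binary[rj[ok_r], cj[ok_c]]) else 0L
  if (ov == 0) stop("empty predicted overlap between illuminated areas")
  # restrict both tiles to the predicted overlap lens (dilated by the search
  # radius), so content outside the shared area cannot produce spurious
  # correlation peaks; erosion removes the static beam-edge rim
  ei <- erode_binary(mask_i$binary, erode_px)
  ej <- erode_binary(mask_j$binary, erode_px)
  lens_i <- ei & shift_binary(ej, sh)
  lens_j <- ej & shift_binary(ei, -sh)
  if (!any(lens_i) || !any(lens_j))
    stop("empty predicted overlap between illuminated areas")
  a <- (tile_i - mean(tile_i[lens_i])) * mask_i$weights * lens_i
  b <- (tile_j - mean(tile_j[lens_j])) * mask_j$weights * lens_j
  cc <- cross_correlate(a, b)
  # search the circular correlation in a window around the predicted
  # displacement, indexing modulo the frame (large offsets alias)
  offs <- -search_radius_px:search_radius_px
  rows <- ((round(pred[2]) + offs) %% d[1]) + 1L
  cols <- ((round(pred[1]) + offs) %% d[2]) + 1L
  sub <- cc[rows, cols, drop = FALSE]
  pk <- which_max2(sub)
  pk_sub <- subpixel_peak(cc, c(rows[pk[1]], cols[pk[2]]))
  dyx <- pk_sub - 1
  # decode as the displacement representative nearest the prediction
  dy <- dyx[1] - d[1] * round((dyx[1] - pred[2]) / d[1])
  dx <- dyx[2] - d[2] * round((dyx[2] - pred[1]) / d[2])
  score <- max(sub) / sqrt(sum(a^2) * sum(b^2))
  list(r_ij = -c(dx, dy), correlation_score = score, overlap_area_px = ov)
}

# integer-shift a binary mask with FALSE fill: out[p] = b[p - sh], sh = (dx, dy)
shift_binary <- function(b, sh) {
  out <- matrix(FALSE, nrow(b), ncol(b))
  r <- seq_len(nrow(b)); c <- seq_len(ncol(b))
  rs <- r - sh[2]; cs <- c - sh[1]
  ok_r <- rs >= 1 & rs <= nrow(b); ok_c <- cs >= 1 & cs <= ncol(b)
  if (any(ok_r) && any(ok_c))
    out[r[ok_r], c[ok_c]] <- b[rs[ok_r], cs[ok_c]]
  out
}

# binary erosion with a (2k+1) square structuring element, via integral image
erode_binary <- function(b, k) {
  if (k < 1) return(b)
  nr <- nrow(b); nc <- ncol(b)
  ii <- matrix(0, nr + 1, nc + 1)
  ii[-1, -1] <- t(apply(apply(!b, 2, cumsum), 1, cumsum))
  r0 <- pmax(seq_len(nr) - k - 1, 0); r1 <- pmin(seq_len(nr) + k, nr)
  c0 <- pmax(seq_len(nc) - k - 1, 0); c1 <- pmin(seq_len(nc) + k, nc)
  cnt <- ii[r1 + 1, c1 + 1] - ii[r0 + 1, c1 + 1] - ii[r1 + 1, c0 + 1] +
    ii[r0 + 1, c0 + 1]
  b & (cnt == 0)
}

# connected components of the pair graph (BFS)
pair_components <- function(n, pairs) {
  comp <- integer(n)
  cur <- 0L
  adj <- vector("list", n)
  for (k in seq_len(nrow(pairs))) {
    adj[[pairs$i[k]]] <- c(adj[[pairs$i[k]]], pairs$j[k])
    adj[[pairs$j[k]]] <- c(adj[[pairs$j[k]]], pairs$i[k])
  }
  for (s in seq_len(n)) {
    if (comp[s] != 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' Global least-squares refinement of tile coordinates
#'
#' Minimizes `sum over pairs of || r_ij - (c_i - c_j) ||^2` as a linear
#' least-squares problem (independently per axis), handling each connected
#' component of the pair graph separately and fixing the translational gauge
#' so the centroid of each component matches its initial centroid.
#'
#' @param coords_init n x 2 matrix of initial coordinates (px).
#' @param pairs Data frame with columns `i, j, r_x, r_y` where `(r_x, r_y)`
#'   estimates `c_i - c_j`.
#' @return A `montage_solution`: `coords` (n x 2), `residuals` (per pair,
#'   x/y), `rms_residual` (px), `n_components`.
#' @export
solve_tile_coords <- function(coords_init, pairs) {
  coords_init <- as.matrix(coords_init)
  n <- nrow(coords_init)
  if (is.null(pairs) || nrow(pairs) == 0) {
    warning("no overlapping pairs; coordinates left unchanged")
    return(structure(list(coords = coords_init,
                          residuals = data.frame(),
                          rms_residual = NA_real_, n_components = n),
                     class = "montage_solution"))
  }
  m <- nrow(pairs)
  A <- matrix(0, m, n)
  A[cbind(seq_len(m), pairs$i)] <- 1
  A[cbind(seq_len(m), pairs$j)] <- -1
  comp <- pair_components(n, pairs)
  coords <- coords_init
  Ap <- MASS::ginv(A)
  for (ax in 1:2) {
    r <- if (ax == 1) pairs$r_x else pairs$r_y
    delta <- Ap %*% (r - A %*% coords_init[, ax])
    # minimum-norm correction is mean-zero on each component touched by
    # pairs; restore each component's initial centroid explicitly
    for (cm in unique(comp)) {
      sel <- comp == cm
      delta[sel] <- delta[sel] - mean(delta[sel])
    }
    coords[, ax] <- coords_init[, ax] + delta
  }
  res <- cbind(pairs$r_x - (coords[pairs$i, 1] - coords[pairs$j, 1]),
               pairs$r_y - (coords[pairs$i, 2] - coords[pairs$j, 2]))
  structure(list(coords = coords,
                 residuals = data.frame(i = pairs$i, j = pairs$j,
                                        res_x = res[, 1], res_y = res[, 2]),
                 rms_residual = sqrt(mean(res^2)),
                 n_components = length(unique(comp))),
            class = "montage_solution")
}

#' Iterative montage refinement
#'
#' Alternates masked pairwise cross-correlation (at the current coordinates)
#' with the global least-squares solve for a fixed number of rounds
#' (default 2: one refinement pass after the initial one).
#'
#' @param tiles List of tile images.
#' @param masks List of their `illumination_mask`s.
#' @param coords_init n x 2 initial coordinates (px).
#' @param d_beam_px Beam diameter in px (pair selection).
#' @param rounds Number of rounds (>= 1, default 2).
#' @param search_radius_px Peak search radius for the pair offsets.
#' @return A `montage_solution` with an extra `pairs` table (`i, j, r_x,
#'   r_y, correlation_score, overlap_area_px`) and `rounds`.
#' @export
refine_montage <- function(tiles, masks, coords_init, d_beam_px, rounds = 2,
                           search_radius_px = 20) {
  if (rounds < 1) stop("rounds must be >= 1")
  coords <- as.matrix(coords_init)
  sol <- NULL
  for (rd in seq_len(rounds)) {
    idx <- find_overlapping_pairs(coords, d_beam_px)
    if (nrow(idx) == 0) return(solve_tile_coords(coords, idx))
    offs <- lapply(seq_len(nrow(idx)), function(k) {
      i <- idx$i[k]; j <- idx$j[k]
      masked_pair_offset(tiles[[i]], tiles[[j]], masks[[i]], masks[[j]],
                         coords[i, ], coords[j, ], search_radius_px)
    })
    pairs <- data.frame(
      i = idx$i, j = idx$j,
      r_x = vapply(offs, function(o) o$r_ij[1], numeric(1)),
      r_y = vapply(offs, function(o) o$r_ij[2], numeric(1)),
      correlation_score = vapply(offs, function(o) o$correlation_score,
                                 numeric(1)),
      overlap_area_px = vapply(offs, function(o) o$overlap_area_px,
                               numeric(1)))
    sol <- solve_tile_coords(coords, pairs)
    sol$pairs <- pairs
    coords <- sol$coords
  }
  sol$rounds <- rounds
  sol
}

#' Assemble tiles into a montage image
#'
#' Places every tile at its (rounded) coordinate on a canvas spanning the
#' union of tile extents, blending overlaps with mask-weight feathering:
#' each covered pixel is the weight-normalized mean of the contributing
#' tiles, so feather weights sum to 1 wherever at least one tile
#' contributes; uncovered pixels are 0.
#'
#' @param tiles List of tile images (equal shapes).
#' @param masks List of their `illumination_mask`s (feather weights).
#' @param coords n x 2 tile coordinates in px.
#' @return List `image` (canvas), `weight` (total feather weight per pixel),
#'   `origin` (canvas origin in montage coordinates, 0-based px).
#' @export
assemble_montage <- function(tiles, masks, coords) {
  coords <- as.matrix(coords)
  stopifnot_finite(coords, "tile coordinates")
  d <- dim(tiles[[1]])
  x0 <- floor(min(coords[, 1])); y0 <- floor(min(coords[, 2]))
  x1 <- ceiling(max(coords[, 1])) + d[2]
  y1 <- ceiling(max(coords[, 2])) + d[1]
  canvas <- matrix(0, y1 - y0, x1 - x0)
  weight <- matrix(0, y1 - y0, x1 - x0)
  for (k in seq_along(tiles)) {
    rr <- round(coords[k, 2]) - y0 + seq_len(d[1])
    cc <- round(coords[k, 1]) - x0 + seq_len(d[2])
    w <- masks[[k]]$weights
    canvas[rr, cc] <- canvas[rr, cc] + tiles[[k]] * w
    weight[rr, cc] <- weight[rr, cc] + w
  }
  covered <- weight > 0
  canvas[covered] <- canvas[covered] / weight[covered]
  list(image = canvas, weight = weight, origin = c(x0, y0))
}

#' Map tile-frame detections into the montage frame with z coordinates
#'
#' Adds each detection's tile coordinate (`m^M = m^T + c_i`) and computes a
#' relative z as the sum of the per-target defocus offset, the deviation of
#' the tile's estimated defocus from the setpoint, and the tile's nominal
#' focus term; larger defocus means further along the beam direction. The
#' z origin is a gauge choice (the setpoint focal plane), not an absolute
#' stage height.
#'
#' @param detections Data frame with `tile_id, x_px, y_px, defocus_offset,
#'   phi, theta, psi, snr` (tile_id indexes `tile_info`).
#' @param solution A `montage_solution` (or n x 2 coordinate matrix).
#' @param tile_info Data frame with one row per tile: `tile_id`,
#'   `estimated_defocus_nm`, `nominal_defocus_nm` (optional, default 0).
#' @param desired_defocus_nm Defocus setpoint in nm (default 800).
#' @param pixel_size_nm Montage pixel size in nm (for `x_m_nm, y_m_nm`).
#' @return Data frame of montage detections: inputs plus `x_m_px, y_m_px,
#'   x_m_nm, y_m_nm, z_nm`.
#' @export
map_detections <- function(detections, solution, tile_info,
                           desired_defocus_nm = 800, pixel_size_nm = 0.15) {
  coords <- if (inherits(solution, "montage_solution")) solution$coords
            else as.matrix(solution)
  idx <- match(detections$tile_id, tile_info$tile_id)
  if (any(is.na(idx))) stop("detection references an unknown tile_id")
  nominal <- tile_info$nominal_defocus_nm
  if (is.null(nominal)) nominal <- rep(0, nrow(tile_info))
  est <- tile_info$estimated_defocus_nm
  if (is.null(est)) est <- rep(desired_defocus_nm, nrow(tile_info))
  out <- detections
  out$x_m_px <- detections$x_px + coords[idx, 1]
  out$y_m_px <- detections$y_px + coords[idx, 2]
  out$x_m_nm <- out$x_m_px * pixel_size_nm
  out$y_m_nm <- out$y_m_px * pixel_size_nm
  off <- detections$defocus_offset
  if (is.null(off)) off <- rep(0, nrow(detections))
  out$z_nm <- off + (est[idx] - desired_defocus_nm) + nominal[idx]
  out
}
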