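# Per-lamella summaries: detection counts and SNR statistics, beam-image-
# shift maps, tile averages, z-extent vs thickness, and region audits
# against the expected false-positive rate. All functions are deterministic
# in their input tables.

#' Summarize detections for one lamella
#'
#' Counts detections per tile and reports the per-tile detection density
#' restricted to tiles with two or more detections (tiles dominated by the
#' expected one false positive are excluded from the density), plus the
#' median SNR.
#'
#' @param detections Data frame with `tile_id` and `snr` columns.
#' @param tile_info Data frame with one row per tile (`tile_id`, optionally
#'   `defocus_nm`, `thickness_nm`, `bis_x_um`, `bis_y_um`).
#' @param lamella_id Label for the lamella.
#' @return A `lamella_stats` list: `lamella_id`, `n_detections`,
#'   `detections_per_tile` (counts from tiles with >= 2 detections),
#'   `median_snr` (NA when there are no detections), `per_tile` table.
#' @export
summarize_lamella <- function(detections, tile_info, lamella_id = "lamella") {
  counts <- table(factor(detections$tile_id, levels = tile_info$tile_id))
  n_det <- vapply(tile_info$tile_id, function(id)
    sum(detections$tile_id == id), numeric(1))
  med_by_tile <- vapply(tile_info$tile_id, function(id) {
    s <- detections$snr[detections$tile_id == id]
    if (length(s)) stats::median(s) else NA_real_
  }, numeric(1))
  per_tile <- cbind(tile_info, n_det = n_det, median_snr = med_by_tile)
  structure(list(
    lamella_id = lamella_id,
    n_detections = nrow(detections),
    detections_per_tile = sort(n_det[n_det >= 2]),
    median_snr = if (nrow(detections)) stats::median(detections$snr)
                 else NA_real_,
    per_tile = per_tile), class = "lamella_stats")
}

#' Binned maps over beam-image shift
#'
#' Square-bins a per-tile quantity over the beam-image-shift plane: either
#' the summed count of a field or its mean per bin. Empty bins are NA.
#'
#' @param per_tile Data frame with `bis_x_um`, `bis_y_um` and the value
#'   field.
#' @param values Name of the field to map.
#' @param statistic `"count"` (sum over tiles in the bin) or `"mean"`.
#' @param bin_um Bin side in microns (default 0.5).
#' @return List `x_breaks`, `y_breaks`, `map` (matrix, rows = y bins).
#' @export
bis_maps <- function(per_tile, values, statistic = c("count", "mean"),
                     bin_um = 0.5) {
  statistic <- match.arg(statistic)
  if (bin_um <= 0) stop("bin_um must be > 0")
  x <- per_tile$bis_x_um; y <- per_tile$bis_y_um
  v <- per_tile[[values]]
  xb <- seq(floor(min(x) / bin_um) * bin_um,
            ceiling(max(x) / bin_um) * bin_um + bin_um, by = bin_um)
  yb <- seq(floor(min(y) / bin_um) * bin_um,
            ceiling(max(y) / bin_um) * bin_um + bin_um, by = bin_um)
  ix <- findInterval(x, xb, rightmost.closed = TRUE)
  iy <- findInterval(y, yb, rightmost.closed = TRUE)
  map <- matrix(NA_real_, length(yb) - 1, length(xb) - 1)
  for (r in seq_len(nrow(map))) for (c in seq_len(ncol(map))) {
    sel <- ix == c & iy == r
    if (any(sel))
      map[r, c] <- if (statistic == "count") sum(v[sel]) else mean(v[sel])
  }
  list(x_breaks = xb, y_breaks = yb, map = map, statistic = statistic)
}

#' Pixel-wise average of all tiles
#'
#' Averaging washes out specimen content and exposes static patterns such
#' as the beam vignette and camera shading.
#'
#' @param tiles List of equally shaped tile images (>= 1).
#' @return Matrix: the pixel-wise mean.
#' @export
tile_average <- function(tiles) {
  if (length(tiles) < 1) stop("need at least one tile")
  d <- dim(tiles[[1]])
  if (!all(vapply(tiles, function(t) identical(dim(t), d), logical(1))))
    stop("tiles must share one shape")
  Reduce(`+`, tiles) / length(tiles)
}

#' Z extent of detections vs estimated ice thickness, per tile
#'
#' @param montage_detections Data frame with `tile_id` and `z_nm`.
#' @param thickness Data frame with `tile_id` and `thickness_nm`.
#' @return Data frame `tile_id, n_det, z_range_nm, thickness_nm`; tiles
#'   with fewer than two detections are omitted.
#' @export
z_extent_vs_thickness <- function(montage_detections, thickness) {
  ids <- unique(montage_detections$tile_id)
  rows <- lapply(ids, function(id) {
    z <- montage_detections$z_nm[montage_detections$tile_id == id]
    if (length(z) < 2) return(NULL)
    data.frame(tile_id = id, n_det = length(z),
               z_range_nm = max(z) - min(z),
               thickness_nm = thickness$thickness_nm[
                 match(id, thickness$tile_id)])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tile_id = integer(0), n_det = integer(0),
                      z_range_nm = numeric(0), thickness_nm = numeric(0))
  out
}

#' Audit detections inside a region against the false-positive expectation
#'
#' Counts detections falling inside a polygon (even-odd rule) and compares
#' with the number expected from the one-false-positive-per-tile criterion
#' alone, i.e. one per tile in the region. Reports counts only; no
#' inference.
#'
#' @param montage_detections Data frame with montage coordinates `x_m_nm,
#'   y_m_nm` (or `x_m_px, y_m_px` if `units = "px"`).
#' @param region_polygon n x 2 polygon in the same units.
#' @param n_tiles_in_region Number of tiles lying in the region.
#' @param units `"nm"` or `"px"`.
#' @return List `observed`, `expected_false_positives`.
#' @export
region_audit <- function(montage_detections, region_polygon,
                         n_tiles_in_region, units = c("nm", "px")) {
  units <- match.arg(units)
  poly <- as.matrix(region_polygon)
  if (nrow(poly) < 3) stop("region polygon needs >= 3 vertices")
  x <- if (units == "nm") montage_detections$x_m_nm
       else montage_detections$x_m_px
  y <- if (units == "nm") montage_detections$y_m_nm
       else montage_detections$y_m_px
  obs <- if (length(x)) sum(point_in_polygon(x, y, poly)) else 0L
  list(observed = obs, expected_false_positives = n_tiles_in_region)
}

#' Worst-case beam tilt induced by beam-image shift
#'
#' @param max_shift_um Largest beam-image shift used (microns).
#' @param tilt_per_um_mrad Column-specific beam tilt per micron of shift
#'   (mrad/micron; 0.17-0.25 reported for Krios columns).
#' @return Worst-case beam tilt in mrad (the product).
#' @export
beam_tilt_worst_case <- function(max_shift_um, tilt_per_um_mrad) {
  if (max_shift_um < 0 || tilt_per_um_mrad < 0)
    stop("inputs must be >= 0")
  max_shift_um * tilt_per_um_mrad
}
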