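# End-to-end synthetic pipeline: plan -> simulate -> preprocess -> match ->
# montage -> report, at desk scale. The geometry is a scaled-down version of
# a real collection (small camera, small beam radius, coarse orientation
# grid) so a full run stays in the minutes range on one CPU; every stage
# runs exactly the code a full-scale collection would use.

#' Default configuration for the synthetic pipeline
#'
#' @param camera_px Camera side in pixels.
#' @param pixel_size Pixel size in Angstrom.
#' @param beam_radius_nm Illuminated radius in nm.
#' @param out_step,in_step Orientation grid steps in degrees.
#' @param defocus_planes,defocus_step_nm Defocus search depth.
#' @return Named list of pipeline parameters.
#' @export
default_pipeline_config <- function(camera_px = 128, pixel_size = 8,
                                    beam_radius_nm = 45, out_step = 20,
                                    in_step = 20, defocus_planes = 3,
                                    defocus_step_nm = 60) {
  list(
    camera_px = camera_px,
    pixel_size = pixel_size,
    beam_radius_nm = beam_radius_nm,
    overlap_factor = 0.95,
    corners_um = NULL,             # default: a small multi-row tile block
    desired_defocus_nm = 800,
    defocus_field_nm = c(0, 200, 0),
    defocus_noise_sd = 30,
    thickness_nm = 150,
    instance_density_um2 = 500,
    organelles = NULL,
    thickness_texture_sd_nm = 25,
    thickness_texture_corr_nm = 5,
    template_box = 32,
    n_blobs = 20,
    b_factor = 0,
    noise_sigma = 10,
    base_intensity = 100,
    signal_scale = 100,
    shading = "annulus",
    fringes = FALSE,
    out_step = out_step,
    in_step = in_step,
    defocus_planes = defocus_planes,
    defocus_step_nm = defocus_step_nm,
    exclusion_radius_px = 6,
    rounds = 2,
    coord_jitter_px = 3)
}

#' Run the full synthetic pipeline
#'
#' Plans a serpentine hexagonal acquisition over a rectangular lamella,
#' simulates the defocus feedback and every tile exposure, preprocesses
#' (mask, noise fill), matches the template in every tile, assembles the
#' montage by masked cross-correlation and least squares, maps detections
#' into 3D montage coordinates and summarizes the lamella.
#'
#' @param config See [default_pipeline_config()].
#' @param seed Integer master seed.
#' @return List with `plan`, `acquisition`, `scene`, `template`, `tiles`,
#'   `masks`, `truth`, `detections`, `solution`, `montage`,
#'   `montage_detections`, `thickness`, `stats`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), seed = 1) {
  px_nm <- config$pixel_size / 10
  r <- config$beam_radius_nm
  corners <- config$corners_um
  if (is.null(corners)) {
    a_um <- sqrt(3) * config$overlap_factor * r / 1000
    corners <- rbind(c(0, 0), c(2 * a_um, 0),
                     c(2 * a_um, 1.5 * a_um), c(0, 1.5 * a_um))
  }
  plan <- corners_to_plan(corners, r, config$overlap_factor)
  acq <- simulate_feedback_acquisition(
    plan, config$defocus_field_nm, config$defocus_noise_sd,
    config$desired_defocus_nm, seed = seed + 1)

  scene_poly_nm <- rbind(
    c(min(corners[, 1]), min(corners[, 2])),
    c(max(corners[, 1]), min(corners[, 2])),
    c(max(corners[, 1]), max(corners[, 2])),
    c(min(corners[, 1]), max(corners[, 2]))) * 1000
  pad <- r * 1.2
  scene_poly_nm <- scene_poly_nm +
    rbind(c(-pad, -pad), c(pad, -pad), c(pad, pad), c(-pad, pad))
  scene <- build_scene(list(
    lamella_polygon = scene_poly_nm,
    thickness_nm = config$thickness_nm,
    thickness_texture_sd_nm = config$thickness_texture_sd_nm,
    thickness_texture_corr_nm = config$thickness_texture_corr_nm,
    instance_density_um2 = config$instance_density_um2,
    organelles = config$organelles,
    defocus_field_nm = c(0, config$defocus_field_nm[2] / 1000,
                         config$defocus_field_nm[3] / 1000),
    beam_radius_nm = r,
    pixel_size = config$pixel_size), seed = seed + 2)

  template <- make_template_volume(config$template_box, config$pixel_size,
                                   config$n_blobs, seed = seed + 3,
                                   b_factor = config$b_factor)
  grid <- make_orientation_grid(config$out_step, config$in_step)
  bank <- project_bank(template, grid)
  beam <- beam_profile(r, fringes = config$fringes)
  camera <- camera_model(c(config$camera_px, config$camera_px),
                         config$pixel_size, config$noise_sigma,
                         config$shading, beam_radius_nm = r)

  n_tiles <- nrow(plan$positions)
  tiles <- masks <- vector("list", n_tiles)
  truth <- detections <- list()
  tile_info <- data.frame(tile_id = seq_len(n_tiles),
                          bis_x_um = plan$positions$bis_x_um,
                          bis_y_um = plan$positions$bis_y_um,
                          estimated_defocus_nm = acq$measured_nm,
                          nominal_defocus_nm = acq$applied_nm -
                            config$desired_defocus_nm,
                          thickness_nm = NA_real_)
  for (i in seq_len(n_tiles)) {
    center_nm <- c(plan$positions$bis_x_um[i],
                   plan$positions$bis_y_um[i]) * 1000
    ctf_true <- ctf_params(acq$true_nm[i] / 1000,
                           pixel_size = config$pixel_size)
    rt <- render_tile(scene, template, center_nm, beam, camera, ctf_true,
                      seed = seed + 10 + i,
                      base_intensity = config$base_intensity,
                      signal_scale = config$signal_scale)
    mask <- illumination_mask(rt$image, config$pixel_size)
    img <- fill_dark_with_noise(rt$image, mask, seed = seed + 1000 + i)
    tiles[[i]] <- img
    masks[[i]] <- mask
    tile_info$thickness_nm[i] <- estimate_thickness(
      rt$image, mask, rt$vacuum_intensity)
    if (nrow(rt$truth))
      truth[[length(truth) + 1L]] <- cbind(tile_id = i, rt$truth)
    ctf_est <- ctf_params(acq$measured_nm[i] / 1000,
                          pixel_size = config$pixel_size)
    res <- match_template(img, mask, template, ctf_est, grid,
                          config$defocus_planes, config$defocus_step_nm,
                          bank = bank)
    det <- extract_peaks(res, mask, config$exclusion_radius_px)
    if (nrow(det))
      detections[[length(detections) + 1L]] <- cbind(tile_id = i, det)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  detections <- if (length(detections)) do.call(rbind, detections)
    else data.frame(tile_id = integer(0), x_px = numeric(0),
                    y_px = numeric(0), defocus_offset = numeric(0),
                    phi = numeric(0), theta = numeric(0), psi = numeric(0),
                    snr = numeric(0))

  px_per_um <- 1000 / px_nm
  ic <- diag(c(px_per_um, px_per_um))
  coords0 <- init_tile_coords(
    cbind(plan$positions$bis_x_um, plan$positions$bis_y_um), ic)
  if (config$coord_jitter_px > 0) {
    coords0 <- coords0 + with_seed(seed + 4, matrix(
      stats::runif(2 * n_tiles, -config$coord_jitter_px,
                   config$coord_jitter_px), n_tiles, 2))
  }
  d_beam_px <- 2 * r / px_nm
  solution <- refine_montage(tiles, masks, coords0, d_beam_px,
                             rounds = config$rounds)
  montage <- assemble_montage(tiles, masks, solution$coords)
  montage_detections <- map_detections(
    detections, solution, tile_info,
    desired_defocus_nm = config$desired_defocus_nm, pixel_size_nm = px_nm)
  stats <- summarize_lamella(detections, tile_info)
  list(plan = plan, acquisition = acq, scene = scene, template = template,
       tiles = tiles, masks = masks, truth = truth,
       detections = detections, solution = solution, montage = montage,
       montage_detections = montage_detections,
       thickness = tile_info[, c("tile_id", "thickness_nm")],
       tile_info = tile_info, stats = stats, config = config)
}
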