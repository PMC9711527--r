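# Shared fixtures. Everything is generated in code; sizes are kept small so
# the whole suite runs in minutes on one CPU.

fx <- new.env()

# small sharp template, 8 A pixels (cached across tests)
fx_template <- function() {
  if (is.null(fx$tmpl)) fx$tmpl <- make_template_volume(32, 8, 20, seed = 7)
  fx$tmpl
}

# wider template whose angular correlation length is below the coarse grid
# step, so search outcomes are approximately independent
fx_template_wide <- function() {
  if (is.null(fx$tmplw)) fx$tmplw <- make_template_volume(48, 8, 20, seed = 7)
  fx$tmplw
}

fx_grid_coarse <- function() {
  if (is.null(fx$gridc)) fx$gridc <- make_orientation_grid(40, 45)
  fx$gridc
}

fx_bank_wide <- function() {
  if (is.null(fx$bankw))
    fx$bankw <- project_bank(fx_template_wide(), fx_grid_coarse())
  fx$bankw
}

# flat lamella scene without roughness texture (noise-only tiles)
fx_scene_flat <- function() {
  if (is.null(fx$scene_flat)) {
    fx$scene_flat <- build_scene(list(
      lamella_polygon = rbind(c(-500, -500), c(500, -500),
                              c(500, 500), c(-500, 500)),
      thickness_nm = 150, instance_density_um2 = 0,
      thickness_texture_sd_nm = 0), seed = 1)
  }
  fx$scene_flat
}

fx_beam <- function() beam_profile(45)

fx_camera <- function(noise_sigma = 10) {
  camera_model(c(128, 128), 8, noise_sigma = noise_sigma,
               beam_radius_nm = 45)
}

fx_ctf <- function(defocus = 0.8) ctf_params(defocus, pixel_size = 8)

# render a noise-only tile and return the masked, noise-filled image
fx_noise_tile <- function(seed, camera = fx_camera(), ctf = fx_ctf(),
                          template = fx_template_wide()) {
  rt <- render_tile(fx_scene_flat(), template, c(0, 0), fx_beam(), camera,
                    ctf, seed = seed)
  mask <- illumination_mask(rt$image, camera$pixel_size)
  list(image = fill_dark_with_noise(rt$image, mask, seed + 5000),
       mask = mask, raw = rt$image)
}

# homogeneous noise frame whose illumination mask covers everything
fx_flat_frame <- function(n, sigma, seed, mean = 100) {
  img <- mean + with_seed_test(seed, matrix(stats::rnorm(n * n, 0, sigma),
                                            n, n))
  mask <- illumination_mask(img, 8)
  list(image = img, mask = mask)
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# independent connected-component labelling oracle (4-connectivity BFS)
label_components <- function(binary) {
  lab <- matrix(0L, nrow(binary), ncol(binary))
  cur <- 0L
  for (start in which(binary & lab == 0)) {
    if (lab[start] != 0) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    nr <- nrow(binary)
    while (length(queue)) {
      v <- queue[length(queue)]; queue <- queue[-length(queue)]
      r <- ((v - 1) %% nr) + 1; c <- ((v - 1) %/% nr) + 1
      for (d in list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))) {
        if (d[1] < 1 || d[1] > nr || d[2] < 1 || d[2] > ncol(binary)) next
        u <- (d[2] - 1) * nr + d[1]
        if (binary[u] && lab[u] == 0) { lab[u] <- cur; queue <- c(queue, u) }
      }
    }
  }
  lab
}

# synthetic CTF-modulated noise image (power spectrum proportional to CTF^2)
fx_ctf_image <- function(n, ctf, seed) {
  noise <- with_seed_test(seed, matrix(stats::rnorm(n * n), n, n))
  apply_ctf_and_bfactor(noise, ctf, 0, 0)
}
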