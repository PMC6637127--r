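#' Load and validate a pipeline configuration
#'
#' Configurations are YAML mappings with blocks `grid`, `scene`,
#' `aberration`, `illumination`, `noise`, `interferogram`, `correction`,
#' `volume`, `output`, and a global `seed`. Unknown presets, inconsistent
#' geometry and malformed fields are reported with their field path before
#' any computation starts; missing optional fields receive defaults. Every
#' run writes its resolved configuration next to its outputs.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return The resolved configuration (named list) with class
#'   `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  need <- function(block, field, default = NULL) {
    v <- cfg[[block]][[field]]
    if (is.null(v)) {
      if (is.null(default))
        stop(sprintf("config field %s.%s is required", block, field), call. = FALSE)
      v <- default
    }
    v
  }
  out <- list(
    seed = as.integer(if (is.null(cfg$seed)) 1L else cfg$seed),
    grid = list(n = as.integer(need("grid", "n", 64L)),
                pitch_nm = need("grid", "pitch_nm", 80),
                wavelength_nm = need("grid", "wavelength_nm", 515),
                na = need("grid", "na", 0.8),
                n_medium = need("grid", "n_medium", 1.33)),
    scene = list(preset = need("scene", "preset", "filaments")),
    aberration = list(rms = need("aberration", "rms", 1.5),
                      corr_length = need("aberration", "corr_length", 0.3),
                      zernike = cfg$aberration$zernike),
    illumination = list(n = as.integer(need("illumination", "n", 0L)),
                        pattern = need("illumination", "pattern", "spiral")),
    noise = list(gamma = need("noise", "gamma", 0)),
    interferogram = list(enabled = isTRUE(cfg$interferogram$enabled),
                         e_r0 = need("interferogram", "e_r0", 1),
                         camera_noise_var = need("interferogram",
                                                 "camera_noise_var", 0)),
    correction = list(tol = need("correction", "tol", 1e-3),
                      max_iter = as.integer(need("correction", "max_iter", 30L)),
                      tile = as.integer(need("correction", "tile", c(1L, 1L))),
                      overlap = need("correction", "overlap", 0.25)),
    volume = list(enabled = isTRUE(cfg$volume$enabled),
                  half_range_um = need("volume", "half_range_um", 2),
                  coarse_step_um = need("volume", "coarse_step_um", 1),
                  fine_step_um = need("volume", "fine_step_um", 0.5)),
    output = list(dir = need("output", "dir", tempfile("classao_run_")),
                  tiff = !isFALSE(cfg$output$tiff)))
  ## eager geometry checks so failures name the offending field
  g <- try(grid_spec(out$grid$n, out$grid$pitch_nm * 1e-9,
                     out$grid$wavelength_nm * 1e-9, out$grid$na,
                     out$grid$n_medium), silent = TRUE)
  if (inherits(g, "try-error"))
    stop("config block `grid`: ", attr(g, "condition")$message, call. = FALSE)
  if (out$illumination$n == 0L) out$illumination$n <- sum(pupil_mask(g))
  if (!out$scene$preset %in%
      c("single_point", "point_grid", "filaments", "speckle_object"))
    stop("config field scene.preset: unknown preset", call. = FALSE)
  if (length(out$correction$tile) != 2L || any(out$correction$tile < 1L))
    stop("config field correction.tile must be two positive integers", call. = FALSE)
  structure(out, class = c("pipeline_config", "list"))
}

#' Run the end-to-end simulation/correction pipeline
#'
#' Executes the full chain on simulator-generated data: scene and screen
#' generation, illumination sampling, reflection-matrix assembly (optionally
#' via synthesized interferograms and demodulation), CLASS correction
#' (tiled when `correction.tile` is not 1x1), PSF/Strehl metrology, and an
#' optional refocused volume with a maximum-intensity projection. All
#' randomness derives from the configured seed, so a config runs to
#' bit-identical payloads.
#'
#' Results are written to the run directory: `config.yaml` (resolved
#' configuration + seed, the provenance record), `metrics.json`,
#' `results.rds` (full R objects), and 32-bit TIFF previews (images scaled
#' to `[0, 1]`; scale factors in the metrics).
#'
#' @param config A [pipeline_config()], a path to one, or a named list.
#' @param seed Optional override of the configured seed.
#' @return Invisibly, a list with the run directory, metrics, and the main
#'   result objects.
#' @export
run_pipeline <- function(config, seed = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  grid <- grid_spec(cfg$grid$n, cfg$grid$pitch_nm * 1e-9,
                    cfg$grid$wavelength_nm * 1e-9, cfg$grid$na, cfg$grid$n_medium)
  t_start <- proc.time()[["elapsed"]]
  log_line <- function(...) message(sprintf("[classao +%6.1fs] ",
                                            proc.time()[["elapsed"]] - t_start),
                                    sprintf(...))

  log_line("scene '%s' on %d x %d grid", cfg$scene$preset, grid$n, grid$n)
  specimen <- make_specimen(cfg$scene$preset, grid, seed = cfg$seed)
  ab_spec <- if (!is.null(cfg$aberration$zernike))
    list(zernike = cfg$aberration$zernike)
  else list(rms = cfg$aberration$rms, corr_length = cfg$aberration$corr_length)
  phase_in <- make_aberration(ab_spec, grid, seed = cfg$seed + 1L, role = "input")
  phase_out <- make_aberration(ab_spec, grid, seed = cfg$seed + 2L, role = "output")
  illum <- sample_illumination_angles(cfg$illumination$n, grid,
                                      cfg$illumination$pattern)

  log_line("assembling matrix, N_in = %d, gamma = %.2f",
           nrow(illum$k), cfg$noise$gamma)
  m <- assemble_matrix(specimen, phase_in, phase_out, illum, grid,
                       noise_spec(cfg$noise$gamma, cfg$seed + 3L))

  if (cfg$interferogram$enabled) {
    log_line("interferogram round trip (E_R0 = %.2f)", cfg$interferogram$e_r0)
    icfg <- interferogram_config(grid, e_r0 = cfg$interferogram$e_r0,
                                 camera_noise_var = cfg$interferogram$camera_noise_var)
    for (j in seq_len(nrow(illum$k))) {
      f <- complex_field(matrix(m$data[, j], grid$n, grid$n), grid, "position",
                         k_in = illum$k[j, ])
      frame <- synthesize_interferogram(f, illum$k[j, ], icfg,
                                        seed = cfg$seed + 10L + j)
      es <- to_lab_frame(hilbert_demodulate(frame), illum$k[j, ],
                         icfg$e_r0)
      m$data[, j] <- as.vector(es$field)
    }
  }

  before_pp <- to_position_basis(m, "in")
  img_before <- confocal_image(before_pp)
  tiles_used <- !all(cfg$correction$tile == 1L)
  if (tiles_used) {
    log_line("tiled correction %d x %d", cfg$correction$tile[1], cfg$correction$tile[2])
    layout <- tile_layout(cfg$correction$tile[1], cfg$correction$tile[2], grid,
                          cfg$correction$overlap)
    tiles <- segment_field(before_pp, layout)
    st <- correct_and_stitch(tiles, layout, tol = cfg$correction$tol,
                             max_iter = cfg$correction$max_iter)
    img_after <- st$image
    correction <- st
    trace <- NULL
  } else {
    log_line("CLASS correction (tol %.1e, max_iter %d)",
             cfg$correction$tol, cfg$correction$max_iter)
    correction <- run_class(m, tol = cfg$correction$tol,
                            max_iter = cfg$correction$max_iter)
    img_after <- confocal_image(correction$corrected)
    trace <- correction$intensity_trace
  }

  ## PSF metrology at the brightest corrected pixel
  pk <- which(img_after == max(img_after), arr.ind = TRUE)[1, ]
  x_ax <- position_axis(grid)
  r_pk <- c(x_ax[pk[1]], x_ax[pk[2]])
  metrics <- list(seed = cfg$seed, n_illuminations = nrow(illum$k),
                  total_intensity_before = sum(img_before),
                  total_intensity_after = sum(img_after))
  if (!tiles_used) {
    psf_b <- try(point_spread_function(m, r_pk), silent = TRUE)
    psf_a <- try(point_spread_function(
      to_wavevector_basis(correction$corrected, "in"), r_pk), silent = TRUE)
    if (!inherits(psf_b, "try-error") && !inherits(psf_a, "try-error")) {
      metrics$strehl_enhancement <- strehl_enhancement(psf_b, psf_a)
      metrics$psf_fwhm_nm_before <- psf_b$fwhm * 1e9
      metrics$psf_fwhm_nm_after <- psf_a$fwhm * 1e9
    }
    metrics$n_iterations <- correction$n_iterations
    metrics$converged <- correction$converged
    metrics$intensity_trace <- trace
  } else {
    metrics$tiles_failed <- sum(correction$failed)
  }

  vol <- NULL
  if (cfg$volume$enabled) {
    log_line("volumetric stack")
    diag_field <- if (tiles_used) {
      complex_field(sqrt(pmax(img_after, 0)) + 0i, grid, "position")
    } else {
      complex_field(confocal_diagonal(correction$corrected), grid, "position")
    }
    coarse <- cfg$volume$coarse_step_um * 1e-6
    depths <- seq(-cfg$volume$half_range_um, cfg$volume$half_range_um,
                  by = cfg$volume$coarse_step_um) * 1e-6
    slices <- lapply(depths, function(z)
      angular_spectrum_propagate(diag_field, z, max_dz = Inf))
    vol <- assemble_volume(slices, depths, cfg$volume$fine_step_um * 1e-6)
    metrics$volume_slices <- length(vol$z)
  }

  dir.create(cfg$output$dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(cfg$output$dir, "config.yaml"))
  if (cfg$output$tiff) {
    write_float_tiff(img_before, file.path(cfg$output$dir, "confocal_before.tiff"))
    write_float_tiff(img_after, file.path(cfg$output$dir, "confocal_after.tiff"))
    if (!tiles_used) {
      write_float_tiff(correction$theta_in$phase,
                       file.path(cfg$output$dir, "theta_in.tiff"))
      write_float_tiff(correction$theta_out$phase,
                       file.path(cfg$output$dir, "theta_out.tiff"))
    }
    if (!is.null(vol))
      write_float_tiff(max_intensity_projection(vol),
                       file.path(cfg$output$dir, "mip.tiff"))
  }
  jsonlite::write_json(metrics, file.path(cfg$output$dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(list(matrix = m, correction = correction, volume = vol,
               truth = list(specimen = specimen, phase_in = phase_in,
                            phase_out = phase_out, illum = illum)),
          file.path(cfg$output$dir, "results.rds"))
  log_line("done -> %s", cfg$output$dir)
  invisible(list(dir = cfg$output$dir, metrics = metrics, matrix = m,
                 correction = correction, volume = vol,
                 image_before = img_before, image_after = img_after))
}

#' Write an image as a normalized 32-bit float TIFF
#'
#' Preview export: the image is shifted/scaled to `[0, 1]`
#' (constant images map to 0) and written as a single-channel 32-bit float
#' TIFF. The applied offset and scale are returned invisibly.
#'
#' @param img Real matrix.
#' @param path Output file path.
#' @return Invisibly, `c(offset, scale)` with
#'   `stored = (img - offset) / scale`.
#' @export
write_float_tiff <- function(img, path) {
  lo <- min(img); hi <- max(img)
  sc <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((img - lo) / sc, path, bits.per.sample = 32L)
  invisible(c(offset = lo, scale = sc))
}
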