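#' Complex field map constructor
#'
#' A complex 2-D field on the sample grid, tagged with its basis and, when it
#' originates from one angle-scanned acquisition, the illumination wavevector
#' and gating time it belongs to.
#'
#' @param field Complex `n x n` matrix.
#' @param grid A [grid_spec()].
#' @param basis `"position"` or `"wavevector"`.
#' @param k_in Optional illumination wavevector `c(kx, ky)` (rad/m).
#' @param tau0 Gating time metadata (seconds; purely descriptive).
#' @return A `complex_field` object.
#' @export
complex_field <- function(field, grid, basis = "position", k_in = NULL, tau0 = 0) {
  basis <- match.arg(basis, c("position", "wavevector"))
  stopifnot(is.matrix(field), nrow(field) == grid$n, ncol(field) == grid$n)
  if (any(!is.finite(Re(field))) || any(!is.finite(Im(field))))
    stop("field contains non-finite values", call. = FALSE)
  structure(list(field = field, grid = grid, basis = basis,
                 k_in = k_in, tau0 = tau0),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d (%s basis), power %.4g\n",
              x$grid$n, x$grid$n, x$basis, sum(Mod(x$field)^2)))
  invisible(x)
}

#' Multiple-scattering noise specification
#'
#' @param gamma Ratio of multiple-scattering (speckle) power to
#'   single-scattering signal power; `gamma = 0` disables noise.
#' @param seed Integer seed for the noise draws.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(gamma = 0, seed = 0L) {
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  structure(list(gamma = gamma, seed = as.integer(seed)), class = "noise_spec")
}

#' Simulate the gated single-scattering field for one illumination
#'
#' Forward model for one angle-scanned acquisition: the specimen is
#' illuminated by the aberrated plane wave
#' `exp(-1i k_i . r) * exp(1i phase_in(k_i))`, multiplied by the complex
#' reflectivity, and the backscattered wave propagates through the output
#' pupil (binary NA mask times `exp(1i phase_out(k))`) to the image plane.
#' The result is the time-gated field `E_S(r_o; k_i, tau0)`, band-limited to
#' the output pupil and linear in the reflectivity.
#'
#' @param specimen A [make_specimen()] result.
#' @param phase_in,phase_out Input/output [pupil_phase()] screens.
#' @param k_i Illumination wavevector `c(kx, ky)` (rad/m); must lie inside
#'   the pupil.
#' @param grid A [grid_spec()] (must match all inputs).
#' @param tau0 Gating-time metadata attached to the output.
#' @return A position-basis [complex_field()].
#' @export
simulate_reflection_field <- function(specimen, phase_in, phase_out, k_i, grid,
                                      tau0 = 0) {
  if (!same_grid(specimen$grid, grid) || !same_grid(phase_in$grid, grid) ||
      !same_grid(phase_out$grid, grid))
    stop("specimen, screens and grid must share one grid_spec", call. = FALSE)
  if (sum(k_i^2) > pupil_radius(grid)^2 * (1 + 1e-9))
    stop("illumination wavevector lies outside the pupil", call. = FALSE)
  ## input aberration: a single phase at k_i (pure pupil model)
  phi_i <- phase_at(phase_in, grid, k_i)
  inc <- exp(-1i * (k_i[1] * position_grids(grid)$x +
                    k_i[2] * position_grids(grid)$y) + 1i * phi_i)
  P <- pupil_mask(grid) * exp(1i * phase_out$phase)
  f <- ifft2c(fft2c(specimen$reflectivity * inc) * P)
  complex_field(f, grid, "position", k_in = k_i, tau0 = tau0)
}

## Phase screen value at wavevector k (nearest node on the screen's grid).
phase_at <- function(screen, grid, k) {
  f <- frequency_axis(grid)
  i <- which.min(abs(f - k[1])); j <- which.min(abs(f - k[2]))
  screen$phase[i, j]
}

#' Assemble the time-gated reflection matrix
#'
#' Runs [simulate_reflection_field()] for every illumination in `illum` and
#' stacks the fields as columns of a reflection matrix with output basis
#' `position` (rows are the `n^2` camera pixels, column-major) and input
#' basis `wavevector` (one column per `k_i`). Multiple scattering is added
#' per column as an independent complex circular-Gaussian speckle field
#' band-limited to the output pupil, scaled so the expected noise power of
#' each column is `gamma` times that column's signal power.
#'
#' @param specimen,phase_in,phase_out,grid As in
#'   [simulate_reflection_field()].
#' @param illum An [sample_illumination_angles()] result.
#' @param noise A [noise_spec()].
#' @param tau0 Gating-time metadata.
#' @return A [reflection_matrix()].
#' @export
assemble_matrix <- function(specimen, phase_in, phase_out, illum, grid,
                            noise = noise_spec(0), tau0 = 0) {
  if (nrow(illum$k) < 1) stop("empty illumination set", call. = FALSE)
  n <- grid$n
  n_in <- nrow(illum$k)
  data <- matrix(0 + 0i, n * n, n_in)
  for (j in seq_len(n_in)) {
    f <- simulate_reflection_field(specimen, phase_in, phase_out,
                                   illum$k[j, ], grid, tau0)
    data[, j] <- as.vector(f$field)
  }
  if (noise$gamma > 0) {
    m <- pupil_mask(grid)
    n_nodes <- sum(m)
    data <- with_seed(noise$seed, {
      for (j in seq_len(n_in)) {
        g <- matrix(stats::rnorm(n * n) + 1i * stats::rnorm(n * n), n, n)
        sp <- ifft2c(g * m)                      # expected power 2 * n_nodes
        p_sig <- sum(Mod(data[, j])^2)
        data[, j] <- data[, j] +
          as.vector(sp) * sqrt(noise$gamma * p_sig / (2 * n_nodes))
      }
      data
    })
  }
  reflection_matrix(data, grid, basis_out = "position", basis_in = "wavevector",
                    k_in = illum$k, tau0 = tau0)
}

#' Off-axis interferogram acquisition parameters
#'
#' The rotating reference wave is `E_R0 * exp(-1i (k_i + k_DG) . r)`: the
#' reference co-rotates with the illumination and carries the grating
#' carrier `k_DG`. Sideband separation demands `|k_DG| > 2 k0 NA` so the
#' carrier band and its conjugate never overlap on the camera spectrum; the
#' constructor enforces this. Frames are synthesized on a camera grid twice
#' as fine as the sample grid (same physical extent) so the carrier band
#' fits inside the camera Nyquist range.
#'
#' @param grid Sample-plane [grid_spec()].
#' @param k_dg Carrier wavevector `c(kx, ky)` (rad/m). Default: 4.2 pupil
#'   radii along x, snapped to a camera frequency node, which clears the DC
#'   band (radius `2 k0 NA`) for the full demodulation window while staying
#'   inside the camera Nyquist range at any Nyquist-valid pixel pitch.
#' @param e_r0 Reference amplitude (> 0 unless explicitly 0 for diagnostics).
#' @param camera_noise_var Variance of additive Gaussian camera noise
#'   (counts^2).
#' @return An `interferogram_config`.
#' @export
interferogram_config <- function(grid, k_dg = NULL, e_r0 = 1,
                                 camera_noise_var = 0) {
  cam <- camera_grid(grid)
  if (is.null(k_dg)) k_dg <- snap_to_grid(cam, c(4.2 * pupil_radius(grid), 0))
  if (sqrt(sum(k_dg^2)) <= 2 * pupil_radius(grid))
    stop("sideband separation violated: need |k_DG| > 2 k0 NA", call. = FALSE)
  kmax_cam <- pi / cam$pitch
  if (sqrt(sum(k_dg^2)) + 2 * pupil_radius(grid) > kmax_cam)
    stop("carrier band exceeds the camera Nyquist range", call. = FALSE)
  if (e_r0 < 0) stop("reference amplitude must be >= 0", call. = FALSE)
  structure(list(k_dg = k_dg, e_r0 = e_r0,
                 camera_noise_var = camera_noise_var, grid = grid),
            class = "interferogram_config")
}

## Camera sampling: 2x finer pitch, same physical extent as the sample grid.
camera_grid <- function(grid) {
  grid_spec(2L * grid$n, grid$pitch / 2, grid$wavelength, grid$na, grid$n_medium)
}

## Exact band-limited resampling between sample and camera grids.
upsample_field <- function(f, grid, cam) {
  n <- grid$n; N <- cam$n
  sp <- fft2c(f)
  big <- matrix(0 + 0i, N, N)
  o <- (N - n) / 2
  big[(o + 1):(o + n), (o + 1):(o + n)] <- sp
  ifft2c(big) * (N / n)
}

crop_spectrum <- function(sp_cam, cam, grid) {
  n <- grid$n; N <- cam$n
  o <- (N - n) / 2
  sp_cam[(o + 1):(o + n), (o + 1):(o + n)] * (n / N)
}

#' Synthesize a rotating-reference off-axis interferogram
#'
#' Camera frame `I(r_o) = |E_S(r_o) + E_R(r_o)|^2` with
#' `E_R = E_R0 exp(-1i (k_i + k_DG) . r_o)`, evaluated on the camera grid
#' (the band-limited field is resampled exactly), plus optional additive
#' Gaussian camera noise.
#'
#' @param field Position-basis [complex_field()] `E_S` on the sample grid.
#' @param k_i Illumination wavevector of this frame (rad/m).
#' @param cfg An [interferogram_config()].
#' @param seed Seed for the camera-noise draw.
#' @return An `interferogram`: list with `frame` (real camera matrix),
#'   `camera_grid`, `grid` (sample grid), `cfg`, `k_in`.
#' @export
synthesize_interferogram <- function(field, k_i, cfg, seed = 0L) {
  grid <- field$grid
  stopifnot(field$basis == "position")
  cam <- camera_grid(grid)
  es <- upsample_field(field$field, grid, cam)
  pg <- position_grids(cam)
  er <- cfg$e_r0 * exp(-1i * ((k_i[1] + cfg$k_dg[1]) * pg$x +
                              (k_i[2] + cfg$k_dg[2]) * pg$y))
  frame <- Mod(es + er)^2
  if (cfg$camera_noise_var > 0)
    frame <- frame + with_seed(seed,
      matrix(stats::rnorm(cam$n^2, 0, sqrt(cfg$camera_noise_var)), cam$n, cam$n))
  structure(list(frame = frame, camera_grid = cam, grid = grid,
                 cfg = cfg, k_in = k_i),
            class = "interferogram")
}

#' @export
print.interferogram <- function(x, ...) {
  cat(sprintf("<interferogram> %d x %d camera px, |k_DG| = %.3g rad/m\n",
              x$camera_grid$n, x$camera_grid$n, sqrt(sum(x$cfg$k_dg^2))))
  invisible(x)
}
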