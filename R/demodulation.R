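#' Demodulate an off-axis interferogram (Hilbert transform about the carrier)
#'
#' Recovers the rotating-reference-frame complex field map
#' `E_GM(r_o; k_i, tau0)` from a camera frame: the frame spectrum is
#' windowed in a disk of `band_radius` about the carrier `+k_DG`, recentred
#' so the carrier maps to zero frequency, and resampled onto the sample
#' grid. On noise-free synthetic frames this satisfies
#' `E_GM = E_S * Conj(E_R0 * exp(-1i k_i . r_o))`.
#'
#' The window must clear the autocorrelation (DC) term, whose band has
#' radius `2 k0 NA`: the call fails unless
#' `band_radius + 2 k0 NA <= |k_DG|`.
#'
#' @param frame An `interferogram` from [synthesize_interferogram()], or a
#'   real camera matrix (then `grid` must be given and is the sample grid).
#' @param k_dg Carrier wavevector (rad/m); defaults to the one recorded in
#'   the frame's configuration.
#' @param band_radius Sideband window radius (rad/m); default `2 k0 NA`,
#'   the full signal band of the co-rotating acquisition.
#' @param grid Sample [grid_spec()] when `frame` is a bare matrix.
#' @return A position-basis [complex_field()] holding `E_GM` on the sample
#'   grid.
#' @export
hilbert_demodulate <- function(frame, k_dg = NULL, band_radius = NULL,
                               grid = NULL) {
  if (inherits(frame, "interferogram")) {
    cam <- frame$camera_grid
    grid <- frame$grid
    if (is.null(k_dg)) k_dg <- frame$cfg$k_dg
    mat <- frame$frame
  } else {
    if (is.null(grid) || is.null(k_dg))
      stop("bare frames need `grid` and `k_dg`", call. = FALSE)
    cam <- camera_grid(grid)
    mat <- frame
    stopifnot(nrow(mat) == cam$n)
  }
  kna <- pupil_radius(grid)
  if (is.null(band_radius)) band_radius <- 2 * kna
  if (band_radius + 2 * kna > sqrt(sum(k_dg^2)) * (1 + 1e-9))
    stop(sprintf(paste0("sideband window overlaps the DC term: need ",
                        "band_radius + 2*k0*NA <= |k_DG| ",
                        "(%.3g + %.3g > %.3g rad/m)"),
                 band_radius, 2 * kna, sqrt(sum(k_dg^2))), call. = FALSE)
  sp <- fft2c(mat + 0i)
  fg <- frequency_grids(cam)
  win <- ((fg$kx - k_dg[1])^2 + (fg$ky - k_dg[2])^2) <= band_radius^2 * (1 + 1e-12)
  sp <- sp * win
  ## recentre: shift spectrum so +k_DG maps to zero frequency (k_DG is on
  ## camera frequency nodes, so this is an exact circular index shift)
  db <- frequency_bin(cam)
  si <- round(k_dg[1] / db); sj <- round(k_dg[2] / db)
  N <- cam$n
  sp <- sp[((seq_len(N) - 1 + si) %% N) + 1, ((seq_len(N) - 1 + sj) %% N) + 1]
  e_gm <- ifft2c(crop_spectrum(sp, cam, grid))
  complex_field(e_gm, grid, "position",
                k_in = if (inherits(frame, "interferogram")) frame$k_in else NULL)
}

#' Convert a rotating-reference field map to the laboratory frame
#'
#' Normalizes out the conjugated reference factor
#' `Conj(E_R0 exp(-1i k_i . r_o))` contained in `E_GM`, returning the
#' laboratory-frame backscattered field
#' `E_S(r_o; k_i, tau0) = E_GM * exp(-1i k_i . r_o) / E_R0`.
#'
#' @param e_gm A position-basis [complex_field()] from
#'   [hilbert_demodulate()].
#' @param k_i Illumination wavevector of the frame (rad/m); defaults to the
#'   one recorded in `e_gm`.
#' @param e_r0 Reference amplitude (> 0).
#' @return A position-basis [complex_field()] holding `E_S`.
#' @export
to_lab_frame <- function(e_gm, k_i = NULL, e_r0 = 1) {
  if (e_r0 <= 0) stop("reference amplitude must be > 0", call. = FALSE)
  if (is.null(k_i)) k_i <- e_gm$k_in
  if (is.null(k_i)) stop("illumination wavevector unknown", call. = FALSE)
  r <- ramp_matrix(e_gm$grid, k_i)
  complex_field(e_gm$field * Conj(r) / e_r0, e_gm$grid, "position",
                k_in = k_i, tau0 = e_gm$tau0)
}

#' Estimate illumination wavevectors from diffusive-sample calibration fields
#'
#' Given demodulated field maps `E_GM` recorded on a diffusive scattering
#' sample, estimates the residual carrier `k_i` of each frame. The spectrum
#' of a diffuse `E_GM` is the pupil disk translated by `k_i` filled with
#' speckle, so the centre is located by correlating the spectral support
#' with the pupil-disk template and refining the correlation peak by
#' quadratic interpolation over 3 x 3 bins; point-like spectra (e.g. a pure
#' phase ramp) fall back to the intensity-weighted centroid.
#'
#' @param calib_frames List of position-basis [complex_field()] maps sharing
#'   one grid.
#' @param confidence_min Minimum accepted peak-to-background ratio of the
#'   template-correlation peak.
#' @return List of `carrier_estimate` objects: `k_hat` (`c(kx, ky)`, rad/m)
#'   and `confidence`.
#' @export
estimate_illumination_wavevector <- function(calib_frames, confidence_min = 2) {
  if (length(calib_frames) < 1) stop("need at least one frame", call. = FALSE)
  grid <- calib_frames[[1]]$grid
  fg <- frequency_grids(grid)
  f <- frequency_axis(grid)
  db <- frequency_bin(grid)
  tmpl <- (fg$kx^2 + fg$ky^2) <= pupil_radius(grid)^2 * (1 + 1e-12)
  tmpl_sp <- fft2c(tmpl + 0i)
  lapply(calib_frames, function(cf) {
    stopifnot(same_grid(cf$grid, grid))
    sp2 <- Mod(fft2c(cf$field))^2
    supp <- sp2 > 0.05 * max(sp2)
    if (sum(supp) <= 9) {
      w <- sp2 / sum(sp2)
      k_hat <- c(sum(w * fg$kx), sum(w * fg$ky))
      conf <- max(sp2) / max(mean(sp2[!supp]), .Machine$double.eps)
    } else {
      ## correlation of support with disk template via FFT (circular)
      corr <- Re(ifft2c(fft2c(supp + 0i) * Conj(tmpl_sp))) * grid$n
      pk <- which(corr == max(corr), arr.ind = TRUE)[1, ]
      refine <- function(v) {
        den <- v[1] - 2 * v[2] + v[3]
        if (den >= 0) 0 else max(min((v[1] - v[3]) / (2 * den), 0.5), -0.5)
      }
      i <- pk[1]; j <- pk[2]
      di <- if (i > 1 && i < grid$n) refine(corr[(i - 1):(i + 1), j]) else 0
      dj <- if (j > 1 && j < grid$n) refine(corr[i, (j - 1):(j + 1)]) else 0
      k_hat <- c(f[i] + di * db, f[j] + dj * db)
      conf <- max(corr) / max(mean(abs(corr)), .Machine$double.eps)
    }
    if (conf < confidence_min)
      stop(sprintf("no spectral peak above the confidence threshold (%.2f < %.2f)",
                   conf, confidence_min), call. = FALSE)
    if (sum(k_hat^2) > pupil_radius(grid)^2 * (1 + 1e-6))
      stop("estimated carrier falls outside the pupil support", call. = FALSE)
    structure(list(k_hat = k_hat, confidence = conf), class = "carrier_estimate")
  })
}
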