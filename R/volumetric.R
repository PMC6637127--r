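#' Angular-spectrum numerical refocusing
#'
#' Propagates a complex field by a signed axial distance `dz` with the exact
#' (non-paraxial) scalar kernel: the spectrum is multiplied by
#' `exp(1i dz sqrt((n_medium k0)^2 - |k|^2))` on propagating modes and
#' evanescent modes are set to zero. The operation is unitary on the
#' propagating band, so `propagate(dz)` then `propagate(-dz)` is the
#' identity there.
#'
#' @param field A position-basis [complex_field()].
#' @param dz Signed propagation distance in metres.
#' @param max_dz Validity bound (metres): refocusing beyond roughly half the
#'   coherence-gate half-width no longer represents the gated field; a
#'   warning (not an error) is raised past it. Default 7.5e-6.
#' @return The propagated position-basis [complex_field()].
#' @export
angular_spectrum_propagate <- function(field, dz, max_dz = 7.5e-6) {
  stopifnot(inherits(field, "complex_field"), field$basis == "position")
  if (abs(dz) > max_dz)
    warning(sprintf("|dz| = %.3g m exceeds the refocusing validity bound %.3g m",
                    abs(dz), max_dz))
  grid <- field$grid
  fg <- frequency_grids(grid)
  kn2 <- (grid$n_medium * k0_of(grid))^2
  kr2 <- fg$kx^2 + fg$ky^2
  prop <- kr2 <= kn2
  kz <- sqrt(pmax(kn2 - kr2, 0))
  kernel <- matrix(0 + 0i, grid$n, grid$n)
  kernel[prop] <- exp(1i * dz * kz[prop])
  complex_field(ifft2c(fft2c(field$field) * kernel), grid, "position",
                k_in = field$k_in, tau0 = field$tau0)
}

#' Assemble a fine-stepped volumetric stack from coarse recorded slices
#'
#' Between consecutive recorded depths, intermediate slices are produced by
#' angular-spectrum propagation from the nearer recorded slice (ties go to
#' the shallower one), and intensities are stored at every fine depth.
#'
#' @param slices List of position-basis [complex_field()] slices (e.g.
#'   corrected confocal amplitudes), one per recorded depth.
#' @param depths Strictly increasing numeric vector of recorded depths
#'   (metres), one per slice, uniformly spaced.
#' @param fine_step Fill-in step (metres); the coarse step must be an
#'   integer multiple of it.
#' @return A `volume_stack`: list with `z` (fine depths), `intensity`
#'   (list of real images), `grid`, and the generating steps.
#' @export
assemble_volume <- function(slices, depths, fine_step) {
  if (length(slices) != length(depths))
    stop("one depth per slice required", call. = FALSE)
  if (length(depths) > 1 && any(diff(depths) <= 0))
    stop("recorded depths must be strictly increasing", call. = FALSE)
  grid <- slices[[1]]$grid
  if (length(slices) == 1) {
    return(structure(list(z = depths, intensity = list(Mod(slices[[1]]$field)^2),
                          grid = grid, coarse_step = NA_real_,
                          fine_step = fine_step), class = "volume_stack"))
  }
  coarse <- diff(depths)
  if (any(abs(coarse - coarse[1]) > 1e-9 * coarse[1]))
    stop("recorded depths must be uniformly spaced", call. = FALSE)
  coarse <- coarse[1]
  m <- coarse / fine_step
  if (abs(m - round(m)) > 1e-9)
    stop("coarse step must be an integer multiple of the fine step", call. = FALSE)
  m <- round(m)
  z <- seq(depths[1], depths[length(depths)], by = fine_step)
  intensity <- vector("list", length(z))
  for (i in seq_along(z)) {
    j <- which.min(abs(depths - z[i]))        # nearer recorded slice
    dz <- z[i] - depths[j]
    f <- if (dz == 0) slices[[j]]
         else angular_spectrum_propagate(slices[[j]], dz, max_dz = coarse)
    intensity[[i]] <- Mod(f$field)^2
  }
  structure(list(z = z, intensity = intensity, grid = grid,
                 coarse_step = coarse, fine_step = fine_step),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  cat(sprintf("<volume_stack> %d slices, z %.1f to %.1f um (step %.2f um)\n",
              length(x$z), min(x$z) * 1e6, max(x$z) * 1e6,
              if (length(x$z) > 1) diff(x$z[1:2]) * 1e6 else NA))
  invisible(x)
}

#' Maximum-intensity projection over a depth range
#'
#' Pixelwise maximum of the stack slices whose depths fall in
#' `[z_min, z_max]`.
#'
#' @param stack A [assemble_volume()] result.
#' @param z_min,z_max Depth range bounds (metres, inclusive).
#' @return A real image matrix.
#' @export
max_intensity_projection <- function(stack, z_min = -Inf, z_max = Inf) {
  sel <- which(stack$z >= z_min & stack$z <= z_max)
  if (length(sel) == 0)
    stop("depth range does not intersect the stack", call. = FALSE)
  Reduce(pmax, stack$intensity[sel])
}
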