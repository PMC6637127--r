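#' Time-gated reflection matrix
#'
#' Container for the complex matrix `E(output mode; input mode)` of elastic
#' backscattering at a fixed optical path delay. Rows are output modes,
#' columns input modes. Each axis carries a basis tag:
#'
#' * output `"position"`: rows are the `n^2` camera pixels (column-major over
#'   the `n x n` grid); output `"wavevector"`: rows are the pupil frequency
#'   nodes in `which(pupil_mask(grid))` order.
#' * input `"wavevector"`: one column per illumination wavevector in `k_in`;
#'   input `"position"`: columns are the `n^2` illumination positions `r_i`
#'   on the pixel grid (the transform zero-fills pupil nodes that were not
#'   sampled when `N_in` is below the pupil-node count).
#'
#' Basis transforms are unitary, so `sum(|data|^2)` is preserved for
#' pupil-band-limited data and round trips are exact.
#'
#' @param data Complex matrix, rows = output modes, columns = input modes.
#' @param grid A [grid_spec()].
#' @param basis_out,basis_in `"position"` or `"wavevector"`.
#' @param k_in For input wavevector basis: `N_in x 2` matrix of illumination
#'   wavevectors (rad/m), on frequency-grid nodes.
#' @param tau0 Gating-time metadata.
#' @return A `reflection_matrix` object.
#' @export
reflection_matrix <- function(data, grid, basis_out = "position",
                              basis_in = "wavevector", k_in = NULL, tau0 = 0) {
  basis_out <- match.arg(basis_out, c("position", "wavevector"))
  basis_in <- match.arg(basis_in, c("position", "wavevector"))
  n_nodes <- sum(pupil_mask(grid))
  rows_want <- if (basis_out == "position") grid$n^2 else n_nodes
  if (nrow(data) != rows_want)
    stop(sprintf("row count %d inconsistent with output basis '%s' (want %d)",
                 nrow(data), basis_out, rows_want), call. = FALSE)
  if (basis_in == "wavevector") {
    if (is.null(k_in) || nrow(k_in) != ncol(data))
      stop("input wavevector basis needs one k_in row per column", call. = FALSE)
  } else if (ncol(data) != grid$n^2) {
    stop("input position basis needs n^2 columns", call. = FALSE)
  }
  structure(list(data = data, grid = grid, basis_out = basis_out,
                 basis_in = basis_in, k_in = k_in, tau0 = tau0),
            class = "reflection_matrix")
}

#' @export
print.reflection_matrix <- function(x, ...) {
  cat(sprintf("<reflection_matrix> %d x %d (out: %s, in: %s), %d x %d px grid\n",
              nrow(x$data), ncol(x$data), x$basis_out, x$basis_in,
              x$grid$n, x$grid$n))
  invisible(x)
}

## column indices of pupil nodes in the vectorized n x n frequency grid
pupil_linear_index <- function(grid) which(pupil_mask(grid))

## map on-grid wavevectors to linear indices in the vectorized frequency grid
k_linear_index <- function(grid, k) {
  f <- frequency_axis(grid)
  db <- frequency_bin(grid)
  i <- round((k[, 1] - f[1]) / db) + 1
  j <- round((k[, 2] - f[1]) / db) + 1
  if (any(i < 1 | i > grid$n | j < 1 | j > grid$n) ||
      any(abs(k[, 1] - f[i]) > 1e-6 * db) || any(abs(k[, 2] - f[j]) > 1e-6 * db))
    stop("illumination wavevectors must lie on frequency-grid nodes", call. = FALSE)
  (j - 1) * grid$n + i
}

#' Transform reflection-matrix axes to the wavevector basis
#'
#' Applies the unitary centred 2-D DFT along the selected axis and restricts
#' the result to the pupil support (output axis) or to the full pupil-node
#' set (input axis).
#'
#' @param m A [reflection_matrix()].
#' @param axis `"out"`, `"in"`, or `"both"`.
#' @return A [reflection_matrix()] with updated basis tags.
#' @export
to_wavevector_basis <- function(m, axis = c("both", "in", "out")) {
  axis <- match.arg(axis)
  if (axis %in% c("out", "both")) {
    if (m$basis_out == "wavevector") {
      if (axis == "out") warning("output axis already in wavevector basis; no-op")
    } else {
      n <- m$grid$n
      idx <- pupil_linear_index(m$grid)
      out <- matrix(0 + 0i, length(idx), ncol(m$data))
      for (j in seq_len(ncol(m$data)))
        out[, j] <- fft2c(matrix(m$data[, j], n, n))[idx]
      m$data <- out
      m$basis_out <- "wavevector"
    }
  }
  if (axis %in% c("in", "both")) {
    if (m$basis_in == "wavevector") {
      if (axis == "in") warning("input axis already in wavevector basis; no-op")
    } else {
      n <- m$grid$n
      nodes <- pupil_nodes(m$grid)
      idx <- pupil_linear_index(m$grid)
      out <- matrix(0 + 0i, nrow(m$data), length(idx))
      for (r in seq_len(nrow(m$data)))
        out[r, ] <- fft2c(matrix(m$data[r, ], n, n))[idx]
      m$data <- out
      m$basis_in <- "wavevector"
      m$k_in <- nodes
    }
  }
  m
}

#' Transform reflection-matrix axes to the position basis
#'
#' Inverse of [to_wavevector_basis()]. Along the input axis, wavevector
#' columns are embedded at their frequency nodes (zero-filling pupil nodes
#' that were not sampled) and the unitary inverse DFT synthesizes one column
#' per illumination position `r_i` on the pixel grid.
#'
#' @inheritParams to_wavevector_basis
#' @return A [reflection_matrix()] with updated basis tags.
#' @export
to_position_basis <- function(m, axis = c("both", "in", "out")) {
  axis <- match.arg(axis)
  n <- m$grid$n
  if (axis %in% c("in", "both")) {
    if (m$basis_in == "position") {
      if (axis == "in") warning("input axis already in position basis; no-op")
    } else {
      cols <- k_linear_index(m$grid, m$k_in)
      out <- matrix(0 + 0i, nrow(m$data), n * n)
      buf <- matrix(0 + 0i, n, n)
      for (r in seq_len(nrow(m$data))) {
        buf[] <- 0 + 0i
        buf[cols] <- m$data[r, ]
        out[r, ] <- ifft2c(buf)
      }
      m$data <- out
      m$basis_in <- "position"
      m$k_in <- NULL
    }
  }
  if (axis %in% c("out", "both")) {
    if (m$basis_out == "position") {
      if (axis == "out") warning("output axis already in position basis; no-op")
    } else {
      idx <- pupil_linear_index(m$grid)
      out <- matrix(0 + 0i, n * n, ncol(m$data))
      buf <- matrix(0 + 0i, n, n)
      for (j in seq_len(ncol(m$data))) {
        buf[] <- 0 + 0i
        buf[idx] <- m$data[, j]
        out[, j] <- ifft2c(buf)
      }
      m$data <- out
      m$basis_out <- "position"
    }
  }
  m
}

#' Time-gated confocal image from the matrix diagonal
#'
#' The confocal image is formed from matrix elements with detection position
#' equal to illumination position:
#' `image(r) = |E(r_o = r; r_i = r)|^2`.
#'
#' @param m A [reflection_matrix()] with both axes in the position basis.
#' @return A real nonnegative `n x n` matrix.
#' @export
confocal_image <- function(m) {
  if (m$basis_out != "position" || m$basis_in != "position")
    stop("confocal_image needs both axes in the position basis", call. = FALSE)
  n <- m$grid$n
  d <- m$data[cbind(seq_len(n * n), seq_len(n * n))]
  matrix(Mod(d)^2, n, n)
}

## complex confocal diagonal amplitude (internal)
confocal_diagonal <- function(m) {
  n <- m$grid$n
  matrix(m$data[cbind(seq_len(n * n), seq_len(n * n))], n, n)
}

#' Point-spread function at a chosen illumination position
#'
#' Extracts the intensity map across `r_o` at a selected `r_i` and measures
#' its full width at half maximum along a grid axis, on a profile through
#' the sub-pixel peak with cubic-spline interpolation at `upsample`-fold
#' resolution.
#'
#' @param m A [reflection_matrix()] with output axis in the position basis;
#'   the input axis may be in either basis (a wavevector-basis input column
#'   is synthesized at `r_i` directly).
#' @param r_i Illumination position `c(x, y)` in metres (grid centre = 0).
#' @param axis Profile axis: 1 (default, the horizontal/x grid axis) or 2.
#' @param upsample Interpolation factor for the FWHM measurement (>= 10).
#' @return A `psf_estimate`: list with `intensity` (`n x n`), `peak`,
#'   `peak_location` (metres, sub-pixel), `fwhm` (metres), `axis`, `grid`.
#' @export
point_spread_function <- function(m, r_i = c(0, 0), axis = 1L, upsample = 20L) {
  if (m$basis_out != "position")
    stop("output axis must be in the position basis", call. = FALSE)
  n <- m$grid$n
  if (m$basis_in == "wavevector") {
    ph <- exp(1i * (m$k_in[, 1] * r_i[1] + m$k_in[, 2] * r_i[2]))
    col <- as.vector(m$data %*% ph) / n
  } else {
    x <- position_axis(m$grid)
    i <- which.min(abs(x - r_i[1])); j <- which.min(abs(x - r_i[2]))
    col <- m$data[, (j - 1) * n + i]
  }
  intensity <- matrix(Mod(col)^2, n, n)
  psf_from_intensity(intensity, m$grid, axis = axis, upsample = upsample)
}

## FWHM metrology on an intensity map (shared with tests and pipeline).
psf_from_intensity <- function(intensity, grid, axis = 1L, upsample = 20L) {
  n <- grid$n
  upsample <- max(10L, as.integer(upsample))
  pk <- which(intensity == max(intensity), arr.ind = TRUE)[1, ]
  if (max(intensity) <= 0 ||
      stats::sd(intensity) < 1e-14 * max(abs(intensity), 1))
    stop("flat (peakless) intensity map: PSF metrology impossible", call. = FALSE)
  if (any(pk == 1L) || any(pk == n))
    stop("PSF peak at the grid border: metrology unreliable", call. = FALSE)
  sub <- function(v) { # 3-point parabolic sub-pixel offset, clamped
    d <- (v[1] - v[3]) / (2 * (v[1] - 2 * v[2] + v[3]))
    if (!is.finite(d)) d <- 0
    max(min(d, 0.5), -0.5)
  }
  di <- sub(intensity[(pk[1] - 1):(pk[1] + 1), pk[2]])
  dj <- sub(intensity[pk[1], (pk[2] - 1):(pk[2] + 1)])
  peak_px <- c(pk[1] + di, pk[2] + dj)
  x <- position_axis(grid)
  peak_loc <- c(stats::approx(seq_len(n), x, peak_px[1])$y,
                stats::approx(seq_len(n), x, peak_px[2])$y)
  ## profile along `axis` through the sub-pixel peak on the other axis
  if (axis == 1L) {
    prof <- vapply(seq_len(n), function(i)
      stats::spline(seq_len(n), intensity[i, ], xout = peak_px[2])$y, 0)
    fine0 <- peak_px[1]
  } else {
    prof <- vapply(seq_len(n), function(j)
      stats::spline(seq_len(n), intensity[, j], xout = peak_px[1])$y, 0)
    fine0 <- peak_px[2]
  }
  fine_x <- seq(1, n, by = 1 / upsample)
  fine <- stats::spline(seq_len(n), prof, xout = fine_x)$y
  pk_val <- max(fine)
  half <- pk_val / 2
  ipk <- which.max(fine)
  left <- which(fine[seq_len(ipk)] < half)
  right <- which(fine[ipk:length(fine)] < half) + ipk - 1
  if (length(left) == 0 || length(right) == 0)
    stop("PSF half-maximum not bracketed on the grid", call. = FALSE)
  l0 <- max(left)                       # last below-half sample left of peak
  r0 <- min(right)                      # first below-half sample right of peak
  xl <- fine_x[l0] + (half - fine[l0]) / (fine[l0 + 1] - fine[l0]) / upsample
  xr <- fine_x[r0 - 1] + (half - fine[r0 - 1]) / (fine[r0] - fine[r0 - 1]) / upsample
  structure(list(intensity = intensity, peak = pk_val,
                 peak_location = peak_loc,
                 fwhm = (xr - xl) * grid$pitch, axis = axis, grid = grid),
            class = "psf_estimate")
}

#' @export
print.psf_estimate <- function(x, ...) {
  cat(sprintf("<psf_estimate> peak %.4g at (%.2f, %.2f) um, FWHM %.1f nm (axis %d)\n",
              x$peak, x$peak_location[1] * 1e6, x$peak_location[2] * 1e6,
              x$fwhm * 1e9, x$axis))
  invisible(x)
}

#' Strehl-ratio enhancement between two PSF estimates
#'
#' The ratio of peak intensities after and before aberration correction,
#' for PSFs extracted at the same illumination position and normalization.
#'
#' @param before,after [point_spread_function()] results.
#' @return The scalar peak ratio `after$peak / before$peak`.
#' @export
strehl_enhancement <- function(before, after) {
  if (before$peak == 0) stop("pre-correction PSF peak is zero", call. = FALSE)
  after$peak / before$peak
}
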