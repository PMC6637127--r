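#' Acquisition grid specification
#'
#' Defines the common discrete geometry shared by every stage: a square
#' sample-plane pixel grid together with the optical constants that fix the
#' pupil. All wavevector-domain quantities live on the discrete Fourier grid
#' of this position grid, with the origin at the array centre
#' (index `n/2 + 1`), and the pupil is the set of frequency nodes with
#' `|k| <= k0 * NA` where `k0 = 2*pi/wavelength`.
#'
#' @param n Number of pixels per side; must be even.
#' @param pitch Sample-plane pixel pitch in metres. Must satisfy
#'   `pitch <= wavelength / (4 * na)` so the double-pass intensity
#'   point-spread function is Nyquist sampled.
#' @param wavelength Centre wavelength in metres (default 515 nm).
#' @param na Numerical aperture of the objective, in (0, 1].
#' @param n_medium Refractive index of the immersion/sample medium,
#'   used by numerical refocusing (default 1.33).
#'
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(64, 80e-9)
#' sum(pupil_mask(g))   # number of resolvable pupil nodes
#' @export
grid_spec <- function(n, pitch, wavelength = 515e-9, na = 0.8, n_medium = 1.33) {
  if (length(n) != 1L || n <= 0 || n %% 2 != 0)
    stop("`n` must be a single positive even integer", call. = FALSE)
  if (na <= 0 || na > 1) stop("`na` must lie in (0, 1]", call. = FALSE)
  if (pitch <= 0 || wavelength <= 0) stop("lengths must be positive", call. = FALSE)
  if (pitch > wavelength / (4 * na) + 1e-15)
    stop(sprintf("pixel pitch %.3g m violates Nyquist bound wavelength/(4 NA) = %.3g m",
                 pitch, wavelength / (4 * na)), call. = FALSE)
  structure(
    list(n = as.integer(n), pitch = pitch, wavelength = wavelength,
         na = na, n_medium = n_medium),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d px, pitch %.1f nm, lambda %.1f nm, NA %.2f, n %.2f\n",
              x$n, x$n, x$pitch * 1e9, x$wavelength * 1e9, x$na, x$n_medium))
  invisible(x)
}

#' @rdname grid_spec
#' @param grid A `grid_spec`.
#' @export
k0_of <- function(grid) 2 * pi / grid$wavelength

#' @rdname grid_spec
#' @export
pupil_radius <- function(grid) k0_of(grid) * grid$na

## Centered spatial axis: x_j = (j - 1 - n/2) * pitch, origin at index n/2+1.
position_axis <- function(grid) (seq_len(grid$n) - 1 - grid$n / 2) * grid$pitch

## Centered frequency axis (rad/m): k_j = 2*pi*(j - 1 - n/2) / (n*pitch).
frequency_axis <- function(grid) {
  2 * pi * (seq_len(grid$n) - 1 - grid$n / 2) / (grid$n * grid$pitch)
}

## Frequency-node spacing (one "bin") in rad/m.
frequency_bin <- function(grid) 2 * pi / (grid$n * grid$pitch)

## n x n matrices of kx (varies along rows) and ky (along columns).
frequency_grids <- function(grid) {
  f <- frequency_axis(grid)
  list(kx = matrix(f, grid$n, grid$n), ky = matrix(f, grid$n, grid$n, byrow = TRUE))
}

position_grids <- function(grid) {
  x <- position_axis(grid)
  list(x = matrix(x, grid$n, grid$n), y = matrix(x, grid$n, grid$n, byrow = TRUE))
}

#' Pupil support mask
#'
#' Logical matrix over the centred frequency grid, `TRUE` at nodes with
#' `|k| <= k0 * NA`.
#'
#' @param grid A [grid_spec()].
#' @return An `n x n` logical matrix.
#' @export
pupil_mask <- function(grid) {
  fg <- frequency_grids(grid)
  (fg$kx^2 + fg$ky^2) <= pupil_radius(grid)^2 * (1 + 1e-12)
}

## fftshift permutation for even n (self-inverse).
shift_index <- function(n) c((n / 2 + 1):n, 1:(n / 2))

## Unitary centred 2-D DFT: origin of both domains at index n/2+1.
fft2c <- function(a) {
  n <- nrow(a); s <- shift_index(n)
  a <- a[s, s, drop = FALSE]
  a <- stats::fft(a) / n
  a[s, s, drop = FALSE]
}

ifft2c <- function(a) {
  n <- nrow(a); s <- shift_index(n)
  a <- a[s, s, drop = FALSE]
  a <- stats::fft(a, inverse = TRUE) / n
  a[s, s, drop = FALSE]
}

#' Wrap phases to the principal interval
#'
#' Maps phase values (radians) to (-pi, pi].
#'
#' @param x Numeric array of phases in radians.
#' @return Array of the same shape, wrapped.
#' @export
wrap_phase <- function(x) Arg(exp(1i * x))

## Plane-wave ramp exp(+1i * (kx*x + ky*y)) as an n x n matrix.
ramp_matrix <- function(grid, k) {
  pg <- position_grids(grid)
  exp(1i * (k[1] * pg$x + k[2] * pg$y))
}

## Coordinates (m) of every pupil node, ordered as which(mask) (column-major).
pupil_nodes <- function(grid) {
  m <- pupil_mask(grid)
  fg <- frequency_grids(grid)
  cbind(kx = fg$kx[m], ky = fg$ky[m])
}

## Snap a wavevector to the nearest frequency-grid node; returns c(kx, ky).
snap_to_grid <- function(grid, k) {
  f <- frequency_axis(grid)
  c(f[which.min(abs(f - k[1]))], f[which.min(abs(f - k[2]))])
}

is_on_grid <- function(grid, k, tol = 1e-6) {
  db <- frequency_bin(grid)
  all(abs(k - snap_to_grid(grid, k)) < tol * db)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("n", "pitch", "wavelength", "na")],
                   unclass(b)[c("n", "pitch", "wavelength", "na")],
                   tolerance = 1e-9))
}
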