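#' Generate a synthetic specimen reflectivity map
#'
#' Produces a complex reflectivity `O(r)` on the sample grid with the ground
#' truth needed by downstream tests retained in the descriptor. Presets:
#'
#' * `single_point`: unit reflector at the centre pixel (an ideal guide star).
#' * `point_grid`: a regular lattice of isolated unit points.
#' * `filaments`: bundles of smooth curvilinear fibres with a Gaussian cross
#'   section about one resolution element wide, emulating myelinated-axon-like
#'   structures.
#' * `speckle_object`: fully developed complex circular-Gaussian reflectivity,
#'   the extended-object worst case with a flat spatial spectrum.
#'
#' All presets are deterministic functions of `(preset, grid, seed)` and
#' return reflectivities normalized to `max |O| = 1`.
#'
#' @param preset One of `"single_point"`, `"point_grid"`, `"filaments"`,
#'   `"speckle_object"`.
#' @param grid A [grid_spec()].
#' @param seed Integer seed; generation is reproducible for a fixed seed.
#' @return A `specimen_map`: list with `reflectivity` (complex `n x n`
#'   matrix), `grid`, and `descriptor` (preset, seed, ground-truth point
#'   locations for point presets).
#' @export
make_specimen <- function(preset, grid, seed = 0L) {
  presets <- c("single_point", "point_grid", "filaments", "speckle_object")
  if (!preset %in% presets)
    stop(sprintf("unknown specimen preset '%s' (expected one of %s)",
                 preset, paste(presets, collapse = ", ")), call. = FALSE)
  n <- grid$n
  refl <- matrix(0 + 0i, n, n)
  desc <- list(preset = preset, seed = as.integer(seed))

  if (preset == "single_point") {
    c0 <- n / 2 + 1
    refl[c0, c0] <- 1 + 0i
    desc$points <- cbind(row = c0, col = c0)
  } else if (preset == "point_grid") {
    spacing <- max(8L, n %/% 8L)
    at <- seq(spacing %/% 2 + 1, n, by = spacing)
    pts <- as.matrix(expand.grid(row = at, col = at))
    refl[pts] <- 1 + 0i
    desc$points <- pts
    desc$n_points <- nrow(pts)
  } else if (preset == "filaments") {
    refl <- with_seed(seed, draw_filaments(grid))
  } else { # speckle_object
    refl <- with_seed(seed, {
      z <- matrix(stats::rnorm(n * n) + 1i * stats::rnorm(n * n), n, n) / sqrt(2)
      z
    })
  }
  mx <- max(Mod(refl))
  if (mx > 0) refl <- refl / mx
  structure(list(reflectivity = refl, grid = grid, descriptor = desc),
            class = "specimen_map")
}

## Smooth random fibres: random-phase sum of a few quadratic Bezier tracks,
## rasterized with a Gaussian profile ~1 resolution element wide.
draw_filaments <- function(grid) {
  n <- grid$n
  refl <- matrix(0 + 0i, n, n)
  n_fib <- max(3L, n %/% 48L * 3L)
  width_px <- max(1.2, 0.51 * grid$wavelength / grid$na / grid$pitch / 2)
  ij <- as.matrix(expand.grid(r = seq_len(n), c = seq_len(n)))
  for (f in seq_len(n_fib)) {
    p0 <- stats::runif(2, 1, n); p2 <- stats::runif(2, 1, n)
    p1 <- (p0 + p2) / 2 + stats::rnorm(2, 0, n / 4)
    t <- seq(0, 1, length.out = 4L * n)
    bez <- cbind((1 - t)^2 %o% p0[1] + 2 * t * (1 - t) %o% p1[1] + t^2 %o% p2[1],
                 (1 - t)^2 %o% p0[2] + 2 * t * (1 - t) %o% p1[2] + t^2 %o% p2[2])
    amp <- stats::runif(1, 0.5, 1) * exp(1i * stats::runif(1, -pi, pi))
    line <- matrix(0, n, n)
    for (s in seq_along(t)) {
      r <- bez[s, 1]; c <- bez[s, 2]
      r0 <- max(1, floor(r - 3 * width_px)); r1 <- min(n, ceiling(r + 3 * width_px))
      c0 <- max(1, floor(c - 3 * width_px)); c1 <- min(n, ceiling(c + 3 * width_px))
      if (r0 > r1 || c0 > c1) next
      rr <- r0:r1; cc <- c0:c1
      g <- exp(-outer((rr - r)^2, (cc - c)^2, "+") / (2 * width_px^2))
      line[rr, cc] <- pmax(line[rr, cc], g)
    }
    refl <- refl + amp * line
  }
  refl
}

#' @export
print.specimen_map <- function(x, ...) {
  cat(sprintf("<specimen_map> preset '%s', %d x %d, seed %d\n",
              x$descriptor$preset, x$grid$n, x$grid$n, x$descriptor$seed))
  invisible(x)
}

## Evaluate seeded code without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Zernike polynomial on the unit pupil (Noll convention)
#'
#' Evaluates the `j`-th Zernike polynomial (Noll single index, Noll
#' normalization: RMS 1 over the unit disk for `j > 1`) at polar pupil
#' coordinates. `j = 1` is piston, `j = 4` defocus `sqrt(3)*(2*rho^2 - 1)`.
#'
#' @param j Noll index (positive integer).
#' @param rho Radial coordinate, normalized so the pupil edge is 1.
#' @param theta Azimuthal angle in radians.
#' @return Numeric array of polynomial values, same shape as `rho`.
#' @export
zernike_noll <- function(j, rho, theta) {
  if (j < 1 || j != round(j)) stop("Noll index must be a positive integer", call. = FALSE)
  ## invert Noll index -> (n, m)
  n <- 0
  while ((n + 1) * (n + 2) / 2 < j) n <- n + 1
  r <- j - n * (n + 1) / 2          # position within order n, 1-based
  ms <- if (n %% 2 == 0) seq(0, n, by = 2) else seq(1, n, by = 2)
  ## Noll ordering within order n: |m| ascending in pairs;
  ## even j -> cosine, odd j -> sine
  seq_m <- integer(0)
  for (m in ms) seq_m <- c(seq_m, if (m == 0) 0 else c(m, m))
  m_here <- seq_m[r]
  ## radial polynomial
  R <- rho * 0
  for (s in 0:((n - m_here) / 2)) {
    R <- R + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m_here) / 2 - s) * factorial((n - m_here) / 2 - s)) *
      rho^(n - 2 * s)
  }
  norm <- if (m_here == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
  ang <- if (m_here == 0) 1 else if (j %% 2 == 0) cos(m_here * theta) else sin(m_here * theta)
  norm * R * ang
}

#' Generate a pupil phase screen
#'
#' Builds a phase map theta(k) on the wavevector grid, zero outside the
#' pupil support. Two parameterizations:
#'
#' * `spec = list(zernike = coeffs)`: a Zernike expansion; `coeffs[j]` is the
#'   coefficient (radians) of Noll mode `j`.
#' * `spec = list(rms = r, corr_length = f)`: a random screen with the
#'   high-order character of tissue-induced aberrations. White Gaussian
#'   noise on the pupil grid is shaped to a Gaussian autocorrelation of 1/e
#'   half-width `f * k0 * NA` across the pupil (`corr_length` is a fraction
#'   of the pupil radius, default 0.3; larger values give smoother
#'   screens), piston over the support is removed and the screen rescaled
#'   to the requested RMS exactly.
#'
#' @param spec Parameter list (see above).
#' @param grid A [grid_spec()].
#' @param seed Integer seed (random screens only).
#' @param role One of `"input"`, `"output"`, `"correction"`.
#' @return A `pupil_phase`: list with `phase` (`n x n` matrix, radians, zero
#'   outside the pupil), `grid`, `role`.
#' @export
make_aberration <- function(spec, grid, seed = 0L, role = "input") {
  m <- pupil_mask(grid)
  if (!is.null(spec$zernike)) {
    fg <- frequency_grids(grid)
    rho <- sqrt(fg$kx^2 + fg$ky^2) / pupil_radius(grid)
    th <- atan2(fg$ky, fg$kx)
    phase <- matrix(0, grid$n, grid$n)
    for (j in seq_along(spec$zernike)) {
      cj <- spec$zernike[j]
      if (cj != 0) phase <- phase + cj * zernike_noll(j, rho, th)
    }
    phase[!m] <- 0
  } else if (!is.null(spec$rms)) {
    if (spec$rms < 0) stop("requested screen rms must be >= 0", call. = FALSE)
    corr <- if (is.null(spec$corr_length)) 0.3 else spec$corr_length
    if (corr <= 0) stop("correlation length must be > 0", call. = FALSE)
    phase <- with_seed(seed, random_screen(grid, spec$rms, corr))
  } else {
    stop("aberration spec needs either $zernike or $rms", call. = FALSE)
  }
  pupil_phase(phase, grid, role)
}

## Gaussian-correlated random field on the pupil grid: white noise is
## shaped so the screen's autocorrelation over k has 1/e half-width
## ell = corr * k0 * NA. The shaping window acts in the domain conjugate
## to k (which fft2c maps onto the position grid): sqrt of the spectral
## density of a Gaussian-correlated process, exp(-|x|^2 ell^2 / 4).
random_screen <- function(grid, rms, corr) {
  n <- grid$n
  m <- pupil_mask(grid)
  ell <- corr * pupil_radius(grid)
  pg <- position_grids(grid)
  filt <- exp(-(pg$x^2 + pg$y^2) * ell^2 / 4)
  g <- matrix(stats::rnorm(n * n), n, n)
  sm <- Re(ifft2c(fft2c(g + 0i) * filt))
  sm[!m] <- 0
  sm <- sm - mean(sm[m])
  s <- sqrt(mean(sm[m]^2))
  if (s > 0 && rms > 0) sm * (rms / s) else sm * 0
}

#' Pupil phase map constructor
#'
#' @param phase Real `n x n` matrix of phase values in radians on the
#'   centred wavevector grid; values outside the pupil support are zeroed.
#' @param grid A [grid_spec()].
#' @param role `"input"`, `"output"`, or `"correction"`.
#' @return A `pupil_phase` object.
#' @export
pupil_phase <- function(phase, grid, role = "correction") {
  stopifnot(is.matrix(phase), nrow(phase) == grid$n, ncol(phase) == grid$n)
  role <- match.arg(role, c("input", "output", "correction"))
  phase[!pupil_mask(grid)] <- 0
  structure(list(phase = phase, grid = grid, role = role), class = "pupil_phase")
}

#' @export
print.pupil_phase <- function(x, ...) {
  m <- pupil_mask(x$grid)
  v <- x$phase[m]
  cat(sprintf("<pupil_phase> role '%s', %d support nodes, rms %.3f rad\n",
              x$role, sum(m), sqrt(mean((v - mean(v))^2))))
  invisible(x)
}

#' Sample illumination wavevectors over the pupil
#'
#' Returns `n_target` distinct transverse wavevectors covering the pupil
#' disk, snapped to frequency-grid nodes so that downstream basis
#' transforms are exact. Patterns:
#'
#' * `"spiral"` (default): a Fermat spiral, which covers the disk with
#'   near-uniform nearest-neighbour spacing at any count.
#' * `"grid"`: nodes of a regular sublattice of the frequency grid inside
#'   the pupil (the full in-disk node set when `n_target` equals the number
#'   of pupil nodes).
#'
#' @param n_target Number of illumination angles requested (>= 1); must not
#'   exceed the number of resolvable pupil nodes on the grid.
#' @param grid A [grid_spec()].
#' @param pattern `"spiral"` or `"grid"`.
#' @return An `illumination_set`: list with `k` (`n_target x 2` matrix of
#'   wavevectors, rad/m), `grid`, `pattern`.
#' @export
sample_illumination_angles <- function(n_target, grid, pattern = c("spiral", "grid")) {
  pattern <- match.arg(pattern)
  if (n_target < 1) stop("n_target must be >= 1", call. = FALSE)
  nodes <- pupil_nodes(grid)
  if (n_target > nrow(nodes))
    stop(sprintf("n_target = %d exceeds the %d resolvable pupil cells on this grid",
                 n_target, nrow(nodes)), call. = FALSE)
  if (n_target == 1) {
    k <- matrix(0, 1, 2, dimnames = list(NULL, c("kx", "ky")))
  } else if (pattern == "spiral") {
    golden <- pi * (3 - sqrt(5))
    mseq <- seq_len(n_target)
    r <- pupil_radius(grid) * sqrt((mseq - 0.5) / n_target)
    a <- mseq * golden
    want <- cbind(r * cos(a), r * sin(a))
    k <- snap_unique(grid, want, nodes, n_target)
  } else {
    stride <- max(1L, floor(sqrt(nrow(nodes) / n_target)))
    f <- frequency_axis(grid); db <- frequency_bin(grid)
    repeat {
      ix <- round(nodes / db)
      keep <- (ix[, 1] %% stride == 0) & (ix[, 2] %% stride == 0)
      if (sum(keep) >= n_target || stride == 1L) break
      stride <- stride - 1L
    }
    sel <- nodes[keep, , drop = FALSE]
    sel <- sel[order(sel[, 1]^2 + sel[, 2]^2), , drop = FALSE]
    k <- sel[seq_len(n_target), , drop = FALSE]
  }
  colnames(k) <- c("kx", "ky")
  structure(list(k = k, grid = grid, pattern = pattern), class = "illumination_set")
}

## Snap target points to nearest unused pupil nodes (greedy, order preserved).
snap_unique <- function(grid, want, nodes, n_target) {
  used <- rep(FALSE, nrow(nodes))
  out <- matrix(0, n_target, 2)
  for (i in seq_len(n_target)) {
    d2 <- (nodes[, 1] - want[i, 1])^2 + (nodes[, 2] - want[i, 2])^2
    d2[used] <- Inf
    j <- which.min(d2)
    used[j] <- TRUE
    out[i, ] <- nodes[j, ]
  }
  out
}

#' @export
print.illumination_set <- function(x, ...) {
  cat(sprintf("<illumination_set> %d angles, pattern '%s', max |k| = %.3g rad/m\n",
              nrow(x$k), x$pattern, sqrt(max(x$k[, 1]^2 + x$k[, 2]^2))))
  invisible(x)
}
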