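## Closed-loop accumulation of single scattering (CLASS).
##
## Working representation for the phase updates: the matrix is held as
## E(r_o; k_i) (position-basis output, wavevector-basis input). The confocal
## diagonal amplitude is
##   D(r) = (1/n) sum_j E(r; k_j) exp(+1i k_j . r)
## and the per-mode "contribution" of input mode j (or output mode m, after
## transposing roles) is one term of that sum. Each update is the exact
## single-coordinate maximizer of sum_r |D(r)|^2 over the mode's phase:
##   theta = -Arg( <c_mode, D - c_mode> ),
## applied Gauss-Seidel (sequential, immediate update, ascending |k|), so the
## total diagonal intensity never decreases.

## one Gauss-Seidel sweep over the columns of C (contributions, n^2 x M);
## ord = update order. Returns phases and the updated running sum.
gs_phase_sweep <- function(C, ord) {
  D <- rowSums(C)
  th <- numeric(ncol(C))
  for (j in ord) {
    S <- D - C[, j]
    t <- -Arg(sum(C[, j] * Conj(S)))
    if (!is.finite(t)) t <- 0           # zero contribution or zero reference
    C[, j] <- C[, j] * exp(1i * t)
    D <- S + C[, j]
    th[j] <- t
  }
  list(theta = th, D = D)
}

## internal state: E(r_o; k_i) columns + geometry. The phase estimation
## operates on the pupil-banded k/k-basis component of the matrix; window
## truncation artifacts of tile sub-matrices that fall outside the pupil
## band are excluded here and handled by apply_correction_operators().
class_state <- function(m) {
  if (m$basis_in != "wavevector")
    m <- to_wavevector_basis(m, "in")
  if (m$basis_out == "wavevector")
    m <- to_position_basis(m, "out")
  grid <- m$grid
  n <- grid$n
  idx <- pupil_linear_index(grid)
  band <- m$data
  buf <- matrix(0 + 0i, n, n)
  for (j in seq_len(ncol(band))) {
    sp <- fft2c(matrix(band[, j], n, n))
    buf[] <- 0 + 0i
    buf[idx] <- sp[idx]
    band[, j] <- ifft2c(buf)
  }
  pg <- position_grids(grid)
  k_in <- m$k_in
  nodes <- pupil_nodes(grid)
  list(cols = band, grid = grid, k_in = k_in, nodes = nodes,
       x = as.vector(pg$x), y = as.vector(pg$y),
       ramp_in = exp(1i * (outer(as.vector(pg$x), k_in[, 1]) +
                           outer(as.vector(pg$y), k_in[, 2]))),
       ramp_out = exp(1i * (outer(as.vector(pg$x), nodes[, 1]) +
                            outer(as.vector(pg$y), nodes[, 2]))),
       ord_in = order(k_in[, 1]^2 + k_in[, 2]^2),
       ord_out = order(nodes[, 1]^2 + nodes[, 2]^2),
       tau0 = m$tau0)
}

state_to_matrix <- function(st) {
  reflection_matrix(st$cols, st$grid, basis_out = "position",
                    basis_in = "wavevector", k_in = st$k_in, tau0 = st$tau0)
}

## Apply accumulated per-mode correction phases to a matrix in ANY basis
## combination as unitary operators that act as the identity outside the
## pupil support: nothing the acquisition recorded is discarded, and zero
## phases reproduce the input bit-for-bit up to FFT round-off.
apply_correction_operators <- function(m, acc_in, k_in, acc_out, grid) {
  n <- grid$n
  data <- m$data
  if (m$basis_in == "wavevector") {
    data <- sweep(data, 2, exp(1i * acc_in), "*")
  } else {
    d_in <- matrix(1 + 0i, n, n)
    d_in[k_linear_index(grid, k_in)] <- exp(1i * acc_in)
    for (r in seq_len(nrow(data)))
      data[r, ] <- ifft2c(fft2c(matrix(data[r, ], n, n)) * d_in)
  }
  d_out <- matrix(1 + 0i, n, n)
  d_out[pupil_linear_index(grid)] <- exp(1i * acc_out)
  if (m$basis_out == "position") {
    for (j in seq_len(ncol(data)))
      data[, j] <- ifft2c(fft2c(matrix(data[, j], n, n)) * d_out)
  } else {
    data <- data * exp(1i * acc_out)
  }
  m$data <- data
  m
}

diagonal_intensity_state <- function(st) {
  sum(Mod(rowSums(st$cols * st$ramp_in) / st$grid$n)^2)
}

input_step_state <- function(st) {
  C <- st$cols * st$ramp_in / st$grid$n
  if (all(Mod(C) == 0)) stop("zero matrix: no signal to correct", call. = FALSE)
  sw <- gs_phase_sweep(C, st$ord_in)
  st$cols <- sweep(st$cols, 2, exp(1i * sw$theta), "*")
  list(state = st, theta = sw$theta, intensity = sum(Mod(sw$D)^2))
}

output_step_state <- function(st) {
  n <- st$grid$n
  idx <- pupil_linear_index(st$grid)
  n_nodes <- nrow(st$nodes)
  ## rows over the output pupil: khat(k_m; k_j), then g_m(r) by input synthesis
  khat <- matrix(0 + 0i, n_nodes, ncol(st$cols))
  for (j in seq_len(ncol(st$cols)))
    khat[, j] <- fft2c(matrix(st$cols[, j], n, n))[idx]
  if (all(Mod(khat) == 0)) stop("zero matrix: no signal to correct", call. = FALSE)
  G <- khat %*% t(st$ramp_in) / n            # n_nodes x n^2 : g_m(r_i)
  C <- t(G) * st$ramp_out / n                # contributions d_m(r)
  sw <- gs_phase_sweep(C, st$ord_out)
  khat <- khat * exp(1i * sw$theta)
  buf <- matrix(0 + 0i, n, n)
  for (j in seq_len(ncol(st$cols))) {
    buf[] <- 0 + 0i
    buf[idx] <- khat[, j]
    st$cols[, j] <- ifft2c(buf)
  }
  list(state = st, theta = sw$theta, intensity = sum(Mod(sw$D)^2))
}

## scatter per-mode phases onto the frequency grid as a pupil_phase
phases_to_map <- function(theta, k, grid, role) {
  ph <- matrix(0, grid$n, grid$n)
  ph[k_linear_index(grid, k)] <- wrap_phase(theta)
  pupil_phase(ph, grid, role)
}

## robust tilt fit of per-mode phases theta at wavevectors k: coarse peak of
## the phasor field's inverse transform (handles multi-wrap tilts), then
## least-squares polish on the wrapped residual. Returns c(tx, ty) in metres.
pupil_tilt_fit <- function(theta, k, grid) {
  u <- matrix(0 + 0i, grid$n, grid$n)
  u[k_linear_index(grid, k)] <- exp(1i * theta)
  c0 <- ifft2c(u)
  pk <- which(Mod(c0) == max(Mod(c0)), arr.ind = TRUE)[1, ]
  x <- position_axis(grid)
  tilt <- -c(x[pk[1]], x[pk[2]])
  d <- wrap_phase(theta - tilt[1] * k[, 1] - tilt[2] * k[, 2])
  A <- cbind(1, k[, 1], k[, 2])
  for (i in 1:4) {
    co <- stats::lm.fit(A, d)$coefficients
    co[!is.finite(co)] <- 0
    d <- wrap_phase(d - A %*% co)
    tilt <- tilt + co[2:3]
  }
  unname(tilt)
}

#' One input-pupil correction sweep
#'
#' Applies, per illumination mode `k_i`, the closed-form phase
#' `theta_i(k_i) = -Arg(<c_i, S_i>)` where `c_i` is the mode's contribution
#' to the confocal diagonal amplitude and `S_i` the sum of all other modes'
#' contributions (the exact single-coordinate maximizer of the total
#' diagonal intensity), sequentially in ascending `|k_i|` with immediate
#' update, then multiplies each column by `exp(1i theta_i)`.
#'
#' @param m A [reflection_matrix()]; both axes are brought to the working
#'   representation internally (input wavevector / output position).
#' @return List: `theta` (a correction [pupil_phase()] sampled at the
#'   illumination nodes), `matrix` (updated, output position / input
#'   wavevector basis), `intensity` (total diagonal intensity after the
#'   sweep).
#' @export
input_correction_step <- function(m) {
  st <- class_state(m)
  r <- input_step_state(st)
  list(theta = phases_to_map(r$theta, st$k_in, st$grid, "correction"),
       matrix = state_to_matrix(r$state), intensity = r$intensity)
}

#' One output-pupil correction sweep
#'
#' Mirror of [input_correction_step()], acting on the output (detection)
#' pupil modes `k_o`: each row of the wavevector-basis matrix receives the
#' phase that maximizes the total confocal diagonal intensity.
#'
#' @inheritParams input_correction_step
#' @return List as in [input_correction_step()], with `theta` sampled on
#'   the full output pupil support.
#' @export
output_correction_step <- function(m) {
  st <- class_state(m)
  r <- output_step_state(st)
  list(theta = phases_to_map(r$theta, st$nodes, st$grid, "correction"),
       matrix = state_to_matrix(r$state), intensity = r$intensity)
}

#' Iterative CLASS aberration correction
#'
#' Alternates input and output correction sweeps until the total confocal
#' diagonal intensity converges: iteration stops when the relative intensity
#' change drops below `tol` or after `max_iter` iterations. The accumulated
#' correction maps `theta(k_i) = sum_j theta_i^(j)` and
#' `theta(k_o) = sum_j theta_o^(j)` estimate the sample-induced input and
#' output aberrations (up to the piston and tip/tilt gauge; see
#' [compare_to_truth()]).
#'
#' @param m A [reflection_matrix()] in any basis combination.
#' @param tol Relative intensity-change convergence threshold (> 0).
#' @param max_iter Maximum number of input+output iterations (>= 1).
#' @return A `class_correction` object: `theta_in`, `theta_out`
#'   (accumulated correction [pupil_phase()] maps, wrapped), `corrected`
#'   (the corrected matrix in position/position basis), `intensity_trace`
#'   (length `n_iterations + 1`, starting at the pre-correction value),
#'   `n_iterations`, `converged`.
#' @export
run_class <- function(m, tol = 1e-3, max_iter = 30L) {
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  st <- class_state(m)
  acc_in <- numeric(nrow(st$k_in))
  acc_out <- numeric(nrow(st$nodes))
  trace <- diagonal_intensity_state(st)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ri <- input_step_state(st)
    st <- ri$state
    acc_in <- acc_in + ri$theta
    ro <- output_step_state(st)
    st <- ro$state
    acc_out <- acc_out + ro$theta
    if (!is.finite(ro$intensity))
      stop(sprintf("non-finite total intensity at iteration %d", it), call. = FALSE)
    trace <- c(trace, ro$intensity)
    if (abs(trace[it + 1] - trace[it]) / trace[it + 1] < tol) {
      converged <- TRUE
      break
    }
  }
  ## gauge fixing: a common tip/tilt applied to both pupils only shifts the
  ## image, so the shared tilt of the accumulated maps is excluded from the
  ## estimates; the corrected matrix therefore keeps the registration of
  ## the uncorrected input. The differential tilt (a genuine input/output
  ## asymmetry) is retained.
  tau <- (pupil_tilt_fit(acc_in, st$k_in, st$grid) +
          pupil_tilt_fit(acc_out, st$nodes, st$grid)) / 2
  acc_in <- acc_in - tau[1] * st$k_in[, 1] - tau[2] * st$k_in[, 2]
  acc_out <- acc_out - tau[1] * st$nodes[, 1] - tau[2] * st$nodes[, 2]
  ## apply the final maps to the matrix as given (unitary, identity outside
  ## the pupil: window-truncation content of tile sub-matrices survives)
  corrected <- apply_correction_operators(m, acc_in, st$k_in, acc_out, st$grid)
  if (corrected$basis_in != "position") corrected <- to_position_basis(corrected, "in")
  if (corrected$basis_out != "position") corrected <- to_position_basis(corrected, "out")
  structure(
    list(theta_in = phases_to_map(acc_in, st$k_in, st$grid, "input"),
         theta_out = phases_to_map(acc_out, st$nodes, st$grid, "output"),
         corrected = corrected, intensity_trace = trace,
         n_iterations = it, converged = converged),
    class = "class_correction")
}

#' @export
print.class_correction <- function(x, ...) {
  tr <- x$intensity_trace
  cat(sprintf("<class_correction> %d iteration(s), %sconverged, intensity %.4g -> %.4g (x%.2f)\n",
              x$n_iterations, if (x$converged) "" else "NOT ",
              tr[1], tr[length(tr)], tr[length(tr)] / tr[1]))
  invisible(x)
}

#' Normalized cross-correlation of two pupil functions
#'
#' `|<exp(1i a), exp(1i b)>| / (||exp(1i a)|| * ||exp(1i b)||)` over the
#' pupil support: 1 for identical maps (piston-invariant), and of order
#' `sqrt(pi / (4 N))` for independent random phases on `N` support nodes.
#'
#' @param a,b [pupil_phase()] maps on the same grid and support.
#' @return Scalar in `[0, 1]`.
#' @export
pupil_cross_correlation <- function(a, b) {
  if (!same_grid(a$grid, b$grid))
    stop("pupil maps live on different grids", call. = FALSE)
  m <- pupil_mask(a$grid)
  Mod(mean(exp(1i * (a$phase[m] - b$phase[m]))))
}

#' Compare a recovered pupil map to ground truth
#'
#' Removes the inherent gauge of reflection-matrix aberration estimation --
#' piston and tip/tilt (a tilt pair only shifts the image) -- and reports
#' the residual. The tilt is first located robustly as the peak of the
#' inverse transform of the residual phasor over the support (a large tilt
#' wraps many times, where a direct fit fails), then piston/tip/tilt are
#' polished by least squares on the wrapped principal value.
#'
#' @param recovered,truth [pupil_phase()] maps on the same grid/support.
#' @return List: `residual` (wrapped residual map after gauge removal),
#'   `rms` (radians), `max_abs` (radians), `correlation`
#'   (`|mean(exp(1i residual))|` over the support), `tilt` (removed tilt
#'   coefficients, metres).
#' @export
compare_to_truth <- function(recovered, truth) {
  if (!same_grid(recovered$grid, truth$grid))
    stop("pupil maps live on different grids", call. = FALSE)
  grid <- recovered$grid
  m <- pupil_mask(grid)
  nodes <- pupil_nodes(grid)
  d0 <- wrap_phase(recovered$phase - truth$phase)
  tilt <- pupil_tilt_fit(d0[m], nodes, grid)
  d <- wrap_phase(d0[m] - tilt[1] * nodes[, 1] - tilt[2] * nodes[, 2])
  d <- wrap_phase(d - Arg(mean(exp(1i * d))))   # piston as circular mean
  res <- matrix(0, grid$n, grid$n)
  res[m] <- d
  list(residual = res, rms = sqrt(mean(d^2)), max_abs = max(abs(d)),
       correlation = Mod(mean(exp(1i * d))), tilt = tilt)
}
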