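## Independent brute-force oracles: direct summation of the discrete
## diffraction integral, no FFTs, used to check the simulator and metrology.

## Coherent field at the image plane for a point reflector at r0 (metres),
## illuminated at k_i, through output pupil phase screen phi_out:
##   f(r) = phase_in_factor * exp(-1i k_i . r0) / n^2 *
##          sum_{|k| <= k0 NA} exp(1i phi_out(k)) exp(1i k . (r - r0))
oracle_point_field <- function(grid, r0 = c(0, 0), k_i = c(0, 0),
                               phi_out = NULL, phi_in_val = 0) {
  n <- grid$n
  nodes <- classao:::pupil_nodes(grid)
  phv <- if (is.null(phi_out)) rep(0, nrow(nodes)) else
    phi_out$phase[classao:::pupil_mask(grid)]
  x <- classao:::position_axis(grid)
  f <- matrix(0 + 0i, n, n)
  for (q in seq_len(nrow(nodes))) {
    kx <- nodes[q, 1]; ky <- nodes[q, 2]
    f <- f + exp(1i * phv[q]) *
      outer(exp(1i * kx * (x - r0[1])), exp(1i * ky * (x - r0[2])))
  }
  f * exp(1i * phi_in_val) * exp(-1i * (k_i[1] * r0[1] + k_i[2] * r0[2])) / n^2
}

## Half-maximum full width of the analytic profile f(x) (vectorized), by
## bisection on each side of the peak at 0. Used for Airy-type references.
oracle_fwhm_of <- function(f, x_upper) {
  half <- f(0) / 2
  side <- function(lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > half) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  2 * side(0, x_upper)
}

## default small test geometry
tiny_grid <- function(n = 32, pitch = 100e-9) grid_spec(n, pitch)

## negate a correction map into an aberration estimate
neg_phase <- function(p) pupil_phase(-p$phase, p$grid, p$role)

## standard matched fixture: speckle object, rms-1.5-rad screens both
## pupils, full-pupil illumination
speckle_fixture <- function(grid, seed, gamma = 0.5, rms = 1.5,
                            preset = "speckle_object") {
  specimen <- make_specimen(preset, grid, seed = seed)
  phase_in <- make_aberration(list(rms = rms), grid, seed = seed + 1000L,
                              role = "input")
  phase_out <- make_aberration(list(rms = rms), grid, seed = seed + 2000L,
                               role = "output")
  illum <- sample_illumination_angles(sum(pupil_mask(grid)), grid)
  list(specimen = specimen, phase_in = phase_in, phase_out = phase_out,
       illum = illum,
       matrix = assemble_matrix(specimen, phase_in, phase_out, illum, grid,
                                noise_spec(gamma, seed + 3000L)))
}
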