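test_that("basis transforms are unitary on the pupil support", {
  g <- tiny_grid(32)
  fx <- speckle_fixture(g, seed = 5, gamma = 0.3)
  m <- fx$matrix
  ## out axis round trip: position -> wavevector -> position
  rt <- to_position_basis(to_wavevector_basis(m, "out"), "out")
  expect_lt(max(Mod(rt$data - m$data)) / max(Mod(m$data)), 1e-12)
  ## Parseval on both axes for band-limited data
  kk <- to_wavevector_basis(m, "both")
  expect_equal(sum(Mod(kk$data)^2), sum(Mod(m$data)^2), tolerance = 1e-12)
  ## full position/position round trip back to the k_in columns
  pp <- to_position_basis(m, "in")
  back <- to_wavevector_basis(pp, "in")
  nodes <- classao:::pupil_nodes(g)
  perm <- match(paste(round(fx$illum$k[, 1], 3), round(fx$illum$k[, 2], 3)),
                paste(round(nodes[, 1], 3), round(nodes[, 2], 3)))
  expect_lt(max(Mod(back$data[, perm] - m$data)) / max(Mod(m$data)), 1e-10)
  ## no-op transforms warn
  expect_warning(to_wavevector_basis(kk, "out"), "no-op")
  expect_warning(to_position_basis(m, "out"), "no-op")
})

test_that("wavevector columns of a point object are pure phase ramps", {
  g <- tiny_grid(16, 150e-9)
  x <- classao:::position_axis(g)
  r0_px <- c(11L, 6L); r0 <- c(x[r0_px[1]], x[r0_px[2]])
  data <- matrix(0 + 0i, g$n^2, 1)
  data[(r0_px[2] - 1) * g$n + r0_px[1], 1] <- 1
  m <- reflection_matrix(data, g, basis_out = "position",
                         basis_in = "wavevector", k_in = matrix(0, 1, 2))
  km <- to_wavevector_basis(m, "out")
  nodes <- classao:::pupil_nodes(g)
  ## direct summation oracle: delta transforms to exp(-1i k . r0) / n
  want <- exp(-1i * (nodes[, 1] * r0[1] + nodes[, 2] * r0[2])) / g$n
  expect_equal(km$data[, 1], want, tolerance = 1e-12)
})

test_that("separable point matrices are rank one in the position basis", {
  g <- tiny_grid(16, 150e-9)
  pt <- make_specimen("single_point", g)
  scr_i <- make_aberration(list(rms = 1.1), g, seed = 1)
  scr_o <- make_aberration(list(rms = 0.9), g, seed = 2)
  il <- sample_illumination_angles(sum(pupil_mask(g)), g)
  m <- assemble_matrix(pt, scr_i, scr_o, il, g, noise_spec(0))
  pp <- to_position_basis(m, "in")
  sv <- svd(pp$data, nu = 0, nv = 0)$d
  expect_lt(sv[2] / sv[1], 1e-10)
})

test_that("a plane mirror maps to sinc-like diagonal dominance in position space", {
  g <- tiny_grid(16, 150e-9)
  nodes <- classao:::pupil_nodes(g)
  ## a specular mirror reflects illumination exp(-1i k.r) into the output
  ## mode at -k: its k/k matrix pairs each k_i with k_o = -k_i
  key <- function(k) paste(round(k[, 1]), round(k[, 2]))
  perm <- match(key(-nodes), key(nodes))
  data <- matrix(0 + 0i, nrow(nodes), nrow(nodes))
  data[cbind(perm, seq_len(nrow(nodes)))] <- 1
  m <- reflection_matrix(data, g, basis_out = "wavevector",
                         basis_in = "wavevector", k_in = nodes)
  pp <- to_position_basis(m, "both")
  mods <- Mod(pp$data)
  diag_vals <- mods[cbind(seq_len(g$n^2), seq_len(g$n^2))]
  expect_true(all(diag_vals >= apply(mods, 1, max) - 1e-12))
})

test_that("the confocal image is the squared matrix diagonal", {
  g <- tiny_grid(16, 150e-9)
  ## unit diagonal -> uniform ones; zero diagonal -> zeros
  d <- diag(g$n^2) + 0i
  m <- reflection_matrix(d, g, basis_out = "position", basis_in = "position")
  expect_equal(confocal_image(m), matrix(1, g$n, g$n))
  d0 <- matrix(1 + 0i, g$n^2, g$n^2); diag(d0) <- 0
  m0 <- reflection_matrix(d0, g, basis_out = "position", basis_in = "position")
  expect_equal(confocal_image(m0), matrix(0, g$n, g$n))
  expect_error(confocal_image(to_wavevector_basis(m, "out")), "position basis")
  ## aberration-free point fixture: profile equals the double-pass oracle
  g2 <- tiny_grid(32)
  pt <- make_specimen("single_point", g2)
  flat <- make_aberration(list(zernike = 0), g2)
  il <- sample_illumination_angles(sum(pupil_mask(g2)), g2, pattern = "grid")
  mm <- assemble_matrix(pt, flat, flat, il, g2, noise_spec(0))
  img <- confocal_image(to_position_basis(mm, "in"))
  h <- oracle_point_field(g2)           # coherent PSF from direct summation
  n_nodes <- nrow(classao:::pupil_nodes(g2))
  ## E(r, r) = h(r) * g(r): with full pupil illumination both factors are h
  want <- Mod(h)^4 * (g2$n^2 / n_nodes * n_nodes / g2$n)^2
  want <- want * max(img) / max(want)   # common normalization
  expect_equal(img, want, tolerance = 1e-8)
})

test_that("PSF metrology matches closed forms and the diffraction oracle", {
  g <- tiny_grid(64, 80e-9)
  n <- g$n
  ## synthetic Gaussian column of known sigma: FWHM = 2 sqrt(2 ln 2) sigma
  x <- classao:::position_axis(g)
  sigma <- 4.3 * g$pitch
  gauss <- outer(exp(-x^2 / (4 * sigma^2)), exp(-x^2 / (4 * sigma^2)))
  m <- reflection_matrix(matrix(as.vector(gauss) + 0i, ncol = 1), g,
                         basis_out = "position", basis_in = "wavevector",
                         k_in = matrix(0, 1, 2))
  psf <- point_spread_function(m, c(0, 0))
  expect_equal(psf$fwhm, 2 * sqrt(2 * log(2)) * sigma, tolerance = 0.01)
  ## aberration-free point fixture: FWHM within 5% of the oracle profile
  pt <- make_specimen("single_point", g)
  flat <- make_aberration(list(zernike = 0), g)
  il <- sample_illumination_angles(sum(pupil_mask(g)), g)
  mm <- assemble_matrix(pt, flat, flat, il, g, noise_spec(0))
  psf0 <- point_spread_function(mm, c(0, 0))
  h <- oracle_point_field(g)
  oracle_psf <- classao:::psf_from_intensity(Mod(h)^2, g)
  expect_equal(psf0$fwhm, oracle_psf$fwhm, tolerance = 0.05)
  ## ... and close to the Airy intensity width 0.51 lambda / NA
  expect_equal(psf0$fwhm, 0.51 * g$wavelength / g$na, tolerance = 0.06)
  ## defocus strictly broadens the PSF
  dz <- make_aberration(list(zernike = c(0, 0, 0, 1.2)), g, role = "output")
  md <- assemble_matrix(pt, flat, dz, il, g, noise_spec(0))
  expect_gt(point_spread_function(md, c(0, 0))$fwhm, psf0$fwhm)
  ## flat column refused
  mflat <- reflection_matrix(matrix(1 + 0i, n^2, 1), g,
                             basis_out = "position", basis_in = "wavevector",
                             k_in = matrix(0, 1, 2))
  expect_error(point_spread_function(mflat, c(0, 0)), "flat")
})

test_that("Strehl enhancement is the peak-intensity ratio", {
  g <- tiny_grid(64, 80e-9)
  pt <- make_specimen("single_point", g)
  flat <- make_aberration(list(zernike = 0), g)
  il <- sample_illumination_angles(sum(pupil_mask(g)), g)
  mm <- assemble_matrix(pt, flat, flat, il, g, noise_spec(0))
  psf <- point_spread_function(mm, c(0, 0))
  expect_equal(strehl_enhancement(psf, psf), 1.0)
  ## rms-1.5-rad screens on both pupils: enhancement after exact correction
  ## equals the inverse Strehl of the applied screens (pupil-integral oracle)
  scr_i <- make_aberration(list(rms = 1.5), g, seed = 31)
  scr_o <- make_aberration(list(rms = 1.5), g, seed = 32)
  ma <- assemble_matrix(pt, scr_i, scr_o, il, g, noise_spec(0))
  ## "before": intensity at the true focus of the aberrated matrix
  before_col <- Mod(ma$data %*% rep(1 + 0i, nrow(il$k)) / g$n)^2
  before_peak <- before_col[(g$n / 2) * g$n + g$n / 2 + 1]
  ## "after": correct with the ground-truth screens and re-extract
  mk <- to_wavevector_basis(ma, "out")
  nodes <- classao:::pupil_nodes(g)
  phi_o <- scr_o$phase[pupil_mask(g)]
  phi_i <- apply(il$k, 1, function(k) classao:::phase_at(scr_i, g, k))
  corr <- mk
  corr$data <- (mk$data * exp(-1i * phi_o)) %*% diag(exp(-1i * phi_i))
  psf_after <- point_spread_function(to_position_basis(corr, "out"), c(0, 0))
  s_in <- Mod(mean(exp(1i * phi_i)))^2
  s_out <- Mod(mean(exp(1i * phi_o)))^2
  expect_equal(psf_after$peak / before_peak, 1 / (s_in * s_out),
               tolerance = 0.02)
  psf_before <- classao:::psf_from_intensity(matrix(before_col, g$n, g$n), g)
  expect_error(strehl_enhancement(list(peak = 0), psf_before), "zero")
})
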