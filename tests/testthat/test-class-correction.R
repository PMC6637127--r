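test_that("correction steps are no-ops on aberration-free matrices", {
  g <- tiny_grid(32)
  fx <- speckle_fixture(g, seed = 6, gamma = 0, rms = 0)
  m <- fx$matrix
  i0 <- sum(confocal_image(to_position_basis(m, "in")))
  st_in <- input_correction_step(m)
  st_out <- output_correction_step(st_in$matrix)
  ## aberration-free data is already optimal: updates vanish
  expect_lt(max(abs(st_in$theta$phase)), 1e-8)
  expect_lt(max(abs(st_out$theta$phase)), 1e-8)
  expect_equal(st_out$intensity, i0, tolerance = 1e-10)
  ## zero matrix refused
  m0 <- m; m0$data[] <- 0 + 0i
  expect_error(input_correction_step(m0), "no signal")
})

test_that("one input sweep recovers a pure input screen on an extended object", {
  g <- tiny_grid(64, 80e-9)
  sp <- make_specimen("speckle_object", g, seed = 7)
  scr_i <- make_aberration(list(rms = 1.5), g, seed = 71, role = "input")
  flat <- make_aberration(list(zernike = 0), g)
  il <- sample_illumination_angles(sum(pupil_mask(g)), g)
  m <- assemble_matrix(sp, scr_i, flat, il, g, noise_spec(0))
  step <- input_correction_step(m)
  cmp <- compare_to_truth(neg_phase(step$theta), scr_i)
  expect_gt(cmp$correlation, 0.99)
})

test_that("CLASS converges and recovers both screens on the matched fixture", {
  g <- tiny_grid(64, 80e-9)
  fx <- speckle_fixture(g, seed = 8, gamma = 0.5)
  res <- run_class(fx$matrix, tol = 1e-3)
  expect_true(res$converged)
  expect_lte(res$n_iterations, 10)      # "5-10 iterations" regime
  expect_equal(length(res$intensity_trace), res$n_iterations + 1)
  ## trace non-decreasing within 1e-9 relative tolerance
  expect_gte(min(diff(res$intensity_trace)),
             -1e-9 * max(res$intensity_trace))
  ## recovered pupil functions match ground truth
  cmp_i <- compare_to_truth(neg_phase(res$theta_in), fx$phase_in)
  cmp_o <- compare_to_truth(neg_phase(res$theta_out), fx$phase_out)
  expect_gt(cmp_i$correlation, 0.99)
  expect_gt(cmp_o$correlation, 0.99)
  ## corrected confocal peak within 10% of the aberration-free oracle image
  flat <- make_aberration(list(zernike = 0), g)
  ideal <- assemble_matrix(fx$specimen, flat, flat, fx$illum, g, noise_spec(0))
  img_ideal <- confocal_image(to_position_basis(ideal, "in"))
  img_corr <- confocal_image(res$corrected)
  expect_equal(max(img_corr), max(img_ideal), tolerance = 0.1)
})

test_that("aberration-free input converges immediately to itself", {
  g <- tiny_grid(32)
  fx <- speckle_fixture(g, seed = 9, gamma = 0, rms = 0)
  res <- run_class(fx$matrix, tol = 1e-3)
  expect_true(res$converged)
  expect_equal(res$n_iterations, 1L)
  img_in <- confocal_image(to_position_basis(fx$matrix, "in"))
  expect_equal(confocal_image(res$corrected), img_in, tolerance = 1e-9)
})

test_that("separable point fixtures are recovered exactly at convergence", {
  g <- tiny_grid(32)
  pt <- make_specimen("single_point", g)
  scr_i <- make_aberration(list(rms = 1.5), g, seed = 41, role = "input")
  scr_o <- make_aberration(list(rms = 1.5), g, seed = 42, role = "output")
  il <- sample_illumination_angles(sum(pupil_mask(g)), g)
  m <- assemble_matrix(pt, scr_i, scr_o, il, g, noise_spec(0))
  res <- run_class(m, tol = 1e-14, max_iter = 40L)
  cmp_i <- compare_to_truth(neg_phase(res$theta_in), scr_i)
  cmp_o <- compare_to_truth(neg_phase(res$theta_out), scr_o)
  ## machine-precision recovery up to the piston/tilt gauge
  expect_lt(cmp_i$max_abs, 1e-6)
  expect_lt(cmp_o$max_abs, 1e-6)
})

test_that("piston and tilt on the truth screens are a pure gauge", {
  g <- tiny_grid(32)
  sp <- make_specimen("speckle_object", g, seed = 10)
  scr_i <- make_aberration(list(rms = 1.2), g, seed = 51, role = "input")
  scr_o <- make_aberration(list(rms = 1.2), g, seed = 52, role = "output")
  il <- sample_illumination_angles(sum(pupil_mask(g)), g)
  fg <- classao:::frequency_grids(g)
  ## an integer-pixel image shift: the same ramp (plus piston) on both pupils
  tilt <- 0.4 + 2 * g$pitch * fg$kx - 1 * g$pitch * fg$ky
  scr_i2 <- pupil_phase(scr_i$phase + tilt, g, "input")
  scr_o2 <- pupil_phase(scr_o$phase + tilt, g, "output")
  m1 <- assemble_matrix(sp, scr_i, scr_o, il, g, noise_spec(0))
  m2 <- assemble_matrix(sp, scr_i2, scr_o2, il, g, noise_spec(0))
  r1 <- run_class(m1, tol = 1e-6)
  r2 <- run_class(m2, tol = 1e-6)
  ## corrected total intensity unchanged by the gauge shift
  expect_equal(tail(r2$intensity_trace, 1), tail(r1$intensity_trace, 1),
               tolerance = 1e-9)
  ## the corrected image is the same up to the global pixel shift
  i1 <- confocal_image(r1$corrected)
  i2 <- confocal_image(r2$corrected)
  expect_equal(sort(i2), sort(i1), tolerance = 1e-6)
  ## compare_to_truth absorbs the added piston/tilt entirely
  cmp <- compare_to_truth(scr_i2, scr_i)
  expect_lt(cmp$rms, 1e-10)
  expect_equal(cmp$correlation, 1, tolerance = 1e-12)
})

test_that("recovered-screen fidelity degrades with multiple-scattering noise", {
  g <- tiny_grid(32)
  corr_at <- function(gamma) {
    cc <- vapply(1:3, function(s) {
      fx <- speckle_fixture(g, seed = 300 + s, gamma = gamma)
      res <- run_class(fx$matrix)
      compare_to_truth(neg_phase(res$theta_in), fx$phase_in)$correlation
    }, 0)
    mean(cc)
  }
  lo <- corr_at(0.2); hi <- corr_at(4)
  expect_gt(lo, hi)                     # monotone on average in gamma
  expect_gt(lo, 0.9)
})

test_that("pupil cross-correlation behaves as a normalized phasor overlap", {
  g <- tiny_grid(32)
  a <- make_aberration(list(rms = 1.0), g, seed = 61)
  expect_equal(pupil_cross_correlation(a, a), 1.0)
  piston <- pupil_phase(a$phase + 0.9, g)
  expect_equal(pupil_cross_correlation(a, piston), 1.0, tolerance = 1e-12)
  ## Monte-Carlo null for independent uniform phases: E ~ sqrt(pi / (4 N))
  m <- pupil_mask(g)
  N <- sum(m)
  draws <- vapply(1:1000, function(s) {
    ph1 <- ph2 <- matrix(0, g$n, g$n)
    set.seed(s)
    ph1[m] <- stats::runif(N, -pi, pi)
    ph2[m] <- stats::runif(N, -pi, pi)
    pupil_cross_correlation(pupil_phase(ph1, g), pupil_phase(ph2, g))
  }, 0)
  expect_equal(mean(draws), sqrt(pi / (4 * N)), tolerance = 0.05)
  b <- make_aberration(list(rms = 1.0), g, seed = 99)
  expect_error(pupil_cross_correlation(a, make_aberration(list(rms = 1), tiny_grid(16, 150e-9))),
               "different grids")
})

test_that("compare_to_truth removes exactly the declared ambiguities", {
  g <- tiny_grid(32)
  truth <- make_aberration(list(rms = 1.3), g, seed = 77)
  same <- compare_to_truth(truth, truth)
  expect_equal(same$rms, 0)
  expect_equal(same$correlation, 1)
  fg <- classao:::frequency_grids(g)
  tilted <- pupil_phase(truth$phase + 2.5 * g$pitch * fg$kx, g)
  cmp <- compare_to_truth(tilted, truth)
  expect_lt(cmp$rms, 1e-8)
  ## independent high-order screens stay clearly distinguishable from a
  ## match; gauge (piston/tilt) removal inflates chance agreement above the
  ## raw phasor-overlap null, so the bound is looser than sqrt(pi/(4N))
  truth_h <- make_aberration(list(rms = 1.3, corr_length = 0.15), g, seed = 87)
  other_h <- make_aberration(list(rms = 1.3, corr_length = 0.15), g, seed = 88)
  expect_lt(compare_to_truth(other_h, truth_h)$correlation, 0.7)
})
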