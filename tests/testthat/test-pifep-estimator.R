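test_that("difference potential handles degenerate and hand-computed cases", {
  th <- reduced_thermo(1)
  surf <- make_model(model_spec("harmonic-1d", list(k = 1)))
  config <- matrix(0, 1, 3)

  # all beads collapsed onto the centroid -> exactly zero
  p0 <- ring_polymer_path(matrix(0, 4, 3), atom_index = 1, mass = 1)
  expect_identical(delta_u_bar(list(p0), config, surf), 0)

  # P = 4 beads at +d, -d, +d, -d about centroid 0: mean slice energy is
  # k d^2 / 2, classical energy 0
  d <- 0.7
  beads <- matrix(0, 4, 3)
  beads[, 1] <- c(d, -d, d, -d)
  pd <- ring_polymer_path(beads, atom_index = 1, mass = 1)
  expect_equal(delta_u_bar(list(pd), config, surf), 0.5 * 1 * d^2)

  # centroid/configuration mismatch is rejected
  expect_error(delta_u_bar(list(pd), matrix(1, 1, 3), surf), "centroid")
})

test_that("difference potential matches a naive slice-loop reimplementation", {
  th <- reduced_thermo(2)
  surf <- make_model(model_spec("morse-1d", list(D = 5, a = 1)))
  set.seed(4)
  for (rep in 1:5) {
    cen <- c(stats::rnorm(1, sd = 0.3), 0, 0)
    config <- matrix(cen, 1, 3)
    p <- sample_free_particle_path(1, 8, th, centroid = cen, dims = 1)
    naive <- 0
    for (i in 1:8) {
      slice <- config
      slice[1, ] <- p$beads[i, ]
      naive <- naive + surf$energy(slice)
    }
    naive <- naive / 8 - surf$energy(config)
    expect_equal(delta_u_bar(list(p), config, surf), naive,
                 tolerance = 1e-12)
  }
})

test_that("inner average obeys its exact identities", {
  th <- reduced_thermo(3)
  surf <- make_model(model_spec("harmonic-1d"))
  config <- matrix(c(0.4, 0, 0), 1)

  # identity masses: numerator and denominator coincide exactly
  reg_id <- quantized_region(1, 1, 1)
  r <- inner_fp_average(config, surf, reg_id, th, P = 8, n_paths = 40,
                        seed = 2)
  expect_identical(r$numerator_mean, r$denominator_mean)
  expect_equal(r$n_paths, 40)

  # free particle (U independent of the quantized coordinate): both means 1
  flat <- make_model(model_spec("harmonic-1d", list(k = 1)))
  flat$energy_many <- function(X) rep(0, dim(X)[1])
  flat$energy <- function(conf) 0
  reg <- quantized_region(1, 1, 2)
  rf <- inner_fp_average(config, flat, reg, th, P = 8, n_paths = 30,
                         seed = 3)
  expect_equal(rf$numerator_mean, 1)
  expect_equal(rf$denominator_mean, 1)
})

test_that("inner average matches the dense Gaussian quadrature oracle", {
  # single fixed centroid on harmonic-1d: the ratio of inner means times
  # the mass factor has a closed form from the centroid-projected ring
  # covariance eigenvalues
  beta <- 3; k <- 1; P <- 16
  th <- reduced_thermo(beta)
  surf <- make_model(model_spec("harmonic-1d", list(k = k)))
  reg <- quantized_region(1, 1, 2)
  n <- 2e4
  r <- inner_fp_average(matrix(c(0.3, 0, 0), 1), surf, reg, th, P,
                        n_paths = n, n_discard = 0, seed = 11)
  mc <- sqrt(2) * r$numerator_mean / r$denominator_mean
  oracle <- finite_p_harmonic_ratio(beta, k, 1, 2, P)
  # generous 3-sigma band from the observed spread of the weights
  expect_lt(abs(mc - oracle) / oracle, 0.01)
})

test_that("ratio estimation: identity, determinism, blocking and errors", {
  fix <- harmonic_fixture(beta = 3, n_configs = 40, seed = 6)
  reg_id <- quantized_region(1, 1, 1)
  est <- estimate_ratio(fix$ensemble, fix$surface, reg_id, fix$thermo,
                        P = 8, n_paths = 20, n_blocks = 5, seed = 7)
  expect_identical(est$ratio, 1)
  expect_identical(est$stderr, 0)
  expect_identical(unique(est$block_values), 1)

  reg <- quantized_region(1, 1, 2)
  e1 <- estimate_ratio(fix$ensemble, fix$surface, reg, fix$thermo,
                       P = 8, n_paths = 20, n_blocks = 5, seed = 7)
  e2 <- estimate_ratio(fix$ensemble, fix$surface, reg, fix$thermo,
                       P = 8, n_paths = 20, n_blocks = 5, seed = 7)
  expect_identical(e1$ratio, e2$ratio)
  expect_length(e1$block_values, 5)
  expect_gt(e1$ratio, 1) # heavier isotope is bound more strongly

  empty <- fix$ensemble
  empty$configurations <- list()
  expect_error(
    estimate_ratio(empty, fix$surface, reg, fix$thermo, P = 8,
                   n_paths = 5, seed = 1),
    "same atom count|empty")
  expect_error(
    estimate_ratio(fix$ensemble, fix$surface, reg, fix$thermo, P = 8,
                   n_paths = 5, n_blocks = 100, seed = 1),
    "blocks")
})

test_that("ratio estimate agrees with the finite-P quadrature oracle", {
  # for the harmonic well the difference potential is independent of the
  # centroid, so the double average equals the single-config quadrature
  # value exactly; this validates the full estimator chain at modest n
  beta <- 3
  fix <- harmonic_fixture(beta = beta, n_configs = 60, seed = 9)
  reg <- quantized_region(1, 1, 2)
  est <- estimate_ratio(fix$ensemble, fix$surface, reg, fix$thermo,
                        P = 16, n_paths = 150, seed = 10)
  oracle <- finite_p_harmonic_ratio(beta, 1, 1, 2, 16)
  expect_lt(abs(est$ratio - oracle), 4 * est$stderr)
  expect_equal(est$metadata$ratio_reduced * sqrt(2), est$ratio,
               tolerance = 1e-12)
})

test_that("estimator symmetry: heavy-to-light perturbation inverts the ratio", {
  beta <- 3
  fix <- harmonic_fixture(beta = beta, n_configs = 80, seed = 14)
  fwd <- estimate_ratio(fix$ensemble, fix$surface,
                        quantized_region(1, 1, 2), fix$thermo,
                        P = 32, n_paths = 150, seed = 15)
  rev <- estimate_ratio(fix$ensemble, fix$surface,
                        quantized_region(1, 2, 1), fix$thermo,
                        P = 32, n_paths = 150, seed = 16)
  se <- sqrt((fwd$stderr / fwd$ratio)^2 +
               (rev$stderr / rev$ratio)^2) * fwd$ratio
  expect_lt(abs(fwd$ratio - 1 / rev$ratio), 3 * se)
})

test_that("block statistics implement the contiguous-block contract", {
  bs <- block_statistics(c(1, 2, 3, 4), 2)
  expect_equal(bs$mean, 2.5)
  expect_equal(bs$block_means, c(1.5, 3.5))
  expect_equal(bs$stderr, stats::sd(c(1.5, 3.5)) / sqrt(2))

  expect_equal(block_statistics(rep(7, 30), 10)$stderr, 0)
  expect_error(block_statistics(1:3, 5), "blocks")

  # remainder goes to the last block
  bs2 <- block_statistics(1:11, 2)
  expect_equal(bs2$block_means, c(mean(1:5), mean(6:11)))

  # Monte-Carlo sanity: blocked stderr of i.i.d. normals tracks sigma/sqrt(n)
  set.seed(31)
  reps <- replicate(100, block_statistics(stats::rnorm(200), 10)$stderr)
  expect_lt(abs(mean(reps) - 1 / sqrt(200)) / (1 / sqrt(200)), 0.5)
})

test_that("umbrella reweighting obeys its limits and shifts anharmonic averages", {
  fix <- harmonic_fixture(beta = 3, n_configs = 50, seed = 18)
  reg <- quantized_region(1, 1, 2)

  # O = 1 -> exactly 1
  one <- reweight_observable(function(cfg) 1, fix$ensemble, fix$surface,
                             reg, fix$thermo, P = 8, n_paths = 20,
                             seed = 19)
  expect_equal(one, 1)

  # free particle -> plain classical average
  flat <- fix$surface
  flat$energy_many <- function(X) rep(0, dim(X)[1])
  flat$energy <- function(conf) 0
  xs <- vapply(fix$ensemble$configurations, function(m) m[1, 1], numeric(1))
  rw_flat <- reweight_observable(function(cfg) cfg[1, 1], fix$ensemble,
                                 flat, reg, fix$thermo, P = 8,
                                 n_paths = 20, seed = 19)
  expect_equal(rw_flat, mean(xs), tolerance = 1e-12)

  # harmonic well: the difference potential is centroid-independent, so
  # reweighting does not shift <x^2> beyond noise
  rw_x2 <- reweight_observable(function(cfg) cfg[1, 1]^2, fix$ensemble,
                               fix$surface, reg, fix$thermo, P = 16,
                               n_paths = 50, seed = 20)
  cl_x2 <- mean(xs^2)
  se <- stats::sd(xs^2) / sqrt(length(xs) / 2)
  expect_lt(abs(rw_x2 - cl_x2), 3 * se)

  # Morse well: quantum weighting pushes the centroid distribution outward
  th <- reduced_thermo(2)
  msurf <- make_model(model_spec("morse-1d", list(D = 8, a = 0.8)))
  mens <- run_metropolis(msurf, matrix(0, 1, 3), th, 20000, 0.5,
                         save_interval = 50, n_equilibration = 1000,
                         seed = 21)
  reg_h <- quantized_region(1, 1, 1e6) # near-classical heavy reference
  rw_x <- reweight_observable(function(cfg) cfg[1, 1], mens, msurf,
                              quantized_region(1, 1, 2), th, P = 32,
                              n_paths = 100, seed = 22)
  cl_x <- mean(vapply(mens$configurations, function(m) m[1, 1], numeric(1)))
  expect_gt(rw_x, cl_x) # light-isotope delocalization samples the soft side
})

test_that("effective potential assembles spring and potential terms", {
  th <- reduced_thermo(2)
  surf <- make_model(model_spec("harmonic-1d", list(k = 1)))
  config <- matrix(0, 1, 3)

  # degenerate ring on U = 0: zero
  flat <- surf
  flat$energy_many <- function(X) rep(0, dim(X)[1])
  flat$energy <- function(conf) 0
  p0 <- ring_polymer_path(matrix(0, 4, 3), mass = 1)
  expect_identical(effective_potential(list(p0), config, flat, th), 0)

  # two displaced beads on U = 0: explicit spring arithmetic
  beads <- matrix(0, 4, 3)
  beads[1, 1] <- 0.5
  beads[3, 1] <- -0.5
  p <- ring_polymer_path(beads, mass = 1)
  lambda2 <- thermal_wavelength_sq(1, th)
  # squared bead differences around the ring: 0.5^2 * 4 links... computed
  # directly from the bead table
  d <- beads - beads[c(2:4, 1), ]
  spring_hand <- (4 / (2 * th$beta * lambda2)) * sum(d^2)
  expect_equal(effective_potential(list(p), config, flat, th), spring_hand)

  # with the harmonic potential the slice average adds k/2 mean(x_i^2)
  expect_equal(effective_potential(list(p), config, surf, th),
               spring_hand + 0.5 * mean(beads[, 1]^2))
})

test_that("convergence scan returns a tidy monotone table", {
  fix <- harmonic_fixture(beta = 3, n_configs = 40, seed = 25)
  reg <- quantized_region(1, 1, 2)
  scan <- convergence_scan(c(4, 8, 16), fix$ensemble, fix$surface, reg,
                           fix$thermo, n_paths = 60, n_blocks = 5,
                           seed = 26)
  expect_equal(nrow(scan), 3)
  expect_equal(scan$P, c(4L, 8L, 16L))
  expect_true(all(c("ratio", "stderr") %in% names(scan)))
  expect_error(
    convergence_scan(c(4, 12), fix$ensemble, fix$surface, reg, fix$thermo,
                     n_paths = 10, seed = 1),
    "power of two")

  # deviations from the exact ratio shrink with P (oracle: closed form)
  exact <- harmonic_isotope_ratio_exact(1, 1, 2, fix$thermo)
  dev <- abs(scan$ratio - exact)
  expect_gt(dev[1], dev[3])
})
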