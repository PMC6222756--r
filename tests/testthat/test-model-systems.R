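test_that("built-in surfaces match their analytic forms", {
  h <- make_model(model_spec("harmonic-1d", list(k = 1, r0 = 0)))
  expect_equal(h$energy(matrix(c(2, 0, 0), 1)), 2.0)
  expect_equal(h$energy(matrix(c(0, 5, -3), 1)), 0) # y,z inactive

  m <- make_model(model_spec("morse-1d", list(D = 4, a = 1.2, r0 = 0.5)))
  expect_equal(m$energy(matrix(c(0.5, 0, 0), 1)), 0)
  # curvature at the minimum equals 2 D a^2 by central finite differences
  hstep <- 1e-4
  curv <- (m$energy(matrix(c(0.5 + hstep, 0, 0), 1)) +
             m$energy(matrix(c(0.5 - hstep, 0, 0), 1))) / hstep^2
  expect_equal(curv, 2 * 4 * 1.2^2, tolerance = 1e-5)

  h3 <- make_model(model_spec("harmonic-3d", list(k = 2)))
  expect_equal(h3$energy(matrix(c(1, 1, 1), 1)), 3)
})

test_that("model specification is validated", {
  expect_error(model_spec("quartic-1d"), "unknown model kind")
  expect_error(model_spec("harmonic-1d", list(k = -1)), "strictly positive")
  expect_error(model_spec("morse-1d", list(D = 0)), "strictly positive")
  expect_error(model_spec("harmonic-1d", list(kk = 1)), "unknown parameter")
  expect_error(model_spec("harmonic-1d", masses = 0), "positive")
  expect_error(model_spec("diatomic-in-bath", list(n_bath = -1)),
               "non-negative")
})

test_that("switching function satisfies its endpoint and smoothness contract", {
  expect_equal(switching_function(5.0, 13.0, 13.5), 1.0)
  expect_equal(switching_function(14.0, 13.0, 13.5), 0.0)
  expect_error(switching_function(1, 2, 2), "r_on < r_off")

  r <- seq(0.5, 15, by = 0.01)
  s <- switching_function(r, 13, 13.5)
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(diff(s) <= 1e-12)) # monotone non-increasing

  # C1 continuity at both endpoints by one-sided finite differences
  h <- 1e-7
  for (r0 in c(13, 13.5)) {
    left <- (switching_function(r0, 13, 13.5) -
               switching_function(r0 - h, 13, 13.5)) / h
    right <- (switching_function(r0 + h, 13, 13.5) -
                switching_function(r0, 13, 13.5)) / h
    expect_equal(left, right, tolerance = 1e-4)
  }
})

test_that("analytic gradients agree with finite differences", {
  set.seed(7)
  cases <- list(
    make_model(model_spec("harmonic-1d", list(k = 3, r0 = 0.2))),
    make_model(model_spec("harmonic-3d", list(k = 2, center = c(1, 0, -1)))),
    make_model(model_spec("morse-1d", list(D = 5, a = 0.9, r0 = 0.3))),
    generate_fixture_system(
      model_spec("diatomic-in-bath", list(n_bath = 6, box = 9)), 11)$surface
  )
  base_bath <- generate_fixture_system(
    model_spec("diatomic-in-bath", list(n_bath = 6, box = 9)), 11)$configuration
  h <- 1e-6
  for (surf in cases) {
    for (rep in 1:5) {
      if (surf$label == "diatomic-in-bath") {
        # jitter a valid packing; overlapping pairs would put the energy at
        # ~1e12 where central differences lose all precision
        conf <- base_bath + matrix(stats::rnorm(surf$n_atoms * 3, sd = 0.05),
                                   surf$n_atoms, 3)
      } else {
        conf <- matrix(stats::rnorm(surf$n_atoms * 3, sd = 0.4),
                       surf$n_atoms, 3)
      }
      g <- surf$gradient(conf)
      for (i in seq_len(surf$n_atoms)) {
        for (d in 1:3) {
          cp <- conf; cp[i, d] <- cp[i, d] + h
          cm <- conf; cm[i, d] <- cm[i, d] - h
          fd <- (surf$energy(cp) - surf$energy(cm)) / (2 * h)
          expect_equal(g[i, d], fd, tolerance = 1e-4)
        }
      }
    }
  }
})

test_that("batch and scalar energy evaluators agree", {
  set.seed(3)
  for (kind in c("harmonic-1d", "harmonic-3d", "morse-1d")) {
    surf <- make_model(model_spec(kind))
    X <- array(stats::rnorm(20 * surf$n_atoms * 3, sd = 0.5),
               dim = c(20, surf$n_atoms, 3))
    many <- surf$energy_many(X)
    one <- vapply(1:20, function(s)
      surf$energy(matrix(X[s, , ], surf$n_atoms, 3)), numeric(1))
    expect_equal(many, one)
  }
})

test_that("fixture generation is deterministic and overlap-free", {
  spec <- model_spec("diatomic-in-bath", list(n_bath = 32, box = 13,
                                              sigma = 2.0))
  f1 <- generate_fixture_system(spec, seed = 7)
  f2 <- generate_fixture_system(spec, seed = 7)
  expect_identical(f1$configuration, f2$configuration)

  # bath-involving pairs respect the overlap floor (the solute bond sits
  # closer by construction)
  d <- as.matrix(dist(f1$configuration))
  diag(d) <- Inf
  expect_true(min(d[-(1:2), ]) >= 0.8 * 2.0)

  # solute-only limit: energy equals the gas-phase diatomic energy
  gas <- generate_fixture_system(
    model_spec("diatomic-in-bath", list(n_bath = 0)), 1)
  expect_equal(gas$surface$energy(gas$configuration), 0)

  # impossible packing errors out
  expect_error(
    generate_fixture_system(
      model_spec("diatomic-in-bath", list(n_bath = 60, box = 4, sigma = 3)),
      seed = 1, max_tries = 50),
    "overlap")
})

test_that("zero coupling decouples solute and bath energies exactly", {
  spec0 <- model_spec("diatomic-in-bath", list(n_bath = 10, box = 11,
                                               coupling = 0))
  f <- generate_fixture_system(spec0, seed = 5)
  conf <- f$configuration
  e_tot <- f$surface$energy(conf)
  bond <- 0.5 * spec0$parameters$k *
    (sqrt(sum((conf[1, ] - conf[2, ])^2)) - spec0$parameters$r0)^2
  # solute sits near the center (zero wall term), so e_tot - bond is the
  # pure bath energy; perturbing only the solute must leave it unchanged
  e_bath <- e_tot - bond
  conf2 <- conf
  conf2[1, ] <- conf2[1, ] + c(0.3, -0.2, 0.1)
  bond2 <- 0.5 * spec0$parameters$k *
    (sqrt(sum((conf2[1, ] - conf2[2, ])^2)) - spec0$parameters$r0)^2
  expect_equal(f$surface$energy(conf2) - bond2, e_bath, tolerance = 1e-12)
})
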