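# Force laws, potentials and the Boltzmann oracle.

test_that("worm-like chain force matches direct evaluation and diverges", {
  # zero extension: entropic terms cancel
  expect_equal(wlc_force(0, Lp = 0.7, Lc = 5.096), 0)
  # half extension: 1.25 kBT/Lp
  expect_equal(wlc_force(5.096 / 2, Lp = 0.7, Lc = 5.096, kBT = 4.11),
               1.25 * 4.11 / 0.7, tolerance = 1e-12)
  # 90% extension: (kBT/Lp) (25 - 0.25 + 0.9)
  expect_equal(wlc_force(0.9 * 5.096, Lp = 0.7, Lc = 5.096, kBT = 4.11),
               (4.11 / 0.7) * (25 - 0.25 + 0.9), tolerance = 1e-12)
  # strictly increasing on [0, 0.999 Lc]
  x <- seq(0, 0.999 * 5.096, length.out = 2000)
  expect_true(all(diff(wlc_force(x, 0.7, 5.096)) > 0))
  # domain error at the contour length
  expect_error(wlc_force(5.096, 0.7, 5.096), "extension")
})

test_that("tether force is restoring and symmetric for all three models", {
  for (kind in c("wlc", "hookean", "reflecting")) {
    m <- neck_linker_model(kind)
    tc <- tether_configuration(m, center = 4.1)
    expect_identical(tether_force(4.1, tc, m), 0)
    x <- 4.1 + c(-2, -0.5, 0.5, 2)
    f <- tether_force(x, tc, m)
    expect_true(all(sign(f) == -sign(x - 4.1)))
    expect_equal(f[1], -f[4])  # odd symmetry about the centre
  }
  # Hookean 1 pN/nm at 2 nm extension
  m <- neck_linker_model("hookean")
  tc <- tether_configuration(m, center = 0)
  expect_equal(tether_force(2, tc, m), -2)
  # Reflecting spring is barely there: 0.01 pN/nm
  m <- neck_linker_model("reflecting")
  tc <- tether_configuration(m, center = 0)
  expect_equal(tether_force(-5, tc, m), 0.05)
})

test_that("potential energy is the antiderivative of the force", {
  for (kind in c("wlc", "hookean", "reflecting")) {
    m <- neck_linker_model(kind)
    tc <- tether_configuration(m, center = 4.1)
    expect_identical(potential_energy(4.1, tc, m), 0)
    # central difference of U equals -force on interior points
    x <- seq(0.5, 7.5, by = 0.25)
    h <- 1e-5
    dU <- (potential_energy(x + h, tc, m) -
           potential_energy(x - h, tc, m)) / (2 * h)
    expect_equal(dU, -tether_force(x, tc, m), tolerance = 1e-6)
  }
  # closed forms
  m <- neck_linker_model("hookean")
  tc <- tether_configuration(m, center = 0)
  expect_equal(potential_energy(2, tc, m), 2)          # 0.5 * 1 * 4
  m <- neck_linker_model("reflecting")
  tc <- tether_configuration(m, center = 0)
  expect_equal(potential_energy(5.3, tc, m), 0.5 * 0.01 * 5.3^2)
  # WLC closed form vs numerical quadrature of the force law
  m <- neck_linker_model("wlc")
  tc <- tether_configuration(m, center = 0)
  for (xx in c(1, 2.5, 4, 4.8)) {
    num <- stats::integrate(function(s) wlc_force(s, 0.7, tc$Lc), 0, xx,
                            rel.tol = 1e-10)$value
    expect_equal(potential_energy(xx, tc, m), num, tolerance = 1e-8)
  }
})

test_that("Boltzmann density recovers Gaussian and uniform closed forms", {
  cst <- physics_constants()
  # Hookean: Gaussian with sd sqrt(kBT/kappa), zone mass from pnorm
  m <- neck_linker_model("hookean")
  tc <- tether_configuration(m, center = 4.1)
  g <- seq(4.1 - 14, 4.1 + 14, length.out = 40001)
  d <- boltzmann_density(tc, m, cst, g)
  h <- diff(g)[1]
  expect_equal(sqrt(sum(d * g^2 * h) - sum(d * g * h)^2), sqrt(4.11),
               tolerance = 1e-4)  # stationary OU sd = sqrt(kBT/kappa)
  p <- density_mass(g, d, 7.2, 9.2)
  expect_equal(p, pnorm((9.2 - 4.1) / sqrt(4.11)) -
                  pnorm((7.2 - 4.1) / sqrt(4.11)), tolerance = 1e-3)
  # Reflecting with kappa -> 0: uniform between the barriers
  m0 <- neck_linker_model("reflecting", kappa = 1e-12)
  tc0 <- tether_configuration(m0, center = 4.1)
  g0 <- seq(-1.2, 9.4, length.out = 20001)
  d0 <- boltzmann_density(tc0, m0, cst, g0)
  expect_equal(density_mass(g0, d0, 7.2, 9.2), 2 / 10.6, tolerance = 1e-3)
  expect_lt(diff(range(d0)), 1e-9)  # flat
  # WLC: density vanishes toward the contour length, grid beyond errors
  mw <- neck_linker_model("wlc")
  tcw <- tether_configuration(mw, center = 0)
  gw <- seq(-0.999 * tcw$Lc, 0.999 * tcw$Lc, length.out = 10001)
  dw <- boltzmann_density(tcw, mw, cst, gw)
  expect_lt(dw[1] / max(dw), 1e-12)
  expect_error(boltzmann_density(tcw, mw, cst, seq(-6, 6, 0.01)), "support")
})

test_that("two-linker tether doubles contour length and halves stiffness", {
  m <- neck_linker_model("wlc")
  expect_equal(tether_configuration(m, 0, n_linkers = 2)$Lc,
               2 * 14 * 0.364)
  mh <- neck_linker_model("hookean")
  expect_equal(tether_configuration(mh, 0, n_linkers = 2)$kappa, 0.5)
  mr <- neck_linker_model("reflecting", motor = "kinesin1_DAL")
  tc <- tether_configuration(mr, 0, n_linkers = 2)
  expect_equal(tc$barriers, c(-2, 2) * 5.3 * 17 / 14)
})
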