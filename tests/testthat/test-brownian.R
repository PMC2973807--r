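# Stochastic integrators: drift/variance laws, exact OU transitions,
# reflection without boundary pile-up, and agreement between the compiled
# generator and R's normal quantiles.

test_that("drag and diffusion constants follow Stokes-Einstein", {
  expect_equal(friction_coefficient(3, 1e-9), 6 * pi * 3e-9, tolerance = 1e-12)
  expect_equal(friction_coefficient(6, 1e-9), 2 * friction_coefficient(3, 1e-9))
  expect_error(friction_coefficient(0))
  D <- diffusion_constant(4.11, friction_coefficient(3))
  expect_equal(D, 4.11 / 5.654867e-8, tolerance = 1e-6)
  # rms free displacement over 1 ns is well below the zone half-width
  expect_equal(sqrt(2 * D * 1e-9), 0.381, tolerance = 1e-2)
  expect_equal(diffusion_constant(0, 1), 0)
})

test_that("Euler step has the stated drift and noise variance", {
  set.seed(1)
  p <- diffusion_params(physics_constants(), dt = 1e-9)
  n <- 2e5
  # constant force: mean displacement f dt / xi
  f0 <- 5
  d <- euler_step(rep(0, n), rep(f0, n), p)
  expect_equal(mean(d), f0 * p$dt / p$xi,
               tolerance = 5 * sqrt(2 * p$D * p$dt / n) / (f0 * p$dt / p$xi))
  # zero force: variance 2 D dt
  d0 <- euler_step(rep(0, n), rep(0, n), p)
  expect_equal(var(d0), 2 * p$D * p$dt, tolerance = 5 / sqrt(n))
  expect_error(euler_step(0, NaN, p), "finite")
})

test_that("OU transition moments match the closed form at several dt", {
  cst <- physics_constants()
  kappa <- 1
  x0 <- 3
  for (dt in c(1e-9, 1e-8, 1e-6)) {
    set.seed(7)
    p <- diffusion_params(cst, dt)
    n <- 2e5
    x1 <- ou_exact_step(rep(x0, n), center = 0, kappa = kappa, p)
    emk <- exp(-kappa * dt / p$xi)
    vth <- (cst$kBT / kappa) * (1 - emk^2)
    expect_equal(mean(x1), x0 * emk, tolerance = 4 * sqrt(vth / n) /
                   max(abs(x0 * emk), 1e-12))
    expect_equal(var(x1), vth, tolerance = 5 / sqrt(n))
  }
  # dt -> infinity: stationary law sd sqrt(kBT/kappa) = 2.027 nm
  set.seed(8)
  p <- diffusion_params(cst, dt = 1)
  xs <- ou_exact_step(rep(50, 1e5), 0, 1, p)
  expect_equal(sd(xs), 2.027, tolerance = 0.02)
  expect_equal(mean(xs), 0, tolerance = 0.03)
})

test_that("Euler converges weakly to the OU stationary variance", {
  cst <- physics_constants()
  kappa <- 1
  target <- cst$kBT / kappa
  bias <- function(dt, nstep = 300, n = 2e4) {
    set.seed(12)
    p <- diffusion_params(cst, dt)
    x <- rnorm(n, 0, sqrt(target))
    for (i in seq_len(nstep)) x <- euler_step(x, -kappa * x, p)
    var(x) - target
  }
  # Euler inflates the variance by kappa dt/(2 xi) relative to target
  b1 <- bias(1e-8)
  expect_equal(b1 / target, 1e-8 / (2 * 5.655e-8), tolerance = 0.35)
  expect_lt(abs(bias(5e-9)), abs(b1))  # halving dt shrinks the bias
})

test_that("reflected steps stay inside and show no boundary pile-up", {
  set.seed(3)
  p <- diffusion_params(physics_constants(), dt = 1e-8)
  bar <- c(-1.2, 9.4)
  n <- 4e4
  x <- runif(n, bar[1], bar[2])
  for (i in 1:400) x <- reflected_step(x, rep(0, n), bar, p)
  expect_true(all(x >= bar[1] & x <= bar[2]))
  # uniform stationary law: mean at the midpoint, window mass = w/(hi-lo)
  expect_equal(mean(x), mean(bar), tolerance = 0.02)
  expect_equal(mean(x >= 7.2 & x <= 9.2), 2 / 10.6, tolerance = 0.03)
  # boundary bins match interior bins (Lepingle correction, no pile-up)
  h <- hist(x, breaks = seq(bar[1], bar[2], length.out = 54), plot = FALSE)
  edge <- mean(h$counts[c(1, length(h$counts))])
  interior <- mean(h$counts[-c(1, length(h$counts))])
  expect_lt(abs(edge - interior), 4 * sqrt(interior))
  expect_error(reflected_step(10, 0, bar, p), "outside")
})

test_that("compiled ziggurat normals match N(0,1) moments and tails", {
  z <- neckstep:::ziggurat_normal(2e6, 123)
  expect_equal(mean(z), 0, tolerance = 4 / sqrt(2e6))
  expect_equal(var(z), 1, tolerance = 0.005)
  expect_equal(mean(z^3), 0, tolerance = 0.01)
  expect_equal(mean(z^4), 3, tolerance = 0.03)
  expect_equal(mean(abs(z) > 3), 2 * pnorm(-3), tolerance = 0.1)
  expect_equal(mean(abs(z) > 4), 2 * pnorm(-4), tolerance = 0.3)
  # deterministic given the seed
  expect_identical(z[1:10], neckstep:::ziggurat_normal(10, 123))
})

test_that("every integrator reproduces its Boltzmann stationary law", {
  # total-variation distance between the long-run histogram and the
  # quadrature oracle, at a dt small enough that discretisation error is
  # below the Monte-Carlo resolution
  tv_dist <- function(name, dt, sim_time, nbins = 100) {
    cfg <- fixture_config(name)
    s <- stationary_distribution(cfg, sim_time = sim_time, seed = 5,
                                 nbins = nbins, dt = dt)
    tc <- s$tether
    g <- (s$bin_edges[-1] + s$bin_edges[-(nbins + 1)]) / 2
    if (cfg$model$kind == "wlc") {
      keep <- abs(g - tc$center) < 0.999 * tc$Lc
      d <- rep(0, nbins)
      d[keep] <- boltzmann_density(tc, cfg$model, cfg$physics, g[keep]) *
        diff(s$bin_edges)[1]
    } else {
      d <- boltzmann_density(tc, cfg$model, cfg$physics, g) *
        diff(s$bin_edges)[1]
    }
    sum(abs(s$probability - d / sum(d))) / 2
  }
  expect_lt(tv_dist("wlc07_kin1", dt = 2.5e-10, sim_time = 1e-2), 0.02)
  expect_lt(tv_dist("hookean_kin1", dt = 1e-8, sim_time = 2e-2), 0.02)
  expect_lt(tv_dist("reflecting_kin1", dt = 1e-8, sim_time = 4e-2), 0.02)
})
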