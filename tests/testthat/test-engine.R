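# Chemomechanical cycle: Gillespie hold, binding zones, Bernoulli channel
# frequencies, run bookkeeping and reproducibility.

test_that("state-1 Gillespie hold has the right mean dwell and branching", {
  r <- rate_constants("wlc")
  set.seed(2)
  draws <- replicate(2e4, {
    g <- gillespie_state1(r)
    c(g$dwell, g$next_state)
  })
  m <- 1 / (250 + 0.25)                # 3.996 ms
  expect_equal(mean(draws[1, ]), m, tolerance = 4 / sqrt(2e4))
  expect_equal(mean(draws[2, ] == 2), 250 / 250.25, tolerance = 0.005)
  # no reverse channel: always to state 2
  r0 <- rate_constants("wlc", k_detach_rev = 0)
  set.seed(3)
  expect_true(all(replicate(200, gillespie_state1(r0)$next_state) == 2L))
})

test_that("binding rate is k_attach inside a zone and zero outside", {
  g <- track_geometry()
  expect_equal(binding_rate(8.2, 8.2, g, 75000), 75000)     # zone centre
  expect_equal(binding_rate(9.2, 8.2, g, 75000), 75000)     # closed edge
  expect_equal(binding_rate(5.0, 8.2, g, 75000), 0)         # outside
  expect_equal(binding_rate(-8.2, c(-8.2, 8.2), g, 75000), 75000)
  expect_equal(binding_rate(-8.2, 8.2, g, 75000), 0)        # rear not allowed
  cfg <- engine_config("kinesin1", "wlc")
  expect_equal(neckstep:::state_sites(2L, cfg), c(-8.2, 8.2))
  expect_equal(neckstep:::state_sites(4L, cfg), 8.2)
})

test_that("channel frequencies match the per-step Bernoulli thresholds", {
  cfg <- engine_config("kinesin1", "wlc")
  dt <- cfg$dt
  n <- 2e5
  set.seed(4)
  # state 4 with the head held in the zone: exits split 8 : 3 : 75000
  u <- runif(n)
  out <- vapply(u, function(uu)
    neckstep:::chem_transition(4L, 8.2, cfg, uu), integer(1))
  p_exp <- c(`3` = 8, `5` = 3, `1` = 75000) * dt
  for (st in names(p_exp)) {
    p <- p_exp[[st]]
    expect_equal(mean(out == as.integer(st)), p,
                 tolerance = 4 * sqrt(p * (1 - p) / n) / p)
  }
  # state 4 out of the zone: binding channel closed
  out2 <- vapply(u, function(uu)
    neckstep:::chem_transition(4L, 5.0, cfg, uu), integer(1))
  expect_false(any(out2 == 1L))
  # state 2 ATP on-rate at 1 mM: 3000/s
  out3 <- vapply(u, function(uu)
    neckstep:::chem_transition(2L, 0, cfg, uu), integer(1))
  expect_equal(mean(out3 == 3L), 3000 * dt,
               tolerance = 4 * sqrt(3000 * dt / n) / (3000 * dt))
  # threshold sums exceeding one are rejected at config build
  expect_error(engine_config("kinesin1", "wlc", dt = 5e-6), "dt too large")
})

test_that("diffusive_state_step keeps the head inside the tether support", {
  set.seed(9)
  for (kind in c("wlc", "hookean", "reflecting")) {
    cfg <- engine_config("kinesin1", kind)
    x <- 0
    for (i in 1:200) {
      st <- diffusive_state_step(4L, x, cfg)
      x <- st$head
      expect_true(is.finite(x))
    }
    if (kind == "reflecting") {
      tc <- neckstep:::state_tethers(cfg)$s4
      expect_true(x >= tc$barriers[1] && x <= tc$barriers[2])
    }
  }
})

test_that("runs are reproducible and bookkeeping is consistent", {
  cfg <- fixture_config("reflecting_kin1")
  r1 <- run_single_motor(cfg, seed = 77)
  r2 <- run_single_motor(cfg, seed = 77)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$run_length, r2$run_length)
  expect_false(identical(
    r1$run_length, run_single_motor(cfg, seed = 78)$run_length))
  # run length equals the sum of logged signed steps
  expect_equal(r1$run_length, sum(r1$events$step))
  expect_equal(r1$run_length,
               8.2 * (r1$n_steps_forward - r1$n_steps_backward))
  # event times strictly increasing, chemistry starts in state 2
  expect_true(all(diff(r1$events$time) >= 0))
  expect_identical(r1$events$state[1], 2)
  expect_identical(r1$termination, "detached")
  expect_identical(r1$events$state[nrow(r1$events)], 5)
})

test_that("no binding fires outside the zone of an allowed site", {
  cfg <- fixture_config("reflecting_kin1")
  for (seed in 1:6) {
    r <- run_single_motor(cfg, seed = seed)
    ev <- r$events
    bind <- which(ev$state == 1)
    expect_gt(length(bind), 0)
    x <- ev$x[bind]
    in_fwd <- abs(x - 8.2) <= 1
    in_rear <- abs(x + 8.2) <= 1
    expect_true(all(in_fwd | in_rear))
    # rear bindings only happen out of state 2
    prev_state <- ev$state[bind - 1]
    expect_true(all(in_fwd[prev_state == 4]))
  }
})

test_that("runs without unbinding only end at max_time", {
  cfg <- engine_config("kinesin1", "reflecting",
                       rates = rate_constants("reflecting", k_unbind = 0),
                       max_time = 0.05)
  r <- run_single_motor(cfg, seed = 5)
  expect_identical(r$termination, "max_time")
  expect_gte(r$total_time, 0.05)
})

test_that("ensembles are deterministic given the base seed", {
  cfg <- fixture_config("hookean_kin1")
  e1 <- simulate_ensemble(cfg, n_runs = 6, base_seed = 10)
  e2 <- simulate_ensemble(cfg, n_runs = 6, base_seed = 10)
  s1 <- ensemble_summary(e1)
  s2 <- ensemble_summary(e2)
  expect_identical(s1$velocity_mean, s2$velocity_mean)
  expect_identical(s1$runlength_mean, s2$runlength_mean)
  # distinct runs within the ensemble
  expect_gt(sd(vapply(e1$runs, function(r) r$run_length, numeric(1))), 0)
})

test_that("backward steps are exceedingly rare", {
  s <- cached_summary("wlc07_kin1", 25)
  expect_lt(s$backward_fraction, 0.01)
})

test_that("binding bookkeeping advances the frame one site per forward bind", {
  a <- list(bound_position = 0, displacement = 0, steps = numeric(0),
            head = 8.3)
  a <- complete_step_on_binding(a, +1)
  expect_equal(a$displacement, 8.2)
  a <- complete_step_on_binding(a, +1)
  expect_equal(a$displacement, 16.4)          # two forward steps add
  expect_equal(a$steps, c(8.2, 8.2))
  b <- complete_step_on_binding(a, -1)        # futile rear rebind
  expect_equal(b$displacement, a$displacement)
  expect_error(complete_step_on_binding(a, 2))
})
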