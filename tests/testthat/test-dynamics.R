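test_that("the cue table drives the three-state machine", {
  expect_equal(apply_cue("State1", "Fuel1"), "State2")
  expect_equal(apply_cue("State2", "Antifuel2"), "State3")
  expect_equal(apply_cue("State3", "Fuel2"), "State2")
  expect_equal(apply_cue("State2", "Antifuel1"), "State1")
  expect_warning(s <- apply_cue("State1", "Antifuel1"), "no-op")
  expect_equal(s, "State1")
  expect_error(apply_cue("State1", "Fuel9"), "unknown cue")
  expect_error(apply_cue("State9", "Fuel1"), "unknown state")

  # the full forward + reverse protocol visits 2, 3, 2, 1
  st <- "State1"
  visited <- character(0)
  for (cue in c("Fuel1", "Antifuel2", "Fuel2", "Antifuel1")) {
    st <- suppressWarnings(apply_cue(st, cue))
    visited <- c(visited, st)
  }
  expect_equal(visited, c("State2", "State3", "State2", "State1"))
})

test_that("every state is reachable from every other within two cues", {
  states <- c("State1", "State2", "State3")
  cues <- c("Fuel1", "Antifuel1", "Fuel2", "Antifuel2")
  for (from in states) {
    reach <- from
    for (c1 in cues) {
      s1 <- suppressWarnings(apply_cue(from, c1))
      reach <- c(reach, s1)
      for (c2 in cues) reach <- c(reach, suppressWarnings(apply_cue(s1, c2)))
    }
    expect_setequal(unique(reach), states)
  }
})

test_that("state equilibria follow the anchor library and keep their ordering", {
  f1 <- state_equilibrium_f("State1")
  f2a <- state_equilibrium_f("State2", state2_mode = "additive")
  f2m <- state_equilibrium_f("State2", state2_mode = "measured",
                             measured_sT_dC = 1.0)
  f3 <- state_equilibrium_f("State3")
  expect_equal(f1, dG_to_fraction(1.9))
  expect_equal(f2a, dG_to_fraction(1.1))        # 1.9 - 0.8 kBT
  expect_equal(round(f2a, 3), 0.250)
  expect_equal(round(f2m, 3), 0.269)
  expect_equal(f3, dG_to_fraction(-0.8))
  expect_true(f1 < f2a && f2a < f3)
  expect_true(f1 < f2m && f2m < f3)

  # ordering holds for any library with an Ld-avid sT (dG > 0) and an
  # Lo-avid dC (dG < 0)
  set.seed(8)
  for (i in 1:20) {
    lib <- data.frame(tag = c("sT", "dC"),
                      dG = c(stats::runif(1, 0.1, 3),
                             stats::runif(1, -3, -0.1)))
    g1 <- state_equilibrium_f("State1", lib)
    g2 <- state_equilibrium_f("State2", lib)
    g3 <- state_equilibrium_f("State3", lib)
    expect_true(g1 < g2 && g2 < g3)
  }

  # hysteresis applies only on the reverse path
  expect_equal(state_equilibrium_f("State1", hysteresis = 0, reverse = TRUE),
               state_equilibrium_f("State1"))
  expect_equal(state_equilibrium_f("State1", hysteresis = 0.05, reverse = TRUE),
               state_equilibrium_f("State1") + 0.05)
  expect_error(state_equilibrium_f("State1",
                                   data.frame(tag = "dC", dG = -0.8)),
               "no entry")
})

test_that("relaxation traces follow the single-exponential law", {
  tr <- relax_trace(0.14, 0.26, tau = 5, times = c(0, 5, 25))
  expect_equal(tr$f[1], 0.14)
  expect_equal(tr$f[2], 0.26 + (0.14 - 0.26) * exp(-1))
  expect_equal(tr$f[2], 0.216, tolerance = 1e-3)
  # by t = 5 tau the trace is within 1% of equilibrium
  expect_lt(abs(tr$f[3] - 0.26) / abs(0.14 - 0.26), 0.01)

  flat <- relax_trace(0.3, 0.3, tau = 2, times = 0:10)
  expect_equal(flat$f, rep(0.3, 11))
  # monotone between f0 and f_eq
  tr2 <- relax_trace(0.9, 0.2, tau = 3, times = seq(0, 30, 0.5))
  expect_true(all(diff(tr2$f) < 0))
  expect_true(all(tr2$f >= 0.2 & tr2$f <= 0.9))
  expect_error(relax_trace(0.1, 0.2, tau = 0, times = 0:5), "tau")
  expect_error(relax_trace(0.1, 0.2, tau = 1, times = c(3, 1)),
               "non-decreasing")
})

test_that("protocol traces are continuous, plateaued and reversible", {
  proto <- data.frame(time_min = c(30, 60, 90, 120),
                      cue = c("Fuel1", "Antifuel2", "Fuel2", "Antifuel1"))
  tr <- simulate_protocol(proto, tau = 5, dt = 0.05)
  expect_equal(tr$f[1], dG_to_fraction(1.9))
  expect_equal(tr$state[nrow(tr)], "State1")
  # continuity at cue times: no jump larger than the dt-step scale
  expect_lt(max(abs(diff(tr$f))), 0.01)
  # plateaus: just before each cue the trace sits at the segment equilibrium
  eqs <- c(dG_to_fraction(1.9), dG_to_fraction(1.1), dG_to_fraction(-0.8),
           dG_to_fraction(1.1), dG_to_fraction(1.9))
  at <- function(t) tr$f[which.min(abs(tr$time_min - t))]
  expect_equal(at(29.9), eqs[1], tolerance = 0.01)
  expect_equal(at(59.9), eqs[2], tolerance = 0.01)
  expect_equal(at(89.9), eqs[3], tolerance = 0.01)
  expect_equal(at(119.9), eqs[4], tolerance = 0.01)
  expect_equal(tr$f[nrow(tr)], eqs[5], tolerance = 0.01)

  # with hysteresis the final f stays above the initial value
  trh <- simulate_protocol(proto, tau = 5, dt = 0.05, hysteresis = 0.04)
  expect_gt(trh$f[nrow(trh)], trh$f[1] + 0.02)

  # no cues: flat trace at the initial equilibrium
  tr0 <- simulate_protocol(data.frame(time_min = numeric(0),
                                      cue = character(0)))
  expect_equal(unique(tr0$f), dG_to_fraction(1.9))

  # grid refinement does not change values at shared time points
  trc <- simulate_protocol(proto, tau = 5, dt = 0.5)
  trf <- simulate_protocol(proto, tau = 5, dt = 0.25)
  shared <- intersect(trc$time_min, trf$time_min)
  expect_equal(trc$f[match(shared, trc$time_min)],
               trf$f[match(shared, trf$time_min)])
})
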