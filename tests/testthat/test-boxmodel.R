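zero_sink <- function(tau_ex = 1) {
  # epsilon 0 gives alpha = 1; k_oh must be > 0 so use a negligible rate
  sink_parameters(k_oh = 1e-300, k_minor = 0, epsilon = 0, tau_ex = tau_ex)
}

no_src <- list(s12_n = 0, s12_s = 0, s13_n = 0, s13_s = 0)

test_that("equal boxes with no sources or sinks are a fixed point", {
  st <- isotope_state(2000, 100, 100, 1.1, 1.1)
  nx <- step_forward(st, no_src, zero_sink())
  expect_equal(nx$m12_n, 100)
  expect_equal(nx$m12_s, 100)
  expect_equal(nx$m13_n, 1.1)
  expect_equal(nx$m13_s, 1.1)
  expect_equal(nx$year, 2001)
})

test_that("interhemispheric exchange moves mass at 1/(2 tau) and conserves totals", {
  st <- isotope_state(2000, 2, 1, 2 * 0.0112, 1 * 0.0112)
  nx <- step_forward(st, no_src, zero_sink(tau_ex = 1))
  expect_equal(nx$m12_n, 1.5)  # delta = -(1/2)*2 + (1/2)*1 = -0.5
  expect_equal(nx$m12_s, 1.5)
  expect_equal(nx$m12_n + nx$m12_s, st$m12_n + st$m12_s, tolerance = 1e-15)
  expect_equal(nx$m13_n + nx$m13_s, st$m13_n + st$m13_s, tolerance = 1e-15)
})

test_that("mass is conserved to 1e-12 relative over many sink-free steps", {
  set.seed(42)
  for (rep in 1:5) {
    m <- runif(2, 1000, 6000)
    r <- 0.0112372 * (1 + runif(2, -0.05, 0.05))
    st <- isotope_state(2000, m[1], m[2], m[1] * r[1], m[2] * r[2])
    tot12 <- st$m12_n + st$m12_s
    tot13 <- st$m13_n + st$m13_s
    sk <- zero_sink(tau_ex = runif(1, 0.5, 3))
    for (i in 1:50) st <- step_forward(st, no_src, sk)
    expect_equal(st$m12_n + st$m12_s, tot12, tolerance = 1e-12)
    expect_equal(st$m13_n + st$m13_s, tot13, tolerance = 1e-12)
  }
})

test_that("constant source and rate converge to the S/k steady state", {
  k <- 0.25
  s_glob <- 500
  sinks <- sink_parameters(k, epsilon = 0)
  st <- isotope_state(2000, 800, 700, 800 * 0.0112, 700 * 0.0112)
  src <- list(s12_n = s_glob * 0.6, s12_s = s_glob * 0.4,
              s13_n = s_glob * 0.6 * 0.011, s13_s = s_glob * 0.4 * 0.011)
  for (i in 1:200) st <- step_forward(st, src, sinks)
  expect_equal(st$m12_n + st$m12_s, (src$s12_n + src$s12_s) / k,
               tolerance = 1e-9)
})

test_that("long runs satisfy the steady-state isotope closed form to 1e-9", {
  conv <- delta_convention()
  eps <- -6.9
  delta_src <- -54
  sp <- split_isotopologues(550, delta_src, conv)
  src <- list(s12_n = sp$s12 / 2, s12_s = sp$s12 / 2,
              s13_n = sp$s13 / 2, s13_s = sp$s13 / 2)
  sinks <- sink_parameters(0.12, epsilon = eps)
  st <- state_from_observation(2000, 1700, -47)
  for (i in 1:600) st <- step_forward(st, src, sinks)
  d_atm <- to_delta(st, conv)$global
  expect_equal((1 + d_atm / 1000) * (1 + eps / 1000), 1 + delta_src / 1000,
               tolerance = 1e-9)
})

test_that("delta reporting uses mass-summed isotopologues for the global value", {
  conv <- delta_convention()
  st <- isotope_state(2000, 100, 300,
                      100 * ratio_from_delta(-40, conv),
                      300 * ratio_from_delta(-60, conv))
  d <- to_delta(st, conv)
  expect_equal(d$nh, -40, tolerance = 1e-9)
  expect_equal(d$sh, -60, tolerance = 1e-9)
  # global is the 12C-mass-weighted combination (-55), not the average of
  # the hemispheric deltas (-50)
  expect_equal(d$global, -55, tolerance = 1e-9)
  expect_equal(d$global,
               combine_isotopologues(400, st$m13_n + st$m13_s, conv))
})

test_that("trajectories are linear in (initial state, sources)", {
  years <- 2000:2009
  f1 <- flat_forcing(years, 300, 250, 3.3, 2.8)
  f2 <- flat_forcing(years, 100, 150, 1.1, 1.6)
  f12 <- flat_forcing(years, 400, 400, 4.4, 4.4)
  sinks <- sink_parameters(0.11, epsilon = -5)
  i1 <- isotope_state(2000, 2000, 1900, 22, 21)
  i2 <- isotope_state(2000, 500, 600, 5.5, 6.6)
  i12 <- isotope_state(2000, 2500, 2500, 27.5, 27.6)
  t1 <- run_forward(f1, sinks, i1)
  t2 <- run_forward(f2, sinks, i2)
  t12 <- run_forward(f12, sinks, i12)
  for (col in c("m12_n", "m12_s", "m13_n", "m13_s")) {
    expect_equal(t12[[col]], t1[[col]] + t2[[col]], tolerance = 1e-12)
  }
})

test_that("scaling sources and initial masses by a common factor leaves delta unchanged", {
  years <- 2000:2014
  f <- flat_forcing(years, 280, 240, 3.1, 2.7)
  f2 <- flat_forcing(years, 560, 480, 6.2, 5.4)
  sinks <- sink_parameters(0.13, epsilon = -6)
  init <- isotope_state(2000, 2400, 2300, 26, 25)
  init2 <- isotope_state(2000, 4800, 4600, 52, 50)
  t1 <- run_forward(f, sinks, init)
  t2 <- run_forward(f2, sinks, init2)
  expect_equal(t2$d13c_global, t1$d13c_global, tolerance = 1e-12)
  expect_equal(t2$ch4_ppb_global, 2 * t1$ch4_ppb_global, tolerance = 1e-12)
})

test_that("25-step constant forcing approaches the analytic steady-state delta", {
  conv <- delta_convention()
  eps <- -6.9
  delta_src <- -53
  sp <- split_isotopologues(600, delta_src, conv)
  f <- flat_forcing(1993:2100, sp$s12 / 2, sp$s12 / 2, sp$s13 / 2, sp$s13 / 2)
  sinks <- sink_parameters(0.35, epsilon = eps)  # short lifetime: fast spin-up
  d_star <- 1000 * ((1 + delta_src / 1000) / (1 + eps / 1000) - 1)
  init <- state_from_observation(1993, tg_to_ppb(600 / 0.35), d_star + 0.5)
  tr <- run_forward(f, sinks, init, n_years = 25)
  expect_equal(tr$d13c_global[26], d_star, tolerance = 1e-3)
})

test_that("invalid steps are rejected with diagnostics", {
  st <- isotope_state(2000, 100, 100, 1.1, 1.1)
  expect_error(step_forward(st, list(s12_n = NaN, s12_s = 0, s13_n = 0,
                                     s13_s = 0), zero_sink()), "finite")
  expect_error(step_forward(st, list(s12_n = -200, s12_s = 0, s13_n = 0,
                                     s13_s = 0), zero_sink()),
               "non-positive mass")
  expect_error(isotope_state(2000, -1, 1, 0.01, 0.01), "positive")
  expect_error(sink_parameters(0.1, epsilon = -150), "alpha")
  expect_error(run_forward(flat_forcing(2000:2004, 1, 1, 0.01, 0.01),
                           zero_sink(), st, n_years = 10), "cover")
})
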