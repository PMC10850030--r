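test_that("degenerate config gives constant series (G stays zero)", {
  s <- generate_outdoor_series(flat_config(seed = 1))
  expect_true(all(s$T_a == 10.5))
  expect_true(all(s$T_d == 10.5 - 4))
  expect_true(all(s$v == 2.5))
  expect_true(all(s$p == 1005))
  expect_true(all(s$A_G == 310))
  expect_true(all(s$G == 0))
})

test_that("seasonal amplitude is recovered from the daily-mean annual cycle", {
  A <- 9
  cfg <- flat_config(seed = 1)
  cfg$T_a$seasonal_amp <- A
  s <- generate_outdoor_series(cfg)
  daily <- tapply(s$T_a, as.Date(s$timestamp, tz = "UTC"), mean)
  expect_equal(max(daily) - min(daily), 2 * A, tolerance = 0.01)
})

test_that("irradiance is zero outside the daylight window and G >= 0", {
  for (seed in 1:3) {
    s <- generate_outdoor_series(outdoor_climate_config(seed = seed))
    hod <- as.integer(format(s$timestamp, "%H", tz = "UTC"))
    doy <- as.integer(format(s$timestamp, "%j", tz = "UTC"))
    hw <- indoorheat:::daylight_half_width(doy, outdoor_climate_config()$solar)
    expect_true(all(s$G[abs(hod - 12) >= hw] == 0))
    expect_true(all(s$G >= 0))
  }
})

test_that("generated series satisfy physical invariants and seed determinism", {
  cfg <- outdoor_climate_config(seed = 99, span_years = 2)
  s1 <- generate_outdoor_series(cfg)
  s2 <- generate_outdoor_series(cfg)
  expect_identical(s1, s2)
  expect_true(all(s1$T_d <= s1$T_a))
  expect_true(all(s1$v >= 0))
  expect_true(all(s1$p > 0))
  expect_true(all(s1$A_G > 0))
  expect_true(all(diff(as.numeric(s1$timestamp)) == 3 * 3600))
  cfg2 <- outdoor_climate_config(seed = 100)
  expect_false(identical(generate_outdoor_series(cfg2)$T_a, s1$T_a[1:2920]))
})

test_that("generator rejects invalid configs", {
  expect_error(outdoor_climate_config(step_hours = 2), "1 or 3")
  expect_error(outdoor_climate_config(span_years = 0.5), "span_years")
  expect_error(outdoor_climate_config(T_a = list(ar = 1)), "AR coefficient")
  expect_error(outdoor_climate_config(T_a = list(seasonal_amp = -1)),
               "amplitudes")
})

test_that("zero scenario is the identity and bias is an exact shift", {
  s <- generate_outdoor_series(outdoor_climate_config(seed = 4))
  null <- apply_climate_scenario(s, scenario_config("null"))
  expect_equal(as.data.frame(null), as.data.frame(s))
  shifted <- apply_climate_scenario(s, scenario_config("b", bias = c(T_a = 2)))
  expect_equal(mean(shifted$T_a) - mean(s$T_a), 2.0, tolerance = 1e-12)
  expect_equal(shifted$T_d, pmin(s$T_d, shifted$T_a))
})

test_that("linear ramp accrues the configured total change", {
  # +4 K over 30 years: last-decade minus first-decade mean = 4 * 20/30
  s <- generate_outdoor_series(flat_config(seed = 1, span_years = 30))
  r <- apply_climate_scenario(s, scenario_config("ramp", trend = c(T_a = 4)))
  n <- nrow(r)
  third <- floor(n / 3)
  d <- mean(r$T_a[(n - third + 1):n]) - mean(r$T_a[1:third])
  expect_equal(d, 4 * 20 / 30, tolerance = 0.01)
  # mean difference to input = bias + offset + trend/2
  full <- apply_climate_scenario(s, scenario_config(
    "x", bias = c(T_a = 1), offset = c(T_a = 2), trend = c(T_a = 4)))
  expect_equal(mean(full$T_a) - mean(s$T_a), 1 + 2 + 2, tolerance = 0.01)
})

test_that("multiplicative scenario components preserve zeros of G", {
  s <- generate_outdoor_series(outdoor_climate_config(seed = 5))
  r <- apply_climate_scenario(s, scenario_config("g", offset = c(G = 0.2)))
  expect_true(all(r$G[s$G == 0] == 0))
  expect_true(all(r$G >= 0))
})

test_that("scenario config validates inputs", {
  expect_error(scenario_config(""), "nonempty")
  expect_error(scenario_config("x", bias = c(bogus = 1)), "unknown variable")
  expect_error(scenario_config("x", trend = c(T_a = Inf)), "finite")
})

test_that("a fast building passes outdoor temperature through", {
  s <- constant_series(200, T_a = 10)
  s$T_a <- 10 + 5 * sin(seq_len(200) / 10)
  s$T_d <- pmin(s$T_d, s$T_a)
  bld <- building_parameters(tau = 0.1, a = 0, q_base = 0, q_work = 0,
                             noise_sd = 0)
  ind <- simulate_indoor(s, bld, seed = 1)
  spin <- 9:200  # one day of spin-up at 3-h steps
  expect_lt(max(abs(ind$T_i[spin] - s$T_a[spin])), 0.1)
})

test_that("constant forcing reaches the closed-form steady state", {
  tau <- 20; a <- 2e-4; q <- 0.05; G <- 400; T_a <- 15
  s <- constant_series(8 * 30, T_a = T_a, G = G)
  bld <- building_parameters(tau = tau, a = a, q_base = q, q_work = 0,
                             noise_sd = 0)
  ind <- simulate_indoor(s, bld, seed = 1)
  expect_equal(ind$T_i[nrow(ind)], T_a + tau * (a * G + q), tolerance = 0.05)
})

test_that("strong heating holds the setpoint in cold weather", {
  s <- constant_series(8 * 10, T_a = -5, T_d = -8)
  bld <- building_parameters(tau = 40, a = 0, q_base = 0, q_work = 0,
                             T_set = 21, k = 5, noise_sd = 0)
  ind <- simulate_indoor(s, bld, seed = 1, T_i0 = 10)
  late <- ind$T_i[30:nrow(ind)]
  expect_true(all(late >= 20.5 & late <= 21.5))
})

test_that("sub-stepping is stable where plain Euler is rejected", {
  s <- constant_series(50)
  bld <- building_parameters(tau = 0.5, noise_sd = 0)
  expect_error(simulate_indoor(s, bld, substeps = FALSE), "unstable step")
  ind <- simulate_indoor(s, bld)  # substeps on: fine
  expect_true(all(is.finite(ind$T_i)))
})

test_that("indoor simulation is deterministic and respects invariants", {
  s <- generate_outdoor_series(outdoor_climate_config(seed = 11))
  bld <- building_parameters(T_set = 21)
  i1 <- simulate_indoor(s, bld, seed = 7)
  i2 <- simulate_indoor(s, bld, seed = 7)
  expect_identical(i1, i2)
  expect_true(all(i1$RH >= 0 & i1$RH <= 100))
  expect_true(all(i1$v_i >= 0))
  expect_identical(nrow(i1), nrow(s))
})

test_that("series CSV round-trips", {
  s <- generate_outdoor_series(outdoor_climate_config(seed = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(s, f)
  r <- read_series_csv(f, "meteo")
  expect_equal(as.data.frame(r), as.data.frame(s), tolerance = 1e-6)
  expect_identical(attr(r, "step_hours"), attr(s, "step_hours"))
})
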