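test_that("no biomass means frozen chemistry", {
  m <- consortium_model(list(make_producer()), S0 = 10, A0 = 1, L0 = 0.5,
                        X0 = 0)
  tr <- simulate_consortium(m, seq(0, 24, 4))
  expect_equal(tr$states[, "S"], rep(10, 7), ignore_attr = TRUE)
  expect_equal(tr$states[, "A"], rep(1, 7), ignore_attr = TRUE)
  expect_equal(tr$states[, "L"], rep(0.5, 7), ignore_attr = TRUE)
})

test_that("mass balance: yields tie product and biomass to substrate", {
  # producer with no death, no maintenance, no uptake
  p <- make_producer(Y_sx = 0.3, Y_a = 0.4, Y_l = 0.2)
  m <- consortium_model(list(p), S0 = 8, X0 = 0.02)
  tr <- simulate_consortium(m, seq(0, 48, 2))
  dS <- 8 - tr$states[, "S"]
  late <- dS > 1e-3
  expect_equal(tr$states[late, "X_P1"] - 0.02, 0.3 * dS[late],
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(tr$states[late, "A"], 0.4 * dS[late], tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(tr$states[late, "L"], 0.2 * dS[late], tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("trajectory invariants: nonnegative, Xm monotone, S monotone", {
  m <- reference_model(c("Bi", "Bv", "Ec", "La"),
                       X0 = c(Bi = 0.01, Bv = 0.002, Ec = 0.05, La = 0.01))
  tr <- simulate_consortium(m, seq(0, 72, 1))
  expect_true(all(tr$states >= 0))
  for (l in tr$labels)
    expect_true(all(diff(tr$states[, paste0("Xm_", l)]) >= -1e-8))
  expect_true(all(diff(tr$states[, "S"]) <= 1e-8))
})

test_that("adaptive solution matches the fixed-step RK4 oracle", {
  m <- reference_model(c("Bi", "Ec"), X0 = c(Bi = 0.01, Ec = 0.05))
  times <- seq(0, 24, 2)
  tr <- simulate_consortium(m, times)
  oracle <- rk4_integrate(build_rhs(m),
                          unname(crossfeed:::initial_state(m)),
                          times, dt = 1e-3)
  # error relative to each state's dynamic range
  scale <- rep(pmax(apply(abs(oracle), 2, max), 1e-6),
               each = nrow(oracle))
  expect_lt(max(abs(tr$states - oracle) / scale), 1e-4)
})

test_that("pair model with one inoculum zeroed reduces to the mono model", {
  pair <- reference_model(c("Bi", "Ec"), X0 = c(Bi = 0.01, Ec = 0))
  mono <- reference_model("Bi", X0 = 0.01)
  times <- seq(0, 48, 2)
  tp <- simulate_consortium(pair, times, rtol = 1e-10, atol = 1e-12)
  tm <- simulate_consortium(mono, times, rtol = 1e-10, atol = 1e-12)
  for (col in c("S", "A", "L", "X_Bi", "Xm_Bi"))
    expect_lt(max(abs(tp$states[, col] - tm$states[, col])), 1e-8)
  # four-species version
  quad <- reference_model(X0 = c(Bi = 0.01, Bv = 0, Ec = 0, La = 0))
  tq <- simulate_consortium(quad, times, rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(tq$states[, "X_Bi"] - tm$states[, "X_Bi"])), 1e-8)
})

test_that("simulation is invariant to a consistent species permutation", {
  lib <- ref_lib()
  ord1 <- c("Bi", "Bv", "Ec", "La")
  ord2 <- c("La", "Ec", "Bi", "Bv")
  x0 <- c(Bi = 0.01, Bv = 0.002, Ec = 0.05, La = 0.01)
  m1 <- consortium_model(unname(lib$species[ord1]),
                         subset_interactions(lib$interactions, ord1),
                         S0 = 10, X0 = x0[ord1])
  m2 <- consortium_model(unname(lib$species[ord2]),
                         subset_interactions(lib$interactions, ord2),
                         S0 = 10, X0 = x0[ord2])
  t1 <- simulate_consortium(m1, seq(0, 48, 4))
  t2 <- simulate_consortium(m2, seq(0, 48, 4))
  for (col in colnames(t1$states))
    expect_equal(t1$states[, col], t2$states[, col], tolerance = 1e-7)
})

test_that("integrator failure carries a diagnostic with the last time", {
  m <- consortium_model(list(make_producer()), S0 = 10, X0 = 0.01)
  err <- tryCatch(simulate_consortium(m, seq(0, 48, 2), max_steps = 3),
                  error = function(e) e)
  expect_s3_class(err, "crossfeed_integration_error")
  expect_true(is.numeric(err$last_time))
})

test_that("trajectories round-trip through CSV", {
  m <- reference_model("Ec")
  tr <- simulate_consortium(m, seq(0, 24, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path, header = c(seed = "1"))
  tr2 <- read_trajectory(path)
  expect_equal(tr2$times, tr$times)
  expect_equal(tr2$states, tr$states, tolerance = 1e-12)
  expect_identical(tr2$labels, "Ec")
})
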