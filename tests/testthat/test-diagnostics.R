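test_that("structural non-identifiability: a pure product is flagged", {
  # residuals depend on a*b only
  resid <- function(cand) {
    ab <- cand[["a"]] * cand[["b"]]
    xs <- 1:10
    ab * xs - 6 * xs
  }
  fit <- list(estimates = c(a = 2, b = 3))
  rep <- parameter_correlation(fit, resid)
  expect_equal(abs(rep$correlation["a", "b"]), 1, tolerance = 1e-6)
  expect_equal(nrow(rep$flagged), 1)
})

test_that("orthogonal linear parameters are uncorrelated", {
  # residuals: a acts on the first half, b on the second
  resid <- function(cand)
    c(rep(cand[["a"]] - 1, 5), rep(cand[["b"]] - 2, 5)) + (1:10) * 0.01
  rep <- parameter_correlation(list(estimates = c(a = 1.1, b = 2.1)), resid)
  expect_lt(abs(rep$correlation["a", "b"]), 0.1)
  expect_equal(diag(rep$correlation), c(a = 1, b = 1))
})

test_that("correlation matrix is symmetric and PSD-consistent", {
  fx <- recovery_fixture()
  free <- paste0("Fx.", c("mu_max", "Y_sx", "Y_a", "I_a"))
  prob <- fit_problem(fx$dataset, list(Fx = fx$species), free = free)
  truth <- as_param_vector(fx$species)
  est <- setNames(truth[sub("^Fx\\.", "", free)], free)
  rep <- parameter_correlation(list(estimates = est), prob)
  R <- rep$correlation
  expect_equal(R, t(R))
  expect_true(all(eigen(R, symmetric = TRUE,
                        only.values = TRUE)$values >= -1e-8))
  expect_true(all(abs(R) <= 1 + 1e-12))
})

test_that("under-determined problems raise an explicit error", {
  resid <- function(cand) cand[["a"]] - 1  # 1 residual, 2 parameters
  expect_error(parameter_correlation(list(estimates = c(a = 1, b = 2)),
                                     resid),
               "under-determined")
})

test_that("average sensitivity zeroes disabled and absent parameters", {
  lib <- ref_lib()
  m <- reference_model(c("Bi", "Ec"), X0 = c(Bi = 0.01, Ec = 0))
  S <- average_sensitivity(m, seq(0, 24, 4))
  expect_true(all(S >= 0))
  # Ec has zero inoculum: all its parameter rows are exactly 0
  expect_equal(max(S[grep("^Ec\\.", rownames(S)), ]), 0)
  # Bi does not consume acids: those slots are 0 and contribute nothing
  expect_equal(max(S["Bi.mu_maxA", ]), 0)
  expect_gt(sum(S["Bi.mu_max", ]), 0)
})

test_that("sensitivity normalization floor only matters for tiny states", {
  # early window: substrate stays above 1 g/L, so its normalization never
  # touches the floor and the entries are eps-independent
  m <- reference_model("Bi", X0 = 0.05)
  t_grid <- seq(0, 6, 1)
  s1 <- average_sensitivity(m, t_grid, eps = 1e-6)
  s2 <- average_sensitivity(m, t_grid, eps = 2e-6)
  tr <- simulate_consortium(m, t_grid)
  big <- colnames(tr$states)[apply(tr$states, 2, min) >= 1]
  expect_gt(length(big), 0)
  expect_equal(s1[, big], s2[, big], tolerance = 1e-12)
})

test_that("zero perturbation gives zero-width bands on the baseline", {
  m <- reference_model("La")
  pb <- perturbation_bands(m, "La.mu_max", fraction = 0, iterations = 5,
                           seed = 1, t_grid = seq(0, 24, 4))
  expect_equal(max(pb$sd), 0)
  expect_equal(pb$mean, pb$baseline, tolerance = 1e-12)
})

test_that("perturbation bands are reproducible and converge with iterations", {
  m <- reference_model(c("Bi", "Ec"), X0 = c(Bi = 0.01, Ec = 0.05))
  tg <- seq(0, 24, 4)
  b1 <- perturbation_bands(m, "Bi.mu_max", 0.05, iterations = 150,
                           seed = 4, t_grid = tg)
  b1b <- perturbation_bands(m, "Bi.mu_max", 0.05, iterations = 150,
                            seed = 4, t_grid = tg)
  expect_identical(b1$mean, b1b$mean)
  b2 <- perturbation_bands(m, "Bi.mu_max", 0.05, iterations = 300,
                           seed = 9, t_grid = tg)
  # means agree within Monte-Carlo error of each other
  scale <- pmax(abs(b2$mean), 1e-3)
  expect_lt(max(abs(b1$mean - b2$mean) / scale), 0.05)
})

test_that("perturbation-band mean approaches the baseline as fraction -> 0", {
  m <- reference_model("Ec", X0 = 0.05)
  tg <- seq(0, 24, 4)
  dev <- vapply(c(0.04, 0.02, 0.01), function(f) {
    pb <- perturbation_bands(m, "Ec.mu_max", f, iterations = 100,
                             seed = 7, t_grid = tg)
    max(abs(pb$mean - pb$baseline) / pmax(abs(pb$baseline), 1e-3))
  }, 0)
  expect_true(all(diff(dev) <= 1e-3 + 0))  # non-increasing (to jitter)
  expect_lt(dev[3], 0.02)
})
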