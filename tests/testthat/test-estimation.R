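test_that("fit error is zero at the generating parameters and positive away", {
  fx <- recovery_fixture()
  prob <- fit_problem(fx$dataset, list(Fx = fx$species),
                      free = c("Fx.mu_max", "Fx.Y_sx"))
  truth <- as_param_vector(fx$species)
  at_truth <- fit_error(c(Fx.mu_max = truth[["mu_max"]],
                          Fx.Y_sx = truth[["Y_sx"]]), prob)
  expect_lt(at_truth, 1e-10)
  # 20 random perturbations all strictly increase the error
  set.seed(11)
  for (i in 1:20) {
    cand <- c(Fx.mu_max = truth[["mu_max"]] * runif(1, 0.7, 1.3),
              Fx.Y_sx = min(truth[["Y_sx"]] * runif(1, 0.7, 1.3), 1))
    if (abs(cand[1] - truth[["mu_max"]]) < 1e-3 &&
        abs(cand[2] - truth[["Y_sx"]]) < 1e-3) next
    expect_gt(fit_error(cand, prob), at_truth)
  }
})

test_that("fit error is invariant to rescaling an observable's units", {
  fx <- recovery_fixture()
  cand <- c(Fx.mu_max = 0.3)
  e1 <- fit_error(cand, fit_problem(fx$dataset, list(Fx = fx$species),
                                    free = "Fx.mu_max"))
  # same data expressed at 1000x counts per gram: normalization absorbs it
  ds2 <- fx$dataset
  ds2$records$copies_Fx <- ds2$records$copies_Fx * 1000
  e2 <- fit_error(cand, fit_problem(
    ds2, list(Fx = fx$species), free = "Fx.mu_max",
    cal = qpcr_calibration(cells_per_gram = 1e15)))
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("a failing candidate draws the finite penalty, not an error", {
  fx <- recovery_fixture()
  prob <- fit_problem(fx$dataset, list(Fx = fx$species),
                      free = list(`Fx.Y_a` = c(0, 2), `Fx.Y_l` = c(0, 2)))
  # Y_a + Y_l > 1 violates the species invariant -> penalty
  expect_equal(fit_error(c(Fx.Y_a = 0.9, Fx.Y_l = 0.9), prob), 1e9)
})

test_that("scatter search solves a one-parameter problem to high accuracy", {
  fx <- recovery_fixture()
  prob <- fit_problem(fx$dataset, list(Fx = fx$species), free = "Fx.Y_a")
  fit <- scatter_search(prob, budget = 150, seed = 2)
  expect_equal(unname(fit$estimates), 0.40, tolerance = 1e-3)
  expect_lte(fit$n_evaluations, 150)
})

test_that("scatter search is deterministic and monotone in the budget", {
  fx <- recovery_fixture()
  prob <- fit_problem(fx$dataset, list(Fx = fx$species),
                      free = c("Fx.mu_max", "Fx.I_a", "Fx.Y_a"))
  f1 <- scatter_search(prob, budget = 250, seed = 5)
  f2 <- scatter_search(prob, budget = 250, seed = 5)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$objective, f2$objective)
  f3 <- scatter_search(prob, budget = 500, seed = 5)
  expect_lte(f3$objective, f1$objective)
})

test_that("empty free set is a configuration error", {
  fx <- recovery_fixture()
  prob <- fit_problem(fx$dataset, list(Fx = fx$species),
                      free = character(0))
  expect_error(scatter_search(prob), "no free parameters")
})

test_that("K_s profile is flat: the half-velocity constant is insensitive", {
  lib <- ref_lib()
  des <- scenario_catalog()[["mono-Bi"]]
  model <- consortium_model(list(lib$species$Bi), S0 = 10, X0 = 0.01)
  ds <- generate_dataset(model, des, noise_model(0, 0, 1))
  prob <- fit_problem(ds, lib$species, free = "Bi.K_s")
  ks0 <- as_param_vector(lib$species$Bi)[["K_s"]]
  prof <- vapply(ks0 * 10^seq(-0.5, 0.5, length.out = 9),
                 function(k) fit_error(c(Bi.K_s = k), prob), 0)
  expect_lt(max(prof) - min(prof), 0.01)
})

test_that("staged calibration wires pairs to exactly two ef entries", {
  lib <- ref_lib()
  pairs <- list(c("Bv", "Ec"), c("Bv", "La"), c("Ec", "La"))
  pair_ds <- lapply(pairs, function(pr) {
    des <- scenario_catalog()[[paste0("pair-", paste(pr, collapse = ""))]]
    m <- consortium_model(unname(lib$species[pr]),
                          subset_interactions(lib$interactions, pr),
                          S0 = 10, X0 = des$inoculum)
    generate_dataset(m, des, noise_model(0, 0, 1))
  })
  res <- staged_calibration(pair_datasets = pair_ds,
                            base_params = lib$species,
                            mono_params = lib$species,
                            budget_pair = 60, seed = 1)
  expect_s3_class(res$interactions, "interaction_matrix")
  expect_length(res$pair_fits, 3)
  for (f in res$pair_fits) expect_length(f$estimates, 2)
  # species kinetics are untouched by stage 2
  for (sp in c("Bv", "Ec", "La"))
    expect_equal(as_param_vector(res$species[[sp]]),
                 as_param_vector(lib$species[[sp]]))
})

test_that("missing mono datasets are reported explicitly", {
  lib <- ref_lib()
  des <- scenario_catalog()[["pair-BvEc"]]
  m <- consortium_model(unname(lib$species[c("Bv", "Ec")]),
                        subset_interactions(lib$interactions, c("Bv", "Ec")),
                        S0 = 10, X0 = des$inoculum)
  ds <- generate_dataset(m, des, noise_model(0, 0, 1))
  expect_error(staged_calibration(mono_datasets = list(),
                                  pair_datasets = list(ds),
                                  base_params = lib$species),
               "Bv, Ec")
})

test_that("fit results round-trip through JSON", {
  fx <- recovery_fixture()
  prob <- fit_problem(fx$dataset, list(Fx = fx$species), free = "Fx.Y_a")
  fit <- scatter_search(prob, budget = 60, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, path)
  fit2 <- read_fit(path)
  expect_equal(fit2$estimates, fit$estimates, tolerance = 1e-12)
  expect_equal(fit2$objective, fit$objective, tolerance = 1e-12)
  expect_equal(fit2$seed, fit$seed)
})
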