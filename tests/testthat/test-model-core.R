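test_that("specific growth rate follows Monod with inhibition and lag", {
  p <- species_params("x", mu_max = 0.8, K_s = 0.1, I_a = 2, I_l = 3,
                      t_lag = 4)
  # no substrate, no growth
  expect_equal(specific_growth_rate(p, 0, 1, 1, 10), 0)
  # half-saturation identity
  expect_equal(specific_growth_rate(p, 0.1, 0, 0, 10), 0.4)
  # lag phase: zero growth before t_lag even with plenty of substrate
  expect_equal(specific_growth_rate(p, 10, 0, 0, 3.9), 0)
  # A = I_a and L = I_l with S >> K_s halves twice: mu_max / 4
  mu <- specific_growth_rate(p, 1e6 * 0.1, 2, 3, 10)
  expect_equal(mu, 0.8 / 4, tolerance = 1e-5)
  # monotonicity in S, A, L
  expect_gt(specific_growth_rate(p, 5, 1, 1, 10),
            specific_growth_rate(p, 1, 1, 1, 10))
  expect_lt(specific_growth_rate(p, 5, 3, 1, 10),
            specific_growth_rate(p, 5, 1, 1, 10))
  # neighbour terms multiply in
  mu0 <- specific_growth_rate(p, 5, 0, 0, 10)
  mu1 <- specific_growth_rate(p, 5, 0, 0, 10,
                              neighbors = list(list(ef = 2, X = 1)))
  expect_equal(mu1, mu0 * 0.5)
  expect_error(specific_growth_rate(p, -1, 0, 0, 1), ">= 0")
})

test_that("state dimension is 3 + 2N for mono, pair and four-species", {
  lib <- ref_lib()
  for (members in list("Bi", c("Bv", "Ec"), c("Bi", "Bv", "Ec", "La"))) {
    m <- reference_model(members)
    rhs <- build_rhs(m)
    y0 <- c(10, 0, 0, rep(c(0.01, 0.01), length(members)))
    expect_length(rhs(0, y0), 3 + 2 * length(members))
    expect_length(state_names(m), 3 + 2 * length(members))
  }
})

test_that("a species with zero biomass contributes no dynamics", {
  m <- reference_model(c("Bi", "Ec"), X0 = c(Bi = 0, Ec = 0.01))
  d <- build_rhs(m)(5, c(10, 0.5, 0.5, 0, 0, 0.01, 0.01))
  nms <- state_names(m)
  expect_equal(d[match(c("X_Bi", "Xm_Bi"), nms)], c(0, 0))
  expect_gt(d[match("X_Ec", nms)], 0)
})

test_that("qPCR copy conversion is the Avogadro identity", {
  cal <- qpcr_calibration(genome_size_bp = 2e6, copies_16s = 1)
  expect_equal(qpcr_copies_per_ml(0, cal), 0)
  # direct arithmetic: 6.02214076e23 * 1e-6 / (2e6 * 660)
  expect_equal(qpcr_copies_per_ml(1e-6, cal), 4.562228e8, tolerance = 1e-6)
  cal2 <- qpcr_calibration(genome_size_bp = 2e6, copies_16s = 2)
  expect_equal(qpcr_copies_per_ml(1e-6, cal2),
               2 * qpcr_copies_per_ml(1e-6, cal))
  expect_error(qpcr_calibration(genome_size_bp = 0), "> 0")
})

test_that("percentage abundance sums to 100 and handles edge cases", {
  mk_traj <- function(xm) {
    n <- length(xm[[1]])
    states <- cbind(S = rep(1, n), A = 0, L = 0)
    labels <- names(xm)
    for (l in labels) {
      states <- cbind(states, 0.5, xm[[l]])
      colnames(states)[ncol(states) - 1:0] <- c(paste0("X_", l),
                                                paste0("Xm_", l))
    }
    structure(list(times = seq_len(n) - 1, states = states,
                   labels = labels), class = "trajectory")
  }
  # single species: 100 %
  p1 <- percent_abundance(mk_traj(list(A = c(1, 2))))
  expect_equal(p1$A, c(100, 100))
  # two species, equal biomass: 50/50
  p2 <- percent_abundance(mk_traj(list(A = c(1, 1), B = c(1, 1))))
  expect_equal(unlist(p2[, c("A", "B")]), rep(50, 4), ignore_attr = TRUE)
  # four species 4:3:2:1
  p4 <- percent_abundance(mk_traj(list(a = 4, b = 3, c = 2, d = 1)))
  expect_equal(unname(unlist(p4[1, -1])), c(40, 30, 20, 10))
  expect_equal(rowSums(p4[, -1]), 100, ignore_attr = TRUE,
               tolerance = 1e-12)
  # all-zero row: NA with a warning, not silent 0/0
  expect_warning(pz <- percent_abundance(mk_traj(list(A = c(0, 1),
                                                      B = c(0, 1)))),
                 "all-zero")
  expect_true(all(is.na(pz[1, -1])))
  # unequal per-species calibrations shift the percentages
  cals <- list(A = qpcr_calibration(cells_per_gram = 2e12),
               B = qpcr_calibration(cells_per_gram = 1e12))
  pc <- percent_abundance(mk_traj(list(A = c(1, 1), B = c(1, 1))), cals)
  expect_equal(pc$A, rep(200 / 3, 2))
})
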