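# Independent fixed-step classical RK4 integrator over an R right-hand
# side. Used as the oracle against the package's adaptive compiled
# integrator; deliberately shares no code with it.
rk4_integrate <- function(rhs, y0, times, dt = 1e-3) {
  out <- matrix(NA_real_, length(times), length(y0))
  out[1, ] <- y0
  y <- y0
  t <- times[1]
  for (i in seq_along(times)[-1]) {
    tn <- times[i]
    while (t < tn - 1e-12) {
      h <- min(dt, tn - t)
      k1 <- rhs(t, y)
      k2 <- rhs(t + h / 2, y + h / 2 * k1)
      k3 <- rhs(t + h / 2, y + h / 2 * k2)
      k4 <- rhs(t + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[i, ] <- y
  }
  out
}

# acid producer with no uptake / maintenance / death knobs beyond arguments
make_producer <- function(name = "P1", mu_max = 0.5, Y_sx = 0.3,
                          Y_a = 0.4, Y_l = 0.2, k_d = 0, t_lag = 0,
                          I_a = 1e4, I_l = 1e4) {
  species_params(name, mu_max = mu_max, K_s = 0.05, Y_sx = Y_sx,
                 Y_a = Y_a, Y_l = Y_l, I_a = I_a, I_l = I_l,
                 k_d = k_d, t_lag = t_lag,
                 produces_acetate = Y_a > 0, produces_lactate = Y_l > 0)
}

ref_lib <- function() {
  read_param_library(system.file("extdata", "reference_params.json",
                                 package = "crossfeed", mustWork = TRUE))
}

# the dense, informative mono-culture fixture used for parameter-recovery
# tests: one organism producing both acids and consuming lactate once the
# sugar is gone, sampled every 2 h
recovery_fixture <- function() {
  fx <- species_params("Fx", mu_max = 0.35, K_s = 0.05, Y_sx = 0.3,
                       Y_a = 0.40, Y_l = 0.30, I_a = 2, I_l = 1.5,
                       k_d = 0.05, t_lag = 3,
                       mu_maxL = 0.10, K_sL = 0.5, Y_sxL = 0.25,
                       produces_acetate = TRUE, produces_lactate = TRUE,
                       consumes_lactate = TRUE)
  design <- culture_design("bioreactor", "Fx", times = seq(0, 60, 2),
                           replicates = 1, inoculum = 0.01)
  model <- consortium_model(list(fx), S0 = 10, X0 = 0.01)
  list(species = fx, design = design, model = model,
       dataset = generate_dataset(model, design, noise_model(0, 0, 1)))
}
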