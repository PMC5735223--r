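#' Batch consortium model
#'
#' Bundles species kinetics, the pairwise interaction matrix and the initial
#' condition of a batch culture into one object whose ODE right-hand side
#' can be built with [build_rhs()] and integrated with
#' [simulate_consortium()].
#'
#' The state vector has dimension `3 + 2N` in fixed order
#' `S, A, L, X_1, Xm_1, ..., X_N, Xm_N` (all g/L): primary substrate,
#' acetate, lactate, then per species the live biomass `X_i` and the
#' measured (cumulative, qPCR-visible) biomass `Xm_i`. DNA persists after
#' cell death, so `Xm` integrates gross growth and never decreases while
#' `X` additionally decays at `k_d`.
#'
#' @param species List of [species_params()] objects.
#' @param interactions An [interaction_matrix()] covering all species, or
#'   `NULL` for a mono-culture (required `NULL` iff N = 1 is not enforced;
#'   `NULL` with N > 1 means no interaction terms).
#' @param S0,A0,L0 Initial substrate / acetate / lactate (g/L).
#' @param X0 Named (by species) or positional vector of initial live biomass
#'   (g/L).
#' @param X0m Initial measured biomass; defaults to `X0`.
#' @return An object of class `consortium_model`.
#' @examples
#' m <- consortium_model(list(species_params("Bi", Y_a = 0.45, Y_l = 0.30,
#'                                           produces_acetate = TRUE,
#'                                           produces_lactate = TRUE)),
#'                       S0 = 10, X0 = 0.01)
#' @export
consortium_model <- function(species, interactions = NULL,
                             S0 = 10, A0 = 0, L0 = 0,
                             X0 = 0.01, X0m = X0) {
  stopifnot(is.list(species), length(species) >= 1,
            all(vapply(species, inherits, TRUE, "species_params")))
  labels <- vapply(species, `[[`, "", "name")
  if (anyDuplicated(labels)) stop("duplicate species labels")
  n <- length(species)

  if (!is.null(interactions)) {
    stopifnot(inherits(interactions, "interaction_matrix"))
    if (!setequal(interactions$species, labels))
      stop("interaction matrix species do not match model species")
    if (!identical(interactions$species, labels))
      interactions <- subset_interactions(interactions, labels)
  }

  expand <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, n)
    if (!is.null(names(x))) {
      if (!all(labels %in% names(x)))
        stop(what, " must name every species")
      x <- x[labels]
    }
    if (length(x) != n) stop(what, " has wrong length")
    if (any(x < 0) || any(!is.finite(x))) stop(what, " must be finite and >= 0")
    unname(x)
  }
  X0 <- expand(X0, "X0")
  X0m <- expand(X0m, "X0m")
  if (any(c(S0, A0, L0) < 0)) stop("initial concentrations must be >= 0")

  structure(list(species = species, labels = labels,
                 interactions = interactions,
                 S0 = S0, A0 = A0, L0 = L0, X0 = X0, X0m = X0m),
            class = "consortium_model")
}

#' @export
print.consortium_model <- function(x, ...) {
  cat("<consortium_model>", length(x$species), "species:",
      paste(x$labels, collapse = ", "), "\n")
  cat("S0 =", x$S0, "g/L; X0 =", paste(signif(x$X0, 3), collapse = ", "),
      "g/L;", if (is.null(x$interactions)) "no interactions"
      else "with interactions", "\n")
  invisible(x)
}

#' State variable names of a model
#'
#' @param model A [consortium_model()].
#' @return Character vector `S, A, L, X_<sp>, Xm_<sp>, ...`.
#' @export
state_names <- function(model) {
  c("S", "A", "L",
    as.vector(rbind(paste0("X_", model$labels), paste0("Xm_", model$labels))))
}

initial_state <- function(model) {
  y0 <- c(model$S0, model$A0, model$L0,
          as.vector(rbind(model$X0, model$X0m)))
  names(y0) <- state_names(model)
  y0
}

#' Specific growth rate on the primary substrate
#'
#' Monod kinetics with multiplicative non-competitive inhibition by the two
#' acids and pairwise interaction factors:
#' \deqn{\mu = \mu_{max} \frac{S}{K_s + S} \frac{I_a}{I_a + A}
#'       \frac{I_l}{I_l + L} \prod_j \mathrm{clamp}(1 - X_j / ef_{ji})}
#' for `t >= t_lag`, and 0 during the lag phase.
#'
#' @param p A [species_params()] object.
#' @param S,A,L Substrate, acetate, lactate concentrations (g/L).
#' @param t Time (h); growth is 0 before `p$params["t_lag"]`.
#' @param neighbors Optional list of `list(ef = , X = )` pairs giving each
#'   neighbour's interaction parameter on this species and its biomass.
#' @return Specific growth rate (1/h), always >= 0.
#' @examples
#' p <- species_params("Bi", mu_max = 0.6, K_s = 0.05)
#' specific_growth_rate(p, S = 0.05, A = 0, L = 0, t = 10)  # mu_max / 2
#' @export
specific_growth_rate <- function(p, S, A, L, t, neighbors = list()) {
  stopifnot(inherits(p, "species_params"))
  if (any(c(S, A, L) < 0)) stop("concentrations must be >= 0")
  if (t < 0) stop("time must be >= 0")
  v <- p$params
  if (t < v[["t_lag"]]) return(0)
  mu <- v[["mu_max"]] * S / (v[["K_s"]] + S) *
    v[["I_a"]] / (v[["I_a"]] + A) *
    v[["I_l"]] / (v[["I_l"]] + L)
  for (nb in neighbors)
    mu <- mu * interaction_multiplier(nb$ef, nb$X)
  mu
}

#' Build the ODE right-hand side of a consortium model
#'
#' Returns a plain R closure `function(t, state)` computing the
#' time-derivative of the full state. This is the reference implementation
#' of the balance equations; [simulate_consortium()] integrates an
#' equivalent compiled version for speed, and the test suite checks the two
#' against each other.
#'
#' Balances (per species `i`):
#' \itemize{
#'   \item `dX_i/dt = (mu_i + muA_i + muL_i - k_d) X_i`
#'   \item `dXm_i/dt = (mu_i + muA_i + muL_i) X_i`
#'   \item `dS/dt = -sum_i (mu_i / Y_sx_i + m_s_i) X_i`
#'   \item `dA/dt = sum_i Y_a_i (mu_i / Y_sx_i) X_i - sum_i (muA_i / Y_sxA_i) X_i`
#'   \item `dL/dt` analogous with `Y_l` and lactate uptake
#' }
#' Secondary (acid) growth rates `muA`, `muL` are Monod in the acid and
#' carry the repression factor `K_rep / (K_rep + S)`: acids are consumed
#' only once the primary carbohydrate is nearly gone.
#'
#' @param model A [consortium_model()].
#' @return Function `(t, state) -> derivative`, both of length `3 + 2N`.
#' @export
build_rhs <- function(model) {
  stopifnot(inherits(model, "consortium_model"))
  sp <- model$species
  n <- length(sp)
  efm <- if (!is.null(model$interactions)) model$interactions$ef else NULL

  function(t, state) {
    S <- max(state[1], 0); A <- max(state[2], 0); L <- max(state[3], 0)
    X <- pmax(state[2 * seq_len(n) + 2], 0)
    dS <- dA <- dL <- 0
    d <- numeric(3 + 2 * n)
    for (i in seq_len(n)) {
      v <- sp[[i]]$params
      caps <- sp[[i]]$capabilities
      mu <- muA <- muL <- 0
      if (t >= v[["t_lag"]]) {
        mu <- v[["mu_max"]] * S / (v[["K_s"]] + S) *
          v[["I_a"]] / (v[["I_a"]] + A) * v[["I_l"]] / (v[["I_l"]] + L)
        if (!is.null(efm) && n > 1)
          for (j in seq_len(n)[-i])
            mu <- mu * interaction_multiplier(efm[i, j], X[j])
        rep_f <- v[["K_rep"]] / (v[["K_rep"]] + S)
        if (caps[["consumes_acetate"]] && v[["mu_maxA"]] > 0)
          muA <- v[["mu_maxA"]] * A / (v[["K_sA"]] + A) * rep_f
        if (caps[["consumes_lactate"]] && v[["mu_maxL"]] > 0)
          muL <- v[["mu_maxL"]] * L / (v[["K_sL"]] + L) * rep_f
      }
      mu_tot <- mu + muA + muL
      d[2 * i + 2] <- (mu_tot - v[["k_d"]]) * X[i]
      d[2 * i + 3] <- mu_tot * X[i]
      dS <- dS - (mu / v[["Y_sx"]] + v[["m_s"]]) * X[i]
      if (caps[["produces_acetate"]]) dA <- dA + v[["Y_a"]] * mu / v[["Y_sx"]] * X[i]
      if (caps[["produces_lactate"]]) dL <- dL + v[["Y_l"]] * mu / v[["Y_sx"]] * X[i]
      if (caps[["consumes_acetate"]] && v[["Y_sxA"]] > 0)
        dA <- dA - muA / v[["Y_sxA"]] * X[i]
      if (caps[["consumes_lactate"]] && v[["Y_sxL"]] > 0)
        dL <- dL - muL / v[["Y_sxL"]] * X[i]
    }
    if (S <= 0 && dS < 0) dS <- 0
    if (A <= 0 && dA < 0) dA <- 0
    if (L <= 0 && dL < 0) dL <- 0
    d[1] <- dS; d[2] <- dA; d[3] <- dL
    d
  }
}
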