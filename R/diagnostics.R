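#' Practical identifiability via the parameter correlation matrix
#'
#' Approximates the parameter covariance at a fit by the linearized
#' (Gauss-Newton) estimate: a central finite-difference Jacobian `J` of the
#' normalized residual vector, covariance proportional to the pseudo-inverse
#' of `J'J` (residual mean square as the variance scale), and the
#' correlation `r_ij = C_ij / sqrt(C_ii C_jj)`. Near-singular `J'J` is
#' handled by the pseudo-inverse and reported, not fatal: parameter pairs
#' with `|r|` above the threshold are flagged as practically
#' non-identifiable.
#'
#' @param fit A `fit_result` from [scatter_search()], or any list with a
#'   named `estimates` vector.
#' @param problem The [fit_problem()] the fit was produced from, or a
#'   function mapping a named candidate vector to a residual vector.
#' @param threshold Flagging threshold on `|r|` (default 0.95).
#' @param step Relative finite-difference step (default 0.01, absolute floor
#'   1e-8).
#' @return A `correlation_report`: `parameters`, `correlation` matrix,
#'   `flagged` data.frame (pairs with `|r| > threshold`), `rank_deficient`.
#' @export
parameter_correlation <- function(fit, problem, threshold = 0.95,
                                  step = 0.01) {
  stopifnot(threshold > 0, threshold < 1)
  resid_fun <- if (is.function(problem)) problem
  else {
    stopifnot(inherits(problem, "fit_problem"))
    function(cand) problem_residuals(problem, cand)
  }
  est <- fit$estimates
  k <- length(est)
  r0 <- resid_fun(est)
  if (length(r0) < k)
    stop("under-determined: ", length(r0), " residuals for ", k,
         " free parameters")

  J <- matrix(0, length(r0), k, dimnames = list(NULL, names(est)))
  for (j in seq_len(k)) {
    h <- max(abs(est[[j]]) * step, 1e-8)
    up <- est; up[[j]] <- est[[j]] + h
    dn <- est; dn[[j]] <- est[[j]] - h
    J[, j] <- (resid_fun(up) - resid_fun(dn)) / (2 * h)
  }

  jtj <- crossprod(J)
  sv <- svd(jtj)
  tol <- max(sv$d) * 1e-12
  pos <- sv$d > tol
  rank_deficient <- sum(pos) < k
  dinv <- ifelse(pos, 1 / sv$d, 0)  # pseudo-inverse over the null space
  # (the residual-mean-square scale of the covariance cancels in r_ij, so
  # the correlation is well defined even at a perfect zero-residual fit)
  C <- sv$v %*% (dinv * t(sv$u))

  dC <- diag(C)
  denom <- sqrt(pmax(dC, 0) %o% pmax(dC, 0))
  R <- ifelse(denom > 0, C / denom, 0)
  R[!is.finite(R)] <- 0
  R <- (R + t(R)) / 2
  R <- pmin(pmax(R, -1), 1)
  diag(R) <- 1
  dimnames(R) <- list(names(est), names(est))

  idx <- which(abs(R) > threshold & upper.tri(R), arr.ind = TRUE)
  flagged <- data.frame(param1 = rownames(R)[idx[, 1]],
                        param2 = colnames(R)[idx[, 2]],
                        r = R[idx])
  structure(list(parameters = names(est), correlation = R,
                 flagged = flagged, threshold = threshold,
                 rank_deficient = rank_deficient),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report>", length(x$parameters), "parameters;",
      nrow(x$flagged), "pair(s) with |r| >", x$threshold,
      if (x$rank_deficient) "(rank deficient)" else "", "\n")
  if (nrow(x$flagged)) print(x$flagged)
  invisible(x)
}

# enumerate perturbable parameters of a model as "<sp>.<slot>"
model_param_names <- function(model) {
  as.vector(vapply(model$labels,
                   function(l) paste0(l, ".", param_slots()),
                   character(17)))
}

# simulate a model with one named parameter replaced
simulate_perturbed <- function(model, name, value, t_grid) {
  if (startsWith(name, "ef.")) {
    parts <- strsplit(name, ".", fixed = TRUE)[[1]]
    model$interactions$ef[parts[2], parts[3]] <- value
  } else {
    sp <- sub("\\..*$", "", name)
    slot <- sub("^[^.]+\\.", "", name)
    i <- match(sp, model$labels)
    if (is.na(i)) stop("unknown species in parameter '", name, "'")
    model$species[[i]] <- do.call(update_params,
                                  c(list(model$species[[i]]),
                                    setNames(list(value), slot)))
  }
  simulate_consortium(model, t_grid)
}

get_param_value <- function(model, name) {
  if (startsWith(name, "ef.")) {
    parts <- strsplit(name, ".", fixed = TRUE)[[1]]
    return(model$interactions$ef[parts[2], parts[3]])
  }
  sp <- sub("\\..*$", "", name)
  slot <- sub("^[^.]+\\.", "", name)
  i <- match(sp, model$labels)
  if (is.na(i)) stop("unknown species in parameter '", name, "'")
  as_param_vector(model$species[[i]])[[slot]]
}

#' Average local sensitivity of every state equation to every parameter
#'
#' For each kinetic parameter `p` and state variable `x_k`, computes the
#' time-averaged normalized local sensitivity
#' `s_pk = mean_t | (dx_k/dp) * p / max(x_k, eps) |`
#' by central differences with a relative step. Parameters that are exactly
#' zero (e.g. a disabled capability's slots) get a zero row, as do
#' parameters of a species with zero inoculum.
#'
#' @param model A [consortium_model()].
#' @param t_grid Output grid for the underlying simulations.
#' @param step Relative finite-difference step (default 0.01).
#' @param eps Floor for the state normalization (default 1e-6).
#' @return Matrix (parameters x state variables) of nonnegative average
#'   sensitivities, rows named `"<sp>.<slot>"`.
#' @export
average_sensitivity <- function(model, t_grid = seq(0, 48, by = 1),
                                step = 0.01, eps = 1e-6) {
  stopifnot(inherits(model, "consortium_model"))
  base <- simulate_consortium(model, t_grid)
  norm <- pmax(abs(base$states), eps)
  pars <- model_param_names(model)
  out <- matrix(0, length(pars), ncol(base$states),
                dimnames = list(pars, colnames(base$states)))
  for (nm in pars) {
    p0 <- get_param_value(model, nm)
    if (p0 == 0) next
    sp <- sub("\\..*$", "", nm)
    if (model$X0[match(sp, model$labels)] == 0 &&
        model$X0m[match(sp, model$labels)] == 0) next
    h <- abs(p0) * step
    up <- tryCatch(simulate_perturbed(model, nm, p0 + h, t_grid),
                   error = function(e) NULL)
    dn <- tryCatch(simulate_perturbed(model, nm, p0 - h, t_grid),
                   error = function(e) NULL)
    if (is.null(up) || is.null(dn))
      stop("simulation failed while perturbing ", nm)
    sens <- abs((up$states - dn$states) / (2 * h) * p0 / norm)
    out[nm, ] <- colMeans(sens)
  }
  out
}

#' Monte-Carlo perturbation bands for one parameter
#'
#' Repeatedly multiplies a single parameter by `1 + delta` with
#' `delta ~ Uniform(-fraction, fraction)`, resimulates, and aggregates the
#' per-time mean and standard deviation of every state variable. Iterations
#' whose simulation fails are dropped and counted.
#'
#' @param model A [consortium_model()].
#' @param parameter Parameter name (`"<sp>.<slot>"` or `"ef.<i>.<j>"`).
#' @param fraction Maximum relative perturbation, in `[0, 0.5]`.
#' @param iterations Number of Monte-Carlo draws (default 5000).
#' @param seed RNG seed.
#' @param t_grid Output grid.
#' @return A `sensitivity_bands` object: `times`, `mean` and `sd` matrices
#'   (time x state), `baseline` states, `settings`, `n_dropped`.
#' @export
perturbation_bands <- function(model, parameter, fraction = 0.05,
                               iterations = 5000, seed = 1,
                               t_grid = seq(0, 48, by = 1)) {
  stopifnot(inherits(model, "consortium_model"),
            fraction >= 0, fraction <= 0.5, iterations >= 1)
  base <- simulate_consortium(model, t_grid)
  p0 <- get_param_value(model, parameter)

  sum1 <- sum2 <- matrix(0, nrow(base$states), ncol(base$states))
  dropped <- 0L
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      delta <- runif(1, -fraction, fraction)
      tr <- tryCatch(
        simulate_perturbed(model, parameter, p0 * (1 + delta), t_grid),
        error = function(e) NULL)
      if (is.null(tr) || any(!is.finite(tr$states))) {
        dropped <- dropped + 1L
        next
      }
      sum1 <- sum1 + tr$states
      sum2 <- sum2 + tr$states^2
    }
  })
  n <- iterations - dropped
  if (n == 0) stop("every Monte-Carlo iteration failed")
  mean_ <- sum1 / n
  var_ <- pmax(sum2 / n - mean_^2, 0)
  dimnames(mean_) <- dimnames(var_) <- dimnames(base$states)
  structure(list(times = base$times, mean = mean_, sd = sqrt(var_),
                 baseline = base$states,
                 settings = list(parameter = parameter, fraction = fraction,
                                 iterations = iterations, seed = seed),
                 n_dropped = dropped),
            class = "sensitivity_bands")
}

#' @export
print.sensitivity_bands <- function(x, ...) {
  s <- x$settings
  cat("<sensitivity_bands>", s$parameter, "+/-", s$fraction * 100,
      "% over", s$iterations, "iterations", paste0("(", x$n_dropped,
      " dropped)\n"))
  invisible(x)
}
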