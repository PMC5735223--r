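#' Simulate a consortium model
#'
#' Integrates the batch ODE system with an adaptive Dormand-Prince 5(4)
#' scheme (compiled). Integration is restarted at each species' lag time so
#' the growth switch never falls inside a step, and nonnegative states are
#' clipped against integrator undershoot.
#'
#' @param model A [consortium_model()].
#' @param times Strictly increasing output grid in hours, starting at 0.
#' @param rtol,atol Relative / absolute integration tolerances.
#' @param max_steps Step budget before the integrator gives up.
#' @return A `trajectory`: list with `times` and a `states` matrix (one row
#'   per time, columns as in [state_names()]).
#' @examples
#' m <- consortium_model(list(species_params("Ec", mu_max = 0.5, Y_a = 0.21,
#'                                           produces_acetate = TRUE)),
#'                       S0 = 10, X0 = 0.01)
#' tr <- simulate_consortium(m, seq(0, 48, by = 2))
#' @export
simulate_consortium <- function(model, times, rtol = 1e-8, atol = 1e-10,
                                max_steps = 1e6) {
  stopifnot(inherits(model, "consortium_model"),
            is.numeric(times), length(times) >= 2,
            all(diff(times) > 0))
  if (times[1] != 0) stop("output grid must start at 0")

  n <- length(model$species)
  P <- vapply(model$species, as_param_vector, numeric(17))
  caps <- vapply(model$species,
                 function(s) as.integer(s$capabilities), integer(4))
  ef <- if (!is.null(model$interactions)) model$interactions$ef else NULL

  res <- cpp_simulate(P, caps, ef, unname(initial_state(model)),
                      as.numeric(times), rtol, atol, max_steps)
  if (res$status != 0) {
    stop(structure(class = c("crossfeed_integration_error", "error",
                             "condition"),
                   list(message = sprintf(
                     "integration failed (status %d) at t = %.4f h",
                     res$status, res$last_time),
                     call = sys.call(-1), last_time = res$last_time)))
  }
  states <- res$states
  states[states < 0 & states > -atol * 100] <- 0
  colnames(states) <- state_names(model)
  structure(list(times = as.numeric(times), states = states,
                 labels = model$labels),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", length(x$times), "time points, states:",
      paste(colnames(x$states), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time_h = x$times, x$states, check.names = FALSE)
}

#' Write / read a trajectory as CSV
#'
#' Column layout: `time_h, S, A, L, X_<name>, Xm_<name>, ...`. Lines
#' starting with `#` carry provenance and are skipped on read.
#'
#' @param traj A `trajectory`.
#' @param path File path.
#' @param header Optional named character vector written as `# key: value`.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `trajectory`.
#' @export
write_trajectory <- function(traj, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(header))
    writeLines(sprintf("# %s: %s", k, header[[k]]), con)
  write.csv(as.data.frame(traj), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  states <- as.matrix(df[, -1, drop = FALSE])
  labels <- sub("^X_", "", grep("^X_", colnames(states), value = TRUE))
  structure(list(times = df$time_h, states = states, labels = labels),
            class = "trajectory")
}
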