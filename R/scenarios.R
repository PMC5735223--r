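#' Run a consortium scenario
#'
#' Simulates a culture design with the given species kinetics and
#' interaction matrix and summarizes it the way the wet-lab readouts are
#' reported: percentage abundance per species over the design's sampling
#' grid, plus substrate/acetate/lactate curves on a dense grid.
#'
#' @param species Named list of [species_params()] covering the design.
#' @param interactions An [interaction_matrix()] (required for more than
#'   one member; entries for every member pair must be present).
#' @param design A [culture_design()].
#' @param cal qPCR calibration(s), for the percentage table.
#' @param dt Dense output step in hours (default 0.25).
#' @return A `consortium_run`: `trajectory` (dense), `percent` (at design
#'   times), `curves` (data.frame `time_h, S, A, L`), `design`.
#' @export
run_consortium <- function(species, interactions, design,
                           cal = qpcr_calibration(), dt = 0.25) {
  stopifnot(inherits(design, "culture_design"))
  if (!all(design$members %in% names(species)))
    stop("species list lacks: ",
         paste(setdiff(design$members, names(species)), collapse = ", "))
  if (length(design$members) > 1) {
    if (is.null(interactions)) stop("interaction matrix required")
    missing <- setdiff(design$members, interactions$species)
    if (length(missing))
      stop("interaction matrix lacks entries for: ",
           paste(missing, collapse = ", "))
  }
  im <- if (length(design$members) > 1)
    subset_interactions(interactions, design$members) else NULL
  model <- consortium_model(unname(species[design$members]), im,
                            S0 = design$S0, X0 = design$inoculum)
  t_end <- max(design$times)
  dense <- sort(unique(c(seq(0, t_end, by = dt), design$times)))
  traj <- simulate_consortium(model, dense)

  at_design <- match(design$times, traj$times)
  sub <- structure(list(times = traj$times[at_design],
                        states = traj$states[at_design, , drop = FALSE],
                        labels = traj$labels), class = "trajectory")
  pct <- percent_abundance(sub, cal)
  curves <- data.frame(time_h = traj$times,
                       traj$states[, c("S", "A", "L")])
  structure(list(trajectory = traj, percent = pct, curves = curves,
                 design = design, model = model),
            class = "consortium_run")
}

#' @export
print.consortium_run <- function(x, ...) {
  cat("<consortium_run>", x$design$name, "\n")
  print(utils::tail(x$percent, 1))
  invisible(x)
}

#' Bacteriostatic knockout specification
#'
#' @param target Species label whose growth is suppressed.
#' @param mode Only `"bacteriostatic"` is implemented: every growth channel
#'   (`mu_max`, `mu_maxA`, `mu_maxL`) is set to 0 while the decay rate `k_d`
#'   and the inoculum are retained — the organism stays in the vessel and is
#'   measured, but cannot grow.
#' @return A `knockout_spec`.
#' @export
knockout_spec <- function(target, mode = "bacteriostatic") {
  mode <- match.arg(mode)
  structure(list(target = target, mode = mode), class = "knockout_spec")
}

#' Simulate a bacteriostatic knockout
#'
#' @param model A [consortium_model()].
#' @param spec A [knockout_spec()] (or a species label).
#' @param times Output grid (default hourly to 48 h).
#' @param cal qPCR calibration(s) for the dominance ranking.
#' @return A `knockout_run`: `trajectory`, `percent`, `ranking` (species
#'   ordered by final percentage abundance, most dominant first), `spec`.
#' @export
knockout <- function(model, spec, times = seq(0, 48, by = 1),
                     cal = qpcr_calibration()) {
  stopifnot(inherits(model, "consortium_model"))
  if (is.character(spec)) spec <- knockout_spec(spec)
  if (!spec$target %in% model$labels)
    stop("unknown knockout target '", spec$target, "'")
  i <- match(spec$target, model$labels)
  p <- model$species[[i]]
  v <- as_param_vector(p)
  v[c("mu_max", "mu_maxA", "mu_maxL")] <- 0  # k_d retained
  model$species[[i]] <- species_from_vector(
    p$name, v, list(produces_acetate = unname(p$capabilities[["produces_acetate"]]),
                    produces_lactate = unname(p$capabilities[["produces_lactate"]]),
                    consumes_acetate = FALSE, consumes_lactate = FALSE))

  traj <- simulate_consortium(model, times)
  pct <- percent_abundance(traj, cal)
  final <- unlist(pct[nrow(pct), model$labels])
  ranking <- names(sort(final, decreasing = TRUE))
  structure(list(trajectory = traj, percent = pct, ranking = ranking,
                 spec = spec), class = "knockout_run")
}

#' @export
print.knockout_run <- function(x, ...) {
  cat("<knockout_run> target:", x$spec$target,
      "| dominance:", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}

#' Linear time alignment between two sampling grids
#'
#' Fits `target = scale * reference + offset` by least squares over paired
#' anchor times, used to compare a fast run (e.g. a stirred bioreactor)
#' with a slower reference experiment on a common axis.
#'
#' @param reference Anchor times on the reference axis (length >= 2).
#' @param target Matching times on the target axis.
#' @return List `scale`, `offset`, and `map` (a function applying the
#'   transform).
#' @examples
#' align_time(c(0, 12), c(0, 48))  # scale 4, offset 0
#' @export
align_time <- function(reference, target) {
  stopifnot(length(reference) == length(target))
  if (length(reference) < 2 || length(unique(reference)) < 2)
    stop("need at least two distinct anchor times")
  fit <- lm(target ~ reference)
  scale <- unname(coef(fit)[2])
  offset <- unname(coef(fit)[1])
  list(scale = scale, offset = offset,
       map = function(t) scale * t + offset)
}
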