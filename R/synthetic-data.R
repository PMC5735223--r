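#' Batch culture design
#'
#' Describes one batch experiment: vessel, community members, initial
#' substrate, sampling grid, replication and per-species inoculum. The
#' packaged catalog ([scenario_catalog()]) enumerates the designs the
#' synthetic-data generator emulates.
#'
#' @param vessel `"microplate"` or `"bioreactor"`.
#' @param members Character vector of species labels (non-empty).
#' @param S0 Initial substrate, g/L (default 10).
#' @param times Strictly increasing sampling times in hours starting at 0
#'   (microplate default: every 12 h to 72 h; bioreactor default: every 2 h
#'   to 24 h).
#' @param replicates Number of replicate cultures (default 2).
#' @param inoculum Scalar or named per-species initial biomass (g/L).
#' @param name Optional design label.
#' @return An object of class `culture_design`.
#' @export
culture_design <- function(vessel = c("microplate", "bioreactor"),
                           members, S0 = 10,
                           times = NULL, replicates = 2,
                           inoculum = 0.01, name = NULL) {
  vessel <- match.arg(vessel)
  stopifnot(length(members) >= 1, !anyDuplicated(members),
            replicates >= 1, S0 >= 0)
  if (is.null(times))
    times <- if (vessel == "microplate") seq(0, 72, by = 12)
             else seq(0, 24, by = 2)
  stopifnot(all(diff(times) > 0), times[1] == 0)
  if (length(inoculum) == 1L && is.null(names(inoculum)))
    inoculum <- setNames(rep(inoculum, length(members)), members)
  stopifnot(all(members %in% names(inoculum)))
  inoculum <- inoculum[members]
  structure(list(vessel = vessel, members = members, S0 = S0,
                 times = as.numeric(times),
                 replicates = as.integer(replicates),
                 inoculum = inoculum,
                 name = name %||% paste(members, collapse = "")),
            class = "culture_design")
}

#' @export
print.culture_design <- function(x, ...) {
  cat("<culture_design>", x$name, sprintf("[%s]", x$vessel),
      "members:", paste(x$members, collapse = ", "),
      sprintf("| S0 = %g g/L | %d..%d h x%d reps\n",
              x$S0, min(x$times), max(x$times), x$replicates))
  invisible(x)
}

#' Observational noise model
#'
#' Multiplicative lognormal noise on qPCR counts (mean-corrected so the
#' expectation equals the noiseless value) and additive Gaussian noise,
#' truncated at zero, on the three concentrations. Noise is strictly
#' observational: it never feeds back into the dynamics. Truncation biases
#' concentration readings upward only when the true value is within a
#' couple of SDs of zero.
#'
#' @param qpcr_cv Coefficient of variation of the lognormal count noise
#'   (default 0.20).
#' @param conc_sd Additive SD for S, A, L in g/L (default 0.15).
#' @param seed RNG seed making a generated dataset reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(qpcr_cv = 0.20, conc_sd = 0.15, seed = 1L) {
  stopifnot(qpcr_cv >= 0, conc_sd >= 0)
  structure(list(qpcr_cv = qpcr_cv, conc_sd = conc_sd,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Generate a synthetic observed dataset
#'
#' Simulates the model at the design's sampling times and overlays the
#' observational noise model, producing the tidy replicated measurement
#' table that the estimation module consumes. With zero noise the dataset
#' is exactly the sampled simulation; the same seed always yields the same
#' dataset.
#'
#' @param model A [consortium_model()] whose species cover the design
#'   members (extra species are dropped; inocula come from the design).
#' @param design A [culture_design()].
#' @param noise A [noise_model()].
#' @param cal A [qpcr_calibration()] (shared) or named per-species list,
#'   used to express biomass as copies/mL.
#' @return An `observed_dataset`: list of `design`, `records` (data.frame
#'   `time_h, replicate, copies_<sp>..., S, A, L`) and `provenance`.
#' @export
generate_dataset <- function(model, design, noise = noise_model(),
                             cal = qpcr_calibration()) {
  stopifnot(inherits(model, "consortium_model"),
            inherits(design, "culture_design"),
            inherits(noise, "noise_model"))
  if (!all(design$members %in% model$labels))
    stop("model lacks design members: ",
         paste(setdiff(design$members, model$labels), collapse = ", "))

  m <- restrict_model(model, design)
  traj <- simulate_consortium(m, design$times)
  xm <- traj$states[, paste0("Xm_", design$members), drop = FALSE]
  cpg <- cal_vector(cal, design$members)
  copies_true <- sweep(xm, 2, cpg, `*`)
  conc_true <- traj$states[, c("S", "A", "L"), drop = FALSE]

  nt <- length(design$times)
  sigma2 <- log(1 + noise$qpcr_cv^2)

  recs <- with_seed(noise$seed, {
    do.call(rbind, lapply(seq_len(design$replicates), function(r) {
      lognoise <- if (noise$qpcr_cv > 0)
        matrix(exp(rnorm(nt * ncol(copies_true), -sigma2 / 2, sqrt(sigma2))),
               nt) else matrix(1, nt, ncol(copies_true))
      cnoise <- if (noise$conc_sd > 0)
        matrix(rnorm(nt * 3, 0, noise$conc_sd), nt) else matrix(0, nt, 3)
      df <- data.frame(time_h = design$times, replicate = r,
                       copies_true * lognoise,
                       pmax(conc_true + cnoise, 0), check.names = FALSE)
      colnames(df) <- c("time_h", "replicate",
                        paste0("copies_", design$members), "S", "A", "L")
      df
    }))
  })
  rownames(recs) <- NULL

  structure(list(design = design, records = recs,
                 provenance = list(
                   noise = unclass(noise),
                   cells_per_gram = as.list(setNames(cpg, design$members)),
                   generator = "crossfeed::generate_dataset")),
            class = "observed_dataset")
}

#' @export
print.observed_dataset <- function(x, ...) {
  cat("<observed_dataset>", x$design$name, "-", nrow(x$records), "records,",
      length(x$design$members), "species\n")
  invisible(x)
}

# reduce a model to the design's members and inocula
restrict_model <- function(model, design) {
  idx <- match(design$members, model$labels)
  interactions <- if (length(idx) > 1 && !is.null(model$interactions))
    subset_interactions(model$interactions, design$members) else NULL
  consortium_model(model$species[idx], interactions,
                   S0 = design$S0, A0 = model$A0, L0 = model$L0,
                   X0 = design$inoculum)
}

cal_vector <- function(cal, members) {
  if (inherits(cal, "qpcr_calibration"))
    return(setNames(rep(cal$cells_per_gram, length(members)), members))
  stopifnot(all(members %in% names(cal)))
  vapply(cal[members], `[[`, 0, "cells_per_gram")
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Catalog of packaged culture designs
#'
#' Enumerates the twelve batch designs the generator emulates: the four
#' mono-cultures, the six paired co-cultures (BiBv, BiEc, BiLa, BvEc, BvLa,
#' EcLa) and the four-species consortium in microplate and bioreactor.
#' Microplate designs sample every 12 h to 72 h in duplicate; the
#' bioreactor samples every 2 h to 24 h. Default inoculum is 0.01 g/L with
#' two documented asymmetries in microplates: the `Ec` inoculum is 5x
#' higher and the `Bv` inoculum 5x lower, mirroring the reported initial
#' cell-count imbalances. The bioreactor is inoculated evenly at 0.02 g/L
#' (equal optical density).
#'
#' @return Named list of [culture_design()] objects (length 12).
#' @examples
#' names(scenario_catalog())
#' @export
scenario_catalog <- function() {
  species <- c("Bi", "Bv", "Ec", "La")
  base <- c(Bi = 0.01, Bv = 0.002, Ec = 0.05, La = 0.01)
  designs <- list()
  for (sp in species)
    designs[[paste0("mono-", sp)]] <-
      culture_design("microplate", sp, inoculum = 0.01,
                     name = paste0("mono-", sp))
  for (pr in combn(species, 2, simplify = FALSE)) {
    nm <- paste0("pair-", paste(pr, collapse = ""))
    designs[[nm]] <- culture_design("microplate", pr,
                                    inoculum = base[pr], name = nm)
  }
  designs[["all-microplate"]] <-
    culture_design("microplate", species, inoculum = base,
                   name = "all-microplate")
  designs[["all-bioreactor"]] <-
    culture_design("bioreactor", species, replicates = 4,
                   inoculum = setNames(rep(0.02, 4), species),
                   name = "all-bioreactor")
  designs
}
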