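#' qPCR calibration constants
#'
#' Bundles the constants needed to move between model biomass (g/L), DNA
#' concentration and absolute genome copies: genome size, rRNA operon copy
#' number, and a biomass-to-copies conversion (`cells_per_gram`, in
#' copies/mL per g/L of biomass) bridging the kinetic model's mass units to
#' qPCR observables.
#'
#' @param genome_size_bp Genome size in base pairs.
#' @param copies_16s Target copies per genome (integer >= 1).
#' @param cells_per_gram Genome copies/mL corresponding to 1 g/L biomass
#'   (default 1e12).
#' @return An object of class `qpcr_calibration`.
#' @export
qpcr_calibration <- function(genome_size_bp = 2e6, copies_16s = 1,
                             cells_per_gram = 1e12) {
  if (genome_size_bp <= 0) stop("genome size must be > 0")
  if (copies_16s < 1) stop("copies_16s must be >= 1")
  if (cells_per_gram <= 0) stop("cells_per_gram must be > 0")
  structure(list(genome_size_bp = genome_size_bp,
                 copies_16s = copies_16s,
                 cells_per_gram = cells_per_gram),
            class = "qpcr_calibration")
}

#' Convert a DNA concentration to genome copies per mL
#'
#' Absolute quantification identity:
#' `copies/mL = N_A * c * n_target / (genome_size * 660)`,
#' with `N_A` Avogadro's number, `c` the DNA concentration in g/mL,
#' `n_target` the per-genome copy number of the qPCR target, and 660 g/mol
#' the average mass of a base pair.
#'
#' @param dna_conc DNA concentration (g/mL), vectorized.
#' @param cal A [qpcr_calibration()].
#' @return Genome copies per mL.
#' @examples
#' qpcr_copies_per_ml(1e-6, qpcr_calibration(genome_size_bp = 2e6))
#' @export
qpcr_copies_per_ml <- function(dna_conc, cal) {
  stopifnot(inherits(cal, "qpcr_calibration"))
  if (any(dna_conc < 0)) stop("DNA concentration must be >= 0")
  6.02214076e23 * dna_conc * cal$copies_16s / (cal$genome_size_bp * 660)
}

#' Convert biomass (g/L) to qPCR copies/mL and back
#'
#' @param biomass Biomass in g/L.
#' @param copies Genome copies per mL.
#' @param cal A [qpcr_calibration()].
#' @return Copies/mL, or biomass in g/L.
#' @export
biomass_to_copies <- function(biomass, cal) {
  stopifnot(inherits(cal, "qpcr_calibration"))
  biomass * cal$cells_per_gram
}

#' @rdname biomass_to_copies
#' @export
copies_to_biomass <- function(copies, cal) {
  stopifnot(inherits(cal, "qpcr_calibration"))
  copies / cal$cells_per_gram
}

#' Percentage abundance over time
#'
#' Converts each species' measured biomass `Xm` to genome copies/mL and
#' expresses it as a percentage of the community total at each time point.
#' Rows sum to 100 within 1e-9. A time point where every species is zero
#' yields a row of `NA` and a warning (never a silent 0/0).
#'
#' @param traj A `trajectory` from [simulate_consortium()].
#' @param cal A single [qpcr_calibration()] shared by all species, or a
#'   named list of per-species calibrations.
#' @return A data.frame `time_h` plus one percentage column per species.
#' @export
percent_abundance <- function(traj, cal = qpcr_calibration()) {
  stopifnot(inherits(traj, "trajectory"))
  labels <- traj$labels
  xm <- traj$states[, paste0("Xm_", labels), drop = FALSE]
  cpg <- if (inherits(cal, "qpcr_calibration"))
    rep(cal$cells_per_gram, length(labels))
  else {
    stopifnot(all(labels %in% names(cal)))
    vapply(cal[labels], `[[`, 0, "cells_per_gram")
  }
  copies <- sweep(xm, 2, cpg, `*`)
  tot <- rowSums(copies)
  pct <- 100 * copies / tot
  if (any(tot == 0)) {
    warning("all-zero measured biomass at ", sum(tot == 0),
            " time point(s); percentages set to NA")
    pct[tot == 0, ] <- NA_real_
  }
  out <- data.frame(time_h = traj$times, pct, check.names = FALSE)
  colnames(out) <- c("time_h", labels)
  out
}
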