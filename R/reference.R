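#' Packaged reference parameter library
#'
#' Loads the reference parameter set for the four-species infant-gut
#' consortium (`Bi` = *B. infantis*, `Bv` = *B. vulgatus*, `Ec` = *E. coli*,
#' `La` = *L. acidophilus*) growing on fructooligosaccharides. The pairwise
#' interaction parameters are the published co-culture estimates; the
#' per-species kinetic slots are package defaults chosen so the packaged
#' scenarios reproduce the reported qualitative outcomes (see the methods
#' vignette).
#'
#' @param path Optional path to an alternative JSON library.
#' @return `reference_params()`: named list of [species_params()];
#'   `reference_interactions()`: an [interaction_matrix()];
#'   `reference_calibrations()`: named list of [qpcr_calibration()].
#' @examples
#' names(reference_params())
#' reference_interactions()$ef["Bv", "Ec"]
#' @export
reference_params <- function(path = NULL) {
  read_param_library(ref_path(path))$species
}

#' @rdname reference_params
#' @export
reference_interactions <- function(path = NULL) {
  read_param_library(ref_path(path))$interactions
}

#' @rdname reference_params
#' @export
reference_calibrations <- function(path = NULL) {
  read_param_library(ref_path(path))$calibrations
}

ref_path <- function(path = NULL) {
  if (!is.null(path)) return(path)
  system.file("extdata", "reference_params.json", package = "crossfeed",
              mustWork = TRUE)
}

#' Build a consortium model from the reference library
#'
#' @param members Species labels to include (default all four).
#' @param X0 Initial live biomass, scalar or named per member (g/L).
#' @param S0,A0,L0 Initial concentrations (g/L).
#' @param path Optional alternative library path.
#' @return A [consortium_model()].
#' @export
reference_model <- function(members = c("Bi", "Bv", "Ec", "La"),
                            X0 = 0.01, S0 = 10, A0 = 0, L0 = 0,
                            path = NULL) {
  lib <- read_param_library(ref_path(path))
  stopifnot(all(members %in% names(lib$species)))
  interactions <- if (length(members) > 1)
    subset_interactions(lib$interactions, members) else NULL
  consortium_model(unname(lib$species[members]), interactions,
                   S0 = S0, A0 = A0, L0 = L0, X0 = X0)
}
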