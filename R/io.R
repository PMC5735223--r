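#' Read / write a parameter library (JSON)
#'
#' A parameter library is a JSON document with a `species` array (each entry
#' carrying `name`, the 17 named parameter slots, `capabilities`, and
#' optionally a qPCR `calibration`) and an optional `interactions` object
#' (`order`, `ef` matrix with null diagonal, bounds).
#'
#' @param path JSON file path.
#' @return A list with elements `species` (named list of
#'   [species_params()]), `interactions` ([interaction_matrix()] or `NULL`)
#'   and `calibrations` (named list of [qpcr_calibration()] or `NULL`).
#' @export
read_param_library <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$species)) stop("parameter library has no 'species' entry")
  species <- list()
  calibrations <- list()
  for (entry in doc$species) {
    v <- unlist(entry$params)
    missing <- setdiff(param_slots(), names(v))
    if (length(missing))
      stop("species ", entry$name, " missing slots: ",
           paste(missing, collapse = ", "))
    caps <- lapply(entry$capabilities, isTRUE)
    species[[entry$name]] <- species_from_vector(entry$name, v, caps)
    if (!is.null(entry$calibration))
      calibrations[[entry$name]] <- do.call(qpcr_calibration,
                                            entry$calibration)
  }
  interactions <- NULL
  if (!is.null(doc$interactions)) {
    ord <- unlist(doc$interactions$order)
    ef <- t(vapply(doc$interactions$ef,
                   function(row) vapply(row, function(x)
                     if (is.null(x)) NA_real_ else as.numeric(x), 0),
                   numeric(length(ord))))
    interactions <- interaction_matrix(
      ord, ef,
      ef_limit = doc$interactions$ef_limit %||% 100,
      ef_min = doc$interactions$ef_min %||% 0.01)
  }
  list(species = species, interactions = interactions,
       calibrations = if (length(calibrations)) calibrations else NULL)
}

#' @rdname read_param_library
#' @param library A list shaped like the return value of
#'   [read_param_library()].
#' @export
write_param_library <- function(library, path) {
  species <- lapply(names(library$species), function(nm) {
    p <- library$species[[nm]]
    entry <- list(name = nm,
                  params = as.list(as_param_vector(p)),
                  capabilities = as.list(p$capabilities))
    if (!is.null(library$calibrations[[nm]]))
      entry$calibration <- unclass(library$calibrations[[nm]])
    entry
  })
  doc <- list(species = species)
  if (!is.null(library$interactions)) {
    im <- library$interactions
    doc$interactions <- list(
      order = im$species,
      ef = apply(im$ef, 1, function(row)
        lapply(row, function(x) if (is.na(x)) NULL else x),
        simplify = FALSE),
      ef_limit = im$ef_limit, ef_min = im$ef_min)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an observed dataset (tidy CSV + JSON sidecar)
#'
#' The CSV holds one row per time x replicate with columns
#' `time_h, replicate, copies_<sp>..., S, A, L`; the sidecar
#' (`<path>.json`) stores the culture design and generation provenance.
#'
#' @param ds An `observed_dataset` from [generate_dataset()].
#' @param path CSV path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` an
#'   `observed_dataset`.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "observed_dataset"))
  write.csv(ds$records, path, row.names = FALSE)
  side <- list(design = design_to_list(ds$design), provenance = ds$provenance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  records <- read.csv(path, comment.char = "#", check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  design <- design_from_list(side$design)
  structure(list(design = design, records = records,
                 provenance = side$provenance),
            class = "observed_dataset")
}

design_to_list <- function(d) {
  list(vessel = d$vessel, members = d$members, S0 = d$S0,
       times = d$times, replicates = d$replicates,
       inoculum = as.list(d$inoculum), name = d$name)
}

design_from_list <- function(l) {
  culture_design(vessel = l$vessel, members = unlist(l$members),
                 S0 = l$S0, times = unlist(l$times),
                 replicates = l$replicates,
                 inoculum = unlist(l$inoculum), name = l$name %||% NULL)
}

#' Serialize a fit result to JSON (with provenance) and back
#'
#' @param fit A `fit_result` from [scatter_search()].
#' @param path JSON path.
#' @return `write_fit` returns `path` invisibly; `read_fit` a list.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  out <- unclass(fit)
  out$estimates <- as.list(out$estimates)  # keep parameter names in JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  out$estimates <- unlist(out$estimates)
  structure(out, class = "fit_result")
}
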