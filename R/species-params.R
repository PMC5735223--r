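#' Canonical kinetic parameter slots
#'
#' Every organism in the model carries a fixed vector of 17 kinetic
#' parameters. This function returns their names in the canonical order used
#' throughout the package (serialization, estimation, sensitivity analysis).
#'
#' Slots, in order:
#' \describe{
#'   \item{mu_max}{maximum specific growth rate on the primary substrate (1/h)}
#'   \item{K_s}{Monod half-velocity constant (g/L)}
#'   \item{Y_sx}{biomass yield on substrate (g biomass / g substrate)}
#'   \item{Y_a}{acetate yield (g acetate / g substrate consumed)}
#'   \item{Y_l}{lactate yield (g lactate / g substrate consumed)}
#'   \item{I_a}{acetate inhibition constant (g/L)}
#'   \item{I_l}{lactate inhibition constant (g/L)}
#'   \item{k_d}{death / decay rate (1/h)}
#'   \item{t_lag}{lag time before growth starts (h)}
#'   \item{mu_maxA, K_sA, Y_sxA}{growth kinetics on acetate as secondary
#'     substrate (1/h, g/L, g/g)}
#'   \item{mu_maxL, K_sL, Y_sxL}{growth kinetics on lactate (1/h, g/L, g/g)}
#'   \item{K_rep}{primary-substrate repression constant gating secondary
#'     (acid) uptake (g/L)}
#'   \item{m_s}{maintenance substrate consumption (g substrate / g biomass / h)}
#' }
#'
#' @return Character vector of length 17.
#' @export
param_slots <- function() {
  c("mu_max", "K_s", "Y_sx", "Y_a", "Y_l", "I_a", "I_l", "k_d", "t_lag",
    "mu_maxA", "K_sA", "Y_sxA", "mu_maxL", "K_sL", "Y_sxL", "K_rep", "m_s")
}

capability_names <- function() {
  c("produces_acetate", "produces_lactate", "consumes_acetate",
    "consumes_lactate")
}

#' Kinetic parameters of one organism
#'
#' Constructs and validates the parameter set of a single species: Monod
#' growth on the primary carbohydrate with non-competitive inhibition by
#' acetate and lactate, first-order decay, a lag phase, optional secondary
#' growth on the two acids (repressed while primary substrate remains), and
#' capability flags stating which acids the organism produces or consumes.
#'
#' If a capability flag is `FALSE` the corresponding yield/uptake slots are
#' forced to 0 (e.g. `produces_acetate = FALSE` forces `Y_a = 0`).
#'
#' @param name Short species label (e.g. `"Bi"`, `"Bv"`, `"Ec"`, `"La"`).
#' @param mu_max,K_s,Y_sx,Y_a,Y_l,I_a,I_l,k_d,t_lag,mu_maxA,K_sA,Y_sxA,mu_maxL,K_sL,Y_sxL,K_rep,m_s
#'   Numeric parameter slots; see [param_slots()] for definitions and units.
#' @param produces_acetate,produces_lactate,consumes_acetate,consumes_lactate
#'   Capability flags.
#' @return An object of class `species_params`.
#' @examples
#' bi <- species_params("Bi", mu_max = 0.6, Y_a = 0.45, Y_l = 0.3,
#'                      produces_acetate = TRUE, produces_lactate = TRUE)
#' as_param_vector(bi)
#' @export
species_params <- function(name,
                           mu_max = 0.5, K_s = 0.05, Y_sx = 0.25,
                           Y_a = 0, Y_l = 0, I_a = 5, I_l = 5,
                           k_d = 0.01, t_lag = 0,
                           mu_maxA = 0, K_sA = 0.5, Y_sxA = 0.3,
                           mu_maxL = 0, K_sL = 0.5, Y_sxL = 0.3,
                           K_rep = 0.05, m_s = 0,
                           produces_acetate = Y_a > 0,
                           produces_lactate = Y_l > 0,
                           consumes_acetate = mu_maxA > 0,
                           consumes_lactate = mu_maxL > 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  v <- c(mu_max = mu_max, K_s = K_s, Y_sx = Y_sx, Y_a = Y_a, Y_l = Y_l,
         I_a = I_a, I_l = I_l, k_d = k_d, t_lag = t_lag,
         mu_maxA = mu_maxA, K_sA = K_sA, Y_sxA = Y_sxA,
         mu_maxL = mu_maxL, K_sL = K_sL, Y_sxL = Y_sxL,
         K_rep = K_rep, m_s = m_s)
  caps <- c(produces_acetate = isTRUE(produces_acetate),
            produces_lactate = isTRUE(produces_lactate),
            consumes_acetate = isTRUE(consumes_acetate),
            consumes_lactate = isTRUE(consumes_lactate))

  if (any(!is.finite(v))) stop("all parameter slots must be finite numbers")
  if (any(v < 0)) stop("all parameter slots must be >= 0")
  if (any(v[c("K_s", "I_a", "I_l", "K_rep")] <= 0))
    stop("K_s, I_a, I_l and K_rep must be > 0")
  if (v[["Y_sx"]] <= 0 || v[["Y_sx"]] > 1)
    stop("Y_sx must lie in (0, 1]")
  if (v[["Y_a"]] + v[["Y_l"]] > 1 + 1e-12)
    stop("Y_a + Y_l must not exceed 1 (product mass cannot exceed substrate)")

  # capability flags switch off the matching channels
  if (!caps[["produces_acetate"]]) v[["Y_a"]] <- 0
  if (!caps[["produces_lactate"]]) v[["Y_l"]] <- 0
  if (!caps[["consumes_acetate"]]) v[c("mu_maxA", "Y_sxA")] <- 0
  if (!caps[["consumes_lactate"]]) v[c("mu_maxL", "Y_sxL")] <- 0
  if (caps[["consumes_acetate"]] &&
      (v[["K_sA"]] <= 0 || v[["Y_sxA"]] <= 0 || v[["mu_maxA"]] <= 0))
    stop("acetate consumer needs mu_maxA, K_sA, Y_sxA > 0")
  if (caps[["consumes_lactate"]] &&
      (v[["K_sL"]] <= 0 || v[["Y_sxL"]] <= 0 || v[["mu_maxL"]] <= 0))
    stop("lactate consumer needs mu_maxL, K_sL, Y_sxL > 0")

  structure(list(name = name, params = v, capabilities = caps),
            class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat("<species_params>", x$name, "\n")
  print(round(x$params, 5))
  cat("capabilities:",
      paste(names(x$capabilities)[x$capabilities], collapse = ", "), "\n")
  invisible(x)
}

#' Serialize species parameters to the 17-slot numeric vector
#'
#' @param p A [species_params()] object.
#' @return Named numeric vector of length 17 in [param_slots()] order.
#' @export
as_param_vector <- function(p) {
  stopifnot(inherits(p, "species_params"))
  p$params[param_slots()]
}

#' Rebuild a species from a 17-slot vector
#'
#' Inverse of [as_param_vector()]. Capability flags default to "slot is
#' non-zero" unless given explicitly.
#'
#' @param name Species label.
#' @param v Named (or 17-long) numeric vector in [param_slots()] order.
#' @param capabilities Optional named logical vector.
#' @return A [species_params()] object.
#' @export
species_from_vector <- function(name, v, capabilities = NULL) {
  stopifnot(length(v) == 17L)
  if (is.null(names(v))) names(v) <- param_slots()
  args <- c(list(name = name), as.list(v[param_slots()]))
  if (!is.null(capabilities)) args <- c(args, as.list(capabilities))
  do.call(species_params, args)
}

#' Replace parameter slots of a species
#'
#' @param p A [species_params()] object.
#' @param ... Named slot replacements, e.g. `mu_max = 0.7`.
#' @return Updated `species_params`.
#' @export
update_params <- function(p, ...) {
  repl <- list(...)
  v <- as_param_vector(p)
  bad <- setdiff(names(repl), param_slots())
  if (length(bad)) stop("unknown parameter slots: ", paste(bad, collapse = ", "))
  v[names(repl)] <- unlist(repl)
  species_from_vector(p$name, v, as.list(p$capabilities))
}
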