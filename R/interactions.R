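#' Pairwise interaction matrix
#'
#' Holds the biomass-scaled interaction parameters `ef[i, j]`: the effect of
#' organism `j` (column) on organism `i`'s (row) specific growth rate. The
#' growth-rate multiplier contributed by neighbour `j` is
#' `clamp(1 - X_j / ef[i, j])`, so the sign convention is: negative `ef`
#' means `j` promotes `i`'s growth, positive means inhibition; magnitudes
#' near 0 are strong effects and magnitudes at the bound `ef_limit` are
#' effectively no interaction. Zero is illegal (it divides the neighbour
#' biomass).
#'
#' @param species Character vector of species labels (row/column order).
#' @param ef Numeric N x N matrix; the diagonal is ignored (set to `NA`).
#' @param ef_limit Upper bound on `|ef|` (default 100).
#' @param ef_min Lower bound on `|ef|` (default 0.01).
#' @return An object of class `interaction_matrix`.
#' @examples
#' im <- interaction_matrix(c("A", "B"), matrix(c(NA, -5, 2, NA), 2, 2))
#' @export
interaction_matrix <- function(species, ef, ef_limit = 100, ef_min = 0.01) {
  n <- length(species)
  stopifnot(n >= 2, is.matrix(ef), nrow(ef) == n, ncol(ef) == n,
            ef_limit > ef_min, ef_min > 0)
  dimnames(ef) <- list(species, species)
  diag(ef) <- NA_real_
  off <- ef[row(ef) != col(ef)]
  if (any(!is.finite(off))) stop("off-diagonal ef entries must be finite")
  if (any(abs(off) < ef_min))
    stop("ef entries must satisfy |ef| >= ", ef_min, " (zero is illegal)")
  if (any(abs(off) > ef_limit))
    stop("ef entries must satisfy |ef| <= ", ef_limit)
  structure(list(species = species, ef = ef,
                 ef_limit = ef_limit, ef_min = ef_min),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("<interaction_matrix> ef[i, j] = effect of column j on row i\n")
  print(x$ef)
  invisible(x)
}

#' Subset an interaction matrix to a set of species
#'
#' @param im An [interaction_matrix()].
#' @param members Labels to keep (length >= 2).
#' @return An `interaction_matrix` over `members`.
#' @export
subset_interactions <- function(im, members) {
  stopifnot(inherits(im, "interaction_matrix"),
            all(members %in% im$species), length(members) >= 2)
  interaction_matrix(members, im$ef[members, members, drop = FALSE],
                     ef_limit = im$ef_limit, ef_min = im$ef_min)
}

#' Interaction growth multiplier
#'
#' Dimensionless factor applied to a species' growth rate by a neighbour
#' with biomass `X_j`: `clamp(1 - X_j / ef, 0, cap)`. Positive `ef` with
#' `X_j` approaching `ef` drives the factor to 0 (growth arrest); negative
#' `ef` raises the factor above 1 (promotion), clamped at `cap` so mutualism
#' cannot blow up; `|ef|` at the bound leaves the factor near 1.
#'
#' @param ef Interaction parameter (non-zero, biomass scale g/L).
#' @param X_j Neighbour biomass (g/L), vectorized.
#' @param cap Upper clamp (default 2).
#' @return Numeric factor(s) in `[0, cap]`.
#' @examples
#' interaction_multiplier(99.99, 0.5)  # ~0.995, essentially no effect
#' interaction_multiplier(0.16, 0.5)   # 0, full growth arrest
#' @export
interaction_multiplier <- function(ef, X_j, cap = 2) {
  if (any(ef == 0)) stop("ef must be non-zero")
  if (any(X_j < 0)) stop("neighbour biomass must be >= 0")
  pmin(pmax(1 - X_j / ef, 0), cap)
}
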