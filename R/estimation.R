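#' Default box bounds for a free parameter
#'
#' Parameter names follow the convention `"<species>.<slot>"` for kinetic
#' slots (e.g. `"Bi.mu_max"`) and `"ef.<affected>.<acting>"` for interaction
#' entries (e.g. `"ef.Bv.Ec"` = effect of Ec on Bv). Interaction entries are
#' optimized over the full signed range; magnitudes below `ef_min` are
#' snapped to the nearest legal value when the candidate is applied.
#'
#' @param name Parameter name.
#' @return Numeric `c(lower, upper)`.
#' @export
default_bounds <- function(name) {
  if (startsWith(name, "ef.")) return(c(-100, 100))
  slot <- sub("^[^.]+\\.", "", name)
  switch(slot,
    mu_max = c(0.01, 2), K_s = c(0.01, 5), Y_sx = c(0.01, 1),
    Y_a = c(0, 1), Y_l = c(0, 1),
    I_a = c(0.01, 50), I_l = c(0.01, 50),
    k_d = c(0, 0.5), t_lag = c(0, 12),
    mu_maxA = c(0, 1), K_sA = c(0.01, 5), Y_sxA = c(0.01, 1),
    mu_maxL = c(0, 1), K_sL = c(0.01, 5), Y_sxL = c(0.01, 1),
    K_rep = c(0.01, 1), m_s = c(0, 0.1),
    stop("unknown parameter slot in '", name, "'"))
}

#' Define a calibration problem
#'
#' Couples one or more observed datasets to a parameterized model: a set of
#' base species parameters (the fixed values), an optional interaction
#' matrix, and a named set of free parameters with finite box bounds.
#' Observed copies/mL are mapped to model g/L through the qPCR calibration,
#' so residuals are computed in model units and normalized per observable.
#'
#' @param datasets List of `observed_dataset` objects (or a single one).
#' @param species Named list of [species_params()] covering every design
#'   member.
#' @param free Character vector of free parameter names (default bounds), or
#'   a named list of `c(lower, upper)` bounds.
#' @param interactions Optional [interaction_matrix()] base values; required
#'   when any dataset has more than one member or any `ef.*` is free.
#' @param cal A [qpcr_calibration()] or named per-species list.
#' @param weights Optional named weights per observable column (e.g.
#'   `c(S = 1, A = 2)`); default 1.
#' @return An object of class `fit_problem`.
#' @export
fit_problem <- function(datasets, species, free, interactions = NULL,
                        cal = qpcr_calibration(), weights = NULL) {
  if (inherits(datasets, "observed_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1,
            all(vapply(datasets, inherits, TRUE, "observed_dataset")))
  members <- unique(unlist(lapply(datasets, function(d) d$design$members)))
  if (!all(members %in% names(species)))
    stop("species list lacks: ",
         paste(setdiff(members, names(species)), collapse = ", "))

  if (is.character(free))
    free <- setNames(lapply(free, default_bounds), free)
  stopifnot(is.list(free), length(free) >= 0, !is.null(names(free)))
  for (nm in names(free)) {
    b <- free[[nm]]
    if (length(b) != 2 || any(!is.finite(b)) || b[1] >= b[2])
      stop("free parameter '", nm, "' needs finite bounds (lower < upper)")
  }

  needs_ef <- any(startsWith(names(free), "ef.")) ||
    any(vapply(datasets, function(d) length(d$design$members) > 1, TRUE))
  if (needs_ef && is.null(interactions)) {
    # default template: every pair at the no-effect bound
    n <- length(members)
    if (n > 1) {
      ef <- matrix(100, n, n); diag(ef) <- NA
      interactions <- interaction_matrix(members, ef)
    }
  }

  structure(list(datasets = datasets, species = species, free = free,
                 interactions = interactions, cal = cal,
                 weights = weights),
            class = "fit_problem")
}

# apply a named candidate vector onto (species, interactions)
apply_candidate <- function(problem, candidate) {
  species <- problem$species
  interactions <- problem$interactions
  for (nm in names(candidate)) {
    val <- candidate[[nm]]
    if (startsWith(nm, "ef.")) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      if (length(parts) != 3) stop("bad interaction name '", nm, "'")
      ef_min <- interactions$ef_min
      if (abs(val) < ef_min) val <- ifelse(val >= 0, ef_min, -ef_min)
      interactions$ef[parts[2], parts[3]] <- val
    } else {
      sp <- sub("\\..*$", "", nm)
      slot <- sub("^[^.]+\\.", "", nm)
      if (is.null(species[[sp]])) stop("unknown species in '", nm, "'")
      args <- setNames(list(val), slot)
      species[[sp]] <- do.call(update_params, c(list(species[[sp]]), args))
    }
  }
  list(species = species, interactions = interactions)
}

# residual vector for one candidate; error = sum(residuals^2)
problem_residuals <- function(problem, candidate) {
  st <- apply_candidate(problem, candidate)
  res <- numeric(0)
  for (ds in problem$datasets) {
    d <- ds$design
    im <- if (length(d$members) > 1)
      subset_interactions(st$interactions, d$members) else NULL
    m <- consortium_model(unname(st$species[d$members]), im,
                          S0 = d$S0, X0 = d$inoculum)
    traj <- simulate_consortium(m, d$times, rtol = 1e-7, atol = 1e-9)
    cpg <- cal_vector(problem$cal, d$members)
    # predictions in model units; observed counts are converted below
    pred <- cbind(traj$states[, paste0("Xm_", d$members), drop = FALSE],
                  traj$states[, c("S", "A", "L"), drop = FALSE])
    colnames(pred) <- c(paste0("copies_", d$members), "S", "A", "L")

    rec <- ds$records
    n_rep <- d$replicates
    for (obs_col in colnames(pred)) {
      obs <- rec[[obs_col]]
      if (startsWith(obs_col, "copies_")) {
        sp <- sub("^copies_", "", obs_col)
        obs <- obs / cpg[[sp]]  # fit in model units (g/L)
      }
      scale <- max(abs(obs))
      if (scale == 0) scale <- 1
      w <- 1
      if (!is.null(problem$weights) && obs_col %in% names(problem$weights))
        w <- problem$weights[[obs_col]]
      pr <- pred[match(rec$time_h, d$times), obs_col]
      res <- c(res, sqrt(w / n_rep) * (obs - pr) / scale)
    }
  }
  res
}

#' Calibration error of a candidate parameter set
#'
#' Sum over observables, times and replicates of squared residuals, each
#' residual normalized by the observable's maximum observed magnitude (so
#' the error is invariant to unit rescaling of any observable) and weighted
#' by `1/replicates`. A candidate whose simulation fails receives a large
#' finite penalty (1e9) rather than an error, so optimizers can keep going.
#'
#' @param candidate Named numeric vector of free-parameter values.
#' @param problem A [fit_problem()].
#' @return Scalar error, `>= 0`; exactly 0 iff the simulation reproduces
#'   every observation.
#' @export
fit_error <- function(candidate, problem) {
  stopifnot(inherits(problem, "fit_problem"))
  r <- tryCatch(problem_residuals(problem, candidate),
                error = function(e) NULL)
  if (is.null(r) || any(!is.finite(r))) return(1e9)
  sum(r^2)
}

#' Scatter-search global parameter estimation
#'
#' Population-based global optimization of [fit_error()] over the free
#' parameters of a [fit_problem()]: Latin-hypercube diversification, a
#' reference set of the best plus most diverse solutions, pairwise linear
#' solution combination, and Nelder-Mead local polish of the incumbent, all
#' inside a hard evaluation budget. The run is deterministic given `seed`,
#' and because the best-so-far solution is tracked across every evaluation,
#' a larger budget can never return a worse objective for the same seed.
#'
#' @param problem A [fit_problem()] with a non-empty free set.
#' @param budget Maximum number of error evaluations (default 2000).
#' @param seed RNG seed.
#' @param n_diverse Diversification sample size (default 50).
#' @param refset_size Reference-set size (default 10: 5 best + 5 diverse).
#' @param polish_maxit Nelder-Mead iterations per polish (default 120).
#' @return A `fit_result`: `estimates`, `objective`, `n_evaluations`,
#'   `seed`, `residuals`, `convergence`, plus provenance (`bounds`,
#'   `budget`).
#' @export
scatter_search <- function(problem, budget = 2000, seed = 1,
                           n_diverse = 50, refset_size = 10,
                           polish_maxit = 120) {
  stopifnot(inherits(problem, "fit_problem"))
  free <- problem$free
  if (length(free) == 0) stop("no free parameters to optimize")
  if (budget < refset_size) stop("budget must be >= refset_size")
  nm <- names(free)
  lb <- vapply(free, `[`, 0, 1)
  ub <- vapply(free, `[`, 0, 2)
  k <- length(nm)

  st <- new.env(parent = emptyenv())
  st$n <- 0L; st$best_f <- Inf; st$best_x <- NULL

  # scale-like parameters (strictly positive, bounds spanning >= 2 decades)
  # are searched in log space so their low range is not squeezed into a
  # corner of the unit cube
  logscale <- lb > 0 & ub / lb >= 100
  unscale <- function(x) {
    x <- pmin(pmax(x, 0), 1)
    v <- ifelse(logscale,
                exp(log(lb) + x * (log(ub) - log(lb))),
                lb + x * (ub - lb))
    setNames(v, nm)
  }
  # residual-vector evaluation (NULL on simulation failure); every call
  # counts against the budget
  evalr <- function(x) {
    if (st$n >= budget)
      stop(structure(class = c("cf_budget_done", "condition"),
                     list(message = "budget", call = NULL)))
    st$n <- st$n + 1L
    r <- tryCatch(problem_residuals(problem, unscale(x)),
                  error = function(e) NULL)
    if (!is.null(r) && any(!is.finite(r))) r <- NULL
    f <- if (is.null(r)) 1e9 else sum(r^2)
    if (f < st$best_f) { st$best_f <- f; st$best_x <- pmin(pmax(x, 0), 1) }
    if (is.null(r)) return(NULL)
    attr(r, "f") <- f
    r
  }
  evalx <- function(x) {
    r <- evalr(x)
    if (is.null(r)) 1e9 else attr(r, "f")
  }

  # Levenberg-Marquardt polish in the unit cube (finite-difference Jacobian)
  lm_polish <- function(x, max_iter = 60) {
    r <- evalr(x)
    if (is.null(r)) return(invisible(NULL))
    f <- attr(r, "f")
    lambda <- 1e-3
    for (it in seq_len(max_iter)) {
      J <- matrix(0, length(r), k)
      for (j in seq_len(k)) {
        h <- 1e-6
        xp <- x; xp[j] <- min(x[j] + h, 1)
        xm <- x; xm[j] <- max(x[j] - h, 0)
        rp <- evalr(xp); rm <- evalr(xm)
        if (is.null(rp) || is.null(rm)) return(invisible(NULL))
        J[, j] <- (rp - rm) / (xp[j] - xm[j])
      }
      g <- crossprod(J, r)
      jtj <- crossprod(J)
      improved <- FALSE
      for (try in 1:8) {
        step <- tryCatch(solve(jtj + lambda * diag(pmax(diag(jtj), 1e-12), k),
                               -g), error = function(e) NULL)
        if (is.null(step)) { lambda <- lambda * 10; next }
        xn <- pmin(pmax(x + as.numeric(step), 0), 1)
        rn <- evalr(xn)
        fn <- if (is.null(rn)) 1e9 else attr(rn, "f")
        if (fn < f) {
          x <- xn; r <- rn; f <- fn
          lambda <- max(lambda / 3, 1e-12)
          improved <- TRUE
          break
        }
        lambda <- lambda * 5
      }
      if (!improved || f <= 1e-16) break
    }
    invisible(NULL)
  }

  # diversification wave: latin hypercube sample -> (points, values)
  new_wave <- function() {
    n_div <- min(n_diverse, budget)
    lhs <- vapply(seq_len(k), function(j) (sample(n_div) - runif(n_div)) / n_div,
                  numeric(n_div))
    lhs <- matrix(lhs, nrow = n_div)
    list(x = lhs, f = apply(lhs, 1, evalx))
  }

  # reference set from a wave: half best, half max-min diverse
  build_refset <- function(wave) {
    ord <- order(wave$f)
    n_div <- nrow(wave$x)
    nb <- ceiling(refset_size / 2)
    ref_idx <- ord[seq_len(min(nb, n_div))]
    rest <- setdiff(seq_len(n_div), ref_idx)
    while (length(ref_idx) < min(refset_size, n_div) && length(rest)) {
      dmin <- vapply(rest, function(i)
        min(sqrt(colSums((t(wave$x[ref_idx, , drop = FALSE]) -
                            wave$x[i, ])^2))), 0)
      pick <- rest[which.max(dmin)]
      ref_idx <- c(ref_idx, pick)
      rest <- setdiff(rest, pick)
    }
    list(x = wave$x[ref_idx, , drop = FALSE], f = wave$f[ref_idx])
  }

  run <- function() {
    rs <- build_refset(new_wave())
    refx <- rs$x; reff <- rs$f
    polished <- rep(FALSE, nrow(refx))

    last_polished <- Inf
    for (outer in seq_len(10000)) {
      # pairwise linear combinations
      pairs <- combn(nrow(refx), 2, simplify = FALSE)
      for (pr in pairs) {
        x1 <- refx[pr[1], ]; x2 <- refx[pr[2], ]
        for (r in runif(2, -0.5, 1.5)) {
          child <- pmin(pmax(x1 + r * (x2 - x1), 0), 1)
          fc <- evalx(child)
          iw <- which.max(reff)
          if (fc < reff[iw]) {
            refx[iw, ] <- child; reff[iw] <- fc; polished[iw] <- FALSE
          }
        }
      }
      # local polish: Levenberg-Marquardt on the residual vector, applied
      # to the best not-yet-polished reference member so distinct basins
      # each get a local descent; once all are polished, shake the
      # incumbent with Nelder-Mead and re-polish
      if (any(!polished)) {
        ip <- which(!polished)[which.min(reff[!polished])]
        polished[ip] <- TRUE
        lm_polish(refx[ip, ])
      } else if (st$best_f < last_polished) {
        last_polished <- st$best_f
        o <- optim(st$best_x, function(x) evalx(x),
                   method = "Nelder-Mead",
                   control = list(maxit = polish_maxit,
                                  warn.1d.NelderMead = FALSE))
        lm_polish(pmin(pmax(o$par, 0), 1))
      } else {
        # stagnation: restart with a fresh diversification wave, keeping
        # the incumbent in the new reference set
        rs <- build_refset(new_wave())
        refx <- rbind(st$best_x, rs$x[-nrow(rs$x), , drop = FALSE])
        reff <- c(st$best_f, rs$f[-length(rs$f)])
        polished <- c(TRUE, rep(FALSE, nrow(refx) - 1))
        last_polished <- Inf
      }
      iw <- which.max(reff)
      if (st$best_f < reff[iw]) {
        refx[iw, ] <- st$best_x; reff[iw] <- st$best_f
        polished[iw] <- TRUE
      }
      if (st$best_f <= 1e-14) break
    }
  }

  with_seed(seed, tryCatch(run(), cf_budget_done = function(c) NULL))

  est <- unscale(st$best_x)
  resid <- tryCatch(problem_residuals(problem, est), error = function(e) NULL)
  structure(list(estimates = est, objective = st$best_f,
                 n_evaluations = st$n, seed = seed,
                 residuals = resid, convergence = is.finite(st$best_f),
                 bounds = list(lower = as.list(lb), upper = as.list(ub)),
                 budget = budget),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> objective =", format(x$objective, digits = 6),
      "after", x$n_evaluations, "evaluations (seed", paste0(x$seed, ")\n"))
  print(signif(x$estimates, 5))
  invisible(x)
}

# default mono-culture free slots for one species (~8, per its capabilities)
default_free_slots <- function(p) {
  slots <- c("mu_max", "Y_sx", "I_a", "I_l", "k_d", "t_lag")
  if (p$capabilities[["produces_acetate"]]) slots <- c(slots, "Y_a")
  if (p$capabilities[["produces_lactate"]]) slots <- c(slots, "Y_l")
  slots
}

#' Staged calibration: mono-cultures first, then pairwise interactions
#'
#' Implements the two-stage protocol: (1) each species' kinetic parameters
#' are fitted to its mono-culture dataset (its interaction-free model);
#' (2) holding all mono-fitted kinetics fixed, each paired co-culture
#' dataset is fitted for exactly its two interaction parameters
#' (`ef.i.j` and `ef.j.i`). Stage 2 never alters a stage-1 estimate.
#'
#' @param mono_datasets Named (by species) list of mono-culture
#'   `observed_dataset`s; ignored when `mono_params` is supplied.
#' @param pair_datasets List of two-member `observed_dataset`s, one per
#'   unordered pair.
#' @param base_params Named list of [species_params()] starting values /
#'   fixed slots.
#' @param cal qPCR calibration(s) for mapping counts to biomass.
#' @param mono_params Optional named list of [species_params()] to use as-is
#'   (skips stage 1, e.g. when mono kinetics are known).
#' @param free_mono Optional named list (per species) of free slot names for
#'   stage 1; defaults to [default_free_slots] per species.
#' @param budget_mono,budget_pair Evaluation budgets per stage-1 / stage-2
#'   fit.
#' @param seed Base RNG seed (stage fits derive distinct seeds from it).
#' @return List with `species` (calibrated [species_params()]),
#'   `interactions` (an [interaction_matrix()], unfitted entries at the
#'   no-effect bound), `mono_fits` and `pair_fits`.
#' @export
staged_calibration <- function(mono_datasets = NULL, pair_datasets,
                               base_params, cal = qpcr_calibration(),
                               mono_params = NULL, free_mono = NULL,
                               budget_mono = 3000, budget_pair = 2000,
                               seed = 1) {
  # stage 1: mono-culture kinetics
  if (is.null(mono_params)) {
    if (is.null(mono_datasets)) stop("need mono_datasets or mono_params")
    needed <- unique(unlist(lapply(pair_datasets,
                                   function(d) d$design$members)))
    missing <- setdiff(needed, names(mono_datasets))
    if (length(missing))
      stop("missing mono-culture dataset(s) for: ",
           paste(missing, collapse = ", "))
    mono_fits <- list()
    mono_params <- base_params
    i <- 0
    for (sp in names(mono_datasets)) {
      i <- i + 1
      slots <- if (!is.null(free_mono)) free_mono[[sp]]
               else default_free_slots(base_params[[sp]])
      prob <- fit_problem(mono_datasets[[sp]], base_params,
                          free = paste0(sp, ".", slots), cal = cal)
      fit <- scatter_search(prob, budget = budget_mono, seed = seed + 1000 * i)
      mono_fits[[sp]] <- fit
      mono_params[[sp]] <- apply_candidate(
        list(species = mono_params, interactions = NULL),
        fit$estimates)$species[[sp]]
    }
  } else mono_fits <- NULL

  # stage 2: two interaction parameters per pair, kinetics frozen
  members <- sort(unique(unlist(lapply(pair_datasets,
                                       function(d) d$design$members))))
  ef <- matrix(100, length(members), length(members),
               dimnames = list(members, members))
  diag(ef) <- NA
  pair_fits <- list()
  i <- 0
  for (ds in pair_datasets) {
    i <- i + 1
    pr <- ds$design$members
    if (length(pr) != 2) stop("pair dataset must have exactly 2 members")
    free <- c(paste0("ef.", pr[1], ".", pr[2]),
              paste0("ef.", pr[2], ".", pr[1]))
    prob <- fit_problem(ds, mono_params, free = free,
                        interactions = interaction_matrix(members, ef),
                        cal = cal)
    fit <- scatter_search(prob, budget = budget_pair, seed = seed + 100 * i)
    pair_fits[[paste(pr, collapse = "")]] <- fit
    for (nm in names(fit$estimates)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      val <- fit$estimates[[nm]]
      if (abs(val) < 0.01) val <- ifelse(val >= 0, 0.01, -0.01)
      ef[parts[2], parts[3]] <- val
    }
  }

  list(species = mono_params[members],
       interactions = interaction_matrix(members, ef),
       mono_fits = mono_fits, pair_fits = pair_fits)
}
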