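#' Construct an activity dataset
#'
#' A velocity-versus-substrate table with measurement errors, tagged with
#' the scan axis, the fixed co-substrate concentration and the urea level
#' it was recorded at. Per-enzyme units (s^-1) throughout; convert bulk
#' velocities at I/O.
#'
#' @param conc_M scanned substrate concentrations (M)
#' @param v0_per_s initial velocities per enzyme (s^-1)
#' @param sem standard errors (> 0)
#' @param axis `"AMP"` or `"ATP"` -- which substrate was scanned
#' @param cosubstrate_M fixed co-substrate concentration (M)
#' @param urea urea concentration label (mol/L)
#' @export
activity_dataset <- function(conc_M, v0_per_s, sem, axis = "AMP",
                             cosubstrate_M = 1e-3, urea = 0) {
  if (length(conc_M) < 4L) stop("an activity dataset needs at least 4 rows")
  if (any(sem <= 0)) stop("standard errors must be positive")
  structure(data.frame(conc_M = conc_M, v0_per_s = v0_per_s, sem = sem),
            class = c("ak_activity_dataset", "data.frame"),
            axis = axis, cosubstrate_M = cosubstrate_M, urea = urea)
}

# assemble the parameter set seen by one dataset: base parameters, overlaid
# with the per-urea fixed inputs (measured Kd_AMP, conformational rates),
# overlaid with the free parameters being optimized
assemble_params <- function(base, inputs, urea, free_values) {
  p <- base
  key <- as.character(urea)
  if (!is.null(inputs) && key %in% names(inputs)) {
    ov <- inputs[[key]]
    for (nm in names(ov)) p[[nm]] <- ov[[nm]]
  }
  for (nm in names(free_values)) p[[nm]] <- free_values[[nm]]
  p
}

model_chi2 <- function(datasets, base, inputs, free_values) {
  terms <- lapply(datasets, function(ds) {
    p <- assemble_params(base, inputs, attr(ds, "urea"), free_values)
    axis <- attr(ds, "axis")
    cos <- attr(ds, "cosubstrate_M")
    cond <- if (axis == "AMP") ak_conditions(atp = cos, amp = 0, urea = attr(ds, "urea"))
            else ak_conditions(atp = 0, amp = cos, urea = attr(ds, "urea"))
    v <- velocity_curve(p, cond, ds$conc_M, axis)$velocity_per_s
    ((v - ds$v0_per_s) / ds$sem)^2
  })
  # sorted accumulation keeps the objective bit-identical under dataset reordering
  sum(sort(unlist(terms)))
}

#' Globally fit kinetic parameters to activity datasets
#'
#' Minimizes the weighted sum of squares
#' `sum(((v_model - v_obs)/sem)^2)` over all datasets simultaneously.
#' The free parameters (by default the urea-independent rate constants
#' `k_cat`, `k_r_T`, `k_r_M`) are shared globally across urea levels; the
#' urea-dependent measured inputs (AMP affinity, conformational rates) are
#' supplied per urea level via `inputs` and held fixed. Optimization runs
#' in log-space (positivity by construction) from a deterministic
#' multi-start schedule: the seed guess itself plus starts drawn
#' log-uniformly within +/- 2 decades of it, best likelihood retained.
#'
#' @param datasets list of [activity_dataset] objects
#' @param base_params an [ak_params] providing all fixed fields and the
#'   seed guess for free parameters
#' @param free character vector of `ak_params` field names to optimize
#' @param inputs named list (by urea label, e.g. `"0"`, `"0.8"`) of lists
#'   of per-urea fixed overrides, e.g. `list(Kd_AMP = 758e-6, conf_rates = ...)`
#' @param n_starts multi-start count (default 16)
#' @param seed RNG seed for the start schedule (default 1234)
#' @return object of class `ak_fit_result`: `estimate` (named vector),
#'   `params_by_urea`, `chi2`, `chi2_red`, `n_obs`, `converged`
#' @export
global_fit <- function(datasets, base_params,
                       free = c("k_cat", "k_r_T", "k_r_M"),
                       inputs = NULL, n_starts = 16, seed = 1234) {
  if (length(datasets) == 0L) stop("need at least one dataset")
  if (inherits(datasets, "ak_activity_dataset")) datasets <- list(datasets)
  stopifnot(inherits(base_params, "ak_params"))
  guess <- log(vapply(free, function(nm) base_params[[nm]], numeric(1)))
  set.seed(seed)
  starts <- matrix(guess, 1L, length(free))
  if (n_starts > 1L)
    starts <- rbind(starts,
                    matrix(runif((n_starts - 1L) * length(free),
                                 min = -2, max = 2) * log(10),
                           ncol = length(free), byrow = TRUE) +
                      matrix(guess, n_starts - 1L, length(free), byrow = TRUE))
  neg <- function(lp) {
    fv <- as.list(exp(lp)); names(fv) <- free
    val <- tryCatch(model_chi2(datasets, base_params, inputs, fv),
                    error = function(e) Inf)
    if (!is.finite(val)) 1e14 else val
  }
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    fit <- if (length(free) == 1L)
      optim(starts[r, ], neg, method = "Brent",
            lower = starts[r, ] - 4 * log(10), upper = starts[r, ] + 4 * log(10),
            control = list(maxit = 2000))
    else
      optim(starts[r, ], neg, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  est <- exp(best$par); names(est) <- free
  n_obs <- sum(vapply(datasets, nrow, integer(1)))
  dof <- max(n_obs - length(free), 1L)
  ureas <- unique(vapply(datasets, function(d) attr(d, "urea"), numeric(1)))
  pbu <- lapply(ureas, function(u)
    assemble_params(base_params, inputs, u, as.list(est)))
  names(pbu) <- as.character(ureas)
  structure(list(estimate = est, params_by_urea = pbu,
                 chi2 = best$value, chi2_red = best$value / dof,
                 n_obs = n_obs, n_free = length(free),
                 converged = best$convergence == 0L),
            class = "ak_fit_result")
}

#' Profile-likelihood confidence interval for one fitted parameter
#'
#' Walks the parameter over `grid`, re-optimizing all other free parameters
#' at each value, and reports the region where the reduced chi-square stays
#' within a threshold of its minimum. The threshold corresponds to a raw
#' chi-square increase of 1 (a 1-sigma interval), i.e.
#' `chi2_red <= chi2_red_min + 1/dof`. A profile still below threshold at a
#' grid edge yields an open bound on that side (only a lower or upper bound
#' can be stated, as for catalytic rates far above the rate-limiting step);
#' an essentially flat profile is flagged unidentifiable.
#'
#' @param fit an `ak_fit_result` from [global_fit]
#' @param datasets,base_params,inputs as passed to [global_fit]
#' @param param name of the profiled parameter
#' @param grid values to profile over (should bracket the estimate)
#' @param n_starts multi-starts for each conditional re-fit (default 2)
#' @return list: `lower`, `upper`, `open_lower`, `open_upper`,
#'   `unidentifiable`, `threshold`, `profile` (data.frame `value`,
#'   `chi2_red`)
#' @export
profile_ci <- function(fit, datasets, base_params, inputs = NULL,
                       param, grid, n_starts = 2) {
  stopifnot(inherits(fit, "ak_fit_result"))
  if (!fit$converged) stop("profile_ci requires a converged fit")
  if (inherits(datasets, "ak_activity_dataset")) datasets <- list(datasets)
  free <- setdiff(names(fit$estimate), param)
  dof <- max(fit$n_obs - fit$n_free, 1L)
  prof <- vapply(grid, function(g) {
    if (length(free) == 0L) {
      fv <- setNames(list(g), param)
      return(model_chi2(datasets, base_params, inputs, fv) / dof)
    }
    base_g <- base_params
    base_g[[param]] <- g
    sub <- global_fit(datasets, base_g, free = free, inputs = inputs,
                      n_starts = n_starts, seed = 1234)
    sub$chi2 / dof
  }, numeric(1))
  thr <- min(min(prof), fit$chi2_red) + 1 / dof
  below <- prof <= thr
  span <- max(prof) - min(prof)
  unident <- span < 0.1 / dof
  cross <- function(i, j) {   # linear interpolation of the threshold crossing
    exp(log(grid[i]) + (thr - prof[i]) * (log(grid[j]) - log(grid[i])) /
          (prof[j] - prof[i]))
  }
  idx <- which(below)
  if (length(idx) == 0L) idx <- which.min(prof)
  lo_i <- min(idx); hi_i <- max(idx)
  open_lower <- lo_i == 1L
  open_upper <- hi_i == length(grid)
  lower <- if (open_lower) grid[1] else cross(lo_i, lo_i - 1L)
  upper <- if (open_upper) grid[length(grid)] else cross(hi_i, hi_i + 1L)
  list(lower = lower, upper = upper,
       open_lower = open_lower, open_upper = open_upper,
       unidentifiable = unident, threshold = thr,
       profile = data.frame(value = grid, chi2_red = prof))
}
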