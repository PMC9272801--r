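# Linear-program layer ------------------------------------------------------
#
# Every evaluation in the package is an LP of the single shape
#     optimize  c'v   s.t.  S v = 0,  lb <= v <= ub
# Knockouts are lb = ub = 0 on member reactions; growth floors and envelope
# growth fixing are bounds on the biomass column, so no extra constraint
# rows are ever needed.  The backend is the simplex of pracma::linprog,
# called in pure standard form (x >= 0): variables are shifted by lb and
# the upper bounds passed as inequality rows.  All bounds are finite
# (capped at +/-1000), so no LP here can be unbounded.

ZERO_TOL <- 1e-6   # flux magnitudes below this count as zero
ENV_DELTA <- 1e-9  # relative slack when fixing growth on the envelope grid

# status: "optimal", "infeasible", or "failure" (numerical)
solve_lp <- function(S, lb, ub, obj, maximize = TRUE) {
  n <- ncol(S)
  shift <- lb
  Aeq <- as.matrix(S)
  beq <- as.vector(-Aeq %*% shift)
  cc <- if (maximize) -obj else obj
  res <- tryCatch(
    pracma::linprog(cc, A = diag(n), b = ub - lb, Aeq = Aeq, beq = beq,
                    maxiter = 5000),
    error = function(e) NULL)
  if (is.null(res))
    return(list(status = "failure", value = NA_real_, flux = NULL))
  if (is.null(res$errno) || res$errno != 1)
    return(list(status = "infeasible", value = NA_real_, flux = NULL))
  v <- unname(res$x + shift)
  list(status = "optimal", value = sum(obj * v), flux = v)
}

# Apply a knockout (indices) and optional biomass-bound override, then
# optimize the flux of column `obj_col`.
model_lp <- function(model, ko = integer(0), obj_col, maximize = TRUE,
                     bio_lb = NULL, bio_ub = NULL) {
  lb <- model$lb; ub <- model$ub
  if (length(ko)) { lb[ko] <- 0; ub[ko] <- 0 }
  b <- model$objective_index
  if (!is.null(bio_lb)) lb[b] <- bio_lb
  if (!is.null(bio_ub)) ub[b] <- bio_ub
  if (lb[b] > ub[b])
    return(list(status = "infeasible", value = NA_real_, flux = NULL))
  obj <- numeric(n_reactions(model)); obj[obj_col] <- 1
  solve_lp(model$stoich, lb, ub, obj, maximize = maximize)
}

lp_error <- function(what, ko, model) {
  stop("LP ", what, " while evaluating design {",
       paste(model$reaction_ids[ko], collapse = ", "), "}", call. = FALSE)
}

#' Maximum growth rate under a knockout
#'
#' Flux balance analysis: maximizes the biomass flux subject to
#' steady-state mass balance and bounds, with every knocked-out reaction
#' fixed to zero flux.
#'
#' @param model a [metabolic_model()].
#' @param ko integer vector of reaction column indices to knock out (empty
#'   for the wild type).
#' @return the optimum growth rate in 1/h; `0` (with attribute
#'   `infeasible = TRUE`) if the knockout leaves no feasible steady state.
#' @export
fba_max_growth <- function(model, ko = integer(0)) {
  r <- model_lp(model, ko, obj_col = model$objective_index, maximize = TRUE)
  if (r$status == "infeasible") return(structure(0, infeasible = TRUE))
  if (r$status != "optimal") lp_error("did not converge", ko, model)
  max(0, r$value)
}

#' Product flux range at a growth floor
#'
#' Minimum and maximum flux through the target exchange subject to biomass
#' flux at or above `growth_floor`. The minimum is the guaranteed synthesis
#' at that growth; tiny negative minima (within the zero tolerance) are
#' clipped to 0.
#'
#' @inheritParams fba_max_growth
#' @param growth_floor biomass flux lower bound (1/h); must be feasible.
#' @return named numeric `c(p_lo, p_hi)` (mmol/gDW/h).
#' @export
product_range_at_growth <- function(model, ko = integer(0), growth_floor = 0) {
  if (is.na(model$target_index))
    stop("model has no resolved target reaction", call. = FALSE)
  floor_lb <- max(model$lb[model$objective_index], growth_floor)
  lo <- model_lp(model, ko, obj_col = model$target_index, maximize = FALSE,
                 bio_lb = floor_lb)
  hi <- model_lp(model, ko, obj_col = model$target_index, maximize = TRUE,
                 bio_lb = floor_lb)
  if (lo$status == "infeasible" || hi$status == "infeasible")
    lp_error(paste0("infeasible at growth floor ", format(growth_floor)),
             ko, model)
  if (lo$status != "optimal" || hi$status != "optimal")
    lp_error("did not converge", ko, model)
  p_lo <- lo$value
  if (p_lo < 0 && p_lo > -ZERO_TOL) p_lo <- 0
  c(p_lo = p_lo, p_hi = hi$value)
}

#' Maximum product flux (growth unconstrained)
#'
#' @inheritParams fba_max_growth
#' @return maximum target flux in mmol/gDW/h; 0 if infeasible.
#' @export
max_product <- function(model, ko = integer(0)) {
  if (is.na(model$target_index))
    stop("model has no resolved target reaction", call. = FALSE)
  r <- model_lp(model, ko, obj_col = model$target_index, maximize = TRUE)
  if (r$status == "infeasible") return(structure(0, infeasible = TRUE))
  if (r$status != "optimal") lp_error("did not converge", ko, model)
  max(0, r$value)
}

#' Production envelope of a design
#'
#' Computes min/max product flux on a grid of `n + 1` evenly spaced growth
#' values from 0 to the design's maximum growth rate. At each grid point
#' the biomass flux is fixed within a +/- 1e-9 * mu_star band (the top
#' point is backed off to mu_star * (1 - 1e-9)) so vertex LPs stay
#' feasible.
#'
#' @inheritParams fba_max_growth
#' @param n number of grid intervals (>= 2).
#' @return an object of class `production_envelope`: list with `mu_grid`,
#'   `p_lo`, `p_hi`, `mu_star` (max growth), `p_max` (the design's maximum
#'   synthesis: the growth-unconstrained product optimum, at least the grid
#'   maximum of `p_hi`) and `mu_apex` (largest grid growth attaining the
#'   envelope's maximum up to relative 1e-6).
#' @export
production_envelope <- function(model, ko = integer(0), n = 10) {
  if (n < 2) stop("envelope grid needs n >= 2", call. = FALSE)
  mu_star <- as.numeric(fba_max_growth(model, ko))
  if (mu_star <= 0)
    stop("production envelope undefined: design has zero maximum growth",
         call. = FALSE)
  mu_grid <- seq(0, mu_star, length.out = n + 1)
  delta <- ENV_DELTA * mu_star
  p_lo <- numeric(n + 1); p_hi <- numeric(n + 1)
  for (k in seq_along(mu_grid)) {
    mu <- mu_grid[k]
    if (k == n + 1) mu <- mu_star * (1 - ENV_DELTA)
    lo_b <- max(0, mu - delta); hi_b <- mu + delta
    lo <- model_lp(model, ko, obj_col = model$target_index, maximize = FALSE,
                   bio_lb = lo_b, bio_ub = hi_b)
    hi <- model_lp(model, ko, obj_col = model$target_index, maximize = TRUE,
                   bio_lb = lo_b, bio_ub = hi_b)
    if (lo$status != "optimal" || hi$status != "optimal")
      lp_error(paste0("failed at envelope growth ", format(mu)), ko, model)
    p_lo[k] <- if (lo$value < 0 && lo$value > -ZERO_TOL) 0 else lo$value
    p_hi[k] <- hi$value
  }
  # exact maximum synthesis (one growth-unconstrained LP) rather than the
  # grid maximum, which under-reads p_max when the apex falls between
  # grid points
  p_max <- max(as.numeric(max_product(model, ko)), max(p_hi))
  new_production_envelope(mu_grid, p_lo, p_hi, mu_star, p_max = p_max)
}

#' Assemble a production envelope from precomputed values
#'
#' Low-level constructor (used by [production_envelope()] and by tests that
#' build envelopes with known geometry). Checks the envelope invariants.
#'
#' @param mu_grid strictly increasing growth grid starting at 0.
#' @param p_lo,p_hi per-grid-point product flux bounds.
#' @param mu_star maximum growth; must equal `mu_grid[length(mu_grid)]`.
#' @param p_max maximum synthesis; defaults to the grid maximum of `p_hi`
#'   and may not be smaller.
#' @return a `production_envelope`.
#' @export
new_production_envelope <- function(mu_grid, p_lo, p_hi,
                                    mu_star = mu_grid[length(mu_grid)],
                                    p_max = max(p_hi)) {
  stopifnot(length(mu_grid) == length(p_lo), length(p_lo) == length(p_hi))
  if (mu_grid[1] != 0 || any(diff(mu_grid) <= 0))
    stop("mu_grid must be strictly increasing from 0", call. = FALSE)
  if (abs(mu_grid[length(mu_grid)] - mu_star) > 1e-9 * max(1, mu_star))
    stop("mu_grid must end at mu_star", call. = FALSE)
  if (any(p_lo > p_hi + ZERO_TOL))
    stop("envelope has p_lo > p_hi", call. = FALSE)
  if (p_max < max(p_hi) - ZERO_TOL)
    stop("p_max below the envelope's upper bound", call. = FALSE)
  apex_ok <- p_hi >= max(p_hi) * (1 - 1e-6)
  structure(list(mu_grid = mu_grid, p_lo = p_lo, p_hi = p_hi,
                 mu_star = mu_star, p_max = max(p_max, max(p_hi)),
                 mu_apex = max(mu_grid[apex_ok])),
            class = "production_envelope")
}

#' @export
print.production_envelope <- function(x, ...) {
  cat("<production_envelope> ", length(x$mu_grid), " grid points\n", sep = "")
  cat("  mu* =", format(x$mu_star), " p_max =", format(x$p_max),
      " mu_apex =", format(x$mu_apex), "\n")
  cat("  guaranteed at mu*:", format(x$p_lo[length(x$p_lo)]), "\n")
  invisible(x)
}
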