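# The three maximized objectives of a knockout design:
#   growth    -- maximum growth rate mu* (FBA)
#   product   -- guaranteed product flux at (near-)maximum growth
#   coupling  -- coupling-strength score from the production envelope
# plus the weak/strong/uncoupled classification.

#' Search and evaluation configuration
#'
#' Collects every tunable of the evaluation and of the genetic-algorithm
#' search, with the package defaults.
#'
#' @param K_max maximum knockouts per design (genome length).
#' @param pop_size population size (even, >= 4).
#' @param crossover_prob probability of uniform crossover per parent pair.
#' @param mutation_rate per-slot reset-mutation probability; default
#'   `1 / K_max`.
#' @param time_limit wall-clock search budget in seconds.
#' @param max_generations generation cap.
#' @param stall_generations,stall_tol terminate when the archive
#'   hypervolume's relative change over `stall_generations` generations
#'   falls below `stall_tol`.
#' @param seed RNG seed; a fixed seed makes the whole run deterministic.
#' @param tau relative growth tolerance when reading off guaranteed
#'   synthesis (floor = `(1 - tau) * mu*`).
#' @param eps_p product-flux threshold below which synthesis counts as
#'   absent.
#' @param f_min growth fraction above which strong coupling requires
#'   guaranteed synthesis at every envelope grid point.
#' @param n_env production-envelope grid intervals.
#' @param min_growth_frac viability threshold as a fraction of wild-type
#'   growth.
#' @param log_level `"info"` for per-generation progress lines, `"quiet"`
#'   for silence.
#' @return a list of class `search_config`.
#' @export
search_config <- function(K_max = 5, pop_size = 200, crossover_prob = 0.8,
                          mutation_rate = 1 / K_max, time_limit = 3600,
                          max_generations = 500, stall_generations = 50,
                          stall_tol = 1e-4, seed = NULL,
                          tau = 1e-3, eps_p = 1e-4, f_min = 0.1, n_env = 10,
                          min_growth_frac = 0.01, log_level = "quiet") {
  stopifnot(K_max >= 1, pop_size >= 4, pop_size %% 2 == 0,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            time_limit >= 0, n_env >= 2)
  structure(list(K_max = as.integer(K_max), pop_size = as.integer(pop_size),
                 crossover_prob = crossover_prob,
                 mutation_rate = mutation_rate, time_limit = time_limit,
                 max_generations = max_generations,
                 stall_generations = as.integer(stall_generations),
                 stall_tol = stall_tol, seed = seed, tau = tau, eps_p = eps_p,
                 f_min = f_min, n_env = as.integer(n_env),
                 min_growth_frac = min_growth_frac, log_level = log_level),
            class = "search_config")
}

#' Guaranteed synthesis at (near-)maximum growth
#'
#' The minimum product flux compatible with growing at at least
#' `(1 - tau)` times the design's maximum growth rate — the flux the
#' design is forced to secrete when growth is (near) optimal.
#'
#' @inheritParams fba_max_growth
#' @param tau relative growth tolerance (default 0: floor exactly at
#'   `mu*`).
#' @return guaranteed product flux (mmol/gDW/h).
#' @export
guaranteed_synthesis <- function(model, ko = integer(0), tau = 0) {
  mu_star <- as.numeric(fba_max_growth(model, ko))
  if (mu_star <= 0)
    stop("guaranteed synthesis undefined at zero maximum growth",
         call. = FALSE)
  unname(product_range_at_growth(model, ko, (1 - tau) * mu_star)["p_lo"])
}

#' Coupling strength of a production envelope
#'
#' A dimensionless score in `[-1, 1]` that rewards designs whose envelope
#' forces synthesis across growth rates (strongly coupled), and among
#' uncoupled designs rewards those whose maximum synthesis costs little
#' growth:
#'
#' * no synthesis possible (`p_max <= eps_p`): `-1`;
#' * coupled (guaranteed flux at maximum growth): the normalized area
#'   under the envelope's lower bound,
#'   `CS = integral(p_lo) / (mu* * p_max)` (trapezoidal on the grid),
#'   in `(0, 1]`;
#' * uncoupled: `CS = -(mu* - mu_apex) / mu*` in `[-1, 0]` — the relative
#'   growth sacrifice needed to reach maximum synthesis, so flatter
#'   envelopes (apex near maximum growth) score closer to 0.
#'
#' The score is continuous across the coupled/uncoupled boundary and
#' invariant to rescaling all fluxes.
#'
#' @param env a [production_envelope()].
#' @param eps_p product-flux zero threshold.
#' @return coupling strength in `[-1, 1]`.
#' @export
coupling_strength <- function(env, eps_p = 1e-4) {
  if (env$p_max <= eps_p) return(-1)
  n <- length(env$mu_grid)
  if (env$p_lo[n] > eps_p) {
    area <- sum(diff(env$mu_grid) * (env$p_lo[-1] + env$p_lo[-n]) / 2)
    area / (env$mu_star * env$p_max)
  } else {
    -(env$mu_star - env$mu_apex) / env$mu_star
  }
}

#' Classify the coupling of a production envelope
#'
#' @inheritParams coupling_strength
#' @param f_min growth fraction above which strong coupling requires
#'   guaranteed synthesis at every grid point.
#' @return one of `"no-synthesis"`, `"uncoupled"`, `"weak"`, `"strong"`.
#'   Weak coupling guarantees synthesis only near maximum growth; strong
#'   coupling guarantees it at all growth rates above `f_min * mu*`.
#' @export
classify_coupling <- function(env, eps_p = 1e-4, f_min = 0.1) {
  if (env$p_max <= eps_p) return("no-synthesis")
  n <- length(env$mu_grid)
  if (env$p_lo[n] <= eps_p) return("uncoupled")
  tested <- env$mu_grid >= f_min * env$mu_star
  if (all(env$p_lo[tested] > eps_p)) "strong" else "weak"
}

fitness_triple <- function(growth, product, coupling, viable, coupling_class) {
  structure(list(growth = growth, product = product, coupling = coupling,
                 viable = viable, coupling_class = coupling_class),
            class = "fitness_triple")
}

nonviable_fitness <- function() fitness_triple(0, 0, -1, FALSE, "no-synthesis")

#' @export
print.fitness_triple <- function(x, ...) {
  cat(sprintf("<fitness> growth=%.6g product=%.6g coupling=%.6g [%s%s]\n",
              x$growth, x$product, x$coupling, x$coupling_class,
              if (x$viable) "" else ", non-viable"))
  invisible(x)
}

design_key <- function(ko) paste0("k:", paste(sort(unique(ko)), collapse = ","))

#' Evaluate a knockout design
#'
#' Computes the fitness triple of a design: maximum growth by FBA; if
#' growth falls below `min_growth_frac` of the wild-type optimum the
#' non-viable sentinel `(0, 0, -1)` is returned; otherwise guaranteed
#' synthesis, the production envelope, coupling strength and coupling
#' class. LP failures also yield the sentinel (with a warning) so a
#' search never aborts on a pathological design.
#'
#' @inheritParams fba_max_growth
#' @param cfg a [search_config()].
#' @param mu_wt wild-type maximum growth; computed if `NULL`.
#' @param cache optional environment used to memoize results by canonical
#'   knockout key (memoization is observationally transparent).
#' @return a `fitness_triple`.
#' @export
evaluate_design <- function(model, ko = integer(0), cfg = search_config(),
                            mu_wt = NULL, cache = NULL) {
  key <- design_key(ko)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  if (is.null(mu_wt)) mu_wt <- as.numeric(fba_max_growth(model))
  fit <- tryCatch({
    mu_star <- as.numeric(fba_max_growth(model, ko))
    if (mu_star < cfg$min_growth_frac * mu_wt) nonviable_fitness()
    else {
      p_guar <- guaranteed_synthesis(model, ko, tau = cfg$tau)
      env <- production_envelope(model, ko, n = cfg$n_env)
      fitness_triple(mu_star, max(0, p_guar),
                     coupling_strength(env, eps_p = cfg$eps_p),
                     TRUE, classify_coupling(env, eps_p = cfg$eps_p,
                                             f_min = cfg$f_min))
    }
  }, error = function(e) {
    warning("design {", key, "} evaluation failed (", conditionMessage(e),
            "); treating as non-viable", call. = FALSE)
    nonviable_fitness()
  })
  if (!is.null(cache)) cache[[key]] <- fit
  fit
}
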