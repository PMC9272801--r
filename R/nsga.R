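# NSGA-II machinery: dominance, non-dominated sorting, crowding distance,
# variation operators, hypervolume, and the main search loop.  All three
# objectives (growth, guaranteed product, coupling strength) are maximized.

fitness_vec <- function(f) c(f$growth, f$product, f$coupling)

#' Pareto dominance between two fitness triples
#'
#' `a` dominates `b` iff `a` is at least as good in all three objectives
#' (growth, product, coupling strength; all maximized) and strictly better
#' in at least one.
#'
#' @param a,b `fitness_triple`s or length-3 numeric vectors.
#' @return logical.
#' @export
dominates <- function(a, b) {
  if (inherits(a, "fitness_triple")) a <- fitness_vec(a)
  if (inherits(b, "fitness_triple")) b <- fitness_vec(b)
  all(a >= b) && any(a > b)
}

#' Fast non-dominated sorting
#'
#' Partitions fitness vectors into Pareto fronts: front 1 is the maximal
#' (non-dominated) set, front 2 is maximal once front 1 is removed, and so
#' on (Deb's NSGA-II sorting).
#'
#' @param fitness numeric matrix, one row per individual, columns =
#'   objectives (all maximized), or a list of `fitness_triple`s.
#' @return list of integer vectors (row indices), one per front; their
#'   union is the input.
#' @export
non_dominated_sort <- function(fitness) {
  F <- as_fitness_matrix(fitness)
  n <- nrow(F)
  if (n == 0) return(list())
  dominated_by <- vector("list", n)  # who each i dominates
  n_dom <- integer(n)                # how many dominate i
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(F[i, ] >= F[j, ]) && any(F[i, ] > F[j, ]))
        dominated_by[[i]] <- c(dominated_by[[i]], j)
      else if (all(F[j, ] >= F[i, ]) && any(F[j, ] > F[i, ]))
        n_dom[i] <- n_dom[i] + 1L
    }
  }
  fronts <- list()
  current <- which(n_dom == 0L)
  while (length(current)) {
    fronts[[length(fronts) + 1]] <- current
    nxt <- integer(0)
    for (i in current) {
      for (j in dominated_by[[i]]) {
        n_dom[j] <- n_dom[j] - 1L
        if (n_dom[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- sort(nxt)
  }
  fronts
}

as_fitness_matrix <- function(fitness) {
  if (is.matrix(fitness)) return(fitness)
  if (is.list(fitness) && length(fitness) &&
      inherits(fitness[[1]], "fitness_triple"))
    return(do.call(rbind, lapply(fitness, fitness_vec)))
  if (is.list(fitness)) return(do.call(rbind, fitness))
  matrix(fitness, nrow = length(fitness) > 0)
}

#' Crowding distance within a Pareto front
#'
#' Per NSGA-II: for each objective the front is sorted, boundary members
#' get infinite distance, and interior members accumulate the normalized
#' gap between their neighbors. Ties are broken by input order (stable
#' sort).
#'
#' @param front numeric matrix of fitness rows (one front).
#' @return numeric vector of crowding distances, one per row.
#' @export
crowding_distance <- function(front) {
  front <- as_fitness_matrix(front)
  n <- nrow(front)
  if (is.null(n) || n == 0) return(numeric(0))
  d <- numeric(n)
  for (m in seq_len(ncol(front))) {
    ord <- order(front[, m])  # stable: ties keep input order
    d[ord[1]] <- Inf
    d[ord[n]] <- Inf
    rng <- front[ord[n], m] - front[ord[1], m]
    if (n > 2 && rng > 0)
      for (k in 2:(n - 1))
        d[ord[k]] <- d[ord[k]] +
          (front[ord[k + 1], m] - front[ord[k - 1], m]) / rng
  }
  d
}

#' Variation: uniform crossover and reset mutation on genomes
#'
#' A genome is a fixed-length integer vector of `K_max` slots; slot value
#' 0 means "no knockout", a positive value indexes a candidate target.
#' Consecutive parent pairs undergo uniform crossover with probability
#' `crossover_prob` (each slot swapped with probability 1/2), then every
#' slot mutates with probability `mutation_rate` to a uniform draw from
#' {0, 1, ..., n_targets}.
#'
#' @param parents integer matrix, rows = genomes, `K_max` columns.
#' @param n_targets number of candidate targets.
#' @param cfg a [search_config()].
#' @return integer matrix of children, same shape as `parents`.
#' @export
vary_genomes <- function(parents, n_targets, cfg) {
  children <- parents
  np <- nrow(parents)
  for (p in seq_len(np %/% 2)) {
    i <- 2 * p - 1; j <- 2 * p
    if (stats::runif(1) < cfg$crossover_prob) {
      swap <- stats::runif(ncol(parents)) < 0.5
      tmp <- children[i, swap]
      children[i, swap] <- children[j, swap]
      children[j, swap] <- tmp
    }
  }
  if (cfg$mutation_rate > 0) {
    mask <- matrix(stats::runif(length(children)) < cfg$mutation_rate,
                   nrow = np)
    if (any(mask))
      children[mask] <- sample.int(n_targets + 1L, sum(mask),
                                   replace = TRUE) - 1L
  }
  children
}

decode_genome <- function(genome) sort(unique(genome[genome > 0L]))

#' Dominated hypervolume of a set of fitness vectors
#'
#' Volume of objective space dominated by the set relative to the
#' reference point `(0, 0, -1)` (zero growth, zero product, worst
#' coupling). Points not strictly better than the reference in any
#' coordinate contribute nothing.
#'
#' @param fitness matrix of fitness rows (growth, product, coupling).
#' @param ref reference point.
#' @return non-negative scalar.
#' @export
hypervolume <- function(fitness, ref = c(0, 0, -1)) {
  F <- as_fitness_matrix(fitness)
  if (is.null(F) || nrow(F) == 0) return(0)
  P <- sweep(F, 2, ref)          # shift so ref is the origin
  P <- pmax(P, 0)
  P <- P[rowSums(P > 0) == 3, , drop = FALSE]  # must dominate ref
  if (nrow(P) == 0) return(0)
  # slice along objective 3
  levels <- sort(unique(P[, 3]), decreasing = TRUE)
  vol <- 0
  for (k in seq_along(levels)) {
    z_hi <- levels[k]
    z_lo <- if (k < length(levels)) levels[k + 1] else 0
    slab <- P[P[, 3] >= z_hi, 1:2, drop = FALSE]
    vol <- vol + (z_hi - z_lo) * hv2d(slab)
  }
  vol
}

# 2D hypervolume w.r.t. origin for maximization (points > 0)
hv2d <- function(pts) {
  if (nrow(pts) == 0) return(0)
  area <- 0; best_y <- 0
  # sweep x descending, accumulating staircase area
  xs <- pts[, 1]; ys <- pts[, 2]
  uniq_x <- sort(unique(xs), decreasing = TRUE)
  for (x in uniq_x) {
    y_here <- max(ys[xs >= x])
    if (y_here > best_y) {
      area <- area + x * (y_here - best_y)
      best_y <- y_here
    }
  }
  area
}

#' NSGA-II search over knockout designs
#'
#' Runs the multi-objective genetic algorithm over subsets of the
#' candidate targets: binary tournament selection on (rank, crowding),
#' uniform crossover + reset mutation, elitist environmental selection,
#' plus an unbounded external archive of every non-dominated evaluated
#' design. The initial population contains the empty design (wild type)
#' so the wild-type Pareto point is present from generation 0.
#' Termination: wall clock >= `time_limit`, generation cap, or archive
#' hypervolume stall.
#'
#' @param model a reduced [metabolic_model()] with resolved target.
#' @param candidates a `candidate_set` from [build_search_space()].
#' @param cfg a [search_config()]; `cfg$seed` fixes the whole run.
#' @return an object of class `pareto_archive`: list with `designs` (list
#'   of integer vectors of target indices), `fitness` (matrix), `classes`,
#'   `n_evaluations`, `generations`, `hv_history`.
#' @export
run_search <- function(model, candidates, cfg = search_config()) {
  if (!length(candidates$targets))
    stop("candidate set is empty; nothing to search", call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  t0 <- proc.time()[["elapsed"]]
  n_t <- length(candidates$targets)
  cols <- vapply(candidates$targets, function(t) t$column, 0L)
  cache <- new.env(parent = emptyenv())
  mu_wt <- as.numeric(fba_max_growth(model))
  n_evals <- 0L
  eval_design <- function(targets_idx) {
    ko <- cols[targets_idx]
    key <- design_key(ko)
    if (is.null(cache[[key]])) n_evals <<- n_evals + 1L
    evaluate_design(model, ko, cfg, mu_wt = mu_wt, cache = cache)
  }
  # archive state
  arch_designs <- list()
  arch_fit <- matrix(numeric(0), 0, 3)
  arch_classes <- character(0); arch_keys <- character(0)
  update_archive <- function(designs, fits) {
    for (k in seq_along(designs)) {
      f <- fits[[k]]
      if (!f$viable) next
      key <- design_key(designs[[k]])
      if (key %in% arch_keys) next
      v <- fitness_vec(f)
      if (nrow(arch_fit) &&
          any(apply(arch_fit, 1, function(a) all(a >= v) && any(a > v))))
        next
      keep <- if (nrow(arch_fit) == 0) logical(0) else
        !apply(arch_fit, 1, function(a) all(v >= a) && any(v > a))
      arch_designs <<- c(arch_designs[keep], list(designs[[k]]))
      arch_fit <<- rbind(arch_fit[keep, , drop = FALSE], v)
      arch_classes <<- c(arch_classes[keep], f$coupling_class)
      arch_keys <<- c(arch_keys[keep], key)
    }
  }
  # initial population: wild type + uniform random genomes
  pop <- matrix(sample.int(n_t + 1L, cfg$pop_size * cfg$K_max,
                           replace = TRUE) - 1L,
                nrow = cfg$pop_size)
  pop[1, ] <- 0L
  evaluate_pop <- function(P) {
    designs <- apply(P, 1, decode_genome, simplify = FALSE)
    fits <- lapply(designs, eval_design)
    update_archive(designs, fits)
    do.call(rbind, lapply(fits, fitness_vec))
  }
  fit <- evaluate_pop(pop)
  hv_hist <- hypervolume(arch_fit)
  gen <- 0L
  log_gen <- function() {
    if (cfg$log_level != "quiet")
      message(sprintf(
        "gen=%d evals=%d archive=%d hv=%.6g best_growth=%.6g best_product=%.6g best_cs=%.6g",
        gen, n_evals, length(arch_designs), hv_hist[length(hv_hist)],
        max(fit[, 1]), max(fit[, 2]), max(fit[, 3])))
  }
  log_gen()
  repeat {
    if (proc.time()[["elapsed"]] - t0 >= cfg$time_limit) break
    if (gen >= cfg$max_generations) break
    if (gen >= cfg$stall_generations) {
      hv_now <- hv_hist[gen + 1]
      hv_old <- hv_hist[gen + 1 - cfg$stall_generations]
      if ((hv_now - hv_old) < cfg$stall_tol * max(hv_old, 1e-12)) break
    }
    # binary tournament on (rank, crowding)
    fronts <- non_dominated_sort(fit)
    rank <- integer(nrow(fit))
    crowd <- numeric(nrow(fit))
    for (r in seq_along(fronts)) {
      rank[fronts[[r]]] <- r
      crowd[fronts[[r]]] <- crowding_distance(fit[fronts[[r]], , drop = FALSE])
    }
    pick <- function() {
      ij <- sample.int(nrow(pop), 2)
      i <- ij[1]; j <- ij[2]
      if (rank[i] < rank[j]) i
      else if (rank[j] < rank[i]) j
      else if (crowd[i] >= crowd[j]) i else j
    }
    parents <- pop[vapply(seq_len(cfg$pop_size), function(...) pick(), 0L),
                   , drop = FALSE]
    children <- vary_genomes(parents, n_t, cfg)
    child_fit <- evaluate_pop(children)
    # elitist environmental selection from parents + children
    comb <- rbind(pop, children)
    comb_fit <- rbind(fit, child_fit)
    fronts <- non_dominated_sort(comb_fit)
    sel <- integer(0)
    for (fr in fronts) {
      if (length(sel) + length(fr) <= cfg$pop_size) {
        sel <- c(sel, fr)
      } else {
        cd <- crowding_distance(comb_fit[fr, , drop = FALSE])
        take <- fr[order(-cd, seq_along(fr))][seq_len(cfg$pop_size - length(sel))]
        sel <- c(sel, take)
        break
      }
    }
    pop <- comb[sel, , drop = FALSE]
    fit <- comb_fit[sel, , drop = FALSE]
    gen <- gen + 1L
    hv_hist <- c(hv_hist, hypervolume(arch_fit))
    log_gen()
  }
  structure(list(designs = arch_designs,
                 fitness = arch_fit,
                 classes = arch_classes,
                 n_evaluations = n_evals,
                 generations = gen,
                 hv_history = hv_hist),
            class = "pareto_archive")
}

#' @export
print.pareto_archive <- function(x, ...) {
  cat("<pareto_archive> ", length(x$designs), " non-dominated designs (",
      x$n_evaluations, " evaluations, ", x$generations, " generations)\n",
      sep = "")
  if (length(x$designs)) {
    F <- x$fitness
    ord <- order(-F[, 1], -F[, 2])
    for (i in ord)
      cat(sprintf("  [%s]  growth=%.6g product=%.6g coupling=%.6g %s\n",
                  paste(x$designs[[i]], collapse = ","), F[i, 1], F[i, 2],
                  F[i, 3], x$classes[i]))
  }
  invisible(x)
}
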