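# Post-processing: strip redundant knockouts, deduplicate, re-filter.

#' Remove redundant knockouts from a design
#'
#' Iteratively attempts to drop each knockout (ascending target index,
#' restarting after any removal); a knockout is dropped when the
#' re-evaluated fitness triple is at least the incumbent in all three
#' objectives (tolerance 1e-6). The result is a fixed point: no further
#' single removal is admissible. Refinement never decreases any objective
#' and never increases design size.
#'
#' @param model a reduced [metabolic_model()].
#' @param design integer vector of candidate-target indices.
#' @param candidates the `candidate_set` the design indexes into.
#' @param cfg a [search_config()].
#' @param cache optional memoization environment shared with the search.
#' @return list with `design` (minimal design) and `fitness` (its
#'   `fitness_triple`).
#' @export
remove_redundant_kos <- function(model, design, candidates,
                                 cfg = search_config(), cache = NULL) {
  tol <- 1e-6
  cols <- vapply(candidates$targets, function(t) t$column, 0L)
  mu_wt <- as.numeric(fba_max_growth(model))
  eval_d <- function(d) evaluate_design(model, cols[d], cfg,
                                        mu_wt = mu_wt, cache = cache)
  design <- sort(unique(design))
  incumbent <- eval_d(design)
  repeat {
    removed <- FALSE
    for (t in design) {
      trial <- setdiff(design, t)
      f <- eval_d(trial)
      inc <- fitness_vec(incumbent)
      if (all(fitness_vec(f) >= inc - tol)) {
        design <- trial
        incumbent <- f
        removed <- TRUE
        break  # restart scan from the smallest index
      }
    }
    if (!removed) break
  }
  list(design = design, fitness = incumbent)
}

#' Filter an archive to its Pareto front
#'
#' Drops duplicate designs (first occurrence kept) and dominated entries.
#' Distinct designs with equal fitness are all kept: they are alternative
#' implementations of the same performance.
#'
#' @param archive a `pareto_archive`.
#' @return a `pareto_archive` whose entries are mutually non-dominated.
#' @export
pareto_filter <- function(archive) {
  n <- length(archive$designs)
  if (n == 0) return(archive)
  keys <- vapply(archive$designs, design_key, "")
  keep <- !duplicated(keys)
  F <- archive$fitness[keep, , drop = FALSE]
  designs <- archive$designs[keep]
  classes <- archive$classes[keep]
  m <- nrow(F)
  dominated <- vapply(seq_len(m), function(i) {
    any(vapply(seq_len(m), function(j) {
      j != i && all(F[j, ] >= F[i, ]) && any(F[j, ] > F[i, ])
    }, TRUE))
  }, TRUE)
  archive$designs <- designs[!dominated]
  archive$fitness <- F[!dominated, , drop = FALSE]
  archive$classes <- classes[!dominated]
  archive
}

#' Refine a whole archive
#'
#' Applies [remove_redundant_kos()] to every archived design, then
#' [pareto_filter()]. Idempotent.
#'
#' @inheritParams remove_redundant_kos
#' @param archive a `pareto_archive` from [run_search()].
#' @return the refined `pareto_archive`.
#' @export
refine_archive <- function(model, archive, candidates,
                           cfg = search_config(), cache = NULL) {
  if (!length(archive$designs)) return(archive)
  out <- lapply(archive$designs, function(d)
    remove_redundant_kos(model, d, candidates, cfg, cache))
  archive$designs <- lapply(out, `[[`, "design")
  fits <- lapply(out, `[[`, "fitness")
  archive$fitness <- do.call(rbind, lapply(fits, fitness_vec))
  archive$classes <- vapply(fits, function(f) f$coupling_class, "")
  pareto_filter(archive)
}

#' Expand a design to original-model reaction ids
#'
#' Maps candidate-target indices to the reaction ids of the unreduced
#' model, expanding lumped composites to all their members.
#'
#' @param design integer vector of candidate-target indices.
#' @param candidates the `candidate_set`.
#' @return sorted character vector of original reaction ids.
#' @export
expand_composites <- function(design, candidates) {
  if (any(design < 1 | design > length(candidates$targets)))
    stop("design indexes unknown candidate targets", call. = FALSE)
  if (!length(design)) return(character(0))
  sort(unique(unlist(lapply(candidates$targets[design],
                            function(t) t$members))))
}
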