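# Independent oracles and shared fixtures for the test suite.

# Brute-force Pareto dominance (maximization), kept deliberately naive and
# separate from the package's implementation.
oracle_dominates <- function(a, b) {
  ge <- TRUE; gt <- FALSE
  for (k in seq_along(a)) {
    if (a[k] < b[k]) ge <- FALSE
    if (a[k] > b[k]) gt <- TRUE
  }
  ge && gt
}

# O(n^2) non-dominated sorting by repeated extraction of the maximal set.
oracle_nds <- function(F) {
  remaining <- seq_len(nrow(F))
  fronts <- list()
  while (length(remaining)) {
    maximal <- remaining[vapply(remaining, function(i) {
      !any(vapply(remaining, function(j)
        j != i && oracle_dominates(F[j, ], F[i, ]), TRUE))
    }, TRUE)]
    fronts[[length(fronts) + 1]] <- maximal
    remaining <- setdiff(remaining, maximal)
  }
  fronts
}

# Extract the maximal (Pareto) rows of a fitness matrix, brute force.
oracle_pareto_rows <- function(F) {
  keep <- vapply(seq_len(nrow(F)), function(i) {
    !any(vapply(seq_len(nrow(F)), function(j)
      j != i && oracle_dominates(F[j, ], F[i, ]), TRUE))
  }, TRUE)
  F[keep, , drop = FALSE]
}

# The toy model's Pareto front, worked out by hand from the LP geometry:
#   wild type      : mu* = 10, nothing guaranteed, apex at mu = 5 -> CS = -1/2
#   KO {RSP}       : mu* = 6, guaranteed 4; integral of max(0, mu - 2)
#                    over [0,6] = 8, p_max = 5 -> CS = 8/30 = 4/15
#   KO {RSP, ALT}  : mu* = 5, guaranteed 5; p_lo = mu -> CS = 12.5/25 = 1/2
toy_front_oracle <- function() {
  matrix(c(10, 0, -0.5,
           6, 4, 4 / 15,
           5, 5, 0.5),
         ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("growth", "product", "coupling")))
}

# Sort fitness rows lexicographically so set comparisons are stable.
sort_rows <- function(F) {
  F[order(F[, 1], F[, 2], F[, 3]), , drop = FALSE]
}

# Exhaustive enumeration of all designs of size <= k_max over the
# candidate targets, evaluated through the package's evaluator.  Used as
# the completeness oracle for the GA (the search must not beat or miss
# this set).
enumerate_front <- function(model, candidates, cfg, k_max) {
  cols <- vapply(candidates$targets, function(t) t$column, 0L)
  nt <- length(cols)
  designs <- list(integer(0))
  for (k in seq_len(min(k_max, nt)))
    designs <- c(designs,
                 lapply(asplit(utils::combn(nt, k), 2), as.integer))
  fits <- lapply(designs, function(d)
    evaluate_design(model, cols[d], cfg))
  viable <- vapply(fits, function(f) f$viable, TRUE)
  F <- do.call(rbind, lapply(fits[viable], function(f)
    c(f$growth, f$product, f$coupling)))
  unique(oracle_pareto_rows(F))
}

# Evaluation settings under which the toy model's hand-derived values are
# exact: no growth tolerance, fine envelope grid.
toy_cfg <- function(...) {
  search_config(K_max = 2, pop_size = 20, max_generations = 50,
                tau = 0, n_env = 50, ...)
}

expect_front_equal <- function(F_got, F_want, cs_tol = 1e-3, tol = 1e-6) {
  F_got <- sort_rows(unname(F_got))
  F_want <- sort_rows(unname(F_want))
  expect_equal(nrow(F_got), nrow(F_want))
  expect_equal(F_got[, 1], F_want[, 1], tolerance = tol)
  expect_equal(F_got[, 2], F_want[, 2], tolerance = tol)
  expect_lt(max(abs(F_got[, 3] - F_want[, 3])), cs_tol)
}

# Path of the installed command-line script.
cli_script <- function() system.file("exec", "gcdesign.R", package = "gcdesign")

run_cli <- function(args) {
  out <- suppressWarnings(
    system2(file.path(R.home("bin"), "Rscript"), c(cli_script(), args),
            stdout = TRUE, stderr = TRUE))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
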