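# Multi-objective GA machinery and the search itself.

test_that("dominance is the strict Pareto order", {
  a <- c(10, 0, -0.5); b <- c(6, 4, 0.267)
  expect_false(dominates(a, b))
  expect_false(dominates(b, a))
  expect_true(dominates(c(6, 4, 0.3), c(6, 4, 0.267)))
  expect_false(dominates(a, a))  # irreflexive
})

test_that("non-dominated sorting equals the brute-force oracle", {
  set.seed(101)
  F <- cbind(runif(200, 0, 10), runif(200, 0, 5), runif(200, -1, 1))
  # inject duplicates and comparable chains
  F[51:60, ] <- F[1:10, ]
  F[61:70, ] <- sweep(F[1:10, ], 2, c(0.1, 0.1, 0.05))
  got <- non_dominated_sort(F)
  want <- oracle_nds(F)
  expect_equal(length(got), length(want))
  for (k in seq_along(want))
    expect_setequal(got[[k]], want[[k]])
  expect_setequal(unlist(got), seq_len(nrow(F)))
})

test_that("non-dominated sorting handles degenerate inputs", {
  same <- matrix(1, 5, 3)
  expect_equal(non_dominated_sort(same), list(1:5))
  chain <- rbind(c(3, 3, 3), c(2, 2, 2), c(1, 1, 1))
  expect_equal(non_dominated_sort(chain), list(1L, 2L, 3L))
})

test_that("crowding distance follows the boundary and gap rules", {
  expect_equal(crowding_distance(rbind(c(1, 2, 3), c(2, 1, 0))),
               c(Inf, Inf))
  three <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  d <- crowding_distance(three)
  expect_equal(d, c(Inf, 3, Inf))  # middle: full-range gap per objective
  expect_equal(crowding_distance(matrix(numeric(0), 0, 3)), numeric(0))
})

test_that("variation operators behave at the extremes and are seeded", {
  cfg0 <- search_config(K_max = 4, crossover_prob = 0, mutation_rate = 0)
  parents <- rbind(c(1L, 0L, 2L, 0L), c(0L, 3L, 0L, 1L))
  expect_identical(vary_genomes(parents, 3, cfg0), parents)

  cfg1 <- search_config(K_max = 4, crossover_prob = 0, mutation_rate = 1)
  set.seed(5)
  kids <- vary_genomes(rbind(rep(0L, 4), rep(0L, 4)), 5, cfg1)
  expect_true(all(kids >= 0 & kids <= 5))
  set.seed(9); k1 <- vary_genomes(parents, 3, search_config(K_max = 4))
  set.seed(9); k2 <- vary_genomes(parents, 3, search_config(K_max = 4))
  expect_identical(k1, k2)
})

test_that("hypervolume is the dominated box volume", {
  # single point (2, 3, 0) vs ref (0, 0, -1): box 2 * 3 * 1
  expect_equal(hypervolume(matrix(c(2, 3, 0), 1)), 6)
  # two nested points: the dominated one adds nothing
  expect_equal(hypervolume(rbind(c(2, 3, 0), c(1, 1, -0.5))), 6)
  # disjoint staircase in 2D at fixed third coordinate
  expect_equal(hypervolume(rbind(c(2, 1, 0), c(1, 2, 0))), 3)
  expect_equal(hypervolume(matrix(numeric(0), 0, 3)), 0)
  # point at the reference contributes nothing
  expect_equal(hypervolume(matrix(c(0, 0, -1), 1)), 0)
})

test_that("the search recovers the exhaustive toy front from any seed", {
  ss <- build_search_space(toy_redox_model())
  for (seed in c(1, 7, 42)) {
    cfg <- toy_cfg(seed = seed)
    arch <- run_search(ss$model, ss$candidates, cfg)
    arch <- refine_archive(ss$model, arch, ss$candidates, cfg)
    expect_front_equal(arch$fitness, toy_front_oracle())
  }
})

test_that("search matches exhaustive enumeration on a family model", {
  fam <- random_coupling_family(4, 1, seed = 3)
  ss <- build_search_space(fam)
  cfg <- search_config(K_max = 2, pop_size = 20, max_generations = 60,
                       tau = 0, n_env = 10, seed = 2)
  want <- enumerate_front(ss$model, ss$candidates, cfg, k_max = 2)
  arch <- run_search(ss$model, ss$candidates, cfg)
  arch <- refine_archive(ss$model, arch, ss$candidates, cfg)
  got <- unique(unname(arch$fitness))
  expect_front_equal(got, want, cs_tol = 1e-6)
})

test_that("a zero time limit stops after the initial population", {
  ss <- build_search_space(toy_redox_model())
  arch <- run_search(ss$model, ss$candidates,
                     toy_cfg(seed = 1, time_limit = 0))
  expect_equal(arch$generations, 0L)
  expect_gte(length(arch$designs), 1)  # wild type is always seeded
})

test_that("identical seeds give identical archives", {
  ss <- build_search_space(toy_redox_model())
  a1 <- run_search(ss$model, ss$candidates, toy_cfg(seed = 99))
  a2 <- run_search(ss$model, ss$candidates, toy_cfg(seed = 99))
  expect_identical(a1$designs, a2$designs)
  expect_identical(a1$fitness, a2$fitness)
  expect_identical(a1$hv_history, a2$hv_history)
})

test_that("archive entries re-evaluate to their stored fitness", {
  ss <- build_search_space(toy_redox_model())
  cfg <- toy_cfg(seed = 4)
  arch <- run_search(ss$model, ss$candidates, cfg)
  cols <- vapply(ss$candidates$targets, function(t) t$column, 0L)
  for (k in seq_along(arch$designs)) {
    f <- evaluate_design(ss$model, cols[arch$designs[[k]]], cfg)
    expect_equal(c(f$growth, f$product, f$coupling),
                 unname(arch$fitness[k, ]), tolerance = 1e-9)
  }
  # archive is mutually non-dominated
  F <- arch$fitness
  for (i in seq_len(nrow(F)))
    for (j in seq_len(nrow(F)))
      if (i != j) expect_false(oracle_dominates(F[i, ], F[j, ]))
})

test_that("archive hypervolume never decreases over generations", {
  ss <- build_search_space(toy_redox_model())
  arch <- run_search(ss$model, ss$candidates, toy_cfg(seed = 11))
  expect_true(all(diff(arch$hv_history) >= -1e-12))
})

test_that("an empty candidate set is a configuration error", {
  ss <- build_search_space(toy_redox_model())
  empty <- ss$candidates; empty$targets <- list()
  expect_error(run_search(ss$model, empty, toy_cfg(seed = 1)), "empty")
})
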