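# Pre-processing: dead reactions, lumping, essentiality screens.

test_that("dead reactions are those that can carry no flux", {
  md <- toy_variants("dead")
  dead <- find_dead_reactions(md)
  expect_equal(md$reaction_ids[dead], "DED")
  expect_length(find_dead_reactions(toy_redox_model()), 0)
  # zero-width bounds force membership
  m0 <- toy_redox_model()
  m0$lb[3] <- 0; m0$ub[3] <- 0
  expect_true(3 %in% find_dead_reactions(m0))
})

test_that("unbranched pairs lump into an equivalent composite", {
  ml <- toy_variants("lumpable")
  lu <- lump_unbranched(ml)
  expect_length(lu$map$lump_groups, 1)
  expect_setequal(lu$map$lump_groups[[1]], c("GRW1", "GRW2"))
  # composite column behaves exactly like the original GRW reaction
  m0 <- toy_redox_model()
  comp <- which(lengths(lu$model$orig_ids) > 1)
  expect_length(comp, 1)
  for (ko_orig in list(integer(0), "RSP", c("RSP", "ALT"))) {
    ko0 <- match(ko_orig, m0$reaction_ids)
    ko1 <- match(ko_orig, lu$model$reaction_ids)
    expect_equal(as.numeric(fba_max_growth(lu$model, ko1)),
                 as.numeric(fba_max_growth(m0, ko0)), tolerance = 1e-6)
  }
  # knocking out the composite equals knocking out GRW in the original
  expect_equal(as.numeric(fba_max_growth(lu$model, comp)),
               as.numeric(fba_max_growth(m0, 2L)), tolerance = 1e-6)
})

test_that("the toy model itself has nothing to lump", {
  lu <- lump_unbranched(toy_redox_model())
  expect_length(lu$map$lump_groups, 0)
  expect_equal(length(lu$model$reaction_ids), 7L)
})

test_that("a chain of unary reactions lumps into one composite", {
  # A -> u1 -> u2 -> B chain replacing ALT
  S <- matrix(0, 6, 9, dimnames = list(
    c("A", "B", "N", "P", "U1", "U2"),
    c("SRC", "GRW", "C1", "C2", "C3", "BIO", "RSP", "PRD", "EXP")))
  S["A", "SRC"] <- 1
  S["A", "GRW"] <- -1; S["B", "GRW"] <- 1; S["N", "GRW"] <- 1
  S["A", "C1"] <- -1; S["U1", "C1"] <- 1
  S["U1", "C2"] <- -1; S["U2", "C2"] <- 1
  S["U2", "C3"] <- -1; S["B", "C3"] <- 1
  S["B", "BIO"] <- -1; S["N", "RSP"] <- -1
  S["A", "PRD"] <- -1; S["N", "PRD"] <- -1; S["P", "PRD"] <- 1
  S["P", "EXP"] <- -1
  m <- metabolic_model(rownames(S), colnames(S), S,
                       lb = rep(0, 9),
                       ub = c(10, 1000, 2, 1000, 1000, 1000, 1000, 1000, 1000),
                       objective_index = 6, target_index = 9,
                       gene_associated = c(FALSE, TRUE, TRUE, TRUE, TRUE,
                                           FALSE, TRUE, TRUE, FALSE))
  lu <- lump_unbranched(m)
  expect_length(lu$map$lump_groups, 1)
  expect_setequal(lu$map$lump_groups[[1]], c("C1", "C2", "C3"))
  expect_equal(as.numeric(fba_max_growth(lu$model)), 10, tolerance = 1e-6)
})

test_that("essentiality screens leave exactly the spec'd toy targets", {
  m <- toy_redox_model()
  cs <- screen_essentials(m, min_growth_frac = 0.01)
  expect_setequal(vapply(cs$targets, function(t) t$label, ""),
                  c("ALT", "RSP"))
  why <- stats::setNames(cs$excluded$reason, cs$excluded$reaction)
  expect_equal(why[["SRC"]], "exchange")
  expect_equal(why[["EXP"]], "target")
  expect_equal(why[["BIO"]], "objective")
  expect_equal(why[["GRW"]], "synthesis-essential")
  expect_equal(why[["PRD"]], "synthesis-essential")
  # a stricter viability cut also drops RSP (mu* = 6 < 0.7 * 10)
  cs2 <- screen_essentials(m, min_growth_frac = 0.7)
  expect_setequal(vapply(cs2$targets, function(t) t$label, ""), "ALT")
  expect_equal(cs2$excluded$reason[cs2$excluded$reaction == "RSP"],
               "growth-essential")
})

test_that("maintenance-like reactions with lb > 0 are never candidates", {
  m <- toy_redox_model()
  m$lb[3] <- 0.5  # ALT now carries obligatory flux
  cs <- screen_essentials(m, min_growth_frac = 0.01)
  expect_equal(cs$excluded$reason[cs$excluded$reaction == "ALT"],
               "fixed-flux")
})

test_that("gene-association and user exclusion filters work", {
  m <- toy_redox_model()
  m$gene_associated[3] <- FALSE  # ALT gene-less
  cs <- screen_essentials(m, gene_assoc_only = TRUE)
  expect_setequal(vapply(cs$targets, function(t) t$label, ""), "RSP")
  cs2 <- screen_essentials(toy_redox_model(), user_exclude = "ALT")
  expect_setequal(vapply(cs2$targets, function(t) t$label, ""), "RSP")
})

test_that("build_search_space composes dead -> lump -> essentials", {
  mc <- toy_variants("combined")
  ss <- build_search_space(mc)
  expect_equal(ss$map$dropped, "DED")
  expect_length(ss$map$lump_groups, 1)
  expect_setequal(ss$map$lump_groups[[1]], c("GRW1", "GRW2"))
  expect_setequal(vapply(ss$candidates$targets, function(t) t$label, ""),
                  c("ALT", "RSP"))
  # the lumped growth pathway is excluded as synthesis-essential
  expect_true("GRW1+GRW2" %in%
                ss$candidates$excluded$reaction[
                  ss$candidates$excluded$reason == "synthesis-essential"])
})

test_that("build_search_space is idempotent", {
  ss <- build_search_space(toy_variants("combined"))
  ss2 <- build_search_space(ss$model)
  expect_equal(ss2$model[names(ss$model)], ss$model[names(ss$model)])
  expect_equal(length(ss2$candidates$targets), length(ss$candidates$targets))
  expect_length(ss2$map$dropped, 0)
  expect_length(ss2$map$lump_groups, 0)
})

test_that("reduction preserves all three objectives for expressible designs", {
  cfg <- search_config(tau = 0, n_env = 20)
  for (variant in c("dead", "lumpable", "combined")) {
    orig <- toy_variants(variant)
    ss <- build_search_space(orig)
    nt <- length(ss$candidates$targets)
    subsets <- list(integer(0))
    for (k in seq_len(nt))
      subsets <- c(subsets, lapply(asplit(utils::combn(nt, k), 2), as.integer))
    for (d in subsets) {
      cols_red <- vapply(ss$candidates$targets[d], function(t) t$column, 0L)
      ids_orig <- expand_composites(d, ss$candidates)
      cols_orig <- match(ids_orig, orig$reaction_ids)
      f_red <- evaluate_design(ss$model, cols_red, cfg)
      f_orig <- evaluate_design(orig, cols_orig, cfg)
      expect_equal(f_red$growth, f_orig$growth, tolerance = 1e-6,
                   info = variant)
      expect_equal(f_red$product, f_orig$product, tolerance = 1e-6,
                   info = variant)
      expect_equal(f_red$coupling, f_orig$coupling, tolerance = 1e-6,
                   info = variant)
    }
  }
})
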