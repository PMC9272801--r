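# Synthetic fixture models with known coupling structure.  All fluxes are
# round numbers so every optimum can be checked against a hand-worked LP.

toy_reactions <- function() {
  # SRC: -> A [0,10];  GRW: A -> B + N;  ALT: A -> B [0,2];
  # BIO: B -> (objective);  RSP: N -> ;  PRD: A + N -> P;  EXP: P -> (target)
  list(
    SRC = list(mets = c(A = 1), lb = 0, ub = 10, gene = FALSE),
    GRW = list(mets = c(A = -1, B = 1, N = 1), lb = 0, ub = 1000, gene = TRUE),
    ALT = list(mets = c(A = -1, B = 1), lb = 0, ub = 2, gene = TRUE),
    BIO = list(mets = c(B = -1), lb = 0, ub = 1000, gene = FALSE),
    RSP = list(mets = c(N = -1), lb = 0, ub = 1000, gene = TRUE),
    PRD = list(mets = c(A = -1, N = -1, P = 1), lb = 0, ub = 1000, gene = TRUE),
    EXP = list(mets = c(P = -1), lb = 0, ub = 1000, gene = FALSE)
  )
}

build_fixture <- function(rxns, objective, target, id) {
  met_ids <- sort(unique(unlist(lapply(rxns, function(r) names(r$mets)))))
  nr <- length(rxns)
  S <- matrix(0, length(met_ids), nr,
              dimnames = list(met_ids, names(rxns)))
  for (j in seq_len(nr)) S[names(rxns[[j]]$mets), j] <- rxns[[j]]$mets
  metabolic_model(met_ids, names(rxns), S,
                  lb = vapply(rxns, function(r) r$lb, 0),
                  ub = vapply(rxns, function(r) r$ub, 0),
                  objective_index = match(objective, names(rxns)),
                  target_index = match(target, names(rxns)),
                  gene_associated = vapply(rxns, function(r) r$gene, TRUE),
                  id = id)
}

#' Toy redox-coupling model
#'
#' A seven-reaction network embodying the redox-balance mechanism of
#' growth coupling: substrate A feeds growth either through `GRW`
#' (A -> B + N, producing the cofactor N) or through the bypass `ALT`
#' (A -> B, capacity 2); N is re-oxidized by respiration `RSP` or by
#' product synthesis `PRD` (A + N -> P). Knocking out `RSP` forces
#' every unit of `GRW` flux to drive synthesis (weak coupling);
#' additionally knocking out `ALT` makes synthesis proportional to
#' growth (strong coupling). Wild-type maximum growth is 10/h; maximum
#' product flux is 5.
#'
#' @return a [metabolic_model()] with objective `BIO` and target `EXP`.
#' @export
toy_redox_model <- function() {
  build_fixture(toy_reactions(), objective = "BIO", target = "EXP",
                id = "toy_redox")
}

#' Toy model variants exercising the reduction rules
#'
#' * `dead`: adds `DED: X -> Y` where X and Y occur nowhere else, so
#'   steady state forces zero flux.
#' * `lumpable`: splits `GRW` into `GRW1: A -> M + N` and `GRW2: M -> B`
#'   with intermediate M unique to the pair, so the two lump into one
#'   composite equivalent to the original `GRW`.
#' * `combined`: both modifications.
#'
#' @param which one of `"dead"`, `"lumpable"`, `"combined"`.
#' @return a [metabolic_model()].
#' @export
toy_variants <- function(which = c("dead", "lumpable", "combined")) {
  which <- match.arg(which)
  rxns <- toy_reactions()
  if (which %in% c("lumpable", "combined")) {
    rxns <- rxns[setdiff(names(rxns), "GRW")]
    rxns <- append(rxns,
                   list(GRW1 = list(mets = c(A = -1, M = 1, N = 1),
                                    lb = 0, ub = 1000, gene = TRUE),
                        GRW2 = list(mets = c(M = -1, B = 1),
                                    lb = 0, ub = 1000, gene = FALSE)),
                   after = 1)
  }
  if (which %in% c("dead", "combined"))
    rxns$DED <- list(mets = c(X = -1, Y = 1), lb = 0, ub = 1000, gene = TRUE)
  build_fixture(rxns, objective = "BIO", target = "EXP",
                id = paste0("toy_", which))
}

#' Seeded family of random branched coupling models
#'
#' Generates a small network of `n_branches` parallel growth pathways
#' sharing substrate A and, for a random subset of branches, producing a
#' cofactor N (at `cofactor_ratio` units per unit flux). N is drained by
#' a closable respiration sink `RSP` or by product synthesis
#' `PRD: A + N -> P`. Branch capacities are random round numbers, so the
#' coupled/uncoupled structure varies across seeds while exhaustive
#' enumeration of small knockout sets stays feasible. The same seed
#' always yields the identical model.
#'
#' @param n_branches number of parallel growth pathways (>= 1).
#' @param cofactor_ratio cofactor units produced per unit of
#'   cofactor-producing branch flux; 0 makes synthesis impossible for
#'   every design.
#' @param seed RNG seed.
#' @return a [metabolic_model()] with objective `BIO` and target `EXP`.
#' @export
random_coupling_family <- function(n_branches = 3, cofactor_ratio = 1,
                                   seed = 1) {
  stopifnot(n_branches >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rxns <- list(SRC = list(mets = c(A = 1), lb = 0, ub = 10, gene = FALSE))
  caps <- sample(c(2, 4, 6, 1000), n_branches, replace = TRUE)
  makes_n <- if (n_branches == 1) TRUE else
    c(TRUE, stats::runif(n_branches - 1) < 0.5)  # branch 1 always cofactor-linked
  for (i in seq_len(n_branches)) {
    mets <- c(A = -1, B = 1)
    if (makes_n[i] && cofactor_ratio > 0)
      mets <- c(mets, N = cofactor_ratio)
    rxns[[paste0("GRW", i)]] <-
      list(mets = mets, lb = 0, ub = caps[i], gene = TRUE)
  }
  rxns$BIO <- list(mets = c(B = -1), lb = 0, ub = 1000, gene = FALSE)
  rxns$RSP <- list(mets = c(N = -1), lb = 0, ub = 1000, gene = TRUE)
  rxns$PRD <- list(mets = c(A = -1, N = -1, P = 1), lb = 0, ub = 1000,
                   gene = TRUE)
  rxns$EXP <- list(mets = c(P = -1), lb = 0, ub = 1000, gene = FALSE)
  build_fixture(rxns, objective = "BIO", target = "EXP",
                id = sprintf("coupling_family_b%d_s%d", n_branches, seed))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
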