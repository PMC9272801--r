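# Model reduction: dead-reaction removal, lumping of unbranched pathways,
# and essentiality screening.  The product is the knockout search space.

# Environment exchanges: boundary (single-metabolite) reactions with no
# gene association.  These encode the medium/assay, not genetics, and are
# never knockout candidates nor lumping partners.  Gene-associated
# single-metabolite reactions (e.g. a respiration sink for a cofactor)
# are genuine enzymatic steps and remain in the design space.
env_exchange <- function(model) model$exchange_flags & !model$gene_associated

#' Find dead reactions under the configured medium
#'
#' A reaction is dead when its flux variability (growth unconstrained) is
#' confined to zero: both its minimum and maximum achievable flux are
#' within 1e-6 of 0. The test is conditional on the current bounds, i.e.
#' on the applied medium.
#'
#' @param model a [metabolic_model()].
#' @return integer vector of dead reaction column indices.
#' @export
find_dead_reactions <- function(model) {
  n <- n_reactions(model)
  dead <- logical(n)
  for (j in seq_len(n)) {
    if (model$lb[j] == 0 && model$ub[j] == 0) { dead[j] <- TRUE; next }
    obj <- numeric(n); obj[j] <- 1
    hi <- solve_lp(model$stoich, model$lb, model$ub, obj, maximize = TRUE)
    if (hi$status == "optimal" && abs(hi$value) > ZERO_TOL) next
    lo <- solve_lp(model$stoich, model$lb, model$ub, obj, maximize = FALSE)
    dead[j] <- (hi$status == "optimal" && lo$status == "optimal" &&
                abs(hi$value) <= ZERO_TOL && abs(lo$value) <= ZERO_TOL)
  }
  which(dead)
}

drop_reactions <- function(model, idx) {
  if (!length(idx)) return(model)
  if (model$objective_index %in% idx)
    stop("cannot drop the biomass objective reaction", call. = FALSE)
  if (!is.na(model$target_index) && model$target_index %in% idx)
    stop("cannot drop the target reaction", call. = FALSE)
  keep <- setdiff(seq_len(n_reactions(model)), idx)
  remap <- match(seq_len(n_reactions(model)), keep)
  metabolic_model(model$metabolite_ids, model$reaction_ids[keep],
                  model$stoich[, keep, drop = FALSE],
                  model$lb[keep], model$ub[keep],
                  objective_index = remap[model$objective_index],
                  target_index = if (is.na(model$target_index)) NA_integer_
                                 else remap[model$target_index],
                  gene_associated = model$gene_associated[keep],
                  orig_ids = model$orig_ids[keep],
                  id = model$id)
}

#' Lump unbranched pathways into composite reactions
#'
#' Iteratively merges internal reaction pairs coupled through a metabolite
#' that participates in exactly two reactions (one producing, one
#' consuming): steady state then fixes their flux ratio, so the pair
#' behaves as a single composite reaction whose knockout means knocking
#' out all members. Merging never involves exchange, biomass or target
#' columns and is skipped when the intersected (rescaled) bounds would be
#' empty. Any design expressible in both models evaluates identically.
#'
#' @param model a [metabolic_model()] with dead reactions already removed.
#' @return list with elements `model` (the lumped model; composite columns
#'   carry all member ids in `orig_ids`) and `map` (a reduction map: list
#'   with `lump_groups`, a list of character vectors of original member
#'   ids, and `dropped`, ids of removed dead reactions — empty here).
#' @export
lump_unbranched <- function(model) {
  input_groups <- vapply(model$orig_ids, function(g)
    paste(sort(g), collapse = "\r"), "")
  repeat {
    S <- model$stoich
    mergeable <- NULL
    protected <- env_exchange(model)
    protected[model$objective_index] <- TRUE
    if (!is.na(model$target_index)) protected[model$target_index] <- TRUE
    for (i in seq_len(n_metabolites(model))) {
      js <- which(S[i, ] != 0)
      if (length(js) != 2 || any(protected[js])) next
      coefs <- S[i, js]
      if (prod(sign(coefs)) >= 0) next  # need one producer, one consumer
      r1 <- js[which(coefs > 0)]; r2 <- js[which(coefs < 0)]
      a <- S[i, r1]; b <- -S[i, r2]
      t <- a / b  # steady state: v2 = t * v1
      lb2 <- max(model$lb[r1], model$lb[r2] / t)
      ub2 <- min(model$ub[r1], model$ub[r2] / t)
      if (lb2 > ub2) next  # bound directions conflict
      mergeable <- list(i = i, r1 = r1, r2 = r2, t = t, lb = lb2, ub = ub2)
      break
    }
    if (is.null(mergeable)) break
    model <- merge_pair(model, mergeable)
  }
  # only groups formed in THIS call, not composites inherited in the input
  out_keys <- vapply(model$orig_ids, function(g)
    paste(sort(g), collapse = "\r"), "")
  new_group <- lengths(model$orig_ids) > 1 & !(out_keys %in% input_groups)
  list(model = model,
       map = list(lump_groups = model$orig_ids[new_group],
                  dropped = character(0)))
}

merge_pair <- function(model, mg) {
  S <- model$stoich
  newcol <- S[, mg$r1] + mg$t * S[, mg$r2]
  newcol[abs(newcol) < 1e-12] <- 0
  S[, mg$r1] <- newcol
  keep <- setdiff(seq_len(n_reactions(model)), mg$r2)
  remap <- match(seq_len(n_reactions(model)), keep)
  ids <- model$reaction_ids
  ids[mg$r1] <- paste(c(model$orig_ids[[mg$r1]], model$orig_ids[[mg$r2]]),
                      collapse = "+")
  orig <- model$orig_ids
  orig[[mg$r1]] <- c(orig[[mg$r1]], orig[[mg$r2]])
  gene <- model$gene_associated
  # one member deletion suffices to zero the whole chain
  gene[mg$r1] <- gene[mg$r1] || gene[mg$r2]
  lb <- model$lb; ub <- model$ub
  lb[mg$r1] <- mg$lb; ub[mg$r1] <- mg$ub
  metabolic_model(model$metabolite_ids, ids[keep], S[, keep, drop = FALSE],
                  lb[keep], ub[keep],
                  objective_index = remap[model$objective_index],
                  target_index = if (is.na(model$target_index)) NA_integer_
                                 else remap[model$target_index],
                  gene_associated = gene[keep], orig_ids = orig[keep],
                  id = model$id)
}

#' Screen out essential single knockouts and build the candidate set
#'
#' Candidate columns are everything except environment exchanges
#' (boundary reactions without gene association), the biomass objective,
#' the target, and reactions whose bounds exclude zero flux
#' (maintenance-like constraints that no deletion can satisfy). Each
#' candidate is knocked out alone; it is excluded when the knockout drops
#' maximum growth below `min_growth_frac` of the wild-type optimum
#' (growth-essential) or makes the maximum product flux zero
#' (synthesis-essential). Reactions without a gene association can
#' optionally be excluded, as can a user-supplied list.
#'
#' @param model a reduced [metabolic_model()] with a resolved target.
#' @param min_growth_frac fraction of wild-type growth below which a
#'   single knockout counts as growth-essential (default 0.01).
#' @param gene_assoc_only exclude reactions without a gene association.
#' @param user_exclude character vector of reaction ids to exclude
#'   (matched against column ids and lumped member ids).
#' @return an object of class `candidate_set`: list with `targets` (a list
#'   of `list(label, column, members, provenance)`) and `excluded` (a
#'   data.frame of reaction label and reason).
#' @export
screen_essentials <- function(model, min_growth_frac = 0.01,
                              gene_assoc_only = FALSE,
                              user_exclude = character(0)) {
  if (is.na(model$target_index))
    stop("model has no resolved target reaction", call. = FALSE)
  mu_wt <- as.numeric(fba_max_growth(model))
  if (mu_wt <= 0)
    stop("wild-type model is infeasible or cannot grow; check the medium",
         call. = FALSE)
  targets <- list()
  excl_lab <- character(0); excl_why <- character(0)
  exclude <- function(lab, why) {
    excl_lab <<- c(excl_lab, lab); excl_why <<- c(excl_why, why)
  }
  for (j in seq_len(n_reactions(model))) {
    lab <- model$reaction_ids[j]
    members <- model$orig_ids[[j]]
    if (j == model$objective_index) { exclude(lab, "objective"); next }
    if (j == model$target_index) { exclude(lab, "target"); next }
    if (env_exchange(model)[j]) { exclude(lab, "exchange"); next }
    if (model$lb[j] == 0 && model$ub[j] == 0) { exclude(lab, "dead"); next }
    if (model$lb[j] > 0 || model$ub[j] < 0) { exclude(lab, "fixed-flux"); next }
    if (gene_assoc_only && !model$gene_associated[j]) {
      exclude(lab, "no-gene"); next
    }
    if (length(user_exclude) &&
        (lab %in% user_exclude || any(members %in% user_exclude))) {
      exclude(lab, "user"); next
    }
    mu_ko <- as.numeric(fba_max_growth(model, ko = j))
    if (mu_ko < min_growth_frac * mu_wt) { exclude(lab, "growth-essential"); next }
    p_ko <- as.numeric(max_product(model, ko = j))
    if (p_ko <= ZERO_TOL) { exclude(lab, "synthesis-essential"); next }
    targets[[length(targets) + 1]] <-
      list(label = lab, column = j, members = members,
           provenance = if (length(members) > 1) "lumped" else "single")
  }
  if (!length(targets))
    warning("no knockout candidates survive the essentiality screens",
            call. = FALSE)
  structure(list(targets = targets,
                 excluded = data.frame(reaction = excl_lab, reason = excl_why,
                                       stringsAsFactors = FALSE)),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set> ", length(x$targets), " knockout targets (",
      sum(vapply(x$targets, function(t) t$provenance, "") == "lumped"),
      " lumped), ", nrow(x$excluded), " excluded\n", sep = "")
  invisible(x)
}

#' Build the knockout search space
#'
#' The full pre-processing pipeline: remove dead reactions, lump unbranched
#' pathways, then screen out essential single knockouts. Running it on its
#' own output changes nothing.
#'
#' @param model a [metabolic_model()] with medium applied and target
#'   resolved.
#' @param min_growth_frac,gene_assoc_only,user_exclude passed to
#'   [screen_essentials()].
#' @return list with `model` (the reduced model), `candidates` (a
#'   `candidate_set`) and `map` (reduction map with `lump_groups` and
#'   `dropped` original reaction ids).
#' @export
build_search_space <- function(model, min_growth_frac = 0.01,
                               gene_assoc_only = FALSE,
                               user_exclude = character(0)) {
  dead <- find_dead_reactions(model)
  dead <- setdiff(dead, c(model$objective_index, model$target_index))
  dropped <- unlist(model$orig_ids[dead])
  model2 <- drop_reactions(model, dead)
  lumped <- lump_unbranched(model2)
  candidates <- screen_essentials(lumped$model,
                                  min_growth_frac = min_growth_frac,
                                  gene_assoc_only = gene_assoc_only,
                                  user_exclude = user_exclude)
  list(model = lumped$model, candidates = candidates,
       map = list(lump_groups = lumped$map$lump_groups,
                  dropped = as.character(dropped)))
}
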