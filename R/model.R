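#' Construct a constraint-based metabolic model
#'
#' The central container of the package: a stoichiometric network with flux
#' bounds, a biomass objective and (optionally) a product exchange target.
#' Fluxes are in mmol/gDW/h; the biomass flux is in 1/h.
#'
#' @param metabolite_ids character vector of metabolite identifiers.
#' @param reaction_ids character vector of reaction identifiers.
#' @param stoich stoichiometric coefficient matrix, metabolites x reactions
#'   (dense or any [Matrix::Matrix]); stored sparse.
#' @param lb,ub numeric per-reaction flux bounds. Non-finite or very large
#'   values are capped to `bound_cap` so every LP stays bounded.
#' @param objective_index column index of the biomass reaction.
#' @param target_index column index of the product exchange reaction, or
#'   `NA` if not yet resolved (see [resolve_target()]).
#' @param gene_associated logical per-reaction flag: reaction has a gene
#'   association (gene-level rules are not parsed beyond this flag).
#' @param orig_ids list of character vectors mapping each column to the
#'   reaction ids of the unreduced model it represents (used by the model
#'   reduction step; defaults to each reaction's own id).
#' @param id model identifier.
#' @param bound_cap magnitude at which bounds are capped (default 1000,
#'   the conventional "unbounded" flux value in constraint-based models).
#'
#' @return An object of class `metabolic_model`: a list with the fields
#'   above plus `exchange_flags` (TRUE for columns touching exactly one
#'   metabolite, i.e. boundary exchange/demand reactions).
#' @export
metabolic_model <- function(metabolite_ids, reaction_ids, stoich, lb, ub,
                            objective_index, target_index = NA_integer_,
                            gene_associated = NULL, orig_ids = NULL,
                            id = "model", bound_cap = 1000) {
  stoich <- methods::as(methods::as(Matrix::Matrix(stoich, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  dimnames(stoich) <- list(as.character(metabolite_ids),
                           as.character(reaction_ids))
  if (is.null(gene_associated)) gene_associated <- rep(FALSE, length(reaction_ids))
  if (is.null(orig_ids)) orig_ids <- as.list(reaction_ids)
  orig_ids <- unname(lapply(orig_ids, as.character))
  lb <- unname(pmax(as.numeric(lb), -bound_cap))
  ub <- unname(pmin(as.numeric(ub), bound_cap))
  gene_associated <- unname(as.logical(gene_associated))
  m <- structure(list(
    id = id,
    metabolite_ids = as.character(metabolite_ids),
    reaction_ids = as.character(reaction_ids),
    stoich = stoich,
    lb = lb,
    ub = ub,
    objective_index = as.integer(objective_index),
    target_index = as.integer(target_index),
    gene_associated = as.logical(gene_associated),
    exchange_flags = compute_exchange_flags(stoich),
    orig_ids = orig_ids
  ), class = "metabolic_model")
  validate_model(m)
  m
}

compute_exchange_flags <- function(stoich) {
  unname(Matrix::colSums(stoich != 0) == 1)
}

#' Validate a metabolic model's structural invariants
#'
#' Checks dimensions, bound ordering and finiteness, objective/target index
#' validity, and consistency of the exchange flags with the stoichiometry.
#' Errors with an informative message on the first violation.
#'
#' @param model a [metabolic_model()].
#' @return `model`, invisibly.
#' @export
validate_model <- function(model) {
  with(model, {
    if (nrow(stoich) != length(metabolite_ids))
      stop("stoichiometry has ", nrow(stoich), " rows but ",
           length(metabolite_ids), " metabolite ids", call. = FALSE)
    if (ncol(stoich) != length(reaction_ids))
      stop("stoichiometry has ", ncol(stoich), " columns but ",
           length(reaction_ids), " reaction ids", call. = FALSE)
    if (length(lb) != ncol(stoich) || length(ub) != ncol(stoich))
      stop("bound vectors must have one entry per reaction", call. = FALSE)
    bad <- which(lb > ub)
    if (length(bad))
      stop("lb > ub for reaction(s): ",
           paste(reaction_ids[bad], collapse = ", "), call. = FALSE)
    if (any(!is.finite(lb)) || any(!is.finite(ub)))
      stop("non-finite flux bounds after capping", call. = FALSE)
    if (is.na(objective_index) || objective_index < 1 ||
        objective_index > ncol(stoich))
      stop("objective_index is not a valid reaction column", call. = FALSE)
    if (!is.na(target_index)) {
      if (target_index < 1 || target_index > ncol(stoich))
        stop("target_index is not a valid reaction column", call. = FALSE)
      if (target_index == objective_index)
        stop("target reaction must differ from the biomass objective",
             call. = FALSE)
    }
    if (anyDuplicated(reaction_ids))
      stop("duplicate reaction ids", call. = FALSE)
    if (anyDuplicated(metabolite_ids))
      stop("duplicate metabolite ids", call. = FALSE)
  })
  flags <- compute_exchange_flags(model$stoich)
  if (!identical(as.logical(flags), as.logical(model$exchange_flags)))
    stop("exchange_flags inconsistent with stoichiometry", call. = FALSE)
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model>", x$id, "\n")
  cat("  metabolites:", length(x$metabolite_ids),
      " reactions:", length(x$reaction_ids),
      " exchanges:", sum(x$exchange_flags), "\n")
  cat("  objective:", x$reaction_ids[x$objective_index], "\n")
  cat("  target:", if (is.na(x$target_index)) "<unresolved>" else
    x$reaction_ids[x$target_index], "\n")
  invisible(x)
}

n_reactions <- function(model) length(model$reaction_ids)

n_metabolites <- function(model) length(model$metabolite_ids)

# Index lookup with an informative error.
rxn_index <- function(model, id) {
  i <- match(id, model$reaction_ids)
  if (anyNA(i))
    stop("unknown reaction id(s): ", paste(id[is.na(i)], collapse = ", "),
         call. = FALSE)
  i
}
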