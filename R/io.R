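#' Read a constraint-based model from SBML or JSON
#'
#' Supports SBML Level 3 with the `fbc` package (flux bounds and objective
#' read from the fbc annotations) and the COBRA-community JSON dialect
#' (`metabolites`/`reactions` arrays with `lower_bound`, `upper_bound`,
#' `objective_coefficient`, `gene_reaction_rule`). Conventional `M_`/`R_`
#' SBML id prefixes are stripped so ids match across the two formats.
#' Bounds are capped to +/-1000.
#'
#' @param path file path.
#' @param format `"auto"` (by extension: `.xml`/`.sbml` vs `.json`),
#'   `"sbml"` or `"json"`.
#' @return a [metabolic_model()] (its `target_index` is unresolved; see
#'   [resolve_target()]).
#' @export
load_model <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xml = , sbml = "sbml", json = "json",
                     stop("cannot infer model format from extension '.", ext,
                          "'; pass format=", call. = FALSE))
  }
  switch(format, sbml = read_model_sbml(path), json = read_model_json(path))
}

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("JSON parse failure in ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  for (f in c("metabolites", "reactions"))
    if (is.null(doc[[f]]))
      stop("JSON model lacks required field '", f, "'", call. = FALSE)
  met_ids <- vapply(doc$metabolites, function(m) as.character(m$id), "")
  rxns <- doc$reactions
  rxn_ids <- vapply(rxns, function(r) as.character(r$id), "")
  nm <- length(met_ids); nr <- length(rxn_ids)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(nr)) {
    mets <- rxns[[j]]$metabolites
    if (length(mets)) {
      ri <- match(names(mets), met_ids)
      if (anyNA(ri))
        stop("reaction ", rxn_ids[j], " references unknown metabolite(s): ",
             paste(names(mets)[is.na(ri)], collapse = ", "), call. = FALSE)
      ii <- c(ii, ri); jj <- c(jj, rep(j, length(ri)))
      xx <- c(xx, vapply(mets, as.numeric, 0))
    }
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nm, nr))
  num_or <- function(v, d) if (is.null(v)) d else as.numeric(v)
  lb <- vapply(rxns, function(r) num_or(r$lower_bound, -1000), 0)
  ub <- vapply(rxns, function(r) num_or(r$upper_bound, 1000), 0)
  ocoef <- vapply(rxns, function(r) num_or(r$objective_coefficient, 0), 0)
  gpr <- vapply(rxns, function(r)
    if (is.null(r$gene_reaction_rule)) "" else as.character(r$gene_reaction_rule), "")
  obj <- which(ocoef != 0)
  if (length(obj) == 0)
    stop("model declares no objective reaction", call. = FALSE)
  if (length(obj) > 1)
    stop("multiple objective reactions are not supported: ",
         paste(rxn_ids[obj], collapse = ", "), call. = FALSE)
  metabolic_model(met_ids, rxn_ids, S, lb, ub, objective_index = obj,
                  gene_associated = nzchar(gpr),
                  id = if (is.null(doc$id)) "model" else as.character(doc$id))
}

strip_sbml_prefix <- function(ids, prefix) {
  has <- startsWith(ids, prefix)
  if (all(has)) substring(ids, nchar(prefix) + 1) else ids
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  ns <- c(s = xml2::xml_ns(doc)[["d1"]],
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp)) stop("SBML model has no species", call. = FALSE)
  sp_id <- xml2::xml_attr(sp, "id")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx)) stop("SBML model has no reactions", call. = FALSE)
  rx_id <- xml2::xml_attr(rx, "id")
  nm <- sum(!boundary); nr <- length(rx)
  met_keep <- sp_id[!boundary]
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  lb <- numeric(nr); ub <- numeric(nr); gene <- logical(nr)
  for (j in seq_len(nr)) {
    node <- rx[[j]]
    for (side in c(-1, 1)) {
      refs <- xml2::xml_find_all(node, if (side < 0)
        "./s:listOfReactants/s:speciesReference" else
        "./s:listOfProducts/s:speciesReference", ns)
      if (!length(refs)) next
      sids <- xml2::xml_attr(refs, "species")
      coef <- side * as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      keep <- sids %in% met_keep
      ri <- match(sids[keep], met_keep)
      ii <- c(ii, ri); jj <- c(jj, rep(j, sum(keep))); xx <- c(xx, coef[keep])
    }
    lbref <- xml2::xml_attr(node, "lowerFluxBound")
    ubref <- xml2::xml_attr(node, "upperFluxBound")
    rev <- xml2::xml_attr(node, "reversible") %in% "true"
    lb[j] <- if (!is.na(lbref) && lbref %in% names(pval)) pval[[lbref]]
             else if (rev) -1000 else 0
    ub[j] <- if (!is.na(ubref) && ubref %in% names(pval)) pval[[ubref]]
             else 1000
    gene[j] <- length(xml2::xml_find_first(node, "./fbc:geneProductAssociation",
                                           ns)) > 0 &&
      !inherits(xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns),
                "xml_missing")
  }
  # collapse duplicated (metabolite, reaction) entries by summation
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nm, nr))
  fobj <- xml2::xml_find_all(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (!length(fobj))
    stop("SBML model declares no fbc objective", call. = FALSE)
  obj_rxn <- xml2::xml_attr(fobj, "reaction")[1]
  obj <- match(obj_rxn, rx_id)
  if (is.na(obj)) stop("fbc objective references unknown reaction ", obj_rxn,
                       call. = FALSE)
  mid <- xml2::xml_attr(xml2::xml_find_first(doc, ".//s:model", ns), "id")
  metabolic_model(strip_sbml_prefix(met_keep, "M_"),
                  strip_sbml_prefix(rx_id, "R_"),
                  S, lb, ub, objective_index = obj, gene_associated = gene,
                  id = if (is.na(mid)) "model" else mid)
}

#' Write a model to SBML or JSON
#'
#' Serializes to the same dialects [load_model()] reads; `load_model()`
#' applied to the written file reproduces the model field-for-field.
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @param format `"auto"` (by extension), `"sbml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xml = , sbml = "sbml", json = "json",
                     stop("cannot infer format from extension", call. = FALSE))
  }
  validate_model(model)
  if (format == "json") write_model_json(model, path)
  else write_model_sbml(model, path)
  invisible(path)
}

write_model_json <- function(model, path) {
  S <- model$stoich
  rxns <- lapply(seq_len(n_reactions(model)), function(j) {
    col <- S[, j]
    nz <- which(col != 0)
    r <- list(id = model$reaction_ids[j],
              metabolites = as.list(stats::setNames(col[nz],
                                                    model$metabolite_ids[nz])),
              lower_bound = model$lb[j],
              upper_bound = model$ub[j],
              gene_reaction_rule = if (model$gene_associated[j])
                paste0("g_", model$reaction_ids[j]) else "")
    if (j == model$objective_index) r$objective_coefficient <- 1
    r
  })
  doc <- list(metabolites = lapply(model$metabolite_ids,
                                   function(m) list(id = m, compartment = "c")),
              reactions = rxns,
              genes = list(),
              id = model$id,
              compartments = list(c = "cytosol"),
              version = "1")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

write_model_sbml <- function(model, path) {
  S <- model$stoich
  num <- function(x) format(x, scientific = FALSE, trim = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false">')
  w('  <model id="', xml_escape(model$id), '" fbc:strict="true">')
  w('    <listOfCompartments>')
  w('      <compartment id="c" constant="true"/>')
  w('    </listOfCompartments>')
  w('    <listOfSpecies>')
  for (m in model$metabolite_ids)
    w('      <species id="M_', xml_escape(m),
      '" compartment="c" hasOnlySubstanceUnits="false" ',
      'boundaryCondition="false" constant="false"/>')
  w('    </listOfSpecies>')
  w('    <listOfParameters>')
  for (j in seq_len(n_reactions(model))) {
    rid <- xml_escape(model$reaction_ids[j])
    w('      <parameter id="R_', rid, '_lb" value="', num(model$lb[j]),
      '" constant="true"/>')
    w('      <parameter id="R_', rid, '_ub" value="', num(model$ub[j]),
      '" constant="true"/>')
  }
  w('    </listOfParameters>')
  w('    <listOfReactions>')
  gene_ids <- character(0)
  for (j in seq_len(n_reactions(model))) {
    rid <- xml_escape(model$reaction_ids[j])
    col <- S[, j]
    nz <- which(col != 0)
    w('      <reaction id="R_', rid, '" reversible="',
      if (model$lb[j] < 0) "true" else "false",
      '" fast="false" fbc:lowerFluxBound="R_', rid,
      '_lb" fbc:upperFluxBound="R_', rid, '_ub">')
    if (model$gene_associated[j]) {
      g <- paste0("G_g_", rid)
      gene_ids <- c(gene_ids, g)
      w('        <fbc:geneProductAssociation>')
      w('          <fbc:geneProductRef fbc:geneProduct="', g, '"/>')
      w('        </fbc:geneProductAssociation>')
    }
    react <- nz[col[nz] < 0]; prod <- nz[col[nz] > 0]
    if (length(react)) {
      w('        <listOfReactants>')
      for (i in react)
        w('          <speciesReference species="M_',
          xml_escape(model$metabolite_ids[i]), '" stoichiometry="',
          num(-col[i]), '" constant="true"/>')
      w('        </listOfReactants>')
    }
    if (length(prod)) {
      w('        <listOfProducts>')
      for (i in prod)
        w('          <speciesReference species="M_',
          xml_escape(model$metabolite_ids[i]), '" stoichiometry="',
          num(col[i]), '" constant="true"/>')
      w('        </listOfProducts>')
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
  w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  w('        <fbc:listOfFluxObjectives>')
  w('          <fbc:fluxObjective fbc:reaction="R_',
    xml_escape(model$reaction_ids[model$objective_index]),
    '" fbc:coefficient="1"/>')
  w('        </fbc:listOfFluxObjectives>')
  w('      </fbc:objective>')
  w('    </fbc:listOfObjectives>')
  if (length(gene_ids)) {
    w('    <fbc:listOfGeneProducts>')
    for (g in unique(gene_ids))
      w('      <fbc:geneProduct fbc:id="', g, '" fbc:label="', g, '"/>')
    w('    </fbc:listOfGeneProducts>')
  }
  w('  </model>')
  w('</sbml>')
}

#' Read a medium definition from a TSV file
#'
#' Expected columns (with header): `exchange_id`, `lb`, `ub`.
#'
#' @param path TSV file path.
#' @return a data.frame suitable for [apply_medium()].
#' @export
read_medium <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("exchange_id", "lb", "ub")
  if (!all(need %in% names(tab)))
    stop("medium file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab[need]
}

# TRUE for exchange columns that can currently import their metabolite:
# standard orientation (coef < 0, metabolite -> outside) imports at
# negative flux; reversed orientation (coef > 0) imports at positive flux.
uptake_capable <- function(model) {
  out <- logical(n_reactions(model))
  for (j in which(model$exchange_flags)) {
    coef <- model$stoich[which(model$stoich[, j] != 0), j]
    out[j] <- if (coef < 0) model$lb[j] < 0 else model$ub[j] > 0
  }
  out
}

#' Apply a growth-medium definition to a model
#'
#' Sets the bounds of each listed exchange reaction and, by default, closes
#' the uptake direction of every unlisted exchange (minimal-medium
#' semantics); secretion directions are untouched.
#'
#' @param model a [metabolic_model()].
#' @param medium data.frame with columns `exchange_id`, `lb`, `ub` (see
#'   [read_medium()]); may have zero rows.
#' @param close_unlisted if `TRUE` (default), unlisted uptake-capable
#'   exchanges have their uptake direction closed.
#' @return the modified model.
#' @export
apply_medium <- function(model, medium, close_unlisted = TRUE) {
  idx <- integer(0)
  if (nrow(medium)) {
    idx <- rxn_index(model, medium$exchange_id)
    bad <- !model$exchange_flags[idx]
    if (any(bad))
      stop("medium entries are not exchange reactions: ",
           paste(medium$exchange_id[bad], collapse = ", "), call. = FALSE)
  }
  if (close_unlisted) {
    close_idx <- setdiff(which(uptake_capable(model)), idx)
    for (j in close_idx) {
      coef <- model$stoich[which(model$stoich[, j] != 0), j]
      if (coef < 0) model$lb[j] <- max(model$lb[j], 0)
      else model$ub[j] <- min(model$ub[j], 0)
    }
  }
  if (length(idx)) {
    model$lb[idx] <- pmax(as.numeric(medium$lb), -1000)
    model$ub[idx] <- pmin(as.numeric(medium$ub), 1000)
  }
  validate_model(model)
  model
}

#' Resolve a target metabolite or reaction to an exchange-reaction index
#'
#' A reaction id must name an exchange (or demand) reaction and resolves to
#' itself. A metabolite id resolves to the unique exchange touching it; if
#' the metabolite has no exchange, a demand reaction (`metabolite -> `,
#' bounds `[0, 1000]`) can be appended with `add_demand = TRUE` (never
#' silently).
#'
#' @param model a [metabolic_model()].
#' @param id metabolite or reaction identifier.
#' @param add_demand append a demand reaction for an exchange-less
#'   metabolite.
#' @return the model with `target_index` set (and possibly one appended
#'   demand reaction).
#' @export
resolve_target <- function(model, id, add_demand = FALSE) {
  j <- match(id, model$reaction_ids)
  if (!is.na(j)) {
    if (!model$exchange_flags[j])
      stop("target reaction ", id, " is not an exchange/demand reaction",
           call. = FALSE)
    model$target_index <- as.integer(j)
    validate_model(model)
    return(model)
  }
  i <- match(id, model$metabolite_ids)
  if (is.na(i))
    stop("'", id, "' matches no reaction or metabolite id", call. = FALSE)
  # candidate exchanges are environment boundary reactions: single
  # metabolite, no gene association, and not the biomass drain
  cand <- which(model$exchange_flags & !model$gene_associated &
                  model$stoich[i, ] != 0)
  cand <- setdiff(cand, model$objective_index)
  if (length(cand) == 1) {
    model$target_index <- as.integer(cand)
  } else if (length(cand) > 1) {
    stop("metabolite ", id, " has multiple candidate exchanges: ",
         paste(model$reaction_ids[cand], collapse = ", "),
         "; pass the reaction id instead", call. = FALSE)
  } else if (add_demand) {
    dm_id <- paste0("DM_", id)
    S <- cbind(model$stoich,
               Matrix::sparseMatrix(i = i, j = 1, x = -1,
                                    dims = c(n_metabolites(model), 1)))
    model <- metabolic_model(model$metabolite_ids,
                             c(model$reaction_ids, dm_id), S,
                             c(model$lb, 0), c(model$ub, 1000),
                             objective_index = model$objective_index,
                             target_index = ncol(S),
                             gene_associated = c(model$gene_associated, FALSE),
                             orig_ids = c(model$orig_ids, list(dm_id)),
                             id = model$id)
    return(model)
  } else {
    stop("metabolite ", id, " has no exchange reaction; ",
         "use add_demand = TRUE to append a demand reaction", call. = FALSE)
  }
  validate_model(model)
  model
}
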