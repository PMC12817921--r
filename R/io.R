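# Model I/O: a cobrapy-compatible JSON dialect and SBML Level 3 with the
# FBC version 2 extension. Both round-trip the documented field set:
# metabolite/reaction ids, names, stoichiometry, bounds, GPR structure,
# formulas, charges, compartments, the objective, and the spontaneous flag
# (encoded as a reaction annotation).

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
PANMET_NS <- "https://panmet.invalid/sbml"

assert_sid <- function(ids, what) {
  bad <- ids[!grepl("^[A-Za-z_][A-Za-z0-9_]*$", ids)]
  if (length(bad)) {
    stop(what, " ids not valid SBML identifiers: ", paste(bad, collapse = ", "))
  }
  invisible(ids)
}

#' Read or write a metabolic model
#'
#' `read_model()` and `write_model()` dispatch on the file extension:
#' `.json` uses the JSON dialect (compatible with the cobrapy JSON schema),
#' `.xml`/`.sbml` uses SBML Level 3 + FBC v2. The spontaneous flag is stored
#' as the reaction annotation `spontaneous` in JSON and as a custom
#' annotation element in SBML.
#'
#' @param path File path ending in `.json`, `.xml`, or `.sbml`.
#' @param model A `metabolic_model` (for `write_model`).
#' @return `read_model()` returns a `metabolic_model`; `write_model()`
#'   returns `path` invisibly.
#' @export
read_model <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = read_model_json(path),
    xml = ,
    sbml = read_model_sbml(path),
    stop("unknown model format: .", ext)
  )
}

#' @rdname read_model
#' @export
write_model <- function(model, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = write_model_json(model, path),
    xml = ,
    sbml = write_model_sbml(model, path),
    stop("unknown model format: .", ext)
  )
  invisible(path)
}

# ---- JSON dialect -----------------------------------------------------------

write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    purrr::compact(
      list(id = m$id, name = m$name, compartment = m$compartment,
           formula = m$formula, charge = if (is.na(m$charge)) NULL else m$charge)
    )
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    ann <- r$annotations[[1L]]
    if (isTRUE(r$spontaneous)) ann$spontaneous <- TRUE
    g <- r$gpr[[1L]]
    purrr::compact(
      list(id = r$id, name = r$name,
           metabolites = as.list(r$stoich[[1L]]),
           lower_bound = r$lower, upper_bound = r$upper,
           gene_reaction_rule = if (gpr_is_unsat(g)) "" else gpr_serialize(g),
           objective_coefficient =
             if (!is.na(model$objective) && r$id == model$objective) 1 else NULL,
           annotation = if (length(ann)) ann else NULL)
    )
  })
  genes <- unique(unlist(lapply(model$reactions$gpr, gpr_genes)))
  obj <- list(
    id = model$id,
    metabolites = mets,
    reactions = rxns,
    genes = lapply(genes, function(g) list(id = g, name = g)),
    compartments = stats::setNames(as.list(model$compartments), model$compartments),
    version = "1"
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- dplyr::bind_rows(lapply(obj$metabolites, function(m) {
    tibble::tibble(id = m$id, name = m$name %||% m$id,
                   formula = m$formula %||% "",
                   charge = if (is.null(m$charge)) NA_integer_ else as.integer(m$charge),
                   compartment = m$compartment %||% sub("^.*_", "", m$id))
  }))
  objective <- NA_character_
  rxns <- dplyr::bind_rows(lapply(obj$reactions, function(r) {
    stoich <- unlist(r$metabolites)
    ann <- r$annotation %||% list()
    spont <- isTRUE(ann$spontaneous)
    ann$spontaneous <- NULL
    if (!is.null(r$objective_coefficient) && r$objective_coefficient != 0) {
      objective <<- r$id
    }
    tibble::tibble(id = r$id, name = r$name %||% r$id,
                   stoich = list(stoich),
                   lower = as.numeric(r$lower_bound %||% -1000),
                   upper = as.numeric(r$upper_bound %||% 1000),
                   gpr = list(gpr_parse(r$gene_reaction_rule %||% "")),
                   spontaneous = spont,
                   annotations = list(ann))
  }))
  metabolic_model(obj$id %||% "model", mets, rxns, objective = objective,
                  compartments = names(obj$compartments) %||% NULL)
}

# ---- SBML L3 + FBC ----------------------------------------------------------

write_model_sbml <- function(model, path) {
  assert_sid(model$metabolites$id, "metabolite")
  assert_sid(model$reactions$id, "reaction")
  genes <- unique(unlist(lapply(model$reactions$gpr, gpr_genes)))
  assert_sid(genes, "gene")

  # deduplicated bound parameters
  bounds <- sort(unique(c(model$reactions$lower, model$reactions$upper)))
  bound_id <- function(v) paste0("bnd_", gsub("[^0-9A-Za-z]", "_", format(v, trim = TRUE, scientific = FALSE)))

  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_CORE_NS, `xmlns:fbc` = SBML_FBC_NS,
    `xmlns:pm` = PANMET_NS, level = "3", version = "1", `fbc:required` = "false"
  )
  mdl <- xml2::xml_add_child(doc, "model", id = model$id, `fbc:strict` = "true")

  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in model$compartments) {
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")
  }

  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(ls, "species", id = paste0("M_", m$id),
      name = m$name, compartment = m$compartment,
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    if (nzchar(m$formula)) xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    if (!is.na(m$charge)) xml2::xml_set_attr(sp, "fbc:charge", as.character(m$charge))
  }

  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (v in bounds) {
    xml2::xml_add_child(lp, "parameter", id = bound_id(v),
      value = format(v, trim = TRUE, scientific = FALSE), constant = "true",
      sboTerm = "SBO:0000626")
  }

  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rx <- xml2::xml_add_child(lr, "reaction", id = paste0("R_", r$id),
      name = r$name, reversible = if (r$lower < 0) "true" else "false",
      fast = "false",
      `fbc:lowerFluxBound` = bound_id(r$lower),
      `fbc:upperFluxBound` = bound_id(r$upper))
    if (isTRUE(r$spontaneous)) {
      ann <- xml2::xml_add_child(rx, "annotation")
      xml2::xml_add_child(ann, "pm:spontaneous", "true")
    }
    s <- r$stoich[[1L]]
    reac <- s[s < 0]
    prod <- s[s > 0]
    if (length(reac)) {
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      for (k in seq_along(reac)) {
        xml2::xml_add_child(lre, "speciesReference",
          species = paste0("M_", names(reac)[k]),
          stoichiometry = format(-unname(reac[k]), trim = TRUE, scientific = FALSE),
          constant = "true")
      }
    }
    if (length(prod)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (k in seq_along(prod)) {
        xml2::xml_add_child(lpr, "speciesReference",
          species = paste0("M_", names(prod)[k]),
          stoichiometry = format(unname(prod[k]), trim = TRUE, scientific = FALSE),
          constant = "true")
      }
    }
    g <- r$gpr[[1L]]
    if (!gpr_is_empty(g) && !gpr_is_unsat(g)) {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      add_gpr_xml(gpa, g)
    }
  }

  lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives", `fbc:activeObjective` = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", `fbc:id` = "obj", `fbc:type` = "maximize")
  if (!is.na(model$objective)) {
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
      `fbc:reaction` = paste0("R_", model$objective), `fbc:coefficient` = "1")
  }

  if (length(genes)) {
    lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(lg, "fbc:geneProduct", `fbc:id` = paste0("G_", g),
        `fbc:label` = g)
    }
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

add_gpr_xml <- function(parent, g) {
  switch(g$op,
    leaf = xml2::xml_add_child(parent, "fbc:geneProductRef",
                               `fbc:geneProduct` = paste0("G_", g$gene)),
    and = {
      nd <- xml2::xml_add_child(parent, "fbc:and")
      for (ch in g$children) add_gpr_xml(nd, ch)
    },
    or = {
      nd <- xml2::xml_add_child(parent, "fbc:or")
      for (ch in g$children) add_gpr_xml(nd, ch)
    },
    stop("cannot serialize GPR op '", g$op, "' to SBML")
  )
}

strip_prefix <- function(x, prefix) {
  ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(d1 = SBML_CORE_NS, fbc = SBML_FBC_NS)
  mdl <- xml2::xml_find_first(doc, ".//d1:model", ns)
  if (inherits(mdl, "xml_missing")) stop("no <model> element in ", path)

  compartments <- xml2::xml_attr(
    xml2::xml_find_all(mdl, ".//d1:listOfCompartments/d1:compartment", ns), "id")

  sp_nodes <- xml2::xml_find_all(mdl, ".//d1:listOfSpecies/d1:species", ns)
  mets <- tibble::tibble(
    id = strip_prefix(xml2::xml_attr(sp_nodes, "id"), "M_"),
    name = xml2::xml_attr(sp_nodes, "name"),
    formula = xml2::xml_attr(sp_nodes, "chemicalFormula") %na% "",
    charge = suppressWarnings(as.integer(xml2::xml_attr(sp_nodes, "charge"))),
    compartment = xml2::xml_attr(sp_nodes, "compartment")
  )
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]

  par_nodes <- xml2::xml_find_all(mdl, ".//d1:listOfParameters/d1:parameter", ns)
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  gp_nodes <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_label <- stats::setNames(
    xml2::xml_attr(gp_nodes, "label"),
    xml2::xml_attr(gp_nodes, "id"))
  gp_label[is.na(gp_label)] <- strip_prefix(names(gp_label)[is.na(gp_label)], "G_")

  rx_nodes <- xml2::xml_find_all(mdl, ".//d1:listOfReactions/d1:reaction", ns)
  rxns <- dplyr::bind_rows(lapply(rx_nodes, function(nd) {
    rid <- strip_prefix(xml2::xml_attr(nd, "id"), "R_")
    reac <- xml2::xml_find_all(nd, "./d1:listOfReactants/d1:speciesReference", ns)
    prod <- xml2::xml_find_all(nd, "./d1:listOfProducts/d1:speciesReference", ns)
    stoich <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                      strip_prefix(xml2::xml_attr(reac, "species"), "M_")),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                      strip_prefix(xml2::xml_attr(prod, "species"), "M_"))
    )
    lb_id <- xml2::xml_attr(nd, "lowerFluxBound")
    ub_id <- xml2::xml_attr(nd, "upperFluxBound")
    gpa <- xml2::xml_find_first(nd, "./fbc:geneProductAssociation/*", ns)
    g <- if (inherits(gpa, "xml_missing")) gpr_empty() else parse_gpr_xml(gpa, gp_label)
    spont_node <- xml2::xml_find_first(nd, "./d1:annotation/*[local-name()='spontaneous']", ns)
    spont <- !inherits(spont_node, "xml_missing") &&
      identical(trimws(xml2::xml_text(spont_node)), "true")
    nm <- xml2::xml_attr(nd, "name")
    tibble::tibble(id = rid, name = if (is.na(nm)) rid else nm,
                   stoich = list(stoich),
                   lower = unname(par_val[lb_id]), upper = unname(par_val[ub_id]),
                   gpr = list(g), spontaneous = spont, annotations = list(list()))
  }))

  fo <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  objective <- if (inherits(fo, "xml_missing")) NA_character_ else
    strip_prefix(xml2::xml_attr(fo, "reaction"), "R_")

  metabolic_model(xml2::xml_attr(mdl, "id") %na% "model", mets, rxns,
                  objective = objective, compartments = compartments)
}

parse_gpr_xml <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- xml2::xml_attr(node, "geneProduct")
    lbl <- gp_label[gid]
    return(gpr_leaf(if (is.na(lbl)) strip_prefix(gid, "G_") else unname(lbl)))
  }
  children <- lapply(xml2::xml_children(node), parse_gpr_xml, gp_label = gp_label)
  if (length(children) == 1L) return(children[[1L]])
  if (nm == "and") new_gpr("and", children = children)
  else if (nm == "or") new_gpr("or", children = children)
  else stop("unknown GPR element <", nm, ">")
}

`%na%` <- function(a, b) ifelse(is.na(a), b, a)

#' Convert universe sentinel GPR leaves to the spontaneous flag
#'
#' Universe models encode spontaneous reactions through a sentinel gene id.
#' Reactions whose GPR is exactly that leaf (or an OR containing it) become
#' `spontaneous = TRUE` with the sentinel removed (the whole rule becomes
#' EMPTY when nothing else remains).
#'
#' @param model A `metabolic_model`.
#' @param sentinel Sentinel gene id (default `"spontaneous"`).
#' @return The converted model.
#' @export
normalize_spontaneous <- function(model, sentinel = "spontaneous") {
  for (i in seq_len(nrow(model$reactions))) {
    g <- model$reactions$gpr[[i]]
    if (!sentinel %in% gpr_genes(g)) next
    if (g$op == "leaf") {
      model$reactions$spontaneous[i] <- TRUE
      model$reactions$gpr[[i]] <- gpr_empty()
    } else if (g$op == "or") {
      keep <- !vapply(g$children, function(ch) {
        ch$op == "leaf" && ch$gene == sentinel
      }, logical(1))
      if (!all(keep)) {
        model$reactions$spontaneous[i] <- TRUE
        ch <- g$children[keep]
        model$reactions$gpr[[i]] <-
          if (length(ch) == 0L) gpr_empty()
          else if (length(ch) == 1L) ch[[1L]]
          else new_gpr("or", children = ch)
      }
    }
  }
  model
}
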