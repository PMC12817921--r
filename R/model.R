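# Constraint-based metabolic model container.
#
# A `metabolic_model` is an S3 list with:
#   id           - model id
#   metabolites  - tibble(id, name, formula, charge, compartment)
#   reactions    - tibble(id, name, stoich<list of named numeric>, lower,
#                  upper, gpr<list of gpr>, spontaneous, annotations<list>)
#   objective    - reaction id of the biomass (or other) objective
#   compartments - character vector
# Formulas are Hill-style strings ("C6H12O6", "" = unknown); charges are
# integers (NA = unknown). Flux bounds are in mmol/gDW/h.

#' Boundary-reaction id prefixes
#'
#' The prefix dialect used to classify single-metabolite boundary reactions
#' as exchange, sink, or demand. Override individual prefixes to match other
#' id conventions.
#'
#' @param exchange,sink,demand Character vectors of id prefixes.
#' @return Named list of prefix vectors.
#' @export
boundary_prefixes <- function(exchange = "EX_", sink = c("SK_", "sink_"),
                              demand = "DM_") {
  list(exchange = exchange, sink = sink, demand = demand)
}

empty_metabolites <- function() {
  tibble::tibble(id = character(0), name = character(0), formula = character(0),
                 charge = integer(0), compartment = character(0))
}

empty_reactions <- function() {
  tibble::tibble(id = character(0), name = character(0), stoich = list(),
                 lower = numeric(0), upper = numeric(0), gpr = list(),
                 spontaneous = logical(0), annotations = list())
}

#' Create a metabolic model
#'
#' @param id Model id.
#' @param metabolites Tibble with columns `id`, `name`, `formula`, `charge`,
#'   `compartment` (missing columns are filled with defaults).
#' @param reactions Tibble with columns `id`, `name`, `stoich` (list of named
#'   numeric vectors; negative = consumed), `lower`, `upper`, `gpr` (list of
#'   `gpr` objects), `spontaneous`, `annotations` (list of named lists).
#' @param objective Reaction id of the objective, or `NA`.
#' @param compartments Character vector; inferred from metabolites if missing.
#' @return A `metabolic_model` object.
#' @export
metabolic_model <- function(id, metabolites = empty_metabolites(),
                            reactions = empty_reactions(),
                            objective = NA_character_, compartments = NULL) {
  metabolites <- fill_metabolite_cols(tibble::as_tibble(metabolites))
  reactions <- fill_reaction_cols(tibble::as_tibble(reactions))
  if (is.null(compartments)) compartments <- unique(metabolites$compartment)
  m <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         objective = objective, compartments = compartments),
    class = "metabolic_model"
  )
  validate_model(m)
}

fill_metabolite_cols <- function(met) {
  if (!"id" %in% names(met)) met$id <- character(0)
  if (!"name" %in% names(met)) met$name <- met$id
  if (!"formula" %in% names(met)) met$formula <- ""
  if (!"charge" %in% names(met)) met$charge <- NA_integer_
  if (!"compartment" %in% names(met)) {
    met$compartment <- sub("^.*_([a-z0-9]+)$", "\\1", met$id)
  }
  met$formula[is.na(met$formula)] <- ""
  met$charge <- as.integer(met$charge)
  met[, c("id", "name", "formula", "charge", "compartment")]
}

fill_reaction_cols <- function(rxn) {
  if (!"id" %in% names(rxn)) rxn$id <- character(0)
  if (!"stoich" %in% names(rxn)) rxn$stoich <- list()
  if (!"name" %in% names(rxn)) rxn$name <- rxn$id
  if (!"lower" %in% names(rxn)) rxn$lower <- -1000
  if (!"upper" %in% names(rxn)) rxn$upper <- 1000
  if (!"gpr" %in% names(rxn)) rxn$gpr <- replicate(nrow(rxn), gpr_empty(), simplify = FALSE)
  if (!"spontaneous" %in% names(rxn)) rxn$spontaneous <- FALSE
  if (!"annotations" %in% names(rxn)) rxn$annotations <- replicate(nrow(rxn), list(), simplify = FALSE)
  rxn[, c("id", "name", "stoich", "lower", "upper", "gpr", "spontaneous",
          "annotations")]
}

validate_model <- function(m) {
  stopifnot(inherits(m, "metabolic_model"))
  if (anyDuplicated(m$metabolites$id)) {
    stop("duplicated metabolite ids: ",
         paste(unique(m$metabolites$id[duplicated(m$metabolites$id)]), collapse = ", "))
  }
  if (anyDuplicated(m$reactions$id)) {
    stop("duplicated reaction ids: ",
         paste(unique(m$reactions$id[duplicated(m$reactions$id)]), collapse = ", "))
  }
  used <- unique(unlist(lapply(m$reactions$stoich, names)))
  dangling <- setdiff(used, m$metabolites$id)
  if (length(dangling)) {
    stop("reactions reference unknown metabolites: ",
         paste(dangling, collapse = ", "))
  }
  if (nrow(m$reactions) && any(m$reactions$lower > m$reactions$upper + 1e-12)) {
    stop("reaction with lower bound above upper bound")
  }
  if (!is.na(m$objective) && !m$objective %in% m$reactions$id) {
    stop("objective reaction '", m$objective, "' not in model")
  }
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$metabolites),
      "  reactions: ", nrow(x$reactions),
      "  objective: ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Classify reactions as exchange, sink, demand, or internal
#'
#' A reaction is a boundary (exchange/sink/demand) candidate iff it has
#' exactly one participating metabolite; the id prefix then decides the
#' class. Single-metabolite reactions with an unrecognized prefix are
#' reported as `"boundary"`.
#'
#' @param model A `metabolic_model`.
#' @param prefixes Prefix dialect, see [boundary_prefixes()].
#' @return Character vector along `model$reactions` with values
#'   `"exchange"`, `"sink"`, `"demand"`, `"boundary"`, or `"internal"`.
#' @export
reaction_types <- function(model, prefixes = boundary_prefixes()) {
  n_mets <- vapply(model$reactions$stoich, function(s) sum(s != 0), integer(1))
  ids <- model$reactions$id
  has_prefix <- function(id, pf) any(startsWith(id, pf))
  vapply(seq_along(ids), function(i) {
    if (n_mets[i] != 1L) return("internal")
    if (has_prefix(ids[i], prefixes$exchange)) "exchange"
    else if (has_prefix(ids[i], prefixes$sink)) "sink"
    else if (has_prefix(ids[i], prefixes$demand)) "demand"
    else "boundary"
  }, character(1))
}

# ---- element formulas -------------------------------------------------------

#' Parse a Hill-style chemical formula into element counts
#' @param formula Formula string such as `"C6H12O6"`; `""` or `NA` = unknown.
#' @return Named numeric vector of element counts, or `NULL` if unknown.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)(\\d*\\.?\\d*)", formula, perl = TRUE)[[1L]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)(\\d*\\.?\\d*)", formula, perl = TRUE))[[1L]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("cannot parse formula: '", formula, "'")
  }
  el <- sub("[0-9.]+$", "", toks)
  cnt <- suppressWarnings(as.numeric(sub("^[A-Za-z]+", "", toks)))
  cnt[is.na(cnt)] <- 1
  tapply(cnt, el, sum)[unique(el)]
}

#' Check the mass and charge balance of a reaction
#'
#' Computes per-element and charge imbalances (sum of coefficient x count
#' over all participants). The verdict is `"balanced"` iff every imbalance is
#' exactly zero and all participants have known formula and charge,
#' `"undetermined"` if any participant lacks a formula or charge (or the
#' reaction is a single-metabolite exchange/sink/demand, which cannot
#' balance by construction), and `"unbalanced"` otherwise.
#'
#' @param reaction Either a reaction id present in `model`, or a named
#'   numeric stoichiometry vector.
#' @param model A `metabolic_model` supplying metabolite formulas/charges.
#' @param prefixes Boundary-id dialect, see [boundary_prefixes()].
#' @param tol Tolerance on imbalance.
#' @return List with `verdict`, `element_imbalance` (named numeric), and
#'   `charge_imbalance`.
#' @export
check_balance <- function(reaction, model, prefixes = boundary_prefixes(),
                          tol = 1e-9) {
  if (is.character(reaction)) {
    i <- match(reaction, model$reactions$id)
    if (is.na(i)) stop("reaction '", reaction, "' not in model")
    stoich <- model$reactions$stoich[[i]]
    rtype <- reaction_types(model, prefixes)[i]
  } else {
    stoich <- reaction
    rtype <- if (sum(stoich != 0) == 1L) "boundary" else "internal"
  }
  if (rtype %in% c("exchange", "sink", "demand", "boundary")) {
    return(list(verdict = "undetermined",
                element_imbalance = numeric(0), charge_imbalance = NA_real_))
  }
  mi <- match(names(stoich), model$metabolites$id)
  if (anyNA(mi)) stop("stoichiometry references unknown metabolites")
  formulas <- lapply(model$metabolites$formula[mi], parse_formula)
  charges <- model$metabolites$charge[mi]
  unknown <- vapply(formulas, is.null, logical(1)) | is.na(charges)
  net <- list()
  for (k in seq_along(stoich)) {
    f <- formulas[[k]]
    if (is.null(f)) next
    for (el in names(f)) {
      net[[el]] <- (net[[el]] %||% 0) + stoich[[k]] * f[[el]]
    }
  }
  element_imbalance <- unlist(net) %||% numeric(0)
  charge_imbalance <- if (any(is.na(charges))) NA_real_ else sum(stoich * charges)
  if (any(unknown)) {
    return(list(verdict = "undetermined", element_imbalance = element_imbalance,
                charge_imbalance = charge_imbalance))
  }
  balanced <- all(abs(element_imbalance) <= tol) && abs(charge_imbalance) <= tol
  list(verdict = if (balanced) "balanced" else "unbalanced",
       element_imbalance = element_imbalance,
       charge_imbalance = charge_imbalance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- orphan accounting ------------------------------------------------------

#' Count orphan reactions
#'
#' An orphan is an internal (not exchange/sink/demand), non-spontaneous
#' reaction with an EMPTY GPR whose name does not contain the substring
#' "diffusion" (case-insensitive). The fraction is taken over all eligible
#' reactions (internal, name not matching "diffusion").
#'
#' @param model A `metabolic_model`.
#' @param prefixes Boundary-id dialect.
#' @return List with `count`, `ids`, `n_eligible`, and `fraction`.
#' @export
count_orphans <- function(model, prefixes = boundary_prefixes()) {
  types <- reaction_types(model, prefixes)
  eligible <- types == "internal" &
    !grepl("diffusion", model$reactions$name, ignore.case = TRUE)
  empty_gpr <- vapply(model$reactions$gpr, gpr_is_empty, logical(1))
  orphan <- eligible & empty_gpr & !model$reactions$spontaneous
  list(count = sum(orphan), ids = model$reactions$id[orphan],
       n_eligible = sum(eligible),
       fraction = if (sum(eligible)) sum(orphan) / sum(eligible) else 0)
}

# ---- media ------------------------------------------------------------------

#' Create a medium recipe
#'
#' A medium recipe names the compounds available for uptake and their
#' maximum uptake rates (positive, mmol/gDW/h). Entries are resolved against
#' a model at application time, either by exchange-reaction id or by the
#' exchanged metabolite id.
#'
#' @param uptakes Named numeric vector (names = metabolite or exchange
#'   reaction ids, values = maximum uptake rates) or a tibble with columns
#'   `metabolite_id` and `max_uptake`.
#' @param name Medium name.
#' @return A `medium_recipe` object (tibble with attribute `name`).
#' @export
medium_recipe <- function(uptakes, name = "medium") {
  if (is.numeric(uptakes)) {
    uptakes <- tibble::tibble(metabolite_id = names(uptakes) %||% character(0),
                              max_uptake = unname(uptakes))
  }
  uptakes <- tibble::as_tibble(uptakes)[, c("metabolite_id", "max_uptake")]
  if (nrow(uptakes) && any(uptakes$max_uptake <= 0)) {
    stop("medium uptake rates must be positive")
  }
  structure(uptakes, name = name, class = c("medium_recipe", class(uptakes)))
}

#' @export
print.medium_recipe <- function(x, ...) {
  cat("<medium_recipe> ", attr(x, "name"), " (", nrow(x), " uptakes)\n", sep = "")
  NextMethod()
}

#' Apply a medium recipe to a model
#'
#' Closes all exchange lower bounds (sets them to 0), then opens each recipe
#' entry's exchange at `-max_uptake`. Non-exchange reactions are untouched,
#' so applying the same recipe twice is a no-op. Recipe entries are resolved
#' by exchange-reaction id or by exchanged metabolite id.
#'
#' @param model A `metabolic_model`.
#' @param recipe A [medium_recipe()].
#' @param on_missing `"error"` (default) to fail listing unresolvable
#'   entries, `"warn"` to skip them with a warning, `"skip"` to skip quietly.
#' @param prefixes Boundary-id dialect.
#' @return The modified model.
#' @export
apply_medium <- function(model, recipe, on_missing = c("error", "warn", "skip"),
                         prefixes = boundary_prefixes()) {
  on_missing <- match.arg(on_missing)
  types <- reaction_types(model, prefixes)
  ex <- which(types == "exchange")
  model$reactions$lower[ex] <- 0
  if (nrow(recipe) == 0L) return(model)
  ex_met <- vapply(model$reactions$stoich[ex],
                   function(s) names(s)[s != 0][1L], character(1))
  ex_ids <- model$reactions$id[ex]
  missing <- character(0)
  for (k in seq_len(nrow(recipe))) {
    entry <- recipe$metabolite_id[k]
    i <- match(entry, ex_ids)
    if (is.na(i)) i <- match(entry, ex_met)
    if (is.na(i)) {
      missing <- c(missing, entry)
      next
    }
    model$reactions$lower[ex[i]] <- -recipe$max_uptake[k]
  }
  if (length(missing)) {
    msg <- paste0("medium entries not resolvable to an exchange: ",
                  paste(missing, collapse = ", "))
    if (on_missing == "error") stop(msg, call. = FALSE)
    if (on_missing == "warn") warning(msg, call. = FALSE)
  }
  model
}

#' Read media recipes from a TSV file
#'
#' Expected columns: `medium_name`, `metabolite_id`, `max_uptake`. Returns a
#' named list of [medium_recipe()] objects, one per distinct `medium_name`,
#' in order of first appearance.
#'
#' @param path TSV file path.
#' @return Named list of `medium_recipe` objects.
#' @export
read_media_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("medium_name", "metabolite_id", "max_uptake") %in% names(tab)))
  names_in_order <- unique(tab$medium_name)
  out <- lapply(names_in_order, function(nm) {
    medium_recipe(tab[tab$medium_name == nm, c("metabolite_id", "max_uptake")],
                  name = nm)
  })
  stats::setNames(out, names_in_order)
}

#' Write media recipes to a TSV file
#' @param recipes A `medium_recipe` or list of them.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_media_tsv <- function(recipes, path) {
  if (inherits(recipes, "medium_recipe")) recipes <- list(recipes)
  tab <- dplyr::bind_rows(lapply(recipes, function(r) {
    tibble::tibble(medium_name = attr(r, "name"), metabolite_id = r$metabolite_id,
                   max_uptake = r$max_uptake)
  }))
  readr::write_tsv(tab, path)
  invisible(path)
}

# ---- model editing helpers --------------------------------------------------

# Keep only the given reactions and the metabolites they use.
subset_model <- function(model, reaction_ids) {
  keep <- model$reactions$id %in% reaction_ids
  rxn <- model$reactions[keep, , drop = FALSE]
  used <- unique(unlist(lapply(rxn$stoich, names)))
  met <- model$metabolites[model$metabolites$id %in% used, , drop = FALSE]
  model$reactions <- rxn
  model$metabolites <- met
  if (!is.na(model$objective) && !model$objective %in% rxn$id) {
    model$objective <- NA_character_
  }
  model
}

# Add reactions (and their metabolites) from `source` to `model` by id.
copy_reactions <- function(model, source, reaction_ids) {
  add <- source$reactions[source$reactions$id %in% reaction_ids, , drop = FALSE]
  add <- add[!add$id %in% model$reactions$id, , drop = FALSE]
  used <- setdiff(unique(unlist(lapply(add$stoich, names))), model$metabolites$id)
  model$metabolites <- dplyr::bind_rows(
    model$metabolites,
    source$metabolites[source$metabolites$id %in% used, , drop = FALSE]
  )
  model$reactions <- dplyr::bind_rows(model$reactions, add)
  model
}

# ---- consensus models -------------------------------------------------------

#' Species-consensus models
#'
#' For each species label, builds the model defined by the set of reactions
#' present in every member model (intersection of reaction ids), with
#' metabolites restricted to those used. GPRs are taken from `pan` (the
#' pan-level, cluster-space model) when provided, else set to EMPTY.
#'
#' @param models Named list of `metabolic_model`s (one per strain).
#' @param species Character vector of species labels along `models`.
#' @param pan Optional pan-level model supplying cluster-space GPRs.
#' @return Named list of consensus `metabolic_model`s, one per species.
#' @export
consensus_model <- function(models, species, pan = NULL) {
  stopifnot(length(models) == length(species), length(models) >= 1L)
  out <- list()
  for (sp in unique(species)) {
    members <- models[species == sp]
    common <- Reduce(intersect, lapply(members, function(m) m$reactions$id))
    if (length(common) == 0L) {
      warning("species '", sp, "': empty reaction intersection")
    }
    base <- members[[1L]]
    cons <- subset_model(base, common)
    cons$id <- paste0("consensus_", sp)
    if (!is.null(pan)) {
      i <- match(cons$reactions$id, pan$reactions$id)
      cons$reactions$gpr <- lapply(seq_along(i), function(k) {
        if (is.na(i[k])) gpr_empty() else pan$reactions$gpr[[i[k]]]
      })
    } else {
      cons$reactions$gpr <- replicate(nrow(cons$reactions), gpr_empty(),
                                      simplify = FALSE)
    }
    out[[sp]] <- cons
  }
  out
}
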