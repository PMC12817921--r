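# Strain-level phenotype prediction by FBA and binary feature table (BFT)
# assembly. A BFT is a tibble with a `feature` column and one 0/1 column
# per strain.

DEFAULT_ELEMENT_SOURCES <- c(C = "glc__D", N = "nh4", P = "pi", S = "so4")

#' Substrate-utilization phenotypes
#'
#' For each candidate metabolite: the default source of the element is
#' closed, the candidate's exchange opened at the default source's rate,
#' and growth tested by FBA. The call is 1 iff the objective reaches
#' `threshold`. Candidates without an exchange in the model score 0.
#'
#' @param model A `metabolic_model` (typically a derived strain model).
#' @param base_medium The [medium_recipe()] designating exactly one source
#'   for the element.
#' @param element One of `"C"`, `"N"`, `"P"`, `"S"`.
#' @param candidates Character vector of candidate metabolite basenames
#'   (without compartment suffix, e.g. `"xyl__D"`) or full extracellular
#'   ids.
#' @param threshold Growth-call threshold on the objective flux (default
#'   `1e-4`).
#' @param sources Named map element -> default source basename.
#' @param extracellular Extracellular compartment suffix.
#' @return Tibble `feature` (`"<element>_source:<candidate>"`), `value`.
#' @export
phenotype_substrates <- function(model, base_medium, element = "C",
                                 candidates, threshold = 1e-4,
                                 sources = DEFAULT_ELEMENT_SOURCES,
                                 extracellular = "e") {
  element <- match.arg(element, names(sources))
  src <- paste0(sources[[element]], "_", extracellular)
  src_rows <- base_medium$metabolite_id %in%
    c(src, paste0("EX_", src))
  if (!any(src_rows)) {
    stop("base medium has no designated ", element, " source (", src, ")")
  }
  rate <- base_medium$max_uptake[src_rows][1L]
  vals <- vapply(candidates, function(cand) {
    cand_id <- if (grepl(paste0("_", extracellular, "$"), cand)) cand else
      paste0(cand, "_", extracellular)
    rec <- tibble::as_tibble(base_medium)[!src_rows, ]
    rec <- rec[rec$metabolite_id != cand_id, ]
    rec <- dplyr::bind_rows(rec, tibble::tibble(metabolite_id = cand_id,
                                                max_uptake = rate))
    m <- apply_medium(model, medium_recipe(rec), on_missing = "skip")
    # a candidate with no exchange cannot be taken up at all
    types <- reaction_types(m)
    ex_mets <- vapply(m$reactions$stoich[types == "exchange"],
                      function(s) names(s)[1L], character(1))
    if (!cand_id %in% ex_mets) return(0L)
    r <- run_fba(m, threshold = threshold)
    as.integer(r$status == "optimal" && r$objective_value >= threshold)
  }, integer(1))
  tibble::tibble(
    feature = paste0(element, "_source:", sub("_[a-z0-9]+$", "", candidates)),
    value = unname(vals)
  )
}

# Maximize a temporary demand for a cytosolic compound on a medium.
max_demand_flux <- function(model, medium, met_id) {
  if (!met_id %in% model$metabolites$id) return(NA_real_)
  dm_id <- paste0("DM_", met_id, "__tmp")
  model$reactions <- dplyr::bind_rows(model$reactions, tibble::tibble(
    id = dm_id, name = paste("demand", met_id),
    stoich = list(stats::setNames(-1, met_id)), lower = 0, upper = 1000,
    gpr = list(gpr_empty()), spontaneous = FALSE, annotations = list(list())
  ))
  m <- apply_medium(model, medium, on_missing = "skip")
  r <- run_fba(m, objective = dm_id)
  if (r$status != "optimal") 0 else r$objective_value
}

#' Auxotrophy phenotypes
#'
#' Auxotrophy is scored as biosynthetic incapacity: a temporary demand for
#' the cytosolic compound is maximized on the minimal medium (without the
#' compound supplied); the strain is auxotrophic (1) iff the maximum demand
#' flux stays below `threshold`. Compounds absent from the model score 1
#' with a warning (the network cannot synthesize what it does not
#' represent).
#'
#' @param model A `metabolic_model`.
#' @param minimal_medium A [medium_recipe()] lacking the tested compounds.
#' @param compounds Cytosolic metabolite ids (e.g. `"trp__L_c"`) or
#'   basenames (suffixed with `_c` automatically).
#' @param threshold Flux threshold (default `1e-4`).
#' @return Tibble `feature` (`"aux:<compound>"`), `value`, `absent`.
#' @export
phenotype_auxotrophies <- function(model, minimal_medium, compounds,
                                   threshold = 1e-4) {
  ids <- ifelse(grepl("_[a-z0-9]+$", compounds) &
                  compounds %in% model$metabolites$id,
                compounds, paste0(sub("_c$", "", compounds), "_c"))
  vals <- vapply(ids, function(met) {
    # the compound itself must not be supplied: biosynthetic capacity only
    base <- sub("_c$", "", met)
    med <- minimal_medium[!minimal_medium$metabolite_id %in%
                            c(paste0(base, "_e"), paste0("EX_", base, "_e")), ]
    f <- max_demand_flux(model, medium_recipe(med, name = "aux_test"), met)
    if (is.na(f)) return(NA_integer_)
    as.integer(f < threshold)
  }, integer(1))
  absent <- is.na(vals)
  if (any(absent)) {
    warning("compound(s) absent from model scored as auxotrophic: ",
            paste(ids[absent], collapse = ", "), call. = FALSE)
    vals[absent] <- 1L
  }
  tibble::tibble(feature = paste0("aux:", sub("_c$", "", ids)),
                 value = unname(vals), absent = unname(absent))
}

#' Biosynthesis phenotypes
#'
#' For each target metabolite a temporary demand is maximized on the given
#' medium; the call is 1 iff the maximum is at least `threshold`. Targets
#' absent from the model score 0 with a warning.
#'
#' @param model A `metabolic_model`.
#' @param medium A [medium_recipe()].
#' @param targets Metabolite ids (with compartment suffix, e.g.
#'   `"hista_c"`).
#' @param threshold Flux threshold (default `1e-4`).
#' @return Tibble `feature` (`"biosynth:<target>"`), `value`, `absent`.
#' @export
phenotype_biosynthesis <- function(model, medium, targets, threshold = 1e-4) {
  vals <- vapply(targets, function(met) {
    f <- max_demand_flux(model, medium, met)
    if (is.na(f)) return(NA_integer_)
    as.integer(f >= threshold)
  }, integer(1))
  absent <- is.na(vals)
  if (any(absent)) {
    warning("target(s) absent from model scored 0: ",
            paste(targets[absent], collapse = ", "), call. = FALSE)
    vals[absent] <- 0L
  }
  tibble::tibble(feature = paste0("biosynth:", targets),
                 value = unname(vals), absent = unname(absent))
}

#' Assemble a binary feature table (BFT)
#'
#' Combines per-strain feature outcomes (tibbles with `feature`, `value`)
#' into one table with features in rows and strains in columns. Outcomes
#' missing for some strain become 0 with a warning; duplicate feature ids
#' within a strain are an error.
#'
#' @param outcomes Named list (names = strain ids) of tibbles with columns
#'   `feature` and `value` (0/1).
#' @return A BFT tibble: `feature` column plus one 0/1 column per strain.
#' @export
build_bft <- function(outcomes) {
  stopifnot(length(outcomes) > 0, !is.null(names(outcomes)))
  long <- dplyr::bind_rows(lapply(names(outcomes), function(s) {
    tab <- tibble::as_tibble(outcomes[[s]])[, c("feature", "value")]
    if (anyDuplicated(tab$feature)) {
      stop("duplicate feature ids for strain '", s, "': ",
           paste(unique(tab$feature[duplicated(tab$feature)]), collapse = ", "))
    }
    tibble::tibble(strain = s, tab)
  }))
  wide <- tidyr::pivot_wider(long, names_from = "strain",
                             values_from = "value")
  n_missing <- sum(is.na(as.matrix(wide[, -1])))
  if (n_missing > 0) {
    warning("missing outcomes scored 0 for ", n_missing, " cell(s)",
            call. = FALSE)
    for (cn in names(wide)[-1]) wide[[cn]][is.na(wide[[cn]])] <- 0L
  }
  stopifnot(all(unlist(wide[, -1]) %in% c(0L, 1L)))
  wide
}

#' Reaction-presence BFT from a deck of strain models
#'
#' One row per reaction id seen in any model; the cell is 1 iff the
#' reaction id is present in the strain's model.
#'
#' @param models Named list (strain id -> `metabolic_model`).
#' @param reactions Optional fixed reaction universe for the rows; defaults
#'   to the union over models.
#' @return A BFT tibble with features `"reaction:<id>"`.
#' @export
reaction_bft <- function(models, reactions = NULL) {
  stopifnot(length(models) > 0, !is.null(names(models)))
  if (is.null(reactions)) {
    reactions <- sort(unique(unlist(lapply(models, function(m) m$reactions$id))))
  }
  outcomes <- lapply(models, function(m) {
    tibble::tibble(feature = paste0("reaction:", reactions),
                   value = as.integer(reactions %in% m$reactions$id))
  })
  build_bft(outcomes)
}

bft_strains <- function(bft) setdiff(names(bft), "feature")

#' Read / write a BFT as TSV
#' @param bft A BFT tibble (`feature` column plus one column per strain).
#' @param path TSV path.
#' @return `write_bft()` returns `path` invisibly; `read_bft()` the tibble.
#' @export
write_bft <- function(bft, path) {
  readr::write_tsv(bft, path)
  invisible(path)
}

#' @rdname write_bft
#' @export
read_bft <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
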