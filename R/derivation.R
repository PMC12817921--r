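# Derivation of strain-specific models from the pan-GSMM and the PAM,
# followed by optional per-medium gap-filling.

#' Derive a strain-specific model from the pan-GSMM
#'
#' A cluster counts as present for the strain iff its PAM cell holds at
#' least one gene without a premature stop (a single intact gene rescues
#' the cluster); reference-only placeholder leaves count absent. Every GPR
#' undergoes [gpr_substitute()] with cluster -> OR(strain's intact genes);
#' reactions whose GPR becomes UNSATISFIABLE are removed together with
#' their now-unused metabolites, while EMPTY-GPR and spontaneous reactions
#' are retained. Exchanges are kept only for surviving extracellular
#' metabolites.
#'
#' @param pan The pan `metabolic_model` (cluster-space GPRs).
#' @param pam The [build_pam()] object.
#' @param strain Strain id (must be a PAM column).
#' @param prefixes Boundary-id dialect.
#' @return A `strain_model`: a `metabolic_model` with extra fields `strain`
#'   and `gapfilled` (named list, filled by [gapfill_strain()]).
#' @export
derive_strain <- function(pan, pam, strain, prefixes = boundary_prefixes()) {
  if (!strain %in% pam$strains) stop("unknown strain: ", strain)
  mapping <- pam_strain_mapping(pam, strain)   # cluster -> intact genes
  leaves <- unique(unlist(lapply(pan$reactions$gpr, gpr_genes)))
  placeholders <- leaves[startsWith(leaves, REFONLY_PREFIX)]
  unknown <- setdiff(leaves, c(pam$clusters, placeholders))
  if (length(unknown)) {
    stop("pan GPR leaves neither in the PAM nor reference-only placeholders: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  for (ph in placeholders) mapping[[ph]] <- character(0)

  model <- pan
  keep <- logical(nrow(model$reactions))
  for (i in seq_len(nrow(model$reactions))) {
    g <- gpr_substitute(model$reactions$gpr[[i]], mapping)
    model$reactions$gpr[[i]] <- g
    keep[i] <- model$reactions$spontaneous[i] || !gpr_is_unsat(g)
  }
  model <- subset_model(model, model$reactions$id[keep])
  model <- prune_disconnected_boundary(model, prefixes)
  model$id <- paste0(pan$id, "_", strain)
  model$objective <- pan$objective
  model <- validate_model(model)
  model$strain <- strain
  model$gapfilled <- list()
  class(model) <- c("strain_model", class(model))
  model
}

#' @export
print.strain_model <- function(x, ...) {
  cat("<strain_model> ", x$strain, ": ", nrow(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites\n", sep = "")
  invisible(x)
}

# Drop boundary reactions whose metabolite no other reaction uses, then
# prune metabolites used by no reaction.
prune_disconnected_boundary <- function(model, prefixes = boundary_prefixes()) {
  repeat {
    types <- reaction_types(model, prefixes)
    usage <- table(unlist(lapply(model$reactions$stoich, names)))
    drop <- vapply(seq_len(nrow(model$reactions)), function(i) {
      if (!types[i] %in% c("exchange", "sink", "demand")) return(FALSE)
      met <- names(model$reactions$stoich[[i]])[1L]
      usage[[met]] <= 1L
    }, logical(1))
    if (!any(drop)) break
    model <- subset_model(model, model$reactions$id[!drop])
  }
  model
}

#' Gap-fill a strain model on one or more media
#'
#' Runs [gapfill_min_penalty()] against the pan model as repository for
#' each medium in order; later rounds see earlier additions. Per-medium
#' penalties are uniform 1 unless a penalty table is given. A medium that
#' cannot be satisfied even with the full pan is recorded as failed and the
#' remaining media are still processed. With `skip = TRUE` the model is
#' returned unchanged (useful for auxotrophy studies on minimal media).
#'
#' @param strain_model A [derive_strain()] result.
#' @param pan The pan `metabolic_model` used as reaction repository.
#' @param media A [medium_recipe()] or ordered list of them.
#' @param min_flux Required objective flux (default 0.001).
#' @param skip Skip gap-filling entirely.
#' @param penalties Optional named penalty vector (default uniform 1).
#' @return The strain model with `gapfilled[[medium]]` set to the added
#'   reaction ids (`NA` on failure) for each medium.
#' @export
gapfill_strain <- function(strain_model, pan, media, min_flux = 0.001,
                           skip = FALSE, penalties = NULL) {
  if (skip) return(strain_model)
  if (inherits(media, "medium_recipe")) media <- list(media)
  for (med in media) {
    med_name <- attr(med, "name") %||% "medium"
    res <- gapfill_min_penalty(strain_model, pan, med, min_flux = min_flux,
                               penalties = penalties)
    if (res$status == "success") {
      cls <- class(strain_model)
      st <- strain_model$strain
      gf <- strain_model$gapfilled
      strain_model <- res$model
      strain_model$strain <- st
      strain_model$gapfilled <- gf
      strain_model$gapfilled[[med_name]] <- res$added
      class(strain_model) <- cls
    } else {
      strain_model$gapfilled[[med_name]] <- NA_character_
      warning("gap-filling failed for strain '", strain_model$strain,
              "' on medium '", med_name, "'", call. = FALSE)
    }
  }
  strain_model
}

#' Generic minimal aerobic medium
#'
#' Glucose, ammonia, phosphate, and sulfate as sole C, N, P, and S sources,
#' plus an aerobic housekeeping set (o2, h2o, h) and a configurable
#' trace-ion list. Each entry is restricted to exchanges actually present
#' in the model; the default uptake rate is 10 mmol/gDW/h.
#'
#' @param model A `metabolic_model`.
#' @param rate Uptake rate applied to every entry (default 10).
#' @param trace_ions Extracellular metabolite basenames of trace ions.
#' @param extracellular Extracellular compartment suffix (default "e").
#' @param prefixes Boundary-id dialect.
#' @return A [medium_recipe()] named `"minimal_aerobic"` containing only
#'   the entries resolvable in the model.
#' @export
default_minimal_medium <- function(model, rate = 10,
                                   trace_ions = c("fe2", "fe3", "k", "mg2",
                                                  "mn2", "zn2", "ca2", "cl",
                                                  "cobalt2", "cu2", "mobd"),
                                   extracellular = "e",
                                   prefixes = boundary_prefixes()) {
  base <- c("glc__D", "nh4", "pi", "so4", "o2", "h2o", "h", trace_ions)
  wanted <- paste0(base, "_", extracellular)
  types <- reaction_types(model, prefixes)
  ex_mets <- vapply(model$reactions$stoich[types == "exchange"],
                    function(s) names(s)[1L], character(1))
  present <- wanted[wanted %in% ex_mets]
  medium_recipe(stats::setNames(rep(rate, length(present)), present),
                name = "minimal_aerobic")
}
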