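# Flux balance analysis: maximize an objective flux subject to steady state
# (S v = 0) and flux bounds.

#' Build the stoichiometric matrix of a model
#' @param model A `metabolic_model`.
#' @return Numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoichiometric_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    s <- model$reactions$stoich[[j]]
    S[names(s), j] <- s
  }
  S
}

#' Run flux balance analysis
#'
#' Maximizes the flux through the objective reaction subject to steady state
#' and the model's flux bounds. A model whose objective cannot carry flux
#' (e.g. a missing pathway intermediate) is reported as `optimal` with value
#' 0, not infeasible; `infeasible` is reserved for bound systems with no
#' steady-state solution at all.
#'
#' @param model A `metabolic_model`.
#' @param objective Reaction id to maximize; defaults to `model$objective`.
#' @param threshold Flux above which `grows` is reported `TRUE` (default
#'   `1e-6`).
#' @return An `fba_result`: list with `status` ("optimal"/"infeasible"),
#'   `objective_value`, `objective`, `fluxes` (named vector), and `grows`.
#' @export
run_fba <- function(model, objective = model$objective, threshold = 1e-6) {
  stopifnot(nrow(model$reactions) > 0)
  if (is.na(objective) || !objective %in% model$reactions$id) {
    stop("objective reaction '", objective, "' not in model")
  }
  S <- stoichiometric_matrix(model)
  obj <- as.numeric(model$reactions$id == objective)
  res <- lp_solve(obj, S, rep(0, nrow(S)), model$reactions$lower,
                  model$reactions$upper, maximize = TRUE)
  if (res$status != "optimal") {
    out <- list(status = "infeasible", objective_value = NA_real_,
                objective = objective,
                fluxes = stats::setNames(rep(NA_real_, ncol(S)), colnames(S)),
                grows = FALSE, threshold = threshold)
  } else {
    out <- list(status = "optimal", objective_value = res$value,
                objective = objective,
                fluxes = stats::setNames(res$x, colnames(S)),
                grows = res$value >= threshold, threshold = threshold)
  }
  structure(out, class = "fba_result")
}

#' @export
print.fba_result <- function(x, ...) {
  cat("<fba_result> status: ", x$status, ", objective ", x$objective, " = ",
      format(x$objective_value, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Tidy an FBA result into a flux table
#' @param x An `fba_result`.
#' @param ... Unused.
#' @return Tibble with columns `reaction` and `flux`.
#' @export
tidy.fba_result <- function(x, ...) {
  tibble::tibble(reaction = names(x$fluxes), flux = unname(x$fluxes))
}

#' One-row summary of an FBA result
#' @param x An `fba_result`.
#' @param ... Unused.
#' @return One-row tibble with `status`, `objective`, `objective_value`,
#'   `grows`.
#' @export
glance.fba_result <- function(x, ...) {
  tibble::tibble(status = x$status, objective = x$objective,
                 objective_value = x$objective_value, grows = x$grows)
}
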