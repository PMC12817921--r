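# Reference-free reconstruction: map cluster representatives onto the
# universe's gene space, carve a draft pan-GSMM that keeps a reaction only
# when its full enzyme complex is supported, and gap-fill with penalties
# derived from the alignment evidence.

#' Map cluster representatives to universe genes
#'
#' One-way global alignment of every cluster representative against every
#' universal gene sequence. A (gene, cluster) pair supports iff identity is
#' at least `id_min` and the coverage of the universal gene is at least
#' `cov_min`; the pair's score is `identity * coverage`.
#'
#' @param representatives Tibble `cluster`, `seq` (from
#'   [cluster_proteins()]'s `$representatives`).
#' @param universe_genes Tibble `gene_id`, `seq` with the universal genes'
#'   protein sequences.
#' @param id_min Minimum identity (default 0.40).
#' @param cov_min Minimum coverage of the universal gene (default 0.70).
#' @return Gene support map: tibble `universal_gene`, `cluster`, `identity`,
#'   `coverage`, `score`.
#' @export
map_clusters_to_universe <- function(representatives, universe_genes,
                                     id_min = 0.40, cov_min = 0.70) {
  stopifnot(nrow(universe_genes) > 0, all(nzchar(universe_genes$seq)))
  hits <- lapply(seq_len(nrow(representatives)), function(i) {
    st <- align_identity_many(universe_genes$seq, representatives$seq[i])
    ok <- st$identity >= id_min & st$cov_pattern >= cov_min
    if (!any(ok)) return(NULL)
    tibble::tibble(universal_gene = universe_genes$gene_id[ok],
                   cluster = representatives$cluster[i],
                   identity = st$identity[ok],
                   coverage = st$cov_pattern[ok])
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble::tibble(universal_gene = character(0), cluster = character(0),
                          identity = numeric(0), coverage = numeric(0),
                          score = numeric(0)))
  }
  out$score <- out$identity * out$coverage
  dplyr::arrange(out, .data$universal_gene, .data$cluster)
}

#' Carve a draft pan-GSMM from a universe
#'
#' Rewrites every universe reaction's GPR by substituting each universal
#' gene with the OR of its supporting clusters (unsupported genes become
#' false). A reaction is included iff the rewritten GPR is satisfiable (AND
#' nodes demand all complex members) or the reaction is spontaneous;
#' reactions with an EMPTY GPR carry no gene requirement and are kept.
#' Exchange reactions are added for every retained extracellular metabolite
#' with bounds (0, 1000), to be opened later by a medium. Bounds are copied
#' from the universe and the objective is the universe biomass.
#'
#' @param universe `metabolic_model` whose GPR leaves are universal gene
#'   ids (spontaneous reactions flagged, e.g. via [normalize_spontaneous()]).
#' @param support Gene support map from [map_clusters_to_universe()].
#' @param extracellular Compartment id treated as extracellular ("e").
#' @param prefixes Boundary-id dialect.
#' @return The draft pan `metabolic_model` with cluster-space GPRs.
#' @export
carve_draft_pan <- function(universe, support, extracellular = "e",
                            prefixes = boundary_prefixes()) {
  if (is.na(universe$objective)) {
    stop("the universe has no biomass (objective) reaction")
  }
  mapping <- split(support$cluster, support$universal_gene)
  types <- reaction_types(universe, prefixes)
  keep <- logical(nrow(universe$reactions))
  new_gprs <- universe$reactions$gpr
  for (i in seq_len(nrow(universe$reactions))) {
    if (types[i] != "internal") next        # boundary rxns handled below
    g <- universe$reactions$gpr[[i]]
    full_map <- stats::setNames(
      lapply(gpr_genes(g), function(u) mapping[[u]] %||% character(0)),
      gpr_genes(g)
    )
    sub <- gpr_substitute(g, full_map)
    if (universe$reactions$spontaneous[i] || !gpr_is_unsat(sub)) {
      keep[i] <- TRUE
      new_gprs[[i]] <- if (gpr_is_unsat(sub)) gpr_empty() else sub
    }
  }
  draft <- universe
  draft$reactions$gpr <- new_gprs
  draft$id <- paste0(universe$id, "_draft_pan")
  draft <- subset_model(draft, universe$reactions$id[keep])

  # exchanges for retained extracellular metabolites
  ex_mets <- draft$metabolites$id[draft$metabolites$compartment == extracellular]
  for (m in ex_mets) {
    ex_id <- paste0(prefixes$exchange[1L], m)
    if (ex_id %in% draft$reactions$id) next
    draft$reactions <- dplyr::bind_rows(draft$reactions, tibble::tibble(
      id = ex_id, name = paste(m, "exchange"),
      stoich = list(stats::setNames(-1, m)), lower = 0, upper = 1000,
      gpr = list(gpr_empty()), spontaneous = FALSE, annotations = list(list())
    ))
  }
  draft$objective <- universe$objective
  validate_model(draft)
}

#' Alignment-derived gap-filling penalties
#'
#' The fractional support of a GPR is the best support among OR branches and
#' the worst among AND members, with per-gene support equal to the best
#' (gene, cluster) score in the map (0 when unsupported; EMPTY rules score 0
#' as they carry no gene evidence). The penalty interpolates linearly from
#' `p_min` (full support) to `p_max` (no support); spontaneous and boundary
#' (exchange/sink/demand) reactions always get `p_min`.
#'
#' @param universe The universe `metabolic_model`.
#' @param support Gene support map from [map_clusters_to_universe()].
#' @param p_min,p_max Penalty range (defaults 0.1 and 10).
#' @param prefixes Boundary-id dialect.
#' @return Named numeric vector: reaction id -> penalty.
#' @export
compute_penalties <- function(universe, support, p_min = 0.1, p_max = 10,
                              prefixes = boundary_prefixes()) {
  best_score <- tapply(pmin(support$score, 1), support$universal_gene, max)
  gene_support <- function(u) {
    s <- best_score[u]
    if (is.na(s)) 0 else unname(s)
  }
  frac_support <- function(g) {
    switch(g$op,
      empty = 0,
      unsat = 0,
      leaf = gene_support(g$gene),
      and = min(vapply(g$children, frac_support, numeric(1))),
      or = max(vapply(g$children, frac_support, numeric(1)))
    )
  }
  types <- reaction_types(universe, prefixes)
  pen <- vapply(seq_len(nrow(universe$reactions)), function(i) {
    if (universe$reactions$spontaneous[i] || types[i] != "internal") {
      return(p_min)
    }
    s <- frac_support(universe$reactions$gpr[[i]])
    p_min + (1 - s) * (p_max - p_min)
  }, numeric(1))
  stats::setNames(pen, universe$reactions$id)
}

#' Exact minimum-penalty gap-filling
#'
#' Finds a set of repository reactions, not already in the model, with
#' minimum total penalty such that the augmented model reaches at least
#' `min_flux` through its objective on the given medium. The search is an
#' exact best-first branch-and-bound over candidate subsets with LP
#' feasibility pruning (a node whose open relaxation cannot reach
#' `min_flux` is cut; a node already feasible needs no further additions).
#' Among equal-penalty optima the lexicographically smallest reaction id
#' set is returned.
#'
#' @param model The gapped `metabolic_model`.
#' @param repository `metabolic_model` supplying candidate reactions (e.g.
#'   the pan-GSMM or the universe).
#' @param medium A [medium_recipe()] applied before solving.
#' @param min_flux Required objective flux (default 0.001).
#' @param penalties Named numeric vector of per-reaction penalties; missing
#'   entries (and `NULL`) default to 1.
#' @param max_candidates Safety cap on the candidate set after reachability
#'   pruning.
#' @return A `gapfill_result`: list with `status` ("success"/"infeasible"),
#'   `added` (reaction ids), `total_penalty`, `objective_value`, `medium`,
#'   and `model` (the augmented model; unchanged on infeasibility).
#' @export
gapfill_min_penalty <- function(model, repository, medium, min_flux = 0.001,
                                penalties = NULL, max_candidates = 60L) {
  stopifnot(min_flux > 0)
  medium_name <- attr(medium, "name") %||% "medium"
  objective <- model$objective
  if (is.na(objective)) stop("model has no objective reaction to gap-fill for")

  base <- apply_medium(model, medium, on_missing = "skip")
  r0 <- run_fba(base, threshold = min_flux)
  if (r0$status == "optimal" && r0$objective_value >= min_flux - 1e-9) {
    return(gapfill_result("success", character(0), 0, r0$objective_value,
                          medium_name, model))
  }

  cand_ids <- setdiff(repository$reactions$id, model$reactions$id)
  full <- copy_reactions(model, repository, cand_ids)
  full_med <- apply_medium(full, medium, on_missing = "skip")
  rfull <- run_fba(full_med, threshold = min_flux)
  if (rfull$status != "optimal" || rfull$objective_value < min_flux - 1e-9) {
    return(gapfill_result("infeasible", character(0), NA_real_,
                          rfull$objective_value, medium_name, model))
  }

  # drop candidates that cannot carry flux even in the full augmentation
  # (blocked reactions never help); keeps the search small
  cand_ids <- prune_blocked_candidates(full_med, cand_ids, min_flux)
  if (length(cand_ids) > max_candidates) {
    stop("gap-filling candidate set too large (", length(cand_ids), " > ",
         max_candidates, ")")
  }
  pen <- stats::setNames(rep(1, length(cand_ids)), cand_ids)
  if (!is.null(penalties)) {
    known <- intersect(names(penalties), cand_ids)
    pen[known] <- penalties[known]
  }
  # branch on expensive candidates first so exclusion is tried early
  cand_ids <- cand_ids[order(-pen[cand_ids], cand_ids)]

  search_env <- new.env(parent = emptyenv())
  search_env$best_pen <- Inf
  search_env$best_sets <- list()

  feasible_with <- function(ids) {
    mm <- apply_medium(copy_reactions(model, repository, ids), medium,
                       on_missing = "skip")
    r <- run_fba(mm, threshold = min_flux)
    r$status == "optimal" && r$objective_value >= min_flux - 1e-9
  }

  recurse <- function(included, undecided) {
    inc_pen <- sum(pen[included])
    if (inc_pen > search_env$best_pen + 1e-9) return(invisible())
    if (feasible_with(included)) {
      if (inc_pen < search_env$best_pen - 1e-9) {
        search_env$best_pen <- inc_pen
        search_env$best_sets <- list(sort(included))
      } else {
        search_env$best_sets <- c(search_env$best_sets, list(sort(included)))
      }
      return(invisible())
    }
    if (length(undecided) == 0L) return(invisible())
    if (!feasible_with(c(included, undecided))) return(invisible())
    j <- undecided[1L]
    rest <- undecided[-1L]
    recurse(included, rest)              # exclude j first
    recurse(c(included, j), rest)        # then include j
  }
  recurse(character(0), cand_ids)

  if (!is.finite(search_env$best_pen)) {
    return(gapfill_result("infeasible", character(0), NA_real_, NA_real_,
                          medium_name, model))
  }
  sets <- unique(search_env$best_sets)
  sets <- sets[vapply(sets, function(s) {
    abs(sum(pen[s]) - search_env$best_pen) <= 1e-9
  }, logical(1))]
  keys <- vapply(sets, function(s) paste(s, collapse = "\r"), character(1))
  added <- sets[[order(keys)[1L]]]

  aug <- copy_reactions(model, repository, added)
  check <- run_fba(apply_medium(aug, medium, on_missing = "skip"),
                   threshold = min_flux)
  gapfill_result("success", added, sum(pen[added]), check$objective_value,
                 medium_name, aug)
}

gapfill_result <- function(status, added, total_penalty, objective_value,
                           medium, model) {
  structure(
    list(status = status, added = added, total_penalty = total_penalty,
         objective_value = objective_value, medium = medium, model = model),
    class = "gapfill_result"
  )
}

#' @export
print.gapfill_result <- function(x, ...) {
  cat("<gapfill_result> ", x$status, " on '", x$medium, "': ",
      length(x$added), " reaction(s), total penalty ",
      format(x$total_penalty), "\n", sep = "")
  invisible(x)
}

#' Tidy a gap-fill result into one row per added reaction
#' @param x A `gapfill_result`.
#' @param ... Unused.
#' @return Tibble with `reaction` and `medium`.
#' @export
tidy.gapfill_result <- function(x, ...) {
  tibble::tibble(reaction = x$added, medium = x$medium)
}

#' One-row summary of a gap-fill result
#' @param x A `gapfill_result`.
#' @param ... Unused.
#' @return One-row tibble: `status`, `medium`, `n_added`, `total_penalty`,
#'   `objective_value`.
#' @export
glance.gapfill_result <- function(x, ...) {
  tibble::tibble(status = x$status, medium = x$medium,
                 n_added = length(x$added), total_penalty = x$total_penalty,
                 objective_value = x$objective_value)
}

# Candidates unable to carry any flux in the fully augmented model cannot
# contribute to a gap-filling solution.
prune_blocked_candidates <- function(full_model, cand_ids, min_flux) {
  S <- stoichiometric_matrix(full_model)
  lower <- full_model$reactions$lower
  upper <- full_model$reactions$upper
  keep <- vapply(cand_ids, function(rid) {
    j <- match(rid, full_model$reactions$id)
    fmax <- lp_solve(as.numeric(seq_along(lower) == j), S, rep(0, nrow(S)),
                     lower, upper, maximize = TRUE)
    if (fmax$status == "optimal" && fmax$value > 1e-9) return(TRUE)
    fmin <- lp_solve(as.numeric(seq_along(lower) == j), S, rep(0, nrow(S)),
                     lower, upper, maximize = FALSE)
    fmin$status == "optimal" && fmin$value < -1e-9
  }, logical(1))
  cand_ids[keep]
}
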