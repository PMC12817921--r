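# Reference-based expansion: translate a curated reference GSMM into
# cluster space via bidirectional best hits (BRH), expand it with new
# content from the reference-free draft, and supplement orphan GPRs.

REFONLY_PREFIX <- "REFONLY__"

#' Bidirectional best hits between strain proteomes and a reference proteome
#'
#' For each strain, every gene is aligned against every reference gene
#' (global, ends-free). A pair is scored `identity * min(coverage_a,
#' coverage_b)` and considered only when identity is at least `id_min` and
#' both coverages at least `cov_min`. The pair (g, r) is kept iff r is g's
#' best hit and g is r's best hit within that strain; score ties are broken
#' by lexicographic gene id.
#'
#' @param strain_proteins Tibble `gene_id`, `strain`, `seq`.
#' @param reference_proteins Tibble `gene_id`, `seq`.
#' @param id_min Minimum identity (default 0.40).
#' @param cov_min Minimum coverage of both partners (default 0.70).
#' @return Tibble `strain`, `strain_gene`, `ref_gene`, `score`.
#' @export
brh_map <- function(strain_proteins, reference_proteins, id_min = 0.40,
                    cov_min = 0.70) {
  stopifnot(nrow(strain_proteins) > 0, nrow(reference_proteins) > 0)
  out <- lapply(split(strain_proteins, strain_proteins$strain), function(sp) {
    hits <- dplyr::bind_rows(lapply(seq_len(nrow(sp)), function(i) {
      st <- align_identity_many(reference_proteins$seq, sp$seq[i])
      ok <- st$identity >= id_min & st$cov_pattern >= cov_min &
        st$cov_subject >= cov_min
      if (!any(ok)) return(NULL)
      tibble::tibble(strain_gene = sp$gene_id[i],
                     ref_gene = reference_proteins$gene_id[ok],
                     score = st$identity[ok] * pmin(st$cov_pattern[ok],
                                                    st$cov_subject[ok]))
    }))
    if (nrow(hits) == 0L) return(NULL)
    best_of <- function(tab, by) {
      tab <- tab[order(-tab$score, tab$strain_gene, tab$ref_gene), ]
      tab[!duplicated(tab[[by]]), ]
    }
    fwd <- best_of(hits, "strain_gene")
    rev <- best_of(hits, "ref_gene")
    pairs <- dplyr::inner_join(fwd, rev,
                               by = c("strain_gene", "ref_gene", "score"))
    if (nrow(pairs) == 0L) return(NULL)
    tibble::tibble(strain = sp$strain[1L], pairs)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble::tibble(strain = character(0), strain_gene = character(0),
                          ref_gene = character(0), score = numeric(0)))
  }
  dplyr::arrange(res, .data$strain, .data$strain_gene)
}

#' Translate a reference model's GPRs into cluster space
#'
#' Each reference gene is assigned to the cluster holding the majority of
#' its BRH partners across strains (ties go to the smallest cluster id);
#' reference genes without any partner become reference-only placeholder
#' leaves (prefix `REFONLY__`) that evaluate absent for every strain during
#' derivation, so the reaction stays in the pan model but is dropped from
#' every strain-specific model. Reactions, bounds, the biomass objective,
#' and metabolites are copied verbatim.
#'
#' @param reference The curated reference `metabolic_model`.
#' @param brh BRH pair table from [brh_map()].
#' @param pam The [build_pam()] object (supplies gene -> cluster).
#' @return List with `model` (translated reference), `assignments` (tibble
#'   `ref_gene`, `cluster`, `n_partners`, `n_agreeing`, `ambiguous`), and
#'   `unmapped` (reference genes without partners).
#' @export
translate_reference_gprs <- function(reference, brh, pam) {
  gene2cluster <- stats::setNames(pam$genes$cluster, pam$genes$gene_id)
  ref_genes <- unique(unlist(lapply(reference$reactions$gpr, gpr_genes)))
  brh$cluster <- gene2cluster[brh$strain_gene]
  missing <- brh$strain_gene[is.na(brh$cluster)]
  if (length(missing)) {
    stop("BRH partner genes not present in the PAM: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  assignments <- dplyr::bind_rows(lapply(ref_genes, function(rg) {
    part <- brh[brh$ref_gene == rg, ]
    if (nrow(part) == 0L) {
      return(tibble::tibble(ref_gene = rg, cluster = NA_character_,
                            n_partners = 0L, n_agreeing = 0L,
                            ambiguous = FALSE))
    }
    votes <- sort(table(part$cluster), decreasing = TRUE)
    winners <- names(votes)[votes == max(votes)]
    tibble::tibble(ref_gene = rg, cluster = sort(winners)[1L],
                   n_partners = nrow(part),
                   n_agreeing = as.integer(max(votes)),
                   ambiguous = length(unique(part$cluster)) > 1L)
  }))
  mapping <- stats::setNames(as.list(ifelse(
    is.na(assignments$cluster),
    paste0(REFONLY_PREFIX, assignments$ref_gene),
    assignments$cluster
  )), assignments$ref_gene)
  model <- reference
  model$reactions$gpr <- lapply(model$reactions$gpr, gpr_substitute,
                                mapping = mapping)
  model$id <- paste0(reference$id, "_translated")
  list(model = model,
       assignments = assignments,
       unmapped = assignments$ref_gene[is.na(assignments$cluster)])
}

#' Expand a translated reference model with draft pan content
#'
#' Starts from the translated reference and adds every draft reaction whose
#' id is absent, provided it is not element/charge-unbalanced when its
#' metabolites are resolved with reference-priority definitions (the
#' reference's formula and charge win when the metabolite id already
#' exists; an `undetermined` verdict passes unless `strict_balance`).
#' Missing metabolites are added. The biomass objective and the NGAM
#' (non-growth associated maintenance, identified by `ngam_id`) keep the
#' reference bounds untouched. An override table may force metabolite
#' formulas/charges or whitelist reactions past the balance check.
#'
#' @param translated_ref Translated reference model (see
#'   [translate_reference_gprs()]).
#' @param draft Reference-free draft pan `metabolic_model` (cluster-space
#'   GPRs).
#' @param ngam_id NGAM reaction id (default `"ATPM"`).
#' @param overrides Optional tibble with any of: `metabolite_id`, `formula`,
#'   `charge` rows forcing definitions; `reaction_id`, `allow` rows
#'   whitelisting reactions.
#' @param strict_balance If `TRUE`, `undetermined` verdicts also block
#'   addition (default `FALSE`).
#' @return List with `model` (expanded pan) and `report` (tibble `reaction`,
#'   `action`, `detail`).
#' @export
expand_with_draft <- function(translated_ref, draft, ngam_id = "ATPM",
                              overrides = NULL, strict_balance = FALSE) {
  model <- translated_ref
  report <- list()
  note <- function(reaction, action, detail = "") {
    report[[length(report) + 1L]] <<- tibble::tibble(
      reaction = reaction, action = action, detail = detail)
  }

  allow <- character(0)
  if (!is.null(overrides)) {
    overrides <- tibble::as_tibble(overrides)
    if (all(c("metabolite_id", "formula") %in% names(overrides))) {
      met_or <- overrides[!is.na(overrides$metabolite_id) &
                            overrides$metabolite_id != "", ]
      for (k in seq_len(nrow(met_or))) {
        i <- match(met_or$metabolite_id[k], model$metabolites$id)
        if (!is.na(i)) {
          model$metabolites$formula[i] <- met_or$formula[k]
          if ("charge" %in% names(met_or)) {
            model$metabolites$charge[i] <- as.integer(met_or$charge[k])
          }
        }
      }
    }
    if ("reaction_id" %in% names(overrides)) {
      allow <- overrides$reaction_id[!is.na(overrides$reaction_id)]
    }
  }

  new_rxns <- draft$reactions[!draft$reactions$id %in% model$reactions$id, ]
  for (i in seq_len(nrow(new_rxns))) {
    r <- new_rxns[i, ]
    # id collision with differing stoichiometry cannot happen here (absent
    # ids only); metabolite resolution prefers reference definitions
    stoich <- r$stoich[[1L]]
    probe <- model
    add_mets <- setdiff(names(stoich), probe$metabolites$id)
    if (length(add_mets)) {
      probe$metabolites <- dplyr::bind_rows(
        probe$metabolites,
        draft$metabolites[match(add_mets, draft$metabolites$id), ]
      )
    }
    verdict <- check_balance(stoich, probe)$verdict
    blocked <- verdict == "unbalanced" ||
      (strict_balance && verdict == "undetermined")
    if (blocked && !r$id %in% allow) {
      note(r$id, "skipped_unbalanced", verdict)
      next
    }
    probe$reactions <- dplyr::bind_rows(probe$reactions, r)
    model <- probe
    note(r$id, "added", verdict)
  }
  model$id <- paste0(translated_ref$id, "_expanded")
  report <- if (length(report)) dplyr::bind_rows(report) else
    tibble::tibble(reaction = character(0), action = character(0),
                   detail = character(0))
  list(model = validate_model(model), report = report)
}

#' Supplement orphan GPRs from the reference-free draft
#'
#' Every expanded-pan reaction with an EMPTY GPR and `spontaneous = FALSE`
#' whose id also exists in the draft with a non-empty GPR receives the
#' draft's cluster-space GPR. Non-empty GPRs are never overwritten, so the
#' orphan count can only decrease.
#'
#' @param expanded The expanded pan `metabolic_model`.
#' @param draft The reference-free draft pan `metabolic_model`.
#' @return The supplemented model.
#' @export
supplement_orphan_gprs <- function(expanded, draft) {
  for (i in seq_len(nrow(expanded$reactions))) {
    if (!gpr_is_empty(expanded$reactions$gpr[[i]])) next
    if (expanded$reactions$spontaneous[i]) next
    j <- match(expanded$reactions$id[i], draft$reactions$id)
    if (is.na(j)) next
    g <- draft$reactions$gpr[[j]]
    if (gpr_is_empty(g) || gpr_is_unsat(g)) next
    expanded$reactions$gpr[[i]] <- g
  }
  expanded
}

#' Read a metabolite/reaction override table
#' @param path TSV with columns `metabolite_id`, `formula`, `charge`,
#'   `reaction_id`, `allow` (any subset).
#' @return Tibble.
#' @export
read_overrides_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
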