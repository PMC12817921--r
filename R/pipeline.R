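# End-to-end orchestration mirroring the tool's three programs:
#   recon_pipeline()    QC -> clustering -> recovery -> carving
#                       [-> reference translation/expansion/supplement]
#   derive_pipeline()   strain derivation -> per-medium gap-fill -> BFTs
#   autopilot_pipeline()recon -> automated penalty-weighted gap-fill of the
#                       draft pan -> derive
# plus analyze_pipeline() for the multi-strain step.

#' Reconstruct a (pan-)GSMM from proteomes and a reaction universe
#'
#' Runs quality filtering (when completeness/genome data are given),
#' greedy protein clustering, optional three-scenario gene recovery (when
#' genomes + GFFs are given), reference-free carving, and — when a curated
#' reference model plus proteome are supplied — BRH translation, expansion
#' with draft content, and orphan GPR supplementation.
#'
#' @param proteins Tibble `gene_id`, `strain`, `seq` over all strains.
#' @param universe Universe `metabolic_model` (sentinel-normalized).
#' @param universe_genes Tibble `gene_id`, `seq` for universal genes.
#' @param genomes Optional named list of `DNAStringSet` per strain.
#' @param gffs Optional named list of gene-coordinate tibbles per strain.
#' @param reference,reference_proteome Optional curated reference
#'   `metabolic_model` and its proteome tibble (`gene_id`, `seq`).
#' @param completeness Optional completeness tibble for [qc_filter()].
#' @param thresholds [qc_thresholds()] used when `completeness` is given.
#' @param cluster_identity,cluster_cov Clustering thresholds.
#' @param map_id_min,map_cov_min Universe-mapping thresholds.
#' @param ngam_id NGAM reaction id for expansion (default "ATPM").
#' @param overrides Optional expansion override table.
#' @return List with `pan` (final pan model), `draft` (reference-free
#'   draft), `pam`, `clustering`, `support`, `qc` (QC report or NULL),
#'   `recovered` (recovery records), `expansion_report`, `brh`,
#'   `translation`, and `strains` (kept strain ids).
#' @export
recon_pipeline <- function(proteins, universe, universe_genes,
                           genomes = NULL, gffs = NULL,
                           reference = NULL, reference_proteome = NULL,
                           completeness = NULL,
                           thresholds = qc_thresholds(),
                           cluster_identity = 0.90, cluster_cov = 0.70,
                           map_id_min = 0.40, map_cov_min = 0.70,
                           ngam_id = "ATPM", overrides = NULL) {
  qc <- NULL
  strains <- sort(unique(proteins$strain))
  if (!is.null(completeness)) {
    if (is.null(genomes)) stop("QC filtering needs genomes for assembly stats")
    stats <- dplyr::bind_rows(lapply(strains, function(s) {
      assembly_stats(genomes[[s]], strain = s)
    }))
    qc <- qc_filter(stats, completeness, thresholds)
    strains <- qc$strain[qc$keep]
    proteins <- proteins[proteins$strain %in% strains, ]
  }

  clustering <- cluster_proteins(proteins, identity = cluster_identity,
                                 cov_long = cluster_cov,
                                 cov_short = cluster_cov)
  pam <- build_pam(clustering, strains = strains)

  recovered <- empty_recovery_records()
  if (!is.null(genomes) && !is.null(gffs)) {
    for (s in intersect(strains, intersect(names(genomes), names(gffs)))) {
      if (is.null(gffs[[s]]) || nrow(gffs[[s]]) == 0L) next
      out <- recover_genes(genomes[[s]], gffs[[s]], clustering, pam, s,
                           proteins[proteins$strain == s,
                                    c("gene_id", "seq")])
      recovered <- dplyr::bind_rows(recovered, out$records)
      pam <- out$pam
    }
  }

  support <- map_clusters_to_universe(clustering$representatives,
                                      universe_genes,
                                      id_min = map_id_min,
                                      cov_min = map_cov_min)
  draft <- carve_draft_pan(universe, support)

  brh <- NULL
  translation <- NULL
  expansion_report <- NULL
  pan <- draft
  if (!is.null(reference)) {
    if (is.null(reference_proteome)) {
      stop("a reference model needs its proteome for BRH translation")
    }
    brh <- brh_map(proteins, reference_proteome)
    translation <- translate_reference_gprs(reference, brh, pam)
    expanded <- expand_with_draft(translation$model, draft,
                                  ngam_id = ngam_id, overrides = overrides)
    expansion_report <- expanded$report
    pan <- supplement_orphan_gprs(expanded$model, draft)
    pan$id <- "pan_gsmm"
  }

  list(pan = pan, draft = draft, pam = pam, clustering = clustering,
       support = support, qc = qc, recovered = recovered,
       expansion_report = expansion_report, brh = brh,
       translation = translation, strains = strains)
}

#' Derive strain-specific models and phenotype BFTs from a pan-GSMM
#'
#' @param pan The pan `metabolic_model`.
#' @param pam The [build_pam()] object.
#' @param media A [medium_recipe()] or ordered list for gap-filling.
#' @param min_flux Gap-filling minimum objective flux.
#' @param skip_gapfill Skip the strain-level gap-filling step.
#' @param penalties Optional penalty table for gap-filling.
#' @param strains Strains to derive (default: all PAM columns).
#' @return List with `models` (named list of strain models), `reaction_bft`,
#'   and `report` (per-strain tibble: reactions, metabolites, gap-filled
#'   ids per medium).
#' @export
derive_pipeline <- function(pan, pam, media = NULL, min_flux = 0.001,
                            skip_gapfill = FALSE, penalties = NULL,
                            strains = pam$strains) {
  models <- lapply(stats::setNames(strains, strains), function(s) {
    m <- derive_strain(pan, pam, s)
    if (!is.null(media)) {
      m <- gapfill_strain(m, pan, media, min_flux = min_flux,
                          skip = skip_gapfill, penalties = penalties)
    }
    m
  })
  report <- dplyr::bind_rows(lapply(models, function(m) {
    tibble::tibble(
      strain = m$strain,
      n_reactions = nrow(m$reactions),
      n_metabolites = nrow(m$metabolites),
      gapfilled = paste(unlist(m$gapfilled), collapse = ",")
    )
  }))
  list(models = models, reaction_bft = reaction_bft(models), report = report)
}

#' Autopilot: reconstruction and derivation without manual curation
#'
#' Runs [recon_pipeline()], replaces manual curation by an automated
#' penalty-weighted gap-fill of the draft pan on the given (or default
#' minimal) medium using [compute_penalties()] evidence, then derives all
#' strain models.
#'
#' @inheritParams recon_pipeline
#' @inheritParams derive_pipeline
#' @param medium Medium for the pan-level gap-fill; defaults to
#'   [default_minimal_medium()] of the draft pan.
#' @param ... Passed to [recon_pipeline()].
#' @return The [recon_pipeline()] list, plus `pan_gapfill`
#'   (a `gapfill_result`) and the [derive_pipeline()] outputs under
#'   `derive`.
#' @export
autopilot_pipeline <- function(proteins, universe, universe_genes,
                               medium = NULL, media = NULL,
                               min_flux = 0.001, skip_gapfill = FALSE, ...) {
  recon <- recon_pipeline(proteins, universe, universe_genes, ...)
  if (is.null(medium)) medium <- default_minimal_medium(recon$draft)
  penalties <- compute_penalties(universe, recon$support)
  gf <- gapfill_min_penalty(recon$pan, universe, medium,
                            min_flux = min_flux, penalties = penalties)
  if (gf$status == "success") recon$pan <- gf$model
  recon$pan_gapfill <- gf
  recon$derive <- derive_pipeline(recon$pan, recon$pam,
                                  media = media %||% list(medium),
                                  min_flux = min_flux,
                                  skip_gapfill = skip_gapfill)
  recon
}

#' Multi-strain analysis over BFTs
#'
#' Merges the given BFTs, computes Jaccard distances and the Ward
#' phylometabolic tree, extracts `k` clusters, and ranks per-cluster
#' characteristic features.
#'
#' @param bfts List of BFT tibbles.
#' @param k Number of clusters to extract.
#' @param drop_constant,exclude Passed to [merge_bfts()].
#' @return List with `bft`, `dist`, `tree`, `clusters`, `frequencies`,
#'   `newick`.
#' @export
analyze_pipeline <- function(bfts, k, drop_constant = FALSE, exclude = NULL) {
  bft <- merge_bfts(bfts, drop_constant = drop_constant, exclude = exclude)
  d <- jaccard_distance_matrix(bft)
  tree <- ward_dendrogram(d)
  cl <- extract_clusters(tree, k)
  freq <- cluster_feature_frequencies(bft, cl)
  list(bft = bft, dist = d, tree = tree, clusters = cl, frequencies = freq,
       newick = write_newick(tree))
}

#' Write a reproducibility manifest
#'
#' Records inputs, configuration, seed, package version, and a content
#' hash, sufficient to reproduce a run bit-identically.
#'
#' @param path Output JSON path.
#' @param config Named list of configuration values.
#' @param seed The RNG seed used.
#' @param inputs Named character vector/list of input descriptions.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, inputs = list()) {
  manifest <- list(
    package = "panmet",
    version = as.character(utils::packageVersion("panmet")),
    seed = seed,
    config = config,
    inputs = inputs,
    config_hash = rlang::hash(list(seed = seed, config = config)),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
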