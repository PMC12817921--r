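# Lazily built, cached synthetic-world artifacts shared across test files.
# Everything derives from seed 42; builders run at most once per session.

.world_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.world_cache[[key]])) .world_cache[[key]] <- builder()
  .world_cache[[key]]
}

tw <- function() cached("world", function() generate_world(seed = 42))

tw_clustering <- function() cached("clustering", function() {
  w <- tw()
  kept <- w$proteins[w$proteins$strain %in% w$roster$strain, ]
  cluster_proteins(kept)
})

# PAM after clustering + recovery on the three planted strains
tw_pam <- function() cached("pam", function() {
  w <- tw()
  cl <- tw_clustering()
  pam <- build_pam(cl, strains = w$roster$strain)
  kept <- w$proteins[w$proteins$strain %in% w$roster$strain, ]
  recs <- list()
  for (s in unname(w$rec_strains)) {
    out <- recover_genes(w$genomes[[s]], w$gffs[[s]], cl, pam, s,
                         kept[kept$strain == s, c("gene_id", "seq")])
    recs[[s]] <- out$records
    pam <- out$pam
  }
  attr(pam, "recovery_records") <- dplyr::bind_rows(recs)
  pam
})

# support map, reference-free draft, BRH, translation, expanded pan
tw_recon <- function() cached("recon", function() {
  w <- tw()
  cl <- tw_clustering()
  pam <- tw_pam()
  support <- map_clusters_to_universe(cl$representatives, w$universe_genes)
  draft <- carve_draft_pan(w$universe, support)
  kept <- w$proteins[w$proteins$strain %in% w$roster$strain, ]
  brh <- brh_map(kept, w$reference_proteome)
  translation <- translate_reference_gprs(w$reference, brh, pam)
  expansion <- expand_with_draft(translation$model, draft)
  pan <- supplement_orphan_gprs(expansion$model, draft)
  list(support = support, draft = draft, brh = brh,
       translation = translation, expansion = expansion, pan = pan)
})

# derived strain models (pre gap-fill) under the hybrid pan
tw_models <- function() cached("models", function() {
  w <- tw()
  pam <- tw_pam()
  pan <- tw_recon()$pan
  lapply(stats::setNames(w$roster$strain, w$roster$strain),
         function(s) derive_strain(pan, pam, s))
})

# family-labelled truth support/draft built from planted representatives
# (used where the clustering stage itself is not under test)
planted_recon <- function(world) {
  reps <- tibble::tibble(cluster = world$families$family,
                         seq = world$families$base_seq)
  support <- map_clusters_to_universe(reps, world$universe_genes)
  draft <- carve_draft_pan(world$universe, support)
  list(support = support, draft = draft)
}
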