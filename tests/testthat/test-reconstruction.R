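test_that("universe mapping honors identity and coverage thresholds", {
  set.seed(21)
  u <- tibble::tibble(gene_id = c("U_a", "U_b"),
                      seq = c(random_aa_seq(150), random_aa_seq(150)))
  reps <- tibble::tibble(
    cluster = c("C1", "C2", "C3"),
    seq = c(u$seq[1],                       # identical to U_a
            mutate_seq(u$seq[2], 0.3),      # ~70% identity to U_b
            random_aa_seq(150))             # unrelated
  )
  sup <- map_clusters_to_universe(reps, u)
  expect_equal(sup$identity[sup$cluster == "C1" & sup$universal_gene == "U_a"], 1)
  expect_true(all(sup$identity >= 0.40 & sup$coverage >= 0.70))
  expect_false("C3" %in% sup$cluster)
  # planted world: every family representative supports exactly its own
  # universal gene
  w <- tw()
  reps_w <- tibble::tibble(cluster = w$families$family,
                           seq = w$families$base_seq)
  sup_w <- map_clusters_to_universe(reps_w, w$universe_genes)
  expect_equal(nrow(sup_w), nrow(w$families))
  expect_equal(sup_w$universal_gene[match(w$families$family, sup_w$cluster)],
               w$families$universal_gene)
})

test_that("carving preserves complexes: AND demands all members", {
  w <- tw()
  pr <- planted_recon(w)
  draft <- pr$draft
  # decoy reactions: AND with an unsupported member, and an isolated
  # unsupported gene -> both excluded
  expect_false("DECOYAND" %in% draft$reactions$id)
  expect_false("DECOY2" %in% draft$reactions$id)
  # OR with one supported branch is included
  expect_true("AAS" %in% draft$reactions$id)
  # spontaneous and EMPTY-GPR reactions are retained
  expect_true(all(c("O2t", "CO2t", "ATPM", "BIOMASS") %in% draft$reactions$id))
  # exchanges exist for all retained extracellular metabolites, with the
  # closed-uptake convention
  types <- reaction_types(draft)
  e_mets <- draft$metabolites$id[draft$metabolites$compartment == "e"]
  ex_mets <- vapply(draft$reactions$stoich[types == "exchange"],
                    function(s) names(s)[1], character(1))
  expect_setequal(ex_mets, e_mets)
  expect_true(all(draft$reactions$lower[types == "exchange"] == 0))
})

test_that("saturated support reproduces the universe's internal reactions", {
  w <- tw()
  all_genes <- c(w$families$universal_gene, "U_dec1", "U_dec2")
  sup_full <- tibble::tibble(universal_gene = all_genes,
                             cluster = paste0("CX", seq_along(all_genes)),
                             identity = 1, coverage = 1, score = 1)
  draft <- carve_draft_pan(w$universe, sup_full)
  internal_u <- w$universe$reactions$id[reaction_types(w$universe) == "internal"]
  internal_d <- draft$reactions$id[reaction_types(draft) == "internal"]
  expect_setequal(internal_d, internal_u)
})

test_that("carving is monotone in support", {
  w <- tw()
  pr <- planted_recon(w)
  sup <- pr$support
  set.seed(31)
  for (k in 1:5) {
    drop <- sample(nrow(sup), 5)
    smaller <- carve_draft_pan(w$universe, sup[-drop, ])
    expect_true(all(smaller$reactions$id %in% pr$draft$reactions$id))
  }
  # internal reactions always a subset of the universe's
  internal_u <- w$universe$reactions$id[reaction_types(w$universe) == "internal"]
  expect_true(all(pr$draft$reactions$id[reaction_types(pr$draft) == "internal"]
                  %in% internal_u))
})

test_that("carving requires a universe biomass", {
  w <- tw()
  u <- w$universe
  u$objective <- NA_character_
  expect_error(carve_draft_pan(u, planted_recon(w)$support), "biomass")
})

test_that("penalties span [p_min, p_max] and respect the GPR structure", {
  w <- tw()
  pr <- planted_recon(w)
  pen <- compute_penalties(w$universe, pr$support)
  expect_equal(unname(pen["HEX"]), 0.1, tolerance = 0.15)   # fully supported
  expect_equal(unname(pen["DECOY2"]), 10)                   # unsupported
  # spontaneous and exchange reactions get p_min exactly
  expect_equal(unname(pen["O2t"]), 0.1)
  expect_equal(unname(pen["EX_glc__D_e"]), 0.1)
  # AND takes the worst member: removing glycB support maximizes GLYC
  sup2 <- pr$support[pr$support$universal_gene != "U_glycB", ]
  pen2 <- compute_penalties(w$universe, sup2)
  expect_equal(unname(pen2["GLYC"]), 10)
  expect_equal(unname(pen2["HEX"]), unname(pen["HEX"]))
})

test_that("penalties are monotone non-increasing in any per-gene score", {
  set.seed(41)
  w <- tw()
  pr <- planted_recon(w)
  sup <- pr$support
  pen0 <- compute_penalties(w$universe, sup)
  for (k in 1:20) {
    i <- sample(nrow(sup), 1)
    sup2 <- sup
    sup2$score[i] <- sup2$score[i] * stats::runif(1)    # degrade one score
    pen2 <- compute_penalties(w$universe, sup2)
    expect_true(all(pen2 >= pen0 - 1e-12))
  }
})
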