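test_that("identical proteomes give the identity BRH mapping", {
  set.seed(61)
  seqs <- replicate(5, random_aa_seq(80))
  ref <- tibble::tibble(gene_id = paste0("r", 1:5), seq = seqs)
  strain <- tibble::tibble(gene_id = paste0("g", 1:5), strain = "s1",
                           seq = seqs)
  pairs <- brh_map(strain, ref)
  expect_equal(nrow(pairs), 5)
  expect_equal(pairs$ref_gene, paste0("r", as.integer(sub("g", "", pairs$strain_gene))))
})

test_that("BRH pairs equal the brute-force mutual-best oracle", {
  set.seed(62)
  for (rep_k in 1:12) {
    n <- 8
    fams <- replicate(n, random_aa_seq(sample(50:90, 1)))
    ref <- tibble::tibble(gene_id = sprintf("r%02d", 1:n), seq = fams)
    # strain genes: mostly family variants, some unrelated, one duplicated
    # family (competition for the same reference gene)
    pick <- sample(n, n, replace = TRUE)
    strain <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:n), strain = "s1",
      seq = vapply(pick, function(f) mutate_seq(fams[f], 0.1), "")
    )
    pairs <- brh_map(strain, ref)

    # oracle: full score matrix, then explicit mutual-best with
    # lexicographic tie-breaks
    score <- matrix(0, n, n, dimnames = list(strain$gene_id, ref$gene_id))
    for (i in 1:n) for (j in 1:n) {
      a <- align_identity(ref$seq[j], strain$seq[i])
      sc <- a$identity * min(a$cov_a, a$cov_b)
      if (a$identity >= 0.40 && a$cov_a >= 0.70 && a$cov_b >= 0.70) {
        score[i, j] <- sc
      }
    }
    expected <- list()
    for (i in 1:n) {
      if (all(score[i, ] == 0)) next
      j <- which(score[i, ] == max(score[i, ]))[1]
      i_back <- which(score[, j] == max(score[, j]))[1]
      if (i_back == i) {
        expected[[length(expected) + 1]] <-
          c(strain$gene_id[i], ref$gene_id[j])
      }
    }
    got <- paste(pairs$strain_gene, pairs$ref_gene)
    want <- vapply(expected, paste, collapse = " ", FUN.VALUE = "")
    expect_setequal(got, want)
  }
})

test_that("reference genes translate to majority clusters or placeholders", {
  pam <- build_pam(tibble::tibble(
    gene_id = c("a1", "a2", "a3", "b1"),
    strain = c("s1", "s2", "s3", "s1"),
    cluster = c("C3", "C3", "C7", "C5")
  ), strains = paste0("s", 1:3))
  ref <- metabolic_model(
    "ref",
    tibble::tibble(id = "m_c", formula = "", charge = NA_integer_,
                   compartment = "c"),
    tibble::tibble(id = c("R1", "R2"), name = "r",
                   stoich = list(c(m_c = 1), c(m_c = -1)),
                   lower = 0, upper = 10,
                   gpr = list(gpr_leaf("rg1"), gpr_leaf("rg2")),
                   spontaneous = FALSE,
                   annotations = list(list(), list())),
    objective = "R1")
  brh <- tibble::tibble(
    strain = c("s1", "s2", "s3"),
    strain_gene = c("a1", "a2", "a3"),
    ref_gene = "rg1", score = 1)
  tr <- translate_reference_gprs(ref, brh, pam)
  # majority C3 (2 votes) over C7 (1)
  expect_equal(tr$model$reactions$gpr[[1]]$gene, "C3")
  expect_true(tr$assignments$ambiguous[tr$assignments$ref_gene == "rg1"])
  # rg2 has no partners: placeholder leaf, reaction retained
  expect_equal(tr$unmapped, "rg2")
  expect_equal(tr$model$reactions$gpr[[2]]$gene,
               paste0(panmet:::REFONLY_PREFIX, "rg2"))
  # reactions/bounds copied verbatim
  expect_equal(tr$model$reactions$lower, ref$reactions$lower)
})

test_that("on the synthetic world, translation matches the planted families", {
  w <- tw()
  tr <- tw_recon()$translation
  cl <- tw_clustering()
  fam_cluster <- stats::setNames(cl$members$cluster,
                                 sub("^S\\d+_", "", cl$members$gene_id))
  asg <- tr$assignments[!is.na(tr$assignments$cluster), ]
  for (k in seq_len(nrow(asg))) {
    fam <- sub("^R_", "", asg$ref_gene[k])
    expect_equal(asg$cluster[k], unname(fam_cluster[fam]))
  }
  expect_equal(tr$unmapped, "R_refonly")
})

test_that("expansion with a subset draft returns the reference unchanged", {
  w <- tw()
  tr <- tw_recon()$translation
  sub_draft <- subset_model(tw_recon()$draft,
                            intersect(tw_recon()$draft$reactions$id,
                                      tr$model$reactions$id))
  out <- expand_with_draft(tr$model, sub_draft)
  expect_setequal(out$model$reactions$id, tr$model$reactions$id)
  expect_equal(sum(out$report$action == "added"), 0)
})

test_that("expansion adds the planted xylose path and skips unbalanced content", {
  rec <- tw_recon()
  w <- tw()
  expect_true(all(c("XYLt", "XYLI", "XYLK", "EX_xyl__D_e") %in%
                    rec$pan$reactions$id))
  skipped <- rec$expansion$report
  expect_equal(skipped$reaction[skipped$action == "skipped_unbalanced"],
               "BADRXN")
  expect_false("BADRXN" %in% rec$pan$reactions$id)
  # expanded pan contains every translated reference reaction
  expect_true(all(rec$translation$model$reactions$id %in% rec$pan$reactions$id))
  # biomass and NGAM bounds inherited bit-exactly from the reference
  for (rid in c("BIOMASS", "ATPM")) {
    i <- match(rid, rec$pan$reactions$id)
    j <- match(rid, w$reference$reactions$id)
    expect_identical(rec$pan$reactions$lower[i], w$reference$reactions$lower[j])
    expect_identical(rec$pan$reactions$upper[i], w$reference$reactions$upper[j])
  }
  expect_identical(rec$pan$objective, w$reference$objective)
  # nothing added is unbalanced under reference-priority definitions
  for (rid in skipped$reaction[skipped$action == "added"]) {
    expect_false(check_balance(rid, rec$pan)$verdict == "unbalanced")
  }
})

test_that("metabolite overrides can whitelist an unbalanced candidate", {
  rec <- tw_recon()
  out <- expand_with_draft(rec$translation$model, rec$draft,
                           overrides = tibble::tibble(reaction_id = "BADRXN",
                                                      allow = TRUE))
  expect_true("BADRXN" %in% out$model$reactions$id)
})

test_that("orphan GPR supplementation copies draft rules and is monotone", {
  rec <- tw_recon()
  expanded <- rec$expansion$model
  before <- count_orphans(expanded)
  supplemented <- supplement_orphan_gprs(expanded, rec$draft)
  after <- count_orphans(supplemented)
  expect_lte(after$count, before$count)
  # the curated orphan (NUCS) received the draft's cluster-space GPR
  i <- match("NUCS", supplemented$reactions$id)
  expect_false(gpr_is_empty(supplemented$reactions$gpr[[i]]))
  j <- match("NUCS", rec$draft$reactions$id)
  expect_true(gpr_identical(supplemented$reactions$gpr[[i]],
                            rec$draft$reactions$gpr[[j]]))
  # non-empty GPRs are never overwritten
  k <- match("HEX", supplemented$reactions$id)
  expect_true(gpr_identical(supplemented$reactions$gpr[[k]],
                            expanded$reactions$gpr[[match("HEX", expanded$reactions$id)]]))
  # orphans absent from the draft stay unchanged (biomass, NGAM)
  for (rid in c("BIOMASS", "ATPM")) {
    ii <- match(rid, supplemented$reactions$id)
    expect_true(gpr_is_empty(supplemented$reactions$gpr[[ii]]))
  }
})
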