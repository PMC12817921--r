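test_that("substrate calls: default source reproduces base growth, missing exchange scores 0", {
  w <- tw()
  models <- tw_models()
  base_med <- w$media$minimal_trp
  for (s in c(w$roster$strain[w$roster$group == "G1"][1],
              w$roster$strain[w$roster$group == "G3"][1])) {
    m <- models[[s]]
    out <- phenotype_substrates(m, base_med, "C",
                                c("glc__D", "xyl__D", "fru"))
    base_growth <- run_fba(apply_medium(m, base_med, on_missing = "skip"),
                           threshold = 1e-4)
    expect_equal(out$value[out$feature == "C_source:glc__D"],
                 as.integer(base_growth$grows))
    expect_equal(out$value[out$feature == "C_source:fru"], 0L)
  }
  expect_error(phenotype_substrates(models[[1]], medium_recipe(c(nh4_e = 10)),
                                    "C", "glc__D"), "source")
})

test_that("phenotype BFTs equal planted truth across all strains", {
  w <- tw()
  models <- tw_models()
  subs <- lapply(models, phenotype_substrates,
                 base_medium = w$media$minimal_trp, element = "C",
                 candidates = c("glc__D", "xyl__D", "fru"))
  aux <- lapply(models, phenotype_auxotrophies,
                minimal_medium = w$media$minimal, compounds = "trp__L")
  bio <- suppressWarnings(
    lapply(models, phenotype_biosynthesis, medium = w$media$minimal_trp,
           targets = "hista_c"))
  cmp_bft <- function(got_list, truth) {
    got <- build_bft(lapply(got_list, function(x) x[, c("feature", "value")]))
    cols <- c("feature", sort(bft_strains(truth)))
    got <- got[order(got$feature), cols]
    truth <- truth[order(truth$feature), cols]
    expect_equal(as.data.frame(got), as.data.frame(truth),
                 ignore_attr = TRUE)
  }
  cmp_bft(subs, expected_truth(w, "substrates"))
  cmp_bft(aux, expected_truth(w, "auxotrophies"))
  cmp_bft(bio, expected_truth(w, "biosynthesis"))
})

test_that("auxotrophy is biosynthetic incapacity, unaffected by supplementation", {
  w <- tw()
  models <- tw_models()
  g3 <- w$roster$strain[w$roster$group == "G3"][1]
  g1 <- w$roster$strain[w$roster$group == "G1"][1]
  # supplying tryptophan in the medium does not flip the call
  with_trp <- phenotype_auxotrophies(models[[g3]], w$media$minimal_trp,
                                     "trp__L")
  without <- phenotype_auxotrophies(models[[g3]], w$media$minimal, "trp__L")
  expect_equal(with_trp$value, without$value)
  expect_equal(without$value, 1L)
  expect_equal(phenotype_auxotrophies(models[[g1]], w$media$minimal,
                                      "trp__L")$value, 0L)
  # a compound the model does not represent scores auxotrophic with warning
  expect_warning(
    out <- phenotype_auxotrophies(models[[g1]], w$media$minimal, "b12"),
    "absent")
  expect_equal(out$value, 1L)
  expect_true(out$absent)
})

test_that("biosynthesis calls step at the threshold and handle absences", {
  w <- tw()
  models <- tw_models()
  g2 <- w$roster$strain[w$roster$group == "G2"][1]
  m <- models[[g2]]
  # medium component with a transporter is trivially producible
  out <- phenotype_biosynthesis(m, w$media$minimal_trp, "trp__L_c")
  expect_equal(out$value, 1L)
  # result invariant for any threshold within (0, max flux]
  fmax <- panmet:::max_demand_flux(m, w$media$minimal_trp, "hista_c")
  expect_gt(fmax, 0)
  for (th in c(1e-6, fmax / 2, fmax)) {
    expect_equal(phenotype_biosynthesis(m, w$media$minimal_trp, "hista_c",
                                        threshold = th)$value, 1L)
  }
  expect_equal(phenotype_biosynthesis(m, w$media$minimal_trp, "hista_c",
                                      threshold = fmax * 1.01)$value, 0L)
  g1 <- w$roster$strain[w$roster$group == "G1"][1]
  expect_warning(
    out2 <- phenotype_biosynthesis(models[[g1]], w$media$minimal_trp,
                                   "hista_c"),
    "absent")
  expect_equal(out2$value, 0L)
})

test_that("BFT assembly validates inputs and partitions outcomes", {
  one <- build_bft(list(sA = tibble::tibble(feature = "f1", value = 1L)))
  expect_equal(dim(one), c(1, 2))
  expect_equal(one$sA, 1L)

  expect_error(build_bft(list(sA = tibble::tibble(
    feature = c("f1", "f1"), value = c(1L, 0L)))), "duplicate")

  expect_warning(
    out <- build_bft(list(
      sA = tibble::tibble(feature = c("f1", "f2"), value = c(1L, 0L)),
      sB = tibble::tibble(feature = "f1", value = 1L))),
    "missing")
  expect_equal(out$sB[out$feature == "f2"], 0L)
})

test_that("reaction-presence BFT row sums equal per-reaction strain counts", {
  models <- tw_models()
  bft <- reaction_bft(models)
  m <- as.matrix(bft[, -1])
  counts <- rowSums(m)
  for (k in sample(nrow(bft), 10)) {
    rid <- sub("^reaction:", "", bft$feature[k])
    expect_equal(unname(counts[k]),
                 sum(vapply(models, function(mm) rid %in% mm$reactions$id,
                            logical(1))))
  }
  # and the full matrix equals planted truth
  w <- tw()
  truth <- expected_truth(w, "reactions")
  for (s in w$roster$strain) {
    rids <- sub("^reaction:", "", bft$feature)
    expect_equal(bft[[s]], as.integer(rids %in% truth[[s]]))
  }
})
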