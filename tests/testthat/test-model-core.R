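balance_toy <- function() {
  mets <- tibble::tibble(
    id = c("A_c", "B_c", "C_c", "U_c", "X_e"),
    formula = c("CH4", "CH4", "C3H6O3", "", "CH4"),
    charge = c(0L, 0L, 0L, NA_integer_, 0L),
    compartment = c("c", "c", "c", "c", "e")
  )
  rxns <- tibble::tibble(
    id = c("AB", "UNK", "EX_X_e", "BAD"),
    name = c("A to B", "unknown partner", "X exchange", "broken"),
    stoich = list(c(A_c = -1, B_c = 1),
                  c(U_c = -1, B_c = 1),
                  c(X_e = -1),
                  c(A_c = -1, C_c = 1)),
    lower = 0, upper = 1000,
    gpr = replicate(4, gpr_empty(), simplify = FALSE),
    spontaneous = FALSE,
    annotations = replicate(4, list(), simplify = FALSE)
  )
  metabolic_model("baltoy", mets, rxns, objective = "AB")
}

test_that("check_balance classifies balanced, unbalanced, and undetermined", {
  m <- balance_toy()
  # identical formulas on both sides
  expect_equal(check_balance("AB", m)$verdict, "balanced")
  # hand element count: glucose -> 2 lactate (C6H12O6 vs 2x C3H6O3)
  mets <- tibble::tibble(
    id = c("glc_c", "lac_c"), formula = c("C6H12O6", "C3H6O3"),
    charge = 0L, compartment = "c"
  )
  rx <- tibble::tibble(id = "SPLIT", name = "split",
                       stoich = list(c(glc_c = -1, lac_c = 2)),
                       lower = 0, upper = 10,
                       gpr = list(gpr_empty()), spontaneous = FALSE,
                       annotations = list(list()))
  m2 <- metabolic_model("glc", mets, rx, objective = "SPLIT")
  b <- check_balance("SPLIT", m2)
  expect_equal(b$verdict, "balanced")
  expect_true(all(abs(b$element_imbalance) < 1e-12))
  # empty formula participant
  expect_equal(check_balance("UNK", m)$verdict, "undetermined")
  # exchange reactions are undetermined by convention
  expect_equal(check_balance("EX_X_e", m)$verdict, "undetermined")
  # element mismatch
  bad <- check_balance("BAD", m)
  expect_equal(bad$verdict, "unbalanced")
})

orphan_toy <- function() {
  mets <- tibble::tibble(id = c("a_c", "b_c", "o2_c", "x_e"),
                         formula = "", charge = NA_integer_,
                         compartment = c("c", "c", "c", "e"))
  mk <- function(id, name, stoich, gpr, spont = FALSE) {
    tibble::tibble(id = id, name = name, stoich = list(stoich), lower = 0,
                   upper = 1000, gpr = list(gpr), spontaneous = spont,
                   annotations = list(list()))
  }
  rxns <- dplyr::bind_rows(
    mk("R1", "with gene", c(a_c = -1, b_c = 1), gpr_leaf("g1")),
    mk("R2", "orphan one", c(a_c = -1, b_c = 2), gpr_empty()),
    mk("R3", "spontaneous empty", c(b_c = -1, a_c = 1), gpr_empty(), spont = TRUE),
    mk("R4", "with gene 2", c(b_c = -2, a_c = 1), gpr_leaf("g2")),
    mk("R5", "with gene 3", c(a_c = -2, b_c = 1), gpr_leaf("g3")),
    mk("DIF", "O2 diffusion", c(o2_c = -1, a_c = 1), gpr_empty()),
    mk("EX_x_e", "x exchange", c(x_e = -1), gpr_empty())
  )
  metabolic_model("orphtoy", mets, rxns, objective = "R1")
}

test_that("count_orphans applies the internal/spontaneous/diffusion rules", {
  m <- orphan_toy()
  o <- count_orphans(m)
  # 5 internal + DIF; 2 with EMPTY GPR (R2, R3), one spontaneous -> only R2;
  # DIF is excluded by name despite EMPTY GPR
  expect_equal(o$count, 1)
  expect_equal(o$ids, "R2")
  expect_equal(o$n_eligible, 5)
  expect_equal(o$fraction, 1 / 5)

  # exchange-only model has no orphans
  ex_only <- subset_model(m, "EX_x_e")
  expect_equal(count_orphans(ex_only)$count, 0)

  # replacing an EMPTY GPR never increases the count
  m2 <- m
  i <- match("R2", m2$reactions$id)
  m2$reactions$gpr[[i]] <- gpr_leaf("g9")
  expect_lte(count_orphans(m2)$count, o$count)
})

test_that("apply_medium opens exactly the recipe uptakes and is idempotent", {
  mets <- tibble::tibble(id = c("glc__D_e", "o2_e", "glc__D_c"),
                         formula = "", charge = NA_integer_,
                         compartment = c("e", "e", "c"))
  rxns <- tibble::tibble(
    id = c("EX_glc__D_e", "EX_o2_e", "GLCt"),
    name = c("glucose exchange", "o2 exchange", "glucose transport"),
    stoich = list(c(glc__D_e = -1), c(o2_e = -1),
                  c(glc__D_e = -1, glc__D_c = 1)),
    lower = c(-1000, -1000, 0), upper = 1000,
    gpr = replicate(3, gpr_empty(), simplify = FALSE),
    spontaneous = FALSE, annotations = replicate(3, list(), simplify = FALSE)
  )
  m <- metabolic_model("med", mets, rxns, objective = "GLCt")

  r0 <- apply_medium(m, medium_recipe(numeric(0)))
  expect_equal(r0$reactions$lower[1:2], c(0, 0))

  rec <- medium_recipe(c(glc__D_e = 10))
  m1 <- apply_medium(m, rec)
  expect_equal(m1$reactions$lower[match("EX_glc__D_e", m1$reactions$id)], -10)
  expect_equal(m1$reactions$upper[match("EX_glc__D_e", m1$reactions$id)], 1000)
  expect_equal(m1$reactions$lower[match("EX_o2_e", m1$reactions$id)], 0)
  # non-exchange untouched
  expect_equal(m1$reactions$lower[match("GLCt", m1$reactions$id)], 0)
  # idempotence
  expect_identical(apply_medium(m1, rec), m1)
  # resolution by exchange reaction id too
  m2 <- apply_medium(m, medium_recipe(c(EX_o2_e = 5)))
  expect_equal(m2$reactions$lower[match("EX_o2_e", m2$reactions$id)], -5)
  # unresolvable entries error listing ids, or skip under the lenient flag
  expect_error(apply_medium(m, medium_recipe(c(nadh_e = 1))), "nadh_e")
  expect_silent(apply_medium(m, medium_recipe(c(nadh_e = 1)), on_missing = "skip"))
})

test_that("media TSV round-trips through read/write", {
  path <- tempfile(fileext = ".tsv")
  rec <- list(
    medium_recipe(c(glc__D_e = 10, nh4_e = 10), name = "minimal"),
    medium_recipe(c(glc__D_e = 5), name = "poor")
  )
  write_media_tsv(rec, path)
  back <- read_media_tsv(path)
  expect_equal(names(back), c("minimal", "poor"))
  expect_equal(back$minimal$max_uptake, c(10, 10))
  expect_equal(attr(back$poor, "name"), "poor")
})

test_that("consensus models intersect reaction sets per species", {
  base <- chain_model()
  drop_one <- function(m, rid) subset_model(m, setdiff(m$reactions$id, rid))
  m1 <- base
  m2 <- drop_one(base, "DM_B_c")
  m3 <- drop_one(base, "At")

  # one strain per species: the consensus is the strain itself
  solo <- consensus_model(list(m1), species = "spA")
  expect_setequal(solo$spA$reactions$id, base$reactions$id)

  # two strains: plain intersection
  duo <- consensus_model(list(m2, m3), species = c("spB", "spB"))
  expect_setequal(duo$spB$reactions$id, c("EX_A_e", "AB"))

  # random families equal the brute-force intersection
  set.seed(77)
  for (k in 1:10) {
    picks <- lapply(1:5, function(i) sample(base$reactions$id, sample(2:4, 1)))
    fam <- lapply(picks, function(p) subset_model(base, p))
    cons <- suppressWarnings(consensus_model(fam, species = rep("s", 5)))
    expect_setequal(cons$s$reactions$id, Reduce(intersect, picks))
  }
})

test_that("model validation catches dangling references and bad bounds", {
  mets <- tibble::tibble(id = "a_c", formula = "", charge = NA_integer_,
                         compartment = "c")
  rx <- tibble::tibble(id = "R1", name = "r", stoich = list(c(zz_c = -1)),
                       lower = 0, upper = 10, gpr = list(gpr_empty()),
                       spontaneous = FALSE, annotations = list(list()))
  expect_error(metabolic_model("bad", mets, rx, objective = "R1"), "zz_c")
  rx2 <- tibble::tibble(id = "R1", name = "r", stoich = list(c(a_c = -1)),
                        lower = 5, upper = 1, gpr = list(gpr_empty()),
                        spontaneous = FALSE, annotations = list(list()))
  expect_error(metabolic_model("bad2", mets, rx2, objective = "R1"), "bound")
})
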