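test_that("a model that already grows needs no additions", {
  full <- gap_toy()
  res <- gapfill_min_penalty(full, full, toy_medium, min_flux = 1)
  expect_equal(res$status, "success")
  expect_equal(res$added, character(0))
  expect_equal(res$total_penalty, 0)
})

test_that("the cheaper of two bridging paths is selected", {
  full <- gap_toy(n_steps = 2)
  # alternative 2-step bridge around S1: m0 -> x -> m1
  alt <- full
  alt$metabolites <- dplyr::bind_rows(
    alt$metabolites,
    tibble::tibble(id = "x_c", name = "x_c", formula = "",
                   charge = NA_integer_, compartment = "c"))
  alt$reactions <- dplyr::bind_rows(alt$reactions, tibble::tibble(
    id = c("A1", "A2"), name = c("alt 1", "alt 2"),
    stoich = list(c(m0_c = -1, x_c = 1), c(x_c = -1, m1_c = 1)),
    lower = 0, upper = 1000,
    gpr = list(gpr_empty(), gpr_empty()), spontaneous = FALSE,
    annotations = list(list(), list())))
  gapped <- subset_model(alt, setdiff(alt$reactions$id, c("S1", "A1", "A2")))
  gapped$objective <- "OBJ"

  res <- gapfill_min_penalty(gapped, alt, toy_medium, min_flux = 1,
                             penalties = c(S1 = 1, A1 = 0.3, A2 = 0.3))
  expect_equal(res$status, "success")
  expect_setequal(res$added, c("A1", "A2"))
  expect_equal(res$total_penalty, 0.6)

  # flip the weights: the single direct reaction wins
  res2 <- gapfill_min_penalty(gapped, alt, toy_medium, min_flux = 1,
                              penalties = c(S1 = 0.5, A1 = 0.3, A2 = 0.3))
  expect_equal(res2$added, "S1")
  expect_equal(res2$total_penalty, 0.5)
})

test_that("equal-penalty optima resolve to the lexicographically smallest set", {
  full <- gap_toy(n_steps = 1)
  alt <- full
  alt$reactions <- dplyr::bind_rows(alt$reactions, tibble::tibble(
    id = "B1", name = "parallel bridge",
    stoich = list(c(m0_c = -1, m1_c = 1)), lower = 0, upper = 1000,
    gpr = list(gpr_empty()), spontaneous = FALSE, annotations = list(list())))
  gapped <- subset_model(alt, setdiff(alt$reactions$id, c("S1", "B1")))
  gapped$objective <- "OBJ"
  res <- gapfill_min_penalty(gapped, alt, toy_medium, min_flux = 1,
                             penalties = c(S1 = 1, B1 = 1))
  expect_equal(res$added, "B1")   # "B1" < "S1"
})

test_that("infeasible gap-fills report status without mutating the model", {
  toy <- gap_toy(n_steps = 2)
  gapped <- subset_model(toy, setdiff(toy$reactions$id, "S1"))
  gapped$objective <- "OBJ"
  # repository without the missing step cannot help
  res <- gapfill_min_penalty(gapped, gapped, toy_medium, min_flux = 1)
  expect_equal(res$status, "infeasible")
  expect_identical(res$model$reactions$id, gapped$reactions$id)
})

test_that("total penalty equals the subset-enumeration brute force", {
  brute_force <- function(model, repo, medium, min_flux, pen) {
    cand <- setdiff(repo$reactions$id, model$reactions$id)
    best <- Inf
    for (mask in 0:(2^length(cand) - 1)) {
      ids <- cand[bitwAnd(mask, 2^(seq_along(cand) - 1)) > 0]
      p <- sum(pen[ids])
      if (p >= best) next
      m <- apply_medium(panmet:::copy_reactions(model, repo, ids), medium,
                        on_missing = "skip")
      r <- run_fba(m)
      if (r$status == "optimal" && r$objective_value >= min_flux - 1e-9) {
        best <- p
      }
    }
    best
  }
  set.seed(51)
  for (case in 1:8) {
    n_steps <- sample(3:5, 1)
    full <- gap_toy(n_steps = n_steps)
    # add parallel duplicates to grow the candidate pool
    extra_ids <- paste0("P", seq_len(sample(2:4, 1)))
    for (eid in extra_ids) {
      k <- sample(n_steps, 1)
      full$reactions <- dplyr::bind_rows(full$reactions, tibble::tibble(
        id = eid, name = eid,
        stoich = list(stats::setNames(c(-1, 1), paste0("m", c(k - 1, k), "_c"))),
        lower = 0, upper = 1000, gpr = list(gpr_empty()), spontaneous = FALSE,
        annotations = list(list())))
    }
    removable <- c(paste0("S", seq_len(n_steps)), extra_ids, "T0")
    gapped <- subset_model(
      full, setdiff(full$reactions$id, sample(removable, sample(2:5, 1))))
    gapped$objective <- "OBJ"
    cand <- setdiff(full$reactions$id, gapped$reactions$id)
    pen <- stats::setNames(round(stats::runif(length(cand), 0.1, 2), 2), cand)

    res <- gapfill_min_penalty(gapped, full, toy_medium, min_flux = 1,
                               penalties = pen)
    ref <- brute_force(gapped, full, toy_medium, 1, pen)
    if (is.infinite(ref)) {
      expect_equal(res$status, "infeasible")
    } else {
      expect_equal(res$status, "success")
      expect_equal(res$total_penalty, ref, tolerance = 1e-9)
      # postcondition: the augmented model truly reaches min_flux
      check <- run_fba(apply_medium(res$model, toy_medium, on_missing = "skip"))
      expect_gte(check$objective_value, 1 - 1e-9)
    }
  }
})

test_that("the planted strain-level gap is closed by exactly one reaction", {
  w <- tw()
  pam <- tw_pam()
  pan <- tw_recon()$pan
  g3 <- w$roster$strain[w$roster$group == "G3"][1]
  sm <- derive_strain(pan, pam, g3)
  gf <- gapfill_strain(sm, pan, w$media$minimal, min_flux = 0.001)
  expect_equal(gf$gapfilled$minimal, "TRPS")
  r <- run_fba(apply_medium(gf, w$media$minimal, on_missing = "skip"))
  expect_gte(r$objective_value, 0.001)
  # on the supplemented medium the strain already grows: nothing added
  gf2 <- gapfill_strain(sm, pan, w$media$minimal_trp)
  expect_equal(gf2$gapfilled$minimal_trp, character(0))
  # skip flag leaves the model untouched even if non-growing
  gf3 <- gapfill_strain(sm, pan, w$media$minimal, skip = TRUE)
  expect_identical(gf3$reactions$id, sm$reactions$id)
  expect_equal(length(gf3$gapfilled), 0)
})
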