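# Small hand-built fixtures shared across test files. Everything is
# constructed in code; nothing is read from disk.

# Random GPR tree with alternating and/or levels (the canonical form that
# gpr_parse produces), depth <= max_depth, over the given gene pool.
random_gpr <- function(genes, max_depth = 5) {
  build <- function(depth, parent_op) {
    if (depth >= max_depth || stats::runif(1) < 0.4) {
      return(gpr_leaf(sample(genes, 1)))
    }
    op <- sample(setdiff(c("and", "or"), parent_op), 1)
    n_ch <- sample(2:3, 1)
    ch <- replicate(n_ch, build(depth + 1, op), simplify = FALSE)
    # children of an op node must not themselves be that op (canonical form)
    if (op == "and") do.call(gpr_and, ch) else do.call(gpr_or, ch)
  }
  build(0, parent_op = "none")
}

# Exhaustive truth-table evaluation oracle: recursion written independently
# of gpr_evaluate (explicit stack-free set logic on the serialized text is
# overkill; instead evaluate by direct structural recursion with base-R
# Reduce, no shared helpers).
oracle_eval <- function(g, present) {
  if (g$op == "empty") return(TRUE)
  if (g$op == "unsat") return(FALSE)
  if (g$op == "leaf") return(is.element(g$gene, present))
  vals <- vapply(g$children, oracle_eval, logical(1), present = present)
  if (g$op == "and") Reduce(`&&`, vals) else Reduce(`||`, vals)
}

# Linear chain toy: EX_A_e -> transport -> convert A->B -> DM_B sink.
chain_model <- function(uptake = 10) {
  mets <- tibble::tibble(
    id = c("A_e", "A_c", "B_c"),
    name = c("A ext", "A cyt", "B cyt"),
    formula = c("C2H2", "C2H2", "C2H2"),
    charge = 0L,
    compartment = c("e", "c", "c")
  )
  rxns <- tibble::tibble(
    id = c("EX_A_e", "At", "AB", "DM_B_c"),
    name = c("A exchange", "A transport", "A to B", "B demand"),
    stoich = list(c(A_e = -1), c(A_e = -1, A_c = 1), c(A_c = -1, B_c = 1),
                  c(B_c = -1)),
    lower = c(-uptake, 0, 0, 0),
    upper = c(1000, 1000, 1000, 1000),
    gpr = list(gpr_empty(), gpr_leaf("g_t"), gpr_leaf("g_ab"), gpr_empty()),
    spontaneous = FALSE,
    annotations = list(list(), list(), list(), list())
  )
  metabolic_model("chain", mets, rxns, objective = "DM_B_c")
}

random_aa_seq <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n, replace = TRUE),
        collapse = "")
}

mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  n_mut <- max(0L, round(rate * length(ch)))
  if (n_mut == 0L) return(seq)
  pos <- sample(seq_along(ch), n_mut)
  alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y")
  for (p in pos) ch[p] <- sample(setdiff(alphabet, ch[p]), 1)
  paste(ch, collapse = "")
}

mk_bft <- function(mat, strains = NULL, features = NULL) {
  if (is.null(strains)) strains <- paste0("s", seq_len(ncol(mat)))
  if (is.null(features)) features <- paste0("f", seq_len(nrow(mat)))
  out <- tibble::as_tibble(stats::setNames(
    c(list(features), lapply(seq_len(ncol(mat)), function(j) as.integer(mat[, j]))),
    c("feature", strains)))
  out
}


# Toy factory: a linear pathway A_e -> A_c -> ... -> Z_c with a demand
# objective; candidate repository reactions bridge removed steps or offer
# alternative routes with chosen penalties.
gap_toy <- function(n_steps = 4, uptake = 10) {
  mets <- tibble::tibble(
    id = c("m0_e", paste0("m", 0:n_steps, "_c")),
    formula = "", charge = NA_integer_,
    compartment = c("e", rep("c", n_steps + 1))
  )
  step_ids <- paste0("S", seq_len(n_steps))
  rxns <- dplyr::bind_rows(
    tibble::tibble(id = "EX_m0_e", name = "uptake",
                   stoich = list(c(m0_e = -1)), lower = -uptake, upper = 1000,
                   gpr = list(gpr_empty()), spontaneous = FALSE,
                   annotations = list(list())),
    tibble::tibble(id = "T0", name = "transport",
                   stoich = list(c(m0_e = -1, m0_c = 1)), lower = 0,
                   upper = 1000, gpr = list(gpr_empty()), spontaneous = FALSE,
                   annotations = list(list())),
    dplyr::bind_rows(lapply(seq_len(n_steps), function(k) {
      tibble::tibble(id = step_ids[k], name = step_ids[k],
                     stoich = list(stats::setNames(c(-1, 1),
                                                   paste0("m", c(k - 1, k), "_c"))),
                     lower = 0, upper = 1000, gpr = list(gpr_empty()),
                     spontaneous = FALSE, annotations = list(list()))
    })),
    tibble::tibble(id = "OBJ", name = "objective demand",
                   stoich = list(stats::setNames(-1, paste0("m", n_steps, "_c"))),
                   lower = 0, upper = 1000, gpr = list(gpr_empty()),
                   spontaneous = FALSE, annotations = list(list()))
  )
  metabolic_model("gaptoy", mets, rxns, objective = "OBJ")
}

toy_medium <- medium_recipe(c(m0_e = 10), name = "toy")

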