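test_that("align_identity: identical, near-identical, and symmetry", {
  s <- random_aa_seq(50)
  r <- align_identity(s, s)
  expect_equal(r$identity, 1)
  expect_equal(r$cov_a, 1)
  expect_equal(r$cov_b, 1)

  r2 <- align_identity("AAAAAAAAAA", "AAAAAAAAAV")
  expect_equal(r2$identity, 0.9)

  set.seed(808)
  for (k in 1:20) {
    a <- random_aa_seq(sample(30:120, 1))
    b <- mutate_seq(a, 0.2)
    expect_equal(align_identity(a, b)$identity, align_identity(b, a)$identity,
                 tolerance = 1e-12)
  }
})

test_that("coverage reflects the aligned span of each sequence", {
  long <- random_aa_seq(200)
  short <- substr(long, 51, 150)   # exact 100-aa window
  r <- align_identity(long, short)
  expect_equal(r$identity, 1)
  expect_equal(r$cov_b, 1)
  expect_equal(r$cov_a, 0.5, tolerance = 0.02)
})

test_that("clustering groups identical sequences and separates families", {
  set.seed(909)
  fam1 <- random_aa_seq(150)
  rec <- tibble::tibble(
    gene_id = paste0("g", 1:6),
    strain = rep(c("s1", "s2", "s3"), 2),
    seq = rep(fam1, 6)
  )
  cl <- cluster_proteins(rec)
  expect_equal(nrow(cl$representatives), 1)

  fam2 <- random_aa_seq(150)   # unrelated family
  rec2 <- tibble::tibble(
    gene_id = paste0("h", 1:6),
    strain = rep(c("s1", "s2", "s3"), each = 2),
    seq = c(fam1, mutate_seq(fam1, 0.03), fam2, mutate_seq(fam2, 0.03),
            mutate_seq(fam1, 0.05), mutate_seq(fam2, 0.05))
  )
  cl2 <- cluster_proteins(rec2)
  expect_equal(nrow(cl2$representatives), 2)
  grp <- split(cl2$members$gene_id, cl2$members$cluster)
  expect_setequal(vapply(grp, paste, collapse = ",", FUN.VALUE = ""),
                  c("h1,h2,h5", "h3,h4,h6"))
})

test_that("every member satisfies the thresholds versus its representative", {
  set.seed(111)
  fams <- replicate(4, random_aa_seq(sample(100:200, 1)))
  rec <- dplyr::bind_rows(lapply(1:4, function(f) {
    tibble::tibble(gene_id = paste0("f", f, "_", 1:5),
                   strain = paste0("s", 1:5),
                   seq = vapply(1:5, function(i) mutate_seq(fams[f], 0.03), ""))
  }))
  cl <- cluster_proteins(rec)
  reps <- stats::setNames(cl$representatives$seq, cl$representatives$cluster)
  for (i in seq_len(nrow(cl$members))) {
    m <- cl$members[i, ]
    sq <- rec$seq[match(m$gene_id, rec$gene_id)]
    r <- align_identity(reps[[m$cluster]], sq)
    expect_gte(r$identity, 0.90)
    expect_gte(r$cov_a, 0.70)
    expect_gte(r$cov_b, 0.70)
  }
})

test_that("clustering is deterministic under the stated ordering rule", {
  set.seed(222)
  fams <- replicate(3, random_aa_seq(140))
  rec <- dplyr::bind_rows(lapply(1:3, function(f) {
    tibble::tibble(gene_id = paste0("f", f, "_", 1:4),
                   strain = paste0("s", 1:4),
                   seq = vapply(1:4, function(i) mutate_seq(fams[f], 0.02), ""))
  }))
  cl1 <- cluster_proteins(rec)
  cl2 <- cluster_proteins(rec[sample(nrow(rec)), ])   # shuffled input
  expect_equal(cl1$members[order(cl1$members$gene_id), ],
               cl2$members[order(cl2$members$gene_id), ])
})

test_that("PAM construction partitions genes into cells", {
  genes <- tibble::tibble(
    gene_id = c("a1", "a2", "b1"),
    strain = c("s1", "s1", "s2"),
    cluster = c("C0001", "C0001", "C0002")
  )
  pam <- build_pam(genes, strains = c("s1", "s2", "s3"))
  wide <- pam_matrix(pam)
  expect_equal(names(wide), c("cluster", "s1", "s2", "s3"))
  expect_equal(wide$s1[wide$cluster == "C0001"], "a1,a2")
  expect_equal(wide$s2[wide$cluster == "C0001"], "")
  # total gene count = sum of cell sizes
  sizes <- sum(vapply(unlist(wide[, -1]), function(x) {
    if (x == "") 0L else length(strsplit(x, ",")[[1]])
  }, integer(1)))
  expect_equal(sizes, nrow(genes))

  expect_error(build_pam(genes, strains = "s1"), "s2")
  dup <- dplyr::bind_rows(genes, genes[1, ])
  dup$cluster[4] <- "C0002"
  expect_error(build_pam(dup, strains = c("s1", "s2")), "a1")
})

test_that("random clusterings keep the PAM a partition", {
  set.seed(333)
  for (k in 1:20) {
    n <- sample(5:40, 1)
    genes <- tibble::tibble(
      gene_id = paste0("g", 1:n),
      strain = sample(paste0("s", 1:4), n, replace = TRUE),
      cluster = sample(paste0("C", 1:6), n, replace = TRUE)
    )
    pam <- build_pam(genes, strains = paste0("s", 1:4))
    cells <- pam_matrix(pam)[, -1]
    all_ids <- unlist(strsplit(unlist(cells)[nzchar(unlist(cells))], ","))
    expect_setequal(all_ids, genes$gene_id)
    expect_equal(anyDuplicated(all_ids), 0L)
  }
})

test_that("PAM TSV round-trips with gene flags", {
  genes <- tibble::tibble(
    gene_id = c("a1", "a2", "b1"), strain = c("s1", "s2", "s2"),
    cluster = c("C0001", "C0001", "C0002"),
    premature_stop = c(FALSE, TRUE, FALSE),
    scenario = c("none", "i", "none")
  )
  pam <- build_pam(genes, strains = c("s1", "s2"))
  path <- tempfile(fileext = ".tsv")
  write_pam(pam, path)
  back <- read_pam(path)
  expect_equal(back$genes[order(back$genes$gene_id), ],
               pam$genes[order(pam$genes$gene_id), ])
  expect_equal(back$strains, pam$strains)
})
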