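test_that("merge_bfts concatenates, excludes, and validates strain sets", {
  a <- mk_bft(matrix(c(1, 0, 0, 1), 2), features = c("a1", "a2"))
  b <- mk_bft(matrix(c(0, 1), 1), features = "b1")
  expect_equal(nrow(merge_bfts(list(a))), 2)
  m <- merge_bfts(list(a, b))
  expect_equal(nrow(m), 3)
  expect_equal(nrow(merge_bfts(list(a, b), exclude = c("a2", "b1"))), 1)
  # constant-row dropping is opt-in
  cst <- mk_bft(matrix(c(1, 1), 1), features = "const")
  expect_equal(nrow(merge_bfts(list(a, cst))), 3)
  expect_equal(nrow(merge_bfts(list(a, cst), drop_constant = TRUE)), 2)
  bad <- mk_bft(matrix(0, 1, 2), strains = c("s1", "sX"), features = "z")
  expect_error(merge_bfts(list(a, bad)), "sX")
  dup <- mk_bft(matrix(0, 1, 2), features = "a1")
  expect_error(merge_bfts(list(a, dup)), "duplicate")
})

test_that("Jaccard distances match hand arithmetic and oracles", {
  # columns (1,1,0) vs (1,0,1): intersection 1, union 3 -> d = 2/3
  b <- mk_bft(matrix(c(1, 1, 0, 1, 0, 1), 3))
  d <- jaccard_distance_matrix(b)
  expect_equal(as.numeric(d), 2 / 3)

  ident <- mk_bft(matrix(c(1, 0, 1, 0), 2))
  expect_equal(as.numeric(jaccard_distance_matrix(ident)), 0)

  # both-empty pair -> 0 by convention
  zz <- mk_bft(matrix(0, 3, 2))
  expect_equal(as.numeric(jaccard_distance_matrix(zz)), 0)

  set.seed(81)
  for (k in 1:20) {
    m <- matrix(stats::rbinom(8 * 5, 1, 0.4), 8, 5)
    b <- mk_bft(m)
    d <- as.matrix(jaccard_distance_matrix(b))
    # brute-force set formula
    for (i in 1:4) for (j in (i + 1):5) {
      fi <- which(m[, i] == 1); fj <- which(m[, j] == 1)
      uni <- length(union(fi, fj))
      ref <- if (uni == 0) 0 else 1 - length(intersect(fi, fj)) / uni
      expect_equal(d[i, j], ref)
    }
    # independent implementation (vegan, binary Jaccard)
    if (all(colSums(m) > 0)) {
      dv <- vegan::vegdist(t(m), method = "jaccard", binary = TRUE)
      expect_equal(as.numeric(jaccard_distance_matrix(b)), as.numeric(dv),
                   tolerance = 1e-12)
    }
  }
})

test_that("adding a constant-1 feature never increases any distance", {
  set.seed(82)
  m <- matrix(stats::rbinom(30, 1, 0.5), 6, 5)
  b <- mk_bft(m)
  b2 <- mk_bft(rbind(m, 1), features = c(paste0("f", 1:6), "const1"))
  expect_true(all(as.matrix(jaccard_distance_matrix(b2)) <=
                    as.matrix(jaccard_distance_matrix(b)) + 1e-12))
})

test_that("Ward tree: forced small cases and height monotonicity", {
  d2 <- stats::as.dist(matrix(c(0, 0.4, 0.4, 0), 2,
                              dimnames = list(c("a", "b"), c("a", "b"))))
  t2 <- ward_dendrogram(d2)
  expect_equal(t2$height, 0.4)
  expect_error(ward_dendrogram(stats::as.dist(matrix(0, 1, 1))), "at least 2")

  m3 <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.8, 0.9, 0.8, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- ward_dendrogram(stats::as.dist(m3))
  expect_equal(sort(t3$merge[1, ]), c(-2, -1))   # A,B merge first
  expect_true(all(diff(t3$height) >= -1e-12))
})

test_that("Ward merges match the reference implementation on random matrices", {
  set.seed(83)
  for (k in 1:20) {
    x <- matrix(stats::rnorm(8 * 4), 8)
    rownames(x) <- paste0("s", 1:8)
    d <- stats::dist(x)
    mine <- ward_dendrogram(d)
    ref <- stats::hclust(d, method = "ward.D")
    expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-9)
    expect_equal(as.matrix(stats::cophenetic(mine)),
                 as.matrix(stats::cophenetic(ref)), tolerance = 1e-9)
  }
})

test_that("cluster extraction yields k groups with size-ordered labels", {
  set.seed(84)
  m <- cbind(matrix(stats::rbinom(40, 1, 0.9), 10, 4),
             matrix(stats::rbinom(20, 1, 0.05), 10, 2))
  b <- mk_bft(m, strains = c(paste0("big", 1:4), paste0("sm", 1:2)))
  tree <- ward_dendrogram(jaccard_distance_matrix(b))
  one <- extract_clusters(tree, 1)
  expect_equal(unique(one$cluster), "Cluster_1")
  alln <- extract_clusters(tree, 6)
  expect_equal(dplyr::n_distinct(alln$cluster), 6)
  two <- extract_clusters(tree, 2)
  expect_equal(dplyr::n_distinct(two$cluster), 2)
  # the larger group gets Cluster_1
  expect_equal(unique(two$cluster[grepl("big", two$strain)]), "Cluster_1")
  expect_error(extract_clusters(tree, 0), "between")
  expect_error(extract_clusters(tree, 7), "between")
})

test_that("phylometabolic clustering recovers the planted strain groups", {
  w <- tw()
  truth <- expected_truth(w, "groups")
  # truth-level BFTs: reaction presence + the three phenotype tables
  models <- tw_models()
  bfts <- list(
    reaction_bft(models),
    expected_truth(w, "substrates"),
    expected_truth(w, "auxotrophies"),
    expected_truth(w, "biosynthesis")
  )
  res <- analyze_pipeline(bfts, k = 3)
  joined <- dplyr::inner_join(res$clusters, truth, by = "strain")
  ari <- mclust::adjustedRandIndex(joined$cluster, joined$group)
  expect_equal(ari, 1)
  expect_match(res$newick, "^\\(")
})

test_that("feature frequencies and characteristic scores match brute force", {
  set.seed(85)
  m <- matrix(stats::rbinom(40, 1, 0.5), 8, 5)
  b <- mk_bft(m)
  asg <- tibble::tibble(strain = paste0("s", 1:5),
                        cluster = c("X", "X", "Y", "Y", "Y"))
  out <- cluster_feature_frequencies(b, asg)
  for (k in seq_len(nrow(out))) {
    inside <- asg$strain[asg$cluster == out$cluster[k]]
    fi <- match(out$feature[k], b$feature)
    expect_equal(out$freq[k], mean(as.numeric(b[fi, inside])))
    outside <- setdiff(asg$strain, inside)
    expect_equal(out$score[k],
                 mean(as.numeric(b[fi, inside])) -
                   mean(as.numeric(b[fi, outside])))
  }
  # constant feature scores 0; exclusive feature scores 1
  cst <- mk_bft(matrix(1, 1, 5), features = "everywhere")
  excl <- mk_bft(matrix(c(1, 1, 0, 0, 0), 1), features = "only_X")
  out2 <- cluster_feature_frequencies(merge_bfts(list(cst, excl)), asg)
  expect_equal(out2$score[out2$feature == "everywhere"], c(0, 0))
  expect_equal(out2$score[out2$feature == "only_X" & out2$cluster == "X"], 1)
  expect_error(cluster_feature_frequencies(b, asg[-1, ]), "s1")
})

test_that("confusion metrics count cells correctly and respect NA", {
  set.seed(86)
  p <- mk_bft(matrix(stats::rbinom(40, 1, 0.5), 8, 5))
  # perfect agreement
  cm <- confusion_metrics(p, p)
  expect_true(all(cm$accuracy == 1))
  expect_true(all(cm$fp == 0 & cm$fn == 0))
  # complement: accuracy 0
  q <- p
  for (s in bft_strains(q)) q[[s]] <- 1L - q[[s]]
  cm2 <- confusion_metrics(p, q)
  expect_true(all(cm2$accuracy == 0))
  # random experimental tables with NAs vs brute force
  for (k in 1:10) {
    e <- p
    for (s in bft_strains(e)) {
      e[[s]] <- stats::rbinom(8, 1, 0.5)
      e[[s]][sample(8, 2)] <- NA
    }
    cm3 <- confusion_metrics(p, e)
    s1 <- bft_strains(p)[1]
    ok <- !is.na(e[[s1]])
    expect_equal(cm3$tp[cm3$strain == s1],
                 sum(p[[s1]][ok] == 1 & e[[s1]][ok] == 1))
    expect_equal(cm3$n[cm3$strain == s1], sum(ok))
  }
  # undefined ratios are NA, not zero
  p0 <- mk_bft(matrix(0, 3, 2))
  cm4 <- confusion_metrics(p0, p0)
  expect_true(all(is.na(cm4$precision)))
  expect_true(all(cm4$specificity == 1))
  expect_error(confusion_metrics(p, mk_bft(matrix(0, 1, 2),
                                           strains = c("zz1", "zz2"))),
               "overlapping")
})

test_that("summary and plots of analysis objects work", {
  set.seed(87)
  p <- mk_bft(matrix(stats::rbinom(40, 1, 0.5), 8, 5))
  e <- p
  e$s1[1] <- 1L - e$s1[1]
  cm <- confusion_metrics(p, e)
  gl <- generics::glance(cm)
  expect_true(gl$mean_accuracy < 1 && gl$mean_accuracy > 0.5)
  expect_s3_class(autoplot(cm), "ggplot")
  tree <- ward_dendrogram(jaccard_distance_matrix(p))
  expect_s3_class(autoplot(tree), "ggplot")
  expect_s3_class(plot_bft(p), "ggplot")
})
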