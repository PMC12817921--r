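# Multi-strain analysis: merged BFTs, Jaccard distances, the Ward
# "phylometabolic tree", cluster extraction, per-cluster feature
# frequencies, and confusion metrics against experimental tables.

#' Merge binary feature tables
#'
#' Row-wise concatenation of BFTs sharing the same strain set
#' (order-insensitive). Feature ids must be disjoint across tables.
#' Constant rows can optionally be dropped, and an explicit exclusion list
#' removes named features (e.g. an entire pathway's reactions) before
#' clustering.
#'
#' @param tables List of BFT tibbles.
#' @param drop_constant Drop rows constant across strains (default FALSE).
#' @param exclude Character vector of feature ids to remove.
#' @return The merged BFT tibble.
#' @export
merge_bfts <- function(tables, drop_constant = FALSE, exclude = NULL) {
  stopifnot(length(tables) >= 1)
  strains <- lapply(tables, bft_strains)
  for (k in seq_along(tables)[-1]) {
    diff <- c(setdiff(strains[[1]], strains[[k]]),
              setdiff(strains[[k]], strains[[1]]))
    if (length(diff)) {
      stop("strain sets differ between BFTs: ", paste(diff, collapse = ", "))
    }
  }
  tables <- lapply(tables, function(t) t[, c("feature", strains[[1]])])
  merged <- dplyr::bind_rows(tables)
  if (anyDuplicated(merged$feature)) {
    stop("duplicate feature ids across BFTs: ",
         paste(unique(merged$feature[duplicated(merged$feature)]), collapse = ", "))
  }
  if (!is.null(exclude)) merged <- merged[!merged$feature %in% exclude, ]
  if (drop_constant) {
    m <- as.matrix(merged[, -1])
    merged <- merged[apply(m, 1, function(r) length(unique(r)) > 1), ]
  }
  merged
}

#' Jaccard distance matrix between strains
#'
#' `d(a, b) = 1 - |Fa inter Fb| / |Fa union Fb|` over each strain's set of
#' 1-features; a pair of strains with no 1-features at all is at distance 0
#' by convention.
#'
#' @param bft A BFT tibble (merged).
#' @return A `stats::dist` object over the strain labels.
#' @export
jaccard_distance_matrix <- function(bft) {
  strains <- bft_strains(bft)
  if (length(strains) < 2) stop("need at least 2 strains")
  m <- as.matrix(bft[, strains])
  storage.mode(m) <- "numeric"
  inter <- crossprod(m)                 # strains x strains
  ones <- colSums(m)
  uni <- outer(ones, ones, "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0
  rownames(d) <- colnames(d) <- strains
  stats::as.dist(d)
}

#' Ward dendrogram over a precomputed distance matrix
#'
#' Agglomerative clustering with Ward linkage through the Lance-Williams
#' update applied directly to the given distances. Ties in the minimum
#' inter-cluster distance are broken deterministically by merging the pair
#' with the lexicographically smallest (label, label) pair, labels taken as
#' the smallest member label of each cluster. The result is
#' `hclust`-compatible (usable with [stats::cutree()], [ape::as.phylo()],
#' ...).
#'
#' @param d A `stats::dist` object with labels.
#' @return A `phylometabolic_tree` (also of class `hclust`).
#' @export
ward_dendrogram <- function(d) {
  labels <- attr(d, "Labels")
  n <- attr(d, "Size")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n < 2) stop("need at least 2 strains to build a dendrogram")
  D <- as.matrix(d)
  diag(D) <- Inf
  sizes <- rep(1, n)
  active <- seq_len(n)
  node_of <- -seq_len(n)                # hclust convention: leaves negative
  min_label <- labels
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    idx <- which(D == min(D[active, active, drop = FALSE]), arr.ind = TRUE)
    idx <- idx[idx[, 1] %in% active & idx[, 2] %in% active &
                 idx[, 1] < idx[, 2], , drop = FALSE]
    # deterministic tie-break on the sorted label pair
    keys <- apply(idx, 1, function(p) {
      lab <- sort(c(min_label[p[1]], min_label[p[2]]))
      paste(lab, collapse = "\r")
    })
    pick <- idx[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    merge[step, ] <- c(node_of[i], node_of[j])
    height[step] <- D[i, j]

    # Lance-Williams Ward update onto position i
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      D[i, k] <- D[k, i] <-
        ((ni + nk) * D[i, k] + (nj + nk) * D[j, k] - nk * D[i, j]) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    node_of[i] <- step
    min_label[i] <- min(min_label[i], min_label[j])
    active <- setdiff(active, j)
    D[j, ] <- Inf; D[, j] <- Inf
  }

  hc <- structure(
    list(merge = merge, height = height, order = hclust_order(merge),
         labels = labels, method = "ward.D",
         dist.method = "jaccard", call = match.call()),
    class = c("phylometabolic_tree", "hclust")
  )
  hc
}

# Leaf order for plotting, by recursive traversal of the merge matrix.
hclust_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' Export a dendrogram to Newick
#' @param tree A `phylometabolic_tree` (or any `hclust`).
#' @param path Optional output file; when `NULL` the newick string is
#'   returned.
#' @return The newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(stats::as.hclust(tree))
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Extract k clusters from a phylometabolic tree
#'
#' Cuts the tree into exactly `k` groups (removing the k-1 highest merges)
#' and labels them `Cluster_1..Cluster_k` by decreasing size, ties broken
#' by smallest member label.
#'
#' @param tree A `phylometabolic_tree`.
#' @param k Number of clusters (1 <= k <= n strains).
#' @return Tibble `strain`, `cluster`.
#' @export
extract_clusters <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("k must be between 1 and ", n)
  raw <- stats::cutree(stats::as.hclust(tree), k = k)
  groups <- split(names(raw), raw)
  first <- vapply(groups, function(g) min(g), character(1))
  ord <- order(-lengths(groups), first)
  relabel <- stats::setNames(paste0("Cluster_", seq_along(ord)),
                             names(groups)[ord])
  tibble::tibble(strain = names(raw),
                 cluster = unname(relabel[as.character(raw)]))
}

#' Per-cluster feature frequencies and characteristic features
#'
#' `freq(f, c)` is the mean of feature row f over cluster c's strains; the
#' characteristic score of f for c is `freq(f, c) - freq(f, complement)`.
#' Features are ranked per cluster by decreasing score.
#'
#' @param bft A BFT tibble.
#' @param assignment Tibble `strain`, `cluster` covering all BFT strains.
#' @return Tibble `cluster`, `feature`, `freq`, `freq_rest`, `score`,
#'   `rank`.
#' @export
cluster_feature_frequencies <- function(bft, assignment) {
  strains <- bft_strains(bft)
  assignment <- tibble::as_tibble(assignment)
  missing <- setdiff(strains, assignment$strain)
  if (length(missing)) {
    stop("assignment does not cover strain(s): ", paste(missing, collapse = ", "))
  }
  m <- as.matrix(bft[, strains])
  rownames(m) <- bft$feature
  out <- dplyr::bind_rows(lapply(unique(assignment$cluster), function(cl) {
    inside <- assignment$strain[assignment$cluster == cl]
    outside <- setdiff(strains, inside)
    freq <- rowMeans(m[, inside, drop = FALSE])
    freq_rest <- if (length(outside)) rowMeans(m[, outside, drop = FALSE])
      else rep(NA_real_, nrow(m))
    tibble::tibble(cluster = cl, feature = bft$feature,
                   freq = unname(freq), freq_rest = unname(freq_rest),
                   score = unname(freq - freq_rest))
  }))
  out <- dplyr::group_by(out, .data$cluster)
  out <- dplyr::mutate(out, rank = rank(-.data$score, ties.method = "min"))
  dplyr::arrange(dplyr::ungroup(out), .data$cluster, .data$rank)
}

#' Confusion metrics between predicted and experimental BFTs
#'
#' Cells are compared over the shared feature/strain labels; experimental
#' `NA` cells are excluded. Per strain, TP/TN/FP/FN counts and accuracy,
#' precision, recall, specificity are reported (undefined ratios as `NA`,
#' never 0), plus the mean and standard deviation across strains via
#' [glance.confusion_metrics()].
#'
#' @param predicted BFT tibble of model predictions (0/1).
#' @param experimental BFT tibble of experimental outcomes (0/1/NA).
#' @return A `confusion_metrics` tibble: one row per strain with counts and
#'   metrics.
#' @export
confusion_metrics <- function(predicted, experimental) {
  feats <- intersect(predicted$feature, experimental$feature)
  strains <- intersect(bft_strains(predicted), bft_strains(experimental))
  if (length(feats) == 0 || length(strains) == 0) {
    stop("no overlapping features/strains between predicted and experimental")
  }
  p <- as.matrix(predicted[match(feats, predicted$feature), strains])
  e <- as.matrix(experimental[match(feats, experimental$feature), strains])
  out <- dplyr::bind_rows(lapply(seq_along(strains), function(k) {
    ok <- !is.na(e[, k])
    pv <- p[ok, k]; ev <- e[ok, k]
    tp <- sum(pv == 1 & ev == 1); tn <- sum(pv == 0 & ev == 0)
    fp <- sum(pv == 1 & ev == 0); fn <- sum(pv == 0 & ev == 1)
    safe <- function(num, den) if (den == 0) NA_real_ else num / den
    tibble::tibble(
      strain = strains[k], n = sum(ok), tp = tp, tn = tn, fp = fp, fn = fn,
      accuracy = safe(tp + tn, tp + tn + fp + fn),
      precision = safe(tp, tp + fp),
      recall = safe(tp, tp + fn),
      specificity = safe(tn, tn + fp)
    )
  }))
  class(out) <- c("confusion_metrics", class(out))
  out
}

#' Mean and standard deviation of confusion metrics across strains
#' @param x A [confusion_metrics()] table.
#' @param ... Unused.
#' @return One-row tibble with `mean_*` and `sd_*` for the four metrics
#'   (NA cells excluded).
#' @export
glance.confusion_metrics <- function(x, ...) {
  metric <- c("accuracy", "precision", "recall", "specificity")
  means <- vapply(metric, function(m) mean(x[[m]], na.rm = TRUE), numeric(1))
  sds <- vapply(metric, function(m) stats::sd(x[[m]], na.rm = TRUE), numeric(1))
  tibble::as_tibble(c(
    stats::setNames(as.list(means), paste0("mean_", metric)),
    stats::setNames(as.list(sds), paste0("sd_", metric))
  ))
}
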