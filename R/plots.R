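# ggplot2 displays for the main result types.

#' Heatmap of a binary feature table
#'
#' @param bft A BFT tibble (`feature` column + one 0/1 column per strain).
#' @param order_strains Optional strain ordering (e.g. a phylometabolic
#'   tree's `labels[tree$order]`).
#' @param drop_constant Hide features constant across strains (display
#'   only; the underlying table is not changed).
#' @return A ggplot object.
#' @export
plot_bft <- function(bft, order_strains = NULL, drop_constant = TRUE) {
  strains <- bft_strains(bft)
  long <- tidyr::pivot_longer(bft, -"feature", names_to = "strain",
                              values_to = "value")
  if (drop_constant) {
    keep <- vapply(split(long$value, long$feature),
                   function(v) length(unique(v)) > 1, logical(1))
    long <- long[long$feature %in% names(keep)[keep], ]
  }
  if (!is.null(order_strains)) {
    long$strain <- factor(long$strain, levels = order_strains)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$strain, y = .data$feature,
                                     fill = factor(.data$value))) +
    ggplot2::geom_tile(color = "grey85", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(`0` = "grey95", `1` = "#2c7fb8"),
                               name = "presence") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @export
autoplot.phylometabolic_tree <- function(object, ...) {
  seg <- dendrogram_segments(object)
  labs <- tibble::tibble(x = seq_along(object$order),
                         label = object$labels[object$order])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = labs$x, labels = labs$label) +
    ggplot2::labs(x = NULL, y = "Ward merge height") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5),
                   panel.grid.major.x = ggplot2::element_blank())
}

# x-position of leaves in plotting order, then recursive union of merge
# segments (three segments per merge: two risers and one bar)
dendrogram_segments <- function(tree) {
  n <- length(tree$labels)
  leaf_x <- stats::setNames(seq_len(n), tree$order)
  node_x <- numeric(n - 1)
  node_h <- tree$height
  segs <- list()
  pos <- function(node) {
    if (node < 0) return(c(leaf_x[[as.character(-node)]], 0))
    c(node_x[node], node_h[node])
  }
  for (k in seq_len(n - 1)) {
    a <- pos(tree$merge[k, 1])
    b <- pos(tree$merge[k, 2])
    node_x[k] <- (a[1] + b[1]) / 2
    segs[[k]] <- tibble::tibble(
      x = c(a[1], b[1], a[1]),
      xend = c(a[1], b[1], b[1]),
      y = c(a[2], b[2], node_h[k]),
      yend = c(node_h[k], node_h[k], node_h[k])
    )
  }
  dplyr::bind_rows(segs)
}

#' @export
autoplot.confusion_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("strain", "accuracy", "precision", "recall", "specificity")],
    -"strain", names_to = "metric", values_to = "value")
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$metric),
    mean = mean(.data$value, na.rm = TRUE),
    sd = stats::sd(.data$value, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$metric, y = .data$mean)) +
    ggplot2::geom_col(fill = "#41ab5d", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.15) +
    ggplot2::geom_point(data = long,
                        ggplot2::aes(y = .data$value), alpha = 0.4,
                        position = ggplot2::position_jitter(width = 0.08,
                                                            height = 0)) +
    ggplot2::ylim(0, NA) +
    ggplot2::labs(x = NULL, y = "value (mean across strains, bars = sd)") +
    ggplot2::theme_minimal(base_size = 10)
}

#' Tidy a PAM into its long gene table
#' @param x A PAM from [build_pam()].
#' @param ... Unused.
#' @return Tibble `gene_id`, `strain`, `cluster`, `premature_stop`,
#'   `scenario`.
#' @export
tidy.panmet_pam <- function(x, ...) x$genes

#' One-row summary of a metabolic model
#' @param x A `metabolic_model`.
#' @param ... Unused.
#' @return Tibble with reaction/metabolite/gene counts, boundary counts,
#'   and the orphan fraction.
#' @export
glance.metabolic_model <- function(x, ...) {
  types <- reaction_types(x)
  o <- count_orphans(x)
  tibble::tibble(
    id = x$id,
    n_reactions = nrow(x$reactions),
    n_metabolites = nrow(x$metabolites),
    n_genes = length(unique(unlist(lapply(x$reactions$gpr, gpr_genes)))),
    n_exchanges = sum(types == "exchange"),
    n_orphans = o$count,
    orphan_fraction = o$fraction,
    objective = x$objective
  )
}
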