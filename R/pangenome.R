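# Protein clustering and the gene presence/absence matrix (PAM).
#
# Clustering mirrors greedy incremental identity clustering (CD-HIT style,
# best-match assignment) but uses exact global ends-free alignments for
# every comparison instead of k-mer prefilters: correctness over speed at
# the scale of tens of strains.

AA_GAP_PENALTY <- c(opening = 10, extension = 0.5)

as_aa <- function(x) {
  if (inherits(x, "AAString") || inherits(x, "AAStringSet")) x
  else Biostrings::AAStringSet(x)
}

#' Global identity and coverage between two protein sequences
#'
#' Sequences are aligned globally with free end gaps (BLOSUM62, gap opening
#' 10, extension 0.5). Identity is the number of identical aligned residues
#' divided by the length of the shorter sequence (the CD-HIT convention);
#' the coverage of each sequence is its aligned, non-terminal-gap span
#' divided by its length.
#'
#' @param a,b Protein sequences (strings or `AAString`).
#' @return List with `identity`, `cov_a`, `cov_b`.
#' @export
align_identity <- function(a, b) {
  r <- align_identity_many(as_aa(as.character(a)), as.character(b))
  list(identity = r$identity, cov_a = r$cov_pattern, cov_b = r$cov_subject)
}

# Vectorized form: many patterns against one subject.
align_identity_many <- function(patterns, subject) {
  patterns <- as_aa(patterns)
  subj <- Biostrings::AAString(as.character(subject))
  al <- Biostrings::pairwiseAlignment(
    patterns, subj, type = "overlap",
    substitutionMatrix = "BLOSUM62",
    gapOpening = AA_GAP_PENALTY[["opening"]],
    gapExtension = AA_GAP_PENALTY[["extension"]]
  )
  plen <- Biostrings::width(patterns)
  slen <- length(subj)
  pr <- methods::slot(Biostrings::pattern(al), "range")
  sr <- methods::slot(Biostrings::subject(al), "range")
  span_p <- BiocGenerics::end(pr) - BiocGenerics::start(pr) + 1L
  span_s <- BiocGenerics::end(sr) - BiocGenerics::start(sr) + 1L
  nm <- Biostrings::nmatch(al)
  tibble::tibble(
    identity = nm / pmin(plen, slen),
    cov_pattern = pmax(span_p, 0L) / plen,
    cov_subject = pmax(span_s, 0L) / slen,
    nmatch = nm
  )
}

#' Greedy incremental protein clustering
#'
#' Sequences are sorted by length (descending; ties broken by gene id) and
#' assigned greedily: each sequence joins the best-scoring existing cluster
#' whose representative it matches at `identity >= identity` with coverage
#' of both representative and member `>= cov_long` / `>= cov_short`
#' (best-match assignment, not first-match); otherwise it founds a new
#' cluster and becomes its representative.
#'
#' @param records Tibble with columns `gene_id`, `strain`, `seq` (amino
#'   acid, may include X). Optional columns `premature_stop` and `scenario`
#'   are carried through.
#' @param identity Minimum identity to the representative (default 0.90).
#' @param cov_long Minimum coverage of the longer sequence, i.e. the
#'   representative (default 0.70).
#' @param cov_short Minimum coverage of the shorter sequence, i.e. the
#'   candidate member (default 0.70).
#' @return A `protein_clustering`: list with `members` (tibble `gene_id`,
#'   `strain`, `cluster`, `identity`, `cov_rep`, `cov_member`) and
#'   `representatives` (tibble `cluster`, `gene_id`, `seq`).
#' @export
cluster_proteins <- function(records, identity = 0.90, cov_long = 0.70,
                             cov_short = 0.70) {
  records <- tibble::as_tibble(records)
  stopifnot(nrow(records) >= 1L, all(nzchar(records$seq)),
            !anyDuplicated(paste(records$strain, records$gene_id)))
  ord <- order(-nchar(records$seq), records$gene_id)
  records <- records[ord, ]

  rep_seqs <- character(0)
  rep_gene <- character(0)
  rep_len <- integer(0)
  assign_cluster <- integer(nrow(records))
  assign_ident <- assign_covr <- assign_covm <- numeric(nrow(records))

  for (i in seq_len(nrow(records))) {
    sq <- records$seq[i]
    l <- nchar(sq)
    cand <- which(l / rep_len >= cov_long)   # reps are never shorter
    best <- NA_integer_
    if (length(cand)) {
      st <- align_identity_many(rep_seqs[cand], sq)
      ok <- st$identity >= identity & st$cov_pattern >= cov_long &
        st$cov_subject >= cov_short
      if (any(ok)) {
        okc <- cand[ok]
        sc <- st$identity[ok]
        best <- okc[order(-sc, okc)][1L]   # best identity, tie: oldest cluster
        k <- which(cand == best)
        assign_ident[i] <- st$identity[k]
        assign_covr[i] <- st$cov_pattern[k]
        assign_covm[i] <- st$cov_subject[k]
      }
    }
    if (is.na(best)) {
      rep_seqs <- c(rep_seqs, sq)
      rep_gene <- c(rep_gene, records$gene_id[i])
      rep_len <- c(rep_len, l)
      best <- length(rep_seqs)
      assign_ident[i] <- 1
      assign_covr[i] <- 1
      assign_covm[i] <- 1
    }
    assign_cluster[i] <- best
  }

  cluster_ids <- sprintf("C%04d", seq_along(rep_seqs))
  members <- tibble::tibble(
    gene_id = records$gene_id, strain = records$strain,
    cluster = cluster_ids[assign_cluster],
    identity = assign_ident, cov_rep = assign_covr, cov_member = assign_covm
  )
  if ("premature_stop" %in% names(records)) {
    members$premature_stop <- records$premature_stop
  }
  if ("scenario" %in% names(records)) members$scenario <- records$scenario
  structure(
    list(members = members,
         representatives = tibble::tibble(cluster = cluster_ids,
                                          gene_id = rep_gene, seq = rep_seqs),
         params = list(identity = identity, cov_long = cov_long,
                       cov_short = cov_short)),
    class = "protein_clustering"
  )
}

#' @export
print.protein_clustering <- function(x, ...) {
  cat("<protein_clustering> ", nrow(x$members), " genes in ",
      nrow(x$representatives), " clusters\n", sep = "")
  invisible(x)
}

#' Build the gene presence/absence matrix (PAM)
#'
#' The PAM has gene clusters in rows and strains in columns; each cell holds
#' the (possibly empty) set of that strain's member genes. Internally it is
#' stored long form as a gene table; [pam_matrix()] gives the wide view.
#' Every gene belongs to exactly one cell (the PAM partitions the gene set).
#'
#' @param clustering A [cluster_proteins()] result, or a tibble with columns
#'   `gene_id`, `strain`, `cluster` (optionally `premature_stop`,
#'   `scenario`).
#' @param strains Character vector of strain ids (columns). Defaults to the
#'   strains present; genes from strains outside this set are an error.
#' @return A `pam` object: list with `genes` (tibble `gene_id`, `strain`,
#'   `cluster`, `premature_stop`, `scenario`), `clusters`, `strains`.
#' @export
build_pam <- function(clustering, strains = NULL) {
  genes <- if (inherits(clustering, "protein_clustering")) {
    clustering$members
  } else {
    tibble::as_tibble(clustering)
  }
  stopifnot(all(c("gene_id", "strain", "cluster") %in% names(genes)))
  if (!"premature_stop" %in% names(genes)) genes$premature_stop <- FALSE
  if (!"scenario" %in% names(genes)) genes$scenario <- "none"
  genes <- genes[, c("gene_id", "strain", "cluster", "premature_stop", "scenario")]
  if (is.null(strains)) strains <- sort(unique(genes$strain))
  unknown <- setdiff(unique(genes$strain), strains)
  if (length(unknown)) {
    stop("genes from strains not in the strain set: ",
         paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("gene ids appear in more than one PAM cell: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  structure(
    list(genes = genes,
         clusters = sort(unique(genes$cluster)),
         strains = strains),
    class = "panmet_pam"
  )
}

#' @export
print.panmet_pam <- function(x, ...) {
  cat("<pam> ", length(x$clusters), " clusters x ", length(x$strains),
      " strains (", nrow(x$genes), " genes)\n", sep = "")
  invisible(x)
}

#' Wide cluster-by-strain view of a PAM
#' @param pam A `pam` object.
#' @return Tibble with a `cluster` column and one column per strain holding
#'   comma-joined member gene ids (`""` where absent).
#' @export
pam_matrix <- function(pam) {
  g <- pam$genes
  cells <- dplyr::summarise(
    dplyr::group_by(g, .data$cluster, .data$strain),
    genes = paste(sort(.data$gene_id), collapse = ","), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(cells, names_from = "strain",
                             values_from = "genes", values_fill = "")
  for (s in setdiff(pam$strains, names(wide))) wide[[s]] <- ""
  wide <- wide[match(pam$clusters, wide$cluster), c("cluster", pam$strains)]
  wide
}

#' Read / write a PAM as TSV
#'
#' The TSV has clusters in rows, strains in columns, and comma-joined gene
#' ids in cells (empty cell = cluster absent from that strain). Gene flags
#' (premature stops, recovery scenario) are stored in a side table
#' `<path>.genes.tsv`.
#'
#' @param pam A `pam` object.
#' @param path Output TSV path.
#' @return `write_pam()` returns `path` invisibly; `read_pam()` a `pam`.
#' @export
write_pam <- function(pam, path) {
  readr::write_tsv(pam_matrix(pam), path)
  readr::write_tsv(pam$genes, paste0(path, ".genes.tsv"))
  invisible(path)
}

#' @rdname write_pam
#' @export
read_pam <- function(path) {
  side <- paste0(path, ".genes.tsv")
  if (file.exists(side)) {
    genes <- readr::read_tsv(side, show_col_types = FALSE,
                             col_types = readr::cols(
                               premature_stop = readr::col_logical()))
    wide <- readr::read_tsv(path, show_col_types = FALSE)
    return(build_pam(genes, strains = setdiff(names(wide), "cluster")))
  }
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  strains <- setdiff(names(wide), "cluster")
  long <- tidyr::pivot_longer(wide, -"cluster", names_to = "strain",
                              values_to = "genes")
  long <- long[!is.na(long$genes) & long$genes != "", ]
  genes <- tidyr::separate_rows(long, "genes", sep = ",")
  names(genes)[names(genes) == "genes"] <- "gene_id"
  build_pam(genes[, c("gene_id", "strain", "cluster")], strains = strains)
}

# Mapping cluster -> character vector of the strain's usable (non-premature)
# genes, for GPR substitution during derivation.
pam_strain_mapping <- function(pam, strain, include_premature = FALSE) {
  g <- pam$genes[pam$genes$strain == strain, ]
  if (!include_premature) g <- g[!g$premature_stop, ]
  split(g$gene_id, factor(g$cluster, levels = pam$clusters))
}
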