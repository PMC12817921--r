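# Assembly statistics and strain quality filtering.

#' QC thresholds for strain filtering
#'
#' Defaults follow common practice for bacterial draft assemblies: at most
#' 2% missing and 100% fragmented expected single-copy orthologs, N50 of at
#' least 50,000 bp, and at most 200 contigs. All comparisons are inclusive
#' (a strain exactly at a threshold is kept).
#'
#' @param max_missing_pct Maximum percent of missing single-copy orthologs.
#' @param max_fragmented_pct Maximum percent of fragmented orthologs.
#' @param min_n50 Minimum N50 in bp.
#' @param max_contigs Maximum number of contigs.
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(max_missing_pct = 2, max_fragmented_pct = 100,
                          min_n50 = 50000, max_contigs = 200) {
  th <- list(max_missing_pct = max_missing_pct,
             max_fragmented_pct = max_fragmented_pct,
             min_n50 = min_n50, max_contigs = max_contigs)
  stopifnot(all(unlist(th) >= 0))
  th
}

#' Assembly statistics from a genome FASTA
#'
#' N50 is the length of the contig at which the cumulative length of contigs
#' sorted in descending order first reaches at least half of the total
#' assembly length.
#'
#' @param genome Path to a nucleotide FASTA file, a
#'   [Biostrings::DNAStringSet], or a numeric vector of contig lengths.
#' @param strain Strain id recorded in the result (defaults to the file
#'   base name).
#' @return One-row tibble with `strain`, `n_contigs`, `n50`, `total_length`.
#' @export
assembly_stats <- function(genome, strain = NULL) {
  if (is.character(genome)) {
    if (is.null(strain)) strain <- tools::file_path_sans_ext(basename(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  }
  lens <- if (is.numeric(genome)) as.integer(genome) else Biostrings::width(genome)
  lens <- lens[lens > 0]
  if (length(lens) == 0L) stop("empty genome: no non-empty contigs")
  if (is.null(strain)) strain <- NA_character_
  sorted <- sort(lens, decreasing = TRUE)
  csum <- cumsum(as.numeric(sorted))
  n50 <- sorted[which(csum >= sum(as.numeric(lens)) / 2)[1L]]
  tibble::tibble(strain = strain, n_contigs = length(lens),
                 n50 = as.integer(n50), total_length = sum(lens))
}

#' Filter strains on assembly and completeness quality
#'
#' A strain is kept iff it satisfies all four thresholds:
#' `pct_missing <= max_missing_pct`, `pct_fragmented <= max_fragmented_pct`,
#' `n50 >= min_n50`, and `n_contigs <= max_contigs`. Comparisons are
#' inclusive, so boundary values are kept. All failing criteria are reported
#' per strain.
#'
#' @param stats Tibble of [assembly_stats()] rows (`strain`, `n_contigs`,
#'   `n50`).
#' @param completeness Tibble with `strain`, `pct_missing`, `pct_fragmented`
#'   (percentages in \[0, 100\]).
#' @param thresholds A [qc_thresholds()] list.
#' @param on_missing_completeness `"error"` (default) to fail on strains
#'   without a completeness record, `"discard"` to drop them with reason
#'   `"no_completeness_record"`.
#' @return Tibble with `strain`, `keep`, and `reasons` (comma-joined failing
#'   criteria, `""` when kept).
#' @export
qc_filter <- function(stats, completeness,
                      thresholds = qc_thresholds(),
                      on_missing_completeness = c("error", "discard")) {
  on_missing_completeness <- match.arg(on_missing_completeness)
  stats <- tibble::as_tibble(stats)
  completeness <- tibble::as_tibble(completeness)
  stopifnot(all(completeness$pct_missing >= 0 & completeness$pct_missing <= 100),
            all(completeness$pct_fragmented >= 0 & completeness$pct_fragmented <= 100))
  tab <- dplyr::left_join(stats, completeness, by = "strain")
  absent <- tab$strain[is.na(tab$pct_missing) | is.na(tab$pct_fragmented)]
  if (length(absent) && on_missing_completeness == "error") {
    stop("no completeness record for strain(s): ", paste(absent, collapse = ", "))
  }
  out <- dplyr::rowwise(tab)
  out <- dplyr::mutate(out, reasons = {
    fails <- character(0)
    if (is.na(.data$pct_missing) || is.na(.data$pct_fragmented)) {
      fails <- "no_completeness_record"
    } else {
      if (.data$pct_missing > thresholds$max_missing_pct) {
        fails <- c(fails, "max_missing_pct")
      }
      if (.data$pct_fragmented > thresholds$max_fragmented_pct) {
        fails <- c(fails, "max_fragmented_pct")
      }
    }
    if (.data$n50 < thresholds$min_n50) fails <- c(fails, "min_n50")
    if (.data$n_contigs > thresholds$max_contigs) fails <- c(fails, "max_contigs")
    paste(fails, collapse = ",")
  })
  out <- dplyr::ungroup(out)
  out$keep <- out$reasons == ""
  out[, c("strain", "keep", "reasons", "n_contigs", "n50",
          "pct_missing", "pct_fragmented")]
}
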