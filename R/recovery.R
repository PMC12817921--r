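# Three-scenario gene recovery: mitigates assembly/gene-calling errors by
# re-examining the genome sequence against cluster representatives.
#   (i)   a premature stop codon broke a protein into two annotated pieces;
#   (ii)  a gene sits in a region overlooked by the gene caller;
#   (iii) a gene extends beyond an annotated (truncated) call into
#         unannotated sequence.
# Recovered genes get ids "<strain>_rec<N>" and update the PAM.

#' Tuning parameters for gene recovery
#'
#' @param min_region Minimum length (bp) of an unannotated region searched
#'   in scenario (ii). Default 60.
#' @param max_pair_gap Maximum genomic gap (bp) between two same-strand
#'   annotated genes considered as a broken pair in scenario (i). Default
#'   300.
#' @param flank Window extension (bp) into unannotated sequence around an
#'   annotated gene in scenario (iii). Default 900.
#' @return Named list of parameters.
#' @export
recovery_params <- function(min_region = 60, max_pair_gap = 300, flank = 900) {
  list(min_region = min_region, max_pair_gap = max_pair_gap, flank = flank)
}

#' Read gene coordinates from a GFF3 file
#'
#' Keeps CDS features (or gene features when no CDS is present) and returns
#' 1-based inclusive coordinates as in the file; conversion to the 0-based
#' half-open convention happens internally during recovery.
#'
#' @param path GFF3 file path.
#' @return Tibble with `contig`, `start`, `end`, `strand`, `gene_id`.
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  types <- as.character(gr$type)
  keep <- if (any(types == "CDS")) types == "CDS" else types == "gene"
  gr <- gr[keep]
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  tibble::tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    gene_id = as.character(ids)
  )
}

translate_dna <- function(dna) {
  # dna: DNAString; returns protein with stops as "*"
  n <- 3L * (length(dna) %/% 3L)
  if (n < 3L) return("")
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::subseq(dna, 1L, n), if.fuzzy.codon = "X")))
}

# Align cluster representatives against one translated query; returns best
# acceptable hit or NULL.
best_rep_hit <- function(rep_tab, query, identity_min, cov_long, cov_short = NULL) {
  if (nrow(rep_tab) == 0L || nchar(query) < 10L) return(NULL)
  # a representative longer than query/cov_long cannot reach its coverage
  rep_tab <- rep_tab[nchar(rep_tab$seq) * cov_long <= nchar(query) + 2L, ,
                     drop = FALSE]
  if (nrow(rep_tab) == 0L) return(NULL)
  st <- align_identity_many(rep_tab$seq, query)
  ok <- st$identity >= identity_min & st$cov_pattern >= cov_long
  if (!is.null(cov_short)) ok <- ok & st$cov_subject >= cov_short
  if (!any(ok)) return(NULL)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(rep_tab$seq[ok][which.max(st$identity[ok])]),
    Biostrings::AAString(query), type = "overlap",
    substitutionMatrix = "BLOSUM62",
    gapOpening = AA_GAP_PENALTY[["opening"]],
    gapExtension = AA_GAP_PENALTY[["extension"]]
  )
  sr <- methods::slot(Biostrings::subject(al), "range")
  best <- which(ok)[which.max(st$identity[ok])]
  list(cluster = rep_tab$cluster[best],
       identity = st$identity[best],
       cov_rep = st$cov_pattern[best],
       q_start = BiocGenerics::start(sr)[1L],
       q_end = BiocGenerics::end(sr)[1L])
}

#' Recover genes missed or broken by assembly and gene calling
#'
#' Re-examines one strain's genome against the cluster representatives and
#' handles three scenarios: (i) two adjacent same-strand annotated genes
#' whose concatenated proteins align to one representative are merged into a
#' single record flagged `premature_stop = TRUE`, replacing the two parts in
#' the PAM; (ii) unannotated regions (at least `min_region` bp) are
#' six-frame translated and searched against representatives of clusters
#' empty for the strain — hits become recovered records (`premature_stop`
#' set when an internal stop interrupts the aligned span); (iii) windows
#' extending an annotated gene into adjacent unannotated sequence are
#' searched the same way, and a hit extending past the annotated part
#' yields a record flagged `premature_stop = TRUE` that replaces the
#' truncated annotated gene. Overlapping calls at one locus are resolved by
#' highest identity, then longest, then lexicographically smallest cluster.
#'
#' @param genome `DNAStringSet` (or FASTA path) of the strain's contigs.
#' @param gff Tibble from [read_gff_genes()] (or GFF3 path): 1-based
#'   inclusive gene coordinates.
#' @param clustering A [cluster_proteins()] result (supplies representatives
#'   and thresholds).
#' @param pam The current [build_pam()] object.
#' @param strain Strain id whose genome is examined.
#' @param proteins Tibble `gene_id`, `seq` with the strain's annotated
#'   protein sequences (needed for scenario i).
#' @param params [recovery_params()].
#' @return List with `records` (tibble of recovered genes: `gene_id`,
#'   `strain`, `seq`, `cluster`, `scenario`, `premature_stop`, `contig`,
#'   `start`, `end`, `identity`, `replaces`) and `pam` (updated).
#' @export
recover_genes <- function(genome, gff, clustering, pam, strain, proteins,
                          params = recovery_params()) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(gff)) gff <- read_gff_genes(gff)
  gff <- tibble::as_tibble(gff)
  missing_contigs <- setdiff(unique(gff$contig), names(genome))
  if (length(missing_contigs)) {
    stop("GFF contigs not in the genome FASTA: ",
         paste(missing_contigs, collapse = ", "))
  }
  idmin <- clustering$params$identity
  cov_long <- clustering$params$cov_long
  cov_short <- clustering$params$cov_short
  reps <- clustering$representatives

  strain_clusters <- unique(pam$genes$cluster[pam$genes$strain == strain])
  empty_reps <- reps[!reps$cluster %in% strain_clusters, , drop = FALSE]
  prot_seq <- stats::setNames(proteins$seq, proteins$gene_id)

  calls <- list()
  add_call <- function(scenario, seqaa, cluster, identity, contig, s, e,
                       premature, replaces) {
    calls[[length(calls) + 1L]] <<- tibble::tibble(
      scenario = scenario, seq = gsub("\\*", "X", seqaa), cluster = cluster,
      identity = identity, contig = contig, start = s, end = e,
      premature_stop = premature, replaces = list(replaces)
    )
  }

  # ---- scenario (i): adjacent split pairs ----------------------------------
  ann <- gff[order(gff$contig, gff$start), ]
  if (nrow(ann) >= 2L) {
    for (k in seq_len(nrow(ann) - 1L)) {
      a <- ann[k, ]; b <- ann[k + 1L, ]
      if (a$contig != b$contig || a$strand != b$strand) next
      if (b$start - a$end - 1L > params$max_pair_gap) next
      pa <- prot_seq[a$gene_id]; pb <- prot_seq[b$gene_id]
      if (is.na(pa) || is.na(pb)) next
      concat <- if (a$strand == "+") paste0(pa, pb) else paste0(pb, pa)
      # only clusters empty for this strain can gain a merged fragment;
      # otherwise an intact neighbor would be re-absorbed spuriously
      hit <- best_rep_hit(empty_reps, concat, idmin, cov_long, cov_short)
      if (is.null(hit)) next
      add_call("i", concat, hit$cluster, hit$identity, a$contig,
               a$start, b$end, TRUE, c(a$gene_id, b$gene_id))
    }
  }

  # ---- scenario (ii): unannotated regions ----------------------------------
  for (ctg in names(genome)) {
    clen <- Biostrings::width(genome[ctg])
    covered <- ann[ann$contig == ctg, ]
    free <- find_free_regions(clen, covered$start, covered$end)
    free <- free[free$end - free$start + 1L >= params$min_region, , drop = FALSE]
    if (nrow(empty_reps)) {
      # a region shorter than the shortest candidate's covered span is dead
      min_span <- 3L * ceiling(cov_long * min(nchar(empty_reps$seq)))
      free <- free[free$end - free$start + 1L >= min_span, , drop = FALSE]
    } else {
      free <- free[0L, , drop = FALSE]
    }
    for (k in seq_len(nrow(free))) {
      region <- Biostrings::subseq(genome[[ctg]], free$start[k], free$end[k])
      hit <- scan_region_frames(region, empty_reps, idmin, cov_long)
      if (is.null(hit)) next
      gcoord <- frame_to_genomic(hit, free$start[k], length(region))
      add_call("ii", hit$sub_seq, hit$cluster, hit$identity, ctg,
               gcoord[1L], gcoord[2L], hit$premature, character(0))
    }
  }

  # ---- scenario (iii): extension of annotated genes ------------------------
  for (k in seq_len(nrow(ann))) {
    a <- ann[k, ]
    ctg <- a$contig
    clen <- Biostrings::width(genome[ctg])
    others <- ann[ann$contig == ctg & ann$gene_id != a$gene_id, ]
    lo_lim <- max(c(1L, others$end[others$end < a$start] + 1L))
    hi_lim <- min(c(clen, others$start[others$start > a$end] - 1L))
    w_start <- max(lo_lim, a$start - params$flank)
    w_end <- min(hi_lim, a$end + params$flank)
    if (w_start == a$start && w_end == a$end) next
    # keep the annotated gene's reading frame within the window
    if (a$strand == "+") {
      w_start <- w_start + (a$start - w_start) %% 3L
    } else {
      w_end <- w_end - (w_end - a$end) %% 3L
    }
    if (w_end - w_start + 1L < 30L) next
    ann_aa <- floor((a$end - a$start + 1L) / 3L)
    if ((w_end - w_start + 1L) - (a$end - a$start + 1L) < 30L) next
    # only representatives reaching past the annotated part can qualify
    cand_reps <- empty_reps[nchar(empty_reps$seq) > ann_aa, , drop = FALSE]
    if (nrow(cand_reps) == 0L) next
    dna <- Biostrings::subseq(genome[[ctg]], w_start, w_end)
    if (a$strand == "-") dna <- Biostrings::reverseComplement(dna)
    tr <- translate_dna(dna)
    hit <- best_rep_hit(cand_reps, tr, idmin, cov_long)
    if (is.null(hit)) next
    span <- hit$q_end - hit$q_start + 1L
    if (span <= ann_aa) next
    sub_seq <- substr(tr, hit$q_start, hit$q_end)
    if (a$strand == "+") {
      g_s <- w_start + (hit$q_start - 1L) * 3L
      g_e <- w_start + hit$q_end * 3L - 1L
    } else {
      g_e <- w_end - (hit$q_start - 1L) * 3L
      g_s <- w_end - hit$q_end * 3L + 1L
    }
    add_call("iii", sub_seq, hit$cluster, hit$identity, ctg, g_s, g_e,
             TRUE, a$gene_id)
  }

  if (length(calls) == 0L) {
    return(list(records = empty_recovery_records(), pam = pam))
  }
  calls <- dplyr::bind_rows(calls)

  # overlap resolution: highest identity, then longest, then smallest cluster
  calls <- calls[order(-calls$identity, -(calls$end - calls$start), calls$cluster), ]
  accepted <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    ov <- accepted &
      calls$contig == calls$contig[i] &
      calls$start <= calls$end[i] & calls$end >= calls$start[i]
    accepted[i] <- !any(ov)
  }
  calls <- calls[accepted, ]
  calls <- calls[order(calls$contig, calls$start), ]
  calls$gene_id <- paste0(strain, "_rec", seq_len(nrow(calls)))
  calls$strain <- strain

  # PAM update: drop replaced genes, add recovered records
  replaced <- unlist(calls$replaces)
  genes <- pam$genes[!(pam$genes$gene_id %in% replaced &
                         pam$genes$strain == strain), ]
  genes <- dplyr::bind_rows(genes, tibble::tibble(
    gene_id = calls$gene_id, strain = strain, cluster = calls$cluster,
    premature_stop = calls$premature_stop, scenario = calls$scenario
  ))
  new_pam <- build_pam(genes, strains = pam$strains)

  records <- calls[, c("gene_id", "strain", "seq", "cluster", "scenario",
                       "premature_stop", "contig", "start", "end", "identity",
                       "replaces")]
  list(records = records, pam = new_pam)
}

empty_recovery_records <- function() {
  tibble::tibble(gene_id = character(0), strain = character(0),
                 seq = character(0), cluster = character(0),
                 scenario = character(0), premature_stop = logical(0),
                 contig = character(0), start = integer(0), end = integer(0),
                 identity = numeric(0), replaces = list())
}

# Unannotated intervals (1-based inclusive) of a contig of length `clen`
# given annotated gene intervals.
find_free_regions <- function(clen, starts, ends) {
  if (length(starts) == 0L) {
    return(tibble::tibble(start = 1L, end = as.integer(clen)))
  }
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  # merge overlapping annotation
  ms <- starts[1L]; me <- ends[1L]
  merged_s <- integer(0); merged_e <- integer(0)
  for (k in seq_along(starts)[-1L]) {
    if (starts[k] <= me + 1L) {
      me <- max(me, ends[k])
    } else {
      merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
      ms <- starts[k]; me <- ends[k]
    }
  }
  merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
  free_s <- c(1L, merged_e + 1L)
  free_e <- c(merged_s - 1L, as.integer(clen))
  keep <- free_s <= free_e
  tibble::tibble(start = free_s[keep], end = free_e[keep])
}

# Scan a region in all six frames against candidate representatives.
scan_region_frames <- function(region, rep_tab, idmin, cov_long) {
  if (nrow(rep_tab) == 0L) return(NULL)
  best <- NULL
  for (strand in c("+", "-")) {
    dna <- if (strand == "+") region else Biostrings::reverseComplement(region)
    for (off in 0:2) {
      if (length(dna) - off < 30L) next
      tr <- translate_dna(Biostrings::subseq(dna, off + 1L, length(dna)))
      hit <- best_rep_hit(rep_tab, tr, idmin, cov_long)
      if (is.null(hit)) next
      sub_seq <- substr(tr, hit$q_start, hit$q_end)
      hit$sub_seq <- sub_seq
      hit$premature <- grepl("\\*", sub_seq)
      hit$strand <- strand
      hit$offset <- off
      if (is.null(best) || hit$identity > best$identity) best <- hit
    }
  }
  best
}

# Genomic coordinates (1-based inclusive, forward strand) of the aligned
# span of a frame hit within a region starting at `region_start`.
frame_to_genomic <- function(hit, region_start, region_len) {
  if (hit$strand == "+") {
    s <- region_start + hit$offset + (hit$q_start - 1L) * 3L
    e <- region_start + hit$offset + hit$q_end * 3L - 1L
  } else {
    e <- region_start + region_len - 1L - hit$offset - (hit$q_start - 1L) * 3L
    s <- region_start + region_len - 1L - hit$offset - hit$q_end * 3L + 1L
  }
  c(as.integer(s), as.integer(e))
}
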