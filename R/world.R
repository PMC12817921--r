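# Seeded synthetic-world generator.
#
# The world emulates a small bacterial clade: a reaction universe (~40
# reactions) with linear pathways, one multi-subunit complex, an isoform
# pair, spontaneous diffusion steps and exchanges; gene families with
# protein sequences (within-family identity ~0.97, between-family identity
# at random-sequence background); a strain roster partitioned into
# metabolic groups by pathway modules (xylose catabolism, histamine
# synthesis, tryptophan-synthase loss); planted gene-recovery cases
# (split / unannotated / truncated genes); genomes + GFF + proteomes; a
# curated reference model covering a subset of the universe with one
# orphan reaction and an NGAM; media recipes and completeness tables; and
# the ground truth for every downstream prediction.
#
# All element formulas are constructed so that every internal reaction
# except the biomass and one deliberately broken decoy is mass-balanced.

WORLD_CODONS <- c(
  F = "TTT", L = "CTG", I = "ATT", M = "ATG", V = "GTG", S = "TCT",
  P = "CCG", T = "ACT", A = "GCG", Y = "TAT", H = "CAT", Q = "CAG",
  N = "AAT", K = "AAA", D = "GAT", E = "GAA", C = "TGT", W = "TGG",
  R = "CGT", G = "GGT", `*` = "TAA"
)

aa_to_dna <- function(protein) {
  paste(WORLD_CODONS[strsplit(protein, "")[[1L]]], collapse = "")
}

random_aa <- function(n) {
  paste(sample(names(WORLD_CODONS)[names(WORLD_CODONS) != "*"], n,
               replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1L]]
  n_mut <- round(rate * length(ch))
  if (n_mut == 0L) return(seq)
  pos <- sample(seq_along(ch), n_mut)
  aas <- names(WORLD_CODONS)[names(WORLD_CODONS) != "*"]
  for (p in pos) ch[p] <- sample(setdiff(aas, ch[p]), 1L)
  paste(ch, collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

world_formulas <- function() {
  c(glc__D = "C6H12O6", xyl__D = "C5H10O5", xylu = "C5H10O5",
    g6p = "C6H13O9P", pyr = "C3H4O3",
    atp = "C10H16N5O13P3", adp = "C10H15N5O10P2", pi = "H3O4P",
    nh4 = "H3N", so4 = "H2O4S", o2 = "O2", co2 = "CO2", h2o = "H2O", h = "H",
    aa = "C3H9NO7S", nuc = "C9H22NO16PS", trp__L = "C6H18N2O14S2",
    hista = "C2H9NO5S", acc1 = "C6H8O6", acc2 = "C6H18N2O14S2",
    acc3 = "C18H44N2O32P2S2", refm = "C9H22NO16PS",
    badA = "CH4", badB = "CH5O", fakeA = "CH4", fakeB = "CH4")
}

# compartments of each metabolite basename (e and/or c)
world_met_compartments <- function() {
  e_and_c <- c("glc__D", "xyl__D", "nh4", "pi", "so4", "o2", "co2", "h2o",
               "h", "trp__L", "hista")
  c_only <- c("xylu", "g6p", "pyr", "atp", "adp", "aa", "nuc", "acc1",
              "acc2", "acc3", "refm", "badA", "badB", "fakeA", "fakeB")
  list(both = e_and_c, cytosol = c_only)
}

world_metabolites <- function(basenames_e, basenames_c) {
  f <- world_formulas()
  dplyr::bind_rows(
    tibble::tibble(id = paste0(basenames_e, "_e"), name = basenames_e,
                   formula = unname(f[basenames_e]), charge = 0L,
                   compartment = "e"),
    tibble::tibble(id = paste0(basenames_c, "_c"), name = basenames_c,
                   formula = unname(f[basenames_c]), charge = 0L,
                   compartment = "c")
  )
}

# Reaction definitions shared by the universe and the reference model.
# gpr strings are in universal-gene space ("spontaneous" = sentinel).
world_reaction_defs <- function() {
  tr <- function(base) stats::setNames(c(-1, 1), paste0(base, c("_e", "_c")))
  list(
    GLCt = list(name = "D-glucose transport", stoich = tr("glc__D"),
                gpr = "U_glct"),
    XYLt = list(name = "D-xylose transport", stoich = tr("xyl__D"),
                gpr = "U_xylt"),
    NH4t = list(name = "ammonia transport", stoich = tr("nh4"), gpr = "U_nh4t"),
    PIt = list(name = "phosphate transport", stoich = tr("pi"), gpr = "U_pit"),
    SO4t = list(name = "sulfate transport", stoich = tr("so4"), gpr = "U_so4t"),
    TRPt = list(name = "L-tryptophan transport", stoich = tr("trp__L"),
                gpr = "U_trpt"),
    HISTAt = list(name = "histamine export",
                  stoich = c(hista_c = -1, hista_e = 1), gpr = "U_histat"),
    O2t = list(name = "O2 diffusion", stoich = tr("o2"), gpr = "spontaneous"),
    CO2t = list(name = "CO2 diffusion", stoich = c(co2_c = -1, co2_e = 1),
                gpr = ""),
    H2Ot = list(name = "H2O diffusion", stoich = tr("h2o"),
                gpr = "spontaneous", lower = -1000),
    Ht = list(name = "H+ diffusion", stoich = tr("h"), gpr = "spontaneous",
              lower = -1000),
    HEX = list(name = "hexokinase",
               stoich = c(glc__D_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1),
               gpr = "U_hex"),
    GLYC = list(name = "glycolysis (lumped)",
                stoich = c(g6p_c = -1, adp_c = -3, pi_c = -2, pyr_c = 2,
                           atp_c = 3, h2o_c = 2, h_c = 4),
                gpr = "U_glycA and U_glycB"),
    RESP = list(name = "pyruvate respiration (lumped)",
                stoich = c(pyr_c = -1, o2_c = -2.5, adp_c = -3, pi_c = -3,
                           co2_c = 3, atp_c = 3, h2o_c = 5),
                gpr = "U_resp"),
    AAS = list(name = "amino acid pool synthesis",
               stoich = c(pyr_c = -1, nh4_c = -1, so4_c = -1, atp_c = -1,
                          h2o_c = -1, aa_c = 1, adp_c = 1, pi_c = 1),
               gpr = "U_aas1 or U_aas2"),
    NUCS = list(name = "nucleotide pool synthesis",
                stoich = c(aa_c = -1, g6p_c = -1, atp_c = -1, h2o_c = -1,
                           nuc_c = 1, adp_c = 1, pi_c = 1),
                gpr = "U_nucs"),
    TRPS = list(name = "tryptophan synthase (lumped)",
                stoich = c(aa_c = -2, atp_c = -1, h2o_c = -1, trp__L_c = 1,
                           adp_c = 1, pi_c = 1),
                gpr = "U_trps"),
    HISDC = list(name = "histidine decarboxylase (lumped)",
                 stoich = c(aa_c = -1, hista_c = 1, co2_c = 1),
                 gpr = "U_hisdc"),
    XYLI = list(name = "xylose isomerase",
                stoich = c(xyl__D_c = -1, xylu_c = 1), gpr = "U_xyli"),
    XYLK = list(name = "xylulose assimilation (lumped)",
                stoich = c(xylu_c = -6, atp_c = -6, h2o_c = -1, g6p_c = 5,
                           adp_c = 6, pi_c = 1),
                gpr = "U_xylk"),
    ACC1 = list(name = "accessory condensation 1",
                stoich = c(pyr_c = -2, acc1_c = 1), gpr = "U_acc1"),
    ACC2 = list(name = "accessory condensation 2",
                stoich = c(aa_c = -2, acc2_c = 1), gpr = "U_acc2"),
    ACC3 = list(name = "accessory condensation 3",
                stoich = c(nuc_c = -2, acc3_c = 1), gpr = "U_acc3"),
    BADRXN = list(name = "broken annotation artifact",
                  stoich = c(badA_c = -1, badB_c = 1), gpr = "U_bad"),
    DECOYAND = list(name = "decoy complex reaction",
                    stoich = c(fakeA_c = -1, fakeB_c = 1),
                    gpr = "U_dec1 and U_glct"),
    DECOY2 = list(name = "decoy isolated reaction",
                  stoich = c(fakeB_c = -1, fakeA_c = 1), gpr = "U_dec2"),
    REFSPEC = list(name = "reference-specific isomerase",
                   stoich = c(nuc_c = -1, refm_c = 1), gpr = "R_refonly"),
    ATPM = list(name = "ATP maintenance requirement",
                stoich = c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1),
                gpr = ""),
    BIOMASS = list(name = "biomass assembly",
                   stoich = c(aa_c = -5, nuc_c = -2, trp__L_c = -0.2,
                              atp_c = -20, h2o_c = -20, adp_c = 20, pi_c = 20),
                   gpr = "")
  )
}

build_world_model <- function(id, reaction_ids, objective = "BIOMASS",
                              exchange_lower = -1000, atpm_lower = 0,
                              spontaneous_sentinel = TRUE) {
  defs <- world_reaction_defs()[reaction_ids]
  rxns <- dplyr::bind_rows(lapply(names(defs), function(rid) {
    d <- defs[[rid]]
    tibble::tibble(id = rid, name = d$name, stoich = list(d$stoich),
                   lower = d$lower %||% 0, upper = 1000,
                   gpr = list(gpr_parse(d$gpr)), spontaneous = FALSE,
                   annotations = list(list()))
  }))
  used <- unique(unlist(lapply(rxns$stoich, names)))
  basen <- unique(sub("_[ec]$", "", used))
  comp <- world_met_compartments()
  mets <- world_metabolites(intersect(basen, comp$both),
                            intersect(basen, c(comp$both, comp$cytosol)))
  mets <- mets[mets$id %in% used, ]
  # exchanges for all extracellular metabolites
  ex <- tibble::tibble(
    id = paste0("EX_", mets$id[mets$compartment == "e"]),
    name = paste(mets$name[mets$compartment == "e"], "exchange"),
    stoich = lapply(mets$id[mets$compartment == "e"],
                    function(m) stats::setNames(-1, m)),
    lower = exchange_lower, upper = 1000,
    gpr = replicate(sum(mets$compartment == "e"), gpr_empty(), simplify = FALSE),
    spontaneous = FALSE,
    annotations = replicate(sum(mets$compartment == "e"), list(), simplify = FALSE)
  )
  rxns <- dplyr::bind_rows(rxns, ex)
  rxns$lower[rxns$id == "ATPM"] <- atpm_lower
  m <- metabolic_model(id, mets, rxns, objective = objective)
  if (spontaneous_sentinel) m <- normalize_spontaneous(m) else m
}

world_family_table <- function() {
  tibble::tibble(
    family = c("glct", "hex", "glycA", "glycB", "resp", "aas1", "aas2",
               "nucs", "trps", "nh4t", "pit", "so4t", "trpt", "histat",
               "xylt", "xyli", "xylk", "hisdc", "acc1", "acc2", "acc3",
               "bad"),
    universal_gene = paste0("U_", c("glct", "hex", "glycA", "glycB", "resp",
                                    "aas1", "aas2", "nucs", "trps", "nh4t",
                                    "pit", "so4t", "trpt", "histat", "xylt",
                                    "xyli", "xylk", "hisdc", "acc1", "acc2",
                                    "acc3", "bad"))
  )
}

# family -> reaction module memberships used for ground truth
WORLD_CORE_FAMILIES <- c("glct", "hex", "glycA", "glycB", "resp", "aas1",
                         "nucs", "nh4t", "pit", "so4t", "trpt", "bad")
WORLD_XYL_FAMILIES <- c("xylt", "xyli", "xylk")
WORLD_HIS_FAMILIES <- c("hisdc", "histat")
WORLD_ACC_FAMILIES <- c("acc1", "acc2", "acc3")

#' Generate the seeded synthetic world
#'
#' Produces strain proteomes, genomes with GFF annotation, a reaction
#' universe with universal-gene sequences, a curated reference model with
#' proteome, media recipes, completeness tables, and the planted ground
#' truth for clustering, recovery, derivation, phenotypes, and strain
#' groups. Identical parameters and seed give identical output.
#'
#' Strain groups differ by pathway modules: group 1 carries the xylose
#' catabolism module (plus three accessory families used to plant the
#' recovery scenarios), group 2 the histamine synthesis module, and group 3
#' lacks tryptophan synthase (a tryptophan auxotroph). The first three
#' strains of group 1 carry the planted recovery cases: a split gene
#' (scenario i), an unannotated gene (scenario ii), and a truncated
#' annotation over a premature stop (scenario iii).
#'
#' @param seed Integer RNG seed.
#' @param n_strains Number of strains passing QC (default 20).
#' @param n_groups Number of metabolic groups, at most 3 (default 3).
#' @param mutation_rate Within-family per-residue substitution rate
#'   (default 0.03, keeping within-family identity ~0.97, safely above the
#'   0.90 clustering threshold; between-family identity stays at the
#'   random background).
#' @param n_qc_fail Extra strains designed to fail quality control.
#' @return A `synthetic_world` list; see [expected_truth()] for the ground
#'   truth accessors and [write_world()] for the on-disk layout.
#' @export
generate_world <- function(seed = 42, n_strains = 20, n_groups = 3,
                           mutation_rate = 0.03, n_qc_fail = 2) {
  stopifnot(n_groups >= 1, n_groups <= 3, n_strains >= 2 * n_groups)
  set.seed(seed)

  fams <- world_family_table()
  fams$length <- sample(120:300, nrow(fams), replace = TRUE)
  fams$base_seq <- vapply(fams$length, random_aa, character(1))
  decoys <- tibble::tibble(
    universal_gene = c("U_dec1", "U_dec2"),
    seq = vapply(c(170L, 190L), random_aa, character(1))
  )

  strains <- sprintf("S%02d", seq_len(n_strains))
  group_of <- rep(seq_len(n_groups), length.out = 0)
  sizes <- diff(floor(seq(0, n_strains, length.out = n_groups + 1)))
  group_of <- rep(seq_len(n_groups), times = sizes)
  roster <- tibble::tibble(strain = strains, group = paste0("G", group_of))

  fam_of_strain <- function(strain, group) {
    f <- WORLD_CORE_FAMILIES
    i <- match(strain, strains)
    if (i %% 2L == 0L) f <- c(f, "aas2")
    if (group == "G1") f <- c(f, WORLD_XYL_FAMILIES, WORLD_ACC_FAMILIES)
    if (group == "G2") f <- c(f, WORLD_HIS_FAMILIES)
    if (group %in% c("G1", "G2")) f <- c(f, "trps")
    f
  }

  # planted recovery strains: first three strains of group 1
  g1 <- roster$strain[roster$group == "G1"]
  rec_split <- if (length(g1) >= 1) g1[1] else NA_character_
  rec_unann <- if (length(g1) >= 2) g1[2] else NA_character_
  rec_trunc <- if (length(g1) >= 3) g1[3] else NA_character_

  proteins <- list()
  genomes <- list()
  gffs <- list()
  recovery_truth <- list()

  all_strain_rows <- dplyr::bind_rows(
    roster,
    tibble::tibble(strain = sprintf("BAD%d", seq_len(n_qc_fail)),
                   group = "QCFAIL")
  )

  for (r in seq_len(nrow(all_strain_rows))) {
    strain <- all_strain_rows$strain[r]
    group <- all_strain_rows$group[r]
    fam_list <- if (group == "QCFAIL") c("glct", "hex", "resp") else
      fam_of_strain(strain, group)

    variants <- stats::setNames(lapply(fam_list, function(f) {
      mutate_protein(fams$base_seq[fams$family == f], mutation_rate)
    }), fam_list)

    # per-gene genome segments: list(gene rows, dna)
    segs <- list()
    prots <- list()
    for (f in fam_list) {
      p <- variants[[f]]
      gid <- paste0(strain, "_", f)
      if (identical(strain, rec_split) && f == "acc1") {
        # scenario (i): internal stop splits the gene in two annotated parts
        m <- floor(nchar(p) / 2)
        pa <- substr(p, 1, m); pb <- substr(p, m + 1, nchar(p))
        segs[[length(segs) + 1L]] <- list(
          dna = paste0(aa_to_dna(pa), "TAA", aa_to_dna(pb), "TAA"),
          genes = tibble::tibble(
            gene_id = paste0(gid, c("a", "b")),
            offset = c(0L, 3L * m + 3L),
            len = c(3L * m, 3L * (nchar(p) - m) + 3L),
            strand = "+")
        )
        prots[[length(prots) + 1L]] <- tibble::tibble(
          gene_id = paste0(gid, c("a", "b")), strain = strain,
          seq = c(pa, pb), family = paste0(gid, c("a", "b")))
        recovery_truth[[length(recovery_truth) + 1L]] <- tibble::tibble(
          strain = strain, scenario = "i", family = f,
          premature_stop = TRUE, replaces = list(paste0(gid, c("a", "b"))))
        next
      }
      if (identical(strain, rec_unann) && f == "acc2") {
        # scenario (ii): intact gene missing from annotation and proteome
        segs[[length(segs) + 1L]] <- list(
          dna = paste0(aa_to_dna(p), "TAA"),
          genes = tibble::tibble(gene_id = character(0), offset = integer(0),
                                 len = integer(0), strand = character(0))
        )
        recovery_truth[[length(recovery_truth) + 1L]] <- tibble::tibble(
          strain = strain, scenario = "ii", family = f,
          premature_stop = FALSE, replaces = list(character(0)))
        next
      }
      if (identical(strain, rec_trunc) && f == "acc3") {
        # scenario (iii): annotation truncated at an internal stop
        m <- floor(nchar(p) / 2)
        pa <- substr(p, 1, m); pb <- substr(p, m + 1, nchar(p))
        segs[[length(segs) + 1L]] <- list(
          dna = paste0(aa_to_dna(pa), "TAA", aa_to_dna(pb), "TAA"),
          genes = tibble::tibble(gene_id = paste0(gid, "t"), offset = 0L,
                                 len = 3L * m, strand = "+")
        )
        prots[[length(prots) + 1L]] <- tibble::tibble(
          gene_id = paste0(gid, "t"), strain = strain, seq = pa,
          family = paste0(gid, "t"))
        recovery_truth[[length(recovery_truth) + 1L]] <- tibble::tibble(
          strain = strain, scenario = "iii", family = f,
          premature_stop = TRUE, replaces = list(paste0(gid, "t")))
        next
      }
      strand <- sample(c("+", "-"), 1L)
      cds <- paste0(aa_to_dna(p), "TAA")
      dna <- if (strand == "+") cds else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
      segs[[length(segs) + 1L]] <- list(
        dna = dna,
        genes = tibble::tibble(gene_id = gid, offset = 0L,
                               len = nchar(cds), strand = strand)
      )
      prots[[length(prots) + 1L]] <- tibble::tibble(
        gene_id = gid, strain = strain, seq = p, family = f)
    }

    segs <- segs[sample(length(segs))]
    n_contigs <- if (group == "QCFAIL") 1L else 3L
    contig_of <- sort(rep(seq_len(n_contigs), length.out = length(segs)))
    contig_seqs <- character(n_contigs)
    gff_rows <- list()
    for (ci in seq_len(n_contigs)) {
      parts <- character(0)
      cursor <- 0L
      for (si in which(contig_of == ci)) {
        spacer <- random_dna(sample(80:150, 1L))
        parts <- c(parts, spacer)
        cursor <- cursor + nchar(spacer)
        sg <- segs[[si]]
        g <- sg$genes
        if (nrow(g)) {
          gff_rows[[length(gff_rows) + 1L]] <- tibble::tibble(
            contig = paste0(strain, "_ctg", ci),
            start = cursor + g$offset + 1L,
            end = cursor + g$offset + g$len,
            strand = g$strand, gene_id = g$gene_id
          )
        }
        parts <- c(parts, sg$dna)
        cursor <- cursor + nchar(sg$dna)
      }
      parts <- c(parts, random_dna(sample(80:150, 1L)))
      contig_seqs[ci] <- paste(parts, collapse = "")
    }
    if (identical(strain, "BAD1")) {
      # heavily fragmented assembly: fails both contig-count and N50 rules
      whole <- paste(contig_seqs, collapse = "")
      starts <- seq(1L, nchar(whole), by = 150L)
      contig_seqs <- substring(whole, starts, pmin(starts + 149L, nchar(whole)))
      n_contigs <- length(contig_seqs)
      gff_rows <- list()
    }
    genome <- Biostrings::DNAStringSet(contig_seqs)
    names(genome) <- paste0(strain, "_ctg", seq_len(n_contigs))
    genomes[[strain]] <- genome
    gffs[[strain]] <- dplyr::bind_rows(gff_rows)
    proteins[[strain]] <- dplyr::bind_rows(prots)
  }

  proteins <- dplyr::bind_rows(proteins)
  recovery_truth <- dplyr::bind_rows(recovery_truth)

  universe <- build_world_model(
    "toy_universe",
    setdiff(names(world_reaction_defs()), "REFSPEC"),
    exchange_lower = -1000, atpm_lower = 0
  )
  universe_genes <- dplyr::bind_rows(
    tibble::tibble(gene_id = fams$universal_gene, seq = fams$base_seq),
    tibble::tibble(gene_id = decoys$universal_gene, seq = decoys$seq)
  )

  ref_fams <- c("glct", "hex", "glycA", "glycB", "resp", "aas1", "aas2",
                "trps", "nh4t", "pit", "so4t", "trpt")
  reference <- build_world_model(
    "toy_reference",
    c("GLCt", "HEX", "GLYC", "RESP", "AAS", "NUCS", "TRPS", "NH4t", "PIt",
      "SO4t", "TRPt", "O2t", "CO2t", "H2Ot", "Ht", "ATPM", "BIOMASS",
      "REFSPEC"),
    exchange_lower = -1000, atpm_lower = 8.39
  )
  # reference GPRs use reference gene ids; NUCS is the curated orphan
  ref_gene_map <- stats::setNames(as.list(paste0("R_", ref_fams)),
                                  paste0("U_", ref_fams))
  reference$reactions$gpr <- lapply(reference$reactions$gpr, gpr_substitute,
                                    mapping = ref_gene_map)
  i_nucs <- match("NUCS", reference$reactions$id)
  reference$reactions$gpr[[i_nucs]] <- gpr_empty()
  reference_proteome <- dplyr::bind_rows(
    tibble::tibble(
      gene_id = paste0("R_", ref_fams),
      seq = vapply(ref_fams, function(f) {
        mutate_protein(fams$base_seq[fams$family == f], 0.02)
      }, character(1))
    ),
    tibble::tibble(gene_id = "R_refonly", seq = random_aa(150L))
  )

  media <- list(
    minimal = medium_recipe(stats::setNames(
      rep(10, 7), paste0(c("glc__D", "nh4", "pi", "so4", "o2", "h2o", "h"), "_e")),
      name = "minimal"),
    minimal_trp = medium_recipe(stats::setNames(
      rep(10, 8), paste0(c("glc__D", "nh4", "pi", "so4", "o2", "h2o", "h",
                           "trp__L"), "_e")),
      name = "minimal_trp")
  )

  completeness <- tibble::tibble(
    strain = all_strain_rows$strain,
    pct_missing = ifelse(all_strain_rows$strain == "BAD2", 5,
                         round(stats::runif(nrow(all_strain_rows), 0, 1), 2)),
    pct_fragmented = round(stats::runif(nrow(all_strain_rows), 0, 40), 2)
  )

  structure(
    list(
      seed = seed,
      params = list(n_strains = n_strains, n_groups = n_groups,
                    mutation_rate = mutation_rate, n_qc_fail = n_qc_fail),
      qc_thresholds = qc_thresholds(min_n50 = 1000, max_contigs = 10),
      roster = roster,
      families = fams,
      proteins = proteins,
      genomes = genomes,
      gffs = gffs,
      universe = universe,
      universe_genes = universe_genes,
      reference = reference,
      reference_proteome = reference_proteome,
      media = media,
      completeness = completeness,
      recovery_truth = recovery_truth,
      rec_strains = c(i = rec_split, ii = rec_unann, iii = rec_trunc)
    ),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world> seed ", x$seed, ": ", nrow(x$roster), " strains in ",
      length(unique(x$roster$group)), " groups, ",
      nrow(x$families), " gene families\n", sep = "")
  invisible(x)
}

# reaction sets per strain implied by the planted design (explicit module
# lists, independent of the GPR machinery)
world_truth_reactions <- function(world, mode = c("hybrid", "reference_free")) {
  mode <- match.arg(mode)
  core <- c("GLCt", "HEX", "GLYC", "RESP", "AAS", "NUCS", "NH4t", "PIt",
            "SO4t", "TRPt", "O2t", "CO2t", "H2Ot", "Ht", "ATPM", "BIOMASS",
            "EX_glc__D_e", "EX_nh4_e", "EX_pi_e", "EX_so4_e", "EX_o2_e",
            "EX_co2_e", "EX_h2o_e", "EX_h_e", "EX_trp__L_e")
  if (mode == "reference_free") core <- c(core, "BADRXN")
  xyl <- c("XYLt", "XYLI", "XYLK", "EX_xyl__D_e")
  his <- c("HISDC", "HISTAt", "EX_hista_e")
  out <- lapply(seq_len(nrow(world$roster)), function(i) {
    s <- world$roster$strain[i]
    g <- world$roster$group[i]
    rxns <- core
    if (g %in% c("G1", "G2")) rxns <- c(rxns, "TRPS")
    if (g == "G1") {
      rxns <- c(rxns, xyl)
      if (!identical(s, unname(world$rec_strains["i"]))) rxns <- c(rxns, "ACC1")
      rxns <- c(rxns, "ACC2")
      if (!identical(s, unname(world$rec_strains["iii"]))) rxns <- c(rxns, "ACC3")
    }
    if (g == "G2") rxns <- c(rxns, his)
    sort(rxns)
  })
  stats::setNames(out, world$roster$strain)
}

world_truth_pam <- function(world) {
  # post-recovery gene table: intact annotated genes in their families,
  # recovered genes added, replaced genes removed
  genes <- world$proteins[world$proteins$strain %in% world$roster$strain, ]
  genes <- tibble::tibble(gene_id = genes$gene_id, strain = genes$strain,
                          cluster = genes$family, premature_stop = FALSE,
                          scenario = "none")
  for (k in seq_len(nrow(world$recovery_truth))) {
    rt <- world$recovery_truth[k, ]
    genes <- genes[!genes$gene_id %in% rt$replaces[[1L]], ]
    genes <- dplyr::bind_rows(genes, tibble::tibble(
      gene_id = paste0(rt$strain, "_rec1"), strain = rt$strain,
      cluster = rt$family, premature_stop = rt$premature_stop,
      scenario = rt$scenario
    ))
  }
  build_pam(genes, strains = world$roster$strain)
}

#' Planted ground truth of a synthetic world
#'
#' @param world A [generate_world()] object.
#' @param query One of `"clusters"` (pre-recovery gene -> family
#'   partition), `"pam"` (post-recovery PAM with flags), `"reactions"` /
#'   `"reactions_rf"` (per-strain reaction id sets under the hybrid /
#'   reference-free pan), `"substrates"`, `"auxotrophies"`,
#'   `"biosynthesis"` (phenotype BFTs), `"groups"` (strain partition), or
#'   `"recoveries"` (planted recovery cases).
#' @return The truth object in the same format the pipeline emits.
#' @export
expected_truth <- function(world, query = c("clusters", "pam", "reactions",
                                            "reactions_rf", "substrates",
                                            "auxotrophies", "biosynthesis",
                                            "groups", "recoveries")) {
  query <- match.arg(query)
  kept <- world$proteins[world$proteins$strain %in% world$roster$strain, ]
  g1 <- world$roster$strain[world$roster$group == "G1"]
  g3 <- world$roster$strain[world$roster$group == "G3"]
  bft_of <- function(feature, positive) {
    vals <- lapply(world$roster$strain, function(s) {
      as.integer(s %in% positive)
    })
    tibble::as_tibble(c(list(feature = feature),
                        stats::setNames(vals, world$roster$strain)))
  }
  switch(query,
    clusters = stats::setNames(kept$family, kept$gene_id),
    pam = world_truth_pam(world),
    reactions = world_truth_reactions(world, "hybrid"),
    reactions_rf = world_truth_reactions(world, "reference_free"),
    substrates = dplyr::bind_rows(
      bft_of("C_source:glc__D", world$roster$strain),
      bft_of("C_source:xyl__D", g1),
      bft_of("C_source:fru", character(0))
    ),
    auxotrophies = bft_of("aux:trp__L", g3),
    biosynthesis = bft_of(
      "biosynth:hista_c",
      world$roster$strain[world$roster$group == "G2"]),
    groups = world$roster,
    recoveries = world$recovery_truth
  )
}

#' Write a synthetic world to disk
#'
#' Layout: `proteomes/<strain>.faa`, `genomes/<strain>.fna`,
#' `gff/<strain>.gff3`, `universe.json` + `universe_genes.faa`,
#' `reference.xml` + `reference_proteome.faa`, `media.tsv`,
#' `completeness.tsv`, and `manifest.json` (seed and parameters).
#'
#' @param world A [generate_world()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  for (d in c("", "proteomes", "genomes", "gff")) {
    dir.create(file.path(dir, d), showWarnings = FALSE, recursive = TRUE)
  }
  for (s in names(world$genomes)) {
    Biostrings::writeXStringSet(world$genomes[[s]],
                                file.path(dir, "genomes", paste0(s, ".fna")))
    pr <- world$proteins[world$proteins$strain == s, ]
    aa <- Biostrings::AAStringSet(stats::setNames(pr$seq, pr$gene_id))
    Biostrings::writeXStringSet(aa,
                                file.path(dir, "proteomes", paste0(s, ".faa")))
    write_gff3(world$gffs[[s]], file.path(dir, "gff", paste0(s, ".gff3")))
  }
  write_model(world$universe, file.path(dir, "universe.json"))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(stats::setNames(world$universe_genes$seq,
                                            world$universe_genes$gene_id)),
    file.path(dir, "universe_genes.faa"))
  write_model(world$reference, file.path(dir, "reference.xml"))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(stats::setNames(world$reference_proteome$seq,
                                            world$reference_proteome$gene_id)),
    file.path(dir, "reference_proteome.faa"))
  write_media_tsv(world$media, file.path(dir, "media.tsv"))
  readr::write_tsv(world$completeness, file.path(dir, "completeness.tsv"))
  jsonlite::write_json(
    list(seed = world$seed, params = world$params,
         strains = world$roster$strain, groups = world$roster$group),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

write_gff3 <- function(gff, path) {
  body <- if (is.null(gff) || nrow(gff) == 0L || !"contig" %in% names(gff)) {
    character(0)
  } else {
    sprintf("%s\tpanmet\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
            gff$contig, gff$start, as.integer(gff$end), gff$strand,
            gff$gene_id)
  }
  writeLines(c("##gff-version 3", body), path)
}
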