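# Filler codons used when building synthetic coding sequences: a fixed
# cycle with no stop codons, so translation is deterministic everywhere.
FILLER_CODONS <- c("GCT", "GAA", "CTG", "AAA", "TCC", "GGA")

#' Build a synthetic spliced coding sequence
#'
#' ATG start, TAA stop, a fixed filler-codon cycle in between, with
#' specific codons overridden (e.g. to place a Tyr at codon 131).
#'
#' @param n_codons total codon count including start and stop.
#' @param constrained named character vector: codon index -> codon.
#' @return Uppercase coding sequence string of length `3 * n_codons`.
#' @export
make_coding_sequence <- function(n_codons, constrained = character(0)) {
  codons <- FILLER_CODONS[((seq_len(n_codons) - 1L) %% length(FILLER_CODONS)) + 1L]
  codons[1L] <- "ATG"
  codons[n_codons] <- "TAA"
  if (length(constrained)) {
    idx <- as.integer(names(constrained))
    stopifnot(all(idx >= 2L), all(idx <= n_codons - 1L))
    codons[idx] <- toupper(constrained)
  }
  paste(codons, collapse = "")
}

#' The packaged four-family fixture
#'
#' A fully deterministic, download-free stand-in for the study data this
#' package's funnel is designed around: four nuclear bestrophinopathy
#' pedigrees (20 members, 8 affected) genotyped at a synthetic toy
#' BEST1-like gene with two protein-coding isoforms, plus a decoy gene.
#'
#' The canonical isoform (id `ENST00000378043`, scaled down to 250
#' codons) carries the reference amino acids Arg47, Thr91, Tyr131 and
#' Arg150; the alternate isoform (`ENST00000526988`, 230 codons) has a
#' unique exon and carries Val216. Ids echo the real Ensembl accessions
#' for recognizability, but every coordinate and sequence here is
#' synthetic. Five variants are planted to reproduce the published
#' per-family genotype configurations exactly:
#'
#' * family A — c.392A>G (p.Tyr131Cys), homozygous in both affected sons,
#'   heterozygous in both parents (autosomal recessive);
#' * family B — c.449G>C (p.Arg150Pro), homozygous in the affected
#'   proband, het parents, absent in the unaffected brother;
#' * family C — c.140G>A (p.Arg47His, canonical isoform) and c.646G>A
#'   (p.Val216Ile, unique exon of the alternate isoform), compound
#'   heterozygous in all four affected siblings, each unaffected member
#'   carrying exactly one of the two;
#' * family D — c.272C>T (p.Thr91Ile), heterozygous in the affected
#'   proband, his unaffected sister and his asymptomatic father
#'   (dominant with incomplete penetrance).
#'
#' The p.Arg47His analogue is given a tiny nonzero population frequency
#' (it was previously reported); the other four are novel (absent from
#' the frequency table). Three decoy variants in a second gene exercise
#' the rarity, impact and segregation filters.
#'
#' @return List with `vcf` (a [variant_set()]), `peds`, `transcripts`,
#'   `coding_seqs`, `freqs`, `panel_genes`, `review_genes` and `truth`
#'   (tibble `family_id`, `key`, `label`, `model`).
#' @export
build_fixture <- function() {
  transcripts <- fixture_transcripts()
  coding_seqs <- fixture_coding_seqs()
  peds <- fixture_pedigrees()
  samples <- unlist(lapply(peds, `[[`, "individual_id"), use.names = FALSE)

  canon <- transcripts$ENST00000378043
  alt_t <- transcripts$ENST00000526988
  other <- transcripts$`OTHER-1`

  gpos <- function(t, cds_pos) project_cds_to_genomic(t, cds_pos)
  base_at <- function(t, cds_pos) {
    substr(fixture_coding_seqs()[[t$transcript_id]], cds_pos, cds_pos)
  }
  v <- tibble::tibble(
    chrom = "chr11",
    pos = c(gpos(canon, 140L), gpos(canon, 272L), gpos(canon, 392L),
            gpos(canon, 449L), gpos(alt_t, 646L),
            gpos(other, 299L), gpos(other, 120L), gpos(other, 452L)),
    id = c("c.140G>A", "c.272C>T", "c.392A>G", "c.449G>C", "c.646G>A",
           "decoy_common", "decoy_synonymous", "decoy_nonsegregating"),
    ref = c(base_at(canon, 140L), base_at(canon, 272L), base_at(canon, 392L),
            base_at(canon, 449L), base_at(alt_t, 646L),
            base_at(other, 299L), base_at(other, 120L), base_at(other, 452L)),
    alt = c("A", "T", "G", "C", "A",
            missense_alt(coding_seqs[["OTHER-1"]], 299L),
            synonymous_alt(coding_seqs[["OTHER-1"]], 120L),
            missense_alt(coding_seqs[["OTHER-1"]], 452L))
  )
  v$info <- replicate(nrow(v), character(0), simplify = FALSE)

  zy <- matrix("0/0", nrow = nrow(v), ncol = length(samples),
               dimnames = list(v$id, samples))
  set_gt <- function(id, gts) zy[id, names(gts)] <<- gts
  set_gt("c.392A>G", c(A_II.1 = "1/1", A_II.2 = "1/1",
                       A_I.1 = "0/1", A_I.2 = "0/1"))
  set_gt("c.449G>C", c(B_II.1 = "1/1", B_I.1 = "0/1", B_I.2 = "0/1"))
  set_gt("c.140G>A", c(C_I.1 = "0/1", C_II.1 = "0/1", C_II.2 = "0/1",
                       C_II.3 = "0/1", C_II.4 = "0/1", C_III.1 = "0/1"))
  set_gt("c.646G>A", c(C_I.2 = "0/1", C_II.1 = "0/1", C_II.2 = "0/1",
                       C_II.3 = "0/1", C_II.4 = "0/1", C_III.2 = "0/1"))
  set_gt("c.272C>T", c(D_II.1 = "0/1", D_I.1 = "0/1", D_II.2 = "0/1"))
  set_gt("decoy_common", c(A_I.1 = "0/1", B_I.2 = "0/1", C_II.1 = "0/1",
                           D_II.1 = "0/1"))
  set_gt("decoy_synonymous", c(C_I.1 = "0/1"))
  set_gt("decoy_nonsegregating", c(A_I.1 = "0/1"))

  geno_a <- matrix(as.integer(substr(zy, 1, 1)), nrow = nrow(v))
  geno_b <- matrix(as.integer(substr(zy, 3, 3)), nrow = nrow(v))
  o <- order(v$pos)
  vcf <- variant_set(v[o, ], geno_a[o, , drop = FALSE],
                     geno_b[o, , drop = FALSE], samples)

  key_of <- function(id) {
    i <- match(id, vcf$variants$id)
    variant_keys(vcf)[i]
  }
  freqs <- tibble::tibble(
    chrom = "chr11",
    pos = c(v$pos[match("c.140G>A", v$id)], v$pos[match("decoy_common", v$id)]),
    ref = c(v$ref[match("c.140G>A", v$id)], v$ref[match("decoy_common", v$id)]),
    alt = c("A", v$alt[match("decoy_common", v$id)]),
    source = c("ExAC", "KG1000"),
    af = c(1e-4, 0.05)
  )
  truth <- tibble::tibble(
    family_id = c("A", "B", "C", "C", "D"),
    key = key_of(c("c.392A>G", "c.449G>C", "c.140G>A", "c.646G>A",
                   "c.272C>T")),
    label = c("p.Tyr131Cys", "p.Arg150Pro", "p.Arg47His", "p.Val216Ile",
              "p.Thr91Ile"),
    model = c("AR_hom", "AR_hom", "comp_het", "comp_het",
              "AD_incomplete_penetrance")
  )
  list(vcf = vcf, peds = peds, transcripts = transcripts,
       coding_seqs = coding_seqs, freqs = freqs,
       panel_genes = "BEST1", review_genes = "BEST1", truth = truth)
}

# internal: the fixture's transcript models (all plus-strand, chr11)
fixture_transcripts <- function() {
  ts <- list(
    # canonical isoform: 250 codons over two coding exons + 3'UTR exon
    transcript_model("ENST00000378043", "BEST1", "chr11", "+",
                     exon_starts = c(1001L, 2001L, 5200L),
                     exon_ends = c(1600L, 2150L, 5400L),
                     cds_start = 1001L, cds_end = 2150L),
    # alternate isoform: 230 codons; middle exon (4001-4120) is unique
    # and carries codon 216; junction 4120 -> 5001 discriminates it
    transcript_model("ENST00000526988", "BEST1", "chr11", "+",
                     exon_starts = c(3001L, 4001L, 5001L),
                     exon_ends = c(3540L, 4120L, 5030L),
                     cds_start = 3001L, cds_end = 5030L),
    # decoy gene: one exon, 200 codons
    transcript_model("OTHER-1", "OTHERGENE", "chr11", "+",
                     exon_starts = 8001L, exon_ends = 8600L,
                     cds_start = 8001L, cds_end = 8600L)
  )
  stats::setNames(ts, vapply(ts, `[[`, character(1), "transcript_id"))
}

# internal: coding sequences with the five constrained codons
fixture_coding_seqs <- function() {
  c(
    ENST00000378043 = make_coding_sequence(
      250L, c("47" = "CGC",   # Arg; c.140 G>A -> CAC = His
              "91" = "ACC",   # Thr; c.272 C>T -> ATC = Ile
              "131" = "TAT",  # Tyr; c.392 A>G -> TGT = Cys
              "150" = "CGA")  # Arg; c.449 G>C -> CCA = Pro
    ),
    ENST00000526988 = make_coding_sequence(
      230L, c("216" = "GTT")  # Val; c.646 G>A -> ATT = Ile
    ),
    `OTHER-1` = make_coding_sequence(200L)
  )
}

# internal: first alternate base giving the requested effect
alt_with_effect <- function(coding_sequence, cds_pos, wanted) {
  ref <- substr(coding_sequence, cds_pos, cds_pos)
  for (b in setdiff(c("A", "C", "G", "T"), ref)) {
    if (codon_change(coding_sequence, cds_pos, ref, b)$effect == wanted) {
      return(b)
    }
  }
  NA_character_
}
missense_alt <- function(cs, p) alt_with_effect(cs, p, "missense")
synonymous_alt <- function(cs, p) alt_with_effect(cs, p, "synonymous")

# internal: the four pedigrees (Fig 5b-style labels with family prefix)
fixture_pedigrees <- function() {
  mk <- function(fam, id, fa, mo, sex, aff) {
    pedigree(fam, paste(fam, id, sep = "_"),
             ifelse(fa == "0", NA, paste(fam, fa, sep = "_")),
             ifelse(mo == "0", NA, paste(fam, mo, sep = "_")),
             sex, aff)
  }
  list(
    A = mk("A", c("I.1", "I.2", "II.1", "II.2"),
           c("0", "0", "I.1", "I.1"), c("0", "0", "I.2", "I.2"),
           c("male", "female", "male", "male"),
           c("unaffected", "unaffected", "affected", "affected")),
    B = mk("B", c("I.1", "I.2", "II.1", "II.2"),
           c("0", "0", "I.1", "I.1"), c("0", "0", "I.2", "I.2"),
           c("male", "female", "male", "male"),
           c("unaffected", "unaffected", "affected", "unaffected")),
    # proband II.3; her two children (spouse unsequenced, parent link
    # missing) are the unaffected single-variant carriers
    C = mk("C", c("I.1", "I.2", "II.1", "II.2", "II.3", "II.4",
                  "III.1", "III.2"),
           c("0", "0", "I.1", "I.1", "I.1", "I.1", "0", "0"),
           c("0", "0", "I.2", "I.2", "I.2", "I.2", "II.3", "II.3"),
           c("male", "female", "male", "female", "female", "male",
             "male", "female"),
           c("unaffected", "unaffected", "affected", "affected",
             "affected", "affected", "unaffected", "unaffected")),
    D = mk("D", c("I.1", "I.2", "II.1", "II.2"),
           c("0", "0", "I.1", "I.1"), c("0", "0", "I.2", "I.2"),
           c("male", "female", "male", "female"),
           c("unaffected", "unaffected", "affected", "unaffected"))
  )
}

#' Simulation configuration
#'
#' Parameters of the gene-drop cohort simulator. Defaults describe the
#' benchmarking condition used throughout this package: nuclear quartets,
#' fully penetrant causal genotypes, error-free calls, and common
#' background variation (every background frequency at least 1%, so the
#' 0.2% rarity filter separates background from causal cleanly).
#'
#' @param seed RNG seed (integer).
#' @param n_families number of families.
#' @param pedigree_shape `"trio"`, `"quartet"`, `"sextet"`, or an
#'   explicit [pedigree()] used as template for every family.
#' @param causal_model `"AR_hom"`, `"comp_het"` or `"AD"`.
#' @param causal_allele_freq population frequency recorded for the
#'   causal variants (0 = novel, absent from the frequency table).
#' @param background_variant_count cohort-level background variants,
#'   each genotyped in every family.
#' @param background_af_distribution list with `points` (point-mass
#'   frequencies), `point_weight`, and `min`/`max` of a uniform range.
#' @param genotyping_error_rate per-call probability of replacing a
#'   genotype with a random one (including missing).
#' @param penetrance probability that a carrier of the causal
#'   configuration is affected.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_families = 50L,
                              pedigree_shape = "quartet",
                              causal_model = "AR_hom",
                              causal_allele_freq = 0,
                              background_variant_count = 200L,
                              background_af_distribution =
                                list(points = c(0.01, 0.05, 0.1, 0.25),
                                     point_weight = 0.5,
                                     min = 0.01, max = 0.5),
                              genotyping_error_rate = 0,
                              penetrance = 1) {
  stopifnot(n_families >= 1L,
            causal_model %in% c("AR_hom", "comp_het", "AD"),
            causal_allele_freq >= 0, causal_allele_freq <= 1,
            genotyping_error_rate >= 0, genotyping_error_rate <= 1,
            penetrance > 0, penetrance <= 1)
  structure(
    list(seed = as.integer(seed), n_families = as.integer(n_families),
         pedigree_shape = pedigree_shape, causal_model = causal_model,
         causal_allele_freq = causal_allele_freq,
         background_variant_count = as.integer(background_variant_count),
         background_af_distribution = background_af_distribution,
         genotyping_error_rate = genotyping_error_rate,
         penetrance = penetrance),
    class = "simulation_config"
  )
}

#' Build a nuclear pedigree of a standard shape
#'
#' @param shape `"trio"` (one child), `"quartet"` (two), `"sextet"` (four).
#' @param family_id family identifier; member ids are
#'   `<family_id>_1 ... <family_id>_n` with 1 = father, 2 = mother.
#' @return A [pedigree()] with all affection statuses `unknown`.
#' @export
make_pedigree <- function(shape = c("trio", "quartet", "sextet"),
                          family_id = "F1") {
  shape <- match.arg(shape)
  n_children <- c(trio = 1L, quartet = 2L, sextet = 4L)[[shape]]
  n <- 2L + n_children
  id <- paste(family_id, seq_len(n), sep = "_")
  pedigree(
    family_id, id,
    father_id = c(NA, NA, rep(id[1], n_children)),
    mother_id = c(NA, NA, rep(id[2], n_children)),
    sex = c("male", "female",
            rep(c("male", "female"), length.out = n_children)),
    affected = rep("unknown", n)
  )
}

#' Gene-drop genotype simulation through a pedigree
#'
#' Founder alleles are drawn from Hardy-Weinberg equilibrium at the given
#' allele frequency; every non-founder receives one allele from each
#' parent, chosen uniformly. A parent absent from the pedigree
#' contributes a population-drawn allele.
#'
#' @param ped a [pedigree()].
#' @param af alternate-allele frequency in `[0, 1]`.
#' @param seed optional RNG seed.
#' @return Tibble `individual_id`, `a`, `b` (0/1 allele integers).
#' @export
gene_drop <- function(ped, af, seed = NULL) {
  stopifnot(af >= 0, af <= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- gene_drop_multi(ped, af)
  tibble::tibble(individual_id = colnames(g$a),
                 a = as.integer(g$a[1, ]), b = as.integer(g$b[1, ]))
}

# internal: vectorized gene drop, one row per variant frequency
gene_drop_multi <- function(ped, afs) {
  n_var <- length(afs)
  ids <- ped$individual_id
  a <- b <- matrix(NA_integer_, n_var, length(ids),
                   dimnames = list(NULL, ids))
  fa <- stats::setNames(ped$father_id, ids)
  mo <- stats::setNames(ped$mother_id, ids)
  pop_draw <- function() stats::rbinom(n_var, 1L, afs)
  transmit <- function(parent) {
    if (is.na(parent)) return(pop_draw())
    pick <- stats::rbinom(n_var, 1L, 0.5)
    ifelse(pick == 1L, a[, parent], b[, parent])
  }
  for (id in topological_order(ped)) {
    if (is.na(fa[id]) && is.na(mo[id])) {
      a[, id] <- pop_draw()
      b[, id] <- pop_draw()
    } else {
      a[, id] <- transmit(fa[id])
      b[, id] <- transmit(mo[id])
    }
  }
  list(a = a, b = b)
}

#' Plant a model-consistent causal genotype configuration
#'
#' Produces genotypes that are Mendelian-consistent and fit the requested
#' inheritance model, then assigns affection statuses from genotype:
#' carriers of the causal configuration are affected with probability
#' `penetrance`, everyone else is unaffected. The proband (first
#' eligible non-founder, or the carrier founder for dominant planting on
#' a childless pedigree) is always affected — families are ascertained
#' through an affected proband.
#'
#' * `AR_hom`: the proband's parents are made heterozygous, transmission
#'   is simulated, and the proband forced homozygous-alternate.
#' * `comp_het`: the father carries variant 1, the mother variant 2
#'   (each heterozygous, so the pair is in trans by construction); the
#'   proband is forced to inherit both.
#' * `AD`: the proband's father is a heterozygous carrier and the
#'   proband is forced to inherit the allele.
#'
#' @param ped a [pedigree()]; existing affection statuses are replaced.
#' @param model `"AR_hom"`, `"comp_het"` or `"AD"`.
#' @param penetrance probability a carrier is affected.
#' @param seed optional RNG seed.
#' @return List: `geno_a`/`geno_b` (variant x member allele matrices, one
#'   row for `AR_hom`/`AD`, two for `comp_het`) and `ped` (pedigree with
#'   assigned affection statuses).
#' @export
plant_causal <- function(ped, model = c("AR_hom", "comp_het", "AD"),
                         penetrance = 1, seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  ids <- ped$individual_id
  has_both <- !is.na(ped$father_id) & !is.na(ped$mother_id)
  proband <- ids[has_both][1]
  if (model %in% c("AR_hom", "comp_het") && is.na(proband)) {
    stop("model ", model, " infeasible on pedigree ", ped$family_id[1],
         ": no member with both parents present")
  }
  n_var <- if (model == "comp_het") 2L else 1L
  a <- b <- matrix(0L, n_var, length(ids), dimnames = list(NULL, ids))
  fa <- stats::setNames(ped$father_id, ids)
  mo <- stats::setNames(ped$mother_id, ids)
  transmit_row <- function(v, parent) {
    if (is.na(parent)) return(0L)
    if (stats::rbinom(1L, 1L, 0.5) == 1L) a[v, parent] else b[v, parent]
  }
  seed_founders <- function() {
    if (model == "AR_hom") {
      b[1L, c(fa[proband], mo[proband])] <<- 1L
    } else if (model == "comp_het") {
      b[1L, fa[proband]] <<- 1L
      b[2L, mo[proband]] <<- 1L
    } else {
      carrier <- if (!is.na(proband)) fa[proband] else ids[1]
      b[1L, carrier] <<- 1L
    }
  }
  seed_founders()
  founder_set <- ids[is.na(fa) & is.na(mo)]
  for (id in setdiff(topological_order(ped), founder_set)) {
    for (v in seq_len(n_var)) {
      a[v, id] <- transmit_row(v, fa[id])
      b[v, id] <- transmit_row(v, mo[id])
    }
  }
  # force the proband into the causal configuration (always possible
  # given the founder seeding above)
  if (model == "AR_hom") {
    a[1L, proband] <- 1L
    b[1L, proband] <- 1L
  } else if (model == "comp_het") {
    a[1L, proband] <- 1L
    b[1L, proband] <- 0L
    a[2L, proband] <- 0L
    b[2L, proband] <- 1L
  } else {
    if (!is.na(proband)) {
      a[1L, proband] <- 1L
      b[1L, proband] <- 0L
    }
  }
  causal <- switch(model,
    AR_hom = a[1L, ] == 1L & b[1L, ] == 1L,
    comp_het = (a[1L, ] + b[1L, ] == 1L) & (a[2L, ] + b[2L, ] == 1L),
    AD = a[1L, ] + b[1L, ] >= 1L
  )
  affected <- ifelse(causal & stats::runif(length(ids)) <= penetrance,
                     "affected", "unaffected")
  names(affected) <- ids
  if (model != "AD" || !is.na(proband)) affected[proband] <- "affected"
  else affected[ids[1]] <- "affected"
  ped2 <- ped
  ped2$affected <- unname(affected[ids])
  list(geno_a = a, geno_b = b, ped = ped2)
}

# internal: draw background allele frequencies from the mixture spec
draw_background_afs <- function(n, dist) {
  use_point <- stats::runif(n) < dist$point_weight
  out <- stats::runif(n, dist$min, dist$max)
  if (any(use_point)) {
    out[use_point] <- sample(dist$points, sum(use_point), replace = TRUE)
  }
  out
}

#' Simulate a multi-family cohort with planted causal variants
#'
#' Per family: causal variant(s) planted by [plant_causal()] under the
#' configured model at family-specific coding positions of the fixture's
#' toy genes, plus cohort-level background variants (shared across
#' families, like real population variation in a joint-called VCF) with
#' frequencies drawn from the configured distribution and genotypes from
#' [gene_drop()]. Causal positions are chosen so the variant is missense
#' on some isoform; background variants land anywhere else in the coding
#' regions. Fully reproducible under `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return List: `vcf` (a [variant_set()]), `peds`, `freqs`,
#'   `transcripts`, `coding_seqs`, and `truth` (tibble `family_id`,
#'   `key`, `model`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  transcripts <- fixture_transcripts()
  coding_seqs <- fixture_coding_seqs()
  coding_ts <- transcripts[c("ENST00000378043", "OTHER-1")]

  # candidate coding positions (genomic) per host transcript
  pool <- dplyr::bind_rows(lapply(coding_ts, function(t) {
    ivs <- cds_intervals(t)
    tibble::tibble(
      transcript_id = t$transcript_id,
      pos = unlist(mapply(seq, ivs$start, ivs$end, SIMPLIFY = FALSE))
    )
  }))
  pool <- pool[sample.int(nrow(pool)), ]

  n_causal_per_fam <- if (cfg$causal_model == "comp_het") 2L else 1L
  n_causal <- cfg$n_families * n_causal_per_fam

  take_causal <- function(n, transcript_id) {
    # missense-capable positions on one transcript (comp-het pairs must
    # share a gene, and gene-drop backgrounds must not collide)
    picked <- tibble::tibble(pos = integer(0), ref = character(0),
                             alt = character(0))
    t <- transcripts[[transcript_id]]
    cs <- coding_seqs[[transcript_id]]
    i <- 1L
    while (nrow(picked) < n && i <= nrow(pool)) {
      if (pool$transcript_id[i] == transcript_id) {
        cp <- project_genomic_to_cds(t, pool$pos[i])
        ref <- substr(cs, cp, cp)
        alt <- missense_alt(cs, cp)
        if (!is.na(alt)) {
          picked <- dplyr::bind_rows(
            picked, tibble::tibble(pos = pool$pos[i], ref = ref, alt = alt))
          pool <- pool[-i, ]
          i <- i - 1L
        }
      }
      i <- i + 1L
    }
    pool <<- pool[!pool$pos %in% picked$pos, ]
    if (nrow(picked) < n) stop("not enough coding positions for causals")
    picked
  }
  causal_tab <- take_causal(n_causal, "ENST00000378043")

  n_bg <- cfg$background_variant_count
  if (nrow(pool) < n_bg) stop("not enough coding positions for backgrounds")
  bg_rows <- pool[seq_len(n_bg), ]
  bg <- tibble::tibble(
    pos = bg_rows$pos,
    ref = vapply(seq_len(n_bg), function(i) {
      t <- transcripts[[bg_rows$transcript_id[i]]]
      cp <- project_genomic_to_cds(t, bg_rows$pos[i])
      substr(coding_seqs[[t$transcript_id]], cp, cp)
    }, character(1)),
    af = draw_background_afs(n_bg, cfg$background_af_distribution)
  )
  bg$alt <- vapply(bg$ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1L)
  }, character(1))

  # assemble per-family pedigrees and genotypes
  fam_ids <- sprintf("F%03d", seq_len(cfg$n_families))
  peds <- list()
  geno_a_cols <- list()
  geno_b_cols <- list()
  truth_rows <- list()
  for (f in seq_len(cfg$n_families)) {
    ped <- if (inherits(cfg$pedigree_shape, "pedigree")) {
      template_pedigree(cfg$pedigree_shape, fam_ids[f])
    } else {
      make_pedigree(cfg$pedigree_shape, fam_ids[f])
    }
    planted <- plant_causal(ped, cfg$causal_model,
                            penetrance = cfg$penetrance)
    peds[[fam_ids[f]]] <- planted$ped
    bg_geno <- gene_drop_multi(planted$ped, bg$af)
    c_idx <- ((f - 1L) * n_causal_per_fam + 1L):(f * n_causal_per_fam)
    # causal rows for *other* families are hom-ref here
    ca <- matrix(0L, n_causal, nrow(ped),
                 dimnames = list(NULL, ped$individual_id))
    cb <- ca
    ca[c_idx, ] <- planted$geno_a
    cb[c_idx, ] <- planted$geno_b
    geno_a_cols[[f]] <- rbind(ca, bg_geno$a)
    geno_b_cols[[f]] <- rbind(cb, bg_geno$b)
    truth_rows[[f]] <- tibble::tibble(
      family_id = fam_ids[f],
      pos = causal_tab$pos[c_idx],
      model = cfg$causal_model
    )
  }
  geno_a <- do.call(cbind, geno_a_cols)
  geno_b <- do.call(cbind, geno_b_cols)

  variants <- tibble::tibble(
    chrom = "chr11",
    pos = c(causal_tab$pos, bg$pos),
    id = c(sprintf("causal_%03d", seq_len(n_causal)),
           sprintf("bg_%03d", seq_len(n_bg))),
    ref = c(causal_tab$ref, bg$ref),
    alt = c(causal_tab$alt, bg$alt)
  )
  variants$info <- replicate(nrow(variants), character(0), simplify = FALSE)

  if (cfg$genotyping_error_rate > 0) {
    n_calls <- length(geno_a)
    hit <- stats::runif(n_calls) < cfg$genotyping_error_rate
    if (any(hit)) {
      draw <- sample(4L, sum(hit), replace = TRUE)
      new_a <- c(0L, 0L, 1L, NA_integer_)[draw]
      new_b <- c(0L, 1L, 1L, NA_integer_)[draw]
      geno_a[hit] <- new_a
      geno_b[hit] <- new_b
    }
  }

  o <- order(variants$pos)
  vcf <- variant_set(variants[o, ], geno_a[o, , drop = FALSE],
                     geno_b[o, , drop = FALSE], colnames(geno_a))
  sources <- sample(c("KG1000", "EVS", "ExAC"), n_bg, replace = TRUE)
  freqs <- tibble::tibble(chrom = "chr11", pos = bg$pos, ref = bg$ref,
                          alt = bg$alt, source = sources, af = bg$af)
  if (cfg$causal_allele_freq > 0) {
    freqs <- dplyr::bind_rows(freqs, tibble::tibble(
      chrom = "chr11", pos = causal_tab$pos, ref = causal_tab$ref,
      alt = causal_tab$alt, source = "ExAC", af = cfg$causal_allele_freq))
  }
  truth <- dplyr::bind_rows(truth_rows)
  vk <- variant_keys(vcf)
  truth$key <- vk[match(truth$pos, vcf$variants$pos)]
  list(vcf = vcf, peds = peds, freqs = freqs, transcripts = transcripts,
       coding_seqs = coding_seqs,
       truth = truth[, c("family_id", "key", "model")])
}

# internal: re-id a template pedigree for family `fam`
template_pedigree <- function(template, fam) {
  relabel <- function(x) {
    ifelse(is.na(x), NA, paste(fam, x, sep = "_"))
  }
  pedigree(fam, relabel(template$individual_id),
           relabel(template$father_id), relabel(template$mother_id),
           template$sex, template$affected)
}

#' Simulate spliced reads over a transcript's junctions
#'
#' Plants exactly `n_spanning_per_junction` junction-spanning reads at
#' every junction of the transcript (split position drawn uniformly
#' among those leaving at least `min_overhang` aligned bases on each
#' side and fitting within the flanking exons), plus `n_nonspanning`
#' exon-contained reads.
#'
#' @param t a [transcript_model()] with at least 2 exons.
#' @param n_spanning_per_junction spanning reads per junction.
#' @param n_nonspanning contained (non-split) reads.
#' @param read_len read length; must be at least `2 * min_overhang`.
#' @param min_overhang minimum aligned bases flanking a junction.
#' @param seed optional RNG seed.
#' @return Alignment tibble (`read_id`, `chrom`, `pos`, `cigar`)
#'   compatible with [count_junction_reads()] and [write_sam()].
#' @export
simulate_spliced_reads <- function(t, n_spanning_per_junction = 11L,
                                   n_nonspanning = 5L, read_len = 75L,
                                   min_overhang = 3L, seed = NULL) {
  stopifnot(read_len >= 2L * min_overhang)
  if (!is.null(seed)) set.seed(seed)
  jn <- junctions_of(t)
  widths <- t$exons$end - t$exons$start + 1L
  rows <- list()
  for (j in seq_len(nrow(jn))) {
    up <- widths[j]
    down <- widths[j + 1L]
    lo <- max(min_overhang, read_len - down)
    hi <- min(read_len - min_overhang, up)
    if (lo > hi) {
      # flanking exons too short for a full-length read: shrink it
      l1 <- min(up, max(min_overhang, read_len %/% 2L))
      l2 <- min(down, read_len - l1)
      if (l1 < min_overhang || l2 < min_overhang) {
        stop("exons flanking junction ", j, " shorter than min_overhang")
      }
      l1s <- rep(l1, n_spanning_per_junction)
      l2s <- rep(l2, n_spanning_per_junction)
    } else {
      l1s <- sample(seq(lo, hi), n_spanning_per_junction, replace = TRUE)
      l2s <- read_len - l1s
    }
    intron <- jn$acceptor_start[j] - jn$donor_end[j] - 1L
    if (n_spanning_per_junction > 0L) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        read_id = sprintf("%s_j%d_sp%03d", t$transcript_id, j,
                          seq_len(n_spanning_per_junction)),
        chrom = t$chrom,
        pos = jn$donor_end[j] - l1s + 1L,
        cigar = sprintf("%dM%dN%dM", l1s, intron, l2s)
      )
    }
  }
  if (n_nonspanning > 0L) {
    host <- sample(seq_len(nrow(t$exons)), n_nonspanning, replace = TRUE)
    len <- pmin(read_len, widths[host])
    start <- t$exons$start[host] +
      vapply(pmax(widths[host] - len, 0L), function(m) {
        sample.int(m + 1L, 1L) - 1L
      }, integer(1))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      read_id = sprintf("%s_bg%03d", t$transcript_id,
                        seq_len(n_nonspanning)),
      chrom = t$chrom, pos = start, cigar = sprintf("%dM", len)
    )
  }
  if (!length(rows)) {
    return(tibble::tibble(read_id = character(0), chrom = character(0),
                          pos = integer(0), cigar = character(0)))
  }
  dplyr::bind_rows(rows)
}

#' Write fixture or simulation outputs as plain-text files
#'
#' Emits whichever components are present in `x`: `fixture.vcf`,
#' `fixture.ped`, `transcripts.tsv`, `coding.fa`, `freqs.tsv`,
#' `panel.tsv` and `truth.tsv`.
#'
#' @param x a list as returned by [build_fixture()] or
#'   [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(x$vcf)) write_vcf(x$vcf, file.path(dir, "fixture.vcf"))
  if (!is.null(x$peds)) write_ped(x$peds, file.path(dir, "fixture.ped"))
  if (!is.null(x$transcripts)) {
    write_transcripts(x$transcripts, file.path(dir, "transcripts.tsv"))
  }
  if (!is.null(x$coding_seqs)) {
    writeLines(paste0(">", names(x$coding_seqs), "\n", x$coding_seqs),
               file.path(dir, "coding.fa"))
  }
  if (!is.null(x$freqs)) {
    write_frequency_table(x$freqs, file.path(dir, "freqs.tsv"))
  }
  if (!is.null(x$panel_genes)) {
    writeLines(c("gene_id", x$panel_genes), file.path(dir, "panel.tsv"))
  }
  if (!is.null(x$truth)) {
    utils::write.table(x$truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
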