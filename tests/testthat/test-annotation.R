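test_that("codon arithmetic follows ceiling(c/3)", {
  expect_equal(cds_position_to_codon(1), 1L)
  expect_equal(cds_position_to_codon(3), 1L)
  expect_equal(cds_position_to_codon(4), 2L)
  expect_equal(cds_position_to_codon(c(392, 449, 140, 646)),
               c(131L, 150L, 47L, 216L))
  expect_error(cds_position_to_codon(0), ">= 1")
  # agrees with brute-force triplet partitioning over a whole CDS
  L <- cds_length(FX$transcripts$ENST00000378043)
  brute <- rep(seq_len(L / 3), each = 3)
  expect_equal(cds_position_to_codon(seq_len(L)), brute)
})

test_that("genomic-to-CDS projection handles strand and introns", {
  plus2 <- transcript_model("p2", "G", "chr1", "+",
                            exon_starts = c(101, 301),
                            exon_ends = c(200, 380),
                            cds_start = 101, cds_end = 380)
  expect_equal(project_genomic_to_cds(plus2, 301), 101L)
  expect_equal(project_genomic_to_cds(plus2, 250), NA_integer_)
  minus1 <- transcript_model("m1", "G", "chr1", "-",
                             exon_starts = 101, exon_ends = 160,
                             cds_start = 101, cds_end = 160)
  expect_equal(project_genomic_to_cds(minus1, 160), 1L)
  expect_equal(project_genomic_to_cds(minus1, 101), 60L)
})

test_that("CDS projection is a strand-monotone bijection with inverse", {
  minus2 <- transcript_model("m2", "G", "chr1", "-",
                             exon_starts = c(101, 301),
                             exon_ends = c(190, 400),
                             cds_start = 131, cds_end = 372)
  for (t in c(FX$transcripts, list(minus2))) {
    ivs <- cds_intervals(t)
    gpos <- unlist(mapply(seq, ivs$start, ivs$end, SIMPLIFY = FALSE))
    cds <- project_genomic_to_cds(t, gpos)
    expect_setequal(cds, seq_len(cds_length(t)))
    d <- diff(cds[order(gpos)])
    if (t$strand == "+") expect_true(all(d > 0)) else expect_true(all(d < 0))
    expect_equal(project_cds_to_genomic(t, cds), gpos)
  }
})

test_that("codon_change translates substitutions with the genetic code", {
  cs <- FX$coding_seqs[["ENST00000378043"]]
  cc <- codon_change(cs, 392, "A", "G")
  expect_equal(cc[c("aa_ref", "aa_alt", "effect")],
               list(aa_ref = "Y", aa_alt = "C", effect = "missense"))
  expect_equal(cc$codon_index, 131L)
  # wobble position of GCG is synonymous
  syn <- codon_change("ATGGCGTAA", 6, "G", "A")
  expect_equal(syn$effect, "synonymous")
  expect_equal(syn$aa_ref, "A")
  # CGA -> TGA gains a stop
  stp <- codon_change("ATGCGATAA", 4, "C", "T")
  expect_equal(stp[c("aa_ref", "aa_alt", "effect")],
               list(aa_ref = "R", aa_alt = "*", effect = "stop_gained"))
  lost <- codon_change("ATGCGATAA", 7, "T", "C")
  expect_equal(lost$effect, "stop_lost")
  expect_error(codon_change(cs, 392, "C", "G"), "reference mismatch")
})

test_that("the five fixture variants yield the published protein changes", {
  expected <- tibble::tibble(
    label = c("p.Arg47His", "p.Thr91Ile", "p.Tyr131Cys", "p.Arg150Pro",
              "p.Val216Ile"),
    tid = c(rep("ENST00000378043", 4), "ENST00000526988"),
    cds = c(140L, 272L, 392L, 449L, 646L),
    aa_ref = c("R", "T", "Y", "R", "V"),
    aa_alt = c("H", "I", "C", "P", "I"),
    codon = c(47L, 91L, 131L, 150L, 216L)
  )
  cons <- annotate_variants(FX$vcf, FX$transcripts, FX$coding_seqs)
  for (i in seq_len(nrow(expected))) {
    key <- fx_key(expected$label[i])
    row <- cons[cons$key == key & cons$transcript_id == expected$tid[i], ]
    expect_equal(nrow(row), 1L)
    expect_equal(row$effect, "missense")
    expect_equal(row$cds_pos, expected$cds[i])
    expect_equal(row$codon_index, expected$codon[i])
    expect_equal(row$aa_ref, expected$aa_ref[i])
    expect_equal(row$aa_alt, expected$aa_alt[i])
  }
})

test_that("isoform-aware annotation keeps per-transcript consequences", {
  # the alternate-isoform variant is missense there, noncoding on the
  # canonical isoform whose span contains it
  cons <- annotate_variants(FX$vcf, FX$transcripts, FX$coding_seqs)
  v216 <- cons[cons$key == fx_key("p.Val216Ile"), ]
  expect_setequal(v216$transcript_id,
                  c("ENST00000378043", "ENST00000526988"))
  expect_equal(v216$effect[v216$transcript_id == "ENST00000526988"],
               "missense")
  expect_equal(v216$effect[v216$transcript_id == "ENST00000378043"],
               "noncoding_for_this_transcript")
  # exactly one protein-altering consequence per family-C variant, on
  # different transcripts of the same gene
  pa <- cons[is_protein_altering(cons$effect) &
               cons$key %in% fx_key(c("p.Arg47His", "p.Val216Ile")), ]
  expect_equal(nrow(pa), 2L)
  expect_equal(length(unique(pa$transcript_id)), 2L)
  expect_equal(unique(pa$gene_id), "BEST1")
  # a variant outside every transcript is intergenic
  far <- annotate_variant("chr11", 999999L, "A", "C", FX$transcripts,
                          FX$coding_seqs)
  expect_equal(far$effect, "intergenic")
})

test_that("variants in a shared constitutive exon hit both isoforms alike", {
  shared <- list(
    a = transcript_model("shA", "G2", "chr2", "+", c(101, 301),
                         c(220, 360), 101, 360),
    b = transcript_model("shB", "G2", "chr2", "+", c(101, 401),
                         c(220, 520), 101, 520)
  )
  seqs <- c(shA = make_coding_sequence(60), shB = make_coding_sequence(80))
  ref <- substr(seqs[["shA"]], 50, 50)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  cons <- annotate_variant("chr2", 150L, ref, alt, shared, seqs)
  expect_equal(nrow(cons), 2L)
  expect_equal(cons$cds_pos, c(50L, 50L))
  expect_equal(length(unique(cons$codon_index)), 1L)
})

test_that("splice-site and splice-region classification by distance", {
  canon <- FX$transcripts$ENST00000378043
  # intron after exon 1 (ends 1600): +2 is splice_site, +5 splice_region
  site <- annotate_variant("chr11", 1602L, "A", "C",
                           FX$transcripts["ENST00000378043"], FX$coding_seqs)
  expect_equal(site$effect, "splice_site")
  region <- annotate_variant("chr11", 1605L, "A", "C",
                             FX$transcripts["ENST00000378043"],
                             FX$coding_seqs)
  expect_equal(region$effect, "splice_region")
  deep <- annotate_variant("chr11", 1700L, "A", "C",
                           FX$transcripts["ENST00000378043"], FX$coding_seqs)
  expect_equal(deep$effect, "noncoding_for_this_transcript")
  expect_true(is_protein_altering("splice_site"))
  expect_false(is_protein_altering("splice_region"))
  expect_true(is_protein_altering("splice_region",
                                  include_potentially_altering = TRUE))
  expect_false(is_protein_altering("synonymous"))
  expect_true(is_protein_altering("missense"))
})

test_that("severity ranking is fixed and complete", {
  expect_true(consequence_severity("stop_gained") >
                consequence_severity("missense"))
  expect_true(consequence_severity("missense") >
                consequence_severity("synonymous"))
  expect_error(consequence_severity("nonsense_mediated_decay"), "unknown")
})

test_that("max_population_af pools sources and defaults to zero", {
  vs <- subset_variants(FX$vcf, seq_len(n_variants(FX$vcf)))
  afs <- max_population_af(vs, FX$freqs)
  keys <- variant_keys(vs)
  expect_equal(afs[keys == fx_key("p.Arg47His")], 1e-4)
  expect_equal(afs[keys == fx_key("p.Arg150Pro")], 0)
  multi <- tibble::tibble(
    chrom = "chr1", pos = 5L, ref = "A", alt = "T",
    source = c("KG1000", "ExAC", "EVS"), af = c(0.001, 0.004, 0.3)
  )
  toy <- variant_set(tibble::tibble(chrom = "chr1", pos = 5L, id = NA,
                                    ref = "A", alt = "T"),
                     matrix(0L, 1, 1), matrix(0L, 1, 1), "s1")
  expect_equal(max_population_af(toy, multi), 0.3)
  expect_equal(max_population_af(toy, multi[2, ]), 0.004)
})
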