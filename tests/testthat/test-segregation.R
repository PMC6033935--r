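test_that("recessive homozygous model matches the published families", {
  zA <- fx_zygosity(fx_key("p.Tyr131Cys"), FX$peds$A)
  resA <- fits_recessive_hom(zA, FX$peds$A)
  expect_true(resA$fits)
  expect_equal(nrow(resA$exceptions), 0L)
  # family B: absent in the unaffected brother, het obligate parents
  zB <- fx_zygosity(fx_key("p.Arg150Pro"), FX$peds$B)
  expect_true(fits_recessive_hom(zB, FX$peds$B)$fits)
  # an unaffected hom-alt member vetoes the fit
  zA_bad <- zA
  zA_bad["A_I.1"] <- "hom_alt"
  expect_false(fits_recessive_hom(zA_bad, FX$peds$A)$fits)
  # a het affected member vetoes too
  zA_het <- zA
  zA_het["A_II.2"] <- "het"
  expect_false(fits_recessive_hom(zA_het, FX$peds$A)$fits)
})

test_that("dominant model separates strict from incomplete penetrance", {
  zD <- fx_zygosity(fx_key("p.Thr91Ile"), FX$peds$D)
  strict <- fits_dominant(zD, FX$peds$D, mode = "strict")
  expect_false(strict$fits)
  ip <- fits_dominant(zD, FX$peds$D, mode = "incomplete_penetrance")
  expect_true(ip$fits)
  expect_equal(sort(ip$exceptions$individual_id[
    ip$exceptions$kind == "unaffected_carrier"]), c("D_I.1", "D_II.2"))
  # a non-carrier affected member fails both modes
  zD_bad <- zD
  zD_bad["D_II.1"] <- "hom_ref"
  expect_false(fits_dominant(zD_bad, FX$peds$D, mode = "strict")$fits)
  expect_false(
    fits_dominant(zD_bad, FX$peds$D, mode = "incomplete_penetrance")$fits)
  # de-novo het in the only affected child fits the strict model
  tp <- trio_ped()
  z <- zyg("1" = "hom_ref", "2" = "hom_ref", "3" = "het")
  expect_true(fits_dominant(z, tp, mode = "strict")$fits)
})

test_that("family C carries a single fitting trans compound-het pair", {
  pedC <- FX$peds$C
  best1 <- which(FX$vcf$variants$pos < 8000)  # BEST1-like gene sites
  res <- find_compound_het(subset_variants(FX$vcf, best1), pedC)
  expect_length(res, 1L)
  expect_setequal(res[[1]]$variants,
                  fx_key(c("p.Arg47His", "p.Val216Ile")))
  cr <- res[[1]]$carriers
  both <- table(cr$individual_id[cr$zygosity == "het"])
  expect_equal(sort(names(both[both == 2L])),
               c("C_II.1", "C_II.2", "C_II.3", "C_II.4"))
  unaff <- unaffected_members(pedC)$individual_id
  expect_true(all(both[unaff] == 1L))
})

test_that("compound-het rejects cis pairs and respects phase flags", {
  qp <- quartet_ped()
  # father homozygous for both variants, mother reference: the affected
  # child's two alternate alleles are forced onto one paternal
  # haplotype, so cis is certain and no flag can rescue the pair
  g1 <- zyg("1" = "hom_alt", "2" = "hom_ref", "3" = "het", "4" = "hom_ref")
  g2 <- g1
  cis <- comp_het_pair(g1, g2, qp)
  expect_false(cis$fits)
  expect_false(comp_het_pair(g1, g2, qp, allow_phase_unknown = TRUE)$fits)
  # genuinely ambiguous donor: variant B could come from the father
  # (cis with A) or the mother (trans) -> phase unknown, flag-dependent
  gA <- zyg("1" = "hom_alt", "2" = "hom_ref", "3" = "het", "4" = "hom_ref")
  gB <- zyg("1" = "het", "2" = "het", "3" = "het", "4" = "hom_ref")
  amb <- comp_het_pair(gA, gB, qp)
  expect_false(amb$fits)
  expect_true("phase_unknown" %in% amb$exceptions$kind)
  expect_true(comp_het_pair(gA, gB, qp, allow_phase_unknown = TRUE)$fits)
  # forced transmission can also *resolve* phase: a parent homozygous
  # for one variant and carrying none of the other is a certain donor
  gC <- zyg("1" = "hom_alt", "2" = "hom_ref", "3" = "het", "4" = "hom_ref")
  gD <- zyg("1" = "hom_ref", "2" = "het", "3" = "het", "4" = "hom_ref")
  expect_true(comp_het_pair(gC, gD, qp)$fits)
  # verdict symmetric in pair order
  expect_equal(comp_het_pair(gA, gB, qp)$fits,
               comp_het_pair(gB, gA, qp)$fits)
  # fewer than two variants: nothing to pair
  expect_length(find_compound_het(subset_variants(FX$vcf, 1L), qp), 0L)
})

test_that("missing genotypes fail strictly and pass leniently", {
  qp <- quartet_ped()
  z <- zyg("1" = "het", "2" = "het", "3" = "hom_alt", "4" = "missing")
  strict <- fits_recessive_hom(z, qp)
  expect_false(strict$fits)
  expect_equal(strict$exceptions$kind, "missing_genotype")
  expect_true(fits_recessive_hom(z, qp, strict = FALSE)$fits)
})

test_that("models never fit a family without affected members", {
  unk <- make_pedigree("trio", "U")  # all statuses unknown
  z <- zyg(stats::setNames(c("het", "het", "hom_alt"),
                           unk$individual_id))
  expect_false(fits_recessive_hom(z, unk)$fits)
  expect_false(fits_dominant(z, unk, mode = "strict")$fits)
})

test_that("adding an unaffected non-carrier never rescues a model", {
  qp <- quartet_ped()
  ext <- pedigree("Q", c("1", "2", "3", "4", "5"),
                  father_id = c(NA, NA, "1", "1", "1"),
                  mother_id = c(NA, NA, "2", "2", "2"),
                  sex = c("male", "female", "male", "female", "male"),
                  affected = c("unaffected", "unaffected", "affected",
                               "unaffected", "unaffected"))
  set.seed(21)
  lv <- c("hom_ref", "het", "hom_alt")
  for (rep in 1:60) {
    z <- stats::setNames(sample(lv, 4, replace = TRUE), c("1", "2", "3", "4"))
    z5 <- c(z, "5" = "hom_ref")
    expect_true(fits_recessive_hom(z5, ext)$fits <=
                  fits_recessive_hom(z, qp)$fits)
    for (mode in c("strict", "incomplete_penetrance")) {
      expect_true(fits_dominant(z5, ext, mode = mode)$fits <=
                    fits_dominant(z, qp, mode = mode)$fits)
    }
    z2 <- stats::setNames(sample(lv, 4, replace = TRUE), c("1", "2", "3", "4"))
    z2_5 <- c(z2, "5" = "hom_ref")
    expect_true(comp_het_pair(z5, z2_5, ext)$fits <=
                  comp_het_pair(z, z2, qp)$fits)
  }
})

test_that("segregation_scan reproduces the per-family models", {
  cons <- annotate_variants(FX$vcf, FX$transcripts, FX$coding_seqs)
  gm <- variant_genes(cons)
  models <- list()
  for (fam in names(FX$peds)) {
    res <- segregation_scan(FX$vcf, FX$peds[[fam]], gm)
    models[[fam]] <- vapply(res, `[[`, character(1), "model")
  }
  expect_true("AR_hom" %in% models$A)
  expect_true("AR_hom" %in% models$B)
  expect_true("comp_het" %in% models$C)
  expect_true("AD_incomplete_penetrance" %in% models$D)
  expect_false("AR_hom" %in% models$D)
  # a pedigree member missing from the VCF is a validation error
  stray <- pedigree("Z", "Z_1", NA, NA, "male", "affected")
  expect_error(segregation_scan(FX$vcf, stray, gm), "absent from VCF")
})

test_that("known-gene review surfaces unfiltered variants per family", {
  cons <- annotate_variants(FX$vcf, FX$transcripts, FX$coding_seqs)
  # family D's het variant is found even though no homozygous model fits
  keys <- known_gene_review(FX$vcf, cons, "BEST1",
                            samples = FX$peds$D$individual_id)
  expect_equal(keys, fx_key("p.Thr91Ile"))
  # review is unfiltered: a synonymous decoy in its gene is included
  keysC <- known_gene_review(FX$vcf, cons, "OTHERGENE",
                             samples = FX$peds$C$individual_id)
  expect_true(any(grepl("^chr11:8", keysC)))
  expect_length(known_gene_review(FX$vcf, cons, "NOSUCHGENE"), 0L)
})
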