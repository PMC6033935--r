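test_that("the packaged fixture matches the published configurations", {
  expect_equal(sum(vapply(FX$peds, nrow, integer(1))), 20L)
  expect_equal(sum(vapply(FX$peds, function(p) nrow(affected_members(p)),
                          integer(1))), 8L)
  # family A: both sons homozygous, both parents het
  zA <- fx_zygosity(fx_key("p.Tyr131Cys"), FX$peds$A)
  expect_equal(zA, c(A_I.1 = "het", A_I.2 = "het",
                     A_II.1 = "hom_alt", A_II.2 = "hom_alt"))
  # family D: proband, father and sister het; mother non-carrier
  zD <- fx_zygosity(fx_key("p.Thr91Ile"), FX$peds$D)
  expect_equal(zD, c(D_I.1 = "het", D_I.2 = "hom_ref",
                     D_II.1 = "het", D_II.2 = "het"))
  # previously-reported variant carries a tiny nonzero frequency, the
  # novel ones none
  afs <- max_population_af(FX$vcf, FX$freqs)
  keys <- variant_keys(FX$vcf)
  expect_gt(afs[keys == fx_key("p.Arg47His")], 0)
  expect_equal(afs[keys == fx_key("p.Val216Ile")], 0)
  # the constrained codons carry the published reference amino acids
  cs <- FX$coding_seqs[["ENST00000378043"]]
  codon <- function(s, i) substr(s, 3 * i - 2, 3 * i)
  aa <- function(s, i) Biostrings::GENETIC_CODE[[codon(s, i)]]
  expect_equal(aa(cs, 47), "R")
  expect_equal(aa(cs, 91), "T")
  expect_equal(aa(cs, 131), "Y")
  expect_equal(aa(cs, 150), "R")
  expect_equal(aa(FX$coding_seqs[["ENST00000526988"]], 216), "V")
})

test_that("gene drop honors frequency extremes and transmission odds", {
  ped <- trio_ped()
  g0 <- gene_drop(ped, 0, seed = 1)
  expect_true(all(g0$a == 0L & g0$b == 0L))
  g1 <- gene_drop(ped, 1, seed = 1)
  expect_true(all(g1$a == 1L & g1$b == 1L))
  # child het fraction vs. exhaustive transmission enumeration at af 0.5
  af <- 0.5
  hw <- c(`0` = (1 - af)^2, `1` = 2 * af * (1 - af), `2` = af^2)
  p_het <- 0
  for (gf in 0:2) for (gm in 0:2) {
    p_f_alt <- gf / 2  # P(transmitted paternal allele is alt)
    p_m_alt <- gm / 2
    p_het <- p_het + hw[[as.character(gf)]] * hw[[as.character(gm)]] *
      (p_f_alt * (1 - p_m_alt) + (1 - p_f_alt) * p_m_alt)
  }
  n_rep <- 10000L
  set.seed(202)
  g <- mendelsieve:::gene_drop_multi(ped, rep(af, n_rep))
  child <- ped$individual_id[3]
  frac <- mean(g$a[, child] + g$b[, child] == 1L)
  se <- sqrt(p_het * (1 - p_het) / n_rep)
  expect_lt(abs(frac - p_het), 3 * se)
})

test_that("planted causal configurations follow their model", {
  qp <- make_pedigree("quartet", "P")
  ar <- plant_causal(qp, "AR_hom", seed = 4)
  ids <- qp$individual_id
  dose_ar <- as.integer(ar$geno_a[1, ] + ar$geno_b[1, ])
  expect_equal(dose_ar[1:3], c(1L, 1L, 2L))
  expect_equal(ar$ped$affected[3], "affected")

  sx <- make_pedigree("sextet", "S")
  ch <- plant_causal(sx, "comp_het", seed = 5)
  sids <- sx$individual_id
  dose <- ch$geno_a + ch$geno_b
  expect_equal(unname(dose[, sids[1]]), c(1L, 0L))  # father: variant 1 only
  expect_equal(unname(dose[, sids[2]]), c(0L, 1L))  # mother: variant 2 only
  aff <- ch$ped$individual_id[ch$ped$affected == "affected"]
  for (id in aff) expect_equal(unname(dose[, id]), c(1L, 1L))

  expect_error(
    plant_causal(pedigree("L", "L_1", NA, NA, "male", "unknown"), "AR_hom"),
    "infeasible"
  )
})

test_that("incomplete penetrance leaves unaffected carriers at rate 1 - f", {
  dp <- make_pedigree("quartet", "D")
  pen <- 0.5
  carrier_unaff <- 0L
  carrier_total <- 0L
  set.seed(77)
  for (rep in 1:300) {
    pl <- plant_causal(dp, "AD", penetrance = pen)
    dose <- pl$geno_a[1, ] + pl$geno_b[1, ]
    proband <- dp$individual_id[3]
    others <- setdiff(names(dose)[dose >= 1], proband)
    carrier_total <- carrier_total + length(others)
    carrier_unaff <- carrier_unaff +
      sum(pl$ped$affected[match(others, pl$ped$individual_id)] ==
            "unaffected")
  }
  frac <- carrier_unaff / carrier_total
  se <- sqrt(pen * (1 - pen) / carrier_total)
  expect_lt(abs(frac - (1 - pen)), 4 * se)
})

test_that("error-free simulated cohorts are Mendelian-consistent", {
  cfg <- simulation_config(seed = 11, n_families = 4,
                           background_variant_count = 25,
                           causal_model = "comp_het")
  sim <- simulate_cohort(cfg)
  for (ped in sim$peds) {
    a <- sim$vcf$geno_a[, ped$individual_id, drop = FALSE]
    b <- sim$vcf$geno_b[, ped$individual_id, drop = FALSE]
    expect_true(mendel_ok(ped, a, b))
  }
})

test_that("identical simulation configs reproduce byte-identical output", {
  cfg <- simulation_config(seed = 99, n_families = 3,
                           background_variant_count = 20)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(write_vcf(s1$vcf), write_vcf(s2$vcf))
  expect_identical(s1$truth, s2$truth)
  expect_identical(write_ped(s1$peds), write_ped(s2$peds))
  s3 <- simulate_cohort(simulation_config(seed = 100, n_families = 3,
                                          background_variant_count = 20))
  expect_false(identical(write_vcf(s1$vcf), write_vcf(s3$vcf)))
})

test_that("genotyping errors perturb calls without changing structure", {
  base <- simulation_config(seed = 55, n_families = 3,
                            background_variant_count = 30)
  noisy <- simulation_config(seed = 55, n_families = 3,
                             background_variant_count = 30,
                             genotyping_error_rate = 0.05)
  s_clean <- simulate_cohort(base)
  s_noisy <- simulate_cohort(noisy)
  expect_equal(dim(s_noisy$vcf$geno_a), dim(s_clean$vcf$geno_a))
  same <- sum(s_noisy$vcf$geno_a == s_clean$vcf$geno_a, na.rm = TRUE)
  expect_lt(same, length(s_clean$vcf$geno_a))
})

test_that("fixture files round-trip through their plain-text formats", {
  dir <- withr::local_tempdir()
  write_fixture(FX, dir)
  vs <- read_vcf(file.path(dir, "fixture.vcf"))
  expect_equal(variant_keys(vs), variant_keys(FX$vcf))
  peds <- parse_ped(file.path(dir, "fixture.ped"))
  expect_named(peds, names(FX$peds))
  ts <- read_transcripts(file.path(dir, "transcripts.tsv"))
  expect_named(ts, names(FX$transcripts))
  expect_equal(ts$ENST00000378043$exons,
               FX$transcripts$ENST00000378043$exons)
  fq <- read_frequency_table(file.path(dir, "freqs.tsv"))
  expect_equal(nrow(fq), nrow(FX$freqs))
})
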