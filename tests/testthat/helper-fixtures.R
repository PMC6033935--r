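# Shared fixture objects, built once per test run.
FX <- build_fixture()

fx_key <- function(label) FX$truth$key[match(label, FX$truth$label)]

# named zygosity vector for one fixture variant restricted to one family
fx_zygosity <- function(key, ped) {
  zy <- zygosity_matrix(FX$vcf)
  zy[match(key, variant_keys(FX$vcf)), ped$individual_id]
}

# a minimal quartet used by hand-built segregation cases:
# 1 father, 2 mother (unaffected), 3 affected child, 4 unaffected child
quartet_ped <- function() {
  pedigree("Q", c("1", "2", "3", "4"),
           father_id = c(NA, NA, "1", "1"),
           mother_id = c(NA, NA, "2", "2"),
           sex = c("male", "female", "male", "female"),
           affected = c("unaffected", "unaffected", "affected",
                        "unaffected"))
}

trio_ped <- function() {
  pedigree("T", c("1", "2", "3"),
           father_id = c(NA, NA, "1"), mother_id = c(NA, NA, "2"),
           sex = c("male", "female", "male"),
           affected = c("unaffected", "unaffected", "affected"))
}

zyg <- function(...) {
  v <- c(...)
  stopifnot(all(v %in% c("hom_ref", "het", "hom_alt", "missing")))
  v
}
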