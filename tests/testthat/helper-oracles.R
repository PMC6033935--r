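# Independent reference implementations used as oracles. These are kept
# deliberately separate in style and mechanism from the package code:
# the segregation predicates are re-derived member-by-member, and the
# compound-het oracle enumerates phased parental haplotypes and
# transmissions forward instead of reasoning about donor sets.

# ---- reference predicates for the single-variant models ----------------

# z: named zygosity vector; ped: pedigree tibble
ref_fits_ar_hom <- function(z, ped) {
  n_aff <- 0L
  for (i in seq_len(nrow(ped))) {
    id <- ped$individual_id[i]
    if (ped$affected[i] == "affected") {
      n_aff <- n_aff + 1L
      if (z[[id]] != "hom_alt") return(FALSE)
      for (p in c(ped$father_id[i], ped$mother_id[i])) {
        if (!is.na(p) && z[[p]] != "het") return(FALSE)
      }
    }
    if (ped$affected[i] == "unaffected" && z[[id]] == "hom_alt") return(FALSE)
  }
  n_aff > 0L
}

ref_fits_dominant <- function(z, ped, mode) {
  is_carrier <- function(id) z[[id]] %in% c("het", "hom_alt")
  n_aff <- 0L
  for (i in seq_len(nrow(ped))) {
    id <- ped$individual_id[i]
    if (ped$affected[i] == "affected") {
      n_aff <- n_aff + 1L
      if (!is_carrier(id)) return(FALSE)
    }
    if (mode == "strict" && ped$affected[i] == "unaffected" &&
        is_carrier(id)) {
      return(FALSE)
    }
  }
  n_aff > 0L
}

# ---- forward-enumeration oracle for compound heterozygosity ------------

# For a nuclear two-generation family (two founders + their children),
# enumerate every phased parental haplotype configuration and every
# transmission choice, and tabulate, per unphased genotype
# configuration, in how many consistent phased states all affected
# children carry the two variants in trans. Keys are the concatenated
# allele counts (v1 then v2) for father, mother, children in pedigree
# order.
build_comp_het_oracle <- function(n_children, affected_children) {
  hap <- expand.grid(v1 = 0:1, v2 = 0:1)  # one haplotype's allele pair
  picks <- as.matrix(expand.grid(rep(list(1:4), n_children)))
  # pick value 1..4 = (father hap A/B, mother hap A/B)
  f_of <- c(1L, 1L, 2L, 2L)
  m_of <- c(1L, 2L, 1L, 2L)
  tab <- new.env(parent = emptyenv())
  for (fA in 1:4) for (fB in 1:4) for (mA in 1:4) for (mB in 1:4) {
    f1 <- c(hap$v1[fA], hap$v1[fB])
    f2 <- c(hap$v2[fA], hap$v2[fB])
    m1 <- c(hap$v1[mA], hap$v1[mB])
    m2 <- c(hap$v2[mA], hap$v2[mB])
    parent_key <- c(sum(f1), sum(f2), sum(m1), sum(m2))
    for (r in seq_len(nrow(picks))) {
      child_key <- integer(0)
      all_trans <- TRUE
      for (ch in seq_len(n_children)) {
        fh <- f_of[picks[r, ch]]
        mh <- m_of[picks[r, ch]]
        c1 <- c(f1[fh], m1[mh])  # (paternal, maternal) allele at v1
        c2 <- c(f2[fh], m2[mh])
        child_key <- c(child_key, sum(c1), sum(c2))
        if (ch %in% affected_children) {
          het_both <- sum(c1) == 1L && sum(c2) == 1L
          trans <- het_both && (c1[1] != c2[1])  # alts from different parents
          if (!trans) all_trans <- FALSE
        }
      }
      key <- paste(c(parent_key, child_key), collapse = "")
      prev <- if (is.null(tab[[key]])) c(0L, 0L) else tab[[key]]
      tab[[key]] <- prev + c(1L, if (all_trans) 1L else 0L)
    }
  }
  tab
}

zyg_levels <- c("hom_ref", "het", "hom_alt")
zyg_to_count <- function(z) match(z, zyg_levels) - 1L

# ---- independent Mendelian-consistency checker -------------------------

# a, b: allele matrices (variant x member); TRUE when every child's
# genotype can be explained by one allele from each present parent.
mendel_ok <- function(ped, a, b) {
  for (i in seq_len(nrow(ped))) {
    id <- ped$individual_id[i]
    fa <- ped$father_id[i]
    mo <- ped$mother_id[i]
    for (v in seq_len(nrow(a))) {
      child <- sort(as.integer(c(a[v, id], b[v, id])))
      if (anyNA(child)) next
      from <- function(p) {
        if (is.na(p)) 0:1 else unique(as.integer(c(a[v, p], b[v, p])))
      }
      ok <- FALSE
      for (x in from(fa)) for (y in from(mo)) {
        if (identical(sort(as.integer(c(x, y))), child)) ok <- TRUE
      }
      if (!ok) return(FALSE)
    }
  }
  TRUE
}
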