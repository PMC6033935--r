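#' Segregation model verdicts
#'
#' The three inheritance models the prioritization funnel applies to each
#' rare protein-altering variant (and variant pair) in a family:
#' autosomal-recessive homozygous ([fits_recessive_hom()]), compound
#' heterozygous with trans-phase inference from parental genotypes
#' ([find_compound_het()] / [comp_het_pair()]), and autosomal dominant in
#' strict or incomplete-penetrance mode ([fits_dominant()]).
#'
#' All models operate on named zygosity vectors (values `hom_ref`, `het`,
#' `hom_alt`, `missing`; names = pedigree individual ids), as produced by
#' [zygosity_matrix()], and are autosomal — sex is never consulted. A
#' model never fits a family with no affected member. Missing genotypes
#' raise `missing_genotype` exceptions and fail the model under the
#' default strict handling; with `strict = FALSE` they are treated as
#' compatible with the model.
#'
#' @name segregation-models
#' @return Each verdict is a `segregation_result`: a list with
#'   `family_id`, `model`, `variants` (one or two keys), `fits` (logical),
#'   `carriers` (tibble `individual_id`, `variant`, `zygosity`) and
#'   `exceptions` (tibble `individual_id`, `kind` with kinds
#'   `unaffected_carrier`, `phase_unknown`, `missing_genotype`).
NULL

segregation_result <- function(family_id, model, variants, fits, carriers,
                               exceptions) {
  structure(
    list(family_id = family_id, model = model, variants = variants,
         fits = fits, carriers = carriers, exceptions = exceptions),
    class = "segregation_result"
  )
}

#' @export
print.segregation_result <- function(x, ...) {
  cat("segregation_result:", x$family_id, x$model,
      paste(x$variants, collapse = " + "),
      if (x$fits) "FITS" else "does not fit", "\n")
  if (nrow(x$exceptions)) {
    cat("  exceptions:",
        paste(x$exceptions$individual_id, x$exceptions$kind, sep = ":",
              collapse = ", "), "\n")
  }
  invisible(x)
}

exceptions_tibble <- function(individual_id = character(0),
                              kind = character(0)) {
  tibble::tibble(individual_id = individual_id, kind = kind)
}

carriers_tibble <- function(geno, variant) {
  tibble::tibble(individual_id = names(geno), variant = variant,
                 zygosity = unname(geno))
}

check_geno <- function(geno, ped) {
  missing_ids <- setdiff(ped$individual_id, names(geno))
  if (length(missing_ids)) {
    stop("no genotype for pedigree member(s): ",
         paste(missing_ids, collapse = ", "))
  }
  geno[ped$individual_id]
}

#' Autosomal-recessive homozygous model
#'
#' Fits when every affected member is homozygous for the alternate
#' allele, no unaffected member is, and every genotyped parent of an
#' affected member is heterozygous (the obligate-carrier constraint).
#'
#' @param geno named zygosity vector (see [zygosity_matrix()]).
#' @param ped a [pedigree()].
#' @param variant variant key used for bookkeeping.
#' @param strict fail on missing genotypes (default) instead of treating
#'   them as compatible.
#' @return A `segregation_result`.
#' @export
fits_recessive_hom <- function(geno, ped, variant = "v", strict = TRUE) {
  geno <- check_geno(geno, ped)
  aff <- ped$individual_id[ped$affected == "affected"]
  unaff <- ped$individual_id[ped$affected == "unaffected"]
  miss <- names(geno)[geno == "missing"]
  exceptions <- exceptions_tibble(miss, rep("missing_genotype", length(miss)))
  known <- function(ids) ids[!ids %in% miss]
  obligate <- unique(unlist(lapply(aff, function(id) {
    p <- parents_of(ped, id)
    c(if (!is.null(p$father)) p$father$individual_id,
      if (!is.null(p$mother)) p$mother$individual_id)
  })))
  fits <- length(aff) > 0L &&
    all(geno[known(aff)] == "hom_alt") &&
    !any(geno[known(unaff)] == "hom_alt") &&
    all(geno[known(obligate)] == "het")
  if (strict && length(miss)) fits <- FALSE
  segregation_result(ped$family_id[1], "AR_hom", variant, fits,
                     carriers_tibble(geno, variant), exceptions)
}

#' Autosomal dominant model
#'
#' `strict`: every affected member carries the alternate allele (het or
#' hom) and no unaffected member does; de-novo carriers are allowed.
#' `incomplete_penetrance`: every affected member is a carrier, and
#' unaffected carriers are tolerated but each is recorded as an
#' `unaffected_carrier` exception — the configuration of a dominant
#' variant inherited from an asymptomatic parent.
#'
#' @inheritParams fits_recessive_hom
#' @param mode `"strict"` or `"incomplete_penetrance"`.
#' @return A `segregation_result` with model `AD_strict` or
#'   `AD_incomplete_penetrance`.
#' @export
fits_dominant <- function(geno, ped, variant = "v",
                          mode = c("strict", "incomplete_penetrance"),
                          strict = TRUE) {
  mode <- match.arg(mode)
  geno <- check_geno(geno, ped)
  aff <- ped$individual_id[ped$affected == "affected"]
  unaff <- ped$individual_id[ped$affected == "unaffected"]
  miss <- names(geno)[geno == "missing"]
  known <- function(ids) ids[!ids %in% miss]
  carrier <- geno %in% c("het", "hom_alt")
  names(carrier) <- names(geno)
  exceptions <- exceptions_tibble(miss, rep("missing_genotype", length(miss)))
  unaff_carriers <- known(unaff)[carrier[known(unaff)]]
  fits <- length(aff) > 0L && all(carrier[known(aff)])
  if (mode == "strict") {
    fits <- fits && length(unaff_carriers) == 0L
  } else {
    exceptions <- dplyr::bind_rows(
      exceptions,
      exceptions_tibble(unaff_carriers,
                        rep("unaffected_carrier", length(unaff_carriers)))
    )
  }
  if (strict && length(miss)) fits <- FALSE
  model <- if (mode == "strict") "AD_strict" else "AD_incomplete_penetrance"
  segregation_result(ped$family_id[1], model, variant, fits,
                     carriers_tibble(geno, variant), exceptions)
}

#' Compound-heterozygous verdict for one variant pair
#'
#' Fits when every affected member is heterozygous for both variants, no
#' unaffected member is heterozygous for both, and the trans
#' configuration is certain for every affected member given parental
#' genotypes. Trans inference per affected child considers, for each
#' variant, which parent can have donated the alternate allele: the
#' donor must carry the allele *and* the other parent must be able to
#' supply the child's reference allele (a homozygous-alternate parent
#' transmits the alternate to every child, so transmission can be forced
#' even when both parents are carriers). Then:
#'
#' * each variant with exactly one possible donor, and the two variants
#'   with *different* donors — trans certain;
#' * some variant with no possible donor — Mendelian inconsistency, does
#'   not fit;
#' * both variants forced to the *same* single donor — a cis
#'   configuration is certain, does not fit (even with
#'   `allow_phase_unknown`);
#' * anything else (a donor genuinely ambiguous, or a parent
#'   ungenotyped/absent) — `phase_unknown` exception; fits only with
#'   `allow_phase_unknown = TRUE`.
#'
#' This is the closed form of enumerating all transmission-consistent
#' parental-origin assignments.
#'
#' @param geno1,geno2 named zygosity vectors for the two variants.
#' @param ped a [pedigree()].
#' @param variants length-2 character vector of variant keys.
#' @param strict fail on missing genotypes.
#' @param allow_phase_unknown accept pairs whose phase cannot be resolved.
#' @return A `segregation_result` with model `comp_het`.
#' @export
comp_het_pair <- function(geno1, geno2, ped, variants = c("v1", "v2"),
                          strict = TRUE, allow_phase_unknown = FALSE) {
  geno1 <- check_geno(geno1, ped)
  geno2 <- check_geno(geno2, ped)
  aff <- ped$individual_id[ped$affected == "affected"]
  unaff <- ped$individual_id[ped$affected == "unaffected"]
  miss <- union(names(geno1)[geno1 == "missing"],
                names(geno2)[geno2 == "missing"])
  known <- function(ids) ids[!ids %in% miss]
  exceptions <- exceptions_tibble(miss, rep("missing_genotype", length(miss)))
  het_both <- geno1 == "het" & geno2 == "het"
  fits <- length(aff) > 0L &&
    all(het_both[known(aff)]) &&
    !any(het_both[known(unaff)])
  # trans-configuration per affected child
  carries <- function(id, geno) geno[id] %in% c("het", "hom_alt")
  gives_ref <- function(id, geno) geno[id] %in% c("het", "hom_ref")
  for (id in aff) {
    if (id %in% miss) next  # already reported as missing_genotype
    p <- parents_of(ped, id)
    pid <- c(father = if (!is.null(p$father)) p$father$individual_id else NA,
             mother = if (!is.null(p$mother)) p$mother$individual_id else NA)
    unknown_parent <- any(is.na(pid)) ||
      any(pid %in% miss, na.rm = TRUE)
    if (unknown_parent) {
      exceptions <- dplyr::bind_rows(
        exceptions, exceptions_tibble(id, "phase_unknown"))
      if (!allow_phase_unknown) fits <- FALSE
      next
    }
    # a parent can be the donor of a het child's alternate allele only
    # if it carries the allele and the other parent can donate reference
    donors_of <- function(geno) {
      pid[c(carries(pid[1], geno) && gives_ref(pid[2], geno),
            carries(pid[2], geno) && gives_ref(pid[1], geno))]
    }
    donors1 <- donors_of(geno1)
    donors2 <- donors_of(geno2)
    if (!length(donors1) || !length(donors2)) {
      fits <- FALSE  # a variant with no parental origin: Mendelian error
    } else if (length(donors1) == 1L && length(donors2) == 1L) {
      if (donors1 == donors2) {
        fits <- FALSE  # cis forced: both alternate alleles from one parent
      }
      # else: trans certain, no exception
    } else {
      exceptions <- dplyr::bind_rows(
        exceptions, exceptions_tibble(id, "phase_unknown"))
      if (!allow_phase_unknown) fits <- FALSE
    }
  }
  if (strict && length(miss)) fits <- FALSE
  carriers <- dplyr::bind_rows(carriers_tibble(geno1, variants[1]),
                               carriers_tibble(geno2, variants[2]))
  segregation_result(ped$family_id[1], "comp_het", variants, fits,
                     carriers, exceptions)
}

#' All compound-heterozygous pairs among variants of one gene
#'
#' Applies [comp_het_pair()] to every unordered pair of the supplied
#' variants (which must already be collapsed to one gene). The verdict is
#' symmetric in the pair order.
#'
#' @param vs a biallelic `variant_set` whose sites share a gene.
#' @param ped a [pedigree()].
#' @param strict,allow_phase_unknown see [comp_het_pair()].
#' @param fitting_only drop non-fitting pairs.
#' @return List of `segregation_result`s (empty when fewer than two
#'   variants are supplied).
#' @export
find_compound_het <- function(vs, ped, strict = TRUE,
                              allow_phase_unknown = FALSE,
                              fitting_only = TRUE) {
  n <- n_variants(vs)
  if (n < 2L) return(list())
  zy <- zygosity_matrix(vs)
  keys <- variant_keys(vs)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      res <- comp_het_pair(zy[i, ], zy[j, ], ped, variants = keys[c(i, j)],
                           strict = strict,
                           allow_phase_unknown = allow_phase_unknown)
      if (!fitting_only || res$fits) out[[length(out) + 1L]] <- res
    }
  }
  out
}

#' Scan one family for model-consistent variants
#'
#' Applies the enabled inheritance models to every supplied variant (and
#' to every variant pair within each gene for the compound-het model) and
#' returns the verdicts. The caller is expected to have applied the
#' upstream rarity and impact filters; sites at which no family member
#' carries an alternate allele are skipped (no model can fit them).
#'
#' @param vs a biallelic `variant_set` containing all pedigree members.
#' @param ped a [pedigree()].
#' @param gene_map tibble `key`, `gene_id` from [variant_genes()], used to
#'   group variants into genes for compound-het pairing.
#' @param models subset of `c("AR_hom", "comp_het", "AD")`.
#' @param penetrance_mode `"strict"` or `"incomplete_penetrance"` for the
#'   dominant model; with incomplete penetrance the strict dominant model
#'   is tried first and reported when it fits.
#' @param strict,allow_phase_unknown missing-genotype / phase handling.
#' @param report_all keep non-fitting verdicts too.
#' @return List of `segregation_result`s.
#' @export
segregation_scan <- function(vs, ped, gene_map,
                             models = c("AR_hom", "comp_het", "AD"),
                             penetrance_mode = "incomplete_penetrance",
                             strict = TRUE, allow_phase_unknown = FALSE,
                             report_all = FALSE) {
  absent <- setdiff(ped$individual_id, vs$samples)
  if (length(absent)) {
    stop("pedigree member(s) absent from VCF samples: ",
         paste(absent, collapse = ", "))
  }
  if (!n_variants(vs)) return(list())
  zy_all <- zygosity_matrix(vs)[, ped$individual_id, drop = FALSE]
  keys <- variant_keys(vs)
  has_alt <- apply(zy_all, 1L, function(z) any(z %in% c("het", "hom_alt")))
  out <- list()
  add <- function(res) {
    if (report_all || res$fits) out[[length(out) + 1L]] <<- res
  }
  for (i in which(has_alt)) {
    geno <- zy_all[i, ]
    if ("AR_hom" %in% models) {
      add(fits_recessive_hom(geno, ped, variant = keys[i], strict = strict))
    }
    if ("AD" %in% models) {
      res <- fits_dominant(geno, ped, variant = keys[i], mode = "strict",
                           strict = strict)
      if (!res$fits && penetrance_mode == "incomplete_penetrance") {
        res2 <- fits_dominant(geno, ped, variant = keys[i],
                              mode = "incomplete_penetrance", strict = strict)
        if (res2$fits || report_all) res <- res2
      }
      add(res)
    }
  }
  if ("comp_het" %in% models && any(has_alt)) {
    gm <- gene_map[gene_map$key %in% keys[has_alt], ]
    for (gene in unique(gm$gene_id)) {
      idx <- which(keys %in% gm$key[gm$gene_id == gene] & has_alt)
      if (length(idx) < 2L) next
      res <- find_compound_het(subset_variants(vs, idx), ped,
                               strict = strict,
                               allow_phase_unknown = allow_phase_unknown,
                               fitting_only = !report_all)
      for (r in res) {
        r$gene_id <- gene
        add(r)
      }
    }
  }
  out
}

#' Unconditional review of a known disease gene
#'
#' Returns every variant annotated to `gene_id` — regardless of
#' frequency, predicted impact or segregation — that is present (at least
#' one alternate allele) in the supplied samples. This reproduces the
#' manual-review route by which a known gene's heterozygous variant can
#' surface even when no formal model fits.
#'
#' @param vs a biallelic `variant_set`.
#' @param consequences tibble from [annotate_variants()].
#' @param gene_id gene to review.
#' @param samples restrict presence to these sample ids (default: all).
#' @return Character vector of variant keys.
#' @export
known_gene_review <- function(vs, consequences, gene_id, samples = NULL) {
  gm <- variant_genes(consequences, protein_altering_only = FALSE)
  keys <- variant_keys(vs)
  in_gene <- keys %in% gm$key[gm$gene_id == gene_id]
  if (!any(in_gene)) return(character(0))
  if (is.null(samples)) samples <- vs$samples
  zy <- zygosity_matrix(vs)[, samples, drop = FALSE]
  present <- apply(zy, 1L, function(z) any(z %in% c("het", "hom_alt")))
  keys[in_gene & present]
}
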