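#' Pipeline configuration
#'
#' Tunable knobs of the prioritization funnel. Defaults reproduce the
#' published filtering strategy: variants present at more than 0.2% in
#' any reference cohort are removed (`max_af = 0.002`, strict `>`),
#' protein-altering consequences are required, all three inheritance
#' models are enabled with the dominant model in incomplete-penetrance
#' mode, and missing genotypes fail a model.
#'
#' @param max_af frequency ceiling; variants with pooled maximum AF
#'   strictly above this are filtered out.
#' @param include_potentially_altering count `splice_region` consequences
#'   as potentially protein-altering.
#' @param models subset of `c("AR_hom", "comp_het", "AD")`.
#' @param penetrance_mode `"strict"` or `"incomplete_penetrance"`.
#' @param panel_genes gene panel for the intersection stage (emulating a
#'   retinopathy panel such as RetNet); empty = see `panel_optional`.
#' @param panel_optional with an empty panel, skip the intersection
#'   instead of removing everything.
#' @param review_genes known disease genes whose variants are always
#'   reviewed (added after panel intersection).
#' @param strict_missing missing genotypes fail segregation models.
#' @param allow_phase_unknown accept compound-het pairs with unresolvable
#'   phase.
#' @param report_all keep non-fitting segregation verdicts in the scan.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(max_af = 0.002,
                            include_potentially_altering = FALSE,
                            models = c("AR_hom", "comp_het", "AD"),
                            penetrance_mode = c("incomplete_penetrance",
                                                "strict"),
                            panel_genes = character(0),
                            panel_optional = TRUE,
                            review_genes = character(0),
                            strict_missing = TRUE,
                            allow_phase_unknown = FALSE,
                            report_all = FALSE) {
  penetrance_mode <- match.arg(penetrance_mode)
  stopifnot(max_af >= 0, max_af <= 1, length(models) >= 1,
            all(models %in% c("AR_hom", "comp_het", "AD")))
  structure(
    list(max_af = max_af,
         include_potentially_altering = include_potentially_altering,
         models = models, penetrance_mode = penetrance_mode,
         panel_genes = panel_genes, panel_optional = panel_optional,
         review_genes = review_genes, strict_missing = strict_missing,
         allow_phase_unknown = allow_phase_unknown,
         report_all = report_all),
    class = "pipeline_config"
  )
}

# report-model precedence for picking one model per (family, variant)
MODEL_RANK <- c(AR_hom = 1L, comp_het = 2L, AD_strict = 3L,
                AD_incomplete_penetrance = 4L, known_gene_review = 5L)

#' Run the prioritization funnel
#'
#' Stages, in fixed order: split multiallelic sites, remove variants with
#' pooled population frequency above `max_af`, keep protein-altering
#' (optionally also potentially-altering) variants, test the enabled
#' inheritance models in every family, intersect with the gene panel, and
#' finally union in the unconditional known-gene review (after the panel,
#' so a review gene outside the panel still surfaces). Families are
#' processed independently. The surviving-variant count after each stage
#' is recorded in the funnel.
#'
#' @param vs a `variant_set` containing every pedigree member as sample.
#' @param peds list of [pedigree()]s.
#' @param transcripts named list of [transcript_model()]s.
#' @param coding_seqs named character vector keyed by transcript id.
#' @param freqs frequency tibble ([read_frequency_table()]).
#' @param config a [pipeline_config()].
#' @return A `candidate_report`: list with `candidates` (tibble
#'   `family_id`, `gene_id`, `chrom`, `pos`, `ref`, `alt`, `key`,
#'   `model`, `pair_key`, `zygosities`, `carriers` (list), `exceptions`
#'   (list), `notes`), `funnel` (tibble `stage`, `n`) and the config.
#'   Output ordering is deterministic: (family, gene, position).
#' @export
run_pipeline <- function(vs, peds, transcripts, coding_seqs, freqs, config) {
  stopifnot(inherits(config, "pipeline_config"))
  members <- unlist(lapply(peds, `[[`, "individual_id"), use.names = FALSE)
  absent <- setdiff(members, vs$samples)
  if (length(absent)) {
    stop("pedigree member(s) absent from VCF samples: ",
         paste(absent, collapse = ", "))
  }
  known_genes <- unique(vapply(transcripts, `[[`, character(1), "gene_id"))
  for (g in setdiff(c(config$panel_genes, config$review_genes), known_genes)) {
    warning("config references unknown gene id: ", g)
  }

  vs <- split_multiallelic(vs)
  funnel <- tibble::tibble(stage = "input", n = n_variants(vs))
  tally <- function(stage, n) {
    funnel <<- dplyr::bind_rows(funnel, tibble::tibble(stage = stage, n = n))
  }

  # 1. rarity: strictly-greater-than filter against the pooled maximum AF
  rare <- max_population_af(vs, freqs) <= config$max_af
  vs_rare <- subset_variants(vs, rare)
  tally("rare", n_variants(vs_rare))

  # 2. impact: at least one (potentially) protein-altering consequence
  cons <- annotate_variants(vs_rare, transcripts, coding_seqs)
  pa_keys <- unique(cons$key[is_protein_altering(
    cons$effect, config$include_potentially_altering)])
  vs_pa <- subset_variants(vs_rare, variant_keys(vs_rare) %in% pa_keys)
  tally("protein_altering", n_variants(vs_pa))

  # 3. per-family segregation
  gene_map <- variant_genes(cons, config$include_potentially_altering,
                            protein_altering_only = TRUE)
  rows <- list()
  for (ped in peds) {
    results <- segregation_scan(
      vs_pa, ped, gene_map, models = config$models,
      penetrance_mode = config$penetrance_mode,
      strict = config$strict_missing,
      allow_phase_unknown = config$allow_phase_unknown,
      report_all = FALSE
    )
    for (res in results) {
      for (k in res$variants) {
        pair <- setdiff(res$variants, k)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          family_id = res$family_id, key = k,
          model = res$model,
          pair_key = if (length(pair)) pair else NA_character_,
          carriers = list(res$carriers[res$carriers$variant == k, ]),
          exceptions = list(res$exceptions)
        )
      }
    }
  }
  seg <- dplyr::bind_rows(rows)
  if (!nrow(seg)) {
    seg <- tibble::tibble(family_id = character(0), key = character(0),
                          model = character(0), pair_key = character(0),
                          carriers = list(), exceptions = list())
  }
  seg <- dplyr::left_join(seg, gene_map, by = "key")
  tally("segregating", length(unique(seg$key)))

  # 4. gene-panel intersection
  seg <- intersect_panel(seg, config$panel_genes, config$panel_optional)
  tally("panel", length(unique(seg$key)))

  # 5. known-gene review union: per family, every variant of a review
  # gene present in that family, regardless of any upstream filter
  all_cons <- annotate_variants(vs, transcripts, coding_seqs)
  for (gene in config$review_genes) {
    for (ped in peds) {
      keys <- known_gene_review(vs, all_cons, gene,
                                samples = ped$individual_id)
      keys <- setdiff(keys, seg$key[seg$family_id == ped$family_id[1]])
      if (!length(keys)) next
      zy <- zygosity_matrix(vs)[, ped$individual_id, drop = FALSE]
      vk <- variant_keys(vs)
      add <- tibble::tibble(
        family_id = ped$family_id[1], key = keys,
        model = "known_gene_review", pair_key = NA_character_,
        carriers = lapply(keys, function(k) {
          carriers_tibble(zy[match(k, vk), ], k)
        }),
        exceptions = list(exceptions_tibble()),
        gene_id = gene
      )
      seg <- dplyr::bind_rows(seg, add)
    }
  }

  # one row per (family, variant): keep the highest-precedence model
  if (nrow(seg)) {
    seg <- seg[order(MODEL_RANK[seg$model]), ]
    seg <- seg[!duplicated(paste(seg$family_id, seg$key)), ]
  }
  tally("final", length(unique(seg$key)))

  vcoord <- tibble::tibble(key = variant_keys(vs), chrom = vs$variants$chrom,
                           pos = vs$variants$pos, ref = vs$variants$ref,
                           alt = vs$variants$alt)
  vcoord <- dplyr::distinct(vcoord)
  cand <- dplyr::left_join(seg, vcoord, by = "key")
  cand$zygosities <- vapply(cand$carriers, function(cr) {
    paste(cr$individual_id, cr$zygosity, sep = ":", collapse = ";")
  }, character(1))
  cand$notes <- vapply(cand$exceptions, function(ex) {
    if (!nrow(ex)) "" else paste(ex$individual_id, ex$kind, sep = ":",
                                 collapse = ";")
  }, character(1))
  cand <- cand[order(cand$family_id, cand$gene_id, cand$pos, cand$alt,
                     cand$model), ]
  cand <- dplyr::relocate(cand, "family_id", "gene_id", "chrom", "pos",
                          "ref", "alt", "key", "model", "pair_key",
                          "zygosities")
  structure(list(candidates = cand, funnel = funnel, config = config),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("candidate_report:", nrow(x$candidates), "row(s),",
      length(unique(x$candidates$key)), "distinct variant(s)\n")
  cat("funnel:", paste(x$funnel$stage, x$funnel$n, sep = "=",
                       collapse = " -> "), "\n")
  invisible(x)
}

#' Gene-panel intersection
#'
#' Keeps candidate rows whose gene is on the panel. With an empty panel
#' the stage is a no-op when `panel_optional` is set, and removes
#' everything otherwise.
#'
#' @param results tibble with a `gene_id` column.
#' @param panel_genes character vector of panel gene ids.
#' @param panel_optional see above.
#' @return Filtered tibble.
#' @export
intersect_panel <- function(results, panel_genes, panel_optional = TRUE) {
  if (!length(panel_genes)) {
    if (panel_optional) return(results)
    return(results[0, , drop = FALSE])
  }
  results[!is.na(results$gene_id) & results$gene_id %in% panel_genes, ,
          drop = FALSE]
}

#' Stage-by-stage survivor counts
#'
#' @param report a `candidate_report`.
#' @return Tibble `stage`, `n`; counts are monotone non-increasing
#'   through the sequential filter stages (the final review-union stage
#'   may add variants back).
#' @export
funnel_counts <- function(report) report$funnel

#' Serialize a candidate report as TSV
#'
#' Deterministic column order with the funnel emitted as a commented
#' header block; rows are sorted by (family, gene, position).
#'
#' @param report a `candidate_report`.
#' @param path optional output file.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
write_report <- function(report, path = NULL) {
  cand <- report$candidates
  cols <- c("family_id", "gene_id", "chrom", "pos", "ref", "alt", "key",
            "model", "pair_key", "zygosities", "notes")
  lines <- c(
    paste0("# funnel: ", paste(report$funnel$stage, report$funnel$n,
                               sep = "=", collapse = " ")),
    paste(cols, collapse = "\t"),
    if (nrow(cand)) {
      do.call(paste, c(lapply(cols, function(cn) {
        v <- cand[[cn]]
        ifelse(is.na(v), ".", as.character(v))
      }), sep = "\t"))
    }
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
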