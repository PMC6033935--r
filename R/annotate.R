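# Severity ranking for gene-level collapsing: higher = more disruptive.
# Fixed, deterministic; used only for ordering, never as evidence.
SEVERITY_RANK <- c(
  stop_gained = 9L, frameshift = 8L, stop_lost = 7L, start_lost = 6L,
  splice_site = 5L, missense = 4L, inframe_indel = 3L, splice_region = 2L,
  synonymous = 1L, noncoding_for_this_transcript = 0L, intergenic = 0L
)

# Effects counted as protein-altering by the impact filter.
PROTEIN_ALTERING_EFFECTS <- c("missense", "stop_gained", "stop_lost",
                              "start_lost", "frameshift", "inframe_indel",
                              "splice_site")

#' Severity rank of a consequence effect
#'
#' @param effect character vector of effect labels.
#' @return Integer ranks (higher = more disruptive).
#' @export
consequence_severity <- function(effect) {
  bad <- setdiff(effect, names(SEVERITY_RANK))
  if (length(bad)) stop("unknown effect: ", paste(bad, collapse = ", "))
  unname(SEVERITY_RANK[effect])
}

#' Is an effect protein-altering?
#'
#' Missense, nonsense (stop gained/lost), start-loss, frameshift,
#' in-frame indels and the two intronic splice-site bases always count.
#' `splice_region` (3-8 nt into the intron) counts only when
#' `include_potentially_altering` is set, the configurable reading of
#' "potentially protein-altering".
#'
#' @param effect character vector of effect labels (or a consequence
#'   tibble, in which case its `effect` column is used).
#' @param include_potentially_altering also count `splice_region`.
#' @return Logical vector.
#' @export
is_protein_altering <- function(effect, include_potentially_altering = FALSE) {
  if (is.data.frame(effect)) effect <- effect$effect
  keep <- PROTEIN_ALTERING_EFFECTS
  if (include_potentially_altering) keep <- c(keep, "splice_region")
  effect %in% keep
}

# internal: one-letter translation of a codon (standard genetic code)
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) stop("not a codon: ", codon)
  aa
}

# internal: reverse complement of a base string
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Amino-acid change of a coding SNV
#'
#' Substitutes `alt_base` at `cds_pos` of a spliced coding sequence
#' (given in translation orientation, start codon first) and translates
#' the affected codon with the standard genetic code.
#'
#' @param coding_sequence spliced CDS string, length divisible by 3.
#' @param cds_pos 1-based position in the CDS.
#' @param ref_base,alt_base single bases in translation orientation.
#' @return List with `aa_ref`, `aa_alt` (one-letter, `*` = stop),
#'   `codon_index` and `effect` (one of `synonymous`, `missense`,
#'   `stop_gained`, `stop_lost`, `start_lost`).
#' @export
codon_change <- function(coding_sequence, cds_pos, ref_base, alt_base) {
  stopifnot(cds_pos >= 1, cds_pos <= nchar(coding_sequence))
  have <- toupper(substr(coding_sequence, cds_pos, cds_pos))
  if (have != toupper(ref_base)) {
    stop("reference mismatch at CDS position ", cds_pos, ": sequence has ",
         have, ", variant claims ", ref_base,
         " (wrong strand or wrong coding sequence?)")
  }
  ci <- cds_position_to_codon(cds_pos)
  codon_from <- toupper(substr(coding_sequence, 3L * ci - 2L, 3L * ci))
  offset <- cds_pos - (3L * ci - 2L) + 1L
  codon_to <- codon_from
  substr(codon_to, offset, offset) <- toupper(alt_base)
  aa_ref <- translate_codon(codon_from)
  aa_alt <- translate_codon(codon_to)
  effect <-
    if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "stop_gained"
    else if (aa_ref == "*") "stop_lost"
    else if (ci == 1L && codon_from == "ATG") "start_lost"
    else "missense"
  list(aa_ref = aa_ref, aa_alt = aa_alt, codon_index = ci, effect = effect)
}

# internal: splice classification of an intronic position relative to a
# transcript's exons; NA when farther than the splice region.
splice_class <- function(t, pos) {
  d_after <- pos - t$exons$end    # bases into the downstream intron
  d_before <- t$exons$start - pos # bases into the upstream intron
  d <- suppressWarnings(min(c(d_after[d_after > 0], d_before[d_before > 0])))
  n_ex <- nrow(t$exons)
  inside_gene <- pos > min(t$exons$start) && pos < max(t$exons$end)
  if (!inside_gene || !is.finite(d)) return(NA_character_)
  if (d <= 2) "splice_site" else if (d <= 8) "splice_region" else NA_character_
}

#' Consequences of one variant on a set of transcript isoforms
#'
#' Projects a variant onto every transcript whose genomic span contains
#' it, yielding one consequence row per such transcript; a variant coding
#' in one isoform may be `noncoding_for_this_transcript` in another, and
#' both rows are retained — this is the isoform-aware step that lets a
#' variant be pathogenic through an alternate transcript only. When no
#' transcript contains the variant a single `intergenic` row is returned.
#'
#' For SNVs in the CDS the codon effect is computed against the
#' transcript's coding sequence (minus-strand alleles are complemented).
#' Intronic SNVs within 2 nt of a junction are `splice_site`, within
#' 3-8 nt `splice_region`. Indels overlapping the CDS are classified by
#' length mod 3 into `frameshift` / `inframe_indel` (no repeat
#' realignment; fixture variants are SNVs).
#'
#' @param chrom,pos,ref,alt the (biallelic) variant.
#' @param transcripts named list of [transcript_model()]s.
#' @param coding_seqs named character vector of spliced coding sequences,
#'   keyed by transcript id, in translation orientation.
#' @return Tibble with columns `transcript_id`, `gene_id`, `effect`,
#'   `cds_pos`, `codon_index`, `aa_ref`, `aa_alt`, `severity`.
#' @export
annotate_variant <- function(chrom, pos, ref, alt, transcripts, coding_seqs) {
  rows <- list()
  for (t in transcripts) {
    if (t$chrom != chrom) next
    span <- transcript_span(t)
    vend <- pos + nchar(ref) - 1L
    if (vend < span[1] || pos > span[2]) next
    is_snv <- nchar(ref) == 1L && nchar(alt) == 1L
    cds_pos <- NA_integer_
    ci <- NA_integer_
    aa_ref <- NA_character_
    aa_alt <- NA_character_
    if (is_snv) {
      cds_pos <- project_genomic_to_cds(t, pos)
      if (!is.na(cds_pos)) {
        r <- ref
        a <- alt
        if (t$strand == "-") {
          r <- revcomp(r)
          a <- revcomp(a)
        }
        cc <- codon_change(coding_seqs[[t$transcript_id]], cds_pos, r, a)
        effect <- cc$effect
        ci <- cc$codon_index
        aa_ref <- cc$aa_ref
        aa_alt <- cc$aa_alt
      } else {
        sc <- splice_class(t, pos)
        effect <- if (!is.na(sc)) sc else "noncoding_for_this_transcript"
      }
    } else {
      ivs <- cds_intervals(t)
      overlaps_cds <- any(pos <= ivs$end & vend >= ivs$start)
      effect <- if (!overlaps_cds) {
        "noncoding_for_this_transcript"
      } else if ((nchar(ref) - nchar(alt)) %% 3L != 0L) {
        "frameshift"
      } else {
        "inframe_indel"
      }
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      transcript_id = t$transcript_id, gene_id = t$gene_id, effect = effect,
      cds_pos = cds_pos, codon_index = ci, aa_ref = aa_ref, aa_alt = aa_alt,
      severity = consequence_severity(effect)
    )
  }
  if (!length(rows)) {
    return(tibble::tibble(
      transcript_id = NA_character_, gene_id = NA_character_,
      effect = "intergenic", cds_pos = NA_integer_, codon_index = NA_integer_,
      aa_ref = NA_character_, aa_alt = NA_character_,
      severity = consequence_severity("intergenic")
    ))
  }
  dplyr::bind_rows(rows)
}

#' Annotate every site of a variant set
#'
#' Applies [annotate_variant()] to each (biallelic) site.
#'
#' @param vs a `variant_set` (after [split_multiallelic()]).
#' @param transcripts named list of [transcript_model()]s.
#' @param coding_seqs named character vector keyed by transcript id.
#' @return Long tibble of consequences with a leading `key` column
#'   (see [variant_keys()]).
#' @export
annotate_variants <- function(vs, transcripts, coding_seqs) {
  keys <- variant_keys(vs)
  v <- vs$variants
  rows <- lapply(seq_len(nrow(v)), function(i) {
    cons <- annotate_variant(v$chrom[i], v$pos[i], v$ref[i], v$alt[i],
                             transcripts, coding_seqs)
    cons$key <- keys[i]
    cons
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble::tibble(transcript_id = character(0), gene_id = character(0),
                          effect = character(0), cds_pos = integer(0),
                          codon_index = integer(0), aa_ref = character(0),
                          aa_alt = character(0), severity = integer(0),
                          key = character(0))
  }
  dplyr::relocate(out, "key")
}

#' Gene-level collapsing of consequences
#'
#' A variant's gene membership is the union over all isoforms on which it
#' has a protein-altering consequence (so compound-het pairs may involve
#' different transcripts of the same gene). With
#' `protein_altering_only = FALSE` any consequence annotated to a gene
#' counts — the membership used by the known-gene review.
#'
#' @param consequences tibble from [annotate_variants()].
#' @param include_potentially_altering passed to [is_protein_altering()].
#' @param protein_altering_only restrict to protein-altering consequences.
#' @return Tibble with `key`, `gene_id` (distinct pairs).
#' @export
variant_genes <- function(consequences, include_potentially_altering = FALSE,
                          protein_altering_only = TRUE) {
  cons <- consequences[!is.na(consequences$gene_id), ]
  if (protein_altering_only) {
    cons <- cons[is_protein_altering(cons$effect, include_potentially_altering), ]
  }
  dplyr::distinct(cons[, c("key", "gene_id")])
}

#' Maximum population allele frequency per site
#'
#' The pooled-maximum reading of "present in either source": each site's
#' frequency is the maximum over all sources in the table, and 0 when the
#' site is absent (novel variant).
#'
#' @param vs a `variant_set`.
#' @param freqs frequency tibble from [read_frequency_table()].
#' @return Numeric vector, one value in `[0, 1]` per site.
#' @export
max_population_af <- function(vs, freqs) {
  keys <- variant_keys(vs)
  if (!nrow(freqs)) return(rep(0, length(keys)))
  fkey <- paste0(freqs$chrom, ":", freqs$pos, ":", freqs$ref, ">", freqs$alt)
  mx <- tapply(freqs$af, fkey, max)
  out <- as.numeric(mx[keys])
  out[is.na(out)] <- 0
  out
}
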