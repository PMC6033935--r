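#' Transcript isoform model
#'
#' Exon/CDS structure of one transcript isoform. Exons are 1-based
#' inclusive genomic intervals, sorted and non-overlapping; `cds_start`
#' and `cds_end` are genomic bounds (`cds_start <= cds_end` regardless of
#' strand — translation order comes from `strand`). The spliced CDS
#' length must be a multiple of 3.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends integer vectors of equal length.
#' @param cds_start,cds_end genomic CDS bounds.
#' @return A `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exon_starts, exon_ends, cds_start, cds_end) {
  stopifnot(strand %in% c("+", "-"),
            length(exon_starts) == length(exon_ends),
            all(exon_starts <= exon_ends),
            cds_start <= cds_end)
  o <- order(exon_starts)
  exons <- tibble::tibble(start = as.integer(exon_starts[o]),
                          end = as.integer(exon_ends[o]))
  if (nrow(exons) > 1L && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop(transcript_id, ": exons overlap or touch")
  }
  t <- structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons,
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end)),
    class = "transcript_model"
  )
  ivs <- cds_intervals(t)
  if (!nrow(ivs)) stop(transcript_id, ": CDS bounds outside all exons")
  in_exon <- function(p) any(p >= exons$start & p <= exons$end)
  if (!in_exon(t$cds_start) || !in_exon(t$cds_end)) {
    stop(transcript_id, ": CDS bound falls outside exons")
  }
  if (cds_length(t) %% 3L != 0L) {
    stop(transcript_id, ": spliced CDS length ", cds_length(t),
         " not divisible by 3")
  }
  t
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("transcript_model", x$transcript_id, "(", x$gene_id, ")", x$chrom,
      x$strand, "\n ", nrow(x$exons), "exon(s), CDS", x$cds_start, "-",
      x$cds_end, "=", cds_length(x), "nt\n")
  invisible(x)
}

#' Coding intervals of a transcript
#'
#' Exon intervals clipped to the CDS bounds, in genomic order.
#' @param t a `transcript_model`.
#' @return Tibble with `start`, `end`.
#' @export
cds_intervals <- function(t) {
  s <- pmax(t$exons$start, t$cds_start)
  e <- pmin(t$exons$end, t$cds_end)
  keep <- s <= e
  tibble::tibble(start = s[keep], end = e[keep])
}

#' @rdname cds_intervals
#' @return `cds_length`: total spliced CDS length in nucleotides.
#' @export
cds_length <- function(t) {
  ivs <- cds_intervals(t)
  sum(ivs$end - ivs$start + 1L)
}

#' Genomic span of a transcript
#' @param t a `transcript_model`.
#' @return Length-2 integer vector (first, last exonic base).
#' @export
transcript_span <- function(t) {
  c(min(t$exons$start), max(t$exons$end))
}

#' Project genomic positions onto spliced CDS coordinates
#'
#' Returns the 1-based position within the spliced coding sequence,
#' counting in translation order (so on the minus strand the coordinate
#' increases toward smaller genomic positions and `cds_end` maps to 1).
#' Intronic, UTR and out-of-transcript positions map to `NA`.
#'
#' @param t a `transcript_model`.
#' @param gpos integer vector of genomic positions.
#' @return Integer vector of CDS positions or `NA`.
#' @export
project_genomic_to_cds <- function(t, gpos) {
  ivs <- cds_intervals(t)
  widths <- ivs$end - ivs$start + 1L
  offsets <- cumsum(c(0L, widths))[seq_len(nrow(ivs))]
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_len(nrow(ivs))) {
    hit <- !is.na(gpos) & gpos >= ivs$start[i] & gpos <= ivs$end[i]
    out[hit] <- offsets[i] + (gpos[hit] - ivs$start[i]) + 1L
  }
  if (t$strand == "-") {
    total <- sum(widths)
    out <- ifelse(is.na(out), NA_integer_, total - out + 1L)
  }
  out
}

#' Inverse of [project_genomic_to_cds()]
#'
#' @param t a `transcript_model`.
#' @param cds_pos integer vector of 1-based spliced CDS positions.
#' @return Integer vector of genomic positions (`NA` outside `1..cds_length`).
#' @export
project_cds_to_genomic <- function(t, cds_pos) {
  total <- cds_length(t)
  p <- as.integer(cds_pos)
  p[!is.na(p) & (p < 1L | p > total)] <- NA_integer_
  if (t$strand == "-") p <- total - p + 1L
  ivs <- cds_intervals(t)
  widths <- ivs$end - ivs$start + 1L
  offsets <- cumsum(c(0L, widths))[seq_len(nrow(ivs))]
  out <- rep(NA_integer_, length(p))
  for (i in seq_len(nrow(ivs))) {
    hit <- !is.na(p) & p > offsets[i] & p <= offsets[i] + widths[i]
    out[hit] <- ivs$start[i] + (p[hit] - offsets[i]) - 1L
  }
  out
}

#' Codon index of a CDS position
#'
#' Standard HGVS-style arithmetic: coding position `c` lies in codon
#' `ceiling(c / 3)`; e.g. c.392 falls in codon 131.
#'
#' @param cds_pos integer vector of 1-based CDS positions.
#' @return Integer vector of codon indices.
#' @export
cds_position_to_codon <- function(cds_pos) {
  if (any(is.na(cds_pos)) || any(cds_pos < 1)) {
    stop("cds_pos must be >= 1")
  }
  as.integer(ceiling(cds_pos / 3))
}

#' Read / write transcript models as TSV
#'
#' Tab-separated, one transcript per row: `transcript_id`, `gene_id`,
#' `chrom`, `strand`, `exon_starts`, `exon_ends` (comma-joined integer
#' lists) and `cds_start`, `cds_end`.
#'
#' @param x path or character lines (reader).
#' @param transcripts named list of `transcript_model` (writer).
#' @param path optional output file.
#' @return Named list of `transcript_model`s; character lines for the writer.
#' @export
read_transcripts <- function(x) {
  lines <- read_text_lines(x)
  df <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                          colClasses = "character")
  out <- lapply(seq_len(nrow(df)), function(i) {
    transcript_model(
      df$transcript_id[i], df$gene_id[i], df$chrom[i], df$strand[i],
      as.integer(strsplit(df$exon_starts[i], ",")[[1]]),
      as.integer(strsplit(df$exon_ends[i], ",")[[1]]),
      as.integer(df$cds_start[i]), as.integer(df$cds_end[i])
    )
  })
  stats::setNames(out, df$transcript_id)
}

#' @rdname read_transcripts
#' @export
write_transcripts <- function(transcripts, path = NULL) {
  lines <- c(
    paste(c("transcript_id", "gene_id", "chrom", "strand", "exon_starts",
            "exon_ends", "cds_start", "cds_end"), collapse = "\t"),
    vapply(transcripts, function(t) {
      paste(t$transcript_id, t$gene_id, t$chrom, t$strand,
            paste(t$exons$start, collapse = ","),
            paste(t$exons$end, collapse = ","),
            t$cds_start, t$cds_end, sep = "\t")
    }, character(1))
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
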