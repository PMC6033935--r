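#' Intron junctions of a transcript
#'
#' One junction per adjacent exon pair: `donor_end` is the last exonic
#' base of the upstream exon and `acceptor_start` the first exonic base
#' of the downstream exon, both as genomic coordinates (left/right in
#' genomic order, whatever the strand). A single-exon transcript has no
#' junctions.
#'
#' @param t a [transcript_model()].
#' @return Tibble `transcript_id`, `chrom`, `donor_end`, `acceptor_start`.
#' @export
junctions_of <- function(t) {
  n <- nrow(t$exons)
  if (n < 2L) {
    return(tibble::tibble(transcript_id = character(0), chrom = character(0),
                          donor_end = integer(0), acceptor_start = integer(0)))
  }
  tibble::tibble(
    transcript_id = t$transcript_id, chrom = t$chrom,
    donor_end = t$exons$end[-n], acceptor_start = t$exons$start[-1]
  )
}

#' Parse a minimal SAM subset
#'
#' Reads gapped alignments from SAM text: QNAME, RNAME, POS and CIGAR are
#' used; FLAG, MAPQ, sequence and qualities are ignored. Header lines
#' (`@...`) and unmapped records (`*` RNAME or CIGAR) are skipped.
#'
#' @param x path to a SAM file or character vector of SAM lines.
#' @return Alignment tibble `read_id`, `chrom`, `pos`, `cigar`.
#' @export
read_sam <- function(x) {
  lines <- read_text_lines(x)
  lines <- lines[!grepl("^@", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(tibble::tibble(read_id = character(0), chrom = character(0),
                          pos = integer(0), cigar = character(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 6L)) stop("malformed SAM line (fewer than 6 fields)")
  aln <- tibble::tibble(
    read_id = vapply(f, `[`, character(1), 1),
    chrom = vapply(f, `[`, character(1), 3),
    pos = as.integer(vapply(f, `[`, character(1), 4)),
    cigar = vapply(f, `[`, character(1), 6)
  )
  aln[aln$chrom != "*" & aln$cigar != "*", ]
}

#' Write alignments as SAM text
#'
#' @param aln alignment tibble (`read_id`, `chrom`, `pos`, `cigar`).
#' @param path optional output file.
#' @param contig_lengths named integer vector for `@SQ` headers; inferred
#'   from the alignments when omitted.
#' @return Character vector of SAM lines (invisibly when `path` given).
#' @export
write_sam <- function(aln, path = NULL, contig_lengths = NULL) {
  if (is.null(contig_lengths)) {
    ends <- vapply(seq_len(nrow(aln)), function(i) {
      b <- alignment_blocks(aln[i, ])[[1]]
      max(IRanges::end(b))
    }, integer(1))
    contig_lengths <- tapply(ends, aln$chrom, max) + 1000L
  }
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
            as.integer(contig_lengths)),
    if (nrow(aln)) {
      paste(aln$read_id, 0L, aln$chrom, aln$pos, 60L, aln$cigar,
            "*", 0L, 0L, "*", "*", sep = "\t")
    }
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Aligned reference blocks of each read
#'
#' CIGAR `N` (skipped intron) splits a read into blocks; `M`/`=`/`X`
#' consume reference, `S`/`I` do not.
#'
#' @param aln alignment tibble.
#' @return `IRangesList`, one element per read, blocks sorted and
#'   non-overlapping.
#' @export
alignment_blocks <- function(aln) {
  GenomicAlignments::extractAlignmentRangesOnReference(aln$cigar,
                                                       pos = aln$pos)
}

#' Count split reads supporting one junction
#'
#' A read supports a junction when two consecutive aligned blocks end
#' exactly at `donor_end` and start exactly at `acceptor_start` (no fuzzy
#' window) with at least `min_overhang` aligned bases on each side.
#' Duplicate `read_id`s are counted once.
#'
#' @param aln alignment tibble ([read_sam()]).
#' @param junction one-row tibble (or list) with `chrom`, `donor_end`,
#'   `acceptor_start`.
#' @param min_overhang minimum aligned bases flanking the junction
#'   (default 3).
#' @return Integer count of supporting reads.
#' @export
count_junction_reads <- function(aln, junction, min_overhang = 3L) {
  stopifnot(min_overhang >= 1L)
  aln <- aln[!duplicated(aln$read_id), ]
  aln <- aln[aln$chrom == junction$chrom, ]
  if (!nrow(aln)) return(0L)
  blocks <- alignment_blocks(aln)
  supports <- vapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    n <- length(b)
    if (n < 2L) return(FALSE)
    s <- IRanges::start(b)
    e <- IRanges::end(b)
    w <- IRanges::width(b)
    any(e[-n] == junction$donor_end &
          s[-1] == junction$acceptor_start &
          w[-n] >= min_overhang & w[-1] >= min_overhang)
  }, logical(1))
  sum(supports)
}

#' Junction support table across isoforms
#'
#' Counts supporting split reads for every junction of every transcript
#' and flags junctions unique to a single isoform (the discriminating
#' junctions whose support evidences that isoform's expression).
#'
#' @param aln alignment tibble.
#' @param transcripts named list of [transcript_model()]s.
#' @param min_overhang see [count_junction_reads()].
#' @return Tibble `transcript_id`, `chrom`, `donor_end`,
#'   `acceptor_start`, `reads`, `discriminating`.
#' @export
isoform_support_table <- function(aln, transcripts, min_overhang = 3L) {
  jn <- dplyr::bind_rows(lapply(transcripts, junctions_of))
  if (!nrow(jn)) {
    return(tibble::tibble(transcript_id = character(0), chrom = character(0),
                          donor_end = integer(0), acceptor_start = integer(0),
                          reads = integer(0), discriminating = logical(0)))
  }
  jkey <- paste(jn$chrom, jn$donor_end, jn$acceptor_start)
  shared <- tapply(jn$transcript_id, jkey, function(x) length(unique(x)))
  jn$discriminating <- as.logical(shared[jkey] == 1L)
  jn$reads <- vapply(seq_len(nrow(jn)), function(i) {
    count_junction_reads(aln, jn[i, ], min_overhang = min_overhang)
  }, integer(1))
  jn[, c("transcript_id", "chrom", "donor_end", "acceptor_start", "reads",
         "discriminating")]
}
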