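#' Multi-sample variant set
#'
#' Container for the sites of a multi-sample VCF. `variants` is a tibble
#' with one row per site (`chrom`, `pos`, `id`, `ref`, `alt`, `info`);
#' `alt` holds the comma-joined ALT alleles until [split_multiallelic()]
#' is applied, and `info` is a list column of named character vectors with
#' the passthrough annotations (population AFs, prediction-score labels).
#' Genotypes live in two integer allele matrices `geno_a` / `geno_b`
#' (site x sample, `NA` = missing allele); genotypes are treated as
#' unphased — phase is re-derived from pedigree logic downstream, never
#' trusted from the caller.
#'
#' All coordinates are 1-based inclusive throughout the package.
#'
#' @param variants tibble as described above.
#' @param geno_a,geno_b integer matrices, one column per sample.
#' @param samples character vector of sample ids (column order).
#' @return A `variant_set`.
#' @export
variant_set <- function(variants, geno_a, geno_b, samples) {
  stopifnot(
    is.data.frame(variants),
    all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
    nrow(variants) == nrow(geno_a), nrow(variants) == nrow(geno_b),
    ncol(geno_a) == length(samples), ncol(geno_b) == length(samples)
  )
  if (!"id" %in% names(variants)) variants$id <- NA_character_
  if (!"info" %in% names(variants)) {
    variants$info <- replicate(nrow(variants), character(0), simplify = FALSE)
  }
  if (nrow(variants) && any(variants$pos < 1)) stop("pos must be >= 1")
  if (nrow(variants) && any(variants$ref == "")) stop("empty REF allele")
  bad <- mapply(function(r, a) any(strsplit(a, ",")[[1]] == r),
                variants$ref, variants$alt)
  if (nrow(variants) && any(bad)) stop("ALT equal to REF at some site")
  colnames(geno_a) <- colnames(geno_b) <- samples
  structure(
    list(variants = tibble::as_tibble(variants), geno_a = geno_a,
         geno_b = geno_b, samples = samples),
    class = "variant_set"
  )
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$variants), "site(s) x", length(x$samples),
      "sample(s)\n")
  print(x$variants[, c("chrom", "pos", "ref", "alt")], n = 10)
  invisible(x)
}

#' Number of sites in a variant set
#' @param vs a `variant_set`.
#' @return Integer count.
#' @export
n_variants <- function(vs) nrow(vs$variants)

#' Canonical variant keys
#'
#' `chrom:pos:ref>alt`, the key used for frequency lookups, reports and
#' truth tables. For unsplit multiallelic sites the comma-joined ALT is used.
#'
#' @param vs a `variant_set` (or a variants tibble).
#' @return Character vector, one key per site.
#' @export
variant_keys <- function(vs) {
  v <- if (inherits(vs, "variant_set")) vs$variants else vs
  if (!nrow(v)) return(character(0))
  paste0(v$chrom, ":", v$pos, ":", v$ref, ">", v$alt)
}

#' Read a multi-sample VCF
#'
#' Parses a VCF 4.x file (via `vcfR`) into a [variant_set()]. INFO
#' key=value annotations are lifted into the `info` list column; flag keys
#' get value `"TRUE"`. Genotype separators `/` and `|` are both accepted
#' and phase is discarded. `./.` (or `.`) becomes a missing genotype.
#'
#' @param x path to a VCF file, or a character vector of VCF lines.
#' @return A `variant_set`.
#' @export
read_vcf <- function(x) {
  lines <- read_text_lines(x)
  tf <- tempfile(fileext = ".vcf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  v <- suppressWarnings(vcfR::read.vcfR(tf, verbose = FALSE))
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) {
    samples <- colnames(v@gt)
    samples <- samples[samples != "FORMAT"]
    if (is.null(samples)) samples <- character(0)
    return(variant_set(
      tibble::tibble(chrom = character(0), pos = integer(0),
                     id = character(0), ref = character(0),
                     alt = character(0), info = list()),
      matrix(NA_integer_, 0, length(samples)),
      matrix(NA_integer_, 0, length(samples)), samples
    ))
  }
  variants <- tibble::tibble(
    chrom = unname(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    id = unname(fix[, "ID"]),
    ref = unname(fix[, "REF"]),
    alt = unname(fix[, "ALT"]),
    info = unname(lapply(fix[, "INFO"], parse_info))
  )
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) {
    samples <- character(0)
    geno_a <- geno_b <- matrix(NA_integer_, nrow(variants), 0)
  } else {
    samples <- colnames(gt)
    al <- parse_gt_matrix(gt)
    geno_a <- al$a
    geno_b <- al$b
  }
  variant_set(variants, geno_a, geno_b, samples)
}

# internal: "0/1"-style matrix -> two integer allele matrices
parse_gt_matrix <- function(gt) {
  parse1 <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(c(NA_integer_, NA_integer_))
    parts <- strsplit(g, "[/|]")[[1]]
    if (length(parts) == 1L) parts <- c(parts, NA_character_)
    suppressWarnings(as.integer(ifelse(parts == ".", NA, parts)))[1:2]
  }
  flat <- vapply(as.vector(gt), parse1, integer(2), USE.NAMES = FALSE)
  a <- matrix(flat[1, ], nrow = nrow(gt), dimnames = dimnames(gt))
  b <- matrix(flat[2, ], nrow = nrow(gt), dimnames = dimnames(gt))
  list(a = a, b = b)
}

# internal: INFO string -> named character vector
parse_info <- function(s) {
  if (is.na(s) || s == "." || s == "") return(character(0))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(
    vapply(kv, function(p) if (length(p) > 1) paste(p[-1], collapse = "=") else "TRUE",
           character(1)),
    vapply(kv, `[`, character(1), 1)
  )
}

#' Write a variant set as VCF text
#'
#' Emits a minimal VCF 4.2 with GT-only FORMAT. `read_vcf(write_vcf(vs))`
#' preserves chrom/pos/ref/alt and genotypes; INFO formatting is
#' canonicalized (key order as stored).
#'
#' @param vs a `variant_set`.
#' @param path optional output file.
#' @return Character vector of VCF lines (invisibly when `path` is given).
#' @export
write_vcf <- function(vs, path = NULL) {
  info_keys <- unique(unlist(lapply(vs$variants$info, names)))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf('##INFO=<ID=%s,Number=.,Type=String,Description="annotation">',
            info_keys),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(vs$samples)) c("FORMAT", vs$samples)), collapse = "\t")
  )
  if (!nrow(vs$variants)) {
    lines <- header
  } else {
    info_str <- vapply(vs$variants$info, function(kv) {
      if (!length(kv)) return(".")
      paste(ifelse(kv == "TRUE", names(kv), paste0(names(kv), "=", kv)),
            collapse = ";")
    }, character(1))
    gt_str <- matrix("./.", nrow(vs$variants), length(vs$samples))
    if (length(vs$samples)) {
      a <- ifelse(is.na(vs$geno_a), ".", vs$geno_a)
      b <- ifelse(is.na(vs$geno_b), ".", vs$geno_b)
      gt_str <- matrix(paste0(a, "/", b), nrow = nrow(vs$variants))
      gt_str[gt_str == "./NA"] <- "./."  # half-calls never serialized wider
    }
    body <- paste(
      vs$variants$chrom, vs$variants$pos,
      ifelse(is.na(vs$variants$id), ".", vs$variants$id),
      vs$variants$ref, vs$variants$alt, ".", "PASS", info_str,
      sep = "\t"
    )
    if (length(vs$samples)) {
      body <- paste(body, "GT", apply(gt_str, 1, paste, collapse = "\t"),
                    sep = "\t")
    }
    lines <- c(header, body)
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Split multiallelic sites into biallelic records
#'
#' Each ALT allele becomes its own record. Genotype allele indices are
#' remapped: the focal ALT becomes 1, REF stays 0, and alleles belonging
#' to *other* ALTs become missing (so a `1/2` genotype splits into two
#' records, each het for its own ALT with the other allele missing).
#' Comma-separated INFO values whose cardinality equals the ALT count are
#' split positionally; all other annotations are copied unchanged.
#'
#' @param vs a `variant_set`.
#' @return A biallelic `variant_set`; total non-missing ALT allele
#'   observations are conserved.
#' @export
split_multiallelic <- function(vs) {
  v <- vs$variants
  if (!nrow(v)) return(vs)
  alts <- strsplit(v$alt, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  out_rows <- list()
  out_a <- list()
  out_b <- list()
  k <- 0L
  for (i in seq_len(nrow(v))) {
    for (j in seq_len(n_alt[i])) {
      k <- k + 1L
      info <- v$info[[i]]
      if (n_alt[i] > 1L && length(info)) {
        info <- vapply(info, function(val) {
          parts <- strsplit(val, ",", fixed = TRUE)[[1]]
          if (length(parts) == n_alt[i]) parts[j] else val
        }, character(1))
      }
      out_rows[[k]] <- tibble::tibble(
        chrom = v$chrom[i], pos = v$pos[i], id = v$id[i],
        ref = v$ref[i], alt = alts[[i]][j], info = list(info)
      )
      remap <- function(al) {
        ifelse(is.na(al), NA_integer_,
               ifelse(al == 0L, 0L, ifelse(al == j, 1L, NA_integer_)))
      }
      out_a[[k]] <- remap(vs$geno_a[i, ])
      out_b[[k]] <- remap(vs$geno_b[i, ])
    }
  }
  variant_set(
    dplyr::bind_rows(out_rows),
    do.call(rbind, out_a), do.call(rbind, out_b),
    vs$samples
  )
}

#' Per-sample zygosity classification
#'
#' Classifies each biallelic genotype by ALT dosage over its non-missing
#' alleles: 0 -> `hom_ref`, 1 -> `het`, 2 -> `hom_alt`; fully missing ->
#' `missing`. A half-call such as `1/.` (produced by multiallelic
#' splitting) counts by its observed allele, so `1/.` is `het`.
#'
#' @param vs a biallelic `variant_set`.
#' @return Character matrix, sites x samples.
#' @export
zygosity_matrix <- function(vs) {
  a <- vs$geno_a
  b <- vs$geno_b
  dose <- ifelse(is.na(a), 0L, (a > 0L) * 1L) + ifelse(is.na(b), 0L, (b > 0L) * 1L)
  z <- matrix(c("hom_ref", "het", "hom_alt")[dose + 1L],
              nrow = nrow(a), dimnames = dimnames(a))
  z[is.na(a) & is.na(b)] <- "missing"
  if (is.null(dim(z))) z <- matrix(z, nrow = nrow(a), dimnames = dimnames(a))
  colnames(z) <- vs$samples
  z
}

#' Subset a variant set
#'
#' @param vs a `variant_set`.
#' @param i integer/logical site index.
#' @return The subsetted `variant_set`.
#' @export
subset_variants <- function(vs, i) {
  variant_set(vs$variants[i, , drop = FALSE],
              vs$geno_a[i, , drop = FALSE],
              vs$geno_b[i, , drop = FALSE],
              vs$samples)
}

#' Read / write a population allele-frequency side table
#'
#' TSV with header `chrom pos ref alt source af`; one row per variant and
#' source (sources emulate reference cohorts such as KG1000 / EVS / ExAC).
#' A variant absent from the table is "not observed" (frequency 0).
#'
#' @param x path or character lines (for `read_frequency_table`).
#' @param freqs tibble with those six columns (for `write_frequency_table`).
#' @param path optional output file.
#' @return Tibble of frequencies; character lines for the writer.
#' @export
read_frequency_table <- function(x) {
  lines <- read_text_lines(x)
  df <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "character",
                                         "character", "character", "numeric"))
  df <- tibble::as_tibble(df)
  stopifnot(identical(names(df), c("chrom", "pos", "ref", "alt", "source", "af")))
  if (any(df$af < 0 | df$af > 1)) stop("allele frequency outside [0, 1]")
  df
}

#' @rdname read_frequency_table
#' @export
write_frequency_table <- function(freqs, path = NULL) {
  lines <- c(paste(c("chrom", "pos", "ref", "alt", "source", "af"),
                   collapse = "\t"),
             if (nrow(freqs)) {
               paste(freqs$chrom, freqs$pos, freqs$ref, freqs$alt,
                     freqs$source, format(freqs$af, scientific = FALSE,
                                          trim = TRUE), sep = "\t")
             })
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
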