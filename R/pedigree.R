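#' Construct a validated pedigree
#'
#' A pedigree is a tibble with one row per individual and columns
#' `family_id`, `individual_id`, `father_id`, `mother_id`, `sex`
#' (`"male"`, `"female"`, `"unknown"`) and `affected` (`"affected"`,
#' `"unaffected"`, `"unknown"`). Missing parents are `NA`. Ids are opaque
#' strings; generation structure is derived only from the parent links.
#'
#' Validation enforces the PED semantics this package relies on:
#' individual ids unique within the family, every non-missing parent
#' reference resolving to a member, parent sex compatible with its role
#' when known, and an acyclic parent graph.
#'
#' @param family_id single family identifier.
#' @param individual_id character vector of member ids.
#' @param father_id,mother_id character vectors; `NA` (or `"0"`) = missing.
#' @param sex character vector in `male`, `female`, `unknown`.
#' @param affected character vector in `affected`, `unaffected`, `unknown`.
#' @return A tibble of class `pedigree`.
#' @examples
#' ped <- pedigree("A",
#'   individual_id = c("I.1", "I.2", "II.1"),
#'   father_id = c(NA, NA, "I.1"), mother_id = c(NA, NA, "I.2"),
#'   sex = c("male", "female", "male"),
#'   affected = c("unaffected", "unaffected", "affected"))
#' affected_members(ped)
#' @export
pedigree <- function(family_id, individual_id, father_id, mother_id, sex,
                     affected) {
  norm_parent <- function(p) {
    p <- as.character(p)
    p[!is.na(p) & p %in% c("0", "")] <- NA_character_
    p
  }
  ped <- tibble::tibble(
    family_id = as.character(family_id),
    individual_id = as.character(individual_id),
    father_id = norm_parent(father_id),
    mother_id = norm_parent(mother_id),
    sex = as.character(sex),
    affected = as.character(affected)
  )
  class(ped) <- c("pedigree", class(tibble::tibble()))
  validate_pedigree(ped)
  ped
}

#' Validate pedigree invariants
#'
#' @param ped a `pedigree`.
#' @return `ped`, invisibly; errors on violation.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped))
  fam <- unique(ped$family_id)
  if (length(fam) != 1L) {
    stop("a pedigree holds exactly one family; got: ",
         paste(fam, collapse = ", "))
  }
  if (anyDuplicated(ped$individual_id)) {
    stop("duplicate individual ids in family ", fam, ": ",
         paste(unique(ped$individual_id[duplicated(ped$individual_id)]),
               collapse = ", "))
  }
  bad_sex <- setdiff(ped$sex, c("male", "female", "unknown"))
  if (length(bad_sex)) stop("invalid sex value: ", paste(bad_sex, collapse = ", "))
  bad_aff <- setdiff(ped$affected, c("affected", "unaffected", "unknown"))
  if (length(bad_aff)) stop("invalid affection value: ", paste(bad_aff, collapse = ", "))
  for (col in c("father_id", "mother_id")) {
    refs <- ped[[col]]
    dangling <- setdiff(refs[!is.na(refs)], ped$individual_id)
    if (length(dangling)) {
      stop("family ", fam, ": ", col, " references unknown individual(s): ",
           paste(dangling, collapse = ", "))
    }
  }
  # parent sex compatibility (only when the parent's sex is known)
  sex_of <- stats::setNames(ped$sex, ped$individual_id)
  f <- ped$father_id[!is.na(ped$father_id)]
  if (any(sex_of[f] == "female")) {
    stop("family ", fam, ": father reference to a female individual")
  }
  m <- ped$mother_id[!is.na(ped$mother_id)]
  if (any(sex_of[m] == "male")) {
    stop("family ", fam, ": mother reference to a male individual")
  }
  # acyclicity: peel individuals whose parents have all been peeled
  remaining <- ped$individual_id
  parents <- stats::setNames(
    lapply(seq_len(nrow(ped)), function(i) {
      stats::na.omit(c(ped$father_id[i], ped$mother_id[i]))
    }),
    ped$individual_id
  )
  repeat {
    peel <- remaining[vapply(remaining, function(id) {
      !any(parents[[id]] %in% remaining)
    }, logical(1))]
    if (!length(peel)) break
    remaining <- setdiff(remaining, peel)
  }
  if (length(remaining)) {
    stop("family ", fam, ": parent graph contains a cycle involving: ",
         paste(remaining, collapse = ", "))
  }
  invisible(ped)
}

#' Parse PED-format pedigrees
#'
#' Reads the de-facto standard 6-column whitespace-delimited PED dialect
#' (family, individual, father, mother, sex, phenotype). `"0"` means a
#' missing parent; sex codes 1 = male, 2 = female, other = unknown;
#' phenotype codes 1 = unaffected, 2 = affected, 0 or -9 = unknown.
#' Extra columns are ignored. Lines starting with `#` and blank lines are
#' skipped.
#'
#' @param x path to a PED file, or a character vector of PED lines
#'   (anything containing a newline, or of length > 1, is treated as content).
#' @return Named list of [pedigree()] objects, one per family, in order of
#'   first appearance.
#' @export
parse_ped <- function(x) {
  lines <- read_text_lines(x)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(stats::setNames(list(), character()))
  fields <- strsplit(trimws(lines), "\\s+")
  nfield <- lengths(fields)
  if (any(nfield < 6L)) {
    bad <- idx[which(nfield < 6L)[1]]
    stop("malformed PED line ", bad, ": fewer than 6 columns")
  }
  mat <- t(vapply(fields, function(f) f[1:6], character(6)))
  df <- tibble::tibble(
    family_id = mat[, 1],
    individual_id = mat[, 2],
    father_id = mat[, 3],
    mother_id = mat[, 4],
    sex = c("1" = "male", "2" = "female")[mat[, 5]],
    affected = c("1" = "unaffected", "2" = "affected")[mat[, 6]]
  )
  df$sex[is.na(df$sex)] <- "unknown"
  df$affected[is.na(df$affected)] <- "unknown"
  fams <- unique(df$family_id)
  out <- lapply(fams, function(fam) {
    sub <- df[df$family_id == fam, ]
    pedigree(fam, sub$individual_id, sub$father_id, sub$mother_id,
             sub$sex, sub$affected)
  })
  stats::setNames(out, fams)
}

#' Write pedigrees in PED format
#'
#' Inverse of [parse_ped()]; `parse_ped(write_ped(peds))` round-trips.
#'
#' @param peds a `pedigree` or list of pedigrees.
#' @param path optional output file; when `NULL` the PED lines are returned.
#' @return Character vector of PED lines (invisibly when `path` is given).
#' @export
write_ped <- function(peds, path = NULL) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  lines <- unlist(lapply(peds, function(ped) {
    sex <- c(male = "1", female = "2", unknown = "0")[ped$sex]
    aff <- c(unaffected = "1", affected = "2", unknown = "0")[ped$affected]
    paste(ped$family_id, ped$individual_id,
          ifelse(is.na(ped$father_id), "0", ped$father_id),
          ifelse(is.na(ped$mother_id), "0", ped$mother_id),
          sex, aff, sep = "\t")
  }), use.names = FALSE)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Members of a pedigree by affection status
#'
#' @param ped a `pedigree`.
#' @return Tibble of the members with the requested status, input order
#'   preserved.
#' @export
affected_members <- function(ped) ped[ped$affected == "affected", ]

#' @rdname affected_members
#' @export
unaffected_members <- function(ped) ped[ped$affected == "unaffected", ]

#' Resolve the parents of an individual
#'
#' @param ped a `pedigree`.
#' @param individual_id member id.
#' @return List with elements `father` and `mother`, each a one-row tibble
#'   or `NULL` when missing. Founders return both `NULL`.
#' @export
parents_of <- function(ped, individual_id) {
  i <- match(individual_id, ped$individual_id)
  if (is.na(i)) {
    stop("no individual '", individual_id, "' in family ", ped$family_id[1])
  }
  get1 <- function(id) {
    if (is.na(id)) NULL else ped[ped$individual_id == id, ]
  }
  list(father = get1(ped$father_id[i]), mother = get1(ped$mother_id[i]))
}

#' Founders of a pedigree
#'
#' Members with neither parent recorded.
#' @param ped a `pedigree`.
#' @return Tibble of founder rows.
#' @export
founders <- function(ped) ped[is.na(ped$father_id) & is.na(ped$mother_id), ]

# internal: accept a path or raw text lines
read_text_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    return(readLines(x))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

# internal: members in an order where parents precede children
topological_order <- function(ped) {
  remaining <- ped$individual_id
  ordered <- character(0)
  parents <- stats::setNames(
    lapply(seq_len(nrow(ped)), function(i) {
      stats::na.omit(c(ped$father_id[i], ped$mother_id[i]))
    }),
    ped$individual_id
  )
  while (length(remaining)) {
    peel <- remaining[vapply(remaining, function(id) {
      !any(parents[[id]] %in% remaining)
    }, logical(1))]
    if (!length(peel)) stop("cycle in pedigree ", ped$family_id[1])
    ordered <- c(ordered, peel)
    remaining <- setdiff(remaining, peel)
  }
  ordered
}
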