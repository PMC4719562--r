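#' Genotype tables
#'
#' The central object of the package is a plain tibble in "wide" genotype
#' layout: one row per individual, a character `individual_id` column, a
#' character `accession_id` column, and one integer column per SNP marker
#' holding the diploid call coded as the dosage of the alternate allele
#' (0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
#' `NA` = missing). Every analysis function in the package consumes and
#' produces this layout, so results chain naturally with the pipe.
#'
#' @name genotype-table
NULL

.RESERVED_COLS <- c("individual_id", "accession_id")

#' Marker identifiers of a genotype table
#'
#' @param g A genotype tibble (see [genotype-table]).
#' @return Character vector of marker column names.
#' @export
marker_ids <- function(g) {
  setdiff(names(g), .RESERVED_COLS)
}

#' Extract the numeric call matrix
#'
#' @param g A genotype tibble.
#' @return Integer matrix (individuals x markers) of alternate-allele
#'   dosages with individual ids as row names.
#' @export
geno_matrix <- function(g) {
  mk <- marker_ids(g)
  m <- as.matrix(as.data.frame(g[, mk, drop = FALSE]))
  storage.mode(m) <- "integer"
  rownames(m) <- g$individual_id
  m
}

#' Validate a genotype table
#'
#' Checks the structural invariants: unique individual and marker ids,
#' every individual mapped to exactly one accession, and calls restricted
#' to dosages 0/1/2 or missing.
#'
#' @param g A data frame in wide genotype layout.
#' @return The input, invisibly, as a tibble; errors describe the first
#'   violated invariant.
#' @export
validate_genotypes <- function(g) {
  g <- tibble::as_tibble(g)
  if (!all(.RESERVED_COLS %in% names(g))) {
    stop("genotype table must have 'individual_id' and 'accession_id' columns",
         call. = FALSE)
  }
  dup_i <- g$individual_id[duplicated(g$individual_id)]
  if (length(dup_i)) {
    stop("duplicated individual id(s): ", paste(unique(dup_i), collapse = ", "),
         call. = FALSE)
  }
  mk <- marker_ids(g)
  dup_m <- mk[duplicated(mk)]
  if (length(dup_m)) {
    stop("duplicated marker id(s): ", paste(unique(dup_m), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(g$accession_id)) {
    stop("every individual must map to an accession", call. = FALSE)
  }
  m <- suppressWarnings(geno_matrix(g))
  bad <- !(is.na(m) | m %in% 0:2)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid call at individual '%s', marker '%s'",
                 g$individual_id[w[1]], mk[w[2]]), call. = FALSE)
  }
  invisible(g)
}

#' Build a genotype table from a call matrix
#'
#' @param calls Integer matrix (individuals x markers), dosage coding.
#' @param accession_of Character vector of accession ids, one per row of
#'   `calls` (recycled if length 1).
#' @param individual_ids,marker_ids Optional id vectors; default to the
#'   dimnames of `calls`.
#' @return Genotype tibble.
#' @export
as_genotypes <- function(calls, accession_of,
                         individual_ids = rownames(calls),
                         marker_ids = colnames(calls)) {
  if (is.null(individual_ids)) individual_ids <- sprintf("I%03d", seq_len(nrow(calls)))
  if (is.null(marker_ids)) marker_ids <- sprintf("M%04d", seq_len(ncol(calls)))
  accession_of <- rep_len(as.character(accession_of), nrow(calls))
  out <- tibble::tibble(individual_id = as.character(individual_ids),
                        accession_id = accession_of)
  cm <- tibble::as_tibble(as.data.frame(calls), .name_repair = "minimal")
  names(cm) <- marker_ids
  out <- dplyr::bind_cols(out, cm)
  validate_genotypes(out)
  out
}

#' Genotype file dialect
#'
#' Declares the four genotype tokens used in a delimited genotype file.
#' The reference allele is, by convention, the first allele of the
#' homozygous-reference token.
#'
#' @param hom_ref,het,hom_alt,missing Tokens for the four call states.
#' @return A named list of class `"genotype_dialect"`.
#' @export
genotype_dialect <- function(hom_ref = "AA", het = "AB", hom_alt = "BB",
                             missing = "NA") {
  tokens <- c(hom_ref = hom_ref, het = het, hom_alt = hom_alt,
              missing = missing)
  if (anyDuplicated(tokens)) stop("dialect tokens must be distinct", call. = FALSE)
  structure(as.list(tokens), class = "genotype_dialect")
}

#' Read a wide genotype TSV
#'
#' Reads the package's wide genotype format: a header line with marker
#' ids, column 1 the individual id, column 2 the accession id, and one
#' token per call as declared by `dialect`. Unknown tokens are rejected.
#'
#' @param path File path.
#' @param dialect A [genotype_dialect()].
#' @return Genotype tibble.
#' @export
read_genotypes <- function(path, dialect = genotype_dialect()) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), name_repair = "minimal",
                         progress = FALSE)
  nm <- names(raw)
  if (length(nm) < 3L || nm[1] != "individual_id" || nm[2] != "accession_id") {
    stop("expected columns: individual_id, accession_id, then marker columns",
         call. = FALSE)
  }
  dup <- nm[duplicated(nm)]
  if (length(dup)) {
    stop("duplicated column(s) in genotype file: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  map <- c(0L, 1L, 2L, NA_integer_)
  names(map) <- unlist(dialect)
  for (j in seq(3L, length(nm))) {
    tok <- raw[[j]]
    unknown <- setdiff(unique(tok), names(map))
    if (length(unknown)) {
      stop(sprintf("unknown genotype token '%s' at marker '%s'",
                   unknown[1], nm[j]), call. = FALSE)
    }
    raw[[j]] <- unname(map[tok])
  }
  validate_genotypes(raw)
  raw
}

#' Write a wide genotype TSV
#'
#' Inverse of [read_genotypes()]: `read_genotypes(write_genotypes(g, p))`
#' returns a table identical to `g`.
#'
#' @param g Genotype tibble.
#' @param path File path.
#' @param dialect A [genotype_dialect()].
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, dialect = genotype_dialect()) {
  validate_genotypes(g)
  tokens <- c(dialect$hom_ref, dialect$het, dialect$hom_alt)
  out <- g
  for (mk in marker_ids(g)) {
    v <- out[[mk]]
    out[[mk]] <- ifelse(is.na(v), dialect$missing, tokens[v + 1L])
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Optional reader for biallelic diploid sites from an (uncompressed or
#' bgzipped) VCF. Sites with more than one ALT allele are rejected. The
#' REF allele is the reference allele of the dosage coding.
#'
#' @param path VCF file path.
#' @param accession_of A data frame with columns `individual_id`,
#'   `accession_id` assigning each VCF sample to an accession.
#' @return Genotype tibble.
#' @export
read_genotypes_vcf <- function(path, accession_of) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the VCF reader requires the 'vcfR' package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    stop(sprintf("marker '%s' has more than 2 alleles", fix[multi, "ID"][1]),
         call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  dos <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = TRUE)
    vapply(a, function(al) {
      if (length(al) != 2L || any(al == ".")) return(NA_integer_)
      sum(as.integer(al))
    }, integer(1))
  }
  calls <- t(apply(gt, 1L, dos))
  colnames(calls) <- colnames(gt)
  rownames(calls) <- ids
  acc <- tibble::as_tibble(accession_of)
  idx <- match(colnames(calls), acc$individual_id)
  if (anyNA(idx)) {
    stop("VCF sample(s) without accession assignment: ",
         paste(colnames(calls)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  as_genotypes(t(calls), accession_of = acc$accession_id[idx],
               individual_ids = colnames(calls), marker_ids = ids)
}

#' Read an accession passport table
#'
#' Expects a TSV with at least `accession_id`; recognised optional
#' columns are `taxon`, `biological_type` (wild/feral/cultivated),
#' `zone`, `latitude`, `longitude`, `growth_habit`, `exclude_flag`.
#'
#' @param path File path.
#' @return Tibble with one row per accession.
#' @export
read_accessions <- function(path) {
  acc <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_accessions(acc)
}

#' Validate an accession passport table
#'
#' @param acc Data frame with at least an `accession_id` column.
#' @return The table as a tibble (invisibly returned and returned).
#' @export
validate_accessions <- function(acc) {
  acc <- tibble::as_tibble(acc)
  if (!"accession_id" %in% names(acc)) {
    stop("accession table must have an 'accession_id' column", call. = FALSE)
  }
  if (anyDuplicated(acc$accession_id)) {
    stop("duplicated accession id(s)", call. = FALSE)
  }
  if ("latitude" %in% names(acc)) {
    bad <- !is.na(acc$latitude) & abs(acc$latitude) > 90
    if (any(bad)) stop("latitude outside [-90, 90]", call. = FALSE)
  }
  if ("longitude" %in% names(acc)) {
    bad <- !is.na(acc$longitude) & abs(acc$longitude) > 180
    if (any(bad)) stop("longitude outside [-180, 180]", call. = FALSE)
  }
  acc
}

#' Read a marker map
#'
#' @param path TSV with columns `marker_id`, `chromosome`, `position_cm`.
#' @return Tibble; markers absent from the map are treated as unmapped by
#'   downstream haplotype-block construction.
#' @export
read_marker_map <- function(path) {
  map <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("marker_id", "chromosome", "position_cm")
  if (!all(need %in% names(map))) {
    stop("marker map needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(map$position_cm < 0, na.rm = TRUE)) {
    stop("map positions must be non-negative", call. = FALSE)
  }
  tibble::as_tibble(map)
}

#' Export genotypes in STRUCTURE input format
#'
#' Writes the two-rows-per-individual integer format consumed by external
#' Bayesian clustering software: column 1 the individual id, column 2 an
#' integer population code derived from the accession id, then one column
#' per marker with allele codes 1 (reference) / 2 (alternate) and -9 for
#' missing. Output bytes are stable for a fixed input.
#'
#' @param g Genotype tibble.
#' @param path Output file path.
#' @param header Write a first line of marker ids (default `TRUE`).
#' @return `path`, invisibly.
#' @export
export_structure <- function(g, path, header = TRUE) {
  validate_genotypes(g)
  m <- geno_matrix(g)
  pop <- as.integer(factor(g$accession_id, levels = unique(g$accession_id)))
  a1 <- ifelse(is.na(m), -9L, ifelse(m == 2L, 2L, 1L))  # first allele copy
  a2 <- ifelse(is.na(m), -9L, ifelse(m >= 1L, 2L, 1L))  # second allele copy
  con <- file(path, open = "wb")
  on.exit(close(con))
  eol <- "\n"
  if (header) {
    writeLines(paste(marker_ids(g), collapse = "\t"), con, sep = eol)
  }
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(g$individual_id[i], pop[i], a1[i, ]), collapse = "\t"),
               con, sep = eol)
    writeLines(paste(c(g$individual_id[i], pop[i], a2[i, ]), collapse = "\t"),
               con, sep = eol)
  }
  invisible(path)
}
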