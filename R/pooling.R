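#' In-silico pooling of accession genotypes
#'
#' Collapses each accession's individuals into a single pooled
#' pseudo-genotype per marker, emulating a pooled-DNA genotyping assay
#' in which every individual contributes equal molar amounts: the allele
#' frequency is computed from the accession's non-missing calls with
#' equal weight per individual; if the frequency of the more common
#' (major) allele is strictly below `cutoff` the pool is scored
#' heterozygous, otherwise homozygous for the major allele. A 50/50 tie
#' is therefore heterozygous. Markers with no calls in an accession stay
#' missing.
#'
#' @param g Genotype tibble (QC'd).
#' @param cutoff Major-allele-frequency threshold in (0.5, 1]
#'   (default 0.75).
#' @return Genotype tibble with one pseudo-individual per accession
#'   (`individual_id == accession_id`); dosage 1 codes the heterozygous
#'   pool, 0/2 the pool homozygous for the reference/alternate allele.
#' @export
pool_genotypes <- function(g, cutoff = 0.75) {
  if (cutoff <= 0.5 || cutoff > 1) stop("cutoff must be in (0.5, 1]", call. = FALSE)
  validate_genotypes(g)
  m <- geno_matrix(g)
  accs <- unique(g$accession_id)
  pooled <- matrix(NA_integer_, length(accs), ncol(m),
                   dimnames = list(accs, colnames(m)))
  for (a in accs) {
    sub <- m[g$accession_id == a, , drop = FALSE]
    n <- colSums(!is.na(sub))
    p_alt <- colSums(sub, na.rm = TRUE) / (2 * n)
    p_major <- pmax(p_alt, 1 - p_alt)
    call <- ifelse(p_major < cutoff, 1L, ifelse(p_alt > 0.5, 2L, 0L))
    call[n == 0L] <- NA_integer_
    pooled[a, ] <- call
  }
  as_genotypes(pooled, accession_of = accs, individual_ids = accs)
}

#' Diversity captured by in-silico pooling
#'
#' Treats each accession's pooled call as one diploid individual and
#' computes the group diversity summary (mode `"pooled_in_silico"`),
#' plus the capture fraction per group: pooled group-total He divided by
#' the un-pooled group-total He. The fraction can exceed 1 when pooling
#' symmetrises skewed within-accession frequencies.
#'
#' @param g Un-pooled genotype tibble.
#' @param pooled Output of [pool_genotypes()] on `g` (computed if
#'   omitted).
#' @param accessions,group_by Grouping as in [summarize_diversity()].
#' @param cutoff Used when `pooled` is omitted.
#' @return Tibble with columns `group`, `mode`, `n_accessions`,
#'   `n_individuals`, `na`, `ho`, `he`, `f`, `capture_fraction` (the
#'   fraction is attached to the pooled rows).
#' @export
pooled_diversity <- function(g, pooled = NULL, accessions = NULL,
                             group_by = NULL, cutoff = 0.75) {
  if (is.null(pooled)) pooled <- pool_genotypes(g, cutoff)
  total <- summarize_diversity(g, accessions, group_by, mode = "group_total")
  pl <- summarize_diversity(pooled, accessions, group_by, mode = "group_total")
  pl$mode <- "pooled_in_silico"
  if (any(total$he == 0, na.rm = TRUE)) {
    stop("group with zero total He: capture fraction undefined", call. = FALSE)
  }
  pl$capture_fraction <- pl$he / total$he[match(pl$group, total$group)]
  total$capture_fraction <- NA_real_
  dplyr::bind_rows(pl, total)
}

#' @rdname pool_genotypes
#' @param pooled Pooled genotype tibble.
#' @param path Output path.
#' @export
export_pooled_structure <- function(pooled, path) {
  export_structure(pooled, path)
}
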