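#' Accession allele-frequency matrix
#'
#' Alternate-allele frequency per accession at each marker (equal weight
#' per individual, missing calls excluded).
#'
#' @param g Genotype tibble.
#' @return Numeric matrix accessions x markers; `NA` where an accession
#'   has no calls at a marker.
#' @export
accession_freq_matrix <- function(g) {
  validate_genotypes(g)
  m <- geno_matrix(g)
  accs <- unique(g$accession_id)
  out <- matrix(NA_real_, length(accs), ncol(m),
                dimnames = list(accs, colnames(m)))
  for (a in accs) {
    sub <- m[g$accession_id == a, , drop = FALSE]
    out[a, ] <- colSums(sub, na.rm = TRUE) / (2 * colSums(!is.na(sub)))
  }
  out
}

# Column-centred SVD with a deterministic sign convention: within each
# component the loading of largest magnitude is made positive.
.pca_core <- function(x, level, coding) {
  centers <- colMeans(x)
  xc <- sweep(x, 2L, centers)
  sv <- svd(xc)
  d <- sv$d
  scores <- sv$u %*% diag(d, nrow = length(d))
  load <- sv$v
  for (j in seq_along(d)) {
    i_star <- which.max(abs(load[, j]))
    if (load[i_star, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  var_comp <- d^2 / (nrow(x) - 1)
  colnames(scores) <- paste0("PC", seq_along(d))
  coords <- tibble::as_tibble(scores)
  coords <- dplyr::bind_cols(tibble::tibble(entity = rownames(x)), coords)
  structure(list(coords = coords, var = var_comp,
                 var_explained = if (sum(var_comp) > 0) var_comp / sum(var_comp)
                                 else rep(0, length(var_comp)),
                 centers = centers, level = level, coding = coding),
            class = "accdiv_pca")
}

#' PCA of accession allele frequencies
#'
#' Principal component analysis of the accessions x markers
#' allele-frequency matrix: columns are centred but not scaled, and the
#' decomposition is by singular values. Markers undefined (no calls) in
#' any accession are dropped first. The sign of each component is fixed
#' deterministically (largest-magnitude loading positive).
#'
#' @param g Genotype tibble.
#' @return Object of class `"accdiv_pca"`; `tidy()` returns the
#'   coordinates, `glance()` the explained-variance table,
#'   `autoplot()` a PC1/PC2 scatter.
#' @export
pca_accessions <- function(g) {
  fq <- accession_freq_matrix(g)
  if (nrow(fq) < 2L) stop("need at least 2 accessions", call. = FALSE)
  keep <- colSums(is.na(fq)) == 0L
  fq <- fq[, keep, drop = FALSE]
  .pca_core(fq, level = "accession", coding = "allele_frequency")
}

#' PCA of individual genotypes
#'
#' PCA of the individuals x markers dosage matrix (0/1/2), with missing
#' calls imputed by the locus mean, columns centred, unscaled, all
#' components retained. Errors if some locus has no calls at all among
#' the selected individuals.
#'
#' @param g Genotype tibble.
#' @param individuals Optional subset of individuals.
#' @return `"accdiv_pca"` object (entities are individuals).
#' @export
pca_individuals <- function(g, individuals = NULL) {
  m <- .subset_matrix(g, individuals)
  if (nrow(m) < 2L) stop("need at least 2 individuals", call. = FALSE)
  n_calls <- colSums(!is.na(m))
  if (any(n_calls == 0L)) {
    stop("locus with all calls missing among the selected individuals: ",
         colnames(m)[which(n_calls == 0L)[1]], call. = FALSE)
  }
  storage.mode(m) <- "double"
  mu <- colMeans(m, na.rm = TRUE)
  for (j in which(colSums(is.na(m)) > 0L)) m[is.na(m[, j]), j] <- mu[j]
  .pca_core(m, level = "individual", coding = "dosage_012_mean_imputed")
}

#' @export
print.accdiv_pca <- function(x, ...) {
  cat(sprintf("PCA (%s level, %d entities, %d components)\n",
              x$level, nrow(x$coords), length(x$var)))
  ve <- round(100 * x$var_explained[seq_len(min(5, length(x$var)))], 1)
  cat("  variance explained (%):", paste(ve, collapse = ", "), "...\n")
  invisible(x)
}

#' @rdname pca_accessions
#' @param x An `accdiv_pca` object.
#' @param ... Unused.
#' @export
tidy.accdiv_pca <- function(x, ...) x$coords

#' @rdname pca_accessions
#' @export
glance.accdiv_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$var), variance = x$var,
                 var_explained = x$var_explained)
}

#' @rdname pca_accessions
#' @param object,colour_by Plotting: `colour_by` is an optional tibble
#'   (`entity`, `group`) used to colour points.
#' @export
autoplot.accdiv_pca <- function(object, colour_by = NULL, ...) {
  d <- object$coords
  pct <- round(100 * object$var_explained[1:2], 1)
  p <- if (!is.null(colour_by)) {
    d <- dplyr::left_join(d, tibble::as_tibble(colour_by), by = "entity")
    ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2,
                                    colour = .data$group))
  } else {
    ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pct[1]),
                  y = sprintf("PC2 (%.1f%%)", pct[2])) +
    ggplot2::theme_minimal()
}

#' Within-accession PC dispersion
#'
#' For each accession with at least two individuals in an
#' individual-level PCA, the mean and variance of all pairwise Euclidean
#' distances in the full PC space (all components). Because the PC
#' rotation is orthogonal, these equal the pairwise distances in the
#' centred, mean-imputed genotype space. The variance uses the
#' population formula (divide by the number of pairs). Accessions with
#' fewer than two individuals are skipped with a message.
#'
#' @param pca An individual-level `"accdiv_pca"`.
#' @param accession_of Tibble (`individual_id`, `accession_id`) mapping
#'   the PCA entities to accessions (e.g. the genotype tibble itself).
#' @return Tibble: `accession_id`, `n`, `mean_dist`, `var_dist`.
#' @export
pc_dispersion <- function(pca, accession_of) {
  stopifnot(inherits(pca, "accdiv_pca"))
  map <- tibble::as_tibble(accession_of)[, c("individual_id", "accession_id")]
  coords <- as.matrix(pca$coords[, -1, drop = FALSE])
  rownames(coords) <- pca$coords$entity
  acc <- map$accession_id[match(rownames(coords), map$individual_id)]
  if (anyNA(acc)) stop("PCA entities missing from accession map", call. = FALSE)
  skipped <- character()
  out <- purrr::map_dfr(split(seq_along(acc), acc), function(idx) {
    a <- acc[idx[1]]
    if (length(idx) < 2L) {
      skipped <<- c(skipped, a)
      return(tibble::tibble())
    }
    d <- stats::dist(coords[idx, , drop = FALSE])
    v <- as.numeric(d)
    tibble::tibble(accession_id = a, n = length(idx),
                   mean_dist = mean(v),
                   var_dist = mean((v - mean(v))^2))
  })
  if (length(skipped)) {
    message("skipped accession(s) with < 2 individuals: ",
            paste(skipped, collapse = ", "))
  }
  out
}

#' Flag near-identical individuals within accessions
#'
#' Computes the identity-by-state proportion (fraction of identical
#' calls over shared called loci) for every within-accession pair and
#' flags pairs at or above the threshold. Highly similar pairs inflate
#' the variance of PC dispersion and deflate within-accession diversity;
#' they typically arise from sibs or accidentally re-sampled clones.
#'
#' @param g Genotype tibble.
#' @param threshold IBS proportion at or above which a pair is flagged
#'   (default 0.99; must be in (0, 1]).
#' @param min_shared Minimum shared called loci for a pair to be
#'   assessed (default 100).
#' @return Tibble: `accession_id`, `id1`, `id2`, `ibs`, `n_shared`.
#' @export
flag_near_identical <- function(g, threshold = 0.99, min_shared = 100L) {
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  validate_genotypes(g)
  m <- geno_matrix(g)
  proto <- tibble::tibble(accession_id = character(), id1 = character(),
                          id2 = character(), ibs = numeric(),
                          n_shared = integer())
  found <- purrr::map_dfr(split(seq_len(nrow(g)), g$accession_id), function(idx) {
    if (length(idx) < 2L) return(tibble::tibble())
    rows <- list()
    for (i in seq_len(length(idx) - 1L)) {
      for (j in seq(i + 1L, length(idx))) {
        xi <- m[idx[i], ]
        xj <- m[idx[j], ]
        ok <- !is.na(xi) & !is.na(xj)
        if (sum(ok) < min_shared) next
        ibs <- mean(xi[ok] == xj[ok])
        if (ibs >= threshold) {
          ids <- sort(c(g$individual_id[idx[i]], g$individual_id[idx[j]]))
          rows[[length(rows) + 1L]] <- tibble::tibble(
            accession_id = g$accession_id[idx[i]],
            id1 = ids[1], id2 = ids[2],
            ibs = ibs, n_shared = sum(ok))
        }
      }
    }
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(proto, found)
}

#' Drop one member of each flagged near-identical pair
#'
#' Deterministic exclusion helper: keeps the lexicographically first id
#' of each flagged pair and drops the other, so diversity and FST can be
#' re-derived on the de-duplicated panel and compared with the original.
#'
#' @param g Genotype tibble.
#' @param flags Output of [flag_near_identical()].
#' @return The filtered genotype tibble.
#' @export
drop_near_identical <- function(g, flags) {
  if (!nrow(flags)) return(g)
  g[!g$individual_id %in% unique(flags$id2), , drop = FALSE]
}

#' Diversity impact of removing near-identical individuals
#'
#' Re-runs the group diversity summary with flagged duplicates removed
#' and returns both versions side by side.
#'
#' @param g Genotype tibble.
#' @param flags Output of [flag_near_identical()].
#' @inheritParams summarize_diversity
#' @return Tibble with a `panel` column (`"all"` / `"deduplicated"`).
#' @export
duplicate_impact <- function(g, flags, accessions = NULL, group_by = NULL) {
  before <- summarize_diversity(g, accessions, group_by)
  after <- summarize_diversity(drop_near_identical(g, flags), accessions,
                               group_by)
  dplyr::bind_rows(dplyr::mutate(before, panel = "all"),
                   dplyr::mutate(after, panel = "deduplicated"))
}
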