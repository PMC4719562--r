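#' QC thresholds
#'
#' Bundles the quality-control filtering rules applied by [apply_qc()].
#' Defaults follow common genebank SNP-panel practice: markers failing in
#' more than half the individuals and monomorphic markers are dropped,
#' individuals with no calls or more than half missing are dropped, and
#' accessions are required to retain at least four genotyped individuals.
#'
#' @param marker_missing_frac_max Drop markers whose missing fraction is
#'   strictly greater than this (default 0.5).
#' @param drop_monomorphic Drop markers with a single observed allele
#'   (default `TRUE`).
#' @param individual_missing_frac_max Drop individuals whose missing
#'   fraction is strictly greater than this (default 0.5).
#' @param accession_min_individuals Minimum retained individuals per
#'   accession (default 4).
#' @param exclude_accessions,exclude_individuals Manual exclusion lists.
#' @param recheck_monomorphic Re-run the monomorphism filter after
#'   individual-level filtering (default `FALSE`; marker filters are
#'   evaluated once, on the full individual set, before individuals are
#'   touched).
#' @return List of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(marker_missing_frac_max = 0.5,
                          drop_monomorphic = TRUE,
                          individual_missing_frac_max = 0.5,
                          accession_min_individuals = 4L,
                          exclude_accessions = character(),
                          exclude_individuals = character(),
                          recheck_monomorphic = FALSE) {
  stopifnot(marker_missing_frac_max >= 0, marker_missing_frac_max <= 1,
            individual_missing_frac_max >= 0, individual_missing_frac_max <= 1,
            accession_min_individuals >= 1)
  structure(list(marker_missing_frac_max = marker_missing_frac_max,
                 drop_monomorphic = drop_monomorphic,
                 individual_missing_frac_max = individual_missing_frac_max,
                 accession_min_individuals = as.integer(accession_min_individuals),
                 exclude_accessions = exclude_accessions,
                 exclude_individuals = exclude_individuals,
                 recheck_monomorphic = recheck_monomorphic),
            class = "qc_thresholds")
}

.is_monomorphic <- function(col) {
  x <- col[!is.na(col)]
  if (!length(x)) return(FALSE)       # all-missing handled by its own rule
  !(any(x >= 1L) && any(x <= 1L))     # alt allele present and ref allele present
}

#' Apply the QC filtering cascade
#'
#' Filters are applied in a fixed order: (1) markers with no calls at
#' all; (2) markers with missing fraction above the cap; (3) monomorphic
#' markers (evaluated on the individual set present at that point);
#' (4) individuals with zero calls on the retained markers;
#' (5) individuals above the missing-fraction cap; (6) accessions left
#' with fewer than the minimum number of individuals; (7) manual
#' exclusions. The per-rule removal counts always add up to the input
#' minus the output, for markers and for individuals.
#'
#' @param g Genotype tibble.
#' @param thresholds A [qc_thresholds()] object.
#' @return A list of class `"qc_result"` with elements `genotypes` (the
#'   filtered tibble) and `report` (per-rule tibble of removal counts and
#'   ids). `tidy()` on the result returns the report.
#' @export
apply_qc <- function(g, thresholds = qc_thresholds()) {
  validate_genotypes(g)
  t <- thresholds
  n_mk_in <- length(marker_ids(g))
  n_ind_in <- nrow(g)
  n_acc_in <- dplyr::n_distinct(g$accession_id)
  report <- list()
  note <- function(rule, markers = character(), individuals = character(),
                   accessions = character()) {
    report[[length(report) + 1L]] <<- tibble::tibble(
      rule = rule,
      n_markers = length(markers), n_individuals = length(individuals),
      n_accessions = length(accessions),
      marker_ids = list(markers), individual_ids = list(individuals),
      accession_ids = list(accessions))
  }
  drop_markers <- function(g, mk) g[, setdiff(names(g), mk), drop = FALSE]

  # (1) markers that produced no genotype at all
  m <- geno_matrix(g)
  all_miss <- colnames(m)[colSums(!is.na(m)) == 0L]
  note("marker_all_missing", markers = all_miss)
  g <- drop_markers(g, all_miss)

  # (2) markers failing in more than the allowed fraction of individuals
  m <- geno_matrix(g)
  frac <- colMeans(is.na(m))
  high <- colnames(m)[frac > t$marker_missing_frac_max]
  note("marker_high_missing", markers = high)
  g <- drop_markers(g, high)

  # (3) monomorphic markers
  if (t$drop_monomorphic) {
    m <- geno_matrix(g)
    mono <- colnames(m)[apply(m, 2L, .is_monomorphic)]
    note("marker_monomorphic", markers = mono)
    g <- drop_markers(g, mono)
  } else {
    note("marker_monomorphic")
  }

  # (4) individuals with no calls on the retained markers
  m <- geno_matrix(g)
  zero <- g$individual_id[rowSums(!is.na(m)) == 0L]
  note("individual_all_missing", individuals = zero)
  g <- g[!g$individual_id %in% zero, , drop = FALSE]

  # (5) individuals above the missing-fraction cap
  m <- geno_matrix(g)
  imiss <- g$individual_id[rowMeans(is.na(m)) > t$individual_missing_frac_max]
  note("individual_high_missing", individuals = imiss)
  g <- g[!g$individual_id %in% imiss, , drop = FALSE]

  # (6) accessions with too few remaining individuals
  cnt <- table(g$accession_id)
  small <- names(cnt)[cnt < t$accession_min_individuals]
  small_ind <- g$individual_id[g$accession_id %in% small]
  note("accession_too_small", individuals = small_ind, accessions = small)
  g <- g[!g$accession_id %in% small, , drop = FALSE]

  # (7) manual exclusions
  man_ind <- unique(c(t$exclude_individuals,
                      g$individual_id[g$accession_id %in% t$exclude_accessions]))
  man_ind <- intersect(man_ind, g$individual_id)
  man_acc <- intersect(t$exclude_accessions, g$accession_id)
  note("manual_exclusion", individuals = man_ind, accessions = man_acc)
  g <- g[!g$individual_id %in% man_ind, , drop = FALSE]

  if (isTRUE(t$recheck_monomorphic)) {
    m <- geno_matrix(g)
    mono2 <- colnames(m)[apply(m, 2L, .is_monomorphic)]
    note("marker_monomorphic_recheck", markers = mono2)
    g <- drop_markers(g, mono2)
  }

  if (!nrow(g) || !length(marker_ids(g))) {
    stop("QC filtering removed every ", if (!nrow(g)) "individual" else "marker",
         "; relax the thresholds", call. = FALSE)
  }
  report <- dplyr::bind_rows(report)
  res <- list(genotypes = g, report = report,
              thresholds = t,
              input = c(markers = n_mk_in, individuals = n_ind_in,
                        accessions = n_acc_in),
              retained = c(markers = length(marker_ids(g)),
                           individuals = nrow(g),
                           accessions = dplyr::n_distinct(g$accession_id)))
  class(res) <- "qc_result"
  res
}

#' @export
print.qc_result <- function(x, ...) {
  cat("SNP panel QC\n")
  cat(sprintf("  markers:     %d -> %d\n", x$input["markers"], x$retained["markers"]))
  cat(sprintf("  individuals: %d -> %d\n", x$input["individuals"], x$retained["individuals"]))
  cat(sprintf("  accessions:  %d -> %d\n", x$input["accessions"], x$retained["accessions"]))
  rep <- x$report[x$report$n_markers + x$report$n_individuals + x$report$n_accessions > 0, ]
  if (nrow(rep)) {
    for (i in seq_len(nrow(rep))) {
      cat(sprintf("  - %s: %d markers, %d individuals, %d accessions\n",
                  rep$rule[i], rep$n_markers[i], rep$n_individuals[i],
                  rep$n_accessions[i]))
    }
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname apply_qc
#' @param x A `qc_result`.
#' @param ... Unused.
#' @export
tidy.qc_result <- function(x, ...) {
  x$report[, c("rule", "n_markers", "n_individuals", "n_accessions")]
}

#' @rdname apply_qc
#' @export
glance.qc_result <- function(x, ...) {
  tibble::tibble(markers_in = x$input[["markers"]],
                 markers_retained = x$retained[["markers"]],
                 individuals_in = x$input[["individuals"]],
                 individuals_retained = x$retained[["individuals"]],
                 accessions_in = x$input[["accessions"]],
                 accessions_retained = x$retained[["accessions"]])
}
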