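#' Per-marker allele frequencies
#'
#' Reference-allele frequency per marker over a set of individuals,
#' `p = (2 * hom_ref + het) / (2 * n_calls)`; missing calls are excluded.
#' Markers with no calls get `p = NA`.
#'
#' @param g Genotype tibble.
#' @param individuals Optional character vector restricting the
#'   computation to a subset of individuals (default: all).
#' @return Tibble with `marker_id`, `n_calls`, `p`.
#' @export
allele_freqs <- function(g, individuals = NULL) {
  m <- .subset_matrix(g, individuals)
  n <- unname(colSums(!is.na(m)))
  p <- 1 - unname(colSums(m, na.rm = TRUE)) / (2 * n)
  p[n == 0L] <- NA_real_
  tibble::tibble(marker_id = colnames(m), n_calls = as.integer(n), p = p)
}

.subset_matrix <- function(g, individuals = NULL) {
  if (!is.null(individuals)) {
    if (!length(individuals)) stop("empty individual set", call. = FALSE)
    missing_ids <- setdiff(individuals, g$individual_id)
    if (length(missing_ids)) {
      stop("unknown individual id(s): ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
    }
    g <- g[g$individual_id %in% individuals, , drop = FALSE]
  }
  geno_matrix(g)
}

.locus_stats_matrix <- function(m) {
  n <- unname(colSums(!is.na(m)))
  p <- 1 - unname(colSums(m, na.rm = TRUE)) / (2 * n)
  p[n == 0L] <- NA_real_
  ho <- unname(colSums(m == 1L, na.rm = TRUE)) / n
  ho[n == 0L] <- NA_real_
  he <- 2 * p * (1 - p)
  na <- (p > 0) + (p < 1)
  f <- ifelse(!is.na(he) & he > 0, (he - ho) / he, NA_real_)
  tibble::tibble(marker_id = colnames(m), n_calls = as.integer(n),
                 p = p, na = as.integer(na), ho = ho, he = he, f = f)
}

#' Per-locus diversity statistics
#'
#' For each marker over a set of individuals: reference-allele frequency
#' `p`, observed allele count `Na` (1 or 2), observed heterozygosity
#' `Ho = het / n_calls`, expected heterozygosity (gene diversity)
#' `He = 1 - p^2 - (1-p)^2 = 2p(1-p)` (unadjusted, i.e. not the
#' small-sample-unbiased variant), and fixation index
#' `F = (He - Ho) / He`, undefined (`NA`) at loci with `He = 0`.
#'
#' @inheritParams allele_freqs
#' @param unbiased If `TRUE`, multiply `He` by `2n/(2n - 1)` (Nei's
#'   small-sample correction on `2n` sampled allele copies). Default
#'   `FALSE`.
#' @return Tibble with one row per marker.
#' @export
locus_stats <- function(g, individuals = NULL, unbiased = FALSE) {
  m <- .subset_matrix(g, individuals)
  st <- .locus_stats_matrix(m)
  if (unbiased) {
    adj <- ifelse(st$n_calls > 0L,
                  2 * st$n_calls / (2 * st$n_calls - 1L), NA_real_)
    st$he <- st$he * adj
    st$f <- ifelse(!is.na(st$he) & st$he > 0, (st$he - st$ho) / st$he, NA_real_)
  }
  st
}

.mean_locus_stats <- function(st) {
  c(na = mean(st$na[st$n_calls > 0], na.rm = TRUE),
    ho = mean(st$ho, na.rm = TRUE),
    he = mean(st$he, na.rm = TRUE),
    f = if (any(!is.na(st$f))) mean(st$f, na.rm = TRUE) else NA_real_)
}

#' Per-accession diversity
#'
#' Mean Na/Ho/He/F across loci for each accession. Loci that are
#' monomorphic within the accession contribute `He = 0` to the mean but
#' are excluded from mean `F` (where F is undefined).
#'
#' @inheritParams locus_stats
#' @return Tibble with one row per accession.
#' @export
accession_diversity <- function(g, unbiased = FALSE) {
  validate_genotypes(g)
  g |>
    dplyr::group_by(.data$accession_id) |>
    dplyr::group_modify(function(rows, key) {
      rows$accession_id <- key$accession_id
      st <- locus_stats(rows, unbiased = unbiased)
      v <- .mean_locus_stats(st)
      tibble::tibble(n_individuals = nrow(rows), na = unname(v["na"]),
                     ho = unname(v["ho"]), he = unname(v["he"]),
                     f = unname(v["f"]))
    }) |>
    dplyr::ungroup()
}

.grouping_table <- function(g, accessions = NULL, group_by = NULL) {
  acc_ids <- unique(g$accession_id)
  if (is.null(group_by)) {
    return(tibble::tibble(accession_id = acc_ids, group = "all"))
  }
  if (is.null(accessions)) {
    stop("grouping by '", group_by, "' requires an accession table", call. = FALSE)
  }
  accessions <- validate_accessions(accessions)
  if (!group_by %in% names(accessions)) {
    stop("no column '", group_by, "' in the accession table", call. = FALSE)
  }
  out <- tibble::tibble(accession_id = acc_ids,
                        group = as.character(accessions[[group_by]][
                          match(acc_ids, accessions$accession_id)]))
  out[!is.na(out$group), , drop = FALSE]
}

#' Group-level diversity summary
#'
#' Summarises diversity per group of accessions in two modes mirroring
#' the usual genebank reporting layout: `"within_accession_mean"` is the
#' unweighted mean over accessions of accession-level locus-mean
#' statistics; `"group_total"` recomputes locus statistics from all the
#' group's individuals pooled. For in-silico pooled summaries see
#' [pooled_diversity()].
#'
#' @param g Genotype tibble.
#' @param accessions Optional accession passport tibble (needed when
#'   `group_by` is given).
#' @param group_by Name of a grouping column in `accessions` (for example
#'   `"taxon"`, `"biological_type"`, `"zone"`); `NULL` summarises the
#'   whole panel as one group. Accessions with `NA` in the grouping
#'   column are dropped from the summary.
#' @param mode Character vector of modes to compute.
#' @param unbiased Use the small-sample-corrected He.
#' @return Tibble with columns `group`, `mode`, `n_accessions`,
#'   `n_individuals`, `na`, `ho`, `he`, `f`.
#' @export
summarize_diversity <- function(g, accessions = NULL, group_by = NULL,
                                mode = c("within_accession_mean", "group_total"),
                                unbiased = FALSE) {
  validate_genotypes(g)
  mode <- match.arg(mode, several.ok = TRUE)
  grouping <- .grouping_table(g, accessions, group_by)
  acc_div <- if ("within_accession_mean" %in% mode) {
    accession_diversity(g, unbiased = unbiased)
  }
  purrr::map_dfr(split(grouping$accession_id, grouping$group), function(accs) {
    members <- g$individual_id[g$accession_id %in% accs]
    if (!length(accs)) stop("group with zero accessions", call. = FALSE)
    rows <- list()
    if ("within_accession_mean" %in% mode) {
      a <- acc_div[acc_div$accession_id %in% accs, , drop = FALSE]
      rows$within <- tibble::tibble(
        mode = "within_accession_mean",
        n_accessions = length(accs), n_individuals = length(members),
        na = mean(a$na), ho = mean(a$ho), he = mean(a$he),
        f = mean(a$f, na.rm = TRUE))
    }
    if ("group_total" %in% mode) {
      st <- locus_stats(g, individuals = members, unbiased = unbiased)
      v <- .mean_locus_stats(st)
      rows$total <- tibble::tibble(
        mode = "group_total",
        n_accessions = length(accs), n_individuals = length(members),
        na = unname(v["na"]), ho = unname(v["ho"]), he = unname(v["he"]),
        f = unname(v["f"]))
    }
    dplyr::bind_rows(rows)
  }, .id = "group") |>
    tibble::as_tibble()
}

#' Minor-allele-frequency spectrum with its neutral expectation
#'
#' Histogram of minor-allele frequencies over polymorphic markers,
#' together with the expected counts under the folded neutral site
#' frequency spectrum for a haploid sample of size `m`: class `i`
#' (`i = 1 .. floor(m/2)`) has weight proportional to
#' `(1/i + 1/(m-i)) / (1 + [i == m-i])`. `m` is taken as the median over
#' markers of twice the number of non-missing individuals, rounded down
#' to an even number. A deficit of observed low-frequency classes
#' relative to the expectation is the classic footprint of SNP
#' ascertainment bias.
#'
#' @inheritParams allele_freqs
#' @param n_bins Number of equal-width frequency bins on (0, 0.5].
#' @return List of class `"maf_spectrum"`: `bins` tibble
#'   (`bin_lo`, `bin_hi`, `observed`, `expected`), `m`, `n_polymorphic`.
#' @export
maf_spectrum <- function(g, individuals = NULL, n_bins = 10L) {
  fr <- allele_freqs(g, individuals)
  m_hap <- stats::median(2 * fr$n_calls[fr$n_calls > 0])
  m_hap <- 2 * floor(m_hap / 2)
  if (is.na(m_hap) || m_hap < 2) stop("haploid sample size below 2", call. = FALSE)
  maf <- pmin(fr$p, 1 - fr$p)
  maf <- maf[!is.na(maf) & maf > 0]
  breaks <- seq(0, 0.5, length.out = n_bins + 1L)
  obs <- as.integer(table(cut(maf, breaks = breaks, include.lowest = FALSE)))
  i <- seq_len(floor(m_hap / 2))
  w <- (1 / i + 1 / (m_hap - i)) / (1 + (i == m_hap - i))
  w <- w / sum(w)
  cls_bin <- cut(i / m_hap, breaks = breaks, include.lowest = FALSE)
  expd <- vapply(levels(cls_bin),
                 function(lv) sum(w[cls_bin == lv]), numeric(1)) * length(maf)
  bins <- tibble::tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                         observed = obs, expected = unname(expd))
  structure(list(bins = bins, m = m_hap, n_polymorphic = length(maf)),
            class = "maf_spectrum")
}

#' @export
print.maf_spectrum <- function(x, ...) {
  cat(sprintf("MAF spectrum: %d polymorphic markers, haploid sample size m = %d\n",
              x$n_polymorphic, x$m))
  print(x$bins)
  invisible(x)
}

#' @rdname maf_spectrum
#' @param object,... Passed from the `autoplot` generic.
#' @export
autoplot.maf_spectrum <- function(object, ...) {
  d <- tidyr::pivot_longer(object$bins, c("observed", "expected"),
                           names_to = "series", values_to = "count")
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                  y = .data$count, fill = .data$series)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "minor allele frequency", y = "markers",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
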