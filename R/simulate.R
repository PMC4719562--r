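#' Simulation configuration
#'
#' Parameters of the hierarchical Balding-Nichols panel generator.
#' Defaults emulate a genebank SNP panel of modest size: 3 genetic
#' clusters of 8 accessions with 6 individuals each, 600 biallelic
#' markers, weak among-cluster differentiation (F_CT = 0.03) and
#' moderate among-accession differentiation within clusters
#' (F_SC = 0.10), no inbreeding, common ancestral allele frequencies
#' (array SNPs are pre-selected to be common), a 4% missing-call rate,
#' 7 chromosomes and European-range accession coordinates.
#'
#' @param n_clusters,accessions_per_cluster,individuals_per_accession
#'   Panel shape.
#' @param n_markers Markers retained (post-ascertainment if enabled).
#' @param f_ct Among-cluster fixation index in \[0, 0.99\].
#' @param f_sc Among-accession-within-cluster fixation index.
#' @param f_is Within-individual inbreeding coefficient.
#' @param ancestral_freq_law `"uniform"` or `"neutral_sfs"` (folded,
#'   truncated to `ancestral_lo`..`ancestral_hi`).
#' @param ancestral_lo,ancestral_hi Ancestral frequency bounds.
#' @param ascertainment List: `enabled`, `discovery_clusters` (cluster
#'   indices supplying the discovery panel), `discovery_n` (individuals
#'   sampled for discovery), `min_minor_copies` (minimum minor-allele
#'   copies in the discovery sample for a candidate SNP to be kept).
#' @param missing_rate Missing-call probability, scalar or one value per
#'   cluster.
#' @param clone_spec Optional list of `list(accession=, n_clones=,
#'   error_rate=)` entries appending near-identical copies of the
#'   accession's first individual.
#' @param map_spec List: `n_chromosomes`, `cm_max`.
#' @param coord_spec List: `centroids` (matrix of lat/lon rows, one per
#'   cluster) and `jitter_sd` in degrees.
#' @param seed Mandatory integer seed.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_clusters = 3L, accessions_per_cluster = 8L,
                       individuals_per_accession = 6L, n_markers = 600L,
                       f_ct = 0.03, f_sc = 0.10, f_is = 0,
                       ancestral_freq_law = c("uniform", "neutral_sfs"),
                       ancestral_lo = 0.1, ancestral_hi = 0.9,
                       ascertainment = list(enabled = FALSE,
                                            discovery_clusters = 1L,
                                            discovery_n = 8L,
                                            min_minor_copies = 2L),
                       missing_rate = 0.04,
                       clone_spec = NULL,
                       map_spec = list(n_chromosomes = 7L, cm_max = 200),
                       coord_spec = list(centroids = NULL, jitter_sd = 2),
                       seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  ancestral_freq_law <- match.arg(ancestral_freq_law)
  stopifnot(f_ct >= 0, f_ct <= 0.99, f_sc >= 0, f_sc <= 0.99,
            f_is >= 0, f_is <= 1,
            all(missing_rate >= 0), all(missing_rate <= 1))
  asc_default <- list(enabled = FALSE, discovery_clusters = 1L,
                      discovery_n = 8L, min_minor_copies = 2L)
  ascertainment <- utils::modifyList(asc_default, ascertainment)
  structure(list(n_clusters = as.integer(n_clusters),
                 accessions_per_cluster = as.integer(accessions_per_cluster),
                 individuals_per_accession = as.integer(individuals_per_accession),
                 n_markers = as.integer(n_markers),
                 f_ct = f_ct, f_sc = f_sc, f_is = f_is,
                 ancestral_freq_law = ancestral_freq_law,
                 ancestral_lo = ancestral_lo, ancestral_hi = ancestral_hi,
                 ascertainment = ascertainment,
                 missing_rate = missing_rate,
                 clone_spec = clone_spec,
                 map_spec = map_spec, coord_spec = coord_spec,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.rbeta_bn <- function(p0, f) {
  if (f <= 0) return(p0)
  out <- stats::rbeta(length(p0), p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
  fixed <- p0 %in% c(0, 1)
  out[fixed] <- p0[fixed]
  out
}

# Diploid dosages for one accession: two allele draws per individual,
# the second copying the first with probability f_is (inbreeding).
.draw_dosages <- function(p_alt, n_ind, f_is) {
  l <- length(p_alt)
  a1 <- matrix(stats::rbinom(n_ind * l, 1L, rep(p_alt, each = n_ind)),
               n_ind, l)
  a2 <- matrix(stats::rbinom(n_ind * l, 1L, rep(p_alt, each = n_ind)),
               n_ind, l)
  if (f_is > 0) {
    same <- matrix(stats::runif(n_ind * l) < f_is, n_ind, l)
    a2[same] <- a1[same]
  }
  a1 + a2
}

#' Simulate a genotype panel with known structure
#'
#' Hierarchical Balding-Nichols generator. Per locus an ancestral
#' frequency `p0` is drawn from the configured law; cluster frequencies
#' are Beta-distributed around `p0` with variance `p0 (1-p0) F_CT`;
#' accession frequencies likewise around their cluster frequency with
#' `F_SC`; genotypes are drawn per individual with inbreeding `F_IS`
#' (hom-ref probability `p^2 + p(1-p) F_IS`, het `2p(1-p)(1-F_IS)`).
#' With ascertainment enabled, candidate loci are generated and kept
#' only when a fixed discovery sample of individuals carries at least
#' `min_minor_copies` copies of the minor allele — the rejection
#' sampling that produces the rare-allele deficit characteristic of
#' array SNP panels. Missing calls are then masked completely at random
#' at the per-cluster rate, clones appended, and map positions and
#' coordinates attached. The returned truth record holds every realised
#' frequency, so any expected statistic can be recomputed.
#'
#' @param cfg A [sim_config()].
#' @return List of class `"synthetic_panel"`: `genotypes`, `accessions`,
#'   `map`, `truth`.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, .simulate_panel_impl(cfg))
}

.simulate_panel_impl <- function(cfg) {
  n_cl <- cfg$n_clusters
  n_acc <- n_cl * cfg$accessions_per_cluster
  n_ind_per_acc <- cfg$individuals_per_accession
  acc_ids <- sprintf("A%02d", seq_len(n_acc))
  cluster_of_acc <- rep(seq_len(n_cl), each = cfg$accessions_per_cluster)
  ind_ids <- as.vector(t(outer(acc_ids, seq_len(n_ind_per_acc),
                               function(a, i) sprintf("%s_I%d", a, i))))
  acc_of_ind <- rep(acc_ids, each = n_ind_per_acc)
  n_ind <- length(ind_ids)
  cluster_of_ind <- cluster_of_acc[match(acc_of_ind, acc_ids)]

  asc <- cfg$ascertainment
  discovery_ids <- character()
  if (isTRUE(asc$enabled)) {
    pool_inds <- ind_ids[cluster_of_ind %in% asc$discovery_clusters]
    discovery_ids <- sample(pool_inds, min(asc$discovery_n, length(pool_inds)))
  }
  disc_idx <- match(discovery_ids, ind_ids)

  draw_p0 <- function(n) {
    if (cfg$ancestral_freq_law == "uniform") {
      stats::runif(n, cfg$ancestral_lo, cfg$ancestral_hi)
    } else {
      # folded neutral SFS truncated to the configured range
      grid <- seq(cfg$ancestral_lo, cfg$ancestral_hi, length.out = 512)
      w <- 1 / (grid * (1 - grid))
      sample(grid, n, replace = TRUE, prob = w)
    }
  }

  kept <- 0L
  tried <- 0L
  geno <- matrix(NA_integer_, n_ind, cfg$n_markers)
  p0_keep <- numeric(cfg$n_markers)
  pcl_keep <- matrix(0, n_cl, cfg$n_markers)
  pacc_keep <- matrix(0, n_acc, cfg$n_markers)

  while (kept < cfg$n_markers) {
    batch <- max(cfg$n_markers - kept, 64L)
    p0 <- draw_p0(batch)
    pcl <- vapply(seq_len(n_cl), function(cl) .rbeta_bn(p0, cfg$f_ct),
                  numeric(batch))
    pcl <- t(pcl)                          # clusters x loci (alt-allele freq)
    pacc <- matrix(0, n_acc, batch)
    for (a in seq_len(n_acc)) {
      pacc[a, ] <- .rbeta_bn(pcl[cluster_of_acc[a], ], cfg$f_sc)
    }
    calls <- matrix(NA_integer_, n_ind, batch)
    for (a in seq_len(n_acc)) {
      rows <- which(acc_of_ind == acc_ids[a])
      calls[rows, ] <- .draw_dosages(pacc[a, ], length(rows), cfg$f_is)
    }
    ok <- rep(TRUE, batch)
    if (isTRUE(asc$enabled)) {
      disc <- calls[disc_idx, , drop = FALSE]
      alt_copies <- colSums(disc)
      minor <- pmin(alt_copies, 2 * length(disc_idx) - alt_copies)
      ok <- minor >= asc$min_minor_copies
    }
    tried <- tried + batch
    take <- which(ok)
    if (length(take)) {
      take <- take[seq_len(min(length(take), cfg$n_markers - kept))]
      idx <- kept + seq_along(take)
      geno[, idx] <- calls[, take]
      p0_keep[idx] <- p0[take]
      pcl_keep[, idx] <- pcl[, take, drop = FALSE]
      pacc_keep[, idx] <- pacc[, take, drop = FALSE]
      kept <- kept + length(take)
    }
    if (tried >= 1e4 && kept / tried < 1e-4) {
      stop(sprintf(paste0("ascertainment acceptance rate %.2e is below 1e-4 ",
                          "after %d candidates; loosen min_minor_copies or ",
                          "enlarge the discovery sample"),
                   kept / tried, tried), call. = FALSE)
    }
  }

  mk_ids <- sprintf("M%04d", seq_len(cfg$n_markers))
  colnames(geno) <- mk_ids
  rownames(geno) <- ind_ids

  # missing completely at random, per cluster
  rate <- rep_len(cfg$missing_rate, n_cl)
  for (cl in seq_len(n_cl)) {
    if (rate[cl] <= 0) next
    rows <- which(cluster_of_ind == cl)
    mask <- matrix(stats::runif(length(rows) * cfg$n_markers) < rate[cl],
                   length(rows), cfg$n_markers)
    block <- geno[rows, , drop = FALSE]
    block[mask] <- NA_integer_
    geno[rows, ] <- block
  }

  # clones: near-identical copies of an accession's first individual
  clone_truth <- tibble::tibble(accession_id = character(),
                                source_id = character(),
                                clone_id = character())
  if (!is.null(cfg$clone_spec)) {
    for (sp in cfg$clone_spec) {
      src_rows <- which(acc_of_ind == sp$accession)
      if (!length(src_rows)) stop("clone_spec names unknown accession", call. = FALSE)
      src <- src_rows[1]
      for (cidx in seq_len(sp$n_clones)) {
        newrow <- geno[src, ]
        flip <- stats::runif(length(newrow)) < sp$error_rate
        newrow[flip] <- sample(0:2, sum(flip), replace = TRUE)
        cid <- sprintf("%s_clone%d", ind_ids[src], cidx)
        geno <- rbind(geno, newrow)
        rownames(geno)[nrow(geno)] <- cid
        acc_of_ind <- c(acc_of_ind, sp$accession)
        clone_truth <- dplyr::bind_rows(clone_truth, tibble::tibble(
          accession_id = sp$accession, source_id = ind_ids[src],
          clone_id = cid))
      }
    }
  }

  genotypes <- as_genotypes(geno, accession_of = acc_of_ind)

  map <- tibble::tibble(
    marker_id = mk_ids,
    chromosome = sprintf("chr%d", sample.int(cfg$map_spec$n_chromosomes,
                                             cfg$n_markers, replace = TRUE)),
    position_cm = round(stats::runif(cfg$n_markers, 0, cfg$map_spec$cm_max), 3))

  centroids <- cfg$coord_spec$centroids
  if (is.null(centroids)) {
    centroids <- cbind(lat = seq(40, 60, length.out = n_cl),
                       lon = seq(-5, 35, length.out = n_cl))
  }
  jit <- cfg$coord_spec$jitter_sd
  accessions <- tibble::tibble(
    accession_id = acc_ids,
    cluster = sprintf("cluster%d", cluster_of_acc),
    taxon = sprintf("cluster%d", cluster_of_acc),
    biological_type = "cultivated",
    latitude = centroids[cluster_of_acc, 1] + stats::rnorm(n_acc, 0, jit),
    longitude = centroids[cluster_of_acc, 2] + stats::rnorm(n_acc, 0, jit))

  truth <- list(config = cfg, p0 = p0_keep,
                cluster_freq = pcl_keep, accession_freq = pacc_keep,
                cluster_of_accession = stats::setNames(cluster_of_acc, acc_ids),
                discovery_ids = discovery_ids,
                clones = clone_truth,
                acceptance_rate = kept / tried)
  structure(list(genotypes = genotypes, accessions = accessions, map = map,
                 truth = truth),
            class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(paste0("synthetic panel: %d markers x %d individuals, ",
                     "%d accessions in %d clusters (F_CT=%.2f, F_SC=%.2f, ",
                     "F_IS=%.2f, seed %d)\n"),
              length(marker_ids(x$genotypes)), nrow(x$genotypes),
              nrow(x$accessions), cfg$n_clusters, cfg$f_ct, cfg$f_sc,
              cfg$f_is, cfg$seed))
  invisible(x)
}

#' Named reference fixtures
#'
#' Deterministic synthetic datasets used by the tests and documentation:
#' * `"tiny"` — 2 accessions x 3 individuals x 10 markers, one cluster,
#'   no missing data.
#' * `"rye-like-default"` — 3 clusters x 8 accessions x 6 individuals,
#'   600 markers, F_CT = 0.03, F_SC = 0.10, ascertainment from
#'   cluster 1.
#' * `"biased-panel"` — 3 clusters x 8 accessions x 6 individuals, 300
#'   mapped markers, F_CT = 0.15, F_SC = 0.05, strong ascertainment
#'   (discovery panel of 8 individuals from cluster 1, minimum 2 minor
#'   copies).
#' * `"clones"` — the tiny shape plus labelled near-identical clones for
#'   duplicate-detection tests.
#'
#' @param name Fixture name.
#' @return A `"synthetic_panel"`.
#' @export
make_fixture <- function(name) {
  cfg <- switch(name,
    "tiny" = sim_config(n_clusters = 1L, accessions_per_cluster = 2L,
                        individuals_per_accession = 3L, n_markers = 10L,
                        f_ct = 0, f_sc = 0.10, missing_rate = 0, seed = 101L),
    "rye-like-default" = sim_config(
      ascertainment = list(enabled = TRUE, discovery_clusters = 1L,
                           discovery_n = 8L, min_minor_copies = 2L),
      seed = 2016L),
    "biased-panel" = sim_config(
      n_markers = 300L, f_ct = 0.15, f_sc = 0.05, missing_rate = 0.02,
      ascertainment = list(enabled = TRUE, discovery_clusters = 1L,
                           discovery_n = 8L, min_minor_copies = 2L),
      seed = 77L),
    "clones" = sim_config(
      n_clusters = 1L, accessions_per_cluster = 3L,
      individuals_per_accession = 4L, n_markers = 120L, f_ct = 0,
      f_sc = 0.10, missing_rate = 0,
      clone_spec = list(list(accession = "A01", n_clones = 1L,
                             error_rate = 0.002)),
      seed = 404L),
    stop("unknown fixture name: '", name, "'", call. = FALSE))
  simulate_panel(cfg)
}

#' Write a synthetic panel to disk
#'
#' Writes the three input TSVs (genotypes, accession passports, marker
#' map) plus a JSON truth summary, the on-disk form consumed by
#' [run_pipeline()].
#'
#' @param panel A `"synthetic_panel"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "synthetic_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(panel$genotypes, file.path(dir, "genotypes.tsv"))
  readr::write_tsv(panel$accessions, file.path(dir, "accessions.tsv"),
                   progress = FALSE)
  readr::write_tsv(panel$map, file.path(dir, "map.tsv"), progress = FALSE)
  cfg <- panel$truth$config
  jsonlite::write_json(list(
    seed = cfg$seed, f_ct = cfg$f_ct, f_sc = cfg$f_sc, f_is = cfg$f_is,
    n_markers = cfg$n_markers,
    acceptance_rate = panel$truth$acceptance_rate,
    discovery_ids = panel$truth$discovery_ids),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
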