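#' Pipeline run configuration
#'
#' Assembles the inputs, grouping choices, stage toggles, thresholds and
#' seeds of a full analysis run. All analysis defaults (0.50 marker
#' missingness cap, 4-individual accession minimum, 0.75 pooling cutoff,
#' 999 permutations, haplotype lengths 2..5) live here rather than being
#' hard-coded in the stages.
#'
#' @param genotypes Genotype tibble, or a path to a wide genotype TSV.
#' @param accessions Accession tibble or TSV path (optional).
#' @param map Marker map tibble or TSV path (optional; required for the
#'   haplotype-bias stage).
#' @param fixture Alternatively, the name of a [make_fixture()] dataset.
#' @param group_by Grouping column used by the grouped stages.
#' @param reference_group Reference group for [bias_curves()] (defaults
#'   to the first group).
#' @param stages Character vector of stages to run, a subset of the
#'   default.
#' @param qc A [qc_thresholds()] object.
#' @param pooling_cutoff Major-allele cutoff for in-silico pooling.
#' @param hap_ks Haplotype lengths for the bias stage.
#' @param n_perm Permutations for AMOVA/FST/Mantel.
#' @param seed Seed used by every stochastic stage.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(genotypes, accessions = NULL, map = NULL,
                       fixture = NULL, group_by = NULL,
                       reference_group = NULL,
                       stages = c("qc", "diversity", "distance", "amova",
                                  "fst", "mantel", "pca", "dispersion",
                                  "pooling", "hapbias", "structure_export"),
                       qc = qc_thresholds(),
                       pooling_cutoff = 0.75,
                       hap_ks = 2:5,
                       n_perm = 999L, seed = 1L) {
  structure(list(genotypes = genotypes, accessions = accessions, map = map,
                 fixture = fixture, group_by = group_by,
                 reference_group = reference_group, stages = stages,
                 qc = qc, pooling_cutoff = pooling_cutoff, hap_ks = hap_ks,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "run_config")
}

.load_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — QC, diversity
#' summaries, genotypic distances, AMOVA, pairwise FST, Mantel test of
#' isolation by distance, accession- and individual-level PCA with PC
#' dispersion and near-identical flags, in-silico pooling with capture
#' fractions, haplotype-merging bias curves, and input export for
#' external Bayesian clustering — and writes every result table as TSV
#' into `out_dir` together with a JSON log of seeds, configuration and
#' package version. A failed stage halts the run with the stage name;
#' tables written before the failure are kept. Identical configuration
#' and seed reproduce identical tables.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (`NULL`: nothing written).
#' @return List of class `"report_bundle"` with one element per
#'   completed stage.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(cfg$fixture)) {
    fx <- make_fixture(cfg$fixture)
    g <- fx$genotypes
    acc <- fx$accessions
    map <- fx$map
    if (is.null(cfg$group_by)) cfg$group_by <- "cluster"
  } else {
    g <- .load_input(cfg$genotypes, read_genotypes)
    acc <- .load_input(cfg$accessions, read_accessions)
    map <- .load_input(cfg$map, read_marker_map)
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list()
  emit <- function(name, tbl) {
    bundle[[name]] <<- tbl
    if (!is.null(out_dir) && is.data.frame(tbl)) {
      readr::write_tsv(tbl, file.path(out_dir, paste0(name, ".tsv")),
                       progress = FALSE)
    }
  }
  stage <- function(name, expr) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  stage("qc", {
    qcres <- apply_qc(g, cfg$qc)
    g <- qcres$genotypes
    emit("qc_report", tidy(qcres))
    emit("qc_summary", glance(qcres))
  })

  stage("diversity", {
    emit("diversity_by_accession", accession_diversity(g))
    emit("diversity_summary",
         summarize_diversity(g, acc, cfg$group_by))
  })

  d2 <- NULL
  stage("distance", {
    d2 <- genotypic_distance(g)
    emit("genotypic_distance", tidy(d2))
  })

  stage("amova", {
    if (is.null(d2)) d2 <- genotypic_distance(g)
    am <- amova(g, acc, cfg$group_by, n_perm = cfg$n_perm, seed = cfg$seed,
                distance = d2)
    emit("amova_table", tidy(am))
    emit("amova_phi", am$phi)
  })

  stage("fst", {
    # fall back to accession-level pairs when the grouping has < 2 levels
    fst_by <- cfg$group_by
    if (!is.null(fst_by) &&
        dplyr::n_distinct(.grouping_table(g, acc, fst_by)$group) < 2L) {
      fst_by <- NULL
    }
    fst <- pairwise_fst(g, acc, fst_by, n_perm = cfg$n_perm,
                        seed = cfg$seed)
    nei <- nei_distance_matrix(g, acc, fst_by)
    tf <- tidy(fst)
    tn <- tidy(nei)
    names(tn)[names(tn) == "distance"] <- "nei_d"
    emit("fst_nei", dplyr::left_join(tf, tn[, c("item1", "item2", "nei_d")],
                                     by = c("item1", "item2")))
  })

  stage("mantel", {
    if (!is.null(acc) && all(c("latitude", "longitude") %in% names(acc)) &&
        dplyr::n_distinct(g$accession_id) >= 3L) {
      acc_he <- accession_diversity(g)
      gd <- nei_distance_matrix(g)     # accession-level genetic distance
      gg <- geo_distance(acc[acc$accession_id %in% rownames(gd), ])
      emit("mantel", mantel_test(gd, gg, n_perm = cfg$n_perm, seed = cfg$seed))
      emit("diversity_geography",
           diversity_geography(acc_he, acc, n_perm = cfg$n_perm,
                               seed = cfg$seed))
    }
  })

  pca_acc <- NULL
  stage("pca", {
    pca_acc <- pca_accessions(g)
    emit("pca_accessions", tidy(pca_acc))
    emit("pca_accessions_variance", glance(pca_acc))
  })

  stage("dispersion", {
    pca_ind <- pca_individuals(g)
    emit("pc_dispersion", pc_dispersion(pca_ind, g))
    emit("near_identical", flag_near_identical(g))
  })

  stage("pooling", {
    pooled <- pool_genotypes(g, cfg$pooling_cutoff)
    emit("pooled_genotypes_summary",
         pooled_diversity(g, pooled, acc, cfg$group_by,
                          cutoff = cfg$pooling_cutoff))
    if (!is.null(out_dir) && "structure_export" %in% cfg$stages) {
      export_structure(pooled, file.path(out_dir, "structure_pooled.str"))
    }
  })

  stage("hapbias", {
    if (!is.null(map)) {
      grouping <- .grouping_table(g, acc, cfg$group_by)
      ref <- cfg$reference_group
      if (is.null(ref)) ref <- sort(unique(grouping$group))[1]
      emit("bias_curves",
           bias_curves(g, map, acc, cfg$group_by, reference = ref,
                       ks = sort(unique(c(1L, cfg$hap_ks))),
                       seed = cfg$seed))
    }
  })

  stage("structure_export", {
    if (!is.null(out_dir)) {
      export_structure(g, file.path(out_dir, "structure_input.str"))
    }
  })

  log <- list(package_version = as.character(utils::packageVersion("accdiv")),
              seed = cfg$seed, n_perm = cfg$n_perm,
              group_by = cfg$group_by, stages = cfg$stages,
              pooling_cutoff = cfg$pooling_cutoff,
              timestamp = NULL)        # deterministic bundles: no wall clock
  bundle$log <- log
  if (!is.null(out_dir)) {
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  class(bundle) <- "report_bundle"
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("analysis bundle with tables:\n ",
      paste(setdiff(names(x), "log"), collapse = ", "), "\n")
  invisible(x)
}
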