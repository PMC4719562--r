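#' Squared genotypic distances between individuals
#'
#' Codominant squared distance per biallelic locus: identical genotypes
#' contribute 0, a homozygote versus a heterozygote 1, and opposite
#' homozygotes 4 (the squared difference of alternate-allele dosages),
#' summed over the loci where both individuals have calls, without
#' rescaling by the number of shared loci (a per-locus-normalised
#' variant is available via `normalize`). This is the distance that
#' feeds the AMOVA machinery.
#'
#' @param g Genotype tibble.
#' @param individuals Optional subset.
#' @param normalize If `TRUE`, divide each pair's sum by its number of
#'   shared called loci (default `FALSE`).
#' @return Symmetric numeric matrix (class `"accdiv_dist"`, kind
#'   `"genotypic_sq"`) with individual ids as dimnames.
#' @export
genotypic_distance <- function(g, individuals = NULL, normalize = FALSE) {
  m <- .subset_matrix(g, individuals)
  if (nrow(m) < 2L) stop("need at least 2 individuals", call. = FALSE)
  d2 <- .sqdist_pairwise(m, normalize)
  .new_dist(d2, "genotypic_sq")
}

# Pairwise-complete squared Euclidean distances on a matrix with NAs.
.sqdist_pairwise <- function(m, normalize = FALSE) {
  z <- m
  z[is.na(z)] <- 0L
  storage.mode(z) <- "double"
  obs <- !is.na(m)
  storage.mode(obs) <- "double"
  z2 <- z^2
  shared <- obs %*% t(obs)
  d2 <- z2 %*% t(obs) + obs %*% t(z2) - 2 * z %*% t(z)
  d2[d2 < 0] <- 0                      # numerical noise
  off <- shared == 0 & row(shared) != col(shared)
  if (any(off)) {
    w <- which(off, arr.ind = TRUE)[1, ]
    stop(sprintf("units '%s' and '%s' share no called loci",
                 rownames(m)[w[1]], rownames(m)[w[2]]), call. = FALSE)
  }
  if (normalize) d2 <- d2 / pmax(shared, 1)
  diag(d2) <- 0
  d2
}

# Expand a dosage matrix into one row per allele copy (0/1 alleles);
# copy 1 carries the alternate allele only for hom-alt, copy 2 for any
# alternate dosage, so a heterozygote contributes alleles 0 and 1.
.allele_matrix <- function(m) {
  a1 <- ifelse(is.na(m), NA_integer_, as.integer(m == 2L))
  a2 <- ifelse(is.na(m), NA_integer_, as.integer(m >= 1L))
  out <- rbind(a1, a2)
  ord <- as.vector(rbind(seq_len(nrow(m)), nrow(m) + seq_len(nrow(m))))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- paste0(rep(rownames(m), each = 2L), c(".1", ".2"))
  out
}

.new_dist <- function(m, kind) {
  structure(m, kind = kind, class = c("accdiv_dist", class(m)))
}

#' @rdname genotypic_distance
#' @param x An `accdiv_dist` matrix.
#' @param ... Unused.
#' @export
tidy.accdiv_dist <- function(x, ...) {
  labs <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(item1 = labs[idx[, 1]], item2 = labs[idx[, 2]],
                 distance = x[idx], kind = attr(x, "kind"))
}

# ---- AMOVA internals --------------------------------------------------

# Sum over within-level pairs of squared distances, divided by level size.
.ss_within <- function(d2, fac) {
  idx <- split(seq_along(fac), fac)
  sum(vapply(idx, function(i) sum(d2[i, i]) / (2 * length(i)), numeric(1)))
}

# Two-level decomposition (among populations / within populations).
.amova2 <- function(d2, pop) {
  pop <- as.character(pop)
  n <- length(pop)
  sizes <- table(pop)
  g_ <- length(sizes)
  ss_total <- sum(d2) / (2 * n)
  ss_wp <- .ss_within(d2, pop)
  ss_ap <- ss_total - ss_wp
  df_ap <- g_ - 1L
  df_wp <- n - g_
  ms_ap <- ss_ap / df_ap
  ms_wp <- if (df_wp > 0L) ss_wp / df_wp else NA_real_
  n0 <- (n - sum(sizes^2) / n) / df_ap
  sigma_w <- ms_wp
  sigma_a <- (ms_ap - ms_wp) / n0
  tot <- sigma_a + sigma_w
  list(ss = c(among = ss_ap, within = ss_wp, total = ss_total),
       df = c(among = df_ap, within = df_wp, total = n - 1L),
       sigma = c(among = sigma_a, within = sigma_w),
       phi = c(phi_pt = if (!is.na(tot) && tot > 0) sigma_a / tot else NA_real_))
}

# Three-level decomposition (among groups / among accessions within
# groups / within accessions), Excoffier-style method of moments with
# unequal-size coefficients.
.amova3 <- function(d2, acc, grp) {
  acc <- as.character(acc)
  grp <- as.character(grp)
  n <- length(acc)
  acc_sizes <- table(acc)
  a_ <- length(acc_sizes)
  grp_of_acc <- tapply(grp, acc, function(x) x[1])
  g_ <- length(unique(grp))
  grp_sizes <- table(grp)

  ss_total <- sum(d2) / (2 * n)
  ss_wp <- .ss_within(d2, acc)
  ss_wg <- .ss_within(d2, grp)
  ss_ap <- ss_wg - ss_wp               # among accessions within groups
  ss_ag <- ss_total - ss_wg            # among groups

  df_ag <- g_ - 1L
  df_ap <- a_ - g_
  df_wp <- n - a_

  sg_a <- tapply(as.numeric(acc_sizes), grp_of_acc, function(x) sum(x^2))
  ng <- as.numeric(grp_sizes[names(sg_a)])
  n1 <- (n - sum(sg_a / ng)) / df_ap
  n2 <- (sum(sg_a / ng) - sum(acc_sizes^2) / n) / df_ag
  n3 <- (n - sum(grp_sizes^2) / n) / df_ag

  sigma_w <- if (df_wp > 0L) ss_wp / df_wp else NA_real_
  sigma_a <- (ss_ap / df_ap - sigma_w) / n1
  sigma_g <- (ss_ag / df_ag - sigma_w - n2 * sigma_a) / n3
  tot <- sigma_w + sigma_a + sigma_g
  phi_ct <- if (!is.na(tot) && tot != 0) sigma_g / tot else NA_real_
  phi_sc <- if (!is.na(sigma_a + sigma_w) && (sigma_a + sigma_w) != 0) {
    sigma_a / (sigma_a + sigma_w)
  } else NA_real_
  phi_st <- if (!is.na(tot) && tot != 0) (sigma_g + sigma_a) / tot else NA_real_
  list(ss = c(among_groups = ss_ag, among_accessions = ss_ap,
              within_accessions = ss_wp, total = ss_total),
       df = c(among_groups = df_ag, among_accessions = df_ap,
              within_accessions = df_wp, total = n - 1L),
       sigma = c(among_groups = sigma_g, among_accessions = sigma_a,
                 within_accessions = sigma_w),
       phi = c(phi_ct = phi_ct, phi_sc = phi_sc, phi_st = phi_st))
}

.pct_of_total <- function(sigma) {
  fl <- pmax(sigma, 0)                 # GenAlEx convention: floor negatives
  if (sum(fl) == 0) return(rep(NA_real_, length(sigma)))
  100 * fl / sum(fl)
}

#' Hierarchical analysis of molecular variance
#'
#' Distance-based AMOVA on squared genotypic distances, decomposing
#' variance among groups, among accessions within groups, and within
#' accessions (or just among/within accessions when no grouping is
#' given). Variance components come from the method-of-moments equations
#' with unequal-size coefficients; negative raw components are retained
#' in the output but floored at zero when percentages are computed.
#'
#' Permutation tests (one-sided, observed value included in the count,
#' `p = (hits + 1) / (n_perm + 1)`) use level-appropriate schemes:
#' the among-accessions-within-groups statistic permutes individuals
#' among accessions within their group; the among-groups statistic
#' permutes whole accessions among groups; the overall
#' `phi_st` permutes individuals among accessions without restriction.
#'
#' @param g Genotype tibble (or `NULL` if `distance` is supplied).
#' @param accessions Accession passport tibble (when grouping).
#' @param group_by Grouping column in `accessions`; `NULL` for the
#'   two-level (accessions only) analysis.
#' @param n_perm Number of permutations (default 999; 0 skips testing).
#' @param seed Seed for the permutations.
#' @param units `"individual"` (default): units are individuals with the
#'   squared genotypic distance, the convention of distance-based Phi-PT
#'   reporting. `"allele"`: each individual is expanded into its two
#'   allele copies and distances are squared allele differences; under
#'   Hardy-Weinberg proportions the resulting Phi statistics estimate
#'   the classical hierarchical F-statistics (the individual-level Phi
#'   inflates them by roughly a factor of two because within-individual
#'   variance is not part of its total). Permutations always move whole
#'   individuals.
#' @param distance Optional precomputed squared-distance matrix whose
#'   dimnames match `g$individual_id` (only for `units = "individual"`).
#' @return Object of class `"accdiv_amova"`; `tidy()` returns the
#'   component table, `glance()` the Phi statistics.
#' @export
amova <- function(g, accessions = NULL, group_by = NULL, n_perm = 999L,
                  seed = NULL, units = c("individual", "allele"),
                  distance = NULL) {
  units <- match.arg(units)
  validate_genotypes(g)
  if (dplyr::n_distinct(g$accession_id) < 2L) {
    stop("AMOVA needs at least 2 accessions", call. = FALSE)
  }
  if (units == "individual") {
    d2 <- if (is.null(distance)) unclass(genotypic_distance(g)) else unclass(distance)
    ind_ids <- rownames(d2)
    unit_ind <- seq_along(ind_ids)
  } else {
    am <- .allele_matrix(geno_matrix(g))
    d2 <- .sqdist_pairwise(am)
    ind_ids <- g$individual_id
    unit_ind <- rep(seq_along(ind_ids), each = 2L)
  }
  ind_acc <- g$accession_id[match(ind_ids, g$individual_id)]
  grouping <- .grouping_table(g, accessions, group_by)
  ind_grp <- grouping$group[match(ind_acc, grouping$accession_id)]
  keep_ind <- !is.na(ind_grp)
  keep_unit <- keep_ind[unit_ind]
  d2 <- d2[keep_unit, keep_unit, drop = FALSE]
  ind_acc <- ind_acc[keep_ind]
  ind_grp <- ind_grp[keep_ind]
  unit_ind <- match(unit_ind[keep_unit], which(keep_ind))
  three_level <- !is.null(group_by) && dplyr::n_distinct(ind_grp) > 1L
  collapsed <- FALSE
  if (three_level && all(table(ind_acc) == 1L)) {
    # one individual per accession (e.g. pooled pseudo-genotypes): the
    # within-accession stratum is empty and not testable; collapse to a
    # two-level among-group / within-group analysis of the units
    three_level <- FALSE
    collapsed <- TRUE
    ind_acc <- ind_grp
  }

  acc_u <- ind_acc[unit_ind]
  grp_u <- ind_grp[unit_ind]
  if (three_level) {
    obs <- .amova3(d2, acc_u, grp_u)
    stat_names <- c("phi_ct", "phi_sc", "phi_st")
  } else {
    obs <- .amova2(d2, acc_u)
    stat_names <- "phi_pt"
  }

  p <- stats::setNames(rep(NA_real_, length(stat_names)), stat_names)
  if (n_perm > 0L) {
    hits <- stats::setNames(rep(0L, length(stat_names)), stat_names)
    run_perms <- function() {
      for (b in seq_len(n_perm)) {
        if (three_level) {
          # among groups: shuffle whole accessions among groups
          acc_levels <- unique(ind_acc)
          grp_of_acc <- ind_grp[match(acc_levels, ind_acc)]
          grp_ct <- sample(grp_of_acc)[match(ind_acc, acc_levels)]
          s_ct <- .amova3(d2, acc_u, grp_ct[unit_ind])$phi["phi_ct"]
          if (!is.na(s_ct) && s_ct >= obs$phi["phi_ct"] - 1e-12) {
            hits["phi_ct"] <<- hits["phi_ct"] + 1L
          }
          # among accessions within groups: shuffle individuals within group
          acc_sc <- ind_acc
          for (gl in unique(ind_grp)) {
            i <- which(ind_grp == gl)
            acc_sc[i] <- ind_acc[i][sample(length(i))]
          }
          s_sc <- .amova3(d2, acc_sc[unit_ind], grp_u)$phi["phi_sc"]
          if (!is.na(s_sc) && s_sc >= obs$phi["phi_sc"] - 1e-12) {
            hits["phi_sc"] <<- hits["phi_sc"] + 1L
          }
          # overall: shuffle individuals among accessions freely
          acc_st <- sample(ind_acc)
          s_st <- .amova3(d2, acc_st[unit_ind], grp_u)$phi["phi_st"]
          if (!is.na(s_st) && s_st >= obs$phi["phi_st"] - 1e-12) {
            hits["phi_st"] <<- hits["phi_st"] + 1L
          }
        } else {
          s <- .amova2(d2, sample(ind_acc)[unit_ind])$phi["phi_pt"]
          if (!is.na(s) && s >= obs$phi["phi_pt"] - 1e-12) {
            hits["phi_pt"] <<- hits["phi_pt"] + 1L
          }
        }
      }
    }
    if (is.null(seed)) run_perms() else withr::with_seed(seed, run_perms())
    p <- (hits + 1) / (n_perm + 1)
    p[is.na(obs$phi[stat_names])] <- NA_real_
  }

  lev <- names(obs$sigma)
  pct <- .pct_of_total(obs$sigma)
  table <- tibble::tibble(
    level = lev,
    df = as.integer(obs$df[lev]),
    ss = as.numeric(obs$ss[lev]),
    sigma2 = as.numeric(obs$sigma),
    pct = pct)
  structure(list(table = table, phi = tibble::tibble(
    statistic = stat_names, value = as.numeric(obs$phi[stat_names]),
    p = as.numeric(p[stat_names])),
    n_perm = n_perm, seed = seed, units = units,
    levels = if (three_level) "group/accession/individual"
             else if (collapsed) "group/accession (within-accession stratum empty)"
             else "accession/individual"),
    class = "accdiv_amova")
}

#' @export
print.accdiv_amova <- function(x, ...) {
  cat("AMOVA (", x$levels, ", ", x$n_perm, " permutations)\n", sep = "")
  print(x$table)
  print(x$phi)
  invisible(x)
}

#' @rdname amova
#' @param x An `accdiv_amova` object.
#' @param ... Unused.
#' @export
tidy.accdiv_amova <- function(x, ...) x$table

#' @rdname amova
#' @export
glance.accdiv_amova <- function(x, ...) {
  out <- tidyr::pivot_wider(x$phi, names_from = "statistic",
                            values_from = c("value", "p"))
  names(out) <- sub("^value_", "", names(out))
  out$n_perm <- x$n_perm
  out
}

#' Pairwise FST between groups
#'
#' For each pair of groups, the among-group Phi statistic of a
#' two-population AMOVA on squared genotypic distances (`method =
#' "amova"`, the default), with a permutation p-value obtained by
#' shuffling individuals between the two groups. `method =
#' "weir_cockerham"` instead computes the multi-locus Weir-Cockerham
#' theta (ratio of sums of the 1984 moment components) as an independent
#' cross-check estimator; no permutation test is run for theta.
#'
#' @param g Genotype tibble.
#' @param accessions Accession passport tibble.
#' @param group_by Grouping column (default groups = accessions
#'   themselves when `NULL`).
#' @param n_perm Permutations per pair (default 999).
#' @param seed Permutation seed.
#' @param method `"amova"` or `"weir_cockerham"`.
#' @param min_group_size Smallest allowed group (default 2 individuals).
#' @return List of class `"pairwise_fst"` with symmetric matrices `fst`
#'   and `p`; `tidy()` returns the long pair table.
#' @export
pairwise_fst <- function(g, accessions = NULL, group_by = NULL,
                         n_perm = 999L, seed = NULL,
                         method = c("amova", "weir_cockerham"),
                         min_group_size = 2L) {
  method <- match.arg(method)
  validate_genotypes(g)
  grouping <- .grouping_table(g, accessions, group_by)
  if (is.null(group_by)) grouping$group <- grouping$accession_id
  grp_of_ind <- grouping$group[match(g$accession_id, grouping$accession_id)]
  keep <- !is.na(grp_of_ind)
  g2 <- g[keep, , drop = FALSE]
  grp_of_ind <- grp_of_ind[keep]
  groups <- sort(unique(grp_of_ind))
  sizes <- table(grp_of_ind)
  if (any(sizes < min_group_size)) {
    stop("group(s) below the minimum size: ",
         paste(names(sizes)[sizes < min_group_size], collapse = ", "),
         call. = FALSE)
  }
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  fst <- matrix(0, k, k, dimnames = list(groups, groups))
  pmat <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  d2_all <- if (method == "amova") unclass(genotypic_distance(g2)) else NULL
  pair_stat <- function(i, j) {
    members <- grp_of_ind %in% c(groups[i], groups[j])
    if (method == "weir_cockerham") {
      m <- geno_matrix(g2)[members, , drop = FALSE]
      return(list(stat = .wc_theta(m, grp_of_ind[members]), p = NA_real_))
    }
    d2 <- d2_all[members, members, drop = FALSE]
    pop <- grp_of_ind[members]
    obs <- .amova2(d2, pop)$phi["phi_pt"]
    pv <- NA_real_
    if (n_perm > 0L) {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        s <- .amova2(d2, sample(pop))$phi["phi_pt"]
        if (!is.na(s) && s >= obs - 1e-12) hits <- hits + 1L
      }
      pv <- (hits + 1) / (n_perm + 1)
    }
    list(stat = unname(obs), p = pv)
  }
  run_all <- function() {
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        r <- pair_stat(i, j)
        fst[i, j] <<- fst[j, i] <<- r$stat
        pmat[i, j] <<- pmat[j, i] <<- r$p
      }
    }
  }
  if (is.null(seed)) run_all() else withr::with_seed(seed, run_all())
  structure(list(fst = .new_dist(fst, "fst"), p = pmat, method = method,
                 n_perm = n_perm, seed = seed),
            class = "pairwise_fst")
}

#' @export
print.pairwise_fst <- function(x, ...) {
  cat("pairwise FST (", x$method, ")\n", sep = "")
  print(round(unclass(x$fst), 4))
  invisible(x)
}

#' @rdname pairwise_fst
#' @param x A `pairwise_fst` object.
#' @param ... Unused.
#' @export
tidy.pairwise_fst <- function(x, ...) {
  out <- tidy(x$fst)
  names(out)[names(out) == "distance"] <- "fst"
  out$kind <- NULL
  idx <- which(upper.tri(x$p), arr.ind = TRUE)
  out$p <- x$p[idx]
  out
}

# Weir & Cockerham (1984) theta for two or more populations, biallelic
# loci, ratio-of-sums over loci. m: dosage matrix, pop: labels.
.wc_theta <- function(m, pop) {
  pops <- unique(pop)
  r <- length(pops)
  num <- 0
  den <- 0
  for (l in seq_len(ncol(m))) {
    x <- m[, l]
    ok <- !is.na(x)
    ni <- vapply(pops, function(pz) sum(ok & pop == pz), numeric(1))
    if (any(ni < 1) || sum(ni) == 0) next
    pi <- vapply(pops, function(pz) {
      v <- x[ok & pop == pz]
      sum(v) / (2 * length(v))
    }, numeric(1))
    hi <- vapply(pops, function(pz) mean(x[ok & pop == pz] == 1L), numeric(1))
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    pbar <- sum(ni * pi) / sum(ni)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / sum(ni)
    if (nbar <= 1 || nc <= 0) next
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                  hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Nei's standard genetic distance
#'
#' From two aligned vectors of per-locus reference-allele frequencies:
#' `Jx`, `Jy` and `Jxy` are the across-loci means of the homozygosity
#' and cross-product sums, `I = Jxy / sqrt(Jx * Jy)` the normalised
#' identity, and `D = -log(I)`. Completely disjoint frequency profiles
#' give `I = 0` and `D = Inf` with a warning.
#'
#' @param fx,fy Numeric vectors of reference-allele frequencies at the
#'   same loci (`NA` allowed; only loci defined in both are used).
#' @return Nei's D (a single number).
#' @export
nei_distance <- function(fx, fy) {
  stopifnot(length(fx) == length(fy))
  ok <- !is.na(fx) & !is.na(fy)
  if (!any(ok)) stop("no shared defined loci", call. = FALSE)
  fx <- fx[ok]
  fy <- fy[ok]
  jx <- mean(fx^2 + (1 - fx)^2)
  jy <- mean(fy^2 + (1 - fy)^2)
  jxy <- mean(fx * fy + (1 - fx) * (1 - fy))
  i <- jxy / sqrt(jx * jy)
  if (i <= 0) {
    warning("genetic identity is 0; Nei's D is infinite")
    return(Inf)
  }
  -log(i)
}

#' Nei distance matrix over groups
#'
#' @inheritParams pairwise_fst
#' @return Symmetric matrix (`accdiv_dist`, kind `"nei_D"`).
#' @export
nei_distance_matrix <- function(g, accessions = NULL, group_by = NULL) {
  validate_genotypes(g)
  grouping <- .grouping_table(g, accessions, group_by)
  if (is.null(group_by)) grouping$group <- grouping$accession_id
  groups <- sort(unique(grouping$group))
  freqs <- lapply(groups, function(grp) {
    accs <- grouping$accession_id[grouping$group == grp]
    allele_freqs(g, g$individual_id[g$accession_id %in% accs])$p
  })
  k <- length(groups)
  d <- matrix(0, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      d[i, j] <- d[j, i] <- nei_distance(freqs[[i]], freqs[[j]])
    }
  }
  .new_dist(d, "nei_D")
}

#' Great-circle distance matrix
#'
#' Haversine distances in kilometres (Earth radius 6371.0 km) between
#' accession coordinates. Pairs involving missing coordinates are `NA`
#' and are dropped by [mantel_test()].
#'
#' @param coords Tibble with `accession_id`, `latitude`, `longitude`.
#' @return Symmetric matrix (`accdiv_dist`, kind `"geographic_km"`).
#' @export
geo_distance <- function(coords) {
  coords <- tibble::as_tibble(coords)
  stopifnot(all(c("accession_id", "latitude", "longitude") %in% names(coords)))
  xy <- cbind(coords$longitude, coords$latitude)
  d <- geosphere::distm(xy, fun = function(a, b) {
    geosphere::distHaversine(a, b, r = 6371000)
  }) / 1000
  dimnames(d) <- list(coords$accession_id, coords$accession_id)
  diag(d) <- 0
  .new_dist(d, "geographic_km")
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the off-diagonal upper triangle, with a
#' permutation p-value obtained by jointly permuting the rows and
#' columns of `b`. Labels present in both matrices are matched; labels
#' with any `NA` pair are dropped before testing. The observed value is
#' included in the permutation count.
#'
#' @param a,b Symmetric distance matrices with dimnames.
#' @param n_perm Number of permutations (default 999).
#' @param seed Permutation seed.
#' @param tails `"one_sided_positive"` (default), `"one_sided_negative"`
#'   or `"two_sided"`.
#' @return One-row tibble: `statistic`, `r`, `p`, `n`, `n_perm`, `seed`,
#'   `tails`.
#' @export
mantel_test <- function(a, b, n_perm = 999L, seed = NULL,
                        tails = c("one_sided_positive", "two_sided",
                                  "one_sided_negative")) {
  tails <- match.arg(tails)
  a <- unclass(a)
  b <- unclass(b)
  labs <- intersect(rownames(a), rownames(b))
  if (length(labs) < 3L) stop("need at least 3 shared labels", call. = FALSE)
  a <- a[labs, labs]
  b <- b[labs, labs]
  ok <- rowSums(is.na(a) + is.na(b)) == 0
  a <- a[ok, ok]
  b <- b[ok, ok]
  n <- nrow(a)
  if (n < 3L) stop("fewer than 3 labels with complete pairs", call. = FALSE)
  ut <- upper.tri(a)
  va <- a[ut]
  if (stats::sd(va) == 0 || stats::sd(b[ut]) == 0) {
    stop("constant distance matrix: Mantel r undefined", call. = FALSE)
  }
  r_obs <- stats::cor(va, b[ut])
  score <- function(r) switch(tails,
    one_sided_positive = r,
    one_sided_negative = -r,
    two_sided = abs(r))
  hits <- 0L
  run <- function() {
    for (i in seq_len(n_perm)) {
      pm <- sample(n)
      r_p <- stats::cor(va, b[pm, pm][ut])
      if (score(r_p) >= score(r_obs) - 1e-12) hits <<- hits + 1L
    }
  }
  if (n_perm > 0L) {
    if (is.null(seed)) run() else withr::with_seed(seed, run())
  }
  tibble::tibble(statistic = "mantel_r", r = r_obs,
                 p = if (n_perm > 0L) (hits + 1) / (n_perm + 1) else NA_real_,
                 n = n, n_perm = n_perm,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 tails = tails)
}

#' Diversity versus geography
#'
#' Pearson correlations (with permutation p-values) of accession-level
#' expected heterozygosity against latitude, longitude and great-circle
#' distance to an assumed geographic origin of the crop (default central
#' Turkey, 39N 35E).
#'
#' @param div Tibble with `accession_id` and `he` (e.g. from
#'   [accession_diversity()]).
#' @param coords Tibble with `accession_id`, `latitude`, `longitude`.
#' @param origin Numeric `c(latitude, longitude)` of the assumed origin.
#' @param n_perm Number of permutations (default 999).
#' @param seed Permutation seed.
#' @param tails `"two_sided"` (default) or one-sided variants as in
#'   [mantel_test()].
#' @return Tibble with one row per predictor.
#' @export
diversity_geography <- function(div, coords, origin = c(39.0, 35.0),
                                n_perm = 999L, seed = NULL,
                                tails = c("two_sided", "one_sided_positive",
                                          "one_sided_negative")) {
  tails <- match.arg(tails)
  d <- dplyr::inner_join(tibble::as_tibble(div), tibble::as_tibble(coords),
                         by = "accession_id")
  d <- d[!is.na(d$he) & !is.na(d$latitude) & !is.na(d$longitude), , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 accessions with He and coordinates",
                         call. = FALSE)
  if (stats::sd(d$he) == 0) stop("zero-variance He", call. = FALSE)
  d$distance_to_origin <- geosphere::distHaversine(
    cbind(d$longitude, d$latitude), c(origin[2], origin[1]), r = 6371000) / 1000
  score <- function(r) switch(tails,
    one_sided_positive = r, one_sided_negative = -r, two_sided = abs(r))
  one <- function(xname) {
    x <- d[[xname]]
    r_obs <- stats::cor(d$he, x)
    pv <- NA_real_
    if (n_perm > 0L) {
      hits <- 0L
      run <- function() {
        for (i in seq_len(n_perm)) {
          r_p <- stats::cor(sample(d$he), x)
          if (score(r_p) >= score(r_obs) - 1e-12) hits <<- hits + 1L
        }
      }
      if (is.null(seed)) run() else withr::with_seed(seed, run())
      pv <- (hits + 1) / (n_perm + 1)
    }
    tibble::tibble(predictor = xname, r = r_obs, p = pv, n = nrow(d),
                   n_perm = n_perm,
                   seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                   tails = tails)
  }
  dplyr::bind_rows(lapply(c("latitude", "longitude", "distance_to_origin"), one))
}

#' Group mean comparisons for accession-level statistics
#'
#' Thin plumbing around `stats::aov` and `stats::t.test` for comparing
#' accession-level values (He, F, PC dispersion, ...) between groups:
#' one- or two-way ANOVA plus, for two-level factors, an unpaired
#' two-sample t-test.
#'
#' @param data Tibble of accession-level records.
#' @param response Name of the numeric response column.
#' @param factors Character vector of one or two factor column names.
#' @param t_test_alternative Passed to `t.test` (default `"two.sided"`).
#' @return Tibble of test rows (`test`, `term`, `statistic`, `df`, `p`).
#' @export
compare_group_means <- function(data, response, factors,
                                t_test_alternative = "two.sided") {
  data <- tibble::as_tibble(data)
  stopifnot(length(factors) %in% 1:2, response %in% names(data),
            all(factors %in% names(data)))
  d <- data[stats::complete.cases(data[, c(response, factors)]), , drop = FALSE]
  for (f in factors) d[[f]] <- factor(d[[f]])
  if (any(vapply(factors, function(f) nlevels(d[[f]]) < 2L, logical(1)))) {
    stop("each factor needs at least 2 groups", call. = FALSE)
  }
  fml <- stats::as.formula(paste(response, "~", paste(factors, collapse = " + ")))
  av <- summary(stats::aov(fml, data = d))[[1]]
  terms <- trimws(rownames(av))
  out <- tibble::tibble(
    test = paste0(length(factors), "-way ANOVA"),
    term = terms[terms != "Residuals"],
    statistic = av$`F value`[terms != "Residuals"],
    df = av$Df[terms != "Residuals"],
    p = av$`Pr(>F)`[terms != "Residuals"])
  for (f in factors) {
    if (nlevels(d[[f]]) == 2L) {
      lv <- levels(d[[f]])
      x <- d[[response]][d[[f]] == lv[1]]
      y <- d[[response]][d[[f]] == lv[2]]
      if (length(x) < 2L || length(y) < 2L) {
        stop("t-test group of size < 2 for factor '", f, "'", call. = FALSE)
      }
      tt <- stats::t.test(x, y, alternative = t_test_alternative)
      out <- dplyr::bind_rows(out, tibble::tibble(
        test = "t-test", term = f, statistic = unname(tt$statistic),
        df = unname(tt$parameter), p = tt$p.value))
    }
  }
  out
}
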