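test_that("squared genotypic distances follow the per-locus 0/1/4 table", {
  g <- make_geno(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L)))
  d <- genotypic_distance(g)
  expect_equal(d[1, 2], 0)

  g2 <- make_geno(rbind(rep(0L, 3), rep(2L, 3)))       # AA vs BB at 3 loci
  expect_equal(genotypic_distance(g2)[1, 2], 12)

  g3 <- make_geno(rbind(c(0L, 1L, 2L), c(1L, 1L, 2L))) # 1 + 0 + 0
  expect_equal(genotypic_distance(g3)[1, 2], 1)

  # missing loci are skipped, not rescaled by default
  g4 <- make_geno(rbind(c(0L, NA_integer_), c(2L, 2L)))
  expect_equal(genotypic_distance(g4)[1, 2], 4)
  expect_equal(genotypic_distance(g4, normalize = TRUE)[1, 2], 4)

  g5 <- make_geno(rbind(c(0L, NA_integer_), c(NA_integer_, 2L)))
  expect_error(genotypic_distance(g5), "share no called loci")
})

test_that("distances agree with a per-pair loop oracle", {
  g <- random_panel(12, 18, miss = 0.15, seed = 13)
  d <- genotypic_distance(g)
  m <- geno_matrix(g)
  for (i in 1:11) {
    for (j in (i + 1):12) {
      expect_equal(d[i, j], brute_sqdist(m[i, ], m[j, ]), tolerance = 1e-10)
    }
  }
})

test_that("two-level AMOVA equals the definitional SSD oracle on a toy", {
  g <- random_panel(6, 10, n_acc = 2, miss = 0, seed = 4)   # 2 acc x 3 ind
  am <- amova(g, n_perm = 0)
  d2 <- unclass(genotypic_distance(g))
  oracle <- brute_amova2(d2, g$accession_id)
  expect_equal(am$table$ss[am$table$level == "among"], oracle$ss_among)
  expect_equal(am$table$ss[am$table$level == "within"], oracle$ss_within)
  expect_equal(am$table$sigma2, c(oracle$sigma_a, oracle$sigma_w))
  expect_equal(am$phi$value, oracle$phi_pt)
})

test_that("three-level AMOVA equals the SSD oracle, including unequal sizes", {
  withr::with_seed(5, {
    acc <- c(rep("a1", 4), rep("a2", 3), rep("a3", 5), rep("a4", 4))
    grp_tbl <- tibble::tibble(accession_id = c("a1", "a2", "a3", "a4"),
                              region = c("g1", "g1", "g2", "g2"))
    calls <- matrix(sample(0:2, length(acc) * 12, replace = TRUE),
                    length(acc), 12)
    g <- make_geno(calls, acc = acc)
  })
  am <- amova(g, grp_tbl, "region", n_perm = 0)
  d2 <- unclass(genotypic_distance(g))
  grp <- grp_tbl$region[match(g$accession_id, grp_tbl$accession_id)]
  oracle <- brute_amova3(d2, g$accession_id, grp)
  expect_equal(am$table$ss, c(oracle$ss_ag, oracle$ss_ap, oracle$ss_wp))
  expect_equal(am$table$sigma2,
               c(oracle$sigma_g, oracle$sigma_a, oracle$sigma_w))
  expect_equal(am$phi$value[am$phi$statistic == "phi_ct"], oracle$phi_ct)
  # df sum to n - 1 and percentages to 100
  expect_equal(sum(am$table$df), nrow(g) - 1L)
  expect_equal(sum(am$table$pct), 100, tolerance = 0.1)
})

test_that("degenerate AMOVA panels are handled explicitly", {
  # genetically identical individuals: all SS and components zero
  g <- make_geno(matrix(rep(c(0L, 1L, 2L), each = 6), 6, 3),
                 acc = rep(c("A", "B"), each = 3))
  am <- amova(g, n_perm = 0)
  expect_equal(am$table$ss, c(0, 0))
  expect_equal(am$table$sigma2, c(0, 0))
  expect_true(is.na(am$phi$value))

  # a single group collapses to the two-level analysis
  fx <- make_fixture("tiny")
  acc1 <- fx$accessions
  acc1$zone <- "only"
  am1 <- amova(fx$genotypes, acc1, "zone", n_perm = 0)
  expect_equal(am1$table$level, c("among", "within"))
})

test_that("pairwise FST is 1 under complete fixation and ~0 under panmixia", {
  g <- make_geno(rbind(matrix(0L, 4, 8), matrix(2L, 4, 8)),
                 acc = rep(c("A", "B"), each = 4))
  res <- pairwise_fst(g, n_perm = 99, seed = 1)
  expect_equal(res$fst["A", "B"], 1)
  expect_lte(res$p["A", "B"], 0.05)

  # toy pair equals the same brute-force AMOVA oracle
  g2 <- random_panel(6, 12, n_acc = 2, miss = 0, seed = 6)
  r2 <- pairwise_fst(g2, n_perm = 0)
  oracle <- brute_amova2(unclass(genotypic_distance(g2)), g2$accession_id)
  expect_equal(r2$fst["ACC1", "ACC2"], oracle$phi_pt)

  # split of one panmictic population: FST near zero, p not small
  fx <- simulate_panel(sim_config(n_clusters = 1L,
                                  accessions_per_cluster = 2L,
                                  individuals_per_accession = 12L,
                                  n_markers = 150L, f_ct = 0, f_sc = 0,
                                  missing_rate = 0, seed = 55L))
  rn <- pairwise_fst(fx$genotypes, n_perm = 199, seed = 2)
  expect_lt(abs(rn$fst[1, 2]), 0.02)
  expect_gt(rn$p[1, 2], 0.1)
})

test_that("Weir-Cockerham theta agrees qualitatively with the AMOVA Phi", {
  g <- make_geno(rbind(matrix(0L, 4, 8), matrix(2L, 4, 8)),
                 acc = rep(c("A", "B"), each = 4))
  r <- pairwise_fst(g, method = "weir_cockerham")
  expect_equal(r$fst["A", "B"], 1)

  fx <- simulate_panel(sim_config(n_clusters = 2L,
                                  accessions_per_cluster = 1L,
                                  individuals_per_accession = 30L,
                                  n_markers = 300L, f_ct = 0.2, f_sc = 0,
                                  missing_rate = 0, seed = 77L))
  th <- pairwise_fst(fx$genotypes, method = "weir_cockerham")$fst[1, 2]
  expect_gt(th, 0.1)
  expect_lt(th, 0.35)
})

test_that("Nei's standard distance matches closed forms and flags disjoint", {
  expect_equal(nei_distance(c(0.3, 0.8), c(0.3, 0.8)), 0)
  expect_equal(nei_distance(0.5, 1), -log(0.5 / sqrt(0.5 * 1)),
               tolerance = 1e-12)
  expect_equal(nei_distance(0.5, 1), 0.3466, tolerance = 1e-4)
  expect_warning(d <- nei_distance(c(1, 1), c(0, 0)), "infinite")
  expect_equal(d, Inf)
  expect_error(nei_distance(NA_real_, 0.5), "no shared")

  g <- random_panel(12, 20, n_acc = 3, miss = 0.05, seed = 10)
  nm <- nei_distance_matrix(g)
  expect_true(isSymmetric(unclass(nm)))
  expect_equal(diag(unclass(nm)), stats::setNames(rep(0, 3), rownames(nm)))
  f1 <- allele_freqs(g, g$individual_id[g$accession_id == "ACC1"])$p
  f2 <- allele_freqs(g, g$individual_id[g$accession_id == "ACC2"])$p
  expect_equal(nm["ACC1", "ACC2"], brute_nei(f1, f2), tolerance = 1e-12)
})

test_that("haversine distances use a 6371 km Earth radius", {
  co <- tibble::tibble(accession_id = c("p1", "p2", "p3"),
                       latitude = c(0, 1, 52.2),
                       longitude = c(0, 0, 21.0))
  d <- geo_distance(co)
  expect_equal(d["p1", "p1"], 0)
  expect_equal(d["p1", "p2"], 2 * pi * 6371 / 360, tolerance = 1e-4)
  expect_true(isSymmetric(unclass(d)))
})

test_that("Mantel test matches exhaustive enumeration on 4 labels", {
  withr::with_seed(2, {
    a <- as.matrix(stats::dist(matrix(stats::rnorm(8), 4)))
    b <- as.matrix(stats::dist(matrix(stats::rnorm(8), 4)))
  })
  dimnames(a) <- dimnames(b) <- list(letters[1:4], letters[1:4])
  res <- mantel_test(a, b, n_perm = 4999, seed = 77)
  ut <- upper.tri(a)
  r_obs <- stats::cor(a[ut], b[ut])
  expect_equal(res$r, r_obs)
  rs <- vapply(all_perms(1:4), function(pm) stats::cor(a[ut], b[pm, pm][ut]),
               numeric(1))
  p_exact <- mean(rs >= r_obs - 1e-12)
  expect_equal(res$p, p_exact, tolerance = 0.03)

  # perfect correlation: r = 1 and the smallest attainable p
  res1 <- mantel_test(a, a, n_perm = 99, seed = 1)
  expect_equal(res1$r, 1)

  # degenerate input
  cst <- a
  cst[] <- 0
  expect_error(mantel_test(a, cst, n_perm = 9), "constant")
})

test_that("Mantel agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  withr::with_seed(3, {
    a <- as.matrix(stats::dist(matrix(stats::rnorm(20), 10)))
    b <- as.matrix(stats::dist(matrix(stats::rnorm(20), 10)))
  })
  dimnames(a) <- dimnames(b) <- list(letters[1:10], letters[1:10])
  ours <- mantel_test(a, b, n_perm = 999, seed = 5)
  ref <- vegan::mantel(a, b, permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - ref$signif), 0.08)
})

test_that("diversity-geography correlations match the Pearson formula", {
  co <- tibble::tibble(accession_id = sprintf("a%d", 1:5),
                       latitude = c(40, 45, 50, 55, 60),
                       longitude = c(10, 12, 8, 15, 11))
  div <- tibble::tibble(accession_id = co$accession_id,
                        he = c(0.20, 0.25, 0.30, 0.35, 0.40))
  res <- diversity_geography(div, co, n_perm = 199, seed = 3)
  expect_equal(res$r[res$predictor == "latitude"], 1)
  expect_equal(res$r[res$predictor == "longitude"],
               brute_pearson(div$he, co$longitude))

  div0 <- div; div0$he <- 0.3
  expect_error(diversity_geography(div0, co), "zero-variance")
})

test_that("group mean comparisons reproduce the hand formulas", {
  d <- tibble::tibble(value = c(1, 2, 3, 1, 2, 3),
                      grp = rep(c("x", "y"), each = 3))
  out <- compare_group_means(d, "value", "grp")
  tt <- out[out$test == "t-test", ]
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p, 1)

  d2 <- tibble::tibble(value = c(5, 6, 7, 1, 2, 3),
                       grp = rep(c("x", "y"), each = 3))
  tt2 <- compare_group_means(d2, "value", "grp")
  tt2 <- tt2[tt2$test == "t-test", ]
  # unpaired t with equal variances/sizes: t = (m1 - m2) / sqrt(2 s^2 / n)
  expect_equal(tt2$statistic, (6 - 2) / sqrt(2 * 1 / 3), tolerance = 1e-12)

  d3 <- tibble::tibble(value = c(1, 2, 3, 4, 5, 6, 10, 11, 12),
                       grp = rep(c("a", "b", "c"), each = 3))
  f <- compare_group_means(d3, "value", "grp")
  gm <- mean(d3$value)
  ms_b <- sum(3 * (tapply(d3$value, d3$grp, mean) - gm)^2) / 2
  ms_w <- sum((d3$value - rep(tapply(d3$value, d3$grp, mean), each = 3))^2) / 6
  expect_equal(f$statistic[f$test == "1-way ANOVA"], ms_b / ms_w,
               tolerance = 1e-12)
})
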