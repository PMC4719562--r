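test_that("accession PCA matches a direct eigendecomposition on a toy", {
  # 3 accessions x 2 loci with distinct frequencies
  calls <- rbind(c(0L, 0L), c(0L, 0L),      # acc A: p_alt = (0, 0)
                 c(2L, 0L), c(2L, 0L),      # acc B: p_alt = (1, 0)
                 c(2L, 2L), c(2L, 2L))      # acc C: p_alt = (1, 1)
  g <- make_geno(calls, acc = rep(c("A", "B", "C"), each = 2))
  res <- pca_accessions(g)
  fq <- accession_freq_matrix(g)
  ev <- eigen(stats::cov(fq))
  expect_equal(res$var[1:2], ev$values[1:2], tolerance = 1e-12)
  # coordinates match up to component sign
  sc <- as.matrix(res$coords[, c("PC1", "PC2")])
  direct <- sweep(fq, 2, colMeans(fq)) %*% ev$vectors
  for (j in 1:2) {
    expect_true(max(abs(sc[, j] - direct[, j])) < 1e-9 ||
                  max(abs(sc[, j] + direct[, j])) < 1e-9)
  }
})

test_that("PCA variance accounting and degenerate inputs behave", {
  g <- random_panel(10, 15, n_acc = 5, miss = 0, seed = 12)
  res <- pca_accessions(g)
  fq <- accession_freq_matrix(g)
  expect_equal(sum(res$var), sum(apply(fq, 2, stats::var)),
               tolerance = 1e-10)
  expect_true(all(diff(res$var) <= 1e-12))
  expect_equal(max(abs(colMeans(as.matrix(res$coords[, -1])))), 0,
               tolerance = 1e-10)

  # identical accessions: no variance, all coordinates zero
  calls <- rbind(c(0L, 1L), c(0L, 1L), c(0L, 1L), c(0L, 1L))
  gi <- make_geno(calls, acc = rep(c("A", "B"), each = 2))
  ri <- pca_accessions(gi)
  expect_equal(max(abs(as.matrix(ri$coords[, -1]))), 0, tolerance = 1e-12)

  expect_error(pca_accessions(make_geno(matrix(0L, 3, 2))), "2 accessions")
})

test_that("individual PCA is an isometry of the centred imputed genotypes", {
  g <- random_panel(14, 30, n_acc = 3, miss = 0.1, seed = 19)
  res <- pca_individuals(g)
  m <- geno_matrix(g)
  storage.mode(m) <- "double"
  mu <- colMeans(m, na.rm = TRUE)
  for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- mu[j]
  mc <- sweep(m, 2, colMeans(m))
  d_pc <- stats::dist(as.matrix(res$coords[, -1]))
  d_raw <- stats::dist(mc)
  expect_equal(as.numeric(d_pc), as.numeric(d_raw), tolerance = 1e-8)

  # duplicated individuals land on identical coordinates
  calls <- rbind(c(0L, 1L, 2L), c(0L, 1L, 2L), c(2L, 1L, 0L))
  gd <- make_geno(calls)
  rd <- pca_individuals(gd)
  expect_equal(as.numeric(rd$coords[1, -1]), as.numeric(rd$coords[2, -1]),
               tolerance = 1e-12)

  # a locus with no calls among the members errors
  gna <- make_geno(cbind(c(0L, 1L), NA_integer_))
  expect_error(pca_individuals(gna), "all calls missing")
})

test_that("accession PCA is invariant to locus order and allele flips", {
  g <- random_panel(12, 10, n_acc = 4, miss = 0, seed = 23)
  base <- pca_accessions(g)
  # locus order
  perm <- c("individual_id", "accession_id", rev(marker_ids(g)))
  g_perm <- g[, perm]
  expect_equal(abs(as.matrix(pca_accessions(g_perm)$coords[, -1])),
               abs(as.matrix(base$coords[, -1])), tolerance = 1e-9)
  # allele relabelling (dosage 2 - g) at every locus
  g_flip <- g
  for (mk in marker_ids(g)) g_flip[[mk]] <- 2L - g_flip[[mk]]
  expect_equal(abs(as.matrix(pca_accessions(g_flip)$coords[, -1])),
               abs(as.matrix(base$coords[, -1])), tolerance = 1e-9)
})

test_that("PC dispersion reduces to pair distances and flags small groups", {
  calls <- rbind(c(0L, 1L, 2L), c(0L, 1L, 2L),       # identical pair
                 c(2L, 1L, 0L), c(0L, 0L, 0L),
                 c(1L, 1L, 1L))
  g <- make_geno(calls, acc = c("A", "A", "B", "B", "C"))
  res <- pca_individuals(g)
  expect_message(disp <- pc_dispersion(res, g), "skipped")
  expect_equal(nrow(disp), 2L)
  a <- disp[disp$accession_id == "A", ]
  expect_equal(a$mean_dist, 0)
  expect_equal(a$var_dist, 0)
  b <- disp[disp$accession_id == "B", ]
  co <- as.matrix(res$coords[, -1])
  expect_equal(b$mean_dist, sqrt(sum((co[3, ] - co[4, ])^2)),
               tolerance = 1e-9)
  expect_equal(b$var_dist, 0)
})

test_that("near-identical flags follow the IBS threshold exactly", {
  withr::with_seed(31, {
    base <- sample(0:2, 100, replace = TRUE)
    twin <- base
    twin[1] <- (base[1] + 1L) %% 3L          # 1 mismatch in 100 -> IBS 0.99
    other <- sample(0:2, 100, replace = TRUE)
    g <- make_geno(rbind(base, base, twin, other),
                   acc = rep("A", 4), ind = c("i1", "i2", "i3", "i4"))
  })
  fl <- flag_near_identical(g)
  expect_true(any(fl$id1 == "i1" & fl$id2 == "i2" & fl$ibs == 1))
  expect_true(any(fl$ibs == 0.99))
  expect_error(flag_near_identical(g, threshold = 1.5), "threshold")

  # dropping keeps the lexicographically first id of each pair
  g2 <- drop_near_identical(g, fl)
  expect_true("i1" %in% g2$individual_id)
  expect_false("i2" %in% g2$individual_id)

  # a clearly distinct panel yields no flags
  gd <- random_panel(10, 120, n_acc = 2, miss = 0, seed = 5)
  expect_equal(nrow(flag_near_identical(gd)), 0L)
})

test_that("duplicate removal re-analysis is self-consistent", {
  fx <- make_fixture("clones")
  g <- fx$genotypes
  fl <- flag_near_identical(g)
  # the labelled clone pair is recovered
  expect_true(fx$truth$clones$clone_id[1] %in% c(fl$id1, fl$id2))
  cmp <- duplicate_impact(g, fl)
  after <- cmp[cmp$panel == "deduplicated", names(cmp) != "panel"]
  direct <- summarize_diversity(drop_near_identical(g, fl))
  expect_equal(as.data.frame(after), as.data.frame(direct))
})
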