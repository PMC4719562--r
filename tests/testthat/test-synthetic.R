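test_that("the generator is deterministic for a fixed seed", {
  cfg <- sim_config(n_markers = 50L, seed = 123L)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$map, b$map)
  expect_identical(a$accessions, b$accessions)
  expect_identical(a$truth$p0, b$truth$p0)

  # different seeds give different panels
  c_ <- simulate_panel(sim_config(n_markers = 50L, seed = 124L))
  expect_false(identical(a$genotypes, c_$genotypes))
})

test_that("inbreeding and panmixia limits behave as the model dictates", {
  full_inbred <- simulate_panel(sim_config(n_clusters = 1L,
                                           accessions_per_cluster = 4L,
                                           individuals_per_accession = 8L,
                                           n_markers = 100L, f_ct = 0,
                                           f_sc = 0.1, f_is = 1,
                                           missing_rate = 0, seed = 9L))
  m <- geno_matrix(full_inbred$genotypes)
  expect_false(any(m == 1L, na.rm = TRUE))

  # F_CT = F_SC = F_IS = 0: no structure anywhere
  null <- simulate_panel(sim_config(n_clusters = 2L,
                                    accessions_per_cluster = 2L,
                                    individuals_per_accession = 12L,
                                    n_markers = 300L, f_ct = 0, f_sc = 0,
                                    missing_rate = 0, seed = 10L))
  st <- locus_stats(null$genotypes)
  expect_lt(abs(mean(st$f, na.rm = TRUE)), 0.02)
  fst <- pairwise_fst(null$genotypes, null$accessions, "cluster", n_perm = 0)
  expect_lt(abs(fst$fst[1, 2]), 0.01)
})

test_that("realised frequencies obey the Balding-Nichols moments", {
  cfg <- sim_config(f_ct = 0.10, f_sc = 0.15, missing_rate = 0, seed = 21L)
  fx <- simulate_panel(cfg)
  tr <- fx$truth
  p0 <- tr$p0

  # Var(cluster freq) = p0 (1 - p0) F_CT, averaged over loci
  v_cl <- apply(tr$cluster_freq, 2, stats::var)
  ratio_ct <- mean(v_cl / (p0 * (1 - p0)))
  expect_lt(abs(ratio_ct - 0.10), 0.02)

  # Var(accession freq | cluster) = p_c (1 - p_c) F_SC
  cl_of <- tr$cluster_of_accession
  num <- 0; den <- 0
  for (cl in unique(cl_of)) {
    rows <- which(cl_of == cl)
    pc <- tr$cluster_freq[cl, ]
    va <- apply(tr$accession_freq[rows, , drop = FALSE], 2, stats::var)
    ok <- pc > 0.02 & pc < 0.98
    num <- num + sum(va[ok] / (pc[ok] * (1 - pc[ok])))
    den <- den + sum(ok)
  }
  expect_lt(abs(num / den - 0.15), 0.03)

  # mean accession-level He ~ (1 - F_total) * E[2 p0 (1 - p0)]; the
  # unbiased estimator removes the 1/(2n) sampling bias of raw He
  f_total <- 1 - (1 - 0.10) * (1 - 0.15)
  he_hat <- mean(accession_diversity(fx$genotypes, unbiased = TRUE)$he)
  he_exp <- (1 - f_total) * mean(2 * p0 * (1 - p0))
  expect_lt(abs(he_hat - he_exp), 0.02)
})

test_that("ascertainment depletes rare alleles relative to the same law", {
  base <- sim_config(n_markers = 400L, f_ct = 0.1, f_sc = 0.05,
                     ancestral_lo = 0.02, ancestral_hi = 0.98,
                     missing_rate = 0, seed = 33L)
  plain <- simulate_panel(base)
  asc_cfg <- sim_config(n_markers = 400L, f_ct = 0.1, f_sc = 0.05,
                        ancestral_lo = 0.02, ancestral_hi = 0.98,
                        missing_rate = 0,
                        ascertainment = list(enabled = TRUE,
                                             discovery_clusters = 1L,
                                             discovery_n = 8L,
                                             min_minor_copies = 2L),
                        seed = 33L)
  asc <- simulate_panel(asc_cfg)
  rare_frac <- function(g) {
    fr <- allele_freqs(g)
    maf <- pmin(fr$p, 1 - fr$p)
    mean(maf < 0.05, na.rm = TRUE)
  }
  expect_lt(rare_frac(asc$genotypes), rare_frac(plain$genotypes))
  expect_true(asc$truth$acceptance_rate <= 1)

  # an impossible ascertainment demand is rejected with a diagnostic
  impossible <- sim_config(n_markers = 10L,
                           ancestral_lo = 0.0001, ancestral_hi = 0.0002,
                           ascertainment = list(enabled = TRUE,
                                                discovery_clusters = 1L,
                                                discovery_n = 4L,
                                                min_minor_copies = 8L),
                           seed = 2L)
  expect_error(simulate_panel(impossible), "acceptance rate")
})

test_that("fixture registry is deterministic and validates names", {
  t1 <- make_fixture("tiny")
  t2 <- make_fixture("tiny")
  expect_identical(t1$genotypes, t2$genotypes)
  expect_equal(dim(geno_matrix(t1$genotypes)), c(6L, 10L))
  expect_error(make_fixture("nope"), "unknown fixture")

  rye <- make_fixture("rye-like-default")
  expect_equal(nrow(rye$accessions), 24L)
  expect_equal(length(marker_ids(rye$genotypes)), 600L)
  expect_true(all(c("latitude", "longitude") %in% names(rye$accessions)))

  cl <- make_fixture("clones")
  expect_equal(nrow(cl$truth$clones), 1L)
  expect_true(cl$truth$clones$clone_id %in% cl$genotypes$individual_id)
})

test_that("seeds are mandatory and configs are validated", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(f_ct = 1.5, seed = 1), "f_ct")
  expect_error(sim_config(missing_rate = 2, seed = 1), "missing_rate")
})

test_that("panels round-trip through the on-disk form", {
  fx <- make_fixture("tiny")
  dir <- withr::local_tempdir()
  write_panel(fx, dir)
  g <- read_genotypes(file.path(dir, "genotypes.tsv"))
  expect_identical(g, fx$genotypes)
  acc <- read_accessions(file.path(dir, "accessions.tsv"))
  expect_equal(acc$accession_id, fx$accessions$accession_id)
  map <- read_marker_map(file.path(dir, "map.tsv"))
  expect_equal(map$marker_id, fx$map$marker_id)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 101L)
})
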