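map_tbl <- function(n, chr = "1") {
  tibble::tibble(marker_id = sprintf("mk%02d", seq_len(n)),
                 chromosome = chr, position_cm = as.numeric(seq_len(n)))
}

test_that("block construction partitions mapped markers per chromosome", {
  map <- map_tbl(10)
  b2 <- define_blocks(map, map$marker_id, 2L)
  expect_equal(nrow(b2), 5L)
  expect_true(all(lengths(b2$marker_ids) == 2L))
  # disjoint, consecutive in map order
  expect_equal(unlist(b2$marker_ids), map$marker_id)

  map7 <- map_tbl(7)
  b3 <- define_blocks(map7, map7$marker_id, 3L)
  expect_equal(nrow(b3), 2L)
  expect_equal(unlist(b3$marker_ids), map7$marker_id[1:6])

  # all unmapped -> no blocks
  empty <- define_blocks(map7, character(), 2L)
  expect_equal(nrow(empty), 0L)

  # ties in cM broken by marker id
  map_tie <- tibble::tibble(marker_id = c("b", "a"), chromosome = "1",
                            position_cm = c(1, 1))
  bt <- define_blocks(map_tie, map_tie$marker_id, 2L)
  expect_equal(bt$marker_ids[[1]], c("a", "b"))
})

test_that("EM reduces to direct counting when phase is unambiguous", {
  # all homozygous: haplotypes readable off the genotypes
  calls <- rbind(c(0L, 0L), c(0L, 0L), c(2L, 2L), c(0L, 2L))
  g <- make_geno(calls)
  hf <- haplotype_freqs(g, c("mk01", "mk02"))
  f <- stats::setNames(hf$freqs$freq, hf$freqs$haplotype)
  expect_equal(unname(f["00"]), 4 / 8)
  expect_equal(unname(f["11"]), 2 / 8)
  expect_equal(unname(f["01"]), 2 / 8)
  expect_true(hf$converged)
  expect_equal(sum(hf$freqs$freq), 1, tolerance = 1e-9)

  # single-SNP block equals allele frequencies
  g1 <- make_geno(matrix(c(0L, 1L, 2L, 1L), 4, 1))
  hf1 <- haplotype_freqs(g1, "mk01")
  expect_equal(hf1$freqs$freq, c(4 / 8, 4 / 8))

  # no double heterozygote: phase resolvable, EM equals counting
  calls2 <- rbind(c(1L, 0L), c(0L, 1L), c(2L, 0L), c(0L, 0L))
  g2 <- make_geno(calls2)
  hf2 <- haplotype_freqs(g2, c("mk01", "mk02"))
  f2 <- stats::setNames(hf2$freqs$freq, hf2$freqs$haplotype)
  # chromosomes: (00,10), (00,01), (10,10), (00,00)
  expect_equal(unname(f2["00"]), 4 / 8, tolerance = 1e-6)
  expect_equal(unname(f2["10"]), 3 / 8, tolerance = 1e-6)
  expect_equal(unname(f2["01"]), 1 / 8, tolerance = 1e-6)
})

test_that("EM matches a brute-force likelihood maximiser on ambiguous data", {
  # one (hom_ref, hom_ref) individual, one double heterozygote
  calls <- rbind(c(0L, 0L), c(1L, 1L))
  g <- make_geno(calls)
  hf <- haplotype_freqs(g, c("mk01", "mk02"), n_restarts = 10, seed = 2)
  oracle <- brute_hap_ml(calls)
  expect_equal(hf$loglik, oracle$loglik, tolerance = 1e-5)
  expect_equal(1 - sum(hf$freqs$freq^2), 1 - sum(oracle$f^2),
               tolerance = 1e-3)

  # individuals missing a member call are excluded per block
  calls3 <- rbind(c(0L, 0L), c(1L, NA_integer_), c(2L, 2L))
  g3 <- make_geno(calls3)
  hf3 <- haplotype_freqs(g3, c("mk01", "mk02"))
  expect_equal(hf3$n_individuals, 2L)
  expect_error(haplotype_freqs(make_geno(rbind(c(NA_integer_, 0L))),
                               c("mk01", "mk02")), "no individuals")
})

test_that("genotype-string mode counts complete multilocus genotypes", {
  calls <- rbind(c(0L, 0L), c(0L, 0L), c(1L, 1L), c(2L, 0L))
  g <- make_geno(calls)
  hf <- haplotype_freqs(g, c("mk01", "mk02"), method = "genotype_string")
  f <- stats::setNames(hf$freqs$freq, hf$freqs$haplotype)
  expect_equal(unname(f["00"]), 0.5)
  expect_equal(unname(f["11"]), 0.25)
  expect_equal(unname(f["20"]), 0.25)
})

test_that("haplotype diversity ratio at k = 1 equals the SNP-level ratio", {
  fx <- simulate_panel(sim_config(n_clusters = 2L,
                                  accessions_per_cluster = 4L,
                                  individuals_per_accession = 6L,
                                  n_markers = 60L, f_ct = 0.1, f_sc = 0.05,
                                  missing_rate = 0, seed = 31L))
  g <- fx$genotypes
  bc <- bias_curves(g, fx$map, fx$accessions, "cluster",
                    reference = "cluster1", ks = 1L)
  # SNP-level He on the same mapped loci
  blocks <- define_blocks(fx$map, marker_ids(g), 1L)
  loci <- unlist(blocks$marker_ids)
  grp <- split(fx$accessions$accession_id, fx$accessions$cluster)
  he_of <- function(accs) {
    members <- g$individual_id[g$accession_id %in% accs]
    st <- locus_stats(g, members)
    mean(st$he[match(loci, st$marker_id)])
  }
  snp_ratio <- he_of(grp$cluster2) / he_of(grp$cluster1)
  expect_equal(bc$ratio[bc$group == "cluster2" & bc$k == 1], snp_ratio,
               tolerance = 1e-9)
})

test_that("groups with identical frequency structure give ratios near 1", {
  fx <- simulate_panel(sim_config(n_clusters = 1L,
                                  accessions_per_cluster = 8L,
                                  individuals_per_accession = 6L,
                                  n_markers = 200L, f_ct = 0, f_sc = 0.05,
                                  missing_rate = 0, seed = 17L))
  acc <- fx$accessions
  acc$half <- rep(c("g1", "g2"), each = 4L)      # arbitrary split
  bc <- bias_curves(fx$genotypes, fx$map, acc, "half", reference = "g1",
                    ks = 1:3)
  expect_true(all(abs(bc$ratio - 1) < 0.05))
})
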