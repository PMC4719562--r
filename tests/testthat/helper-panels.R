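# Small panel builders and independent brute-force oracles used across
# the test files. The oracles deliberately use naive loops and the
# definitional formulas, never the package's optimised code paths.

# Build a genotype tibble from a dosage matrix (rows = individuals).
make_geno <- function(calls, acc = NULL, ind = NULL, mk = NULL) {
  calls <- as.matrix(calls)
  if (is.null(acc)) acc <- rep("ACC1", nrow(calls))
  if (is.null(ind)) ind <- sprintf("ind%02d", seq_len(nrow(calls)))
  if (is.null(mk)) mk <- sprintf("mk%02d", seq_len(ncol(calls)))
  as_genotypes(calls, accession_of = acc, individual_ids = ind,
               marker_ids = mk)
}

# Random panel with optional missing data; always polymorphic overall.
random_panel <- function(n_ind, n_mk, n_acc = 2, miss = 0, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      calls <- matrix(sample(0:2, n_ind * n_mk, replace = TRUE), n_ind, n_mk)
      if (miss > 0) calls[runif(length(calls)) < miss] <- NA
      ok_mk <- apply(calls, 2, function(x) sum(!is.na(x)) > 0)
      ok_ind <- apply(calls, 1, function(x) sum(!is.na(x)) > 0)
      if (all(ok_mk) && all(ok_ind)) break
    }
    acc <- rep(sprintf("ACC%d", seq_len(n_acc)), length.out = n_ind)
    make_geno(calls, acc = sort(acc))
  })
}

# --- oracles -----------------------------------------------------------

# Gene diversity via generic allele counting (1 - sum of allele freqs^2).
brute_he <- function(calls_col) {
  x <- calls_col[!is.na(calls_col)]
  if (!length(x)) return(NA_real_)
  alleles <- c(rep(0, 2 * sum(x == 0) + sum(x == 1)),
               rep(1, 2 * sum(x == 2) + sum(x == 1)))
  fr <- table(alleles) / length(alleles)
  1 - sum(fr^2)
}

# Squared genotypic distance between two dosage vectors, shared loci.
brute_sqdist <- function(x, y) {
  s <- 0
  any_shared <- FALSE
  for (l in seq_along(x)) {
    if (!is.na(x[l]) && !is.na(y[l])) {
      any_shared <- TRUE
      s <- s + (x[l] - y[l])^2
    }
  }
  if (!any_shared) stop("no shared loci")
  unname(s)
}

# Sum over unordered within-set pairs of d2.
.sum_pairs <- function(d2, idx) {
  s <- 0
  for (a in idx) for (b in idx) s <- s + d2[a, b]
  s / 2
}

# Two-level AMOVA from the definitional sums of squares.
brute_amova2 <- function(d2, pop) {
  n <- length(pop)
  pops <- unique(pop)
  ss_total <- .sum_pairs(d2, seq_len(n)) / n
  ss_wp <- 0
  for (pz in pops) {
    idx <- which(pop == pz)
    ss_wp <- ss_wp + .sum_pairs(d2, idx) / length(idx)
  }
  ss_ap <- ss_total - ss_wp
  g <- length(pops)
  sizes <- sapply(pops, function(pz) sum(pop == pz))
  n0 <- (n - sum(sizes^2) / n) / (g - 1)
  sigma_w <- ss_wp / (n - g)
  sigma_a <- (ss_ap / (g - 1) - sigma_w) / n0
  list(ss_among = ss_ap, ss_within = ss_wp,
       sigma_a = sigma_a, sigma_w = sigma_w,
       phi_pt = sigma_a / (sigma_a + sigma_w))
}

# Three-level AMOVA from the definitional sums of squares.
brute_amova3 <- function(d2, acc, grp) {
  n <- length(acc)
  ss_total <- .sum_pairs(d2, seq_len(n)) / n
  ss_wp <- 0
  for (az in unique(acc)) {
    idx <- which(acc == az)
    ss_wp <- ss_wp + .sum_pairs(d2, idx) / length(idx)
  }
  ss_wg <- 0
  for (gz in unique(grp)) {
    idx <- which(grp == gz)
    ss_wg <- ss_wg + .sum_pairs(d2, idx) / length(idx)
  }
  ss_ap <- ss_wg - ss_wp
  ss_ag <- ss_total - ss_wg
  accs <- unique(acc)
  grps <- unique(grp)
  a_ <- length(accs)
  g_ <- length(grps)
  n_a <- sapply(accs, function(az) sum(acc == az))
  grp_of_acc <- sapply(accs, function(az) grp[acc == az][1])
  n_g <- sapply(grps, function(gz) sum(grp == gz))
  sga_over_ng <- sum(sapply(grps, function(gz) {
    sum(n_a[grp_of_acc == gz]^2) / n_g[grps == gz]
  }))
  n1 <- (n - sga_over_ng) / (a_ - g_)
  n2 <- (sga_over_ng - sum(n_a^2) / n) / (g_ - 1)
  n3 <- (n - sum(n_g^2) / n) / (g_ - 1)
  sigma_w <- ss_wp / (n - a_)
  sigma_a <- (ss_ap / (a_ - g_) - sigma_w) / n1
  sigma_g <- (ss_ag / (g_ - 1) - sigma_w - n2 * sigma_a) / n3
  list(ss_ag = ss_ag, ss_ap = ss_ap, ss_wp = ss_wp,
       sigma_g = sigma_g, sigma_a = sigma_a, sigma_w = sigma_w,
       phi_ct = sigma_g / (sigma_g + sigma_a + sigma_w))
}

# Nei's standard distance from first principles.
brute_nei <- function(fx, fy) {
  ok <- !is.na(fx) & !is.na(fy)
  jx <- 0; jy <- 0; jxy <- 0; L <- 0
  for (l in which(ok)) {
    jx <- jx + fx[l]^2 + (1 - fx[l])^2
    jy <- jy + fy[l]^2 + (1 - fy[l])^2
    jxy <- jxy + fx[l] * fy[l] + (1 - fx[l]) * (1 - fy[l])
    L <- L + 1
  }
  unname(-log((jxy / L) / sqrt((jx / L) * (jy / L))))
}

# All permutations of a vector (for the exhaustive Mantel oracle).
all_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# ML haplotype frequencies for a 2-SNP block by grid + polish on the
# 4-haplotype simplex (independent of the EM implementation).
brute_hap_ml <- function(geno_rows) {
  pairs_of <- function(gvec) {
    # haplotypes ordered 00, 01, 10, 11 (index 1..4)
    idx <- function(h) h[1] * 2 + h[2] + 1
    het <- which(gvec == 1)
    base <- ifelse(gvec == 2, 1, 0)
    if (!length(het)) return(matrix(rep(idx(base), 2), ncol = 2))
    combos <- expand.grid(rep(list(0:1), length(het)))
    out <- NULL
    for (r in seq_len(nrow(combos))) {
      h1 <- base; h2 <- base
      h1[het] <- as.numeric(combos[r, ])
      h2[het] <- 1 - as.numeric(combos[r, ])
      i1 <- idx(h1); i2 <- idx(h2)
      out <- rbind(out, c(min(i1, i2), max(i1, i2)))
    }
    unique(out)
  }
  plist <- apply(geno_rows, 1, pairs_of, simplify = FALSE)
  loglik <- function(f) {
    ll <- 0
    for (pr in plist) {
      lik <- 0
      for (r in seq_len(nrow(pr))) {
        mult <- if (pr[r, 1] == pr[r, 2]) 1 else 2
        lik <- lik + mult * f[pr[r, 1]] * f[pr[r, 2]]
      }
      if (lik <= 0) return(-Inf)
      ll <- ll + log(lik)
    }
    ll
  }
  softmax <- function(t) { e <- exp(t - max(t)); e / sum(e) }
  best <- list(value = -Inf)
  for (s in 1:20) {
    t0 <- withr::with_seed(s, stats::rnorm(4))
    opt <- stats::optim(t0, function(t) -loglik(softmax(t)),
                        method = "BFGS", control = list(maxit = 500))
    if (-opt$value > best$value) {
      best <- list(value = -loglik(softmax(opt$par)) * -1,
                   f = softmax(opt$par))
    }
  }
  list(f = best$f, loglik = best$value)
}

# Pearson r from the textbook formula.
brute_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
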