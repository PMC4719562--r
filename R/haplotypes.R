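#' Partition mapped markers into haplotype blocks
#'
#' Per chromosome, mapped markers are sorted by centimorgan position
#' (ties broken by marker id) and partitioned into consecutive,
#' non-overlapping windows of exactly `k` markers; trailing remainder
#' markers are dropped. Markers absent from the map are never used.
#'
#' @param map Marker map tibble (`marker_id`, `chromosome`, `position_cm`).
#' @param markers Character vector of markers available in the genotype
#'   table (blocks are built only from these).
#' @param k Block length in SNPs (1 to 5).
#' @return Tibble with `block_id`, `chromosome`, `k` and a `marker_ids`
#'   list-column of the `k` member markers in map order. May be empty.
#' @export
define_blocks <- function(map, markers, k) {
  stopifnot(k >= 1, k <= 5)
  map <- map[map$marker_id %in% markers & !is.na(map$chromosome) &
               !is.na(map$position_cm), , drop = FALSE]
  map <- map[order(map$chromosome, map$position_cm, map$marker_id), , drop = FALSE]
  out <- purrr::map_dfr(split(map, map$chromosome), function(chr) {
    n_blocks <- nrow(chr) %/% k
    if (!n_blocks) return(tibble::tibble())
    idx <- seq_len(n_blocks * k)
    tibble::tibble(chromosome = chr$chromosome[1],
                   block_index = rep(seq_len(n_blocks), each = k),
                   marker_id = chr$marker_id[idx]) |>
      dplyr::group_by(.data$chromosome, .data$block_index) |>
      dplyr::summarise(marker_ids = list(.data$marker_id), .groups = "drop")
  })
  if (!nrow(out)) {
    return(tibble::tibble(block_id = character(), chromosome = character(),
                          k = integer(), marker_ids = list()))
  }
  tibble::tibble(block_id = sprintf("%s_k%d_b%02d", out$chromosome, k,
                                    out$block_index),
                 chromosome = as.character(out$chromosome),
                 k = as.integer(k),
                 marker_ids = out$marker_ids)
}

# All 2^k haplotypes as a k-column 0/1 matrix, row i encoding i-1 in binary
# (first marker = most significant bit); row names are the allele strings.
.hap_space <- function(k) {
  h <- as.matrix(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE])
  dimnames(h) <- list(apply(h, 1L, paste, collapse = ""), NULL)
  h
}

# Unordered haplotype pairs compatible with an unphased genotype vector
# (dosages 0/1/2, no missing): a two-column index matrix into .hap_space(k).
.compatible_pairs <- function(gvec, hap) {
  k <- length(gvec)
  het <- which(gvec == 1L)
  base <- ifelse(gvec == 2L, 1L, 0L)
  if (!length(het)) {
    i <- sum(base * 2^(rev(seq_len(k)) - 1)) + 1L
    return(matrix(c(i, i), ncol = 2L))
  }
  assign <- as.matrix(expand.grid(rep(list(0:1), length(het))))
  h1 <- matrix(base, nrow(assign), k, byrow = TRUE)
  h2 <- h1
  h1[, het] <- assign
  h2[, het] <- 1L - assign
  pow <- 2^(rev(seq_len(k)) - 1)
  i1 <- as.integer(h1 %*% pow) + 1L
  i2 <- as.integer(h2 %*% pow) + 1L
  keep <- i1 <= i2                    # unordered: each pair once
  cbind(i1[keep], i2[keep])
}

.em_once <- function(pairs_by_geno, geno_count, f0, n_hap, tol, max_iter) {
  n_chrom <- 2 * sum(geno_count)
  f <- f0
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    counts <- numeric(n_hap)
    ll <- 0
    for (gi in seq_along(pairs_by_geno)) {
      pr <- pairs_by_geno[[gi]]
      w <- f[pr[, 1L]] * f[pr[, 2L]] * ifelse(pr[, 1L] == pr[, 2L], 1, 2)
      tot <- sum(w)
      if (tot <= 0) {                 # genotype stranded by zero freqs
        w <- rep(1 / length(w), length(w))
        tot <- .Machine$double.xmin
      } else {
        w <- w / tot
      }
      ll <- ll + geno_count[gi] * log(tot)
      inc <- geno_count[gi] * w
      for (r in seq_len(nrow(pr))) {
        counts[pr[r, 1L]] <- counts[pr[r, 1L]] + inc[r]
        counts[pr[r, 2L]] <- counts[pr[r, 2L]] + inc[r]
      }
    }
    f <- counts / n_chrom
    if (is.finite(ll_old) && ll < ll_old - 1e-9) {
      stop("EM log-likelihood decreased; numerical failure", call. = FALSE)
    }
    if (abs(ll - ll_old) < tol) {
      return(list(f = f, loglik = ll, n_iter = iter, converged = TRUE))
    }
    ll_old <- ll
  }
  list(f = f, loglik = ll_old, n_iter = max_iter, converged = FALSE)
}

#' Haplotype frequencies from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies for a block of `k` SNPs via
#' the Excoffier-Slatkin EM algorithm over the `2^k`-haplotype simplex:
#' the E-step distributes each multilocus genotype over its compatible
#' haplotype pairs in proportion to the current pair probabilities, the
#' M-step re-estimates frequencies from the expected haplotype counts.
#' Individuals missing any member call are excluded from the block. The
#' best of `n_restarts` runs (uniform start plus random starts) is kept.
#'
#' `method = "genotype_string"` is a simpler alternative that treats each
#' complete multilocus genotype string as one allele of a multi-allelic
#' locus and counts it directly (no phase resolution).
#'
#' @param g Genotype tibble.
#' @param markers Ordered character vector of the block's member markers.
#' @param individuals Optional subset of individuals.
#' @param method `"em"` (default) or `"genotype_string"`.
#' @param tol Log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param n_restarts Restarts (default 5: uniform + 4 random).
#' @param seed Seed for the random restarts (default 1).
#' @return List of class `"hap_freqs"`: `freqs` tibble
#'   (`haplotype`, `freq`), `loglik`, `n_iter`, `converged`,
#'   `n_individuals`, `method`.
#' @export
haplotype_freqs <- function(g, markers, individuals = NULL,
                            method = c("em", "genotype_string"),
                            tol = 1e-8, max_iter = 500L, n_restarts = 5L,
                            seed = 1L) {
  method <- match.arg(method)
  m <- .subset_matrix(g, individuals)
  m <- m[, markers, drop = FALSE]
  complete <- rowSums(is.na(m)) == 0L
  m <- m[complete, , drop = FALSE]
  if (!nrow(m)) stop("no individuals with complete calls at the block", call. = FALSE)
  k <- length(markers)

  if (method == "genotype_string") {
    gs <- apply(m, 1L, paste, collapse = "")
    tab <- table(gs)
    f <- as.numeric(tab) / sum(tab)
    return(structure(list(
      freqs = tibble::tibble(haplotype = names(tab), freq = f),
      loglik = sum(as.numeric(tab) * log(f)),
      n_iter = 0L, converged = TRUE, n_individuals = nrow(m),
      method = method), class = "hap_freqs"))
  }

  hap <- .hap_space(k)
  n_hap <- nrow(hap)
  gs <- apply(m, 1L, paste, collapse = "")
  geno_count <- table(gs)
  uniq <- m[match(names(geno_count), gs), , drop = FALSE]
  pairs_by_geno <- lapply(seq_len(nrow(uniq)),
                          function(i) .compatible_pairs(uniq[i, ], hap))
  geno_count <- as.numeric(geno_count)

  run <- function(f0) .em_once(pairs_by_geno, geno_count, f0, n_hap, tol, max_iter)
  best <- run(rep(1 / n_hap, n_hap))
  if (n_restarts > 1L) {
    withr::with_seed(seed, {
      for (r in seq_len(n_restarts - 1L)) {
        f0 <- stats::rgamma(n_hap, 1)
        cand <- run(f0 / sum(f0))
        if (cand$loglik > best$loglik) best <- cand
      }
    })
  }
  structure(list(
    freqs = tibble::tibble(haplotype = rownames(hap), freq = best$f),
    loglik = best$loglik, n_iter = best$n_iter, converged = best$converged,
    n_individuals = nrow(m), method = method), class = "hap_freqs")
}

#' @export
print.hap_freqs <- function(x, ...) {
  cat(sprintf("haplotype frequencies (%s, %d individuals, loglik %.4f)\n",
              x$method, x$n_individuals, x$loglik))
  print(x$freqs[x$freqs$freq > 1e-6, ])
  invisible(x)
}

.hap_he <- function(hf) 1 - sum(hf$freqs$freq^2)

#' Haplotype-diversity curves as an ascertainment-bias diagnostic
#'
#' For each group and each block length `k`, computes the mean across
#' blocks of the haplotype gene diversity `1 - sum(f_h^2)` from that
#' group's estimated haplotype frequencies, and its ratio to a reference
#' group. SNPs discovered in a narrow panel under-represent rare alleles
#' in other groups, depressing their SNP-level diversity; merging
#' neighbouring SNPs into longer haplotypes dampens this distortion, so
#' a ratio that climbs with `k` flags ascertainment bias against the
#' non-reference group.
#'
#' @param g Genotype tibble.
#' @param map Marker map tibble.
#' @param accessions Accession passport tibble (when grouping).
#' @param group_by Grouping column name; `NULL` is not allowed here
#'   (ratios need at least two groups).
#' @param reference Label of the reference group for the ratio.
#' @param ks Integer vector of block lengths (default `1:5`).
#' @param method,tol,max_iter,n_restarts,seed Passed to
#'   [haplotype_freqs()].
#' @return Tibble of class `"bias_curves"` with `group`, `k`, `n_blocks`,
#'   `he`, `ratio`.
#' @export
bias_curves <- function(g, map, accessions = NULL, group_by = NULL,
                        reference, ks = 1:5,
                        method = c("em", "genotype_string"),
                        tol = 1e-8, max_iter = 500L, n_restarts = 5L,
                        seed = 1L) {
  method <- match.arg(method)
  grouping <- .grouping_table(g, accessions, group_by)
  groups <- split(grouping$accession_id, grouping$group)
  if (!reference %in% names(groups)) {
    stop("reference group '", reference, "' not found", call. = FALSE)
  }
  rows <- purrr::map_dfr(ks, function(k) {
    blocks <- define_blocks(map, marker_ids(g), k)
    purrr::map_dfr(names(groups), function(grp) {
      members <- g$individual_id[g$accession_id %in% groups[[grp]]]
      hes <- purrr::map_dbl(blocks$marker_ids, function(mk) {
        hf <- tryCatch(
          haplotype_freqs(g, mk, individuals = members, method = method,
                          tol = tol, max_iter = max_iter,
                          n_restarts = n_restarts, seed = seed),
          error = function(e) NULL)
        if (is.null(hf)) NA_real_ else .hap_he(hf)
      })
      tibble::tibble(group = grp, k = k,
                     n_blocks = sum(!is.na(hes)),
                     he = mean(hes, na.rm = TRUE))
    })
  })
  ref_he <- rows$he[rows$group == reference]
  names(ref_he) <- rows$k[rows$group == reference]
  if (any(ref_he == 0, na.rm = TRUE)) {
    stop("reference group has zero haplotype diversity at some k", call. = FALSE)
  }
  rows$ratio <- unname(rows$he / ref_he[as.character(rows$k)])
  attr(rows, "reference") <- reference
  class(rows) <- c("bias_curves", class(rows))
  rows
}

#' @rdname bias_curves
#' @param object,... Passed from the `autoplot` generic.
#' @export
autoplot.bias_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$ratio,
                                       colour = .data$group)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "haplotype length (SNPs)",
                  y = paste0("gene diversity relative to ",
                             attr(object, "reference")),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
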