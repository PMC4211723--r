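#' Per-locus allele frequencies
#'
#' Frequencies are computed from all typed gene copies at each locus;
#' monomorphic loci are permitted (single allele with frequency 1).
#'
#' @param g a [genotype_table()].
#' @return object of class `allele_frequencies`: list with `freq` (per locus,
#'   a named numeric vector summing to 1) and `n_copies` (typed gene copies
#'   per locus).
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_table"))
  freq <- vector("list", length(g$loci))
  names(freq) <- g$loci
  n_copies <- integer(length(g$loci))
  names(n_copies) <- g$loci
  for (j in seq_along(g$loci)) {
    copies <- c(g$a1[, j], g$a2[, j])
    copies <- copies[!is.na(copies)]
    if (length(copies) == 0) stop("locus entirely missing: ", g$loci[j])
    tab <- table(copies)
    freq[[j]] <- as.numeric(tab) / length(copies)
    names(freq[[j]]) <- names(tab)
    n_copies[j] <- length(copies)
  }
  structure(list(freq = freq, n_copies = n_copies),
            class = "allele_frequencies")
}

#' Multilocus and single-locus heterozygosity
#'
#' MLH is the fraction of an individual's typed loci at which it is
#' heterozygous; SLH is the per-locus 0/1 heterozygosity indicator (NA where
#' the call is missing). MLH is always the mean of the non-missing SLH
#' entries, i.e. it renormalises per individual over typed loci.
#'
#' @param g a [genotype_table()].
#' @return object of class `het_profile`: list with `mlh` (named vector),
#'   `slh` (individuals x loci 0/1/NA matrix) and `n_typed` (typed loci per
#'   individual).
#' @export
heterozygosity_profile <- function(g) {
  stopifnot(inherits(g, "genotype_table"))
  slh <- (g$a1 != g$a2) * 1L
  n_typed <- rowSums(!is.na(slh))
  if (any(n_typed == 0)) {
    stop("individual(s) with zero typed loci: ",
         paste(g$ids[n_typed == 0], collapse = ", "))
  }
  mlh <- rowMeans(slh, na.rm = TRUE)
  structure(list(mlh = mlh, slh = slh, n_typed = n_typed),
            class = "het_profile")
}

#' @export
as.data.frame.het_profile <- function(x, ...) {
  data.frame(id = names(x$mlh), mlh = unname(x$mlh),
             n_typed = unname(x$n_typed), row.names = NULL)
}

# log multinomial probability of a genotype array conditional on allele counts
# (Levene's exact distribution): counts is a K x K upper-triangular matrix.
log_array_prob <- function(counts, allele_counts) {
  n <- sum(counts)
  H <- sum(counts[upper.tri(counts)])
  lfactorial(n) + H * log(2) + sum(lfactorial(allele_counts)) -
    lfactorial(2 * n) - sum(lfactorial(counts[upper.tri(counts, diag = TRUE)]))
}

# enumerate every genotype array with the given allele counts, calling
# fn(logp) per array; aborts (returns FALSE) if more than max_arrays visited
enumerate_genotype_arrays <- function(allele_counts, fn, max_arrays = 1e5) {
  K <- length(allele_counts)
  counts <- matrix(0L, K, K)
  n_seen <- 0L
  n_nodes <- 0L
  node_budget <- 10 * max_arrays   # abort infeasible searches early
  cells <- which(upper.tri(counts, diag = TRUE), arr.ind = TRUE)
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  rec <- function(cell, remaining) {
    n_nodes <<- n_nodes + 1L
    if (n_seen > max_arrays || n_nodes > node_budget) return(FALSE)
    if (cell > nrow(cells)) {
      if (all(remaining == 0)) {
        n_seen <<- n_seen + 1L
        if (n_seen > max_arrays) return(FALSE)
        fn(log_array_prob(counts, allele_counts))
      }
      return(TRUE)
    }
    k <- cells[cell, 1]; l <- cells[cell, 2]
    if (k == l) {
      cap <- remaining[k] %/% 2L
      # last cell of row k is (k, K); if K == k the row ends here
      for (v in 0:cap) {
        counts[k, k] <<- v
        rem <- remaining; rem[k] <- rem[k] - 2L * v
        if (!rec(cell + 1L, rem)) return(FALSE)
      }
      counts[k, k] <<- 0L
    } else {
      cap <- min(remaining[k], remaining[l])
      last_of_row <- l == K
      for (v in 0:cap) {
        rem <- remaining
        rem[k] <- rem[k] - v; rem[l] <- rem[l] - v
        if (last_of_row && rem[k] != 0L) next  # row k must be exhausted
        counts[k, l] <<- v
        if (!rec(cell + 1L, rem)) return(FALSE)
      }
      counts[k, l] <<- 0L
    }
    TRUE
  }
  completed <- rec(1L, as.integer(allele_counts))
  list(completed = completed, n_arrays = n_seen)
}

#' Exact Hardy-Weinberg equilibrium test at one locus
#'
#' Conditional exact test on the observed allele counts (Levene's
#' distribution): the p-value is the total probability of genotype arrays no
#' more probable than the observed one. Arrays are fully enumerated when
#' their number does not exceed `max_arrays`; otherwise a Monte-Carlo version
#' draws `n_mc` random pairings of the observed gene copies.
#'
#' @param g a [genotype_table()].
#' @param locus locus name.
#' @param n_mc Monte-Carlo trials used when enumeration is infeasible.
#' @param seed integer RNG seed (Monte-Carlo path only).
#' @param max_arrays enumeration bound on the number of genotype arrays.
#' @return list with `p_value`, `method` (`"exact"` or `"mc"`), and
#'   `n_arrays` or `n_mc`.
#' @export
hwe_exact_test <- function(g, locus, n_mc = 1e4, seed = 1L, max_arrays = 1e5) {
  stopifnot(inherits(g, "genotype_table"))
  j <- match(locus, g$loci)
  if (is.na(j)) stop("unknown locus: ", locus)
  a1 <- g$a1[, j]; a2 <- g$a2[, j]
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  if (length(a1) < 2) stop("need >= 2 typed individuals at locus ", locus)
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) == 1) {
    warning("monomorphic locus ", locus, "; HWE p-value is 1")
    return(list(p_value = 1, method = "exact", n_arrays = 1L))
  }
  K <- length(alleles)
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  obs <- matrix(0L, K, K)
  for (r in seq_along(i1)) {
    k <- min(i1[r], i2[r]); l <- max(i1[r], i2[r])
    obs[k, l] <- obs[k, l] + 1L
  }
  allele_counts <- tabulate(c(i1, i2), nbins = K)
  logp_obs <- log_array_prob(obs, allele_counts)
  tol <- 1e-9

  if (K == 2) {
    # biallelic: arrays are indexed by the heterozygote count n12, which
    # shares the parity of the allele counts
    cmin <- min(allele_counts)
    n_arrays <- cmin %/% 2 + 1
    if (n_arrays <= max_arrays) {
      p <- 0
      for (n12 in seq(cmin %% 2, cmin, by = 2)) {
        cnt <- matrix(0L, 2, 2)
        cnt[1, 1] <- (allele_counts[1] - n12) %/% 2
        cnt[2, 2] <- (allele_counts[2] - n12) %/% 2
        cnt[1, 2] <- n12
        lp <- log_array_prob(cnt, allele_counts)
        if (lp <= logp_obs + tol) p <- p + exp(lp)
      }
      return(list(p_value = min(1, p), method = "exact",
                  n_arrays = n_arrays))
    }
  } else {
    # cheap upper bound on the array count decides whether full
    # enumeration is worth attempting
    caps <- numeric(0)
    for (k in seq_len(K)) for (l in k:K) {
      caps <- c(caps, if (k == l) allele_counts[k] %/% 2
                else min(allele_counts[k], allele_counts[l]))
    }
    if (sum(log(caps + 1)) <= log(max_arrays)) {
      acc <- new.env()
      acc$p <- 0
      res <- enumerate_genotype_arrays(allele_counts, function(lp) {
        if (lp <= logp_obs + tol) acc$p <- acc$p + exp(lp)
      }, max_arrays = max_arrays)
      if (res$completed) {
        return(list(p_value = min(1, acc$p), method = "exact",
                    n_arrays = res$n_arrays))
      }
    }
  }

  # Monte-Carlo: random re-pairings of the observed gene copies, vectorised
  copies <- c(i1, i2)
  n <- length(i1)
  const <- lfactorial(n) + sum(lfactorial(allele_counts)) - lfactorial(2 * n)
  odd <- seq(1, 2 * n, 2); even <- odd + 1L
  hits <- 0L
  with_seed(seed, {
    for (t in seq_len(n_mc)) {
      perm <- sample(copies)
      a <- perm[odd]; b <- perm[even]
      k <- pmin(a, b); l <- pmax(a, b)
      cnt <- tabulate((k - 1L) * K + l, nbins = K * K)
      lp <- const + sum(k != l) * log(2) - sum(lfactorial(cnt))
      if (lp <= logp_obs + tol) hits <- hits + 1L
    }
  })
  list(p_value = (1 + hits) / (n_mc + 1), method = "mc", n_mc = n_mc)
}

# Weir & Cockerham (1984) within-population variance components at one locus
# for a single sample: per allele, b = n/(n-1) [p(1-p) - (2n-1)/(4n) hbar],
# c = hbar/2, and f = 1 - sum(c)/sum(b + c) over alleles (and loci).
wc_components_locus <- function(a1, a2) {
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  if (n < 2) return(NULL)
  alleles <- unique(c(a1, a2))
  if (length(alleles) < 2) return(NULL)
  b <- c_ <- numeric(length(alleles))
  for (k in seq_along(alleles)) {
    al <- alleles[k]
    p <- (sum(a1 == al) + sum(a2 == al)) / (2 * n)
    hbar <- mean((a1 == al) != (a2 == al))
    b[k] <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * hbar)
    c_[k] <- hbar / 2
  }
  c(b = sum(b), c = sum(c_))
}

#' Multilocus F_IS (Weir & Cockerham 1984)
#'
#' Within-group inbreeding coefficient f, combining loci by summing the
#' Weir-Cockerham variance components before forming the ratio. Negative
#' values indicate heterozygote excess relative to Hardy-Weinberg
#' proportions.
#'
#' @param g a [genotype_table()].
#' @param group optional group label; if `NULL`, all individuals are used.
#' @return scalar f.
#' @export
fis <- function(g, group = NULL) {
  stopifnot(inherits(g, "genotype_table"))
  if (!is.null(group)) {
    if (is.null(g$group)) stop("genotype table has no group labels")
    keep <- which(!is.na(g$group) & g$group == group)
    if (length(keep) < 2) stop("group has fewer than 2 individuals: ", group)
    g <- subset_individuals(g, keep)
  }
  comp <- vapply(seq_along(g$loci),
                 function(j) {
                   x <- wc_components_locus(g$a1[, j], g$a2[, j])
                   if (is.null(x)) c(b = 0, c = 0) else x
                 }, numeric(2))
  b_sum <- sum(comp["b", ]); c_sum <- sum(comp["c", ])
  if (b_sum + c_sum == 0) {
    stop("all loci monomorphic (or untyped) within group; F_IS undefined")
  }
  1 - c_sum / (b_sum + c_sum)
}

# core g2 statistic from a 0/1 heterozygosity matrix with NA for missing:
# ratio of the within-individual cross-locus mean product to the
# cross-individual one, each weighted by the corresponding typed-cell
# counts, minus 1.
g2_statistic <- function(slh) {
  H <- slh; H[is.na(H)] <- 0
  M <- (!is.na(slh)) * 1
  HtH <- crossprod(H)          # sum_i h_ik h_il
  MtM <- crossprod(M)          # sum_i m_ik m_il
  ch <- colSums(H); cm <- colSums(M)
  off <- function(A) sum(A) - sum(diag(A))
  within <- off(HtH)
  w_within <- off(MtM)
  cross <- off(outer(ch, ch)) - within
  w_cross <- off(outer(cm, cm)) - off(MtM)
  if (w_within == 0 || cross == 0) return(NA_real_)
  (within / w_within) / (cross / w_cross) - 1
}

#' g2 identity disequilibrium
#'
#' Multilocus estimator of identity disequilibrium (excess covariance in
#' heterozygosity among loci) for codominant panels with missing data,
#' following the covariance-ratio formulation of David et al. (2007): the
#' typed-cell-weighted mean cross-locus product of heterozygosity indicators
#' within individuals, divided by the analogous cross-individual product,
#' minus one. A value of zero means no variance in inbreeding; positive
#' values validate the use of multilocus heterozygosity as an inbreeding
#' proxy. The permutation null shuffles each locus's heterozygosity column
#' independently across individuals, destroying among-locus covariance while
#' preserving per-locus heterozygosity and missingness.
#'
#' @param g a [genotype_table()].
#' @param n_permutations permutations for the p-value.
#' @param seed integer RNG seed.
#' @return list with `g2`, `p_value`, `n_permutations`, `seed`, and the
#'   permuted statistics `perm` (for diagnostics).
#' @export
g2_identity_disequilibrium <- function(g, n_permutations = 1000, seed = 1L) {
  stopifnot(inherits(g, "genotype_table"))
  if (length(g$ids) < 10) stop("need >= 10 individuals for g2")
  hp <- heterozygosity_profile(g)
  slh <- hp$slh
  poly <- apply(slh, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0 && any(x == 1)
  })
  if (sum(poly) < 2) stop("need >= 2 polymorphic loci for g2")
  slh <- slh[, poly, drop = FALSE]
  obs <- g2_statistic(slh)
  if (!is.finite(obs)) stop("g2 undefined for this table")
  n <- nrow(slh)
  perm_stats <- numeric(n_permutations)
  with_seed(seed, {
    for (p in seq_len(n_permutations)) {
      sp <- apply(slh, 2, function(col) col[sample.int(n)])
      perm_stats[p] <- g2_statistic(sp)
    }
  })
  pv <- (1 + sum(perm_stats >= obs, na.rm = TRUE)) / (n_permutations + 1)
  list(g2 = obs, p_value = pv, n_permutations = n_permutations,
       seed = seed, perm = perm_stats)
}
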