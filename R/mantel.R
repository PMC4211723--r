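#' Construct a pairwise matrix
#'
#' Container for square symmetric dyadic data (relatedness, day differences,
#' centroid distances) consumed by the Mantel machinery. The diagonal is
#' ignored by all tests; `NA` off-diagonal entries are treated as masked
#' dyads and excluded pairwise.
#'
#' @param values square symmetric numeric matrix with id dimnames (or an id
#'   vector supplied via `ids`).
#' @param kind `"similarity"` or `"distance"`.
#' @param units free-text units ("days", "meters", "unitless").
#' @param ids optional ids overriding dimnames.
#' @return object of class `pairwise_matrix`.
#' @export
pairwise_matrix <- function(values, kind = c("distance", "similarity"),
                            units = "unitless", ids = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(ids)) ids <- rownames(values)
  if (is.null(ids)) stop("pairwise matrix needs ids (dimnames or `ids`)")
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate ids in pairwise matrix")
  off <- upper.tri(values)
  if (any(abs(values[off] - t(values)[off]) > 1e-9, na.rm = TRUE)) {
    stop("pairwise matrix is not symmetric")
  }
  if (any(is.na(values[off]) != is.na(t(values)[off]))) {
    stop("asymmetric NA mask in pairwise matrix")
  }
  dimnames(values) <- list(ids, ids)
  structure(list(ids = ids, values = values, kind = kind, units = units),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  v <- x$values[upper.tri(x$values)]
  cat(sprintf("pairwise_matrix (%s, %s): %d ids, %d/%d dyads masked\n",
              x$kind, x$units, length(x$ids), sum(is.na(v)), length(v)))
  invisible(x)
}

as_pm_values <- function(a) {
  if (inherits(a, "pairwise_matrix")) a$values
  else if (inherits(a, "relatedness_matrix")) a$values
  else a
}

check_aligned <- function(...) {
  ms <- list(...)
  ids <- lapply(ms, rownames)
  for (k in seq_along(ids)[-1]) {
    if (!identical(ids[[1]], ids[[k]])) {
      stop("pairwise matrices have mismatched or differently ordered ids")
    }
  }
  invisible(TRUE)
}

# upper-triangle vectors with pairwise-complete mask
tri_vectors <- function(...) {
  ms <- list(...)
  ut <- upper.tri(ms[[1]])
  vs <- lapply(ms, function(m) m[ut])
  ok <- Reduce(`&`, lapply(vs, function(v) !is.na(v)))
  lapply(vs, function(v) v[ok])
}

#' Mantel correlation between two pairwise matrices
#'
#' Pearson correlation over the n(n-1)/2 unordered off-diagonal dyads,
#' excluding masked (NA) dyads pairwise.
#'
#' @param a,b aligned [pairwise_matrix()] (or plain matrices /
#'   `relatedness_matrix`) with identical id order.
#' @return scalar r in \[-1, 1\].
#' @export
mantel_r <- function(a, b) {
  av <- as_pm_values(a); bv <- as_pm_values(b)
  check_aligned(av, bv)
  if (nrow(av) < 4) stop("need n >= 4 for a Mantel correlation")
  v <- tri_vectors(av, bv)
  if (length(v[[1]]) < 3) stop("fewer than 3 usable dyads")
  if (stats::sd(v[[1]]) == 0 || stats::sd(v[[2]]) == 0) {
    stop("zero variance in a matrix's off-diagonal entries")
  }
  stats::cor(v[[1]], v[[2]])
}

# r between two full matrices under a row/column permutation of b
mantel_r_perm <- function(av, bv, perm) {
  bp <- bv[perm, perm]
  v <- tri_vectors(av, bp)
  if (stats::sd(v[[1]]) == 0 || stats::sd(v[[2]]) == 0) return(NA_real_)
  stats::cor(v[[1]], v[[2]])
}

# bootstrap over sample units (ids): resample ids with replacement, take the
# induced submatrices, drop dyads that are two copies of the same original id
boot_mantel_r <- function(av, bv, idx) {
  same <- outer(idx, idx, `==`)
  aa <- av[idx, idx]; bb <- bv[idx, idx]
  aa[same] <- NA; bb[same] <- NA
  ut <- upper.tri(aa)
  x <- aa[ut]; y <- bb[ut]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

mantel_core <- function(av, bv, n_permutations, n_boot, seed,
                        partial = FALSE, conditioning = NA_character_) {
  r_obs <- {
    v <- tri_vectors(av, bv)
    if (stats::sd(v[[1]]) == 0 || stats::sd(v[[2]]) == 0) {
      stop("zero variance in a matrix's off-diagonal entries")
    }
    stats::cor(v[[1]], v[[2]])
  }
  n <- nrow(av)
  perm_r <- numeric(n_permutations)
  with_seed(sub_seed(seed, 1L), {
    for (p in seq_len(n_permutations)) {
      perm_r[p] <- mantel_r_perm(av, bv, sample.int(n))
    }
  })
  p_value <- (1 + sum(abs(perm_r) >= abs(r_obs), na.rm = TRUE)) /
    (n_permutations + 1)
  boot_r <- numeric(n_boot)
  with_seed(sub_seed(seed, 2L), {
    for (b in seq_len(n_boot)) {
      boot_r[b] <- boot_mantel_r(av, bv, sample.int(n, replace = TRUE))
    }
  })
  ci <- stats::quantile(boot_r, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(r = r_obs, ci_lower = ci[1], ci_upper = ci[2],
                 p_value = p_value, n_permutations = n_permutations,
                 n_boot = n_boot, seed = seed, partial = partial,
                 conditioning = conditioning, perm_r = perm_r),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%sMantel r = %.4f (%.4f, %.4f), p = %.4g [%d perms, %d boot]\n",
              if (x$partial) sprintf("partial (| %s) ", x$conditioning) else "",
              x$r, x$ci_lower, x$ci_upper, x$p_value,
              x$n_permutations, x$n_boot))
  invisible(x)
}

#' Mantel permutation test with bootstrap confidence limits
#'
#' Null distribution by jointly permuting rows and columns of one matrix;
#' the two-sided p-value is (1 + #\{|r_perm| >= |r_obs|\})/(n_permutations+1).
#' 95% confidence limits come from resampling sample units (ids) with
#' replacement and recomputing r on the induced submatrices, with dyads
#' formed by two copies of the same resampled id excluded; percentile bounds
#' are reported.
#'
#' @param a,b aligned pairwise matrices.
#' @param n_permutations number of permutations (default 10000).
#' @param n_boot bootstrap draws for the confidence limits (default 1000).
#' @param seed integer RNG seed.
#' @return object of class `mantel_result` with `r`, `ci_lower`, `ci_upper`,
#'   `p_value`, and the run settings.
#' @export
mantel_test <- function(a, b, n_permutations = 10000, n_boot = 1000, seed = 1L) {
  av <- as_pm_values(a); bv <- as_pm_values(b)
  check_aligned(av, bv)
  if (nrow(av) < 4) stop("need n >= 4")
  if (n_permutations < 99) warning("fewer than 99 permutations; p-value is coarse")
  mantel_core(av, bv, n_permutations, n_boot, seed)
}

# residualise the off-diagonal of y on the off-diagonal of x (element-wise
# simple regression), returning a symmetric residual matrix; masked cells
# stay NA
residual_matrix <- function(yv, xv) {
  ut <- upper.tri(yv)
  y <- yv[ut]; x <- xv[ut]
  ok <- !is.na(y) & !is.na(x)
  if (stats::sd(x[ok]) == 0) stop("conditioning matrix has zero variance")
  fit <- stats::lm.fit(cbind(1, x[ok]), y[ok])
  res <- rep(NA_real_, length(y))
  res[ok] <- fit$residuals
  out <- matrix(NA_real_, nrow(yv), ncol(yv), dimnames = dimnames(yv))
  out[ut] <- res
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

#' Partial Mantel test
#'
#' Correlation between the element-wise residuals of `a ~ c` and `b ~ c`
#' (Smouse-Long-Sokal). The permutation null jointly permutes rows and
#' columns of the residualised `a`; confidence limits are the id-level
#' bootstrap of [mantel_test()] applied to the residual matrices.
#'
#' @param a,b,c aligned pairwise matrices; `c` is the conditioning matrix
#'   (e.g. winter-range centroid distance).
#' @param n_permutations,n_boot,seed as in [mantel_test()].
#' @return object of class `mantel_result` with `partial = TRUE`.
#' @export
partial_mantel_test <- function(a, b, c, n_permutations = 10000,
                                n_boot = 1000, seed = 1L) {
  av <- as_pm_values(a); bv <- as_pm_values(b); cv <- as_pm_values(c)
  check_aligned(av, bv, cv)
  if (nrow(av) < 4) stop("need n >= 4")
  ra <- residual_matrix(av, cv)
  rb <- residual_matrix(bv, cv)
  v <- tri_vectors(ra, rb)
  if (stats::sd(v[[1]]) < 1e-12 || stats::sd(v[[2]]) < 1e-12) {
    stop("conditioning matrix is collinear with a or b (residual variance ~ 0)")
  }
  cname <- if (inherits(c, "pairwise_matrix")) c$units else "c"
  mantel_core(ra, rb, n_permutations, n_boot, seed,
              partial = TRUE, conditioning = cname)
}
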