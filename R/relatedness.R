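#' Pairwise Queller-Goodnight relatedness matrix
#'
#' Estimates pairwise relatedness r for every dyad by the Queller & Goodnight
#' (1989) coefficient, with reference allele frequencies taken from the full
#' sample (focal dyad included). At a locus where the focal individual
#' carries alleles a,b and the partner c,d, the directed numerator is
#' 0.5*(I(a=c) + I(a=d) + I(b=c) + I(b=d)) - p_a - p_b and the denominator is
#' 1 + I(a=b) - p_a - p_b. Numerators and denominators are summed over shared
#' typed loci before division (ratio of sums), and the estimate is
#' symmetrised by averaging the two directed ratios. Dyads sharing no typed
#' locus get `NA`; dyads sharing fewer than `min_loci` typed loci are flagged
#' in the `low_overlap` attribute but retained.
#'
#' Because the estimator is centred on sample frequencies, the mean
#' off-diagonal r over a sample drawn from its own reference frequencies is
#' approximately 0; parent-offspring dyads have expectation 0.5 and half-sibs
#' 0.25.
#'
#' @param g a [genotype_table()] with at least 2 individuals and 1
#'   polymorphic locus.
#' @param min_loci overlap threshold below which a dyad is flagged.
#' @return object of class `relatedness_matrix`: list with `ids`, `values`
#'   (square symmetric matrix, diagonal `NA`) and `low_overlap` (logical
#'   matrix).
#' @export
queller_goodnight <- function(g, min_loci = 5L) {
  stopifnot(inherits(g, "genotype_table"))
  n <- length(g$ids)
  if (n < 2) stop("need >= 2 individuals")
  af <- allele_frequencies(g)
  poly <- vapply(af$freq, function(f) length(f) > 1, logical(1))
  if (!any(poly)) stop("all loci monomorphic; relatedness undefined")
  loci <- which(poly)

  num <- matrix(0, n, n)   # directed numerator sums, row = focal
  den <- matrix(0, n, n)
  shared <- matrix(0L, n, n)
  for (j in loci) {
    a1 <- g$a1[, j]; a2 <- g$a2[, j]
    typed <- !is.na(a1)
    fr <- af$freq[[g$loci[j]]]
    p1 <- fr[a1]; p2 <- fr[a2]            # frequencies of focal alleles
    # allele-sharing counts S_xy = number of matches among the 4 cross pairs
    eq <- function(x, y) (x == y) * 1
    S <- outer(a1, a1, eq) + outer(a1, a2, eq) +
         outer(a2, a1, eq) + outer(a2, a2, eq)
    S[!typed, ] <- NA; S[, !typed] <- NA
    hom <- (a1 == a2) * 1
    # directed per-locus terms: focal x in rows
    num_j <- 0.5 * S - matrix(p1 + p2, n, n)
    den_j <- matrix(1 + hom - (p1 + p2), n, n)
    ok <- !is.na(S)
    num[ok] <- num[ok] + num_j[ok]
    den[ok] <- den[ok] + den_j[ok]
    shared <- shared + ok
  }
  directed <- num / den
  r <- (directed + t(directed)) / 2
  r[shared == 0] <- NA
  diag(r) <- NA
  dimnames(r) <- list(g$ids, g$ids)
  low <- shared < min_loci
  diag(low) <- FALSE
  dimnames(low) <- dimnames(r)
  structure(list(ids = g$ids, values = r, low_overlap = low),
            class = "relatedness_matrix")
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  v <- x$values[upper.tri(x$values)]
  cat(sprintf(
    "relatedness_matrix: %d individuals, mean r = %.4f (sd %.4f), %d low-overlap dyads\n",
    length(x$ids), mean(v, na.rm = TRUE), stats::sd(v, na.rm = TRUE),
    sum(x$low_overlap[upper.tri(x$low_overlap)])))
  invisible(x)
}
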