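# shared fixtures and an MCMC shape small enough for unit tests
`%||%` <- function(a, b) if (is.null(a)) b else a

quick_mcmc <- mcmc_settings(n_chains = 2, n_iter = 1500, burn_frac = 1/3,
                            n_adapt = 400)

# tiny hand-built table: 3 individuals x 2 loci, one missing call
tiny_table <- function() {
  genotype_table(
    ids = c("i1", "i2", "i3"), loci = c("L1", "L2"),
    a1 = rbind(c("A", "C"), c("A", "C"), c("B", NA)),
    a2 = rbind(c("A", "D"), c("B", "C"), c("B", NA)),
    group = c("g1", "g1", "g2"))
}

# n unrelated individuals drawn from one allele pool (HWE, no inbreeding)
random_table <- function(n, n_loci = 17, n_alleles = 8, seed = 1) {
  set.seed(seed)
  freqs <- lapply(seq_len(n_loci), function(j) {
    w <- rgamma(n_alleles, 1); w / sum(w)
  })
  draw <- function() vapply(freqs, function(f)
    sample.int(length(f), 2, replace = TRUE, prob = f), integer(2))
  a1 <- matrix("", n, n_loci); a2 <- matrix("", n, n_loci)
  for (i in seq_len(n)) {
    g <- draw()
    a1[i, ] <- sprintf("%03d", 100 + g[1, ])
    a2[i, ] <- sprintf("%03d", 100 + g[2, ])
  }
  genotype_table(sprintf("r%03d", seq_len(n)),
                 sprintf("loc%02d", seq_len(n_loci)), a1, a2)
}

# random symmetric matrix with zero diagonal and ids, for Mantel nulls
random_sym <- function(n, seed, ids = sprintf("m%02d", seq_len(n))) {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n)
  m <- m + t(m); diag(m) <- 0
  dimnames(m) <- list(ids, ids)
  m
}

expect_symmetric <- function(m) {
  expect_equal(m, t(m))
}
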