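test_that("allele frequencies match direct counting", {
  g <- genotype_table(c("a", "b"), "L1", cbind(c("A", "A")), cbind(c("A", "B")))
  af <- allele_frequencies(g)
  expect_equal(af$freq$L1, c(A = 0.75, B = 0.25))
  expect_equal(unname(af$n_copies["L1"]), 4L)
  # monomorphic locus is allowed
  gm <- genotype_table(c("a", "b"), "L1", cbind(c("A", "A")), cbind(c("A", "A")))
  expect_equal(allele_frequencies(gm)$freq$L1, c(A = 1))
  # fully missing locus is an error naming the locus
  gmiss <- genotype_table(c("a", "b"), c("L1", "L2"),
                          cbind(c("A", "A"), c(NA, NA)),
                          cbind(c("A", "B"), c(NA, NA)))
  expect_error(allele_frequencies(gmiss), "L2")
})

test_that("allele frequencies agree with a brute-force tally on random tables", {
  for (seed in 1:3) {
    g <- random_table(25, n_loci = 5, seed = seed)
    af <- allele_frequencies(g)
    for (j in seq_along(g$loci)) {
      tally <- list()
      for (i in seq_along(g$ids)) {
        for (al in c(g$a1[i, j], g$a2[i, j])) {
          if (!is.na(al)) tally[[al]] <- (tally[[al]] %||% 0) + 1
        }
      }
      expected <- unlist(tally) / sum(unlist(tally))
      expect_equal(af$freq[[j]][names(expected)], expected)
      expect_equal(sum(af$freq[[j]]), 1, tolerance = 1e-12)
    }
  }
})

test_that("MLH averages SLH over typed loci only", {
  # heterozygous at 8 of 16 typed loci, 1 missing
  a1 <- c(rep("A", 8), rep("A", 8), NA)
  a2 <- c(rep("B", 8), rep("A", 8), NA)
  g <- genotype_table("x", sprintf("L%02d", 1:17), rbind(a1), rbind(a2))
  hp <- heterozygosity_profile(g)
  expect_equal(unname(hp$mlh["x"]), 0.5)
  expect_equal(unname(hp$n_typed["x"]), 16L)
  # fully homozygous individual
  gh <- genotype_table("y", c("L1", "L2"), rbind(c("A", "B")), rbind(c("A", "B")))
  hph <- heterozygosity_profile(gh)
  expect_equal(unname(hph$mlh), 0)
  expect_equal(unname(hph$slh[1, ]), c(0L, 0L))
})

test_that("MLH equals the mean of non-missing SLH on random tables (identity)", {
  for (seed in 4:8) {
    g <- simulate_genotypes(sim_config(seed = seed, missing_rate = 0.05))$genotypes
    hp <- heterozygosity_profile(g)
    recount <- apply(hp$slh, 1, function(s) mean(s, na.rm = TRUE))
    expect_equal(hp$mlh, recount)
    expect_true(all(hp$mlh >= 0 & hp$mlh <= 1))
  }
})

test_that("exact HWE test matches full enumeration on a 2-allele case", {
  # AA=1, BB=1: gene copies {A,A,B,B}; of the 3 equally likely pairings,
  # one gives {AA,BB} -> P(obs) = 1/3 and no array is less probable
  g <- genotype_table(c("a", "b"), "L", cbind(c("A", "B")), cbind(c("A", "B")))
  res <- hwe_exact_test(g, "L")
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
})

test_that("HWE-conformant counts give p near 1 and Monte-Carlo agrees with exact", {
  a1 <- c(rep("A", 25), rep("A", 50), rep("B", 25))
  a2 <- c(rep("A", 25), rep("B", 50), rep("B", 25))
  g <- genotype_table(sprintf("i%03d", 1:100), "L", cbind(a1), cbind(a2))
  exact <- hwe_exact_test(g, "L")
  expect_equal(exact$method, "exact")
  expect_gt(exact$p_value, 0.9)
  mc <- hwe_exact_test(g, "L", n_mc = 2000, seed = 5, max_arrays = 3)
  expect_equal(mc$method, "mc")
  se <- sqrt(exact$p_value * (1 - exact$p_value) / 2000)
  expect_lt(abs(mc$p_value - exact$p_value), 3 * se + 1e-3)
  # monomorphic locus: warning, p = 1
  gm <- genotype_table(c("a", "b"), "L", cbind(c("A", "A")), cbind(c("A", "A")))
  expect_warning(resm <- hwe_exact_test(gm, "L"), "monomorphic")
  expect_equal(resm$p_value, 1)
})

test_that("F_IS is ~0 at HWE proportions and exactly -1 for all-heterozygotes", {
  a1 <- c(rep("A", 25), rep("A", 50), rep("B", 25))
  a2 <- c(rep("A", 25), rep("B", 50), rep("B", 25))
  g <- genotype_table(sprintf("i%03d", 1:100), "L", cbind(a1), cbind(a2))
  expect_lt(abs(fis(g)), 0.01)
  # every individual heterozygous A/B at one biallelic locus:
  # per allele b = n/(n-1) (1/4 - (2n-1)/(4n)) = -1/4, c = 1/2 -> f = -1
  gh <- genotype_table(sprintf("h%d", 1:20), "L",
                       cbind(rep("A", 20)), cbind(rep("B", 20)))
  expect_equal(fis(gh), -1, tolerance = 1e-12)
  gm <- genotype_table(c("a", "b"), "L", cbind(c("A", "A")), cbind(c("A", "A")))
  expect_error(fis(gm), "monomorphic")
})

test_that("pooled F_IS of HWE-simulated populations centres on 0", {
  f_vals <- vapply(1:30, function(s) fis(random_table(60, 8, seed = s)), 0)
  expect_lt(abs(mean(f_vals)), 3 * sd(f_vals) / sqrt(length(f_vals)))
})

test_that("g2 is ~0 under random union of gametes and >0 with inbreeding variance", {
  null_g <- random_table(500, n_loci = 10, seed = 11)
  g2_null <- g2_identity_disequilibrium(null_g, n_permutations = 200, seed = 1)
  expect_lt(abs(g2_null$g2), 0.01)
  # 50/50 mixture of outbred and selfed-lineage individuals
  set.seed(12)
  n <- 500; L <- 10; n_alleles <- 6
  freqs <- lapply(1:L, function(j) { w <- rgamma(n_alleles, 1); w / sum(w) })
  a1 <- matrix("", n, L); a2 <- matrix("", n, L)
  for (i in 1:n) {
    selfed <- i <= n / 2     # selfing: f = 0.5, autozygous per locus w.p. 1/2
    for (j in 1:L) {
      al <- sample.int(n_alleles, 2, replace = TRUE, prob = freqs[[j]])
      if (selfed && runif(1) < 0.5) al[2] <- al[1]
      a1[i, j] <- as.character(al[1]); a2[i, j] <- as.character(al[2])
    }
  }
  gmix <- genotype_table(sprintf("s%03d", 1:n), sprintf("L%02d", 1:L), a1, a2)
  g2_mix <- g2_identity_disequilibrium(gmix, n_permutations = 200, seed = 2)
  expect_gt(g2_mix$g2, 0)
  expect_lt(g2_mix$p_value, 0.05)
})

test_that("seeded statistics reproduce bit-identically", {
  g <- random_table(60, 8, seed = 3)
  r1 <- g2_identity_disequilibrium(g, 100, seed = 9)
  r2 <- g2_identity_disequilibrium(g, 100, seed = 9)
  expect_identical(r1, r2)
  h1 <- hwe_exact_test(g, "loc01", n_mc = 500, seed = 4, max_arrays = 3)
  h2 <- hwe_exact_test(g, "loc01", n_mc = 500, seed = 4, max_arrays = 3)
  expect_identical(h1, h2)
})
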