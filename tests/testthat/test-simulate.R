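test_that("default config reproduces the study's shape", {
  cfg <- sim_config(seed = 1L)
  sim <- simulate_genotypes(cfg)
  expect_equal(dim(sim$genotypes), c(134L, 17L))
  expect_equal(completeness(sim$genotypes), 0.99, tolerance = 0.01)
  expect_equal(as.integer(table(sim$genotypes$group)[c("NM", "NR", "RG", "SM")]),
               c(30L, 30L, 44L, 30L))
  expect_true(all(sim$truth$haplogroup %in% c("1", "2")))
  expect_true(all(sim$truth$age %in% 1:11))
  expect_true(all(sim$truth$f_true %in% c(0, 0.25)))
})

test_that("generators are pure functions of config and seed", {
  a <- simulate_dataset(sim_config(seed = 9L))
  b <- simulate_dataset(sim_config(seed = 9L))
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$dates, b$dates)
  expect_identical(a$records, b$records)
  c <- simulate_genotypes(sim_config(seed = 10L))
  expect_false(identical(a$genotypes$a1, c$genotypes$a1))
})

test_that("simulated data satisfy the consuming modules' invariants", {
  d <- simulate_dataset(sim_config(seed = 2L))
  # migration records: start <= end where both present
  ok <- !is.na(d$dates$spring_init)
  expect_true(all(d$dates$spring_init[ok] <= d$dates$spring_term[ok]))
  okf <- !is.na(d$dates$fall_init)
  expect_true(all(d$dates$fall_init[okf] <= d$dates$fall_term[okf]))
  expect_equal(sum(ok), 104); expect_equal(sum(okf), 95)
  # capture records: 102 December, 79 March, 47 repeats
  expect_equal(sum(d$records$march == 0), 102)
  expect_equal(sum(d$records$march == 1), 79)
  expect_equal(sum(duplicated(d$records$id)), 47)
  expect_true(all(d$records$fat_percent > 0 & d$records$fat_percent < 100))
  expect_true(all(d$records$mass_kg > 0))
  # SLH columns derive from the simulated genotypes
  hp <- heterozygosity_profile(d$genotypes)
  i <- match(d$records$id, d$truth$id)
  typed <- !is.na(hp$slh[i, "loc02"])
  expect_equal(d$records$slh_loc02[typed], unname(hp$slh[i, "loc02"][typed]))
})

test_that("a no-inbreeding-variance config propagates to g2 ~ 0", {
  cfg <- sim_config(seed = 3L, inbred_fraction = 0, family_fraction = 0)
  sim <- simulate_genotypes(cfg)
  expect_true(all(sim$truth$f_true == 0))
  g2 <- g2_identity_disequilibrium(sim$genotypes, 200, seed = 1)
  expect_lt(abs(g2$g2), 0.015)
  expect_gt(g2$p_value, 0.05)
})

test_that("haplogroup day-shift matches negative-binomial mean arithmetic", {
  # one large group so range effects drop out: E[diff] ~ exp(b0) - exp(b0 + b)
  cfg <- sim_config(seed = 4L, n_individuals = 3000, groups = c(NM = 3000),
                    captures = c(december_only = 3000, march_only = 0, both = 0),
                    n_spring = 3000, n_fall = 3000,
                    family_fraction = 0, inbred_fraction = 0, family_sd = 0)
  sim <- simulate_genotypes(cfg)
  mig <- simulate_migration_dates(sim$truth, cfg)
  hap <- sim$truth$haplogroup[match(mig$dates$id, sim$truth$id)]
  diff_days <- mean(mig$dates$fall_term[hap == "1"]) -
    mean(mig$dates$fall_term[hap == "2"])
  # exp(2.932) - exp(2.932 - 0.350) = 5.54, inflated slightly by the age term
  expect_gt(diff_days, 4); expect_lt(diff_days, 7)
  # dates fall inside the field windows (early Oct - late Nov)
  expect_gte(min(mig$dates$fall_term), 277)
  expect_lte(stats::quantile(mig$dates$fall_term, 0.995), 340)
})

test_that("planted SLH and March effects shape simulated fat", {
  cfg <- sim_config(seed = 5L, n_individuals = 2000, groups = c(NM = 2000),
                    captures = c(december_only = 1000, march_only = 0,
                                 both = 1000),
                    n_spring = 2000, n_fall = 2000, missing_rate = 0)
  sim <- simulate_genotypes(cfg)
  cond <- simulate_condition(sim$truth, sim$genotypes, cfg)
  rec <- cond$records
  # heterozygotes at the negatively planted locus have lower mean logit fat
  dec <- rec[rec$march == 0, ]
  lfat <- qlogis(dec$fat_percent / 100)
  d_eff <- mean(lfat[dec$slh_loc02 == 1]) - mean(lfat[dec$slh_loc02 == 0])
  expect_lt(abs(d_eff - (-0.24)), 0.06)
  p_eff <- mean(lfat[dec$slh_loc12 == 1]) - mean(lfat[dec$slh_loc12 == 0])
  expect_lt(abs(p_eff - 0.18), 0.06)
  # March captures are leaner than December ones
  expect_lt(mean(rec$fat_percent[rec$march == 1]),
            mean(rec$fat_percent[rec$march == 0]))
  # null config: fat independent of every locus
  cfg0 <- sim_config(seed = 6L, planted_fat_loci = c(loc02 = 0, loc12 = 0))
  sim0 <- simulate_genotypes(cfg0)
  cond0 <- simulate_condition(sim0$truth, sim0$genotypes, cfg0)
  expect_error(simulate_condition(sim0$truth, sim0$genotypes,
                                  sim_config(seed = 6L,
                                             planted_fat_loci = c(locXX = 1))),
               "absent")
})

test_that("GPS tracks are reproducible and closed-loop recoverable", {
  cfg <- sim_config(seed = 7L)
  sim <- simulate_genotypes(cfg)
  mig <- simulate_migration_dates(sim$truth, cfg)
  ids <- mig$dates$id[!is.na(mig$dates$spring_init)][1:8]
  t1 <- simulate_gps_track(sim$truth, mig$dates, cfg, ids = ids)
  t2 <- simulate_gps_track(sim$truth, mig$dates, cfg, ids = ids)
  expect_identical(t1, t2)
  tt <- attr(t1, "truth")
  ex <- extract_all_migrations(t1, "spring")
  cmp <- merge(ex$records, tt, by = "id", suffixes = c("_ext", "_true"))
  expect_equal(nrow(cmp), 8)
  expect_true(all(abs(cmp$start_day_ext - cmp$start_day_true) <= 1))
  expect_true(all(abs(cmp$end_day_ext - cmp$end_day_true) <= 1))
})

test_that("simulate_dataset writes the consuming formats round-trippably", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 8L, n_individuals = 30,
                    groups = c(NM = 8, NR = 8, RG = 8, SM = 6),
                    captures = c(december_only = 12, march_only = 8, both = 10),
                    n_spring = 25, n_fall = 22)
  d <- simulate_dataset(cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "genotypes.csv")))
  g <- read_genotype_table(file.path(dir, "genotypes.csv"), "csv")
  expect_identical(g$a1, d$genotypes$a1)
  rec <- read.csv(file.path(dir, "capture_records.csv"))
  expect_equal(nrow(rec), nrow(d$records))
})
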