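#' Simulation configuration
#'
#' Default values emulate the study conditions: 134 adult females genotyped
#' at 17 microsatellite loci with ~99% completeness across four winter-range
#' groups, 2 mtDNA haplogroups, capture records split December/March with 47
#' repeats, haplogroup-shifted fall migration on the day-count scale, and
#' single-locus heterozygosity effects on logit body fat. Planted effect
#' sizes default to posterior medians reported from field data, so the
#' generator's truth matches field-scale effect sizes.
#'
#' @param n_individuals number of animals.
#' @param n_loci microsatellite panel size.
#' @param alleles_per_locus allele-pool size per locus (frequencies drawn
#'   from a flat Dirichlet).
#' @param missing_rate per-call missing probability.
#' @param groups named integer vector of winter-range group sizes.
#' @param haplogroup_freq haplogroup frequencies (matrilineally inherited).
#' @param inbred_fraction fraction of animals that are full-sib-mating
#'   offspring (pedigree f = 0.25); with the default 0.2 the expected
#'   variance in inbreeding is 0.2*0.8*0.25^2 = 0.01, i.e. expected
#'   identity disequilibrium g2 of about 0.01.
#' @param family_size,family_fraction full-sib family structure: the given
#'   fraction of each group is arranged into families of this size (sharing
#'   dam, sire, and haplogroup), producing related dyads and, through the
#'   shared family effect on timing, relatedness-timing covariance.
#' @param family_sd SD of the shared per-family effect on log migration-day
#'   counts.
#' @param migration_beta named effects on the log day-count scale for fall
#'   termination (intercept, standardized age, winter-range dummies,
#'   haplogroup-2 shift) and spring initiation intercept.
#' @param nb_dispersion negative-binomial size parameter of day counts.
#' @param fat_beta named effects on logit fat fraction (intercept, age,
#'   March, range dummies); `planted_fat_loci` maps locus names to SLH
#'   effects (all other loci 0).
#' @param fat_phi beta-regression precision; at the default the SD of fat
#'   around a mean of 0.10 is about 0.03, the scale of field fat
#'   measurements.
#' @param fat_sigma_b SD of the per-individual intercept for fat.
#' @param mass_beta effects on log mass (kg): intercept, linear and
#'   quadratic standardized age, March.
#' @param mass_sigma_b,mass_sigma_e random-intercept and residual SD of log
#'   mass.
#' @param captures counts of December-only, March-only and both-capture
#'   animals (must sum to `n_individuals`).
#' @param n_spring,n_fall animals with usable spring / fall migration data.
#' @param julian_anchors earliest Julian day for each migration response.
#' @param gps list of track parameters: `intervals_h` candidate fix
#'   schedules (hours), `jitter_sd` residency GPS scatter (m),
#'   `pattern_radius` radius of the deterministic residency micro-movement
#'   (m), `migration_km` winter-to-summer displacement.
#' @param seed mandatory integer seed; every generator is a pure function of
#'   (config, seed).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 134, n_loci = 17,
                       alleles_per_locus = 8, missing_rate = 0.01,
                       groups = c(NM = 30, NR = 30, RG = 44, SM = 30),
                       haplogroup_freq = c("1" = 0.6, "2" = 0.4),
                       inbred_fraction = 0.2,
                       family_size = 6, family_fraction = 0.9,
                       family_sd = 0.30,
                       migration_beta = c(fall_term_intercept = 2.932,
                                          age = -0.095,
                                          NR = 0.1768, RG = -0.270,
                                          SM = -0.440,
                                          haplogroup2 = -0.350,
                                          spring_init_intercept = 2.5),
                       nb_dispersion = 10,
                       fat_beta = c(intercept = -2.15, age = -0.05,
                                    march = -0.52, NR = -0.10, RG = -0.11,
                                    SM = -0.06),
                       planted_fat_loci = c(loc02 = -0.24, loc12 = 0.18),
                       fat_phi = 100, fat_sigma_b = 0.15,
                       mass_beta = c(intercept = 4.25, age = 0.10,
                                     age2 = -0.08, march = -0.05),
                       mass_sigma_b = 0.06, mass_sigma_e = 0.04,
                       captures = c(december_only = 55, march_only = 32,
                                    both = 47),
                       n_spring = 104, n_fall = 95,
                       julian_anchors = c(spring_init = 101, fall_term = 279),
                       gps = list(intervals_h = c(0.5, 1, 5),
                                  jitter_sd = 50, pattern_radius = 100,
                                  migration_km = 30),
                       seed = 1L) {
  stopifnot(sum(groups) == n_individuals,
            sum(captures) == n_individuals,
            missing_rate >= 0, missing_rate <= 1,
            inbred_fraction >= 0, inbred_fraction <= 1,
            !is.null(seed))
  structure(as.list(environment()), class = "sim_config")
}

# draw one diploid genotype (2 x n_loci allele-index matrix) from allele
# frequency list
draw_gametes <- function(freqs) {
  vapply(freqs, function(f) sample.int(length(f), 2, replace = TRUE,
                                       prob = f), integer(2))
}

mendelian_offspring <- function(dam, sire) {
  L <- ncol(dam)
  rbind(dam[cbind(sample(1:2, L, replace = TRUE), 1:L)],
        sire[cbind(sample(1:2, L, replace = TRUE), 1:L)])
}

#' Simulate a pedigree-structured genotype table
#'
#' Founder gametes are drawn from flat-Dirichlet allele frequencies per
#' locus. Within each winter-range group a configurable fraction of animals
#' is arranged into full-sib families (shared dam and sire, shared
#' matrilineal haplogroup); a configurable fraction of animals is instead
#' the offspring of a full-sib mating (pedigree inbreeding f = 0.25),
#' inducing variance in inbreeding and hence identity disequilibrium.
#' Calls are masked at the missing rate. Allele labels are 3-digit strings
#' so both CSV and GenePop dialects round-trip.
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes` (a [genotype_table()]) and `truth` (data
#'   frame: id, group, family, f_true, haplogroup, age, plus the allele
#'   frequency list as an attribute).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(sub_seed(cfg$seed, 11L), {
    L <- cfg$n_loci
    freqs <- lapply(seq_len(L), function(j) {
      w <- stats::rgamma(cfg$alleles_per_locus, 1)
      w / sum(w)
    })
    names(freqs) <- sprintf("loc%02d", seq_len(L))

    n <- cfg$n_individuals
    ids <- sprintf("D%03d", seq_len(n))
    group <- rep(names(cfg$groups), cfg$groups)
    family <- rep(NA_character_, n)
    hap <- rep(NA_character_, n)
    f_true <- rep(0, n)
    a1 <- matrix(0L, n, L); a2 <- matrix(0L, n, L)

    fam_no <- 0L
    for (gname in names(cfg$groups)) {
      members <- which(group == gname)
      n_fam_members <- floor(length(members) * cfg$family_fraction /
                               cfg$family_size) * cfg$family_size
      fam_members <- members[seq_len(n_fam_members)]
      singles <- setdiff(members, fam_members)
      if (n_fam_members > 0) {
        for (fam in split(fam_members,
                          ceiling(seq_along(fam_members) / cfg$family_size))) {
          fam_no <- fam_no + 1L
          if (stats::runif(1) < cfg$inbred_fraction) {
            # dam and sire are full sibs: the whole family has f = 0.25
            g1 <- draw_gametes(freqs); g2 <- draw_gametes(freqs)
            dam <- mendelian_offspring(g1, g2)
            sire <- mendelian_offspring(g1, g2)
            fam_f <- 0.25
          } else {
            dam <- draw_gametes(freqs); sire <- draw_gametes(freqs)
            fam_f <- 0
          }
          fh <- sample(names(cfg$haplogroup_freq), 1,
                       prob = cfg$haplogroup_freq)
          for (i in fam) {
            off <- mendelian_offspring(dam, sire)
            a1[i, ] <- off[1, ]; a2[i, ] <- off[2, ]
            family[i] <- sprintf("F%03d", fam_no)
            hap[i] <- fh
            f_true[i] <- fam_f
          }
        }
      }
      for (i in singles) {
        if (stats::runif(1) < cfg$inbred_fraction) {
          # offspring of a full-sib mating: pedigree f = 0.25
          g1 <- draw_gametes(freqs); g2 <- draw_gametes(freqs)
          p1 <- mendelian_offspring(g1, g2)
          p2 <- mendelian_offspring(g1, g2)
          off <- mendelian_offspring(p1, p2)
          f_true[i] <- 0.25
        } else {
          off <- draw_gametes(freqs)
        }
        a1[i, ] <- off[1, ]; a2[i, ] <- off[2, ]
        hap[i] <- sample(names(cfg$haplogroup_freq), 1,
                         prob = cfg$haplogroup_freq)
      }
    }
    lab <- function(idx) sprintf("%03d", 100 + idx)
    a1c <- matrix(lab(a1), n, L); a2c <- matrix(lab(a2), n, L)
    miss <- matrix(stats::runif(n * L) < cfg$missing_rate, n, L)
    a1c[miss] <- NA; a2c[miss] <- NA
    # no individual may end up fully untyped
    all_gone <- rowSums(!is.na(a1c)) == 0
    a1c[all_gone, 1] <- lab(a1[all_gone, 1])
    a2c[all_gone, 1] <- lab(a2[all_gone, 1])

    age <- sample(1:11, n, replace = TRUE)
    g <- genotype_table(ids, names(freqs), a1c, a2c, group = group)
    truth <- data.frame(id = ids, group = group, family = family,
                        f_true = f_true, haplogroup = hap, age = age)
    attr(truth, "allele_freqs") <- freqs
    list(genotypes = g, truth = truth)
  })
}

#' Simulate migration dates with haplogroup and family structure
#'
#' Fall-termination day counts are negative-binomial with log mean
#' intercept + age effect * standardized age + winter-range effects +
#' haplogroup-2 shift + a shared per-family normal effect (which makes
#' related animals migrate at similar times, the signal the Mantel tests
#' look for). Fall initiation is termination minus a short transit
#' duration; spring initiation is an analogous negative-binomial count with
#' no haplogroup shift (the study found the mtDNA signal in fall only), and
#' spring termination adds a transit duration. Counts are returned on the
#' Julian day-of-year scale via the configured anchors. Animals without
#' usable collar data for a season get NA dates.
#'
#' @param truth truth table from [simulate_genotypes()].
#' @param cfg the same [sim_config()].
#' @return list with `dates` (data frame: id, spring_init, spring_term,
#'   fall_init, fall_term as Julian days, NA where unobserved) and `truth`
#'   (per-id true counts, family effects, and which season each animal is
#'   observed in).
#' @export
simulate_migration_dates <- function(truth, cfg) {
  if (any(is.na(truth$haplogroup))) stop("missing haplogroup in truth table")
  with_seed(sub_seed(cfg$seed, 22L), {
    n <- nrow(truth)
    mb <- cfg$migration_beta
    age_std <- as.numeric(standardize(truth$age))
    range_eff <- c(NM = 0, NR = unname(mb["NR"]), RG = unname(mb["RG"]),
                   SM = unname(mb["SM"]))[truth$group]
    hap_eff <- ifelse(truth$haplogroup == "2", mb["haplogroup2"], 0)
    fams <- unique(truth$family[!is.na(truth$family)])
    fam_eff <- function() {
      u <- stats::setNames(stats::rnorm(length(fams), 0, cfg$family_sd), fams)
      ifelse(is.na(truth$family), stats::rnorm(n, 0, cfg$family_sd),
             u[truth$family])
    }
    u_fall <- fam_eff(); u_spring <- fam_eff()
    eta_fall <- mb["fall_term_intercept"] + mb["age"] * age_std +
      range_eff + hap_eff + u_fall
    fall_term_count <- stats::rnbinom(n, size = cfg$nb_dispersion,
                                      mu = exp(eta_fall))
    fall_dur <- 1 + stats::rpois(n, 3)
    eta_spring <- mb["spring_init_intercept"] + range_eff + u_spring
    spring_init_count <- stats::rnbinom(n, size = cfg$nb_dispersion,
                                        mu = exp(eta_spring))
    spring_dur <- 1 + stats::rpois(n, 3)

    obs_spring <- truth$id %in% sample(truth$id, cfg$n_spring)
    obs_fall <- truth$id %in% sample(truth$id, cfg$n_fall)
    anchors <- cfg$julian_anchors
    dates <- data.frame(
      id = truth$id,
      spring_init = ifelse(obs_spring, anchors["spring_init"] +
                             spring_init_count, NA),
      spring_term = ifelse(obs_spring, anchors["spring_init"] +
                             spring_init_count + spring_dur, NA),
      fall_init = ifelse(obs_fall, anchors["fall_term"] + fall_term_count -
                           fall_dur, NA),
      fall_term = ifelse(obs_fall, anchors["fall_term"] + fall_term_count,
                         NA))
    mig_truth <- data.frame(
      id = truth$id, fall_term_count = fall_term_count,
      spring_init_count = spring_init_count,
      family_effect_fall = u_fall, family_effect_spring = u_spring,
      observed_spring = obs_spring, observed_fall = obs_fall)
    list(dates = dates, truth = mig_truth)
  })
}

#' Simulate condition capture records with planted SLH effects
#'
#' One or two capture records per animal (December/March mix per the
#' config). Percent body fat is beta-distributed with logit mean driven by
#' the intercept, standardized age, a March indicator, winter-range dummies,
#' a per-individual random intercept, and the planted single-locus
#' heterozygosity effects, which are computed from the actual simulated
#' genotypes (missing SLH imputed at the locus mean). Mass is log-normal
#' with a quadratic age effect and its own random intercept.
#'
#' @param truth truth table from [simulate_genotypes()].
#' @param genotypes the matching [genotype_table()].
#' @param cfg the same [sim_config()].
#' @return list with `records` (data frame: id, capture_period, march, age,
#'   winter_range, haplogroup, slh_* columns, mass_kg, fat_percent) and
#'   `truth` (true coefficient vectors and random intercepts).
#' @export
simulate_condition <- function(truth, genotypes, cfg) {
  missing_planted <- setdiff(names(cfg$planted_fat_loci), genotypes$loci)
  if (length(missing_planted)) {
    stop("planted locus label(s) absent from genotype table: ",
         paste(missing_planted, collapse = ", "))
  }
  with_seed(sub_seed(cfg$seed, 33L), {
    n <- nrow(truth)
    hp <- heterozygosity_profile(genotypes)
    slh <- hp$slh
    for (j in seq_len(ncol(slh))) {           # impute missing at locus mean
      m <- is.na(slh[, j])
      if (any(m)) slh[m, j] <- mean(slh[, j], na.rm = TRUE)
    }
    cap <- rep(c("december_only", "march_only", "both"), cfg$captures)
    cap <- sample(cap)                        # assign capture pattern to ids
    rec_id <- c(truth$id[cap != "march_only"], truth$id[cap != "december_only"])
    rec_march <- c(rep(0L, sum(cap != "march_only")),
                   rep(1L, sum(cap != "december_only")))
    i <- match(rec_id, truth$id)
    age_std <- as.numeric(standardize(truth$age))[i]
    fb <- cfg$fat_beta
    range_eff <- c(NM = 0, NR = unname(fb["NR"]), RG = unname(fb["RG"]),
                   SM = unname(fb["SM"]))[truth$group[i]]
    slh_eff <- rep(0, length(i))
    for (loc in names(cfg$planted_fat_loci)) {
      slh_eff <- slh_eff + cfg$planted_fat_loci[loc] * slh[i, loc]
    }
    b_fat <- stats::rnorm(n, 0, cfg$fat_sigma_b)
    eta_fat <- fb["intercept"] + fb["age"] * age_std +
      fb["march"] * rec_march + range_eff + slh_eff + b_fat[i]
    mu <- stats::plogis(eta_fat)
    fat <- stats::rbeta(length(i), mu * cfg$fat_phi, (1 - mu) * cfg$fat_phi)

    mbta <- cfg$mass_beta
    b_mass <- stats::rnorm(n, 0, cfg$mass_sigma_b)
    eta_mass <- mbta["intercept"] + mbta["age"] * age_std +
      mbta["age2"] * age_std^2 + mbta["march"] * rec_march + b_mass[i] +
      stats::rnorm(length(i), 0, cfg$mass_sigma_e)
    records <- data.frame(
      id = rec_id,
      capture_period = ifelse(rec_march == 1, "March", "December"),
      march = rec_march,
      age = truth$age[i], winter_range = truth$group[i],
      haplogroup = truth$haplogroup[i])
    records <- cbind(records,
                     stats::setNames(as.data.frame(slh[i, , drop = FALSE]),
                                     paste0("slh_", colnames(slh))))
    records$mass_kg <- exp(eta_mass)
    records$fat_percent <- 100 * fat
    rownames(records) <- NULL
    cond_truth <- list(fat_beta = fb, planted_fat_loci = cfg$planted_fat_loci,
                       fat_phi = cfg$fat_phi,
                       b_fat = stats::setNames(b_fat, truth$id),
                       mass_beta = mbta,
                       b_mass = stats::setNames(b_mass, truth$id))
    list(records = records, truth = cond_truth)
  })
}

#' Simulate GPS tracks around planted spring migrations
#'
#' Residency at the winter and summer range centres is a small deterministic
#' micro-movement pattern plus Gaussian GPS jitter; the transit between the
#' centres is linear in time, starting at noon of the true initiation day
#' and arriving at noon of the true termination day. Each animal is assigned
#' one of the three collar schedules (fix every 30 min, 60 min, or 5 h).
#' With `jitter_sd = 0` tracks are deterministic given the config.
#'
#' @param truth truth table from [simulate_genotypes()].
#' @param dates date table from [simulate_migration_dates()].
#' @param cfg the same [sim_config()].
#' @param ids optional subset of animals to track.
#' @return data frame with columns `id`, `time` (fractional Julian day),
#'   `x`, `y` (meters, projected), plus attribute `truth` (per-id planted
#'   start/end days, centres, fix interval).
#' @export
simulate_gps_track <- function(truth, dates, cfg, ids = NULL) {
  with_seed(sub_seed(cfg$seed, 44L), {
    gp <- cfg$gps
    ok <- !is.na(dates$spring_init)
    use <- dates$id[ok]
    if (!is.null(ids)) use <- intersect(use, ids)
    group_centers <- cbind(x = c(NM = 0, NR = 8000, RG = 16000, SM = 24000),
                           y = c(NM = 0, NR = 6000, RG = 0, SM = 6000))
    out <- vector("list", length(use))
    tr_truth <- vector("list", length(use))
    for (k in seq_along(use)) {
      id <- use[k]
      i <- match(id, dates$id)
      g <- truth$group[match(id, truth$id)]
      start <- dates$spring_init[i]; end <- dates$spring_term[i]
      wc <- group_centers[g, ] + stats::rnorm(2, 0, 2000)
      theta <- stats::runif(1, 0, 2 * pi)
      sc <- wc + gp$migration_km * 1000 * c(cos(theta), sin(theta))
      interval_d <- sample(gp$intervals_h, 1) / 24
      times <- seq(1, 240, by = interval_d)
      # center path: winter until noon of start day, linear transit, summer
      t0 <- start + 0.5; t1 <- end + 0.5
      if (t1 <= t0) t1 <- t0 + 1
      frac <- pmin(1, pmax(0, (times - t0) / (t1 - t0)))
      cx <- wc[1] + frac * (sc[1] - wc[1])
      cy <- wc[2] + frac * (sc[2] - wc[2])
      # deterministic residency micro-pattern + GPS jitter
      ang <- 2 * pi * (seq_along(times) %% 7) / 7
      px <- gp$pattern_radius * cos(ang) * (frac %in% c(0, 1))
      py <- gp$pattern_radius * sin(ang) * (frac %in% c(0, 1))
      x <- cx + px + stats::rnorm(length(times), 0, gp$jitter_sd)
      y <- cy + py + stats::rnorm(length(times), 0, gp$jitter_sd)
      out[[k]] <- data.frame(id = id, time = times, x = x, y = y)
      tr_truth[[k]] <- data.frame(id = id, start_day = start, end_day = end,
                                  winter_x = wc[1], winter_y = wc[2],
                                  summer_x = sc[1], summer_y = sc[2],
                                  interval_d = interval_d)
    }
    tracks <- do.call(rbind, out)
    attr(tracks, "truth") <- do.call(rbind, tr_truth)
    tracks
  })
}

#' Simulate a complete study-shaped dataset
#'
#' Runs every generator under one config and, optionally, writes the
#' consuming modules' CSV formats (genotypes in both dialects, capture
#' records, migration dates, and the truth tables) into a directory.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory.
#' @param tracks whether to simulate GPS tracks (heavier; off by default).
#' @return list with `genotypes`, `truth`, `dates`, `migration_truth`,
#'   `records`, `condition_truth`, and optionally `tracks`.
#' @export
simulate_dataset <- function(cfg = sim_config(), dir = NULL, tracks = FALSE) {
  gsim <- simulate_genotypes(cfg)
  mig <- simulate_migration_dates(gsim$truth, cfg)
  cond <- simulate_condition(gsim$truth, gsim$genotypes, cfg)
  out <- list(genotypes = gsim$genotypes, truth = gsim$truth,
              dates = mig$dates, migration_truth = mig$truth,
              records = cond$records, condition_truth = cond$truth)
  if (tracks) out$tracks <- simulate_gps_track(gsim$truth, mig$dates, cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_genotype_table(out$genotypes, file.path(dir, "genotypes.csv"), "csv")
    write_genotype_table(out$genotypes, file.path(dir, "genotypes.gen"),
                         "genepop")
    utils::write.csv(out$records, file.path(dir, "capture_records.csv"),
                     row.names = FALSE)
    utils::write.csv(out$dates, file.path(dir, "migration_dates.csv"),
                     row.names = FALSE)
    utils::write.csv(out$truth, file.path(dir, "truth_individuals.csv"),
                     row.names = FALSE)
    utils::write.csv(out$migration_truth,
                     file.path(dir, "truth_migration.csv"), row.names = FALSE)
    if (tracks) utils::write.csv(out$tracks, file.path(dir, "gps_tracks.csv"),
                                 row.names = FALSE)
  }
  out
}
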