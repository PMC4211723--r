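# FNV-1a hash of a serialised object, for provenance headers
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# CSV with a one-line provenance comment header
write_report_csv <- function(df, path, hash) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# hfcmig %s config %s",
                     as.character(utils::packageVersion("hfcmig")), hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a report CSV written by [run_pipeline()]
#' @param path report CSV path.
#' @return data frame (the provenance header is skipped).
#' @export
read_report_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Simulate winter and summer range centroids
#'
#' Light stand-in for GPS-derived centroids when no tracks are simulated:
#' winter centroids scatter (SD 2 km) around the four winter-range group
#' centres; summer centroids sit ~30 km away in a random direction.
#'
#' @param truth truth table from [simulate_genotypes()].
#' @param cfg the [sim_config()].
#' @return data frame: id, winter_x/y, summer_x/y (meters).
#' @export
simulate_range_centroids <- function(truth, cfg) {
  with_seed(sub_seed(cfg$seed, 55L), {
    gc <- cbind(x = c(NM = 0, NR = 8000, RG = 16000, SM = 24000),
                y = c(NM = 0, NR = 6000, RG = 0, SM = 6000))
    n <- nrow(truth)
    wx <- gc[truth$group, "x"] + stats::rnorm(n, 0, 2000)
    wy <- gc[truth$group, "y"] + stats::rnorm(n, 0, 2000)
    th <- stats::runif(n, 0, 2 * pi)
    data.frame(id = truth$id,
               winter_x = wx, winter_y = wy,
               summer_x = wx + cfg$gps$migration_km * 1000 * cos(th),
               summer_y = wy + cfg$gps$migration_km * 1000 * sin(th))
  })
}

#' Run the full analysis chain on a simulated dataset
#'
#' Executes the stages in dependency order: genotype simulation ->
#' heterozygosity, g2 and group-wise F_IS -> Queller-Goodnight relatedness
#' -> timing and centroid distance matrices -> Mantel and partial Mantel
#' tests -> negative-binomial fall-termination model -> hierarchical beta
#' fat model with shrinkage refit -> residual diagnostics. Writes
#' the study-style coefficient tables (timing
#' coefficients, Mantel correlations, fat coefficients) plus diversity and
#' diagnostics CSVs, each with a provenance header, and returns everything
#' invisibly. Identical config and seed give byte-identical outputs.
#'
#' @param cfg a [sim_config()]; its seed drives every stage.
#' @param out_dir output directory for report CSVs (NULL to skip writing).
#' @param n_permutations,n_boot Mantel test effort.
#' @param mcmc an [mcmc_settings()] shared by the regression fits.
#' @param shrinkage whether to run the shrinkage-prior refit of the fat
#'   model.
#' @return list with `data`, `genostats` (g2, fis, het), `relatedness`,
#'   `mantel` (Mantel summary table), `fit_fall_term`, `fit_fat`,
#'   `shrinkage`, and output `paths`.
#' @export
run_pipeline <- function(cfg = sim_config(), out_dir = NULL,
                         n_permutations = 10000, n_boot = 1000,
                         mcmc = mcmc_settings(), shrinkage = TRUE) {
  hash <- config_hash(cfg)
  msg <- function(...) message(sprintf("[hfcmig %s] ", hash), sprintf(...))
  msg("simulating dataset (seed %d)", cfg$seed)
  dat <- simulate_dataset(cfg)

  msg("genotype statistics")
  hp <- heterozygosity_profile(dat$genotypes)
  g2 <- g2_identity_disequilibrium(dat$genotypes, n_permutations = 1000,
                                   seed = sub_seed(cfg$seed, 61L))
  fis_by_group <- vapply(names(cfg$groups),
                         function(gr) fis(dat$genotypes, gr), 0)
  genostats <- list(g2 = g2, fis = fis_by_group, het = hp)

  msg("relatedness matrix")
  qg <- queller_goodnight(dat$genotypes)

  msg("Mantel tests (%d permutations)", n_permutations)
  centroids <- simulate_range_centroids(dat$truth, cfg)
  responses <- c(end_spring = "spring_term", start_spring = "spring_init",
                 end_fall = "fall_term", start_fall = "fall_init")
  mantel_rows <- list()
  for (metric in names(responses)) {
    dates <- stats::setNames(dat$dates[[responses[metric]]], dat$dates$id)
    dates <- dates[!is.na(dates)]
    tm <- suppressWarnings(timing_distance_matrix(dates))
    keep <- tm$ids
    qg_sub <- pairwise_matrix(qg$values[keep, keep], kind = "similarity",
                              units = "relatedness")
    ci <- match(keep, centroids$id)
    win <- centroid_distance_matrix(centroids[ci, ], "winter")
    sum_ <- centroid_distance_matrix(centroids[ci, ], "summer")
    tests <- list(
      list(label = metric, res = mantel_test(
        qg_sub, tm, n_permutations, n_boot, seed = sub_seed(cfg$seed, 62L))),
      list(label = paste(metric, "| winter distance"), res = partial_mantel_test(
        qg_sub, tm, win, n_permutations, n_boot,
        seed = sub_seed(cfg$seed, 63L))),
      list(label = paste(metric, "| summer distance"), res = partial_mantel_test(
        qg_sub, tm, sum_, n_permutations, n_boot,
        seed = sub_seed(cfg$seed, 64L))))
    for (tt in tests) {
      mantel_rows[[tt$label]] <- data.frame(
        metric = tt$label, r = tt$res$r, ci_lower = tt$res$ci_lower,
        ci_upper = tt$res$ci_upper, p_value = tt$res$p_value)
    }
  }
  mantel_tab <- do.call(rbind, mantel_rows)
  rownames(mantel_tab) <- NULL

  msg("negative-binomial fall-termination model")
  fall <- merge(dat$dates[!is.na(dat$dates$fall_term), c("id", "fall_term")],
                dat$truth, by = "id")
  fall$fall_term_days <- as.numeric(correct_to_earliest(
    stats::setNames(fall$fall_term, fall$id)))
  fall$winter_range <- fall$group
  des_nb <- design_spec("fall_term_days",
                        c("age", "winter_range", "haplogroup"))
  fit_fall <- fit_negbin(des_nb, fall, mcmc, seed = sub_seed(cfg$seed, 65L))

  msg("hierarchical beta fat model")
  slh_cols <- grep("^slh_", names(dat$records), value = TRUE)
  des_fat <- design_spec("fat_percent",
                         c(slh_cols, "age", "march", "winter_range"),
                         random_intercept = "id")
  fit_fat <- fit_beta_fat(des_fat, dat$records, mcmc,
                          seed = sub_seed(cfg$seed, 66L))
  shrink <- NULL
  if (shrinkage) {
    msg("shrinkage-prior refit")
    shrink <- shrinkage_refit(fit_fat)
  }

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      timing = write_report_csv(coef_table(fit_fall),
                                file.path(out_dir, "table1_timing.csv"), hash),
      mantel = write_report_csv(mantel_tab,
                                file.path(out_dir, "table2_mantel.csv"), hash),
      fat = write_report_csv(coef_table(fit_fat),
                             file.path(out_dir, "table3_fat.csv"), hash),
      genostats = write_report_csv(
        data.frame(statistic = c("g2", "g2_p", paste0("fis_", names(fis_by_group))),
                   value = c(g2$g2, g2$p_value, unname(fis_by_group))),
        file.path(out_dir, "genostats.csv"), hash),
      het = write_report_csv(as.data.frame(hp),
                             file.path(out_dir, "heterozygosity.csv"), hash),
      residuals = write_report_csv(residual_plot_data(fit_fat),
                                   file.path(out_dir, "fat_residuals.csv"),
                                   hash))
    if (!is.null(shrink)) {
      paths["shrinkage"] <- write_report_csv(
        shrink$comparison, file.path(out_dir, "fat_shrinkage.csv"), hash)
    }
    msg("wrote %d report files to %s", length(paths), out_dir)
  }
  invisible(list(data = dat, genostats = genostats, relatedness = qg,
                 mantel = mantel_tab, fit_fall_term = fit_fall,
                 fit_fat = fit_fat, shrinkage = shrink, paths = paths,
                 config_hash = hash))
}
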