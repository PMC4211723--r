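#' Standardize a covariate by twice its standard deviation
#'
#' Centers at the mean and divides by 2*SD (population SD, denominator n),
#' so a binary covariate and the standardized continuous one are on
#' comparable scales (Gelman-Hill convention); the result has mean 0 and
#' population SD 0.5.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @return standardized vector with attributes `center` and `scale`
#'   (`scale` = 2*SD), so the transform is invertible.
#' @export
standardize <- function(values) {
  if (length(unique(values[!is.na(values)])) < 2) {
    stop("cannot standardize a constant")
  }
  ctr <- mean(values, na.rm = TRUE)
  x <- values[!is.na(values)]
  scl <- 2 * sqrt(mean((x - ctr)^2))
  out <- (values - ctr) / scl
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Invert [standardize()]
#' @param z standardized vector carrying `center`/`scale` attributes (or
#'   supply them explicitly).
#' @param center,scale transform constants.
#' @return vector on the original scale.
#' @export
de_standardize <- function(z, center = attr(z, "center"),
                           scale = attr(z, "scale")) {
  as.numeric(z) * scale + center
}

#' Specify a regression design
#'
#' Declares the response, the ordered fixed-effect covariates, dummy-coding
#' reference levels, the age polynomial degree, and an optional random
#' intercept grouping. Character/factor covariates become dummy sets
#' omitting the reference level; numeric covariates enter as given, except
#' `age_var`, which is standardized by [standardize()] (and squared if
#' `age_degree = 2`).
#'
#' @param response response column name.
#' @param covariates ordered character vector of covariate column names.
#' @param age_var name of the age column (standardized); NULL to skip.
#' @param age_degree 1 (linear) or 2 (adds a quadratic term).
#' @param reference_levels named character vector of factor reference
#'   levels; defaults follow the study layout (winter range NM, haplogroup
#'   1, capture period December).
#' @param random_intercept optional grouping column for a per-group random
#'   intercept (e.g. `"id"` for repeat captures).
#' @return object of class `design_spec`.
#' @export
design_spec <- function(response, covariates, age_var = "age",
                        age_degree = 1,
                        reference_levels = c(winter_range = "NM",
                                             haplogroup = "1",
                                             capture_period = "December"),
                        random_intercept = NULL) {
  stopifnot(age_degree %in% c(1, 2))
  structure(list(response = response, covariates = covariates,
                 age_var = age_var, age_degree = age_degree,
                 reference_levels = reference_levels,
                 random_intercept = random_intercept),
            class = "design_spec")
}

# design matrix with intercept, named columns, plus response and grouping
build_design <- function(design, data) {
  stopifnot(inherits(design, "design_spec"))
  y <- data[[design$response]]
  if (is.null(y)) stop("response column not found: ", design$response)
  n <- nrow(data)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  age_info <- NULL
  for (v in design$covariates) {
    col <- data[[v]]
    if (is.null(col)) stop("covariate column not found: ", v)
    if (!is.null(design$age_var) && v == design$age_var) {
      z <- standardize(col)
      age_info <- list(center = attr(z, "center"), scale = attr(z, "scale"))
      X <- cbind(X, age_std = as.numeric(z))
      if (design$age_degree == 2) X <- cbind(X, age_std2 = as.numeric(z)^2)
    } else if (is.numeric(col)) {
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- v
    } else {
      col <- as.character(col)
      ref <- design$reference_levels[v]
      levs <- sort(unique(col))
      if (!is.na(ref) && ref %in% levs) levs <- c(ref, setdiff(levs, ref))
      for (lv in levs[-1]) {
        X <- cbind(X, (col == lv) * 1)
        colnames(X)[ncol(X)] <- paste0(v, lv)
      }
    }
  }
  ind <- NULL; J <- 0L; group_levels <- NULL
  if (!is.null(design$random_intercept)) {
    gcol <- data[[design$random_intercept]]
    if (is.null(gcol)) stop("random-intercept column not found: ",
                            design$random_intercept)
    group_levels <- unique(as.character(gcol))
    ind <- match(as.character(gcol), group_levels)
    J <- length(group_levels)
  }
  list(y = y, X = X, ind = ind, J = J, group_levels = group_levels,
       age_info = age_info)
}

#' MCMC settings
#'
#' Sampler run shape. The package's contract is convergence-based, not
#' mechanism-based: any run shape is acceptable provided R-hat < 1.05 and
#' effective sample sizes are adequate for the reported parameters. Defaults
#' are 4 chains of 10000 iterations with 25% discarded as burn-in.
#'
#' @param n_chains number of chains.
#' @param n_iter post-adaptation iterations per chain (including burn-in).
#' @param burn_frac fraction of `n_iter` discarded as burn-in.
#' @param n_adapt adaptation iterations.
#' @param thin thinning interval.
#' @return list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 4, n_iter = 10000, burn_frac = 0.25,
                          n_adapt = 1000, thin = 1) {
  structure(list(n_chains = n_chains, n_iter = n_iter,
                 burn_frac = burn_frac, n_adapt = n_adapt, thin = thin),
            class = "mcmc_settings")
}
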