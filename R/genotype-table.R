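#' Construct a genotype table
#'
#' The central genotype container: diploid calls for a set of individuals at a
#' panel of codominant loci (microsatellites), with optional per-individual
#' group labels (e.g. winter-range study area). Allele labels are opaque
#' strings and are never interpreted numerically, so fragment-size panels
#' ("152"/"158") and letter-coded panels ("A"/"B") behave identically.
#'
#' @param ids character vector of unique individual identifiers.
#' @param loci character vector of unique locus names.
#' @param a1,a2 character matrices (individuals x loci) holding the two allele
#'   labels of each call. A missing call has `NA` in both matrices; the
#'   recognised missing codes `"0"`, `"000"`, `""` and `"NA"` are normalised
#'   to `NA` on construction. Allele order within a call is not meaningful.
#' @param group optional character/factor vector of per-individual group
#'   labels (recycled `NA` allowed).
#'
#' @return An object of class `genotype_table`: a list with elements `ids`,
#'   `loci`, `a1`, `a2`, `group`.
#' @seealso [read_genotype_table()], [allele_frequencies()],
#'   [heterozygosity_profile()]
#' @export
genotype_table <- function(ids, loci, a1, a2, group = NULL) {
  ids <- as.character(ids)
  loci <- as.character(loci)
  if (anyDuplicated(ids)) {
    stop("duplicate individual id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(loci)) {
    stop("duplicate locus name(s): ",
         paste(unique(loci[duplicated(loci)]), collapse = ", "))
  }
  a1 <- normalize_missing(as.matrix(a1))
  a2 <- normalize_missing(as.matrix(a2))
  if (!all(dim(a1) == c(length(ids), length(loci))) ||
      !all(dim(a2) == c(length(ids), length(loci)))) {
    stop("allele matrices must be (n individuals) x (n loci)")
  }
  # a call is either fully typed or fully missing
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    bad <- which(half, arr.ind = TRUE)[1, ]
    stop(sprintf("half-missing call for individual '%s' at locus '%s'",
                 ids[bad[1]], loci[bad[2]]))
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  if (!is.null(group)) {
    group <- as.character(group)
    if (length(group) != length(ids)) stop("group must have one label per individual")
  }
  structure(list(ids = ids, loci = loci, a1 = a1, a2 = a2, group = group),
            class = "genotype_table")
}

# recognised missing-data codes, normalised to NA
normalize_missing <- function(x) {
  x[x %in% c("0", "00", "000", "", "NA") | is.na(x)] <- NA_character_
  x
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals x %d loci, completeness %.3f\n",
              length(x$ids), length(x$loci), completeness(x)))
  if (!is.null(x$group)) {
    cat("groups:", paste(sprintf("%s (%d)", names(table(x$group)),
                                 table(x$group)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(length(x$ids), length(x$loci))

#' Fraction of non-missing calls
#'
#' @param g a [genotype_table()].
#' @return proportion of (individual, locus) cells with a typed call, in
#'   \[0, 1\].
#' @export
completeness <- function(g) {
  stopifnot(inherits(g, "genotype_table"))
  mean(!is.na(g$a1))
}

#' Logical matrix of typed calls
#' @noRd
typed_matrix <- function(g) !is.na(g$a1)

#' Read a genotype table from file
#'
#' Two dialects are supported. `"csv"` expects a header
#' `id,group,<locus>_a,<locus>_b,...` with one row per individual; `"genepop"`
#' parses the classic GenePop layout (title line, locus names one per line or
#' comma-separated, `Pop` separators, individuals as `id , 001002 003003 ...`
#' with 2- or 3-digit allele codes). GenePop `Pop` blocks become group labels
#' (`pop1`, `pop2`, ...). Missing codes (`0`, `000`, empty, `NA`) are
#' normalised on read.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"genepop"`.
#' @return a [genotype_table()].
#' @export
read_genotype_table <- function(path, dialect = c("csv", "genepop")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         csv = read_genotype_csv(path),
         genepop = read_genotype_genepop(path))
}

read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (ncol(df) < 4 || names(df)[1] != "id") {
    stop("genotype CSV must start with columns id,group and at least one locus pair")
  }
  has_group <- names(df)[2] == "group"
  allele_cols <- names(df)[(if (has_group) 3 else 2):ncol(df)]
  if (length(allele_cols) %% 2 != 0) {
    stop("odd number of allele columns; each locus needs <locus>_a,<locus>_b")
  }
  loci_a <- allele_cols[seq(1, length(allele_cols), by = 2)]
  loci_b <- allele_cols[seq(2, length(allele_cols), by = 2)]
  loci <- sub("_a$", "", loci_a)
  if (!all(sub("_b$", "", loci_b) == loci)) {
    stop("allele columns must alternate <locus>_a,<locus>_b; got mismatched pairs")
  }
  if (anyDuplicated(df$id)) {
    line <- which(duplicated(df$id))[1] + 1L
    stop(sprintf("duplicate individual id '%s' at line %d", df$id[duplicated(df$id)][1], line))
  }
  genotype_table(
    ids = df$id, loci = loci,
    a1 = as.matrix(df[loci_a]), a2 = as.matrix(df[loci_b]),
    group = if (has_group) ifelse(df$group == "", NA, df$group) else NULL
  )
}

read_genotype_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("GenePop file too short")
  body <- lines[-1]  # drop title line
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_idx) == 0) stop("GenePop file has no 'Pop' separator")
  locus_lines <- body[seq_len(pop_idx[1] - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[loci != ""]
  ids <- character(); grp <- character()
  a1 <- NULL; a2 <- NULL
  pop_no <- 0L
  for (i in seq(pop_idx[1], length(body))) {
    ln <- body[i]
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) {
      pop_no <- pop_no + 1L
      next
    }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2) {
      stop(sprintf("malformed GenePop individual line %d (no comma): %s",
                   i + 1L, ln))
    }
    id <- trimws(parts[1])
    calls <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(calls) != length(loci)) {
      stop(sprintf("line %d: %d genotypes for %d loci", i + 1L,
                   length(calls), length(loci)))
    }
    w <- nchar(calls)
    if (!all(w %in% c(4L, 6L))) {
      stop(sprintf("line %d: allele codes must be 2 or 3 digits per allele", i + 1L))
    }
    half <- w / 2L
    ids <- c(ids, id); grp <- c(grp, paste0("pop", pop_no))
    a1 <- rbind(a1, substr(calls, 1, half))
    a2 <- rbind(a2, substr(calls, half + 1, w))
  }
  genotype_table(ids = ids, loci = loci, a1 = a1, a2 = a2, group = grp)
}

#' Write a genotype table to file
#'
#' Inverse of [read_genotype_table()]; a write-then-read round trip
#' reproduces the table (up to the GenePop dialect's requirement of numeric
#' allele codes and per-block groups).
#'
#' @param g a [genotype_table()].
#' @param path output file path.
#' @param dialect `"csv"` or `"genepop"`.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(g, path, dialect = c("csv", "genepop")) {
  stopifnot(inherits(g, "genotype_table"))
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    out <- data.frame(id = g$ids,
                      group = if (is.null(g$group)) "" else ifelse(is.na(g$group), "", g$group),
                      stringsAsFactors = FALSE)
    for (j in seq_along(g$loci)) {
      out[[paste0(g$loci[j], "_a")]] <- ifelse(is.na(g$a1[, j]), "", g$a1[, j])
      out[[paste0(g$loci[j], "_b")]] <- ifelse(is.na(g$a2[, j]), "", g$a2[, j])
    }
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    if (!all(grepl("^[0-9]+$", c(g$a1[!is.na(g$a1)], g$a2[!is.na(g$a2)])))) {
      stop("GenePop output requires numeric allele codes")
    }
    pad <- function(x) ifelse(is.na(x), "000", formatC(x, width = 3, flag = "0"))
    grp <- if (is.null(g$group)) rep("pop1", length(g$ids)) else g$group
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("genotype export", g$loci), con)
    for (gv in unique(grp)) {
      writeLines("Pop", con)
      for (i in which(grp == gv)) {
        writeLines(paste0(g$ids[i], " , ",
                          paste0(pad(g$a1[i, ]), pad(g$a2[i, ]), collapse = " ")), con)
      }
    }
  }
  invisible(path)
}

#' Subset a genotype table by individuals
#'
#' @param g a [genotype_table()].
#' @param keep character ids or logical/integer index.
#' @return a [genotype_table()] restricted to `keep`.
#' @export
subset_individuals <- function(g, keep) {
  stopifnot(inherits(g, "genotype_table"))
  if (is.character(keep)) keep <- match(keep, g$ids)
  genotype_table(g$ids[keep], g$loci, g$a1[keep, , drop = FALSE],
                 g$a2[keep, , drop = FALSE],
                 group = if (is.null(g$group)) NULL else g$group[keep])
}
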