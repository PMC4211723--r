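# run code under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a distinct 32-bit sub-seed from a base seed and a stream index
sub_seed <- function(seed, stream) {
  (as.integer(seed) + 1664525L * as.integer(stream)) %% 2147483647L
}

#' Write a square pairwise matrix as CSV
#'
#' Shared on-disk format for relatedness and distance matrices: first row and
#' first column are individual ids, the diagonal is written `NA`. Read/write
#' round trips are exact.
#'
#' @param m a square matrix with dimnames, or a `pairwise_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  if (inherits(m, "pairwise_matrix")) m <- m$values
  stopifnot(is.matrix(m), nrow(m) == ncol(m), !is.null(rownames(m)))
  out <- m
  diag(out) <- NA
  df <- data.frame(id = rownames(out), out, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a square pairwise matrix from CSV
#'
#' @param path CSV written by [write_matrix_csv()] (or any externally
#'   produced matrix in the same layout, e.g. a coancestry matrix).
#' @return numeric matrix with id dimnames; diagonal is `NA`.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop("matrix CSV is not square")
  dimnames(m) <- list(ids, colnames(m))
  if (!identical(ids, colnames(m))) stop("row and column ids disagree")
  m
}
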