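#' Correct migration dates to the earliest migrant
#'
#' Rescales Julian day-of-year dates to counts of days since the earliest
#' date among all individuals, the response scale of the negative-binomial
#' timing models. Missing dates propagate.
#'
#' @param dates named numeric vector (id -> Julian day), NA allowed.
#' @return named non-negative integer vector; the earliest date maps to 0.
#' @export
correct_to_earliest <- function(dates) {
  if (length(dates) == 0 || all(is.na(dates))) {
    stop("no non-missing dates to correct")
  }
  out <- dates - min(dates, na.rm = TRUE)
  storage.mode(out) <- "integer"
  out
}

#' Pairwise migration-timing distance matrix
#'
#' Absolute pairwise differences (in days) between individuals' migration
#' dates. Individuals with missing dates are dropped with a warning. The
#' matrix is shift-invariant: translating all dates leaves it unchanged, so
#' raw Julian dates and earliest-corrected counts give the same matrix.
#'
#' @param dates named numeric vector (id -> Julian day or day count).
#' @return a [pairwise_matrix()] with kind `"distance"`, units `"days"`.
#' @export
timing_distance_matrix <- function(dates) {
  if (is.null(names(dates))) stop("dates must be named by individual id")
  miss <- is.na(dates)
  if (any(miss)) {
    warning("dropping ", sum(miss), " individual(s) with missing dates: ",
            paste(names(dates)[miss], collapse = ", "))
    dates <- dates[!miss]
  }
  if (length(dates) < 2) stop("fewer than 2 individuals with dates")
  m <- abs(outer(dates, dates, `-`))
  pairwise_matrix(m, kind = "distance", units = "days")
}

#' Pairwise centroid distance matrix
#'
#' Euclidean distances (meters) between individuals' seasonal range
#' centroids, used as the conditioning matrix in partial Mantel tests.
#'
#' @param centroids data frame with columns `id`, `winter_x`, `winter_y`,
#'   `summer_x`, `summer_y` (a season's pair may be NA).
#' @param season `"winter"` or `"summer"`.
#' @return a [pairwise_matrix()] with units `"meters"`.
#' @export
centroid_distance_matrix <- function(centroids, season = c("winter", "summer")) {
  season <- match.arg(season)
  xs <- centroids[[paste0(season, "_x")]]
  ys <- centroids[[paste0(season, "_y")]]
  ok <- is.finite(xs) & is.finite(ys)
  if (any(!ok)) {
    warning("dropping ", sum(!ok), " individual(s) with missing ", season,
            " centroid")
  }
  if (sum(ok) < 2) stop("fewer than 2 individuals with ", season, " centroids")
  xs <- xs[ok]; ys <- ys[ok]
  m <- sqrt(outer(xs, xs, `-`)^2 + outer(ys, ys, `-`)^2)
  dimnames(m) <- list(centroids$id[ok], centroids$id[ok])
  pairwise_matrix(m, kind = "distance", units = "meters")
}

# convex-hull containment with boundary counted as inside: test against the
# hull polygon inflated by a tiny factor about its centroid
in_hull <- function(px, py, hx, hy, tol = 1e-9) {
  cx <- mean(hx); cy <- mean(hy)
  hx2 <- cx + (hx - cx) * (1 + tol)
  hy2 <- cy + (hy - cy) * (1 + tol)
  as.logical(mgcv::in.out(cbind(hx2, hy2), cbind(px, py)))
}

mcp_hull <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) stop("degenerate hull: fewer than 3 distinct fixes")
  h <- grDevices::chull(pts[, 1], pts[, 2])
  list(x = pts[h, 1], y = pts[h, 2],
       centroid = c(mean(x), mean(y)))
}

#' Extract migration dates from a GPS track
#'
#' Demarcates one season's migration as the period of travel between the
#' winter and summer home ranges, each a minimum convex polygon (MCP) around
#' the fixes of the residency period. The origin MCP is built from fixes
#' before the season window; migration initiation is the time of the last
#' fix inside that MCP after which no same-season fix re-enters it
#' ("directed movement, without return"), so a brief excursion that returns
#' is not scored as migration. The destination MCP is built from fixes after
#' the season window; termination is the time of the first fix inside it
#' with all subsequent fixes through the end of the window remaining inside.
#' Range centroids are the mean fix locations of the two residency periods
#' (extended by the fixes the rule assigns to each range). Boundary fixes
#' count as inside a hull. An animal whose track never leaves the origin MCP
#' is flagged `resident` with missing dates (such animals are excluded from
#' that season's analyses).
#'
#' @param track data frame with columns `id`, `time` (POSIXct or numeric
#'   days), `x`, `y` in a projected planar coordinate system (meters).
#' @param season `"spring"` (winter -> summer) or `"fall"` (summer ->
#'   winter).
#' @param window integer Julian day-of-year c(start, end) bracketing the
#'   season's possible movement; defaults: spring Mar 1-Jul 15 (60, 196),
#'   fall Sep 1-Dec 15 (244, 349).
#' @return list with `id`, `season`, `start_day`, `end_day` (Julian
#'   day-of-year, NA if not migrating), `resident` flag, and `origin` /
#'   `destination` centroids.
#' @export
extract_migration_dates <- function(track, season = c("spring", "fall"),
                                    window = NULL) {
  season <- match.arg(season)
  if (is.null(window)) {
    window <- if (season == "spring") c(60L, 196L) else c(244L, 349L)
  }
  day <- track_day(track$time)
  o <- order(day)
  day <- day[o]; x <- track$x[o]; y <- track$y[o]
  if (anyDuplicated(day)) {
    # strictly increasing timestamps required; tolerate by tiny jitter order
    if (any(diff(day) < 0)) stop("timestamps not increasing")
  }
  pre <- day < window[1]
  post <- day > window[2]
  mid <- !pre & !post
  if (sum(pre) < 3 || sum(post) < 3) {
    stop("track does not span the ", season, " season window")
  }
  origin <- mcp_hull(x[pre], y[pre])
  dest <- mcp_hull(x[post], y[post])

  idx_mid <- which(mid)
  in_origin <- in_hull(x[idx_mid], y[idx_mid], origin$x, origin$y)
  in_dest <- in_hull(x[idx_mid], y[idx_mid], dest$x, dest$y)

  id1 <- track$id[1]
  if (all(in_origin)) {
    return(list(id = id1, season = season, start_day = NA_integer_,
                end_day = NA_integer_, resident = TRUE,
                origin = origin$centroid, destination = dest$centroid))
  }
  # initiation: last in-origin fix with no later same-season re-entry
  last_in <- max(which(in_origin))
  if (last_in == length(idx_mid)) {
    # ends season inside origin: no permanent departure
    return(list(id = id1, season = season, start_day = NA_integer_,
                end_day = NA_integer_, resident = TRUE,
                origin = origin$centroid, destination = dest$centroid))
  }
  start_day <- day[idx_mid[last_in]]
  # termination, two passes: the first entry into the hull of the
  # post-window fixes anchors the destination residency, whose MCP is then
  # rebuilt from every fix from that entry onward so that the full
  # destination range (not just its post-window part) defines "remaining
  # inside"
  first_entry <- which(in_dest & seq_along(idx_mid) > last_in)
  end_day <- NA_integer_
  if (length(first_entry)) {
    res_idx <- c(idx_mid[first_entry[1]:length(idx_mid)], which(post))
    dest <- mcp_hull(x[res_idx], y[res_idx])
    in_dest <- in_hull(x[idx_mid], y[idx_mid], dest$x, dest$y)
    stays <- rev(cumprod(rev(in_dest))) == 1  # all later fixes stay inside
    cand <- which(in_dest & stays & seq_along(idx_mid) > last_in)
    if (length(cand)) end_day <- day[idx_mid[cand[1]]]
  }

  origin_pts <- c(which(pre), idx_mid[seq_len(last_in)][in_origin[seq_len(last_in)]])
  dest_pts <- which(post)
  if (length(first_entry)) {
    dest_pts <- c(idx_mid[first_entry[1]:length(idx_mid)], dest_pts)
  }
  list(id = id1, season = season,
       start_day = as.integer(floor(start_day)),
       end_day = as.integer(floor(end_day)),
       resident = FALSE,
       origin = c(mean(x[origin_pts]), mean(y[origin_pts])),
       destination = c(mean(x[dest_pts]), mean(y[dest_pts])))
}

# timestamps to fractional Julian day-of-year
track_day <- function(time) {
  if (inherits(time, "POSIXct")) {
    lt <- as.POSIXlt(time, tz = "UTC")
    lt$yday + 1 + (lt$hour + lt$min / 60) / 24
  } else {
    as.numeric(time)
  }
}

#' Extract migration records for a set of tracks
#'
#' Applies [extract_migration_dates()] per individual for both seasons
#' present and assembles a migration-record table plus range centroids.
#'
#' @param tracks data frame with columns `id`, `time`, `x`, `y`.
#' @param seasons character subset of c("spring", "fall").
#' @return list with `records` (data frame: id, season, start_day, end_day,
#'   resident) and `centroids` (data frame: id, winter_x/y, summer_x/y).
#' @export
extract_all_migrations <- function(tracks, seasons = "spring") {
  ids <- unique(tracks$id)
  rec <- list(); cen <- list()
  for (id in ids) {
    tr <- tracks[tracks$id == id, , drop = FALSE]
    for (s in seasons) {
      r <- tryCatch(extract_migration_dates(tr, s), error = function(e) NULL)
      if (is.null(r)) next
      rec[[paste(id, s)]] <- data.frame(
        id = id, season = s, start_day = r$start_day, end_day = r$end_day,
        resident = r$resident)
      winter <- if (s == "spring") r$origin else r$destination
      summer <- if (s == "spring") r$destination else r$origin
      cen[[paste(id, s)]] <- data.frame(
        id = id, winter_x = winter[1], winter_y = winter[2],
        summer_x = summer[1], summer_y = summer[2])
    }
  }
  list(records = do.call(rbind, rec), centroids = do.call(rbind, cen))
}
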