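#' Construct a trajectory
#'
#' A trajectory is the time-ordered GPS track of one animal at a nominal fix
#' interval, with planar coordinates in metres.
#'
#' @param animal_id Single identifier token.
#' @param t Numeric vector of fix times (epoch seconds, UTC), strictly
#'   increasing.
#' @param x,y Numeric vectors of planar coordinates (metres east / north).
#' @param interval_s Nominal seconds between fixes. Defaults to the modal
#'   time step, which is robust to isolated gaps.
#' @return An object of class `trajectory`: a list with elements
#'   `animal_id`, `interval_s` and `fixes` (a data frame `t`, `x`, `y`).
#' @export
trajectory <- function(animal_id, t, x, y, interval_s = NULL) {
  stopifnot(length(animal_id) == 1, length(t) == length(x),
            length(t) == length(y))
  t <- as.numeric(t)
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(t)))
    stop("fix coordinates and times must be finite")
  if (is.unsorted(t, strictly = TRUE))
    stop("fix timestamps must be strictly increasing for animal '",
         animal_id, "'")
  if (is.null(interval_s)) interval_s <- modal_interval(t)
  structure(list(animal_id = as.character(animal_id),
                 interval_s = interval_s,
                 fixes = data.frame(t = t, x = as.numeric(x),
                                    y = as.numeric(y))),
            class = "trajectory")
}

modal_interval <- function(t) {
  if (length(t) < 2) return(NA_real_)
  d <- diff(t)
  tab <- table(d)
  as.numeric(names(tab)[which.max(tab)])
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> animal %s: %d fixes, nominal interval %s s\n",
              x$animal_id, nrow(x$fixes), format(x$interval_s)))
  invisible(x)
}

#' Project longitude/latitude to local planar metres
#'
#' Local equirectangular projection around an origin:
#' `x = R * cos(lat0) * dlon`, `y = R * dlat` (radians, R = 6371008.8 m).
#' Sub-decimetre accurate for the kilometre-scale extents of a tracking
#' study; not a general map projection.
#'
#' @param lon,lat Numeric vectors, degrees.
#' @param origin Length-2 numeric `c(lon0, lat0)` in degrees. The origin
#'   maps to (0, 0).
#' @return Two-column matrix with columns `x`, `y` in metres.
#' @export
to_planar <- function(lon, lat, origin) {
  stopifnot(length(origin) == 2)
  if (any(abs(c(lat, origin[2])) >= 89))
    stop("unsupported region: |latitude| >= 89 degrees")
  rad <- pi / 180
  x <- R_EARTH * cos(origin[2] * rad) * (lon - origin[1]) * rad
  y <- R_EARTH * (lat - origin[2]) * rad
  cbind(x = x, y = y)
}

# Accepts epoch seconds (numeric or all-numeric strings) or ISO-8601
# date-times ("2012-07-10 08:00:00" / "...T..."), interpreted as UTC.
parse_timestamp <- function(ts) {
  if (is.numeric(ts)) return(as.numeric(ts))
  ts <- trimws(as.character(ts))
  if (all(grepl("^-?[0-9]+(\\.[0-9]+)?$", ts))) return(as.numeric(ts))
  out <- as.POSIXct(sub("T", " ", ts, fixed = TRUE), tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  if (any(is.na(out))) stop("unparseable timestamp: ",
                            ts[which(is.na(out))[1]])
  as.numeric(out)
}

resolve_columns <- function(df, wanted, dialect, path) {
  cols <- stats::setNames(wanted, wanted)
  if (!is.null(dialect)) cols[names(dialect)] <- dialect
  for (w in wanted) {
    if (!cols[[w]] %in% names(df))
      stop("configuration error: file '", path, "' has no column '",
           cols[[w]], "' (expected for '", w, "')")
  }
  cols
}

#' Read a GPS fix table
#'
#' Reads a delimited fix table (header `animal_id,timestamp,x,y` in metres,
#' or `animal_id,timestamp,lon,lat` in degrees) and returns one trajectory
#' per animal, fixes sorted by time. Longitude/latitude input is converted
#' to planar metres with [to_planar()], origin at the centroid of the data.
#'
#' @param path Path to a CSV file.
#' @param dialect Optional named character vector mapping canonical column
#'   names (`animal_id`, `timestamp`, `x`, `y`, `lon`, `lat`) to the file's
#'   column names, e.g. `c(animal_id = "ID")`.
#' @return Named list of [trajectory()] objects, one per animal.
#' @export
read_fix_table <- function(path, dialect = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  base <- resolve_columns(df, c("animal_id", "timestamp"), dialect, path)
  xy_cols <- c("x", "y")
  lonlat <- !is.null(dialect) && all(c("lon", "lat") %in% names(dialect))
  if (!lonlat) {
    have_xy <- all((if (is.null(dialect)) xy_cols else
                      ifelse(xy_cols %in% names(dialect),
                             dialect[xy_cols], xy_cols)) %in% names(df))
    lonlat <- !have_xy && all(c("lon", "lat") %in% names(df))
  }
  if (lonlat) {
    cc <- resolve_columns(df, c("lon", "lat"), dialect, path)
    origin <- c(mean(df[[cc[["lon"]]]]), mean(df[[cc[["lat"]]]]))
    pl <- to_planar(df[[cc[["lon"]]]], df[[cc[["lat"]]]], origin)
    df$.x <- pl[, "x"]; df$.y <- pl[, "y"]
  } else {
    cc <- resolve_columns(df, c("x", "y"), dialect, path)
    df$.x <- df[[cc[["x"]]]]; df$.y <- df[[cc[["y"]]]]
  }
  df$.t <- parse_timestamp(df[[base[["timestamp"]]]])
  df$.id <- as.character(df[[base[["animal_id"]]]])
  dup <- duplicated(df[, c(".id", ".t")])
  if (any(dup))
    stop("duplicate timestamp for animal '", df$.id[which(dup)[1]],
         "' at row ", which(dup)[1])
  out <- lapply(split(df, df$.id), function(g) {
    g <- g[order(g$.t), ]
    trajectory(g$.id[1], g$.t, g$.x, g$.y)
  })
  out[order(names(out))]
}

#' Read a behavioural observation log
#'
#' Reads a CSV with header `animal_id,t_start,t_end,behaviour`, one row per
#' observed bout. Labels must come from the ethogram; bouts of one animal
#' must not overlap (abutting bouts are fine).
#'
#' @param path Path to a CSV file.
#' @return Data frame with columns `animal_id`, `t_start`, `t_end`
#'   (epoch seconds) and `behaviour`.
#' @export
read_observation_log <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "t_start", "t_end", "behaviour")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("configuration error: observation log lacks column '",
         miss[1], "'")
  segs <- data.frame(animal_id = as.character(df$animal_id),
                     t_start = parse_timestamp(df$t_start),
                     t_end = parse_timestamp(df$t_end),
                     behaviour = as.character(df$behaviour),
                     stringsAsFactors = FALSE)
  validate_segments(segs)
}

validate_segments <- function(segs) {
  bad <- !segs$behaviour %in% ETHOGRAM
  if (any(bad))
    stop("unknown behaviour label '", segs$behaviour[which(bad)[1]],
         "'; ethogram labels are: ", paste(ETHOGRAM, collapse = ", "))
  if (any(segs$t_end <= segs$t_start))
    stop("observation segment with t_end <= t_start (row ",
         which(segs$t_end <= segs$t_start)[1], ")")
  for (id in unique(segs$animal_id)) {
    g <- segs[segs$animal_id == id, ]
    g <- g[order(g$t_start), ]
    if (nrow(g) > 1 && any(g$t_start[-1] < g$t_end[-nrow(g)] - 1e-9)) {
      i <- which(g$t_start[-1] < g$t_end[-nrow(g)] - 1e-9)[1]
      stop("overlapping observation segments for animal '", id,
           "' around t = ", g$t_start[i + 1], " .. ", g$t_end[i])
    }
  }
  segs
}

SAMPLE_COLUMNS <- c("animal_id", "t_start", "t_end", "distance_m",
                    "angle_deg", "behaviour", "purity")

#' Write / read interval samples
#'
#' Interval samples are written as CSV with header
#' `animal_id,t_start,t_end,distance_m,angle_deg,behaviour,purity`.
#' An undefined turning angle is written as an empty field so that
#' "undefined" survives a round trip (it is distinct from 0 degrees).
#'
#' @param samples Data frame of interval samples (or a `labelled_dataset`,
#'   whose `$samples` are written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interval_samples <- function(samples, path) {
  if (inherits(samples, "labelled_dataset")) samples <- samples$samples
  if (nrow(samples) == 0) {
    samples <- as.data.frame(
      stats::setNames(rep(list(character(0)), length(SAMPLE_COLUMNS)),
                      SAMPLE_COLUMNS))
  }
  stopifnot(all(SAMPLE_COLUMNS %in% names(samples)))
  write.csv(samples[, SAMPLE_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_interval_samples
#' @export
read_interval_samples <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (col in c("t_start", "t_end", "distance_m", "angle_deg"))
    df[[col]] <- as.numeric(df[[col]])
  for (col in c("animal_id", "behaviour", "purity"))
    df[[col]] <- as.character(df[[col]])
  df
}
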