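#' Observed seconds per behaviour within an interval
#'
#' Intersects the window `[t_start, t_end)` with a set of non-overlapping
#' observation segments and totals the observed seconds per behaviour. Time
#' not covered by any segment is reported under the reserved key
#' `"unobserved"`.
#'
#' @param t_start,t_end Interval bounds (epoch seconds).
#' @param segments Data frame of observation segments for one animal
#'   (`t_start`, `t_end`, `behaviour`).
#' @return Named numeric vector of seconds (behaviours with positive
#'   overlap, plus `"unobserved"` when coverage is incomplete).
#' @export
overlap_by_behaviour <- function(t_start, t_end, segments) {
  stopifnot(t_end > t_start)
  ov <- pmax(0, pmin(segments$t_end, t_end) - pmax(segments$t_start, t_start))
  keep <- ov > 0
  out <- if (any(keep)) {
    v <- tapply(ov[keep], segments$behaviour[keep], sum)
    stats::setNames(as.numeric(v), names(v))
  } else stats::setNames(numeric(0), character(0))
  unobs <- (t_end - t_start) - sum(out)
  if (unobs > 1e-9) out <- c(out, unobserved = unobs)
  out
}

#' Label an interval from its behaviour overlaps
#'
#' In `"pure"` mode the interval gets a label only if a single behaviour
#' covers (essentially) the whole interval; in `"dominant"` mode it gets the
#' behaviour with the most observed seconds, provided the interval is fully
#' observed. Ties for the maximum, partial observation coverage, and empty
#' overlaps all yield `NA` (no label): partially observed intervals are
#' never used, and a tie rule would be arbitrary.
#'
#' @param overlaps Named seconds as returned by [overlap_by_behaviour()].
#' @param duration Interval duration in seconds.
#' @param mode `"pure"` or `"dominant"`.
#' @param coverage Minimum fraction of the interval that must be covered
#'   (by the single behaviour in pure mode; by observation in dominant
#'   mode). The default 0.99 absorbs the 1 s recording granularity of
#'   observation logs against exact GPS timestamps.
#' @return Behaviour label or `NA_character_`.
#' @export
label_interval <- function(overlaps, duration, mode = c("pure", "dominant"),
                           coverage = 0.99) {
  mode <- match.arg(mode)
  obs <- overlaps[names(overlaps) != "unobserved"]
  if (length(obs) == 0) return(NA_character_)
  if (sum(overlaps) > duration * (1 + 1e-6))
    stop("overlap seconds exceed interval duration")
  if (mode == "pure") {
    i <- which.max(obs)
    if (obs[i] >= coverage * duration) return(names(obs)[i])
    return(NA_character_)
  }
  unobs <- duration - sum(obs)
  if (unobs > (1 - coverage) * duration) return(NA_character_)
  m <- max(obs)
  if (sum(obs >= m - 1e-9) > 1) return(NA_character_)
  names(obs)[which.max(obs)]
}

#' Construct a labelled dataset
#'
#' @param samples Data frame of interval samples (columns
#'   `animal_id`, `t_start`, `t_end`, `distance_m`, `angle_deg`,
#'   `behaviour`, `purity`).
#' @param classes Ordered class labels; defaults to the sorted labels
#'   occurring in `samples`. Classes may have zero samples (they still count
#'   for coverage checks and confusion-matrix layout).
#' @param metadata Free-form list (habitat tag, interval_s, ...).
#' @return An object of class `labelled_dataset`.
#' @export
labelled_dataset <- function(samples, classes = NULL, metadata = list()) {
  if (is.null(classes)) classes <- sort(unique(samples$behaviour))
  if (nrow(samples) && !all(samples$behaviour %in% classes))
    stop("sample behaviour outside the class set")
  structure(list(samples = samples, classes = classes, metadata = metadata),
            class = "labelled_dataset")
}

#' @export
print.labelled_dataset <- function(x, ...) {
  cat(sprintf("<labelled_dataset> %d samples, classes: %s\n",
              nrow(x$samples), paste(x$classes, collapse = ", ")))
  if (nrow(x$samples)) print(table(x$samples$behaviour))
  invisible(x)
}

#' Pool behaviour classes
#'
#' Rewrites labels according to `pooling` (e.g.
#' `c(Lying = "Resting", Standing = "Resting")`), recomputes the class list
#' (alphabetical) and leaves every sample's metrics untouched.
#'
#' @param dataset A [labelled_dataset()].
#' @param pooling Named character vector, `names = source label`,
#'   `values = target label`. `NULL` or empty means no pooling.
#' @return A [labelled_dataset()].
#' @export
pool_classes <- function(dataset, pooling) {
  stopifnot(inherits(dataset, "labelled_dataset"))
  if (is.null(pooling) || length(pooling) == 0) return(dataset)
  unknown <- setdiff(names(pooling), dataset$classes)
  if (length(unknown))
    stop("pooling references unknown label '", unknown[1], "'")
  map <- stats::setNames(dataset$classes, dataset$classes)
  map[names(pooling)] <- pooling
  samples <- dataset$samples
  if (nrow(samples)) samples$behaviour <- unname(map[samples$behaviour])
  labelled_dataset(samples, classes = sort(unique(unname(map))),
                   metadata = dataset$metadata)
}

#' Couple a trajectory to observations and build a labelled dataset
#'
#' Computes interval metrics, assigns a behaviour label to each between-fix
#' interval (pure or dominant mode), drops unlabelled intervals and labels
#' outside `class_filter`, applies class pooling, and finally drops samples
#' with an undefined turning angle (the classifier needs both features).
#' In dominant mode the `purity` column records whether the interval would
#' also have been labelled in pure mode.
#'
#' @param traj A [trajectory()].
#' @param segments Observation segments (as from [read_observation_log()]).
#' @param mode `"pure"` or `"dominant"`.
#' @param class_filter Labels to keep before pooling; defaults to the four
#'   dominant behaviours (Foraging, Lying, Standing, Walking).
#' @param pooling Optional pooling map, see [pool_classes()].
#' @param metadata Passed to [labelled_dataset()]; `interval_s` is added.
#' @inheritParams label_interval
#' @return A [labelled_dataset()].
#' @export
build_labelled_dataset <- function(traj, segments,
                                   mode = c("pure", "dominant"),
                                   class_filter = DOMINANT_BEHAVIOURS,
                                   pooling = NULL, coverage = 0.99,
                                   metadata = list()) {
  mode <- match.arg(mode)
  metrics <- interval_metrics(traj)
  segs <- segments[segments$animal_id == traj$animal_id, , drop = FALSE]
  n <- nrow(metrics)
  lab <- character(n); pur <- character(n)
  for (i in seq_len(n)) {
    ov <- overlap_by_behaviour(metrics$t_start[i], metrics$t_end[i], segs)
    dur <- metrics$t_end[i] - metrics$t_start[i]
    l <- label_interval(ov, dur, mode, coverage)
    lab[i] <- l
    pur[i] <- if (mode == "pure") "pure" else {
      lp <- label_interval(ov, dur, "pure", coverage)
      if (!is.na(lp) && identical(lp, l)) "pure" else "dominant"
    }
  }
  keep <- !is.na(lab) & lab %in% class_filter
  samples <- data.frame(animal_id = traj$animal_id,
                        t_start = metrics$t_start,
                        t_end = metrics$t_end,
                        distance_m = metrics$distance_m,
                        angle_deg = metrics$angle_deg,
                        behaviour = lab, purity = pur,
                        stringsAsFactors = FALSE)[keep, ]
  classes <- sort(unique(class_filter))
  ds <- labelled_dataset(samples, classes = classes,
                         metadata = c(metadata,
                                      list(interval_s = traj$interval_s,
                                           label_mode = mode)))
  ds <- pool_classes(ds, pooling)
  defined <- !is.na(ds$samples$angle_deg)
  ds$samples <- ds$samples[defined, ]
  rownames(ds$samples) <- NULL
  if (nrow(ds$samples) == 0) warning("no labelled intervals remain")
  ds
}

#' Time budget of observed behaviour
#'
#' Divides observations into wall-clock time classes of `class_width`
#' seconds (e.g. 1800 for half-hour classes) and returns, per class, the
#' proportion of observed time allocated to each behaviour. Proportions per
#' class sum to 1.
#'
#' @param segments Observation segments.
#' @param class_width Width of the time classes in seconds (1800 or 3600).
#' @return Matrix, rows = time classes (start second as rowname),
#'   columns = behaviours.
#' @export
time_budget <- function(segments, class_width = 1800) {
  stopifnot(class_width > 0, nrow(segments) > 0)
  pieces <- list()
  for (i in seq_len(nrow(segments))) {
    s <- segments$t_start[i]; e <- segments$t_end[i]
    edges <- unique(c(s, seq(ceiling(s / class_width) * class_width, e,
                             by = class_width), e))
    edges <- sort(edges[edges >= s & edges <= e])
    if (length(edges) < 2) edges <- c(s, e)
    pieces[[i]] <- data.frame(
      class_start = floor(edges[-length(edges)] / class_width) * class_width,
      behaviour = segments$behaviour[i],
      seconds = diff(edges))
  }
  pieces <- do.call(rbind, pieces)
  tab <- tapply(pieces$seconds,
                list(factor(pieces$class_start),
                     factor(pieces$behaviour)), sum, default = 0)
  sweep(tab, 1, rowSums(tab), "/")
}
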