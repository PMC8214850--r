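#' @useDynLib gardenhunt, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aggregate
NULL

# Timestamps are treated as local clock time with no DST (stored as UTC);
# minute resolution is sufficient for the 5-minute event rule.
.parse_timestamps <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  for (fmt in fmts) {
    idx <- which(is.na(out) & !is.na(x))
    if (!length(idx)) break
    out[idx] <- as.POSIXct(strptime(x[idx], fmt, tz = "UTC"))
  }
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop("unparseable timestamp in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  out
}

#' Collapse photo records into detection events
#'
#' Consecutive photos of the same species at the same camera separated by
#' less than `gap_minutes` are merged into a single detection event; a gap of
#' exactly `gap_minutes` or more starts a new event ("less than 5 min" is
#' strict).
#'
#' @param photos data frame with columns `camera_id`, `species`, `timestamp`
#'   (POSIXct or ISO-8601 character).
#' @param gap_minutes minimum separation, in minutes, between events.
#' @return data frame of events with columns `camera_id`, `species`,
#'   `start_time`, `end_time`, `n_photos`, ordered by camera, species, time.
#' @export
collapse_events <- function(photos, gap_minutes = 5) {
  stopifnot(is.data.frame(photos))
  need <- c("camera_id", "species", "timestamp")
  miss <- setdiff(need, names(photos))
  if (length(miss)) stop("photos is missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(photos))
    return(data.frame(camera_id = character(), species = character(),
                      start_time = as.POSIXct(character(), tz = "UTC"),
                      end_time = as.POSIXct(character(), tz = "UTC"),
                      n_photos = integer(), stringsAsFactors = FALSE))
  if (any(is.na(photos$species) | !nzchar(as.character(photos$species))))
    stop("species must be non-empty for every photo record")
  ts <- .parse_timestamps(photos$timestamp)
  ord <- order(photos$camera_id, photos$species, ts)
  cam <- as.character(photos$camera_id)[ord]
  sp <- as.character(photos$species)[ord]
  ts <- ts[ord]
  key <- paste(cam, sp, sep = "\r")
  gap <- as.numeric(difftime(ts, c(ts[1], ts[-length(ts)]), units = "mins"))
  new_event <- c(TRUE, key[-1] != key[-length(key)]) | gap >= gap_minutes
  new_event[1] <- TRUE
  eid <- cumsum(new_event)
  out <- data.frame(
    camera_id = cam[new_event],
    species = sp[new_event],
    start_time = ts[new_event],
    end_time = as.POSIXct(tapply(as.numeric(ts), eid, max),
                          origin = "1970-01-01", tz = "UTC"),
    n_photos = as.integer(tabulate(eid)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Tabulate detection events per species and per class
#'
#' @param events data frame from [collapse_events()].
#' @param class_map optional data frame with columns `species`, `class`
#'   (e.g. "mammal"/"bird"); species absent from the map are counted under
#'   class "unidentified" with a warning.
#' @return list with `by_species` (species, class, D) and `by_class`
#'   (class, D) data frames; D is the detection-event count.
#' @export
tabulate_detections <- function(events, class_map = NULL) {
  stopifnot(is.data.frame(events))
  if (!nrow(events)) {
    by_sp <- data.frame(species = character(), class = character(),
                        D = integer(), stringsAsFactors = FALSE)
    return(list(by_species = by_sp,
                by_class = data.frame(class = character(), D = integer(),
                                      stringsAsFactors = FALSE)))
  }
  tab <- table(as.character(events$species))
  by_sp <- data.frame(species = names(tab), D = as.integer(tab),
                      stringsAsFactors = FALSE)
  if (is.null(class_map)) {
    by_sp$class <- NA_character_
  } else {
    stopifnot(all(c("species", "class") %in% names(class_map)))
    idx <- match(by_sp$species, class_map$species)
    by_sp$class <- as.character(class_map$class)[idx]
    if (anyNA(by_sp$class)) {
      warning("unknown species code(s) counted as 'unidentified': ",
              paste(by_sp$species[is.na(by_sp$class)], collapse = ", "))
      by_sp$class[is.na(by_sp$class)] <- "unidentified"
    }
  }
  by_sp <- by_sp[order(-by_sp$D, by_sp$species), c("species", "class", "D")]
  rownames(by_sp) <- NULL
  by_cl <- if (all(is.na(by_sp$class)))
    data.frame(class = "all", D = sum(by_sp$D), stringsAsFactors = FALSE)
  else aggregate(D ~ class, data = by_sp, FUN = sum)
  list(by_species = by_sp, by_class = by_cl)
}

#' Frequency of detection per 100 camera-days
#'
#' FD = 100 * D / camera_days: the standard rate used to compare camera-trap
#' surveys of different effort. The raw value is returned; round with
#' [round_half_up()] for reporting at two decimals.
#'
#' @param D detection-event count(s).
#' @param camera_days total survey effort in camera-days (> 0).
#' @return numeric FD value(s).
#' @export
frequency_of_detection <- function(D, camera_days) {
  if (any(!is.finite(camera_days)) || any(camera_days <= 0))
    stop("camera_days must be positive")
  if (any(D < 0)) stop("D must be non-negative")
  100 * D / camera_days
}

#' Round half away from zero
#'
#' Decimal rounding where .5 always rounds up in magnitude, as used for
#' printed report tables (base R `round` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Inverse-distance-weighted track density at camera sites
#'
#' Summarises off-camera wildlife sign (tracks, scats, direct observations)
#' as sum_j 1 / max(d_ij, d_floor)^q over all records j, where d_ij is the
#' planar distance in metres from site i to record j. Small q gives a very
#' smooth surface; the survey default is q = 0.25. The floor avoids division
#' by zero when a record coincides with a camera.
#'
#' @param site_xy data frame or matrix with columns `x`, `y` (projected
#'   metres), one row per site.
#' @param records data frame with columns `x`, `y` of track records.
#' @param q positive inverse-distance power.
#' @param d_floor_m minimum distance in metres.
#' @return numeric vector of raw (unstandardized) densities, one per site.
#' @export
track_density <- function(site_xy, records, q = 0.25, d_floor_m = 1) {
  site_xy <- as.data.frame(site_xy)
  stopifnot(all(c("x", "y") %in% names(site_xy)), q > 0, d_floor_m > 0)
  if (is.null(records) || !nrow(records)) {
    warning("no track records; density is 0 at every site")
    return(rep(0, nrow(site_xy)))
  }
  if (any(!is.finite(records$x)) || any(!is.finite(records$y)))
    stop("track record coordinates must be finite")
  vapply(seq_len(nrow(site_xy)), function(i) {
    d <- sqrt((records$x - site_xy$x[i])^2 + (records$y - site_xy$y[i])^2)
    sum(pmax(d, d_floor_m)^(-q))
  }, numeric(1))
}

#' Standardize to zero mean and unit sample standard deviation
#'
#' Missing values are ignored in the moments and preserved in the output.
#' The sample (n-1) standard deviation is used.
#'
#' @param values numeric vector with at least two distinct non-missing values.
#' @export
standardize <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least two non-missing values")
  s <- stats::sd(values[ok])
  if (!is.finite(s) || s == 0) stop("zero variance: cannot standardize")
  out <- values
  out[ok] <- (values[ok] - mean(values[ok])) / s
  out
}

#' Filter camera sites by activity and distance to conuco
#'
#' Retains sites with total active days >= `min_active_days` and distance to
#' the nearest conuco <= `max_dist_conuco_m`; every exclusion is logged with
#' its reason.
#'
#' @param covariates data frame with `camera_id` and `dist_conuco` (metres).
#' @param deployments data frame with `camera_id`, `start`, `end` (Date or
#'   parseable character; inclusive activity intervals).
#' @param min_active_days minimum total days a camera must have been active.
#' @param max_dist_conuco_m maximum distance to conuco in metres.
#' @return list with `retained` (character camera ids) and `log` (data frame
#'   camera_id, reason) of exclusions.
#' @export
filter_sites <- function(covariates, deployments, min_active_days = 7,
                         max_dist_conuco_m = 5000) {
  stopifnot(all(c("camera_id", "dist_conuco") %in% names(covariates)))
  act <- deployment_active_days(deployments)
  days <- act$days[match(covariates$camera_id, act$camera_id)]
  days[is.na(days)] <- 0
  log <- data.frame(camera_id = character(), reason = character(),
                    stringsAsFactors = FALSE)
  short <- covariates$camera_id[days < min_active_days]
  far <- covariates$camera_id[covariates$dist_conuco > max_dist_conuco_m]
  if (length(short))
    log <- rbind(log, data.frame(camera_id = as.character(short),
                                 reason = "min_active_days"))
  if (length(far))
    log <- rbind(log, data.frame(camera_id = as.character(far),
                                 reason = "distance"))
  retained <- setdiff(as.character(covariates$camera_id),
                      unique(log$camera_id))
  if (!length(retained)) warning("no sites retained after filtering")
  list(retained = retained, log = log)
}

#' Total active days per camera
#' @param deployments data frame with `camera_id`, `start`, `end`.
#' @return data frame camera_id, days.
#' @export
deployment_active_days <- function(deployments) {
  stopifnot(all(c("camera_id", "start", "end") %in% names(deployments)))
  st <- as.Date(deployments$start)
  en <- as.Date(deployments$end)
  if (any(en < st)) stop("deployment interval ends before it starts")
  days <- as.integer(en - st) + 1L
  agg <- aggregate(days, list(camera_id = as.character(deployments$camera_id)),
                   FUN = sum)
  names(agg)[2] <- "days"
  agg
}

# Visit windows: the season is split into consecutive periods of
# `period_days`; each period is cut into windows of `visit_days`, the last
# window of each period truncated at the period boundary (60 = 21 + 21 + 18),
# so effort normalised by actual window length stays <= 1.
.visit_windows <- function(season_days, visit_days, period_days) {
  starts <- integer(0); ends <- integer(0)
  for (p0 in seq(0, season_days - 1, by = period_days)) {
    pend <- min(p0 + period_days, season_days)
    off <- seq(p0, pend - 1, by = visit_days)
    starts <- c(starts, off)
    ends <- c(ends, pmin(off + visit_days, pend))
  }
  data.frame(start_offset = starts, end_offset = ends,
             length = ends - starts)
}

#' Build per-species detection histories from events and deployments
#'
#' Divides a `season_days`-long season into visits of `visit_days` (the last
#' visit of each `period_days` block truncated at the block boundary) and
#' produces, per species, the site-by-visit binary detection matrix `y`, the
#' paired effort matrix (active days / window length, NA when the camera was
#' absent or inoperative for the whole visit) and the standardized
#' visit-start date covariate.
#'
#' @param events data frame from [collapse_events()].
#' @param deployments data frame with `camera_id`, `start`, `end` activity
#'   intervals (and optionally `x`, `y`, `block`).
#' @param season_start Date (or parseable character) of day 1 of the season.
#' @param visit_days visit window length in days.
#' @param season_days season length in days.
#' @param period_days sampling-period length in days (visits never span a
#'   period boundary).
#' @param species optional character vector restricting the output.
#' @return named list of `detection_history` objects, one per species, each
#'   with elements `species`, `sites`, `visits`, `y`, `effort`, `date`.
#' @export
build_histories <- function(events, deployments, season_start,
                            visit_days = 21, season_days = 180,
                            period_days = 60, species = NULL) {
  season_start <- as.Date(season_start)
  stopifnot(visit_days >= 1, season_days >= visit_days,
            period_days >= visit_days)
  win <- .visit_windows(season_days, visit_days, period_days)
  J <- nrow(win)
  sites <- sort(unique(as.character(deployments$camera_id)))
  M <- length(sites)
  dep <- deployments
  dep$camera_id <- as.character(dep$camera_id)
  dep$start <- as.Date(dep$start)
  dep$end <- as.Date(dep$end)

  # active days of each site within each visit window (window end exclusive)
  active <- matrix(0L, M, J, dimnames = list(sites, NULL))
  for (k in seq_len(nrow(dep))) {
    i <- match(dep$camera_id[k], sites)
    s_off <- as.integer(dep$start[k] - season_start)
    e_off <- as.integer(dep$end[k] - season_start) + 1L # exclusive
    ov <- pmax(0L, pmin(e_off, win$end_offset) - pmax(s_off, win$start_offset))
    active[i, ] <- active[i, ] + ov
  }
  effort <- sweep(active, 2, win$length, "/")
  effort[active == 0L] <- NA_real_

  if (nrow(events)) {
    missing_cam <- setdiff(unique(as.character(events$camera_id)), sites)
    if (length(missing_cam))
      stop("events reference cameras with no deployment: ",
           paste(missing_cam, collapse = ", "))
  }
  ev_date <- as.Date(as.POSIXct(events$start_time, tz = "UTC"))
  ev_off <- as.integer(ev_date - season_start)
  if (nrow(events) && any(ev_off < 0 | ev_off >= season_days))
    stop("event outside the season window: camera ",
         events$camera_id[which(ev_off < 0 | ev_off >= season_days)[1]],
         " on ", ev_date[which(ev_off < 0 | ev_off >= season_days)[1]])
  ev_visit <- if (nrow(events))
    findInterval(ev_off, win$start_offset) else integer(0)
  # each event must fall inside an activity interval of its camera
  if (nrow(events)) {
    for (k in seq_len(nrow(events))) {
      cam <- as.character(events$camera_id[k])
      ivals <- dep[dep$camera_id == cam, , drop = FALSE]
      if (!any(ev_date[k] >= ivals$start & ev_date[k] <= ivals$end))
        stop("event outside any deployment interval: camera ", cam,
             " on ", ev_date[k])
    }
  }

  date_std <- standardize(win$start_offset)
  date_mat <- matrix(rep(date_std, each = M), M, J, dimnames = list(sites, NULL))
  visits <- data.frame(win,
                       start_date = season_start + win$start_offset)

  sp_all <- sort(unique(as.character(events$species)))
  if (!is.null(species)) sp_all <- intersect(species, sp_all)
  out <- lapply(sp_all, function(sp) {
    y <- matrix(0L, M, J, dimnames = list(sites, NULL))
    sel <- as.character(events$species) == sp
    if (any(sel)) {
      ii <- match(as.character(events$camera_id)[sel], sites)
      jj <- ev_visit[sel]
      y[cbind(ii, jj)] <- 1L
    }
    y[is.na(effort)] <- NA_integer_
    structure(list(species = sp, sites = sites, visits = visits,
                   y = y, effort = effort, date = date_mat),
              class = "detection_history")
  })
  names(out) <- sp_all
  out
}

#' @export
print.detection_history <- function(x, ...) {
  nd <- sum(x$y == 1L, na.rm = TRUE)
  cat("Detection history:", x$species, "\n",
      length(x$sites), "sites x", ncol(x$y), "visits;",
      nd, "detections;", sum(is.na(x$y)), "missing site-visits\n")
  invisible(x)
}

#' Write a detection history as a wide CSV
#'
#' One row per site with columns `y_1..y_J` and `eff_1..eff_J`; missing
#' site-visits are written as `NA`.
#' @param history a `detection_history`.
#' @param path output file path.
#' @export
write_history_csv <- function(history, path) {
  J <- ncol(history$y)
  df <- data.frame(camera_id = history$sites,
                   history$y, history$effort, check.names = FALSE)
  names(df) <- c("camera_id", paste0("y_", seq_len(J)), paste0("eff_", seq_len(J)))
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}
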