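#' Parameters of a synthetic camera-trap + interview study
#'
#' Collects every generator parameter into one serializable object so that a
#' full synthetic study can be regenerated bit-identically from (truth,
#' seed). Defaults mirror the Gran Sabana design: 60 deployed sites in six
#' blocks, three 60-day periods with 21-day visits (up to 9 per site),
#' bimodal tree cover with a savanna mode at 10-20% and a forest mode at
#' 70-80%, distance to conuco with mean about 1.58 km and range 0-8 km, 159
#' off-camera track records, and 29 interview respondents in four
#' communities. Abundance (log link) and detection (logit link) coefficients
#' are expressed on the standardized covariate scales.
#'
#' @param seed master integer seed; all generator randomness derives from it.
#' @param n_sites number of deployed camera sites.
#' @param n_periods,period_days,visit_days,season_start survey calendar.
#' @param species named list; each element has `beta` (named log-scale
#'   abundance coefficients: `(Intercept)` plus any of `tree_buffer`,
#'   `dist_river`, `dist_conuco`) and `alpha` (named logit-scale detection
#'   coefficients: `(Intercept)` plus any of `effort`, `date`).
#' @param knockout_frac fraction of camera-visits made inoperative (NA
#'   effort) to exercise missing-data handling.
#' @param n_tracks number of off-camera track records.
#' @param n_interviews number of interview respondents.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(seed = 1,
                            n_sites = 60,
                            n_periods = 3,
                            period_days = 60,
                            visit_days = 21,
                            season_start = "2015-09-21",
                            species = list(
                              paca = list(
                                beta = c("(Intercept)" = 0.7,
                                         tree_buffer = 0.5,
                                         dist_conuco = -0.4),
                                alpha = c("(Intercept)" = -1.0, effort = 1.0)),
                              agouti = list(
                                beta = c("(Intercept)" = 0.4,
                                         tree_buffer = 0.8),
                                alpha = c("(Intercept)" = -1.2, effort = 1.0)),
                              curassow = list(
                                beta = c("(Intercept)" = -0.3,
                                         tree_buffer = 0.7,
                                         dist_conuco = -0.5),
                                alpha = c("(Intercept)" = -0.8, effort = 0.8))),
                            knockout_frac = 0.05,
                            n_tracks = 159,
                            n_interviews = 29) {
  structure(list(
    seed = as.integer(seed),
    n_sites = n_sites, n_periods = n_periods, period_days = period_days,
    visit_days = visit_days, season_start = as.character(season_start),
    season_days = n_periods * period_days,
    species = species,
    # tree cover %: savanna and forest beta components (modes ~16% and ~78%)
    tree_mix = list(w_savanna = 0.45, savanna = c(2.5, 9), forest = c(8, 3)),
    # metres; gamma gives mean ~1.58 km, truncated at the 8 km range limit
    conuco_dist = list(shape = 1.3, scale = 1215, max = 8000),
    river_dist = list(rate = 1 / 400, max = 3000),
    n_far_sites = 3,     # sites forced beyond the 5 km analysis limit
    n_short_sites = 4,   # cameras failing within the first week
    hunting_glm = c("(Intercept)" = -1.475, tree_buffer = 0.041,
                    dist_river = 0.001, dist_conuco = -2e-04),
    knockout_frac = knockout_frac,
    n_tracks = n_tracks,
    n_interviews = n_interviews,
    communities = c(Wuarapata = 11, `Uroy-Uaray` = 8, Kawi = 5,
                    `Mare-Paru` = 5),
    # per-vernacular citation probabilities (multinomial weights)
    citation_rate = 3, # Poisson rate of extra citations per hunter
    citation_prob = c(urana = 0.20, waikin = 0.18, pauwi = 0.14,
                      akuri = 0.10, maikuri = 0.09, maru = 0.07,
                      wora = 0.06, pakira = 0.05, kutsari = 0.04,
                      kariyawku = 0.04, armadillo = 0.03),
    preference_weight = c(waikin = 0.45, urana = 0.30, pauwi = 0.15,
                          akuri = 0.05, maikuri = 0.05),
    prop_active_hunters = 19 / 29, prop_inactive_hunters = 5 / 29
  ), class = "synthetic_truth")
}

#' Vernacular-to-taxon map used by the synthetic interviews
#'
#' Sends ambiguous vernacular names to genus-level taxa: the two brocket
#' deer vernaculars both map to Mazama and "armadillo" to Dasypus.
#' @return data frame `vernacular`, `taxon`.
#' @export
gh_taxonomy_map <- function() {
  data.frame(
    vernacular = c("urana", "akuri", "waikin", "maikuri", "pakira",
                   "kutsari", "kariyawku", "armadillo", "pauwi", "maru",
                   "wora"),
    taxon = c("Cuniculus", "Dasyprocta", "Odocoileus", "Tapirus", "Tayassu",
              "Mazama", "Mazama", "Dasypus", "Crax", "Tinamus", "Penelope"),
    stringsAsFactors = FALSE)
}

#' Write / read a synthetic truth as JSON
#' @param truth a `synthetic_truth`.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  x <- unclass(truth)
  # named vectors must become JSON objects, not bare arrays
  x$species <- lapply(x$species, function(sp)
    list(beta = as.list(sp$beta), alpha = as.list(sp$alpha)))
  for (nm in c("hunting_glm", "communities", "citation_prob",
               "preference_weight"))
    x[[nm]] <- as.list(x[[nm]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$species <- lapply(x$species, function(sp)
    list(beta = unlist(sp$beta), alpha = unlist(sp$alpha)))
  for (nm in c("hunting_glm", "communities", "citation_prob",
               "preference_weight"))
    x[[nm]] <- unlist(x[[nm]])
  structure(x, class = "synthetic_truth")
}

.rtrunc <- function(n, rfun, max, ...) {
  x <- rfun(n, ...)
  while (any(bad <- x > max)) x[bad] <- rfun(sum(bad), ...)
  x
}

#' Simulate the synthetic landscape: site covariates and track records
#'
#' Tree cover is drawn from a two-component beta mixture with a savanna
#' mode at 10-20% and a forest mode at 70-80%; distance to conuco from a
#' truncated gamma (mean ~1.58 km, range 0-8 km) with a few sites forced
#' beyond the 5 km analysis limit; track records cluster near forested
#' sites. The hunting flag follows a logistic model on the raw covariates.
#'
#' @param truth a [synthetic_truth()].
#' @return list with `covariates` (camera_id, x, y, block, tree_buffer,
#'   dist_river, dist_conuco, hunting) and `tracks` (x, y, date, note).
#' @export
simulate_landscape <- function(truth) {
  set.seed(truth$seed)
  M <- truth$n_sites
  ids <- sprintf("S%02d", seq_len(M))
  blocks <- sprintf("B%02d", rep_len(1:6, M))
  # six 7 km blocks on a 3 x 2 grid; site coordinates uniform within block
  bx <- (match(blocks, sprintf("B%02d", 1:6)) - 1) %% 3
  by <- (match(blocks, sprintf("B%02d", 1:6)) - 1) %/% 3
  x <- bx * 7000 + stats::runif(M, 500, 6500)
  y <- by * 7000 + stats::runif(M, 500, 6500)

  mix <- truth$tree_mix
  comp <- stats::runif(M) < mix$w_savanna
  tree <- ifelse(comp,
                 stats::rbeta(M, mix$savanna[1], mix$savanna[2]),
                 stats::rbeta(M, mix$forest[1], mix$forest[2])) * 100
  tree <- pmin(pmax(tree, 0), 100)

  dc <- .rtrunc(M, stats::rgamma, truth$conuco_dist$max,
                shape = truth$conuco_dist$shape,
                scale = truth$conuco_dist$scale)
  far <- sample.int(M, truth$n_far_sites)
  dc[far] <- stats::runif(truth$n_far_sites, 5200, truth$conuco_dist$max)
  dr <- .rtrunc(M, stats::rexp, truth$river_dist$max,
                rate = truth$river_dist$rate)

  hg <- truth$hunting_glm
  ph <- stats::plogis(hg[["(Intercept)"]] + hg[["tree_buffer"]] * tree +
                      hg[["dist_river"]] * dr + hg[["dist_conuco"]] * dc)
  hunting <- stats::runif(M) < ph

  # tracks: most sign accumulates near forested sites, the rest anywhere
  nt <- truth$n_tracks
  n_forest <- round(0.7 * nt)
  fsites <- which(tree > 50)
  if (!length(fsites)) fsites <- seq_len(M)
  anchor <- sample(fsites, n_forest, replace = TRUE)
  tx <- c(x[anchor] + stats::rnorm(n_forest, 0, 300),
          stats::runif(nt - n_forest, 0, 21000))
  ty <- c(y[anchor] + stats::rnorm(n_forest, 0, 300),
          stats::runif(nt - n_forest, 0, 14000))
  tracks <- data.frame(
    x = tx, y = ty,
    date = as.character(as.Date(truth$season_start) +
                          sample.int(truth$season_days, nt, replace = TRUE) - 1),
    note = sample(c("tracks", "scat", "burrow", "direct observation"),
                  nt, replace = TRUE),
    stringsAsFactors = FALSE)

  list(covariates = data.frame(camera_id = ids, x = x, y = y, block = blocks,
                               tree_buffer = tree, dist_river = dr,
                               dist_conuco = dc, hunting = hunting,
                               stringsAsFactors = FALSE),
       tracks = tracks)
}

# per-site logical activity calendar -> deployment interval rows
.runs_to_intervals <- function(active, camera_id, xy, block, season_start) {
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  if (!length(keep)) return(NULL)
  data.frame(camera_id = camera_id, x = xy[1], y = xy[2], block = block,
             start = as.character(season_start + starts[keep] - 1),
             end = as.character(season_start + ends[keep] - 1),
             stringsAsFactors = FALSE)
}

#' Simulate the camera-trap survey: deployments and photo records
#'
#' Sites are split over the three sampling periods (a third of them kept in
#' place for the whole season, the rest deployed for one period each, as
#' when a fixed pool of cameras is rotated). A few cameras fail within the
#' first week, and a configurable fraction of camera-visits is knocked out
#' to exercise missing-effort handling. Detections follow the
#' Royle-Nichols process: N_i ~ Poisson(exp(x_i . beta)) per species, and
#' each operative visit detects with p = 1 - (1 - r_ij)^N_i where
#' logit(r_ij) includes the visit effort (and optionally date). Detected
#' visits emit 1-3 photo timestamps within one five-minute burst.
#'
#' @param truth a [synthetic_truth()].
#' @param landscape result of [simulate_landscape()].
#' @return list with `photos`, `deployments`, and `latent` (per-species
#'   site abundances actually drawn).
#' @export
simulate_rn_survey <- function(truth, landscape) {
  set.seed(truth$seed + 1L)
  cov <- landscape$covariates
  M <- nrow(cov)
  season_start <- as.Date(truth$season_start)
  S <- truth$season_days
  win <- .visit_windows(S, truth$visit_days, truth$period_days)
  J <- nrow(win)

  n_fixed <- floor(M * 0.3)
  fixed <- sample.int(M, n_fixed)
  rotating <- setdiff(seq_len(M), fixed)
  period_of <- rep_len(seq_len(truth$n_periods), length(rotating))

  # deployment and retrieval are staggered within each period (field crews
  # take several days to service a block), so visit effort varies in (0, 1]
  active <- matrix(FALSE, M, S)
  activate_period <- function(i, p) {
    d1 <- sample(0:8, 1); d2 <- sample(0:8, 1)
    a <- (p - 1) * truth$period_days + 1 + d1
    b <- p * truth$period_days - d2
    if (a <= b) active[i, a:b] <<- TRUE
  }
  for (i in fixed) for (p in seq_len(truth$n_periods)) activate_period(i, p)
  for (k in seq_along(rotating))
    activate_period(rotating[k], period_of[k])
  short <- sample.int(M, truth$n_short_sites)
  for (i in short) {
    first <- which(active[i, ])[1]
    keep <- first:(first + sample(3:5, 1) - 1)
    active[i, ] <- FALSE
    active[i, keep] <- TRUE
  }
  # knock out whole visits at random (camera inoperative)
  for (i in seq_len(M)) for (j in seq_len(J)) {
    if (stats::runif(1) < truth$knockout_frac) {
      days <- (win$start_offset[j] + 1):win$end_offset[j]
      active[i, days] <- FALSE
    }
  }

  effort <- matrix(NA_real_, M, J)
  for (j in seq_len(J)) {
    days <- (win$start_offset[j] + 1):win$end_offset[j]
    a <- rowSums(active[, days, drop = FALSE])
    effort[, j] <- ifelse(a == 0, NA, a / win$length[j])
  }
  date_std <- standardize(win$start_offset)

  std <- function(v) (v - mean(v)) / stats::sd(v)
  xs <- list(tree_buffer = std(cov$tree_buffer),
             dist_river = std(cov$dist_river),
             dist_conuco = std(cov$dist_conuco))

  photos <- list()
  latent <- list()
  for (sp in names(truth$species)) {
    pars <- truth$species[[sp]]
    eta_lam <- rep(pars$beta[["(Intercept)"]], M)
    for (tm in setdiff(names(pars$beta), "(Intercept)"))
      eta_lam <- eta_lam + pars$beta[[tm]] * xs[[tm]]
    N <- stats::rpois(M, exp(eta_lam))
    latent[[sp]] <- N
    for (i in seq_len(M)) {
      if (N[i] == 0) next
      for (j in seq_len(J)) {
        if (is.na(effort[i, j])) next
        eta_r <- pars$alpha[["(Intercept)"]]
        if ("effort" %in% names(pars$alpha))
          eta_r <- eta_r + pars$alpha[["effort"]] * effort[i, j]
        if ("date" %in% names(pars$alpha))
          eta_r <- eta_r + pars$alpha[["date"]] * date_std[j]
        p <- 1 - (1 - stats::plogis(eta_r))^N[i]
        if (stats::runif(1) < p) {
          days <- (win$start_offset[j] + 1):win$end_offset[j]
          days <- days[active[i, days]]
          d0 <- if (length(days) == 1) days else sample(days, 1)
          t0 <- as.POSIXct(season_start + d0 - 1, tz = "UTC") +
            stats::runif(1, 6 * 3600, 18 * 3600)
          nph <- sample(1:3, 1)
          ts <- t0 + cumsum(c(0, stats::runif(nph - 1, 30, 240)))
          photos[[length(photos) + 1]] <- data.frame(
            camera_id = cov$camera_id[i], species = sp,
            timestamp = format(ts, "%Y-%m-%d %H:%M:%S"),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  photos <- if (length(photos)) do.call(rbind, photos) else
    data.frame(camera_id = character(), species = character(),
               timestamp = character(), stringsAsFactors = FALSE)
  deployments <- do.call(rbind, lapply(seq_len(M), function(i)
    .runs_to_intervals(active[i, ], cov$camera_id[i],
                       c(cov$x[i], cov$y[i]), cov$block[i], season_start)))
  list(photos = photos, deployments = deployments, latent = latent)
}

#' Simulate the interview survey
#'
#' Respondents are allocated to the four communities; active and inactive
#' hunters cite a multinomial draw of game taxa (vernacular names) and
#' active hunters usually rank up to three preferences, the first drawn by
#' the preference weights. Habitat and season preferences are drawn from
#' community-level probabilities.
#'
#' @param truth a [synthetic_truth()].
#' @return data frame, one row per respondent, with semicolon-separated
#'   multi-response fields.
#' @export
simulate_interviews <- function(truth) {
  set.seed(truth$seed + 2L)
  N <- truth$n_interviews
  comm <- rep(names(truth$communities), truth$communities)
  comm <- rep_len(comm, N)
  cp <- truth$citation_prob / sum(truth$citation_prob)
  pw <- truth$preference_weight / sum(truth$preference_weight)
  status <- sample(c("active", "inactive", "non-hunter"), N, replace = TRUE,
                   prob = c(truth$prop_active_hunters,
                            truth$prop_inactive_hunters,
                            1 - truth$prop_active_hunters -
                              truth$prop_inactive_hunters))
  rows <- lapply(seq_len(N), function(i) {
    cites <- character(); prefs <- character()
    if (status[i] != "non-hunter") {
      k <- min(1 + stats::rpois(1, truth$citation_rate), length(cp))
      cites <- sample(names(cp), k, prob = cp)
      if (status[i] == "active" && stats::runif(1) < 0.75) {
        cand <- intersect(names(pw), cites)
        if (length(cand)) {
          w <- pw[cand] / sum(pw[cand])
          first <- sample(cand, 1, prob = w)
          rest <- setdiff(cites, first)
          prefs <- c(first, if (length(rest))
            utils::head(sample(rest), min(2, length(rest))))
        }
      }
    }
    data.frame(
      respondent_id = sprintf("R%02d", i),
      community = comm[i],
      age = sample(22:70, 1),
      gender = sample(c("m", "f"), 1, prob = c(26 / 29, 3 / 29)),
      hunter_status = status[i],
      cited_taxa = paste(cites, collapse = ";"),
      ranked_preferences = paste(prefs, collapse = ";"),
      habitat_pref = sample(c("forest", "savanna", "mixed"), 1,
                            prob = c(0.55, 0.2, 0.25)),
      season_pref = sample(c("rainy", "all year", "none"), 1,
                           prob = c(0.65, 0.2, 0.15)),
      occupations = paste(sample(c("agriculture", "fishing", "mining",
                                   "tourism"),
                                 sample(1:3, 1)), collapse = ";"),
      food_sources = paste(sample(c("conuco", "fishing and hunting",
                                    "processed food"),
                                  sample(1:3, 1)), collapse = ";"),
      technologies = paste(sample(c("shotgun", "bow", "sling"),
                                  sample(1:2, 1), prob = c(0.75, 0.1, 0.15)),
                           collapse = ";"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a complete synthetic study
#'
#' Runs the landscape, survey and interview generators under the truth's
#' master seed and (optionally) writes the exact CSV dialects the analysis
#' pipeline reads, plus the truth as JSON for recovery scoring.
#'
#' @param truth a [synthetic_truth()].
#' @param dir optional output directory; created if missing.
#' @return invisibly, a list with `photos`, `deployments`, `covariates`,
#'   `tracks`, `interviews`, `latent`, `truth`.
#' @export
simulate_study <- function(truth = synthetic_truth(), dir = NULL) {
  land <- simulate_landscape(truth)
  surv <- simulate_rn_survey(truth, land)
  interviews <- simulate_interviews(truth)
  out <- list(photos = surv$photos, deployments = surv$deployments,
              covariates = land$covariates, tracks = land$tracks,
              interviews = interviews, latent = surv$latent, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$photos, file.path(dir, "photos.csv"),
                     row.names = FALSE)
    utils::write.csv(out$deployments, file.path(dir, "deployments.csv"),
                     row.names = FALSE)
    utils::write.csv(out$covariates, file.path(dir, "covariates.csv"),
                     row.names = FALSE)
    utils::write.csv(out$tracks, file.path(dir, "tracks.csv"),
                     row.names = FALSE)
    utils::write.csv(out$interviews, file.path(dir, "interviews.csv"),
                     row.names = FALSE)
    utils::write.csv(gh_taxonomy_map(), file.path(dir, "taxonomy_map.csv"),
                     row.names = FALSE)
    write_truth_json(truth, file.path(dir, "truth.json"))
  }
  invisible(out)
}
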