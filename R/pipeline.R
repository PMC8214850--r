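#' Analysis run configuration
#'
#' Defaults reproduce the study settings: 21-day visits, sites retained
#' with at least 7 active days and within 5 km of a conuco, 10,000
#' goodness-of-fit bootstrap samples, model averaging over delta (Q)AICc
#' <= 10, and a 10-detection inclusion threshold for model selection.
#'
#' @param paths named list of input paths (`photos`, `deployments`,
#'   `covariates`, `tracks`, `interviews`, `taxonomy_map`); ignored when
#'   `simulate = TRUE`.
#' @param out output directory.
#' @param simulate generate the inputs with [simulate_study()] instead of
#'   reading files.
#' @param visit_days,season_start,season_days,period_days visit calendar.
#' @param min_active_days,max_dist_conuco site filters.
#' @param boot_B GOF bootstrap samples.
#' @param delta_max model-averaging delta cutoff.
#' @param detection_threshold minimum site-visit detections for a species
#'   to enter model selection.
#' @param quadratic_species species allowed a quadratic tree-cover term.
#' @param n_starts optimizer starts per model fit.
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(paths = list(), out = tempfile("gardenhunt_run_"),
                       simulate = FALSE,
                       visit_days = 21, season_start = "2015-09-21",
                       season_days = 180, period_days = 60,
                       min_active_days = 7, max_dist_conuco = 5000,
                       boot_B = 10000, delta_max = 10,
                       detection_threshold = 10,
                       quadratic_species = character(),
                       n_starts = 5, seed = 1) {
  structure(list(paths = paths, out = out, simulate = simulate,
                 visit_days = visit_days, season_start = season_start,
                 season_days = season_days, period_days = period_days,
                 min_active_days = min_active_days,
                 max_dist_conuco = max_dist_conuco,
                 boot_B = boot_B, delta_max = delta_max,
                 detection_threshold = detection_threshold,
                 quadratic_species = quadratic_species,
                 n_starts = n_starts, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file; keys as in [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

.read_input <- function(paths, key, required = TRUE) {
  p <- paths[[key]]
  if (is.null(p) || !file.exists(p)) {
    if (required) stop("missing input file for '", key, "'",
                       if (!is.null(p)) paste0(": ", p))
    return(NULL)
  }
  utils::read.csv(p, stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates ingest (or simulation) -> event collapsing -> site filters
#' -> detection histories -> covariate standardization -> full-model RN
#' fit, GOF bootstrap and c-hat -> candidate-set fitting and (Q)AICc
#' ranking -> variable importance and conditional averaging -> ethno
#' indexes -> hunting-selection analyses, writing per-stage CSVs, a
#' `report.json` and a `manifest.json` under `config$out`.
#'
#' @param config a [run_config()].
#' @return invisibly, the report as a list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  out_dir <- config$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  inputs <- .stage("ingest", {
    if (isTRUE(config$simulate) || identical(config$simulate, "gran-sabana")) {
      truth <- synthetic_truth(seed = config$seed,
                               visit_days = config$visit_days,
                               season_start = config$season_start,
                               period_days = config$period_days)
      simulate_study(truth, dir = file.path(out_dir, "inputs"))
    } else {
      list(photos = .read_input(config$paths, "photos"),
           deployments = .read_input(config$paths, "deployments"),
           covariates = .read_input(config$paths, "covariates"),
           tracks = .read_input(config$paths, "tracks", required = FALSE),
           interviews = .read_input(config$paths, "interviews",
                                    required = FALSE))
    }
  })
  tax_map <- if (!is.null(config$paths$taxonomy_map))
    utils::read.csv(config$paths$taxonomy_map, stringsAsFactors = FALSE)
  else if (isTRUE(config$simulate) || identical(config$simulate, "gran-sabana"))
    gh_taxonomy_map() else NULL

  events <- .stage("events", collapse_events(inputs$photos))
  tallies <- .stage("events", tabulate_detections(events))
  camera_days <- sum(deployment_active_days(inputs$deployments)$days)
  fd <- tallies$by_species
  fd$FD <- round_half_up(frequency_of_detection(fd$D, camera_days), 2)

  filt <- .stage("filters", filter_sites(inputs$covariates,
                                         inputs$deployments,
                                         config$min_active_days,
                                         config$max_dist_conuco))
  dep_kept <- inputs$deployments[
    inputs$deployments$camera_id %in% filt$retained, ]
  ev_kept <- events[events$camera_id %in% filt$retained, ]

  histories <- .stage("histories",
    build_histories(ev_kept, dep_kept, config$season_start,
                    config$visit_days, config$season_days,
                    config$period_days))

  cov <- .stage("covariates", {
    cv <- inputs$covariates[inputs$covariates$camera_id %in% filt$retained, ]
    raw_td <- if (!is.null(inputs$tracks) && nrow(inputs$tracks))
      track_density(cv[c("x", "y")], inputs$tracks) else rep(0, nrow(cv))
    std <- cv
    if (stats::sd(raw_td) > 0) std$tracks_dens <- standardize(raw_td)
    else std$tracks_dens <- 0
    std$tree_buffer <- standardize(cv$tree_buffer)
    std$dist_river <- standardize(cv$dist_river)
    std$dist_conuco <- standardize(cv$dist_conuco)
    list(std = std, raw = cv)
  })

  species_results <- list()
  for (sp in names(histories)) {
    h <- histories[[sp]]
    ndet <- sum(h$y == 1L, na.rm = TRUE)
    if (ndet < config$detection_threshold) next
    res <- .stage(paste0("fit[", sp, "]"), {
      quad <- sp %in% config$quadratic_species
      full <- rn_spec(sp,
                      detection_terms = c("effort", "date", "tracks_dens"),
                      site_terms = c("tree_buffer",
                                     if (quad) "tree_buffer2",
                                     "dist_river", "dist_conuco"))
      full_fit <- fit_rn(full, h, cov$std, n_starts = config$n_starts)
      if (!full_fit$converged) {
        list(species = sp, detections = ndet, converged = FALSE)
      } else {
        gof <- gof_bootstrap(full_fit, B = config$boot_B)
        specs <- enumerate_models(allow_quadratic = quad, species = sp)
        fits <- lapply(specs, function(s)
          tryCatch(fit_rn(s, h, cov$std, n_starts = config$n_starts),
                   error = function(e) structure(list(converged = FALSE),
                                                 class = "rn_fit")))
        tab <- rank_models(fits, c_hat = gof$c_hat)
        imp <- variable_importance(tab)
        avg <- model_average(tab, delta_max = config$delta_max)
        lam <- average_predictions(tab, delta_max = config$delta_max)
        list(species = sp, detections = ndet, converged = TRUE,
             full_fit = full_fit, gof = gof, table = tab,
             importance = imp, averaged = avg, lambda = lam)
      }
    })
    species_results[[sp]] <- res
  }

  ethno <- NULL
  if (!is.null(inputs$interviews) && nrow(inputs$interviews)) {
    ethno <- .stage("indices", {
      counts <- tally_citations(inputs$interviews, tax_map)
      list(counts = counts, table = indices_table(counts))
    })
  }

  hunting <- .stage("hunting", {
    gl <- if ("hunting" %in% names(cov$raw))
      fit_hunting_glm(cov$raw) else NULL
    chi <- NULL
    if (!is.null(inputs$interviews) &&
        all(c("community", "habitat_pref", "season_pref") %in%
            names(inputs$interviews))) {
      hab <- table(inputs$interviews$community, inputs$interviews$habitat_pref)
      sea <- table(inputs$interviews$community, inputs$interviews$season_pref)
      chi <- list(habitat = chi2_contingency(unclass(hab)),
                  season = chi2_contingency(unclass(sea)))
    }
    cmp <- lapply(species_results, function(r) {
      if (!isTRUE(r$converged) || is.null(gl)) return(NULL)
      idx <- match(r$lambda$camera_id, cov$raw$camera_id)
      compare_lambda_by_hunting(r$lambda$lambda,
                                cov$raw$hunting[idx])
    })
    list(glm = gl, chi2 = chi, comparison = cmp[!vapply(cmp, is.null,
                                                        logical(1))])
  })

  # ---- outputs ----------------------------------------------------------
  utils::write.csv(fd, file.path(out_dir, "detections.csv"),
                   row.names = FALSE)
  utils::write.csv(filt$log, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  for (sp in names(histories))
    write_history_csv(histories[[sp]],
                      file.path(out_dir, paste0("history_", sp, ".csv")))
  gof_rows <- list(); avg_rows <- list(); tab_rows <- list()
  for (sp in names(species_results)) {
    r <- species_results[[sp]]
    if (!isTRUE(r$converged)) next
    gof_rows[[sp]] <- data.frame(species = sp, chi2 = r$gof$chi2_obs,
                                 p = r$gof$p_value, c_hat = r$gof$c_hat)
    a <- r$averaged; a$species <- sp
    avg_rows[[sp]] <- a
    t <- as.data.frame(r$table)[c("model", "k", "loglik", "ic", "delta",
                                  "weight")]
    t$species <- sp
    tab_rows[[sp]] <- t
  }
  if (length(gof_rows))
    utils::write.csv(do.call(rbind, gof_rows),
                     file.path(out_dir, "gof.csv"), row.names = FALSE)
  if (length(avg_rows))
    utils::write.csv(do.call(rbind, avg_rows),
                     file.path(out_dir, "averaged_coefs.csv"),
                     row.names = FALSE)
  if (length(tab_rows))
    utils::write.csv(do.call(rbind, tab_rows),
                     file.path(out_dir, "model_tables.csv"),
                     row.names = FALSE)
  if (!is.null(ethno))
    utils::write.csv(ethno$table, file.path(out_dir, "indices.csv"),
                     row.names = FALSE)
  if (!is.null(hunting$glm))
    utils::write.csv(hunting$glm$coefficients,
                     file.path(out_dir, "glm.csv"), row.names = FALSE)

  report <- list(
    seed = config$seed,
    camera_days = camera_days,
    n_sites_retained = length(filt$retained),
    n_excluded = nrow(filt$log),
    n_visits = if (length(histories)) ncol(histories[[1]]$y) else 0L,
    detections = fd,
    species = lapply(species_results, function(r) {
      if (!isTRUE(r$converged))
        return(list(species = r$species, detections = r$detections,
                    converged = FALSE))
      list(species = r$species, detections = r$detections, converged = TRUE,
           gof = list(chi2 = r$gof$chi2_obs, p = r$gof$p_value,
                      c_hat = r$gof$c_hat),
           criterion = attr(r$table, "criterion"),
           top_models = utils::head(as.data.frame(r$table)[
             c("model", "k", "loglik", "ic", "delta", "weight")], 5),
           importance = r$importance,
           averaged = r$averaged)
    }),
    indices = if (!is.null(ethno)) ethno$table else NULL,
    hunting = list(
      glm = if (!is.null(hunting$glm)) hunting$glm$coefficients else NULL,
      chi2 = if (!is.null(hunting$chi2)) lapply(hunting$chi2, function(h)
        list(chi2 = h$chi2, df = h$df, p = h$p)) else NULL,
      comparison = lapply(hunting$comparison, function(cm)
        list(by_group = cm$by_group, diff_medians = cm$diff_medians))))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "rows")

  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("gardenhunt")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config)[setdiff(names(unclass(config)), "paths")],
    files = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}
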