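# One small synthetic study shared across test files (built once per run).
# Seed fixed so expectations are stable.
gh_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    truth <- synthetic_truth(seed = 101)
    study <- simulate_study(truth)
    events <- collapse_events(study$photos)
    filt <- filter_sites(study$covariates, study$deployments)
    dep <- study$deployments[study$deployments$camera_id %in% filt$retained, ]
    ev <- events[events$camera_id %in% filt$retained, ]
    histories <- build_histories(ev, dep, truth$season_start)
    cov <- study$covariates[study$covariates$camera_id %in% filt$retained, ]
    cov$tracks_dens <- standardize(track_density(cov[c("x", "y")],
                                                 study$tracks))
    cov$tree_buffer <- standardize(cov$tree_buffer)
    cov$dist_river <- standardize(cov$dist_river)
    cov$dist_conuco <- standardize(cov$dist_conuco)
    cache <<- list(truth = truth, study = study, events = events,
                   filt = filt, histories = histories, covariates = cov)
    cache
  }
})

# Tiny deterministic photo table for event-collapsing unit tests.
make_photos <- function(minutes, camera = "C1", species = "sp",
                        origin = "2015-10-01 08:00:00") {
  t0 <- as.POSIXct(origin, tz = "UTC")
  data.frame(camera_id = rep(camera, length(minutes)),
             species = rep(species, length(minutes)),
             timestamp = format(t0 + minutes * 60, "%Y-%m-%d %H:%M:%S"),
             stringsAsFactors = FALSE)
}
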