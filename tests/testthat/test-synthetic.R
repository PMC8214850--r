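test_that("generators are seed-deterministic", {
  t1 <- synthetic_truth(seed = 303)
  a <- simulate_study(t1)
  b <- simulate_study(t1)
  expect_identical(a$photos, b$photos)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$interviews, b$interviews)
  # a different seed changes the data
  c <- simulate_study(synthetic_truth(seed = 304))
  expect_false(identical(a$photos, c$photos))
})

test_that("truth serializes to JSON and regenerates bit-identically", {
  t1 <- synthetic_truth(seed = 404)
  path <- tempfile(fileext = ".json")
  write_truth_json(t1, path)
  t2 <- read_truth_json(path)
  expect_equal(t2$seed, t1$seed)
  expect_equal(t2$species$paca$beta, t1$species$paca$beta)
  a <- simulate_study(t1)
  b <- simulate_study(t2)
  expect_identical(a$photos, b$photos)
  unlink(path)
})

test_that("tree cover is bimodal with savanna and forest modes", {
  truth <- synthetic_truth(seed = 505, n_sites = 10000)
  truth$n_far_sites <- 0; truth$n_short_sites <- 0
  land <- simulate_landscape(truth)
  tv <- land$covariates$tree_buffer
  expect_true(all(tv >= 0 & tv <= 100))
  # both mode regions well populated, the trough between them sparse
  expect_gt(mean(tv >= 5 & tv <= 25), 0.2)
  expect_gt(mean(tv >= 65 & tv <= 85), 0.2)
  d <- density(tv, bw = 4)
  mid <- d$y[d$x > 40 & d$x < 50]
  lo <- max(d$y[d$x > 10 & d$x < 20])
  hi <- max(d$y[d$x > 70 & d$x < 80])
  expect_lt(min(mid) * 1.5, min(lo, hi))
})

test_that("distances emulate the field distributions", {
  truth <- synthetic_truth(seed = 506, n_sites = 5000)
  truth$n_far_sites <- 0; truth$n_short_sites <- 0
  land <- simulate_landscape(truth)
  dc <- land$covariates$dist_conuco
  expect_true(all(dc >= 0 & dc <= 8000))
  expect_equal(mean(dc) / 1000, 1.58, tolerance = 0.1)
  expect_true(all(is.finite(as.matrix(
    land$covariates[c("tree_buffer", "dist_river", "dist_conuco")]))))
  expect_equal(nrow(land$tracks), truth$n_tracks)
})

test_that("default design yields the study's sampling geometry", {
  fx <- gh_fixture()
  expect_equal(nrow(fx$study$covariates), 60)
  expect_equal(nrow(fx$study$interviews), 29)
  expect_equal(nrow(fx$study$tracks), 159)
  # filters leave close to the 54 analysed sites
  expect_gte(length(fx$filt$retained), 50)
  expect_lte(length(fx$filt$retained), 57)
  # some partial-effort and some missing site-visits must exist
  eff <- fx$histories[[1]]$effort
  expect_gt(sum(is.na(eff)), 0)
  expect_gt(sum(!is.na(eff) & eff < 1), 0)
})

test_that("per-visit detection frequency matches the Poisson closed form", {
  # constant covariates: P(y = 1) = 1 - E[(1-r)^N] = 1 - exp(-lambda r)
  set.seed(66)
  M <- 5000; lam <- 1.8; r <- 0.35
  N <- rpois(M, lam)
  y <- rbinom(M, 1, 1 - (1 - r)^N)
  expected <- 1 - exp(-lam * r)
  se <- sqrt(expected * (1 - expected) / M)
  expect_lt(abs(mean(y) - expected), 2 * se + 1e-12)

  # the survey generator reproduces the same law through the full pipeline
  truth <- synthetic_truth(
    seed = 604, n_sites = 600,
    species = list(flat = list(
      beta = c("(Intercept)" = log(1.8)),
      alpha = c("(Intercept)" = qlogis(0.35)))))
  truth$knockout_frac <- 0; truth$n_short_sites <- 0; truth$n_far_sites <- 0
  land <- simulate_landscape(truth)
  surv <- simulate_rn_survey(truth, land)
  ev <- collapse_events(surv$photos)
  h <- build_histories(ev, surv$deployments, truth$season_start)$flat
  obs_rate <- mean(h$y, na.rm = TRUE)
  n_cells <- sum(!is.na(h$y))
  expect_lt(abs(obs_rate - expected),
            3 * sqrt(expected * (1 - expected) / n_cells))
})

test_that("degenerate coefficient settings behave as expected", {
  # an essentially absent species yields no photos
  truth0 <- synthetic_truth(
    seed = 607,
    species = list(ghost = list(beta = c("(Intercept)" = -30),
                                alpha = c("(Intercept)" = 0))))
  st0 <- simulate_study(truth0)
  expect_equal(nrow(st0$photos), 0)

  # near-perfect detection of an abundant species saturates operative visits
  truth1 <- synthetic_truth(
    seed = 608, n_sites = 30,
    species = list(sat = list(beta = c("(Intercept)" = 3),
                              alpha = c("(Intercept)" = 8))))
  truth1$knockout_frac <- 0; truth1$n_short_sites <- 0; truth1$n_far_sites <- 0
  land <- simulate_landscape(truth1)
  surv <- simulate_rn_survey(truth1, land)
  h <- build_histories(collapse_events(surv$photos), surv$deployments,
                       truth1$season_start)$sat
  expect_equal(mean(h$y, na.rm = TRUE), 1)
})

test_that("preference weight concentrated on one taxon maximizes its Pv", {
  truth <- synthetic_truth(seed = 609, n_interviews = 200)
  truth$preference_weight <- c(urana = 1)
  iv <- simulate_interviews(truth)
  ct <- tally_citations(iv, gh_taxonomy_map())
  expect_equal(unname(pv(ct, "Cuniculus")),
               ct$N_pref * (ct$p[["Cuniculus"]] / ct$n_pref))
  expect_equal(sum(ct$p), ct$p[["Cuniculus"]]) # only first choice possible
  # zero hunters leave the index pipeline empty, which errors as specified
  truth0 <- synthetic_truth(seed = 610)
  truth0$prop_active_hunters <- 0; truth0$prop_inactive_hunters <- 0
  iv0 <- simulate_interviews(truth0)
  ct0 <- tally_citations(iv0, gh_taxonomy_map())
  expect_equal(ct0$n, 0L)
  expect_error(hv(ct0), "undefined")
})

test_that("simulate_study writes the CSV dialects the pipeline reads", {
  dir <- tempfile("sim_")
  st <- simulate_study(synthetic_truth(seed = 611), dir = dir)
  files <- c("photos.csv", "deployments.csv", "covariates.csv",
             "tracks.csv", "interviews.csv", "taxonomy_map.csv",
             "truth.json")
  expect_true(all(file.exists(file.path(dir, files))))
  ph <- read.csv(file.path(dir, "photos.csv"), stringsAsFactors = FALSE)
  expect_identical(names(ph), c("camera_id", "species", "timestamp"))
  ev <- collapse_events(ph)
  expect_equal(nrow(ev), nrow(collapse_events(st$photos)))
  unlink(dir, recursive = TRUE)
})

test_that("a generated covariate effect is recovered end to end", {
  # simulate -> histories -> candidate set -> selection: the true
  # tree-cover effect must attract support in most replicates while a null
  # covariate stays unremarkable (scaled-down version of the full
  # recovery experiment in the acceptance suite)
  set.seed(70)
  hits <- 0; null_sw <- numeric(0); n_rep <- 6
  for (rep in seq_len(n_rep)) {
    truth <- synthetic_truth(
      seed = 700 + rep,
      species = list(sim = list(
        beta = c("(Intercept)" = 0.7, tree_buffer = 1.0),
        alpha = c("(Intercept)" = -1.0, effort = 1.0))))
    st <- simulate_study(truth)
    filt <- filter_sites(st$covariates, st$deployments)
    dep <- st$deployments[st$deployments$camera_id %in% filt$retained, ]
    ev <- collapse_events(st$photos)
    ev <- ev[ev$camera_id %in% filt$retained, ]
    h <- build_histories(ev, dep, truth$season_start)$sim
    cov <- st$covariates[st$covariates$camera_id %in% filt$retained, ]
    cov$tree_buffer <- standardize(cov$tree_buffer)
    cov$dist_conuco <- standardize(cov$dist_conuco)
    specs <- list(
      rn_spec("sim"),
      rn_spec("sim", site_terms = "tree_buffer"),
      rn_spec("sim", site_terms = "dist_conuco"),
      rn_spec("sim", site_terms = c("tree_buffer", "dist_conuco")))
    fits <- lapply(specs, fit_rn, history = h, covariates = cov,
                   n_starts = 1)
    tab <- rank_models(fits)
    imp <- variable_importance(tab, c("tree_buffer", "dist_conuco"))
    if (imp$sum_of_weights[imp$term == "tree_buffer"] > 0.6) hits <- hits + 1
    null_sw <- c(null_sw, imp$sum_of_weights[imp$term == "dist_conuco"])
  }
  expect_gte(hits, ceiling(0.7 * n_rep))
  expect_lt(median(null_sw), 0.6)
})
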