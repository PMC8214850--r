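test_that("candidate sets have the documented cardinality and hierarchy", {
  lin <- enumerate_models(allow_quadratic = FALSE)
  quad <- enumerate_models(allow_quadratic = TRUE)
  expect_length(lin, 32)
  expect_length(quad, 48)
  # effort in every model; quadratic never without linear; no duplicates
  for (s in quad) {
    expect_true("effort" %in% s$detection_terms)
    if ("tree_buffer2" %in% s$site_terms)
      expect_true("tree_buffer" %in% s$site_terms)
  }
  labels <- vapply(quad, format, character(1))
  expect_equal(anyDuplicated(labels), 0L)
})

test_that("information criteria match their closed forms", {
  expect_equal(aicc(-100, 3, 54), 206.48)
  expect_error(aicc(-100, 10, 11), "sample too small")
  # AICc tends to AIC as n grows
  expect_equal(aicc(-100, 3, 1e8), 206, tolerance = 1e-5)
  # at c_hat = 1 QAICc differs from AICc only via the extra parameter
  k <- 3; n <- 54
  expect_equal(qaicc(-100, k, n, 1),
               aicc(-100, k + 1, n), tolerance = 1e-12)
  expect_gt(qaicc(-100, k, n, 1), aicc(-100, k, n))
})

test_that("Akaike weights normalize and order by delta", {
  w <- akaike_weights(c(0, 2))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w, 3), c(0.731, 0.269))
  expect_equal(akaike_weights(c(0, 0)), c(0.5, 0.5))
  set.seed(2)
  d <- sort(c(0, rexp(10, 0.2)))
  expect_equal(sum(akaike_weights(d)), 1, tolerance = 1e-12)
})

# small helper: fabricate converged fits with chosen logliks for table tests
fake_fit <- function(spec, loglik, n_sites = 54, coefs = NULL) {
  k <- 2 + length(spec$detection_terms) + length(spec$site_terms)
  cn <- c(paste0("p_", c("(Intercept)", spec$detection_terms)),
          paste0("lam_", c("(Intercept)", spec$site_terms)))
  co <- if (is.null(coefs)) setNames(rep(0.1, k), cn) else coefs
  structure(list(spec = spec, loglik = loglik, k = k, n_sites = n_sites,
                 converged = TRUE, coef = co,
                 vcov = diag(1e-4, k, k) |>
                   (\(m) { dimnames(m) <- list(cn, cn); m })()),
            class = "rn_fit")
}

test_that("ranking is invariant to a constant shift of all logliks", {
  specs <- enumerate_models(FALSE)[1:6]
  ll <- c(-100, -99, -104, -98.5, -101, -97)
  t1 <- rank_models(Map(fake_fit, specs, ll))
  t2 <- rank_models(Map(fake_fit, specs, ll + 37.5))
  expect_equal(t1$model, t2$model)
  expect_equal(t1$delta, t2$delta, tolerance = 1e-9)
  expect_equal(t1$weight, t2$weight, tolerance = 1e-9)
  expect_equal(sum(t1$weight), 1, tolerance = 1e-9)
  expect_equal(t1$delta[1], 0)
  expect_true(!is.unsorted(t1$ic))
})

test_that("variable importance equals a brute-force tally with the scale", {
  specs <- enumerate_models(FALSE)
  set.seed(4)
  fits <- Map(fake_fit, specs, rnorm(32, -100, 2))
  tab <- rank_models(fits)
  imp <- variable_importance(tab)
  for (tm in imp$term) {
    manual <- sum(tab$weight[vapply(tab$spec, function(s)
      tm %in% c(s$detection_terms, s$site_terms), logical(1))])
    expect_equal(imp$sum_of_weights[imp$term == tm], manual,
                 tolerance = 1e-12)
  }
  expect_equal(imp$sum_of_weights[imp$term == "effort"], 1)
  expect_equal(imp$support[imp$term == "effort"], "very strong")

  # equal-k, equal-loglik models share the weight evenly
  two <- rank_models(list(
    fake_fit(rn_spec(site_terms = "dist_river"), -100),
    fake_fit(rn_spec(site_terms = "tree_buffer"), -100)))
  vi <- variable_importance(two, "dist_river")
  expect_equal(vi$sum_of_weights, 0.5)
  expect_equal(vi$support, "moderate")
  none <- variable_importance(two, "dist_conuco")
  expect_equal(none$sum_of_weights, 0)
  expect_equal(none$support, "low")
})

test_that("conditional averaging reproduces the hand-computed example", {
  # two equal-weight models, coefficients 1 and 3, zero variance:
  # estimate 2, unconditional SE = 0.5*|1-2| + 0.5*|3-2| = 1
  s1 <- rn_spec(site_terms = "dist_conuco")
  s2 <- rn_spec(site_terms = c("dist_conuco", "dist_river"))
  f1 <- fake_fit(s1, -100)
  # loglik offset chosen so the two AICc values tie exactly:
  # 2*(k2-k1) plus the difference of small-sample corrections, halved
  off <- (2 + 2 * 5 * 6 / 48 - 2 * 4 * 5 / 49) / 2
  f2 <- fake_fit(s2, -100 + off)
  f1$coef["lam_dist_conuco"] <- 1; f2$coef["lam_dist_conuco"] <- 3
  f1$vcov[] <- 0; f2$vcov[] <- 0
  tab <- rank_models(list(f1, f2))
  expect_equal(tab$delta, c(0, 0), tolerance = 1e-3)
  avg <- model_average(tab, terms = "dist_conuco")
  expect_equal(avg$estimate, 2, tolerance = 1e-3)
  expect_equal(avg$se, 1, tolerance = 1e-3)
  expect_equal(avg$lo95, 2 - 1.96, tolerance = 1e-2)
})

test_that("a single retained model averages to itself", {
  s1 <- rn_spec(site_terms = "dist_conuco")
  f1 <- fake_fit(s1, -100)
  f1$coef["lam_dist_conuco"] <- -0.4
  f1$vcov[] <- diag(0.04, f1$k)
  tab <- rank_models(list(f1))
  avg <- model_average(tab, terms = "dist_conuco")
  expect_equal(avg$estimate, -0.4)
  expect_equal(avg$se, 0.2)
  expect_equal(avg$hi95, -0.4 + 1.96 * 0.2)
})

test_that("averaged predictions stay inside the per-model envelope", {
  fx <- gh_fixture()
  set.seed(21)
  fits <- lapply(list(rn_spec("paca"),
                      rn_spec("paca", site_terms = "tree_buffer"),
                      rn_spec("paca", site_terms = c("tree_buffer",
                                                     "dist_conuco"))),
                 fit_rn, history = fx$histories$paca,
                 covariates = fx$covariates, n_starts = 1)
  tab <- rank_models(fits)
  avg <- average_predictions(tab)
  per <- sapply(tab$fit, function(f) predict_lambda(f)$lambda)
  expect_true(all(avg$lambda >= apply(per, 1, min) - 1e-9))
  expect_true(all(avg$lambda <= apply(per, 1, max) + 1e-9))
})

test_that("overdispersion inflation follows the c-hat rule", {
  expect_equal(apply_overdispersion(0.1, 4), 0.2)
  expect_equal(apply_overdispersion(0.1, 0.5), 0.1) # no deflation
  expect_equal(apply_overdispersion(0.1, 1), 0.1)
  df <- data.frame(estimate = 1, se = 0.1, lo95 = 1 - 0.196,
                   hi95 = 1 + 0.196)
  out <- apply_overdispersion(df, 4)
  expect_equal(out$se, 0.2)
  expect_equal(out$hi95, 1 + 1.96 * 0.2)
})

test_that("the c-hat ratio and GOF p-value follow their definitions", {
  g <- structure(list(chi2_obs = 120, boot_mean = 100, B = 10,
                      p_value = 0.3, c_hat = 120 / 100),
                 class = "gof_result")
  expect_equal(g$c_hat, 1.2)
  # degenerate bootstrap equal to the observed statistic gives p = 1
  fx <- gh_fixture()
  set.seed(30)
  f <- fit_rn(rn_spec("paca", site_terms = "tree_buffer"),
              fx$histories$paca, fx$covariates, n_starts = 1)
  g1 <- gof_bootstrap(f, B = 15, seed = 99)
  expect_true(g1$p_value >= 0 && g1$p_value <= 1)
  expect_equal(g1$c_hat, g1$chi2_obs / mean(g1$boot_stats))
})

test_that("GOF bootstrap is reproducible under a fixed seed", {
  fx <- gh_fixture()
  set.seed(31)
  f <- fit_rn(rn_spec("agouti", site_terms = "tree_buffer"),
              fx$histories$agouti, fx$covariates, n_starts = 1)
  g1 <- gof_bootstrap(f, B = 10, seed = 123)
  g2 <- gof_bootstrap(f, B = 10, seed = 123)
  expect_identical(g1$boot_stats, g2$boot_stats)
  expect_identical(g1$p_value, g2$p_value)
})

test_that("null covariates do not attract strong support", {
  # data generated with no covariate effects: median sum of weights of each
  # optional covariate over replicates must stay below the 'strong' band
  set.seed(55)
  M <- 54; J <- 6
  n_rep <- 12
  sw <- matrix(NA_real_, n_rep, 2,
               dimnames = list(NULL, c("tree_buffer", "dist_conuco")))
  for (rep in seq_len(n_rep)) {
    tree <- standardize(rnorm(M)); con <- standardize(rnorm(M))
    N <- rpois(M, exp(0.5))
    y <- matrix(rbinom(M * J, 1, rep(1 - 0.65^N, J)), M, J)
    h <- structure(list(species = "null", sites = sprintf("S%02d", 1:M),
                        visits = data.frame(start_offset = 0:(J - 1) * 21),
                        y = y, effort = matrix(1, M, J),
                        date = matrix(0, M, J)),
                   class = "detection_history")
    cov <- data.frame(camera_id = sprintf("S%02d", 1:M),
                      tree_buffer = tree, dist_conuco = con)
    specs <- list(rn_spec("null", detection_terms = character()),
                  rn_spec("null", detection_terms = character(),
                          site_terms = "tree_buffer"),
                  rn_spec("null", detection_terms = character(),
                          site_terms = "dist_conuco"),
                  rn_spec("null", detection_terms = character(),
                          site_terms = c("tree_buffer", "dist_conuco")))
    fits <- lapply(specs, fit_rn, history = h, covariates = cov,
                   n_starts = 1)
    tab <- rank_models(fits)
    imp <- variable_importance(tab, c("tree_buffer", "dist_conuco"))
    sw[rep, ] <- imp$sum_of_weights
  }
  expect_lt(median(sw[, "tree_buffer"]), 0.6)
  expect_lt(median(sw[, "dist_conuco"]), 0.6)
})
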