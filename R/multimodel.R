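#' Enumerate the candidate Royle-Nichols model set
#'
#' Detection side: effort is always included; date and track density are
#' each optional (4 combinations). Site side: distance to river and distance
#' to conuco are each optional, and the tree-cover term is absent or linear
#' (8 combinations) or, when a quadratic response is allowed, absent, linear
#' or linear + quadratic (12 combinations). The Cartesian product gives 32
#' models in the linear case and 48 in the quadratic case.
#'
#' @param allow_quadratic allow a quadratic tree-cover term.
#' @param species species label stamped on each spec.
#' @return list of [rn_spec()] objects.
#' @export
enumerate_models <- function(allow_quadratic = FALSE, species = "species") {
  det_opts <- list(character(), "date", "tracks_dens", c("date", "tracks_dens"))
  tree_opts <- list(character(), "tree_buffer")
  if (allow_quadratic)
    tree_opts <- c(tree_opts, list(c("tree_buffer", "tree_buffer2")))
  specs <- list()
  for (dt in det_opts)
    for (tr in tree_opts)
      for (rv in c(FALSE, TRUE))
        for (co in c(FALSE, TRUE)) {
          st <- c(tr, if (rv) "dist_river", if (co) "dist_conuco")
          specs[[length(specs) + 1]] <-
            rn_spec(species, detection_terms = c("effort", dt),
                    site_terms = st)
        }
  specs
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1), with n the number of sites.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n effective sample size (sites).
#' @export
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1)) stop("sample too small: need n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Quasi-likelihood AICc for overdispersed data
#'
#' QAICc = -2 logLik / c_hat + 2k' + 2k'(k'+1)/(n-k'-1) with k' = k + 1:
#' the overdispersion ratio c-hat is counted as an extra estimated
#' parameter.
#'
#' @inheritParams aicc
#' @param c_hat overdispersion ratio (> 0).
#' @export
qaicc <- function(loglik, k, n, c_hat) {
  if (any(c_hat <= 0)) stop("c_hat must be positive")
  kp <- k + 1
  if (any(n <= kp + 1)) stop("sample too small: need n > k + 2")
  -2 * loglik / c_hat + 2 * kp + 2 * kp * (kp + 1) / (n - kp - 1)
}

#' Akaike weights from criterion differences
#' @param deltas non-negative criterion differences with min 0.
#' @export
akaike_weights <- function(deltas) {
  if (any(deltas < 0)) stop("deltas must be non-negative")
  w <- exp(-deltas / 2)
  w / sum(w)
}

#' Rank fitted candidate models by (Q)AICc
#'
#' Uses AICc when `c_hat <= 1` and QAICc otherwise (c-hat from the
#' full-model goodness-of-fit bootstrap). Non-converged fits are dropped
#' with a message.
#'
#' @param fits list of `rn_fit` objects for one species.
#' @param c_hat overdispersion ratio from [gof_bootstrap()].
#' @param n effective sample size; default taken from the fits.
#' @return a `model_table` data frame with columns `model`, `k`, `loglik`,
#'   `ic`, `delta`, `weight`, a list column `spec`, and attributes
#'   `criterion` and `c_hat`.
#' @export
rank_models <- function(fits, c_hat = 1, n = NULL) {
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!all(conv))
    message(sum(!conv), " non-converged model(s) dropped from the set")
  fits <- fits[conv]
  if (!length(fits)) stop("no converged models to rank")
  if (is.null(n)) n <- fits[[1]]$n_sites
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  k <- vapply(fits, function(f) f$k, numeric(1))
  use_q <- c_hat > 1
  ic <- if (use_q) qaicc(ll, k, n, c_hat) else aicc(ll, k, n)
  ord <- order(ic)
  tab <- data.frame(
    model = vapply(fits, function(f) format(f$spec), character(1))[ord],
    k = k[ord], loglik = ll[ord], ic = ic[ord],
    delta = ic[ord] - min(ic),
    stringsAsFactors = FALSE)
  tab$weight <- akaike_weights(tab$delta)
  tab$spec <- lapply(fits[ord], function(f) f$spec)
  tab$fit <- fits[ord]
  attr(tab, "criterion") <- if (use_q) "QAICc" else "AICc"
  attr(tab, "c_hat") <- c_hat
  class(tab) <- c("model_table", "data.frame")
  tab
}

#' @export
print.model_table <- function(x, n = 10, ...) {
  cat("Model selection table (", attr(x, "criterion"),
      ", c-hat = ", format(attr(x, "c_hat"), digits = 3), ")\n", sep = "")
  df <- as.data.frame(x)[seq_len(min(n, nrow(x))),
                         c("model", "k", "loglik", "ic", "delta", "weight")]
  df$loglik <- round(df$loglik, 2); df$ic <- round(df$ic, 2)
  df$delta <- round(df$delta, 2); df$weight <- round(df$weight, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

.support_label <- function(w) {
  if (w > 0.9) "very strong" else if (w > 0.6) "strong"
  else if (w > 0.3) "moderate" else "low"
}

.spec_has_term <- function(spec, term) {
  term %in% c(spec$detection_terms, spec$site_terms)
}

#' Sum-of-weights variable importance
#'
#' The importance of a covariate is the sum of Akaike weights of the models
#' containing it, with the informal support scale: very strong (> 0.9),
#' strong (0.6-0.9], moderate (0.3-0.6], low [0, 0.3].
#'
#' @param table a `model_table`.
#' @param term covariate name, or NULL for all terms in the table.
#' @return data frame with `term`, `sum_of_weights`, `support`.
#' @export
variable_importance <- function(table, term = NULL) {
  specs <- table$spec
  if (is.null(term)) {
    term <- unique(unlist(lapply(specs, function(s)
      c(s$detection_terms, s$site_terms))))
  }
  sw <- vapply(term, function(tm)
    sum(table$weight[vapply(specs, .spec_has_term, logical(1), term = tm)]),
    numeric(1))
  data.frame(term = term, sum_of_weights = as.numeric(sw),
             support = vapply(as.numeric(sw), .support_label, character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# coefficient and variance of `term` in one fit (NA when absent)
.fit_coef <- function(fit, term) {
  nm <- names(fit$coef)
  hit <- which(nm %in% paste0(c("p_", "lam_"), term))
  if (!length(hit)) return(c(NA_real_, NA_real_))
  c(fit$coef[hit[1]], fit$vcov[hit[1], hit[1]])
}

#' Conditional model-averaged coefficients
#'
#' Averages each coefficient over the models that contain it, restricted to
#' models with delta (Q)AICc <= `delta_max`, with weights renormalized over
#' that subset. The standard error uses the unconditional-variance form
#' SE = sum w'_m sqrt(var_m + (beta_m - est)^2), and 95% intervals are
#' inflated by sqrt(c_hat) when c_hat > 1.
#'
#' @param table a `model_table` from [rank_models()] (fits attached).
#' @param delta_max retain models with delta <= this value.
#' @param terms coefficients to average; default all terms present.
#' @return data frame with `term`, `estimate`, `se`, `lo95`, `hi95`,
#'   `sum_of_weights`, `support`.
#' @export
model_average <- function(table, delta_max = 10, terms = NULL) {
  keep <- table$delta <= delta_max
  if (!any(keep)) stop("no models within delta_max")
  sub <- table[keep, , drop = FALSE]
  c_hat <- attr(table, "c_hat")
  infl <- sqrt(max(c_hat, 1))
  if (is.null(terms))
    terms <- unique(unlist(lapply(sub$spec, function(s)
      c("(Intercept)", s$detection_terms, s$site_terms))))
  imp_all <- variable_importance(table)
  rows <- lapply(terms, function(tm) {
    cv <- t(vapply(sub$fit, .fit_coef, numeric(2), term = tm))
    has <- !is.na(cv[, 1])
    if (!any(has)) return(NULL) # term in no retained model: omitted
    w <- sub$weight[has] / sum(sub$weight[has])
    b <- cv[has, 1]; v <- pmax(cv[has, 2], 0)
    est <- sum(w * b)
    se <- sum(w * sqrt(v + (b - est)^2))
    half <- 1.96 * se * infl
    sw <- if (tm %in% imp_all$term)
      imp_all$sum_of_weights[imp_all$term == tm] else 1
    data.frame(term = tm, estimate = est, se = se,
               lo95 = est - half, hi95 = est + half,
               sum_of_weights = sw,
               support = .support_label(sw),
               stringsAsFactors = FALSE)
  })
  dropped <- terms[vapply(rows, is.null, logical(1))]
  if (length(dropped))
    message("term(s) in no retained model, omitted: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Model-averaged abundance predictions
#'
#' Weighted average of per-model lambda predictions over models with
#' delta <= `delta_max` (weights renormalized); a convex combination, so
#' averaged values lie within the per-model envelope.
#'
#' @inheritParams model_average
#' @param newdata optional covariate table passed to [predict_lambda()].
#' @return data frame `camera_id`, `lambda`.
#' @export
average_predictions <- function(table, delta_max = 10, newdata = NULL) {
  keep <- table$delta <= delta_max
  if (!any(keep)) stop("no models within delta_max")
  sub <- table[keep, , drop = FALSE]
  w <- sub$weight / sum(sub$weight)
  preds <- lapply(sub$fit, predict_lambda, newdata = newdata)
  lam <- Reduce(`+`, Map(function(p, wi) wi * p$lambda, preds, w))
  data.frame(camera_id = preds[[1]]$camera_id, lambda = lam,
             stringsAsFactors = FALSE)
}

# Pearson chi-square over observed site-visit cells against the fitted
# marginal detection probability; cells clamped away from 0/1.
.rn_pearson_chi2 <- function(y, p, warn = TRUE) {
  obs <- !is.na(y)
  pc <- p[obs]
  if (any(pc < 1e-8 | pc > 1 - 1e-8)) {
    if (warn) warning("fitted cell probabilities clamped to [1e-8, 1-1e-8]")
    pc <- pmin(pmax(pc, 1e-8), 1 - 1e-8)
  }
  sum((y[obs] - pc)^2 / (pc * (1 - pc)))
}

# Quick refit used for bootstrap replicates: same designs, warm start.
.rn_refit <- function(fit, y_new) {
  nll <- .rn_negloglik_factory(y_new, fit$det, fit$X, fit$K, with_grad = TRUE)
  opt <- stats::optim(unname(fit$coef), nll$fn, nll$gr, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-9))
  f2 <- fit
  f2$coef[] <- opt$par
  np <- length(fit$alpha)
  f2$alpha[] <- opt$par[seq_len(np)]
  f2$beta[] <- opt$par[-seq_len(np)]
  f2$loglik <- -opt$value
  f2$y <- y_new
  f2
}

#' Parametric-bootstrap goodness of fit and overdispersion ratio
#'
#' Computes a Pearson chi-square statistic over the observed site-visit
#' cells against the fitted marginal detection probabilities, simulates `B`
#' datasets from the fitted model, refits each (warm-started at the original
#' estimates) and recomputes the statistic. The p-value is the proportion of
#' bootstrap statistics at least as large as the observed one, and
#' c_hat = observed / bootstrap mean.
#'
#' @param fit a converged `rn_fit`.
#' @param B number of bootstrap samples.
#' @param seed optional integer seed for reproducibility.
#' @return object of class `gof_result`: `chi2_obs`, `boot_mean`, `B`,
#'   `p_value`, `c_hat`, `boot_stats`.
#' @export
gof_bootstrap <- function(fit, B = 10000, seed = NULL) {
  if (!fit$converged) stop("fit did not converge; GOF not defined")
  if (!is.null(seed)) set.seed(seed)
  chi2_obs <- .rn_pearson_chi2(fit$y, .rn_marginal_p(fit))
  boot <- vapply(seq_len(B), function(b) {
    y_b <- .rn_simulate_y(fit)
    f_b <- .rn_refit(fit, y_b)
    .rn_pearson_chi2(y_b, .rn_marginal_p(f_b), warn = FALSE)
  }, numeric(1))
  boot_mean <- mean(boot)
  structure(list(chi2_obs = chi2_obs, boot_mean = boot_mean, B = B,
                 p_value = mean(boot >= chi2_obs - 1e-12),
                 c_hat = chi2_obs / boot_mean,
                 boot_stats = boot),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat("Parametric-bootstrap GOF: chi2 =", format(x$chi2_obs, digits = 5),
      " p =", format(x$p_value, digits = 3),
      " c-hat =", format(x$c_hat, digits = 3),
      " (B =", x$B, ")\n")
  invisible(x)
}

#' Inflate uncertainty for overdispersion
#'
#' When `c_hat > 1`, standard errors are multiplied by sqrt(c_hat) and 95%
#' intervals widened accordingly; when `c_hat <= 1` nothing is changed (a
#' deliberately conservative treatment of underdispersion).
#'
#' @param x a numeric vector of standard errors, or a data frame with
#'   columns `estimate`, `se` (and optionally `lo95`, `hi95`).
#' @param c_hat overdispersion ratio (> 0).
#' @export
apply_overdispersion <- function(x, c_hat) {
  if (c_hat <= 0) stop("c_hat must be positive")
  infl <- sqrt(max(c_hat, 1))
  if (is.numeric(x)) return(x * infl)
  stopifnot(is.data.frame(x), all(c("estimate", "se") %in% names(x)))
  x$se <- x$se * infl
  if (all(c("lo95", "hi95") %in% names(x))) {
    x$lo95 <- x$estimate - 1.96 * x$se
    x$hi95 <- x$estimate + 1.96 * x$se
  }
  x
}
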