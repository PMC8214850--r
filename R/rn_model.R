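#' Royle-Nichols model specification
#'
#' Describes one candidate model: which observation covariates enter the
#' per-individual detection probability r (logit link) and which site
#' covariates enter the abundance mean lambda (log link). Intercepts are
#' always present. A quadratic tree term requires the linear term
#' (hierarchical polynomial).
#'
#' @param species species label.
#' @param detection_terms subset of `c("effort", "date", "tracks_dens")`.
#' @param site_terms subset of `c("tree_buffer", "tree_buffer2",
#'   "dist_river", "dist_conuco")`.
#' @return an object of class `rn_spec`.
#' @export
rn_spec <- function(species = "species", detection_terms = "effort",
                    site_terms = character()) {
  det_ok <- c("effort", "date", "tracks_dens")
  site_ok <- c("tree_buffer", "tree_buffer2", "dist_river", "dist_conuco")
  detection_terms <- unique(as.character(detection_terms))
  site_terms <- unique(as.character(site_terms))
  if (length(setdiff(detection_terms, det_ok)))
    stop("unknown detection term(s): ",
         paste(setdiff(detection_terms, det_ok), collapse = ", "))
  if (length(setdiff(site_terms, site_ok)))
    stop("unknown site term(s): ",
         paste(setdiff(site_terms, site_ok), collapse = ", "))
  if ("tree_buffer2" %in% site_terms && !"tree_buffer" %in% site_terms)
    stop("tree_buffer2 requires tree_buffer (hierarchical polynomial)")
  detection_terms <- det_ok[det_ok %in% detection_terms]
  site_terms <- site_ok[site_ok %in% site_terms]
  structure(list(species = species, detection_terms = detection_terms,
                 site_terms = site_terms),
            class = "rn_spec")
}

#' @export
format.rn_spec <- function(x, ...) {
  p <- paste(c("1", x$detection_terms), collapse = "+")
  l <- paste(c("1", x$site_terms), collapse = "+")
  paste0("p(", p, ") lam(", l, ")")
}

#' @export
print.rn_spec <- function(x, ...) {
  cat("RN model spec [", x$species, "]: ", format(x), "\n", sep = "")
  invisible(x)
}

#' Abundance-induced detection probability
#'
#' The probability that at least one of N independent individuals, each
#' detected with probability r per visit, is detected: p = 1 - (1 - r)^N.
#'
#' @param r per-individual detection probability in [0, 1].
#' @param N non-negative integer abundance.
#' @export
detection_prob <- function(r, N) {
  if (any(r < 0 | r > 1, na.rm = TRUE)) stop("r must be in [0, 1]")
  if (any(N < 0, na.rm = TRUE)) stop("N must be non-negative")
  1 - (1 - r)^N
}

#' Single-site Royle-Nichols log-likelihood contribution
#'
#' Integrates the latent abundance N out of the Bernoulli detection process
#' by a truncated Poisson sum: log sum_{N=0..K} Pois(N; lambda)
#' prod_j p_j(N)^y_j (1 - p_j(N))^(1-y_j), with lambda = exp(x . beta) and
#' r_j = plogis(W[j, ] . alpha). Missing visits (NA in `y`) are skipped.
#'
#' @param y length-J 0/1/NA detection vector for one site.
#' @param W J x length(alpha) detection design matrix (first column usually
#'   the intercept).
#' @param x site design vector of length length(beta).
#' @param alpha detection coefficients (logit scale).
#' @param beta abundance coefficients (log scale).
#' @param K latent-abundance truncation bound.
#' @export
site_loglik <- function(y, W, x, alpha, beta, K = 200) {
  W <- as.matrix(W)
  stopifnot(length(y) == nrow(W), ncol(W) == length(alpha),
            length(x) == length(beta))
  if (any(!is.finite(W[!is.na(y), , drop = FALSE])) || any(!is.finite(x)))
    stop("non-finite covariates for this site")
  eta <- as.numeric(W %*% alpha)
  logq <- stats::plogis(eta, lower.tail = FALSE, log.p = TRUE)
  logq[is.na(y)] <- 0
  ll <- rn_site_loglik_cpp(matrix(as.integer(y), 1), matrix(logq, 1),
                           sum(x * beta), as.integer(K))
  as.numeric(ll)
}

# Assemble detection design (list of M x J matrices) and site design matrix
# for a spec against a detection history + site covariate table.
.rn_designs <- function(spec, history, covariates) {
  sites <- history$sites
  covariates <- as.data.frame(covariates)
  idx <- match(sites, as.character(covariates$camera_id))
  if (anyNA(idx))
    stop("covariates missing for site(s): ",
         paste(sites[is.na(idx)], collapse = ", "))
  covariates <- covariates[idx, , drop = FALSE]
  M <- length(sites); J <- ncol(history$y)
  det <- list()
  for (tm in spec$detection_terms) {
    det[[tm]] <- switch(tm,
      effort = history$effort,
      date = history$date,
      tracks_dens = matrix(covariates$tracks_dens, M, J))
    if (is.null(det[[tm]]) || all(is.na(det[[tm]])))
      stop("detection covariate unavailable: ", tm)
  }
  Xcols <- lapply(spec$site_terms, function(tm) {
    v <- if (tm == "tree_buffer2") covariates$tree_buffer^2 else covariates[[tm]]
    if (is.null(v)) stop("site covariate unavailable: ", tm)
    as.numeric(v)
  })
  X <- do.call(cbind, c(list(`(Intercept)` = rep(1, M)), Xcols))
  colnames(X) <- c("(Intercept)", spec$site_terms)
  list(det = det, X = X, covariates = covariates)
}

# Negative log-likelihood and its analytic gradient for optim(). The two
# closures share a one-slot cache so the fn/gr pair BFGS requests at the
# same point costs a single C++ pass.
.rn_negloglik_factory <- function(y, det, X, K, with_grad = FALSE) {
  M <- nrow(y); J <- ncol(y)
  nd <- length(det)
  obs <- !is.na(y)
  det0 <- lapply(det, function(v) { v[!obs] <- 0; v })
  cache <- new.env(parent = emptyenv())
  evalpt <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
    alpha <- par[seq_len(nd + 1)]
    beta <- par[-seq_len(nd + 1)]
    eta <- matrix(alpha[1], M, J)
    for (t in seq_len(nd)) eta <- eta + alpha[t + 1] * det0[[t]]
    logq <- stats::plogis(eta, lower.tail = FALSE, log.p = TRUE)
    loglam <- pmin(pmax(as.numeric(X %*% beta), -30), 25)
    res <- rn_loglik_grad_cpp(y, logq, loglam, as.integer(K))
    cache$par <- par
    cache$res <- res
    res
  }
  fn <- function(par) {
    ll <- sum(evalpt(par)$ll)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  if (!with_grad) return(fn)
  gr <- function(par) {
    res <- evalpt(par)
    if (!all(is.finite(res$ll))) return(rep(0, length(par)))
    ga <- c(sum(res$geta),
            vapply(det0, function(v) sum(res$geta * v), numeric(1)))
    gb <- as.numeric(crossprod(X, res$glam))
    unname(-c(ga, gb))
  }
  list(fn = fn, gr = gr)
}

#' Fit a Royle-Nichols model by maximum likelihood
#'
#' Maximizes the truncated-sum marginal likelihood with quasi-Newton (BFGS)
#' optimization from `n_starts` jittered initializations; the coefficient
#' covariance is the inverse observed information at the optimum. The
#' truncation bound K is checked automatically: if doubling K moves the
#' log-likelihood by more than 1e-6, K is doubled and the fit refined.
#'
#' @param spec an [rn_spec()].
#' @param history a `detection_history` for the spec's species.
#' @param covariates site covariate table (standardized columns
#'   `tree_buffer`, `dist_river`, `dist_conuco`, `tracks_dens` as needed),
#'   one row per site keyed by `camera_id`.
#' @param K truncation bound; default `max(50, 3 *` a method-of-moments
#'   abundance guess `)`.
#' @param n_starts number of jittered optimizer starts (seed-controlled by
#'   the caller's RNG state).
#' @param control passed to [stats::optim()] (merged over defaults).
#' @return an object of class `rn_fit`.
#' @export
fit_rn <- function(spec, history, covariates, K = NULL, n_starts = 5,
                   control = list()) {
  y <- history$y
  storage.mode(y) <- "integer"
  if (!any(!is.na(y))) stop("no observed site-visits")
  d <- .rn_designs(spec, history, covariates)
  nd <- length(d$det); ns <- ncol(d$X) - 1
  if (is.null(K)) {
    p_site <- rowMeans(y == 1L, na.rm = TRUE)
    p_site[is.nan(p_site)] <- 0
    guess <- log1p(-pmin(p_site, 0.95)) / log(0.75) # N needed at r = 0.25
    K <- max(50, ceiling(3 * max(guess, 1)))
  }
  nll <- .rn_negloglik_factory(y, d$det, d$X, K, with_grad = TRUE)
  mean_det <- mean(rowSums(y == 1L, na.rm = TRUE))
  base <- c(-1, rep(0, nd), log(max(mean_det, 0.25)), rep(0, ns))
  ctl <- utils::modifyList(list(maxit = 500, reltol = 1e-10), control)
  best <- NULL
  any_conv <- FALSE
  for (s in seq_len(max(1, n_starts))) {
    par0 <- if (s == 1) base else base + stats::rnorm(length(base), 0, 0.5)
    opt <- tryCatch(stats::optim(par0, nll$fn, nll$gr, method = "BFGS",
                                 control = ctl),
                    error = function(e) NULL)
    if (is.null(opt)) next
    if (opt$convergence == 0) any_conv <- TRUE
    if (is.null(best) || opt$value < best$value - 1e-9 ||
        (opt$convergence == 0 && best$convergence != 0 &&
         opt$value < best$value + 1e-6))
      best <- opt
  }
  if (is.null(best)) stop("optimization failed on every start")

  # truncation-stability check; enlarge K until doubling is inert
  reps <- 0
  repeat {
    nll2 <- .rn_negloglik_factory(y, d$det, d$X, 2 * K)
    if (abs(nll2(best$par) - best$value) < 1e-6 || reps >= 3) break
    K <- 2 * K
    nll <- .rn_negloglik_factory(y, d$det, d$X, K, with_grad = TRUE)
    best <- stats::optim(best$par, nll$fn, nll$gr, method = "BFGS",
                         control = ctl)
    reps <- reps + 1
  }

  hess <- tryCatch(stats::optimHess(best$par, nll$fn, nll$gr),
                   error = function(e) NULL)
  vcov <- NULL
  pos_def <- FALSE
  if (!is.null(hess)) {
    vcov <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vcov)) {
      vcov <- (vcov + t(vcov)) / 2
      ev <- eigen(vcov, symmetric = TRUE, only.values = TRUE)$values
      pos_def <- all(ev > -1e-8 * max(abs(ev), 1))
    }
  }
  anames <- c("(Intercept)", spec$detection_terms)
  bnames <- colnames(d$X)
  alpha <- stats::setNames(best$par[seq_len(nd + 1)], anames)
  beta <- stats::setNames(best$par[-seq_len(nd + 1)], bnames)
  cn <- c(paste0("p_", anames), paste0("lam_", bnames))
  if (!is.null(vcov)) dimnames(vcov) <- list(cn, cn)
  n_sites <- sum(rowSums(!is.na(y)) > 0)
  structure(list(
    spec = spec, alpha = alpha, beta = beta,
    coef = stats::setNames(best$par, cn),
    loglik = -best$value, K = K, vcov = vcov,
    n_sites = n_sites, n_obs = sum(!is.na(y)),
    k = length(best$par),
    converged = any_conv && best$convergence == 0 && !is.null(vcov) && pos_def,
    boundary = exp(beta[["(Intercept)"]]) < 1e-3,
    y = y, det = d$det, X = d$X, sites = history$sites
  ), class = "rn_fit")
}

#' @export
print.rn_fit <- function(x, ...) {
  cat("Royle-Nichols fit [", x$spec$species, "]: ", format(x$spec), "\n",
      sep = "")
  cat(" logLik", formatC(x$loglik, digits = 4, format = "f"),
      " k", x$k, " sites", x$n_sites, " K", x$K,
      if (!x$converged) " (NOT converged)" else "",
      if (x$boundary) " (lambda at 0 boundary)" else "", "\n")
  cat(" detection (logit):", paste(names(x$alpha),
      formatC(x$alpha, digits = 3, format = "f"), collapse = ", "), "\n")
  cat(" abundance (log):  ", paste(names(x$beta),
      formatC(x$beta, digits = 3, format = "f"), collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.rn_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' @export
vcov.rn_fit <- function(object, ...) object$vcov

#' Predict site-level expected abundance from a fitted RN model
#'
#' lambda_i = exp(x_i . beta); standard errors by the delta method from the
#' coefficient covariance. A warning is issued when a prediction covariate
#' lies more than 5 SD outside the training range.
#'
#' @param fit a converged `rn_fit`.
#' @param newdata optional covariate table (defaults to the training sites).
#' @return data frame with `camera_id`, `lambda`, `se`.
#' @export
predict_lambda <- function(fit, newdata = NULL) {
  if (!fit$converged) stop("fit did not converge; no predictions")
  if (is.null(newdata)) {
    X <- fit$X
    ids <- fit$sites
  } else {
    newdata <- as.data.frame(newdata)
    cols <- colnames(fit$X)[-1]
    Xc <- lapply(cols, function(tm) {
      v <- if (tm == "tree_buffer2") newdata$tree_buffer^2 else newdata[[tm]]
      if (is.null(v)) stop("newdata lacks covariate: ", tm)
      as.numeric(v)
    })
    X <- do.call(cbind, c(list(rep(1, nrow(newdata))), Xc))
    colnames(X) <- colnames(fit$X)
    ids <- if (!is.null(newdata$camera_id)) as.character(newdata$camera_id)
           else as.character(seq_len(nrow(X)))
    for (j in seq_along(cols)) {
      tr <- fit$X[, j + 1]
      s <- stats::sd(tr)
      if (s > 0 && any(X[, j + 1] > max(tr) + 5 * s | X[, j + 1] < min(tr) - 5 * s))
        warning("covariate ", cols[j], " outside +-5 SD of training range ",
                "(extrapolation)")
    }
  }
  bidx <- grep("^lam_", names(fit$coef))
  Vb <- fit$vcov[bidx, bidx, drop = FALSE]
  lam <- exp(as.numeric(X %*% fit$beta))
  se <- lam * sqrt(pmax(rowSums((X %*% Vb) * X), 0))
  data.frame(camera_id = ids, lambda = lam, se = se,
             stringsAsFactors = FALSE)
}

# Per-individual detection probability matrix r_ij implied by a fit,
# NA where the site-visit was unobserved.
.rn_r_matrix <- function(fit) {
  y <- fit$y
  obs <- !is.na(y)
  eta <- matrix(fit$alpha[1], nrow(y), ncol(y))
  for (t in seq_along(fit$det)) {
    v <- fit$det[[t]]
    v[!obs] <- 0
    eta <- eta + fit$alpha[t + 1] * v
  }
  r <- stats::plogis(eta)
  r[!obs] <- NA_real_
  r
}

# Fitted marginal detection probability p_ij = 1 - E[(1-r)^N]
# = 1 - exp(-lambda_i r_ij) for Poisson N (closed form).
.rn_marginal_p <- function(fit) {
  r <- .rn_r_matrix(fit)
  lam <- exp(pmin(pmax(as.numeric(fit$X %*% fit$beta), -30), 25))
  1 - exp(-lam * r)
}

# Simulate one replicate detection matrix from a fitted model (parametric
# bootstrap draw): N_i ~ Pois(lambda_i), y_ij ~ Bern(1 - (1-r_ij)^N_i).
.rn_simulate_y <- function(fit) {
  r <- .rn_r_matrix(fit)
  lam <- exp(pmin(pmax(as.numeric(fit$X %*% fit$beta), -30), 25))
  N <- stats::rpois(length(lam), lam)
  p <- 1 - (1 - r)^N
  y <- fit$y
  obs <- !is.na(y)
  y[obs] <- stats::rbinom(sum(obs), 1L, p[obs])
  y
}
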