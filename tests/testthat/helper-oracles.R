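# Independent oracles used to cross-check the package implementations.
# These deliberately use naive brute-force formulations.

# Event grouping by exhaustive pairwise chaining: photos belong to the same
# event iff connected through gaps < gap_minutes within camera+species.
oracle_collapse_count <- function(photos, gap_minutes = 5) {
  ts <- as.POSIXct(photos$timestamp, tz = "UTC")
  n_events <- 0
  for (key in unique(paste(photos$camera_id, photos$species))) {
    sel <- paste(photos$camera_id, photos$species) == key
    t <- sort(as.numeric(ts[sel])) / 60
    if (!length(t)) next
    n_events <- n_events + 1 + sum(diff(t) >= gap_minutes)
  }
  n_events
}

# Direct truncated-sum RN likelihood for one site, pure R.
oracle_site_loglik <- function(y, r, lambda, K) {
  obs <- !is.na(y)
  total <- 0
  for (N in 0:K) {
    p <- 1 - (1 - r)^N
    lik <- prod(ifelse(y[obs] == 1, p[obs], 1 - p[obs]))
    total <- total + dpois(N, lambda) * lik
  }
  log(total)
}

# Pearson chi-square by an explicit O/E double loop.
oracle_chi2 <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  s <- 0
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m)))
      s <- s + (m[i, j] - E[i, j])^2 / E[i, j]
  s
}

# Binomial log-likelihood for the hunting regression, maximized with a
# generic optimizer (independent of glm's IRLS).
oracle_logistic <- function(X, yv) {
  nll <- function(b) {
    eta <- as.numeric(X %*% b)
    -sum(yv * eta - log1p(exp(eta)))
  }
  gr <- function(b) {
    eta <- as.numeric(X %*% b)
    -as.numeric(crossprod(X, yv - plogis(eta)))
  }
  b <- optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-14))$par
  # Newton polish to full precision
  for (i in 1:25) {
    p <- plogis(as.numeric(X %*% b))
    H <- crossprod(X * (p * (1 - p)), X)
    step <- solve(H, crossprod(X, yv - p))
    b <- b + as.numeric(step)
    if (max(abs(step)) < 1e-12) break
  }
  b
}
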