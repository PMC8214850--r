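#' Logistic regression of hunting occurrence on site covariates
#'
#' Fits logit(hunting) ~ tree_buffer + dist_conuco + dist_river by IRLS
#' maximum likelihood on the raw covariate scales (tree cover in percent,
#' distances in metres), with Wald z statistics and two-sided p-values.
#'
#' @param site_table data frame with logical/0-1 `hunting` and numeric
#'   `tree_buffer`, `dist_conuco`, `dist_river`.
#' @return object of class `hunting_glm`: `coefficients` data frame (term,
#'   estimate, se, z, p), `null_deviance`, `deviance`, `aic`, `n`, and the
#'   underlying `glm` object as `model`.
#' @export
fit_hunting_glm <- function(site_table) {
  need <- c("hunting", "tree_buffer", "dist_conuco", "dist_river")
  miss <- setdiff(need, names(site_table))
  if (length(miss)) stop("site_table missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- site_table[stats::complete.cases(site_table[need]), need]
  df$hunting <- as.integer(as.logical(df$hunting))
  for (v in need[-1])
    if (stats::sd(df[[v]]) == 0)
      stop("covariate with zero variance: ", v)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(hunting ~ tree_buffer + dist_conuco + dist_river,
               family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep_warn || any(abs(stats::coef(fit)) > 50))
    stop("complete or quasi-complete separation: fitted probabilities ",
         "numerically 0 or 1; coefficients are not identifiable")
  sm <- summary(fit)$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(sm), estimate = sm[, 1],
                              se = sm[, 2], z = sm[, 3], p = sm[, 4],
                              row.names = NULL, stringsAsFactors = FALSE),
    null_deviance = fit$null.deviance, deviance = fit$deviance,
    aic = stats::AIC(fit), n = nrow(df), model = fit),
    class = "hunting_glm")
}

#' @export
print.hunting_glm <- function(x, ...) {
  cat("Hunting-occurrence logistic regression (n =", x$n, ")\n")
  df <- x$coefficients
  df[-1] <- lapply(df[-1], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  cat("Null deviance:", round(x$null_deviance, 3),
      " Residual deviance:", round(x$deviance, 3),
      " AIC:", round(x$aic, 3), "\n")
  invisible(x)
}

#' Pearson chi-square test of a contingency table
#'
#' Classic chi2 = sum (O - E)^2 / E with expected counts from the margins
#' and no continuity correction; df = (rows - 1)(cols - 1). Rows or columns
#' with a zero margin are dropped with a warning, and a warning is issued
#' when any expected count is below 5 (the p-value is still reported).
#'
#' @param observed matrix (or data frame) of non-negative integer counts.
#' @return object of class `contingency_result`: `observed`, `expected`,
#'   `chi2`, `df`, `p`.
#' @export
chi2_contingency <- function(observed) {
  m <- as.matrix(observed)
  if (any(m < 0) || any(m != round(m)))
    stop("observed must contain non-negative integer counts")
  zr <- rowSums(m) == 0; zc <- colSums(m) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " zero-margin row(s) and ",
            sum(zc), " zero-margin column(s)")
    m <- m[!zr, !zc, drop = FALSE]
  }
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need at least a 2x2 table after dropping zero margins")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  if (any(ht$expected < 5))
    warning("expected count below 5 in ", sum(ht$expected < 5),
            " cell(s); chi-square approximation may be poor")
  structure(list(observed = m, expected = ht$expected,
                 chi2 = unname(ht$statistic), df = unname(ht$parameter),
                 p = unname(ht$p.value)),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("Pearson chi-square: X2 =", format(round(x$chi2, 4), nsmall = 4),
      " df =", x$df, " p =", format(x$p, digits = 4), "\n")
  invisible(x)
}

#' Compare predicted abundance between hunted and unhunted sites
#'
#' Descriptive comparison (no hypothesis test): per-group median and
#' interquartile range of the predicted lambda, and the difference of
#' medians (hunted minus unhunted).
#'
#' @param lambda_predictions numeric vector of predicted site abundances.
#' @param hunting_flags logical (or 0/1) vector aligned with the
#'   predictions.
#' @return list with `by_group` data frame (group, n, median, q25, q75) and
#'   `diff_medians`; a group with no sites yields NA and a `note`.
#' @export
compare_lambda_by_hunting <- function(lambda_predictions, hunting_flags) {
  stopifnot(length(lambda_predictions) == length(hunting_flags))
  fl <- as.logical(hunting_flags)
  grp_stats <- function(v) {
    if (!length(v)) return(c(n = 0, median = NA, q25 = NA, q75 = NA))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
    c(n = length(v), median = q[2], q25 = q[1], q75 = q[3])
  }
  hunted <- grp_stats(lambda_predictions[fl])
  unhunted <- grp_stats(lambda_predictions[!fl])
  by_group <- data.frame(group = c("hunted", "unhunted"),
                         rbind(hunted, unhunted), row.names = NULL,
                         stringsAsFactors = FALSE)
  note <- NULL
  if (any(by_group$n == 0))
    note <- paste("empty group:",
                  paste(by_group$group[by_group$n == 0], collapse = ", "))
  list(by_group = by_group,
       diff_medians = hunted[["median"]] - unhunted[["median"]],
       note = note)
}
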