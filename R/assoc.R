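# Reliability and validity statistics: Guttman's lambda-6, Kendall's
# tau-b, and the stepwise OLS decomposition regressions.

#' Guttman's lambda-6 internal-consistency reliability
#'
#' `lambda6 = 1 - sum_j s2_j (1 - R2_j) / s2_total`, where `R2_j` is the
#' squared multiple correlation of item `j` regressed on all remaining
#' items and `s2_total` the variance of the row sums. Sample variances use
#' the n-1 denominator throughout (the convention cancels between
#' numerator and denominator, so lambda-6 is denominator-invariant; n-1 is
#' kept for the per-item error variances reported alongside). Items that
#' are perfectly predicted by the rest contribute zero error variance
#' (two identical items give lambda-6 = 1).
#'
#' @param items Numeric matrix or data frame, units x items; complete
#'   cases only are used. Needs at least `ncol + 1` complete rows and no
#'   constant column.
#' @return List with `lambda6`, `smc` (per-item squared multiple
#'   correlations), `n` (complete rows used).
#' @export
guttman_lambda6 <- function(items) {
  x <- as.matrix(items)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (n < k + 1) stop("need at least items + 1 complete rows", call. = FALSE)
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    stop("constant item column(s): ",
         paste(colnames(x)[v == 0], collapse = ", "), call. = FALSE)
  }
  err <- numeric(k); smc <- numeric(k)
  for (j in seq_len(k)) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    rss <- sum(fit$residuals^2)
    err[j] <- rss / (n - 1)
    smc[j] <- 1 - rss / ((n - 1) * v[j])
  }
  total <- stats::var(rowSums(x))
  if (total == 0) stop("total score has zero variance", call. = FALSE)
  list(lambda6 = 1 - sum(err) / total, smc = smc, n = n)
}

#' Kendall's tau-b with tie-corrected normal inference
#'
#' Rank correlation with tie corrections in both margins; the two-sided
#' p-value comes from the normal approximation with tie-adjusted variance
#' (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return List with `tau`, `p_value`, `n`.
#' @export
kendall_tau_b <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("tau-b is undefined for a constant vector", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = FALSE))
  list(tau = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Pairwise tau-b correlation table
#'
#' Convenience wrapper producing the validity-correlation machinery: tau-b
#' and its p-value for every column of `x` against every column of `y`.
#'
#' @param x,y Data frames of unit-aligned numeric columns.
#' @return Tibble (`x`, `y`, `tau`, `p_value`, `n`).
#' @export
tau_b_table <- function(x, y) {
  out <- list()
  for (cx in names(x)) for (cy in names(y)) {
    r <- kendall_tau_b(x[[cx]], y[[cy]])
    out[[length(out) + 1]] <- tibble::tibble(
      x = cx, y = cy, tau = r$tau, p_value = r$p_value, n = r$n)
  }
  dplyr::bind_rows(out)
}

significance_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   .default = "")
}

#' Stepwise OLS decomposition of the composite index
#'
#' For one outcome, fits five models with identical controls: the overall
#' index plus controls, then each of the four domain sub-indices in its
#' place. Listwise deletion, ordinary (non-robust) standard errors, no
#' multiple-testing adjustment across the five descriptive models.
#'
#' @param outcome Numeric vector aligned with `pi_result` rows, or the
#'   name of a column in `covariates`.
#' @param pi_result Per-region result tibble from [compute_pi()] (element
#'   `pi`).
#' @param covariates Tibble keyed by `region` with the controls `gni_log`
#'   and `pct_urban` (and the outcome column if named).
#' @param controls Character vector of control column names.
#' @return Tibble of coefficient rows: `outcome`, `predictor` (model
#'   label), `term`, `estimate`, `se`, `p_value`, `stars`, `n`.
#' @export
stepwise_decomposition <- function(outcome, pi_result, covariates,
                                   controls = c("gni_log", "pct_urban")) {
  df <- dplyr::inner_join(pi_result, covariates, by = "region")
  outcome_name <- if (is.character(outcome) && length(outcome) == 1) {
    outcome
  } else {
    df$.outcome <- outcome
    ".outcome"
  }
  predictors <- c("pi", names(domain_map()))
  out <- list()
  for (pred in predictors) {
    vars <- c(outcome_name, pred, controls)
    d <- df[stats::complete.cases(df[, vars]), vars]
    if (nrow(d) < length(vars) + 1) {
      stop("too few complete cases for predictor ", pred, call. = FALSE)
    }
    X <- stats::model.matrix(
      stats::reformulate(c(pred, controls)), data = d)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      stop("collinear model column(s): ", paste(dropped, collapse = ", "),
           call. = FALSE)
    }
    fit <- stats::lm(stats::reformulate(c(pred, controls),
                                        response = outcome_name), data = d)
    cf <- summary(fit)$coefficients
    out[[pred]] <- tibble::tibble(
      outcome = if (outcome_name == ".outcome") "outcome" else outcome_name,
      predictor = pred, term = rownames(cf), estimate = cf[, 1],
      se = cf[, 2], p_value = cf[, 4],
      stars = significance_stars(cf[, 4]), n = nrow(d))
  }
  dplyr::bind_rows(out)
}
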