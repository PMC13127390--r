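#' Overall percent agreement (OPA)
#'
#' The fraction of cases on which every observer on the panel assigned the
#' identical category, with a binomial confidence interval on the unanimous
#' count. The Wilson score interval is the default: unlike a case-resampling
#' bootstrap it yields a nonzero upper bound when no case is unanimous, and
#' its lower bound is exactly 0 at a zero count.
#'
#' @param m a [score_matrix()].
#' @param ci `"wilson"` (default) or `"clopper-pearson"`.
#' @param level confidence level.
#' @return an `agree_est` with `estimate`, `lower`, `upper`, and the number of
#'   cases `n`.
#' @examples
#' m <- score_matrix(matrix(c(0, 0, 1, 3, 3, 3), 2, byrow = TRUE))
#' opa(m)  # 1 unanimous case of 2
#' @export
opa <- function(m, ci = c("wilson", "clopper-pearson"), level = 0.95) {
  stopifnot(inherits(m, "score_matrix"))
  ci <- match.arg(ci)
  n <- nrow(m$scores)
  x <- sum(unanimous_cases(m))
  int <- if (ci == "wilson") wilson_ci(x, n, level) else clopper_pearson_ci(x, n, level)
  est <- agree_est(x / n, int[1], int[2], method = ci, n = n)
  est$successes <- x
  est
}

unanimous_cases <- function(m) {
  s <- m$scores
  rowSums(s == s[, 1]) == ncol(s)
}

#' Wilson score interval for a binomial proportion
#'
#' @param x success count.
#' @param n trial count.
#' @param level confidence level.
#' @return numeric `c(lower, upper)`.
#' @export
wilson_ci <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  out <- c(centre - half, centre + half)
  # exact endpoints at the degenerate counts (centre - half underflows to ~1e-18)
  if (x == 0) out[1] <- 0
  if (x == n) out[2] <- 1
  pmin(pmax(out, 0), 1)
}

#' @rdname wilson_ci
#' @export
clopper_pearson_ci <- function(x, n, level = 0.95) {
  a <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lower, upper)
}

#' Fleiss' kappa for a fixed-size rater panel
#'
#' Chance-corrected agreement for N subjects each rated by the same number R
#' of observers into C nominal categories, computed from the per-case count
#' table: per-case agreement P_i = (sum_j n_ij^2 - R) / (R (R - 1)), observed
#' agreement is the mean of P_i, expected agreement is sum_j p_j^2 from the
#' pooled category proportions, and kappa = (P_obs - P_exp) / (1 - P_exp).
#' The 95% interval is kappa +/- z * SE with the Fleiss-Nee-Landis
#' fixed-marginal large-sample standard error.
#'
#' @param x a [score_matrix()] or a count table as returned by
#'   [count_table()] (rows must all sum to the same R >= 2).
#' @param level confidence level.
#' @return an `agree_est`, or an undefined-statistic marker when all ratings
#'   fall in a single category (chance agreement is then 1 and kappa has no
#'   value).
#' @export
fleiss_kappa <- function(x, level = 0.95) {
  cnt <- if (inherits(x, "score_matrix")) count_table(x) else as.matrix(x)
  n <- nrow(cnt)
  R <- unique(rowSums(cnt))
  if (length(R) != 1) stop("unbalanced count table: rows must all sum to R")
  if (R < 2) stop("Fleiss' kappa needs at least 2 ratings per case")
  p_j <- colSums(cnt) / (n * R)
  p_exp <- sum(p_j^2)
  if (1 - p_exp < .Machine$double.eps^0.5)
    return(undefined_stat("all ratings in one category; chance agreement = 1"))
  P_i <- (rowSums(cnt^2) - R) / (R * (R - 1))
  kappa <- (mean(P_i) - p_exp) / (1 - p_exp)
  # Fleiss, Nee & Landis fixed-marginal SE
  s <- sum(p_j * (1 - p_j))
  se <- sqrt(2 * (s^2 - sum(p_j * (1 - p_j) * (1 - 2 * p_j)))) /
    (s * sqrt(n * R * (R - 1)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- agree_est(kappa, kappa - z * se, kappa + z * se,
                   method = "Fleiss-Nee-Landis", n = n)
  est$se <- se
  est
}

#' Intraclass correlation ICC(A,1)
#'
#' Single-rater absolute-agreement intraclass correlation from the two-way
#' random-effects ANOVA (cases and observers both random), the model used for
#' ordinal scores entered as their numeric codes. With mean squares MSR
#' (cases), MSC (observers) and MSE (residual) from the n x k layout,
#' \deqn{ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)).}
#' The confidence interval is the McGraw-Wong F-based interval with
#' Satterthwaite degrees of freedom.
#'
#' @param m a [score_matrix()], or a numeric matrix (cases x observers).
#' @param level confidence level.
#' @return an `agree_est` with an `components` field (mean squares and
#'   degrees of freedom), or an undefined-statistic marker when the scores
#'   carry no variance at all.
#' @export
icc_a1 <- function(m, level = 0.95) {
  y <- if (inherits(m, "score_matrix")) m$scores else as.matrix(m)
  storage.mode(y) <- "double"
  n <- nrow(y); k <- ncol(y)
  if (n < 2) stop("ICC needs at least 2 cases")
  if (k < 2) stop("ICC needs at least 2 observers")
  grand <- mean(y)
  row_m <- rowMeans(y)
  col_m <- colMeans(y)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((y - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  comp <- list(ms_rows = msr, ms_cols = msc, ms_error = mse, n = n, k = k,
               df_rows = n - 1, df_cols = k - 1, df_error = (n - 1) * (k - 1))
  if (msr + msc + mse < .Machine$double.eps^0.5)
    return(undefined_stat("zero total variance: all scores identical"))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  icc <- (msr - mse) / denom
  est <- agree_est(icc, NA_real_, NA_real_, method = "McGraw-Wong F", n = n)
  est$components <- comp
  # McGraw-Wong CI for ICC(A,1)
  a <- 1 - level
  if (mse <= 0) {
    # degenerate perfect fit: interval collapses onto the estimate
    est$lower <- icc; est$upper <- icc
    return(est)
  }
  fj <- msc / mse
  vn <- (k - 1) * (n - 1) *
    (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * fj^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  f_l <- stats::qf(1 - a / 2, n - 1, v)
  f_u <- stats::qf(1 - a / 2, v, n - 1)
  est$lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  est$upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  est$lower <- max(-1, min(est$lower, 1))
  est$upper <- max(-1, min(est$upper, 1))
  est
}

#' Fit the full agreement summary for a rater panel
#'
#' The central fitting function: computes overall percent agreement, Fleiss'
#' kappa and ICC(A,1), each with its 95% interval, for one score matrix.
#'
#' @param m a [score_matrix()].
#' @param ci_method interval method for OPA, see [opa()].
#' @param level confidence level.
#' @param grouping_name label carried into printed reports.
#' @return an object of class `agreement` with components `opa`, `kappa`,
#'   `icc`, `n_cases`, `n_observers`.
#' @examples
#' cfg <- her2_default_config(n_cases = 60)
#' fit <- agreement(simulate_panel(cfg, seed = 1))
#' fit
#' coef(fit)
#' @export
agreement <- function(m, ci_method = c("wilson", "clopper-pearson"),
                      level = 0.95, grouping_name = "panel") {
  stopifnot(inherits(m, "score_matrix"))
  ci_method <- match.arg(ci_method)
  structure(list(grouping_name = grouping_name,
                 n_cases = nrow(m$scores), n_observers = ncol(m$scores),
                 opa = opa(m, ci = ci_method, level = level),
                 kappa = fleiss_kappa(m, level = level),
                 icc = icc_a1(m, level = level),
                 level = level),
            class = "agreement")
}

#' @export
print.agreement <- function(x, ...) {
  cat(sprintf("Agreement for %s: %d cases x %d observers\n",
              x$grouping_name, x$n_cases, x$n_observers))
  line <- function(nm, e) {
    if (is_undefined(e)) cat(sprintf("  %-14s undefined (%s)\n", nm, e$reason))
    else cat(sprintf("  %-14s %s (%s-%s)\n", nm, fmt2(e$estimate),
                     fmt2(e$lower), fmt2(e$upper)))
  }
  line("OPA", x$opa)
  line("Fleiss' kappa", x$kappa)
  line("ICC(A,1)", x$icc)
  invisible(x)
}

#' @export
summary.agreement <- function(object, ...) {
  print(object)
  if (!is_undefined(object$icc)) {
    cmp <- object$icc$components
    cat(sprintf("  ANOVA mean squares: cases %.4f (df %d), observers %.4f (df %d), residual %.4f (df %d)\n",
                cmp$ms_rows, cmp$df_rows, cmp$ms_cols, cmp$df_cols,
                cmp$ms_error, cmp$df_error))
  }
  invisible(object)
}

#' @export
coef.agreement <- function(object, ...) {
  c(opa = object$opa$estimate, fleiss_kappa = object$kappa$estimate,
    icc = object$icc$estimate)
}

#' @export
confint.agreement <- function(object, parm, level, ...) {
  out <- rbind(opa = c(object$opa$lower, object$opa$upper),
               fleiss_kappa = c(object$kappa$lower, object$kappa$upper),
               icc = c(object$icc$lower, object$icc$upper))
  colnames(out) <- c("lower", "upper")
  out
}
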