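## Statistical utilities for comparing conditions and for comparing modeled
## with measured values: Friedman tests across repeated-measures conditions,
## pairwise Wilcoxon signed-rank tests with Bonferroni-Holm correction, and
## linear regression of measured on modeled values reporting R^2 and RMSE.
## The rank tests delegate to the standard implementations in `stats` (which
## include average-rank tie handling and exact small-sample distributions)
## and are wrapped into a uniform outcome record.

#' Friedman test across conditions (repeated measures)
#'
#' Rank-based Friedman chi-squared test on a subjects x conditions matrix,
#' with average-rank tie correction; degenerate all-equal rows rank as
#' midranks, and a fully constant matrix yields chi-squared 0, p = 1.
#'
#' @param block_matrix numeric matrix, rows = subjects (blocks), columns =
#'   conditions.
#' @param alpha significance level for the decision field (default 0.05).
#' @return list of class `test_outcome`: `statistic` (chi-squared), `dof`,
#'   `p_value`, `significant`.
#' @export
friedman_test <- function(block_matrix, alpha = 0.05) {
  block_matrix <- as.matrix(block_matrix)
  if (nrow(block_matrix) < 2 || ncol(block_matrix) < 2)
    stop("invalid-argument: need >= 2 subjects and >= 2 conditions", call. = FALSE)
  r <- t(apply(block_matrix, 1, rank))
  if (all(abs(r - r[, 1]) < .Machine$double.eps^0.5)) {
    out <- list(statistic = 0, dof = ncol(block_matrix) - 1L, p_value = 1,
                significant = FALSE)
    class(out) <- "test_outcome"
    return(out)
  }
  ht <- stats::friedman.test(block_matrix)
  out <- list(statistic = unname(ht$statistic), dof = unname(ht$parameter),
              p_value = ht$p.value, significant = ht$p.value < alpha)
  class(out) <- "test_outcome"
  out
}

#' Pairwise Wilcoxon signed-rank tests with Bonferroni-Holm correction
#'
#' Each element of `paired_samples` is a list/pair of equal-length vectors.
#' Zero differences are dropped (the common convention).  The exact
#' signed-rank distribution is used for n <= 25 non-zero differences (absent
#' ties), the normal approximation with tie correction otherwise.  P-values
#' are Holm-adjusted across the supplied family.
#'
#' @param paired_samples list of pairs, e.g. `list(list(x1, y1), list(x2, y2))`.
#' @param alpha significance level applied to the adjusted p-values.
#' @return list of `test_outcome`s with fields `statistic` (V), `p_value`,
#'   `adjusted_p`, `significant`, `n_nonzero`.
#' @export
wilcoxon_holm <- function(paired_samples, alpha = 0.05) {
  raw <- lapply(paired_samples, function(pr) {
    x <- pr[[1]]; y <- pr[[2]]
    if (length(x) != length(y))
      stop("invalid-argument: paired vectors must have equal length", call. = FALSE)
    d <- x - y
    d <- d[d != 0]
    if (!length(d))
      stop("undefined-test: all differences are zero", call. = FALSE)
    ht <- suppressWarnings(
      stats::wilcox.test(d, exact = length(d) <= 25, correct = FALSE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         n_nonzero = length(d))
  })
  adj <- p.adjust(vapply(raw, `[[`, numeric(1), "p_value"), method = "holm")
  mapply(function(r, a) {
    out <- c(r, list(adjusted_p = a, significant = a < alpha))
    class(out) <- "test_outcome"
    out
  }, raw, adj, SIMPLIFY = FALSE)
}

#' Linear regression of measured against modeled values
#'
#' Ordinary least squares `measured ~ modeled`; reports slope, intercept,
#' the coefficient of determination of the fit, the residual RMSE (primary),
#' and additionally the raw modeled-versus-measured RMSE
#' (`rmse_agreement`).
#'
#' @param modeled,measured equal-length numeric vectors (n >= 3).
#' @return list of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `rmse`, `rmse_agreement`.
#' @export
regress_model_vs_measured <- function(modeled, measured) {
  if (length(modeled) != length(measured) || length(modeled) < 3)
    stop("invalid-argument: need equal-length vectors with n >= 3", call. = FALSE)
  if (sd(modeled) < .Machine$double.eps^0.5 * (1 + abs(mean(modeled))))
    stop("undefined-fit: zero variance in modeled values", call. = FALSE)
  fit <- lm(measured ~ modeled)
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((measured - mean(measured))^2)
  out <- list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
              r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
              rmse = sqrt(mean(resid(fit)^2)),
              rmse_agreement = sqrt(mean((measured - modeled)^2)))
  class(out) <- "regression_result"
  out
}

#' @export
print.test_outcome <- function(x, ...) {
  cat(sprintf("<test_outcome: stat %.4g%s, p %.4g%s%s>\n", x$statistic,
              if (!is.null(x$dof)) sprintf(", df %d", x$dof) else "",
              x$p_value,
              if (!is.null(x$adjusted_p)) sprintf(", holm %.4g", x$adjusted_p) else "",
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression: slope %.3f, intercept %.3f, R2 %.3f, RMSE %.3f>\n",
              x$slope, x$intercept, x$r_squared, x$rmse))
  invisible(x)
}
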