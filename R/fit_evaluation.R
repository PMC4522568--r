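#' Goodness-of-fit indices for a converged fit
#'
#' Computes the model chi-square `T = c * F_ML` (multiplier `c = N - 1`
#' under the default `"wishart"` dialect, `c = N` under `"normal"`), its
#' p-value on `df = 45 - p` degrees of freedom (45 distinct covariance
#' moments, no means), and
#'
#' * RMSEA `= sqrt(max(T - df, 0) / (df * c))` — the denominator multiplier
#'   pairs with the chi-square dialect;
#' * CFI `= 1 - max(T - df, 0) / max(T - df, T_b - df_b, 0)` against the
#'   independence baseline (diagonal covariance, fit in closed form:
#'   `T_b = c * (sum(log(S_ii)) - log|S|)`, `df_b = 36`);
#' * SRMR `= sqrt(mean over the lower triangle incl. diagonal of
#'   ((S_ij - Sigma_ij) / sqrt(S_ii S_jj))^2)` (45 cells by default; the
#'   36-cell off-diagonal variant is available via `srmr_diagonal =
#'   FALSE`).
#'
#' @param fit A converged `mtmm_fit`.
#' @param dialect `"wishart"` (multiplier `N - 1`, matching the `N - 1`
#'   covariance divisor) or `"normal"` (multiplier `N`).
#' @param srmr_diagonal Include the 9 standardized diagonal residuals in
#'   SRMR (default `TRUE`).
#' @return An object of class `mtmm_indices`: `chi_square`, `df`,
#'   `p_value`, `rmsea`, `cfi`, `srmr`, plus the baseline `baseline_chi_square`
#'   and `baseline_df`.
#' @export
compute_indices <- function(fit, dialect = c("wishart", "normal"), srmr_diagonal = TRUE) {
  stopifnot(inherits(fit, "mtmm_fit"))
  if (!fit$converged) stop("fit indices are only defined for converged fits")
  dialect <- match.arg(dialect)
  mult <- if (dialect == "wishart") fit$N - 1 else fit$N

  p_free <- count_free_parameters(fit$spec)
  df <- 45L - p_free
  if (df <= 0) stop("non-positive degrees of freedom")

  T_stat <- mult * max(fit$discrepancy, 0)
  p_value <- pchisq(T_stat, df, lower.tail = FALSE)
  rmsea <- sqrt(max(T_stat - df, 0) / (df * mult))

  S <- fit$S
  T_b <- mult * (sum(log(diag(S))) - determinant(S, logarithm = TRUE)$modulus[1])
  df_b <- 36L
  num <- max(T_stat - df, 0)
  den <- max(T_stat - df, T_b - df_b, 0)
  cfi <- if (den == 0) 1 else 1 - num / den

  sigma_hat <- implied_covariance(fit$spec, fit$point)
  d <- sqrt(diag(S))
  res <- (S - sigma_hat) / tcrossprod(d)
  cells <- if (srmr_diagonal) lower.tri(res, diag = TRUE) else lower.tri(res)
  srmr <- sqrt(mean(res[cells]^2))

  structure(
    list(chi_square = T_stat, df = df, p_value = p_value,
         rmsea = rmsea, cfi = cfi, srmr = srmr,
         baseline_chi_square = as.numeric(T_b), baseline_df = df_b,
         dialect = dialect),
    class = "mtmm_indices"
  )
}

#' @export
print.mtmm_indices <- function(x, ...) {
  cat(sprintf(
    "<mtmm_indices> chi2(%d) = %.3f (p = %.4f), RMSEA = %.4f, CFI = %.4f, SRMR = %.4f\n",
    x$df, x$chi_square, x$p_value, x$rmsea, x$cfi, x$srmr))
  invisible(x)
}

#' Apply the fit acceptance criteria
#'
#' Rejection rules: chi-square p-value below 0.05, RMSEA above 0.05, CFI
#' below 0.95, SRMR above 0.05. Boundary values count as acceptable
#' (p-value of exactly 0.05, RMSEA/SRMR of exactly 0.05, CFI of exactly
#' 0.95 are not rejections).
#'
#' @param indices An `mtmm_indices` object.
#' @return Named logical vector `reject_chi2`, `reject_rmsea`,
#'   `reject_cfi`, `reject_srmr`.
#' @export
classify_fit <- function(indices) {
  stopifnot(inherits(indices, "mtmm_indices"))
  c(reject_chi2 = indices$p_value < 0.05,
    reject_rmsea = indices$rmsea > 0.05,
    reject_cfi = indices$cfi < 0.95,
    reject_srmr = indices$srmr > 0.05)
}
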