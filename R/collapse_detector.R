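Z_CRIT <- qnorm(0.975) # 1.959964

#' Loading sets
#'
#' The 18 loading positions are grouped into six sets of three, each set
#' holding the loadings of one method: Sets 1--3 are the trait loadings of
#' methods 1--3, Sets 4--6 the method-factor loadings of methods 1--3. In a
#' fitted methods-minus-one model the reference method's set of method
#' loadings is fixed at zero by construction (structurally zero) and is
#' excluded from collapse statistics.
#'
#' @name loading-sets
#' @keywords internal
NULL

#' Per-loading Wald significance
#'
#' A loading is non-significant when its 95% Wald confidence interval
#' contains zero, i.e. when `|estimate| <= z * SE` with `z = qnorm(0.975)`;
#' significance requires `|z-ratio|` strictly greater than the critical
#' value, so a boundary z-ratio counts as non-significant. Loadings whose
#' standard error is unavailable are marked indeterminate (`NA`).
#'
#' @param fit A converged `mtmm_fit` with standard errors.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Data frame with one row per loading position: `indicator`,
#'   `method`, `type` (`"trait"`/`"method"`), `set` (1--6), `label` (`NA`
#'   for structurally zero loadings), `estimate`, `se`, `z`, and `nonsig`
#'   (`TRUE`/`FALSE`, `NA` when indeterminate or structurally zero).
#' @export
loading_significance <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "mtmm_fit"))
  if (!fit$converged) stop("loading significance is only defined for converged fits")
  if (is.null(fit$standard_errors)) {
    stop("fit has no standard errors; call fit_ml() with se = TRUE")
  }
  zc <- qnorm(1 - alpha / 2)
  spec <- fit$spec
  lay <- variable_layout()
  rows <- lapply(1:9, function(k) {
    out <- list()
    for (type in c("trait", "method")) {
      label <- if (type == "trait") spec$lambda[k] else spec$gamma[k]
      set <- if (type == "trait") lay$method[k] else 3L + lay$method[k]
      if (is.na(label)) {
        out[[type]] <- data.frame(
          indicator = lay$indicator[k], method = lay$method[k], type = type,
          set = set, label = NA_character_, estimate = 0, se = NA_real_,
          z = NA_real_, nonsig = NA, stringsAsFactors = FALSE)
      } else {
        est <- fit$point[[label]]
        se <- fit$standard_errors[[label]]
        z <- if (is.na(se)) NA_real_ else est / se
        nonsig <- if (is.na(z)) NA else !(abs(z) > zc)
        out[[type]] <- data.frame(
          indicator = lay$indicator[k], method = lay$method[k], type = type,
          set = set, label = label, estimate = est, se = se, z = z,
          nonsig = nonsig, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$set, out$indicator), ]
}

# Method factors eligible for collapse statistics: those carrying free
# loadings (the CMm1 reference method's factor is structurally zero).
eligible_method_factors <- function(spec) {
  lay <- variable_layout()
  which(vapply(1:3, function(m) any(!is.na(spec$gamma[lay$method == m])), logical(1)))
}

#' Detect method-factor collapse
#'
#' A method factor collapses when all three of its loadings are jointly
#' non-significant, emptying the factor of empirical content. Structurally
#' zero factors (the reference method of a fitted methods-minus-one model)
#' are excluded. Indeterminate loadings (no standard error) do not count as
#' non-significant unless `include_indeterminate = TRUE`.
#'
#' @param fit A converged `mtmm_fit` with standard errors.
#' @param spec Model spec; defaults to the fit's own.
#' @param alpha Two-sided significance level (default 0.05).
#' @param include_indeterminate Count loadings without standard errors as
#'   non-significant (default `FALSE`).
#' @return Named logical vector over the eligible method factors
#'   (`M1`..`M3`).
#' @export
detect_collapse <- function(fit, spec = fit$spec, alpha = 0.05,
                            include_indeterminate = FALSE) {
  sig <- loading_significance(fit, alpha = alpha)
  eligible <- eligible_method_factors(spec)
  out <- logical(0)
  for (m in eligible) {
    ns <- sig$nonsig[sig$type == "method" & sig$method == m]
    if (include_indeterminate) ns[is.na(ns)] <- TRUE else ns[is.na(ns)] <- FALSE
    out[paste0("M", m)] <- all(ns)
  }
  out
}

#' Per-set non-significance profile
#'
#' Counts, for each of the six loading sets, how many of its three loadings
#' are non-significant, and flags per-method-factor collapse.
#'
#' @inheritParams detect_collapse
#' @return List with `counts` (named integer vector `set1`..`set6`; `NA`
#'   for a structurally zero set), `structural_zero` (logical per set) and
#'   `collapse` (as [detect_collapse()]).
#' @export
significance_profile <- function(fit, alpha = 0.05, include_indeterminate = FALSE) {
  sig <- loading_significance(fit, alpha = alpha)
  counts <- integer(6)
  structural <- logical(6)
  for (s in 1:6) {
    rows <- sig[sig$set == s, ]
    if (all(is.na(rows$label))) {
      counts[s] <- NA_integer_
      structural[s] <- TRUE
    } else {
      ns <- rows$nonsig
      if (include_indeterminate) ns[is.na(ns)] <- TRUE else ns[is.na(ns)] <- FALSE
      counts[s] <- sum(ns)
    }
  }
  names(counts) <- names(structural) <- paste0("set", 1:6)
  list(counts = counts, structural_zero = structural,
       collapse = detect_collapse(fit, alpha = alpha,
                                  include_indeterminate = include_indeterminate))
}
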