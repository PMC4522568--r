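#' Default starting values for the ML fit
#'
#' Scale-aware deterministic starts: trait loadings start at
#' `sqrt(0.5 * S_ii)`, method loadings at `sqrt(0.25 * S_ii)`, error
#' variances at `0.5 * S_ii`, correlations at 0. A label shared across
#' several observed variables starts at the mean of its per-variable values.
#'
#' @param spec An `mtmm_model`.
#' @param S 9x9 sample covariance matrix.
#' @return Named numeric starting point over `spec$free`.
#' @export
default_start <- function(spec, S) {
  stopifnot(inherits(spec, "mtmm_model"))
  d <- diag(S)
  start <- setNames(numeric(length(spec$free)), spec$free)
  acc <- list()
  add <- function(acc, label, value) {
    acc[[label]] <- c(acc[[label]], value)
    acc
  }
  for (k in 1:9) {
    acc <- add(acc, spec$lambda[k], sqrt(0.5 * d[k]))
    if (!is.na(spec$gamma[k])) acc <- add(acc, spec$gamma[k], sqrt(0.25 * d[k]))
    acc <- add(acc, spec$theta[k], 0.5 * d[k])
  }
  for (label in names(acc)) start[label] <- mean(acc[[label]])
  # free correlations remain at 0
  start
}

# Latent covariance matrix over the factors the model actually uses
# (trait + methods carrying at least one free loading), unit diagonal.
assemble_psi <- function(spec, point) {
  point <- validate_point(spec, point)
  lay <- variable_layout()
  active <- c(TRUE, vapply(1:3, function(m) any(!is.na(spec$gamma[lay$method == m])), logical(1)))
  q <- sum(active)
  psi <- diag(q)
  labels <- c("T", paste0("M", 1:3))[active]
  dimnames(psi) <- list(labels, labels)
  methods_active <- which(active[-1])
  for (a in methods_active) for (b in methods_active) {
    if (a < b && !is.na(spec$rho[a, b])) {
      psi[paste0("M", a), paste0("M", b)] <- point[spec$rho[a, b]]
      psi[paste0("M", b), paste0("M", a)] <- point[spec$rho[a, b]]
    }
  }
  psi
}

#' Test a symmetric matrix for non-positive definiteness
#'
#' @param m Square symmetric matrix.
#' @param tolerance Negative eigenvalues smaller than `-tolerance` count as
#'   non-positive definite.
#' @return `TRUE` iff the smallest eigenvalue is below `-tolerance`.
#' @export
check_npd <- function(m, tolerance = 1e-8) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-8) stop("'m' must be symmetric")
  min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -tolerance
}

#' Fit a model to a sample covariance matrix by maximum likelihood
#'
#' Minimizes the normal-theory discrepancy
#' \eqn{F_{ML} = \ln|\Sigma(\theta)| + tr(S\Sigma(\theta)^{-1}) - \ln|S| - 9}
#' over the free parameters by BFGS with the analytic gradient, equality
#' constraints moving shared labels in lockstep. Estimates are unbounded:
#' negative error variances and correlations outside \[-1, 1\] are
#' representable, so improper solutions are observable rather than masked.
#' A fit is converged when the largest absolute gradient entry falls below
#' `gtol` (a derivative criterion in the dialect of mainstream SEM
#' software; default `3e-5` on the F_ML scale); otherwise it is
#' non-converged at the iteration cap (default 1000) or when the line
#' search can no longer find a positive-definite decreasing step. A
#' stricter dialect that additionally requires the relative parameter
#' change to fall below `xtol` is available.
#'
#' @param spec An `mtmm_model`.
#' @param S Symmetric positive-definite 9x9 sample covariance matrix
#'   (divisor `N - 1`).
#' @param N Sample size (> 9).
#' @param start Optional named starting point; defaults to
#'   [default_start()].
#' @param max_iterations Iteration cap (default 1000).
#' @param se Compute standard errors for converged fits (default `TRUE`).
#' @param gtol Gradient convergence criterion (default `3e-5`).
#' @param xtol Optional relative-parameter-change criterion; `NULL`
#'   (default) disables it.
#' @return An object of class `mtmm_fit` with fields `point`,
#'   `standard_errors`, `converged`, `iterations`, `discrepancy`,
#'   `theta_npd`, `psi_npd` (improper-solution flags; `NA` for
#'   non-converged fits), `log_notes`, and the inputs `spec`, `S`, `N`.
#' @export
fit_ml <- function(spec, S, N, start = NULL, max_iterations = 1000L, se = TRUE,
                   gtol = 3e-5, xtol = NULL) {
  stopifnot(inherits(spec, "mtmm_model"), is.matrix(S), all(dim(S) == 9L))
  if (max(abs(S - t(S))) > 1e-8) stop("'S' must be symmetric")
  if (N <= 9) stop("'N' must exceed the number of observed variables")
  S <- (S + t(S)) / 2
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (!ok) stop("'S' is not positive definite")

  start_vec <- if (is.null(start)) default_start(spec, S) else validate_point(spec, start)
  maps <- param_maps(spec)
  res <- fit_ml_cpp(maps$L, maps$P, maps$Th, S, unname(start_vec),
                    max_iter = as.integer(max_iterations), gtol = gtol,
                    xtol = if (is.null(xtol)) -1 else xtol)

  point <- setNames(as.numeric(res$par), spec$free)
  converged <- isTRUE(res$converged)
  notes <- if (nzchar(res$note)) res$note else character(0)

  theta_npd <- NA
  psi_npd <- NA
  if (converged) {
    theta_npd <- any(point[spec$theta] < 0)
    psi_npd <- check_npd(assemble_psi(spec, point))
  }

  fit <- structure(
    list(
      point = point,
      standard_errors = NULL,
      converged = converged,
      iterations = as.integer(res$iterations),
      discrepancy = as.numeric(res$fml),
      theta_npd = theta_npd,
      psi_npd = psi_npd,
      log_notes = notes,
      spec = spec,
      S = S,
      N = as.integer(N),
      start = start_vec
    ),
    class = "mtmm_fit"
  )
  if (se && converged) {
    se_res <- standard_errors(spec, point, S, N)
    fit$standard_errors <- se_res$se
    fit$log_notes <- c(fit$log_notes, se_res$notes)
  }
  fit
}

#' @export
print.mtmm_fit <- function(x, ...) {
  cat(sprintf("<mtmm_fit> %s: %s after %d iterations, F_ML = %.6g\n",
              x$spec$family,
              if (x$converged) "converged" else "NON-converged",
              x$iterations, x$discrepancy))
  if (isTRUE(x$theta_npd)) cat("  improper solution: negative error variance (Theta npd)\n")
  if (isTRUE(x$psi_npd)) cat("  improper solution: latent covariance matrix (Psi) npd\n")
  for (n in x$log_notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Standard errors from the inverse information matrix
#'
#' The information matrix of `(N - 1)/2 * F_ML` is approximated by central
#' finite differences of the analytic gradient at the estimate; standard
#' errors are square roots of the diagonal of its inverse. Labels whose
#' entry is not estimable (singular information, or a negative diagonal of
#' the inverse at a saddle) are reported as `NA` with a log note rather
#' than raised.
#'
#' @param spec An `mtmm_model`.
#' @param point Converged parameter estimates (named).
#' @param S Sample covariance matrix.
#' @param N Sample size.
#' @return List with `se` (named vector, `NA` where not estimable) and
#'   `notes` (character diagnostics).
#' @export
standard_errors <- function(spec, point, S, N) {
  point <- validate_point(spec, point)
  maps <- param_maps(spec)
  p <- length(point)
  th <- unname(point)
  H <- matrix(NA_real_, p, p)
  hstep <- 1e-4 * pmax(1, abs(th))
  for (j in seq_len(p)) {
    up <- th; up[j] <- up[j] + hstep[j]
    dn <- th; dn[j] <- dn[j] - hstep[j]
    gu <- fml_eval_cpp(up, maps$L, maps$P, maps$Th, S, gradient = TRUE)
    gd <- fml_eval_cpp(dn, maps$L, maps$P, maps$Th, S, gradient = TRUE)
    if (!gu$pd || !gd$pd) {
      return(list(se = setNames(rep(NA_real_, p), spec$free),
                  notes = "information matrix not computable: Sigma not PD near the estimate"))
    }
    H[, j] <- (gu$gradient - gd$gradient) / (2 * hstep[j])
  }
  H <- (H + t(H)) / 2
  info <- (N - 1) / 2 * H
  inv <- tryCatch(solve(info), error = function(e) NULL)
  notes <- character(0)
  se <- setNames(rep(NA_real_, p), spec$free)
  if (is.null(inv)) {
    notes <- "information matrix singular; standard errors unavailable"
  } else {
    v <- diag(inv)
    bad <- v <= 0
    se[!bad] <- sqrt(v[!bad])
    if (any(bad)) {
      notes <- paste0("non-positive information-inverse diagonal for: ",
                      paste(spec$free[bad], collapse = ", "))
    }
  }
  list(se = se, notes = notes)
}

#' Evaluate the ML discrepancy and its gradient at a point
#'
#' Mostly a diagnostic / testing surface over the compiled backend.
#'
#' @param spec An `mtmm_model`.
#' @param point Named parameter vector.
#' @param S Sample covariance matrix.
#' @return List with `pd` (is the implied covariance positive definite),
#'   `fml` and the named `gradient`.
#' @export
fml_eval <- function(spec, point, S) {
  point <- validate_point(spec, point)
  maps <- param_maps(spec)
  res <- fml_eval_cpp(unname(point), maps$L, maps$P, maps$Th, S, gradient = TRUE)
  res$gradient <- setNames(as.numeric(res$gradient), spec$free)
  res
}
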