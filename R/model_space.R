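#' Model families for the single-trait, three-method design
#'
#' Four confirmatory factor structures for nine observed variables
#' (three methods, three indicators per method), each with one trait factor
#' and up to three method factors:
#'
#' * `"UM_constrained"` — uncorrelated method factors with loadings
#'   constrained equal across methods for the same indicator (the structure
#'   implied by interchangeable methods): 3 distinct trait loadings, 3
#'   distinct method loadings.
#' * `"UM_unconstrained"` — uncorrelated method factors, all 18 loadings
#'   free.
#' * `"CMm1"` — the correlated methods-minus-one structure for structurally
#'   different methods: no method factor for a reference method, method
#'   factors for the remaining two methods free to correlate.
#' * `"CM"` — method factors for all three methods with all three
#'   method-factor correlations free.
#'
#' All factor variances are fixed to 1 for identification, trait--method
#' covariances are fixed to 0, the error covariance matrix is diagonal with
#' one free variance per observed variable, and no mean structure is used.
#'
#' @name model-families
#' @keywords internal
NULL

MODEL_FAMILIES <- c("UM_constrained", "UM_unconstrained", "CMm1", "CM")

#' Build a model specification
#'
#' Constructs the loading pattern, equality-constraint groups (encoded by
#' shared parameter labels), and latent covariance structure of one of the
#' four model families. Parameter labels follow the scheme `lam_i_m`,
#' `gam_i_m`, `theta_i_m` and `rho_m_m'`; in the constrained model the
#' method index is dropped from the loading labels (`lam_i`, `gam_i`) so
#' that the equality constraint across methods is carried by label sharing.
#'
#' @param family One of `"UM_constrained"`, `"UM_unconstrained"`, `"CMm1"`,
#'   `"CM"`.
#' @param reference_method Integer in 1..3; only used (and required) for the
#'   `"CMm1"` family, whose reference method carries no method factor.
#'   Defaults to 1.
#' @return An object of class `mtmm_model`: a list with the family, the
#'   per-variable label vectors for trait loadings, method loadings and
#'   error variances, the method-factor correlation labels, and the
#'   canonical free-parameter vector.
#' @examples
#' spec <- build_model("CMm1")
#' count_free_parameters(spec)
#' @export
build_model <- function(family, reference_method = if (family == "CMm1") 1L else NULL) {
  family <- match.arg(family, MODEL_FAMILIES)
  if (family == "CMm1") {
    if (is.null(reference_method) || length(reference_method) != 1L ||
        !reference_method %in% 1:3) {
      stop("'reference_method' must be a single integer in 1..3 for the CMm1 family")
    }
    reference_method <- as.integer(reference_method)
  } else if (!is.null(reference_method)) {
    stop("'reference_method' is only meaningful for the CMm1 family")
  }

  lay <- variable_layout()
  theta <- paste0("theta_", lay$indicator, "_", lay$method)

  if (family == "UM_constrained") {
    lambda <- paste0("lam_", lay$indicator)
    gamma <- paste0("gam_", lay$indicator)
  } else {
    lambda <- paste0("lam_", lay$indicator, "_", lay$method)
    gamma <- paste0("gam_", lay$indicator, "_", lay$method)
  }
  if (family == "CMm1") {
    gamma[lay$method == reference_method] <- NA_character_
  }

  # method-factor correlations: labels for free pairs, NA = fixed at 0
  rho <- matrix(NA_character_, 3, 3, dimnames = list(paste0("M", 1:3), paste0("M", 1:3)))
  pairs <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  if (family == "CM") {
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      rho[a, b] <- rho[b, a] <- paste0("rho_", a, "_", b)
    }
  } else if (family == "CMm1") {
    nonref <- setdiff(1:3, reference_method)
    a <- min(nonref); b <- max(nonref)
    rho[a, b] <- rho[b, a] <- paste0("rho_", a, "_", b)
  }

  free <- c(
    unique(lambda),
    unique(gamma[!is.na(gamma)]),
    theta,
    unique(rho[upper.tri(rho)][!is.na(rho[upper.tri(rho)])])
  )

  structure(
    list(
      family = family,
      n_methods = 3L,
      n_indicators_per_method = 3L,
      reference_method = if (family == "CMm1") reference_method else NULL,
      lambda = lambda,
      gamma = gamma,
      theta = theta,
      rho = rho,
      free = free
    ),
    class = "mtmm_model"
  )
}

#' @export
print.mtmm_model <- function(x, ...) {
  cat("<mtmm_model> family:", x$family)
  if (!is.null(x$reference_method)) cat(" (reference method", x$reference_method, ")")
  cat("\n  9 observed variables, 3 methods x 3 indicators\n")
  cat("  free parameters:", count_free_parameters(x), "\n")
  invisible(x)
}

#' Number of distinct free parameters
#'
#' Counts distinct free parameter labels (loadings, error variances and free
#' method-factor correlations; there is no mean structure). The four
#' families use 15 (`UM_constrained`), 25 (`CMm1`), 27 (`UM_unconstrained`)
#' and 30 (`CM`) parameters.
#'
#' @param spec An `mtmm_model`.
#' @return Integer count of free parameters.
#' @export
count_free_parameters <- function(spec) {
  stopifnot(inherits(spec, "mtmm_model"))
  length(spec$free)
}

validate_point <- function(spec, point) {
  if (is.list(point)) point <- unlist(point)
  if (is.null(names(point))) stop("a parameter point must be a named numeric vector")
  missing <- setdiff(spec$free, names(point))
  if (length(missing)) {
    stop("parameter point incomplete; missing: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(point), spec$free)
  if (length(extra)) {
    stop("parameter point has labels that are not free in this model: ",
         paste(extra, collapse = ", "))
  }
  point[spec$free]
}

# Loading, latent-covariance and error matrices at a parameter point.
model_matrices <- function(spec, point) {
  point <- validate_point(spec, point)
  Lambda <- matrix(0, 9, 4, dimnames = list(variable_names(), c("T", paste0("M", 1:3))))
  lay <- variable_layout()
  Lambda[, 1] <- point[spec$lambda]
  for (k in 1:9) {
    if (!is.na(spec$gamma[k])) Lambda[k, 1L + lay$method[k]] <- point[spec$gamma[k]]
  }
  Psi <- diag(4)
  dimnames(Psi) <- list(colnames(Lambda), colnames(Lambda))
  for (a in 1:2) for (b in (a + 1):3) {
    if (!is.na(spec$rho[a, b])) Psi[a + 1, b + 1] <- Psi[b + 1, a + 1] <- point[spec$rho[a, b]]
  }
  Theta <- point[spec$theta]
  names(Theta) <- variable_names()
  list(Lambda = Lambda, Psi = Psi, Theta = Theta)
}

#' Model-implied covariance matrix
#'
#' Evaluates the factor-analytic decomposition
#' \eqn{\Sigma = \Lambda \Psi \Lambda^\top + \Theta} at a complete parameter
#' point: the trait--method loading matrix times the latent covariance
#' matrix (unit factor variances, free method-factor correlations where the
#' family allows them) plus the diagonal error covariance matrix.
#'
#' @param spec An `mtmm_model`.
#' @param point Named numeric vector with one value per free label of
#'   `spec`.
#' @return Symmetric 9x9 matrix in the canonical variable order.
#' @export
implied_covariance <- function(spec, point) {
  m <- model_matrices(spec, point)
  sigma <- m$Lambda %*% m$Psi %*% t(m$Lambda)
  diag(sigma) <- diag(sigma) + m$Theta
  dimnames(sigma) <- list(variable_names(), variable_names())
  sigma
}

# Integer parameter-index maps consumed by the compiled fit loop.
# Entries are 1-based indices into the free-parameter vector; 0 = fixed at 0.
param_maps <- function(spec) {
  idx <- setNames(seq_along(spec$free), spec$free)
  lay <- variable_layout()
  L <- matrix(0L, 9, 4)
  L[, 1] <- idx[spec$lambda]
  for (k in 1:9) {
    if (!is.na(spec$gamma[k])) L[k, 1L + lay$method[k]] <- idx[[spec$gamma[k]]]
  }
  P <- matrix(0L, 4, 4)
  for (a in 1:2) for (b in (a + 1):3) {
    if (!is.na(spec$rho[a, b])) P[a + 1, b + 1] <- P[b + 1, a + 1] <- idx[[spec$rho[a, b]]]
  }
  Th <- unname(idx[spec$theta])
  list(L = L, P = P, Th = Th)
}

#' Serialize / restore a model specification
#'
#' A model spec is fully determined by its family and (for `CMm1`) the
#' reference method; the JSON form records both plus the label layout so a
#' manifest is self-describing.
#'
#' @param spec An `mtmm_model`.
#' @param txt JSON string produced by `model_to_json()`.
#' @return `model_to_json()` returns a JSON string; `model_from_json()`
#'   returns an `mtmm_model`.
#' @export
model_to_json <- function(spec) {
  stopifnot(inherits(spec, "mtmm_model"))
  jsonlite::toJSON(
    list(
      family = spec$family,
      reference_method = spec$reference_method,
      lambda = spec$lambda,
      gamma = spec$gamma,
      theta = spec$theta,
      free = spec$free
    ),
    auto_unbox = TRUE, null = "null"
  )
}

#' @rdname model_to_json
#' @export
model_from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt)
  build_model(obj$family, reference_method = obj$reference_method)
}
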