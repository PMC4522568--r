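# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Define one cell of the simulation design grid
#'
#' A population cell fixes the data-generating family, the sample size, the
#' consistency level (share of true-score variance due to the trait), the
#' target indicator reliability, and — for the methods-minus-one family —
#' the correlation between the two non-reference method factors. Trait,
#' method-factor and indicator variances are all 1.
#'
#' @param population_family `"UM_constrained"` (interchangeable methods) or
#'   `"CMm1"` (structurally different methods, method 1 as reference).
#' @param sample_size Number of observations per replication (the study
#'   grid uses 250 and 1000).
#' @param consistency Consistency level in (0, 1]; 0 is rejected because a
#'   zero trait loading leaves the trait factor unidentified.
#' @param reliability_base Target reliability in (0, 1); indicator
#'   reliabilities are jittered around this value (see
#'   [jitter_reliabilities()]).
#' @param method_correlation Correlation between the non-reference method
#'   factors; must be 0 for `UM_constrained` populations.
#' @param jitter_seed Integer seed controlling the reliability jitter draws.
#' @return An object of class `mtmm_cell`.
#' @export
population_cell <- function(population_family, sample_size, consistency,
                            reliability_base, method_correlation = 0,
                            jitter_seed = 1L) {
  population_family <- match.arg(population_family, c("UM_constrained", "CMm1"))
  stopifnot(sample_size > 9, length(consistency) == 1L, length(reliability_base) == 1L)
  if (consistency <= 0 || consistency > 1) {
    stop("'consistency' must be in (0, 1]: a zero trait loading leaves the trait unidentified")
  }
  if (reliability_base <= 0 || reliability_base >= 1) {
    stop("'reliability_base' must be in (0, 1)")
  }
  if (population_family == "UM_constrained" && method_correlation != 0) {
    stop("method-factor correlations are 0 by definition in UM_constrained populations")
  }
  if (abs(method_correlation) >= 1) stop("'method_correlation' must be in (-1, 1)")
  structure(
    list(
      population_family = population_family,
      sample_size = as.integer(sample_size),
      consistency = consistency,
      reliability_base = reliability_base,
      method_correlation = method_correlation,
      jitter_seed = as.integer(jitter_seed)
    ),
    class = "mtmm_cell"
  )
}

#' @export
print.mtmm_cell <- function(x, ...) {
  cat(sprintf(
    "<mtmm_cell> %s population: N = %d, con = %.2f, rel = %.2f, corr(M2,M3) = %.2f\n",
    x$population_family, x$sample_size, x$consistency, x$reliability_base,
    x$method_correlation
  ))
  invisible(x)
}

#' Jittered indicator reliabilities
#'
#' Draws per-indicator reliabilities `base + (b - 0.5) * 0.05` with
#' `b ~ Beta(3, 3)`, so each value lies within 0.025 of the base level and
#' the expected value equals the base. The jitter keeps indicators from
#' being exactly parallel, which would be an unrealistically clean
#' population.
#'
#' @param reliability_base Base reliability in (0, 1).
#' @param jitter_seed Integer seed; the draws are reproducible from it.
#' @param n Number of draws (9 for method-specific reliabilities, 3 when
#'   the same value is reused across methods).
#' @return Numeric vector of length `n`.
#' @export
jitter_reliabilities <- function(reliability_base, jitter_seed, n = 9L) {
  if (reliability_base <= 0 || reliability_base >= 1) {
    stop("'reliability_base' must be in (0, 1)")
  }
  b <- with_seed(jitter_seed, rbeta(n, 3, 3))
  reliability_base + (b - 0.5) * 0.05
}

#' Derive population parameter values from design levels
#'
#' Inverts the consistency and reliability definitions under unit trait,
#' method and indicator variances:
#' \eqn{con = \lambda^2 / (\lambda^2 + \gamma^2)} and
#' \eqn{rel = \lambda^2 + \gamma^2}, giving
#' \eqn{\lambda = \sqrt{rel \cdot con}}, \eqn{\gamma = \sqrt{rel (1 - con)}}
#' and error variance \eqn{\theta = 1 - rel} (positive roots throughout).
#' For `CMm1` populations the reference-method indicators carry no method
#' factor, so all their true-score variance is trait variance:
#' \eqn{\lambda = \sqrt{rel}}, \eqn{\gamma = 0}. For `UM_constrained`
#' populations the shared loading labels require reliabilities that are
#' equal across methods for the same indicator.
#'
#' @param cell An `mtmm_cell`.
#' @param reliabilities Numeric vector of 9 reliabilities in canonical
#'   variable order (for `UM_constrained`, equal across methods within
#'   indicator).
#' @return Named parameter vector for the population model of the cell's
#'   family (a complete point for `build_model(cell$population_family)`).
#' @export
derive_population_point <- function(cell, reliabilities) {
  stopifnot(inherits(cell, "mtmm_cell"), length(reliabilities) == 9L)
  if (any(reliabilities <= 0 | reliabilities >= 1)) {
    stop("reliabilities must lie in (0, 1)")
  }
  con <- cell$consistency
  lay <- variable_layout()
  spec <- build_model(cell$population_family,
                      reference_method = if (cell$population_family == "CMm1") 1L else NULL)

  point <- numeric(0)
  if (cell$population_family == "UM_constrained") {
    rel_i <- reliabilities[1:3]
    for (m in 2:3) {
      if (any(abs(reliabilities[lay$method == m] - rel_i) > 1e-12)) {
        stop("UM_constrained populations share loadings across methods; ",
             "reliabilities must be equal across methods within indicator")
      }
    }
    point[paste0("lam_", 1:3)] <- sqrt(rel_i * con)
    point[paste0("gam_", 1:3)] <- sqrt(rel_i * (1 - con))
    point[spec$theta] <- 1 - reliabilities
  } else {
    ref <- spec$reference_method
    for (k in 1:9) {
      i <- lay$indicator[k]; m <- lay$method[k]; rel <- reliabilities[k]
      if (m == ref) {
        point[paste0("lam_", i, "_", m)] <- sqrt(rel)
      } else {
        point[paste0("lam_", i, "_", m)] <- sqrt(rel * con)
        point[paste0("gam_", i, "_", m)] <- sqrt(rel * (1 - con))
      }
    }
    point[spec$theta] <- 1 - reliabilities
    point[spec$rho[2, 3]] <- cell$method_correlation
  }
  point[spec$free]
}

#' Assemble the fixed population for a design cell
#'
#' Draws the reliability jitter once (three draws reused across methods for
#' `UM_constrained`, nine independent draws for `CMm1`), derives the
#' population parameter point, and evaluates the population covariance
#' matrix. The jitter is drawn once per cell and held fixed across the
#' cell's replications, so each cell has a single population covariance.
#'
#' @param cell An `mtmm_cell`.
#' @return An object of class `mtmm_population`: the cell, the jittered
#'   reliabilities (length 9), the population parameter point, the
#'   population model spec, and the 9x9 population covariance matrix.
#' @export
build_population <- function(cell) {
  stopifnot(inherits(cell, "mtmm_cell"))
  if (cell$population_family == "UM_constrained") {
    rel <- rep(jitter_reliabilities(cell$reliability_base, cell$jitter_seed, n = 3L), times = 3)
  } else {
    rel <- jitter_reliabilities(cell$reliability_base, cell$jitter_seed, n = 9L)
  }
  spec <- build_model(cell$population_family,
                      reference_method = if (cell$population_family == "CMm1") 1L else NULL)
  point <- derive_population_point(cell, rel)
  structure(
    list(
      cell = cell,
      reliabilities = rel,
      point = point,
      spec = spec,
      sigma = implied_covariance(spec, point)
    ),
    class = "mtmm_population"
  )
}

#' Draw a multivariate-normal sample from a population covariance
#'
#' Rows are i.i.d. mean-zero multivariate normal with the given covariance;
#' the sample covariance matrix uses the `N - 1` divisor, which pairs with
#' the Wishart chi-square convention used downstream.
#'
#' @param sigma_pop Symmetric positive-definite 9x9 covariance matrix.
#' @param n Sample size (> 9).
#' @param seed Integer seed; the draw is reproducible from it.
#' @return List with `data` (an `n` x 9 matrix with canonical column
#'   names) and `S` (the 9x9 sample covariance matrix).
#' @export
sample_dataset <- function(sigma_pop, n, seed) {
  p <- nrow(sigma_pop)
  stopifnot(is.matrix(sigma_pop), ncol(sigma_pop) == p, n > p)
  if (max(abs(sigma_pop - t(sigma_pop))) > 1e-10) stop("'sigma_pop' must be symmetric")
  ok <- tryCatch({ chol(sigma_pop); TRUE }, error = function(e) FALSE)
  if (!ok) stop("'sigma_pop' is not positive definite")
  x <- with_seed(seed, MASS::mvrnorm(n, mu = rep(0, p), Sigma = sigma_pop))
  colnames(x) <- if (p == 9) variable_names() else colnames(sigma_pop)
  list(data = x, S = cov(x))
}

#' Write a population manifest
#'
#' Records the cell levels, jittered reliabilities, derived parameter point
#' and jitter seed as JSON for reproducibility.
#'
#' @param population An `mtmm_population`.
#' @param path File path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
population_manifest <- function(population, path = NULL) {
  stopifnot(inherits(population, "mtmm_population"))
  obj <- list(
    cell = unclass(population$cell),
    reliabilities = population$reliabilities,
    point = as.list(population$point),
    family = population$spec$family
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
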