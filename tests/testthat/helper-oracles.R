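# Independent oracle for the implied covariance: expands the two-factor
# linear model Y_im = lambda_im T + gamma_im M_m + eps_im entry by entry,
# without the Lambda Psi Lambda' matrix algebra used by the package.
oracle_sigma <- function(lam, gam, theta, rho = diag(3)) {
  method_of <- rep(1:3, each = 3)
  out <- matrix(0, 9, 9)
  for (k in 1:9) for (l in 1:9) {
    mk <- method_of[k]; ml <- method_of[l]
    v <- lam[k] * lam[l] + gam[k] * gam[l] * rho[mk, ml]
    if (k == l) v <- v + theta[k]
    out[k, l] <- v
  }
  out
}

# Extract per-variable lambda/gamma/theta vectors and the 3x3 method-factor
# correlation matrix from a spec + point, by plain label lookup.
point_vectors <- function(spec, point) {
  lam <- unname(point[spec$lambda])
  gam <- ifelse(is.na(spec$gamma), 0, point[spec$gamma])
  theta <- unname(point[spec$theta])
  rho <- diag(3)
  for (a in 1:2) for (b in (a + 1):3) {
    if (!is.na(spec$rho[a, b])) rho[a, b] <- rho[b, a] <- point[[spec$rho[a, b]]]
  }
  list(lam = lam, gam = unname(gam), theta = theta, rho = rho)
}

# A random admissible parameter point for a family (loadings and error
# variances well inside the PD cone, correlations mild).
random_point <- function(spec, seed) {
  set.seed(seed)
  point <- setNames(numeric(length(spec$free)), spec$free)
  for (lbl in spec$free) {
    point[lbl] <- if (startsWith(lbl, "lam")) runif(1, 0.3, 0.8)
    else if (startsWith(lbl, "gam")) runif(1, 0.2, 0.6)
    else if (startsWith(lbl, "theta")) runif(1, 0.2, 0.6)
    else runif(1, -0.5, 0.5)
  }
  point
}

all_families <- function() {
  lapply(c("UM_constrained", "CMm1", "UM_unconstrained", "CM"), function(f) {
    build_model(f, reference_method = if (f == "CMm1") 1L else NULL)
  })
}

mid_grid_cell <- function(family = "UM_constrained", N = 250L, rho = 0, seed = 11L) {
  population_cell(family, N, consistency = 0.5, reliability_base = 0.7,
                  method_correlation = rho, jitter_seed = seed)
}

# Fabricated converged fit object for testing significance rules in
# isolation from the optimizer.
fake_fit <- function(spec, point, se) {
  structure(
    list(point = point, standard_errors = se, converged = TRUE,
         iterations = 1L, discrepancy = 0, theta_npd = FALSE,
         psi_npd = FALSE, log_notes = character(0), spec = spec,
         S = diag(9), N = 250L),
    class = "mtmm_fit"
  )
}
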