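test_that("analytic gradient matches central finite differences", {
  for (spec in all_families()) {
    pop <- build_population(population_cell(
      "CMm1", 250, 0.5, 0.7, 0.5, jitter_seed = 21))
    S <- pop$sigma
    p <- random_point(spec, seed = 77)
    g <- fml_eval(spec, p, S)$gradient
    h <- 1e-6
    for (lbl in sample(spec$free, 6)) {
      up <- p; up[lbl] <- up[lbl] + h
      dn <- p; dn[lbl] <- dn[lbl] - h
      num <- (fml_eval(spec, up, S)$fml - fml_eval(spec, dn, S)$fml) / (2 * h)
      expect_equal(unname(g[lbl]), num, tolerance = 1e-5)
    }
  }
})

test_that("discrepancy is nonnegative and zero only at equality", {
  spec <- build_model("CM")
  for (s in 1:5) {
    p <- random_point(spec, seed = 400 + s)
    q <- random_point(spec, seed = 500 + s)
    sig_p <- implied_covariance(spec, p)
    sig_q <- implied_covariance(spec, q)
    expect_gt(fml_eval(spec, p, sig_q)$fml, 0)
    expect_lt(abs(fml_eval(spec, p, sig_p)$fml), 1e-10)
  }
})

test_that("fitting the generating family to its population covariance is exact", {
  pops <- list(
    build_population(population_cell("UM_constrained", 250, 0.5, 0.7, 0, 31)),
    build_population(population_cell("CMm1", 250, 0.5, 0.7, 0.5, 31))
  )
  for (pop in pops) {
    fit <- fit_ml(pop$spec, pop$sigma, 1000)
    expect_true(fit$converged)
    expect_lte(fit$discrepancy, 1e-9)
    expect_lt(max(abs(fit$point - pop$point[names(fit$point)])), 1e-5)
    expect_false(fit$theta_npd)
    expect_false(fit$psi_npd)
    # fixed-point identity: the fitted implied covariance used as data
    # reproduces a zero discrepancy
    refit <- fit_ml(pop$spec, implied_covariance(pop$spec, fit$point), 1000, se = FALSE)
    expect_lte(refit$discrepancy, 1e-9)
  }
})

test_that("the unconstrained model recovers method-wise equal loadings from
           constrained populations", {
  pop <- build_population(population_cell("UM_constrained", 250, 0.5, 0.7, 0, 13))
  umu <- build_model("UM_unconstrained")
  fit <- fit_ml(umu, pop$sigma, 1000, se = FALSE)
  expect_lte(fit$discrepancy, 1e-8)
  lam <- abs(fit$point[umu$lambda])
  expect_lt(max(abs(lam[1:3] - lam[4:6])), 1e-3)
  expect_lt(max(abs(lam[1:3] - lam[7:9])), 1e-3)
})

test_that("nested families order the minimized discrepancy", {
  pop <- build_population(population_cell("CMm1", 250, 0.6, 0.7, 0.5, 8))
  specs <- all_families()
  names(specs) <- vapply(specs, `[[`, "", "family")
  # frozen seeds where all four fits converge on the drawn sample
  for (seed in c(101, 104, 105)) {
    ds <- sample_dataset(pop$sigma, 1000, seed = seed)
    fits <- lapply(specs, fit_ml, S = ds$S, N = 1000, se = FALSE)
    conv <- vapply(fits, `[[`, logical(1), "converged")
    f <- vapply(fits, `[[`, numeric(1), "discrepancy")
    if (conv[["CM"]] && conv[["UM_unconstrained"]] && conv[["UM_constrained"]]) {
      expect_lte(f[["CM"]], f[["UM_unconstrained"]] + 1e-6)
      expect_lte(f[["UM_unconstrained"]], f[["UM_constrained"]] + 1e-6)
    }
    if (conv[["CM"]] && conv[["CMm1"]]) {
      expect_lte(f[["CM"]], f[["CMm1"]] + 1e-6)
    }
    expect_true(conv[["UM_constrained"]] && conv[["CMm1"]])
  }
})

test_that("standard errors are positive, shrink like 1/sqrt(N), and flag
           population loadings as significant", {
  pop <- build_population(mid_grid_cell(seed = 23))
  se_small <- list(); se_big <- list()
  z_ok <- 0; n_fits <- 0
  for (r in 1:60) {
    ds1 <- sample_dataset(pop$sigma, 250, seed = 600 + r)
    ds2 <- sample_dataset(pop$sigma, 1000, seed = 900 + r)
    f1 <- fit_ml(pop$spec, ds1$S, 250)
    f2 <- fit_ml(pop$spec, ds2$S, 1000)
    if (f1$converged) {
      expect_true(all(f1$standard_errors > 0, na.rm = TRUE))
      se_small[[length(se_small) + 1]] <- f1$standard_errors
    }
    if (f2$converged) {
      se_big[[length(se_big) + 1]] <- f2$standard_errors
      z <- abs(f2$point / f2$standard_errors)
      lamgam <- c(pop$spec$lambda, pop$spec$gamma)
      n_fits <- n_fits + 1
      if (all(z[unique(lamgam)] > 1.96, na.rm = TRUE)) z_ok <- z_ok + 1
    }
  }
  ratio <- mean(colMeans(do.call(rbind, se_big))) /
    mean(colMeans(do.call(rbind, se_small)))
  expect_gt(ratio, 0.5 * 0.8)
  expect_lt(ratio, 0.5 * 1.2)
  # at N = 1000, rel 0.7, con 0.5 every loading is comfortably significant
  expect_gte(z_ok / n_fits, 0.99)
})

test_that("non-positive-definiteness detection covers closed-form cases", {
  expect_false(check_npd(diag(2)))
  expect_true(check_npd(diag(c(1, -0.01))))
  m <- matrix(c(1, 1.2, 1.2, 1), 2, 2)  # eigenvalues 1 +/- 1.2
  expect_true(check_npd(m))
  expect_false(check_npd(matrix(c(1, 0.9, 0.9, 1), 2, 2)))
  expect_error(check_npd(matrix(1, 2, 3)))
})

test_that("fits are deterministic in all inputs", {
  pop <- build_population(mid_grid_cell(seed = 2))
  ds <- sample_dataset(pop$sigma, 250, seed = 5)
  f1 <- fit_ml(pop$spec, ds$S, 250)
  f2 <- fit_ml(pop$spec, ds$S, 250)
  expect_identical(f1$point, f2$point)
  expect_identical(f1$iterations, f2$iterations)
  expect_identical(f1$standard_errors, f2$standard_errors)
})

test_that("estimator rejects degenerate inputs", {
  spec <- build_model("UM_constrained")
  expect_error(fit_ml(spec, diag(9), 5), "exceed")
  bad <- diag(9); bad[1, 1] <- -1
  expect_error(fit_ml(spec, bad, 250), "positive definite")
  asym <- diag(9); asym[1, 2] <- 0.5
  expect_error(fit_ml(spec, asym, 250), "symmetric")
})
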