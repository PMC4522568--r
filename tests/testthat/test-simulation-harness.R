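test_that("the design grid has the documented dimensions", {
  cells <- population_grid()
  expect_equal(nrow(cells), 216L)
  expect_equal(sum(cells$population_family == "UM_constrained"), 54L)
  expect_equal(sum(cells$population_family == "CMm1"), 162L)
  expect_equal(cells$cell_id, 1:216)
  expect_true(all(cells$rho[cells$population_family == "UM_constrained"] == 0))

  grid <- build_grid()
  expect_equal(nrow(grid), 864L)
  expect_equal(as.integer(table(grid$fitted)), rep(216L, 4))
  # full profile: 1000 replications per grid entry
  expect_equal(nrow(grid) * 1000, 864000)
  # ordering is deterministic
  expect_identical(grid, build_grid())
})

test_that("the seed stream is deterministic, 31-bit, and collision-averse", {
  expect_identical(seed_stream(1, 5, 10), seed_stream(1, 5, 10))
  s <- vapply(0:500, function(r) seed_stream(1, 7, r), integer(1))
  expect_true(all(s >= 0 & s < 2^31))
  expect_equal(length(unique(s)), 501L)
  expect_false(seed_stream(1, 7, 1) == seed_stream(2, 7, 1))
  expect_false(seed_stream(1, 7, 1) == seed_stream(1, 8, 1))
})

test_that("cell runs aggregate outcomes with the documented denominators", {
  cells <- population_grid()
  row <- cells[cells$population_family == "UM_constrained" & cells$N == 250 &
                 cells$con == 0.5 & cells$rel == 0.7, ]
  out <- run_cell(row, fitted_families = c("UM_constrained", "CM"),
                  n_replications = 8, master_seed = 42)
  s <- out$summary
  expect_equal(nrow(s), 2L)
  expect_equal(s$requested, c(8L, 8L))
  expect_equal(s$pct_convergence, 100 * s$converged / s$requested)
  expect_equal(s$pct_theta_npd, 100 * s$n_theta_npd / s$requested)
  expect_equal(s$pct_psi_npd, 100 * s$n_psi_npd / s$requested)
  # collapse is undefined for the trait-only-reference factor set of a CMm1
  # fit but defined for all three factors of the other families
  expect_false(any(is.na(s$pct_collapse_M1[s$fitted == "UM_constrained"])))
  # determinism from the master seed
  out2 <- run_cell(row, fitted_families = c("UM_constrained", "CM"),
                   n_replications = 8, master_seed = 42)
  expect_identical(out$summary, out2$summary)
  expect_identical(out$sets, out2$sets)
})

test_that("pooled rate tables implement the outcome formulas", {
  base <- data.frame(
    cell_id = 1:2, population_family = "UM_constrained", N = 250, con = 0.5,
    rel = 0.7, rho = 0, fitted = "CM", requested = c(1000L, 1000L),
    converged = c(997L, 995L), pct_convergence = c(99.7, 99.5),
    n_theta_npd = c(5L, 0L), pct_theta_npd = c(0.5, 0),
    n_psi_npd = c(0L, 0L), pct_psi_npd = c(0, 0), master_seed = 1,
    stringsAsFactors = FALSE
  )
  t2 <- aggregate_table2(base)
  row <- t2[t2$fitted == "CM", ]
  expect_equal(row$total_replications, 2000L)
  expect_equal(row$n_nonconverged, 8L)
  expect_equal(row$pct_nonconvergence, 0.4)
  expect_equal(row$pct_theta_npd, 0.25)
  expect_equal(t2$population_family[nrow(t2)], "Total")
  expect_equal(t2$total_replications[nrow(t2)], 2000L)
  # all-converged summaries pool to zero non-convergence
  allconv <- base; allconv$converged <- allconv$requested
  expect_equal(aggregate_table2(allconv)$pct_nonconvergence, c(0, 0))
})

test_that("grid runs are reproducible and write their report files", {
  cells <- population_grid()[c(14, 100), ]
  run <- run_grid(cells, fitted_families = c("UM_constrained", "CMm1"),
                  n_replications = 5, master_seed = 7)
  run2 <- run_grid(cells[2:1, ], fitted_families = c("UM_constrained", "CMm1"),
                   n_replications = 5, master_seed = 7)
  # identical results regardless of cell scheduling order
  reord <- run2$summary[order(run2$summary$cell_id,
                              match(run2$summary$fitted, run$summary$fitted)), ]
  rownames(reord) <- NULL
  expect_equal(run$summary, reord)

  dir <- tempfile("mtmmrun")
  write_run_outputs(run, dir)
  expect_true(file.exists(file.path(dir, "table2.csv")))
  expect_true(file.exists(file.path(dir, "fit_rejection_rates.csv")))
  expect_true(file.exists(file.path(dir, "loading_significance.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  t2 <- utils::read.csv(file.path(dir, "table2.csv"))
  expect_true("pct_nonconvergence" %in% names(t2))
})

test_that("rejection and collapse tables pool cells correctly", {
  cells <- population_grid()
  sub <- cells[cells$population_family == "CMm1" & cells$N == 250 &
                 cells$rel == 0.7 & cells$con == 0.6, ]
  run <- run_grid(sub, fitted_families = "UM_unconstrained",
                  n_replications = 6, master_seed = 3)
  rej <- rejection_rates(run)
  expect_equal(sort(unique(rej$criterion)), c("cfi", "chi2", "rmsea", "srmr"))
  expect_true(all(rej$pct_rejected >= 0 & rej$pct_rejected <= 100))
  ct <- collapse_table(run)
  expect_true(all(ct$n_nonsig %in% 0:3))
  # within each group x set the distribution sums to the converged count
  grp <- ct[ct$rho == 0.2 & ct$set == 5, ]
  expect_equal(sum(grp$n_reps), run$summary$converged[run$summary$rho == 0.2])
})

test_that("the audit mode fits all four structures to a plain CSV", {
  pop <- build_population(population_cell("CMm1", 500, 0.5, 0.7, 0.5, 61))
  ds <- sample_dataset(pop$sigma, 500, seed = 8)
  path <- tempfile(fileext = ".csv")
  utils::write.table(ds$data, path, sep = ",", row.names = FALSE, col.names = FALSE)
  audit <- mtmm_audit(path)
  expect_equal(nrow(audit), 4L)
  expect_equal(audit$family,
               c("UM_constrained", "UM_unconstrained", "CMm1", "CM"))
  cm1 <- audit[audit$family == "CMm1", ]
  expect_true(cm1$converged)
  expect_equal(cm1$df, 20)
  expect_gt(cm1$p_value, 0.01)  # the generating structure fits its own data
  expect_error(mtmm_audit(ds$data[, 1:5]), "nine")
})
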