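#' Deterministic per-replication seed stream
#'
#' Derives a 31-bit seed from the master seed, the cell index in the full
#' design grid, and the replication index (0 is reserved for the cell's
#' reliability-jitter draw), by iterated multiplicative hashing that is
#' exact in double arithmetic. Identical inputs give identical seeds
#' regardless of scheduling order, so cells are parallelism-safe work
#' units.
#'
#' @param master_seed Integer master seed.
#' @param cell_id Cell index (1-based, stable over the full grid).
#' @param replication Replication index (0 = jitter draw).
#' @return Integer seed in `[0, 2^31 - 1)`.
#' @export
seed_stream <- function(master_seed, cell_id, replication) {
  m <- 2147483647
  x <- as.numeric(master_seed) %% m
  x <- (x * 69069 + as.numeric(cell_id) + 1) %% m
  x <- (x * 69069 + as.numeric(replication) + 1) %% m
  x <- (x * 69069 + 12345) %% m
  as.integer(x)
}

#' The population side of the design grid
#'
#' 216 population cells: 54 for the constrained uncorrelated-methods family
#' (2 sample sizes x 9 consistency levels x 3 reliability levels, method
#' correlation fixed 0) and 162 for the methods-minus-one family (the same
#' crossed with 3 method-factor correlation levels). Ordering is
#' deterministic: population family, then sample size, consistency,
#' reliability, correlation.
#'
#' @return Data frame with columns `cell_id`, `population_family`, `N`,
#'   `con`, `rel`, `rho`.
#' @export
population_grid <- function() {
  um <- expand.grid(rho = 0, rel = c(0.6, 0.7, 0.8),
                    con = (1:9) / 10, N = c(250L, 1000L),
                    KEEP.OUT.ATTRS = FALSE)
  um <- um[order(um$N, um$con, um$rel), c("N", "con", "rel", "rho")]
  um$population_family <- "UM_constrained"
  cm <- expand.grid(rho = c(0.2, 0.5, 0.8), rel = c(0.6, 0.7, 0.8),
                    con = (1:9) / 10, N = c(250L, 1000L),
                    KEEP.OUT.ATTRS = FALSE)
  cm <- cm[order(cm$N, cm$con, cm$rel, cm$rho), c("N", "con", "rel", "rho")]
  cm$population_family <- "CMm1"
  out <- rbind(um, cm)[, c("population_family", "N", "con", "rel", "rho")]
  out <- data.frame(cell_id = seq_len(nrow(out)), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' The full design grid
#'
#' Every population cell crossed with the four fitted families: 864
#' entries, each standing for one (population x fitted model) condition. At
#' the full profile of 1000 replications per cell this amounts to 864,000
#' model fits.
#'
#' @return Data frame with one row per (population cell, fitted family)
#'   pair, in deterministic order.
#' @export
build_grid <- function() {
  cells <- population_grid()
  out <- merge(cells, data.frame(fitted = MODEL_FAMILIES, stringsAsFactors = FALSE))
  out <- out[order(out$cell_id, match(out$fitted, MODEL_FAMILIES)), ]
  rownames(out) <- NULL
  out[, c("cell_id", "population_family", "N", "con", "rel", "rho", "fitted")]
}

cell_from_row <- function(row, jitter_seed) {
  population_cell(
    population_family = row$population_family,
    sample_size = row$N,
    consistency = row$con,
    reliability_base = row$rel,
    method_correlation = row$rho,
    jitter_seed = jitter_seed
  )
}

empty_fit_record <- function(note = "fit crashed") {
  list(converged = FALSE, iterations = NA_integer_, fml = NA_real_,
       theta_npd = NA, psi_npd = NA, rejections = NULL, profile = NULL,
       note = note)
}

#' Run one design cell
#'
#' Builds the cell's fixed population (reliability jitter drawn once from
#' the seed stream), then for each replication draws one dataset and fits
#' every requested family to that same dataset, so fitted families are
#' compared on identical data. Outcomes are aggregated into one summary row
#' per fitted family; a crashed fit is logged and counted as non-converged.
#'
#' Denominators follow the study's outcome definitions: convergence and
#' improper-solution percentages use requested replications; fit-index
#' rejection and collapse rates use converged fits by default
#' (switchable to requested).
#'
#' @param row One row of [population_grid()] (or a one-row data frame with
#'   the same columns).
#' @param fitted_families Character vector of families to fit.
#' @param n_replications Replications for this cell.
#' @param master_seed Integer master seed.
#' @param indices Compute fit indices and rejection rates (default `TRUE`).
#' @param collapse Compute standard errors, loading significance and
#'   collapse outcomes (default `TRUE`).
#' @param dialect Chi-square dialect passed to [compute_indices()].
#' @param rejection_denominator `"converged"` (default) or `"requested"`.
#' @return List with `summary` (one row per fitted family) and `sets`
#'   (long-format per-set non-significance distribution, when `collapse`).
#' @export
run_cell <- function(row, fitted_families = MODEL_FAMILIES, n_replications,
                     master_seed, indices = TRUE, collapse = TRUE,
                     dialect = "wishart",
                     rejection_denominator = c("converged", "requested")) {
  rejection_denominator <- match.arg(rejection_denominator)
  stopifnot(n_replications >= 1)
  if (is.data.frame(row)) row <- as.list(row[1, ])
  cell_id <- as.integer(row$cell_id)
  cell <- cell_from_row(row, jitter_seed = seed_stream(master_seed, cell_id, 0L))
  pop <- build_population(cell)
  specs <- lapply(fitted_families, function(f) {
    build_model(f, reference_method = if (f == "CMm1") 1L else NULL)
  })
  names(specs) <- fitted_families

  records <- lapply(fitted_families, function(f) vector("list", n_replications))
  names(records) <- fitted_families

  for (r in seq_len(n_replications)) {
    ds <- sample_dataset(pop$sigma, cell$sample_size, seed = seed_stream(master_seed, cell_id, r))
    for (f in fitted_families) {
      rec <- tryCatch({
        fit <- fit_ml(specs[[f]], ds$S, cell$sample_size, se = collapse)
        out <- list(converged = fit$converged, iterations = fit$iterations,
                    fml = fit$discrepancy, theta_npd = fit$theta_npd,
                    psi_npd = fit$psi_npd, rejections = NULL, profile = NULL,
                    note = NULL)
        if (fit$converged && indices) {
          out$rejections <- classify_fit(compute_indices(fit, dialect = dialect))
        }
        if (fit$converged && collapse) {
          out$profile <- significance_profile(fit)
        }
        out
      }, error = function(e) empty_fit_record(conditionMessage(e)))
      records[[f]][[r]] <- rec
    }
  }

  summaries <- list()
  sets <- list()
  for (f in fitted_families) {
    recs <- records[[f]]
    conv <- vapply(recs, function(x) isTRUE(x$converged), logical(1))
    n_conv <- sum(conv)
    n_theta <- sum(vapply(recs, function(x) isTRUE(x$theta_npd), logical(1)))
    n_psi <- sum(vapply(recs, function(x) isTRUE(x$psi_npd), logical(1)))
    srow <- data.frame(
      cell_id = cell_id, population_family = row$population_family,
      N = row$N, con = row$con, rel = row$rel, rho = row$rho, fitted = f,
      requested = n_replications, converged = n_conv,
      pct_convergence = 100 * n_conv / n_replications,
      n_theta_npd = n_theta, pct_theta_npd = 100 * n_theta / n_replications,
      n_psi_npd = n_psi, pct_psi_npd = 100 * n_psi / n_replications,
      master_seed = master_seed, stringsAsFactors = FALSE
    )
    if (indices) {
      denom <- if (rejection_denominator == "converged") max(n_conv, 1L) else n_replications
      for (crit in c("reject_chi2", "reject_rmsea", "reject_cfi", "reject_srmr")) {
        n_rej <- sum(vapply(recs, function(x) isTRUE(x$rejections[[crit]]), logical(1)))
        srow[[paste0("n_", crit)]] <- n_rej
        srow[[paste0("pct_", crit)]] <- 100 * n_rej / denom
      }
      srow$rejection_denominator <- rejection_denominator
      srow$n_eval <- n_conv
    }
    if (collapse) {
      eligible <- eligible_method_factors(specs[[f]])
      denom <- max(n_conv, 1L)
      any_collapse <- 0L
      for (m in 1:3) {
        key <- paste0("M", m)
        if (m %in% eligible) {
          n_col <- sum(vapply(recs, function(x) isTRUE(x$profile$collapse[[key]]), logical(1)))
          srow[[paste0("n_collapse_", key)]] <- n_col
          srow[[paste0("pct_collapse_", key)]] <- 100 * n_col / denom
        } else {
          srow[[paste0("n_collapse_", key)]] <- NA_integer_
          srow[[paste0("pct_collapse_", key)]] <- NA_real_
        }
      }
      n_any <- sum(vapply(recs, function(x) {
        isTRUE(any(x$profile$collapse))
      }, logical(1)))
      srow$n_collapse_any <- n_any
      srow$pct_collapse_any <- 100 * n_any / denom
      srow$collapse_denominator <- "converged"

      counts <- lapply(recs[conv], function(x) x$profile$counts)
      if (length(counts)) {
        tab <- expand.grid(set = 1:6, n_nonsig = 0:3, KEEP.OUT.ATTRS = FALSE)
        tab$n_reps <- mapply(function(s, k) {
          sum(vapply(counts, function(cc) !is.na(cc[s]) && cc[s] == k, logical(1)))
        }, tab$set, tab$n_nonsig)
        structural <- vapply(1:6, function(s) {
          all(vapply(counts, function(cc) is.na(cc[s]), logical(1)))
        }, logical(1))
        tab <- tab[!structural[tab$set], ]
        tab <- data.frame(cell_id = cell_id,
                          population_family = row$population_family,
                          N = row$N, con = row$con, rel = row$rel, rho = row$rho,
                          fitted = f, tab, converged = n_conv,
                          stringsAsFactors = FALSE)
        sets[[f]] <- tab
      }
    }
    summaries[[f]] <- srow
  }
  list(summary = do.call(rbind, summaries),
       sets = if (length(sets)) do.call(rbind, sets) else NULL)
}

#' Run a set of design cells
#'
#' Loops [run_cell()] over the rows of a population grid (the full 216-cell
#' grid by default, or any subset of its rows) and binds the per-cell
#' summaries. End-to-end deterministic from `master_seed` at fixed
#' configuration, independent of cell order.
#'
#' @param cells Data frame of population cells (rows of
#'   [population_grid()]).
#' @inheritParams run_cell
#' @return List of class `mtmm_run`: `summary`, `sets`, and a `manifest`
#'   recording the configuration.
#' @export
run_grid <- function(cells = population_grid(), fitted_families = MODEL_FAMILIES,
                     n_replications = 100L, master_seed = 1L, indices = TRUE,
                     collapse = TRUE, dialect = "wishart",
                     rejection_denominator = "converged") {
  res <- lapply(seq_len(nrow(cells)), function(j) {
    run_cell(cells[j, ], fitted_families = fitted_families,
             n_replications = n_replications, master_seed = master_seed,
             indices = indices, collapse = collapse, dialect = dialect,
             rejection_denominator = rejection_denominator)
  })
  summary <- do.call(rbind, lapply(res, `[[`, "summary"))
  rownames(summary) <- NULL
  sets <- do.call(rbind, lapply(res, `[[`, "sets"))
  if (!is.null(sets)) rownames(sets) <- NULL
  structure(
    list(
      summary = summary,
      sets = sets,
      manifest = list(
        master_seed = master_seed, n_replications = n_replications,
        fitted_families = fitted_families, dialect = dialect,
        rejection_denominator = rejection_denominator,
        n_cells = nrow(cells),
        package_version = as.character(utils::packageVersion("mtmmsim"))
      )
    ),
    class = "mtmm_run"
  )
}

#' Pool convergence and improper-solution rates
#'
#' Aggregates cell summaries by (population family x fitted family):
#' pooled problematic counts, pooled totals, and percentages to two
#' decimals, with a grand-total row per criterion. Weights are the
#' requested replications per cell.
#'
#' @param summary Cell-summary data frame (the `summary` element of an
#'   `mtmm_run`, or any row subset).
#' @return Data frame with columns `population_family`, `fitted`,
#'   `total_replications`, `n_nonconverged`, `pct_nonconvergence`,
#'   `n_theta_npd`, `pct_theta_npd`, `n_psi_npd`, `pct_psi_npd`, plus a
#'   `Total` row.
#' @export
aggregate_table2 <- function(summary) {
  if (inherits(summary, "mtmm_run")) summary <- summary$summary
  key <- interaction(summary$population_family, summary$fitted, drop = TRUE)
  rows <- lapply(split(summary, key), function(d) {
    total <- sum(d$requested)
    nonconv <- sum(d$requested - d$converged)
    data.frame(
      population_family = d$population_family[1], fitted = d$fitted[1],
      n_cells = length(unique(d$cell_id)), total_replications = total,
      n_nonconverged = nonconv,
      pct_nonconvergence = round(100 * nonconv / total, 2),
      n_theta_npd = sum(d$n_theta_npd),
      pct_theta_npd = round(100 * sum(d$n_theta_npd) / total, 2),
      n_psi_npd = sum(d$n_psi_npd),
      pct_psi_npd = round(100 * sum(d$n_psi_npd) / total, 2),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$population_family, match(out$fitted, MODEL_FAMILIES)), ]
  total <- sum(out$total_replications)
  out <- rbind(out, data.frame(
    population_family = "Total", fitted = "", n_cells = sum(out$n_cells),
    total_replications = total,
    n_nonconverged = sum(out$n_nonconverged),
    pct_nonconvergence = round(100 * sum(out$n_nonconverged) / total, 2),
    n_theta_npd = sum(out$n_theta_npd),
    pct_theta_npd = round(100 * sum(out$n_theta_npd) / total, 2),
    n_psi_npd = sum(out$n_psi_npd),
    pct_psi_npd = round(100 * sum(out$n_psi_npd) / total, 2),
    stringsAsFactors = FALSE
  ))
  rownames(out) <- NULL
  out
}

#' Pool fit-index rejection rates
#'
#' Aggregates per-criterion rejection counts over cells, by default per
#' (population family x fitted family x N x method correlation), pooling
#' consistency and reliability levels.
#'
#' @param summary Cell-summary data frame or `mtmm_run`.
#' @param by Grouping columns.
#' @return Long data frame with one row per group x criterion.
#' @export
rejection_rates <- function(summary,
                            by = c("population_family", "fitted", "N", "rho")) {
  if (inherits(summary, "mtmm_run")) summary <- summary$summary
  if (!"n_reject_chi2" %in% names(summary)) {
    stop("summary carries no rejection counts; run with indices = TRUE")
  }
  crits <- c("chi2", "rmsea", "cfi", "srmr")
  key <- interaction(summary[by], drop = TRUE)
  rows <- lapply(split(summary, key), function(d) {
    denom <- if (d$rejection_denominator[1] == "converged") sum(d$n_eval) else sum(d$requested)
    do.call(rbind, lapply(crits, function(cr) {
      n <- sum(d[[paste0("n_reject_", cr)]])
      cbind(d[1, by, drop = FALSE],
            data.frame(criterion = cr, n_rejected = n, n_evaluated = denom,
                       pct_rejected = if (denom > 0) 100 * n / denom else NA_real_,
                       stringsAsFactors = FALSE))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pool per-set non-significance distributions
#'
#' Aggregates the long-format set tables (distribution of 0--3
#' non-significant loadings per loading set) over reliability and sample
#' size, mirroring how the collapse results are reported per consistency
#' and correlation condition.
#'
#' @param sets The `sets` element of an `mtmm_run`.
#' @param by Grouping columns (besides `set` and `n_nonsig`).
#' @return Aggregated data frame with counts and within-group percentages.
#' @export
collapse_table <- function(sets, by = c("population_family", "fitted", "con", "rho")) {
  if (inherits(sets, "mtmm_run")) sets <- sets$sets
  if (is.null(sets)) stop("no set tables; run with collapse = TRUE")
  key <- interaction(sets[c(by, "set", "n_nonsig")], drop = TRUE)
  rows <- lapply(split(sets, key), function(d) {
    cbind(d[1, c(by, "set", "n_nonsig"), drop = FALSE],
          data.frame(n_reps = sum(d$n_reps), stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  grp <- interaction(out[c(by, "set")], drop = TRUE)
  out$pct <- unlist(lapply(split(out$n_reps, grp), function(v) 100 * v / max(sum(v), 1)))[order(order(grp))]
  out <- out[do.call(order, out[c(by, "set", "n_nonsig")]), ]
  rownames(out) <- NULL
  out
}

#' Audit a user dataset against all four model structures
#'
#' Reads a plain numeric table of nine indicator columns in the canonical
#' variable order (method-major: the three indicators of method 1, then
#' method 2, then method 3), fits all four families, and reports fit and
#' collapse diagnostics side by side.
#'
#' @param data A headerless CSV path, or an N x 9 numeric matrix / data
#'   frame.
#' @param dialect Chi-square dialect (see [compute_indices()]).
#' @return Data frame with one row per family: convergence, discrepancy,
#'   fit indices, rejection flags, improper-solution flags, and collapsed
#'   method factors.
#' @export
mtmm_audit <- function(data, dialect = "wishart") {
  if (is.character(data)) data <- read.csv(data, header = FALSE)
  data <- as.matrix(data)
  if (ncol(data) != 9) stop("expected nine indicator columns")
  storage.mode(data) <- "double"
  N <- nrow(data)
  S <- cov(data)
  rows <- lapply(MODEL_FAMILIES, function(f) {
    spec <- build_model(f, reference_method = if (f == "CMm1") 1L else NULL)
    fit <- fit_ml(spec, S, N)
    out <- data.frame(family = f, converged = fit$converged,
                      iterations = fit$iterations, fml = fit$discrepancy,
                      stringsAsFactors = FALSE)
    if (fit$converged) {
      ind <- compute_indices(fit, dialect = dialect)
      rej <- classify_fit(ind)
      out$chi_square <- ind$chi_square; out$df <- ind$df
      out$p_value <- ind$p_value; out$rmsea <- ind$rmsea
      out$cfi <- ind$cfi; out$srmr <- ind$srmr
      out$rejected_by <- paste(sub("reject_", "", names(rej)[rej]), collapse = ",")
      out$theta_npd <- fit$theta_npd; out$psi_npd <- fit$psi_npd
      col <- detect_collapse(fit)
      out$collapsed_factors <- paste(names(col)[col], collapse = ",")
    } else {
      out[c("chi_square", "df", "p_value", "rmsea", "cfi", "srmr")] <- NA_real_
      out$rejected_by <- NA_character_
      out$theta_npd <- NA; out$psi_npd <- NA
      out$collapsed_factors <- NA_character_
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write run outputs to a directory
#'
#' Writes `table2.csv` (pooled convergence / improper-solution rates),
#' `fit_rejection_rates.csv`, `loading_significance.csv` (per-set
#' distributions) and `manifest.json`.
#'
#' @param run An `mtmm_run`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  stopifnot(inherits(run, "mtmm_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(aggregate_table2(run), file.path(dir, "table2.csv"), row.names = FALSE)
  if ("n_reject_chi2" %in% names(run$summary)) {
    utils::write.csv(rejection_rates(run), file.path(dir, "fit_rejection_rates.csv"),
                     row.names = FALSE)
  }
  if (!is.null(run$sets)) {
    utils::write.csv(collapse_table(run), file.path(dir, "loading_significance.csv"),
                     row.names = FALSE)
  }
  writeLines(as.character(jsonlite::toJSON(run$manifest, auto_unbox = TRUE, digits = NA)),
             file.path(dir, "manifest.json"))
  invisible(dir)
}
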