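# Temperature-niche null model: rebuild presence-absence worlds in which
# occupancy is constrained only by each species' observed temperature range,
# then rerun the bioregionalization and regression to test whether
# province-diversity relationships could arise from temperature alone.

#' Species temperature ranges from occupied cells
#'
#' For each species, the minimum and maximum of mean annual sea-surface
#' temperature across the cells it occupies. Single-cell species get a
#' degenerate range `[t, t]`; ranges can never extend beyond the observed
#' cell temperatures.
#'
#' @param x cells x species count (or binary) matrix, or a `cell_matrix`
#'   (whose own `env` is then used).
#' @param env environmental table with `cell_id` and `sst_mean`; ignored
#'   when `x` is a `cell_matrix`.
#' @return data.frame: `species`, `t_min`, `t_max`, `n_cells`.
#' @export
temp_ranges <- function(x, env = NULL) {
  if (inherits(x, "cell_matrix")) {
    env <- x$env
    x <- x$x
  }
  sst <- env$sst_mean[match(rownames(x), env$cell_id)]
  if (anyNA(sst))
    abort("cells without a temperature value: ",
          paste(utils::head(rownames(x)[is.na(sst)], 5), collapse = ", "))
  pres <- x > 0
  occ <- colSums(pres)
  if (any(occ == 0))
    abort("species occupying no cell: ",
          paste(utils::head(colnames(x)[occ == 0], 5), collapse = ", "))
  t_min <- apply(pres, 2, function(p) min(sst[p]))
  t_max <- apply(pres, 2, function(p) max(sst[p]))
  data.frame(species = colnames(x), t_min = t_min, t_max = t_max,
             n_cells = occ, row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate one temperature-constrained null world
#'
#' Fills each cell with exactly as many species as the real matrix holds
#' there (the richness quota), drawn uniformly without replacement from the
#' cell's candidate pool: the species whose temperature range contains the
#' cell's mean annual SST (`mode = "point"`, the default, self-consistent
#' with ranges built from cell means) or overlaps the cell's
#' `mean +/- annual SD` interval (`mode = "interval"`). Geography enters
#' only through temperature. Deterministic given `seed`.
#'
#' @param x cells x species matrix or `cell_matrix`.
#' @param ranges output of [temp_ranges()].
#' @param env environmental table (ignored when `x` is a `cell_matrix`).
#' @param seed integer seed.
#' @param mode `"point"` or `"interval"` range-overlap rule.
#' @return binary cells x species matrix with the same dimnames as `x`; row
#'   sums equal the real per-cell richness exactly.
#' @export
simulate_null <- function(x, ranges, env = NULL, seed = 1L,
                          mode = c("point", "interval")) {
  mode <- match.arg(mode)
  if (inherits(x, "cell_matrix")) {
    env <- x$env
    x <- x$x
  }
  sst <- env$sst_mean[match(rownames(x), env$cell_id)]
  sst_sd <- if (mode == "interval") {
    env$sst_sd[match(rownames(x), env$cell_id)]
  } else rep(0, nrow(x))
  ranges <- ranges[match(colnames(x), ranges$species), ]
  quota <- rowSums(x > 0)
  out <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(nrow(x))) {
      pool <- which(ranges$t_min <= sst[i] + sst_sd[i] &
                      ranges$t_max >= sst[i] - sst_sd[i])
      if (length(pool) < quota[i])
        abort("cell ", rownames(x)[i], ": candidate pool (", length(pool),
              ") smaller than richness quota (", quota[i], ")")
      take <- if (length(pool) == quota[i]) pool else
        sample(pool, quota[i])
      out[i, take] <- 1L
    }
  })
  out
}

#' Replicated null-model experiment
#'
#' For each replicate: simulate a temperature-constrained null world, derive
#' nominal provinces from it by Q-mode varimax factor analysis with the same
#' factor count as the real analysis, and refit the combined
#' provinces-plus-abiotic-factors regression of (observed) diversity. The
#' distribution of coefficients and significance indicators across
#' replicates shows what province structure and province-diversity
#' association temperature alone can generate. Per-replicate seeds are
#' spawned deterministically from the master seed.
#'
#' @param cm a `cell_matrix` (real data or synthetic world).
#' @param div diversity table for the same cells ([diversity_table()]); the
#'   observed diversity is reused by default since the null targets
#'   biogeography, not diversity; set `recompute_diversity = TRUE` to
#'   recompute raw richness from each simulated matrix instead.
#' @param n_reps number of replicates (default 100; scale up as needed).
#' @param n_factors province count, normally the real-data parallel-analysis
#'   value.
#' @param seed master seed.
#' @param metric diversity column to model (default `"fisher_alpha"`).
#' @param extraction factor extraction method for the per-replicate Q-mode
#'   analysis (default `"paf"`, whose non-iterative cost suits thousands of
#'   replicates; `"minres"` gives the same loadings to within rotation
#'   noise).
#' @param recompute_diversity use each null world's own raw richness as the
#'   response instead of the observed diversity.
#' @param alpha significance threshold for the per-replicate flags.
#' @param log_response passed to [sar_fit()].
#' @param spatial fit the spatial error model per replicate (default FALSE:
#'   the OLS companion is what varies of interest across replicates and is
#'   far cheaper; set TRUE for the full model).
#' @return object of class `null_experiment`: list with
#'   \describe{
#'     \item{replicates}{data.frame: `replicate`, `term`, `beta`, `p_value`,
#'       `significant`}
#'     \item{alignment}{per replicate, the share of SST variance explained
#'       by the simulated dominant-province partition (high values mean the
#'       null provinces form temperature-aligned bands)}
#'     \item{summary}{per term: mean, sd, 2.5/50/97.5 percent quantiles of
#'       beta, and the fraction of replicates where the term was significant}
#'   }
#' @export
null_experiment <- function(cm, div, n_reps = 100L, n_factors, seed = 1L,
                            metric = "fisher_alpha", extraction = "paf",
                            recompute_diversity = FALSE, alpha = 0.001,
                            log_response = TRUE, spatial = FALSE) {
  if (n_reps < 1) abort("n_reps must be >= 1")
  ranges <- temp_ranges(cm)
  ab <- abiotic_fa(cm$env)
  coords <- as.matrix(cm$cells[, c("center_lon", "center_lat")])
  rownames(coords) <- cm$cells$cell_id
  seeds <- spawn_seeds(seed, n_reps)
  sst <- cm$env$sst_mean[match(rownames(cm$x), cm$env$cell_id)]

  rep_rows <- vector("list", n_reps)
  alignment <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    sim <- tryCatch(
      simulate_null(cm$x, ranges, cm$env, seed = seeds[r]),
      error = function(e) abort("replicate ", r, ": ", conditionMessage(e)))
    fs <- tryCatch({
      corr <- cell_correlation(sim, binarize = FALSE)
      varimax_fa(corr, n_factors, extraction = extraction)
    }, error = function(e) abort("replicate ", r, ": ", conditionMessage(e)))
    dom <- apply(fs$loadings, 1, which.max)
    alignment[r] <- summary(stats::lm(sst ~ factor(dom)))$r.squared

    y <- if (recompute_diversity) rowSums(sim) else div[[metric]]
    ids <- rownames(cm$x)
    X <- cbind(fs$loadings, ab$scores[ids, , drop = FALSE])
    colnames(X) <- c(paste0("province", seq_len(n_factors)),
                     paste0("abiotic", seq_len(ncol(ab$scores))))
    ok <- is.finite(y)
    fit <- if (spatial) {
      sar_fit(y[ok], X[ok, , drop = FALSE], coords[ids[ok], , drop = FALSE],
              log_response = log_response, alpha = alpha,
              label = paste0("null_rep", r))
    } else {
      ols_only_fit(y[ok], X[ok, , drop = FALSE], log_response, alpha,
                   paste0("null_rep", r))
    }
    rep_rows[[r]] <- cbind(replicate = r, fit$terms)
  }
  replicates <- do.call(rbind, rep_rows)
  summary <- do.call(rbind, lapply(split(replicates, replicates$term), function(d) {
    q <- stats::quantile(d$beta, c(0.025, 0.5, 0.975))
    data.frame(term = d$term[1], mean_beta = mean(d$beta),
               sd_beta = stats::sd(d$beta),
               q025 = q[1], median = q[2], q975 = q[3],
               prop_significant = mean(d$significant), row.names = NULL)
  }))
  temp_factor <- if ("sst_mean" %in% rownames(ab$loadings))
    paste0("abiotic", which.max(abs(ab$loadings["sst_mean", ]))) else NA
  structure(list(replicates = replicates, alignment = alignment,
                 summary = summary, n_reps = n_reps, n_factors = n_factors,
                 seed = seed, metric = metric, alpha = alpha,
                 temp_factor = temp_factor),
            class = "null_experiment")
}

# plain standardized OLS in the same terms layout as sar_fit
ols_only_fit <- function(y, X, log_response, alpha, label) {
  if (log_response) {
    if (any(y <= 0)) abort("log response requested but y has non-positive values")
    y <- log(y)
  }
  ys <- as.numeric(scale(y))
  Xs <- scale(as.matrix(X))
  fit <- stats::lm(ys ~ Xs)
  co <- summary(fit)$coefficients[-1, , drop = FALSE]
  list(terms = data.frame(term = colnames(X), beta = co[, 1],
                          p_value = co[, 4], significant = co[, 4] < alpha,
                          row.names = NULL),
       adjusted_R2 = summary(fit)$adj.r.squared, model_label = label)
}

#' @export
print.null_experiment <- function(x, ...) {
  cat("null_experiment:", x$n_reps, "replicates,", x$n_factors,
      "simulated provinces, response =", x$metric, "\n")
  print(transform(x$summary, mean_beta = round(mean_beta, 3),
                  sd_beta = round(sd_beta, 3)))
  invisible(x)
}
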