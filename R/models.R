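# Regression layer: R-mode abiotic factor analysis, spatial-error
# autoregressions with OLS companions, the combined abiotic/province model
# suite, key-variable selection, and the path-regression suite that emulates
# a structural equation model.

#' Varimax factor analysis of the abiotic variables (R-mode)
#'
#' Collapses the eight collinear environmental variables into a small number
#' of orthogonal factors (default 3) and returns per-cell factor scores by
#' the regression method. Keeping loadings rather than discarding variables
#' preserves information that model selection would throw away.
#'
#' @param env environmental table (data.frame with the [env_variables()]
#'   columns, or a numeric matrix of cells x variables).
#' @param n_factors number of factors (default 3).
#' @param extraction passed to [varimax_fa()].
#' @return object of class `abiotic_factors`: list with `loadings`
#'   (variables x factors), `scores` (cells x factors, unit variance),
#'   `uniqueness` (per variable), and the underlying `factor_solution`.
#' @export
abiotic_fa <- function(env, n_factors = 3L, extraction = "minres") {
  vars <- if (is.data.frame(env)) {
    present <- intersect(env_variables(), names(env))
    if (length(present) < 2) abort("environmental table lacks the standard variables")
    as.matrix(env[, present, drop = FALSE])
  } else as.matrix(env)
  sds <- apply(vars, 2, stats::sd)
  if (any(sds == 0))
    abort("constant environmental variable(s): ",
          paste(colnames(vars)[sds == 0], collapse = ", "))
  R <- stats::cor(vars)
  fs <- varimax_fa(R, n_factors, extraction = extraction)
  scores <- factor_scores(vars, fs)
  rownames(scores) <- rownames(vars)
  structure(list(loadings = fs$loadings, scores = scores,
                 uniqueness = fs$uniqueness, solution = fs),
            class = "abiotic_factors")
}

#' @export
print.abiotic_factors <- function(x, ...) {
  cat("abiotic_factors:", nrow(x$loadings), "variables x",
      ncol(x$loadings), "factors\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Row-standardized k-nearest-neighbour spatial weights
#'
#' Builds the kNN adjacency on Euclidean distance between cell centres,
#' symmetrizes it (neighbourhood union), and row-standardizes. The symmetric
#' base guarantees real eigenvalues for the autoregressive log-determinant.
#'
#' @param coords 2-column matrix of cell centres (lon, lat or any planar
#'   coordinates).
#' @param k number of neighbours (default 5).
#' @return list: `W` row-standardized weights, `eigenvalues` of `W`.
#' @export
knn_weights <- function(coords, k = 5L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k >= n) abort("k must be smaller than the number of cells")
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, order(d[i, ])[seq_len(k)]] <- 1
  A <- pmax(A, t(A))                    # symmetrize: union of neighbourhoods
  rs <- rowSums(A)
  W <- A / rs
  # W = D^-1 A is similar to the symmetric D^-1/2 A D^-1/2: real spectrum
  M <- A / sqrt(outer(rs, rs))
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  list(W = W, eigenvalues = ev)
}

# design-matrix check: error naming collinear columns
check_design <- function(X) {
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    abort("constant predictor column(s): ",
          paste(colnames(X)[sds == 0], collapse = ", "))
  q <- qr(cbind(1, scale(X)))
  if (q$rank < ncol(X) + 1) {
    bad <- colnames(X)[q$pivot[seq(q$rank + 1, ncol(X) + 1)] - 1]
    abort("singular design; collinear column(s): ", paste(bad, collapse = ", "))
  }
}

#' Spatial autoregression of diversity with an OLS companion
#'
#' Fits the spatial error model `y = X b + u`, `u = lambda W u + e` (or the
#' spatial lag model `y = rho W y + X b + e`) by maximum likelihood over a
#' row-standardized kNN weights matrix, with the log-determinant evaluated
#' from the eigenvalues of `W`. Response and predictors are standardized to
#' unit variance first (the response optionally after a log transform), so
#' all slopes are beta coefficients and comparable across predictors. The
#' ordinary least-squares companion of the same design is always fitted too;
#' its adjusted R-squared is reported and its p-values drive the
#' significance flags, matching the general-linear-model presentation, while
#' the autoregressive coefficient table is kept alongside.
#'
#' @param y response vector (diversity values).
#' @param X predictor matrix with named columns.
#' @param coords cell centres for the spatial weights.
#' @param model `"error"` (default) or `"lag"`.
#' @param k_neighbors kNN neighbourhood size (default 5).
#' @param log_response log-transform `y` before standardizing.
#' @param alpha significance threshold for the flags (default 0.001).
#' @param label model label carried through to summaries.
#' @return object of class `regression_result`: list with `terms`
#'   (data.frame: `term`, `beta`, `p_value`, `significant` from the OLS
#'   companion), `sar_terms` (same layout, ML fit), `adjusted_R2`,
#'   `spatial_param`, `spatial_param_p`, `model`, `model_label`, `n`,
#'   `r_squared` (unadjusted, OLS).
#' @export
sar_fit <- function(y, X, coords, model = c("error", "lag"), k_neighbors = 5L,
                    log_response = FALSE, alpha = 0.001, label = "model") {
  model <- match.arg(model)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  if (n < 10) abort("need at least 10 cells")
  if (nrow(X) != n) abort("y and X disagree on length")
  if (log_response) {
    if (any(y <= 0)) abort("log response requested but y has non-positive values")
    y <- log(y)
  }
  check_design(X)
  ys <- as.numeric(scale(y))
  Xs <- scale(X)

  # OLS companion
  ols <- stats::lm(ys ~ Xs)
  co <- summary(ols)$coefficients[-1, , drop = FALSE]
  ols_terms <- data.frame(term = colnames(X), beta = co[, 1],
                          p_value = co[, 4],
                          significant = co[, 4] < alpha,
                          row.names = NULL)
  r2 <- summary(ols)$r.squared
  adj_r2 <- summary(ols)$adj.r.squared

  w <- knn_weights(coords, k_neighbors)
  W <- w$W
  ev <- w$eigenvalues
  lo <- 1 / min(ev) + 1e-6
  hi <- 1 / max(ev) - 1e-6
  Xs1 <- cbind(`(Intercept)` = 1, Xs)

  if (model == "error") {
    conc_ll <- function(lambda) {
      yt <- ys - lambda * (W %*% ys)
      Xt <- Xs1 - lambda * (W %*% Xs1)
      fit <- stats::lm.fit(Xt, yt)
      sse <- sum(fit$residuals^2)
      sum(log(1 - lambda * ev)) - n / 2 * log(sse / n)
    }
    opt <- stats::optimize(conc_ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
    lambda <- opt$maximum
    yt <- ys - lambda * (W %*% ys)
    Xt <- Xs1 - lambda * (W %*% Xs1)
    fit <- stats::lm.fit(Xt, yt)
    sse <- sum(fit$residuals^2)
    sigma2 <- sse / n
    vc <- sigma2 * solve(crossprod(Xt))
    beta <- fit$coefficients[-1]
    se <- sqrt(diag(vc))[-1]
    lr <- 2 * (opt$objective - conc_ll(0))
    sp <- lambda
  } else {
    Wy <- as.numeric(W %*% ys)
    f0 <- stats::lm.fit(Xs1, ys)
    fL <- stats::lm.fit(Xs1, Wy)
    conc_ll <- function(rho) {
      e <- f0$residuals - rho * fL$residuals
      sum(log(1 - rho * ev)) - n / 2 * log(sum(e^2) / n)
    }
    opt <- stats::optimize(conc_ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
    rho <- opt$maximum
    fit <- stats::lm.fit(Xs1, ys - rho * Wy)
    sse <- sum(fit$residuals^2)
    sigma2 <- sse / n
    vc <- sigma2 * solve(crossprod(Xs1))
    beta <- fit$coefficients[-1]
    se <- sqrt(diag(vc))[-1]
    lr <- 2 * (opt$objective - conc_ll(0))
    sp <- rho
  }
  z <- beta / se
  sar_terms <- data.frame(term = colnames(X), beta = unname(beta),
                          p_value = 2 * stats::pnorm(-abs(z)),
                          significant = 2 * stats::pnorm(-abs(z)) < alpha,
                          row.names = NULL)
  structure(list(terms = ols_terms, sar_terms = sar_terms,
                 adjusted_R2 = adj_r2, r_squared = r2,
                 spatial_param = sp,
                 spatial_param_p = stats::pchisq(max(lr, 0), 1,
                                                 lower.tail = FALSE),
                 model = model, model_label = label, n = n, alpha = alpha),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("regression_result [", x$model_label, "] n =", x$n,
      " adjR2 =", round(x$adjusted_R2, 3),
      " spatial", x$model, "param =", round(x$spatial_param, 3), "\n")
  print(transform(x$terms, beta = round(beta, 4),
                  p_value = signif(p_value, 3)))
  invisible(x)
}

#' Regression suite of diversity on abiotic factors (+/- province loadings)
#'
#' One spatial regression (with OLS companion) per diversity metric. The
#' abiotic-only layout regresses each metric on the three abiotic factor
#' scores; adding `provinces` gives the combined layout with K province
#' loadings ahead of the abiotic factors. Significance is flagged at
#' `alpha` (default 0.001).
#'
#' @param div diversity table from [diversity_table()] (must carry
#'   `cell_id`).
#' @param abiotic an `abiotic_factors` object whose score rows are named by
#'   cell.
#' @param provinces optional cell x factor province loading matrix
#'   (rownames = cell_id).
#' @param coords cell centres (matrix with rownames = cell_id, or columns
#'   `center_lon`, `center_lat` of a cells data.frame).
#' @param metrics diversity columns to model.
#' @param alpha,model,k_neighbors,log_response passed to [sar_fit()].
#' @return named list of `regression_result`, one per metric; see
#'   [suite_table()] for a flat summary.
#' @export
model_suite <- function(div, abiotic, provinces = NULL, coords,
                        metrics = c("fisher_alpha", "simpson_D", "cJ1", "sqs"),
                        alpha = 0.001, model = "error", k_neighbors = 5L,
                        log_response = TRUE) {
  ids <- div$cell_id
  scores <- abiotic$scores
  if (is.null(rownames(scores))) abort("abiotic scores lack cell rownames")
  missing_ab <- setdiff(ids, rownames(scores))
  if (length(missing_ab))
    abort("cells missing from abiotic scores: ",
          paste(utils::head(missing_ab, 5), collapse = ", "))
  X <- scores[ids, , drop = FALSE]
  colnames(X) <- paste0("abiotic", seq_len(ncol(X)))
  if (!is.null(provinces)) {
    missing_pr <- setdiff(ids, rownames(provinces))
    if (length(missing_pr))
      abort("cells missing from province loadings: ",
            paste(utils::head(missing_pr, 5), collapse = ", "))
    P <- provinces[ids, , drop = FALSE]
    colnames(P) <- paste0("province", seq_len(ncol(P)))
    X <- cbind(P, X)
  }
  if (is.data.frame(coords) && all(c("center_lon", "center_lat") %in% names(coords))) {
    rn <- if (!is.null(coords$cell_id)) coords$cell_id else rownames(coords)
    coords <- as.matrix(coords[, c("center_lon", "center_lat")])
    rownames(coords) <- rn
  }
  coords <- coords[ids, , drop = FALSE]
  out <- lapply(metrics, function(m) {
    if (!m %in% names(div)) abort("metric not in diversity table: ", m)
    y <- div[[m]]
    ok <- is.finite(y)
    if (!all(ok)) warning(sum(!ok), " cells with undefined ", m, " dropped",
                          call. = FALSE)
    sar_fit(y[ok], X[ok, , drop = FALSE], coords[ok, , drop = FALSE],
            model = model, k_neighbors = k_neighbors,
            log_response = log_response, alpha = alpha, label = m)
  })
  names(out) <- metrics
  out
}

#' Flatten a model suite into one table
#'
#' @param suite result of [model_suite()].
#' @return data.frame: `metric`, `term`, `beta`, `p_value`, `significant`,
#'   `adjusted_R2`, `spatial_param`.
#' @export
suite_table <- function(suite) {
  do.call(rbind, lapply(names(suite), function(m) {
    r <- suite[[m]]
    cbind(metric = m, r$terms,
          adjusted_R2 = r$adjusted_R2, spatial_param = r$spatial_param)
  }))
}

#' Select the key abiotic variables for the path analysis
#'
#' Takes the variable with the highest absolute loading on each abiotic
#' factor, then fills the set with the variables of highest uniqueness (the
#' share of variance the factors fail to explain) until the configured size
#' is reached. Latitude is always included and counts toward the size. Ties
#' break by the environmental-table order; deterministic.
#'
#' @param abiotic an `abiotic_factors` object.
#' @param key_size total number of key variables including latitude
#'   (default 7).
#' @param include_latitude include `"latitude"` (default TRUE).
#' @return character vector of variable names, latitude first.
#' @export
select_key_variables <- function(abiotic, key_size = 7L,
                                 include_latitude = TRUE) {
  L <- abiotic$loadings
  vars <- rownames(L)
  top <- unique(vars[apply(abs(L), 2, which.max)])
  budget <- key_size - as.integer(include_latitude)
  uniq_order <- vars[order(-abiotic$uniqueness)]   # stable: table order on ties
  fill <- setdiff(uniq_order, top)
  selected <- c(top, utils::head(fill, max(0L, budget - length(top))))
  selected <- vars[vars %in% selected]             # restore table order
  if (include_latitude) c("latitude", selected) else selected
}

#' Path-regression suite emulating a structural equation model
#'
#' Every node (each key abiotic variable, latitude, each province loading,
#' and the diversity metric) is taken in turn as the dependent variable of
#' one multiple regression on all permitted other nodes; province loadings
#' are never regressed on each other because they are mathematically
#' interdependent. Every coefficient significant at `alpha` (default 0.01)
#' becomes a signed directed edge.
#'
#' @param data data.frame of aligned node columns (cells as rows).
#' @param province_cols names of the province-loading columns.
#' @param alpha per-test significance threshold (default 0.01).
#' @return object of class `path_graph`: list with `nodes`, `edges`
#'   (data.frame `from`, `to`, `sign`, `beta`, `p`), `alpha`, `n_tests`.
#' @export
path_suite <- function(data, province_cols, alpha = 0.01) {
  nodes <- names(data)
  if (!all(province_cols %in% nodes))
    abort("province_cols not all present in data")
  edges <- list()
  n_tests <- 0L
  for (dep in nodes) {
    preds <- setdiff(nodes, dep)
    if (dep %in% province_cols) preds <- setdiff(preds, province_cols)
    Z <- scale(as.matrix(data[, preds, drop = FALSE]))
    y <- as.numeric(scale(data[[dep]]))
    fit <- stats::lm(y ~ Z)
    co <- summary(fit)$coefficients
    rows <- match(paste0("Z", preds), rownames(co))
    co <- co[rows, , drop = FALSE]
    n_tests <- n_tests + length(preds)
    sig <- which(co[, 4] < alpha)
    for (s in sig) {
      edges[[length(edges) + 1L]] <- data.frame(
        from = preds[s], to = dep,
        sign = sign(co[s, 1]), beta = co[s, 1], p = co[s, 4],
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), sign = numeric(),
               beta = numeric(), p = numeric())
  structure(list(nodes = nodes, edges = edges, alpha = alpha,
                 n_tests = n_tests),
            class = "path_graph")
}

#' @export
print.path_graph <- function(x, ...) {
  cat("path_graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "significant edges of", x$n_tests, "tests (alpha =", x$alpha, ")\n")
  if (nrow(x$edges)) print(transform(x$edges, beta = round(beta, 3),
                                     p = signif(p, 3)))
  invisible(x)
}
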