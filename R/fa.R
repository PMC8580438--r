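# Factor-analysis engine shared by the bioregionalization (Q-mode, factoring
# cells) and abiotic (R-mode, factoring variables) analyses: minres /
# principal-axis extraction from a correlation matrix, varimax rotation, and
# parallel analysis for factor retention.

# minres extraction: minimize the off-diagonal residuals of R - LL' over the
# uniquenesses, loadings from the truncated eigendecomposition of the
# reduced correlation matrix.
fa_extract_minres <- function(R, k) {
  p <- ncol(R)
  smc <- tryCatch(1 - 1 / diag(solve(R)), error = function(e) rep(0.5, p))
  smc[!is.finite(smc)] <- 0.5
  psi0 <- pmin(pmax(1 - smc, 0.05), 0.95)
  loadings_for <- function(psi) {
    Rm <- R
    diag(Rm) <- 1 - psi
    e <- eigen(Rm, symmetric = TRUE)
    val <- pmax(e$values[seq_len(k)], 0)
    e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(val), k)
  }
  objective <- function(psi) {
    L <- loadings_for(psi)
    resid <- R - tcrossprod(L)
    diag(resid) <- 0
    sum(resid^2)
  }
  opt <- stats::optim(psi0, objective, method = "L-BFGS-B",
                      lower = 0.005, upper = 1,
                      control = list(maxit = 1000))
  loadings_for(opt$par)
}

# principal-axis extraction: iterate communalities on the diagonal.
fa_extract_paf <- function(R, k, max_iter = 100L, tol = 1e-6) {
  p <- ncol(R)
  smc <- tryCatch(1 - 1 / diag(solve(R)), error = function(e) rep(0.5, p))
  smc[!is.finite(smc)] <- 0.5
  h2 <- pmin(pmax(smc, 0.05), 0.95)
  L <- NULL
  for (i in seq_len(max_iter)) {
    Rm <- R
    diag(Rm) <- h2
    e <- eigen(Rm, symmetric = TRUE)
    val <- pmax(e$values[seq_len(k)], 0)
    L <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(val), k)
    h2_new <- pmin(rowSums(L^2), 1)
    if (max(abs(h2_new - h2)) < tol) break
    h2 <- h2_new
  }
  L
}

#' Varimax factor analysis of a correlation matrix
#'
#' Extracts `n_factors` factors by minimum-residual (default) or
#' principal-axis factoring and applies an orthogonal varimax rotation
#' (convergence 1e-6). Factor signs are fixed so each factor's
#' largest-magnitude loading is positive, and factors are ordered by
#' explained variance (sum of squared loadings). Communalities are invariant
#' under the rotation.
#'
#' In Q-mode use (the bioregionalization), rows of `corr` are *cells* and the
#' returned loadings describe each cell's affinity to a latent compositional
#' province; in R-mode use (abiotic variables) rows are variables.
#'
#' @param corr square symmetric correlation matrix (unit diagonal).
#' @param n_factors number of factors, `1 <= n_factors < ncol(corr)`.
#' @param extraction `"minres"` (default) or `"paf"`.
#' @return object of class `factor_solution`: list with `loadings`
#'   (rows x factors, dimnames preserved), `eigenvalues` (SS loadings per
#'   factor), `communalities`, `uniqueness`, `n_factors`, `rotation`
#'   (`"varimax"`), `extraction`.
#' @export
varimax_fa <- function(corr, n_factors, extraction = c("minres", "paf")) {
  extraction <- match.arg(extraction)
  corr <- as.matrix(corr)
  p <- ncol(corr)
  if (n_factors < 1 || n_factors >= p)
    abort("n_factors must satisfy 1 <= n_factors < ", p)
  if (any(abs(corr - t(corr)) > 1e-8)) abort("correlation matrix not symmetric")
  L <- switch(extraction,
              minres = fa_extract_minres(corr, n_factors),
              paf = fa_extract_paf(corr, n_factors))
  if (n_factors > 1) {
    rot <- stats::varimax(L, normalize = TRUE, eps = 1e-6)
    L <- L %*% rot$rotmat
  }
  # sign convention and variance ordering
  for (j in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  ss <- colSums(L^2)
  ord <- order(ss, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  ss <- ss[ord]
  rownames(L) <- rownames(corr)
  colnames(L) <- paste0("factor", seq_len(n_factors))
  h2 <- rowSums(L^2)
  structure(list(loadings = L, eigenvalues = unname(ss),
                 communalities = h2, uniqueness = 1 - h2,
                 n_factors = n_factors, rotation = "varimax",
                 extraction = extraction),
            class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat("factor_solution:", nrow(x$loadings), "rows x", x$n_factors,
      "factors (", x$extraction, "+ varimax )\n")
  cat("SS loadings:", paste(round(x$eigenvalues, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Factor scores by the regression method
#'
#' @param data observations x variables matrix (will be standardized).
#' @param fs a `factor_solution` over the same variables.
#' @return observations x factors score matrix (unit variance up to sampling).
#' @export
factor_scores <- function(data, fs) {
  Z <- scale(as.matrix(data))
  R <- stats::cor(as.matrix(data))
  scores <- Z %*% solve(R, fs$loadings)
  # rescale to unit variance so scores are comparable across factors
  scale(scores)[, , drop = FALSE]
}

#' Parallel analysis for factor retention
#'
#' Compares the eigenvalue scree of the observed correlation matrix with
#' screes from `n_random` same-shape matrices whose entries are permuted
#' independently within each column of the observed data (respecting each
#' variable's marginal distribution, which matters for binary data). The
#' retained count is the length of the leading run of observed eigenvalues
#' exceeding the chosen quantile of the permuted eigenvalues at the same
#' rank. Deterministic given `seed`.
#'
#' @param data observations x variables matrix as used for the factor
#'   analysis (for the Q-mode bioregionalization pass the transposed,
#'   binarized species x cells matrix; see [bioregion_fa()]).
#' @param n_random number of permuted matrices (default 100).
#' @param quantile quantile of the permuted eigenvalue distribution
#'   (default 0.95).
#' @param seed integer seed.
#' @return integer: number of factors to retain (possibly 0), with the
#'   observed eigenvalues and the permutation threshold as attributes.
#' @export
parallel_analysis <- function(data, n_random = 100L, quantile = 0.95,
                              seed = 1L) {
  data <- as.matrix(data)
  sds <- apply(data, 2, stats::sd)
  if (any(sds == 0))
    abort("zero-variance column(s): ",
          paste(utils::head(colnames(data)[sds == 0], 5), collapse = ", "))
  obs <- eigen(stats::cor(data), symmetric = TRUE, only.values = TRUE)$values
  perm <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_random), function(i) {
      shuffled <- apply(data, 2, sample)
      eigen(stats::cor(shuffled), symmetric = TRUE, only.values = TRUE)$values
    }, numeric(length(obs)))
  })
  thr <- apply(perm, 1, stats::quantile, probs = quantile)
  below <- which(obs <= thr)
  n_keep <- if (length(below) == 0L) length(obs) else below[1L] - 1L
  structure(as.integer(n_keep), observed = obs, threshold = thr)
}
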