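# Bioregionalization: continuous province loadings from a Q-mode varimax
# factor analysis of the cell x species matrix, cross-checked by PAM
# clustering and correspondence analysis.

#' Cell-by-cell correlation matrix (Q-mode preparation)
#'
#' Correlates cells across species. By default incidence counts are reduced
#' to presence-absence first: occurrence-database counts track sampling
#' effort more than abundance, so composition, not effort, should drive the
#' bioregionalization.
#'
#' @param x cells x species count matrix (or a `cell_matrix`).
#' @param binarize reduce to presence-absence before correlating (default).
#' @return symmetric cells x cells product-moment correlation matrix with
#'   unit diagonal.
#' @export
cell_correlation <- function(x, binarize = TRUE) {
  if (inherits(x, "cell_matrix")) x <- x$x
  x <- as.matrix(x)
  if (nrow(x) < 3 || ncol(x) < 2) abort("need at least 3 cells and 2 species")
  v <- if (binarize) (x > 0) + 0 else x
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0))
    abort("zero-variance cell vector(s): ",
          paste(utils::head(rownames(v)[sds == 0], 5), collapse = ", "))
  stats::cor(t(v))
}

#' Q-mode varimax factor analysis of the cell x species matrix
#'
#' The province model: each retained factor is a latent compositional
#' province, and a cell's loading on it measures how fully the cell's fauna
#' belongs to that province. High loadings on one factor mark province
#' cores; middling loadings split across factors mark transition zones, so
#' the scheme accommodates both sharp boundaries and gradients. The factor
#' count defaults to the parallel-analysis value but can be fixed, mirroring
#' the usual dual reporting of parallel-analysis and scree-based counts.
#'
#' @param x cells x species count matrix or `cell_matrix`.
#' @param n_factors `NULL` (choose by [parallel_analysis()]) or a fixed count.
#' @param binarize reduce to presence-absence first (default TRUE).
#' @param extraction passed to [varimax_fa()].
#' @param seed seed for the parallel analysis permutations.
#' @param ... further arguments to [parallel_analysis()].
#' @return a `factor_solution` whose `loadings` rows are cells; the
#'   parallel-analysis count is attached as attribute `"n_factors_pa"` when
#'   it was run.
#' @export
bioregion_fa <- function(x, n_factors = NULL, binarize = TRUE,
                         extraction = "minres", seed = 1L, ...) {
  if (inherits(x, "cell_matrix")) x <- x$x
  x <- as.matrix(x)
  pa <- NULL
  if (is.null(n_factors)) {
    v <- if (binarize) (x > 0) + 0 else x
    pa <- parallel_analysis(t(v), seed = seed, ...)
    n_factors <- max(1L, as.integer(pa))
  }
  corr <- cell_correlation(x, binarize = binarize)
  fs <- varimax_fa(corr, n_factors, extraction = extraction)
  if (!is.null(pa)) attr(fs, "n_factors_pa") <- as.integer(pa)
  fs
}

#' Assign each cell to its dominant province factor
#'
#' @param fs a `factor_solution` with cells as rows.
#' @return data.frame: `cell_id`, `province` (index of the max-loading
#'   factor), `max_loading`.
#' @export
dominant_factor <- function(fs) {
  L <- fs$loadings
  data.frame(cell_id = rownames(L),
             province = apply(L, 1, which.max),
             max_loading = apply(L, 1, max),
             stringsAsFactors = FALSE)
}

#' Pairwise compositional dissimilarity between cells
#'
#' Sorensen (Bray-Curtis on presences, the default) or Jaccard
#' dissimilarity, used as input to [pam_cluster()].
#'
#' @param x cells x species count matrix or `cell_matrix`.
#' @param method `"sorensen"` or `"jaccard"`.
#' @return symmetric dissimilarity matrix in `[0, 1]`.
#' @export
cell_dissimilarity <- function(x, method = c("sorensen", "jaccard")) {
  method <- match.arg(method)
  if (inherits(x, "cell_matrix")) x <- x$x
  v <- (as.matrix(x) > 0) + 0
  a <- tcrossprod(v)                    # shared species
  s <- rowSums(v)
  tot <- outer(s, s, "+")
  d <- switch(method,
              sorensen = 1 - 2 * a / tot,
              jaccard = 1 - a / (tot - a))
  diag(d) <- 0
  dimnames(d) <- list(rownames(v), rownames(v))
  d
}

# total cost and nearest-medoid assignment for a medoid set
pam_cost <- function(d, medoids) {
  dm <- d[, medoids, drop = FALSE]
  nearest <- max.col(-dm, ties.method = "first")
  list(cost = sum(dm[cbind(seq_len(nrow(d)), nearest)]),
       assignment = medoids[nearest])
}

#' Partitioning around medoids (PAM)
#'
#' k-medoids on a precomputed dissimilarity matrix. Small instances (at most
#' 5000 candidate medoid sets) are solved exactly by enumeration; larger
#' ones use the classical BUILD + SWAP heuristic, whose best-improving
#' single swap is accepted until none exists, so the final cost is a local
#' minimum under single swaps and never increases across iterations. Fully
#' deterministic: all ties (in BUILD gains, SWAP improvements, enumeration
#' order and nearest-medoid assignment) break toward the lowest index, and
#' no random numbers are consumed.
#'
#' @param d square symmetric dissimilarity matrix.
#' @param k number of medoids, `1 <= k <= nrow(d)`.
#' @return object of class `cluster_solution`: list with `k`, `medoids`
#'   (indices), `medoid_ids` (rownames if present), `assignment` (medoid
#'   index per object), `total_cost`, `iterations` (0 when solved by
#'   enumeration).
#' @export
pam_cluster <- function(d, k) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k <= 0) abort("k must be positive")
  if (k > n) abort("k cannot exceed the number of objects")
  if (any(abs(d - t(d)) > 1e-10)) abort("dissimilarity matrix not symmetric")

  if (choose(n, k) <= 5000) {
    sets <- utils::combn(n, k)
    costs <- apply(sets, 2, function(med) pam_cost(d, med)$cost)
    medoids <- sets[, which.min(costs)]   # first minimum: lexicographic tie-break
    cur <- pam_cost(d, medoids)
    return(structure(list(k = k, medoids = medoids,
                          medoid_ids = rownames(d)[medoids],
                          assignment = cur$assignment,
                          total_cost = cur$cost, iterations = 0L),
                     class = "cluster_solution"))
  }

  # BUILD: greedy seeding, ties to lowest index (which.min is first-min)
  medoids <- which.min(colSums(d))
  while (length(medoids) < k) {
    best_cand <- NA_integer_
    best_cost <- Inf
    for (cand in setdiff(seq_len(n), medoids)) {
      cost <- pam_cost(d, c(medoids, cand))$cost
      if (cost < best_cost) {
        best_cost <- cost
        best_cand <- cand
      }
    }
    medoids <- c(medoids, best_cand)
  }
  cur <- pam_cost(d, medoids)
  iterations <- 0L

  # SWAP: best strictly improving swap until convergence
  repeat {
    iterations <- iterations + 1L
    best <- NULL
    best_cost <- cur$cost
    for (mi in seq_along(medoids)) {
      for (h in setdiff(seq_len(n), medoids)) {
        trial <- medoids
        trial[mi] <- h
        cost <- pam_cost(d, trial)$cost
        if (cost < best_cost - 1e-12) {
          best_cost <- cost
          best <- trial
        }
      }
    }
    if (is.null(best)) break
    medoids <- best
    cur <- pam_cost(d, medoids)
  }
  medoids <- sort(medoids)
  cur <- pam_cost(d, medoids)
  structure(list(k = k, medoids = medoids,
                 medoid_ids = rownames(d)[medoids],
                 assignment = cur$assignment,
                 total_cost = cur$cost,
                 iterations = iterations),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("cluster_solution: k =", x$k, " cost =", round(x$total_cost, 4), "\n")
  invisible(x)
}

#' Correspondence analysis of the cell x species matrix
#'
#' Standard CA by singular value decomposition of the standardized residual
#' matrix, used to demonstrate the distinctiveness of province clusters in
#' ordination space. Returns row (cell) principal coordinates on the first
#' `n_axes` axes and each axis' share of the total chi-square inertia.
#'
#' @param x non-negative matrix with no all-zero rows or columns.
#' @param n_axes number of axes requested (default 2); if the residual rank
#'   is lower, the available axes are returned with a warning.
#' @return list: `row_scores` (cells x axes), `col_scores`
#'   (species x axes), `inertia` (per retained axis), `inertia_share`,
#'   `total_inertia`.
#' @export
correspondence_analysis <- function(x, n_axes = 2L) {
  if (inherits(x, "cell_matrix")) x <- x$x
  x <- as.matrix(x)
  if (any(x < 0)) abort("matrix must be non-negative")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0))
    abort("matrix must have no all-zero rows or columns")
  P <- x / sum(x)
  r <- rowSums(P)
  cc <- colSums(P)
  Sres <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(Sres)
  keep <- which(sv$d > 1e-10)
  if (length(keep) < n_axes) {
    warning("residual rank ", length(keep), " < ", n_axes,
            " axes requested; returning available axes", call. = FALSE)
  }
  axes <- utils::head(keep, n_axes)
  if (length(axes) == 0L) {
    empty <- matrix(0, nrow(x), 0, dimnames = list(rownames(x), NULL))
    return(list(row_scores = empty,
                col_scores = matrix(0, ncol(x), 0,
                                    dimnames = list(colnames(x), NULL)),
                inertia = numeric(0), inertia_share = numeric(0),
                total_inertia = 0))
  }
  d <- sv$d[axes]
  row_scores <- sweep(sv$u[, axes, drop = FALSE], 1, sqrt(r), "/") %*%
    diag(d, length(axes))
  col_scores <- sweep(sv$v[, axes, drop = FALSE], 1, sqrt(cc), "/") %*%
    diag(d, length(axes))
  rownames(row_scores) <- rownames(x)
  rownames(col_scores) <- colnames(x)
  colnames(row_scores) <- colnames(col_scores) <-
    paste0("CA", seq_along(axes))
  list(row_scores = row_scores, col_scores = col_scores,
       inertia = d^2,
       inertia_share = if (sum(sv$d^2) > 0) d^2 / sum(sv$d^2) else rep(0, length(axes)),
       total_inertia = sum(sv$d^2))
}
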