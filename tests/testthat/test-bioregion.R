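test_that("cell correlation behaves on constructed assemblages", {
  # three cells over six species: two identical, one disjoint from both
  x <- rbind(a = c(1, 2, 3, 0, 0, 0),
             b = c(2, 1, 5, 0, 0, 0),
             d = c(0, 0, 0, 1, 1, 2))
  r <- cell_correlation(x)
  expect_equal(r["a", "b"], 1)              # identical presence profiles
  expect_equal(r["a", "d"], -1)             # complementary halves
  expect_equal(diag(r), c(a = 1, b = 1, d = 1))
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)                # positive semi-definite
  # zero-variance cell is named in the error
  x2 <- rbind(a = c(1, 1, 1), b = c(1, 0, 1), d = c(0, 1, 1))
  expect_error(cell_correlation(x2), "zero-variance.*a")
})

test_that("varimax factor analysis recovers planted block structure", {
  blk <- function(p, r) {
    m <- matrix(r, p, p)
    diag(m) <- 1
    m
  }
  R <- matrix(0, 8, 8, dimnames = list(paste0("v", 1:8), paste0("v", 1:8)))
  R[1:4, 1:4] <- blk(4, 0.85)
  R[5:8, 5:8] <- blk(4, 0.85)
  for (extraction in c("minres", "paf")) {
    fs <- varimax_fa(R, 2, extraction = extraction)
    L <- fs$loadings
    dom <- apply(abs(L), 1, which.max)
    expect_equal(unname(dom), rep(unname(c(dom[1], dom[5])), each = 4))
    expect_true(all(apply(abs(L), 1, max) > 0.85))
    expect_true(all(apply(abs(L), 1, min) < 0.1))
    # communalities equal the rotated row sums of squares by construction;
    # the rotation must not change them
    expect_equal(fs$communalities, rowSums(L^2), tolerance = 1e-8)
    # sign convention: each factor's largest-magnitude loading positive
    expect_true(all(apply(L, 2, function(cl) cl[which.max(abs(cl))]) > 0))
    # explained-variance ordering
    expect_true(all(diff(fs$eigenvalues) <= 1e-8))
  }
  expect_error(varimax_fa(R, 8), "n_factors")
})

test_that("communalities are invariant under the varimax rotation", {
  set.seed(8)
  Z <- matrix(rnorm(300), 50, 6)
  Z[, 2] <- Z[, 1] + rnorm(50, 0, 0.4)
  Z[, 4] <- Z[, 3] + rnorm(50, 0, 0.4)
  R <- cor(Z)
  unrot <- divprov:::fa_extract_minres(R, 2)
  fs <- varimax_fa(R, 2)
  expect_equal(sort(rowSums(unrot^2)), sort(unname(fs$communalities)),
               tolerance = 1e-6)
})

test_that("parallel analysis keeps planted factors and rejects noise", {
  set.seed(21)
  noise <- matrix(rnorm(60 * 15), 60, 15)
  expect_lte(parallel_analysis(noise, seed = 4), 1)
  # three planted blocks of unequal size in a binary species x cell matrix;
  # equal complementary blocks would be rank-deficient after centering
  # (K symmetric blocks span only K - 1 contrast dimensions)
  sizes <- list(1:60, 61:100, 101:125)
  blocks <- lapply(1:3, function(b) {
    rows <- matrix(rbinom(200 * 10, 1, 0.02), 200, 10)
    rows[sizes[[b]], ] <- rbinom(length(sizes[[b]]) * 10, 1, 0.9)
    rows
  })
  data <- do.call(cbind, blocks)   # 200 species x 30 cells
  expect_equal(as.integer(parallel_analysis(data, seed = 9)), 3L)
  # deterministic given the seed
  expect_equal(as.integer(parallel_analysis(data, seed = 9)),
               as.integer(parallel_analysis(data, seed = 9)))
})

test_that("PAM recovers separated triads at the exhaustive optimum", {
  pts <- rbind(matrix(rnorm(6, 0, 0.05), 3), matrix(rnorm(6, 10, 0.05), 3))
  d <- as.matrix(dist(pts))
  fit <- pam_cluster(d, 2)
  expect_equal(fit$total_cost, brute_pam_cost(d, 2), tolerance = 1e-12)
  expect_equal(length(unique(fit$assignment[1:3])), 1L)
  expect_equal(length(unique(fit$assignment[4:6])), 1L)
  # medoids assign to themselves
  expect_true(all(fit$assignment[fit$medoids] == fit$medoids))
})

test_that("PAM edge cases: k = n, duplicates, invalid k", {
  set.seed(2)
  m <- matrix(runif(25), 5)
  d <- (m + t(m)) / 2
  diag(d) <- 0
  expect_equal(pam_cluster(d, 5)$total_cost, 0)
  d2 <- d
  d2[2, ] <- d2[1, ]; d2[, 2] <- d2[, 1]; d2[2, 2] <- 0; d2[1, 2] <- d2[2, 1] <- 0
  fit <- pam_cluster(d2, 2)
  expect_equal(fit$assignment[1], fit$assignment[2])  # duplicates co-assigned
  expect_error(pam_cluster(d, 0), "positive")
})

test_that("heuristic PAM agrees with cluster::pam on larger instances", {
  skip_if_not_installed("cluster")
  set.seed(14)
  pts <- matrix(runif(120), 60, 2)      # large enough to skip enumeration
  d <- as.matrix(dist(pts))
  fit <- pam_cluster(d, 4)
  ref <- cluster::pam(stats::as.dist(d), 4)
  expect_equal(fit$total_cost, unname(ref$objective["swap"]) * 60,
               tolerance = 1e-6)
})

test_that("correspondence analysis matches its defining geometry", {
  # independent 2x2 table: zero inertia, fewer than 2 meaningful axes
  indep <- outer(c(2, 3), c(4, 6))
  expect_warning(ca0 <- correspondence_analysis(indep), "rank")
  expect_equal(ca0$total_inertia, 0, tolerance = 1e-12)
  # two disjoint blocks separate with opposite signs on axis 1
  x <- rbind(a = c(5, 4, 0, 0), b = c(4, 5, 0, 0),
             d = c(0, 0, 5, 4), e = c(0, 0, 4, 5))
  ca <- correspondence_analysis(x)
  s1 <- ca$row_scores[, 1]
  expect_true(prod(s1[c("a", "b")]) > 0)
  expect_true(prod(s1[c("d", "e")]) > 0)
  expect_true(s1["a"] * s1["d"] < 0)
  # mass-weighted centroid of row scores sits at the origin
  r <- rowSums(x) / sum(x)
  expect_equal(as.numeric(r %*% ca$row_scores), c(0, 0), tolerance = 1e-10)
  expect_error(correspondence_analysis(rbind(c(1, 0), c(1, 0))), "all-zero")
})

test_that("correspondence analysis agrees with an independent implementation", {
  skip_if_not_installed("MASS")
  set.seed(6)
  x <- matrix(rpois(60, 4) + 1, 6, 10)
  ca <- correspondence_analysis(x)
  ref <- MASS::corresp(x, nf = 2)
  expect_equal(ca$inertia, ref$cor[1:2]^2, tolerance = 1e-8)
  # principal row coordinates match up to axis sign
  ref_rows <- diag(ref$cor[1:2]) %*% t(ref$rscore * 1)
  for (j in 1:2) {
    expect_equal(unname(abs(ca$row_scores[, j])),
                 unname(abs(ref$rscore[, j] * ref$cor[j])), tolerance = 1e-6)
  }
})

test_that("compositional dissimilarities are bounded and symmetric", {
  x <- rbind(a = c(1, 1, 0, 0), b = c(0, 1, 1, 0), d = c(0, 0, 1, 1))
  for (m in c("sorensen", "jaccard")) {
    d <- cell_dissimilarity(x, method = m)
    expect_equal(d, t(d))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(unname(diag(d)), rep(0, 3))
  }
  expect_equal(cell_dissimilarity(x)["a", "d"], 1)  # disjoint cells
})
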