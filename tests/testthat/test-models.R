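make_grouped_env <- function(n = 150, seed = 2) {
  # three latent drivers -> 3/2/3 variable groups mirroring the standard
  # temperature / salinity / nutrient structure
  withr::with_seed(seed, {
    g1 <- rnorm(n); g2 <- rnorm(n); g3 <- rnorm(n)
    data.frame(
      sst_mean = g1 + rnorm(n, 0, 0.2),
      sst_sd = -g1 + rnorm(n, 0, 0.2),
      sal_mean = g2 + rnorm(n, 0, 0.2),
      sal_sd = g2 + rnorm(n, 0, 0.2),
      oxygen = -g1 + rnorm(n, 0, 0.2),
      nitrate = g3 + rnorm(n, 0, 0.2),
      silicate = g3 + rnorm(n, 0, 0.2),
      phosphate = g3 + rnorm(n, 0, 0.2))
  })
}

test_that("abiotic factor analysis separates orthogonal variable groups", {
  env <- make_grouped_env()
  af <- abiotic_fa(env)
  L <- af$loadings
  grp <- list(c("sst_mean", "sst_sd", "oxygen"),
              c("sal_mean", "sal_sd"),
              c("nitrate", "silicate", "phosphate"))
  fac_of <- apply(abs(L), 1, which.max)
  for (g in grp) expect_equal(length(unique(fac_of[g])), 1L)
  expect_true(all(apply(abs(L), 1, max) > 0.9))
  expect_equal(unname(colMeans(af$scores)), rep(0, 3), tolerance = 1e-8)
  expect_equal(unname(apply(af$scores, 2, sd)), rep(1, 3), tolerance = 1e-8)
  # a variable unrelated to everything keeps uniqueness near 1
  env$phosphate <- rnorm(nrow(env))
  af2 <- abiotic_fa(env)
  expect_gt(af2$uniqueness["phosphate"], 0.8)
  env$sst_sd <- 1
  expect_error(abiotic_fa(env), "constant")
})

test_that("spatial error regression recovers planted coefficients", {
  withr::with_seed(4, {
    n <- 200
    coords <- cbind(runif(n, 0, 10), runif(n, 0, 10))
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- 0.8 * x1 + rnorm(n, 0, 0.6)
  })
  f <- sar_fit(y, cbind(x1 = x1, x2 = x2), coords)
  b <- f$terms$beta[f$terms$term == "x1"]
  expect_lt(abs(b - 0.8), 0.1)
  expect_lt(f$terms$p_value[f$terms$term == "x1"], 1e-3)
  expect_false(f$terms$significant[f$terms$term == "x2"])
  # without a spatial process, SAR and OLS betas agree closely
  expect_lt(max(abs(f$sar_terms$beta - f$terms$beta)), 0.05)
  expect_lt(abs(f$spatial_param), 0.2)
})

test_that("spatial error regression detects a planted spatial parameter", {
  withr::with_seed(11, {
    n <- 200
    coords <- cbind(runif(n, 0, 10), runif(n, 0, 10))
    W <- knn_weights(coords, 5)$W
    x1 <- rnorm(n)
    u <- solve(diag(n) - 0.6 * W, rnorm(n, 0, 0.5))
    y <- 0.8 * x1 + u
  })
  f <- sar_fit(y, cbind(x1 = x1), coords)
  expect_gt(f$spatial_param, 0.3)
  expect_lt(f$spatial_param_p, 0.01)
})

test_that("permuted responses yield no significant terms", {
  withr::with_seed(7, {
    n <- 120
    coords <- cbind(runif(n), runif(n))
    X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
    y <- 0.8 * X[, 1] + rnorm(n, 0, 0.6)
    hits <- vapply(1:100, function(i) {
      f <- divprov:::ols_only_fit(sample(y), X, FALSE, 0.001, "perm")
      any(f$terms$significant)
    }, logical(1))
  })
  expect_gte(mean(!hits), 0.95)
})

test_that("betas are standardized: predictor rescaling changes nothing", {
  withr::with_seed(9, {
    n <- 80
    coords <- cbind(seq_len(n), rep(0, n))
    X <- cbind(a = rnorm(n), b = rnorm(n))
    y <- X[, 1] - 0.5 * X[, 2] + rnorm(n, 0, 0.5)
  })
  f1 <- sar_fit(y, X, coords)
  X2 <- X
  X2[, 1] <- X2[, 1] * 1000
  f2 <- sar_fit(y, X2, coords)
  expect_equal(f1$terms$beta, f2$terms$beta, tolerance = 1e-9)
  expect_error(sar_fit(y, cbind(a = X[, 1], b = X[, 1]), coords), "collinear")
})

test_that("model suite aligns inputs and reports nested-model R2 correctly", {
  w <- generate_world(synth_config(n_cells = 40, K = 2, pool_size = 120,
                                   effort_range = c(200, 800),
                                   richness_range = c(60, 30)), seed = 6)
  cm <- ingest(w$records, w$env, min_species = 5, min_records = 100)
  div <- diversity_table(cm)
  ab <- abiotic_fa(cm$env)
  fs <- bioregion_fa(cm, n_factors = 2)
  s1 <- model_suite(div, ab, coords = cm$cells, metrics = "fisher_alpha")
  s2 <- model_suite(div, ab, provinces = fs$loadings, coords = cm$cells,
                    metrics = "fisher_alpha")
  # unadjusted R2 never decreases when province loadings are added
  expect_gte(s2$fisher_alpha$r_squared, s1$fisher_alpha$r_squared - 1e-10)
  tab <- suite_table(s2)
  expect_true(all(c("metric", "term", "beta", "p_value") %in% names(tab)))
  # misaligned cells are reported
  bad <- div
  bad$cell_id[1] <- "nonexistent"
  expect_error(model_suite(bad, ab, coords = cm$cells,
                           metrics = "fisher_alpha"), "missing")
})

test_that("a flat response yields a near-zero adjusted R2", {
  withr::with_seed(13, {
    n <- 100
    coords <- cbind(seq_len(n), 0)
    X <- cbind(a = rnorm(n), b = rnorm(n), d = rnorm(n))
    y <- 5 + rnorm(n, 0, 0.01)
  })
  f <- sar_fit(y, X, coords)
  expect_lte(f$adjusted_R2, 0.01)
})

test_that("key-variable selection follows loading and uniqueness rules", {
  af <- structure(list(
    loadings = matrix(c(0.9, 0.1, 0.1, 0.2, 0.1, 0.1, 0.1, 0.1,
                        0.1, 0.8, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1,
                        0.1, 0.1, 0.9, 0.1, 0.1, 0.1, 0.1, 0.1), 8, 3,
                      dimnames = list(env_variables(), NULL)),
    uniqueness = setNames(c(0.1, 0.2, 0.1, 0.9, 0.8, 0.7, 0.6, 0.5),
                          env_variables())), class = "abiotic_factors")
  key <- select_key_variables(af)
  expect_equal(key[1], "latitude")
  expect_length(key, 7)
  # argmax variables present; remainder filled by decreasing uniqueness
  expect_true(all(c("sst_mean", "sst_sd", "sal_mean") %in% key))
  expect_true(all(c("sal_sd", "oxygen", "nitrate") %in% key))
  # one variable maximal on two factors is counted once
  af$loadings[1, 3] <- 0.95
  af$loadings[3, 3] <- 0.1
  key2 <- select_key_variables(af)
  expect_length(key2, 7)
  expect_equal(sum(key2 == "sst_mean"), 1L)
})

test_that("path suite recovers a mediation chain and bans province edges", {
  hits_direct <- hits_chain <- logical(10)
  for (s in 1:10) {
    withr::with_seed(100 + s, {
      n <- 150
      env <- rnorm(n)
      prov <- 0.9 * env + rnorm(n, 0, 0.4)
      divv <- 0.9 * prov + rnorm(n, 0, 0.4)
      data <- data.frame(env = env, province1 = prov, diversity = divv)
    })
    pg <- path_suite(data, "province1", alpha = 0.01)
    e <- pg$edges
    hits_chain[s] <- any(e$from == "env" & e$to == "province1") &&
      any(e$from == "province1" & e$to == "diversity")
    hits_direct[s] <- any(e$from == "env" & e$to == "diversity" & e$p < 0.01)
  }
  expect_gte(sum(hits_chain), 9)
  expect_lte(sum(hits_direct), 1)
  # province-province regressions are structurally excluded
  withr::with_seed(3, {
    d2 <- data.frame(a = rnorm(50), province1 = rnorm(50),
                     province2 = rnorm(50), diversity = rnorm(50))
  })
  pg2 <- path_suite(d2, c("province1", "province2"))
  expect_false(any(pg2$edges$from %in% c("province1", "province2") &
                     pg2$edges$to %in% c("province1", "province2")))
  # and those tests are not even counted
  expect_equal(pg2$n_tests, 4 * 3 - 2)
})
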