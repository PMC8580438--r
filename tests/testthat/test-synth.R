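test_that("configuration validation catches inconsistent worlds", {
  expect_error(synth_config(n_cells = 10, K = 5, transition_width = 4),
               "transition zones")
  expect_error(synth_config(effort_range = c(500, 100)), "effort_range")
  expect_error(synth_config(shared_fraction = 1.2), "shared_fraction")
  expect_error(generate_scenario("not_a_scenario"), "unknown scenario")
})

test_that("worlds are fully deterministic given the seed", {
  cfg <- synth_config(n_cells = 20, K = 2, pool_size = 60,
                      transition_width = 2, effort_range = c(150, 400),
                      richness_range = c(40, 25))
  w1 <- generate_world(cfg, seed = 9)
  w2 <- generate_world(cfg, seed = 9)
  expect_identical(w1$records, w2$records)
  expect_identical(w1$env, w2$env)
  w3 <- generate_world(cfg, seed = 10)
  expect_false(identical(w1$records, w3$records))
})

test_that("noise injectors produce exactly the configured rejections", {
  cfg <- synth_config(n_cells = 20, K = 2, pool_size = 60,
                      transition_width = 2, effort_range = c(150, 400),
                      richness_range = c(40, 25),
                      noise_missing_epithet = 0.03,
                      noise_low_precision = 0.05)
  w <- generate_world(cfg, seed = 4)
  total <- nrow(w$records)
  out <- filter_records(w$records)
  rej <- attr(out, "rejections")
  expect_equal(unname(rej["no_species_name"]), round(0.03 * total))
  expect_equal(unname(rej["low_precision"]), round(0.05 * total))
  expect_equal(nrow(out), total - round(0.03 * total) - round(0.05 * total))
})

test_that("uniform effort at the threshold passes the cell filter exactly", {
  cfg <- synth_config(n_cells = 16, K = 2, pool_size = 80,
                      transition_width = 2, effort_range = c(150, 150),
                      richness_range = c(40, 25),
                      noise_missing_epithet = 0, noise_low_precision = 0)
  w <- generate_world(cfg, seed = 2)
  grid <- grid_records(filter_records(w$records))
  expect_true(all(grid$cells$n == 150L))
  filtered <- filter_cells(grid)
  expect_equal(nrow(filtered$cells), 16L)
})

test_that("species stay inside their province pools (no leakage)", {
  cfg <- synth_config(n_cells = 40, K = 4, pool_size = 60,
                      transition_width = 2, effort_range = c(200, 500),
                      richness_range = c(40, 25),
                      noise_missing_epithet = 0, noise_low_precision = 0)
  w <- generate_world(cfg, seed = 5)
  grid <- grid_records(filter_records(w$records))
  tr <- w$truth
  for (i in seq_len(cfg$n_cells)) {
    allowed <- unlist(tr$pools[tr$weights[i, ] > 0])
    seen <- grid$counts$species[grid$counts$cell_id == tr$cell_id[i]]
    expect_true(all(seen %in% allowed))
  }
})

test_that("a single-province world shows at most one factor", {
  cfg <- synth_config(n_cells = 30, K = 1, transition_width = 0,
                      pool_size = 150, effort_range = c(300, 1000),
                      richness_range = c(50, 40))
  w <- generate_world(cfg, seed = 8)
  cm <- ingest(w$records, w$env, min_species = 5, min_records = 100)
  v <- (cm$x > 0) + 0
  expect_lte(as.integer(parallel_analysis(t(v), seed = 3)), 1L)
})

test_that("scenario worlds encode their planted diversity drivers", {
  pm <- generate_scenario("province_mediated",
                          synth_config(n_cells = 40, K = 2, pool_size = 100,
                                       transition_width = 2,
                                       effort_range = c(300, 1000)),
                          seed = 3)
  # stepped diversity: alpha targets take exactly K distinct core values
  core <- pm$truth$province != "transition"
  expect_equal(length(unique(pm$truth$alpha_target[core])), 2L)
  de <- generate_scenario("direct_environment",
                          synth_config(n_cells = 40, K = 2, pool_size = 100,
                                       transition_width = 2,
                                       effort_range = c(300, 1000)),
                          seed = 3)
  # smooth function of realized temperature, single pool (no turnover)
  expect_equal(cor(de$truth$alpha_target, de$env$sst_mean), 1)
  expect_length(de$truth$pools, 1L)
  nf <- generate_scenario("null_flat",
                          synth_config(n_cells = 40, K = 2, pool_size = 100,
                                       transition_width = 2,
                                       effort_range = c(300, 1000)),
                          seed = 3)
  expect_equal(length(unique(nf$truth$alpha_target)), 1L)
})

test_that("generated names and coordinates satisfy the ingest contract", {
  cfg <- synth_config(n_cells = 10, K = 2, pool_size = 50,
                      transition_width = 2, effort_range = c(150, 300),
                      richness_range = c(30, 20),
                      noise_missing_epithet = 0, noise_low_precision = 0)
  w <- generate_world(cfg, seed = 1)
  expect_true(all(is_binomial(w$records$taxon_name)))
  expect_true(all(divprov:::decimal_places(w$records$lat) >= 2))
  # every record grids back into the cell it was generated for
  grid <- grid_records(w$records)
  expect_equal(sort(unique(grid$counts$cell_id)), sort(w$truth$cell_id))
  expect_equal(sum(grid$cells$n), nrow(w$records))
})
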