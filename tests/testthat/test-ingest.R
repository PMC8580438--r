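test_that("record filter enforces full binomials and stated precision", {
  recs <- occ_df(
    name = c("Nerita", "Nerita atramentosa", "Nerita atramentosa",
             "Nerita atramentosa", "Austrocochlea porcata"),
    lat = c("-33.87", "-33.9", "-33.87", "not-a-number", "-33.90"),
    lon = c("151.21", "151.21", "151.21", "151.21", "151.21"))
  out <- filter_records(recs)
  # genus-only name and 1-decimal latitude rejected; malformed rejected
  # without aborting; trailing zero counts as stated precision
  expect_equal(out$taxon_name,
               c("Nerita atramentosa", "Austrocochlea porcata"))
  rej <- attr(out, "rejections")
  expect_equal(unname(rej["no_species_name"]), 1L)
  expect_equal(unname(rej["low_precision"]), 1L)
  expect_equal(unname(rej["malformed"]), 1L)
})

test_that("record filter is idempotent and order-preserving", {
  recs <- occ_df(
    name = c("Aa bb", "Cc dd", "Ee", "Ff gg"),
    lat = c("10.11", "20.2", "30.33", "40.44"),
    lon = c("100.00", "101.01", "102.02", "103.03"))
  once <- filter_records(recs)
  twice <- filter_records(once)
  expect_equal(twice$taxon_name, once$taxon_name)
  expect_equal(once$taxon_name, c("Aa bb", "Ff gg"))
})

test_that("record filter accepts a pluggable validity list", {
  valid <- c("Aa bb")
  recs <- occ_df(c("Aa bb", "Cc dd"), c("10.11", "10.11"),
                 c("100.11", "100.11"))
  out <- filter_records(recs, name_validator = function(x) x %in% valid)
  expect_equal(out$taxon_name, "Aa bb")
})

test_that("gridding follows the half-open 0.5-degree convention", {
  expect_equal(floor_half(-33.87), -34)
  expect_equal(floor_half(-34.00), -34)  # boundary goes to its own cell
  expect_equal(floor_half(151.21), 151)
  recs <- occ_df(
    name = rep("Aa bb", 4),
    lat = c("-33.87", "-33.87", "-34.00", "-33.40"),
    lon = c("151.21", "151.21", "151.21", "151.21"))
  g <- grid_records(recs)
  cell <- g$cells[g$cells$cell_id == cell_id(-34, 151), ]
  expect_equal(cell$center_lat, -33.75)
  expect_equal(cell$center_lon, 151.25)
  # two records of one species in one cell: incidence 2, S contribution 1
  expect_equal(cell$n, 3L)   # includes the exact-boundary record
  expect_equal(cell$S, 1L)
  expect_equal(sum(g$cells$n), nrow(recs))  # conservation
})

test_that("gridding partitions records among non-overlapping cells", {
  set.seed(31)
  recs <- occ_df(rep("Aa bb", 300),
                 sprintf("%.3f", runif(300, -40, -10)),
                 sprintf("%.3f", runif(300, 110, 155)))
  g <- grid_records(recs)
  expect_equal(sum(g$cells$n), 300L)
  expect_false(anyDuplicated(g$cells$cell_id) > 0)
})

test_that("cell filter thresholds are inclusive at S = 10, n = 150", {
  cells <- data.frame(cell_id = c("a", "b", "c"),
                      n = c(200L, 149L, 150L), S = c(9L, 30L, 10L),
                      s1 = 0L, s2 = 0L, lower_lat = 0, lower_lon = 0,
                      center_lat = 0.25, center_lon = 0.25)
  grid <- structure(list(counts = data.frame(cell_id = "c", species = "x",
                                             count = 150L),
                         cells = cells), class = "occ_grid")
  out <- filter_cells(grid)
  expect_equal(out$cells$cell_id, "c")
  excl <- attr(out, "excluded")
  expect_setequal(excl$cell_id, c("a", "b"))
  expect_error(filter_cells(grid, min_species = 100), "no cells survive")
})

test_that("matrix assembly joins environment and preserves row sums", {
  recs <- occ_df(
    name = c("Aa bb", "Aa bb", "Cc dd", "Ee ff", "Gg hh", "Ii jj"),
    lat = c("10.11", "10.12", "10.13", "10.61", "10.62", "10.63"),
    lon = rep("100.11", 6))
  g <- grid_records(recs)
  env <- data.frame(cell_id = g$cells$cell_id, sst_mean = c(20, 21))
  cm <- build_matrix(g, env)
  expect_equal(dim(cm$x), c(2L, 5L))      # disjoint assemblages, 5 species
  expect_equal(unname(rowSums(cm$x)),
               as.numeric(g$cells$n[match(rownames(cm$x), g$cells$cell_id)]))
  # shared species occupy a single column
  recs2 <- occ_df(c("Aa bb", "Aa bb"), c("10.11", "10.61"), c("100.11", "100.11"))
  cm2 <- build_matrix(grid_records(recs2),
                      data.frame(cell_id = unique(cell_id(c(10, 10.5), c(100, 100))),
                                 sst_mean = c(20, 21)))
  expect_equal(ncol(cm2$x), 1L)
  # env missing a retained cell: dropped with warning
  expect_warning(cm3 <- build_matrix(g, env[1, , drop = FALSE]),
                 "lack environmental data")
  expect_equal(nrow(cm3$x), 1L)
  # duplicated env cell errors
  expect_error(build_matrix(g, rbind(env, env[1, ])), "duplicate cell_id")
})
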