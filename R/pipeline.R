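# End-to-end orchestration: synth/ingest -> diversity -> bioregion ->
# models -> nullsim, with one master seed, per-stage outputs, and a manifest
# recording input/output hashes so a run is reproducible and auditable.

#' Read a pipeline run configuration
#'
#' A flat YAML file with one block per stage; unspecified keys fall back to
#' the documented stage defaults. See [run_all()] for the keys.
#'
#' @param path path to a YAML file.
#' @return a named list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Export cells with their dominant province as GeoJSON
#'
#' One polygon feature per 0.5-degree cell with its dominant factor and
#' maximum loading as properties, for mapping.
#'
#' @param cells cells data.frame (`lower_lat`, `lower_lon`, `cell_id`).
#' @param dominant output of [dominant_factor()] aligned by `cell_id`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_cells_geojson <- function(cells, dominant, path) {
  dom <- dominant[match(cells$cell_id, dominant$cell_id), ]
  features <- lapply(seq_len(nrow(cells)), function(i) {
    la <- cells$lower_lat[i]; lo <- cells$lower_lon[i]
    ring <- list(c(lo, la), c(lo + 0.5, la), c(lo + 0.5, la + 0.5),
                 c(lo, la + 0.5), c(lo, la))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(cell_id = cells$cell_id[i],
                           province = dom$province[i],
                           max_loading = dom$max_loading[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes the stages in order, writing each stage's outputs as CSV under
#' `config$out_dir` and a `manifest.json` recording per-stage status,
#' output files and their MD5 hashes. A stage failure is recorded in the
#' manifest, later stages are not attempted, and completed-stage outputs are
#' left intact. All randomness derives from `config$seed` through named
#' per-stage substreams, so the same configuration yields byte-identical
#' outputs.
#'
#' Recognized keys (all optional except `out_dir` and one of
#' `input`/`synth`):
#' \describe{
#'   \item{out_dir}{output directory (created).}
#'   \item{seed}{master seed (default 1).}
#'   \item{input}{list(`occurrences`, `env`): paths to CSV inputs.}
#'   \item{synth}{list(`scenario`, plus any [synth_config()] argument):
#'     generate the inputs instead.}
#'   \item{ingest}{list(`min_species`, `min_records`, `min_decimals`).}
#'   \item{diversity}{list(`quorum`).}
#'   \item{bioregion}{list(`n_factors` ("auto" or integer), `n_random`,
#'     `pam_k` ("auto" or integer), `run_ca`).}
#'   \item{models}{list(`alpha`, `metrics`, `k_neighbors`, `model`,
#'     `log_response`, `path_alpha`, `key_size`).}
#'   \item{nullsim}{list(`enabled`, `n_reps`, `metric`).}
#' }
#'
#' @param config configuration list or path to a YAML file.
#' @return the manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$out_dir)) abort("config$out_dir is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  stage_seeds <- spawn_seeds(seed, 6L)
  manifest <- list(seed = seed, started = "run", stages = list())
  state <- new.env()

  record <- function(name, files) {
    manifest$stages[[name]] <<- list(
      status = "complete",
      outputs = as.list(tools::md5sum(unlist(files))))
  }
  fail <- function(name, e) {
    manifest$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(e))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }

  stages <- list(
    inputs = function() {
      if (!is.null(config$synth)) {
        sc <- config$synth
        scenario <- sc$scenario %||% "gradient"
        sc$scenario <- NULL
        cfg <- do.call(synth_config, sc)
        world <- generate_world(cfg, seed = stage_seeds[1], scenario = scenario)
        state$records <- world$records
        state$env <- world$env
        state$world <- world
        c(write_stage_csv(world$records, config$out_dir, "occurrences.csv"),
          write_stage_csv(world$env, config$out_dir, "env.csv"))
      } else {
        if (is.null(config$input$occurrences) || is.null(config$input$env))
          abort("config$input must name 'occurrences' and 'env' files")
        if (!file.exists(config$input$occurrences))
          abort("missing occurrence file: ", config$input$occurrences)
        if (!file.exists(config$input$env))
          abort("missing env file: ", config$input$env)
        state$records <- read_occurrences(config$input$occurrences)
        state$env <- read_env(config$input$env)
        character(0)
      }
    },
    ingest = function() {
      p <- config$ingest %||% list()
      state$cm <- ingest(state$records, state$env,
                         min_decimals = p$min_decimals %||% 2L,
                         min_species = p$min_species %||% 10L,
                         min_records = p$min_records %||% 150L)
      triplets <- data.frame(
        cell_id = rep(rownames(state$cm$x), ncol(state$cm$x)),
        species = rep(colnames(state$cm$x), each = nrow(state$cm$x)),
        count = as.vector(state$cm$x))
      triplets <- triplets[triplets$count > 0, ]
      c(write_stage_csv(triplets, config$out_dir, "matrix.csv"),
        write_stage_csv(state$cm$cells, config$out_dir, "cells.csv"))
    },
    diversity = function() {
      p <- config$diversity %||% list()
      state$div <- diversity_table(state$cm, quorum = p$quorum %||% 0.5)
      write_stage_csv(state$div, config$out_dir, "diversity.csv")
    },
    bioregion = function() {
      p <- config$bioregion %||% list()
      nf <- p$n_factors %||% "auto"
      state$fs <- bioregion_fa(state$cm,
                               n_factors = if (identical(nf, "auto")) NULL else as.integer(nf),
                               seed = stage_seeds[3],
                               n_random = p$n_random %||% 100L)
      dom <- dominant_factor(state$fs)
      loadings <- data.frame(cell_id = rownames(state$fs$loadings),
                             state$fs$loadings, row.names = NULL)
      files <- c(write_stage_csv(loadings, config$out_dir,
                                 "province_loadings.csv"))
      k <- p$pam_k %||% "auto"
      k <- if (identical(k, "auto")) state$fs$n_factors else as.integer(k)
      cl <- pam_cluster(cell_dissimilarity(state$cm), k)
      clusters <- data.frame(cell_id = rownames(state$cm$x),
                             cluster = match(cl$assignment, cl$medoids))
      files <- c(files, write_stage_csv(clusters, config$out_dir,
                                        "clusters.csv"))
      if (isTRUE(p$run_ca %||% TRUE)) {
        ca <- correspondence_analysis(state$cm)
        ca_df <- data.frame(cell_id = rownames(ca$row_scores), ca$row_scores,
                            row.names = NULL)
        files <- c(files, write_stage_csv(ca_df, config$out_dir,
                                          "ca_scores.csv"))
      }
      files <- c(files, write_cells_geojson(state$cm$cells, dom,
                                            file.path(config$out_dir,
                                                      "provinces.geojson")))
      files
    },
    models = function() {
      p <- config$models %||% list()
      metrics <- p$metrics %||% c("fisher_alpha", "simpson_D", "cJ1", "sqs")
      state$ab <- abiotic_fa(state$cm$env)
      suite1 <- model_suite(state$div, state$ab, provinces = NULL,
                            coords = state$cm$cells, metrics = metrics,
                            alpha = p$alpha %||% 0.001,
                            model = p$model %||% "error",
                            k_neighbors = p$k_neighbors %||% 5L,
                            log_response = p$log_response %||% TRUE)
      suite2 <- model_suite(state$div, state$ab,
                            provinces = state$fs$loadings,
                            coords = state$cm$cells, metrics = metrics,
                            alpha = p$alpha %||% 0.001,
                            model = p$model %||% "error",
                            k_neighbors = p$k_neighbors %||% 5L,
                            log_response = p$log_response %||% TRUE)
      key <- select_key_variables(state$ab, key_size = p$key_size %||% 7L)
      node_df <- data.frame(latitude = state$cm$cells$center_lat)
      env_keys <- setdiff(key, "latitude")
      node_df <- cbind(node_df, state$cm$env[, env_keys, drop = FALSE])
      P <- state$fs$loadings
      colnames(P) <- paste0("province", seq_len(ncol(P)))
      node_df <- cbind(node_df, P)
      node_df$diversity <- state$div$fisher_alpha
      node_df <- node_df[stats::complete.cases(node_df), ]
      state$paths <- path_suite(node_df, colnames(P),
                                alpha = p$path_alpha %||% 0.01)
      c(write_stage_csv(suite_table(suite1), config$out_dir,
                        "model_abiotic.csv"),
        write_stage_csv(suite_table(suite2), config$out_dir,
                        "model_combined.csv"),
        write_stage_csv(state$paths$edges, config$out_dir, "path_edges.csv"))
    },
    nullsim = function() {
      p <- config$nullsim %||% list()
      if (!isTRUE(p$enabled %||% FALSE)) return(character(0))
      ne <- null_experiment(state$cm, state$div,
                            n_reps = p$n_reps %||% 100L,
                            n_factors = state$fs$n_factors,
                            seed = stage_seeds[6],
                            metric = p$metric %||% "fisher_alpha")
      c(write_stage_csv(ne$summary, config$out_dir, "null_summary.csv"),
        write_stage_csv(ne$replicates, config$out_dir,
                        "null_replicates.csv"))
    })

  for (name in names(stages)) {
    result <- tryCatch(stages[[name]](), error = function(e) e)
    if (inherits(result, "error")) {
      fail(name, result)
      warning("stage '", name, "' failed: ", conditionMessage(result),
              call. = FALSE)
      return(invisible(manifest))
    }
    record(name, result)
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
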