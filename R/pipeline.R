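# Pipeline orchestration: run the full analysis over a substance table (or a
# freshly generated synthetic space) and write a reproducible report bundle.

#' Pipeline run configuration
#'
#' Assembles and validates the configuration of [run_pipeline()]. Either
#' `input` (a substance-table path) or `generate` (a [space_config()]) must
#' be given. All stochastic stages require `seed`.
#'
#' @param out_dir output directory (created if missing).
#' @param input path to a substance table (see [read_substances()]), or NULL.
#' @param generate a [space_config()] for synthetic input, or NULL.
#' @param weight_tables path to a weight-table file (see
#'   [read_weight_tables()]); NULL skips the retrodiction stage.
#' @param discovery optional path to an element discovery-year table
#'   (columns `element`, `year`).
#' @param sce_years years at which SCE networks are built and compared;
#'   default: every 5th year of the window plus the final year.
#' @param backbone_threshold ubiquity percentage for [backbone()].
#' @param ubiquity_year,ubiquity_sizes,ubiquity_reps ubiquity stage settings;
#'   `ubiquity_year` defaults to the final window year.
#' @param taus tolerance sweep for retrodiction.
#' @param seed master seed for all stochastic stages.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(out_dir, input = NULL, generate = NULL,
                       weight_tables = NULL, discovery = NULL,
                       sce_years = NULL, backbone_threshold = 60,
                       ubiquity_year = NULL,
                       ubiquity_sizes = seq(5, 95, by = 5),
                       ubiquity_reps = 100,
                       taus = seq(0.01, 0.20, by = 0.01), seed = NULL) {
  if (is.null(input) && is.null(generate))
    .stopf("run_config needs either an input substance table or a generator config")
  for (p in c(input, weight_tables, discovery))
    if (!is.null(p) && !file.exists(p)) .stopf("input path does not exist: %s", p)
  if (is.null(seed)) .stopf("a master seed is mandatory (stochastic stages)")
  structure(list(out_dir = out_dir, input = input, generate = generate,
                 weight_tables = weight_tables, discovery = discovery,
                 sce_years = sce_years, backbone_threshold = backbone_threshold,
                 ubiquity_year = ubiquity_year, ubiquity_sizes = ubiquity_sizes,
                 ubiquity_reps = ubiquity_reps, taus = taus,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [run_config()]; the
#' `generate` section, when present, is passed to [space_config()].
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$generate)) y$generate <- do.call(space_config, y$generate)
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes the pipeline stages over the configured chemical space and
#' writes a report bundle into `out_dir`: per-year statistics, the
#' final-year similarity matrix, per-year SCE networks (GraphML + JSON),
#' the year-by-year overlap matrix, the backbone table, the ubiquity table
#' and (when weight tables are configured) the retrodiction score sweep. A
#' `manifest.json` records package version, seed, parameters and the status
#' of every artifact; a failing stage aborts with a stage-named error after
#' writing the manifest with a FAILED marker for that stage.
#'
#' @param config a [run_config()] or path to a YAML file for
#'   [read_run_config()].
#' @param stages which stages to run: subset of `"generate"`, `"stats"`,
#'   `"sce"`, `"compare"`, `"backbone"`, `"ubiquity"`, `"retrodict"`, or
#'   `"all"` (default). Stages compose: running them individually against
#'   the same `out_dir` equals one `"all"` run.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, stages = "all") {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("generate", "stats", "sce", "compare", "backbone",
                  "ubiquity", "retrodict")
  if (identical(stages, "all")) stages <- all_stages
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "chemspacer",
                   version = as.character(utils::packageVersion("chemspacer")),
                   seed = config$seed,
                   parameters = config[setdiff(names(config), "out_dir")],
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   artifacts = list())
  note <- function(name, file, status, ...) {
    manifest$artifacts[[name]] <<- c(list(file = file, status = status), list(...))
  }
  flush_manifest <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE, pretty = TRUE)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      note(name, NA_character_, "FAILED", error = conditionMessage(e))
      flush_manifest()
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # -- input / generate ------------------------------------------------------
  if (!is.null(config$generate)) {
    gen <- run_stage("generate", generate_space(config$generate))
    space <- gen$space
    if ("generate" %in% stages) {
      f <- file.path(config$out_dir, "substances.csv")
      write_substances(space, f)
      data.table::fwrite(gen$truth, file.path(config$out_dir, "planted_truth.csv"))
      note("substances", f, "OK", n = n_substances(space),
           seed = config$generate$seed)
    }
  } else {
    space <- run_stage("load", read_substances(config$input))
  }
  discovery <- if (!is.null(config$discovery))
    data.table::fread(config$discovery) else NULL
  yr <- space$window
  sce_years <- config$sce_years %||% unique(c(seq(yr[1], yr[2], by = 5), yr[2]))

  if ("stats" %in% stages) run_stage("stats", {
    ys <- year_stats(space, discovery)
    f <- file.path(config$out_dir, "year_stats.csv")
    data.table::fwrite(ys, f)
    cc <- space$substances[, .N, by = .(year, combination)]
    f2 <- file.path(config$out_dir, "combination_counts.csv")
    data.table::fwrite(cc[order(year, combination)], f2)
    note("year_stats", f, "OK", n_years = nrow(ys))
    note("combination_counts", f2, "OK")
  })

  networks <- NULL
  get_networks <- function() {
    if (is.null(networks)) networks <<- sce_series(space, sce_years)
    networks
  }

  if ("sce" %in% stages) run_stage("sce", {
    nets <- get_networks()
    dir.create(file.path(config$out_dir, "sce"), showWarnings = FALSE)
    for (y in names(nets)) {
      write_sce_graphml(nets[[y]], file.path(config$out_dir, "sce",
                                             paste0("sce_", y, ".graphml")))
      write_sce_json(nets[[y]], file.path(config$out_dir, "sce",
                                          paste0("sce_", y, ".json")))
    }
    sm <- similarity_matrix(space, yr[2])
    f <- file.path(config$out_dir, paste0("similarity_", yr[2], ".csv"))
    data.table::fwrite(sm, f)
    note("sce_networks", file.path(config$out_dir, "sce"), "OK",
         years = names(nets))
    note("similarity_matrix", f, "OK", n_pairs = nrow(sm))
  })

  if ("compare" %in% stages) run_stage("compare", {
    m <- overlap_matrix(get_networks())
    f <- file.path(config$out_dir, "overlap_matrix.csv")
    data.table::fwrite(data.table::as.data.table(m, keep.rownames = "year"), f)
    note("overlap_matrix", f, "OK", n_years = nrow(m))
  })

  if ("backbone" %in% stages) run_stage("backbone", {
    bb <- backbone(get_networks(), threshold = config$backbone_threshold,
                   end_year = yr[2])
    f <- file.path(config$out_dir, "backbone.csv")
    data.table::fwrite(bb, f)
    note("backbone", f, "OK", threshold = config$backbone_threshold,
         n_edges = nrow(bb))
  })

  if ("ubiquity" %in% stages) run_stage("ubiquity", {
    uy <- config$ubiquity_year %||% yr[2]
    ub <- ubiquity(space, uy, sample_sizes = config$ubiquity_sizes,
                   reps = config$ubiquity_reps, seed = config$seed)
    f <- file.path(config$out_dir,
                   sprintf("ubiquity_%d_seed%d.csv", uy, config$seed))
    data.table::fwrite(ub, f)
    note("ubiquity", f, "OK", year = uy, reps = config$ubiquity_reps,
         seed = config$seed)
  })

  if ("retrodict" %in% stages) {
    if (is.null(config$weight_tables)) {
      note("retro_scores", NA_character_, "SKIPPED",
           reason = "no weight tables configured")
    } else run_stage("retrodict", {
      tabs <- read_weight_tables(config$weight_tables)
      sc <- data.table::rbindlist(lapply(tabs, function(A)
        retro_score_sweep(space, A, taus = config$taus,
                          reference_year = yr[2])))
      f <- file.path(config$out_dir, "retro_scores.csv")
      data.table::fwrite(sc, f)
      note("retro_scores", f, "OK", chemists = names(tabs))
    })
  }

  flush_manifest()
  invisible(manifest)
}
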