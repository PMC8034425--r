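#' @title End-to-end pipeline orchestration
#' @name pipeline
#' @description
#' Runs the analysis stages (descriptors, screen analysis, fingerprint
#' comparison, target consensus, genomics statistics, network enrichment)
#' in dependency order from a single configuration, writing one CSV per
#' stage plus a run-metadata record. Stages can be toggled; disabled
#' stages are skipped. Identical configuration + seed produces
#' byte-identical outputs.
NULL

#' Default pipeline configuration
#'
#' All stages enabled on synthetic inputs (the packaged structure fixture
#' for descriptors, generated data elsewhere).
#'
#' @param out_dir output directory.
#' @param seed root seed; stages derive child seeds by fixed offsets.
#' @return Named list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(out_dir = tempfile("screenkit_run_"),
                                    seed = 1) {
  list(
    out_dir = out_dir,
    seed = seed,
    stages = list(descriptors = TRUE, screen = TRUE, compare = TRUE,
                  consensus = TRUE, genomics = TRUE, network = TRUE),
    descriptors = list(
      sdf = system.file("extdata", "nsc765598.mol", package = "screenkit"),
      logp = 4.867901, molar_refractivity = 87.77),
    screen = list(plates_tsv = NULL, n_lines = 60),
    compare = list(library_csv = NULL, endpoint = "GI50",
                   min_common = 25, top_k = 15),
    consensus = list(predictor_csvs = NULL, min_predictors = 3),
    genomics = list(matrix_tsv = NULL, survival_tsv = NULL,
                    index_gene = "EGFR"),
    network = list(edges_tsv = NULL, gmt = NULL, confidence_min = 0.9,
                   background = 20531))
}

#' Load a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_pipeline_config()].
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  base <- default_pipeline_config()
  modify <- function(base, user) {
    for (nm in names(user)) {
      base[[nm]] <- if (is.list(user[[nm]]) && is.list(base[[nm]]))
        modify(base[[nm]], user[[nm]]) else user[[nm]]
    }
    base
  }
  modify(base, user)
}

.stage_log <- function(...) message("[screenkit] ", ...)

.need_file <- function(path, what) {
  if (!is.null(path) && !file.exists(path))
    stop("stage '", what, "': input path does not exist: ", path)
  path
}

#' Run the pipeline
#'
#' Executes the enabled stages in dependency order. Each stage writes one
#' CSV into `config$out_dir`; a failing stage aborts with the stage named,
#' retaining the outputs already written. Inputs left `NULL` in the
#' configuration are generated synthetically from the stage's child seed.
#'
#' @param config configuration list from [default_pipeline_config()] or
#'   [read_pipeline_config()].
#' @return Invisible list of class `pipeline_bundle`: per-stage result
#'   objects plus `outputs` (named vector of written files).
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  bundle <- list()
  emit <- function(name, df) {
    path <- file.path(config$out_dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    outputs[[name]] <<- path
  }
  run_stage <- function(name, fn) {
    if (!isTRUE(config$stages[[name]])) return(invisible(NULL))
    .stage_log("stage ", name, " ...")
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    .stage_log("stage ", name, " done (",
               format(round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)),
               " s)")
    bundle[[name]] <<- res
    res
  }

  run_stage("descriptors", function() {
    cfg <- config$descriptors
    mols <- read_sdf(.need_file(cfg$sdf, "descriptors"))
    d <- do.call(rbind, lapply(mols, descriptor_set,
                               logp = cfg$logp,
                               molar_refractivity = cfg$molar_refractivity))
    emit("descriptors", d)
    d
  })

  screen_res <- run_stage("screen", function() {
    cfg <- config$screen
    plates <- if (!is.null(cfg$plates_tsv))
      read_plates_tsv(.need_file(cfg$plates_tsv, "screen"))
    else gen_dose_plates(n_lines = cfg$n_lines,
                         seed = child_seed(config$seed, 101))$plates
    s <- summarize_screen(plates)
    emit("screen_params", s$params)
    emit("screen_panel_ranges", s$panel_ranges)
    s
  })

  run_stage("compare", function() {
    cfg <- config$compare
    if (is.null(screen_res)) stop("compare requires the screen stage")
    seed_fp <- to_fingerprint(screen_res, cfg$endpoint)
    lib <- if (!is.null(cfg$library_csv))
      read_fingerprint_csv(.need_file(cfg$library_csv, "compare"), cfg$endpoint)
    else {
      gl <- gen_fingerprint_library(n_lines = nrow(screen_res$params),
                                    endpoint = cfg$endpoint,
                                    seed = child_seed(config$seed, 202))
      lapply(gl$library, function(f) {
        names(f$values) <- screen_res$params$cell_line
        f
      })
    }
    hits <- rank_library(seed_fp, lib, min_common = cfg$min_common,
                         top_k = cfg$top_k)
    emit("compare_hits", hits)
    hits
  })

  run_stage("consensus", function() {
    cfg <- config$consensus
    entries <- if (!is.null(cfg$predictor_csvs))
      read_predictor_csvs(vapply(cfg$predictor_csvs, .need_file, "",
                                 what = "consensus"))
    else gen_predictor_outputs(fixture = TRUE)$entries
    cons <- consensus_rank(entries, min_predictors = cfg$min_predictors)
    emit("consensus_targets", cons)
    cons
  })

  run_stage("genomics", function() {
    cfg <- config$genomics
    m <- if (!is.null(cfg$matrix_tsv))
      read_alteration_tsv(.need_file(cfg$matrix_tsv, "genomics"))
    else gen_alteration_matrix(seed = child_seed(config$seed, 303))$matrix
    enr <- cooccurrence_enrichment(m, cfg$index_gene)
    emit("genomics_enrichment", enr)
    surv <- if (!is.null(cfg$survival_tsv))
      read_survival_tsv(.need_file(cfg$survival_tsv, "genomics"))
    else gen_survival(seed = child_seed(config$seed, 304))$records
    lr <- logrank_test(surv$time_months, surv$event, surv$group)
    emit("genomics_survival",
         data.frame(chi2 = lr$chi2, p = lr$p, hr = lr$hr,
                    hr_lo = lr$hr_ci[1], hr_hi = lr$hr_ci[2]))
    list(enrichment = enr, logrank = lr)
  })

  run_stage("network", function() {
    cfg <- config$network
    g <- if (!is.null(cfg$edges_tsv))
      read_edges_tsv(.need_file(cfg$edges_tsv, "network"))
    else demo_ppi_network()
    gs <- graph_summary(g, confidence_min = cfg$confidence_min)
    hubs <- hub_nodes(g, 3, among = c("MTOR", "MAP2K1", "EGFR", "FGFR1",
                                      "TGFB1", "NOS2"),
                      confidence_min = cfg$confidence_min)
    emit("network_summary",
         cbind(data.frame(n_nodes = gs$n_nodes, n_edges = gs$n_edges,
                          avg_degree = gs$avg_degree,
                          avg_local_clustering = gs$avg_local_clustering),
               hub1 = hubs$gene[1], hub2 = hubs$gene[2], hub3 = hubs$gene[3]))
    list(summary = gs, hubs = hubs)
  })

  meta <- data.frame(
    seed = config$seed,
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))),
    screenkit_version = as.character(utils::packageVersion("screenkit")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  utils::write.csv(meta, file.path(config$out_dir, "run_metadata.csv"),
                   row.names = FALSE)
  outputs[["run_metadata"]] <- file.path(config$out_dir, "run_metadata.csv")
  bundle$outputs <- outputs
  invisible(structure(bundle, class = "pipeline_bundle"))
}

#' Render a text report from a pipeline bundle
#'
#' Deterministic plain-text tables, one section per stage present in the
#' bundle. Re-rendering the same bundle gives identical text.
#'
#' @param bundle result of [run_pipeline()].
#' @return Character vector of report lines (invisibly printable via
#'   `cat(..., sep = "\n")`).
#' @export
render_report <- function(bundle) {
  lines <- c("screenkit pipeline report",
             "=========================")
  section <- function(title, body) c("", title, strrep("-", nchar(title)), body)
  df_lines <- function(d, n = 10) utils::capture.output(print(utils::head(d, n)))
  if (!is.null(bundle$descriptors))
    lines <- c(lines, section("Drug-likeness descriptors",
                              df_lines(bundle$descriptors)))
  if (!is.null(bundle$screen))
    lines <- c(lines, section("Screen endpoint summary (uM)",
                              df_lines(bundle$screen$panel_ranges, 30)))
  if (!is.null(bundle$compare))
    lines <- c(lines, section("Fingerprint comparison (top hits)",
                              df_lines(bundle$compare)))
  if (!is.null(bundle$consensus))
    lines <- c(lines, section("Consensus targets",
                              df_lines(bundle$consensus)))
  if (!is.null(bundle$genomics))
    lines <- c(lines, section("Alteration co-occurrence enrichment",
                              df_lines(bundle$genomics$enrichment)))
  if (!is.null(bundle$network)) {
    gs <- bundle$network$summary
    lines <- c(lines, section("Interaction network",
      c(sprintf("nodes: %d  edges: %d  avg degree: %.1f  avg clustering: %.3f",
                gs$n_nodes, gs$n_edges, gs$avg_degree,
                gs$avg_local_clustering),
        df_lines(bundle$network$hubs))))
  }
  lines
}
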