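#' Run the full trait-network pipeline into an output directory
#'
#' Orchestrates every stage — data input (file or simulation), optional
#' aggregation, log-transform, network construction, metrics, importance,
#' bootstrap, rarefaction, group comparison — and writes a deterministic
#' directory tree:
#' \preformatted{
#'   out_dir/
#'     config.yaml            copy of the resolved configuration (provenance)
#'     run.log                seed, package versions, stage timings, retries
#'     data/trait_table.csv   the analysed table (and ground_truth.json for
#'                            simulated data)
#'     networks/              edge list CSV, GraphML, r/p matrices
#'     metrics/               per-trait metrics CSV, scalar JSON, importance
#'     summaries/             bootstrap and rarefaction summary CSVs
#'     tests/                 group t-tests CSV, Duncan letters CSVs
#'     figures/               network, degree, importance, rarefaction plots,
#'                            each with a CSV twin of the plotted numbers
#' }
#' Given the same configuration and seed, every CSV output is byte-identical
#' across runs.
#'
#' @param config A named list, or path to a YAML/JSON file holding one, with
#'   any of the elements: `input` (CSV path) or `simulate` (argument list for
#'   [simulate_traits()]); `traits`; `id_col`; `aggregate_by`; `log`
#'   (default `TRUE`); `alpha` (default 0.05); `method` (community detection,
#'   default `"greedy"`); `bootstrap` (list: `B`, `fraction_min`);
#'   `rarefaction` (list: `counts`, `R`, `replace`); `compare` (list: `by`,
#'   `aridity_boundary`, `B`); `seed` (required).
#' @param out_dir Output directory (created; existing files overwritten).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_ptn_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) abort("`config` must be a list or a path to a YAML/JSON file")
  if (is.null(config$seed)) abort("config must set `seed`")
  alpha <- config$alpha %||% 0.05
  cd_method <- config$method %||% "greedy"
  do_log <- config$log %||% TRUE

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
    log_lines <<- c(log_lines, sprintf("stage %-12s %.2fs", name,
                                       as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("data", "networks", "metrics", "summaries", "tests", "figures")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  log_lines <- c(
    sprintf("ptnet %s | R %s.%s | igraph %s", utils::packageVersion("ptnet"),
            R.version$major, R.version$minor, utils::packageVersion("igraph")),
    sprintf("seed %d", as.integer(config$seed))
  )
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))

  # --- input -----------------------------------------------------------------
  data <- stage("input", {
    if (!is.null(config$input)) {
      read_trait_table(config$input, traits = config$traits, id_col = config$id_col)
    } else if (!is.null(config$simulate)) {
      args <- config$simulate
      args$seed <- args$seed %||% config$seed
      do.call(simulate_traits, args)
    } else {
      abort("config needs `input` (a CSV path) or `simulate` (generator arguments)")
    }
  })
  traits <- resolve_traits(data, config$traits)
  write_trait_table(data, file.path(out_dir, "data", "trait_table.csv"))
  truth <- ptn_truth(data)
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(membership = as.list(truth$membership), hub_trait = truth$hub_trait,
           sigma = truth$sigma, seed = truth$seed),
      file.path(out_dir, "data", "ground_truth.json"),
      auto_unbox = TRUE, digits = NA, matrix = "columnmajor")
  }

  if (!is.null(config$aggregate_by)) {
    data <- stage("aggregate", aggregate_records(data, config$aggregate_by, traits))
  }
  ldata <- if (do_log) stage("log", log_transform(data, traits)) else data

  # --- network + metrics -----------------------------------------------------
  net <- stage("network", threshold_network(ldata, alpha = alpha, traits = traits))
  write_ptn_edges(net, file.path(out_dir, "networks", "edges.csv"))
  write_ptn_graphml(net, file.path(out_dir, "networks", "network.graphml"))
  write_ptn_matrices(net, file.path(out_dir, "networks", "correlation.csv"))

  metrics <- stage("metrics", network_metrics(
    net, method = cd_method,
    seed = if (cd_method == "louvain") config$seed else NULL))
  write_ptn_metrics(metrics,
                    csv_path = file.path(out_dir, "metrics", "trait_metrics.csv"),
                    json_path = file.path(out_dir, "metrics", "network_metrics.json"))
  categories <- if (all(traits %in% trait_categories()$trait)) trait_categories()
  importance <- NULL
  if (!is.null(categories)) {
    importance <- trait_importance(metrics, categories)
    readr::write_csv(importance, file.path(out_dir, "metrics", "importance.csv"),
                     progress = FALSE)
  }

  # --- bootstrap -------------------------------------------------------------
  bcfg <- config$bootstrap %||% list()
  boot <- stage("bootstrap", bootstrap_ptn(
    ldata, B = bcfg$B %||% 1000, fraction_min = bcfg$fraction_min %||% 0.75,
    alpha = alpha, method = cd_method, traits = traits, seed = config$seed))
  readr::write_csv(tidy(boot), file.path(out_dir, "summaries", "bootstrap.csv"),
                   progress = FALSE)
  log_lines <- c(log_lines, sprintf("bootstrap retries %d", boot$retries))
  duncan_deg <- stage("duncan", duncan_mrt(
    boot$replicates |>
      dplyr::filter(.data$parameter == "degree") |>
      dplyr::transmute(item = .data$trait, value = .data$value),
    alpha = alpha))
  readr::write_csv(tidy(duncan_deg), file.path(out_dir, "tests", "degree_letters.csv"),
                   progress = FALSE)

  # --- rarefaction -----------------------------------------------------------
  rar <- NULL
  if (!isFALSE(config$rarefaction)) {
    rcfg <- if (is.list(config$rarefaction)) config$rarefaction else list()
    rar <- stage("rarefaction", rarefy_ptn(
      ldata, counts = rcfg$counts, R = rcfg$R %||% 500,
      alpha = alpha, replace = rcfg$replace %||% TRUE,
      method = cd_method, traits = traits, seed = config$seed))
    readr::write_csv(tidy(rar), file.path(out_dir, "summaries", "rarefaction.csv"),
                     progress = FALSE)
  }

  # --- group comparison ------------------------------------------------------
  comp <- NULL
  ccfg <- config$compare
  if (!is.null(ccfg)) {
    comp <- stage("compare", compare_group_ptns(
      data, by = ccfg$by %||% "life_form",
      aridity_boundary = ccfg$aridity_boundary %||% 0.2,
      B = ccfg$B %||% 500, alpha = alpha, method = cd_method,
      traits = traits, log = do_log, seed = config$seed))
    if (nrow(comp$tests)) {
      readr::write_csv(
        tidy(comp), file.path(out_dir, "tests", "group_tests.csv"),
        progress = FALSE)
    }
    for (g in names(comp$groups)) {
      res <- comp$groups[[g]]
      write_ptn_edges(res$net, file.path(out_dir, "networks", paste0("edges_", g, ".csv")))
      readr::write_csv(tidy(res$boot),
                       file.path(out_dir, "summaries", paste0("bootstrap_", g, ".csv")),
                       progress = FALSE)
      readr::write_csv(tidy(res$duncan_degree),
                       file.path(out_dir, "tests", paste0("degree_letters_", g, ".csv")),
                       progress = FALSE)
    }
  }

  # --- figures (each with a CSV twin of the plotted numbers) -----------------
  stage("figures", {
    save_fig <- function(gg, name, twin) {
      ggplot2::ggsave(file.path(out_dir, "figures", paste0(name, ".png")), gg,
                      width = 7, height = 5, dpi = 150)
      readr::write_csv(twin, file.path(out_dir, "figures", paste0(name, ".csv")),
                       progress = FALSE)
    }
    save_fig(plot_ptn(net, metrics), "network", tidy(metrics))
    save_fig(plot_degree(boot, duncan_deg), "degree",
             dplyr::filter(tidy(boot), .data$parameter == "degree"))
    if (!is.null(importance)) save_fig(plot_importance(importance), "importance", importance)
    if (!is.null(rar)) save_fig(autoplot(rar), "rarefaction", tidy(rar))
    invisible(NULL)
  })

  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(data = data, network = net, metrics = metrics,
                 importance = importance, bootstrap = boot,
                 duncan_degree = duncan_deg, rarefaction = rar,
                 comparison = comp, out_dir = out_dir))
}
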