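#' Pipeline configuration
#'
#' Bundles every stage's settings into one validated object. Exactly one
#' data source must be given: either a response table on disk (analyze
#' mode: `responses_path`, with demographics in the same file or in
#' `participants_path`) or a [sim_config()] (simulate mode). The master
#' `seed` drives every random stage through deterministic substreams — in
#' simulate mode it also overrides the simulation config's own seed, so one
#' integer reproduces the whole bundle.
#'
#' @param quiz_source `"table1"` or a quiz CSV path.
#' @param responses_path,participants_path CSVs for analyze mode.
#' @param simulation A [sim_config()] for simulate mode.
#' @param k_grid Crowd sizes for the convergence curve.
#' @param n_draws Random crowds per size in the convergence curve.
#' @param bootstrap_k1,bootstrap_k2,bootstrap_B Crowd-size comparison test
#'   settings (defaults compare 10 vs 1000, capped at the cohort size).
#' @param aggregator Crowd aggregator, `"mean"` or `"median"`.
#' @param models Registered bias models to fit (default all).
#' @param network_threshold Edge threshold for the food graph.
#' @param cluster_cut Tree-cut height for food clustering.
#' @param seed Master integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(quiz_source = "table1",
                            responses_path = NULL,
                            participants_path = NULL,
                            simulation = NULL,
                            k_grid = c(1, 2, 5, 10, 20, 50, 100, 200, 500,
                                       1000),
                            n_draws = 100,
                            bootstrap_k1 = 10, bootstrap_k2 = 1000,
                            bootstrap_B = 1000,
                            aggregator = c("mean", "median"),
                            models = bias_models(),
                            network_threshold = 0.3,
                            cluster_cut = 0.7,
                            seed = 1L) {
  aggregator <- match.arg(aggregator)
  has_file <- !is.null(responses_path)
  has_sim <- !is.null(simulation)
  if (has_file == has_sim) {
    abort("exactly one of responses_path / simulation must be supplied")
  }
  if (has_sim && !inherits(simulation, "sim_config")) {
    abort("simulation must be a sim_config() object")
  }
  bad <- setdiff(models, bias_models())
  if (length(bad) > 0) {
    abort(sprintf("unknown bias model(s): %s", paste(bad, collapse = ", ")))
  }
  structure(
    list(quiz_source = quiz_source, responses_path = responses_path,
         participants_path = participants_path, simulation = simulation,
         k_grid = k_grid, n_draws = n_draws,
         bootstrap_k1 = bootstrap_k1, bootstrap_k2 = bootstrap_k2,
         bootstrap_B = bootstrap_B, aggregator = aggregator,
         models = models, network_threshold = network_threshold,
         cluster_cut = cluster_cut, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s",
                  stage, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes load -> (simulate) -> QC -> metrics -> crowd -> bias models ->
#' error network, writing one artifact file per stage under `out_dir` plus a
#' `manifest.json` (package version, seed, QC report, MD5 checksum of every
#' artifact) and a `report.json` bundling the headline numbers. Identical
#' config and seed produce a byte-identical bundle.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every stage's in-memory result and the
#'   artifact paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character()
  add_path <- function(name, file) {
    paths[[name]] <<- file
    file
  }

  quiz <- run_stage("load_quiz", load_quiz(config$quiz_source))
  write_quiz_json(quiz, add_path("quiz", file.path(out_dir, "quiz.json")))

  cohort <- if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$seed <- config$seed
    run_stage("simulate", simulate_cohort(quiz, sim))
  } else {
    run_stage("read_responses",
              read_responses(config$responses_path,
                             config$participants_path, quiz = quiz))
  }
  files <- write_responses(cohort$participants, cohort$responses, out_dir)
  add_path("participants", files[["participants"]])
  add_path("responses", files[["responses"]])

  qc <- run_stage("qc", apply_qc(cohort$participants, cohort$responses, quiz))
  write_json_stable(unclass(qc$report),
                    add_path("qc_report", file.path(out_dir, "qc_report.json")))

  metrics <- run_stage("metrics", compute_metrics(qc$responses, quiz))
  readr::write_csv(metrics, add_path("metrics",
                                     file.path(out_dir, "metrics.csv")))
  psum <- participant_summary(metrics)
  readr::write_csv(psum, add_path("participant_summary",
                                  file.path(out_dir, "participant_summary.csv")))
  fsum <- per_food_summary(metrics, quiz)
  readr::write_csv(fsum, add_path("per_food_summary",
                                  file.path(out_dir, "per_food_summary.csv")))

  n_participants <- dplyr::n_distinct(metrics$participant_id)
  crowd <- run_stage("crowd", {
    k_grid <- config$k_grid[config$k_grid <= n_participants]
    curve <- convergence_curve(qc$responses, quiz, k_grid = k_grid,
                               n_draws = config$n_draws,
                               aggregator = config$aggregator,
                               seed = sub_seed(config$seed, 20L))
    k1 <- min(config$bootstrap_k1, n_participants)
    k2 <- min(config$bootstrap_k2, n_participants)
    boot <- bootstrap_crowd_test(qc$responses, quiz, k1 = k1, k2 = k2,
                                 B = config$bootstrap_B,
                                 seed = sub_seed(config$seed, 21L))
    consensus <- crowd_estimate(qc$responses, quiz, k = n_participants,
                                aggregator = config$aggregator,
                                seed = sub_seed(config$seed, 22L))
    small <- crowd_estimate(qc$responses, quiz,
                            k = min(10, n_participants),
                            aggregator = config$aggregator,
                            seed = sub_seed(config$seed, 23L))
    list(curve = curve, boot = boot, consensus = consensus, small = small)
  })
  readr::write_csv(crowd$curve, add_path("convergence",
                                         file.path(out_dir, "convergence.csv")))
  write_json_stable(as.list(glance(crowd$boot)),
                    add_path("bootstrap_test",
                             file.path(out_dir, "bootstrap_test.json")))

  expert <- NULL
  if (any(qc$participants$is_expert)) {
    expert <- run_stage("expert_comparison",
      expert_comparison(qc$responses, qc$participants, quiz,
                        seed = sub_seed(config$seed, 24L)))
    write_json_stable(
      c(as.list(glance(expert)), list(curve = as.data.frame(tidy(expert)))),
      add_path("expert_comparison",
               file.path(out_dir, "expert_comparison.json"))
    )
  }

  fits <- run_stage("bias_models", {
    purrr::map(rlang::set_names(config$models), function(mn) {
      fit_bias_model(metrics, qc$participants, quiz, model = mn)
    })
  })
  write_json_stable(
    purrr::map(fits, function(f) {
      c(as.list(glance(f)),
        list(coefficients = as.data.frame(tidy(f))))
    }),
    add_path("bias_fits", file.path(out_dir, "bias_fits.json"))
  )
  dcurve <- density_bias_curve(metrics, quiz)
  readr::write_csv(dcurve, add_path("density_bias_curve",
                                    file.path(out_dir, "density_bias_curve.csv")))

  network <- run_stage("error_network", {
    mat <- error_correlation_matrix(metrics)
    graph <- build_food_graph(mat, threshold = config$network_threshold)
    clusters <- cluster_foods(mat, cut_height = config$cluster_cut)
    list(matrix = mat, graph = graph, clusters = clusters)
  })
  readr::write_csv(
    tibble::as_tibble(network$matrix, rownames = "food_id"),
    add_path("correlation_matrix", file.path(out_dir, "correlation_matrix.csv"))
  )
  gfiles <- write_food_graph(network$graph,
                             file.path(out_dir, "food_graph.graphml"),
                             file.path(out_dir, "food_graph_edges.csv"))
  add_path("graphml", gfiles[["graphml"]])
  add_path("edges_csv", gfiles[["edges_csv"]])
  write_json_stable(
    split(network$clusters$food_id, network$clusters$cluster),
    add_path("clusters", file.path(out_dir, "clusters.json"))
  )

  report <- list(
    seed = config$seed,
    mode = if (is.null(config$simulation)) "analyze" else "simulate",
    qc = unclass(qc$report),
    n_participants = n_participants,
    mean_D = mean(psum$D),
    mean_abs_e_kcal = mean(psum$mean_abs_e_kcal),
    mean_abs_eta = mean(psum$mean_abs_eta),
    median_e = stats::median(metrics$e),
    consensus = as.list(glance(crowd$consensus)),
    crowd_of_10 = as.list(glance(crowd$small)),
    bootstrap = as.list(glance(crowd$boot)),
    expert = if (!is.null(expert)) as.list(glance(expert)),
    density_mass_correlation = density_mass_correlation(quiz),
    bias_models = purrr::map(fits, function(f) as.list(glance(f))),
    n_network_edges = igraph::ecount(network$graph),
    n_clusters = dplyr::n_distinct(network$clusters$cluster)
  )
  write_json_stable(report, add_path("report",
                                     file.path(out_dir, "report.json")))

  manifest <- list(
    package = "crowdcal",
    version = as.character(utils::packageVersion("crowdcal")),
    seed = config$seed,
    artifacts = purrr::imap(paths, function(p, nm) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  write_json_stable(manifest, file.path(out_dir, "manifest.json"))

  invisible(list(
    quiz = quiz, cohort = cohort, qc = qc, metrics = metrics,
    participant_summary = psum, per_food_summary = fsum,
    crowd = crowd, expert = expert, bias_fits = fits,
    density_bias_curve = dcurve, network = network,
    report = report, paths = paths, out_dir = out_dir
  ))
}
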