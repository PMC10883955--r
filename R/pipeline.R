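#' Configuration for a full pipeline run
#'
#' Exactly one of `input` (a cohort CSV) or `n` (size of a synthetic
#' cohort) drives the data stage.
#'
#' @param output_dir directory for all artifacts (created if needed).
#' @param input optional path to a cohort CSV.
#' @param n synthetic cohort size (used when `input` is NULL).
#' @param seed integer seed for synthetic generation and structure search.
#' @param learning a [learning_config()].
#' @param threshold classification threshold for the diagnostic stage, or
#'   NULL for the sample prevalence.
#' @param ci_method risk-difference CI method ("newcombe" or "wald").
#' @param metric strength-of-influence metric.
#' @param ldl_boundary LDL-C discretization boundary (mg/dL).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir, input = NULL, n = 491, seed = 42,
                            learning = learning_config(),
                            threshold = NULL, ci_method = "newcombe",
                            metric = "euclidean", ldl_boundary = 130) {
  if (!is.null(threshold)) {
    ok <- (is.numeric(threshold) && threshold > 0 && threshold < 1) ||
      identical(threshold, "prevalence") || identical(threshold, "youden")
    if (!ok)
      stop("threshold must lie in (0, 1), or be \"prevalence\" or \"youden\"",
           call. = FALSE)
  }
  if (!is.null(input) && !file.exists(input))
    stop("input file not found: ", input, call. = FALSE)
  structure(list(output_dir = output_dir, input = input, n = n,
                 seed = as.integer(seed), learning = learning,
                 threshold = threshold, ci_method = ci_method,
                 metric = metric, ldl_boundary = ldl_boundary),
            class = "pipeline_config")
}

#' Run the full cohort analysis pipeline
#'
#' Stages, in order: (1) load or generate the cohort; (2) descriptive
#' baseline table; (3) fit the knowledge-based network; (4) learn a
#' structure by Bayesian search and fit it; (5) AIC/BIC comparison of the
#' two structures (maximum-likelihood fits); (6) leave-one-out
#' cross-validated diagnostics for both networks; (7) conditional
#' probability and strength-of-influence reports for the knowledge-based
#' network. Eight CSV artifacts, two serialized networks, a DOT graph and
#' a JSON manifest are written to the output directory. Given an identical
#' configuration the CSV outputs are byte-identical across runs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage log lines.
#' @return The run manifest (also written as `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  schema <- cohort_schema(ldl_boundary = config$ldl_boundary)
  stages <- list()
  state <- new.env()
  log_line <- function(...) if (!quiet) message("[pipeline] ", ...)

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      writeLines(paste0("FAILED at stage '", name, "': ",
                        conditionMessage(res)), out("FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    stages[[length(stages) + 1L]] <<- list(
      stage = name, status = "completed",
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  run_stage("data", function() {
    tab <- if (!is.null(config$input)) {
      load_cohort(config$input, schema, quiet = TRUE)
    } else {
      raw <- sample_cohort(config$n, seed = config$seed, continuous = TRUE)
      discretize_cohort(raw, schema)
    }
    write_cohort(tab, out("cohort.csv"))
    state$data <- tab
    log_line("data: ", nrow(tab), " records (seed ", config$seed, ")")
  })
  run_stage("table1", function() {
    rep <- table1_report(state$data, method = config$ci_method,
                         schema = schema)
    write_report_csv(rep, out("table1.csv"))
    state$table1 <- rep
  })
  run_stage("fit_knowledge", function() {
    state$fit_k <- fit_bayes_net(knowledge_dag(), state$data,
                                 alpha = config$learning$prior_alpha)
    write_bayes_net(state$fit_k, out("knowledge_net.yml"))
    write_dag_dot(state$fit_k$dag, out("knowledge_net.dot"))
  })
  run_stage("fit_search", function() {
    g <- bayesian_search(state$data, config$learning, trace = TRUE)
    state$dag_s <- g
    state$fit_s <- fit_bayes_net(g, state$data,
                                 alpha = config$learning$prior_alpha)
    write_bayes_net(state$fit_s, out("search_net.yml"))
    tr <- attr(g, "trace")
    if (!is.null(tr))
      utils::write.csv(tr, out("search_trace.csv"), row.names = FALSE)
    log_line("search: ", nrow(g$edges), " arcs, BDeu score ",
             round(attr(g, "score"), 2))
  })
  run_stage("criteria", function() {
    ml_k <- fit_bayes_net(knowledge_dag(), state$data, alpha = 0)
    ml_s <- fit_bayes_net(state$dag_s, state$data, alpha = 0)
    state$crit <- list(
      knowledge = information_criteria(ml_k, state$data),
      search = information_criteria(ml_s, state$data))
    tab <- do.call(rbind, lapply(names(state$crit), function(m)
      data.frame(model = m, aic = state$crit[[m]]$aic,
                 bic = state$crit[[m]]$bic, loglik = state$crit[[m]]$loglik,
                 k = state$crit[[m]]$k)))
    write_report_csv(tab, out("criteria.csv"))
    log_line("criteria: knowledge BIC ", round(tab$bic[1], 1),
             ", search BIC ", round(tab$bic[2], 1))
  })
  run_stage("loocv_diagnostics", function() {
    alpha <- config$learning$prior_alpha
    sc_k <- loocv_scores(knowledge_dag(), state$data, alpha = alpha)
    sc_s <- loocv_scores(state$dag_s, state$data, alpha = alpha)
    labels <- state$data$ascvd
    reports <- list(
      knowledge = diagnostic_indices(sc_k, labels, config$threshold),
      search = diagnostic_indices(sc_s, labels, config$threshold))
    cmp <- compare_models(reports, state$crit)
    write_report_csv(cmp, out("diagnostics.csv"))
    write_report_csv(roc_points(sc_k, labels), out("roc_knowledge.csv"))
    write_report_csv(roc_points(sc_s, labels), out("roc_search.csv"))
    state$reports <- reports
    log_line("LOOCV: knowledge AUC ", round(100 * reports$knowledge$auc, 1),
             ", search AUC ", round(100 * reports$search$auc, 1))
  })
  run_stage("reports", function() {
    write_report_csv(cp_report(state$fit_k, schema = schema),
                     out("cp_report.csv"))
    write_report_csv(strength_table(state$fit_k, metric = config$metric),
                     out("strength.csv"))
  })

  outputs <- c("cohort.csv", "table1.csv", "criteria.csv", "diagnostics.csv",
               "roc_knowledge.csv", "roc_search.csv", "cp_report.csv",
               "strength.csv")
  manifest <- list(
    package = "ascvdbn",
    version = as.character(utils::packageVersion("ascvdbn")),
    seed = config$seed,
    n = nrow(state$data),
    input = config$input %||% "synthetic",
    config = list(prior_alpha = config$learning$prior_alpha,
                  restarts = config$learning$restarts,
                  max_parents = config$learning$max_parents,
                  ess = config$learning$ess,
                  threshold = config$threshold %||% "prevalence",
                  ci_method = config$ci_method, metric = config$metric,
                  ldl_boundary = config$ldl_boundary),
    stages = stages,
    outputs = outputs)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

# deterministic CSV writer (fixed significant digits, no quoting surprises)
write_report_csv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
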