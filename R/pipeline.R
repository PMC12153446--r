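#' Default end-to-end run configuration
#'
#' Every analysis constant lives here rather than being hard-coded: the
#' screening cutoffs (CES-D >= 10, GAD-7 >= 5), the EBIC hyperparameter
#' (gamma = 0.5) and its sensitivity set, the 10 cross-validation folds,
#' the 1,000 bootstrap iterations at 95% confidence, and the case-dropping
#' grid up to 0.75.
#'
#' @param seed Global seed; all stage seeds are derived from it.
#' @return A nested list understood by [run_pipeline()]; serializable to
#'   YAML.
#' @export
default_config <- function(seed = 20170101L) {
  list(
    seed = as.integer(seed),
    log_level = "info",
    input = list(roster = NULL,     # path to a roster CSV; NULL = simulate
                 column_map = list()),
    simulate = list(n = 2000L, stage_counts = c(0L, 0L, 0L)),
    screening = list(living_alone_code = 2L, cesd_cutoff = 10L,
                     gad_cutoff = 5L),
    selection = list(gamma = 0.5, n_folds = 10L, n_lambda = 100L,
                     lambda_min_ratio = 0.01, mode = "direct_ebic"),
    gamma_sensitivity = c(0.1, 0.5, 0.9),
    bootstrap = list(n_boot = 1000L, ci_level = 0.95,
                     drop_proportions = seq(0.10, 0.75, by = 0.05),
                     cs_correlation = 0.7, cs_probability = 0.95,
                     mode = "direct_ebic", n_lambda = 40L),
    layout = list(n_iter = 500L)
  )
}

stage_seed <- function(config, k) (config$seed %% 2146000000L) + 1009L * k

plog <- function(config, level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (levels[[config$log_level %||% "info"]] <= levels[[level]])
    message(format(Sys.time(), "%H:%M:%S "), ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

selection_from <- function(sel, seed) {
  selection_config(gamma = sel$gamma %||% 0.5,
                   n_folds = sel$n_folds %||% 10L,
                   n_lambda = sel$n_lambda %||% 100L,
                   lambda_min_ratio = sel$lambda_min_ratio %||% 0.01,
                   seed = seed, mode = sel$mode %||% "direct_ebic")
}

read_artifact <- function(out_dir, file, stage) {
  path <- file.path(out_dir, file)
  if (!file.exists(path))
    stop("missing upstream artifact '", file, "' in ", out_dir,
         "; run the '", stage, "' stage first")
  path
}

write_model_json <- function(model, path) {
  jsonlite::write_json(list(lambda_used = model$lambda_used,
                            gamma_used = model$gamma_used,
                            node_labels = model$node_labels,
                            communities = as.list(model$communities)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run one pipeline stage
#'
#' Stages consume the previous stage's serialized artifacts from `out_dir`
#' and write their own there: `simulate` (roster + ground truth), `screen`
#' (screening report, retained sample, descriptives), `estimate` (Spearman
#' matrix, selected model, gamma sensitivity), `stability` (bootstrap CIs,
#' difference tests, CS), `report` (centrality, combined table, figure,
#' manifest).
#'
#' @param stage One of `"simulate"`, `"screen"`, `"estimate"`,
#'   `"stability"`, `"report"`.
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
run_stage <- function(stage = c("simulate", "screen", "estimate",
                                "stability", "report"),
                      config = default_config(), out_dir) {
  stage <- match.arg(stage)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  w <- function(path) { written <<- c(written, path); path }

  if (stage == "simulate") {
    plog(config, "info", "simulate: n = ", config$simulate$n)
    truth <- make_ground_truth(seed = stage_seed(config, 1L))
    X <- sample_ordinal(truth, n = config$simulate$n,
                        seed = stage_seed(config, 2L))
    roster <- inject_missingness(X, config$simulate$stage_counts,
                                 seed = stage_seed(config, 3L))
    write_roster(roster, w(file.path(out_dir, "roster.csv")))
    write_matrix(truth$partials, w(file.path(out_dir, "true_partials.csv")))
    jsonlite::write_json(list(communities = as.list(truth$communities),
                              bridge_edges = truth$bridge_edges),
                         w(file.path(out_dir, "ground_truth.json")),
                         auto_unbox = TRUE, digits = NA)
  } else if (stage == "screen") {
    roster_path <- config$input$roster %||%
      read_artifact(out_dir, "roster.csv", "simulate")
    plog(config, "info", "screen: ", roster_path)
    roster <- parse_roster(roster_path, config$input$column_map %||% list())
    res <- apply_exclusions(roster,
                            config$screening$living_alone_code %||% 2L)
    jsonlite::write_json(unclass(res$report),
                         w(file.path(out_dir, "screening_report.json")),
                         auto_unbox = TRUE, digits = NA)
    write_roster(res$retained, w(file.path(out_dir, "retained.csv")))
    d <- descriptives(res$retained)
    utils::write.csv(d$items, w(file.path(out_dir, "descriptives.csv")),
                     row.names = FALSE)
    jsonlite::write_json(as.list(d$prevalence),
                         w(file.path(out_dir, "prevalence.json")),
                         auto_unbox = TRUE, digits = NA)
  } else if (stage == "estimate") {
    retained <- parse_roster(read_artifact(out_dir, "retained.csv", "screen"))
    X <- make_item_matrix(retained)
    plog(config, "info", "estimate: n = ", nrow(X), ", p = ", ncol(X))
    S <- nearest_psd(spearman_matrix(X))
    write_matrix(S, w(file.path(out_dir, "corr_spearman.csv")))
    cfg <- selection_from(config$selection, stage_seed(config, 4L))
    fit <- select_network(X, cfg)
    write_matrix(fit$model$weights,
                 w(file.path(out_dir, "model_weights.csv")))
    utils::write.csv(edge_list(fit$model),
                     w(file.path(out_dir, "model_edges.csv")),
                     row.names = FALSE)
    write_model_json(fit$model, w(file.path(out_dir, "model.json")))
    gs <- config$gamma_sensitivity %||% numeric(0)
    if (length(gs) > 1) {
      sens <- gamma_sensitivity(X, gs, cfg)
      jsonlite::write_json(list(edge_counts = as.list(sens$edge_counts),
                                comparisons = sens$comparisons),
                           w(file.path(out_dir, "gamma_sensitivity.json")),
                           auto_unbox = TRUE, digits = NA)
    }
  } else if (stage == "stability") {
    retained <- parse_roster(read_artifact(out_dir, "retained.csv", "screen"))
    X <- make_item_matrix(retained)
    bc <- config$bootstrap
    est <- selection_from(list(gamma = config$selection$gamma,
                               n_lambda = bc$n_lambda %||% 40L,
                               lambda_min_ratio =
                                 config$selection$lambda_min_ratio,
                               mode = bc$mode %||% "direct_ebic"),
                          stage_seed(config, 5L))
    cfg <- boot_config(n_boot = bc$n_boot %||% 1000L,
                       seed = stage_seed(config, 6L),
                       ci_level = bc$ci_level %||% 0.95,
                       drop_proportions = bc$drop_proportions %||%
                         seq(0.10, 0.75, by = 0.05),
                       cs_correlation = bc$cs_correlation %||% 0.7,
                       cs_probability = bc$cs_probability %||% 0.95)
    plog(config, "info", "stability: ", cfg$n_boot, " bootstrap iterations")
    boot <- bootstrap_edges(X, est, cfg)
    eb <- boot$edges; eb$n_boot <- cfg$n_boot
    utils::write.csv(eb, w(file.path(out_dir, "boot_edges.csv")),
                     row.names = FALSE)
    utils::write.csv(difference_test_edges(boot),
                     w(file.path(out_dir, "diff_edges.csv")))
    utils::write.csv(difference_test_centrality(boot, "ei"),
                     w(file.path(out_dir, "diff_ei.csv")))
    utils::write.csv(difference_test_centrality(boot, "bei"),
                     w(file.path(out_dir, "diff_bei.csv")))
    cs <- case_drop_bootstrap(X, est, cfg)
    jsonlite::write_json(list(cs = as.list(cs$cs),
                              interpretation = as.list(cs$interpretation),
                              n_boot = cfg$n_boot, curve = cs$curve),
                         w(file.path(out_dir, "cs.json")),
                         auto_unbox = TRUE, digits = NA)
  } else if (stage == "report") {
    Wp <- read_artifact(out_dir, "model_weights.csv", "estimate")
    mj <- jsonlite::read_json(read_artifact(out_dir, "model.json",
                                            "estimate"))
    W <- read_matrix(Wp)
    model <- new_network_model(W, unlist(mj$node_labels),
                               unlist(mj$communities),
                               mj$lambda_used, mj$gamma_used)
    retained <- parse_roster(read_artifact(out_dir, "retained.csv", "screen"))
    cent <- centrality_table(model)
    utils::write.csv(as.data.frame(cent),
                     w(file.path(out_dir, "centrality.csv")),
                     row.names = FALSE)
    t1 <- make_table1(descriptives(retained), cent)
    utils::write.csv(t1, w(file.path(out_dir, "table1.csv")),
                     row.names = FALSE)
    coords <- fruchterman_reingold(model, seed = stage_seed(config, 7L),
                                   n_iter = config$layout$n_iter %||% 500L)
    rn <- render_network(model, coords, file.path(out_dir, "network"))
    written <- c(written, unlist(rn$paths, use.names = FALSE))
  }
  invisible(written)
}

#' Run the full screen-to-report pipeline
#'
#' Orchestrates all stages in order (the `simulate` stage is only run when
#' no input roster is configured), writes every artifact plus a serialized
#' copy of the configuration, and finishes with a manifest recording an MD5
#' hash of each artifact and the derived per-stage seeds. Any stage failure
#' aborts with the stage name after writing a partial manifest.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, the manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(out_dir, "config_used.yaml"))
  stages <- c(if (is.null(config$input$roster)) "simulate",
              "screen", "estimate", "stability", "report")
  written <- file.path(out_dir, "config_used.yaml")
  for (st in stages) {
    res <- tryCatch(run_stage(st, config, out_dir), error = function(e) e)
    if (inherits(res, "error")) {
      manifest <- build_manifest(config, out_dir, written, failed = st)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stop("pipeline stage '", st, "' failed: ", conditionMessage(res))
    }
    written <- c(written, res)
  }
  manifest <- build_manifest(config, out_dir, written, failed = NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

build_manifest <- function(config, out_dir, files, failed = NULL) {
  files <- unique(normalizePath(files, mustWork = FALSE))
  files <- files[file.exists(files)]
  hashes <- unname(tools::md5sum(files))
  list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
       config_hash = unname(tools::md5sum(file.path(out_dir,
                                                    "config_used.yaml"))),
       global_seed = config$seed,
       stage_seeds = setNames(as.list(stage_seed(config, 1:7)),
                              c("truth", "sample", "roster", "selection",
                                "boot_estimator", "bootstrap", "layout")),
       failed_stage = failed,
       artifacts = data.frame(file = basename(files), md5 = hashes,
                              stringsAsFactors = FALSE))
}
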