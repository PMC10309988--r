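# End-to-end orchestration: generate or load a cohort, compute economics and
# resistance profiles, the contingency analysis, the typology, and the five
# decision trees; optionally write every artefact with a checksum manifest
# and render a Markdown report.

#' Pipeline run configuration
#'
#' @param input Path to a farm table (CSV/JSON), or `NULL` to generate a
#'   synthetic cohort from `synth`.
#' @param synth A [synth_config()] used when `input` is `NULL`; its seed is
#'   overridden by `seed`.
#' @param scenario Veterinary-service scenario for cost denominators
#'   (`"A"` default).
#' @param seed Master seed for generation, clustering and tree splits.
#' @param out_dir Output directory for artefacts (`NULL` = keep in memory).
#' @param tree_models Which trees to fit (default all five).
#' @param tree_runs Runs for [repeated_split_select()] (default 100).
#' @param tree_alpha Screening level (default 0.05).
#' @param control A [tree_control()].
#' @param k Fixed number of typology clusters, or `NULL` to choose by the
#'   elbow rule.
#' @param k_max,restarts k-means search range and restarts.
#' @param verbose Print stage progress.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, synth = synth_config(),
                       scenario = c("A", "B"), seed = 1L, out_dir = NULL,
                       tree_models = c("infestation", "model1", "model2",
                                       "model3", "model4"),
                       tree_runs = 100, tree_alpha = 0.05,
                       control = tree_control(), k = NULL, k_max = 10,
                       restarts = 25, verbose = FALSE) {
  scenario <- match.arg(scenario)
  known <- c("infestation", "model1", "model2", "model3", "model4")
  if (!all(tree_models %in% known)) {
    abort(paste0("unknown tree model(s): ",
                 paste(setdiff(tree_models, known), collapse = ", ")),
          class = "acarecon_config_error")
  }
  structure(
    list(input = input, synth = synth, scenario = scenario,
         seed = as.integer(seed), out_dir = out_dir,
         tree_models = tree_models, tree_runs = tree_runs,
         tree_alpha = tree_alpha, control = control, k = k, k_max = k_max,
         restarts = restarts, verbose = verbose),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Scalar fields of the YAML file override the [run_config()] defaults;
#' nested `synth` fields override the [synth_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  synth_args <- raw$synth %||% list()
  raw$synth <- NULL
  args <- raw
  args$synth <- do.call(synth_config, synth_args)
  do.call(run_config, args)
}

with_stage <- function(stage, verbose, expr) {
  if (verbose) message("stage: ", stage)
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)),
          class = "acarecon_stage_error", parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Stages: load or generate the cohort; validate records (error-severity
#' violations abort, naming the farms involved); per-farm economic summary
#' and acaricide-cost metrics; resistance profiles; infestation x resistance
#' contingency report; typology (ordinal recoding, WSS curve, elbow choice,
#' k-means, cluster profiles); and the requested decision trees with terminal
#' node profiles. Deterministic given the configuration seed. When
#' `out_dir` is set every tabular artefact is written as CSV along with a
#' `manifest.csv` of MD5 checksums.
#'
#' @param config A [run_config()].
#' @return A list of class `acarecon_bundle` with elements `farms`, `truth`,
#'   `economics`, `metrics`, `profiles`, `association`, `typology`, `trees`,
#'   `config`, and `manifest` (when written).
#' @export
run_pipeline <- function(config = run_config()) {
  v <- config$verbose

  cohort <- with_stage("input", v, {
    if (is.null(config$input)) {
      sc <- config$synth
      sc$seed <- config$seed
      generate_cohort(sc)
    } else {
      list(farms = read_farm_table(config$input), truth = NULL)
    }
  })
  farms <- cohort$farms

  with_stage("validation", v, {
    if (is.null(farms) || nrow(farms) == 0) {
      abort("empty cohort", class = "acarecon_input_error")
    }
    viol <- validate_farm_table(farms)
    errors <- viol[viol$severity == "error", ]
    if (nrow(errors) > 0) {
      abort(paste0("invalid farm record(s): ",
                   paste(unique(errors$farm_id), collapse = ", ")),
            class = "acarecon_validation_error")
    }
  })

  economics <- with_stage("economics", v, economic_summary(farms))
  metrics <- with_stage("economics", v, {
    acaricide_cost_metrics(farms, economics, scenario = config$scenario)
  })
  profiles <- with_stage("resistance", v, resistance_profiles(farms))
  association <- with_stage("association", v, {
    association_report(profiles, farms$high_infestation)
  })

  typology <- with_stage("typology", v, {
    mat <- ordinal_recode(farms)
    curve <- wss_curve(mat, k_max = config$k_max, restarts = config$restarts,
                       seed = config$seed)
    elbow <- choose_k_elbow(curve)
    k <- config$k %||% elbow$k
    result <- cluster_farms(mat, k, restarts = config$restarts,
                            seed = config$seed)
    list(curve = curve, elbow = elbow, result = result,
         profile = profile_clusters(farms, result$assignments))
  })

  tdat <- with_stage("trees", v, tree_data(farms, metrics, profiles))
  attrs <- c("technology", "high_infestation", "am_resistant", "cy_resistant",
             "iv_resistant")
  trees <- with_stage("trees", v, {
    out <- list()
    for (m in config$tree_models) {
      spec <- tree_spec(m)
      if (m == "infestation") {
        fit <- fit_cart(tdat, spec$response, spec$predictors,
                        task = spec$task, control = config$control)
        scores <- predict_tree(fit, tdat)
        roc <- auc_roc(scores, tdat$high_infestation == "yes")
        out[[m]] <- list(model = fit, auc = roc,
                         nodes = profile_nodes(fit, tdat, setdiff(attrs, "technology")))
      } else {
        sel <- repeated_split_select(
          tdat, spec$response, spec$predictors, task = spec$task,
          n_runs = config$tree_runs, seed = config$seed,
          alpha = config$tree_alpha, control = config$control
        )
        nodes <- profile_nodes(sel$model, tdat, attrs)
        out[[m]] <- c(sel, list(nodes = nodes))
      }
    }
    out
  })

  bundle <- structure(
    list(farms = farms, truth = cohort$truth, economics = economics,
         metrics = metrics, profiles = profiles, association = association,
         typology = typology, trees = trees, config = config,
         manifest = NULL),
    class = "acarecon_bundle"
  )
  if (!is.null(config$out_dir)) {
    bundle$manifest <- write_bundle(bundle, config$out_dir)
  }
  bundle
}

flatten_nodes <- function(nodes) {
  base <- nodes[setdiff(names(nodes), "composition")]
  comp <- purrr::map_dfr(nodes$composition, function(x) {
    if (length(x) == 0) return(tibble::tibble(.rows = 1))
    tibble::as_tibble(as.list(x))
  })
  dplyr::bind_cols(tibble::as_tibble(base), comp)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)
  write_farm_table(bundle$farms, path("farms.csv"))
  readr::write_csv(bundle$economics, path("economic_summary.csv"))
  readr::write_csv(bundle$metrics, path("acaricide_metrics.csv"))
  readr::write_csv(bundle$profiles, path("resistance_profiles.csv"))
  readr::write_csv(bundle$association, path("association.csv"))
  readr::write_csv(bundle$typology$curve, path("typology_wss.csv"))
  readr::write_csv(
    tibble::tibble(farm_id = names(bundle$typology$result$assignments),
                   cluster = bundle$typology$result$assignments),
    path("typology_assignments.csv")
  )
  readr::write_csv(bundle$typology$profile, path("typology_profile.csv"))
  for (m in names(bundle$trees)) {
    readr::write_csv(flatten_nodes(bundle$trees[[m]]$nodes),
                     path(paste0("tree_", m, "_nodes.csv")))
    if (!is.null(bundle$trees[[m]]$run_log)) {
      readr::write_csv(bundle$trees[[m]]$run_log,
                       path(paste0("tree_", m, "_runlog.csv")))
    }
  }
  files <- sort(setdiff(list.files(out_dir), "manifest.csv"))
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files)))
  )
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

md_table <- function(df, digits = 2) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- round(df[[j]], digits)
  }
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  cells <- matrix(as.character(cells), nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

#' Render a bundle as a Markdown report
#'
#' Produces a human-readable summary: cohort overview, economic summary by
#' typology cluster, the infestation x resistance contingency report, the
#' typology profile, and one section per fitted tree with its terminal-node
#' table. Rendering is idempotent: the same bundle always yields the same
#' text.
#'
#' @param bundle An `acarecon_bundle` from [run_pipeline()].
#' @param path Optional file to write the report to.
#' @return The report as a character vector of lines, invisibly when `path`
#'   is given.
#' @export
render_report <- function(bundle, path = NULL) {
  for (part in c("farms", "economics", "association", "typology", "trees")) {
    if (is.null(bundle[[part]])) {
      abort(paste0("bundle is missing artefact '", part, "'"),
            class = "acarecon_input_error")
    }
  }
  econ_by_cluster <- dplyr::bind_cols(
    bundle$economics,
    tibble::tibble(cluster = bundle$typology$result$assignments)
  ) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(dplyr::across(c("tc_a", "tc_b", "amp", "tr", "p_a", "p_b",
                                     "cpm"), mean), .groups = "drop")

  lines <- c(
    "# Farm-system tick-control economics report",
    "",
    paste0("Cohort: ", nrow(bundle$farms), " farms; scenario ",
           bundle$config$scenario, "; seed ", bundle$config$seed, "."),
    "",
    "## Economic summary by typology cluster (means, USD/yr)",
    "",
    md_table(econ_by_cluster),
    "",
    "## High tick infestation vs acaricide resistance",
    "",
    md_table(bundle$association),
    "",
    paste0("High-infestation prevalence: ",
           round(prevalence(bundle$farms$high_infestation)$pct, 2), "%."),
    "",
    "## Farm typology",
    "",
    paste0("Clusters chosen: k = ", bundle$typology$result$k,
           if (isTRUE(bundle$typology$elbow$low_confidence))
             " (low-confidence elbow)" else "", "."),
    "",
    md_table(bundle$typology$profile)
  )
  for (m in names(bundle$trees)) {
    tr <- bundle$trees[[m]]
    hdr <- c("", paste0("## Decision tree: ", m), "")
    meta <- if (!is.null(tr$auc)) {
      paste0("AUC-ROC ", round(tr$auc$auc, 2), " (95% CI ",
             round(tr$auc$ci_low, 2), "-", round(tr$auc$ci_high, 2), ").")
    } else {
      paste0("Selected run ", tr$run, ": test R2 ",
             round(tr$metrics$r2_test, 2), ", test MSE ",
             round(tr$metrics$mse_test, 2), ".")
    }
    lines <- c(lines, hdr, meta, "", md_table(flatten_nodes(tr$nodes)))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
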