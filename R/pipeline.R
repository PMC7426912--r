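#' Run the full panel-discovery pipeline from a YAML config
#'
#' Executes, end to end: optional simulation of a multi-study collection,
#' preprocessing (probe collapse, per-study KNN imputation, intersection
#' merge, per-sample z-scoring), repeated DRPT selection, cross-validated
#' scoring of every subset, ranking of the top subsets, QQ frequency
#' thresholding, training of the candidate SVM models (top subsets plus the
#' frequent-gene panel) and validation on a held-out simulated study. All
#' non-plot outputs are written to `outdir` as plain text (TSV/JSON) and are
#' bit-reproducible for a fixed config.
#'
#' The YAML schema has four optional blocks, each holding the arguments of
#' the corresponding constructor: `simulation` ([sim_config()]), `drpt`
#' ([drpt_params()]), `evaluation` ([eval_config()]), and `threshold`
#' (field `override`).
#'
#' @param config Path to a YAML file, or an already-parsed named list.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the merged training data, subsets, scores,
#'   top ids, frequency table, threshold, models and validation PR curves.
#' @export
run_full_pipeline <- function(config, outdir = tempfile("ucpanel_run")) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) abort("`config` must be a YAML file path or a named list")
  known <- c("simulation", "drpt", "evaluation", "threshold")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) {
    abort(sprintf("unknown config block(s): %s (expected %s)",
                  paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  }
  scfg <- do.call(sim_config, as.list(cfg$simulation))
  params <- do.call(drpt_params, as.list(cfg$drpt))
  evcfg <- do.call(eval_config, as.list(cfg$evaluation))
  override <- cfg$threshold$override

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "run.log")
  log_line <- function(fmt, ...) {
    msg <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    message(msg)
    cat(msg, "\n", file = logf, append = TRUE)
  }

  log_line("simulating %d studies (seed %d)", length(scfg$n_controls), scfg$seed)
  sim <- simulate_multi_study(scfg)
  for (nm in names(sim$studies)) {
    write_expression_table(sim$studies[[nm]]$probes,
                           file.path(outdir, paste0(nm, "_probes.tsv")))
    readr::write_tsv(sim$studies[[nm]]$map,
                     file.path(outdir, paste0(nm, "_probe_map.tsv")),
                     progress = FALSE)
    readr::write_tsv(sim$studies[[nm]]$labels,
                     file.path(outdir, paste0(nm, "_labels.tsv")),
                     progress = FALSE)
  }
  jsonlite::write_json(list(informative = sim$truth$informative,
                            blocks = sim$truth$blocks,
                            study_scale = sim$truth$study_scale,
                            study_offset = sim$truth$study_offset,
                            seed = sim$truth$seed),
                       file.path(outdir, "truth.json"), auto_unbox = TRUE)

  log_line("preprocessing: collapse, impute, merge, z-score")
  D <- preprocess_simulated(sim)
  log_line("training matrix: %d samples x %d genes", nrow(D), length(expr_genes(D)))

  log_line("running DRPT %d times (base seed %d)", evcfg$n_runs, evcfg$base_seed)
  subsets <- run_repeated_selection(D, params, evcfg)

  log_line("cross-validating %d subsets (%d x %d-fold)", length(subsets),
           evcfg$repeats, evcfg$k)
  scores <- purrr::imap(subsets, function(s, nm) {
    cross_validate_subset(D, s, evcfg, id = nm)
  })
  score_tab <- dplyr::bind_rows(purrr::map(scores, glance))
  readr::write_tsv(score_tab, file.path(outdir, "subset_scores.tsv"),
                   progress = FALSE)

  top_t <- min(evcfg$top_t, length(subsets))
  top_ids <- rank_subsets_top_t(scores, top_t)
  log_line("top %d subsets: %s", top_t, paste(top_ids, collapse = ", "))

  freq <- selection_frequencies(subsets)
  readr::write_tsv(freq, file.path(outdir, "selection_frequencies.tsv"),
                   progress = FALSE)
  c_star <- tryCatch(qq_frequency_threshold(freq, override = override),
                     error = function(e) {
                       warn(sprintf("frequency threshold unavailable (%s)",
                                    conditionMessage(e)))
                       NA_integer_
                     })
  log_line("frequency threshold c* = %s", c_star)

  panels <- purrr::map(top_ids, function(id) subsets[[id]])
  names(panels) <- top_ids
  if (!is.na(c_star) && any(freq$count > c_star)) {
    panels$frequent <- frequent_gene_subset(freq, c_star)
  }
  for (nm in names(panels)) {
    write_feature_subset(panels[[nm]],
                         file.path(outdir, paste0("subset_", nm, ".txt")))
  }
  models <- purrr::map(panels, function(p) {
    train_linear_svm(D, p, cost = evcfg$svm_cost)
  })
  for (nm in names(models)) {
    jsonlite::write_json(unclass(models[[nm]]),
                         file.path(outdir, paste0("model_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }

  log_line("validating on a freshly simulated held-out study")
  vsim <- simulate_validation_study(scfg)
  V <- collapse_probes_to_genes(vsim$probes, vsim$map) |>
    attach_labels(vsim$labels) |>
    impute_missing_knn() |>
    zscore_per_sample()
  V <- V[, c("sample_id", "label",
             intersect(expr_genes(V), expr_genes(D)))]
  curves <- purrr::map(models, function(m) {
    if (all(m$genes %in% expr_genes(V))) evaluate_model(m, V) else NULL
  })
  curves <- purrr::compact(curves)
  for (nm in names(curves)) {
    readr::write_tsv(tibble::as_tibble(curves[[nm]]),
                     file.path(outdir, paste0("pr_curve_", nm, ".tsv")),
                     progress = FALSE)
  }
  ap_tab <- tibble::tibble(model = names(curves),
                           ap = purrr::map_dbl(curves, curve_ap))
  readr::write_tsv(ap_tab, file.path(outdir, "validation_ap.tsv"),
                   progress = FALSE)
  log_line("done: %d candidate models, validation AP %s",
           length(models), paste(sprintf("%.3f", ap_tab$ap), collapse = ", "))

  invisible(list(training = D, subsets = subsets, scores = scores,
                 top_ids = top_ids, frequencies = freq, c_star = c_star,
                 models = models, validation = V, curves = curves,
                 outdir = outdir))
}
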