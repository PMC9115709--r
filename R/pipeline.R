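# End-to-end screen pipeline ---------------------------------------------------
#
# descriptors -> drug-likeness -> PAMPA/Caco-2 -> efficacy/PV -> group
# comparisons -> QSAR fit -> 80/20 split -> k-fold cross-validation, with every
# stage output written to a run directory. One top-level seed fans out to
# deterministic per-stage sub-seeds; text tables carry 6 significant digits,
# machine-readable JSON artifacts keep full precision; outputs carry no
# timestamps so identical configurations give byte-identical artifacts.

#' Pipeline run configuration
#'
#' @param output_dir Directory to write stage outputs into (created if
#'   needed).
#' @param seed Top-level integer seed; per-stage sub-seeds are derived from it
#'   deterministically.
#' @param descriptor_path Optional path to a descriptor table; when `NULL` a
#'   synthetic table is generated under `sim`.
#' @param viability_path Optional path to a viability table; when `NULL`
#'   synthetic readouts are generated under `sim`.
#' @param caco2_path Optional path to a Caco-2 label table (`drug_id`,
#'   `caco2_class`).
#' @param ph Working pH for the PAMPA model.
#' @param pampa_threshold Low-permeability cutoff on predicted PAMPA.
#' @param ro5_max_violations Rule-of-Five violation allowance.
#' @param qed_threshold QED compliance cutoff.
#' @param stepwise_criterion `"p_enter"` or `"aic"`.
#' @param p_enter Stepwise entry p-value threshold.
#' @param cv_folds Cross-validation folds.
#' @param aggregation PV aggregation, `"replicate"` or `"mean"`.
#' @param sim A [sim_config()] used for any synthetic stage (its seed is
#'   overridden by the derived stage seed).
#' @return List of class `run_config`.
#' @export
run_config <- function(output_dir, seed = 1L,
                       descriptor_path = NULL, viability_path = NULL,
                       caco2_path = NULL,
                       ph = 7.4, pampa_threshold = -6.14,
                       ro5_max_violations = 0, qed_threshold = 0.5,
                       stepwise_criterion = "p_enter", p_enter = 0.05,
                       cv_folds = 5, aggregation = "replicate",
                       sim = NULL) {
  stopifnot(is.character(output_dir), length(output_dir) == 1)
  vals <- c(ph = ph, pampa_threshold = pampa_threshold,
            ro5_max_violations = ro5_max_violations, qed_threshold = qed_threshold,
            p_enter = p_enter, cv_folds = cv_folds)
  if (any(!is.finite(vals))) {
    stop_spq("all numeric configuration values must be finite", class = "validation")
  }
  for (p in c(descriptor_path, viability_path, caco2_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop_spq(sprintf("configured input does not exist: %s", p),
               class = "schema", path = p)
    }
  }
  structure(
    list(output_dir = output_dir, seed = as.integer(seed),
         descriptor_path = descriptor_path, viability_path = viability_path,
         caco2_path = caco2_path, ph = ph, pampa_threshold = pampa_threshold,
         ro5_max_violations = ro5_max_violations, qed_threshold = qed_threshold,
         stepwise_criterion = stepwise_criterion, p_enter = p_enter,
         cv_folds = cv_folds, aggregation = aggregation,
         sim = sim),
    class = "run_config"
  )
}

write_table_6sig <- function(data, path) {
  out <- dplyr::mutate(data, dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 6)))
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.list),
                                          ~ vapply(.x, function(v) paste(unlist(v), collapse = "; "),
                                                   character(1))))
  readr::write_csv(out, path)
  invisible(path)
}

run_comparison <- function(pv_table, labels, name) {
  res <- tryCatch(
    compare_pv_groups(pv_table, labels),
    spq_error = function(e) NULL
  )
  if (is.null(res)) {
    return(tibble::tibble(comparison = name, status = "not run: insufficient or one-sided grouping"))
  }
  dplyr::bind_cols(tibble::tibble(comparison = name, status = "ok"), res)
}

#' Run the full screening pipeline
#'
#' Executes every stage and writes all artifacts into
#' `config$output_dir`: `descriptors.csv`, `druglikeness.csv`,
#' `permeability.csv`, `viability.csv`, `efficacy.csv`, `pv.csv`,
#' `comparisons.csv`, `qsar_model.json`, `split.json`, `cv.json` and
#' `metadata.json` (configuration echo, seed, package version, per-stage row
#' counts, and the interpretation flags raised during the run).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with every stage result and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$output_dir, f)
  flags <- character()

  # stage 1: descriptors
  sim <- config$sim %||% sim_config(seed = stage_seed(config$seed, 11L))
  descriptors <- if (is.null(config$descriptor_path)) {
    flags <- c(flags, "descriptor table generated synthetically")
    simulate_descriptor_table(sim)
  } else {
    read_descriptor_table(config$descriptor_path)
  }
  range_flags <- validate_descriptor_ranges(descriptors)

  # stage 2: drug-likeness
  profile <- profile_druglikeness(descriptors,
                                  max_violations = config$ro5_max_violations,
                                  qed_threshold = config$qed_threshold)
  flags <- c(flags, sprintf("QED compliance threshold %.2f (configuration choice)",
                            config$qed_threshold))

  # stage 3: permeability
  caco2 <- if (!is.null(config$caco2_path)) {
    readr::read_csv(config$caco2_path, show_col_types = FALSE, progress = FALSE)
  } else NULL
  permeability <- permeability_table(descriptors, ph = config$ph,
                                     threshold = config$pampa_threshold,
                                     caco2_labels = caco2)
  flags <- c(flags, sprintf("PAMPA model evaluated at pH %.2f", config$ph))

  # stage 4: viability -> efficacy -> PV
  viability <- if (is.null(config$viability_path)) {
    flags <- c(flags, "viability readouts generated synthetically")
    pv_targets <- simulate_pv_truth(descriptors, sim)
    withCallingHandlers(
      simulate_viability(descriptors, pv_targets, sim),
      spq_warning = function(w) {
        flags <<- c(flags, conditionMessage(w)); invokeRestart("muffleWarning")
      }
    )
  } else {
    read_viability_table(config$viability_path)
  }
  efficacy <- withCallingHandlers(
    compute_efficacy(viability),
    spq_warning = function(w) {
      flags <<- c(flags, conditionMessage(w)); invokeRestart("muffleWarning")
    }
  )
  pv_table <- build_pv_table(efficacy, aggregation = config$aggregation)
  if (config$aggregation == "replicate") {
    flags <- c(flags, sprintf(
      "%d PV records interpreted as %d drugs x %d replicates (replicate-level regression input)",
      nrow(pv_table), dplyr::n_distinct(pv_table$drug_id),
      max(pv_table$replicate)))
  }

  # stage 5: group comparisons
  label_of <- function(x) tibble::tibble(drug_id = profile$drug_id, label = x)
  comparisons <- dplyr::bind_rows(
    run_comparison(pv_table,
                   tibble::tibble(drug_id = permeability$drug_id,
                                  label = permeability$pampa_class == "high"),
                   "pampa_high_vs_low"),
    run_comparison(pv_table,
                   tibble::tibble(
                     drug_id = permeability$drug_id,
                     label = dplyr::case_when(
                       permeability$caco2_class == "permeable" ~ TRUE,
                       permeability$caco2_class == "impermeable" ~ FALSE,
                       TRUE ~ NA
                     )),
                   "caco2_permeable_vs_impermeable"),
    run_comparison(pv_table, label_of(profile$ro5_pass), "ro5_pass_vs_fail"),
    run_comparison(pv_table, label_of(profile$ghose_pass), "ghose_pass_vs_fail"),
    run_comparison(pv_table, label_of(profile$veber_pass), "veber_pass_vs_fail"),
    run_comparison(pv_table, label_of(profile$qed_pass), "qed_pass_vs_fail")
  )

  # stage 6: QSAR regression on the merged design
  design <- dplyr::inner_join(pv_table, descriptors, by = "drug_id")
  fit_full <- qsar_fit(design)
  fit_step <- qsar_forward_stepwise(design, criterion = config$stepwise_criterion,
                                    p_enter = config$p_enter)
  split <- split_pareto(design, seed = stage_seed(config$seed, 12L))
  fit_train <- qsar_fit(split$training)
  val_pred <- predict(fit_train, split$validation)
  val_metrics <- oos_metrics(split$validation$pv, val_pred)
  cv <- qsar_cross_validate(design, k = config$cv_folds,
                            seed = stage_seed(config$seed, 13L))

  # write artifacts
  write_table_6sig(descriptors, path("descriptors.csv"))
  write_table_6sig(dplyr::select(profile, -"per_rule_details"), path("druglikeness.csv"))
  write_table_6sig(permeability, path("permeability.csv"))
  write_table_6sig(viability, path("viability.csv"))
  write_table_6sig(efficacy, path("efficacy.csv"))
  write_table_6sig(pv_table, path("pv.csv"))
  write_table_6sig(comparisons, path("comparisons.csv"))

  model_json <- list(
    full = list(intercept = fit_full$intercept,
                coefficients = as.list(fit_full$coefficients),
                t_values = as.list(fit_full$t_values),
                p_values = as.list(fit_full$p_values),
                r2 = fit_full$r2, rmse = fit_full$rmse,
                overall_p = fit_full$overall_p, n_obs = fit_full$n_obs),
    stepwise = list(selected = fit_step$selected,
                    selection_order = fit_step$selection_order,
                    intercept = fit_step$intercept,
                    coefficients = as.list(fit_step$coefficients),
                    r2 = fit_step$r2, rmse = fit_step$rmse,
                    criterion = config$stepwise_criterion,
                    p_enter = config$p_enter),
    training_validation = list(
      n_training = length(split$training_idx),
      n_validation = length(split$validation_idx),
      training_r2 = fit_train$r2, training_rmse = fit_train$rmse,
      validation_r2 = unname(val_metrics["r2"]),
      validation_rmse = unname(val_metrics["rmse"]))
  )
  jsonlite::write_json(model_json, path("qsar_model.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(training_idx = split$training_idx, validation_idx = split$validation_idx,
         proportions = as.list(split$proportions), seed = split$seed),
    path("split.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(k = cv$k, seed = cv$seed, per_fold = cv$per_fold,
         training_r2 = cv$training_r2, training_rmse = cv$training_rmse,
         validation_r2 = cv$validation_r2, validation_rmse = cv$validation_rmse),
    path("cv.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  metadata <- list(
    package_version = as.character(utils::packageVersion("spheroidperm")),
    seed = config$seed,
    config = list(
      ph = config$ph, pampa_threshold = config$pampa_threshold,
      ro5_max_violations = config$ro5_max_violations,
      qed_threshold = config$qed_threshold,
      stepwise_criterion = config$stepwise_criterion, p_enter = config$p_enter,
      cv_folds = config$cv_folds, aggregation = config$aggregation,
      descriptor_path = config$descriptor_path %||% "synthetic",
      viability_path = config$viability_path %||% "synthetic"
    ),
    row_counts = list(
      descriptors = nrow(descriptors), druglikeness = nrow(profile),
      permeability = nrow(permeability), viability = nrow(viability),
      efficacy = nrow(efficacy), pv = nrow(pv_table),
      comparisons = nrow(comparisons)
    ),
    range_warnings = nrow(range_flags),
    flags = flags
  )
  jsonlite::write_json(metadata, path("metadata.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    descriptors = descriptors, druglikeness = profile, permeability = permeability,
    viability = viability, efficacy = efficacy, pv = pv_table,
    comparisons = comparisons, fit_full = fit_full, fit_stepwise = fit_step,
    split = split, cv = cv, metadata = metadata,
    output_dir = config$output_dir
  ))
}

#' Write a human-readable run report
#'
#' Assembles `report.txt` in a completed run directory: group comparisons
#' (means, standard errors, p-values, degeneracy flags), model coefficients
#' with significance markers, fit and cross-validation metrics, and every
#' interpretation flag raised during the run. Regeneration is idempotent.
#'
#' @param run_dir A directory produced by [run_pipeline()].
#' @return The report path, invisibly.
#' @export
write_report <- function(run_dir) {
  needed <- c("comparisons.csv", "qsar_model.json", "cv.json", "metadata.json", "pv.csv")
  missing <- needed[!file.exists(file.path(run_dir, needed))]
  if (length(missing) > 0) {
    stop_spq(sprintf("incomplete run: missing artifact(s) %s",
                     paste(missing, collapse = ", ")),
             class = "reporting", missing = missing)
  }
  comparisons <- readr::read_csv(file.path(run_dir, "comparisons.csv"),
                                 show_col_types = FALSE, progress = FALSE)
  model <- jsonlite::read_json(file.path(run_dir, "qsar_model.json"))
  cv <- jsonlite::read_json(file.path(run_dir, "cv.json"))
  metadata <- jsonlite::read_json(file.path(run_dir, "metadata.json"))
  pv <- readr::read_csv(file.path(run_dir, "pv.csv"), show_col_types = FALSE,
                        progress = FALSE)

  lines <- c(
    "Spheroid drug-permeability screen report",
    "========================================",
    "",
    sprintf("PV records: %d (mean %.4f, sd %.4f)", nrow(pv), mean(pv$pv), sd(pv$pv)),
    "",
    "Group comparisons (mean PV, TRUE vs FALSE group)",
    "------------------------------------------------"
  )
  for (i in seq_len(nrow(comparisons))) {
    row <- comparisons[i, ]
    if (row$status != "ok") {
      lines <- c(lines, sprintf("%-32s %s", row$comparison, row$status))
    } else {
      deg <- if (isTRUE(row$degenerate)) " [degenerate: zero within-group variance]" else ""
      lines <- c(lines, sprintf(
        "%-32s %0.4f +/- %0.4f (n=%d) vs %0.4f +/- %0.4f (n=%d), t=%0.3f, p=%0.4g%s",
        row$comparison, row$mean_true, row$se_true, row$n_true,
        row$mean_false, row$se_false, row$n_false, row$statistic, row$p_value, deg))
    }
  }
  coefs <- model$full$coefficients
  pvals <- model$full$p_values
  lines <- c(lines, "",
             "QSAR model (all nine descriptors)",
             "---------------------------------",
             sprintf("intercept: %0.4f", model$full$intercept))
  for (term in names(coefs)) {
    p <- pvals[[term]]
    star <- if (!is.null(p) && is.numeric(p) && p < 0.05) " *" else ""
    lines <- c(lines, sprintf("%-18s %+0.4f (p=%0.4g)%s", term, coefs[[term]],
                              if (is.numeric(p)) p else NA, star))
  }
  lines <- c(lines,
             sprintf("fit: r2 = %0.3f, rmse = %0.4f, n = %d",
                     model$full$r2, model$full$rmse, model$full$n_obs),
             sprintf("stepwise (%s): selected %s", model$stepwise$criterion,
                     paste(unlist(model$stepwise$selected), collapse = ", ")),
             sprintf("80/20 split: %d training / %d validation; training r2 = %0.3f, validation r2 = %0.3f",
                     model$training_validation$n_training,
                     model$training_validation$n_validation,
                     model$training_validation$training_r2,
                     model$training_validation$validation_r2),
             "",
             sprintf("%d-fold cross-validation", cv$k),
             sprintf("training:   r2 = %0.3f, rmse = %0.4f", cv$training_r2, cv$training_rmse),
             sprintf("validation: r2 = %0.3f, rmse = %0.4f", cv$validation_r2, cv$validation_rmse),
             "",
             "Run flags",
             "---------",
             paste0("- ", unlist(metadata$flags)))
  out <- file.path(run_dir, "report.txt")
  writeLines(lines, out)
  invisible(out)
}
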