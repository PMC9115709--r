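# Train/validation splitting and k-fold cross-validation -----------------------
#
# The screen's 48 PV records are partitioned 80/20 ("Pareto rule"): validation
# size = floor(0.2 * n), so 48 -> 39 training / 9 validation. Cross-validation
# shuffles the records into k disjoint folds whose sizes differ by at most one
# (48, k = 5 -> folds of 10,10,10,9,9; training complements of 38,38,38,39,39),
# fits on each complement and evaluates on both partitions. Validation R^2 is
# computed about the validation-fold mean; aggregates are unweighted means
# over folds (pooled-prediction evaluation available).

#' Pareto (80/20) train/validation split
#'
#' Randomly permutes the records under `seed` and assigns
#' `floor(prop_validation * n)` of them to validation, the rest to training.
#'
#' @param data Tibble of records.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param prop_validation Validation proportion (default 0.2).
#' @return An object of class `split_plan`: `training` / `validation` tibbles,
#'   the corresponding row indices, the proportions and the seed.
#' @export
split_pareto <- function(data, seed = NULL, prop_validation = 0.2) {
  n <- nrow(data)
  if (n < 5) {
    stop_spq(sprintf("need at least 5 records to split (got %d)", n),
             class = "insufficient_data")
  }
  n_val <- floor(prop_validation * n)
  perm <- with_seed_if(seed, sample.int(n))
  validation_idx <- sort(perm[seq_len(n_val)])
  training_idx <- sort(perm[-seq_len(n_val)])
  structure(
    list(
      training = data[training_idx, , drop = FALSE],
      validation = data[validation_idx, , drop = FALSE],
      training_idx = training_idx,
      validation_idx = validation_idx,
      proportions = c(training = 1 - prop_validation, validation = prop_validation),
      seed = seed
    ),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("train/validation split: %d training, %d validation (%.0f%%/%.0f%%), seed = %s\n",
              length(x$training_idx), length(x$validation_idx),
              100 * x$proportions["training"], 100 * x$proportions["validation"],
              ifelse(is.null(x$seed), "<current RNG>", x$seed)))
  invisible(x)
}

# out-of-sample metrics; R^2 about the evaluation-set mean
oos_metrics <- function(observed, predicted) {
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  c(r2 = if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot,
    rmse = sqrt(mean((observed - predicted)^2)))
}

#' k-fold cross-validation of the QSAR model
#'
#' Shuffles the records (under `seed`) into `k` disjoint folds with sizes
#' differing by at most one. For each fold the model is fit on the complement
#' and R^2/RMSE are evaluated on both the training complement and the held-out
#' fold; aggregate metrics are unweighted means over folds (set
#' `pooled = TRUE` to also evaluate all held-out predictions pooled together).
#' `k = n` reduces to leave-one-out (held-out R^2 is undefined on single
#' observations and reported as `NA`; pooled metrics cover that case).
#'
#' @inheritParams qsar_fit
#' @param k Number of folds (default 5); `2 <= k <= n`.
#' @param seed Integer seed for the fold shuffle; `NULL` uses the current RNG
#'   stream.
#' @param pooled Also compute pooled-prediction validation metrics.
#' @return An object of class `qsar_cv`: `per_fold` metric tibble,
#'   `fold_assignments`, aggregate `training_r2`, `training_rmse`,
#'   `validation_r2`, `validation_rmse`, optional `pooled_*` metrics, `k`,
#'   `seed`, `descriptors`.
#' @export
qsar_cross_validate <- function(data, k = 5, seed = NULL,
                                descriptors = qsar_descriptors(),
                                response = "pv", rmse_df_adjust = FALSE,
                                pooled = FALSE) {
  n <- nrow(data)
  if (k < 2 || k > n) {
    stop_spq(sprintf("k must satisfy 2 <= k <= n (k = %d, n = %d)", k, n),
             class = "insufficient_data")
  }
  perm <- with_seed_if(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), length.out = n)

  per_fold <- purrr::map_dfr(seq_len(k), function(f) {
    train <- data[fold != f, , drop = FALSE]
    test <- data[fold == f, , drop = FALSE]
    fit <- qsar_fit(train, descriptors = descriptors, response = response,
                    rmse_df_adjust = rmse_df_adjust)
    pred <- predict(fit, test)
    val <- oos_metrics(test[[response]], pred)
    tibble::tibble(
      fold = f, n_train = nrow(train), n_validation = nrow(test),
      r2_train = fit$r2, rmse_train = fit$rmse,
      r2_validation = unname(val["r2"]), rmse_validation = unname(val["rmse"])
    )
  })

  out <- list(
    k = k, seed = seed, descriptors = descriptors, response = response,
    fold_assignments = tibble::tibble(row = seq_len(n), fold = fold),
    per_fold = per_fold,
    training_r2 = mean(per_fold$r2_train),
    training_rmse = mean(per_fold$rmse_train),
    validation_r2 = mean(per_fold$r2_validation),
    validation_rmse = mean(per_fold$rmse_validation)
  )
  if (pooled) {
    pooled_pred <- numeric(n)
    for (f in seq_len(k)) {
      fit <- qsar_fit(data[fold != f, , drop = FALSE], descriptors = descriptors,
                      response = response, rmse_df_adjust = rmse_df_adjust)
      pooled_pred[fold == f] <- predict(fit, data[fold == f, , drop = FALSE])
    }
    pm <- oos_metrics(data[[response]], pooled_pred)
    out$pooled_validation_r2 <- unname(pm["r2"])
    out$pooled_validation_rmse <- unname(pm["rmse"])
  }
  structure(out, class = "qsar_cv")
}

#' @export
print.qsar_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (n = %d, %d descriptors)\n",
              x$k, nrow(x$fold_assignments), length(x$descriptors)))
  cat(sprintf("training:   r2 = %.4f, rmse = %.4f\n", x$training_r2, x$training_rmse))
  cat(sprintf("validation: r2 = %.4f, rmse = %.4f\n", x$validation_r2, x$validation_rmse))
  invisible(x)
}

#' Per-fold cross-validation metrics
#'
#' @param x A `qsar_cv`.
#' @param ... Unused.
#' @return One row per fold with training/validation R^2 and RMSE.
#' @export
tidy.qsar_cv <- function(x, ...) x$per_fold

#' One-row cross-validation summary
#'
#' @param x A `qsar_cv`.
#' @param ... Unused.
#' @return Tibble of aggregate (fold-mean) training and validation metrics.
#' @export
glance.qsar_cv <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    training_r2 = x$training_r2, training_rmse = x$training_rmse,
    validation_r2 = x$validation_r2, validation_rmse = x$validation_rmse
  )
}
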