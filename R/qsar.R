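# QSAR multiple linear regression ---------------------------------------------
#
# PV ~ intercept + nine molecular descriptors, fit by ordinary least squares.
# Descriptors enter untransformed, as tabulated. Reported fit metrics:
#   r2   = 1 - SS_res / SS_tot on the fitting data
#   rmse = sqrt(SS_res / n)  -- plain root-mean-square of residuals (1/n, not
#          1/(n - p)); switchable via `rmse_df_adjust`.
# Forward stepwise selection starts from the intercept-only model and, at each
# step, admits the candidate with the smallest entry p-value below `p_enter`
# (or the largest AIC improvement), refitting the final model.

#' Construct a QSAR linear model from known coefficients
#'
#' Builds a prediction-only model object from an intercept and named
#' descriptor coefficients (for instance a published coefficient set), usable
#' with [predict()].
#'
#' @param coefficients Named numeric vector of descriptor coefficients.
#' @param intercept Intercept term.
#' @return An object of class `qsar_model`.
#' @export
#' @examples
#' m <- qsar_model(c(mw = 0.0036, logp = 0.0309), intercept = 0.1235)
#' predict(m, tibble::tibble(mw = 300, logp = 2))
qsar_model <- function(coefficients, intercept = 0) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            all(nzchar(names(coefficients))), length(intercept) == 1)
  structure(
    list(intercept = unname(intercept), coefficients = coefficients,
         selected = names(coefficients)),
    class = "qsar_model"
  )
}

#' Fit the QSAR model by ordinary least squares
#'
#' @param data Tibble containing the response and descriptor columns, one row
#'   per observation (e.g. per drug and replicate).
#' @param descriptors Character vector of descriptor columns to use; default
#'   all nine regression candidates ([qsar_descriptors()]). May be empty for
#'   the intercept-only model.
#' @param response Name of the response column (default `"pv"`).
#' @param rmse_df_adjust If `TRUE`, divide by the residual degrees of freedom
#'   instead of n when computing RMSE. Default `FALSE` (plain
#'   root-mean-square residual).
#' @return An object of classes `qsar_fit`, `qsar_model` with components
#'   `intercept`, `coefficients`, `selected`, `t_values`, `p_values`, `r2`,
#'   `rmse`, `overall_p` (regression F-test), `n_obs`, `fitted`, `residuals`
#'   and the underlying `lm` fit.
#' @export
qsar_fit <- function(data, descriptors = qsar_descriptors(), response = "pv",
                     rmse_df_adjust = FALSE) {
  assert_columns(data, c(response, descriptors), "QSAR design")
  assert_no_na(data, c(response, descriptors), "QSAR design")
  n <- nrow(data)
  p <- length(descriptors)
  if (n <= p + 1) {
    stop_spq(sprintf("need more observations (%d) than descriptors + 1 (%d)", n, p + 1),
             class = "insufficient_data")
  }
  df <- data[, c(response, descriptors), drop = FALSE]
  names(df)[1] <- ".response"
  fml <- if (p == 0) .response ~ 1 else
    stats::reformulate(sprintf("`%s`", descriptors), response = ".response")
  fit <- lm(fml, data = df)

  cf <- coef(fit)
  if (anyNA(cf)) {
    aliased <- gsub("`", "", names(cf)[is.na(cf)])
    stop_spq(sprintf("rank-deficient design; linearly dependent column(s): %s",
                     paste(aliased, collapse = ", ")),
             class = "collinearity", columns = aliased)
  }
  # summary.lm warns on exact-fit data; degenerate statistics are handled
  # explicitly downstream (significance_summary)
  sm <- suppressWarnings(summary(fit))
  ct <- sm$coefficients
  rownames(ct) <- gsub("`", "", rownames(ct))
  names(cf) <- gsub("`", "", names(cf))

  res <- stats::residuals(fit)
  ss_res <- sum(res^2)
  y <- df$.response
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  rmse_div <- if (rmse_df_adjust) max(fit$df.residual, 1) else n
  overall_p <- if (p == 0 || is.null(sm$fstatistic)) NA_real_ else
    unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3], lower.tail = FALSE))

  structure(
    list(
      intercept = unname(cf["(Intercept)"]),
      coefficients = cf[setdiff(names(cf), "(Intercept)")],
      selected = descriptors,
      selection_order = NULL,
      t_values = ct[, "t value"],
      p_values = ct[, "Pr(>|t|)"],
      std_errors = ct[, "Std. Error"],
      r2 = r2,
      rmse = sqrt(ss_res / rmse_div),
      overall_p = overall_p,
      n_obs = n,
      response = response,
      fitted = unname(stats::fitted(fit)),
      residuals = unname(res),
      observed = y,
      lm_fit = fit
    ),
    class = c("qsar_fit", "qsar_model")
  )
}

#' Forward stepwise descriptor selection
#'
#' Starts from the intercept-only model; at each step fits every remaining
#' candidate and admits the one that most improves the entry criterion --
#' under `"p_enter"` the candidate with the smallest entering-coefficient
#' p-value, admitted only if strictly below `p_enter`; under `"aic"` the
#' candidate with the largest AIC decrease. Stops when no candidate
#' qualifies, then refits the final model and records the selection order.
#' `p_enter = 1` effectively forces all candidates in; `p_enter = 0` returns
#' the intercept-only model.
#'
#' @inheritParams qsar_fit
#' @param candidates Candidate descriptor columns.
#' @param criterion `"p_enter"` (default) or `"aic"`.
#' @param p_enter Entry threshold on the entering coefficient's two-tailed
#'   p-value (used by the `"p_enter"` criterion).
#' @return A `qsar_fit` with `selected` and `selection_order` reflecting the
#'   stepwise path.
#' @export
qsar_forward_stepwise <- function(data, candidates = qsar_descriptors(),
                                  response = "pv",
                                  criterion = c("p_enter", "aic"),
                                  p_enter = 0.05, rmse_df_adjust = FALSE) {
  criterion <- match.arg(criterion)
  if (length(candidates) == 0) {
    stop_spq("candidate set is empty", class = "validation")
  }
  assert_columns(data, c(response, candidates), "QSAR design")
  assert_no_na(data, c(response, candidates), "QSAR design")

  selected <- character()
  remaining <- candidates
  y0 <- data[[response]]
  current_aic <- stats::AIC(lm(y0 ~ 1))

  repeat {
    if (length(remaining) == 0) break
    if (nrow(data) <= length(selected) + 2) break  # no room for another term
    trials <- purrr::map(remaining, function(cand) {
      fit <- qsar_fit(data, descriptors = c(selected, cand), response = response,
                      rmse_df_adjust = rmse_df_adjust)
      list(
        candidate = cand,
        entry_p = unname(fit$p_values[cand]),
        aic = stats::AIC(fit$lm_fit)
      )
    })
    if (criterion == "p_enter") {
      ps <- vapply(trials, function(t) t$entry_p %||% NA_real_, numeric(1))
      ps[is.na(ps)] <- 1  # degenerate (zero-residual) entries cannot qualify
      best <- which.min(ps)
      if (!(ps[best] < p_enter)) break
    } else {
      aics <- vapply(trials, function(t) t$aic, numeric(1))
      best <- which.min(aics)
      if (!(aics[best] < current_aic)) break
      current_aic <- aics[best]
    }
    selected <- c(selected, trials[[best]]$candidate)
    remaining <- setdiff(remaining, selected)
  }

  out <- qsar_fit(data, descriptors = selected, response = response,
                  rmse_df_adjust = rmse_df_adjust)
  out$selection_order <- selected
  out
}

#' Predict PVs from a QSAR model
#'
#' Linear combination of the selected descriptors:
#' `intercept + sum(coefficients * descriptors)`. Each unit increase in a
#' descriptor changes the prediction by exactly its coefficient.
#'
#' @param object A `qsar_model` or `qsar_fit`.
#' @param newdata Tibble containing every selected descriptor column.
#' @param ... Unused.
#' @return Numeric vector of predicted PVs.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  sel <- names(object$coefficients)
  assert_columns(newdata, sel, "prediction data")
  assert_no_na(newdata, sel, "prediction data")
  if (length(sel) == 0) return(rep(object$intercept, nrow(newdata)))
  x <- as.matrix(newdata[, sel, drop = FALSE])
  drop(object$intercept + x %*% object$coefficients)
}

#' Coefficient significance summary
#'
#' Terms ordered by decreasing absolute t statistic, flagged significant at a
#' two-tailed p below `alpha`. A saturated zero-residual fit has undefined
#' t/p values; such terms are reported with `NA` statistics and
#' `degenerate = TRUE` instead of crashing.
#'
#' @param model A `qsar_fit`.
#' @param alpha Significance level (default 0.05).
#' @return Tibble `term`, `estimate`, `std_error`, `statistic`, `p_value`,
#'   `significant`, `degenerate`.
#' @export
significance_summary <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "qsar_fit"))
  terms <- names(model$t_values)
  est <- c("(Intercept)" = model$intercept, model$coefficients)[terms]
  stat <- model$t_values
  p <- model$p_values
  degenerate <- !is.finite(stat)
  out <- tibble::tibble(
    term = terms,
    estimate = unname(est),
    std_error = unname(model$std_errors),
    statistic = ifelse(degenerate, NA_real_, unname(stat)),
    p_value = ifelse(degenerate, NA_real_, unname(p)),
    significant = !degenerate & !is.na(p) & p < alpha,
    degenerate = degenerate
  )
  out[order(-abs(ifelse(is.na(out$statistic), -Inf, out$statistic))), ]
}

#' @export
print.qsar_fit <- function(x, ...) {
  cat(sprintf("QSAR linear model: %s ~ %s\n", x$response,
              if (length(x$selected) == 0) "1" else paste(x$selected, collapse = " + ")))
  cat(sprintf("n = %d, r2 = %.4f, rmse = %.4f, overall p = %s\n",
              x$n_obs, x$r2, x$rmse,
              ifelse(is.na(x$overall_p), "NA", format.pval(x$overall_p))))
  if (!is.null(x$selection_order) && length(x$selection_order) > 0) {
    cat("selection order:", paste(x$selection_order, collapse = " -> "), "\n")
  }
  print(significance_summary(x), n = Inf)
  invisible(x)
}

#' @export
print.qsar_model <- function(x, ...) {
  cat("QSAR coefficient model\n")
  print(c("(Intercept)" = x$intercept, x$coefficients))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a QSAR fit
#'
#' @param x A `qsar_fit`.
#' @param alpha Significance level for the `significant` flag.
#' @param ... Unused.
#' @return One row per model term with estimate, standard error, t statistic,
#'   p-value and significance flag (broom conventions).
#' @export
tidy.qsar_fit <- function(x, alpha = 0.05, ...) {
  s <- significance_summary(x, alpha = alpha)
  tibble::tibble(
    term = s$term, estimate = s$estimate, std.error = s$std_error,
    statistic = s$statistic, p.value = s$p_value, significant = s$significant
  )
}

#' One-row fit summary of a QSAR fit
#'
#' @param x A `qsar_fit`.
#' @param ... Unused.
#' @return Tibble with `r.squared`, `rmse`, `p.value` (overall F-test),
#'   `n_obs`, `n_selected`.
#' @export
glance.qsar_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r2, rmse = x$rmse, p.value = x$overall_p,
    n_obs = x$n_obs, n_selected = length(x$selected)
  )
}

#' Augment data with QSAR fit predictions and residuals
#'
#' @param x A `qsar_fit`.
#' @param data Data to augment; defaults to reconstructing fitted values and
#'   residuals of the training data.
#' @param ... Unused.
#' @return `data` with `.fitted` and (when the response is present) `.resid`.
#' @export
augment.qsar_fit <- function(x, data = NULL, ...) {
  if (is.null(data)) {
    return(tibble::tibble(.observed = x$observed, .fitted = x$fitted,
                          .resid = x$residuals))
  }
  out <- tibble::as_tibble(data)
  out$.fitted <- predict(x, out)
  if (x$response %in% names(out)) out$.resid <- out[[x$response]] - out$.fitted
  out
}
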