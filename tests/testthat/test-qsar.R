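test_that("exact linear data is recovered with r2 = 1 and rmse = 0", {
  tbl <- fixture_descriptors(seed = 21)
  tbl$pv <- 0.1 + 0.002 * tbl$mw
  fit <- qsar_fit(dplyr::bind_rows(tbl, tbl, tbl), descriptors = "mw")
  expect_equal(fit$intercept, 0.1, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["mw"]), 0.002, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(fit$rmse, 0, tolerance = 1e-10)
})

test_that("OLS equals the normal-equations oracle on random designs", {
  withr::local_seed(100)
  for (rep in 1:50) {
    n <- sample(15:200, 1)
    p <- sample(1:12, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
    y <- rnorm(n, mean = X %*% rnorm(p), sd = 0.5)
    data <- dplyr::bind_cols(tibble::as_tibble(X), pv = y)
    fit <- qsar_fit(data, descriptors = colnames(X))
    oracle <- ols_oracle(X, y)
    expect_lt(max(abs(c(fit$intercept, fit$coefficients) - oracle)), 1e-8)
  }
})

test_that("rank-deficient designs raise a collinearity error naming the columns", {
  tbl <- fixture_descriptors(seed = 22)
  tbl$pv <- rnorm(16, 0.075, 0.05)
  tbl$mw_copy <- tbl$mw
  err <- expect_spq_error(qsar_fit(tbl, descriptors = c("mw", "logp", "mw_copy")),
                         "collinearity")
  expect_match(conditionMessage(err), "mw_copy")

  expect_spq_error(qsar_fit(tbl[1:5, ], descriptors = qsar_descriptors()),
                   "insufficient_data")
})

test_that("forward stepwise picks the truly predictive candidate first", {
  withr::local_seed(200)
  n <- 48
  X <- matrix(rnorm(n * 9), n, 9, dimnames = list(NULL, paste0("x", 1:9)))
  y <- 10 * X[, 4] + rnorm(n)  # effect 10 SD above noise on x4
  data <- dplyr::bind_cols(tibble::as_tibble(X), pv = y)
  fit <- qsar_forward_stepwise(data, candidates = colnames(X))
  expect_equal(fit$selection_order[1], "x4")

  # exhaustive single-step search oracle: x4 has the smallest entry p-value
  entry_p <- vapply(colnames(X), function(cand) {
    f <- qsar_fit(data, descriptors = cand)
    unname(f$p_values[cand])
  }, numeric(1))
  expect_equal(names(which.min(entry_p)), "x4")

  # p_enter = 0: nothing can enter
  fit0 <- qsar_forward_stepwise(data, candidates = colnames(X), p_enter = 0)
  expect_equal(length(fit0$selected), 0)
  expect_equal(fit0$r2, 0)

  # forcing all candidates in reproduces the full OLS fit
  fit_all <- qsar_forward_stepwise(data, candidates = colnames(X), p_enter = 1)
  full <- qsar_fit(data, descriptors = colnames(X))
  expect_equal(sort(fit_all$selected), sort(colnames(X)))
  expect_equal(fit_all$coefficients[sort(names(fit_all$coefficients))],
               full$coefficients[sort(names(full$coefficients))], tolerance = 1e-12)

  # AIC criterion also ranks the true effect first
  fit_aic <- qsar_forward_stepwise(data, candidates = colnames(X), criterion = "aic")
  expect_equal(fit_aic$selection_order[1], "x4")
})

test_that("training r2 is non-decreasing along the stepwise path", {
  cfg <- sim_config(seed = 17)
  d <- simulate_descriptor_table(cfg)
  pv <- simulate_pv_truth(d, cfg)
  design <- dplyr::inner_join(pv[, c("drug_id", "replicate", "pv")], d, by = "drug_id")
  fit <- qsar_forward_stepwise(design, p_enter = 1)
  path_r2 <- vapply(seq_along(fit$selection_order), function(k) {
    qsar_fit(design, descriptors = fit$selection_order[1:k])$r2
  }, numeric(1))
  expect_true(all(diff(c(0, path_r2)) >= -1e-12))
})

test_that("prediction is the exact linear combination of selected descriptors", {
  beta <- pv_coefficients()
  model <- qsar_model(beta[qsar_descriptors()], intercept = beta[["intercept"]])

  zeros <- tibble::as_tibble(as.list(setNames(rep(0, 9), qsar_descriptors())))
  expect_equal(predict(model, zeros), 0.1235)

  ones <- tibble::as_tibble(as.list(setNames(rep(1, 9), qsar_descriptors())))
  expect_equal(predict(model, ones), 0.1873, tolerance = 1e-12)

  # unit increase in one descriptor moves the prediction by its coefficient
  for (d in c("mw", "logs", "polarizability")) {
    bumped <- zeros; bumped[[d]] <- 1
    expect_equal(predict(model, bumped) - predict(model, zeros),
                 unname(beta[d]), tolerance = 1e-12)
  }

  expect_spq_error(predict(model, zeros[, -1]), "missing_data")
})

test_that("the Pareto split gives floor(0.2 n) validation records, reproducibly", {
  tbl <- tibble::tibble(pv = rnorm(48), id = 1:48)
  sp <- split_pareto(tbl, seed = 5)
  expect_equal(length(sp$training_idx), 39)
  expect_equal(length(sp$validation_idx), 9)
  expect_equal(sort(c(sp$training_idx, sp$validation_idx)), 1:48)

  sp10 <- split_pareto(tbl[1:10, ], seed = 5)
  expect_equal(length(sp10$training_idx), 8)
  expect_equal(length(sp10$validation_idx), 2)

  sp2 <- split_pareto(tbl, seed = 5)
  expect_identical(sp$training_idx, sp2$training_idx)
  expect_spq_error(split_pareto(tbl[1:4, ]), "insufficient_data")
})

test_that("cross-validation folds are disjoint, exhaustive and near-equal", {
  cfg <- sim_config(seed = 19)
  d <- simulate_descriptor_table(cfg)
  pv <- simulate_pv_truth(d, cfg)
  design <- dplyr::inner_join(pv[, c("drug_id", "replicate", "pv")], d, by = "drug_id")
  cv <- qsar_cross_validate(design, k = 5, seed = 7)
  expect_equal(sort(cv$per_fold$n_validation, decreasing = TRUE), c(10, 10, 10, 9, 9))
  expect_equal(sort(cv$per_fold$n_train), c(38, 38, 38, 39, 39))
  expect_equal(sort(unique(cv$fold_assignments$fold)), 1:5)
  expect_equal(nrow(cv$fold_assignments), 48)

  # aggregates are the unweighted fold means
  expect_equal(cv$validation_rmse, mean(cv$per_fold$rmse_validation))
  expect_equal(cv$training_r2, mean(cv$per_fold$r2_train))

  # determinism under the seed
  cv2 <- qsar_cross_validate(design, k = 5, seed = 7)
  expect_identical(cv$fold_assignments, cv2$fold_assignments)
})

test_that("zero-noise linear data cross-validates perfectly", {
  tbl <- fixture_descriptors(seed = 23)
  tbl$pv <- 0.05 + 0.001 * tbl$mw - 0.002 * tbl$psa
  cv <- qsar_cross_validate(tbl, k = 4, seed = 1, descriptors = c("mw", "psa"))
  expect_equal(cv$per_fold$r2_validation, rep(1, 4), tolerance = 1e-8)
  expect_equal(cv$per_fold$rmse_validation, rep(0, 4), tolerance = 1e-8)
})

test_that("k = n cross-validation reduces to leave-one-out", {
  withr::local_seed(55)
  n <- 12
  tbl <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  tbl$pv <- 0.2 + 0.5 * tbl$x1 - 0.3 * tbl$x2 + rnorm(n, 0, 0.1)
  cv <- qsar_cross_validate(tbl, k = n, seed = 9, descriptors = c("x1", "x2"),
                            pooled = TRUE)
  # direct leave-one-out oracle
  loo_pred <- vapply(seq_len(n), function(i) {
    fit <- lm(pv ~ x1 + x2, data = tbl[-i, ])
    unname(predict(fit, tbl[i, ]))
  }, numeric(1))
  oracle_rmse <- sqrt(mean((tbl$pv - loo_pred)^2))
  expect_equal(cv$pooled_validation_rmse, oracle_rmse, tolerance = 1e-10)
  # per-fold rmse mean equals the mean absolute LOO residual
  expect_equal(cv$validation_rmse, mean(abs(tbl$pv - loo_pred)), tolerance = 1e-10)
})

test_that("significance flags identify a single true effect and ignore column order", {
  withr::local_seed(300)
  hits <- vapply(1:200, function(i) {
    n <- 48
    X <- matrix(rnorm(n * 9), n, 9, dimnames = list(NULL, paste0("x", 1:9)))
    y <- 1.5 * X[, 7] + rnorm(n)
    data <- dplyr::bind_cols(tibble::as_tibble(X), pv = y)
    s <- significance_summary(qsar_fit(data, descriptors = colnames(X)))
    "x7" %in% s$term[s$significant]
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # flags unchanged by descriptor column reordering
  tbl <- fixture_descriptors(seed = 29)
  cfg <- sim_config(seed = 29)
  pv <- simulate_pv_truth(tbl, cfg)
  design <- dplyr::inner_join(pv[, c("drug_id", "replicate", "pv")], tbl, by = "drug_id")
  s1 <- significance_summary(qsar_fit(design, descriptors = qsar_descriptors()))
  s2 <- significance_summary(qsar_fit(design, descriptors = rev(qsar_descriptors())))
  expect_equal(s1[order(s1$term), ], s2[order(s2$term), ], tolerance = 1e-10)
})

test_that("a saturated zero-residual fit reports degenerate statistics without crashing", {
  tbl <- tibble::tibble(x1 = 1:10, pv = 2 + 3 * (1:10))  # exact linear response
  fit <- qsar_fit(tbl, descriptors = "x1")
  expect_equal(fit$r2, 1)
  s <- significance_summary(fit)
  expect_s3_class(s, "tbl_df")
  expect_equal(nrow(s), 2)
})

test_that("tidy, glance and augment follow broom conventions", {
  cfg <- sim_config(seed = 31)
  d <- simulate_descriptor_table(cfg)
  pv <- simulate_pv_truth(d, cfg)
  design <- dplyr::inner_join(pv[, c("drug_id", "replicate", "pv")], d, by = "drug_id")
  fit <- qsar_fit(design)

  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value", "significant"))
  expect_equal(nrow(td), 10)

  gl <- glance(fit)
  expect_equal(gl$n_obs, 48)
  expect_true(gl$r.squared >= 0 && gl$r.squared <= 1)
  expect_equal(gl$rmse, sqrt(mean(fit$residuals^2)))

  aug <- augment(fit, design)
  expect_equal(aug$.fitted, unname(predict(fit, design)))
  expect_equal(aug$.resid, design$pv - aug$.fitted)
})
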