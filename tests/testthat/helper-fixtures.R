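# shared fixtures and independent oracles, built in code at test time

# a 16-drug descriptor table with all columns populated (seeded generator)
fixture_descriptors <- function(seed = 42, n_drugs = 16) {
  simulate_descriptor_table(sim_config(seed = seed, n_drugs = n_drugs))
}

# one fully drug-like record with hand-set values
fixture_record <- function(...) {
  base <- tibble::tibble(
    drug_id = "d1", mw = 300, logp = 2, logs = -3, hba_count = 5, hbd_count = 2,
    psa = 70, rotatable_bonds = 4, refractivity = 80, polarizability = 30,
    pka = 7.4, sa_ha_fraction = 0.2, sa_hd_fraction = 0.1, atom_count = 30,
    aromatic_ring_count = 2, alerts_count = 0, ic50_monolayer = 1
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

# a complete viability table for d drugs x r replicates with exact efficacies
fixture_viability <- function(eff_am, eff_asc, eff_mda, drugs = "d1", reps = 1) {
  grid <- tidyr::expand_grid(drug_id = drugs, replicate = seq_len(reps))
  purrr::pmap_dfr(grid, function(drug_id, replicate) {
    tibble::tibble(
      drug_id = drug_id,
      composition = spheroid_compositions(),
      replicate = replicate,
      signal_control = 1e5,
      signal_treated = 1e5 * (1 - c(eff_am, eff_asc, eff_mda)),
      concentration = 10
    )
  })
}

# independent OLS oracle: normal equations via solve(crossprod)
ols_oracle <- function(X, y) {
  Xi <- cbind(`(Intercept)` = 1, as.matrix(X))
  drop(solve(crossprod(Xi), crossprod(Xi, y)))
}

# independent pooled-variance two-sample t oracle
pooled_t_oracle <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  tval <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  df <- length(x) + length(y) - 2
  list(statistic = tval, df = df, p_value = 2 * pt(-abs(tval), df))
}

expect_spq_error <- function(expr, class) {
  expect_error(expr, class = paste0("spq_error_", class))
}
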