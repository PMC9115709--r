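test_that("Rule-of-Five violations are counted with strict-inequality thresholds", {
  # interior point: no violations
  r <- evaluate_ro5(fixture_record(mw = 300, logp = 2, hbd_count = 2, hba_count = 5))
  expect_equal(r$ro5_violations, 0L)
  expect_true(r$ro5_pass)

  # doxorubicin-like: three threshold breaches, fails even at one allowed violation
  r <- evaluate_ro5(fixture_record(mw = 543.5, logp = 1.3, hbd_count = 6, hba_count = 12),
                    max_violations = 1)
  expect_equal(r$ro5_violations, 3L)
  expect_false(r$ro5_pass)
  expect_setequal(r$ro5_failed[[1]], c("mw > 500", "hbd_count > 5", "hba_count > 10"))

  # exact boundaries are not violations
  r <- evaluate_ro5(fixture_record(mw = 500, logp = 5, hbd_count = 5, hba_count = 10))
  expect_equal(r$ro5_violations, 0L)

  err <- expect_spq_error(evaluate_ro5(fixture_record()[, c("drug_id", "mw", "logp")]),
                          "missing_data")
  expect_match(conditionMessage(err), "hba_count")
})

test_that("tightening the violation allowance can only turn pass into fail", {
  tbl <- fixture_descriptors(seed = 11)
  for (allow in 3:1) {
    loose <- evaluate_ro5(tbl, max_violations = allow)$ro5_pass
    tight <- evaluate_ro5(tbl, max_violations = allow - 1)$ro5_pass
    expect_true(all(loose[tight]), info = sprintf("allowance %d -> %d", allow, allow - 1))
  }
})

test_that("Ghose filter uses inclusive bounds and names the breached bound", {
  expect_true(evaluate_ghose(fixture_record(mw = 300, logp = 2, refractivity = 80,
                                            atom_count = 30))$ghose_pass)
  r <- evaluate_ghose(fixture_record(mw = 150))
  expect_false(r$ghose_pass)
  expect_equal(r$ghose_failed[[1]], "mw below 160")
  # upper boundary values pass (inclusive)
  expect_true(evaluate_ghose(fixture_record(mw = 480, logp = 5.6, refractivity = 130,
                                            atom_count = 70))$ghose_pass)
})

test_that("Veber's rule uses inclusive bounds", {
  expect_true(evaluate_veber(fixture_record(rotatable_bonds = 5, psa = 90))$veber_pass)
  expect_false(evaluate_veber(fixture_record(rotatable_bonds = 11, psa = 90))$veber_pass)
  expect_true(evaluate_veber(fixture_record(rotatable_bonds = 10, psa = 140))$veber_pass)
})

test_that("unweighted QED matches the independent desirability-formula oracle", {
  # frozen oracle: published ADS formulas composed by equal-weight geometric
  # mean, evaluated independently (RDKit QED.ads) for this vector
  rec <- fixture_record(mw = 300, logp = 2.5, hba_count = 5, hbd_count = 1,
                        psa = 70, rotatable_bonds = 4, aromatic_ring_count = 2,
                        alerts_count = 0)
  expect_equal(compute_qed_unweighted(rec)$qed_value, 0.9199864654792246,
               tolerance = 1e-9)
})

test_that("QED is 1 at the desirability argmaxes and invariant to descriptor roles", {
  params <- list(mw = c(0, 800), logp = c(-10, 10), hba_count = c(0, 20),
                 hbd_count = c(0, 20), psa = c(0, 300), rotatable_bonds = c(0, 20),
                 aromatic_ring_count = c(0, 10), alerts_count = c(-5, 10))
  argmax <- purrr::imap_dbl(params, function(bracket, prop) {
    stats::optimize(function(x) qed_desirability(x, prop),
                    bracket, maximum = TRUE, tol = 1e-12)$maximum
  })
  rec <- fixture_record()
  for (nm in names(argmax)) rec[[nm]] <- argmax[[nm]]
  expect_equal(compute_qed_unweighted(rec)$qed_value, 1, tolerance = 1e-8)

  # geometric mean is symmetric: swapping which descriptor carries a given
  # desirability leaves QED unchanged
  d_target <- c(0.9, 0.5)
  inv <- function(prop, d) {
    stats::uniroot(function(x) qed_desirability(x, prop) - d,
                   c(argmax[[prop]], 2000), tol = 1e-12)$root
  }
  rec1 <- rec; rec1$mw <- inv("mw", 0.9); rec1$psa <- inv("psa", 0.5)
  rec2 <- rec; rec2$mw <- inv("mw", 0.5); rec2$psa <- inv("psa", 0.9)
  expect_equal(compute_qed_unweighted(rec1)$qed_value,
               compute_qed_unweighted(rec2)$qed_value, tolerance = 1e-9)
})

test_that("QED is strictly increasing in each descriptor's desirability", {
  rec <- fixture_record()
  base <- compute_qed_unweighted(rec)$qed_value
  # moving any descriptor away from high desirability lowers QED
  worse <- list(mw = 700, logp = 9, hba_count = 12, hbd_count = 8, psa = 250,
                rotatable_bonds = 15, aromatic_ring_count = 7, alerts_count = 4)
  for (nm in names(worse)) {
    rec2 <- rec; rec2[[nm]] <- worse[[nm]]
    expect_lt(compute_qed_unweighted(rec2)$qed_value, base)
  }
  # missing any of the eight inputs is an error, never a silent subset QED
  expect_spq_error(compute_qed_unweighted(dplyr::select(rec, -"alerts_count")),
                   "missing_data")
})

test_that("profiles aggregate the four rules and are stable under row reordering", {
  rec <- fixture_record()
  p <- profile_druglikeness(rec)
  expect_true(p$ro5_pass && p$ghose_pass && p$veber_pass && p$qed_pass)

  only_veber_fails <- fixture_record(rotatable_bonds = 12)
  p <- profile_druglikeness(only_veber_fails)
  expect_false(p$veber_pass)
  expect_true(p$ro5_pass && p$ghose_pass && p$qed_pass)

  tbl <- fixture_descriptors(seed = 5)
  p1 <- profile_druglikeness(tbl)
  perm <- rev(seq_len(nrow(tbl)))
  p2 <- profile_druglikeness(tbl[perm, ])
  expect_equal(as.data.frame(p2[order(p2$drug_id), names(p2) != "per_rule_details"]),
               as.data.frame(p1[order(p1$drug_id), names(p1) != "per_rule_details"]))

  # re-evaluation is bit-identical (pure function of record and config)
  expect_identical(
    profile_druglikeness(tbl)[, 1:7],
    profile_druglikeness(tbl)[, 1:7]
  )
})

test_that("a rule with missing inputs is marked not evaluable while others are evaluated", {
  rec <- dplyr::select(fixture_record(), -"atom_count")  # breaks Ghose only
  p <- profile_druglikeness(rec)
  expect_true(is.na(p$ghose_pass))
  expect_match(p$per_rule_details[[1]]$ghose[1], "not evaluable")
  expect_true(p$ro5_pass)
  expect_true(p$veber_pass)
  expect_false(is.na(p$qed_value))
})
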