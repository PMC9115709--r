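# Drug-likeness rules ---------------------------------------------------------
#
# Four rule sets over the physicochemical descriptors:
#   * Lipinski Rule of Five: violations counted for MW > 500, logP > 5,
#     HBD > 5, HBA > 10 (strict inequalities); pass iff violations <=
#     max_violations (default 0).
#   * Ghose filter: 160 <= MW <= 480, -0.4 <= logP <= 5.6,
#     40 <= refractivity <= 130, 20 <= atom count <= 70 (inclusive).
#   * Veber's rule: rotatable bonds <= 10 and PSA <= 140 A^2 (inclusive).
#   * Unweighted QED: equal-weight geometric mean of eight asymmetric
#     double-sigmoid desirability functions with the published parameter set.

require_fields <- function(data, fields, rule) {
  missing_cols <- setdiff(fields, names(data))
  if (length(missing_cols) > 0) {
    stop_spq(sprintf("%s: missing descriptor(s): %s", rule,
                     paste(missing_cols, collapse = ", ")),
             class = "missing_data", columns = missing_cols)
  }
  for (f in fields) {
    if (anyNA(data[[f]])) {
      bad <- data$drug_id[is.na(data[[f]])]
      stop_spq(sprintf("%s: missing descriptor '%s' for drug_id %s", rule, f,
                       paste(bad, collapse = ", ")),
               class = "missing_data", column = f, drug_id = bad)
    }
  }
  invisible(data)
}

#' Lipinski Rule of Five
#'
#' Counts violations of MW > 500 Da, logP > 5, H-bond donors > 5 and
#' H-bond acceptors > 10. Boundary values (e.g. MW exactly 500) are not
#' violations: the rule's thresholds are strict inequalities.
#'
#' @param data Descriptor tibble with `drug_id`, `mw`, `logp`, `hba_count`,
#'   `hbd_count`.
#' @param max_violations Violation allowance; a drug passes iff its violation
#'   count is `<= max_violations`. Default 0 (strict compliance); set 1 for
#'   the common one-violation reading.
#' @return Tibble `drug_id`, `ro5_violations`, `ro5_pass`, `ro5_failed`
#'   (list-column of failed conditions).
#' @export
evaluate_ro5 <- function(data, max_violations = 0) {
  require_fields(data, c("drug_id", "mw", "logp", "hba_count", "hbd_count"), "Rule of Five")
  stopifnot(is.numeric(max_violations), max_violations >= 0)
  conds <- list(
    "mw > 500"        = data$mw > 500,
    "logp > 5"        = data$logp > 5,
    "hbd_count > 5"   = data$hbd_count > 5,
    "hba_count > 10"  = data$hba_count > 10
  )
  hit <- do.call(cbind, conds)
  violations <- rowSums(hit)
  failed <- apply(hit, 1, function(row) names(conds)[row], simplify = FALSE)
  tibble::tibble(
    drug_id = data$drug_id,
    ro5_violations = as.integer(violations),
    ro5_pass = violations <= max_violations,
    ro5_failed = failed
  )
}

#' Ghose filter
#'
#' Pass iff 160 <= MW <= 480, -0.4 <= logP <= 5.6, 40 <= molar refractivity
#' <= 130 and 20 <= heavy-atom count <= 70, all bounds inclusive.
#'
#' @inheritParams evaluate_ro5
#' @return Tibble `drug_id`, `ghose_pass`, `ghose_failed` (list-column of
#'   failure details such as `"mw below 160"`).
#' @export
evaluate_ghose <- function(data) {
  require_fields(data, c("drug_id", "mw", "logp", "refractivity", "atom_count"),
                 "Ghose filter")
  bounds <- list(
    mw = c(160, 480), logp = c(-0.4, 5.6), refractivity = c(40, 130),
    atom_count = c(20, 70)
  )
  details <- lapply(seq_len(nrow(data)), function(i) {
    fails <- character()
    for (f in names(bounds)) {
      b <- bounds[[f]]
      x <- data[[f]][i]
      if (x < b[1]) fails <- c(fails, sprintf("%s below %g", f, b[1]))
      if (x > b[2]) fails <- c(fails, sprintf("%s above %g", f, b[2]))
    }
    fails
  })
  tibble::tibble(
    drug_id = data$drug_id,
    ghose_pass = lengths(details) == 0,
    ghose_failed = details
  )
}

#' Veber's rule
#'
#' Pass iff rotatable bonds <= 10 and polar surface area <= 140 A^2
#' (inclusive bounds).
#'
#' @inheritParams evaluate_ro5
#' @return Tibble `drug_id`, `veber_pass`, `veber_failed` (list-column).
#' @export
evaluate_veber <- function(data) {
  require_fields(data, c("drug_id", "rotatable_bonds", "psa"), "Veber's rule")
  details <- lapply(seq_len(nrow(data)), function(i) {
    fails <- character()
    if (data$rotatable_bonds[i] > 10) fails <- c(fails, "rotatable_bonds above 10")
    if (data$psa[i] > 140) fails <- c(fails, "psa above 140")
    fails
  })
  tibble::tibble(
    drug_id = data$drug_id,
    veber_pass = lengths(details) == 0,
    veber_failed = details
  )
}

# Published asymmetric-double-sigmoid (ADS) desirability parameters, one row
# per QED property, verbatim from the original fitted parameter table. dmax is
# the function's maximum, used to normalise each desirability into (0, 1].
qed_ads_params <- function() {
  tibble::tribble(
    ~property,             ~a,          ~b,          ~c,          ~d,          ~e,          ~f,          ~dmax,
    "mw",                  2.817065973, 392.5754953, 290.7489764, 2.419764353, 49.22325677, 65.37051707, 104.9805561,
    "logp",                3.172690585, 137.8624751, 2.534937431, 4.581497897, 0.822739154, 0.576295591, 131.3186604,
    "hba_count",           2.948620388, 160.4605972, 3.615294657, 4.435986202, 0.290141953, 1.300669958, 148.7763046,
    "hbd_count",           1.618662227, 1010.051101, 0.985094388, 0.000000001, 0.713820843, 0.920922555, 258.1632616,
    "psa",                 1.876861559, 125.2232657, 62.90773554, 87.83366614, 12.01999824, 28.51324732, 104.5686167,
    "rotatable_bonds",     0.010000000, 272.4121427, 2.558379970, 1.565547684, 1.271567166, 2.758063707, 105.4420403,
    "aromatic_ring_count", 3.217788970, 957.7374108, 2.274627939, 0.000000001, 1.317690384, 0.375760881, 312.3372610,
    "alerts_count",        0.010000000, 1199.094025, -0.09002883, 0.000000001, 0.185904477, 0.875193782, 417.7253140
  )
}

qed_properties <- function() qed_ads_params()$property

#' QED desirability of a descriptor value
#'
#' Evaluates the published asymmetric double-sigmoid desirability function for
#' one QED property, normalised by its maximum so the result lies in (0, 1].
#'
#' @param x Numeric vector of descriptor values.
#' @param property One of `"mw"`, `"logp"`, `"hba_count"`, `"hbd_count"`,
#'   `"psa"`, `"rotatable_bonds"`, `"aromatic_ring_count"`, `"alerts_count"`.
#' @return Numeric vector of desirabilities.
#' @export
qed_desirability <- function(x, property) {
  params <- qed_ads_params()
  if (!property %in% params$property) {
    stop_spq(sprintf("unknown QED property '%s'", property), class = "validation")
  }
  p <- params[params$property == property, ]
  raw <- p$a + p$b / (1 + exp(-(x - p$c + p$d / 2) / p$e)) *
    (1 - 1 / (1 + exp(-(x - p$c - p$d / 2) / p$f)))
  raw / p$dmax
}

#' Unweighted quantitative estimate of drug-likeness (QED)
#'
#' Maps each of the eight QED descriptors (MW, logP, HBA, HBD, PSA, rotatable
#' bonds, aromatic rings, structural alerts) through its desirability function
#' and combines them as an equal-weight geometric mean:
#' `exp(mean(log d_i))`. All eight descriptors must be present -- there is no
#' silent subset QED.
#'
#' @inheritParams evaluate_ro5
#' @return Tibble `drug_id`, `qed_value`.
#' @export
compute_qed_unweighted <- function(data) {
  props <- qed_properties()
  require_fields(data, c("drug_id", props), "unweighted QED")
  d <- vapply(props, function(p) qed_desirability(data[[p]], p),
              numeric(nrow(data)))
  d <- matrix(d, nrow = nrow(data),
              dimnames = list(NULL, props))
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop_spq("non-finite or non-positive desirability encountered in QED",
             class = "numerical")
  }
  tibble::tibble(
    drug_id = data$drug_id,
    qed_value = exp(rowMeans(log(d)))
  )
}

#' Drug-likeness profile across all four rules
#'
#' Aggregates Rule-of-Five, Ghose, Veber and unweighted-QED evaluations into
#' one row per drug. A rule whose required descriptors are missing is marked
#' not evaluable (`NA` pass flag plus a detail entry) while the remaining
#' rules are still evaluated.
#'
#' @inheritParams evaluate_ro5
#' @param qed_threshold QED compliance cutoff; `qed_pass` is
#'   `qed_value >= qed_threshold`. The dichotomisation threshold is a
#'   configuration choice (default 0.5) and is echoed in pipeline metadata.
#' @return Tibble with columns `drug_id`, `ro5_violations`, `ro5_pass`,
#'   `ghose_pass`, `veber_pass`, `qed_value`, `qed_pass` and
#'   `per_rule_details` (list-column mapping rule to failed conditions).
#' @export
profile_druglikeness <- function(data, max_violations = 0, qed_threshold = 0.5) {
  validate_descriptor_tbl(data)
  n <- nrow(data)
  blank <- function(cols) tibble::as_tibble(c(list(drug_id = data$drug_id), cols))

  ro5 <- tryCatch(evaluate_ro5(data, max_violations), spq_error_missing_data = function(e) {
    blank(list(ro5_violations = rep(NA_integer_, n), ro5_pass = rep(NA, n),
               ro5_failed = rep(list(paste("not evaluable:", conditionMessage(e))), n)))
  })
  ghose <- tryCatch(evaluate_ghose(data), spq_error_missing_data = function(e) {
    blank(list(ghose_pass = rep(NA, n),
               ghose_failed = rep(list(paste("not evaluable:", conditionMessage(e))), n)))
  })
  veber <- tryCatch(evaluate_veber(data), spq_error_missing_data = function(e) {
    blank(list(veber_pass = rep(NA, n),
               veber_failed = rep(list(paste("not evaluable:", conditionMessage(e))), n)))
  })
  qed <- tryCatch(compute_qed_unweighted(data), spq_error_missing_data = function(e) {
    blank(list(qed_value = rep(NA_real_, n)))
  })

  details <- lapply(seq_len(n), function(i) {
    list(
      ro5 = ro5$ro5_failed[[i]],
      ghose = ghose$ghose_failed[[i]],
      veber = veber$veber_failed[[i]],
      qed = if (is.na(qed$qed_value[i])) "not evaluable: missing QED descriptor"
            else character()
    )
  })
  tibble::tibble(
    drug_id = data$drug_id,
    ro5_violations = ro5$ro5_violations,
    ro5_pass = ro5$ro5_pass,
    ghose_pass = ghose$ghose_pass,
    veber_pass = veber$veber_pass,
    qed_value = qed$qed_value,
    qed_pass = qed$qed_value >= qed_threshold,
    per_rule_details = details
  )
}
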