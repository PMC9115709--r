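# Drug efficacy and permeability value (PV) -----------------------------------
#
# Efficacy per spheroid: efficacy = 1 - viability, with viability the
# treated/control luminescence ratio against the matched control of the same
# spheroid composition. PV per drug and replicate:
#   PV = Eff_A:M - (Eff_ASC + Eff_MDA) / 2
# i.e. how much less effective a drug is in the stroma/cancer co-culture
# spheroid than in the two monoculture spheroids; low PV indicates the
# multicellular barrier blocked the drug. Efficacies and PVs are stored as
# fractions, never percents.

#' Spheroid composition vocabulary
#'
#' The three spheroid types of the screen: the hASC + MDA-MB-231 multicellular
#' spheroid and the two monocellular spheroids.
#'
#' @return Character vector of allowed `composition` values.
#' @export
spheroid_compositions <- function() c("multicellular_AM", "mono_ASC", "mono_MDA")

validate_viability_tbl <- function(data) {
  cols <- c("drug_id", "composition", "replicate", "signal_treated", "signal_control")
  assert_columns(data, cols, "viability table")
  assert_no_na(data, cols, "viability table")
  bad_comp <- setdiff(unique(data$composition), spheroid_compositions())
  if (length(bad_comp) > 0) {
    stop_spq(sprintf("composition outside vocabulary {%s}: %s",
                     paste(spheroid_compositions(), collapse = ", "),
                     paste(bad_comp, collapse = ", ")),
             class = "validation", compositions = bad_comp)
  }
  if (any(data$signal_control <= 0)) {
    bad <- which(data$signal_control <= 0)
    stop_spq(sprintf("signal_control must be positive (rows %s)",
                     paste(head(bad, 5), collapse = ", ")),
             class = "measurement", rows = bad)
  }
  if (any(data$signal_treated < 0)) {
    stop_spq("signal_treated must be non-negative", class = "measurement")
  }
  if (any(!is_count_like(data$replicate) | data$replicate < 1)) {
    stop_spq("replicate must be a positive integer", class = "validation")
  }
  key <- paste(data$drug_id, data$composition, data$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop_spq(sprintf("duplicate (drug_id, composition, replicate) measurement: %s",
                     gsub("\r", " / ", dup)),
             class = "validation")
  }
  invisible(data)
}

#' Read a viability table
#'
#' Delimited text with columns `drug_id`, `composition`, `replicate`,
#' `signal_treated`, `signal_control` and optionally `concentration` (uM).
#'
#' @param path Path to a `.csv` or `.tsv` file.
#' @return Validated tibble.
#' @export
read_viability_table <- function(path) {
  if (!file.exists(path)) {
    stop_spq(sprintf("viability table not found: %s", path), class = "schema", path = path)
  }
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  data <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  validate_viability_tbl(data)
  tibble::as_tibble(data)
}

#' Compute viability and drug efficacy from luminescence readouts
#'
#' `viability = signal_treated / signal_control` against the matched control
#' of the same spheroid composition; `efficacy = 1 - viability`. Both stored
#' as fractions (rendered as percent only in reports). Negative efficacies
#' (growth under treatment) are retained with a warning, not clipped --
#' clipping would bias the downstream regression.
#'
#' @param data Viability tibble (see [read_viability_table()]).
#' @return `data` with `viability` and `efficacy` columns added.
#' @export
compute_efficacy <- function(data) {
  validate_viability_tbl(data)
  out <- dplyr::mutate(
    data,
    viability = .data$signal_treated / .data$signal_control,
    efficacy = 1 - .data$viability
  )
  n_neg <- sum(out$efficacy < 0)
  if (n_neg > 0) {
    warn_spq(sprintf("%d measurement(s) show growth under treatment (negative efficacy); values retained",
                     n_neg),
             class = "growth_under_treatment")
  }
  tibble::as_tibble(out)
}

#' Permeability value from matched efficacies
#'
#' `pv = eff_am - (eff_asc + eff_mda) / 2`, exact to floating point. Inputs
#' must come from the same drug and replicate; pairing is enforced by
#' [build_pv_table()].
#'
#' @param eff_am Efficacy in the multicellular (hASC:MDA) spheroid, fraction.
#' @param eff_asc Efficacy in the hASC monoculture spheroid, fraction.
#' @param eff_mda Efficacy in the MDA-MB-231 monoculture spheroid, fraction.
#' @return Numeric vector of PVs.
#' @export
compute_pv <- function(eff_am, eff_asc, eff_mda) {
  eff_am - 0.5 * (eff_asc + eff_mda)
}

#' Build the PV table from per-spheroid efficacies
#'
#' Pairs the three composition efficacies per drug (and replicate) and applies
#' [compute_pv()]. Under `aggregation = "replicate"` (default, the regression
#' input) each (drug, replicate) triple yields one PV, so a complete
#' 16-drug x 3-replicate screen gives 48 rows; under `"mean"` replicate
#' efficacies are averaged per composition first, one PV per drug.
#'
#' @param efficacies Output of [compute_efficacy()].
#' @param aggregation `"replicate"` or `"mean"`.
#' @return Tibble `drug_id`, `replicate` (replicate aggregation only), `pv`.
#' @export
build_pv_table <- function(efficacies, aggregation = c("replicate", "mean")) {
  aggregation <- match.arg(aggregation)
  assert_columns(efficacies, c("drug_id", "composition", "replicate", "efficacy"),
                 "efficacy table")
  data <- efficacies

  if (aggregation == "mean") {
    data <- data |>
      dplyr::group_by(.data$drug_id, .data$composition) |>
      dplyr::summarise(efficacy = mean(.data$efficacy), .groups = "drop") |>
      dplyr::mutate(replicate = 1L)
  }

  wide <- tidyr::pivot_wider(
    data[, c("drug_id", "replicate", "composition", "efficacy")],
    names_from = "composition", values_from = "efficacy"
  )
  for (comp in spheroid_compositions()) {
    if (!comp %in% names(wide)) wide[[comp]] <- NA_real_
  }
  incomplete <- wide |>
    tidyr::pivot_longer(dplyr::all_of(spheroid_compositions()),
                        names_to = "composition", values_to = "efficacy") |>
    dplyr::filter(is.na(.data$efficacy))
  if (nrow(incomplete) > 0) {
    cells <- sprintf("(%s, %s, replicate %d)", incomplete$drug_id,
                     incomplete$composition, incomplete$replicate)
    stop_spq(sprintf("incomplete composition triple(s); missing: %s",
                     paste(head(cells, 10), collapse = "; ")),
             class = "pairing", missing_cells = cells)
  }

  out <- wide |>
    dplyr::mutate(pv = compute_pv(.data$multicellular_AM, .data$mono_ASC, .data$mono_MDA)) |>
    dplyr::arrange(.data$drug_id, .data$replicate)
  if (aggregation == "mean") {
    out <- out[, c("drug_id", "pv")]
  } else {
    out <- out[, c("drug_id", "replicate", "pv")]
  }
  tibble::as_tibble(out)
}

#' Compare PV distributions between two drug groups
#'
#' Unpaired two-sample t-test of PVs split by a per-drug boolean label (e.g.
#' Rule-of-Five compliance or PAMPA class). The default is the equal-variance
#' (pooled, "student") test; Welch is available. PV rows whose drug has no
#' label are dropped with a message. With zero variance in both groups the
#' test statistic is degenerate: the comparison is reported with
#' `degenerate = TRUE` and p = 0 (different means) or p = 1 (equal means)
#' rather than crashing.
#'
#' @param pv_table Tibble with `drug_id` and `pv` columns.
#' @param labels Tibble `drug_id`, `label` (logical), or a logical vector
#'   named by drug_id.
#' @param test `"student"` (equal variance, default) or `"welch"`.
#' @return One-row tibble: group sizes, means and standard errors for the
#'   `TRUE` and `FALSE` groups, mean difference (`TRUE` minus `FALSE`), t
#'   statistic, degrees of freedom, two-tailed p-value, method, number of
#'   dropped rows, and a degenerate-variance flag.
#' @export
compare_pv_groups <- function(pv_table, labels, test = c("student", "welch")) {
  test <- match.arg(test)
  assert_columns(pv_table, c("drug_id", "pv"), "PV table")
  if (is.logical(labels) && !is.null(names(labels))) {
    labels <- tibble::tibble(drug_id = names(labels), label = unname(labels))
  }
  assert_columns(labels, c("drug_id", "label"), "label table")
  merged <- dplyr::left_join(pv_table, labels[, c("drug_id", "label")], by = "drug_id")
  n_dropped <- sum(is.na(merged$label))
  if (n_dropped > 0) {
    inform(sprintf("compare_pv_groups: dropped %d PV row(s) with no group label", n_dropped))
    merged <- merged[!is.na(merged$label), ]
  }
  x <- merged$pv[merged$label]    # TRUE group
  y <- merged$pv[!merged$label]   # FALSE group
  if (length(x) < 2 || length(y) < 2) {
    stop_spq(sprintf("each group needs >= 2 observations (sizes: TRUE %d, FALSE %d)",
                     length(x), length(y)),
             class = "insufficient_data")
  }

  degenerate <- isTRUE(all.equal(var(x), 0)) && isTRUE(all.equal(var(y), 0))
  if (degenerate) {
    equal <- isTRUE(all.equal(mean(x), mean(y)))
    statistic <- if (equal) 0 else sign(mean(x) - mean(y)) * Inf
    p_value <- if (equal) 1 else 0
    df <- length(x) + length(y) - 2
    method <- paste(test, "t-test (degenerate: zero within-group variance)")
  } else {
    ht <- t.test(x, y, var.equal = (test == "student"))
    statistic <- unname(ht$statistic)
    p_value <- ht$p.value
    df <- unname(ht$parameter)
    method <- ht$method
  }

  tibble::tibble(
    n_true = length(x), n_false = length(y),
    mean_true = mean(x), mean_false = mean(y),
    se_true = sd(x) / sqrt(length(x)), se_false = sd(y) / sqrt(length(y)),
    estimate = mean(x) - mean(y),
    statistic = statistic, df = df, p_value = p_value,
    method = method, n_dropped = n_dropped, degenerate = degenerate
  )
}
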