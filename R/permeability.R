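# PAMPA prediction and Caco-2 label handling ----------------------------------
#
# Predicted PAMPA permeability on the log(cm/s) scale:
#   logP_PAMPA = 0.42*logP - 0.26*|pKa - pH| - 1.11*SA_HA - 1.01*SA_HD - 4.93
# with SA_HA / SA_HD the fractions of molecular surface area occupied by
# H-bond acceptor and donor atoms (fractional convention; the published
# coefficients only give plausible magnitudes for inputs in [0, 1]).
# Drugs with logP_PAMPA strictly below -6.14 are classed low-permeability.

#' Predict PAMPA permeability from descriptors
#'
#' Linear descriptor model of artificial-membrane permeability:
#' `0.42 * logp - 0.26 * abs(pka - ph) - 1.11 * sa_ha_fraction -
#'  1.01 * sa_hd_fraction - 4.93`, exact to floating point.
#'
#' @param data Descriptor tibble with `drug_id`, `logp`, `pka`,
#'   `sa_ha_fraction`, `sa_hd_fraction`.
#' @param ph Working pH in `[0, 14]`; default 7.4 (physiological). Recorded in
#'   the output so downstream artifacts carry the convention used.
#' @return Tibble `drug_id`, `logp_pampa`, `ph`.
#' @export
predict_pampa <- function(data, ph = 7.4) {
  require_fields(data, c("drug_id", "logp", "pka", "sa_ha_fraction", "sa_hd_fraction"),
                 "PAMPA prediction")
  if (!is.numeric(ph) || length(ph) != 1 || !is.finite(ph) || ph < 0 || ph > 14) {
    stop_spq("ph must be a single number in [0, 14]", class = "validation")
  }
  tibble::tibble(
    drug_id = data$drug_id,
    logp_pampa = 0.42 * data$logp - 0.26 * abs(data$pka - ph) -
      1.11 * data$sa_ha_fraction - 1.01 * data$sa_hd_fraction - 4.93,
    ph = ph
  )
}

#' Classify predicted PAMPA permeability
#'
#' `"low"` iff `logp_pampa` is strictly below the threshold (default -6.14),
#' otherwise `"high"`; a value exactly at the threshold is `"high"`.
#'
#' @param logp_pampa Numeric vector of predicted PAMPA permeabilities.
#' @param threshold Low-permeability cutoff on the log scale.
#' @return Character vector of `"low"` / `"high"`.
#' @export
classify_pampa <- function(logp_pampa, threshold = -6.14) {
  if (any(!is.finite(logp_pampa))) {
    stop_spq("non-finite logp_pampa value", class = "numerical")
  }
  ifelse(logp_pampa < threshold, "low", "high")
}

caco2_vocabulary <- function() c("permeable", "impermeable")

#' Attach Caco-2 permeability class labels
#'
#' Caco-2 classes are ingested annotations (e.g. from predicted ADMET
#' features), never computed: drugs without a label are marked `"unknown"`,
#' with no imputation.
#'
#' @param data Tibble with a `drug_id` column.
#' @param labels Tibble with columns `drug_id`, `caco2_class`, or a character
#'   vector named by drug_id. Labels must be `"permeable"` or
#'   `"impermeable"`.
#' @return `data` with a `caco2_class` column added.
#' @export
attach_caco2_labels <- function(data, labels) {
  assert_columns(data, "drug_id", "Caco-2 labelling")
  if (is.character(labels) && !is.null(names(labels))) {
    labels <- tibble::tibble(drug_id = names(labels), caco2_class = unname(labels))
  }
  assert_columns(labels, c("drug_id", "caco2_class"), "Caco-2 label table")
  bad <- setdiff(unique(labels$caco2_class), caco2_vocabulary())
  if (length(bad) > 0) {
    stop_spq(sprintf("Caco-2 label(s) outside vocabulary {permeable, impermeable}: %s",
                     paste(bad, collapse = ", ")),
             class = "validation", labels = bad)
  }
  out <- dplyr::left_join(data, labels[, c("drug_id", "caco2_class")], by = "drug_id")
  out$caco2_class[is.na(out$caco2_class)] <- "unknown"
  out
}

#' Permeability estimate table
#'
#' Convenience wrapper combining [predict_pampa()], [classify_pampa()] and
#' (optionally) [attach_caco2_labels()] into the standard permeability output
#' table.
#'
#' @inheritParams predict_pampa
#' @inheritParams classify_pampa
#' @param caco2_labels Optional Caco-2 label table (see
#'   [attach_caco2_labels()]); when `NULL` all drugs are `"unknown"`.
#' @return Tibble `drug_id`, `logp_pampa`, `pampa_class`, `caco2_class`, `ph`.
#' @export
permeability_table <- function(data, ph = 7.4, threshold = -6.14, caco2_labels = NULL) {
  out <- predict_pampa(data, ph = ph)
  out$pampa_class <- classify_pampa(out$logp_pampa, threshold = threshold)
  if (is.null(caco2_labels)) {
    out$caco2_class <- "unknown"
  } else {
    out <- attach_caco2_labels(out, caco2_labels)
  }
  out[, c("drug_id", "logp_pampa", "pampa_class", "caco2_class", "ph")]
}
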