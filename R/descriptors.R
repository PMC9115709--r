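# Descriptor data model -------------------------------------------------------
#
# One row per drug. The nine regression descriptors (molecular weight, logP,
# logS, H-bond acceptor/donor counts, polar surface area, rotatable bonds,
# molar refractivity, polarizability) are mandatory; the remaining fields
# (pKa, H-bond surface-area fractions, atom/ring/alert counts, monolayer IC50,
# a line-notation structure) are optional and recorded as absent -- never as
# zero -- when a table does not provide them.

#' Canonical descriptor field names
#'
#' The nine descriptors used as QSAR regression candidates, in their canonical
#' column order.
#'
#' @return Character vector of descriptor column names.
#' @export
#' @examples
#' qsar_descriptors()
qsar_descriptors <- function() {
  c("mw", "logp", "logs", "hba_count", "hbd_count", "psa",
    "rotatable_bonds", "refractivity", "polarizability")
}

descriptor_fields <- function() {
  c("drug_id", "structure", qsar_descriptors(), "pka",
    "sa_ha_fraction", "sa_hd_fraction", "atom_count",
    "aromatic_ring_count", "alerts_count", "ic50_monolayer")
}

mandatory_fields <- function() c("drug_id", qsar_descriptors())

integer_fields <- function() {
  c("hba_count", "hbd_count", "rotatable_bonds", "atom_count",
    "aromatic_ring_count", "alerts_count")
}

# case-insensitive header alias dictionary; header names are normalised
# (lower case, non-alphanumerics -> "_") before lookup
descriptor_aliases <- function() {
  list(
    drug_id = c("drug_id", "drug", "id", "compound", "compound_id", "name", "drug_name"),
    structure = c("structure", "smiles", "canonical_smiles"),
    mw = c("mw", "molweight", "mol_weight", "molecular_weight", "mw_da"),
    logp = c("logp", "log_p", "alogp", "clogp", "xlogp"),
    logs = c("logs", "log_s", "logsol", "log_solubility"),
    hba_count = c("hba_count", "hba", "n_hba", "h_bond_acceptors",
                  "hydrogen_bond_acceptors", "acceptor_count", "hydrogen_acceptor_count"),
    hbd_count = c("hbd_count", "hbd", "n_hbd", "h_bond_donors",
                  "hydrogen_bond_donors", "donor_count", "hydrogen_donor_count"),
    psa = c("psa", "tpsa", "polar_surface_area"),
    rotatable_bonds = c("rotatable_bonds", "rotb", "nrotb", "n_rotatable_bonds",
                        "rotatable_bond_count"),
    refractivity = c("refractivity", "mr", "molar_refractivity"),
    polarizability = c("polarizability", "polarisability", "apol"),
    pka = c("pka", "p_ka"),
    sa_ha_fraction = c("sa_ha_fraction", "sa_ha", "saha", "ha_surface_fraction"),
    sa_hd_fraction = c("sa_hd_fraction", "sa_hd", "sahd", "hd_surface_fraction"),
    atom_count = c("atom_count", "heavy_atom_count", "n_atoms", "natoms"),
    aromatic_ring_count = c("aromatic_ring_count", "arom", "aromatic_rings",
                            "n_aromatic_rings"),
    alerts_count = c("alerts_count", "alerts", "structural_alerts"),
    ic50_monolayer = c("ic50_monolayer", "ic50", "ic50_um")
  )
}

normalise_header <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_|_$", "", x)
}

map_headers <- function(headers) {
  aliases <- descriptor_aliases()
  lookup <- unlist(lapply(names(aliases), function(f) setNames(rep(f, length(aliases[[f]])), aliases[[f]])))
  norm <- normalise_header(headers)
  mapped <- unname(lookup[norm])
  ifelse(is.na(mapped), headers, mapped)
}

#' Read a per-drug molecular descriptor table
#'
#' Reads a delimited text table (comma- or tab-separated, header row, one row
#' per drug), maps column names through a case-insensitive alias dictionary
#' (e.g. `MW`, `MolWeight` -> `mw`), validates the record invariants and
#' returns a tibble with canonical column names. Mandatory columns are
#' `drug_id` plus the nine regression descriptors ([qsar_descriptors()]);
#' optional descriptor columns absent from the file are simply not present in
#' the output (missing is never coerced to zero). Unknown extra columns are
#' preserved as passthrough metadata under `schema_policy = "lenient"`.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @param schema_policy `"lenient"` (default) keeps unrecognised columns;
#'   `"strict"` raises a schema error if any column name is not in the alias
#'   dictionary.
#' @param delim Field delimiter; guessed from the file extension when `NULL`.
#' @return A tibble with one validated row per drug.
#' @export
read_descriptor_table <- function(path, schema_policy = c("lenient", "strict"),
                                  delim = NULL) {
  schema_policy <- match.arg(schema_policy)
  if (!file.exists(path)) {
    stop_spq(sprintf("descriptor table not found: %s", path), class = "schema", path = path)
  }
  delim <- delim %||% if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  names(raw) <- map_headers(names(raw))

  known <- descriptor_fields()
  unknown <- setdiff(names(raw), known)
  if (schema_policy == "strict" && length(unknown) > 0) {
    stop_spq(sprintf("unrecognised column(s) under strict schema policy: %s",
                     paste(unknown, collapse = ", ")),
             class = "schema", columns = unknown)
  }
  missing <- setdiff(mandatory_fields(), names(raw))
  if (length(missing) > 0) {
    stop_spq(sprintf("descriptor table is missing mandatory column(s): %s",
                     paste(missing, collapse = ", ")),
             class = "schema", columns = missing)
  }

  numeric_fields <- setdiff(intersect(known, names(raw)), c("drug_id", "structure"))
  out <- raw
  for (col in numeric_fields) {
    vals <- trimws(out[[col]])
    vals[vals == ""] <- NA_character_
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(parsed))
    if (length(bad) > 0) {
      stop_spq(sprintf("non-numeric value '%s' in column '%s', row %d",
                       vals[bad[1]], col, bad[1]),
               class = "parse", column = col, rows = bad)
    }
    out[[col]] <- parsed
  }
  out <- tibble::as_tibble(out)
  # passthrough metadata columns keep their natural types
  for (col in setdiff(names(out), known)) {
    out[[col]] <- utils::type.convert(out[[col]], as.is = TRUE)
  }
  # canonical columns first, passthrough columns after
  ord <- c(intersect(known, names(out)), setdiff(names(out), known))
  out <- out[, ord]
  validate_descriptor_tbl(out)
  out
}

#' Write a descriptor table
#'
#' Inverse of [read_descriptor_table()]; writes full precision so a
#' write/read round trip is lossless.
#'
#' @param data Descriptor tibble.
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(data, path) {
  validate_descriptor_tbl(data)
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) {
    readr::write_tsv(data, path)
  } else {
    readr::write_csv(data, path)
  }
  invisible(path)
}

# hard invariants of a descriptor table; violations are errors
validate_descriptor_tbl <- function(data, what = "descriptor table") {
  assert_columns(data, mandatory_fields(), what, class = "schema")
  if (anyDuplicated(data$drug_id)) {
    dup <- unique(data$drug_id[duplicated(data$drug_id)])
    stop_spq(sprintf("%s: duplicate drug_id: %s", what, paste(dup, collapse = ", ")),
             class = "validation", drug_id = dup)
  }
  check <- function(field, ok, rule) {
    if (!field %in% names(data)) return(invisible(NULL))
    x <- data[[field]]
    bad <- which(!is.na(x) & !ok(x))
    if (length(bad) > 0) {
      stop_spq(sprintf("%s: invariant violated (%s) for drug_id %s",
                       what, rule, paste(data$drug_id[bad], collapse = ", ")),
               class = "validation", field = field, rows = bad)
    }
  }
  check("mw", function(x) x > 0, "mw > 0")
  check("psa", function(x) x >= 0, "psa >= 0")
  check("sa_ha_fraction", function(x) x >= 0 & x <= 1, "0 <= sa_ha_fraction <= 1")
  check("sa_hd_fraction", function(x) x >= 0 & x <= 1, "0 <= sa_hd_fraction <= 1")
  for (field in integer_fields()) {
    check(field, function(x) is_count_like(x), sprintf("%s is a non-negative integer", field))
  }
  invisible(data)
}

# soft plausibility screens: outside these windows a value is suspicious for a
# small-molecule drug but not impossible, so it warns rather than rejects
plausibility_ranges <- function() {
  list(
    mw = c(50, 2000), logp = c(-10, 15), logs = c(-15, 5), psa = c(0, 500),
    hba_count = c(0, 30), hbd_count = c(0, 20), rotatable_bonds = c(0, 40),
    refractivity = c(5, 300), polarizability = c(1, 200), pka = c(-5, 16)
  )
}

#' Screen descriptor values for implausible ranges
#'
#' Produces per-record soft warnings (e.g. a molecular weight outside the
#' plausible small-molecule window) without rejecting any row.
#'
#' @param data Descriptor tibble.
#' @return Tibble with columns `drug_id`, `field`, `value`, `message`; zero
#'   rows when every value is plausible.
#' @export
validate_descriptor_ranges <- function(data) {
  validate_descriptor_tbl(data)
  ranges <- plausibility_ranges()
  flags <- purrr::map_dfr(intersect(names(ranges), names(data)), function(field) {
    r <- ranges[[field]]
    x <- data[[field]]
    bad <- which(!is.na(x) & (x < r[1] | x > r[2]))
    if (length(bad) == 0) return(tibble::tibble())
    tibble::tibble(
      drug_id = data$drug_id[bad], field = field, value = x[bad],
      message = sprintf("%s outside plausible small-molecule range [%g, %g]",
                        field, r[1], r[2])
    )
  })
  if (nrow(flags) == 0) {
    flags <- tibble::tibble(drug_id = character(), field = character(),
                            value = numeric(), message = character())
  }
  flags
}

#' Compute descriptors from a line-notation structure
#'
#' Convenience path that fills the structure-derivable descriptor fields from
#' a SMILES string using the Open Babel backend (ChemmineR + ChemmineOB).
#' Fills `mw`, `logp`, `hba_count` (N + O convention), `hbd_count`, `psa`
#' (topological PSA), `rotatable_bonds` (non-ring single bonds between
#' non-terminal heavy atoms), `refractivity`, `atom_count` and
#' `aromatic_ring_count`. `logs`, `pka`, `polarizability`, the surface-area
#' fractions and `alerts_count` are left absent: no backend value exists for
#' them here and they are never silently approximated. Every field the
#' backend filled is flagged `"computed"` in the `provenance` attribute of
#' the result.
#'
#' @param structure A single SMILES string.
#' @param drug_id Identifier for the returned record.
#' @return One-row tibble of the computed fields, with a named `provenance`
#'   attribute marking each as `"computed"`.
#' @export
descriptors_from_structure <- function(structure, drug_id = "compound") {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop_spq("structure-based descriptor computation requires the ChemmineR and ChemmineOB packages",
             class = "capability")
  }
  if (!is.character(structure) || length(structure) != 1 || is.na(structure) ||
      !nzchar(trimws(structure))) {
    stop_spq("unparseable structure: empty or non-string input", class = "structure")
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(setNames(structure, drug_id))),
    error = function(e) stop_spq(sprintf("unparseable structure '%s': %s", structure,
                                         conditionMessage(e)),
                                 class = "structure")
  )
  if (!ChemmineR::validSDF(sdf)[1]) {
    stop_spq(sprintf("unparseable structure '%s'", structure), class = "structure")
  }
  props <- ChemmineR::propOB(sdf)
  rings <- ChemmineR::rings(sdf, type = "count", arom = TRUE)
  # rings() returns a named vector for one molecule, a data frame for several
  n_arom <- if (is.matrix(rings) || is.data.frame(rings)) rings[1, "AROMATIC"] else rings[["AROMATIC"]]
  rotb <- ChemmineR::smartsSearchOB(sdf, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]",
                                    uniqueMatches = TRUE)
  out <- tibble::tibble(
    drug_id = drug_id,
    structure = structure,
    mw = props$MW[1],
    logp = props$logP[1],
    hba_count = as.numeric(props$HBA2[1]),
    hbd_count = as.numeric(props$HBD[1]),
    psa = props$TPSA[1],
    rotatable_bonds = as.numeric(rotb[1]),
    refractivity = props$MR[1],
    atom_count = sum(ChemmineR::atomcount(sdf)[[1]]),
    aromatic_ring_count = as.numeric(n_arom)
  )
  computed <- setdiff(names(out), c("drug_id", "structure"))
  attr(out, "provenance") <- setNames(rep("computed", length(computed)), computed)
  out
}
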