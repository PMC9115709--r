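test_that("a complete 16-drug table loads with aliased, case-insensitive headers", {
  tbl <- fixture_descriptors()
  path <- withr::local_tempfile(fileext = ".csv")
  # write with unconventional header spellings
  out <- tbl
  names(out)[names(out) == "mw"] <- "MolWeight"
  names(out)[names(out) == "logp"] <- "LogP"
  names(out)[names(out) == "hba_count"] <- "H-Bond Acceptors"
  names(out)[names(out) == "psa"] <- "TPSA"
  readr::write_csv(out, path)

  got <- read_descriptor_table(path)
  expect_equal(nrow(got), 16)
  expect_true(all(c("mw", "logp", "hba_count", "psa") %in% names(got)))
  expect_equal(got$mw, tbl$mw)
  # unknown extra column preserved as passthrough metadata
  expect_true("rule_violator" %in% names(got))
  # ...but rejected under the strict schema policy
  expect_spq_error(read_descriptor_table(path, schema_policy = "strict"), "schema")
})

test_that("an empty table with a valid header yields an empty collection", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(fixture_record()[0, ], path)
  got <- read_descriptor_table(path)
  expect_equal(nrow(got), 0)
})

test_that("schema, parse and invariant violations are classed errors naming the offender", {
  ok <- fixture_record()
  path <- withr::local_tempfile(fileext = ".csv")

  readr::write_csv(dplyr::select(ok, -"logs"), path)
  err <- expect_spq_error(read_descriptor_table(path), "schema")
  expect_match(conditionMessage(err), "logs")

  bad <- ok; bad$mw <- "heavy"
  readr::write_csv(bad, path)
  err <- expect_spq_error(read_descriptor_table(path), "parse")
  expect_match(conditionMessage(err), "mw")
  expect_match(conditionMessage(err), "row 1")

  readr::write_csv(dplyr::bind_rows(ok, ok), path)
  expect_spq_error(read_descriptor_table(path), "validation")

  bad <- ok; bad$sa_ha_fraction <- 1.5
  readr::write_csv(bad, path)
  err <- expect_spq_error(read_descriptor_table(path), "validation")
  expect_match(conditionMessage(err), "sa_ha_fraction")

  bad <- ok; bad$hba_count <- 2.5
  readr::write_csv(bad, path)
  expect_spq_error(read_descriptor_table(path), "validation")
})

test_that("missing optional columns stay absent rather than becoming zero", {
  ok <- fixture_record()
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(ok[, c("drug_id", qsar_descriptors())], path)
  got <- read_descriptor_table(path)
  expect_false("pka" %in% names(got))
  expect_false("sa_ha_fraction" %in% names(got))
})

test_that("write/read round trip is lossless for all defined fields", {
  tbl <- fixture_descriptors(seed = 3)
  for (ext in c(".csv", ".tsv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_descriptor_table(tbl, path)
    back <- read_descriptor_table(path)
    expect_equal(as.data.frame(back[names(tbl)]), as.data.frame(tbl),
                 tolerance = 1e-12)
  }
})

test_that("range screening warns softly without rejecting rows", {
  expect_equal(nrow(validate_descriptor_ranges(fixture_record(logp = 2.1))), 0)

  flags <- validate_descriptor_ranges(fixture_record(mw = 50000))
  expect_equal(nrow(flags), 1)
  expect_equal(flags$field, "mw")
  expect_match(flags$message, "plausible small-molecule range")

  # 16 generated drug-plausible records: no warnings
  expect_equal(nrow(validate_descriptor_ranges(fixture_descriptors())), 0)
})

test_that("structure-based descriptors match hand-derived values", {
  benzene <- descriptors_from_structure("c1ccccc1", drug_id = "benzene")
  expect_equal(benzene$mw, 78.11, tolerance = 1e-3)
  expect_equal(benzene$hbd_count, 0)
  expect_equal(benzene$aromatic_ring_count, 1)
  expect_equal(benzene$atom_count, 6)
  expect_equal(attr(benzene, "provenance")[["mw"]], "computed")
  # fields with no backend value are absent, never approximated
  expect_false("logs" %in% names(benzene))
  expect_false("polarizability" %in% names(benzene))

  ethanol <- descriptors_from_structure("CCO")
  expect_equal(ethanol$hbd_count, 1)
  expect_equal(ethanol$hba_count, 1)
  # terminal-bond convention: both single bonds touch a terminal heavy atom
  expect_equal(ethanol$rotatable_bonds, 0)

  expect_spq_error(descriptors_from_structure(""), "structure")
})

test_that("structure-based computation is deterministic", {
  a <- descriptors_from_structure("CC(=O)Oc1ccccc1C(=O)O")
  b <- descriptors_from_structure("CC(=O)Oc1ccccc1C(=O)O")
  expect_identical(as.data.frame(a), as.data.frame(b))
})
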