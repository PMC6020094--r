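test_that("SMILES files are read with unparseable entries logged, not dropped", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("# a comment", "CCO ethanol", "c1ccccc1 benzene",
               "CC(=O)O", "not_a_smiles broken"), f)
  got <- read_molecules(f, "smi")
  expect_length(got$records, 3)
  expect_equal(got$report$input_count, 4)
  expect_equal(got$report$parsed_count, 3)
  expect_equal(got$report$removals$reason, "UNPARSEABLE")
  expect_equal(got$records[[1]]$id, "ethanol")
  expect_equal(got$records[[3]]$smiles, canonicalize("CC(=O)O"))
})

test_that("zero parseable molecules is an explicit error", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("not_a_smiles", "alsobad!"), f)
  expect_error(read_molecules(f, "smi"), "empty input")
  expect_error(read_molecules(tempfile(), "smi"), "not found")
})

test_that("CSV input uses id column and carries extra columns as properties", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = c("a", "b"), smiles = c("CCO", "CCN"),
                       assay = c(1.5, 2.5)), f, row.names = FALSE)
  got <- read_molecules(f, "csv")
  expect_equal(vapply(got$records, `[[`, character(1), "id"), c("a", "b"))
  expect_equal(got$records[[2]]$source_index, 1L)
  expect_equal(got$records[[1]]$properties$assay, 1.5)
})

test_that("duplicate ids are suffixed with an ordinal and logged", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO x", "CCN x", "CCC x"), f)
  got <- read_molecules(f, "smi")
  expect_equal(vapply(got$records, `[[`, character(1), "id"),
               c("x", "x_2", "x_3"))
  expect_equal(sum(got$report$removals$reason == "DUPLICATE_ID"), 2)
  expect_equal(got$report$parsed_count, 3)
})

test_that("an SDF V2000 block round-trips to the canonical SMILES", {
  recs <- fixture_records(c("CCO", "CC(=O)Oc1ccccc1C(=O)O"))
  f <- withr::local_tempfile(fileext = ".sdf")
  write_molecules(recs, f, "sdf")
  got <- read_molecules(f, "sdf")
  expect_equal(vapply(got$records, `[[`, character(1), "smiles"),
               vapply(recs, `[[`, character(1), "smiles"))
})

test_that("canonicalize maps spellings of one graph to one string, idempotently", {
  expect_identical(canonicalize("OCC"), canonicalize("CCO"))
  expect_identical(canonicalize(canonicalize("c1ccccc1O")),
                   canonicalize("Oc1ccccc1"))
  expect_error(canonicalize("C1CC"), "cannot parse")
})

test_that("washing keeps the largest fragment and disconnects simple salts", {
  expect_equal(wash_molecule(molecule_record("CCO.Cl"))$smiles,
               canonicalize("CCO"))
  # sodium acetate, ionic and covalent forms both yield the acetate anion
  acetate <- canonicalize("CC(=O)[O-]")
  expect_equal(wash_molecule(molecule_record("CC(=O)[O-].[Na+]"))$smiles,
               acetate)
  expect_equal(wash_molecule(molecule_record("CC(=O)O[Na]"))$smiles,
               acetate)
  # single fragment untouched
  benz <- molecule_record("c1ccccc1")
  expect_equal(wash_molecule(benz)$smiles, benz$smiles)
})

test_that("washing is idempotent and fragment choice maximizes heavy atoms", {
  recs <- fixture_corpus(15, seed = 9, include_salts = TRUE)
  expect_true(any(grepl(".", vapply(recs, `[[`, character(1), "smiles"),
                        fixed = TRUE)))
  for (rec in recs) {
    w1 <- wash_molecule(rec)
    w2 <- wash_molecule(w1)
    expect_identical(w1$smiles, w2$smiles)
    expect_false(grepl(".", w1$smiles, fixed = TRUE))
    # no input fragment has more heavy atoms than the kept one
    frags <- strsplit(rec$smiles, ".", fixed = TRUE)[[1]]
    heavy <- vapply(frags, function(s)
      molecule_record(s)$structure$n_heavy, numeric(1))
    expect_gte(w1$structure$n_heavy, max(heavy))
  }
})

test_that("read -> write -> read preserves count and canonical SMILES", {
  recs <- fixture_corpus(10, seed = 3)
  for (fmt in c("smi", "sdf")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_molecules(recs, f, fmt)
    got <- read_molecules(f, fmt)
    expect_length(got$records, length(recs))
    expect_equal(vapply(got$records, `[[`, character(1), "smiles"),
                 vapply(recs, `[[`, character(1), "smiles"))
  }
})
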