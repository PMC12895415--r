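test_that("residualDelta is exact subtraction and rejects non-finite input", {
  expect_equal(residualDelta(3.5, 3.0), 0.5)
  expect_equal(residualDelta(2.7, 2.7), 0.0)
  set.seed(4)
  eh <- runif(50, 2, 6)
  el <- runif(50, 1.5, 5.5)
  oracle <- vapply(seq_along(eh), function(k) eh[k] - el[k], numeric(1))
  expect_identical(residualDelta(eh, el), oracle)
  expect_error(residualDelta(NA_real_, 1), "finite")
  expect_error(residualDelta(1, Inf), "finite")
})

test_that("Molecule validity enforces the structural contract", {
  expect_error(Molecule("bad", c("C", "C"), matrix(0, 2, 3)),
               "coincident|zero pairwise")
  expect_error(Molecule("bad", c("C", "Xx"),
                        rbind(c(0, 0, 0), c(1, 0, 0))),
               "unknown element")
  m <- Molecule("ok", c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                bonds = cbind(1, 2, 1))
  expect_equal(nAtoms(m), 2L)
  expect_equal(hac(m), 2L)
  expect_equal(m@nH, c(3, 3))   # ethane-like implicit hydrogens
})

test_that("dataset write/read round trip is lossless", {
  ds <- toyFixtures()
  dir <- withr::local_tempdir()
  writeDataset(ds, dir)
  back <- readDataset(file.path(dir, "molecules.json"),
                      file.path(dir, "electronic.json"),
                      file.path(dir, "targets.json"))
  expect_equal(nrow(attr(back, "dropReport")), 0L)
  expect_identical(sort(datasetIds(back)), sort(datasetIds(ds)))
  for (id in datasetIds(ds)) {
    a <- molecules(ds)[[id]]; b <- molecules(back)[[id]]
    expect_identical(b@elements, a@elements)
    expect_identical(b@smiles, a@smiles)
    expect_lt(max(abs(b@coords - a@coords)), 1e-12)
    expect_equal(b@bonds, a@bonds, ignore_attr = TRUE)
    ea <- electronicRecords(ds)[[id]]; eb <- electronicRecords(back)[[id]]
    expect_lt(abs(ea$e_s1_low - eb$e_s1_low), 1e-12)
    expect_lt(max(abs(ea$w_homo - eb$w_homo)), 1e-12)
    expect_lt(max(abs(ea$potential - eb$potential)), 1e-12)
  }
  tgA <- targetRecords(ds); tgB <- targetRecords(back)
  tgB <- tgB[match(tgA$molecule_id, tgB$molecule_id), ]
  expect_lt(max(abs(tgA$e_s1_high - tgB$e_s1_high)), 1e-12)
})

test_that("joining drops incomplete records with a report, never silently", {
  ds <- toyFixtures()
  sub <- ds[c("benzene", "pyridine", "ethane")]
  dir <- withr::local_tempdir()
  writeDataset(sub, dir)
  full <- readDataset(file.path(dir, "molecules.json"),
                      file.path(dir, "electronic.json"),
                      file.path(dir, "targets.json"))
  expect_equal(length(datasetIds(full)), 3L)
  expect_equal(nrow(attr(full, "dropReport")), 0L)

  # delete one target row
  tg <- jsonlite::read_json(file.path(dir, "targets.json"),
                            simplifyVector = TRUE)
  tg$records <- tg$records[tg$records$molecule_id != "pyridine", ]
  jsonlite::write_json(tg, file.path(dir, "targets.json"),
                       auto_unbox = TRUE, digits = NA)
  two <- readDataset(file.path(dir, "molecules.json"),
                     file.path(dir, "electronic.json"),
                     file.path(dir, "targets.json"))
  expect_equal(length(datasetIds(two)), 2L)
  rep <- attr(two, "dropReport")
  expect_true("pyridine" %in% rep$molecule_id)
  expect_equal(rep$reason[rep$molecule_id == "pyridine"], "missing_target")
})

test_that("per-atom array length mismatch is a hard error naming the record", {
  ds <- toyFixtures()
  sub <- ds[c("benzene", "ethane")]
  dir <- withr::local_tempdir()
  writeDataset(sub, dir)
  el <- jsonlite::read_json(file.path(dir, "electronic.json"))
  bad <- which(vapply(el$records, `[[`, character(1), "molecule_id") ==
                 "ethane")
  el$records[[bad]]$mulliken <- list(0.1)   # ethane has 2 atoms
  jsonlite::write_json(el, file.path(dir, "electronic.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(readDataset(file.path(dir, "molecules.json"),
                           file.path(dir, "electronic.json"),
                           file.path(dir, "targets.json")),
               "ethane.*mulliken|mulliken.*ethane")
})

test_that("electronic record normalizes HOMO populations and flags bad f", {
  r <- electronicRecord("x", 3.0, w_homo = c(2, 2, 4))
  expect_equal(sum(r$w_homo), 1)
  expect_equal(r$w_homo, c(0.25, 0.25, 0.5))
  expect_error(electronicRecord("x", 3.0, f_low = -0.1), ">= 0")
  # missing oscillator strength is allowed and kept as NA, not zeroed
  r2 <- electronicRecord("x", 3.0)
  expect_true(is.na(r2$f_low))
})

test_that("XYZ + CSV import builds molecules with correct geometry", {
  dir <- withr::local_tempdir()
  xyz <- file.path(dir, "mols.xyz")
  writeLines(c("3", "water-ish", "O 0.0 0.0 0.0", "H 0.96 0.0 0.0",
               "H -0.24 0.93 0.0",
               "2", "dimer", "C 0.0 0.0 0.0", "C 1.54 0.0 0.0"), xyz)
  tab <- file.path(dir, "mols.csv")
  write.csv(data.frame(id = c("w1", "c2"), smiles = c("O", "CC")), tab,
            row.names = FALSE)
  el <- file.path(dir, "elec.json")
  jsonlite::write_json(list(schema_version = "1.0", records = list(
    list(molecule_id = "w1", e_s1_low = 4.0),
    list(molecule_id = "c2", e_s1_low = 5.0))), el, auto_unbox = TRUE)
  ds <- readDataset(xyz, el, moleculeTable = tab)
  expect_identical(sort(datasetIds(ds)), c("c2", "w1"))
  expect_equal(molecules(ds)$w1@elements, c("O", "H", "H"))
  expect_equal(unname(molecules(ds)$c2@coords[2, 1]), 1.54)
})
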