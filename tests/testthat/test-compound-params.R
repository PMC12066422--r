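test_that("fraction unbound is the complement of protein binding", {
  expect_equal(fupFromPpbr(0.74), 0.26)
  expect_equal(fupFromPpbr(0), 1)
  expect_equal(fupFromPpbr(0.89), 0.11)
  expect_error(fupFromPpbr(1), "\\[0, 1\\)")
  expect_error(fupFromPpbr(-0.1), "\\[0, 1\\)")
})

test_that("apparent clearance derives from Vss and half-life", {
  expect_equal(clappFromVssHalflife(100, 6.93), 10)
  expect_equal(clappFromVssHalflife(69.3, 6.93), 6.93)
  expect_equal(clappFromVssHalflife(95.9, 0.693), 95.9)
  expect_error(clappFromVssHalflife(0, 1), "positive")
  expect_error(clappFromVssHalflife(1, 0), "positive")
})

test_that("effective permeability follows the log-linear regression", {
  # closed forms: 10^(-0.3355) and 10^(0.6795 - 0.3355)
  expect_equal(peffFromPapp(1), 0.4618490, tolerance = 1e-6)
  expect_equal(peffFromPapp(10), 2.2080047, tolerance = 1e-6)
  # increasing power law
  papp <- sort(abs(rnorm(25, 5, 3)) + 0.01)
  expect_true(all(diff(peffFromPapp(papp)) > 0))
  expect_error(peffFromPapp(0), "positive")
})

test_that("gi_ka derives from effective permeability and intestinal radius", {
  expect_equal(gikaFromPeff(0.625, 1.25), 1)
  expect_equal(gikaFromPeff(1.25, 1.25), 2)
  expect_equal(gikaFromPeff(0.625), gikaFromPeff(0.625, 1.25))
  expect_error(gikaFromPeff(-1), "positive")
})

test_that("molecular weight is computed from SMILES with published rounding", {
  # printed SMILES contain embedded spaces; they must parse unchanged
  expect_equal(mwFromSmiles("C1CC2 = CN = CN2C1C3 = C(C=C(C=C3)C#N)F"), 227.24)
  expect_equal(mwFromSmiles("C1CC(N2C = NC = C2C1)C3 = CC = C(C=C3)C#N"), 223.27)
  expect_equal(mwFromSmiles("C"), 16.04)
  expect_error(mwFromSmiles("notasmiles((("), "notasmiles")
  expect_error(mwFromSmiles(""), "non-empty")
})

test_that("calibration rescales Kp scaler and clearance and nothing else", {
  lib <- asiLibrary()
  bax <- lib[["Baxdrostat"]]
  cal <- applyCalibration(bax)
  expect_equal(kpScaler(cal), 0.16 * 0.85)
  expect_equal(apparentClearance(cal), 14.83 / 4.7)
  # every other field untouched
  for (sl in setdiff(methods::slotNames("CompoundRecord"),
                     c("kpScaler", "clApp")))
    expect_identical(methods::slot(cal, sl), methods::slot(bax, sl))

  # identity factors are a no-op; repeated application compounds
  expect_identical(applyCalibration(bax, calibrationFactors(1, 1)), bax)
  twice <- applyCalibration(cal)
  expect_equal(kpScaler(twice), kpScaler(bax) * 0.85^2)
  expect_false(isTRUE(all.equal(kpScaler(twice), kpScaler(cal))))
})

test_that("the five-compound library is complete and internally consistent", {
  lib <- asiLibrary()
  expect_named(lib, c("Baxdrostat", "BI689648", "Lorundrostat",
                      "Dexfadrostat", "LCI699"))
  bax <- lib[["Baxdrostat"]]
  expect_equal(unname(kpValues(bax)["brain"]), 45.07)
  expect_equal(unname(kpValues(bax)["liver"]), 4.75)
  expect_equal(ic50(lib[["Lorundrostat"]], "cyp11b2"), 1.27)
  expect_equal(ic50(lib[["Lorundrostat"]], "cyp11b1"), 475)
  for (rec in lib) expect_true(methods::validObject(rec))
  # selectivity ordering: all four ASIs selective, the comparator weakly so
  si <- vapply(lib, function(r)
    selectivityIndex(ic50(r, "cyp11b1"), ic50(r, "cyp11b2")), numeric(1))
  expect_true(all(si[setdiff(names(lib), "LCI699")] > 1))
  expect_lt(si[["LCI699"]], 10)
})

test_that("compound sheets round-trip exactly", {
  for (rec in asiLibrary()) {
    f <- withr::local_tempfile(fileext = ".yaml")
    writeCompoundSheet(rec, f)
    back <- readCompoundSheet(f)
    expect_equal(back, rec)
  }
  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(list(name = "x", smiles = "C")), f2)
  expect_error(readCompoundSheet(f2), "missing fields")
})

test_that("records reject out-of-range parameters with the field named", {
  expect_error(toyRecord(clApp = -1), "clApp")
  expect_error(toyRecord(fup = 1.2), "fup")
  expect_error(toyRecord(kp = setNames(rep(1, 10), kpTissues()[-1])), "missing")
})
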