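test_that("well-formed tables read with ids preserved and logS autocomputed", {
  df <- data.frame(id = c("a1", "a2", "a3"),
                   name = c("x", "y", "z"),
                   smiles = c("C", "CC", "CCC"),
                   solubility = c(0.00660, 1.0, 18.5))
  tab <- read_compound_table(write_compound_csv(df))
  expect_equal(tab$id, c("a1", "a2", "a3"))
  # dataset minimum 0.00660 mol/L -> logS = -2.1805
  expect_equal(tab$logS[1], log10(0.00660), tolerance = 1e-12)
  expect_equal(round(tab$logS[1], 4), -2.1805)
  expect_equal(tab$logS[3], log10(18.5), tolerance = 1e-12)
})

test_that("domain violations are reported with their row numbers", {
  df <- data.frame(id = c("a", "b", "c"), solubility = c(1, 0, 2))
  expect_error(read_compound_table(write_compound_csv(df)),
               "row\\(s\\) 2")
  df2 <- data.frame(id = c("a", "a"), solubility = c(1, 2))
  expect_error(read_compound_table(write_compound_csv(df2)), "duplicate")
  df3 <- data.frame(id = "a", solubility = 1, logS = 0.7)
  expect_error(read_compound_table(write_compound_csv(df3)),
               "inconsistent")
  df4 <- data.frame(name = "x", smiles = "C")
  expect_error(read_compound_table(write_compound_csv(df4)), "schema")
})

test_that("schema mapping and kcal conversion are applied on read", {
  df <- data.frame(sample = "q1", smi = "C", sol = 0.5, Gsolv = -10)
  cfg <- list(unit_system = "kcal",
              columns = list(id = "sample", smiles = "smi",
                             solubility = "sol", dG_solv = "Gsolv"))
  tab <- read_compound_table(write_compound_csv(df), cfg)
  expect_equal(tab$dG_solv, -41.84)       # kcal -> kJ
  expect_equal(attr(tab, "unit_system"), "kJ")
})

test_that("lattice-energy / sublimation-enthalpy consistency is enforced", {
  ok <- data.frame(id = "a", logS = 0, U_latt = -100,
                   dH_sub = dH_sub_from_Ulatt(-100))
  expect_silent(validate_compound_table(ok))
  bad <- data.frame(id = "a", logS = 0, U_latt = -100, dH_sub = 90)
  expect_error(validate_compound_table(bad), "2RT")
})

test_that("write/read round trip preserves numeric fields", {
  df <- data.frame(id = c("a", "b"), solubility = c(0.123456789012345, 3.3),
                   logS = log10(c(0.123456789012345, 3.3)),
                   dG_solv = c(-41.123456789, -17.5),
                   V_m = c(0.1234567890123, 0.2))
  tab <- validate_compound_table(df)
  path <- tempfile(fileext = ".csv")
  write_compound_table(tab, path)
  back <- read_compound_table(path)
  for (col in c("solubility", "logS", "dG_solv", "V_m")) {
    expect_equal(back[[col]], tab[[col]], tolerance = 1e-12)
  }
})

test_that("preprocessing drops exactly the offending columns with reasons", {
  df <- data.frame(a = rnorm(10), b = rep(2, 10), c = letters[1:10],
                   d = rnorm(10))
  out <- preprocess_design_matrix(df)
  expect_equal(colnames(out$X), c("a", "d"))
  rep <- attr(out, "preprocess_report")
  expect_setequal(rep$column, c("b", "c"))
  expect_equal(rep$reason[rep$column == "b"], "zero-variance")
  expect_equal(rep$reason[rep$column == "c"], "non-numeric")

  # identity on clean input, and idempotent
  clean <- as.data.frame(matrix(rnorm(50), 10, 5))
  p1 <- preprocess_design_matrix(clean)
  expect_equal(unname(p1$X), unname(as.matrix(clean)))
  p2 <- preprocess_design_matrix(p1)
  expect_equal(p2$X, p1$X)

  expect_error(preprocess_design_matrix(data.frame(k = rep(1, 5))),
               "no columns survive")
  expect_error(
    preprocess_design_matrix(data.frame(a = c(1, NA, 3), b = 1:3)),
    "missing values")
})

test_that("feature matrix invariants hold", {
  X <- matrix(1:6, 3, 2, dimnames = list(NULL, c("a", "a")))
  expect_error(feature_matrix(X), "unique")
  fm <- make_fm(n = 12, p = 3)
  expect_equal(dim(fm), c(12L, 3L))
  expect_error(feature_matrix(matrix(1:6, 3, 2,
                                     dimnames = list(NULL, c("a", "b"))),
                              provenance = "junk"), "provenance")
})
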