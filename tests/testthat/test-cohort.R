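test_that("cohort CSV round-trip is the identity, cell-exact", {
  co <- fixture_cohort(n = 25, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path, quiet = TRUE)
  expect_identical(as.matrix(as.data.frame(back)),
                   as.matrix(as.data.frame(co)))
})

test_that("schema and validation errors name the offending column and row", {
  co <- fixture_cohort(n = 10, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  d <- as.data.frame(co)
  d$omega3 <- NULL
  utils::write.csv(d, path, row.names = FALSE)
  expect_error(read_cohort(path, quiet = TRUE), "omega3")

  d <- as.data.frame(co)
  d$dha[4] <- 2
  utils::write.csv(d, path, row.names = FALSE)
  expect_error(read_cohort(path, quiet = TRUE), "row 4.*dha")

  # empty file with a valid header is allowed for I/O round trips
  utils::write.csv(as.data.frame(co)[0, ], path, row.names = FALSE)
  expect_equal(nrow(read_cohort(path, quiet = TRUE)), 0L)
})

test_that("validate_cohort reports range and degenerate-class violations", {
  co <- fixture_cohort(n = 30, seed = 5)
  expect_equal(nrow(validate_cohort(co)), 0L)

  d <- as.data.frame(co)
  d$age[2] <- 17
  v <- validate_cohort(cohort_table(d, validate = FALSE))
  expect_equal(v$row, 2L)
  expect_equal(v$column, "age")

  d <- as.data.frame(co)
  d$transfer_state <- 0
  v <- validate_cohort(cohort_table(d, validate = FALSE))
  expect_true(any(grepl("single-class", v$issue)))
})

test_that("summarize_cohort matches hand arithmetic and the n-1 convention", {
  d <- as.data.frame(fixture_cohort(n = 4, seed = 11))
  d$oocyte_count <- c(0, 5, 10, 15)
  s <- summarize_cohort(cohort_table(d))
  oo <- s[s$feature == "oocyte_count", ]
  expect_equal(oo$mean, 7.5)
  expect_equal(oo$min, 0)
  expect_equal(oo$max, 15)
  expect_equal(oo$sd, sd(c(0, 5, 10, 15)))

  # binary means are class proportions exactly
  co <- fixture_cohort(n = 50, seed = 2)
  s <- summarize_cohort(co)
  expect_equal(s$mean[s$feature == "dha"], mean(as.data.frame(co)$dha))

  # single-row cohort: SD guard returns 0
  s1 <- summarize_cohort(cohort_table(as.data.frame(co)[1, ]))
  expect_true(all(s1$sd == 0))

  expect_error(summarize_cohort(fixture_cohort(n = 25, seed = 1)[0, ]),
               "empty")
})

test_that("binarize_intakes applies the 100%-of-daily-requirement rule", {
  rdi <- fixture_rdi()
  intakes <- data.frame(
    patient_id = "A", product = "supp1", ingredient = "folic_acid",
    amount = 480, unit = "ug")  # 120% of 400
  flags <- binarize_intakes(intakes, rdi)
  expect_equal(flags$folic_acid[flags$patient_id == "A"], 1L)
  expect_equal(flags$omega3[flags$patient_id == "A"], 0L)

  # patient with no records at all gets all-zero flags
  flags <- binarize_intakes(intakes, rdi, patient_ids = c("A", "B"))
  expect_true(all(flags[flags$patient_id == "B", -1] == 0))
})

test_that("sum-across-products vs per-product policies differ as documented", {
  rdi <- fixture_rdi()
  two <- data.frame(
    patient_id = "A", product = c("p1", "p2"), ingredient = "omega3",
    amount = c(600, 600), unit = "mg")  # 60% + 60%
  expect_equal(binarize_intakes(two, rdi, "sum_across_products")$omega3, 1L)
  expect_equal(binarize_intakes(two, rdi, "per_product")$omega3, 0L)
})

test_that("binarize_intakes flags unknown ingredients and unit mismatches", {
  rdi <- fixture_rdi()
  unknown <- data.frame(patient_id = "A", product = "p", ingredient = "kale",
                        amount = 5, unit = "g")
  expect_warning(binarize_intakes(unknown, rdi), "kale")
  wrong_unit <- data.frame(patient_id = "A", product = "p",
                           ingredient = "folic_acid", amount = 1, unit = "mg")
  expect_error(binarize_intakes(wrong_unit, rdi), "folic_acid")
})

test_that("binarization is monotone under the sum policy", {
  rdi <- fixture_rdi()
  flags <- matrix(withr::with_seed(8, rbinom(5 * 4, 1, 0.5)), nrow = 5,
                  dimnames = list(NULL, rdi$ingredient))
  intakes <- generate_intake_fixture(flags, rdi, seed = 9)
  before <- binarize_intakes(intakes, rdi, patient_ids = paste0("P", 1:5))
  extra <- data.frame(patient_id = "P1", product = "extra",
                      ingredient = "omega3", amount = 50, unit = "mg")
  after <- binarize_intakes(rbind(intakes, extra), rdi,
                            patient_ids = paste0("P", 1:5))
  ing <- rdi$ingredient
  expect_true(all(after[order(after$patient_id), ing] >=
                    before[order(before$patient_id), ing]))
})
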