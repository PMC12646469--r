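test_that("default marginal spec carries the published prevalences", {
  spec <- default_table2_spec()
  expect_equal(spec$binary[["dha"]], 0.72)
  expect_equal(spec$binary[["melatonin"]], 0.006)
  expect_equal(spec$binary[["working_status"]], 0.72)
  expect_true(all(spec$binary >= 0 & spec$binary <= 1))
  expect_equal(length(spec$binary), 20L)
  expect_equal(spec$outcome_prevalence, 0.38)
})

test_that("truncated negative binomial calibration hits the target moments", {
  nb <- calibrate_truncated_nb(mean = 7.58, sd = 9.81, hi = 58)
  expect_equal(unname(nb$moments["mean"]), 7.58, tolerance = 1e-7)
  expect_equal(unname(nb$moments["sd"]), 9.81, tolerance = 1e-7)
  expect_error(calibrate_truncated_nb(mean = 5, sd = 1),
               "variance > mean")
})

test_that("intercept calibration matches closed forms for a null signal", {
  cfg <- synthetic_config(10, seed = 1)
  expect_equal(calibrate_intercept(cfg, target = 0.38), qlogis(0.38))
  expect_equal(calibrate_intercept(cfg, target = 0.5), 0)
})

test_that("calibrated intercept reproduces the target prevalence on fresh draws", {
  beta <- c(omega3 = 1.5, folic_acid = 1.0, oocyte_count = 0.8)
  cfg <- synthetic_config(100000, seed = 31, beta = beta,
                          target_prevalence = 0.38)
  co <- generate_cohort(cfg)
  expect_equal(mean(cohort_outcome(co)), 0.38, tolerance = 0.011)
})

test_that("identical configs give byte-identical cohorts; n = 0 is empty", {
  cfg <- synthetic_config(80, seed = 12, beta = c(dha = 1))
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_equal(nrow(generate_cohort(synthetic_config(0, seed = 1))), 0L)
  expect_error(synthetic_config(-1), ">= 0")
})

test_that("binary marginals at n = 1e5 fall inside the 4-sigma band", {
  co <- generate_cohort(synthetic_config(100000, seed = 99))
  spec <- default_table2_spec()
  d <- as.data.frame(co)
  for (f in names(spec$binary)) {
    p <- spec$binary[[f]]
    tol <- 4 * sqrt(p * (1 - p) / 100000)
    expect_lt(abs(mean(d[[f]]) - p), tol)
  }
  expect_true(all(d$age >= 24 & d$age <= 43))
  expect_true(all(d$oocyte_count >= 0 & d$oocyte_count <= 58))
  expect_equal(mean(d$oocyte_count), 7.58, tolerance = 0.15 / 7.58)
  expect_equal(sd(d$oocyte_count), 9.81, tolerance = 0.3 / 9.81)
})

test_that("planted-signal odds ratio matches the enumeration oracle", {
  beta <- c(omega3 = 2, folic_acid = 2, dietician_support = 1)
  cfg <- synthetic_config(5000, seed = 77, beta = beta)
  b0 <- calibrate_intercept(cfg)
  spec <- cfg$marginals
  p <- c(o = spec$binary[["omega3"]], f = spec$binary[["folic_acid"]],
         d = spec$binary[["dietician_support"]])
  s <- sqrt(p * (1 - p))
  # brute-force expectation over the 2^3 support of the binary drivers
  py_given_o <- function(o) {
    num <- 0
    for (f in 0:1) for (dd in 0:1) {
      w <- dbinom(f, 1, p["f"]) * dbinom(dd, 1, p["d"])
      eta <- b0 + 2 * (o - p["o"]) / s["o"] + 2 * (f - p["f"]) / s["f"] +
        1 * (dd - p["d"]) / s["d"]
      num <- num + w * plogis(eta)
    }
    num
  }
  or_true <- (py_given_o(1) / (1 - py_given_o(1))) /
    (py_given_o(0) / (1 - py_given_o(0)))

  co <- as.data.frame(generate_cohort(cfg))
  tab <- table(co$omega3, co$transfer_state)
  or_emp <- (tab["1", "1"] * tab["0", "0"]) / (tab["1", "0"] * tab["0", "1"])
  se_log <- sqrt(sum(1 / tab))
  expect_lt(abs(log(or_emp) - log(or_true)), 4 * se_log)
})

test_that("null-signal cohorts show no predictor-outcome association", {
  co <- as.data.frame(generate_cohort(synthetic_config(2000, seed = 55)))
  y <- co$transfer_state
  X <- as.matrix(co[, table2_features()])
  obs_max <- max(abs(cor(X, y)))
  null_max <- withr::with_seed(56, replicate(200, {
    max(abs(cor(X, sample(y))))
  }))
  # familywise permutation check at alpha = 0.01
  expect_lt(obs_max, quantile(null_max, 0.99))
})

test_that("intake fixtures round-trip through binarization exactly", {
  rdi <- fixture_rdi()
  flags <- matrix(withr::with_seed(21, rbinom(20 * 4, 1, 0.4)), nrow = 20,
                  dimnames = list(paste0("P", 1:20), rdi$ingredient))
  intakes <- generate_intake_fixture(flags, rdi, seed = 22)
  out <- binarize_intakes(intakes, rdi, patient_ids = rownames(flags))
  out <- out[match(rownames(flags), out$patient_id), rdi$ingredient]
  expect_equal(unname(as.matrix(out)), unname(flags),
               ignore_attr = TRUE)
})

test_that("gaussian-copula hook induces the requested dependence", {
  R <- diag(22)
  i <- match(c("dha", "omega3"), table2_features())
  R[i[1], i[2]] <- R[i[2], i[1]] <- 0.7
  co <- as.data.frame(generate_cohort(
    synthetic_config(20000, seed = 5, correlation = R)))
  expect_gt(cor(co$dha, co$omega3), 0.3)
  co0 <- as.data.frame(generate_cohort(synthetic_config(20000, seed = 5)))
  expect_lt(abs(cor(co0$dha, co0$omega3)), 0.05)
})
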