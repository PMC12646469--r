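# Shared fixtures, built in code.

# minimal daily-requirement table
fixture_rdi <- function() {
  data.frame(
    ingredient = c("folic_acid", "omega3", "vit_d", "coq10"),
    daily_requirement = c(400, 1000, 15, 100),
    unit = c("ug", "mg", "ug", "mg"),
    stringsAsFactors = FALSE
  )
}

# small cohort with a planted signal on three supplements
fixture_cohort <- function(n = 150, seed = 42,
                           beta = c(omega3 = 1.5, folic_acid = 1.2,
                                    dietician_support = 0.8)) {
  generate_cohort(synthetic_config(n, seed = seed, beta = beta))
}

# replace the outcome by a permutation of itself (label-permuted null)
permute_outcome <- function(cohort, seed = 1L) {
  d <- as.data.frame(cohort)
  d$transfer_state <- withr::with_seed(seed, sample(d$transfer_state))
  cohort_table(d, provenance = "label-permuted")
}
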