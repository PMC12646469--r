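# Deliberately WRONG evaluation protocol, kept in the test harness only:
# SMOTE is applied to the full dataset BEFORE splitting, so synthetic rows
# derived from (and placed near) test-fold parents contaminate evaluation.
# Used to demonstrate that the leakage guard in cross_validate() matters.
cross_validate_smote_before_split <- function(spec, cohort, cv) {
  X <- cohort_matrix(cohort)
  y <- cohort_outcome(cohort)
  sm <- smote_oversample(X, y, cv$smote_neighbors,
                         seed = derive_seed(cv$seed, "leak"))
  Xa <- sm$X
  ya <- sm$y
  folds <- stratified_folds(ya, cv$k, seed = derive_seed(cv$seed, "folds"))
  vapply(seq_along(folds), function(f) {
    test <- folds[[f]]
    train <- setdiff(seq_along(ya), test)
    fspec <- spec
    fspec$seed <- derive_seed(cv$seed, paste0("fold", f))
    fitted <- fit_model(build_model(fspec), Xa[train, , drop = FALSE],
                        ya[train])
    mean(predict(fitted, Xa[test, , drop = FALSE], type = "class") == ya[test])
  }, numeric(1))
}
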