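test_that("classification uses the <= cutoff convention, low = positive", {
  expect_true(as.logical(classify_hvsi(61, 121)))    # flagged row
  expect_false(as.logical(classify_hvsi(122, 121)))  # boundary mismatch row
  expect_true(as.logical(classify_hvsi(121, 121)))   # boundary is positive
  expect_identical(attr(classify_hvsi(50, 121), "orientation"),
                   "lower_is_positive")
  expect_error(classify_hvsi(1200, 121), "0, 999")
})

test_that("confusion partitions the verification fixture as printed", {
  recs <- load_verification_fixture()
  cc <- confusion(recs, "hvsi<=121", "fv<400")
  expect_identical(c(cc$tp, cc$fp, cc$fn, cc$tn), c(2L, 1L, 1L, 16L))
  expect_identical(cc$total, 20L)
})

test_that("confusion handles degenerate labelings", {
  recs <- toy_records(c(500, 600, 700))
  cc <- confusion(recs, "hvsi<=100", "fv<400")  # nothing flagged or positive
  expect_identical(c(cc$tp, cc$fp, cc$fn, cc$tn), c(0L, 0L, 0L, 3L))
  expect_error(confusion(recs[0, ], "hvsi<=100", "fv<400"), "no records")
  expect_error(parse_rule <- confusion(recs, "bogus<1", "fv<400"), "parse")
})

test_that("accuracy metrics reproduce the printed percentages", {
  m <- accuracy_metrics(list(tp = 2, fp = 1, fn = 1, tn = 16))
  expect_equal(unname(m), c(66.7, 94.1, 66.7, 94.1))
  expect_equal(unname(accuracy_metrics(list(tp = 1, fp = 0, fn = 0, tn = 1))),
               c(100, 100, 100, 100))
  m3 <- accuracy_metrics(list(tp = 3, fp = 1, fn = 0, tn = 16))
  expect_equal(unname(m3[c("sensitivity", "specificity")]), c(100, 94.1))
})

test_that("zero-denominator metrics are absent, not 0 or 100", {
  m <- accuracy_metrics(list(tp = 0, fp = 0, fn = 0, tn = 5))
  expect_true(is.na(m["sensitivity"]))
  expect_true(is.na(m["ppv"]))
  expect_equal(unname(m["specificity"]), 100)
})

test_that("sens/spec complement the error rates", {
  for (cc in list(list(tp = 5, fp = 3, fn = 2, tn = 9),
                  list(tp = 1, fp = 7, fn = 4, tn = 2))) {
    m <- accuracy_metrics(cc)
    fnr <- 100 * cc$fn / (cc$tp + cc$fn)
    fpr <- 100 * cc$fp / (cc$tn + cc$fp)
    expect_equal(unname(m["sensitivity"]) + fnr, 100, tolerance = 0.05)
    expect_equal(unname(m["specificity"]) + fpr, 100, tolerance = 0.05)
  }
})

test_that("ROC handles separation, ties, and the hand-counted toy", {
  sep <- toy_records(c(10, 20, 500, 600), fv = c(300, 300, 800, 800))
  r <- hvsi_roc(sep, "fv<400", ci_method = "none")
  expect_equal(r$auc, 1.0)
  # separated gap 20..500: reported cutoff at its midpoint
  expect_equal(r$youden_cutoff, 260)

  tied <- toy_records(rep(100, 6), fv = c(300, 300, 300, 800, 800, 800))
  expect_equal(hvsi_roc(tied, "fv<400", ci_method = "none")$auc, 0.5)

  toy <- toy_records(c(1, 3, 2, 4), fv = c(300, 300, 800, 800))
  r2 <- hvsi_roc(toy, "fv<400", ci_method = "none")
  # brute force: positives {1,3}, negatives {2,4}, lower = positive-leaning
  expect_equal(r2$auc, auc_pair_count(-c(1, 3), -c(2, 4)))
  expect_error(hvsi_roc(toy_records(1:3, fv = c(300, 300, 300)), "fv<400"),
               "both classes")
})

test_that("ROC curve is monotone and invariant under monotone transforms", {
  set.seed(31)
  recs <- simulate_cohort(80, 80, seed = 31)$records
  r <- hvsi_roc(recs, "fv<400", ci_method = "none")
  o <- order(1 - r$specificities, r$sensitivities)
  expect_true(all(diff(r$sensitivities[o]) >= -1e-12))
  recs2 <- recs
  recs2$hvsi <- log1p(recs$hvsi) * 37 + 2   # strictly increasing transform
  r2 <- hvsi_roc(recs2, "fv<400", ci_method = "none")
  expect_equal(r2$auc, r$auc)
})

test_that("DeLong and bootstrap intervals bracket the AUC", {
  recs <- simulate_cohort(60, 60, seed = 41)$records
  r <- hvsi_roc(recs, "fv<400")   # n >= 30 per class -> DeLong
  expect_true(r$auc_ci[1] <= r$auc && r$auc <= r$auc_ci[2])
  small <- simulate_cohort(12, 12, seed = 42)$records
  r2 <- hvsi_roc(small, "group", ci_boot_n = 200)
  expect_true(r2$auc_ci[1] <= r2$auc + 1e-9 && r2$auc <= r2$auc_ci[2] + 1e-9)
})

test_that("Youden cutoff on the fixture matches the exhaustive scan", {
  # exhaustive scan of the 20 rows: every cutoff in [122, 200) captures all
  # three reduced-flow patients (HVSI 41, 61, 122) at one false positive
  # (HVSI 71), J = 1 + 16/17 - 1; reported at the gap midpoint (122+200)/2
  recs <- load_verification_fixture()
  r <- hvsi_roc(recs, "fv<400", ci_method = "none")
  expect_equal(r$youden_cutoff, 161)
  expect_equal(r$youden_sens, 1)
  expect_equal(r$youden_spec, 16 / 17)
})

test_that("concordance counts agreements", {
  recs <- load_verification_fixture()
  conc <- concordance(recs, "hvsi<=121", "fv<400")
  expect_identical(conc$agree, 18L)
  expect_equal(conc$pct, 90.0)
  expect_equal(concordance(recs, "fv<400", "fv<400")$pct, 100)
  two <- toy_records(c(50, 900), fv = c(800, 300))
  expect_equal(concordance(two, "hvsi<=121", "fv<400")$pct, 0)
})

test_that("association matches the closed-form OLS oracle", {
  d <- data.frame(x = c(1, 2, 4, 7, 11), y = c(2.2, 4.1, 8.3, 15.2, 22.8))
  a <- association(d, "x", "y")
  o <- ols_oracle(d$x, d$y)
  expect_equal(a$slope, o$slope, tolerance = 1e-12)
  expect_equal(a$intercept, o$intercept, tolerance = 1e-12)
  expect_equal(a$pearson_r^2, a$r2, tolerance = 1e-12)

  exact <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
  expect_equal(association(exact, "x", "y")$r2, 1.0)

  set.seed(3)
  null <- data.frame(x = rnorm(5000), y = rnorm(5000))
  expect_lt(association(null, "x", "y")$r2, 0.01)
  expect_error(association(data.frame(x = rep(1, 5), y = 1:5), "x", "y"),
               "variance")
  expect_error(association(data.frame(x = 1:2, y = 1:2), "x", "y"), "n >= 3")
})
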