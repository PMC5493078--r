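totals1m <- c(NAS = 1e6, NAT = 1e6, AS = 1e6, AT = 1e6)

test_that("fold change applies the zero substitution and is unsigned", {
  expect_equal(fold_change(10, 10), 1)
  expect_equal(fold_change(2, 0), 4)      # forced by the 0 -> 0.5 rule
  expect_equal(fold_change(0, 2), 4)
  expect_equal(fold_change(0, 0), 1)
  # printed cold-acclimation-specific tag, AT vs AS
  expect_equal(fold_change(1154.99, 29.49), 1154.99 / 29.49)
  expect_error(fold_change(-1, 2), "non-negative")
})

test_that("tag statistics give the closed-form CV for concentrated tags", {
  st <- tag_stats(c(NAS = 10, NAT = 20, AS = 10, AT = 20),
                  c(NAS = 1e6, NAT = 2e6, AS = 1e6, AT = 2e6))
  expect_equal(st$cv, 0)  # all four TPMs equal
  expect_equal(st$total_count, 60)
  # single-library support: mean v/4, sample sd v/2, CV = 2 exactly
  set.seed(51)
  for (v in round(runif(20, 1, 5000))) {
    st <- tag_stats(c(0, 0, 0, v), totals1m)
    expect_equal(st$cv, 2)
    expect_gt(st$cv, 1.5)  # always clears the default CV filter
  }
  # population SD variant: CV = sqrt(3)
  st <- tag_stats(c(0, 0, 0, 100), totals1m, sd_type = "population")
  expect_equal(st$cv, sqrt(3))
  expect_error(tag_stats(c(0, 0, 0, 0), totals1m), "all-zero")
})

test_that("the prefilter applies CV and abundance boundaries as worded", {
  set.seed(52)
  tg <- random_tags(3)
  ut <- unitag_table(data.frame(
    tag = tg,
    NAS = c(0L, 0L, 25L), NAT = c(0L, 0L, 25L),
    AS = c(0L, 0L, 25L), AT = c(49L, 50L, 25L)), totals1m)
  kept <- prefilter_tags(ut)
  expect_identical(kept$tag, tg[2])  # 49 < 50 out; CV 0 out; 50 in
  expect_equal(kept$total_count, 50)
  # per-library-max rule is switchable
  kept_max <- prefilter_tags(ut, sage_thresholds(count_rule = "max"))
  expect_identical(kept_max$tag, tg[2])
})

test_that("exclusive classification tests the observed library against the pooled rest", {
  set.seed(53)
  th <- sage_thresholds()
  res <- classify_exclusive(c(0, 0, 0, 50), totals1m, th)
  expect_equal(res$category, "EXCL_AT")
  expect_equal(res$fold_change, 50 / 0.5)  # TPM 50 over the substitute
  expect_equal(res$p_value,
               audic_claverie_p(0, 50, 3e6, 1e6, sided = "two"))
  expect_lt(res$p_value, 0.001)
  # abundant tag but shallow TPM: FC 2 < 4, no call
  deep <- c(NAS = 5e7, NAT = 5e7, AS = 5e7, AT = 5e7)
  expect_null(classify_exclusive(c(0, 0, 0, 50), deep, th))
  # not exclusive: two supported libraries
  expect_null(classify_exclusive(c(1, 0, 0, 50), totals1m, th))
})

test_that("fold-change boundaries differ between the two searches as worded", {
  th <- sage_thresholds()
  # FC exactly 4.0 passes the exclusive search (">= 4.0") ...
  tot <- c(NAS = 1e7, NAT = 1e7, AS = 1e7, AT = 5e7)
  res <- classify_exclusive(c(0, 0, 0, 100), tot, th)  # TPM 2.0, FC 4.0
  expect_equal(res$fold_change, 4)
  expect_equal(res$category, "EXCL_AT")
  # ... and fails the over-represented search ("higher than 4.0")
  expect_null(classify_overrepresented(c(10, 10, 40, 40), totals1m, th,
                                       axis = "treatment"))
  res2 <- classify_overrepresented(c(10, 10, 40, 41), totals1m, th,
                                   axis = "treatment")
  expect_equal(res2$category, "OVER_A")
  expect_gt(res2$fold_change, 4)
})

test_that("over-represented classification pools counts on the chosen axis", {
  th <- sage_thresholds()
  # pooled A = 50 tags over 2e6 -> TPM 25; pooled N = 0 -> substitute 0.5
  res <- classify_overrepresented(c(0, 0, 20, 30), totals1m, th,
                                  axis = "treatment")
  expect_equal(res$category, "OVER_A")
  expect_equal(res$fold_change, 25 / 0.5)
  expect_equal(res$p_value, audic_claverie_p(0, 50, 2e6, 2e6, sided = "two"))
  # perfectly balanced: FC 1, no call
  expect_null(classify_overrepresented(c(10, 10, 10, 10), totals1m, th))
  # genotype axis pools tolerant vs susceptible
  res2 <- classify_overrepresented(c(0, 20, 0, 30), totals1m, th,
                                   axis = "genotype")
  expect_equal(res2$category, "OVER_T")
})

test_that("the full search emits exclusive calls once and over-represented calls per axis", {
  set.seed(54)
  tg <- random_tags(4)
  ut <- unitag_table(data.frame(
    tag = tg,
    NAS = c(0L, 5L, 100L, 0L),
    NAT = c(0L, 5L, 100L, 0L),
    AS = c(0L, 150L, 100L, 0L),
    AT = c(200L, 3000L, 100L, 60L)), totals1m)
  calls <- call_differential_tags(ut)
  # tag 1: exclusive AT only, never duplicated into pooled sets
  expect_identical(calls$category[calls$tag == tg[1]], "EXCL_AT")
  # tag 2: over-represented on both axes (acclimated and tolerant)
  expect_setequal(calls$category[calls$tag == tg[2]],
                  c("OVER_A", "OVER_T"))
  # tag 3: balanced, CV 0, never called
  expect_false(tg[3] %in% calls$tag)
  # tag 4: exclusive AT as well
  expect_identical(calls$category[calls$tag == tg[4]], "EXCL_AT")
  # reported calls respect the thresholds and carry a BH column
  expect_true(all(calls$p_value < 0.001))
  expect_true(all(calls$fold_change >= 4))
  expect_true(all(calls$p_adj >= calls$p_value))
  # empty table in, empty calls out
  ut0 <- unitag_table(data.frame(tag = tg[1], NAS = 1L, NAT = 1L,
                                 AS = 1L, AT = 1L), totals1m)
  expect_identical(nrow(call_differential_tags(ut0)), 0L)
})
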