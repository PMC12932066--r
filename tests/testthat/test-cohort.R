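# Cohort summary arithmetic on the packaged reference table.

test_that("reference cohort reproduces the published summary statistics", {
  tab <- load_reference_cohort()
  expect_equal(nrow(tab), 12L)
  s <- summarize_cohort(tab)
  expect_identical(s$median_psa, 6.38)
  expect_identical(s$median_psa_density, 0.18)
  expect_identical(s$median_size_cc, 36.1)
  expect_equal(s$psa_range, c(4.57, 14.24))
  expect_equal(s$positivity_fraction, 1)
  expect_equal(s$concordance_fraction, 6 / 12)
})

test_that("median is the midpoint of the central order statistics", {
  tab <- load_reference_cohort()
  psa <- sort(tab$psa_ng_ml)
  expect_equal(stats::median(tab$psa_ng_ml), mean(psa[6:7]))
  # the density median needs half-away-from-zero rounding to report 0.18
  expect_equal(mean(sort(tab$psa_density)[6:7]), 0.175)
  expect_identical(prostamould:::round_half_away(0.175, 2), 0.18)
  expect_identical(prostamould:::round_half_away(36.05, 1), 36.1)
  expect_identical(prostamould:::round_half_away(-0.175, 2), -0.18)
})

test_that("summaries are invariant to row permutation and handle n = 1", {
  tab <- load_reference_cohort()
  perm <- tab[sample.int(nrow(tab)), ]
  expect_equal(unclass(summarize_cohort(perm)), unclass(summarize_cohort(tab)))
  expect_equal(cohort_concordance(perm), cohort_concordance(tab))
  expect_equal(cohort_positivity(perm), cohort_positivity(tab))
  one <- tab[3, ]
  s1 <- summarize_cohort(one)
  expect_equal(s1$median_psa, 5.34)
  expect_equal(s1$n, 1L)
})

test_that("positivity counts recorded grades; concordance needs both", {
  tab <- load_reference_cohort()[1:4, ]
  tab$mould_gg[2] <- NA
  expect_equal(cohort_positivity(tab), 0.75)
  err <- tryCatch(cohort_concordance(tab), error = function(e) e)
  expect_match(conditionMessage(err), "row")
  tab$mould_gg <- NA
  expect_equal(cohort_positivity(tab), 0)
  allmatch <- load_reference_cohort()
  allmatch$mould_gg <- allmatch$clinical_gg
  expect_equal(cohort_concordance(allmatch), 1)
})

test_that("malformed cohort tables are rejected", {
  tf <- tempfile(fileext = ".csv")
  writeLines("n,psa_ng_ml\n1,5.0", tf)
  expect_error(read_cohort_table(tf), "lacks columns")
  unlink(tf)
  # lesion volumes flatten across semicolon-separated entries
  tab <- load_reference_cohort()
  vols <- cohort_lesion_volumes(tab)
  expect_length(vols, 14L)   # 12 patients, two with a second lesion
  expect_true(all(vols >= 0.13 & vols <= 2.41))
})
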