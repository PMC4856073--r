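# Repeat quantification: restriction arithmetic, coverage totals, PFGE.

test_that("restriction repeat counts follow the two locus conventions", {
  expect_identical(restriction_repeat_count(34.5, "normal"), 16L)
  expect_identical(restriction_repeat_count(220, "expanded"), 110L)
  expect_identical(restriction_repeat_count(325, "expanded"), 162L)
  expect_identical(restriction_repeat_count(675, "expanded"), 337L)
  expect_identical(restriction_repeat_count(2.0, "expanded"), 1L)
  expect_identical(restriction_repeat_count(2.5, "normal"), 0L)
  expect_error(restriction_repeat_count(2.0, "normal"), "flank")
  expect_error(restriction_repeat_count(-1, "expanded"))
})

test_that("digest and count invert each other for synthetic arrays", {
  ref <- fx_ref()
  for (n_units in c(3L, 16L, 40L)) {
    s <- realize_sequence(normal_chrVIII(ref, n_units), ref)
    frs <- insilico_digest(s, "GAATTC")
    cup <- frs[frs == n_units * 2000L + 2500L]
    expect_length(cup, 1L)
    expect_identical(restriction_repeat_count(cup / 1000, "normal"), n_units)
  }
})

test_that("strain estimates reproduce the published table and ratio span", {
  est <- strain_estimate(c(34.5, 220), coverage_total = 200, strain = "BYAT711")
  expect_identical(est$per_locus$repeats, c(16L, 110L))
  expect_identical(est$chromosomal_total, 126L)
  expect_identical(est$ratio, 1.59)

  est2 <- strain_estimate(c(34.5, 290, 450), coverage_total = 506)
  expect_identical(est2$chromosomal_total, 386L)
  expect_identical(est2$ratio, 1.31)

  est3 <- strain_estimate(34.5, coverage_total = 16)
  expect_identical(est3$ratio, 1)
  expect_error(strain_estimate(numeric(0), 10), "fragment")

  tab <- mutant_strain_table()
  ratios <- vapply(seq_len(nrow(tab)), function(i) {
    strain_estimate(tab$fragments_kb[[i]], tab$coverage_total[i])$ratio
  }, numeric(1))
  expect_identical(range(ratios), c(1.31, 1.59))
})

test_that("coverage totals convert fold excess by the reference unit count", {
  expect_identical(fold_excess_to_copies(100, 2L), 200)
  rt <- fx_roundtrip("parental")
  expect_identical(rt$repeat_total, 16L)
  # invariance under depth rescaling (doubling coverage changes nothing)
  pr <- rt$analysis$profile
  pr2 <- normalize_to_copies(lapply(rt$analysis$depth, `*`, 2), fx_ref(),
                             exclude = "chrVIII")
  expect_identical(coverage_repeat_total(pr2, fx_ref()),
                   coverage_repeat_total(pr, fx_ref()))
})

test_that("PFGE sizes interpolate log-linearly inside the ladder", {
  cal <- pfge_calibration(c(1, 2, 3, 4), c(800, 400, 200, 100))
  expect_equal(pfge_size(cal, 3), 200)
  expect_equal(pfge_size(cal, 2.5), sqrt(400 * 200))
  expect_error(pfge_size(cal, 5), "outside")
  expect_error(pfge_calibration(c(1, 2), c(100, 100)), "decrease")

  # forward model: migration proportional to log(size); recovery within 2%
  sizes <- c(900, 700, 500, 350, 240, 160, 110, 80)
  migr <- 10 - 2.5 * log10(sizes / 50)
  cal2 <- pfge_calibration(migr, sizes)
  truth <- c(820, 430, 300, 130)
  est <- pfge_size(cal2, 10 - 2.5 * log10(truth / 50))
  expect_true(all(abs(est - truth) / truth < 0.02))
})

test_that("the strain report table assembles per-locus columns", {
  tab <- mutant_strain_table()
  ests <- lapply(seq_len(nrow(tab)), function(i) {
    strain_estimate(tab$fragments_kb[[i]], tab$coverage_total[i],
                    strain = tab$strain[i])
  })
  rep <- repeat_count_report(ests)
  expect_identical(nrow(rep), 9L)
  expect_identical(rep$chromosomal_total[rep$strain == "BYAT724"], 661L)
  expect_identical(rep$per_locus[rep$strain == "BYAT725"], "16 + 162 + 265")
})
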