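# The three-step formation model.

test_that("step 1 creates the disomic M0 intermediate with three Asn-RS copies", {
  ref <- fx_ref()
  par <- fx_models()$parental
  expect_identical(count_marker_copies(par, "AsnRS", ref), 1L)
  s1 <- apply_step1(par, ref)
  expect_identical(count_marker_copies(s1, "AsnRS", ref), 3L)
  expect_identical(topology_key(s1, ref), topology_key(fx_models()$M0, ref))
  # the duplication adds length
  m0 <- s1$chromosomes[[length(s1$chromosomes)]]
  expect_gt(nchar(realize_sequence(m0, ref)),
            nchar(realize_sequence(par$chromosomes[[1L]], ref)))
  expect_error(apply_step1(par, ref, c("delta_VIII_D", "delta_XVI_A")),
               "same chromosome")
  expect_error(apply_step1(par, ref, c("delta_VIII_D", "delta_VIII_E")),
               "span")
})

test_that("each step-2 scenario reproduces the corresponding deduced topology", {
  ref <- fx_ref()
  ms <- fx_models()
  c711 <- formation_scenario(ref, "left_delta")
  expect_identical(topology_key(c711, ref), topology_key(ms$BYAT711, ref))
  expect_identical(count_marker_copies(c711, "AsnRS", ref), 4L)

  c725 <- formation_scenario(ref, "right_telomere")
  expect_identical(topology_key(c725, ref), topology_key(ms$BYAT725, ref))
  expect_identical(count_marker_copies(c725, "AsnRS", ref), 5L)

  c721 <- formation_scenario(ref, "right_capture")
  expect_identical(topology_key(c721, ref), topology_key(ms$BYAT721, ref))
  expect_identical(count_marker_copies(c721, "AsnRS", ref), 5L)
})

test_that("step-2 preconditions reject invalid side/termination pairs", {
  ref <- fx_ref()
  s1 <- apply_step1(fx_models()$parental, ref)
  expect_error(apply_step2(s1, ref, side = "left",
                           termination = "telomere_repeat_addition"),
               "delta-delta")
  expect_error(apply_step2(s1, ref, side = "right", termination = "delta"),
               "telomere")
  expect_error(apply_step2(fx_models()$parental, ref, side = "left"),
               "M0")
})

test_that("step 3 homogenizes the normal homolog and cannot run twice", {
  ref <- fx_ref()
  s1 <- apply_step1(fx_models()$parental, ref)
  s2 <- apply_step2(s1, ref, side = "right", amplification_count = 34L,
                    termination = "neo_telomere_capture")
  expect_identical(count_marker_copies(s2, "AsnRS", ref), 4L)
  s3 <- apply_step3(s2, ref, array_units = 30L)
  expect_identical(count_marker_copies(s3, "AsnRS", ref), 5L)
  expect_false(attr(s3, "informational"))
  # the two expanded loci may differ in size
  units <- unlist(lapply(s3$chromosomes, function(cm) {
    vapply(Filter(function(p) inherits(p, "TandemArraySpec") &&
                    !is.null(p$junction), cm$parts),
           `[[`, integer(1), "copy_count")
  }))
  expect_setequal(units, c(30L, 34L))
  expect_error(apply_step3(s3, ref), "no normal homolog")

  # legal but unobserved: homogenizing the single-macrotene case
  c711 <- formation_scenario(ref, "left_delta")
  s3b <- apply_step3(c711, ref)
  expect_true(attr(s3b, "informational"))
})

test_that("sequence content is conserved outside explicit deletions", {
  ref <- fx_ref()
  co <- ref$layout$coords
  c721 <- formation_scenario(ref, "right_capture")
  v <- model_copy_vector(c721, ref, "chrVIII")
  # every base of the parental backbone persists except the deleted right
  # subtelomere (the CUP region itself lives on the array parts)
  keep <- c(1:co$cup_l, (co$cup_r + 1L):co$subtel)
  expect_true(all(v[keep] >= 1L))
  expect_true(all(v[(co$subtel + 1L):co$len_viii] == 0L))
  c711 <- formation_scenario(ref, "left_delta")
  v2 <- model_copy_vector(c711, ref, "chrVIII")
  expect_true(all(v2[c(keep, (co$subtel + 1L):co$len_viii)] >= 1L))
})

test_that("the stochastic mode draws a scenario deterministically per seed", {
  ref <- fx_ref()
  a <- formation_random(ref, seed = 4L)
  b <- formation_random(ref, seed = 4L)
  expect_identical(attr(a, "scenario"), attr(b, "scenario"))
  expect_identical(topology_key(a, ref), topology_key(b, ref))
  scns <- vapply(1:8, function(s) attr(formation_random(ref, seed = s), "scenario"), "")
  expect_gt(length(unique(scns)), 1L)
})
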