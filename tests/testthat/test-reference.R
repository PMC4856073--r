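# Synthetic reference construction: scaling rules, confounders, layout.

test_that("scaling keeps chromosome totals while fixed elements keep their size", {
  ref <- fx_ref()
  expect_identical(nchar(ref$chromosomes$chrVIII), 56300L)
  units <- ref$features[ref$features$class == "repeat_unit", ]
  expect_identical(nrow(units), 2L)
  expect_true(all(units$end - units$start == 2000L))
  co <- ref$layout$coords
  expect_identical(co$d_left, 11650L)   # 116.5 kb image
  expect_identical(co$e_left, 13380L)   # 133.8 kb image
  expect_identical(co$f_left, 12322L)   # nt 123,222 image
  expect_identical(co$xvia_end, 5650L)  # 56.5 kb image
  expect_identical(co$asn_start, co$cup_l - 7000L) # 70 kb upstream, scaled
})

test_that("full-scale coordinates are exact", {
  ref1 <- build_reference(1.0)
  co <- ref1$layout$coords
  expect_identical(nchar(ref1$chromosomes$chrVIII), 563000L)
  expect_identical(co$subtel, 549500L)
  expect_identical(nchar(ref1$chromosomes$chrVIII) - co$subtel, 13500L)
})

test_that("the repeat unit contains no EcoRI or BamHI site and the planted motifs", {
  lay <- fx_ref()$layout
  expect_false(grepl("GAATTC", lay$unit, fixed = TRUE))
  expect_false(grepl("GGATCC", lay$unit, fixed = TRUE))
  m1 <- substr(lay$unit, lay$micro_p1 + 1L, lay$micro_p1 + lay$micro_len)
  m2 <- substr(lay$unit, lay$micro_p2 + 1L, lay$micro_p2 + lay$micro_len)
  expect_identical(m2, revcomp(m1))
  expect_identical(lay$micro_p2 - (lay$micro_p1 + lay$micro_len), 745L)
})

test_that("chromosome I shares chromosome VIII's subtelomere except the unique marker", {
  ref <- fx_ref()
  co <- ref$layout$coords
  v8 <- substr(ref$chromosomes$chrVIII, co$subtel + 1L, co$len_viii)
  c1 <- substr(ref$chromosomes$chrI, co$len_i - co$wsub + 1L, co$len_i)
  off <- co$imd2 - co$subtel
  # identical outside the marker window
  expect_identical(substr(v8, 1L, off), substr(c1, 1L, off))
  expect_identical(substr(v8, off + 601L, co$wsub), substr(c1, off + 601L, co$wsub))
  # and different inside it
  expect_false(substr(v8, off + 1L, off + 600L) == substr(c1, off + 1L, off + 600L))
})

test_that("reference invariants hold and collisions are rejected", {
  ref <- fx_ref()
  expect_silent(validate_reference(ref))
  cen <- ref$features[ref$features$class == "centromere", ]
  expect_identical(sort(cen$chrom), sort(names(ref$chromosomes)))
  expect_error(build_reference(0.01), "collide")
})

test_that("reference FASTA + BED round trip preserves sequences and layout", {
  ref <- fx_ref()
  fa <- tempfile(fileext = ".fa")
  bed <- tempfile(fileext = ".bed")
  write_reference(ref, fa, bed)
  back <- read_reference(fa, bed)
  expect_identical(back$chromosomes, ref$chromosomes)
  expect_identical(back$layout$unit, ref$layout$unit)
  expect_identical(back$layout$coords$cup_l, ref$layout$coords$cup_l)
  expect_identical(back$layout$coords$subtel, ref$layout$coords$subtel)
  expect_setequal(back$features$name, ref$features$name)
})
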