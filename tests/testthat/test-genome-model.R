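# Chromosome model realization, in-silico digestion, marker counting.

test_that("segment realization reproduces the reference and obeys the part-sum rule", {
  ref <- fx_ref()
  n <- nchar(ref$chromosomes$chrVIII)
  whole <- chromosome_model("c", list(segment_spec("chrVIII", 0L, n)))
  expect_identical(realize_sequence(whole, ref), ref$chromosomes$chrVIII)

  mac <- fx_models()$BYAT711$chromosomes[[2L]]
  parts_cat <- paste(vapply(mac$parts, macrotene:::realize_part, "", ref = ref),
                     collapse = "")
  expect_identical(realize_sequence(mac, ref), parts_cat)

  minus <- segment_spec("chrVIII", 1000L, 2000L, "-")
  expect_identical(realize_sequence(chromosome_model("m", list(minus)), ref),
                   revcomp(seq_extract <- substr(ref$chromosomes$chrVIII, 1001L, 2000L)))
})

test_that("tandem arrays carry their units, flanks and junction geometry", {
  ref <- fx_ref()
  a16 <- macrotene:::realize_array(tandem_array_spec(16L), ref)
  expect_identical(nchar(a16), 34500L) # 16 x 2 kb + 2.5 kb flank
  expect_true(grepl(strrep(ref$layout$unit, 16L), a16, fixed = TRUE))

  js <- make_strand_switch_junction(ref, 38L)
  astar <- macrotene:::realize_array(tandem_array_spec(30L, junction = js), ref)
  # both ends present the locus-left flank, one reverse complemented
  expect_identical(substr(astar, 1L, 1250L), ref$layout$flank_l)
  expect_identical(substr(astar, nchar(astar) - 1249L, nchar(astar)),
                   revcomp(ref$layout$flank_l))
  expect_identical(nchar(astar), 2L * 1250L + 29L * 2000L + 2L * 400L + 38L)

  expect_error(
    macrotene:::realize_array(tandem_array_spec(4L, junction = js,
                                                junction_index = 9L), ref),
    "junction_index"
  )
})

test_that("a mirrored segment model realizes the reverse complement", {
  ref <- fx_ref()
  parts <- list(segment_spec("chrVIII", 100L, 700L, "+"),
                segment_spec("chrXVI", 50L, 400L, "-"),
                segment_spec("chrII", 0L, 900L, "+"))
  mirror <- rev(lapply(parts, function(p) {
    segment_spec(p$chrom, p$start, p$end, if (p$orientation == "+") "-" else "+")
  }))
  fwd <- realize_sequence(chromosome_model("a", parts), ref)
  bwd <- realize_sequence(chromosome_model("b", mirror), ref)
  expect_identical(bwd, revcomp(fwd))
})

test_that("in-silico digestion partitions the sequence and finds planted sites", {
  expect_error(insilico_digest("", "GAATTC"), "empty")
  expect_error(insilico_digest("ACGTACGT", "GAA"), "at least 4")
  expect_identical(insilico_digest("ACGTACGTACGT", "GAATTC"), 12L)

  set.seed(5)
  base <- macrotene:::scrub_motifs(macrotene:::random_dna(5000L), "GAATTC")
  planted <- c(1200L, 2600L, 4100L)
  for (p in planted) base <- macrotene:::seq_replace(base, p, "GAATTC")
  expect_identical(insilico_digest(base, "GAATTC"),
                   diff(c(0L, planted, 5000L)))

  frs <- insilico_digest(fx_ref()$chromosomes$chrVIII, "GAATTC")
  expect_identical(sum(frs), nchar(fx_ref()$chromosomes$chrVIII))
})

test_that("realize->digest round trip: CUP EcoRI fragment is units + flank", {
  ref <- fx_ref()
  for (n_units in c(5L, 16L, 24L)) {
    chrom <- normal_chrVIII(ref, n_units)
    s <- realize_sequence(chrom, ref)
    frs <- insilico_digest(s, "GAATTC")
    expect_true((n_units * 2000L + 2500L) %in% frs)
  }
})

test_that("marker copies match the string-search oracle across models", {
  ref <- fx_ref()
  ms <- fx_models()
  expect_identical(count_marker_copies(ms$parental, "AsnRS", ref), 1L)
  expect_identical(count_marker_copies(ms$BYAT711, "AsnRS", ref), 4L)
  expect_identical(count_marker_copies(ms$BYAT721, "AsnRS", ref), 5L)
  expect_identical(count_marker_copies(ms$BYAT725, "AsnRS", ref), 5L)
  expect_error(count_marker_copies(ms$parental, "NOPE", ref), "unknown")

  fi <- ref$features[ref$features$name == "AsnRS", ]
  probe <- substr(ref$chromosomes$chrVIII, fi$start + 1L, fi$end)
  for (mn in c("parental", "BYAT711", "BYAT721")) {
    pool <- realize_cell(ms[[mn]], ref)$chromosomes
    hits <- sum(vapply(pool, function(s) {
      length(gregexpr(probe, s, fixed = TRUE)[[1L]][
        gregexpr(probe, s, fixed = TRUE)[[1L]] > 0]) +
        length(gregexpr(revcomp(probe), s, fixed = TRUE)[[1L]][
          gregexpr(revcomp(probe), s, fixed = TRUE)[[1L]] > 0])
    }, numeric(1)))
    expect_identical(as.integer(hits),
                     count_marker_copies(ms[[mn]], "AsnRS", ref))
  }
})

test_that("cell JSON serialization round-trips the topology", {
  ref <- fx_ref()
  for (mn in c("BYAT711", "BYAT725")) {
    cell <- fx_models()[[mn]]
    path <- tempfile(fileext = ".json")
    cell_to_json(cell, path)
    back <- cell_from_json(path)
    expect_identical(topology_key(back, ref, with_sizes = TRUE),
                     topology_key(cell, ref, with_sizes = TRUE))
    expect_identical(realize_cell(back, ref), realize_cell(cell, ref))
  }
})
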