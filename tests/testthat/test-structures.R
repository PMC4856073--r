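# Constraint-based topology enumeration, observables, ranking.

test_that("parental constraints admit exactly the normal chromosome", {
  sol <- enumerate_structures(fx_constraints_parental())
  expect_length(sol, 1L)
  expect_identical(topology_key(sol[[1L]]$cell, fx_ref()),
                   topology_key(fx_models()$parental, fx_ref()))
})

test_that("the disomic single-macrotene constraint set admits four topologies", {
  sol <- enumerate_structures(fx_constraints_711())
  expect_length(sol, 4L)
  keys <- vapply(sol, function(s) topology_key(s$cell, fx_ref()), "")
  expect_identical(anyDuplicated(keys), 0L)
  expect_true(topology_key(fx_models()$BYAT711, fx_ref()) %in% keys)
})

test_that("solution counts match the permutation-orientation oracle", {
  # one macrotene cassette between the two locus edges
  expect_identical(length(enumerate_structures(fx_constraints_711())),
                   oracle_arrangements(c("Aexp", "Anorm", "D", "E")))
  # same blocks but no expanded array: two arrangements
  ref <- fx_ref()
  b <- macrotene:::model_blocks(ref)
  mac <- chromosome_model("chrVIII_mac", list(
    b$left_arm(), tandem_array_spec(16L), b$D("-"), b$E("+"),
    tandem_array_spec(16L), b$right_arm()
  ))
  cell <- cell_model("x", c(list(normal_chrVIII(ref), mac),
                            list(b$chrXVI(), b$chrI(), b$chrII())))
  cs <- constraint_set(
    ref, ploidy_viii = 2,
    expected_levels = rbind(fx_levels_viii(c(2, 3, 3, 4, 2, 2)),
                            fx_levels_xvi(c(1, 1))),
    array_classes = character(0), band_sizes_kb = fx_bands(cell),
    n_delta_junctions = 1L, max_normal_arrays = 3L
  )
  expect_identical(length(enumerate_structures(cs)),
                   oracle_arrangements(c("Anorm", "D", "E", "Anorm")))
})

test_that("unsatisfiable constraints return empty with diagnostics", {
  cs <- constraint_set(
    fx_ref(), ploidy_viii = 1,
    expected_levels = rbind(fx_levels_viii(c(1, 1, 1, 1, 1, 1)),
                            fx_levels_xvi(c(1, 1))),
    array_classes = rep("strand_switch", 3L) # no room for three arrays
  )
  sol <- enumerate_structures(cs)
  expect_length(sol, 0L)
  expect_false(is.null(attr(sol, "diagnostics")))
})

test_that("predicted observables: bands, probes, digest conservation", {
  ref <- fx_ref()
  obs <- predict_observables(fx_models()$parental, ref)
  frs <- obs$cup_fragments_kb[["chrVIII"]]
  expect_true(any(abs(frs - 34.5) < 1e-9))
  # digest fragments per chromosome sum to the band size
  cm <- fx_models()$BYAT711$chromosomes[[2L]]
  s <- realize_sequence(cm, ref)
  expect_identical(sum(insilico_digest(s, "GAATTC")), nchar(s))

  obs721 <- predict_observables(fx_models()$BYAT721, ref)
  b <- obs721$bands
  macs <- b[grepl("mac", b$chrom), ]
  # only the larger of the two macrotene chromosomes carries the right-arm probe
  expect_identical(macs$YH240[order(macs$size_kb)], c(FALSE, TRUE))
  expect_true(all(macs$CUP))
})

test_that("ranking ties the four equivalent topologies and demotes violators", {
  ref <- fx_ref()
  sol <- enumerate_structures(fx_constraints_711())
  obs <- predict_observables(fx_models()$BYAT711, ref)$bands
  observed <- obs[grepl("VIII", obs$chrom),
                  c("size_kb", "AsnRS", "YH240", "YP22")]
  ranked <- rank_against_observation(sol, observed, ref)
  expect_identical(length(unique(ranked$score)), 1L) # four-way tie

  worse <- c(sol, list(structure(list(cell = fx_models()$parental,
                                      key = "parental"),
                                 class = "StructureSolution")))
  ranked2 <- rank_against_observation(worse, observed, ref)
  expect_lt(ranked2$score[ranked2$solution == 5L],
            max(ranked2$score))
})

test_that("the canonical key identifies a model with its reverse complement", {
  ref <- fx_ref()
  cm <- fx_models()$BYAT711$chromosomes[[2L]]
  mirror_parts <- rev(lapply(cm$parts, function(p) {
    if (inherits(p, "SegmentSpec")) {
      segment_spec(p$chrom, p$start, p$end,
                   if (p$orientation == "+") "-" else "+", p$label)
    } else {
      p
    }
  }))
  mirrored <- cell_model("m", list(chromosome_model("c", mirror_parts)))
  orig <- cell_model("o", list(cm))
  expect_identical(topology_key(mirrored, ref), topology_key(orig, ref))
  expect_false(topology_key(fx_models()$BYAT711, ref) ==
                 topology_key(fx_models()$BYAT725, ref))
})
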