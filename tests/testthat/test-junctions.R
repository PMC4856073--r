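# Unmapped-read assembly and junction classification.

# tile error-free reads over a sequence at a given fold depth
tile_reads <- function(seq, depth, L = 100L, prefix = "t") {
  step <- max(1L, round(L / depth))
  starts <- seq(1L, nchar(seq) - L + 1L, by = step)
  data.frame(id = paste0(prefix, seq_along(starts)),
             seq = substring(seq, starts, starts + L - 1L),
             stringsAsFactors = FALSE)
}

# window of the realized expanded array around its junction point; the
# default flank matches the span that junction-spanning reads can cover,
# as in a real unmapped pool (and below the largest assembly word size,
# which is what lets the palindrome arms assemble through the junction)
junction_window <- function(array, ref, flank = 180L) {
  s <- macrotene:::realize_array(array, ref)
  ji <- array$junction_index
  brk <- 1250L + (ji - 1L) * 2000L +
    if (array$junction$kind == "strand_switch") {
      array$junction$switch_offset
    } else {
      ref$layout$micro_p2 + ref$layout$micro_len
    }
  substr(s, brk - flank + 1L, brk + flank)
}

test_that("collect_unmapped returns exactly the unmapped reads", {
  ref <- fx_ref()
  mapped <- data.frame(id = "a", seq = substr(ref$chromosomes$chrII, 1001L, 1100L))
  al <- map_reads(mapped, ref)
  expect_identical(nrow(collect_unmapped(al)), 0L)
  rt <- fx_roundtrip("BYAT711")
  pool <- collect_unmapped(rt$analysis$alignments)
  expect_identical(pool$id, rt$analysis$alignments$unmapped$id)
  expect_gt(nrow(pool), 20L)
})

test_that("identical error-free reads assemble into one junction contig", {
  ref <- fx_ref()
  js <- make_strand_switch_junction(ref, 38L)
  win <- junction_window(tandem_array_spec(30L, junction = js), ref, flank = 65L)
  pool <- tile_reads(win, depth = 50)
  contigs <- assemble_junctions(pool, haploid_depth = 50)
  expect_identical(nrow(contigs), 1L)
  ctg <- contigs$contig[1L]
  expect_true(grepl(js$loop_seq, ctg, fixed = TRUE) ||
                grepl(revcomp(js$loop_seq), ctg, fixed = TRUE))
})

test_that("two junctions give two contigs with per-cell support estimates", {
  ref <- fx_ref()
  js <- make_strand_switch_junction(ref, 38L)
  jm <- make_microhomology_junction(ref)
  w1 <- junction_window(tandem_array_spec(30L, junction = js), ref, flank = 65L)
  w2 <- junction_window(tandem_array_spec(24L, junction = jm), ref, flank = 65L)
  pool <- rbind(tile_reads(w1, 50, prefix = "a"),
                tile_reads(w2, 100, prefix = "b"))
  contigs <- assemble_junctions(pool, haploid_depth = 50)
  expect_identical(nrow(contigs), 2L)
  sup <- sort(contigs$support_copies)
  expect_lt(abs(sup[1L] - 1), 0.35)
  expect_lt(abs(sup[2L] - 2), 0.5)
})

test_that("contigs at or below 0.5 copies per genome are discarded", {
  ref <- fx_ref()
  js <- make_strand_switch_junction(ref, 38L)
  win <- junction_window(tandem_array_spec(30L, junction = js), ref, flank = 65L)
  pool <- tile_reads(win, depth = 15) # 0.3 copies at 50x haploid depth
  contigs <- assemble_junctions(pool, haploid_depth = 50)
  expect_identical(nrow(contigs), 0L)
  expect_identical(nrow(assemble_junctions(pool[0, ], 50)), 0L)
})

test_that("strand-switch contigs classify with the exact loop and coordinates", {
  ref <- fx_ref()
  for (loop_len in c(38L, 63L)) {
    js <- make_strand_switch_junction(ref, loop_len, switch_offset = 400L)
    win <- junction_window(tandem_array_spec(20L, junction = js), ref)
    call <- classify_junction(win, ref)
    expect_identical(call$class, "strand_switch_palindrome")
    expect_identical(call$loop_length, loop_len)
    expect_identical(call$mismatches_in_palindrome, 0L)
    expect_identical(call$pos1, ref$layout$coords$cup_l + 1250L + 400L)
  }
  # reverse-complemented contig: same call
  js <- make_strand_switch_junction(ref, 38L)
  win <- junction_window(tandem_array_spec(20L, junction = js), ref)
  expect_identical(classify_junction(revcomp(win), ref)$loop_length, 38L)
})

test_that("one substitution inside the palindrome does not change the call", {
  ref <- fx_ref()
  js <- make_strand_switch_junction(ref, 63L, switch_offset = 260L,
                                    arm_mismatches = 1L)
  win <- junction_window(tandem_array_spec(20L, junction = js), ref)
  call <- classify_junction(win, ref)
  expect_identical(call$class, "strand_switch_palindrome")
  expect_identical(call$loop_length, 63L)
  expect_identical(call$mismatches_in_palindrome, 1L)
})

test_that("inverted-microhomology contigs report motif length and spacing", {
  ref <- fx_ref()
  jm <- make_microhomology_junction(ref)
  win <- junction_window(tandem_array_spec(24L, junction = jm), ref)
  call <- classify_junction(win, ref)
  expect_identical(call$class, "inverted_microhomology")
  expect_identical(call$microhomology_length, 16L)
  expect_identical(call$reference_spacing, 745L)
})

test_that("telomere fusions and fully-mapping contigs are recognized", {
  ref <- fx_ref()
  co <- ref$layout$coords
  cap <- revcomp(macrotene:::telomere_run(120L, seed = 5L))
  fused <- paste0(revcomp(substr(ref$chromosomes$chrVIII, co$f_left + 1L,
                                 co$f_left + 150L)), cap)
  call <- classify_junction(fused, ref)
  expect_identical(call$class, "telomere_fusion")
  # left-aligned fusion point (a chance base match can shift it by one)
  expect_lte(abs(call$pos1 - co$f_left), 2L)

  plain <- substr(ref$chromosomes$chrXVI, 8001L, 8300L)
  expect_identical(classify_junction(plain, ref)$class, "unclassified")
})

test_that("junctions falling in delta elements are flagged unresolvable", {
  ref <- fx_ref()
  b <- macrotene:::model_blocks(ref)
  # inverted delta-delta adjacency as in the D(-) | E(+) cassette junction
  dseq <- macrotene:::realize_part(b$D("-"), ref)
  eseq <- macrotene:::realize_part(b$E("+"), ref)
  win <- paste0(substr(dseq, nchar(dseq) - 400L, nchar(dseq)),
                substr(eseq, 1L, 400L))
  expect_identical(classify_junction(win, ref)$class, "repeat_ambiguous")
  # co-oriented chimeric delta (truncated right arm | extra D copy)
  tseq <- macrotene:::realize_part(b$right_arm_trunc(), ref)
  win2 <- paste0(substr(tseq, nchar(tseq) - 400L, nchar(tseq)),
                 substr(macrotene:::realize_part(b$D("+"), ref), 1L, 400L))
  expect_identical(classify_junction(win2, ref)$class, "repeat_ambiguous")
})

test_that("junction copy number estimates spanning depth per cell", {
  ref <- fx_ref()
  js <- make_strand_switch_junction(ref, 38L)
  win <- junction_window(tandem_array_spec(30L, junction = js), ref)
  call <- classify_junction(win, ref)
  pool <- tile_reads(win, depth = 50)
  est <- junction_copy_number(win, call$contig_break, pool, haploid_depth = 50)
  expect_lt(abs(est - 1), 0.25)
  est2 <- junction_copy_number(win, call$contig_break, tile_reads(win, 100),
                               haploid_depth = 50)
  expect_lt(abs(est2 - 2), 0.45)
  expect_identical(junction_copy_number(win, call$contig_break,
                                        data.frame(id = character(0),
                                                   seq = character(0)), 50), 0)
  expect_error(junction_copy_number(win, call$contig_break, pool, 0), "positive")
})

test_that("a junction-free genome yields no junction calls", {
  rt <- fx_roundtrip("parental")
  expect_identical(nrow(rt$analysis$junctions), 0L)
})
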