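# Mapping, depth, normalization, smoothing.

test_that("verbatim reads map at their origin with zero mismatches", {
  ref <- fx_ref()
  pos <- c(5000L, 30100L, 46000L)
  reads <- data.frame(
    id = paste0("r", seq_along(pos)),
    seq = substring(ref$chromosomes$chrVIII, pos + 1L, pos + 100L)
  )
  al <- map_reads(reads, ref)
  expect_identical(al$alignments$pos, pos)
  expect_true(all(al$alignments$mismatches == 0L))
  expect_true(all(al$alignments$chrom == "chrVIII"))
  # minus-strand copies land at the same coordinates
  al2 <- map_reads(data.frame(id = reads$id, seq = macrotene:::revcomp_many(reads$seq)),
                   ref)
  expect_identical(al2$alignments$pos, pos)
  expect_true(all(al2$alignments$strand == "-"))
})

test_that("a read straddling a strand-switch junction midpoint is unmapped", {
  ref <- fx_ref()
  js <- make_strand_switch_junction(ref, 38L)
  astar <- macrotene:::realize_array(tandem_array_spec(30L, junction = js), ref)
  brk <- 1250L + 14L * 2000L + 400L # end of the forward arm
  read <- substr(astar, brk - 40L, brk + 59L)
  al <- map_reads(data.frame(id = "j", seq = read), ref)
  expect_identical(nrow(al$unmapped), 1L)
  # oracle: no ungapped placement anywhere reaches the mismatch threshold
  expect_false(oracle_mappable(read, ref, 10L))
})

test_that("shared-subtelomere reads are ambiguous and follow the multi-map policy", {
  ref <- fx_ref()
  co <- ref$layout$coords
  # a window of the shared block downstream of the unique marker
  f <- ref$features[ref$features$name == "IMD2", ]
  read <- substr(ref$chromosomes$chrVIII, f$end + 21L, f$end + 120L)
  rd <- data.frame(id = "s", seq = read)
  first <- map_reads(rd, ref, policy = "first")
  expect_true(first$alignments$ambiguous[1L])
  expect_identical(first$alignments$chrom[1L], "chrVIII") # first in order
  expect_identical(first$alignments$weight[1L], 1)
  split <- map_reads(rd, ref, policy = "split")
  expect_identical(nrow(split$alignments), 2L)
  expect_setequal(split$alignments$chrom, c("chrVIII", "chrI"))
  expect_true(all(split$alignments$weight == 0.5))
})

test_that("mismatched reads are placed by seeding and capped by the threshold", {
  ref <- fx_ref()
  base <- substr(ref$chromosomes$chrXVI, 9001L, 9100L)
  mut <- base
  for (p in c(30L, 60L, 85L)) {
    substr(mut, p, p) <- chartr("ACGT", "GTAC", substr(mut, p, p))
  }
  al <- map_reads(data.frame(id = "m", seq = mut), ref)
  expect_identical(al$alignments$pos, 9000L)
  expect_identical(al$alignments$mismatches, 3L)
  # beyond 10% mismatches the read is unmapped
  worse <- base
  for (p in seq(3L, 90L, by = 8L)) {
    substr(worse, p, p) <- chartr("ACGT", "GTAC", substr(worse, p, p))
  }
  expect_identical(nrow(map_reads(data.frame(id = "w", seq = worse), ref)$unmapped), 1L)
})

test_that("depth counts covering reads exactly and conserves aligned bases", {
  ref <- fx_ref()
  none <- map_reads(data.frame(id = character(0), seq = character(0)), ref)
  d0 <- depth_profile(none, ref)
  expect_true(all(vapply(d0, sum, numeric(1)) == 0))

  one <- map_reads(data.frame(id = "r", seq = substr(ref$chromosomes$chrII, 501L, 600L)),
                   ref)
  d1 <- depth_profile(one, ref)
  expect_identical(which(d1$chrII > 0), 501:600)
  expect_true(all(d1$chrII[501:600] == 1))

  reads <- data.frame(id = paste0("r", 1:50),
                      seq = substring(ref$chromosomes$chrII,
                                      seq(1000L, 5900L, by = 100L) + 1L,
                                      seq(1000L, 5900L, by = 100L) + 100L))
  al <- map_reads(reads, ref)
  d <- depth_profile(al, ref)
  expect_identical(sum(unlist(d)), sum(al$alignments$weight * 100))
})

test_that("normalization anchors haploid at 1 and is scale invariant", {
  ref <- fx_ref()
  lens <- vapply(ref$chromosomes, nchar, integer(1))
  depth <- lapply(lens, function(n) rep(30, n))
  pr <- normalize_to_copies(depth, ref)
  expect_true(all(abs(unlist(pr$values) - 1) < 1e-12))
  pr2 <- normalize_to_copies(lapply(depth, `*`, 2), ref)
  expect_equal(pr$values, pr2$values)
  expect_error(normalize_to_copies(lapply(lens, function(n) rep(0, n)), ref),
               "zero")
})

test_that("smoothing is the centered moving average with shrinking edges", {
  ref <- fx_ref()
  lens <- vapply(ref$chromosomes, nchar, integer(1))
  mk <- function(v) {
    vals <- lapply(lens, function(n) rep(1, n))
    vals$chrII <- v
    structure(list(values = vals, median_depth = 1, window = 1L),
              class = "CopyNumberProfile")
  }
  step <- c(rep(1, 20000), rep(4, 20000))
  pr <- mk(step)
  expect_identical(smooth_profile(pr, 1L)$values$chrII, step)
  sm <- smooth_profile(pr, 501L)
  expect_equal(sm$values$chrII[20000], (1 + 4) / 2, tolerance = 0.01)

  set.seed(42)
  noise <- rnorm(40000)
  sm2 <- smooth_profile(mk(noise), 151L)$values$chrII
  brute <- vapply(c(1L, 76L, 5000L, 39999L), function(i) {
    lo <- max(1L, i - 75L); hi <- min(40000L, i + 75L)
    mean(noise[lo:hi])
  }, numeric(1))
  expect_equal(sm2[c(1L, 76L, 5000L, 39999L)], brute)
  expect_error(smooth_profile(pr, 150L), "window")
})

test_that("the split policy reveals the shared-subtelomere deletion artifact", {
  rt <- fx_roundtrip("BYAT721")
  ref <- fx_ref()
  co <- ref$layout$coords
  al <- map_reads(rt$analysis$alignments$reads, ref, policy = "split")
  pr <- normalize_to_copies(depth_profile(al, ref), ref, exclude = "chrVIII")
  f <- ref$features[ref$features$name == "IMD2", ]
  block <- pr$values$chrVIII[(co$subtel + 1L):(co$len_viii - 400L)]
  expect_lt(mean(block), 1) # coverage lower than one copy
  w <- nchar(al$reads$seq[match(al$alignments$id, al$reads$id)])
  rows <- al$alignments$chrom == "chrVIII"
  marker_reads <- sum(pmin(al$alignments$pos[rows] + w[rows], f$end) -
                        pmax(al$alignments$pos[rows], f$start) >= 10L)
  expect_identical(marker_reads, 0L) # complete absence of marker reads
})
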