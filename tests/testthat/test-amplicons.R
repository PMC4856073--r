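# Integer-level segmentation, staircase decomposition, deletion calls.

mk_profile <- function(v, chrom = "chrVIII") {
  vals <- list()
  vals[[chrom]] <- v
  structure(list(values = vals, median_depth = 50, window = 1L),
            class = "CopyNumberProfile")
}

test_that("a flat profile yields one level-1 segment", {
  set.seed(1)
  pr <- mk_profile(1 + rnorm(30000, 0, 0.1))
  segs <- segment_levels(pr, window = 150L)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$level, 1L)
  expect_false(segs$non_integer)
})

test_that("noiseless staircases segment at the exact breakpoints", {
  v <- c(rep(2, 9000), rep(3, 4500), rep(5, 6000), rep(1, 10500))
  segs <- segment_levels(mk_profile(v), window = 150L)
  expect_identical(segs$level, c(2L, 3L, 5L, 1L))
  expect_identical(segs$start, c(0L, 9000L, 13500L, 19500L))
  expect_identical(segs$end, c(9000L, 13500L, 19500L, 30000L))
})

test_that("integer levels survive noise for long segments (seeded)", {
  set.seed(7)
  for (rep_i in 1:3) {
    lv <- sample(1:5, 4)
    v <- rep(lv, each = 4500) + rnorm(18000, 0, 0.2)
    segs <- segment_levels(mk_profile(v), window = 150L)
    expect_identical(segs$level, as.integer(lv))
  }
})

test_that("means far from any integer are flagged, not forced", {
  set.seed(2)
  v <- c(rep(1, 15000), rep(2.5, 15000)) + rnorm(30000, 0, 0.05)
  segs <- segment_levels(mk_profile(v), window = 150L)
  expect_true(any(segs$non_integer))
})

test_that("staircase decomposition is minimal, right-aligned and exact", {
  toy <- function(levels) {
    n <- length(levels)
    data.frame(chrom = "c", start = (seq_len(n) - 1L) * 100L,
               end = seq_len(n) * 100L, level = levels,
               mean_raw = levels, non_integer = FALSE)
  }
  expect_identical(nrow(staircase_decompose(toy(c(2, 2, 2)), 2)), 0L)

  amp <- staircase_decompose(toy(c(2, 3, 4)), 2)
  expect_identical(nrow(amp), 2L)
  expect_identical(amp$end, c(300L, 300L))       # right-aligned nesting
  expect_identical(sort(amp$start), c(100L, 200L))
  expect_true(all(amp$extra_copies == 1L))

  expect_error(staircase_decompose(toy(c(1, 0, 1)), 1), "deletion")
})

test_that("decomposition cardinality equals the brute-force oracle on random staircases", {
  set.seed(11)
  for (case_i in 1:12) {
    n_seg <- sample(2:6, 1)
    h <- pmax(0L, sample(0:4, n_seg, replace = TRUE))
    if (all(h == 0L)) h[1L] <- 1L
    segs <- data.frame(chrom = "c", start = (seq_len(n_seg) - 1L) * 10L,
                       end = seq_len(n_seg) * 10L, level = h + 1L,
                       mean_raw = h + 1, non_integer = FALSE)
    amp <- staircase_decompose(segs, 1)
    expect_identical(nrow(amp), as.integer(oracle_min_calls(h)),
                     info = paste(h, collapse = ","))
    # reconstruction identity
    rebuilt <- integer(n_seg)
    for (i in seq_len(nrow(amp))) {
      covered <- segs$start >= amp$start[i] & segs$end <= amp$end[i]
      rebuilt[covered] <- rebuilt[covered] + amp$extra_copies[i]
    }
    expect_identical(rebuilt, as.integer(h))
  }
})

test_that("deletions require terminal sub-unit coverage; markers decide", {
  ref <- fx_ref()
  no_reads <- map_reads(data.frame(id = character(0), seq = character(0)), ref)
  segs <- data.frame(chrom = "chrVIII",
                     start = c(0L, 40000L), end = c(40000L, 56300L),
                     level = c(1L, 1L), mean_raw = c(1, 1), non_integer = FALSE)
  expect_identical(nrow(call_deletions(segs, ref, no_reads)), 0L)

  segs$level[2L] <- 0L
  segs$mean_raw[2L] <- 0.05
  del <- call_deletions(segs, ref, no_reads)
  expect_identical(nrow(del), 1L)
  expect_true(del$terminal)
  expect_identical(del$evidence, "zero_marker_reads") # marker region uncovered
})

test_that("the mutant pools segment to the reported levels and breakpoints", {
  ref <- fx_ref()
  co <- ref$layout$coords
  win <- fx_roundtrip("BYAT711")$analysis$seg_window

  s711 <- fx_roundtrip("BYAT711")$analysis$segments
  s711 <- s711[s711$chrom == "chrVIII", ]
  expect_identical(s711$level[1:3], c(2L, 3L, 4L))
  bounds <- c(s711$start, s711$end)
  expect_lte(min(abs(bounds - co$d_left)), win)  # 116.5 kb image
  expect_lte(min(abs(bounds - co$e_left)), win)  # 133.8 kb image

  rt721 <- fx_roundtrip("BYAT721")
  s721 <- rt721$analysis$segments
  left <- s721[s721$chrom == "chrVIII" & s721$end <= co$cup_l, "level"]
  expect_identical(left, c(2L, 3L, 5L))
  right <- s721[s721$chrom == "chrVIII" & s721$start >= co$cup_r & s721$end <= co$subtel, "level"]
  expect_identical(right, 1L)
  del <- rt721$analysis$deletions
  expect_identical(nrow(del), 1L)
  expect_true(del$terminal)
  expect_identical(del$evidence, "zero_marker_reads")
  expect_lte(abs(del$start - co$subtel), win)    # 549.5 kb image
  expect_identical(del$end, co$len_viii)         # runs to the telomere
})
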