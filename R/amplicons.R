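# Integer copy-number segmentation of profiles, decomposition of level
# staircases into amplicons with multiplicities, and terminal deletion
# calls backed by unique-marker evidence.

# Binary segmentation of a numeric series into piecewise-constant segments
# with a BIC-like penalty. Returns 0-based changepoint indices (positions
# AFTER which a new segment starts), on the windowed series.
binary_segment <- function(x, penalty_mult = 3) {
  n <- length(x)
  if (n < 4L) return(integer(0))
  sigma2 <- (stats::mad(diff(x)) / sqrt(2))^2
  if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- stats::var(x) / 10
  if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- 1e-12
  lambda <- penalty_mult * sigma2 * log(n)

  best_split <- function(lo, hi) {
    # best single changepoint of x[lo..hi] (1-based inclusive) by RSS gain
    m <- hi - lo + 1L
    if (m < 4L) return(NULL)
    xs <- x[lo:hi]
    cs <- cumsum(xs)
    cs2 <- cumsum(xs^2)
    k <- seq_len(m - 1L)
    rss_l <- cs2[k] - cs[k]^2 / k
    rss_r <- (cs2[m] - cs2[k]) - (cs[m] - cs[k])^2 / (m - k)
    rss0 <- cs2[m] - cs[m]^2 / m
    gain <- rss0 - (rss_l + rss_r)
    kbest <- which.max(gain)
    if (gain[kbest] > lambda) lo + kbest - 1L else NULL
  }

  cps <- integer(0)
  queue <- list(c(1L, n))
  while (length(queue) > 0L) {
    seg <- queue[[1L]]; queue <- queue[-1L]
    sp <- best_split(seg[1L], seg[2L])
    if (!is.null(sp)) {
      cps <- c(cps, sp)
      queue <- c(queue, list(c(seg[1L], sp)), list(c(sp + 1L, seg[2L])))
    }
  }
  sort(cps)
}

#' Segment a copy-number profile into integer levels
#'
#' Windowed means are segmented by binary changepoint detection with a
#' BIC-like penalty; each segment's level is the nearest integer of its
#' mean. Segments shorter than `min_segment_length` are merged into their
#' closest neighbor. The CUP array region (whose level is orders of
#' magnitude above the segmental scale) should be masked via `mask`.
#'
#' @param profile a `CopyNumberProfile`.
#' @param window analysis window in nt (windowed means are computed on
#'   non-overlapping windows of this size).
#' @param min_segment_length minimum segment length in nt.
#' @param mask named list of 0-based half-open intervals to exclude, e.g.
#'   `list(chrVIII = cbind(start, end))`.
#' @param max_integer_distance means farther than this from any integer are
#'   flagged non-integer rather than forced.
#' @param penalty_mult multiplier of the BIC-like changepoint penalty.
#' @return data.frame of `LevelSegment`s: `chrom`, `start`, `end` (0-based
#'   half-open), `level`, `mean_raw`, `non_integer`.
#' @export
segment_levels <- function(profile, window = 1500L, min_segment_length = 3L * window,
                           mask = NULL, max_integer_distance = 0.35,
                           penalty_mult = 3) {
  stopifnot(inherits(profile, "CopyNumberProfile"))
  out <- list()
  for (chrom in names(profile$values)) {
    v <- profile$values[[chrom]]
    if (length(v) == 0L) stop("empty profile")
    runs <- rbind(c(0L, length(v)))
    mk <- mask[[chrom]]
    if (!is.null(mk)) {
      # split [0, n) at the masked intervals
      bounds <- sort(unique(c(0L, as.vector(mk), length(v))))
      runs <- cbind(bounds[-length(bounds)], bounds[-1L])
      keep <- !apply(runs, 1L, function(r) {
        any(mk[, 1L] <= r[1L] & mk[, 2L] >= r[2L])
      })
      runs <- runs[keep, , drop = FALSE]
    }
    for (ri in seq_len(nrow(runs))) {
      lo <- runs[ri, 1L]; hi <- runs[ri, 2L]
      if (hi - lo < window) next
      nw <- (hi - lo) %/% window
      wm <- vapply(seq_len(nw), function(i) {
        mean(v[(lo + (i - 1L) * window + 1L):(lo + i * window)])
      }, numeric(1))
      cps <- binary_segment(wm, penalty_mult)
      starts_w <- c(0L, cps)
      ends_w <- c(cps, nw)
      segs <- data.frame(
        start = lo + starts_w * window,
        end = ifelse(ends_w == nw, hi, lo + ends_w * window),
        stringsAsFactors = FALSE
      )
      segs$mean_raw <- vapply(seq_len(nrow(segs)), function(i) {
        mean(wm[(starts_w[i] + 1L):ends_w[i]])
      }, numeric(1))
      # merge short segments into the neighbor with the closer mean
      repeat {
        len <- segs$end - segs$start
        short <- which(len < min_segment_length)
        if (length(short) == 0L || nrow(segs) == 1L) break
        i <- short[which.min(len[short])]
        nb <- c(if (i > 1L) i - 1L, if (i < nrow(segs)) i + 1L)
        nb <- nb[which.min(abs(segs$mean_raw[nb] - segs$mean_raw[i]))]
        j <- min(i, nb); k <- max(i, nb)
        w1 <- segs$end[j] - segs$start[j]; w2 <- segs$end[k] - segs$start[k]
        segs$mean_raw[j] <- (segs$mean_raw[j] * w1 + segs$mean_raw[k] * w2) / (w1 + w2)
        segs$end[j] <- segs$end[k]
        segs <- segs[-k, , drop = FALSE]
      }
      # merge adjacent segments that would round to the same level
      segs$level <- as.integer(floor(segs$mean_raw + 0.5))
      repeat {
        same <- which(diff(segs$level) == 0L)
        if (length(same) == 0L) break
        i <- same[1L]
        w1 <- segs$end[i] - segs$start[i]; w2 <- segs$end[i + 1L] - segs$start[i + 1L]
        segs$mean_raw[i] <- (segs$mean_raw[i] * w1 + segs$mean_raw[i + 1L] * w2) / (w1 + w2)
        segs$end[i] <- segs$end[i + 1L]
        segs <- segs[-(i + 1L), , drop = FALSE]
        segs$level <- as.integer(floor(segs$mean_raw + 0.5))
      }
      segs$chrom <- chrom
      segs$non_integer <- abs(segs$mean_raw - segs$level) > max_integer_distance
      out[[length(out) + 1L]] <- segs
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("chrom", "start", "end", "level", "mean_raw", "non_integer")]
}

# ---- staircase decomposition ----------------------------------------------

# Exact DP over open-interval weight multisets: states are integer
# partitions of the target height; transition cost = number of newly
# opened calls; secondary objective keeps calls open as long as possible
# (right-aligned nesting).
partitions_of <- function(n) {
  if (n == 0L) return(list(integer(0)))
  rec <- function(n, maxpart) {
    if (n == 0L) return(list(integer(0)))
    out <- list()
    for (p in seq.int(min(n, maxpart), 1L)) {
      for (rest in rec(n - p, p)) out[[length(out) + 1L]] <- c(p, rest)
    }
    out
  }
  rec(n, n)
}

# size of the maximal common sub-multiset of two sorted integer vectors
common_multiset <- function(a, b) {
  keep <- integer(0)
  bb <- b
  for (x in a) {
    j <- match(x, bb)
    if (!is.na(j)) { keep <- c(keep, x); bb <- bb[-j] }
  }
  keep
}

#' Decompose integer level segments into a minimal amplicon multiset
#'
#' Finds a minimum-cardinality multiset of intervals, each with an integer
#' `extra_copies >= 1`, whose pointwise sum equals `level - baseline`
#' across the chromosome. Among minimum-cardinality solutions, calls are
#' kept open as long as possible, which yields the right-aligned nesting
#' seen in the observed amplicon ladders. Deterministic.
#'
#' @param segments data.frame from [segment_levels()] (one chromosome or
#'   several; processed per chromosome).
#' @param baseline baseline ploidy (>= 1).
#' @param on_deletion `"error"` (default): any segment below baseline is an
#'   error (deletions are routed to [call_deletions()]); `"skip"`: such
#'   segments are excluded from the decomposition.
#' @return data.frame of `AmpliconCall`s: `name`, `chrom`, `start`, `end`,
#'   `extra_copies`.
#' @export
staircase_decompose <- function(segments, baseline, on_deletion = c("error", "skip")) {
  on_deletion <- match.arg(on_deletion)
  stopifnot(baseline >= 1L)
  out <- list()
  for (chrom in unique(segments$chrom)) {
    segs <- segments[segments$chrom == chrom, , drop = FALSE]
    segs <- segs[order(segs$start), , drop = FALSE]
    if (any(segs$level < baseline)) {
      if (on_deletion == "error") {
        stop("segment level below baseline on ", chrom,
             " (deletion; route to call_deletions)")
      }
      segs <- segs[segs$level >= baseline, , drop = FALSE]
    }
    if (nrow(segs) == 0L) next
    h <- segs$level - as.integer(baseline)
    n <- nrow(segs)
    if (all(h == 0L)) next

    # DP over segments; states = partitions (sorted desc) of h[i]
    states <- lapply(seq_len(n), function(i) partitions_of(h[i]))
    key <- function(p) if (length(p) == 0L) "0" else paste(p, collapse = ",")
    # cost[[i]] : named vector of (opens, -kept) lexicographic cost per state
    prev_tab <- NULL
    back <- vector("list", n)
    for (i in seq_len(n)) {
      tab <- list()
      for (si in seq_along(states[[i]])) {
        s <- states[[i]][[si]]
        if (i == 1L) {
          tab[[key(s)]] <- list(cost = c(length(s), 0), prev = NA, state = s)
        } else {
          best <- NULL
          for (pk in names(prev_tab)) {
            p <- prev_tab[[pk]]$state
            kept <- common_multiset(p, s)
            opens <- length(s) - length(kept)
            cost <- prev_tab[[pk]]$cost + c(opens, -length(kept))
            if (is.null(best) || cost[1L] < best$cost[1L] ||
                (cost[1L] == best$cost[1L] && cost[2L] < best$cost[2L])) {
              best <- list(cost = cost, prev = pk, state = s)
            }
          }
          tab[[key(s)]] <- best
        }
      }
      back[[i]] <- tab
      prev_tab <- tab
    }
    # choose the best final state, then walk back building intervals
    fin <- back[[n]]
    bk <- names(fin)[which.min(vapply(fin, function(e)
      e$cost[1L] * 1e6 + e$cost[2L], numeric(1)))]
    path <- character(n)
    path[n] <- bk
    for (i in seq.int(n, 2L)) path[i - 1L] <- back[[i]][[path[i]]]$prev

    # reconstruct call intervals: walk left to right keeping open calls
    calls <- list()   # each: list(weight, start_seg)
    open <- list()
    for (i in seq_len(n)) {
      s <- back[[i]][[path[i]]]$state
      open_w <- vapply(open, `[[`, numeric(1), "weight")
      kept_w <- common_multiset(sort(open_w, decreasing = TRUE),
                                sort(s, decreasing = TRUE))
      # close open calls not kept (match larger weights first)
      new_open <- list()
      pool <- kept_w
      for (oc in open[order(-open_w)]) {
        j <- match(oc$weight, pool)
        if (!is.na(j)) { new_open[[length(new_open) + 1L]] <- oc; pool <- pool[-j] }
        else {
          oc$end_seg <- i - 1L
          calls[[length(calls) + 1L]] <- oc
        }
      }
      open <- new_open
      # open new calls for the remainder of s
      rem <- s
      for (w in vapply(open, `[[`, numeric(1), "weight")) {
        j <- match(w, rem); if (!is.na(j)) rem <- rem[-j]
      }
      for (w in rem) open[[length(open) + 1L]] <- list(weight = w, start_seg = i)
    }
    for (oc in open) { oc$end_seg <- n; calls[[length(calls) + 1L]] <- oc }
    calls <- Filter(function(oc) oc$weight > 0, calls)
    if (length(calls) > 0L) {
      df <- data.frame(
        chrom = chrom,
        start = segs$start[vapply(calls, `[[`, numeric(1), "start_seg")],
        end = segs$end[vapply(calls, `[[`, numeric(1), "end_seg")],
        extra_copies = as.integer(vapply(calls, `[[`, numeric(1), "weight")),
        stringsAsFactors = FALSE
      )
      df <- df[order(df$start, -df$end, df$extra_copies), , drop = FALSE]
      out[[length(out) + 1L]] <- df
    }
  }
  if (length(out) == 0L) {
    return(data.frame(name = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      extra_copies = integer(0)))
  }
  res <- do.call(rbind, out)
  res$name <- paste0("amplicon_", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("name", "chrom", "start", "end", "extra_copies")]
}

#' Call terminal deletions with unique-marker evidence
#'
#' Terminal segments whose integer level is below 1 are deletion
#' candidates. A candidate is confirmed by `zero_marker_reads` when a
#' region-unique marker gene inside it has zero covering reads (the
#' decisive evidence when a sequence-identical homologous twin region
#' inflates apparent coverage); otherwise the call rests on
#' `sub_unit_coverage` alone.
#'
#' @param segments data.frame from [segment_levels()].
#' @param ref a `ReferenceGenome`.
#' @param alignments an `AlignmentSet`.
#' @return data.frame of `DeletionCall`s: `chrom`, `start`, `end`,
#'   `terminal`, `evidence`.
#' @export
call_deletions <- function(segments, ref, alignments) {
  aln <- alignments$alignments
  w <- nchar(alignments$reads$seq[match(aln$id, alignments$reads$id)])
  out <- list()
  for (chrom in unique(segments$chrom)) {
    segs <- segments[segments$chrom == chrom, , drop = FALSE]
    segs <- segs[order(segs$start), , drop = FALSE]
    n <- nrow(segs)
    chrom_len <- nchar(ref$chromosomes[[chrom]])
    for (side in c("first", "last")) {
      # gather the maximal terminal run of sub-1 segments
      idx <- if (side == "first") seq_len(n) else rev(seq_len(n))
      run <- integer(0)
      for (i in idx) {
        if (segs$level[i] < 1L) run <- c(run, i) else break
      }
      if (length(run) == 0L) next
      start <- min(segs$start[run]); end <- max(segs$end[run])
      # terminal when the run reaches the chromosome end up to a masked
      # margin (telomeric runs are excluded from segmentation); terminal
      # calls extend to the physical end
      terminal <- (side == "first" && start <= 600L) ||
        (side == "last" && end >= chrom_len - 600L)
      if (terminal && side == "first") start <- 0L
      if (terminal && side == "last") end <- chrom_len
      # unique markers inside the candidate region
      f <- ref$features
      mk <- f[f$class == "marker_gene" & f$chrom == chrom &
                f$start >= start & f$end <= end, , drop = FALSE]
      evidence <- "sub_unit_coverage"
      if (nrow(mk) > 0L) {
        rows <- which(aln$chrom == chrom)
        for (mi in seq_len(nrow(mk))) {
          # a marker read must overlap the marker by an informative amount
          nreads <- sum(pmin(aln$pos[rows] + w[rows], mk$end[mi]) -
                          pmax(aln$pos[rows], mk$start[mi]) >= 10L)
          if (nreads == 0L) { evidence <- "zero_marker_reads"; break }
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = start, end = end, terminal = terminal,
        evidence = evidence, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), terminal = logical(0),
                      evidence = character(0)))
  }
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}
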