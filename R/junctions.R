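# Breakpoint discovery from unmapped reads: greedy de Bruijn assembly into
# junction contigs, classification of the junction geometry against the
# reference (strand-switch quasi-palindrome, inverted microhomology,
# telomere fusion, or delta-repeat ambiguous), and per-cell junction copy
# number from spanning-read counts.

#' Collect unmapped reads
#' @param alignments an `AlignmentSet`.
#' @return data.frame `id`, `seq` of exactly the reads flagged unmapped.
#' @export
collect_unmapped <- function(alignments) {
  alignments$unmapped
}

# Unitigs of the de Bruijn graph of `seqs` at word size k, after dropping
# k-mers seen fewer than min_count times (tip/error clipping).
debruijn_unitigs <- function(seqs, k, min_count = 2L) {
  seqs <- seqs[nchar(seqs) >= k]
  if (length(seqs) == 0L) return(character(0))
  km <- unlist(lapply(seqs, function(s) {
    n <- nchar(s) - k + 1L
    substring(s, seq_len(n), seq_len(n) + k - 1L)
  }), use.names = FALSE)
  km <- km[!grepl("[^ACGT]", km)]
  tab <- table(km)
  kmers <- names(tab)[tab >= min_count]
  if (length(kmers) == 0L) return(character(0))
  pre <- substring(kmers, 1L, k - 1L)
  suf <- substring(kmers, 2L, k)
  pre_map <- split(seq_along(kmers), pre)
  succ_of <- function(i) pre_map[[suf[i]]] %||% integer(0)
  suf_map <- split(seq_along(kmers), suf)
  pred_of <- function(i) suf_map[[pre[i]]] %||% integer(0)

  used <- logical(length(kmers))
  contigs <- character(0)
  comp_id <- integer(length(kmers))
  walk <- function(start) {
    path <- start
    used[start] <<- TRUE
    i <- start
    repeat {
      nxt <- succ_of(i)
      nxt <- nxt[!used[nxt]]
      if (length(succ_of(i)) != 1L) break
      j <- succ_of(i)
      if (used[j] || length(pred_of(j)) != 1L) break
      path <- c(path, j)
      used[j] <<- TRUE
      i <- j
    }
    path
  }
  starts <- which(vapply(seq_along(kmers), function(i) {
    p <- pred_of(i)
    length(p) != 1L || length(succ_of(p)) > 1L
  }, logical(1)))
  order_all <- c(starts, setdiff(seq_along(kmers), starts))
  for (s in order_all) {
    if (used[s]) next
    path <- walk(s)
    contigs <- c(contigs, paste0(kmers[path[1L]],
                                 paste(substring(kmers[path[-1L]], k, k), collapse = "")))
  }
  contigs
}

#' Assemble unmapped reads into junction contigs
#'
#' Greedy de Bruijn assembly is attempted at each word size in `k_list`
#' (error k-mers are clipped at depth < 2); the read pool is augmented with
#' its reverse complements, and contigs contained in a longer contig (or in
#' its reverse complement) are collapsed. Support is the number of pool
#' reads whose best placement covers more than half of the read on the
#' contig, so the normalized support
#' `support_copies = reads * read_length / ((contig overlap window) * haploid_depth)`
#' estimates the junction's per-cell copy number; contigs at or below 0.5
#' copies per genome are discarded.
#'
#' @param pool data.frame `id`, `seq` from [collect_unmapped()].
#' @param haploid_depth raw depth corresponding to one copy per cell
#'   (e.g. `profile$median_depth`).
#' @param k_list word sizes to try.
#' @param min_support_copies contig-support threshold (copies per genome).
#' @param min_length minimum contig length to report.
#' @return data.frame of `JunctionContig`s: `contig`, `length`,
#'   `supporting_read_count`, `support_copies`.
#' @export
assemble_junctions <- function(pool, haploid_depth, k_list = c(21L, 51L, 71L),
                               min_support_copies = 0.5, min_length = 120L) {
  if (nrow(pool) == 0L) {
    return(data.frame(contig = character(0), length = integer(0),
                      supporting_read_count = integer(0),
                      support_copies = numeric(0)))
  }
  seqs <- c(pool$seq, revcomp_many(pool$seq))
  contigs <- character(0)
  for (k in k_list) {
    contigs <- c(contigs, debruijn_unitigs(seqs, k))
  }
  # canonical orientation, then containment dedupe (longest kept)
  canon <- vapply(contigs, function(s) min(s, revcomp(s)), "")
  canon <- unique(canon)
  canon <- canon[order(-nchar(canon))]
  keep <- logical(length(canon))
  for (i in seq_along(canon)) {
    contained <- FALSE
    if (i > 1L) {
      for (j in which(keep)) {
        if (grepl(canon[i], canon[j], fixed = TRUE) ||
            grepl(revcomp(canon[i]), canon[j], fixed = TRUE)) {
          contained <- TRUE
          break
        }
      }
    }
    keep[i] <- !contained
  }
  canon <- canon[keep]
  canon <- canon[nchar(canon) >= min_length]
  if (length(canon) == 0L) {
    return(data.frame(contig = character(0), length = integer(0),
                      supporting_read_count = integer(0),
                      support_copies = numeric(0)))
  }
  L <- max(nchar(pool$seq))
  clen <- nchar(canon)
  sup <- integer(length(canon))
  wins <- numeric(length(canon))
  for (i in seq_along(canon)) {
    ov <- contig_read_overlaps(pool$seq, canon[i])
    good <- which(ov$good)
    sup[i] <- length(good)
    # normalization window: the span of observed supporting placements
    # (unmapped reads concentrate at the junction, so the contig length
    # itself would overestimate the sampling window)
    wins[i] <- if (length(good) == 0L) 1 else {
      max(1, max(ov$start[good] + L) - min(ov$start[good]) - L + 1)
    }
  }
  res <- data.frame(contig = unname(canon), length = clen,
                    supporting_read_count = sup,
                    support_copies = sup * L / (wins * haploid_depth),
                    stringsAsFactors = FALSE)
  res <- res[res$support_copies > min_support_copies, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Best ungapped placement of each read on a contig (either strand),
# anchored by an exact terminal k-mer of the read; returns per-read
# placement start (0-based, may be negative for overhanging reads),
# overlap length, mismatch count within the overlap, and whether the
# placement is a "good" support (majority of the read on the contig,
# <= 2 mismatches).
contig_read_overlaps <- function(read_seqs, contig, k = 21L, max_mm = 2L) {
  C <- nchar(contig)
  n <- length(read_seqs)
  res <- data.frame(start = rep(NA_integer_, n), overlap = 0L,
                    mm = NA_integer_, strand = NA_character_,
                    good = FALSE)
  for (i in seq_len(n)) {
    best <- NULL
    for (strand in c("+", "-")) {
      s <- if (strand == "+") read_seqs[i] else revcomp(read_seqs[i])
      L <- nchar(s)
      if (L < k) next
      for (off in c(0L, L - k)) {
        seed <- substr(s, off + 1L, off + k)
        m <- gregexpr(seed, contig, fixed = TRUE)[[1L]]
        if (m[1L] == -1L) next
        for (p in as.integer(m)) {
          start <- p - 1L - off # 0-based read start on contig
          a <- max(0L, -start)          # first read index - 1 in overlap
          b <- min(L, C - start) - 1L   # last read index - 1
          if (b < a) next
          ov <- b - a + 1L
          mm <- count_mismatch_pairs(substr(s, a + 1L, b + 1L),
                                     substr(contig, start + a + 1L, start + b + 1L))
          if (is.null(best) || ov - 10L * mm > best$score) {
            best <- list(score = ov - 10L * mm, start = start, overlap = ov,
                         mm = mm, strand = strand, L = L)
          }
        }
      }
      if (!is.null(best) && best$overlap == nchar(s) && best$mm == 0L) break
    }
    if (!is.null(best)) {
      res$start[i] <- best$start
      res$overlap[i] <- best$overlap
      res$mm[i] <- best$mm
      res$strand[i] <- best$strand
      res$good[i] <- best$overlap > best$L / 2 && best$mm <= max_mm
    }
  }
  res
}

# Shared post-processing of candidate arm placements: keep near-maximal
# extensions, collapse CUP repeat-unit translates to the leftmost copy,
# flag multi-placements that fall in dispersed delta elements.
finish_arm <- function(placements, qry_len, ref) {
  if (length(placements) == 0L) return(NULL)
  exts <- vapply(placements, `[[`, numeric(1), "ext")
  best <- placements[exts >= max(exts) - 2L]
  if (length(best) > 1L) {
    ch <- vapply(best, `[[`, "", "chrom")
    st <- vapply(best, `[[`, numeric(1), "start")
    units <- ref$features[ref$features$class == "repeat_unit", , drop = FALSE]
    in_unit <- vapply(seq_along(best), function(i) {
      any(units$chrom == ch[i] & st[i] >= units$start - qry_len &
            st[i] < units$end)
    }, logical(1))
    if (all(in_unit) && length(unique(ch)) == 1L &&
        all((st - min(st)) %% ref$layout$unit_length == 0)) {
      best <- best[which.min(st)]
    }
  }
  deltas <- ref$features[ref$features$class == "delta", , drop = FALSE]
  in_delta <- vapply(best, function(b) {
    any(deltas$chrom == b$chrom & b$start < deltas$end &
          b$start + b$ext > deltas$start)
  }, logical(1))
  first <- best[[1L]]
  first$n_best <- length(best)
  first$ambiguous_delta <- length(best) > 1L && any(in_delta)
  first
}

# Mismatch-tolerant maximal extension along a match/mismatch vector:
# returns the largest prefix length with <= mm_budget mismatches whose
# last position is anchored by 4 consecutive matches, or 0.
anchored_extent <- function(mv, mm_budget, k) {
  mm_cum <- cumsum(!mv)
  ok <- which(mm_cum <= mm_budget & mv)
  anchored <- ok[ok <= 4L | (mv[pmax(1L, ok - 1L)] & mv[pmax(1L, ok - 2L)] &
                               mv[pmax(1L, ok - 3L)])]
  if (length(anchored) == 0L || max(anchored) < k) return(0L)
  max(anchored)
}

# Maximal mismatch-tolerant extension of `qry` from its START against every
# forward-strand occurrence of its leading k-mer in the reference.
map_arm_fwd <- function(qry, ref, k = 21L, mm_budget = 2L) {
  if (nchar(qry) < k) return(NULL)
  seed <- substr(qry, 1L, k)
  placements <- list()
  for (chrom in names(ref$chromosomes)) {
    subj <- ref$chromosomes[[chrom]]
    m <- gregexpr(seed, subj, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) next
    for (p in as.integer(m)) {
      start0 <- p - 1L
      maxext <- min(nchar(qry), nchar(subj) - start0)
      mv <- match_vector(substr(qry, 1L, maxext),
                         substr(subj, start0 + 1L, start0 + maxext))
      ext <- anchored_extent(mv, mm_budget, k)
      if (ext == 0L) next
      placements[[length(placements) + 1L]] <-
        list(chrom = chrom, start = start0, ext = ext,
             mm = sum(!mv[seq_len(ext)]))
    }
  }
  finish_arm(placements, nchar(qry), ref)
}

rev_str <- function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")

# Maximal extension of `qry` from its END (leftward) against every
# forward-strand occurrence of its trailing k-mer. `start` in the result
# is the leftmost reference position covered by the arm.
map_arm_bwd <- function(qry, ref, k = 21L, mm_budget = 2L) {
  L <- nchar(qry)
  if (L < k) return(NULL)
  seed <- substr(qry, L - k + 1L, L)
  placements <- list()
  for (chrom in names(ref$chromosomes)) {
    subj <- ref$chromosomes[[chrom]]
    m <- gregexpr(seed, subj, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) next
    for (p in as.integer(m)) {
      end0 <- p - 1L + k # 0-based exclusive ref end of the seed
      n_avail <- min(L, end0)
      a <- rev_str(substr(qry, L - n_avail + 1L, L))
      b <- rev_str(substr(subj, end0 - n_avail + 1L, end0))
      ext <- anchored_extent(match_vector(a, b), mm_budget, k)
      if (ext == 0L) next
      placements[[length(placements) + 1L]] <-
        list(chrom = chrom, start = end0 - ext, ext = ext,
             mm = sum(!match_vector(substr(a, 1L, ext), substr(b, 1L, ext))))
    }
  }
  finish_arm(placements, L, ref)
}

empty_junction_call <- function(class = "unclassified") {
  data.frame(class = class, chrom = NA_character_, pos1 = NA_integer_,
             pos2 = NA_integer_, loop_length = NA_integer_,
             microhomology_length = NA_integer_,
             reference_spacing = NA_integer_,
             mismatches_in_palindrome = NA_integer_,
             contig_break = NA_integer_, stringsAsFactors = FALSE)
}

#' Classify a junction contig against the reference
#'
#' Aligns the contig prefix and suffix to the reference on both strands
#' and reports the junction geometry:
#' \describe{
#'   \item{strand_switch_palindrome}{prefix and suffix map to the same
#'     reference region on opposite strands; the unaligned middle is the
#'     single-strand loop (`loop_length`).}
#'   \item{inverted_microhomology}{the switch occurs across two inverted
#'     near-identical motifs; reports the motif length and their
#'     `reference_spacing`.}
#'   \item{telomere_fusion}{one side is a telomeric `(C1-3A)n` run (>= 15
#'     nt); the focal coordinate is the first joined reference base.}
#'   \item{repeat_ambiguous}{an arm maps equally well to two or more
#'     dispersed delta-element copies; reported but unresolvable.}
#' }
#'
#' @param contig contig sequence.
#' @param ref a `ReferenceGenome`.
#' @return one-row data.frame (a `JunctionCall` without copy number):
#'   `class`, `chrom`, `pos1`, `pos2` (0-based focal coordinates),
#'   `loop_length`, `microhomology_length`, `reference_spacing`,
#'   `mismatches_in_palindrome`, `contig_break` (0-based offset of the
#'   junction point on the contig as given).
#' @export
classify_junction <- function(contig, ref) {
  L <- nchar(contig)
  rc <- revcomp(contig)

  # telomere fusion: a telomeric run anchored at one end
  for (orient in c("fwd", "rc")) {
    s <- if (orient == "fwd") contig else rc
    t_len <- telomeric_anchor(s, "left")
    if (t_len > 0L) {
      rest <- substr(s, t_len + 1L, nchar(s))
      if (telomeric_anchor(s, "right") > 0L && nchar(rest) < 30L) {
        return(empty_junction_call("unclassified"))
      }
      arm <- map_arm_fwd(rest, ref)
      if (!is.null(arm)) {
        # left-align the fusion point: the anchor may have absorbed
        # reference bases that happen to continue the telomeric pattern
        chromseq <- ref$chromosomes[[arm$chrom]]
        p <- arm$start
        t <- t_len
        while (t > 0L && p > 0L &&
               substr(chromseq, p, p) == substr(s, t, t)) {
          p <- p - 1L
          t <- t - 1L
        }
        out <- empty_junction_call("telomere_fusion")
        if (arm$ambiguous_delta) out$class <- "repeat_ambiguous"
        out$chrom <- arm$chrom
        out$pos1 <- p
        out$contig_break <- if (orient == "fwd") t else L - t
        return(out)
      }
      return(empty_junction_call("unclassified"))
    }
  }
  deltas <- ref$features[ref$features$class == "delta", , drop = FALSE]
  near_delta <- function(chrom, pos) {
    any(deltas$chrom == chrom & pos >= deltas$start - 10L &
          pos <= deltas$end + 10L)
  }

  pre_p <- map_arm_fwd(contig, ref)   # prefix on + strand
  suf_m <- map_arm_fwd(rc, ref)       # suffix on - strand (rc prefix on +)
  suf_p <- map_arm_bwd(contig, ref)   # suffix on + strand
  pre_m <- map_arm_bwd(rc, ref)       # prefix on - strand (rc suffix on +)
  full <- function(a) !is.null(a) && a$ext == L
  if (full(pre_p) || full(suf_m) || full(suf_p) || full(pre_m)) {
    return(empty_junction_call("unclassified")) # fully mapping: no junction
  }

  # inverted junction, prefix(+) / suffix(-): arms end at the junction
  if (!is.null(pre_p) && !is.null(suf_m)) {
    A <- pre_p; B <- suf_m
    if (A$ambiguous_delta || B$ambiguous_delta) {
      out <- empty_junction_call("repeat_ambiguous")
      out$chrom <- A$chrom
      out$pos1 <- A$start + A$ext
      out$contig_break <- A$ext
      return(out)
    }
    gap <- L - A$ext - B$ext           # >0: unaligned middle; <0: overlap
    bA <- A$start + A$ext              # prefix reference end (0-based excl)
    bB <- B$start + B$ext              # suffix (rc-prefix) reference end
    mh <- -gap
    if (A$chrom == B$chrom && mh >= 8L && (bA - mh) - bB > 0L) {
      out <- empty_junction_call("inverted_microhomology")
      out$chrom <- A$chrom
      out$pos1 <- bA - mh
      out$pos2 <- bB
      out$microhomology_length <- mh
      out$reference_spacing <- (bA - mh) - bB
      out$mismatches_in_palindrome <- A$mm + B$mm
      out$contig_break <- A$ext
      return(out)
    }
    if (A$chrom == B$chrom && gap >= 0L && abs(bA - bB) <= 5L) {
      out <- empty_junction_call("strand_switch_palindrome")
      out$chrom <- A$chrom
      out$pos1 <- bA
      out$pos2 <- bB
      out$loop_length <- gap
      out$mismatches_in_palindrome <- A$mm + B$mm
      out$contig_break <- A$ext
      return(out)
    }
    # inverted switch whose arms end in dispersed delta copies: geometry
    # is unresolvable even when each arm anchors in unique flanking
    # sequence
    if (near_delta(A$chrom, bA) || near_delta(B$chrom, bB)) {
      out <- empty_junction_call("repeat_ambiguous")
      out$chrom <- A$chrom
      out$pos1 <- bA
      out$pos2 <- bB
      out$contig_break <- A$ext
      return(out)
    }
  }

  # inverted junction, prefix(-) / suffix(+): arms START at the junction
  if (!is.null(pre_m) && !is.null(suf_p)) {
    A <- pre_m; B <- suf_p
    if (A$ambiguous_delta || B$ambiguous_delta) {
      out <- empty_junction_call("repeat_ambiguous")
      out$chrom <- B$chrom
      out$pos1 <- B$start
      out$contig_break <- L - B$ext
      return(out)
    }
    gap <- L - A$ext - B$ext
    aA <- A$start                      # prefix(-) leftmost ref position
    aB <- B$start                      # suffix(+) leftmost ref position
    mh <- -gap
    if (A$chrom == B$chrom && mh >= 8L && (aB - mh) - aA > 0L) {
      out <- empty_junction_call("inverted_microhomology")
      out$chrom <- A$chrom
      out$pos1 <- aA
      out$pos2 <- aB - mh
      out$microhomology_length <- mh
      out$reference_spacing <- (aB - mh) - aA - A$ext + mh
      out$mismatches_in_palindrome <- A$mm + B$mm
      out$contig_break <- A$ext
      return(out)
    }
    if (A$chrom == B$chrom && gap >= 0L && abs(aA - aB) <= 5L) {
      out <- empty_junction_call("strand_switch_palindrome")
      out$chrom <- A$chrom
      out$pos1 <- aA
      out$pos2 <- aB
      out$loop_length <- gap
      out$mismatches_in_palindrome <- A$mm + B$mm
      out$contig_break <- A$ext
      return(out)
    }
    if (near_delta(A$chrom, aA) || near_delta(B$chrom, aB)) {
      out <- empty_junction_call("repeat_ambiguous")
      out$chrom <- A$chrom
      out$pos1 <- aA
      out$pos2 <- aB
      out$contig_break <- A$ext
      return(out)
    }
  }

  # colinear junction, prefix(+) / suffix(+): e.g. chimeric co-oriented
  # delta-delta fusions
  if (!is.null(pre_p) && !is.null(suf_p)) {
    A <- pre_p; S <- suf_p
    bA <- A$start + A$ext
    aS <- S$start
    colinear_novel <- !(A$chrom == S$chrom && abs(aS - bA) <= 5L &&
                          L - A$ext - S$ext <= 0L)
    if (colinear_novel) {
      cls <- if (A$ambiguous_delta || S$ambiguous_delta ||
                 near_delta(A$chrom, bA) || near_delta(S$chrom, aS)) {
        "repeat_ambiguous"
      } else {
        "unclassified"
      }
      out <- empty_junction_call(cls)
      out$chrom <- A$chrom
      out$pos1 <- bA
      out$pos2 <- aS
      out$contig_break <- A$ext
      return(out)
    }
  }
  empty_junction_call("unclassified")
}

#' Per-cell copy number of a junction from spanning reads
#'
#' Counts reads whose placement on the contig covers the junction point
#' with at least `margin` nt on both sides, and converts the count to
#' copies per cell:
#' `copies = n_spanning * read_length / (window * haploid_depth)` with
#' `window = read_length - 2 * margin + 1` spanning start positions.
#' Candidate reads are taken from the full read set (not only the unmapped
#' pool): reads that straddle the junction by only a little beyond
#' `margin` are often force-placed on the reference with mismatches, and
#' skipping them would bias the estimate downward.
#'
#' @param contig contig sequence.
#' @param contig_break 0-based junction offset on the contig (from
#'   [classify_junction()]).
#' @param reads data.frame `id`, `seq` (the full read set, or the unmapped
#'   pool).
#' @param haploid_depth raw depth of one copy per cell.
#' @param margin minimum anchored nt on each side of the junction.
#' @param shared_left length of reference-shared sequence immediately left
#'   of the junction point on the contig (the microhomology length for
#'   inverted-microhomology junctions); the left anchor must clear it,
#'   since reads that only touch the shared motif are not junction
#'   evidence.
#' @return numeric copies-per-cell estimate.
#' @export
junction_copy_number <- function(contig, contig_break, reads, haploid_depth,
                                 margin = 10L, shared_left = 0L) {
  if (haploid_depth <= 0) stop("haploid depth must be positive")
  if (nrow(reads) == 0L) return(0)
  cand <- junction_candidate_reads(contig, contig_break, reads)
  if (length(cand) == 0L) return(0)
  ov <- contig_read_overlaps(reads$seq[cand], contig)
  L <- max(nchar(reads$seq))
  span <- !is.na(ov$start) & ov$mm <= 2L &
    ov$start + margin <= contig_break - shared_left &
    ov$start + L - margin >= contig_break
  W <- L - 2L * margin - shared_left + 1L
  sum(span) * L / (W * haploid_depth)
}

# Indices of reads containing (on either strand) an exact 21-mer from the
# window around the junction point of the contig; a cheap census
# pre-filter over the full read set.
junction_candidate_reads <- function(contig, contig_break, reads, k = 21L,
                                     halfwin = 40L) {
  lo <- max(1L, contig_break - halfwin)
  hi <- min(nchar(contig), contig_break + halfwin)
  win <- substr(contig, lo, hi)
  n <- nchar(win) - k + 1L
  if (n < 1L) return(integer(0))
  kmers <- unique(substring(win, seq_len(n), seq_len(n) + k - 1L))
  kmers <- unique(c(kmers, revcomp_many(kmers)))
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  subject <- Biostrings::DNAString(paste(reads$seq, collapse = "N"))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  m <- Biostrings::matchPDict(pd, subject)
  pos <- unlist(Biostrings::startIndex(m), use.names = FALSE)
  if (length(pos) == 0L) return(integer(0))
  # map concatenated positions back to read indices
  lens <- nchar(reads$seq)
  starts <- cumsum(c(0L, lens[-length(lens)] + 1L)) # 0-based read starts
  sort(unique(findInterval(pos - 1L, starts)))
}

#' Discover and classify all junctions in one pass
#'
#' Convenience wrapper: collects unmapped reads, assembles junction
#' contigs, classifies each, and attaches spanning-read copy numbers and
#' contig support.
#'
#' @param alignments an `AlignmentSet`.
#' @param haploid_depth raw depth of one copy per cell.
#' @param ref a `ReferenceGenome`.
#' @param k_list assembly word sizes.
#' @return data.frame of `JunctionCall`s (one row per reported contig).
#' @export
find_junctions <- function(alignments, haploid_depth, ref,
                           k_list = c(21L, 51L, 71L)) {
  pool <- collect_unmapped(alignments)
  contigs <- assemble_junctions(pool, haploid_depth, k_list)
  calls <- list()
  for (i in seq_len(nrow(contigs))) {
    call <- classify_junction(contigs$contig[i], ref)
    shared <- if (call$class == "inverted_microhomology") {
      call$microhomology_length
    } else {
      0L
    }
    call$copy_number <- if (!is.na(call$contig_break)) {
      junction_copy_number(contigs$contig[i], call$contig_break,
                           alignments$reads, haploid_depth,
                           shared_left = shared)
    } else {
      contigs$support_copies[i]
    }
    call$supporting_read_count <- contigs$supporting_read_count[i]
    call$support_copies <- contigs$support_copies[i]
    call$contig <- contigs$contig[i]
    calls[[i]] <- call
  }
  if (length(calls) == 0L) {
    out <- empty_junction_call()[0, ]
    out$copy_number <- numeric(0)
    out$supporting_read_count <- integer(0)
    out$support_copies <- numeric(0)
    out$contig <- character(0)
    return(out)
  }
  res <- do.call(rbind, calls)
  # a junction assembled more than once (e.g. at different word sizes, or
  # from reads of its two strands) is reported once, at its best support
  res <- res[order(-res$supporting_read_count), , drop = FALSE]
  res <- res[!duplicated(res[, c("class", "chrom", "pos1")]), , drop = FALSE]
  rownames(res) <- NULL
  res
}
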