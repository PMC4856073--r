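# Read mapping (exact multi-pattern stage + seeded mismatch extension),
# per-base depth, copies-per-cell normalization and smoothing.

#' Map reads to the reference
#'
#' Each read is assigned its best ungapped placement: an exact multi-pattern
#' pass (both strands) resolves error-free reads, and remaining reads are
#' placed by k-mer seeding plus full-length mismatch counting. Reads whose
#' best placement exceeds `max_mismatch_frac * read_length` mismatches are
#' reported unmapped. Ties among equal-score placements (delta elements,
#' CUP repeat units, shared subtelomeres) are resolved by the multi-map
#' policy: `"first"` keeps the first placement in chromosome-then-coordinate
#' order with weight 1 (deterministic, reproduces the shared-subtelomere
#' mis-mapping artifact); `"split"` emits every tied placement with weight
#' 1/k.
#'
#' @param reads a `ReadSet` or data.frame with columns `id`, `seq`.
#' @param ref a `ReferenceGenome`.
#' @param max_mismatch_frac maximum mismatch fraction for a mapped read.
#' @param seed_k seed k-mer length.
#' @param policy `"first"` or `"split"`.
#' @return an `AlignmentSet`: list with `alignments` (data.frame `id`,
#'   `chrom`, `pos` 0-based, `strand`, `mismatches`, `weight`, `ambiguous`),
#'   `unmapped` (data.frame `id`, `seq`), `reads`, `policy`.
#' @export
map_reads <- function(reads, ref, max_mismatch_frac = 0.1, seed_k = 21L,
                      policy = c("first", "split")) {
  policy <- match.arg(policy)
  if (inherits(reads, "ReadSet")) reads <- reads$reads
  stopifnot(all(c("id", "seq") %in% names(reads)))
  chrom_names <- names(ref$chromosomes)
  subjects <- lapply(ref$chromosomes, Biostrings::DNAString)
  chrom_len <- vapply(ref$chromosomes, nchar, integer(1))

  all_hits <- vector("list", 0L)
  unmapped <- list()

  widths <- nchar(reads$seq)
  for (w in sort(unique(widths))) {
    if (w < seed_k) stop("read shorter than seed k-mer")
    sel <- which(widths == w)
    rseq <- reads$seq[sel]
    fwd <- Biostrings::DNAStringSet(rseq)
    rev <- Biostrings::reverseComplement(fwd)
    rseq_rc <- as.character(rev)
    max_mm <- as.integer(floor(max_mismatch_frac * w))

    exact_hits <- data.table::rbindlist(lapply(seq_along(chrom_names), function(ci) {
      out <- list()
      for (st in c("+", "-")) {
        pd <- Biostrings::PDict(if (st == "+") fwd else rev)
        m <- Biostrings::matchPDict(pd, subjects[[ci]])
        si <- Biostrings::startIndex(m)
        nh <- lengths(si)
        if (sum(nh) == 0L) next
        out[[st]] <- data.table::data.table(
          ridx = rep(sel, nh),
          chrom_i = ci,
          pos = unlist(si[nh > 0L], use.names = FALSE) - 1L,
          strand = st, mm = 0L
        )
      }
      data.table::rbindlist(out)
    }))
    resolved <- unique(exact_hits$ridx)
    todo <- setdiff(sel, resolved)

    seed_hits <- NULL
    if (length(todo) > 0L) {
      idx_in_sel <- match(todo, sel)
      offs <- unique(c(0L, (w - seed_k) %/% 2L, w - seed_k))
      cand <- list()
      for (st in c("+", "-")) {
        rs <- if (st == "+") rseq[idx_in_sel] else rseq_rc[idx_in_sel]
        for (o in offs) {
          seeds <- substring(rs, o + 1L, o + seed_k)
          keep <- !grepl("[^ACGT]", seeds)
          if (!any(keep)) next
          pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds[keep]))
          kidx <- which(keep)
          for (ci in seq_along(chrom_names)) {
            m <- Biostrings::matchPDict(pd, subjects[[ci]])
            si <- Biostrings::startIndex(m)
            nh <- lengths(si)
            if (sum(nh) == 0L) next
            cand[[length(cand) + 1L]] <- data.table::data.table(
              ridx = rep(todo[kidx], nh),
              chrom_i = ci,
              pos = unlist(si[nh > 0L], use.names = FALSE) - 1L - o,
              strand = st
            )
          }
        }
      }
      if (length(cand) > 0L) {
        cc <- unique(data.table::rbindlist(cand))
        cc <- cc[cc$pos >= 0L & cc$pos + w <= chrom_len[cc$chrom_i], ]
        if (nrow(cc) > 0L) {
          # count mismatches for each candidate placement
          mm <- integer(nrow(cc))
          for (ci in unique(cc$chrom_i)) {
            rows <- which(cc$chrom_i == ci)
            refseq <- substring(ref$chromosomes[[ci]], cc$pos[rows] + 1L,
                                cc$pos[rows] + w)
            ii <- match(cc$ridx[rows], sel)
            qry <- ifelse(cc$strand[rows] == "+", rseq[ii], rseq_rc[ii])
            mm[rows] <- count_mismatch_pairs(qry, refseq)
          }
          cc$mm <- mm
          cc <- cc[!is.na(cc$mm) & cc$mm <= max_mm, ]
          if (nrow(cc) > 0L) {
            best <- cc[, list(bmm = min(mm)), by = "ridx"]
            cc <- merge(cc, best, by = "ridx")
            seed_hits <- cc[cc$mm == cc$bmm,
                            c("ridx", "chrom_i", "pos", "strand", "mm")]
          }
        }
      }
    }

    hits_w <- data.table::rbindlist(list(exact_hits, seed_hits), use.names = TRUE,
                                    fill = TRUE)
    mapped_idx <- unique(hits_w$ridx)
    unmapped[[length(unmapped) + 1L]] <- setdiff(sel, mapped_idx)
    all_hits[[length(all_hits) + 1L]] <- hits_w
  }

  hits <- data.table::rbindlist(all_hits)
  un_idx <- sort(unlist(unmapped))
  if (nrow(hits) == 0L) {
    aln <- data.frame(id = character(0), chrom = character(0), pos = integer(0),
                      strand = character(0), mismatches = integer(0),
                      weight = numeric(0), ambiguous = logical(0))
  } else {
    data.table::setorderv(hits, c("ridx", "chrom_i", "pos", "strand"))
    nplace <- hits[, list(k = .N), by = "ridx"]
    hits <- merge(hits, nplace, by = "ridx", sort = FALSE)
    if (policy == "first") {
      hits <- hits[!duplicated(hits$ridx), ]
      hits$weight <- 1
    } else {
      hits$weight <- 1 / hits$k
    }
    aln <- data.frame(
      id = reads$id[hits$ridx],
      chrom = chrom_names[hits$chrom_i],
      pos = hits$pos,
      strand = hits$strand,
      mismatches = hits$mm,
      weight = hits$weight,
      ambiguous = hits$k > 1L,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(alignments = aln,
         unmapped = data.frame(id = reads$id[un_idx], seq = reads$seq[un_idx],
                               stringsAsFactors = FALSE),
         reads = reads, policy = policy,
         chrom_names = chrom_names),
    class = "AlignmentSet"
  )
}

#' Per-base raw depth from alignments
#'
#' `depth[i]` is the (weighted) number of reads whose placement covers
#' position `i`.
#'
#' @param alignments an `AlignmentSet`.
#' @param ref a `ReferenceGenome`.
#' @return named list of numeric depth vectors, one per chromosome.
#' @export
depth_profile <- function(alignments, ref) {
  aln <- alignments$alignments
  w <- nchar(alignments$reads$seq[match(aln$id, alignments$reads$id)])
  out <- list()
  for (chrom in names(ref$chromosomes)) {
    n <- nchar(ref$chromosomes[[chrom]])
    rows <- which(aln$chrom == chrom)
    if (length(rows) == 0L) {
      out[[chrom]] <- numeric(n)
    } else {
      ir <- IRanges::IRanges(start = aln$pos[rows] + 1L, width = w[rows])
      cov <- IRanges::coverage(ir, weight = aln$weight[rows], width = n)
      out[[chrom]] <- as.numeric(cov)
    }
  }
  out
}

#' Normalize raw depth to copies per cell
#'
#' Divides by the genome-wide median depth over all positions of all
#' chromosomes, so that haploid regions sit at 1.
#'
#' @param depth named list of depth vectors from [depth_profile()].
#' @param ref a `ReferenceGenome`.
#' @param exclude chromosomes to leave out of the median (e.g. the focal,
#'   amplified chromosome; in the study genome the amplified loci are a
#'   negligible length fraction, but in a compact synthetic genome the
#'   focal chromosome is not, so the median of the other chromosomes is
#'   the faithful anchor).
#' @return a `CopyNumberProfile`: list with `values` (named list of
#'   copies-per-cell vectors), `median_depth`, and `window` (1 = raw).
#' @export
normalize_to_copies <- function(depth, ref, exclude = NULL) {
  keep <- setdiff(names(depth), exclude)
  if (length(keep) == 0L) stop("no chromosomes left to anchor the median")
  med <- stats::median(unlist(depth[keep], use.names = FALSE))
  if (!is.finite(med) || med == 0) stop("genome-wide median depth is zero")
  structure(list(values = lapply(depth, function(v) v / med),
                 median_depth = med, window = 1L),
            class = "CopyNumberProfile")
}

#' Smooth a copy-number profile with a centered sliding window
#'
#' Centered moving average; edge positions use shrinking windows.
#'
#' @param profile a `CopyNumberProfile`.
#' @param window odd window size in nt (e.g. 1500, or 200 for subtelomere
#'   zooms).
#' @return a smoothed `CopyNumberProfile`.
#' @export
smooth_profile <- function(profile, window) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  if (any(vapply(profile$values, length, integer(1)) < window)) {
    stop("window larger than chromosome")
  }
  structure(list(values = lapply(profile$values, running_mean, window = window),
                 median_depth = profile$median_depth, window = as.integer(window)),
            class = "CopyNumberProfile")
}
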