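# End-to-end analysis pipeline: reads -> alignments -> copy-number profile
# -> level segments, amplicons and deletions -> junction calls -> repeat
# totals; plus derivation of a structure-enumeration constraint set from
# the calls.

#' Analyze a read set against the reference
#'
#' Runs the coverage pipeline (mapping, depth, copies-per-cell
#' normalization anchored on the non-focal chromosomes, integer-level
#' segmentation with the CUP array masked, terminal-deletion calls) and
#' the junction-discovery pipeline (unmapped-read assembly and
#' classification), and computes the coverage-based repeat total.
#'
#' @param reads a `ReadSet` or data.frame `id`, `seq`.
#' @param ref a `ReferenceGenome`.
#' @param policy multi-map policy for [map_reads()].
#' @param seg_window segmentation window in nt; defaults to the smoothing
#'   scale of the coverage analysis (1500 nt) scaled with the genome.
#' @param focal chromosome carrying the amplified locus.
#' @return a `MacroteneAnalysis` list: `alignments`, `depth`, `profile`,
#'   `segments`, `deletions`, `junctions`, `repeat_total`.
#' @export
analyze_readset <- function(reads, ref, policy = "first", seg_window = NULL,
                            focal = "chrVIII") {
  scale <- ref$layout$scale
  if (is.null(seg_window)) {
    seg_window <- max(100L, as.integer(round(1500 * (if (is.na(scale)) 1 else scale))))
  }
  al <- map_reads(reads, ref, policy = policy)
  dp <- depth_profile(al, ref)
  pr <- normalize_to_copies(dp, ref, exclude = focal)
  co <- ref$layout$coords
  # mask the CUP array (orders of magnitude above the segmental scale) and
  # dispersed repeats (delta elements, telomeric runs): under a
  # deterministic multi-map policy, reads falling entirely inside a repeat
  # copy pile onto the first copy, spiking one instance and zeroing the
  # others; positions outside the repeat are anchored by unique sequence,
  # so deltas are masked without margin (telomeres with a small one, since
  # chromosome ends also lose edge coverage)
  mask <- list()
  mask[[focal]] <- cbind(co$cup_l - 1000L, co$cup_r + 1000L)
  rep_feats <- ref$features[ref$features$class %in% c("delta", "telomere_motif"), ,
                            drop = FALSE]
  for (i in seq_len(nrow(rep_feats))) {
    chrom <- rep_feats$chrom[i]
    n <- nchar(ref$chromosomes[[chrom]])
    margin <- if (rep_feats$class[i] == "delta") 0L else 120L
    iv <- cbind(max(0L, rep_feats$start[i] - margin),
                min(n, rep_feats$end[i] + margin))
    mask[[chrom]] <- rbind(mask[[chrom]], iv)
  }
  segs <- segment_levels(pr, window = seg_window, mask = mask,
                         min_segment_length = 2L * seg_window)
  dels <- call_deletions(segs, ref, al)
  jc <- find_junctions(al, pr$median_depth, ref)
  structure(
    list(alignments = al, depth = dp, profile = pr, segments = segs,
         deletions = dels, junctions = jc,
         repeat_total = coverage_repeat_total(pr, ref),
         seg_window = seg_window, focal = focal),
    class = "MacroteneAnalysis"
  )
}

#' Simulated PFGE and Southern readout of a cell model
#'
#' Stands in for the gel experiments: returns the focal-derived band sizes
#' and the CUP-hybridizing EcoRI fragment sizes of a realized cell.
#'
#' @param cell a `CellModel`.
#' @param ref a `ReferenceGenome`.
#' @return list with `band_sizes_kb` (focal-derived molecules) and
#'   `cup_fragments_kb` (sorted; the normal ~34.5 kb fragment plus one
#'   expanded fragment per expanded locus).
#' @export
simulated_pfge <- function(cell, ref) {
  obs <- predict_observables(cell, ref)
  focal_rows <- grepl("VIII", obs$bands$chrom)
  frs <- sort(unlist(obs$cup_fragments_kb, use.names = FALSE))
  list(band_sizes_kb = obs$bands$size_kb[focal_rows],
       cup_fragments_kb = frs)
}

#' Derive a structure-enumeration constraint set from pipeline calls
#'
#' Converts observed level segments, junction calls, and gel readouts into
#' a [constraint_set()]: expected per-atom levels from the segments,
#' molecule count from the left-arm level, expanded-array count and
#' classes from the palindromic junction copy numbers, neo-telomere
#' attachment sites from telomere-fusion calls, normal-locus presence and
#' expanded-array sizes from the CUP restriction fragments. Delta-delta
#' junction counts are left unconstrained (their copy estimates are
#' repeat-ambiguous by nature).
#'
#' @param analysis a `MacroteneAnalysis`.
#' @param ref a `ReferenceGenome`.
#' @param pfge output of [simulated_pfge()] (or measured equivalents).
#' @return a `ConstraintSet`.
#' @export
constraints_from_calls <- function(analysis, ref, pfge = NULL) {
  atoms <- structure_atoms(ref)
  segs <- analysis$segments
  # level of the segment with the largest overlap (atoms whose midpoints
  # fall inside masked repeats still pick up their flanking segment)
  level_at <- function(chrom, start, end) {
    s <- segs[segs$chrom == chrom & segs$start < end & segs$end > start, ,
              drop = FALSE]
    if (nrow(s) == 0L) return(NA_integer_)
    ov <- pmin(s$end, end) - pmax(s$start, start)
    s$level[which.max(ov)]
  }
  expected <- atoms
  expected$level <- vapply(seq_len(nrow(atoms)), function(i) {
    lv <- level_at(atoms$chrom[i], atoms$start[i], atoms$end[i])
    if (is.na(lv)) 1L else lv
  }, integer(1))
  ploidy <- expected$level[1L]
  # the shared right subtelomere attracts the twin chromosome's reads
  # (mis-mapping confounder); its true level is read from the unique IMD2
  # marker instead of the raw segment level
  imd2 <- ref$features[ref$features$name == "IMD2", , drop = FALSE]
  if (nrow(imd2) == 1L) {
    sub_i <- which(atoms$chrom == imd2$chrom & atoms$start <= imd2$start &
                     atoms$end >= imd2$end)
    if (length(sub_i) == 1L) {
      v <- analysis$profile$values[[imd2$chrom]]
      expected$level[sub_i] <-
        as.integer(round(mean(v[(imd2$start + 1L):imd2$end])))
    }
  }

  jc <- analysis$junctions
  classes <- character(0)
  if (nrow(jc) > 0L) {
    pal <- jc[jc$class %in% c("strand_switch_palindrome",
                              "inverted_microhomology"), , drop = FALSE]
    for (i in seq_len(nrow(pal))) {
      kind <- if (pal$class[i] == "strand_switch_palindrome") {
        "strand_switch"
      } else {
        "inverted_microhomology"
      }
      classes <- c(classes, rep(kind, max(1L, round(pal$copy_number[i]))))
    }
  }
  neo <- integer(0)
  if (nrow(jc) > 0L) {
    tf <- jc[jc$class == "telomere_fusion" & !is.na(jc$pos1), , drop = FALSE]
    neo <- tf$pos1
  }

  normal_band <- TRUE
  exp_units <- NULL
  bands <- NULL
  if (!is.null(pfge)) {
    frs <- pfge$cup_fragments_kb
    normal_band <- any(abs(frs - 34.5) <= 1)
    big <- sort(frs[frs > 40], decreasing = TRUE)
    if (length(big) > 0L) {
      exp_units <- vapply(big, restriction_repeat_count,
                          integer(1), locus_kind = "expanded")
      exp_units <- exp_units[seq_len(min(length(exp_units), length(classes)))]
    }
    bands <- pfge$band_sizes_kb
  }
  if (!is.null(exp_units) && length(exp_units) < length(classes)) {
    exp_units <- c(exp_units,
                   rep(30L, length(classes) - length(exp_units)))
  }
  constraint_set(
    ref, ploidy_viii = ploidy, expected_levels = expected,
    array_classes = classes, expanded_units = exp_units,
    neo_sites = neo, normal_band_present = normal_band,
    max_normal_arrays = ploidy + 1L,
    band_sizes_kb = bands
  )
}

#' Full-pipeline round trip from a cell model
#'
#' Simulates reads from the model, runs the complete analysis, derives the
#' constraint set (using the model's simulated gel readouts as the
#' experimental side data), enumerates structures, and reports whether the
#' generating topology is among the solutions.
#'
#' @param cell the generating `CellModel`.
#' @param ref a `ReferenceGenome`.
#' @param config a [simulation_config()].
#' @return list with `analysis`, `constraints`, `solutions`,
#'   `generator_recovered` (logical), `repeat_total`, `true_units`.
#' @export
pipeline_roundtrip <- function(cell, ref, config = simulation_config()) {
  reads <- simulate_reads(cell, ref, config)
  analysis <- analyze_readset(reads, ref)
  pfge <- simulated_pfge(cell, ref)
  constraints <- constraints_from_calls(analysis, ref, pfge)
  solutions <- enumerate_structures(constraints)
  gen_key <- topology_key(cell, ref)
  sol_keys <- vapply(solutions, function(s) topology_key(s$cell, ref), "")
  list(analysis = analysis, constraints = constraints, solutions = solutions,
       generator_recovered = gen_key %in% sol_keys,
       repeat_total = analysis$repeat_total,
       true_units = true_unit_count(cell, ref))
}
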