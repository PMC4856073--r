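# Core data model: chromosomes as ordered, oriented segments and tandem
# arrays; sequence realization; in-silico restriction digestion; marker
# copy counting.
#
# Coordinates are 0-based half-open throughout the internal model; printed
# reports are 1-based inclusive.

#' Reference genome container
#'
#' @param chromosomes named list (or character vector) of nucleotide
#'   sequences, in the order used for deterministic multi-map resolution.
#' @param features data.frame with columns `name`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `class`; `class` is one of
#'   `repeat_unit`, `delta`, `marker_gene`, `centromere`, `telomere_motif`,
#'   `ars`.
#' @param layout list of layout constants produced by [build_reference()]
#'   (repeat unit sequence, flanks, key coordinates).
#' @return an object of class `ReferenceGenome`.
#' @export
reference_genome <- function(chromosomes, features, layout = list()) {
  chromosomes <- as.list(chromosomes)
  stopifnot(!is.null(names(chromosomes)), all(nzchar(names(chromosomes))))
  obj <- structure(
    list(chromosomes = chromosomes, features = features, layout = layout),
    class = "ReferenceGenome"
  )
  validate_reference(obj)
  obj
}

#' Validate a ReferenceGenome against its structural invariants
#'
#' Checks interval bounds, the one-centromere rule, the repeat-unit length,
#' and the absence of EcoRI/BamHI sites inside the repeat unit.
#'
#' @param ref a `ReferenceGenome`.
#' @return `ref`, invisibly; errors if an invariant is violated.
#' @export
validate_reference <- function(ref) {
  f <- ref$features
  lens <- vapply(ref$chromosomes, nchar, integer(1))
  stopifnot(all(f$chrom %in% names(lens)))
  if (any(f$start < 0 | f$end > lens[f$chrom] | f$start >= f$end)) {
    stop("feature interval outside chromosome bounds")
  }
  cen <- f[f$class == "centromere", ]
  if (!all(sort(cen$chrom) == sort(names(lens))) || nrow(cen) != length(lens)) {
    stop("each chromosome must carry exactly one centromere feature")
  }
  unit <- f[f$class == "repeat_unit", ]
  ulen <- ref$layout$unit_length %||% 2000L
  if (nrow(unit) > 0 && any(unit$end - unit$start != ulen)) {
    stop("repeat_unit feature length must equal unit_length")
  }
  if (!is.null(ref$layout$unit)) {
    u <- ref$layout$unit
    if (grepl("GAATTC", u, fixed = TRUE) || grepl("GGATCC", u, fixed = TRUE)) {
      stop("restriction site inside the repeat unit")
    }
  }
  invisible(ref)
}

#' Look up a named feature interval
#' @param ref `ReferenceGenome`.
#' @param name feature name.
#' @return one-row data.frame.
#' @keywords internal
feature_interval <- function(ref, name) {
  hit <- ref$features[ref$features$name == name, , drop = FALSE]
  if (nrow(hit) == 0L) stop("unknown feature: ", name)
  hit[1L, , drop = FALSE]
}

# ---- model part constructors -----------------------------------------------

#' Oriented reference segment
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @param orientation `"+"` or `"-"`.
#' @param label optional block label (e.g. an amplicon name).
#' @return a `SegmentSpec`.
#' @export
segment_spec <- function(chrom, start, end, orientation = "+", label = NULL) {
  stopifnot(start < end, orientation %in% c("+", "-"))
  structure(
    list(chrom = chrom, start = as.integer(start), end = as.integer(end),
         orientation = orientation, label = label),
    class = c("SegmentSpec", "ModelPart")
  )
}

#' Quasi-palindromic junction specification
#'
#' Describes the single breakpoint carried by an expanded tandem array:
#' either a strand-switch palindrome leaving a short non-palindromic
#' single-strand loop, or a switch across two short inverted near-identical
#' motifs (microhomology) that sit a fixed distance apart in the repeat
#' unit.
#'
#' @param kind `"strand_switch"` or `"inverted_microhomology"`.
#' @param loop_length loop length in nt (strand_switch only).
#' @param loop_seq loop sequence; normally built by
#'   [make_strand_switch_junction()] so that its ends cannot be absorbed
#'   into the flanking palindrome arms.
#' @param switch_offset 1-based position within the repeat unit at which
#'   the strand switch occurs.
#' @param microhomology_length length of the inverted motif (nt).
#' @param reference_spacing distance between the two inverted motif copies
#'   on the reference (nt), measured between the motif-proximal ends.
#' @param arm_mismatches number of substitutions carried by the inverted
#'   palindrome arm relative to the reference (0 or 1 in practice).
#' @return a `PalindromeSpec`.
#' @export
palindrome_spec <- function(kind = c("strand_switch", "inverted_microhomology"),
                            loop_length = 0L, loop_seq = NULL,
                            switch_offset = 400L,
                            microhomology_length = 16L,
                            reference_spacing = 745L,
                            arm_mismatches = 0L) {
  kind <- match.arg(kind)
  stopifnot(loop_length >= 0L, microhomology_length >= 1L,
            reference_spacing > microhomology_length)
  structure(
    list(kind = kind, loop_length = as.integer(loop_length),
         loop_seq = loop_seq, switch_offset = as.integer(switch_offset),
         microhomology_length = as.integer(microhomology_length),
         reference_spacing = as.integer(reference_spacing),
         arm_mismatches = as.integer(arm_mismatches)),
    class = "PalindromeSpec"
  )
}

#' Tandem repeat array part
#'
#' An array of `copy_count` repeat units flanked by the fixed CUP-locus
#' flank sequence, optionally carrying one quasi-palindromic junction.
#' With a junction the downstream portion of the array is realized in
#' inverted orientation, so both ends of the part present the locus-left
#' flank (one of them reverse complemented).
#'
#' @param copy_count total number of repeat units (>= 1).
#' @param junction optional [palindrome_spec()].
#' @param junction_index unit index (1-based) at which the junction sits;
#'   defaults to the middle of the array.
#' @return a `TandemArraySpec`.
#' @export
tandem_array_spec <- function(copy_count, junction = NULL, junction_index = NULL) {
  stopifnot(copy_count >= 1L)
  if (!is.null(junction)) {
    stopifnot(inherits(junction, "PalindromeSpec"))
    if (is.null(junction_index)) junction_index <- max(1L, ceiling(copy_count / 2))
    if (junction_index < 1L || junction_index > copy_count) {
      stop("junction_index outside array")
    }
  }
  structure(
    list(copy_count = as.integer(copy_count), junction = junction,
         junction_index = if (is.null(junction)) NULL else as.integer(junction_index)),
    class = c("TandemArraySpec", "ModelPart")
  )
}

#' Telomere cap descriptor
#' @param kind `"native"` (the backbone already ends in its own telomere),
#'   `"neo_telomeric_repeat"` (a fresh telomeric run is appended), or
#'   `"captured_subtelomere"` (the terminal part carries another
#'   chromosome's subtelomere and telomere).
#' @param seed seed for the deterministic telomeric-run generator.
#' @return a telomere cap descriptor.
#' @export
telomere_cap <- function(kind = c("native", "neo_telomeric_repeat",
                                  "captured_subtelomere"), seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, seed = as.integer(seed)), class = "TelomereCap")
}

#' Linear chromosome model
#' @param name chromosome name.
#' @param parts ordered list of [segment_spec()] / [tandem_array_spec()].
#' @param left_cap,right_cap [telomere_cap()] descriptors.
#' @return a `ChromosomeModel`.
#' @export
chromosome_model <- function(name, parts, left_cap = telomere_cap("native"),
                             right_cap = telomere_cap("native")) {
  stopifnot(length(parts) >= 1L, inherits(left_cap, "TelomereCap"),
            inherits(right_cap, "TelomereCap"))
  structure(list(name = name, parts = parts, left_cap = left_cap,
                 right_cap = right_cap),
            class = "ChromosomeModel")
}

#' Whole-cell model: linear chromosomes plus optional circular episomes
#' @param name cell/strain label.
#' @param chromosomes list of [chromosome_model()].
#' @param episomes optional list of [tandem_array_spec()] treated as
#'   circular molecules.
#' @return a `CellModel`.
#' @export
cell_model <- function(name, chromosomes, episomes = list()) {
  stopifnot(all(vapply(chromosomes, inherits, TRUE, "ChromosomeModel")))
  structure(list(name = name, chromosomes = chromosomes, episomes = episomes),
            class = "CellModel")
}

# ---- sequence realization --------------------------------------------------

# Apply `n_mm` deterministic substitutions to the tail of an arm sequence
# (used to plant the single palindrome mismatch seen in one mutant series).
mutate_arm <- function(arm, n_mm) {
  if (n_mm == 0L) return(arm)
  L <- nchar(arm)
  pos <- L - 12L - 7L * (seq_len(n_mm) - 1L)
  pos <- pos[pos >= 1L]
  for (p in pos) {
    b <- substr(arm, p, p)
    substr(arm, p, p) <- chartr("ACGT", "GTAC", b)
  }
  arm
}

realize_array <- function(part, ref) {
  lay <- ref$layout
  U <- lay$unit
  Fl <- lay$flank_l
  Fr <- lay$flank_r
  n <- part$copy_count
  j <- part$junction
  if (is.null(j)) {
    return(paste0(Fl, strrep(U, n), Fr))
  }
  ji <- part$junction_index
  if (ji < 1L || ji > n) stop("junction_index outside array")
  a <- ji - 1L
  b <- max(0L, n - 1L - a)
  if (j$kind == "strand_switch") {
    s <- j$switch_offset
    stopifnot(s >= 1L, s < nchar(U))
    arm1 <- substr(U, 1L, s)
    arm2 <- mutate_arm(arm1, j$arm_mismatches)
    loop <- j$loop_seq %||% make_loop_seq(U, s, j$loop_length, seed = 7L)
    half1 <- paste0(Fl, strrep(U, a), arm1)
    half2 <- paste0(Fl, strrep(U, b), arm2)
    paste0(half1, loop, revcomp(half2))
  } else {
    mh <- j$microhomology_length
    p1 <- lay$micro_p1 # 0-based start of motif M in the unit
    p2 <- lay$micro_p2 # 0-based start of the inverted copy of M
    stopifnot((p2 - (p1 + mh)) == j$reference_spacing)
    half1 <- paste0(Fl, strrep(U, a), substr(U, 1L, p2 + mh))
    half2 <- paste0(Fl, strrep(U, b), substr(U, 1L, p1 + mh))
    rc2 <- revcomp(half2)
    paste0(half1, substr(rc2, mh + 1L, nchar(rc2)))
  }
}

# Deterministic loop sequence whose first/last two bases cannot extend the
# flanking palindrome arms (so the classifier recovers the exact loop
# length) and which is not itself palindromic.
make_loop_seq <- function(unit, switch_offset, loop_length, seed = 7L) {
  if (loop_length == 0L) return("")
  cont1 <- substr(unit, switch_offset + 1L, switch_offset + 1L)
  cont2 <- substr(unit, switch_offset + 2L, switch_offset + 2L)
  comp <- function(b) chartr("ACGT", "TGCA", b)
  with_seed(seed + loop_length + switch_offset, {
    repeat {
      loop <- random_dna(loop_length)
      ok <- TRUE
      pick_not <- function(avoid) sample(setdiff(DNA_BASES, avoid), 1L)
      substr(loop, 1L, 1L) <- pick_not(cont1)
      if (loop_length >= 2L) substr(loop, 2L, 2L) <- pick_not(cont2)
      substr(loop, loop_length, loop_length) <- pick_not(comp(cont1))
      if (loop_length >= 4L) {
        substr(loop, loop_length - 1L, loop_length - 1L) <- pick_not(comp(cont2))
      }
      if (loop_length >= 2L && loop == revcomp(loop)) ok <- FALSE
      if (ok) break
    }
    loop
  })
}

realize_part <- function(part, ref) {
  if (inherits(part, "SegmentSpec")) {
    chrom <- ref$chromosomes[[part$chrom]]
    if (is.null(chrom)) stop("unresolvable chromosome: ", part$chrom)
    if (part$end > nchar(chrom)) stop("segment outside chromosome bounds")
    s <- seq_extract(chrom, part$start, part$end)
    if (part$orientation == "-") revcomp(s) else s
  } else if (inherits(part, "TandemArraySpec")) {
    realize_array(part, ref)
  } else {
    stop("unknown model part")
  }
}

cap_sequence <- function(cap, side) {
  if (cap$kind != "neo_telomeric_repeat") return("")
  run <- telomere_run(300L, seed = cap$seed)
  if (side == "right") revcomp(run) else run
}

#' Realize a chromosome model as nucleotide sequence
#'
#' Segments are extracted from the reference (reverse complemented when on
#' the minus strand); tandem arrays contribute `copy_count` units plus the
#' fixed flanks and any loop adjustment; strand-switch junctions place the
#' downstream portion of the array in inverted orientation with the
#' specified non-palindromic loop between the two inverted copies.
#'
#' @param model a `ChromosomeModel`.
#' @param ref a `ReferenceGenome`.
#' @return nucleotide sequence (character scalar).
#' @export
realize_sequence <- function(model, ref) {
  body <- paste(vapply(model$parts, realize_part, "", ref = ref), collapse = "")
  paste0(cap_sequence(model$left_cap, "left"), body,
         cap_sequence(model$right_cap, "right"))
}

#' Realize every molecule of a cell model
#' @param cell a `CellModel`.
#' @param ref a `ReferenceGenome`.
#' @return named list with `chromosomes` (named character vector) and
#'   `episomes` (character vector of circular sequences).
#' @export
realize_cell <- function(cell, ref) {
  chroms <- vapply(cell$chromosomes, realize_sequence, "", ref = ref)
  names(chroms) <- vapply(cell$chromosomes, `[[`, "", "name")
  epis <- vapply(cell$episomes, realize_array, "", ref = ref)
  list(chromosomes = as.list(chroms), episomes = as.list(epis))
}

# ---- in-silico digestion ---------------------------------------------------

#' In-silico restriction digest
#'
#' Cuts at the start of every occurrence of the recognition motif and
#' returns fragment lengths in genomic order. Fragments partition the
#' sequence (their lengths sum to the sequence length).
#'
#' @param sequence nucleotide sequence (character scalar).
#' @param enzyme_site recognition motif, length >= 4 (e.g. `"GAATTC"`).
#' @return integer vector of fragment lengths.
#' @export
insilico_digest <- function(sequence, enzyme_site) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("empty sequence")
  if (nchar(enzyme_site) < 4L) stop("enzyme site must be at least 4 nt")
  m <- Biostrings::matchPattern(enzyme_site, Biostrings::DNAString(sequence))
  cuts <- sort(unique(BiocGenerics::start(m) - 1L)) # 0-based cut positions
  bounds <- unique(c(0L, cuts, nchar(sequence)))
  frags <- diff(bounds)
  frags[frags > 0L]
}

# ---- marker counting -------------------------------------------------------

#' Count copies of a marker gene across a cell model
#'
#' A marker copy is a model part (segment) that fully contains the marker's
#' annotated reference interval. Episomal arrays never carry marker genes.
#'
#' @param cell a `CellModel`.
#' @param marker marker feature name (e.g. the Asn-RS transgene).
#' @param ref a `ReferenceGenome`.
#' @return integer copy number per cell.
#' @export
count_marker_copies <- function(cell, marker, ref) {
  fi <- feature_interval(ref, marker)
  if (fi$class != "marker_gene") stop("feature is not a marker_gene: ", marker)
  n <- 0L
  for (chrom in cell$chromosomes) {
    for (p in chrom$parts) {
      if (inherits(p, "SegmentSpec") && p$chrom == fi$chrom &&
          p$start <= fi$start && p$end >= fi$end) {
        n <- n + 1L
      }
    }
  }
  n
}

# ---- per-position model copy number ---------------------------------------

#' Expected copies-per-cell vector implied by a cell model
#'
#' Sums, over all segment parts of all chromosomes, the coverage of each
#' reference position of `chrom`. Tandem arrays are excluded (their copy
#' number lives on the repeat-quantifier scale, not the segmental one).
#'
#' @param cell a `CellModel`.
#' @param ref a `ReferenceGenome`.
#' @param chrom reference chromosome name.
#' @return integer vector of length `nchar(ref$chromosomes[[chrom]])`.
#' @export
model_copy_vector <- function(cell, ref, chrom) {
  n <- nchar(ref$chromosomes[[chrom]])
  v <- integer(n)
  for (cm in cell$chromosomes) {
    for (p in cm$parts) {
      if (inherits(p, "SegmentSpec") && p$chrom == chrom) {
        v[(p$start + 1L):p$end] <- v[(p$start + 1L):p$end] + 1L
      }
    }
  }
  v
}

#' Total repeat-unit equivalents placed by the generator in a cell
#'
#' Computed from realized array lengths: (length - flanks - loop) /
#' unit_length, summed over chromosomal arrays and episomes. This is the
#' ground truth against which coverage-based repeat totals are compared.
#'
#' @param cell a `CellModel`.
#' @param ref a `ReferenceGenome`.
#' @return numeric unit count.
#' @export
true_unit_count <- function(cell, ref) {
  lay <- ref$layout
  fl <- nchar(lay$flank_l)
  fr <- nchar(lay$flank_r)
  one <- function(part) {
    len <- nchar(realize_array(part, ref))
    if (is.null(part$junction)) {
      (len - fl - fr) / lay$unit_length
    } else if (part$junction$kind == "strand_switch") {
      (len - 2 * fl - part$junction$loop_length) / lay$unit_length
    } else {
      (len - 2 * fl + part$junction$microhomology_length) / lay$unit_length
    }
  }
  total <- 0
  for (cm in cell$chromosomes) {
    for (p in cm$parts) if (inherits(p, "TandemArraySpec")) total <- total + one(p)
  }
  for (p in cell$episomes) total <- total + one(p)
  total
}
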