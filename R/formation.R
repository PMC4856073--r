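# The three-step mechanistic model of macrotene chromosome formation,
# executed as transformations on CellModels:
#   step 1 - delta-mediated segmental duplication concomitant with disomy
#            (one normal homolog + an intermediate macrotene M0 carrying
#            two normal CUP loci and two Asn-RS copies);
#   step 2 - an accidental quasi-palindromic junction in the left or right
#            CUP locus of M0 triggers massive tandem amplification,
#            terminated either by a delta-delta interaction (internal
#            deletion, amplicons VIII-D/VIII-E inverted) or, when the
#            distal arm is lost, by acquisition of a new telomere
#            (telomeric-repeat addition at the VIII-F boundary, or capture
#            of the XVI-A subtelomere);
#   step 3 - the normal homolog is homogenized from the CUP locus rightward
#            using the macrotene as template (long-range loss of
#            heterozygosity), yielding the observed two-macrotene cells.

is_normal_viii <- function(cm, ref) {
  key <- topology_key(cell_model("tmp", list(cm)), ref)
  norm <- topology_key(cell_model("tmp", list(normal_chrVIII(ref))), ref)
  key == norm
}

has_expanded_array <- function(cm) {
  any(vapply(cm$parts, function(p) {
    inherits(p, "TandemArraySpec") && !is.null(p$junction)
  }, logical(1)))
}

count_normal_arrays <- function(cm) {
  sum(vapply(cm$parts, function(p) {
    inherits(p, "TandemArraySpec") && is.null(p$junction)
  }, logical(1)))
}

#' Step 1: delta-mediated segmental duplication with disomy
#'
#' From a parental haploid cell, produces one normal chromosome VIII plus
#' an intermediate macrotene (M0) in which the segment between the two
#' co-oriented delta elements - spanning the CUP locus and the Asn-RS
#' transgene - is duplicated in tandem, with a chimeric delta at the
#' junction. The cell afterwards carries two normal CUP loci and three
#' Asn-RS copies (two on M0, one on the normal homolog).
#'
#' @param parental a parental-type `CellModel`.
#' @param ref a `ReferenceGenome`.
#' @param delta_pair names of the two co-oriented delta features bounding
#'   the duplication.
#' @param parental_units repeat units in the normal CUP locus.
#' @return the disomic `CellModel` with M0.
#' @export
apply_step1 <- function(parental, ref,
                        delta_pair = c("delta_VIII_D", "delta_VIII_16"),
                        parental_units = 16L) {
  d1 <- feature_interval(ref, delta_pair[1L])
  d2 <- feature_interval(ref, delta_pair[2L])
  if (d1$chrom != d2$chrom || d1$strand != d2$strand) {
    stop("delta pair must be co-oriented on the same chromosome")
  }
  span <- c(min(d1$start, d2$start), max(d1$end, d2$end))
  asn <- feature_interval(ref, "AsnRS")
  co <- ref$layout$coords
  if (!(span[1L] <= asn$start && span[2L] >= asn$end) ||
      !(span[1L] <= co$cup_l && span[2L] >= co$cup_r)) {
    stop("delta pair must span the CUP locus and the Asn-RS gene")
  }
  viii <- which(vapply(parental$chromosomes, is_normal_viii, TRUE, ref = ref))
  if (length(viii) != 1L) stop("parental cell must carry one normal chromosome VIII")
  b <- model_blocks(ref)
  m0 <- chromosome_model("chrVIII_M0", list(
    b$left_arm(), tandem_array_spec(parental_units), b$right_arm_trunc(),
    b$D("+"), tandem_array_spec(parental_units), b$right_arm_trunc(),
    b$subtel()
  ))
  cell_model(paste0(parental$name, "+M0"),
             append(parental$chromosomes, list(m0)),
             episomes = parental$episomes)
}

#' Step 2: quasi-palindromic template switch and amplification cascade
#'
#' A quasi-palindromic junction arises in the left or right normal CUP
#' locus of the M0 intermediate and triggers massive tandem amplification.
#' `side = "left"` must terminate by the delta-delta interaction
#' (`termination = "delta"`): an internal deletion places the extra
#' VIII-D/VIII-E copies in inverted orientation and the right chromosome
#' end is kept (the single-macrotene topology). `side = "right"` deletes
#' the distal arm and requires a new telomere:
#' `"telomere_repeat_addition"` caps an inverted extra VIII-F copy with
#' telomeric repeats, `"neo_telomere_capture"` appends an inverted extra
#' VIII-E copy joined to a captured XVI-A subtelomere.
#'
#' @param cell a `CellModel` containing an M0-type chromosome.
#' @param ref a `ReferenceGenome`.
#' @param side which CUP locus of M0 switches: `"left"` or `"right"`.
#' @param amplification_count repeat units of the resulting expanded array.
#' @param termination `"delta"`, `"telomere_repeat_addition"`, or
#'   `"neo_telomere_capture"`.
#' @param junction optional [palindrome_spec()]; defaults to the junction
#'   kind observed for the corresponding scenario (38 nt loop for the left
#'   case; inverted microhomology for right/telomere-addition; 63 nt loop
#'   with one palindrome mismatch for right/capture).
#' @param parental_units repeat units of the preserved normal locus.
#' @return the transformed `CellModel` (one macrotene + normal homolog).
#' @export
apply_step2 <- function(cell, ref, side = c("left", "right"),
                        amplification_count = 30L,
                        termination = c("delta", "telomere_repeat_addition",
                                        "neo_telomere_capture"),
                        junction = NULL, parental_units = 16L) {
  side <- match.arg(side)
  termination <- match.arg(termination)
  m0_i <- which(vapply(cell$chromosomes, function(cm) {
    count_normal_arrays(cm) == 2L && !has_expanded_array(cm)
  }, logical(1)))
  if (length(m0_i) != 1L) stop("cell must contain one M0-type chromosome")
  if (side == "left" && termination != "delta") {
    stop("left-locus amplification terminates by the delta-delta interaction")
  }
  if (side == "right" && termination == "delta") {
    stop("right-locus amplification deletes the distal arm and needs a new telomere")
  }
  b <- model_blocks(ref)
  if (side == "left") {
    jx <- junction %||% make_strand_switch_junction(ref, 38L)
    mac <- chromosome_model("chrVIII_mac", list(
      b$left_arm(), tandem_array_spec(amplification_count, junction = jx),
      b$D("-"), b$E("+"), tandem_array_spec(parental_units), b$right_arm()
    ))
  } else if (termination == "telomere_repeat_addition") {
    jx <- junction %||% make_microhomology_junction(ref)
    mac <- chromosome_model("chrVIII_mac", list(
      b$left_arm(), tandem_array_spec(parental_units), b$right_arm_trunc(),
      b$D("+"), tandem_array_spec(amplification_count, junction = jx),
      b$F("-")
    ), right_cap = telomere_cap("neo_telomeric_repeat", seed = 725L))
  } else {
    jx <- junction %||% make_strand_switch_junction(ref, 63L,
                                                    switch_offset = 260L,
                                                    arm_mismatches = 1L)
    mac <- chromosome_model("chrVIII_mac", list(
      b$left_arm(), tandem_array_spec(parental_units), b$right_arm_trunc(),
      b$D("+"), tandem_array_spec(amplification_count, junction = jx),
      b$E("-"), b$XVIA("-")
    ), right_cap = telomere_cap("captured_subtelomere"))
  }
  chroms <- cell$chromosomes
  chroms[[m0_i]] <- mac
  cell_model(paste0(cell$name, "+step2_", side), chroms,
             episomes = cell$episomes)
}

#' Step 3: homogenization of the normal homolog
#'
#' Replaces the normal chromosome VIII by a macrotene-templated copy: the
#' region from the CUP locus rightward is converted to the macrotene's
#' arrangement (its first expanded array and everything distal to it), the
#' long-range loss-of-heterozygosity reading of the two-macrotene mutants.
#' The copied expanded array may take an independent size, since the two
#' expanded loci of a mutant differ. Applying the step to a cell whose
#' macrotene retains the full right arm is legal but produces a structure
#' not observed among the mutants; the result carries attribute
#' `informational = TRUE` in that case.
#'
#' @param cell a `CellModel` with one macrotene and one normal homolog.
#' @param ref a `ReferenceGenome`.
#' @param array_units repeat units of the newly created expanded array
#'   (defaults to the macrotene's count).
#' @return the two-macrotene `CellModel`.
#' @export
apply_step3 <- function(cell, ref, array_units = NULL) {
  norm_i <- which(vapply(cell$chromosomes, is_normal_viii, TRUE, ref = ref))
  if (length(norm_i) == 0L) stop("no normal homolog present")
  norm_i <- norm_i[1L]
  mac_i <- which(vapply(cell$chromosomes, has_expanded_array, logical(1)))
  if (length(mac_i) != 1L) stop("cell must contain exactly one macrotene chromosome")
  mac <- cell$chromosomes[[mac_i]]
  first_exp <- which(vapply(mac$parts, function(p) {
    inherits(p, "TandemArraySpec") && !is.null(p$junction)
  }, logical(1)))[1L]
  tract <- mac$parts[first_exp:length(mac$parts)]
  if (!is.null(array_units)) {
    arr <- tract[[1L]]
    tract[[1L]] <- tandem_array_spec(array_units, junction = arr$junction,
                                     junction_index = max(1L, ceiling(array_units / 2)))
  }
  b <- model_blocks(ref)
  new_chrom <- chromosome_model("chrVIII_mac_copy",
                                c(list(b$left_arm()), tract),
                                right_cap = mac$right_cap)
  chroms <- cell$chromosomes
  chroms[[norm_i]] <- new_chrom
  out <- cell_model(paste0(cell$name, "+step3"), chroms,
                    episomes = cell$episomes)
  # a macrotene that kept its full right arm duplicates it here: legal but
  # not among the observed structures
  full_right <- any(vapply(tract, function(p) {
    inherits(p, "SegmentSpec") && p$chrom == "chrVIII" &&
      p$end == ref$layout$coords$len_viii
  }, logical(1)))
  attr(out, "informational") <- full_right
  out
}

#' Run a complete formation scenario
#'
#' Convenience wrapper executing steps 1-3 for one of the three observed
#' scenarios and returning the final cell. The `"left_delta"` scenario
#' stops after step 2 (the single-macrotene mutant keeps its normal
#' homolog); the two right-locus scenarios apply step 3.
#'
#' @param ref a `ReferenceGenome`.
#' @param scenario `"left_delta"`, `"right_telomere"`, or
#'   `"right_capture"`.
#' @param amplification_counts one (left) or two (right) expanded-array
#'   unit counts.
#' @param parental optional starting `CellModel`.
#' @return the final `CellModel`.
#' @export
formation_scenario <- function(ref,
                               scenario = c("left_delta", "right_telomere",
                                            "right_capture"),
                               amplification_counts = NULL,
                               parental = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(parental)) parental <- builtin_model(ref, "parental")
  s1 <- apply_step1(parental, ref)
  if (scenario == "left_delta") {
    n <- (amplification_counts %||% 30L)[1L]
    return(apply_step2(s1, ref, side = "left", amplification_count = n))
  }
  counts <- amplification_counts %||%
    (if (scenario == "right_telomere") c(32L, 28L) else c(34L, 30L))
  term <- if (scenario == "right_telomere") "telomere_repeat_addition"
          else "neo_telomere_capture"
  s2 <- apply_step2(s1, ref, side = "right", amplification_count = counts[1L],
                    termination = term)
  apply_step3(s2, ref, array_units = counts[2L])
}

#' Random-side formation draw
#'
#' The template switch should strike either CUP locus of M0 with equal
#' probability; this draws the side under a seed and runs the
#' corresponding scenario (right-side termination chosen uniformly among
#' the two observed neo-telomere routes).
#'
#' @param ref a `ReferenceGenome`.
#' @param seed integer seed.
#' @param p_left probability of the left-locus case.
#' @return the final `CellModel` (attribute `scenario` records the draw).
#' @export
formation_random <- function(ref, seed = 1L, p_left = 0.5) {
  with_seed(seed, {
    scn <- if (stats::runif(1) < p_left) {
      "left_delta"
    } else {
      sample(c("right_telomere", "right_capture"), 1L)
    }
    out <- formation_scenario(ref, scn)
    attr(out, "scenario") <- scn
    out
  })
}
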