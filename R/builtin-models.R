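# Built-in library of the deduced mutant chromosome structures, expressed
# as CellModels over the synthetic reference. Amplicon boundaries follow
# the published coordinates (VIII-D left 116.5 kb, VIII-D/E overlap
# boundary 133.8 kb, VIII-F left boundary nt 123,222, XVI-A = left 56.5 kb
# of chromosome XVI, terminal deletion from 549.5 kb), scaled with the
# reference.

#' Construct a strand-switch junction spec against a given reference
#'
#' Generates the deterministic non-palindromic loop whose terminal bases
#' cannot be absorbed into the palindrome arms.
#'
#' @param ref `ReferenceGenome`.
#' @param loop_length loop length (nt).
#' @param switch_offset 1-based switch position within the repeat unit.
#' @param arm_mismatches substitutions carried by the inverted arm.
#' @return a [palindrome_spec()].
#' @export
make_strand_switch_junction <- function(ref, loop_length, switch_offset = 400L,
                                        arm_mismatches = 0L) {
  palindrome_spec(
    "strand_switch", loop_length = loop_length,
    loop_seq = make_loop_seq(ref$layout$unit, switch_offset, loop_length),
    switch_offset = switch_offset, arm_mismatches = arm_mismatches
  )
}

#' Inverted-microhomology junction spec bound to the reference unit motifs
#' @param ref `ReferenceGenome`.
#' @return a [palindrome_spec()].
#' @export
make_microhomology_junction <- function(ref) {
  lay <- ref$layout
  palindrome_spec("inverted_microhomology",
                  microhomology_length = lay$micro_len,
                  reference_spacing = lay$micro_gap)
}

# Named segment blocks used by the built-in models, the structure
# enumerator and the formation simulator.
model_blocks <- function(ref) {
  co <- ref$layout$coords
  list(
    left_arm = function() segment_spec("chrVIII", 0L, co$cup_l, "+", "VIII-left"),
    right_arm = function() segment_spec("chrVIII", co$cup_r, co$len_viii, "+", "VIII-right"),
    right_arm_trunc = function() segment_spec("chrVIII", co$cup_r, co$subtel, "+", "VIII-right-trunc"),
    subtel = function() segment_spec("chrVIII", co$subtel, co$len_viii, "+", "VIII-subtel"),
    D = function(o = "+") segment_spec("chrVIII", co$d_left, co$cup_l, o, "VIII-D"),
    E = function(o = "+") segment_spec("chrVIII", co$e_left, co$cup_l, o, "VIII-E"),
    F = function(o = "+") segment_spec("chrVIII", co$f_left, co$cup_l, o, "VIII-F"),
    XVIA = function(o = "+") segment_spec("chrXVI", 0L, co$xvia_end, o, "XVI-A"),
    chrXVI = function() chromosome_model("chrXVI", list(
      segment_spec("chrXVI", 0L, co$len_xvi, "+", "XVI"))),
    chrI = function() chromosome_model("chrI", list(
      segment_spec("chrI", 0L, co$len_i, "+", "I"))),
    chrII = function() chromosome_model("chrII", list(
      segment_spec("chrII", 0L, co$len_ii, "+", "II")))
  )
}

#' Normal chromosome VIII model (left arm, CUP array, right arm)
#' @param ref `ReferenceGenome`.
#' @param n_units repeat units in the CUP locus.
#' @param name chromosome name.
#' @return a `ChromosomeModel`.
#' @export
normal_chrVIII <- function(ref, n_units = 16L, name = "chrVIII") {
  b <- model_blocks(ref)
  chromosome_model(name, list(b$left_arm(), tandem_array_spec(n_units),
                              b$right_arm()))
}

#' Built-in library of deduced cell models
#'
#' Returns the parental strain, the intermediate single-macrotene disome
#' (M0), and the three deduced mutant classes: a single macrotene with an
#' internally inverted amplicon block (BYAT711 type), two macrotenes capped
#' by direct telomeric-repeat addition at the VIII-F boundary (BYAT725
#' type), and two macrotenes capped by a captured XVI-A subtelomere
#' (BYAT721-series type).
#'
#' @param ref `ReferenceGenome` from [build_reference()].
#' @param cup_copies named list of expanded-array unit counts; defaults are
#'   desk-scale stand-ins for the multi-hundred-copy arrays of the real
#'   mutants (one value for BYAT711, two for the two-macrotene mutants).
#' @param parental_units repeat units in the normal CUP locus (16).
#' @return named list of `CellModel`s.
#' @export
builtin_models <- function(ref,
                           cup_copies = list(BYAT711 = 30L,
                                             BYAT725 = c(28L, 32L),
                                             BYAT721 = c(30L, 34L)),
                           parental_units = 16L) {
  b <- model_blocks(ref)
  others <- list(b$chrXVI(), b$chrI(), b$chrII())
  j711 <- make_strand_switch_junction(ref, 38L, switch_offset = 400L)
  j721 <- make_strand_switch_junction(ref, 63L, switch_offset = 260L,
                                      arm_mismatches = 1L)
  j725 <- make_microhomology_junction(ref)

  parental <- cell_model("parental", c(list(normal_chrVIII(ref, parental_units)), others))

  m0_chrom <- chromosome_model("chrVIII_M0", list(
    b$left_arm(), tandem_array_spec(parental_units), b$right_arm_trunc(),
    b$D("+"), tandem_array_spec(parental_units), b$right_arm_trunc(),
    b$subtel()
  ))
  M0 <- cell_model("M0", c(list(normal_chrVIII(ref, parental_units), m0_chrom), others))

  mac711 <- chromosome_model("chrVIII_mac", list(
    b$left_arm(), tandem_array_spec(cup_copies$BYAT711[1L], junction = j711),
    b$D("-"), b$E("+"), tandem_array_spec(parental_units), b$right_arm()
  ))
  BYAT711 <- cell_model("BYAT711",
                        c(list(normal_chrVIII(ref, parental_units), mac711), others))

  cap725 <- telomere_cap("neo_telomeric_repeat", seed = 725L)
  mac725_s <- chromosome_model("chrVIII_mac1", list(
    b$left_arm(), tandem_array_spec(cup_copies$BYAT725[1L], junction = j725),
    b$F("-")
  ), right_cap = cap725)
  mac725_l <- chromosome_model("chrVIII_mac2", list(
    b$left_arm(), tandem_array_spec(parental_units), b$right_arm_trunc(),
    b$D("+"), tandem_array_spec(cup_copies$BYAT725[2L], junction = j725),
    b$F("-")
  ), right_cap = cap725)
  BYAT725 <- cell_model("BYAT725", c(list(mac725_s, mac725_l), others))

  cap721 <- telomere_cap("captured_subtelomere")
  mac721_s <- chromosome_model("chrVIII_mac1", list(
    b$left_arm(), tandem_array_spec(cup_copies$BYAT721[1L], junction = j721),
    b$E("-"), b$XVIA("-")
  ), right_cap = cap721)
  mac721_l <- chromosome_model("chrVIII_mac2", list(
    b$left_arm(), tandem_array_spec(parental_units), b$right_arm_trunc(),
    b$D("+"), tandem_array_spec(cup_copies$BYAT721[2L], junction = j721),
    b$E("-"), b$XVIA("-")
  ), right_cap = cap721)
  BYAT721 <- cell_model("BYAT721", c(list(mac721_s, mac721_l), others))

  list(parental = parental, M0 = M0, BYAT711 = BYAT711,
       BYAT725 = BYAT725, BYAT721 = BYAT721)
}

#' Fetch one built-in model by name
#' @param ref `ReferenceGenome`.
#' @param name one of `"parental"`, `"M0"`, `"BYAT711"`, `"BYAT725"`,
#'   `"BYAT721"`.
#' @param ... forwarded to [builtin_models()].
#' @return a `CellModel`.
#' @export
builtin_model <- function(ref, name, ...) {
  models <- builtin_models(ref, ...)
  if (!name %in% names(models)) stop("unknown model name: ", name)
  models[[name]]
}
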