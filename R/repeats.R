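# CUP tandem-repeat quantification by the two independent estimators:
# sequencing coverage over the reference repeat units, and EcoRI/BamHI
# restriction fragment sizes read off PFGE gels.

#' Total repeat units per cell from coverage
#'
#' The mean copies-per-cell over the reference repeat-unit positions,
#' multiplied by the number of unit copies carried by the reference
#' assembly. With a 2-unit reference, a locus at 100-fold haploid excess
#' corresponds to 200 units per cell.
#'
#' @param profile a `CopyNumberProfile`.
#' @param ref a `ReferenceGenome`.
#' @return integer estimate of total repeat units per cell.
#' @export
coverage_repeat_total <- function(profile, ref) {
  units <- ref$features[ref$features$class == "repeat_unit", , drop = FALSE]
  if (nrow(units) == 0L) stop("repeat unit not annotated in reference")
  vals <- numeric(0)
  for (i in seq_len(nrow(units))) {
    v <- profile$values[[units$chrom[i]]]
    vals <- c(vals, v[(units$start[i] + 1L):units$end[i]])
  }
  as.integer(round(mean(vals) * nrow(units)))
}

#' Convert a fold excess over haploid coverage into copies per cell
#' @param fold_excess fold excess of the locus over haploid coverage.
#' @param reference_units repeat-unit copies in the reference assembly.
#' @return copies per cell.
#' @export
fold_excess_to_copies <- function(fold_excess, reference_units = 2L) {
  fold_excess * reference_units
}

#' Repeat count from a restriction fragment size
#'
#' For the preserved normal locus the fragment is flank plus units:
#' `round((fragment - flank) / unit)`. For expanded loci the convention is
#' `floor(fragment / unit)` with no flank term (the convention that
#' reproduces the published per-locus counts; it can overcount by one unit
#' when the physical fragment carries the full flank). Internal arithmetic
#' is in nt to avoid float drift on one-decimal kb values.
#'
#' @param fragment_kb fragment size in kb (one decimal carried).
#' @param locus_kind `"normal"` or `"expanded"`.
#' @param unit_kb repeat unit size in kb.
#' @param flank_kb non-repeat flank inside the normal-locus fragment, kb.
#' @return integer repeat count.
#' @export
restriction_repeat_count <- function(fragment_kb,
                                     locus_kind = c("normal", "expanded"),
                                     unit_kb = 2, flank_kb = 2.5) {
  locus_kind <- match.arg(locus_kind)
  stopifnot(fragment_kb > 0)
  frag_nt <- as.integer(round(fragment_kb * 1000))
  unit_nt <- as.integer(round(unit_kb * 1000))
  flank_nt <- as.integer(round(flank_kb * 1000))
  if (locus_kind == "normal") {
    if (frag_nt < flank_nt) stop("fragment smaller than the locus flank")
    as.integer(round((frag_nt - flank_nt) / unit_nt))
  } else {
    as.integer(frag_nt %/% unit_nt)
  }
}

#' Reconcile restriction-based and coverage-based repeat totals
#'
#' The first fragment is the preserved normal locus; any further fragments
#' are expanded loci. Returns per-locus counts, the chromosomal total, the
#' coverage total, and their ratio (2 decimals).
#'
#' @param fragments_kb numeric vector of hybridizing EcoRI fragment sizes
#'   (kb), normal locus first.
#' @param coverage_total total units per cell from
#'   [coverage_repeat_total()]; alternatively supply `profile` and `ref`.
#' @param profile optional `CopyNumberProfile` used when `coverage_total`
#'   is missing.
#' @param ref optional `ReferenceGenome` (with `profile`).
#' @param strain strain label.
#' @return a `RepeatCountEstimate`: list with `strain`, `per_locus`
#'   (data.frame `fragment_kb`, `kind`, `repeats`), `chromosomal_total`,
#'   `coverage_total`, `ratio`.
#' @export
strain_estimate <- function(fragments_kb, coverage_total = NULL,
                            profile = NULL, ref = NULL, strain = NA_character_) {
  if (length(fragments_kb) < 1L) stop("at least one fragment required")
  if (is.null(coverage_total)) {
    if (is.null(profile) || is.null(ref)) {
      stop("supply coverage_total, or profile and ref")
    }
    coverage_total <- coverage_repeat_total(profile, ref)
  }
  kind <- c("normal", rep("expanded", length(fragments_kb) - 1L))
  reps <- vapply(seq_along(fragments_kb), function(i) {
    restriction_repeat_count(fragments_kb[i], kind[i])
  }, integer(1))
  total <- sum(reps)
  structure(
    list(strain = strain,
         per_locus = data.frame(fragment_kb = fragments_kb, kind = kind,
                                repeats = reps, stringsAsFactors = FALSE),
         chromosomal_total = total,
         coverage_total = as.integer(round(coverage_total)),
         ratio = round(coverage_total / total, 2)),
    class = "RepeatCountEstimate"
  )
}

#' @export
print.RepeatCountEstimate <- function(x, ...) {
  cat("Strain:", x$strain, "\n")
  cat("Fragments (kb):", paste(x$per_locus$fragment_kb, collapse = " + "),
      "-> repeats:", paste(x$per_locus$repeats, collapse = " + "),
      "=", x$chromosomal_total, "\n")
  cat("Coverage total:", x$coverage_total, " ratio:",
      formatC(x$ratio, format = "f", digits = 2), "\n")
  invisible(x)
}

#' Published per-strain fragment sizes and coverage totals
#'
#' The hybridizing EcoRI fragment sizes (kb; normal locus first) and the
#' coverage-derived total repeat units per cell reported for the nine
#' evolved mutants. These published measurements are inputs to
#' [strain_estimate()].
#'
#' @return data.frame with `strain`, `fragments_kb` (list column),
#'   `coverage_total`.
#' @export
mutant_strain_table <- function() {
  data.frame(
    strain = c("BYAT711", "BYAT725", "BYAT721", "BYAT722", "BYAT723",
               "BYAT724", "BYAT726", "BYAT727", "BYAT729"),
    fragments_kb = I(list(
      c(34.5, 220), c(34.5, 325, 530), c(34.5, 550, 560),
      c(34.5, 450, 540), c(34.5, 290, 450), c(34.5, 600, 690),
      c(34.5, 470, 540), c(34.5, 620, 670), c(34.5, 280, 675)
    )),
    coverage_total = c(200L, 650L, 760L, 714L, 506L, 880L, 722L, 876L, 696L),
    stringsAsFactors = FALSE
  )
}

# ---- PFGE size calibration -------------------------------------------------

#' PFGE ladder calibration
#'
#' Band migration is interpolated against log fragment size; migration
#' must be strictly increasing as size decreases.
#'
#' @param migration_cm ladder migration distances (cm).
#' @param size_kb ladder fragment sizes (kb).
#' @return a `PFGECalibration`.
#' @export
pfge_calibration <- function(migration_cm, size_kb) {
  stopifnot(length(migration_cm) == length(size_kb), length(size_kb) >= 2L)
  o <- order(migration_cm)
  migration_cm <- migration_cm[o]
  size_kb <- size_kb[o]
  if (any(diff(size_kb) >= 0)) {
    stop("size must strictly decrease with increasing migration")
  }
  structure(list(migration_cm = migration_cm, size_kb = size_kb),
            class = "PFGECalibration")
}

#' Fragment size from PFGE migration
#'
#' Monotone piecewise-linear interpolation in (migration, log size); exact
#' at ladder points; refuses to extrapolate.
#'
#' @param calibration a [pfge_calibration()].
#' @param migration_cm query migration(s), cm.
#' @return fragment size(s) in kb.
#' @export
pfge_size <- function(calibration, migration_cm) {
  rng <- range(calibration$migration_cm)
  if (any(migration_cm < rng[1L] | migration_cm > rng[2L])) {
    stop("migration outside the ladder range")
  }
  exp(stats::approx(calibration$migration_cm, log(calibration$size_kb),
                    xout = migration_cm)$y)
}

#' Table-style repeat-count report for several strains
#' @param estimates list of `RepeatCountEstimate`s.
#' @return data.frame with one row per strain.
#' @export
repeat_count_report <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(
      strain = e$strain,
      fragments_kb = paste(e$per_locus$fragment_kb, collapse = " + "),
      per_locus = paste(e$per_locus$repeats, collapse = " + "),
      chromosomal_total = e$chromosomal_total,
      coverage_total = e$coverage_total,
      ratio = e$ratio,
      stringsAsFactors = FALSE
    )
  }))
}
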