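# Construction of the scaled synthetic reference genome, including the
# confounders that shaped the original analysis: a CUP tandem-repeat locus
# whose mapping reference carries only two unit copies, sequence-identical
# dispersed delta elements at amplicon boundaries, and a chromosome-I right
# subtelomere identical to chromosome VIII's except for one unique marker
# gene.

# Fixed element sizes (never scaled; they carry the arithmetic).
UNIT_LEN <- 2000L
FLANK_HALF <- 1250L
DELTA_LEN <- 300L
TEL_LEN <- 300L
CEN_LEN <- 120L
ASN_LEN <- 1000L
IMD2_LEN <- 600L
MICRO_LEN <- 16L
MICRO_P1 <- 300L   # 0-based start of the inverted-motif copy in the unit
MICRO_GAP <- 745L  # reference spacing between the two inverted motifs

# Full-scale (scale = 1) landmark coordinates, in nt.
FULLSCALE <- list(
  len_viii = 563000L, cen_viii = 105600L,
  d_left = 116500L, f_left = 123222L, e_left = 133800L,
  yh120 = 120000L, asn_upstream = 70000L,
  cup_l = 210000L, cup_anchor = 216500L, # right-arm mapping anchor
  yh240 = 239000L, subtel = 549500L, imd2 = 553000L,
  len_xvi = 300000L, xvia_end = 56500L, yp22 = 20000L, cen_xvi = 150000L,
  len_i = 230000L, cen_i = 151000L,
  len_ii = 400000L, cen_ii = 238000L
)

# Build the canonical 2 kb repeat unit: plants the two inverted
# near-identical 16 nt motifs (quasi-palindrome substrate), removes
# EcoRI/BamHI sites, and pins the bases flanking the motifs so that
# junction-arm alignments terminate exactly at the motif boundaries.
build_repeat_unit <- function() {
  comp1 <- function(b) chartr("ACGT", "TGCA", b)
  pick_not <- function(avoid) setdiff(DNA_BASES, avoid)[1L]
  p1 <- MICRO_P1
  p2 <- MICRO_P1 + MICRO_LEN + MICRO_GAP
  repeat {
    U <- random_dna(UNIT_LEN)
    M <- random_dna(MICRO_LEN)
    if (M == revcomp(M)) next
    U <- seq_replace(U, p1, M)
    U <- seq_replace(U, p2, revcomp(M))
    U <- scrub_motifs(U, c("GAATTC", "GGATCC"))
    # motif occurrences must be unique and survive scrubbing
    if (substr(U, p1 + 1L, p1 + MICRO_LEN) != M) next
    if (substr(U, p2 + 1L, p2 + MICRO_LEN) != revcomp(M)) next
    nf <- length(gregexpr(M, U, fixed = TRUE)[[1L]])
    nr <- length(gregexpr(revcomp(M), U, fixed = TRUE)[[1L]])
    if (nf != 1L || nr != 1L) next
    # pin extension-stop bases around the motifs (1-based indices)
    iA <- p2 + MICRO_LEN + 1L
    substr(U, iA, iA) <- pick_not(comp1(substr(U, p1, p1)))
    iB <- p1 + MICRO_LEN + 1L
    substr(U, iB, iB) <- pick_not(comp1(substr(U, p2, p2)))
    if (grepl("GAATTC", U, fixed = TRUE) || grepl("GGATCC", U, fixed = TRUE)) next
    break
  }
  list(unit = U, p1 = p1, p2 = p2)
}

#' Build the scaled synthetic reference genome
#'
#' Emits four chromosome analogs: chrVIII (carrying the CUP repeat locus,
#' the Asn-RS transgene 70 kb (scaled) upstream of it, delta elements at
#' the amplicon boundaries and a 13 kb (scaled) right subtelomere), chrXVI
#' (whose left 56.5 kb (scaled) is the XVI-A amplicon), chrI (whose right
#' subtelomere is sequence-identical to chrVIII's except for the unique
#' IMD2 marker present only on chrVIII), and a neutral chrII that anchors
#' the genome-wide median at haploid coverage.
#'
#' The chromosome VIII analog has total length `round(563000 * scale)`;
#' positions left of the CUP locus scale exactly as `round(x * scale)`;
#' right-arm landmarks are mapped affinely into the remaining span (the
#' mapping is exact at `scale = 1`). Element sizes that carry arithmetic
#' (2 kb repeat unit, 2.5 kb flank total, 300 nt delta and telomere runs,
#' marker genes) are never scaled.
#'
#' @param scale genome scale factor in (0, 1]; desk-scale default 0.1.
#' @param seed integer seed for the deterministic sequence generator.
#' @param reference_cup_units number of repeat-unit copies included in the
#'   mapping reference (the historical reference assembly carries 2, while
#'   parental cells carry 16).
#' @return a [reference_genome()] with a populated `layout`.
#' @export
build_reference <- function(scale = 0.1, seed = 20160304L,
                            reference_cup_units = 2L) {
  stopifnot(scale > 0, scale <= 1)
  fs <- FULLSCALE
  sc <- function(x) as.integer(round(x * scale))

  cup_width <- 2L * FLANK_HALF + UNIT_LEN * reference_cup_units
  len_viii <- sc(fs$len_viii)
  cup_l <- sc(fs$cup_l)
  cup_r <- cup_l + cup_width
  f_right <- (len_viii - cup_r) / (fs$len_viii - fs$cup_anchor)
  pos_right <- function(x) cup_r + as.integer(round((x - fs$cup_anchor) * f_right))

  d_left <- sc(fs$d_left); f_left <- sc(fs$f_left); e_left <- sc(fs$e_left)
  cen8 <- sc(fs$cen_viii)
  asn_start <- cup_l - sc(fs$asn_upstream)
  subtel <- pos_right(fs$subtel)
  imd2 <- pos_right(fs$imd2)
  wsub <- len_viii - subtel
  if (imd2 + IMD2_LEN > len_viii - TEL_LEN) {
    imd2 <- subtel + max(20L, (wsub - TEL_LEN - IMD2_LEN) %/% 2L)
  }
  yh240 <- pos_right(fs$yh240)
  probe_w <- max(200L, sc(1000))

  # collision checks (scale too small -> features collide)
  need <- c(TEL_LEN + 100L, cen8, cen8 + CEN_LEN, d_left, d_left + DELTA_LEN,
            f_left, e_left, e_left + DELTA_LEN, asn_start,
            asn_start + ASN_LEN, cup_l - 3000L, cup_l)
  if (any(diff(need) < 0L) ||
      imd2 < subtel || imd2 + IMD2_LEN > len_viii - TEL_LEN ||
      subtel - DELTA_LEN <= yh240 + probe_w ||
      cup_r >= yh240) {
    stop("scale too small: synthetic features collide")
  }

  with_seed(seed, {
    uinfo <- build_repeat_unit()
    U <- uinfo$unit
    delta_seq <- random_dna(DELTA_LEN)
    flank_l <- paste0("GAATTC", scrub_motifs(random_dna(FLANK_HALF - 6L),
                                             c("GAATTC", "GGATCC")))
    flank_r <- scrub_motifs(random_dna(FLANK_HALF), c("GAATTC", "GGATCC"))
    cup_block <- paste0(flank_l, strrep(U, reference_cup_units), flank_r)
    left_pad <- paste0("GGATCC", scrub_motifs(random_dna(2994L), c("GAATTC", "GGATCC")))
    right_pad <- paste0("GAATTC", scrub_motifs(random_dna(2988L), c("GAATTC", "GGATCC")),
                        "GGATCC")

    chrVIII <- random_dna(len_viii)
    chrVIII <- seq_replace(chrVIII, 0L, telomere_run(TEL_LEN, seed + 11L))
    chrVIII <- seq_replace(chrVIII, len_viii - TEL_LEN,
                           revcomp(telomere_run(TEL_LEN, seed + 12L)))
    chrVIII <- seq_replace(chrVIII, d_left, delta_seq)
    chrVIII <- seq_replace(chrVIII, e_left, delta_seq)
    chrVIII <- seq_replace(chrVIII, subtel - DELTA_LEN, delta_seq)
    chrVIII <- seq_replace(chrVIII, cup_l - 3000L,
                           paste0(left_pad, cup_block, right_pad))

    len_xvi <- sc(fs$len_xvi); xvia_end <- sc(fs$xvia_end)
    chrXVI <- random_dna(len_xvi)
    chrXVI <- seq_replace(chrXVI, 0L, telomere_run(TEL_LEN, seed + 13L))
    chrXVI <- seq_replace(chrXVI, len_xvi - TEL_LEN,
                          revcomp(telomere_run(TEL_LEN, seed + 14L)))
    chrXVI <- seq_replace(chrXVI, xvia_end - DELTA_LEN, delta_seq)

    len_i <- sc(fs$len_i)
    chrI <- random_dna(len_i)
    chrI <- seq_replace(chrI, 0L, telomere_run(TEL_LEN, seed + 15L))
    # right subtelomere: identical to chrVIII's block except the IMD2 image
    sub_block <- seq_extract(chrVIII, subtel, len_viii)
    sub_block <- seq_replace(sub_block, imd2 - subtel, random_dna(IMD2_LEN))
    chrI <- seq_replace(chrI, len_i - wsub, sub_block)

    len_ii <- sc(fs$len_ii)
    chrII <- random_dna(len_ii)
    chrII <- seq_replace(chrII, 0L, telomere_run(TEL_LEN, seed + 16L))
    chrII <- seq_replace(chrII, len_ii - TEL_LEN,
                         revcomp(telomere_run(TEL_LEN, seed + 17L)))

    feat <- function(name, chrom, start, width, strand, class) {
      data.frame(name = name, chrom = chrom, start = as.integer(start),
                 end = as.integer(start + width), strand = strand,
                 class = class, stringsAsFactors = FALSE)
    }
    unit_feats <- do.call(rbind, lapply(seq_len(reference_cup_units), function(i) {
      s <- cup_l + FLANK_HALF + (i - 1L) * UNIT_LEN
      rbind(feat(paste0("CUP_unit_", i), "chrVIII", s, UNIT_LEN, "+", "repeat_unit"),
            feat(paste0("ARS_unit_", i), "chrVIII", s + uinfo$p2 + 20L, 160L, "+", "ars"))
    }))
    features <- rbind(
      feat("TEL08L", "chrVIII", 0L, TEL_LEN, "+", "telomere_motif"),
      feat("TEL08R", "chrVIII", len_viii - TEL_LEN, TEL_LEN, "+", "telomere_motif"),
      feat("CEN8", "chrVIII", cen8, CEN_LEN, "+", "centromere"),
      feat("delta_VIII_D", "chrVIII", d_left, DELTA_LEN, "+", "delta"),
      feat("delta_VIII_E", "chrVIII", e_left, DELTA_LEN, "+", "delta"),
      feat("delta_VIII_16", "chrVIII", subtel - DELTA_LEN, DELTA_LEN, "+", "delta"),
      feat("YH120", "chrVIII", sc(fs$yh120), probe_w, "+", "marker_gene"),
      feat("AsnRS", "chrVIII", asn_start, ASN_LEN, "+", "marker_gene"),
      feat("YH240", "chrVIII", yh240, probe_w, "+", "marker_gene"),
      feat("IMD2", "chrVIII", imd2, IMD2_LEN, "+", "marker_gene"),
      unit_feats,
      feat("TEL16L", "chrXVI", 0L, TEL_LEN, "+", "telomere_motif"),
      feat("TEL16R", "chrXVI", len_xvi - TEL_LEN, TEL_LEN, "+", "telomere_motif"),
      feat("CEN16", "chrXVI", sc(fs$cen_xvi), CEN_LEN, "+", "centromere"),
      feat("delta_XVI_A", "chrXVI", xvia_end - DELTA_LEN, DELTA_LEN, "+", "delta"),
      feat("YP22", "chrXVI", sc(fs$yp22), probe_w, "+", "marker_gene"),
      feat("TEL01L", "chrI", 0L, TEL_LEN, "+", "telomere_motif"),
      feat("TEL01R", "chrI", len_i - TEL_LEN, TEL_LEN, "+", "telomere_motif"),
      feat("CEN1", "chrI", sc(fs$cen_i), CEN_LEN, "+", "centromere"),
      feat("TEL02L", "chrII", 0L, TEL_LEN, "+", "telomere_motif"),
      feat("TEL02R", "chrII", len_ii - TEL_LEN, TEL_LEN, "+", "telomere_motif"),
      feat("CEN2", "chrII", sc(fs$cen_ii), CEN_LEN, "+", "centromere")
    )

    layout <- list(
      scale = scale, seed = seed,
      unit_length = UNIT_LEN, unit = U,
      micro_p1 = uinfo$p1, micro_p2 = uinfo$p2, micro_len = MICRO_LEN,
      micro_gap = MICRO_GAP,
      flank_l = flank_l, flank_r = flank_r,
      flank_total = 2L * FLANK_HALF,
      reference_cup_units = as.integer(reference_cup_units),
      delta_seq = delta_seq,
      coords = list(
        len_viii = len_viii, cen8 = cen8, d_left = d_left, f_left = f_left,
        e_left = e_left, asn_start = asn_start, cup_l = cup_l, cup_r = cup_r,
        yh240 = yh240, subtel = subtel, imd2 = imd2, wsub = wsub,
        xvia_end = xvia_end, len_xvi = len_xvi, len_i = len_i, len_ii = len_ii
      ),
      amplicons = data.frame(
        name = c("VIII-D", "VIII-E", "VIII-F", "XVI-A"),
        chrom = c("chrVIII", "chrVIII", "chrVIII", "chrXVI"),
        start = c(d_left, e_left, f_left, 0L),
        end = c(cup_l, cup_l, cup_l, xvia_end),
        stringsAsFactors = FALSE
      )
    )

    ref <- reference_genome(
      chromosomes = list(chrVIII = chrVIII, chrXVI = chrXVI,
                         chrI = chrI, chrII = chrII),
      features = features, layout = layout
    )
    # the CUP-containing EcoRI fragment must obey the flank+units identity
    frs <- insilico_digest(chrVIII, "GAATTC")
    cut_starts <- cumsum(c(0L, frs[-length(frs)]))
    i <- match(cup_l, cut_starts)
    if (is.na(i) || frs[i] != cup_width) {
      stop("internal error: CUP EcoRI fragment does not match flank + units")
    }
    ref
  })
}
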