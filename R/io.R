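# External interfaces: FASTA + BED for the reference, JSON for cell
# models, a minimal SAM dialect for alignments, bedGraph/TSV exports for
# depth and calls, BEDPE-style junction records.

#' Write a ReferenceGenome as FASTA plus a 6-column BED of features
#' @param ref `ReferenceGenome`.
#' @param fasta_path output FASTA.
#' @param bed_path output BED (0-based half-open; name column carries
#'   `name|class`).
#' @return `fasta_path`, invisibly.
#' @export
write_reference <- function(ref, fasta_path, bed_path = NULL) {
  seqs <- Biostrings::DNAStringSet(unlist(ref$chromosomes))
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(bed_path)) {
    f <- ref$features
    bed <- data.frame(f$chrom, f$start, f$end,
                      paste0(f$name, "|", f$class), 0L, f$strand)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(fasta_path)
}

#' Read a ReferenceGenome from FASTA plus the feature BED
#'
#' Rebuilds the layout (repeat unit, flanks, key coordinates) from the
#' annotated features, assuming the naming conventions of
#' [build_reference()].
#'
#' @param fasta_path FASTA path.
#' @param bed_path BED path written by [write_reference()].
#' @return a `ReferenceGenome`.
#' @export
read_reference <- function(fasta_path, bed_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  chroms <- as.list(as.character(seqs))
  names(chroms) <- sub("\\s.*$", "", names(chroms))
  bed <- utils::read.table(bed_path, sep = "\t", stringsAsFactors = FALSE)
  nm <- strsplit(bed$V4, "|", fixed = TRUE)
  features <- data.frame(
    name = vapply(nm, `[`, "", 1L), chrom = bed$V1,
    start = bed$V2, end = bed$V3, strand = bed$V6,
    class = vapply(nm, `[`, "", 2L), stringsAsFactors = FALSE
  )
  fi <- function(name) features[features$name == name, , drop = FALSE][1L, ]
  u1 <- fi("CUP_unit_1")
  units <- features[features$class == "repeat_unit", , drop = FALSE]
  unit <- substr(chroms[[u1$chrom]], u1$start + 1L, u1$end)
  cup_l <- u1$start - FLANK_HALF
  cup_r <- max(units$end) + FLANK_HALF
  M <- substr(unit, MICRO_P1 + 1L, MICRO_P1 + MICRO_LEN)
  layout <- list(
    scale = NA_real_, seed = NA_integer_,
    unit_length = nchar(unit), unit = unit,
    micro_p1 = MICRO_P1, micro_p2 = MICRO_P1 + MICRO_LEN + MICRO_GAP,
    micro_len = MICRO_LEN, micro_gap = MICRO_GAP,
    flank_l = substr(chroms[[u1$chrom]], cup_l + 1L, cup_l + FLANK_HALF),
    flank_r = substr(chroms[[u1$chrom]], cup_r - FLANK_HALF + 1L, cup_r),
    flank_total = 2L * FLANK_HALF,
    reference_cup_units = nrow(units),
    delta_seq = {
      d <- features[features$class == "delta", , drop = FALSE][1L, ]
      substr(chroms[[d$chrom]], d$start + 1L, d$end)
    },
    coords = list(
      len_viii = nchar(chroms$chrVIII), cen8 = fi("CEN8")$start,
      d_left = fi("delta_VIII_D")$start, f_left = NA_integer_,
      e_left = fi("delta_VIII_E")$start,
      asn_start = fi("AsnRS")$start, cup_l = cup_l, cup_r = cup_r,
      yh240 = fi("YH240")$start, subtel = fi("delta_VIII_16")$end,
      imd2 = fi("IMD2")$start,
      wsub = nchar(chroms$chrVIII) - fi("delta_VIII_16")$end,
      xvia_end = fi("delta_XVI_A")$end,
      len_xvi = nchar(chroms$chrXVI), len_i = nchar(chroms$chrI),
      len_ii = nchar(chroms$chrII)
    )
  )
  reference_genome(chroms, features, layout)
}

# ---- cell model JSON -------------------------------------------------------

part_to_list <- function(p) {
  if (inherits(p, "SegmentSpec")) {
    list(type = "segment", chrom = p$chrom, start = p$start, end = p$end,
         orientation = p$orientation, label = p$label)
  } else {
    out <- list(type = "tandem_array", copy_count = p$copy_count)
    if (!is.null(p$junction)) {
      out$junction_index <- p$junction_index
      out$junction <- p$junction[c("kind", "loop_length", "loop_seq",
                                   "switch_offset", "microhomology_length",
                                   "reference_spacing", "arm_mismatches")]
    }
    out
  }
}

part_from_list <- function(x) {
  if (x$type == "segment") {
    segment_spec(x$chrom, x$start, x$end, x$orientation, x$label)
  } else {
    j <- NULL
    if (!is.null(x$junction)) {
      j <- do.call(palindrome_spec, x$junction)
    }
    tandem_array_spec(x$copy_count, junction = j,
                      junction_index = x$junction_index)
  }
}

#' Serialize a CellModel to JSON
#' @param cell a `CellModel`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
cell_to_json <- function(cell, path = NULL) {
  x <- list(
    name = cell$name,
    chromosomes = lapply(cell$chromosomes, function(cm) {
      list(name = cm$name,
           parts = lapply(cm$parts, part_to_list),
           left_cap = cm$left_cap[c("kind", "seed")],
           right_cap = cm$right_cap[c("kind", "seed")])
    }),
    episomes = lapply(cell$episomes, part_to_list)
  )
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a CellModel from JSON
#' @param path JSON file path or JSON string.
#' @return a `CellModel`.
#' @export
cell_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  chroms <- lapply(x$chromosomes, function(cm) {
    chromosome_model(
      cm$name, lapply(cm$parts, part_from_list),
      left_cap = telomere_cap(cm$left_cap$kind, cm$left_cap$seed),
      right_cap = telomere_cap(cm$right_cap$kind, cm$right_cap$seed)
    )
  })
  cell_model(x$name, chroms, episomes = lapply(x$episomes, part_from_list))
}

# ---- SAM -------------------------------------------------------------------

#' Write an AlignmentSet as minimal SAM
#'
#' Emits `@SQ` header lines, FLAG (0/16 strand, 4 unmapped), 1-based POS,
#' all-`M` CIGAR, and the `NM` tag. Multi-placement rows under the
#' `"split"` policy all carry the secondary-alignment bit except the
#' first.
#'
#' @param alignments an `AlignmentSet`.
#' @param ref a `ReferenceGenome`.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, ref, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (chrom in names(ref$chromosomes)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", chrom,
                       nchar(ref$chromosomes[[chrom]])), con)
  }
  reads <- alignments$reads
  aln <- alignments$alignments
  w <- nchar(reads$seq[match(aln$id, reads$id)])
  sec <- duplicated(aln$id)
  flags <- ifelse(aln$strand == "-", 16L, 0L) + ifelse(sec, 256L, 0L)
  seqs <- reads$seq[match(aln$id, reads$id)]
  neg <- aln$strand == "-"
  if (any(neg)) seqs[neg] <- revcomp_many(seqs[neg])
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                   aln$id, flags, aln$chrom, aln$pos + 1L,
                   ifelse(aln$ambiguous, 0L, 60L), w, seqs, aln$mismatches)
  writeLines(lines, con)
  un <- alignments$unmapped
  if (nrow(un) > 0L) {
    writeLines(sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", un$id, un$seq),
               con)
  }
  invisible(path)
}

#' Read a minimal SAM file into an AlignmentSet
#'
#' Understands the dialect written by [write_sam()]: header `@SQ` lines,
#' FLAG strand and unmapped bits, POS, all-`M` CIGAR, optional NM tag.
#'
#' @param path SAM path.
#' @param ref a `ReferenceGenome`.
#' @return an `AlignmentSet`.
#' @export
read_sam <- function(path, ref) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  fields <- strsplit(body, "\t", fixed = TRUE)
  flag <- vapply(fields, function(f) as.integer(f[2L]), integer(1))
  unmapped <- bitwAnd(flag, 4L) > 0L
  neg <- bitwAnd(flag, 16L) > 0L
  id <- vapply(fields, `[`, "", 1L)
  seq <- vapply(fields, `[`, "", 10L)
  seq_fwd <- seq
  if (any(neg)) seq_fwd[neg] <- revcomp_many(seq[neg])
  nm <- vapply(fields, function(f) {
    hit <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(hit) > 0L) as.integer(sub("NM:i:", "", hit[1L])) else 0L
  }, integer(1))
  keep <- !unmapped
  aln <- data.frame(
    id = id[keep],
    chrom = vapply(fields[keep], `[`, "", 3L),
    pos = vapply(fields[keep], function(f) as.integer(f[4L]), integer(1)) - 1L,
    strand = ifelse(neg[keep], "-", "+"),
    mismatches = nm[keep],
    weight = 1,
    ambiguous = vapply(fields[keep], function(f) as.integer(f[5L]), integer(1)) == 0L,
    stringsAsFactors = FALSE
  )
  first <- !duplicated(id)
  structure(
    list(alignments = aln,
         unmapped = data.frame(id = id[unmapped & first],
                               seq = seq_fwd[unmapped & first],
                               stringsAsFactors = FALSE),
         reads = data.frame(id = id[first], seq = seq_fwd[first],
                            stringsAsFactors = FALSE),
         policy = "first", chrom_names = names(ref$chromosomes)),
    class = "AlignmentSet"
  )
}

# ---- tracks and call tables ------------------------------------------------

#' Export depth vectors as bedGraph
#' @param depth named list of numeric vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(depth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(depth)) {
    v <- depth[[chrom]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- c(0L, ends[-length(ends)])
    writeLines(sprintf("%s\t%d\t%d\t%g", chrom, starts, ends, r$values), con)
  }
  invisible(path)
}

#' Export amplicon or deletion calls as BED (score = extra copies)
#' @param calls data.frame with `chrom`, `start`, `end` and either `name`
#'   and `extra_copies` (amplicons) or `evidence` (deletions).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  name <- if ("name" %in% names(calls)) calls$name else calls$evidence
  score <- if ("extra_copies" %in% names(calls)) calls$extra_copies else 0L
  bed <- data.frame(calls$chrom, calls$start, calls$end, name, score, "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export junction calls as TSV and BEDPE-style breakpoint records
#' @param junctions data.frame from [find_junctions()].
#' @param tsv_path output TSV.
#' @param bedpe_path optional BEDPE output (two single-base anchors).
#' @return `tsv_path`, invisibly.
#' @export
write_junctions <- function(junctions, tsv_path, bedpe_path = NULL) {
  utils::write.table(junctions[, setdiff(names(junctions), "contig")],
                     tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bedpe_path)) {
    j <- junctions[!is.na(junctions$pos1), , drop = FALSE]
    pos2 <- ifelse(is.na(j$pos2), j$pos1, j$pos2)
    bedpe <- data.frame(j$chrom, j$pos1, j$pos1 + 1L,
                        j$chrom, pos2, pos2 + 1L,
                        j$class, round(j$copy_number, 3), "+", "-")
    utils::write.table(bedpe, bedpe_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(tsv_path)
}

#' Write junction contigs as FASTA
#' @param contigs data.frame from [assemble_junctions()].
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
write_contigs_fasta <- function(contigs, path) {
  ids <- sprintf("contig_%03d support=%d copies=%.2f", seq_len(nrow(contigs)),
                 contigs$supporting_read_count, contigs$support_copies)
  writeLines(as.vector(rbind(paste0(">", ids), contigs$contig)), path)
  invisible(path)
}

#' Export a copy-number profile as TSV (one row per run of equal value)
#' @param profile a `CopyNumberProfile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  rows <- list()
  for (chrom in names(profile$values)) {
    v <- round(profile$values[[chrom]], 4)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    rows[[chrom]] <- data.frame(chrom = chrom,
                                start = c(0L, ends[-length(ends)]),
                                end = ends, copies = r$values)
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
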