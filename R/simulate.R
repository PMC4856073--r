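# Uniform short-read simulation from a realized cell, with a simple i.i.d.
# substitution error model and per-read truth tracking.

#' Simulation configuration
#' @param coverage target fold coverage (>= 0); desk-scale default 50.
#' @param read_length read length in nt (30..500).
#' @param substitution_error_rate per-base substitution probability (<= 0.05).
#' @param seed RNG seed.
#' @param scale genome scale factor this configuration is meant for
#'   (carried for bookkeeping).
#' @return a `SimulationConfig`.
#' @export
simulation_config <- function(coverage = 50, read_length = 100L,
                              substitution_error_rate = 0.001,
                              seed = 1L, scale = 0.1) {
  stopifnot(coverage >= 0, read_length >= 30L, read_length <= 500L,
            substitution_error_rate >= 0, substitution_error_rate <= 0.05)
  structure(list(coverage = coverage, read_length = as.integer(read_length),
                 substitution_error_rate = substitution_error_rate,
                 seed = as.integer(seed), scale = scale),
            class = "SimulationConfig")
}

# Inject i.i.d. substitution errors into a character vector of reads.
add_substitution_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  L <- nchar(seqs[1L])
  n_err <- stats::rbinom(length(seqs), L, rate)
  idx <- which(n_err > 0L)
  for (i in idx) {
    pos <- sample.int(L, n_err[i])
    s <- seqs[i]
    for (p in pos) {
      b <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(DNA_BASES, b), 1L)
    }
    seqs[i] <- s
  }
  seqs
}

#' Simulate uniform single-end reads from a cell model
#'
#' Reads are drawn uniformly over the realized sequence pool (all
#' chromosomes plus circular episomes; episomal reads may wrap the origin),
#' on either strand with equal probability. The expected read count is
#' `coverage * total_length / read_length`. Deterministic under a fixed
#' seed.
#'
#' @param cell a `CellModel`.
#' @param ref a `ReferenceGenome`.
#' @param config a [simulation_config()].
#' @return a `ReadSet`: list with `reads` (data.frame `id`, `seq`) and
#'   `truth` (data.frame `id`, `molecule`, `pos` (0-based start on the
#'   realized molecule), `strand`).
#' @export
simulate_reads <- function(cell, ref, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  pool <- realize_cell(cell, ref)
  mols <- c(pool$chromosomes, pool$episomes)
  if (length(pool$episomes) > 0L) {
    names(mols)[seq_along(pool$episomes) + length(pool$chromosomes)] <-
      paste0("episome_", seq_along(pool$episomes))
  }
  circular <- c(rep(FALSE, length(pool$chromosomes)), rep(TRUE, length(pool$episomes)))
  lens <- vapply(mols, nchar, integer(1))
  if (sum(lens) == 0L) stop("realized genome is empty")
  L <- config$read_length
  n_reads <- as.integer(round(config$coverage * sum(lens) / L))
  empty <- list(
    reads = data.frame(id = character(0), seq = character(0)),
    truth = data.frame(id = character(0), molecule = character(0),
                       pos = integer(0), strand = character(0))
  )
  class(empty) <- "ReadSet"
  if (n_reads == 0L) return(empty)

  with_seed(config$seed, {
    # effective sampling length per molecule (linear molecules lose L-1
    # start positions at the right end)
    eff <- ifelse(circular, lens, pmax(0L, lens - L + 1L))
    mi <- sample.int(length(mols), n_reads, replace = TRUE, prob = eff)
    pos <- integer(n_reads)
    seqs <- character(n_reads)
    for (k in seq_along(mols)) {
      sel <- which(mi == k)
      if (length(sel) == 0L) next
      p <- sample.int(eff[k], length(sel), replace = TRUE) - 1L
      s <- mols[[k]]
      if (circular[k]) {
        s2 <- paste0(s, substr(s, 1L, L)) # allow wrap-around
        seqs[sel] <- substring(s2, p + 1L, p + L)
      } else {
        seqs[sel] <- substring(s, p + 1L, p + L)
      }
      pos[sel] <- p
    }
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    neg <- strand == "-"
    if (any(neg)) seqs[neg] <- revcomp_many(seqs[neg])
    seqs <- add_substitution_errors(seqs, config$substitution_error_rate)
    ids <- sprintf("read_%07d", seq_len(n_reads))
    out <- list(
      reads = data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE),
      truth = data.frame(id = ids, molecule = names(mols)[mi], pos = pos,
                         strand = strand, stringsAsFactors = FALSE)
    )
    class(out) <- "ReadSet"
    out
  })
}

#' Write a ReadSet as FASTQ (constant quality) plus a truth table TSV
#' @param readset a `ReadSet`.
#' @param fastq_path output FASTQ path.
#' @param truth_path optional truth-table TSV path.
#' @return `fastq_path`, invisibly.
#' @export
write_readset <- function(readset, fastq_path, truth_path = NULL) {
  r <- readset$reads
  qual <- strrep("I", nchar(r$seq))
  lines <- as.vector(rbind(paste0("@", r$id), r$seq, "+", qual))
  writeLines(lines, fastq_path)
  if (!is.null(truth_path)) {
    utils::write.table(readset$truth, truth_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(fastq_path)
}

#' Read a FASTQ file into a ReadSet (no truth table)
#' @param path FASTQ path.
#' @return a `ReadSet` with empty truth.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  stopifnot(length(lines) %% 4L == 0L)
  ids <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
  ids <- sub("\\s.*$", "", ids)
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  out <- list(reads = data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE),
              truth = data.frame(id = character(0), molecule = character(0),
                                 pos = integer(0), strand = character(0)))
  class(out) <- "ReadSet"
  out
}
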