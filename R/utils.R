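# Low-level sequence and RNG helpers shared across the package.

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators inside the
#' package never disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Random DNA string
#' @param n length in nucleotides.
#' @return character scalar of length `n`.
#' @keywords internal
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of a DNA character string
#' @param x character scalar (ACGT alphabet).
#' @return reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return("")
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

# Vectorised reverse complement via Biostrings (fast for many sequences).
revcomp_many <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 0-based half-open substring extraction (internal coordinate convention).
seq_extract <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

# Overwrite seq[start, end) (0-based half-open) with `value`.
seq_replace <- function(seq, start, value) {
  stopifnot(start >= 0, start + nchar(value) <= nchar(seq))
  paste0(substr(seq, 1L, start), value, substr(seq, start + nchar(value) + 1L, nchar(seq)))
}

# Remove every occurrence of the given motifs (and their reverse
# complements) by point substitution; used to guarantee, e.g., the absence
# of EcoRI/BamHI sites inside the repeat unit.
scrub_motifs <- function(seq, motifs) {
  all_motifs <- unique(c(motifs, vapply(motifs, revcomp, "")))
  repeat {
    hit <- NULL
    for (m in all_motifs) {
      p <- regexpr(m, seq, fixed = TRUE)
      if (p > 0) {
        hit <- as.integer(p)
        break
      }
    }
    if (is.null(hit)) break
    # flip the middle base of the occurrence
    i <- hit + 2L
    base <- substr(seq, i, i)
    repl <- setdiff(DNA_BASES, base)[1L]
    substr(seq, i, i) <- repl
  }
  seq
}

# Deterministic telomeric repeat run on the C-rich strand: (C{1,3}A)+,
# trimmed to n nt. Yeast-style degenerate telomeric repeats.
telomere_run <- function(n = 300L, seed = 1L) {
  with_seed(seed, {
    ks <- sample(1:3, ceiling(n / 2) + 4L, replace = TRUE)
    s <- paste(vapply(ks, function(k) paste0(strrep("C", k), "A"), ""), collapse = "")
    substr(s, 1L, n)
  })
}

# Does either end of a sequence look telomeric? Returns the matched length
# of the longest telomeric run anchored at the given end (0 if none).
telomeric_anchor <- function(seq, end = c("left", "right"), min_len = 15L) {
  end <- match.arg(end)
  # tolerate a partial leading repeat on either pattern phase
  pats <- c("^(A?(C{1,3}A)+C{0,3})", "^(G{0,3}(TG{1,3})+T?)")
  s <- if (end == "left") seq else revcomp(seq)
  best <- 0L
  for (p in pats) {
    m <- regexpr(p, s, perl = TRUE)
    if (m > 0) best <- max(best, attr(m, "match.length"))
  }
  if (best >= min_len) best else 0L
}

# Count mismatches between equal-length character strings (vectorised over
# pairs). Used by the mapper's extension stage.
count_mismatch_pairs <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(integer(0))
  vapply(seq_along(a), function(i) {
    x <- utf8ToInt(a[[i]])
    y <- utf8ToInt(b[[i]])
    if (length(x) != length(y)) return(NA_integer_)
    sum(x != y)
  }, integer(1))
}

# Match/mismatch logical vector between two equal-length strings.
match_vector <- function(a, b) {
  utf8ToInt(a) == utf8ToInt(b)
}

# Centered moving average with shrinking windows at the edges.
running_mean <- function(x, window) {
  n <- length(x)
  if (window <= 1L) return(x)
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
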