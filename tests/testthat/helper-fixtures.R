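# Shared fixtures (built lazily, cached for the whole run) and
# independent oracles used by the property tests.

fx <- new.env(parent = emptyenv())

fx_ref <- function() {
  if (is.null(fx$ref)) fx$ref <- build_reference(0.1)
  fx$ref
}

fx_models <- function() {
  if (is.null(fx$models)) fx$models <- builtin_models(fx_ref())
  fx$models
}

# Full simulate -> analyze -> enumerate round trip, one per built-in model,
# at the study conditions (0.1-scale genome, 50x coverage, 0.1% errors).
fx_roundtrip <- function(name) {
  key <- paste0("rt_", name)
  if (is.null(fx[[key]])) {
    fx[[key]] <- pipeline_roundtrip(
      fx_models()[[name]], fx_ref(),
      simulation_config(coverage = 50, seed = 11)
    )
  }
  fx[[key]]
}

# Per-atom expected-level table builders for hand-written constraint sets.
fx_levels_viii <- function(l) {
  co <- fx_ref()$layout$coords
  data.frame(chrom = "chrVIII",
             start = c(0L, co$d_left, co$f_left, co$e_left, co$cup_r, co$subtel),
             end = c(co$d_left, co$f_left, co$e_left, co$cup_l, co$subtel,
                     co$len_viii),
             level = l)
}

fx_levels_xvi <- function(l) {
  co <- fx_ref()$layout$coords
  data.frame(chrom = "chrXVI", start = c(0L, co$xvia_end),
             end = c(co$xvia_end, co$len_xvi), level = l)
}

fx_bands <- function(cell) {
  b <- predict_observables(cell, fx_ref())$bands
  b$size_kb[grepl("VIII", b$chrom)]
}

# The explicit constraint sets of the observed strains (levels, junction
# classes, delta-junction counts and band sizes as the study reports them).
fx_constraints_711 <- function() {
  if (is.null(fx$cs711)) {
    fx$cs711 <- constraint_set(
      fx_ref(), ploidy_viii = 2,
      expected_levels = rbind(fx_levels_viii(c(2, 3, 3, 4, 2, 2)),
                              fx_levels_xvi(c(1, 1))),
      array_classes = "strand_switch", expanded_units = 30L,
      band_sizes_kb = fx_bands(fx_models()$BYAT711),
      n_delta_junctions = 1L
    )
  }
  fx$cs711
}

fx_constraints_parental <- function() {
  constraint_set(
    fx_ref(), ploidy_viii = 1,
    expected_levels = rbind(fx_levels_viii(rep(1, 6)), fx_levels_xvi(c(1, 1))),
    array_classes = character(0),
    band_sizes_kb = fx_bands(fx_models()$parental),
    n_delta_junctions = 0L
  )
}

# ---- independent oracles ---------------------------------------------------

# Exhaustive ungapped placement oracle: is there any placement of the
# read, on either strand of any chromosome, with at most max_mm
# substitutions?
oracle_mappable <- function(read, ref, max_mm) {
  for (chrom in names(ref$chromosomes)) {
    subj <- Biostrings::DNAString(ref$chromosomes[[chrom]])
    for (q in c(read, revcomp(read))) {
      if (Biostrings::countPattern(q, subj, max.mismatch = max_mm) > 0L) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Brute-force minimum-cardinality staircase decomposition: iterative
# deepening over interval multisets with integer weights.
oracle_min_calls <- function(h) {
  n <- length(h)
  if (all(h == 0L)) return(0L)
  maxh <- max(h)
  cands <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      for (w in seq_len(maxh)) {
        v <- integer(n)
        v[i:j] <- w
        cands[[length(cands) + 1L]] <- v
      }
    }
  }
  found <- function(target, k, from) {
    if (all(target == 0L)) return(TRUE)
    if (k == 0L) return(FALSE)
    for (ci in from:length(cands)) {
      v <- cands[[ci]]
      if (all(target - v >= 0L)) {
        if (found(target - v, k - 1L, ci)) return(TRUE)
      }
    }
    FALSE
  }
  for (k in 1:8) if (found(h, k, 1L)) return(k)
  NA_integer_
}

# Independent permutation-orientation count of valid single-macrotene
# cassette arrangements: middle parts between the left arm (cup-left edge)
# and the full right arm (cup-right edge), joined under the rules
# "array end meets a locus edge" / "delta meets delta", written from
# scratch as plain lookup tables.
oracle_arrangements <- function(middle_parts) {
  ends <- list(
    Aexp = c("arr", "arr"), Anorm = c("arr", "arr"),
    D = c("delta", "cupL"), E = c("delta", "cupL")
  )
  ok_join <- function(a, b) {
    (a == "arr" && b %in% c("cupL", "cupR")) ||
      (b == "arr" && a %in% c("cupL", "cupR")) ||
      (a == "delta" && b == "delta")
  }
  n <- length(middle_parts)
  perm_idx <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_idx(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  count <- 0L
  seen <- character(0)
  for (ord in perm_idx(seq_len(n))) {
    parts <- middle_parts[ord]
    n_or <- 2L^n
    for (mask in seq_len(n_or) - 1L) {
      flips <- as.logical(bitwAnd(mask, 2L^(seq_len(n) - 1L)))
      # arrays have identical ends; skip flipped duplicates
      if (any(flips & parts %in% c("Aexp", "Anorm"))) next
      labs <- lapply(seq_len(n), function(i) {
        e <- ends[[parts[i]]]
        if (flips[i]) rev(e) else e
      })
      valid <- ok_join("cupL", labs[[1L]][1L])
      if (valid && n > 1L) {
        for (i in seq_len(n - 1L)) {
          if (!ok_join(labs[[i]][2L], labs[[i + 1L]][1L])) {
            valid <- FALSE
            break
          }
        }
      }
      if (valid) valid <- ok_join(labs[[n]][2L], "cupR")
      if (valid) {
        sig <- paste(parts, ifelse(flips, "-", "+"), collapse = "|")
        if (!sig %in% seen) {
          seen <- c(seen, sig)
          count <- count + 1L
        }
      }
    }
  }
  count
}
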