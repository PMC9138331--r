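# Independent brute-force oracles for the exact algebra, built on
# Biostrings' IUPAC code table rather than the package's own map, so the
# two routes share no code.

oracle_base_sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "")

# all concrete expansions of an IUPAC string, by exhaustive enumeration
oracle_expand <- function(s) {
  sets <- oracle_base_sets[strsplit(s, "")[[1L]]]
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  sort(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste,
             collapse = ""))
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

# minimum Hamming distance between a concrete window and any expansion
oracle_min_hamming <- function(primer, window) {
  min(vapply(oracle_expand(primer), oracle_hamming, numeric(1), b = window))
}

# concrete (non-degenerate) dimer score: longest complementary run over
# all ungapped offsets of a against reversed b
oracle_concrete_dimer <- function(a, b) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  av <- strsplit(a, "")[[1L]]
  bv <- rev(strsplit(b, "")[[1L]])
  na <- length(av); nb <- length(bv)
  best <- 0L
  for (off in seq(-(nb - 1L), na - 1L)) {
    run <- 0L
    for (i in seq(max(1L, off + 1L), min(na, off + nb))) {
      if (comp[av[i]] == bv[i - off]) {
        run <- run + 1L
        best <- max(best, run)
      } else {
        run <- 0L
      }
    }
  }
  best
}

oracle_dimer <- function(a, b) {
  max(vapply(oracle_expand(a), function(ax) {
    max(vapply(oracle_expand(b), function(bx) {
      oracle_concrete_dimer(ax, bx)
    }, numeric(1)))
  }, numeric(1)))
}

# brute-force hairpin: max admissible stem (>= min_stem, loop >= min_loop)
# over all stem/loop decompositions of a concrete sequence
oracle_concrete_hairpin <- function(a, min_loop = 3L, min_stem = 3L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  v <- strsplit(a, "")[[1L]]
  n <- length(v)
  best <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0L
    while (i + s <= n && j - s >= 1L && (j - s) - (i + s) - 1L >= min_loop &&
           comp[v[i + s]] == v[j - s]) {
      s <- s + 1L
    }
    if (s >= min_stem) best <- max(best, s)
  }
  best
}

oracle_hairpin <- function(a, min_loop = 3L, min_stem = 3L) {
  max(vapply(oracle_expand(a), oracle_concrete_hairpin, numeric(1),
             min_loop = min_loop, min_stem = min_stem))
}

# naive all-windows priming-site scan on a circular or linear template
oracle_find_sites <- function(primer, template, max_mismatch = 2L,
                              clamp_len = 3L, circular = TRUE) {
  pv <- strsplit(primer, "")[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  rc <- paste(rev(comp[pv]), collapse = "")
  tv <- strsplit(template, "")[[1L]]
  L <- length(tv)
  plen <- length(pv)
  matches <- function(psym, tsym) {
    length(intersect(oracle_base_sets[[psym]], oracle_base_sets[[tsym]])) > 0L
  }
  hits <- list()
  starts <- if (circular) 0:(L - 1L) else 0:(L - plen)
  for (strand in c("+", "-")) {
    pat <- strsplit(if (strand == "+") primer else rc, "")[[1L]]
    clamp_idx <- if (clamp_len == 0L) integer() else if (strand == "+") {
      seq(plen - clamp_len + 1L, plen)
    } else {
      seq_len(clamp_len)
    }
    for (s in starts) {
      win <- tv[((s + seq_len(plen) - 1L) %% L) + 1L]
      mm <- sum(!mapply(matches, pat, win))
      mm_clamp <- sum(!mapply(matches, pat[clamp_idx], win[clamp_idx]))
      if (mm <= max_mismatch && mm_clamp == 0L) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = s, end = s + plen, strand = strand, mismatches = mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random IUPAC sequence with degeneracy at most max_deg (rejection
# sampling; ambiguity-rich alphabet weighting keeps acceptance high)
rand_iupac <- function(len, max_deg = Inf,
                       weights = c(rep(8, 4), rep(2, 6), rep(1, 4), 1)) {
  codes <- names(Biostrings::IUPAC_CODE_MAP)
  repeat {
    s <- paste(sample(codes, len, replace = TRUE, prob = weights),
               collapse = "")
    if (degeneracy(s) <= max_deg) return(s)
  }
}

rand_concrete <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
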