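# Conserved-window scanning over multiple alignments and enumeration of
# degenerate primer candidates/pairs under length and degeneracy budgets.
# This automates the by-eye identification of conserved priming regions:
# a column's consensus symbol covers every base seen at or above a
# frequency threshold, and windows are scored by how many alignment rows
# they match exactly.

#' Build a per-column base-count profile from a multiple alignment
#'
#' Counts A/C/G/T and gap observations in every alignment column.
#' Ambiguity codes in the input rows are counted fractionally across their
#' base sets (an R adds 1/2 to A and 1/2 to G), so profiles built from
#' partially ambiguous GenBank sequences remain well calibrated.
#'
#' @param sequences Named character vector of aligned sequences (equal
#'   lengths; `-` and `.` are gaps), or a `Biostrings::DNAStringSet`.
#' @param name Label for the source alignment (e.g. the gene name);
#'   propagated to candidates as their `gene_location`.
#' @return An object of class `alignment_profile`: a list with `counts`
#'   (5 x L matrix, rows A,C,G,T,gap), `n_sequences`, `source_name` and the
#'   input `sequences` (kept for coverage computation).
#' @examples
#' p <- build_profile(c(s1 = "ACG", s2 = "ACG", s3 = "ACG"), name = "toy")
#' p$counts
#' @export
build_profile <- function(sequences, name = "alignment") {
  if (methods::is(sequences, "XStringSet")) {
    sequences <- as.character(sequences)
  }
  if (length(sequences) < 2L) {
    stop("an alignment needs at least 2 sequences", call. = FALSE)
  }
  sequences <- toupper(sequences)
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: sequence lengths differ (",
         paste(unique(widths), collapse = ", "), ")", call. = FALSE)
  }
  L <- widths[1L]
  if (L == 0L) stop("alignment has zero columns", call. = FALSE)
  mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  mat[mat == "."] <- "-"
  ok <- mat %in% c(names(.IUPAC_MASK), "-")
  if (!all(ok)) {
    stop("invalid character '", mat[!ok][1L], "' in alignment", call. = FALSE)
  }
  counts <- matrix(0, nrow = 5L, ncol = L,
                   dimnames = list(c("A", "C", "G", "T", "gap"), NULL))
  for (j in seq_len(L)) {
    col <- mat[, j]
    counts["gap", j] <- sum(col == "-")
    for (sym in unique(col[col != "-"])) {
      bs <- .IUPAC_BASES[[sym]]
      counts[bs, j] <- counts[bs, j] + sum(col == sym) / length(bs)
    }
  }
  structure(list(counts = counts, n_sequences = length(sequences),
                 source_name = name, sequences = sequences),
            class = "alignment_profile")
}

#' @export
print.alignment_profile <- function(x, ...) {
  cat(sprintf("alignment_profile '%s': %d sequences x %d columns\n",
              x$source_name, x$n_sequences, ncol(x$counts)))
  invisible(x)
}

#' Degenerate consensus symbol for one alignment column
#'
#' The consensus covers every base whose frequency among non-gap
#' observations is at least `min_base_freq`; the minimal IUPAC code for
#' that set is returned. If no base reaches the threshold the single most
#' frequent base is used, breaking ties alphabetically (deterministic).
#' All-gap columns return `NA`, which disqualifies any window containing
#' them.
#'
#' @param counts Numeric vector of counts named A,C,G,T (a `gap` element is
#'   ignored), e.g. one column of an [build_profile()] counts matrix.
#' @param min_base_freq Minimum base frequency to be covered (default
#'   0.05: a base seen in at least 5\% of sequences enters the consensus).
#' @return A single IUPAC symbol, or `NA_character_` for all-gap columns.
#' @examples
#' consensus_column(c(A = 5, C = 0, G = 5, T = 0))  # "R"
#' @export
consensus_column <- function(counts, min_base_freq = 0.05) {
  bc <- counts[c("A", "C", "G", "T")]
  if (any(is.na(bc)) || any(bc < 0)) stop("counts must be non-negative")
  tot <- sum(bc)
  if (tot == 0) return(NA_character_)
  keep <- names(bc)[bc / tot >= min_base_freq]
  if (length(keep) == 0L) {
    keep <- names(bc)[bc == max(bc)][1L]  # lexicographically first maximum
  }
  minimal_code(keep)
}

# Per-column consensus masks, cardinalities and disqualification flags for
# a profile; shared by scan_windows and pair_primers.
.profile_consensus <- function(profile, min_base_freq, max_gap_fraction) {
  counts <- profile$counts
  L <- ncol(counts)
  syms <- vapply(seq_len(L), function(j) {
    consensus_column(counts[, j], min_base_freq)
  }, character(1))
  gap_frac <- counts["gap", ] / profile$n_sequences
  disq <- is.na(syms) | gap_frac > max_gap_fraction
  masks <- ifelse(is.na(syms), 0L, .IUPAC_MASK[ifelse(is.na(syms), "N", syms)])
  list(symbols = syms, masks = as.integer(masks),
       card = .CARDINALITY[as.integer(masks) + 1L], disqualified = disq,
       gap_column = gap_frac > 0.5)
}

#' Scan an alignment profile for degenerate primer candidates
#'
#' Every window within the length range whose columns are all usable (not
#' all-gap, gap fraction within `max_gap_fraction`) yields the consensus
#' degenerate sequence; windows within the degeneracy budget are emitted in
#' both orientations. Coverage is the fraction of alignment rows the
#' consensus matches with zero mismatches (rows with a gap in the window do
#' not count as matched). Output order is deterministic: ascending
#' degeneracy, then descending coverage, then ascending start.
#'
#' @param profile An [build_profile()] result.
#' @param length_range Integer pair, allowed primer lengths (default
#'   c(18, 26); must lie within 15-35).
#' @param max_degeneracy Degeneracy budget per primer (default 216, the
#'   level retained for final wet testing; up to 1536 was trialled).
#' @param max_gap_fraction Columns gappier than this disqualify windows
#'   (default 0.10).
#' @param min_base_freq Passed to [consensus_column()].
#' @return Data frame of candidates: `sequence`, `alignment_start` (0-based
#'   column of the site on the forward strand), `length`, `orientation`
#'   ("forward"/"reverse"; reverse sequences are given 5'->3' in primer
#'   orientation), `degeneracy`, `coverage_fraction`, `three_prime_clamp`
#'   (TRUE when the last 3 primer positions are ambiguity-free) and
#'   `gene_location`.
#' @export
scan_windows <- function(profile, length_range = c(18L, 26L),
                         max_degeneracy = 216, max_gap_fraction = 0.10,
                         min_base_freq = 0.05) {
  stopifnot(inherits(profile, "alignment_profile"))
  length_range <- as.integer(length_range)
  if (length_range[1L] < 15L || length_range[2L] > 35L ||
      length_range[1L] > length_range[2L]) {
    stop("length_range must be an increasing pair within [15, 35]",
         call. = FALSE)
  }
  if (max_degeneracy < 1) stop("max_degeneracy must be >= 1", call. = FALSE)
  L <- ncol(profile$counts)
  empty <- data.frame(sequence = character(), alignment_start = integer(),
                      length = integer(), orientation = character(),
                      degeneracy = numeric(), coverage_fraction = numeric(),
                      three_prime_clamp = logical(),
                      gene_location = character(),
                      stringsAsFactors = FALSE)
  if (L < length_range[1L]) {
    warning("profile shorter than the minimum primer length; no candidates")
    return(empty)
  }
  cons <- .profile_consensus(profile, min_base_freq, max_gap_fraction)

  # row masks (0 = gap) and per-position agreement with the consensus
  rows <- do.call(rbind, strsplit(profile$sequences, "", fixed = TRUE))
  rows[rows == "."] <- "-"
  rmask <- matrix(0L, nrow = nrow(rows), ncol = L)
  nongap <- rows != "-"
  rmask[nongap] <- .IUPAC_MASK[rows[nongap]]
  agree <- matrix(bitwAnd(as.vector(rmask),
                          rep(cons$masks, each = nrow(rmask))) > 0L,
                  nrow = nrow(rmask))
  agree[!nongap] <- FALSE
  # cumulative count of disagreeing positions per row, for O(1) window tests
  miss_cum <- cbind(0L, t(apply(!agree, 1L, cumsum)))

  disq_cum <- c(0L, cumsum(cons$disqualified))
  logcard <- log(cons$card)
  logcard[cons$disqualified] <- 0
  lc_cum <- c(0, cumsum(logcard))

  out <- list()
  for (len in seq(length_range[1L], length_range[2L])) {
    starts <- seq_len(L - len + 1L)
    ok <- (disq_cum[starts + len] - disq_cum[starts]) == 0L
    # degeneracy prefilter via log-sums (exact product recheck below)
    ldeg <- lc_cum[starts + len] - lc_cum[starts]
    starts <- starts[ok & ldeg <= log(max_degeneracy) + 1e-9]
    if (length(starts) == 0L) next
    deg <- vapply(starts, function(s) prod(cons$card[s:(s + len - 1L)]),
                  numeric(1))
    keep <- deg <= max_degeneracy
    starts <- starts[keep]; deg <- deg[keep]
    if (length(starts) == 0L) next
    seq_fwd <- vapply(starts, function(s) {
      paste(cons$symbols[s:(s + len - 1L)], collapse = "")
    }, character(1))
    cov <- colMeans((miss_cum[, starts + len, drop = FALSE] -
                       miss_cum[, starts, drop = FALSE]) == 0L)
    clamp_fwd <- vapply(starts, function(s) {
      all(cons$card[(s + len - 3L):(s + len - 1L)] == 1L)
    }, logical(1))
    clamp_rev <- vapply(starts, function(s) {
      all(cons$card[s:(s + 2L)] == 1L)
    }, logical(1))
    out[[length(out) + 1L]] <- data.frame(
      sequence = c(seq_fwd, reverse_complement(seq_fwd)),
      alignment_start = rep(starts - 1L, 2L), length = len,
      orientation = rep(c("forward", "reverse"), each = length(starts)),
      degeneracy = rep(deg, 2L), coverage_fraction = rep(cov, 2L),
      three_prime_clamp = c(clamp_fwd, clamp_rev),
      gene_location = profile$source_name, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  ord <- order(res$degeneracy, -res$coverage_fraction, res$alignment_start,
               res$length, res$orientation)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Pair forward and reverse candidates into anticipated amplicons
#'
#' Combines every forward candidate with every reverse candidate sited
#' downstream of it and keeps pairs whose anticipated product size falls in
#' `amplicon_range`. Sizes are measured on the gap-stripped consensus
#' (columns that are gap in the majority of rows do not count towards
#' product length), from the forward primer's first base to the reverse
#' site's last base.
#'
#' @param candidates Data frame from [scan_windows()].
#' @param amplicon_range Numeric pair of allowed product sizes in
#'   nucleotides.
#' @param profile The profile the candidates came from (needed for the
#'   gap-stripped coordinate map).
#' @param max_gap_fraction,min_base_freq As in [scan_windows()].
#' @return Data frame of pairs: forward/reverse sequences and starts,
#'   degeneracies, `anticipated_size` and a `set_name`.
#' @export
pair_primers <- function(candidates, amplicon_range, profile,
                         max_gap_fraction = 0.10, min_base_freq = 0.05) {
  stopifnot(inherits(profile, "alignment_profile"))
  empty <- data.frame(set_name = character(), forward = character(),
                      forward_start = integer(), reverse = character(),
                      reverse_start = integer(), anticipated_size = integer(),
                      pair_degeneracy = numeric(), stringsAsFactors = FALSE)
  fw <- candidates[candidates$orientation == "forward", , drop = FALSE]
  rv <- candidates[candidates$orientation == "reverse", , drop = FALSE]
  if (nrow(fw) == 0L || nrow(rv) == 0L) return(empty)
  cons <- .profile_consensus(profile, min_base_freq, max_gap_fraction)
  # ungapped(c) = number of non-gap consensus columns in [0, c)
  ungapped <- c(0L, cumsum(!cons$gap_column))
  f0 <- fw$alignment_start
  r_end <- rv$alignment_start + rv$length
  size <- outer(ungapped[r_end + 1L], ungapped[f0 + 1L], "-")  # [j, i]
  ok <- outer(r_end, f0, ">") & size >= amplicon_range[1L] &
    size <= amplicon_range[2L]
  hit <- which(ok, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  j <- hit[, 1L]; i <- hit[, 2L]
  res <- data.frame(
    set_name = sprintf("%s-%d-%d", profile$source_name, f0[i],
                       rv$alignment_start[j]),
    forward = fw$sequence[i], forward_start = f0[i],
    reverse = rv$sequence[j], reverse_start = rv$alignment_start[j],
    anticipated_size = size[cbind(j, i)],
    pair_degeneracy = fw$degeneracy[i] * rv$degeneracy[j],
    stringsAsFactors = FALSE)
  res <- res[order(res$forward_start, res$reverse_start,
                   res$forward, res$reverse), , drop = FALSE]
  rownames(res) <- NULL
  res
}
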