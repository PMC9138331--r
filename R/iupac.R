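# IUPAC nucleotide codes as 4-bit masks (A=1, C=2, G=4, T=8). All exact
# algebra on degenerate sequences (degeneracy counting, expansion,
# complementation, mismatch counting) is done on these masks.

.IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.BASE_BIT <- c(A = 1L, C = 2L, G = 4L, T = 8L)

.IUPAC_MASK <- vapply(.IUPAC_BASES, function(b) sum(.BASE_BIT[b]), integer(1))

# mask -> symbol lookup, indexed by mask value 1..15
.MASK_CODE <- character(15L)
.MASK_CODE[.IUPAC_MASK] <- names(.IUPAC_MASK)

# complement of a mask: swap A<->T and C<->G bits
.COMP_MASK <- vapply(0:15, function(m) {
  bitwOr(bitwOr(bitwShiftL(bitwAnd(m, 1L), 3L),  # A -> T
                bitwShiftL(bitwAnd(m, 2L), 1L)), # C -> G
         bitwOr(bitwShiftR(bitwAnd(m, 4L), 1L),  # G -> C
                bitwShiftR(bitwAnd(m, 8L), 3L))) # T -> A
}, integer(1))

.CARDINALITY <- vapply(0:15, function(m) {
  sum(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L)
}, integer(1))

# Split a sequence string into uppercase single characters, with validation.
# Gaps, U and anything outside the 15 IUPAC codes are rejected, naming the
# offending character and its 1-based position.
.iupac_chars <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(.IUPAC_MASK))
  if (length(bad) > 0L) {
    stop(sprintf("invalid IUPAC character '%s' at position %d in %s",
                 chars[bad[1L]], bad[1L], what), call. = FALSE)
  }
  chars
}

.iupac_masks <- function(x, what = "sequence") {
  unname(.IUPAC_MASK[.iupac_chars(x, what)])
}

#' Degeneracy of an IUPAC-coded sequence
#'
#' The degeneracy of a degenerate primer is the number of distinct concrete
#' A/C/G/T sequences it encodes: the product over positions of the size of
#' each IUPAC symbol's base set (A/C/G/T count 1; R,Y,S,W,K,M count 2;
#' B,D,H,V count 3; N counts 4). Fully determinate sequences have
#' degeneracy 1.
#'
#' @param x Character vector of IUPAC nucleotide sequences (case
#'   insensitive; gaps and U are rejected).
#' @return Numeric vector of degeneracies (exact integers; returned as
#'   numeric so products above `.Machine$integer.max` are representable).
#' @examples
#' degeneracy("GGRTARTCNGARTAHCGNCGNGG")  # 1536
#' degeneracy(c("ACGT", "NN"))            # 1, 16
#' @export
degeneracy <- function(x) {
  vapply(x, function(s) prod(.CARDINALITY[.iupac_masks(s) + 1L]),
         numeric(1), USE.NAMES = FALSE)
}

#' Expand a degenerate sequence into its concrete sequences
#'
#' Enumerates every concrete A/C/G/T sequence representable by an
#' IUPAC-coded sequence. The size of the result always equals
#' [degeneracy()]. Expansion is refused above `cap` to guard against
#' combinatorial blow-up.
#'
#' @param x A single IUPAC sequence.
#' @param cap Maximum degeneracy that will be expanded (default 10000).
#' @return Character vector of concrete sequences, in lexicographic
#'   position-wise order.
#' @examples
#' expand_iupac("AR")  # "AA" "AG"
#' @export
expand_iupac <- function(x, cap = 10000) {
  chars <- .iupac_chars(x)
  d <- prod(.CARDINALITY[.IUPAC_MASK[chars] + 1L])
  if (d > cap) {
    stop(sprintf("degeneracy %s exceeds expansion cap %s",
                 format(d, big.mark = ","), format(cap, big.mark = ",")),
         call. = FALSE)
  }
  sets <- .IUPAC_BASES[chars]
  out <- ""
  for (s in sets) {
    out <- as.vector(t(outer(out, s, paste0)))
  }
  out
}

#' Reverse complement of an IUPAC-coded sequence
#'
#' Applies the standard IUPAC complement map (A-T, C-G, R-Y, K-M, S-S, W-W,
#' B-V, D-H, N-N) and reverses. The operation is an involution and
#' preserves degeneracy.
#'
#' @param x Character vector of IUPAC sequences.
#' @return Character vector of reverse-complemented sequences.
#' @examples
#' reverse_complement("AR")  # "YT"
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    m <- .COMP_MASK[.iupac_masks(s) + 1L]
    paste(.MASK_CODE[rev(m)], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Minimal IUPAC code for a set of bases
#'
#' Returns the unique IUPAC symbol whose base set is exactly the given set.
#'
#' @param bases Character vector, a non-empty subset of A, C, G, T
#'   (duplicates allowed and ignored).
#' @return A single IUPAC symbol.
#' @examples
#' minimal_code(c("A", "G"))  # "R"
#' @export
minimal_code <- function(bases) {
  bases <- unique(toupper(bases))
  if (length(bases) == 0L) stop("base set must be non-empty", call. = FALSE)
  if (!all(bases %in% names(.BASE_BIT))) {
    stop("bases must be among A, C, G, T", call. = FALSE)
  }
  .MASK_CODE[sum(.BASE_BIT[bases])]
}

#' Base set of an IUPAC symbol
#'
#' @param code A single IUPAC symbol.
#' @return Character vector of the concrete bases the symbol stands for.
#' @examples
#' base_set("H")  # "A" "C" "T"
#' @export
base_set <- function(code) {
  .IUPAC_BASES[[.iupac_chars(code, "code")[1L]]]
}

#' Mismatches between a degenerate primer and a concrete window
#'
#' Counts positions where the window base is not contained in the primer
#' symbol's base set. This equals the minimum Hamming distance between the
#' window and any concrete expansion of the primer. The window may itself
#' carry ambiguity codes (e.g. N in a draft template); a position matches
#' whenever the two base sets intersect.
#'
#' @param primer IUPAC sequence.
#' @param window Sequence of the same length.
#' @return Non-negative integer mismatch count.
#' @examples
#' count_mismatches("AR", "AC")  # 1
#' @export
count_mismatches <- function(primer, window) {
  p <- .iupac_masks(primer, "primer")
  w <- .iupac_masks(window, "window")
  if (length(p) != length(w)) {
    stop(sprintf("primer length (%d) and window length (%d) differ",
                 length(p), length(w)), call. = FALSE)
  }
  sum(bitwAnd(p, w) == 0L)
}
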