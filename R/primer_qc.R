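# Deterministic, run-length-based screening of primers for hairpins,
# self-dimers and cross-dimers. Scores are degenerate-aware: two IUPAC
# symbols can pair whenever some base of one is Watson-Crick complementary
# to some base of the other, so a score upper-bounds the score of every
# concrete expansion (and equals the maximum over expansions).

# can symbol masks a and b pair? (some base of a complements some base of b)
.can_pair <- function(ma, mb) bitwAnd(ma, .COMP_MASK[mb + 1L]) > 0L

#' Longest complementary run between two primers (dimer score)
#'
#' Slides one primer along the reverse of the other (the antiparallel
#' duplex geometry) and reports the longest run of consecutive positions
#' that can base-pair, together with the offset achieving it (the smallest
#' offset on ties) and the longest pairable run that involves the 3'
#' terminal base of either primer. Use `dimer_score(a, a)` for a
#' self-dimer.
#'
#' @param a,b IUPAC primer sequences.
#' @return List with `score` (integer run length), `offset` (shift of the
#'   reversed `b` relative to `a`; 0 aligns both 5' ends of `a` with the 3'
#'   end of `b`) and `three_prime_run` (longest run containing either 3'
#'   terminal base).
#' @examples
#' dimer_score("AAAA", "TTTT")$score  # 4
#' @export
dimer_score <- function(a, b) {
  ma <- .iupac_masks(a, "primer a")
  mb_r <- rev(.iupac_masks(b, "primer b"))   # b read 3' -> 5'
  na <- length(ma); nb <- length(mb_r)
  best <- 0L; best_off <- NA_integer_; best3 <- 0L
  for (off in seq(-(nb - 1L), na - 1L)) {
    i <- seq(max(1L, off + 1L), min(na, off + nb))
    j <- i - off
    pair <- .can_pair(ma[i], mb_r[j])
    if (!any(pair)) next
    r <- rle(pair)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    mx <- max(r$lengths[runs])
    if (mx > best) { best <- mx; best_off <- off }
    # runs touching a's 3' end (i == na) or b's 3' end (j == 1, since b is
    # reversed its first element is the 3' terminal base)
    for (k in runs) {
      ii <- i[starts[k]:ends[k]]; jj <- j[starts[k]:ends[k]]
      if (na %in% ii || 1L %in% jj) best3 <- max(best3, r$lengths[k])
    }
  }
  list(score = best, offset = best_off, three_prime_run = best3)
}

#' Longest stable hairpin stem within a primer
#'
#' Searches all stem/loop decompositions: a stem of length s pairs
#' positions i..i+s-1 with j..j-s+1 (antiparallel, degenerate-aware), with
#' the intervening loop at least `min_loop` bases. Stems shorter than
#' `min_stem` are considered too unstable to report and score 0.
#'
#' @param a IUPAC primer sequence.
#' @param min_loop Minimum loop length (default 3, the physical minimum).
#' @param min_stem Minimum stem length counted as a hairpin (default 3).
#' @return Integer: the longest admissible stem length, or 0.
#' @examples
#' hairpin_score("GGGGAAAACCCC")  # 4
#' hairpin_score("AAAATTTT")      # 0: a 3-bp stem would leave a 2-base loop
#' @export
hairpin_score <- function(a, min_loop = 3L, min_stem = 3L) {
  if (min_loop < 3L) stop("min_loop must be >= 3", call. = FALSE)
  m <- .iupac_masks(a, "primer")
  n <- length(m)
  best <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i - 1L < min_loop) next
      # extend stem pairing (i, j), (i+1, j-1), ...
      s <- 0L
      while (i + s <= n && j - s >= 1L &&
             (j - s) - (i + s) - 1L >= min_loop &&
             .can_pair(m[i + s], m[j - s])) {
        s <- s + 1L
      }
      if (s >= min_stem && s > best) best <- s
    }
  }
  best
}

#' Screen primer pairs for hairpins and dimers
#'
#' Annotates every pair with a QC report (self-dimer, cross-dimer and
#' hairpin scores, plus a 3'-dimer flag) and filters to passing pairs
#' unless `report_only`. High scores did not always prevent amplification
#' in practice, so `report_only = TRUE` keeps all pairs annotated.
#'
#' @param pairs Data frame with `forward` and `reverse` IUPAC sequence
#'   columns (e.g. from [pair_primers()]).
#' @param thresholds Named list of maxima: `self`, `cross`, `hairpin`,
#'   `three_prime` (defaults 5, 5, 4, 3).
#' @param report_only Keep failing pairs (annotated, `pass = FALSE`)?
#' @param min_loop,min_stem Passed to [hairpin_score()].
#' @return The input with columns `self_dimer_score`, `cross_dimer_score`,
#'   `hairpin_score`, `three_prime_dimer`, `pass` appended; failing rows
#'   dropped unless `report_only`.
#' @export
qc_filter <- function(pairs, thresholds = list(), report_only = FALSE,
                      min_loop = 3L, min_stem = 3L) {
  th <- utils::modifyList(list(self = 5L, cross = 5L, hairpin = 4L,
                               three_prime = 3L), thresholds)
  n <- nrow(pairs)
  self_s <- cross_s <- hp <- integer(n)
  tp <- logical(n)
  for (i in seq_len(n)) {
    f <- pairs$forward[i]; r <- pairs$reverse[i]
    sf <- dimer_score(f, f); sr <- dimer_score(r, r); cx <- dimer_score(f, r)
    self_s[i] <- max(sf$score, sr$score)
    cross_s[i] <- cx$score
    hp[i] <- max(hairpin_score(f, min_loop, min_stem),
                 hairpin_score(r, min_loop, min_stem))
    tp[i] <- max(sf$three_prime_run, sr$three_prime_run,
                 cx$three_prime_run) > th$three_prime
  }
  pairs$self_dimer_score <- self_s
  pairs$cross_dimer_score <- cross_s
  pairs$hairpin_score <- hp
  pairs$three_prime_dimer <- tp
  pairs$pass <- self_s <= th$self & cross_s <= th$cross & hp <= th$hairpin &
    !tp
  if (!report_only) pairs <- pairs[pairs$pass, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}
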