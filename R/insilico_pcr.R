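# In-silico PCR: locate degenerate-primer binding sites on (by default
# circular) mitogenome templates, enumerate predicted amplicons, and
# classify each reaction by the single-band-of-anticipated-size rule.

# template string -> integer mask vector; ambiguous template bases keep
# their full base set so they match any primer symbol with an intersecting
# set (permissive, mirroring wet-lab ambiguity).
.template_masks <- function(template) .iupac_masks(template, "template")

# circular index helper: 0-based position p on a template of length L
.wrap1 <- function(p, L) (p %% L) + 1L

#' Find priming sites of a degenerate primer on a template
#'
#' Scans both strands for windows matching the primer with at most
#' `max_mismatch` mismatches and zero mismatches within the 3'-terminal
#' `clamp_len` bases (mismatches at the extending end suppress
#' amplification). On circular templates, windows wrapping the origin are
#' included.
#'
#' @param primer IUPAC primer sequence (5'->3').
#' @param template Template sequence (may contain ambiguity codes, which
#'   match permissively).
#' @param max_mismatch Maximum mismatches outside the clamp (default 2).
#' @param clamp_len Number of 3'-terminal primer bases that must match
#'   exactly (default 3; 0 disables the clamp).
#' @param circular Treat the template as circular (default TRUE)?
#' @param template_id Label copied into the result.
#' @return Data frame of sites: `template_id`, `start`, `end` (0-based
#'   half-open on the forward strand; `end` may exceed the template length
#'   for origin-wrapping sites), `strand` ("+"/"-"), `mismatches`,
#'   `three_prime_mismatch` (always FALSE for retained sites when
#'   `clamp_len` > 0).
#' @export
find_sites <- function(primer, template, max_mismatch = 2L, clamp_len = 3L,
                       circular = TRUE, template_id = "template") {
  pm_fwd <- .iupac_masks(primer, "primer")
  tm <- .template_masks(template)
  L <- length(tm)
  plen <- length(pm_fwd)
  if (L < plen) stop("template shorter than primer", call. = FALSE)
  n_starts <- if (circular) L else L - plen + 1L
  starts0 <- seq_len(n_starts) - 1L

  scan_one <- function(pmask, clamp_idx) {
    mm <- integer(n_starts)
    mm_clamp <- integer(n_starts)
    for (j in seq_len(plen)) {
      tj <- tm[.wrap1(starts0 + (j - 1L), L)]
      miss <- bitwAnd(pmask[j], tj) == 0L
      mm <- mm + miss
      if (j %in% clamp_idx) mm_clamp <- mm_clamp + miss
    }
    list(mm = mm, clamp = mm_clamp)
  }

  out <- list()
  # forward strand: primer 3' end is the window's last clamp_len positions
  clamp_f <- if (clamp_len > 0L) seq(plen - clamp_len + 1L, plen) else integer()
  sf <- scan_one(pm_fwd, clamp_f)
  keep <- sf$mm <= max_mismatch & sf$clamp == 0L
  if (any(keep)) {
    out[[1L]] <- data.frame(template_id = template_id,
                            start = starts0[keep],
                            end = starts0[keep] + plen, strand = "+",
                            mismatches = sf$mm[keep],
                            three_prime_mismatch = sf$clamp[keep] > 0L,
                            stringsAsFactors = FALSE)
  }
  # minus strand: match the reverse complement on the forward strand; the
  # primer's 3' end maps to the first clamp_len window positions
  pm_rev <- rev(.COMP_MASK[pm_fwd + 1L])
  clamp_r <- if (clamp_len > 0L) seq_len(clamp_len) else integer()
  sr <- scan_one(pm_rev, clamp_r)
  keep <- sr$mm <= max_mismatch & sr$clamp == 0L
  if (any(keep)) {
    out[[length(out) + 1L]] <- data.frame(template_id = template_id,
                                          start = starts0[keep],
                                          end = starts0[keep] + plen,
                                          strand = "-",
                                          mismatches = sr$mm[keep],
                                          three_prime_mismatch =
                                            sr$clamp[keep] > 0L,
                                          stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(template_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(),
                      three_prime_mismatch = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# extract a (possibly wrapping) 0-based half-open slice of a circular
# template string
.circ_substr <- function(template, start, end) {
  L <- nchar(template)
  idx <- .wrap1(seq(start, end - 1L), L)
  paste(strsplit(template, "", fixed = TRUE)[[1L]][idx], collapse = "")
}

#' Predict amplicons of a primer pair on a template
#'
#' Combines every forward-primer site on the plus strand with every
#' reverse-primer site on the minus strand and emits each combination
#' whose product length (going rightwards from the forward site, wrapping
#' the origin on circular templates) falls within `size_range`.
#'
#' @param forward,reverse IUPAC primer sequences (both 5'->3').
#' @param template Template sequence.
#' @param size_range Numeric pair of admissible product lengths (default
#'   c(50, 3000)).
#' @param max_mismatch,clamp_len,circular,template_id As in [find_sites()].
#' @return Data frame of amplicons: `template_id`, `start`, `end` (0-based
#'   half-open on the forward strand; `end` > template length denotes an
#'   origin-wrapping product), `length`, `fwd_mismatches`,
#'   `rev_mismatches`, `sequence` and `insert` (sequence with both primer
#'   footprints trimmed).
#' @export
predict_amplicons <- function(forward, reverse, template,
                              size_range = c(50L, 3000L), max_mismatch = 2L,
                              clamp_len = 3L, circular = TRUE,
                              template_id = "template") {
  fs <- find_sites(forward, template, max_mismatch, clamp_len, circular,
                   template_id)
  rs <- find_sites(reverse, template, max_mismatch, clamp_len, circular,
                   template_id)
  fs <- fs[fs$strand == "+", , drop = FALSE]
  rs <- rs[rs$strand == "-", , drop = FALSE]
  empty <- data.frame(template_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      fwd_mismatches = integer(), rev_mismatches = integer(),
                      sequence = character(), insert = character(),
                      stringsAsFactors = FALSE)
  if (nrow(fs) == 0L || nrow(rs) == 0L) return(empty)
  L <- nchar(template)
  flen <- nchar(forward); rlen <- nchar(reverse)
  out <- list()
  for (i in seq_len(nrow(fs))) {
    for (j in seq_len(nrow(rs))) {
      f0 <- fs$start[i]
      r_end <- rs$end[j]
      if (circular) {
        len <- ((r_end - f0 - 1L) %% L) + 1L   # in 1..L, wrapping allowed
      } else {
        len <- r_end - f0
        if (len <= 0L) next
      }
      if (len < flen + rlen) next  # primers must not overlap
      if (len < size_range[1L] || len > size_range[2L]) next
      seqs <- .circ_substr(template, f0, f0 + len)
      out[[length(out) + 1L]] <- data.frame(
        template_id = template_id, start = f0, end = f0 + len, length = len,
        fwd_mismatches = fs$mismatches[i], rev_mismatches = rs$mismatches[j],
        sequence = seqs,
        insert = substr(seqs, flen + 1L, len - rlen),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify a PCR reaction from its predicted amplicons
#'
#' Applies the gel-scoring rule: a reaction succeeds only as a single band
#' of the anticipated size. Two or more predicted products classify as
#' `multiple_products` regardless of their sizes; one product outside the
#' size tolerance is `wrong_size`; none is `no_product`.
#'
#' @param amplicons Data frame from [predict_amplicons()] (only the
#'   `length` column is used).
#' @param anticipated_size Expected product size in nucleotides.
#' @param tolerance_fraction Relative size tolerance (default 0.15).
#' @return An object of class `reaction_call`: list with `status` (one of
#'   "single_product", "no_product", "multiple_products", "wrong_size")
#'   and the `amplicons`.
#' @examples
#' classify_reaction(data.frame(length = 387), 387)$status  # single_product
#' @export
classify_reaction <- function(amplicons, anticipated_size,
                              tolerance_fraction = 0.15) {
  if (tolerance_fraction < 0 || tolerance_fraction >= 1) {
    stop("tolerance_fraction must be in [0, 1)", call. = FALSE)
  }
  n <- nrow(amplicons)
  status <- if (n == 0L) {
    "no_product"
  } else if (n >= 2L) {
    "multiple_products"
  } else if (abs(amplicons$length[1L] - anticipated_size) <=
             tolerance_fraction * anticipated_size) {
    "single_product"
  } else {
    "wrong_size"
  }
  structure(list(status = status, amplicons = amplicons),
            class = "reaction_call")
}

#' @export
print.reaction_call <- function(x, ...) {
  cat(sprintf("reaction_call: %s (%d predicted amplicon%s)\n", x$status,
              nrow(x$amplicons), if (nrow(x$amplicons) == 1L) "" else "s"))
  invisible(x)
}
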