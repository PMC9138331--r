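# Conserved-window scanning and primer pairing on alignment profiles.

test_that("build_profile counts columns, gaps and fractional ambiguity", {
  p <- build_profile(c(a = "ACG", b = "ACG", c = "ACG"))
  expect_equal(unname(p$counts["A", ]), c(3, 0, 0))
  expect_equal(unname(p$counts["gap", ]), c(0, 0, 0))
  expect_equal(p$n_sequences, 3L)

  p2 <- build_profile(c(a = "AC", b = "A-"))
  expect_equal(unname(p2$counts["gap", 2]), 1)
  expect_equal(unname(p2$counts["C", 2]), 1)

  # an R contributes half a count to A and to G
  p3 <- build_profile(c(a = "R", b = "A"))
  expect_equal(unname(p3$counts["A", 1]), 1.5)
  expect_equal(unname(p3$counts["G", 1]), 0.5)

  expect_error(build_profile(c("AC", "ACG")), "ragged")
  expect_error(build_profile(character()), "at least 2")
  expect_error(build_profile("ACGT"), "at least 2")
})

test_that("planted polymorphic-site frequency is recovered in the profile", {
  aln <- simulate_alignment(200, 60,
                            polymorphic = data.frame(column = 30, freq = 0.3),
                            seed = 21)
  p <- build_profile(aln)
  minor <- sort(p$counts[c("A", "C", "G", "T"), 31], decreasing = TRUE)[2]
  expect_gt(minor / 200, 0.20)
  expect_lt(minor / 200, 0.40)
})

test_that("consensus_column covers bases at threshold with deterministic tie-break", {
  expect_identical(consensus_column(c(A = 10, C = 0, G = 0, T = 0)), "A")
  expect_identical(consensus_column(c(A = 5, C = 0, G = 5, T = 0)), "R")
  # 1% frequencies fall under the 5% default threshold
  expect_identical(consensus_column(c(A = 97, C = 1, G = 1, T = 1)), "A")
  # nothing reaches an extreme threshold: most frequent base, ties broken
  # alphabetically
  expect_identical(consensus_column(c(A = 5, C = 5, G = 5, T = 5),
                                    min_base_freq = 0.9), "A")
  expect_identical(consensus_column(c(A = 0, C = 0, G = 0, T = 0)),
                   NA_character_)
})

test_that("lowering min_base_freq never decreases a column degeneracy", {
  set.seed(22)
  for (i in 1:50) {
    counts <- stats::setNames(rpois(4, 3), c("A", "C", "G", "T"))
    if (sum(counts) == 0) counts["A"] <- 1
    degs <- vapply(c(0.5, 0.2, 0.05, 0.01), function(f) {
      length(base_set(consensus_column(counts, f)))
    }, integer(1))
    expect_true(all(diff(degs) >= 0))
  }
})

test_that("an alignment of identical sequences yields full-coverage unit-degeneracy windows", {
  aln <- simulate_alignment(5, 100, seed = 23)
  p <- build_profile(aln, name = "toy")
  cand <- scan_windows(p)
  fwd <- cand[cand$orientation == "forward", ]
  expect_equal(nrow(fwd), sum((100 - 18:26) + 1))
  expect_true(all(cand$degeneracy == 1))
  expect_true(all(cand$coverage_fraction == 1))
  expect_true(all(cand$length >= 18 & cand$length <= 26))
})

test_that("the degeneracy budget forbids uniformly 50/50 columns", {
  rows <- c(rep(strrep("A", 18), 20), rep(strrep("G", 18), 20))
  p <- build_profile(rows)
  cand <- scan_windows(p, length_range = c(18, 18), max_degeneracy = 216)
  expect_equal(nrow(cand), 0L)  # 2^18 >> 216
})

test_that("a planted conserved block is the top-ranked candidate region", {
  block <- 40:63  # 24 conserved columns, 0-based
  aln <- simulate_alignment(60, 120,
                            variable_cols = setdiff(0:119, block), seed = 24)
  p <- build_profile(aln, name = "planted")
  cand <- scan_windows(p, max_degeneracy = 216)
  expect_gt(nrow(cand), 0)
  top <- cand[1, ]
  expect_gte(top$alignment_start, min(block))
  expect_lte(top$alignment_start + top$length, max(block) + 1L)
  expect_equal(top$coverage_fraction, 1)
})

test_that("emitted candidates all satisfy their bounds, deterministically", {
  aln <- simulate_alignment(30, 90, variable_cols = c(5, 25, 50, 70),
                            polymorphic = data.frame(column = c(40, 60),
                                                     freq = 0.4),
                            seed = 25)
  p <- build_profile(aln)
  a <- scan_windows(p, max_degeneracy = 64)
  b <- scan_windows(p, max_degeneracy = 64)
  expect_identical(a, b)
  expect_true(all(a$degeneracy <= 64))
  expect_true(all(a$length >= 18 & a$length <= 26))
  expect_true(all(a$coverage_fraction >= 0 & a$coverage_fraction <= 1))
  # reverse candidates are the reverse complements of their forward twin
  fwd <- a[a$orientation == "forward", ]
  rev <- a[a$orientation == "reverse", ]
  key <- function(d) paste(d$alignment_start, d$length)
  m <- match(key(fwd), key(rev))
  expect_false(anyNA(m))
  expect_identical(vapply(fwd$sequence, reverse_complement, character(1),
                          USE.NAMES = FALSE),
                   rev$sequence[m])
})

test_that("windows containing gappy columns are disqualified", {
  rows <- c(a = paste0(strrep("A", 30), "-", strrep("C", 30)),
            b = paste0(strrep("A", 30), "-", strrep("C", 30)))
  p <- build_profile(rows)
  cand <- scan_windows(p, length_range = c(18, 18))
  # no window may straddle column 30 (0-based), which is all-gap
  expect_true(all(cand$alignment_start + cand$length <= 30 |
                    cand$alignment_start > 30))
})

test_that("pair_primers computes anticipated sizes on the gapless consensus", {
  aln <- simulate_alignment(4, 400, seed = 26)
  p <- build_profile(aln, name = "g")
  cand <- scan_windows(p, length_range = c(20, 20))
  fwd <- cand[cand$orientation == "forward" & cand$alignment_start == 0, ]
  rev <- cand[cand$orientation == "reverse" & cand$alignment_start == 380, ]
  pairs <- pair_primers(rbind(fwd, rev), c(300, 800), p)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$anticipated_size, 400L)
  expect_equal(nrow(pair_primers(rbind(fwd, rev), c(500, 800), p)), 0L)
})

test_that("majority-gap columns do not count towards the anticipated size", {
  rows <- c(a = paste0(strrep("A", 100), strrep("-", 50), strrep("C", 100)),
            b = paste0(strrep("A", 100), strrep("-", 50), strrep("C", 100)),
            c = paste0(strrep("A", 100), strrep("T", 50), strrep("C", 100)))
  p <- build_profile(rows, name = "gappy")
  cand <- scan_windows(p, length_range = c(20, 20))
  fwd <- cand[cand$orientation == "forward" & cand$alignment_start == 0, ]
  rev <- cand[cand$orientation == "reverse" & cand$alignment_start == 230, ]
  pairs <- pair_primers(rbind(fwd, rev), c(50, 400), p)
  expect_equal(pairs$anticipated_size, 200L)  # 250 columns - 50 gap columns
})

test_that("too-short profiles warn and return no candidates", {
  p <- build_profile(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  expect_warning(cand <- scan_windows(p), "shorter")
  expect_equal(nrow(cand), 0L)
})
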