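# The seeded mitogenome / population simulator and its ground truth.

test_that("simulation is byte-identical under a fixed seed", {
  a <- simulate_mitogenome(seed = 61)
  b <- simulate_mitogenome(seed = 61)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth, b$truth)
  c <- simulate_mitogenome(seed = 62)
  expect_false(identical(a$genome, c$genome))

  sim <- simulate_mitogenome(seed = 61)
  p1 <- simulate_population(sim, 8, k = 2, seed = 63)
  p2 <- simulate_population(sim, 8, k = 2, seed = 63)
  expect_identical(p1$genomes, p2$genomes)
  expect_identical(p1$truth, p2$truth)
})

test_that("planted primer blocks amplify their loci as single products", {
  sim <- simulate_mitogenome(seed = 64)
  tab <- read_primer_table(system.file("extdata", "primers_lepidoptera.tsv",
                                       package = "mtmlsa"))
  ps <- stats::setNames(tab$sequence, tab$name)
  li <- sim$truth$loci
  for (i in seq_len(nrow(li))) {
    amp <- predict_amplicons(ps[[li$forward[i]]], ps[[li$reverse[i]]],
                             sim$genome, size_range = c(100, 1200))
    call <- classify_reaction(amp, li$length[i])
    expect_equal(call$status, "single_product")
    expect_equal(amp$length, li$length[i])
    expect_equal(nchar(amp$insert), li$insert_length[i])
  }
  # the stock layout reproduces the reference ND6 / 16S product geometry
  expect_equal(li$length[li$locus == "ND6"], 690L)
  expect_equal(li$length[li$locus == "16S-5p"], 510L)
  expect_equal(li$length[li$locus == "16S-3p"], 550L)
})

test_that("spec validation rejects ill-formed layouts", {
  segs <- data.frame(label = c("g1", "g2"), length = c(100L, 50L))
  sites <- data.frame(name = "p1", sequence = "ACGTACGTACGTACGTACGT",
                      orientation = "forward", segment = "g2", offset = 40L,
                      stringsAsFactors = FALSE)
  loci <- data.frame(locus = character(), forward = character(),
                     reverse = character())
  expect_error(genome_spec(segs, sites, loci), "does not fit")
  sites$offset <- 0L; sites$segment <- "g9"
  expect_error(genome_spec(segs, sites, loci), "unknown segment")
})

test_that("transposing trnG away silences the trnG-anchored ND3 pair only", {
  sim <- simulate_mitogenome(seed = 65)
  moved <- apply_rearrangement(sim, list(op = "transpose", segment = "trnG",
                                         after = "16S"))
  tab <- read_primer_table(system.file("extdata", "primers_lepidoptera.tsv",
                                       package = "mtmlsa"))
  ps <- stats::setNames(tab$sequence, tab$name)
  li <- sim$truth$loci
  status <- vapply(seq_len(nrow(li)), function(i) {
    amp <- predict_amplicons(ps[[li$forward[i]]], ps[[li$reverse[i]]],
                             moved$genome, size_range = c(100, 1200))
    classify_reaction(amp, li$length[i])$status
  }, character(1))
  names(status) <- li$locus
  expect_equal(unname(status["ND3"]), "no_product")
  expect_true(all(status[setdiff(li$locus, "ND3")] == "single_product"))
})

test_that("identity moves change nothing and unknown segments error", {
  sim <- simulate_mitogenome(seed = 66)
  same <- apply_rearrangement(sim, list(op = "identity"))
  expect_identical(same$genome, sim$genome)
  expect_identical(same$truth$loci$length, sim$truth$loci$length)
  expect_error(apply_rearrangement(sim, list(op = "transpose",
                                             segment = "trnQ",
                                             after = "16S")),
               "unknown segment")
})

test_that("inverting trnP flips its primer to the wrong strand and kills ND6", {
  sim <- simulate_mitogenome(seed = 67)
  inv <- apply_rearrangement(sim, list(op = "invert", segment = "trnP"))
  expect_true(inv$truth$loci$disrupted[inv$truth$loci$locus == "ND6"])
  tab <- read_primer_table(system.file("extdata", "primers_lepidoptera.tsv",
                                       package = "mtmlsa"))
  ps <- stats::setNames(tab$sequence, tab$name)
  li <- sim$truth$loci
  amp <- predict_amplicons(ps[["ND6-J-10090-Lepido"]],
                           ps[["ND6-N-10589-Dipt/Lepido"]], inv$genome,
                           size_range = c(100, 1200))
  expect_equal(classify_reaction(amp, 690)$status, "no_product")
  # ND3, elsewhere on the genome, is untouched
  amp2 <- predict_amplicons(ps[["ND3-J-Gly-Lepido"]],
                            ps[["ND3-N-Arg-Lepido"]], inv$genome,
                            size_range = c(100, 1200))
  expect_equal(classify_reaction(amp2,
                                 li$length[li$locus == "ND3"])$status,
               "single_product")
})

test_that("population truth honours k, including the degenerate k = 1", {
  sim <- simulate_mitogenome(seed = 68)
  pop1 <- simulate_population(sim, 6, k = 1, seed = 69)
  expect_true(all(vapply(pop1$sequences, function(s) {
    length(unique(s)) == 1L
  }, logical(1))))
  expect_equal(pop1$truth$n_concatenated, 1L)
  expect_identical(unname(pop1$genomes[1]), sim$genome)

  # combinatorial bracket for independent assignment over two loci
  pop2 <- simulate_population(sim, 40, k = c(2, 3), seed = 70,
                              loci = c("ND3", "ND6"))
  expect_gte(pop2$truth$n_concatenated, 3L)
  expect_lte(pop2$truth$n_concatenated, 6L)

  expect_error(simulate_population(sim, 5, k = 6, seed = 71),
               "cannot exceed")
  expect_error(simulate_population(sim, 20, k = 12, n_polymorphic = 8,
                                   seed = 72),
               "polymorphic sites")
})

test_that("planted substitutions stay clear of the primer-landing blocks", {
  sim <- simulate_mitogenome(seed = 73)
  pop <- simulate_population(sim, 10, k = 4, seed = 74)
  li <- sim$truth$loci
  for (l in names(pop$truth$poly_sites)) {
    sites <- pop$truth$poly_sites[[l]]
    row <- li[li$locus == l, ]
    expect_true(all(sites >= row$insert_start & sites < row$insert_end))
  }
  # consequently every individual still amplifies every locus
  tab <- read_primer_table(system.file("extdata", "primers_lepidoptera.tsv",
                                       package = "mtmlsa"))
  ps <- stats::setNames(tab$sequence, tab$name)
  g <- pop$genomes[[5]]
  for (i in seq_len(nrow(li))) {
    amp <- predict_amplicons(ps[[li$forward[i]]], ps[[li$reverse[i]]], g,
                             size_range = c(100, 1200))
    expect_equal(classify_reaction(amp, li$length[i])$status,
                 "single_product")
  }
})

test_that("simulated alignments plant the requested column structure", {
  aln <- simulate_alignment(50, 30, variable_cols = c(0, 29),
                            polymorphic = data.frame(column = 10,
                                                     freq = 0.5),
                            seed = 75)
  expect_length(aln, 50)
  expect_true(all(nchar(aln) == 30))
  m <- do.call(rbind, strsplit(unname(aln), ""))
  ref <- strsplit(attr(aln, "reference"), "")[[1]]
  conserved <- setdiff(seq_len(30), c(1, 30, 11))
  for (j in conserved) expect_true(all(m[, j] == ref[j]))
  expect_equal(length(unique(m[, 11])), 2L)
})
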