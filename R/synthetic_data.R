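# Seeded simulator of circular mitogenomes and haplotype-structured
# populations. Genomes are built from an explicit gene-order spec
# (protein-coding genes, rRNAs and the tRNAs used as primer anchors);
# primer-landing blocks are set to exact concrete expansions of the
# supplied degenerate primers, everything else is i.i.d. uniform A/C/G/T.
# Every planted quantity is recorded as ground truth so the analysis
# modules can be checked by exact parameter recovery, and tRNA-order
# rearrangements (transpositions, inversions) can be applied to reproduce
# the primer-failure mechanism seen in rearranged lineages.

.rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Construct a mitogenome simulation spec
#'
#' @param segments Data frame with columns `label` and `length`: the gene
#'   order of the circular genome (each label once).
#' @param sites Data frame with columns `name`, `sequence` (IUPAC),
#'   `orientation` ("forward"/"reverse"), `segment`, `offset` (0-based
#'   within the segment): the primer-landing blocks to plant.
#' @param loci Data frame with columns `locus`, `forward`, `reverse`
#'   (site names): the primer pairs defining the typed loci.
#' @return Object of class `genome_spec`.
#' @seealso [default_genome_spec()] for the stock layout.
#' @export
genome_spec <- function(segments, sites, loci) {
  stopifnot(all(c("label", "length") %in% names(segments)),
            all(c("name", "sequence", "orientation", "segment", "offset")
                %in% names(sites)),
            all(c("locus", "forward", "reverse") %in% names(loci)))
  if (anyDuplicated(segments$label)) {
    stop("segment labels must be unique", call. = FALSE)
  }
  if (anyDuplicated(sites$name)) {
    stop("site names must be unique", call. = FALSE)
  }
  for (i in seq_len(nrow(sites))) {
    seg <- match(sites$segment[i], segments$label)
    if (is.na(seg)) {
      stop("site '", sites$name[i], "' references unknown segment '",
           sites$segment[i], "'", call. = FALSE)
    }
    plen <- nchar(sites$sequence[i])
    if (sites$offset[i] < 0L ||
        sites$offset[i] + plen > segments$length[seg]) {
      stop("primer '", sites$name[i], "' (", plen,
           " nt) does not fit in segment '", sites$segment[i],
           "' at offset ", sites$offset[i], call. = FALSE)
    }
    degeneracy(sites$sequence[i])  # validates IUPAC
  }
  bad <- setdiff(c(loci$forward, loci$reverse), sites$name)
  if (length(bad) > 0L) {
    stop("loci reference unknown sites: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(segments = segments, sites = sites, loci = loci),
            class = "genome_spec")
}

#' Stock mitogenome layout with the universal primer anchors
#'
#' A compact circular mitogenome (~6.2 kb; real insect mitogenomes are
#' ~15.5 kb, the intergene spacers are shortened here) in the standard
#' insect gene order: COI, trnL, COIII, trnG, ND3, trnA, trnR, trnN, ...,
#' trnT, trnP, ND6, CytB, ..., 16S. Primer-landing blocks carry the
#' Lepidoptera universal primer set: the 3' COI pair (forward in COI,
#' reverse in trnL), the ND3 pair anchored in the flanking trnG/trnA, the
#' ND6 pair anchored in trnP with the reverse primer in CytB, and the two
#' overlapping 16S pairs. Offsets are chosen so the ND6 product is 690 nt
#' and the two 16S products 510 and 550 nt, matching the reference locus
#' geometry.
#'
#' @param primers Optional data frame with `name` and `sequence` columns
#'   overriding the bundled Lepidoptera primer table.
#' @return A [genome_spec()].
#' @export
default_genome_spec <- function(primers = NULL) {
  if (is.null(primers)) {
    primers <- read_primer_table(
      system.file("extdata", "primers_lepidoptera.tsv", package = "mtmlsa"))
  }
  seqs <- stats::setNames(primers$sequence, primers$name)
  need <- c("C1-J-2183-Lepido", "L2-N-3014-Lepido", "ND3-J-Gly-Lepido",
            "ND3-N-Arg-Lepido", "ND6-J-10090-Lepido",
            "ND6-N-10589-Dipt/Lepido", "LR-J-12888-Dipt/Lepido",
            "LR-N-13398-Dipt/Lepido", "LR-J-13342-Dipt/Lepido",
            "LR-N-13889-Dipt/Lepido")
  miss <- setdiff(need, names(seqs))
  if (length(miss) > 0L) {
    stop("primer table lacks: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  segments <- data.frame(
    label = c("COI", "trnL", "COIII", "trnG", "ND3", "trnA", "trnR", "trnN",
              "spacer1", "trnT", "trnP", "ND6", "CytB", "spacer2", "16S"),
    length = c(1600L, 65L, 300L, 68L, 387L, 67L, 66L, 66L,
               200L, 66L, 66L, 594L, 1140L, 150L, 1325L),
    stringsAsFactors = FALSE)
  sites <- data.frame(
    name = need,
    sequence = unname(seqs[need]),
    orientation = c("forward", "reverse", "forward", "reverse", "forward",
                    "reverse", "forward", "reverse", "forward", "reverse"),
    segment = c("COI", "trnL", "trnG", "trnA", "trnP", "CytB",
                "16S", "16S", "16S", "16S"),
    offset = c(890L, 25L, 24L, 20L, 20L, 30L, 100L, 590L, 560L, 1087L),
    stringsAsFactors = FALSE)
  loci <- data.frame(
    locus = c("COI-3p", "ND3", "ND6", "16S-5p", "16S-3p"),
    forward = c("C1-J-2183-Lepido", "ND3-J-Gly-Lepido", "ND6-J-10090-Lepido",
                "LR-J-12888-Dipt/Lepido", "LR-J-13342-Dipt/Lepido"),
    reverse = c("L2-N-3014-Lepido", "ND3-N-Arg-Lepido",
                "ND6-N-10589-Dipt/Lepido", "LR-N-13398-Dipt/Lepido",
                "LR-N-13889-Dipt/Lepido"),
    stringsAsFactors = FALSE)
  genome_spec(segments, sites, loci)
}

# Rebuild genome string and coordinate truth from per-segment sequences
# and site placements (shared by simulate_mitogenome and
# apply_rearrangement).
.assemble_genome <- function(seg_order, seg_seqs, sites, loci) {
  seg_len <- nchar(seg_seqs[seg_order])
  seg_start <- c(0L, cumsum(seg_len))[seq_along(seg_order)]
  names(seg_start) <- seg_order
  genome <- paste(seg_seqs[seg_order], collapse = "")
  L <- nchar(genome)
  sites$start <- seg_start[sites$segment] + sites$offset
  sites$end <- sites$start + nchar(sites$planted)
  truth_segments <- data.frame(label = seg_order, start = unname(seg_start),
                               end = unname(seg_start + seg_len),
                               stringsAsFactors = FALSE)
  tl <- loci
  tl$start <- tl$end <- tl$length <- NA_integer_
  tl$insert_start <- tl$insert_end <- tl$insert_length <- NA_integer_
  tl$disrupted <- FALSE
  for (i in seq_len(nrow(tl))) {
    fi <- match(tl$forward[i], sites$name)
    ri <- match(tl$reverse[i], sites$name)
    if (sites$strand[fi] != "+" || sites$strand[ri] != "-") {
      tl$disrupted[i] <- TRUE
      next
    }
    f0 <- sites$start[fi]
    re <- sites$end[ri]
    len <- ((re - f0 - 1L) %% L) + 1L
    tl$start[i] <- f0
    tl$end[i] <- f0 + len
    tl$length[i] <- len
    tl$insert_start[i] <- f0 + (sites$end[fi] - sites$start[fi])
    tl$insert_end[i] <- f0 + len - (sites$end[ri] - sites$start[ri])
    tl$insert_length[i] <- tl$insert_end[i] - tl$insert_start[i]
  }
  list(genome = genome,
       truth = list(segments = truth_segments, sites = sites, loci = tl),
       seg_seqs = seg_seqs, seg_order = seg_order)
}

#' Simulate a circular mitogenome with planted primer-landing blocks
#'
#' Draws i.i.d. uniform background sequence for every segment, then
#' overwrites each primer-landing block with one concrete expansion of its
#' degenerate primer (chosen by a seeded draw; reverse-oriented primers
#' are planted as the reverse complement, so they bind the minus strand).
#' All coordinates are recorded as ground truth.
#'
#' @param spec A [genome_spec()] (default [default_genome_spec()]).
#' @param seed Integer seed; the whole simulation is deterministic in it.
#' @return Object of class `mito_sim`: list with `genome` (character
#'   string), `spec`, `truth` (lists `segments`, `sites`, `loci` of
#'   0-based half-open coordinates on the forward strand) and `seed`.
#' @export
simulate_mitogenome <- function(spec = default_genome_spec(), seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(seed)
  seg_seqs <- stats::setNames(
    vapply(spec$segments$length, .rand_seq, character(1)),
    spec$segments$label)
  sites <- spec$sites
  sites$strand <- ifelse(sites$orientation == "forward", "+", "-")
  sites$planted <- NA_character_
  for (i in seq_len(nrow(sites))) {
    ex <- expand_iupac(sites$sequence[i], cap = 1e5)
    pick <- ex[sample.int(length(ex), 1L)]
    if (sites$strand[i] == "-") pick <- reverse_complement(pick)
    sites$planted[i] <- pick
    seg <- sites$segment[i]
    substr(seg_seqs[[seg]], sites$offset[i] + 1L,
           sites$offset[i] + nchar(pick)) <- pick
  }
  asm <- .assemble_genome(spec$segments$label, seg_seqs, sites, spec$loci)
  structure(list(genome = asm$genome, spec = spec, truth = asm$truth,
                 seed = seed),
            class = "mito_sim")
}

#' @export
print.mito_sim <- function(x, ...) {
  cat(sprintf("mito_sim: circular genome of %d nt, %d segments, %d loci (seed %d)\n",
              nchar(x$genome), nrow(x$truth$segments), nrow(x$truth$loci),
              x$seed))
  invisible(x)
}

#' Rotate a circular sequence
#'
#' Returns the same circular sequence written from a different origin:
#' position `offset` of `x` becomes position 0.
#'
#' @param x Sequence string.
#' @param offset 0-based rotation offset.
#' @return Rotated string of the same length.
#' @export
rotate_sequence <- function(x, offset) {
  L <- nchar(x)
  offset <- ((offset %% L) + L) %% L
  if (offset == 0L) return(x)
  paste0(substr(x, offset + 1L, L), substr(x, 1L, offset))
}

#' Apply a tRNA-order rearrangement to a simulated genome
#'
#' Transposes or inverts a named segment; primer-landing blocks move (and,
#' for inversions, flip strand) with their segment, and the truth table is
#' recomputed. A locus whose forward primer no longer sits on the plus
#' strand, or reverse primer no longer on the minus strand, is marked
#' `disrupted`. This reproduces the mechanism by which gene-order
#' rearrangements abolish amplification of tRNA-anchored primer sets in
#' some lineages.
#'
#' @param sim A [simulate_mitogenome()] result.
#' @param move List: `op` one of "transpose", "invert", "identity";
#'   `segment` the segment label; for transpositions `after` names the
#'   segment after which it is reinserted (or "origin" for the front).
#' @return A new `mito_sim` with rebuilt genome and truth.
#' @examples
#' \donttest{
#' sim <- simulate_mitogenome(seed = 7)
#' moved <- apply_rearrangement(sim,
#'   list(op = "transpose", segment = "trnG", after = "16S"))
#' }
#' @export
apply_rearrangement <- function(sim, move) {
  stopifnot(inherits(sim, "mito_sim"))
  op <- match.arg(move$op, c("transpose", "invert", "identity"))
  segs <- sim$truth$segments
  seg_seqs <- stats::setNames(
    substring(sim$genome, segs$start + 1L, segs$end), segs$label)
  sites <- sim$truth$sites
  order_now <- segs$label
  if (op != "identity") {
    target <- move$segment
    if (!target %in% order_now) {
      stop("unknown segment '", target, "'", call. = FALSE)
    }
    if (op == "transpose") {
      after <- move$after
      if (!identical(after, "origin") && !after %in% order_now) {
        stop("unknown segment '", after, "'", call. = FALSE)
      }
      order_now <- setdiff(order_now, target)
      pos <- if (identical(after, "origin")) 0L else match(after, order_now)
      order_now <- append(order_now, target, after = pos)
    } else {  # invert
      seg_len <- nchar(seg_seqs[[target]])
      seg_seqs[[target]] <- reverse_complement(seg_seqs[[target]])
      in_seg <- sites$segment == target
      plens <- nchar(sites$planted[in_seg])
      sites$offset[in_seg] <- seg_len - sites$offset[in_seg] - plens
      sites$strand[in_seg] <- ifelse(sites$strand[in_seg] == "+", "-", "+")
      sites$planted[in_seg] <- reverse_complement(sites$planted[in_seg])
    }
  }
  asm <- .assemble_genome(order_now, seg_seqs, sites, sim$spec$loci)
  structure(list(genome = asm$genome, spec = sim$spec, truth = asm$truth,
                 seed = sim$seed),
            class = "mito_sim")
}

#' Simulate a haplotype-structured population of mitogenomes
#'
#' Each individual is assigned one haplotype class per locus; class j
#' differs from the reference by a transition substitution at the j-1-th
#' of `n_polymorphic` seeded polymorphic sites inside the locus insert
#' (never inside a primer-landing block), so classes are pairwise
#' distinct and every requested class is realised (the per-locus class
#' assignment is a random surjection). Individuals are spread over
#' `n_locations`; with `n_shared` set, exactly that many concatenated
#' haplotypes are made to occur in two locations (each concatenated class
#' otherwise lives in a single location).
#'
#' @param sim A [simulate_mitogenome()] result.
#' @param n_individuals Number of individuals.
#' @param k Integer vector of haplotype-class counts per locus (recycled
#'   across loci; each k must satisfy k <= n_individuals and
#'   k <= n_polymorphic + 1).
#' @param n_polymorphic Polymorphic sites seeded per locus (default 8).
#' @param n_locations Number of sampling locations (default 1).
#' @param n_shared Concatenated haplotypes forced to appear in >= 2
#'   locations (default NULL: locations assigned at random and the
#'   realised count recorded).
#' @param seed Integer seed.
#' @param loci Subset of locus labels to simulate (default all).
#' @return List with `sequences` (locus -> named vector of insert
#'   sequences per individual, ready for [assign_haplotypes()]),
#'   `genomes` (named vector of full genome strings), `locations` (named
#'   vector) and `truth` (planted class matrix, per-locus class counts,
#'   concatenated class count, realised shared-haplotype count,
#'   polymorphic site positions).
#' @export
simulate_population <- function(sim, n_individuals, k, n_polymorphic = 8L,
                                n_locations = 1L, n_shared = NULL,
                                seed = 1L, loci = NULL) {
  stopifnot(inherits(sim, "mito_sim"))
  tl <- sim$truth$loci
  if (is.null(loci)) loci <- tl$locus
  tl <- tl[match(loci, tl$locus), , drop = FALSE]
  if (any(is.na(tl$locus)) || any(tl$disrupted)) {
    stop("requested loci must exist and be undisrupted", call. = FALSE)
  }
  n_loci <- nrow(tl)
  k <- rep_len(as.integer(k), n_loci)
  if (any(k < 1L)) stop("k must be >= 1", call. = FALSE)
  if (any(k > n_individuals)) {
    stop("haplotype classes per locus cannot exceed the number of individuals",
         call. = FALSE)
  }
  if (any(k > n_polymorphic + 1L)) {
    stop("infeasible spec: k exceeds available polymorphic sites + 1",
         call. = FALSE)
  }
  L <- nchar(sim$genome)
  if (any(tl$insert_end > L)) {
    stop("origin-wrapping loci are not supported by the population simulator",
         call. = FALSE)
  }
  set.seed(seed)
  transition <- c(A = "G", C = "T", G = "A", T = "C")

  # seeded polymorphic sites and class substitution plans per locus
  poly_sites <- vector("list", n_loci)
  names(poly_sites) <- tl$locus
  for (l in seq_len(n_loci)) {
    span <- seq(tl$insert_start[l], tl$insert_end[l] - 1L)  # 0-based
    # sites private to this locus: overlapping loci (the two 16S
    # fragments) must not pick up each other's substitutions
    for (m in seq_len(n_loci)[-l]) {
      span <- span[span < tl$insert_start[m] | span >= tl$insert_end[m]]
    }
    if (length(span) < n_polymorphic) {
      stop("locus '", tl$locus[l], "' has too few private insert sites for ",
           n_polymorphic, " polymorphic sites", call. = FALSE)
    }
    poly_sites[[l]] <- sort(sample(span, n_polymorphic))
  }

  # random surjective class assignment per locus
  classes <- matrix(NA_integer_, nrow = n_individuals, ncol = n_loci,
                    dimnames = list(sprintf("ind%03d", seq_len(n_individuals)),
                                    tl$locus))
  for (l in seq_len(n_loci)) {
    perm <- sample.int(n_individuals)
    cls <- integer(n_individuals)
    cls[perm[seq_len(k[l])]] <- seq_len(k[l])
    if (n_individuals > k[l]) {
      cls[perm[(k[l] + 1L):n_individuals]] <-
        sample.int(k[l], n_individuals - k[l], replace = TRUE)
    }
    classes[, l] <- cls
  }

  # build individual genomes by applying class substitutions
  ref_chars <- strsplit(sim$genome, "", fixed = TRUE)[[1L]]
  genomes <- character(n_individuals)
  for (i in seq_len(n_individuals)) {
    chars <- ref_chars
    for (l in seq_len(n_loci)) {
      cl <- classes[i, l]
      if (cl > 1L) {
        pos <- poly_sites[[l]][cl - 1L] + 1L   # 1-based
        chars[pos] <- transition[chars[pos]]
      }
    }
    genomes[i] <- paste(chars, collapse = "")
  }
  names(genomes) <- rownames(classes)

  sequences <- lapply(seq_len(n_loci), function(l) {
    stats::setNames(substring(genomes, tl$insert_start[l] + 1L,
                              tl$insert_end[l]), names(genomes))
  })
  names(sequences) <- tl$locus

  # locations and shared concatenated haplotypes
  key <- apply(classes, 1L, paste, collapse = "|")
  location <- rep(1L, n_individuals)
  if (n_locations > 1L) {
    if (n_locations > n_individuals) {
      stop("more locations than individuals", call. = FALSE)
    }
    if (is.null(n_shared)) {
      perm <- sample.int(n_individuals)
      location[perm[seq_len(n_locations)]] <- seq_len(n_locations)
      if (n_individuals > n_locations) {
        location[perm[(n_locations + 1L):n_individuals]] <-
          sample.int(n_locations, n_individuals - n_locations, replace = TRUE)
      }
    } else {
      groups <- split(seq_len(n_individuals), key)
      groups <- groups[order(-lengths(groups))]
      if (length(groups) < n_locations) {
        stop("infeasible: fewer concatenated haplotypes than locations",
             call. = FALSE)
      }
      home <- rep_len(seq_len(n_locations), length(groups))
      for (g in seq_along(groups)) location[groups[[g]]] <- home[g]
      eligible <- which(lengths(groups) >= 2L)
      if (length(eligible) < n_shared) {
        stop("infeasible: not enough multi-member haplotypes to share ",
             n_shared, " across locations", call. = FALSE)
      }
      for (g in eligible[seq_len(n_shared)]) {
        mover <- groups[[g]][1L]
        location[mover] <- (home[g] %% n_locations) + 1L
      }
    }
  }
  location <- stats::setNames(paste0("loc", location), names(genomes))

  hap_loc <- unique(data.frame(h = key, l = unname(location)))
  truth <- list(classes = classes,
                k = stats::setNames(k, tl$locus),
                n_concatenated = length(unique(key)),
                n_shared = sum(table(hap_loc$h) >= 2L),
                poly_sites = poly_sites)
  list(sequences = sequences, genomes = genomes, locations = location,
       truth = truth)
}

#' Simulate a toy multiple alignment with planted structure
#'
#' Generates `n_seq` equal-length sequences from a random reference:
#' columns listed in `variable_cols` are i.i.d. uniform per row
#' (hypervariable), columns in `polymorphic` carry a transition minor
#' allele at the given frequency, and all other columns are perfectly
#' conserved. Useful ground truth for consensus scanning.
#'
#' @param n_seq Number of rows.
#' @param length Alignment length.
#' @param variable_cols Integer vector of 0-based hypervariable columns.
#' @param polymorphic Optional data frame with columns `column` (0-based)
#'   and `freq` (minor-allele frequency).
#' @param seed Integer seed.
#' @return Named character vector of sequences; the reference row is kept
#'   as attribute `reference`.
#' @export
simulate_alignment <- function(n_seq, length, variable_cols = integer(0),
                               polymorphic = NULL, seed = 1L) {
  set.seed(seed)
  transition <- c(A = "G", C = "T", G = "A", T = "C")
  ref <- strsplit(.rand_seq(length), "", fixed = TRUE)[[1L]]
  mat <- matrix(rep(ref, each = n_seq), nrow = n_seq)
  for (j in variable_cols) {
    mat[, j + 1L] <- sample(c("A", "C", "G", "T"), n_seq, replace = TRUE)
  }
  if (!is.null(polymorphic)) {
    for (r in seq_len(nrow(polymorphic))) {
      j <- polymorphic$column[r] + 1L
      minor <- transition[ref[j]]
      hit <- stats::runif(n_seq) < polymorphic$freq[r]
      mat[hit, j] <- minor
    }
  }
  out <- apply(mat, 1L, paste, collapse = "")
  names(out) <- sprintf("seq%03d", seq_len(n_seq))
  attr(out, "reference") <- paste(ref, collapse = "")
  out
}
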