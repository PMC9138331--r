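---
title: "Universal primer design and multi-locus mitochondrial haplotyping with mtmlsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Universal primer design and multi-locus mitochondrial haplotyping with mtmlsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtmlsa)
```

## The problem

When an exotic insect pest is first detected at a border, knowing whether
the specimens are connected to earlier detections, or where they may have
come from, shapes the response. Population-level genetic markers answer
those questions, but classical markers (microsatellites, nuclear SNP
panels) are species-specific and unavailable for the many species nobody
anticipated. Mitochondrial multi-locus sequence analysis (mtMLSA) takes a
different route: a fixed panel of mitochondrial loci — the 5′ COI barcode,
the 3′ COI fragment, the complete ND3 and ND6 genes, and two overlapping
16S rRNA fragments — each amplified with *degenerate* PCR primers designed
to work across whole insect orders, sequenced, and concatenated into a
composite haplotype. The concatenation resolves more population haplotypes
than any single locus, and the primers work off the shelf on species with
no prior sequence data.

`mtmlsa` implements the computational side of that protocol:

* exact algebra on IUPAC-coded degenerate sequences (degeneracy counting,
  expansion, complementation, mismatch-aware matching);
* conserved-window scanning of multiple alignments to enumerate degenerate
  primer candidates and pairs under explicit length/degeneracy budgets;
* deterministic hairpin / self-dimer / cross-dimer screening;
* in-silico PCR on circular mitogenome templates with the single-band
  success rule;
* per-locus and concatenated haplotype assignment with per-locus and
  per-location summaries;
* a seeded simulator of mitogenome populations that provides exact ground
  truth for all of the above.

The two published universal primer tables (Diptera and Lepidoptera, 31
records, 26 distinct primers) ship with the package as plain TSV.

## Degeneracy and the IUPAC algebra

A degenerate primer written in IUPAC codes (R = A/G, Y = C/T, …, N =
A/C/G/T) stands for the set of all concrete sequences obtained by choosing
one base per position. Its *degeneracy* is the size of that set:

$$D(p) = \prod_{i=1}^{|p|} |B(p_i)|$$

where $B(\cdot)$ is the base set of a symbol. Degeneracy measures how many
primer species are present in the synthesised oligo mix — high degeneracy
buys taxonomic universality at the cost of diluting the optimally matching
primer. The published panels trialled degeneracy from 2× up to 1536× and
retained up to 216× for routine use; both numbers are exposed as
configurable budgets, not hard-coded.

```{r}
degeneracy("GGRTARTCNGARTAHCGNCGNGG")   # the most degenerate COI primer
```

`count_mismatches(primer, window)` counts positions where the window base
falls outside the primer symbol's base set, which equals the minimum
Hamming distance between the window and any expansion of the primer. The
test suite verifies this equivalence (and `|expand| == degeneracy`)
against brute-force enumeration oracles built on an independent IUPAC
table.

One transcription convention is worth noting: the published tables print a
degeneracy of 0 for primers with *no* degenerate positions, where the
product rule gives 1. The table reader treats a printed 0 as 1 and
otherwise warns whenever a stated degeneracy disagrees with the recomputed
one — the recomputed value is always authoritative.

## Primer design from alignments

The original priming sites were found by eye in large per-gene alignments.
`mtmlsa` replaces visual inspection with an explicit, deterministic rule:

1. `build_profile()` tallies per-column A/C/G/T/gap counts (ambiguity
   codes in input rows count fractionally across their base sets).
2. `consensus_column()` forms the minimal IUPAC code covering every base
   at frequency ≥ `min_base_freq` among non-gap observations. The default
   0.05 means a base carried by ≥ 5 % of sequences is covered by the
   primer; rarer bases (sequencing noise, singletons) are ignored rather
   than allowed to inflate degeneracy. If no base reaches the threshold
   the most frequent base is used, ties broken alphabetically, so output
   is reproducible byte for byte.
3. `scan_windows()` slides every window of 18–26 nt (the published primer
   length range; configurable within 15–35) and keeps windows whose
   consensus degeneracy is within the budget (default 216). Columns that
   are all-gap or gappier than `max_gap_fraction` (default 0.10)
   disqualify a window — primers cannot span indel-rich regions. Both
   orientations are emitted; candidates are ranked by ascending
   degeneracy, then descending coverage (the fraction of alignment rows
   matched with zero mismatches), then position.
4. `pair_primers()` crosses forward and reverse candidates and keeps
   pairs whose anticipated product size — measured on the gap-stripped
   consensus — falls in the requested range, chosen so products are short
   enough to Sanger-sequence in one read yet long enough to contain
   several variable sites.

Ambiguity in the last three primer positions is reported as a 3′-clamp
flag rather than forbidden: the published designs deliberately tolerated
3′-adjacent degeneracy and it did not generally impede amplification.

## QC scoring

Hairpin and dimer screening is run-length based, not thermodynamic: no
energy model was specified for the original designs, and a deterministic
integer score keeps the filter reproducible. Two IUPAC symbols *can pair*
when some base of one is Watson–Crick complementary to some base of the
other, so every score is the maximum over concrete expansions (verified
against brute force in the tests). `dimer_score()` reports the longest
pairable run over all ungapped antiparallel offsets; `hairpin_score()`
the longest self-complementary stem whose loop is at least 3 nt (the
physical minimum). Stems shorter than 3 bp are too unstable to matter and
score 0. Default thresholds — self/cross-dimer ≤ 5, hairpin ≤ 4, 3′-
anchored run ≤ 3 — are conventional rules of thumb; because several
published primers amplified well despite high scores, `qc_filter()` has a
`report_only` mode that annotates without discarding.

## In-silico PCR

`find_sites()` scans both strands of a template (circular by default —
these are mitogenomes; wrap-around windows are included) for windows with
at most `max_mismatch` mismatches (default 2) and zero mismatches in the
3′-terminal `clamp_len` bases (default 3), since extension is most
sensitive to 3′ mismatches. The wet protocol never states a mismatch
tolerance — annealing was empirical at 42–50 °C — so these defaults are
conservative and configurable, not inferred. Ambiguous template bases
match permissively (intersection of base sets non-empty).

`predict_amplicons()` pairs every forward site on the plus strand with
every reverse site on the minus strand and keeps products within a size
window; `classify_reaction()` then applies the gel rule used to score the
wet PCRs: success is exactly one product of the anticipated size
(±15 % by default); two or more products are `multiple_products`
regardless of size; one product of the wrong size is `wrong_size`.

Properties verified in the tests: the site list equals a naive
all-windows oracle, and rotating a circular template changes coordinates
but never the multiset of amplicon lengths and sequences.

## Haplotyping and concatenation

Haplotypes are defined by exact sequence identity of the amplicon insert
(primer footprints trimmed), with no alignment step: the loci are
fixed-size mitochondrial fragments and haplotype counting is distinct-
sequence counting. Sequences of unequal length are distinct haplotypes,
so indel-bearing 16S variants separate by length. A sequence containing
any N is marked missing at that locus rather than wildcard-merged —
wildcard merging would make counts depend on merge order. Specimens
missing any locus are excluded from the concatenated count but still
count per locus.

For any locus subset the concatenated count $H_c$ obeys

$$\max_l H_l \;\le\; H_c \;\le\; \min\!\big(n_\text{complete},\ \textstyle\prod_l H_l\big),$$

and adding a locus can never decrease it — the resolution gain of
concatenation holds by construction and is asserted on every run of the
property tests. The six-locus panel spans 658 + 733 + 387 + 690 + 510 +
550 = 3528 bp:

```{r}
mtmlsa_loci()
```

`summarize_loci()` reproduces the per-locus/concatenated table layout;
`summarize_locations()` the per-location haplotype counts and the number
of haplotypes shared between locations.

## The simulator and what it does (and does not) show

`simulate_mitogenome()` builds a compact circular genome (~6.2 kb; real
insect mitogenomes are ~15.5 kb — intergenic and non-target spans are
shortened because only the relative layout matters for priming) in the
standard insect gene order, with the Lepidoptera primer set planted as
exact expansions at their anchor positions: the ND3 pair in the flanking
trnG/trnA tRNAs, the ND6 forward primer in trnP with the reverse in CytB,
the 3′ COI pair in COI/trnL, and both 16S pairs within 16S. Offsets are
chosen so the ND6 and 16S products are 690, 510 and 550 nt, matching the
reference locus geometry. Background sequence is i.i.d. uniform A/C/G/T —
the simplest null that still exercises false-priming logic.

`simulate_population()` assigns each individual one haplotype class per
locus. Class $j$ differs from the reference by a transition at the
$j{-}1$-th of `n_polymorphic` seeded sites (default 8) inside the locus
insert, never inside a primer block and never inside a region shared with
another typed locus (the two 16S fragments overlap), so planted per-locus
class counts are recovered *exactly* by `assign_haplotypes()`. Class
assignment is a random surjection, so every requested class is realised;
requesting more classes than `n_polymorphic + 1` or than individuals is an
error. With `n_shared` set, each concatenated haplotype is homed to one
location and exactly `n_shared` multi-member haplotypes have one member
moved to a second location.

`apply_rearrangement()` transposes or inverts a named segment, carrying
primer blocks along (inversions flip them to the other strand). This
reproduces the known failure mechanism of tRNA-anchored primers in
lineages with rearranged gene orders: transposing trnG away from ND3
leaves the trnG-anchored ND3 pair with no correctly flanking sites, so
in-silico PCR returns `no_product` while all other loci still amplify as
single products.

What passing these tests shows: the arithmetic, matching, classification
and counting machinery is exact on data whose truth is known. What it
does not show: performance on real mitogenomes, where primer-site
divergence is phylogenetically structured rather than planted, templates
carry compositional bias (insect mtDNA is strongly AT-rich),
heteroplasmy, nuclear pseudogene copies and sequencing error all exist,
and haplotype structure is shaped by demography. The published empirical
success/failure matrices across dozens of fly and moth families depend on
wet-lab outcomes and are not desk-reproducible; the simulator covers
their *mechanisms* (size filtering, multiple products through internal
priming, rearrangement-induced failure), not their rates.

## Numerical and design choices

* Coordinates are 0-based half-open on the forward strand everywhere,
  including all file output; reverse primers are reported 5′→3′ in primer
  orientation with their site on the forward strand.
* Candidate ranking, consensus tie-breaks and haplotype id assignment
  (dense integers, first-seen order, starting at 1) are all deterministic;
  identical inputs give byte-identical outputs.
* Degeneracies are computed as exact integer products (returned as
  doubles; the largest published value, 1536, is far below any precision
  limit). Window prefiltering uses log-degeneracy sums with an exact
  product recheck, so no window is ever admitted or rejected by rounding.
* Test problem sizes: oracle-equivalence sweeps use 1000 random sequences
  (degeneracy ≤ 10⁴) and 1000 primer/window draws (degeneracy ≤ 256);
  haplotype recovery runs 1000 seeded populations of 4–10 individuals
  over 2–5 loci with up to 4 classes each. These sizes make the
  brute-force oracles exhaustive while keeping the default test run
  fast; the properties asserted are size-independent.
* All randomness is seeded; simulation functions take explicit integer
  seeds and are reproducible across sessions.

## Known limitations

* No thermodynamic Tm/ΔG model: annealing behaviour is outside scope, and
  the QC scores are combinatorial proxies.
* Amplicon prediction considers forward-on-plus × reverse-on-minus
  combinations only; single-primer artefacts (one primer acting at two
  inverted sites) are not modelled.
* Haplotype assignment is exact-match only by design; it will not merge
  sequences differing by sequencing error. Upstream quality control is
  assumed.
* The anticipated product sizes bundled with the stock simulator layout
  derive from the reference locus lengths, not from the original
  appendix of per-set sizes, which is not reproduced here.
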