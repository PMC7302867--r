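---
title: "Polytract detection and locational enrichment: models and methods"
author: "polytractr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polytract detection and locational enrichment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polytractr)
```

## The problem

Very short tandem repeats — runs of a 1, 2 or 3 nt unit, here called
*polytracts* — occupy a few percent of a typical mammalian genome and are
hotspots for replication slippage, mapping error and disease-associated
expansion. `polytractr` does two things:

1. builds an exhaustive, perfect-match census of mono-, di- and
   tri-nucleotide repeats (MNR/DNR/TNR) in any reference genome, with
   canonical species groups, single-nucleotide *hinge* sites and summary
   statistics; and
2. tests whether an arbitrary set of genomic features (editing sites,
   variants, enhancers, binding segments, ...) is over- or
   under-represented inside the repeat *territory*, with exact binomial
   and hypergeometric models, relative risks with confidence intervals,
   and distribution-comparison analytics.

## The repeat model

A polytract is a **maximal perfect run** whose smallest period is 1, 2 or
3 nt; a trailing incomplete unit is part of the run. Minimum sizes are 6
repeated units for MNR and 3 for DNR/TNR, i.e. 6, 6 and 9 nt. The
smallest-period rule resolves clade degeneracy: `AAAAAA` is an MNR only
(period 1), `ATATAT` a DNR only. The three clade scans are otherwise
independent, so a nucleotide may belong to records of different clades
(the last base of a poly-A run can begin a period-2 run); combined
analyses always use the merged nucleotide union. Non-ACGT characters
terminate runs, and soft-masked lowercase is scanned as uppercase.

Because complementary strands carry the same repeat (a poly-A on the
forward strand is a poly-T on the reverse) and a run can be read in any
phase, units are canonicalized into **species** groups closed under
cyclic rotation and reverse complement: 2 MNR groups (A/T, C/G), 4 DNR
groups (TA, CT/GA, CA/GT, GC) and 10 TNR groups (AAC, AAG, AAT, ACC,
GAC, ACT, CAG, AGG, ATC, CGG). Dinucleotide and trinucleotide words that
are themselves homopolymers (AA, CCC, ...) are excluded — their runs are
MNRs — leaving 4 + 12 + 60 mapped words. The group labels are the
field's conventional names and are not always the lexicographically
smallest member of their orbit (e.g. GAC, CAG, CGG), so the catalog is
an explicit validated table rather than a derivation rule.

```{r}
scan_sequence("TTTTTTGATGTGTGTGCAACAACAACAA")
```

A **hinge** is a single nucleotide that separates two tandem polytracts:
one record ends exactly at the hinge, another starts immediately after
it, and the base itself is inside no record of any clade. When several
records share a boundary, the longest abutting record per side labels
the hinge (ties broken by the fixed clade priority MNR > DNR > TNR; the
choice only affects the duplex label, never the hinge count).

**Adjacency extension** widens every record by one nucleotide on both
sides (clipped at sequence ends) before territory construction. Repeat
boundaries are precisely where slippage and mapping artifacts
concentrate, so extension is the default of the enrichment analysis and
can be switched off (`extend = FALSE`).

### Numerical design of the scanner

The production scanner compares the sequence with itself at lag *p* and
reads maximal runs off the run-length encoding; a run of the lagged
equality of length *g* is a maximal period-*p* region of *g* + *p*
bases, which makes two-sided maximality structural rather than checked.
Degenerate runs are rejected by inspecting the leading unit: for a
period-3 region of at least 9 nt, an additional shorter period would
collapse it to a homopolymer (Fine and Wilf), so "leading unit is a
homopolymer" is the only case to exclude. The package also ships
`scan_bruteforce()`, a deliberately naive reference scanner (C++) that
enumerates every interval and tests period, smallest period and
maximality from first principles; the test suite holds the two
implementations identical across thousands of random sequences, and the
same cross-check is recomputed by `scripts/acceptance.R` at every run.

## The enrichment model

For a genome of *N* nucleotides and a territory of *n* nucleotides
(a merged subset of polytracts, one species, one clade, hinges, ...),
a feature with *k* of *M* instances inside the territory is tested
against the null that instances land at the territory's occupancy rate:

$$p_{\mathrm{over}} = \sum_{i=k}^{M} \binom{M}{i}
  \left(\tfrac{n}{N}\right)^i \left(1-\tfrac{n}{N}\right)^{M-i},
\qquad
\mathrm{RR} = \frac{k/M}{n/N}.$$

Under-representation uses the lower tail \(P(X \le k)\). Tails are exact
(`pbinom`), never normal approximations. Two overlap modes exist:
**singleton** counts each instance at most once (an instance spanning
two disjoint territory intervals still counts once), **multiplex**
counts nucleotides (then *M* and *k* are nucleotide totals). One
published rendering of the formula swaps the roles of the feature and
the territory (*n* trials with success probability *M*/*N*); the two
parameterizations differ numerically, and this package follows the
instance-based semantics by default while exposing the swapped form as
`parameterization = "printed"` for comparability.

The 95% CI of the relative risk uses the **Katz log method**,
\(\exp(\log \mathrm{RR} \pm 1.96\,\mathrm{SE})\) with
\(\mathrm{SE} = \sqrt{1/k - 1/M + 1/n - 1/N}\) — the standard
large-sample interval for a risk ratio. At *k* = 0 the RR is 0 and the
CI is flagged undefined rather than fabricated. Simulation in the test
suite confirms ~95% coverage of the design value at *M* = 10,000.

Enhancer-style *embedding* questions ("how many of *E* enhancers embed
at least one polytract?") use the hypergeometric tail on four numbers
(*E*, *k_e*, *N*, *n*). Note this parameterization mixes units — counts
drawn against nucleotides — and is provided exactly as stated for
comparability; the per-enhancer binomial with success probability
\(1-(1-n/N)^{L}\) is the dimensionally consistent alternative and can be
assembled from `binom_p()`.

Significance defaults to a nominal \(\alpha = 0.01\); landscape scans of
many features apply Bonferroni control via `m_tests` (about 100
simultaneous features give an effective threshold near \(10^{-4}\)).
`rr_heatmap_impute()` implements the reporting rule for RR heatmaps:
cells that are not elevated (RR < 1) or not significant (p > 0.01) are
displayed as RR = 1 so only supported effects remain visible; the
under-representation view mirrors the rule.

Length distributions of repeat species are compared with the two-sample
Kolmogorov–Smirnov statistic \(D = \sup_t |F_i(t) - F_j(t)|\); species
are then clustered on the rows of the *D* matrix with distance one minus
the Pearson correlation and average linkage. Both steps are
deterministic, so dendrograms reproduce bit for bit.

## Genomic region categories

Each polytract is assigned one of seven categories from an
Ensembl-dialect GTF, by precedence:

`exonic_splicing` > `UTR5` > `UTR3` > `ncRNA` > `intronic` >
`up_down_stream` > `intergenic`.

`exonic_splicing` is the coding (CDS) part of a protein-coding exon or a
window of `splice_window` (default 2) nt around an intron/exon boundary;
the UTR categories would be unreachable if plain exon overlap took top
precedence, which is why the coding part anchors the category. `ncRNA`
is an exon of any non-protein-coding biotype. `intronic` is the
remaining gene body, `up_down_stream` the `updown_kb` (default 1 kb)
flank anchored at the transcription start/end site. The precedence
order and the identity of the ncRNA category follow the ANNOVAR
convention; a repeat spanning two categories gets the higher-precedence
one. Duplicate exon lines are collapsed to unique intervals, and
introns are derived per transcript from the exon gaps, so no separate
transcript database is required.

## The synthetic-data generator

Every statistic above is testable without downloading a genome:

* `generate_background()` draws an i.i.d. ACGT sequence and
  deterministically repairs any accidental qualifying run (substituting
  the run's center base) until a full scan is empty.
* `plant_tracts()` writes requested perfect repeats into the background,
  repairs flank bases that would extend a run, verifies by re-scanning,
  and returns the genome together with its exact truth records. Planted
  repeats are at least 2 nt apart unless a hinge (1-nt gap) is
  explicitly requested.
* `generate_features()` places *M* instances independently: with
  probability \(\pi = c \cdot n/N\) uniformly inside the territory,
  otherwise uniformly outside. The singleton overlap is then exactly
  binomial with success probability \(\pi\), so `c = 1` realizes the
  null of the enrichment test and the empirical RR converges to *c*.

What the generator deliberately does **not** emulate: realistic base
composition (isochores, GC gradients), N-gaps, near-repeats one
mismatch away from qualifying, or feature classes with intrinsic
spatial clustering. Passing tests therefore demonstrate the
correctness of the detection and inference machinery, not robustness
to compositional artifacts of real genomes.

```{r}
bg <- generate_background(5000, seed = 7)
pl <- plant_tracts(bg, data.frame(pos = c(1000, 2000),
                                  unit = c("A", "CAG"),
                                  n_units = c(8, 5),
                                  partial_nt = c(0, 2)))
scan_sequence(pl$genome)
```

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| minimum units | 6 (MNR), 3 (DNR/TNR) | census definition; 6/6/9 nt with partial terminal units admitted |
| `min_len` of `filter_long_tnr()` | 18 nt | "6 units" long-TNR subset convention |
| `extend` | `TRUE` for tracts, `FALSE` for hinges | +/-1 nt adjacency extension of the territory |
| `mode` | `singleton` | instance-level vs nucleotide-level overlap |
| `alpha` | 0.01 | nominal significance level |
| `m_tests` | 1 | Bonferroni divisor for landscapes |
| `updown_kb` | 1 | gene-flank width, kb |
| `splice_window` | 2 nt | half-width of splice-junction windows |
| `conf_level` | 0.95 | Katz interval level |

Genome size *N* counts all bases of the analyzed sequences including
Ns, matching the census convention of dividing by total genome size;
hinge territories default to the exact single bases (no extension), as
the hinge is itself a boundary object.

## Problem sizes used in validation

The shipped checks run at desk scale, chosen so the full suite
completes in minutes on one CPU: scanner-vs-reference equivalence on
1,000 random 500-nt sequences; exact recovery of planted repeats in
fifty 1-Mb synthetic genomes; null calibration with 10,000 feature sets
of *M* = 1,000 on a 100-kb toy territory occupying 7.1% of its genome
(a proportion at which the discrete binomial tail sits essentially at
the nominal 1%, so the false-positive rate is informative); and CI
coverage over 1,000 replicates at *M* = 10,000 for enrichment
multipliers 2, 4 and 8. `scripts/acceptance.R` recomputes the same
quantities from scratch at slightly reduced replicate counts and writes
them as JSON.

## Known limitations

* Only perfect repeats of unit length 1–3 are modeled; fuzzy repeats
  and 4–6 nt units are out of scope.
* The binomial null treats feature instances as independent single
  draws; spatially autocorrelated features (peaks, clustered editing
  sites) violate this and should be interpreted with care, especially
  in multiplex mode where nucleotides of one instance are clearly not
  independent.
* The hypergeometric embedding test inherits the unit-mixing of its
  published four-number parameterization (see above).
* Region annotation reflects the supplied GTF; fractions such as the
  intronic/intergenic share of a real genome vary with annotation
  version and contig selection.
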