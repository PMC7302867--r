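# polytractr

Census and locational enrichment analysis of perfect short tandem
repeats ("polytracts") in reference genomes.

## What it does

Very short tandem repeats — maximal perfect runs of a 1, 2 or 3 nt unit
(MNR/DNR/TNR) — cover a few percent of a typical genome and concentrate
replication slippage, mapping error and disease-associated expansion.
`polytractr`:

* scans any FASTA genome exhaustively for perfect MNR/DNR/TNR runs
  (minimum 6/3/3 units, i.e. 6/6/9 nt, incomplete terminal unit
  included), assigning each run the clade of its smallest period and a
  canonical **species** label closed under strand and phase: 2 MNR
  groups (A/T, C/G), 4 DNR groups (TA, CT/GA, CA/GT, GC), 10 TNR groups
  (AAC, AAG, AAT, ACC, GAC, ACT, CAG, AGG, ATC, CGG);
* finds **hinges** — single nucleotides separating two tandem
  polytracts — and reports their flanking species duplex;
* builds repeat **territory** (merged nucleotide sets, optionally
  extended by one neighboring base on each side) and tests arbitrary
  genomic features for over-/under-representation inside it with the
  exact binomial model

  ```
  p_over = sum_{i=k..M} C(M,i) (n/N)^i (1 - n/N)^(M-i),   RR = (k/M) / (n/N)
  ```

  in instance ("singleton") or nucleotide ("multiplex") overlap mode,
  with Katz 95% confidence intervals for the relative risk, a
  four-number hypergeometric embedding test, and Bonferroni control for
  feature landscapes;
* annotates repeats into seven genomic region categories from an
  Ensembl GTF, compares species length distributions with pairwise
  Kolmogorov–Smirnov statistics and 1-correlation/average-linkage
  clustering;
* simulates genomes with planted repeats and feature sets with a
  designed enrichment multiplier, so the whole pipeline is testable
  offline.

## Worked example

```r
library(polytractr)

# a 100-kb synthetic genome with 50 planted repeats and 2 hinges
bg <- generate_background(100000, seed = 42)
pl <- plant_tracts(bg, random_plant_spec(100000, 50, seed = 43,
                                         n_hinges = 2),
                   allow_hinge = TRUE)

tracts <- scan_sequence(pl$genome)
summarize_catalog(tracts, c(seq = 100000L), by = "clade")
#>   bin count nucleotides percent mean_length median_length density_per_mb empty
#> 1 MNR     2          28   0.028    14.00000            14             20 FALSE
#> 2 DNR     7         101   0.101    14.42857            15             70 FALSE
#> 3 TNR    41        1019   1.019    24.85366            25            410 FALSE

nrow(find_hinges(tracts, c(seq = 100000L)))
#> [1] 2

terr <- polytract_territory(tracts, c(seq = 100000L), extend = TRUE)
terr
#> polytract territory 'all': n = 1,246 of N = 100,000 nt (1.246%),
#> 48 interval(s), adjacency-extended

# features planted 3x denser inside the territory than chance
feats <- generate_features(terr, 2000, c = 3, seed = 44)
polytract_enrichment(feats, terr, feature_id = "simulated_sites")
#>           feature subset      mode direction  k    M    n     N         p    RR
#> 1 simulated_sites    all singleton      over 72 2000 1246 1e+05 7.563e-15 2.889
#>   ci_low ci_high significant
#> 1  2.288   3.649        TRUE
```

The scan recovers every planted repeat exactly; 72 of 2,000 simulated
sites fall inside the 1.25% territory, an empirical relative risk of
2.9 (95% CI 2.3–3.6, bracketing the design value 3) with an exact
binomial tail of 8e-15 against uniform placement.

A command-line interface wraps the same functions
(`exec/polytractr scan|hinges|summarize|enrich|annotate|simulate`); see
`?polytractr_main`.

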