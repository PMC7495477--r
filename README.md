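# memstab

Selection of thermostabilising point variants for α-helical membrane
proteins.

Membrane proteins are usually too unstable in detergent for structural
and biophysical work, and the standard remedy — alanine-scanning every
position for stabilising substitutions — costs hundreds of constructs.
`memstab` ranks candidate stabilising single-residue variants from
sequence-level information so that a campaign of a few dozen variants
can capture most of what a full scan would find. Three independent
evidence streams are combined:

* **data-driven** — a scoring matrix derived from scanning-mutagenesis
  stability datasets by abundance-weighted, rank-based scoring of six
  bioinformatic factors;
* **deep-sequence** — "odd-one-out" residues in a large multiple
  sequence alignment, substituted toward the family consensus;
* **model-based** — per-model unfolding ΔΔG tables from saturation
  mutagenesis of structural models, aggregated across models.

The package also designs the non-overlapping inverse-PCR mutagenic
primer pairs needed to build the selected variants, and analyses the
GFP-based thermal-challenge assays used to test them (four-parameter
logistic melting curves, ΔTm with propagated errors, single-temperature
screens, enrichment evaluation). Seeded synthetic-data generators for
every input class make the whole pipeline testable end to end.

## The scoring model

Each stability record (variant, % of wild-type stability) is classified
as stabilising (> 140%), destabilising (< 80%) or neutral. For every
factor f with levels ℓ (amino-acid identity, topology class,
conservation decade, lipid-contact bin, helix-contact bin, disorder
bin), abundance-weighted class frequencies are

    w_stab(ℓ)   = #stabilising records at ℓ / #records at ℓ
    w_destab(ℓ) = #destabilising records at ℓ / #records at ℓ

so rare and common levels are comparable. Levels are then ranked:
ordered by w_stab descending, rank r gets stabilising score L + 1 − r;
ordered by w_destab descending, rank r gets destabilising score r; the
combined score is the sum. A level ranked 4th of 20 for stabilising
association and last for destabilising association therefore scores
17 + 20 = 37. The score of a position is the **product** of its factor
scores, normalised to percent of the target's maximum, and the proposed
substitution is alanine (leucine for native alanine).

Primer melting temperatures use nearest-neighbour thermodynamics,

    Tm = (ΔH°_init + Σ ΔH°_stack) · 1000
         ─────────────────────────────────────── − 273.15
         (ΔS°_init + Σ ΔS°_stack + R · ln C_p)

with the unified dinucleotide parameter set, C_p the primer
concentration (default 0.5 µM) and an entropic monovalent-salt
correction (default 50 mM; set `na_conc = 1` for the bare 1 M reference
equation). ΔTm errors propagate in quadrature:
`SEM_ΔTm = sqrt(SEM_WT² + SEM_variant²)`.

## Worked example

```r
library(memstab)

fx <- sim_stability_dataset(1)        # 2,000 records, 300-residue target
m  <- stability_matrix(fx$records, fx$features)
print(m)
#> Stability scoring matrix (abundance-weighted, rank-based)
#>   records: 2000 -> stabilising 258, neutral 752, destabilising 990
#>   class thresholds: >140% stabilising, <80% destabilising
#>   factors: amino_acid, topology, conservation_bin, lipid_contact_bin, ...

cl <- data_driven_candidates(m, fx$target, fx$features)
print(cl, n = 3)
#> Candidate list (data_driven): 300 ranked entries
#>       module position wt_aa mut_aa   score norm_score rank
#>  data_driven       43     G      A 5702400  100.00000    1
#>  data_driven      223     A      L 4740120   83.12500    2
#>  data_driven       73     G      A 2882880   50.55556    3

ec <- enrichment_curve(cl, fx$truth)
ec$cumulative_pct[75]                 # % of stabilisers in top quartile
#> 41.4
```

The matrix classifies the 2,000 records against the 140%/80% thresholds
(258 stabilising, 990 destabilising here), ranks every factor level,
and the resulting position ranking concentrates 41% of the known
stabilisers in the first quartile — against 25% for random ordering.

Primer design and melt analysis:

```r
pp <- design_primer_pair(pl, pl$cds_start, parse_variant_label("G30A"))
print(pp)
#> Primer pair for G30A (GGC -> GCC)
#>   forward (25 nt, Tm 65.2 C): CTCTGCGCAGGCCCATCGCTATCGC
#>   reverse (40 nt, Tm 65.5 C): TTCTGAATAAAACCATGAACATGCGCCTGTTCTTGGTATA
#>   annealing recommendation: 62.0 C

res <- melt_summary(curves, wildtype = "WT")
#>   construct mean_tm sem_tm n delta_tm sem_delta_tm      status
#>          WT    49.4    0.1 8      0.0          0.1        <NA>
#>       G130A    61.9    0.2 3     12.6          0.2 stabilising
```

A command-line entry point ships in `inst/exec/memstab` with
subcommands `score`, `select`, `primers`, `melt`, `evaluate` and
`simulate`; all outputs are plain TSV and byte-reproducible under a
fixed `--seed`.

## Vignette

`vignettes/memstab-methods.Rmd` documents the models and their
assumptions, every tunable parameter with its default and rationale,
what the synthetic generators emulate (and what they deliberately do
not), and the package's numerical choices and known limitations.
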