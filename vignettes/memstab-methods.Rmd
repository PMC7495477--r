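---
title: "memstab: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{memstab: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memstab)
```

# Scope

`memstab` selects candidate thermostabilising point variants of
α-helical membrane proteins from three evidence streams, designs the
mutagenic primers to build them, and analyses the thermal-challenge
assays used to test them. This vignette records the models, the
tunable parameters, and the design decisions that were genuinely open,
with their rationale. It states no empirical result that the package's
tests do not themselves compute.

# The data-driven scoring matrix

## Model

Stability records carry a relative stability in percent of wild-type.
Classification is strict: above 140% stabilising, below 80%
destabilising, boundaries inclusive to neutral. The thresholds are
deliberately stringent so that only clear effects train the matrix;
both are arguments of `stability_matrix()`.

Six per-residue factors are used: wild-type amino acid (20 levels),
topology class (6 levels: TM helix, cytosolic helix/loop,
extracellular helix/loop, re-entrant), conservation decade (10 levels),
and lipid-contact, helix-contact and disorder scores binned into five
equal bins on [0, 1]. Decade binning for conservation matches the
granularity at which conservation effects on stability are usually
reported (moderately conserved positions tolerate substitution best);
five bins for the unit-interval predictors keep at least tens of
observations per level at realistic dataset sizes (~2,000 records).
Bin edges are fixed, not data-dependent, so matrices from different
datasets are comparable.

Abundance weighting divides each level's stabilising (destabilising)
count by that level's total observation count. Neutral records enter
the denominator but neither numerator: the weight is the frequency with
which observing that level went with a clear effect, which removes the
skew toward abundant levels (alanine vs tryptophan). Rank conversion
then discards the magnitudes: levels ordered by stabilising weight
descending receive stabilising score L+1−r at rank r, levels ordered by
destabilising weight descending receive destabilising score r, and the
combined score is the sum, in 2..2L. The canonical worked example: a
residue type ranked 4th of 20 on the stabilising side and last on the
destabilising side scores 17 + 20 = 37.

A position's final score is the **product** of its five (or six)
combined factor scores. The factor scores are multiplied as raw
integers, not rescaled per factor first: the combined integer is
presented as the quantity of interest by the construction above, and
rescaling per factor would only change scores by a constant overall
factor within a fixed factor set, leaving ranks unchanged. Scores are
reported as percent of the per-target maximum. No smoothing is applied
to sparse levels; with the strict rank conversion, smoothing could only
reorder near-ties, and the tie rules below already make those
deterministic.

## Decisions and degeneracies

* **Ties** in weight are broken by observation count (better-sampled
  level first), then lexicographic level name. Deterministic output is
  worth more here than any claim about which tie order is "right".
* **Unseen levels** at scoring time (a residue type absent from the
  training records, say) receive the median combined score of their
  factor, with a warning, rather than an error: small training sets
  will miss rare residues and a hard failure would make the tool
  unusable on exactly the targets it is for. The warning keeps the
  fallback visible.
* **Disorder** is a sixth factor, included by default
  (`include_disorder = TRUE`); the five-factor mode is selectable
  because the disorder factor was a later addition to this kind of
  scoring and five-factor ranking is the variant validated in vitro.
* **Multi-state records** (apo/agonist/antagonist) for one variant are
  treated as independent records — the conformations differ, so the
  stability readouts are genuinely distinct measurements.
* Fewer than two observed levels of a factor is an error (nothing to
  rank).

# Deep-sequence stream

The full covariance treatment of family sequence data (pairwise
couplings, sequence reweighting) is out of scope; tables produced by
such software are ingested unchanged via `read_effect_table()` and a
column map. The built-in scorer is the independent-sites
simplification: for each query position, `effect(pos, x) =
ln((count_x + p)/(count_wt + p))` over the alignment column, with
pseudocount `p = 1` guarding empty counts. Positive effects mean the
query residue is an "odd-one-out" relative to the family. Selection
keeps strictly positive effects, takes the best substitution per site,
normalises to percent of the best site, and keeps sites strictly above
the 70% cutoff (the `cutoff_percent` default).

# Model-based stream

Per-model tables of unfolding ΔΔG are aggregated with the convention
**negative = stabilising** (the most negative mean change is the
strongest stabilisation). The per-position count of models with
negative ΔΔG is the primary sort key — agreement across models guards
against single-model artefacts — with mean ΔΔG ascending as the
secondary key. With one model this reduces exactly to a sort by ΔΔG.
Normalised scores are percent of the most negative mean, restricted to
the favourable sign so percents stay in (0, 100]; the 70% cutoff
selects positions for the saturation scan, which is read from the
single best model (lowest post-minimisation unfolding energy). Per
selected site the substitution with the most negative scan ΔΔG wins;
sites where no substitution is stabilising are dropped with a warning.
Ties anywhere break by position ascending.

# Selection policies

Exclusion lists (literature-critical residues) drop candidates
position-wide before anything else. "Top X% of ranked sites" is
interpreted per module — each module ranks the whole sequence — which
matches how per-module quotas are used in practice. Overlap rules:

* `highest_score_wins`: one candidate per position, by normalised
  score; ties break by module priority (data-driven > model-based >
  deep-sequence) then substitution alphabetically. Normalised percent
  scores are compared directly across modules; this is a documented
  approximation, since the raw scores live on different scales.
* `drop_identical_substitution_only`: only exact (position,
  substitution) duplicates collapse.
* `allow_all`: different substitutions at one site all survive; exact
  duplicate pairs still collapse to one entry.

Quotas take the top of each module's surviving ranked list; a quota
larger than the list warns and takes all.

# Primer design

Primers are for whole-plasmid inverse PCR: a forward primer carrying
the mutant codon and a back-to-back reverse primer on the opposite
strand, products blunt-ligated. The mutant codon minimises nucleotide
edits from the wild-type codon, with ties broken by host codon usage
(an E. coli table ships as the default, replaceable) then
alphabetically.

Melting temperatures use the unified nearest-neighbour parameter set
(ΔH° in kcal/mol, ΔS° in cal/(K·mol), terminal-dependent initiation
terms), primer concentration C_p = 5×10⁻⁷ M by default (0.5 µM, the
usual PCR primer concentration), R = 1.987 cal/(K·mol). Bases
mismatched against the template contribute no stack terms (their two
flanking stacks are skipped) — the simplest defensible treatment short
of a full mismatch parameter set.

**Salt correction.** At the parameter set's 1 M reference state, any
primer long enough to carry ten matched bases on each side of a
mismatch (≥ 21 nt) melts in the mid-70s °C at 0.5 µM — above the
65–70 °C design window, which would make the iterative optimisation
below inert and pin every primer at the flank floor. The standard
entropic monovalent-salt correction (0.368·n_stacks·ln[Na⁺]) is
therefore applied, with [Na⁺] = 50 mM by default as a PCR-typical
monovalent concentration. Under it the window corresponds to realistic
mutagenic primer lengths (~25–40 nt). Setting `na_conc = 1` in
`thermo_params()` recovers the bare reference-state equation.

The forward primer is seeded with 10 nt on each side of the mutant
codon and grown (or shrunk) at the 3′ end only — the 5′ flank is the
floor — until its Tm enters [65, 70] °C, taking the shortest in-window
length; if single-base steps skip the window, the closest achievable
length is used. The reverse primer starts immediately 5′ of the
forward's first template base and grows at its 3′ end to minimise
|Tm_rev − Tm_fwd|. The annealing recommendation is min(Tm_fwd, Tm_rev)
− 3 °C capped at 62 °C; because the forward optimisation takes the
shortest in-window length (Tm near 65), the recommendation sits at the
62 °C target whenever the window is reachable. The annealing formula
itself is a package convention (a −3 °C margin under the limiting
primer), as only the 62 °C goal is standard.

Every design asserts, in silico, that blunt ligation of the
whole-plasmid amplicon reconstructs the wild-type plasmid with exactly
the intended codon replaced, that primers never overlap, and that the
reverse primer is at least 18 nt. Hairpin/primer-dimer screening is
out of scope.

# Melting-curve analysis

Signals are normalised to the on-ice reference lane, then fitted with
the variable-slope four-parameter logistic

y(T) = bottom + (top − bottom) / (1 + exp(h·(T − Tm)))

by nonlinear least squares (Levenberg–Marquardt). Multi-start
initialisation: Tm₀ at the temperature of half-maximal normalised
signal (by linear interpolation), h₀ ∈ {0.2, 0.5, 1.0}, top₀/bottom₀
from the data extremes; the best residual sum wins. If every start
fails (degenerate data), a direct Nelder–Mead least-squares search
supplies parameters so the caller still gets a diagnosable object. A
fit is **reliable** only when the fitted Tm lies inside the sampled
temperature range, the curve decreases (h > 0), and at least 20% of
the on-ice signal is lost across the transition — otherwise no melt
was actually observed in the sampled window.

Per-construct Tm is the mean over repeat fits; SEM = sd/√n for n > 1
and absent for n = 1. ΔTm errors propagate in quadrature,
SEM_Δ = √(SEM_WT² + SEM_var²), absent when either input is absent.
The campaign classification cutoff is the mean of the available SEM_Δ
values: |ΔTm| at or beyond the cutoff is called
stabilising/destabilising. Reported tables round to one decimal in °C
and classify on the rounded values, matching how such tables are read.
Multiple intensity columns per lane (double glycosylation bands) are
summed before fitting.

The single-temperature screen pools every heated/on-ice survival
measurement (relative to wild-type) and takes the lower bound of the
two-sided t-based 95% confidence interval of the pooled mean as the
hit cutoff; a variant is a hit when its median relative survival
strictly exceeds the cutoff. Whether such published cutoffs derive
from a CI on the pooled mean, the pooled median, or the wild-type
distribution alone is not decidable from typical descriptions; the
pooled-mean lower bound is adopted and `cutoff` overrides it for
reproducing a specific campaign's literal value.

# Evaluation

`enrichment_curve()` reports, at each rank, the cumulative percent of
all known stabilisers found and the running true-positive rate.
`random_baseline()` draws repeated position subsets without
replacement (default 10 samplings of 100) and reports mean ± SD class
counts. `success_rate()` is the integer percent of tested variants
confirmed stabilising (or destabilising), rounded half away from zero.
No significance testing of enrichment is performed.

# Synthetic fixtures

The generators emulate the statistical structure of scanning-campaign
data for helical membrane proteins, not any real protein family:

* `sim_stability_dataset()` — 2,000 records over a 300-residue target
  by default. Class probabilities start from base rates of 7.6%
  stabilising and 48.5% destabilising per position and are multiplied
  by planted factor effects: G > T > A > Q > E > H enriched among
  stabilisers, I/Y/W/D/C/V among destabilisers, TM-helix positions
  stabilising and cytosolic-helix positions destabilising on
  substitution, conservation effects peaking at 50–60% (stabilising)
  and 80–90% (destabilising), plus mild lipid/helix/disorder trends.
  Effect multipliers were fixed once at values giving campaign-like
  enrichment (roughly 40% of stabilisers in the first ranked quartile)
  and are not exposed as tuning knobs. Relative stabilities are drawn
  strictly inside the class intervals, so classification is exact by
  construction.
* `sim_msa()` — 500 sequences by default (a scaled-down stand-in for
  the >8,000-deep alignments used in practice), dominant residue at
  ~70% per column, planted odd-one-out query positions.
* `sim_ddg_tables()` — planted sites with mean ΔΔG in −2.5..−1.5
  kcal/mol across models, background in −0.3..+1.5, per-model Gaussian
  noise, one model with the lowest unfolding energy carrying the
  saturation scan.
* `sim_melt_curves()` — 4PL signal plus Gaussian noise on the
  normalised scale, on-ice lane included, default grid 20–90 °C.
* `sim_plasmid()` — usage-weighted reverse translation of a target CDS
  in a random backbone of configurable GC content.

What the fixtures do **not** emulate: real family phylogeny and
covariance (columns are independent), realistic energy-function error
structure (noise is homoscedastic Gaussian), gel quantification
artefacts, or expression failure. Passing tests therefore demonstrate
that the machinery recovers planted structure of the right shape and
size, not field performance on real targets.

All generators are fully deterministic under their seed, and every
fixture is written in exactly the file dialects the readers and the
CLI consume (round-trip tested).

# Test problem sizes

The suite exercises the pipeline at the sizes above: 20 seeds of the
2,000-record dataset for matrix recovery and enrichment, 50 seeds of
the ΔΔG generator at 1 kcal/mol noise for site recovery, 100 seeds of
noisy melt curves for Tm accuracy (median error < 0.5 °C at 3% noise),
and 100 seeded plasmids for the primer contract. These sizes were
chosen as the smallest that make the stochastic checks stable across
seeds.

# Known limitations

* Cross-module comparability of normalised percent scores is an
  approximation; the streams' raw scores measure different things.
* The consensus scorer ignores covariation between positions and
  sequence redundancy; genuine covariance-model output should be
  preferred when available.
* The nearest-neighbour model treats mismatched bases as contributing
  nothing, rather than using mismatch-specific parameters.
* Classification cutoffs derived from campaign SEMs are only as good
  as the repeat structure; single-repeat variants carry no error and
  are classified against the other variants' cutoff.
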