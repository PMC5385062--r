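---
title: "Methods: screening, primer design and niche statistics for dark fungal lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, primer design and niche statistics for dark fungal lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darktaxa)
```

## The problem

Global soil ITS amplicon surveys consistently recover a large fraction of
OTUs that match no named species even loosely: at 80% ITS similarity —
roughly family-to-order rank in fungi — these "dark" OTUs cannot be placed
anywhere in the fungal tree. A short ITS2 fragment carries too little
phylogenetic signal to resolve their position, so the workflow this package
implements recovers the flanking conserved genes instead: screen the
unidentifiable OTUs, cluster them into candidate order-level groups, design
*taxon-specific* PCR primers inside the variable ITS so that each primer,
paired with a universal eukaryote rRNA primer, pulls out the 18S or 28S
gene of exactly one target group from a complex soil DNA extract; assemble
the reads into long 18S–ITS–28S constructs with an overlap-based chimera
check; and finally quantify each group's environmental niche from its
occurrences across sites.

Every stage is a plain function over tibbles, and a synthetic-data module
generates all inputs the pipeline needs, so the whole chain is testable
without any external database.

## Sequence identity and clustering

All identity computations use one definition: a global alignment with free
end gaps under unit match scoring (match 1, mismatch 0) plus an
infinitesimal gap-extension cost (1e-4) that, among alignments with the
same number of matches, selects the one with fewest gap columns. Identity
is matches divided by the aligned columns of the end-gap-free span, and
*coverage* ("overlap") is that span's column count. Under this scoring,
unrelated random DNA scores about 0.48, sequences at 3% substitution
divergence about 0.97, and at 30% divergence about 0.73 — so the 0.80
screening/linkage threshold cleanly separates within-group from
between-group comparisons, and the identity of a random reference never
drifts above the screen the way a short high-identity local hit would.
All coordinates anywhere in the package are 0-based half-open.

* `screen_unidentifiable()` keeps OTUs whose best identity against every
  named reference is below 0.80 (the operational definition of a dark
  OTU), retaining the best hit per OTU.
* `single_linkage_cluster()` links two OTUs iff identity ≥ 0.80 *and*
  coverage ≥ 100 bases, and takes connected components — single linkage,
  order-independent by construction (components are renumbered by their
  smallest member id).
* `select_targets()` regroups each cluster at a stricter, exclusive 0.95
  bound: every ≥2-member component becomes a *grouped* target (one primer
  set serving nearly identical OTUs), every singleton an *individual*
  target, so each cluster — in particular every major cluster (> 10
  OTUs) — contributes at least one target. When the number of individual
  targets per cluster is capped, the most abundant members win (total
  reads, ties by id): the most abundant OTU is the one most likely to be
  recoverable by PCR from the original extract.

Components at 0.95 are used for grouping (rather than requiring all
pairwise links) because transitive chaining is exactly what single-linkage
tools produce in practice; with the package's default synthetic
divergences (3% within groups) the two definitions coincide.

## Primer design

Candidates are every substring of length 16–21 of the variable window (the
ITS2 record), as-is for forward primers and reverse-complemented for
reverse primers. For a grouped target a candidate is eligible only if the
underlying template slice is identical across all members — one oligo must
serve the whole group. Five criteria filter the enumeration, all bounds
configurable in `primer_config()`:

| criterion | bound | measured by |
|---|---|---|
| melting temperature | 54–58 °C | `melting_temperature()` |
| GC content | 33–62% | `gc_fraction()` |
| length | 16–21 bases | — |
| 3′-decamer specificity | exact matches in < 20 OTUs | `three_prime_specificity()` |
| flank distance | > 20 bases from both window boundaries | — |

The GC window implements the design bound on base composition as a GC
percentage: a bound read instead as an AT:GC odds ratio in [0.33, 0.62]
would asymmetrically forbid GC-poor oligos and contradicts standard primer
practice.

The default Tm model is the unified nearest-neighbour thermodynamic table
with duplex initiation terms, the entropic monovalent-salt correction
0.368 (N−1) ln[Na+], and the CT/4 concentration term for
non-self-complementary duplexes, evaluated at 0.5 µM total oligo and
50 mM Na+ — ordinary end-point PCR conditions. The Wallace 2/4 rule is
available as a simple alternative (`method = "wallace"`); the 54–58 °C
window applies to whichever estimator the configuration selects. The
nearest-neighbour implementation is checked in the test suite against
values frozen from an independent implementation, and satisfies duplex
symmetry (Tm of an oligo equals that of its reverse complement).

The 3′-decamer count scans *both strands* of every OTU (primers act on
double-stranded templates) for the candidate's terminal 10-mer as an exact
substring; the candidate's own target counts, so a self-match of 1 is the
floor. Passing candidates are ranked by fewest decamer hits, then Tm
closest to 56 °C, then longer length, then 5′ position — specificity is
the scarce resource, Tm centrality buys PCR robustness, longer oligos bind
more stably, and position is only a deterministic tie-break.

Reverse specific primers are paired with the forward universal primers
NS5a and NS7a (amplifying the 18S gene); forward specific primers with the
reverse universals TW13 and LR5 (28S gene); two alternative pairs per
candidate give each target a second chance on the bench. The universal
oligo sequences shipped in `default_universal_primers()` are **synthetic
stand-ins** (the real oligos are vendor-table data, not package truth);
they are editable configuration, and the simulator plants their binding
sites so in-silico PCR is exercised end to end.

`insilico_pcr()` reports a product wherever the two primers of a pair bind
convergently within 3000 bases; binding is an exact plus-strand match of
the primer (or of its reverse complement, for the reverse role), and when
`max_mismatch > 0` substitutions are tolerated anywhere *except* the 3′
decamer. More than one product on a template flags the pair as unspecific
there.

If a grouped target admits no group-wide compliant oligo, the pipeline's
design stage falls back to designing individual primers for the group's
most abundant member — the same decision a bench workflow makes when one
primer cannot serve a set of near-identical templates.

## Construct assembly and chimera control

Sanger reads of the flanking genes typically overlap the pyrosequenced
ITS2 fragment, and that overlap is the package's first chimera filter.
`overlap_consistency()` scans every ungapped dovetail placement of one
segment against the other (both orientations, containment allowed) and
scores each placement over its *entire* overlap window (matches −
mismatches, ties to the longer overlap). Not trimming inside the window is
the point: a chimeric junction inside the overlap depresses the identity
of the whole window instead of being clipped away. Verdicts: `ok` when
the best overlap spans ≥ 30 bases at ≥ 0.97 identity, `chimera_flag` when
a long overlap disagrees, `no_overlap` otherwise. The 30/0.97 defaults
reflect Sanger-grade, quality-trimmed reads, where true overlaps are
near-identical; both are configurable.

`assemble_construct()` orders 2–4 segments 18S → ITS → 28S by their
claimed region, chains `ok` overlaps into one merged sequence (length =
Σ lengths − Σ overlaps), resolves disagreeing bases inside an `ok` overlap
in favour of the Sanger segment, and aborts with `chimera_flag`,
`no_overlap` or `conflict` (two same-region claims with different
sequence) without producing a construct. Assembly is invariant to segment
input order.

## Niche statistics

For a group of OTUs and an environmental variable, the group sample is the
variable's values at occupied sites, each weighted by the summed member
occurrences there (binary occupancy is the degenerate case); the null
sample is the variable at *all* non-missing sites. Sites missing a
variable are dropped from analyses of that variable only; a group with no
occurrences is reported "nd" rather than silently dropped.

A niche is **significantly narrow** iff (i) the null SD exceeds the
weighted group SD more than 2-fold and (ii) the classic Levene test
(absolute deviations from group means; Brown–Forsythe medians available)
between the null values and the weight-expanded group values is
significant at α = 0.05, star-graded `*`/`**`/`***` at 0.05/0.01/0.001.
Both SDs are frequency-weighted population SDs, so the ratio and the
Levene W are invariant under affine rescaling of the variable. The
conjunction matters: a huge sample can make Levene significant at a
biologically trivial SD ratio, and a tiny sample can show a large ratio
without evidence — neither alone is a niche.

Bias toward biomes or regions is tested by permutation:
the G statistic of observed versus site-frequency-proportional expected
category weights, with site labels permuted 999 times and
p = (1 + #{permuted ≥ observed}) / (n_perm + 1). The add-one estimator
never returns an impossible p = 0 and makes the p-value super-uniform
under the null. This direct permutation test replaces a random-forest
importance-permutation procedure: it tests the same null (no association
between occurrences and the categorical factor) with an exactly
enumerable statistic — the test suite checks it against exhaustive
enumeration on a six-site toy — at the cost of ignoring interactions with
the continuous predictors.

`cv_r2()` wraps *any* predictor honouring a `fit(data, y)` /
`predict(model, newdata)` contract in repeated 10-fold cross-validation
(100 repeats by default): per repeat, sites are randomly partitioned, each
fold is predicted out-of-fold, and R² = 1 − SSE/SST is computed on the
pooled out-of-fold predictions about the overall mean — so a
training-mean predictor scores ≤ 0 by construction and a memorising
oracle scores exactly 1, which is how the harness itself is tested.
Pooling per repeat (rather than averaging per-fold R²) keeps small folds
from dominating the summary. Random-forest machinery is deliberately not
reimplemented: `predictor_rf()` wraps the randomForest package when
present, and the default predictor table is the six-variable set (MAT,
MAP, pH, soil C, soil P, time since fire).

## The synthetic-data generator

`sim_config()` defines the study conditions; its defaults are the
conditions under which the acceptance checks run and are not adjusted per
test. A random root operon (18S 500, ITS1 150, 5.8S 155, ITS2 250, 28S
550 bases) receives the universal primer binding sites
(mutation-protected, emulating ultra-conserved priming sites); 4 clade
ancestors mutate from the root and 8 OTUs from each ancestor, conserved
genes at a rate calibrated to 4% expected between-clade divergence and
spacers to 30% (3% within clades) — the regime the 0.80/0.95 thresholds
assume. Mutations are i.i.d. substitutions to a uniform alternative base,
no indels: identity arithmetic stays analytic (the calibration test checks
realized divergence against 1 − exp(−2·rate·depth)), and all operons share
one coordinate map. OTU *records* are the ITS2 slice of their operon,
emulating pyrosequenced ITS2 amplicons.

Site environments are uniform (MAT −5–28 °C, MAP 100–4000 mm, pH 3–8.5,
fire 0–100 yr) or log-normal (soil C, P), spanning tundra-to-tropics
ranges; biome (6 levels) and region (8 levels) are uniform categorical.
Occupancy follows a Gaussian response:
P(present) = p_max · exp(−(v − µ)² / 2σ²) on the clade's focal variable,
the standard unimodal niche model; σ = ∞ gives a niche-neutral clade. The
default model plants a narrow pH niche (σ = 0.25 × the null SD of pH,
p_max = 0.8) on clade 1, a narrow MAT niche on clade 2, and leaves the
rest flat at p_max = 0.3, so every statistic sees positive and null cases
in one community.

What the generator does *not* emulate — sequencing error, indels, chimera
formation in silico during PCR, read-depth structure, phylogenetically
realistic trees, spatial autocorrelation of environments — bounds what
green tests mean: they demonstrate the pipeline's logic under its stated
model, not performance on raw survey data.

## Problem sizes and numerical conventions

The test suite and the acceptance script use: the default community
(4 clades × 8 OTUs, 200 sites) for end-to-end recovery; 20 random
instances of up to 50 OTUs for the clustering-versus-oracle equivalence;
100 clean and 100 chimeric read sets for the QC rates; 100 seeds for
narrowness power, 200 for its size, and 200 for permutation
super-uniformity at 999 permutations. Degenerate inputs follow fixed
conventions: a single distinct value has SD 0 (not an error), two
deviation-free samples give Levene p = 1, a single-level factor gives
bias p = 1, zero-occurrence groups raise a typed "nd" condition, and
permutation p-values live on the grid k/1000.

## Limitations

* The identity definition is tuned for screening robustness, not for
  reporting alignment-quality statistics; its "coverage" grows with
  sequence length for unrelated pairs and is a gate, not a similarity.
* Grouped-target design requires equal-length, coordinate-aligned member
  sequences (guaranteed by the substitution-only simulator); real
  ITS2 sets with indels would need a prior multiple alignment.
* Reference-database chimera detection and per-region taxonomy checks are
  out of scope; `assemble_construct()` implements only the overlap-based
  first-pass control.
* The bias test conditions on the observed per-site weights and treats
  sites as exchangeable; strong spatial structure in real metadata would
  call for restricted permutations.
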