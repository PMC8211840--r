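---
title: "Methods: forensic STR profiling of opium poppy with poppystr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forensic STR profiling of opium poppy with poppystr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poppystr)
```

## The problem

Individualizing opium poppy (*Papaver somniferum*) material — plants, raw
opium, seed lots — requires a validated panel of short tandem repeat (STR)
markers, exactly as human forensic identification does. poppystr implements
the computational side of building and validating such a panel: mining a
genome for perfect microsatellites and selecting marker candidates, naming
sequenced alleles in a reproducible sequence-based nomenclature, calling
genotypes from capillary-electrophoresis (CE) peak tables against an
allelic ladder, computing the internal-validation metrics forensic
guidelines expect, and asking the population-level question that matters
for crop varieties: which cultivars can the panel tell apart?

Everything runs on synthetic data generated by the package itself, so the
entire pipeline is exercised and tested without any external download.

## Microsatellite mining

`scan_perfect_ssrs()` reports every maximal perfect tandem repeat with a
2–6 nt motif. Conventions, all asserted by tests against an independent
brute-force oracle:

* a run is reported under its **shortest period** — `(AG)x12` is one
  dinucleotide locus, never `(AGAG)x6`; mononucleotide runs are never
  reported (motif primitivity check);
* `N` breaks a run; lowercase is uppercased; coordinates are 1-based,
  inclusive, forward strand;
* partial copies at the edges of a periodic region do not count towards the
  repeat number; among the equivalent phase anchors the lexicographically
  smallest motif is reported (so a run preceded by a chance partial copy is
  still reported as `AGAT`, not a rotation).

Default minimum repeat numbers (first search phase) are 6 for
dinucleotides and 5 for tri- to hexanucleotides. Candidate selection
(`select_candidates()`) then applies the development rules: tetranucleotides
with 7 or more repeats, penta-/hexanucleotides with 8 or more,
trinucleotides within 10–15 repeats, and only loci placed on named
chromosomes. `summarize_ssr_distribution()` reports loci/Mb per chromosome
(per-chromosome only by default, scaffolds switchable) because genome-scale
density figures are conventionally quoted per chromosome.

Uniqueness filtering (`uniqueness_filter()`) re-expresses the original
selection script as three configurable predicates over 12-column tabular
alignment hits: at most `max_significant_hits` hits below a significance
e-value, at most `max_high_cover_hits` hits at high query cover, and a
minimum bitscore gap between best and second-best hit. Filters of this
kind are tuned on manually curated loci and the tuned values rarely
published; the defaults here (1e-10, 80% cover, one hit each, 10 bits) are
explicit stand-ins and every rejection carries the violated rule. A candidate without a self-hit (≥99.9%
identity, ~full cover) is treated as malformed input.

`interlocus_distances()` flags same-chromosome marker pairs closer than
50 Mb as possibly linked — the working rule used when assembling the panel
— and `dimer_score()` provides the simplified primer cross-dimer scan
(maximum contiguous Watson–Crick window over all ungapped offsets against
the reverse complement; pairs scoring ≤5 are conventionally compatible).

## Sequence-based allele nomenclature

The nomenclature engine follows the convention that separates length
variation *inside* the repeat region from variation in the flanking
regions. An allele named `n.x` has `n` total repeats and `x` intermediate
bases inside the repeat region; flanking indels appear only as descriptors
in parentheses and never change `n.x`. The canonical worked example is a
locus with repeat structure `(AAGA)7AG(AAGA)1`: both the 186 bp allele and
its 184 bp variant (which lost a TC dinucleotide downstream of the
repeats) are named 8.2, the shorter one as `8.2 (D42TCdel)`. The size-based
alternative convention, also implemented, renames the pair 8 and 8.2 — and
breaks down entirely when a flanking deletion is longer than the repeat
region (an `(AGA)3` allele with a 10-nt upstream deletion would go
negative), which `name_allele(convention = "size_based")` reports as an
explicit negative-numbering error.

Anchoring of descriptor positions, which the convention leaves implicit, is
fixed here as: U1 is the base immediately upstream (5') of the repeat
region counting away from it, D1 the base immediately downstream; a
multi-base variant is anchored at its repeat-proximal end and its sequence
is written 5'→3'. Descriptors print D-side first, each side sorted by
position, separated by "; ".

`decompose_amplicon()` locates the repeat region as the maximal segment
tiled by the reference's motifs with interruptions of at most `max_gap`
(default 6) bases; among co-optimal chains it prefers more total repeats,
then fewer interruptions, then the longest uninterrupted leading run, then
the leftmost start (the longest-uninterrupted-sequence idea), and reports a
remaining tie as an ambiguity error. Flank variants are then recovered by
global pairwise alignment (match 1, mismatch −1.5, gap open 4, gap extend
0.5 — chosen so a contiguous 10-nt deletion is preferred over scattered
mismatches) and read off the gapped strings column by column. A round-trip
property test (`simulate_allele_sequence()` then `decompose_amplicon()`
then rebuild) runs over randomized structures and variants every time the
suite runs.

`allele_shorthand()` rewrites any descriptor whose sequence exceeds
`max_seq_len` (default 5, which keeps `TCdel` verbatim but shortens 8–10 nt
deletions) as side+position+"-"+length+kind, e.g. `U11-10del`; it is
idempotent and, for deletions, invertible from the reference
(`expand_shorthand()`).

SID labels (`sid_label()`) are four uppercase letters derived from a SHA-1
digest of the allele sequence. Because a bare 3-letter hash prefix has a
~50% birthday-collision chance at 158 alleles, labels are assigned over the
inventory in sorted sequence order and a colliding prefix deterministically
falls through to the next digest window, so the first three letters alone
identify every allele of a fixed inventory. The published SID algorithm
this mirrors is not public in detail; these labels are deterministic and
documented but not expected to match any published label verbatim.

`diagnose_null()` aligns each primer (the reverse one as its reverse
complement) against an extended amplicon and reports substitutions by
offset from the primer 3' end (offsets within the last 5 bases are
high severity — the classic null-allele cause) and any indel overlapping
the site, reproducing both published failure modes (a G→A next to the
3'-terminal base; an 8-nt deletion under the primer).

## CE genotyping

`apply_threshold()` only flags sub-threshold peaks (200 rfu analytical
threshold by default; stutter studies conventionally lower it to 25–50
rfu); nothing is deleted, so consumers decide. `build_ladder()` composes an
allelic ladder by greedy set cover over samples (ties by lexicographic
sample id), reporting alleles carried by no sample as missing — the
situation of a real panel where a few alleles cannot be ladder-represented.
Bins are ±0.4 bp around ladder sizes, the standard default binning range,
with a runtime assertion that no two bins can overlap.

`call_genotypes()` assigns passing peaks to bins, filters backward-stutter
candidates (one repeat unit below a taller peak, ratio at or below the
marker's mean+3·SD threshold from `stutter_stats()`, fallback 0.15), and
calls up to two alleles: zero surviving alleles is a locus dropout, a
single allele is a homozygote that carries an allelic-dropout suspicion
flag when the dose metadata is low (homozygosity and allelic dropout are
indistinguishable in a single profile, so a flag, never a hard decision).
Forward (n+k) stutter is classified but not filtered by default — it is
rare, and filtering it risks deleting a true minor allele one repeat above;
`filter_forward_stutter = TRUE` enables it.

`classify_stutters()` types peaks at expected stutter positions (n−k,
n−2k, n+k with k = one repeat unit; optionally the n−2/3/4 bp series that
some pentanucleotide loci produce) within a ±0.5 bp matching tolerance.
Peaks sitting on a *called allele* position are excluded from candidacy —
with adjacent heterozygous alleles, the neighbouring allele peak lies
exactly one repeat unit away and would otherwise masquerade as a huge
stutter — and a backward stutter is never assigned a peak taller than its
parent. The stutter ratio is S_R = φ_S/φ_A, stutter over allele peak
height.

`sizing_precision()` summarizes repeated ladder injections: per-allele mean
and SD, the grand mean SD with SEM = SD(per-allele SDs)/√n, and a verdict
flag for alleles whose 3·SD exceeds the bin half-width (the criterion under
which an allele's mobility is too variable for ±0.4 bp bins).

## Validation metrics

Codominant normalization precedes the balance metrics: a heterozygote's two
peak heights are averaged, a homozygote's single peak is halved.

* **IELB** (inter-locus balance): locus height over the mean height across
  the assay's loci; over a complete profile IELB averages to 1 exactly (an
  algebraic identity the tests assert). Non-amplifying loci are excluded
  from the denominator; pooling incomplete profiles is what makes
  study-level means differ from 1.
* **ICB** (intracolour balance): min/max within a dye channel; a one-locus
  dye group returns 1 with an explicit flag rather than NA.
* **Heterozygote balance**: Hb = φ_HMW/φ_LMW (can exceed 1),
  Hb′ = φ_smaller/φ_larger = min(Hb, 1/Hb) ≤ 1.

All three are scale-invariant in the global rfu gain, asserted over
simulated profiles. `stutter_stats()` reports mean, median, SD, min, max
and mean±3·SD per marker × stutter type, the mean+3·SD filter threshold,
per-allele mean ratios, and the least-squares trend of mean S_R against
repeat number fitted on per-allele means (matching how allele-specific
stutter is conventionally presented; groups with no observed stutter are
reported absent, a known upward bias). `sensitivity_report()` classifies
calls against truth across a dilution series into full profiles, locus
dropouts and allelic dropouts, with Hb/Hb′ summaries per dose.
`cross_reactivity()` counts, per non-target taxon, markers with any passing
peak, once per marker, with near-threshold peaks noted separately.

## Population analysis

Genotypes live in long tibbles (`sample_id`, `variety`, `category`,
`marker`, `allele_1`, `allele_2`); `read_genotype_matrix()` /
`write_genotype_matrix()` provide the wide "a1/a2" TSV interchange format.
Null or failed loci are encoded as missing, not as a "null" allele label —
in profile data a null allele cannot be distinguished from amplification
failure.

`pop_summary()` gives per-marker allele counts (N_al), frequencies, and
observed heterozygosity (fraction of heterozygous samples).
`identity_analysis()` runs all pairwise comparisons at 0 allele mismatches;
markers missing in either sample are skipped but counted, and pairs typed
at fewer than `min_overlap` (default 20) markers are flagged low
confidence. `variety_discrimination()` applies the rule that one variety
differs from another only if *all* its plants differ from all of the
other's: one cross-variety 0-mismatch pair makes the pair of varieties
indistinguishable, and indistinguishable varieties form connected
components, each counted as a single distinguishable unit.

PCA (`str_pca()`) runs on allele-dosage columns (0/1/2 copies per
marker-allele), column-centered and unscaled by default — binary dosage
columns have comparable variance, so scaling is a switch, not a default;
missing dosages are mean-imputed. Sign is fixed by making each component's
largest-magnitude loading positive, so scores are reproducible run to run.
`str_upgma()` clusters Euclidean distances over the first 3 PC axes with
average linkage; samples are processed in lexicographic id order, making
exact-tie resolution deterministic via `hclust`'s index rule; the tree is
exported as newick through ape and flat clusters default to k = 4 (one per
cultivar category). `flag_mislabels()` compares each sample's distance to
its own variety centroid (excluding itself) against foreign centroids over
all PC axes; the default margin of 1 dosage unit is about a third of the
displacement a single homozygous allele swap causes (√8 ≈ 2.8), so
residual-heterozygosity noise and genetically indistinguishable varieties
do not trigger flags while a genuinely foreign profile always does.

## The synthetic-data generator

The generator defines the study conditions everything is tested under.

* **Genomes** (`generate_genome()`): i.i.d. background at a given GC
  (default 0.39, a plant-genome-like value), planted perfect repeats made
  maximal by construction (the flanking bases are forced not to extend the
  run), overlap and bounds checked per spec with the offending spec named.
* **Panels** (`synthetic_panel()`): default 27 markers over 3 multiplexes
  and 4 dye channels, tri- to pentanucleotide motifs, per-marker allele
  inventories of 3–14 alleles (Poisson around a mean of 5.85 per locus, the
  diversity scale of the real panel), allele sizes one motif length apart,
  non-overlapping 90 bp size windows per dye, and a nomenclature reference
  per marker whose flanks are generated free of the marker motif (including
  boundary-straddling occurrences).
* **Varieties** (`generate_varieties()`): pure breeding lines — one modal
  allele per variety per marker, residual heterozygosity 0.076 (the
  observed mean heterozygosity of the real material), optional
  `clone_groups` that share modal profiles to engineer indistinguishable
  variety groups, and `force_modal_first` to make each variety's first
  plant fully homozygous modal. The forcing knob exists because with 4–9
  plants per variety and 27 markers the probability that a variety contains
  a fully-modal plant by chance is only ~50%, so engineered
  indistinguishable groups would not reliably produce the cross-variety
  identical pair they are meant to contain; forcing makes the engineered
  condition deterministic.
* **CE profiles** (`simulate_profiles()`): per-copy lognormal heights
  (meanlog log(2000), sdlog 0.25 at the 1.25 ng reference dose), per-dye
  gains, linear decay of log-height with fragment size (0.002/bp) which
  yields the observed drift of heterozygote balance with allele size
  without claiming its mechanism; stutter ratios linear in repeat number
  per type (backward 0.02 + 0.004·NR by default), optional 1-bp series for
  designated markers; dropout per allele copy, logistic in log2(dose) with
  d50 = 0.2 ng and slope 2 — the dilution-series behaviour of the real
  assays brackets 0.3 ng as the lowest fully reliable dose, and no
  quantitative dropout model is published, so the logistic form and its
  parameters are this module's documented choice, exposed as configuration;
  Gaussian sizing noise (SD 0.06 bp, the published mean sizing SD);
  (variety, marker) null-allele assignments that emit nothing; and
  flagging (never deletion) below the analytical threshold. Every emitted
  peak has exactly one provenance record in the returned truth table, and
  all randomness flows from per-sample sub-streams derived from one seed.

What the simulator does **not** model — and what passing tests therefore do
not show about real data: continuous electropherogram traces, pull-up /
spectral bleed between dyes, off-scale clipping, PCR inhibition, size-calling
from a size standard (sizes arrive in bp), and non-linear stutter behaviour.

## Numerical choices and problem sizes

Tie-breaks and tolerances are collected here: bin half-width 0.4 bp;
stutter-position tolerance 0.5 bp; decomposition `max_gap` 6; shorthand
trigger above 5 nt; flank-variant alignment scores as above; primer-site
alignment match 2 / mismatch −3 / gap open 5 / extend 0.5 (so an 8-nt
deletion beats a mismatch-laden placement); 3'-terminal severity window 5
bases; stutter filter fallback 0.15; identity minimum overlap 20 of 27
markers; PCA sign convention by largest loading; UPGMA ties by id-sorted
index order.

The test suite runs the statistical checks at deliberately desk-scale
sizes: the miner oracle over 200 random sequences up to 5 kb; balance
identities over ~1,000 simulated profiles; stutter-slope recovery from
≥1,000 backward-stutter observations (recovered within 15%); dropout-d50
recovery from the five published dose points at ≥500 heterozygous loci per
dose (within 20%, by a binomial GLM refit in log2 dose — an estimator
independent of the simulator's forward code); sizing SD 0.06 bp recovered
from 151+ alleles × 10 injections within [0.05, 0.07]; and the full
discrimination rehearsal on 36 varieties (4–9 plants each) with engineered
indistinguishable groups of four and two varieties plus two planted
mislabels.

## Known limitations

Decomposition assumes the reference flanks are recoverable at the amplicon
ends and the repeat region does not bleed into the flanks; references whose
flanks contain the repeat motif adjacent to the boundary (a real
possibility in repeat-degenerate loci) would need manual structures. The
bimodal stutter clouds produced by isoalleles are reported, not delimited.
The SID labels, while deterministic, are not the published labels.
Hardy–Weinberg and forensic match-probability statistics are deliberately
out of scope: inbred variety sets are not populations, and the study design
this package mirrors declines them for that reason.
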