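# poppystr

Forensic microsatellite (STR) marker development and internal validation
for opium poppy (*Papaver somniferum*), in R.

Crop individualization — tracing a plant, raw opium or a seed lot back to a
cultivar — needs the same machinery as human forensic DNA profiling: a
panel of polymorphic STR markers, an allelic ladder, a reproducible allele
nomenclature, and validation statistics showing the assays are balanced,
sensitive and specific. poppystr implements that computational pipeline
end to end for people building or evaluating plant STR panels:

* **Mining & selection** — find every maximal perfect microsatellite
  (2–6 nt motifs) in a genome FASTA, summarize density and motif classes,
  and apply the marker-development rules (tetra ≥ 7 repeats, penta/hexa
  ≥ 8, tri 10–15, chromosome placement, alignment-based uniqueness,
  inter-locus distance ≥ 50 Mb, primer cross-dimer score ≤ 5).
* **Sequence-based nomenclature** — decompose sequenced allele amplicons
  against a marker reference and name them `n.x (descriptors)`, where `n`
  is the total repeat count, `x` the intermediate bases inside the repeat
  region, and flanking indels are descriptors (`D42TCdel`, `U11-10del`)
  that never change `n.x`; the size-based alternative convention and its
  negative-numbering failure mode are implemented for contrast, plus
  digest-derived SID labels and primer-site null-allele diagnosis.
* **CE genotyping** — allelic-ladder composition by greedy set cover,
  ±0.4 bp bin calling with stutter filtering, stutter classification
  (n−k, n−2k, n+k, and n−2/3/4 bp series), and ladder sizing precision.
* **Validation metrics** — inter-locus balance (IELB), intracolour balance
  (ICB), heterozygote balance in both conventions
  (Hb = φ_HMW/φ_LMW, Hb′ = φ_smaller/φ_larger), stutter-ratio summaries
  with mean + 3·SD filter thresholds and allele-size trends, sensitivity /
  dropout reports over a dilution series, species cross-reactivity counts.
* **Population analysis** — allele counts and observed heterozygosity,
  0-mismatch identity analysis, the variety-discrimination rule (two
  varieties are distinguishable only if *all* their plants differ),
  dosage-PCA and UPGMA clustering with newick export, mislabel flagging.
* **Synthetic data** — genomes with planted repeats, inbred multi-variety
  genotype sets, and CE peak tables with stutter, dose-dependent dropout,
  degradation-driven heterozygote imbalance, sizing noise and null alleles,
  all seeded and with full per-peak provenance, so every stage above runs
  and is tested without any external data.

Functions are tidyverse-style: data frames in, tibbles out, `tidy()` /
`glance()` / `autoplot()` for the fitted objects.

## Worked example

```r
library(poppystr)

panel <- synthetic_panel(n_markers = 9, seed = 8)        # 3 multiplexes, 4 dyes
vs    <- generate_varieties(panel, n_varieties = 6, plants_per_variety = 4,
                            residual_het_rate = 0.076, seed = 8)
sim   <- simulate_profiles(vs$genotypes, panel, sim_config(), dose_ng = 1.25,
                           seed = 8)
lad   <- build_ladder(panel$inventory, vs$genotypes)
calls <- call_genotypes(apply_threshold(sim$peaks, 200), lad, panel)

sum(calls$locus_dropout)
#> [1] 0

head(ielb(normalize_profile(calls, panel)), 3)
#> # A tibble: 3 × 6
#>   sample_id assay marker norm_height  ielb n_loci_in_assay
#> 1 S0001         1 SYN001       1448.  1.12               3
#> 2 S0001         2 SYN002       1928.  1.36               3
#> 3 S0001         3 SYN003       1230.  1.09               3

pop_summary(vs$genotypes)$overall
#> # A tibble: 1 × 3
#>   mean_n_al median_n_al mean_h_obs
#> 1      5.11           5      0.106

variety_discrimination(vs$genotypes, min_overlap = 7)$n_distinguishable_units
#> [1] 6
```

At full dose with no dropout the calls reproduce the simulated genotypes
exactly; the IELB column shows each locus's height relative to its assay
mean (it averages to 1 over a complete profile), and the six synthetic
varieties — drawn with disjoint founder profiles — are all distinguishable
under the all-plants-differ rule.

Allele naming, from structure to shorthand:

```r
nm <- name_allele(parse_structure("(AGA)3"),
                  variants = flank_variant("U", 11, "del", "TGTTAAAATG"))
nm$full
#> [1] "3 (U11TGTTAAAATGdel)"
allele_shorthand(nm)$full
#> [1] "3 (U11-10del)"
```

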