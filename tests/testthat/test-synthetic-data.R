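test_that("planted repeats appear verbatim and genome generation is
           deterministic", {
  planted <- planted_repeat("chr1", 1001, "AGAT", 10)
  g1 <- generate_genome(n_chrom = 1, chrom_length = 3000, planted = planted,
                        seed = 11)
  expect_equal(substr(g1$sequences[["chr1"]], 1001, 1040), strrep("AGAT", 10))
  # flanks must not extend the run
  expect_false(substr(g1$sequences[["chr1"]], 1000, 1000) == "T")
  expect_false(substr(g1$sequences[["chr1"]], 1041, 1041) == "A")
  g2 <- generate_genome(n_chrom = 1, chrom_length = 3000, planted = planted,
                        seed = 11)
  expect_identical(g1$sequences, g2$sequences)
  g3 <- generate_genome(n_chrom = 1, chrom_length = 3000, planted = planted,
                        seed = 12)
  expect_false(identical(g1$sequences, g3$sequences))
})

test_that("FASTA round trip is byte-identical for a fixed seed", {
  g <- generate_genome(n_chrom = 2, chrom_length = 500, seed = 3)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(g, f1)
  write_genome_fasta(generate_genome(n_chrom = 2, chrom_length = 500,
                                     seed = 3), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(read_genome_fasta(f1), g$sequences)
})

test_that("out-of-bounds and overlapping planted specs are rejected with the
           offending spec identified", {
  expect_error(
    generate_genome(n_chrom = 1, chrom_length = 100,
                    planted = planted_repeat("chr1", 90, "AGAT", 10)),
    "chr1:90")
  both <- rbind(planted_repeat("chr1", 100, "AGAT", 10),
                planted_repeat("chr1", 120, "AAG", 10))
  expect_error(
    generate_genome(n_chrom = 1, chrom_length = 1000, planted = both),
    "overlap")
  expect_error(planted_repeat("chr1", 1, "ATAT", 5), "periodic")
})

test_that("an unplanted genome mined with first-phase thresholds matches the
           brute-force oracle", {
  g <- generate_genome(n_chrom = 1, chrom_length = 10000, gc = 0.4, seed = 21)
  got <- scan_perfect_ssrs(g$sequences)
  want <- brute_ssr_oracle(g$sequences[["chr1"]])
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$start, want$start)
})

test_that("zero residual heterozygosity gives fully homozygous plants and a
           disjoint-pool design gives no cross-variety identity", {
  panel <- synthetic_panel(n_markers = 6, seed = 2)
  vs <- generate_varieties(panel, n_varieties = 4, plants_per_variety = 3,
                           residual_het_rate = 0, seed = 2)
  expect_true(all(vs$genotypes$allele_1 == vs$genotypes$allele_2))
  expect_equal(pop_summary(vs$genotypes)$overall$mean_h_obs, 0)
  ia <- identity_analysis(vs$genotypes, min_overlap = 3)
  cross <- ia[ia$variety_1 != ia$variety_2, ]
  expect_equal(nrow(cross), 0L)
})

test_that("realized heterozygosity is unbiased for the residual rate", {
  panel <- synthetic_panel(n_markers = 27, seed = 5)
  rate <- 0.076
  reps <- 40
  n_obs <- 27 * 60
  hobs <- withr::with_seed(1301, {
    vapply(seq_len(reps), function(i) {
      vs <- generate_varieties(panel, n_varieties = 12,
                               plants_per_variety = 5,
                               residual_het_rate = rate,
                               seed = sample.int(1e6, 1))
      mean(vs$genotypes$allele_1 != vs$genotypes$allele_2)
    }, numeric(1))
  })
  se <- sqrt(rate * (1 - rate) / n_obs) / sqrt(reps)
  expect_lt(abs(mean(hobs) - rate), 3 * se)
})

test_that("pool size beyond the inventory errors", {
  panel <- synthetic_panel(n_markers = 4, seed = 2)
  expect_error(generate_varieties(panel, n_varieties = 2,
                                  plants_per_variety = 2,
                                  allele_pool_size = 99),
               "inventory")
})

test_that("degenerate simulator config yields exactly the allele peaks at
           exact sizes, and every peak has one provenance record", {
  panel <- synthetic_panel(n_markers = 5, seed = 7)
  vs <- generate_varieties(panel, n_varieties = 3, plants_per_variety = 2,
                           residual_het_rate = 0.2, seed = 7)
  cfg <- sim_config(sizing_sd = 0, dropout_d50 = NULL,
                    stutter = tibble::tibble(type = c("n-k", "n-2k", "n+k"),
                                             base = 0, slope = 0))
  sim <- simulate_profiles(vs$genotypes, panel, cfg, seed = 9)
  expect_true(all(sim$truth$peak_provenance$provenance == "allele"))
  expect_equal(nrow(sim$peaks), nrow(sim$truth$peak_provenance))
  sizes <- merge(sim$peaks,
                 unique(panel$inventory[, c("marker", "allele", "size_bp")]),
                 by = c("marker", "size_bp"))
  expect_equal(nrow(sizes), nrow(sim$peaks))  # all sizes exact
  # one allele peak per distinct allele carried
  want <- unique(rbind(
    vs$genotypes[, c("sample_id", "marker")] |>
      transform(allele = vs$genotypes$allele_1),
    vs$genotypes[, c("sample_id", "marker")] |>
      transform(allele = vs$genotypes$allele_2)))
  expect_equal(nrow(sim$peaks), nrow(want))
})

test_that("null-allele assignments silence the whole marker for the variety", {
  panel <- synthetic_panel(n_markers = 4, seed = 7)
  vs <- generate_varieties(panel, n_varieties = 2, plants_per_variety = 3,
                           seed = 7)
  nulls <- tibble::tibble(variety = "VAR01",
                          marker = panel$markers$marker[2])
  cfg <- sim_config(dropout_d50 = NULL, null_alleles = nulls)
  sim <- simulate_profiles(vs$genotypes, panel, cfg, seed = 3)
  hit <- sim$peaks[sim$peaks$variety == "VAR01" &
                     sim$peaks$marker == nulls$marker, ]
  expect_equal(nrow(hit), 0L)
  other <- sim$peaks[sim$peaks$variety == "VAR02" &
                       sim$peaks$marker == nulls$marker, ]
  expect_gt(nrow(other), 0L)
})

test_that("with fixed ratios and no noise, stutter height is exactly ratio
           times parent height", {
  panel <- synthetic_panel(n_markers = 3, seed = 8)
  vs <- generate_varieties(panel, n_varieties = 2, plants_per_variety = 2,
                           residual_het_rate = 0, seed = 8)
  cfg <- sim_config(sizing_sd = 0, dropout_d50 = NULL,
                    stutter = tibble::tibble(type = "n-k", base = 0.07,
                                             slope = 0))
  sim <- simulate_profiles(vs$genotypes, panel, cfg, seed = 4)
  joined <- dplyr::inner_join(
    sim$peaks, sim$truth$peak_provenance[, c("peak_id", "provenance")],
    by = "peak_id")
  st <- joined[joined$provenance == "stutter:n-k", ]
  par <- joined[joined$provenance == "allele", ]
  m <- dplyr::inner_join(st, par, by = c("sample_id", "marker"),
                         suffix = c("_s", "_a"),
                         relationship = "many-to-many")
  m <- merge(m, panel$markers[, c("marker", "motif_length")], by = "marker")
  m <- m[abs(m$size_bp_a - m$size_bp_s - m$motif_length) < 1e-9, ]
  expect_gt(nrow(m), 0)
  expect_equal(m$height_rfu_s, 0.07 * m$height_rfu_a)
})

test_that("simulation is deterministic for a fixed seed and dose must be
           positive", {
  panel <- synthetic_panel(n_markers = 3, seed = 8)
  vs <- generate_varieties(panel, n_varieties = 2, plants_per_variety = 2,
                           seed = 8)
  s1 <- simulate_profiles(vs$genotypes, panel, sim_config(), seed = 6)
  s2 <- simulate_profiles(vs$genotypes, panel, sim_config(), seed = 6)
  expect_identical(s1$peaks, s2$peaks)
  expect_error(simulate_profiles(vs$genotypes, panel, sim_config(),
                                 dose_ng = 0), "positive")
})

test_that("amplicon construction matches the published length arithmetic of
           the 184/186 bp pair", {
  # flanks totalling 152 bp + repeat region 34 bp = 186; the TC deletion
  # shortens the amplicon to 184
  up <- flank_without(100, "AAGA", "U")
  down_core <- flank_without(52, "AAGA", "D")
  down <- paste0(substr(down_core, 1, 41), "TC",
                 substr(down_core, 44, 52))
  ref <- marker_reference("TET", up, "(AAGA)7AG(AAGA)1", down, pigtail = 0)
  large <- simulate_allele_sequence(ref)
  expect_equal(nchar(large), 186L)
  small <- simulate_allele_sequence(
    ref, variants = flank_variant("D", 42, "del", "TC"))
  expect_equal(nchar(small), 184L)
})
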