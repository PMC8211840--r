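mini_ladder <- function() {
  inventory <- tibble::tibble(
    marker = "M1", allele = c("8", "9"), size_bp = c(186.1, 190.1))
  genotypes <- tibble::tibble(sample_id = "L1", marker = "M1",
                              allele_1 = "8", allele_2 = "9")
  build_ladder(inventory, genotypes)
}

peak_row <- function(size, height, sample = "S1", marker = "M1") {
  tibble::tibble(sample_id = sample, marker = marker, size_bp = size,
                 height_rfu = height,
                 peak_id = paste0("p", round(size * 10), round(height)))
}

test_that("thresholding only flags, never deletes, and is order-independent", {
  pk <- dplyr::bind_rows(peak_row(186.1, 150), peak_row(190.1, 250))
  out <- apply_threshold(pk, 200)
  expect_equal(nrow(out), 2L)
  expect_equal(out$below_threshold, c(TRUE, FALSE))
  expect_equal(apply_threshold(pk, 0)$below_threshold, c(FALSE, FALSE))
  perm <- apply_threshold(pk[2:1, ], 200)
  expect_equal(perm$below_threshold, c(FALSE, TRUE))
})

test_that("greedy ladder composition matches the brute-force optimum and
           reports uncoverable alleles", {
  inventory <- tibble::tibble(marker = "M", allele = c("a", "b", "c", "d"),
                              size_bp = c(100, 110, 120, 130))
  genotypes <- tibble::tibble(
    sample_id = c("S1", "S1", "S2", "S2", "S3"),
    marker = "M",
    allele_1 = c("a", "b", "b", "c", "c"),
    allele_2 = c("a", "b", "b", "c", "c"))
  lad <- build_ladder(inventory, genotypes)
  expect_equal(lad$samples, c("S1", "S2"))
  expect_equal(lad$missing_alleles$allele, "d")
  # brute force: no single sample covers {a,b,c}
  expect_gt(length(lad$samples), 1)

  solo <- tibble::tibble(sample_id = "S9", marker = "M",
                         allele_1 = c("a", "c"), allele_2 = c("b", "d"))
  lad2 <- build_ladder(inventory, solo)
  expect_equal(lad2$samples, "S9")
  expect_equal(nrow(lad2$missing_alleles), 0L)
})

test_that("overlapping bins violate the ladder invariant", {
  inventory <- tibble::tibble(marker = "M1", allele = c("8", "8.2"),
                              size_bp = c(186.1, 186.6))
  genotypes <- tibble::tibble(sample_id = "L1", marker = "M1",
                              allele_1 = "8", allele_2 = "8.2")
  expect_error(build_ladder(inventory, genotypes, half_width = 0.4),
               "overlapping bins")
})

test_that("bin calling assigns within the half-width and leaves the rest
           off-ladder", {
  lad <- mini_ladder()
  panel <- fake_panel("M1", 4)
  pk <- apply_threshold(dplyr::bind_rows(
    peak_row(186.3, 1500),   # |186.3-186.1| = 0.2 <= 0.4 -> allele 8
    peak_row(187.0, 1400)),  # 0.9 from either bin -> off-ladder
    200)
  calls <- call_genotypes(pk, lad, panel)
  expect_equal(calls$allele_1, "8")
  expect_equal(calls$zygosity, "hom")
  expect_equal(calls$n_off_ladder, 1L)
})

test_that("backward stutter below the filter ratio is removed and a
           homozygote is called; above it a heterozygote is kept", {
  lad <- mini_ladder()
  panel <- fake_panel("M1", 4)
  pk <- apply_threshold(dplyr::bind_rows(
    peak_row(190.1, 2000),
    peak_row(186.1, 100)), 50)  # one repeat (4 bp) below, ratio 0.05
  calls <- call_genotypes(pk, lad, panel,
                          stutter_thresholds = c(M1 = 0.10))
  expect_equal(calls$zygosity, "hom")
  expect_equal(calls$allele_1, "9")

  pk2 <- apply_threshold(dplyr::bind_rows(
    peak_row(190.1, 2000),
    peak_row(186.1, 900)), 50)  # ratio 0.45 > threshold -> true het
  calls2 <- call_genotypes(pk2, lad, panel,
                           stutter_thresholds = c(M1 = 0.10))
  expect_equal(calls2$zygosity, "het")
  expect_equal(sort(c(calls2$allele_1, calls2$allele_2)), c("8", "9"))
})

test_that("zero surviving peaks is a locus dropout and low dose marks
           single-allele calls as suspected allelic dropout", {
  lad <- mini_ladder()
  panel <- fake_panel("M1", 4)
  pk <- apply_threshold(peak_row(186.1, 120), 200)  # below threshold
  calls <- call_genotypes(pk, lad, panel)
  expect_true(calls$locus_dropout)

  pk2 <- apply_threshold(
    dplyr::mutate(peak_row(186.1, 900), dose_ng = 0.156), 200)
  calls2 <- call_genotypes(pk2, lad, panel)
  expect_true(calls2$allelic_dropout_suspected)
  pk3 <- apply_threshold(
    dplyr::mutate(peak_row(186.1, 900), dose_ng = 1.25), 200)
  expect_false(call_genotypes(pk3, lad, panel)$allelic_dropout_suspected)
})

test_that("stutter classification types repeat-unit offsets and the 1-bp
           series, and never types a taller peak as backward stutter", {
  lad <- mini_ladder()
  panel <- fake_panel("M1", 5)
  # parent at 190.1 (penta): n-k at 185.1, n-2k at 180.1, n+k at 195.1,
  # series at 188.1/187.1/186.1... keep bins clear by using marker window
  inventory <- tibble::tibble(marker = "M1", allele = "9", size_bp = 200)
  genotypes <- tibble::tibble(sample_id = "L1", marker = "M1",
                              allele_1 = "9", allele_2 = "9")
  lad <- build_ladder(inventory, genotypes)
  pk <- apply_threshold(dplyr::bind_rows(
    peak_row(200, 2000),
    peak_row(195, 100), peak_row(190, 40), peak_row(205, 30),
    peak_row(198, 90), peak_row(197, 60), peak_row(196, 35)), 25)
  calls <- call_genotypes(pk, lad, panel, stutter_thresholds = c(M1 = 0))
  st <- classify_stutters(pk, calls, panel, series_1bp_markers = "M1")
  expect_setequal(st$type,
                  c("n-k", "n-2k", "n+k", "n-2bp", "n-3bp", "n-4bp"))
  expect_equal(st$sr[st$type == "n-k"], 100 / 2000)
  # a peak taller than the parent is never its backward stutter
  pk_tall <- apply_threshold(dplyr::bind_rows(
    peak_row(200, 1000), peak_row(195, 1500)), 25)
  calls_tall <- call_genotypes(pk_tall, lad, panel,
                               stutter_thresholds = c(M1 = 0))
  st_tall <- classify_stutters(pk_tall, calls_tall, panel)
  expect_false(any(st_tall$type %in% c("n-k", "n-2k") &
                     st_tall$phi_s > st_tall$phi_a))
})

test_that("classified stutters match simulator provenance exactly in a
           noise-free run", {
  panel <- synthetic_panel(n_markers = 4, seed = 13)
  vs <- generate_varieties(panel, n_varieties = 2, plants_per_variety = 3,
                           residual_het_rate = 0, seed = 13)
  cfg <- sim_config(sizing_sd = 0, dropout_d50 = NULL,
                    stutter = tibble::tibble(type = c("n-k", "n+k"),
                                             base = c(0.06, 0.02), slope = 0),
                    analytical_threshold = 25)
  sim <- simulate_profiles(vs$genotypes, panel, cfg, seed = 13)
  lad <- build_ladder(panel$inventory, vs$genotypes)
  pk <- apply_threshold(sim$peaks, 25)
  calls <- call_genotypes(pk, lad, panel, stutter_thresholds = NULL,
                          default_stutter_threshold = 0.10,
                          filter_forward_stutter = TRUE)
  st <- classify_stutters(sim$peaks, calls, panel)
  truth <- sim$truth$peak_provenance
  n_true <- table(truth$provenance)
  expect_equal(sum(st$type == "n-k"), unname(n_true[["stutter:n-k"]]))
  expect_equal(sum(st$type == "n+k"), unname(n_true[["stutter:n+k"]]))
  expect_true(all(abs(st$sr[st$type == "n-k"] - 0.06) < 1e-9))
})

test_that("end-to-end noise-free calls reproduce the true genotypes at 100%
           concordance", {
  panel <- synthetic_panel(n_markers = 6, seed = 17)
  vs <- generate_varieties(panel, n_varieties = 4, plants_per_variety = 3,
                           residual_het_rate = 0.25, seed = 17)
  cfg <- sim_config(sizing_sd = 0, dropout_d50 = NULL)
  sim <- simulate_profiles(vs$genotypes, panel, cfg, seed = 17)
  lad <- build_ladder(panel$inventory, vs$genotypes)
  calls <- call_genotypes(apply_threshold(sim$peaks, 200), lad, panel)
  cmp <- merge(calls, vs$genotypes, by = c("sample_id", "marker"),
               suffixes = c("_called", "_true"))
  expect_equal(nrow(cmp), nrow(vs$genotypes))
  expect_true(all(
    pmin(cmp$allele_1_called, cmp$allele_2_called) ==
      pmin(cmp$allele_1_true, cmp$allele_2_true) &
    pmax(cmp$allele_1_called, cmp$allele_2_called) ==
      pmax(cmp$allele_1_true, cmp$allele_2_true)))
})

test_that("locus-dropout rate is non-increasing in dose", {
  panel <- synthetic_panel(n_markers = 5, seed = 19)
  vs <- generate_varieties(panel, n_varieties = 6, plants_per_variety = 5,
                           residual_het_rate = 0.3, seed = 19)
  lad <- build_ladder(panel$inventory, vs$genotypes)
  doses <- c(0.0781, 0.3125, 1.25)
  rates <- vapply(doses, function(d) {
    sim <- simulate_profiles(vs$genotypes, panel,
                             sim_config(dropout_d50 = 0.2), dose_ng = d,
                             seed = 23)
    calls <- call_genotypes(apply_threshold(sim$peaks, 50), lad, panel)
    mean(calls$locus_dropout)
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
})

test_that("sizing precision reports per-allele SD, the overall SEM and the
           3SD-vs-bin verdict", {
  sz <- tibble::tibble(marker = "M", allele = "8", injection = 1:3,
                       size_bp = c(100, 100, 100))
  expect_equal(sizing_precision(sz)$per_allele$sd_size, 0)
  sz2 <- tibble::tibble(marker = "M", allele = "8", injection = 1:3,
                        size_bp = c(99.9, 100, 100.1))
  p <- sizing_precision(sz2)
  expect_equal(p$per_allele$sd_size, 0.1, tolerance = 1e-10)
  expect_false(p$per_allele$exceeds_bin)   # 0.3 <= 0.4
  sz3 <- tibble::tibble(marker = "M", allele = c("8", "9", "9"),
                        injection = c(1, 1, 2),
                        size_bp = c(1, 2, 3))
  expect_error(sizing_precision(sz3), "two injections")
  wobble <- tibble::tibble(marker = "M", allele = "16", injection = 1:5,
                           size_bp = c(100, 100.5, 99.5, 100.4, 99.6))
  expect_true(sizing_precision(wobble)$per_allele$exceeds_bin)
})
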