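#' Codominant normalization of called profiles
#'
#' Reduces each call to one height per locus: a heterozygote's two peak
#' heights are averaged, a homozygote's single peak height is halved (it
#' represents two co-migrating allele copies).
#'
#' @param calls A [call_genotypes()] result (amplifying loci only are kept).
#' @param panel Optional panel supplying the marker -> assay/dye map when the
#'   calls lack those columns.
#' @return Tibble: sample_id, marker (plus assay/dye when available),
#'   `norm_height`.
#' @export
normalize_profile <- function(calls, panel = NULL) {
  x <- filter(calls, !.data$locus_dropout)
  x <- mutate(x, norm_height = if_else(.data$zygosity == "het",
                                       (.data$height_1 + .data$height_2) / 2,
                                       .data$height_1 / 2))
  if (!is.null(panel)) {
    x <- left_join(x, select(panel$markers, "marker", "assay", "dye"),
                   by = "marker")
  }
  select(x, dplyr::any_of(c("sample_id", "marker", "assay", "dye",
                            "dose_ng", "zygosity", "norm_height")))
}

#' Inter-locus balance (IELB)
#'
#' IELB of a locus is its normalized peak height divided by the mean
#' normalized height across all amplifying loci of the same sample and
#' assay. Over a complete profile the IELB values average to 1 exactly.
#'
#' @param normalized Output of [normalize_profile()] (needs an `assay`
#'   column).
#' @return Tibble with one `ielb` per sample x assay x marker, plus
#'   `n_loci_in_assay`.
#' @export
ielb <- function(normalized) {
  stopifnot("assay" %in% names(normalized))
  normalized |>
    group_by(.data$sample_id, .data$assay) |>
    mutate(ielb = .data$norm_height / mean(.data$norm_height),
           n_loci_in_assay = n()) |>
    ungroup() |>
    select("sample_id", "assay", "marker", "norm_height", "ielb",
           "n_loci_in_assay")
}

#' Intracolour balance (ICB)
#'
#' ICB of a dye channel is the lowest normalized locus height divided by the
#' highest within the same sample, assay and dye. A one-locus dye group
#' returns 1 with an explicit flag rather than NA.
#'
#' @param normalized Output of [normalize_profile()] (needs `assay` and
#'   `dye`).
#' @return Tibble with one `icb` per sample x assay x dye and a
#'   `single_locus` flag.
#' @export
icb <- function(normalized) {
  stopifnot(all(c("assay", "dye") %in% names(normalized)))
  normalized |>
    group_by(.data$sample_id, .data$assay, .data$dye) |>
    summarise(icb = min(.data$norm_height) / max(.data$norm_height),
              single_locus = n() == 1L, .groups = "drop")
}

#' Heterozygote balance (Hb and Hb')
#'
#' Two conventions: `Hb = phi_HMW / phi_LMW` orients the ratio by fragment
#' size (high- over low-molecular-weight allele) and can exceed 1; `Hb' =
#' phi_smaller / phi_larger` orients by peak height and never exceeds 1, so
#' `Hb' = min(Hb, 1/Hb)`.
#'
#' @param calls A [call_genotypes()] result; only heterozygous calls with two
#'   distinct allele sizes are used.
#' @return Tibble with `hb`, `hb_prime` and the allele size difference per
#'   heterozygous call.
#' @export
het_balance <- function(calls) {
  calls |>
    filter(!.data$locus_dropout, .data$zygosity == "het",
           .data$size_1 != .data$size_2) |>
    mutate(
      phi_hmw = if_else(.data$size_2 > .data$size_1, .data$height_2,
                        .data$height_1),
      phi_lmw = if_else(.data$size_2 > .data$size_1, .data$height_1,
                        .data$height_2),
      hb = .data$phi_hmw / .data$phi_lmw,
      hb_prime = pmin(.data$height_1, .data$height_2) /
        pmax(.data$height_1, .data$height_2),
      size_diff_bp = abs(.data$size_2 - .data$size_1)) |>
    select(dplyr::any_of(c("sample_id", "marker", "dose_ng")),
           "phi_hmw", "phi_lmw", "hb", "hb_prime", "size_diff_bp")
}

# Five-number summary used across the validation metrics.
metric_summary <- function(x) {
  n <- length(x)
  tibble(mean = mean(x), median = median(x),
         sd = if (n > 1) sd(x) else 0,
         min = min(x), max = max(x),
         lower_3sd = mean(x) - 3 * (if (n > 1) sd(x) else 0),
         upper_3sd = mean(x) + 3 * (if (n > 1) sd(x) else 0),
         n = n, single_observation = n == 1L)
}

#' Stutter-ratio statistics and filter thresholds
#'
#' Summarizes stutter observations per marker and stutter type (mean,
#' median, SD, min, max, mean +/- 3*SD, n), derives the per-marker/type
#' stutter filter threshold as mean + 3*SD, reports allele-specific mean
#' ratios, and fits the trend of mean stutter ratio against parent repeat
#' number by least squares on per-allele means. Groups with no observation
#' are absent from the output (their omission biases ratios upward, as
#' samples without recognized stutter cannot contribute).
#'
#' @param observations A [classify_stutters()] result (needs `parent_nr` for
#'   the trend fit).
#' @return List: `by_marker_type` (summaries + `filter_threshold`),
#'   `by_allele` (per marker x type x parent allele mean S_R), `trend`
#'   (slope/intercept per marker x type, NA with fewer than 3 distinct
#'   alleles).
#' @export
stutter_stats <- function(observations) {
  if (nrow(observations) == 0L) abort("no stutter observations")
  by_mt <- observations |>
    group_by(.data$marker, .data$type) |>
    dplyr::group_modify(~ metric_summary(.x$sr)) |>
    ungroup() |>
    mutate(filter_threshold = .data$upper_3sd)
  by_allele <- observations |>
    group_by(.data$marker, .data$type, .data$parent_allele,
             parent_nr = .data$parent_nr) |>
    summarise(mean_sr = mean(.data$sr), n = n(), .groups = "drop")
  trend <- by_allele |>
    filter(!is.na(.data$parent_nr)) |>
    group_by(.data$marker, .data$type) |>
    dplyr::group_modify(function(d, g) {
      if (length(unique(d$parent_nr)) < 3) {
        return(tibble(slope = NA_real_, intercept = NA_real_,
                      n_alleles = nrow(d)))
      }
      fit <- lm(mean_sr ~ parent_nr, data = d)
      tibble(slope = coef(fit)[["parent_nr"]],
             intercept = coef(fit)[["(Intercept)"]], n_alleles = nrow(d))
    }) |>
    ungroup()
  list(by_marker_type = by_mt, by_allele = by_allele, trend = trend)
}

#' Sensitivity report across a dilution series
#'
#' Classifies each sample x marker call against the true genotype: a marker
#' with no surviving allele is a locus dropout; a true heterozygote called
#' as a single allele is an allelic dropout; a profile with every marker
#' called is full. Heterozygote-balance summaries are reported per dose.
#'
#' @param calls_by_dose Tibble binding [call_genotypes()] results across
#'   doses (needs a `dose_ng` column per call or per table).
#' @param truth_genotypes True genotype tibble (`sample_id`, `marker`,
#'   `allele_1`, `allele_2`).
#' @return List: `per_dose` (samples, full profiles, locus and allelic
#'   dropout counts), `het_balance_by_dose` (mean/SD of Hb and Hb').
#' @export
sensitivity_report <- function(calls_by_dose, truth_genotypes) {
  truth <- truth_genotypes |>
    mutate(true_het = .data$allele_1 != .data$allele_2) |>
    select("sample_id", "marker", true_1 = "allele_1", true_2 = "allele_2",
           "true_het")
  x <- calls_by_dose |>
    inner_join(truth, by = c("sample_id", "marker")) |>
    mutate(allelic_dropout = !.data$locus_dropout & .data$true_het &
             .data$zygosity == "hom")
  per_dose <- x |>
    group_by(.data$dose_group) |>
    summarise(
      n_samples = dplyr::n_distinct(.data$sample_id),
      n_locus_dropouts = sum(.data$locus_dropout),
      n_allelic_dropouts = sum(.data$allelic_dropout),
      full_profiles = sum(tapply(.data$locus_dropout, .data$sample_id,
                                 function(z) !any(z))),
      locus_dropout_rate = mean(.data$locus_dropout),
      .groups = "drop")
  hb <- het_balance(calls_by_dose)
  hb_by_dose <- NULL
  if (nrow(hb) > 0 && "dose_group" %in% names(calls_by_dose)) {
    hb <- inner_join(hb,
                     distinct(calls_by_dose, .data$sample_id, .data$marker,
                              .data$dose_group),
                     by = c("sample_id", "marker"))
    hb_by_dose <- hb |>
      group_by(.data$dose_group) |>
      summarise(hb_mean = mean(.data$hb), hb_sd = sd(.data$hb),
                hb_prime_mean = mean(.data$hb_prime),
                hb_prime_sd = sd(.data$hb_prime), n_het = n(),
                .groups = "drop")
  }
  list(per_dose = per_dose, het_balance_by_dose = hb_by_dose)
}

#' Species cross-reactivity summary
#'
#' Counts, per non-target taxon, the markers showing at least one passing
#' peak (a marker counts once regardless of how many peaks it shows), and
#' reports near-threshold peaks separately.
#'
#' @param peaks Peak table with a `taxon` column.
#' @param taxa Tibble with `taxon` and logical `target` columns.
#' @param analytical_threshold rfu threshold.
#' @param near_factor Peaks below `near_factor * threshold` are flagged
#'   near-threshold.
#' @return Tibble per non-target taxon: `n_markers_amplifying`,
#'   `n_markers_near_threshold_only`.
#' @export
cross_reactivity <- function(peaks, taxa, analytical_threshold = 200,
                             near_factor = 1.5) {
  non_target <- filter(taxa, !.data$target)
  x <- peaks |>
    inner_join(non_target, by = "taxon") |>
    filter(.data$height_rfu >= analytical_threshold) |>
    mutate(near = .data$height_rfu < near_factor * analytical_threshold)
  non_target |>
    left_join(
      x |> group_by(.data$taxon) |>
        summarise(
          n_markers_amplifying = dplyr::n_distinct(.data$marker),
          n_markers_near_threshold_only =
            sum(tapply(.data$near, .data$marker, all)),
          .groups = "drop"),
      by = "taxon") |>
    mutate(n_markers_amplifying = dplyr::coalesce(.data$n_markers_amplifying, 0L)) |>
    select("taxon", "n_markers_amplifying",
           dplyr::any_of("n_markers_near_threshold_only"))
}
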