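#' Simulation configuration for CE profile generation
#'
#' Controls every artifact model in the simulator. Heights: lognormal parent
#' heights at the reference dose, multiplied by a per-dye gain and scaled
#' linearly with dose; log-height decays linearly with fragment size
#' (degradation), which generates realistic heterozygote imbalance. Dropout
#' acts per allele copy with a logistic amplification probability in
#' log2(dose) (midpoint `dropout_d50` ng, slope `dropout_slope`). Stutter
#' ratios are linear in the parent's repeat number per stutter type; two-base
#' and shorter "n-1" series peaks (n-2/3/4 bp) can be enabled per marker.
#'
#' @param dye_gains Named positive gains per dye channel.
#' @param height_meanlog,height_sdlog Lognormal parameters of a single-copy
#'   parent peak at the reference dose.
#' @param ref_dose_ng Dose at which heights follow the lognormal model.
#' @param degradation_slope Decay rate of log peak height per bp of fragment
#'   size.
#' @param stutter Tibble with columns `type` ("n-k", "n-2k", "n+k"), `base`,
#'   `slope`: stutter ratio = base + slope * NR (truncated at 0). Base
#'   ratios must lie in [0, 0.5).
#' @param series_1bp_markers Markers producing an n-1 bp stutter series.
#' @param series_1bp_ratios Ratios for the n-2, n-3, n-4 bp series peaks.
#' @param dropout_d50 Dose (ng) at which a single allele copy amplifies with
#'   probability 0.5; `NULL` disables dropout.
#' @param dropout_slope Logistic slope per log2(dose) unit.
#' @param sizing_sd Gaussian sizing noise SD in bp.
#' @param null_alleles Tibble with columns `variety`, `marker`: combinations
#'   that never amplify.
#' @param analytical_threshold Minimum rfu for a peak to be treated as
#'   signal; lower peaks are flagged, never deleted.
#' @return A `sim_config` list.
#' @export
sim_config <- function(dye_gains = c(B = 1, G = 0.9, Y = 0.8, R = 0.7),
                       height_meanlog = log(2000), height_sdlog = 0.25,
                       ref_dose_ng = 1.25,
                       degradation_slope = 0.002,
                       stutter = tibble(type = c("n-k", "n-2k", "n+k"),
                                        base = c(0.02, 0.005, 0.003),
                                        slope = c(0.004, 0, 0)),
                       series_1bp_markers = character(),
                       series_1bp_ratios = c(0.05, 0.03, 0.02),
                       dropout_d50 = 0.2, dropout_slope = 2,
                       sizing_sd = 0.06,
                       null_alleles = NULL,
                       analytical_threshold = 200) {
  stopifnot(all(dye_gains > 0), height_sdlog >= 0, ref_dose_ng > 0,
            degradation_slope >= 0, sizing_sd >= 0,
            analytical_threshold >= 0,
            all(stutter$base >= 0), all(stutter$base < 0.5),
            all(c("type", "base", "slope") %in% names(stutter)))
  if (!is.null(dropout_d50)) stopifnot(dropout_d50 > 0, dropout_slope > 0)
  if (is.null(null_alleles)) {
    null_alleles <- tibble(variety = character(), marker = character())
  }
  structure(list(dye_gains = dye_gains, height_meanlog = height_meanlog,
                 height_sdlog = height_sdlog, ref_dose_ng = ref_dose_ng,
                 degradation_slope = degradation_slope, stutter = stutter,
                 series_1bp_markers = series_1bp_markers,
                 series_1bp_ratios = series_1bp_ratios,
                 dropout_d50 = dropout_d50, dropout_slope = dropout_slope,
                 sizing_sd = sizing_sd, null_alleles = null_alleles,
                 analytical_threshold = analytical_threshold),
            class = "sim_config")
}

#' Simulate capillary-electrophoresis peak tables from genotypes
#'
#' For each surviving allele copy a parent peak is emitted, plus stutter
#' peaks at offsets of one repeat unit (and the n-1 bp series where enabled).
#' Null-allele (variety, marker) combinations emit nothing; dropout removes
#' individual allele copies (a heterozygote losing one copy becomes an
#' apparent homozygote, losing both a locus dropout). Peak sizes carry
#' Gaussian sizing noise; sub-threshold peaks are flagged, not deleted.
#' All randomness flows from per-sample sub-streams derived from `seed`.
#'
#' @param genotypes Long genotype tibble (as in
#'   [generate_varieties()]`$genotypes`).
#' @param panel An [synthetic_panel()].
#' @param config A [sim_config()].
#' @param dose_ng DNA amount per reaction (> 0).
#' @param seed Integer seed.
#' @return List of class `sim_profiles`: `peaks` (tibble: sample_id, variety,
#'   assay, marker, dye, size_bp, height_rfu, dose_ng, below_threshold,
#'   peak_id) and `truth` (per-peak provenance plus the input genotypes).
#' @export
simulate_profiles <- function(genotypes, panel, config = sim_config(),
                              dose_ng = 1.25, seed = 1) {
  stopifnot(inherits(panel, "str_panel"), inherits(config, "sim_config"))
  if (dose_ng <= 0) abort("dose_ng must be positive")
  if (!"category" %in% names(genotypes)) genotypes$category <- NA_character_
  inv <- panel$inventory
  g <- genotypes |>
    tidyr::pivot_longer(c("allele_1", "allele_2"), names_to = "copy",
                        values_to = "allele") |>
    inner_join(inv, by = c("marker", "allele"))
  if (nrow(g) < nrow(genotypes) * 2) {
    abort("some genotype alleles have no fragment size in the panel")
  }
  # null alleles: whole (variety, marker) combinations emit nothing
  g <- anti_join(g, config$null_alleles, by = c("variety", "marker"))
  samples <- unique(genotypes$sample_id)
  res <- purrr::map(seq_along(samples), function(si) {
    withr::with_seed(derive_seed(seed, si), {
      gs <- g[g$sample_id == samples[si], , drop = FALSE]
      if (nrow(gs) == 0L) return(NULL)
      # per-copy dropout
      if (!is.null(config$dropout_d50)) {
        p_amp <- plogis(config$dropout_slope *
                          (log2(dose_ng) - log2(config$dropout_d50)))
        gs <- gs[stats::runif(nrow(gs)) < p_amp, , drop = FALSE]
      }
      if (nrow(gs) == 0L) return(NULL)
      gs$copy_height <- rlnorm(nrow(gs), config$height_meanlog,
                               config$height_sdlog) *
        config$dye_gains[gs$dye] * (dose_ng / config$ref_dose_ng) *
        exp(-config$degradation_slope * gs$size_bp)
      parents <- gs |>
        group_by(.data$sample_id, .data$variety, .data$category, .data$assay,
                 .data$marker, .data$dye, .data$allele, .data$nr,
                 .data$size_bp) |>
        summarise(height_rfu = sum(.data$copy_height), .groups = "drop") |>
        mutate(provenance = "allele", parent_allele = .data$allele,
               k = nchar_motif(.data$marker, panel))
      st <- purrr::pmap(config$stutter, function(type, base, slope) {
        ratio <- pmax(0, base + slope * parents$nr)
        off <- switch(type, `n-k` = -parents$k, `n-2k` = -2L * parents$k,
                      `n+k` = parents$k)
        keep <- ratio > 0
        if (!any(keep)) return(NULL)
        parents[keep, ] |>
          mutate(size_bp = .data$size_bp + off[keep],
                 height_rfu = .data$height_rfu * ratio[keep],
                 provenance = paste0("stutter:", type))
      }) |> bind_rows()
      ser <- NULL
      in_series <- parents$marker %in% config$series_1bp_markers
      if (any(in_series)) {
        ser <- purrr::map(seq_along(config$series_1bp_ratios), function(j) {
          parents[in_series, ] |>
            mutate(size_bp = .data$size_bp - (j + 1L),
                   height_rfu = .data$height_rfu * config$series_1bp_ratios[j],
                   provenance = paste0("stutter:n-", j + 1L, "bp"))
        }) |> bind_rows()
      }
      peaks <- bind_rows(parents, st, ser) |> select(-"k")
      if (config$sizing_sd > 0) {
        peaks$size_bp <- peaks$size_bp + rnorm(nrow(peaks), 0, config$sizing_sd)
      }
      peaks
    })
  }) |> bind_rows()
  if (nrow(res) == 0L) {
    abort("simulation produced no peaks (all loci null or dropped out)")
  }
  res <- res |>
    mutate(dose_ng = dose_ng,
           below_threshold = .data$height_rfu < config$analytical_threshold,
           peak_id = sprintf("P%06d", row_number()))
  peaks <- select(res, "sample_id", "variety", "category", "assay", "marker",
                  "dye", "size_bp", "height_rfu", "dose_ng",
                  "below_threshold", "peak_id")
  truth <- list(
    peak_provenance = select(res, "peak_id", "sample_id", "marker",
                             "provenance", "parent_allele"),
    genotypes = genotypes)
  out <- list(peaks = peaks, truth = truth, config = config, seed = seed)
  class(out) <- "sim_profiles"
  out
}

nchar_motif <- function(marker, panel) {
  panel$markers$motif_length[match(marker, panel$markers$marker)]
}

#' Write a peak table to TSV
#' @param peaks Peak tibble (the `peaks` element of [simulate_profiles()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  readr::write_tsv(peaks, path, progress = FALSE)
  invisible(path)
}

#' Read a peak table from TSV
#'
#' Accepts the native dialect of [write_peak_table()] as well as
#' GeneMapper-like genotype-table exports, whose column names
#' (`Sample.Name`/`Sample Name`, `Marker`, `Dye`, `Size`, `Height`) are
#' mapped onto the native schema.
#'
#' @param path Input path.
#' @return Peak tibble.
#' @export
read_peak_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  nm <- names(x)
  shim <- c("Sample.Name" = "sample_id", "Sample Name" = "sample_id",
            "Marker" = "marker", "Dye" = "dye", "Size" = "size_bp",
            "Height" = "height_rfu")
  hit <- nm %in% names(shim)
  names(x)[hit] <- shim[nm[hit]]
  x
}
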