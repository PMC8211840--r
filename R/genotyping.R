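#' Flag peaks below the analytical threshold
#'
#' Flags only -- no peak is ever deleted, so downstream consumers decide what
#' to do with sub-threshold signal.
#'
#' @param peaks Peak tibble with a `height_rfu` column.
#' @param analytical_threshold Threshold in rfu (>= 0).
#' @return `peaks` with a `below_threshold` logical column.
#' @export
apply_threshold <- function(peaks, analytical_threshold = 200) {
  stopifnot(analytical_threshold >= 0)
  mutate(peaks, below_threshold = .data$height_rfu < analytical_threshold)
}

#' Compose an allelic ladder by greedy sample selection
#'
#' Picks samples so that the selected set jointly carries every allele in the
#' inventory: at each step the sample covering the most uncovered alleles is
#' chosen (ties broken by lexicographic sample id). Alleles carried by no
#' sample are reported as missing and the ladder is built from the rest.
#'
#' @param inventory Tibble with `marker`, `allele`, `size_bp` columns.
#' @param genotypes Long genotype tibble (`sample_id`, `marker`, `allele_1`,
#'   `allele_2`).
#' @param half_width Bin half-width in bp (default 0.4).
#' @return A list of class `ladder_definition`: `samples` (selected ids),
#'   `bins` (marker, allele, center size, half-width, plus dye if present),
#'   `missing_alleles`, `half_width`.
#' @export
build_ladder <- function(inventory, genotypes, half_width = 0.4) {
  key <- function(m, a) paste(m, a, sep = "\r")
  want <- key(inventory$marker, inventory$allele)
  carried <- genotypes |>
    tidyr::pivot_longer(c("allele_1", "allele_2"), values_to = "allele") |>
    filter(!is.na(.data$allele)) |>
    distinct(.data$sample_id, .data$marker, .data$allele) |>
    mutate(k = key(.data$marker, .data$allele)) |>
    filter(.data$k %in% want)
  coverable <- unique(carried$k)
  missing <- inventory[!want %in% coverable, c("marker", "allele")]
  by_sample <- split(carried$k, carried$sample_id)
  uncovered <- coverable
  selected <- character()
  while (length(uncovered) > 0L) {
    gain <- vapply(by_sample, function(k) sum(k %in% uncovered), integer(1))
    best <- names(by_sample)[which(gain == max(gain))]
    pick <- sort(best)[1]
    selected <- c(selected, pick)
    uncovered <- setdiff(uncovered, by_sample[[pick]])
    by_sample[[pick]] <- NULL
  }
  bins <- inventory[want %in% coverable, , drop = FALSE] |>
    mutate(half_width = half_width) |>
    arrange(.data$marker, .data$size_bp)
  # no-overlap invariant: adjacent centers must differ by more than 2x hw
  gapcheck <- bins |>
    group_by(.data$marker) |>
    summarise(min_gap = if (n() > 1) min(diff(sort(.data$size_bp))) else Inf,
              .groups = "drop")
  if (any(gapcheck$min_gap <= 2 * half_width)) {
    abort(sprintf("overlapping bins in marker %s (adjacent centers %.2f bp apart)",
                  gapcheck$marker[gapcheck$min_gap <= 2 * half_width][1],
                  min(gapcheck$min_gap)))
  }
  out <- list(samples = selected, bins = bins, missing_alleles = missing,
              half_width = half_width)
  class(out) <- "ladder_definition"
  out
}

#' @export
print.ladder_definition <- function(x, ...) {
  cat(sprintf("<ladder_definition> %d bins over %d markers from %d samples (%d missing alleles)\n",
              nrow(x$bins), length(unique(x$bins$marker)), length(x$samples),
              nrow(x$missing_alleles)))
  invisible(x)
}

#' Call genotypes from a thresholded peak table
#'
#' Assigns each passing peak to the unique ladder bin within the bin
#' half-width (no-overlap is asserted at runtime), filters backward-stutter
#' candidates (a binned peak one repeat unit below a taller called allele
#' with height ratio at or below the marker's stutter threshold), and calls
#' up to two alleles per sample and marker. Zero surviving alleles is a
#' locus dropout; one is a homozygote, flagged as a suspected allelic
#' dropout when the sample's dose metadata is low; more than two surviving
#' alleles raises an error flag on the call. Passing peaks inside a
#' marker's size window that match no bin are counted as off-ladder.
#'
#' @param peaks Peak tibble with `below_threshold` flags (see
#'   [apply_threshold()]) and `marker` assignment columns from the simulator
#'   or an import shim. Peaks are matched to markers by dye + size window
#'   when a `marker` column is absent.
#' @param ladder A [build_ladder()] result.
#' @param panel An [synthetic_panel()] (for motif lengths).
#' @param stutter_thresholds Named per-marker ratio thresholds for the n-k
#'   filter; markers without an estimate use `default_stutter_threshold`.
#' @param default_stutter_threshold Fallback filter ratio (default 0.15).
#' @param low_dose_ng Dose at or below which single-allele calls carry the
#'   allelic-dropout suspicion flag.
#' @param filter_forward_stutter Also filter candidates one repeat unit
#'   above a taller called peak (off by default; forward stutter is rare and
#'   normally reported, not filtered).
#' @return Tibble of class `genotype_calls`: sample_id, marker, allele_1,
#'   allele_2, zygosity, heights, flags (`locus_dropout`,
#'   `allelic_dropout_suspected`, `too_many_alleles`), `n_off_ladder`.
#' @export
call_genotypes <- function(peaks, ladder, panel,
                           stutter_thresholds = NULL,
                           default_stutter_threshold = 0.15,
                           low_dose_ng = 0.35,
                           filter_forward_stutter = FALSE) {
  stopifnot(inherits(ladder, "ladder_definition"))
  if (!"below_threshold" %in% names(peaks)) {
    abort("peaks must be thresholded first (apply_threshold)")
  }
  bins <- ladder$bins
  hw <- ladder$half_width
  passing <- filter(peaks, !.data$below_threshold)
  # bin assignment: join by marker, keep |size - center| <= hw
  assigned <- passing |>
    inner_join(select(bins, "marker", bin_allele = "allele",
                      center = "size_bp"),
               by = "marker", relationship = "many-to-many") |>
    filter(abs(.data$size_bp - .data$center) <= hw)
  if (anyDuplicated(assigned$peak_id %||% seq_len(nrow(assigned)))) {
    dup <- assigned$peak_id[duplicated(assigned$peak_id)][1]
    abort(sprintf("peak %s matches two bins; ladder invariant violated", dup))
  }
  # off-ladder: passing peaks within the marker's ladder window, unassigned
  windows <- bins |>
    group_by(.data$marker) |>
    summarise(lo = min(.data$size_bp) - hw, hi = max(.data$size_bp) + hw,
              .groups = "drop")
  off <- passing |>
    anti_join(assigned, by = intersect(c("peak_id", "sample_id", "marker", "size_bp"),
                                       names(passing))) |>
    inner_join(windows, by = "marker") |>
    filter(.data$size_bp >= .data$lo, .data$size_bp <= .data$hi) |>
    count(.data$sample_id, .data$marker, name = "n_off_ladder")
  k_of <- setNames(panel$markers$motif_length, panel$markers$marker)
  thr_of <- function(m) {
    if (!is.null(stutter_thresholds) && m %in% names(stutter_thresholds)) {
      stutter_thresholds[[m]]
    } else default_stutter_threshold
  }
  # expected sample x marker universe: every marker for every sample seen
  universe <- tidyr::expand_grid(
    sample_id = unique(peaks$sample_id),
    marker = unique(bins$marker))
  if (nrow(assigned) == 0L) {
    calls <- tibble(sample_id = character(), marker = character(),
                    allele_1 = character(), allele_2 = character(),
                    height_1 = numeric(), height_2 = numeric(),
                    size_1 = numeric(), size_2 = numeric(),
                    zygosity = character(), dose_ng = numeric(),
                    too_many_alleles = logical())
    return(finalize_calls(universe, calls, off, low_dose_ng))
  }
  calls <- assigned |>
    group_by(.data$sample_id, .data$marker) |>
    dplyr::group_modify(function(d, g) {
      k <- k_of[[g$marker]]
      d <- arrange(d, dplyr::desc(.data$height_rfu))
      # stutter filter: one repeat unit below (optionally also above) a
      # taller retained peak
      offs <- if (filter_forward_stutter) c(k, -k) else k
      keep <- rep(TRUE, nrow(d))
      for (i in seq_len(nrow(d))) {
        if (!keep[i]) next
        taller <- which(keep & d$height_rfu > d$height_rfu[i])
        gaps <- d$center[taller] - d$center[i]
        near <- vapply(gaps, function(g_) any(abs(g_ - offs) < 1e-6),
                       logical(1))
        is_stutter <- any(near & d$height_rfu[i] / d$height_rfu[taller] <=
                            thr_of(g$marker))
        if (is_stutter) keep[i] <- FALSE
      }
      d <- d[keep, , drop = FALSE]
      n_al <- nrow(d)
      if (n_al == 0L) {
        return(tibble(allele_1 = NA_character_, allele_2 = NA_character_,
                      height_1 = NA_real_, height_2 = NA_real_,
                      size_1 = NA_real_, size_2 = NA_real_,
                      zygosity = NA_character_, dose_ng = NA_real_,
                      too_many_alleles = FALSE))
      }
      d <- arrange(d, .data$center)
      tibble(
        allele_1 = d$bin_allele[1],
        allele_2 = if (n_al >= 2) d$bin_allele[2] else d$bin_allele[1],
        height_1 = d$height_rfu[1],
        height_2 = if (n_al >= 2) d$height_rfu[2] else d$height_rfu[1],
        size_1 = d$center[1],
        size_2 = if (n_al >= 2) d$center[2] else d$center[1],
        zygosity = if (n_al >= 2) "het" else "hom",
        dose_ng = if ("dose_ng" %in% names(d)) d$dose_ng[1] else NA_real_,
        too_many_alleles = n_al > 2)
    }) |>
    ungroup()
  finalize_calls(universe, calls, off, low_dose_ng)
}

finalize_calls <- function(universe, calls, off, low_dose_ng = 0.35) {
  out <- universe |>
    left_join(calls, by = c("sample_id", "marker")) |>
    left_join(off, by = c("sample_id", "marker")) |>
    mutate(
      n_off_ladder = dplyr::coalesce(.data$n_off_ladder, 0L),
      locus_dropout = is.na(.data$allele_1),
      too_many_alleles = dplyr::coalesce(.data$too_many_alleles, FALSE),
      allelic_dropout_suspected = !.data$locus_dropout &
        .data$zygosity == "hom" & !is.na(.data$dose_ng) &
        .data$dose_ng <= low_dose_ng)
  class(out) <- c("genotype_calls", class(out))
  out
}

#' Classify stutter peaks against called parent alleles
#'
#' Types every sub-parent peak lying at an expected stutter position of a
#' called allele peak: one repeat unit below (n-k), two below (n-2k), one
#' above (n+k), and -- for markers with the 1-bp series enabled -- n-2/3/4 bp.
#' Matching uses a +/- `tol` bp window (default 0.5). Backward types are
#' never assigned to a peak taller than its parent; peaks matching no
#' expected position stay unclassified noise. The stutter ratio is
#' S_R = phi_S / phi_A.
#'
#' @param peaks Full peak table (run the upstream stutter filter disabled, so
#'   candidate stutter peaks survive thresholding at a lowered rfu minimum).
#' @param calls A [call_genotypes()] result.
#' @param panel Panel for motif lengths.
#' @param series_1bp_markers Markers with the n-1 bp series enabled.
#' @param tol Stutter-position matching tolerance in bp.
#' @return Tibble of stutter observations: marker, parent allele, type,
#'   `phi_s`, `phi_a`, `sr`, `parent_nr` when available.
#' @export
classify_stutters <- function(peaks, calls, panel,
                              series_1bp_markers = character(), tol = 0.5) {
  k_of <- setNames(panel$markers$motif_length, panel$markers$marker)
  parents <- calls |>
    filter(!.data$locus_dropout) |>
    tidyr::pivot_longer(cols = c("allele_1", "allele_2"),
                        names_to = "slot", values_to = "allele") |>
    mutate(height = if_else(.data$slot == "allele_1", .data$height_1,
                            .data$height_2),
           size = if_else(.data$slot == "allele_1", .data$size_1,
                          .data$size_2)) |>
    distinct(.data$sample_id, .data$marker, .data$allele, .data$height,
             .data$size)
  obs <- purrr::pmap(
    list(parents$sample_id, parents$marker, parents$allele,
         parents$height, parents$size),
    function(sid, m, al, h_a, s_a) {
      k <- k_of[[m]]
      offs <- tibble(type = c("n-k", "n-2k", "n+k"),
                     off = c(-k, -2 * k, k))
      if (m %in% series_1bp_markers) {
        offs <- bind_rows(offs, tibble(type = paste0("n-", 2:4, "bp"),
                                       off = -(2:4)))
      }
      p <- peaks[peaks$sample_id == sid & peaks$marker == m, , drop = FALSE]
      # peaks sitting on a called allele position are allele peaks, never
      # stutter candidates (an adjacent heterozygous allele lies exactly one
      # repeat unit away)
      called_sizes <- parents$size[parents$sample_id == sid &
                                     parents$marker == m]
      keep <- vapply(p$size_bp, function(s) {
        all(abs(s - called_sizes) > tol)
      }, logical(1))
      p <- p[keep, , drop = FALSE]
      purrr::pmap(offs, function(type, off) {
        hit <- which(abs(p$size_bp - (s_a + off)) <= tol)
        if (length(hit) == 0L) return(NULL)
        hit <- hit[which.max(p$height_rfu[hit])]
        phi_s <- p$height_rfu[hit]
        backward <- off < 0
        if (backward && phi_s > h_a) return(NULL)
        tibble(sample_id = sid, marker = m, parent_allele = al, type = type,
               phi_s = phi_s, phi_a = h_a, sr = phi_s / h_a)
      }) |> bind_rows()
    }) |> bind_rows()
  if (nrow(obs) == 0L) {
    return(tibble(sample_id = character(), marker = character(),
                  parent_allele = character(), type = character(),
                  phi_s = numeric(), phi_a = numeric(), sr = numeric()))
  }
  if (is.null(panel$inventory)) {
    return(mutate(obs, parent_nr = NA_integer_))
  }
  nr_map <- panel$inventory |> distinct(.data$marker, .data$allele, .data$nr)
  left_join(obs, nr_map, by = c("marker", "parent_allele" = "allele")) |>
    rename(parent_nr = "nr")
}

#' Sizing precision of repeated allelic-ladder injections
#'
#' @param sizes Tibble with columns `marker`, `allele`, `injection`,
#'   `size_bp` (at least two injections per allele).
#' @param half_width Bin half-width the 3*SD verdict is checked against.
#' @return List with `per_allele` (mean, SD, `exceeds_bin` = 3*SD >
#'   half-width) and `summary` (mean SD, SEM = SD(per-allele SDs)/sqrt(n),
#'   min, max SD, n alleles).
#' @export
sizing_precision <- function(sizes, half_width = 0.4) {
  per <- sizes |>
    group_by(.data$marker, .data$allele) |>
    summarise(n_injections = n(), mean_size = mean(.data$size_bp),
              sd_size = sd(.data$size_bp), .groups = "drop")
  if (any(per$n_injections < 2)) {
    abort("each allele needs at least two injections")
  }
  per <- mutate(per, exceeds_bin = 3 * .data$sd_size > half_width)
  summary <- tibble(
    mean_sd = mean(per$sd_size),
    sem = sd(per$sd_size) / sqrt(nrow(per)),
    min_sd = min(per$sd_size),
    max_sd = max(per$sd_size),
    n_alleles = nrow(per))
  list(per_allele = per, summary = summary)
}
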