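#' Read and write genotype matrices
#'
#' The wide on-disk format has columns `sample_id`, `variety`, `category`,
#' then one column per marker holding "a1/a2" allele pairs (empty cell =
#' missing). In memory genotypes are long tibbles with `allele_1`/`allele_2`
#' columns.
#'
#' @param genotypes Long genotype tibble.
#' @param path File path.
#' @return `read_genotype_matrix()` returns the long tibble;
#'   `write_genotype_matrix()` returns `path` invisibly.
#' @export
write_genotype_matrix <- function(genotypes, path) {
  wide <- genotypes |>
    mutate(cell = if_else(is.na(.data$allele_1), "",
                          paste(.data$allele_1, .data$allele_2, sep = "/"))) |>
    select(dplyr::any_of(c("sample_id", "variety", "category")), "marker",
           "cell") |>
    tidyr::pivot_wider(names_from = "marker", values_from = "cell")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = "c"))
  meta <- intersect(c("sample_id", "variety", "category"), names(wide))
  wide |>
    tidyr::pivot_longer(-dplyr::all_of(meta), names_to = "marker",
                        values_to = "cell") |>
    tidyr::separate(.data$cell, into = c("allele_1", "allele_2"), sep = "/",
                    fill = "right") |>
    mutate(allele_1 = dplyr::na_if(.data$allele_1, ""),
           allele_2 = dplyr::coalesce(.data$allele_2, .data$allele_1))
}

#' Export a simulation run (peaks, truth, config) to plain-text files
#'
#' Writes the peak table and per-peak provenance as TSV and echoes the
#' configuration as JSON alongside.
#'
#' @param sim A [simulate_profiles()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_profiles"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(sim$peaks, file.path(dir, "peaks.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$peak_provenance,
                   file.path(dir, "peak_provenance.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$genotypes, file.path(dir, "genotypes.tsv"),
                   progress = FALSE)
  cfg <- sim$config
  cfg$stutter <- as.data.frame(cfg$stutter)
  cfg$null_alleles <- as.data.frame(cfg$null_alleles)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
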