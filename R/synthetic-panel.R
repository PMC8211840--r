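#' Build a synthetic STR marker panel
#'
#' Creates a multiplexed marker panel emulating a plant STR profiling system:
#' tri- to pentanucleotide markers spread over assays and four dye channels,
#' each with an allele inventory (consecutive repeat numbers around a
#' reference allele, fragment sizes offset by one motif length per repeat)
#' and a [marker_reference()] usable by the nomenclature engine. Marker size
#' windows within a dye are spaced so that bins can never collide across
#' markers.
#'
#' @param n_markers Number of markers (default 27, split over 3 assays).
#' @param n_assays Number of multiplex assays.
#' @param mean_alleles Approximate mean inventory size per marker; per-marker
#'   counts are drawn between 3 and 14.
#' @param seed Integer seed.
#' @return A list of class `str_panel`: `markers` (tibble with marker, assay,
#'   dye, motif, motif_length), `inventory` (tibble with marker, allele label,
#'   repeat number `nr`, `size_bp`, dye, assay), `references` (named list of
#'   marker references).
#' @export
synthetic_panel <- function(n_markers = 27, n_assays = 3, mean_alleles = 5.85,
                            seed = 1) {
  stopifnot(n_markers >= 1, n_assays >= 1)
  dyes <- c("B", "G", "Y", "R")
  withr::with_seed(derive_seed(seed, 17L), {
    motif_len <- sample(c(3L, 4L, 5L), n_markers, replace = TRUE,
                        prob = c(0.3, 0.5, 0.2))
    motifs <- vapply(motif_len, random_primitive_motif, character(1))
    assay <- rep_len(seq_len(n_assays), n_markers)
    dye <- unlist(lapply(seq_len(n_assays), function(a) {
      k <- sum(assay == a)
      rep_len(dyes, k)
    }))
    markers <- tibble(
      marker = sprintf("SYN%03d", seq_len(n_markers)),
      assay = assay, dye = dye,
      motif = motifs, motif_length = motif_len)
    # distinct size windows per (assay, dye): 90 bp apart, alleles inside
    markers <- markers |>
      group_by(.data$assay, .data$dye) |>
      mutate(window = row_number()) |>
      ungroup() |>
      mutate(base_size = 80 + (.data$window - 1L) * 90)
    n_alleles <- pmin(14L, pmax(3L, stats::rpois(n_markers, mean_alleles - 3) + 3L))
    ref_nr <- sample(7:12, n_markers, replace = TRUE)
    inventory <- purrr::pmap(
      list(markers$marker, markers$motif_length, markers$base_size,
           n_alleles, ref_nr, markers$dye, markers$assay),
      function(m, k, b, na, rnr, dy, as_) {
        nrs <- seq(rnr - (na %/% 2), length.out = na)
        nrs <- nrs[nrs >= 3]
        tibble(marker = m, allele = as.character(nrs), nr = nrs,
               size_bp = b + k * nrs, dye = dy, assay = as_)
      }) |> bind_rows()
    references <- purrr::pmap(
      list(markers$marker, markers$motif, ref_nr),
      function(m, mo, rnr) {
        marker_reference(
          m,
          upstream = make_flank(30L, mo, side = "U"),
          structure = sprintf("(%s)%d", mo, rnr),
          downstream = make_flank(30L, mo, side = "D"),
          pigtail = 7L)
      })
    names(references) <- markers$marker
    out <- list(markers = select(markers, -"window", -"base_size"),
                inventory = inventory, references = references, seed = seed)
    class(out) <- "str_panel"
    out
  })
}

# Random primitive motif of length k.
random_primitive_motif <- function(k) {
  repeat {
    m <- paste(sample(DNA_BASES, k, replace = TRUE), collapse = "")
    if (is_primitive_motif(m)) return(m)
  }
}

# Random flank that cannot be confused with the repeat region: no occurrence
# of the motif within the flank or straddling the flank/repeat boundary
# (primitive motifs can still self-overlap, e.g. ATA), and a boundary base
# that does not extend the run.
make_flank <- function(len, motif, side) {
  p <- nchar(motif)
  for (try in 1:500) {
    f <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    joined <- if (side == "U") paste0(f, substr(motif, 1L, p - 1L))
              else paste0(substr(motif, 2L, p), f)
    if (grepl(motif, joined, fixed = TRUE)) next
    if (side == "U" && substr(f, len, len) == substr(motif, p, p)) next
    if (side == "D" && substr(f, 1, 1) == substr(motif, 1, 1)) next
    return(f)
  }
  abort("could not generate a motif-free flank")
}

#' @export
print.str_panel <- function(x, ...) {
  cat(sprintf("<str_panel> %d markers, %d assays, %d alleles\n",
              nrow(x$markers), length(unique(x$markers$assay)),
              nrow(x$inventory)))
  invisible(x)
}
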