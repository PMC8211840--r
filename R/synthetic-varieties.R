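#' Generate inbred variety genotype sets
#'
#' Emulates pure breeding lines: each variety gets a per-marker allele pool
#' and a modal (founder) allele; plants are homozygous for the modal allele
#' except for a residual heterozygosity rate at which a plant carries the
#' modal plus a second pool allele. Varieties listed together in
#' `clone_groups` share pools and modal profiles, producing engineered
#' indistinguishable groups; with `force_modal_first` each variety's first
#' plant is fully homozygous modal, guaranteeing a cross-variety 0-mismatch
#' pair within every clone group.
#'
#' @param panel An [synthetic_panel()] object.
#' @param n_varieties Number of varieties.
#' @param plants_per_variety Scalar, per-variety vector, or length-2 range
#'   (plants drawn uniformly within it).
#' @param allele_pool_size Alleles per variety per marker (<= inventory size;
#'   error otherwise).
#' @param residual_het_rate Per-marker probability that a plant is
#'   heterozygous.
#' @param clone_groups Optional list of integer vectors of variety indices
#'   sharing one genotype pool.
#' @param force_modal_first Force plant 1 of each variety to the pure modal
#'   profile (default FALSE; slightly depresses realized heterozygosity).
#' @param seed Integer seed.
#' @return List of class `variety_set`: `genotypes` (long tibble: sample_id,
#'   variety, category, marker, allele_1, allele_2), `modal_profiles`,
#'   `pools`, `seed`.
#' @export
generate_varieties <- function(panel, n_varieties = 36, plants_per_variety = 5,
                               allele_pool_size = 2,
                               residual_het_rate = 0.076,
                               clone_groups = NULL,
                               force_modal_first = FALSE, seed = 1) {
  stopifnot(inherits(panel, "str_panel"), n_varieties >= 1,
            residual_het_rate >= 0, residual_het_rate <= 1)
  inv <- split(panel$inventory$allele, panel$inventory$marker)
  markers <- panel$markers$marker
  short <- names(inv)[vapply(inv, length, integer(1)) < allele_pool_size]
  if (length(short) > 0) {
    abort(sprintf("allele_pool_size %d exceeds inventory of marker %s",
                  allele_pool_size, short[1]))
  }
  varieties <- sprintf("VAR%02d", seq_len(n_varieties))
  categories <- rep_len(c("culinary", "dual", "pharmaceutical", "ornamental"),
                        n_varieties)
  if (length(plants_per_variety) == 2 && n_varieties > 2) {
    counts_range <- plants_per_variety
  } else {
    counts_range <- NULL
  }
  withr::with_seed(derive_seed(seed, 29L), {
    n_plants <- if (!is.null(counts_range)) {
      sample(counts_range[1]:counts_range[2], n_varieties, replace = TRUE)
    } else rep_len(plants_per_variety, n_varieties)
    # per-variety pools; redraw until non-cloned modal profiles are distinct
    draw_pools <- function() {
      lapply(seq_len(n_varieties), function(v) {
        lapply(inv, function(a) sample(a, allele_pool_size))
      })
    }
    pools <- draw_pools()
    if (!is.null(clone_groups)) {
      for (grp in clone_groups) {
        for (v in grp[-1]) pools[[v]] <- pools[[grp[1]]]
      }
    }
    leader <- seq_len(n_varieties)
    if (!is.null(clone_groups)) {
      for (grp in clone_groups) leader[grp] <- grp[1]
    }
    modal_key <- function() vapply(pools, function(p) {
      paste(vapply(p, `[`, character(1), 1L), collapse = "|")
    }, character(1))
    for (attempt in 1:100) {
      keys <- modal_key()[unique(leader)]
      if (!anyDuplicated(keys)) break
      pools <- draw_pools()
      if (!is.null(clone_groups)) {
        for (grp in clone_groups) for (v in grp[-1]) pools[[v]] <- pools[[grp[1]]]
      }
    }
    if (anyDuplicated(modal_key()[unique(leader)])) {
      abort("could not draw distinct modal profiles; enlarge the panel")
    }
    rows <- list()
    sample_counter <- 0L
    for (v in seq_len(n_varieties)) {
      pool_v <- pools[[v]]
      for (pl in seq_len(n_plants[v])) {
        sample_counter <- sample_counter + 1L
        sid <- sprintf("S%04d", sample_counter)
        het <- stats::runif(length(markers)) < residual_het_rate
        if (force_modal_first && pl == 1L) het[] <- FALSE
        a1 <- vapply(markers, function(m) pool_v[[m]][1L], character(1))
        a2 <- ifelse(het,
                     vapply(markers, function(m) pool_v[[m]][min(2L, length(pool_v[[m]]))],
                            character(1)),
                     a1)
        rows[[sample_counter]] <- tibble(
          sample_id = sid, variety = varieties[v], category = categories[v],
          marker = markers, allele_1 = a1, allele_2 = a2)
      }
    }
    modal <- tibble(
      variety = rep(varieties, each = length(markers)),
      marker = rep(markers, n_varieties),
      modal_allele = unlist(lapply(seq_len(n_varieties), function(v) {
        vapply(markers, function(m) pools[[v]][[m]][1L], character(1))
      })))
    out <- list(genotypes = bind_rows(rows), modal_profiles = modal,
                pools = pools, varieties = varieties, seed = seed)
    class(out) <- "variety_set"
    out
  })
}

#' @export
print.variety_set <- function(x, ...) {
  cat(sprintf("<variety_set> %d varieties, %d samples, %d markers\n",
              length(x$varieties), length(unique(x$genotypes$sample_id)),
              length(unique(x$genotypes$marker))))
  invisible(x)
}
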