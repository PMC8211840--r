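#' Per-marker descriptive statistics of a genotype set
#'
#' @param genotypes Long genotype tibble (`sample_id`, `marker`, `allele_1`,
#'   `allele_2`; NA alleles are missing data).
#' @return List: `per_marker` (N_al, allele count table, H_Obs over
#'   non-missing samples), `allele_frequencies` (summing to 1 per marker),
#'   `overall` (mean/median N_al, mean H_Obs).
#' @export
pop_summary <- function(genotypes) {
  g <- filter(genotypes, !is.na(.data$allele_1), !is.na(.data$allele_2))
  per_marker <- g |>
    group_by(.data$marker) |>
    summarise(
      n_samples = n(),
      n_al = dplyr::n_distinct(c(.data$allele_1, .data$allele_2)),
      h_obs = mean(.data$allele_1 != .data$allele_2),
      .groups = "drop")
  freqs <- g |>
    tidyr::pivot_longer(c("allele_1", "allele_2"), values_to = "allele") |>
    count(.data$marker, .data$allele, name = "count") |>
    group_by(.data$marker) |>
    mutate(frequency = .data$count / sum(.data$count)) |>
    ungroup()
  overall <- tibble(
    mean_n_al = mean(per_marker$n_al),
    median_n_al = median(per_marker$n_al),
    mean_h_obs = mean(per_marker$h_obs))
  list(per_marker = per_marker, allele_frequencies = freqs, overall = overall)
}

# Unordered genotype key per sample x marker ("a|b" with a <= b, NA -> "").
genotype_keys <- function(genotypes) {
  mutate(genotypes,
         key = if_else(is.na(.data$allele_1) | is.na(.data$allele_2),
                       NA_character_,
                       paste(pmin(.data$allele_1, .data$allele_2),
                             pmax(.data$allele_1, .data$allele_2),
                             sep = "|")))
}

#' Full-profile identity analysis
#'
#' Pairwise comparison of all samples with 0 allele mismatches: a pair is
#' reported iff every marker typed in both samples carries the identical
#' unordered allele pair. Markers missing in either sample are skipped but
#' counted; pairs with fewer co-typed markers than `min_overlap` are flagged
#' low confidence.
#'
#' @param genotypes Long genotype tibble.
#' @param min_overlap Minimum number of co-typed markers for a confident
#'   match (default 20).
#' @return Tibble of matching pairs: `sample_1`, `sample_2`, their
#'   varieties when present, `n_compared`, `low_confidence`.
#' @export
identity_analysis <- function(genotypes, min_overlap = 20) {
  keyed <- genotype_keys(genotypes)
  wide <- keyed |>
    select(dplyr::any_of(c("sample_id", "variety")), "marker", "key") |>
    tidyr::pivot_wider(names_from = "marker", values_from = "key")
  meta_cols <- intersect(c("sample_id", "variety"), names(wide))
  m <- as.matrix(wide[, setdiff(names(wide), meta_cols)])
  n <- nrow(m)
  if (n < 2) return(tibble(sample_1 = character(), sample_2 = character(),
                           n_compared = integer(), low_confidence = logical()))
  idx <- combn(n, 2)
  res <- purrr::map(seq_len(ncol(idx)), function(c_) {
    i <- idx[1, c_]; j <- idx[2, c_]
    both <- !is.na(m[i, ]) & !is.na(m[j, ])
    if (any(m[i, both] != m[j, both])) return(NULL)
    tibble(sample_1 = wide$sample_id[i], sample_2 = wide$sample_id[j],
           variety_1 = if ("variety" %in% meta_cols) wide$variety[i] else NA,
           variety_2 = if ("variety" %in% meta_cols) wide$variety[j] else NA,
           n_compared = sum(both))
  }) |> bind_rows()
  if (nrow(res) == 0L) {
    return(tibble(sample_1 = character(), sample_2 = character(),
                  variety_1 = character(), variety_2 = character(),
                  n_compared = integer(), low_confidence = logical()))
  }
  mutate(res, low_confidence = .data$n_compared < min_overlap)
}

# Minimal union-find for connected components of the indistinguishability
# graph.
components_of <- function(nodes, edges_1, edges_2) {
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (e in seq_along(edges_1)) {
    r1 <- find(edges_1[e]); r2 <- find(edges_2[e])
    if (r1 != r2) parent[[max(r1, r2)]] <- min(r1, r2)
  }
  vapply(nodes, find, character(1))
}

#' Variety discrimination from identity pairs
#'
#' Two varieties are indistinguishable iff at least one cross-variety
#' 0-mismatch sample pair exists (a variety differs from another only when
#' all its plants differ from all of the other's). Indistinguishable
#' varieties are grouped as connected components of the indistinguishability
#' graph; each component counts as a single distinguishable unit.
#'
#' @param genotypes Long genotype tibble with a `variety` column.
#' @param identity_pairs Optional precomputed [identity_analysis()] result.
#' @param min_overlap Passed to [identity_analysis()] when pairs are not
#'   supplied.
#' @return List: `matrix` (symmetric logical distinguishability matrix),
#'   `groups` (tibble variety -> group id), `indistinguishable_groups` (list
#'   of multi-variety components), `n_distinguishable_units`.
#' @export
variety_discrimination <- function(genotypes, identity_pairs = NULL,
                                   min_overlap = 20) {
  stopifnot("variety" %in% names(genotypes))
  if (is.null(identity_pairs)) {
    identity_pairs <- identity_analysis(genotypes, min_overlap = min_overlap)
  }
  varieties <- sort(unique(genotypes$variety))
  cross <- filter(identity_pairs, .data$variety_1 != .data$variety_2)
  mat <- matrix(TRUE, length(varieties), length(varieties),
                dimnames = list(varieties, varieties))
  diag(mat) <- NA
  for (i in seq_len(nrow(cross))) {
    mat[cross$variety_1[i], cross$variety_2[i]] <- FALSE
    mat[cross$variety_2[i], cross$variety_1[i]] <- FALSE
  }
  comp <- components_of(varieties, cross$variety_1, cross$variety_2)
  groups <- tibble(variety = varieties, group = unname(comp))
  multi <- split(groups$variety, groups$group)
  multi <- unname(multi[vapply(multi, length, integer(1)) > 1])
  list(matrix = mat, groups = groups, indistinguishable_groups = multi,
       n_distinguishable_units = length(unique(comp)))
}

# Allele-dosage indicator matrix: one column per marker-allele, entries
# 0/1/2; missing genotypes contribute NA.
dosage_matrix <- function(genotypes) {
  long <- genotypes |>
    tidyr::pivot_longer(c("allele_1", "allele_2"), values_to = "allele") |>
    filter(!is.na(.data$allele)) |>
    count(.data$sample_id, .data$marker, .data$allele, name = "dosage") |>
    mutate(col = paste(.data$marker, .data$allele, sep = "."))
  wide <- long |>
    select("sample_id", "col", "dosage") |>
    tidyr::pivot_wider(names_from = "col", values_from = "dosage",
                       values_fill = 0L)
  # markers entirely missing for a sample: set that marker's columns to NA
  missing <- genotypes |>
    filter(is.na(.data$allele_1) | is.na(.data$allele_2)) |>
    distinct(.data$sample_id, .data$marker)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  if (nrow(missing) > 0) {
    marker_of_col <- sub("\\.[^.]*$", "", colnames(m))
    for (i in seq_len(nrow(missing))) {
      m[missing$sample_id[i], marker_of_col == missing$marker[i]] <- NA
    }
  }
  m
}

#' Principal component analysis of a genotype set
#'
#' Expands genotypes to allele-dosage columns (0/1/2 copies per
#' marker-allele), column-centers them (unscaled by default: binary dosage
#' columns have comparable variance), imputes missing dosages at the column
#' mean and runs a standard PCA. A deterministic sign convention makes the
#' largest-magnitude loading of every component positive.
#'
#' @param genotypes Long genotype tibble.
#' @param scale. Scale columns to unit variance (default FALSE).
#' @return Object of class `str_pca`: `scores` tibble (sample metadata +
#'   PC columns), `loadings`, `variance_explained`, `sdev`.
#' @export
str_pca <- function(genotypes, scale. = FALSE) {
  m <- dosage_matrix(genotypes)
  if (any(is.na(m))) {
    mu <- colMeans(m, na.rm = TRUE)
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- mu[j]
  }
  keep <- apply(m, 2, function(x) stats::var(x) > 0)
  if (!any(keep)) abort("no genetic variance: all samples identical")
  m <- m[, keep, drop = FALSE]
  p <- prcomp(m, center = TRUE, scale. = scale.)
  # sign convention: largest-|loading| element positive
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  meta <- genotypes |>
    distinct(.data$sample_id,
             dplyr::across(dplyr::any_of(c("variety", "category"))))
  scores <- as_tibble(p$x, rownames = "sample_id") |>
    left_join(meta, by = "sample_id") |>
    relocate(dplyr::any_of(c("sample_id", "variety", "category")))
  out <- list(scores = scores, loadings = p$rotation,
              variance_explained = p$sdev^2 / sum(p$sdev^2), sdev = p$sdev)
  class(out) <- "str_pca"
  out
}

#' @export
print.str_pca <- function(x, ...) {
  ve <- round(100 * x$variance_explained[seq_len(min(3, length(x$sdev)))], 1)
  cat(sprintf("<str_pca> %d samples, %d components; PC1-3 variance %%: %s\n",
              nrow(x$scores), length(x$sdev), paste(ve, collapse = ", ")))
  invisible(x)
}

#' UPGMA clustering on principal-component scores
#'
#' Average-linkage (UPGMA) agglomerative clustering on Euclidean distances
#' over the first `n_axes` principal components. Samples are processed in
#' lexicographic id order, so exact distance ties resolve deterministically
#' (by [stats::hclust()]'s index-based rule) regardless of input row order.
#' Ultrametric input distances are reproduced exactly by the cophenetic
#' distances of the tree.
#'
#' @param pca An [str_pca()] object (or a tibble of scores with a
#'   `sample_id` column and PC columns).
#' @param n_axes Number of PC axes to use (default 3).
#' @param k Number of flat clusters to cut (default 4, one per cultivar
#'   category).
#' @return Object of class `str_upgma`: `hclust`, `clusters` tibble,
#'   `newick` string, `n_axes`.
#' @export
str_upgma <- function(pca, n_axes = 3, k = 4) {
  scores <- if (inherits(pca, "str_pca")) pca$scores else pca
  pcs <- grep("^PC\\d+$", names(scores), value = TRUE)
  n_axes <- min(n_axes, length(pcs))
  stopifnot(n_axes >= 1, nrow(scores) >= 2)
  ord <- order(scores$sample_id)
  m <- as.matrix(scores[ord, pcs[seq_len(n_axes)]])
  rownames(m) <- scores$sample_id[ord]
  hc <- hclust(dist(m, method = "euclidean"), method = "average")
  k <- min(k, nrow(m))
  cl <- cutree(hc, k = k)
  clusters <- tibble(sample_id = names(cl), cluster = unname(cl)) |>
    left_join(select(scores, dplyr::any_of(c("sample_id", "variety",
                                             "category"))),
              by = "sample_id")
  newick <- ape::write.tree(ape::as.phylo(hc))
  out <- list(hclust = hc, clusters = clusters, newick = newick,
              n_axes = n_axes, k = k)
  class(out) <- "str_upgma"
  out
}

#' Write the UPGMA tree to a newick file
#' @param upgma An [str_upgma()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(upgma, path) {
  writeLines(upgma$newick, path)
  invisible(path)
}

#' Flag putatively mislabeled samples
#'
#' A sample is flagged when its Euclidean distance (in PC space) to its own
#' variety's centroid -- computed excluding the sample itself -- exceeds its
#' distance to some other variety's centroid by more than `margin`. The
#' nearest foreign variety is reported. By default all PC axes are used
#' (full dosage-space distances); the default margin of 1 is about a third
#' of the displacement caused by a single homozygous allele swap
#' (sqrt(8) ~ 2.8 in dosage units), so residual-heterozygosity noise and
#' genetically indistinguishable varieties do not trigger flags while a
#' genuinely foreign profile, differing at many loci, always does.
#'
#' @param pca An [str_pca()] object.
#' @param n_axes PC axes used; `NULL` (default) uses all axes.
#' @param margin Required distance advantage of a foreign centroid, in
#'   allele-dosage units (default 1); `Inf` disables flagging.
#' @return Tibble of flagged samples: `sample_id`, `variety`,
#'   `nearest_variety`, `d_own`, `d_nearest`.
#' @export
flag_mislabels <- function(pca, n_axes = NULL, margin = 1) {
  stopifnot(inherits(pca, "str_pca"), "variety" %in% names(pca$scores))
  scores <- pca$scores
  pcs <- grep("^PC\\d+$", names(scores), value = TRUE)
  n_axes <- if (is.null(n_axes)) length(pcs) else min(n_axes, length(pcs))
  m <- as.matrix(scores[, pcs[seq_len(n_axes)]])
  rownames(m) <- scores$sample_id
  variety <- scores$variety
  sizes <- table(variety)
  if (any(sizes < 2)) {
    abort("every variety needs at least 2 samples for centroid estimation")
  }
  sums <- rowsum(m, variety)
  flags <- purrr::map(seq_len(nrow(m)), function(i) {
    v <- variety[i]
    own <- (sums[v, ] - m[i, ]) / (sizes[[v]] - 1)
    d_own <- sqrt(sum((m[i, ] - own)^2))
    others <- setdiff(rownames(sums), v)
    d_other <- vapply(others, function(o) {
      sqrt(sum((m[i, ] - sums[o, ] / sizes[[o]])^2))
    }, numeric(1))
    j <- which.min(d_other)
    if (is.finite(margin) && d_own - d_other[j] > margin) {
      tibble(sample_id = rownames(m)[i], variety = v,
             nearest_variety = others[j], d_own = d_own,
             d_nearest = d_other[j])
    } else NULL
  }) |> bind_rows()
  if (nrow(flags) == 0L) {
    return(tibble(sample_id = character(), variety = character(),
                  nearest_variety = character(), d_own = numeric(),
                  d_nearest = numeric()))
  }
  flags
}
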