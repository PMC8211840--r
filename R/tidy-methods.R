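#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a genotype PCA
#'
#' @param x An [str_pca()] object.
#' @param ... Unused.
#' @return One row per sample with PC scores and metadata ("scores"), in
#'   broom style.
#' @export
tidy.str_pca <- function(x, ...) {
  x$scores
}

#' @rdname tidy.str_pca
#' @return For `glance()`: a one-row summary (samples, components, variance
#'   explained by PC1-PC3).
#' @export
glance.str_pca <- function(x, ...) {
  ve <- x$variance_explained
  tibble(n_samples = nrow(x$scores), n_components = length(x$sdev),
         var_pc1 = ve[1], var_pc2 = ve[2] %||% NA_real_,
         var_pc3 = ve[3] %||% NA_real_,
         var_pc123 = sum(ve[seq_len(min(3, length(ve)))]))
}

#' Tidy a UPGMA clustering
#'
#' @param x An [str_upgma()] object.
#' @param ... Unused.
#' @return One row per sample with its flat-cluster assignment.
#' @export
tidy.str_upgma <- function(x, ...) {
  x$clusters
}

#' @rdname tidy.str_upgma
#' @export
glance.str_upgma <- function(x, ...) {
  tibble(n_samples = length(x$hclust$order), k = x$k, n_axes = x$n_axes,
         max_height = max(x$hclust$height))
}
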