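#' @importFrom rlang abort warn %||% .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join inner_join anti_join distinct n rename relocate
#'   row_number across if_else first last pull count slice
#' @importFrom tibble tibble as_tibble
#' @importFrom stats sd median prcomp hclust cutree dist rnorm rlnorm runif
#'   rbinom plogis qlogis glm binomial coef lm setNames quantile
#' @importFrom utils combn head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Split a DNA string into a character vector of single bases.
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Reverse complement of a DNA string
#'
#' @param x A DNA string over A/C/G/T.
#' @return The reverse complement as a character scalar.
#' @export
#' @examples
#' revcomp("AGAT")
revcomp <- function(x) {
  check_dna(x)
  chartr("ACGT", "TGCA", paste(rev(str_chars(toupper(x))), collapse = ""))
}

# Validate that a string is plain DNA; name the first offending character.
check_dna <- function(x, allow_n = FALSE, what = "sequence") {
  if (length(x) != 1L || !is.character(x) || is.na(x) || nchar(x) == 0L) {
    abort(sprintf("%s must be a non-empty character scalar", what))
  }
  alphabet <- if (allow_n) c(DNA_BASES, "N") else DNA_BASES
  ch <- str_chars(toupper(x))
  bad <- which(!ch %in% alphabet)
  if (length(bad) > 0L) {
    abort(sprintf("invalid character '%s' at position %d of %s",
                  ch[bad[1L]], bad[1L], what))
  }
  invisible(as.vector(toupper(x), "character"))
}

# Minimal period of a string (smallest q dividing nchar such that the string
# is a whole-number repetition of its first q characters).
minimal_period <- function(motif) {
  p <- nchar(motif)
  for (q in seq_len(p - 1L)) {
    if (p %% q == 0L && motif == strrep(substr(motif, 1L, q), p / q)) {
      return(q)
    }
  }
  p
}

is_primitive_motif <- function(motif) minimal_period(motif) == nchar(motif)

# Derive a reproducible per-unit sub-seed from a master seed (kept < 2^31).
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483587)
}

fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE)
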