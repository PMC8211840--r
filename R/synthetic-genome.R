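#' Specify a repeat to plant into a synthetic genome
#'
#' @param chrom Chromosome id.
#' @param start 1-based start position of the run.
#' @param motif Motif (2-6 nt, A/C/G/T, primitive).
#' @param n_repeats Number of tandem copies to plant.
#' @return One-row tibble.
#' @export
planted_repeat <- function(chrom, start, motif, n_repeats) {
  motif <- check_dna(motif, what = "motif")
  if (nchar(motif) < 2 || nchar(motif) > 6) abort("motif length must be 2-6 nt")
  if (!is_primitive_motif(motif)) {
    abort(sprintf("motif '%s' is periodic; specify its shortest period", motif))
  }
  stopifnot(start >= 1, n_repeats >= 1)
  tibble(chrom = chrom, start = as.integer(start), motif = motif,
         n_repeats = as.integer(n_repeats))
}

#' Generate a synthetic genome with planted perfect repeats
#'
#' Background bases are i.i.d. with the requested GC content; each planted
#' run is inserted exactly as specified and made maximal by forcing the bases
#' immediately flanking the run not to extend it by one motif period.
#' Deterministic for a fixed seed.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp (scalar or vector).
#' @param planted Tibble of [planted_repeat()] rows (may be empty/NULL).
#' @param gc GC fraction of the background.
#' @param seed Integer seed.
#' @return A list of class `synthetic_genome`: `sequences` (named character),
#'   `planted` (registry tibble with end coordinates and motif class), `gc`,
#'   `seed`.
#' @export
generate_genome <- function(n_chrom = 2, chrom_length = 10000, planted = NULL,
                            gc = 0.39, seed = 1) {
  stopifnot(n_chrom >= 1, all(chrom_length >= 10), gc > 0, gc < 1)
  lens <- rep_len(as.integer(chrom_length), n_chrom)
  chroms <- paste0("chr", seq_len(n_chrom))
  names(lens) <- chroms
  if (is.null(planted)) {
    planted <- tibble(chrom = character(), start = integer(),
                      motif = character(), n_repeats = integer())
  }
  planted <- mutate(planted,
                    motif_length = nchar(.data$motif),
                    end = .data$start + .data$motif_length * .data$n_repeats - 1L)
  for (i in seq_len(nrow(planted))) {
    sp <- planted[i, ]
    if (!sp$chrom %in% chroms || sp$start < 1 || sp$end > lens[[sp$chrom]]) {
      abort(sprintf("planted spec out of bounds: %s:%d motif %s x%d",
                    sp$chrom, sp$start, sp$motif, sp$n_repeats))
    }
  }
  # reject overlaps, including the one-base maximality margins
  if (nrow(planted) > 1) {
    for (ch in unique(planted$chrom)) {
      p <- planted[planted$chrom == ch, ]
      p <- p[order(p$start), ]
      if (nrow(p) > 1) {
        ov <- which(p$start[-1] - 1L <= p$end[-nrow(p)] + 1L)
        if (length(ov) > 0) {
          abort(sprintf("planted specs overlap on %s at start %d",
                        ch, p$start[ov[1] + 1L]))
        }
      }
    }
  }
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sequences <- withr::with_seed(seed, {
    setNames(lapply(chroms, function(ch) {
      v <- sample(DNA_BASES, lens[[ch]], replace = TRUE, prob = probs)
      p <- planted[planted$chrom == ch, ]
      for (i in seq_len(nrow(p))) {
        mo <- str_chars(p$motif[i])
        run <- rep_len(mo, p$motif_length[i] * p$n_repeats[i])
        v[p$start[i]:p$end[i]] <- run
        # maximality: the base before the run must differ from the motif's
        # last base, the base after from its first
        if (p$start[i] > 1L && v[p$start[i] - 1L] == mo[length(mo)]) {
          v[p$start[i] - 1L] <- setdiff(DNA_BASES, mo[length(mo)])[1]
        }
        if (p$end[i] < lens[[ch]] && v[p$end[i] + 1L] == mo[1]) {
          v[p$end[i] + 1L] <- setdiff(DNA_BASES, mo[1])[1]
        }
      }
      paste(v, collapse = "")
    }), chroms)
  })
  out <- list(sequences = unlist(sequences), planted = planted,
              chrom_lengths = lens, gc = gc, seed = seed)
  class(out) <- "synthetic_genome"
  out
}

#' Write genome sequences to FASTA
#' @param genome A `synthetic_genome` or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- if (inherits(genome, "synthetic_genome")) genome$sequences else genome
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read genome sequences from FASTA
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
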