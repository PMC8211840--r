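#' Scan sequences for perfect microsatellites
#'
#' Finds every maximal perfect (uninterrupted) tandem repeat with a motif of
#' 2-6 nt. A run is reported under its shortest period, so a `(AG)x12` run is
#' a single dinucleotide locus, never a tetranucleotide `(AGAG)x6`.
#' Mononucleotide runs are never reported. `N` (and any ambiguity code) breaks
#' a run; lowercase input is uppercased.
#'
#' Coordinates are 1-based and inclusive on the forward strand of the given
#' sequence. A reported locus spans exactly `n_repeats` full motif copies
#' inside the maximal periodic region; partial copies at the region edges
#' never count towards `n_repeats`, and among the equivalent phase anchors
#' the one whose motif is lexicographically smallest is reported.
#'
#' @param sequences Named character vector of DNA sequences (names are
#'   chromosome/scaffold ids), a single unnamed string, or a
#'   [Biostrings::DNAStringSet].
#' @param min_repeats Named integer vector giving the minimum number of
#'   repeats per motif length ("2" through "6"). The default mirrors a
#'   genome-wide first-pass search: 6 for dinucleotides, 5 for tri- to
#'   hexanucleotides.
#' @return A tibble with columns `chrom`, `start`, `end`, `motif`,
#'   `motif_length`, `n_repeats`, sorted by (chrom, start, motif_length).
#' @export
#' @examples
#' scan_perfect_ssrs(c(chr1 = paste0("CCT", strrep("AGAT", 7), "GGC")))
scan_perfect_ssrs <- function(sequences,
                              min_repeats = c(`2` = 6, `3` = 5, `4` = 5,
                                              `5` = 5, `6` = 5)) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  stopifnot(all(c("2", "3", "4", "5", "6") %in% names(min_repeats)))
  res <- purrr::imap(sequences, function(s, nm) {
    if (nchar(s) == 0L) return(NULL)
    s <- check_dna(s, allow_n = TRUE, what = sprintf("sequence '%s'", nm))
    scan_one_sequence(s, nm, min_repeats)
  })
  out <- bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  motif = character(), motif_length = integer(),
                  n_repeats = integer()))
  }
  arrange(out, .data$chrom, .data$start, .data$motif_length)
}

# Vectorized single-sequence scan: for each period p, self-shifted equality
# runs mark periodic regions; each maximal region yields one locus.
scan_one_sequence <- function(s, chrom, min_repeats) {
  ints <- utf8ToInt(s)
  n_int <- utf8ToInt("N")
  L <- length(ints)
  out <- list()
  for (p in 2:6) {
    min_nr <- as.integer(min_repeats[[as.character(p)]])
    if (L < p * min_nr) next
    eq <- ints[seq_len(L - p)] == ints[(p + 1L):L]
    eq[ints[seq_len(L - p)] == n_int] <- FALSE
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & r$lengths + p >= p * min_nr)
    if (length(keep) == 0L) next
    a <- starts[keep]
    reg_len <- r$lengths[keep] + p
    nr <- reg_len %/% p
    # phase choice within the periodic region: among the anchors that fit
    # the maximal number of full copies, take the lexicographically smallest
    # motif (reports AGAT, not a rotated phase, when a partial copy flanks
    # the run)
    part <- reg_len %% p
    a <- vapply(seq_along(a), function(i) {
      if (part[i] == 0L) return(a[i])
      cand <- a[i] + 0:part[i]
      mo <- substring(s, cand, cand + p - 1L)
      cand[which(mo == min(mo))[1]]
    }, integer(1))
    motif <- substring(s, a, a + p - 1L)
    prim <- vapply(motif, is_primitive_motif, logical(1), USE.NAMES = FALSE)
    ok <- prim & nr >= min_nr
    if (!any(ok)) next
    out[[length(out) + 1L]] <- tibble(
      chrom = chrom,
      start = a[ok],
      end = a[ok] + nr[ok] * p - 1L,
      motif = motif[ok],
      motif_length = p,
      n_repeats = nr[ok]
    )
  }
  bind_rows(out)
}

#' Canonical form of a microsatellite motif
#'
#' Returns the lexicographically smallest string among all rotations of the
#' motif and all rotations of its reverse complement, so that `GATA`, `ATAG`
#' and `ATCT` aggregate into one motif class. Idempotent.
#'
#' @param motif Character vector of motifs, each 2-6 nt, primitive (not itself
#'   a repetition of a shorter motif).
#' @return Character vector of canonical motifs.
#' @export
#' @examples
#' canonical_motif(c("GATA", "ATAG", "ATCT"))
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    m <- check_dna(m, what = "motif")
    p <- nchar(m)
    if (p < 2L || p > 6L) abort("motif length must be 2-6 nt")
    if (!is_primitive_motif(m)) {
      abort(sprintf("motif '%s' is periodic; report it at its shortest period", m))
    }
    rot <- function(x) {
      ch <- str_chars(x)
      vapply(seq_len(p), function(i) {
        paste(ch[c(i:p, seq_len(i - 1L))[seq_len(p)]], collapse = "")
      }, character(1))
    }
    min(c(rot(m), rot(revcomp(m))))
  }, character(1), USE.NAMES = FALSE)
}

#' Summarize the genomic distribution of microsatellite loci
#'
#' @param loci Tibble of loci from [scan_perfect_ssrs()].
#' @param chrom_lengths Named numeric vector of sequence lengths in bp, or a
#'   tibble with columns `chrom` and `length_bp` (optionally `is_chromosome`).
#' @param include_scaffolds If `FALSE` (default) and an `is_chromosome` column
#'   is available, density is computed over flagged chromosomes only.
#' @return A list of tibbles: `per_chromosome` (with `density_per_mb`),
#'   `by_motif_length` (counts and fractions), `by_n_repeats`.
#' @export
summarize_ssr_distribution <- function(loci, chrom_lengths,
                                       include_scaffolds = FALSE) {
  if (!is.data.frame(chrom_lengths)) {
    chrom_lengths <- tibble(chrom = names(chrom_lengths),
                            length_bp = as.numeric(chrom_lengths))
  }
  if (!"is_chromosome" %in% names(chrom_lengths)) {
    chrom_lengths$is_chromosome <- TRUE
  }
  if (!include_scaffolds) {
    chrom_lengths <- filter(chrom_lengths, .data$is_chromosome)
    loci <- filter(loci, .data$chrom %in% chrom_lengths$chrom)
  }
  missing <- setdiff(unique(loci$chrom), chrom_lengths$chrom)
  if (length(missing) > 0L) {
    abort(sprintf("loci reference sequences with unknown length: %s",
                  paste(missing, collapse = ", ")))
  }
  per_chrom <- loci |>
    count(.data$chrom, name = "n_loci") |>
    dplyr::right_join(chrom_lengths, by = "chrom") |>
    mutate(n_loci = dplyr::coalesce(.data$n_loci, 0L),
           density_per_mb = .data$n_loci / (.data$length_bp / 1e6)) |>
    select("chrom", "n_loci", "length_bp", "density_per_mb") |>
    arrange(.data$chrom)
  by_len <- loci |>
    count(.data$motif_length, name = "n") |>
    mutate(fraction = if (sum(.data$n) > 0) .data$n / sum(.data$n) else numeric(0))
  by_nr <- loci |> count(.data$motif_length, .data$n_repeats, name = "n")
  list(per_chromosome = per_chrom, by_motif_length = by_len,
       by_n_repeats = by_nr)
}

#' Candidate-selection criteria for marker development
#'
#' Second-phase selection rules: tetranucleotides with 7 or more repeats,
#' penta-/hexanucleotides with 8 or more, trinucleotides within a 10-15
#' repeat window, and (by default) only loci placed on a named chromosome.
#' Dinucleotides are not carried into the candidate phase.
#'
#' @param min_nr_tetra,min_nr_penta,min_nr_hexa Minimum repeat numbers.
#' @param tri_range Inclusive repeat-number window for trinucleotides.
#' @param require_chromosome Keep only loci with `on_chromosome = TRUE`.
#' @return A `candidate_criteria` list.
#' @export
candidate_criteria <- function(min_nr_tetra = 7, min_nr_penta = 8,
                               min_nr_hexa = 8, tri_range = c(10, 15),
                               require_chromosome = TRUE) {
  stopifnot(min_nr_tetra > 0, min_nr_penta > 0, min_nr_hexa > 0,
            length(tri_range) == 2, tri_range[1] <= tri_range[2])
  structure(list(min_nr_tetra = min_nr_tetra, min_nr_penta = min_nr_penta,
                 min_nr_hexa = min_nr_hexa, tri_range = tri_range,
                 require_chromosome = require_chromosome),
            class = "candidate_criteria")
}

#' Select candidate marker loci
#'
#' Filters mined loci by per-motif-length repeat-number rules and chromosome
#' placement. Stable (input) order is preserved; the operation is idempotent.
#'
#' @param loci Tibble of loci with columns `motif_length`, `n_repeats` and,
#'   when `criteria$require_chromosome` is set, `on_chromosome`.
#' @param criteria A [candidate_criteria()] object.
#' @return The filtered tibble.
#' @export
select_candidates <- function(loci, criteria = candidate_criteria()) {
  stopifnot(inherits(criteria, "candidate_criteria"))
  if (criteria$require_chromosome && !"on_chromosome" %in% names(loci)) {
    abort("loci must carry an 'on_chromosome' column (see flag_chromosomes())")
  }
  keep <- with(criteria, {
    (loci$motif_length == 3 & loci$n_repeats >= tri_range[1] &
       loci$n_repeats <= tri_range[2]) |
      (loci$motif_length == 4 & loci$n_repeats >= min_nr_tetra) |
      (loci$motif_length == 5 & loci$n_repeats >= min_nr_penta) |
      (loci$motif_length == 6 & loci$n_repeats >= min_nr_hexa)
  })
  if (criteria$require_chromosome) keep <- keep & loci$on_chromosome
  loci[keep, , drop = FALSE]
}

#' Flag loci located on named chromosomes
#'
#' @param loci Tibble of loci with a `chrom` column.
#' @param chromosomes Character vector of chromosome names; everything else is
#'   treated as an unplaced scaffold.
#' @return `loci` with an `on_chromosome` logical column.
#' @export
flag_chromosomes <- function(loci, chromosomes) {
  mutate(loci, on_chromosome = .data$chrom %in% chromosomes)
}

#' Uniqueness thresholds for alignment-based locus filtering
#'
#' Uniqueness rules of this kind are normally tuned on a curated training
#' set of loci and the tuned values rarely published; these defaults are
#' explicit, documented stand-ins.
#'
#' @param sig_evalue E-value below which a hit counts as significant.
#' @param high_cover Query-cover fraction at or above which a hit counts as
#'   high-cover.
#' @param max_significant_hits,max_high_cover_hits Maximum allowed counts
#'   (the self-hit included).
#' @param min_best_hit_gap Minimum bitscore gap between the best and
#'   second-best hit.
#' @return A `uniqueness_thresholds` list.
#' @export
uniqueness_thresholds <- function(sig_evalue = 1e-10, high_cover = 0.80,
                                  max_significant_hits = 1,
                                  max_high_cover_hits = 1,
                                  min_best_hit_gap = 10) {
  stopifnot(sig_evalue > 0, high_cover > 0, high_cover <= 1,
            max_significant_hits >= 0, max_high_cover_hits >= 0,
            min_best_hit_gap >= 0)
  structure(list(sig_evalue = sig_evalue, high_cover = high_cover,
                 max_significant_hits = max_significant_hits,
                 max_high_cover_hits = max_high_cover_hits,
                 min_best_hit_gap = min_best_hit_gap),
            class = "uniqueness_thresholds")
}

#' Filter candidate loci by genome-wide uniqueness of their flanking sequence
#'
#' Consumes 12-column tabular alignment hits (BLAST outfmt-6 dialect, one
#' query per candidate) and keeps a candidate iff (i) the number of
#' significant hits is within bounds, (ii) the number of high-query-cover hits
#' is within bounds, and (iii) the best-hit bitscore exceeds the second best
#' by at least the configured gap. Every rejection carries the violated
#' rule(s). Kept and rejected sets partition the input.
#'
#' @param candidates Tibble with a `locus_id` column matching `qseqid` in
#'   `hits`.
#' @param hits Tibble of tabular hits (see [read_blast_hits()]); an optional
#'   `qcovs` column (percent) supplies query cover, otherwise it is computed
#'   from `qstart`/`qend` and `query_lengths`.
#' @param thresholds A [uniqueness_thresholds()] object.
#' @param query_lengths Named vector of query lengths in bp (needed only when
#'   `hits` lacks `qcovs`).
#' @return A list with tibbles `kept` and `rejected` (the latter with a
#'   `reason` column).
#' @export
uniqueness_filter <- function(candidates, hits,
                              thresholds = uniqueness_thresholds(),
                              query_lengths = NULL) {
  stopifnot(inherits(thresholds, "uniqueness_thresholds"),
            "locus_id" %in% names(candidates))
  if ("qcovs" %in% names(hits)) {
    hits$cover <- hits$qcovs / 100
  } else {
    if (is.null(query_lengths)) {
      abort("hits lack a 'qcovs' column; supply query_lengths")
    }
    hits$cover <- (abs(hits$qend - hits$qstart) + 1) /
      query_lengths[hits$qseqid]
  }
  reasons <- purrr::map_chr(candidates$locus_id, function(id) {
    h <- hits[hits$qseqid == id, , drop = FALSE]
    self <- any(h$pident >= 99.9 & h$cover >= 0.999)
    if (!self) {
      abort(sprintf(
        "candidate '%s' has no self-hit: malformed alignment input", id))
    }
    viol <- character()
    if (sum(h$evalue < thresholds$sig_evalue) > thresholds$max_significant_hits) {
      viol <- c(viol, "significant-hit count")
    }
    if (sum(h$cover >= thresholds$high_cover) > thresholds$max_high_cover_hits) {
      viol <- c(viol, "high-cover-hit count")
    }
    bs <- sort(h$bitscore, decreasing = TRUE)
    if (length(bs) >= 2 && (bs[1] - bs[2]) < thresholds$min_best_hit_gap) {
      viol <- c(viol, "best-hit gap")
    }
    paste(viol, collapse = "; ")
  })
  list(kept = candidates[reasons == "", , drop = FALSE],
       rejected = mutate(candidates[reasons != "", , drop = FALSE],
                         reason = reasons[reasons != ""]))
}

#' Pairwise physical distances between markers, with linkage flags
#'
#' Marker pairs on the same chromosome closer than `linkage_threshold_bp`
#' (default 50 Mb) are flagged as possibly linked; pairs on different
#' chromosomes are independent.
#'
#' @param markers Tibble with columns `marker`, `chrom`, `position_bp`.
#' @param linkage_threshold_bp Distance below which weak-to-moderate linkage
#'   is suspected.
#' @return Tibble of all unordered pairs with `distance_bp` (NA across
#'   chromosomes) and a `linkage` flag.
#' @export
interlocus_distances <- function(markers, linkage_threshold_bp = 50e6) {
  stopifnot(all(c("marker", "chrom", "position_bp") %in% names(markers)),
            nrow(markers) >= 2)
  idx <- combn(nrow(markers), 2)
  tibble(
    marker_1 = markers$marker[idx[1, ]],
    marker_2 = markers$marker[idx[2, ]],
    chrom_1 = markers$chrom[idx[1, ]],
    chrom_2 = markers$chrom[idx[2, ]],
    distance_bp = ifelse(
      markers$chrom[idx[1, ]] == markers$chrom[idx[2, ]],
      abs(markers$position_bp[idx[1, ]] - markers$position_bp[idx[2, ]]),
      NA_real_)
  ) |>
    mutate(linkage = if_else(!is.na(.data$distance_bp) &
                               .data$distance_bp < linkage_threshold_bp,
                             "possible linkage", "independent"))
}

#' Primer cross-dimer score
#'
#' A simplified ungapped primer-dimer scan: the score is the maximum, over
#' all offsets of `primer_a` against the reverse complement of `primer_b`, of
#' the length of the longest contiguous Watson-Crick matched window.
#' Symmetric in its arguments; a primer against its own reverse complement
#' scores its full length. Pairs are conventionally accepted into one
#' multiplex when the score is 5 or lower.
#'
#' @param primer_a,primer_b Primer sequences (A/C/G/T, length >= 8).
#' @return Integer score.
#' @export
#' @examples
#' dimer_score("ACGTACGTACGT", revcomp("ACGTACGTACGT"))
dimer_score <- function(primer_a, primer_b) {
  a <- check_dna(primer_a, what = "primer_a")
  b <- check_dna(primer_b, what = "primer_b")
  if (nchar(a) < 8 || nchar(b) < 8) abort("primers must be at least 8 nt")
  x <- utf8ToInt(a)
  y <- utf8ToInt(revcomp(b))
  na <- length(x); nb <- length(y)
  best <- 0L
  for (off in (-(nb - 1L)):(na - 1L)) {
    i <- max(1L, off + 1L):min(na, off + nb)
    j <- i - off
    m <- x[i] == y[j]
    if (any(m)) {
      r <- rle(m)
      best <- max(best, max(r$lengths[r$values]))
    }
  }
  as.integer(best)
}

#' Read 12-column tabular alignment hits
#'
#' Parses the standard 12-column tabular alignment format (qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore),
#' with an optional 13th `qcovs` column.
#'
#' @param path Path to a tab-separated hits file without header.
#' @return Tibble of hits.
#' @export
read_blast_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  if (ncol(x) == 13) cols <- c(cols, "qcovs")
  if (ncol(x) < 12) abort("expected at least 12 tab-separated columns")
  setNames(x[, seq_along(cols)], cols)
}
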