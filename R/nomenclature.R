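#' Parse a repeat-structure string
#'
#' Repeat structures are serialized as in `"(AAGA)7AG(AAGA)1"`: parenthesized
#' motif blocks with a repeat count, interleaved with literal interruption
#' strings. The total repeat number `n` is the sum of block counts; the
#' intermediate-base count `x` is the total length of interruption strings
#' inside the repeat region.
#'
#' @param x A structure string.
#' @return A `repeat_structure` tibble with columns `kind`
#'   ("repeat"/"interruption"), `motif`, `count`, `seq`.
#' @export
#' @examples
#' parse_structure("(AAGA)7AG(AAGA)1")
parse_structure <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nchar(x) > 0L)
  tokens <- stringr::str_match_all(x, "\\(([ACGT]+)\\)(\\d+)|([ACGT]+)")[[1]]
  consumed <- paste(tokens[, 1], collapse = "")
  if (consumed != x) abort(sprintf("cannot parse structure '%s'", x))
  blocks <- purrr::pmap(list(tokens[, 2], tokens[, 3], tokens[, 4]),
    function(motif, count, inter) {
      if (!is.na(motif)) {
        tibble(kind = "repeat", motif = motif, count = as.integer(count),
               seq = NA_character_)
      } else {
        tibble(kind = "interruption", motif = NA_character_, count = NA_integer_,
               seq = inter)
      }
    })
  new_repeat_structure(bind_rows(blocks))
}

new_repeat_structure <- function(blocks) {
  stopifnot(all(c("kind", "motif", "count", "seq") %in% names(blocks)),
            nrow(blocks) >= 1)
  class(blocks) <- c("repeat_structure", class(tibble()))
  blocks
}

#' Serialize a repeat structure
#' @param structure A `repeat_structure` tibble.
#' @return The canonical structure string, e.g. `"(AAGA)7AG(AAGA)1"`.
#' @export
format_structure <- function(structure) {
  paste(ifelse(structure$kind == "repeat",
               sprintf("(%s)%d", structure$motif, structure$count),
               structure$seq),
        collapse = "")
}

#' Expand a repeat structure to its DNA sequence
#' @param structure A `repeat_structure` tibble.
#' @return Character scalar.
#' @export
expand_structure <- function(structure) {
  paste(ifelse(structure$kind == "repeat",
               strrep(structure$motif, structure$count),
               structure$seq),
        collapse = "")
}

#' Total repeat number and intermediate bases of a structure
#' @param structure A `repeat_structure` tibble.
#' @return For `total_repeats()`, the integer repeat number n; for
#'   `extra_bases()`, the number x of interruption bases inside the repeat
#'   region.
#' @export
total_repeats <- function(structure) {
  sum(structure$count[structure$kind == "repeat"])
}

#' @rdname total_repeats
#' @export
extra_bases <- function(structure) {
  s <- structure$seq[structure$kind == "interruption"]
  if (length(s) == 0L) 0L else sum(nchar(s))
}

#' Construct a flanking-region variant descriptor
#'
#' Positions are anchored at the repeat region and count away from it: U1 is
#' the base immediately upstream (5') of the repeat region, D1 the base
#' immediately downstream (3'). A multi-base variant's `position` is its
#' repeat-proximal end, and `seq` is always given in genomic (5'->3')
#' orientation, so `D42TCdel` deletes the TC occupying downstream positions
#' 42-43 and `U11TGTTAAAATGdel` deletes the 10 bases occupying upstream
#' positions 11-20.
#'
#' @param side "U" (upstream) or "D" (downstream).
#' @param position 1-based offset from the repeat-region boundary.
#' @param kind "del", "ins" or "sub".
#' @param seq The deleted (del), inserted (ins) or observed replacement (sub)
#'   sequence.
#' @return A one-row `flank_variant` tibble.
#' @export
flank_variant <- function(side, position, kind, seq) {
  stopifnot(side %in% c("U", "D"), position >= 1,
            kind %in% c("del", "ins", "sub"))
  check_dna(seq, what = "variant sequence")
  tibble(side = side, position = as.integer(position), kind = kind,
         seq = toupper(seq), len = nchar(seq))
}

empty_variants <- function() {
  tibble(side = character(), position = integer(), kind = character(),
         seq = character(), len = integer())
}

#' Define a marker reference for allele decomposition and naming
#'
#' @param marker Marker id.
#' @param upstream,downstream Flanking sequences inside the amplicon (primer
#'   to repeat region), non-empty.
#' @param structure Reference repeat structure (string or
#'   `repeat_structure`).
#' @param pigtail Length in bp of the pig-tail sequence on the reverse primer
#'   (0 or 7). Added to the physical fragment size, never part of the
#'   sequenced insert.
#' @return A `marker_reference` object.
#' @export
marker_reference <- function(marker, upstream, structure, downstream,
                             pigtail = 7L) {
  if (is.character(structure)) structure <- parse_structure(structure)
  up <- check_dna(upstream, what = "upstream flank")
  down <- check_dna(downstream, what = "downstream flank")
  stopifnot(pigtail %in% c(0L, 7L), nrow(structure) >= 1)
  obj <- list(marker = marker, upstream = up, structure = structure,
              downstream = down, pigtail = as.integer(pigtail))
  obj$ref_length <- nchar(up) + nchar(expand_structure(structure)) +
    nchar(down) + obj$pigtail
  structure(obj, class = "marker_reference")
}

#' @export
print.marker_reference <- function(x, ...) {
  cat(sprintf("<marker_reference> %s: %s, flanks %d+%d bp, pigtail %d, ref %d bp\n",
              x$marker, format_structure(x$structure), nchar(x$upstream),
              nchar(x$downstream), x$pigtail, x$ref_length))
  invisible(x)
}

# Map a U/D-side position to an index in the flank string.
flank_index <- function(flank_len, side, position) {
  if (side == "D") position else flank_len - position + 1L
}

# Apply the variants of one side to a flank sequence. Variants are applied
# right-to-left in string coordinates so earlier edits do not shift later
# ones.
apply_flank_variants <- function(flank, variants, side) {
  v <- variants[variants$side == side, , drop = FALSE]
  if (nrow(v) == 0L) return(flank)
  L <- nchar(flank)
  v$idx_start <- vapply(seq_len(nrow(v)), function(i) {
    if (v$kind[i] == "ins") {
      if (side == "D") v$position[i] else L - v$position[i] + 1L
    } else {
      span_far <- v$position[i] + v$len[i] - 1L
      if (side == "D") v$position[i] else L - span_far + 1L
    }
  }, integer(1))
  if (any(v$idx_start < 1L |
          (v$kind != "ins" & v$idx_start + v$len - 1L > L) |
          (v$kind == "ins" & v$idx_start > L + 1L))) {
    abort(sprintf("variant position outside %s flank (length %d)",
                  if (side == "U") "upstream" else "downstream", L))
  }
  v <- v[order(v$idx_start, decreasing = TRUE), , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    a <- v$idx_start[i]
    if (v$kind[i] == "ins") {
      flank <- paste0(substr(flank, 1L, a - 1L), v$seq[i],
                      substr(flank, a, nchar(flank)))
    } else {
      b <- a + v$len[i] - 1L
      if (v$kind[i] == "del" &&
          substr(flank, a, b) != v$seq[i]) {
        abort(sprintf("deletion sequence '%s' does not match reference flank",
                      v$seq[i]))
      }
      repl <- if (v$kind[i] == "del") "" else v$seq[i]
      flank <- paste0(substr(flank, 1L, a - 1L), repl,
                      substr(flank, b + 1L, nchar(flank)))
    }
  }
  flank
}

#' Build an allele amplicon sequence from a reference
#'
#' Constructs the sequenced insert: upstream flank (with applied U variants) +
#' expanded repeat structure + downstream flank (with applied D variants).
#' The pig tail contributes to fragment size arithmetic but is not part of
#' the returned sequence.
#'
#' @param reference A [marker_reference()].
#' @param structure Repeat structure of the allele (string or
#'   `repeat_structure`); defaults to the reference structure.
#' @param variants A tibble of [flank_variant()] rows, or `NULL`.
#' @return Character scalar with attribute `fragment_size` (sequence length +
#'   pigtail).
#' @export
#' @examples
#' ref <- marker_reference("M1", "ACCTG", "(AGA)3", "TTGCA", pigtail = 0)
#' simulate_allele_sequence(ref)
simulate_allele_sequence <- function(reference, structure = NULL,
                                     variants = NULL) {
  stopifnot(inherits(reference, "marker_reference"))
  if (is.null(structure)) structure <- reference$structure
  if (is.character(structure)) structure <- parse_structure(structure)
  if (is.null(variants)) variants <- empty_variants()
  up <- apply_flank_variants(reference$upstream, variants, "U")
  down <- apply_flank_variants(reference$downstream, variants, "D")
  amp <- paste0(up, expand_structure(structure), down)
  attr(amp, "fragment_size") <- nchar(amp) + reference$pigtail
  amp
}

# Maximal tandem runs of `motif` within `s`: tibble(start, end, count).
motif_runs <- function(s, motif) {
  p <- nchar(motif)
  L <- nchar(s)
  if (L < p) return(tibble(start = integer(), end = integer(),
                           count = integer(), motif = character()))
  occ <- integer()
  i <- 1L
  hits <- gregexpr(motif, s, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(tibble(start = integer(), end = integer(),
                                    count = integer(), motif = character()))
  hits <- as.integer(hits)
  runs <- list()
  k <- 1L
  while (k <= length(hits)) {
    start <- hits[k]
    cnt <- 1L
    nxt <- start + p
    while (TRUE) {
      if (substr(s, nxt, nxt + p - 1L) == motif && nxt + p - 1L <= L) {
        cnt <- cnt + 1L
        nxt <- nxt + p
      } else break
    }
    runs[[length(runs) + 1L]] <-
      tibble(start = start, end = nxt - 1L, count = cnt, motif = motif)
    # skip occurrences consumed by this run
    k <- k + 1L
    while (k <= length(hits) && hits[k] < nxt) k <- k + 1L
  }
  bind_rows(runs)
}

#' Decompose an allele amplicon against its marker reference
#'
#' Locates the repeat region as the maximal segment tiled by the reference's
#' motifs with minimal interruptions (chains of motif runs separated by gaps
#' of at most `max_gap` bases), then recovers flanking-region variants by
#' global alignment of the observed flanks against the reference flanks.
#' Among co-optimal repeat-region chains the decomposition prefers (i) more
#' total repeats, (ii) fewer interruptions, (iii) the longest uninterrupted
#' leading run, (iv) the leftmost start; a tie remaining after all four rules
#' is reported as an ambiguity error listing the co-optimal structures.
#'
#' @param amplicon The allele sequence (insert only, no pig tail).
#' @param reference A [marker_reference()].
#' @param max_gap Longest interruption (bp) allowed inside the repeat region.
#' @return A list of class `allele_decomposition` with elements `structure`
#'   (a `repeat_structure`), `variants` (a `flank_variant` tibble) and
#'   `reference`.
#' @export
decompose_amplicon <- function(amplicon, reference, max_gap = 6L) {
  stopifnot(inherits(reference, "marker_reference"))
  amp <- check_dna(amplicon, what = "amplicon")
  motifs <- unique(reference$structure$motif[reference$structure$kind == "repeat"])
  runs <- bind_rows(lapply(motifs, function(m) motif_runs(amp, m)))
  if (nrow(runs) == 0L) {
    abort("unalignable amplicon: no reference motif found")
  }
  runs <- arrange(runs, .data$start)
  # drop runs nested inside another run
  keep <- rep(TRUE, nrow(runs))
  for (i in seq_len(nrow(runs))) {
    if (any(runs$start <= runs$start[i] & runs$end >= runs$end[i] &
            seq_len(nrow(runs)) != i & keep)) keep[i] <- FALSE
  }
  runs <- runs[keep, , drop = FALSE]
  # chain runs separated by gaps <= max_gap
  gap_before <- c(Inf, runs$start[-1] - runs$end[-nrow(runs)] - 1L)
  chain_id <- cumsum(gap_before > max_gap)
  chains <- split(seq_len(nrow(runs)), chain_id)
  score <- function(ix) {
    ch <- runs[ix, , drop = FALSE]
    c(total = sum(ch$count),
      n_inter = length(ix) - 1L,
      lead = ch$count[1],
      start = ch$start[1])
  }
  sc <- t(vapply(chains, score, numeric(4)))
  ord <- order(-sc[, "total"], sc[, "n_inter"], -sc[, "lead"], sc[, "start"])
  if (length(ord) > 1L) {
    a <- sc[ord[1], ]; b <- sc[ord[2], ]
    if (all(a == b)) {
      abort(sprintf(
        "ambiguous decomposition: co-optimal repeat regions at %d and %d",
        a[["start"]], b[["start"]]))
    }
  }
  best <- runs[chains[[ord[1]]], , drop = FALSE]
  region_start <- best$start[1]
  region_end <- best$end[nrow(best)]
  blocks <- list()
  for (i in seq_len(nrow(best))) {
    if (i > 1L) {
      gap <- substr(amp, best$end[i - 1L] + 1L, best$start[i] - 1L)
      if (nchar(gap) > 0L) {
        blocks[[length(blocks) + 1L]] <-
          tibble(kind = "interruption", motif = NA_character_,
                 count = NA_integer_, seq = gap)
      }
    }
    blocks[[length(blocks) + 1L]] <-
      tibble(kind = "repeat", motif = best$motif[i], count = best$count[i],
             seq = NA_character_)
  }
  structure_obs <- new_repeat_structure(bind_rows(blocks))
  obs_up <- substr(amp, 1L, region_start - 1L)
  obs_down <- substr(amp, region_end + 1L, nchar(amp))
  if (nchar(obs_up) == 0L && nchar(reference$upstream) > 0L) {
    abort("unalignable amplicon: upstream flank anchor missing")
  }
  if (nchar(obs_down) == 0L && nchar(reference$downstream) > 0L) {
    abort("unalignable amplicon: downstream flank anchor missing")
  }
  variants <- bind_rows(
    diff_flank(reference$upstream, obs_up, "U"),
    diff_flank(reference$downstream, obs_down, "D"))
  out <- list(structure = structure_obs, variants = variants,
              reference = reference, amplicon = amp)
  class(out) <- "allele_decomposition"
  out
}

# Variant calling on one flank by global pairwise alignment; returns a
# flank_variant tibble in U/D coordinates.
diff_flank <- function(ref, obs, side) {
  ref <- as.vector(ref, "character")
  obs <- as.vector(obs, "character")
  if (identical(ref, obs)) return(empty_variants())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ref), Biostrings::DNAString(obs),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1.5, baseOnly = TRUE),
    gapOpening = 4, gapExtension = 0.5)
  pa <- str_chars(as.character(Biostrings::alignedPattern(aln)))
  sa <- str_chars(as.character(Biostrings::alignedSubject(aln)))
  L <- nchar(ref)
  events <- list()
  i <- 1L
  ref_pos <- 0L   # reference coordinate of the last consumed ref base
  while (i <= length(pa)) {
    if (pa[i] != "-" && sa[i] != "-" && pa[i] == sa[i]) {
      ref_pos <- ref_pos + 1L
      i <- i + 1L
    } else if (sa[i] == "-") {            # deletion in observed flank
      j <- i
      while (j <= length(pa) && sa[j] == "-") j <- j + 1L
      seq <- paste(pa[i:(j - 1L)], collapse = "")
      events[[length(events) + 1L]] <-
        list(kind = "del", ref_from = ref_pos + 1L,
             ref_to = ref_pos + (j - i), seq = seq)
      ref_pos <- ref_pos + (j - i)
      i <- j
    } else if (pa[i] == "-") {            # insertion in observed flank
      j <- i
      while (j <= length(pa) && pa[j] == "-") j <- j + 1L
      seq <- paste(sa[i:(j - 1L)], collapse = "")
      events[[length(events) + 1L]] <-
        list(kind = "ins", ref_from = ref_pos, ref_to = ref_pos, seq = seq)
      i <- j
    } else {                              # substitution run
      j <- i
      while (j <= length(pa) && pa[j] != "-" && sa[j] != "-" &&
             pa[j] != sa[j]) j <- j + 1L
      seq <- paste(sa[i:(j - 1L)], collapse = "")
      events[[length(events) + 1L]] <-
        list(kind = "sub", ref_from = ref_pos + 1L,
             ref_to = ref_pos + (j - i), seq = seq)
      ref_pos <- ref_pos + (j - i)
      i <- j
    }
  }
  rows <- purrr::map(events, function(e) {
    pos <- if (side == "D") {
      if (e$kind == "ins") e$ref_from + 1L else e$ref_from
    } else {
      if (e$kind == "ins") L - e$ref_from else L - e$ref_to + 1L
    }
    flank_variant(side, pos, e$kind, e$seq)
  })
  if (length(rows) == 0L) return(empty_variants())
  bind_rows(rows)
}

# Format one descriptor, e.g. "D42TCdel" or shorthand "U11-10del".
format_descriptor <- function(side, position, kind, seq, len, short = FALSE) {
  body <- if (short || is.na(seq)) paste0("-", len) else seq
  paste0(side, position, body, kind)
}

order_descriptors <- function(v) {
  v[order(match(v$side, c("D", "U")), v$position), , drop = FALSE]
}

#' Name a sequenced allele
#'
#' Under the repeat-structure-based convention the integer part is the total
#' repeat number n and the suffix is the count x of intermediate bases inside
#' the repeat region; flanking-region indels appear only as descriptors and
#' never change n.x. Under the size-based alternative the designation is
#' derived from the total fragment-length offset, so flanking indels shift
#' the number; when the subtraction exceeds the repeat region itself the
#' convention breaks down and a negative-numbering error marker is returned.
#'
#' @param decomposition An [decompose_amplicon()] result, or a
#'   `repeat_structure` (then `variants`/`reference` must be given).
#' @param variants,reference Used when `decomposition` is a bare structure.
#' @param convention "repeat_based" (default) or "size_based".
#' @return An `allele_name` object with fields `n`, `x`, `designation`
#'   (string), `numeric` (n.x as a number when representable), `descriptors`,
#'   `full` (designation plus descriptors) and `negative_numbering`.
#' @export
name_allele <- function(decomposition, variants = NULL, reference = NULL,
                        convention = c("repeat_based", "size_based")) {
  convention <- match.arg(convention)
  if (inherits(decomposition, "allele_decomposition")) {
    structure_ <- decomposition$structure
    variants <- decomposition$variants
    reference <- decomposition$reference
  } else {
    structure_ <- decomposition
    if (is.character(structure_)) structure_ <- parse_structure(structure_)
    if (is.null(variants)) variants <- empty_variants()
  }
  n <- total_repeats(structure_)
  x <- extra_bases(structure_)
  neg <- FALSE
  if (convention == "size_based") {
    k <- nchar(structure_$motif[structure_$kind == "repeat"][1])
    indel_delta <- sum(ifelse(variants$kind == "del", -variants$len,
                              ifelse(variants$kind == "ins", variants$len, 0L)))
    L_eq <- n * k + x + indel_delta
    if (L_eq < 0) {
      neg <- TRUE
      n <- NA_integer_; x <- NA_integer_
    } else {
      n <- L_eq %/% k
      x <- L_eq %% k
    }
  }
  desc <- order_descriptors(variants)
  designation <- if (neg) NA_character_
    else if (x > 0) paste0(n, ".", x) else as.character(n)
  full <- designation
  if (!neg && nrow(desc) > 0L) {
    full <- paste0(designation, " (",
                   paste(purrr::pmap_chr(
                     list(desc$side, desc$position, desc$kind, desc$seq, desc$len),
                     function(s, p, k, q, l) format_descriptor(s, p, k, q, l)),
                     collapse = "; "), ")")
  }
  out <- list(n = n, x = x, designation = designation,
              numeric = if (neg || is.na(n)) NA_real_
                        else if (x < 10) n + x / 10 else NA_real_,
              descriptors = desc, full = full, convention = convention,
              negative_numbering = neg)
  class(out) <- "allele_name"
  if (neg) {
    out$error <- "negative numbering: size-based convention cannot name this allele"
  }
  out
}

#' @export
print.allele_name <- function(x, ...) {
  if (x$negative_numbering) {
    cat("<allele_name>", x$error, "\n")
  } else {
    cat("<allele_name>", x$full, sprintf("[%s]\n", x$convention))
  }
  invisible(x)
}

#' Shorthand form of an allele name
#'
#' Rewrites every descriptor whose sequence is longer than `max_seq_len` as
#' side + position + "-" + length + kind (e.g. `U11TGTTAAAATGdel` becomes
#' `U11-10del`); shorter descriptors are kept verbatim. Idempotent, and
#' invertible given the marker reference.
#'
#' @param name An `allele_name`.
#' @param max_seq_len Longest descriptor sequence kept verbatim (default 5).
#' @return The `allele_name` with shortened descriptors and an updated `full`
#'   string.
#' @export
allele_shorthand <- function(name, max_seq_len = 5L) {
  stopifnot(inherits(name, "allele_name"))
  d <- name$descriptors
  if (nrow(d) > 0L) {
    shorten <- !is.na(d$seq) & d$len > max_seq_len
    d$seq[shorten] <- NA_character_
    name$descriptors <- d
    if (nrow(d) > 0L) {
      name$full <- paste0(
        name$designation,
        if (nrow(d) > 0L) paste0(" (", paste(purrr::pmap_chr(
          list(d$side, d$position, d$kind, d$seq, d$len),
          function(s, p, k, q, l) format_descriptor(s, p, k, q, l)),
          collapse = "; "), ")") else "")
    }
  }
  name
}

#' Expand shorthand deletion descriptors back to full form
#'
#' Shorthand is invertible for deletions given the marker reference: the
#' deleted bases are read back from the reference flank at the descriptor's
#' position. Insertion/substitution shorthand cannot be expanded (the lost
#' sequence is not in the reference) and raises an error.
#'
#' @param name An `allele_name` with (possibly) shorthand descriptors.
#' @param reference The [marker_reference()] the allele was named against.
#' @return The `allele_name` with full descriptors restored.
#' @export
expand_shorthand <- function(name, reference) {
  stopifnot(inherits(name, "allele_name"),
            inherits(reference, "marker_reference"))
  d <- name$descriptors
  for (i in seq_len(nrow(d))) {
    if (!is.na(d$seq[i])) next
    if (d$kind[i] != "del") {
      abort("only deletion shorthand is invertible from the reference")
    }
    flank <- if (d$side[i] == "U") reference$upstream else reference$downstream
    L <- nchar(flank)
    a <- if (d$side[i] == "D") d$position[i] else L - (d$position[i] + d$len[i] - 1L) + 1L
    d$seq[i] <- substr(flank, a, a + d$len[i] - 1L)
  }
  name$descriptors <- d
  name$full <- paste0(
    name$designation,
    if (nrow(d) > 0L) paste0(" (", paste(purrr::pmap_chr(
      list(d$side, d$position, d$kind, d$seq, d$len),
      function(s, p, k, q, l) format_descriptor(s, p, k, q, l)),
      collapse = "; "), ")") else "")
  name
}

#' Deterministic short identifier (SID) labels for allele sequences
#'
#' Derives an uppercase letter code from a SHA-1 digest of the uppercased
#' sequence, so identical sequences always receive the same label and
#' isoalleles (same length, different sequence) receive distinct ones.
#' Labels are assigned over the inventory in lexicographic sequence order;
#' when a digest window would repeat another label's three-letter prefix,
#' the next window of the same digest is used, so that the first three
#' letters alone identify every allele in the labelled set (mirroring
#' routine-use shorthand). Exhausting the digest raises an error demanding a
#' longer label. The assignment is deterministic for a fixed inventory (and
#' registry); labels recorded in a registry are honoured unchanged.
#'
#' @param sequences Character vector of allele sequences (names, if present,
#'   are carried through as ids).
#' @param n_letters Label length (default 4).
#' @param registry Optional tibble from a previous call, whose labels are
#'   honoured and whose prefixes stay reserved.
#' @return Tibble with `id`, `sequence`, `sid`, `prefix3` and attribute
#'   `prefix3_unique` (always `TRUE` unless a registry introduced clashes).
#' @export
sid_label <- function(sequences, n_letters = 4L, registry = NULL) {
  stopifnot(length(sequences) >= 1, n_letters >= 3)
  ids <- names(sequences) %||% paste0("allele", seq_along(sequences))
  seqs <- toupper(unname(sequences))
  known <- character()   # sequence -> sid
  if (!is.null(registry)) {
    known <- setNames(registry$sid, registry$sequence)
  }
  used_prefix <- unique(substr(known, 1L, 3L))
  uniq <- sort(setdiff(unique(seqs), names(known)))
  for (s in uniq) {
    raw <- as.integer(digest::digest(s, algo = "sha1", serialize = FALSE,
                                     raw = TRUE))
    lab <- NA_character_
    for (j in 0:(length(raw) - n_letters)) {
      cand <- paste(LETTERS[(raw[j + seq_len(n_letters)] %% 26L) + 1L],
                    collapse = "")
      if (!substr(cand, 1L, 3L) %in% used_prefix) {
        lab <- cand
        break
      }
    }
    if (is.na(lab)) {
      abort(sprintf(
        "SID digest exhausted at label length %d; increase n_letters",
        n_letters))
    }
    known[[s]] <- lab
    used_prefix <- c(used_prefix, substr(lab, 1L, 3L))
  }
  out <- tibble(id = ids, sequence = seqs, sid = unname(known[seqs]),
                prefix3 = substr(unname(known[seqs]), 1L, 3L))
  pre <- unique(tibble(sequence = c(names(known)),
                       prefix3 = substr(unname(known), 1L, 3L)))
  attr(out, "prefix3_unique") <- !anyDuplicated(pre$prefix3)
  out
}

#' Diagnose null-allele causes at primer binding sites
#'
#' Aligns each primer against an extended amplicon sequence (spanning both
#' priming sites) and reports substitutions by their offset from the primer's
#' 3' end, plus any indel overlapping the site. Mismatches within the
#' 3'-terminal region (default last 5 bases) are classified high severity --
#' the classic cause of a null allele -- and everything else moderate.
#'
#' @param extended The extended reference-strand sequence covering both
#'   primer sites.
#' @param primer_f,primer_r Forward and reverse primer sequences (the reverse
#'   primer as synthesized, i.e. reverse-complement of the top strand).
#' @param terminal_window 3'-end window treated as high severity.
#' @return Tibble with `primer`, `kind` (sub/ins/del), `offset_3prime`,
#'   `ref`, `obs`, `length`, `severity`. Zero rows for perfect matches.
#' @export
diagnose_null <- function(extended, primer_f, primer_r, terminal_window = 5L) {
  ext <- check_dna(extended, what = "extended sequence")
  f <- check_dna(primer_f, what = "primer_f")
  r <- check_dna(primer_r, what = "primer_r")
  site_report <- function(primer_top, label, offset_map) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(primer_top), Biostrings::DNAString(ext),
      type = "global-local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3, baseOnly = TRUE),
      gapOpening = 5, gapExtension = 0.5)
    pa <- str_chars(as.character(Biostrings::alignedPattern(aln)))
    sa <- str_chars(as.character(Biostrings::alignedSubject(aln)))
    p_pos <- 0L
    rows <- list()
    for (i in seq_along(pa)) {
      if (pa[i] != "-") p_pos <- p_pos + 1L
      if (pa[i] == "-") {
        rows[[length(rows) + 1L]] <- tibble(
          primer = label, kind = "ins", offset_3prime = offset_map(p_pos),
          ref = NA_character_, obs = sa[i], length = 1L)
      } else if (sa[i] == "-") {
        rows[[length(rows) + 1L]] <- tibble(
          primer = label, kind = "del", offset_3prime = offset_map(p_pos),
          ref = pa[i], obs = NA_character_, length = 1L)
      } else if (pa[i] != sa[i]) {
        rows[[length(rows) + 1L]] <- tibble(
          primer = label, kind = "sub", offset_3prime = offset_map(p_pos),
          ref = pa[i], obs = sa[i], length = 1L)
      }
    }
    bind_rows(rows)
  }
  lf <- nchar(f)
  rep_f <- site_report(f, "F", function(p) lf - p + 1L)
  # reverse primer anneals as its reverse complement on the top strand; its
  # 3' end maps to the leftmost base of that representation
  rep_r <- site_report(revcomp(r), "R", function(p) p)
  out <- bind_rows(rep_f, rep_r)
  if (nrow(out) == 0L) {
    return(tibble(primer = character(), kind = character(),
                  offset_3prime = integer(), ref = character(),
                  obs = character(), length = integer(),
                  severity = character()))
  }
  # merge adjacent single-base indel rows of the same event
  out <- out |>
    arrange(.data$primer, .data$kind, .data$offset_3prime) |>
    group_by(.data$primer, .data$kind) |>
    mutate(gap = c(0, diff(.data$offset_3prime)),
           event = cumsum(.data$gap != 1 & .data$gap != -1)) |>
    group_by(.data$primer, .data$kind, .data$event) |>
    summarise(offset_3prime = min(.data$offset_3prime),
              ref = paste(stats::na.omit(.data$ref), collapse = ""),
              obs = paste(stats::na.omit(.data$obs), collapse = ""),
              length = n(), .groups = "drop") |>
    select(-"event") |>
    mutate(severity = if_else(.data$kind != "sub", "indel",
                              if_else(.data$offset_3prime <= terminal_window,
                                      "high", "moderate")))
  out
}
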