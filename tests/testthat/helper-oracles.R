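# Independent brute-force oracles and small fixture builders shared by the
# test files. The oracles deliberately use naive per-position algorithms,
# distinct from the package's vectorized implementations.

random_dna <- function(n, prob = c(0.3, 0.2, 0.2, 0.3)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# Naive perfect-SSR scanner: walks every position per period, extends the
# periodic region character by character, picks the lexicographically
# smallest phase anchor and checks primitivity by rotation distinctness.
brute_ssr_oracle <- function(s, min_repeats = c(`2` = 6, `3` = 5, `4` = 5,
                                                `5` = 5, `6` = 5)) {
  ch <- strsplit(toupper(s), "")[[1]]
  L <- length(ch)
  rows <- list()
  for (p in 2:6) {
    min_nr <- min_repeats[[as.character(p)]]
    i <- 1
    while (i <= L - p) {
      if (ch[i] != "N" && ch[i] == ch[i + p]) {
        j <- i
        while (j <= L - p && ch[j] != "N" && ch[j] == ch[j + p]) j <- j + 1
        reg_len <- (j + p - 1) - i + 1
        nr <- reg_len %/% p
        part <- reg_len %% p
        if (nr >= min_nr) {
          anchors <- i + 0:part
          motifs <- vapply(anchors, function(a) {
            paste(ch[a:(a + p - 1)], collapse = "")
          }, character(1))
          b <- which(motifs == min(motifs))[1]
          mch <- strsplit(motifs[b], "")[[1]]
          rots <- vapply(seq_len(p), function(k) {
            paste(mch[c(k:p, seq_len(k - 1))[seq_len(p)]], collapse = "")
          }, character(1))
          if (length(unique(rots)) == p) {
            rows[[length(rows) + 1]] <- data.frame(
              start = anchors[b], end = anchors[b] + nr * p - 1,
              motif = motifs[b], motif_length = p, n_repeats = nr)
          }
        }
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(), motif = character(),
                      motif_length = integer(), n_repeats = integer())
  }
  out[order(out$start, out$motif_length), , drop = FALSE]
}

# Literal re-evaluation of the three uniqueness predicates, used as an
# oracle against uniqueness_filter().
uniqueness_oracle <- function(id, hits, thr) {
  h <- hits[hits$qseqid == id, , drop = FALSE]
  ok1 <- sum(h$evalue < thr$sig_evalue) <= thr$max_significant_hits
  ok2 <- sum(h$qcovs / 100 >= thr$high_cover) <= thr$max_high_cover_hits
  bs <- sort(h$bitscore, decreasing = TRUE)
  ok3 <- length(bs) < 2 || (bs[1] - bs[2]) >= thr$min_best_hit_gap
  ok1 && ok2 && ok3
}

# Reference fixture for the tetranucleotide worked example: a marker whose
# repeat region is (AAGA)7AG(AAGA)1 and whose downstream flank carries TC at
# positions 42-43.
tet_reference <- function(pigtail = 0) {
  marker_reference(
    "TET1",
    upstream = strrep("ACCTG", 6),
    structure = "(AAGA)7AG(AAGA)1",
    downstream = paste0(strrep("TTGCA", 8), "ATC"),
    pigtail = pigtail)
}

# Trinucleotide fixture: (AGA)3 with TGTTAAAATG at upstream positions 11-20.
tri_reference <- function() {
  marker_reference(
    "TRI1",
    upstream = paste0("GCCTT", "TGTTAAAATG", strrep("CTGCC", 2)),
    structure = "(AGA)3",
    downstream = strrep("TTGCA", 6),
    pigtail = 0)
}

random_primitive_motif_test <- function(k) {
  repeat {
    m <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
               collapse = "")
    ch <- strsplit(m, "")[[1]]
    rots <- vapply(seq_len(k), function(i) {
      paste(ch[c(i:k, seq_len(i - 1))[seq_len(k)]], collapse = "")
    }, character(1))
    if (length(unique(rots)) == k) return(m)
  }
}

# Flank free of the motif (including boundary-straddling occurrences), with
# boundary bases that cannot extend the run.
flank_without <- function(len, motif, side) {
  p <- nchar(motif)
  repeat {
    f <- random_dna(len)
    joined <- if (side == "U") paste0(f, substr(motif, 1, p - 1))
              else paste0(substr(motif, 2, p), f)
    if (grepl(motif, joined, fixed = TRUE)) next
    if (side == "U" && substr(f, len, len) == substr(motif, p, p)) next
    if (side == "D" && substr(f, 1, 1) == substr(motif, 1, 1)) next
    return(f)
  }
}

# At most one random variant per flank side, placed away from the flank ends
# and built so that alignment-based recovery is unambiguous (substituted and
# inserted bases differ from the reference context).
random_variants <- function(ref) {
  one_side <- function(side) {
    if (runif(1) < 0.4) return(NULL)
    flank <- if (side == "U") ref$upstream else ref$downstream
    L <- nchar(flank)
    kind <- sample(c("del", "sub", "ins"), 1, prob = c(0.45, 0.35, 0.2))
    len <- switch(kind, del = sample(1:8, 1), sub = sample(1:3, 1),
                  ins = sample(1:6, 1))
    # keep edits >= 8 bp away from the repeat boundary so an edit can never
    # be chained into the repeat region
    pos <- sample(8:(L - len - 3), 1)
    idx <- if (side == "D") pos else L - (pos + len - 1) + 1
    ref_seg <- substr(flank, idx, idx + len - 1)
    if (kind == "del") {
      return(poppystr::flank_variant(side, pos, "del", ref_seg))
    }
    if (kind == "sub") {
      seq <- vapply(strsplit(ref_seg, "")[[1]], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
      return(poppystr::flank_variant(side, pos, "sub",
                                     paste(seq, collapse = "")))
    }
    # insertion: first/last inserted base must differ from the bases the
    # insertion lands between, so the gap cannot slide
    left <- substr(flank, idx - 1, idx - 1)
    right <- substr(flank, idx, idx)
    seq <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    seq[1] <- sample(setdiff(c("A", "C", "G", "T"), c(left, right)), 1)
    seq[len] <- sample(setdiff(c("A", "C", "G", "T"), c(left, right)), 1)
    poppystr::flank_variant(side, pos, "ins", paste(seq, collapse = ""))
  }
  out <- rbind(one_side("U"), one_side("D"))
  if (is.null(out)) out <- poppystr:::empty_variants()
  out
}

# Minimal panel stand-in for call_genotypes()/classify_stutters(): only the
# markers table is consulted.
fake_panel <- function(markers, motif_lengths) {
  list(markers = tibble::tibble(marker = markers,
                                motif_length = as.integer(motif_lengths)))
}
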