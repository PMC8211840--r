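test_that("repeat structure parsing and serialization round-trip", {
  s <- parse_structure("(AAGA)7AG(AAGA)1")
  expect_equal(format_structure(s), "(AAGA)7AG(AAGA)1")
  expect_equal(total_repeats(s), 8L)
  expect_equal(extra_bases(s), 2L)
  expect_equal(nchar(expand_structure(s)), 7 * 4 + 2 + 4)
  expect_error(parse_structure("(AAGA)"), "parse")
})

test_that("flanking indels never change the repeat-based n.x, and the two
           conventions diverge exactly as on the tetranucleotide pair", {
  ref <- tet_reference()
  amp_large <- simulate_allele_sequence(ref)
  amp_small <- simulate_allele_sequence(
    ref, variants = flank_variant("D", 42, "del", "TC"))
  expect_equal(nchar(amp_large) - nchar(amp_small), 2L)

  dec_l <- decompose_amplicon(amp_large, ref)
  dec_s <- decompose_amplicon(amp_small, ref)
  expect_equal(format_structure(dec_l$structure), "(AAGA)7AG(AAGA)1")
  expect_equal(format_structure(dec_s$structure), "(AAGA)7AG(AAGA)1")
  expect_equal(dec_s$variants$position, 42L)
  expect_equal(dec_s$variants$seq, "TC")

  expect_equal(name_allele(dec_l)$full, "8.2")
  expect_equal(name_allele(dec_s)$full, "8.2 (D42TCdel)")
  # the size-based alternative renames the deleted variant but not the other
  expect_equal(name_allele(dec_s, convention = "size_based")$designation, "8")
  expect_equal(name_allele(dec_l, convention = "size_based")$designation, "8.2")
})

test_that("a flanking deletion larger than the repeat region breaks the
           size-based convention with a negative-numbering error", {
  ref <- tri_reference()
  amp <- simulate_allele_sequence(
    ref, variants = flank_variant("U", 11, "del", "TGTTAAAATG"))
  dec <- decompose_amplicon(amp, ref)
  nm <- name_allele(dec)
  expect_equal(nm$full, "3 (U11TGTTAAAATGdel)")
  sz <- name_allele(dec, convention = "size_based")
  expect_true(sz$negative_numbering)
  expect_match(sz$error, "negative numbering")
})

test_that("shorthand rewrites long descriptors as side+pos-length+kind and is
           idempotent and invertible for deletions", {
  nm <- name_allele(parse_structure("(AAGA)5AG(AAGA)1"),
                    variants = rbind(
                      flank_variant("D", 1, "del", "AGATAAAGA"),
                      flank_variant("D", 33, "del", "TC")))
  expect_equal(nm$full, "6.2 (D1AGATAAAGAdel; D33TCdel)")
  sh <- allele_shorthand(nm)
  expect_equal(sh$full, "6.2 (D1-9del; D33TCdel)")
  expect_equal(allele_shorthand(sh)$full, sh$full)

  nm2 <- name_allele(parse_structure("(AGA)3"),
                     variants = flank_variant("U", 11, "del", "TGTTAAAATG"))
  expect_equal(allele_shorthand(nm2)$full, "3 (U11-10del)")
  nm3 <- name_allele(parse_structure("(AGACT)14"),
                     variants = flank_variant("U", 25, "del", "TTGACCGA"))
  expect_equal(allele_shorthand(nm3)$full, "14 (U25-8del)")

  # no descriptors: unchanged
  plain <- name_allele(parse_structure("(AGAT)9"))
  expect_equal(allele_shorthand(plain)$full, "9")

  # inversion against the reference restores the deleted bases
  ref <- tri_reference()
  restored <- expand_shorthand(allele_shorthand(nm2), ref)
  expect_equal(restored$full, "3 (U11TGTTAAAATGdel)")
})

test_that("decompose . simulate is the identity over randomized structures
           and flank variants", {
  withr::with_seed(99, {
    for (rep in 1:40) {
      k <- sample(3:5, 1)
      motif <- random_primitive_motif_test(k)
      n1 <- sample(4:9, 1)
      inter <- if (runif(1) < 0.5) {
        substr(paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                     collapse = ""), 1, sample(1:(k - 1), 1))
      } else NULL
      struct <- if (is.null(inter)) {
        sprintf("(%s)%d", motif, n1)
      } else {
        sprintf("(%s)%d%s(%s)%d", motif, n1, inter, motif, sample(1:3, 1))
      }
      ref <- marker_reference(
        "RT", upstream = flank_without(40, motif, "U"),
        structure = struct, downstream = flank_without(40, motif, "D"),
        pigtail = 0)
      variants <- random_variants(ref)
      amp <- simulate_allele_sequence(ref, structure = struct,
                                      variants = variants)
      dec <- decompose_amplicon(amp, ref)
      expect_equal(format_structure(dec$structure), struct)
      # reconstruction must reproduce the amplicon byte for byte
      rebuilt <- simulate_allele_sequence(ref, structure = dec$structure,
                                          variants = dec$variants)
      expect_equal(as.character(rebuilt), as.character(amp))
      # same variant fingerprint (side, kind, length)
      fp <- function(v) sort(paste(v$side, v$kind, v$len))
      expect_equal(fp(dec$variants), fp(variants))
    }
  })
})

test_that("fragment size equals reference length plus repeat delta, indels
           and pigtail for every named allele", {
  ref <- marker_reference("SZ", strrep("CCTGA", 6), "(AGAT)8",
                          strrep("TGGAC", 6), pigtail = 7)
  cases <- list(
    list(struct = "(AGAT)8", v = NULL),
    list(struct = "(AGAT)10", v = NULL),
    list(struct = "(AGAT)6AG(AGAT)2", v = flank_variant("D", 3, "del", "GA")),
    list(struct = "(AGAT)8", v = flank_variant("U", 4, "ins", "TTT")))
  for (cs in cases) {
    amp <- simulate_allele_sequence(ref, cs$struct, cs$v)
    st <- parse_structure(cs$struct)
    indels <- if (is.null(cs$v)) 0 else
      sum(ifelse(cs$v$kind == "del", -cs$v$len,
                 ifelse(cs$v$kind == "ins", cs$v$len, 0)))
    expect_equal(
      attr(amp, "fragment_size"),
      ref$ref_length + 4 * (total_repeats(st) - 8) + extra_bases(st) + indels)
  }
})

test_that("SID labels are deterministic, injective on the inventory, and
           3-letter prefixes are unique on a panel-scale allele set", {
  s1 <- sid_label(c(a = "ACGTACGT"))
  s2 <- sid_label(c(a = "ACGTACGT"))
  expect_equal(s1$sid, s2$sid)
  pair <- sid_label(c(x = "ACGTACGT", y = "ACGTACGA"))
  expect_false(pair$sid[1] == pair$sid[2])

  # synthetic inventory of 158 allele sequences, as a full profiling panel
  withr::with_seed(1234, {
    panel <- synthetic_panel(n_markers = 27, seed = 4)
    seqs <- unlist(lapply(unique(panel$inventory$marker), function(m) {
      ref <- panel$references[[m]]
      nrs <- panel$inventory$nr[panel$inventory$marker == m]
      motif <- ref$structure$motif[1]
      vapply(nrs, function(n) {
        as.character(simulate_allele_sequence(
          ref, sprintf("(%s)%d", motif, n)))
      }, character(1))
    }))
    labs <- sid_label(seqs[1:158])
    expect_equal(anyDuplicated(labs$sid), 0L)
    expect_true(attr(labs, "prefix3_unique"))
  })
})

test_that("null-allele diagnosis reports 3'-terminal substitutions as high
           severity and indels overlapping a primer site", {
  primer_f <- "GATTACAGATCCTGAGCA"
  primer_r <- "TGCCATGGATTCAGTGGA"
  mid <- strrep("AGAT", 10)
  template <- paste0("CCGTA", primer_f, mid, revcomp(primer_r), "TTGCA")
  expect_equal(nrow(diagnose_null(template, primer_f, primer_r)), 0L)

  # substitution next to the last base of the F primer 3' end
  f_mut <- template
  pos <- 5 + nchar(primer_f) - 1  # offset 2 from the 3' end
  substr(f_mut, pos, pos) <- "A"
  rep <- diagnose_null(f_mut, primer_f, primer_r)
  expect_equal(rep$primer, "F")
  expect_equal(rep$kind, "sub")
  expect_equal(rep$offset_3prime, 2L)
  expect_equal(rep$severity, "high")

  # 8-nt deletion overlapping the R primer site
  r_start <- 5 + nchar(primer_f) + nchar(mid) + 1
  del_tpl <- paste0(substr(template, 1, r_start + 3),
                    substr(template, r_start + 12, nchar(template)))
  rep2 <- diagnose_null(del_tpl, primer_f, primer_r)
  rep2r <- rep2[rep2$primer == "R", ]
  expect_true(any(rep2r$kind == "del" & rep2r$length == 8))
  expect_true(all(rep2r$severity[rep2r$kind == "del"] == "indel"))
})
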