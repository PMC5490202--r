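test_that("codon translation follows the standard code and gap rules", {
  cod <- codon_alignment(c(a = "ATGGCT", b = "AT-GCT", c = "---GCN",
                           d = "ATGNNN"))
  aa <- translate_codons(cod)
  expect_identical(unname(aa$seqs), c("MA", "XA", "-X", "MX"))
  expect_identical(aa$n_columns, 2L)
  expect_warning(translate_codons(codon_alignment(c(a = "TAAGCT"))),
                 "stop codon")
})

test_that("a gapless alignment is entirely core with an empty catalogue", {
  aln <- protein_alignment(c(a = "MSKAGWLDPT", b = "MSKAGWLDPT",
                             c = "MSRAGWIDPT"))
  cx <- extract_core(aln, 0.9)
  expect_identical(cx$core$n_core, 10L)
  expect_identical(nrow(cx$insertions), 0L)
  expect_identical(cx$core$column_map, 1:10)
})

test_that("a rare occupied column is catalogued after its left core neighbour", {
  # column 4 occupied by one of five sequences at threshold 0.5
  aln <- protein_alignment(c(s1 = "MSK-AGW", s2 = "MSK-AGW", s3 = "MSKLAGW",
                             s4 = "MSK-AGW", s5 = "MSK-AGW"))
  cx <- extract_core(aln, 0.5)
  expect_identical(cx$core$n_core, 6L)
  expect_identical(cx$insertions$identifier, "s3")
  expect_identical(cx$insertions$after_position, 3L)
  expect_identical(cx$insertions$segment, "L")
})

test_that("terminal non-core columns become extensions, not insertions", {
  aln <- protein_alignment(c(s1 = "KWMSKAGW--", s2 = "--MSKAGWLP",
                             s3 = "--MSKAGW--", s4 = "--MSKAGW--"))
  cx <- extract_core(aln, 0.9)
  expect_identical(cx$core$n_core, 6L)
  expect_identical(nrow(cx$insertions), 0L)
  expect_identical(unname(cx$core$terminal_n[["s1"]]), "KW")
  expect_identical(unname(cx$core$terminal_c[["s2"]]), "LP")
})

test_that("no qualifying column raises an empty-core error", {
  aln <- protein_alignment(c(a = "M---", b = "-S--", c = "--K-", d = "---A"))
  expect_error(extract_core(aln, 0.9), "empty-core")
})

test_that("core decomposition is lossless and monotone in the threshold", {
  set.seed(42)
  for (rep in 1:20) {
    seqs <- random_aln(sample(3:8, 1), sample(8:16, 1), p_gap = 0.3)
    aln <- protein_alignment(seqs)
    prev <- Inf
    for (th in c(0.2, 0.4, 0.6, 0.8, 1.0)) {
      cx <- tryCatch(extract_core(aln, th), error = function(e) NULL)
      n_core <- if (is.null(cx)) 0L else cx$core$n_core
      expect_lte(n_core, prev)   # n_core non-increasing in threshold
      prev <- n_core
      if (is.null(cx)) next
      for (id in aln$ids)
        expect_identical(reconstruct_sequence(cx$core, cx$insertions, id),
                         gsub("-", "", aln$seqs[[id]]))
    }
  }
})

test_that("clade-conserved insertions are reported at the planted site", {
  map <- clade_map(data.frame(identifier = paste0("m", 1:4),
                              clade = "DDKB", super_clade = "DDK"))
  catalogue <- data.frame(
    identifier = c("m1", "m2", "m3", "m2"),
    after_position = c(10L, 10L, 10L, 4L),
    segment = c("QA", "QA", "GA", "W"), stringsAsFactors = FALSE)
  hits <- conserved_insertions(catalogue, map, min_fraction = 0.7)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$after_position, 10L)
  expect_identical(hits$segment_length, 2L)
  expect_identical(hits$n_carriers, 3L)
  expect_identical(nrow(conserved_insertions(catalogue[0, ], map, 0.5)), 0L)
})

test_that("generator-planted clade insertions are recovered exactly", {
  spec <- synthetic_spec(
    clades = data.frame(label = c("A", "B"), super_clade = c("S1", "S2"),
                        n_sequences = c(8L, 8L)),
    n_core = 40L, insertion_rate = 0, fragment_fraction = 0,
    clade_insertions = data.frame(clade = "A", after_position = 10L,
                                  length = 2L, fraction = 0.75),
    seed = 11L)
  fam <- generate_family(spec)
  cx <- extract_core(fam$alignment, 0.9)
  expect_identical(cx$core$n_core, 40L)
  hits <- conserved_insertions(cx$insertions, fam$map, min_fraction = 0.7)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$after_position, 10L)
  expect_identical(hits$segment_length, 2L)
  expect_identical(hits$n_carriers, 6L)  # 0.75 x 8
})

test_that("anchor mapping: fixed offset, gap checks and column walk", {
  aln <- protein_alignment(c(anchor = "MSKAGWLD", other = "MSKAGWLD"))
  core <- extract_core(aln, 0.9)$core
  core0 <- set_anchor(core, "anchor", offset = 0L)
  expect_identical(map_position(core0, 1L), 1L)
  core1 <- set_anchor(core, "anchor", offset = -1L)
  expect_identical(map_position(core1, 5L), 4L)
  expect_error(map_position(core1, 100L), "mapping error")

  # anchor gapped over columns 2-4: residue 5 found by walking non-gaps
  aln2 <- protein_alignment(c(anchor = "M---AGWLD", o1 = "MSKLAGWLD",
                              o2 = "MSKLAGWLD", o3 = "MSKLAGWLD"))
  core2 <- set_anchor(extract_core(aln2, 0.5)$core, "anchor")
  expect_identical(map_position(core2, 5L), 8L)
  expect_identical(map_position(core2, 2L), 5L)
  # gapped-position queries through a fixed offset are refused
  core2f <- set_anchor(extract_core(aln2, 0.5)$core, "anchor", offset = 0L)
  expect_error(map_position(core2f, 2L), "gapped")
})

test_that("anchor residues in extensions and insertions consume numbering", {
  aln <- protein_alignment(c(anchor = "KWMSKL-AGW", o1 = "--MSK--AGW",
                             o2 = "--MSA--AGW", o3 = "--MSKW-AGW"))
  cx <- extract_core(aln, 0.75)
  core <- set_anchor(cx$core, "anchor")
  # anchor = KW | MSK | L insertion | AGW : residue 6 is the insertion
  expect_error(map_position(core, 6L, cx$insertions),
               "extension or insertion")
  expect_identical(map_position(core, 3L, cx$insertions), 1L)
  expect_identical(map_position(core, 7L, cx$insertions), 4L)
})

test_that("translation commutes with subsetting by codon triple", {
  set.seed(7)
  prot <- protein_alignment(random_aln(5, 12, p_gap = 0.2, p_x = 0.1,
                                       alphabet_size = 20))
  cod <- back_translate(prot, seed = 3L)
  keep <- c(2L, 5L, 9L)
  nt_cols <- as.integer(outer(c(-2L, -1L, 0L), 3L * keep, "+"))
  m <- do.call(rbind, strsplit(unname(cod$seqs), ""))
  sub_seqs <- apply(m[, nt_cols, drop = FALSE], 1L, paste, collapse = "")
  names(sub_seqs) <- cod$ids
  left <- translate_codons(codon_alignment(sub_seqs))
  mp <- do.call(rbind, strsplit(unname(prot$seqs), ""))
  right <- apply(mp[, keep, drop = FALSE], 1L, paste, collapse = "")
  expect_identical(unname(left$seqs), unname(right))
})
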