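toy_family <- function() {
  # focal clade F: consensus MSKAG; contrast clade C: consensus MTRAG
  seqs <- c(f1 = "MSKAG", f2 = "MSKAG", f3 = "MSKAG", f4 = "MSKTG",
            c1 = "MTRAG", c2 = "MTRAG", c3 = "MTRAG", c4 = "MTKAG")
  map <- clade_map(data.frame(
    identifier = names(seqs),
    clade = rep(c("F", "C"), each = 4),
    super_clade = rep(c("SF", "SC"), each = 4)))
  list(core = core_of(seqs), map = map)
}

test_that("characteristic residues satisfy the in/out frequency rule", {
  fam <- toy_family()
  ref <- find_characteristic(fam$core, fam$map, "F", "C")
  # position 2: S in 4/4 focal, 0/4 contrast; position 3: K 4/4 vs 1/4
  expect_identical(ref$position, c(2L, 3L))
  expect_identical(ref$residue, c("S", "K"))
  expect_equal(ref$focal_fraction, c(1, 1))
  expect_equal(ref$fraction_C, c(0, 0.25))
  # M at position 1 and G at 5 fail the contrast bound; A at 4 is 3/4 both
  expect_false(1L %in% ref$position)
})

test_that("identical focal and contrast composition yields an empty set", {
  seqs <- c(a1 = "MSKA", a2 = "MSKA", b1 = "MSKA", b2 = "MSKA")
  map <- clade_map(data.frame(identifier = names(seqs),
                              clade = rep(c("A", "B"), each = 2),
                              super_clade = rep(c("SA", "SB"), each = 2)))
  ref <- find_characteristic(core_of(seqs), map, "A", "B")
  expect_identical(nrow(ref), 0L)
})

test_that("overlapping focal and contrast groups are refused", {
  fam <- toy_family()
  expect_error(find_characteristic(fam$core, fam$map, "F", list("C", "SF")),
               "clade-definition")
})

test_that("a single contrast reduces the multi-contrast rule", {
  fam <- toy_family()
  one <- find_characteristic(fam$core, fam$map, "F", "C")
  multi <- find_characteristic(fam$core, fam$map, "F", list(only = "C"))
  expect_identical(one$position, multi$position)
  expect_identical(one$residue, multi$residue)
})

test_that("multi-contrast entries must clear every contrast separately", {
  seqs <- c(f1 = "SK", f2 = "SK",          # focal
            c1 = "SA", c2 = "SA",          # contrast 1 shares S
            d1 = "TK", d2 = "TK")          # contrast 2 shares K
  map <- clade_map(data.frame(identifier = names(seqs),
                              clade = rep(c("F", "C1", "C2"), each = 2),
                              super_clade = rep(c("SF", "S1", "S2"),
                                                each = 2)))
  core <- core_of(seqs)
  expect_identical(nrow(find_characteristic(core, map, "F",
                                            list("C1", "C2"))), 0L)
  # against C1 alone, K at position 2 discriminates
  ref <- find_characteristic(core, map, "F", "C1")
  expect_identical(ref$position, 2L)
  expect_identical(ref$residue, "K")
})

test_that("discriminant discovery matches the exhaustive oracle", {
  set.seed(303)
  for (rep in 1:20) {
    n_f <- sample(3:4, 1); n_c <- sample(3:4, 1)
    seqs <- random_aln(n_f + n_c, sample(6:15, 1))
    map <- clade_map(data.frame(
      identifier = names(seqs),
      clade = c(rep("F", n_f), rep("C", n_c)),
      super_clade = c(rep("SF", n_f), rep("SC", n_c))))
    core <- core_of(seqs)
    ref <- find_characteristic(core, map, "F", "C")
    mat <- as.matrix(core$aln)
    orc <- oracle_characteristic(mat[1:n_f, , drop = FALSE],
                                 list(mat[-(1:n_f), , drop = FALSE]))
    expect_identical(ref$position, orc$position)
    expect_identical(ref$residue, orc$residue)
  }
})

test_that("reference sets shrink as bounds tighten and never share entries
           with the reversed search", {
  set.seed(404)
  for (rep in 1:10) {
    seqs <- random_aln(8, 12)
    map <- clade_map(data.frame(identifier = names(seqs),
                                clade = rep(c("F", "C"), each = 4),
                                super_clade = rep(c("SF", "SC"), each = 4)))
    core <- core_of(seqs)
    loose <- find_characteristic(core, map, "F", "C", 0.6, 0.4)
    tight_in <- find_characteristic(core, map, "F", "C", 0.8, 0.4)
    tight_out <- find_characteristic(core, map, "F", "C", 0.6, 0.2)
    key <- function(r) paste(r$position, r$residue)
    expect_true(all(key(tight_in) %in% key(loose)))
    expect_true(all(key(tight_out) %in% key(loose)))
    fwd <- find_characteristic(core, map, "F", "C", 0.7, 0.3)
    rev <- find_characteristic(core, map, "C", "F", 0.7, 0.3)
    expect_length(intersect(key(fwd), key(rev)), 0)
  }
})

test_that("match scores count agreement at reference positions", {
  fam <- toy_family()
  ref <- residue_set(data.frame(position = c(1L, 2L, 3L, 4L, 5L),
                                residue = c("M", "S", "K", "W", "W")))
  ms <- match_score(fam$core, "f1", ref)   # agrees at 1,2,3 only
  expect_identical(ms$matched, 3L)
  expect_identical(ms$observed, 5L)
  expect_identical(ms$total, 5L)
  expect_false(ms$fragmentary)
  expect_error(match_score(fam$core, "f1",
                           residue_set(data.frame(position = 99L,
                                                  residue = "S"))),
               "range error")
})

test_that("a clade consensus matches its own reference set in full", {
  fam <- toy_family()
  ref <- find_characteristic(fam$core, fam$map, "F", "C")
  ms <- match_score(fam$core, "f1", ref)
  expect_identical(ms$matched, ms$total)
})

test_that("fragmentary sequences are scored but flagged", {
  seqs <- c(a = "MSKAG", b = "MSKAG", frag = "MS---")
  map <- clade_map(data.frame(identifier = names(seqs),
                              clade = c("A", "A", "A"),
                              super_clade = "SA"))
  core <- core_of(seqs)
  ref <- residue_set(data.frame(position = 1:5,
                                residue = c("M", "S", "K", "A", "G")))
  mt <- match_table(core, map, ref)
  frag_row <- mt$scores[mt$scores$identifier == "frag", ]
  expect_identical(frag_row$matched, 2L)
  expect_identical(frag_row$observed, 2L)
  expect_true(frag_row$fragmentary)
  # ranges over complete sequences only
  expect_identical(mt$by_clade$min_matched, 5)
  expect_identical(mt$by_clade$n, 2L)
})

test_that("match scores survive column-order permutation of the input", {
  set.seed(505)
  seqs <- random_aln(6, 10, p_gap = 0.1)
  map <- clade_map(data.frame(identifier = names(seqs),
                              clade = rep(c("F", "C"), each = 3),
                              super_clade = rep(c("SF", "SC"), each = 3)))
  core <- core_of(seqs)
  ref <- find_characteristic(core, map, "F", "C", 0.6, 0.5)
  perm <- sample(core$n_core)
  m <- as.matrix(core$aln)[, perm, drop = FALSE]
  seqs_p <- stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
  core_p <- core_of(seqs_p)
  inv <- order(perm)  # unified position p now sits at column inv[p]
  for (id in names(seqs)) {
    ref_p <- ref
    ref_p$position <- sort(inv[ref$position])
    ref_p$residue <- ref$residue[order(inv[ref$position])]
    expect_identical(match_score(core_p, id, ref_p)$matched,
                     match_score(core, id, ref)$matched)
  }
})
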