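test_that("frequency profiles count observed residues only", {
  core <- core_of(c(s1 = "SM", s2 = "SM", s3 = "SM", s4 = "AM"))
  prof <- position_profile(core)
  expect_identical(prof$modal_residue[1], "S")
  expect_equal(prof$modal_fraction[1], 0.75)
  expect_identical(prof$n_observed, c(4L, 4L))

  # gaps and X excluded from the denominator
  core2 <- core_of(c(s1 = "S", s2 = "S", s3 = "X", s4 = "-"))
  prof2 <- position_profile(core2)
  expect_equal(prof2$modal_fraction, 1)
  expect_identical(prof2$n_observed, 2L)
  # all-sequences denominator available for sensitivity analysis
  expect_equal(position_profile(core2, include_gaps = TRUE)$modal_fraction,
               0.5)
})

test_that("identical sequences give modal fraction one everywhere", {
  core <- core_of(c(a = "MSKAGW", b = "MSKAGW", c = "MSKAGW"))
  prof <- position_profile(core)
  expect_true(all(prof$modal_fraction == 1))
  s <- conservation_summary(classify_tiers(prof))
  expect_equal(unlist(s[, c("percent_invariant", "percent_highly",
                            "percent_well", "percent_conserved")],
               use.names = FALSE), c(100, 100, 100, 100))
})

test_that("tier boundaries are strict: 96% is highly, not invariant", {
  seqs <- c(rep("S", 96), rep("A", 4))
  core <- core_of(stats::setNames(seqs, sprintf("q%03d", 1:100)))
  tier <- classify_tiers(position_profile(core))$tier
  expect_identical(as.character(tier), "highly")
  # exactly 50% is not conserved (strict bound), and ties are flagged
  core2 <- core_of(c(a = "S", b = "S", c = "A", d = "A"))
  prof2 <- classify_tiers(position_profile(core2))
  expect_identical(as.character(prof2$tier), "not_conserved")
  expect_true(prof2$tie)
  expect_identical(prof2$modal_residue, "A")  # alphabetical tie-break
})

test_that("profiles and tiers agree with the brute-force oracle", {
  set.seed(101)
  for (rep in 1:25) {
    seqs <- random_aln(sample(3:10, 1), sample(5:20, 1))
    core <- core_of(seqs)
    prof <- classify_tiers(position_profile(core))
    orc <- oracle_profile(as.matrix(core$aln))
    for (p in seq_len(core$n_core)) {
      expect_identical(prof$n_observed[p], as.integer(orc[p, "n"]))
      if (prof$n_observed[p] > 0L) {
        expect_identical(prof$modal_residue[p], unname(orc[p, "modal"]))
        expect_equal(prof$modal_fraction[p],
                     as.numeric(orc[p, "fraction"]))
      }
      expect_identical(
        as.character(prof$tier[p]),
        oracle_tier(as.numeric(orc[p, "fraction"]),
                    as.integer(orc[p, "n"])))
    }
  }
})

test_that("tier counts are cumulative and order-invariant", {
  set.seed(202)
  for (rep in 1:10) {
    seqs <- random_aln(8, 12)
    core <- core_of(seqs)
    prof <- classify_tiers(position_profile(core))
    s <- conservation_summary(prof)
    expect_true(s$raw_invariant <= s$raw_highly &&
                s$raw_highly <= s$raw_well &&
                s$raw_well <= s$raw_conserved &&
                s$raw_conserved <= 100)
    # permuting sequence order changes nothing
    perm <- sample(names(seqs))
    core_p <- core_of(seqs[perm])
    expect_equal(position_profile(core_p)$modal_fraction,
                 prof$modal_fraction)
    # duplicating a sequence never decreases its own residues' frequencies
    dup <- c(seqs, stats::setNames(seqs[1], "dup"))
    prof_d <- position_profile(core_of(dup))
    cts <- attr(prof, "counts"); cts_d <- attr(prof_d, "counts")
    row1 <- strsplit(unname(seqs[1]), "")[[1]]
    obs_cols <- which(colSums(as.matrix(core_of(seqs)$aln) != "-") > 0)
    for (p in seq_along(obs_cols)) {
      r <- row1[obs_cols[p]]
      if (!r %in% rownames(cts) || prof$n_observed[p] == 0L) next
      expect_gte(cts_d[r, p] / max(prof_d$n_observed[p], 1L),
                 cts[r, p] / prof$n_observed[p] - 1e-12)
    }
  }
})

test_that("unobserved positions are flagged and excluded from numerators", {
  core <- core_of(c(a = "MS", b = "MS", frag1 = "M-", frag2 = "M-"))
  prof <- classify_tiers(position_profile(core, c("frag1", "frag2")))
  expect_identical(as.character(prof$tier), c("invariant", "unobserved"))
  s <- conservation_summary(prof)
  expect_equal(s$percent_invariant, 50)  # 1 of 2 core positions
})

test_that("invariant positions are listed with their residue", {
  core <- core_of(c(a = "MSA", b = "MSK", c = "MSR"))
  inv <- invariant_positions(position_profile(core))
  expect_identical(inv$position, c(1L, 2L))
  expect_identical(inv$residue, c("M", "S"))
  core95 <- core_of(stats::setNames(c(rep("S", 19), "A"),
                                    sprintf("t%02d", 1:20)))
  expect_identical(nrow(invariant_positions(position_profile(core95))), 0L)
})

test_that("clade summaries recover generator-planted tier mixtures", {
  spec <- synthetic_spec(
    clades = data.frame(label = c("A", "B"), super_clade = c("S1", "S2"),
                        n_sequences = c(60L, 60L)),
    n_core = 100L,
    tier_mix = c(invariant = 0.1, highly = 0.1, well = 0.2,
                 conserved = 0.3, variable = 0.3),
    insertion_rate = 0, fragment_fraction = 0, seed = 5L)
  fam <- generate_family(spec)
  core <- extract_core(fam$alignment, 0.9)$core
  tab <- summarize_clades(core, fam$map, c("A", "B"))
  for (r in 1:2) {
    expect_equal(tab$percent_invariant[r], 10, tolerance = 0.02)
    expect_equal(tab$percent_highly[r], 20, tolerance = 0.02)
    expect_equal(tab$percent_well[r], 40, tolerance = 0.02)
    expect_equal(tab$percent_conserved[r], 70, tolerance = 0.02)
  }
  expect_warning(summarize_clades(core, fam$map, c("A", "ghost")),
                 "no members")
})

test_that("summary percentages round half away from zero to one decimal", {
  # 17/265 = 6.41509... -> 6.4 ; 18/265 = 6.79245... -> 6.8
  prof <- data.frame(position = 1:265,
                     modal_fraction = c(rep(1, 18), rep(0.2, 247)),
                     n_observed = 265L)
  class(prof) <- c("frequency_profile", "data.frame")
  attr(prof, "n_subset") <- 10L
  s <- conservation_summary(classify_tiers(prof))
  expect_equal(s$percent_invariant, 6.8)
})
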