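# Tier bands on the modal-residue fraction, and the midpoint each planted
# column is calibrated to.  "variable" columns sit below the conserved bound.
TIER_BANDS <- list(
  invariant = c(0.99, 1.00),
  highly    = c(0.90, 0.99),
  well      = c(0.70, 0.90),
  conserved = c(0.50, 0.70),
  variable  = c(0.00, 0.50))
TIER_TARGETS <- c(invariant = 0.995, highly = 0.945, well = 0.80,
                  conserved = 0.60, variable = 0.25)

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Specify a synthetic clade-structured alignment
#'
#' Describes the simulated family: clades with their sizes and super-clade
#' membership, the number of core positions, the mixture of planted
#' conservation tiers, clade-diagnostic positions, insertion behaviour and
#' terminal fragmentation (mimicking incomplete transcriptome-derived
#' sequences).  The defaults mirror a D14/KAI2-like family: a 265-position
#' core, a tier mixture matching family-wide conservation levels, and a
#' third of the sequences truncated.
#'
#' @param clades Data frame with columns `label`, `super_clade`,
#'   `n_sequences`.
#' @param n_core Number of core positions.
#' @param tier_mix Named fractions over
#'   `invariant`/`highly`/`well`/`conserved`/`variable`; must sum to 1.
#' @param n_diagnostic Number of clade-diagnostic positions planted per
#'   pair in `diagnostic_pairs`.
#' @param diagnostic_pairs List of `c(focal, contrast)` clade-label pairs;
#'   default the first two clades when `n_diagnostic > 0`.
#' @param insertion_rate Expected random singleton insertions per sequence
#'   (Poisson).
#' @param clade_insertions Optional data frame `clade`, `after_position`,
#'   `length`, `fraction`: conserved insertions carried by a fraction of a
#'   clade.
#' @param fragment_fraction Fraction of sequences truncated at one
#'   terminus.
#' @param fragment_range Range (fractions of the alignment length) the
#'   truncation length is drawn from, uniformly.
#' @param seed Integer seed; the single source of randomness.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(clades = data.frame(
                             label = c("cladeA", "cladeB", "cladeC"),
                             super_clade = c("SC1", "SC2", "SC2"),
                             n_sequences = c(40L, 40L, 40L),
                             stringsAsFactors = FALSE),
                           n_core = 265L,
                           tier_mix = c(invariant = 0.068, highly = 0.109,
                                        well = 0.249, conserved = 0.257,
                                        variable = 0.317),
                           n_diagnostic = 0L,
                           diagnostic_pairs = NULL,
                           insertion_rate = 0.05,
                           clade_insertions = NULL,
                           fragment_fraction = 0.30,
                           fragment_range = c(0.05, 0.25),
                           seed = 1L) {
  stopifnot(is.data.frame(clades),
            all(c("label", "super_clade", "n_sequences") %in% names(clades)))
  if (abs(sum(tier_mix) - 1) > 1e-8)
    stop("spec error: tier_mix must sum to 1", call. = FALSE)
  if (!setequal(names(tier_mix), names(TIER_TARGETS)))
    stop("spec error: tier_mix must name the five tiers", call. = FALSE)
  if (fragment_fraction < 0 || fragment_fraction > 1)
    stop("spec error: fragment_fraction must lie in [0,1]", call. = FALSE)
  if (n_diagnostic > 0L && is.null(diagnostic_pairs))
    diagnostic_pairs <- list(clades$label[1:2])
  n_diag_total <- n_diagnostic * length(diagnostic_pairs)
  if (n_diag_total > n_core)
    stop("spec error: more diagnostic positions than core positions",
         call. = FALSE)
  structure(list(clades = clades, n_core = as.integer(n_core),
                 tier_mix = tier_mix[names(TIER_TARGETS)],
                 n_diagnostic = as.integer(n_diagnostic),
                 diagnostic_pairs = diagnostic_pairs,
                 insertion_rate = insertion_rate,
                 clade_insertions = clade_insertions,
                 fragment_fraction = fragment_fraction,
                 fragment_range = fragment_range,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Integer tier counts matching tier_mix over n positions (largest remainder)
tier_counts <- function(tier_mix, n) {
  raw <- tier_mix * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Number of deviant sequences for one clade-column: binomial at the tier's
# target modal fraction, truncated to the counts whose realized modal
# fraction stays inside the tier band (strict lower, inclusive upper).
draw_deviant_count <- function(n, tier) {
  band <- TIER_BANDS[[tier]]
  m <- TIER_TARGETS[[tier]]
  cmax <- n - 1L - floor(band[1] * n)           # (n-c)/n > band lo
  cmin <- max(0L, n - floor(band[2] * n))       # (n-c)/n <= band hi
  if (band[2] >= 1) cmin <- 0L
  if (cmax < cmin) cmax <- cmin                 # tiny n: band may collapse
  c0 <- stats::rbinom(1L, n, 1 - m)
  min(max(c0, cmin), cmax)
}

#' Generate a clade-structured synthetic alignment with known truth
#'
#' Builds an aligned protein family in which every downstream quantity is
#' known by construction: each core column carries a planted conservation
#' tier realized by a truncated-binomial deviation model (so the realized
#' within-clade modal fraction always lies inside the planted tier's
#' band); diagnostic columns give designated clade pairs distinct
#' consensus residues (within-clade frequency held above 0.9, cross-clade
#' frequency of the focal residue held at zero by excluding it from
#' deviant draws); insertions appear as extra low-occupancy columns; and a
#' fraction of sequences is truncated at one terminus, as
#' transcriptome-derived fragments are.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `alignment` (a [protein_alignment()]), `map` (a
#'   `clade_map`) and `truth` (planted tiers, per-clade consensus matrix,
#'   diagnostic table, insertion and fragment records).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    cl <- spec$clades
    n_core <- spec$n_core
    ids <- unlist(lapply(seq_len(nrow(cl)), function(i)
      sprintf("%s_seq%03d", cl$label[i], seq_len(cl$n_sequences[i]))))
    clade_of <- rep(cl$label, cl$n_sequences)
    map <- clade_map(data.frame(identifier = ids, clade = clade_of,
                                super_clade = rep(cl$super_clade,
                                                  cl$n_sequences),
                                stringsAsFactors = FALSE))
    n_seq <- length(ids)

    # assign diagnostic columns, then tiers for the rest
    # Diagnostic columns are planted away from the termini: terminal
    # fragmentation thins coverage near the ends, and a clade-diagnostic
    # signal should not be confounded with missing data.
    pairs <- spec$diagnostic_pairs
    n_diag_total <- spec$n_diagnostic * length(pairs)
    diag_window <- seq(max(1L, round(0.3 * n_core)),
                       min(n_core, round(0.7 * n_core)))
    if (n_diag_total > length(diag_window))
      stop("spec error: too many diagnostic positions for n_core",
           call. = FALSE)
    diag_pos <- if (n_diag_total > 0L)
      sort(sample(diag_window, n_diag_total)) else integer(0)
    diag_pair_of <- rep(seq_along(pairs), each = spec$n_diagnostic)
    rest <- setdiff(seq_len(n_core), diag_pos)
    counts <- tier_counts(spec$tier_mix, length(rest))
    tier_of <- character(n_core)
    tier_of[rest] <- sample(rep(names(TIER_TARGETS), counts))
    tier_of[diag_pos] <- "highly"

    # consensus residues: shared across clades except diagnostic columns
    base_cons <- sample(AA_LETTERS, n_core, replace = TRUE)
    cons <- matrix(rep(base_cons, each = nrow(cl)), nrow = nrow(cl),
                   dimnames = list(cl$label, NULL))
    diag_tab <- NULL
    if (n_diag_total > 0L) {
      recs <- list()
      for (j in seq_along(diag_pos)) {
        p <- diag_pos[j]
        pair <- pairs[[diag_pair_of[j]]]
        two <- sample(AA_LETTERS, 2L)
        cons[, p] <- two[2L]           # contrast residue everywhere ...
        cons[pair[1L], p] <- two[1L]   # ... except the focal clade
        recs[[j]] <- data.frame(position = p, focal = pair[1L],
                                contrast = pair[2L],
                                focal_residue = two[1L],
                                contrast_residue = two[2L],
                                stringsAsFactors = FALSE)
      }
      diag_tab <- do.call(rbind, recs)
    }

    # core residue matrix: per clade-column truncated-binomial deviation
    m <- matrix("-", nrow = n_seq, ncol = n_core,
                dimnames = list(ids, NULL))
    for (i in seq_len(nrow(cl))) {
      rows <- which(clade_of == cl$label[i])
      n <- length(rows)
      for (p in seq_len(n_core)) {
        consensus <- cons[i, p]
        m[rows, p] <- consensus
        cdev <- draw_deviant_count(n, tier_of[p])
        if (cdev > 0L) {
          dev_rows <- rows[sample.int(n, cdev)]
          pool <- setdiff(AA_LETTERS, consensus)
          if (p %in% diag_pos)   # never leak the focal residue cross-clade
            pool <- setdiff(pool, cons[, p])
          m[dev_rows, p] <- sample(pool, cdev, replace = TRUE)
        }
      }
    }

    # insertions: random singletons plus planted clade-conserved ones
    ins <- list()
    if (spec$insertion_rate > 0) {
      for (i in seq_len(n_seq)) {
        k <- stats::rpois(1L, spec$insertion_rate)
        if (k > 0L) for (z in seq_len(k)) {
          len <- sample(1:5, 1L)
          ins[[length(ins) + 1L]] <- data.frame(
            identifier = ids[i],
            after_position = sample(n_core - 1L, 1L),
            segment = paste(sample(AA_LETTERS, len, replace = TRUE),
                            collapse = ""),
            planted = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
    if (!is.null(spec$clade_insertions)) {
      ci <- spec$clade_insertions
      for (r in seq_len(nrow(ci))) {
        members <- ids[clade_of == ci$clade[r]]
        n_carry <- round(ci$fraction[r] * length(members))
        carriers <- members[sample.int(length(members), n_carry)]
        seg <- paste(sample(AA_LETTERS, ci$length[r], replace = TRUE),
                     collapse = "")
        for (id in carriers)
          ins[[length(ins) + 1L]] <- data.frame(
            identifier = id, after_position = as.integer(ci$after_position[r]),
            segment = seg, planted = TRUE, stringsAsFactors = FALSE)
      }
    }
    ins <- if (length(ins)) do.call(rbind, ins) else
      data.frame(identifier = character(), after_position = integer(),
                 segment = character(), planted = logical(),
                 stringsAsFactors = FALSE)

    # assemble aligned matrix: insertion blocks become extra columns
    blocks <- split(seq_len(nrow(ins)), ins$after_position)
    col_chunks <- list(); core_col_of <- integer(n_core)
    add_block <- function(after) {
      rows_here <- blocks[[as.character(after)]]
      if (is.null(rows_here)) return(NULL)
      width <- max(nchar(ins$segment[rows_here]))
      blk <- matrix("-", nrow = n_seq, ncol = width,
                    dimnames = list(ids, NULL))
      for (r in rows_here) {
        chars <- strsplit(ins$segment[r], "")[[1L]]
        # a second insertion by the same sequence at one site right-fills
        row_now <- blk[ins$identifier[r], ]
        free <- which(row_now == "-")[seq_along(chars)]
        if (anyNA(free)) {  # widen block if needed
          extra <- sum(is.na(free))
          blk <- cbind(blk, matrix("-", n_seq, extra))
          row_now <- blk[ins$identifier[r], ]
          free <- which(row_now == "-")[seq_along(chars)]
        }
        row_now[free] <- chars
        blk[ins$identifier[r], ] <- row_now
      }
      blk
    }
    blk0 <- add_block(0L)
    if (!is.null(blk0)) col_chunks[[length(col_chunks) + 1L]] <- blk0
    for (p in seq_len(n_core)) {
      col_chunks[[length(col_chunks) + 1L]] <- m[, p, drop = FALSE]
      core_col_of[p] <- sum(vapply(col_chunks, ncol, integer(1L)))
      blk <- add_block(p)
      if (!is.null(blk)) col_chunks[[length(col_chunks) + 1L]] <- blk
    }
    full <- do.call(cbind, col_chunks)

    # terminal fragmentation: truncate whole leading/trailing column spans
    frag <- data.frame(identifier = character(), side = character(),
                       n_columns_masked = integer(),
                       stringsAsFactors = FALSE)
    n_frag <- round(spec$fragment_fraction * n_seq)
    if (n_frag > 0L) {
      frag_ids <- ids[sample.int(n_seq, n_frag)]
      for (id in frag_ids) {
        side <- sample(c("N", "C"), 1L)
        k <- round(stats::runif(1L, spec$fragment_range[1L],
                                spec$fragment_range[2L]) * ncol(full))
        if (k > 0L) {
          colsel <- if (side == "N") seq_len(k)
                    else seq(ncol(full) - k + 1L, ncol(full))
          full[id, colsel] <- "-"
        }
        frag <- rbind(frag, data.frame(identifier = id, side = side,
                                       n_columns_masked = as.integer(k),
                                       stringsAsFactors = FALSE))
      }
    }

    aln <- new_alignment(apply(full, 1L, paste, collapse = ""),
                         type = "protein",
                         provenance = sprintf("synthetic (seed %d)",
                                              spec$seed))
    truth <- list(
      tiers = data.frame(position = seq_len(n_core), tier = tier_of,
                         stringsAsFactors = FALSE),
      consensus = cons,
      diagnostic = diag_tab,
      insertions = ins,
      fragments = frag,
      core_column = core_col_of,
      spec = spec)
    list(alignment = aln, map = map, truth = truth)
  })
}

# synonymous codons of each amino acid (standard code, stops excluded)
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))[AA_LETTERS]
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Each residue is replaced by a synonymous codon drawn uniformly under
#' the standard genetic code; gaps become `---` and `X` becomes `NNN`, so
#' [translate_codons()] applied to the result reproduces the input.
#'
#' @param alignment A [protein_alignment()].
#' @param seed Integer seed for the codon draws.
#' @return A [codon_alignment()] with three times as many columns.
#' @export
back_translate <- function(alignment, seed = 1L) {
  stopifnot(inherits(alignment, "protein_alignment"))
  tab <- codons_by_aa()
  with_seed(seed, {
    seqs <- vapply(alignment$seqs, function(s) {
      chars <- strsplit(s, "")[[1L]]
      codons <- vapply(chars, function(a) {
        if (a == "-") return("---")
        if (a == "X") return("NNN")
        opts <- tab[[a]]
        opts[sample.int(length(opts), 1L)]
      }, character(1L), USE.NAMES = FALSE)
      paste(codons, collapse = "")
    }, character(1L))
    new_alignment(seqs, type = "codon",
                  provenance = paste0("back-translated: ",
                                      alignment$provenance))
  })
}
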