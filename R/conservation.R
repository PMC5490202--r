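#' Default conservation tier thresholds
#'
#' Cumulative tiers on the modal-residue frequency within a sequence
#' subset, all strict lower bounds: conserved (> 0.50), well conserved
#' (> 0.70), highly conserved (> 0.90) and invariant (> 0.99).
#'
#' @param conserved,well,highly,invariant Strict lower bounds.
#' @return Named numeric vector of the four thresholds.
#' @export
tier_thresholds <- function(conserved = 0.50, well = 0.70,
                            highly = 0.90, invariant = 0.99) {
  th <- c(conserved = conserved, well = well, highly = highly,
          invariant = invariant)
  if (!(th[1] >= 0.5 && all(diff(th) > 0) && th[4] < 1))
    stop("thresholds must satisfy 0.5 <= conserved < well < highly < invariant < 1",
         call. = FALSE)
  th
}

TIER_LEVELS <- c("invariant", "highly", "well", "conserved",
                 "not_conserved", "unobserved")

#' Per-position amino-acid frequency profile of a sequence subset
#'
#' Counts residues at every unified position among the given sequences.
#' Gaps and `X` are excluded from the denominator: a fragmentary
#' (truncated) sequence is simply unobserved at the positions it lacks and
#' must not dilute conservation.  The modal residue is the most frequent
#' one; ties are broken alphabetically and flagged.
#'
#' @param core A `core_alignment` from [extract_core()].
#' @param subset Identifiers to profile (default: all sequences).
#' @param include_gaps If `TRUE`, gaps and `X` count in the denominator
#'   (all-sequences denominator, for sensitivity analysis only).
#' @return A data frame of class `frequency_profile` with one row per
#'   unified position: `position`, `modal_residue`, `modal_fraction`,
#'   `n_observed`, `tie`.  The full 20-row count matrix is kept in
#'   attribute `"counts"` (amino acids x positions).
#' @export
position_profile <- function(core, subset = NULL, include_gaps = FALSE) {
  stopifnot(inherits(core, "core_alignment"))
  if (is.null(subset)) subset <- core$aln$ids
  if (length(subset) == 0L) stop("subset must be non-empty", call. = FALSE)
  missing <- setdiff(subset, core$aln$ids)
  if (length(missing))
    stop("membership error: identifier(s) absent from core: ",
         paste(missing, collapse = ", "), call. = FALSE)
  m <- as.matrix(core$aln)[subset, , drop = FALSE]
  counts <- apply(m, 2L, function(col)
    table(factor(col, levels = AA_LETTERS)))
  dim(counts) <- c(length(AA_LETTERS), core$n_core)
  rownames(counts) <- AA_LETTERS
  n_obs <- colSums(counts)
  denom <- if (include_gaps) rep(length(subset), core$n_core) else n_obs
  top <- apply(counts, 2L, max)
  modal_idx <- apply(counts, 2L, which.max)  # ties: first = alphabetical
  tie <- colSums(counts == rep(top, each = length(AA_LETTERS))) > 1L & top > 0L
  prof <- data.frame(
    position = seq_len(core$n_core),
    modal_residue = ifelse(n_obs > 0L, AA_LETTERS[modal_idx], NA_character_),
    modal_fraction = ifelse(denom > 0L, top / denom, NA_real_),
    n_observed = as.integer(n_obs),
    tie = tie,
    stringsAsFactors = FALSE)
  rownames(prof) <- NULL
  attr(prof, "counts") <- counts
  attr(prof, "n_subset") <- length(subset)
  class(prof) <- c("frequency_profile", "data.frame")
  prof
}

#' Classify positions into conservation tiers
#'
#' A position's tier is the highest threshold its modal fraction strictly
#' exceeds.  Positions with no observed residue are classified
#' `"unobserved"` and excluded from the summary numerators (the
#' denominator is always the number of core positions).
#'
#' @param profile A `frequency_profile` from [position_profile()].
#' @param thresholds Tier thresholds, see [tier_thresholds()].
#' @return The profile with an added `tier` column (factor over invariant,
#'   highly, well, conserved, not_conserved, unobserved), carrying the
#'   cumulative summary in attribute `"summary"` (see
#'   [conservation_summary()]).
#' @export
classify_tiers <- function(profile, thresholds = tier_thresholds()) {
  stopifnot(inherits(profile, "frequency_profile"))
  f <- profile$modal_fraction
  tier <- rep("not_conserved", nrow(profile))
  tier[!is.na(f) & f > thresholds["conserved"]] <- "conserved"
  tier[!is.na(f) & f > thresholds["well"]] <- "well"
  tier[!is.na(f) & f > thresholds["highly"]] <- "highly"
  tier[!is.na(f) & f > thresholds["invariant"]] <- "invariant"
  tier[profile$n_observed == 0L] <- "unobserved"
  profile$tier <- factor(tier, levels = TIER_LEVELS)
  attr(profile, "thresholds") <- thresholds
  profile
}

# Round half away from zero to `digits` decimals (R's round() rounds half
# to even; tabulated percentages use the conventional half-up rule).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cumulative conservation summary of a classified profile
#'
#' @param profile A profile with a `tier` column ([classify_tiers()]).
#' @param clade Label to attach to the row.
#' @param n_sequences Number of sequences the profile was computed over
#'   (defaults to the profile's own subset size).
#' @param digits Decimal places for the rounded percentages (half-up).
#' @return One-row data frame: `clade`, `n_sequences`, cumulative
#'   `percent_invariant`, `percent_highly`, `percent_well`,
#'   `percent_conserved` (rounded), plus unrounded `raw_*` columns.
#' @export
conservation_summary <- function(profile, clade = "all",
                                 n_sequences = attr(profile, "n_subset"),
                                 digits = 1L) {
  stopifnot("tier" %in% names(profile))
  n_core <- nrow(profile)
  n_inv <- sum(profile$tier == "invariant")
  n_high <- n_inv + sum(profile$tier == "highly")
  n_well <- n_high + sum(profile$tier == "well")
  n_cons <- n_well + sum(profile$tier == "conserved")
  raw <- c(n_inv, n_high, n_well, n_cons) / n_core * 100
  data.frame(clade = clade, n_sequences = n_sequences,
             percent_invariant = round_half_up(raw[1], digits),
             percent_highly = round_half_up(raw[2], digits),
             percent_well = round_half_up(raw[3], digits),
             percent_conserved = round_half_up(raw[4], digits),
             raw_invariant = raw[1], raw_highly = raw[2],
             raw_well = raw[3], raw_conserved = raw[4],
             stringsAsFactors = FALSE)
}

#' Invariant positions of a profile
#'
#' @param profile A `frequency_profile`.
#' @param thresholds Tier thresholds; the invariant bound is used.
#' @return Data frame `position`, `residue`, `modal_fraction` for every
#'   position whose modal fraction strictly exceeds the invariant bound.
#' @export
invariant_positions <- function(profile, thresholds = tier_thresholds()) {
  stopifnot(inherits(profile, "frequency_profile"))
  keep <- !is.na(profile$modal_fraction) &
    profile$modal_fraction > thresholds["invariant"]
  out <- data.frame(position = profile$position[keep],
                    residue = profile$modal_residue[keep],
                    modal_fraction = profile$modal_fraction[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Conservation summaries for a list of clades
#'
#' Computes a [position_profile()] and cumulative tier summary for each
#' requested clade or super-clade label, on that clade's members only.
#' Empty clades are skipped with a warning.
#'
#' @param core A `core_alignment`.
#' @param map A `clade_map`.
#' @param clades Character vector of clade/super-clade labels, or a named
#'   list of label vectors to pool several clades under one row name.
#' @param thresholds Tier thresholds.
#' @param include_gaps Passed to [position_profile()].
#' @return Data frame with one summary row per clade, in request order.
#' @export
summarize_clades <- function(core, map, clades,
                             thresholds = tier_thresholds(),
                             include_gaps = FALSE) {
  stopifnot(inherits(core, "core_alignment"), inherits(map, "clade_map"))
  if (!is.list(clades))
    clades <- stats::setNames(as.list(clades), clades)
  if (is.null(names(clades)))
    names(clades) <- vapply(clades, paste, character(1L), collapse = "+")
  rows <- list()
  for (label in names(clades)) {
    members <- intersect(clade_members(map, clades[[label]]), core$aln$ids)
    if (length(members) == 0L) {
      warning("clade '", label, "' has no members in the core alignment; ",
              "skipped", call. = FALSE)
      next
    }
    prof <- classify_tiers(
      position_profile(core, members, include_gaps = include_gaps),
      thresholds)
    rows[[label]] <- conservation_summary(prof, clade = label,
                                          n_sequences = length(members))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
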