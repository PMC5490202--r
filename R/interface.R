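#' Assess conservation of a residue set clade by clade
#'
#' For each clade and each position of the residue set (e.g. the 18
#' MAX2-interaction residues), reports the clade's consensus (modal)
#' residue, its frequency and tier, and whether the position counts as
#' conserved there.  The default criterion requires both that the modal
#' fraction strictly exceeds the conserved bound (0.50) and that the modal
#' residue equals the reference residue; the two sub-criteria are reported
#' separately so alternative definitions can be audited.
#'
#' @param core A `core_alignment`.
#' @param map A `clade_map`.
#' @param set A `residue_set` (see [read_residue_set()]).
#' @param clades Label vector, or named list of label vectors to pool
#'   several clades into one group (e.g. monilophyte DDKA + DDKB).
#' @param thresholds Tier thresholds ([tier_thresholds()]).
#' @param require_reference If `TRUE` (default) the modal residue must
#'   equal the reference residue; if `FALSE` only the frequency bound is
#'   applied.
#' @param conserved_bound Tier bound the modal fraction must strictly
#'   exceed (default the conserved bound, 0.50).
#' @return A list of class `interface_report`: `positions` (one row per
#'   clade x position with `consensus_residue`, `consensus_fraction`,
#'   `tier`, `meets_frequency`, `matches_reference`, `conserved_flag`) and
#'   `by_clade` (clade, `n_not_conserved`, set size).
#' @export
assess_residue_set <- function(core, map, set, clades,
                               thresholds = tier_thresholds(),
                               require_reference = TRUE,
                               conserved_bound = thresholds["conserved"]) {
  stopifnot(inherits(core, "core_alignment"), inherits(map, "clade_map"))
  if (nrow(set) == 0L) stop("residue set is empty", call. = FALSE)
  if (min(set$position) < 1L || max(set$position) > core$n_core)
    stop("range error: residue-set position(s) outside 1..", core$n_core,
         call. = FALSE)
  if (!is.list(clades))
    clades <- stats::setNames(as.list(clades), clades)
  if (is.null(names(clades)))
    names(clades) <- vapply(clades, paste, character(1L), collapse = "+")
  rows <- list()
  for (label in names(clades)) {
    members <- intersect(clade_members(map, clades[[label]]), core$aln$ids)
    if (length(members) == 0L) {
      warning("clade '", label, "' has no members in the core; skipped",
              call. = FALSE)
      next
    }
    prof <- classify_tiers(position_profile(core, members), thresholds)
    sub <- prof[set$position, , drop = FALSE]
    meets_freq <- !is.na(sub$modal_fraction) &
      sub$modal_fraction > conserved_bound
    matches_ref <- !is.na(sub$modal_residue) &
      sub$modal_residue == set$residue
    flag <- meets_freq & (if (require_reference) matches_ref else TRUE)
    rows[[label]] <- data.frame(
      clade = label, position = set$position,
      reference_residue = set$residue,
      consensus_residue = sub$modal_residue,
      consensus_fraction = sub$modal_fraction,
      tier = as.character(sub$tier),
      meets_frequency = meets_freq,
      matches_reference = matches_ref,
      conserved_flag = flag,
      stringsAsFactors = FALSE)
  }
  positions <- do.call(rbind, rows)
  rownames(positions) <- NULL
  counts <- vapply(split(positions$conserved_flag, positions$clade),
                   function(x) sum(!x), integer(1L))
  by_clade <- data.frame(clade = names(counts),
                         n_not_conserved = as.integer(counts),
                         set_size = nrow(set),
                         stringsAsFactors = FALSE, row.names = NULL)
  by_clade <- by_clade[match(names(clades)[names(clades) %in% by_clade$clade],
                             by_clade$clade), , drop = FALSE]
  rownames(by_clade) <- NULL
  structure(list(positions = positions, by_clade = by_clade),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat("residue-set conservation report\n")
  print(x$by_clade)
  invisible(x)
}

#' Rank clades by number of non-conserved residue-set positions
#'
#' @param report An `interface_report` from [assess_residue_set()].
#' @return The `by_clade` table ordered by `n_not_conserved` descending,
#'   ties broken alphabetically by clade label.
#' @export
compare_clades <- function(report) {
  stopifnot(inherits(report, "interface_report"))
  tab <- report$by_clade
  tab <- tab[order(-tab$n_not_conserved, tab$clade), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
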