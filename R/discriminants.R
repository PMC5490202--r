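#' Discover clade-characteristic residues
#'
#' A (position, amino acid) pair is characteristic of the focal clade when
#' the amino acid occurs in at least `in_min` of the focal clade's observed
#' residues at that position AND in less than `out_max` of each contrast
#' group's observed residues there.  Frequencies are computed over observed
#' (non-gap, non-`X`) residues, consistent with the conservation module.
#' With the default bounds (0.70 / 0.30) at most one amino acid per
#' position can qualify; if looser bounds ever admit several, the one with
#' the highest focal frequency (alphabetical on ties) is kept so positions
#' stay unique.
#'
#' @param core A `core_alignment`.
#' @param map A `clade_map`.
#' @param focal Clade/super-clade label(s) defining the focal group.
#' @param contrasts A single label vector, or a list of label vectors; the
#'   `out_max` bound must hold against every contrast group independently.
#' @param in_min Minimum focal frequency (inclusive), default 0.70.
#' @param out_max Maximum contrast frequency (exclusive), default 0.30.
#' @return A data frame of class `reference_set`, columns `position`,
#'   `residue`, `focal_fraction` and one `fraction_<group>` column per
#'   contrast group; attributes `focal`, `contrasts`, `in_min`, `out_max`.
#' @export
find_characteristic <- function(core, map, focal, contrasts,
                                in_min = 0.70, out_max = 0.30) {
  stopifnot(inherits(core, "core_alignment"), inherits(map, "clade_map"))
  if (!(in_min > 0 && in_min <= 1) || !(out_max >= 0 && out_max <= 1))
    stop("in_min and out_max must lie in (0,1] and [0,1]", call. = FALSE)
  if (!is.list(contrasts)) contrasts <- list(contrasts)
  if (is.null(names(contrasts)))
    names(contrasts) <- vapply(contrasts, paste, character(1L),
                               collapse = "+")
  focal_ids <- intersect(clade_members(map, focal), core$aln$ids)
  if (length(focal_ids) == 0L)
    stop("clade-definition error: focal group is empty", call. = FALSE)
  contrast_ids <- lapply(contrasts, function(cl)
    intersect(clade_members(map, cl), core$aln$ids))
  if (any(lengths(contrast_ids) == 0L))
    stop("clade-definition error: empty contrast group(s): ",
         paste(names(contrasts)[lengths(contrast_ids) == 0L],
               collapse = ", "), call. = FALSE)
  overlap <- intersect(focal_ids, unlist(contrast_ids))
  if (length(overlap))
    stop("clade-definition error: focal and contrast groups overlap (",
         paste(utils::head(overlap, 3L), collapse = ", "), " ...)",
         call. = FALSE)

  freq_of <- function(ids) {
    counts <- attr(position_profile(core, ids), "counts")
    n <- colSums(counts)
    sweep(counts, 2L, pmax(n, 1L), "/")  # freq 0 where nothing observed
  }
  f_focal <- freq_of(focal_ids)
  f_contr <- lapply(contrast_ids, freq_of)

  pass <- f_focal >= in_min
  for (fc in f_contr) pass <- pass & (fc < out_max)
  rows <- list()
  for (p in seq_len(core$n_core)) {
    aas <- AA_LETTERS[pass[, p]]
    if (length(aas) == 0L) next
    if (length(aas) > 1L)
      aas <- aas[order(-f_focal[aas, p], aas)][1L]
    row <- data.frame(position = p, residue = aas,
                      focal_fraction = f_focal[aas, p],
                      stringsAsFactors = FALSE)
    for (g in names(f_contr))
      row[[paste0("fraction_", g)]] <- f_contr[[g]][aas, p]
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), residue = character(),
               focal_fraction = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "focal") <- focal
  attr(out, "contrasts") <- contrasts
  attr(out, "in_min") <- in_min
  attr(out, "out_max") <- out_max
  class(out) <- c("reference_set", "data.frame")
  out
}

#' Score one sequence against a reference residue set
#'
#' @param core A `core_alignment`.
#' @param identifier Sequence to score.
#' @param reference A `reference_set` (from [find_characteristic()]) or any
#'   data frame with `position` and `residue` columns (e.g. a loaded
#'   [read_residue_set()] table).
#' @return One-row data frame: `identifier`, `matched` (reference positions
#'   where the sequence carries the reference amino acid), `observed`
#'   (reference positions where it carries any non-gap, non-`X` residue)
#'   and `total` (size of the reference set), plus `fragmentary` — `TRUE`
#'   when `observed/total < 0.8`, warning that the match count of a
#'   truncated sequence is not comparable to a full-length one.
#' @export
match_score <- function(core, identifier, reference) {
  stopifnot(inherits(core, "core_alignment"))
  if (!identifier %in% core$aln$ids)
    stop("membership error: identifier absent from core: ", identifier,
         call. = FALSE)
  if (nrow(reference) > 0 &&
      (min(reference$position) < 1L || max(reference$position) > core$n_core))
    stop("range error: reference positions outside 1..", core$n_core,
         call. = FALSE)
  row <- strsplit(core$aln$seqs[[identifier]], "")[[1L]]
  res <- row[reference$position]
  observed <- sum(res %in% AA_LETTERS)
  matched <- sum(res == reference$residue)
  total <- nrow(reference)
  data.frame(identifier = identifier, matched = matched,
             observed = observed, total = total,
             fragmentary = total > 0L && observed / total < 0.8,
             stringsAsFactors = FALSE)
}

#' Match table of all sequences against a reference set, by clade
#'
#' Scores every sequence and summarises per clade, reproducing numerically
#' the heat-style per-clade match ranges of a reference-set figure.
#'
#' @param core A `core_alignment`.
#' @param map A `clade_map`.
#' @param reference As in [match_score()].
#' @param complete_only If `TRUE` (default), per-clade min/max ranges are
#'   computed over non-fragmentary sequences only (ranges quoted for
#'   sufficiently complete sequences); all sequences still appear in the
#'   per-sequence table.
#' @return List with `scores` (per-sequence data frame with clade columns)
#'   and `by_clade` (clade, n, min_matched, max_matched, mean_matched).
#' @export
match_table <- function(core, map, reference, complete_only = TRUE) {
  stopifnot(inherits(map, "clade_map"))
  scores <- do.call(rbind, lapply(core$aln$ids, function(id)
    match_score(core, id, reference)))
  scores <- merge(scores, map, by = "identifier", all.x = TRUE,
                  sort = FALSE)
  scores <- scores[match(core$aln$ids, scores$identifier), , drop = FALSE]
  rownames(scores) <- NULL
  use <- if (complete_only) scores[!scores$fragmentary, , drop = FALSE]
         else scores
  use <- use[!is.na(use$clade), , drop = FALSE]
  by_clade <- if (nrow(use)) {
    agg <- split(use$matched, use$clade)
    data.frame(clade = names(agg),
               n = vapply(agg, length, integer(1L)),
               min_matched = vapply(agg, min, numeric(1L)),
               max_matched = vapply(agg, max, numeric(1L)),
               mean_matched = vapply(agg, mean, numeric(1L)),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(clade = character(), n = integer(),
               min_matched = numeric(), max_matched = numeric(),
               mean_matched = numeric(), stringsAsFactors = FALSE)
  }
  list(scores = scores, by_clade = by_clade)
}
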