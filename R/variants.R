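#' Specify a dataset variant (clade removal + position masking)
#'
#' @param name Variant name.
#' @param remove_clades Clade labels whose members are dropped.
#' @param remove_super_clades Super-clade labels whose members are dropped.
#' @param mask_positions Amino-acid (unified) positions to remove; on a
#'   codon alignment each position removes its nucleotide triple.
#' @param output_format `"fasta"` or `"nexus"` (used by [run_variants()]).
#' @return A `variant_spec` list.
#' @export
variant_spec <- function(name, remove_clades = character(),
                         remove_super_clades = character(),
                         mask_positions = integer(),
                         output_format = c("fasta", "nexus")) {
  structure(list(name = name,
                 remove_clades = as.character(remove_clades),
                 remove_super_clades = as.character(remove_super_clades),
                 mask_positions = sort(unique(as.integer(mask_positions))),
                 output_format = match.arg(output_format)),
            class = "variant_spec")
}

#' Apply a variant specification to an alignment
#'
#' Drops the sequences of the removed clades/super-clades and removes the
#' masked positions.  Positions are counted in amino acids: on a protein
#' alignment position p removes column p; on a codon alignment it removes
#' nucleotide columns 3p-2..3p.  The manifest records counts before and
#' after and the exact columns removed, including the scale they were
#' counted on.
#'
#' @param alignment A `protein_alignment` or `codon_alignment`.
#' @param map A `clade_map`.
#' @param spec A [variant_spec()].
#' @return List with `alignment` (the reduced alignment) and `manifest`.
#' @export
apply_variant <- function(alignment, map, spec) {
  stopifnot(inherits(alignment, "cc_alignment"), inherits(map, "clade_map"),
            inherits(spec, "variant_spec"))
  known <- c(map$clade, map$super_clade)
  unknown <- setdiff(c(spec$remove_clades, spec$remove_super_clades), known)
  if (length(unknown))
    stop("variant error: unknown clade label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  drop_ids <- clade_members(map, c(spec$remove_clades,
                                   spec$remove_super_clades))
  keep <- setdiff(alignment$ids, drop_ids)
  if (length(keep) == 0L)
    stop("empty-dataset error: variant '", spec$name,
         "' removes every sequence", call. = FALSE)
  out <- subset_alignment(alignment, keep)
  is_codon <- inherits(alignment, "codon_alignment")
  aa_len <- if (is_codon) alignment$n_columns %/% 3L else alignment$n_columns
  bad <- spec$mask_positions[spec$mask_positions < 1L |
                             spec$mask_positions > aa_len]
  if (length(bad))
    stop("variant error: masked position(s) outside 1..", aa_len, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  cols_removed <- if (is_codon)
    as.integer(outer(c(-2L, -1L, 0L), 3L * spec$mask_positions, "+"))
  else spec$mask_positions
  if (length(cols_removed)) {
    m <- as.matrix(out)[, -cols_removed, drop = FALSE]
    out <- alignment_from_matrix(m, out)
  }
  manifest <- list(
    name = spec$name,
    n_sequences_before = length(alignment$ids),
    n_sequences_after = length(out$ids),
    sequences_removed = unname(intersect(alignment$ids, drop_ids)),
    position_scale = if (is_codon)
      "amino-acid positions on the untrimmed alignment (1 position = 3 nucleotide columns)"
    else "amino-acid positions on the untrimmed alignment",
    positions_masked = spec$mask_positions,
    columns_removed = sort(cols_removed),
    n_columns_before = alignment$n_columns,
    n_columns_after = out$n_columns)
  list(alignment = out, manifest = manifest)
}

#' Clade-deletion jackknife series
#'
#' Builds one dataset per listed clade with that clade's members removed
#' (named `No_<clade>`), plus the full dataset (`Full`), in deterministic
#' order: full first, then the clades in the order given.
#'
#' @param alignment A protein or codon alignment.
#' @param map A `clade_map`.
#' @param clades_to_drop Clade (or super-clade) labels to delete in turn.
#' @return Named list of `apply_variant()` results.
#' @export
jackknife_series <- function(alignment, map, clades_to_drop) {
  stopifnot(inherits(map, "clade_map"))
  for (cl in clades_to_drop)
    if (length(clade_members(map, cl)) == 0L)
      stop("variant error: clade '", cl, "' has no members", call. = FALSE)
  out <- list(Full = apply_variant(alignment, map, variant_spec("Full")))
  for (cl in clades_to_drop) {
    nm <- paste0("No_", cl)
    sc <- cl %in% map$super_clade
    out[[nm]] <- apply_variant(
      alignment, map,
      variant_spec(nm,
                   remove_clades = if (sc) character() else cl,
                   remove_super_clades = if (sc) cl else character()))
  }
  out
}
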