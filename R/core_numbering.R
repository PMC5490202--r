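#' Translate a codon alignment to a protein alignment
#'
#' Applies the standard genetic code codon by codon.  A fully gapped codon
#' (`---`) becomes `-`; any codon containing `N` or a partial gap becomes
#' `X` (the residue cannot be called from a fragmentary codon).  In-frame
#' stop codons are kept as `X` and reported with a warning rather than
#' failing: deposited family alignments occasionally contain mis-called
#' ORF boundaries.
#'
#' @param codon_alignment A [codon_alignment()].
#' @return A [protein_alignment()] with `n_columns/3` columns.
#' @export
translate_codons <- function(codon_alignment) {
  stopifnot(inherits(codon_alignment, "codon_alignment"))
  code <- Biostrings::GENETIC_CODE
  n_codons <- codon_alignment$n_columns %/% 3L
  n_stop <- 0L
  out <- vapply(codon_alignment$seqs, function(s) {
    if (n_codons == 0L) return("")
    codons <- substring(s, seq(1L, by = 3L, length.out = n_codons),
                        seq(3L, by = 3L, length.out = n_codons))
    aa <- character(n_codons)
    plain <- !grepl("[N-]", codons)
    aa[!plain] <- ifelse(codons[!plain] == "---", "-", "X")
    if (any(plain)) {
      tr <- unname(code[codons[plain]])
      stops <- tr == "*"
      n_stop <<- n_stop + sum(stops)
      tr[stops] <- "X"
      aa[plain] <- tr
    }
    paste(aa, collapse = "")
  }, character(1L))
  if (n_stop > 0L)
    warning(n_stop, " in-frame stop codon(s) encoded as 'X'", call. = FALSE)
  new_alignment(out, type = "protein",
                provenance = paste0("translated: ",
                                    codon_alignment$provenance))
}

#' Identify core columns and catalogue insertions
#'
#' A column is a core column when the fraction of sequences with a non-gap
#' character there (an `X` counts as occupied) is at least
#' `occupancy_threshold`.  Core columns are numbered 1..n_core left to
#' right: the unified numbering every downstream report uses.  Residues in
#' non-core columns *between* the first and last core column are recorded
#' per sequence as insertions keyed to the nearest preceding core position
#' ("after position k"); residues in non-core columns before the first or
#' after the last core column are kept as terminal extensions, not
#' insertions.
#'
#' The decomposition is lossless at the residue level: for every sequence,
#' N-terminal extension + core residues + catalogued insertions +
#' C-terminal extension, concatenated in position order, reproduce the
#' original sequence with its gaps removed (see [reconstruct_sequence()]).
#'
#' @param alignment A [protein_alignment()].
#' @param occupancy_threshold Minimum non-gap column occupancy for a core
#'   column, in (0, 1]. The default 0.90 reproduces a manual "present in
#'   almost every sequence" trimming rule.
#' @return A list with components `core` (a `core_alignment`) and
#'   `insertions` (an `insertion_catalogue` data frame with columns
#'   `identifier`, `after_position`, `segment`).
#' @export
extract_core <- function(alignment, occupancy_threshold = 0.90) {
  stopifnot(inherits(alignment, "protein_alignment"))
  if (!(occupancy_threshold > 0 && occupancy_threshold <= 1))
    stop("occupancy_threshold must be in (0, 1]", call. = FALSE)
  m <- as.matrix(alignment)
  n_seq <- nrow(m)
  if (n_seq == 0L) stop("empty-core error: alignment has no sequences",
                        call. = FALSE)
  occ <- colMeans(m != "-")
  core_cols <- which(occ >= occupancy_threshold)
  if (length(core_cols) == 0L)
    stop("empty-core error: no column reaches occupancy ",
         occupancy_threshold, call. = FALSE)
  n_core <- length(core_cols)
  first_core <- core_cols[1L]
  last_core <- core_cols[n_core]

  # preceding core position for every original column (0 = before core)
  prev_core <- cumsum(seq_len(ncol(m)) %in% core_cols)

  ids <- rownames(m)
  term_n <- term_c <- stats::setNames(character(n_seq), ids)
  ins_id <- character(0); ins_after <- integer(0); ins_seg <- character(0)
  noncore_internal <- setdiff(seq(first_core, last_core), core_cols)
  if (first_core > 1L || last_core < ncol(m) || length(noncore_internal)) {
    for (i in seq_len(n_seq)) {
      row <- m[i, ]
      if (first_core > 1L) {
        seg <- row[seq_len(first_core - 1L)]
        term_n[i] <- paste(seg[seg != "-"], collapse = "")
      }
      if (last_core < ncol(m)) {
        seg <- row[seq(last_core + 1L, ncol(m))]
        term_c[i] <- paste(seg[seg != "-"], collapse = "")
      }
      occupied <- noncore_internal[row[noncore_internal] != "-"]
      if (length(occupied)) {
        for (k in split(occupied, prev_core[occupied])) {
          ins_id <- c(ins_id, ids[i])
          ins_after <- c(ins_after, prev_core[k[1L]])
          ins_seg <- c(ins_seg, paste(row[k], collapse = ""))
        }
      }
    }
  }
  core_aln <- alignment_from_matrix(m[, core_cols, drop = FALSE], alignment)
  core <- structure(
    list(aln = core_aln, n_core = n_core,
         column_map = as.integer(core_cols),
         occupancy_threshold = occupancy_threshold,
         terminal_n = term_n, terminal_c = term_c,
         anchor = NULL),
    class = "core_alignment")
  catalogue <- data.frame(identifier = ins_id, after_position = ins_after,
                          segment = ins_seg, stringsAsFactors = FALSE)
  catalogue <- catalogue[order(match(catalogue$identifier, ids),
                               catalogue$after_position), , drop = FALSE]
  rownames(catalogue) <- NULL
  class(catalogue) <- c("insertion_catalogue", "data.frame")
  list(core = core, insertions = catalogue)
}

#' @export
print.core_alignment <- function(x, ...) {
  cat(sprintf("core alignment: %d sequences x %d core positions (occupancy >= %g)\n",
              length(x$aln$ids), x$n_core, x$occupancy_threshold))
  if (!is.null(x$anchor))
    cat(sprintf("anchor: %s (offset %+d)\n", x$anchor$id, x$anchor$offset))
  invisible(x)
}

#' Reassemble a sequence from its core decomposition
#'
#' Concatenates, in order: the N-terminal extension, the core residues
#' interleaved with any catalogued insertions, and the C-terminal
#' extension.  The result equals the original aligned sequence with gaps
#' removed — the lossless-decomposition contract of [extract_core()].
#'
#' @param core A `core_alignment` from [extract_core()].
#' @param insertions The matching `insertion_catalogue`.
#' @param identifier Sequence identifier.
#' @return The reconstructed (ungapped) sequence string.
#' @export
reconstruct_sequence <- function(core, insertions, identifier) {
  stopifnot(inherits(core, "core_alignment"))
  if (!identifier %in% core$aln$ids)
    stop("membership error: identifier absent from core: ", identifier,
         call. = FALSE)
  row <- strsplit(core$aln$seqs[[identifier]], "")[[1L]]
  ins <- insertions[insertions$identifier == identifier, , drop = FALSE]
  pieces <- core$terminal_n[[identifier]]
  pieces <- c(pieces, ins$segment[ins$after_position == 0L])
  for (p in seq_len(core$n_core)) {
    if (row[p] != "-") pieces <- c(pieces, row[p])
    pieces <- c(pieces, ins$segment[ins$after_position == p])
  }
  pieces <- c(pieces, core$terminal_c[[identifier]])
  paste(pieces, collapse = "")
}

#' Report insertions conserved within a clade
#'
#' An insertion is clade-conserved when members of the clade carry an
#' insertion of the same length at the same point (after the same unified
#' position) at a frequency of at least `min_fraction` of the clade.
#'
#' @param catalogue An `insertion_catalogue` from [extract_core()].
#' @param map A `clade_map` covering the catalogued identifiers.
#' @param min_fraction Minimum fraction of clade members carrying the
#'   insertion (default 0.5).
#' @return Data frame with columns `after_position`, `clade`,
#'   `segment_length`, `n_carriers`, `clade_size`, `fraction`.
#' @export
conserved_insertions <- function(catalogue, map, min_fraction = 0.5) {
  stopifnot(inherits(map, "clade_map"))
  empty <- data.frame(after_position = integer(), clade = character(),
                      segment_length = integer(), n_carriers = integer(),
                      clade_size = integer(), fraction = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(catalogue) == 0L) return(empty)
  cat2 <- merge(catalogue, map, by = "identifier")
  if (nrow(cat2) == 0L) return(empty)
  cat2$segment_length <- nchar(cat2$segment)
  # one carrier per (sequence, site, length) even if a sequence has several
  cat2 <- unique(cat2[, c("identifier", "clade", "after_position",
                          "segment_length")])
  agg <- stats::aggregate(identifier ~ clade + after_position + segment_length,
                          data = cat2, FUN = length)
  names(agg)[names(agg) == "identifier"] <- "n_carriers"
  sizes <- table(map$clade)
  agg$clade_size <- as.integer(sizes[agg$clade])
  agg$fraction <- agg$n_carriers / agg$clade_size
  agg <- agg[agg$fraction >= min_fraction, , drop = FALSE]
  agg <- agg[order(agg$after_position, agg$clade), c(
    "after_position", "clade", "segment_length", "n_carriers",
    "clade_size", "fraction")]
  rownames(agg) <- NULL
  agg
}

#' Declare the anchor sequence for residue-number mapping
#'
#' The unified numbering is anchored on a reference sequence (for the
#' D14/KAI2 study alignment, Arabidopsis KAI2, whose residue numbers are
#' +1 relative to the unified scheme, i.e. offset -1).
#'
#' @param core A `core_alignment`.
#' @param identifier Anchor sequence identifier (must be in the core).
#' @param offset Optional fixed integer offset such that
#'   `unified = residue_number + offset`.  When `NULL`, [map_position()]
#'   derives positions by walking the anchor's residues.
#' @return The `core_alignment` with the anchor set.
#' @export
set_anchor <- function(core, identifier, offset = NULL) {
  stopifnot(inherits(core, "core_alignment"))
  if (!identifier %in% core$aln$ids)
    stop("membership error: anchor not in core: ", identifier, call. = FALSE)
  core$anchor <- list(id = identifier,
                      offset = if (is.null(offset)) NULL
                               else as.integer(offset))
  core
}

#' Map an anchor residue number to its unified position
#'
#' With a fixed anchor offset, `unified = residue_number + offset`, checked
#' against the anchor's actual residues.  Without one, the anchor's
#' residues are counted directly: its N-terminal extension and catalogued
#' insertions consume residue numbers without occupying unified positions,
#' and gapped core columns are skipped, so the returned unified position is
#' the core column that physically holds the requested residue.
#'
#' @param core A `core_alignment` with an anchor set (see [set_anchor()]).
#' @param anchor_residue_number Residue number in the anchor's own
#'   (ungapped) numbering, starting at 1.
#' @param insertions Optional `insertion_catalogue`; needed only when the
#'   anchor itself carries catalogued insertions.
#' @return The unified position (integer in 1..n_core).
#' @export
map_position <- function(core, anchor_residue_number, insertions = NULL) {
  stopifnot(inherits(core, "core_alignment"))
  if (is.null(core$anchor))
    stop("mapping error: no anchor sequence set; call set_anchor() first",
         call. = FALSE)
  id <- core$anchor$id
  row <- strsplit(core$aln$seqs[[id]], "")[[1L]]
  if (!is.null(core$anchor$offset)) {
    pos <- as.integer(anchor_residue_number + core$anchor$offset)
    if (pos < 1L || pos > core$n_core)
      stop("mapping error: residue ", anchor_residue_number,
           " maps outside the core (unified ", pos, ")", call. = FALSE)
    if (row[pos] == "-")
      stop("mapping error: anchor is gapped at unified position ", pos,
           call. = FALSE)
    return(pos)
  }
  ins_len <- integer(core$n_core + 1L)  # index p+1 = insertions after p
  if (!is.null(insertions)) {
    ins <- insertions[insertions$identifier == id, , drop = FALSE]
    for (j in seq_len(nrow(ins)))
      ins_len[ins$after_position[j] + 1L] <-
        ins_len[ins$after_position[j] + 1L] + nchar(ins$segment[j])
  }
  # tag every residue of the anchor, in order, with the unified position it
  # occupies (NA for extension / insertion residues)
  tags <- rep(NA_integer_, nchar(core$terminal_n[[id]]) + ins_len[1L])
  for (p in seq_len(core$n_core)) {
    if (row[p] != "-") tags <- c(tags, p)
    if (ins_len[p + 1L] > 0L)
      tags <- c(tags, rep(NA_integer_, ins_len[p + 1L]))
  }
  tags <- c(tags, rep(NA_integer_, nchar(core$terminal_c[[id]])))
  n <- as.integer(anchor_residue_number)
  if (n < 1L || n > length(tags))
    stop("mapping error: anchor has no residue number ", n, call. = FALSE)
  if (is.na(tags[n]))
    stop("mapping error: anchor residue ", n,
         " lies in a terminal extension or insertion, outside the core",
         call. = FALSE)
  tags[n]
}

#' Write a core alignment and its column map
#'
#' @param core A `core_alignment`.
#' @param fasta_path Path for the core FASTA.
#' @param map_path Path for the TSV column map
#'   (`unified_position`, `original_column`).
#' @return Invisibly, the two paths.
#' @export
write_core_alignment <- function(core, fasta_path, map_path) {
  write_alignment(core$aln, fasta_path, format = "fasta")
  utils::write.table(
    data.frame(unified_position = seq_len(core$n_core),
               original_column = core$column_map),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta_path, map = map_path))
}
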