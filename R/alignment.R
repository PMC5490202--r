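#' @keywords internal
"_PACKAGE"

# Residue alphabets. 'X' marks an unknown amino acid (fragmentary,
# transcriptome-derived entries); '-' marks a gap or absent position.
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET_FULL <- c(AA_LETTERS, "X", "-")
NT_ALPHABET_FULL <- c("A", "C", "G", "T", "N", "-")

#' Construct a validated protein alignment
#'
#' A `protein_alignment` is a rectangular, gapped amino-acid matrix held as
#' named sequence strings.  Residues are drawn from the 20 standard amino
#' acids plus `X` (unknown) and `-` (gap/absent).  Lower-case letters are
#' normalised to upper case, and `.` and `?` are normalised to `-`, so that
#' heterogeneous transcriptome-derived entries can be ingested directly.
#'
#' @param seqs Named character vector of aligned sequences (names are the
#'   sequence identifiers).
#' @param provenance Free-text description of where the alignment came from.
#' @return An object of class `protein_alignment` with elements `ids`,
#'   `seqs`, `n_columns` and `provenance`.
#' @examples
#' aln <- protein_alignment(c(a = "MS-K", b = "MSAK"))
#' aln$n_columns
#' @export
protein_alignment <- function(seqs, provenance = "") {
  new_alignment(seqs, type = "protein", provenance = provenance)
}

#' Construct a validated codon alignment
#'
#' Like [protein_alignment()] but over nucleotides `A,C,G,T,N,-`, with the
#' additional requirement that the number of columns is divisible by 3.
#'
#' @inheritParams protein_alignment
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(seqs, provenance = "") {
  new_alignment(seqs, type = "codon", provenance = provenance)
}

new_alignment <- function(seqs, type = c("protein", "codon"),
                          provenance = "") {
  type <- match.arg(type)
  seqs <- unlist(seqs)
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("identifier error: all sequences must carry non-empty identifiers",
         call. = FALSE)
  if (anyDuplicated(ids))
    stop("identifier error: duplicate identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- toupper(seqs)
  seqs <- gsub("[.?]", "-", seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    stop("alignment-shape error: rows have unequal lengths (",
         paste(sort(unique(lens)), collapse = ", "), ")", call. = FALSE)
  n_columns <- if (length(lens)) lens[[1L]] else 0L
  alphabet <- if (type == "protein") AA_ALPHABET_FULL else NT_ALPHABET_FULL
  seen <- unique(strsplit(paste(seqs, collapse = ""), "")[[1L]])
  bad <- setdiff(seen, alphabet)
  if (length(bad))
    stop("alphabet error: symbol(s) not in the ", type, " alphabet: ",
         paste(sort(bad), collapse = " "), call. = FALSE)
  if (type == "codon" && n_columns %% 3L != 0L)
    stop("alignment-shape error: codon alignment length ", n_columns,
         " is not divisible by 3", call. = FALSE)
  structure(
    list(ids = ids, seqs = stats::setNames(as.character(seqs), ids),
         n_columns = as.integer(n_columns), provenance = provenance),
    class = c(paste0(type, "_alignment"), "cc_alignment"))
}

#' @export
print.cc_alignment <- function(x, ...) {
  kind <- if (inherits(x, "codon_alignment")) "codon" else "protein"
  cat(sprintf("%s alignment: %d sequences x %d columns\n",
              kind, length(x$ids), x$n_columns))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
as.matrix.cc_alignment <- function(x, ...) {
  if (length(x$ids) == 0L)
    return(matrix(character(), nrow = 0L, ncol = x$n_columns))
  m <- do.call(rbind, strsplit(x$seqs, ""))
  rownames(m) <- x$ids
  m
}

# Rebuild an alignment from a character matrix, preserving class/provenance.
alignment_from_matrix <- function(m, template) {
  seqs <- apply(m, 1L, paste, collapse = "")
  if (nrow(m) > 0L) names(seqs) <- rownames(m)
  type <- if (inherits(template, "codon_alignment")) "codon" else "protein"
  new_alignment(seqs, type = type, provenance = template$provenance)
}

#' Subset an alignment by sequence identifier
#'
#' @param alignment A `protein_alignment` or `codon_alignment`.
#' @param ids Identifiers to keep, in the order of the original alignment.
#' @return An alignment of the same type containing only `ids`.
#' @export
subset_alignment <- function(alignment, ids) {
  stopifnot(inherits(alignment, "cc_alignment"))
  missing <- setdiff(ids, alignment$ids)
  if (length(missing))
    stop("membership error: identifier(s) absent from alignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  keep <- alignment$ids[alignment$ids %in% ids]
  type <- if (inherits(alignment, "codon_alignment")) "codon" else "protein"
  new_alignment(alignment$seqs[keep], type = type,
                provenance = alignment$provenance)
}
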