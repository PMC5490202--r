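#' Read a protein or codon alignment from FASTA or NEXUS
#'
#' FASTA files are read through Biostrings; NEXUS data matrices (interleaved
#' or sequential) through ape.  ASSUMPTIONS/TREES blocks in NEXUS files are
#' ignored.  The result is validated: rows must be rectangular, identifiers
#' unique and non-empty, and every character within the alphabet of `type`.
#' Sequence order is preserved from the file.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"nexus"`; defaults to a guess from the file
#'   extension (`.nex`/`.nxs` mean NEXUS, anything else FASTA).
#' @param type `"protein"` or `"codon"` (nucleotide, length divisible by 3).
#' @return A [protein_alignment()] or [codon_alignment()].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "nexus"),
                           type = c("protein", "codon")) {
  format <- match.arg(format)
  type <- match.arg(type)
  if (!file.exists(path)) stop("I/O error: no such file: ", path,
                               call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.(nex|nxs|nexus)$", path, ignore.case = TRUE))
      "nexus" else "fasta"
  seqs <- switch(format,
    fasta = {
      ss <- Biostrings::readBStringSet(path)
      stats::setNames(as.character(ss), names(ss))
    },
    nexus = {
      recs <- ape::read.nexus.data(path)
      vapply(recs, paste, character(1L), collapse = "")
    })
  new_alignment(seqs, type = type, provenance = path)
}

#' Write an alignment to FASTA or NEXUS
#'
#' @param alignment A `protein_alignment` or `codon_alignment`.
#' @param path Output path.
#' @param format `"fasta"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path, format = c("fasta", "nexus")) {
  stopifnot(inherits(alignment, "cc_alignment"))
  format <- match.arg(format)
  if (format == "fasta") {
    lines <- as.vector(rbind(paste0(">", alignment$ids),
                             unname(alignment$seqs)))
    writeLines(lines, path)
  } else {
    fmt <- if (inherits(alignment, "codon_alignment")) "dna" else "protein"
    ape::write.nexus.data(strsplit(alignment$seqs, ""), file = path,
                          format = fmt, interleaved = FALSE)
  }
  invisible(path)
}

#' Read a clade map from a tab-separated file
#'
#' Expects a header row and three columns: `identifier`, `clade`,
#' `super_clade`.  Identifiers need not all occur in any particular
#' alignment (membership is validated later, against the alignment each
#' analysis uses), but each identifier may be mapped at most once and each
#' clade must belong to exactly one super-clade.
#'
#' @param path Path to the TSV file.
#' @return A `clade_map`: a data frame with columns `identifier`, `clade`,
#'   `super_clade`.
#' @export
read_clade_map <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  if (ncol(df) < 3L)
    stop("clade map must have columns identifier, clade, super_clade",
         call. = FALSE)
  names(df)[1:3] <- c("identifier", "clade", "super_clade")
  clade_map(df[, 1:3])
}

#' Construct a validated clade map
#'
#' @param df Data frame with columns `identifier`, `clade`, `super_clade`.
#' @return The validated `clade_map`.
#' @export
clade_map <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("identifier", "clade", "super_clade") %in% names(df)))
  df <- df[, c("identifier", "clade", "super_clade")]
  if (anyDuplicated(df$identifier))
    stop("identifier error: identifier(s) mapped more than once: ",
         paste(unique(df$identifier[duplicated(df$identifier)]),
               collapse = ", "), call. = FALSE)
  per_clade <- unique(df[, c("clade", "super_clade")])
  if (anyDuplicated(per_clade$clade))
    stop("hierarchy error: clade(s) assigned to more than one super-clade: ",
         paste(unique(per_clade$clade[duplicated(per_clade$clade)]),
               collapse = ", "), call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("clade_map", "data.frame")
  df
}

#' Members of a clade or super-clade
#'
#' @param map A `clade_map`.
#' @param labels Clade and/or super-clade labels; a sequence is selected if
#'   its clade or its super-clade matches any label.
#' @return Character vector of identifiers.
#' @export
clade_members <- function(map, labels) {
  stopifnot(inherits(map, "clade_map"))
  map$identifier[map$clade %in% labels | map$super_clade %in% labels]
}

#' Read a residue-set table (unified position + reference amino acid)
#'
#' Tab-separated with a header and columns `position`, `residue` and an
#' optional `note`.  Positions must be strictly increasing.
#'
#' @param path Path to the TSV file.
#' @return Data frame of class `residue_set` with columns `position`
#'   (integer), `residue`, `note`.
#' @export
read_residue_set <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  names(df)[1:2] <- c("position", "residue")
  if (!"note" %in% names(df)) df$note <- ""
  residue_set(data.frame(position = as.integer(df$position),
                         residue = toupper(df$residue),
                         note = df$note, stringsAsFactors = FALSE))
}

#' Construct a validated residue set
#'
#' @param df Data frame with integer `position` and single-letter `residue`.
#' @return The validated `residue_set`.
#' @export
residue_set <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("position", "residue") %in% names(df)))
  if (!"note" %in% names(df)) df$note <- ""
  df$position <- as.integer(df$position)
  if (is.unsorted(df$position, strictly = TRUE))
    stop("residue-set positions must be strictly increasing", call. = FALSE)
  if (any(!df$residue %in% AA_LETTERS))
    stop("alphabet error: invalid reference residue(s): ",
         paste(setdiff(df$residue, AA_LETTERS), collapse = " "),
         call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("residue_set", "data.frame")
  df
}

#' Write a tabular report as TSV plus a JSON mirror
#'
#' Every report the pipeline produces is written twice: a tab-separated
#' table for spreadsheets and a JSON mirror (same rows, unrounded values)
#' for programmatic use.  Re-reading the TSV with [read_report()] yields
#' identical values.
#'
#' @param report A data frame.
#' @param path Output path for the TSV; the JSON mirror is written next to
#'   it with extension `.json`.
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_report <- function(report, path) {
  report <- as.data.frame(report)
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  json_path <- sub("\\.[A-Za-z]+$", "", path)
  json_path <- paste0(json_path, ".json")
  jsonlite::write_json(report, json_path, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  invisible(c(tsv = path, json = json_path))
}

#' Read back a TSV report written by [write_report()]
#'
#' @param path Path to the TSV file.
#' @return A data frame.
#' @export
read_report <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
}
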