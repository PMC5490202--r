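#' Build a validated pipeline run configuration
#'
#' Collects every parameter of an end-to-end run.  Values can come from a
#' YAML file ([read_run_config()]) or be given directly; validation happens
#' before any computation so a bad configuration fails fast.
#'
#' @param alignment Path to the input alignment (FASTA or NEXUS).
#' @param clade_map Path to the clade-map TSV.
#' @param residue_set Optional path to a residue-set TSV (e.g. the MAX2
#'   interface) for the interface report.
#' @param alignment_type `"protein"` or `"codon"`; codon alignments are
#'   translated before core extraction.
#' @param occupancy_threshold Core-column occupancy threshold, in (0, 1].
#' @param thresholds Tier thresholds ([tier_thresholds()]).
#' @param in_min,out_max Characteristic-residue bounds, in (0, 1].
#' @param profile_clades Labels (or named list of label vectors) for the
#'   conservation summary rows; default: every super-clade then every
#'   clade in the map.
#' @param focal,contrasts Focal and contrast groups for the discriminant
#'   report; default: first super-clade vs the rest.
#' @param interface_clades Clades for the interface report; default: all.
#' @param jackknife_clades Clades deleted in turn for the variant series;
#'   default none.
#' @param mask_positions Positions removed from every variant dataset.
#' @param out_dir Output directory (created if absent).
#' @param seed Seed for any synthetic step.
#' @param anchor,anchor_offset Optional anchor sequence id and offset for
#'   unified-position reports.
#' @return A validated `run_config` list.
#' @export
run_config <- function(alignment, clade_map, residue_set = NULL,
                       alignment_type = c("protein", "codon"),
                       occupancy_threshold = 0.90,
                       thresholds = tier_thresholds(),
                       in_min = 0.70, out_max = 0.30,
                       profile_clades = NULL,
                       focal = NULL, contrasts = NULL,
                       interface_clades = NULL,
                       jackknife_clades = character(),
                       mask_positions = integer(),
                       out_dir = "cladecons_out", seed = 1L,
                       anchor = NULL, anchor_offset = NULL) {
  alignment_type <- match.arg(alignment_type)
  for (p in c(alignment, clade_map, residue_set))
    if (!is.null(p) && !file.exists(p))
      stop("configuration error: input file not found: ", p, call. = FALSE)
  if (!(occupancy_threshold > 0 && occupancy_threshold <= 1))
    stop("configuration error: occupancy_threshold must be in (0, 1]",
         call. = FALSE)
  if (!(in_min > 0 && in_min <= 1) || !(out_max > 0 && out_max <= 1))
    stop("configuration error: in_min and out_max must be in (0, 1]",
         call. = FALSE)
  structure(list(alignment = alignment, clade_map = clade_map,
                 residue_set = residue_set,
                 alignment_type = alignment_type,
                 occupancy_threshold = occupancy_threshold,
                 thresholds = thresholds, in_min = in_min,
                 out_max = out_max, profile_clades = profile_clades,
                 focal = focal, contrasts = contrasts,
                 interface_clades = interface_clades,
                 jackknife_clades = jackknife_clades,
                 mask_positions = as.integer(mask_positions),
                 out_dir = out_dir, seed = as.integer(seed),
                 anchor = anchor, anchor_offset = anchor_offset),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `thresholds` may be a
#' mapping with keys `conserved`, `well`, `highly`, `invariant`.  Paths are
#' resolved relative to the YAML file's directory.
#'
#' @param path Path to the YAML configuration.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("configuration error: config file not found: ", path,
         call. = FALSE)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  th <- if (is.null(y$thresholds)) tier_thresholds()
        else do.call(tier_thresholds, y$thresholds)
  run_config(
    alignment = resolve(y$alignment), clade_map = resolve(y$clade_map),
    residue_set = resolve(y$residue_set),
    alignment_type = y$alignment_type %||% "protein",
    occupancy_threshold = y$occupancy_threshold %||% 0.90,
    thresholds = th,
    in_min = y$in_min %||% 0.70, out_max = y$out_max %||% 0.30,
    profile_clades = y$profile_clades,
    focal = y$focal, contrasts = y$contrasts,
    interface_clades = y$interface_clades,
    jackknife_clades = y$jackknife_clades %||% character(),
    mask_positions = y$mask_positions %||% integer(),
    out_dir = y$out_dir %||% "cladecons_out",
    seed = y$seed %||% 1L,
    anchor = y$anchor, anchor_offset = y$anchor_offset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_inputs <- function(config) {
  aln <- read_alignment(config$alignment, type = config$alignment_type)
  codon <- NULL
  if (config$alignment_type == "codon") {
    codon <- aln
    aln <- translate_codons(aln)
  }
  map <- read_clade_map(config$clade_map)
  cx <- extract_core(aln, config$occupancy_threshold)
  core <- cx$core
  if (!is.null(config$anchor))
    core <- set_anchor(core, config$anchor, config$anchor_offset)
  list(alignment = aln, codon = codon, map = map, core = core,
       insertions = cx$insertions)
}

run_manifest <- function(config, extra = list()) {
  inputs <- c(alignment = config$alignment, clade_map = config$clade_map,
              residue_set = config$residue_set)
  c(list(package = "cladecons",
         version = as.character(utils::packageVersion("cladecons")),
         parameters = config[setdiff(names(config),
                                     c("out_dir"))],
         input_md5 = as.list(tools::md5sum(inputs[!is.na(inputs)]))),
    extra)
}

ensure_out <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  config$out_dir
}

log_msg <- function(...) message("[cladecons] ", ...)

#' Run the conservation-profile stage
#'
#' Core extraction, per-position tier table and per-clade cumulative
#' conservation summaries, written to `out_dir` as TSV + JSON together
#' with the core alignment, column map, insertion catalogue and a run
#' manifest.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with `core`, `insertions`, `summary` (the
#'   clade summary table) and `tier_table`.
#' @export
run_profile <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- ensure_out(config)
  env <- load_inputs(config)
  log_msg("core: ", env$core$n_core, " positions from ",
          env$alignment$n_columns, " columns (occupancy >= ",
          config$occupancy_threshold, ")")
  clades <- config$profile_clades %||%
    c(unique(env$map$super_clade), unique(env$map$clade))
  summary <- summarize_clades(env$core, env$map, clades,
                              thresholds = config$thresholds)
  whole <- classify_tiers(position_profile(env$core), config$thresholds)
  tier_table <- whole[, c("position", "modal_residue", "modal_fraction",
                          "n_observed", "tie", "tier")]
  tier_table$tier <- as.character(tier_table$tier)
  write_core_alignment(env$core, file.path(out, "core_alignment.fasta"),
                       file.path(out, "core_column_map.tsv"))
  write_report(env$insertions, file.path(out, "insertion_catalogue.tsv"))
  write_report(summary, file.path(out, "conservation_summary.tsv"))
  write_report(tier_table, file.path(out, "position_tiers.tsv"))
  jsonlite::write_json(run_manifest(config,
                                    list(n_core = env$core$n_core)),
                       file.path(out, "manifest_profile.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(core = env$core, insertions = env$insertions,
                 summary = summary, tier_table = tier_table))
}

#' Run the discriminant (characteristic-residue) stage
#'
#' Derives the characteristic residue set of the focal group against the
#' contrast group(s) and scores every sequence against it, writing the
#' reference set, the per-sequence match table and the per-clade match
#' ranges.
#'
#' @param config A `run_config` with `focal` and `contrasts` set (defaults
#'   to first super-clade vs all others).
#' @return Invisibly, a list with `reference`, `scores`, `by_clade`.
#' @export
run_discriminants <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- ensure_out(config)
  env <- load_inputs(config)
  supers <- unique(env$map$super_clade)
  focal <- config$focal %||% supers[1L]
  contrasts <- config$contrasts %||% list(setdiff(supers, supers[1L]))
  ref <- find_characteristic(env$core, env$map, focal, contrasts,
                             in_min = config$in_min,
                             out_max = config$out_max)
  log_msg("characteristic set: ", nrow(ref), " positions (",
          paste(unlist(focal), collapse = "+"), " vs ",
          length(contrasts), " contrast group(s))")
  mt <- match_table(env$core, env$map, ref)
  write_report(as.data.frame(ref), file.path(out, "reference_set.tsv"))
  write_report(mt$scores, file.path(out, "match_scores.tsv"))
  write_report(mt$by_clade, file.path(out, "match_ranges.tsv"))
  jsonlite::write_json(run_manifest(config, list(n_reference = nrow(ref))),
                       file.path(out, "manifest_discriminants.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(reference = ref, scores = mt$scores,
                 by_clade = mt$by_clade))
}

#' Run the residue-set (interface) assessment stage
#'
#' @param config A `run_config` with `residue_set` pointing at a TSV of
#'   (position, reference residue) rows.
#' @return Invisibly, the `interface_report`.
#' @export
run_interface <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$residue_set))
    stop("configuration error: run_interface requires residue_set",
         call. = FALSE)
  out <- ensure_out(config)
  env <- load_inputs(config)
  set <- read_residue_set(config$residue_set)
  clades <- config$interface_clades %||% unique(env$map$clade)
  rep <- assess_residue_set(env$core, env$map, set, clades,
                            thresholds = config$thresholds)
  write_report(rep$positions, file.path(out, "interface_positions.tsv"))
  write_report(compare_clades(rep), file.path(out, "interface_ranking.tsv"))
  jsonlite::write_json(run_manifest(config, list(set_size = nrow(set))),
                       file.path(out, "manifest_interface.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rep)
}

#' Run the dataset-variant stage
#'
#' Writes the full dataset plus one clade-deletion jackknife dataset per
#' clade in `jackknife_clades`, each with its JSON manifest, applying any
#' `mask_positions` to every dataset.
#'
#' @param config A `run_config`.
#' @return Invisibly, the named list of variants.
#' @export
run_variants <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- ensure_out(config)
  aln <- read_alignment(config$alignment, type = config$alignment_type)
  map <- read_clade_map(config$clade_map)
  series <- jackknife_series(aln, map, config$jackknife_clades)
  for (nm in names(series)) {
    v <- series[[nm]]
    if (length(config$mask_positions)) {
      spec <- variant_spec(nm, mask_positions = config$mask_positions)
      v <- apply_variant(v$alignment, map, spec)
      v$manifest$n_sequences_before <- series[[nm]]$manifest$n_sequences_before
      v$manifest$sequences_removed <- series[[nm]]$manifest$sequences_removed
      series[[nm]] <- v
    }
    write_alignment(v$alignment,
                    file.path(out, paste0("dataset_", nm, ".fasta")))
    jsonlite::write_json(v$manifest,
                         file.path(out, paste0("dataset_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  log_msg("variants: ", length(series), " dataset(s) written")
  invisible(series)
}

#' Run the complete pipeline
#'
#' Profile, discriminants, interface (when a residue set is configured)
#' and variants (when jackknife clades are configured), in that order,
#' into one output directory.  Given identical inputs and configuration
#' the bundle is reproduced identically.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list of the stage results.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  res <- list(profile = run_profile(config),
              discriminants = run_discriminants(config))
  if (!is.null(config$residue_set))
    res$interface <- run_interface(config)
  if (length(config$jackknife_clades))
    res$variants <- run_variants(config)
  invisible(res)
}

#' Write a synthetic dataset to disk
#'
#' Convenience wrapper used by the `simulate` subcommand: generates a
#' family from a [synthetic_spec()] and writes the alignment (FASTA), the
#' clade map (TSV) and the truth tables.
#'
#' @param spec A `synthetic_spec`.
#' @param out_dir Output directory.
#' @return Invisibly, the [generate_family()] result.
#' @export
write_synthetic <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fam <- generate_family(spec)
  write_alignment(fam$alignment, file.path(out_dir, "synthetic.fasta"))
  utils::write.table(fam$map, file.path(out_dir, "clade_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_report(fam$truth$tiers, file.path(out_dir, "truth_tiers.tsv"))
  write_report(fam$truth$insertions,
               file.path(out_dir, "truth_insertions.tsv"))
  if (!is.null(fam$truth$diagnostic))
    write_report(fam$truth$diagnostic,
                 file.path(out_dir, "truth_diagnostic.tsv"))
  invisible(fam)
}
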