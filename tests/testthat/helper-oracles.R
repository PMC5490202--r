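# Brute-force oracles, written independently of the package internals:
# plain loops over a character matrix, no shared helpers.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# per-column modal residue / fraction / n_observed by direct counting
oracle_profile <- function(mat) {
  t(apply(mat, 2L, function(col) {
    col <- col[!col %in% c("-", "X")]
    if (length(col) == 0L)
      return(c(modal = NA, fraction = NA, n = 0))
    tab <- table(col)
    best <- sort(names(tab)[tab == max(tab)])[1L]  # alphabetical tie-break
    c(modal = best, fraction = unname(tab[best]) / length(col),
      n = length(col))
  }))
}

oracle_tier <- function(frac, n_obs,
                        th = c(0.50, 0.70, 0.90, 0.99)) {
  if (n_obs == 0) return("unobserved")
  if (frac > th[4]) "invariant"
  else if (frac > th[3]) "highly"
  else if (frac > th[2]) "well"
  else if (frac > th[1]) "conserved"
  else "not_conserved"
}

# brute-force characteristic-residue search: every position x amino acid
oracle_characteristic <- function(mat_focal, mats_contrast,
                                  in_min = 0.7, out_max = 0.3) {
  hits <- list()
  for (p in seq_len(ncol(mat_focal))) {
    obs_f <- mat_focal[, p]; obs_f <- obs_f[!obs_f %in% c("-", "X")]
    if (length(obs_f) == 0L) next
    for (aa in AA20) {
      if (sum(obs_f == aa) / length(obs_f) < in_min) next
      ok <- TRUE
      for (mc in mats_contrast) {
        obs_c <- mc[, p]; obs_c <- obs_c[!obs_c %in% c("-", "X")]
        fr <- if (length(obs_c)) sum(obs_c == aa) / length(obs_c) else 0
        if (fr >= out_max) { ok <- FALSE; break }
      }
      if (ok) hits[[length(hits) + 1L]] <- c(p, aa)
    }
  }
  if (!length(hits)) return(data.frame(position = integer(),
                                       residue = character()))
  data.frame(position = as.integer(vapply(hits, `[`, "", 1L)),
             residue = vapply(hits, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

# random gapped protein alignment as a named character vector
random_aln <- function(n_seq, n_col, p_gap = 0.15, p_x = 0.05,
                       alphabet_size = 4L) {
  pool <- AA20[seq_len(alphabet_size)]  # small alphabet: frequent ties
  m <- matrix(sample(pool, n_seq * n_col, replace = TRUE), n_seq, n_col)
  m[matrix(stats::runif(n_seq * n_col) < p_gap, n_seq, n_col)] <- "-"
  m[matrix(stats::runif(n_seq * n_col) < p_x, n_seq, n_col)] <- "X"
  stats::setNames(apply(m, 1L, paste, collapse = ""),
                  sprintf("s%02d", seq_len(n_seq)))
}

# a core alignment covering every column that has at least one residue
core_of <- function(seqs) {
  extract_core(protein_alignment(seqs), occupancy_threshold = 1e-9)$core
}
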