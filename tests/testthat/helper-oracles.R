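suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

# Per-base boolean-mask coverage oracle: fraction of window bases covered by
# any TE interval (1-based closed coordinates, same contig assumed).
oracle_coverage <- function(win_start, win_end, te_starts, te_ends) {
  mask <- logical(win_end - win_start + 1L)
  for (i in seq_along(te_starts)) {
    s <- max(te_starts[i], win_start)
    e <- min(te_ends[i], win_end)
    if (s <= e) mask[(s - win_start + 1L):(e - win_start + 1L)] <- TRUE
  }
  mean(mask)
}

# Independent brute-force motif scanner: literal position-by-position
# membership check.
oracle_motif_hits <- function(protein, columns) {
  chars <- strsplit(protein, "")[[1]]
  k <- length(columns)
  hits <- integer(0)
  if (length(chars) < k) return(hits)
  for (s in seq_len(length(chars) - k + 1L)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      cl <- columns[[j]]
      if (!is.null(cl) && !(chars[s + j - 1L] %in% cl)) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# Closed-form Welch two-sample t (textbook formulas).
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  tt <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

# Compact simulation used by several tests: one small contig, a single
# cluster, no TE background unless asked.
quick_sim <- function(seed, n_genes = 2, n_pseudogenes = 1, divergence = 0,
                      bg = 0, contig = 5e5, cluster = n_genes + n_pseudogenes,
                      ...) {
  simulate_genome(sim_config(
    seed = seed, contig_lengths = c(c1 = contig), n_genes = n_genes,
    n_pseudogenes = n_pseudogenes, cluster_size = cluster,
    cluster_margin_bp = 6e4, background_te_density = bg,
    divergence = divergence, ...))
}

# Map a planted lesion kind to the classifier reason it must produce.
lesion_reason <- c(frameshift_indel = "frameshift_indel",
                   nonsense_substitution = "premature_stop",
                   exon_deletion = "missing_exon")
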